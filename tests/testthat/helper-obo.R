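# Hand-built mini-ontologies and corpora used across test files.

obo_header <- function(name = "test") {
  c("format-version: 1.2", paste0("ontology: ", name))
}

term <- function(id, name, is_a = character(), xof = list(), extra = character()) {
  c(
    "",
    "[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    if (length(is_a)) paste0("is_a: ", is_a) else character(),
    vapply(xof, function(p) paste0("intersection_of: ", paste(p, collapse = " ")),
           character(1)),
    extra
  )
}

# GO-like side of the curated worked examples: a B cell apoptosis positive
# regulator, a growth negative regulator, and an apoptosis negative regulator.
worked_go_lines <- function() {
  c(
    obo_header("go-mini"),
    term("GO:0008150", "biological_process"),
    term("GO:0065007", "biological regulation", is_a = "GO:0008150"),
    term("GO:0006915", "apoptotic process", is_a = "GO:0008150"),
    term("GO:0001783", "B cell apoptotic process", is_a = "GO:0006915"),
    term("GO:0070242", "thymocyte apoptotic process", is_a = "GO:0006915"),
    term("GO:0040007", "growth", is_a = "GO:0008150"),
    term("GO:0002904", "positive regulation of B cell apoptotic process",
         is_a = "GO:0065007",
         xof = list("GO:0065007", c("positively_regulates", "GO:0001783"))),
    term("GO:0045926", "negative regulation of growth",
         is_a = "GO:0065007",
         xof = list("GO:0065007", c("negatively_regulates", "GO:0040007"))),
    term("GO:0043066", "negative regulation of apoptotic process",
         is_a = "GO:0065007",
         xof = list("GO:0065007", c("negatively_regulates", "GO:0006915")))
  )
}

# Phenotype side: EQ-defined regulatory phenotypes plus an undefined
# specific subclass (for subclass-inferred matching).
worked_pheno_lines <- function() {
  c(
    obo_header("pheno-mini"),
    term("MP:0000001", "mammalian phenotype"),
    term("PATO:0000001", "quality"),
    term("PATO:0000912", "increased rate", is_a = "PATO:0000001"),
    term("PATO:0000911", "decreased rate", is_a = "PATO:0000001"),
    term("PATO:0000460", "abnormal", is_a = "PATO:0000001"),
    term("MP:0008782", "increased B cell apoptosis", is_a = "MP:0000001",
         xof = list("MP:0000001", c("phenotype_of", "GO:0001783"),
                    c("has_quality", "PATO:0000912"),
                    c("has_quality", "PATO:0000460"))),
    term("MP:0009541", "increased thymocyte apoptosis", is_a = "MP:0000001",
         xof = list("MP:0000001", c("phenotype_of", "GO:0070242"),
                    c("has_quality", "PATO:0000912"),
                    c("has_quality", "PATO:0000460"))),
    term("MP:0001732", "postnatal growth retardation", is_a = "MP:0000001",
         xof = list("MP:0000001", c("phenotype_of", "GO:0040007"),
                    c("has_quality", "PATO:0000911"),
                    c("has_quality", "PATO:0000460"))),
    term("MP:0006043", "decreased apoptosis", is_a = "MP:0000001",
         xof = list("MP:0000001", c("phenotype_of", "GO:0006915"),
                    c("has_quality", "PATO:0000911"),
                    c("has_quality", "PATO:0000460"))),
    term("MP:0008236", "decreased susceptibility to neuronal excitotoxicity",
         is_a = "MP:0006043")
  )
}

worked_graphs <- function() {
  list(go = parse_obo(worked_go_lines()), pheno = parse_obo(worked_pheno_lines()))
}

# gene-level corpora matching the curated examples
worked_corpora <- function() {
  functions <- annotation_corpus(data.frame(
    gene = c("Fnip1", "Gpc3", "Bag6"),
    class_id = c("GO:0002904", "GO:0045926", "GO:0043066"),
    evidence = "IDA", stringsAsFactors = FALSE
  ))
  phenotypes <- annotation_corpus(data.frame(
    gene = c("Fnip1", "Gpc3", "Bag6"),
    class_id = c("MP:0008782", "MP:0001732", "MP:0008236"),
    stringsAsFactors = FALSE
  ))
  list(functions = functions, phenotypes = phenotypes)
}

# random DAG fixture: n classes, parents sampled among earlier classes
random_dag_lines <- function(n, seed, prefix = "T") {
  withr::with_seed(seed, {
    ids <- sprintf("%s:%04d", prefix, seq_len(n))
    lines <- c(obo_header("dag"), term(ids[1], "root"))
    for (i in seq(2, n)) {
      parents <- sample(ids[seq_len(i - 1)], min(i - 1, sample(1:2, 1)))
      lines <- c(lines, term(ids[i], paste("node", i), is_a = parents))
    }
    lines
  })
}
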