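#' Specification for synthetic fixtures
#'
#' Declares the size and planted structure of a synthetic study system: a
#' GO-like process ontology with regulation classes, an MP-like phenotype
#' ontology with Entity-Quality definitions over the processes, annotation
#' corpora with rule-consistent (and optionally rule-violating) gene
#' annotations, and an interaction network carrying phenotype-similarity
#' signal. Identical spec + seed yields byte-identical serialised outputs.
#'
#' @param n_processes Number of process classes in the GO-like ontology.
#' @param n_regulators_pos,n_regulators_neg Number of positive / negative
#'   regulation classes; each regulates a distinct process, so their sum may
#'   not exceed `n_processes`.
#' @param eq_coverage Fraction of processes given increased / decreased /
#'   abnormal phenotype classes (all three per covered process).
#' @param n_genes Number of genes in the annotation corpora.
#' @param annotation_noise Fraction of genes receiving one random extra
#'   phenotype class.
#' @param inconsistency_rate Fraction of genes receiving a planted
#'   rule-violating function/phenotype pair.
#' @param seed Integer seed controlling every random choice.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_processes = 50, n_regulators_pos = 20,
                         n_regulators_neg = 20, eq_coverage = 1,
                         n_genes = 100, annotation_noise = 0,
                         inconsistency_rate = 0, seed = 1) {
  stopifnot(
    n_processes >= 0, n_regulators_pos >= 0, n_regulators_neg >= 0,
    n_genes >= 0,
    eq_coverage >= 0, eq_coverage <= 1,
    annotation_noise >= 0, annotation_noise <= 1,
    inconsistency_rate >= 0, inconsistency_rate <= 1
  )
  if (n_regulators_pos + n_regulators_neg > n_processes) {
    stop("each regulator needs a distinct regulated process: ",
         "n_regulators_pos + n_regulators_neg must not exceed n_processes")
  }
  structure(
    list(
      n_processes = as.integer(n_processes),
      n_regulators_pos = as.integer(n_regulators_pos),
      n_regulators_neg = as.integer(n_regulators_neg),
      eq_coverage = eq_coverage,
      n_genes = as.integer(n_genes),
      annotation_noise = annotation_noise,
      inconsistency_rate = inconsistency_rate,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

obo_stanza <- function(id, name, is_a = character(), xof = list()) {
  c(
    "",
    "[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    if (length(is_a)) paste0("is_a: ", is_a) else character(),
    vapply(xof, function(p) paste0("intersection_of: ", paste(p, collapse = " ")),
           character(1))
  )
}

fixture_go_root <- function() "GO:0008150"
fixture_regulation_genus <- function() "GO:0065007"
fixture_mp_root <- function() "MP:0000001"

#' Generate a GO-like and an MP-like toy ontology with planted structure
#'
#' The GO-like ontology has a process root, a 'biological regulation' class,
#' `n_processes` process classes arranged in a random DAG (parents sampled
#' among earlier classes, so acyclicity holds by construction), and
#' regulation classes carrying `intersection_of` logical definitions
#' (`positively_regulates` / `negatively_regulates` some process), each over
#' a distinct process. The MP-like ontology declares the PATO quality
#' classes of the default [quality_config()] and, for a fraction
#' `eq_coverage` of processes, an abnormal-, increased- and decreased-rate
#' phenotype class with Entity-Quality logical definitions; the directional
#' classes are subclasses of the abnormal one and carry the abnormal quality
#' as a modifier.
#'
#' @param spec A [fixture_spec()].
#' @return List with `go` and `pheno` (`ontology_graph`s), `go_obo` /
#'   `pheno_obo` (serialised OBO lines), and `plant_log` (data frames
#'   `regulations` and `eq` recording every planted axiom).
#' @export
make_toy_ontologies <- function(spec) {
  local_seed(spec$seed, {
    root <- fixture_go_root()
    reg_genus <- fixture_regulation_genus()
    procs <- sprintf("GO:1%06d", seq_len(spec$n_processes))

    go_lines <- c(
      "format-version: 1.2",
      "ontology: go-fixture",
      obo_stanza(root, "biological_process"),
      obo_stanza(reg_genus, "biological regulation", is_a = root)
    )
    for (i in seq_len(spec$n_processes)) {
      pool <- c(root, procs[seq_len(i - 1L)])
      k <- min(length(pool), sample(1:2, 1L))
      parents <- sample(pool, k)
      go_lines <- c(go_lines,
                    obo_stanza(procs[[i]], paste("process", i), is_a = parents))
    }
    n_reg <- spec$n_regulators_pos + spec$n_regulators_neg
    regulated <- if (n_reg > 0L) sample(procs, n_reg) else character()
    reg_log <- NULL
    if (spec$n_regulators_pos > 0L) {
      for (i in seq_len(spec$n_regulators_pos)) {
        id <- sprintf("GO:2%06d", i)
        target <- regulated[[i]]
        go_lines <- c(go_lines, obo_stanza(
          id, paste0("positive regulation of ", sub("^GO:", "process ", target)),
          is_a = reg_genus,
          xof = list(reg_genus, c("positively_regulates", target))
        ))
        reg_log <- rbind(reg_log, data.frame(
          regulator = id, regulated = target, sign = "positive",
          stringsAsFactors = FALSE
        ))
      }
    }
    if (spec$n_regulators_neg > 0L) {
      for (i in seq_len(spec$n_regulators_neg)) {
        id <- sprintf("GO:3%06d", i)
        target <- regulated[[spec$n_regulators_pos + i]]
        go_lines <- c(go_lines, obo_stanza(
          id, paste0("negative regulation of ", sub("^GO:", "process ", target)),
          is_a = reg_genus,
          xof = list(reg_genus, c("negatively_regulates", target))
        ))
        reg_log <- rbind(reg_log, data.frame(
          regulator = id, regulated = target, sign = "negative",
          stringsAsFactors = FALSE
        ))
      }
    }
    if (is.null(reg_log)) {
      reg_log <- data.frame(regulator = character(), regulated = character(),
                            sign = character(), stringsAsFactors = FALSE)
    }

    mp_root <- fixture_mp_root()
    q <- quality_config()
    pheno_lines <- c(
      "format-version: 1.2",
      "ontology: pheno-fixture",
      obo_stanza(mp_root, "phenotype fixture root"),
      obo_stanza("PATO:0000001", "quality"),
      obo_stanza(q$increased_qualities[[1]], "increased rate",
                 is_a = "PATO:0000001"),
      obo_stanza(q$decreased_qualities[[1]], "decreased rate",
                 is_a = "PATO:0000001"),
      obo_stanza(q$abnormal_qualities[[1]], "abnormal", is_a = "PATO:0000001")
    )
    n_eq <- round(spec$eq_coverage * spec$n_processes)
    covered <- if (n_eq > 0L) sort(sample(procs, n_eq)) else character()
    eq_log <- NULL
    for (i in seq_along(covered)) {
      p <- covered[[i]]
      pn <- sub("^GO:", "process ", p)
      abn <- sprintf("MP:1%06d", i)
      inc <- sprintf("MP:2%06d", i)
      dec <- sprintf("MP:3%06d", i)
      pheno_lines <- c(
        pheno_lines,
        obo_stanza(abn, paste0("abnormal ", pn), is_a = mp_root, xof = list(
          mp_root, c("phenotype_of", p),
          c("has_quality", q$abnormal_qualities[[1]])
        )),
        obo_stanza(inc, paste0("increased ", pn), is_a = abn, xof = list(
          mp_root, c("phenotype_of", p),
          c("has_quality", q$increased_qualities[[1]]),
          c("has_quality", q$abnormal_qualities[[1]])
        )),
        obo_stanza(dec, paste0("decreased ", pn), is_a = abn, xof = list(
          mp_root, c("phenotype_of", p),
          c("has_quality", q$decreased_qualities[[1]]),
          c("has_quality", q$abnormal_qualities[[1]])
        ))
      )
      eq_log <- rbind(eq_log, data.frame(
        phenotype_class = c(abn, inc, dec), entity = p,
        direction = c("abnormal", "increased", "decreased"),
        stringsAsFactors = FALSE
      ))
    }
    if (is.null(eq_log)) {
      eq_log <- data.frame(phenotype_class = character(), entity = character(),
                           direction = character(), stringsAsFactors = FALSE)
    }

    list(
      go = parse_obo(go_lines),
      pheno = parse_obo(pheno_lines),
      go_obo = go_lines,
      pheno_obo = pheno_lines,
      plant_log = list(regulations = reg_log, eq = eq_log, processes = procs)
    )
  })
}

#' Generate annotation corpora with planted consistent / inconsistent pairs
#'
#' Each gene draws 1-3 function classes from the rule-bearing functions
#' (regulators and processes). Phenotype annotations are then generated by
#' applying the correspondence rules to those functions, so the corpus is
#' rule-consistent by construction. A fraction `inconsistency_rate` of genes
#' additionally receives one planted rule-violating pair (a function class
#' and a phenotype class drawn from an inconsistency pattern), and a
#' fraction `annotation_noise` receives one random extra phenotype class.
#' The truth log records every planted pair.
#'
#' @param spec A [fixture_spec()].
#' @param rules Data frame from [build_correspondence_rules()].
#' @param patterns Data frame from [build_inconsistency_patterns()]; may be
#'   empty when `inconsistency_rate = 0`.
#' @return List with `functions` and `phenotypes` (`annotation_corpus`) and
#'   `truth_log` (data frame `gene`, `function_class`, `phenotype_class`,
#'   `kind` in consistent / inconsistent / noise).
#' @export
make_annotation_corpora <- function(spec, rules, patterns) {
  if (!nrow(rules)) {
    stop("cannot generate corpora without correspondence rules")
  }
  if (spec$inconsistency_rate > 0 && !nrow(patterns)) {
    stop("inconsistency_rate > 0 requires a non-empty pattern list")
  }
  local_seed(spec$seed + 1L, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    pool <- sort(unique(rules$function_class))
    pheno_pool <- sort(unique(c(rules$phenotype_class, patterns$phenotype_class)))

    fun_rows <- list()
    phe_rows <- list()
    log_rows <- list()
    for (g in genes) {
      funcs <- sample(pool, min(length(pool), sample(1:3, 1L)))
      hits <- rules[rules$function_class %in% funcs, , drop = FALSE]
      fun_rows[[g]] <- data.frame(gene = g, class_id = funcs,
                                  stringsAsFactors = FALSE)
      if (nrow(hits)) {
        phe_rows[[g]] <- data.frame(gene = g, class_id = hits$phenotype_class,
                                    stringsAsFactors = FALSE)
        log_rows[[g]] <- data.frame(
          gene = g, function_class = hits$function_class,
          phenotype_class = hits$phenotype_class, kind = "consistent",
          stringsAsFactors = FALSE
        )
      }
    }

    n_inc <- round(spec$inconsistency_rate * spec$n_genes)
    inc_genes <- if (n_inc > 0L) sample(genes, n_inc) else character()
    for (g in inc_genes) {
      pat <- patterns[sample(nrow(patterns), 1L), , drop = FALSE]
      fun_rows[[paste0(g, ".inc")]] <- data.frame(
        gene = g, class_id = pat$function_class, stringsAsFactors = FALSE
      )
      phe_rows[[paste0(g, ".inc")]] <- data.frame(
        gene = g, class_id = pat$phenotype_class, stringsAsFactors = FALSE
      )
      log_rows[[paste0(g, ".inc")]] <- data.frame(
        gene = g, function_class = pat$function_class,
        phenotype_class = pat$phenotype_class, kind = "inconsistent",
        stringsAsFactors = FALSE
      )
    }

    n_noise <- round(spec$annotation_noise * spec$n_genes)
    noise_genes <- if (n_noise > 0L) sample(genes, n_noise) else character()
    for (g in noise_genes) {
      cl <- sample(pheno_pool, 1L)
      phe_rows[[paste0(g, ".noise")]] <- data.frame(
        gene = g, class_id = cl, stringsAsFactors = FALSE
      )
      log_rows[[paste0(g, ".noise")]] <- data.frame(
        gene = g, function_class = NA_character_, phenotype_class = cl,
        kind = "noise", stringsAsFactors = FALSE
      )
    }

    functions <- annotation_corpus(do.call(rbind, fun_rows))
    functions$evidence <- "IDA"
    phenotypes <- annotation_corpus(do.call(rbind, phe_rows))
    truth_log <- do.call(rbind, log_rows)
    truth_log <- truth_log[order(truth_log$gene, truth_log$kind,
                                 truth_log$function_class,
                                 truth_log$phenotype_class), , drop = FALSE]
    rownames(truth_log) <- NULL
    list(functions = annotation_corpus(as.data.frame(functions)),
         phenotypes = phenotypes, truth_log = truth_log)
  })
}

#' Generate an interaction network with planted phenotype-similarity signal
#'
#' Positive (interacting) pairs are sampled among gene pairs that share at
#' least one phenotype class with probability `signal`, and uniformly among
#' all pairs otherwise; every other pair is a negative. With `signal = 1`
#' positives carry maximal phenotype-sharing signal, with `signal = 0` the
#' network is a pure null.
#'
#' @param spec A [fixture_spec()].
#' @param phenotypes Non-empty `annotation_corpus`.
#' @param signal Probability in `[0, 1]` that a positive is drawn from the
#'   phenotype-sharing pairs.
#' @param n_positives Number of positive pairs (default 2% of all pairs).
#' @return List with `positives` (data frame `gene1`, `gene2`), `genes`,
#'   `n_pairs` and `n_sharing` (number of phenotype-sharing pairs).
#' @export
make_interaction_network <- function(spec, phenotypes, signal = 1,
                                     n_positives = NULL) {
  if (!nrow(phenotypes)) {
    stop("cannot build an interaction network from an empty phenotype corpus")
  }
  stopifnot(signal >= 0, signal <= 1)
  local_seed(spec$seed + 2L, {
    genes <- sort(unique(phenotypes$gene))
    n <- length(genes)
    if (n < 2L) {
      stop("need at least two annotated genes")
    }
    idx <- utils::combn(n, 2L)
    all_pairs <- data.frame(
      gene1 = genes[idx[1L, ]], gene2 = genes[idx[2L, ]],
      stringsAsFactors = FALSE
    )
    n_pairs <- nrow(all_pairs)
    if (is.null(n_positives)) {
      n_positives <- max(1L, round(0.02 * n_pairs))
    }
    # pairs sharing >= 1 phenotype class, via self-join on class
    df <- unique(data.frame(gene = phenotypes$gene,
                            class_id = phenotypes$class_id,
                            stringsAsFactors = FALSE))
    j <- merge(df, df, by = "class_id")
    j <- j[j$gene.x < j$gene.y, c("gene.x", "gene.y")]
    sharing_keys <- unique(paste(j$gene.x, j$gene.y))
    all_keys <- paste(all_pairs$gene1, all_pairs$gene2)
    share_idx <- which(all_keys %in% sharing_keys)

    n_positives <- min(n_positives, n_pairs)
    from_sharing <- stats::rbinom(1L, n_positives, signal)
    from_sharing <- min(from_sharing, length(share_idx))
    picked <- if (from_sharing > 0L) {
      sample(share_idx, from_sharing)
    } else {
      integer()
    }
    remaining <- setdiff(seq_len(n_pairs), picked)
    n_rest <- n_positives - from_sharing
    if (n_rest > 0L) {
      picked <- c(picked, sample(remaining, n_rest))
    }
    positives <- all_pairs[sort(picked), , drop = FALSE]
    rownames(positives) <- NULL
    list(positives = positives, genes = genes, n_pairs = n_pairs,
         n_sharing = length(share_idx))
  })
}

#' Write a complete fixture bundle to disk
#'
#' Serialises the toy ontologies (OBO), the function corpus (GAF 2.1), the
#' phenotype corpus (simple two-column TSV), the interaction positives
#' (STRING-style links with confidence 999 on positives) and the plant /
#' truth logs (JSON), giving a self-contained input directory for the
#' pipeline.
#'
#' @param onts Result of [make_toy_ontologies()].
#' @param corpora Result of [make_annotation_corpora()].
#' @param network Optional result of [make_interaction_network()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(onts, corpora, network = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(onts$go_obo, file.path(dir, "go.obo"))
  writeLines(onts$pheno_obo, file.path(dir, "pheno.obo"))

  f <- as.data.frame(corpora$functions)
  gaf <- vapply(seq_len(nrow(f)), function(i) {
    paste(c("FIX", f$gene[i], f$gene[i], "", f$class_id[i], "FIX:0000001",
            f$evidence[i], "", "P", "", "", "protein", "taxon:10090",
            "20260101", "FIX", "", ""), collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.1", gaf), file.path(dir, "functions.gaf"))

  p <- as.data.frame(corpora$phenotypes)
  writeLines(paste(p$gene, p$class_id, sep = "\t"),
             file.path(dir, "phenotypes.tsv"))

  logs <- list(
    regulations = onts$plant_log$regulations,
    eq = onts$plant_log$eq,
    truth = corpora$truth_log
  )
  if (!is.null(network)) {
    writeLines(
      c("protein1 protein2 combined_score",
        paste(network$positives$gene1, network$positives$gene2, 999)),
      file.path(dir, "links.txt")
    )
  }
  jsonlite::write_json(logs, file.path(dir, "plant_log.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
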