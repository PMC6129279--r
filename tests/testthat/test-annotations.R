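gaf_row <- function(gene, class_id, evidence = "IDA", qualifier = "",
                    extension = "", aspect = "P") {
  paste(c("DB", gene, gene, qualifier, class_id, "REF:1", evidence, "",
          aspect, "", "", "protein", "taxon:10090", "20260101", "DB",
          extension, ""), collapse = "\t")
}

test_that("GAF filtering drops electronic, negated and contextual rows", {
  lines <- c(
    "!gaf-version: 2.1",
    gaf_row("g1", "GO:0000001", evidence = "IEA"),
    gaf_row("g2", "GO:0000002", evidence = "IDA", qualifier = "NOT|involved_in"),
    gaf_row("g3", "GO:0000003", evidence = "IDA", extension = "occurs_in(CL:0000236)"),
    gaf_row("g4", "GO:0000004", evidence = "IDA"),
    gaf_row("g5", "GO:0000005", evidence = "TAS")
  )
  corpus <- parse_gaf(lines)
  expect_setequal(corpus$gene, c("g4", "g5"))
  expect_true(all(corpus$score == 1.0))
  expect_false(is_closed(corpus))

  # filters are individually switchable
  expect_true("g2" %in% parse_gaf(lines, drop_negated = FALSE)$gene)
  expect_true("g3" %in% parse_gaf(lines, drop_contextual = FALSE)$gene)
})

test_that("GAF rows with a wrong column count raise an error naming the line", {
  lines <- c("!gaf-version: 2.1", "a\tb\tc")
  expect_error(parse_gaf(lines), "line 2")
})

test_that("phenotype TSV dialects parse to distinct scored pairs", {
  simple <- c("g1\tMP:0008782", "g1\tMP:0008782", "g2\tMP:0001732")
  corpus <- parse_phenotype_tsv(simple, dialect = "simple")
  expect_equal(nrow(corpus), 2L) # duplicates collapse to set semantics
  expect_true(all(corpus$score == 1.0))

  mgi <- paste("Gpc3<tm1>/Gpc3<tm1>", "Gpc3<tm1>", "MGI:2", "B6", "MP:0001732",
               "123", "MGI:104903", sep = "\t")
  m <- parse_phenotype_tsv(c(mgi, mgi), dialect = "mgi_gene_pheno")
  expect_equal(m$gene, "MGI:104903")
  expect_equal(m$class_id, "MP:0001732")

  # unexpected prefix is skipped with a warning
  expect_warning(
    h <- parse_phenotype_tsv(c("1\tG1\tHP:0000001", "2\tG2\tMP:0000001"),
                             dialect = "hpo_gene_pheno"),
    "prefix"
  )
  expect_equal(h$gene, "G1")
  expect_equal(nrow(parse_phenotype_tsv(character(), dialect = "simple")), 0L)
})

test_that("phenotype pairs round-trip through the simple dialect", {
  set.seed(31)
  pairs <- unique(data.frame(
    gene = sample(sprintf("g%02d", 1:8), 20, replace = TRUE),
    class_id = sample(sprintf("MP:%07d", 1:12), 20, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  corpus <- parse_phenotype_tsv(paste(pairs$gene, pairs$class_id, sep = "\t"))
  expect_setequal(paste(corpus$gene, corpus$class_id),
                  paste(pairs$gene, pairs$class_id))
})

test_that("predicted-function scores pass through and invalid scores error", {
  corpus <- parse_predicted_functions("g1\tGO:0002904\t0.9")
  expect_equal(corpus$score, 0.9)
  expect_equal(corpus$evidence, "PRED")
  expect_error(parse_predicted_functions("g1\tGO:0002904\t0"), "line 1")
  expect_error(parse_predicted_functions(c("g1\tGO:1\t0.5", "g2\tGO:2\t1.2")),
               "line 2")
  set.seed(13)
  scores <- round(runif(50, 0.01, 1), 3)
  lines <- paste(sprintf("g%02d", 1:50), sprintf("GO:%07d", 1:50), scores,
                 sep = "\t")
  expect_equal(sort(parse_predicted_functions(lines)$score), sort(scores))
})

test_that("identifier mapping renames, drops and merges as configured", {
  corpus <- annotation_corpus(data.frame(
    gene = c("P1", "P2", "P3"), class_id = c("GO:1", "GO:2", "GO:3"),
    stringsAsFactors = FALSE
  ))
  mapped <- suppressMessages(
    map_ids(corpus, c(P1 = "MGI:1", P2 = "MGI:1"), on_missing = "drop")
  )
  # two sources merge onto one target; unmapped P3 dropped
  expect_equal(unique(mapped$gene), "MGI:1")
  expect_setequal(mapped$class_id, c("GO:1", "GO:2"))
  kept <- map_ids(corpus, c(P1 = "MGI:1"), on_missing = "keep")
  expect_setequal(kept$gene, c("MGI:1", "P2", "P3"))
  expect_error(map_ids(corpus, c(P1 = "MGI:1"), on_missing = "error"), "missing")
})

test_that("propagation applies the true-path rule with max-score aggregation", {
  g <- parse_obo(c(obo_header(), term("A:1", "root"),
                   term("A:2", "mid", is_a = "A:1"),
                   term("A:3", "leaf", is_a = "A:2")))
  # annotation to root only is unchanged
  root_only <- annotation_corpus(data.frame(gene = "g", class_id = "A:1",
                                            stringsAsFactors = FALSE))
  expect_equal(nrow(propagate(root_only, g)), 1L)
  # leaf annotation reaches all three classes
  leaf <- annotation_corpus(data.frame(gene = "g", class_id = "A:3",
                                       stringsAsFactors = FALSE))
  closed <- propagate(leaf, g)
  expect_setequal(closed$class_id, c("A:1", "A:2", "A:3"))
  expect_true(all(closed$score == 1.0))
  expect_true(is_closed(closed))
})

test_that("propagated scores equal a brute-force max over descendants", {
  g <- parse_obo(random_dag_lines(20, seed = 17))
  set.seed(18)
  corpus <- annotation_corpus(data.frame(
    gene = sample(c("g1", "g2", "g3"), 15, replace = TRUE),
    class_id = sample(g$terms, 15, replace = TRUE),
    evidence = "PRED",
    score = round(runif(15, 0.1, 1), 2),
    stringsAsFactors = FALSE
  ))
  closed <- propagate(corpus, g)
  closure <- oracle_closure_matrix(g)
  for (i in seq_len(nrow(closed))) {
    gene <- closed$gene[i]
    cl <- closed$class_id[i]
    src <- corpus[corpus$gene == gene, ]
    expected <- max(src$score[closure[src$class_id, cl] > 0])
    expect_equal(closed$score[i], expected)
  }
})

test_that("propagation is idempotent, order-independent and never raises scores above sources", {
  g <- parse_obo(random_dag_lines(15, seed = 23))
  set.seed(24)
  df <- data.frame(
    gene = sample(c("a", "b"), 10, replace = TRUE),
    class_id = sample(g$terms, 10, replace = TRUE),
    evidence = "PRED", score = round(runif(10, 0.2, 1), 2),
    stringsAsFactors = FALSE
  )
  corpus <- annotation_corpus(df)
  once <- propagate(corpus, g)
  twice <- propagate(once, g)
  expect_equal(as.data.frame(once), as.data.frame(twice))
  shuffled <- annotation_corpus(df[sample(nrow(df)), ])
  expect_equal(as.data.frame(propagate(shuffled, g)), as.data.frame(once))
  expect_true(max(once$score) <= max(corpus$score))
})

test_that("interaction links filter at the confidence threshold inclusively", {
  lines <- c(
    "protein1 protein2 combined_score",
    "p1 p2 299",
    "p1 p3 300",
    "p2 p3 850",
    "p3 p3 900",
    "p3 p2 850"
  )
  pairs <- parse_string_links(lines, min_score = 300)
  expect_equal(pairs, data.frame(gene1 = c("p1", "p2"), gene2 = c("p3", "p3"),
                                 stringsAsFactors = FALSE))
  mapped <- parse_string_links(lines, id_map = c(p1 = "G1", p3 = "G3"))
  expect_equal(mapped, data.frame(gene1 = "G1", gene2 = "G3",
                                  stringsAsFactors = FALSE))
})

test_that("link filtering equals a brute-force row filter on a random file", {
  set.seed(41)
  a <- sprintf("p%02d", sample(1:12, 100, replace = TRUE))
  b <- sprintf("p%02d", sample(1:12, 100, replace = TRUE))
  s <- sample(0:999, 100, replace = TRUE)
  lines <- paste(a, b, s)
  pairs <- parse_string_links(lines, min_score = 300)
  keep <- s >= 300 & a != b
  expected <- unique(data.frame(gene1 = pmin(a[keep], b[keep]),
                                gene2 = pmax(a[keep], b[keep]),
                                stringsAsFactors = FALSE))
  expected <- expected[order(expected$gene1, expected$gene2), ]
  rownames(expected) <- NULL
  expect_equal(pairs, expected)
})

test_that("corpus construction enforces the score contract", {
  expect_error(
    annotation_corpus(data.frame(gene = "g", class_id = "GO:1", score = 1.5)),
    "score"
  )
  expect_error(
    annotation_corpus(data.frame(gene = "g", class_id = "GO:1", score = 0)),
    "score"
  )
})
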