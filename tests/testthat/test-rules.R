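test_that("quality sets must be pairwise disjoint", {
  expect_error(quality_config(increased_qualities = "PATO:0000460"),
               "disjoint")
  q <- quality_config()
  expect_equal(q$increased_qualities, "PATO:0000912")
  expect_equal(q$abnormal_qualities, "PATO:0000460")
})

test_that("EQ decomposition extracts entity and direction, treating abnormal as a modifier", {
  g <- worked_graphs()$pheno
  d <- decompose_phenotype_class(g, "MP:0009541")
  expect_equal(d$entity, "GO:0070242")
  expect_equal(d$direction, "increased") # abnormal quality is only a modifier
  expect_equal(decompose_phenotype_class(g, "MP:0001732")$direction, "decreased")
  # no logical definition -> none
  expect_null(decompose_phenotype_class(g, "MP:0008236"))
})

test_that("non-entity-prefix and ambiguous definitions yield no decomposition", {
  lines <- c(
    obo_header(),
    term("MP:0000001", "root"),
    term("PATO:0000912", "increased rate"),
    term("PATO:0000911", "decreased rate"),
    term("MP:0000010", "anatomical phenotype", is_a = "MP:0000001",
         xof = list("MP:0000001", c("phenotype_of", "UBERON:0000955"),
                    c("has_quality", "PATO:0000912"))),
    term("MP:0000011", "conflicting directions", is_a = "MP:0000001",
         xof = list("MP:0000001", c("phenotype_of", "GO:0000001"),
                    c("has_quality", "PATO:0000912"),
                    c("has_quality", "PATO:0000911"))),
    term("MP:0000012", "abnormal only", is_a = "MP:0000001",
         xof = list("MP:0000001", c("phenotype_of", "GO:0000001"),
                    c("has_quality", "PATO:0000460")))
  )
  g <- parse_obo(lines)
  expect_null(decompose_phenotype_class(g, "MP:0000010"))
  expect_warning(d <- decompose_phenotype_class(g, "MP:0000011"), "ambiguous")
  expect_null(d)
  expect_equal(decompose_phenotype_class(g, "MP:0000012")$direction, "abnormal")
})

test_that("planted EQ classes are recovered field-by-field", {
  spec <- fixture_spec(n_processes = 4, n_regulators_pos = 2,
                       n_regulators_neg = 2, eq_coverage = 1, seed = 5)
  onts <- make_toy_ontologies(spec)
  decs <- decompose_phenotypes(onts$pheno)
  planted <- onts$plant_log$eq
  planted <- planted[order(planted$phenotype_class), ]
  rownames(planted) <- NULL
  expect_equal(decs, planted) # 12 planted decompositions, all fields
  expect_equal(nrow(decs), 12L)
})

test_that("regulation indexing finds logical-definition regulation classes", {
  g <- worked_graphs()$go
  regs <- index_regulations(g)
  expect_equal(regs[regs$regulator == "GO:0002904", ],
               data.frame(regulator = "GO:0002904", regulated = "GO:0001783",
                          sign = "positive", stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  expect_setequal(regs$sign[regs$regulator %in% c("GO:0045926", "GO:0043066")],
                  "negative")
  # no regulation definitions -> empty
  empty <- parse_obo(c(obo_header(), term("A:1", "root")))
  expect_equal(nrow(index_regulations(empty)), 0L)
})

test_that("a genus filter restricts regulation indexing", {
  g <- worked_graphs()$go
  expect_equal(nrow(index_regulations(g, genus = "GO:0065007")), 3L)
  expect_equal(nrow(index_regulations(g, genus = "GO:0008150")), 0L)
})

test_that("planted regulation axioms are indexed exactly", {
  spec <- fixture_spec(n_processes = 40, n_regulators_pos = 20,
                       n_regulators_neg = 20, seed = 2)
  onts <- make_toy_ontologies(spec)
  regs <- index_regulations(onts$go)
  planted <- onts$plant_log$regulations
  planted <- planted[order(planted$regulator, planted$regulated, planted$sign), ]
  rownames(planted) <- NULL
  expect_equal(regs, planted)
  expect_equal(nrow(regs), 40L)
})

test_that("correspondence rules implement the three meta-rules", {
  regs <- data.frame(regulator = "GO:0002904", regulated = "GO:0001783",
                     sign = "positive", stringsAsFactors = FALSE)
  decs <- data.frame(phenotype_class = "MP:X1", entity = "GO:0001783",
                     direction = "decreased", stringsAsFactors = FALSE)
  r <- build_correspondence_rules(regs, decs)
  expect_equal(r, data.frame(function_class = "GO:0002904",
                             phenotype_class = "MP:X1",
                             rule_kind = "inc_dec", stringsAsFactors = FALSE))

  # abnormal rule fires regardless of regulation structure
  decs2 <- data.frame(phenotype_class = "MP:Y1", entity = "GO:0001783",
                      direction = "abnormal", stringsAsFactors = FALSE)
  r2 <- build_correspondence_rules(regs[0, ], decs2)
  expect_equal(r2$function_class, "GO:0001783")
  expect_equal(r2$rule_kind, "abnormal")
})

test_that("rule and pattern generation equal double-loop join oracles", {
  spec <- fixture_spec(n_processes = 20, n_regulators_pos = 8,
                       n_regulators_neg = 7, eq_coverage = 0.8, seed = 9)
  onts <- make_toy_ontologies(spec)
  regs <- index_regulations(onts$go)
  decs <- decompose_phenotypes(onts$pheno)
  expect_equal(build_correspondence_rules(regs, decs), oracle_rules(regs, decs))
  expect_equal(build_inconsistency_patterns(regs, decs),
               oracle_patterns(regs, decs))
})

test_that("mirror inconsistency example from co-annotation is generated", {
  regs <- data.frame(regulator = "GO:0002904", regulated = "GO:0001783",
                     sign = "positive", stringsAsFactors = FALSE)
  decs <- data.frame(phenotype_class = "MP:0008782", entity = "GO:0001783",
                     direction = "increased", stringsAsFactors = FALSE)
  p <- build_inconsistency_patterns(regs, decs)
  expect_equal(p, data.frame(function_class = "GO:0002904",
                             phenotype_class = "MP:0008782",
                             rule_kind = "inc_dec", stringsAsFactors = FALSE))
  expect_equal(nrow(build_inconsistency_patterns(regs, decs[0, ])), 0L)
})

test_that("no class pair appears in both the rule and the pattern list", {
  spec <- fixture_spec(n_processes = 30, n_regulators_pos = 10,
                       n_regulators_neg = 10, seed = 4)
  onts <- make_toy_ontologies(spec)
  regs <- index_regulations(onts$go)
  decs <- decompose_phenotypes(onts$pheno)
  rules <- build_correspondence_rules(regs, decs)
  patterns <- build_inconsistency_patterns(regs, decs)
  expect_length(intersect(paste(rules$function_class, rules$phenotype_class),
                          paste(patterns$function_class, patterns$phenotype_class)),
                0L)
})

test_that("swapping every regulation sign exchanges rules and mirrored patterns", {
  spec <- fixture_spec(n_processes = 20, n_regulators_pos = 6,
                       n_regulators_neg = 6, seed = 8)
  onts <- make_toy_ontologies(spec)
  regs <- index_regulations(onts$go)
  decs <- decompose_phenotypes(onts$pheno)
  flipped <- regs
  flipped$sign <- ifelse(regs$sign == "positive", "negative", "positive")
  # a pos-reg/decreased rule becomes, under the flip, a neg-reg/decreased
  # pattern (violating dec_inc); kinds mirror accordingly
  rules <- build_correspondence_rules(regs, decs)
  rules_dir <- rules[rules$rule_kind != "abnormal", ]
  pat_flip <- build_inconsistency_patterns(flipped, decs)
  mirror <- c(inc_dec = "dec_inc", dec_inc = "inc_dec")
  expected <- data.frame(
    function_class = rules_dir$function_class,
    phenotype_class = rules_dir$phenotype_class,
    rule_kind = unname(mirror[rules_dir$rule_kind]),
    stringsAsFactors = FALSE
  )
  expected <- expected[order(expected$function_class, expected$phenotype_class,
                             expected$rule_kind), ]
  rownames(expected) <- NULL
  expect_equal(pat_flip, expected)
})

test_that("rule serialization is byte-identical across reruns", {
  spec <- fixture_spec(n_processes = 10, n_regulators_pos = 4,
                       n_regulators_neg = 3, seed = 6)
  onts <- make_toy_ontologies(spec)
  rules <- build_correspondence_rules(index_regulations(onts$go),
                                      decompose_phenotypes(onts$pheno))
  f1 <- tempfile()
  f2 <- tempfile()
  write_rules_tsv(rules, f1)
  write_rules_tsv(rules, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(read_rules_tsv(f1), rules)
})
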