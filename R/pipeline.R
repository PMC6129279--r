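#' Read and validate a pipeline run configuration
#'
#' A run configuration names the inputs and switches of a full workflow run.
#' Recognised fields: `go_obo`, `pheno_obo` (required paths), one or both of
#' `gaf` and `predicted_functions`, `phenotypes` + `phenotype_dialect`,
#' optional `string_links` + `min_link_score`, optional `quality_config`
#' (YAML), `mode` (`exact`/`inferred`), `genus` (optional regulation genus
#' filter), `normalize`, `out_dir` (required) and `seed`. All referenced
#' paths must exist at validation time.
#'
#' @param config A named list, or the path of a YAML file containing one.
#' @return A validated `run_config` list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    phenotype_dialect = "simple", min_link_score = 300, mode = "exact",
    genus = NULL, normalize = TRUE, seed = 1
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  for (k in c("go_obo", "pheno_obo", "phenotypes", "out_dir")) {
    if (is.null(config[[k]])) stop("run config is missing required field: ", k)
  }
  if (is.null(config$gaf) && is.null(config$predicted_functions)) {
    stop("run config needs `gaf` and/or `predicted_functions`")
  }
  paths <- c("go_obo", "pheno_obo", "gaf", "predicted_functions",
             "phenotypes", "string_links", "quality_config")
  for (k in paths) {
    p <- config[[k]]
    if (!is.null(p) && !file.exists(p)) {
      stop("run config path does not exist (", k, "): ", p)
    }
  }
  config$mode <- match.arg(config$mode, c("exact", "inferred"))
  structure(config, class = "run_config")
}

run_stage <- function(name, manifest, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end workflow
#'
#' Executes, in order: ontology parsing, rule and pattern generation,
#' annotation loading and filtering, the consistency check, rule-based
#' phenotype prediction with the found/novel split, phenotype similarity,
#' and the Fmax and (when an interaction file is given) ROC evaluations.
#' All outputs are plain-text TSV/JSON under `out_dir` in a fixed layout
#' (`rules/`, `findings/`, `predictions/`, `sim/`, `eval/`), plus a
#' `manifest.json` recording package version, input checksums, per-stage
#' row counts and output checksums. Reruns on identical inputs produce
#' identical output checksums.
#'
#' @param config A `run_config`, a named list, or a YAML path
#'   (see [read_run_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  set.seed(cfg$seed)
  out <- cfg$out_dir
  for (d in c("", "rules", "findings", "predictions", "sim", "eval")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  input_paths <- Filter(Negate(is.null), cfg[c(
    "go_obo", "pheno_obo", "gaf", "predicted_functions", "phenotypes",
    "string_links", "quality_config"
  )])
  manifest <- list(
    tool = "regphen",
    version = as.character(utils::packageVersion("regphen")),
    mode = cfg$mode,
    inputs = lapply(input_paths, function(p) unname(tools::md5sum(p))),
    counts = list()
  )

  go <- run_stage("parse_go", manifest, parse_obo(cfg$go_obo))
  pheno <- run_stage("parse_pheno", manifest, parse_obo(cfg$pheno_obo))
  quality <- if (!is.null(cfg$quality_config)) {
    read_quality_config(cfg$quality_config)
  } else {
    quality_config()
  }

  regs <- run_stage("index_regulations", manifest,
                    index_regulations(go, genus = cfg$genus))
  decs <- run_stage("decompose_phenotypes", manifest,
                    decompose_phenotypes(pheno, quality))
  rules <- run_stage("build_rules", manifest,
                     build_correspondence_rules(regs, decs))
  patterns <- run_stage("build_patterns", manifest,
                        build_inconsistency_patterns(regs, decs))
  write_rules_tsv(rules, file.path(out, "rules", "rules.tsv"))
  write_rules_tsv(patterns, file.path(out, "rules", "patterns.tsv"))
  manifest$counts$regulations <- nrow(regs)
  manifest$counts$decompositions <- nrow(decs)
  manifest$counts$rules <- nrow(rules)
  manifest$counts$patterns <- nrow(patterns)

  functions <- run_stage("load_functions", manifest, {
    if (!is.null(cfg$gaf)) parse_gaf(cfg$gaf) else
      parse_predicted_functions(cfg$predicted_functions)
  })
  phenotypes <- run_stage("load_phenotypes", manifest,
                          parse_phenotype_tsv(cfg$phenotypes,
                                              dialect = cfg$phenotype_dialect))
  manifest$counts$function_annotations <- nrow(functions)
  manifest$counts$phenotype_annotations <- nrow(phenotypes)

  findings <- run_stage("check", manifest,
                        check_corpus(functions, phenotypes, patterns,
                                     mode = cfg$mode, graph = pheno))
  write.table(findings, file.path(out, "findings", "findings.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$findings <- nrow(findings)

  predictions <- run_stage("predict", manifest,
                           predict_phenotypes(functions, rules))
  parts <- run_stage("split_novel", manifest,
                     split_novel(predictions, phenotypes, graph = pheno,
                                 match = cfg$mode))
  write_predictions_tsv(predictions,
                        file.path(out, "predictions", "predictions.tsv"))
  write_predictions_tsv(parts$found, file.path(out, "predictions", "found.tsv"))
  write_predictions_tsv(parts$novel, file.path(out, "predictions", "novel.tsv"))
  manifest$counts$predictions <- nrow(predictions)
  manifest$counts$predictions_found <- nrow(parts$found)
  manifest$counts$predictions_novel <- nrow(parts$novel)

  ic <- run_stage("information_content", manifest,
                  information_content(phenotypes, pheno))
  sim <- run_stage("similarity", manifest,
                   gene_similarity_matrix(phenotypes, ic, pheno,
                                          normalize = isTRUE(cfg$normalize)))
  write_ic_tsv(ic, file.path(out, "sim", "ic.tsv"))
  write_similarity_tsv(sim, file.path(out, "sim", "similarity.tsv"))
  manifest$counts$similarity_genes <- length(sim$genes)

  fm <- run_stage("fmax", manifest,
                  fmax(predictions, phenotypes, pheno))
  jsonlite::write_json(
    list(fmax = fm$fmax, best_threshold = fm$best_threshold, n = fm$n,
         curve = fm$curve),
    file.path(out, "eval", "fmax.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  manifest$counts$fmax_genes <- fm$n
  manifest$eval <- list(fmax = fm$fmax)

  if (!is.null(cfg$string_links)) {
    roc <- run_stage("roc", manifest, {
      links <- parse_string_links(cfg$string_links,
                                  min_score = cfg$min_link_score)
      scored_genes <- sim$genes
      links <- links[links$gene1 %in% scored_genes &
                       links$gene2 %in% scored_genes, , drop = FALSE]
      pair_scores <- similarity_pairs(sim)

      merged_pheno <- annotation_corpus(rbind(
        as.data.frame(phenotypes),
        data.frame(gene = predictions$gene,
                   class_id = predictions$phenotype_class,
                   evidence = NA_character_, score = predictions$score,
                   aspect = NA_character_, stringsAsFactors = FALSE)
      ))
      ic_m <- information_content(merged_pheno, pheno)
      sim_m <- gene_similarity_matrix(merged_pheno, ic_m, pheno,
                                      normalize = isTRUE(cfg$normalize))
      pair_scores_m <- similarity_pairs(sim_m)
      keep <- links$gene1 %in% sim_m$genes & links$gene2 %in% sim_m$genes
      list(
        original = roc_auc(pair_scores, links),
        merged = roc_auc(pair_scores_m, links[keep, , drop = FALSE])
      )
    })
    jsonlite::write_json(
      list(
        auc_original = roc$original$auc, auc_merged = roc$merged$auc,
        positives = roc$original$positives, negatives = roc$original$negatives
      ),
      file.path(out, "eval", "roc.json"), auto_unbox = TRUE, digits = NA
    )
    manifest$eval$auc_original <- roc$original$auc
    manifest$eval$auc_merged <- roc$merged$auc
  }

  out_files <- sort(setdiff(
    list.files(out, recursive = TRUE, full.names = TRUE),
    file.path(out, "manifest.json")
  ))
  manifest$outputs <- stats::setNames(
    lapply(out_files, function(p) unname(tools::md5sum(p))),
    sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out), "/?"), "",
        out_files)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
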