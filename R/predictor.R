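#' Predict loss-of-function phenotypes from function annotations
#'
#' Applies the correspondence rules to each gene's direct function
#' annotations: every annotation (f, s) combined with a rule
#' (f, ph, kind) emits the prediction that loss of the gene yields
#' phenotype ph with score s. Experimental annotations carry score 1.0;
#' predicted-function annotations pass their predictor's score through.
#' Multiple licensing functions for the same (gene, phenotype) are collapsed
#' to the maximum score, keeping the licensing rule of the maximal row
#' (ties broken deterministically by rule kind, then source function).
#'
#' @param functions An unclosed `annotation_corpus`. GAF-derived records are
#'   restricted to the biological-process aspect by default (rules are
#'   defined over processes); records without an aspect always pass.
#' @param rules Data frame from [build_correspondence_rules()].
#' @param allow_propagated Permit a closed corpus as input (exploratory use;
#'   by default a closed corpus is an error since rules are meant to fire on
#'   directly asserted functions only).
#' @param aspects GAF aspects admitted to rule application.
#' @return Data frame `gene`, `phenotype_class`, `score`, `rule_kind`,
#'   `source_function`, sorted by gene then phenotype.
#' @export
predict_phenotypes <- function(functions, rules, allow_propagated = FALSE,
                               aspects = "P") {
  if (is_closed(functions) && !allow_propagated) {
    stop("rules apply to direct annotations; pass allow_propagated = TRUE ",
         "to use a closed corpus")
  }
  empty <- data.frame(
    gene = character(), phenotype_class = character(), score = numeric(),
    rule_kind = character(), source_function = character(),
    stringsAsFactors = FALSE
  )
  if (!nrow(functions) || !nrow(rules)) {
    return(empty)
  }
  f <- as.data.frame(functions)
  f <- f[is.na(f$aspect) | f$aspect %in% aspects, , drop = FALSE]
  m <- merge(f, rules, by.x = "class_id", by.y = "function_class")
  if (!nrow(m)) {
    return(empty)
  }
  ord <- order(m$gene, m$phenotype_class, -m$score, m$rule_kind, m$class_id)
  m <- m[ord, , drop = FALSE]
  m <- m[!duplicated(m[c("gene", "phenotype_class")]), , drop = FALSE]
  out <- data.frame(
    gene = m$gene, phenotype_class = m$phenotype_class, score = m$score,
    rule_kind = m$rule_kind, source_function = m$class_id,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Partition predictions into already-asserted and novel
#'
#' A prediction counts as "found" when the gene already carries a matching
#' phenotype annotation: equal to the predicted class (`exact`), or equal to
#' any subclass of it (`inferred` — a gene asserted to increased B cell
#' apoptosis matches a predicted increased apoptosis). The partition is
#' disjoint and exhaustive.
#'
#' @param predictions Data frame from [predict_phenotypes()].
#' @param existing `annotation_corpus` of asserted phenotype annotations.
#' @param graph Phenotype `ontology_graph`; required for `match = "inferred"`.
#' @param match `"exact"` or `"inferred"`.
#' @return List with data frames `found` and `novel`.
#' @export
split_novel <- function(predictions, existing, graph = NULL,
                        match = c("exact", "inferred")) {
  match <- match.arg(match)
  if (!nrow(predictions)) {
    return(list(found = predictions, novel = predictions))
  }
  if (match == "exact") {
    keys <- paste(existing$gene, existing$class_id)
  } else {
    if (is.null(graph)) {
      stop("inferred matching requires the phenotype ontology graph")
    }
    anc_of <- function(cl) if (cl %in% graph$terms) ancestors(graph, cl) else cl
    anc_sets <- lapply(unique(existing$class_id), anc_of)
    names(anc_sets) <- unique(existing$class_id)
    reps <- lengths(anc_sets[existing$class_id])
    keys <- unique(paste(
      rep(existing$gene, reps),
      unlist(anc_sets[existing$class_id], use.names = FALSE)
    ))
  }
  found <- paste(predictions$gene, predictions$phenotype_class) %in% keys
  list(
    found = predictions[found, , drop = FALSE],
    novel = predictions[!found, , drop = FALSE]
  )
}

#' Write predictions as TSV
#'
#' @param predictions Data frame from [predict_phenotypes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
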