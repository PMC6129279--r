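#' Protein-function-prediction style Fmax over a threshold grid
#'
#' CAFA-style evaluation of scored class predictions against annotated truth
#' over the ontology structure. For each threshold t, a gene i's prediction
#' set P_i(t) is the ontology closure of its predicted classes with score at
#' least t, and T_i is the closure of its true annotations; ontology roots
#' are excluded from both (closure makes them trivially present). Per-gene
#' precision pr_i(t) = |P_i(t) n T_i| / |P_i(t)| is defined only when
#' P_i(t) is non-empty and averaged over the m(t) genes with at least one
#' prediction at t; recall rc_i(t) = |P_i(t) n T_i| / |T_i| is averaged over
#' all n genes of the evaluation set. Fmax is the maximum over the grid of
#' the harmonic mean of the two averages.
#'
#' The evaluation set comprises genes with at least one truth annotation and
#' at least one prediction anywhere on the grid.
#'
#' @param predictions Data frame with columns `gene`, `phenotype_class`,
#'   `score` (e.g. from [predict_phenotypes()]).
#' @param truth `annotation_corpus` of true annotations; propagated
#'   internally when not already closed.
#' @param graph Phenotype `ontology_graph` (supplies closure and roots).
#' @param thresholds Score grid; default 0, 0.01, ..., 1 (101 steps).
#' @param propagate_predictions Closure-propagate prediction sets before
#'   counting (default); `FALSE` evaluates the raw predicted sets.
#' @return An `fmax_result`: list with `fmax`, `best_threshold`, `curve`
#'   (data frame `threshold`, `avg_pr`, `avg_rc`, `m`; `avg_pr` is `NA`
#'   where m(t) = 0) and `n`.
#' @export
fmax <- function(predictions, truth, graph,
                 thresholds = seq(0, 1, by = 0.01),
                 propagate_predictions = TRUE) {
  truth <- if (is_closed(truth)) truth else propagate(truth, graph)
  roots <- graph$roots
  anc_of <- function(cl) if (cl %in% graph$terms) ancestors(graph, cl) else cl

  truth_sets <- lapply(split(truth$class_id, truth$gene),
                       function(x) setdiff(unique(x), roots))
  truth_sets <- truth_sets[lengths(truth_sets) > 0L]

  if (nrow(predictions)) {
    pred_split <- split(predictions[, c("phenotype_class", "score")],
                        predictions$gene)
  } else {
    pred_split <- list()
  }
  eval_genes <- sort(intersect(names(truth_sets), names(pred_split)))
  n <- length(eval_genes)
  if (n == 0L) {
    stop("empty evaluation set: no gene has both truth and predictions")
  }

  # per gene: classes sorted by decreasing score with (propagated) class sets
  gene_pred <- lapply(eval_genes, function(g) {
    p <- pred_split[[g]]
    p <- p[order(-p$score, p$phenotype_class), , drop = FALSE]
    p <- p[!duplicated(p$phenotype_class), , drop = FALSE]
    sets <- if (propagate_predictions) {
      lapply(p$phenotype_class, anc_of)
    } else {
      as.list(p$phenotype_class)
    }
    list(scores = p$score, sets = sets)
  })
  names(gene_pred) <- eval_genes

  curve <- data.frame(
    threshold = thresholds, avg_pr = NA_real_, avg_rc = NA_real_,
    m = NA_integer_
  )
  fvals <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    t <- thresholds[[k]]
    pr_sum <- 0
    rc_sum <- 0
    m <- 0L
    for (g in eval_genes) {
      gp <- gene_pred[[g]]
      keep <- gp$scores >= t
      if (any(keep)) {
        pset <- setdiff(unique(unlist(gp$sets[keep], use.names = FALSE)), roots)
      } else {
        pset <- character()
      }
      if (length(pset)) {
        tset <- truth_sets[[g]]
        tp <- length(intersect(pset, tset))
        pr_sum <- pr_sum + tp / length(pset)
        rc_sum <- rc_sum + tp / length(tset)
        m <- m + 1L
      }
    }
    avg_pr <- if (m > 0L) pr_sum / m else NA_real_
    avg_rc <- rc_sum / n
    curve$avg_pr[k] <- avg_pr
    curve$avg_rc[k] <- avg_rc
    curve$m[k] <- m
    fvals[k] <- if (m > 0L && (avg_pr + avg_rc) > 0) {
      2 * avg_pr * avg_rc / (avg_pr + avg_rc)
    } else {
      0
    }
  }
  best <- which.max(fvals)
  structure(
    list(
      fmax = fvals[best], best_threshold = thresholds[best],
      curve = curve, n = n
    ),
    class = "fmax_result"
  )
}

#' @export
print.fmax_result <- function(x, ...) {
  cat("<fmax_result> Fmax = ", format(x$fmax, digits = 4),
      " at t = ", x$best_threshold, " (n = ", x$n, " genes)\n", sep = "")
  invisible(x)
}

canonical_pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' ROC AUC for similarity-ranked gene pairs
#'
#' Ranks all scored unordered gene pairs and treats the given interacting
#' pairs as positives and every other scored pair as a negative. The AUC is
#' computed by the rank-sum (Mann-Whitney) formulation with midrank tie
#' correction, which equals the trapezoidal area under the empirical ROC
#' curve; all-tied scores give 0.5.
#'
#' @param pair_scores Data frame `gene1`, `gene2`, `score` (e.g. from
#'   [similarity_pairs()]); pairs are unordered and must be unique.
#' @param positives Data frame `gene1`, `gene2` of interacting pairs; every
#'   positive pair must be present in `pair_scores`.
#' @return A `roc_result`: list with `auc`, `positives`, `negatives`.
#' @export
roc_auc <- function(pair_scores, positives) {
  keys <- canonical_pair_key(pair_scores$gene1, pair_scores$gene2)
  if (anyDuplicated(keys)) {
    stop("duplicate pairs in pair_scores")
  }
  pos_keys <- unique(canonical_pair_key(positives$gene1, positives$gene2))
  missing <- setdiff(pos_keys, keys)
  if (length(missing)) {
    stop(length(missing), " positive pair(s) absent from pair_scores")
  }
  is_pos <- keys %in% pos_keys
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative pair")
  }
  r <- rank(pair_scores$score) # midranks for ties
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(
    list(auc = auc, positives = n_pos, negatives = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4), " (",
      x$positives, " positives / ", x$negatives, " negatives)\n", sep = "")
  invisible(x)
}
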