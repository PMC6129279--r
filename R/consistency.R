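empty_finding_frame <- function() {
  data.frame(
    gene = character(), function_class = character(),
    phenotype_class = character(), violated_rule = character(),
    mode = character(), inferred_via = character(),
    stringsAsFactors = FALSE
  )
}

#' Flag genes with mutually inconsistent function and phenotype annotations
#'
#' Scans the direct (unpropagated) annotations of each gene for pairs that
#' instantiate an inconsistency pattern: a function annotation to the
#' pattern's regulation class together with a phenotype annotation to the
#' pattern's phenotype class. In `exact` mode only directly matching
#' phenotype annotations count. In `inferred` mode a phenotype annotation to
#' a strict subclass of the pattern's phenotype also matches, and the
#' asserted subclass is recorded in `inferred_via`; exact matches are always
#' a subset of inferred matches. Subclass inference is applied to the
#' phenotype side only unless `infer_functions = TRUE`, reflecting that a
#' specific asserted phenotype (e.g. decreased apoptosis in one neuronal
#' context) does not carry the general implication of its superclass.
#'
#' @param functions Unclosed `annotation_corpus` of function annotations.
#' @param phenotypes Unclosed `annotation_corpus` of phenotype annotations.
#' @param patterns Data frame from [build_inconsistency_patterns()].
#' @param mode `"exact"` or `"inferred"`.
#' @param graph Phenotype `ontology_graph`; required in inferred mode.
#'   Patterns whose phenotype class is absent from the graph are skipped for
#'   subclass inference (with a warning) but still match exactly.
#' @param function_graph Optional function `ontology_graph` for
#'   function-side inference.
#' @param infer_functions Also match function annotations to strict
#'   subclasses of the pattern's function class (default off).
#' @return Data frame `gene`, `function_class`, `phenotype_class`,
#'   `violated_rule`, `mode`, `inferred_via` (`NA` for exact matches),
#'   sorted and deduplicated.
#' @export
check_corpus <- function(functions, phenotypes, patterns,
                         mode = c("exact", "inferred"), graph = NULL,
                         function_graph = NULL, infer_functions = FALSE) {
  mode <- match.arg(mode)
  if (is_closed(functions) || is_closed(phenotypes)) {
    warning("check_corpus expects direct (unpropagated) annotations",
            call. = FALSE)
  }
  if (mode == "inferred" && is.null(graph)) {
    stop("inferred mode requires the phenotype ontology graph")
  }
  if (!nrow(patterns) || !nrow(functions) || !nrow(phenotypes)) {
    return(empty_finding_frame())
  }

  fun <- data.frame(gene = functions$gene, function_class = functions$class_id,
                    stringsAsFactors = FALSE)
  if (isTRUE(infer_functions)) {
    if (is.null(function_graph)) {
      stop("infer_functions requires function_graph")
    }
    extra <- lapply(unique(patterns$function_class), function(fc) {
      if (!fc %in% function_graph$terms) {
        return(NULL)
      }
      sub <- setdiff(descendants(function_graph, fc), fc)
      hit <- fun[fun$function_class %in% sub, , drop = FALSE]
      if (!nrow(hit)) {
        return(NULL)
      }
      data.frame(gene = hit$gene, function_class = fc, stringsAsFactors = FALSE)
    })
    fun <- unique(rbind(fun, do.call(rbind, extra)))
  }

  phe <- data.frame(gene = phenotypes$gene, asserted = phenotypes$class_id,
                    stringsAsFactors = FALSE)

  # phenotype match table: pattern phenotype -> asserted class it matches
  match_tab <- data.frame(phenotype_class = unique(patterns$phenotype_class),
                          stringsAsFactors = FALSE)
  match_tab$matches <- match_tab$phenotype_class
  match_tab$inferred_via <- NA_character_
  if (mode == "inferred") {
    in_graph <- match_tab$phenotype_class %in% graph$terms
    if (any(!in_graph)) {
      warning(sum(!in_graph), " pattern phenotype class(es) absent from the ",
              "graph; subclass inference skipped for them", call. = FALSE)
    }
    extra <- lapply(match_tab$phenotype_class[in_graph], function(p) {
      sub <- setdiff(descendants(graph, p), p)
      if (!length(sub)) {
        return(NULL)
      }
      data.frame(phenotype_class = p, matches = sub, inferred_via = sub,
                 stringsAsFactors = FALSE)
    })
    match_tab <- rbind(match_tab, do.call(rbind, extra))
  }

  hits_f <- merge(fun, patterns, by = "function_class")
  if (!nrow(hits_f)) {
    return(empty_finding_frame())
  }
  hits_fp <- merge(hits_f, match_tab, by = "phenotype_class")
  out <- merge(hits_fp, phe, by.x = c("gene", "matches"),
               by.y = c("gene", "asserted"))
  if (!nrow(out)) {
    return(empty_finding_frame())
  }
  out <- data.frame(
    gene = out$gene, function_class = out$function_class,
    phenotype_class = out$phenotype_class, violated_rule = out$rule_kind,
    mode = mode, inferred_via = out$inferred_via,
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(out$gene, out$function_class, out$phenotype_class,
                   out$inferred_via, na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate consistency findings per pattern
#'
#' @param findings Data frame from [check_corpus()].
#' @return Data frame `function_class`, `phenotype_class`, `violated_rule`,
#'   `n_genes`, sorted by decreasing gene count.
#' @export
summarize_findings <- function(findings) {
  if (!nrow(findings)) {
    return(data.frame(
      function_class = character(), phenotype_class = character(),
      violated_rule = character(), n_genes = integer(),
      stringsAsFactors = FALSE
    ))
  }
  key <- findings[, c("function_class", "phenotype_class", "violated_rule")]
  agg <- stats::aggregate(
    list(n_genes = findings$gene), by = key,
    FUN = function(g) length(unique(g))
  )
  agg <- agg[order(-agg$n_genes, agg$function_class, agg$phenotype_class), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
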