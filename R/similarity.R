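#' Corpus-based information content
#'
#' IC(c) = -log p(c), where p(c) is the fraction of annotated genes that are
#' annotated (after ontology closure) to class c. The corpus is propagated
#' internally when not already closed. Classes with zero frequency are
#' absent from the table; a class covering every gene has IC 0. Natural
#' logarithm; any fixed base rescales all values uniformly and cannot change
#' best-match rankings.
#'
#' @param phenotypes A non-empty `annotation_corpus`.
#' @param graph An `ontology_graph`.
#' @return An `ic_table`: list with `ic` (named numeric), `corpus_size`
#'   (number of annotated genes) and `basis = "genes"`.
#' @export
information_content <- function(phenotypes, graph) {
  if (!nrow(phenotypes)) {
    stop("cannot compute information content from an empty corpus")
  }
  closed <- if (is_closed(phenotypes)) phenotypes else propagate(phenotypes, graph)
  pairs <- unique(data.frame(gene = closed$gene, class_id = closed$class_id,
                             stringsAsFactors = FALSE))
  total <- length(unique(pairs$gene))
  counts <- table(pairs$class_id)
  ic <- -log(as.numeric(counts) / total)
  names(ic) <- names(counts)
  structure(
    list(ic = ic, corpus_size = total, basis = "genes"),
    class = "ic_table"
  )
}

ic_bearing_ancestors <- function(graph, class_id, ic) {
  a <- if (class_id %in% graph$terms) ancestors(graph, class_id) else class_id
  ic$ic[intersect(a, names(ic$ic))]
}

#' Resnik pairwise class similarity
#'
#' The IC of the most informative common ancestor (MICA) of the two classes;
#' 0 when no common ancestor carries an IC entry.
#'
#' @param c1,c2 Class ids present in `graph`.
#' @param ic An `ic_table` from [information_content()].
#' @param graph An `ontology_graph`.
#' @return Non-negative number.
#' @export
resnik <- function(c1, c2, ic, graph) {
  assert_in_graph(graph, c1)
  assert_in_graph(graph, c2)
  common <- intersect(ancestors(graph, c1), ancestors(graph, c2))
  vals <- ic$ic[intersect(common, names(ic$ic))]
  if (!length(vals)) {
    return(0)
  }
  max(vals)
}

#' Best-Match-Average similarity between two class sets
#'
#' BMA(A, B) = ( avg over a in A of max over b in B of sim(a, b)
#'             + avg over b in B of max over a in A of sim(a, b) ) / 2
#' with Resnik pairwise similarity; symmetric by construction.
#'
#' @param set_a,set_b Non-empty character vectors of class ids.
#' @inheritParams resnik
#' @return Non-negative number.
#' @export
bma <- function(set_a, set_b, ic, graph) {
  if (!length(set_a) || !length(set_b)) {
    stop("BMA is undefined for an empty class set; filter unannotated genes first")
  }
  m <- matrix(0, nrow = length(set_a), ncol = length(set_b))
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      m[i, j] <- resnik(set_a[[i]], set_b[[j]], ic, graph)
    }
  }
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

# Pairwise Resnik matrix over a class vector, via precomputed IC-bearing
# ancestor sets (one pass per class, then set intersections per pair).
class_sim_matrix <- function(classes, ic, graph) {
  k <- length(classes)
  anc_ic <- lapply(classes, ic_bearing_ancestors, graph = graph, ic = ic)
  s <- matrix(0, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) {
    ai <- anc_ic[[i]]
    if (!length(ai)) next
    for (j in i:k) {
      common <- intersect(names(ai), names(anc_ic[[j]]))
      if (length(common)) {
        s[i, j] <- s[j, i] <- max(ai[common])
      }
    }
  }
  s
}

#' Gene-by-gene phenotype similarity matrix
#'
#' Pairwise Best-Match-Average Resnik similarity over the genes' phenotype
#' class sets (the corpus is used as given: pass direct annotations for
#' direct-set similarity). With `normalize = TRUE` all entries are divided
#' by the global maximum entry, so the largest similarity becomes 1 whenever
#' any similarity is nonzero; normalised values are used as interaction
#' prediction scores. Genes whose classes are all absent from the graph are
#' dropped with a warning.
#'
#' @param phenotypes A non-empty `annotation_corpus`.
#' @inheritParams resnik
#' @param normalize Divide by the global maximum entry.
#' @return A `similarity_matrix`: list with `genes`, symmetric `values`
#'   matrix and `normalized` flag.
#' @export
gene_similarity_matrix <- function(phenotypes, ic, graph, normalize = TRUE) {
  if (!nrow(phenotypes)) {
    stop("empty phenotype corpus")
  }
  df <- as.data.frame(phenotypes)
  in_graph <- df$class_id %in% graph$terms
  if (any(!in_graph)) {
    warning(sum(!in_graph), " annotation(s) to classes absent from the graph",
            " ignored in similarity", call. = FALSE)
    df <- df[in_graph, , drop = FALSE]
  }
  if (!nrow(df)) {
    stop("no annotations to classes present in the graph")
  }
  sets <- split(df$class_id, df$gene)
  sets <- lapply(sets, unique)
  genes <- sort(names(sets))
  sets <- sets[genes]
  classes <- sort(unique(df$class_id))
  s <- class_sim_matrix(classes, ic, graph)
  n <- length(genes)
  values <- matrix(0, n, n, dimnames = list(genes, genes))
  row_max <- function(m) apply(m, 1L, max)
  for (i in seq_len(n)) {
    ci <- sets[[i]]
    for (j in i:n) {
      m <- s[ci, sets[[j]], drop = FALSE]
      v <- (mean(row_max(m)) + mean(apply(m, 2L, max))) / 2
      values[i, j] <- values[j, i] <- v
    }
  }
  normalized <- FALSE
  if (isTRUE(normalize)) {
    mx <- max(values)
    if (mx > 0) values <- values / mx
    normalized <- TRUE
  }
  structure(
    list(genes = genes, values = values, normalized = normalized),
    class = "similarity_matrix"
  )
}

#' Long-format pair scores from a similarity matrix
#'
#' Unordered off-diagonal pairs (self-pairs are excluded from interaction
#' ranking).
#'
#' @param sim A `similarity_matrix`.
#' @return Data frame `gene1`, `gene2`, `score`.
#' @export
similarity_pairs <- function(sim) {
  n <- length(sim$genes)
  if (n < 2L) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  idx <- which(upper.tri(sim$values), arr.ind = TRUE)
  out <- data.frame(
    gene1 = sim$genes[idx[, 1L]], gene2 = sim$genes[idx[, 2L]],
    score = sim$values[idx], stringsAsFactors = FALSE
  )
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a similarity matrix / IC table as TSV
#'
#' @param sim A `similarity_matrix`.
#' @param ic An `ic_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  write.table(similarity_pairs(sim), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
write_ic_tsv <- function(ic, path) {
  df <- data.frame(class_id = names(ic$ic), ic = unname(ic$ic),
                   stringsAsFactors = FALSE)
  df <- df[order(df$class_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
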