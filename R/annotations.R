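#' Construct an annotation corpus
#'
#' A corpus is a data frame of gene-to-class assignments with columns `gene`,
#' `class_id`, `evidence`, `score` and `aspect` (GO aspect where known,
#' otherwise `NA`), carrying a `closed` attribute that records whether
#' ontology closure (annotation propagation) has been applied. Duplicate
#' (gene, class) rows are collapsed keeping the maximum score.
#'
#' @param df Data frame with at least `gene` and `class_id`; `evidence`,
#'   `score` (default 1.0) and `aspect` are filled in when absent.
#' @param closed Logical; `TRUE` after [propagate()].
#' @return An `annotation_corpus` (a data frame subclass).
#' @export
annotation_corpus <- function(df = NULL, closed = FALSE) {
  if (is.null(df)) {
    df <- data.frame(gene = character(), class_id = character(),
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "class_id") %in% names(df)))
  if (is.null(df$evidence)) df$evidence <- rep(NA_character_, nrow(df))
  if (is.null(df$score)) df$score <- rep(1.0, nrow(df))
  if (is.null(df$aspect)) df$aspect <- rep(NA_character_, nrow(df))
  df <- df[, c("gene", "class_id", "evidence", "score", "aspect")]
  if (nrow(df)) {
    if (any(!is.finite(df$score) | df$score <= 0 | df$score > 1)) {
      stop("annotation scores must lie in (0, 1]")
    }
    ord <- order(df$gene, df$class_id, -df$score, df$evidence)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df[c("gene", "class_id")]), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, closed = isTRUE(closed),
            class = c("annotation_corpus", "data.frame"))
}

#' Has ontology closure been applied to a corpus?
#' @param corpus An `annotation_corpus`.
#' @return Logical.
#' @export
is_closed <- function(corpus) isTRUE(attr(corpus, "closed"))

#' Number of distinct genes in a corpus
#' @param corpus An `annotation_corpus`.
#' @return Integer.
#' @export
n_genes <- function(corpus) length(unique(corpus$gene))

default_evidence_whitelist <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")
}

split_tsv_rows <- function(lines, comment_char = "!") {
  keep <- !startsWith(lines, comment_char) & nzchar(lines)
  list(rows = strsplit(lines[keep], "\t", fixed = TRUE),
       line_no = which(keep))
}

#' Parse a GAF 2.x function-annotation file
#'
#' Keeps rows whose evidence code (column 7) is in the whitelist — by default
#' the experimental and curated codes EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC,
#' so electronic (IEA) annotations are dropped. Negated rows (a `NOT`
#' qualifier in column 4) and context-specific rows (a non-empty annotation
#' extension in column 16, i.e. annotations conditional on a cell type,
#' tissue or developmental stage) are dropped by default. Kept rows get score
#' 1.0; the GO aspect (column 9) is retained.
#'
#' @param x Path (optionally gzipped), connection, or character lines.
#' @param evidence_whitelist Evidence codes to keep.
#' @param drop_negated Drop rows carrying a `NOT` qualifier.
#' @param drop_contextual Drop rows with a non-empty annotation extension.
#' @return An unclosed `annotation_corpus`.
#' @export
parse_gaf <- function(x, evidence_whitelist = default_evidence_whitelist(),
                      drop_negated = TRUE, drop_contextual = TRUE) {
  sp <- split_tsv_rows(read_text_lines(x))
  nfield <- lengths(sp$rows)
  bad <- which(nfield < 16L | nfield > 17L)
  if (length(bad)) {
    stop("GAF row with ", nfield[bad[1]], " columns (expected 16-17) at line ",
         sp$line_no[bad[1]])
  }
  if (!length(sp$rows)) {
    return(annotation_corpus())
  }
  m <- do.call(rbind, lapply(sp$rows, function(r) r[1:16]))
  qualifier <- m[, 4]
  keep <- m[, 7] %in% evidence_whitelist
  if (isTRUE(drop_negated)) {
    negated <- vapply(
      strsplit(qualifier, "|", fixed = TRUE),
      function(q) "NOT" %in% q, logical(1)
    )
    keep <- keep & !negated
  }
  if (isTRUE(drop_contextual)) {
    keep <- keep & !nzchar(m[, 16])
  }
  annotation_corpus(data.frame(
    gene = m[keep, 2], class_id = m[keep, 5], evidence = m[keep, 7],
    score = rep(1.0, sum(keep)), aspect = m[keep, 9],
    stringsAsFactors = FALSE
  ))
}

phenotype_dialects <- function() {
  list(
    simple = list(gene_col = 1L, class_col = 2L, class_prefix = NULL,
                  comment_char = "#"),
    # MGI_Gene_Pheno.rpt layout: allelic composition, allele symbol,
    # allele id, genetic background, MP id, PubMed, MGI marker accession
    mgi_gene_pheno = list(gene_col = 7L, class_col = 5L, class_prefix = "MP",
                          comment_char = "#"),
    # genes_to_phenotype.txt layout: entrez id, gene symbol, HPO term id, ...
    hpo_gene_pheno = list(gene_col = 2L, class_col = 3L, class_prefix = "HP",
                          comment_char = "#")
  )
}

#' Parse a gene-to-phenotype TSV file
#'
#' Supports three dialects: `simple` (gene, class), `mgi_gene_pheno`
#' (the MGI_Gene_Pheno.rpt layout; gene = MGI marker accession in column 7,
#' phenotype = MP id in column 5) and `hpo_gene_pheno` (HPO
#' genes_to_phenotype layout; gene symbol column 2, HP id column 3). Column
#' positions can be overridden. Rows whose class id does not carry the
#' dialect's expected prefix are skipped with a warning. All kept pairs get
#' score 1.0.
#'
#' @param x Path, connection, or character lines.
#' @param dialect One of `"simple"`, `"mgi_gene_pheno"`, `"hpo_gene_pheno"`.
#' @param gene_col,class_col Optional 1-based column overrides.
#' @param class_prefix Optional expected CURIE prefix (`NULL` = any).
#' @return An unclosed `annotation_corpus`.
#' @export
parse_phenotype_tsv <- function(x, dialect = c("simple", "mgi_gene_pheno",
                                               "hpo_gene_pheno"),
                                gene_col = NULL, class_col = NULL,
                                class_prefix = NULL) {
  dialect <- match.arg(dialect)
  d <- phenotype_dialects()[[dialect]]
  if (is.null(gene_col)) gene_col <- d$gene_col
  if (is.null(class_col)) class_col <- d$class_col
  if (is.null(class_prefix)) class_prefix <- d$class_prefix
  sp <- split_tsv_rows(read_text_lines(x), comment_char = d$comment_char)
  if (!length(sp$rows)) {
    return(annotation_corpus())
  }
  need <- max(gene_col, class_col)
  short <- which(lengths(sp$rows) < need)
  if (length(short)) {
    stop("phenotype TSV row with too few columns at line ", sp$line_no[short[1]])
  }
  gene <- vapply(sp$rows, `[[`, character(1), gene_col)
  class_id <- vapply(sp$rows, `[[`, character(1), class_col)
  ok <- grepl("^[A-Za-z][A-Za-z0-9_]*:\\S+$", class_id)
  if (!is.null(class_prefix)) {
    ok <- ok & curie_prefix(class_id) %in% class_prefix
  }
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with unexpected class id prefix skipped",
            call. = FALSE)
  }
  annotation_corpus(data.frame(
    gene = gene[ok], class_id = class_id[ok],
    stringsAsFactors = FALSE
  ))
}

#' Parse predicted function annotations with scores
#'
#' Reads a three-column TSV (gene, GO class, score) as produced by a
#' sequence-based function predictor. Scores must lie in (0, 1]; rows outside
#' that range raise an error naming the line. Records carry evidence code
#' `PRED`.
#'
#' @param x Path, connection, or character lines.
#' @return An unclosed `annotation_corpus` with the given scores.
#' @export
parse_predicted_functions <- function(x) {
  sp <- split_tsv_rows(read_text_lines(x), comment_char = "#")
  if (!length(sp$rows)) {
    return(annotation_corpus())
  }
  short <- which(lengths(sp$rows) < 3L)
  if (length(short)) {
    stop("predicted-function row with fewer than 3 columns at line ",
         sp$line_no[short[1]])
  }
  gene <- vapply(sp$rows, `[[`, character(1), 1L)
  class_id <- vapply(sp$rows, `[[`, character(1), 2L)
  score <- suppressWarnings(as.numeric(vapply(sp$rows, `[[`, character(1), 3L)))
  bad <- which(!is.finite(score) | score <= 0 | score > 1)
  if (length(bad)) {
    stop("prediction score outside (0, 1] at line ", sp$line_no[bad[1]])
  }
  annotation_corpus(data.frame(
    gene = gene, class_id = class_id, evidence = "PRED", score = score,
    stringsAsFactors = FALSE
  ))
}

#' Rename corpus genes through an identifier mapping
#'
#' Two source identifiers mapping onto one target merge their annotation
#' sets (per-class maximum score).
#'
#' @param corpus An `annotation_corpus`.
#' @param mapping Named character vector, `names = source id`,
#'   `values = target id`.
#' @param on_missing What to do with genes absent from the mapping:
#'   `"drop"` removes them (count reported via a message), `"keep"` passes
#'   them through unchanged, `"error"` aborts.
#' @return An `annotation_corpus` with renamed genes.
#' @export
map_ids <- function(corpus, mapping, on_missing = c("drop", "keep", "error")) {
  on_missing <- match.arg(on_missing)
  df <- as.data.frame(corpus)
  hit <- df$gene %in% names(mapping)
  if (any(!hit)) {
    n_missing <- length(unique(df$gene[!hit]))
    if (on_missing == "error") {
      stop(n_missing, " gene id(s) missing from the mapping")
    }
    if (on_missing == "drop") {
      message(n_missing, " unmapped gene id(s) dropped")
      df <- df[hit, , drop = FALSE]
      hit <- rep(TRUE, nrow(df))
    }
  }
  df$gene[hit] <- unname(mapping[df$gene[hit]])
  annotation_corpus(df, closed = is_closed(corpus))
}

#' Propagate annotations to all is_a ancestors
#'
#' Applies the true-path rule: every annotated class contributes annotations
#' to all of its ancestors, each ancestor receiving the maximum score over
#' the descendant annotations that reach it. Classes absent from the graph
#' are kept unpropagated with a warning. Idempotent; never decreases a score.
#'
#' @param corpus An `annotation_corpus`.
#' @param graph An `ontology_graph`.
#' @return A closed `annotation_corpus`.
#' @export
propagate <- function(corpus, graph) {
  if (!nrow(corpus)) {
    return(annotation_corpus(as.data.frame(corpus), closed = TRUE))
  }
  in_graph <- corpus$class_id %in% graph$terms
  if (any(!in_graph)) {
    warning(sum(!in_graph), " annotation(s) to classes absent from the graph",
            " kept without propagation", call. = FALSE)
  }
  anc_of <- function(cl) if (cl %in% graph$terms) ancestors(graph, cl) else cl
  anc_sets <- lapply(unique(corpus$class_id), anc_of)
  names(anc_sets) <- unique(corpus$class_id)
  reps <- lengths(anc_sets[corpus$class_id])
  expanded <- data.frame(
    gene = rep(corpus$gene, reps),
    class_id = unlist(anc_sets[corpus$class_id], use.names = FALSE),
    evidence = rep(corpus$evidence, reps),
    score = rep(corpus$score, reps),
    aspect = rep(corpus$aspect, reps),
    stringsAsFactors = FALSE
  )
  annotation_corpus(expanded, closed = TRUE)
}

#' Parse a STRING-style protein-links file
#'
#' Whitespace-separated rows of (protein1, protein2, combined score); a
#' header row is detected and skipped. Keeps pairs with score >=
#' `min_score` (the conventional low-confidence cutoff of 300 by default),
#' maps endpoints through `id_map` when given (pairs with an unmappable
#' endpoint are dropped), removes self-pairs, and canonicalises each pair as
#' (min, max) by string order with duplicates removed.
#'
#' @param x Path, connection, or character lines.
#' @param min_score Minimum combined score (inclusive).
#' @param id_map Optional named character vector mapping protein ids to gene
#'   ids.
#' @return Data frame `gene1`, `gene2` of unordered pairs.
#' @export
parse_string_links <- function(x, min_score = 300, id_map = NULL) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(trimws(lines), "\\s+")
  short <- which(lengths(rows) < 3L)
  if (length(short)) {
    stop("protein-links row with fewer than 3 columns at line ", short[1])
  }
  if (length(rows) && is.na(suppressWarnings(as.numeric(rows[[1]][3])))) {
    rows <- rows[-1] # header
  }
  if (!length(rows)) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      stringsAsFactors = FALSE))
  }
  a <- vapply(rows, `[[`, character(1), 1L)
  b <- vapply(rows, `[[`, character(1), 2L)
  s <- as.numeric(vapply(rows, `[[`, character(1), 3L))
  keep <- is.finite(s) & s >= min_score
  a <- a[keep]
  b <- b[keep]
  if (!is.null(id_map)) {
    ok <- a %in% names(id_map) & b %in% names(id_map)
    a <- unname(id_map[a[ok]])
    b <- unname(id_map[b[ok]])
  }
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  out <- data.frame(
    gene1 = pmin(a, b), gene2 = pmax(a, b), stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
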