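#' Quality configuration for Entity-Quality decomposition
#'
#' Declares which PATO-style quality classes encode an increased rate, a
#' decreased rate, and plain abnormality, and which CURIE prefixes are treated
#' as process/function entities. The abnormal quality doubles as a modifier:
#' a definition carrying both an increased/decreased quality and the abnormal
#' quality decomposes to increased/decreased (the abnormality is a constraint
#' distinguishing the phenotype from a physiological change, not a direction).
#'
#' @param increased_qualities Class ids read as "increased rate"
#'   (default `PATO:0000912`, increased rate).
#' @param decreased_qualities Class ids read as "decreased rate"
#'   (default `PATO:0000911`, decreased rate).
#' @param abnormal_qualities Class ids read as "abnormal"
#'   (default `PATO:0000460`, abnormal).
#' @param entity_prefixes CURIE prefixes accepted as entities (default `GO`).
#' @return A `quality_config` list. The three quality sets must be pairwise
#'   disjoint.
#' @export
quality_config <- function(increased_qualities = "PATO:0000912",
                           decreased_qualities = "PATO:0000911",
                           abnormal_qualities = "PATO:0000460",
                           entity_prefixes = "GO") {
  sets <- list(increased_qualities, decreased_qualities, abnormal_qualities)
  all_q <- unlist(sets)
  if (anyDuplicated(all_q)) {
    stop("quality sets must be pairwise disjoint; shared: ",
         paste(unique(all_q[duplicated(all_q)]), collapse = ", "))
  }
  structure(
    list(
      increased_qualities = increased_qualities,
      decreased_qualities = decreased_qualities,
      abnormal_qualities = abnormal_qualities,
      entity_prefixes = entity_prefixes
    ),
    class = "quality_config"
  )
}

#' Read a quality configuration from a YAML file
#'
#' Expected keys: `increased_qualities`, `decreased_qualities`,
#' `abnormal_qualities`, `entity_prefixes`; missing keys fall back to the
#' [quality_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `quality_config`.
#' @export
read_quality_config <- function(path) {
  y <- yaml::read_yaml(path)
  d <- quality_config()
  pick <- function(key) if (!is.null(y[[key]])) as.character(y[[key]]) else d[[key]]
  quality_config(
    increased_qualities = pick("increased_qualities"),
    decreased_qualities = pick("decreased_qualities"),
    abnormal_qualities = pick("abnormal_qualities"),
    entity_prefixes = pick("entity_prefixes")
  )
}

curie_prefix <- function(x) sub(":.*$", "", x)

#' Decompose one phenotype class into an entity and a direction
#'
#' Applies the Entity-Quality reading to a phenotype class's logical
#' definition: the unique filler with an entity prefix becomes the entity,
#' and the quality fillers determine the direction (`increased`, `decreased`,
#' or `abnormal`). Returns `NULL` when the class has no logical definition,
#' no or several candidate entities, or no configured quality; a definition
#' carrying qualities from both the increased and the decreased set is
#' ambiguous and yields `NULL` with a warning.
#'
#' @param graph An `ontology_graph` (typically the phenotype ontology).
#' @param class_id Phenotype class id.
#' @param quality A [quality_config()].
#' @return A list with `phenotype_class`, `entity`, `direction`, or `NULL`.
#' @export
decompose_phenotype_class <- function(graph, class_id, quality = quality_config()) {
  assert_in_graph(graph, class_id)
  def <- graph$logical_defs[[class_id]]
  if (is.null(def)) {
    return(NULL)
  }
  fillers <- c(def$genus, def$differentia$filler)
  entities <- unique(fillers[curie_prefix(fillers) %in% quality$entity_prefixes])
  if (length(entities) != 1L) {
    return(NULL)
  }
  inc <- any(fillers %in% quality$increased_qualities)
  dec <- any(fillers %in% quality$decreased_qualities)
  abn <- any(fillers %in% quality$abnormal_qualities)
  if (inc && dec) {
    warning("ambiguous direction for ", class_id,
            ": both increased and decreased qualities present", call. = FALSE)
    return(NULL)
  }
  direction <- if (inc) "increased" else if (dec) "decreased" else if (abn) "abnormal" else NA
  if (is.na(direction)) {
    return(NULL)
  }
  list(phenotype_class = class_id, entity = entities, direction = direction)
}

#' Decompose every phenotype class in an ontology
#'
#' @inheritParams decompose_phenotype_class
#' @return Data frame with columns `phenotype_class`, `entity`, `direction`
#'   (one row per decomposable class), sorted by `phenotype_class`.
#' @export
decompose_phenotypes <- function(graph, quality = quality_config()) {
  rows <- lapply(names(graph$logical_defs), function(id) {
    d <- decompose_phenotype_class(graph, id, quality)
    if (is.null(d)) NULL else as.data.frame(d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      phenotype_class = character(), entity = character(),
      direction = character(), stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$phenotype_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Index regulation classes of a GO-like ontology
#'
#' Collects every class whose logical definition contains a
#' `positively_regulates` or `negatively_regulates` differentia, yielding one
#' record per (regulator, regulated process, sign). The genus is unrestricted
#' by default so that trimmed ontologies whose definitions omit the
#' 'biological regulation' genus still index; pass `genus` to restore
#' strictness. Classes defined with both signs are unusual and emit a warning,
#' but both records are kept.
#'
#' @param graph An `ontology_graph`.
#' @param genus Optional class id; when given, only definitions whose genus
#'   set contains it are indexed.
#' @param use_relationship_fallback When `TRUE`, plain `relationship:`
#'   regulation edges (no logical definition) also contribute records.
#' @return Data frame `regulator`, `regulated`, `sign` (`positive`/`negative`),
#'   deduplicated and sorted.
#' @export
index_regulations <- function(graph, genus = NULL,
                              use_relationship_fallback = FALSE) {
  sign_of <- c(positively_regulates = "positive", negatively_regulates = "negative")
  rows <- lapply(names(graph$logical_defs), function(id) {
    def <- graph$logical_defs[[id]]
    if (!is.null(genus) && !genus %in% def$genus) {
      return(NULL)
    }
    d <- def$differentia
    d <- d[d$relation %in% names(sign_of), , drop = FALSE]
    if (!nrow(d)) {
      return(NULL)
    }
    if (length(unique(d$relation)) > 1L) {
      warning("class ", id, " is defined with both regulation signs", call. = FALSE)
    }
    data.frame(
      regulator = id, regulated = d$filler,
      sign = unname(sign_of[d$relation]), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (isTRUE(use_relationship_fallback)) {
    rel <- graph$relationships
    rel <- rel[rel$relation %in% names(sign_of), , drop = FALSE]
    if (nrow(rel)) {
      out <- rbind(out, data.frame(
        regulator = rel$source, regulated = rel$target,
        sign = unname(sign_of[rel$relation]), stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(out)) {
    out <- data.frame(
      regulator = character(), regulated = character(), sign = character(),
      stringsAsFactors = FALSE
    )
  }
  out <- out[out$regulator != out$regulated, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$regulator, out$regulated, out$sign), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_rule_frame <- function() {
  data.frame(
    function_class = character(), phenotype_class = character(),
    rule_kind = character(), stringsAsFactors = FALSE
  )
}

finish_rule_frame <- function(out) {
  if (is.null(out) || !nrow(out)) {
    return(empty_rule_frame())
  }
  out <- unique(out)
  out <- out[order(out$function_class, out$phenotype_class, out$rule_kind), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate correspondence rules between functions and phenotypes
#'
#' Implements the three loss-of-function meta-rules. For a regulation record
#' (r, p, positive) and a decomposition (ph, p, decreased), loss of the
#' positive regulator r predicts the decreased-rate phenotype ph (`inc_dec`).
#' For (r, p, negative) and (ph, p, increased), loss of the negative regulator
#' predicts the increased-rate phenotype (`dec_inc`). Every abnormal
#' decomposition (ph, p, abnormal) yields the unconditional rule that loss of
#' a gene involved in p predicts the abnormal-p phenotype (`abnormal`).
#'
#' @param regulations Data frame from [index_regulations()].
#' @param decompositions Data frame from [decompose_phenotypes()].
#' @return Data frame `function_class`, `phenotype_class`, `rule_kind`,
#'   deduplicated and sorted (byte-stable ordering).
#' @export
build_correspondence_rules <- function(regulations, decompositions) {
  join <- function(sign, direction, kind) {
    r <- regulations[regulations$sign == sign, , drop = FALSE]
    d <- decompositions[decompositions$direction == direction, , drop = FALSE]
    m <- merge(r, d, by.x = "regulated", by.y = "entity")
    if (!nrow(m)) {
      return(NULL)
    }
    data.frame(
      function_class = m$regulator, phenotype_class = m$phenotype_class,
      rule_kind = kind, stringsAsFactors = FALSE
    )
  }
  abn <- decompositions[decompositions$direction == "abnormal", , drop = FALSE]
  abn_rows <- if (nrow(abn)) {
    data.frame(
      function_class = abn$entity, phenotype_class = abn$phenotype_class,
      rule_kind = "abnormal", stringsAsFactors = FALSE
    )
  } else {
    NULL
  }
  finish_rule_frame(rbind(
    join("positive", "decreased", "inc_dec"),
    join("negative", "increased", "dec_inc"),
    abn_rows
  ))
}

#' Generate inconsistency patterns (mirror of the correspondence rules)
#'
#' A function/phenotype class pair that contradicts the rules: a positive
#' regulator of p paired with the increased-p phenotype (violating `inc_dec`),
#' or a negative regulator paired with the decreased-p phenotype (violating
#' `dec_inc`). A gene co-annotated to both members of a pattern carries
#' mutually inconsistent annotations.
#'
#' @inheritParams build_correspondence_rules
#' @return Data frame `function_class`, `phenotype_class`, `rule_kind` (the
#'   violated rule), deduplicated and sorted.
#' @export
build_inconsistency_patterns <- function(regulations, decompositions) {
  join <- function(sign, direction, kind) {
    r <- regulations[regulations$sign == sign, , drop = FALSE]
    d <- decompositions[decompositions$direction == direction, , drop = FALSE]
    m <- merge(r, d, by.x = "regulated", by.y = "entity")
    if (!nrow(m)) {
      return(NULL)
    }
    data.frame(
      function_class = m$regulator, phenotype_class = m$phenotype_class,
      rule_kind = kind, stringsAsFactors = FALSE
    )
  }
  finish_rule_frame(rbind(
    join("positive", "increased", "inc_dec"),
    join("negative", "decreased", "dec_inc")
  ))
}

#' Write / read rule and pattern tables as TSV
#'
#' Serialises `function_class`, `phenotype_class`, `rule_kind` with a header
#' line; identical inputs produce byte-identical files.
#'
#' @param rules Data frame as produced by [build_correspondence_rules()] or
#'   [build_inconsistency_patterns()].
#' @param path Output (input) file path.
#' @return `write_rules_tsv` returns `path` invisibly; `read_rules_tsv`
#'   returns the data frame.
#' @export
write_rules_tsv <- function(rules, path) {
  write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules_tsv
#' @export
read_rules_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character")
}
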