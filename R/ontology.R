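#' Default relation vocabulary for OBO parsing
#'
#' Relation names recognised without a warning flag. Covers the regulation
#' relations that define GO regulation classes and the relations used in
#' Entity-Quality phenotype definitions.
#'
#' @return Character vector of relation names.
#' @export
obo_relation_vocabulary <- function() {
  c(
    "part_of", "regulates", "positively_regulates", "negatively_regulates",
    "occurs_in", "results_in", "has_part", "towards",
    "phenotype_of", "inheres_in", "has_quality", "has_modifier"
  )
}

read_text_lines <- function(x) {
  if (inherits(x, "connection")) {
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    con <- gzfile(x, "rt") # reads plain text transparently as well
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (is.character(x)) {
    return(x)
  }
  stop("input must be a file path, a connection, or a character vector of lines")
}

strip_obo_comment <- function(x) {
  sub("\\s*!.*$", "", x)
}

#' Parse an OBO ontology into a queryable graph
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas into an `ontology_graph`: declared
#' classes with labels, the `is_a` DAG, labelled `relationship` edges, and
#' structured logical definitions assembled from `intersection_of` tag groups
#' (a bare class becomes the genus; a relation + class pair becomes a
#' differentia). Obsolete terms are dropped with a warning and contribute no
#' edges. Gzip-compressed files are read transparently.
#'
#' @param x Path to an OBO file (optionally gzipped), a connection, or a
#'   character vector of OBO lines.
#' @param relation_vocabulary Character vector of recognised relation names.
#'   Unknown relation names are retained verbatim but flagged
#'   (`known = FALSE` in differentia / relationship records).
#'
#' @return An object of class `ontology_graph`: a list with elements
#'   `terms` (character), `labels` (named character), `parents` (named list of
#'   `is_a` parents), `relationships` (data frame `relation`, `source`,
#'   `target`, `known`), `logical_defs` (named list with `genus` and
#'   `differentia` per defined class), and `roots`.
#'
#' @details Errors are raised for duplicate term ids, malformed stanza lines
#'   (with the line number), `is_a`/`relationship` edges whose endpoints are
#'   not declared in the file, and cyclic `is_a` structure (one cycle is
#'   named). Logical-definition fillers may reference classes external to the
#'   file (e.g. GO ids inside a phenotype ontology) and are not required to be
#'   declared.
#' @export
parse_obo <- function(x, relation_vocabulary = obo_relation_vocabulary()) {
  lines <- read_text_lines(x)
  stanza <- NA_character_
  terms <- list()
  cur <- NULL

  flush_term <- function(cur, terms) {
    if (is.null(cur)) {
      return(terms)
    }
    if (is.null(cur$id)) {
      stop("[Term] stanza without an id tag (near line ", cur$line, ")")
    }
    if (!is.null(terms[[cur$id]])) {
      stop("duplicate term id: ", cur$id)
    }
    terms[[cur$id]] <- cur
    terms
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      terms <- flush_term(cur, terms)
      cur <- NULL
      stanza <- line
      if (identical(line, "[Term]")) {
        cur <- list(
          line = i, id = NULL, name = NA_character_, is_a = character(),
          rels = list(), xof = list(), obsolete = FALSE
        )
      }
      next
    }
    if (!identical(stanza, "[Term]")) next # header or Typedef content
    m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_-]*):\\s*(.*)$", line))[[1]]
    if (length(m) == 0L) {
      stop("malformed OBO line ", i, ": ", line)
    }
    tag <- m[[2]]
    val <- strip_obo_comment(m[[3]])
    if (tag == "id") {
      cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "is_a") {
      cur$is_a <- c(cur$is_a, val)
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    } else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) != 2L) {
        stop("malformed relationship on line ", i, ": ", line)
      }
      cur$rels[[length(cur$rels) + 1L]] <- parts
    } else if (tag == "intersection_of") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (!length(parts) %in% 1:2) {
        stop("malformed intersection_of on line ", i, ": ", line)
      }
      cur$xof[[length(cur$xof) + 1L]] <- parts
    }
    # other tags (def, synonym, xref, ...) are ignored
  }
  terms <- flush_term(cur, terms)

  obsolete <- vapply(terms, function(t) isTRUE(t$obsolete), logical(1))
  if (any(obsolete)) {
    warning(sum(obsolete), " obsolete term(s) dropped", call. = FALSE)
    terms <- terms[!obsolete]
  }

  ids <- names(terms)
  labels <- vapply(terms, function(t) t$name, character(1))
  parents <- lapply(terms, function(t) unique(t$is_a))

  missing_parents <- setdiff(unique(unlist(parents)), ids)
  if (length(missing_parents)) {
    stop(
      "is_a parent(s) not declared in the ontology: ",
      paste(missing_parents, collapse = ", ")
    )
  }

  rel_list <- unlist(lapply(terms, function(t) {
    lapply(t$rels, function(r) data.frame(
      relation = r[[1]], source = t$id, target = r[[2]],
      stringsAsFactors = FALSE
    ))
  }), recursive = FALSE)
  rel_rows <- if (length(rel_list)) do.call(rbind, rel_list) else NULL
  if (is.null(rel_rows)) {
    rel_rows <- data.frame(
      relation = character(), source = character(), target = character(),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(rel_rows)) {
    missing_rel <- setdiff(rel_rows$target, ids)
    if (length(missing_rel)) {
      stop(
        "relationship target(s) not declared in the ontology: ",
        paste(missing_rel, collapse = ", ")
      )
    }
  }
  rel_rows$known <- rel_rows$relation %in% relation_vocabulary

  logical_defs <- list()
  for (id in ids) {
    xof <- terms[[id]]$xof
    if (!length(xof)) next
    genus <- unlist(lapply(xof, function(p) if (length(p) == 1L) p else NULL))
    diff_parts <- Filter(function(p) length(p) == 2L, xof)
    differentia <- data.frame(
      relation = vapply(diff_parts, `[[`, character(1), 1L),
      filler = vapply(diff_parts, `[[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
    differentia$known <- differentia$relation %in% relation_vocabulary
    logical_defs[[id]] <- list(
      defined_class = id,
      genus = if (length(genus)) genus else character(),
      differentia = differentia
    )
  }

  check_is_a_acyclic(parents)

  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  structure(
    list(
      terms = ids,
      labels = labels,
      parents = parents,
      relationships = rel_rows,
      logical_defs = logical_defs,
      roots = roots,
      cache = new.env(parent = emptyenv())
    ),
    class = "ontology_graph"
  )
}

# Kahn's algorithm; on failure walk the residual graph to name one cycle.
check_is_a_acyclic <- function(parents) {
  ids <- names(parents)
  indeg <- vapply(parents, length, integer(1)) # edges point child -> parent
  children <- list()
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  queue <- ids[indeg == 0L]
  done <- 0L
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    done <- done + 1L
    for (ch in children[[cur]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < length(ids)) {
    residual <- ids[indeg > 0L]
    # follow parent links inside the residual set until a repeat
    path <- residual[[1L]]
    repeat {
      nxt <- intersect(parents[[path[length(path)]]], residual)[1L]
      if (nxt %in% path) {
        cyc <- c(path[seq(match(nxt, path), length(path))], nxt)
        stop("cyclic is_a structure: ", paste(cyc, collapse = " -> "))
      }
      path <- c(path, nxt)
    }
  }
  invisible(TRUE)
}

#' Number of classes in an ontology graph
#' @param graph An `ontology_graph`.
#' @return Integer count of (non-obsolete) classes.
#' @export
n_classes <- function(graph) length(graph$terms)

#' @export
print.ontology_graph <- function(x, ...) {
  cat(
    "<ontology_graph> ", length(x$terms), " classes, ",
    sum(lengths(x$parents)), " is_a edges, ",
    length(x$logical_defs), " logical definitions, roots: ",
    paste(x$roots, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

assert_in_graph <- function(graph, class_id) {
  if (!class_id %in% graph$terms) {
    stop("unknown class: ", class_id)
  }
}

closure_walk <- function(link_map, class_id) {
  seen <- character()
  queue <- class_id
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, link_map[[cur]])
  }
  sort(seen)
}

children_map <- function(graph) {
  cache <- graph$cache
  if (is.null(cache$children)) {
    ch <- lapply(graph$terms, function(...) character())
    names(ch) <- graph$terms
    for (id in graph$terms) {
      for (p in graph$parents[[id]]) ch[[p]] <- c(ch[[p]], id)
    }
    cache$children <- ch
  }
  cache$children
}

#' Reflexive-transitive is_a ancestors of a class
#'
#' Self-inclusive closure over `is_a` edges only (`part_of` and other
#' relationships never contribute), matching subclass-based inference.
#'
#' @param graph An `ontology_graph`.
#' @param class_id Class identifier (CURIE string).
#' @return Sorted character vector of ancestor ids, including `class_id`.
#' @export
ancestors <- function(graph, class_id) {
  assert_in_graph(graph, class_id)
  cache <- graph$cache
  if (is.null(cache$anc)) cache$anc <- list()
  hit <- cache$anc[[class_id]]
  if (!is.null(hit)) {
    return(hit)
  }
  out <- closure_walk(graph$parents, class_id)
  cache$anc[[class_id]] <- out
  out
}

#' Reflexive-transitive is_a descendants of a class
#'
#' @inheritParams ancestors
#' @return Sorted character vector of descendant ids, including `class_id`.
#' @export
descendants <- function(graph, class_id) {
  assert_in_graph(graph, class_id)
  cache <- graph$cache
  if (is.null(cache$desc)) cache$desc <- list()
  hit <- cache$desc[[class_id]]
  if (!is.null(hit)) {
    return(hit)
  }
  out <- closure_walk(children_map(graph), class_id)
  cache$desc[[class_id]] <- out
  out
}
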