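# Independent brute-force oracles. These deliberately avoid the package's
# own traversal/joining code paths: closure is computed by boolean matrix
# powering, joins by double loops, metrics by literal transliteration.

# A[c, a] == 1 iff a is a (reflexive-transitive) is_a ancestor of c
oracle_closure_matrix <- function(graph) {
  ids <- graph$terms
  n <- length(ids)
  A <- diag(1, n)
  rownames(A) <- colnames(A) <- ids
  for (id in ids) {
    for (p in graph$parents[[id]]) A[id, p] <- 1
  }
  repeat {
    B <- ((A %*% A) > 0) * 1
    if (all(B == A)) break
    A <- B
  }
  A
}

oracle_ancestors <- function(graph, id, closure = oracle_closure_matrix(graph)) {
  sort(colnames(closure)[closure[id, ] > 0])
}

oracle_descendants <- function(graph, id, closure = oracle_closure_matrix(graph)) {
  sort(rownames(closure)[closure[, id] > 0])
}

oracle_rules <- function(regs, decs) {
  out <- list()
  for (i in seq_len(nrow(regs))) {
    for (j in seq_len(nrow(decs))) {
      if (regs$regulated[i] != decs$entity[j]) next
      if (regs$sign[i] == "positive" && decs$direction[j] == "decreased") {
        out[[length(out) + 1]] <- c(regs$regulator[i], decs$phenotype_class[j], "inc_dec")
      }
      if (regs$sign[i] == "negative" && decs$direction[j] == "increased") {
        out[[length(out) + 1]] <- c(regs$regulator[i], decs$phenotype_class[j], "dec_inc")
      }
    }
  }
  for (j in seq_len(nrow(decs))) {
    if (decs$direction[j] == "abnormal") {
      out[[length(out) + 1]] <- c(decs$entity[j], decs$phenotype_class[j], "abnormal")
    }
  }
  oracle_rule_frame(out)
}

oracle_patterns <- function(regs, decs) {
  out <- list()
  for (i in seq_len(nrow(regs))) {
    for (j in seq_len(nrow(decs))) {
      if (regs$regulated[i] != decs$entity[j]) next
      if (regs$sign[i] == "positive" && decs$direction[j] == "increased") {
        out[[length(out) + 1]] <- c(regs$regulator[i], decs$phenotype_class[j], "inc_dec")
      }
      if (regs$sign[i] == "negative" && decs$direction[j] == "decreased") {
        out[[length(out) + 1]] <- c(regs$regulator[i], decs$phenotype_class[j], "dec_inc")
      }
    }
  }
  oracle_rule_frame(out)
}

oracle_rule_frame <- function(rows) {
  if (!length(rows)) {
    return(data.frame(function_class = character(), phenotype_class = character(),
                      rule_kind = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  df <- unique(data.frame(function_class = m[, 1], phenotype_class = m[, 2],
                          rule_kind = m[, 3], stringsAsFactors = FALSE))
  df <- df[order(df$function_class, df$phenotype_class, df$rule_kind), ]
  rownames(df) <- NULL
  df
}

# gene-counting IC over the closure matrix
oracle_ic <- function(phenotypes, graph) {
  closure <- oracle_closure_matrix(graph)
  genes <- unique(phenotypes$gene)
  classes <- graph$terms
  counts <- sapply(classes, function(cl) {
    sum(sapply(genes, function(g) {
      direct <- phenotypes$class_id[phenotypes$gene == g]
      direct <- intersect(direct, graph$terms)
      any(closure[direct, cl, drop = FALSE] > 0)
    }))
  })
  ic <- -log(counts[counts > 0] / length(genes))
  ic
}

oracle_resnik <- function(c1, c2, ic, graph,
                          closure = oracle_closure_matrix(graph)) {
  best <- 0
  for (a in names(ic)) {
    if (!a %in% colnames(closure)) next
    if (closure[c1, a] > 0 && closure[c2, a] > 0 && ic[[a]] > best) {
      best <- ic[[a]]
    }
  }
  best
}

oracle_bma <- function(A, B, ic, graph, closure = oracle_closure_matrix(graph)) {
  best_ab <- sapply(A, function(a) max(sapply(B, function(b)
    oracle_resnik(a, b, ic, graph, closure))))
  best_ba <- sapply(B, function(b) max(sapply(A, function(a)
    oracle_resnik(a, b, ic, graph, closure))))
  (mean(best_ab) + mean(best_ba)) / 2
}

# literal transliteration of the Fmax formulas over a threshold grid
oracle_fmax <- function(pred, truth, graph, thresholds) {
  closure <- oracle_closure_matrix(graph)
  roots <- graph$roots
  close_set <- function(classes) {
    out <- character()
    for (cl in classes) {
      out <- union(out, if (cl %in% rownames(closure)) {
        colnames(closure)[closure[cl, ] > 0]
      } else {
        cl
      })
    }
    setdiff(out, roots)
  }
  truth_sets <- lapply(split(truth$class_id, truth$gene), close_set)
  truth_sets <- truth_sets[sapply(truth_sets, length) > 0]
  pred_genes <- unique(pred$gene)
  eval_genes <- intersect(names(truth_sets), pred_genes)
  n <- length(eval_genes)
  best <- 0
  for (t in thresholds) {
    prs <- c()
    rcs <- c()
    for (g in eval_genes) {
      cls <- pred$phenotype_class[pred$gene == g & pred$score >= t]
      P <- close_set(cls)
      Ti <- truth_sets[[g]]
      tp <- length(intersect(P, Ti))
      if (length(P) > 0) prs <- c(prs, tp / length(P))
      rcs <- c(rcs, tp / length(Ti))
    }
    if (!length(prs)) next
    avg_pr <- mean(prs)
    avg_rc <- sum(rcs) / n
    if (avg_pr + avg_rc > 0) {
      f <- 2 * avg_pr * avg_rc / (avg_pr + avg_rc)
      if (f > best) best <- f
    }
  }
  best
}

# ( #(pos > neg) + 0.5 * #(pos == neg) ) / (P * N)
oracle_auc <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      if (p > q) wins <- wins + 1 else if (p == q) wins <- wins + 0.5
    }
  }
  wins / (length(pos_scores) * length(neg_scores))
}

# triple loop over genes x function annotations x phenotype annotations
oracle_check <- function(functions, phenotypes, patterns, mode = "exact",
                         graph = NULL) {
  closure <- if (!is.null(graph)) oracle_closure_matrix(graph) else NULL
  rows <- list()
  for (g in unique(functions$gene)) {
    fs <- functions$class_id[functions$gene == g]
    ps <- phenotypes$class_id[phenotypes$gene == g]
    for (f in fs) {
      for (p in ps) {
        for (k in seq_len(nrow(patterns))) {
          if (patterns$function_class[k] != f) next
          pc <- patterns$phenotype_class[k]
          if (p == pc) {
            rows[[length(rows) + 1]] <- c(g, f, pc, NA)
          } else if (mode == "inferred" && pc %in% rownames(closure) &&
                       p %in% rownames(closure) && closure[p, pc] > 0) {
            rows[[length(rows) + 1]] <- c(g, f, pc, p)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), function_class = character(),
                      phenotype_class = character(),
                      inferred_via = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  df <- unique(data.frame(gene = m[, 1], function_class = m[, 2],
                          phenotype_class = m[, 3], inferred_via = m[, 4],
                          stringsAsFactors = FALSE))
  df <- df[order(df$gene, df$function_class, df$phenotype_class,
                 df$inferred_via, na.last = FALSE), ]
  rownames(df) <- NULL
  df
}
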