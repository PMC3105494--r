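# Independent brute-force oracles the structural implementation is
# checked against.  They share no code with the package internals: the
# closure is computed by Floyd-Warshall over a boolean matrix and every
# definition is evaluated literally.

# reflexive-transitive closure matrix over the named classes of an
# axiom data frame (subclass edges + both directions of equivalences)
oracle_closure <- function(ax) {
  classes <- sort(unique(c(ax$lhs, ax$rhs)))
  n <- length(classes)
  R <- diag(n) > 0
  dimnames(R) <- list(classes, classes)
  for (i in seq_len(nrow(ax))) {
    if (ax$kind[i] == "subclass_of") R[ax$lhs[i], ax$rhs[i]] <- TRUE
    if (ax$kind[i] == "equivalent_classes") {
      R[ax$lhs[i], ax$rhs[i]] <- TRUE
      R[ax$rhs[i], ax$lhs[i]] <- TRUE
    }
  }
  for (k in seq_len(n)) R <- R | (R[, k] %o% R[k, ])
  R
}

oracle_disjoint_pairs <- function(ax) {
  d <- ax[ax$kind == "disjoint_classes", c("lhs", "rhs"), drop = FALSE]
  rownames(d) <- NULL
  d
}

# a and b disjoint iff some told pair lies over them (ancestor check)
oracle_disjoint <- function(R, d, a, b) {
  if (!nrow(d)) return(FALSE)
  anc <- function(x) if (x %in% rownames(R)) colnames(R)[R[x, ]] else x
  any((d$lhs %in% anc(a) & d$rhs %in% anc(b)) |
      (d$lhs %in% anc(b) & d$rhs %in% anc(a)))
}

oracle_unsatisfiable <- function(ax) {
  R <- oracle_closure(ax)
  d <- oracle_disjoint_pairs(ax)
  if (!nrow(d)) return(character(0))
  classes <- rownames(R)
  unsat <- vapply(classes, function(cl) {
    anc <- colnames(R)[R[cl, ]]
    any(d$lhs %in% anc & d$rhs %in% anc)
  }, TRUE)
  sort(classes[unsat])
}

# literal evaluation of the conservativity condition on every mapping
# pair: same opposite-source endpoint, distinct own-source entities not
# entailed equivalent by the source alone
oracle_conservativity <- function(source_ax, m, side, side_is_source1) {
  R <- oracle_closure(source_ax)
  eq <- function(a, b) {
    if (a == b) return(TRUE)
    if (!(a %in% rownames(R)) || !(b %in% rownames(R))) return(FALSE)
    R[a, b] && R[b, a]
  }
  own <- if (side_is_source1) m$entity1 else m$entity2
  opp <- if (side_is_source1) m$entity2 else m$entity1
  out <- list()
  nm <- nrow(m)
  for (i in seq_len(nm - 1L)) {
    for (j in seq(i + 1L, nm)) {
      if (opp[i] != opp[j]) next
      if (own[i] == own[j]) next
      if (eq(own[i], own[j])) next
      ids <- sort(c(m$id[i], m$id[j]))
      out[[length(out) + 1L]] <- ids
    }
  }
  if (!length(out)) {
    return(data.frame(mapping1_id = character(0), mapping2_id = character(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res[, 1L], res[, 2L]), , drop = FALSE]
  data.frame(mapping1_id = res[, 1L], mapping2_id = res[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

# exhaustive minimum-weight vertex cover over all 2^n vertex subsets
oracle_min_cover_weight <- function(edges, weights) {
  verts <- sort(unique(c(edges[, 1L], edges[, 2L])))
  n <- length(verts)
  best <- Inf
  for (mask in 0:(2^n - 1L)) {
    inset <- verts[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    covered <- all(edges[, 1L] %in% inset | edges[, 2L] %in% inset)
    if (covered) best <- min(best, sum(weights[inset]))
  }
  best
}

# random ontology over named-class axioms only (for oracle comparisons)
random_named_ontology <- function(n_classes, n_sub, n_eq = 0L, n_dis = 0L,
                                  name = "RND") {
  classes <- sprintf("C%02d", seq_len(n_classes))
  pick <- function(k) {
    i <- sample.int(n_classes, k, replace = TRUE)
    j <- sample.int(n_classes, k, replace = TRUE)
    keep <- i != j
    data.frame(lhs = classes[i[keep]], rhs = classes[j[keep]],
               stringsAsFactors = FALSE)
  }
  sub <- pick(n_sub); eq <- pick(n_eq); dis <- pick(n_dis)
  ax <- axiom_table(
    c(rep("subclass_of", nrow(sub)), rep("equivalent_classes", nrow(eq)),
      rep("disjoint_classes", nrow(dis))),
    c(sub$lhs, eq$lhs, dis$lhs),
    c(sub$rhs, eq$rhs, dis$rhs)
  )
  ontology(name, ax)
}

# random mapping set between two entity pools
random_mapping_set <- function(pair, ents1, ents2, n) {
  e1 <- sample(ents1, n, replace = TRUE)
  e2 <- sample(ents2, n, replace = TRUE)
  m <- data.frame(
    cui = "", source1 = pair[1L], entity1 = e1,
    source2 = pair[2L], entity2 = e2,
    relation = "equivalence", confidence = NA_real_,
    stringsAsFactors = FALSE
  )
  m <- m[!duplicated(m[c("entity1", "entity2")]), , drop = FALSE]
  m$id <- sprintf("map%03d", seq_len(nrow(m)))
  mapping_set(pair, m[c("id", "cui", "source1", "entity1", "source2",
                        "entity2", "relation", "confidence")])
}

random_conflict_graph_df <- function(n_vertices, n_edges) {
  ids <- sprintf("mu%02d", seq_len(n_vertices))
  i <- sample.int(n_vertices, n_edges, replace = TRUE)
  j <- sample.int(n_vertices, n_edges, replace = TRUE)
  keep <- i != j
  if (!any(keep)) { i <- 1L; j <- 2L; keep <- TRUE }
  data.frame(principle = "conservativity",
             mapping1_id = ids[i[keep]], mapping2_id = ids[j[keep]],
             witness = "", stringsAsFactors = FALSE)
}
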