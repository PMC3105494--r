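#' Detect consistency-principle violations (disjointness heuristic)
#'
#' Two mappings \eqn{\mu = (e, f)} and \eqn{\mu' = (e', f')} between
#' sources `o1` and `o2` conflict when one source entails a subsumption
#' between its endpoints while the other entails their disjointness: the
#' merged theory then makes the subsumed endpoints unsatisfiable.  Both
#' orientations are checked and the reflexive case `e == e'` counts (a
#' single entity mapped to two disjoint classes is incoherent).  The
#' heuristic needs only the two sources classified independently; it is
#' sound but incomplete for incoherence in general.
#'
#' With `use_modules = TRUE`, classification runs on the bottom-locality
#' modules of the mapped entities instead of the whole sources; modules
#' preserve the relevant entailments, so the output is identical.
#'
#' @param o1,o2 [ontology()] objects for the mapping pair, in pair order.
#' @param mappings A [mapping_set()] between them.
#' @param use_modules Classify locality modules of the mapped entities
#'   rather than the full sources.
#' @return A conflict data frame (`principle == "consistency"`) with a
#'   witness describing the entailed subsumption and the told disjoint
#'   pair behind the inferred disjointness; unordered mapping pairs are
#'   deduplicated, rows ordered canonically by id.
#' @export
detect_disjointness_conflicts <- function(o1, o2, mappings, use_modules = FALSE) {
  m <- mappings$mappings
  if (any(m$source1 == m$source2)) {
    stop("mapping set violates the cross-source contract (same-source mapping)")
  }
  if (!nrow(m)) return(conflict_frame())
  if (!setequal(mappings$pair, c(o1$name, o2$name))) {
    stop("ontologies do not match the mapping pair")
  }
  if (o1$name != mappings$pair[1L]) { tmp <- o1; o1 <- o2; o2 <- tmp }
  flip <- m$source1 != o1$name
  e1 <- ifelse(flip, m$entity2, m$entity1)   # endpoint in o1
  e2 <- ifelse(flip, m$entity1, m$entity2)   # endpoint in o2
  ord <- order(m$id)
  m <- m[ord, , drop = FALSE]; e1 <- e1[ord]; e2 <- e2[ord]

  cl1 <- side_closure(o1, e1, use_modules)
  cl2 <- side_closure(o2, e2, use_modules)
  S1 <- subsumption_matrix(cl1, e1)
  S2 <- subsumption_matrix(cl2, e2)
  D1 <- disjointness_matrix(cl1, e1)
  D2 <- disjointness_matrix(cl2, e2)

  conflict <- ((S1 | t(S1)) & D2) | ((S2 | t(S2)) & D1)
  idx <- which(conflict & upper.tri(conflict, diag = FALSE), arr.ind = TRUE)
  if (!nrow(idx)) return(conflict_frame())
  out <- conflict_frame(
    principle = rep("consistency", nrow(idx)),
    mapping1_id = m$id[idx[, 1L]],
    mapping2_id = m$id[idx[, 2L]],
    witness = vapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      consistency_witness(o1, o2, cl1, cl2, e1[i], e2[i], e1[j], e2[j])
    }, "")
  )
  canonical_conflicts(out)
}

side_closure <- function(o, mapped_entities, use_modules) {
  if (use_modules) {
    classify(extract_bottom_module(o, unique(mapped_entities))$ontology)
  } else {
    classify(o)
  }
}

# S[i, j] <- entity i subsumed by entity j (over the mapped entities)
subsumption_matrix <- function(closure, ents) {
  n <- length(ents)
  S <- matrix(FALSE, n, n)
  uniq <- unique(ents)
  pos <- split(seq_len(n), match(ents, uniq))
  for (ui in seq_along(uniq)) {
    anc <- ancestors_of(closure, uniq[ui])
    cols <- which(ents %in% anc | ents == uniq[ui])
    S[pos[[ui]], cols] <- TRUE
  }
  S
}

# D[i, j] <- entities i and j inferred disjoint
disjointness_matrix <- function(closure, ents) {
  n <- length(ents)
  D <- matrix(FALSE, n, n)
  told <- closure$disjoint
  if (!nrow(told)) return(D)
  for (k in seq_len(nrow(told))) {
    under_a <- which(ents %in% descendants_of(closure, told$a[k]))
    under_b <- which(ents %in% descendants_of(closure, told$b[k]))
    if (length(under_a) && length(under_b)) {
      D[under_a, under_b] <- TRUE
      D[under_b, under_a] <- TRUE
    }
  }
  D
}

consistency_witness <- function(o1, o2, cl1, cl2, ei1, ei2, ej1, ej2) {
  dis_pair <- function(closure, a, b) {
    d <- closure$disjoint
    anc_a <- ancestors_of(closure, a); anc_b <- ancestors_of(closure, b)
    hit <- which((d$a %in% anc_a & d$b %in% anc_b) |
                 (d$a %in% anc_b & d$b %in% anc_a))[1L]
    c(d$a[hit], d$b[hit])
  }
  if (entails_subsumption(cl1, ei1, ej1) || entails_subsumption(cl1, ej1, ei1)) {
    if (inferred_disjoint(cl2, ei2, ej2)) {
      sub <- if (entails_subsumption(cl1, ei1, ej1)) c(ei1, ej1) else c(ej1, ei1)
      dp <- dis_pair(cl2, ei2, ej2)
      return(sprintf("%s: %s below %s; %s: %s disjoint %s (told %s|%s)",
                     o1$name, sub[1L], sub[2L], o2$name, ei2, ej2, dp[1L], dp[2L]))
    }
  }
  sub <- if (entails_subsumption(cl2, ei2, ej2)) c(ei2, ej2) else c(ej2, ei2)
  dp <- dis_pair(cl1, ei1, ej1)
  sprintf("%s: %s below %s; %s: %s disjoint %s (told %s|%s)",
          o2$name, sub[1L], sub[2L], o1$name, ei1, ej1, dp[1L], dp[2L])
}
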