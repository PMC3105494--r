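#' Structural classification of an ontology
#'
#' Computes the reflexive-transitive subsumption closure of the told
#' `SubClassOf` edges, with `EquivalentClasses(a b)` contributing both
#' `a` below `b` and `b` below `a` (cycles are legal and encode
#' equivalence).  Complex axioms contribute nothing: the reasoner is sound
#' but incomplete with respect to OWL 2 DL.  Told `DisjointClasses` pairs
#' are carried along for the disjointness queries.
#'
#' @param x An [ontology()].
#' @return An object of class `subsumption_closure` with elements
#'   `classes` (all named entities), `anc` (named list: each class to its
#'   superclasses, reflexive), `disjoint` (data frame of told disjoint
#'   pairs `a`, `b`) and `graph` (the underlying [igraph][igraph::graph]
#'   with edges pointing from subclass to superclass).
#' @export
classify <- function(x) {
  stopifnot(inherits(x, "ontology"))
  classes <- ont_signature(x)
  ax <- x$axioms
  sub <- ax[ax$kind == "subclass_of", c("lhs", "rhs")]
  eq <- ax[ax$kind == "equivalent_classes", c("lhs", "rhs")]
  edges <- rbind(sub, eq, stats::setNames(eq[, c("rhs", "lhs")], c("lhs", "rhs")))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = classes))
  anc <- lapply(stats::setNames(classes, classes), function(cl) {
    igraph::subcomponent(g, cl, mode = "out")$name
  })
  dis <- ax[ax$kind == "disjoint_classes", c("lhs", "rhs")]
  names(dis) <- c("a", "b")
  rownames(dis) <- NULL
  structure(
    list(classes = classes, anc = anc, disjoint = dis, graph = g),
    class = "subsumption_closure"
  )
}

#' @export
print.subsumption_closure <- function(x, ...) {
  cat(sprintf("<subsumption_closure> %d classes, %d told disjoint pairs\n",
              length(x$classes), nrow(x$disjoint)))
  invisible(x)
}

ancestors_of <- function(closure, a) {
  # unknown entities have only the reflexive subsumption
  closure$anc[[a]] %||% a
}

descendants_of <- function(closure, a) {
  if (!a %in% closure$classes) return(a)
  igraph::subcomponent(closure$graph, a, mode = "in")$name
}

#' Entailed subsumption, equivalence and disjointness queries
#'
#' `entails_subsumption(cl, a, b)` is true when `a` is below `b` in the
#' closure; `entails_equivalence` requires mutual subsumption.
#' `inferred_disjoint(cl, a, b)` applies downward inheritance of told
#' disjointness: true when some told disjoint pair `(d1, d2)` has `a`
#' below `d1` and `b` below `d2` (either assignment).  Entities absent
#' from the ontology are treated as fresh satisfiable classes.
#'
#' @param closure A [classify()] result.
#' @param a,b Named classes (local names).
#' @return Logical scalar.
#' @export
entails_subsumption <- function(closure, a, b) {
  if (a == b) return(TRUE)
  b %in% ancestors_of(closure, a)
}

#' @rdname entails_subsumption
#' @export
entails_equivalence <- function(closure, a, b) {
  entails_subsumption(closure, a, b) && entails_subsumption(closure, b, a)
}

#' @rdname entails_subsumption
#' @export
inferred_disjoint <- function(closure, a, b) {
  d <- closure$disjoint
  if (!nrow(d)) return(FALSE)
  anc_a <- ancestors_of(closure, a)
  anc_b <- ancestors_of(closure, b)
  any((d$a %in% anc_a & d$b %in% anc_b) | (d$a %in% anc_b & d$b %in% anc_a))
}

#' Structurally unsatisfiable classes of a merged ontology
#'
#' A named class is reported when the closure places it below both members
#' of some told disjoint pair.  Intended for the union of two sources and
#' a mapping set built by [merge_with_mappings()]; sound but incomplete
#' with respect to full OWL 2 DL reasoning.
#'
#' @param merged An [ontology()] (typically from [merge_with_mappings()]).
#' @return Sorted character vector of unsatisfiable class names (qualified
#'   names when the input came from [merge_with_mappings()]).
#' @export
find_unsatisfiable <- function(merged) {
  cl <- classify(merged)
  d <- cl$disjoint
  if (!nrow(d)) return(character(0))
  unsat <- character(0)
  for (i in seq_len(nrow(d))) {
    both <- intersect(descendants_of(cl, d$a[i]), descendants_of(cl, d$b[i]))
    unsat <- c(unsat, both)
  }
  sort(unique(unsat))
}
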