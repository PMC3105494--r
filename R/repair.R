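#' Build the conflict graph
#'
#' Vertices are the mapping ids appearing in conflicts; each conflict is
#' an undirected edge.  Parallel conflicts (the same unordered pair under
#' several principles or witnesses) collapse to a single edge.
#'
#' @param conflicts A conflict data frame (from the detectors, possibly
#'   row-bound across principles).
#' @return An undirected simple [igraph][igraph::graph] whose vertex
#'   names are mapping ids.
#' @export
build_conflict_graph <- function(conflicts) {
  if (!nrow(conflicts)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  ids <- sort(unique(c(conflicts$mapping1_id, conflicts$mapping2_id)))
  g <- igraph::graph_from_data_frame(
    conflicts[, c("mapping1_id", "mapping2_id")],
    directed = FALSE, vertices = data.frame(name = ids)
  )
  igraph::simplify(g)
}

#' Minimal-total-confidence diagnosis of a conflict graph
#'
#' To disambiguate every conflict, at least one mapping per conflict edge
#' must be removed while the sum of removed confidences is minimised — a
#' minimum-weight vertex cover per connected component.  Components with
#' at most `exact_limit` vertices are solved exactly by branch and bound
#' (ties broken by fewer removals, then lexicographically smallest id
#' set); larger components fall back to a deterministic greedy cover
#' (repeatedly removing the vertex with the highest
#' uncovered-degree-to-confidence ratio) and are flagged inexact.
#'
#' @param graph A conflict graph from [build_conflict_graph()].
#' @param confidences Named numeric vector: confidence per mapping id;
#'   every vertex must have one.
#' @param exact_limit Largest component size solved exactly (default 20).
#' @return An object of class `repair_plan`: `removed`, `kept` (both
#'   sorted id vectors partitioning the conflicted ids),
#'   `total_removed_confidence`, and `components` (data frame with
#'   `id`, `component`, `exact`, `removed`).
#' @export
diagnose <- function(graph, confidences, exact_limit = 20L) {
  ids <- igraph::V(graph)$name
  if (length(ids)) {
    missing <- setdiff(ids, names(confidences))
    if (length(missing)) {
      stop("missing confidence for mapping id(s): ",
           paste(utils::head(missing, 3L), collapse = ", "))
    }
  }
  comp <- if (length(ids)) igraph::components(graph)$membership else integer(0)
  removed <- character(0)
  comp_rows <- list()
  for (k in sort(unique(comp))) {
    verts <- sort(ids[comp == k])
    sub <- igraph::induced_subgraph(graph, verts)
    el <- igraph::as_edgelist(sub)
    w <- confidences[verts]
    if (length(verts) <= exact_limit) {
      sol <- exact_min_cover(el, w)
      exact <- TRUE
    } else {
      sol <- greedy_cover(el, w)
      exact <- FALSE
    }
    removed <- c(removed, sol)
    comp_rows[[length(comp_rows) + 1L]] <- data.frame(
      id = verts, component = k, exact = exact, removed = verts %in% sol,
      stringsAsFactors = FALSE
    )
  }
  components <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(id = character(0), component = integer(0),
               exact = logical(0), removed = logical(0))
  rownames(components) <- NULL
  structure(
    list(
      removed = sort(removed),
      kept = sort(setdiff(ids, removed)),
      total_removed_confidence = sum(unname(confidences[removed])),
      components = components
    ),
    class = "repair_plan"
  )
}

#' @export
print.repair_plan <- function(x, ...) {
  cat(sprintf("<repair_plan> remove %d of %d conflicted mappings (total confidence %.4g)\n",
              length(x$removed), length(x$removed) + length(x$kept),
              x$total_removed_confidence))
  if (any(!x$components$exact)) {
    cat("  note: some components solved greedily (approximate)\n")
  }
  invisible(x)
}

# Branch and bound minimum-weight vertex cover.  `edges` is a 2-column
# character matrix, `weights` a named numeric vector over the component's
# vertices.  Tie-breaks: total weight, then number of removals, then the
# lexicographically smallest sorted id set.
exact_min_cover <- function(edges, weights) {
  if (!nrow(edges)) return(character(0))
  best <- NULL
  better <- function(cand_w, cand) {
    if (is.null(best)) return(TRUE)
    if (cand_w < best$w - 1e-12) return(TRUE)
    if (cand_w > best$w + 1e-12) return(FALSE)
    if (length(cand) != length(best$set)) return(length(cand) < length(best$set))
    paste(sort(cand), collapse = "\r") < paste(sort(best$set), collapse = "\r")
  }
  rec <- function(removed, w) {
    if (!is.null(best) && w > best$w + 1e-12) return()
    uncovered <- !(edges[, 1L] %in% removed | edges[, 2L] %in% removed)
    if (!any(uncovered)) {
      if (better(w, removed)) best <<- list(w = w, set = removed)
      return()
    }
    e <- edges[which(uncovered)[1L], ]
    for (v in sort(e)) {
      rec(c(removed, v), w + weights[[v]])
    }
  }
  rec(character(0), 0)
  best$set
}

greedy_cover <- function(edges, weights) {
  removed <- character(0)
  repeat {
    uncovered <- edges[!(edges[, 1L] %in% removed | edges[, 2L] %in% removed), ,
                       drop = FALSE]
    if (!nrow(uncovered)) return(removed)
    deg <- table(c(uncovered[, 1L], uncovered[, 2L]))
    cand <- sort(names(deg))
    score <- vapply(cand, function(v) {
      d <- as.numeric(deg[[v]])
      if (weights[[v]] <= 0) Inf else d / weights[[v]]
    }, 0)
    removed <- c(removed, cand[which.max(score)])
  }
}

#' Repair a mapping set given its conflicts
#'
#' Scores every conflicted mapping by module-overlap confidence, runs the
#' minimal-total-confidence [diagnose()], and returns the disambiguated
#' mapping set (all unconflicted mappings plus the kept conflicted ones,
#' with their computed confidences filled in).
#'
#' @param o1,o2 Source [ontology()] objects (pair order).
#' @param mappings The full [mapping_set()].
#' @param conflicts Conflict data frame (any mix of principles).
#' @param lexical_threshold Passed to [score_mappings()].
#' @param exact_limit Passed to [diagnose()].
#' @param confidences Optional named numeric vector overriding the
#'   computed confidences (e.g. externally supplied scores).
#' @return A list with `kept_mappings` (a [mapping_set()]), `plan` (the
#'   [diagnose()] result) and `scores` (the confidence table).
#' @export
repair_alignment <- function(o1, o2, mappings, conflicts,
                             lexical_threshold = 0.9, exact_limit = 20L,
                             confidences = NULL) {
  ids <- sort(unique(c(conflicts$mapping1_id, conflicts$mapping2_id)))
  bad <- setdiff(ids, mappings$mappings$id)
  if (length(bad)) {
    stop("conflict report references unknown mapping id(s): ",
         paste(utils::head(bad, 3L), collapse = ", "))
  }
  if (length(ids)) {
    scores <- score_mappings(ids, o1, o2, mappings, lexical_threshold)
    conf <- stats::setNames(scores$combined, scores$mapping_id)
    if (!is.null(confidences)) conf[names(confidences)] <- confidences
  } else {
    scores <- data.frame(mapping_id = character(0), base_ratio = numeric(0),
                         lexical_ratio = numeric(0), combined = numeric(0))
    conf <- numeric(0)
  }
  plan <- diagnose(build_conflict_graph(conflicts), conf, exact_limit)
  m <- mappings$mappings
  keep <- !(m$id %in% plan$removed)
  kept <- m[keep, , drop = FALSE]
  hit <- match(kept$id, names(conf))
  kept$confidence <- ifelse(is.na(hit), kept$confidence, unname(conf[hit]))
  list(
    kept_mappings = mapping_set(mappings$pair, kept),
    plan = plan,
    scores = scores
  )
}
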