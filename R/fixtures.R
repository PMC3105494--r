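#' Specification of a synthetic audit fixture
#'
#' Describes a pair of isomorphic taxonomies plus a CUI-style mapping
#' file with planted errors, emulating the two error modes an alignment
#' audit must catch: ambiguous fan-in mappings (two entities of one
#' source attached to the same CUI, a conservativity violation) and
#' cross-branch mappings that land in a disjoint branch of the partner
#' ontology (a consistency violation).
#'
#' @param n_classes Named classes per source (default 300).
#' @param branching Mean children per internal node (default 3).
#' @param sibling_disjointness_rate Probability that an unordered sibling
#'   pair is declared disjoint (default 0.5).
#' @param true_mapping_fraction Fraction of classes given a shared CUI
#'   with their isomorphic counterpart (default 0.6).
#' @param ambiguity_rate Fraction of mapped classes that receive an extra
#'   same-source member on their CUI (default 0.05).
#' @param violation_rate Fraction of mapped classes whose partner is
#'   re-pointed into a branch disjoint from their parent's image (default
#'   0.05).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_classes = 300L, branching = 3,
                         sibling_disjointness_rate = 0.5,
                         true_mapping_fraction = 0.6,
                         ambiguity_rate = 0.05,
                         violation_rate = 0.05,
                         seed = 1L) {
  rates <- c(sibling_disjointness_rate, true_mapping_fraction,
             ambiguity_rate, violation_rate)
  stopifnot(n_classes >= 1L, branching > 0, all(rates >= 0 & rates <= 1))
  structure(
    list(n_classes = as.integer(n_classes), branching = branching,
         sibling_disjointness_rate = sibling_disjointness_rate,
         true_mapping_fraction = true_mapping_fraction,
         ambiguity_rate = ambiguity_rate, violation_rate = violation_rate,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# sample() without the scalar-x surprise
sample_vec <- function(x, size = length(x)) x[sample.int(length(x), size)]

# run code under a private RNG stream, restoring global state afterwards
with_fixture_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# rooted tree: each later node attaches to an existing node, preferring
# nodes still short of `branching` children
random_tree_parents <- function(n, branching) {
  parent <- rep(NA_integer_, n)
  nchild <- integer(n)
  for (i in seq_len(n)[-1L]) {
    w <- pmax(branching - nchild[seq_len(i - 1L)], 0.1)
    p <- sample.int(i - 1L, 1L, prob = w)
    parent[i] <- p
    nchild[p] <- nchild[p] + 1L
  }
  parent
}

sibling_disjoint_pairs <- function(parent, rate) {
  out <- list()
  for (p in unique(stats::na.omit(parent))) {
    kids <- which(parent == p)
    if (length(kids) < 2L) next
    for (i in seq_len(length(kids) - 1L)) {
      for (j in seq(i + 1L, length(kids))) {
        if (stats::runif(1L) < rate) {
          out[[length(out) + 1L]] <- c(kids[i], kids[j])
        }
      }
    }
  }
  if (!length(out)) matrix(integer(0), ncol = 2L) else do.call(rbind, out)
}

taxonomy_from_structure <- function(parent, dis, source, labels) {
  n <- length(parent)
  ent <- fixture_entity(source, seq_len(n))
  rows <- list()
  for (i in which(!is.na(parent))) {
    rows[[length(rows) + 1L]] <- c("subclass_of", ent[i], ent[parent[i]])
  }
  for (k in seq_len(nrow(dis))) {
    rows[[length(rows) + 1L]] <- c("disjoint_classes", ent[dis[k, 1L]], ent[dis[k, 2L]])
  }
  ax <- if (length(rows)) {
    m <- do.call(rbind, rows)
    axiom_table(m[, 1L], m[, 2L], m[, 3L])
  } else empty_axioms()
  ontology(source, ax, labels = stats::setNames(labels, ent))
}

fixture_entity <- function(source, i) sprintf("%s_%04d", source, i)

fixture_labels <- function(n) sprintf("Concept %04d", seq_len(n))

#' Generate a random taxonomy with sibling disjointness
#'
#' A rooted tree of `SubClassOf` axioms over `n_classes` named classes;
#' each unordered sibling pair is independently declared disjoint with
#' `sibling_disjointness_rate`.  Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param source Source identifier for the generated ontology.
#' @return An [ontology()].
#' @export
generate_taxonomy <- function(spec, source = "ALPHA") {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    parent <- random_tree_parents(spec$n_classes, spec$branching)
    dis <- sibling_disjoint_pairs(parent, spec$sibling_disjointness_rate)
    taxonomy_from_structure(parent, dis, source, fixture_labels(spec$n_classes))
  })
}

#' Generate a mapped ontology pair with planted errors
#'
#' Builds one taxonomy, an isomorphic copy with renamed entities (shared
#' labels), and an MRCONSO-style RRF document assigning a synthetic CUI
#' to a `true_mapping_fraction` sample of counterpart pairs.  Two error
#' modes are then planted: *ambiguity* adds a previously unmapped
#' same-source entity to an existing CUI (a fan-in, detectable by the
#' conservativity check); *violation* re-points a mapped class's partner
#' to an unmapped class lying under a branch declared disjoint from an
#' ancestor of its parent's image (detectable by the disjointness
#' heuristic, since the parent's mapping stays in place).  The document is
#' returned as RRF text so the full extract-and-audit path is exercised.
#'
#' @param spec A [fixture_spec()].
#' @param sources Two source identifiers (default `c("ALPHA", "BETA")`).
#' @return A list: `o1`, `o2` ([ontology()]s), `rrf` (RRF document,
#'   single string), `truth` (lists `correct_mapping_ids`,
#'   `planted_ambiguous_ids`, `planted_violation_ids`), `sources`.
#' @export
generate_mapped_pair <- function(spec, sources = c("ALPHA", "BETA")) {
  stopifnot(inherits(spec, "fixture_spec"), length(sources) == 2L)
  with_fixture_rng(spec$seed, {
    n <- spec$n_classes
    parent <- random_tree_parents(n, spec$branching)
    dis <- sibling_disjoint_pairs(parent, spec$sibling_disjointness_rate)
    labels <- fixture_labels(n)
    o1 <- taxonomy_from_structure(parent, dis, sources[1L], labels)
    o2 <- taxonomy_from_structure(parent, dis, sources[2L], labels)

    anc <- ancestor_chains(parent)
    mapped <- sort(sample.int(n, max(1L, round(spec$true_mapping_fraction * n))))
    unmapped <- setdiff(seq_len(n), mapped)
    cui <- sprintf("C%07d", seq_len(n))

    n_amb <- round(spec$ambiguity_rate * length(mapped))
    n_vio <- round(spec$violation_rate * length(mapped))
    if (n_amb > length(unmapped)) {
      stop("ambiguity_rate needs ", n_amb, " unmapped classes for extra members, ",
           "but only ", length(unmapped), " exist; lower the rates")
    }

    # ambiguity: extra first-source member on an existing CUI
    amb_target <- sample_vec(mapped, n_amb)
    amb_extra <- sample_vec(unmapped, n_amb)
    used <- amb_extra

    # violation: re-point the partner of c into a branch disjoint from an
    # ancestor of its mapped parent's image
    vio_c <- integer(0); vio_d <- integer(0)
    if (n_vio > 0L) {
      eligible <- setdiff(mapped, amb_target)
      eligible <- eligible[!is.na(parent[eligible]) &
                           parent[eligible] %in% setdiff(mapped, amb_target)]
      for (c in sample_vec(eligible)) {
        if (length(vio_c) >= n_vio) break
        # the parent's own mapping must stay in place for the planted
        # conflict to be witnessed, so never re-point a chosen parent
        if (c %in% vio_c || parent[c] %in% vio_c || c %in% parent[vio_c]) next
        p <- parent[c]
        hit <- which(dis[, 1L] %in% anc[[p]] | dis[, 2L] %in% anc[[p]])
        d_found <- NA_integer_
        for (h in hit) {
          s2 <- if (dis[h, 1L] %in% anc[[p]]) dis[h, 2L] else dis[h, 1L]
          cand <- setdiff(intersect(descendant_set(parent, s2), unmapped), used)
          if (length(cand)) { d_found <- sort(cand)[1L]; break }
        }
        if (is.na(d_found)) next
        vio_c <- c(vio_c, c); vio_d <- c(vio_d, d_found)
        used <- c(used, d_found)
      }
      if (length(vio_c) < n_vio) {
        stop("violation_rate asks for ", n_vio, " planted violations but only ",
             length(vio_c), " classes have a mapped parent with a disjoint ",
             "sibling branch containing an unmapped class; lower the rate or ",
             "raise sibling_disjointness_rate")
      }
    }

    rrf <- character(0)
    row <- function(cui, src, idx) {
      rrf_row(cui, src, fixture_entity(src, idx), labels[idx])
    }
    truth_correct <- character(0); truth_amb <- character(0); truth_vio <- character(0)
    for (i in mapped) {
      rrf <- c(rrf, row(cui[i], sources[1L], i))
      if (i %in% vio_c) {
        d <- vio_d[match(i, vio_c)]
        rrf <- c(rrf, row(cui[i], sources[2L], d))
        truth_vio <- c(truth_vio, mapping_id(cui[i], sources[1L],
                                             fixture_entity(sources[1L], i),
                                             sources[2L], fixture_entity(sources[2L], d)))
      } else {
        rrf <- c(rrf, row(cui[i], sources[2L], i))
        truth_correct <- c(truth_correct, mapping_id(cui[i], sources[1L],
                                                     fixture_entity(sources[1L], i),
                                                     sources[2L], fixture_entity(sources[2L], i)))
      }
      if (i %in% amb_target) {
        u <- amb_extra[match(i, amb_target)]
        rrf <- c(rrf, row(cui[i], sources[1L], u))
        truth_amb <- c(truth_amb, mapping_id(cui[i], sources[1L],
                                             fixture_entity(sources[1L], u),
                                             sources[2L], fixture_entity(sources[2L], i)))
      }
    }
    list(
      o1 = o1, o2 = o2,
      rrf = paste0(paste(rrf, collapse = "\n"), "\n"),
      truth = list(correct_mapping_ids = sort(truth_correct),
                   planted_ambiguous_ids = sort(truth_amb),
                   planted_violation_ids = sort(truth_vio)),
      sources = sources
    )
  })
}

ancestor_chains <- function(parent) {
  n <- length(parent)
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    chain <- i; p <- parent[i]
    while (!is.na(p)) { chain <- c(chain, p); p <- parent[p] }
    anc[[i]] <- chain
  }
  anc
}

descendant_set <- function(parent, root) {
  n <- length(parent)
  out <- root
  frontier <- root
  while (length(frontier)) {
    kids <- which(parent %in% frontier)
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# standard 18-column MRCONSO row; only CUI, LAT, SAB, TTY, CODE, STR filled
rrf_row <- function(cui, sab, code, str, lat = "ENG") {
  f <- rep("", 18L)
  f[1L] <- cui; f[2L] <- lat; f[12L] <- sab; f[13L] <- "PT"
  f[14L] <- code; f[15L] <- str
  paste0(paste(f, collapse = "|"), "|")
}

#' Extract the mapping set of a generated fixture
#'
#' Convenience wrapper: parses the fixture's RRF document and generates
#' the equivalence mappings for its source pair, exactly as the pipeline
#' would.
#'
#' @param fix A [generate_mapped_pair()] result.
#' @return A [mapping_set()].
#' @export
fixture_mappings <- function(fix) {
  groups <- parse_mrconso(fix$rrf, sources = fix$sources)
  generate_mappings(groups, fix$sources)
}
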