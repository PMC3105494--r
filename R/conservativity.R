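conflict_frame <- function(principle = character(0), mapping1_id = character(0),
                           mapping2_id = character(0), witness = character(0)) {
  data.frame(principle = principle, mapping1_id = mapping1_id,
             mapping2_id = mapping2_id, witness = witness,
             stringsAsFactors = FALSE)
}

canonical_conflicts <- function(df) {
  if (!nrow(df)) return(df)
  swap <- df$mapping1_id > df$mapping2_id
  tmp <- df$mapping1_id[swap]
  df$mapping1_id[swap] <- df$mapping2_id[swap]
  df$mapping2_id[swap] <- tmp
  df <- df[!duplicated(df[c("principle", "mapping1_id", "mapping2_id")]), , drop = FALSE]
  df <- df[order(df$mapping1_id, df$mapping2_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Detect conservativity-principle violations
#'
#' The mapping theory should not introduce new semantic relationships
#' between entities of a single source.  Because the theory contains only
#' cross-source equivalences, a violation for one source reduces to a
#' fan-in: two distinct entities of that source mapped to the same entity
#' of the other source, without the source alone entailing their
#' equivalence.  Each such non-equivalent pair of mappings is one
#' conflict; the shared opposite-source entity is the witness.
#'
#' @param source The [ontology()] of the side being checked.
#' @param mappings A [mapping_set()] involving `source$name`.
#' @param side Source identifier of the side to check; defaults to
#'   `source$name`.
#' @return A data frame of conflicts with columns `principle`
#'   (`"conservativity"`), `mapping1_id`, `mapping2_id`, `witness`, in
#'   canonical id order.
#' @seealso [conservativity_groups()] for the fan-in group view.
#' @export
detect_conservativity_conflicts <- function(source, mappings, side = source$name) {
  m <- mappings$mappings
  if (any(m$source1 == m$source2)) {
    stop("mapping set violates the cross-source contract (same-source mapping)")
  }
  if (!side %in% mappings$pair) stop("side '", side, "' is not in the mapping pair")
  if (!nrow(m)) return(conflict_frame())
  closure <- classify(source)
  flip <- m$source2 == side
  own <- ifelse(flip, m$entity2, m$entity1)
  opp_src <- ifelse(flip, m$source1, m$source2)
  opp <- ifelse(flip, m$entity1, m$entity2)
  out <- conflict_frame()
  for (key in sort(unique(paste0(opp_src, ":", opp)))) {
    idx <- which(paste0(opp_src, ":", opp) == key)
    ents <- own[idx]
    keep <- !duplicated(ents)
    idx <- idx[keep]; ents <- ents[keep]
    if (length(idx) < 2L) next
    o <- order(m$id[idx])
    idx <- idx[o]; ents <- ents[o]
    for (i in seq_len(length(idx) - 1L)) {
      for (j in seq(i + 1L, length(idx))) {
        if (entails_equivalence(closure, ents[i], ents[j])) next
        out <- rbind(out, conflict_frame(
          "conservativity", m$id[idx[i]], m$id[idx[j]],
          sprintf("shared %s; %s:%s and %s:%s not equivalent in %s",
                  key, side, ents[i], side, ents[j], side)
        ))
      }
    }
  }
  canonical_conflicts(out)
}

#' Fan-in groups behind conservativity conflicts
#'
#' Summarises, per shared opposite-source entity, the group of distinct
#' `side` entities mapped onto it (size `k` yields `choose(k, 2)` pairwise
#' conflicts when none are entailed equivalent).  Exposed because conflict
#' tallies can be counted as mappings involved, as unordered pairs, or as
#' groups.
#'
#' @inheritParams detect_conservativity_conflicts
#' @return Data frame with columns `witness` (shared entity), `size`
#'   (distinct fan-in entities) and `mapping_ids` (semicolon-joined).
#' @export
conservativity_groups <- function(source, mappings, side = source$name) {
  conflicts <- detect_conservativity_conflicts(source, mappings, side)
  if (!nrow(conflicts)) {
    return(data.frame(witness = character(0), size = integer(0),
                      mapping_ids = character(0)))
  }
  wit <- sub(";.*$", "", sub("^shared ", "", conflicts$witness))
  ids_by_wit <- lapply(split(c(conflicts$mapping1_id, conflicts$mapping2_id),
                             c(wit, wit)), function(v) sort(unique(v)))
  data.frame(
    witness = names(ids_by_wit),
    size = vapply(ids_by_wit, length, 0L),
    mapping_ids = vapply(ids_by_wit, paste, "", collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
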