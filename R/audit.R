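#' Audit a mapping set against its two sources
#'
#' Runs the selected detectors: the conservativity check for each side
#' and the disjointness-based consistency heuristic, and returns the
#' combined conflict table together with summary counts.  Conservativity
#' tallies are reported three ways — unordered conflicting pairs, distinct
#' mappings involved, and fan-in groups — because all three conventions
#' are used when quoting conflict counts.
#'
#' @param o1,o2 Source [ontology()] objects.
#' @param mappings A [mapping_set()] between them.
#' @param principles Subset of `c("conservativity", "consistency")`.
#' @param use_modules Passed to [detect_disjointness_conflicts()].
#' @return An object of class `alignment_audit`: `conflicts` (row-bound
#'   conflict data frame) and `summary` (named list of counts).
#' @export
audit_alignment <- function(o1, o2, mappings,
                            principles = c("conservativity", "consistency"),
                            use_modules = FALSE) {
  principles <- match.arg(principles, several.ok = TRUE)
  if (o1$name != mappings$pair[1L]) { tmp <- o1; o1 <- o2; o2 <- tmp }
  conflicts <- conflict_frame()
  summary <- list()
  if ("conservativity" %in% principles) {
    c1 <- detect_conservativity_conflicts(o1, mappings)
    c2 <- detect_conservativity_conflicts(o2, mappings)
    cons <- canonical_conflicts(rbind(c1, c2))
    conflicts <- rbind(conflicts, cons)
    g1 <- conservativity_groups(o1, mappings)
    g2 <- conservativity_groups(o2, mappings)
    summary$conservativity_pairs <- nrow(cons)
    summary$conservativity_mappings <-
      length(unique(c(cons$mapping1_id, cons$mapping2_id)))
    summary$conservativity_groups <- nrow(g1) + nrow(g2)
  }
  if ("consistency" %in% principles) {
    inc <- detect_disjointness_conflicts(o1, o2, mappings, use_modules)
    conflicts <- rbind(conflicts, inc)
    summary$consistency_pairs <- nrow(inc)
    summary$consistency_mappings <-
      length(unique(c(inc$mapping1_id, inc$mapping2_id)))
  }
  summary$conflicted_mappings <-
    length(unique(c(conflicts$mapping1_id, conflicts$mapping2_id)))
  summary$total_mappings <- nrow(mappings$mappings)
  rownames(conflicts) <- NULL
  structure(list(conflicts = conflicts, summary = summary),
            class = "alignment_audit")
}

#' @export
print.alignment_audit <- function(x, ...) {
  cat("<alignment_audit>\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %s: %d\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}

#' Write a conflict report as TSV
#'
#' Columns `principle`, `mapping1_id`, `mapping2_id`, `witness`;
#' deterministic row order (principle, then ids).
#'
#' @param conflicts Conflict data frame.
#' @return The document as a single string.
#' @export
write_conflicts <- function(conflicts) {
  o <- order(conflicts$principle, conflicts$mapping1_id, conflicts$mapping2_id)
  conflicts <- conflicts[o, , drop = FALSE]
  lines <- c("principle\tmapping1_id\tmapping2_id\twitness",
             if (nrow(conflicts))
               paste(conflicts$principle, conflicts$mapping1_id,
                     conflicts$mapping2_id, conflicts$witness, sep = "\t"))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname write_conflicts
#' @param text Conflict TSV document.
#' @export
read_conflicts <- function(text) {
  lines <- split_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (!identical(lines[1L], "principle\tmapping1_id\tmapping2_id\twitness")) {
    stop("malformed conflict TSV header")
  }
  if (length(lines) == 1L) return(conflict_frame())
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  conflict_frame(
    principle = vapply(parts, `[[`, "", 1L),
    mapping1_id = vapply(parts, `[[`, "", 2L),
    mapping2_id = vapply(parts, `[[`, "", 3L),
    witness = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "", "")
  )
}
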