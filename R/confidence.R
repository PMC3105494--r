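#' Token-set lexical similarity between two labels
#'
#' Labels are lowercased, punctuation is stripped, and they are split on
#' whitespace and underscores; the score is the Jaccard index of the two
#' token sets.  Symmetric; `1` for equal normalised token sets; `0` when
#' both labels are empty after normalisation.
#'
#' @param label1,label2 Character scalars.
#' @return A number in `[0, 1]`.
#' @export
lexical_similarity <- function(label1, label2) {
  t1 <- label_tokens(label1)
  t2 <- label_tokens(label2)
  if (!length(t1) && !length(t2)) return(0)
  length(intersect(t1, t2)) / length(union(t1, t2))
}

label_tokens <- function(label) {
  s <- tolower(label)
  s <- gsub("[_[:space:]]+", " ", s)
  s <- gsub("[^a-z0-9 ]", "", s)
  toks <- strsplit(trimws(s), " ", fixed = TRUE)[[1L]]
  unique(toks[nzchar(toks)])
}

#' Module-overlap confidence of a mapping (locality principle)
#'
#' A correct mapping should carry its neighbourhood with it: the entities
#' semantically related to one endpoint should map onto those related to
#' the other.  The neighbourhoods are the bottom-locality module
#' signatures of the two endpoints, each excluding the endpoint itself.
#' The base ratio is the pooled fraction of module entities that the
#' mapping set links into the opposite module; the lexical ratio
#' additionally links module entities whose labels reach
#' `lexical_threshold` under [lexical_similarity()], compensating for
#' sparse mapping coverage.  The combined score is the lexical ratio.
#'
#' @param mapping_id Id of the mapping to score (must be in
#'   `all_mappings`).
#' @param o1,o2 The two source [ontology()] objects (pair order).
#' @param all_mappings The full [mapping_set()] used to count links.
#' @param lexical_threshold Minimum lexical similarity for an augmented
#'   link (default `0.9`).
#' @return A one-row data frame: `mapping_id`, `base_ratio`,
#'   `lexical_ratio`, `combined`.
#' @export
compute_confidence <- function(mapping_id, o1, o2, all_mappings,
                               lexical_threshold = 0.9) {
  score_mappings(mapping_id, o1, o2, all_mappings, lexical_threshold)
}

#' @rdname compute_confidence
#' @param mapping_ids Ids to score (default: all mappings in the set).
#' @return `score_mappings` returns one row per id, in input order.
#' @export
score_mappings <- function(mapping_ids, o1, o2, all_mappings,
                           lexical_threshold = 0.9) {
  m <- all_mappings$mappings
  missing <- setdiff(mapping_ids, m$id)
  if (length(missing)) {
    stop("mapping id(s) not in the mapping set: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  if (o1$name != all_mappings$pair[1L]) { tmp <- o1; o1 <- o2; o2 <- tmp }
  flip <- m$source1 != o1$name
  e1 <- ifelse(flip, m$entity2, m$entity1)
  e2 <- ifelse(flip, m$entity1, m$entity2)
  partners12 <- split(e2, e1)   # o1 entity -> mapped o2 entities
  partners21 <- split(e1, e2)
  mod_cache1 <- new.env(parent = emptyenv())
  mod_cache2 <- new.env(parent = emptyenv())
  module_sig <- function(o, ent, cache) {
    if (is.null(cache[[ent]])) {
      cache[[ent]] <- setdiff(extract_bottom_module(o, ent)$signature, ent)
    }
    cache[[ent]]
  }
  rows <- lapply(mapping_ids, function(id) {
    i <- match(id, m$id)
    M1 <- module_sig(o1, e1[i], mod_cache1)
    M2 <- module_sig(o2, e2[i], mod_cache2)
    if (!length(M1) && !length(M2)) {
      return(data.frame(mapping_id = id, base_ratio = 0, lexical_ratio = 0,
                        combined = 0, stringsAsFactors = FALSE))
    }
    mapped1 <- vapply(M1, function(x) any(partners12[[x]] %in% M2), TRUE)
    mapped2 <- vapply(M2, function(y) any(partners21[[y]] %in% M1), TRUE)
    base <- (sum(mapped1) + sum(mapped2)) / (length(M1) + length(M2))
    lab1 <- ont_label(o1, M1); lab2 <- ont_label(o2, M2)
    lex1 <- mapped1; lex2 <- mapped2
    for (a in which(!lex1)) {
      lex1[a] <- any(vapply(lab2, function(l) {
        lexical_similarity(lab1[a], l) >= lexical_threshold
      }, TRUE))
    }
    for (b in which(!lex2)) {
      lex2[b] <- any(vapply(lab1, function(l) {
        lexical_similarity(lab2[b], l) >= lexical_threshold
      }, TRUE))
    }
    lexr <- (sum(lex1) + sum(lex2)) / (length(M1) + length(M2))
    data.frame(mapping_id = id, base_ratio = base, lexical_ratio = lexr,
               combined = lexr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
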