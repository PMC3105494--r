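#' Column layout of an MRCONSO-style RRF file
#'
#' The UMLS Rich Release Format is pipe-delimited with 18 columns; only
#' five matter here.  Synthetic fixtures may use a narrower layout, so the
#' positions are configurable.
#'
#' @param cui,lat,sab,code,str 1-based column positions of the concept
#'   unique identifier, language, source abbreviation, source-local code
#'   and entity string.  Defaults are the standard MRCONSO positions.
#' @return A named integer vector used by [parse_mrconso()].
#' @export
rrf_layout <- function(cui = 1L, lat = 2L, sab = 12L, code = 14L, str = 15L) {
  c(cui = cui, lat = lat, sab = sab, code = code, str = str)
}

#' Parse an MRCONSO-style RRF document into CUI groups
#'
#' Rows are filtered to the requested source vocabularies and language,
#' and grouped by CUI.  The entity identity policy decides the local name
#' of each member: `"code"` uses the source-local code when non-empty and
#' otherwise falls back to the normalised string (trimmed, internal
#' whitespace collapsed to underscores); `"label"` always normalises the
#' string.  Duplicate members within a CUI and source collapse to one.
#'
#' @param text RRF document: single string or character vector of lines.
#'   A trailing pipe per row is tolerated; rows with fewer columns than
#'   the layout requires are skipped and reported.
#' @param sources Character vector of source abbreviations (SAB) to keep.
#' @param language Language code to keep (default `"ENG"`).
#' @param layout Column positions, see [rrf_layout()].
#' @param identity `"code"` (default) or `"label"`.
#' @return A data frame of class `cui_groups` with columns `cui`,
#'   `source`, `entity`, `label`, one row per distinct member, ordered by
#'   `cui`, `source`, `entity`.  Skipped-row messages are attached as
#'   attribute `"errors"`.
#' @export
parse_mrconso <- function(text, sources, language = "ENG",
                          layout = rrf_layout(), identity = c("code", "label")) {
  identity <- match.arg(identity)
  lines <- split_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  need <- max(layout)
  errors <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "|", fixed = TRUE)[[1L]]
    if (length(f) < need) {
      errors <- c(errors, sprintf("row %d: %d columns, need %d", i, length(f), need))
      next
    }
    rows[[i]] <- f[layout]
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows)) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- names(rrf_layout())
    df <- df[df$sab %in% sources & df$lat == language, , drop = FALSE]
  } else {
    df <- data.frame(cui = character(0), lat = character(0), sab = character(0),
                     code = character(0), str = character(0))
  }
  if (!nrow(df)) {
    warning("no MRCONSO rows survive the source/language filter")
    out <- data.frame(cui = character(0), source = character(0),
                      entity = character(0), label = character(0))
  } else {
    entity <- if (identity == "code") {
      ifelse(nzchar(df$code), df$code, normalise_local(df$str))
    } else {
      normalise_local(df$str)
    }
    out <- data.frame(cui = df$cui, source = df$sab, entity = entity,
                      label = trimws(df$str), stringsAsFactors = FALSE)
    out <- out[!duplicated(out[c("cui", "source", "entity")]), , drop = FALSE]
    out <- out[order(out$cui, out$source, out$entity), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "errors") <- errors
  class(out) <- c("cui_groups", class(out))
  out
}

normalise_local <- function(s) {
  gsub("[[:space:]]+", "_", trimws(s))
}

#' A set of cross-source equivalence mappings
#'
#' The mapping theory between a pair of sources: one row per mapping with
#' a deterministic id, the CUI(s) it came from, the two endpoints, the
#' relation and an optional confidence in `[0, 1]`.
#'
#' @param pair Character vector of the two source identifiers, in order.
#' @param mappings Data frame with columns `id`, `cui`, `source1`,
#'   `entity1`, `source2`, `entity2`, `relation`, `confidence`.
#' @return An object of class `mapping_set`.
#' @export
mapping_set <- function(pair, mappings = empty_mappings()) {
  stopifnot(length(pair) == 2L, pair[1L] != pair[2L])
  m <- mappings
  req <- c("id", "cui", "source1", "entity1", "source2", "entity2",
           "relation", "confidence")
  stopifnot(all(req %in% names(m)))
  if (anyDuplicated(m$id)) stop("mapping ids must be unique")
  if (any(m$source1 == m$source2)) {
    stop("a mapping may not join two entities of the same source")
  }
  ok_pair <- (m$source1 == pair[1L] & m$source2 == pair[2L]) |
             (m$source1 == pair[2L] & m$source2 == pair[1L])
  if (!all(ok_pair)) stop("every mapping must join the declared source pair")
  conf <- m$confidence[!is.na(m$confidence)]
  if (any(conf < 0 | conf > 1)) stop("confidence values must lie in [0, 1]")
  rownames(m) <- NULL
  structure(list(pair = pair, mappings = m), class = "mapping_set")
}

empty_mappings <- function() {
  data.frame(id = character(0), cui = character(0),
             source1 = character(0), entity1 = character(0),
             source2 = character(0), entity2 = character(0),
             relation = character(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.mapping_set <- function(x, ...) {
  cat(sprintf("<mapping_set> %s ~ %s: %d mappings\n",
              x$pair[1L], x$pair[2L], nrow(x$mappings)))
  invisible(x)
}

mapping_id <- function(cui, source1, entity1, source2, entity2) {
  sprintf("%s|%s:%s|%s:%s", cui, source1, entity1, source2, entity2)
}

#' Generate the equivalence mapping theory for a source pair
#'
#' For every CUI, each entity of the first source is declared equivalent
#' to each entity of the second (the full cross-product); entities of the
#' same source are never mapped to each other, since the CUI file is read
#' as a mapping theory, not as domain content.  An entity pair reachable
#' through several CUIs yields a single mapping annotated with all of
#' them (semicolon-separated, the id taken from the first CUI in sort
#' order).
#'
#' @param groups A [parse_mrconso()] result (or any data frame with
#'   columns `cui`, `source`, `entity`, `label`).
#' @param pair Character vector of two source identifiers.
#' @return A [mapping_set()]; mapping ids are `cui|src1:ent1|src2:ent2`.
#' @export
generate_mappings <- function(groups, pair) {
  stopifnot(length(pair) == 2L)
  g <- as.data.frame(groups)
  g <- g[g$source %in% pair, , drop = FALSE]
  out <- list()
  for (cui in sort(unique(g$cui))) {
    a <- g[g$cui == cui & g$source == pair[1L], , drop = FALSE]
    b <- g[g$cui == cui & g$source == pair[2L], , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    grid <- expand.grid(i = order(a$entity), j = order(b$entity))
    out[[length(out) + 1L]] <- data.frame(
      cui = cui,
      source1 = pair[1L], entity1 = a$entity[grid$i],
      source2 = pair[2L], entity2 = b$entity[grid$j],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(mapping_set(pair))
  m <- do.call(rbind, out)
  # merge duplicates by endpoint pair, keeping all CUI annotations
  key <- paste(m$entity1, m$entity2, sep = "\r")
  cuis <- vapply(split(m$cui, key), function(cs) {
    paste(sort(unique(cs)), collapse = ";")
  }, "")
  m <- m[!duplicated(key), , drop = FALSE]
  m$cui <- unname(cuis[paste(m$entity1, m$entity2, sep = "\r")])
  first_cui <- vapply(strsplit(m$cui, ";", fixed = TRUE), `[[`, "", 1L)
  m$id <- mapping_id(first_cui, m$source1, m$entity1, m$source2, m$entity2)
  m$relation <- "equivalence"
  m$confidence <- NA_real_
  m <- m[order(m$id), c("id", "cui", "source1", "entity1", "source2",
                        "entity2", "relation", "confidence")]
  mapping_set(pair, m)
}

# ---- mapping i/o ------------------------------------------------------------

MAPPING_TSV_HEADER <- c("id", "cui", "source1", "entity1", "source2",
                        "entity2", "relation", "confidence")

#' Read and write mapping sets
#'
#' Two dialects: a TSV with columns `id`, `cui`, `source1`, `entity1`,
#' `source2`, `entity2`, `relation`, `confidence`, and an OWL 2
#' functional-style document of `EquivalentClasses` (or `SubClassOf` /
#' `DisjointClasses`) axioms carrying the id, CUI and confidence as axiom
#' annotations.  `read_mappings` autodetects the dialect;
#' `read_mappings(write_mappings(m))` is the identity.
#'
#' @param x A [mapping_set()].
#' @param dialect `"tsv"` or `"owl"`.
#' @return `write_mappings` returns the document as one string;
#'   `read_mappings` returns a [mapping_set()].
#' @export
write_mappings <- function(x, dialect = c("tsv", "owl")) {
  dialect <- match.arg(dialect)
  m <- x$mappings
  if (dialect == "tsv") {
    lines <- paste(MAPPING_TSV_HEADER, collapse = "\t")
    if (nrow(m)) {
      conf <- ifelse(is.na(m$confidence), "", format(m$confidence, digits = 15L))
      lines <- c(lines, paste(m$id, m$cui, m$source1, m$entity1, m$source2,
                              m$entity2, m$relation, conf, sep = "\t"))
    }
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  p1 <- tolower(x$pair[1L]); p2 <- tolower(x$pair[2L])
  lines <- c(
    "Prefix(ma:=<http://example.org/mapping-annotation#>)",
    sprintf("Prefix(%s:=<%s>)", p1, default_namespace(x$pair[1L])),
    sprintf("Prefix(%s:=<%s>)", p2, default_namespace(x$pair[2L])),
    sprintf("Ontology(<http://example.org/mappings/%s-%s>", x$pair[1L], x$pair[2L])
  )
  op <- c(equivalence = "EquivalentClasses", subsumption = "SubClassOf",
          disjointness = "DisjointClasses")
  for (i in seq_len(nrow(m))) {
    ann <- c(
      sprintf('Annotation(ma:id "%s")', m$id[i]),
      if (nzchar(m$cui[i]) && !is.na(m$cui[i]))
        sprintf('Annotation(ma:cui "%s")', m$cui[i]),
      if (!is.na(m$confidence[i]))
        sprintf('Annotation(ma:confidence "%s")',
                format(m$confidence[i], digits = 15L))
    )
    pe1 <- paste0(tolower(m$source1[i]), ":", m$entity1[i])
    pe2 <- paste0(tolower(m$source2[i]), ":", m$entity2[i])
    lines <- c(lines, sprintf("%s(%s %s %s)", op[[m$relation[i]]],
                              paste(ann, collapse = " "), pe1, pe2))
  }
  paste0(paste(c(lines, ")"), collapse = "\n"), "\n")
}

#' @rdname write_mappings
#' @param text Mapping document (string or lines).
#' @param pair Source pair; required for the TSV dialect only when the
#'   document has no rows, and for the OWL dialect inferred from the
#'   prefix declarations when omitted.
#' @export
read_mappings <- function(text, pair = NULL) {
  lines <- split_lines(text)
  probe <- lines[nzchar(trimws(lines))]
  if (length(probe) && startsWith(probe[1L], "id\t")) {
    return(read_mappings_tsv(lines, pair))
  }
  read_mappings_owl(lines, pair)
}

read_mappings_tsv <- function(lines, pair) {
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, MAPPING_TSV_HEADER)) {
    stop("mapping TSV header must be: ", paste(MAPPING_TSV_HEADER, collapse = ", "))
  }
  if (length(lines) == 1L) {
    if (is.null(pair)) stop("empty mapping TSV needs an explicit source pair")
    return(mapping_set(pair))
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else "", "")
  m <- data.frame(
    id = get(1L), cui = get(2L), source1 = get(3L), entity1 = get(4L),
    source2 = get(5L), entity2 = get(6L), relation = get(7L),
    confidence = suppressWarnings(as.numeric(get(8L))),
    stringsAsFactors = FALSE
  )
  if (is.null(pair)) pair <- c(m$source1[1L], m$source2[1L])
  mapping_set(pair, m)
}

read_mappings_owl <- function(lines, pair) {
  prefixes <- character(0)
  rows <- list()
  op <- c(EquivalentClasses = "equivalence", SubClassOf = "subsumption",
          DisjointClasses = "disjointness")
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || grepl("^(#|//|Ontology\\()", line) || line == ")") next
    if (grepl("^Prefix\\(", line)) {
      m <- regmatches(line, regexec("^Prefix\\(\\s*([A-Za-z][A-Za-z0-9_.-]*):=<([^>]*)>\\s*\\)$", line))[[1L]]
      if (length(m) != 3L) stop(sprintf("line %d: malformed Prefix declaration", ln))
      prefixes[m[2L]] <- source_from_iri(m[3L])
      next
    }
    mm <- regmatches(line, regexec("^(EquivalentClasses|SubClassOf|DisjointClasses)\\((.*)\\)$", line))[[1L]]
    if (length(mm) != 3L) stop(sprintf("line %d: malformed mapping axiom", ln))
    body <- mm[3L]
    anns <- regmatches(body, gregexpr('Annotation\\(\\s*ma:([A-Za-z]+)\\s+"([^"]*)"\\s*\\)', body))[[1L]]
    ann <- character(0)
    for (a in anns) {
      p <- regmatches(a, regexec('Annotation\\(\\s*ma:([A-Za-z]+)\\s+"([^"]*)"\\s*\\)', a))[[1L]]
      ann[p[2L]] <- p[3L]
    }
    toks <- strsplit(trimws(strip_annotations(body)), "\\s+")[[1L]]
    if (length(toks) != 2L || !all(grepl(paste0("^", PN_RE, "$"), toks))) {
      stop(sprintf("line %d: mapping axiom must join two named classes", ln))
    }
    pfx <- sub(":.*$", "", toks)
    src <- unname(prefixes[pfx])
    if (anyNA(src)) stop(sprintf("line %d: undeclared prefix", ln))
    rows[[length(rows) + 1L]] <- data.frame(
      id = ann["id"] %|NA|% "", cui = ann["cui"] %|NA|% "",
      source1 = src[1L], entity1 = sub("^[^:]*:", "", toks[1L]),
      source2 = src[2L], entity2 = sub("^[^:]*:", "", toks[2L]),
      relation = op[[mm[2L]]],
      confidence = suppressWarnings(as.numeric(ann["confidence"] %|NA|% NA_character_)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    if (is.null(pair)) {
      srcs <- setdiff(unname(prefixes), "mapping-annotation")
      if (length(srcs) != 2L) stop("cannot infer source pair from an empty mapping document")
      pair <- srcs
    }
    return(mapping_set(pair))
  }
  m <- do.call(rbind, rows)
  if (is.null(pair)) pair <- c(m$source1[1L], m$source2[1L])
  mapping_set(pair, m)
}

`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a
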