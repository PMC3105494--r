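#' Restricted ontology representation
#'
#' An `ontology` holds the axioms of a single source vocabulary (FMA, NCI,
#' SNOMED CT, ...) in a restricted axiom language: `SubClassOf`,
#' `EquivalentClasses` and `DisjointClasses` over named classes, plus opaque
#' `complex` axioms whose class expressions are not interpreted but whose
#' signature is retained (for module extraction).  Class identifiers are the
#' local names within the source; the source itself gives the namespace.
#'
#' @param name Source vocabulary identifier, e.g. `"FMA"`.
#' @param axioms A data frame with columns `kind` (one of `"subclass_of"`,
#'   `"equivalent_classes"`, `"disjoint_classes"`, `"complex"`), `lhs`, `rhs`
#'   (named classes; `rhs` is `NA` for complex axioms with no named
#'   superclass position), `sig` (list column: the full signature of the
#'   axiom, a character vector) and `raw` (verbatim text of complex axioms,
#'   `NA` otherwise).
#' @param labels Named character vector mapping local names to
#'   human-readable labels.  Missing labels default to the local name with
#'   underscores read as spaces.
#' @param namespace IRI namespace used when serialising to functional
#'   syntax; defaults to an `example.org` namespace embedding `name`.
#' @return An object of class `ontology`.
#' @export
ontology <- function(name, axioms = empty_axioms(), labels = character(0),
                     namespace = default_namespace(name)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  axioms <- validate_axioms(axioms)
  structure(
    list(name = name, namespace = namespace, axioms = axioms,
         labels = labels),
    class = "ontology"
  )
}

default_namespace <- function(name) {
  paste0("http://example.org/", name, "#")
}

empty_axioms <- function() {
  ax <- data.frame(kind = character(0), lhs = character(0), rhs = character(0),
                   stringsAsFactors = FALSE)
  ax$sig <- list()
  ax$raw <- character(0)
  ax
}

NAMED_KINDS <- c("subclass_of", "equivalent_classes", "disjoint_classes")

validate_axioms <- function(ax) {
  if (nrow(ax) == 0L) return(empty_axioms())
  stopifnot(all(c("kind", "lhs") %in% names(ax)))
  if (is.null(ax$rhs)) ax$rhs <- NA_character_
  if (is.null(ax$raw)) ax$raw <- NA_character_
  if (is.null(ax$sig)) {
    ax$sig <- lapply(seq_len(nrow(ax)), function(i) {
      unique(stats::na.omit(c(ax$lhs[i], ax$rhs[i])))
    })
  }
  bad <- !ax$kind %in% c(NAMED_KINDS, "complex")
  if (any(bad)) stop("unknown axiom kind: ", paste(unique(ax$kind[bad]), collapse = ", "))
  named <- ax$kind %in% NAMED_KINDS
  if (any(named & (is.na(ax$lhs) | is.na(ax$rhs)))) {
    stop("subclass_of/equivalent_classes/disjoint_classes axioms need named lhs and rhs")
  }
  ax <- ax[c("kind", "lhs", "rhs", "sig", "raw")]
  rownames(ax) <- NULL
  ax
}

#' Build an axiom table from kind/lhs/rhs vectors
#'
#' Convenience constructor used throughout the tests and the fixture
#' generator.  `DisjointClasses` axioms are pairwise: supply one row per
#' unordered pair.
#'
#' @param kind,lhs,rhs Character vectors of equal length.
#' @return An axiom data frame suitable for [ontology()].
#' @export
axiom_table <- function(kind, lhs, rhs) {
  validate_axioms(data.frame(kind = kind, lhs = lhs, rhs = rhs,
                             stringsAsFactors = FALSE))
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %s: %d axioms, %d named entities\n",
              x$name, nrow(x$axioms), length(ont_signature(x))))
  invisible(x)
}

#' Signature of an ontology
#'
#' All entity (and, for complex axioms, property) names occurring in the
#' ontology's axioms.
#'
#' @param x An [ontology()].
#' @return Character vector, sorted.
#' @export
ont_signature <- function(x) {
  stopifnot(inherits(x, "ontology"))
  sort(unique(c(unlist(x$axioms$sig, use.names = FALSE),
                stats::na.omit(c(x$axioms$lhs, x$axioms$rhs)))))
}

#' Human-readable label of an entity
#'
#' Falls back to the local name with underscores replaced by spaces when no
#' label was recorded.
#'
#' @param x An [ontology()].
#' @param entities Character vector of local names.
#' @return Character vector of labels.
#' @export
ont_label <- function(x, entities) {
  out <- unname(x$labels[entities])
  miss <- is.na(out)
  out[miss] <- gsub("_", " ", entities[miss], fixed = TRUE)
  out
}

# ---- native TSV dialect -----------------------------------------------------

#' Read and write ontologies
#'
#' Two dialects are supported: a native TSV format (columns `kind`, `lhs`,
#' `rhs`, `extra_signature`; header required) and a subset of the OWL 2
#' functional-style syntax (`Prefix`, `SubClassOf`, `EquivalentClasses`,
#' `DisjointClasses`; unsupported class expressions are retained as opaque
#' complex axioms with their signature).  `parse_ontology` autodetects the
#' dialect from the first non-empty line.
#'
#' @param text Character scalar (whole document) or character vector of
#'   lines.
#' @param name Source vocabulary identifier for the resulting ontology.
#'   For the functional dialect it defaults to the source encoded in the
#'   `Ontology(<iri>)` header when present.
#' @param dialect `"tsv"` or `"functional"`.
#' @return `parse_ontology` returns an [ontology()]; `write_ontology`
#'   returns the document as a single string.
#' @export
parse_ontology <- function(text, name = NULL, dialect = NULL) {
  lines <- split_lines(text)
  probe <- lines[nzchar(trimws(lines))]
  if (is.null(dialect)) {
    dialect <- if (length(probe) && grepl("^(kind\t|#)", probe[1])) "tsv"
               else "functional"
  }
  switch(dialect,
    tsv = parse_ontology_tsv(lines, name),
    functional = parse_ontology_functional(lines, name),
    stop("unknown ontology dialect: ", dialect)
  )
}

split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text
}

parse_ontology_tsv <- function(lines, name) {
  lines <- lines[nzchar(trimws(lines))]
  named_hdr <- grep("^# ontology: ", lines, value = TRUE)
  if (is.null(name) && length(named_hdr)) {
    name <- sub("^# ontology: ", "", named_hdr[1L])
  }
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) {
    return(ontology(name %||% "ONTOLOGY"))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[1:2], c("kind", "lhs"))) {
    stop("native ontology TSV requires a 'kind\tlhs\trhs\textra_signature' header")
  }
  body <- lines[-1L]
  body <- body[!grepl("^#", body)]
  if (!length(body)) return(ontology(name %||% "ONTOLOGY"))
  parts <- strsplit(body, "\t", fixed = TRUE)
  n <- length(parts)
  kind <- lhs <- rhs <- character(n)
  sig <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < 2L) {
      stop(sprintf("line %d: expected at least kind and lhs columns", i + 1L))
    }
    kind[i] <- p[1L]
    lhs[i] <- p[2L]
    rhs[i] <- if (length(p) >= 3L && nzchar(p[3L])) p[3L] else NA_character_
    extra <- if (length(p) >= 4L && nzchar(p[4L])) {
      trimws(strsplit(p[4L], ",", fixed = TRUE)[[1L]])
    } else character(0)
    sig[[i]] <- unique(c(stats::na.omit(c(p[2L], rhs[i])), extra))
  }
  ax <- data.frame(kind = kind, lhs = lhs, rhs = rhs, stringsAsFactors = FALSE)
  ax$sig <- sig
  ax$raw <- NA_character_
  ontology(name %||% "ONTOLOGY", validate_axioms(ax))
}

# ---- functional-style dialect ----------------------------------------------

# A prefixed name: prefix:Local_Name.  Local names may contain letters,
# digits, underscores, hyphens and dots.
PN_RE <- "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.-]*"

parse_ontology_functional <- function(lines, name) {
  prefixes <- character(0)   # prefix -> iri
  onto_name <- NULL
  ax_rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || grepl("^(#|//)", line)) next
    if (grepl("^Prefix\\(", line)) {
      m <- regmatches(line, regexec("^Prefix\\(\\s*([A-Za-z][A-Za-z0-9_.-]*):=<([^>]*)>\\s*\\)$", line))[[1L]]
      if (length(m) != 3L) stop(sprintf("line %d: malformed Prefix declaration", ln))
      prefixes[m[2L]] <- m[3L]
      next
    }
    if (grepl("^Ontology\\(", line)) {
      m <- regmatches(line, regexec("^Ontology\\(\\s*<([^>]*)>\\s*$", line))[[1L]]
      if (length(m) == 2L) onto_name <- source_from_iri(m[2L])
      next
    }
    if (line == ")") next
    m <- regmatches(line, regexec("^(SubClassOf|EquivalentClasses|DisjointClasses)\\((.*)\\)$", line))[[1L]]
    if (length(m) != 3L) stop(sprintf("line %d: malformed axiom: %s", ln, line))
    op <- m[2L]; body <- m[3L]
    if (!balanced_parens(body)) stop(sprintf("line %d: unbalanced parentheses", ln))
    body_noann <- strip_annotations(body)
    toks <- trimws(strsplit(body_noann, "\\s+")[[1L]])
    toks <- toks[nzchar(toks)]
    simple <- length(toks) >= 2L && all(grepl(paste0("^", PN_RE, "$"), toks))
    if (simple) {
      locals <- sub("^[^:]*:", "", toks)
      if (op == "SubClassOf") {
        if (length(toks) != 2L) stop(sprintf("line %d: SubClassOf takes two classes", ln))
        ax_rows[[length(ax_rows) + 1L]] <-
          list(kind = "subclass_of", lhs = locals[1L], rhs = locals[2L],
               sig = locals, raw = NA_character_)
      } else if (op == "EquivalentClasses") {
        if (length(toks) != 2L) stop(sprintf("line %d: EquivalentClasses takes two named classes in this dialect", ln))
        ax_rows[[length(ax_rows) + 1L]] <-
          list(kind = "equivalent_classes", lhs = locals[1L], rhs = locals[2L],
               sig = locals, raw = NA_character_)
      } else {
        # n-ary DisjointClasses expands to all unordered pairs
        if (length(toks) < 2L) stop(sprintf("line %d: DisjointClasses needs >= 2 classes", ln))
        for (i in seq_len(length(locals) - 1L)) {
          for (j in seq(i + 1L, length(locals))) {
            ax_rows[[length(ax_rows) + 1L]] <-
              list(kind = "disjoint_classes", lhs = locals[i], rhs = locals[j],
                   sig = c(locals[i], locals[j]), raw = NA_character_)
          }
        }
      }
    } else {
      # opaque complex axiom: keep verbatim, collect the full signature
      names_in <- regmatches(body_noann, gregexpr(PN_RE, body_noann))[[1L]]
      if (!length(names_in)) stop(sprintf("line %d: axiom mentions no named entities", ln))
      locals <- sub("^[^:]*:", "", names_in)
      first_tok <- toks[1L]
      lhs <- if (grepl(paste0("^", PN_RE, "$"), first_tok %||% "")) {
        sub("^[^:]*:", "", first_tok)
      } else NA_character_
      ax_rows[[length(ax_rows) + 1L]] <-
        list(kind = "complex", lhs = lhs, rhs = NA_character_,
             sig = unique(locals), raw = line)
    }
  }
  if (is.null(name)) name <- onto_name %||% "ONTOLOGY"
  if (!length(ax_rows)) return(ontology(name))
  ax <- data.frame(
    kind = vapply(ax_rows, `[[`, "", "kind"),
    lhs  = vapply(ax_rows, `[[`, "", "lhs"),
    rhs  = vapply(ax_rows, `[[`, "", "rhs"),
    stringsAsFactors = FALSE
  )
  ax$sig <- lapply(ax_rows, `[[`, "sig")
  ax$raw <- vapply(ax_rows, `[[`, "", "raw")
  ontology(name, validate_axioms(ax))
}

balanced_parens <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  all(depth >= 0L) && depth[length(depth)] == 0L
}

strip_annotations <- function(body) {
  # removes leading Annotation(...) groups (balanced) from an axiom body
  repeat {
    body <- trimws(body)
    if (!grepl("^Annotation\\(", body)) return(body)
    chars <- strsplit(body, "")[[1L]]
    depth <- 0L; end <- NA_integer_
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") {
        depth <- depth - 1L
        if (depth == 0L) { end <- i; break }
      }
    }
    if (is.na(end)) stop("unbalanced Annotation(...)")
    body <- substring(body, end + 1L)
  }
}

source_from_iri <- function(iri) {
  frag <- sub("#$", "", iri)
  utils::tail(strsplit(frag, "/", fixed = TRUE)[[1L]], 1L)
}

# ---- writers ----------------------------------------------------------------

#' @rdname parse_ontology
#' @param x An [ontology()] to serialise.
#' @export
write_ontology <- function(x, dialect = c("tsv", "functional")) {
  dialect <- match.arg(dialect)
  ax <- x$axioms
  if (dialect == "tsv") {
    lines <- c(sprintf("# ontology: %s", x$name),
               "kind\tlhs\trhs\textra_signature")
    for (i in seq_len(nrow(ax))) {
      extra <- setdiff(ax$sig[[i]], stats::na.omit(c(ax$lhs[i], ax$rhs[i])))
      lines <- c(lines, paste(
        ax$kind[i],
        ax$lhs[i],
        ifelse(is.na(ax$rhs[i]), "", ax$rhs[i]),
        paste(extra, collapse = ","),
        sep = "\t"))
    }
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  p <- tolower(x$name)
  lines <- c(
    sprintf("Prefix(%s:=<%s>)", p, x$namespace),
    sprintf("Ontology(<%s>", sub("#$", "", x$namespace))
  )
  qn <- function(e) paste0(p, ":", e)
  for (i in seq_len(nrow(ax))) {
    lines <- c(lines, switch(ax$kind[i],
      subclass_of        = sprintf("SubClassOf(%s %s)", qn(ax$lhs[i]), qn(ax$rhs[i])),
      equivalent_classes = sprintf("EquivalentClasses(%s %s)", qn(ax$lhs[i]), qn(ax$rhs[i])),
      disjoint_classes   = sprintf("DisjointClasses(%s %s)", qn(ax$lhs[i]), qn(ax$rhs[i])),
      complex            = ax$raw[i]
    ))
  }
  paste0(paste(c(lines, ")"), collapse = "\n"), "\n")
}

#' Merge two sources and a mapping set into one ontology
#'
#' Entity names are qualified with their source (`FMA:Joint`) so the merged
#' signature is collision-free; every equivalence mapping becomes an
#' `EquivalentClasses` axiom between the qualified names.  The merged
#' ontology is the input to [find_unsatisfiable()].
#'
#' @param o1,o2 [ontology()] objects for the two sources.
#' @param mappings A [mapping_set()] between them (may be empty).
#' @return An [ontology()] named `"<o1>+<o2>"` over qualified entity names.
#' @export
merge_with_mappings <- function(o1, o2, mappings = NULL) {
  qualify <- function(o) {
    ax <- o$axioms
    q <- function(v) ifelse(is.na(v), v, paste0(o$name, ":", v))
    ax$lhs <- q(ax$lhs); ax$rhs <- q(ax$rhs)
    ax$sig <- lapply(ax$sig, function(s) paste0(o$name, ":", s))
    ax
  }
  ax <- rbind(qualify(o1), qualify(o2))
  if (!is.null(mappings) && nrow(mappings$mappings)) {
    m <- mappings$mappings
    eq <- data.frame(
      kind = "equivalent_classes",
      lhs = paste0(m$source1, ":", m$entity1),
      rhs = paste0(m$source2, ":", m$entity2),
      stringsAsFactors = FALSE
    )
    eq$sig <- Map(c, eq$lhs, eq$rhs)
    eq$raw <- NA_character_
    ax <- rbind(ax, eq)
  }
  rownames(ax) <- NULL
  ontology(paste0(o1$name, "+", o2$name), ax)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
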