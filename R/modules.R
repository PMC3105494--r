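#' Syntactic bottom-locality module extraction
#'
#' Extracts the subset of an ontology's axioms that is relevant to a seed
#' signature under syntactic bottom (\eqn{\bot}) locality, iterated to a
#' fixpoint.  Out-of-signature classes are read as the empty class, so an
#' axiom joins the module exactly when it could constrain the seed:
#' `SubClassOf(a b)` when `a` is in the signature; `EquivalentClasses(a b)`
#' when either side is; `DisjointClasses(a b)` when both are; a complex
#' axiom when its named subclass-position class is.  Each admitted axiom's
#' signature is added before the next pass.  Bottom modules preserve all
#' entailed subsumptions, equivalences and inferred disjointness over
#' their signature.
#'
#' @param x An [ontology()].
#' @param seed Character vector of entity names.  Names outside the
#'   ontology signature contribute nothing (fresh satisfiable classes).
#' @return An object of class `locality_module` with elements
#'   `seed_signature`, `axioms` (row indices into `x$axioms` are dropped;
#'   the subset keeps the host order), `signature` and `ontology` (the
#'   module packaged as an [ontology()] so it can be classified directly).
#' @export
extract_bottom_module <- function(x, seed) {
  stopifnot(inherits(x, "ontology"))
  seed <- unique(as.character(seed))
  ax <- x$axioms
  n <- nrow(ax)
  in_mod <- rep(FALSE, n)
  sig <- seed
  repeat {
    added <- FALSE
    for (i in seq_len(n)) {
      if (in_mod[i]) next
      nonlocal <- switch(ax$kind[i],
        subclass_of        = ax$lhs[i] %in% sig,
        equivalent_classes = ax$lhs[i] %in% sig || ax$rhs[i] %in% sig,
        disjoint_classes   = ax$lhs[i] %in% sig && ax$rhs[i] %in% sig,
        complex            = !is.na(ax$lhs[i]) && ax$lhs[i] %in% sig
      )
      if (isTRUE(nonlocal)) {
        in_mod[i] <- TRUE
        sig <- unique(c(sig, ax$sig[[i]]))
        added <- TRUE
      }
    }
    if (!added) break
  }
  mod_ax <- ax[in_mod, , drop = FALSE]
  rownames(mod_ax) <- NULL
  structure(
    list(
      seed_signature = seed,
      axioms = mod_ax,
      signature = sort(unique(c(seed, unlist(mod_ax$sig, use.names = FALSE)))),
      ontology = ontology(x$name, mod_ax, labels = x$labels,
                          namespace = x$namespace)
    ),
    class = "locality_module"
  )
}

#' @export
print.locality_module <- function(x, ...) {
  cat(sprintf("<locality_module> seed %d, axioms %d, signature %d\n",
              length(x$seed_signature), nrow(x$axioms), length(x$signature)))
  invisible(x)
}
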