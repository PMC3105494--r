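---
title: "Auditing cross-ontology equivalence mappings with logic-based principles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing cross-ontology equivalence mappings with logic-based principles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignaudit)
```

## The problem

Biomedical terminologies such as FMA, NCI Thesaurus and SNOMED CT describe
overlapping domains with independently chosen vocabularies.  Metathesaurus-style
integration assigns a concept unique identifier (CUI) to synonymous entities
across sources, which induces a *mapping theory* `M`: one
`EquivalentClasses(e1 e2)` axiom for every pair of entities from different
sources sharing a CUI.  Read logically, `O1 ∪ O2 ∪ M` often entails things
nobody intended — equivalences between entities that a source keeps distinct,
or outright unsatisfiable classes.  `alignaudit` detects such errors from three
principles and repairs them automatically:

* **Conservativity** — `M` should not create new semantic relationships
  *inside* one source.  Because `M` contains only cross-source equivalences,
  a violation reduces to a *fan-in*: two distinct entities `e1`, `e1'` of one
  source mapped to the same entity `e2` of the other while the source alone
  does not entail `e1 ≡ e1'`.
* **Consistency** — every named class of `O1 ∪ O2 ∪ M` should be satisfiable.
  The *disjointness heuristic* flags a pair of mappings `μ = (e, f)`,
  `μ' = (e', f')` when one source entails `e ⊑ e'` while the other entails
  `f` and `f'` disjoint; the merge then makes `e` (and `f`) unsatisfiable.
* **Locality** — a correct mapping should carry its neighbourhood with it:
  the entities semantically related to `e` should map onto those related to
  `f`.  This yields a per-mapping confidence used to choose *which* member of
  each conflict to drop.

## Restricted representation and the structural reasoner

The axiom language is deliberately small: `SubClassOf`, `EquivalentClasses`
and `DisjointClasses` over named classes, plus opaque `complex` axioms that
are parsed, kept for signatures and module extraction, and ignored by
inference.  Every detection technique above needs only subsumption and
disjointness queries, so `classify()` computes the reflexive–transitive
closure of told subclass edges (equivalences contribute both directions;
cycles are legal and encode equivalence) and carries the told disjoint pairs.
Disjointness is inherited downward only: `inferred_disjoint(a, b)` holds when
some told pair `(d1, d2)` has `a ⊑ d1` and `b ⊑ d2`.  A class is reported by
`find_unsatisfiable()` when it sits below both members of a told disjoint
pair.  This reasoner is *sound but incomplete* with respect to OWL 2 DL:
everything it reports is a genuine entailment of the named-class fragment,
but entailments that require complex class expressions are invisible to it.
Consequently the unsatisfiability counts it produces on rich ontologies are
lower bounds, never upper bounds.

Unknown entities in queries are treated as fresh satisfiable classes rather
than errors, which keeps file-level pipelines robust to mappings that
reference entities absent from a trimmed source.

## Bottom-locality modules

`extract_bottom_module()` implements syntactic ⊥-locality, iterated to a
fixpoint: reading every out-of-signature class as the empty class, an axiom
is non-local (and joins the module) when it could still constrain the
signature — `SubClassOf(a b)` when `a ∈ Σ`; `EquivalentClasses(a b)` when
either side is in `Σ`; `DisjointClasses(a b)` only when both are; a complex
axiom when its subclass-position named class is.  Each admitted axiom's
signature joins `Σ` before the next pass, with a deterministic worklist by
axiom position.  The disjointness rule (both sides required) keeps modules
small while still preserving `inferred_disjoint` over the module signature,
because any relevant told pair consists of ancestors of signature members and
is therefore pulled in; the test suite checks entailment preservation
exhaustively on random ontologies.  These modules justify the consistency
detector's `use_modules` optimisation (identical output, smaller
classification) and define the neighbourhoods used for confidence scoring.

## Confidence and diagnosis

For a mapping `μ = (e, f)` let `M1` and `M2` be the module signatures of `e`
and `f`, each excluding the endpoint itself (a module always contains its own
seed, so including endpoints would give every mapping a non-zero floor).  The
base ratio pools both sides:

```
conf(μ) = (#{x ∈ M1 mapped into M2} + #{y ∈ M2 mapped into M1}) / (|M1| + |M2|)
```

Mapping sets are often too sparse for this to discriminate, so a lexical
augmentation also links `x ∈ M1` to `y ∈ M2` when their labels reach a
token-set Jaccard of `lexical_threshold` (default **0.9**, i.e. near-identical
labels; lower it to credit looser wording).  The combined score *is* the
augmented ratio — augmentation replaces rather than averages, and both ratios
are reported so the effect is inspectable.  `lexical_ratio ≥ base_ratio`
always holds since augmentation only adds links.

Conflicts form an undirected graph over mapping ids.  Repair must remove at
least one mapping per conflict while minimising the total removed confidence
— a minimum-weight vertex cover per connected component.  Components with at
most `exact_limit` vertices (default **20**) are solved exactly by branch and
bound with deterministic tie-breaks (fewer removals, then lexicographically
smallest id set); larger components use a deterministic greedy cover
(highest uncovered-degree-to-confidence ratio first) and are flagged
`exact = FALSE` in the repair plan.  No randomised tie-breaking exists
anywhere in the pipeline; identical inputs give identical outputs.

Removing mappings can never create a new conservativity or consistency
conflict (both detectors are monotone in the mapping set), so covering all
conflict edges guarantees that the kept set re-audits clean — a property the
pipeline tests assert end-to-end.

## What the synthetic generator emulates — and what it does not

`generate_mapped_pair()` builds a rooted random taxonomy (each new class
attaches to an existing one, preferring parents still short of `branching`
children), declares each unordered sibling pair disjoint with
`sibling_disjointness_rate`, and copies it isomorphically into a second
source with renamed entities but shared labels.  A `true_mapping_fraction`
sample of counterpart pairs receives a shared synthetic CUI, emitted as a
standard 18-column RRF document so the real extraction path is exercised.
Errors are planted in the two shapes the detectors target:

* *ambiguity*: an unmapped same-source class is added to an existing CUI,
  creating a fan-in (guaranteed conservativity conflict, since distinct tree
  classes are never entailed equivalent);
* *violation*: a mapped class whose parent is also mapped has its partner
  re-pointed to an unmapped class lying under a branch disjoint from an
  ancestor of the parent's image (guaranteed disjointness-heuristic conflict,
  because the parent's mapping stays in place).

Defaults are `n_classes = 300`, `branching = 3`,
`sibling_disjointness_rate = 0.5`, `true_mapping_fraction = 0.6`,
`ambiguity_rate = violation_rate = 0.05`.  The structural knobs are chosen to
look like a mid-size clinical terminology fragment: shallow bushy trees,
disjointness declared between roughly half the sibling pairs (rich enough in
negative information for the heuristic to bite, as in NCI), a bit over half
the vocabulary covered by the thesaurus, and a few percent of planted noise.
Planting only where the structure admits detection makes recall 1.0 *by
construction* — these fixtures validate the machinery, not the field
difficulty of the task.  Real source pairs are **not** isomorphic, their
labels vary lexically, entities appear under multiple CUIs, and errors are
not confined to the two planted shapes; passing on fixtures therefore shows
correctness of the detectors and repair, not expected precision on UMLS-scale
data.

Each fixture uses a single private RNG stream seeded from `fixture_spec$seed`
and restores the caller's RNG state, so generation is reproducible and
side-effect free.

## Numerical and design choices

* Equivalence is mutual subsumption; n-ary `DisjointClasses` expands to all
  unordered pairs at parse time.
* Entity identity when reading RRF defaults to the source code (`CODE`)
  with fallback to the whitespace-normalised string; configurable because
  sources differ in whether codes or strings are the stable identifier.
  No term-type or suppression filtering is applied by default.
* An entity pair reachable through several CUIs becomes one mapping carrying
  all CUI annotations; duplicate RRF rows collapse.
* Conservativity tallies are exposed three ways (unordered pairs, mappings
  involved, fan-in groups) because published conflict counts do not fix one
  convention; a fan-in of `k` entities yields `choose(k, 2)` pairs and one
  group.
* The consistency detector scans unordered mapping pairs, includes the
  reflexive `e = e'` case (one entity mapped to two disjoint classes is
  incoherent), deduplicates pairs witnessed in both directions, and reports
  the first witness in a deterministic order.
* Floating-point ties in branch and bound use a `1e-12` tolerance; confidence
  ratios are exact rationals of small integers, so ties are decided by the
  structural tie-breaks in practice.
* Problem sizes in the test suite — ontologies of up to 30 classes for the
  brute-force oracle comparisons, mapping sets of up to 200, conflict graphs
  of up to 12 vertices for the exhaustive cover oracle, and ten 300-class
  fixture replicates — are chosen so that the independent oracles
  (Floyd–Warshall closure, literal pairwise definitions, `2^n` subset
  enumeration) stay exact and the whole suite runs in a few minutes.

## Known limitations

* No tableau/hypertableau reasoning: entailments through existential or
  universal restrictions, property hierarchies or individuals are invisible;
  DL-complete unsatisfiability counts on rich sources will exceed the
  structural ones.
* The greedy cover for components above `exact_limit` is approximate; the
  plan flags such components rather than pretending optimality.
* The lexical matcher is a deliberately simple token-set Jaccard; confidence
  values (and hence which member of a conflict is dropped) depend on it, and
  different matchers will disambiguate differently.
* Step 4 of a full curation workflow — expert repair of inherent source
  incompatibilities — is supported only by `residual_incoherence()`, which
  exports the remaining structurally unsatisfiable classes with witnessing
  subsumption chains for manual review.
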