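# alignaudit

Logic-based auditing and repair of cross-ontology equivalence mappings.

Metathesaurus-style terminology integration (UMLS being the canonical
example) groups entities from independent source vocabularies — FMA, NCI
Thesaurus, SNOMED CT, and over a hundred others — under shared concept
unique identifiers (CUIs).  Each CUI induces equivalence mappings
`EquivalentClasses(e1 e2)` between entities of different sources.  Read
together with the sources' own axioms, these mappings frequently entail
things no curator intended: equivalences between entities a source keeps
distinct, or classes that become unsatisfiable outright.  `alignaudit` is
for terminology curators and ontology-alignment researchers who want those
errors surfaced and repaired *before* the merged vocabulary is used.

## Method

Given sources `O1`, `O2` and a mapping theory `M` of cross-source
equivalences, the package audits `M` with three principles:

* **Conservativity** — `O1 ∪ M` must not entail new relationships between
  entities of `O1`.  Since `M` contains only cross-source equivalences, a
  violation is a fan-in: mappings `e1 ≡ e2` and `e1' ≡ e2` with
  `O1 ⊭ e1 ≡ e1'`.  Each such unordered pair of mappings is one conflict.
* **Consistency** — every named class of `O1 ∪ O2 ∪ M` must be satisfiable.
  The disjointness heuristic flags mappings `μ = (e, f)`, `μ' = (e', f')`
  whenever `O1 ⊨ e ⊑ e'` and `O2 ⊨ f ⊓ f' ⊑ ⊥` (or symmetrically); every
  such pair makes `e` and `f` unsatisfiable in the merge.
* **Locality** — a correct mapping carries its neighbourhood with it.  The
  confidence of `μ = (e, f)` is the pooled fraction of the ⊥-locality module
  signatures of `e` and `f` (endpoints excluded) that `M` — optionally
  augmented with near-identical-label correspondences — links across:

  `conf(μ) = (|M1 ↦ M2| + |M2 ↦ M1|) / (|M1| + |M2|)`

Conflicts form a graph over mapping ids; repair removes one mapping per
conflict minimising total removed confidence — a minimum-weight vertex
cover per connected component, solved exactly (branch and bound) up to a
size limit and greedily above it.  All reasoning uses a sound structural
reasoner (told subsumption closure + downward-inherited disjointness) over
a restricted axiom language; complex OWL class expressions are retained for
signatures and modules but ignored by inference.

## Worked example

Five MRCONSO rows share the CUI for "Joint" across FMA and SNOMED CT, but
FMA keeps `Joint` and `Set_of_joints` distinct — the classic ambiguity the
conservativity principle catches:

```r
library(alignaudit)

rrf <- c(
  "C0022417|ENG|||||||||P|FMA||Joint|Joint|||",
  "C0022417|ENG|||||||||P|FMA||Set_of_joints|Set_of_joints|||",
  "C0022417|ENG|||||||||P|SNOMEDCT||Joint_structure|Joint_structure|||")
fma <- ontology("FMA", axiom_table(
  c("subclass_of", "subclass_of"),
  c("Joint", "Set_of_joints"),
  c("Anatomical_structure", "Anatomical_set")))

m <- generate_mappings(parse_mrconso(rrf, c("FMA", "SNOMEDCT")),
                       c("FMA", "SNOMEDCT"))
audit <- audit_alignment(fma, ontology("SNOMEDCT"), m)
audit
#> <alignment_audit>
#>   conservativity_pairs: 1
#>   conservativity_mappings: 2
#>   conservativity_groups: 1
#>   consistency_pairs: 0
#>   consistency_mappings: 0
#>   conflicted_mappings: 2
#>   total_mappings: 2
audit$conflicts$witness
#> [1] "shared SNOMEDCT:Joint_structure; FMA:Joint and FMA:Set_of_joints not equivalent in FMA"
```

Both FMA entities were mapped to `Joint_structure` (2 mappings, 1 conflicting
pair, 1 fan-in group); the witness names the shared endpoint and the
non-equivalent pair.  On a synthetic fixture with known ground truth the
whole pipeline — extract, audit, score, repair, re-audit — closes:

```r
fix <- generate_mapped_pair(fixture_spec(seed = 7))   # 300 classes/source
m <- fixture_mappings(fix)
audit <- audit_alignment(fix$o1, fix$o2, m)
audit$summary$conservativity_pairs   #> 9    (one per planted ambiguity)
audit$summary$consistency_pairs      #> 179  (planted cross-branch mappings
                                     #       conflict with several ancestors)
rep <- repair_alignment(fix$o1, fix$o2, m, audit$conflicts)
rep$plan
#> <repair_plan> remove 18 of 139 conflicted mappings (total confidence 7.914)
#>   note: some components solved greedily (approximate)
```

All 18 removed mappings are exactly the planted errors (9 ambiguous + 9
violating), and re-auditing the kept set reports zero conflicts.  The same
steps are available from the shell via `inst/cli/alignaudit.R`
(`extract`, `audit`, `repair` subcommands).

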