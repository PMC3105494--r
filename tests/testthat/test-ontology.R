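# ontology representation, parsers, and the structural reasoner

test_that("functional-syntax parsing handles named, n-ary and complex axioms", {
  doc <- c(
    "Prefix(fma:=<http://example.org/FMA#>)",
    "Ontology(<http://example.org/FMA>",
    "SubClassOf(fma:Lymphokine fma:Protein)",
    "EquivalentClasses(fma:Arm fma:Upper_limb)",
    "DisjointClasses(fma:Material fma:Immaterial fma:Abstract)",
    "SubClassOf(fma:Pleural_Tissue ObjectAllValuesFrom(fma:has_location fma:Thoracic_Cavity))",
    ")"
  )
  o <- parse_ontology(doc)
  expect_equal(o$name, "FMA")
  expect_equal(sum(o$axioms$kind == "subclass_of"), 1L)
  expect_equal(sum(o$axioms$kind == "equivalent_classes"), 1L)
  # n-ary disjointness expands to all unordered pairs
  expect_equal(sum(o$axioms$kind == "disjoint_classes"), 3L)
  cx <- o$axioms[o$axioms$kind == "complex", ]
  expect_equal(nrow(cx), 1L)
  expect_equal(cx$lhs, "Pleural_Tissue")
  expect_setequal(cx$sig[[1]],
                  c("Pleural_Tissue", "has_location", "Thoracic_Cavity"))
  expect_true(all(c("Lymphokine", "Protein", "Thoracic_Cavity") %in%
                    ont_signature(o)))
})

test_that("malformed documents fail with a line number", {
  expect_error(parse_ontology("SubClassOf(fma:A fma:B"), "line 1")
  expect_error(parse_ontology(c("", "NotAnAxiom(x y)")), "line 2")
  expect_error(parse_ontology("a\tb", dialect = "tsv"), "header")
  expect_error(parse_ontology("x", dialect = "nonesuch"), "dialect")
})

test_that("empty documents give empty ontologies", {
  o <- parse_ontology("", name = "X", dialect = "functional")
  expect_equal(nrow(o$axioms), 0L)
  expect_equal(length(ont_signature(o)), 0L)
})

test_that("parse-write-parse is the identity in both dialects", {
  set.seed(11)
  for (rep in 1:10) {
    o <- random_named_ontology(12L, 14L, n_eq = 3L, n_dis = 3L, name = "RT")
    for (dialect in c("tsv", "functional")) {
      o2 <- parse_ontology(write_ontology(o, dialect), name = "RT")
      expect_equal(o2$axioms[c("kind", "lhs", "rhs")],
                   o$axioms[c("kind", "lhs", "rhs")])
      o3 <- parse_ontology(write_ontology(o2, dialect), name = "RT")
      expect_equal(o3$axioms, o2$axioms)
    }
  }
})

test_that("classification entails told facts, reflexivity and equivalence cycles", {
  nci <- ontology("NCI", axiom_table(
    "subclass_of", "Therapeutic_Lymphokine", "Pharmacologic_Substance"))
  cl <- classify(nci)
  expect_true(entails_subsumption(cl, "Therapeutic_Lymphokine",
                                  "Pharmacologic_Substance"))
  for (a in cl$classes) expect_true(entails_subsumption(cl, a, a))
  expect_true(entails_equivalence(cl, "Pharmacologic_Substance",
                                  "Pharmacologic_Substance"))
  # a cycle of subclass axioms encodes equivalence
  cyc <- classify(ontology("C", axiom_table(
    c("subclass_of", "subclass_of"), c("a", "b"), c("b", "a"))))
  expect_true(entails_equivalence(cyc, "a", "b"))
  # unknown entities act as fresh satisfiable classes
  expect_true(entails_equivalence(cl, "Nonesuch", "Nonesuch"))
  expect_false(entails_subsumption(cl, "Nonesuch", "Pharmacologic_Substance"))
})

test_that("closure equals brute-force reachability on random ontologies", {
  set.seed(42)
  for (rep in 1:25) {
    o <- random_named_ontology(sample(5:30, 1L), sample(5:50, 1L),
                               n_eq = sample(0:4, 1L))
    cl <- classify(o)
    R <- oracle_closure(o$axioms)
    for (a in rownames(R)) {
      expect_setequal(cl$anc[[a]], colnames(R)[R[a, ]])
    }
  }
})

test_that("inferred disjointness matches the disjoint-ancestor oracle", {
  nci <- lymphokine_nci()
  cl <- classify(nci)
  expect_true(inferred_disjoint(cl, "Protein", "Therapeutic_Lymphokine"))
  expect_true(inferred_disjoint(cl, "Therapeutic_Lymphokine", "Protein"))
  expect_false(inferred_disjoint(cl, "Therapeutic_Lymphokine",
                                 "Therapeutic_Lymphokine"))
  set.seed(99)
  for (rep in 1:15) {
    o <- random_named_ontology(12L, 16L, n_dis = sample(1:5, 1L))
    cl <- classify(o)
    R <- oracle_closure(o$axioms)
    d <- oracle_disjoint_pairs(o$axioms)
    cls <- cl$classes
    for (a in cls) for (b in cls) {
      expect_equal(inferred_disjoint(cl, a, b), oracle_disjoint(R, d, a, b),
                   info = paste(a, b))
    }
  }
})

test_that("an ontology without negative information has no disjointness or unsatisfiability", {
  o <- random_named_ontology(15L, 25L, n_eq = 3L)
  cl <- classify(o)
  pairs <- expand.grid(a = cl$classes, b = cl$classes,
                       stringsAsFactors = FALSE)
  expect_false(any(mapply(function(a, b) inferred_disjoint(cl, a, b),
                          pairs$a, pairs$b)))
  expect_length(find_unsatisfiable(o), 0L)
})

test_that("structural unsatisfiability equals the exhaustive oracle", {
  set.seed(7)
  for (rep in 1:20) {
    o <- random_named_ontology(sample(8:30, 1L), sample(10:40, 1L),
                               n_eq = sample(0:3, 1L), n_dis = sample(1:6, 1L))
    expect_equal(find_unsatisfiable(o), oracle_unsatisfiable(o$axioms))
  }
})

test_that("unsatisfiability vanishes when disjointness axioms are dropped", {
  set.seed(21)
  for (rep in 1:10) {
    o <- random_named_ontology(15L, 25L, n_dis = 5L)
    unsat <- find_unsatisfiable(o)
    stripped <- ontology(o$name, o$axioms[o$axioms$kind != "disjoint_classes", ])
    expect_length(find_unsatisfiable(stripped), 0L)
    expect_true(all(unsat %in% ont_signature(o)))
  }
})

test_that("closure is idempotent and monotone under added axioms", {
  set.seed(5)
  for (rep in 1:10) {
    o <- random_named_ontology(12L, 18L, n_eq = 2L, n_dis = 2L)
    cl <- classify(o)
    # re-assert every entailed subsumption as a told axiom: closure unchanged
    ent <- do.call(rbind, lapply(cl$classes, function(a) {
      data.frame(lhs = a, rhs = cl$anc[[a]], stringsAsFactors = FALSE)
    }))
    ent <- ent[ent$lhs != ent$rhs, , drop = FALSE]
    extended <- ontology(o$name, rbind(
      o$axioms,
      axiom_table(rep("subclass_of", nrow(ent)), ent$lhs, ent$rhs)
    ))
    cl2 <- classify(extended)
    for (a in cl$classes) expect_setequal(cl2$anc[[a]], cl$anc[[a]])
    # adding fresh axioms never removes entailments
    bigger <- ontology(o$name, rbind(
      o$axioms,
      axiom_table("subclass_of", sample(cl$classes, 1L), "Fresh_Top")
    ))
    cl3 <- classify(bigger)
    for (a in cl$classes) expect_true(all(cl$anc[[a]] %in% cl3$anc[[a]]))
  }
})
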