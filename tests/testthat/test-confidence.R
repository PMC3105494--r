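# locality-based confidence scoring and conflict diagnosis

test_that("lexical similarity is normalised token-set Jaccard", {
  expect_equal(lexical_similarity("Joint", "joint"), 1)
  expect_equal(lexical_similarity("Upper limb", "Upper_Extremity"), 1 / 3)
  expect_equal(lexical_similarity("Protein", "Thoracic cavity"), 0)
  expect_equal(lexical_similarity("Set_of_joints", "set OF Joints"), 1)
  expect_equal(lexical_similarity("", "  "), 0)
  expect_equal(lexical_similarity("a b", "b a"), 1)
  expect_equal(lexical_similarity("Heart (organ)", "heart organ"), 1)
  # symmetry on arbitrary inputs
  set.seed(1)
  for (rep in 1:20) {
    w <- function() paste(sample(letters, sample(1:4, 1), TRUE), collapse = " ")
    l1 <- w(); l2 <- w()
    expect_equal(lexical_similarity(l1, l2), lexical_similarity(l2, l1))
  }
})

test_that("a mapping with an unmapped neighbourhood scores zero base ratio", {
  # the upper-extremity pattern: the endpoints are mapped but nothing in
  # their modules is
  o1 <- ontology("NCI", axiom_table("subclass_of", "Upper_Extremity", "Body_Region"))
  o2 <- ontology("FMA", axiom_table("subclass_of", "Arm", "Limb_segment"))
  m <- mapping_set(c("NCI", "FMA"), data.frame(
    id = "mu", cui = "", source1 = "NCI", entity1 = "Upper_Extremity",
    source2 = "FMA", entity2 = "Arm", relation = "equivalence",
    confidence = NA_real_, stringsAsFactors = FALSE))
  s <- compute_confidence("mu", o1, o2, m)
  expect_equal(s$base_ratio, 0)
  expect_gte(s$lexical_ratio, s$base_ratio)
})

test_that("fully corresponding modules score one; partial overlap gives the pooled ratio", {
  # chains a1 < a2 < a3 and b1 < b2 < b3, with the whole chain mapped
  mk <- function(src, pfx) ontology(src, axiom_table(
    rep("subclass_of", 2), paste0(pfx, 1:2), paste0(pfx, 2:3)))
  o1 <- mk("A", "a"); o2 <- mk("B", "b")
  full <- mapping_set(c("A", "B"), data.frame(
    id = paste0("m", 1:3), cui = "", source1 = "A", entity1 = paste0("a", 1:3),
    source2 = "B", entity2 = paste0("b", 1:3), relation = "equivalence",
    confidence = NA_real_, stringsAsFactors = FALSE))
  s <- compute_confidence("m1", o1, o2, full, lexical_threshold = 2)
  expect_equal(s$base_ratio, 1)
  # drop the a3~b3 mapping: modules of a1/b1 are {a2,a3}/{b2,b3}, one of
  # each mapped -> pooled ratio 2/4
  part <- mapping_set(c("A", "B"), full$mappings[1:2, ])
  s2 <- compute_confidence("m1", o1, o2, part, lexical_threshold = 2)
  expect_equal(s2$base_ratio, 0.5)
})

test_that("pooled ratio matches a hand-computed 3-of-5 plus 2-of-4 fixture", {
  # module of e has 5 entities, 3 mapped into the partner module; module
  # of f has 4 entities, 2 mapped back: ratio (3+2)/(5+4) = 5/9
  ax1 <- axiom_table(rep("subclass_of", 5), "e", paste0("p", 1:5))
  ax2 <- axiom_table(rep("subclass_of", 4), "f", paste0("q", 1:4))
  o1 <- ontology("A", ax1); o2 <- ontology("B", ax2)
  m <- data.frame(
    id = c("mu", paste0("x", 1:3)), cui = "",
    source1 = "A", entity1 = c("e", "p1", "p2", "p3"),
    source2 = "B", entity2 = c("f", "q1", "q2", "q1"),
    relation = "equivalence", confidence = NA_real_,
    stringsAsFactors = FALSE)
  ms <- mapping_set(c("A", "B"), m)
  s <- compute_confidence("mu", o1, o2, ms, lexical_threshold = 2)
  expect_equal(s$base_ratio, 5 / 9)
})

test_that("lexical augmentation only adds correspondences and respects its threshold", {
  o1 <- ontology("A", axiom_table("subclass_of", "e", "Shared_Term"),
                 labels = c(Shared_Term = "shared term"))
  o2 <- ontology("B", axiom_table("subclass_of", "f", "Also_Shared_Term"),
                 labels = c(Also_Shared_Term = "also shared term"))
  m <- mapping_set(c("A", "B"), data.frame(
    id = "mu", cui = "", source1 = "A", entity1 = "e", source2 = "B",
    entity2 = "f", relation = "equivalence", confidence = NA_real_,
    stringsAsFactors = FALSE))
  lo <- compute_confidence("mu", o1, o2, m, lexical_threshold = 0.5)
  hi <- compute_confidence("mu", o1, o2, m, lexical_threshold = 0.9)
  expect_equal(lo$base_ratio, 0)
  expect_equal(lo$lexical_ratio, 1)   # Jaccard 2/3 passes 0.5 both ways
  expect_equal(hi$lexical_ratio, 0)   # but not 0.9
  expect_equal(lo$combined, lo$lexical_ratio)
})

test_that("confidence is invariant under entity renaming", {
  set.seed(61)
  o1 <- random_named_ontology(12L, 16L, name = "A")
  o2 <- random_named_ontology(12L, 16L, name = "B")
  m <- random_mapping_set(c("A", "B"), ont_signature(o1), ont_signature(o2), 20L)
  s <- score_mappings(m$mappings$id, o1, o2, m, lexical_threshold = 2)
  ren <- function(v) paste0("Z", v)
  o1r <- ontology("A", within(o1$axioms, { lhs <- ren(lhs); rhs <- ren(rhs) }))
  o1r$axioms$sig <- lapply(o1$axioms$sig, ren)
  mr <- m$mappings; mr$entity1 <- ren(mr$entity1)
  mr$id <- paste0("Z", mr$id)
  msr <- mapping_set(c("A", "B"), mr)
  sr <- score_mappings(msr$mappings$id, o1r, o2, msr, lexical_threshold = 2)
  expect_equal(sr$base_ratio, s$base_ratio)
})

test_that("scoring an unknown mapping id is a contract error", {
  m <- lymphokine_mappings()
  expect_error(
    compute_confidence("nonesuch", lymphokine_fma(), lymphokine_nci(), m),
    "not in the mapping set")
})

test_that("the conflict graph collapses parallel conflicts and finds components", {
  k <- upper_limb_conflicts()
  g <- build_conflict_graph(rbind(k, k))   # duplicates collapse
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 4L)
  expect_equal(igraph::components(g)$no, 1L)
  expect_equal(igraph::vcount(build_conflict_graph(k[0, ])), 0L)
  set.seed(17)
  for (rep in 1:10) {
    df <- random_conflict_graph_df(sample(4:12, 1L), sample(3:15, 1L))
    g <- build_conflict_graph(df)
    # union-find oracle for component count
    ids <- sort(unique(c(df$mapping1_id, df$mapping2_id)))
    parent <- stats::setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (i in seq_len(nrow(df))) {
      parent[[find(df$mapping1_id[i])]] <- find(df$mapping2_id[i])
    }
    n_comp <- length(unique(vapply(ids, find, "")))
    expect_equal(igraph::components(g)$no, n_comp)
  }
})

test_that("the upper-limb 4-cycle diagnosis removes the two cheap diagonal mappings", {
  g <- build_conflict_graph(upper_limb_conflicts())
  plan <- diagnose(g, c(mu1 = 0.5, mu2 = 0.06, mu3 = 0.30, mu4 = 0.5))
  expect_equal(plan$removed, c("mu2", "mu3"))
  expect_equal(plan$total_removed_confidence, 0.36)
  expect_true(all(plan$components$exact))
})

test_that("a single conflict removes its cheaper endpoint", {
  df <- upper_limb_conflicts()[1, ]
  g <- build_conflict_graph(df)
  plan <- diagnose(g, c(mu1 = 0.2, mu2 = 0.9))
  expect_equal(plan$removed, "mu1")
  expect_equal(plan$kept, "mu2")
})

test_that("exact diagnosis matches the exhaustive minimum cover on random graphs", {
  set.seed(271)
  for (rep in 1:50) {
    df <- random_conflict_graph_df(sample(4:12, 1L), sample(3:18, 1L))
    ids <- sort(unique(c(df$mapping1_id, df$mapping2_id)))
    conf <- stats::setNames(round(stats::runif(length(ids)), 3L), ids)
    g <- build_conflict_graph(df)
    plan <- diagnose(g, conf, exact_limit = 12L)
    edges <- unique(t(apply(df[c("mapping1_id", "mapping2_id")], 1L, sort)))
    expect_true(all(edges[, 1L] %in% plan$removed |
                    edges[, 2L] %in% plan$removed))
    expect_equal(plan$total_removed_confidence,
                 oracle_min_cover_weight(edges, conf))
  }
})

test_that("components above the exact limit fall back to a valid greedy cover", {
  set.seed(31)
  df <- random_conflict_graph_df(15L, 30L)
  ids <- sort(unique(c(df$mapping1_id, df$mapping2_id)))
  conf <- stats::setNames(stats::runif(length(ids)), ids)
  plan <- diagnose(build_conflict_graph(df), conf, exact_limit = 5L)
  covered <- df$mapping1_id %in% plan$removed | df$mapping2_id %in% plan$removed
  expect_true(all(covered))
  expect_true(any(!plan$components$exact))
  expect_error(diagnose(build_conflict_graph(df), conf[-1]), "missing confidence")
})
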