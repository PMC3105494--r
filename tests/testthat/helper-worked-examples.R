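# Small fixtures used across tests: the joint-ambiguity example, the
# lymphokine incoherence example, and the upper-limb 4-cycle of conflicts.

joint_rrf <- function() {
  c("C0022417|ENG|||||||||P|FMA||Joint|Joint|||",
    "C0022417|ENG|||||||||P|FMA||Set_of_joints|Set_of_joints|||",
    "C0022417|ENG|||||||||P|SNOMEDCT||Joint_structure|Joint_structure|||",
    "C0022417|ENG|||||||||P|NCI||Joint|Joint|||",
    "C0022417|ENG|||||||||P|NCI||Articulation|Articulation|||")
}

# FMA fragment where Joint and Set_of_joints are unrelated siblings of
# different parents
joint_fma <- function() {
  ontology("FMA", axiom_table(
    c("subclass_of", "subclass_of"),
    c("Joint", "Set_of_joints"),
    c("Anatomical_structure", "Anatomical_set")
  ))
}

lymphokine_fma <- function() {
  ontology("FMA", axiom_table("subclass_of", "Lymphokine", "Protein"))
}

lymphokine_nci <- function() {
  ontology("NCI", axiom_table(
    c("subclass_of", "disjoint_classes"),
    c("Therapeutic_Lymphokine", "Pharmacologic_Substance"),
    c("Pharmacologic_Substance", "Protein")
  ))
}

lymphokine_mappings <- function() {
  mapping_set(c("FMA", "NCI"), data.frame(
    id = c("m_protein", "m_lymphokine"), cui = "",
    source1 = "FMA", entity1 = c("Protein", "Lymphokine"),
    source2 = "NCI", entity2 = c("Protein", "Therapeutic_Lymphokine"),
    relation = "equivalence", confidence = NA_real_,
    stringsAsFactors = FALSE
  ))
}

# the 4-cycle of conflicts between two ambiguous upper-limb mappings
upper_limb_conflicts <- function() {
  data.frame(
    principle = "conservativity",
    mapping1_id = c("mu1", "mu3", "mu1", "mu2"),
    mapping2_id = c("mu2", "mu4", "mu3", "mu4"),
    witness = "", stringsAsFactors = FALSE
  )
}
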