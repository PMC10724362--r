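#' Three divergent canonical writings of zidovudine
#'
#' Zidovudine (the antiretroviral AZT) written three ways: the default
#' canonical form of one widely used toolkit (aromatic lowercase
#' notation), the rooted writing of the same toolkit that lies farthest
#' from the default in a chemical language model's feature space, and a
#' second toolkit's canonical form (which prefers the Kekule convention).
#' All three encode the identical achiral molecular graph; their string,
#' token and embedding divergence is the worked example used throughout
#' the package documentation.
#'
#' @return data.frame with columns `representation`
#'   (`native_canonical`, `max_distance_rooted`, `alternative_canonical`)
#'   and `smiles`.
#' @export
zidovudine_variants <- function() {
  data.frame(
    representation = c("native_canonical", "max_distance_rooted",
                       "alternative_canonical"),
    smiles = c(
      "Cc1cn(C2CC(N=[N+]=[N-])C(CO)O2)c(=O)[nH]c1=O",
      "O=c1[nH]c(=O)c(C)cn1C1CC(N=[N+]=[N-])C(CO)O1",
      "CC1=CN(C(=O)NC1=O)C2CC(C(O2)CO)N=[N+]=[N-]"
    ),
    stringsAsFactors = FALSE
  )
}

#' Functional descriptors of the nine reference query molecules
#'
#' Curated short functional labels for nine structurally and functionally
#' distinct drug-like query molecules, the inputs to the
#' functional-similarity stage of the patent pipeline (see
#' [build_similarity_prompt()]).  Descriptors name well-documented protein
#' targets, target classes, or downstream effects.
#'
#' @return data.frame with columns `molecule` and `descriptors`
#'   (comma-separated).
#' @export
query_descriptors <- function() {
  data.frame(
    molecule = c("zidovudine", "penicillin", "nirmatrelvir", "LSD",
                 "fentanyl", "SB-759335-B", "BMS-536924", "558441-90-0",
                 "fluticasone furoate"),
    descriptors = c(
      "reverse transcriptase inhibitor, antiviral, albumin ligand, phosphorylase ligand",
      "antibiotic, antibacterial, beta-lactamase ligand, penicillin-binding protein ligand",
      "SARS-CoV-2 inhibitor, antiviral, protease inhibitor, peptidase inhibitor",
      "dopaminergic, serotonergic, histamine receptor ligand, psychoactive",
      "opioid receptor ligand (mu, kappa, delta), analgesic, anesthetic",
      "serine-threonine kinase inhibitor, kinase inhibitor, MSK inhibitor, AKT inhibitor, YES inhibitor",
      "IGF inhibitor, INSR inhibitor, CYP inhibitor, MEK inhibitor, FAK inhibitor, LCK inhibitor, kinase inhibitor",
      "anti-HIV, GPCR ligand, CXC chemokine receptor ligand",
      "nuclear hormone receptor ligand, glucocorticoid receptor ligand, anti-inflammatory, anti-allergic"
    ),
    stringsAsFactors = FALSE
  )
}
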