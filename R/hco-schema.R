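#' Build the Human Connectomics Ontology schema
#'
#' Constructs the HCO TBox: four classes describing gray-matter parts,
#' white-matter parts and the tractography-specific \code{hco:MR_Node} /
#' \code{hco:MR_Route} concepts (an MR_Node is a gray-matter part where a
#' tractography-reconstructed connection begins or ends; an MR_Route is the
#' reconstructed white-matter pathway linking two MR_Nodes), the anchor
#' anatomy classes those definitions reference, and the eleven object
#' properties of the connectomics vocabulary. \code{hco:part_of} and
#' \code{hco:part} are transitive umbrella properties over the regional /
#' constitutional part properties of the source anatomy ontology; they are
#' deliberately not declared inverses of each other. \code{hco:mr_connection}
#' and \code{hco:continuous_with} are symmetric. The role chain
#' \code{is_tracto_connected o tracto_connects -> mr_connection} encodes
#' that two different nodes joined by one route are connected.
#'
#' Building twice yields structurally identical TBoxes.
#'
#' @return an \code{hco_tbox}.
#' @examples
#' schema <- build_hco_schema()
#' length(schema$properties)  # 11 object properties, no data property
#' @export
build_hco_schema <- function() {
  anat <- ce_named("fma:Anatomical_structure")
  part_disjunction <- ce_or(
    ce_some("fma:constitutional_part_of", anat),
    ce_some("fma:regional_part_of", anat)
  )
  tbox(
    classes = c(
      "hco:Gray_matter_part", "hco:White_matter_part",
      "hco:MR_Node", "hco:MR_Route",
      "fma:Region_of_cell_part_cluster_of_neuraxis",
      "fma:Gray_matter_of_neuraxis", "fma:White_matter_of_neuraxis",
      "fma:Anatomical_structure"
    ),
    properties = list(
      property_decl("hco:is_tracto_connected", inverse = "hco:tracto_connects",
                    domain = "hco:MR_Node", range = "hco:MR_Route"),
      property_decl("hco:tracto_connects", inverse = "hco:is_tracto_connected",
                    domain = "hco:MR_Route", range = "hco:MR_Node"),
      property_decl("hco:mr_connection", symmetric = TRUE,
                    domain = "hco:MR_Node", range = "hco:MR_Node"),
      property_decl("hco:continuous_with", symmetric = TRUE,
                    domain = "fma:Anatomical_structure",
                    range = "fma:Anatomical_structure"),
      property_decl("hco:part_of", transitive = TRUE,
                    domain = "fma:Anatomical_structure",
                    range = "fma:Anatomical_structure"),
      property_decl("hco:part", transitive = TRUE,
                    domain = "fma:Anatomical_structure",
                    range = "fma:Anatomical_structure"),
      property_decl("fma:regional_part", inverse = "fma:regional_part_of",
                    super_properties = "hco:part"),
      property_decl("fma:regional_part_of", inverse = "fma:regional_part",
                    super_properties = "hco:part_of"),
      property_decl("fma:constitutional_part", inverse = "fma:constitutional_part_of",
                    super_properties = "hco:part"),
      property_decl("fma:constitutional_part_of", inverse = "fma:constitutional_part",
                    super_properties = "hco:part_of"),
      property_decl("fma:attributed_continuous_with")
    ),
    subclass_axioms = list(
      list(lhs = "hco:Gray_matter_part",
           rhs = ce_named("fma:Region_of_cell_part_cluster_of_neuraxis")),
      list(lhs = "hco:White_matter_part",
           rhs = ce_named("fma:Region_of_cell_part_cluster_of_neuraxis")),
      list(lhs = "hco:MR_Node", rhs = ce_named("hco:Gray_matter_part")),
      list(lhs = "hco:MR_Route", rhs = ce_named("hco:White_matter_part"))
    ),
    equivalence_axioms = list(
      list(lhs = "hco:Gray_matter_part",
           rhs = ce_and(ce_named("fma:Gray_matter_of_neuraxis"), part_disjunction)),
      list(lhs = "hco:White_matter_part",
           rhs = ce_and(ce_named("fma:White_matter_of_neuraxis"), part_disjunction)),
      list(lhs = "hco:MR_Node",
           rhs = ce_and(ce_named("hco:Gray_matter_part"),
                        ce_some("hco:is_tracto_connected", ce_named("hco:MR_Route")))),
      list(lhs = "hco:MR_Route",
           rhs = ce_and(ce_named("hco:White_matter_part"),
                        ce_some("hco:tracto_connects", ce_named("hco:MR_Node"))))
    ),
    chain_axioms = list(
      c("hco:is_tracto_connected", "hco:tracto_connects", "hco:mr_connection")
    )
  )
}
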