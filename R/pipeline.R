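#' Reference TBox for the synthetic cohort
#'
#' Convenience wrapper chaining the standard steps: generate the mini
#' anatomy fixture, extract the gross-anatomy view from the mapped seed
#' terms (excluding the whole-body hub), translate the view into DL class
#' axioms, and merge the result with the connectomics schema. The kept
#' part-of properties are declared with the schema's characteristics
#' (inverses, umbrella super-properties) so the merge is conflict-free.
#'
#' @param mini an \code{hco_mini_fma} (default: freshly generated).
#' @return an \code{hco_tbox} in which all competency-query terms resolve.
#' @export
build_reference_tbox <- function(mini = generate_mini_fma()) {
  schema <- build_hco_schema()
  view <- extract_view(mini$graph, extraction_config(
    seeds = mini$manifest$seed_terms,
    exclusions = "fma:Human_body"))
  keep <- c("fma:regional_part", "fma:constitutional_part",
            "fma:regional_part_of", "fma:constitutional_part_of",
            "fma:attributed_continuous_with")
  decls <- unname(schema$properties[c(keep, "hco:part_of", "hco:part")])
  tr <- translate_frame_to_dl(view, translation_config(
    keep_properties = keep, properties = decls))
  # the umbrella properties' declared domain/range must resolve in the
  # translated TBox as well
  tb <- tr$tbox
  tb <- tbox(classes = c(tb$classes, "fma:Anatomical_structure"),
             properties = tb$properties,
             subclass_axioms = tb$subclass_axioms,
             equivalence_axioms = tb$equivalence_axioms,
             chain_axioms = tb$chain_axioms)
  merge_tbox(tb, schema)
}

#' Annotate and saturate one subject bundle
#'
#' Binarizes the bundle's region matrices, annotates them into an ABox and
#' saturates the resulting knowledge base.
#'
#' @param bundle an \code{hco_subject_bundle} from [generate_cohort()].
#' @param tbox reference TBox (see [build_reference_tbox()]).
#' @param config an [annotation_config()].
#' @return an \code{hco_saturated_kb}.
#' @export
saturate_subject <- function(bundle, tbox, config = annotation_config()) {
  bins <- lapply(bundle$matrices, binarize_matrix, config = config)
  ab <- annotate_subject(bundle$parcellation, bundle$adjacency, bins, tbox,
                         config)
  saturate(kb(tbox, ab))
}

#' Extract parcel ids from query answers
#'
#' Cortical parcel individuals follow the naming convention
#' \code{<subject>_gray_matter_of_<region>_<id>}; this helper pulls the
#' trailing numeric ids back out of an answer set, dropping answers that are
#' not parcel individuals (routes, bundles, regions).
#'
#' @param answers character vector of individual names (or an
#'   \code{hco_query_result}).
#' @return sorted integer vector of parcel ids.
#' @export
answer_parcel_ids <- function(answers) {
  if (inherits(answers, "hco_query_result")) answers <- answers$answers
  hit <- grepl("_gray_matter_of_.*_[0-9]+$", answers)
  sort(as.integer(sub("^.*_", "", answers[hit])))
}

#' Run the four competency queries over a cohort
#'
#' @param saturated list of \code{hco_saturated_kb}, one per subject.
#' @return data.frame with columns \code{subject_id}, \code{query},
#'   \code{answers} (list column of sorted individual names).
#' @export
query_cohort <- function(saturated) {
  rows <- list()
  for (s in saturated) {
    subjects <- unique(sub("^hco:(s[0-9]+)_.*$", "\\1",
                           grep("^hco:s[0-9]+_", s$kb$abox$individuals,
                                value = TRUE)))
    subj <- if (length(subjects) == 1) subjects else paste(subjects, collapse = "+")
    for (n in 1:4) {
      res <- answer_query(competency_query(n), s)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj, query = n,
        answers = I(list(res$answers)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
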