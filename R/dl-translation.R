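#' Configure the frame-to-DL translation
#'
#' @param keep_properties entity-level predicates translated into class-level
#'   existential restrictions.
#' @param properties list of [property_decl()] objects declared in the output
#'   TBox; must cover \code{keep_properties}. Defaults to plain declarations
#'   of the kept properties.
#' @return a list of class \code{hco_translation_config}.
#' @export
translation_config <- function(keep_properties = c("fma:regional_part",
                                                   "fma:constitutional_part",
                                                   "fma:regional_part_of",
                                                   "fma:constitutional_part_of",
                                                   "fma:attributed_continuous_with"),
                               properties = NULL) {
  keep_properties <- as_term(unique(keep_properties))
  if (is.null(properties)) {
    properties <- lapply(keep_properties, property_decl)
  }
  pnames <- vapply(properties, function(p) p$name, "")
  miss <- setdiff(keep_properties, pnames)
  if (length(miss) > 0)
    stop("keep_properties not covered by declarations: ",
         paste(miss, collapse = ", "))
  structure(list(keep_properties = keep_properties, properties = properties),
            class = "hco_translation_config")
}

#' Translate a frame-style view into a DL TBox
#'
#' Converts a view in which part-whole and adjacency relations are stored as
#' entity-level triples (each entity doubling as class and individual) into
#' a pure class-level TBox: every entity becomes a declared named class,
#' every subsumption triple becomes a named subclass axiom, and every triple
#' \code{(A, p, B)} over a kept property becomes the existential axiom
#' \code{A SubClassOf (p some B)}. Inverse assertions are not duplicated --
#' one stored triple yields one existential axiom; class-level inverse
#' consequences are left to the saturation engine. No individuals are
#' emitted, so no punning remains.
#'
#' Triples whose predicate is neither subsumption nor kept are dropped and
#' counted, not fatal: the source ontology carries many relation types that
#' a gross-anatomy module deliberately discards.
#'
#' @param view an \code{hco_frame_graph}.
#' @param config a [translation_config()].
#' @return a list with \code{tbox} (the translated \code{hco_tbox}) and
#'   \code{report}, a data.frame of dropped triples.
#' @export
translate_frame_to_dl <- function(view, config = translation_config()) {
  stopifnot(inherits(view, "hco_frame_graph"),
            inherits(config, "hco_translation_config"))
  validate_frame_graph(view)
  tr <- view$triples
  is_sub <- tr$predicate == .subsumption_predicate
  is_kept <- tr$predicate %in% config$keep_properties
  dropped <- tr[!is_sub & !is_kept, , drop = FALSE]
  rownames(dropped) <- NULL

  subs <- tr[is_sub, , drop = FALSE]
  kept <- tr[is_kept, , drop = FALSE]
  subclass_axioms <- c(
    lapply(seq_len(nrow(subs)), function(i)
      list(lhs = subs$subject[i], rhs = ce_named(subs$object[i]))),
    lapply(seq_len(nrow(kept)), function(i)
      list(lhs = kept$subject[i],
           rhs = ce_some(kept$predicate[i], ce_named(kept$object[i]))))
  )
  tb <- tbox(classes = view$entities,
             properties = config$properties,
             subclass_axioms = subclass_axioms)
  list(tbox = tb, report = dropped)
}
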