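#' Configure a partonomy view extraction
#'
#' Controls [extract_view()]. The defaults mirror the procedure used to carve
#' a gross-anatomy view out of the full anatomy ontology: start from the
#' mapped, most specific terms (the seeds), walk the part-of partonomy
#' upward (entity to its whole) along \code{fma:regional_part_of} and
#' \code{fma:constitutional_part_of}, bring in nearest-neighbor partners
#' related by \code{fma:attributed_continuous_with}, close under
#' subsumption, then discard metaclasses and out-of-domain hubs such as
#' \code{fma:Human_body}.
#'
#' @param seeds character vector of seed entity terms.
#' @param follow_properties properties whose triples are followed
#'   transitively from subject to object.
#' @param lateral_properties properties treated as lateral (neighborhood)
#'   links rather than partonomy steps.
#' @param lateral_policy \code{"one_step"} admits the partner entity of any
#'   lateral triple touching the view (once, then the partonomy closure is
#'   re-run from the newcomers); \code{"closed"} keeps only lateral triples
#'   whose both ends are already in the view.
#' @param exclusions entities removed (with their incident triples) after
#'   closure, e.g. \code{"fma:Human_body"}.
#' @param keep_properties predicates retained in the output besides
#'   subsumption and lateral links.
#' @param superclass_closure include all subsumers of view entities.
#' @return a list of class \code{hco_extraction_config}.
#' @export
extraction_config <- function(seeds = character(),
                              follow_properties = c("fma:regional_part_of",
                                                    "fma:constitutional_part_of"),
                              lateral_properties = "fma:attributed_continuous_with",
                              lateral_policy = c("one_step", "closed"),
                              exclusions = character(),
                              keep_properties = c("fma:regional_part",
                                                  "fma:constitutional_part",
                                                  "fma:regional_part_of",
                                                  "fma:constitutional_part_of",
                                                  "fma:attributed_continuous_with"),
                              superclass_closure = TRUE) {
  lateral_policy <- match.arg(lateral_policy)
  structure(list(
    seeds = as_term(unique(seeds)),
    follow_properties = as_term(unique(follow_properties)),
    lateral_properties = as_term(unique(lateral_properties)),
    lateral_policy = lateral_policy,
    exclusions = if (length(exclusions)) as_term(unique(exclusions)) else character(),
    keep_properties = as_term(unique(keep_properties)),
    superclass_closure = isTRUE(superclass_closure)
  ), class = "hco_extraction_config")
}

# transitive closure of `included` over subject->object edges of `edges`
.close_over <- function(included, edges) {
  repeat {
    add <- setdiff(edges$object[edges$subject %in% included], included)
    if (length(add) == 0) break
    included <- c(included, add)
  }
  included
}

#' Extract a partonomy view from a frame graph
#'
#' Computes the subgraph reachable from the seeds, in order: (1) seeds;
#' (2) transitive closure along the follow properties (entity to whole);
#' (3) lateral expansion per the configured policy, with the partonomy
#' closure re-run from newly admitted entities; (4) subsumption closure
#' (all subsumers, transitively); (5) removal of metaclass-flagged and
#' excluded entities together with their incident triples; (6) restriction
#' of the triples to subsumption edges, kept properties and lateral
#' properties. Exclusions are applied after closure so an excluded hub does
#' not truncate the traversal prematurely. Deterministic throughout.
#'
#' @param graph an \code{hco_frame_graph}.
#' @param config an [extraction_config()].
#' @return the view as an \code{hco_frame_graph} (metaclass flags of
#'   surviving entities are carried over).
#' @export
extract_view <- function(graph, config) {
  stopifnot(inherits(graph, "hco_frame_graph"),
            inherits(config, "hco_extraction_config"))
  unknown <- setdiff(config$seeds, graph$entities)
  if (length(unknown) > 0)
    stop("unknown seed term(s): ", paste(unknown, collapse = ", "))
  if (length(config$seeds) == 0) {
    return(frame_graph())
  }
  tr <- graph$triples
  follow <- tr[tr$predicate %in% config$follow_properties, , drop = FALSE]
  sub_edges <- tr[tr$predicate == .subsumption_predicate, , drop = FALSE]

  # (1)+(2) seeds and partonomy closure
  included <- .close_over(config$seeds, follow)

  # (3) lateral expansion
  lat <- tr[tr$predicate %in% config$lateral_properties, , drop = FALSE]
  if (config$lateral_policy == "one_step" && nrow(lat) > 0) {
    touching <- unique(c(lat$object[lat$subject %in% included],
                         lat$subject[lat$object %in% included]))
    newcomers <- setdiff(touching, included)
    if (length(newcomers) > 0)
      included <- .close_over(c(included, newcomers), follow)
  }

  # (4) subsumption closure
  if (config$superclass_closure)
    included <- .close_over(included, sub_edges)

  # (5) drop metaclasses and exclusions with incident triples
  dropped <- union(intersect(graph$metaclasses, included), config$exclusions)
  included <- setdiff(included, dropped)

  # (6) restrict triples
  keep_pred <- unique(c(.subsumption_predicate, config$keep_properties,
                        config$lateral_properties))
  out <- tr[tr$predicate %in% keep_pred &
              tr$subject %in% included & tr$object %in% included, , drop = FALSE]
  frame_graph(entities = included, triples = out,
              metaclasses = intersect(graph$metaclasses, included))
}
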