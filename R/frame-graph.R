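#' Frame-style ontology graphs
#'
#' The source anatomy ontology is frame-style (OWL Full punning): each entity
#' is simultaneously a class and an individual, and part-whole relations are
#' stored as plain triples between entities. A frame graph is the input to
#' [extract_view()] and [translate_frame_to_dl()]. Subsumption edges use the
#' distinguished predicate \code{rdfs:subClassOf}; entities known to be
#' metaclasses (template machinery of the source ontology, not anatomy) are
#' flagged so view extraction can discard them.
#'
#' @param entities character vector of entity term names.
#' @param triples data.frame with columns \code{subject}, \code{predicate},
#'   \code{object}; endpoints must be declared entities.
#' @param metaclasses character vector of entities flagged as metaclasses.
#' @param validate check invariants (default TRUE).
#' @return an object of class \code{hco_frame_graph}.
#' @export
frame_graph <- function(entities = character(),
                        triples = data.frame(subject = character(),
                                             predicate = character(),
                                             object = character()),
                        metaclasses = character(),
                        validate = TRUE) {
  triples <- unique(data.frame(subject = as.character(triples$subject),
                               predicate = as.character(triples$predicate),
                               object = as.character(triples$object),
                               stringsAsFactors = FALSE))
  triples <- triples[order(triples$subject, triples$predicate, triples$object), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  g <- structure(list(entities = sort(unique(as_term(entities))),
                      triples = triples,
                      metaclasses = sort(unique(as.character(metaclasses)))),
                 class = "hco_frame_graph")
  if (validate) validate_frame_graph(g)
  g
}

#' @rdname frame_graph
#' @param g an \code{hco_frame_graph}.
#' @export
validate_frame_graph <- function(g) {
  miss <- setdiff(unique(c(g$triples$subject, g$triples$object)), g$entities)
  if (length(miss) > 0)
    stop("triple endpoint(s) not declared as entities: ",
         paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(g$metaclasses, g$entities)
  if (length(miss) > 0)
    stop("metaclass flag on unknown entity: ", paste(miss, collapse = ", "))
  invisible(g)
}

#' @export
print.hco_frame_graph <- function(x, ...) {
  cat("<frame graph> ", length(x$entities), " entities, ", nrow(x$triples),
      " triples, ", length(x$metaclasses), " metaclass(es)\n", sep = "")
  invisible(x)
}

# predicate used for subsumption edges inside frame graphs
.subsumption_predicate <- "rdfs:subClassOf"

#' Compare two frame graphs
#'
#' Symmetric difference of entity sets and triple sets, in deterministic
#' (lexicographic) order. Useful for inspecting the effect of different
#' extraction configurations.
#'
#' @param a,b frame graphs.
#' @return a list with \code{entities_only_a}, \code{entities_only_b},
#'   \code{triples_only_a}, \code{triples_only_b} and a logical
#'   \code{identical}.
#' @export
diff_views <- function(a, b) {
  tk <- function(tr) paste(tr$subject, tr$predicate, tr$object)
  ta <- tk(a$triples); tb <- tk(b$triples)
  res <- list(
    entities_only_a = sort(setdiff(a$entities, b$entities)),
    entities_only_b = sort(setdiff(b$entities, a$entities)),
    triples_only_a = a$triples[ta %in% setdiff(ta, tb), , drop = FALSE],
    triples_only_b = b$triples[tb %in% setdiff(tb, ta), , drop = FALSE]
  )
  res$identical <- length(res$entities_only_a) == 0 &&
    length(res$entities_only_b) == 0 &&
    nrow(res$triples_only_a) == 0 && nrow(res$triples_only_b) == 0
  res
}
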