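#' Object property declarations
#'
#' Declares an object property with the characteristics the saturation engine
#' understands: an optional inverse, transitivity, symmetry, super-properties
#' and an optional domain/range annotation. A symmetric property is its own
#' inverse; inverse pairing must be mutual at the TBox level.
#'
#' @param name property term name.
#' @param inverse optional inverse property term name.
#' @param transitive,symmetric logical flags.
#' @param super_properties character vector of super-property term names.
#' @param domain,range optional class term names (annotations only; not used
#'   for type inference).
#' @return an object of class \code{hco_property}.
#' @export
property_decl <- function(name, inverse = NULL, transitive = FALSE,
                          symmetric = FALSE, super_properties = character(),
                          domain = NULL, range = NULL) {
  if (symmetric) inverse <- as_term(name)
  structure(list(
    name = as_term(name),
    inverse = if (!is.null(inverse)) as_term(inverse),
    transitive = isTRUE(transitive),
    symmetric = isTRUE(symmetric),
    super_properties = sort(unique(as_term(super_properties))),
    domain = if (!is.null(domain)) as_term(domain),
    range = if (!is.null(range)) as_term(range)
  ), class = "hco_property")
}

.axiom_key <- function(ax) paste0(ax$lhs, " :: ", ce_to_string(ce_canonical(ax$rhs)))

.dedup_axioms <- function(axs) {
  if (length(axs) == 0) return(list())
  keys <- vapply(axs, .axiom_key, "")
  axs[!duplicated(keys)][order(unique(keys))]
}

.dedup_chains <- function(chains) {
  if (length(chains) == 0) return(list())
  keys <- vapply(chains, paste, "", collapse = " ")
  chains[!duplicated(keys)][order(unique(keys))]
}

#' Terminological box (TBox)
#'
#' Container for class declarations, property declarations, subclass and
#' equivalence axioms (named left-hand side, class-expression right-hand
#' side) and role-chain axioms \code{p o q -> r}.
#'
#' @param classes character vector of class term names.
#' @param properties list of [property_decl()] objects.
#' @param subclass_axioms,equivalence_axioms lists of
#'   \code{list(lhs = term, rhs = expression)}.
#' @param chain_axioms list of length-3 character vectors \code{c(p, q, r)}
#'   meaning \code{p o q} is a sub-property of \code{r}.
#' @param validate check referential integrity (default TRUE).
#' @return an object of class \code{hco_tbox}.
#' @seealso [build_hco_schema()], [merge_tbox()]
#' @export
tbox <- function(classes = character(), properties = list(),
                 subclass_axioms = list(), equivalence_axioms = list(),
                 chain_axioms = list(), validate = TRUE) {
  pnames <- vapply(properties, function(p) p$name, "")
  if (anyDuplicated(pnames)) stop("duplicate property declarations")
  props <- properties[order(pnames)]
  names(props) <- sort(pnames)
  tb <- structure(list(
    classes = sort(unique(as_term(classes))),
    properties = props,
    subclass_axioms = .dedup_axioms(subclass_axioms),
    equivalence_axioms = .dedup_axioms(equivalence_axioms),
    chain_axioms = .dedup_chains(chain_axioms)
  ), class = "hco_tbox")
  if (validate) validate_tbox(tb)
  tb
}

#' Validate a TBox
#'
#' Checks referential integrity (every term used in an axiom is declared),
#' mutual inverse pairing, symmetric-own-inverse consistency and acyclicity
#' of the super-property graph. Errors on the first violation.
#'
#' @param tb an \code{hco_tbox}.
#' @return the TBox, invisibly.
#' @export
validate_tbox <- function(tb) {
  pnames <- names(tb$properties)
  for (p in tb$properties) {
    if (!is.null(p$inverse)) {
      if (!p$inverse %in% pnames)
        stop("inverse of ", p$name, " not declared: ", p$inverse)
      q <- tb$properties[[p$inverse]]
      if (is.null(q$inverse) || q$inverse != p$name)
        stop("inverse pairing not mutual for ", p$name, " / ", p$inverse)
    }
    if (p$symmetric && (is.null(p$inverse) || p$inverse != p$name))
      stop("symmetric property must be its own inverse: ", p$name)
    miss <- setdiff(p$super_properties, pnames)
    if (length(miss) > 0)
      stop("undeclared super-property of ", p$name, ": ", paste(miss, collapse = ", "))
    for (t in c(p$domain, p$range)) {
      if (!is.null(t) && !t %in% tb$classes)
        stop("undeclared domain/range class of ", p$name, ": ", t)
    }
  }
  # super-property graph must be acyclic
  edges <- do.call(rbind, lapply(tb$properties, function(p) {
    if (length(p$super_properties) == 0) return(NULL)
    cbind(p$name, p$super_properties)
  }))
  if (!is.null(edges)) {
    visiting <- character(); done <- character()
    visit <- function(v) {
      if (v %in% done) return(invisible())
      if (v %in% visiting) stop("cycle in super-property graph at ", v)
      visiting <<- c(visiting, v)
      for (w in edges[edges[, 1] == v, 2]) visit(w)
      visiting <<- setdiff(visiting, v)
      done <<- c(done, v)
    }
    for (v in unique(edges[, 1])) visit(v)
  }
  check_axiom <- function(ax, kind) {
    if (!ax$lhs %in% tb$classes)
      stop("undeclared class on left of ", kind, " axiom: ", ax$lhs)
    miss_c <- setdiff(ce_class_terms(ax$rhs), tb$classes)
    if (length(miss_c) > 0)
      stop("undeclared class in ", kind, " axiom for ", ax$lhs, ": ",
           paste(miss_c, collapse = ", "))
    miss_p <- setdiff(ce_property_terms(ax$rhs), pnames)
    if (length(miss_p) > 0)
      stop("undeclared property in ", kind, " axiom for ", ax$lhs, ": ",
           paste(miss_p, collapse = ", "))
  }
  for (ax in tb$subclass_axioms) check_axiom(ax, "subclass")
  for (ax in tb$equivalence_axioms) check_axiom(ax, "equivalence")
  for (ch in tb$chain_axioms) {
    miss <- setdiff(ch, pnames)
    if (length(miss) > 0)
      stop("undeclared property in chain axiom: ", paste(miss, collapse = ", "))
  }
  invisible(tb)
}

#' Assertional box (ABox)
#'
#' Individuals with class-membership (type) assertions and object-property
#' (role) assertions. Referential integrity against a paired TBox is checked
#' by [validate_kb()].
#'
#' @param individuals character vector of individual term names.
#' @param types data.frame with columns \code{individual}, \code{class}.
#' @param roles data.frame with columns \code{property}, \code{subject},
#'   \code{object}.
#' @return an object of class \code{hco_abox}.
#' @export
abox <- function(individuals = character(),
                 types = data.frame(individual = character(), class = character()),
                 roles = data.frame(property = character(), subject = character(),
                                    object = character())) {
  types <- unique(data.frame(individual = as.character(types$individual),
                             class = as.character(types$class),
                             stringsAsFactors = FALSE))
  roles <- unique(data.frame(property = as.character(roles$property),
                             subject = as.character(roles$subject),
                             object = as.character(roles$object),
                             stringsAsFactors = FALSE))
  types <- types[order(types$individual, types$class), , drop = FALSE]
  roles <- roles[order(roles$property, roles$subject, roles$object), , drop = FALSE]
  rownames(types) <- NULL; rownames(roles) <- NULL
  structure(list(individuals = sort(unique(as_term(individuals))),
                 types = types, roles = roles),
            class = "hco_abox")
}

#' Knowledge base
#'
#' A TBox/ABox pair; the unit everything downstream reads and writes.
#'
#' @param tbox an \code{hco_tbox}.
#' @param abox an \code{hco_abox}.
#' @param validate check ABox referential integrity against the TBox.
#' @return an object of class \code{hco_kb}.
#' @export
kb <- function(tbox, abox = NULL, validate = TRUE) {
  if (is.null(abox)) abox <- structure(list(
    individuals = character(),
    types = data.frame(individual = character(), class = character(),
                       stringsAsFactors = FALSE),
    roles = data.frame(property = character(), subject = character(),
                       object = character(), stringsAsFactors = FALSE)),
    class = "hco_abox")
  k <- structure(list(tbox = tbox, abox = abox), class = "hco_kb")
  if (validate) validate_kb(k)
  k
}

#' @rdname kb
#' @param x an \code{hco_kb}.
#' @export
validate_kb <- function(x) {
  validate_tbox(x$tbox)
  ab <- x$abox
  miss <- setdiff(unique(c(ab$types$individual, ab$roles$subject, ab$roles$object)),
                  ab$individuals)
  if (length(miss) > 0)
    stop("undeclared individual(s): ", paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(unique(ab$types$class), x$tbox$classes)
  if (length(miss) > 0)
    stop("type assertion uses undeclared class(es): ",
         paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(unique(ab$roles$property), names(x$tbox$properties))
  if (length(miss) > 0)
    stop("role assertion uses undeclared property(ies): ",
         paste(utils::head(miss, 5), collapse = ", "))
  invisible(x)
}

#' @export
print.hco_tbox <- function(x, ...) {
  cat("<TBox> ", length(x$classes), " classes, ", length(x$properties),
      " object properties, ", length(x$subclass_axioms), " subclass axioms, ",
      length(x$equivalence_axioms), " equivalence axioms, ",
      length(x$chain_axioms), " chain axioms\n", sep = "")
  invisible(x)
}

#' @export
print.hco_abox <- function(x, ...) {
  cat("<ABox> ", length(x$individuals), " individuals, ",
      nrow(x$types), " type assertions, ", nrow(x$roles),
      " role assertions\n", sep = "")
  invisible(x)
}

#' @export
print.hco_kb <- function(x, ...) {
  print(x$tbox); print(x$abox); invisible(x)
}

.prop_equal <- function(p, q) {
  identical(p$name, q$name) &&
    identical(p$inverse, q$inverse) &&
    identical(p$transitive, q$transitive) &&
    identical(p$symmetric, q$symmetric) &&
    identical(p$super_properties, q$super_properties) &&
    identical(p$domain, q$domain) &&
    identical(p$range, q$range)
}

#' Merge two TBoxes
#'
#' Union of declarations and axioms. Idempotent and commutative up to
#' serialization order. A property redeclared with different characteristics
#' is a conflict and errors, naming the clashing term.
#'
#' @param base,extension TBoxes to merge.
#' @return the merged \code{hco_tbox}.
#' @export
merge_tbox <- function(base, extension) {
  props <- base$properties
  for (p in extension$properties) {
    if (p$name %in% names(props)) {
      if (!.prop_equal(props[[p$name]], p))
        stop("conflicting redeclaration of property ", p$name)
    } else {
      props[[p$name]] <- p
    }
  }
  tbox(classes = c(base$classes, extension$classes),
       properties = unname(props),
       subclass_axioms = c(base$subclass_axioms, extension$subclass_axioms),
       equivalence_axioms = c(base$equivalence_axioms, extension$equivalence_axioms),
       chain_axioms = c(base$chain_axioms, extension$chain_axioms))
}
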