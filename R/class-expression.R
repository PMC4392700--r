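#' Class expressions
#'
#' A class expression is a finite tree over named classes, conjunctions,
#' disjunctions and existential restrictions -- the fragment used both on the
#' right-hand side of schema axioms (e.g. the MR_Node definition
#' \code{Gray_matter_part and (is_tracto_connected some MR_Route)}) and as
#' queries. Conjunction and disjunction lists must have at least two
#' children; structural equality is order-insensitive for their children
#' (a canonical form sorts children by serialization).
#'
#' @param term a prefixed class term name.
#' @return an object of class \code{hco_expr}.
#' @examples
#' ce_and(ce_named("hco:Gray_matter_part"),
#'        ce_some("hco:is_tracto_connected", ce_named("hco:MR_Route")))
#' @export
ce_named <- function(term) {
  structure(list(variant = "named", term = as_term(term)), class = "hco_expr")
}

.ce_nary <- function(variant, args) {
  args <- lapply(args, function(e) {
    if (!inherits(e, "hco_expr")) stop("children must be class expressions")
    e
  })
  if (length(args) < 2) stop(variant, " requires at least 2 children")
  structure(list(variant = variant, children = args), class = "hco_expr")
}

#' @rdname ce_named
#' @param ... two or more child expressions (or a single list of them).
#' @export
ce_and <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !inherits(args[[1]], "hco_expr")) {
    args <- args[[1]]
  }
  .ce_nary("and", args)
}

#' @rdname ce_named
#' @export
ce_or <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !inherits(args[[1]], "hco_expr")) {
    args <- args[[1]]
  }
  .ce_nary("or", args)
}

#' @rdname ce_named
#' @param property object-property term name.
#' @param filler filler class expression.
#' @export
ce_some <- function(property, filler) {
  if (!inherits(filler, "hco_expr")) stop("filler must be a class expression")
  structure(list(variant = "some", property = as_term(property), filler = filler),
            class = "hco_expr")
}

#' Serialize, canonicalize and compare class expressions
#'
#' `ce_to_string()` prints an expression in Manchester-like syntax with full
#' parenthesization. `ce_canonical()` sorts and/or children recursively by
#' their serialization, giving a normal form under which `ce_equal()` is
#' order-insensitive structural equality.
#'
#' @param x a class expression.
#' @return a character scalar (`ce_to_string`), an expression
#'   (`ce_canonical`), or a logical (`ce_equal`).
#' @export
ce_to_string <- function(x) {
  stopifnot(inherits(x, "hco_expr"))
  switch(x$variant,
    named = x$term,
    some  = paste0("(", x$property, " some ", ce_to_string(x$filler), ")"),
    and   = paste0("(", paste(vapply(x$children, ce_to_string, ""), collapse = " and "), ")"),
    or    = paste0("(", paste(vapply(x$children, ce_to_string, ""), collapse = " or "), ")")
  )
}

#' @rdname ce_to_string
#' @export
ce_canonical <- function(x) {
  stopifnot(inherits(x, "hco_expr"))
  switch(x$variant,
    named = x,
    some  = ce_some(x$property, ce_canonical(x$filler)),
    {
      kids <- lapply(x$children, ce_canonical)
      kids <- kids[order(vapply(kids, ce_to_string, ""))]
      .ce_nary(x$variant, kids)
    }
  )
}

#' @rdname ce_to_string
#' @param y a second class expression.
#' @export
ce_equal <- function(x, y) {
  identical(ce_to_string(ce_canonical(x)), ce_to_string(ce_canonical(y)))
}

#' @export
print.hco_expr <- function(x, ...) {
  cat("<class expression> ", ce_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.hco_expr <- function(x, ...) ce_to_string(x)

# All named-class terms / property terms referenced in an expression.
ce_class_terms <- function(x) {
  switch(x$variant,
    named = x$term,
    some  = ce_class_terms(x$filler),
    unique(unlist(lapply(x$children, ce_class_terms)))
  )
}

ce_property_terms <- function(x) {
  switch(x$variant,
    named = character(),
    some  = unique(c(x$property, ce_property_terms(x$filler))),
    unique(unlist(lapply(x$children, ce_property_terms)))
  )
}

# Flat list encoding used by the canonical JSON format.
ce_to_list <- function(x) {
  switch(x$variant,
    named = list(named = x$term),
    some  = list(some = list(property = x$property, filler = ce_to_list(x$filler))),
    and   = list(and = lapply(x$children, ce_to_list)),
    or    = list(or = lapply(x$children, ce_to_list))
  )
}

ce_from_list <- function(l) {
  if (!is.list(l) || length(l) != 1) stop("malformed expression encoding")
  key <- names(l)
  switch(key,
    named = ce_named(l$named),
    some  = ce_some(l$some$property, ce_from_list(l$some$filler)),
    and   = ce_and(lapply(l$and, ce_from_list)),
    or    = ce_or(lapply(l$or, ce_from_list)),
    stop("unknown expression variant: ", key)
  )
}
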