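#' Prefixed term names
#'
#' Every entity in the toolkit -- classes, object properties, individuals --
#' is identified by a prefixed term name of the form \code{"ns:Local_name"}.
#' Domain terms live in one of three namespaces: \code{fma} (source anatomy
#' ontology concepts), \code{hco} (connectomics schema terms and per-subject
#' individuals) and \code{data} (ad-hoc dataset terms). The RDF layer
#' additionally uses \code{rdf}, \code{rdfs} and \code{owl} for vocabulary
#' predicates.
#'
#' @param x character vector of prefixed names.
#' @return `as_term()` returns the validated character vector.
#' @examples
#' as_term("fma:Right_precentral_gyrus")
#' term_namespace("hco:MR_Node")
#' term_local("hco:MR_Node")
#' @export
as_term <- function(x) {
  if (!is.character(x)) stop("term names must be character")
  bad <- x[!is_term(x)]
  if (length(bad) > 0) {
    stop("invalid term name(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  x
}

.term_namespaces <- c("fma", "hco", "data", "rdf", "rdfs", "owl")

#' @rdname as_term
#' @export
is_term <- function(x) {
  grepl(paste0("^(", paste(.term_namespaces, collapse = "|"), "):[^[:space:]:]+$"), x)
}

#' @rdname as_term
#' @export
term_namespace <- function(x) sub(":.*$", "", as_term(x))

#' @rdname as_term
#' @export
term_local <- function(x) sub("^[^:]+:", "", as_term(x))

#' @rdname as_term
#' @param namespace namespace prefix, one of \code{fma}, \code{hco}, \code{data}.
#' @param name local name (no whitespace, no colon).
#' @export
make_term <- function(namespace, name) {
  as_term(paste0(namespace, ":", name))
}

fma <- function(name) make_term("fma", name)
hco_term <- function(name) make_term("hco", name)
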