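#' Parse a Manchester-like class-expression query
#'
#' Grammar: \code{expr := or_expr}; \code{or_expr := and_expr ('or'
#' and_expr)*}; \code{and_expr := atom ('and' atom)*}; \code{atom := IDENT |
#' IDENT 'some' atom | '(' expr ')'}. Precedence \code{some > and > or};
#' \code{some} is right-associative over atoms, so \code{p some q some C}
#' parses as \code{p some (q some C)}. Identifiers may be written without a
#' namespace prefix; they are then resolved against the supplied vocabulary,
#' \code{hco} first, then \code{fma} (an identifier present in both is an
#' ambiguity error). Without a vocabulary, all identifiers must be prefixed.
#'
#' @param text query string.
#' @param tbox optional \code{hco_tbox} used to resolve unprefixed names.
#' @return a class expression ([ce_named()] tree); `parse_query(ce_to_string(x))`
#'   reproduces `x`.
#' @examples
#' parse_query("hco:part_of some fma:Right_temporal_lobe")
#' @export
parse_query <- function(text, tbox = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- .tokenize_query(text)
  state <- new.env()
  state$toks <- toks
  state$pos <- 1L
  expr <- .parse_or(state, text)
  if (state$pos <= nrow(state$toks)) {
    stop("syntax error at position ", state$toks$start[state$pos],
         ": unexpected '", state$toks$token[state$pos], "'")
  }
  .resolve_expr(expr, tbox)
}

.tokenize_query <- function(text) {
  pat <- "\\(|\\)|[A-Za-z_][A-Za-z0-9_:]*"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(),
                      stringsAsFactors = FALSE))
  }
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # anything outside tokens must be whitespace
  resid <- text
  regmatches(resid, gregexpr(pat, resid)) <- list(rep("", length(toks)))
  stray <- regmatches(resid, regexpr("[^[:space:]]", resid))
  if (length(stray) == 1 && nzchar(stray))
    stop("syntax error: unexpected character '", stray, "'")
  data.frame(token = toks, start = as.integer(m), stringsAsFactors = FALSE)
}

.peek <- function(state) {
  if (state$pos > nrow(state$toks)) NULL else state$toks$token[state$pos]
}

.advance <- function(state) state$pos <- state$pos + 1L

.syntax_error <- function(state, text, expected) {
  at <- if (state$pos > nrow(state$toks)) {
    paste0("end of input (position ", nchar(text) + 1L, ")")
  } else {
    paste0("position ", state$toks$start[state$pos], " ('",
           state$toks$token[state$pos], "')")
  }
  stop("syntax error at ", at, ": expected ", expected)
}

.parse_or <- function(state, text) {
  parts <- list(.parse_and(state, text))
  while (identical(.peek(state), "or")) {
    .advance(state)
    parts[[length(parts) + 1L]] <- .parse_and(state, text)
  }
  if (length(parts) == 1) parts[[1]] else .ce_nary("or", parts)
}

.parse_and <- function(state, text) {
  parts <- list(.parse_atom(state, text))
  while (identical(.peek(state), "and")) {
    .advance(state)
    parts[[length(parts) + 1L]] <- .parse_atom(state, text)
  }
  if (length(parts) == 1) parts[[1]] else .ce_nary("and", parts)
}

.parse_atom <- function(state, text) {
  tok <- .peek(state)
  if (is.null(tok)) .syntax_error(state, text, "an identifier or '('")
  if (tok == "(") {
    .advance(state)
    inner <- .parse_or(state, text)
    if (!identical(.peek(state), ")")) .syntax_error(state, text, "')'")
    .advance(state)
    return(inner)
  }
  if (tok %in% c(")", "and", "or", "some"))
    .syntax_error(state, text, "an identifier or '('")
  .advance(state)
  if (identical(.peek(state), "some")) {
    .advance(state)
    filler <- .parse_atom(state, text)
    return(structure(list(variant = "some", property = tok, filler = filler),
                     class = "hco_expr"))
  }
  structure(list(variant = "named", term = tok), class = "hco_expr")
}

.resolve_name <- function(name, kind, tbox) {
  if (grepl(":", name, fixed = TRUE)) return(as_term(name))
  if (is.null(tbox))
    stop("unprefixed name '", name, "' requires a vocabulary (tbox) to resolve")
  vocab <- if (kind == "class") tbox$classes else names(tbox$properties)
  cand <- paste0(c("hco:", "fma:"), name)
  hit <- cand[cand %in% vocab]
  if (length(hit) == 2)
    stop("ambiguous unprefixed name '", name, "': both ", cand[1], " and ",
         cand[2], " exist")
  if (length(hit) == 0)
    stop("unknown ", kind, " name: ", name)
  hit
}

.resolve_expr <- function(expr, tbox) {
  switch(expr$variant,
    named = ce_named(.resolve_name(expr$term, "class", tbox)),
    some  = ce_some(.resolve_name(expr$property, "property", tbox),
                    .resolve_expr(expr$filler, tbox)),
    and   = .ce_nary("and", lapply(expr$children, .resolve_expr, tbox = tbox)),
    or    = .ce_nary("or", lapply(expr$children, .resolve_expr, tbox = tbox))
  )
}

#' Answer a class-expression query against a saturated knowledge base
#'
#' Returns the duplicate-free, lexicographically sorted set of individuals
#' satisfying the expression ([holds()] semantics). A pure function of the
#' expression and the saturated store; answers never shrink when assertions
#' are added.
#'
#' @param expr a class expression, or a query string parsed with the
#'   knowledge base's vocabulary.
#' @param s an \code{hco_saturated_kb}.
#' @return a list of class \code{hco_query_result} with elements
#'   \code{query} (the expression) and \code{answers} (sorted character).
#' @export
answer_query <- function(expr, s) {
  stopifnot(inherits(s, "hco_saturated_kb"))
  if (is.character(expr)) expr <- parse_query(expr, s$kb$tbox)
  stopifnot(inherits(expr, "hco_expr"))
  .check_expr_vocab(expr, s$kb$tbox)
  st <- list(types = list(df = s$types), roles = list(df = s$roles),
             subs = list(df = s$subsumptions),
             cex = list(df = s$class_existentials))
  structure(list(query = expr,
                 answers = sort(unique(.eval_expr_set(expr, st)))),
            class = "hco_query_result")
}

#' @export
print.hco_query_result <- function(x, ...) {
  cat("<query> ", ce_to_string(x$query), "\n", sep = "")
  cat(length(x$answers), " answer(s)\n", sep = "")
  if (length(x$answers) > 0) cat(paste0("  ", x$answers, "\n"), sep = "")
  invisible(x)
}

#' The four medial-BA6 competency queries
#'
#' Ready-made class expressions for the competency questions the schema was
#' designed to answer over the right medial premotor cortex: (1) parts of the
#' right superior frontal gyrus whose connectivity passes through the
#' corticospinal tract or reaches gray matter of the right precentral gyrus
#' (an SMA-like pattern); (2) parts connected to the right medial parietal
#' cortex -- expressed as the conjunction of the parietal-cortex and
#' medial-segment restrictions -- or to the inferior frontal
#' (orbitobasal) cortex (a pre-SMA-like pattern); (3) query 1 widened by
#' connections to gray matter merely contiguous with the precentral gyrus,
#' so its answers always contain query 1's; (4) the white-matter bundles
#' with a route connecting the right superior frontal gyrus to the right
#' temporal lobe.
#'
#' @param n query number, 1 to 4.
#' @return a class expression.
#' @examples
#' ce_to_string(competency_query(1))
#' @export
competency_query <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || !n %in% 1:4)
    stop("competency query number must be 1, 2, 3 or 4")
  rsfg <- ce_some("hco:part_of", ce_named("fma:Right_superior_frontal_gyrus"))
  via_cst <- ce_some("hco:is_tracto_connected",
                     ce_some("hco:part_of",
                             ce_named("fma:Right_corticospinal_tract_of_brain")))
  to_precentral <- ce_some("hco:mr_connection",
                           ce_some("hco:part_of",
                                   ce_named("fma:Right_precentral_gyrus")))
  switch(n,
    ce_and(rsfg, ce_or(via_cst, to_precentral)),
    ce_and(rsfg, ce_or(
      ce_some("hco:mr_connection",
              ce_and(ce_some("hco:part_of",
                             ce_named("fma:Cortex_of_right_parietal_lobe")),
                     ce_some("hco:part_of",
                             ce_named("fma:Medial_segment_of_cerebral_hemisphere")))),
      ce_some("hco:mr_connection",
              ce_some("hco:part_of",
                      ce_named("fma:Orbitobasal_segment_of_right_frontal_lobe"))))),
    ce_and(rsfg, ce_or(via_cst, to_precentral,
      ce_some("hco:mr_connection",
              ce_some("hco:continuous_with",
                      ce_some("hco:part_of",
                              ce_named("fma:Right_precentral_gyrus")))))),
    ce_some("hco:part",
            ce_and(ce_some("hco:tracto_connects",
                           ce_some("hco:part_of",
                                   ce_named("fma:Right_temporal_lobe"))),
                   ce_some("hco:tracto_connects",
                           ce_some("hco:part_of",
                                   ce_named("fma:Right_superior_frontal_gyrus")))))
  )
}
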