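#' Cross-subject term sets and overlap statistics
#'
#' After lifting parcel-level tractography connections to gyrus-level
#' anatomy terms, each subject is described by the set of region terms found
#' connected to the target region. The overlap report counts, for each
#' level k, how many terms of the union are present in at least k subjects.
#' Term comparison is exact string equality on trimmed strings: no case
#' folding and no harmonization of near-duplicate variants, which is the
#' policy consistent with the published percentages.
#'
#' @param sets named list: subject id -> character vector of terms.
#' @return `subject_term_sets()` returns a validated named list of class
#'   \code{hco_term_sets}.
#' @export
subject_term_sets <- function(sets) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stop("term sets must be named by subject id")
  sets <- lapply(sets, function(s) {
    s <- trimws(as.character(s))
    if (any(!nzchar(s))) stop("empty term string")
    sort(unique(s))
  })
  structure(sets, class = "hco_term_sets")
}

#' Load the shipped five-subject connected-term transcription
#'
#' Reads the packaged transcription of the regions found connected to the
#' right medial BA6 by diffusion tractography in five healthy subjects
#' (gyrus-level and other-region terms, verbatim including truncated
#' variants). The file is checksummed against corruption.
#'
#' @param path override the packaged file (mainly for tests).
#' @return an \code{hco_term_sets} with five subjects.
#' @export
load_ba6_term_sets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ba6_connected_terms.tsv", package = "hco")
    if (!nzchar(path)) stop("packaged fixture not found")
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .ba6_fixture_md5))
      stop("fixture corruption: checksum mismatch for ", path)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  subject_term_sets(split(d$term, d$subject_id))
}

# frozen at packaging time; regenerate with tools::md5sum() if the
# transcription is ever corrected
.ba6_fixture_md5 <- "720984be92e97dbeba2074bec66db5e4"

#' Overlap fractions across subjects
#'
#' For each level k, counts the terms of the union present in at least k
#' subjects and reports the percentage of the union, computed at full
#' precision and displayed rounded half-up to one decimal.
#'
#' @param sets an \code{hco_term_sets} (or coercible named list).
#' @param levels integer levels k to report (default all 1..n).
#' @return a list of class \code{hco_overlap_report}: \code{total_terms},
#'   and a data.frame \code{report} with columns \code{k}, \code{count},
#'   \code{fraction} (raw percentage) and \code{fraction_1dp}.
#' @examples
#' overlap_fractions(subject_term_sets(list(a = c("A", "B"), b = c("A", "C"),
#'                                          c = "A")), levels = c(3, 2, 1))
#' @export
overlap_fractions <- function(sets, levels = NULL) {
  if (!inherits(sets, "hco_term_sets")) sets <- subject_term_sets(sets)
  n <- length(sets)
  if (n < 1) stop("at least one subject is required")
  if (is.null(levels)) levels <- seq_len(n)
  if (any(levels < 1 | levels > n)) stop("levels must lie in 1..", n)
  membership <- table(unlist(lapply(sets, unique)))
  total <- length(membership)
  if (total == 0) stop("empty term union: overlap fractions are undefined")
  counts <- vapply(levels, function(k) sum(membership >= k), 0L)
  frac <- 100 * counts / total
  # round half up (not banker's rounding) for display
  disp <- floor(frac * 10 + 0.5) / 10
  structure(list(total_terms = total,
                 report = data.frame(k = as.integer(levels), count = counts,
                                     fraction = frac, fraction_1dp = disp)),
            class = "hco_overlap_report")
}

#' @export
print.hco_overlap_report <- function(x, ...) {
  cat("<overlap report> union of ", x$total_terms, " terms\n", sep = "")
  for (i in seq_len(nrow(x$report)))
    cat(sprintf("  in >= %d subjects: %d terms (%.1f%%)\n",
                x$report$k[i], x$report$count[i], x$report$fraction_1dp[i]))
  invisible(x)
}

#' Derive per-subject connected-term sets from a saturated knowledge base
#'
#' Lifts parcel-level connections to region-level terms: for each subject,
#' collects the region classes of every individual found
#' \code{hco:mr_connection}-related to any individual that is
#' \code{hco:part_of} an individual typed with the target class. A
#' connected individual's region classes are its own asserted anatomy
#' (\code{fma}) types plus, for cortical parcels following the annotation
#' naming convention, the type of the region individual two asserted
#' part-steps up (parcel -> gray-matter-of-region -> region).
#'
#' @param s an \code{hco_saturated_kb} (typically one subject's).
#' @param target_class class term, e.g.
#'   \code{"fma:Right_superior_frontal_gyrus"}.
#' @return an \code{hco_term_sets}, one entry per subject found in the KB.
#' @export
derive_term_sets <- function(s, target_class) {
  stopifnot(inherits(s, "hco_saturated_kb"))
  target_class <- as_term(target_class)
  if (!target_class %in% s$kb$tbox$classes)
    stop("unknown target class: ", target_class)
  ty <- s$types; rl <- s$roles
  asserted <- s$kb$abox$roles
  target_inds <- ty$individual[ty$class == target_class]
  parts <- rl$subject[rl$property == "hco:part_of" & rl$object %in% target_inds]
  conn <- unique(rl$object[rl$property == "hco:mr_connection" &
                             rl$subject %in% parts])
  if (length(conn) == 0) return(subject_term_sets(stats::setNames(list(), character())))
  # asserted types only: derived supertypes (taxonomy categories, schema
  # anchors) are not region terms
  asserted_types <- s$kb$abox$types
  region_terms_of <- function(q) {
    own <- asserted_types$class[asserted_types$individual == q &
                                  grepl("^fma:", asserted_types$class)]
    gm <- asserted$object[asserted$property == "fma:regional_part_of" &
                            asserted$subject == q]
    reg <- asserted$object[asserted$property == "fma:constitutional_part_of" &
                             asserted$subject %in% gm]
    lifted <- asserted_types$class[asserted_types$individual %in% reg &
                                     grepl("^fma:", asserted_types$class)]
    unique(c(own, lifted))
  }
  subj_of <- sub("^hco:(s[0-9]+)_.*$", "\\1", conn)
  sets <- lapply(split(conn, subj_of), function(q)
    sort(unique(unlist(lapply(q, region_terms_of)))))
  subject_term_sets(sets)
}
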