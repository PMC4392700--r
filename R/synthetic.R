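#' Synthetic neuroanatomy and cohorts
#'
#' Everything in the package is exercisable offline: [generate_mini_fma()]
#' builds a small deterministic frame-style anatomy graph with the partonomy
#' chains the competency queries need, and [generate_cohort()] builds a
#' five-subject cohort of parcellations, nearest-neighbor adjacencies and
#' per-seed connectivity matrices with planted SMA-like and pre-SMA-like
#' connectivity patterns whose recovery is provable rather than
#' probabilistic.
#'
#' @name synthetic
NULL

# the 20 anatomically labeled seed tracts (JHU-style naming, bilateral
# stems doubled per hemisphere, the two corpus-callosum forceps unpaired)
hco_tract_labels <- function() {
  stems <- c("anterior_radiation_of_thalamus", "corticospinal_tract_of_brain",
             "anterior_segment_of_cingulum", "inferior_occipitofrontal_fasciculus",
             "inferior_longitudinal_fasciculus", "uncinate_fasciculus",
             "superior_longitudinal_fasciculus", "posterior_segment_of_cingulum",
             "temporal_part_of_superior_longitudinal_fasciculus")
  bilateral <- as.vector(t(outer(c("Right_", "Left_"), stems, paste0)))
  c(paste0("fma:", bilateral),
    "fma:Anterior_forceps_of_corpus_callosum",
    "fma:Posterior_forceps_of_corpus_callosum")
}

# cortical region classes with lobe assignment; mirrored per hemisphere
.region_pool <- function() {
  right <- data.frame(
    term = paste0("fma:Right_", c(
      "superior_frontal_gyrus", "middle_frontal_gyrus", "precentral_gyrus",
      "frontal_pole", "postcentral_gyrus", "precuneus", "supramarginal_gyrus",
      "superior_temporal_gyrus", "middle_temporal_gyrus",
      "inferior_temporal_gyrus", "lateral_occipital_gyrus", "lingual_gyrus")),
    lobe = paste0("fma:Right_", c(
      rep("frontal_lobe", 4), rep("parietal_lobe", 3),
      rep("temporal_lobe", 3), rep("occipital_lobe", 2))),
    hemisphere = "fma:Right_cerebral_hemisphere",
    stringsAsFactors = FALSE)
  left <- right
  left$term <- sub("fma:Right_", "fma:Left_", left$term)
  left$lobe <- sub("fma:Right_", "fma:Left_", left$lobe)
  left$hemisphere <- "fma:Left_cerebral_hemisphere"
  segments <- data.frame(
    term = c("fma:Cortex_of_right_parietal_lobe",
             "fma:Orbitobasal_segment_of_right_frontal_lobe"),
    lobe = c("fma:Medial_segment_of_cerebral_hemisphere",
             "fma:Right_frontal_lobe"),
    hemisphere = "fma:Right_cerebral_hemisphere",
    stringsAsFactors = FALSE)
  rbind(right, left, segments)
}

.extra_region_terms <- function() {
  stems <- c("thalamus", "caudate_nucleus", "putamen", "globus_pallidus",
             "nucleus_accumbens", "amygdala", "hippocampus")
  bilateral <- as.vector(t(outer(c("Right_", "Left_"), stems, paste0)))
  c(paste0("fma:", bilateral), "fma:Brainstem")
}

# partonomy-hint chains for every region / tract / extra-region class
.partonomy_hints <- function() {
  hints <- list()
  pool <- .region_pool()
  for (i in seq_len(nrow(pool))) {
    hints[[pool$term[i]]] <- data.frame(
      property = "fma:regional_part_of",
      ancestor = c(pool$lobe[i], pool$hemisphere[i]),
      stringsAsFactors = FALSE)
  }
  for (t in .extra_region_terms()) {
    anc <- if (t == "fma:Brainstem") "fma:Brain" else
      if (grepl(":Right_", t)) "fma:Right_cerebral_hemisphere" else
        "fma:Left_cerebral_hemisphere"
    hints[[t]] <- data.frame(property = "fma:regional_part_of",
                             ancestor = anc, stringsAsFactors = FALSE)
  }
  for (t in hco_tract_labels()) {
    anc <- if (grepl("forceps", t)) "fma:Corpus_callosum" else
      if (grepl(":Right_", t)) "fma:White_matter_of_right_cerebral_hemisphere" else
        "fma:White_matter_of_left_cerebral_hemisphere"
    hints[[t]] <- data.frame(property = "fma:regional_part_of",
                             ancestor = anc, stringsAsFactors = FALSE)
  }
  hints
}

#' Generate the mini anatomy fixture
#'
#' Builds a deterministic frame-style graph standing in for the full
#' reference anatomy ontology: cortical gyri and segments with their
#' part-whole chains up to lobes, hemispheres, brain and neuraxis (and
#' onward to the whole body, so the exclusion machinery has something to
#' exclude), the twenty anatomically labeled seed tracts, the non-cortical
#' gray-matter regions, a small subsumption taxonomy rooted at
#' \code{fma:Anatomical_structure}, exactly one metaclass-flagged template
#' entity, and a couple of deliberately out-of-scope relation triples
#' (sulcal boundaries) that exercise the translation report. The fixture is
#' synthetic: names follow the reference ontology's conventions, but no
#' content is copied from it.
#'
#' @return a list of class \code{hco_mini_fma} with \code{graph} (an
#'   \code{hco_frame_graph}) and \code{manifest} (entity/triple counts and
#'   the mapped seed terms).
#' @export
generate_mini_fma <- function() {
  pool <- .region_pool()
  tracts <- hco_tract_labels()
  extras <- .extra_region_terms()
  lobes <- unique(pool$lobe)
  hemis <- c("fma:Right_cerebral_hemisphere", "fma:Left_cerebral_hemisphere")
  wm <- c("fma:White_matter_of_right_cerebral_hemisphere",
          "fma:White_matter_of_left_cerebral_hemisphere")
  anchors <- c("fma:Anatomical_structure",
               "fma:Region_of_cell_part_cluster_of_neuraxis",
               "fma:Gray_matter_of_neuraxis", "fma:White_matter_of_neuraxis")
  categories <- c("fma:Gyrus", "fma:Lobe", "fma:Neural_tract",
                  "fma:Subcortical_structure", "fma:Cerebral_hemisphere",
                  "fma:Segment_of_cerebral_hemisphere")
  trunk <- c("fma:Brain", "fma:Neuraxis", "fma:Nervous_system", "fma:Human_body",
             "fma:Corpus_callosum")
  gm_entities <- c("fma:Gray_matter_of_right_precentral_gyrus",
                   "fma:Gray_matter_of_left_precentral_gyrus")
  sulci <- c("fma:Right_central_sulcus", "fma:Left_central_sulcus")
  metaclass <- "fma:Anatomical_entity_template"

  entities <- c(pool$term, tracts, extras, lobes, hemis, wm, anchors,
                categories, trunk, gm_entities, sulci, metaclass)

  t3 <- function(s, p, o) data.frame(subject = s, predicate = p, object = o,
                                     stringsAsFactors = FALSE)
  sub_p <- .subsumption_predicate
  rpo <- "fma:regional_part_of"; cpo <- "fma:constitutional_part_of"
  triples <- rbind(
    # taxonomy
    t3(pool$term, sub_p,
       ifelse(grepl("Cortex_of|Orbitobasal", pool$term),
              "fma:Segment_of_cerebral_hemisphere", "fma:Gyrus")),
    t3(tracts, sub_p, "fma:Neural_tract"),
    t3(extras, sub_p, "fma:Subcortical_structure"),
    t3(lobes, sub_p, "fma:Lobe"),
    t3("fma:Medial_segment_of_cerebral_hemisphere", sub_p,
       "fma:Segment_of_cerebral_hemisphere"),
    t3(hemis, sub_p, "fma:Cerebral_hemisphere"),
    t3(wm, sub_p, "fma:White_matter_of_neuraxis"),
    t3(gm_entities, sub_p, "fma:Gray_matter_of_neuraxis"),
    t3(c(categories, trunk[trunk != "fma:Human_body"], anchors[-1], sulci),
       sub_p, "fma:Anatomical_structure"),
    # one metaclass on a subsumption chain, for the discard rule
    t3("fma:Gyrus", sub_p, metaclass),
    # partonomy: region -> lobe/segment -> hemisphere -> brain -> body
    t3(pool$term, rpo, pool$lobe),
    t3(lobes, rpo, ifelse(grepl("Right_", lobes), hemis[1], hemis[2])),
    t3("fma:Medial_segment_of_cerebral_hemisphere", rpo, hemis[1]),
    t3(hemis, rpo, "fma:Brain"),
    t3(wm, cpo, c(hemis[1], hemis[2])),
    t3(extras, rpo,
       ifelse(extras == "fma:Brainstem", "fma:Brain",
              ifelse(grepl(":Right_", extras), hemis[1], hemis[2]))),
    t3(tracts, rpo,
       ifelse(grepl("forceps", tracts), "fma:Corpus_callosum",
              ifelse(grepl(":Right_", tracts), wm[1], wm[2]))),
    t3("fma:Corpus_callosum", cpo, "fma:Brain"),
    t3("fma:Brain", rpo, "fma:Neuraxis"),
    t3("fma:Neuraxis", cpo, "fma:Nervous_system"),
    t3("fma:Nervous_system", cpo, "fma:Human_body"),
    # frame-style gray matter of a gyrus, stored in both directions
    t3(gm_entities, cpo, c("fma:Right_precentral_gyrus", "fma:Left_precentral_gyrus")),
    t3(c("fma:Right_precentral_gyrus", "fma:Left_precentral_gyrus"),
       "fma:constitutional_part", gm_entities),
    # nearest-neighbor knowledge
    t3("fma:Right_precentral_gyrus", "fma:attributed_continuous_with",
       "fma:Right_postcentral_gyrus"),
    t3("fma:Left_precentral_gyrus", "fma:attributed_continuous_with",
       "fma:Left_postcentral_gyrus"),
    # out-of-scope relations, kept to exercise the translation report
    t3(c("fma:Right_precentral_gyrus", "fma:Left_precentral_gyrus"),
       "fma:bounded_by", sulci)
  )
  graph <- frame_graph(entities = entities, triples = triples,
                       metaclasses = metaclass)
  seeds <- c(pool$term, tracts, extras)
  list2 <- list(graph = graph,
                manifest = list(
                  n_entities = length(graph$entities),
                  n_triples = nrow(graph$triples),
                  n_metaclasses = length(graph$metaclasses),
                  seed_terms = sort(seeds),
                  tract_terms = sort(tracts),
                  extra_region_terms = sort(extras)))
  class(list2) <- "hco_mini_fma"
  list2
}

#' Cohort generation settings
#'
#' Defaults describe the emulated study: five subjects, 1000 cortical
#' parcels each, the eleven-parcel right medial BA6 target mask with the
#' parcel numbers 20, 12, 32, 9, 17, 13, 42, 18, 24, 25, 38, fifteen
#' non-cortical regions, and twenty-two seed masks (twenty labeled tracts
#' plus one rest-of-white-matter mask per hemisphere). Planted connectivity:
#' SMA-like parcels (9, 17, 42) reach the corticospinal tract or precentral
#' gray matter; pre-SMA-like parcels (18, 24, 25, 38) reach medial parietal
#' or orbitobasal frontal gray matter; parcels 12 and 32 reach gray matter
#' merely adjacent to the precentral gyrus (picked up by the widened query
#' only); one superior-longitudinal-fasciculus route links parcel 17 to the
#' right temporal lobe. Planted values equal the row maximum by
#' construction, and noise values are drawn strictly below the level that
#' would survive binarization in a row holding a planted entry, so planted
#' truth is recovered exactly at zero noise and noise can only add answers.
#'
#' @param n_subjects number of subjects.
#' @param n_parcels cortical parcels per subject.
#' @param mask1_parcel_ids parcel ids forming the first target mask.
#' @param extra_region_terms non-cortical region classes.
#' @param seed_masks character vector of tract terms, \code{NA} for
#'   rest-of-white-matter seeds.
#' @param planted list with \code{sma}, \code{presma}, \code{cq3_extra}
#'   parcel-id vectors (pairwise disjoint, all in \code{mask1_parcel_ids}).
#' @param noise_rate per-cell probability of a spurious connectivity value;
#'   default 0.01, a realistic false-streamline rate after thresholding.
#' @param rng_seed integer seed; identical seeds give bitwise-identical
#'   cohorts.
#' @return a list of class \code{hco_cohort_config}.
#' @export
cohort_config <- function(n_subjects = 5,
                          n_parcels = 1000,
                          mask1_parcel_ids = c(20, 12, 32, 9, 17, 13, 42, 18, 24, 25, 38),
                          extra_region_terms = .extra_region_terms(),
                          seed_masks = c(hco_tract_labels(), NA, NA),
                          planted = list(sma = c(9, 17, 42),
                                         presma = c(18, 24, 25, 38),
                                         cq3_extra = c(12, 32)),
                          noise_rate = 0.01,
                          rng_seed = 1L) {
  if (any(!mask1_parcel_ids %in% seq_len(n_parcels)))
    stop("mask1 parcel ids must lie in 1..n_parcels")
  if (length(mask1_parcel_ids) > n_parcels)
    stop("mask1 cannot exceed the parcel count")
  if (length(intersect(planted$sma, planted$presma)) > 0 ||
      length(intersect(planted$sma, planted$cq3_extra)) > 0 ||
      length(intersect(planted$presma, planted$cq3_extra)) > 0)
    stop("planted parcel sets must be pairwise disjoint")
  if (any(!unlist(planted) %in% mask1_parcel_ids))
    stop("planted parcels must belong to the first target mask")
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must lie in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_parcels = as.integer(n_parcels),
                 mask1_parcel_ids = as.integer(mask1_parcel_ids),
                 extra_region_terms = as_term(extra_region_terms),
                 seed_masks = seed_masks,
                 planted = planted,
                 noise_rate = noise_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "hco_cohort_config")
}

#' Generate a synthetic cohort
#'
#' Produces one bundle per subject: the parcellation (mask-1 parcels
#' assigned to the right superior frontal gyrus, the remaining parcels
#' spread deterministically over the cortical region pool), the
#' nearest-neighbor adjacency (a ring within each region's parcels plus the
#' planted cross-gyrus edge the contiguity query needs), the per-seed
#' connectivity matrices of shape \code{length(mask1) x (n_parcels -
#' length(mask1) + n_extra_regions)} with planted and noise values, and the
#' planted truth. The only randomness is noise placement; draws follow a
#' fixed order (subject by subject, matrix by matrix), so a fixed seed gives
#' bitwise-identical output.
#'
#' @param config a [cohort_config()].
#' @return list of per-subject bundles, each of class
#'   \code{hco_subject_bundle} with elements \code{parcellation},
#'   \code{adjacency}, \code{matrices}, \code{truth}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "hco_cohort_config"))
  pool <- .region_pool()
  hints <- .partonomy_hints()
  mask1 <- config$mask1_parcel_ids
  other_ids <- sort(setdiff(seq_len(config$n_parcels), mask1))
  # deterministic near-equal cyclic split of the remaining parcels over the pool
  assignment <- pool$term[rep(seq_len(nrow(pool)), length.out = length(other_ids))]
  region_of <- stats::setNames(assignment, as.character(other_ids))
  block <- function(term) as.integer(names(region_of)[region_of == term])

  # planted target parcels / regions (identical across subjects)
  precentral <- block("fma:Right_precentral_gyrus")
  postcentral <- block("fma:Right_postcentral_gyrus")
  medial_parietal <- block("fma:Cortex_of_right_parietal_lobe")
  orbitobasal <- block("fma:Orbitobasal_segment_of_right_frontal_lobe")
  temporal <- block("fma:Right_inferior_temporal_gyrus")
  targets <- list(precentral = precentral[1], contiguity = postcentral[1],
                  contiguity_neighbor = precentral[2],
                  medial_parietal = medial_parietal[1],
                  orbitobasal = orbitobasal[1], temporal = temporal[1])

  extra_ids <- tolower(term_local(config$extra_region_terms))
  col_labels <- c(as.character(other_ids), extra_ids)
  masks <- config$seed_masks
  rest_idx <- which(is.na(masks))

  plant_for_mask <- function(label, mask_idx) {
    # returns data.frame(row_id, col_label) of planted cells for this seed
    p <- config$planted
    cells <- NULL
    add <- function(rows, col) rbind(cells, data.frame(
      row_id = rows, col_label = as.character(col), stringsAsFactors = FALSE))
    if (identical(label, "fma:Right_corticospinal_tract_of_brain")) {
      # all SMA-like parcels but the last reach the brainstem through the CST
      cells <- add(p$sma[seq_len(max(1, length(p$sma) - 1))], "brainstem")
    }
    if (identical(label, "fma:Right_superior_longitudinal_fasciculus")) {
      cells <- add(p$sma[min(2, length(p$sma))], targets$temporal)
    }
    if (identical(label, "fma:Right_anterior_segment_of_cingulum")) {
      half <- ceiling(length(p$presma) / 2)
      cells <- add(p$presma[seq_len(half)], targets$medial_parietal)
      if (half < length(p$presma)) {
        cells <- rbind(cells, data.frame(
          row_id = p$presma[(half + 1):length(p$presma)],
          col_label = as.character(targets$orbitobasal), stringsAsFactors = FALSE))
      }
    }
    if (length(rest_idx) > 0 && mask_idx == rest_idx[1]) {
      cells <- add(p$sma[length(p$sma)], targets$precentral)
      cells <- rbind(cells, data.frame(
        row_id = p$cq3_extra, col_label = as.character(targets$contiguity),
        stringsAsFactors = FALSE))
    }
    cells
  }

  set.seed(config$rng_seed)
  lapply(seq_len(config$n_subjects), function(si) {
    subj <- paste0("s", si)
    parcels <- rbind(
      data.frame(parcel_id = mask1,
                 region_term = "fma:Right_superior_frontal_gyrus",
                 hemisphere = "right", stringsAsFactors = FALSE),
      data.frame(parcel_id = other_ids,
                 region_term = unname(region_of[as.character(other_ids)]),
                 hemisphere = ifelse(grepl("right", tolower(region_of)), "right",
                                     ifelse(grepl("left", tolower(region_of)),
                                            "left", "midline")),
                 stringsAsFactors = FALSE))
    parc <- parcellation(subj, parcels,
                         extra_regions = data.frame(
                           region_id = extra_ids,
                           region_term = config$extra_region_terms,
                           stringsAsFactors = FALSE),
                         partonomy_hints = hints)

    ring <- function(ids) {
      ids <- as.character(ids)
      if (length(ids) < 2) return(NULL)
      e <- data.frame(a = ids, b = c(ids[-1], ids[1]), stringsAsFactors = FALSE)
      if (length(ids) == 2) e <- e[1, , drop = FALSE]
      e
    }
    edges <- do.call(rbind, c(
      list(ring(mask1)),
      lapply(unique(region_of), function(t) ring(block(t))),
      list(data.frame(a = as.character(targets$contiguity),
                      b = as.character(targets$contiguity_neighbor),
                      stringsAsFactors = FALSE))))
    adj <- adjacency(edges)

    matrices <- lapply(seq_along(masks), function(mi) {
      label <- masks[mi]
      v <- matrix(0, nrow = length(mask1), ncol = length(col_labels),
                  dimnames = list(as.character(mask1), col_labels))
      noise <- matrix(stats::runif(length(v)) < config$noise_rate,
                      nrow = nrow(v))
      vals <- matrix(stats::runif(length(v), min = 1, max = 100), nrow = nrow(v))
      v[noise] <- vals[noise]
      cells <- plant_for_mask(if (is.na(label)) NA_character_ else label, mi)
      if (!is.null(cells)) {
        for (k in seq_len(nrow(cells)))
          v[as.character(cells$row_id[k]), cells$col_label[k]] <- 1000
      }
      region_matrix(v, seed_label = if (!is.na(label)) label)
    })

    truth <- list(
      subject_id = subj,
      sma_parcels = sort(as.integer(config$planted$sma)),
      presma_parcels = sort(as.integer(config$planted$presma)),
      cq3_parcels = sort(as.integer(c(config$planted$sma,
                                      config$planted$cq3_extra))),
      cq4_bundles = paste0("hco:", subj, "_right_superior_longitudinal_fasciculus"),
      targets = targets)
    structure(list(parcellation = parc, adjacency = adj, matrices = matrices,
                   truth = truth),
              class = "hco_subject_bundle")
  })
}
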