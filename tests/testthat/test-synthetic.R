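test_that("the mini anatomy fixture matches its manifest and is deterministic", {
  mini <- generate_mini_fma()
  expect_equal(mini$manifest$n_entities, length(mini$graph$entities))
  expect_equal(mini$manifest$n_triples, nrow(mini$graph$triples))
  expect_equal(mini$manifest$n_metaclasses, 1)
  expect_length(mini$graph$metaclasses, 1)
  expect_length(mini$manifest$tract_terms, 20)
  expect_length(mini$manifest$extra_region_terms, 15)
  mini2 <- generate_mini_fma()
  expect_identical(mini, mini2)
  # every gyrus reaches the neuraxis through the part-of chain (BFS oracle)
  o <- oracle_extract_view(mini$graph,
                           extraction_config(seeds = "fma:Right_lingual_gyrus",
                                             superclass_closure = FALSE))
  expect_true(all(c("fma:Right_occipital_lobe", "fma:Brain", "fma:Neuraxis",
                    "fma:Human_body") %in% o$entities))
})

test_that("all competency-query vocabulary resolves in the derived reference TBox", {
  tb <- build_reference_tbox()
  for (n in 1:4) expect_silent(hco:::.check_expr_vocab(competency_query(n), tb))
})

test_that("the default cohort has the study's shape: 22 seed matrices of 11 x 1004", {
  cfg <- cohort_config()
  expect_equal(cfg$n_subjects, 5L)
  b <- generate_cohort(cohort_config(n_subjects = 1))[[1]]
  expect_length(b$matrices, 22)
  labeled <- vapply(b$matrices, function(m) !is.null(m$seed_label), TRUE)
  expect_equal(sum(labeled), 20)
  for (m in b$matrices) {
    expect_equal(dim(m$values), c(11, 1004))
    expect_true(all(m$values >= 0))
  }
  expect_equal(nrow(b$parcellation$parcels), 1000)
  expect_equal(nrow(b$parcellation$extra_regions), 15)
  # 1004 = 1000 parcels - 11 mask-1 parcels + 15 extra regions
  expect_equal(ncol(b$matrices[[1]]$values),
               1000 - length(cfg$mask1_parcel_ids) + 15)
})

test_that("the shape identity holds for non-default configurations", {
  for (np in c(60, 150)) {
    cfg <- cohort_config(n_subjects = 1, n_parcels = np)
    b <- generate_cohort(cfg)[[1]]
    expect_equal(dim(b$matrices[[1]]$values),
                 c(11, np - 11 + length(cfg$extra_region_terms)))
  }
})

test_that("a fixed seed reproduces the cohort bitwise", {
  c1 <- generate_cohort(cohort_config(n_subjects = 2, n_parcels = 80,
                                      rng_seed = 42))
  c2 <- generate_cohort(cohort_config(n_subjects = 2, n_parcels = 80,
                                      rng_seed = 42))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(n_subjects = 2, n_parcels = 80,
                                      rng_seed = 43))
  expect_false(identical(c1, c3))
})

test_that("invalid cohort configurations are rejected with a reason", {
  expect_error(cohort_config(mask1_parcel_ids = c(1, 2, 5000)), "1..n_parcels")
  expect_error(cohort_config(planted = list(sma = c(9, 17), presma = c(17, 24),
                                            cq3_extra = 12)),
               "disjoint")
  expect_error(cohort_config(planted = list(sma = 9, presma = 24,
                                            cq3_extra = 999)),
               "first target mask")
  expect_error(cohort_config(noise_rate = 1), "noise_rate")
})

test_that("planted truth is recovered exactly at zero noise on a reduced cohort", {
  tb <- build_reference_tbox()
  cohort <- generate_cohort(cohort_config(n_subjects = 2, n_parcels = 120,
                                          noise_rate = 0))
  for (b in cohort) {
    s <- saturate_subject(b, tb)
    expect_identical(answer_parcel_ids(answer_query(competency_query(1), s)),
                     b$truth$sma_parcels)
    expect_identical(answer_parcel_ids(answer_query(competency_query(2), s)),
                     b$truth$presma_parcels)
    expect_identical(answer_parcel_ids(answer_query(competency_query(3), s)),
                     b$truth$cq3_parcels)
    expect_true(all(b$truth$cq4_bundles %in%
                      answer_query(competency_query(4), s)$answers))
  }
})

test_that("noise only adds answers: planted parcels stay contained", {
  tb <- build_reference_tbox()
  b <- generate_cohort(cohort_config(n_subjects = 1, n_parcels = 120,
                                     noise_rate = 0.01, rng_seed = 7))[[1]]
  s <- saturate_subject(b, tb)
  cq1 <- answer_parcel_ids(answer_query(competency_query(1), s))
  cq2 <- answer_parcel_ids(answer_query(competency_query(2), s))
  cq3 <- answer_query(competency_query(3), s)$answers
  cq1_full <- answer_query(competency_query(1), s)$answers
  expect_true(all(b$truth$sma_parcels %in% cq1))
  expect_true(all(b$truth$presma_parcels %in% cq2))
  expect_true(all(cq1_full %in% cq3))
})
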