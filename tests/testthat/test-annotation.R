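# small reference TBox shared by the annotation tests
ref_tbox <- build_reference_tbox()

two_parcel_setup <- function() {
  hints <- list(
    "fma:Right_superior_frontal_gyrus" = data.frame(
      property = "fma:regional_part_of", ancestor = "fma:Right_frontal_lobe",
      stringsAsFactors = FALSE),
    "fma:Left_superior_frontal_gyrus" = data.frame(
      property = "fma:regional_part_of", ancestor = "fma:Left_frontal_lobe",
      stringsAsFactors = FALSE))
  parc <- parcellation("s1", data.frame(
    parcel_id = c(17L, 39L),
    region_term = c("fma:Right_superior_frontal_gyrus",
                    "fma:Left_superior_frontal_gyrus"),
    hemisphere = c("right", "left")), partonomy_hints = hints)
  m <- binary_matrix(matrix(1, 1, 1, dimnames = list("17", "39")),
                     seed_label = "fma:Anterior_forceps_of_corpus_callosum")
  list(parc = parc, adj = adjacency(), m = m)
}

test_that("voxel-wise aggregation averages over voxel pairs", {
  # one voxel per region: identity
  v <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("v1", "v2"), c("w1", "w2")))
  map <- c(v1 = "R1", v2 = "R2", w1 = "C1", w2 = "C2")
  out <- aggregate_voxelwise(v, map)
  expect_equal(out["R1", "C1"], 1)
  expect_equal(out["R2", "C2"], 4)
  # two voxels in one region: hand mean (0.2 + 0.4) / 2 = 0.3
  v2 <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("a", "b"), "c"))
  out2 <- aggregate_voxelwise(v2, c(a = "R", b = "R", c = "C"))
  expect_equal(out2["R", "C"], 0.3)
  # constant matrices aggregate to the same constant
  v3 <- matrix(7, 3, 2, dimnames = list(paste0("a", 1:3), paste0("b", 1:2)))
  out3 <- aggregate_voxelwise(v3, c(a1 = "R", a2 = "R", a3 = "S",
                                    b1 = "C", b2 = "C"))
  expect_true(all(out3 == 7))
  # all-zero stays all-zero
  expect_true(all(aggregate_voxelwise(v3 * 0, c(a1 = "R", a2 = "R", a3 = "S",
                                                b1 = "C", b2 = "C")) == 0))
  expect_error(aggregate_voxelwise(v2, c(a = "R", c = "C")), "unmapped.*b")
})

test_that("binarization follows log1p, row-max normalization and >= threshold", {
  # ln(1+9)/ln(1+99) = 0.5 exactly, ln(1+99)/ln(1+99) = 1
  m <- region_matrix(matrix(c(9, 99, 0), 1, 3,
                            dimnames = list("r", c("a", "b", "c"))))
  b <- binarize_matrix(m)
  expect_equal(unname(b$values[1, ]), c(0, 1, 0))
  # all-zero rows stay all-zero
  z <- region_matrix(matrix(0, 2, 3, dimnames = list(c("r1", "r2"),
                                                     c("a", "b", "c"))))
  expect_true(all(binarize_matrix(z)$values == 0))
  # every non-empty row keeps its maximum; exact threshold ties survive
  set.seed(42)
  for (i in 1:20) {
    v <- matrix(stats::rexp(12) * 50, 3, 4,
                dimnames = list(paste0("r", 1:3), paste0("c", 1:4)))
    v[sample(12, 3)] <- 0
    bb <- binarize_matrix(region_matrix(v))
    for (r in 1:3) {
      if (any(v[r, ] > 0))
        expect_equal(bb$values[r, which.max(v[r, ])], 1)
    }
  }
  expect_error(binarize_matrix(matrix(-1, 1, 1, dimnames = list("r", "c"))),
               "non-negative")
  expect_error(annotation_config(threshold = 0), "0, 1")
})

test_that("one connected cell produces the full route annotation pattern", {
  s <- two_parcel_setup()
  ab <- annotate_subject(s$parc, s$adj, list(s$m), ref_tbox)
  rl <- ab$roles
  p17 <- "hco:s1_gray_matter_of_right_superior_frontal_gyrus_17"
  p39 <- "hco:s1_gray_matter_of_left_superior_frontal_gyrus_39"
  route <- "hco:s1_mr_route_1"
  bundle <- "hco:s1_anterior_forceps_of_corpus_callosum"
  expect_true(all(c(p17, p39, route, bundle) %in% ab$individuals))
  expect_true(any(rl$property == "hco:tracto_connects" & rl$subject == route &
                    rl$object == p17))
  expect_true(any(rl$property == "hco:tracto_connects" & rl$subject == route &
                    rl$object == p39))
  expect_true(any(rl$property == "fma:regional_part_of" & rl$subject == route &
                    rl$object == bundle))
  expect_true(any(rl$property == "hco:mr_connection" & rl$subject == p17 &
                    rl$object == p39))
  ty <- ab$types
  expect_true(any(ty$individual == route & ty$class == "hco:MR_Route"))
  expect_true(any(ty$individual == bundle &
                    ty$class == "fma:Anterior_forceps_of_corpus_callosum"))
  # the parcel-to-gyrus chain of the annotation convention
  gm <- "hco:s1_gray_matter_of_right_superior_frontal_gyrus"
  expect_true(any(rl$property == "fma:regional_part_of" & rl$subject == p17 &
                    rl$object == gm))
  expect_true(any(rl$property == "fma:constitutional_part_of" & rl$subject == gm &
                    rl$object == "hco:s1_right_superior_frontal_gyrus"))
})

test_that("route counts equal nonzero cells: k cells, k routes, 2k tracto assertions", {
  set.seed(7)
  hints <- list()
  for (trial in 1:10) {
    n_row <- sample(2:4, 1); n_col <- sample(3:6, 1)
    parc <- parcellation("s9", data.frame(
      parcel_id = seq_len(n_row + n_col),
      region_term = rep(c("fma:Right_superior_frontal_gyrus",
                          "fma:Right_precentral_gyrus"),
                        c(n_row, n_col)),
      hemisphere = "right"))
    mats <- lapply(1:2, function(i) {
      v <- matrix(stats::rbinom(n_row * n_col, 1, 0.4), n_row, n_col,
                  dimnames = list(as.character(seq_len(n_row)),
                                  as.character(n_row + seq_len(n_col))))
      binary_matrix(v)
    })
    k <- sum(vapply(mats, function(m) sum(m$values), 0))
    pairs <- unique(do.call(rbind, lapply(mats, function(m)
      which(m$values == 1, arr.ind = TRUE))))
    ab <- annotate_subject(parc, adjacency(), mats, ref_tbox)
    ty <- ab$types; rl <- ab$roles
    expect_equal(sum(ty$class == "hco:MR_Route"), k)
    expect_equal(sum(rl$property == "hco:tracto_connects"), 2 * k)
    expect_equal(sum(rl$property == "hco:mr_connection"), nrow(pairs))
    # no self-connections are ever emitted
    mr <- rl[rl$property == "hco:mr_connection", ]
    expect_true(all(mr$subject != mr$object))
  }
})

test_that("zero matrices annotate to parcels only; bad inputs error", {
  s <- two_parcel_setup()
  zero <- binary_matrix(matrix(0, 1, 1, dimnames = list("17", "39")))
  ab <- annotate_subject(s$parc, s$adj, list(zero), ref_tbox)
  expect_equal(sum(ab$types$class == "hco:MR_Route"), 0)
  expect_true(all(ab$types$class[grepl("_17$|_39$", ab$types$individual)] ==
                    "hco:Gray_matter_part"))
  expect_error(
    parcellation("s1", data.frame(parcel_id = c(1L, 1L),
                                  region_term = "fma:Right_precentral_gyrus",
                                  hemisphere = "right")),
    "duplicate parcel ids")
  stray <- binary_matrix(matrix(1, 1, 1, dimnames = list("17", "999")))
  expect_error(annotate_subject(s$parc, s$adj, list(stray), ref_tbox),
               "not in parcellation")
  expect_error(adjacency(data.frame(a = "1", b = "1")), "self-pair")
})

test_that("adjacency edges become one continuous_with assertion each", {
  s <- two_parcel_setup()
  adj <- adjacency(data.frame(a = "17", b = "39"))
  ab <- annotate_subject(s$parc, adj, list(), ref_tbox)
  cw <- ab$roles[ab$roles$property == "hco:continuous_with", ]
  expect_equal(nrow(cw), 1)
})
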