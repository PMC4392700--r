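ref_tbox <- build_reference_tbox()

test_that("the grammar binds some tighter than and, and and tighter than or", {
  tb <- tbox(classes = c("hco:A", "hco:B", "hco:C"),
             properties = list(property_decl("hco:p")))
  e <- parse_query("hco:A and hco:B or hco:C")
  expect_equal(e$variant, "or")
  expect_equal(e$children[[1]]$variant, "and")
  expect_equal(e$children[[2]]$term, "hco:C")
  # some is right-associative over atoms
  e2 <- parse_query("hco:p some hco:p some hco:A")
  expect_true(ce_equal(e2, ce_some("hco:p", ce_some("hco:p", ce_named("hco:A")))))
  # parse . print is the identity
  for (txt in c("hco:A and (hco:B or hco:C)",
                "(hco:p some hco:A) and hco:B",
                "hco:p some (hco:A or (hco:B and hco:C))")) {
    e3 <- parse_query(txt)
    expect_true(ce_equal(parse_query(ce_to_string(e3)), e3), info = txt)
  }
})

test_that("syntax errors report a position; name resolution is hco-first", {
  expect_error(parse_query("hco:A and (hco:B or"), "end of input")
  expect_error(parse_query("hco:A hco:B"), "position")
  expect_error(parse_query("and hco:A"), "syntax error")
  # unprefixed resolution against a vocabulary
  e <- parse_query("part_of some Right_temporal_lobe", ref_tbox)
  expect_equal(e$property, "hco:part_of")
  expect_equal(e$filler$term, "fma:Right_temporal_lobe")
  expect_error(parse_query("part_of some Nowhere_gyrus", ref_tbox),
               "unknown class")
  amb <- merge_tbox(ref_tbox, tbox(classes = "hco:Right_temporal_lobe"))
  expect_error(parse_query("Right_temporal_lobe", amb), "ambiguous")
  expect_error(parse_query("part_of some Right_temporal_lobe"), "vocabulary")
})

test_that("the published query strings parse to the shipped competency queries", {
  q1 <- "(part_of some Right_superior_frontal_gyrus) and ((is_tracto_connected some (part_of some Right_corticospinal_tract_of_brain)) or (mr_connection some (part_of some Right_precentral_gyrus)))"
  q2 <- "(part_of some Right_superior_frontal_gyrus) and (mr_connection some ((part_of some Cortex_of_right_parietal_lobe) and (part_of some Medial_segment_of_cerebral_hemisphere)) or mr_connection some (part_of some Orbitobasal_segment_of_right_frontal_lobe))"
  q3 <- "(part_of some Right_superior_frontal_gyrus) and ((is_tracto_connected some (part_of some Right_corticospinal_tract_of_brain)) or (mr_connection some (part_of some Right_precentral_gyrus)) or (mr_connection some (continuous_with some (part_of some Right_precentral_gyrus))))"
  q4 <- "part some ((tracto_connects some (part_of some Right_temporal_lobe)) and (tracto_connects some (part_of some Right_superior_frontal_gyrus)))"
  for (n in 1:4) {
    parsed <- parse_query(c(q1, q2, q3, q4)[n], ref_tbox)
    expect_true(ce_equal(parsed, competency_query(n)), info = paste("query", n))
    # round trip through the printer
    expect_true(ce_equal(parse_query(ce_to_string(competency_query(n))),
                         competency_query(n)))
  }
  # query 2 groups the medial-parietal conjunction under the connection
  cq2 <- competency_query(2)
  disj <- cq2$children[[2]]
  expect_equal(disj$variant, "or")
  inner <- disj$children[[1]]$filler
  expect_true(ce_equal(inner,
    ce_and(ce_some("hco:part_of", ce_named("fma:Cortex_of_right_parietal_lobe")),
           ce_some("hco:part_of",
                   ce_named("fma:Medial_segment_of_cerebral_hemisphere")))))
  # query 4 structure: a bundle with routes to both regions
  cq4 <- competency_query(4)
  expect_equal(cq4$variant, "some")
  expect_equal(cq4$property, "hco:part")
  expect_equal(cq4$filler$variant, "and")
  expect_error(competency_query(5), "1, 2, 3 or 4")
})

test_that("the evaluator agrees with the per-individual oracle on random KBs", {
  for (seed in 1:25) {
    k <- random_kb(seed)
    s <- saturate(k)
    o <- oracle_saturate(k)
    classes <- k$tbox$classes
    pn <- names(k$tbox$properties)
    set.seed(seed + 1000)
    exprs <- list(
      ce_named(sample(classes, 1)),
      ce_some(sample(pn, 1), ce_named(sample(classes, 1))),
      ce_and(ce_named(sample(classes, 1)),
             ce_some(sample(pn, 1), ce_named(sample(classes, 1)))),
      ce_or(ce_named(sample(classes, 1)),
            ce_some(sample(pn, 1),
                    ce_some(sample(pn, 1), ce_named(sample(classes, 1))))))
    for (e in exprs) {
      got <- answer_query(e, s)$answers
      want <- sort(Filter(function(i) o$holds(i, e), k$abox$individuals))
      expect_identical(got, as.character(want),
                       info = paste("seed", seed, ce_to_string(e)))
    }
  }
})

test_that("answers are monotone under added assertions and empty when nothing matches", {
  k <- random_kb(5)
  s <- saturate(k)
  e <- ce_some(names(k$tbox$properties)[1], ce_named(k$tbox$classes[1]))
  base <- answer_query(e, s)$answers
  inds <- k$abox$individuals
  bigger <- kb(k$tbox, abox(
    individuals = inds,
    types = rbind(k$abox$types,
                  data.frame(individual = inds[1], class = k$tbox$classes[1])),
    roles = rbind(k$abox$roles,
                  data.frame(property = names(k$tbox$properties)[1],
                             subject = inds[2], object = inds[1]))))
  grown <- answer_query(e, saturate(bigger))$answers
  expect_true(all(base %in% grown))
  # no role assertion, no class-level existential: empty answer set
  tb <- tbox(classes = "hco:C", properties = list(property_decl("hco:q")))
  s0 <- saturate(kb(tb, abox(individuals = "hco:i")))
  expect_length(answer_query(ce_some("hco:q", ce_named("hco:C")), s0)$answers, 0)
  expect_error(answer_query(ce_named("hco:Nope"), s0), "unknown class")
})
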