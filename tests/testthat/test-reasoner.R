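test_that("part-of assertions compose across the partonomy chain", {
  schema <- build_hco_schema()
  tb <- merge_tbox(schema, tbox(classes = c(
    "fma:Right_superior_frontal_gyrus", "fma:Right_frontal_lobe")))
  ab <- abox(
    individuals = c("hco:p17", "hco:gm_rsfg", "hco:rsfg", "hco:lobe"),
    types = data.frame(
      individual = c("hco:p17", "hco:rsfg", "hco:lobe"),
      class = c("hco:Gray_matter_part", "fma:Right_superior_frontal_gyrus",
                "fma:Right_frontal_lobe")),
    roles = data.frame(
      property = c("fma:regional_part_of", "fma:constitutional_part_of",
                   "fma:regional_part_of"),
      subject = c("hco:p17", "hco:gm_rsfg", "hco:rsfg"),
      object = c("hco:gm_rsfg", "hco:rsfg", "hco:lobe")))
  s <- saturate(kb(tb, ab))
  rl <- s$roles
  # role hierarchy lifts both part properties into part_of, transitivity closes
  expect_true(any(rl$property == "hco:part_of" & rl$subject == "hco:p17" &
                    rl$object == "hco:lobe"))
  # and the inverse direction materializes under hco:part
  expect_true(any(rl$property == "hco:part" & rl$subject == "hco:lobe" &
                    rl$object == "hco:p17"))
  expect_true(holds("hco:p17",
                    parse_query("hco:part_of some fma:Right_frontal_lobe"), s))
})

test_that("the tracto chain derives a symmetric, irreflexive mr_connection", {
  schema <- build_hco_schema()
  ab <- abox(
    individuals = c("hco:n1", "hco:n2", "hco:r118"),
    types = data.frame(individual = c("hco:n1", "hco:n2", "hco:r118"),
                       class = c("hco:Gray_matter_part", "hco:Gray_matter_part",
                                 "hco:MR_Route")),
    roles = data.frame(property = c("hco:is_tracto_connected",
                                    "hco:tracto_connects"),
                       subject = c("hco:n1", "hco:r118"),
                       object = c("hco:r118", "hco:n2")))
  s <- saturate(kb(schema, ab))
  mr <- s$roles[s$roles$property == "hco:mr_connection", ]
  expect_true(any(mr$subject == "hco:n1" & mr$object == "hco:n2"))
  expect_true(any(mr$subject == "hco:n2" & mr$object == "hco:n1"))
  # a node reaches itself through its own route, but no self-connection is derived
  expect_false(any(mr$subject == mr$object))
  # realization: n1 satisfies the MR_Node definition
  ty <- s$types
  expect_true(any(ty$individual == "hco:n1" & ty$class == "hco:MR_Node"))
  expect_true(any(ty$individual == "hco:r118" & ty$class == "hco:MR_Route"))
})

test_that("an empty ABox saturates to reflexive subsumption only", {
  s <- saturate(kb(build_hco_schema()))
  expect_equal(nrow(s$types), 0)
  expect_equal(nrow(s$roles), 0)
  expect_true(all(paste(s$kb$tbox$classes, s$kb$tbox$classes) %in%
                    paste(s$subsumptions$sub, s$subsumptions$super)))
})

test_that("class-level existentials answer holds() through anonymous fillers", {
  tb <- tbox(
    classes = c("hco:A", "hco:B"),
    properties = list(
      property_decl("fma:constitutional_part_of", super_properties = "hco:part_of"),
      property_decl("hco:part_of", transitive = TRUE)),
    subclass_axioms = list(
      list(lhs = "hco:A",
           rhs = ce_some("fma:constitutional_part_of", ce_named("hco:B")))))
  ab <- abox(individuals = "hco:i",
             types = data.frame(individual = "hco:i", class = "hco:A"))
  s <- saturate(kb(tb, ab))
  expect_true(holds("hco:i", ce_some("hco:part_of", ce_named("hco:B")), s))
  expect_false(holds("hco:i", ce_some("fma:constitutional_part_of",
                                      ce_named("hco:A")), s))
  expect_error(holds("hco:i", ce_named("hco:Missing"), s), "unknown class")
})

test_that("saturation equals the naive fixpoint oracle on random knowledge bases", {
  for (seed in 1:60) {
    k <- random_kb(seed)
    got <- saturated_keys(saturate(k))
    want <- oracle_saturate(k)
    for (part in c("subs", "cex", "types", "roles"))
      expect_identical(got[[part]], want[[part]],
                       info = paste("seed", seed, part))
  }
})

test_that("saturation is idempotent and monotone", {
  for (seed in 61:75) {
    k <- random_kb(seed)
    s1 <- saturate(k)
    # idempotence: feeding the derived facts back adds nothing
    k2 <- kb(k$tbox, abox(individuals = k$abox$individuals,
                          types = s1$types, roles = s1$roles))
    s2 <- saturate(k2)
    expect_identical(saturated_keys(s2), saturated_keys(s1),
                     info = paste("idempotence, seed", seed))
    # monotonicity: one extra assertion never removes a derived fact
    inds <- k$abox$individuals
    extra_roles <- rbind(k$abox$roles,
                         data.frame(property = names(k$tbox$properties)[1],
                                    subject = inds[1],
                                    object = inds[length(inds)]))
    s3 <- saturate(kb(k$tbox, abox(individuals = inds, types = k$abox$types,
                                   roles = extra_roles)))
    before <- saturated_keys(s1); after <- saturated_keys(s3)
    for (part in c("subs", "cex", "types", "roles"))
      expect_true(all(before[[part]] %in% after[[part]]),
                  info = paste("monotonicity, seed", seed, part))
  }
})

test_that("derived part_of equals graph reachability over the part edges", {
  tb <- build_reference_tbox()
  cfg <- cohort_config(n_subjects = 1, n_parcels = 80, noise_rate = 0.02,
                       rng_seed = 11)
  b <- generate_cohort(cfg)[[1]]
  s <- saturate_subject(b, tb)
  asserted <- s$kb$abox$roles
  part_edges <- asserted[asserted$property %in%
                           c("fma:regional_part_of", "fma:constitutional_part_of"), ]
  g <- igraph::graph_from_data_frame(part_edges[, c("subject", "object")])
  reach <- igraph::distances(g, mode = "out")
  pairs <- expand.grid(from = rownames(reach), to = colnames(reach),
                       stringsAsFactors = FALSE)
  pairs <- pairs[is.finite(reach[as.matrix(pairs)]) & pairs$from != pairs$to, ]
  want <- sort(paste(pairs$from, pairs$to))
  part_of <- s$roles[s$roles$property == "hco:part_of", ]
  got <- sort(paste(part_of$subject, part_of$object))
  expect_identical(got, want)
})

test_that("the rule trace covers every derived fact", {
  k <- random_kb(3)
  s <- saturate(k, trace = TRUE)
  expect_true(all(c("rule", "premises", "conclusion") %in% names(s$trace)))
  # every derived (non-asserted) role fact has a trace entry
  asserted <- paste("role(", k$abox$roles$property, ", ", k$abox$roles$subject,
                    ", ", k$abox$roles$object, ")", sep = "")
  derived <- paste("role(", s$roles$property, ", ", s$roles$subject, ", ",
                   s$roles$object, ")", sep = "")
  traced <- s$trace$conclusion
  expect_true(all(setdiff(derived, asserted) %in% traced))
})
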