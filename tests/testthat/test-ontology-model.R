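test_that("term names parse, validate and round-trip", {
  expect_equal(term_namespace("fma:Right_precentral_gyrus"), "fma")
  expect_equal(term_local("fma:Right_precentral_gyrus"), "Right_precentral_gyrus")
  expect_equal(make_term("hco", "MR_Node"), "hco:MR_Node")
  expect_error(as_term("no_namespace"), "invalid term")
  expect_error(as_term("fma:has space"), "invalid term")
  expect_error(as_term("xyz:Thing"), "invalid term")
})

test_that("class expressions canonicalize order-insensitively", {
  a <- ce_and(ce_named("hco:A"), ce_named("hco:B"))
  b <- ce_and(ce_named("hco:B"), ce_named("hco:A"))
  expect_true(ce_equal(a, b))
  expect_false(ce_equal(a, ce_or(ce_named("hco:A"), ce_named("hco:B"))))
  nested <- ce_some("hco:p", ce_or(ce_named("fma:Y"), ce_named("fma:X")))
  expect_equal(ce_to_string(ce_canonical(nested)),
               "(hco:p some (fma:X or fma:Y))")
  expect_error(ce_and(ce_named("hco:A")), "at least 2")
  # list encoding round-trips
  expect_true(ce_equal(ce_from_list(ce_to_list(nested)), nested))
})

test_that("the schema has the published shape: 11 object properties, 4 connectomics classes", {
  schema <- build_hco_schema()
  expect_length(schema$properties, 11)
  hco_classes <- grep("^hco:", schema$classes, value = TRUE)
  expect_setequal(hco_classes, c("hco:Gray_matter_part", "hco:White_matter_part",
                                 "hco:MR_Node", "hco:MR_Route"))
  # the MR_Node definition: a gray matter part tracto-connected to a route
  def <- Filter(function(ax) ax$lhs == "hco:MR_Node", schema$equivalence_axioms)[[1]]
  expect_true(ce_equal(def$rhs,
    ce_and(ce_named("hco:Gray_matter_part"),
           ce_some("hco:is_tracto_connected", ce_named("hco:MR_Route")))))
  # characteristics
  expect_true(schema$properties[["hco:part_of"]]$transitive)
  expect_true(schema$properties[["hco:mr_connection"]]$symmetric)
  expect_equal(schema$properties[["hco:is_tracto_connected"]]$inverse,
               "hco:tracto_connects")
  expect_equal(schema$properties[["fma:regional_part_of"]]$super_properties,
               "hco:part_of")
  expect_null(schema$properties[["hco:part_of"]]$inverse)
  expect_length(schema$chain_axioms, 1)
  expect_equal(schema$chain_axioms[[1]],
               c("hco:is_tracto_connected", "hco:tracto_connects",
                 "hco:mr_connection"))
  # deterministic construction
  expect_identical(hco:::.kb_to_list(kb(schema)),
                   hco:::.kb_to_list(kb(build_hco_schema())))
})

test_that("TBox validation rejects broken declarations", {
  expect_error(tbox(properties = list(
    property_decl("hco:p", inverse = "hco:q"),
    property_decl("hco:q"))), "not mutual")
  expect_error(tbox(properties = list(
    property_decl("hco:p", super_properties = "hco:q"),
    property_decl("hco:q", super_properties = "hco:p"))), "cycle")
  expect_error(tbox(classes = "hco:A",
                    subclass_axioms = list(list(lhs = "hco:A",
                                                rhs = ce_named("hco:B")))),
               "undeclared class")
})

test_that("merge_tbox is identity on empty, unions disjoint, rejects conflicts", {
  schema <- build_hco_schema()
  expect_identical(hco:::.kb_to_list(kb(merge_tbox(schema, tbox()))),
                   hco:::.kb_to_list(kb(schema)))
  a <- tbox(classes = c("hco:A", "hco:B", "hco:C"))
  b <- tbox(classes = c("fma:X", "fma:Y", "fma:Z"))
  expect_length(merge_tbox(a, b)$classes, 6)
  # commutative up to serialization order
  expect_identical(hco:::.kb_to_list(kb(merge_tbox(a, b))),
                   hco:::.kb_to_list(kb(merge_tbox(b, a))))
  p1 <- tbox(properties = list(property_decl("hco:p", transitive = TRUE)))
  p2 <- tbox(properties = list(property_decl("hco:p", transitive = FALSE)))
  expect_error(merge_tbox(p1, p2), "conflicting redeclaration.*hco:p")
})

test_that("knowledge bases round-trip through all three formats", {
  schema <- build_hco_schema()
  ab <- abox(individuals = c("hco:n1", "hco:r1", "hco:n2"),
             types = data.frame(individual = c("hco:n1", "hco:r1"),
                                class = c("hco:Gray_matter_part", "hco:MR_Route")),
             roles = data.frame(property = c("hco:is_tracto_connected",
                                             "hco:tracto_connects"),
                                subject = c("hco:n1", "hco:r1"),
                                object = c("hco:r1", "hco:n2")))
  k <- kb(schema, ab)
  for (ext in c("json", "ttl", "nt")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_kb(k, path)
    back <- read_kb(path)
    expect_identical(hco:::.kb_to_list(back), hco:::.kb_to_list(k))
  }
})

test_that("the writer is bit-stable", {
  k <- kb(build_hco_schema())
  p1 <- tempfile(fileext = ".ttl"); p2 <- tempfile(fileext = ".ttl")
  write_kb(k, p1); write_kb(k, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("a minimal N-Triples file yields one type assertion", {
  path <- tempfile(fileext = ".nt")
  writeLines(c(
    "<http://example.org/hco#Gray_matter_part> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://www.w3.org/2002/07/owl#Class> .",
    "<http://example.org/hco#n1> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://www.w3.org/2002/07/owl#NamedIndividual> .",
    "<http://example.org/hco#n1> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://example.org/hco#Gray_matter_part> ."
  ), path)
  k <- read_kb(path)
  expect_equal(nrow(k$abox$types), 1)
  expect_equal(k$abox$types$class, "hco:Gray_matter_part")
})

test_that("malformed input fails with a line number", {
  path <- tempfile(fileext = ".nt")
  writeLines(c(
    "<http://example.org/hco#A> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://www.w3.org/2002/07/owl#Class> .",
    "this is not a triple"
  ), path)
  expect_error(read_kb(path), "line 2")
})

test_that("the shipped mini anatomy fixture round-trips as a frame graph", {
  mini <- generate_mini_fma()
  for (ext in c("json", "ttl", "nt")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_frame_graph(mini$graph, path)
    back <- read_frame_graph(path)
    expect_identical(back$entities, mini$graph$entities)
    expect_identical(back$metaclasses, mini$graph$metaclasses)
    # the rdf:type-to-metaclass normalization maps onto subClassOf, which
    # the fixture already uses, so triples are unchanged
    expect_identical(back$triples, mini$graph$triples)
  }
})
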