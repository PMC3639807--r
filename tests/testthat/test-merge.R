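test_that("merging promotes isHostedIn and links the host individual", {
  ex <- example_graph_cached()
  fish <- mhbi_example_fish()
  expect_true(validate_ontology(ex)$overall_pass)
  expect_true(validate_ontology(fish)$overall_pass)
  merged <- merge_ontologies(ex, fish)
  expect_equal(unname(merged$declarations[ms("isHostedIn")]),
               "object-property")
  expect_true(has_triple(merged, mi("BifBaungi"), ms("isHostedIn"),
                         fi("SilBagMysHemurus")))
  expect_false(has_triple(merged, mi("BifBaungi"), ms("isHostedIn"),
                          literal("SilBagMysHemurus")))
  expect_equal(match_triples(merged, ms("isHostedIn"),
                             "http://www.w3.org/2000/01/rdf-schema#range")$object,
               fi("TaxonName"))
  expect_true(validate_ontology(merged)$overall_pass)
  # round-trip of the merged graph
  rt <- parse_ontology(serialize_ontology(merged, "turtle"), "turtle")
  expect_true(graphs_equal(merged, rt))
})

test_that("merge conserves every non-replaced triple of both sources", {
  ex <- example_graph_cached()
  fish <- mhbi_example_fish()
  merged <- merge_ontologies(ex, fish)
  st <- attr(merged, "merge_stats")
  old_range <- 1L  # xsd range axiom of isHostedIn replaced by fish range
  expect_equal(n_triples(merged),
               n_triples(ex) + n_triples(fish) -
                 st$n_replaced + st$n_replaced -  # literals swapped for links
                 old_range + 1L)
  # schema of neither source otherwise altered: fish triples all present
  ftr <- match_triples(fish)
  for (i in seq_len(nrow(ftr))) {
    obj <- if (ftr$is_literal[i]) literal(ftr$object[i], ftr$datatype[i])
           else ftr$object[i]
    expect_true(has_triple(merged, ftr$subject[i], ftr$predicate[i], obj))
  }
})

test_that("merging with an empty fish ontology keeps literals under the default policy", {
  ex <- example_graph_cached()
  fish <- build_fish_schema()
  expect_warning(merged <- merge_ontologies(ex, fish), "unresolved")
  expect_true(has_triple(merged, mi("BifBaungi"), ms("isHostedIn"),
                         literal("SilBagMysHemurus")))
  expect_equal(attr(merged, "merge_stats")$n_kept_literal, 1L)
  # error policy aborts listing the label
  expect_error(merge_ontologies(ex, fish,
                                merge_plan(unresolved_policy = "error")),
               "SilBagMysHemurus")
})

test_that("drop policy removes exactly the unresolvable host links", {
  ds <- generate_dataset(generator_config(seed = 23, host_fraction = 1,
                                          unresolvable_host_fraction = 0.4))
  s <- build_mhbi_schema()
  g <- ingest_records(s, ds$specimens, ds$taxa, ds$publications)
  fish <- build_fish_schema()
  for (lb in ds$hosts$label) fish <- add_fish_taxon(fish, lb)
  merged <- merge_ontologies(g, fish,
                             merge_plan(unresolved_policy = "drop"))
  st <- attr(merged, "merge_stats")
  expect_equal(st$n_replaced, ds$manifest$hosts_resolvable)
  expect_equal(st$n_replaced + st$n_dropped, ds$manifest$hosts_total)
  links <- match_triples(merged, predicate = ms("isHostedIn"))
  expect_equal(nrow(links), ds$manifest$hosts_resolvable)
  expect_true(all(!links$is_literal))
})

test_that("host labels resolve per the plan's matching mode", {
  fish <- add_fish_taxon(build_fish_schema(), "SilBagMysHemurus")
  expect_equal(resolve_host("SilBagMysHemurus", fish), fi("SilBagMysHemurus"))
  expect_true(is.na(resolve_host("silbagmyshemurus", fish)))
  norm <- merge_plan(match_mode = "normalized-label")
  expect_equal(resolve_host("silbagmyshemurus", fish, norm),
               fi("SilBagMysHemurus"))
  expect_equal(resolve_host("sil-bag-mys-hemurus", fish, norm),
               fi("SilBagMysHemurus"))
  mapped <- merge_plan(match_mode = "explicit-map",
                       explicit_map = c("catfish host" = fi("SilBagMysHemurus")))
  expect_equal(resolve_host("catfish host", fish, mapped),
               fi("SilBagMysHemurus"))
  # two individuals normalizing identically -> ambiguity error
  fish2 <- add_fish_taxon(fish, "Sil-Bag-Mys-Hemurus")
  expect_error(resolve_host("silbagmyshemurus", fish2, norm), "ambiguous")
})
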