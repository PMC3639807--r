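test_that("the worked-example tables reproduce the expected graph exactly", {
  tabs <- mhbi_example_tables()
  g <- ingest_records(build_mhbi_schema(
    extensions = c("part-hierarchy", "synonym")),
    tabs$specimens, tabs$taxa, tabs$publications)
  # the packaged graph is the same ingestion plus the synonym assertions
  full <- mhbi_example_graph()
  extra <- setdiff(
    paste(full$triples$subject, full$triples$predicate, full$triples$object),
    paste(g$triples$subject, g$triples$predicate, g$triples$object))
  expect_setequal(extra, c(
    paste(mi("BycGharui"), ms("hasSynonym"), mi("SiloGharui")),
    paste(mi("BycGharui"), rdf_type, ms("TaxonName")),
    paste(mi("SiloGharui"), rdf_type, ms("TaxonName"))))
  expect_true(validate_ontology(full)$overall_pass)
})

test_that("the balanced tree yields the arithmetic number of rows", {
  ds <- generate_dataset(generator_config(2, 2, 2, 2, 1, seed = 7))
  expect_equal(ds$manifest$species, 16L)           # 2*2*2*2
  expect_equal(sum(ds$taxa$rank == "Species"), 16L)
  expect_equal(nrow(ds$specimens), 16L)
  expect_equal(ds$manifest$TaxonName, 16L + 8L + 4L + 2L)
})

test_that("generation is deterministic under a seed and leaves the RNG state alone", {
  set.seed(123); before <- .Random.seed
  d1 <- generate_dataset(generator_config(seed = 99))
  expect_identical(.Random.seed, before)
  d2 <- generate_dataset(generator_config(seed = 99))
  expect_identical(d1, d2)
  d3 <- generate_dataset(generator_config(seed = 100))
  expect_false(identical(d1$taxa, d3$taxa))
})

test_that("host_fraction 0 produces no host values", {
  ds <- generate_dataset(generator_config(seed = 3, host_fraction = 0))
  expect_true(all(!nzchar(ds$taxa$host_name)))
  expect_equal(nrow(ds$hosts), 0L)
})

test_that("manifest counts equal ingested per-concept counts across seeds", {
  s <- build_mhbi_schema()
  for (seed in 1:20) {
    ds <- generate_dataset(generator_config(seed = seed,
                                            n_specimens_per_species = 2L))
    g <- ingest_records(s, ds$specimens, ds$taxa, ds$publications)
    count <- function(cls) nrow(match_triples(g, predicate = rdf_type,
                                              object = ms(cls)))
    expect_equal(count("Specimen"), ds$manifest$Specimen,
                 label = paste("seed", seed))
    expect_equal(count("TaxonName"), ds$manifest$TaxonName)
    expect_equal(count("PublicationCitation"), ds$manifest$PublicationCitation)
    expect_true(validate_ontology(g)$overall_pass)
  }
})

test_that("collision injection exercises homonym disambiguation", {
  ds <- generate_dataset(generator_config(seed = 5, inject_collision = TRUE))
  expect_warning(
    g <- ingest_records(build_mhbi_schema(), ds$specimens, ds$taxa,
                        ds$publications),
    "homonymous")
  # all species individuals still distinct
  sp <- match_triples(g, predicate = ms("rank"), object = mi("Species"))
  expect_equal(nrow(sp), sum(ds$taxa$rank == "Species"))
})

test_that("out-of-bound configurations are rejected", {
  expect_error(generator_config(n_orders = 0), "positive")
  expect_error(generator_config(10, 10, 10, 10, 5), "bound")
  expect_error(generator_config(host_fraction = 1.5), "\\[0, 1\\]")
})

test_that("datasets write to CSV and manifest JSON and read back for ingestion", {
  d <- withr::local_tempdir()
  ds <- generate_dataset(generator_config(seed = 4))
  write_dataset(ds, d)
  expect_true(all(file.exists(file.path(
    d, c("specimens.csv", "taxa.csv", "publications.csv", "hosts.csv",
         "manifest.json")))))
  man <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  expect_equal(man$Specimen, ds$manifest$Specimen)
  tabs <- read_annotation_tables(file.path(d, "specimens.csv"),
                                 file.path(d, "taxa.csv"),
                                 file.path(d, "publications.csv"))
  g <- ingest_records(build_mhbi_schema(), tabs$specimens, tabs$taxa,
                      tabs$publications)
  expect_equal(nrow(match_triples(g, predicate = rdf_type,
                                  object = ms("Specimen"))),
               man$Specimen)
})

test_that("all 20 mutants are registered, one per battery test", {
  expect_equal(mutant_ids(), c(paste0("C", 1:8), paste0("K", 1:12)))
  expect_error(mutate_schema("C9"), "arg")
})
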