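test_that("species instance names follow the 3-letter-genus rule", {
  expect_identical(species_instance_name("Bifurcohaptor", "baungi"),
                   "BifBaungi")
  expect_identical(species_instance_name("Bycanistes", "gharui"), "BycGharui")
  expect_identical(species_instance_name("Aaa", "x"), "AaaX")
  expect_error(species_instance_name("Ab", "x"), "at least 3")
  expect_error(species_instance_name("", "x"), "non-empty")
})

test_that("higher taxa keep their full name, title-cased", {
  expect_identical(higher_taxon_instance_name("Genus", "Bifurcohaptor"),
                   "Bifurcohaptor")
  expect_identical(higher_taxon_instance_name("Family", "Ancylodiscoididae"),
                   "Ancylodiscoididae")
  expect_identical(higher_taxon_instance_name("Order", "Dactylogyridea"),
                   "Dactylogyridea")
  expect_identical(higher_taxon_instance_name("Order", "dactylogyridea"),
                   "Dactylogyridea")
  expect_error(higher_taxon_instance_name("Species", "Bifurcohaptor baungi"),
               "species_instance_name")
})

test_that("publication instance names concatenate surnames and year", {
  expect_identical(publication_instance_name(c("Lim", "Furtado"), 1983),
                   "LimFurtado1983")
  expect_identical(publication_instance_name("Jain", 1958), "Jain1958")
  expect_error(publication_instance_name(character(0), 1983), "author")
  expect_error(publication_instance_name("Lim", 83), "4-digit")
})

test_that("specimen labels and identifiers follow the two abbreviation schemes", {
  expect_identical(specimen_instance_name("Bifurcohaptor", "baungi",
                                          "ventral bar", 1),
                   "bif-baungi-vb-i1")
  expect_identical(specimen_instance_name("Bifurcohaptor", "baungi",
                                          "ventral bar", 2),
                   "bif-baungi-vb-i2")
  expect_error(specimen_instance_name("Bifurcohaptor", "baungi",
                                      "ventral bar", 0), "positive")
  expect_error(specimen_instance_name("Bifurcohaptor", "baungi",
                                      "spiral filament", 1),
               "no registered abbreviation")
  expect_identical(specimen_id("Bifurcohaptor", "baungi", "ventral bar"),
                   "j1-bif-bau-ven-bar")
})

test_that("naming is deterministic and collision-scanned across a batch", {
  # determinism
  expect_identical(species_instance_name("Bifurcohaptor", "baungi"),
                   species_instance_name("Bifurcohaptor", "baungi"))
  # distinct pairs -> distinct labels after disambiguation
  genus <- c("Bifurcohaptor", "Bifuroides", "Dactylogyrus")
  epithet <- c("baungi", "baungi", "baungi")
  expect_warning(map <- species_label_map(genus, epithet), "homonymous")
  expect_equal(length(unique(map)), 3L)
  # identical pairs share a label, no warning
  expect_silent(map2 <- species_label_map(c("Aus", "Aus"), c("bus", "bus")))
  expect_equal(length(map2), 1L)
})

test_that("ingesting the worked example yields the expected instance triples", {
  g <- example_graph_cached()
  expect_true(has_triple(g, mi("BifBaungi"), ms("isBelong"),
                         mi("Bifurcohaptor")))
  expect_true(has_triple(g, mi("bif-baungi-vb-i1"), ms("isCitedIn"),
                         mi("LimFurtado1983")))
  expect_true(has_triple(g, mi("BifBaungi"), ms("authorship"),
                         literal("Lim & Furtado")))
  expect_true(has_triple(g, mi("BifBaungi"), ms("year"),
                         literal(1983L, "integer")))
  expect_true(has_triple(g, mi("BifBaungi"), ms("locality"),
                         literal("Tasek Bera, Pahang; Bukit Merah Reservoir, Perak")))
  expect_true(has_triple(g, mi("bif-baungi-vb-i1"), ms("kindOfSpecimen"),
                         mi("Illustration")))
  expect_true(has_triple(g, mi("bif-baungi-vb-i1"), ms("isHaptorBar"),
                         mi("HaptorSclerotisedpartBar")))
  expect_true(has_triple(g, mi("Bifurcohaptor"), ms("rank"), mi("Genus")))
  expect_true(has_triple(g, mi("Bifurcohaptor"), ms("hasSpecies"),
                         mi("BifBaungi")))
  expect_true(has_triple(g, mi("BifBaungi"), ms("isHostedIn"),
                         literal("SilBagMysHemurus")))
  # one typeForName triple per specimen (functionality respected)
  tfn <- match_triples(g, subject = mi("bif-baungi-vb-i1"),
                       predicate = ms("typeForName"))
  expect_equal(nrow(tfn), 1L)
  expect_equal(nrow(check_functional_violations(g, ms("typeForName"))), 0L)
})

test_that("a record without a host emits no isHostedIn triple, all else equal", {
  tabs <- mhbi_example_tables()
  tabs$taxa$host_name <- ""
  s <- build_mhbi_schema()
  g <- ingest_records(s, tabs$specimens, tabs$taxa, tabs$publications)
  expect_equal(nrow(match_triples(g, predicate = ms("isHostedIn"))), 0L)
  with_host <- ingest_records(s, mhbi_example_tables()$specimens,
                              mhbi_example_tables()$taxa,
                              mhbi_example_tables()$publications)
  expect_equal(n_triples(with_host) - n_triples(g), 1L)
})

test_that("every emitted predicate is declared: strict-mode ingest never fails", {
  ds <- generate_dataset(generator_config(seed = 11))
  s <- build_mhbi_schema()
  expect_silent(g <- ingest_records(s, ds$specimens, ds$taxa,
                                    ds$publications))
  expect_true(g$strict)
  # batch of n distinct records -> exactly n individuals typed Specimen
  expect_equal(nrow(match_triples(g, predicate = rdf_type,
                                  object = ms("Specimen"))),
               nrow(ds$specimens))
})

test_that("a dangling citation key aborts ingestion", {
  tabs <- mhbi_example_tables()
  tabs$specimens$citation_key <- "Nobody1900"
  s <- build_mhbi_schema()
  expect_error(ingest_records(s, tabs$specimens, tabs$taxa,
                              tabs$publications), "dangling")
})

test_that("assert_inverse emits the taxon-side part triple on demand", {
  tabs <- mhbi_example_tables()
  s <- build_mhbi_schema()
  g <- ingest_records(s, tabs$specimens, tabs$taxa, tabs$publications,
                      assert_inverse = TRUE)
  expect_true(has_triple(g, mi("BifBaungi"), ms("part"),
                         mi("bif-baungi-vb-i1")))
})

test_that("annotation tables round-trip through CSV files", {
  tabs <- mhbi_example_tables()
  d <- withr::local_tempdir()
  utils::write.csv(tabs$specimens, file.path(d, "s.csv"), row.names = FALSE)
  utils::write.csv(tabs$taxa, file.path(d, "t.csv"), row.names = FALSE)
  utils::write.csv(tabs$publications, file.path(d, "p.csv"), row.names = FALSE)
  rt <- read_annotation_tables(file.path(d, "s.csv"), file.path(d, "t.csv"),
                               file.path(d, "p.csv"))
  g <- ingest_records(build_mhbi_schema(), rt$specimens, rt$taxa,
                      rt$publications)
  expect_true(graphs_equal(
    g, ingest_records(build_mhbi_schema(), tabs$specimens, tabs$taxa,
                      tabs$publications)))
  # missing column is an input error
  expect_error(read_annotation_tables(file.path(d, "t.csv"),
                                      file.path(d, "t.csv"),
                                      file.path(d, "p.csv")),
               "lacks column")
})
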