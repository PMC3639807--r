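test_that("the schema census matches the canonical listing", {
  cen <- schema_census(build_mhbi_schema())
  expect_equal(cen$n_concepts, 7L)
  expect_equal(cen$n_core_properties, 27L)
  bd <- cen$breakdown
  expect_equal(bd$object[bd$concept == "Specimen"], 4L)
  expect_equal(bd$datatype[bd$concept == "Specimen"], 3L)
  expect_equal(bd$object[bd$concept == "TaxonName"], 8L)
  expect_equal(bd$datatype[bd$concept == "TaxonName"], 4L)
  expect_equal(bd$object[bd$concept == "PublicationCitation"], 2L)
  expect_equal(bd$datatype[bd$concept == "PublicationCitation"], 5L)
  expect_equal(bd$datatype[bd$concept == "shared"], 1L)
  # census arithmetic: (4+3) + (8+4) + (2+5) + 1 = 27
  expect_equal(sum(bd$object) + sum(bd$datatype), 27L)
})

test_that("exactly one concept is newly coined; the rest reuse TDWG terms", {
  voc <- mhbi_vocabulary()
  con <- voc[voc$type == "concept", ]
  expect_equal(nrow(con), 7L)
  expect_equal(con$term[con$source == "mhbi-new"], "DiagnosticPartTerms")
})

test_that("controlled-term individuals carry the required members", {
  g <- build_mhbi_schema()
  members <- function(concept) {
    hits <- match_triples(g, predicate = rdf_type, object = ms(concept))
    sort(basename(sub("^.*#", "", hits$subject)))
  }
  expect_setequal(members("DiagnosticPartTerms"),
                  c("HaptorSclerotisedpartBar", "HaptorSclerotisedpartAnchor",
                    "FullImage"))
  expect_true(all(c("Illustration", "DigitalObject", "StillImage") %in%
                    members("KindOfSpecimenTerms")))
  expect_setequal(members("TaxonRankTerms"),
                  c("Species", "Genus", "Family", "Order"))
  expect_true(all(c("JournalArticle", "Book") %in%
                    members("PublicationTypeTerms")))
})

test_that("declared characteristics follow the evidence: typeForName/part and isBelong/hasSpecies", {
  g <- build_mhbi_schema()
  expect_true(has_triple(g, ms("typeForName"), rdf_type,
                         "http://www.w3.org/2002/07/owl#FunctionalProperty"))
  expect_true(has_triple(g, ms("part"), rdf_type,
                         "http://www.w3.org/2002/07/owl#InverseFunctionalProperty"))
  expect_true(has_triple(g, ms("isBelong"), rdf_type,
                         "http://www.w3.org/2002/07/owl#TransitiveProperty"))
  expect_true(has_triple(g, ms("hasSpecies"), rdf_type,
                         "http://www.w3.org/2002/07/owl#TransitiveProperty"))
  expect_true(has_triple(g, ms("isBelong"),
                         "http://www.w3.org/2002/07/owl#inverseOf",
                         ms("hasSpecies")))
  expect_length(transitive_characteristic_conflicts(g), 0L)
})

test_that("extension registration is monotonic and never alters the core", {
  core <- build_mhbi_schema()
  ext <- register_extension_property(core, "hasSynonym", kind = "object",
                                     domain = "TaxonName", range = "TaxonName",
                                     characteristics = "symmetric")
  # every core triple survives, census still 27
  core_tr <- match_triples(core)
  for (i in sample(nrow(core_tr), 20)) {
    obj <- if (core_tr$is_literal[i])
      literal(core_tr$object[i], core_tr$datatype[i]) else core_tr$object[i]
    expect_true(has_triple(ext, core_tr$subject[i], core_tr$predicate[i], obj))
  }
  expect_equal(schema_census(ext)$n_core_properties, 27L)
  expect_equal(schema_census(ext)$n_extension_properties, 1L)
})

test_that("sub-properties inherit domain and range from their super property", {
  g <- build_mhbi_schema(extensions = "part-hierarchy")
  dom <- function(p) match_triples(g, ms(p), "http://www.w3.org/2000/01/rdf-schema#domain")$object
  rng <- function(p) match_triples(g, ms(p), "http://www.w3.org/2000/01/rdf-schema#range")$object
  for (p in c("fullImage", "isBar", "isHaptor")) {
    expect_equal(dom(p), dom("part"))
    expect_equal(rng(p), rng("part"))
    expect_true(has_triple(g, ms(p),
                           "http://www.w3.org/2000/01/rdf-schema#subPropertyOf",
                           ms("part")))
  }
  # sub-property axiom survives a serialization round trip
  rt <- parse_ontology(serialize_ontology(g, "turtle"), "turtle")
  expect_true(has_triple(rt, ms("isBar"),
                         "http://www.w3.org/2000/01/rdf-schema#subPropertyOf",
                         ms("part")))
})

test_that("extension name collisions and bad configurations are rejected", {
  g <- build_mhbi_schema()
  expect_error(register_extension_property(g, "isBelong", kind = "object"),
               "collision")
  expect_error(build_mhbi_schema(extensions = c("synonym", "synonym")),
               "configuration error")
  expect_error(build_mhbi_schema(extensions = "frobnicate"),
               "configuration error")
  expect_error(register_extension_property(g, "badDt", kind = "datatype",
                                           domain = "TaxonName",
                                           range = "string",
                                           characteristics = "transitive"),
               "datatype")
})

test_that("the fish schema has exactly one concept and shares no IRI with the core schema", {
  fish <- build_fish_schema()
  expect_equal(sum(fish$declarations == "concept-class"), 1L)
  mhbi_g <- build_mhbi_schema()
  expect_length(intersect(names(fish$declarations),
                          names(mhbi_g$declarations)), 0L)
  expect_true(validate_ontology(fish)$overall_pass)
  # a host individual is typed under the fish TaxonName concept
  fish <- add_fish_taxon(fish, "SilBagMysHemurus")
  expect_true(has_triple(fish, fi("SilBagMysHemurus"), rdf_type,
                         fi("TaxonName")))
})
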