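# Packaged worked example, parametric synthetic-dataset generator, and the
# 20 targeted schema mutants (one per validator test).

#' The worked example annotation tables
#'
#' The Bifurcohaptor baungi record set: one ventral-bar illustration
#' (bif-baungi-vb-i1), its taxon chain up to order Dactylogyridea, the
#' LimFurtado1983 source publication, the fish host SilBagMysHemurus and
#' the BycGharui/SiloGharui synonym pair (those two labels are used
#' verbatim; the genera they abbreviate are not on record).
#'
#' @return Named list of data frames: `specimens`, `taxa`, `publications`,
#'   `hosts`, `synonyms`.
#' @export
mhbi_example_tables <- function() {
  specimens <- data.frame(
    genus = "Bifurcohaptor", species_epithet = "baungi",
    diagnostic_part = "ventral bar", kind_of_specimen = "illustration",
    image_path = "/images/BIF-BAUNGI-ventral-bar-single.jpg",
    image_description = "",
    sequence_number = 1L, citation_key = "LimFurtado1983",
    stringsAsFactors = FALSE
  )
  taxa <- data.frame(
    rank = c("Species", "Genus", "Family", "Order"),
    name_complete = c("Bifurcohaptor baungi", "Bifurcohaptor",
                      "Ancylodiscoididae", "Dactylogyridea"),
    authorship = c("Lim & Furtado", "Jain", "", ""),
    year = c(1983L, 1958L, NA, NA),
    locality = c("Tasek Bera, Pahang; Bukit Merah Reservoir, Perak",
                 "", "", ""),
    parent_name = c("Bifurcohaptor", "Ancylodiscoididae", "Dactylogyridea",
                    ""),
    host_name = c("SilBagMysHemurus", "", "", ""),
    stringsAsFactors = FALSE
  )
  publications <- data.frame(
    authors = "Lim;Furtado", year = 1983L,
    title = paste("Ancylodiscoidins (Monogenea: Dactylogyridae) from two",
                  "freshwater fish species of Peninsular Malaysia"),
    pub_type = "journal article",
    parent_publication = "Folia Parasitologica",
    number = "30, 377-380",
    stringsAsFactors = FALSE
  )
  hosts <- data.frame(label = "SilBagMysHemurus", stringsAsFactors = FALSE)
  synonyms <- data.frame(a = "BycGharui", b = "SiloGharui",
                         stringsAsFactors = FALSE)
  list(specimens = specimens, taxa = taxa, publications = publications,
       hosts = hosts, synonyms = synonyms)
}

#' The worked example as an ontology graph
#'
#' Builds the schema (with the symmetric `hasSynonym` extension), ingests
#' [mhbi_example_tables()] and asserts the synonym pair. The inverse `part`
#' and the genus-to-family closure links are deliberately not asserted:
#' they are the entailments the inference operations demonstrate.
#'
#' @param extensions Extension sets passed to [build_mhbi_schema()].
#' @return An `ontology_graph` that passes all 20 structural tests.
#' @export
mhbi_example_graph <- function(extensions = c("part-hierarchy", "synonym")) {
  tabs <- mhbi_example_tables()
  g <- build_mhbi_schema(extensions = extensions)
  g <- ingest_records(g, tabs$specimens, tabs$taxa, tabs$publications)
  if ("synonym" %in% extensions) {
    syn <- schema_iri(g, "hasSynonym")
    for (i in seq_len(nrow(tabs$synonyms))) {
      a <- instance_iri(g, tabs$synonyms$a[i])
      b <- instance_iri(g, tabs$synonyms$b[i])
      for (x in c(a, b)) {
        if (is.na(declaration_kind(g, x))) g <- declare(g, x, "individual")
        g <- add_triple(g, x, rdf_iri("type"), schema_iri(g, "TaxonName"))
      }
      g <- add_triple(g, a, syn, b)
    }
  }
  g
}

#' The worked example fish ontology
#'
#' The simple Fish schema plus the single host individual the example
#' needs.
#'
#' @return An `ontology_graph`.
#' @export
mhbi_example_fish <- function() {
  fish <- build_fish_schema()
  for (lb in mhbi_example_tables()$hosts$label)
    fish <- add_fish_taxon(fish, lb)
  fish
}

# -- synthetic data generator -------------------------------------------------

#' Generator configuration
#'
#' Parameters of the synthetic taxonomy/specimen generator. Defaults give a
#' mid-sized but quick dataset; the bounds keep any configuration at desk
#' scale (at most 10^4 individuals).
#'
#' @param n_orders,n_families_per_order,n_genera_per_family,n_species_per_genus
#'   Tree shape (positive integers).
#' @param n_specimens_per_species Images per species (non-negative).
#' @param n_publications Number of source publications (positive).
#' @param host_fraction Fraction of species with a host name.
#' @param unresolvable_host_fraction Fraction of host names that will not
#'   resolve against the generated fish ontology.
#' @param seed Integer RNG seed; the same seed yields identical tables.
#' @param inject_collision Add a second genus sharing a 3-letter prefix and
#'   an epithet with an existing species, to exercise homonym
#'   disambiguation.
#' @return A `mhbi_generator_config`.
#' @export
generator_config <- function(n_orders = 2L, n_families_per_order = 2L,
                             n_genera_per_family = 2L,
                             n_species_per_genus = 2L,
                             n_specimens_per_species = 1L,
                             n_publications = 3L,
                             host_fraction = 0.5,
                             unresolvable_host_fraction = 0,
                             seed = 1L, inject_collision = FALSE) {
  cfg <- list(n_orders = as.integer(n_orders),
              n_families_per_order = as.integer(n_families_per_order),
              n_genera_per_family = as.integer(n_genera_per_family),
              n_species_per_genus = as.integer(n_species_per_genus),
              n_specimens_per_species = as.integer(n_specimens_per_species),
              n_publications = as.integer(n_publications),
              host_fraction = host_fraction,
              unresolvable_host_fraction = unresolvable_host_fraction,
              seed = as.integer(seed),
              inject_collision = isTRUE(inject_collision))
  counts <- unlist(cfg[1:6])
  if (any(counts[c(1:4, 6)] < 1L) || counts[5] < 0L)
    stop("configuration error: tree counts must be positive ",
         "(specimens per species may be 0)", call. = FALSE)
  n_species <- prod(counts[1:4])
  if (n_species * max(1L, counts[5]) + n_species > 1e4)
    stop("configuration error: requested dataset exceeds the 10^4 ",
         "individual bound", call. = FALSE)
  if (host_fraction < 0 || host_fraction > 1 ||
      unresolvable_host_fraction < 0 || unresolvable_host_fraction > 1)
    stop("configuration error: fractions must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "mhbi_generator_config")
}

# Pronounceable pseudo-Latin names; collision-checked within a run.
syllable_name <- function(n_syll, used) {
  con <- c("b", "c", "d", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  repeat {
    s <- paste0(sample(con, n_syll, replace = TRUE),
                sample(vow, n_syll, replace = TRUE), collapse = "")
    if (!s %in% used) return(s)
  }
}

#' Generate a synthetic annotation dataset
#'
#' Emits taxonomically consistent tables shaped by the configuration: a
#' balanced order/family/genus/species tree, specimen rows for each
#' species, publications cited round-robin, and host names for a fraction
#' of species (a sub-fraction of which deliberately resolve to nothing).
#' Deterministic under the seed. The attached `manifest` records the exact
#' expected per-concept individual counts after ingestion.
#'
#' @param config A [generator_config()].
#' @return List of data frames `specimens`, `taxa`, `publications`,
#'   `hosts` plus a `manifest` list of expected counts.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "mhbi_generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  used <- character(0)
  nm <- function(n_syll, suffix = "") {
    base <- syllable_name(n_syll, used)
    used <<- c(used, base)
    paste0(toupper(substr(base, 1, 1)), substring(base, 2), suffix)
  }

  taxa <- list(); specimens <- list(); hosts <- character(0)
  pubs <- do.call(rbind, lapply(seq_len(config$n_publications), function(i) {
    n_auth <- sample(1:3, 1)
    data.frame(
      authors = paste(replicate(n_auth, nm(2)), collapse = ";"),
      year = sample(1900:2010, 1),
      title = paste("Monogeneans of synthetic dataset", i),
      pub_type = "journal article",
      parent_publication = "Synthetic Journal of Parasitology",
      number = as.character(i), stringsAsFactors = FALSE)
  }))
  pub_keys <- vapply(seq_len(nrow(pubs)), function(i)
    publication_instance_name(strsplit(pubs$authors[i], ";")[[1]],
                              pubs$year[i]), "")

  add_taxon <- function(rank, name, parent, host = "") {
    taxa[[length(taxa) + 1L]] <<- data.frame(
      rank = rank, name_complete = name,
      authorship = if (rank == "Species") nm(2) else "",
      year = if (rank == "Species") sample(1900:2010, 1) else NA_integer_,
      locality = "", parent_name = parent, host_name = host,
      stringsAsFactors = FALSE)
  }

  pub_i <- 0L
  species_keys <- character(0)
  for (o in seq_len(config$n_orders)) {
    order_name <- nm(3, "idea")
    add_taxon("Order", order_name, "")
    for (f in seq_len(config$n_families_per_order)) {
      fam_name <- nm(3, "idae")
      add_taxon("Family", fam_name, order_name)
      for (g in seq_len(config$n_genera_per_family)) {
        gen_name <- nm(3, "us")
        add_taxon("Genus", gen_name, fam_name)
        for (s in seq_len(config$n_species_per_genus)) {
          epithet <- tolower(syllable_name(3, used))
          used <- c(used, epithet)
          host <- ""
          if (stats::runif(1) < config$host_fraction) {
            unresolvable <- stats::runif(1) <
              config$unresolvable_host_fraction
            host <- nm(4)
            if (!unresolvable) hosts <- c(hosts, host)
          }
          add_taxon("Species", paste(gen_name, epithet), gen_name, host)
          species_keys <- c(species_keys, paste(gen_name, epithet, sep = "|"))
          for (i in seq_len(config$n_specimens_per_species)) {
            pub_i <- pub_i + 1L
            specimens[[length(specimens) + 1L]] <- data.frame(
              genus = gen_name, species_epithet = epithet,
              diagnostic_part = sample(c("ventral bar", "dorsal bar"), 1),
              kind_of_specimen = "illustration",
              image_path = sprintf("/images/%s-%s-%d.jpg",
                                   toupper(gen_name), epithet, i),
              image_description = "",
              sequence_number = i,
              citation_key = pub_keys[(pub_i - 1L) %% length(pub_keys) + 1L],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  taxa <- do.call(rbind, taxa)
  specimens <- if (length(specimens)) do.call(rbind, specimens) else
    data.frame(genus = character(0), species_epithet = character(0),
               diagnostic_part = character(0), kind_of_specimen = character(0),
               image_path = character(0), image_description = character(0),
               sequence_number = integer(0), citation_key = character(0),
               stringsAsFactors = FALSE)

  if (config$inject_collision && nrow(taxa[taxa$rank == "Species", ])) {
    first_sp <- taxa[taxa$rank == "Species", ][1, ]
    words <- strsplit(first_sp$name_complete, " ")[[1]]
    clash_genus <- paste0(substr(words[1], 1, 3), "oclashus")
    add2 <- data.frame(
      rank = c("Genus", "Species"),
      name_complete = c(clash_genus, paste(clash_genus, words[2])),
      authorship = c("", "Synth"), year = c(NA_integer_, 1999L),
      locality = "", parent_name = c(first_sp$parent_name, clash_genus),
      host_name = "", stringsAsFactors = FALSE)
    taxa <- rbind(taxa, add2)
  }

  n_species <- sum(taxa$rank == "Species")
  manifest <- list(
    Specimen = nrow(specimens),
    TaxonName = nrow(taxa),
    PublicationCitation = nrow(pubs),
    species = n_species,
    genera = sum(taxa$rank == "Genus"),
    families = sum(taxa$rank == "Family"),
    orders = sum(taxa$rank == "Order"),
    hosts_resolvable = length(unique(hosts)),
    hosts_total = sum(nzchar(taxa$host_name))
  )
  list(specimens = specimens, taxa = taxa, publications = pubs,
       hosts = data.frame(label = unique(hosts), stringsAsFactors = FALSE),
       manifest = manifest)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a generated dataset to CSV tables
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `specimens.csv`, `taxa.csv`,
#'   `publications.csv`, `hosts.csv` and `manifest.json`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nmx in c("specimens", "taxa", "publications", "hosts"))
    utils::write.csv(dataset[[nmx]], file.path(dir, paste0(nmx, ".csv")),
                     row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(dataset$manifest,
                                           auto_unbox = TRUE, pretty = TRUE)),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

# -- targeted mutants ---------------------------------------------------------

#' The registered schema mutants
#'
#' @return Character vector of the 20 mutant ids (C1..C8, K1..K12), each a
#'   minimal axiom-level edit of the reference schema on which exactly the
#'   like-named validator test fails.
#' @export
mutant_ids <- function() c(names(CLARITY_TEST_NAMES), names(COHERENCE_TEST_NAMES))

#' Build a targeted schema mutant
#'
#' Applies a minimal axiom-level edit to the reference schema (built with
#' both extension sets, so the property hierarchy and symmetric property
#' exist to mutate) such that the named validator test fails while tests
#' not logically entailed by the edit keep passing.
#'
#' @param target One of [mutant_ids()].
#' @param schema Optional base schema; defaults to
#'   `build_mhbi_schema(extensions = c("part-hierarchy", "synonym"))`.
#' @return The mutated `ontology_graph`.
#' @export
#' @examples
#' bad <- mutate_schema("C8")
#' validate_ontology(bad)$clarity$C8$passed
mutate_schema <- function(target,
                          schema = build_mhbi_schema(
                            extensions = c("part-hierarchy", "synonym"))) {
  target <- match.arg(target, mutant_ids())
  g <- schema
  si <- function(x) schema_iri(g, x)
  switch(target,
    C1 = {
      r <- si("_cardinalityRestriction1")
      g <- add_triple(g, r, rdf_iri("type"), owl_iri("Restriction"))
      g <- add_triple(g, r, owl_iri("onProperty"), si("isBelong"))
      add_triple(g, r, owl_iri("cardinality"), literal(1L, "integer"))
    },
    C2 = {
      add_triple(g, si("KindOfSpecimenTerms"), owl_iri("oneOf"),
                 si("Specimen"))
    },
    C3 = {
      g$imports <- c(g$imports, NS_OWL)
      g
    },
    C4 = {
      add_triple(g, si("Specimen"), rdf_iri("type"), si("TaxonName"))
    },
    C5 = {
      add_triple(g, si("isCitedIn"), rdfs_iri("range"), owl_iri("Class"))
    },
    C6 = {
      add_triple(g, si("Specimen"), rdfs_iri("subClassOf"),
                 rdfs_iri("Resource"))
    },
    C7 = {
      note <- si("curatorNote")
      g <- declare(g, note, "annotation-property")
      add_triple(g, note, rdfs_iri("subPropertyOf"), si("definedTerm"))
    },
    C8 = {
      # keep K6/K7 green: the inverse pair stays functionally consistent
      g <- set_characteristic(g, si("isBelong"), "functional")
      set_characteristic(g, si("hasSpecies"), "inverse-functional")
    },
    K1 = {
      orphan <- si("orphanProp")
      g <- declare(g, orphan, "object-property")
      add_triple(g, orphan, rdfs_iri("range"), si("TaxonName"))
    },
    K2 = {
      sub <- si("TypeSpecimen")
      g <- declare(g, sub, "concept-class")
      g <- add_triple(g, sub, rdfs_iri("subClassOf"), si("Specimen"))
      add_triple(g, si("kindOfSpecimen"), rdfs_iri("domain"), sub)
    },
    K3 = {
      sub <- si("BarTerms")
      g <- declare(g, sub, "concept-class")
      g <- add_triple(g, sub, rdfs_iri("subClassOf"),
                      si("DiagnosticPartTerms"))
      add_triple(g, si("isHaptorBar"), rdfs_iri("range"), sub)
    },
    K4 = {
      bad <- match_triples(g, si("isBar"), rdfs_iri("domain"))
      g <- remove_triples(g, bad)
      add_triple(g, si("isBar"), rdfs_iri("domain"),
                 si("PublicationCitation"))
    },
    K5 = {
      bad <- match_triples(g, si("isHaptor"), rdfs_iri("range"))
      g <- remove_triples(g, bad)
      add_triple(g, si("isHaptor"), rdfs_iri("range"),
                 si("PublicationCitation"))
    },
    K6 = {
      drop_characteristic(g, si("part"), "inverse-functional")
    },
    K7 = {
      drop_characteristic(g, si("typeForName"), "functional")
    },
    K8 = {
      g <- register_extension_property(g, "isMemberOf", kind = "object",
                                       super = "isBelong")
      g <- register_extension_property(g, "hasMember", kind = "object",
                                       super = "hasGenus")
      set_inverse(g, si("isMemberOf"), si("hasMember"))
    },
    K9 = {
      g <- register_extension_property(g, "synonymOf", kind = "object",
                                       domain = "TaxonName",
                                       range = "TaxonName")
      set_inverse(g, si("hasSynonym"), si("synonymOf"))
    },
    K10 = {
      g <- register_extension_property(g, "memberOfGenus", kind = "object",
                                       super = "hasGenus")
      g <- register_extension_property(g, "genusHasMember", kind = "object",
                                       domain = "TaxonName",
                                       range = "TaxonName")
      set_inverse(g, si("memberOfGenus"), si("genusHasMember"))
    },
    K11 = {
      drop_characteristic(g, si("hasSpecies"), "transitive")
    },
    K12 = {
      g <- register_extension_property(g, "describedBy", kind = "object",
                                       domain = "TaxonName",
                                       range = "PublicationCitation")
      g <- register_extension_property(g, "describes", kind = "object",
                                       domain = "TaxonName",
                                       range = "PublicationCitation")
      set_inverse(g, si("describedBy"), si("describes"))
    }
  )
}

#' Run the full mutant selectivity matrix
#'
#' Validates every registered mutant with the full battery and returns the
#' 20 x 20 pass/fail matrix (rows: mutants; columns: tests). The diagonal
#' must fail; off-diagonal failures occur only where the edit logically
#' entails them.
#'
#' @param schema Optional base schema passed to [mutate_schema()].
#' @return Logical matrix of `passed` flags, dimnames mutant id x test id.
#' @export
mutant_selectivity_matrix <- function(schema = build_mhbi_schema(
  extensions = c("part-hierarchy", "synonym"))) {
  ids <- mutant_ids()
  out <- matrix(NA, length(ids), length(ids), dimnames = list(ids, ids))
  for (m in ids) {
    rep <- validate_ontology(mutate_schema(m, schema))
    res <- c(rep$clarity, rep$coherence)
    out[m, ] <- vapply(ids, function(t) res[[t]]$passed, TRUE)
  }
  out
}
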