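# The MHBI controlled vocabulary: 7 concepts and 27 core properties, most
# reused from the TDWG LSID vocabulary, plus the controlled-term individuals
# and the simple Fish schema used for host linking.

mhbi_concepts_table <- function() {
  data.frame(
    name = c("Specimen", "TaxonName", "PublicationCitation",
             "DiagnosticPartTerms", "KindOfSpecimenTerms",
             "TaxonRankTerms", "PublicationTypeTerms"),
    source = c("tdwg", "tdwg", "tdwg", "mhbi-new", "tdwg", "tdwg", "tdwg"),
    description = c(
      "An illustrated image of a monogenean haptoral bar",
      "A single scientific name at any rank",
      "A reference to the publication describing the species",
      "Controlled terms for the monogenean sclerotised hard parts",
      "Controlled terms for the kind of specimen record",
      "Controlled terms for taxonomic rank",
      "Controlled terms for the type of publication"),
    stringsAsFactors = FALSE
  )
}

# Census layout follows the Methods listing: Specimen 4 object + 3 datatype,
# TaxonName 8 object + 4 datatype, PublicationCitation 2 object + 5 datatype,
# definedTerm shared across the four *Terms concepts: 27 in total.
#
# `kind` is the census kind; `declared_kind` is how the standalone schema
# declares the property. They differ only for isHostedIn, which holds host
# names as literals until the ontology is merged with a host ontology and the
# property is promoted to object-valued.
mhbi_properties_table <- function() {
  p <- function(name, local, concept, kind, domain, range,
                characteristics = "", inverse = NA_character_,
                declared_kind = kind)
    data.frame(name = name, local = local, concept = concept, kind = kind,
               declared_kind = declared_kind, domain = domain, range = range,
               characteristics = characteristics, inverse = inverse,
               super = NA_character_, core = TRUE, stringsAsFactors = FALSE)
  rbind(
    p("kindOfSpecimen", "kindOfSpecimen", "Specimen", "object",
      "Specimen", "KindOfSpecimenTerms"),
    p("isHaptorBar", "isHaptorBar", "Specimen", "object",
      "Specimen", "DiagnosticPartTerms"),
    p("isCitedIn", "isCitedIn", "Specimen", "object",
      "Specimen", "PublicationCitation"),
    p("typeForName", "typeForName", "Specimen", "object",
      "Specimen", "TaxonName", "functional", "part"),
    p("specimenId", "specimenId", "Specimen", "datatype", "Specimen", "string"),
    p("imgDir", "imgDir", "Specimen", "datatype", "Specimen", "string"),
    p("imgDescription", "imgDescription", "Specimen", "datatype",
      "Specimen", "string"),

    p("rank", "rank", "TaxonName", "object", "TaxonName", "TaxonRankTerms"),
    p("isBelong", "isBelong", "TaxonName", "object", "TaxonName", "TaxonName",
      "transitive", "hasSpecies"),
    p("part", "part", "TaxonName", "object", "TaxonName", "Specimen",
      "inverse-functional", "typeForName"),
    p("hasSpecies", "hasSpecies", "TaxonName", "object",
      "TaxonName", "TaxonName", "transitive", "isBelong"),
    p("hasGenus", "hasGenus", "TaxonName", "object", "TaxonName", "TaxonName"),
    p("hasFamily", "hasFamily", "TaxonName", "object", "TaxonName", "TaxonName"),
    p("hasOrder", "hasOrder", "TaxonName", "object", "TaxonName", "TaxonName"),
    p("isHostedIn", "isHostedIn", "TaxonName", "object",
      "TaxonName", "string", declared_kind = "datatype"),
    p("nameComplete", "nameComplete", "TaxonName", "datatype",
      "TaxonName", "string"),
    p("authorship", "authorship", "TaxonName", "datatype",
      "TaxonName", "string"),
    p("year", "year", "TaxonName", "datatype", "TaxonName", "integer"),
    p("locality", "locality", "TaxonName", "datatype", "TaxonName", "string"),

    p("pubType", "pubType", "PublicationCitation", "object",
      "PublicationCitation", "PublicationTypeTerms"),
    p("lists", "lists", "PublicationCitation", "object",
      "PublicationCitation", "TaxonName"),
    p("author", "author", "PublicationCitation", "datatype",
      "PublicationCitation", "string"),
    p("year", "publicationYear", "PublicationCitation", "datatype",
      "PublicationCitation", "integer"),
    p("title", "title", "PublicationCitation", "datatype",
      "PublicationCitation", "string"),
    p("parentPublicationString", "parentPublicationString",
      "PublicationCitation", "datatype", "PublicationCitation", "string"),
    p("number", "number", "PublicationCitation", "datatype",
      "PublicationCitation", "string"),

    p("definedTerm", "definedTerm", "shared", "datatype",
      "DiagnosticPartTerms|KindOfSpecimenTerms|TaxonRankTerms|PublicationTypeTerms",
      "string")
  )
}

# Controlled-term individuals per *Terms concept. PublicationTypeTerms and
# KindOfSpecimenTerms are attested only by example members; the remainder up
# to the reported counts are synthetic placeholders (authoritative = FALSE).
mhbi_terms_table <- function() {
  t <- function(concept, label, term, authoritative = TRUE)
    data.frame(concept = concept, label = label, term = term,
               authoritative = authoritative, stringsAsFactors = FALSE)
  rbind(
    t("DiagnosticPartTerms", "HaptorSclerotisedpartBar",
      "haptor sclerotised part bar"),
    t("DiagnosticPartTerms", "HaptorSclerotisedpartAnchor",
      "haptor sclerotised part anchor"),
    t("DiagnosticPartTerms", "FullImage", "full image"),
    t("KindOfSpecimenTerms", "Illustration", "illustration"),
    t("KindOfSpecimenTerms", "DigitalObject", "digital object"),
    t("KindOfSpecimenTerms", "StillImage", "still image"),
    t("TaxonRankTerms", "Species", "species"),
    t("TaxonRankTerms", "Genus", "genus"),
    t("TaxonRankTerms", "Family", "family"),
    t("TaxonRankTerms", "Order", "order"),
    t("PublicationTypeTerms", "JournalArticle", "journal article"),
    t("PublicationTypeTerms", "Book", "book"),
    t("PublicationTypeTerms", "BookSection", "book section", FALSE),
    t("PublicationTypeTerms", "Thesis", "thesis", FALSE)
  )
}

prefix_ns <- function(graph, prefix) {
  if (!prefix %in% names(graph$prefixes)) return(NULL)
  unname(graph$prefixes[[prefix]])
}
schema_ns   <- function(graph) prefix_ns(graph, "mhbi")
instance_ns <- function(graph) prefix_ns(graph, "mhbii")
fish_ns     <- function(graph) prefix_ns(graph, "fish")

schema_iri   <- function(graph, local) iri(schema_ns(graph), local)
instance_iri <- function(graph, local) iri(instance_ns(graph), local)

range_object <- function(graph, range) {
  if (range %in% c("string", "integer")) xsd_datatype_iri(range)
  else schema_iri(graph, range)
}

#' The MHBI vocabulary manifest
#'
#' Machine-readable listing of the vocabulary: one row per concept and per
#' core property, with its source (TDWG LSID reuse or newly coined), census
#' kind, domain/range, OWL characteristics and inverse pairing.
#'
#' @return A data frame with columns `term`, `type`, `concept`, `kind`,
#'   `source`, `domain`, `range`, `characteristics`, `inverse`.
#' @export
mhbi_vocabulary <- function() {
  con <- mhbi_concepts_table()
  props <- mhbi_properties_table()
  rbind(
    data.frame(term = con$name, type = "concept", concept = NA_character_,
               kind = NA_character_, source = con$source,
               domain = NA_character_, range = NA_character_,
               characteristics = NA_character_, inverse = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(term = props$name, type = "property", concept = props$concept,
               kind = props$kind,
               source = ifelse(props$name %in%
                                 c("isHaptorBar", "definedTerm", "part"),
                               "mhbi-new", "tdwg"),
               domain = props$domain, range = props$range,
               characteristics = props$characteristics,
               inverse = props$inverse, stringsAsFactors = FALSE)
  )
}

#' Build the MHBI schema graph
#'
#' Constructs the reference ontology: 7 concept classes, 27 core properties
#' with domains, ranges, OWL characteristics (`typeForName` functional,
#' `part` inverse-functional, `isBelong`/`hasSpecies` a transitive inverse
#' pair) and the controlled-term individuals. `isHostedIn` is declared as a
#' datatype property holding the host name literal; [merge_ontologies()]
#' promotes it to an object property targeting a host ontology.
#'
#' @param base_iri Schema namespace.
#' @param extensions Character vector of bundled extension sets to register
#'   on top of the core: `"part-hierarchy"` (sub-properties `fullImage`,
#'   `isBar`, `isHaptor` under `part`) and/or `"synonym"` (the symmetric
#'   `hasSynonym` property). Unknown or duplicated names are a configuration
#'   error. The core census stays 27 regardless.
#' @return An `ontology_graph` that passes all 20 structural tests.
#' @export
#' @examples
#' schema <- build_mhbi_schema()
#' schema_census(schema)
build_mhbi_schema <- function(base_iri = "http://purl.example.org/mhbi/schema#",
                              extensions = character(0)) {
  known <- c("part-hierarchy", "synonym")
  if (anyDuplicated(extensions) || !all(extensions %in% known))
    stop("configuration error: extensions must be a subset of ",
         paste(known, collapse = ", "), " without duplicates", call. = FALSE)

  g <- ontology_graph(base_iri = base_iri)
  for (cn in mhbi_concepts_table()$name)
    g <- declare(g, schema_iri(g, cn), "concept-class")

  props <- mhbi_properties_table()
  for (i in seq_len(nrow(props))) {
    piri <- schema_iri(g, props$local[i])
    g <- declare(g, piri, paste0(props$declared_kind[i], "-property"))
  }
  for (i in seq_len(nrow(props))) {
    piri <- schema_iri(g, props$local[i])
    for (d in strsplit(props$domain[i], "|", fixed = TRUE)[[1]])
      g <- add_triple(g, piri, rdfs_iri("domain"), schema_iri(g, d))
    g <- add_triple(g, piri, rdfs_iri("range"), range_object(g, props$range[i]))
    if (nzchar(props$characteristics[i]))
      for (ch in strsplit(props$characteristics[i], "|", fixed = TRUE)[[1]])
        g <- set_characteristic(g, piri, ch)
    if (!is.na(props$inverse[i])) {
      qi <- props$local[match(props$inverse[i], props$name)]
      g <- set_inverse(g, piri, schema_iri(g, qi))
    }
  }

  terms <- mhbi_terms_table()
  for (i in seq_len(nrow(terms))) {
    tiri <- instance_iri(g, terms$label[i])
    g <- declare(g, tiri, "individual")
    g <- add_triple(g, tiri, rdf_iri("type"),
                    schema_iri(g, terms$concept[i]))
    g <- add_triple(g, tiri, schema_iri(g, "definedTerm"),
                    literal(terms$term[i]))
  }

  if ("part-hierarchy" %in% extensions)
    for (nm in c("fullImage", "isBar", "isHaptor"))
      g <- register_extension_property(g, nm, kind = "object",
                                       super = "part")
  if ("synonym" %in% extensions)
    g <- register_extension_property(g, "hasSynonym", kind = "object",
                                     domain = "TaxonName",
                                     range = "TaxonName",
                                     characteristics = "symmetric")
  g
}

#' Build the simple Fish schema graph
#'
#' A deliberately minimal host ontology: one `TaxonName` concept in the fish
#' namespace with naming and rank datatype properties, enough to type host
#' individuals such as `SilBagMysHemurus` for linking via `isHostedIn`.
#'
#' @param base_iri Fish namespace.
#' @return An `ontology_graph` (passes all 20 structural tests).
#' @export
build_fish_schema <- function(base_iri = "http://purl.example.org/fish#") {
  g <- ontology_graph(base_iri = base_iri,
                      prefixes = c(rdf = NS_RDF, rdfs = NS_RDFS,
                                   owl = NS_OWL, xsd = NS_XSD,
                                   fish = base_iri))
  taxon <- iri(base_iri, "TaxonName")
  g <- declare(g, taxon, "concept-class")
  for (nm in c("nameComplete", "rank")) {
    piri <- iri(base_iri, nm)
    g <- declare(g, piri, "datatype-property")
    g <- add_triple(g, piri, rdfs_iri("domain"), taxon)
    g <- add_triple(g, piri, rdfs_iri("range"), xsd_iri("string"))
  }
  g
}

#' Add a fish taxon individual to a fish graph
#'
#' @param fish Fish `ontology_graph`.
#' @param label Individual local name (e.g. `"SilBagMysHemurus"`).
#' @param name_complete Optional full scientific name literal.
#' @return The updated graph.
#' @export
add_fish_taxon <- function(fish, label, name_complete = NULL) {
  ns <- fish$base_iri
  ind <- iri(ns, label)
  fish <- declare(fish, ind, "individual")
  fish <- add_triple(fish, ind, rdf_iri("type"), iri(ns, "TaxonName"))
  if (!is.null(name_complete))
    fish <- add_triple(fish, ind, iri(ns, "nameComplete"),
                       literal(name_complete))
  fish
}

#' Register an extension property on a schema
#'
#' Adds a non-core property without touching any existing axiom (extension
#' monotonicity: the core triple set is preserved). When `super` is given
#' and domain/range are not, they are inherited from the super property, as
#' the sub-property hierarchy under `part` requires.
#'
#' @param schema An `ontology_graph` holding the MHBI schema.
#' @param name Property local name; colliding with a core property is an
#'   error.
#' @param kind `"object"` or `"datatype"`.
#' @param domain,range Concept local names (or `"string"`/`"integer"` range
#'   for datatype properties); default inherited from `super`.
#' @param characteristics Character vector drawn from `"functional"`,
#'   `"inverse-functional"`, `"transitive"`, `"symmetric"`.
#' @param inverse Optional local name of an existing property to pair as
#'   inverse.
#' @param super Optional local name of the super property.
#' @return The updated graph.
#' @export
register_extension_property <- function(schema, name,
                                        kind = c("object", "datatype"),
                                        domain = NULL, range = NULL,
                                        characteristics = character(0),
                                        inverse = NULL, super = NULL) {
  kind <- match.arg(kind)
  if (name %in% mhbi_properties_table()$local)
    stop("name collision: '", name, "' is a core property", call. = FALSE)
  piri <- schema_iri(schema, name)
  if (!is.na(declaration_kind(schema, piri)))
    stop("name collision: <", piri, "> is already declared", call. = FALSE)
  if (kind == "datatype" &&
      any(characteristics %in% c("transitive", "symmetric",
                                 "inverse-functional")))
    stop("datatype properties cannot be transitive, symmetric or ",
         "inverse-functional", call. = FALSE)

  schema <- declare(schema, piri, paste0(kind, "-property"))
  siri <- NULL
  if (!is.null(super)) {
    siri <- schema_iri(schema, super)
    if (is.na(declaration_kind(schema, siri)))
      stop("unknown super property '", super, "'", call. = FALSE)
    schema <- add_triple(schema, piri, rdfs_iri("subPropertyOf"), siri)
  }
  dom_iris <- if (!is.null(domain)) {
    vapply(domain, function(d) schema_iri(schema, d), "")
  } else if (!is.null(siri)) property_domains(schema, siri) else character(0)
  rng_iris <- if (!is.null(range)) {
    vapply(range, function(r) range_object(schema, r), "")
  } else if (!is.null(siri)) {
    unique(match_triples(schema, siri, rdfs_iri("range"))$object)
  } else character(0)
  for (d in dom_iris) schema <- add_triple(schema, piri, rdfs_iri("domain"), d)
  for (r in rng_iris) schema <- add_triple(schema, piri, rdfs_iri("range"), r)
  for (ch in characteristics) schema <- set_characteristic(schema, piri, ch)
  if (!is.null(inverse))
    schema <- set_inverse(schema, piri, schema_iri(schema, inverse))
  schema
}

#' Schema census
#'
#' Counts concept-class declarations and core properties (by the canonical
#' manifest) in a graph, with the per-concept object/datatype breakdown of
#' the Methods-style listing.
#'
#' @param graph An `ontology_graph`.
#' @return List with `n_concepts`, `n_core_properties`, `breakdown` (data
#'   frame by concept group) and `n_extension_properties`.
#' @export
schema_census <- function(graph) {
  classes <- declared_of_kind(graph, "concept-class")
  props <- mhbi_properties_table()
  core_iris <- vapply(props$local, function(l) schema_iri(graph, l), "")
  declared_props <- names(graph$declarations)[
    graph$declarations %in% c("object-property", "datatype-property")]
  core_present <- intersect(core_iris, declared_props)
  present <- props[core_iris %in% declared_props, , drop = FALSE]
  groups <- unique(present$concept)
  breakdown <- do.call(rbind, lapply(groups, function(gp) {
    sub <- present[present$concept == gp, , drop = FALSE]
    data.frame(concept = gp,
               object = sum(sub$kind == "object"),
               datatype = sum(sub$kind == "datatype"),
               stringsAsFactors = FALSE)
  }))
  list(
    n_concepts = length(classes),
    n_core_properties = length(core_present),
    breakdown = breakdown,
    n_extension_properties = length(setdiff(declared_props, core_iris))
  )
}

#' Check the vocabulary-level characteristic invariant
#'
#' Transitive properties carry no cardinality-related characteristic: a
#' transitive property that is also functional or inverse-functional is
#' reported.
#'
#' @param graph An `ontology_graph`.
#' @return Character vector of offending property IRIs (empty when clean).
#' @export
transitive_characteristic_conflicts <- function(graph) {
  props <- names(graph$declarations)[
    graph$declarations %in% c("object-property", "datatype-property")]
  bad <- vapply(props, function(p) {
    has_characteristic(graph, p, "transitive") &&
      (has_characteristic(graph, p, "functional") ||
         has_characteristic(graph, p, "inverse-functional"))
  }, TRUE)
  props[bad]
}
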