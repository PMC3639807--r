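# Instance naming conventions and conversion of tabular specimen / taxon /
# publication records into instance triples.
#
# Naming rules: a species individual takes the first three letters of the
# genus plus the title-cased epithet (Bifurcohaptor baungi -> BifBaungi);
# genus, family and order individuals take the full name; a publication is
# the concatenated author surnames plus year (LimFurtado1983); a specimen
# image label is lowercase genus prefix, epithet, part abbreviation and a
# 1-based sequence number (bif-baungi-vb-i1).

ascii_fold <- function(x) {
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  if (anyNA(x)) stop("name is not ASCII-foldable", call. = FALSE)
  gsub("[^A-Za-z0-9 -]", "", x)
}

title_case1 <- function(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))

#' Species instance name
#'
#' First three letters of the genus, title-cased, concatenated with the
#' title-cased epithet: `("Bifurcohaptor", "baungi")` gives `"BifBaungi"`.
#'
#' @param genus Genus name (at least 3 letters).
#' @param epithet Species epithet.
#' @return Instance label (character scalar, no whitespace).
#' @export
species_instance_name <- function(genus, epithet) {
  genus <- trimws(ascii_fold(genus)); epithet <- trimws(ascii_fold(epithet))
  if (!nzchar(genus) || !nzchar(epithet))
    stop("genus and epithet must be non-empty", call. = FALSE)
  if (nchar(genus) < 3L)
    stop("genus must have at least 3 letters: '", genus, "'", call. = FALSE)
  paste0(title_case1(substr(genus, 1, 3)), title_case1(epithet))
}

#' Higher-taxon instance name
#'
#' Genus, family and order individuals are labelled with the full name,
#' title-cased. Species require [species_instance_name()].
#'
#' @param rank `"Genus"`, `"Family"` or `"Order"`.
#' @param name Full taxon name.
#' @return Instance label.
#' @export
higher_taxon_instance_name <- function(rank, name) {
  if (identical(rank, "Species"))
    stop("use species_instance_name() for species", call. = FALSE)
  rank <- match.arg(rank, c("Genus", "Family", "Order"))
  name <- trimws(ascii_fold(name))
  if (!nzchar(name)) stop("name must be non-empty", call. = FALSE)
  title_case1(name)
}

#' Publication instance name
#'
#' Concatenated title-cased author surnames followed by the 4-digit year:
#' `(c("Lim", "Furtado"), 1983)` gives `"LimFurtado1983"`.
#'
#' @param authors Character vector of surnames (at least one).
#' @param year 4-digit integer year.
#' @return Instance label.
#' @export
publication_instance_name <- function(authors, year) {
  authors <- trimws(ascii_fold(authors))
  authors <- authors[nzchar(authors)]
  if (!length(authors)) stop("at least one author surname is required",
                             call. = FALSE)
  year <- as.integer(year)
  if (is.na(year) || year < 1000L || year > 9999L)
    stop("year must be a 4-digit integer", call. = FALSE)
  paste0(paste(vapply(authors, title_case1, ""), collapse = ""), year)
}

#' Diagnostic-part abbreviation table
#'
#' Maps a diagnostic-part label to its specimen-label abbreviation and to
#' the controlled-term individual it annotates. Only the ventral-bar
#' abbreviation is attested in print; the rest follow the same pattern and
#' are extensible via the `parts` argument of [specimen_instance_name()] and
#' [annotate_specimen()].
#'
#' @return Data frame with columns `part`, `abbrev`, `term_label`.
#' @export
part_abbreviations <- function() {
  data.frame(
    part = c("ventral bar", "dorsal bar", "anchor", "full image"),
    abbrev = c("vb", "db", "an", "fi"),
    term_label = c("HaptorSclerotisedpartBar", "HaptorSclerotisedpartBar",
                   "HaptorSclerotisedpartAnchor", "FullImage"),
    stringsAsFactors = FALSE
  )
}

lookup_part <- function(part_label, parts = part_abbreviations()) {
  i <- match(tolower(trimws(part_label)), parts$part)
  if (is.na(i))
    stop("no registered abbreviation for diagnostic part '", part_label, "'",
         call. = FALSE)
  parts[i, , drop = FALSE]
}

#' Specimen instance name
#'
#' Lowercase 3-letter genus prefix, epithet, part abbreviation and 1-based
#' sequence number, hyphen-joined with an `i` sequence marker:
#' `("Bifurcohaptor", "baungi", "ventral bar", 1)` gives
#' `"bif-baungi-vb-i1"`.
#'
#' @inheritParams species_instance_name
#' @param part_label Diagnostic-part label with a registered abbreviation.
#' @param seq Positive integer sequence number.
#' @param parts Abbreviation table, see [part_abbreviations()].
#' @return Instance label.
#' @export
specimen_instance_name <- function(genus, epithet, part_label, seq,
                                   parts = part_abbreviations()) {
  genus <- trimws(ascii_fold(genus)); epithet <- trimws(ascii_fold(epithet))
  if (nchar(genus) < 3L)
    stop("genus must have at least 3 letters", call. = FALSE)
  seq <- as.integer(seq)
  if (is.na(seq) || seq < 1L)
    stop("sequence number must be a positive integer (1-based)", call. = FALSE)
  ab <- lookup_part(part_label, parts)$abbrev
  paste0(tolower(substr(genus, 1, 3)), "-", tolower(epithet), "-", ab,
         "-i", seq)
}

#' Specimen identifier literal
#'
#' A second abbreviation scheme used for the `specimenId` value: a source
#' tag, 3-letter genus and epithet prefixes, and the first three letters of
#' each word of the part label, hyphen-joined
#' (`"j1-bif-bau-ven-bar"`). The source tag is a free configuration knob;
#' its printed value `"j1"` is unexplained in the source material and kept
#' as the default.
#'
#' @inheritParams specimen_instance_name
#' @param source_tag Leading tag, default `"j1"`.
#' @return Identifier string.
#' @export
specimen_id <- function(genus, epithet, part_label, source_tag = "j1") {
  genus <- tolower(trimws(ascii_fold(genus)))
  epithet <- tolower(trimws(ascii_fold(epithet)))
  if (nchar(genus) < 3L || nchar(epithet) < 3L)
    stop("genus and epithet must have at least 3 letters", call. = FALSE)
  words <- strsplit(tolower(trimws(part_label)), "[[:space:]]+")[[1]]
  paste(c(source_tag, substr(genus, 1, 3), substr(epithet, 1, 3),
          substr(words, 1, 3)), collapse = "-")
}

#' Collision-free species labels for a batch
#'
#' Applies [species_instance_name()] to each (genus, epithet) pair and, when
#' two distinct genera collide on the same 3-letter prefix and epithet,
#' disambiguates by lengthening the colliding genus prefixes (4 letters, 5,
#' ...) until unique, with a warning. Identical pairs always map to the same
#' label.
#'
#' @param genus,epithet Parallel character vectors.
#' @return Character vector of labels named by `"genus|epithet"` keys.
#' @export
species_label_map <- function(genus, epithet) {
  key <- paste(genus, epithet, sep = "|")
  uniq <- !duplicated(key)
  g <- genus[uniq]; e <- epithet[uniq]; k <- key[uniq]
  if (!length(g)) return(stats::setNames(character(0), character(0)))
  labels <- unlist(mapply(species_instance_name, g, e,
                          USE.NAMES = FALSE, SIMPLIFY = FALSE))
  width <- rep(3L, length(labels))
  clashed <- character(0)
  repeat {
    dup <- labels %in% labels[duplicated(labels)]
    if (!any(dup)) break
    clashed <- union(clashed, labels[dup])
    width[dup] <- width[dup] + 1L
    if (any(width > nchar(g))) {
      over <- which(dup & width > nchar(g))
      stop("cannot disambiguate homonymous species labels: ",
           paste(k[over], collapse = ", "), call. = FALSE)
    }
    labels[dup] <- mapply(function(gn, ep, w) {
      paste0(title_case1(substr(gn, 1, w)), title_case1(ep))
    }, g[dup], e[dup], width[dup], USE.NAMES = FALSE)
  }
  if (length(clashed))
    warning("homonymous species labels disambiguated by longer genus prefix: ",
            paste(clashed, collapse = ", "), call. = FALSE)
  stats::setNames(labels, k)
}

taxon_instance_label <- function(rank, name, genus = NULL) {
  if (rank == "Species") {
    parts <- strsplit(trimws(name), "[[:space:]]+")[[1]]
    if (length(parts) == 2L)
      species_instance_name(parts[1], parts[2])
    else species_instance_name(genus, name)
  } else higher_taxon_instance_name(rank, name)
}

#' Annotate one specimen record as instance triples
#'
#' Emits the triples describing one haptoral-bar image: the specimen
#' individual with its `kindOfSpecimen`, `isHaptorBar`, `typeForName` and
#' `isCitedIn` links and `specimenId` / `imgDir` / `imgDescription`
#' literals, plus the species individual's `rank`, `isBelong` link to its
#' genus and (when present) `isHostedIn` host literal. The inverse `part`
#' statement is not asserted by default: it is derivable from `typeForName`
#' by inverse materialization ([materialize_inverse()]); set
#' `assert_inverse = TRUE` to emit it.
#'
#' @param graph Graph holding the MHBI schema (triples are added to it).
#' @param record List or one-row data frame with fields `genus`,
#'   `species_epithet`, `diagnostic_part`, `kind_of_specimen`, `image_path`,
#'   `image_description`, `sequence_number`, `citation_key` and optional
#'   `host_name`.
#' @param assert_inverse Also assert the inverse `part` triple.
#' @param parts Part-abbreviation table.
#' @return The updated graph.
#' @export
annotate_specimen <- function(graph, record, assert_inverse = FALSE,
                              parts = part_abbreviations(),
                              label_map = NULL) {
  r <- as.list(record)
  part_row <- lookup_part(r$diagnostic_part, parts)
  spec <- instance_iri(graph,
                       specimen_instance_name(r$genus, r$species_epithet,
                                              r$diagnostic_part,
                                              r$sequence_number, parts))
  key <- paste(r$genus, r$species_epithet, sep = "|")
  taxon_label <- if (!is.null(label_map) && key %in% names(label_map))
    label_map[[key]] else species_instance_name(r$genus, r$species_epithet)
  taxon <- instance_iri(graph, taxon_label)
  kind_label <- gsub("[[:space:]]", "",
                     title_case_words(r$kind_of_specimen))
  kind_ind <- instance_iri(graph, kind_label)
  if (is.na(declaration_kind(graph, kind_ind)))
    stop("unknown kind-of-specimen term '", r$kind_of_specimen, "'",
         call. = FALSE)
  cite <- instance_iri(graph, r$citation_key)
  if (is.na(declaration_kind(graph, cite)))
    stop("dangling reference: citation '", r$citation_key,
         "' is not a known publication individual", call. = FALSE)

  graph <- declare(graph, spec, "individual")
  graph <- add_triple(graph, spec, rdf_iri("type"),
                      schema_iri(graph, "Specimen"))
  graph <- add_triple(graph, spec, schema_iri(graph, "kindOfSpecimen"),
                      kind_ind)
  graph <- add_triple(graph, spec, schema_iri(graph, "isHaptorBar"),
                      instance_iri(graph, part_row$term_label))
  graph <- add_triple(graph, spec, schema_iri(graph, "typeForName"), taxon)
  graph <- add_triple(graph, spec, schema_iri(graph, "isCitedIn"), cite)
  graph <- add_triple(graph, spec, schema_iri(graph, "specimenId"),
                      literal(specimen_id(r$genus, r$species_epithet,
                                          r$diagnostic_part)))
  graph <- add_triple(graph, spec, schema_iri(graph, "imgDir"),
                      literal(r$image_path))
  if (!is.null(r$image_description) && !is.na(r$image_description) &&
      nzchar(r$image_description))
    graph <- add_triple(graph, spec, schema_iri(graph, "imgDescription"),
                        literal(r$image_description))
  if (assert_inverse)
    graph <- add_triple(graph, taxon, schema_iri(graph, "part"), spec)
  graph
}

title_case_words <- function(x) {
  words <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  paste(vapply(words, title_case1, ""), collapse = " ")
}

rank_property_for <- function(rank)
  switch(rank, Species = "hasSpecies", Genus = "hasGenus",
         Family = "hasFamily", Order = "hasOrder")

annotate_taxon <- function(graph, record, label_map = NULL) {
  r <- as.list(record)
  rank <- match.arg(r$rank, c("Species", "Genus", "Family", "Order"))
  label <- NULL
  if (rank == "Species" && !is.null(label_map)) {
    words <- strsplit(trimws(r$name_complete), "[[:space:]]+")[[1]]
    genus <- if (length(words) == 2L) words[1] else r$parent_name
    epithet <- words[length(words)]
    key <- paste(genus, epithet, sep = "|")
    if (key %in% names(label_map)) label <- label_map[[key]]
  }
  if (is.null(label))
    label <- taxon_instance_label(rank, r$name_complete, r$parent_name)
  ind <- instance_iri(graph, label)
  kind <- declaration_kind(graph, ind)
  if (is.na(kind)) graph <- declare(graph, ind, "individual")
  graph <- add_triple(graph, ind, rdf_iri("type"),
                      schema_iri(graph, "TaxonName"))
  graph <- add_triple(graph, ind, schema_iri(graph, "rank"),
                      instance_iri(graph, rank))
  graph <- add_triple(graph, ind, schema_iri(graph, "nameComplete"),
                      literal(r$name_complete))
  if (!is.null(r$authorship) && !is.na(r$authorship) && nzchar(r$authorship))
    graph <- add_triple(graph, ind, schema_iri(graph, "authorship"),
                        literal(r$authorship))
  if (!is.null(r$year) && !is.na(r$year))
    graph <- add_triple(graph, ind, schema_iri(graph, "year"),
                        literal(as.integer(r$year), "integer"))
  if (!is.null(r$locality) && !is.na(r$locality) && nzchar(r$locality))
    graph <- add_triple(graph, ind, schema_iri(graph, "locality"),
                        literal(r$locality))
  if (!is.null(r$host_name) && !is.na(r$host_name) && nzchar(r$host_name))
    graph <- add_triple(graph, ind, schema_iri(graph, "isHostedIn"),
                        literal(r$host_name))
  if (!is.null(r$parent_name) && !is.na(r$parent_name) &&
      nzchar(r$parent_name) && rank != "Order") {
    parent_rank <- switch(rank, Species = "Genus", Genus = "Family",
                          Family = "Order")
    parent <- instance_iri(
      graph, higher_taxon_instance_name(parent_rank, r$parent_name))
    if (is.na(declaration_kind(graph, parent)))
      graph <- declare(graph, parent, "individual")
    graph <- add_triple(graph, parent, rdf_iri("type"),
                        schema_iri(graph, "TaxonName"))
    graph <- add_triple(graph, ind, schema_iri(graph, "isBelong"), parent)
    if (rank == "Species")
      graph <- add_triple(graph, parent, schema_iri(graph, "hasSpecies"), ind)
  }
  graph
}

annotate_publication <- function(graph, record) {
  r <- as.list(record)
  authors <- strsplit(r$authors, ";", fixed = TRUE)[[1]]
  label <- publication_instance_name(authors, r$year)
  ind <- instance_iri(graph, label)
  if (is.na(declaration_kind(graph, ind)))
    graph <- declare(graph, ind, "individual")
  graph <- add_triple(graph, ind, rdf_iri("type"),
                      schema_iri(graph, "PublicationCitation"))
  ptype_label <- gsub("[[:space:]]", "", title_case_words(r$pub_type))
  graph <- add_triple(graph, ind, schema_iri(graph, "pubType"),
                      instance_iri(graph, ptype_label))
  for (a in trimws(authors))
    graph <- add_triple(graph, ind, schema_iri(graph, "author"), literal(a))
  graph <- add_triple(graph, ind, schema_iri(graph, "publicationYear"),
                      literal(as.integer(r$year), "integer"))
  graph <- add_triple(graph, ind, schema_iri(graph, "title"),
                      literal(r$title))
  if (!is.null(r$parent_publication) && !is.na(r$parent_publication) &&
      nzchar(r$parent_publication))
    graph <- add_triple(graph, ind,
                        schema_iri(graph, "parentPublicationString"),
                        literal(r$parent_publication))
  if (!is.null(r$number) && !is.na(r$number) && nzchar(as.character(r$number)))
    graph <- add_triple(graph, ind, schema_iri(graph, "number"),
                        literal(as.character(r$number)))
  graph
}

#' Ingest tabular records into an ontology graph
#'
#' Converts the delimited tables (one row per specimen, taxon or
#' publication) into instance triples on top of a built schema, applying
#' the deterministic naming rules. Publications are ingested first (so
#' citation keys resolve), then taxa bottom-up, then specimens.
#'
#' @param schema An `ontology_graph` from [build_mhbi_schema()].
#' @param specimens,taxa,publications Data frames (see
#'   [read_annotation_tables()] for the column contract).
#' @param assert_inverse Assert inverse `part` triples, see
#'   [annotate_specimen()].
#' @param parts Part-abbreviation table.
#' @return The graph with all instance triples added.
#' @export
ingest_records <- function(schema, specimens, taxa, publications,
                           assert_inverse = FALSE,
                           parts = part_abbreviations()) {
  g <- schema
  sp_taxa <- taxa[taxa$rank == "Species", , drop = FALSE]
  sp_words <- strsplit(trimws(sp_taxa$name_complete), "[[:space:]]+")
  sp_genus <- ifelse(lengths(sp_words) == 2L,
                     vapply(sp_words, `[`, "", 1L), sp_taxa$parent_name)
  sp_epithet <- vapply(sp_words, function(w) w[length(w)], "")
  label_map <- species_label_map(c(sp_genus, specimens$genus),
                                 c(sp_epithet, specimens$species_epithet))
  for (i in seq_len(nrow(publications)))
    g <- annotate_publication(g, publications[i, , drop = FALSE])
  rank_order <- c("Order", "Family", "Genus", "Species")
  taxa <- taxa[order(match(taxa$rank, rank_order)), , drop = FALSE]
  for (i in seq_len(nrow(taxa)))
    g <- annotate_taxon(g, taxa[i, , drop = FALSE], label_map = label_map)
  for (i in seq_len(nrow(specimens)))
    g <- annotate_specimen(g, specimens[i, , drop = FALSE],
                           assert_inverse = assert_inverse, parts = parts,
                           label_map = label_map)
  g
}

SPECIMEN_COLUMNS <- c("genus", "species_epithet", "diagnostic_part",
                      "kind_of_specimen", "image_path", "image_description",
                      "sequence_number", "citation_key")
TAXON_COLUMNS <- c("rank", "name_complete", "authorship", "year", "locality",
                   "parent_name", "host_name")
PUBLICATION_COLUMNS <- c("authors", "year", "title", "pub_type",
                         "parent_publication", "number")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("input error: ", what, " table lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read annotation tables from CSV files
#'
#' Reads the three (optionally four) comma-separated UTF-8 tables with
#' header rows: specimens (`genus`, `species_epithet`, `diagnostic_part`,
#' `kind_of_specimen`, `image_path`, `image_description`,
#' `sequence_number`, `citation_key`), taxa (`rank`, `name_complete`,
#' `authorship`, `year`, `locality`, `parent_name`, `host_name`) and
#' publications (`authors` with `;`-separated surnames, `year`, `title`,
#' `pub_type`, `parent_publication`, `number`).
#'
#' @param specimens,taxa,publications File paths.
#' @return Named list of data frames.
#' @export
read_annotation_tables <- function(specimens, taxa, publications) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    encoding = "UTF-8")
  list(
    specimens = check_columns(rd(specimens), SPECIMEN_COLUMNS, "specimens"),
    taxa = check_columns(rd(taxa), TAXON_COLUMNS, "taxa"),
    publications = check_columns(rd(publications), PUBLICATION_COLUMNS,
                                 "publications")
  )
}
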