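# Linking the parasite ontology to a host (Fish) ontology.
#
# The standalone MHBI schema keeps host names as literals on isHostedIn.
# Merging redefines isHostedIn as an object property whose range is the
# fish TaxonName concept and rewrites each resolvable host literal into an
# object link to the fish individual, leaving every other axiom of both
# sources untouched.

#' Merge plan for the host link
#'
#' @param match_mode `"exact-label"` (compare instance local names),
#'   `"normalized-label"` (case-fold and strip hyphens/spaces first) or
#'   `"explicit-map"` (consult `explicit_map` first, fall back to exact).
#' @param explicit_map Optional named character vector, host label -> fish
#'   individual IRI.
#' @param unresolved_policy What to do with a host literal that matches no
#'   fish individual: `"keep-literal"` (default; lossless, with a warning),
#'   `"drop"`, or `"error"` (abort listing the unresolved labels).
#' @return A `mhbi_merge_plan`.
#' @export
merge_plan <- function(match_mode = c("exact-label", "normalized-label",
                                      "explicit-map"),
                       explicit_map = NULL,
                       unresolved_policy = c("keep-literal", "drop", "error")) {
  structure(list(
    match_mode = match.arg(match_mode),
    explicit_map = explicit_map,
    unresolved_policy = match.arg(unresolved_policy)
  ), class = "mhbi_merge_plan")
}

normalize_label <- function(x) tolower(gsub("[- _]", "", x))

#' Resolve a host label against a fish ontology
#'
#' @param label Host name literal from an `isHostedIn` statement.
#' @param fish Fish `ontology_graph`.
#' @param plan A [merge_plan()].
#' @return Fish individual IRI, or `NA_character_` when unresolved. Two or
#'   more candidates under normalization raise an ambiguity error listing
#'   them.
#' @export
resolve_host <- function(label, fish, plan = merge_plan()) {
  if (plan$match_mode == "explicit-map" && !is.null(plan$explicit_map) &&
      label %in% names(plan$explicit_map))
    return(unname(plan$explicit_map[[label]]))
  individuals <- declared_of_kind(fish, "individual")
  locals <- vapply(individuals, iri_local_name, "")
  hits <- if (plan$match_mode == "normalized-label") {
    individuals[normalize_label(locals) == normalize_label(label)]
  } else {
    individuals[locals == label]
  }
  if (length(hits) > 1L)
    stop("ambiguous host label '", label, "': matches ",
         paste(sprintf("<%s>", hits), collapse = ", "), call. = FALSE)
  if (length(hits) == 1L) hits else NA_character_
}

#' Merge the MHBI ontology with a host ontology
#'
#' Takes the union of both graphs, promotes `isHostedIn` from a datatype to
#' an object property (domain: MHBI `TaxonName`, range: fish `TaxonName`)
#' and converts each resolvable host literal into an object link to the
#' matching fish individual. Neither source schema is otherwise altered;
#' fish IRIs keep their own namespace.
#'
#' @param mhbi MHBI `ontology_graph` (schema + instances).
#' @param fish Fish `ontology_graph`.
#' @param plan A [merge_plan()].
#' @return The merged `ontology_graph`, with a bookkeeping list in
#'   `attr(, "merge_stats")`: `n_replaced`, `n_kept_literal`, `n_dropped`,
#'   `unresolved` labels.
#' @export
#' @examples
#' ex <- mhbi_example_graph()
#' fish <- mhbi_example_fish()
#' merged <- merge_ontologies(ex, fish)
#' attr(merged, "merge_stats")$n_replaced
merge_ontologies <- function(mhbi, fish, plan = merge_plan()) {
  host_p <- schema_iri(mhbi, "isHostedIn")
  fish_taxon <- iri(fish$base_iri, "TaxonName")

  merged <- graph_union(mhbi, fish)

  host_triples <- match_triples(merged, predicate = host_p)
  lit <- host_triples[host_triples$is_literal, , drop = FALSE]

  resolved <- vapply(lit$object, function(lb)
    resolve_host(lb, fish, plan), "")
  unresolved <- unique(lit$object[is.na(resolved)])
  if (length(unresolved) && plan$unresolved_policy == "error")
    stop("merge aborted; unresolved host label(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  if (length(unresolved) && plan$unresolved_policy == "keep-literal")
    warning("unresolved host label(s) kept as literals: ",
            paste(unresolved, collapse = ", "), call. = FALSE)

  # promote the property declaration
  merged <- undeclare(merged, host_p)
  merged <- declare(merged, host_p, "object-property")
  old_range <- match_triples(merged, host_p, rdfs_iri("range"))
  merged <- remove_triples(merged, old_range)
  merged <- add_triple(merged, host_p, rdfs_iri("range"), fish_taxon)

  ok <- !is.na(resolved)
  merged <- remove_triples(merged, lit[ok, , drop = FALSE])
  for (i in which(ok))
    merged <- add_triple(merged, lit$subject[i], host_p, resolved[i])
  n_dropped <- 0L
  if (length(unresolved) && plan$unresolved_policy == "drop") {
    merged <- remove_triples(merged, lit[!ok, , drop = FALSE])
    n_dropped <- sum(!ok)
  }

  attr(merged, "merge_stats") <- list(
    n_replaced = sum(ok),
    n_kept_literal = if (plan$unresolved_policy == "keep-literal")
      sum(!ok) else 0L,
    n_dropped = n_dropped,
    unresolved = unresolved
  )
  merged
}
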