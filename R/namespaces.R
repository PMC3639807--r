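# Namespace registry and IRI helpers.
#
# The schema never appeared with a published namespace, so the bases are
# configurable placeholders; schema terms, instance individuals and the fish
# ontology each get their own prefix so merged graphs stay disentangled.

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"

#' Default namespace prefixes
#'
#' Prefix map used by new graphs: the W3C core namespaces plus the project
#' namespaces for the MHBI schema (`mhbi`), MHBI instances (`mhbii`) and the
#' simple Fish ontology (`fish`).
#'
#' @param base_iri Base IRI of the MHBI schema namespace (must end in `#` or
#'   `/`). Instance and fish namespaces are derived from it unless the full
#'   map is supplied to [ontology_graph()] directly.
#' @return Named character vector mapping prefix to namespace IRI.
#' @export
default_prefixes <- function(base_iri = "http://purl.example.org/mhbi/schema#") {
  stopifnot(is.character(base_iri), length(base_iri) == 1L, nzchar(base_iri))
  root <- sub("schema#?$", "", base_iri)
  if (identical(root, base_iri)) root <- sub("#$", "/", base_iri)
  c(
    rdf   = NS_RDF,
    rdfs  = NS_RDFS,
    owl   = NS_OWL,
    xsd   = NS_XSD,
    mhbi  = base_iri,
    mhbii = paste0(root, "instance#"),
    fish  = paste0(sub("mhbi/?$", "", sub("instance#?$|schema#?$", "", root)), "fish#")
  )
}

iri <- function(namespace, local_name) {
  if (!nzchar(local_name) || grepl("[[:space:]]", local_name))
    stop("local name must be non-empty and contain no whitespace: ",
         deparse(local_name), call. = FALSE)
  paste0(namespace, local_name)
}

rdf_iri  <- function(x) iri(NS_RDF, x)
rdfs_iri <- function(x) iri(NS_RDFS, x)
owl_iri  <- function(x) iri(NS_OWL, x)
xsd_iri  <- function(x) iri(NS_XSD, x)

iri_local_name <- function(x) sub("^.*[#/]", "", x)
iri_namespace  <- function(x) sub("([#/])[^#/]*$", "\\1", x)

is_builtin_namespace <- function(x) {
  startsWith(x, NS_RDF) | startsWith(x, NS_RDFS) |
    startsWith(x, NS_OWL) | startsWith(x, NS_XSD)
}

# Built-in predicates a well-formed OWL graph may use without declaring.
builtin_predicates <- function() {
  c(rdf_iri("type"),
    rdfs_iri("domain"), rdfs_iri("range"), rdfs_iri("subClassOf"),
    rdfs_iri("subPropertyOf"), rdfs_iri("label"), rdfs_iri("comment"),
    owl_iri("inverseOf"), owl_iri("imports"), owl_iri("oneOf"),
    owl_iri("onProperty"), owl_iri("cardinality"),
    owl_iri("minCardinality"), owl_iri("maxCardinality"))
}

# Built-in predicates that legitimately take literal objects.
builtin_literal_predicates <- function() {
  c(rdfs_iri("label"), rdfs_iri("comment"),
    owl_iri("cardinality"), owl_iri("minCardinality"), owl_iri("maxCardinality"))
}
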