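#' Minimal RDF triple graph with OWL node-kind tagging
#'
#' An `ontology_graph` is a set of (subject, predicate, object) triples plus a
#' declarations map tagging each project IRI with its node kind (concept
#' class, object/datatype/annotation property, or individual), a list of
#' imported ontology IRIs, a base IRI and a prefix map. Triples have set
#' semantics: adding the same statement twice leaves the graph unchanged.
#'
#' Blank nodes are not supported outside restriction axioms: every entity is
#' named, mirroring the fully named graphs the annotation scheme produces.
#'
#' @param base_iri Ontology base IRI (also the default schema namespace).
#' @param prefixes Named character vector prefix -> namespace; defaults to
#'   [default_prefixes()] of `base_iri`.
#' @param strict If `TRUE` (default), predicates must be declared properties
#'   or OWL/RDF built-ins, and literal objects may only appear on datatype or
#'   annotation predicates. Use `strict = FALSE` when loading third-party
#'   files.
#' @return An object of class `ontology_graph`.
#' @export
#' @examples
#' g <- ontology_graph()
#' g <- declare(g, "http://purl.example.org/mhbi/schema#Specimen", "concept-class")
#' n_triples(g)
ontology_graph <- function(base_iri = "http://purl.example.org/mhbi/schema#",
                           prefixes = default_prefixes(base_iri),
                           strict = TRUE) {
  structure(
    list(
      triples = empty_triples(),
      declarations = character(0),
      imports = character(0),
      base_iri = base_iri,
      prefixes = prefixes,
      strict = strict
    ),
    class = "ontology_graph"
  )
}

empty_triples <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), is_literal = logical(0),
             datatype = character(0), stringsAsFactors = FALSE)
}

NODE_KINDS <- c("concept-class", "object-property", "datatype-property",
                "annotation-property", "individual")

#' Typed RDF literal
#'
#' Wraps a value as an RDF literal for use as a triple object. Table values
#' in the annotation scheme are plain text except `year`, which is an
#' integer.
#'
#' @param value Scalar value (character, numeric or logical).
#' @param datatype `"string"` or `"integer"`.
#' @return An object of class `rdf_literal`.
#' @export
literal <- function(value, datatype = if (is.numeric(value)) "integer" else "string") {
  datatype <- match.arg(datatype, c("string", "integer"))
  if (datatype == "integer") {
    value <- suppressWarnings(as.integer(value))
    if (is.na(value)) stop("integer literal is not coercible to integer", call. = FALSE)
  }
  structure(list(value = as.character(value), datatype = datatype),
            class = "rdf_literal")
}

is_literal_obj <- function(x) inherits(x, "rdf_literal")

triple_keys <- function(tr) {
  paste(tr$subject, tr$predicate, tr$object, tr$is_literal, tr$datatype,
        sep = "\r")
}

#' @export
print.ontology_graph <- function(x, ...) {
  kinds <- table(factor(x$declarations, levels = NODE_KINDS))
  cat("<ontology_graph> ", nrow(x$triples), " triples, ",
      length(x$declarations), " declarations (",
      paste(sprintf("%s: %d", names(kinds), as.integer(kinds)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Number of triples in a graph
#' @param graph An `ontology_graph`.
#' @return Integer triple count (declaration map entries are not triples).
#' @export
n_triples <- function(graph) nrow(graph$triples)

#' Declare an IRI's node kind
#'
#' Registers an IRI as a concept class, property or individual. Node kinds
#' are mutually exclusive: re-declaring an IRI under a different kind is an
#' error (this exclusivity underpins the no-meta-class clarity check).
#'
#' @param graph An `ontology_graph`.
#' @param iri Absolute IRI to declare.
#' @param kind One of `"concept-class"`, `"object-property"`,
#'   `"datatype-property"`, `"annotation-property"`, `"individual"`.
#' @return The updated graph.
#' @export
declare <- function(graph, iri, kind) {
  kind <- match.arg(kind, NODE_KINDS)
  stopifnot(inherits(graph, "ontology_graph"), is.character(iri), length(iri) == 1L)
  existing <- graph$declarations[iri]
  if (!is.na(existing) && existing != kind)
    stop("declaration conflict: <", iri, "> already declared as ", existing,
         ", cannot redeclare as ", kind, call. = FALSE)
  graph$declarations[iri] <- kind
  graph
}

#' Remove an IRI declaration
#'
#' Retracts the node-kind declaration of an IRI (used by ontology merging to
#' redefine a property's kind). Triples mentioning the IRI are untouched.
#'
#' @inheritParams declare
#' @return The updated graph.
#' @export
undeclare <- function(graph, iri) {
  graph$declarations <- graph$declarations[names(graph$declarations) != iri]
  graph
}

declaration_kind <- function(graph, iri) {
  k <- graph$declarations[iri]
  if (is.na(k)) NA_character_ else unname(k)
}

declared_of_kind <- function(graph, kind) {
  names(graph$declarations)[graph$declarations == kind]
}

#' Add one triple to a graph
#'
#' Adds a single statement. In strict mode the predicate must be a declared
#' property or an OWL/RDF built-in, and a literal object is only allowed on
#' datatype or annotation predicates. Adding a triple that is already present
#' is a no-op (set semantics).
#'
#' @param graph An `ontology_graph`.
#' @param subject Subject IRI (a literal subject is a structural error).
#' @param predicate Predicate IRI.
#' @param object Object IRI (character) or [literal()].
#' @return The updated graph.
#' @export
add_triple <- function(graph, subject, predicate, object) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (is_literal_obj(subject))
    stop("structural error: a literal cannot be the subject of a triple",
         call. = FALSE)
  if (is_literal_obj(predicate))
    stop("structural error: a literal cannot be the predicate of a triple",
         call. = FALSE)
  stopifnot(is.character(subject), length(subject) == 1L,
            is.character(predicate), length(predicate) == 1L)

  obj_is_lit <- is_literal_obj(object)
  if (graph$strict) {
    pkind <- declaration_kind(graph, predicate)
    builtin <- predicate %in% builtin_predicates() ||
      is_builtin_namespace(predicate)
    if (is.na(pkind) && !builtin)
      stop("declaration error: predicate <", predicate,
           "> is not a declared property (strict mode)", call. = FALSE)
    if (!is.na(pkind) && !pkind %in% c("object-property", "datatype-property",
                                       "annotation-property"))
      stop("declaration error: <", predicate, "> is declared as ", pkind,
           " and cannot be used as a predicate", call. = FALSE)
    if (obj_is_lit) {
      lit_ok <- (!is.na(pkind) && pkind %in% c("datatype-property",
                                               "annotation-property")) ||
        predicate %in% builtin_literal_predicates()
      if (!lit_ok)
        stop("structural error: literal object on non-datatype predicate <",
             predicate, ">", call. = FALSE)
    }
  }

  row <- if (obj_is_lit) {
    data.frame(subject = subject, predicate = predicate, object = object$value,
               is_literal = TRUE, datatype = object$datatype,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(is.character(object), length(object) == 1L)
    data.frame(subject = subject, predicate = predicate, object = object,
               is_literal = FALSE, datatype = NA_character_,
               stringsAsFactors = FALSE)
  }
  if (!triple_keys(row) %in% triple_keys(graph$triples))
    graph$triples <- rbind(graph$triples, row)
  graph
}

#' Add several triples given as a data frame
#'
#' Bulk variant of [add_triple()] taking rows in the internal triple layout
#' (`subject`, `predicate`, `object`, `is_literal`, `datatype`).
#'
#' @param graph An `ontology_graph`.
#' @param triples Data frame of triples.
#' @return The updated graph.
#' @export
add_triples <- function(graph, triples) {
  for (i in seq_len(nrow(triples))) {
    obj <- if (triples$is_literal[i])
      literal(triples$object[i], triples$datatype[i]) else triples$object[i]
    graph <- add_triple(graph, triples$subject[i], triples$predicate[i], obj)
  }
  graph
}

#' Triple-pattern matching
#'
#' Returns the triples unifying with a pattern; `NULL` components are
#' wildcards, so `match_triples(g)` returns every triple. A fully ground
#' pattern returns at most one row (set semantics).
#'
#' @param graph An `ontology_graph`.
#' @param subject,predicate Optional IRI to match.
#' @param object Optional IRI or [literal()] to match.
#' @return Data frame of matching triples (possibly zero rows).
#' @export
#' @examples
#' g <- ontology_graph(strict = FALSE)
#' g <- add_triple(g, "http://x#a", "http://x#p", "http://x#b")
#' match_triples(g, predicate = "http://x#p")
match_triples <- function(graph, subject = NULL, predicate = NULL, object = NULL) {
  tr <- graph$triples
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(subject))   keep <- keep & tr$subject == subject
  if (!is.null(predicate)) keep <- keep & tr$predicate == predicate
  if (!is.null(object)) {
    if (is_literal_obj(object)) {
      keep <- keep & tr$is_literal & tr$object == object$value &
        tr$datatype == object$datatype
    } else {
      keep <- keep & !tr$is_literal & tr$object == object
    }
  }
  tr[keep, , drop = FALSE]
}

#' Does the graph contain a given triple?
#' @inheritParams match_triples
#' @return `TRUE` if the ground triple is present.
#' @export
has_triple <- function(graph, subject, predicate, object) {
  nrow(match_triples(graph, subject, predicate, object)) > 0L
}

#' Triple-set equality of two graphs
#'
#' Compares the triple sets only (declarations are compared separately by
#' callers that need them); order never matters.
#'
#' @param a,b `ontology_graph` objects.
#' @return `TRUE` iff both graphs hold exactly the same statements.
#' @export
graphs_equal <- function(a, b) {
  setequal(triple_keys(a$triples), triple_keys(b$triples))
}

#' Merge the raw contents of two graphs
#'
#' Set-union of triples, union of declarations (conflicting kinds raise an
#' error), union of imports and prefixes. This is plumbing; ontology-aware
#' merging with host-link promotion is [merge_ontologies()].
#'
#' @param a,b `ontology_graph` objects.
#' @return Combined `ontology_graph` (base IRI and strictness of `a`).
#' @export
graph_union <- function(a, b) {
  out <- a
  for (iri in names(b$declarations))
    out <- declare(out, iri, unname(b$declarations[iri]))
  keep <- !triple_keys(b$triples) %in% triple_keys(a$triples)
  out$triples <- rbind(a$triples, b$triples[keep, , drop = FALSE])
  out$imports <- union(a$imports, b$imports)
  newpref <- b$prefixes[!names(b$prefixes) %in% names(a$prefixes)]
  out$prefixes <- c(a$prefixes, newpref)
  out
}

remove_triples <- function(graph, rows) {
  if (nrow(rows) == 0L) return(graph)
  keep <- !triple_keys(graph$triples) %in% triple_keys(rows)
  graph$triples <- graph$triples[keep, , drop = FALSE]
  graph
}

# -- characteristic helpers ---------------------------------------------------

CHARACTERISTIC_CLASSES <- c(
  functional           = "FunctionalProperty",
  `inverse-functional` = "InverseFunctionalProperty",
  transitive           = "TransitiveProperty",
  symmetric            = "SymmetricProperty"
)

#' Assert an OWL property characteristic
#'
#' @param graph An `ontology_graph`.
#' @param property Property IRI.
#' @param characteristic One of `"functional"`, `"inverse-functional"`,
#'   `"transitive"`, `"symmetric"`.
#' @return The updated graph.
#' @export
set_characteristic <- function(graph, property, characteristic) {
  characteristic <- match.arg(characteristic, names(CHARACTERISTIC_CLASSES))
  kind <- declaration_kind(graph, property)
  if (identical(kind, "datatype-property") &&
      characteristic %in% c("inverse-functional", "transitive", "symmetric"))
    stop("datatype property <", property, "> cannot be ", characteristic,
         call. = FALSE)
  add_triple(graph, property, rdf_iri("type"),
             owl_iri(CHARACTERISTIC_CLASSES[[characteristic]]))
}

has_characteristic <- function(graph, property, characteristic) {
  has_triple(graph, property, rdf_iri("type"),
             owl_iri(CHARACTERISTIC_CLASSES[[characteristic]]))
}

drop_characteristic <- function(graph, property, characteristic) {
  remove_triples(graph, match_triples(
    graph, property, rdf_iri("type"),
    owl_iri(CHARACTERISTIC_CLASSES[[characteristic]])))
}

#' Declare two properties as mutual inverses
#' @param graph An `ontology_graph`.
#' @param p,q Property IRIs.
#' @return The updated graph.
#' @export
set_inverse <- function(graph, p, q) {
  for (x in c(p, q))
    if (identical(declaration_kind(graph, x), "datatype-property"))
      stop("datatype property <", x, "> cannot carry an inverse", call. = FALSE)
  graph <- add_triple(graph, p, owl_iri("inverseOf"), q)
  if (p != q) graph <- add_triple(graph, q, owl_iri("inverseOf"), p)
  graph
}

inverse_of <- function(graph, property) {
  out <- union(match_triples(graph, subject = property,
                             predicate = owl_iri("inverseOf"))$object,
               match_triples(graph, predicate = owl_iri("inverseOf"),
                             object = property)$subject)
  setdiff(unique(out), character(0))
}

property_domains <- function(graph, property)
  unique(match_triples(graph, property, rdfs_iri("domain"))$object)

property_ranges <- function(graph, property)
  unique(match_triples(graph, property, rdfs_iri("range"))$object[
    !match_triples(graph, property, rdfs_iri("range"))$is_literal])

super_properties <- function(graph, property)
  unique(match_triples(graph, property, rdfs_iri("subPropertyOf"))$object)
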