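# Structural quality battery: 8 clarity tests and 12 coherence tests run
# over any ontology_graph. Every test returns a complete result (never
# aborts), with one violation row per offending axiom. The operational
# readings follow the conventional semantics of the identically named
# Protege ontology tests.

CLARITY_TEST_NAMES <- c(
  C1 = "No Cardinality Restriction on Transitive Properties",
  C2 = "No Classes or Properties in Enumerations",
  C3 = "No Import of System Ontologies",
  C4 = "No Meta-Class",
  C5 = "No Properties with Class as Range",
  C6 = "No Sub Classes of RDF Classes",
  C7 = "No Super or Sub Properties of Annotation Properties",
  C8 = "Transitive Properties cannot be Functional"
)

COHERENCE_TEST_NAMES <- c(
  K1  = "Domain of a Property should not be empty",
  K2  = "Domain of a Property should not contain redundant Classes",
  K3  = "Range of a Property should not contain redundant Classes",
  K4  = "Domain of a Sub Property can only narrow Super Property",
  K5  = "Range of a Sub Property can only narrow Super Property",
  K6  = "Inverse of Functional must be Inverse Functional",
  K7  = "Inverse of Inverse Functional must be Functional",
  K8  = "Inverse of Sub Property must be Subproperty of Inverse of Super Property",
  K9  = "Inverse of Symmetric Property must be Symmetric Property",
  K10 = "Inverse of Top Level Property must be Top Level Property",
  K11 = "Inverse of Transitive Property must be Transitive Property",
  K12 = "Inverse Property must have matching Range and Domain"
)

test_result <- function(id, name, violations) {
  structure(list(test_id = id, name = name,
                 passed = nrow(violations) == 0L, violations = violations),
            class = "mhbi_test_result")
}

no_violations <- function()
  data.frame(axiom = character(0), explanation = character(0),
             stringsAsFactors = FALSE)

violation <- function(axiom, explanation)
  data.frame(axiom = axiom, explanation = explanation,
             stringsAsFactors = FALSE)

#' @export
print.mhbi_test_result <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", x$test_id, x$name,
              if (x$passed) "pass" else
                sprintf("FAIL (%d violation(s))", nrow(x$violations))))
  invisible(x)
}

all_properties <- function(graph)
  names(graph$declarations)[graph$declarations %in%
                              c("object-property", "datatype-property",
                                "annotation-property")]

non_annotation_properties <- function(graph)
  names(graph$declarations)[graph$declarations %in%
                              c("object-property", "datatype-property")]

transitive_properties <- function(graph) {
  props <- non_annotation_properties(graph)
  props[vapply(props, function(p)
    has_characteristic(graph, p, "transitive"), TRUE)]
}

# Asserted subclass closure as a lookup: is `a` a (possibly indirect)
# subclass of `b`? No reasoner is in scope, so only asserted rdfs:subClassOf
# edges are followed.
# Transitive closure of an asserted edge relation, as "a\rb" pair keys.
asserted_closure <- function(graph, predicate) {
  edges <- match_triples(graph, predicate = predicate)
  a <- edges$subject; b <- edges$object
  pairs <- unique(paste(a, b, sep = "\r"))
  repeat {
    new <- character(0)
    for (i in seq_along(a)) {
      nxt <- b[a == b[i]]
      if (length(nxt)) new <- c(new, paste(a[i], nxt, sep = "\r"))
    }
    new <- setdiff(unique(new), pairs)
    if (!length(new)) break
    pairs <- c(pairs, new)
    sp <- strsplit(pairs, "\r", fixed = TRUE)
    a <- vapply(sp, `[`, "", 1L); b <- vapply(sp, `[`, "", 2L)
  }
  pairs
}

subclass_closure <- function(graph) asserted_closure(graph, rdfs_iri("subClassOf"))

is_subclass <- function(closure, a, b) paste(a, b, sep = "\r") %in% closure

subproperty_closure <- function(graph) asserted_closure(graph, rdfs_iri("subPropertyOf"))

#' Run the 8 clarity tests
#'
#' Structural checks that the ontology's definitions admit only one
#' reading: no cardinality restriction mentions a transitive property (C1);
#' no enumeration contains a class or property (C2); no RDF/RDFS/OWL/XSD
#' system ontology is imported (C3); no declared class is an instance of
#' another declared class (C4); no property has a meta-level class term as
#' range (C5); no declared class subclasses an RDF/RDFS built-in (C6);
#' annotation properties sit in no property hierarchy (C7); no transitive
#' property is functional (C8).
#'
#' @param graph An `ontology_graph`. The graph is never modified.
#' @return List of 8 `mhbi_test_result` objects, ids C1..C8.
#' @export
run_clarity <- function(graph) {
  trans <- transitive_properties(graph)
  type_p <- rdf_iri("type")

  # C1: restriction nodes typed owl:Restriction with owl:onProperty a
  # transitive property and any cardinality facet
  restr <- match_triples(graph, predicate = type_p,
                         object = owl_iri("Restriction"))$subject
  card_preds <- c(owl_iri("cardinality"), owl_iri("minCardinality"),
                  owl_iri("maxCardinality"))
  v1 <- no_violations()
  for (r in restr) {
    on <- match_triples(graph, r, owl_iri("onProperty"))$object
    has_card <- any(vapply(card_preds, function(cp)
      nrow(match_triples(graph, r, cp)) > 0L, TRUE))
    bad <- intersect(on, trans)
    if (has_card && length(bad))
      v1 <- rbind(v1, violation(bad, sprintf(
        "cardinality restriction <%s> constrains transitive property", r)))
  }

  # C2: owl:oneOf members that are declared classes or properties
  ones <- match_triples(graph, predicate = owl_iri("oneOf"))
  cls_or_prop <- c(declared_of_kind(graph, "concept-class"),
                   all_properties(graph))
  bad2 <- ones[ones$object %in% cls_or_prop, , drop = FALSE]
  v2 <- if (nrow(bad2)) violation(bad2$object, sprintf(
    "enumeration on <%s> contains a class or property", bad2$subject))
  else no_violations()

  # C3: imports of the RDF / RDFS / OWL / XSD namespaces
  sys_imports <- graph$imports[is_builtin_namespace(graph$imports)]
  v3 <- if (length(sys_imports))
    violation(sys_imports, "system ontology namespace imported")
  else no_violations()

  # C4: a declared class asserted as instance of another declared class
  classes <- declared_of_kind(graph, "concept-class")
  t4 <- match_triples(graph, predicate = type_p)
  bad4 <- t4[t4$subject %in% classes & t4$object %in% classes &
               t4$subject != t4$object, , drop = FALSE]
  v4 <- if (nrow(bad4)) violation(bad4$subject, sprintf(
    "declared class is an instance of declared class <%s>", bad4$object))
  else no_violations()

  # C5: property range is a meta-level class term
  meta <- c(owl_iri("Class"), rdfs_iri("Class"), rdf_iri("Property"),
            rdfs_iri("Resource"), rdfs_iri("Datatype"))
  rng <- match_triples(graph, predicate = rdfs_iri("range"))
  bad5 <- rng[rng$object %in% meta, , drop = FALSE]
  v5 <- if (nrow(bad5)) violation(bad5$subject, sprintf(
    "range of property is the meta-level term <%s>", bad5$object))
  else no_violations()

  # C6: declared class subClassOf an RDF/RDFS built-in
  sub <- match_triples(graph, predicate = rdfs_iri("subClassOf"))
  bad6 <- sub[sub$subject %in% classes &
                (startsWith(sub$object, NS_RDF) |
                   startsWith(sub$object, NS_RDFS)), , drop = FALSE]
  v6 <- if (nrow(bad6)) violation(bad6$subject, sprintf(
    "declared class is a subclass of the built-in <%s>", bad6$object))
  else no_violations()

  # C7: annotation properties in sub/super-property axioms
  ann <- declared_of_kind(graph, "annotation-property")
  subp <- match_triples(graph, predicate = rdfs_iri("subPropertyOf"))
  bad7 <- subp[subp$subject %in% ann | subp$object %in% ann, , drop = FALSE]
  v7 <- if (nrow(bad7)) violation(
    ifelse(bad7$subject %in% ann, bad7$subject, bad7$object),
    "annotation property occurs in a property hierarchy axiom")
  else no_violations()

  # C8: transitive and functional
  bad8 <- trans[vapply(trans, function(p)
    has_characteristic(graph, p, "functional"), TRUE)]
  v8 <- if (length(bad8))
    violation(bad8, "transitive property is also functional")
  else no_violations()

  vs <- list(C1 = v1, C2 = v2, C3 = v3, C4 = v4, C5 = v5, C6 = v6, C7 = v7,
             C8 = v8)
  lapply(stats::setNames(names(vs), names(vs)), function(id)
    test_result(id, CLARITY_TEST_NAMES[[id]], vs[[id]]))
}

inverse_pairs <- function(graph) {
  inv <- match_triples(graph, predicate = owl_iri("inverseOf"))
  unique(inv[, c("subject", "object"), drop = FALSE])
}

#' Run the 12 coherence tests
#'
#' Consistency checks over the declared property axioms: non-empty domains
#' (K1); no ancestor-descendant redundancy within one property's domain or
#' range set (K2/K3); sub-property domains and ranges only narrow the super
#' property's (K4/K5); functional/inverse-functional duality across inverse
#' pairs (K6/K7); inverse of a sub-property is a sub-property of the
#' super's inverse (K8); symmetry, top-levelness and transitivity carry
#' across inverse pairs (K9/K10/K11); and inverse pairs have swapped
#' domain/range sets (K12).
#'
#' @param graph An `ontology_graph`. Never modified.
#' @return List of 12 `mhbi_test_result` objects, ids K1..K12.
#' @export
run_coherence <- function(graph) {
  props <- non_annotation_properties(graph)
  closure <- subclass_closure(graph)
  pclosure <- subproperty_closure(graph)
  pairs <- inverse_pairs(graph)

  # K1
  nodom <- props[vapply(props, function(p)
    length(property_domains(graph, p)) == 0L, TRUE)]
  v1 <- if (length(nodom)) violation(nodom, "property has no declared domain")
  else no_violations()

  redundant_in <- function(set) {
    if (length(set) < 2L) return(character(0))
    bad <- character(0)
    for (a in set) for (b in set)
      if (a != b && is_subclass(closure, a, b))
        bad <- c(bad, a)
    unique(bad)
  }
  # K2 / K3
  v2 <- no_violations(); v3 <- no_violations()
  for (p in props) {
    rd <- redundant_in(property_domains(graph, p))
    if (length(rd)) v2 <- rbind(v2, violation(p, sprintf(
      "domain contains a class and its subclass (%s)",
      paste(rd, collapse = ", "))))
    rr <- redundant_in(property_ranges(graph, p))
    if (length(rr)) v3 <- rbind(v3, violation(p, sprintf(
      "range contains a class and its subclass (%s)",
      paste(rr, collapse = ", "))))
  }

  # K4 / K5: every declared domain (range) class of the sub-property must
  # equal or specialise some domain (range) class of each super property;
  # a sub-property with no own declaration inherits and passes.
  narrow_ok <- function(sub_set, super_set) {
    if (!length(sub_set) || !length(super_set)) return(TRUE)
    all(vapply(sub_set, function(a)
      any(vapply(super_set, function(b)
        a == b || is_subclass(closure, a, b), TRUE)), TRUE))
  }
  subp <- match_triples(graph, predicate = rdfs_iri("subPropertyOf"))
  subp <- subp[subp$subject %in% props & subp$object %in% props, ,
               drop = FALSE]
  v4 <- no_violations(); v5 <- no_violations()
  for (i in seq_len(nrow(subp))) {
    p <- subp$subject[i]; s <- subp$object[i]
    if (!narrow_ok(property_domains(graph, p), property_domains(graph, s)))
      v4 <- rbind(v4, violation(p, sprintf(
        "domain does not narrow super property <%s>", s)))
    if (!narrow_ok(property_ranges(graph, p), property_ranges(graph, s)))
      v5 <- rbind(v5, violation(p, sprintf(
        "range does not narrow super property <%s>", s)))
  }

  # K6 - K11 over declared inverse pairs
  v6 <- no_violations(); v7 <- no_violations(); v8 <- no_violations()
  v9 <- no_violations(); v10 <- no_violations(); v11 <- no_violations()
  v12 <- no_violations()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$subject[i]; q <- pairs$object[i]
    if (has_characteristic(graph, p, "functional") &&
        !has_characteristic(graph, q, "inverse-functional"))
      v6 <- rbind(v6, violation(p, sprintf(
        "functional but inverse <%s> is not inverse-functional", q)))
    if (has_characteristic(graph, p, "inverse-functional") &&
        !has_characteristic(graph, q, "functional"))
      v7 <- rbind(v7, violation(p, sprintf(
        "inverse-functional but inverse <%s> is not functional", q)))
    if (has_characteristic(graph, p, "symmetric") &&
        !has_characteristic(graph, q, "symmetric"))
      v9 <- rbind(v9, violation(p, sprintf(
        "symmetric but inverse <%s> is not symmetric", q)))
    p_top <- length(super_properties(graph, p)) == 0L
    q_top <- length(super_properties(graph, q)) == 0L
    if (p_top != q_top)
      v10 <- rbind(v10, violation(p, sprintf(
        "top-levelness differs from inverse <%s>", q)))
    if (has_characteristic(graph, p, "transitive") &&
        !has_characteristic(graph, q, "transitive"))
      v11 <- rbind(v11, violation(p, sprintf(
        "transitive but inverse <%s> is not transitive", q)))
    if (!setequal(property_domains(graph, p), property_ranges(graph, q)) ||
        !setequal(property_ranges(graph, p), property_domains(graph, q)))
      v12 <- rbind(v12, violation(p, sprintf(
        "domain/range not swapped with inverse <%s>", q)))

    # K8: p sub-property of p2, both with inverses -> q must be a (possibly
    # derived) sub-property of p2's inverse
    for (p2 in super_properties(graph, p)) {
      q2s <- inverse_of(graph, p2)
      for (q2 in q2s) {
        ok <- q == q2 ||
          paste(q, q2, sep = "\r") %in% pclosure
        if (!ok)
          v8 <- rbind(v8, violation(p, sprintf(
            "inverse <%s> is not a subproperty of <%s> (inverse of super <%s>)",
            q, q2, p2)))
      }
    }
  }

  vs <- list(K1 = v1, K2 = v2, K3 = v3, K4 = v4, K5 = v5, K6 = v6, K7 = v7,
             K8 = v8, K9 = v9, K10 = v10, K11 = v11, K12 = v12)
  lapply(stats::setNames(names(vs), names(vs)), function(id)
    test_result(id, COHERENCE_TEST_NAMES[[id]], vs[[id]]))
}

#' Validate an ontology graph with the full 20-test battery
#'
#' Runs the 8 clarity and 12 coherence tests and assembles a report.
#' `lenient` downgrades named tests to warnings so third-party ontologies
#' can be checked selectively; downgraded tests still report their
#' violations but no longer gate `overall_pass`.
#'
#' @param graph An `ontology_graph`.
#' @param lenient Character vector of test ids (e.g. `c("K4", "K5")`) to
#'   exclude from the overall verdict.
#' @return A `mhbi_validation_report`: fields `clarity` (8 results),
#'   `coherence` (12 results), `overall_pass`.
#' @export
#' @examples
#' rep <- validate_ontology(build_mhbi_schema())
#' rep$overall_pass
validate_ontology <- function(graph, lenient = character(0)) {
  clarity <- run_clarity(graph)
  coherence <- run_coherence(graph)
  all_res <- c(clarity, coherence)
  gating <- all_res[!names(all_res) %in% lenient]
  structure(list(
    clarity = clarity,
    coherence = coherence,
    lenient = lenient,
    overall_pass = all(vapply(gating, function(r) r$passed, TRUE))
  ), class = "mhbi_validation_report")
}

#' @export
print.mhbi_validation_report <- function(x, ...) {
  cat(format_report(x, "text"))
  invisible(x)
}

#' Render a validation report
#'
#' @param report A `mhbi_validation_report`.
#' @param format `"text"` or `"json"`. Field order is stable; test names
#'   are the canonical battery names.
#' @return Character scalar (text block or JSON document).
#' @export
format_report <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  results <- c(report$clarity, report$coherence)
  if (format == "text") {
    lines <- vapply(results, function(r) {
      head <- sprintf("[%s] %-70s %s", r$test_id, r$name,
                      if (r$passed) "pass" else "FAIL")
      if (r$passed) head
      else paste(c(head, sprintf("      - <%s>: %s", r$violations$axiom,
                                 r$violations$explanation)), collapse = "\n")
    }, "")
    paste0(paste(lines, collapse = "\n"),
           sprintf("\noverall: %s\n",
                   if (report$overall_pass) "PASS" else "FAIL"))
  } else {
    obj <- list(
      tests = lapply(unname(results), function(r) list(
        test_id = r$test_id, name = r$name, passed = r$passed,
        violations = if (nrow(r$violations)) r$violations else
          data.frame(axiom = character(0), explanation = character(0)))),
      lenient = as.character(report$lenient),
      overall_pass = report$overall_pass
    )
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE))
  }
}
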