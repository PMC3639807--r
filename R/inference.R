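# Entailment materialization licensed by OWL property characteristics.
#
# The asserted triple set is never modified: each operation returns an
# entailment set (inferred triples only, with a provenance rule tag), so
# asserted and inferred knowledge stay distinguishable until the caller
# explicitly folds them in.

entailment_set <- function(subject = character(0), object = character(0),
                           predicate = character(0), rule = character(0)) {
  data.frame(subject = subject, predicate = predicate, object = object,
             is_literal = rep(FALSE, length(subject)),
             datatype = rep(NA_character_, length(subject)), rule = rule,
             stringsAsFactors = FALSE)
}

assert_object_property <- function(graph, property) {
  kind <- declaration_kind(graph, property)
  if (!identical(kind, "object-property"))
    stop("usage error: <", property, "> is not a declared object property",
         call. = FALSE)
}

property_edges <- function(graph, property) {
  tr <- match_triples(graph, predicate = property)
  tr[!tr$is_literal, c("subject", "object"), drop = FALSE]
}

new_only <- function(graph, ent) {
  if (!nrow(ent)) return(ent)
  ent <- ent[!duplicated(ent[c("subject", "predicate", "object")]), ,
             drop = FALSE]
  keys <- paste(ent$subject, ent$predicate, ent$object, FALSE,
                NA_character_, sep = "\r")
  ent[!keys %in% triple_keys(graph$triples), , drop = FALSE]
}

#' Transitive closure of a property
#'
#' Materializes every link entailed by transitivity: if a species belongs
#' to its genus and the genus to its family, the species belongs to the
#' family. Computed as an iterative fixpoint over the asserted edge set;
#' terminates on cyclic inputs (cycle members become mutually linked and
#' the cycles are reported in the `cycles` attribute as a diagnostic, since
#' a taxonomic hierarchy should be acyclic but inputs need not be).
#'
#' @param graph An `ontology_graph`.
#' @param property IRI of a transitive object property (using a
#'   non-transitive property is a usage error).
#' @return Data frame of inferred triples (asserted ones excluded) with a
#'   `rule` column set to `"transitive"`; strongly connected cycle
#'   components, if any, in `attr(, "cycles")`.
#' @export
#' @examples
#' s <- build_mhbi_schema()
#' ex <- mhbi_example_graph()
#' isBelong <- paste0(s$prefixes[["mhbi"]], "isBelong")
#' transitive_closure(ex, isBelong)
transitive_closure <- function(graph, property) {
  assert_object_property(graph, property)
  if (!has_characteristic(graph, property, "transitive"))
    stop("usage error: <", property, "> lacks the transitive characteristic",
         call. = FALSE)
  edges <- property_edges(graph, property)
  nodes <- unique(c(edges$subject, edges$object))
  n <- length(nodes)
  reach <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (n) reach[cbind(match(edges$subject, nodes),
                     match(edges$object, nodes))] <- TRUE
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  idx <- which(reach, arr.ind = TRUE)
  ent <- entailment_set(subject = nodes[idx[, 1]], object = nodes[idx[, 2]],
                        predicate = rep(property, nrow(idx)),
                        rule = rep("transitive", nrow(idx)))
  ent <- new_only(graph, ent)

  on_cycle <- which(diag(reach))
  cycles <- list()
  if (length(on_cycle)) {
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in on_cycle) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      members <- intersect(which(reach[i, ] & reach[, i]), on_cycle)
      comp[members] <- cid
      cycles[[cid]] <- nodes[members]
    }
    warning("cycle detected in <", property, "> over ",
            sum(!is.na(comp)), " node(s); closure still computed",
            call. = FALSE)
  }
  attr(ent, "cycles") <- cycles
  ent
}

#' Symmetric materialization of a property
#'
#' For every asserted `(a, P, b)` adds `(b, P, a)` when absent: a synonym
#' relation between two taxon names holds in both directions.
#'
#' @param graph An `ontology_graph`.
#' @param property IRI of a symmetric object property.
#' @return Data frame of inferred triples, `rule = "symmetric"`.
#' @export
materialize_symmetric <- function(graph, property) {
  assert_object_property(graph, property)
  if (!has_characteristic(graph, property, "symmetric"))
    stop("usage error: <", property, "> lacks the symmetric characteristic",
         call. = FALSE)
  edges <- property_edges(graph, property)
  edges <- edges[edges$subject != edges$object, , drop = FALSE]
  ent <- entailment_set(subject = edges$object, object = edges$subject,
                        predicate = rep(property, nrow(edges)),
                        rule = rep("symmetric", nrow(edges)))
  new_only(graph, ent)
}

#' Inverse materialization of a property pair
#'
#' For a declared inverse pair `(P, Q)`, every asserted `(a, P, b)` entails
#' `(b, Q, a)` and vice versa: a specimen being the type for a name entails
#' that the name has the specimen as a part.
#'
#' @param graph An `ontology_graph`.
#' @param p,q IRIs of two object properties declared as mutual inverses
#'   (an undeclared pair is a usage error).
#' @return Data frame of inferred triples, `rule = "inverse"`.
#' @export
materialize_inverse <- function(graph, p, q) {
  assert_object_property(graph, p)
  assert_object_property(graph, q)
  if (!(q %in% inverse_of(graph, p)))
    stop("usage error: <", p, "> and <", q,
         "> are not declared as an inverse pair", call. = FALSE)
  e_p <- property_edges(graph, p)
  e_q <- property_edges(graph, q)
  ent <- rbind(
    entailment_set(subject = e_p$object, object = e_p$subject,
                   predicate = rep(q, nrow(e_p)),
                   rule = rep("inverse", nrow(e_p))),
    entailment_set(subject = e_q$object, object = e_q$subject,
                   predicate = rep(p, nrow(e_q)),
                   rule = rep("inverse", nrow(e_q)))
  )
  new_only(graph, ent)
}

#' Materialize all entailments of the schema's characteristic properties
#'
#' Runs transitive, symmetric and inverse materialization for every
#' property of the graph carrying the corresponding characteristic or
#' inverse declaration, iterating to a fixpoint (a transitive link may feed
#' an inverse entailment and conversely).
#'
#' @param graph An `ontology_graph`.
#' @param fold If `TRUE`, returns the graph with entailments added;
#'   otherwise returns the entailment data frame.
#' @return Graph or entailment data frame, per `fold`.
#' @export
materialize_all <- function(graph, fold = FALSE) {
  all_ent <- entailment_set()
  work <- graph
  repeat {
    round_ent <- entailment_set()
    obj_props <- declared_of_kind(work, "object-property")
    for (p in obj_props) {
      if (has_characteristic(work, p, "transitive")) {
        e <- suppressWarnings(transitive_closure(work, p))
        attr(e, "cycles") <- NULL
        round_ent <- rbind(round_ent, e)
      }
      if (has_characteristic(work, p, "symmetric"))
        round_ent <- rbind(round_ent, materialize_symmetric(work, p))
      for (q in inverse_of(work, p))
        if (q > p || !(p %in% inverse_of(work, q)))
          round_ent <- rbind(round_ent, materialize_inverse(work, p, q))
    }
    round_ent <- new_only(work, round_ent)
    if (!nrow(round_ent)) break
    work <- add_triples(work, round_ent[, colnames(empty_triples())])
    all_ent <- rbind(all_ent, round_ent)
  }
  if (fold) work else all_ent
}

#' Detect functional / inverse-functional violations
#'
#' A functional property admits one object per subject; an
#' inverse-functional property one subject per object. Lists every
#' violating subject (or object) with its value set.
#'
#' @param graph An `ontology_graph`.
#' @param property Property IRI carrying the functional or
#'   inverse-functional characteristic.
#' @return Data frame with columns `node` and `values`
#'   (comma-joined offending values); zero rows on clean data.
#' @export
check_functional_violations <- function(graph, property) {
  fun <- has_characteristic(graph, property, "functional")
  ifun <- has_characteristic(graph, property, "inverse-functional")
  if (!fun && !ifun)
    stop("<", property, "> is neither functional nor inverse-functional",
         call. = FALSE)
  tr <- match_triples(graph, predicate = property)
  out <- list()
  if (fun) {
    per <- split(tr$object, tr$subject)
    bad <- per[vapply(per, function(v) length(unique(v)) > 1L, TRUE)]
    if (length(bad))
      out[[length(out) + 1L]] <- data.frame(
        node = names(bad),
        values = vapply(bad, function(v) paste(unique(v), collapse = ", "), ""),
        stringsAsFactors = FALSE, row.names = NULL)
  }
  if (ifun) {
    obj <- tr[!tr$is_literal, , drop = FALSE]
    per <- split(obj$subject, obj$object)
    bad <- per[vapply(per, function(v) length(unique(v)) > 1L, TRUE)]
    if (length(bad))
      out[[length(out) + 1L]] <- data.frame(
        node = names(bad),
        values = vapply(bad, function(v) paste(unique(v), collapse = ", "), ""),
        stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out))
    data.frame(node = character(0), values = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
}
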