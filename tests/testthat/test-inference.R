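# Entailment materialization, checked against independent oracles
# (igraph reachability for transitive closure, unordered-pair enumeration
# for symmetric completion).

chain_graph <- function() {
  g <- ontology_graph()
  g <- declare(g, ms("isBelong"), "object-property")
  g <- declare(g, ms("hasSpecies"), "object-property")
  g <- set_characteristic(g, ms("isBelong"), "transitive")
  g <- set_characteristic(g, ms("hasSpecies"), "transitive")
  g <- set_inverse(g, ms("isBelong"), ms("hasSpecies"))
  g <- add_triple(g, mi("BifBaungi"), ms("isBelong"), mi("Bifurcohaptor"))
  add_triple(g, mi("Bifurcohaptor"), ms("isBelong"), mi("Ancylodiscoididae"))
}

test_that("transitive closure infers the species-to-family link", {
  ent <- transitive_closure(chain_graph(), ms("isBelong"))
  expect_equal(nrow(ent), 1L)
  expect_equal(ent$subject, mi("BifBaungi"))
  expect_equal(ent$object, mi("Ancylodiscoididae"))
  expect_equal(ent$rule, "transitive")
})

test_that("a single triple and an already-closed graph entail nothing", {
  g <- ontology_graph()
  g <- declare(g, ms("p"), "object-property")
  g <- set_characteristic(g, ms("p"), "transitive")
  g <- add_triple(g, mi("a"), ms("p"), mi("b"))
  expect_equal(nrow(transitive_closure(g, ms("p"))), 0L)
  closed <- materialize_all(chain_graph(), fold = TRUE)
  expect_equal(nrow(materialize_all(closed)), 0L)  # fixpoint
})

test_that("closure on random DAGs equals igraph reachability", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (case in 1:8) {
    n <- sample(10:25, 1)
    # random DAG: edges only from lower to higher index
    from <- sample(n - 1, 40, replace = TRUE)
    to <- pmin(n, from + sample(n - 1, 40, replace = TRUE))
    keep <- from < to
    edges <- unique(cbind(from[keep], to[keep]))
    g <- ontology_graph(strict = FALSE)
    g <- declare(g, ms("p"), "object-property")
    g <- set_characteristic(g, ms("p"), "transitive")
    for (i in seq_len(nrow(edges)))
      g <- add_triple(g, mi(paste0("n", edges[i, 1])), ms("p"),
                      mi(paste0("n", edges[i, 2])))
    ent <- transitive_closure(g, ms("p"))
    mine <- union(paste(mi(paste0("n", edges[, 1])),
                        mi(paste0("n", edges[, 2]))),
                  paste(ent$subject, ent$object))

    ig <- igraph::graph_from_edgelist(cbind(paste0("n", edges[, 1]),
                                            paste0("n", edges[, 2])))
    reach <- character(0)
    for (v in igraph::V(ig)$name) {
      r <- setdiff(names(igraph::subcomponent(ig, v, mode = "out")), v)
      if (length(r)) reach <- c(reach, paste(mi(v), mi(r)))
    }
    expect_setequal(mine, reach)
  }
})

test_that("cyclic input still terminates, with a cycle diagnostic", {
  g <- ontology_graph(strict = FALSE)
  g <- declare(g, ms("p"), "object-property")
  g <- set_characteristic(g, ms("p"), "transitive")
  for (e in list(c("a", "b"), c("b", "c"), c("c", "a")))
    g <- add_triple(g, mi(e[1]), ms("p"), mi(e[2]))
  expect_warning(ent <- transitive_closure(g, ms("p")), "cycle")
  cycles <- attr(ent, "cycles")
  expect_equal(length(cycles), 1L)
  expect_setequal(cycles[[1]], mi(c("a", "b", "c")))
  # closure of a 3-cycle: all 9 pairs, 3 asserted, 6 inferred
  expect_equal(nrow(ent), 6L)
})

test_that("symmetric completion mirrors asserted pairs and ignores self-loops", {
  g <- ontology_graph(strict = FALSE)
  g <- declare(g, ms("hasSynonym"), "object-property")
  g <- set_characteristic(g, ms("hasSynonym"), "symmetric")
  g <- add_triple(g, mi("BycGharui"), ms("hasSynonym"), mi("SiloGharui"))
  g <- add_triple(g, mi("x"), ms("hasSynonym"), mi("x"))
  ent <- materialize_symmetric(g, ms("hasSynonym"))
  expect_equal(nrow(ent), 1L)
  expect_equal(ent$subject, mi("SiloGharui"))
  expect_equal(ent$object, mi("BycGharui"))

  # random pair set: completion equals the unordered-pair oracle
  set.seed(13)
  nodes <- paste0("t", 1:12)
  pairs <- unique(t(replicate(30, sample(nodes, 2))))
  g2 <- ontology_graph(strict = FALSE)
  g2 <- declare(g2, ms("s"), "object-property")
  g2 <- set_characteristic(g2, ms("s"), "symmetric")
  for (i in seq_len(nrow(pairs)))
    g2 <- add_triple(g2, mi(pairs[i, 1]), ms("s"), mi(pairs[i, 2]))
  ent2 <- materialize_symmetric(g2, ms("s"))
  all_edges <- rbind(
    data.frame(a = mi(pairs[, 1]), b = mi(pairs[, 2])),
    data.frame(a = ent2$subject, b = ent2$object))
  # oracle: each unordered pair appears exactly twice (both directions)
  key <- apply(cbind(pmin(all_edges$a, all_edges$b),
                     pmax(all_edges$a, all_edges$b)), 1, paste,
               collapse = "|")
  expect_true(all(table(key) == 2L))
  expect_equal(length(unique(key)), nrow(unique(
    cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))))
})

test_that("inverse materialization swaps subject and object across the pair", {
  g <- example_graph_cached()
  ent <- materialize_inverse(g, ms("typeForName"), ms("part"))
  expect_true(any(ent$subject == mi("BifBaungi") &
                    ent$predicate == ms("part") &
                    ent$object == mi("bif-baungi-vb-i1")))
  # closure then inverse reaches the family level
  all_ent <- materialize_all(g)
  expect_true(any(all_ent$subject == mi("Ancylodiscoididae") &
                    all_ent$predicate == ms("hasSpecies") &
                    all_ent$object == mi("BifBaungi")))
  # a fully materialized graph entails nothing further
  folded <- materialize_all(g, fold = TRUE)
  expect_equal(nrow(materialize_inverse(folded, ms("typeForName"),
                                        ms("part"))), 0L)
})

test_that("inferred and asserted triples stay disjoint; assertions are never removed", {
  g <- example_graph_cached()
  before <- match_triples(g)
  ent <- materialize_all(g)
  keys_asserted <- paste(before$subject, before$predicate, before$object)
  keys_inferred <- paste(ent$subject, ent$predicate, ent$object)
  expect_length(intersect(keys_asserted, keys_inferred), 0L)
  folded <- materialize_all(g, fold = TRUE)
  expect_true(all(keys_asserted %in%
                    paste(folded$triples$subject, folded$triples$predicate,
                          folded$triples$object)))
})

test_that("characteristic misuse is a usage error", {
  g <- build_mhbi_schema()
  expect_error(transitive_closure(g, ms("rank")), "transitive")
  expect_error(materialize_symmetric(g, ms("rank")), "symmetric")
  expect_error(materialize_inverse(g, ms("rank"), ms("isBelong")),
               "inverse pair")
  expect_error(transitive_closure(g, ms("nameComplete")), "object property")
})

test_that("functional violations are detected on mutant data and absent on clean data", {
  g <- example_graph_cached()
  expect_equal(nrow(check_functional_violations(g, ms("typeForName"))), 0L)
  bad <- add_triple(g, mi("bif-baungi-vb-i1"), ms("typeForName"),
                    mi("Bifurcohaptor"))
  v <- check_functional_violations(bad, ms("typeForName"))
  expect_equal(nrow(v), 1L)
  expect_equal(v$node, mi("bif-baungi-vb-i1"))
  # inverse-functional side: two specimens as the same part target
  empty <- ontology_graph()
  empty <- declare(empty, ms("part"), "object-property")
  empty <- set_characteristic(empty, ms("part"), "inverse-functional")
  expect_equal(nrow(check_functional_violations(empty, ms("part"))), 0L)
})
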