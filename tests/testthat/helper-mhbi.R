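# Shared helpers: IRI shorthands for the default namespaces and a random
# graph generator for property-style round-trip tests.

ms <- function(x) paste0("http://purl.example.org/mhbi/schema#", x)
mi <- function(x) paste0("http://purl.example.org/mhbi/instance#", x)
fi <- function(x) paste0("http://purl.example.org/fish#", x)

rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

# A random lax-mode graph: IRI triples plus literal triples with awkward
# string content (quotes, backslashes, unicode) and integer literals.
random_graph <- function(n_triples = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- ontology_graph(strict = FALSE)
  locals <- paste0("node", seq_len(8))
  strings <- c("plain", "with \"quotes\"", "back\\slash", "tab\there",
               "semi; colon", "ampersand & angle <x>", "tasek bera, pahang")
  for (i in seq_len(n_triples)) {
    s <- ms(sample(locals, 1))
    p <- ms(paste0("p", sample(4, 1)))
    if (stats::runif(1) < 0.4) {
      if (stats::runif(1) < 0.5) {
        g <- add_triple(g, s, p, literal(sample(strings, 1)))
      } else {
        g <- add_triple(g, s, p, literal(sample.int(3000, 1), "integer"))
      }
    } else {
      g <- add_triple(g, s, p, ms(sample(locals, 1)))
    }
  }
  g
}

example_graph_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mhbi_example_graph()
    cache
  }
})

schema_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_mhbi_schema(extensions = c("part-hierarchy", "synonym"))
    cache
  }
})
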