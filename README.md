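# mhbi: semantic annotation of monogenean haptoral bar images

Monogeneans are parasitic flatworms of fish (and amphibians and reptiles)
identified largely by the shape of their sclerotised hard parts — the
haptoral bars, anchors and hooks of the posterior attachment organ.
Digitised illustrations of these structures, extracted from the taxonomic
literature, are typically filed away in directory trees where the image and
the knowledge about it (species, authority, locality, source publication)
drift apart. **mhbi** represents that knowledge as an OWL ontology instead:
every image, taxon name and publication becomes a named individual in an
RDF triple graph, connected by a small controlled vocabulary, so that the
collection can be queried, extended and linked to host-species ontologies
without schema migrations.

The package is aimed at biodiversity informaticians curating
parasite-image collections, and at anyone who needs a compact, fully
testable reference implementation of an ontology-engineering workflow in R.

## The scheme

The vocabulary has **7 concepts** — `Specimen`, `TaxonName`,
`PublicationCitation`, and four controlled-term classes
(`DiagnosticPartTerms`, `KindOfSpecimenTerms`, `TaxonRankTerms`,
`PublicationTypeTerms`) — and **27 core properties**: 4 object + 3 datatype
properties on `Specimen`, 8 object + 4 datatype on `TaxonName`, 2 object +
5 datatype on `PublicationCitation`, and one shared `definedTerm`. Most
terms reuse the TDWG LSID vocabulary; `DiagnosticPartTerms` is newly
coined for the sclerotised hard parts.

Four property characteristics carry the semantics the toolkit
materializes:

| property      | characteristic       | entailment                                        |
|---------------|----------------------|---------------------------------------------------|
| `isBelong`    | transitive           | species → genus → family lifts to species → family |
| `hasSpecies`  | transitive (inverse of `isBelong`) | family `hasSpecies` species        |
| `typeForName` | functional           | with inverse-functional inverse `part`            |
| `hasSynonym`  | symmetric            | a synonym link holds in both directions           |

Individuals are named deterministically: species `Bifurcohaptor baungi`
becomes `BifBaungi` (3-letter genus prefix + epithet), the publication by
Lim & Furtado (1983) becomes `LimFurtado1983`, and the first ventral-bar
image of the species becomes `bif-baungi-vb-i1`.

Any graph — built, ingested, merged or third-party — can be checked with
the structural battery of **8 clarity tests** (e.g. "Transitive Properties
cannot be Functional") and **12 coherence tests** (e.g. "Inverse of
Transitive Property must be Transitive Property").

## Worked example

```r
library(mhbi)

schema <- build_mhbi_schema()
schema_census(schema)[c("n_concepts", "n_core_properties")]
#> $n_concepts
#> [1] 7
#> $n_core_properties
#> [1] 27

ex  <- mhbi_example_graph()      # Bifurcohaptor baungi annotation
iri <- function(x) paste0("http://purl.example.org/mhbi/schema#", x)

tc <- transitive_closure(ex, iri("isBelong"))
tc[, c("subject", "object")]
#>                                               subject
#> 2     http://purl.example.org/mhbi/instance#BifBaungi
#> 5 http://purl.example.org/mhbi/instance#Bifurcohaptor
#> 6     http://purl.example.org/mhbi/instance#BifBaungi
#>                                                    object
#> 2 http://purl.example.org/mhbi/instance#Ancylodiscoididae
#> 5    http://purl.example.org/mhbi/instance#Dactylogyridea
#> 6    http://purl.example.org/mhbi/instance#Dactylogyridea
```

The closure infers that `BifBaungi` belongs to the family
Ancylodiscoididae and the order Dactylogyridea from the asserted
species → genus → family → order chain. Merging with the bundled fish
ontology promotes `isHostedIn` from a host-name literal to an object link:

```r
merged <- merge_ontologies(ex, mhbi_example_fish())
attr(merged, "merge_stats")$n_replaced
#> [1] 1
validate_ontology(merged)$overall_pass
#> [1] TRUE
```

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mhbi.R",package="mhbi"))')" \
    build --out mhbi.ttl
# exit 0; then: validate --in mhbi.ttl  (exit 0, report to stdout)
```

Subcommands: `build`, `ingest`, `infer`, `validate`, `merge`, `query`,
`fixtures`. Exit codes: 0 success, 1 validation failure, 2 input error.

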