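---
title: "The MHBI annotation scheme: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MHBI annotation scheme: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhbi)
```

## The problem and the model

Monogenean taxonomy rests on the morphology of sclerotised hard parts,
and the primary evidence is a body of published illustrations. This
package encodes a collection of such haptoral-bar images as an OWL
ontology: a set of RDF triples over named individuals (specimen images,
taxon names at four ranks, publications, controlled terms), typed under
seven concept classes and connected by twenty-seven core properties. The
graph is deliberately minimal — no blank nodes outside restriction
axioms, no reasoner beyond the three entailment rules the vocabulary's
characteristics license — because the scheme's value is that its
structure can be checked exhaustively.

The entailment rules are the scientifically meaningful part of the
semantics:

* **transitivity** of `isBelong` (and its inverse `hasSpecies`): rank
  membership composes, so a species asserted under its genus and the
  genus under its family is inferred to belong to the family;
* **inverseness** of `typeForName`/`part`: an image that is the type
  illustration for a name entails the name's `part` link back to the
  image;
* **symmetry** of `hasSynonym`: synonymy has no direction.

Inferred triples are kept apart from asserted ones (with a provenance
rule tag) until explicitly folded in; a fully materialized graph is a
fixpoint, and re-running materialization on it yields nothing.

## Vocabulary census and interpretation choices

The census is fixed: 7 concepts and 27 core properties in the breakdown
4+3 (Specimen), 8+4 (TaxonName), 2+5 (PublicationCitation) and 1 shared
`definedTerm`. Extension properties (`fullImage`, `isBar`, `isHaptor`
under the `part` super-property; `hasSynonym`) never count against the
core and never mutate core axioms — `schema_census()` verifies both.

Several points were genuinely open and were resolved as follows.

* **Characteristics.** Only the four characteristics listed above are
  assigned; every other property carries none. Assigning more (say,
  making `rank` functional) would be defensible but is not evidenced by
  the scheme's own worked inferences, and a minimal assignment keeps the
  coherence battery's inverse-duality tests (K6/K7) meaningful.
* **Inverse pairings.** `typeForName`↔`part` and `isBelong`↔`hasSpecies`
  are declared. `hasGenus`/`hasFamily`/`hasOrder` are plain rank-specific
  object properties *without* inverse axioms: declaring three more
  inverses of `isBelong` would break the uniqueness that test K12's
  swapped-domain/range check presumes.
* **`isHostedIn`.** The census groups it with the TaxonName object
  properties, but in the standalone parasite ontology it is declared as a
  datatype property holding the host name as a literal; merging with a
  host ontology is exactly the operation that redefines it as an object
  property with the fish `TaxonName` range. This keeps the standalone
  graph self-contained (host names are data until a host ontology
  exists) while the merged graph carries real links.
* **`isHaptorBar`.** Used as the Specimen→DiagnosticPartTerms annotation
  property, matching how the instance data employs it; the alternative
  sub-property-of-`part` reading survives in the extension hierarchy
  (`fullImage`/`isBar`/`isHaptor`), which the coherence tests K4/K5/K8/K10
  exercise.
* **Two `year` properties.** TaxonName and PublicationCitation both
  carry a year; they are distinct IRIs (`year`, `publicationYear`) so
  each keeps an unambiguous domain. The vocabulary manifest records both
  under the field name `year`.
* **Controlled-term membership.** `KindOfSpecimenTerms` and
  `PublicationTypeTerms` have only some members attested
  (illustration/digital object/still image; journal article/book); the
  remainder up to the reported counts are placeholders flagged
  `authoritative = FALSE` in `mhbi_terms_table()` and are trivially
  replaceable.
* **`lists`.** Its range is modelled as TaxonName (a publication lists
  the taxa it treats); no instance data exercises it, and the choice is
  flagged unverified.

## Naming rules

Instance naming is deterministic and ASCII-folded so every label is
IRI-safe: `BifBaungi` (first three letters of the genus, title-cased,
plus title-cased epithet), full names for higher ranks, concatenated
surnames plus year for publications (`LimFurtado1983`), and the
lowercase hyphenated specimen label `bif-baungi-vb-i1` (genus prefix,
epithet, part abbreviation, 1-based sequence). The `specimenId` literal
uses a second abbreviation scheme (`j1-bif-bau-ven-bar`) whose leading
tag is a configuration knob defaulting to the attested `j1`.

Only the ventral-bar abbreviation `vb` is attested; the table extends it
with `db`, `an`, `fi` on the same pattern and is user-configurable. Two
genera can collide on a 3-letter prefix while sharing an epithet; the
batch-level `species_label_map()` disambiguates by lengthening the
colliding genus prefixes until unique, with a warning. This is the one
place the naming rule alone cannot guarantee injectivity, and the
generator can inject such collisions on demand (`inject_collision`).

## The validation battery

Eight clarity and twelve coherence tests run as pure structural checks
over the triple set; they always return all twenty results and never
mutate the graph. The operational readings follow the conventional
semantics of the identically named Protégé ontology tests, with these
clarifications:

* *redundant classes* (K2/K3): a property's domain or range set contains
  a class together with one of its (asserted-closure) subclasses;
* *narrowing* (K4/K5): checked against asserted `rdfs:subClassOf` only —
  no inferred subsumption, since no reasoner is in scope;
* *top-level property* (K10): no asserted super-property;
* *K8*: the required sub-property link may be asserted or derivable
  through the asserted sub-property closure;
* *system ontologies* (C3): exactly the RDF, RDFS, OWL and XSD
  namespaces; user ontologies may be imported freely;
* *C8* is read strictly as transitive-and-functional. The stronger
  vocabulary-level invariant (transitive properties carry no
  cardinality-related characteristic at all) is checked separately by
  `transitive_characteristic_conflicts()`.

Every test has a registered mutant — a minimal axiom-level edit of the
reference schema on which that test fails. Mutants are axiom edits, not
text patches, so they survive serialization changes. Two mutants deserve
a note: the C8 mutant marks `isBelong` functional *and* `hasSpecies`
inverse-functional, so that the functional-duality tests K6/K7 stay
green and C8 reports exactly one violation; and the K12 mutant uses a
fresh extension pair (`describedBy`/`describes` with deliberately
unswapped domains), because the standalone `isHostedIn` is a datatype
property and datatype properties cannot carry inverses. The full
20×20 selectivity matrix (`mutant_selectivity_matrix()`) has an
all-fail diagonal and no off-diagonal failures.

`validate_ontology(..., lenient = c("K4", "K5"))` downgrades named tests
for third-party files; downgraded tests still report violations but no
longer gate the overall verdict.

## Serialization

Graphs round-trip through Turtle and RDF/XML exactly (triple set,
declarations map, imports, base IRI). Node-kind declarations are
rendered as `rdf:type` statements against the OWL vocabulary on output
and routed back into the declarations map on input, so the triple set
itself is compared one-to-one. Literals are plain strings or
`xsd:integer`; strings serialize as plain literals in both formats (the
RDF 1.1 reading under which a plain literal and an explicit
`xsd:string` are the same term), which keeps the two formats isomorphic
for an independent parser. The Turtle writer emits one statement per
line; the reader accepts that subset plus `a`, prefixed names, full
IRIs and typed literals, and reports the line number on malformed input.

## The synthetic-data generator

`generate_dataset()` emulates the *cardinality structure* of a real
image collection: a balanced order/family/genus/species tree (defaults
2×2×2×2), a configurable number of specimen rows per species, a small
publication pool cited round-robin, and host names for a configurable
fraction of species (default 0.5, half-way between none and full host
coverage; a sub-fraction can be made deliberately unresolvable to
exercise merge policies). Names come from a collision-checked
pronounceable syllable sampler, so the naming rules meet realistic
Latinate input. Identical seeds give byte-identical tables, and the
generator restores the caller's RNG state.

What it does **not** emulate: real collections are strongly unbalanced
(a few speciose genera and many monotypic ones), epithets repeat across
genera constantly, authorities and years correlate, and the real
corpus's 159 images over 591 species imply far sparser specimen coverage
than the balanced tree. Passing tests on generated data therefore
demonstrate the pipeline's bookkeeping and structural guarantees, not
robustness to the full messiness of legacy taxonomic text. The real
image corpus is not distributed in machine-readable form; its published
instance counts appear here only as generator parameters, never as
expected values.

## Numerical and procedural choices

* Triple sets use exact string keys; there is no tolerance anywhere —
  equality of graphs is set equality of statements.
* Transitive closure is an iterative boolean-matrix fixpoint; cycles
  (taxonomically impossible, input-possible) still terminate, are
  closed, and are reported as strongly connected components in a
  warning diagnostic. Validation of the hierarchy is deliberately a
  separate concern from inference.
* Test problem sizes are the package's own choices for a desk-scale
  suite: 200 random graphs for the round-trip property, reachability
  oracles on 30–50-node graphs, and 20 generator seeds for the
  bookkeeping property.
* The closure's independent oracles are igraph reachability (test
  suite) and a Floyd–Warshall matrix sweep (acceptance script), both
  disjoint from the implementation path.

## Limitations

* No OWL-DL reasoning, SPARQL, named graphs or network import
  resolution; the query surface is triple-pattern matching.
* The Turtle reader targets the writer's subset (plus modest extras);
  arbitrary third-party Turtle (collections, blank-node syntax,
  multi-line literals) is out of scope, though RDF/XML from standard
  tools parses.
* The merge operation implements exactly the single-property host link;
  general ontology alignment is out of scope.
* Whether the original scheme used LSID URNs as instance identifiers is
  unrecorded; the namespaces here are configurable placeholder HTTP
  IRIs.
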