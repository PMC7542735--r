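---
title: "Representing and validating symbiotic interactions at the instance level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing and validating symbiotic interactions at the instance level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiotax)
```

## The representation and its assumptions

`symbiotax` treats a symbiotic interaction as a *process* occurring between
*individual organisms of two or more different species* in *intimate
association* — not as a property of species, and not restricted to mutually
beneficial association. The package's three components mirror that stance:

* a class taxonomy whose nodes carry both a textual definition and a
  machine-readable **differentia** — the constraints on an interaction
  profile (outcome pattern, spatial mode, contact mode, fatality,
  necessity) that characterise the class;
* a **referent-tracking store** for instance-level assertions: particulars
  with instance unique identifiers (`IUI-n`), temporal regions (`t_n`),
  instantiation tuples and relation tuples over a closed vocabulary;
* a **validator** that checks stores against the axioms of the
  representation and reports findings with rule identifiers and severities.

The taxonomy's structure encodes one substantive ontological commitment:
the ecto/endo location distinction outranks both intimacy and outcomes.
`ectosymbiosis` and `endosymbiosis` are the only direct children of the
root, every other subtype lives under exactly one of them, and no class
descends from both. That is why predation and parasitism end up in
different sub-branches (transient vs. intimate agonism) rather than as
siblings under a shared "one benefits, one is harmed" class.

```{r taxonomy}
tax <- build_taxonomy()
tax
head(branch_labels(tax), 10)
```

## The classifier

`classify_interaction()` reduces a profile to its unordered pairwise
outcome patterns and maps each through the differentia. Three
combinations are *defined to fail*, each with its own condition class:

* **all-neutral outcomes** (`symbio_neutralism_error`): "neutralism" would
  be a process in which an organism affects another, in which no organism
  is affected — a contradiction, so no class exists for it;
* **harm/neutral or harm/harm under the endo mode**
  (`symbio_unsupported_error`): endosymbiosis is defined only for the
  mutualism, commensalism, parasitism and parasitoidism families;
* **missing discriminating input** (`symbio_ambiguity_error`): an ecto
  benefit/harm pair cannot be placed without a contact mode (intimate
  agonism vs. transient agonism differ exactly there), and no pair can be
  placed without a spatial mode.

Design choices where the representation itself is silent, adopted once and
kept:

* **Unspecified spatial mode raises the ambiguity error** rather than
  returning the bare root class. Returning "symbiosis" would be formally
  defensible, but a silent, maximally unspecific answer is less useful to
  a curator than an explicit demand for the missing discriminator, and it
  would blur the disjointness guarantee between the two location branches.
* **Fatality defaults to non-fatal, with a warning**, when harm is
  asserted without fatality information. Fatality only separates sibling
  classes (parasitism/parasitoidism, grazing/predation), and the non-fatal
  sibling is the weaker claim.
* **Necessity applies per benefiting participant.** `obligate` refines the
  eight refineable classes to their "obligatory …" child, `facultative` to
  "facultative …"; if both beneficiaries of a mutualism are obligate the
  refined class is returned once. Transient agonism (grazing, predation)
  has no such refinements and ignores necessity. "Exclusively realizes" in
  the obligatory reading is represented as this boolean differentia, not
  as a modal check over alternative realizations — whether a function
  could have been realized some other way is not decidable from profile
  data.
* **More than two participants**: the classifier returns the union of the
  pairwise classifications, so a three-party endo profile
  (benefit, harm, neutral) is *both* a parasitism and a commensalism.
  In this multi-party mode, pairs whose pattern is undefined under the
  given spatial mode (here: the harm/neutral pair) are skipped as long as
  some pair classifies; a two-participant profile still fails loudly. No
  single "tripartite" class is attempted.

```{r classify}
classify_interaction(tax, interaction_profile(
  c("benefit", "harm", "neutral"), fatal = FALSE, spatial = "endo"))
```

The test suite sweeps the full discrete pairwise space — 5 patterns × 2
spatial modes × 3 contact modes × 3 necessity values × 3 fatality states,
270 profiles — and checks with an independent brute-force oracle that every
profile yields either labels or one of the three defined errors, that every
returned label satisfies the differentia of all of its ancestors, and that
any profile satisfying a class's differentia classifies to that class or a
descendant whenever it classifies at all (a satisfying profile may still
leave a *consulted* field unspecified, in which case the defined ambiguity
error is the correct outcome).

## Labels, identifiers and synonyms

Only four minted classes have published identifiers (APOLLO_SV:00000337
ectosymbiosis, 00000354 endosymbiosis, 00000371 bodily harm, 00000372
bodily benefit). All other minted classes receive deterministic local
identifiers (`SYMB:0000001` onward, in subtype-table row order) so that
exports are reproducible; they are deliberately namespaced apart from any
published ontology. Three classes are referenced as imports — GO:0044419,
GO:0051704, and GO:0051705 (multi-organism behavior, used only in the
symbiosis equivalence axiom) — and are exported as references (identifier,
label, parent) without definitions or differentia.

The scenario tables use contracted spellings ("obligatory
endoparasitism"); a fixed synonym table maps each contraction to its
canonical label, and every user-facing lookup accepts both.

## The referent-tracking store and validator

Temporal regions carry no numeric endpoints; ordering is purely relational
through `precedes` and the occurrent-parthood relations. `t_max` denotes
the maximal region ("holds at all times") and participates in no parthood
edges. `part-of-occurrent` tolerates reflexivity; `proper-part-of-occurrent`
is irreflexive; both must be acyclic, and `precedes` must be a strict
partial order (checked with igraph).

Two severity decisions keep the validator faithful to the printed
scenarios while still enforcing the axioms:

* **R1 (participant cardinality)** distinguishes a *positive violation*
  from *incompleteness*: an instance with exactly one has-participant
  tuple contradicts the min-2 axiom (error), while an instance with none
  has simply not had its participation asserted (warning). The
  endomutualism scenario as printed omits the two participant tuples of
  its interaction, so the verbatim fixture draws the warning; a
  `build_scenario(3, augmented = TRUE)` variant adds them.
* **R3 (endo location)** defaults to warning when no located-in tuple is
  asserted, because none of the printed endo scenarios asserts one; a
  spatially-disjoint-from tuple among the participants, by contrast, is a
  contradiction and an error. R4 is the exact dual for the ecto branch.

Outcome annotations are optional store metadata: the scenario tables carry
outcomes implicitly through the interaction's type, so the neutralism rule
(R7) fires only when annotations are present and all neutral. Species
identity (R2) is decided by taxon-identifier string equality; organisms
without taxa are skipped with an info finding rather than guessed at.

Two errata in the printed tables are resolved in the fixtures' favour of
internal consistency and documented here: the dermatophyte colony of the
first scenario is typed with taxid 5551 (the taxid printed in the scenario
description; the results paragraph prints a different organism's taxid),
and the "mosquito denoted by IUI-8" in the second scenario's notes is
IUI-5 per the identifier column. The third scenario's prose refers to an
interval "t_21" that its table prints as t_18; the fixture follows the
table.

## Export formats

All three formats (`json`, `ttl`, `ofn`) are deterministic — stable prefix
table, canonical statement order — and lossless for both taxonomies and
stores; `import(export(x))` reproduces `x` exactly. Because a relation
tuple is a *temporally qualified* statement, the Turtle export reifies each
tuple as an `rdf:Statement` annotated with its holds-at region and note,
rather than using named graphs; this keeps the output a single,
self-contained document that any RDF 1.1 parser accepts (the test suite
parses it with an independent Python RDF library). The differentia travel
as a compact `key=value` annotation string so that round trips do not
depend on parsing OWL class expressions; the three printed equivalence
axioms are nevertheless emitted as genuine OWL restrictions
(`owl:minQualifiedCardinality 2` on has-participant, existential
restrictions on located-in / spatially-disjoint-from) for consumption by
DL tooling. Subsumption inside the package is computed structurally; no
reasoner is invoked.

## The synthetic generator

`generate_synthetic()` emulates the shape of the vector-transmission
scenario: one symbiont aggregate engaging in a chain of `chain_length`
interactions with successive hosts, with participant, occupation,
temporal-parthood, location and outcome assertions consistent with each
interaction's type, and a precedes path linking the chain
(`chain_length - 1` edges). Host and symbiont taxa are drawn from disjoint
pools taken from the worked scenarios, so generated interactions are
always interspecies. Defaults (chain length 3, types sampled from the
obligatory endoparasitism/endocommensalism pair) reproduce the worked
transmission chain's shape at its natural size.

What the generator does *not* emulate: free-text particulars and
anatomical detail (no occurs-in sites, no part-of anatomy), interactions
whose type changes over time, one-to-many host–population interactions,
and stores with missing or partial assertions (it always generates
complete, clean stores). Passing tests therefore show that the validator
is sound on well-formed chains and complete against the five injected
fault kinds — not that it catches every malformation a hand-curated store
could exhibit.

`inject_fault()` produces the negative cases: dropping a participant
tuple (R1), collapsing participants onto one taxon (R2), reversing a
precedes edge (R6), all-neutral outcome annotations (R7), and a
spatially-disjoint-from assertion inside an endosymbiosis (R3). Target
selection is seeded; the fault-detection study in the acceptance script
runs 100 seeded stores per fault kind, a size at which every fault kind is
exercised across all chain positions while the whole study stays
comfortably within interactive runtimes.

## Known limitations

* Class-expression axioms are emitted but not consumed: the importer
  rebuilds the graph from the declarations and is-a axioms and skips
  equivalence blocks, which is lossless for this package's objects but
  means foreign OWL files are only understood in the documented dialect.
* The description-logic limitation of the axioms themselves carries over:
  nothing in the exported restrictions states that the harmed organism is
  distinct from the benefited one.
* Intimacy is taken as given input (the contact mode) and advisory
  evidence (rule R8); the package does not attempt to infer it from
  behaviour, reflecting the acknowledged vagueness of the phrase.
* Whether a host interacting with a population of conspecific symbionts
  is one one-to-many interaction or many one-to-one interactions is left
  to the curator; the worked fixtures follow the one-interaction-per-
  aggregate convention.
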