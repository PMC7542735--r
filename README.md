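# symbiotax

Instance-level, realism-based representation of symbiotic interactions
between organisms.

## The problem

Terminological resources have long disagreed about what "symbiosis" means:
some thesauri equate it with mutually beneficial association, some define it
between *species* rather than between the individual organisms that actually
interact, and some define it circularly. Yet the interactions that matter to
epidemiology, microbiology and ecology — a dermatophyte colonising a
patient's skin, a malaria parasite moving between human hosts through a
mosquito vector, an aphid depending on its bacterial endosymbiont for amino
acids — happen between **individual organisms of different species**, and a
single organism can move from one interaction type to another over its
lifetime (a commensal *S. aureus* colony turning pathogenic). Capturing such
data requires (i) a principled taxonomy of interaction types with
machine-readable differentia, and (ii) an instance-level (referent-tracking)
representation of the particulars, their types, and the temporal regions
over which relations hold.

`symbiotax` is aimed at ontologists and informaticians who need to encode,
validate and exchange such data: it implements the taxonomy, a classifier, a
referent-tracking tuple store, a rule-based consistency validator,
deterministic OWL/RDF export with lossless round trip, the three worked
scenarios, and a seeded synthetic-scenario generator with fault injection.

## The representation

**Taxonomy.** `symbiosis` — *an interspecies interaction between two or more
organisms in intimate association* — sits under *interspecies interaction
between organisms* (GO:0044419), itself under *multi-organism process*
(GO:0051704). Axiomatically:

```
'interspecies interaction between organisms' and
  (('has participant' min 2 ('organism' and ('is bearer of' some 'contact')))
   or ('has occurrent part' some 'multi-organism behavior'
       and ('has participant' min 2 'organism')))
```

Three characteristics differentiate its 33 descendants (34 classes in the
branch including the root):

1. **Outcome** per participant: benefit (+), harm (−), neutral (0), with
   fatality splitting sibling classes (parasitism/parasitoidism,
   grazing/predation). The pairwise patterns map as +/+ → mutualism,
   +/0 → commensalism, +/− → agonism (ecto) or parasitism/parasitoidism
   (endo), −/0 → amensalism, −/− → antagonism. A 0/0 interaction
   ("neutralism") is a contradiction — a process that affects its
   participants affecting none of them — and has no class; the classifier
   raises a dedicated error instead.
2. **Location**: `ectosymbiosis` (participants spatially disjoint) vs.
   `endosymbiosis` (one organism located in another *extended organism*,
   so gut-dwelling organisms count as inside the host). Amensalism,
   antagonism and the agonism family are ecto-only.
3. **Necessity**: `obligatory …` subtypes realize a biological *function*
   of a participant; `facultative …` subtypes realize a *role* (merely
   advantageous). Each of the eight ecto/endo
   parasitism/parasitoidism/commensalism/mutualism classes has both
   refinements.

Two auxiliary process classes, `bodily harm` and `bodily benefit`
(APOLLO_SV:00000371/00000372), annotate outcomes outside the branch.

**Referent tracking.** Particulars get IUIs (`IUI-n`), temporal regions get
identifiers (`t_n`, with `t_max` = "at all times"), and assertions are
tuples: *particular instantiates type at t* and *particular relation
particular, holding at t*, over a closed relation vocabulary
(has-participant, occurs-in, part-of, precedes, occupies-temporal-region,
part-of-occurrent, proper-part-of-occurrent, has-input, has-output,
located-in, spatially-disjoint-from).

**Validation.** Eight rules (R1–R8) check stores against the axioms:
participant cardinality ≥ 2, interspecies participants, endo/ecto spatial
coherence, temporal parthood, precedes as a strict partial order, the
neutralism contradiction, and an advisory intimacy-evidence check.

## Worked example

```r
library(symbiotax)
tax <- build_taxonomy()
tax
#> Symbiosis taxonomy: 39 classes ( 36 minted, 3 imported )
#> Symbiosis branch size: 34

# a parasite benefits (and needs the interaction to realize a biological
# function); the host is harmed, non-fatally; the parasite lives inside it
profile <- interaction_profile(c("benefit", "harm"), fatal = FALSE,
                               spatial = "endo", necessity = "obligate")
classify_interaction(tax, profile)
#> [1] "obligatory endosymbiotic parasitism"

# the vector-transmission scenario: P. vivax (taxid 5855) moving between two
# human hosts (9606) through an A. gambiae mosquito (7165)
s2 <- build_scenario(2)
s2
#> Referent-tracking store: 9 IUIs, 10 temporal regions, 9 instantiation tuples, 19 relation tuples
participants_of(s2, "IUI-10")   # the mosquito and the parasite aggregate
#> [1] "IUI-5" "IUI-6"
temporal_check(s2)$order        # the four interactions in temporal order
#> [1] "IUI-9"  "IUI-10" "IUI-11" "IUI-12"

report <- validate_store(s2, tax)
report
#> Validation report: 0 error(s), 8 warning(s), 0 info
```

The eight warnings report assertions the printed scenario leaves out (no
located-in tuples for the endosymbioses, and temporal parthood only into
the hosts' lifespans, not the parasite aggregates') — incompleteness, not
contradiction. Injecting a contradiction is detected as an error:

```r
bad <- inject_fault(s2, "precedes_cycle", seed = 1)
validation_errors(validate_store(bad, tax))
#>   rule_id severity subject                   message
#> 1      R6    error <store> precedes contains a cycle
```

Exports are deterministic and lossless in all three formats:

```r
doc <- export_store(s2, "ttl")      # or "ofn", "json"
rt_equal(s2, import_document(doc))
#> [1] TRUE
```

A thin command-line wrapper is provided in `exec/symbio`:

```sh
exec/symbio classify --outcomes "+,-" --fatal false --spatial endo --necessity obligate
exec/symbio scenario 2 --out store.json
exec/symbio validate store.json        # exit 0 = valid, 1 = errors, 2 = usage
exec/symbio export --taxonomy --format ttl --out taxonomy.ttl
exec/symbio generate --seed 7 --chain 4 --out synthetic.json
exec/symbio inject --fault same_species --seed 1 --store store.json --out bad.json
```

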