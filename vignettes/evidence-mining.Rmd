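---
title: "Mining species interactions and their geography from sequence and citation metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining species interactions and their geography from sequence and citation metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cargomine)
```

## The problem

Descriptive metadata attached to public nucleotide-sequence submissions is a
large, systematically collected — and systematically under-used — record of
where organisms have been found and what they have been found *in* or *on*.
A sequence record for a pestivirus may carry a `host` qualifier reading
"sheep" and a `country` qualifier reading "Italy: Milan"; together with the
taxonomic identity of the sequenced organism these two free-text fields are
evidence of a species–species interaction (the virus was found in *Ovis
aries*) and of a species–location interaction (the virus was found in Italy,
in Lombardy).  Citation metadata adds an independent, complementary signal:
two organisms repeatedly discussed in the same papers are plausibly
interacting, and a species repeatedly discussed in papers about a country is
plausibly present there.

cargomine implements this extraction pipeline offline and file-driven: every
input is a plain-text table or XML file, and every stage is testable against
a synthetic corpus with known ground truth.  Because the evidence base is
generic we use the neutral terms **cargo** (the species found in/on another,
often a pathogen) and **carrier** (the species it is found in/on, often a
host): an organism pathogenic in one host may be commensal in another, so
pathogenicity is a property of the interaction, not the organism.

## The pipeline

### Taxonomy and rank normalization

Public taxonomy dumps tag many strains, isolates and unclassified entries as
"species".  Since the unit of output is the species, non-viral ranks at or
below species level are re-derived from the shape of the scientific name,
applying the first matching rule of:

1. any decimal digit in the name → *no rank*;
2. any of the tokens `unclassified`, `uncultured`, `var` (token-boundary,
   case-insensitive, so `var.` matches and `Varanus` does not) → *no rank*;
3. exactly two whitespace tokens → *species*;
4. three or more tokens → *subspecies*;
5. one token → *no rank*.

Viruses and viroids are exempt — virus nomenclature is legitimately
multi-word and digit-bearing ("Pestivirus type 2").  Two points here are
design choices rather than received rules, and we record them explicitly:
the rules are evaluated **in the listed order with first-match-wins**,
because the demotion rules must override binomial shape ("Bacillus sp. 56"
has a digit *and* could miscount as a binomial); and a **one-word** non-viral
name gets *no rank*, because a single token cannot be a binomial.
Reclassification is idempotent, which the test suite checks by property.

Everything below species level rolls up: `resolve_to_species()` walks parent
links to the first species-level ancestor, and organisms at genus level or
above are discarded.  Organisms of interest missing from the dump are forced
into the tree under a preferred parent, or under a configured per-category
fallback node.

### Host disambiguation

The `host` qualifier is free text.  Matching is staged, and the first stage
to succeed wins: (1) normalized exact match against scientific names;
(2) match against curated alternative-name sets (common names, breeds,
misspellings, acronyms); (3) a heuristic that strips parenthetical qualifier
text ("cattle (dairy)") and retries, then tries the leading two-token
binomial ("Bos taurus breed Holstein") and retries.  The staging is this
package's own definition of the disambiguation step; the governing principle
is **precision over recall**: a key matching two or more distinct species at
the same stage is never guessed, and a match above species level is
discarded rather than approximated.  Multi-host strings ("cow; goat") are
deliberately left unresolved and logged — splitting them would require a
policy for dividing the evidence that no input we model specifies.

Normalization throughout (hosts and places alike) is case-folding, diacritic
stripping, whitespace collapsing and edge-punctuation trimming; it is
idempotent, so normalized keys can be looked up as raw keys.  There is no
fuzzy matching anywhere: edit-distance matching would trade auditable
precision for recall, and the discard log makes the misses visible instead.

### Two-level geolocation

`country` qualifiers follow the `"Country: Location"` convention and are
split at the first colon.  The country part is matched against a gazetteer
of countries, alternative country names, historical countries and water
bodies.  Historical countries (Yugoslavia) are discarded unless the location
part identifies a present-day country — by naming one, or by naming a place
inside a configured successor country; the successor table is configuration,
not algorithm.  Water bodies are discarded unless the location part rescues
a country, and also when the location part is itself a water body.
Contradictory strings ("USA: Japan") resolve by the country part.

Region identification targets the first administrative division only
(states, home nations, provinces).  The location part is split into
candidate substrings — comma/semicolon-delimited chunks plus their
individual whitespace tokens — and every candidate is looked up within the
already-identified country.  Matches are ranked by tier: admin1 (and state
codes, which count as admin1) beat capitals beat second- and third-level
divisions beat cities, towns, villages; the **highest-tier** match wins.
Ties at equal tier break to the leftmost candidate, with a whole-chunk match
beating a single-token match — the candidate grammar and tie-breaks are this
package's definitions, chosen to make the result total and deterministic.
Two guards matter in practice: state codes only match tokens that are whole
uppercase 2–3 letter strings *before* normalization (so "MA" resolves to
Massachusetts but the "ma" in "Palma" cannot), and countries flagged as
having no usable administrative divisions (microstates) skip region
identification entirely.

### Literature evidence

PubMed-style search terms are generated per organism as
`((any of the names and alternative names) AND (all inclusion terms)) NOT
(any exclusion terms)`, with names lowercased, deduplicated and
alphabetically ordered, each curly-quoted and tagged `[Text Word]`.  The
rendering reproduces the published query dialect exactly, including its
idiosyncrasy that the final element of a multi-term OR group carries no
space before its field tag.  Country queries use the MeSH vocabulary where
the country is listed and a title/abstract query over official plus
alternative names where it is not; region queries OR-join the region name
with its configured major cities and landmarks.

The package never queries services: PMID sets arrive as files, and a small
adapter can derive them from raw title/abstract records by substring match.
Evidence is set intersection.  Region citations count only where the paper
is also about the country (PMID~RC~ = PMID~R~ ∩ PMID~C~).  A cargo–carrier
or species–location pair supported *only* by citations requires **at least
five shared papers** — the threshold is inclusive at five — while shared
citations attach to sequence-backed pairs without any threshold.  We read
the threshold as applying to publication-only interactions exclusively,
which is how the two-step assembly is implemented.

### Assembly and export

Step one accumulates sequence evidence per (cargo, carrier) and per
(species, country[, region]) pair; step two intersects PMID sets over the
cargoes and carriers the sequence corpus defined.  Self-pairs (a species
co-cited with itself) are skipped in the publication-only route.  Exporters
write the two published CSV schemas — interactions with cargo/carrier names,
classifications, evidence counts and semicolon-separated identifier lists;
locations with species, country, region and the same evidence fields.
Identifier lists are truncated to the first 100 in ascending numeric order
(the truncation order is our choice, for determinism); counts always
reflect untruncated totals.  The category cross-tab counts unique pairs,
with a configurable domestic-animal list overriding the carrier
classification (never for humans).

### Validation statistics and the sharing network

`overlap()` implements the share/union arithmetic used to compare the mined
dataset against external lists: shared count, the two directed percentages,
and the union.  Percentages are rounded **half-up** to two decimals, which
is the convention the reproducible published cells follow; base R's
round-half-to-even would disagree on boundary values.  External lists enter
as plain identifier TSVs; synonym harmonization is a user-supplied mapping,
out of algorithmic scope, and a reader flag drops negative-prevalence rows
for presence-only comparison.  `shared_cargo_network()` summarizes cargo
sharing as an undirected graph — node weight the number of unique cargo
species per carrier, edge weight the number shared — exported as an edge
list or GraphML; layout is out of scope.

## The synthetic corpus

`generate_fixture()` builds every input from one seed: a taxonomy with
deliberate rank misannotations for the reclassifier to fix (virus names
exempt), forced-in supplemental organisms, unique common names per carrier,
a gazetteer embedding the demonstration entries plus synthetic countries
with regions and towns, a record corpus, and PMID sets with planted
co-citation blocks.  The qualifier rates default to the corpus conditions
the pipeline is designed for — 7.1% of records carry a host qualifier,
17.5% a country qualifier, and 59.9% of country qualifiers carry
sub-country text — and the generator's ground-truth tables are derived from
its own construction, never by running the pipeline.  PMID blocks are
allocated from disjoint ranges so that planted overlaps are the only
overlaps: pairs planted with five or more shared papers must surface as
publication-only interactions, pairs planted with one to four must not.

Noise rates (garbled hosts, unresolvable historical countries, bare water
bodies) default to zero: the clean corpus is the reference condition under
which the pipeline must achieve precision = recall = 1, and the noise
classes exist to exercise the discard accounting (every non-recovered
record must appear with the correct reason).  What the fixture does *not*
emulate is the messiness of real free text — truncated Latin names,
vernacular spellings outside the curated sets, multi-host strings — so
passing the recovery test demonstrates the correctness of the machinery,
not the real-world disambiguation rate.

The test suite runs the recovery property at 10^4 records and the unit
suites at a few hundred to a couple of thousand records; these sizes give
stable binomial checks on the qualifier rates (3σ bands) while keeping the
whole suite fast.

## Numerical and degenerate-input choices

* Empty host strings and empty organism-name sets are errors; absent
  qualifiers are values (`NA`), never errors.
* A malformed XML record is skipped and logged with a reason; a file that
  does not parse at all is an error.
* `overlap()` on an empty side is an error (the percentage is undefined),
  not a `NaN`.
* Unknown tax_ids in lookups are errors; unknown tax_ids in a corpus are
  discards.
* All matching is exact post-normalization; determinism is tested by
  re-running assignments and regenerating fixtures.

## Limitations

* The host-disambiguation heuristic is intentionally minimal; its recall on
  real host strings depends entirely on the curated alternative-name sets.
* Historical-country rescue depends on the configured successor map and the
  gazetteer's coverage of successor-country places.
* The gazetteer tier vocabulary is fixed configuration; tiers below admin1
  serve only as evidence for their admin1 region.
* Corpus-scale figures from real snapshots (millions of records, curated
  name sets for hundreds of thousands of organisms) are outside what the
  synthetic corpus can or should reproduce; the package validates machinery
  and arithmetic, and ships the published-table arithmetic as computed
  checks.
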