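---
title: "Mining age-phenotype evidence from abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining age-phenotype evidence from abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemine)
```

## The problem and the model

Statements linking an age or age range to a disease are abundant in
biomedical abstracts but unstructured. `agemine` extracts them with a
deliberately rule-based, inspectable pipeline — regular expressions and
dictionaries rather than statistical models — which trades sensitivity for
precision and auditability: every extraction can be traced to a named
pattern, cue or lexicon string, and every behavioural table is data that a
user can replace.

The unit of knowledge is the **evidence instance**: one normalized age
range from one abstract, linked to phenotype concepts through a short
whole-sentence snippet, carrying one of five relationship types (age of
onset, diagnosis, observation, occurrence, evaluation), a gender when the
snippet mentions exactly one, and publication metadata. Two hard
population rules apply: an instance whose relationship cannot be
determined, or that maps to no phenotype, is never stored.

## Age detection and normalization

Ages are recognised only when written numerically and anchored by an age
cue word (*year(s)/yr(s)*, *month(s)*, *week(s)*, *day(s)*, *age(d)*,
*old*); spelled-out numbers ("two to five years old") and bare numbers are
deliberately not parsed, which avoids mistaking durations, doses and counts
for ages. The pattern table (`age_patterns()`) distinguishes five roles:

* `range` — "between 45 and 64 years", "12 to 18 years", "aged 20-35";
* `open_low` / `open_high` — "under 5 years", "30 years or less",
  "70 years or more": the unstated bound is filled from the 0–120-year
  human age span and the range is flagged **inferred**;
* `point` — "59-year-old", "6 months old", "at age 34";
* `mean` — "mean age was 47": a point range recording a group average.

Sub-year units convert at 1 month = 1/12 year, 1 week = 1/52, 1 day =
1/365; bounds are clamped to [0, 120]. The 120-year ceiling is taken from
the adult age-class upper bound and is the single maximum used everywhere
(inference, classes, the count matrix).

When patterns overlap on the same text ("aged 30 years or less" contains
"aged 30 years"), the higher-priority pattern wins, then the longer match,
then the earlier one; open-ended and range patterns outrank point patterns,
which outrank "aged N". One candidate instance is kept per distinct
normalized range. When an abstract states both an explicit range and a
group mean, the range wins by default: preferring the mean is a documented
failure mode of early rule sets, reproducible with
`legacy_mean_priority = TRUE` for comparison.

Each range receives the most specific **age class** whose interval contains
it: infant newborn [0, 1/12], infant [0, 2], preschool child [2, 6], child
[2, 12], adolescent [12, 18], young adult [18, 24], adult [18, 120], middle
aged [45, 64], aged [64, 120], 80-and-over [80, 120], with a root class
[0, 120] for ranges no other class contains. "Most specific" means smallest
interval width; the only possible ties are point ages on shared class
boundaries (e.g. exactly 18), broken deterministically in favour of the
earlier-listed, younger-starting class. Property tests check the
implementation against an independent brute-force containment scan on
10,000 random ranges, and that every point age is covered by a non-root
class.

## Relationship typing

Cues for the five types live in `relation_cues()` with a precedence level:
onset > diagnosis > observation > occurrence > evaluation, on the rationale
that specific clinical events should outrank generic study verbs when both
occur ("disease onset occurred at age 34" is an onset statement even though
*occurred* also fires). Matching goes beyond bag-of-words co-occurrence:
cues are sought first in the mention's sentence, then in the adjacent
sentences, then in the whole abstract, and the first non-empty window
decides. Within a window, precedence level wins, then proximity to the age
mention, then earlier text position — fully deterministic. If no cue fires
anywhere the mention abstains (`UNDETERMINED`) and is later dropped by the
population filter.

The original per-type expression lists this design stands in for are not
public; the table here was written from the semantics of the five type
names and is exposed as replaceable data (TSV) precisely so users can
substitute their own. Conditional relationships (an age linked to ulcers
*in HIV-positive patients*) are out of scope: the pipeline will link the
age to both phenotypes independently, a known limitation shared with the
class of tools it belongs to.

## Snippet generation

The snippet is 1–3 whole sentences — never truncated, possibly
non-consecutive — always containing the age sentence. Other sentences are
scored: +3 for a concluding sentence (a CONCLUSION(S) section, or the final
sentence of an unstructured abstract), +2 for patient/subject wording, +2
for a cue of the assigned relationship type, +1 for adjacency to the age
sentence; the two best positive scorers join, ties to the earlier sentence.
The factor list (structure, concluding sentence, patient/subject wording,
relationship type) defines the score; the exact weights are this package's
own choice, made explicit so they can be tested — the reference procedure
they replace is not publicly recoverable.

Structured abstracts are detected by uppercase section headings (≤4 words
ending in a colon at a sentence start, from a configurable label set:
OBJECTIVE, BACKGROUND, METHODS, RESULTS, CONCLUSIONS, PATIENTS, DESIGN,
SETTING, …). Sentences are segmented by a rule-based splitter
(terminal `.?!` + space + capital/digit) with an abbreviation exception
list (e.g., i.e., vs., Dr., Fig., no., approx., et al., single-letter
initials) and no splitting inside decimal numbers; sentences never cross
section boundaries. Character offsets are 1-based inclusive throughout,
matching `substr()` semantics in R.

## Phenotype mapping

Mapping is **perfect-match only**: lexicon strings (ontology term names and
synonyms first, then concept-subset strings) are sought in the snippet
after normalization — lowercase, collapsed whitespace, surrounding
punctuation stripped, no stemming, no fuzzy matching — on token boundaries,
so "man" never matches *human* and "flu" never matches *fluid*. All
occurrences of all strings are reported: when "squamous cell carcinoma"
matches, the nested "carcinoma" match is kept too but flagged **redundant**,
as is any hit whose ontology term is a strict ancestor of another hit's
term. Redundant hits are harmless — they add generality, not error — and
are excluded from phenotype queries and the clustering matrix by default
(flags restore them). Redundancy is resolved longest-span-first against
already-kept hits, which guarantees that deleting a redundant hit never
changes the non-redundant set.

The disease ontology is read from OBO 1.2 (`id`, `name`, `synonym`,
`is_a`, `xref` tags; obsolete terms skipped; cycles and missing parents are
errors). A licensed concept vocabulary cannot be shipped, so the concept
subset is a neutral three-column TSV (concept ID, semantic type, string)
restricted to a semantic-type allow-list defaulting to disease, drug and
finding; disease-type concept hits whose IDs are cross-referenced by an
ontology term inherit that term, which is how concept hits join the
disease hierarchy. A synthetic mini-lexicon ships for testing.

A property suite checks the matcher against an independent brute-force
position-by-position scan on 1,000 random snippets.

## The evidence store and queries

Queries come in three modes — by age, by phenotype, or both — plus
conjunctive refinement filters (publication year, publication type,
curation status, relationship type, gender). Age matching uses **interval
intersection**: the browser question is "what evidence touches this age
(range)?", and overlap is the natural reading; a strict containment mode
(`contained = TRUE`) is provided since the alternative reading is
defensible. Phenotype queries expand over the ontology: the query term or
any descendant matches, so high-level terms retrieve all their subtypes.
The curated-subset preset (`wiki_preset = TRUE`) keeps only
onset/diagnosis/observation evidence with non-inferred ranges — the subset
worth surfacing to human curators.

Persistence is JSON-lines with a schema header, ordered by instance ID so
unmodified stores rewrite byte-identically; a relational-style TSV export
of query results is available through the CLI. Corrupt or
version-mismatched files fail loudly with no partial load.

## Disease-age clustering

For every disease mapped in the store, instances are counted per integer
age: an instance with range [12, 18] adds one count to each of ages 12–18
for each of its (non-redundant) diseases; fractional bounds round outward,
since counting "instances per age" requires a discretization and outward
rounding never drops a covered age. Inferred ranges are excluded — an
inferred [0, 30] would smear one mention across 31 cells of fabricated
precision. Rows are normalized by the **number of instances** associated
with the disease (not the row sum: that is the literal reading of
"instances associated with that disease"; `row_sum = TRUE` gives the
alternative), which corrects literature-coverage bias and makes row
duplication of the store a no-op — a tested invariance. Note rows of
multi-age instances deliberately sum to more than 1.

Diseases cluster agglomeratively with distance `1 − r` (Pearson, so
distances lie in [0, 2]) on normalized rows; zero-variance rows are
excluded (correlation undefined) and diseases with fewer than
`min_instances = 5` instances are dropped to suppress unstable singleton
profiles (configurable). Average linkage (UPGMA) is the default because it
is the customary choice for profile correlation matrices; complete and
single linkage are available. Dendrograms export as Newick via `ape`
(colons in term IDs are sanitised, as ":" is Newick syntax). Cluster age
profiles are the per-age mean of member count rows; the peak is the
earliest age attaining the maximum.

## The synthetic-data generator

`generate_corpus()` emulates the study conditions end to end: each
age-related abstract embeds one sampled age rendered through one of the
package's own extraction patterns (point, range or open-ended), one
relationship cue phrase (or none), one disease name from a 13-term
two-branch mini ontology, and gendered wording, inside either a structured
(OBJECTIVE/METHODS/RESULTS/CONCLUSIONS) or unstructured abstract. Defaults
— 200 abstracts, the five relationship types at equal weight plus a 20%
no-cue fraction, 10% inferred ranges, 10% non-age-related abstracts, 30%
structured, gender mix 40/30/30 — were chosen once as a realistic desk-scale
test bed with every pipeline branch exercised, and are not tuned
thereafter. Gold tables record every planted value; a single seeded RNG
stream (restored afterwards) makes outputs byte-identical per seed. A
`corruption` parameter rewrites ages non-numerically so that recovery
degrades, for monotonicity testing.

`generate_two_group_store()` plants the clustering fixture directly: two
groups of five diseases with single-age instances drawn from normal
profiles (sd 3) peaking at 20 and 60 — echoing the real-world contrast
between diseases of youth (sexually transmitted infections) and of late
middle age (cancers, cardiovascular disease). Thirty instances per disease
keep within-group correlations high enough that a 2-cut recovers the
partition exactly (adjusted Rand index 1) across 20 seeds, which the
acceptance suite asserts.

What passing these tests does **not** show: real abstracts paraphrase ages
in ways no finite template set covers, mention multiple cohorts, negate
("no cases under 40"), hedge, and use disease names with abbreviations and
morphology the perfect matcher will miss. The synthetic corpus measures
internal consistency — that the pipeline recovers exactly what its own rule
tables can express — not real-world sensitivity, which for this family of
rule-based miners is known to trade away recall for precision.

## Evaluation harness

Four scorers mirror a four-task human-reader protocol: age-related-abstract
detection (precision/sensitivity/F over PMIDs plus the fraction of
perfectly extracted ranges among true positives), relationship assignment
(fractions correct / undetermined of all records, and incorrect among
assigned), snippet quality (via the gold TSV's three-way judgement), and
phenotype mapping per instance. Mapping has two modes: harmless redundant
extras either excluded from false-positive counting or counted as false
positives; gold phenotypes absent from both lexicons are true negatives and
excluded from the denominator. Zero-denominator conventions are explicit:
precision is 0 (with a warning) when nothing was retrieved but gold is
non-empty, and incorrect-of-assigned is `NA` when nothing was assigned —
never a silent `NaN`.

## Numerical and interface choices

* Offsets: 1-based inclusive spans everywhere (R `substr()` convention).
* Determinism: no stage uses randomness; fixtures take a mandatory seed and
  restore the caller's RNG state.
* Degenerate inputs: empty abstracts are rejected at segmentation; an empty
  ontology warns; an all-inferred store cannot build a matrix (error, not
  an empty matrix); fewer than two usable rows cannot cluster.
* Test problem sizes: 1,000 random snippets for the matcher oracle, 10,000
  random ranges for the age-class oracle, 200 clean abstracts for full
  planted recovery, 20 seeds for cluster recovery — sizes at which every
  property has repeatedly flagged real defects during development while
  keeping the default suite fast.
* The command-line front end (`inst/scripts/agemine`) is a thin wrapper
  with verbs for simulating, parsing, populating, querying, clustering and
  evaluating; the intermediate stages (age extraction, relationship typing,
  snippet building, mapping) are exposed as R functions, which are the
  intended API for stage-wise use.

## Known limitations

Numeric-only age parsing; no negation, hedging or abbreviation expansion;
no word-sense disambiguation (a perfect match is a hit even in a negated
clause); conditional age-phenotype relationships are flattened into
independent links; English only; titles are not mined unless
`include_titles = TRUE`. These are deliberate boundaries of a
precision-first, rule-transparent design.
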