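---
title: "Quantifying information overlap between coded events and clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying information overlap between coded events and clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehroverlap)
library(dplyr)
```

## The problem

An electronic health record stores the same clinical reality twice: as
structured, coded events (conditions, drug prescriptions, measurements,
observations, procedures) and as free-text notes. How much of the coded
information is restated in the text, and how much of what clinicians
write ever becomes a code? `ehroverlap` answers this with a directional,
occurrence-level overlap estimate:

1. **Extract** concept mentions from note text (dictionary longest-match
   against the vocabulary, with ConText-style qualifier rules for
   negation, temporality and experiencer; qualified mentions are
   excluded so only asserted, present, patient-experienced concepts are
   compared).
2. **Embed** every concept as one vector: the arithmetic mean of its
   per-synonym encoder outputs; measurement and observation concepts are
   embedded from descriptions enriched with a representative value and
   unit (`"systolic blood pressure: 140 mmHg"`).
3. **Match** within comparison groups — a single visit, or the whole
   patient record — by taking the Cartesian product of structured and
   extracted concepts and keeping, per concept and direction, only the
   highest cosine similarity. The two directions are deliberately not
   reciprocal.
4. **Calibrate** a similarity threshold by minimising the weighted Gini
   impurity of the similar/nonsimilar split over annotated concept
   pairs, sampled stratified by similarity bin and domain.
5. **Quantify**: the percentage of concept occurrences whose best
   counterpart reaches the threshold, per direction, grouping, domain
   and subpopulation.

Exact code agreement is deliberately not required: a coded
"fracture: hand/foot bone" and an extracted "closed fracture of hand"
should count as the same information even though the vocabularies
differ. Cosine similarity between concept embeddings supplies that
fuzziness; the calibrated threshold decides how much of it to accept.

## A worked run on synthetic data

Real GP databases cannot be redistributed, so the package ships a
generator that plants a *known* overlap and keeps the bookkeeping
needed to verify every stage.

```{r worked-run}
cfg <- synth_config(seed = 42, n_patients = 100, p_mention = 0.4,
                    cluster_noise = 0, p_outside_visit = 0)
vocab <- generate_vocabulary(cfg)
pop <- generate_population(cfg, vocab)

lexicon <- build_lexicon(vocab)
mentions <- extract_concepts(pop$notes, lexicon) |>
  apply_context_rules(pop$notes) |>
  filter_unmodified()

encoder <- synthetic_encoder(vocab, dim = 64, cluster_noise = 0, seed = 42)
index <- embed_concepts(vocab, encoder, events = pop$events, enrich = TRUE)

matches <- run_matching(pop$events, mentions, pop$notes, index,
                        grouping = "visit", vocabulary = vocab)
glance(quantify_overlap(matches, threshold = 0.65))
```

With `cluster_noise = 0` every planted mention matches its code at
cosine 1, so the structured-to-unstructured percentage re-estimates the
planted `p_mention = 0.4` up to binomial noise. (With the default
`p_outside_visit = 0.5` half the notes detach from their visits and the
visit-level estimate shrinks accordingly — which is exactly what that
parameter models.) This *parameter
recovery* is the package's headline correctness property and is
enforced in the test suite to within two percentage points at five
thousand coded occurrences.

## The model and its conventions

**Grouping.** Visit grouping compares what was recorded together during
one encounter; events and notes without a visit link are excluded there
(they are the labs and secondary-care letters recorded outside visits).
Record grouping pools everything a patient has, so each concept faces a
superset of counterparts and best similarities can only grow — record
overlap percentages therefore dominate visit percentages on the same
data.

**Counting.** The unit is the concept *occurrence*, not the distinct
concept: similarity is computed once per distinct pair within a group
(it depends only on concept identity), and the occurrence count carries
the multiplicity back into the totals. Matchless concepts — empty
counterpart side, or no usable embedding — stay in the denominator:
they are genuinely uncomplemented information, and dropping them would
inflate overlap. A distinct-concept mode remains available
(`quantify_overlap(distinct_concepts = TRUE)`) as a sensitivity check.

**Embedding.** Synonym vectors are averaged raw, before any
normalisation; cosine removes scale afterwards. Averaging duplicated
synonym lists is a no-op (tested); antipodal synonym pairs cancel to a
zero vector, and such concepts are excluded with a warning rather than
silently matched at an undefined angle. Value/unit enrichment uses one
representative per (concept, unit) — the median observed value — so the
index stays concept-keyed. Per-event embedding would multiply index
size by event count for no benefit at the matching stage, which works
on concepts; the median representative is a deliberate simplification.

**Threshold calibration.** Candidate thresholds run from 0.35 to 1.00
in steps of 0.05 — below 0.35 pairs are reliably unrelated, and 0.05 is
the resolution at which annotation effort is spent. The split
convention is inclusive (`similarity >= t` counts as matched), used
identically in calibration and quantification. Per sample the whole
argmin set is reported; the global choice is the *largest* minimiser
across samples — the conservative rule, preferring to miss borderline
matches over accepting spurious ones. Ties inside a group's maximum
take the lexicographically smallest counterpart id, which fixes
determinism without affecting the reported similarity.

## What the synthetic generator emulates — and what it does not

The generator emulates a primary-care EHR at the structural level:
Poisson visit and event counts (visits clamped to at least one per
patient), five coded domains, one SOAP-style consultation note per
visit, extra text-only concepts, planted negations, and a configurable
fraction of material recorded outside visits (default 0.5, echoing GP
databases where record-level event totals run a multiple of the
visit-linked ones). Default intensities — about three coded events and
a handful of extracted concepts per visit, mention probability 0.4 —
sit near the per-visit medians and the extracted-to-structured ratios
reported for large GP databases.

It does **not** emulate clinical language. Note text is filler tokens
with embedded surface forms; surface forms are globally unique, so
extraction ambiguity is zero by construction. This is deliberate: the
dictionary extractor is a pluggable stand-in for a validated clinical
NER+L framework, and the synthetic fixture isolates the matching and
threshold machinery from extractor quality. Consequently, passing tests
demonstrate that the *pipeline* recovers planted quantities faithfully;
they say nothing about extraction recall on real Dutch clinical text,
which must come from a validated external extractor emitting the same
mention schema. The same applies to the synthetic encoder: its
near-orthogonal latent geometry (random unit vectors in 64 dimensions,
within-concept noise `cluster_noise`) is a controlled idealisation of a
real multilingual sentence encoder's 768-dimensional space.

The annotation stand-in (`simulate_annotations()`) mirrors this logic
for threshold calibration: four direction-by-grouping samples, up to
five pairs per similarity bin and domain, labels driven by a latent
boundary at 0.60 with 5% label noise within one grid step of the
boundary — annotators disagree most where pairs are genuinely
borderline. Files written from it are synthetic and are named as such;
with a real annotated release, `read_annotations()` loads it directly
(a column-mapping argument absorbs foreign headers, and a key check
rejects files whose pairs were edited or reordered between export and
import).

## Numerical choices and degenerate inputs

* Cosine similarities are clamped to `[-1, 1]`; matrix-product
  similarities agree with the pairwise definition to well under 1e-9
  (tested).
* Zero-norm vectors are a domain error at the cosine level and an
  exclusion-with-warning at the index level.
* Argmin sets on the impurity curve use a 1e-12 tolerance so
  floating-point noise cannot split a flat minimum.
* Empty inputs degrade gracefully: empty notes yield no mentions, empty
  match tables yield zero-total reports with a warning, single-label
  annotation samples warn that their minimum is trivial.
* Unknown domains collapse to `"other"` with a warning rather than an
  error; the domain inventory of source vocabularies is open-ended.
* All randomness flows from one integer seed through independent
  derived streams (a small string-hash of the stage name), so the
  generator, the sampler and the pipeline are reproducible from a
  single knob; identical config and seed give byte-identical CSVs.

## Problem sizes

The shipped tests and the acceptance script use populations of 25–250
patients (up to ~1,000 visits and ~6,000 coded occurrences for the
recovery checks), 200 concepts with 3 synonyms each, and 64-dimensional
embeddings. These sizes give binomial noise comfortably inside the
two-percentage-point recovery band while keeping a full run in the
order of a minute; all stages scale linearly in occurrences except
matching, which is quadratic per group in distinct concepts (a visit
has few; a whole record has tens).

## Known limitations

* The dictionary extractor has no disambiguation: colliding surface
  forms resolve to the lowest concept id, logged. Real text needs a
  real extractor behind the mention schema.
* Time is ignored within a group; record grouping happily matches a
  concept coded in 2021 to text written in 2023. Nearest-visit
  assignment or sliding windows are out of scope.
* One threshold serves all domains and populations; per-domain
  calibration would need per-domain annotation samples.
* Overlap percentages are reported without confidence intervals; at
  occurrence counts in the thousands the binomial error is a fraction
  of a point, but small subpopulations deserve caution.
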