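# ehroverlap

Quantifies the information overlap between the two halves of an
electronic health record: structured, coded clinical events (conditions,
drugs, measurements, observations, procedures) and free-text notes. It
is written for EHR researchers who need to know, before designing an
observational study on a database, how much of the coded information is
restated in text and how much of the narrative ever becomes a code.

## Method

For each comparison group — a single patient visit, or a whole patient
record — the package:

1. extracts concept mentions from note text by dictionary longest-match
   against the vocabulary, attaches ConText-style qualifiers (negation,
   temporality, experiencer) by trigger rules, and keeps only
   unmodified mentions;
2. embeds every concept as the mean of its synonym description vectors
   (value/unit-enriched for measurements and observations) through a
   pluggable encoder;
3. forms the Cartesian product of the *m* structured and *n* extracted
   concepts in the group (*m·n* cosine evaluations) and keeps, per
   concept and direction, only the best match:

   `s2u(c) = max over extracted e of cos(v_c, v_e)`, and symmetrically
   for `u2s(e)` — the two directions are not reciprocal;
4. calibrates the similarity threshold *t\** by minimising the weighted
   Gini impurity of the similar/nonsimilar split over annotated pairs:

   `G(t) = (|A|/n)·gini(A) + (|B|/n)·gini(B)`, with
   `A = {pairs: sim ≥ t}`, `gini(X) = 1 − p² − (1−p)²`, taking the
   largest per-sample minimiser as the conservative choice;
5. reports, per direction, grouping, domain and subpopulation, the
   percentage of concept occurrences whose best counterpart reaches
   *t\**, together with raw counts and a full threshold-sweep curve.

A synthetic EHR generator plants a known mention probability
(`p_mention`) so that the whole pipeline can be validated by parameter
recovery, and a synthetic annotation generator stands in for a manual
annotation round where none is available.

## Worked example

```r
library(ehroverlap)

cfg <- synth_config(seed = 42, n_patients = 100, p_mention = 0.4,
                    cluster_noise = 0, p_outside_visit = 0)
vocab <- generate_vocabulary(cfg)
pop <- generate_population(cfg, vocab)

mentions <- extract_concepts(pop$notes, build_lexicon(vocab)) |>
  apply_context_rules(pop$notes) |>
  filter_unmodified()

encoder <- synthetic_encoder(vocab, dim = 64, cluster_noise = 0, seed = 42)
index <- embed_concepts(vocab, encoder, events = pop$events, enrich = TRUE)
matches <- run_matching(pop$events, mentions, pop$notes, index,
                        grouping = "visit", vocabulary = vocab)
glance(quantify_overlap(matches, threshold = 0.65))
#> # A tibble: 2 × 7
#>   population grouping direction               total matched percentage threshold
#>   <chr>      <chr>    <chr>                   <int>   <int>      <dbl>     <dbl>
#> 1 all        visit    structured_to_unstruct…   956     384       40.2      0.65
#> 2 all        visit    unstructured_to_struct…  1255     381       30.4      0.65
```

Forty percent of coded concepts were planted into their visit's note
(`p_mention = 0.4`), and the structured-to-unstructured row re-estimates
that as 40.2% of 956 coded occurrences — the parameter recovery that
anchors the package's correctness. Threshold calibration from an
annotation file looks like:

```r
ann <- simulate_annotations(seed = 42)   # synthetic stand-in for a manual round
tr <- find_threshold(ann)
glance(tr)
#> # A tibble: 1 × 5
#>   threshold n_samples band_lo band_hi min_impurity
#>       <dbl>     <int>   <dbl>   <dbl>        <dbl>
#> 1       0.6         4     0.6     0.6      0.00612
```

`autoplot(tr)` draws the per-sample impurity curves,
`plot_threshold_sweep()` the overlap-versus-threshold curves, and
`autoplot()` on an overlap report the per-domain breakdown.
`run_pipeline(overlap_config(...))` chains every stage and writes a
report directory with a manifest of row counts and content hashes; see
the vignette in `vignettes/information-overlap.Rmd` for the model,
conventions and limitations.

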