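# End-to-end helper: run the synthetic population through extraction,
# embedding and matching, returning the match table(s).
run_synthetic_matches <- function(cfg, groupings = "visit") {
  v <- generate_vocabulary(cfg)
  pop <- generate_population(cfg, v)
  lex <- build_lexicon(v)
  um <- filter_unmodified(
    apply_context_rules(extract_concepts(pop$notes, lex), pop$notes))
  enc <- synthetic_encoder(v, cfg$embedding_dim, cfg$cluster_noise, cfg$seed)
  idx <- embed_concepts(v, enc)
  matches <- dplyr::bind_rows(lapply(groupings, function(g) {
    run_matching(pop$events, um, pop$notes, idx, g, v)
  }))
  list(matches = matches, vocabulary = v, population = pop)
}

test_that("full planted overlap gives 100% structured-to-unstructured", {
  cfg <- synth_config(seed = 101, n_patients = 30, p_mention = 1,
                      cluster_noise = 0, p_outside_visit = 0, p_negated = 0)
  r <- run_synthetic_matches(cfg)
  rep <- quantify_overlap(r$matches, 0.65)
  s2u <- glance(rep)
  s2u <- s2u[s2u$direction == "structured_to_unstructured", ]
  expect_equal(s2u$percentage, 100)
  expect_equal(s2u$matched, s2u$total)
})

test_that("no planted mentions and no extras give empty totals", {
  cfg <- synth_config(seed = 102, n_patients = 10, p_mention = 0,
                      extra_mentions_per_visit = 0, p_outside_visit = 0)
  v <- generate_vocabulary(cfg)
  pop <- generate_population(cfg, v)
  um <- filter_unmodified(apply_context_rules(
    extract_concepts(pop$notes, build_lexicon(v)), pop$notes))
  expect_equal(nrow(um), 0L)
  idx <- embed_concepts(v, synthetic_encoder(v, 64, 0, 102))
  m <- run_matching(pop$events, um, pop$notes, idx, "visit", v)
  rep <- quantify_overlap(m, 0.65)
  gl <- glance(rep)
  # the structured side has totals but no matches; the extracted side is absent
  expect_equal(sum(gl$matched), 0L)
})

test_that("the all-domain row is the exact sum of its domain rows", {
  cfg <- synth_config(seed = 103, n_patients = 40)
  r <- run_synthetic_matches(cfg, c("visit", "record"))
  rep <- tibble::as_tibble(quantify_overlap(r$matches, 0.65))
  sums <- rep |>
    dplyr::filter(domain != "all") |>
    dplyr::group_by(grouping, direction) |>
    dplyr::summarise(total = sum(total), matched = sum(matched),
                     .groups = "drop")
  alls <- rep |>
    dplyr::filter(domain == "all") |>
    dplyr::select(grouping, direction, total, matched) |>
    dplyr::arrange(grouping, direction)
  expect_equal(as.data.frame(dplyr::arrange(sums, grouping, direction)),
               as.data.frame(alls), ignore_attr = TRUE)
})

test_that("quantify at a grid point equals the sweep curve exactly", {
  cfg <- synth_config(seed = 104, n_patients = 30)
  r <- run_synthetic_matches(cfg, c("visit", "record"))
  grid <- threshold_grid()
  sweep <- threshold_sweep(r$matches, grid)
  for (t in c(0.35, 0.65, 0.9)) {
    gl <- glance(quantify_overlap(r$matches, t))
    sl <- sweep[abs(sweep$threshold - t) < 1e-9, ]
    merged <- dplyr::inner_join(gl, sl, by = c("grouping", "direction"),
                                suffix = c("_q", "_s"))
    expect_equal(merged$matched_q, merged$matched_s)
    expect_equal(merged$percentage_q, merged$percentage_s)
  }
})

test_that("sweep curves are non-increasing and hit their extremes", {
  cfg <- synth_config(seed = 105, n_patients = 30)
  r <- run_synthetic_matches(cfg, c("visit", "record"))
  sweep <- threshold_sweep(r$matches, threshold_grid(-1, 1.01, 0.1005))
  by_curve <- split(sweep, paste(sweep$grouping, sweep$direction))
  for (cur in by_curve) {
    cur <- cur[order(cur$threshold), ]
    expect_true(all(diff(cur$percentage) <= 1e-9))
  }
  # at t = -1 everything with any counterpart is matched
  at_bottom <- sweep[sweep$threshold == -1, ]
  with_counterpart <- r$matches |>
    dplyr::filter(!is.na(similarity)) |>
    dplyr::group_by(grouping, direction) |>
    dplyr::summarise(n = sum(n_occurrences), .groups = "drop")
  expect_equal(
    dplyr::arrange(at_bottom[c("grouping", "direction", "matched")],
                   grouping, direction)$matched,
    dplyr::arrange(with_counterpart, grouping, direction)$n
  )
  # just above 1 nothing matches
  expect_true(all(sweep$matched[sweep$threshold > 1] == 0L))
})

test_that("an empty match table yields a zero report with a warning", {
  expect_warning(rep <- quantify_overlap(empty <- tibble::tibble(
    group_id = character(0), grouping = character(0),
    patient_id = character(0), direction = character(0),
    concept_id = character(0), domain = character(0),
    n_occurrences = integer(0), best_match_concept_id = character(0),
    similarity = numeric(0)
  ), 0.65), "zero totals")
  expect_equal(nrow(rep), 0L)
})

test_that("subpopulation selection keeps exactly the defining visits", {
  events <- make_events(
    list(event_id = "E1", patient_id = "P1", visit_id = "V1", concept_id = "C1"),
    list(event_id = "E2", patient_id = "P1", visit_id = "V2", concept_id = "C2"),
    list(event_id = "E3", patient_id = "P2", visit_id = "V3", concept_id = "C1"),
    list(event_id = "E4", patient_id = "P2", visit_id = "V4", concept_id = "C4")
  )
  notes <- make_notes(
    list(note_id = "N1", patient_id = "P1", visit_id = "V1", text = "a"),
    list(note_id = "N2", patient_id = "P2", visit_id = "V3", text = "b"),
    list(note_id = "N3", patient_id = "P2", visit_id = "V4", text = "c")
  )
  vocab <- toy_vocabulary()
  sub <- filter_subpopulation(events, notes, "C1", vocab, name = "hypertension")
  expect_equal(sub$visit_ids, c("V1", "V3"))
  expect_equal(sort(unique(sub$events$visit_id)), c("V1", "V3"))
  expect_equal(sort(unique(sub$notes$visit_id)), c("V1", "V3"))

  expect_error(filter_subpopulation(events, notes, "C999", vocab),
               class = "ehroverlap_validation_error")
  expect_error(filter_subpopulation(events, notes, character(0)),
               class = "ehroverlap_validation_error")

  everything <- filter_subpopulation(events, notes, vocab$concept_id, vocab)
  expect_equal(sort(everything$visit_ids), c("V1", "V2", "V3", "V4"))

  expect_warning(none <- filter_subpopulation(events, notes, "C3", vocab),
                 "no visits")
  expect_equal(nrow(none$events), 0L)
})

test_that("a subpopulation's totals never exceed the full population's", {
  cfg <- synth_config(seed = 106, n_patients = 40)
  r <- run_synthetic_matches(cfg)
  full <- glance(quantify_overlap(r$matches, 0.65))
  defining <- r$vocabulary$concept_id[1:10]
  sub <- filter_subpopulation(r$population$events, r$population$notes,
                              defining, r$vocabulary)
  um <- filter_unmodified(apply_context_rules(
    extract_concepts(sub$notes, build_lexicon(r$vocabulary)), sub$notes))
  idx <- embed_concepts(r$vocabulary,
                        synthetic_encoder(r$vocabulary, 64, cfg$cluster_noise,
                                          cfg$seed))
  m <- run_matching(sub$events, um, sub$notes, idx, "visit", r$vocabulary)
  subg <- glance(quantify_overlap(m, 0.65, population = "sub"))
  both <- dplyr::inner_join(full, subg, by = "direction",
                            suffix = c("_full", "_sub"))
  expect_true(all(both$total_sub <= both$total_full))
})
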