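# A small two-visit fixture: P1 has visits V1, V2, one lab event without
# a visit link, and one note per visit.
fixture_tables <- function() {
  events <- make_events(
    list(event_id = "E1", patient_id = "P1", visit_id = "V1", concept_id = "C1"),
    list(event_id = "E2", patient_id = "P1", visit_id = "V2", concept_id = "C2"),
    list(event_id = "E3", patient_id = "P1", concept_id = "C3",
         value = 140, unit = "mmHg")
  )
  notes <- make_notes(
    list(note_id = "N1", patient_id = "P1", visit_id = "V1", text = "x"),
    list(note_id = "N2", patient_id = "P1", visit_id = "V2", text = "y")
  )
  mentions <- tibble::tibble(
    note_id = c("N1", "N2"), start = 0L, end = 1L,
    concept_id = c("C4", "C1"), domain = "condition",
    negated = FALSE, temporality = "present", experiencer = "patient"
  )
  list(events = events, notes = notes, mentions = mentions)
}

test_that("visit grouping excludes material recorded outside visits", {
  f <- fixture_tables()
  g <- group_concepts(f$events, f$mentions, f$notes, "visit")
  expect_equal(sort(unique(g$group_id)), c("V1", "V2"))
  expect_false("C3" %in% g$concept_id) # the unlinked lab is in neither group

  # a visit with a note but no coded events keeps an extracted-only group
  no_ev <- g[g$group_id == "V1", ]
  expect_true(all(c("structured", "extracted") %in% g$side))

  # no visit links at all -> no visit groups
  loose_ev <- dplyr::mutate(f$events, visit_id = NA_character_)
  loose_nt <- dplyr::mutate(f$notes, visit_id = NA_character_)
  expect_equal(nrow(group_concepts(loose_ev, f$mentions, loose_nt, "visit")), 0L)
})

test_that("record grouping is a superset containing outside-visit material", {
  f <- fixture_tables()
  rec <- group_concepts(f$events, f$mentions, f$notes, "record")
  expect_equal(unique(rec$group_id), "P1")
  expect_true("C3" %in% rec$concept_id)

  vis <- group_concepts(f$events, f$mentions, f$notes, "visit")
  expect_gte(sum(rec$n_occurrences), sum(vis$n_occurrences))
})

test_that("a 2-by-5 group needs exactly 10 pairwise comparisons", {
  withr::with_seed(41, {
    mat <- matrix(rnorm(7 * 16), nrow = 7)
    rownames(mat) <- sprintf("C%d", 1:7)
  })
  idx <- make_index(mat)
  groups <- tibble::tibble(
    group_id = "V1", grouping = "visit", patient_id = "P1",
    side = c(rep("structured", 2), rep("extracted", 5)),
    concept_id = sprintf("C%d", 1:7),
    domain = "condition", n_occurrences = 1L
  )
  m <- best_matches(groups, idx)
  expect_equal(attr(m, "n_comparisons"), 10L)
  expect_equal(sum(m$direction == "structured_to_unstructured"), 2L)
  expect_equal(sum(m$direction == "unstructured_to_structured"), 5L)
  expect_true(all(!is.na(m$similarity)))
})

test_that("an empty counterpart side yields matchless records", {
  idx <- make_index(rbind(C1 = c(1, 0), C2 = c(0, 1)))
  groups <- tibble::tibble(
    group_id = "V1", grouping = "visit", patient_id = "P1",
    side = "structured", concept_id = c("C1", "C2"),
    domain = "condition", n_occurrences = c(2L, 1L)
  )
  m <- best_matches(groups, idx)
  expect_equal(nrow(m), 2L)
  expect_true(all(is.na(m$best_match_concept_id)))
  expect_true(all(is.na(m$similarity)))
  expect_equal(attr(m, "n_comparisons"), 0L)
})

test_that("identical concepts on both sides match at similarity 1", {
  idx <- make_index(rbind(A = c(1, 1), B = c(1, -2)))
  groups <- tibble::tibble(
    group_id = "V1", grouping = "visit", patient_id = "P1",
    side = c("structured", "extracted"), concept_id = c("A", "A"),
    domain = "condition", n_occurrences = 1L
  )
  m <- best_matches(groups, idx)
  expect_equal(m$similarity, c(1, 1))
  expect_equal(m$best_match_concept_id, c("A", "A"))
})

test_that("ties in the maximum take the lexicographically smallest id", {
  # B and C are identical vectors, both orthogonal to nothing
  idx <- make_index(rbind(A = c(1, 0), C = c(0.6, 0.8), B = c(0.6, 0.8)))
  groups <- tibble::tibble(
    group_id = "G", grouping = "visit", patient_id = "P1",
    side = c("structured", "extracted", "extracted"),
    concept_id = c("A", "B", "C"), domain = "condition", n_occurrences = 1L
  )
  m <- best_matches(groups, idx)
  s2u <- m[m$direction == "structured_to_unstructured", ]
  expect_equal(s2u$best_match_concept_id, "B")
})

test_that("concepts missing from the index count but never match", {
  idx <- make_index(rbind(A = c(1, 0), B = c(0, 1)))
  groups <- tibble::tibble(
    group_id = "G", grouping = "visit", patient_id = "P1",
    side = c("structured", "structured", "extracted"),
    concept_id = c("A", "ZZ", "B"), domain = "condition",
    n_occurrences = c(1L, 3L, 1L)
  )
  m <- best_matches(groups, idx)
  zz <- m[m$concept_id == "ZZ", ]
  expect_equal(nrow(zz), 1L)
  expect_true(is.na(zz$similarity))
  expect_equal(zz$n_occurrences, 3L)
  expect_equal(attr(m, "n_comparisons"), 1L)
})

test_that("best matches equal a brute-force scan of the Cartesian product", {
  withr::with_seed(53, {
    mat <- matrix(rnorm(12 * 8), nrow = 12)
    rownames(mat) <- sprintf("C%02d", 1:12)
    idx <- make_index(mat)
    for (rep in 1:10) {
      s_ids <- sample(rownames(mat), sample(1:5, 1))
      e_ids <- sample(rownames(mat), sample(1:5, 1))
      groups <- tibble::tibble(
        group_id = "G", grouping = "visit", patient_id = "P",
        side = c(rep("structured", length(s_ids)), rep("extracted", length(e_ids))),
        concept_id = c(s_ids, e_ids), domain = "condition", n_occurrences = 1L
      )
      m <- best_matches(groups, idx)
      oracle <- oracle_best_match(s_ids, e_ids, mat)
      for (s in s_ids) {
        row <- m[m$direction == "structured_to_unstructured" & m$concept_id == s, ]
        expect_equal(row$similarity, oracle[[s]]$sim, tolerance = 1e-9)
        expect_equal(row$best_match_concept_id, oracle[[s]]$id)
      }
    }
  })
})

test_that("record-level best similarity dominates visit-level (max over superset)", {
  cfg <- synth_config(seed = 37, n_patients = 25, p_outside_visit = 0.3)
  v <- generate_vocabulary(cfg)
  pop <- generate_population(cfg, v)
  lex <- build_lexicon(v)
  um <- filter_unmodified(
    apply_context_rules(extract_concepts(pop$notes, lex), pop$notes))
  idx <- embed_concepts(v, synthetic_encoder(v, 64, 0.1, 37))
  vis <- run_matching(pop$events, um, pop$notes, idx, "visit", v)
  rec <- run_matching(pop$events, um, pop$notes, idx, "record", v)

  joined <- dplyr::inner_join(
    dplyr::filter(vis, !is.na(similarity)),
    dplyr::filter(rec, !is.na(similarity)),
    by = c("patient_id", "direction", "concept_id"),
    suffix = c("_visit", "_record"), relationship = "many-to-many"
  )
  expect_gt(nrow(joined), 0L)
  expect_true(all(joined$similarity_record >= joined$similarity_visit - 1e-9))
})

test_that("enlarging the counterpart set never lowers a best similarity", {
  withr::with_seed(61, {
    mat <- matrix(rnorm(10 * 8), nrow = 10)
    rownames(mat) <- sprintf("C%02d", 1:10)
  })
  idx <- make_index(mat)
  base_groups <- function(e_ids) tibble::tibble(
    group_id = "G", grouping = "visit", patient_id = "P",
    side = c("structured", rep("extracted", length(e_ids))),
    concept_id = c("C01", e_ids), domain = "condition", n_occurrences = 1L
  )
  small <- best_matches(base_groups(c("C02", "C03")), idx)
  large <- best_matches(base_groups(c("C02", "C03", "C04", "C05", "C06")), idx)
  s_small <- small$similarity[small$direction == "structured_to_unstructured"]
  s_large <- large$similarity[large$direction == "structured_to_unstructured"]
  expect_gte(s_large, s_small)
})

test_that("match tables round-trip through CSV", {
  f <- fixture_tables()
  idx <- make_index(rbind(C1 = c(1, 0), C2 = c(0, 1), C3 = c(1, 1),
                          C4 = c(-1, 0)))
  m <- run_matching(f$events, f$mentions, f$notes, idx, "record")
  path <- withr::local_tempfile(fileext = ".csv")
  write_matches(m, path)
  back <- read_matches(path)
  expect_equal(as.data.frame(back), as.data.frame(m), tolerance = 1e-12,
               ignore_attr = TRUE)
})
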