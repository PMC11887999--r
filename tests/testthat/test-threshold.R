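test_that("the default grid has 13 sampling bins at 0.05 spacing", {
  grid <- threshold_grid()
  expect_equal(length(grid$bins), 13L)
  expect_equal(grid$points[1], 0.35)
  expect_equal(grid$points[length(grid$points)], 1.0)
  expect_error(threshold_grid(0.8, 0.5), class = "ehroverlap_config_error")
})

test_that("weighted Gini matches hand-computed splits", {
  sims <- c(0.9, 0.8, 0.4, 0.3)
  labs <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(weighted_gini(sims, labs, 0.6), 0)   # perfect split
  expect_equal(weighted_gini(sims, labs, 0.2), 0.5) # one impure group

  # mixed case: both sides half similar at t = 0.65
  expect_equal(
    weighted_gini(c(0.9, 0.7, 0.6, 0.4), c(TRUE, FALSE, TRUE, FALSE), 0.65),
    0.5
  )

  # labels as strings are accepted
  expect_equal(weighted_gini(sims, c("similar", "similar", "nonsimilar",
                                     "nonsimilar"), 0.6), 0)
  expect_error(weighted_gini(sims, c(TRUE, NA, FALSE, FALSE), 0.6),
               class = "ehroverlap_validation_error")
  expect_error(weighted_gini(numeric(0), logical(0), 0.5),
               class = "ehroverlap_validation_error")
})

test_that("impurity is bounded, label-inversion symmetric, and oracle-exact", {
  withr::with_seed(71, {
    for (rep in 1:50) {
      n <- sample(1:50, 1)
      sims <- runif(n)
      labs <- runif(n) < 0.5
      t <- runif(1)
      g <- weighted_gini(sims, labs, t)
      expect_gte(g, 0)
      expect_lte(g, 0.5)
      expect_equal(g, weighted_gini(sims, !labs, t))
      expect_equal(g, oracle_weighted_gini(sims, labs, t), tolerance = 1e-12)
    }
  })
})

test_that("annotations separable at 0.6 put every argmin one step from 0.6", {
  ann <- simulate_annotations(seed = 3, boundary = 0.6, p_flip = 0)
  tr <- find_threshold(ann)
  per_sample <- split(tr$minimizers$threshold, tr$minimizers$sample_id)
  expect_equal(length(per_sample), 4L)
  for (m in per_sample) {
    expect_true(all(abs(m - 0.6) <= 0.05 + 1e-9))
  }
  expect_equal(min(tr$minimizers$impurity), 0)
  expect_equal(tr$threshold, 0.6)
})

test_that("a single-class sample warns and minimises trivially", {
  ann <- tibble::tibble(sample_id = "S2U-visit",
                        similarity = c(0.4, 0.6, 0.9),
                        label = "similar")
  expect_warning(tr <- find_threshold(ann), "single label class")
  expect_equal(min(tr$minimizers$impurity), 0)
  expect_true(0.35 %in% tr$minimizers$threshold)
})

test_that("the conservative rule picks the largest minimiser across samples", {
  ann <- dplyr::bind_rows(
    tibble::tibble(sample_id = "A", similarity = c(0.9, 0.5),
                   label = c("similar", "nonsimilar")),
    tibble::tibble(sample_id = "B", similarity = c(0.95, 0.8),
                   label = c("similar", "nonsimilar"))
  )
  tr <- find_threshold(ann)
  # sample A separates anywhere in (0.5, 0.9], sample B in (0.8, 0.95]
  expect_equal(tr$threshold, max(tr$minimizers$threshold))
  expect_gte(tr$threshold, 0.85)
})

test_that("tidy and glance expose curves and the chosen threshold", {
  tr <- find_threshold(simulate_annotations(seed = 5))
  td <- tidy(tr)
  expect_true(all(c("sample_id", "threshold", "impurity", "is_minimizer") %in%
                    names(td)))
  expect_equal(nrow(td), 4L * length(threshold_grid()$points))
  gl <- glance(tr)
  expect_equal(gl$n_samples, 4L)
  expect_gte(gl$band_lo, threshold_grid()$lo)
})

test_that("bin-stratified sampling respects the per-domain cap and the seed", {
  cfg <- synth_config(seed = 43, n_patients = 60)
  v <- generate_vocabulary(cfg)
  pop <- generate_population(cfg, v)
  um <- filter_unmodified(apply_context_rules(
    extract_concepts(pop$notes, build_lexicon(v)), pop$notes))
  idx <- embed_concepts(v, synthetic_encoder(v, 64, 0.1, 43))
  matches <- dplyr::bind_rows(
    run_matching(pop$events, um, pop$notes, idx, "visit", v),
    run_matching(pop$events, um, pop$notes, idx, "record", v)
  )
  s <- sample_annotation_pairs(matches, v, per_domain = 5L, seed = 7)
  expect_lte(nrow(s), 4L * 13L * 5L * 5L)
  counts <- dplyr::count(s, sample_id, bin_lo, domain)
  expect_lte(max(counts$n), 5L)
  expect_true(all(s$similarity >= s$bin_lo - 1e-9))
  expect_true(all(s$similarity <= s$bin_lo + 0.05 + 1e-9 | s$bin_lo == 0.95))
  # pairs are unique within a sample
  expect_equal(anyDuplicated(s[c("sample_id", "source_concept_id",
                                 "match_concept_id")]), 0L)
  # reproducible under the same seed, different under another
  s2 <- sample_annotation_pairs(matches, v, per_domain = 5L, seed = 7)
  expect_identical(s, s2)

  # a bin with fewer pairs than the cap takes what exists, silently
  tiny <- matches[!is.na(matches$similarity), ][1:3, ]
  tiny$similarity <- c(0.97, 0.98, 0.99)
  s3 <- sample_annotation_pairs(tiny, v, per_domain = 5L, seed = 7)
  expect_lte(nrow(s3), 3L)
})

test_that("annotation files round-trip and reject edited pair keys", {
  ann <- simulate_annotations(seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  blank <- dplyr::mutate(ann, label = NA_character_)
  write_annotations(blank, path)
  back <- read_annotations(path, exported = blank)
  expect_equal(nrow(back), nrow(ann))
  expect_true(all(is.na(back$label)))

  tampered <- blank
  tampered$match_concept_id[1] <- "SOMETHING-ELSE"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(tampered, path2)
  expect_error(read_annotations(path2, exported = blank),
               class = "ehroverlap_integrity_error")

  # column-mapping loads files with foreign headers
  foreign <- ann
  names(foreign)[names(foreign) == "label"] <- "annotation"
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(foreign, path3)
  mapped <- read_annotations(path3, mapping = list(label = "annotation"))
  expect_equal(mapped$label, ann$label)
})

test_that("simulated annotations fill the declared sampling frame", {
  ann <- simulate_annotations(seed = 1)
  expect_equal(nrow(ann), 4L * 13L * 5L * 5L)
  expect_equal(sort(unique(ann$sample_id)),
               c("S2U-record", "S2U-visit", "U2S-record", "U2S-visit"))
  expect_true(all(ann$similarity >= 0.35 & ann$similarity <= 1))
  # labels follow the boundary except possibly within one grid step of it
  off_band <- abs(ann$similarity - 0.6) >= 0.05
  expect_equal(ann$label[off_band] == "similar",
               ann$similarity[off_band] >= 0.6)
})
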