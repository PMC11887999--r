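#' Similarity threshold grid
#'
#' Evenly spaced candidate thresholds from `lo` to `hi`, the grid used
#' both for bin-stratified annotation sampling and for impurity
#' minimisation. The defaults (0.35 to 1.00 in steps of 0.05, 13 bins)
#' span the range where concept pairs stop being obviously unrelated.
#'
#' @param lo,hi Grid bounds, `lo < hi`.
#' @param step Grid spacing, > 0.
#' @return A `threshold_grid`: list with `lo`, `hi`, `step`, `points`
#'   (the grid values) and `bins` (lower edges of the sampling bins).
#' @export
threshold_grid <- function(lo = 0.35, hi = 1.0, step = 0.05) {
  if (!(lo < hi) || step <= 0) {
    abort("need lo < hi and step > 0", class = "ehroverlap_config_error")
  }
  points <- seq(lo, hi, by = step)
  points <- round(points, 10)
  structure(list(lo = lo, hi = hi, step = step, points = points,
                 bins = points[points < hi]),
            class = "threshold_grid")
}

#' Weighted Gini impurity of a threshold split
#'
#' Splits labelled concept pairs into A = pairs with similarity at or
#' above `threshold` (the side counted as matched) and B = the rest.
#' For a set with fraction `p` labelled similar the Gini impurity is
#' `1 - p^2 - (1 - p)^2` (an empty set contributes 0); the weighted
#' impurity averages the two sides by their share of the pairs. It is 0
#' when the threshold separates similar from nonsimilar pairs
#' perfectly and at most 0.5 for binary labels.
#'
#' @param similarity Numeric vector of pair similarities.
#' @param label Logical vector (`TRUE` = annotated similar), or a
#'   character vector of `"similar"` / `"nonsimilar"`.
#' @param threshold The candidate threshold.
#' @return The weighted impurity, a number in `[0, 0.5]`.
#' @export
weighted_gini <- function(similarity, label, threshold) {
  label <- as_similar_label(label)
  if (length(similarity) == 0L) {
    abort("weighted_gini needs at least one labelled pair",
          class = "ehroverlap_validation_error")
  }
  if (anyNA(label) || anyNA(similarity)) {
    abort("all pairs must be labelled with a known similarity",
          class = "ehroverlap_validation_error")
  }
  in_a <- similarity >= threshold
  n <- length(similarity)
  gini_part <- function(lab) {
    m <- length(lab)
    if (m == 0L) return(0)
    p <- mean(lab)
    (m / n) * (1 - p^2 - (1 - p)^2)
  }
  gini_part(label[in_a]) + gini_part(label[!in_a])
}

as_similar_label <- function(label) {
  if (is.character(label)) {
    out <- rep(NA, length(label))
    out[label %in% c("similar", "true", "TRUE", "1")] <- TRUE
    out[label %in% c("nonsimilar", "false", "FALSE", "0")] <- FALSE
    as.logical(out)
  } else {
    as.logical(label)
  }
}

#' Impurity curve over a threshold grid
#'
#' @param similarity,label As in [weighted_gini()].
#' @param grid A `threshold_grid`.
#' @return A tibble with `threshold` and `impurity` per grid point.
#' @export
gini_curve <- function(similarity, label, grid = threshold_grid()) {
  tibble(
    threshold = grid$points,
    impurity = map_dbl(grid$points, ~ weighted_gini(similarity, label, .x))
  )
}

#' Determine the similarity threshold from annotated samples
#'
#' Evaluates the weighted Gini impurity on every grid point for each
#' annotation sample (the four direction-by-grouping samples), collects
#' each sample's set of impurity-minimising thresholds, and picks the
#' conservative global threshold: the largest minimiser across all
#' samples. A sample containing only one label class is degenerate (its
#' curve is minimised trivially at an extreme) and triggers a warning.
#'
#' @param annotations A labelled annotation tibble with columns
#'   `sample_id`, `similarity`, `label` (see
#'   [sample_annotation_pairs()] for the export schema).
#' @param grid A `threshold_grid`.
#' @return A `threshold_result`: list with `curves` (tibble of
#'   `sample_id`, `threshold`, `impurity`), `minimizers` (tibble of
#'   `sample_id`, `threshold`, per-sample argmin sets), `threshold` (the
#'   conservative choice), and `grid`.
#' @export
find_threshold <- function(annotations, grid = threshold_grid()) {
  stopifnot(all(c("sample_id", "similarity", "label") %in% names(annotations)))
  annotations$label <- as_similar_label(annotations$label)
  if (anyNA(annotations$label)) {
    abort("all annotation rows must be labelled before threshold determination",
          class = "ehroverlap_validation_error")
  }
  one_class <- annotations |>
    group_by(.data$sample_id) |>
    summarise(single = n_distinct(.data$label) == 1L, .groups = "drop")
  if (any(one_class$single)) {
    warn(sprintf(
      "sample(s) with a single label class (impurity minimised trivially): %s",
      paste(one_class$sample_id[one_class$single], collapse = ", ")
    ))
  }

  curves <- annotations |>
    group_by(.data$sample_id) |>
    reframe(gini_curve(.data$similarity, .data$label, grid))
  minimizers <- curves |>
    group_by(.data$sample_id) |>
    filter(.data$impurity <= min(.data$impurity) + 1e-12) |>
    ungroup() |>
    select("sample_id", "threshold", "impurity")

  structure(list(
    curves = curves,
    minimizers = minimizers,
    threshold = max(minimizers$threshold),
    grid = grid
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  band <- range(x$minimizers$threshold)
  cat(sprintf(
    "<threshold_result: %d sample(s); per-sample minimizers in [%.2f, %.2f]; conservative threshold %.2f>\n",
    n_distinct(x$curves$sample_id), band[1], band[2], x$threshold))
  invisible(x)
}

#' @rdname find_threshold
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  x$curves |>
    mutate(is_minimizer = paste(.data$sample_id, .data$threshold) %in%
             paste(x$minimizers$sample_id, x$minimizers$threshold))
}

#' @rdname find_threshold
#' @method glance threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    n_samples = n_distinct(x$curves$sample_id),
    band_lo = min(x$minimizers$threshold),
    band_hi = max(x$minimizers$threshold),
    min_impurity = min(x$minimizers$impurity)
  )
}

#' Sample concept pairs for manual annotation
#'
#' Draws the four annotation samples (direction x grouping) from a
#' match table: within each sample, each similarity bin of the grid
#' (`[b, b + step)`; the last bin closed at the top) and each concept
#' domain contributes up to `per_domain` distinct concept pairs, drawn
#' uniformly without replacement. Underfilled bins take what exists.
#' The `label` column is exported empty, to be filled with `similar` /
#' `nonsimilar` by annotators and re-imported with
#' [read_annotations()].
#'
#' @param matches A match tibble covering one or both groupings.
#' @param vocabulary Optional `ehr_vocabulary` used to attach preferred
#'   descriptions to both sides of each pair.
#' @param grid A `threshold_grid`.
#' @param per_domain Pairs to draw per (sample, bin, domain), default 5.
#' @param seed Integer seed making the draw reproducible.
#' @return An annotation tibble: `sample_id`, `direction`, `grouping`,
#'   `bin_lo`, `domain`, `source_concept_id`, `source_description`,
#'   `match_concept_id`, `match_description`, `similarity`, `label`.
#' @export
sample_annotation_pairs <- function(matches, vocabulary = NULL,
                                    grid = threshold_grid(), per_domain = 5L,
                                    seed = 1L) {
  if (nrow(matches) == 0L) {
    abort("cannot sample annotation pairs from an empty match table",
          class = "ehroverlap_validation_error")
  }
  pairs <- matches |>
    filter(!is.na(.data$similarity), .data$similarity >= grid$lo) |>
    arrange(desc(.data$similarity)) |>
    distinct(.data$direction, .data$grouping, .data$concept_id,
             .data$best_match_concept_id, .keep_all = TRUE) |>
    mutate(
      bin_lo = pmin(grid$lo + floor((.data$similarity - grid$lo) / grid$step) *
                      grid$step, max(grid$bins)),
      sample_id = paste0(ifelse(.data$direction == MATCH_DIRECTIONS[1L],
                                "S2U", "U2S"), "-", .data$grouping)
    )

  sampled <- withr::with_seed(derive_seed(seed, "annotation-sampling"), {
    pairs |>
      group_by(.data$sample_id, .data$bin_lo, .data$domain) |>
      slice_sample(n = per_domain) |>
      ungroup()
  })

  out <- sampled |>
    transmute(
      .data$sample_id, .data$direction, .data$grouping,
      bin_lo = round(.data$bin_lo, 10), .data$domain,
      source_concept_id = .data$concept_id,
      source_description = describe(.data$concept_id, vocabulary),
      match_concept_id = .data$best_match_concept_id,
      match_description = describe(.data$best_match_concept_id, vocabulary),
      .data$similarity,
      label = NA_character_
    ) |>
    arrange(.data$sample_id, .data$bin_lo, .data$domain,
            .data$source_concept_id, .data$match_concept_id)
  out
}

describe <- function(ids, vocabulary) {
  if (is.null(vocabulary)) return(NA_character_)
  unname(setNames(vocabulary$preferred, vocabulary$concept_id)[ids])
}

#' Export and re-import annotation files
#'
#' `write_annotations()` writes the sampled pairs (normally with an
#' empty `label` column) for annotators; `read_annotations()` loads a
#' filled file back. When the original export is supplied, the imported
#' pair keys must match it exactly — a content check that protects
#' against silent row edits or reordering between export and import. A
#' column-mapping list allows files with different header names
#' (e.g. an externally released annotation table) to be loaded.
#'
#' @param annotations An annotation tibble.
#' @param path File path.
#' @param exported The original exported tibble to verify keys against
#'   (optional).
#' @param mapping Optional named list mapping this package's column
#'   names to the file's column names.
#' @return `path` (write) or the annotation tibble (read).
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations, path, na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, exported = NULL, mapping = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    for (ours in names(mapping)) {
      theirs <- mapping[[ours]]
      if (!theirs %in% names(df)) {
        abort(sprintf("mapped column '%s' not found in %s", theirs, basename(path)),
              class = "ehroverlap_schema_error")
      }
      df[[ours]] <- df[[theirs]]
    }
  }
  required <- c("sample_id", "source_concept_id", "match_concept_id",
                "similarity", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing required column(s): %s",
                  basename(path), paste(missing, collapse = ", ")),
          class = "ehroverlap_schema_error")
  }
  df$similarity <- as.numeric(df$similarity)
  df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  if (!is.null(exported)) {
    key <- function(d) rlang::hash(
      d[order(d$sample_id, d$source_concept_id, d$match_concept_id),
        c("sample_id", "source_concept_id", "match_concept_id")]
    )
    if (key(df) != key(exported)) {
      abort("imported annotation pairs do not match the exported sample",
            class = "ehroverlap_integrity_error")
    }
  }
  df
}

#' Simulate an annotated concept-pair file (synthetic stand-in)
#'
#' Generates a synthetic annotation table with the structure of a real
#' annotated concept-match release: four samples (direction x
#' grouping), pairs drawn per similarity bin and domain, and binary
#' similar/nonsimilar labels. Labels follow a latent decision boundary
#' (`boundary`, default 0.60): pairs above it are similar, below it
#' nonsimilar, except that labels within one grid step of the boundary
#' are flipped with probability `p_flip` — annotators disagree most
#' where pairs are genuinely borderline. Files written from this
#' generator are synthetic and should be named accordingly; they stand
#' in for manual annotation wherever none is available.
#'
#' @param seed Integer seed.
#' @param boundary Latent similar/nonsimilar boundary on the similarity
#'   scale.
#' @param grid A `threshold_grid` (bins to fill).
#' @param per_domain Pairs per (sample, bin, domain).
#' @param domains Domains represented in the samples.
#' @param p_flip Probability of flipping a label within one grid step
#'   of the boundary.
#' @return A labelled annotation tibble (same schema as
#'   [sample_annotation_pairs()]).
#' @export
simulate_annotations <- function(seed = 1L, boundary = 0.60,
                                 grid = threshold_grid(), per_domain = 5L,
                                 domains = CODED_DOMAINS, p_flip = 0.05) {
  samples <- c("S2U-record", "U2S-record", "S2U-visit", "U2S-visit")
  frame <- tidyr::expand_grid(
    sample_id = samples,
    bin_lo = grid$bins,
    domain = domains,
    k = seq_len(per_domain)
  )
  withr::with_seed(derive_seed(seed, "synthetic-annotations"), {
    bin_width <- grid$step
    sim <- frame$bin_lo + runif(nrow(frame)) * bin_width
    sim <- pmin(sim, 1)
    lab <- sim >= boundary
    near <- abs(sim - boundary) < grid$step
    flip <- near & runif(nrow(frame)) < p_flip
    lab[flip] <- !lab[flip]
    frame |>
      mutate(
        direction = ifelse(startsWith(.data$sample_id, "S2U"),
                           MATCH_DIRECTIONS[1L], MATCH_DIRECTIONS[2L]),
        grouping = ifelse(endsWith(.data$sample_id, "record"), "record", "visit"),
        source_concept_id = sprintf("SRC%05d", seq_len(nrow(frame))),
        source_description = NA_character_,
        match_concept_id = sprintf("MTC%05d", seq_len(nrow(frame))),
        match_description = NA_character_,
        similarity = sim,
        label = ifelse(lab, "similar", "nonsimilar")
      ) |>
      select("sample_id", "direction", "grouping", "bin_lo", "domain",
             "source_concept_id", "source_description", "match_concept_id",
             "match_description", "similarity", "label")
  })
}
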