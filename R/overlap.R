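#' Quantify directional information overlap at a threshold
#'
#' Applies the calibrated similarity threshold to a match table and
#' counts, per direction and concept domain, how many concept
#' occurrences have a counterpart at or above the threshold. The
#' counting unit is the occurrence (event instance / mention instance),
#' carried by `n_occurrences`; matchless concepts — no counterpart in
#' the group, or no usable embedding — count toward totals only, since
#' they are genuinely uncomplemented information. An `"all"` domain row
#' sums the domain rows exactly.
#'
#' @param matches A match tibble from [run_matching()] (one or more
#'   groupings concatenated).
#' @param threshold The similarity threshold; occurrences with
#'   `similarity >= threshold` count as matched.
#' @param population Label for the population the matches came from.
#' @param distinct_concepts If `TRUE`, count distinct concepts per
#'   group instead of occurrences (sensitivity analysis).
#' @return An `overlap_report` tibble: `population`, `grouping`,
#'   `direction`, `domain` (including `"all"`), `total`, `matched`,
#'   `percentage` (1 decimal), with the threshold stored as an
#'   attribute.
#' @export
quantify_overlap <- function(matches, threshold, population = "all",
                             distinct_concepts = FALSE) {
  if (nrow(matches) == 0L) {
    warn("empty match table: overlap report has zero totals")
    out <- tibble(population = character(0), grouping = character(0),
                  direction = character(0), domain = character(0),
                  total = integer(0), matched = integer(0),
                  percentage = numeric(0))
    return(new_overlap_report(out, threshold))
  }
  weight <- if (distinct_concepts) rep(1L, nrow(matches)) else matches$n_occurrences
  per_domain <- matches |>
    mutate(w = weight,
           hit = !is.na(.data$similarity) & .data$similarity >= threshold) |>
    group_by(.data$grouping, .data$direction, .data$domain) |>
    summarise(total = sum(.data$w), matched = sum(.data$w[.data$hit]),
              .groups = "drop")
  all_row <- per_domain |>
    group_by(.data$grouping, .data$direction) |>
    summarise(domain = "all", total = sum(.data$total),
              matched = sum(.data$matched), .groups = "drop")
  out <- bind_rows(all_row, per_domain) |>
    mutate(population = population, .before = 1L) |>
    mutate(percentage = round(100 * .data$matched / pmax(.data$total, 1L), 1)) |>
    arrange(.data$grouping, .data$direction, .data$domain != "all", .data$domain)
  new_overlap_report(out, threshold)
}

new_overlap_report <- function(x, threshold) {
  attr(x, "threshold") <- threshold
  class(x) <- c("overlap_report", class(x))
  x
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("# Overlap report at similarity threshold %.2f\n",
              attr(x, "threshold")))
  NextMethod()
}

#' @rdname quantify_overlap
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  x |>
    as_tibble() |>
    filter(.data$domain == "all") |>
    select("population", "grouping", "direction", "total", "matched",
           "percentage") |>
    mutate(threshold = attr(x, "threshold"))
}

#' Percentage matched as a function of the threshold
#'
#' Recomputes the matched percentage at every grid threshold, per
#' direction and grouping. Because raising the threshold can only
#' unmatch occurrences, each curve is non-increasing in the threshold;
#' evaluating [quantify_overlap()] at a grid point agrees with this
#' curve exactly.
#'
#' @param matches A match tibble.
#' @param grid A `threshold_grid`.
#' @return A tibble: `grouping`, `direction`, `threshold`, `total`,
#'   `matched`, `percentage`.
#' @export
threshold_sweep <- function(matches, grid = threshold_grid()) {
  list_rbind(map(grid$points, function(t) {
    quantify_overlap(matches, t) |>
      as_tibble() |>
      filter(.data$domain == "all") |>
      transmute(.data$grouping, .data$direction, threshold = t,
                .data$total, .data$matched, .data$percentage)
  }))
}

#' Restrict data to a subpopulation of visits
#'
#' Selects the visits carrying at least one structured event whose
#' concept belongs to the defining set (e.g. all type 2 diabetes codes
#' for a chronic-disorder subpopulation) and restricts events and notes
#' to those visits. Downstream matching and quantification on the
#' result yields the subpopulation's overlap; the scope is visit-level
#' by construction.
#'
#' @param events Structured events tibble.
#' @param notes Notes tibble.
#' @param concept_ids Non-empty defining concept set.
#' @param vocabulary Optional `ehr_vocabulary`; when supplied, defining
#'   ids must resolve in it.
#' @param name Subpopulation label, carried through for reporting.
#' @return A list with the restricted `events` and `notes`, the `name`,
#'   and the selected `visit_ids`.
#' @export
filter_subpopulation <- function(events, notes, concept_ids, vocabulary = NULL,
                                 name = "subpopulation") {
  if (length(concept_ids) == 0L) {
    abort("a subpopulation needs a non-empty defining concept set",
          class = "ehroverlap_validation_error")
  }
  if (!is.null(vocabulary)) {
    unknown <- setdiff(concept_ids, vocabulary$concept_id)
    if (length(unknown) > 0L) {
      abort(sprintf("defining concept id(s) not in vocabulary: %s",
                    paste(unknown, collapse = ", ")),
            class = "ehroverlap_validation_error")
    }
  }
  visit_ids <- events |>
    filter(!is.na(.data$visit_id), .data$concept_id %in% concept_ids) |>
    pull(.data$visit_id) |>
    unique() |>
    sort()
  if (length(visit_ids) == 0L) {
    warn(sprintf("subpopulation '%s' selects no visits", name))
  }
  list(
    name = name,
    visit_ids = visit_ids,
    events = filter(events, .data$visit_id %in% visit_ids),
    notes = filter(notes, .data$visit_id %in% visit_ids)
  )
}

#' Write an overlap report as CSV and JSON
#'
#' @param report An `overlap_report`.
#' @param path_csv,path_json Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_overlap_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) readr::write_csv(as_tibble(report), path_csv)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(threshold = attr(report, "threshold"), cells = as_tibble(report)),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
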