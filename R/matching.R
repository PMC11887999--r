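#' Group structured and extracted concepts for comparison
#'
#' Builds the comparison groups over which structured events and
#' extracted (unmodified) mentions are matched. With
#' `grouping = "visit"`, one group per visit id holding at least one
#' event or mention; events and notes without a visit link are excluded
#' (they are recorded outside visits). With `grouping = "record"`, one
#' group per patient holding everything, visit-linked or not. Concepts
#' are deduplicated within a group — similarity depends only on concept
#' identity — and `n_occurrences` carries the multiplicity into the
#' counting stage.
#'
#' @param events Structured events tibble.
#' @param mentions Mentions tibble (pass through [filter_unmodified()]
#'   first; this function does not re-filter).
#' @param notes Notes tibble, used to resolve each mention's note to its
#'   patient and visit.
#' @param grouping `"visit"` or `"record"`.
#' @param vocabulary Optional `ehr_vocabulary`; when given, concept
#'   domains are resolved from it (otherwise they are filled from the
#'   embedding index during matching).
#' @return A tibble with one row per (group, side, distinct concept):
#'   `group_id`, `grouping`, `patient_id`, `side` (`"structured"` /
#'   `"extracted"`), `concept_id`, `domain`, `n_occurrences`.
#' @export
group_concepts <- function(events, mentions, notes, grouping = c("visit", "record"),
                           vocabulary = NULL) {
  grouping <- match.arg(grouping)
  mention_loc <- mentions |>
    left_join(select(notes, "note_id", "patient_id", "visit_id"), by = "note_id")

  if (grouping == "visit") {
    ev <- filter(events, !is.na(.data$visit_id))
    mn <- filter(mention_loc, !is.na(.data$visit_id))
    key <- "visit_id"
  } else {
    ev <- events
    mn <- mention_loc
    key <- "patient_id"
  }

  structured <- ev |>
    mutate(group_id = .data[[key]], side = "structured") |>
    count(.data$group_id, .data$patient_id, .data$side, .data$concept_id,
          name = "n_occurrences")
  extracted <- mn |>
    mutate(group_id = .data[[key]], side = "extracted") |>
    count(.data$group_id, .data$patient_id, .data$side, .data$concept_id,
          name = "n_occurrences")

  out <- bind_rows(structured, extracted) |>
    mutate(grouping = grouping, .after = "group_id") |>
    arrange(.data$patient_id, .data$group_id, desc(.data$side), .data$concept_id)
  if (!is.null(vocabulary)) {
    out <- left_join(out,
                     select(as_tibble(vocabulary), "concept_id", "domain"),
                     by = "concept_id")
  } else {
    out$domain <- NA_character_
  }
  out
}

#' Best cross-type matches within comparison groups
#'
#' For every group, forms the Cartesian product of the distinct
#' structured and extracted concepts (m structured x n extracted gives
#' m*n similarity evaluations, computed as one matrix product) and keeps
#' for each concept only its highest-similarity counterpart on the other
#' side, in both directions. The two directions are deliberately not
#' reciprocal: several extracted concepts may all name one structured
#' concept as their best match. Ties take the lexicographically
#' smallest counterpart id. Concepts absent from the index (no usable
#' embedding) yield matchless records: they stay in the totals but can
#' never match. Concepts on a side with an empty counterpart side are
#' likewise matchless.
#'
#' @param groups Output of [group_concepts()].
#' @param index A `concept_index`.
#' @return A match tibble: `group_id`, `grouping`, `patient_id`,
#'   `direction`, `concept_id`, `domain`, `n_occurrences`,
#'   `best_match_concept_id`, `similarity`. The total number of pairwise
#'   similarity evaluations is attached as attribute `n_comparisons`.
#' @export
best_matches <- function(groups, index) {
  known <- rownames(index$unit_embeddings)
  domain_of <- setNames(index$concepts$domain, index$concepts$concept_id)
  n_comparisons <- 0L

  per_group <- groups |>
    tidyr::nest(.by = c("group_id", "grouping", "patient_id"))
  out <- vector("list", nrow(per_group))
  for (g in seq_len(nrow(per_group))) {
    dat <- per_group$data[[g]]
    s <- filter(dat, .data$side == "structured")
    e <- filter(dat, .data$side == "extracted")
    s_ok <- s$concept_id[s$concept_id %in% known]
    e_ok <- e$concept_id[e$concept_id %in% known]

    sim <- NULL
    if (length(s_ok) > 0L && length(e_ok) > 0L) {
      sim <- index_similarity(index, sort(s_ok), sort(e_ok))
      n_comparisons <- n_comparisons + length(sim)
    }
    s2u <- direction_records(s, sim, known, byrow = TRUE)
    u2s <- direction_records(e, if (is.null(sim)) NULL else t(sim), known,
                             byrow = TRUE)
    rec <- bind_rows(
      mutate(s2u, direction = MATCH_DIRECTIONS[1L]),
      mutate(u2s, direction = MATCH_DIRECTIONS[2L])
    )
    rec$group_id <- per_group$group_id[g]
    rec$grouping <- per_group$grouping[g]
    rec$patient_id <- per_group$patient_id[g]
    out[[g]] <- rec
  }
  res <- list_rbind(out)
  if (nrow(res) > 0L) {
    res$domain <- ifelse(is.na(res$domain) | res$domain == "",
                         unname(domain_of[res$concept_id]), res$domain)
    res <- res |>
      select("group_id", "grouping", "patient_id", "direction", "concept_id",
             "domain", "n_occurrences", "best_match_concept_id", "similarity") |>
      arrange(.data$patient_id, .data$group_id, .data$direction, .data$concept_id)
  } else {
    res <- empty_matches()
  }
  attr(res, "n_comparisons") <- n_comparisons
  res
}

# One direction's records for the source side `src`; `sim` has sources
# as rows (already transposed for the extracted direction), with sorted
# rownames/colnames.
direction_records <- function(src, sim, known, byrow = TRUE) {
  if (nrow(src) == 0L) {
    return(tibble(concept_id = character(0), domain = character(0),
                  n_occurrences = integer(0),
                  best_match_concept_id = character(0), similarity = numeric(0)))
  }
  best_id <- rep(NA_character_, nrow(src))
  best_sim <- rep(NA_real_, nrow(src))
  if (!is.null(sim) && ncol(sim) > 0L) {
    pos <- match(src$concept_id, rownames(sim))
    for (i in which(!is.na(pos))) {
      row <- sim[pos[i], ]
      j <- which.max(row) # columns sorted by concept_id: first max = smallest id
      best_id[i] <- colnames(sim)[j]
      best_sim[i] <- row[j]
    }
  }
  tibble(concept_id = src$concept_id, domain = src$domain,
         n_occurrences = src$n_occurrences,
         best_match_concept_id = best_id, similarity = best_sim)
}

empty_matches <- function() {
  tibble(group_id = character(0), grouping = character(0),
         patient_id = character(0), direction = character(0),
         concept_id = character(0), domain = character(0),
         n_occurrences = integer(0), best_match_concept_id = character(0),
         similarity = numeric(0))
}

#' Run the grouping and matching stage end to end
#'
#' Convenience wrapper: [group_concepts()] then [best_matches()], for
#' one grouping method. Output order is deterministic (patient, group,
#' direction, concept).
#'
#' @param events Structured events tibble.
#' @param mentions Unmodified mentions tibble.
#' @param notes Notes tibble.
#' @param index A `concept_index`.
#' @param grouping `"visit"` or `"record"`.
#' @param vocabulary Optional `ehr_vocabulary` for domain resolution.
#' @return A match tibble (see [best_matches()]).
#' @export
run_matching <- function(events, mentions, notes, index,
                         grouping = c("visit", "record"), vocabulary = NULL) {
  grouping <- match.arg(grouping)
  groups <- group_concepts(events, mentions, notes, grouping, vocabulary)
  best_matches(groups, index)
}

#' Write / read a match table
#'
#' @param matches A match tibble.
#' @param path Output file path.
#' @return `path` (write) or the match tibble (read).
#' @export
write_matches <- function(matches, path) {
  readr::write_csv(matches, path)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  read_table_checked(
    path,
    required = c("group_id", "grouping", "patient_id", "direction",
                 "concept_id", "domain", "n_occurrences",
                 "best_match_concept_id", "similarity"),
    col_types = readr::cols(
      group_id = readr::col_character(),
      grouping = readr::col_character(),
      patient_id = readr::col_character(),
      direction = readr::col_character(),
      concept_id = readr::col_character(),
      domain = readr::col_character(),
      n_occurrences = readr::col_integer(),
      best_match_concept_id = readr::col_character(),
      similarity = readr::col_double()
    )
  )
}
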