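#' Read a concept vocabulary table
#'
#' Reads a UTF-8 CSV with one row per concept description (synonym) and
#' groups the rows into one concept per row. The expected header is
#' `concept_id, vocabulary_id, domain, description, language`; the first
#' description listed for a concept is taken as its preferred term, and a
#' domain outside the closed set (condition, drug, measurement,
#' observation, procedure) is mapped to `"other"` with a warning.
#'
#' @param path Path to a `concepts.csv` file.
#' @return A tibble of class `ehr_vocabulary` with one row per concept:
#'   `concept_id`, `vocabulary_id`, `domain`, `preferred`, and a
#'   `descriptions` list-column of tibbles with `text` and `language`.
#' @export
read_vocabulary <- function(path) {
  df <- read_table_checked(
    path,
    required = c("concept_id", "vocabulary_id", "domain", "description", "language"),
    col_types = readr::cols(.default = readr::col_character())
  )
  as_vocabulary(df)
}

#' Build a vocabulary from a long description table
#'
#' @param df A data frame with columns `concept_id`, `vocabulary_id`,
#'   `domain`, `description`, `language` (one row per synonym).
#' @return An `ehr_vocabulary` tibble; see [read_vocabulary()].
#' @export
as_vocabulary <- function(df) {
  df <- as_tibble(df)
  df$description <- trimws(df$description)
  if (any(is.na(df$description) | df$description == "")) {
    abort("every concept description must be non-empty after trimming",
          class = "ehroverlap_integrity_error")
  }
  dup <- duplicated(df[c("concept_id", "description", "language")])
  if (any(dup)) {
    abort(sprintf(
      "duplicated vocabulary rows for concept id(s): %s",
      paste(unique(df$concept_id[dup]), collapse = ", ")
    ), class = "ehroverlap_integrity_error")
  }
  conflicting <- df |>
    distinct(.data$concept_id, .data$vocabulary_id, .data$domain) |>
    count(.data$concept_id) |>
    filter(.data$n > 1L)
  if (nrow(conflicting) > 0L) {
    abort(sprintf(
      "concept id(s) with conflicting vocabulary/domain assignments: %s",
      paste(conflicting$concept_id, collapse = ", ")
    ), class = "ehroverlap_integrity_error")
  }
  df$domain <- normalize_domain(df$domain)
  vocab <- df |>
    group_by(.data$concept_id, .data$vocabulary_id, .data$domain) |>
    summarise(
      preferred = .data$description[1L],
      descriptions = list(rename(pick("description", "language"),
                                 text = "description")),
      .groups = "drop"
    ) |>
    arrange(.data$concept_id)
  class(vocab) <- c("ehr_vocabulary", class(vocab))
  vocab
}

#' Flatten a vocabulary to one row per description
#'
#' @param vocabulary An `ehr_vocabulary` tibble.
#' @return A tibble with columns `concept_id`, `vocabulary_id`, `domain`,
#'   `description`, `language`.
#' @export
vocabulary_terms <- function(vocabulary) {
  vocabulary |>
    as_tibble() |>
    select("concept_id", "vocabulary_id", "domain", "descriptions") |>
    tidyr::unnest("descriptions") |>
    rename(description = "text")
}

#' Write a vocabulary back to CSV
#'
#' Inverse of [read_vocabulary()]: emits one row per description.
#'
#' @param vocabulary An `ehr_vocabulary` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocabulary, path) {
  readr::write_csv(vocabulary_terms(vocabulary), path)
  invisible(path)
}

#' Read structured clinical events
#'
#' Expected header: `event_id, patient_id, visit_id, event_date,
#' concept_id, value, unit`. `visit_id`, `value` and `unit` may be blank.
#' Dates must be ISO-8601 (`YYYY-MM-DD`); unparseable dates are a
#' row-level error reporting data line numbers. When a vocabulary is
#' supplied, rows referencing unknown concepts are dropped with a message,
#' and a value on a non-measurement/observation concept is blanked with a
#' warning (the event itself is kept).
#'
#' @param path Path to an `events.csv` file.
#' @param vocabulary Optional `ehr_vocabulary` used to validate concept
#'   references.
#' @return A tibble of structured events.
#' @export
read_events <- function(path, vocabulary = NULL) {
  df <- read_table_checked(
    path,
    required = c("event_id", "patient_id", "visit_id", "event_date",
                 "concept_id", "value", "unit"),
    col_types = readr::cols(
      event_id = readr::col_character(),
      patient_id = readr::col_character(),
      visit_id = readr::col_character(),
      event_date = readr::col_character(),
      concept_id = readr::col_character(),
      value = readr::col_double(),
      unit = readr::col_character()
    )
  )
  df$event_date <- parse_iso_dates(df$event_date, path)
  if (!is.null(vocabulary)) {
    df <- resolve_concepts(df, vocabulary, what = "event")
    bad_value <- !is.na(df$value) &
      !(df$domain %in% c("measurement", "observation"))
    if (any(bad_value)) {
      warn(sprintf(
        "%d event(s) carry a numeric value on a non-measurement/observation concept; value cleared",
        sum(bad_value)
      ))
      df$value[bad_value] <- NA_real_
    }
    df$domain <- NULL
  }
  df
}

#' Read clinical notes
#'
#' Expected header: `note_id, patient_id, visit_id, note_date, note_type,
#' text`. `visit_id` may be blank; `text` may be empty (such notes yield
#' zero extracted mentions and are flagged with a message). A note type
#' outside `consultation` / `referral_communication` is mapped to
#' `"other"` with a warning.
#'
#' @param path Path to a `notes.csv` file.
#' @return A tibble of clinical notes.
#' @export
read_notes <- function(path) {
  df <- read_table_checked(
    path,
    required = c("note_id", "patient_id", "visit_id", "note_date",
                 "note_type", "text"),
    col_types = readr::cols(.default = readr::col_character())
  )
  df$note_date <- parse_iso_dates(df$note_date, path)
  df$text[is.na(df$text)] <- ""
  unknown <- !(df$note_type %in% NOTE_TYPES)
  if (any(unknown)) {
    warn(sprintf("%d note(s) with unrecognised note_type mapped to 'other'",
                 sum(unknown)))
    df$note_type[unknown] <- "other"
  }
  n_empty <- sum(df$text == "")
  if (n_empty > 0L) {
    message(sprintf("%d note(s) have empty text (they yield no mentions)", n_empty))
  }
  df
}

#' Write events / notes tables
#'
#' @param x The tibble to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_events
#' @export
write_notes <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Assemble per-patient records
#'
#' Gathers events and notes into one row per patient id appearing in
#' either table, ordered by patient id. Useful for record-level views;
#' the matching stage works directly on the flat tables.
#'
#' @param events A structured-events tibble ([read_events()] layout).
#' @param notes A clinical-notes tibble ([read_notes()] layout).
#' @return A tibble with one row per patient: `patient_id`, list-columns
#'   `events` and `notes`, and a `visit_ids` list-column of the distinct
#'   non-missing visit ids seen for that patient.
#' @export
assemble_records <- function(events, notes) {
  ids <- sort(union(unique(events$patient_id), unique(notes$patient_id)))
  ev_list <- map(ids, ~ filter(events, .data$patient_id == .x))
  nt_list <- map(ids, ~ filter(notes, .data$patient_id == .x))
  tibble(
    patient_id = ids,
    events = ev_list,
    notes = nt_list,
    visit_ids = map2(ev_list, nt_list, function(ev, nt) {
      sort(unique(stats::na.omit(c(ev$visit_id, nt$visit_id))))
    })
  )
}

# --- internal helpers -------------------------------------------------------

read_table_checked <- function(path, required, col_types) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ehroverlap_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing required column(s): %s",
                  basename(path), paste(missing, collapse = ", ")),
          class = "ehroverlap_schema_error")
  }
  readr::read_csv(path, col_types = col_types, show_col_types = FALSE,
                  progress = FALSE)
}

parse_iso_dates <- function(x, path) {
  parsed <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(parsed))
  if (length(bad) > 0L) {
    abort(sprintf("%s: unparseable date(s) on data line(s) %s",
                  basename(path), paste(head(bad, 10L), collapse = ", ")),
          class = "ehroverlap_parse_error")
  }
  parsed
}

resolve_concepts <- function(df, vocabulary, what) {
  df <- left_join(df,
                  select(as_tibble(vocabulary), "concept_id", "domain"),
                  by = "concept_id")
  unresolved <- is.na(df$domain)
  if (any(unresolved)) {
    message(sprintf("dropped %d %s row(s) referencing unknown concept id(s)",
                    sum(unresolved), what))
    df <- df[!unresolved, , drop = FALSE]
  }
  df
}
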