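# Shared in-code fixtures: a tiny hand-readable vocabulary, builders for
# events/notes rows, and an index constructor that places prescribed
# vectors behind the public embedding API.

toy_vocabulary <- function() {
  as_vocabulary(tibble::tribble(
    ~concept_id, ~vocabulary_id, ~domain, ~description, ~language,
    "C1", "ICPC", "condition", "Hypertension", "en",
    "C1", "ICPC", "condition", "high blood pressure", "en",
    "C2", "ICPC", "condition", "Type 2 diabetes", "en",
    "C3", "LAB", "measurement", "systolic blood pressure", "en",
    "C4", "ATC", "drug", "metformin", "en"
  ))
}

make_events <- function(...) {
  rows <- list(...)
  tibble::tibble(
    event_id = vapply(rows, `[[`, "", "event_id"),
    patient_id = vapply(rows, `[[`, "", "patient_id"),
    visit_id = vapply(rows, function(r) r$visit_id %||% NA_character_, ""),
    event_date = as.Date(vapply(rows, function(r) r$date %||% "2022-01-01", "")),
    concept_id = vapply(rows, `[[`, "", "concept_id"),
    value = vapply(rows, function(r) r$value %||% NA_real_, 0),
    unit = vapply(rows, function(r) r$unit %||% NA_character_, "")
  )
}

make_notes <- function(...) {
  rows <- list(...)
  tibble::tibble(
    note_id = vapply(rows, `[[`, "", "note_id"),
    patient_id = vapply(rows, `[[`, "", "patient_id"),
    visit_id = vapply(rows, function(r) r$visit_id %||% NA_character_, ""),
    note_date = as.Date(vapply(rows, function(r) r$date %||% "2022-01-01", "")),
    note_type = vapply(rows, function(r) r$note_type %||% "consultation", ""),
    text = vapply(rows, `[[`, "", "text")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index whose concept vectors are exactly the rows of `mat` (rownames =
# concept ids), built through the public encoder + embedding API.
make_index <- function(mat, domains = NULL) {
  ids <- rownames(mat)
  if (is.null(domains)) domains <- rep("condition", length(ids))
  vocab <- as_vocabulary(tibble::tibble(
    concept_id = ids, vocabulary_id = "TEST", domain = domains,
    description = paste("desc", tolower(ids)), language = "en"
  ))
  lookup <- mat
  rownames(lookup) <- paste("desc", tolower(ids))
  enc <- new_encoder("fixed", ncol(mat), function(text, language = NULL) {
    key <- tolower(trimws(gsub("[[:punct:]]", " ", text)))
    lookup[key, , drop = FALSE]
  })
  embed_concepts(vocab, enc)
}

# Brute-force oracles, independent of the implementation under test.

oracle_weighted_gini <- function(similarity, label, threshold) {
  a_lab <- c(); b_lab <- c()
  for (i in seq_along(similarity)) {
    if (similarity[i] >= threshold) a_lab <- c(a_lab, label[i])
    else b_lab <- c(b_lab, label[i])
  }
  part <- function(lab) {
    if (length(lab) == 0) return(0)
    p <- sum(lab) / length(lab)
    (length(lab) / length(similarity)) * (1 - p^2 - (1 - p)^2)
  }
  part(a_lab) + part(b_lab)
}

oracle_best_match <- function(src_ids, other_ids, vectors) {
  out <- list()
  for (s in src_ids) {
    best_sim <- NA_real_; best_id <- NA_character_
    for (o in sort(other_ids)) {
      sim <- cosine_similarity(vectors[s, ], vectors[o, ])
      if (is.na(best_sim) || sim > best_sim + 1e-12) {
        best_sim <- sim; best_id <- o
      }
    }
    out[[s]] <- list(id = best_id, sim = best_sim)
  }
  out
}
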