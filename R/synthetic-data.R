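#' Configuration for the synthetic EHR generator
#'
#' Bundles every knob of the synthetic general-practice population:
#' vocabulary size and synonym count, per-visit event intensities, the
#' planted probability `p_mention` that a coded concept is also written
#' into the visit note (the quantity the downstream pipeline must
#' recover), rates of extra text-only and negated mentions, and the
#' fraction of material recorded outside visits (labs, secondary-care
#' letters). Identical config and seed give byte-identical output.
#'
#' Default intensities are chosen to echo a primary-care visit: a
#' handful of coded events (around three, spread over five domains),
#' one consultation note with roughly half the coded concepts restated
#' in text plus a few text-only concepts, and about half of all
#' material recorded outside visits — mirroring the severalfold excess
#' of record-level over visit-level data seen in GP databases.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_patients Number of patients.
#' @param visits_per_patient Mean visits per patient (Poisson, clamped
#'   to at least one visit).
#' @param events_per_visit Mean coded events per visit *per domain*
#'   (five domains: condition, drug, measurement, observation,
#'   procedure).
#' @param p_mention Probability in `[0, 1]` that a coded concept of a
#'   visit is also mentioned in the visit's note.
#' @param extra_mentions_per_visit Mean count of text-only concepts per
#'   note (Poisson).
#' @param p_negated Probability that a text-only mention is planted
#'   with a preceding negation trigger.
#' @param p_outside_visit Probability that an event, or a whole note,
#'   is recorded without a visit link.
#' @param n_concepts_per_domain Vocabulary size per domain.
#' @param synonyms_per_concept Number of surface forms per concept.
#' @param cluster_noise Within-concept angular noise of the synthetic
#'   encoder (0 = all synonyms embed identically).
#' @param embedding_dim Dimension of the synthetic embedding space.
#' @param start_date,end_date Date window for visits (ISO-8601 strings).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_patients = 100L,
                         visits_per_patient = 3,
                         events_per_visit = 0.6,
                         p_mention = 0.4,
                         extra_mentions_per_visit = 3,
                         p_negated = 0.1,
                         p_outside_visit = 0.5,
                         n_concepts_per_domain = 40L,
                         synonyms_per_concept = 3L,
                         cluster_noise = 0.1,
                         embedding_dim = 64L,
                         start_date = "2021-01-01",
                         end_date = "2024-01-01") {
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    visits_per_patient = visits_per_patient,
    events_per_visit = events_per_visit,
    p_mention = p_mention,
    extra_mentions_per_visit = extra_mentions_per_visit,
    p_negated = p_negated, p_outside_visit = p_outside_visit,
    n_concepts_per_domain = as.integer(n_concepts_per_domain),
    synonyms_per_concept = as.integer(synonyms_per_concept),
    cluster_noise = cluster_noise, embedding_dim = as.integer(embedding_dim),
    start_date = as.Date(start_date), end_date = as.Date(end_date)
  )
  probs <- c("p_mention", "p_negated", "p_outside_visit")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("%s must be in [0, 1]", p), class = "ehroverlap_config_error")
    }
  }
  counts <- c("n_patients", "visits_per_patient", "events_per_visit",
              "extra_mentions_per_visit", "n_concepts_per_domain",
              "synonyms_per_concept", "embedding_dim")
  for (p in counts) {
    if (cfg[[p]] < 0) {
      abort(sprintf("%s must be >= 0", p), class = "ehroverlap_config_error")
    }
  }
  if (cfg$cluster_noise < 0) {
    abort("cluster_noise must be >= 0", class = "ehroverlap_config_error")
  }
  structure(cfg, class = "synth_config")
}

MEASUREMENT_UNITS <- c("mmHg", "mmol/L", "kg", "%", "cm", "bpm")
NEGATION_PREFIXES <- c("no", "geen")

#' Generate a synthetic concept vocabulary
#'
#' Produces `n_concepts_per_domain` concepts for each of the five coded
#' domains, each with `synonyms_per_concept` pronounceable synonym
#' strings (alternating Dutch/English language tags; later synonyms may
#' be two-word forms to exercise longest-match extraction). Every word
#' is globally unique, so surface forms never collide across concepts:
#' extraction ambiguity is zero by construction and the matching and
#' threshold stages are tested in isolation from extractor quality.
#' Measurement and observation concepts additionally carry a fixed unit
#' (in a `unit` column) used when events are generated.
#'
#' @param config A `synth_config`.
#' @return An `ehr_vocabulary` tibble with an extra `unit` column.
#' @export
generate_vocabulary <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_concepts <- config$n_concepts_per_domain * length(CODED_DOMAINS)
  forms_per <- config$synonyms_per_concept
  # later synonyms alternate one- and two-word forms
  words_per_concept <- sum(ifelse(seq_len(forms_per) %% 2L == 1L, 1L, 2L))
  n_words <- n_concepts * words_per_concept

  withr::with_seed(derive_seed(config$seed, "vocabulary"), {
    words <- make_words(n_words)
    rows <- vector("list", n_concepts)
    w <- 1L
    for (i in seq_len(n_concepts)) {
      domain <- CODED_DOMAINS[((i - 1L) %/% config$n_concepts_per_domain) + 1L]
      forms <- character(forms_per)
      for (j in seq_len(forms_per)) {
        take <- if (j %% 2L == 1L) 1L else 2L
        forms[j] <- paste(words[w:(w + take - 1L)], collapse = " ")
        w <- w + take
      }
      rows[[i]] <- tibble(
        concept_id = sprintf("C%04d", i),
        vocabulary_id = "SYNTH",
        domain = domain,
        description = forms,
        language = rep_len(c("nl", "en"), forms_per)
      )
    }
    long <- list_rbind(rows)
  })
  vocab <- as_vocabulary(long)
  idx <- as.integer(sub("^C", "", vocab$concept_id))
  vocab$unit <- ifelse(
    vocab$domain %in% c("measurement", "observation"),
    MEASUREMENT_UNITS[(idx %% length(MEASUREMENT_UNITS)) + 1L],
    NA_character_
  )
  vocab
}

# Pronounceable unique 6-letter CVCVCV words; the syllable alphabet is
# disjoint (by shape) from the "fillNNNN" filler tokens and from every
# shipped context-rule trigger.
make_words <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  syllables <- as.vector(outer(consonants, vowels, paste0))
  words <- character(0)
  while (length(words) < n) {
    batch <- paste0(sample(syllables, 2L * n, replace = TRUE),
                    sample(syllables, 2L * n, replace = TRUE),
                    sample(syllables, 2L * n, replace = TRUE))
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

#' Generate a synthetic patient population with planted overlap
#'
#' Simulates visits carrying coded events across the five domains and
#' one note per visit whose text is filler tokens with embedded concept
#' surface forms: each distinct coded concept of the visit is restated
#' in the note with probability `p_mention`, extra text-only concepts
#' (never coded in the same visit) are added at the configured rate, and
#' a fraction of those carries a preceding negation trigger. Events and
#' notes lose their visit link with probability `p_outside_visit`
#' (detached notes become referral/communication notes). The returned
#' ground-truth table records every planted mention, so parameter
#' recovery — most importantly re-estimating `p_mention` from the
#' pipeline's structured-to-unstructured visit overlap — can be checked
#' exactly.
#'
#' @param config A `synth_config`.
#' @param vocabulary The vocabulary from [generate_vocabulary()].
#' @return A `synthetic_population` list: `events`, `notes`,
#'   `ground_truth` (one row per planted mention: `patient_id`,
#'   `visit_id`, `note_id`, `concept_id`, `kind` coded/extra, `negated`,
#'   `note_linked`), and `config`.
#' @export
generate_population <- function(config, vocabulary) {
  stopifnot(inherits(config, "synth_config"))
  forms_by_concept <- split(normalize_text(vocabulary_terms(vocabulary)$description),
                            vocabulary_terms(vocabulary)$concept_id)
  pools <- split(vocabulary$concept_id, vocabulary$domain)
  pools <- pools[intersect(CODED_DOMAINS, names(pools))]
  all_ids <- vocabulary$concept_id
  units <- setNames(vocabulary$unit, vocabulary$concept_id)
  domains <- setNames(vocabulary$domain, vocabulary$concept_id)
  base_value <- setNames(5 + 10 * (seq_along(all_ids) %% 20L), all_ids)
  date_span <- as.integer(config$end_date - config$start_date)

  ev_rows <- list(); nt_rows <- list(); gt_rows <- list()

  withr::with_seed(derive_seed(config$seed, "population"), {
    n_visits <- pmax(1L, rpois(config$n_patients, config$visits_per_patient))
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%04d", p)
      for (v in seq_len(n_visits[p])) {
        vid <- sprintf("%s-V%02d", pid, v)
        vdate <- config$start_date + sample.int(max(date_span, 1L), 1L) - 1L
        # coded events, per domain
        concepts <- unlist(lapply(pools, function(pool) {
          k <- rpois(1L, config$events_per_visit)
          if (k == 0L) character(0) else sample(pool, k, replace = TRUE)
        }), use.names = FALSE)
        n_ev <- length(concepts)
        detached <- runif(n_ev) < config$p_outside_visit
        vals <- rep(NA_real_, n_ev)
        is_meas <- domains[concepts] %in% c("measurement", "observation")
        vals[is_meas] <- round(base_value[concepts[is_meas]] *
                                 (1 + 0.1 * rnorm(sum(is_meas))), 1)
        if (n_ev > 0L) {
          ev_rows[[length(ev_rows) + 1L]] <- tibble(
            patient_id = pid,
            visit_id = ifelse(detached, NA_character_, vid),
            event_date = vdate + ifelse(detached, sample.int(5L, n_ev, replace = TRUE), 0L),
            concept_id = concepts,
            value = vals,
            unit = ifelse(is.na(vals), NA_character_, units[concepts])
          )
        }
        # the visit note: planted mentions
        distinct_coded <- unique(concepts)
        mentioned <- distinct_coded[runif(length(distinct_coded)) < config$p_mention]
        k_extra <- rpois(1L, config$extra_mentions_per_visit)
        extra_pool <- setdiff(all_ids, distinct_coded)
        k_extra <- min(k_extra, length(extra_pool))
        extras <- if (k_extra > 0L) sample(extra_pool, k_extra) else character(0)
        negated <- if (k_extra > 0L) runif(k_extra) < config$p_negated else logical(0)

        note_detached <- runif(1L) < config$p_outside_visit
        nid <- sprintf("%s-N", vid)
        planted <- tibble(
          concept_id = c(mentioned, extras),
          kind = c(rep("coded", length(mentioned)), rep("extra", length(extras))),
          negated = c(rep(FALSE, length(mentioned)), negated)
        )
        if (nrow(planted) > 0L) {
          planted <- planted[sample.int(nrow(planted)), , drop = FALSE]
          gt_rows[[length(gt_rows) + 1L]] <- tibble(
            patient_id = pid, visit_id = vid, note_id = nid,
            planted, note_linked = !note_detached
          )
        }
        nt_rows[[length(nt_rows) + 1L]] <- tibble(
          note_id = nid,
          patient_id = pid,
          visit_id = if (note_detached) NA_character_ else vid,
          note_date = vdate,
          note_type = if (note_detached) "referral_communication" else "consultation",
          text = compose_note_text(planted, forms_by_concept)
        )
      }
    }
  })

  events <- if (length(ev_rows) > 0L) list_rbind(ev_rows) else
    tibble(patient_id = character(0), visit_id = character(0),
           event_date = as.Date(character(0)), concept_id = character(0),
           value = numeric(0), unit = character(0))
  events <- bind_cols(tibble(event_id = sprintf("E%06d", seq_len(nrow(events)))),
                      events)
  notes <- list_rbind(nt_rows)
  gt <- if (length(gt_rows) > 0L) list_rbind(gt_rows) else
    tibble(patient_id = character(0), visit_id = character(0),
           note_id = character(0), concept_id = character(0),
           kind = character(0), negated = logical(0), note_linked = logical(0))

  structure(list(events = events, notes = notes, ground_truth = gt,
                 config = config),
            class = "synthetic_population")
}

# Note text: runs of filler tokens with planted surface forms embedded;
# negated plants get a negation trigger directly before the form. Filler
# runs are longer than the context-rule scope so a trigger can never
# leak onto the next planted mention.
compose_note_text <- function(planted, forms_by_concept, gap = 6L) {
  tokens <- filler_tokens(gap)
  if (nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      forms <- forms_by_concept[[planted$concept_id[i]]]
      form <- forms[sample.int(length(forms), 1L)]
      if (planted$negated[i]) {
        form <- paste(sample(NEGATION_PREFIXES, 1L), form)
      }
      tokens <- c(tokens, form, filler_tokens(gap))
    }
  }
  paste(tokens, collapse = " ")
}

filler_tokens <- function(n) {
  sprintf("fill%04d", sample.int(9999L, n, replace = TRUE))
}
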