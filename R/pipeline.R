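#' Pipeline run configuration
#'
#' One JSON-serialisable object holding everything a full run needs:
#' input tables (paths, or in-memory tibbles), encoder choice,
#' enrichment flag, grouping methods, threshold policy and seed. A
#' single seed feeds all stochastic stages through independent derived
#' streams, so one integer reproduces the whole run.
#'
#' @param concepts,events,notes Paths to the input CSVs, or the
#'   corresponding tibbles.
#' @param rules Context rules tibble or path (default: shipped rules).
#' @param encoder `"hash"`, `"synthetic"`, or a `concept_encoder`.
#' @param enrich Enrich measurement/observation embeddings with value
#'   and unit.
#' @param groupings Grouping methods to run (`"visit"`, `"record"`).
#' @param grid A `threshold_grid`.
#' @param per_domain Annotation pairs per (sample, bin, domain).
#' @param threshold Either a number, or `"from_annotations"` to
#'   calibrate from `annotations`.
#' @param annotations Labelled annotation tibble or path (needed when
#'   `threshold = "from_annotations"`).
#' @param subpopulations Optional named list of defining concept-id
#'   vectors.
#' @param seed Integer seed.
#' @param synth Optional `synth_config`; when given, the input tables
#'   are generated instead of read.
#' @return An `overlap_config` list.
#' @export
overlap_config <- function(concepts = NULL, events = NULL, notes = NULL,
                           rules = NULL, encoder = "hash", enrich = TRUE,
                           groupings = c("visit", "record"),
                           grid = threshold_grid(), per_domain = 5L,
                           threshold = "from_annotations", annotations = NULL,
                           subpopulations = NULL, seed = 1L, synth = NULL) {
  groupings <- match.arg(groupings, several.ok = TRUE)
  if (is.null(synth) && (is.null(concepts) || is.null(events) || is.null(notes))) {
    abort("config needs concepts, events and notes (or a synth config)",
          class = "ehroverlap_config_error")
  }
  if (identical(threshold, "from_annotations") && is.null(annotations) &&
      is.null(synth)) {
    abort("threshold = 'from_annotations' needs an annotations input",
          class = "ehroverlap_config_error")
  }
  structure(list(
    concepts = concepts, events = events, notes = notes, rules = rules,
    encoder = encoder, enrich = enrich, groupings = groupings, grid = grid,
    per_domain = as.integer(per_domain), threshold = threshold,
    annotations = annotations, subpopulations = subpopulations,
    seed = as.integer(seed), synth = synth
  ), class = "overlap_config")
}

#' Run the full overlap pipeline
#'
#' Orchestrates every stage — (optionally) simulate, extract, embed,
#' match per grouping, calibrate or apply the threshold, sweep and
#' quantify — and writes all outputs plus a manifest with per-stage row
#' counts, exclusion counts and content hashes into `out_dir`.
#' Rerunning with an identical config and inputs reproduces identical
#' manifest hashes.
#'
#' @param config An `overlap_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with every intermediate: `vocabulary`,
#'   `events`, `notes`, `mentions`, `index`, `matches`, `threshold`
#'   (a `threshold_result` or the fixed number), `sweep`, `report`,
#'   `subpopulation_reports`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("overlap-run-")) {
  stopifnot(inherits(config, "overlap_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed)

  # --- stage 1: inputs (read or simulate) ----------------------------------
  if (!is.null(config$synth)) {
    vocabulary <- generate_vocabulary(config$synth)
    population <- generate_population(config$synth, vocabulary)
    events <- population$events
    notes <- population$notes
    write_vocabulary(vocabulary, file.path(out_dir, "concepts.csv"))
    write_events(events, file.path(out_dir, "events.csv"))
    write_notes(notes, file.path(out_dir, "notes.csv"))
  } else {
    vocabulary <- load_or_pass(config$concepts, read_vocabulary, as_vocabulary)
    events <- load_or_pass(config$events, function(p) read_events(p, vocabulary))
    notes <- load_or_pass(config$notes, read_notes)
  }
  manifest$n_concepts <- nrow(vocabulary)
  manifest$n_events <- nrow(events)
  manifest$n_notes <- nrow(notes)

  # --- stage A: concept extraction -----------------------------------------
  rules <- if (is.null(config$rules)) default_context_rules() else
    load_or_pass(config$rules, read_context_rules)
  lexicon <- build_lexicon(vocabulary)
  mentions <- extract_concepts(notes, lexicon)
  mentions <- apply_context_rules(mentions, notes, rules)
  unmodified <- filter_unmodified(mentions)
  manifest$n_mentions <- nrow(mentions)
  manifest$n_mentions_unmodified <- nrow(unmodified)
  manifest$n_mentions_excluded_qualified <- nrow(mentions) - nrow(unmodified)
  write_mentions(mentions, file.path(out_dir, "mentions.csv"))

  # --- stage B: embeddings --------------------------------------------------
  encoder <- resolve_encoder(config, vocabulary)
  index <- embed_concepts(vocabulary, encoder, events = events,
                          mentions = unmodified, enrich = config$enrich)
  write_index(index, file.path(out_dir, "index"))
  manifest$n_embedded <- nrow(index$concepts)
  manifest$encoder <- index$encoder

  # --- stages 2-3: grouping + matching -------------------------------------
  matches <- list_rbind(map(config$groupings, function(g) {
    m <- run_matching(events, unmodified, notes, index, g, vocabulary)
    write_matches(m, file.path(out_dir, sprintf("matches_%s.csv", g)))
    manifest[[sprintf("n_matches_%s", g)]] <<- nrow(m)
    manifest[[sprintf("n_comparisons_%s", g)]] <<- attr(m, "n_comparisons")
    m
  }))
  if ("visit" %in% config$groupings) {
    loc <- left_join(unmodified,
                     select(notes, "note_id", "visit_id"), by = "note_id")
    manifest$n_mentions_excluded_no_visit <- sum(is.na(loc$visit_id))
  }

  # --- stage C: threshold ---------------------------------------------------
  if (identical(config$threshold, "from_annotations")) {
    ann <- if (!is.null(config$annotations)) {
      load_or_pass(config$annotations, read_annotations)
    } else {
      sample_annotation_pairs(matches, vocabulary, config$grid,
                              config$per_domain, config$seed)
    }
    if (all(is.na(ann$label))) {
      abort("annotation input is unlabelled; label it or set a numeric threshold",
            class = "ehroverlap_validation_error")
    }
    threshold_result <- find_threshold(ann, config$grid)
    t_star <- threshold_result$threshold
    jsonlite::write_json(
      list(threshold = t_star,
           minimizers = threshold_result$minimizers,
           curves = threshold_result$curves),
      file.path(out_dir, "threshold.json"), auto_unbox = TRUE, digits = NA)
  } else {
    threshold_result <- config$threshold
    t_star <- config$threshold
  }
  manifest$threshold <- t_star

  # --- stage 4: quantification ---------------------------------------------
  sweep <- threshold_sweep(matches, config$grid)
  readr::write_csv(sweep, file.path(out_dir, "sweep.csv"))
  report <- quantify_overlap(matches, t_star)
  write_overlap_report(report, file.path(out_dir, "overlap_report.csv"),
                       file.path(out_dir, "overlap_report.json"))

  subpop_reports <- NULL
  if (!is.null(config$subpopulations)) {
    subpop_reports <- purrr::imap(config$subpopulations, function(ids, nm) {
      sub <- filter_subpopulation(events, notes, ids, vocabulary, nm)
      sub_mentions <- semi_join(unmodified,
                                select(sub$notes, "note_id"), by = "note_id")
      m <- run_matching(sub$events, sub_mentions, sub$notes, index, "visit",
                        vocabulary)
      quantify_overlap(m, t_star, population = nm)
    })
    sub_all <- list_rbind(map(subpop_reports, as_tibble))
    readr::write_csv(sub_all, file.path(out_dir, "overlap_subpopulations.csv"))
  }

  manifest$file_hashes <- file_hashes(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(serializable_config(config),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    vocabulary = vocabulary, events = events, notes = notes,
    mentions = mentions, unmodified = unmodified, index = index,
    matches = matches, threshold = threshold_result, threshold_value = t_star,
    sweep = sweep, report = report, subpopulation_reports = subpop_reports,
    manifest = manifest, out_dir = out_dir
  ))
}

load_or_pass <- function(x, reader, coercer = identity) {
  if (is.character(x) && length(x) == 1L) reader(x) else coercer(x)
}

resolve_encoder <- function(config, vocabulary) {
  enc <- config$encoder
  if (inherits(enc, "concept_encoder")) return(enc)
  if (identical(enc, "hash")) {
    return(hash_encoder(config$synth$embedding_dim %||% 64L))
  }
  if (identical(enc, "synthetic")) {
    if (is.null(config$synth)) {
      abort("the synthetic encoder needs a synth config",
            class = "ehroverlap_config_error")
    }
    return(synthetic_encoder(vocabulary, config$synth$embedding_dim,
                             config$synth$cluster_noise, config$synth$seed))
  }
  abort(sprintf("unknown encoder '%s'", enc), class = "ehroverlap_config_error")
}

file_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, c("manifest.json", "config_resolved.json"))
  setNames(
    lapply(files, function(f) {
      rlang::hash(readBin(file.path(dir, f), "raw",
                          file.info(file.path(dir, f))$size))
    }),
    files
  )
}

serializable_config <- function(config) {
  out <- unclass(config)
  out$grid <- out$grid[c("lo", "hi", "step")]
  for (field in c("concepts", "events", "notes", "rules", "annotations")) {
    if (!is.null(out[[field]]) && !is.character(out[[field]])) {
      out[[field]] <- sprintf("<in-memory table: %d rows>", nrow(out[[field]]))
    }
  }
  if (inherits(out$encoder, "concept_encoder")) out$encoder <- out$encoder$name
  if (!is.null(out$synth)) out$synth <- unclass(out$synth)
  out
}
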