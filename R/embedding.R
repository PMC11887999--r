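#' Enrich a measurement description with its value and unit
#'
#' For measurement and observation concepts the numeric value and unit
#' carry much of the information (a blood pressure code means little
#' without the reading), so their descriptions are enriched to
#' `"<description>: <value> <unit>"` before embedding. The value is
#' formatted locale-independently with a period decimal separator;
#' absent value or unit parts are omitted. Descriptions of other domains
#' pass through unchanged.
#'
#' @param description Base concept description text.
#' @param value Optional numeric value (NA to omit).
#' @param unit Optional unit string (NA to omit).
#' @param domain Concept domain; only `"measurement"` and
#'   `"observation"` are enriched.
#' @return The enriched description text (character vector).
#' @export
enrich_description <- function(description, value = NA_real_, unit = NA_character_,
                               domain = "measurement") {
  stopifnot(length(value) %in% c(1L, length(description)))
  enrichable <- domain %in% c("measurement", "observation")
  suffix <- mapply(function(v, u) {
    parts <- c(
      if (!is.na(v)) format(v, trim = TRUE, scientific = FALSE, decimal.mark = "."),
      if (!is.na(u) && nzchar(u)) u
    )
    if (length(parts) == 0L) "" else paste0(": ", paste(parts, collapse = " "))
  }, rep_len(value, length(description)), rep_len(unit, length(description)))
  ifelse(enrichable & suffix != "", paste0(description, suffix), description)
}

#' Cosine similarity between two embedding vectors
#'
#' `dot(u, v) / (|u| |v|)`, clamped to `[-1, 1]` against floating-point
#' drift. Zero-norm inputs are a domain error: callers must have
#' excluded non-embeddable concepts beforehand.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("cosine similarity is undefined for zero-norm vectors",
          class = "ehroverlap_domain_error")
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Build a concept embedding index
#'
#' Embeds every concept in the vocabulary (or only those referenced by
#' `events` / `mentions` when given) as the element-wise mean of its
#' per-description encoder outputs — one comprehensive vector per
#' concept, however many synonyms it has. With `enrich = TRUE` and an
#' events table, measurement and observation concepts are embedded from
#' enriched descriptions instead: one representative enrichment per
#' distinct (concept, unit) pair using the median observed value, so the
#' index stays concept-keyed. Concepts whose mean vector has zero norm
#' cannot be compared and are excluded with a warning.
#'
#' @param vocabulary An `ehr_vocabulary` tibble.
#' @param encoder A `concept_encoder`.
#' @param events Optional events tibble; supplies values/units for
#'   enrichment and, with `mentions`, restricts which concepts are
#'   embedded.
#' @param mentions Optional mentions tibble (with `concept_id`), used
#'   together with `events` to restrict the index.
#' @param enrich Logical; enrich measurement/observation descriptions
#'   with value and unit.
#' @return A `concept_index`: list with `concepts` (tibble of
#'   `concept_id`, `domain`), `embeddings` (matrix, one row per concept),
#'   `unit_embeddings` (row-normalised copy used for cosine), `encoder`,
#'   `dim` and `enriched`.
#' @export
embed_concepts <- function(vocabulary, encoder, events = NULL, mentions = NULL,
                           enrich = FALSE) {
  stopifnot(inherits(encoder, "concept_encoder"))
  wanted <- vocabulary$concept_id
  if (!is.null(events) || !is.null(mentions)) {
    referenced <- unique(c(events$concept_id, mentions$concept_id))
    wanted <- intersect(wanted, referenced)
  }
  vocab <- vocabulary[match(sort(wanted), vocabulary$concept_id), , drop = FALSE]

  enrichments <- NULL
  if (enrich && !is.null(events)) {
    enrichments <- events |>
      filter(!is.na(.data$value)) |>
      group_by(.data$concept_id, .data$unit) |>
      summarise(value = median(.data$value), .groups = "drop")
  }

  vectors <- matrix(NA_real_, nrow = nrow(vocab), ncol = encoder$dim)
  for (i in seq_len(nrow(vocab))) {
    desc <- vocab$descriptions[[i]]
    texts <- desc$text
    langs <- desc$language
    if (!is.null(enrichments) &&
        vocab$domain[i] %in% c("measurement", "observation")) {
      en <- filter(enrichments, .data$concept_id == vocab$concept_id[i])
      if (nrow(en) > 0L) {
        combos <- tidyr::expand_grid(text = texts, en)
        texts <- enrich_description(combos$text, combos$value, combos$unit,
                                    domain = vocab$domain[i])
        langs <- rep(langs, times = nrow(en))
      }
    }
    emb <- encoder$encode(texts, langs)
    if (!is.matrix(emb) || ncol(emb) != encoder$dim) {
      abort(sprintf("encoder returned wrong shape for concept %s",
                    vocab$concept_id[i]))
    }
    vectors[i, ] <- colMeans(emb)
  }

  norms <- sqrt(rowSums(vectors^2))
  zero <- norms == 0 | !is.finite(norms)
  if (any(zero)) {
    warn(sprintf("excluded %d concept(s) with zero-norm embeddings: %s",
                 sum(zero), paste(vocab$concept_id[zero], collapse = ", ")))
  }
  keep <- !zero
  embeddings <- vectors[keep, , drop = FALSE]
  rownames(embeddings) <- vocab$concept_id[keep]
  unit_emb <- embeddings / sqrt(rowSums(embeddings^2))

  structure(list(
    concepts = tibble(concept_id = vocab$concept_id[keep],
                      domain = vocab$domain[keep]),
    excluded = vocab$concept_id[zero],
    embeddings = embeddings,
    unit_embeddings = unit_emb,
    encoder = encoder$name,
    dim = encoder$dim,
    enriched = isTRUE(enrich)
  ), class = "concept_index")
}

#' @export
print.concept_index <- function(x, ...) {
  cat(sprintf("<concept_index: %d concepts, %d dimensions, encoder '%s'%s>\n",
              nrow(x$concepts), x$dim, x$encoder,
              if (x$enriched) ", value/unit enriched" else ""))
  invisible(x)
}

#' Pairwise cosine similarities between two sets of indexed concepts
#'
#' @param index A `concept_index`.
#' @param ids_a,ids_b Concept ids present in the index.
#' @return A `length(ids_a)` x `length(ids_b)` matrix of cosine
#'   similarities, clamped to `[-1, 1]`.
#' @export
index_similarity <- function(index, ids_a, ids_b) {
  missing <- setdiff(c(ids_a, ids_b), rownames(index$unit_embeddings))
  if (length(missing) > 0L) {
    abort(sprintf("concept id(s) not in index: %s",
                  paste(missing, collapse = ", ")),
          class = "ehroverlap_domain_error")
  }
  s <- index$unit_embeddings[ids_a, , drop = FALSE] %*%
    t(index$unit_embeddings[ids_b, , drop = FALSE])
  s[s > 1] <- 1
  s[s < -1] <- -1
  s
}

#' Export / import a concept index as plain tables
#'
#' `write_index()` writes `embeddings.csv` (concept_id plus one column
#' per dimension) and `index_meta.json` into `dir`; `read_index()`
#' rebuilds the `concept_index` from them.
#'
#' @param index A `concept_index`.
#' @param dir Directory to write to / read from.
#' @return `dir` (write) or a `concept_index` (read).
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- as_tibble(index$embeddings, .name_repair = ~ paste0("d", seq_along(.x)))
  emb <- bind_cols(index$concepts, emb)
  readr::write_csv(emb, file.path(dir, "embeddings.csv"))
  jsonlite::write_json(
    list(encoder = index$encoder, dim = index$dim, enriched = index$enriched,
         excluded = index$excluded),
    file.path(dir, "index_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_index
#' @export
read_index <- function(dir) {
  emb <- readr::read_csv(file.path(dir, "embeddings.csv"),
                         show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "index_meta.json"))
  m <- as.matrix(emb[setdiff(names(emb), c("concept_id", "domain"))])
  dimnames(m) <- list(emb$concept_id, NULL)
  structure(list(
    concepts = select(emb, "concept_id", "domain"),
    excluded = as.character(unlist(meta$excluded)),
    embeddings = m,
    unit_embeddings = m / sqrt(rowSums(m^2)),
    encoder = meta$encoder,
    dim = as.integer(meta$dim),
    enriched = isTRUE(meta$enriched)
  ), class = "concept_index")
}
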