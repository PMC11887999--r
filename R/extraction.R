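#' Build a dictionary lexicon from a vocabulary
#'
#' Maps every distinct normalised description (case-folded, punctuation
#' stripped, whitespace collapsed) to its concept id. When two concepts
#' share a normalised description the collision is logged and the lowest
#' concept id wins — real word-sense disambiguation is the job of an
#' external extractor plugged in behind the same mention schema.
#'
#' @param vocabulary An `ehr_vocabulary` tibble (non-empty).
#' @return A `concept_lexicon`: list with `table` (tibble of `form`,
#'   `n_tokens`, `concept_id`, `domain`), a constant-time lookup
#'   environment, and `max_tokens`.
#' @export
build_lexicon <- function(vocabulary) {
  if (is.null(vocabulary) || nrow(vocabulary) == 0L) {
    abort("cannot build a lexicon from an empty concept table",
          class = "ehroverlap_config_error")
  }
  terms <- vocabulary_terms(vocabulary)
  tab <- tibble(
    form = normalize_text(terms$description),
    concept_id = terms$concept_id,
    domain = terms$domain
  ) |>
    distinct() |>
    arrange(.data$form, .data$concept_id)

  collided <- tab |> count(.data$form) |> filter(.data$n > 1L)
  if (nrow(collided) > 0L) {
    message(sprintf(
      "%d lexicon collision(s); lowest concept_id wins for: %s",
      nrow(collided), paste(head(collided$form, 5L), collapse = "; ")
    ))
    tab <- tab |> group_by(.data$form) |> slice(1L) |> ungroup()
  }
  tab$n_tokens <- stringr::str_count(tab$form, stringr::fixed(" ")) + 1L

  env <- new.env(parent = emptyenv(), size = nrow(tab) * 2L)
  for (i in seq_len(nrow(tab))) {
    assign(tab$form[i], list(concept_id = tab$concept_id[i],
                             domain = tab$domain[i]), envir = env)
  }
  structure(list(table = tab, env = env, max_tokens = max(tab$n_tokens)),
            class = "concept_lexicon")
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat(sprintf("<concept_lexicon: %d surface forms, %d concepts, up to %d tokens>\n",
              nrow(x$table), length(unique(x$table$concept_id)), x$max_tokens))
  invisible(x)
}

#' Extract concept mentions from clinical notes
#'
#' Greedy left-to-right longest-match dictionary extraction over the
#' normalised token stream of each note: at every position the longest
#' lexicon entry starting there is taken (so "type 2 diabetes" beats
#' "diabetes") and matching resumes after it, giving non-overlapping
#' spans. Qualifiers are default-initialised (not negated, present,
#' patient) — see [apply_context_rules()]. Empty notes yield no
#' mentions. This is a deliberately simple, pluggable stand-in for a
#' full clinical NER+L framework: any component emitting the same
#' mention schema can replace it.
#'
#' @param notes A notes tibble ([read_notes()] layout).
#' @param lexicon A `concept_lexicon`.
#' @return A mentions tibble: `note_id`, `start`, `end` (0-based
#'   half-open token span), `concept_id`, `domain`, `negated`,
#'   `temporality`, `experiencer`.
#' @export
extract_concepts <- function(notes, lexicon) {
  stopifnot(inherits(lexicon, "concept_lexicon"))
  token_lists <- tokenize(notes$text)
  out <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    out[[i]] <- match_tokens(token_lists[[i]], lexicon, notes$note_id[i])
  }
  res <- list_rbind(out)
  if (nrow(res) == 0L) {
    res <- empty_mentions()
  }
  res$negated <- FALSE
  res$temporality <- "present"
  res$experiencer <- "patient"
  res
}

match_tokens <- function(tokens, lexicon, note_id) {
  n <- length(tokens)
  if (n == 0L) return(NULL)
  starts <- integer(0); ends <- integer(0)
  cids <- character(0); doms <- character(0)
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq.int(min(lexicon$max_tokens, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      entry <- get0(key, envir = lexicon$env, inherits = FALSE)
      if (!is.null(entry)) {
        starts <- c(starts, i - 1L)
        ends <- c(ends, i + len - 1L)
        cids <- c(cids, entry$concept_id)
        doms <- c(doms, entry$domain)
        hit_len <- len
        break
      }
    }
    i <- i + max(hit_len, 1L)
  }
  if (length(starts) == 0L) return(NULL)
  tibble(note_id = note_id, start = starts, end = ends,
         concept_id = cids, domain = doms)
}

empty_mentions <- function() {
  tibble(note_id = character(0), start = integer(0), end = integer(0),
         concept_id = character(0), domain = character(0))
}

#' ConText-style qualifier rules
#'
#' `default_context_rules()` returns the small trigger inventory shipped
#' with the package (`inst/extdata/context_rules.csv`): negation,
#' temporality and experiencer triggers with forward scope 5, in English
#' and Dutch. `read_context_rules()` loads a custom rule file with the
#' same schema: `trigger, effect_field, effect_value, direction, scope`.
#' The mechanism is the point here, not the inventory — production use
#' of real clinical text calls for a validated rule set.
#'
#' @param path Path to a rules CSV.
#' @return A rules tibble.
#' @export
read_context_rules <- function(path) {
  rules <- read_table_checked(
    path,
    required = c("trigger", "effect_field", "effect_value", "direction", "scope"),
    col_types = readr::cols(
      trigger = readr::col_character(),
      effect_field = readr::col_character(),
      effect_value = readr::col_character(),
      direction = readr::col_character(),
      scope = readr::col_integer()
    )
  )
  validate_context_rules(rules)
}

#' @rdname read_context_rules
#' @export
default_context_rules <- function() {
  read_context_rules(system.file("extdata", "context_rules.csv",
                                 package = "ehroverlap", mustWork = TRUE))
}

validate_context_rules <- function(rules) {
  rules$trigger <- normalize_text(rules$trigger)
  if (any(rules$trigger == "")) {
    abort("context rule triggers must be non-empty",
          class = "ehroverlap_config_error")
  }
  if (any(rules$scope < 1L)) {
    abort("context rule scope must be >= 1", class = "ehroverlap_config_error")
  }
  stopifnot(all(rules$direction %in% c("forward", "backward", "bidirectional")),
            all(rules$effect_field %in% c("negated", "temporality", "experiencer")))
  rules
}

#' Attach context qualifiers to extracted mentions
#'
#' For every occurrence of a rule trigger in a note's token stream, all
#' mentions within the rule's scope (token distance, counted from the
#' trigger's edge; 1 = immediately adjacent) in the rule's direction
#' receive the qualifier effect. Effects are monotone away from the
#' default: once a mention is negated it stays negated, and a
#' temporality or experiencer already set to a non-default value is not
#' overwritten by a later trigger.
#'
#' @param mentions A mentions tibble from [extract_concepts()].
#' @param notes The notes the mentions came from.
#' @param rules A rules tibble (default: [default_context_rules()]).
#' @return The mentions tibble with qualifiers set.
#' @export
apply_context_rules <- function(mentions, notes, rules = default_context_rules()) {
  rules <- validate_context_rules(rules)
  if (nrow(mentions) == 0L) return(mentions)
  token_lists <- setNames(tokenize(notes$text), notes$note_id)
  trig_tokens <- stringr::str_split(rules$trigger, stringr::fixed(" "))

  for (nid in unique(mentions$note_id)) {
    tokens <- token_lists[[nid]]
    rows <- which(mentions$note_id == nid)
    for (r in seq_len(nrow(rules))) {
      occ <- find_occurrences(tokens, trig_tokens[[r]])
      for (ts in occ) {
        te <- ts + length(trig_tokens[[r]]) # half-open trigger span [ts, te)
        fwd <- rules$direction[r] %in% c("forward", "bidirectional")
        bwd <- rules$direction[r] %in% c("backward", "bidirectional")
        hit <- rep(FALSE, length(rows))
        if (fwd) {
          d <- mentions$start[rows] - te + 1L
          hit <- hit | (d >= 1L & d <= rules$scope[r])
        }
        if (bwd) {
          d <- ts - mentions$end[rows] + 1L
          hit <- hit | (d >= 1L & d <= rules$scope[r])
        }
        if (any(hit)) {
          mentions <- apply_effect(mentions, rows[hit],
                                   rules$effect_field[r], rules$effect_value[r])
        }
      }
    }
  }
  mentions
}

find_occurrences <- function(tokens, trigger) {
  k <- length(trigger)
  n <- length(tokens)
  if (n < k) return(integer(0))
  cand <- which(tokens == trigger[1L])
  cand <- cand[cand + k - 1L <= n]
  keep <- vapply(cand, function(s) all(tokens[s:(s + k - 1L)] == trigger),
                 logical(1))
  cand[keep] - 1L # 0-based
}

apply_effect <- function(mentions, rows, field, value) {
  if (field == "negated") {
    mentions$negated[rows] <- TRUE
  } else {
    current <- mentions[[field]][rows]
    default <- if (field == "temporality") "present" else "patient"
    mentions[[field]][rows] <- ifelse(current == default, value, current)
  }
  mentions
}

#' Keep only unmodified mentions
#'
#' Retains exactly the mentions whose qualifiers equal the default (not
#' negated, present, experienced by the patient). Negated, historical,
#' hypothetical or other-experiencer mentions describe information about
#' absence, the past, or someone else, and are excluded from the overlap
#' comparison to keep it to the core asserted concepts.
#'
#' @param mentions A mentions tibble with qualifiers set.
#' @return The filtered mentions tibble.
#' @export
filter_unmodified <- function(mentions) {
  filter(mentions, !.data$negated,
         .data$temporality == "present",
         .data$experiencer == "patient")
}

#' Write / read a mentions table
#'
#' @param mentions A mentions tibble.
#' @param path Output file path.
#' @return `path` (write) or the mentions tibble (read).
#' @export
write_mentions <- function(mentions, path) {
  readr::write_csv(mentions, path)
  invisible(path)
}

#' @rdname write_mentions
#' @export
read_mentions <- function(path) {
  read_table_checked(
    path,
    required = c("note_id", "start", "end", "concept_id", "domain",
                 "negated", "temporality", "experiencer"),
    col_types = readr::cols(
      note_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      concept_id = readr::col_character(),
      domain = readr::col_character(),
      negated = readr::col_logical(),
      temporality = readr::col_character(),
      experiencer = readr::col_character()
    )
  )
}
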