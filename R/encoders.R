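#' Encoder contract
#'
#' An encoder turns concept description text into fixed-dimension
#' embedding vectors. Any encoder usable by [embed_concepts()] is a list
#' of class `concept_encoder` with fields `name`, `dim` and `encode`,
#' where `encode(text, language)` returns a numeric matrix with one row
#' per input text and `dim` columns. Encoders must be deterministic per
#' input and place all languages in one shared space (the multilingual
#' assumption: a Dutch and an English description of the same concept
#' land near each other).
#'
#' Two encoders ship with the package: [hash_encoder()], a deterministic
#' content-hash baseline with no semantics, and [synthetic_encoder()],
#' which embeds a generated vocabulary's descriptions around known latent
#' concept vectors so downstream matching has ground truth. An adapter
#' around a real sentence-transformer (e.g. a BioLORD-class model, 768
#' dimensions) plugs in through the same contract.
#'
#' @param name Encoder name (stored as provenance in the index).
#' @param dim Embedding dimension.
#' @param encode_fn Function `(text, language) -> matrix`.
#' @return A `concept_encoder` object.
#' @export
new_encoder <- function(name, dim, encode_fn) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(dim), dim >= 1, is.function(encode_fn))
  structure(list(name = name, dim = as.integer(dim), encode = encode_fn),
            class = "concept_encoder")
}

#' @export
print.concept_encoder <- function(x, ...) {
  cat(sprintf("<concept_encoder: %s, %d dimensions>\n", x$name, x$dim))
  invisible(x)
}

#' Deterministic hash encoder
#'
#' Maps each distinct normalised description to a reproducible random
#' unit vector seeded by a hash of the text. Descriptions of different
#' concepts are near-orthogonal in expectation; synonyms of one concept
#' are unrelated (the encoder knows no semantics). It serves as a
#' fallback and as a null baseline: with it, overlap estimates collapse
#' to exact-surface-form agreement.
#'
#' @param dim Embedding dimension (default 64).
#' @return A `concept_encoder`.
#' @export
hash_encoder <- function(dim = 64L) {
  dim <- as.integer(dim)
  new_encoder("hash", dim, function(text, language = NULL) {
    hashed_vectors(normalize_text(text), dim)
  })
}

#' Synthetic-geometry encoder for a generated vocabulary
#'
#' Assigns every concept in a synthetic vocabulary a latent unit vector
#' (near-orthogonal across concepts for dimensions of a few dozen and
#' up), then embeds each description as that latent vector plus
#' `cluster_noise` times a description-specific unit perturbation. At
#' `cluster_noise = 0` all synonyms of a concept embed identically, in
#' any language tag; unknown descriptions fall back to a hashed vector
#' and are flagged via the `"unknown"` attribute of the returned matrix.
#'
#' Enriched measurement descriptions (`"<description>: <value> <unit>"`,
#' see [enrich_description()]) are recognised by their description
#' prefix and embed near the base concept, perturbed by the full
#' enriched text — emulating how a real sentence encoder shifts a
#' vector slightly when the text gains a value and unit.
#'
#' @param vocabulary An `ehr_vocabulary` (typically from
#'   [generate_vocabulary()]).
#' @param dim Embedding dimension (default 64).
#' @param cluster_noise Within-concept angular noise, >= 0. Roughly: the
#'   cosine between two synonyms of one concept concentrates near
#'   `1 / (1 + cluster_noise^2)`.
#' @param seed Integer seed fixing the latent geometry.
#' @return A `concept_encoder`.
#' @export
synthetic_encoder <- function(vocabulary, dim = 64L, cluster_noise = 0.1,
                              seed = 1L) {
  stopifnot(cluster_noise >= 0)
  dim <- as.integer(dim)
  ids <- vocabulary$concept_id
  latents <- withr::with_seed(derive_seed(seed, "latent-geometry"), {
    m <- matrix(rnorm(length(ids) * dim), nrow = length(ids))
    m / sqrt(rowSums(m^2))
  })
  rownames(latents) <- ids

  terms <- vocabulary_terms(vocabulary)
  term_to_id <- setNames(terms$concept_id, normalize_text(terms$description))
  term_tokens <- stringr::str_count(names(term_to_id), stringr::fixed(" ")) + 1L
  max_tok <- max(term_tokens)

  lookup_concept <- function(txt) {
    # exact match first, then longest known token prefix (enriched text)
    hit <- term_to_id[txt]
    if (!is.na(hit)) return(hit)
    toks <- strsplit(txt, " ", fixed = TRUE)[[1L]]
    for (n in rev(seq_len(min(max_tok, length(toks))))) {
      hit <- term_to_id[paste(toks[seq_len(n)], collapse = " ")]
      if (!is.na(hit)) return(hit)
    }
    NA_character_
  }

  new_encoder(sprintf("synthetic-d%d", dim), dim, function(text, language = NULL) {
    txt <- normalize_text(text)
    out <- matrix(0, nrow = length(txt), ncol = dim)
    unknown <- logical(length(txt))
    for (i in seq_along(txt)) {
      cid <- lookup_concept(txt[i])
      if (is.na(cid)) {
        unknown[i] <- TRUE
        out[i, ] <- hashed_vectors(txt[i], dim)
      } else if (cluster_noise == 0) {
        out[i, ] <- latents[cid, ]
      } else {
        out[i, ] <- latents[cid, ] + cluster_noise * hashed_vectors(txt[i], dim)
      }
    }
    attr(out, "unknown") <- unknown
    out
  })
}

# One reproducible random unit vector per distinct string.
hashed_vectors <- function(text, dim) {
  out <- matrix(0, nrow = length(text), ncol = dim)
  for (i in seq_along(text)) {
    out[i, ] <- withr::with_seed(string_seed(text[i]), {
      v <- rnorm(dim)
      v / sqrt(sum(v^2))
    })
  }
  if (length(text) == 1L) out else out
}
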