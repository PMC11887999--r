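# Text normalisation shared by the lexicon builder, the extractor and the
# synthetic/hash encoders. The invariant that matters: the exact same
# normalisation is applied when the lexicon is built and when note text is
# matched, otherwise dictionary lookup silently fails.

normalize_text <- function(x) {
  x <- tolower(enc2utf8(as.character(x)))
  x <- stringr::str_replace_all(x, "[[:punct:]]", " ")
  x <- stringr::str_squish(x)
  x
}

tokenize <- function(x) {
  x <- normalize_text(x)
  out <- stringr::str_split(x, stringr::fixed(" "))
  out[x == ""] <- list(character(0))
  out
}
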