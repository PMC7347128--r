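#' Configure the text-cleaning and tokenization pipeline
#'
#' Call descriptions are short, noisy free text ("SEWAGE  Smell!!",
#' "grafiti on wall"). The pipeline lower-cases, strips punctuation and
#' digits, applies an explicit whole-word misspelling map, and drops a small
#' list of English function words (articles, prepositions, conjunctions).
#' No automatic spell correction is performed: misspellings are handled only
#' through `normalization_map`, which keeps the pipeline deterministic and
#' auditable.
#'
#' @param stopwords Character vector of lowercase tokens to drop. Defaults to
#'   the ~55-word list packaged in `inst/extdata/stopwords.txt`.
#' @param normalization_map Named character vector mapping misspelled tokens
#'   to canonical spellings, e.g. `c(grafiti = "graffiti")`. Applied
#'   whole-word after case folding.
#' @param fields_to_scan Character vector of text column names to tokenize,
#'   in order. Defaults to the descriptor column only.
#'
#' @return A `blight_text_config` list.
#' @export
#' @examples
#' cfg <- text_config(normalization_map = c(grafiti = "graffiti"))
#' clean_text("Grafiti on WALL!!", cfg)
text_config <- function(stopwords = default_stopwords(),
                        normalization_map = character(),
                        fields_to_scan = "descriptor") {
  stopwords <- tolower(as.character(stopwords))
  if (length(normalization_map) > 0L) {
    if (is.null(names(normalization_map)) || any(names(normalization_map) == "")) {
      stop_config("text_config: normalization_map must be a named character vector")
    }
    bad <- !grepl("^[a-z]+$", c(names(normalization_map), tolower(normalization_map)))
    if (any(bad)) {
      stop_config("text_config: normalization_map keys and values must be single lowercase alphabetic tokens")
    }
  }
  structure(
    list(
      stopwords = stopwords,
      normalization_map = normalization_map,
      fields_to_scan = as.character(fields_to_scan)
    ),
    class = "blight_text_config"
  )
}

#' Default stopword list
#'
#' @return Character vector of lowercase English articles, prepositions,
#'   conjunctions and a few copulas/pronouns.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "blight311")
  readLines(path, warn = FALSE)
}

#' Clean a free-text call description
#'
#' Lower-cases, replaces every non-letter with a space (digits and
#' punctuation carry no lexicon signal here), applies the whole-word
#' normalization map, and collapses whitespace. `NA`/`NULL` input yields
#' `""`. Idempotent: cleaning a cleaned string is a no-op.
#'
#' @param raw Character vector (or `NULL`) of raw text.
#' @param config A [text_config()].
#' @return Character vector of cleaned strings, same length as `raw`
#'   (length 1 for `NULL`).
#' @export
#' @examples
#' clean_text("SEWAGE  Smell!!")
clean_text <- function(raw, config = text_config()) {
  if (is.null(raw)) raw <- NA_character_
  out <- tolower(as.character(raw))
  out[is.na(out)] <- ""
  out <- gsub("[^a-z]+", " ", out)
  nm <- config$normalization_map
  if (length(nm) > 0L) {
    for (i in seq_along(nm)) {
      out <- gsub(paste0("\\b", names(nm)[i], "\\b"), tolower(nm[[i]]), out)
    }
  }
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Tokenize cleaned text
#'
#' Splits on whitespace and removes stopwords. Duplicate tokens are kept at
#' this stage; deduplication happens when a record is scored against the
#' lexicon, so token-frequency information stays available upstream.
#'
#' @param cleaned A single cleaned string (output of [clean_text()]).
#' @param config A [text_config()].
#' @return Character vector of tokens in text order (possibly empty).
#' @export
#' @examples
#' tokenize(clean_text("The sidewalk is BROKEN"))
tokenize <- function(cleaned, config = text_config()) {
  stopifnot(length(cleaned) == 1L)
  if (is.na(cleaned) || !nzchar(cleaned)) {
    return(character())
  }
  toks <- strsplit(cleaned, " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% config$stopwords]
}

#' Tokenize the text fields of a call tibble
#'
#' Applies [clean_text()] and [tokenize()] to each configured text field of
#' every record and stores the concatenated token sequence in a list-column
#' `tokens` plus its distinct set size in `n_distinct_tokens`.
#'
#' @param calls A call tibble (see [read_calls()]).
#' @param config A [text_config()]; its `fields_to_scan` must name columns
#'   of `calls`.
#' @return `calls` with `tokens` (list of character vectors) and
#'   `n_distinct_tokens` columns added.
#' @export
tokenize_calls <- function(calls, config = text_config()) {
  assert_columns(calls, config$fields_to_scan, "tokenize_calls")
  fields <- config$fields_to_scan
  toks <- purrr::pmap(calls[fields], function(...) {
    pieces <- clean_text(unlist(list(...)), config)
    unlist(lapply(pieces, tokenize, config = config), use.names = FALSE)
  })
  calls$tokens <- toks
  calls$n_distinct_tokens <- vapply(toks, function(x) length(unique(x)), integer(1))
  calls
}
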