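#' Partition the training vocabulary by class exclusivity
#'
#' The core of the blight-identification algorithm: every token observed in
#' the labelled training calls is placed in exactly one of three disjoint
#' sets — `blight_only` (appears in at least one blight call and no
#' non-blight call), `nonblight_only` (the reverse), or `shared`. By default
#' the scoring vocabulary is the blight-exclusive set; shared tokens are
#' excluded because they carry little class signal when they appear at
#' similar rates in both classes. An optional ratio rule admits shared
#' tokens whose blight/non-blight document-frequency ratio exceeds
#' `shared_ratio` (off by default).
#'
#' @param calls A tokenized, labelled call tibble: needs `tokens` and a
#'   non-missing `blight_label` for at least one record of each class
#'   (unlabeled records are dropped with a warning).
#' @param min_freq Minimum number of training records a token must appear in
#'   to enter the vocabulary (default 1, i.e. no floor).
#' @param shared_ratio Optional positive number; when given, shared tokens
#'   with blight-rate / non-blight-rate at least this value join the scoring
#'   vocabulary.
#' @return A `blight_lexicon` object: list with character-vector elements
#'   `blight_only`, `nonblight_only`, `shared`, `scoring_vocabulary`, and a
#'   one-row `summary` tibble of set sizes and percentage shares of the
#'   vocabulary.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   tokens = list(c("rat", "trash", "odor"), c("noise", "trash")),
#'   blight_label = c(1L, 0L)
#' )
#' build_lexicon(calls)$blight_only
build_lexicon <- function(calls, min_freq = 1, shared_ratio = NULL) {
  assert_columns(calls, c("tokens", "blight_label"), "build_lexicon")
  labelled <- !is.na(calls$blight_label)
  if (any(!labelled)) {
    warn(sprintf("build_lexicon: dropping %d unlabeled record(s)", sum(!labelled)))
    calls <- calls[labelled, ]
  }
  n_blight <- sum(calls$blight_label == 1L)
  n_non <- sum(calls$blight_label == 0L)
  if (n_blight == 0L || n_non == 0L) {
    stop_data("build_lexicon: need at least one record of each class; exclusivity is undefined on single-class input")
  }
  doc_freq <- function(token_lists) {
    tok <- unlist(lapply(token_lists, unique), use.names = FALSE)
    c(table(tok))
  }
  df_b <- doc_freq(calls$tokens[calls$blight_label == 1L])
  df_n <- doc_freq(calls$tokens[calls$blight_label == 0L])
  vocab <- union(names(df_b), names(df_n))
  freq <- setNames(numeric(length(vocab)), vocab)
  freq[names(df_b)] <- freq[names(df_b)] + df_b
  freq[names(df_n)] <- freq[names(df_n)] + df_n
  vocab <- vocab[freq[vocab] >= min_freq]
  in_b <- vocab %in% names(df_b)
  in_n <- vocab %in% names(df_n)
  blight_only <- sort(vocab[in_b & !in_n])
  nonblight_only <- sort(vocab[!in_b & in_n])
  shared <- sort(vocab[in_b & in_n])

  scoring <- blight_only
  if (!is.null(shared_ratio)) {
    if (!is_scalar_number(shared_ratio) || shared_ratio <= 0) {
      stop_config("build_lexicon: shared_ratio must be a positive number")
    }
    rate_b <- df_b[shared] / n_blight
    rate_n <- df_n[shared] / n_non
    scoring <- sort(c(blight_only, shared[rate_b / rate_n >= shared_ratio]))
  }

  n_total <- length(blight_only) + length(nonblight_only) + length(shared)
  structure(
    list(
      blight_only = blight_only,
      nonblight_only = nonblight_only,
      shared = shared,
      scoring_vocabulary = scoring,
      summary = tibble::tibble(
        n_tokens = n_total,
        n_blight_only = length(blight_only),
        n_nonblight_only = length(nonblight_only),
        n_shared = length(shared),
        pct_blight_only = 100 * length(blight_only) / n_total,
        pct_nonblight_only = 100 * length(nonblight_only) / n_total,
        pct_shared = 100 * length(shared) / n_total
      )
    ),
    class = "blight_lexicon"
  )
}

#' @export
print.blight_lexicon <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<blight_lexicon> %d tokens: %d blight-exclusive (%.0f%%), %d non-blight-exclusive (%.0f%%), %d shared (%.0f%%); scoring vocabulary %d tokens\n",
    s$n_tokens, s$n_blight_only, s$pct_blight_only,
    s$n_nonblight_only, s$pct_nonblight_only,
    s$n_shared, s$pct_shared, length(x$scoring_vocabulary)
  ))
  invisible(x)
}

#' Percentage shares of a token partition
#'
#' Helper for reporting the three-way partition at arbitrary counts, e.g.
#' a partition of (516, 415, 182) exclusive/exclusive/shared tokens out of
#' 1,113 has a blight-exclusive share of 46% to the nearest percent.
#'
#' @param n_blight_only,n_nonblight_only,n_shared Non-negative counts.
#' @return One-row tibble with the counts, total, and unrounded percentage
#'   shares.
#' @export
partition_shares <- function(n_blight_only, n_nonblight_only, n_shared) {
  total <- n_blight_only + n_nonblight_only + n_shared
  if (total <= 0) stop_data("partition_shares: empty partition")
  tibble::tibble(
    n_tokens = total,
    n_blight_only = n_blight_only,
    n_nonblight_only = n_nonblight_only,
    n_shared = n_shared,
    pct_blight_only = 100 * n_blight_only / total,
    pct_nonblight_only = 100 * n_nonblight_only / total,
    pct_shared = 100 * n_shared / total
  )
}

#' Score calls by unique lexicon-token count
#'
#' The model's primary predictor: the number of *distinct* scoring-
#' vocabulary tokens present in a record. Distinct types, not occurrences —
#' repeating a lexicon word does not raise the score. Tokens unseen in
#' training simply do not score.
#'
#' @param calls A tokenized call tibble (has a `tokens` list-column).
#' @param lexicon A [build_lexicon()] object, or a character vector used
#'   directly as the scoring vocabulary.
#' @return `calls` with an integer `unique_token_count` column added.
#' @export
#' @examples
#' calls <- tibble::tibble(tokens = list(c("rat", "rat", "trash", "wall")))
#' score_calls(calls, c("rat", "trash", "odor"))$unique_token_count # 2
score_calls <- function(calls, lexicon) {
  assert_columns(calls, "tokens", "score_calls")
  vocab <- if (inherits(lexicon, "blight_lexicon")) lexicon$scoring_vocabulary else as.character(lexicon)
  calls$unique_token_count <- vapply(
    calls$tokens,
    function(toks) length(intersect(unique(toks), vocab)),
    integer(1)
  )
  calls
}

#' Write / read a lexicon as a two-column CSV
#'
#' Serializes the partition for audit and reuse: columns `token`,
#' `partition` (`blight_only` / `nonblight_only` / `shared`), plus a
#' `scoring` flag.
#'
#' @param lexicon A `blight_lexicon`.
#' @param path Output CSV path.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon` returns
#'   a `blight_lexicon` (summary recomputed from the stored partition).
#' @export
write_lexicon <- function(lexicon, path) {
  df <- tibble::tibble(
    token = c(lexicon$blight_only, lexicon$nonblight_only, lexicon$shared),
    partition = rep(
      c("blight_only", "nonblight_only", "shared"),
      c(length(lexicon$blight_only), length(lexicon$nonblight_only), length(lexicon$shared))
    )
  )
  df$scoring <- df$token %in% lexicon$scoring_vocabulary
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    token = readr::col_character(), partition = readr::col_character(),
    scoring = readr::col_logical()
  ), progress = FALSE)
  pick <- function(p) sort(df$token[df$partition == p])
  lex <- list(
    blight_only = pick("blight_only"),
    nonblight_only = pick("nonblight_only"),
    shared = pick("shared"),
    scoring_vocabulary = sort(df$token[df$scoring])
  )
  lex$summary <- partition_shares(
    length(lex$blight_only), length(lex$nonblight_only), length(lex$shared)
  )
  structure(lex, class = "blight_lexicon")
}
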