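#' @importFrom ggplot2 ggplot aes geom_col geom_tile geom_text geom_point
#'   geom_errorbar geom_hline labs scale_fill_gradient theme_minimal
#'   facet_wrap autoplot
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Bar chart of the token partition
#'
#' @param lexicon A `blight_lexicon`.
#' @return A ggplot.
#' @export
plot_token_partition <- function(lexicon) {
  s <- lexicon$summary
  df <- tibble::tibble(
    partition = factor(
      c("blight-exclusive", "non-blight-exclusive", "shared"),
      levels = c("blight-exclusive", "non-blight-exclusive", "shared")
    ),
    n = c(s$n_blight_only, s$n_nonblight_only, s$n_shared),
    pct = c(s$pct_blight_only, s$pct_nonblight_only, s$pct_shared)
  )
  ggplot(df, aes(x = .data$partition, y = .data$n)) +
    geom_col(fill = "grey35") +
    geom_text(aes(label = sprintf("%d (%.0f%%)", .data$n, .data$pct)), vjust = -0.4) +
    labs(x = NULL, y = "tokens",
         title = "Training-vocabulary partition by class exclusivity") +
    theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `blight_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot blight_confusion
#' @export
autoplot.blight_confusion <- function(object, ...) {
  df <- tibble::tibble(
    predicted = factor(c("blight", "blight", "non-blight", "non-blight"),
                       levels = c("non-blight", "blight")),
    actual = factor(c("blight", "non-blight", "blight", "non-blight"),
                    levels = c("blight", "non-blight")),
    count = c(object$tp, object$fp, object$fn, object$tn)
  )
  ggplot(df, aes(x = .data$actual, y = .data$predicted, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = format(.data$count, big.mark = ","))) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = "Predicted vs actual blight labels") +
    theme_minimal()
}

#' Score separation between classes
#'
#' Distribution of the unique lexicon-token count by true label — the
#' visual counterpart of the classifier's discriminating power.
#'
#' @param calls Scored, labelled call tibble.
#' @return A ggplot.
#' @export
plot_score_separation <- function(calls) {
  assert_columns(calls, c("unique_token_count", "blight_label"),
                 "plot_score_separation")
  df <- calls[!is.na(calls$blight_label), ]
  df$label <- factor(ifelse(df$blight_label == 1, "blight", "non-blight"))
  ggplot(df, aes(x = .data$unique_token_count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35") +
    facet_wrap(~label, ncol = 1, scales = "free_y") +
    labs(x = "unique lexicon-token count", y = "calls",
         title = "Lexicon score by true class") +
    theme_minimal()
}

#' Dot-and-interval plot of the vacancy correlation battery
#'
#' Pearson r per (vacancy type, duration) with approximate 95% Fisher-z
#' intervals.
#'
#' @param battery Output of [vacancy_battery()].
#' @return A ggplot.
#' @export
plot_vacancy_correlations <- function(battery) {
  df <- battery[!battery$degenerate, ]
  zse <- 1 / sqrt(df$n - 3)
  z <- atanh(df$r)
  df$lo <- tanh(z - 1.96 * zse)
  df$hi <- tanh(z + 1.96 * zse)
  df$measure <- paste(df$vacancy_type, df$duration)
  ggplot(df, aes(x = .data$r, y = .data$measure)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$lo, xmax = .data$hi), width = 0.2) +
    geom_hline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~pairing) +
    labs(x = "Pearson r vs tract blight", y = NULL,
         title = "Convergent validity against vacancy measures") +
    theme_minimal()
}
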