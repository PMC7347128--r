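#' Model specifications for the three blight classifiers
#'
#' Three fixed, named logistic-regression specifications on the binary
#' blight outcome:
#' * model 1 — unique lexicon-token count only;
#' * model 2 — count + borough (5 levels, Bronx reference);
#' * model 3 — count + borough + responsible agency (15 levels,
#'   "unassigned" reference).
#'
#' @param model_id 1, 2 or 3.
#' @return A `blight_model_spec` list with `model_id`, `covariates`, and the
#'   categorical `levels` (reference level first, remaining levels
#'   alphabetical — that order fixes the design-matrix columns).
#' @export
model_spec <- function(model_id) {
  if (!model_id %in% 1:3) {
    stop_config("model_spec: model_id must be 1, 2 or 3")
  }
  covariates <- list(
    "unique_token_count",
    c("unique_token_count", "borough"),
    c("unique_token_count", "borough", "agency")
  )[[model_id]]
  levels <- list(
    borough = c("Bronx", sort(setdiff(BOROUGHS, "Bronx"))),
    agency = c("unassigned", sort(setdiff(AGENCIES, "unassigned")))
  )
  structure(
    list(
      model_id = as.integer(model_id),
      covariates = covariates,
      levels = levels[intersect(c("borough", "agency"), covariates)]
    ),
    class = "blight_model_spec"
  )
}

#' Split calls into fit and holdout sets
#'
#' Simple random sampling without replacement: `round(fraction * n)` records
#' form the fit set, the remainder the holdout. Disjoint and exhaustive, and
#' reproducible under a fixed seed.
#'
#' @param calls A call tibble.
#' @param fraction Sampling fraction in (0, 1]; 1 leaves an empty holdout.
#' @param seed Integer seed.
#' @return List with tibbles `fit` and `holdout`.
#' @export
split_calls <- function(calls, fraction = 0.5, seed = 1L) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    stop_config("split_calls: fraction must be in (0, 1]")
  }
  if (nrow(calls) == 0L) stop_data("split_calls: no records")
  n_fit <- round(fraction * nrow(calls))
  idx <- withr::with_seed(derive_seed(seed, "split"),
                          sample.int(nrow(calls), n_fit))
  list(fit = calls[sort(idx), ], holdout = calls[setdiff(seq_len(nrow(calls)), idx), ])
}

#' Build the design matrix and response for a model specification
#'
#' Intercept column of ones, the token count, then one 0/1 indicator column
#' per non-reference level of each categorical covariate in the spec, in
#' alphabetical order within covariate. Reference levels (Bronx;
#' "unassigned") are absorbed into the intercept: a Bronx record has all
#' four borough indicators 0. Categorical values outside the configured
#' vocabulary are an error naming the offending level — they would
#' otherwise be silently coded as the reference.
#'
#' @param calls Scored call tibble; needs `unique_token_count` and, for
#'   models 2–3, `borough` / `agency`.
#' @param spec A [model_spec()].
#' @param response Name of the 0/1 response column, or `NULL` to build a
#'   prediction-time design with no response (default `"blight_label"`).
#' @return List with `x` (numeric matrix, first column `(Intercept)`) and
#'   `y` (integer vector or `NULL`).
#' @export
build_design <- function(calls, spec, response = "blight_label") {
  needed <- spec$covariates
  assert_columns(calls, needed, "build_design")
  n <- nrow(calls)
  cols <- list(`(Intercept)` = rep(1, n))
  if ("unique_token_count" %in% needed) {
    cols$unique_token_count <- as.numeric(calls$unique_token_count)
  }
  for (cov in intersect(c("borough", "agency"), needed)) {
    levs <- spec$levels[[cov]]
    vals <- as.character(calls[[cov]])
    unseen <- setdiff(unique(vals), levs)
    if (length(unseen) > 0L) {
      stop_data(sprintf(
        "build_design: %s level(s) not in the configured vocabulary: %s",
        cov, paste(unseen, collapse = ", ")
      ))
    }
    for (lev in levs[-1]) {
      cols[[paste0(cov, ":", lev)]] <- as.numeric(vals == lev)
    }
  }
  x <- do.call(cbind, cols)
  y <- NULL
  if (!is.null(response)) {
    assert_columns(calls, response, "build_design")
    y <- calls[[response]]
    if (anyNA(y) || !all(y %in% c(0L, 1L))) {
      stop_data("build_design: response must be 0/1 with no missing values")
    }
    y <- as.integer(y)
  }
  list(x = x, y = y)
}

#' Fit a logistic regression by maximum likelihood
#'
#' Bernoulli-logit GLM fit by iteratively reweighted least squares
#' (`stats::glm.fit`), with Wald standard errors from the inverse observed
#' information. Convergence tolerance 1e-8 on the deviance change, at most
#' 100 iterations; non-convergence is an error carrying the convergence
#' report. Quasi-complete separation — a covariate pattern that perfectly
#' predicts the outcome, which inflates coefficients and standard errors
#' without breaking IRLS — is flagged (warning + `separation` field) when
#' any |coefficient| exceeds `separation_bound` or any standard error
#' exceeds 10 times the bound. An optional ridge penalty `ridge` (off by
#' default) stabilizes separated fits at the cost of bias.
#'
#' @param x Design matrix (first column the intercept; see
#'   [build_design()]).
#' @param y 0/1 response vector, `length(y) == nrow(x)`; `nrow(x)` must
#'   exceed `ncol(x)`.
#' @param separation_bound Absolute-coefficient bound for the separation
#'   flag (default 15).
#' @param ridge Non-negative L2 penalty on non-intercept coefficients
#'   (default 0 = plain ML).
#' @param spec Optional [model_spec()] stored for prediction.
#' @return A `blight_model` object: coefficients, standard errors,
#'   `vcov`, `n_fit`, `convergence` (iterations, converged, deviance),
#'   `separation` (flag + offending terms), `spec`.
#' @export
fit_logistic <- function(x, y, separation_bound = 15, ridge = 0, spec = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop_data("fit_logistic: x and y sizes differ")
  if (!all(y %in% c(0L, 1L))) stop_data("fit_logistic: response must be 0/1")
  if (nrow(x) <= ncol(x)) {
    stop_data("fit_logistic: need more observations than parameters")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  if (ridge > 0) {
    # ridge via data augmentation: sqrt(2*ridge) pseudo-observations at y=1/2
    p <- ncol(x)
    aug <- diag(sqrt(2 * ridge), p)
    aug[, 1] <- 0 # intercept unpenalized
    colnames(aug) <- colnames(x)
    fit <- suppressWarnings(glm.fit(
      rbind(x, aug), c(y, rep(0.5, p)),
      family = binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    ))
  } else {
    fit <- suppressWarnings(glm.fit(
      x, y,
      family = binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    ))
  }
  if (!fit$converged) {
    stop_numeric(
      sprintf("fit_logistic: IRLS did not converge in %d iterations (deviance %.6g)",
              fit$iter, fit$deviance),
      convergence = list(iterations = fit$iter, deviance = fit$deviance)
    )
  }
  coefs <- fit$coefficients
  qr_r <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  covmat <- chol2inv(qr_r)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  vcov <- matrix(NA_real_, ncol(x), ncol(x),
                 dimnames = list(colnames(x), colnames(x)))
  vcov[piv, piv] <- covmat
  se <- sqrt(diag(vcov))
  separated_terms <- names(coefs)[
    (!is.na(coefs) & abs(coefs) > separation_bound) |
      (!is.na(se) & se > 10 * separation_bound)
  ]
  if (length(separated_terms) > 0L) {
    warn(sprintf(
      "fit_logistic: possible quasi-complete separation (terms: %s)",
      paste(separated_terms, collapse = ", ")
    ), class = "blight311_separation_warning")
  }
  structure(
    list(
      coefficients = coefs,
      std_errors = se,
      vcov = vcov,
      n_fit = nrow(x),
      fitted = fit$fitted.values[seq_len(nrow(x))],
      convergence = list(
        iterations = fit$iter,
        converged = fit$converged,
        deviance = fit$deviance,
        null_deviance = fit$null.deviance
      ),
      separation = list(
        flagged = length(separated_terms) > 0L,
        terms = separated_terms,
        bound = separation_bound
      ),
      ridge = ridge,
      spec = spec
    ),
    class = "blight_model"
  )
}

#' Fit one of the three blight models to scored, labelled calls
#'
#' Convenience wrapper: builds the [model_spec()] design from the calls and
#' runs [fit_logistic()].
#'
#' @param calls Scored, labelled call tibble.
#' @param model_id 1, 2 or 3.
#' @inheritParams fit_logistic
#' @return A `blight_model`.
#' @export
fit_blight_model <- function(calls, model_id = 1, separation_bound = 15, ridge = 0) {
  spec <- model_spec(model_id)
  d <- build_design(calls, spec)
  fit_logistic(d$x, d$y, separation_bound = separation_bound,
               ridge = ridge, spec = spec)
}

#' @export
print.blight_model <- function(x, ...) {
  id <- if (!is.null(x$spec)) x$spec$model_id else NA
  cat(sprintf("<blight_model%s> n = %d, %d coefficient(s)%s\n",
              if (is.na(id)) "" else paste0(" ", id), x$n_fit,
              length(x$coefficients),
              if (x$separation$flagged) " [separation flagged]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict blight probability for new calls
#'
#' Inverse-logit of the linear predictor under the fitted model's own
#' design coding; unseen categorical levels are an error.
#'
#' @param model A `blight_model` fitted via [fit_blight_model()] (it must
#'   carry a spec), or pass a bare design matrix as `calls` for a model fit
#'   via [fit_logistic()] directly.
#' @param calls Scored call tibble (or design matrix).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, calls) {
  stopifnot(inherits(model, "blight_model"))
  if (is.matrix(calls)) {
    x <- calls
    missing <- setdiff(names(model$coefficients), colnames(x))
    if (length(missing) > 0L) {
      stop_data(sprintf("predict_proba: design lacks column(s): %s",
                        paste(missing, collapse = ", ")))
    }
    x <- x[, names(model$coefficients), drop = FALSE]
  } else {
    if (is.null(model$spec)) {
      stop_config("predict_proba: model has no stored spec; pass a design matrix")
    }
    x <- build_design(calls, model$spec, response = NULL)$x
  }
  beta <- model$coefficients
  beta[is.na(beta)] <- 0 # rank-deficient columns contribute nothing
  as.numeric(plogis(drop(x %*% beta)))
}

#' Threshold probabilities into binary blight labels
#'
#' @param probability Numeric vector in \[0, 1\].
#' @param threshold Cutoff in \[0, 1\]; a probability *equal* to the
#'   threshold classifies as blight. Default 0.5 — with the roughly 80/20
#'   blight/non-blight class balance typical of labelled 311 corpora, the
#'   cutoff materially shifts specificity, so it is exposed everywhere.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(probability, threshold = 0.5) {
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    stop_config("classify: threshold must be in [0, 1]")
  }
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    stop_data("classify: probabilities must be in [0, 1]")
  }
  as.integer(probability >= threshold)
}

#' Tidy a fitted blight model
#'
#' @param x A `blight_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (Wald z), `p.value`.
#' @method tidy blight_model
#' @export
tidy.blight_model <- function(x, ...) {
  z <- x$coefficients / x$std_errors
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' Model-level summary of a fitted blight model
#'
#' @param x A `blight_model`.
#' @param ... Unused.
#' @return One-row tibble: `model_id`, `n_fit`, `n_terms`, `deviance`,
#'   `null.deviance`, `iterations`, `converged`, `separation_flagged`.
#' @method glance blight_model
#' @export
glance.blight_model <- function(x, ...) {
  tibble::tibble(
    model_id = if (!is.null(x$spec)) x$spec$model_id else NA_integer_,
    n_fit = x$n_fit,
    n_terms = length(x$coefficients),
    deviance = x$convergence$deviance,
    null.deviance = x$convergence$null_deviance,
    iterations = x$convergence$iterations,
    converged = x$convergence$converged,
    separation_flagged = x$separation$flagged
  )
}

#' Serialize a fitted model to JSON and back
#'
#' Stores coefficients, standard errors, the categorical coding, the
#' classification threshold and the seed so a scored export can be
#' re-classified without refitting.
#'
#' @param model A `blight_model`.
#' @param path JSON path.
#' @param threshold,seed Provenance recorded alongside the fit.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `blight_model`.
#' @export
write_model <- function(model, path, threshold = 0.5, seed = NA_integer_) {
  payload <- list(
    model_id = if (!is.null(model$spec)) model$spec$model_id else NA_integer_,
    coefficients = as.list(model$coefficients),
    std_errors = as.list(model$std_errors),
    levels = if (!is.null(model$spec)) model$spec$levels else NULL,
    n_fit = model$n_fit,
    convergence = model$convergence,
    separation = model$separation,
    threshold = threshold,
    seed = seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- if (!is.na(p$model_id)) model_spec(p$model_id) else NULL
  structure(
    list(
      coefficients = unlist(p$coefficients),
      std_errors = unlist(p$std_errors),
      vcov = NULL,
      n_fit = p$n_fit,
      fitted = NULL,
      convergence = p$convergence,
      separation = p$separation,
      ridge = 0,
      spec = spec,
      threshold = p$threshold,
      seed = p$seed
    ),
    class = "blight_model"
  )
}
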