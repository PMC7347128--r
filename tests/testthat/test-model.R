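test_that("split_calls is disjoint, exhaustive, and reproducible", {
  calls <- tibble::tibble(record_id = sprintf("r%02d", 1:10))
  s <- split_calls(calls, 0.5, seed = 99)
  expect_equal(nrow(s$fit), 5L)
  expect_equal(nrow(s$holdout), 5L)
  expect_length(intersect(s$fit$record_id, s$holdout$record_id), 0L)
  expect_setequal(c(s$fit$record_id, s$holdout$record_id), calls$record_id)
  again <- split_calls(calls, 0.5, seed = 99)
  expect_identical(again$fit$record_id, s$fit$record_id)
  expect_false(identical(split_calls(calls, 0.5, seed = 100)$fit$record_id,
                         s$fit$record_id))
  expect_equal(nrow(split_calls(calls, 1)$holdout), 0L)
  expect_error(split_calls(calls, 0), class = "blight311_config_error")
  expect_error(split_calls(calls, 1.2), class = "blight311_config_error")
})

test_that("build_design dummy-codes categoricals against the stated reference levels", {
  spec <- model_spec(3)
  calls <- tibble::tibble(
    unique_token_count = c(3L, 0L, 7L),
    borough = c("Bronx", "Staten Island", "Queens"),
    agency = c("unassigned", "Police", "Sanitation"),
    blight_label = c(1L, 0L, 1L)
  )
  d <- build_design(calls, spec)
  expect_equal(unname(d$x[, "(Intercept)"]), rep(1, 3))
  borough_cols <- grep("^borough:", colnames(d$x), value = TRUE)
  agency_cols <- grep("^agency:", colnames(d$x), value = TRUE)
  expect_length(borough_cols, 4L)
  expect_length(agency_cols, 14L)
  # alphabetical within covariate, reference absent
  expect_equal(borough_cols, paste0("borough:", sort(setdiff(
    blight_vocabularies()$boroughs, "Bronx"))))
  expect_false("agency:unassigned" %in% agency_cols)
  # Bronx / unassigned rows have all indicators zero
  expect_equal(sum(d$x[1, borough_cols]), 0)
  expect_equal(sum(d$x[1, agency_cols]), 0)
  expect_equal(unname(d$x[2, "borough:Staten Island"]), 1)
  expect_equal(sum(d$x[2, borough_cols]), 1)
  expect_equal(unname(d$x[3, "agency:Sanitation"]), 1)
  expect_equal(d$y, c(1L, 0L, 1L))

  bad <- dplyr::mutate(calls, borough = c("Bronx", "Yonkers", "Queens"))
  expect_error(build_design(bad, spec), "Yonkers", class = "blight311_data_error")
})

test_that("fit_logistic matches closed-form solutions on saturated problems", {
  # intercept-only on balanced labels: beta0 = 0 by symmetry
  x <- matrix(1, 40, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(0L, 1L), 20)
  fit0 <- fit_logistic(x, y)
  expect_equal(unname(fit0$coefficients), 0, tolerance = 1e-8)

  # 2x2 table: x=1 -> 30 events / 10 non-events; x=0 -> 10 / 30
  xv <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  yv <- rep(c(1L, 0L, 1L, 0L), c(30, 10, 10, 30))
  fit <- fit_logistic(cbind("(Intercept)" = 1, x = xv), yv)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(1 / 3), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x"]), log(9), tolerance = 1e-6)
})

test_that("fit_logistic agrees with a brute-force likelihood grid at small n", {
  withr::with_seed(17, {
    for (i in 1:3) {
      n <- sample(40:100, 1)
      x <- rpois(n, 4)
      y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
      fit <- fit_logistic(cbind("(Intercept)" = 1, count = x), y)
      b <- unname(fit$coefficients)
      grid <- grid_logistic_mle(x, y, b[1] + c(-0.5, 0.5), b[2] + c(-0.5, 0.5))
      expect_equal(b[1], grid[1], tolerance = 0.01)
      expect_equal(b[2], grid[2], tolerance = 0.01)
    }
  })
})

test_that("fitted probabilities satisfy the intercept score equation", {
  calls <- scored_frame(300, seed = 12)
  fit <- fit_blight_model(calls, 2)
  expect_equal(sum(fit$fitted), sum(calls$blight_label), tolerance = 1e-6)
})

test_that("fit_logistic matches the standard GLM interface on the same design", {
  calls <- scored_frame(400, seed = 31)
  mine <- fit_blight_model(calls, 2)
  ref <- stats::glm(
    blight_label ~ unique_token_count + factor(borough, levels = model_spec(2)$levels$borough),
    family = binomial(), data = calls
  )
  expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(mine$std_errors),
               unname(summary(ref)$coefficients[, "Std. Error"]), tolerance = 1e-6)
})

test_that("quasi-complete separation is flagged, and the optional ridge tames it", {
  x <- cbind("(Intercept)" = 1, z = rep(c(0, 1), each = 25))
  y <- rep(c(0L, 1L), each = 25) # z perfectly predicts y
  expect_warning(fit <- fit_logistic(x, y),
                 class = "blight311_separation_warning")
  expect_true(fit$separation$flagged)
  expect_true("z" %in% fit$separation$terms)
  ridge <- fit_logistic(x, y, ridge = 1)
  expect_false(ridge$separation$flagged)
  expect_lt(abs(ridge$coefficients["z"]), 15)
})

test_that("predict_proba is the inverse logit of the linear predictor", {
  model <- structure(
    list(coefficients = c("(Intercept)" = -1.27, unique_token_count = 0.37),
         std_errors = c(0.009, 0.002), spec = model_spec(1),
         separation = list(flagged = FALSE)),
    class = "blight_model"
  )
  calls <- tibble::tibble(unique_token_count = c(0L, 7L))
  p <- predict_proba(model, calls)
  expect_equal(p[1], plogis(-1.27), tolerance = 1e-12)
  expect_equal(round(p[1], 3), 0.219)
  expect_equal(p[2], plogis(-1.27 + 0.37 * 7), tolerance = 1e-12)
  expect_equal(round(p[2], 3), 0.789)
  # zero linear predictor -> 0.5
  m0 <- structure(
    list(coefficients = c("(Intercept)" = 0, unique_token_count = 0),
         spec = model_spec(1)),
    class = "blight_model"
  )
  expect_equal(predict_proba(m0, calls), c(0.5, 0.5))
  # strictly increasing in the count when the slope is positive
  many <- tibble::tibble(unique_token_count = 0:22)
  expect_true(all(diff(predict_proba(model, many)) > 0))
})

test_that("classify applies the >= threshold convention and validates inputs", {
  expect_equal(classify(c(0.6, 0.5, 0.4), 0.5), c(1L, 1L, 0L))
  expect_error(classify(0.5, 1.5), class = "blight311_config_error")
  expect_error(classify(1.4, 0.5), class = "blight311_data_error")
})

test_that("tidy and glance summarize a fitted model in broom shapes", {
  calls <- scored_frame(250, seed = 8)
  fit <- fit_blight_model(calls, 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 6L)
  gl <- glance(fit)
  expect_equal(gl$model_id, 2L)
  expect_equal(gl$n_fit, 250L)
  expect_true(gl$converged)
})

test_that("model JSON serialization round-trips and predicts identically", {
  calls <- scored_frame(200, seed = 4)
  fit <- fit_blight_model(calls, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path, threshold = 0.4, seed = 7L)
  back <- read_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$std_errors, fit$std_errors)
  expect_equal(back$threshold, 0.4)
  expect_equal(predict_proba(back, calls), predict_proba(fit, calls))
})
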