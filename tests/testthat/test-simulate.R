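test_that("the corpus generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_records = 300, n_blight_tokens = 40, n_nonblight_tokens = 40,
                    n_shared_tokens = 10, seed = 5)
  a <- simulate_calls(cfg)
  b <- simulate_calls(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$mapping, b$mapping)
  c2 <- simulate_calls(sim_config(n_records = 300, n_blight_tokens = 40,
                                  n_nonblight_tokens = 40, n_shared_tokens = 10,
                                  seed = 6))
  expect_false(identical(a$calls$descriptor, c2$calls$descriptor))
})

test_that("the latent token count follows the configured truncated distribution", {
  cfg <- sim_config(n_records = 4000, seed = 2, compose_text = FALSE)
  k <- simulate_calls(cfg)$calls$latent_token_count
  expect_true(all(k >= 0 & k <= 22))
  expect_equal(mean(k), 7, tolerance = 0.05)
  expect_equal(sd(k), 4.4, tolerance = 0.1)
})

test_that("labels are independent of the token count when the count coefficient is zero", {
  sig <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_records = 800, beta_count = 0,
                      beta_borough = setNames(rep(0, 4), names(sim_config()$beta_borough)),
                      compose_text = FALSE, seed = 100 + s)
    calls <- simulate_calls(cfg)$calls
    p <- suppressWarnings(stats::chisq.test(
      table(calls$latent_token_count > stats::median(calls$latent_token_count),
            calls$true_blight)
    ))$p.value
    if (p < 0.01) sig <- sig + 1L
  }
  # ~19/20 expected non-significant at the 1% level
  expect_lte(sig, 3L)
})

test_that("empirical blight rates track the generating inverse-logit curve", {
  cfg <- sim_config(n_records = 6000, compose_text = FALSE,
                    beta_borough = setNames(rep(0, 4), names(sim_config()$beta_borough)),
                    seed = 9)
  calls <- simulate_calls(cfg)$calls
  by_k <- calls |>
    dplyr::group_by(latent_token_count) |>
    dplyr::summarise(n = dplyr::n(), rate = mean(true_blight), .groups = "drop") |>
    dplyr::filter(n >= 50)
  expected <- plogis(cfg$beta0 + cfg$beta_count * by_k$latent_token_count)
  band <- 3 * sqrt(expected * (1 - expected) / by_k$n)
  expect_true(all(abs(by_k$rate - expected) <= pmax(band, 0.02)))
})

test_that("class vocabularies never leak across classes at full exclusivity", {
  for (s in 1:3) {
    cfg <- sim_config(n_records = 400, n_blight_tokens = 25, n_nonblight_tokens = 25,
                      n_shared_tokens = 0, exclusivity = 1, seed = 40 + s)
    sim <- simulate_calls(cfg)
    tokened <- tokenize_calls(sim$calls)
    blight_toks <- unique(unlist(tokened$tokens[sim$calls$true_blight == 1]))
    non_toks <- unique(unlist(tokened$tokens[sim$calls$true_blight == 0]))
    expect_length(intersect(blight_toks, sim$vocabulary$nonblight), 0L)
    expect_length(intersect(non_toks, sim$vocabulary$blight), 0L)
  }
})

test_that("with a fully leaky vocabulary the realized lexicon score equals the latent count", {
  cfg <- sim_config(n_records = 500, n_blight_tokens = 60, n_nonblight_tokens = 40,
                    n_shared_tokens = 10, exclusivity = 0, leak_rate = 1, seed = 13)
  sim <- simulate_calls(cfg)
  scored <- score_calls(tokenize_calls(sim$calls), sim$vocabulary$blight)
  expect_equal(scored$unique_token_count, sim$calls$latent_token_count)
})

test_that("an end-to-end refit on scored records recovers the generating coefficients", {
  cfg <- sim_config(n_records = 5000, n_blight_tokens = 60, n_nonblight_tokens = 40,
                    n_shared_tokens = 10, exclusivity = 0, leak_rate = 1, seed = 101)
  sim <- simulate_calls(cfg)
  scored <- score_calls(tokenize_calls(sim$calls), sim$vocabulary$blight)
  scored$blight_label <- sim$calls$true_blight
  fit <- fit_blight_model(scored, 2)
  truth <- c(cfg$beta0, cfg$beta_count, cfg$beta_borough)
  est <- fit$coefficients
  expect_true(all(abs(est - truth) <= 3 * fit$std_errors))
})

test_that("simulate_tracts tiles the plane with uniquely labelled unit squares", {
  tracts <- simulate_tracts(4)
  ids <- vapply(tracts$features, `[[`, "", "tract_id")
  expect_equal(length(unique(ids)), 4L)
  shoelace <- function(m) {
    j <- c(2:nrow(m), 1)
    abs(sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2])) / 2
  }
  areas <- vapply(tracts$features, function(f) shoelace(f$rings[[1]]), 0)
  expect_equal(areas, rep(1, 4))
  expect_equal(sum(areas), 4)
  # every generated point falls in exactly one tract
  withr::with_seed(3, {
    pts <- tibble::tibble(longitude = runif(50, 0, 2), latitude = runif(50, 0, 2),
                          locatable = TRUE)
  })
  hits <- vapply(seq_len(50), function(i) {
    sum(vapply(tracts$features,
               function(f) blight311:::point_in_rings(pts$longitude[i], pts$latitude[i], f$rings),
               logical(1)))
  }, integer(1))
  expect_true(all(hits >= 1L)) # boundary points may touch two squares
  interior <- pts$longitude %% 1 > 1e-9 & pts$latitude %% 1 > 1e-9
  expect_true(all(hits[interior] == 1L))
})

test_that("simulate_vacancy hits exact, null, and intermediate correlation targets", {
  withr::with_seed(55, {
    summaries <- tibble::tibble(tract_id = sprintf("T%04d", 1:900),
                                pct_blight = runif(900, 10, 90))
  })
  vac <- simulate_vacancy(
    summaries,
    targets = c("commercial.long" = 1, "residential.long" = 0.5),
    location = 50, scale = 5, seed = 3
  )
  expect_equal(nrow(vac), 900 * 9)
  r_of <- function(type, dur) {
    v <- vac[vac$vacancy_type == type & vac$duration == dur, ]
    correlate(v$value, summaries$pct_blight)$r
  }
  expect_equal(r_of("commercial", "long"), 1, tolerance = 1e-12)
  expect_equal(r_of("residential", "long"), 0.5, tolerance = 0.1)
  # untargeted combinations default to independence; 95% band at n = 900
  expect_lt(abs(r_of("total", "short")), 0.07)
})

test_that("synthetic calls survive the CSV and HUD writers and their readers", {
  cfg <- sim_config(n_records = 120, n_blight_tokens = 20, n_nonblight_tokens = 20,
                    n_shared_tokens = 5, n_tracts = 4, seed = 77)
  sim <- simulate_calls(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_calls_csv(sim$calls, csv)
  back <- read_calls(csv)
  expect_equal(nrow(back), 120L)
  expect_equal(back$record_id, sim$calls$record_id)
  expect_equal(back$descriptor, sim$calls$descriptor)
  expect_equal(back$created_date, sim$calls$created_date)
  expect_equal(back$latitude, sim$calls$latitude, tolerance = 1e-12)

  summaries <- tibble::tibble(tract_id = c("A", "B", "C"),
                              pct_blight = c(10, 50, 90))
  hud <- withr::local_tempfile(fileext = ".csv")
  write_hud_csv(simulate_vacancy(summaries, seed = 1), hud)
  vac_back <- read_vacancy(hud, "HUD_USPS")
  expect_equal(nrow(vac_back), 27L)
})
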