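# Fixture builders shared across test files. Everything is generated in
# code; CSV/GeoJSON fixtures are written to tempfiles at test time.

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Five hand-written Socrata-dialect rows used as the hand-parse oracle.
socrata_fixture_lines <- function() {
  c(
    "Unique Key,Created Date,Complaint Type,Descriptor,Agency,Borough,Latitude,Longitude",
    "10000001,01/15/2018 08:30:00 AM,Rodent,rat sighting in alley,Health and Mental Hygiene,Bronx,40.8448,-73.8648",
    "10000002,02/01/2018 01:05:10 PM,Noise,loud music at night,Police,Brooklyn,40.6782,-73.9442",
    "10000003,03/20/2018 11:59:59 PM,Graffiti,grafiti on wall,Sanitation,Manhattan,40.7831,-73.9712",
    "10000004,2018-04-02,Rodent,mouse droppings,Health and Mental Hygiene,Queens,40.7282,-73.7949",
    "10000005,05/30/2018 06:00:00 AM,Street Condition,broken sidewalk slab,Transportation,Staten Island,40.5795,-74.1502"
  )
}

# Minimal labelled, tokenized calls for lexicon/model tests.
tiny_labelled_calls <- function() {
  tibble::tibble(
    tokens = list(
      c("rat", "trash", "odor"),
      c("rat", "odor"),
      c("noise", "trash"),
      c("noise", "party")
    ),
    blight_label = c(1L, 1L, 0L, 0L)
  )
}

# Deterministic scored/labelled frame with borough/agency columns for
# design-matrix and fit tests.
scored_frame <- function(n = 200, seed = 42) {
  withr::with_seed(seed, {
    count <- rpois(n, 5)
    borough <- sample(blight_vocabularies()$boroughs, n, TRUE)
    agency <- sample(blight_vocabularies()$agencies, n, TRUE)
    p <- plogis(-1 + 0.4 * count)
    tibble::tibble(
      unique_token_count = count,
      borough = borough,
      agency = agency,
      blight_label = rbinom(n, 1, p)
    )
  })
}

# Brute-force log-likelihood grid search: the independent oracle for
# logistic fits with at most 2 free parameters.
grid_logistic_mle <- function(x, y, b0_range, b1_range, step = 0.005) {
  b0s <- seq(b0_range[1], b0_range[2], by = step)
  b1s <- seq(b1_range[1], b1_range[2], by = step)
  best <- c(NA, NA)
  best_ll <- -Inf
  for (b0 in b0s) {
    lp0 <- b0 + outer(x, b1s)
    ll <- colSums(y * lp0 - log1p(exp(lp0)))
    i <- which.max(ll)
    if (ll[i] > best_ll) {
      best_ll <- ll[i]
      best <- c(b0, b1s[i])
    }
  }
  best
}

# End-to-end runs on a synthetic corpus written through the real file
# dialects (Socrata CSV, GeoJSON, HUD CSV).
pipeline_inputs <- function(dir, n_records = 400, seed = 19) {
  # leaky vocabulary: blight terms reach non-blight records often enough
  # that scoring needs the shared-token skew rule, which keeps the training
  # fit away from quasi-complete separation
  cfg <- sim_config(n_records = n_records, n_blight_tokens = 40,
                    n_nonblight_tokens = 40, n_shared_tokens = 10,
                    exclusivity = 0.7, n_tracts = 9, seed = seed)
  sim <- simulate_calls(cfg)
  paths <- list(
    calls = file.path(dir, "calls.csv"),
    mapping = file.path(dir, "mapping.csv"),
    tracts = file.path(dir, "tracts.geojson"),
    vacancy = file.path(dir, "vacancy.csv")
  )
  write_calls_csv(sim$calls, paths$calls)
  readr::write_csv(sim$mapping, paths$mapping)
  write_tracts_geojson(sim$tracts, paths$tracts)
  truth <- sim$calls |>
    dplyr::group_by(tract_id = true_tract_id) |>
    dplyr::summarise(pct_blight = 100 * mean(true_blight), .groups = "drop")
  write_hud_csv(simulate_vacancy(truth, seed = seed), paths$vacancy)
  c(paths, list(sim = sim))
}

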