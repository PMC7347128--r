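#' Configuration for the synthetic 311 corpus generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' two-class short-text records whose vocabularies have controllable class
#' exclusivity, borough/agency categorical effects, a generative logistic
#' link with known coefficients, point coordinates inside toy tract
#' polygons, and vacancy tables with a specified correlation to tract
#' blight. Defaults echo a six-month city-scale labelled corpus: a
#' 516/415/182 blight-exclusive/non-blight-exclusive/shared vocabulary, a
#' truncated negative-binomial token count (mean 7, SD 4.4, max 22), and
#' logistic truth (intercept -1.27, count slope 0.37) with borough effects
#' (Bronx reference) of Brooklyn -0.58, Manhattan -0.38, Queens -0.76,
#' Staten Island -0.21. Agency effects default to zero: a separation-free
#' baseline (real-data agency terms can be separation artifacts with no
#' usable truth value).
#'
#' @param n_records Number of records to generate.
#' @param n_blight_tokens,n_nonblight_tokens,n_shared_tokens Sizes of the
#'   three generating vocabularies (disjoint by construction).
#' @param token_count_mean,token_count_sd,token_count_max Latent blight-
#'   token count distribution: negative binomial with this mean/SD,
#'   rejection-truncated at the max.
#' @param beta0,beta_count True intercept and token-count coefficient.
#' @param beta_borough Named vector of true borough effects (non-Bronx
#'   levels).
#' @param beta_agency Named vector of true agency effects (non-"unassigned"
#'   levels); zeros by default.
#' @param borough_probs,agency_probs Category probabilities (must sum
#'   to 1).
#' @param exclusivity In \[0, 1\]: the fraction of the blight vocabulary
#'   that is strictly class-exclusive (never drawn for a non-blight
#'   record). The remaining tokens form a leaky pool that non-blight
#'   records may draw from, so they are realized as shared at corpus
#'   scale. At 1 (default) the realized vocabularies are exactly
#'   class-exclusive and the lexicon partition recovers the generating
#'   sets; at 0 with `leak_rate = 1` every record's realized lexicon score
#'   equals its latent count, so a refit on scored records recovers the
#'   generating coefficients end to end.
#' @param leak_rate Per-slot probability that a non-blight record draws a
#'   scored token from the leaky blight pool instead of its own
#'   vocabulary (default 0.1; irrelevant at `exclusivity = 1`).
#' @param shared_rate,stopword_rate Poisson means for shared-vocabulary and
#'   stopword filler tokens per record.
#' @param n_tracts Number of unit-square tracts records are scattered over.
#' @param compose_text Compose descriptor text (default `TRUE`). Turn off
#'   for replicate studies that only exercise the generative logistic layer
#'   (covariates, latent count, label) — text composition dominates the
#'   generator's run time and is irrelevant there.
#' @param seed Integer master seed; every sub-generator derives its own
#'   stream from it.
#' @return A `blight_sim_config` list.
#' @export
sim_config <- function(n_records = 5000,
                       n_blight_tokens = 516,
                       n_nonblight_tokens = 415,
                       n_shared_tokens = 182,
                       token_count_mean = 7,
                       token_count_sd = 4.4,
                       token_count_max = 22,
                       beta0 = -1.27,
                       beta_count = 0.37,
                       beta_borough = c(
                         "Brooklyn" = -0.58, "Manhattan" = -0.38,
                         "Queens" = -0.76, "Staten Island" = -0.21
                       ),
                       beta_agency = setNames(
                         rep(0, length(AGENCIES) - 1L),
                         setdiff(AGENCIES, "unassigned")
                       ),
                       borough_probs = c(
                         "Bronx" = 0.17, "Brooklyn" = 0.31, "Manhattan" = 0.19,
                         "Queens" = 0.27, "Staten Island" = 0.06
                       ),
                       agency_probs = NULL,
                       exclusivity = 1,
                       leak_rate = 0.1,
                       shared_rate = 2,
                       stopword_rate = 2,
                       n_tracts = 25,
                       compose_text = TRUE,
                       seed = 1L) {
  if (n_records < 1) stop_config("sim_config: n_records must be positive")
  if (n_blight_tokens < 1 || n_nonblight_tokens < 1) {
    stop_config("sim_config: class vocabularies must be non-empty")
  }
  if (n_shared_tokens < 0) stop_config("sim_config: n_shared_tokens must be >= 0")
  if (n_shared_tokens == 0 && shared_rate > 0) shared_rate <- 0
  if (exclusivity < 0 || exclusivity > 1) {
    stop_config("sim_config: exclusivity must be in [0, 1]")
  }
  if (leak_rate < 0 || leak_rate > 1) {
    stop_config("sim_config: leak_rate must be in [0, 1]")
  }
  if (token_count_sd^2 <= token_count_mean) {
    stop_config("sim_config: token count SD^2 must exceed the mean (negative binomial)")
  }
  if (is.null(agency_probs)) {
    agency_probs <- setNames(rep(1 / length(AGENCIES), length(AGENCIES)), AGENCIES)
  }
  for (p in list(borough_probs, agency_probs)) {
    if (abs(sum(p) - 1) > 1e-8) stop_config("sim_config: category probabilities must sum to 1")
  }
  structure(
    list(
      n_records = as.integer(n_records),
      n_blight_tokens = as.integer(n_blight_tokens),
      n_nonblight_tokens = as.integer(n_nonblight_tokens),
      n_shared_tokens = as.integer(n_shared_tokens),
      token_count_mean = token_count_mean,
      token_count_sd = token_count_sd,
      token_count_max = token_count_max,
      beta0 = beta0, beta_count = beta_count,
      beta_borough = beta_borough, beta_agency = beta_agency,
      borough_probs = borough_probs, agency_probs = agency_probs,
      exclusivity = exclusivity,
      leak_rate = leak_rate,
      shared_rate = shared_rate, stopword_rate = stopword_rate,
      n_tracts = as.integer(n_tracts),
      compose_text = isTRUE(compose_text),
      seed = as.integer(seed)
    ),
    class = "blight_sim_config"
  )
}

# purely alphabetic pseudo-words (survive cleaning untouched): prefix plus
# a base-26 letter index, e.g. blt + "aab"
make_vocab <- function(prefix, n) {
  idx <- seq_len(n) - 1L
  width <- max(3L, ceiling(log(max(n, 2)) / log(26)))
  word <- character(n)
  for (w in seq_len(width)) {
    word <- paste0(letters[(idx %% 26L) + 1L], word)
    idx <- idx %/% 26L
  }
  paste0(prefix, word)
}

rnbinom_trunc <- function(n, mean, sd, max, eps = 1e-9) {
  size <- mean^2 / (sd^2 - mean)
  out <- rnbinom(n, size = size, mu = mean)
  bad <- which(out > max)
  while (length(bad) > 0L) {
    out[bad] <- rnbinom(length(bad), size = size, mu = mean)
    bad <- bad[out[bad] > max]
  }
  out
}

#' Generate a synthetic labelled 311 corpus with known ground truth
#'
#' For each record: draw borough and agency; draw a latent blight-token
#' count from the truncated negative binomial; compute the true linear
#' predictor from the configured coefficients and draw the blight label
#' Bernoulli(inverse-logit); then compose descriptor text from the
#' class-appropriate vocabularies plus shared-vocabulary and stopword
#' filler, with light case/punctuation noise so the text-cleaning stage is
#' exercised. Blight records draw their scored slots from the full blight
#' vocabulary; non-blight records draw each slot from the leaky part of
#' the blight vocabulary with probability `leak_rate` and otherwise from
#' their own vocabulary (see [sim_config()]).
#' Each record's complaint type encodes its label (blight records get one
#' of seven types mapped to the seven blight domains), emulating a
#' manually resolved complaint-type coding. Coordinates fall uniformly in
#' a uniformly assigned tract of the unit-square grid. Fully reproducible
#' under the config seed.
#'
#' @param config A [sim_config()].
#' @return List:
#' * `calls` — tibble in post-ingest shape (`record_id`, `created_date`,
#'   `complaint_type`, `descriptor`, `agency`, `borough`,
#'   `longitude`/`latitude`, `locatable`) plus ground-truth columns
#'   `latent_token_count`, `true_proba`, `true_blight`, `true_tract_id`;
#' * `mapping` — the complaint-type to domain mapping tibble;
#' * `vocabulary` — the generating token sets (`blight`, `nonblight`,
#'   `shared`);
#' * `tracts` — the `blight_tracts` grid;
#' * `config` — the input config.
#' @export
simulate_calls <- function(config = sim_config()) {
  stopifnot(inherits(config, "blight_sim_config"))
  vocab <- list(
    blight = make_vocab("blt", config$n_blight_tokens),
    nonblight = make_vocab("non", config$n_nonblight_tokens),
    shared = if (config$n_shared_tokens > 0) make_vocab("shr", config$n_shared_tokens) else character()
  )
  # the first (1 - exclusivity) share of the blight vocabulary is leaky:
  # reachable by non-blight records, hence realized as shared
  n_leaky <- round((1 - config$exclusivity) * config$n_blight_tokens)
  leaky_pool <- vocab$blight[seq_len(n_leaky)]
  tracts <- simulate_tracts(config$n_tracts)
  tract_ids <- vapply(tracts$features, `[[`, "", "tract_id")
  blight_types <- paste("blight complaint", LETTERS[seq_along(BLIGHT_DOMAINS)])
  nonblight_types <- paste("routine complaint", LETTERS[1:7])
  mapping <- tibble::tibble(
    complaint_type = c(blight_types, nonblight_types),
    domain = c(BLIGHT_DOMAINS, rep(NONBLIGHT_DOMAIN, length(nonblight_types)))
  )
  stop_pool <- default_stopwords()

  n <- config$n_records
  calls <- withr::with_seed(derive_seed(config$seed, "corpus"), {
    borough <- sample(names(config$borough_probs), n, TRUE, config$borough_probs)
    agency <- sample(names(config$agency_probs), n, TRUE, config$agency_probs)
    k <- rnbinom_trunc(n, config$token_count_mean, config$token_count_sd,
                       config$token_count_max)
    lp <- config$beta0 + config$beta_count * k +
      ifelse(borough == "Bronx", 0, config$beta_borough[borough]) +
      ifelse(agency == "unassigned", 0, config$beta_agency[agency])
    p <- plogis(lp)
    y <- rbinom(n, 1L, p)

    descriptor <- character(n)
    if (config$compose_text) for (i in seq_len(n)) {
      ki <- k[i]
      if (y[i] == 1L) {
        scored <- sample(vocab$blight, min(ki, length(vocab$blight)))
      } else if (ki > 0L) {
        from_leaky <- if (n_leaky > 0) rbinom(1L, ki, config$leak_rate) else 0L
        scored <- c(
          if (from_leaky > 0) sample(leaky_pool, min(from_leaky, n_leaky)),
          sample(vocab$nonblight, min(ki - from_leaky, length(vocab$nonblight)))
        )
      } else {
        scored <- character()
      }
      # blight records repeat already-drawn tokens (duplicates exercise the
      # distinct-count rule without shifting the latent score); non-blight
      # records take fresh non-blight vocabulary
      class_filler <- if (y[i] == 1L) {
        if (length(scored) > 0) sample(scored, rpois(1L, 1), TRUE) else character()
      } else {
        sample(vocab$nonblight, min(rpois(1L, 3), length(vocab$nonblight)))
      }
      shared_filler <- if (length(vocab$shared) > 0 && config$shared_rate > 0) {
        sample(vocab$shared, min(rpois(1L, config$shared_rate), length(vocab$shared)))
      } else character()
      stops <- sample(stop_pool, rpois(1L, config$stopword_rate), TRUE)
      toks <- sample(c(scored, class_filler, shared_filler, stops))
      # case/punctuation noise exercises clean_text
      up <- runif(length(toks)) < 0.1
      toks[up] <- toupper(toks[up])
      descriptor[i] <- paste(toks, collapse = " ")
      if (runif(1) < 0.15 && nzchar(descriptor[i])) {
        descriptor[i] <- paste0(descriptor[i], "!!")
      }
    }

    tract <- sample(tract_ids, n, TRUE)
    side <- attr(tracts, "side")
    cell <- match(tract, tract_ids) - 1L
    lon <- (cell %% side) + runif(n)
    lat <- (cell %/% side) + runif(n)
    created <- as.Date("2018-01-01") + sample.int(181L, n, TRUE) - 1L

    tibble::tibble(
      record_id = sprintf("SIM%08d", seq_len(n)),
      created_date = created,
      complaint_type = ifelse(y == 1L,
                              sample(blight_types, n, TRUE),
                              sample(nonblight_types, n, TRUE)),
      descriptor = descriptor,
      agency = agency,
      borough = borough,
      longitude = lon,
      latitude = lat,
      locatable = TRUE,
      latent_token_count = as.integer(k),
      true_proba = p,
      true_blight = as.integer(y),
      true_tract_id = tract
    )
  })
  list(calls = calls, mapping = mapping, vocabulary = vocab,
       tracts = tracts, config = config)
}

#' Generate a grid of unit-square toy tracts
#'
#' `n_tracts` non-overlapping unit squares filling a near-square grid
#' (row-major from the origin), with synthetic FIPS-style 11-digit ids.
#' Deterministic.
#'
#' @param n_tracts Number of tracts.
#' @return A `blight_tracts` object (see [read_tracts()]); the grid side
#'   length is stored in attribute `"side"`.
#' @export
simulate_tracts <- function(n_tracts) {
  if (n_tracts < 1) stop_config("simulate_tracts: n_tracts must be positive")
  side <- ceiling(sqrt(n_tracts))
  features <- lapply(seq_len(n_tracts) - 1L, function(cell) {
    x0 <- cell %% side
    y0 <- cell %/% side
    ring <- rbind(
      c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1)
    )
    list(tract_id = sprintf("36%09d", cell + 1L), rings = list(ring))
  })
  structure(list(features = features), class = "blight_tracts", side = side)
}

#' Generate tract vacancy measures with a target blight correlation
#'
#' For each of the nine HUD/USPS (type, duration) combinations, the tract
#' vacancy percentage is built as `r * z + sqrt(1 - r^2) * noise`, where
#' `z` is the standardized tract blight percentage, then rescaled to
#' `location + scale * value` and clipped to \[0, 100\]. The population
#' correlation with tract blight is exactly the target `r`; the realized
#' correlation converges to it as the number of tracts grows (Fisher-z
#' sampling error). Combinations absent from `targets` default to r = 0.
#'
#' @param summaries Tract summary tibble with `tract_id` and `pct_blight`.
#' @param targets Named numeric vector of target correlations in (-1, 1),
#'   names `"<type>.<duration>"` over types residential/commercial/total
#'   and durations short/medium/long — e.g.
#'   `c("commercial.long" = 0.16)`.
#' @param location,scale Mean and SD of the emitted vacancy percentages
#'   before clipping.
#' @param seed Integer seed.
#' @return Long vacancy tibble in [read_vacancy()] format
#'   (`source = "HUD_USPS"`, percentages).
#' @export
simulate_vacancy <- function(summaries, targets = c("commercial.long" = 0.16),
                             location = 8, scale = 4, seed = 1L) {
  assert_columns(summaries, c("tract_id", "pct_blight"), "simulate_vacancy")
  if (nrow(summaries) < 2L) stop_data("simulate_vacancy: need at least 2 tracts")
  if (length(targets) > 0 && any(abs(targets) >= 1 & targets != 1)) {
    stop_config("simulate_vacancy: target correlations must be in (-1, 1) or exactly 1")
  }
  combos <- expand.grid(vacancy_type = HUD_TYPES, duration = HUD_DURATIONS,
                        stringsAsFactors = FALSE)
  pb <- summaries$pct_blight
  if (sd(pb) == 0) stop_data("simulate_vacancy: tract blight percentages have zero variance")
  z <- (pb - mean(pb)) / sd(pb)
  n <- length(z)
  withr::with_seed(derive_seed(seed, "vacancy"), {
    purrr::pmap_dfr(combos, function(vacancy_type, duration) {
      key <- paste(vacancy_type, duration, sep = ".")
      r <- if (key %in% names(targets)) unname(targets[[key]]) else 0
      noise <- if (abs(r) == 1) rep(0, n) else rnorm(n)
      v <- r * z + sqrt(max(0, 1 - r^2)) * noise
      tibble::tibble(
        tract_id = summaries$tract_id,
        source = "HUD_USPS",
        vacancy_type = vacancy_type,
        duration = duration,
        value = pmin(100, pmax(0, location + scale * v)),
        is_percentage = TRUE
      )
    })
  })
}

# --- writers that emit the same dialects the readers consume --------------

#' Write synthetic calls in the Socrata 311 CSV dialect
#'
#' Emits the default [call_field_map()] headers with Socrata-style
#' datetimes, so the synthetic path exercises the real parser.
#'
#' @param calls Call tibble (ground-truth columns are dropped).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, path) {
  fm <- call_field_map()
  dt <- format(as.POSIXct(calls$created_date, tz = "UTC") + 9 * 3600,
               "%m/%d/%Y %I:%M:%S %p")
  out <- tibble::tibble(
    !!fm[["record_id"]] := calls$record_id,
    !!fm[["created_date"]] := dt,
    !!fm[["complaint_type"]] := calls$complaint_type,
    !!fm[["descriptor"]] := calls$descriptor,
    !!fm[["agency"]] := calls$agency,
    !!fm[["borough"]] := calls$borough,
    !!fm[["latitude"]] := calls$latitude,
    !!fm[["longitude"]] := calls$longitude
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write tract polygons as GeoJSON
#'
#' @param tracts A `blight_tracts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracts_geojson <- function(tracts, path) {
  stopifnot(inherits(tracts, "blight_tracts"))
  features <- lapply(tracts$features, function(f) {
    coords <- lapply(f$rings, function(m) {
      m <- rbind(m, m[1, ])
      lapply(seq_len(nrow(m)), function(j) c(m[j, 1], m[j, 2]))
    })
    list(
      type = "Feature",
      properties = list(tract_id = f$tract_id),
      geometry = list(type = "Polygon", coordinates = coords)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a long vacancy table in the wide HUD/USPS CSV dialect
#'
#' Inverse of [read_vacancy()]'s HUD layout: one row per tract, nine
#' percentage columns.
#'
#' @param vacancies Long vacancy tibble (`source = "HUD_USPS"`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hud_csv <- function(vacancies, path) {
  cols <- hud_wide_columns()
  wide <- vacancies |>
    dplyr::mutate(key = unname(cols[paste(.data$vacancy_type, .data$duration, sep = ".")])) |>
    dplyr::select("tract_id", "key", "value") |>
    tidyr::pivot_wider(names_from = "key", values_from = "value")
  readr::write_csv(wide[c("tract_id", unname(cols))], path)
  invisible(path)
}
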