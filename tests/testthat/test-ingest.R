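test_that("read_calls parses the Socrata dialect and preserves row counts", {
  path <- write_fixture_csv(socrata_fixture_lines())
  calls <- read_calls(path)
  expect_equal(nrow(calls), 5L)
  # hand-parsed oracle values
  expect_equal(calls$record_id, sprintf("1000000%d", 1:5))
  expect_equal(calls$complaint_type,
               c("Rodent", "Noise", "Graffiti", "Rodent", "Street Condition"))
  expect_equal(calls$descriptor[3], "grafiti on wall")
  expect_equal(calls$borough[5], "Staten Island")
  expect_equal(calls$latitude, c(40.8448, 40.6782, 40.7831, 40.7282, 40.5795))
  expect_equal(calls$longitude[1], -73.8648)
  # both date dialects parse
  expect_equal(calls$created_date,
               as.Date(c("2018-01-15", "2018-02-01", "2018-03-20",
                         "2018-04-02", "2018-05-30")))
  expect_true(all(calls$locatable))
})

test_that("read_calls handles empty files and missing coordinates without dropping rows", {
  header_only <- write_fixture_csv(socrata_fixture_lines()[1])
  expect_equal(nrow(read_calls(header_only)), 0L)

  lines <- socrata_fixture_lines()[1:4]
  lines[3] <- sub("40.6782", "", lines[3]) # blank latitude
  calls <- read_calls(write_fixture_csv(lines))
  expect_equal(nrow(calls), 3L)
  expect_equal(sum(!calls$locatable), 1L)
  expect_false(calls$locatable[2])
})

test_that("read_calls names a missing mandatory column", {
  lines <- c("Unique Key,Created Date,Descriptor,Agency,Borough",
             "1,01/01/2018 01:00:00 AM,x,Police,Bronx")
  expect_error(read_calls(write_fixture_csv(lines)),
               "Complaint Type", class = "blight311_config_error")
  expect_error(read_calls(tempfile()), "not found",
               class = "blight311_config_error")
})

test_that("filter_high_frequency retains exactly the types at or above the threshold", {
  calls <- tibble::tibble(complaint_type = rep(c("A", "B"), c(1500, 999)))
  out <- filter_high_frequency(calls, min_count = 1000)
  expect_equal(out$complaint_types, "A")
  expect_equal(nrow(out$calls), 1500L)
  expect_equal(out$summary$retained_pct, 100 * 1500 / 2499)

  # degenerate threshold keeps everything
  all_kept <- filter_high_frequency(calls, min_count = 1)
  expect_equal(nrow(all_kept$calls), nrow(calls))
  expect_setequal(all_kept$complaint_types, c("A", "B"))

  expect_error(filter_high_frequency(calls, min_count = 0),
               class = "blight311_config_error")
})

test_that("filter_high_frequency matches a brute-force tally and is idempotent", {
  withr::with_seed(7, {
    types <- sample(LETTERS[1:10], 3000, TRUE, prob = runif(10))
  })
  calls <- tibble::tibble(complaint_type = types)
  out <- filter_high_frequency(calls, min_count = 250)
  tally <- table(types)
  expect_setequal(out$complaint_types, names(tally)[tally >= 250])
  expect_equal(nrow(out$calls), sum(tally[tally >= 250]))
  again <- filter_high_frequency(out$calls, min_count = 250)
  expect_equal(again$calls, out$calls)
  expect_equal(again$complaint_types, out$complaint_types)
})

test_that("assign_domains labels blight, non-blight, and unlabeled types as stated", {
  mapping <- tibble::tibble(
    complaint_type = c("Rodent", "Noise"),
    domain = c("sanitary conditions", "non-blight")
  )
  calls <- tibble::tibble(complaint_type = c("Rodent", "Noise", "Mystery"))
  out <- assign_domains(calls, mapping)
  expect_equal(out$domain_label, c("sanitary conditions", "non-blight", "unlabeled"))
  expect_equal(out$blight_label, c(1L, 0L, NA_integer_))
  # every record gets exactly one of the three label kinds
  expect_true(all(out$domain_label %in%
                    c(blight_vocabularies()$blight_domains, "non-blight", "unlabeled")))
  # a bad mapping is rejected
  expect_error(
    assign_domains(calls, tibble::tibble(complaint_type = "x", domain = "potholes")),
    class = "blight311_data_error"
  )
  expect_error(
    assign_domains(calls, tibble::tibble(complaint_type = c("x", "x"),
                                         domain = c("noise", "non-blight"))),
    class = "blight311_data_error"
  )
})

test_that("cohens_kappa reproduces hand-computed values and is symmetric", {
  expect_equal(cohens_kappa(c("A", "B", "C"), c("A", "B", "C"))$kappa, 1)
  # p_o = 3/4, p_e = 1/2 by hand -> kappa = 0.5
  a <- c("A", "A", "B", "B")
  b <- c("A", "B", "B", "B")
  expect_equal(cohens_kappa(a, b)$kappa, 0.5)
  expect_equal(cohens_kappa(b, a)$kappa, cohens_kappa(a, b)$kappa)
  expect_error(cohens_kappa(a, b[1:3]), class = "blight311_data_error")
})

test_that("cohens_kappa flags degenerate agreement and matches an independent implementation", {
  deg <- cohens_kappa(rep("A", 5), rep("A", 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$kappa))
  expect_equal(deg$p_observed, 1)

  skip_if_not_installed("e1071")
  withr::with_seed(11, {
    for (i in 1:5) {
      a <- sample(LETTERS[1:4], 300, TRUE)
      b <- ifelse(runif(300) < 0.6, a, sample(LETTERS[1:4], 300, TRUE))
      tab <- table(factor(a, LETTERS[1:4]), factor(b, LETTERS[1:4]))
      expect_equal(cohens_kappa(a, b)$kappa,
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    }
  })
})

test_that("read_vacancy expands the HUD layout and normalizes the ACS layout", {
  hud <- write_fixture_csv(c(
    "tract_id,res_vac_short_pct,res_vac_medium_pct,res_vac_long_pct,com_vac_short_pct,com_vac_medium_pct,com_vac_long_pct,tot_vac_short_pct,tot_vac_medium_pct,tot_vac_long_pct",
    "36001000100,1,2,3,4,5,6,7,8,9",
    "36001000200,9,8,7,6,5,4,3,2,1"
  ))
  rec <- read_vacancy(hud, "HUD_USPS")
  expect_equal(nrow(rec), 18L) # 2 tracts x 3 types x 3 durations
  expect_true(all(rec$is_percentage))
  one <- rec[rec$tract_id == "36001000100" & rec$vacancy_type == "commercial" &
               rec$duration == "long", ]
  expect_equal(one$value, 6)

  acs <- write_fixture_csv(c(
    "tract_id,total_housing_units,vacant_housing_units",
    "36001000100,200,30",
    "36001000200,400,10"
  ))
  arec <- read_vacancy(acs, "ACS")
  pct <- arec[arec$is_percentage, ]
  expect_equal(pct$value[pct$tract_id == "36001000100"], 100 * 30 / 200)
  cnt <- arec[!arec$is_percentage, ]
  expect_equal(cnt$value[cnt$tract_id == "36001000200"], 10)
})

test_that("read_vacancy rejects out-of-range values and duplicate keys", {
  bad <- write_fixture_csv(c(
    "tract_id,res_vac_short_pct,res_vac_medium_pct,res_vac_long_pct,com_vac_short_pct,com_vac_medium_pct,com_vac_long_pct,tot_vac_short_pct,tot_vac_medium_pct,tot_vac_long_pct",
    "36001000100,-1,2,3,4,5,6,7,8,9"
  ))
  expect_error(read_vacancy(bad, "HUD_USPS"), "out of range",
               class = "blight311_data_error")

  dup <- write_fixture_csv(c(
    "tract_id,res_vac_short_pct,res_vac_medium_pct,res_vac_long_pct,com_vac_short_pct,com_vac_medium_pct,com_vac_long_pct,tot_vac_short_pct,tot_vac_medium_pct,tot_vac_long_pct",
    "36001000100,1,2,3,4,5,6,7,8,9",
    "36001000100,1,2,3,4,5,6,7,8,9"
  ))
  expect_error(read_vacancy(dup, "HUD_USPS"), "duplicate",
               class = "blight311_data_error")
})
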