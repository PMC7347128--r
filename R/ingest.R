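#' Column mapping for 311 CSV exports
#'
#' Defaults follow the Socrata NYC open-data export dialect. Override any
#' entry to read exports with different headers. Entries beyond the named
#' defaults are treated as additional free-text columns and kept verbatim.
#'
#' @param record_id,created_date,complaint_type,descriptor,agency,borough,latitude,longitude
#'   CSV column names for the respective fields.
#' @return Named character vector (internal field -> CSV column).
#' @export
call_field_map <- function(record_id = "Unique Key",
                           created_date = "Created Date",
                           complaint_type = "Complaint Type",
                           descriptor = "Descriptor",
                           agency = "Agency",
                           borough = "Borough",
                           latitude = "Latitude",
                           longitude = "Longitude") {
  c(
    record_id = record_id, created_date = created_date,
    complaint_type = complaint_type, descriptor = descriptor,
    agency = agency, borough = borough,
    latitude = latitude, longitude = longitude
  )
}

# Socrata exports print "MM/DD/YYYY HH:MM:SS AM/PM"; ISO-8601 dates and
# datetimes also occur in open-data downloads. Anything else parses to NA.
parse_call_date <- function(x) {
  x <- as.character(x)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  socrata <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}", x)
  out[socrata] <- as.Date(strptime(x[socrata], "%m/%d/%Y %I:%M:%S %p", tz = "UTC"))
  bare <- socrata & is.na(out)
  out[bare] <- as.Date(strptime(x[bare], "%m/%d/%Y", tz = "UTC"))
  iso <- !socrata & !is.na(x) & nzchar(x)
  out[iso] <- as.Date(substr(x[iso], 1, 10), format = "%Y-%m-%d")
  out
}

#' Read a 311 service-request CSV export
#'
#' One row per call. Rows with missing or unparseable coordinates are kept
#' and flagged `locatable = FALSE` rather than dropped, so record counts
#' reconcile through the pipeline.
#'
#' @param path Path to a delimited text file with a header row.
#' @param field_map A [call_field_map()]. Mandatory fields: complaint type,
#'   descriptor, borough, agency; a missing mandatory column is a
#'   configuration error naming the column.
#' @return A tibble with columns `record_id`, `created_date`,
#'   `complaint_type`, `descriptor` (plus any extra mapped text columns),
#'   `agency`, `borough`, `longitude`, `latitude`, `locatable`.
#' @export
read_calls <- function(path, field_map = call_field_map()) {
  if (!file.exists(path)) {
    stop_config(sprintf("read_calls: file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("complaint_type", "descriptor", "borough", "agency")
  for (field in mandatory) {
    if (!field_map[[field]] %in% names(raw)) {
      stop_config(sprintf(
        "read_calls: required column '%s' (field '%s') not found in %s",
        field_map[[field]], field, path
      ))
    }
  }
  get_col <- function(field) {
    col <- field_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  lat <- suppressWarnings(as.numeric(get_col("latitude")))
  lon <- suppressWarnings(as.numeric(get_col("longitude")))
  out <- tibble::tibble(
    record_id = get_col("record_id"),
    created_date = parse_call_date(get_col("created_date")),
    complaint_type = get_col("complaint_type"),
    descriptor = get_col("descriptor"),
    agency = get_col("agency"),
    borough = get_col("borough"),
    longitude = lon,
    latitude = lat,
    locatable = !is.na(lat) & !is.na(lon)
  )
  extra <- setdiff(names(field_map), c(names(call_field_map())))
  for (field in extra) {
    out[[field]] <- get_col(field)
  }
  out
}

#' Keep only high-frequency complaint types
#'
#' A complaint type is retained iff its record count is at least
#' `min_count`; retained records are exactly those with a retained type.
#' The default of 1,000 records matches a six-month city-scale volume and
#' should be lowered for smaller extracts.
#'
#' @param calls A call tibble.
#' @param min_count Positive integer threshold (default 1000).
#' @return A list with `calls` (the retained rows), `complaint_types`
#'   (character vector of retained types), and `summary` (a one-row tibble
#'   with total/retained record and type counts and the retained share).
#' @export
#' @examples
#' calls <- tibble::tibble(complaint_type = rep(c("A", "B"), c(3, 1)))
#' filter_high_frequency(calls, min_count = 2)$complaint_types
filter_high_frequency <- function(calls, min_count = 1000) {
  if (!is_scalar_number(min_count) || min_count < 1) {
    stop_config("filter_high_frequency: min_count must be a positive integer")
  }
  if (nrow(calls) == 0L) {
    stop_data("filter_high_frequency: no records")
  }
  counts <- dplyr::count(calls, .data$complaint_type, name = "n")
  keep_types <- sort(counts$complaint_type[counts$n >= min_count])
  retained <- dplyr::filter(calls, .data$complaint_type %in% keep_types)
  list(
    calls = retained,
    complaint_types = keep_types,
    summary = tibble::tibble(
      total_records = nrow(calls),
      total_types = nrow(counts),
      retained_types = length(keep_types),
      retained_records = nrow(retained),
      retained_pct = 100 * nrow(retained) / nrow(calls)
    )
  )
}

#' Read a complaint-type to blight-domain mapping
#'
#' @param path 2-column CSV (`complaint_type`, `domain`); each domain must
#'   be one of the seven blight domains or `"non-blight"`.
#' @return A tibble with columns `complaint_type` and `domain`.
#' @export
read_domain_mapping <- function(path) {
  mapping <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  assert_columns(mapping, c("complaint_type", "domain"), "read_domain_mapping")
  validate_domain_mapping(mapping)
}

validate_domain_mapping <- function(mapping) {
  allowed <- c(BLIGHT_DOMAINS, NONBLIGHT_DOMAIN)
  bad <- setdiff(unique(mapping$domain), allowed)
  if (length(bad) > 0L) {
    stop_data(sprintf(
      "domain mapping: unknown domain(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  dup <- mapping$complaint_type[duplicated(mapping$complaint_type)]
  if (length(dup) > 0L) {
    stop_data(sprintf(
      "domain mapping: complaint type(s) mapped more than once: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  tibble::as_tibble(mapping)
}

#' Assign blight-domain and binary blight labels
#'
#' Labels each call from the complaint-type mapping. A call whose type is
#' absent from the mapping gets `domain_label = "unlabeled"` and a missing
#' `blight_label`: unmapped types are excluded from lexicon training and
#' model fitting rather than silently treated as non-blight.
#'
#' @param calls A call tibble.
#' @param mapping Tibble with `complaint_type`, `domain` columns
#'   (see [read_domain_mapping()]).
#' @return `calls` with `domain_label` and integer `blight_label`
#'   (1 = blight domain, 0 = non-blight, `NA` = unlabeled) added.
#' @export
assign_domains <- function(calls, mapping) {
  mapping <- validate_domain_mapping(mapping)
  idx <- match(calls$complaint_type, mapping$complaint_type)
  domain <- mapping$domain[idx]
  domain[is.na(idx)] <- UNLABELED_DOMAIN
  calls$domain_label <- domain
  calls$blight_label <- dplyr::case_when(
    domain %in% BLIGHT_DOMAINS ~ 1L,
    domain == NONBLIGHT_DOMAIN ~ 0L,
    TRUE ~ NA_integer_
  )
  calls
}

#' Cohen's kappa for two categorical codings
#'
#' Chance-corrected agreement between two raters who each assigned every
#' item to one category: kappa = (p_o - p_e) / (1 - p_e), with observed
#' agreement p_o and expected agreement p_e from the product of the raters'
#' marginal distributions. Unweighted, multi-category.
#'
#' @param labels_a,labels_b Equal-length category vectors (length >= 2).
#' @return A one-row tibble with `kappa`, `p_observed`, `p_expected`, `n`,
#'   and `degenerate`. When both raters use a single identical category,
#'   p_e = 1 and kappa is undefined: `degenerate = TRUE`, `kappa = NA`, and
#'   `p_observed` still reports raw agreement.
#' @export
#' @examples
#' cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B"))$kappa # 0.5
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_data("cohens_kappa: label sequences differ in length")
  }
  n <- length(labels_a)
  if (n < 2L) {
    stop_data("cohens_kappa: need at least 2 paired labels")
  }
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  cats <- sort(union(labels_a, labels_b))
  p_o <- mean(labels_a == labels_b)
  ma <- tabulate(match(labels_a, cats), length(cats)) / n
  mb <- tabulate(match(labels_b, cats), length(cats)) / n
  p_e <- sum(ma * mb)
  degenerate <- isTRUE(all.equal(p_e, 1))
  tibble::tibble(
    kappa = if (degenerate) NA_real_ else (p_o - p_e) / (1 - p_e),
    p_observed = p_o,
    p_expected = p_e,
    n = n,
    degenerate = degenerate
  )
}

# --- vacancy tables -------------------------------------------------------

HUD_TYPES <- c("residential", "commercial", "total")
HUD_DURATIONS <- c("short", "medium", "long")

# Wide HUD/USPS quarterly dialect: tract_id plus <res|com|tot>_vac_<dur>_pct.
hud_wide_columns <- function() {
  prefix <- c(residential = "res", commercial = "com", total = "tot")
  cols <- as.vector(outer(prefix, HUD_DURATIONS,
                          function(p, d) paste0(p, "_vac_", d, "_pct")))
  setNames(cols, as.vector(outer(names(prefix), HUD_DURATIONS, paste, sep = ".")))
}

#' Read a tract-level vacancy table
#'
#' Two layouts are supported. `source = "HUD_USPS"`: one row per tract with
#' nine percentage columns (`res|com|tot` crossed with `short|medium|long`),
#' expanded to long format — a 2-tract file yields 18 records.
#' `source = "ACS"`: DP04-style counts (`total_housing_units`,
#' `vacant_housing_units`), normalized to a residential vacancy percentage
#' of unspecified duration (100 * vacant / total).
#'
#' @param path CSV path; must contain a `tract_id` column.
#' @param source `"ACS"` or `"HUD_USPS"`.
#' @return Long tibble with `tract_id`, `source`, `vacancy_type`
#'   (residential/commercial/total), `duration` (short/medium/long/
#'   unspecified), `value`, `is_percentage`.
#' @export
read_vacancy <- function(path, source = c("HUD_USPS", "ACS")) {
  source <- match.arg(source)
  raw <- readr::read_csv(path, col_types = readr::cols(
    tract_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  assert_columns(raw, "tract_id", "read_vacancy")
  if (source == "HUD_USPS") {
    cols <- hud_wide_columns()
    assert_columns(raw, unname(cols), "read_vacancy (HUD_USPS layout)")
    long <- tidyr::pivot_longer(
      raw[c("tract_id", unname(cols))],
      cols = -"tract_id",
      names_to = "key", values_to = "value"
    )
    key <- names(cols)[match(long$key, cols)]
    parts <- strsplit(key, ".", fixed = TRUE)
    out <- tibble::tibble(
      tract_id = long$tract_id,
      source = "HUD_USPS",
      vacancy_type = vapply(parts, `[`, "", 1L),
      duration = vapply(parts, `[`, "", 2L),
      value = long$value,
      is_percentage = TRUE
    )
  } else {
    assert_columns(raw, c("total_housing_units", "vacant_housing_units"),
                   "read_vacancy (ACS layout)")
    if (any(raw$vacant_housing_units < 0 | raw$total_housing_units < 0, na.rm = TRUE) ||
        any(raw$vacant_housing_units != floor(raw$vacant_housing_units), na.rm = TRUE)) {
      stop_data("read_vacancy: ACS unit counts must be non-negative integers")
    }
    out <- dplyr::bind_rows(
      tibble::tibble(
        tract_id = raw$tract_id, source = "ACS", vacancy_type = "residential",
        duration = "unspecified", value = as.numeric(raw$vacant_housing_units),
        is_percentage = FALSE
      ),
      tibble::tibble(
        tract_id = raw$tract_id, source = "ACS", vacancy_type = "residential",
        duration = "unspecified",
        value = 100 * raw$vacant_housing_units / raw$total_housing_units,
        is_percentage = TRUE
      )
    )
  }
  validate_vacancy(out)
}

validate_vacancy <- function(records) {
  pct <- records$is_percentage
  bad_pct <- pct & (records$value < 0 | records$value > 100)
  bad_cnt <- !pct & records$value < 0
  bad <- which(!is.na(records$value) & (bad_pct | bad_cnt))
  if (length(bad) > 0L) {
    stop_data(sprintf(
      "vacancy data: %d value(s) out of range (tracts: %s)",
      length(bad), paste(unique(records$tract_id[bad]), collapse = ", ")
    ))
  }
  key <- paste(records$tract_id, records$vacancy_type, records$duration,
               records$is_percentage)
  dup <- duplicated(key)
  if (any(dup)) {
    stop_data(sprintf(
      "vacancy data: duplicate (tract, type, duration) rows: %s",
      paste(unique(key[dup]), collapse = "; ")
    ))
  }
  tibble::as_tibble(records)
}
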