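#' Read census-tract polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon or MultiPolygon features in WGS84
#' lon/lat, each carrying the tract identifier as a property. No
#' reprojection is performed: planar containment is adequate at tract
#' scale.
#'
#' @param path GeoJSON path.
#' @param id_property Name of the feature property holding the tract id
#'   (default `"tract_id"`).
#' @return A `blight_tracts` object: list of features, each with
#'   `tract_id` and `rings` (list of 2-column lon/lat matrices; first ring
#'   of each polygon is the exterior, holes follow — containment uses the
#'   even-odd rule so holes are handled uniformly).
#' @export
read_tracts <- function(path, id_property = "tract_id") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop_data("read_tracts: not a GeoJSON FeatureCollection")
  features <- lapply(gj$features, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) {
      stop_data(sprintf("read_tracts: feature lacks the '%s' property", id_property))
    }
    geom <- f$geometry
    polys <- switch(
      geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop_data(sprintf("read_tracts: unsupported geometry type '%s'", geom$type))
    )
    rings <- unlist(lapply(polys, function(poly) {
      lapply(poly, function(ring) {
        m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
        close_ring(m)
      })
    }), recursive = FALSE)
    list(tract_id = as.character(id), rings = rings)
  })
  structure(list(features = features), class = "blight_tracts")
}

# drop a duplicated closing vertex; a ring needs >= 3 distinct vertices
close_ring <- function(m) {
  if (nrow(m) >= 2L && all(m[1, ] == m[nrow(m), ])) {
    m <- m[-nrow(m), , drop = FALSE]
  }
  if (nrow(m) < 3L) stop_data("tract polygon: ring with fewer than 3 vertices")
  m
}

#' @export
print.blight_tracts <- function(x, ...) {
  cat(sprintf("<blight_tracts> %d tract(s)\n", length(x$features)))
  invisible(x)
}

# Even-odd ray casting with an explicit boundary test: a point on any ring
# edge counts as inside. Needed so the documented boundary tie-break
# (lexicographically smallest containing tract id) is deterministic.
point_in_rings <- function(px, py, rings, eps = 1e-12) {
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      x1 <- ring[j, 1]; y1 <- ring[j, 2]
      x2 <- ring[i, 1]; y2 <- ring[i, 2]
      # on-segment check
      cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
      if (abs(cross) <= eps &&
          px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
          py >= min(y1, y2) - eps && py <= max(y1, y2) + eps) {
        return(TRUE)
      }
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        if (px < xint) crossings <- crossings + 1L
      }
      j <- i
    }
  }
  crossings %% 2L == 1L
}

#' Assign calls to census tracts by point-in-polygon
#'
#' Locatable records get the tract whose polygon contains their
#' coordinates; points on a shared boundary are assigned to the
#' lexicographically smallest containing `tract_id`; points in no polygon
#' (and un-locatable records) get `NA`.
#'
#' @param calls Call tibble with `longitude`, `latitude`, `locatable`.
#' @param tracts A [read_tracts()] / [simulate_tracts()] object.
#' @return `calls` with a `tract_id` character column added.
#' @export
assign_tracts <- function(calls, tracts) {
  stopifnot(inherits(tracts, "blight_tracts"))
  assert_columns(calls, c("longitude", "latitude", "locatable"), "assign_tracts")
  feats <- tracts$features[order(vapply(tracts$features, `[[`, "", "tract_id"))]
  # bounding-box prefilter keeps the exact containment test to a handful of
  # candidate tracts per point
  bbox <- t(vapply(feats, function(f) {
    m <- do.call(rbind, f$rings)
    c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
  }, numeric(4)))
  calls$tract_id <- vapply(seq_len(nrow(calls)), function(i) {
    if (!isTRUE(calls$locatable[i])) return(NA_character_)
    px <- calls$longitude[i]; py <- calls$latitude[i]
    cand <- which(px >= bbox[, 1] & px <= bbox[, 2] &
                    py >= bbox[, 3] & py <= bbox[, 4])
    for (j in cand) {
      if (point_in_rings(px, py, feats[[j]]$rings)) return(feats[[j]]$tract_id)
    }
    NA_character_
  }, character(1))
  calls
}

#' Aggregate classified calls to tract level
#'
#' One summary row per tract with at least `min_calls` assigned records:
#' call count, predicted-blight count, and the predicted-blight percentage.
#' Hard classifications are aggregated by default (the tract percentage is
#' a percentage of *classified* calls); `use_probability = TRUE` instead
#' averages the predicted probabilities, which is smoother in sparse
#' tracts.
#'
#' @param calls Call tibble with `tract_id` and `predicted_label`
#'   (and `predicted_proba` when `use_probability`).
#' @param min_calls Minimum assigned calls for a tract to be summarized
#'   (default 1); tracts with zero calls never appear since their
#'   percentage is undefined.
#' @param use_probability Aggregate mean predicted probability instead of
#'   classified counts.
#' @return List with `summaries` (tibble: `tract_id`, `n_calls`,
#'   `n_blight_predicted`, `pct_blight`) and `reconciliation` (one-row
#'   tibble accounting for every input record: total, unassigned,
#'   below-min-calls, summarized).
#' @export
aggregate_tracts <- function(calls, min_calls = 1, use_probability = FALSE) {
  assert_columns(calls, "tract_id", "aggregate_tracts")
  needed <- if (use_probability) "predicted_proba" else "predicted_label"
  assert_columns(calls, needed, "aggregate_tracts")
  assigned <- dplyr::filter(calls, !is.na(.data$tract_id))
  summaries <- assigned |>
    dplyr::group_by(.data$tract_id) |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      n_blight_predicted = if (use_probability) NA_integer_ else
        as.integer(sum(.data$predicted_label)),
      pct_blight = if (use_probability) 100 * mean(.data$predicted_proba) else
        100 * sum(.data$predicted_label) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$tract_id)
  kept <- summaries$n_calls >= min_calls
  list(
    summaries = summaries[kept, ],
    reconciliation = tibble::tibble(
      total_records = nrow(calls),
      unassigned = nrow(calls) - nrow(assigned),
      below_min_calls = sum(summaries$n_calls[!kept]),
      summarized = sum(summaries$n_calls[kept])
    )
  )
}

#' Pearson correlation over paired tract values
#'
#' Product-moment correlation with a two-sided p-value from the
#' t-transform on n - 2 degrees of freedom. Pairs with a missing value in
#' either series are dropped first.
#'
#' @param x,y Equal-length numeric vectors (paired over tracts).
#' @return One-row tibble: `r`, `p_value`, `n`, `degenerate`. Zero variance
#'   in either series makes the correlation undefined: `r = NA`,
#'   `degenerate = TRUE`.
#' @export
#' @examples
#' correlate(c(1, 2, 3), c(1, 2, 4))
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_data("correlate: series differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_data(sprintf("correlate: need at least 3 complete pairs (have %d)", length(x)))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                          degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
                 degenerate = FALSE)
}

#' Correlate tract blight against every vacancy measure
#'
#' Joins tract summaries to a long vacancy table and computes one
#' correlation row per available (source, vacancy type, duration) —
#' percentage vacancy measures pair with the tract's predicted-blight
#' percentage, count measures pair with the predicted-blight count
#' (convergent validity diverges between the two pairings, so they are
#' never mixed).
#'
#' @param summaries Tract summary tibble (see [aggregate_tracts()]).
#' @param vacancies Long vacancy tibble (see [read_vacancy()]).
#' @return Tibble with `source`, `vacancy_type`, `duration`, `pairing`
#'   (`"percent"` or `"count"`), `r`, `p_value`, `n`, `degenerate`.
#' @export
vacancy_battery <- function(summaries, vacancies) {
  assert_columns(summaries, c("tract_id", "pct_blight"), "vacancy_battery")
  assert_columns(vacancies, c("tract_id", "source", "vacancy_type", "duration",
                              "value", "is_percentage"), "vacancy_battery")
  joined <- dplyr::inner_join(vacancies, summaries, by = "tract_id")
  if (nrow(joined) == 0L) {
    stop_data(sprintf(
      "vacancy_battery: no tract_id overlap (summaries: %s...; vacancies: %s...)",
      paste(head(summaries$tract_id, 3), collapse = ","),
      paste(head(unique(vacancies$tract_id), 3), collapse = ",")
    ))
  }
  joined |>
    dplyr::group_by(.data$source, .data$vacancy_type, .data$duration,
                    .data$is_percentage) |>
    dplyr::group_modify(function(g, key) {
      blight <- if (key$is_percentage) g$pct_blight else as.numeric(g$n_blight_predicted)
      correlate(g$value, blight)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(pairing = ifelse(.data$is_percentage, "percent", "count")) |>
    dplyr::select("source", "vacancy_type", "duration", "pairing",
                  "r", "p_value", "n", "degenerate")
}

#' Export tract summaries as GeoJSON
#'
#' Writes one feature per summarized tract with `tract_id`, `n_calls`,
#' `n_blight_predicted` and `pct_blight` as properties, using the tract
#' polygons' geometry. Mapping itself is left to GIS tools.
#'
#' @param summaries Tract summary tibble.
#' @param tracts A `blight_tracts` object supplying geometry.
#' @param path Output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_tract_geojson <- function(summaries, tracts, path) {
  stopifnot(inherits(tracts, "blight_tracts"))
  by_id <- setNames(tracts$features,
                    vapply(tracts$features, `[[`, "", "tract_id"))
  features <- lapply(seq_len(nrow(summaries)), function(i) {
    id <- summaries$tract_id[i]
    f <- by_id[[id]]
    if (is.null(f)) stop_data(sprintf("write_tract_geojson: no polygon for tract %s", id))
    coords <- lapply(f$rings, function(m) {
      m <- rbind(m, m[1, ]) # re-close for GeoJSON
      lapply(seq_len(nrow(m)), function(j) c(m[j, 1], m[j, 2]))
    })
    list(
      type = "Feature",
      properties = list(
        tract_id = id,
        n_calls = summaries$n_calls[i],
        n_blight_predicted = summaries$n_blight_predicted[i],
        pct_blight = summaries$pct_blight[i]
      ),
      geometry = list(type = "Polygon", coordinates = coords)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
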