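# Distance-to-nearest-mine computation, near/far partition and the
# distance-concentration profile.

EARTH_RADIUS_M <- 6371008.8  # mean Earth radius (IUGG), metres

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km.  Spherical
#' rather than ellipsoidal distance is used throughout: the worst-case
#' spherical error (< 0.5 %) is far below the granularity of the 6.4 km
#' partition threshold.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees
#'   (vectorised, recycled).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / 1000
}

#' Distance from each source to its nearest abandoned mine
#'
#' @param sources Data frame with `source_id`, `lat`, `lon`.
#' @param mines Data frame with `mine_id`, `lat`, `lon`; at least one row.
#' @param config An [analysis_config()]; supplies the near/far threshold.
#' @return Data frame (`source_id`, `nearest_mine_id`, `distance_km`,
#'   `near`), one row per source.  `near` is strict: distance strictly
#'   below the threshold.  Ties go to the first mine in input order.
#' @export
nearest_mine <- function(sources, mines, config = analysis_config()) {
  if (is.null(mines) || nrow(mines) == 0L)
    stop("nearest_mine requires at least one mine site")
  stopifnot(all(c("source_id", "lat", "lon") %in% names(sources)),
            all(c("mine_id", "lat", "lon") %in% names(mines)))
  d <- geosphere::distm(cbind(sources$lon, sources$lat),
                        cbind(mines$lon, mines$lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = EARTH_RADIUS_M))
  d <- d / 1000
  idx <- apply(d, 1L, which.min)  # which.min takes the first tie
  dist_km <- d[cbind(seq_len(nrow(sources)), idx)]
  data.frame(source_id = sources$source_id,
             nearest_mine_id = mines$mine_id[idx],
             distance_km = dist_km,
             near = dist_km < config$distance_threshold_km,
             stringsAsFactors = FALSE)
}

# Per-analyte harmonized values joined with proximity; internal helper.
join_proximity <- function(values, proximity) {
  idx <- match(values$source_id, proximity$source_id)
  if (any(is.na(idx)))
    stop("every source with an analysis value needs a proximity result")
  cbind(values, proximity[idx, c("distance_km", "near")])
}

#' Near/far partition summaries and two-group tests
#'
#' Splits the harmonized analysis values at the proximity threshold and
#' summarises each stratum per analyte (detection frequency, ROS median
#' and IQR, MCL exceedance), plus a joint arsenic-uranium block and a
#' Peto-Peto comparison of near versus far concentrations per analyte.
#'
#' @param values Harmonized values (from [harmonize()]`$values`).
#' @param proximity Result of [nearest_mine()].
#' @param config An [analysis_config()].
#' @return List: `tables` (data frame of near/far rows per analyte block),
#'   `joint` (near/far joint-block rows), `tests` (named list of
#'   `peto_peto_test` per analyte, `NULL` with a warning where a stratum
#'   cannot support the test).
#' @export
partition_summaries <- function(values, proximity,
                                config = analysis_config()) {
  tables <- list()
  tests <- list()
  labels <- c("near", "far")
  for (analyte in c("arsenic", "uranium")) {
    v <- join_proximity(values[values$analyte == analyte, , drop = FALSE],
                        proximity)
    thr <- if (analyte == "arsenic") config$mcl_arsenic else
      config$mcl_uranium
    rows <- lapply(c(TRUE, FALSE), function(is_near) {
      vi <- v[v$near == is_near, , drop = FALSE]
      lab <- labels[2L - is_near]
      if (nrow(vi) == 0L)
        return(data.frame(stratum = lab, n = 0L,
                          detection_frequency = NA_real_,
                          ros_median = NA_real_, ros_q1 = NA_real_,
                          ros_q3 = NA_real_, frac_exceed_mcl = NA_real_,
                          n_indeterminate = 0L, ros_unavailable = TRUE,
                          stringsAsFactors = FALSE))
      analyte_summary(vi$value_ug_L, vi$censored, thr, stratum = lab)
    })
    tab <- do.call(rbind, rows)
    tab$analyte <- analyte
    tables[[analyte]] <- tab
    nr <- v[v$near, , drop = FALSE]
    fr <- v[!v$near, , drop = FALSE]
    tests[[analyte]] <- tryCatch(
      peto_peto_test(fr$value_ug_L, fr$censored, nr$value_ug_L, nr$censored),
      error = function(e) {
        warning("near/far test skipped for ", analyte, ": ",
                conditionMessage(e))
        NULL
      })
  }
  pairs <- analyte_pairs(values)
  pairs <- cbind(pairs,
                 near = proximity$near[match(pairs$source_id,
                                             proximity$source_id)])
  joint <- do.call(rbind, lapply(c(TRUE, FALSE), function(is_near) {
    joint_summary(pairs[pairs$near == is_near, , drop = FALSE], config,
                  stratum = labels[2L - is_near])
  }))
  list(tables = do.call(rbind, tables), joint = joint, tests = tests)
}

# Wide per-source pairing of the two analytes; sources missing one
# analyte are dropped (callers count them via attr "n_skipped").
analyte_pairs <- function(values) {
  a <- values[values$analyte == "arsenic", , drop = FALSE]
  u <- values[values$analyte == "uranium", , drop = FALSE]
  common <- intersect(a$source_id, u$source_id)
  ai <- match(common, a$source_id)
  ui <- match(common, u$source_id)
  out <- data.frame(source_id = common,
                    as_value = a$value_ug_L[ai], as_censored = a$censored[ai],
                    u_value = u$value_ug_L[ui], u_censored = u$censored[ui],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- length(union(a$source_id, u$source_id)) -
    length(common)
  out
}

#' Distance-concentration profile
#'
#' Bins sources by distance to the nearest mine and reports the per-bin
#' ROS median against the overall ROS median, the tabular analogue of a
#' median-versus-distance line plot.  Bins too censored or too small for
#' the ROS fit fall back to substitution at limit/sqrt(2) for censored
#' values and are flagged; bins with a single source are flagged low-n.
#'
#' @param values Harmonized values for one analyte.
#' @param proximity Result of [nearest_mine()].
#' @param bin_km Bin width in km (> 0).
#' @return Data frame of class `distance_profile`: `bin_lo_km`,
#'   `bin_hi_km`, `n`, `median_ug_L`, `substitution`, `low_n`,
#'   `overall_median_ug_L`.
#' @export
distance_profile <- function(values, proximity, bin_km = 5) {
  stopifnot(bin_km > 0)
  v <- join_proximity(values, proximity)
  if (nrow(v) == 0L) stop("distance_profile requires at least one value")
  bin <- floor(v$distance_km / bin_km)
  overall <- robust_median(v$value_ug_L, v$censored)
  rows <- lapply(sort(unique(bin)), function(b) {
    vi <- v[bin == b, , drop = FALSE]
    med <- robust_median(vi$value_ug_L, vi$censored)
    data.frame(bin_lo_km = b * bin_km, bin_hi_km = (b + 1) * bin_km,
               n = nrow(vi), median_ug_L = med$median,
               substitution = med$substitution, low_n = nrow(vi) < 2L)
  })
  out <- do.call(rbind, rows)
  out$overall_median_ug_L <- overall$median
  class(out) <- c("distance_profile", "data.frame")
  out
}

# ROS median with flagged substitution fallback (limit / sqrt(2)) when the
# ROS preconditions fail.
robust_median <- function(value, censored) {
  if (sum(!censored) >= 3L && length(unique(value[!censored])) >= 2L &&
      all(value > 0)) {
    fit <- ros_fit(value, censored)
    list(median = unname(fit$summary["median"]), substitution = FALSE)
  } else {
    x <- ifelse(censored, value / sqrt(2), value)
    list(median = stats::median(x), substitution = TRUE)
  }
}
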