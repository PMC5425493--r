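# Robust regression on order statistics (ROS) for multiply left-censored
# concentrations.  Probability is apportioned across the distinct
# reporting limits by the Hirsch-Stedinger exceedance recursion, Weibull
# plotting positions are assigned within each censoring interval, detected
# values are regressed on normal scores on the log scale, censored values
# are imputed from the fitted line, and summary statistics are computed on
# the combined set in original units (the "robust" variant: no lognormal
# moment back-transform).

#' Interval census for multiply censored data
#'
#' Partitions the data by the distinct censoring limits L_1 < ... < L_k,
#' augmented with a virtual limit L_0 below all data.  For each level j:
#' `A[j]` counts detected values in \[L_j, L_(j+1)) (closed on the left,
#' so a detect equal to a limit belongs to the interval starting at that
#' limit); `B[j]` counts observations known to lie below L_j (detects
#' strictly below plus censored results with limit <= L_j); `C[j]` counts
#' results censored exactly at L_j.
#'
#' @param values Numeric: detected value, or reporting limit if censored.
#' @param censored Logical vector parallel to `values`.
#' @return A list of class `ros_census`: `limits` (L_0..L_k, L_0 virtual),
#'   `A`, `B`, `C` (C\[1\] = 0 at the virtual limit), `n_total`.
#' @export
censoring_intervals <- function(values, censored) {
  n <- length(values)
  if (n == 0L) stop("censoring_intervals requires at least one value")
  stopifnot(length(censored) == n, is.numeric(values))
  detects <- values[!censored]
  cen_limits <- values[censored]
  limits <- sort(unique(cen_limits))
  virtual <- min(values, 0)      # at or below all data; L_0 of the census
  L <- c(virtual, limits)        # L[1] is the virtual limit L_0
  k <- length(limits)
  upper <- c(L[-1L], Inf)        # interval right edges
  A <- integer(k + 1L)
  B <- integer(k + 1L)
  C <- integer(k + 1L)
  for (j in seq_len(k + 1L)) {
    A[j] <- sum(detects >= L[j] & detects < upper[j])
    B[j] <- sum(detects < L[j]) + sum(cen_limits <= L[j])
    C[j] <- if (j == 1L) 0L else sum(cen_limits == L[j])
  }
  structure(list(limits = L, A = A, B = B, C = C, n_total = n),
            class = "ros_census")
}

#' Hirsch-Stedinger exceedance-probability recursion
#'
#' Computes, from the highest censoring level downward, the probability
#' `P[j]` of exceeding each limit: with P_(k+1) = 0,
#' P_j = P_(j+1) + A_j / (A_j + B_j) * (1 - P_(j+1)), levels with
#' A_j + B_j = 0 carrying the value down unchanged.  Equivalent to a
#' Kaplan-Meier survival estimate on the flipped (right-censored) data.
#'
#' @param census A `ros_census` from [censoring_intervals()].
#' @return Numeric vector `P` parallel to `census$limits` (P\[1\] at the
#'   virtual limit is 1 whenever any detect lies below the lowest limit).
#' @export
exceedance_recursion <- function(census) {
  stopifnot(inherits(census, "ros_census"))
  k1 <- length(census$limits)
  P <- numeric(k1 + 1L)          # P[k1 + 1] is P_(k+1) = 0
  for (j in rev(seq_len(k1))) {
    denom <- census$A[j] + census$B[j]
    P[j] <- if (denom == 0) P[j + 1L]
            else P[j + 1L] + census$A[j] / denom * (1 - P[j + 1L])
  }
  P <- P[seq_len(k1)]
  # the virtual limit sits below all data and is exceeded with certainty;
  # the recursion already yields 1 whenever any detect lies below L_1
  P[1L] <- 1
  stopifnot(all(P >= 0), all(P <= 1), all(diff(P) <= 1e-12))
  P
}

#' Weibull plotting positions for multiply censored data
#'
#' Detected values falling in censoring interval j, ranked ascending
#' i = 1..A_j, receive p = (1 - P_j) + (P_j - P_(j+1)) i / (A_j + 1);
#' censored values at limit L_j, i = 1..C_j, receive
#' p = (1 - P_j) i / (C_j + 1).  With no censoring this reduces exactly
#' to the Weibull position i / (n + 1).
#'
#' @param values,censored As in [censoring_intervals()].
#' @param census Optional precomputed census.
#' @param P Optional precomputed exceedance probabilities.
#' @return Numeric vector of plotting positions parallel to `values`,
#'   all strictly inside (0, 1).
#' @export
ros_plotting_positions <- function(values, censored, census = NULL, P = NULL) {
  if (is.null(census)) census <- censoring_intervals(values, censored)
  if (is.null(P)) P <- exceedance_recursion(census)
  L <- census$limits
  k1 <- length(L)
  Pnext <- c(P[-1L], 0)
  upper <- c(L[-1L], Inf)
  p <- numeric(length(values))
  for (j in seq_len(k1)) {
    det_j <- which(!censored & values >= L[j] & values < upper[j])
    if (length(det_j) > 0L) {
      ranks <- rank(values[det_j], ties.method = "first")
      p[det_j] <- (1 - P[j]) +
        (P[j] - Pnext[j]) * ranks / (length(det_j) + 1)
    }
    if (j > 1L) {
      cen_j <- which(censored & values == L[j])
      if (length(cen_j) > 0L)
        p[cen_j] <- (1 - P[j]) * seq_along(cen_j) / (length(cen_j) + 1)
    }
  }
  stopifnot(all(p > 0), all(p < 1))
  p
}

#' Fit a robust ROS model to left-censored concentrations
#'
#' Regresses the natural log of the detected values on the normal scores
#' of their plotting positions, imputes each censored observation from the
#' fitted line at its own plotting position, and computes summary
#' statistics on the combined set of observed and imputed values in
#' original units.  Imputed values support the summary statistics only and
#' are never reported as measurements.
#'
#' @param values Numeric, all > 0: detected value or reporting limit.
#' @param censored Logical vector parallel to `values`.
#' @return An object of class `ros_fit`; see Details.
#' @details The fit requires at least 3 detected values with at least 2
#'   distinct magnitudes; anything less is an unsupported input and errors
#'   (near-fully-censored strata are reported as unavailable, not
#'   guessed).  The summary uses type-7 quantiles (linear interpolation
#'   between order statistics).  With zero censored observations the
#'   summary equals the ordinary sample statistics exactly.
#' @examples
#' f <- ros_fit(c(1, 1.5, 2, 2.5, 5), c(TRUE, FALSE, TRUE, FALSE, FALSE))
#' f$summary["median"]
#' @export
ros_fit <- function(values, censored) {
  n <- length(values)
  stopifnot(length(censored) == n)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("ros_fit requires all values and reporting limits to be > 0")
  detects <- values[!censored]
  if (length(detects) < 3L)
    stop("ros_fit requires at least 3 detected values (got ",
         length(detects), ")")
  if (length(unique(detects)) < 2L)
    stop("ros_fit requires at least 2 distinct detected magnitudes")

  census <- censoring_intervals(values, censored)
  P <- exceedance_recursion(census)
  p <- ros_plotting_positions(values, censored, census, P)
  z <- stats::qnorm(p)

  fit <- stats::lm.fit(cbind(1, z[!censored]), log(detects))
  intercept <- unname(fit$coefficients[1L])
  slope <- unname(fit$coefficients[2L])

  imputed <- exp(intercept + slope * z[censored])
  combined <- values
  combined[censored] <- imputed

  qs <- stats::quantile(combined, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                        names = FALSE)
  summary <- c(n = n, n_censored = sum(censored),
               mean = mean(combined), sd = stats::sd(combined),
               p10 = qs[1L], q1 = qs[2L], median = qs[3L], q3 = qs[4L],
               p90 = qs[5L], iqr = qs[4L] - qs[2L])
  structure(list(n_total = n, n_censored = sum(censored),
                 censoring_levels = census$limits[-1L],
                 exceedance_probs = P,
                 plotting_positions = p,
                 slope = slope, intercept = intercept,
                 imputed_values = imputed,
                 combined_values = combined,
                 summary = summary),
            class = "ros_fit")
}

#' @export
print.ros_fit <- function(x, ...) {
  cat(sprintf("Robust ROS fit: n = %d (%d censored at %d level%s)\n",
              x$n_total, x$n_censored, length(x$censoring_levels),
              if (length(x$censoring_levels) == 1L) "" else "s"))
  cat(sprintf("  log-scale intercept %.4f, slope %.4f\n",
              x$intercept, x$slope))
  cat(sprintf("  mean %.3g  median %.3g  sd %.3g  IQR %.3g-%.3g ug/L\n",
              x$summary["mean"], x$summary["median"], x$summary["sd"],
              x$summary["q1"], x$summary["q3"]))
  invisible(x)
}

#' Serialize a ROS fit to JSON
#'
#' @param fit A `ros_fit`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
ros_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ros_fit"))
  obj <- unclass(fit)
  obj$summary <- as.list(obj$summary)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fraction of observations that are detections
#'
#' @param censored Logical vector (or a `values`/`censored` pair; only the
#'   flags matter).
#' @return Fraction detected in \[0, 1\].
#' @export
detection_frequency <- function(censored) {
  if (length(censored) == 0L)
    stop("detection_frequency requires at least one observation")
  mean(!censored)
}
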