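# Exceedance classification, co-occurrence correlation and the censored
# two-group comparison used for the near/far mine contrast.

#' Classify MCL exceedance for censored analysis values
#'
#' A detected value strictly greater than the threshold exceeds; a
#' censored observation never exceeds, but when its reporting limit lies
#' above the threshold the truth is unknowable and the observation is
#' flagged indeterminate for diagnostics.
#'
#' @param value Numeric: detected value or reporting limit (ug/L).
#' @param censored Logical vector parallel to `value`.
#' @param threshold Positive threshold (ug/L).
#' @return Data frame with logical columns `exceeds` and `indeterminate`.
#' @export
classify_exceedance <- function(value, censored, threshold) {
  stopifnot(length(threshold) == 1L, threshold > 0,
            length(value) == length(censored))
  data.frame(exceeds = !censored & value > threshold,
             indeterminate = censored & value > threshold)
}

#' Joint exceedance classification for paired arsenic/uranium values
#'
#' @param as_value,as_censored Arsenic analysis value and flag.
#' @param u_value,u_censored Uranium analysis value and flag.
#' @param config An [analysis_config()].
#' @return Data frame with logical columns `exceeds_both`,
#'   `exceeds_half_both`, `detected_both`.
#' @export
co_exceedance <- function(as_value, as_censored, u_value, u_censored,
                          config = analysis_config()) {
  a_full <- classify_exceedance(as_value, as_censored, config$mcl_arsenic)
  u_full <- classify_exceedance(u_value, u_censored, config$mcl_uranium)
  a_half <- classify_exceedance(as_value, as_censored,
                                config$half_mcl_fraction * config$mcl_arsenic)
  u_half <- classify_exceedance(u_value, u_censored,
                                config$half_mcl_fraction * config$mcl_uranium)
  data.frame(exceeds_both = a_full$exceeds & u_full$exceeds,
             exceeds_half_both = a_half$exceeds & u_half$exceeds,
             detected_both = !as_censored & !u_censored)
}

#' Kendall rank correlation of paired analysis values
#'
#' Tie-corrected Kendall tau-b with censored observations entered at
#' their reporting limits, so two results censored at the same limit are
#' indistinguishable and tie.  The p-value uses the normal approximation
#' with tie-corrected variance.  The bound substitution biases tau toward
#' zero when censoring is heavy; a fully censored-data tau is out of
#' scope.
#'
#' @param x,y Paired analysis values (detected value or reporting limit);
#'   at least 10 pairs.
#' @return List with `tau` and `p_value`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L)
    stop("kendall_tau requires at least 10 pairs (got ", length(x), ")")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

# Peto-Peto weights and score on flipped data; shared by the public test.
# Returns the weighted score for membership in group `b` and its variance.
peto_peto_score <- function(time, event, in_b) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; in_b <- in_b[ord]
  dt <- sort(unique(time[event]))
  score <- 0; var <- 0
  surv <- 1
  for (t in dt) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    dj <- sum(event & time == t)
    n1j <- sum(at_risk & in_b)
    d1j <- sum(event & time == t & in_b)
    w <- surv                     # pooled KM just before t (G-rho, rho = 1)
    ej <- dj * n1j / nj
    vj <- if (nj > 1) dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
          else 0
    score <- score + w * (d1j - ej)
    var <- var + w^2 * vj
    surv <- surv * (nj - dj) / nj
  }
  list(score = score, var = var)
}

#' Peto-Peto two-group test for left-censored concentrations
#'
#' Flips the data to right-censored form (subtracting from a constant
#' above the maximum magnitude), then computes the Peto-Peto generalized
#' Wilcoxon score test — a weighted log-rank statistic whose weights are
#' the pooled Kaplan-Meier estimate just before each event time (the
#' G-rho family at rho = 1).  The squared normalized score
#' is reported as a chi-square statistic with 1 degree of freedom.  The
#' result is invariant to the choice of flip constant because the
#' statistic depends only on ranks.
#'
#' @param values_a,censored_a First group: analysis values and flags.
#' @param values_b,censored_b Second group.
#' @return List of class `peto_peto_test`: `statistic` (chi-square, 1 df),
#'   `p_value`, `group_sizes`, `score` (positive when group b tends to
#'   have *larger* concentrations than group a).
#' @export
peto_peto_test <- function(values_a, censored_a, values_b, censored_b) {
  stopifnot(length(values_a) == length(censored_a),
            length(values_b) == length(censored_b))
  if (length(values_a) < 5L || length(values_b) < 5L)
    stop("peto_peto_test requires at least 5 observations per group")
  if (all(censored_a) || all(censored_b))
    stop("peto_peto_test requires at least one detect per group")
  values <- c(values_a, values_b)
  censored <- c(censored_a, censored_b)
  in_b <- rep(c(FALSE, TRUE), c(length(values_a), length(values_b)))
  M <- max(values) + 1
  time <- M - values              # left-censored X < L -> T > M - L
  event <- !censored
  s <- peto_peto_score(time, event, in_b)
  stat <- if (s$var <= 0) 0 else s$score^2 / s$var
  # group-b mass at early flipped times (= large concentrations) makes the
  # raw score positive, so it already points toward "b larger"
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 group_sizes = c(a = length(values_a), b = length(values_b)),
                 score = s$score),
            class = "peto_peto_test")
}

#' @export
print.peto_peto_test <- function(x, ...) {
  cat(sprintf(
    "Peto-Peto two-group test: X^2 = %.3g (1 df), p = %.3g (n = %d, %d)\n",
    x$statistic, x$p_value, x$group_sizes[1L], x$group_sizes[2L]))
  invisible(x)
}

#' Single-analyte exceedance summary for one stratum
#'
#' Builds one summary row in the layout of the regional tables: sample
#' size, detection frequency, ROS median and IQR, and the fraction of
#' sources exceeding the MCL.  Strata too censored for the ROS fit are
#' reported with the distributional statistics marked unavailable (`NA`)
#' rather than guessed.
#'
#' @param value,censored Analysis values and flags for the stratum.
#' @param threshold The analyte's MCL (ug/L).
#' @param stratum Stratum label.
#' @return One-row data frame.
#' @export
analyte_summary <- function(value, censored, threshold, stratum = "overall") {
  n <- length(value)
  cls <- classify_exceedance(value, censored, threshold)
  med <- q1 <- q3 <- NA_real_
  ros_ok <- sum(!censored) >= 3L && length(unique(value[!censored])) >= 2L
  if (ros_ok) {
    fit <- ros_fit(value, censored)
    med <- unname(fit$summary["median"])
    q1 <- unname(fit$summary["q1"])
    q3 <- unname(fit$summary["q3"])
  }
  data.frame(stratum = stratum, n = n,
             detection_frequency = detection_frequency(censored),
             ros_median = med, ros_q1 = q1, ros_q3 = q3,
             frac_exceed_mcl = mean(cls$exceeds),
             n_indeterminate = sum(cls$indeterminate),
             ros_unavailable = !ros_ok,
             stringsAsFactors = FALSE)
}

#' Joint arsenic-uranium summary for one stratum
#'
#' Co-detection frequency, Kendall correlation of the paired analysis
#' values, and the half-MCL and full-MCL co-exceedance fractions, for
#' sources carrying both analytes.  Sources missing an analyte are
#' skipped and counted in `n_skipped`.
#'
#' @param pairs Data frame with `as_value`, `as_censored`, `u_value`,
#'   `u_censored` (one row per source with both analytes).
#' @param config An [analysis_config()].
#' @param stratum Stratum label.
#' @param n_skipped Number of sources lacking one analyte.
#' @return One-row data frame.
#' @export
joint_summary <- function(pairs, config = analysis_config(),
                          stratum = "overall", n_skipped = 0L) {
  n <- nrow(pairs)
  co <- co_exceedance(pairs$as_value, pairs$as_censored,
                      pairs$u_value, pairs$u_censored, config)
  tau <- tau_p <- NA_real_
  if (n >= 10L) {
    kt <- kendall_tau(pairs$as_value, pairs$u_value)
    tau <- kt$tau; tau_p <- kt$p_value
  }
  data.frame(stratum = stratum, n = n,
             detection_frequency = mean(co$detected_both),
             tau = tau, tau_p = tau_p,
             frac_exceed_half_both = mean(co$exceeds_half_both),
             frac_exceed_both = mean(co$exceeds_both),
             n_skipped = n_skipped,
             stringsAsFactors = FALSE)
}
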