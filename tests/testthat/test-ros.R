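# The worked multiply-censored example used throughout:
# {<1, 1.5, <2, 2.5, 5} with limits 1 and 2.
ex_values <- c(1, 1.5, 2, 2.5, 5)
ex_censored <- c(TRUE, FALSE, TRUE, FALSE, FALSE)

test_that("interval census counts detects, belows and censored per level", {
  cs <- censoring_intervals(c(1, 2, 3), rep(FALSE, 3))
  expect_equal(length(cs$limits), 1L)      # only the virtual limit
  expect_equal(cs$A, 3L)
  expect_equal(cs$B, 0L)

  cs <- censoring_intervals(ex_values, ex_censored)
  expect_equal(cs$limits[-1L], c(1, 2))
  expect_equal(cs$A, c(0L, 1L, 2L))        # [virtual,1), [1,2), [2,Inf)
  expect_equal(cs$C, c(0L, 1L, 1L))
  expect_equal(cs$B[3L], 3L)               # 1.5 plus both nondetects
  expect_equal(sum(cs$A) + sum(cs$C), cs$n_total)
})

test_that("a detect equal to a limit belongs to the closed-left interval", {
  cs <- censoring_intervals(c(2, 2.0), c(TRUE, FALSE))
  # detect 2.0 counts in the interval starting at limit 2, not below it
  expect_equal(cs$A, c(0L, 1L))
  expect_equal(cs$B, c(0L, 1L))            # only the nondetect lies below
})

test_that("exceedance recursion reproduces hand-computed probabilities", {
  cs <- censoring_intervals(ex_values, ex_censored)
  P <- exceedance_recursion(cs)
  expect_equal(P[3L], 0.4)                       # 2/(2+3)
  expect_equal(P[2L], 0.4 + (1 / 2) * 0.6)       # 0.7
  # single censored value below all detects: {<1, 2, 3}
  cs2 <- censoring_intervals(c(1, 2, 3), c(TRUE, FALSE, FALSE))
  P2 <- exceedance_recursion(cs2)
  expect_equal(P2[2L], 2 / 3)
  expect_equal(P2[1L], 1)                        # virtual level
  # no censoring: all mass above the virtual limit
  expect_equal(exceedance_recursion(censoring_intervals(1:4, rep(FALSE, 4))),
               1)
})

test_that("recursion equals flipped-data Kaplan-Meier on small instances", {
  # deterministic enumeration of censoring patterns over a value grid,
  # including detect-equals-limit ties, then seeded random cases to n=12
  run_case <- function(values, censored) {
    if (all(censored) || !any(censored)) return(invisible(NULL))
    cs <- censoring_intervals(values, censored)
    P <- exceedance_recursion(cs)
    km <- km_exceedance_oracle(values, censored, cs$limits[-1L])
    expect_equal(unname(P[-1L]), unname(km), tolerance = 1e-12)
  }
  grid <- list(c(1, 2, 3), c(1, 1, 2), c(2, 2, 2, 5), c(1, 2, 2, 3, 5))
  for (v in grid) {
    n <- length(v)
    for (mask in 0:(2^n - 1)) {
      censored <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      run_case(v, censored)
    }
  }
  set.seed(20)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    v <- sample(1:6, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    censored <- stats::runif(n) < 0.4
    run_case(v, censored)
  }
})

test_that("uncensored plotting positions reduce to Weibull i/(n+1)", {
  expect_equal(ros_plotting_positions(c(1, 2, 3, 4), rep(FALSE, 4)),
               (1:4) / 5)
  set.seed(3)
  for (n in c(3, 7, 20)) {
    x <- stats::rlnorm(n)
    expect_equal(sort(ros_plotting_positions(x, rep(FALSE, n))),
                 (1:n) / (n + 1))
  }
})

test_that("plotting positions match hand computation for censored data", {
  p <- ros_plotting_positions(ex_values, ex_censored)
  expect_equal(p[2L], 0.3 + 0.3 * (1 / 2))            # detected 1.5
  expect_equal(p[4L], 0.6 + 0.4 * (1 / 3))            # detected 2.5
  expect_equal(p[5L], 0.6 + 0.4 * (2 / 3))            # detected 5
  expect_equal(p[1L], (1 - 0.7) * (1 / 2))            # censored <1
  expect_equal(p[3L], (1 - 0.4) * (1 / 2))            # censored <2
  expect_true(all(p > 0 & p < 1))
})

test_that("plotting positions are invariant under input permutation", {
  set.seed(8)
  for (rep in 1:15) {
    n <- sample(4:15, 1)
    v <- round(stats::rlnorm(n, 0, 1), 2) + 0.01
    cen <- stats::runif(n) < 0.3
    if (sum(!cen) == 0) next
    perm <- sample(n)
    p1 <- ros_plotting_positions(v, cen)
    p2 <- ros_plotting_positions(v[perm], cen[perm])
    # compare as value/flag-keyed multisets
    k1 <- order(cen, v, p1); k2 <- order(cen[perm], v[perm], p2)
    expect_equal(p2[k2], p1[k1])
  }
})

test_that("fully detected data gives ordinary sample statistics exactly", {
  x <- c(1, 2, 3, 4, 5)
  f <- ros_fit(x, rep(FALSE, 5))
  expect_identical(f$combined_values, x)
  expect_equal(unname(f$summary["mean"]), 3)
  expect_equal(unname(f$summary["median"]), 3)
  expect_equal(unname(f$summary["sd"]), stats::sd(x))
  expect_equal(unname(f$summary["iqr"]),
               unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7))))
  set.seed(11)
  y <- stats::rlnorm(40, 1, 0.7)
  g <- ros_fit(y, rep(FALSE, 40))
  expect_equal(unname(g$summary["mean"]), mean(y))
  expect_equal(unname(g$summary["p90"]),
               unname(stats::quantile(y, 0.9, type = 7)))
})

test_that("the full ROS chain matches a spreadsheet-style hand oracle", {
  # independent computation: hand plotting positions, closed-form least
  # squares of log detects on normal scores, imputation from the line
  p_det <- c(0.45, 0.6 + 0.4 / 3, 0.6 + 0.8 / 3)
  z <- stats::qnorm(p_det)
  y <- log(c(1.5, 2.5, 5))
  slope_o <- sum((z - mean(z)) * (y - mean(y))) / sum((z - mean(z))^2)
  int_o <- mean(y) - slope_o * mean(z)
  z_cen <- stats::qnorm(c(0.15, 0.30))
  imp_o <- exp(int_o + slope_o * z_cen)
  comb_o <- c(imp_o[1L], 1.5, imp_o[2L], 2.5, 5)

  f <- ros_fit(ex_values, ex_censored)
  expect_equal(f$slope, slope_o, tolerance = 1e-12)
  expect_equal(f$intercept, int_o, tolerance = 1e-12)
  expect_equal(f$imputed_values, imp_o, tolerance = 1e-12)
  expect_equal(sort(f$combined_values), sort(comb_o), tolerance = 1e-12)
  expect_equal(unname(f$summary["mean"]), mean(comb_o), tolerance = 1e-12)
  expect_equal(unname(f$summary["median"]),
               unname(stats::quantile(comb_o, 0.5, type = 7)),
               tolerance = 1e-12)
  # combined set is the union of observed detects and positive imputations
  expect_true(all(f$imputed_values > 0))
  expect_setequal(f$combined_values[!ex_censored], c(1.5, 2.5, 5))
})

test_that("imputed values respect their interval's probability bound", {
  set.seed(21)
  for (rep in 1:10) {
    s <- censored_lognormal(60, 1, 0.6, limits = c(1.5, 3))
    if (sum(s$censored) < 2 || sum(!s$censored) < 3) next
    f <- ros_fit(s$values, s$censored)
    cs <- censoring_intervals(s$values, s$censored)
    P <- exceedance_recursion(cs)
    for (j in seq_along(cs$limits[-1L])) {
      L <- cs$limits[j + 1L]
      at <- which(s$values[s$censored] == L)
      if (length(at) == 0) next
      bound <- exp(f$intercept + f$slope * stats::qnorm(1 - P[j + 1L]))
      expect_true(all(f$imputed_values[at] <= bound + 1e-9))
      # within a limit, imputations increase with rank
      expect_true(all(diff(f$imputed_values[at]) >= 0))
    }
  }
})

test_that("slope recovers the lognormal shape on censored samples", {
  set.seed(99)
  x <- stats::rlnorm(1000, meanlog = 1, sdlog = 0.5)
  lim <- sample(c(1.0, 2.5), 1000, replace = TRUE)
  cen <- x < lim
  f <- ros_fit(ifelse(cen, lim, x), cen)
  expect_gt(mean(cen), 0.15)
  expect_equal(f$slope, 0.5, tolerance = 0.1)
  expect_equal(f$intercept, 1, tolerance = 0.1)
})

test_that("unsupported inputs error with the violated precondition", {
  expect_error(ros_fit(c(1, 2, 3), c(TRUE, TRUE, FALSE)), "3 detected")
  expect_error(ros_fit(c(2, 2, 2), rep(FALSE, 3)), "distinct")
  expect_error(ros_fit(c(0, 1, 2), rep(FALSE, 3)), "> 0")
})

test_that("detection frequency is the detected fraction", {
  expect_equal(detection_frequency(rep(FALSE, 4)), 1)
  expect_equal(detection_frequency(ex_censored), 0.6)
  expect_equal(detection_frequency(rep(TRUE, 3)), 0)
  expect_error(detection_frequency(logical(0)), "at least one")
})

test_that("ros_fit serializes to parseable JSON", {
  f <- ros_fit(ex_values, ex_censored)
  parsed <- jsonlite::fromJSON(ros_fit_json(f))
  expect_equal(parsed$slope, f$slope)
  expect_equal(parsed$summary$median, unname(f$summary["median"]))
  expect_length(parsed$combined_values, 5L)
})
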