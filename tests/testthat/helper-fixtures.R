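# Shared fixtures and independent oracles used across the suite.

# Build a uws_data object in code (no files).
make_uws <- function(measurements, sources = NULL) {
  defaults <- data.frame(source_id = "s1", analyte = "arsenic",
                         value = NA_real_, censored = FALSE,
                         reporting_limit = NA_real_, units = "ug_per_L",
                         survey_id = "sv1", sample_date = "",
                         method_documented = TRUE, stringsAsFactors = FALSE)
  m <- measurements
  for (col in setdiff(names(defaults), names(m)))
    m[[col]] <- defaults[[col]]
  m <- m[names(defaults)]
  if (is.null(sources)) {
    ids <- unique(m$source_id)
    sources <- data.frame(source_id = ids,
                          lat = 36 + seq_along(ids) * 0.01,
                          lon = -109 - seq_along(ids) * 0.01,
                          region = "r1", source_type = "well",
                          stringsAsFactors = FALSE)
  }
  structure(list(sources = sources, measurements = m,
                 rejected = data.frame(row = integer(),
                                       source_id = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)),
            class = "uws_data")
}

# Flipped-data Kaplan-Meier oracle: probability of exceeding each level,
# via survival::survfit on right-censored flipped data.
km_exceedance_oracle <- function(values, censored, levels) {
  M <- max(values) + 1
  sf <- survival::survfit(
    survival::Surv(M - values, !censored) ~ 1)
  surv_at <- stats::stepfun(sf$time, c(1, sf$surv))
  vapply(levels, function(L) 1 - surv_at(M - L), 0)
}

# Brute-force O(n^2) Kendall tau-b with tie correction.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Left-censored sample from a lognormal with per-observation limits.
censored_lognormal <- function(n, meanlog, sdlog, limits) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  lim <- sample(limits, n, replace = TRUE)
  cen <- x < lim
  list(values = ifelse(cen, lim, x), censored = cen)
}
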