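# Data-selection rules applied before any statistics: convert uranium
# activity to mass, drop undocumented results, and collapse each source's
# measurement history to the single maximum observation per analyte.

#' Convert uranium activity to mass concentration
#'
#' Applies the fixed natural-uranium equivalence (default 0.67 pCi per ug
#' U): mass = activity / pci_per_ug.  The same factor applies to detected
#' values and to reporting limits — a censored activity bound becomes a
#' censored mass bound.
#'
#' @param activity Activity concentration(s) in pCi/L; must be >= 0.
#' @param pci_per_ug Equivalence factor in pCi per ug.  Default 0.67.
#' @return Mass concentration(s) in ug/L.
#' @examples
#' activity_to_mass(0.67)  # 1 ug/L
#' activity_to_mass(20.1)  # 30 ug/L, the uranium MCL
#' @export
activity_to_mass <- function(activity, pci_per_ug = 0.67) {
  if (!is.numeric(activity) || any(is.na(activity)))
    stop("activity must be numeric and non-missing")
  if (any(activity < 0)) stop("activity must be non-negative")
  if (!is.numeric(pci_per_ug) || length(pci_per_ug) != 1L || pci_per_ug <= 0)
    stop("pci_per_ug must be a single positive number")
  activity / pci_per_ug
}

#' Apply documentation-based inclusion rules
#'
#' Removes measurements whose laboratory method is undocumented or that
#' are censored without a stated reporting limit.  Sources left with no
#' measurement for either analyte are excluded entirely and reported with
#' a reason code.
#'
#' @param data A `uws_data` object.
#' @return A list with `included` (a `uws_data` object) and `excluded`
#'   (data frame: source_id, reason).
#' @export
apply_inclusion_rules <- function(data) {
  stopifnot(inherits(data, "uws_data"))
  m <- data$measurements
  keep <- m$method_documented &
    (!m$censored | (!is.na(m$reporting_limit) & m$reporting_limit > 0))
  m_kept <- m[keep, , drop = FALSE]
  surviving <- unique(m_kept$source_id)
  dropped_sources <- setdiff(data$sources$source_id, surviving)
  excluded <- data.frame(source_id = dropped_sources,
                         reason = rep("undocumented", length(dropped_sources)),
                         stringsAsFactors = FALSE)
  included <- data
  included$measurements <- m_kept
  included$sources <-
    data$sources[data$sources$source_id %in% surviving, , drop = FALSE]
  rownames(included$measurements) <- NULL
  rownames(included$sources) <- NULL
  list(included = included, excluded = excluded)
}

#' Collapse one source's measurements to the maximum observation
#'
#' Implements the exposure-screening reduction: when a source has several
#' results for one analyte, the maximum is retained.  A detected result
#' ranks by its value and a censored result by its reporting limit; if a
#' detected and a censored result tie at the maximum magnitude the
#' detected one is selected (it carries more information).
#'
#' @param values Numeric vector: detected value, or reporting limit where
#'   censored.  Must already be in ug/L.
#' @param censored Logical vector parallel to `values`.
#' @param survey_ids Optional provenance labels.
#' @return One-row data frame: `value_ug_L`, `censored`,
#'   `n_samples_collapsed`, `provenance`.
#' @export
max_per_source <- function(values, censored,
                           survey_ids = rep(NA_character_, length(values))) {
  n <- length(values)
  if (n == 0L) stop("max_per_source requires at least one measurement")
  stopifnot(length(censored) == n, is.numeric(values), all(values > 0))
  mx <- max(values)
  at_max <- which(values == mx)
  # tie-break: prefer a detected observation at the maximum magnitude
  pick <- if (any(!censored[at_max])) at_max[!censored[at_max]][1L]
          else at_max[1L]
  data.frame(value_ug_L = values[pick], censored = censored[pick],
             n_samples_collapsed = n,
             provenance = paste(unique(stats::na.omit(survey_ids)),
                                collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Harmonize a survey dataset to one analysis value per source and analyte
#'
#' Runs the full data-selection chain: uranium activity results are
#' converted to ug/L (values and reporting limits alike), undocumented
#' results are excluded, and each source's history is collapsed to its
#' maximum observation per analyte.
#'
#' @param data A `uws_data` object.
#' @param config An [analysis_config()].
#' @return A list with `values` (data frame: source_id, analyte,
#'   value_ug_L, censored, n_samples_collapsed, provenance) and
#'   `excluded` (from [apply_inclusion_rules()]).
#' @export
harmonize <- function(data, config = analysis_config()) {
  stopifnot(inherits(data, "uws_data"))
  inc <- apply_inclusion_rules(data)
  m <- inc$included$measurements
  if (nrow(m) > 0L) {
    is_act <- m$units == "pCi_per_L"
    m$value[is_act & !m$censored] <-
      activity_to_mass(m$value[is_act & !m$censored], config$pci_per_ug)
    m$reporting_limit[is_act & m$censored] <-
      activity_to_mass(m$reporting_limit[is_act & m$censored],
                       config$pci_per_ug)
    m$units <- "ug_per_L"
  }
  magnitude <- ifelse(m$censored, m$reporting_limit, m$value)
  keyed <- split(seq_len(nrow(m)),
                 list(m$source_id, m$analyte), drop = TRUE)
  rows <- lapply(keyed, function(idx) {
    out <- max_per_source(magnitude[idx], m$censored[idx], m$survey_id[idx])
    out$source_id <- m$source_id[idx[1L]]
    out$analyte <- m$analyte[idx[1L]]
    out
  })
  values <- do.call(rbind, rows)
  if (is.null(values)) {
    values <- data.frame(source_id = character(), analyte = character(),
                         value_ug_L = numeric(), censored = logical(),
                         n_samples_collapsed = integer(),
                         provenance = character(), stringsAsFactors = FALSE)
  } else {
    values <- values[, c("source_id", "analyte", "value_ug_L", "censored",
                         "n_samples_collapsed", "provenance")]
    values <- values[order(values$analyte, values$source_id), , drop = FALSE]
    rownames(values) <- NULL
  }
  list(values = values, excluded = inc$excluded,
       sources = inc$included$sources)
}
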