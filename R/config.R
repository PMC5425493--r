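#' Analysis configuration
#'
#' Bundles the regulatory and geometric constants used throughout the
#' pipeline: the US drinking-water Maximum Contaminant Levels (MCLs) for
#' arsenic and uranium, the uranium activity-to-mass equivalence, the
#' mine-proximity partition threshold, and reporting options.
#'
#' @param mcl_arsenic Arsenic MCL in ug/L.  Default 10.
#' @param mcl_uranium Uranium MCL in ug/L.  Default 30.
#' @param half_mcl_fraction Fraction of the MCL used for the "half both
#'   MCLs" co-exceedance screen.  Default 0.5.
#' @param pci_per_ug Uranium activity-to-mass equivalence in pCi per ug U.
#'   Default 0.67, the standard isotopic-composition assumption for
#'   natural uranium.
#' @param distance_threshold_km Distance defining "near" a mine, km.
#'   Default 6.4 (4 miles).
#' @param profile_bin_km Bin width of the distance-concentration profile,
#'   km.  Default 5.
#' @param alpha Significance levels flagged in reports.  Default
#'   `c(0.01, 0.001)`.
#' @return An object of class `aquaros_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$mcl_arsenic
#' @export
analysis_config <- function(mcl_arsenic = 10,
                            mcl_uranium = 30,
                            half_mcl_fraction = 0.5,
                            pci_per_ug = 0.67,
                            distance_threshold_km = 6.4,
                            profile_bin_km = 5,
                            alpha = c(0.01, 0.001)) {
  num <- c(mcl_arsenic = mcl_arsenic, mcl_uranium = mcl_uranium,
           half_mcl_fraction = half_mcl_fraction, pci_per_ug = pci_per_ug,
           distance_threshold_km = distance_threshold_km,
           profile_bin_km = profile_bin_km)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all configuration values must be finite and strictly positive")
  if (half_mcl_fraction >= 1)
    stop("half_mcl_fraction must lie in (0, 1)")
  structure(list(mcl_arsenic = mcl_arsenic,
                 mcl_uranium = mcl_uranium,
                 half_mcl_fraction = half_mcl_fraction,
                 pci_per_ug = pci_per_ug,
                 distance_threshold_km = distance_threshold_km,
                 profile_bin_km = profile_bin_km,
                 alpha = sort(alpha, decreasing = TRUE)),
            class = "aquaros_config")
}

#' Read a flat key-value configuration file
#'
#' Lines have the form `key = value`; blank lines and lines starting with
#' `#` are ignored.  Recognised keys are the arguments of
#' [analysis_config()]; unknown keys are an error so typos fail loudly.
#'
#' @param path Path to the configuration file.
#' @return An `aquaros_config` object with file values overriding defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(analysis_config())
  parts <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", lines))
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("unparseable config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(parts, `[[`, "", 2L)
  vals <- lapply(parts, function(p) {
    v <- as.numeric(strsplit(p[[3L]], "[,; ]+")[[1L]])
    if (any(is.na(v))) stop("non-numeric config value in line: ", p[[1L]])
    v
  })
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  names(vals) <- keys
  do.call(analysis_config, vals)
}

#' @export
print.aquaros_config <- function(x, ...) {
  cat("Water-quality analysis configuration\n")
  cat(sprintf("  MCL arsenic:         %g ug/L\n", x$mcl_arsenic))
  cat(sprintf("  MCL uranium:         %g ug/L\n", x$mcl_uranium))
  cat(sprintf("  half-MCL fraction:   %g\n", x$half_mcl_fraction))
  cat(sprintf("  U activity to mass:  %g pCi/ug\n", x$pci_per_ug))
  cat(sprintf("  proximity threshold: %g km\n", x$distance_threshold_km))
  cat(sprintf("  profile bin width:   %g km\n", x$profile_bin_km))
  invisible(x)
}
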