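# End-to-end orchestration: read, harmonize, summarise overall and per
# region, partition by mine proximity, profile by distance, export
# GeoJSON, and record a run manifest.

#' Overall and per-region exceedance summaries
#'
#' Builds the three-block regional table: one arsenic block and one
#' uranium block (n, detection frequency, ROS median/IQR, MCL exceedance
#' fraction) and one joint block (co-detection, Kendall tau, half-MCL and
#' full-MCL co-exceedance), each with an overall row followed by one row
#' per region.
#'
#' @param values Harmonized values ([harmonize()]`$values`).
#' @param sources Source table with `source_id` and `region`.
#' @param config An [analysis_config()].
#' @return List of data frames `arsenic`, `uranium`, `joint`.
#' @export
region_summaries <- function(values, sources, config = analysis_config()) {
  region_of <- sources$region[match(values$source_id, sources$source_id)]
  regions <- sort(unique(sources$region))
  out <- list()
  for (analyte in c("arsenic", "uranium")) {
    sel <- values$analyte == analyte
    thr <- if (analyte == "arsenic") config$mcl_arsenic else
      config$mcl_uranium
    strata <- c(list(overall = which(sel)),
                lapply(stats::setNames(regions, regions),
                       function(r) which(sel & region_of == r)))
    rows <- lapply(names(strata), function(s) {
      idx <- strata[[s]]
      if (length(idx) == 0L)
        return(NULL)
      analyte_summary(values$value_ug_L[idx], values$censored[idx], thr,
                      stratum = s)
    })
    tab <- do.call(rbind, rows)
    tab$analyte <- analyte
    out[[analyte]] <- tab
  }
  pairs <- analyte_pairs(values)
  pair_region <- sources$region[match(pairs$source_id, sources$source_id)]
  jrows <- lapply(c("overall", regions), function(s) {
    p <- if (s == "overall") pairs else
      pairs[pair_region == s, , drop = FALSE]
    joint_summary(p, config, stratum = s,
                  n_skipped = if (s == "overall")
                    attr(pairs, "n_skipped") else 0L)
  })
  out$joint <- do.call(rbind, jrows)
  out
}

#' Per-source GeoJSON summary table
#'
#' @param values Harmonized values.
#' @param config An [analysis_config()].
#' @return Data frame keyed by `source_id` suitable for [write_geojson()].
#' @export
geojson_summaries <- function(values, config = analysis_config()) {
  wide <- analyte_pairs(values)
  # also keep single-analyte sources
  all_ids <- unique(values$source_id)
  out <- data.frame(source_id = all_ids, stringsAsFactors = FALSE)
  for (analyte in c("arsenic", "uranium")) {
    v <- values[values$analyte == analyte, , drop = FALSE]
    i <- match(out$source_id, v$source_id)
    pre <- if (analyte == "arsenic") "as" else "u"
    thr <- if (analyte == "arsenic") config$mcl_arsenic else
      config$mcl_uranium
    out[[paste0(pre, "_value")]] <- v$value_ug_L[i]
    out[[paste0(pre, "_censored")]] <- v$censored[i]
    cls <- classify_exceedance(ifelse(is.na(v$value_ug_L[i]), 0,
                                      v$value_ug_L[i]),
                               ifelse(is.na(v$censored[i]), TRUE,
                                      v$censored[i]), thr)
    ex <- cls$exceeds
    ex[is.na(v$value_ug_L[i])] <- NA
    out[[paste0("exceeds_", pre)]] <- ex
  }
  out
}

#' Run the full analysis pipeline
#'
#' Reads sources and mines, harmonizes, and writes the report bundle:
#' `summary_regions.csv` (three analyte blocks, overall + per region),
#' `summary_proximity.csv` and `proximity_tests.csv` (near/far blocks and
#' their two-group tests), `distance_profile.csv` (per-analyte binned
#' medians with the overall median as reference), `sources.geojson`, and
#' `manifest.json` (config snapshot, input digests, output digests,
#' stage timings, collected warnings).
#'
#' Fractions are written at full precision; companion `*_pct` columns
#' give percentages rounded to one decimal for display.
#'
#' @param sources_csv,mines_csv Input CSV paths.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param dialect Column dialect for the sources file.
#' @return Invisibly, a list with all computed tables and the manifest.
#' @export
run_pipeline <- function(sources_csv, mines_csv,
                         config = analysis_config(),
                         out_dir = ".", dialect = uws_dialect()) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings <<- c(timings, stats::setNames(t1 - t0, stage))
    t0 <<- t1
  }

  data <- withCallingHandlers(
    read_sources(sources_csv, dialect),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  if (nrow(data$rejected) > 0L)
    note(sprintf("%d input row(s) rejected during read", nrow(data$rejected)))
  mines <- read_mines(mines_csv)
  tick("read")

  harm <- harmonize(data, config)
  if (nrow(harm$excluded) > 0L)
    note(sprintf("%d source(s) excluded: %s", nrow(harm$excluded),
                 paste(harm$excluded$source_id, collapse = ",")))
  tick("harmonize")

  reg <- region_summaries(harm$values, harm$sources, config)
  summary_tab <- rbind(
    cbind(block = "arsenic",
          reg$arsenic[c("analyte", "stratum", "n", "detection_frequency",
                        "ros_median", "ros_q1", "ros_q3", "frac_exceed_mcl",
                        "n_indeterminate", "ros_unavailable")]),
    cbind(block = "uranium",
          reg$uranium[c("analyte", "stratum", "n", "detection_frequency",
                        "ros_median", "ros_q1", "ros_q3", "frac_exceed_mcl",
                        "n_indeterminate", "ros_unavailable")]))
  summary_tab$detection_frequency_pct <-
    round(100 * summary_tab$detection_frequency, 1)
  summary_tab$frac_exceed_mcl_pct <-
    round(100 * summary_tab$frac_exceed_mcl, 1)
  joint_tab <- reg$joint
  joint_tab$detection_frequency_pct <-
    round(100 * joint_tab$detection_frequency, 1)
  joint_tab$frac_exceed_half_both_pct <-
    round(100 * joint_tab$frac_exceed_half_both, 1)
  joint_tab$frac_exceed_both_pct <- round(100 * joint_tab$frac_exceed_both, 1)
  n_ind <- sum(summary_tab$n_indeterminate[summary_tab$stratum == "overall"])
  if (n_ind > 0L)
    note(sprintf("%d indeterminate exceedance classification(s)", n_ind))
  tick("region_summaries")

  prox <- nearest_mine(harm$sources, mines, config)
  part <- withCallingHandlers(
    partition_summaries(harm$values, prox, config),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  part$tables$detection_frequency_pct <-
    round(100 * part$tables$detection_frequency, 1)
  part$tables$frac_exceed_mcl_pct <-
    round(100 * part$tables$frac_exceed_mcl, 1)
  tests_tab <- do.call(rbind, lapply(names(part$tests), function(a) {
    tst <- part$tests[[a]]
    if (is.null(tst))
      data.frame(analyte = a, statistic = NA_real_, p_value = NA_real_,
                 n_far = NA_integer_, n_near = NA_integer_)
    else
      data.frame(analyte = a, statistic = tst$statistic,
                 p_value = tst$p_value,
                 n_far = unname(tst$group_sizes["a"]),
                 n_near = unname(tst$group_sizes["b"]))
  }))
  tick("proximity")

  profiles <- do.call(rbind, lapply(c("arsenic", "uranium"), function(a) {
    pr <- distance_profile(harm$values[harm$values$analyte == a, ,
                                       drop = FALSE],
                           prox, config$profile_bin_km)
    if (any(pr$substitution))
      note(sprintf("substitution fallback in %d %s profile bin(s)",
                   sum(pr$substitution), a))
    if (any(pr$low_n))
      note(sprintf("%d low-n %s profile bin(s)", sum(pr$low_n), a))
    cbind(analyte = a, as.data.frame(pr))
  }))
  tick("profile")

  gsum <- geojson_summaries(harm$values, config)
  src_geo <- harm$sources

  paths <- c(summary_regions = file.path(out_dir, "summary_regions.csv"),
             summary_joint = file.path(out_dir, "summary_joint.csv"),
             summary_proximity = file.path(out_dir, "summary_proximity.csv"),
             proximity_tests = file.path(out_dir, "proximity_tests.csv"),
             distance_profile = file.path(out_dir, "distance_profile.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"),
             geojson = file.path(out_dir, "sources.geojson"))
  utils::write.csv(summary_tab, paths["summary_regions"], row.names = FALSE)
  utils::write.csv(joint_tab, paths["summary_joint"], row.names = FALSE)
  joint_prox <- part$joint
  joint_prox$analyte <- "arsenic_and_uranium"
  utils::write.csv(rbind_fill(part$tables, joint_prox),
                   paths["summary_proximity"], row.names = FALSE)
  utils::write.csv(tests_tab, paths["proximity_tests"], row.names = FALSE)
  utils::write.csv(profiles, paths["distance_profile"], row.names = FALSE)
  utils::write.csv(harm$excluded, paths["exclusions"], row.names = FALSE)
  write_geojson(src_geo, gsum, paths["geojson"])
  tick("write")

  manifest <- list(
    config = unclass(config),
    inputs = list(sources_csv = unname(tools::md5sum(sources_csv)),
                  mines_csv = unname(tools::md5sum(mines_csv))),
    outputs = as.list(tools::md5sum(unname(paths))),
    timings_s = as.list(round(timings, 3)),
    n_sources = nrow(harm$sources),
    n_mines = nrow(mines),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(summary = summary_tab, joint = joint_tab,
                 proximity = part, proximity_tests = tests_tab,
                 profiles = profiles, prox = prox, harmonized = harm,
                 manifest = manifest, paths = paths))
}

# rbind data frames on the union of their columns, padding with NA.
rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (col in setdiff(cols, names(a))) a[[col]] <- NA
  for (col in setdiff(cols, names(b))) b[[col]] <- NA
  rbind(a[cols], b[cols])
}

#' Generate a synthetic dataset and write it to disk
#'
#' Writes `sources.csv` (flat measurement-per-row layout readable by
#' [read_sources()]), `mines.csv`, and `truth.json` holding the latent
#' generator state.
#'
#' @param spec A [generator_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, named vector of the three file paths.
#' @export
simulate_to_dir <- function(spec = generator_spec(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_survey(spec)
  paths <- c(sources = file.path(out_dir, "sources.csv"),
             mines = file.path(out_dir, "mines.csv"),
             truth = file.path(out_dir, "truth.json"))
  write_sources_csv(gen$data, paths["sources"])
  utils::write.csv(gen$mines, paths["mines"], row.names = FALSE)
  jsonlite::write_json(gen$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
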