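test_that("haversine reproduces the one-degree closed form", {
  # one degree of longitude on the equator: R * pi / 180
  expect_equal(haversine_km(0, 0, 0, 1), 6371.0088 * pi / 180,
               tolerance = 1e-3)
  expect_equal(haversine_km(36, -109, 36, -109), 0)
})

test_that("haversine is symmetric and satisfies the triangle inequality", {
  set.seed(17)
  for (rep in 1:30) {
    p <- matrix(c(stats::runif(3, -60, 60), stats::runif(3, -170, 170)),
                ncol = 2)
    dab <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    dba <- haversine_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    dac <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    dcb <- haversine_km(p[3, 1], p[3, 2], p[2, 1], p[2, 2])
    expect_equal(dab, dba, tolerance = 1e-9)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("nearest_mine picks the minimum and applies the strict threshold", {
  sources <- data.frame(source_id = c("a", "b"),
                        lat = c(36, 36), lon = c(-109, -108))
  mines <- data.frame(mine_id = c("m1", "m2"),
                      lat = c(36, 36.03), lon = c(-109, -109))
  pr <- nearest_mine(sources, mines)
  expect_equal(pr$nearest_mine_id[1L], "m1")
  expect_equal(pr$distance_km[1L], 0)
  expect_true(pr$near[1L])
  expect_false(pr$near[2L])            # ~90 km away
  expect_true(all(pr$distance_km >= 0))
  # ties broken by first mine in input order
  mines2 <- data.frame(mine_id = c("mA", "mB"),
                       lat = c(36.05, 35.95), lon = c(-109, -109))
  expect_equal(nearest_mine(sources[1L, ], mines2)$nearest_mine_id, "mA")
  expect_error(nearest_mine(sources, mines[0, ]), "at least one mine")
})

test_that("near is distance strictly below the configured threshold", {
  src <- data.frame(source_id = "s", lat = 36, lon = -109)
  d <- 6.4 / (6371.0088 * pi / 180) # degrees north for exactly 6.4 km
  mine <- data.frame(mine_id = "m", lat = 36 + d, lon = -109)
  pr <- nearest_mine(src, mine)
  expect_equal(pr$distance_km, 6.4, tolerance = 1e-6)
  expect_false(pr$near)                 # boundary is not "near"
})

test_that("partition counts sum to the total and strata summarise", {
  gen <- generate_survey(generator_spec(n_sources = 120, n_mines = 20,
                                        seed = 4))
  h <- harmonize(gen$data)
  pr <- nearest_mine(h$sources, gen$mines)
  # tiny near stratum: the two-group tests may be skipped with a warning
  ps <- suppressWarnings(partition_summaries(h$values, pr))
  for (a in c("arsenic", "uranium")) {
    tab <- ps$tables[ps$tables$analyte == a, ]
    expect_equal(sum(tab$n), sum(h$values$analyte == a))
    expect_setequal(tab$stratum, c("near", "far"))
  }
  expect_equal(sum(ps$joint$n), nrow(h$sources))
})

test_that("an all-far partition yields an n=0 near row and skipped test", {
  gen <- generate_survey(generator_spec(n_sources = 40, n_mines = 2,
                                        seed = 9))
  h <- harmonize(gen$data)
  pr <- nearest_mine(h$sources, gen$mines)
  pr$near <- FALSE                      # force the degenerate partition
  warns <- testthat::capture_warnings(
    ps <- partition_summaries(h$values, pr))
  expect_true(any(grepl("skipped", warns)))
  near_rows <- ps$tables[ps$tables$stratum == "near", ]
  expect_true(all(near_rows$n == 0))
  far_rows <- ps$tables[ps$tables$stratum == "far", ]
  expect_equal(sum(far_rows$n), nrow(h$values))
  expect_null(ps$tests$arsenic)
})

test_that("identical strata give a zero two-group statistic", {
  v <- c(1, 2, 3, 4, 5, 6); cen <- rep(FALSE, 6)
  t0 <- peto_peto_test(v, cen, v, cen)
  expect_equal(t0$statistic, 0)
})

test_that("distance profile bins partition the sources", {
  gen <- generate_survey(generator_spec(n_sources = 150, seed = 13))
  h <- harmonize(gen$data)
  pr <- nearest_mine(h$sources, gen$mines)
  va <- h$values[h$values$analyte == "arsenic", ]
  prof <- distance_profile(va, pr, bin_km = 5)
  expect_equal(sum(prof$n), nrow(va))
  expect_true(all(prof$bin_hi_km - prof$bin_lo_km == 5))
  expect_true(all(diff(prof$bin_lo_km) > 0))
  expect_equal(length(unique(prof$overall_median_ug_L)), 1L)
  # one giant bin degenerates to the overall summary
  prof1 <- distance_profile(va, pr, bin_km = 1e6)
  expect_equal(nrow(prof1), 1L)
  expect_equal(prof1$median_ug_L, prof1$overall_median_ug_L)
})

test_that("profile medians decline with distance for enriched generators", {
  gen <- generate_survey(generator_spec(n_sources = 500, n_mines = 80,
                                        seed = 2))
  h <- harmonize(gen$data)
  pr <- nearest_mine(h$sources, gen$mines)
  for (a in c("arsenic", "uranium")) {
    va <- h$values[h$values$analyte == a, ]
    prof <- distance_profile(va, pr, bin_km = 5)
    # substitution-fallback bins are flagged as not comparable ROS medians
    prof <- prof[prof$n >= 10 & !prof$substitution, ]
    ct <- stats::cor.test(prof$bin_lo_km, prof$median_ug_L,
                          method = "spearman", exact = FALSE)
    expect_lt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.05)
  }
})

test_that("sparse bins fall back to flagged substitution", {
  values <- data.frame(source_id = c("a", "b", "c"),
                       analyte = "arsenic",
                       value_ug_L = c(2, 1, 3), censored = c(FALSE, TRUE, FALSE),
                       stringsAsFactors = FALSE)
  prox <- data.frame(source_id = c("a", "b", "c"),
                     distance_km = c(1, 2, 30), near = c(TRUE, TRUE, FALSE))
  prof <- distance_profile(values, prox, bin_km = 5)
  expect_true(all(prof$substitution))  # <3 detects everywhere
  expect_true(prof$low_n[prof$bin_lo_km == 30])
  expect_equal(prof$median_ug_L[2L], 3) # single detected source
})
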