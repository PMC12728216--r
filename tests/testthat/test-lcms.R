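uv_time <- seq(0, 10, by = 1 / 120) # 2 Hz

test_that("peak detection recovers Gaussian apexes and areas", {
  # single noiseless Gaussian of unit area at 5.00 min
  sig <- stats::dnorm(uv_time, 5, 0.05)
  pk <- detect_peaks(uv_time, sig)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$apex_rt - 5), 1 / 120 + 1e-9)
  expect_lt(abs(pk$area - 1), 0.01) # closed-form Gaussian integral = 1
  expect_true(pk$start < pk$apex_rt, pk$apex_rt <= pk$end)
  # two disjoint Gaussians with true area ratio 3:1
  sig2 <- 3 * stats::dnorm(uv_time, 3, 0.05) + stats::dnorm(uv_time, 7, 0.05)
  pk2 <- detect_peaks(uv_time, sig2)
  expect_identical(nrow(pk2), 2L)
  expect_lt(abs(pk2$area[1] / pk2$area[2] - 3), 3 * 0.02)
  # flat trace with white noise only
  set.seed(7)
  expect_identical(nrow(detect_peaks(uv_time, rnorm(length(uv_time), 0, 0.2))), 0L)
  expect_error(detect_peaks(1:3, 1:3), "at least 5 points")
})

test_that("EIC extraction sums centroids within tolerance", {
  ms <- data.frame(scan_time_min = rep(1:5, each = 2),
                   mz = rep(c(500.0, 612.3), 5),
                   intensity = c(rbind(10 * (1:5), 99)))
  run <- chrom_run(data.frame(time_min = 1:5, a254 = 0), ms)
  eic <- extract_eic(run, 500.0, tol = 0.5)
  expect_identical(eic$intensity, as.numeric(10 * (1:5)))
  # absent target -> all zeros
  expect_identical(extract_eic(run, 800, tol = 0.5)$intensity, rep(0, 5))
  # both centroids inside a wide window are summed
  eic2 <- extract_eic(run, 556, tol = 60)
  expect_identical(eic2$intensity, as.numeric(10 * (1:5) + 99))
})

test_that("UV matching picks the nearest apex with area tie-breaking", {
  eic_pk <- data.frame(apex_rt = 5.02, start = 4.9, end = 5.1, height = 1, area = 1)
  uv_pk <- data.frame(apex_rt = c(5.00, 7.10), start = c(4.9, 7.0),
                      end = c(5.1, 7.2), height = c(2, 3), area = c(10, 30))
  m <- match_target(eic_pk, uv_pk, rt_tol = 0.2)
  expect_identical(m$uv_index, 1L)
  expect_identical(m$flag, "")
  # nothing within tolerance
  m2 <- match_target(data.frame(apex_rt = 6, start = 5.9, end = 6.1,
                                height = 1, area = 1), uv_pk, rt_tol = 0.2)
  expect_identical(m2$flag, "not-found")
  # equidistant apexes: larger area wins, flagged
  uv_tie <- data.frame(apex_rt = c(4.95, 5.05), start = c(4.8, 5.0),
                       end = c(5.0, 5.2), height = c(1, 1), area = c(5, 50))
  m3 <- match_target(data.frame(apex_rt = 5.00, start = 4.9, end = 5.1,
                                height = 1, area = 1), uv_tie, rt_tol = 0.2)
  expect_identical(m3$uv_index, 2L)
  expect_identical(m3$flag, "multiple-candidates")
})

test_that("conversion percent covers area, aggregate and normalized modes", {
  pk <- function(area) data.frame(apex_rt = seq_along(area), start = 0, end = 1,
                                  height = area, area = area)
  expect_equal(conversion_percent(pk(42), 1, "area")$conversion_pct, 100)
  expect_equal(conversion_percent(pk(c(75, 25)), 1, "area")$conversion_pct, 75)
  # aggregate: parent 40 + adduct 20 over total 100
  agg <- conversion_percent(pk(c(40, 20, 40)), c(1, 2), "aggregate")
  expect_equal(agg$conversion_pct, 60)
  # normalized: denominator restricted to MS-identified peaks
  nrm <- conversion_percent(pk(c(30, 10, 60)), 1, "normalized", identified_index = c(1, 2))
  expect_equal(nrm$conversion_pct, 75)
  # unmatched -> 0 with flag; all-zero total errors
  expect_identical(conversion_percent(pk(c(1, 2)), integer(0), "area")$flags, "not-found")
  expect_error(conversion_percent(pk(0), 1, "area"), "undefined conversion")
})

test_that("noiseless simulated runs round-trip conversion exactly", {
  camp <- enumerate_campaign()
  spec <- camp$complexes[camp$complexes$id == "Re(CO)3(M1Y1)", ]
  sp <- make_species_frame(spec, rts = 5.0, fractions = 0.75)
  sim <- sim_chromatogram(sp, noise_sd = 0, seed = 1)
  res <- characterize_library(stats::setNames(list(sim$run), spec$id), spec)
  expect_equal(res$table$conversion_pct, 75, tolerance = 1e-4)
  expect_equal(res$table$rt_min, 5, tolerance = 0.02)
  # invariance to uniform UV scaling (area-percent is scale free)
  run2 <- sim$run
  run2$uv$a254 <- run2$uv$a254 * 37
  res2 <- characterize_library(stats::setNames(list(run2), spec$id), spec)
  expect_equal(res2$table$conversion_pct, res$table$conversion_pct, tolerance = 1e-9)
})

test_that("recovered conversion converges to truth as noise shrinks", {
  camp <- enumerate_campaign()
  spec <- camp$complexes[camp$complexes$id == "IrCN(M4Y1)", ]
  errs <- vapply(c(1.0, 0.3, 0.0), function(ns) {
    sim <- sim_chromatogram(make_species_frame(spec, 4.2, 0.6), noise_sd = ns, seed = 42)
    res <- characterize_library(stats::setNames(list(sim$run), spec$id), spec)
    abs(res$table$conversion_pct - 60)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9 + 0.5)) # non-increasing within jitter
  expect_lt(errs[3], 1e-4)
})

test_that("aggregate mode sums the IrCp* parent and MeCN adduct species", {
  camp <- enumerate_campaign()
  spec <- camp$complexes[camp$complexes$id == "IrCp*(P1A1)", ]
  sp <- make_species_frame(spec, rts = c(4.0, 5.5), fractions = c(0.4, 0.2))
  sim <- sim_chromatogram(sp, noise_sd = 0, seed = 1)
  res <- characterize_library(stats::setNames(list(sim$run), spec$id), spec)
  expect_equal(res$table$conversion_pct, 60, tolerance = 1e-3)
  expect_identical(res$table$species, "M+;M2+ (MeCN adduct)")
})

test_that("library characterization summarises a known 12-compound library", {
  camp <- enumerate_campaign()
  specs <- camp$complexes[camp$complexes$scaffold_id == "Re(CO)3", ][1:12, ]
  set.seed(9)
  truth <- runif(12, 0.3, 1.0)
  runs <- stats::setNames(lapply(seq_len(12), function(i) {
    sim_chromatogram(make_species_frame(specs[i, ], 3 + 0.3 * i, truth[i]),
                     noise_sd = 0.3, seed = 100 + i)$run
  }), specs$id)
  res <- characterize_library(runs, specs)
  expect_true(all(abs(res$table$conversion_pct - 100 * truth) < 2))
  expect_lt(abs(res$summary$mean - mean(100 * truth)), 1)
  expect_match(res$summary$label, "^\\d+ ± \\d+%$")
  # all-100% library: mean 100, SD 0
  runs100 <- stats::setNames(lapply(seq_len(3), function(i) {
    sim_chromatogram(make_species_frame(specs[i, ], 4, 1.0),
                     noise_sd = 0, seed = i)$run
  }), specs$id[1:3])
  res100 <- characterize_library(runs100, specs[1:3, ])
  expect_equal(res100$summary$mean, 100, tolerance = 1e-6)
  expect_equal(res100$summary$sd, 0, tolerance = 1e-6)
  # missing run reported as absent, not an error
  resmiss <- characterize_library(runs[1], specs[1:2, ])
  expect_identical(resmiss$table$flags[2], "absent")
})

test_that("chromatogram dialect round-trips through CSV files", {
  camp <- enumerate_campaign()
  spec <- camp$complexes[1, ]
  sim <- sim_chromatogram(make_species_frame(spec, 5, 0.8), noise_sd = 0.2, seed = 3)
  stem <- file.path(withr::local_tempdir(), "run1")
  write_chrom_run(sim$run, stem)
  back <- read_chrom_run(stem)
  expect_equal(back$uv$a254, sim$run$uv$a254, tolerance = 1e-9)
  expect_equal(back$ms$mz, sim$run$ms$mz, tolerance = 1e-9)
})
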