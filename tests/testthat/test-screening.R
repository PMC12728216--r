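test_that("dilution grids reproduce the printed concentration values", {
  expect_identical(dilution_grid(50, 2, 7),
                   c(50, 25, 12.5, 6.25, 3.13, 1.56, 0.78, 0.39))
  g <- dilution_grid(100, 2, 11)
  expect_identical(length(g), 12L)
  expect_identical(g[12], 0.049) # 100 / 2^11 = 0.0488 reported as 0.049
  expect_identical(dilution_grid(7, 2, 0), 7)
  # raw grid is exact powers
  expect_equal(dilution_grid(50, 2, 7, report = FALSE), 50 / 2^(0:7), tolerance = 1e-12)
  expect_error(dilution_grid(-1, 2, 3), "invalid")
  expect_error(dilution_grid(50, 1, 3), "invalid")
})

test_that("percent of control normalizes against growth and blank wells", {
  expect_equal(percent_of_control(0.9, 0.9, 0.1), 100)
  expect_equal(percent_of_control(0.1, 0.9, 0.1), 0)
  expect_equal(percent_of_control(0.5, 0.9, 0.1), 50)
  expect_equal(percent_of_control(0.05, 0.9, 0.1), 0) # clipped below at 0
  expect_error(percent_of_control(0.5, 0.1, 0.2), "degenerate")
})

test_that("MIC calling uses the highest contiguous inhibited block", {
  grid <- dilution_grid(50, 2, 7)
  mic <- call_mic(grid, c(0, 0, 0, 0, 80, 95, 99, 100))
  expect_identical(mic$value, 6.25)
  expect_false(mic$censored)
  # growth everywhere above threshold -> censored, rendered "-"
  cens <- call_mic(grid, rep(90, 8))
  expect_true(cens$censored)
  expect_identical(cens$display, "-")
  # non-monotone series: inhibited at 50, growth at 25, inhibited at 12.5
  nm <- call_mic(grid, c(5, 80, 5, 5, 90, 95, 99, 100))
  expect_identical(nm$value, 50)
  # order independence
  o <- sample(8)
  expect_identical(call_mic(grid[o], c(0, 0, 0, 0, 80, 95, 99, 100)[o])$value, 6.25)
})

test_that("MIC is monotone under added high-concentration inhibition", {
  grid <- dilution_grid(50, 2, 7)
  set.seed(3)
  for (k in 1:25) {
    growth <- runif(8, 0, 100)
    m1 <- call_mic(grid, growth)
    growth2 <- growth
    growth2[1:sample(8, 1)] <- 0 # extra inhibition from the top down
    m2 <- call_mic(grid, growth2)
    v1 <- if (m1$censored) Inf else m1$value
    v2 <- if (m2$censored) Inf else m2$value
    expect_lte(v2, v1)
  }
})

test_that("activity and toxicity classification respect their cutoffs", {
  expect_identical(binarize_activity(6.25), 1L)
  expect_identical(binarize_activity(12.5), 0L)
  expect_identical(binarize_activity(NA), 0L)
  mic <- call_mic(dilution_grid(50, 2, 7), c(0, 0, 0, 0, 0, 95, 99, 100))
  expect_identical(binarize_activity(mic), 1L)
  expect_true(classify_toxicity(45))   # the 45% viability ligand is toxic
  expect_false(classify_toxicity(50))  # strict <
  expect_false(classify_toxicity(100))
})

test_that("4PL fitting recovers noiseless parameters and inverts analytically", {
  conc <- 100 / 2^(0:11)
  resp <- 0 + (100 - 0) / (1 + (10 / conc)^1)
  fit <- fit_4pl(conc, resp)
  expect_false(fit$failed)
  expect_equal(fit$ec50, 10, tolerance = 0.01)
  expect_equal(fit$hill, 1, tolerance = 0.01)
  # analytic HC10: HC50 = 50, hill = 1 -> 50/9 = 5.56 to 3 s.f.
  resp50 <- 100 / (1 + (50 / conc)^1)
  hc10 <- ec_at(fit_4pl(conc, resp50), 10)
  expect_equal(hc10, 50 / 9, tolerance = 5e-4)
  expect_equal(signif(hc10, 3), 5.56)
  # decreasing viability curve
  via <- 100 / (1 + (conc / 12)^1.5)
  cfit <- fit_4pl(conc, via)
  expect_equal(ec_at(cfit, 50), 12, tolerance = 0.05)
  # flat response -> failed-fit flag, and ec_at propagates NA
  flat <- fit_4pl(conc, rep(100, 12))
  expect_true(flat$failed)
  expect_true(is.na(ec_at(flat, 50)))
  expect_error(fit_4pl(c(1, 2, 4), c(1, 2, 3)), "4 distinct")
})

test_that("therapeutic index reproduces printed arithmetic conventions", {
  # CC50 12.4, HC10 73, MIC 0.39 -> 32
  expect_identical(therapeutic_index(12.4, 73, 0.39)$display, "32")
  # censored HC10 treated as infinite: CC50 38.5, MIC 0.39-0.78 -> 49-99
  ti <- therapeutic_index(38.5, NA, 0.39, 0.78)
  expect_identical(c(ti$ti_lo, ti$ti_hi), c(49, 99))
  # half-away-from-zero rounding: 7.3/0.20 = 36.5 -> 37, 11.9/0.39 = 30.51 -> 31
  expect_identical(therapeutic_index(7.3, 81, 0.20, 0.39)$display, "19-37")
  expect_identical(therapeutic_index(11.9, NA, 0.39, 0.78)$display, "15-31")
  # numerator = min(CC50, HC10)
  expect_identical(therapeutic_index(100, 12.4, 0.39)$numerator, 12.4)
  # degenerate single-MIC identity
  expect_identical(therapeutic_index(6.25, NA, 6.25)$display, "1")
})

test_that("plate-level MIC calling recovers simulated truth", {
  truth <- c(a = 1.56, b = 6.25, c = 200, d = 0.39, e = 50)
  sim <- sim_mic_plate(truth, noise_sd = 0, seed = 1)
  mics <- plate_mics(sim$plate, sim$grid, n_compounds = 5)
  got <- vapply(mics, function(m) if (m$censored) Inf else m$value, numeric(1))
  expect_identical(got, unname(c(1.56, 6.25, Inf, 0.39, 50)))
})
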