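# Seeded synthetic-data generators. Every generator is a deterministic
# function of (parameters, seed) and returns its ground truth alongside the
# data, so every pipeline stage is testable without instrument files.

#' Simulate an LC-MS chromatography run
#'
#' The UV trace is a sum of Gaussian peaks (SD `peak_sd` min) whose areas are
#' proportional to the species' true conversion fractions, plus one impurity
#' peak absorbing the remaining fraction, on a Gaussian-noise baseline. MS
#' scans carry each species' isotope envelope (from [isotope_pattern()])
#' co-eluting with its UV peak; centroid intensities get scaled-Poisson noise
#' when `noise_sd > 0`.
#'
#' @param species Data frame with columns `label`, `formula` (ion
#'   composition), `z`, `rt` (min), `fraction` (fractions >= 0 summing to at
#'   most 1).
#' @param noise_sd UV baseline noise SD in mAU (0 = noiseless everywhere).
#' @param seed Integer seed.
#' @param t_max Run length in minutes (default 10).
#' @param peak_sd Chromatographic peak SD in minutes (default 0.05).
#' @param uv_hz,ms_hz Sampling rates in Hz (defaults 2 and 1).
#' @param total_area Total UV peak area in mAU x min shared by all peaks
#'   (default 50; area-percent is scale free).
#' @param impurity_rt Retention time of the impurity peak (default 8).
#' @param impurity_formula Optional ion composition for the impurity, making
#'   it MS-identifiable (for normalized-mode workflows).
#' @return A list: `run` (a [chrom_run()]), `truth` (kind, fractions, RTs,
#'   seed, co-elution flag), and `impurity_mz` when the impurity carries an
#'   ion.
#' @export
sim_chromatogram <- function(species, noise_sd = 0.5, seed = 1L, t_max = 10,
                             peak_sd = 0.05, uv_hz = 2, ms_hz = 1,
                             total_area = 50, impurity_rt = 8,
                             impurity_formula = NULL) {
  stopifnot(all(species$fraction >= 0), sum(species$fraction) <= 1 + 1e-9)
  set.seed(seed)
  rts <- c(species$rt, impurity_rt)
  fracs <- c(species$fraction, max(1 - sum(species$fraction), 0))
  co_elution <- any(diff(sort(rts[fracs > 0])) < 4 * peak_sd)
  tt <- seq(0, t_max, by = 1 / (uv_hz * 60))
  uv <- numeric(length(tt))
  for (i in seq_along(rts)) {
    if (fracs[i] > 0) {
      uv <- uv + total_area * fracs[i] * stats::dnorm(tt, rts[i], peak_sd)
    }
  }
  if (noise_sd > 0) uv <- uv + stats::rnorm(length(tt), 0, noise_sd)
  scan_t <- seq(0, t_max, by = 1 / (ms_hz * 60))
  ms_species <- data.frame(formula = species$formula, z = species$z,
                           rt = species$rt, fraction = species$fraction,
                           stringsAsFactors = FALSE)
  impurity_mz <- NULL
  if (!is.null(impurity_formula)) {
    ms_species <- rbind(ms_species,
                        data.frame(formula = impurity_formula, z = 1,
                                   rt = impurity_rt,
                                   fraction = utils::tail(fracs, 1)))
    impurity_mz <- (monoisotopic_mass(impurity_formula) - ELECTRON_MASS)
  }
  ms <- list()
  for (i in seq_len(nrow(ms_species))) {
    if (ms_species$fraction[i] <= 0) next
    pat <- isotope_pattern(ms_species$formula[i], z = ms_species$z[i], prune = 1e-3)
    sel <- which(abs(scan_t - ms_species$rt[i]) <= 4 * peak_sd)
    if (!length(sel)) next
    shape <- stats::dnorm(scan_t[sel], ms_species$rt[i], peak_sd) /
      stats::dnorm(0, 0, peak_sd)
    grid <- expand.grid(k = seq_along(sel), p = seq_len(nrow(pat)))
    inten <- 1e6 * ms_species$fraction[i] * shape[grid$k] *
      pat$abundance[grid$p] / 100
    if (noise_sd > 0) {
      kappa <- 50
      inten <- stats::rpois(length(inten), inten / kappa) * kappa
    }
    keep <- inten > 0
    ms[[length(ms) + 1L]] <- data.frame(scan_time_min = scan_t[sel][grid$k[keep]],
                                        mz = pat$mz[grid$p[keep]],
                                        intensity = inten[keep])
  }
  ms <- if (length(ms)) do.call(rbind, ms) else {
    data.frame(scan_time_min = numeric(0), mz = numeric(0), intensity = numeric(0))
  }
  ms <- ms[order(ms$scan_time_min, ms$mz), , drop = FALSE]
  rownames(ms) <- NULL
  run <- chrom_run(data.frame(time_min = tt, a254 = uv), ms)
  truth <- list(kind = "chromatogram",
                fractions = stats::setNames(species$fraction, species$label),
                conversion_pct = 100 * sum(species$fraction),
                rts = rts, seed = seed, noise_sd = noise_sd,
                co_elution = co_elution)
  out <- list(run = run, truth = truth)
  if (!is.null(impurity_mz)) out$impurity_mz <- impurity_mz
  out
}

#' Simulate a broth-microdilution MIC plate
#'
#' One compound per row (up to 8), dilution series across the first
#' `length(grid)` columns, growth-control wells in columns 9-10 and blanks in
#' 11-12. Growth is full below the true MIC and suppressed at and above it,
#' with a logistic transition one dilution step wide centred half a step
#' below the MIC; Gaussian noise of SD `noise_sd` percent of the control
#' window is added to every well.
#'
#' @param true_mics Named numeric vector (<= 8 compounds) of true MICs in uM;
#'   values above `max(grid)` simulate no inhibition in range.
#' @param grid Concentration grid (default `dilution_grid(50, 2, 7)`).
#' @param noise_sd Noise SD in percent of control (default 2).
#' @param seed Integer seed.
#' @param od_blank,od_ctrl Blank and full-growth OD600 levels.
#' @return A list: `plate` (8 x 12 matrix, rownames A-H), `grid`,
#'   `compounds`, `ctrl_cols`, `blank_cols`, `truth`.
#' @export
sim_mic_plate <- function(true_mics, grid = dilution_grid(50, 2, 7),
                          noise_sd = 2, seed = 1L, od_blank = 0.05,
                          od_ctrl = 1.0) {
  stopifnot(length(true_mics) <= 8L, all(true_mics > 0))
  set.seed(seed)
  nc <- length(grid)
  plate <- matrix(od_blank, nrow = 8, ncol = 12,
                  dimnames = list(LETTERS[1:8], 1:12))
  span <- od_ctrl - od_blank
  for (i in seq_along(true_mics)) {
    growth <- 100 * stats::plogis(8 * (log2(true_mics[i] / grid) - 0.5))
    plate[i, seq_len(nc)] <- od_blank + span * growth / 100
  }
  plate[, 9:10] <- od_ctrl
  plate[, 11:12] <- od_blank
  if (noise_sd > 0) {
    plate <- plate + matrix(stats::rnorm(96, 0, noise_sd / 100 * span), 8, 12)
  }
  list(plate = plate, grid = grid,
       compounds = names(true_mics) %||% paste0("cpd", seq_along(true_mics)),
       ctrl_cols = 9:10, blank_cols = 11:12,
       truth = list(kind = "mic_plate", true_mics = true_mics,
                    censored = true_mics > max(grid), noise_sd = noise_sd,
                    seed = seed))
}

#' Simulate a 4PL dose-response titration
#'
#' Samples the four-parameter logistic curve on a 2-fold dilution grid and
#' adds Gaussian noise in percent points. Use a negative `hill` for a
#' decreasing (viability) curve, positive for an increasing (haemolysis) one.
#'
#' @param true_ec50 EC50 in uM.
#' @param hill Hill slope (sign sets direction).
#' @param bottom,top Asymptotes in percent.
#' @param start Top concentration (default 100 uM).
#' @param n_points Number of concentrations (2-fold grid; default 12).
#' @param noise_sd Response noise SD in percent points (default 5).
#' @param seed Integer seed.
#' @return A list: `conc`, `resp`, `truth`.
#' @export
sim_dose_response <- function(true_ec50, hill = 1, bottom = 0, top = 100,
                              start = 100, n_points = 12, noise_sd = 5,
                              seed = 1L) {
  stopifnot(true_ec50 > 0, n_points >= 2)
  set.seed(seed)
  conc <- start / 2^(seq_len(n_points) - 1)
  resp <- bottom + (top - bottom) / (1 + (true_ec50 / conc)^hill)
  if (noise_sd > 0) resp <- resp + stats::rnorm(n_points, 0, noise_sd)
  list(conc = conc, resp = resp,
       truth = list(kind = "dose_response", ec50 = true_ec50, hill = hill,
                    bottom = bottom, top = top, noise_sd = noise_sd,
                    seed = seed))
}

#' Simulate a planted-rule binary activity dataset
#'
#' Background fingerprint bits are i.i.d. sparse Bernoulli(`density`), the
#' sparsity regime of real structural fingerprints; the causal bits are
#' commoner substructures, Bernoulli(`causal_density`). The label is a
#' threshold on a linear score over the causal bits (the default +/-2 weights
#' with intercept -1 leave a unit margin around the decision boundary, so the
#' rule is deterministic and wide-margin), then flipped with probability
#' `label_noise`. This is the stated world for the SVM property checks: a
#' bit-determined rule the classifier should recover.
#'
#' @param n Number of compounds (default 192, the campaign's modelling set
#'   size).
#' @param rule List with `bits` (causal bit indices), `weights` (same
#'   length) and `intercept`; default six bits with alternating +/-2 weights
#'   and intercept -1.
#' @param n_bits Fingerprint width (default 598).
#' @param density Background bit density (default 0.01).
#' @param causal_density Causal bit density (default 0.5).
#' @param label_noise Label flip probability (default 0.05).
#' @param seed Integer seed.
#' @return A list: `X` (n x n_bits 0/1 matrix), `y` (0/1 labels), `truth`.
#' @export
sim_activity_dataset <- function(n = 192L,
                                 rule = list(bits = c(3L, 7L, 11L, 15L, 19L, 23L),
                                             weights = c(2, -2, 2, -2, 2, -2),
                                             intercept = -1),
                                 n_bits = 598L, density = 0.01,
                                 causal_density = 0.5,
                                 label_noise = 0.05, seed = 1L) {
  stopifnot(length(rule$bits) == length(rule$weights), max(rule$bits) <= n_bits)
  set.seed(seed)
  X <- matrix(stats::rbinom(n * n_bits, 1L, density), nrow = n)
  X[, rule$bits] <- stats::rbinom(n * length(rule$bits), 1L, causal_density)
  colnames(X) <- paste0("bit", seq_len(n_bits))
  score <- as.numeric(X[, rule$bits, drop = FALSE] %*% rule$weights) +
    (rule$intercept %||% 0)
  y <- as.integer(score > 0)
  if (label_noise > 0) {
    flip <- stats::runif(n) < label_noise
    y[flip] <- 1L - y[flip]
  }
  list(X = X, y = y,
       truth = list(kind = "activity", rule = rule, density = density,
                    causal_density = causal_density,
                    label_noise = label_noise, seed = seed))
}
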