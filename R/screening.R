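# Plate-based Direct-to-Biology analytics: dilution grids, percent of
# control, MIC calling, toxicity flags, 4PL dose-response fits and
# therapeutic indices.

# Round half away from zero (the convention the printed TI table follows;
# base round() is half-to-even and gives 36.5 -> 36, not 37).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Reporting convention for concentrations on the 2-fold grid: two decimal
# places at >= 0.1 uM (3.125 -> 3.13, 0.78125 -> 0.78), two significant
# figures below (0.0488 -> 0.049). Reproduces every printed grid value.
report_conc <- function(x) {
  ifelse(abs(x) >= 0.1,
         round_half_away(x, 2),
         round_half_away(x * 10^(2 - ceiling(log10(abs(x)))), 0) *
           10^(ceiling(log10(abs(x))) - 2))
}

#' Two-fold serial dilution grid
#'
#' @param start Top concentration in uM (> 0).
#' @param factor Dilution factor (> 1; default 2).
#' @param n_steps Number of dilutions; the grid has `n_steps + 1` members.
#' @param report Report values using the printed-grid convention (two
#'   decimals at >= 0.1 uM, two significant figures below)? Default `TRUE`.
#' @return Numeric vector, decreasing: `start, start/factor, ...`.
#' @examples
#' dilution_grid(50, 2, 7) # 50 25 12.5 6.25 3.13 1.56 0.78 0.39
#' @export
dilution_grid <- function(start, factor = 2, n_steps = 7, report = TRUE) {
  if (!is.finite(start) || start <= 0 || !is.finite(factor) || factor <= 1 ||
      n_steps < 0 || n_steps != round(n_steps)) {
    stop("invalid dilution-grid parameters", call. = FALSE)
  }
  grid <- start / factor^(0:n_steps)
  if (report) report_conc(grid) else grid
}

#' Percent of control
#'
#' `100 * (signal - blank) / (ctrl - blank)`, clipped below at 0.
#'
#' @param signal Raw well signal(s).
#' @param growth_ctrl_mean Mean of growth-control wells.
#' @param blank_mean Mean of blank wells.
#' @return Percent of control (vectorized over `signal`).
#' @export
percent_of_control <- function(signal, growth_ctrl_mean, blank_mean = 0) {
  if (!is.finite(growth_ctrl_mean) || growth_ctrl_mean <= blank_mean) {
    stop("degenerate controls: growth control must exceed blank", call. = FALSE)
  }
  pmax(100 * (signal - blank_mean) / (growth_ctrl_mean - blank_mean), 0)
}

#' Call the minimum inhibitory concentration
#'
#' The MIC is the lowest concentration at which growth is at or below
#' `inhibit_threshold` percent of control *and* stays inhibited at every
#' higher concentration (the highest contiguous inhibited block). If even the
#' top concentration allows growth the result is censored (`> max`), rendered
#' `"-"`.
#'
#' @param conc Concentration grid in uM (any order; sorted internally).
#' @param growth_pct Percent growth of control, same length as `conc`.
#' @param inhibit_threshold "Complete inhibition" operationalized as growth at
#'   or below this percent (default 10).
#' @return A list of class `mic_result`: `value` (uM, `NA` if censored),
#'   `censored`, `display`, `grid`, `threshold`.
#' @export
call_mic <- function(conc, growth_pct, inhibit_threshold = 10) {
  stopifnot(length(conc) == length(growth_pct), all(conc > 0))
  o <- order(conc, decreasing = TRUE)
  conc <- conc[o]
  growth_pct <- growth_pct[o]
  inhibited <- growth_pct <= inhibit_threshold
  run <- which(!inhibited)
  top_block <- if (!length(run)) length(conc) else run[1L] - 1L
  if (top_block == 0L) {
    structure(list(value = NA_real_, censored = TRUE, display = "-",
                   grid = conc, threshold = inhibit_threshold),
              class = "mic_result")
  } else {
    structure(list(value = conc[top_block], censored = FALSE,
                   display = formatC(conc[top_block], format = "fg"),
                   grid = conc, threshold = inhibit_threshold),
              class = "mic_result")
  }
}

#' @export
print.mic_result <- function(x, ...) {
  cat("MIC:", if (x$censored) paste0("- (no inhibition up to ", max(x$grid), " uM)")
      else paste0(x$value, " uM"), "\n")
  invisible(x)
}

#' Binary activity label from an MIC
#'
#' Active (1) iff the MIC is uncensored and at or below `cutoff` (default
#' 6.25 uM, the campaign's activity threshold).
#'
#' @param mic A `mic_result`, or a numeric MIC value (`NA` = censored).
#' @param cutoff Activity cutoff in uM.
#' @return 0 or 1.
#' @export
binarize_activity <- function(mic, cutoff = 6.25) {
  value <- if (inherits(mic, "mic_result")) {
    if (mic$censored) NA_real_ else mic$value
  } else {
    as.numeric(mic)
  }
  as.integer(!is.na(value) && value <= cutoff)
}

#' Toxicity flag from single-dose viability
#'
#' Toxic iff viability at 50 uM is strictly below 50 percent of control.
#'
#' @param viability_pct Percent cell viability at 50 uM.
#' @return Logical.
#' @export
classify_toxicity <- function(viability_pct) {
  stopifnot(all(viability_pct >= 0))
  viability_pct < 50
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `resp = bottom + (top - bottom) / (1 + (ec50 / conc)^hill)`.
#' A positive `hill` describes a response increasing with concentration (e.g.
#' normalized haemolysis); a negative `hill` a decreasing one (viability).
#' Initialization takes `bottom`/`top` from the response extremes, `ec50`
#' from the concentration nearest the half-range crossing and `hill = +/-1`;
#' optimization is bounded L-BFGS-B on `(bottom, top, log ec50, hill)`.
#'
#' @param conc Concentrations in uM (at least 4 distinct values, > 0).
#' @param resp Responses in percent of control.
#' @return A list of class `fourpl_fit`: `bottom`, `top`, `hill`, `ec50`,
#'   `rss`, `converged`, `failed` (flat or non-convergent input).
#' @export
fit_4pl <- function(conc, resp) {
  stopifnot(length(conc) == length(resp), all(conc > 0))
  if (length(unique(conc)) < 4L) {
    stop("at least 4 distinct concentrations required", call. = FALSE)
  }
  failed <- function(reason) {
    structure(list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                   ec50 = NA_real_, rss = NA_real_, converged = FALSE,
                   failed = TRUE, reason = reason), class = "fourpl_fit")
  }
  rng <- range(resp)
  if (diff(rng) < 1e-6 || diff(rng) < 0.02 * max(abs(rng), 1)) {
    return(failed("flat response"))
  }
  lc <- log(conc)
  direction <- sign(stats::cor(lc, resp))
  if (!is.finite(direction) || direction == 0) direction <- 1
  half <- mean(rng)
  ec50_0 <- exp(stats::approx(resp + seq_along(resp) * 1e-9, lc, xout = half,
                              rule = 2, ties = "ordered")$y)
  par0 <- c(bottom = rng[1], top = rng[2], lec50 = log(ec50_0),
            hill = direction * 1)
  obj <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + (exp(p[3]) / conc)^p[4])
    sum((resp - pred)^2)
  }
  span <- diff(rng)
  lower <- c(rng[1] - span, rng[1], log(min(conc)) - log(1e3), -10)
  upper <- c(rng[2], rng[2] + span, log(max(conc)) + log(1e3), 10)
  fit <- try(stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) {
    return(failed("optimizer failure"))
  }
  p <- fit$par
  structure(list(bottom = unname(p[1]), top = unname(p[2]),
                 hill = unname(p[4]), ec50 = unname(exp(p[3])),
                 rss = fit$value, converged = fit$convergence == 0,
                 failed = FALSE, reason = NULL), class = "fourpl_fit")
}

#' Invert a 4PL fit at a response level
#'
#' Solves the fitted curve for the concentration giving response `p`:
#' CC50 is `ec_at(fit, 50)` on a viability fit, HC10 `ec_at(fit, 10)` on a
#' normalized haemolysis fit.
#'
#' @param fit A `fourpl_fit`.
#' @param p Response level in percent (strictly between `bottom` and `top`).
#' @return Concentration in uM (`NA` if the fit failed or `p` is outside the
#'   fitted range).
#' @export
ec_at <- function(fit, p) {
  if (isTRUE(fit$failed)) return(NA_real_)
  lo <- min(fit$bottom, fit$top)
  hi <- max(fit$bottom, fit$top)
  if (p <= lo || p >= hi) return(NA_real_)
  r <- (fit$top - fit$bottom) / (p - fit$bottom) - 1
  if (r <= 0) return(NA_real_)
  fit$ec50 * r^(-1 / fit$hill)
}

#' Therapeutic index from toxicity and MIC values
#'
#' `min(CC50, HC10)` divided by the MIC, rounded half away from zero to an
#' integer. An MIC range gives a TI range: the upper TI uses the lower MIC
#' bound. A censored HC10 (no haemolysis at the tested range) enters as
#' infinite, so the numerator falls back to the CC50.
#'
#' @param cc50 CC50 in uM.
#' @param hc10 HC10 in uM, or `NA`/`Inf` when censored.
#' @param mic_lo,mic_hi Bounds of the MIC (printed grid values); a single MIC
#'   has `mic_hi = mic_lo`.
#' @return A list of class `ti_result`: `ti_lo`, `ti_hi`, `display` (e.g.
#'   `"49-99"` or `"32"`), `numerator`.
#' @export
therapeutic_index <- function(cc50, hc10 = NA, mic_lo, mic_hi = mic_lo) {
  stopifnot(cc50 > 0, mic_lo > 0, mic_hi >= mic_lo)
  if (is.na(hc10)) hc10 <- Inf
  numerator <- min(cc50, hc10)
  ti_hi <- round_half_away(numerator / mic_lo)
  ti_lo <- round_half_away(numerator / mic_hi)
  structure(list(ti_lo = ti_lo, ti_hi = ti_hi,
                 display = if (ti_lo == ti_hi) sprintf("%d", as.integer(ti_hi))
                           else sprintf("%d-%d", as.integer(ti_lo), as.integer(ti_hi)),
                 numerator = numerator,
                 inputs = list(cc50 = cc50, hc10 = hc10,
                               mic_lo = mic_lo, mic_hi = mic_hi)),
            class = "ti_result")
}

#' @export
print.ti_result <- function(x, ...) {
  cat("Therapeutic index:", x$display, "\n")
  invisible(x)
}

#' Call MICs for every compound row of a dilution plate
#'
#' Normalizes each dose well to percent of control using the designated
#' control and blank columns, then applies [call_mic()] row-wise.
#'
#' @param plate 8 x 12 signal matrix (rows = compounds).
#' @param grid Concentration grid occupying the first `length(grid)` columns.
#' @param ctrl_cols,blank_cols Column indices of growth controls and blanks.
#' @param inhibit_threshold Passed to [call_mic()].
#' @param n_compounds Rows carrying compounds (default all 8).
#' @return A list of `mic_result`, one per compound row.
#' @export
plate_mics <- function(plate, grid, ctrl_cols = 9:10, blank_cols = 11:12,
                       inhibit_threshold = 10, n_compounds = 8L) {
  ctrl <- mean(plate[, ctrl_cols])
  blank <- mean(plate[, blank_cols])
  lapply(seq_len(n_compounds), function(i) {
    growth <- percent_of_control(plate[i, seq_along(grid)], ctrl, blank)
    call_mic(grid, growth, inhibit_threshold = inhibit_threshold)
  })
}

#' Printed biological data for the six re-synthesized lead compounds
#'
#' The lead-compound table shipped with the package: MIC range against
#' S. aureus (printed dilution-grid values, uM), HC10 (uM, `NA` when censored
#' above the tested 200 uM), CC50 (uM) and the printed therapeutic index.
#'
#' @return A data frame, one row per lead compound.
#' @export
lead_compound_table <- function() {
  path <- system.file("extdata", "lead_compounds.csv", package = "metalloscreen",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
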