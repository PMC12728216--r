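# Endpoint summaries for the transfer-hydrogenation plate screens and the
# UV-absorbance stability assay.

#' Fluorescence endpoint change
#'
#' Final minus initial reading (the coumarin-azide assay statistic: product
#' formation makes the trace rise). Negative values are allowed.
#'
#' @param times,signals Kinetic trace (at least 2 points, times increasing).
#' @return Change in arbitrary units.
#' @export
delta_fluorescence <- function(times, signals) {
  check_trace(times, signals)
  signals[length(signals)] - signals[1L]
}

#' Absorbance endpoint change
#'
#' Global maximum minus final reading (the harmaline assay statistic:
#' substrate consumption makes the trace fall after any mixing transient).
#'
#' @inheritParams delta_fluorescence
#' @return Change in absorbance units (>= 0).
#' @export
delta_absorbance <- function(times, signals) {
  check_trace(times, signals)
  max(signals) - signals[length(signals)]
}

check_trace <- function(times, signals) {
  if (length(times) < 2L || length(signals) != length(times)) {
    stop("kinetic trace needs at least 2 points", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Average replicate kinetic traces point-wise
#'
#' @param traces List of equal-length signal vectors on a shared time grid.
#' @return The mean trace.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  n <- lengths(traces)
  if (length(unique(n)) != 1L) stop("replicate traces must share a time grid", call. = FALSE)
  Reduce(`+`, traces) / length(traces)
}

#' Flag transfer-hydrogenation hits
#'
#' A fluorescence hit is a change strictly greater than `fl_threshold`
#' (default 15000 arb. units); total conversion in the absorbance assay is a
#' change of at least `abs_total` (default 2.0 A.U.).
#'
#' @param summaries Data frame with columns `compound_id` and `delta_fl`
#'   and/or `delta_abs`.
#' @param fl_threshold Strict fluorescence hit threshold.
#' @param abs_total Total-conversion absorbance threshold (inclusive).
#' @return `summaries` with logical columns `fl_hit` / `total_conversion`
#'   appended.
#' @export
flag_hits <- function(summaries, fl_threshold = 15000, abs_total = 2.0) {
  if (!is.null(summaries$delta_fl)) {
    summaries$fl_hit <- summaries$delta_fl > fl_threshold
  }
  if (!is.null(summaries$delta_abs)) {
    summaries$total_conversion <- summaries$delta_abs >= abs_total
  }
  summaries
}

#' Percent spectral change at a reference wavelength
#'
#' Stability statistic for incubation assays: the absolute relative change in
#' absorbance at `lambda_ref` between the initial and final spectra. Less
#' than 10 percent over the incubation is the conventional stability
#' criterion.
#'
#' @param spectrum_t0,spectrum_t_end Data frames `wavelength_nm`, `a`.
#' @param lambda_ref Reference wavelength in nm (default 320).
#' @param stable_below Stability criterion in percent (default 10).
#' @return A list: `pct_change`, `stable`.
#' @export
stability_change <- function(spectrum_t0, spectrum_t_end, lambda_ref = 320,
                             stable_below = 10) {
  a0 <- interp_spectrum(spectrum_t0, lambda_ref)
  a1 <- interp_spectrum(spectrum_t_end, lambda_ref)
  if (!is.finite(a0) || a0 == 0) {
    stop("undefined stability change: initial absorbance is zero at ",
         lambda_ref, " nm", call. = FALSE)
  }
  pct <- 100 * abs(a1 - a0) / a0
  list(pct_change = pct, stable = pct < stable_below)
}

interp_spectrum <- function(spec, lambda) {
  stopifnot(all(c("wavelength_nm", "a") %in% names(spec)))
  if (lambda < min(spec$wavelength_nm) || lambda > max(spec$wavelength_nm)) {
    stop("spectrum does not cover the reference wavelength", call. = FALSE)
  }
  stats::approx(spec$wavelength_nm, spec$a, xout = lambda, ties = "ordered")$y
}
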