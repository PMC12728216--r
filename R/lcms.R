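# Automated LC-MS library characterization: peak picking on UV traces,
# extracted-ion chromatograms for target ions, UV/EIC matching and
# conversion% reporting.

#' Construct a chromatography run
#'
#' @param uv Data frame `time_min`, `a254` (254 nm absorbance, mAU), times
#'   strictly increasing.
#' @param ms Data frame in long format `scan_time_min`, `mz`, `intensity`
#'   (centroided scans); may have zero rows.
#' @param compound_id,library_id Metadata.
#' @return A list of class `chrom_run`.
#' @export
chrom_run <- function(uv, ms, compound_id = NA_character_, library_id = NA_character_) {
  stopifnot(all(c("time_min", "a254") %in% names(uv)),
            all(c("scan_time_min", "mz", "intensity") %in% names(ms)))
  if (is.unsorted(uv$time_min, strictly = TRUE)) {
    stop("UV times must be strictly increasing", call. = FALSE)
  }
  if (nrow(ms) && any(ms$intensity < 0)) stop("negative MS intensity", call. = FALSE)
  structure(list(uv = uv, ms = ms, compound_id = compound_id,
                 library_id = library_id), class = "chrom_run")
}

#' Read a run from the tabular chromatogram dialect
#'
#' Two files per run: `<stem>.uv.csv` with columns `time_min`, `a254` and
#' `<stem>.ms.csv` with columns `scan_time_min`, `mz`, `intensity`.
#'
#' @param stem Path stem (without the `.uv.csv` / `.ms.csv` suffix).
#' @param compound_id Compound id; defaults to the stem's base name.
#' @return A `chrom_run`.
#' @export
read_chrom_run <- function(stem, compound_id = basename(stem)) {
  uv <- utils::read.csv(paste0(stem, ".uv.csv"), stringsAsFactors = FALSE)
  msf <- paste0(stem, ".ms.csv")
  ms <- if (file.exists(msf)) {
    utils::read.csv(msf, stringsAsFactors = FALSE)
  } else {
    data.frame(scan_time_min = numeric(0), mz = numeric(0), intensity = numeric(0))
  }
  chrom_run(uv, ms, compound_id = compound_id)
}

#' Write a run in the tabular chromatogram dialect
#'
#' @param run A `chrom_run`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_chrom_run <- function(run, stem) {
  utils::write.csv(run$uv, paste0(stem, ".uv.csv"), row.names = FALSE)
  utils::write.csv(run$ms, paste0(stem, ".ms.csv"), row.names = FALSE)
  invisible(stem)
}

#' Detect peaks in a chromatographic trace
#'
#' Moving-average smoothing, then local maxima above both a robust noise gate
#' (baseline median plus `noise_k` times a robust noise SD estimated from
#' first differences) and `min_height_frac` of the global maximum. Peak
#' bounds extend to the flanking local minima or the baseline crossing,
#' whichever comes first; the area is the trapezoidal integral of the raw
#' signal above a straight baseline drawn between the bounds.
#'
#' @param time,signal Numeric vectors (at least 5 points, times increasing).
#' @param smooth_window Moving-average window in points (odd; default 5).
#' @param noise_k Noise-gate multiplier (default 3).
#' @param min_height_frac Minimum apex height as a fraction of the global
#'   maximum (default 0.01).
#' @return A data frame with one row per peak: `apex_rt`, `start`, `end`,
#'   `height`, `area` (signal x min), sorted by `apex_rt`.
#' @export
detect_peaks <- function(time, signal, smooth_window = 5L, noise_k = 3,
                         min_height_frac = 0.01) {
  n <- length(time)
  if (n < 5L || length(signal) != n) {
    stop("trace must have at least 5 points", call. = FALSE)
  }
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- as.numeric(stats::filter(signal, rep(1 / w, w), sides = 2))
  pad <- (w - 1L) %/% 2L
  if (pad > 0L) {
    sm[seq_len(pad)] <- sm[pad + 1L]
    sm[(n - pad + 1L):n] <- sm[n - pad]
  }
  base_med <- stats::median(sm)
  noise_sd <- stats::mad(diff(signal)) / sqrt(2)
  gate <- max(base_med + noise_k * noise_sd, min_height_frac * max(sm))
  apex <- which(diff(sign(diff(sm))) < 0) + 1L
  apex <- apex[sm[apex] > gate]
  if (!length(apex)) {
    return(data.frame(apex_rt = numeric(0), start = numeric(0), end = numeric(0),
                      height = numeric(0), area = numeric(0)))
  }
  floor_level <- base_med
  bounds <- t(vapply(apex, function(i) {
    lo <- i
    while (lo > 1L && sm[lo - 1L] < sm[lo] && sm[lo] > floor_level) lo <- lo - 1L
    hi <- i
    while (hi < n && sm[hi + 1L] < sm[hi] && sm[hi] > floor_level) hi <- hi + 1L
    c(lo, hi)
  }, numeric(2)))
  peaks <- lapply(seq_along(apex), function(k) {
    lo <- bounds[k, 1]; hi <- bounds[k, 2]
    if (hi - lo < 2L) return(NULL)
    idx <- lo:hi
    baseline <- signal[lo] + (signal[hi] - signal[lo]) *
      (time[idx] - time[lo]) / (time[hi] - time[lo])
    y <- pmax(signal[idx] - baseline, 0)
    area <- sum(diff(time[idx]) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    data.frame(apex_rt = time[apex[k]], start = time[lo], end = time[hi],
               height = signal[apex[k]], area = max(area, 0))
  })
  out <- do.call(rbind, peaks)
  if (is.null(out)) {
    return(data.frame(apex_rt = numeric(0), start = numeric(0), end = numeric(0),
                      height = numeric(0), area = numeric(0)))
  }
  # merged shoulders can yield duplicate apexes after smoothing; keep unique
  out <- out[!duplicated(out$apex_rt), , drop = FALSE]
  out <- out[order(out$apex_rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extracted-ion chromatogram
#'
#' Per MS scan, the sum of centroid intensities within `tol` Th of
#' `target_mz`; zero where no centroid matches.
#'
#' @param run A `chrom_run`.
#' @param target_mz Target m/z in Th.
#' @param tol Symmetric tolerance in Th (default 0.5, ion-trap scale).
#' @return A data frame `time_min`, `intensity`, one row per scan.
#' @export
extract_eic <- function(run, target_mz, tol = 0.5) {
  stopifnot(tol > 0)
  ms <- run$ms
  times <- sort(unique(ms$scan_time_min))
  if (!length(times)) return(data.frame(time_min = numeric(0), intensity = numeric(0)))
  hit <- abs(ms$mz - target_mz) <= tol
  agg <- tapply(ms$intensity[hit], factor(ms$scan_time_min[hit], levels = times), sum)
  data.frame(time_min = times,
             intensity = ifelse(is.na(agg), 0, as.numeric(agg)))
}

#' Match EIC peaks to UV peaks by retention time
#'
#' For each EIC peak the UV peak whose apex is nearest within `rt_tol` is
#' selected; exact distance ties are broken toward the larger UV area (and
#' flagged `multiple-candidates`). EIC peaks with no UV peak in tolerance are
#' flagged `not-found`.
#'
#' @param eic_peaks,uv_peaks Peak tables from [detect_peaks()].
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @return A data frame with one row per EIC peak: `eic_rt`, `uv_index` (row
#'   into `uv_peaks`, NA if unmatched), `uv_rt`, `flag`.
#' @export
match_target <- function(eic_peaks, uv_peaks, rt_tol = 0.1) {
  stopifnot(rt_tol > 0)
  if (!nrow(eic_peaks)) {
    return(data.frame(eic_rt = numeric(0), uv_index = integer(0),
                      uv_rt = numeric(0), flag = character(0)))
  }
  rows <- lapply(seq_len(nrow(eic_peaks)), function(i) {
    rt <- eic_peaks$apex_rt[i]
    if (!nrow(uv_peaks)) {
      return(data.frame(eic_rt = rt, uv_index = NA_integer_, uv_rt = NA_real_,
                        flag = "not-found"))
    }
    d <- abs(uv_peaks$apex_rt - rt)
    inwin <- which(d <= rt_tol)
    if (!length(inwin)) {
      return(data.frame(eic_rt = rt, uv_index = NA_integer_, uv_rt = NA_real_,
                        flag = "not-found"))
    }
    dmin <- min(d[inwin])
    cand <- inwin[abs(d[inwin] - dmin) < 1e-9]
    flag <- ""
    if (length(cand) > 1L) {
      cand <- cand[which.max(uv_peaks$area[cand])]
      flag <- "multiple-candidates"
    }
    data.frame(eic_rt = rt, uv_index = cand, uv_rt = uv_peaks$apex_rt[cand],
               flag = flag)
  })
  do.call(rbind, rows)
}

#' Conversion percent from integrated UV peak areas
#'
#' `area` mode: 100 x matched area / total UV peak area. `aggregate` mode is
#' arithmetically the same but sums over several matched species first (the
#' parent-plus-MeCN-adduct rule used for IrCp* libraries). `normalized` mode
#' divides by the area of MS-identified peaks only (`identified_index`),
#' the renormalization-to-100% treatment applied to RuCy libraries whose UV
#' response is weak.
#'
#' @param uv_peaks Peak table from [detect_peaks()].
#' @param matched_index Integer rows of `uv_peaks` assigned to the target
#'   species (may be empty).
#' @param mode One of `"area"`, `"aggregate"`, `"normalized"`.
#' @param identified_index Rows of `uv_peaks` with any MS identification
#'   (required denominator for `"normalized"`; defaults to `matched_index`).
#' @param min_height_frac Peaks below this fraction of the tallest peak are
#'   dropped from all totals as integration noise (default 0.01).
#' @return A list of class `conversion_result`: `conversion_pct`, `mode`,
#'   `flags` (character vector), `matched_area`, `total_area`.
#' @export
conversion_percent <- function(uv_peaks, matched_index, mode = c("area", "aggregate", "normalized"),
                               identified_index = NULL, min_height_frac = 0.01) {
  mode <- match.arg(mode)
  flags <- character(0)
  matched_index <- unique(matched_index[!is.na(matched_index)])
  keep <- if (nrow(uv_peaks)) {
    which(uv_peaks$height >= min_height_frac * max(uv_peaks$height))
  } else integer(0)
  keep <- union(keep, matched_index)
  denom_index <- if (mode == "normalized") {
    unique(c(matched_index, identified_index[!is.na(identified_index)]))
  } else {
    keep
  }
  total <- sum(uv_peaks$area[denom_index])
  if (!length(matched_index)) {
    return(structure(list(conversion_pct = 0, mode = mode, flags = "not-found",
                          matched_area = 0, total_area = total),
                     class = "conversion_result"))
  }
  if (!is.finite(total) || total <= 0) {
    stop("undefined conversion: total UV peak area is zero", call. = FALSE)
  }
  pct <- 100 * sum(uv_peaks$area[matched_index]) / total
  structure(list(conversion_pct = min(max(pct, 0), 100), mode = mode,
                 flags = flags, matched_area = sum(uv_peaks$area[matched_index]),
                 total_area = total),
            class = "conversion_result")
}

scaffold_conversion_mode <- function(scaffold_id) {
  switch(scaffold_id, "IrCp*" = "aggregate", "RuCy" = "normalized", "area")
}

#' Characterize a library of runs against complex specs
#'
#' The automated pipeline: for each complex, compute its expected ion species,
#' extract their EICs, pick EIC and UV peaks, match them by retention time and
#' integrate the matched UV peaks into a conversion percent. The mode follows
#' the scaffold (aggregate for IrCp*, normalized for RuCy, plain area percent
#' otherwise) unless overridden.
#'
#' @param runs Named list of `chrom_run` objects, names = compound ids.
#' @param specs Complex data frame from [assemble_complexes()].
#' @param mz_tol m/z tolerance in Th (default 0.5).
#' @param rt_tol Retention-time match tolerance in minutes (default 0.1).
#' @param mode Conversion mode override; `NULL` (default) selects by scaffold.
#' @param other_ions Optional data frame `compound_id`, `mz` of known
#'   non-target ions (identified impurities), used by normalized mode.
#' @param ... Passed to [detect_peaks()].
#' @return A list with `table` (per-compound `compound_id`, `rt_min`,
#'   `conversion_pct`, `species`, `flags`) and `summary` (`mean`, `sd`, `n`,
#'   `label` formatted like `"75 +/- 16%"`).
#' @export
characterize_library <- function(runs, specs, mz_tol = 0.5, rt_tol = 0.1,
                                 mode = NULL, other_ions = NULL, ...) {
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, ]
    run <- runs[[spec$id]]
    if (is.null(run)) {
      return(data.frame(compound_id = spec$id, rt_min = NA_real_,
                        conversion_pct = NA_real_, species = "",
                        flags = "absent", stringsAsFactors = FALSE))
    }
    use_mode <- mode %||% scaffold_conversion_mode(spec$scaffold_id)
    ions <- expected_ions(spec)
    uv_peaks <- detect_peaks(run$uv$time_min, run$uv$a254, ...)
    matched_idx <- integer(0)
    matched_labels <- character(0)
    flags <- character(0)
    principal_rt <- NA_real_
    for (j in seq_len(nrow(ions))) {
      eic <- extract_eic(run, ions$mz[j], tol = mz_tol)
      if (!nrow(eic) || max(eic$intensity) <= 0) next
      eic_peaks <- detect_peaks(eic$time_min, eic$intensity, ...)
      m <- match_target(eic_peaks, uv_peaks, rt_tol = rt_tol)
      hit <- m[!is.na(m$uv_index), , drop = FALSE]
      if (nrow(hit)) {
        # principal match for this species: largest matched UV peak
        best <- hit$uv_index[which.max(uv_peaks$area[hit$uv_index])]
        matched_idx <- union(matched_idx, best)
        matched_labels <- c(matched_labels, ions$label[j])
        flags <- union(flags, m$flag[nzchar(m$flag)])
      }
    }
    identified_idx <- matched_idx
    if (!is.null(other_ions)) {
      oi <- other_ions[other_ions$compound_id == spec$id, , drop = FALSE]
      for (mz in oi$mz) {
        eic <- extract_eic(run, mz, tol = mz_tol)
        if (!nrow(eic) || max(eic$intensity) <= 0) next
        eic_peaks <- detect_peaks(eic$time_min, eic$intensity, ...)
        m <- match_target(eic_peaks, uv_peaks, rt_tol = rt_tol)
        identified_idx <- union(identified_idx, m$uv_index[!is.na(m$uv_index)])
      }
    }
    conv <- conversion_percent(uv_peaks, matched_idx, mode = use_mode,
                               identified_index = identified_idx)
    if (length(matched_idx)) {
      principal_rt <- uv_peaks$apex_rt[matched_idx[which.max(uv_peaks$area[matched_idx])]]
    }
    data.frame(compound_id = spec$id, rt_min = principal_rt,
               conversion_pct = conv$conversion_pct,
               species = paste0(matched_labels, collapse = ";"),
               flags = paste0(union(flags, conv$flags), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$conversion_pct)
  mu <- mean(tab$conversion_pct[ok])
  sdv <- if (sum(ok) > 1L) stats::sd(tab$conversion_pct[ok]) else 0
  list(table = tab,
       summary = list(mean = mu, sd = sdv, n = sum(ok),
                      label = sprintf("%.0f ± %.0f%%", mu, sdv)))
}
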