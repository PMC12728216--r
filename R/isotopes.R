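# Monoisotopic masses, isotope-pattern convolution and expected ion species.
#
# Metal complexes of Ru, Ir and Re are strongly polyisotopic, so target-ion
# matching needs the full envelope, not a single mass. Patterns are built by
# iterative per-element convolution of the shipped isotope table, with
# centroid merging and abundance pruning.

.metalloscreen_cache <- new.env(parent = emptyenv())

#' Electron rest mass in Da
#'
#' Subtracted once per charge when converting ion masses to m/z.
#' @export
ELECTRON_MASS <- 0.000548579909

#' The shipped isotope table
#'
#' Standard isotopic masses and abundances (IUPAC-CIAAW 2021 representative
#' values) read from `inst/extdata/isotopes.tsv` and cached per session.
#'
#' @return A named list; one data frame (`mass`, `abundance`) per element,
#'   masses strictly increasing.
#' @export
isotope_table <- function() {
  if (!is.null(.metalloscreen_cache$isotopes)) return(.metalloscreen_cache$isotopes)
  path <- system.file("extdata", "isotopes.tsv", package = "metalloscreen", mustWork = TRUE)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- lapply(split(raw[c("mass", "abundance")], raw$element), function(d) {
    d <- d[order(d$mass), , drop = FALSE]
    rownames(d) <- NULL
    stopifnot(abs(sum(d$abundance) - 1) < 1e-4, !is.unsorted(d$mass, strictly = TRUE))
    d
  })
  .metalloscreen_cache$isotopes <- tab
  tab
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of that element's most abundant
#' isotope. The empty formula has mass 0.
#'
#' @param f Formula (string or `chem_formula`).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.0106
#' @export
monoisotopic_mass <- function(f) {
  f <- parse_formula(f)
  if (!length(f)) return(0)
  tab <- isotope_table()
  unknown <- setdiff(names(f), names(tab))
  if (length(unknown)) {
    stop("element(s) not in isotope table: ", paste0(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(vapply(names(f), function(el) {
    iso <- tab[[el]]
    f[[el]] * iso$mass[which.max(iso$abundance)]
  }, numeric(1)))
}

# Merge centroid peaks closer than `width` Th into abundance-weighted
# centroids, greedily chaining along the sorted mass axis.
merge_centroids <- function(mass, ab, width) {
  o <- order(mass)
  mass <- mass[o]
  ab <- ab[o]
  if (length(mass) > 1L) {
    grp <- cumsum(c(1, diff(mass) >= width))
    mass <- as.numeric(tapply(mass * ab, grp, sum) / tapply(ab, grp, sum))
    ab <- as.numeric(tapply(ab, grp, sum))
  }
  list(mass = mass, ab = ab)
}

convolve_centroids <- function(a, b, width, floor_frac = 1e-12) {
  mass <- outer(a$mass, b$mass, "+")
  ab <- outer(a$ab, b$ab, "*")
  out <- merge_centroids(as.numeric(mass), as.numeric(ab), width)
  keep <- out$ab >= floor_frac * max(out$ab)
  list(mass = out$mass[keep], ab = out$ab[keep])
}

#' Isotope pattern of an ion
#'
#' Iterative per-element convolution of the isotope distributions in
#' [isotope_table()]. Peaks closer than `merge_width` are merged into
#' abundance-weighted centroids, peaks below `prune` of the base peak dropped,
#' and abundances normalized so the base peak is exactly 100. m/z values
#' subtract `z` electron masses and divide by `z`.
#'
#' @param f Ion composition (string or `chem_formula`).
#' @param z Positive integer charge.
#' @param prune Minimum relative abundance retained, as a fraction of the base
#'   peak. Use 0 to keep everything.
#' @param merge_width Centroid merge width in Th.
#' @return A data frame of class `isotope_pattern` with columns `mz` (ascending)
#'   and `abundance` (max exactly 100), and attribute `charge`.
#' @examples
#' isotope_pattern("Cl2") # 100 : 64.0 : 10.2
#' @export
isotope_pattern <- function(f, z = 1L, prune = 1e-4, merge_width = 0.01) {
  f <- parse_formula(f)
  stopifnot(z >= 1, z == round(z), prune >= 0, merge_width > 0)
  tab <- isotope_table()
  unknown <- setdiff(names(f), names(tab))
  if (length(unknown)) {
    stop("element(s) not in isotope table: ", paste0(unknown, collapse = ", "),
         call. = FALSE)
  }
  acc <- list(mass = 0, ab = 1)
  for (el in names(f)) {
    iso <- tab[[el]]
    single <- list(mass = iso$mass, ab = iso$abundance)
    n <- f[[el]]
    # binary exponentiation keeps the peak count low for large H/C counts
    pow <- single
    while (n > 0L) {
      if (n %% 2L == 1L) acc <- convolve_centroids(acc, pow, merge_width)
      n <- n %/% 2L
      if (n > 0L) pow <- convolve_centroids(pow, pow, merge_width)
    }
  }
  ab <- 100 * acc$ab / max(acc$ab)
  ab[which.max(acc$ab)] <- 100 # guard the base peak against rounding drift
  keep <- ab >= 100 * prune
  keep[which.max(ab)] <- TRUE # never prune the base peak
  mz <- (acc$mass[keep] - z * ELECTRON_MASS) / z
  out <- data.frame(mz = mz, abundance = ab[keep])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("isotope_pattern", "data.frame"), charge = as.integer(z))
}

# Composition change from chloride loss plus acetonitrile pick-up: the MeCN
# adduct dication seen for IrCp* complexes.
MECN_ADDUCT_DELTA <- c(Cl = -1, C = 2, H = 3, N = 1)

#' Expected ion species for a complex
#'
#' IrCp* complexes are characterized as the aggregate of the parent cation
#' `[M]+` and the MeCN adduct dication `[M - Cl + C2H3N]2+`; every other
#' scaffold is matched on the parent cation alone. The rule is extensible via
#' `extra`.
#'
#' @param complex A one-row data frame or list with at least `id`,
#'   `scaffold_id`, `formula` and `charge`.
#' @param extra Optional list of additional species, each a list with `label`,
#'   `formula_delta` (signed named vector) and `z`.
#' @return A data frame with columns `complex_id`, `label`, `z`, `formula`
#'   (character ion composition), `mz` (monoisotopic m/z).
#' @export
expected_ions <- function(complex, extra = NULL) {
  complex <- as.list(complex)
  stopifnot(!is.null(complex$id), !is.null(complex$scaffold_id), !is.null(complex$formula))
  base <- parse_formula(complex$formula[[1]])
  species <- list(list(label = "M+", formula_delta = numeric(0), z = 1L))
  if (identical(complex$scaffold_id[[1]], "IrCp*")) {
    species <- c(species, list(list(label = "M2+ (MeCN adduct)",
                                    formula_delta = MECN_ADDUCT_DELTA, z = 2L)))
  }
  species <- c(species, extra)
  rows <- lapply(species, function(s) {
    ion <- combine_formula(base, s$formula_delta)
    data.frame(complex_id = complex$id[[1]], label = s$label, z = as.integer(s$z),
               formula = format_formula(ion),
               mz = mz_of(list(formula_delta = s$formula_delta, z = s$z), base),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Monoisotopic m/z of an ion species
#'
#' @param species A list with `formula_delta` (signed named vector, may be
#'   empty) and `z` (positive integer charge).
#' @param base Base cation composition (string or `chem_formula`).
#' @return m/z in Th: `(monoisotopic mass of (base + delta) - z * m_e) / z`.
#' @export
mz_of <- function(species, base) {
  z <- as.integer(species$z)
  stopifnot(z >= 1)
  ion <- combine_formula(base, species$formula_delta %||% numeric(0))
  (monoisotopic_mass(ion) - z * ELECTRON_MASS) / z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
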