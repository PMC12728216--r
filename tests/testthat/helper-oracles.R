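# Independent oracles used to freeze expected values. These deliberately do
# not share code with the implementation paths they check.

# Brute-force isotopologue enumeration: every atom independently picks an
# isotope; probabilities multiply, masses add. Exact for small formulas
# (feasible while the product of isotope-count^atom-count stays small).
brute_force_pattern <- function(formula_str, max_combos = 5e5) {
  f <- metalloscreen::parse_formula(formula_str)
  tab <- metalloscreen::isotope_table()
  choices <- list()
  for (el in names(f)) {
    iso <- tab[[el]]
    for (a in seq_len(f[[el]])) choices[[length(choices) + 1L]] <- seq_len(nrow(iso))
  }
  stopifnot(prod(lengths(choices)) <= max_combos)
  combos <- do.call(expand.grid, choices)
  el_of_atom <- rep(names(f), times = as.integer(f))
  mass <- numeric(nrow(combos))
  prob <- rep(1, nrow(combos))
  for (j in seq_along(el_of_atom)) {
    iso <- tab[[el_of_atom[j]]]
    mass <- mass + iso$mass[combos[[j]]]
    prob <- prob * iso$abundance[combos[[j]]]
  }
  data.frame(mass = mass, prob = prob)
}

# Aggregate a spectrum into nominal-mass clusters and normalize to sum 1,
# removing any dependence on centroid-merge tie-breaking.
nominal_spectrum <- function(mass, weight) {
  agg <- tapply(weight, round(mass), sum)
  out <- as.numeric(agg) / sum(agg)
  names(out) <- names(agg)
  out
}

# Max abs difference between the convolution engine and the brute-force
# oracle for one formula, over the union of nominal-mass bins (zero-filled,
# both normalized to sum 1).
spectrum_max_diff <- function(formula_str) {
  conv <- metalloscreen::isotope_pattern(formula_str, z = 1, prune = 0)
  got <- nominal_spectrum(conv$mz + metalloscreen::ELECTRON_MASS, conv$abundance)
  bf <- brute_force_pattern(formula_str)
  want <- nominal_spectrum(bf$mass, bf$prob)
  bins <- union(names(got), names(want))
  g <- ifelse(bins %in% names(got), got[bins], 0)
  w <- ifelse(bins %in% names(want), want[bins], 0)
  max(abs(g - w))
}

# Closed-form area of an amplitude-A Gaussian peak of SD s (signal x min).
gaussian_area <- function(A, s) A * s * sqrt(2 * pi)

# Quadrature oracle for a sampled trace (full trapezoid over the window).
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Convenience: the shipped ion-trap style two-species run for a complex spec.
make_species_frame <- function(spec, rts, fractions) {
  ions <- metalloscreen::expected_ions(spec)
  data.frame(label = ions$label, formula = ions$formula, z = ions$z,
             rt = rts[seq_len(nrow(ions))],
             fraction = fractions[seq_len(nrow(ions))],
             stringsAsFactors = FALSE)
}
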