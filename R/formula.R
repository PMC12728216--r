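# Elemental-formula algebra: the integer bookkeeping that underpins ligand
# coupling, complex assembly and all mass computations.

#' Parse a Hill-notation elemental formula
#'
#' Accepts strings such as `"C14H12N4"` or `"IrC22H16N2"`. Element symbols are
#' one capital letter optionally followed by one lowercase letter; counts
#' default to 1. An empty string is the empty formula.
#'
#' @param x A character scalar, a named numeric vector of element counts, or an
#'   existing `chem_formula` object (returned unchanged).
#' @return A `chem_formula`: a named integer vector of non-negative element
#'   counts, zero counts dropped.
#' @examples
#' parse_formula("C14H12N4")
#' parse_formula("H2O")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.numeric(x)) return(chem_formula(x))
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- gsub("[[:space:]]", "", x)
  if (!nzchar(x)) return(chem_formula(integer(0)))
  toks <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1L]]
  if (nchar(paste0(toks, collapse = "")) != nchar(x)) {
    stop("malformed formula string: '", x, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(n), suppressWarnings(as.integer(n)), 1L)
  counts <- integer(0)
  for (i in seq_along(el)) {
    counts[el[i]] <- if (el[i] %in% names(counts)) counts[[el[i]]] + n[i] else n[i]
  }
  chem_formula(counts)
}

#' @rdname parse_formula
#' @param counts Named numeric vector of element counts.
#' @export
chem_formula <- function(counts) {
  if (length(counts)) {
    stopifnot(!is.null(names(counts)), all(nzchar(names(counts))))
    if (any(is.na(counts))) stop("NA element count", call. = FALSE)
    if (any(counts < 0)) {
      stop("negative element count (formula underflow): ",
           paste0(names(counts)[counts < 0], collapse = ", "), call. = FALSE)
    }
    if (any(counts != round(counts))) stop("element counts must be integers", call. = FALSE)
    counts <- counts[counts > 0]
    # canonical Hill storage order so equal formulas are identical objects
    els <- names(counts)
    ord <- if ("C" %in% els) {
      c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
    } else {
      sort(els)
    }
    counts <- counts[ord]
  }
  out <- as.integer(round(counts))
  names(out) <- names(counts)
  structure(out, class = "chem_formula")
}

#' Combine a formula with a signed element delta
#'
#' Element-wise addition of `delta` (which may carry negative counts, e.g. the
#' MeCN-adduct delta `c(Cl = -1, C = 2, H = 3, N = 1)`) onto `base`. A result
#' with any negative count is an underflow error.
#'
#' @param base Formula (string or `chem_formula`).
#' @param delta Named numeric vector of signed element counts, or formula.
#' @return A `chem_formula`.
#' @examples
#' combine_formula("C14H12N4", c(N = -2, H = 2)) # back to parent atom sum
#' @export
combine_formula <- function(base, delta) {
  base <- parse_formula(base)
  if (inherits(delta, "chem_formula")) delta <- unclass(delta)
  stopifnot(is.numeric(delta))
  els <- union(names(base), names(delta))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(base)] <- out[names(base)] + as.numeric(base)
  out[names(delta)] <- out[names(delta)] + as.numeric(delta)
  if (any(out < 0)) {
    stop("formula underflow: element(s) ",
         paste0(els[out < 0], collapse = ", "), " would go negative",
         call. = FALSE)
  }
  chem_formula(out)
}

#' @export
`+.chem_formula` <- function(e1, e2) combine_formula(e1, parse_formula(e2))

#' Format a formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (plain alphabetical order when no carbon is present).
#'
#' @param f Formula (string or `chem_formula`).
#' @return A character scalar such as `"C14H12N4"`.
#' @export
format_formula <- function(f) {
  f <- parse_formula(f)
  if (!length(f)) return("")
  els <- names(f)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    if (f[[e]] == 1L) e else paste0(e, f[[e]])
  }, character(1)), collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) format_formula(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.chem_formula <- function(x, ...) format_formula(x)
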