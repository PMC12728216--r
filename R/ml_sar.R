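# Structure-activity modelling: fixed-width binary fingerprints for metal
# complexes, stratified cross-validated linear-SVM classification and
# support-vector feature importance, plus descriptor correlations.
#
# The published 598-bit metal-complex fingerprint is defined elsewhere; this
# module ships a same-width, versioned emulation (scaffold one-hot block,
# donor-environment block, hashed ligand-substructure block) so the true bit
# definitions can be dropped in later without touching the modelling code.

#' Fingerprint configuration
#'
#' Block layout of the 598-bit vector: `n_scaffold` one-hot scaffold-identity
#' bits, `n_donor` donor-environment bits (ligand class, chelate ring size,
#' halide/carbonyl/axial features), and the remaining bits filled by hashed
#' ligand-substructure tokens.
#'
#' @param n_bits Total width (default 598).
#' @param n_scaffold Scaffold block size (default 5).
#' @param n_donor Donor-environment block size (default 13).
#' @param radius Token n-gram radius for structure strings (default 3).
#' @param hash_seed Integer salt for the token hash (default 7).
#' @param version Config version tag.
#' @return A list of class `fp_config`.
#' @export
fp_config <- function(n_bits = 598L, n_scaffold = 5L, n_donor = 13L,
                      radius = 3L, hash_seed = 7L, version = "emulated-0.1") {
  stopifnot(n_bits > n_scaffold + n_donor, radius >= 1)
  structure(list(n_bits = as.integer(n_bits), n_scaffold = as.integer(n_scaffold),
                 n_donor = as.integer(n_donor), radius = as.integer(radius),
                 hash_seed = as.integer(hash_seed), version = version,
                 scaffolds = c("IrCN", "IrCp*", "RuCy", "Re(CO)3", "Mn(CO)3")),
            class = "fp_config")
}

# Deterministic small polynomial string hash into [0, m). Kept in exact
# integer-safe double range, so it is platform independent.
hash_token <- function(token, m, seed = 0L) {
  codes <- utf8ToInt(token)
  h <- 17 + seed
  for (cd in codes) h <- (h * 31 + cd) %% m
  as.integer(h)
}

#' Featurize a metal complex into a fixed-width bit vector
#'
#' Deterministic given the config version and seed: the scaffold block is
#' one-hot, the donor block encodes ligand class, chelate ring size and
#' coarse fragment features, and ligand tokens (structure-string n-grams when
#' a SMILES is available, element-count tokens otherwise) are hashed into the
#' remaining bits.
#'
#' @param complex One-row data frame or list with `scaffold_id`,
#'   `ligand_class`, `formula`, `ligand_id`; optional `smiles`.
#' @param config A [fp_config()].
#' @return Named integer vector of 0/1 of length `config$n_bits`.
#' @export
featurize <- function(complex, config = fp_config()) {
  complex <- as.list(complex)
  v <- integer(config$n_bits)
  names(v) <- feature_names(config)
  sc <- match(complex$scaffold_id[[1]], config$scaffolds)
  if (is.na(sc)) stop("unknown scaffold: ", complex$scaffold_id[[1]], call. = FALSE)
  v[sc] <- 1L
  d0 <- config$n_scaffold
  cls <- complex$ligand_class[[1]]
  frag <- parse_formula(complex$formula[[1]])
  donor <- c(
    cls == "Tz-4-P",                 # 5-membered chelate, triazole-4-pyridine
    cls == "Tz-1-MP",                # 6-membered chelate, methylene linker
    ("Cl" %in% names(frag)),         # retained halide
    ("Br" %in% names(frag)),
    ("O" %in% names(frag)) && frag[["O"]] >= 3, # carbonyl-rich fragment
    complex$scaffold_id[[1]] %in% c("Re(CO)3", "Mn(CO)3"), # axial imidazole
    ("F" %in% names(frag)),
    ("S" %in% names(frag)),
    frag[["N"]] >= 6,                # N-rich coordination sphere
    frag[["C"]] >= 25,               # large aromatic surface
    frag[["H"]] / max(frag[["C"]], 1) > 1, # aliphatic character
    ("N" %in% names(frag)) && frag[["N"]] >= 4 && cls == "Tz-4-P",
    ("O" %in% names(frag)) && !(complex$scaffold_id[[1]] %in% c("Re(CO)3", "Mn(CO)3"))
  )
  v[d0 + seq_len(config$n_donor)] <- as.integer(donor[seq_len(config$n_donor)])
  h0 <- d0 + config$n_donor
  m <- config$n_bits - h0
  smiles <- complex$smiles[[1]] %||% NA_character_
  tokens <- if (!is.na(smiles) && nzchar(smiles)) {
    ngrams(smiles, config$radius)
  } else {
    paste0(names(frag), ":", as.integer(frag))
  }
  tokens <- c(tokens, paste0("lig:", complex$ligand_id[[1]] %||% ""))
  for (tk in tokens) v[h0 + 1L + hash_token(tk, m, config$hash_seed)] <- 1L
  v
}

ngrams <- function(s, k) {
  n <- nchar(s)
  if (n <= k) return(s)
  vapply(seq_len(n - k + 1L), function(i) substr(s, i, i + k - 1L), character(1))
}

#' @rdname featurize
#' @param complexes Complex data frame (one row per compound).
#' @return `featurize_library`: a 0/1 matrix, one row per complex.
#' @export
featurize_library <- function(complexes, config = fp_config()) {
  X <- t(vapply(seq_len(nrow(complexes)), function(i) featurize(complexes[i, ], config),
                integer(config$n_bits)))
  rownames(X) <- complexes$id
  colnames(X) <- feature_names(config)
  X
}

feature_names <- function(config) {
  c(paste0("scaffold:", config$scaffolds[seq_len(config$n_scaffold)]),
    paste0("donor:", seq_len(config$n_donor)),
    paste0("sub:", seq_len(config$n_bits - config$n_scaffold - config$n_donor)))
}

#' Binary activity labels from an MIC table
#'
#' @param mic_table Data frame with columns `compound_id` and `mic_uM`
#'   (`NA` = censored).
#' @param cutoff Activity cutoff in uM (default 6.25).
#' @return Named integer vector of 0/1 labels.
#' @export
make_labels <- function(mic_table, cutoff = 6.25) {
  stats::setNames(
    vapply(mic_table$mic_uM, binarize_activity, integer(1), cutoff = cutoff),
    mic_table$compound_id)
}

#' Stratified k-fold cross-validation of a linear SVM
#'
#' Folds are stratified by class under a fixed seed; each fold is scored on
#' held-out data with AUC, precision, recall and F1, and the report carries
#' the fold assignment for reproducibility. Needs at least `k` members of
#' each class.
#'
#' @param X Bit matrix (rows = compounds).
#' @param y Binary labels.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param C SVM regularization constant (default 1).
#' @return A list of class `cv_report`: `per_fold` (data frame), `mean`,
#'   `sd`, `folds` (assignment vector), `k`, `seed`, `model` (fit on all
#'   data).
#' @export
cv_train_svm <- function(X, y, k = 5L, seed = 1L, C = 1) {
  X <- as.matrix(X)
  k <- as.integer(k)
  y <- as.integer(y > 0)
  stopifnot(nrow(X) == length(y))
  if (sum(y == 1L) < k || sum(y == 0L) < k) {
    stop("stratification error: need at least k members of each class", call. = FALSE)
  }
  folds <- integer(length(y))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  per_fold <- t(vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- svm_linear(X[tr, , drop = FALSE], y[tr], C = C)
    classification_metrics(predict(fit, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(4)))
  per_fold <- as.data.frame(per_fold)
  per_fold$fold <- seq_len(k)
  structure(list(per_fold = per_fold[, c("fold", "auc", "precision", "recall", "f1")],
                 mean = colMeans(per_fold[c("auc", "precision", "recall", "f1")], na.rm = TRUE),
                 sd = vapply(per_fold[c("auc", "precision", "recall", "f1")],
                             stats::sd, numeric(1), na.rm = TRUE),
                 folds = folds, k = k, seed = seed,
                 model = svm_linear(X, y, C = C)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated linear SVM (seed %d)\n", x$k, x$seed))
  for (m in names(x$mean)) {
    cat(sprintf("  mean %-9s %.2f ± %.2f\n", toupper(m), x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Support-vector feature importance of a linear SVM
#'
#' Ranks features by the absolute value of the primal weight vector
#' `w = sum_i alpha_i y_i x_i` recovered from the support vectors; a positive
#' sign associates the feature with the active class. Only defined for the
#' linear kernel.
#'
#' @param model A `linear_svm` (or a `cv_report`, whose full-data model is
#'   used).
#' @param feature_names Feature names (defaults to `names(model$w)` order).
#' @return A data frame `feature`, `weight`, sorted by `|weight|` descending.
#' @export
feature_importance <- function(model, feature_names = NULL) {
  if (inherits(model, "cv_report")) model <- model$model
  if (!inherits(model, "linear_svm")) {
    stop("unsupported kernel: feature importance needs a linear SVM", call. = FALSE)
  }
  nm <- feature_names %||% paste0("bit", seq_along(model$w))
  out <- data.frame(feature = nm, weight = model$w, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$weight)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptor correlations for SAR analysis
#'
#' Pearson and Spearman coefficients for the declared descriptor pairs
#' (retention time vs cLogP, molecular weight vs activity and toxicity,
#' sp3-carbon fraction vs activity by default), plus active/inactive group
#' means. Constant columns are flagged rather than given a coefficient.
#'
#' @param table Data frame with the descriptor columns referenced in `pairs`.
#' @param pairs List of 2-element character vectors naming column pairs.
#' @return A list: `correlations` (data frame `x`, `y`, `pearson`,
#'   `spearman`, `n`, `flag`), `group_summary` (means by `activity` when that
#'   column exists).
#' @export
descriptor_correlations <- function(table,
                                    pairs = list(c("rt_min", "clogp"),
                                                 c("mw", "activity"),
                                                 c("mw", "toxicity_pct"),
                                                 c("fsp3", "activity"))) {
  stopifnot(nrow(table) >= 3L)
  rows <- lapply(pairs, function(p) {
    x <- table[[p[1]]]
    y <- table[[p[2]]]
    if (is.null(x) || is.null(y)) {
      return(data.frame(x = p[1], y = p[2], pearson = NA_real_, spearman = NA_real_,
                        n = 0L, flag = "missing-column"))
    }
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(x = p[1], y = p[2], pearson = NA_real_, spearman = NA_real_,
                        n = sum(ok), flag = "undefined-correlation"))
    }
    data.frame(x = p[1], y = p[2],
               pearson = stats::cor(x[ok], y[ok]),
               spearman = stats::cor(x[ok], y[ok], method = "spearman"),
               n = sum(ok), flag = "")
  })
  group <- NULL
  if (!is.null(table$activity)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    num <- setdiff(num, "activity")
    group <- stats::aggregate(table[num], by = list(activity = table$activity),
                              FUN = mean, na.rm = TRUE)
  }
  list(correlations = do.call(rbind, rows), group_summary = group)
}
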