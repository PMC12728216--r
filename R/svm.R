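# Linear support-vector machine via dual coordinate descent (the L1-loss
# algorithm of Hsieh et al., ICML 2008). Implemented in-package because the
# weight vector w = sum_i alpha_i y_i x_i must be recoverable for
# support-vector feature importance, and no SVM library is assumed.

#' Fit a linear SVM by dual coordinate descent
#'
#' Hinge-loss (L1) SVM with box constraint `0 <= alpha_i <= C`, solved in the
#' dual with sequential coordinate updates; a bias term is handled through an
#' augmented constant feature. The solver is deterministic (no randomized
#' sweep order), so refits are bit-identical.
#'
#' @param X Numeric matrix, rows = samples.
#' @param y Labels in `{-1, +1}` (or `{0, 1}`, remapped).
#' @param C Regularization constant (default 1).
#' @param max_pass Maximum sweeps over the data (default 200).
#' @param tol Stop when the largest alpha update in a sweep falls below this
#'   (default 1e-8).
#' @return A list of class `linear_svm`: `w`, `b`, `alpha`, `support`
#'   (indices with alpha > 0), `converged`, `passes`.
#' @export
svm_linear <- function(X, y, C = 1, max_pass = 200L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y), C > 0)
  n <- nrow(X)
  Xa <- cbind(X, 1) # augmented bias feature
  Q <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  passes <- 0L
  converged <- FALSE
  for (pass in seq_len(max_pass)) {
    passes <- pass
    delta_max <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * Xa[i, ]) - 1
      a_new <- min(max(alpha[i] - g / Q[i], 0), C)
      d <- a_new - alpha[i]
      if (d != 0) {
        w <- w + d * y[i] * Xa[i, ]
        alpha[i] <- a_new
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) {
      converged <- TRUE
      break
    }
  }
  p <- ncol(X)
  w <- unname(w)
  structure(list(w = w[seq_len(p)], b = w[p + 1L], alpha = alpha,
                 support = which(alpha > 0), converged = converged,
                 passes = passes, C = C),
            class = "linear_svm")
}

#' Decision values of a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Numeric matrix.
#' @param ... Unused.
#' @return Numeric decision values; the sign is the predicted class.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$w + object$b)
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) on decision scores; ties share rank.
#'
#' @param scores Decision values.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`, `NA` when one class is absent.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classification_metrics <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  pred <- as.integer(scores > 0)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(auc = roc_auc(scores, labels), precision = precision, recall = recall, f1 = f1)
}
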