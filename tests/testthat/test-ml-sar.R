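test_that("fingerprints are 598 bits, deterministic, and block-structured", {
  camp <- enumerate_campaign()
  cfg <- fp_config()
  ids <- c("Re(CO)3(M1Y1)", "IrCN(M1Y1)", "RuCy(P1A1)", "IrCp*(M5Y2)")
  for (id in ids) {
    v <- featurize(camp$complexes[camp$complexes$id == id, ], cfg)
    expect_identical(length(v), 598L)
    expect_true(all(v %in% c(0L, 1L)))
  }
  row <- camp$complexes[camp$complexes$id == "Re(CO)3(M1Y1)", ]
  expect_identical(featurize(row, cfg), featurize(row, cfg))
  # same ligand on two scaffolds: scaffold one-hot block must differ
  a <- featurize(camp$complexes[camp$complexes$id == "Re(CO)3(M1Y1)", ], cfg)
  b <- featurize(camp$complexes[camp$complexes$id == "IrCN(M1Y1)", ], cfg)
  expect_false(identical(a[1:5], b[1:5]))
  expect_identical(sum(a[1:5]), 1L)
  expect_identical(sum(b[1:5]), 1L)
  X <- featurize_library(camp$complexes[1:10, ], cfg)
  expect_identical(dim(X), c(10L, 598L))
  expect_error(featurize(list(scaffold_id = "PtCl2", ligand_class = "Tz-4-P",
                              formula = "C2H4", ligand_id = "x"), cfg),
               "unknown scaffold")
})

test_that("labelling delegates to the 6.25 uM activity cutoff", {
  tab <- data.frame(compound_id = c("a", "b", "c", "d"),
                    mic_uM = c(3.13, 50, 6.25, NA))
  expect_identical(unname(make_labels(tab)), c(1L, 0L, 1L, 0L))
})

test_that("cross-validated SVM separates a separable planted rule perfectly", {
  d <- sim_activity_dataset(n = 192,
                            rule = list(bits = c(3L, 7L), weights = c(2, -2),
                                        intercept = -1),
                            label_noise = 0, seed = 3)
  rep <- cv_train_svm(d$X, d$y, k = 5, seed = 2)
  expect_identical(unname(rep$mean[["auc"]]), 1)
  expect_true(all(rep$per_fold$auc == 1))
  # report internals: folds partition, metrics in [0,1], F1 identity per fold
  expect_identical(sort(unique(rep$folds)), 1:5)
  m <- as.matrix(rep$per_fold[, c("auc", "precision", "recall", "f1")])
  expect_true(all(m >= 0 & m <= 1))
  f1 <- with(rep$per_fold, 2 * precision * recall / (precision + recall))
  expect_true(all(abs(f1 - rep$per_fold$f1) < 1e-12))
  expect_match(paste(utils::capture.output(print(rep)), collapse = "\n"),
               "fold", ignore.case = TRUE)
})

test_that("permuted labels give chance-level AUC", {
  d <- sim_activity_dataset(n = 200, label_noise = 0, seed = 9)
  set.seed(101)
  aucs <- vapply(1:3, function(i) {
    yp <- sample(d$y)
    mean(cv_train_svm(d$X, yp, k = 5, seed = i)$per_fold$auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("stratification guards and class requirements hold", {
  d <- sim_activity_dataset(n = 40, label_noise = 0, seed = 2)
  y <- rep(0L, 40)
  y[1:3] <- 1L # fewer positives than folds
  expect_error(cv_train_svm(d$X, y, k = 5, seed = 1), "stratification")
})

test_that("support-vector importance recovers planted bits and symmetries", {
  d <- sim_activity_dataset(n = 192,
                            rule = list(bits = c(3L, 7L), weights = c(2, -2),
                                        intercept = -1),
                            label_noise = 0, seed = 3)
  fit <- svm_linear(d$X, d$y)
  imp <- feature_importance(fit, colnames(d$X))
  expect_true(all(c("bit3", "bit7") %in% imp$feature[1:3]))
  # signs point toward the class the bit drives
  expect_gt(imp$weight[imp$feature == "bit3"], 0)
  expect_lt(imp$weight[imp$feature == "bit7"], 0)
  # a constant bit gets exactly zero weight and ranks last
  Xc <- d$X
  Xc[, 42] <- 0L
  fitc <- svm_linear(Xc, d$y)
  impc <- feature_importance(fitc, colnames(Xc))
  expect_identical(fitc$w[42], 0)
  expect_true(which(impc$feature == "bit42") >
                sum(abs(impc$weight) > 0))
  # flipping all labels negates every weight
  fitf <- svm_linear(d$X, 1L - d$y)
  expect_equal(fitf$w, -fit$w, tolerance = 1e-9)
  expect_error(feature_importance(structure(list(), class = "rbf_svm")),
               "unsupported kernel")
})

test_that("descriptor correlations report declared pairs and flag degenerates", {
  set.seed(5)
  n <- 60
  clogp <- rnorm(n, 2, 1)
  tab <- data.frame(compound_id = seq_len(n),
                    rt_min = 1.2 + 0.8 * clogp, # perfectly collinear
                    clogp = clogp,
                    mw = rnorm(n, 600, 80),
                    fsp3 = runif(n),
                    toxicity_pct = runif(n, 0, 100))
  # planted negative MW-activity relationship through a logistic generator
  tab$activity <- rbinom(n, 1, plogis(-(tab$mw - 600) / 40))
  out <- descriptor_correlations(tab)
  rt_row <- out$correlations[out$correlations$x == "rt_min", ]
  expect_equal(rt_row$pearson, 1, tolerance = 1e-12)
  mw_row <- out$correlations[out$correlations$x == "mw" &
                               out$correlations$y == "activity", ]
  expect_lt(mw_row$pearson, 0)
  expect_identical(nrow(out$group_summary), 2L)
  # constant descriptor flagged, no coefficient
  tab$clogp <- 1
  out2 <- descriptor_correlations(tab)
  expect_identical(out2$correlations$flag[1], "undefined-correlation")
  expect_true(is.na(out2$correlations$pearson[1]))
})
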