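test_that("cluster-mean feature extraction yields one column per (metric, cluster)", {
  d <- c(6, 6, 6)
  lv_a <- array(0L, d); lv_a[1:2, 1, 1] <- 1L; lv_a[4, 4, 4] <- 2L; lv_a[6, 6, 6] <- 3L
  lv_f <- array(0L, d); lv_f[2, 2, 2] <- 1L; lv_f[3, 3, 3] <- 2L; lv_f[5, 5, 1] <- 3L
  tab_a <- data.frame(cluster_id = 1:3, atlas_label = c("A", "B", "C"))
  attr(tab_a, "label_volume") <- lv_a
  tab_f <- data.frame(cluster_id = 1:3, atlas_label = c("D", "E", "F"))
  attr(tab_f, "label_volume") <- lv_f
  subj_maps <- lapply(c(0, 1, 2, 3), function(c0) array(c0, d))
  fm <- extract_features(list(ALFF = subj_maps, fALFF = subj_maps),
                         list(ALFF = tab_a, fALFF = tab_f),
                         c("patient", "patient", "control", "control"))
  expect_equal(ncol(fm$values), 6)          # 3 ALFF + 3 fALFF clusters
  expect_equal(unname(fm$values[2, ]), rep(1, 6))  # constant map -> constant
  # single-voxel cluster picks that voxel's value
  m4 <- array(0, d); m4[4, 4, 4] <- 42
  fm2 <- extract_features(list(ALFF = list(m4, m4)), list(ALFF = tab_a),
                          c("patient", "control"))
  expect_equal(unname(fm2$values[1, 2]), 42)
  expect_error(extract_features(list(ALFF = subj_maps),
                                list(ALFF = NULL),
                                rep("patient", 4)), "no clusters")
})

test_that("min-max scaling maps training ranges onto [-1, 1] with clipping", {
  tr <- cbind(a = c(2, 4, 6), b = c(0, 1, 2))
  sc <- scale_features(tr)
  expect_equal(unname(sc[, 1]), c(-1, 0, 1))
  expect_true(all(sc >= -1 & sc <= 1))
  te <- scale_features(tr, cbind(a = c(1, 7), b = c(0.5, 1)))
  expect_equal(unname(te[, 1]), c(-1, 1))   # out-of-range values clip
  expect_equal(unname(te[2, 2]), 0)
  expect_warning(sc2 <- scale_features(cbind(k = c(3, 3, 3))), "constant")
  expect_true(all(sc2 == 0))
})

test_that("Q-learning training is seeded, inert at alpha = 0, and separates", {
  fm <- separable_features(20, 18, mu = 0.6, sd = 0.1, seed = 2)
  Xs <- scale_features(fm$values)
  f0 <- q_train(Xs, fm$labels, alpha = 0, epochs = 50, seed = 1)
  expect_true(all(f0$weights == 0))
  f1 <- q_train(Xs, fm$labels, epochs = 300, seed = 9)
  f2 <- q_train(Xs, fm$labels, epochs = 300, seed = 9)
  expect_identical(f1$weights, f2$weights)
  f3 <- q_train(Xs, fm$labels, epochs = 300, seed = 10)
  expect_false(identical(f1$weights, f3$weights))
  pr <- q_predict(f1, Xs)
  expect_equal(mean(pr$labels == fm$labels), 1)   # separable fixture learned
  expect_error(q_train(Xs, rep("patient", nrow(Xs))), "both classes")
  expect_error(q_train(Xs, fm$labels, gamma = 1), "gamma")
})

test_that("prediction scores are action-value differences with a control tie rule", {
  model <- structure(list(weights = matrix(0, 2, 4), gamma = 0.9,
                          alpha = 0.001, epochs = 1L, epsilon0 = 0,
                          seed = 1L, feature_names = paste0("f", 1:3)),
                     class = "q_model")
  X <- matrix(rnorm(9), 3, 3)
  pr <- q_predict(model, X)
  expect_true(all(pr$scores == 0))
  expect_true(all(pr$labels == "control"))        # ties go to control
  # adding the same constant to both biases leaves scores unchanged
  m2 <- model; m2$weights[, 4] <- m2$weights[, 4] + 5
  expect_equal(q_predict(m2, X)$scores, pr$scores)
  expect_error(q_predict(model, matrix(0, 2, 5)), "dimension")
})

test_that("LOOCV separates the synthetic fixture and respects fold isolation", {
  fm <- separable_features(16, 14, mu = 0.6, sd = 0.1, seed = 4)
  rep1 <- loocv(fm, epochs = 200, seed = 3)
  expect_gte(rep1$accuracy, 95)
  expect_gte(rep1$auc, 0.99)
  expect_equal(nrow(rep1$predictions), 30)
  # the held-out subject cannot influence the fold's scaling or training:
  # replacing subject 1 by an extreme outlier leaves fold 1's model intact
  fm_out <- fm
  fm_out$values[1, ] <- 1e4
  tr_ref <- scale_features(fm$values[-1, , drop = FALSE])
  tr_out <- scale_features(fm_out$values[-1, , drop = FALSE])
  expect_identical(tr_ref, tr_out)
  w_ref <- q_train(tr_ref, fm$labels[-1], epochs = 50, seed = 7)$weights
  w_out <- q_train(tr_out, fm_out$labels[-1], epochs = 50, seed = 7)$weights
  expect_identical(w_ref, w_out)
  # and the outlier itself is clipped into the training range
  sc <- scale_features(fm_out$values[-1, , drop = FALSE],
                       fm_out$values[1, , drop = FALSE])
  expect_true(all(sc <= 1))
  expect_error(loocv(feature_matrix(matrix(1:2, 2, 1), c("patient", "control"))),
               "at least 3")
})

test_that("whole-sample scaling mode exists and differs from per-fold", {
  fm <- separable_features(8, 8, mu = 0.3, sd = 0.3, seed = 6)
  r1 <- loocv(fm, epochs = 100, seed = 2, scaling = "per-fold")
  r2 <- loocv(fm, epochs = 100, seed = 2, scaling = "whole-sample")
  expect_false(identical(r1$predictions$score, r2$predictions$score))
})

test_that("report_metrics reproduces percentage formulas and flags undefined", {
  r <- report_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(c(r$accuracy, r$sensitivity, r$specificity, r$precision),
               rep(100, 4))
  # swapping the positive class swaps sensitivity and specificity
  truth <- factor(c(rep("patient", 6), rep("control", 4)),
                  c("patient", "control"))
  pred <- factor(c(rep("patient", 4), rep("control", 2), "patient",
                   rep("control", 3)), c("patient", "control"))
  a <- report_metrics(truth, pred)
  flip <- function(f) factor(ifelse(f == "patient", "control", "patient"),
                             c("patient", "control"))
  b <- report_metrics(flip(truth), flip(pred))
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  und <- report_metrics(tp = 0, fp = 0, tn = 4, fn = 0)
  expect_true(is.na(und$precision))
  expect_true("precision" %in% und$undefined)
})

test_that("the ROC staircase and trapezoidal AUC match an independent oracle", {
  skip_if_not_installed("pROC")
  set.seed(12)
  truth <- factor(sample(c("patient", "control"), 60, TRUE),
                  c("patient", "control"))
  scores <- rnorm(60) + (truth == "patient") * 0.8
  pred <- factor(ifelse(scores > 0, "patient", "control"),
                 c("patient", "control"))
  rep1 <- report_metrics(truth, pred, scores)
  oracle <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("control", "patient"),
    direction = "<", quiet = TRUE)))
  expect_equal(rep1$auc, oracle, tolerance = 1e-12)
  expect_equal(rep1$roc$fpr[1], 0)
  expect_equal(rep1$roc$tpr[nrow(rep1$roc)], 1)
  expect_true(all(diff(rep1$roc$fpr) >= 0) && all(diff(rep1$roc$tpr) >= 0))
  # perfectly separated scores give AUC 1
  sep <- report_metrics(truth,
                        factor(ifelse(truth == "patient", "patient", "control"),
                               c("patient", "control")),
                        ifelse(truth == "patient", 1, -1))
  expect_equal(sep$auc, 1)
})

test_that("the whole classification chain absorbs per-feature affine rescaling", {
  fm <- separable_features(10, 9, mu = 0.4, sd = 0.2, seed = 8)
  fm2 <- fm
  fm2$values <- sweep(sweep(fm$values, 2, c(2, 5, 0.3, 1, 10, 4), "*"),
                      2, c(-3, 0, 7, 1, 2, 0), "+")
  r1 <- loocv(fm, epochs = 80, seed = 3)
  r2 <- loocv(fm2, epochs = 80, seed = 3)
  expect_equal(r1$predictions$score, r2$predictions$score, tolerance = 1e-10)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("Q-models round-trip through their JSON serialisation", {
  fm <- separable_features(6, 6, seed = 14)
  Xs <- scale_features(fm$values)
  fit <- q_train(Xs, fm$labels, epochs = 30, seed = 2)
  p <- tempfile(fileext = ".json")
  write_q_model(fit, p)
  fit2 <- read_q_model(p)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-12)
  expect_equal(fit2$gamma, fit$gamma)
  expect_equal(q_predict(fit2, Xs)$scores, q_predict(fit, Xs)$scores,
               tolerance = 1e-12)
})
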