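#' Subjects-by-features matrix with group labels
#'
#' @param values numeric matrix, one row per subject.
#' @param labels `"patient"`/`"control"` per subject (patient is the
#'   positive class throughout).
#' @param feature_names optional column names.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  labels <- factor(as.character(labels), levels = c("patient", "control"))
  if (nrow(values) != length(labels)) stop("one label per subject required")
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  if (anyNA(labels)) stop("labels must be 'patient' or 'control'")
  if (!is.null(feature_names)) colnames(values) <- feature_names
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  structure(list(values = values, labels = labels,
                 feature_names = colnames(values)),
            class = "feature_matrix")
}

#' Cluster-mean features from metric maps
#'
#' One feature per (metric, cluster): the mean of each subject's z-map over
#' the cluster's voxels. `maps_by_metric` and `clusters_by_metric` are
#' parallel named lists (e.g. `ALFF`, `fALFF`); each cluster table must carry
#' the `label_volume` attribute produced by [grf_cluster_correction()].
#'
#' @param maps_by_metric named list; each element a list of per-subject
#'   `metric_map`s (or 3D arrays).
#' @param clusters_by_metric named list of cluster tables.
#' @param labels per-subject group labels.
#' @return A `feature_matrix` with
#'   `sum(cluster counts)` columns named `<metric>.<atlas label or id>`.
#' @export
extract_features <- function(maps_by_metric, clusters_by_metric, labels) {
  stopifnot(is.list(maps_by_metric), is.list(clusters_by_metric))
  metrics <- names(maps_by_metric)
  blocks <- list()
  for (m in metrics) {
    tab <- clusters_by_metric[[m]]
    if (is.null(tab) || nrow(tab) == 0) next
    lab_vol <- attr(tab, "label_volume")
    if (is.null(lab_vol)) stop("cluster table lacks a label_volume attribute")
    maps <- maps_by_metric[[m]]
    vals <- lapply(maps, function(mm) if (inherits(mm, "metric_map")) mm$values else mm)
    for (r in seq_len(nrow(tab))) {
      vox <- which(lab_vol == tab$cluster_id[r])
      if (!length(vox)) stop("cluster ", tab$cluster_id[r], " is empty")
      col <- vapply(vals, function(a) mean(a[vox]), numeric(1))
      nm <- sprintf("%s.%s", m, tab$atlas_label[r])
      # disambiguate repeated atlas labels within a metric
      while (nm %in% names(blocks)) nm <- paste0(nm, "'")
      blocks[[nm]] <- col
    }
  }
  if (!length(blocks)) stop("no clusters available for feature extraction")
  feature_matrix(do.call(cbind, blocks), labels, names(blocks))
}

#' Min-max scale features to the interval -1..1
#'
#' The affine map per feature sends the training minimum to -1 and maximum
#' to +1; values of `apply_to` outside the training range are clipped.
#' Constant training columns map to 0 (with a warning).
#'
#' @param train numeric matrix (or `feature_matrix`) defining the ranges.
#' @param apply_to matrix to scale; defaults to `train`.
#' @return Scaled numeric matrix with attributes `train_min`, `train_max`.
#' @export
scale_features <- function(train, apply_to = train) {
  tr <- if (inherits(train, "feature_matrix")) train$values else as.matrix(train)
  ap <- if (inherits(apply_to, "feature_matrix")) apply_to$values else as.matrix(apply_to)
  lo <- apply(tr, 2, min); hi <- apply(tr, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warning("constant training feature(s) scaled to 0: ",
            paste(colnames(tr)[flat], collapse = ", "))
    rng[flat] <- 1
  }
  out <- sweep(ap, 2, lo)
  out <- sweep(out, 2, rng, "/") * 2 - 1
  out[, flat] <- 0
  out <- pmin(pmax(out, -1), 1)
  attr(out, "train_min") <- lo
  attr(out, "train_max") <- hi
  out
}

#' Train the Q-learning classifier
#'
#' Classification is cast as a sequential decision problem: an episode is
#' one seeded shuffle of the training set; the state is the current
#' subject's (scaled) feature vector; the two actions are predict-patient
#' and predict-control; the reward is +1 for a correct prediction and -1
#' otherwise; the next state is the next subject in the shuffled stream
#' (terminal after the last, where the bootstrap term is dropped). Action
#' values are linear, `Q(s, a) = w_a . [s; 1]`, learned by the
#' temporal-difference update
#' `w_a <- w_a + alpha * (r + gamma * max_a' Q(s', a') - Q(s, a)) * [s; 1]`
#' under epsilon-greedy behaviour with epsilon decaying linearly from
#' `epsilon0` to 0 across epochs. Weights start at zero, so `alpha = 0`
#' leaves them unchanged.
#'
#' @param features scaled numeric matrix (subjects x features).
#' @param labels `"patient"`/`"control"` per subject; both classes must be
#'   present.
#' @param gamma discount factor in `[0, 1)`; default 0.9.
#' @param alpha learning rate (> 0 for learning); default 0.001.
#' @param epochs number of passes over the shuffled training set.
#' @param epsilon0 initial exploration rate.
#' @param seed integer seed (shuffles and exploration).
#' @return Object of class `q_model`: `weights` (2 x (p+1); rows
#'   predict-patient, predict-control; last column the bias), hyperparameters
#'   and `feature_names`.
#' @export
q_train <- function(features, labels, gamma = 0.9, alpha = 0.001,
                    epochs = 1000L, epsilon0 = 0.3, seed = 1L) {
  X <- as.matrix(features)
  y <- as.integer(factor(as.character(labels),
                         levels = c("control", "patient"))) - 1L
  if (anyNA(y)) stop("labels must be 'patient' or 'control'")
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  if (!(gamma >= 0 && gamma < 1)) stop("`gamma` must lie in [0, 1)")
  if (alpha < 0) stop("`alpha` must be non-negative")
  set.seed(as.integer(seed))
  w <- qlearn_train_cpp(X, y, gamma, alpha, as.integer(epochs), epsilon0)
  rownames(w) <- c("predict_patient", "predict_control")
  colnames(w) <- c(colnames(X) %||% paste0("f", seq_len(ncol(X))), "bias")
  structure(list(weights = w, gamma = gamma, alpha = alpha,
                 epochs = as.integer(epochs), epsilon0 = epsilon0,
                 seed = as.integer(seed),
                 feature_names = colnames(X)),
            class = "q_model")
}

#' Predict with a trained Q-model
#'
#' The decision score is `g(s) = Q(s, patient) - Q(s, control)`; the label is
#' patient when `g(s) > 0` and control otherwise (ties go to control).
#'
#' @param model a `q_model`.
#' @param features matrix with the model's feature dimension.
#' @return list with `labels` (factor patient/control) and `scores`.
#' @export
q_predict <- function(model, features) {
  stopifnot(inherits(model, "q_model"))
  X <- as.matrix(features)
  p <- ncol(model$weights) - 1L
  if (ncol(X) != p) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(X), p))
  }
  dw <- model$weights[1, ] - model$weights[2, ]
  scores <- as.numeric(cbind(X, 1) %*% dw)
  labels <- factor(ifelse(scores > 0, "patient", "control"),
                   levels = c("patient", "control"))
  list(labels = labels, scores = scores)
}

#' Leave-one-out cross-validation of the Q-learning classifier
#'
#' For each subject, feature scaling and training use only the remaining
#' subjects (per-fold scaling avoids leaking the held-out subject's range;
#' `scaling = "whole-sample"` scales once on everyone for fidelity
#' experiments). Pooled held-out labels and decision scores yield the
#' confusion matrix, the percentage metrics, and the ROC/AUC.
#'
#' @param features a `feature_matrix` (>= 3 subjects).
#' @param gamma,alpha,epochs,epsilon0 hyperparameters, see [q_train()].
#' @param seed integer seed; fold f trains with seed `seed + f`.
#' @param scaling `"per-fold"` (default) or `"whole-sample"`.
#' @return A `classification_report` (see [report_metrics()]) with an extra
#'   `predictions` data.frame (subject, truth, predicted, score).
#' @export
loocv <- function(features, gamma = 0.9, alpha = 0.001, epochs = 1000L,
                  epsilon0 = 0.3, seed = 1L,
                  scaling = c("per-fold", "whole-sample")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(features, "feature_matrix"))
  X <- features$values
  y <- features$labels
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 subjects")
  scores <- numeric(n)
  pred <- character(n)
  whole <- if (scaling == "whole-sample") scale_features(X) else NULL
  for (i in seq_len(n)) {
    if (scaling == "per-fold") {
      Xtr <- scale_features(X[-i, , drop = FALSE])
      Xte <- scale_features(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    } else {
      Xtr <- whole[-i, , drop = FALSE]
      Xte <- whole[i, , drop = FALSE]
    }
    fit <- q_train(Xtr, y[-i], gamma = gamma, alpha = alpha, epochs = epochs,
                   epsilon0 = epsilon0, seed = seed + i)
    pr <- q_predict(fit, Xte)
    scores[i] <- pr$scores
    pred[i] <- as.character(pr$labels)
  }
  pred <- factor(pred, levels = c("patient", "control"))
  rep <- report_metrics(truth = y, predicted = pred, scores = scores)
  rep$predictions <- data.frame(subject = seq_len(n), truth = y,
                                predicted = pred, score = scores)
  rep
}

# ROC staircase by descending score; ties grouped. Returns fpr/tpr points
# from (0,0) to (1,1).
roc_points <- function(truth, scores) {
  pos <- truth == "patient"
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(p)[grp_end]; fp <- cumsum(!p)[grp_end]
  data.frame(fpr = c(0, fp / sum(!pos)), tpr = c(0, tp / sum(pos)))
}

#' Classification metrics from a confusion matrix and scores
#'
#' Patient is the positive class. Accuracy, sensitivity, specificity and
#' precision are reported as percentages; a metric with a zero denominator
#' is reported as `NA` and listed in the `undefined` field rather than
#' forced to 0. The AUC is the trapezoidal integral of the ROC staircase
#' obtained by sweeping a threshold over the pooled scores.
#'
#' Either give `truth`/`predicted` (plus optional `scores`) or the four
#' counts directly.
#'
#' @param truth,predicted factors with levels patient/control.
#' @param scores optional decision scores (needed for ROC/AUC).
#' @param tp,fp,tn,fn confusion counts, used when `truth` is missing.
#' @return Object of class `classification_report`: `confusion` (tp, fp,
#'   tn, fn), `accuracy`, `sensitivity`, `specificity`, `precision`
#'   (percent), `auc`, `roc` (data.frame fpr/tpr), `undefined`.
#' @export
report_metrics <- function(truth = NULL, predicted = NULL, scores = NULL,
                           tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(truth)) {
    truth <- factor(as.character(truth), levels = c("patient", "control"))
    predicted <- factor(as.character(predicted), levels = c("patient", "control"))
    tp <- sum(truth == "patient" & predicted == "patient")
    fp <- sum(truth == "control" & predicted == "patient")
    tn <- sum(truth == "control" & predicted == "control")
    fn <- sum(truth == "patient" & predicted == "control")
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || sum(counts) == 0) stop("confusion counts required")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    confusion = counts,
    accuracy = pct(tp + tn, sum(counts)),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp),
    auc = NA_real_, roc = NULL
  )
  out$undefined <- names(Filter(is.na, out[c("accuracy", "sensitivity",
                                             "specificity", "precision")]))
  if (!is.null(scores) && !is.null(truth) &&
      sum(truth == "patient") > 0 && sum(truth == "control") > 0) {
    roc <- roc_points(truth, scores)
    out$roc <- roc
    out$auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  }
  structure(out, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  precision %.2f%%\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}
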