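#' Leave-one-out cross-validation of a ridge logistic panel
#'
#' For each sample, the model is refit on the remaining n - 1 samples
#' (imputation means recomputed inside each training fold, so no
#' information leaks from the held-out sample), a Youden threshold is chosen
#' on the training-fold canonical values, and the held-out sample's
#' canonical value is classified against that threshold. Sensitivity,
#' specificity, accuracy and AUC are computed from the n held-out
#' predictions only; `mae` is the mean absolute error of the held-out
#' probabilities against the 0/1 labels.
#'
#' @param x samples x features table.
#' @param y binary labels.
#' @param ridge ridge penalty, default 1e-8.
#' @param max_iter optimizer cap per fold (default 200 keeps large
#'   near-separable fits bounded; the flagged-result contract still holds).
#' @return object of class `cv_metrics` with `scheme = "loocv"`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc`, `mae`,
#'   `canonical_values` (held-out linear predictors), `probabilities`,
#'   `decisions`, `y`, `skipped_folds`.
#' @export
loocv <- function(x, y, ridge = 1e-8, max_iter = 200L) {
  vals <- as_values_matrix(x, "x")
  y01 <- as_binary01(y)
  n <- nrow(vals)
  if (n < 6L) stop("need at least 6 samples for LOOCV")
  if (min(table(y01)) < 3L) stop("need at least 3 samples per class")

  canon <- prob <- rep(NA_real_, n)
  decision <- rep(NA_integer_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y01[-i]
    if (length(unique(ytr)) < 2L) {
      skipped <- c(skipped, i)
      warning(sprintf("fold %d skipped: single-class training set", i))
      next
    }
    fit <- ridge_logistic(vals[-i, , drop = FALSE], ytr, ridge = ridge,
                          max_iter = max_iter)
    tr_canon <- predict(fit, vals[-i, , drop = FALSE], type = "link")
    thr <- youden_threshold(roc_curve(tr_canon, ytr))$threshold
    canon[i] <- predict(fit, vals[i, , drop = FALSE], type = "link")
    prob[i] <- stats::plogis(canon[i])
    decision[i] <- as.integer(canon[i] >= thr)
  }
  cv_metrics_from(canon, prob, decision, y01, scheme = "loocv",
                  skipped = skipped)
}

#' Stratified k-fold cross-validation of a ridge logistic panel
#'
#' As [loocv()], but over k stratified folds with seed-reproducible fold
#' assignment. When a class has fewer members than `k`, `k` is reduced to
#' that class size with a warning so that every fold holds out at least one
#' sample of each class.
#'
#' @inheritParams loocv
#' @param k number of folds, default 10.
#' @param seed integer seed for the fold assignment.
#' @return a `cv_metrics` object with `scheme = "kfold"`, plus `k`, `seed`
#'   and `folds`.
#' @export
kfold_cv <- function(x, y, k = 10L, seed, ridge = 1e-8, max_iter = 200L) {
  if (missing(seed)) stop("`seed` is required for reproducible folds")
  vals <- as_values_matrix(x, "x")
  y01 <- as_binary01(y)
  n <- nrow(vals)
  if (k > n) stop("k cannot exceed the sample count")
  min_class <- min(table(y01))
  if (min_class < k) {
    warning(sprintf("class smaller than k; reducing folds to %d", min_class))
    k <- min_class
  }

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  fold <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }

  canon <- prob <- rep(NA_real_, n)
  decision <- rep(NA_integer_, n)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(y01[train])) < 2L) {
      skipped <- c(skipped, f)
      warning(sprintf("fold %d skipped: single-class training set", f))
      next
    }
    fit <- ridge_logistic(vals[train, , drop = FALSE], y01[train],
                          ridge = ridge, max_iter = max_iter)
    tr_canon <- predict(fit, vals[train, , drop = FALSE], type = "link")
    thr <- youden_threshold(roc_curve(tr_canon, y01[train]))$threshold
    canon[test] <- predict(fit, vals[test, , drop = FALSE], type = "link")
    prob[test] <- stats::plogis(canon[test])
    decision[test] <- as.integer(canon[test] >= thr)
  }
  out <- cv_metrics_from(canon, prob, decision, y01, scheme = "kfold",
                         skipped = skipped)
  out$k <- k; out$seed <- seed; out$folds <- fold
  out
}

cv_metrics_from <- function(canon, prob, decision, y01, scheme, skipped) {
  ok <- !is.na(decision)
  sens <- mean(decision[ok & y01 == 1L] == 1L)
  spec <- mean(decision[ok & y01 == 0L] == 0L)
  acc <- mean(decision[ok] == y01[ok])
  auc <- if (length(unique(y01[ok])) == 2L)
    roc_curve(canon[ok], y01[ok])$auc else NA_real_
  structure(list(scheme = scheme,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 auc = auc,
                 mae = mean(abs(prob[ok] - y01[ok])),
                 canonical_values = canon,
                 probabilities = prob,
                 decisions = decision,
                 y = y01,
                 skipped_folds = skipped), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("%s cross-validation (held-out predictions only)\n",
              if (x$scheme == "loocv") "leave-one-out"
              else sprintf("%d-fold stratified", x$k)))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  AUC %.3f  MAE %.3f\n", x$auc, x$mae))
  invisible(x)
}

#' Cross-validated AIC of a candidate panel
#'
#' Complexity-penalized score used to rank candidate panels:
#' `AIC = n * ln(MAE) + 2 * (m + 1)`, where MAE is the mean absolute error
#' of held-out probabilities from 10-fold cross-validation, m the number of
#' compounds in the panel (+1 for the intercept). Lower is better. A zero
#' MAE yields `-Inf` with attribute `degenerate = TRUE`.
#'
#' @param cv a `cv_metrics` object (or a number, taken as the MAE).
#' @param m_features number of compounds in the panel.
#' @param n number of samples the MAE was estimated on.
#' @return the AIC value.
#' @examples
#' aic_model(0.25, m_features = 4, n = 40)   # 40*log(0.25) + 10
#' @export
aic_model <- function(cv, m_features, n) {
  mae <- if (inherits(cv, "cv_metrics")) cv$mae else cv
  if (!is.finite(mae) || mae < 0) stop("invalid MAE")
  if (mae == 0)
    return(structure(-Inf, degenerate = TRUE))
  n * log(mae) + 2 * (m_features + 1)
}
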