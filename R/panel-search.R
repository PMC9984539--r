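#' Correlation-based feature selection (CFS)
#'
#' Greedy forward search over features maximizing the CFS merit
#' `k * rbar_cf / sqrt(k + k (k - 1) * rbar_ff)`, where `rbar_cf` is the
#' mean absolute Pearson correlation between the k selected features and the
#' class, and `rbar_ff` the mean absolute pairwise correlation among them.
#' The search stops as soon as no addition improves the merit, so redundant
#' copies of an informative feature do not enter.
#'
#' @param x samples x features table (complete or mean-imputable).
#' @param y binary labels.
#' @return character vector of selected feature ids, with the final merit as
#'   attribute `merit`.
#' @export
cfs_select <- function(x, y) {
  vals <- as_values_matrix(x, "x")
  if (ncol(vals) < 2L) stop("need at least 2 candidate features")
  y01 <- as_binary01(y)
  if (anyNA(vals))
    for (j in which(colSums(is.na(vals)) > 0L))
      vals[is.na(vals[, j]), j] <- mean(vals[, j], na.rm = TRUE)

  sdv <- apply(vals, 2L, stats::sd)
  usable <- sdv > 0
  r_cf <- rep(0, ncol(vals))
  r_cf[usable] <- abs(suppressWarnings(stats::cor(vals[, usable, drop = FALSE],
                                                  y01)))
  r_ff <- matrix(0, ncol(vals), ncol(vals))
  r_ff[usable, usable] <- abs(suppressWarnings(
    stats::cor(vals[, usable, drop = FALSE])))
  r_ff[!is.finite(r_ff)] <- 0
  r_cf[!is.finite(r_cf)] <- 0

  merit <- function(sel) {
    k <- length(sel)
    rcf <- mean(r_cf[sel])
    rff <- if (k > 1L) mean(r_ff[sel, sel][upper.tri(diag(k))]) else 0
    k * rcf / sqrt(k + k * (k - 1) * rff)
  }

  selected <- which.max(r_cf)
  best <- merit(selected)
  remaining <- setdiff(seq_len(ncol(vals)), selected)
  repeat {
    if (!length(remaining)) break
    cand_merit <- vapply(remaining, function(j) merit(c(selected, j)),
                         numeric(1))
    j_best <- which.max(cand_merit)
    if (cand_merit[j_best] <= best + 1e-12) break
    best <- cand_merit[j_best]
    selected <- c(selected, remaining[j_best])
    remaining <- remaining[-j_best]
  }
  structure(colnames(vals)[selected], merit = best)
}

#' Search candidate biomarker panels
#'
#' Enumerates candidate feature subsets (exhaustively up to `max_m`
#' features, or a CFS-seeded greedy path when the exhaustive lattice is too
#' large or `strategy = "greedy"`), evaluates each by leave-one-out
#' cross-validation (primary, Youden-ranked) and/or stratified 10-fold
#' cross-validation (parallel, AIC-ranked), and returns both winners with
#' the full search log.
#'
#' Youden ties are broken toward fewer features, then higher sensitivity,
#' reflecting the preference for a small panel with high sensitivity.
#'
#' @param x samples x features table restricted to the candidate pool.
#' @param y binary labels.
#' @param max_m largest subset size for the exhaustive search, default 4.
#' @param strategy `"exhaustive"` (default, up to `max_m`) or `"greedy"`.
#' @param schemes which evaluations to run: subset of
#'   `c("loocv", "kfold")`; AIC requires `"kfold"`, Youden ranking uses
#'   LOOCV when available, else the k-fold metrics.
#' @param k,seed fold count and seed for the k-fold arm.
#' @param ridge ridge penalty passed to [ridge_logistic()].
#' @return object of class `search_result`: `log` (one row per candidate:
#'   features, m, and the requested metrics), `best_by_youden`,
#'   `best_by_aic` (rows of `log`), `strategy`.
#' @export
search_panels <- function(x, y, max_m = 4L,
                          strategy = c("exhaustive", "greedy"),
                          schemes = c("loocv", "kfold"),
                          k = 10L, seed = 1L, ridge = 1e-8) {
  strategy <- match.arg(strategy)
  schemes <- match.arg(schemes, several.ok = TRUE)
  vals <- as_values_matrix(x, "x")
  if (ncol(vals) == 0L) stop("empty candidate pool")
  feats <- colnames(vals)
  y01 <- as_binary01(y)
  n <- nrow(vals)

  subsets <- list()
  if (strategy == "exhaustive") {
    for (m in seq_len(min(max_m, length(feats))))
      subsets <- c(subsets,
                   utils::combn(feats, m, simplify = FALSE))
  } else {
    path <- cfs_select(vals, y01)
    subsets <- lapply(seq_along(path), function(i) path[seq_len(i)])
    # also score each single feature so the log is informative
    subsets <- unique(c(lapply(feats, identity), subsets))
  }

  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sel <- subsets[[i]]
    xs <- vals[, sel, drop = FALSE]
    row <- list(features = paste(sel, collapse = "+"), m = length(sel))
    if ("loocv" %in% schemes) {
      cv <- loocv(xs, y01, ridge = ridge)
      row$loocv_sensitivity <- cv$sensitivity
      row$loocv_specificity <- cv$specificity
      row$loocv_accuracy <- cv$accuracy
      row$loocv_auc <- cv$auc
      row$youden_J <- cv$sensitivity + cv$specificity - 1
    }
    if ("kfold" %in% schemes) {
      cvk <- kfold_cv(xs, y01, k = k, seed = seed, ridge = ridge)
      row$kfold_sensitivity <- cvk$sensitivity
      row$kfold_specificity <- cvk$specificity
      row$kfold_mae <- cvk$mae
      row$aic <- as.numeric(aic_model(cvk, length(sel), n))
      if (!("loocv" %in% schemes))
        row$youden_J <- cvk$sensitivity + cvk$specificity - 1
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, rows)

  sens_col <- if ("loocv" %in% schemes) "loocv_sensitivity"
              else "kfold_sensitivity"
  ord_y <- order(-log$youden_J, log$m, -log[[sens_col]])
  best_by_youden <- log[ord_y[1L], , drop = FALSE]
  best_by_aic <- if ("kfold" %in% schemes)
    log[order(log$aic, log$m)[1L], , drop = FALSE] else NULL

  structure(list(log = log,
                 best_by_youden = best_by_youden,
                 best_by_aic = best_by_aic,
                 strategy = strategy,
                 schemes = schemes),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("panel search (%s): %d candidate subsets\n",
              x$strategy, nrow(x$log)))
  cat("best by Youden J:\n"); print(x$best_by_youden, row.names = FALSE)
  if (!is.null(x$best_by_aic)) {
    cat("best by AIC:\n"); print(x$best_by_aic, row.names = FALSE)
  }
  invisible(x)
}
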