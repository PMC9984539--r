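#' Partial least squares discriminant analysis (PLS-DA)
#'
#' Fits a PLS1 model of a binary class indicator on a feature table by the
#' NIPALS algorithm. Features are centered and autoscaled to unit (n-1)
#' variance internally; the class is coded case = 1 / control = 0 and
#' centered. The per-feature regression coefficients of the class on the
#' autoscaled features are the quantities whose significance is assessed by
#' [plsda_permutation()].
#'
#' With `n_components` equal to the feature count (full rank), the
#' coefficients coincide with ordinary least squares on the autoscaled data.
#'
#' @param x samples x features table (matrix or [feature_table()]).
#' @param y binary labels: logical, 0/1 numeric, or 2-level factor (second
#'   level = case).
#' @param n_components number of latent components
#'   (<= min(n_samples - 1, n_features)); default 2.
#' @return object of class `plsda` with elements `coefficients` (per-feature,
#'   autoscaled-x scale), `x_weights`, `x_loadings`, `y_loadings`, `scores`,
#'   `centers`, `scales`, `y_mean`, `fitted`, `n_components`.
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- rep(c(0, 1), each = 10)
#' x[, 1] <- x[, 1] + y          # informative feature
#' fit <- plsda(x, y)
#' coef(fit)
#' @export
plsda <- function(x, y, n_components = 2L) {
  vals <- as_values_matrix(x, "x")
  y01 <- as_binary01(y)
  n <- nrow(vals); p <- ncol(vals)
  if (length(y01) != n) stop("length of `y` must match rows of `x`")
  if (length(unique(y01)) < 2L) stop("`y` has a single class")
  if (min(table(y01)) < 2L) stop("need at least 2 samples per class")
  if (anyNA(vals)) stop("PLS-DA requires a complete matrix; impute first")
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(n_samples - 1, n_features)")

  sc <- autoscale(vals)
  ym <- mean(y01)
  core <- plsda_core(sc$x, y01 - ym, n_components)

  B <- core$coefficients
  names(B) <- colnames(vals)
  fitted <- drop(sc$x %*% B) + ym

  structure(list(coefficients = B,
                 x_weights = core$W, x_loadings = core$P,
                 y_loadings = core$Cl, scores = core$Tt,
                 centers = sc$centers, scales = sc$scales,
                 y_mean = ym, fitted = fitted,
                 n_components = core$a_used,
                 feature_ids = colnames(vals)),
            class = "plsda")
}

# NIPALS PLS1 on a pre-scaled X and centered y
plsda_core <- function(Xs, yc, n_components) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Cl <- numeric(n_components)
  Tt <- matrix(0, n, n_components)
  Xd <- Xs; yd <- yc
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)            # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break             # y fully explained; stop early
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(Xd, t_) / tt
    c_ <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - c_ * t_
    W[, a] <- w; P[, a] <- p_; Cl[a] <- c_; Tt[, a] <- t_
    a_used <- a
  }
  if (a_used == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Cl <- Cl[seq_len(a_used)]
  Tt <- Tt[, seq_len(a_used), drop = FALSE]
  # regression coefficients on the scaled X: B = W (P'W)^-1 c
  list(coefficients = drop(W %*% solve(crossprod(P, W), Cl)),
       W = W, P = P, Cl = Cl, Tt = Tt, a_used = a_used)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA fit: %d features, %d component(s)\n",
              length(x$coefficients), x$n_components))
  top <- order(abs(x$coefficients), decreasing = TRUE)
  k <- min(5L, length(top))
  cat("largest |coefficients| (autoscaled X):\n")
  print(round(x$coefficients[top[seq_len(k)]], 4))
  invisible(x)
}

#' @export
coef.plsda <- function(object, scale = c("autoscaled", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "autoscaled") object$coefficients
  else object$coefficients / object$scales
}

#' @export
predict.plsda <- function(object, newdata, ...) {
  vals <- as_values_matrix(newdata, "newdata")
  vals <- vals[, object$feature_ids, drop = FALSE]
  Xs <- sweep(sweep(vals, 2L, object$centers), 2L, object$scales, `/`)
  drop(Xs %*% object$coefficients) + object$y_mean
}

#' Permutation significance of PLS-DA coefficients
#'
#' Refits the PLS-DA model under `B` random permutations of the class labels
#' and computes, for each feature, the two-sided permutation p-value of its
#' coefficient with the add-one estimator:
#' `p_j = (1 + #\{b : |coef_j(b)| >= |coef_j|\}) / (B + 1)`.
#' Label permutation is the exchangeability-valid null here; all features
#' share the same permutations (one refit per permutation).
#'
#' @inheritParams plsda
#' @param B number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return list with `p` (named per-feature p-values in `[1/(B+1), 1]`),
#'   `coefficients` (observed), `B`, `seed`.
#' @export
plsda_permutation <- function(x, y, n_components = 2L, B = 999L, seed) {
  if (B < 100L) stop("B must be at least 100 for stable permutation p-values")
  if (missing(seed)) stop("`seed` is required for reproducibility")
  vals <- as_values_matrix(x, "x")
  fit <- plsda(vals, y, n_components)
  obs <- fit$coefficients
  y01 <- as_binary01(y)
  Xs <- sweep(sweep(vals, 2L, fit$centers), 2L, fit$scales, `/`)

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  exceed <- integer(length(obs))
  athr <- abs(obs)
  for (b in seq_len(B)) {
    yp <- sample(y01)
    cb <- plsda_core(Xs, yp - mean(yp), n_components)$coefficients
    exceed <- exceed + (abs(cb) >= athr)
  }
  p <- (1 + exceed) / (B + 1)
  names(p) <- names(obs)
  list(p = p, coefficients = obs, B = B, seed = seed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate q-values,
#' `q_(i) = min_{j >= i} min(1, m p_(j) / j)`, used pipeline-wide for the
#' "p < 0.05, FDR corrected" selections.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differential features
#'
#' Combines PLS-DA coefficients, permutation p-values and BH q-values into a
#' differential table, applying the selection rule q < alpha together with a
#' discard list (unannotated peaks, drug-related compounds).
#'
#' @param coefficients named per-feature PLS-DA coefficients.
#' @param p named permutation p-values (same features).
#' @param alpha FDR level in (0, 1), default 0.05.
#' @param exclusion_list feature ids to discard regardless of significance.
#' @return data.frame `(feature_id, coefficient, p_perm, q_bh, direction,
#'   selected, excluded)` with `direction` read from the coefficient sign
#'   (case coded 1).
#' @export
select_features <- function(coefficients, p, alpha = 0.05,
                            exclusion_list = character(0)) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  stopifnot(length(coefficients) == length(p))
  q <- bh_fdr(p)
  excluded <- names(coefficients) %in% exclusion_list
  data.frame(feature_id = names(coefficients),
             coefficient = unname(coefficients),
             p_perm = unname(p),
             q_bh = unname(q),
             direction = ifelse(coefficients >= 0, "up_in_case",
                                "down_in_case"),
             selected = q < alpha & !excluded,
             excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Per-feature z-score matrix for heatmaps
#'
#' Standardizes each feature to mean 0 and (n-1) SD 1 across all samples in
#' the comparison and returns the features x samples matrix used for
#' heatmap display. Constant features become all-zero rows with a warning.
#'
#' @param x samples x features table.
#' @return features x samples numeric matrix of z-scores.
#' @export
zscore_matrix <- function(x) {
  vals <- as_values_matrix(x, "x")
  if (nrow(vals) < 2L) stop("need at least 2 samples")
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sdv) | sdv == 0
  if (any(zero)) {
    warning(sprintf("%d zero-SD feature(s) set to all-zero z-scores",
                    sum(zero)))
    sdv[zero] <- 1
  }
  z <- sweep(sweep(vals, 2L, mu), 2L, sdv, `/`)
  z[, zero] <- 0
  t(z)
}

#' One-call differential analysis of a feature table
#'
#' Convenience wrapper running [plsda()], [plsda_permutation()] and
#' [select_features()] on a labelled cohort table.
#'
#' @param table samples x features table (complete cases required;
#'   ratio-normalize and impute upstream).
#' @param metadata data.frame with `sample_id` and the label column.
#' @param label name of a binary label column in `metadata` (`"group"` with
#'   values case/control, or a 0/1 or logical column).
#' @param n_components,B,alpha,seed,exclusion_list passed through.
#' @return the [select_features()] data.frame.
#' @export
differential_analysis <- function(table, metadata, label = "group",
                                  n_components = 2L, B = 999L,
                                  alpha = 0.05, seed,
                                  exclusion_list = character(0)) {
  vals <- as_values_matrix(table, "table")
  lab <- metadata[[label]][match(rownames(vals), metadata$sample_id)]
  y <- as_binary01(lab)
  perm <- plsda_permutation(vals, y, n_components = n_components,
                            B = B, seed = seed)
  select_features(perm$coefficients, perm$p, alpha = alpha,
                  exclusion_list = exclusion_list)
}

# coerce labels to 0/1 with 1 = case
as_binary01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    lv <- sort(unique(y))
    if (identical(lv, c("case", "control")) ||
        identical(lv, c("control", "case")))
      return(as.integer(y == "case"))
    if (length(lv) > 2L) stop("`y` must be binary")
    return(as.integer(y == lv[length(lv)]))
  }
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1))) stop("numeric `y` must be coded 0/1")
  as.integer(y)
}

# center + unit-variance autoscaling with a guard for constant features
autoscale <- function(vals) {
  centers <- colMeans(vals)
  scales <- apply(vals, 2L, stats::sd)
  const <- !is.finite(scales) | scales < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant feature(s) scaled by guard epsilon",
                    sum(const)))
    scales[const] <- 1e-12
  }
  list(x = sweep(sweep(vals, 2L, centers), 2L, scales, `/`),
       centers = centers, scales = scales)
}
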