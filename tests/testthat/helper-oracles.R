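# Independent brute-force oracles used to check the package's
# implementations. These deliberately avoid the code paths they verify.

# Benjamini-Hochberg step-up by the definition:
# q_(i) = min_{j >= i} min(1, m p_(j) / j)
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[ord[j]] / j), numeric(1))
    q_sorted[i] <- min(vals)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# AUC by exhaustive concordant-pair counting with ties counted 1/2
auc_bruteforce <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Youden J by exhaustive scan over all candidate cutpoints (midpoints of
# consecutive unique scores plus outside sentinels), rule score >= thr
youden_bruteforce <- function(scores, y) {
  u <- sort(unique(scores))
  cand <- c(min(u) - 1, (u[-1] + u[-length(u)]) / 2, u, max(u) + 1)
  best <- -Inf
  best_sens <- -Inf
  for (thr in cand) {
    sens <- mean(scores[y == 1] >= thr)
    spec <- mean(scores[y == 0] < thr)
    J <- sens + spec - 1
    if (J > best + 1e-12 ||
        (abs(J - best) <= 1e-12 && sens > best_sens)) {
      best <- J
      best_sens <- sens
    }
  }
  list(J = best, sensitivity = best_sens)
}

# Penalized ridge-logistic loss minimized by iterative grid refinement.
# Parameters: intercept + one coefficient per column of x.
grid_ridge_oracle <- function(x, y, ridge = 1e-8, lo = -10, hi = 10,
                              n_grid = 13L, n_zoom = 14L) {
  X1 <- cbind(1, x)
  d <- ncol(X1)
  loss <- function(B) {
    # B: d x K matrix of candidate parameter vectors
    eta <- X1 %*% B
    # stable log(1 + e^eta)
    lp <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    colSums(lp - y * eta) + ridge * colSums(B[-1, , drop = FALSE]^2)
  }
  center <- rep(0, d)
  width <- rep(hi - lo, d)
  for (z in seq_len(n_zoom)) {
    axes <- lapply(seq_len(d), function(j)
      seq(center[j] - width[j] / 2, center[j] + width[j] / 2,
          length.out = n_grid))
    grid <- as.matrix(expand.grid(axes))
    vals <- loss(t(grid))
    center <- grid[which.min(vals), ]
    width <- width * 2.5 / (n_grid - 1)   # keep the next window overlapping
  }
  center
}

# total matched distance of the optimal one-to-one assignment by
# enumerating all control permutations (classes of size <= 6)
optimal_match_bruteforce <- function(case_scores, control_scores) {
  k <- min(length(case_scores), length(control_scores))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (p in perms(seq_along(control_scores))) {
    d <- sum(abs(case_scores[seq_len(k)] - control_scores[p[seq_len(k)]]))
    if (d < best) best <- d
  }
  best
}

# exhaustive permutation p-value for Pearson's r (two-sided), n <= 7
perm_pvalue_cor <- function(x, y) {
  r_obs <- abs(cor(x, y))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rs <- vapply(perms(seq_along(y)), function(p) abs(cor(x, y[p])), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# upper hypergeometric tail P(X >= k) by direct summation of
# choose(K, i) choose(N - K, n - i) / choose(N, n)
hyper_tail_bruteforce <- function(k, K, N, n) {
  imax <- min(K, n)
  if (k > imax) return(0)
  s <- 0
  for (i in k:imax)
    s <- s + exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  s
}

# strip feature_table attributes down to a plain named matrix
as_matrix_plain <- function(x) {
  out <- unclass(x)
  attr(out, "layer") <- NULL
  attr(out, "units") <- NULL
  out
}

# small labelled data set with planted group separation on the first
# `n_inf` features (standardized shift d on the log scale)
make_panel_data <- function(n_per_group = 20L, n_feat = 6L, n_inf = 2L,
                            d = 2, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  y <- rep(c(0L, 1L), each = n_per_group)
  x <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(n_feat))))
  for (j in seq_len(n_inf)) x[, j] <- x[, j] + d * y
  list(x = x, y = y)
}
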