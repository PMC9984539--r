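#' ROC curve and AUC by Mann-Whitney concordance
#'
#' Builds the receiver operating characteristic curve of a score against a
#' binary outcome using every unique score as a threshold (rule: score >=
#' threshold predicts case), and computes the AUC as the Mann-Whitney
#' concordance probability with ties counted 1/2.
#'
#' @param scores numeric scores (canonical values, probabilities, ...).
#' @param y binary labels aligned with `scores`.
#' @return object of class `roc_curve` with `thresholds`, `sensitivity`,
#'   `specificity` (parallel vectors, including the all-case and no-case
#'   endpoints) and `auc`.
#' @examples
#' roc <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' roc$auc   # 0.75
#' @export
roc_curve <- function(scores, y) {
  y01 <- as_binary01(y)
  if (length(y01) != length(scores)) stop("`y` must align with `scores`")
  if (length(unique(y01)) < 2L) stop("both classes must be present")
  if (anyNA(scores)) stop("scores must be complete")
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)

  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # cumulative counts below each unique threshold (rule: score >= thr)
  ord <- order(scores)
  case_sorted <- y01[ord] == 1L
  u <- sort(unique(scores))
  n_le <- findInterval(u, scores[ord])        # elements <= u[k]
  cases_le <- cumsum(case_sorted)[n_le]
  k <- length(u)
  cases_lt <- c(0, cases_le[-k])
  controls_lt <- c(0, (n_le - cases_le)[-k])
  thr <- c(u, Inf)
  sens <- c((n1 - cases_lt) / n1, 0)
  spec <- c(controls_lt / n0, 1)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_case = n1, n_control = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d case / %d control, AUC = %.4f\n",
              x$n_case, x$n_control, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  ord <- order(1 - x$specificity, x$sensitivity)
  graphics::plot(c(1, (1 - x$specificity)[ord], 0),
                 c(1, x$sensitivity[ord], 0), type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-index threshold selection
#'
#' Scans the ROC thresholds for the maximum of `J = sensitivity +
#' specificity - 1`. Ties are broken in favour of the threshold with the
#' higher sensitivity (the study preferred sensitive models).
#'
#' @param roc a [roc_curve()] (or a list with `thresholds`, `sensitivity`,
#'   `specificity`).
#' @return list `(threshold, J, sensitivity, specificity)`.
#' @export
youden_threshold <- function(roc) {
  J <- roc$sensitivity + roc$specificity - 1
  best <- which(J >= max(J) - 1e-12)
  if (length(best) > 1L)
    best <- best[which.max(roc$sensitivity[best])]
  list(threshold = roc$thresholds[best],
       J = J[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best])
}

#' Unpaired two-sided t test on canonical values
#'
#' Pooled-variance Student's t comparison of a model's canonical values
#' between the two outcome groups.
#'
#' @param values numeric canonical values.
#' @param y binary labels.
#' @return list `(t, df, p, degenerate)`; `degenerate` is `TRUE` when the
#'   pooled variance is zero (then `t` is 0 with p = 1 for identical group
#'   means, +/-Inf with p = 0 otherwise).
#' @examples
#' compare_groups_t(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1))
#' @export
compare_groups_t <- function(values, y) {
  y01 <- as_binary01(y)
  a <- values[y01 == 1L]; b <- values[y01 == 0L]
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 per group")
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    dm <- mean(a) - mean(b)
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf,
                df = df, p = if (dm == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
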