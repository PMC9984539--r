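#' Propensity scores from clinical covariates
#'
#' Fits a logistic regression of case status on the four matching
#' covariates — age at enrollment, sex, phenotype (sporadic/familial) and
#' brainstem lesion — and returns the fitted case probabilities. Under
#' complete separation the fit falls back to the package's ridge-stabilized
#' logistic with a warning.
#'
#' @param metadata data.frame with `sample_id`, the label column, and the
#'   covariate columns.
#' @param target_label name of the binary label column (default `"group"`,
#'   case/control).
#' @param covariates covariate column names; default the four clinical ones.
#' @return named numeric vector of propensity scores in (0, 1), one per
#'   sample, in `metadata` order.
#' @export
fit_propensity <- function(metadata, target_label = "group",
                           covariates = c("age", "sex", "phenotype",
                                          "brainstem_lesion")) {
  missing_cov <- setdiff(covariates, names(metadata))
  if (length(missing_cov))
    stop("covariate(s) not in metadata: ", paste(missing_cov, collapse = ", "))
  y <- as_binary01(metadata[[target_label]])
  if (length(unique(y)) < 2L) stop("need both classes to fit a propensity model")
  X <- as.matrix(metadata[, covariates, drop = FALSE])
  if (anyNA(X)) stop("covariates must be complete for matching")

  df <- data.frame(y = y, X)
  fml <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      # both glm separation symptoms: saturated probabilities, no convergence
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  mu <- stats::fitted(fit)
  separated <- separated || any(mu < 1e-8 | mu > 1 - 1e-8)
  if (separated || !fit$converged) {
    warning("separation in the propensity model; using ridge-stabilized fit")
    rfit <- ridge_logistic(X, y, ridge = 1e-4)
    scores <- predict(rfit, X, type = "response")
  } else {
    scores <- stats::fitted(fit)
  }
  names(scores) <- metadata$sample_id
  scores
}

#' Greedy one-to-one nearest-neighbor matching
#'
#' Pairs each case with the single nearest unused control by absolute
#' propensity-score difference: cases are processed in descending score
#' order, without replacement and without a caliper; score ties among
#' controls are broken by the smallest control id. Deterministic.
#'
#' @param scores named propensity scores for all samples.
#' @param labels binary labels aligned with `scores` (case/control, 0/1 or
#'   logical).
#' @return object of class `match_result`: `pairs` data.frame
#'   `(case_id, control_id, distance)` and `unmatched` ids. The pair count
#'   is `min(n_case, n_control)`.
#' @export
match_pairs <- function(scores, labels) {
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  y <- as_binary01(labels)
  if (length(y) != length(scores)) stop("`labels` must align with `scores`")
  cases <- names(scores)[y == 1L]
  controls <- names(scores)[y == 0L]
  if (!length(cases) || !length(controls))
    stop("both classes must be non-empty")

  cases <- cases[order(scores[cases], decreasing = TRUE)]
  available <- controls[order(controls)]    # id order fixes ties
  pairs <- vector("list", min(length(cases), length(controls)))
  k <- 0L
  for (cs in cases) {
    if (!length(available)) break
    d <- abs(scores[available] - scores[cs])
    pick <- available[which.min(d)]         # first minimum = smallest id
    k <- k + 1L
    pairs[[k]] <- data.frame(case_id = cs, control_id = pick,
                             distance = unname(d[pick]),
                             stringsAsFactors = FALSE)
    available <- setdiff(available, pick)
  }
  pairs <- do.call(rbind, pairs[seq_len(k)])
  matched <- c(pairs$case_id, pairs$control_id)
  structure(list(pairs = pairs,
                 unmatched = setdiff(names(scores), matched),
                 settings = list(replacement = FALSE, caliper = NULL,
                                 order = "descending case score",
                                 ties = "smallest control id")),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d pairs, %d unmatched\n",
              nrow(x$pairs), length(x$unmatched)))
  cat(sprintf("  mean |score difference|: %.4g\n", mean(x$pairs$distance)))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Absolute standardized mean differences (SMD) of the matching covariates,
#' `|mean_case - mean_control| / sqrt((var_case + var_control)/2)`, on the
#' full cohort and on the matched subset.
#'
#' @param metadata cohort metadata.
#' @param match a [match_pairs()] result.
#' @param target_label,covariates as in [fit_propensity()].
#' @return data.frame `(covariate, smd_pre, smd_post)`.
#' @export
covariate_balance <- function(metadata, match, target_label = "group",
                              covariates = c("age", "sex", "phenotype",
                                             "brainstem_lesion")) {
  y <- as_binary01(metadata[[target_label]])
  smd <- function(ids) {
    keep <- metadata$sample_id %in% ids
    vapply(covariates, function(cv) {
      v <- metadata[[cv]][keep]; g <- y[keep]
      s <- sqrt((stats::var(v[g == 1L]) + stats::var(v[g == 0L])) / 2)
      if (!is.finite(s) || s == 0) return(0)
      abs(mean(v[g == 1L]) - mean(v[g == 0L])) / s
    }, numeric(1))
  }
  data.frame(covariate = covariates,
             smd_pre = unname(smd(metadata$sample_id)),
             smd_post = unname(smd(c(match$pairs$case_id,
                                     match$pairs$control_id))),
             stringsAsFactors = FALSE)
}
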