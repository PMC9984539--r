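#' Metabolite-protein Pearson correlation screen
#'
#' Correlates every metabolite with every protein across the samples shared
#' by the two tables. For each pair, Pearson's r is computed on
#' pairwise-complete observations; the two-sided p-value comes from the t
#' reference `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom, and q-values come from one Benjamini-Hochberg pass over the full
#' metabolite x protein grid. Pairs with fewer than 4 complete observations
#' are skipped; pairs with |r| numerically 1 are flagged `degenerate` and
#' reported with the smallest representable p rather than 0.
#'
#' @param metab samples x metabolites table (normalized ratio levels).
#' @param prot samples x proteins table.
#' @return data.frame of class `correlation_table`:
#'   `(metabolite_id, protein_id, n, r, t_stat, p, q_bh, degenerate,
#'   skipped, skip_reason)`; `q_bh` is `NA` for skipped pairs.
#' @export
correlate_features <- function(metab, prot) {
  mv <- as_values_matrix(metab, "metab")
  pv <- as_values_matrix(prot, "prot")
  shared <- intersect(rownames(mv), rownames(pv))
  if (length(shared) < 4L)
    stop("fewer than 4 shared samples between the tables")
  mv <- mv[shared, , drop = FALSE]
  pv <- pv[shared, , drop = FALSE]

  grid <- expand.grid(metabolite_id = colnames(mv),
                      protein_id = colnames(pv),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_pair <- integer(nrow(grid))
  r <- t_stat <- p <- rep(NA_real_, nrow(grid))
  degenerate <- logical(nrow(grid))
  skip_reason <- rep(NA_character_, nrow(grid))

  for (k in seq_len(nrow(grid))) {
    x <- mv[, grid$metabolite_id[k]]
    y <- pv[, grid$protein_id[k]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    n_pair[k] <- n
    if (n < 4L) {
      skip_reason[k] <- "fewer than 4 complete pairs"
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      skip_reason[k] <- "constant variable"
      next
    }
    rk <- stats::cor(x[ok], y[ok])
    r[k] <- rk
    if (1 - rk^2 < 1e-14) {
      degenerate[k] <- TRUE
      t_stat[k] <- sign(rk) * Inf
      p[k] <- .Machine$double.xmin
    } else {
      tk <- rk * sqrt((n - 2) / (1 - rk^2))
      t_stat[k] <- tk
      p[k] <- 2 * stats::pt(abs(tk), df = n - 2, lower.tail = FALSE)
    }
  }

  skipped <- !is.na(skip_reason)
  q <- rep(NA_real_, nrow(grid))
  if (any(!skipped)) q[!skipped] <- bh_fdr(p[!skipped])
  out <- data.frame(grid, n = n_pair, r = r, t_stat = t_stat, p = p,
                    q_bh = q, degenerate = degenerate, skipped = skipped,
                    skip_reason = skip_reason, stringsAsFactors = FALSE)
  class(out) <- c("correlation_table", class(out))
  out
}

#' Screen correlated metabolite-protein pairs
#'
#' Marks the pairs passing the study's screen: `|r| > r_min` and
#' `q_bh < alpha`, both strict (a pair with r exactly 0.5 fails).
#'
#' @param table a [correlate_features()] result.
#' @param r_min minimum |Pearson r|, default 0.5.
#' @param alpha FDR level, default 0.05.
#' @return the table with a logical `passes` column.
#' @export
filter_correlations <- function(table, r_min = 0.5, alpha = 0.05) {
  if (!(r_min >= 0 && r_min <= 1)) stop("r_min must be in [0, 1]")
  table$passes <- !table$skipped & !is.na(table$q_bh) &
    abs(table$r) > r_min & table$q_bh < alpha
  table
}
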