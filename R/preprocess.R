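#' Normalize a metabolite table to per-sample ratio levels
#'
#' Converts raw peak intensities to "plasma ratio levels": each sample's
#' features are divided by that sample's total observed signal, so observed
#' cells in a row sum to 1. Missing cells stay missing and are excluded from
#' the total. Idempotent.
#'
#' @param table a [feature_table()] (or numeric matrix), non-negative values.
#' @return a feature table of ratio levels (layer `"ratio"`).
#' @examples
#' m <- matrix(c(2, 3, 5), 1, dimnames = list("S1", c("a", "b", "c")))
#' normalize_to_ratio(m)   # 0.2 0.3 0.5
#' @export
normalize_to_ratio <- function(table) {
  vals <- as_values_matrix(table, "table")
  if (any(vals < 0, na.rm = TRUE))
    stop("negative values cannot be ratio-normalized")
  tot <- rowSums(vals, na.rm = TRUE)
  bad <- tot <= 0
  if (any(bad))
    stop("sample(s) with no positive signal: ",
         paste(rownames(vals)[bad], collapse = ", "))
  out <- vals / tot
  rewrap(out, table, layer = "ratio", units = "fraction of total signal")
}

#' Average technical duplicates
#'
#' Collapses duplicate wells to one row per biological sample by the
#' arithmetic mean. When one member of a pair is missing, the observed value
#' is kept; when both are missing the cell stays missing.
#'
#' @param table a feature table whose rows are replicate wells.
#' @param replicate_map data.frame with columns `replicate_id` (a row of
#'   `table`) and `sample_id` (the biological sample it belongs to).
#' @return feature table with one row per biological sample, in first-seen
#'   order of `sample_id`.
#' @export
average_duplicates <- function(table, replicate_map) {
  vals <- as_values_matrix(table, "table")
  if (!all(c("replicate_id", "sample_id") %in% names(replicate_map)))
    stop("`replicate_map` needs columns replicate_id and sample_id")
  unknown <- setdiff(replicate_map$replicate_id, rownames(vals))
  if (length(unknown))
    stop("unknown replicate id(s): ", paste(unknown, collapse = ", "))
  samples <- unique(replicate_map$sample_id)
  out <- matrix(NA_real_, length(samples), ncol(vals),
                dimnames = list(samples, colnames(vals)))
  for (s in samples) {
    reps <- replicate_map$replicate_id[replicate_map$sample_id == s]
    sub <- vals[reps, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_
    out[s, ] <- m
  }
  rewrap(out, table)
}

#' Exclude per-group statistical outliers
#'
#' For each feature and each group, values farther than `k_sd` group
#' standard deviations from the group mean are set to missing and logged.
#' The mean and SD are computed once on the original values (single pass, no
#' iterative re-exclusion) with the n-1 SD convention, and the comparison is
#' a strict inequality, so a value exactly at mean + k_sd * SD is retained.
#' This is the +/-2 SD rule used for plasma protein assays and the +/-3 SD
#' rule used for qPCR relative quantification.
#'
#' @param table a feature table.
#' @param metadata data.frame with `sample_id` and the grouping column.
#' @param group_label name of the grouping column in `metadata`.
#' @param k_sd positive multiplier (2 for proteins, 3 for miRNA qPCR).
#' @return list with `table` (cells masked) and `qc`, a `qc_report` holding
#'   `excluded_cells` (sample, feature, reason) and `skipped_features`
#'   (feature-group combinations with fewer than 3 observed values).
#' @examples
#' m <- matrix(c(1, 1, 1, 1, 10), 5, 1,
#'             dimnames = list(paste0("S", 1:5), "f"))
#' md <- data.frame(sample_id = paste0("S", 1:5), grp = "A")
#' # SD is inflated by the outlier itself: nothing excluded at k_sd = 2
#' exclude_outliers(m, md, "grp", k_sd = 2)$qc$excluded_cells
#' @export
exclude_outliers <- function(table, metadata, group_label, k_sd) {
  vals <- as_values_matrix(table, "table")
  if (!is.numeric(k_sd) || length(k_sd) != 1L || k_sd <= 0)
    stop("`k_sd` must be a positive scalar")
  if (!group_label %in% names(metadata))
    stop(sprintf("grouping column `%s` not in metadata", group_label))
  grp <- metadata[[group_label]][match(rownames(vals), metadata$sample_id)]
  if (anyNA(grp))
    stop("samples missing from metadata: ",
         paste(rownames(vals)[is.na(grp)], collapse = ", "))
  groups <- unique(grp)
  if (any(table(grp) < 3))
    stop("each group needs at least 3 members")

  excluded <- list()
  skipped <- list()
  for (g in groups) {
    rows <- which(grp == g)
    sub <- vals[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 2L, stats::sd, na.rm = TRUE)
    for (j in seq_len(ncol(sub))) {
      if (n_obs[j] < 3L) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(feature_id = colnames(vals)[j], group = as.character(g),
                     n_observed = n_obs[j], stringsAsFactors = FALSE)
        next
      }
      if (!is.finite(sdv[j]) || sdv[j] == 0) next
      far <- which(!is.na(sub[, j]) &
                     abs(sub[, j] - mu[j]) > k_sd * sdv[j])
      if (length(far)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          sample_id = rownames(vals)[rows[far]],
          feature_id = colnames(vals)[j],
          reason = sprintf("beyond %.3g SD of group %s mean", k_sd, g),
          stringsAsFactors = FALSE)
        vals[rows[far], j] <- NA_real_
      }
    }
  }
  skipped_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(feature_id = character(0), group = character(0),
               n_observed = integer(0), stringsAsFactors = FALSE)
  if (nrow(skipped_df))
    warning(sprintf("%d feature-group combination(s) skipped (<3 observed values)",
                    nrow(skipped_df)))
  qc <- structure(list(
    excluded_cells = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(sample_id = character(0), feature_id = character(0),
                 reason = character(0), stringsAsFactors = FALSE),
    skipped_features = skipped_df,
    k_sd = k_sd), class = "qc_report")
  list(table = rewrap(vals, table), qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  if (!is.null(x$k_sd)) cat(sprintf("  outlier rule: +/- %g SD, single pass, strict\n", x$k_sd))
  cat(sprintf("  excluded cells: %d\n", nrow(x$excluded_cells)))
  if (!is.null(x$skipped_features) && nrow(x$skipped_features))
    cat(sprintf("  skipped feature-groups: %d\n", nrow(x$skipped_features)))
  if (!is.null(x$dropped_samples) && length(x$dropped_samples))
    cat("  dropped samples:", paste(x$dropped_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Rank candidate endogenous controls by expression stability
#'
#' Scores each candidate control miRNA by a combined inter/intra-group
#' variability of its Cq values, `s = sqrt(Var(group means) + mean(within-
#' group variances))` (n-1 variance convention). Lower is more stable; the
#' first-ranked candidate is the control used for delta-Cq normalization.
#' This is a simplified NormFinder-style stability score.
#'
#' @param cq a Cq feature table (layer `"mirna_cq"` or plain matrix).
#' @param metadata data.frame with `sample_id` and the grouping column.
#' @param candidate_controls character vector of >= 2 candidate column ids.
#' @param group_label grouping column name (default `"group"`).
#' @return data.frame `(control_id, stability)` sorted ascending by
#'   stability; attribute `chosen` holds the winner.
#' @export
control_stability <- function(cq, metadata, candidate_controls,
                              group_label = "group") {
  vals <- as_values_matrix(cq, "cq")
  if (length(candidate_controls) < 2L)
    stop("need at least 2 candidate controls")
  absent <- setdiff(candidate_controls, colnames(vals))
  if (length(absent))
    stop("candidate control(s) absent from table: ",
         paste(absent, collapse = ", "))
  grp <- metadata[[group_label]][match(rownames(vals), metadata$sample_id)]
  if (length(unique(grp[!is.na(grp)])) < 2L)
    stop("need at least 2 groups")

  score <- vapply(candidate_controls, function(id) {
    x <- vals[, id]
    ok <- !is.na(x) & !is.na(grp)
    gm <- tapply(x[ok], grp[ok], mean)
    wv <- tapply(x[ok], grp[ok], function(v)
      if (length(v) > 1L) stats::var(v) else 0)
    between <- if (length(gm) > 1L) stats::var(as.numeric(gm)) else 0
    sqrt(between + mean(as.numeric(wv)))
  }, numeric(1))

  out <- data.frame(control_id = candidate_controls, stability = score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$stability, out$control_id), ]
  rownames(out) <- NULL
  attr(out, "chosen") <- out$control_id[1L]
  out
}

#' Delta-Cq relative expression
#'
#' Computes `delta Cq = Cq(miRNA) - Cq(endogenous control)` per sample and
#' miRNA. Lower delta Cq means more abundant. Samples whose control Cq is
#' missing are dropped and logged. The control column is removed from the
#' output. The output stays on the delta-Cq scale (not 2^-deltaCq); the sign
#' convention is recorded in the table's `units` tag.
#'
#' @param cq a Cq feature table.
#' @param control_id column id of the chosen endogenous control.
#' @return list with `table` (feature table, layer `"mirna_rel"`) and `qc`
#'   (a `qc_report` naming any dropped samples).
#' @export
delta_cq <- function(cq, control_id) {
  vals <- as_values_matrix(cq, "cq")
  if (!control_id %in% colnames(vals))
    stop(sprintf("control `%s` not in table", control_id))
  ctrl <- vals[, control_id]
  dropped <- rownames(vals)[is.na(ctrl)]
  keep <- !is.na(ctrl)
  out <- vals[keep, setdiff(colnames(vals), control_id), drop = FALSE] -
    ctrl[keep]
  qc <- structure(list(
    excluded_cells = data.frame(sample_id = character(0),
                                feature_id = character(0),
                                reason = character(0),
                                stringsAsFactors = FALSE),
    dropped_samples = dropped,
    control_id = control_id), class = "qc_report")
  list(table = feature_table(out, layer = "mirna_rel",
                             units = "delta Cq (lower = more abundant)"),
       qc = qc)
}
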