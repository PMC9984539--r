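#' Configuration for a synthetic multi-omic cohort
#'
#' Defines the statistical structure of a simulated case-control cohort with
#' three plasma layers: metabolite peak intensities (log-normal), protein
#' concentrations in ng/ml (log-normal, correlated with informative
#' metabolites), and miRNA qPCR Cq values with endogenous-control and
#' spike-in columns. Case status is assigned through a logistic model on
#' four clinical covariates (age, sex, phenotype, brainstem lesion) so that
#' the cohort carries genuine confounding for propensity matching to remove.
#'
#' The defaults emulate a small matched clinical cohort: 20 cases and 20
#' controls, 200 metabolite peaks of which 4 are informative, 4 assayed
#' proteins (2 informative), 8 target miRNAs (3 informative) plus two
#' endogenous-control candidates and one exogenous spike-in.
#'
#' @param n_case,n_control group sizes (> 0).
#' @param n_metabolites,n_proteins,n_mirnas features per layer (> 0).
#' @param n_informative_per_layer named or unnamed vector of informative
#'   feature counts; a single value is recycled to all three layers subject
#'   to the layer sizes.
#' @param effect_size standardized mean shift (Cohen's d, log scale for
#'   abundance layers, Cq scale for miRNAs) applied to informative features.
#' @param covariate_model named coefficients `(intercept, age, sex,
#'   phenotype, brainstem)` of the logistic case-assignment model; age enters
#'   centered at 45 years and scaled by 12.
#' @param noise_sd within-group SD on the log scale (and Cq scale).
#' @param missing_rate,outlier_rate cell-level rates in `[0, 1)` used by
#'   [inject_missingness_and_outliers()].
#' @param seed integer seed; the same config and seed give a bit-identical
#'   cohort.
#' @return a list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_case = 20L, n_control = 20L,
                          n_metabolites = 200L, n_proteins = 4L,
                          n_mirnas = 8L,
                          n_informative_per_layer = c(metabolite = 4L,
                                                      protein = 2L,
                                                      mirna = 3L),
                          effect_size = 1.5,
                          covariate_model = c(intercept = 0, age = 0.8,
                                              sex = 0.5, phenotype = 0.8,
                                              brainstem = 0.7),
                          noise_sd = 1, missing_rate = 0, outlier_rate = 0,
                          seed = 1L) {
  counts <- c(n_case = n_case, n_control = n_control,
              n_metabolites = n_metabolites, n_proteins = n_proteins,
              n_mirnas = n_mirnas)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v))
      stop(sprintf("invalid cohort configuration: `%s` must be a positive integer", nm))
  }
  if (length(n_informative_per_layer) == 1L)
    n_informative_per_layer <- c(metabolite = n_informative_per_layer,
                                 protein = n_informative_per_layer,
                                 mirna = n_informative_per_layer)
  if (is.null(names(n_informative_per_layer)))
    names(n_informative_per_layer) <- c("metabolite", "protein", "mirna")
  sizes <- c(metabolite = n_metabolites, protein = n_proteins,
             mirna = n_mirnas)
  for (nm in c("metabolite", "protein", "mirna")) {
    v <- n_informative_per_layer[[nm]]
    if (!is.finite(v) || v < 0 || v != round(v) || v > sizes[[nm]])
      stop(sprintf(
        "invalid cohort configuration: `n_informative_per_layer[%s]` must be in [0, %d]",
        nm, sizes[[nm]]))
  }
  for (nm in c("missing_rate", "outlier_rate")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v >= 1)
      stop(sprintf("invalid cohort configuration: `%s` must be in [0, 1)", nm))
  }
  if (!is.finite(effect_size))
    stop("invalid cohort configuration: `effect_size` must be finite")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("invalid cohort configuration: `noise_sd` must be positive")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("invalid cohort configuration: `seed` must be an integer")
  needed <- c("intercept", "age", "sex", "phenotype", "brainstem")
  if (!all(needed %in% names(covariate_model)))
    stop("invalid cohort configuration: `covariate_model` must name ",
         paste(needed, collapse = ", "))
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_metabolites = as.integer(n_metabolites),
                 n_proteins = as.integer(n_proteins),
                 n_mirnas = as.integer(n_mirnas),
                 n_informative_per_layer =
                   vapply(n_informative_per_layer[c("metabolite", "protein",
                                                    "mirna")], as.integer, 1L),
                 effect_size = effect_size,
                 covariate_model = covariate_model[needed],
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic multi-omic cohort
#'
#' Simulates a case-control cohort with the structure described in
#' [cohort_config()]. Abundance layers are log-normal: for feature j,
#' `log(value) = mu_j + delta_j * case + N(0, noise_sd)` where `delta_j` is
#' `+/- effect_size * noise_sd` for informative features (signs alternate)
#' and 0 otherwise. miRNA Cq values are Normal(25, 2)-based cycle numbers;
#' informative miRNAs shift Cq by `-effect_size * noise_cq` in cases (lower
#' Cq = more abundant), two endogenous-control candidates have 5-10x lower
#' variance than targets, and a spike-in column is constant up to small
#' pipetting noise. Covariates confound case status through the logistic
#' model in the config: cases are the `n_case` samples with the largest
#' latent logistic utilities.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `metabolites`,
#'   `proteins` (both [feature_table()]), `mirna_cq` (feature_table, layer
#'   `"mirna_cq"`, including columns `ctrl_miR_A`, `ctrl_miR_B`,
#'   `spike_in`), `metadata` (data.frame with `sample_id`, `group`, `age`,
#'   `sex`, `phenotype`, `brainstem_lesion`) and `truth` (informative
#'   feature ids with signed effects per layer, plus empty missing/outlier
#'   registers filled by [inject_missingness_and_outliers()]).
#' @examples
#' coh <- generate_cohort(cohort_config(n_case = 10, n_control = 10,
#'                                      n_metabolites = 30, seed = 42))
#' dim(coh$metabolites)
#' coh$truth$metabolites
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config object")
  n <- config$n_case + config$n_control
  sample_ids <- sprintf("S%03d", seq_len(n))

  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  # clinical covariates
  age <- pmin(pmax(stats::rnorm(n, 45, 12), 18), 85)
  sex <- stats::rbinom(n, 1L, 0.5)
  phenotype <- stats::rbinom(n, 1L, 0.45)        # 0 sporadic, 1 familial
  brainstem <- stats::rbinom(n, 1L, 0.3)

  cm <- config$covariate_model
  lp <- cm[["intercept"]] + cm[["age"]] * (age - 45) / 12 +
    cm[["sex"]] * sex + cm[["phenotype"]] * phenotype +
    cm[["brainstem"]] * brainstem
  # latent logistic utilities; the top n_case are cases, so group sizes are
  # exact while covariates still shift case probability
  utility <- lp + stats::rlogis(n)
  group <- rep("control", n)
  group[order(utility, decreasing = TRUE)[seq_len(config$n_case)]] <- "case"
  case <- as.integer(group == "case")

  ninf <- config$n_informative_per_layer
  signed_effects <- function(k) {
    if (k == 0L) return(numeric(0))
    s <- rep_len(c(1, -1), k)
    s * config$effect_size * config$noise_sd
  }

  sim_abundance <- function(n_feat, n_inf, base_mu, base_sd, prefix) {
    ids <- sprintf("%s%03d", prefix, seq_len(n_feat))
    mu <- stats::rnorm(n_feat, base_mu, base_sd)
    delta <- numeric(n_feat)
    inf_idx <- seq_len(n_inf)
    delta[inf_idx] <- signed_effects(n_inf)
    logv <- matrix(stats::rnorm(n * n_feat, 0, config$noise_sd), n, n_feat)
    logv <- sweep(logv, 2L, mu, `+`) + outer(case, delta)
    vals <- exp(logv)
    dimnames(vals) <- list(sample_ids, ids)
    list(values = vals,
         truth = data.frame(feature_id = ids[inf_idx],
                            effect = delta[inf_idx],
                            stringsAsFactors = FALSE))
  }

  metab <- sim_abundance(config$n_metabolites, ninf[["metabolite"]],
                         base_mu = log(1e4), base_sd = 1, prefix = "met")
  prot <- sim_abundance(config$n_proteins, ninf[["protein"]],
                        base_mu = log(50), base_sd = 0.8, prefix = "prot")

  # correlate the first informative protein with the first informative
  # metabolite (shared latent factor) so the association screen has signal
  if (ninf[["protein"]] >= 1L && ninf[["metabolite"]] >= 1L) {
    shared <- log(metab$values[, 1L]) -
      mean(log(metab$values[, 1L]))
    prot$values[, 1L] <- exp(log(prot$values[, 1L]) + 0.8 * shared)
  }

  # miRNA Cq layer: targets + 2 endogenous-control candidates + spike-in
  mirna_ids <- sprintf("miR%03d", seq_len(config$n_mirnas))
  cq_sd <- 2 * config$noise_sd / 1.5          # target-level Cq variability
  mu_cq <- stats::rnorm(config$n_mirnas, 25, 1.5)
  delta_cq_eff <- numeric(config$n_mirnas)
  delta_cq_eff[seq_len(ninf[["mirna"]])] <- -signed_effects(ninf[["mirna"]]) *
    cq_sd / config$noise_sd
  cq <- matrix(stats::rnorm(n * config$n_mirnas, 0, cq_sd),
               n, config$n_mirnas)
  cq <- sweep(cq, 2L, mu_cq, `+`) + outer(case, delta_cq_eff)
  ctrl_a <- 24 + stats::rnorm(n, 0, cq_sd / 8)   # stable endogenous control
  ctrl_b <- 26 + stats::rnorm(n, 0, cq_sd / 5)
  spike <- 20 + stats::rnorm(n, 0, 0.05)
  cq_all <- cbind(cq, ctrl_miR_A = ctrl_a, ctrl_miR_B = ctrl_b,
                  spike_in = spike)
  dimnames(cq_all) <- list(sample_ids,
                           c(mirna_ids, "ctrl_miR_A", "ctrl_miR_B",
                             "spike_in"))

  metadata <- data.frame(sample_id = sample_ids,
                         group = group,
                         age = age,
                         sex = sex,
                         phenotype = phenotype,
                         brainstem_lesion = brainstem,
                         stringsAsFactors = FALSE)

  truth <- list(
    metabolites = metab$truth,
    proteins = prot$truth,
    mirnas = data.frame(feature_id = mirna_ids[seq_len(ninf[["mirna"]])],
                        effect_cq = delta_cq_eff[seq_len(ninf[["mirna"]])],
                        stringsAsFactors = FALSE),
    endogenous_controls = c("ctrl_miR_A", "ctrl_miR_B"),
    spike_in = "spike_in",
    missing = data.frame(layer = character(0), sample_id = character(0),
                         feature_id = character(0),
                         stringsAsFactors = FALSE),
    outliers = data.frame(layer = character(0), sample_id = character(0),
                          feature_id = character(0), value = numeric(0),
                          stringsAsFactors = FALSE))

  structure(list(
    metabolites = feature_table(metab$values, "metabolite",
                                units = "peak intensity"),
    proteins = feature_table(prot$values, "protein", units = "ng/ml"),
    mirna_cq = feature_table(cq_all, "mirna_cq", units = "cycles"),
    metadata = metadata,
    truth = truth,
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d cases / %d controls\n",
              sum(x$metadata$group == "case"),
              sum(x$metadata$group == "control")))
  cat(sprintf("  metabolites: %d  proteins: %d  miRNA columns: %d\n",
              ncol(x$metabolites), ncol(x$proteins), ncol(x$mirna_cq)))
  cat(sprintf("  informative: %d metabolites, %d proteins, %d miRNAs\n",
              nrow(x$truth$metabolites), nrow(x$truth$proteins),
              nrow(x$truth$mirnas)))
  invisible(x)
}

#' Inject missing cells and gross outliers into a cohort
#'
#' Cells of the metabolite and protein layers are set missing independently
#' with probability `missing_rate`. A fraction `outlier_rate` of the
#' remaining observed cells is displaced to 8 within-group standard
#' deviations above the group mean (at most one injection per feature and
#' group), which keeps abundances positive and guarantees the injected cells
#' are flagged by the single-pass [exclude_outliers()] rule at `k_sd = 2`
#' whenever groups have at least 8 members. All injected positions are
#' recorded in `truth$missing` and `truth$outliers`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the [cohort_config()] carrying `missing_rate`,
#'   `outlier_rate` and a seed (a derived stream keeps this reproducible yet
#'   distinct from the generation stream).
#' @return the modified `synthetic_cohort`.
#' @export
inject_missingness_and_outliers <- function(cohort, config = cohort$config) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop("`cohort` must be a synthetic_cohort")
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config object")
  if (config$missing_rate == 0 && config$outlier_rate == 0) return(cohort)

  old <- local_seed(config$seed + 7919L)
  on.exit(restore_seed(old), add = TRUE)

  grp <- cohort$metadata$group
  for (layer in c("metabolites", "proteins")) {
    vals <- as_values_matrix(cohort[[layer]])
    nm <- if (layer == "metabolites") "metabolite" else "protein"

    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(vals)) < config$missing_rate,
                     nrow(vals), ncol(vals))
      idx <- which(miss, arr.ind = TRUE)
      if (nrow(idx)) {
        vals[miss] <- NA_real_
        cohort$truth$missing <- rbind(
          cohort$truth$missing,
          data.frame(layer = nm,
                     sample_id = rownames(vals)[idx[, 1L]],
                     feature_id = colnames(vals)[idx[, 2L]],
                     stringsAsFactors = FALSE))
      }
    }

    if (config$outlier_rate > 0) {
      n_obs <- sum(!is.na(vals))
      n_out <- stats::rbinom(1L, n_obs, config$outlier_rate)
      # at most one outlier per feature-group so one injected point cannot
      # mask another; displaced to mean + 8 group-SD on the positive side,
      # which keeps abundances positive and guarantees the single-pass
      # +/-2 SD rule flags it in groups of >= 8
      units <- expand.grid(feature = seq_len(ncol(vals)),
                           group = unique(grp),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
      n_out <- min(n_out, nrow(units))
      if (n_out > 0L) {
        pick_units <- units[sample(nrow(units), n_out), , drop = FALSE]
        rows <- integer(n_out); cols <- integer(n_out)
        for (k in seq_len(n_out)) {
          j <- pick_units$feature[k]
          in_grp <- which(grp == pick_units$group[k] & !is.na(vals[, j]))
          if (!length(in_grp)) next
          i <- if (length(in_grp) == 1L) in_grp else sample(in_grp, 1L)
          m <- mean(vals[in_grp, j])
          s <- stats::sd(vals[in_grp, j])
          if (!is.finite(s) || s == 0) s <- abs(m) * 0.1 + 1
          vals[i, j] <- m + 8 * s
          rows[k] <- i; cols[k] <- j
        }
        keep <- rows > 0L
        cohort$truth$outliers <- rbind(
          cohort$truth$outliers,
          data.frame(layer = nm,
                     sample_id = rownames(vals)[rows[keep]],
                     feature_id = colnames(vals)[cols[keep]],
                     value = vals[cbind(rows[keep], cols[keep])],
                     stringsAsFactors = FALSE))
      }
    }
    cohort[[layer]] <- rewrap(vals, cohort[[layer]])
  }
  cohort
}

#' Write cohort tables to a directory
#'
#' Writes `metabolites.csv`, `proteins.csv`, `mirna_cq.csv` (samples as
#' rows, first column `sample_id`), `metadata.csv` and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(tab, file) {
    vals <- as_values_matrix(tab)
    df <- data.frame(sample_id = rownames(vals), vals,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  wr(cohort$metabolites, "metabolites.csv")
  wr(cohort$proteins, "proteins.csv")
  wr(cohort$mirna_cq, "mirna_cq.csv")
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a feature-table CSV written by [write_cohort()]
#'
#' @param path CSV path with a `sample_id` first column.
#' @param layer,units passed to [feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, layer = "metabolite", units = "") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  storage.mode(vals) <- "double"
  feature_table(vals, layer = layer, units = units)
}

# Seed handling: set a temporary RNG state and restore the caller's state so
# package functions do not perturb the user's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
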