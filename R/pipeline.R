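#' Configuration for an end-to-end pipeline run
#'
#' Bundles the stage parameters of [run_pipeline()]: either a simulation
#' request (a [cohort_config()]) or a directory of cohort CSVs, the stage
#' toggles, and every analysis parameter with the study defaults
#' (alpha = 0.05, B permutations, 10-fold, ridge = 1e-8, |r| > 0.5,
#' +/-2 SD for proteins and +/-3 SD for miRNA relative expression).
#'
#' @param simulate a [cohort_config()] (default: the package default
#'   cohort) or `NULL` when `input_dir` is given.
#' @param input_dir directory holding `metabolites.csv`, `proteins.csv`,
#'   `mirna_cq.csv`, `metadata.csv` as written by [write_cohort()].
#' @param stages character vector of stages to run, in pipeline order.
#' @param label metadata column holding the case/control contrast.
#' @param alpha,B,n_components differential-stage parameters.
#' @param k,ridge cross-validation folds and ridge penalty.
#' @param r_min correlation-screen threshold.
#' @param k_sd named outlier multipliers for the protein and miRNA layers.
#' @param max_m,pool_size panel-search subset cap and CFS pool cap.
#' @param gmt,gene_lists optional pathway annotation file and named list of
#'   gene-list files enabling the enrichment stage.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @return a list of class `run_config`.
#' @export
run_config <- function(simulate = cohort_config(),
                       input_dir = NULL,
                       stages = c("simulate", "preprocess", "differential",
                                  "matching", "association", "panel_search",
                                  "fixed_model"),
                       label = "group",
                       alpha = 0.05, B = 999L, n_components = 2L,
                       k = 10L, ridge = 1e-8, r_min = 0.5,
                       k_sd = c(protein = 2, mirna = 3),
                       max_m = 3L, pool_size = 8L,
                       gmt = NULL, gene_lists = NULL,
                       seed = 1L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either `simulate` or `input_dir` must be given")
  if (!is.null(input_dir)) {
    needed <- c("metabolites.csv", "proteins.csv", "mirna_cq.csv",
                "metadata.csv")
    absent <- needed[!file.exists(file.path(input_dir, needed))]
    if (length(absent))
      stop("missing input file(s): ", paste(absent, collapse = ", "))
    stages <- setdiff(stages, "simulate")
  }
  if (!is.null(gmt) && !"enrichment" %in% stages)
    stages <- c(stages, "enrichment")
  structure(list(simulate = simulate, input_dir = input_dir,
                 stages = stages, label = label,
                 alpha = alpha, B = as.integer(B),
                 n_components = as.integer(n_components),
                 k = as.integer(k), ridge = ridge, r_min = r_min,
                 k_sd = k_sd, max_m = as.integer(max_m),
                 pool_size = as.integer(pool_size),
                 gmt = gmt, gene_lists = gene_lists,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments;
#'   a `simulate` mapping is passed to [cohort_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(cohort_config, y$simulate)
  if (!is.null(y$k_sd)) y$k_sd <- unlist(y$k_sd)
  do.call(run_config, y)
}

#' Run the end-to-end biomarker pipeline
#'
#' Orchestrates simulate -> preprocess -> differential -> matching ->
#' association -> panel search -> fixed-model evaluation (and optional
#' file-based pathway enrichment) from one [run_config()], writing every
#' stage's artifacts plus a manifest to `out_dir`. A single global seed
#' deterministically derives per-stage seeds, so rerunning with the same
#' config and seed reproduces the differential table and search results
#' byte-identically. A stage failure halts the run with a stage-scoped
#' error; artifacts already written are retained.
#'
#' The fixed-model stage refits the winning panel on the full cohort and
#' freezes it as a fixed weighted combination (JSON coefficients file),
#' then records its canonical values, ROC/Youden summary and the unpaired
#' t test between groups.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @param out_dir output directory (created; reused if existing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat("", file = log_path)

  # deterministic per-stage seed derivation from the global seed
  old <- local_seed(config$seed)
  stage_seeds <- stats::setNames(sample.int(2^30, 8L),
                                 c("simulate", "preprocess", "differential",
                                   "matching", "association", "panel_search",
                                   "fixed_model", "enrichment"))
  restore_seed(old)

  manifest <- list(package_version = as.character(utils::packageVersion("plasmapanel")),
                   global_seed = config$seed,
                   stage_seeds = as.list(stage_seeds),
                   parameters = config[c("label", "alpha", "B",
                                         "n_components", "k", "ridge",
                                         "r_min", "max_m", "pool_size")],
                   stages = list())
  done <- function(stage, outputs, extra = NULL) {
    manifest$stages[[stage]] <<- c(list(status = "completed",
                                        outputs = outputs), extra)
    logline("stage %s completed", stage)
  }
  run_stage <- function(stage, body) {
    logline("stage %s started", stage)
    tryCatch(body(), error = function(e) {
      logline("stage %s FAILED: %s", stage, conditionMessage(e))
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage `%s` failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  env <- new.env(parent = emptyenv())

  ## --- simulate / load -----------------------------------------------------
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      cc <- config$simulate
      cc$seed <- as.integer(stage_seeds[["simulate"]] %% 2^30)
      coh <- generate_cohort(cc)
      coh <- inject_missingness_and_outliers(coh, cc)
      cdir <- file.path(out_dir, "cohort")
      write_cohort(coh, cdir)
      env$cohort <- coh
      done("simulate", outputs = list(dir = "cohort"),
           extra = list(seed = cc$seed))
    })
  } else {
    run_stage("load", function() {
      env$cohort <- list(
        metabolites = read_feature_table(
          file.path(config$input_dir, "metabolites.csv"), "metabolite"),
        proteins = read_feature_table(
          file.path(config$input_dir, "proteins.csv"), "protein"),
        mirna_cq = read_feature_table(
          file.path(config$input_dir, "mirna_cq.csv"), "mirna_cq"),
        metadata = utils::read.csv(file.path(config$input_dir, "metadata.csv"),
                                   stringsAsFactors = FALSE))
      done("load", outputs = list(dir = config$input_dir))
    })
  }

  ## --- preprocess ----------------------------------------------------------
  if ("preprocess" %in% config$stages) {
    run_stage("preprocess", function() {
      coh <- env$cohort
      env$metab_ratio <- normalize_to_ratio(coh$metabolites)
      prot <- exclude_outliers(coh$proteins, coh$metadata, config$label,
                               k_sd = config$k_sd[["protein"]])
      env$proteins <- prot$table
      ctrl_candidates <- intersect(c("ctrl_miR_A", "ctrl_miR_B"),
                                   colnames(coh$mirna_cq))
      if (length(ctrl_candidates) >= 2L) {
        stab <- control_stability(coh$mirna_cq, coh$metadata,
                                  ctrl_candidates, config$label)
        ctrl <- attr(stab, "chosen")
      } else {
        stab <- NULL
        ctrl <- colnames(coh$mirna_cq)[ncol(coh$mirna_cq)]
      }
      cq <- as_values_matrix(coh$mirna_cq)
      cq <- cq[, setdiff(colnames(cq), "spike_in"), drop = FALSE]
      dq <- delta_cq(feature_table(cq, "mirna_cq", "cycles"), ctrl)
      mir <- exclude_outliers(dq$table, coh$metadata, config$label,
                              k_sd = config$k_sd[["mirna"]])
      env$mirna_rel <- mir$table
      utils::write.csv(
        data.frame(sample_id = rownames(env$metab_ratio),
                   as_values_matrix(env$metab_ratio), check.names = FALSE),
        file.path(out_dir, "metabolites_ratio.csv"), row.names = FALSE)
      done("preprocess",
           outputs = list(metabolites_ratio = "metabolites_ratio.csv"),
           extra = list(control_chosen = ctrl,
                        protein_cells_excluded = nrow(prot$qc$excluded_cells),
                        mirna_cells_excluded = nrow(mir$qc$excluded_cells)))
    })
  }

  ## --- differential --------------------------------------------------------
  if ("differential" %in% config$stages) {
    run_stage("differential", function() {
      x <- as_values_matrix(env$metab_ratio)
      # PLS-DA needs a complete matrix: mean-impute masked cells
      for (j in which(colSums(is.na(x)) > 0L))
        x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
      env$metab_complete <- x
      dt <- differential_analysis(x, env$cohort$metadata,
                                  label = config$label,
                                  n_components = config$n_components,
                                  B = config$B, alpha = config$alpha,
                                  seed = stage_seeds[["differential"]])
      env$differential <- dt
      utils::write.table(dt, file.path(out_dir, "differential_table.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      z <- zscore_matrix(x)
      utils::write.csv(data.frame(feature_id = rownames(z), z,
                                  check.names = FALSE),
                       file.path(out_dir, "zscore_matrix.csv"),
                       row.names = FALSE)
      done("differential",
           outputs = list(table = "differential_table.tsv",
                          zscores = "zscore_matrix.csv"),
           extra = list(seed = stage_seeds[["differential"]],
                        n_selected = sum(dt$selected)))
    })
  }

  ## --- matching ------------------------------------------------------------
  if ("matching" %in% config$stages) {
    run_stage("matching", function() {
      md <- env$cohort$metadata
      scores <- fit_propensity(md, config$label)
      mres <- match_pairs(scores, md[[config$label]])
      env$match <- mres
      bal <- covariate_balance(md, mres, config$label)
      utils::write.table(mres$pairs, file.path(out_dir, "matched_pairs.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(bal, file.path(out_dir, "covariate_balance.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      done("matching", outputs = list(pairs = "matched_pairs.tsv",
                                      balance = "covariate_balance.tsv"),
           extra = list(n_pairs = nrow(mres$pairs)))
    })
  }

  ## --- association ---------------------------------------------------------
  if ("association" %in% config$stages) {
    run_stage("association", function() {
      sel <- env$differential$feature_id[env$differential$selected]
      if (!length(sel))
        sel <- env$differential$feature_id[
          order(env$differential$p_perm)][seq_len(min(10L,
                                                      nrow(env$differential)))]
      ct <- correlate_features(env$metab_complete[, sel, drop = FALSE],
                               env$proteins)
      ct <- filter_correlations(ct, r_min = config$r_min,
                                alpha = config$alpha)
      env$correlations <- ct
      utils::write.table(ct, file.path(out_dir, "correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      done("association", outputs = list(table = "correlations.tsv"),
           extra = list(n_passing = sum(ct$passes)))
    })
  }

  ## --- panel search --------------------------------------------------------
  if ("panel_search" %in% config$stages) {
    run_stage("panel_search", function() {
      coh <- env$cohort
      sel <- env$differential$feature_id[env$differential$selected]
      if (!length(sel))
        sel <- env$differential$feature_id[
          order(env$differential$p_perm)][seq_len(min(4L,
                                                      nrow(env$differential)))]
      prot <- as_values_matrix(env$proteins)
      mir <- as_values_matrix(env$mirna_rel)
      shared <- Reduce(intersect, list(rownames(env$metab_complete),
                                       rownames(prot), rownames(mir)))
      pool <- cbind(env$metab_complete[shared, sel, drop = FALSE],
                    prot[shared, , drop = FALSE],
                    mir[shared, , drop = FALSE])
      for (j in which(colSums(is.na(pool)) > 0L))
        pool[is.na(pool[, j]), j] <- mean(pool[, j], na.rm = TRUE)
      y <- coh$metadata[[config$label]][match(shared,
                                              coh$metadata$sample_id)]
      keep <- cfs_select(pool, y)
      if (length(keep) > config$pool_size)
        keep <- keep[seq_len(config$pool_size)]
      sr <- search_panels(pool[, keep, drop = FALSE], y,
                          max_m = config$max_m,
                          schemes = c("loocv", "kfold"),
                          k = config$k,
                          seed = stage_seeds[["panel_search"]],
                          ridge = config$ridge)
      env$search <- sr
      env$panel_pool <- pool
      env$panel_y <- y
      utils::write.table(sr$log, file.path(out_dir, "panel_search_log.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      done("panel_search",
           outputs = list(log = "panel_search_log.tsv"),
           extra = list(seed = stage_seeds[["panel_search"]],
                        pool = keep,
                        best_by_youden = sr$best_by_youden$features,
                        best_by_aic = sr$best_by_aic$features))
    })
  }

  ## --- fixed-model evaluation ----------------------------------------------
  if ("fixed_model" %in% config$stages) {
    run_stage("fixed_model", function() {
      sel <- strsplit(env$search$best_by_youden$features, "+",
                      fixed = TRUE)[[1L]]
      xs <- env$panel_pool[, sel, drop = FALSE]
      fit <- ridge_logistic(xs, env$panel_y, ridge = config$ridge)
      fm <- fixed_model(name = "run winner (refit on full cohort)",
                        coefficients = fit$beta,
                        intercept = fit$intercept)
      cv <- canonical_values(fm, xs)
      roc <- roc_curve(cv, env$panel_y)
      yj <- youden_threshold(roc)
      tt <- compare_groups_t(cv, env$panel_y)
      jsonlite::write_json(list(name = fm$name,
                                coefficients = as.list(fm$coefficients),
                                intercept = fm$intercept),
                           file.path(out_dir, "fixed_model.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      metrics <- data.frame(auc = roc$auc, youden_J = yj$J,
                            sensitivity = yj$sensitivity,
                            specificity = yj$specificity,
                            t = tt$t, p = tt$p)
      utils::write.table(metrics, file.path(out_dir, "fixed_model_metrics.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      done("fixed_model",
           outputs = list(model = "fixed_model.json",
                          metrics = "fixed_model_metrics.tsv"))
    })
  }

  ## --- optional enrichment --------------------------------------------------
  if ("enrichment" %in% config$stages && !is.null(config$gmt)) {
    run_stage("enrichment", function() {
      ann <- read_gmt(config$gmt)
      sets <- lapply(config$gene_lists, function(f) readLines(f))
      enr <- lapply(sets, enrich_pathways, annotation = ann,
                    alpha = config$alpha)
      for (nm in names(enr))
        utils::write.table(enr[[nm]],
                           file.path(out_dir, sprintf("enrichment_%s.tsv", nm)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      xr <- cross_reference(lapply(enr, function(e)
        e$pathway_id[e$enriched]))
      writeLines(xr$common, file.path(out_dir, "common_pathways.txt"))
      done("enrichment",
           outputs = list(common = "common_pathways.txt"),
           extra = list(n_common = length(xr$common)))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("pipeline finished")
  invisible(manifest)
}
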