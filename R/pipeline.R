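# End-to-end orchestration: simulate (or load) -> extract -> select ->
# train -> evaluate -> report.  Every artifact needed to regenerate the
# report numbers is persisted (feature matrix, selection results, model
# summaries, per-patient scores), and every seed derives from the single
# master seed, so a rerun with the same configuration is bit-identical.

#' Pipeline run configuration
#'
#' @param input "synthetic" or a directory in the [write_cohort()] layout.
#' @param sim a [sim_config()] (synthetic mode only).
#' @param corr_threshold,min_auc selection thresholds (defaults 0.95, 0.6).
#' @param C,sigma SVM parameters (defaults 1, 0.012).
#' @param n_repeats hold-out repetitions (default 10).
#' @param lasso_repeats CV repetitions inside the LASSO (default 50).
#' @param train_fraction default 0.8.
#' @param n_folds CV folds (default 10).
#' @param bootstrap_B bootstrap replicates for table CIs (default 2000).
#' @param master_seed master seed (default 1).
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(input = "synthetic", sim = sim_config(),
                       corr_threshold = 0.95, min_auc = 0.6,
                       C = 1, sigma = 0.012, n_repeats = 10,
                       lasso_repeats = 50, train_fraction = 0.8,
                       n_folds = 10, bootstrap_B = 2000, master_seed = 1L) {
  stopifnot(corr_threshold > 0, corr_threshold < 1, min_auc >= 0.5,
            min_auc < 1, C > 0, sigma > 0, n_repeats >= 1,
            train_fraction > 0, train_fraction < 1)
  if (!identical(input, "synthetic") && !dir.exists(input))
    stop("input directory does not exist: ", input)
  structure(list(input = input, sim = sim, corr_threshold = corr_threshold,
                 min_auc = min_auc, C = C, sigma = sigma,
                 n_repeats = n_repeats, lasso_repeats = lasso_repeats,
                 train_fraction = train_fraction, n_folds = n_folds,
                 bootstrap_B = bootstrap_B,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Simulates or loads a cohort, extracts the 3,132-feature matrix, runs
#' the three repeated hold-out experiments (ultrasomics, reader score,
#' combined), evaluates the best models (full-cohort diagnostics table,
#' AFP-normal subgroup table, ROC and decision curves, paired DeLong and
#' Wilcoxon comparisons, baseline table), and writes all artifacts to
#' \code{out_dir}.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param cohort optional pre-built \code{ceus_cohort} (overrides
#'   \code{config$input}).
#' @param features optional pre-extracted feature matrix (patients x
#'   features) matching the cohort.
#' @return invisible list with all in-memory results (cohort, features,
#'   reports, tables).
#' @export
run_pipeline <- function(config = run_config(), out_dir, cohort = NULL,
                         features = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))
  .log_line(logf, "pipeline start; master_seed = ", config$master_seed)

  if (is.null(cohort)) {
    cohort <- if (identical(config$input, "synthetic")) {
      .log_line(logf, "simulating cohort: ", config$sim$n_fnh, " FNH + ",
                config$sim$n_hcc, " HCC")
      simulate_cohort(config$sim)
    } else {
      .log_line(logf, "reading cohort from ", config$input)
      read_cohort(config$input)
    }
  }
  y <- cohort_labels(cohort)
  score <- cohort_scores(cohort)
  cov <- cohort_covariates(cohort)

  if (is.null(features)) {
    .log_line(logf, "extracting features for ", length(y), " patients")
    features <- extract_cohort_features(cohort)
  }
  utils::write.csv(data.frame(id = rownames(features), features,
                              check.names = FALSE),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  .log_line(logf, "feature matrix: ", nrow(features), " x ", ncol(features))
  utils::write.csv(data.frame(feature = colnames(features),
                              folded_auc = .col_aucs(features, y)),
                   file.path(out_dir, "univariate_auc.csv"),
                   row.names = FALSE)

  sel_args <- list(corr_threshold = config$corr_threshold,
                   min_auc = config$min_auc, n_folds = config$n_folds,
                   n_repeats = config$lasso_repeats)
  reports <- list()
  for (ps in c("ultrasomics", "reader_score", "combined")) {
    .log_line(logf, "experiment: ", ps)
    reports[[ps]] <- run_experiment(
      X = if (ps == "reader_score") NULL else features,
      y = y, score = score, predictor_set = ps,
      C = config$C, sigma = config$sigma, n_repeats = config$n_repeats,
      train_fraction = config$train_fraction, cv_folds = config$n_folds,
      selection = sel_args, master_seed = config$master_seed)
    .log_line(logf, sprintf("  mean validation AUC %.3f (best %.3f, repeat %d)",
                            reports[[ps]]$mean_validation_auc,
                            max(reports[[ps]]$validation_aucs),
                            reports[[ps]]$best_repeat_index))
  }

  # summarise per-repeat results
  summaries <- lapply(reports, function(rep) {
    list(predictor_set = rep$predictor_set,
         mean_validation_auc = rep$mean_validation_auc,
         best_repeat_index = rep$best_repeat_index,
         validation_aucs = rep$validation_aucs,
         train_aucs = vapply(rep$per_repeat, function(z) z$train_auc, 0),
         cv_aucs = vapply(rep$per_repeat, function(z) z$cv_auc, 0),
         n_selected = vapply(rep$per_repeat, function(z) z$n_selected, 0L),
         selected_features = rep$selected_features)
  })
  jsonlite::write_json(summaries, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  best_sel <- reports$ultrasomics$per_repeat[[
    reports$ultrasomics$best_repeat_index]]$selection
  if (!is.null(best_sel)) {
    jsonlite::write_json(
      list(kept_after_corr = best_sel$kept_after_corr,
           kept_after_auc = best_sel$kept_after_auc,
           lasso_selected = best_sel$lasso_selected,
           chosen_lambda = best_sel$chosen_lambda,
           lambda_path = best_sel$lambda_path,
           cv_deviance = best_sel$cv_deviance, cv_se = best_sel$cv_se),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    .log_line(logf, "best ultrasomics repeat selected ",
              length(best_sel$lasso_selected), " features (lambda = ",
              signif(best_sel$chosen_lambda, 3), ")")
  }

  # paired comparisons on a common validation split: the repeat where the
  # combined model peaked (splits are shared across predictor sets)
  r_star <- reports$combined$best_repeat_index
  va <- reports$combined$per_repeat[[r_star]]$split$validation
  val_scores <- lapply(reports, function(rep)
    rep$per_repeat[[r_star]]$validation_scores)
  val_probs <- lapply(reports, function(rep)
    rep$per_repeat[[r_star]]$validation_probs)
  yv <- y[va]

  dl <- list(
    combined_vs_ultrasomics = delong_test(val_scores$combined,
                                          val_scores$ultrasomics, yv),
    combined_vs_reader = delong_test(val_scores$combined,
                                     val_scores$reader_score, yv),
    ultrasomics_vs_reader = delong_test(val_scores$ultrasomics,
                                        val_scores$reader_score, yv))
  wx <- list(
    combined_vs_ultrasomics = wilcoxon_signed_rank(
      reports$combined$validation_aucs, reports$ultrasomics$validation_aucs),
    combined_vs_reader = wilcoxon_signed_rank(
      reports$combined$validation_aucs, reports$reader_score$validation_aucs))
  jsonlite::write_json(list(delong = dl, wilcoxon_on_repeat_aucs = wx),
                       file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)

  tab_val <- diagnostics_table(val_scores, yv, B = config$bootstrap_B,
                               seed = sub_seed(config$master_seed, 0L, 23L))
  utils::write.csv(tab_val, file.path(out_dir, "diagnostics_validation.csv"),
                   row.names = FALSE)

  # subgroup (AFP-normal HCC + all FNH): best models re-scored on the full
  # cohort, thresholds kept from the validation table
  full_scores <- lapply(reports, function(rep) {
    m <- rep$per_repeat[[rep$best_repeat_index]]$model
    ps <- rep$predictor_set
    Xfull <- .design_for(rep, rep$best_repeat_index, features, score,
                         seq_along(y))
    predict(m, Xfull)
  })
  thr <- stats::setNames(as.list(tab_val$threshold), tab_val$model)
  sub_idx <- afp_normal_subset(y, cov$afp_band)
  tab_sub <- subgroup_eval(full_scores, y, sub_idx, thresholds = thr,
                           B = config$bootstrap_B,
                           seed = sub_seed(config$master_seed, 0L, 29L))
  utils::write.csv(tab_sub, file.path(out_dir, "diagnostics_subgroup.csv"),
                   row.names = FALSE)
  .log_line(logf, "subgroup size ", length(sub_idx), " (",
            sum(y[sub_idx] == 1), " AFP-normal HCC + ",
            sum(y[sub_idx] == 0), " FNH)")

  # ROC + DCA curves on the common validation split
  for (nm in names(val_scores)) {
    roc <- roc_auc(val_scores[[nm]], yv)
    utils::write.csv(data.frame(threshold = roc$thresholds,
                                sensitivity = roc$sensitivities,
                                specificity = roc$specificities),
                     file.path(out_dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  }
  dca <- lapply(val_probs, function(p) net_benefit_curve(p, yv))
  dca_df <- data.frame(threshold = dca[[1]]$thresholds,
                       nb_all = dca[[1]]$net_benefit_all, nb_none = 0)
  for (nm in names(dca)) dca_df[[paste0("nb_", nm)]] <- dca[[nm]]$net_benefit_model
  utils::write.csv(dca_df, file.path(out_dir, "dca.csv"), row.names = FALSE)

  bt <- baseline_table(cov[, setdiff(names(cov), c("id", "label",
                                                   "reader_score"))], y)
  utils::write.csv(bt, file.path(out_dir, "baseline_table.csv"),
                   row.names = FALSE)
  .log_line(logf, "pipeline complete")

  invisible(list(cohort = cohort, features = features, reports = reports,
                 diagnostics_validation = tab_val,
                 diagnostics_subgroup = tab_sub, comparisons = list(
                   delong = dl, wilcoxon = wx),
                 dca = dca, baseline = bt, out_dir = out_dir))
}

# rebuild the design matrix a fitted repeat expects, for arbitrary rows
.design_for <- function(report, r, features, score, rows) {
  pr <- report$per_repeat[[r]]
  cols <- list()
  if (!is.null(pr$selection) && !pr$fallback) {
    pars <- pr$selection$normalization_params
    pars <- pars[pars$feature %in% pr$selection$lasso_selected, , drop = FALSE]
    cols$feats <- apply_normalization(features[rows, , drop = FALSE], pars)
  }
  if (report$predictor_set %in% c("reader_score", "combined") || pr$fallback) {
    tr <- pr$split$train
    mu_s <- mean(score[tr]); sd_s <- stats::sd(score[tr])
    if (is.na(sd_s) || sd_s == 0) sd_s <- 1
    cols$score <- matrix((score[rows] - mu_s) / sd_s,
                         dimnames = list(NULL, "reader_score"))
  }
  do.call(cbind, cols)
}
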