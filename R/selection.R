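# Feature selection chain: correlation filter -> univariate AUC filter ->
# z-normalization -> LASSO logistic regression with the 1-SE rule.  The
# chain is always fitted on training data only; normalization parameters
# are carried in the result so validation data can be transformed without
# leakage.

#' Univariate (Mann-Whitney) AUC of one feature
#'
#' Rank-based AUC with ties counted 1/2.  By default the value is folded
#' as \code{max(AUC, 1 - AUC)} so that discriminative features are scored
#' identically regardless of direction.
#'
#' @param x numeric feature values.
#' @param y binary labels (0/1), both classes present.
#' @param fold fold direction (default TRUE).
#' @return AUC in [0.5, 1] (folded) or [0, 1] (raw).
#' @export
univariate_auc <- function(x, y, fold = TRUE) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(x)
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  if (fold) max(a, 1 - a) else a
}

# vectorized folded AUC over matrix columns (midranks per column)
.col_aucs <- function(X, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  a <- apply(X, 2, function(x)
    (sum(rank(x)[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1))
  pmax(a, 1 - a)
}

#' Redundancy (correlation) filter
#'
#' Greedy pass over features in order of descending ranking (univariate
#' folded AUC unless supplied): a feature is dropped if its absolute
#' Pearson correlation with any already-kept feature exceeds
#' \code{threshold}.  Zero-variance features are dropped first with a
#' warning (their correlation is undefined).
#'
#' @param X patients x features matrix with column names.
#' @param y binary labels, used to compute the default ranking.
#' @param threshold correlation cut (default 0.95).
#' @param ranking optional named per-feature ranking (higher = kept first).
#' @return character vector of kept feature names.
#' @export
correlation_filter <- function(X, y = NULL, threshold = 0.95, ranking = NULL) {
  stopifnot(nrow(X) >= 2, threshold > 0, threshold < 1)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s) dropped before ",
            "correlation filtering")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (is.null(ranking)) {
    if (is.null(y)) stop("either y or ranking must be supplied")
    ranking <- .col_aucs(X, y)
  } else {
    ranking <- ranking[colnames(X)]
  }
  ord <- order(ranking, decreasing = TRUE)
  X <- X[, ord, drop = FALSE]
  cm <- abs(suppressWarnings(stats::cor(X)))
  p <- ncol(X)
  keep <- logical(p)
  for (j in seq_len(p)) {
    if (j == 1 || all(cm[j, keep] <= threshold, na.rm = TRUE)) keep[j] <- TRUE
  }
  colnames(X)[keep]
}

#' Univariate-AUC filter
#'
#' Keeps features whose folded univariate AUC is at least \code{min_auc}
#' (boundary inclusive).
#'
#' @inheritParams correlation_filter
#' @param min_auc AUC cut (default 0.6).
#' @return character vector of kept feature names.
#' @export
auc_filter <- function(X, y, min_auc = 0.6) {
  a <- .col_aucs(X, y)
  kept <- colnames(X)[a >= min_auc]
  message(ncol(X) - length(kept), " feature(s) removed by the AUC filter")
  kept
}

#' Z-score normalization fitted on training data
#'
#' Normalizes by the training mean and population SD (divide by n); the
#' same parameters are applied to \code{X_apply}.  Zero-SD training
#' columns are dropped with a warning.
#'
#' @param X_train training matrix.
#' @param X_apply optional matrix to transform with the training
#'   parameters (same columns).
#' @return list with \code{train}, \code{apply} (NULL if not given) and
#'   \code{params} (data.frame feature/mean/sd).
#' @export
zscore <- function(X_train, X_apply = NULL) {
  mu <- colMeans(X_train)
  n <- nrow(X_train)
  sd_pop <- sqrt(colMeans(X_train^2) - mu^2)
  sd_pop[sd_pop < 0] <- 0
  keep <- sd_pop > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance column(s) dropped in z-scoring")
  tr <- sweep(sweep(X_train[, keep, drop = FALSE], 2, mu[keep]), 2,
              sd_pop[keep], "/")
  ap <- NULL
  if (!is.null(X_apply))
    ap <- sweep(sweep(X_apply[, keep, drop = FALSE], 2, mu[keep]), 2,
                sd_pop[keep], "/")
  list(train = tr, apply = ap,
       params = data.frame(feature = colnames(X_train)[keep],
                           mean = mu[keep], sd = sd_pop[keep],
                           stringsAsFactors = FALSE))
}

# stratified fold assignment (1..n_folds), deterministic given seed
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' LASSO logistic feature selection with the 1-SE rule
#'
#' L1-penalized logistic regression over a 100-value log-spaced lambda
#' path (down to 1e-4 of lambda_max).  The cross-validation criterion is
#' the mean binomial deviance, averaged over \code{n_repeats} repetitions
#' of stratified \code{n_folds}-fold CV; the chosen lambda is the largest
#' whose mean deviance is within one standard error of the minimum (the
#' 1-SE rule; the SE curve is the across-repeat average of the CV standard
#' errors).  Features with nonzero coefficients at the chosen lambda are
#' returned.
#'
#' @param X normalized training matrix (patients x features).
#' @param y binary labels.
#' @param n_folds folds per CV repetition (default 10).
#' @param n_repeats CV repetitions (default 50).
#' @param rule "1se" or "min".
#' @param seed master seed for fold assignment.
#' @return list: \code{selected} (feature names; empty with
#'   \code{empty = TRUE} if the rule retains none), \code{chosen_lambda},
#'   \code{lambda_path}, \code{cv_deviance}, \code{cv_se},
#'   \code{coefficients}.
#' @export
lasso_select <- function(X, y, n_folds = 10, n_repeats = 50,
                         rule = c("1se", "min"), seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(length(unique(y)) == 2)
  n_folds <- max(2L, min(n_folds, min(table(y))))  # every fold needs both classes
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        nlambda = 100, lambda.min.ratio = 1e-4,
                        standardize = FALSE)
  path <- fit$lambda
  cvm <- matrix(NA_real_, length(path), n_repeats)
  cvsd <- matrix(NA_real_, length(path), n_repeats)
  for (r in seq_len(n_repeats)) {
    foldid <- stratified_folds(y, n_folds, seed = sub_seed(seed, r, 3L))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                            lambda = path, foldid = foldid,
                            type.measure = "deviance", standardize = FALSE)
    m <- match(path, cv$lambda)
    cvm[, r] <- cv$cvm[m]
    cvsd[, r] <- cv$cvsd[m]
  }
  mean_dev <- rowMeans(cvm)
  mean_se <- rowMeans(cvsd)
  ok <- !is.na(mean_dev)
  i_min <- which(ok)[which.min(mean_dev[ok])]
  lambda_star <- if (rule == "min") path[i_min] else {
    cut <- mean_dev[i_min] + mean_se[i_min]
    max(path[ok & mean_dev <= cut])
  }
  cf <- as.matrix(stats::coef(fit, s = lambda_star))
  nz <- rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
  list(selected = nz, empty = length(nz) == 0,
       chosen_lambda = lambda_star, lambda_path = path,
       cv_deviance = mean_dev, cv_se = mean_se,
       coefficients = cf[cf[, 1] != 0, 1])
}

#' Events-per-variable (EPV) check
#'
#' Warns (does not fail) when the number of events is below ten times the
#' number of candidate covariates, following the standard multivariate
#' rule of thumb.
#'
#' @param n_events number of events (positive-class patients).
#' @param n_covariates number of model covariates.
#' @return list(pass, n_events, n_covariates, required); warns if not
#'   passed.
#' @export
epv_check <- function(n_events, n_covariates) {
  required <- 10 * n_covariates
  pass <- n_events >= required
  if (!pass)
    warning("events-per-variable rule violated: ", n_events, " events < 10 x ",
            n_covariates, " covariates (", required, " required)")
  list(pass = pass, n_events = n_events, n_covariates = n_covariates,
       required = required)
}

#' Full selection chain on training data
#'
#' Pipeline order: correlation filter -> AUC filter -> z-normalization ->
#' LASSO (1-SE).  Each stage's output is a subset of its input's columns.
#' An EPV warning is issued if the final set is large relative to the
#' number of events.
#'
#' @param X training feature matrix (raw scale).
#' @param y binary training labels.
#' @param corr_threshold correlation cut (default 0.95).
#' @param min_auc univariate AUC cut (default 0.6).
#' @param n_folds,n_repeats,rule,seed passed to [lasso_select()].
#' @return object of class \code{selection_result}: kept_after_corr,
#'   kept_after_auc, lasso_selected, lambda_path, chosen_lambda,
#'   cv_deviance, cv_se, normalization_params, empty flag.
#' @export
select_features <- function(X, y, corr_threshold = 0.95, min_auc = 0.6,
                            n_folds = 10, n_repeats = 50, rule = "1se",
                            seed = 1L) {
  kept_corr <- correlation_filter(X, y, threshold = corr_threshold)
  kept_auc <- auc_filter(X[, kept_corr, drop = FALSE], y, min_auc = min_auc)
  if (length(kept_auc) < 2) {
    return(structure(list(kept_after_corr = kept_corr,
                          kept_after_auc = kept_auc,
                          lasso_selected = character(0), empty = TRUE,
                          chosen_lambda = NA_real_, lambda_path = numeric(0),
                          cv_deviance = numeric(0), cv_se = numeric(0),
                          normalization_params = NULL),
                     class = "selection_result"))
  }
  z <- zscore(X[, kept_auc, drop = FALSE])
  ls <- lasso_select(z$train, y, n_folds = n_folds, n_repeats = n_repeats,
                     rule = rule, seed = seed)
  epv_check(sum(y == 1), length(ls$selected))
  structure(list(kept_after_corr = kept_corr, kept_after_auc = kept_auc,
                 lasso_selected = ls$selected, empty = ls$empty,
                 chosen_lambda = ls$chosen_lambda,
                 lambda_path = ls$lambda_path,
                 cv_deviance = ls$cv_deviance, cv_se = ls$cv_se,
                 coefficients = ls$coefficients,
                 normalization_params = z$params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n",
      " after correlation filter:", length(x$kept_after_corr), "\n",
      " after AUC filter:        ", length(x$kept_after_auc), "\n",
      " LASSO selected:          ", length(x$lasso_selected),
      sprintf(" (lambda = %.4g)\n", x$chosen_lambda))
  invisible(x)
}

#' Apply stored normalization parameters to new data
#'
#' @param X matrix containing at least the parameterised columns.
#' @param params data.frame (feature, mean, sd) from [zscore()] or a
#'   \code{selection_result}.
#' @return normalized matrix restricted to the parameterised columns.
#' @export
apply_normalization <- function(X, params) {
  if (inherits(params, "selection_result")) params <- params$normalization_params
  sweep(sweep(X[, params$feature, drop = FALSE], 2, params$mean), 2,
        params$sd, "/")
}
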