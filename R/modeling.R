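# RBF-kernel support vector machine (C-SVC) trained by sequential minimal
# optimisation, plus the repeated 80/20 hold-out experiment that wraps
# selection + training + validation.  The kernel convention is
# k(u, v) = exp(-sigma * ||u - v||^2) with sigma = 0.012 by default (the
# kernlab parameterisation); the alternative exp(-||u-v||^2 / (2 s^2)) is
# available via `sigma_convention = "bandwidth"`.

.sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

.rbf_kernel <- function(A, B, sigma, sigma_convention = "scale") {
  g <- if (sigma_convention == "bandwidth") 1 / (2 * sigma^2) else sigma
  exp(-g * .sq_dist(A, B))
}

# SMO solver (Platt-style, deterministic scan order).  Returns alpha and b
# for the decision function f(x) = sum_i alpha_i y_i k(x_i, x) + b.
.smo <- function(K, y, C, tol = 1e-3, eps = 1e-12, max_passes = 200L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  f <- rep(0, n)           # current decision values
  E <- f - y

  take_step <- function(i1, i2) {
    if (i1 == i2) return(FALSE)
    a1 <- alpha[i1]; a2 <- alpha[i2]
    y1 <- y[i1]; y2 <- y[i2]
    E1 <- E[i1]; E2 <- E[i2]
    s <- y1 * y2
    if (s > 0) { L <- max(0, a1 + a2 - C); H <- min(C, a1 + a2) }
    else       { L <- max(0, a2 - a1);     H <- min(C, C + a2 - a1) }
    if (L >= H) return(FALSE)
    k11 <- K[i1, i1]; k12 <- K[i1, i2]; k22 <- K[i2, i2]
    eta <- k11 + k22 - 2 * k12
    if (eta <= 0) return(FALSE)  # RBF kernel: only for duplicated points
    a2new <- a2 + y2 * (E1 - E2) / eta
    a2new <- min(max(a2new, L), H)
    if (abs(a2new - a2) < eps * (a2new + a2 + eps)) return(FALSE)
    a1new <- a1 + s * (a2 - a2new)
    d1 <- (a1new - a1) * y1
    d2 <- (a2new - a2) * y2
    b1 <- b - E1 - d1 * k11 - d2 * k12
    b2 <- b - E2 - d1 * k12 - d2 * k22
    bnew <- if (a1new > 0 && a1new < C) b1
            else if (a2new > 0 && a2new < C) b2
            else (b1 + b2) / 2
    f <<- f + d1 * K[, i1] + d2 * K[, i2] + (bnew - b)
    E <<- f - y
    alpha[i1] <<- a1new
    alpha[i2] <<- a2new
    b <<- bnew
    TRUE
  }

  examine <- function(i2) {
    r2 <- E[i2] * y[i2]
    if (!((r2 < -tol && alpha[i2] < C) || (r2 > tol && alpha[i2] > 0)))
      return(FALSE)
    nb <- which(alpha > 0 & alpha < C)
    if (length(nb) > 1) {
      i1 <- nb[which.max(abs(E[nb] - E[i2]))]
      if (take_step(i1, i2)) return(TRUE)
    }
    for (i1 in nb) if (take_step(i1, i2)) return(TRUE)
    for (i1 in seq_len(n)) if (take_step(i1, i2)) return(TRUE)
    FALSE
  }

  examine_all <- TRUE
  for (pass in seq_len(max_passes)) {
    changed <- 0L
    idx <- if (examine_all) seq_len(n) else which(alpha > 0 & alpha < C)
    for (i2 in idx) changed <- changed + examine(i2)
    if (examine_all) {
      if (changed == 0L) break
      examine_all <- FALSE
    } else if (changed == 0L) {
      examine_all <- TRUE
    }
  }
  list(alpha = alpha, b = b)
}

#' Train an RBF-kernel SVM classifier
#'
#' C-support vector classification solved by SMO.  Optionally fits a Platt
#' probability calibration (logistic regression of the class on the
#' decision value) on out-of-fold decision values from an internal
#' stratified CV, so calibration never sees its own training predictions.
#'
#' @param X numeric design matrix (rows = patients); predictors should be
#'   on comparable scales (z-scored upstream).
#' @param y binary labels (0/1).
#' @param C error-margin trade-off (default 1).
#' @param sigma RBF kernel parameter, \code{exp(-sigma ||u-v||^2)}
#'   (default 0.012).
#' @param sigma_convention "scale" (kernlab-style, default) or
#'   "bandwidth" for \code{exp(-||u-v||^2/(2 sigma^2))}.
#' @param calibrate fit Platt scaling (default TRUE).
#' @param tol SMO KKT tolerance (default 1e-3; tighten for high-precision
#'   comparisons).
#' @param calib_folds folds for calibration decision values (default 5).
#' @param seed seed for the calibration folds.
#' @return object of class \code{svm_model}.
#' @export
svm_rbf <- function(X, y, C = 1, sigma = 0.012, sigma_convention = "scale",
                    calibrate = TRUE, calib_folds = 5L, seed = 1L,
                    tol = 1e-3) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  stopifnot(C > 0, sigma > 0)
  ypm <- ifelse(y == 1, 1, -1)
  K <- .rbf_kernel(X, X, sigma, sigma_convention)
  sol <- .smo(K, ypm, C, tol = tol)
  model <- structure(list(X = X, y = y, alpha = sol$alpha, b = sol$b,
                          C = C, sigma = sigma,
                          sigma_convention = sigma_convention,
                          platt = NULL, features = colnames(X)),
                     class = "svm_model")
  if (calibrate) {
    nf <- min(calib_folds, min(table(y)))
    d_oof <- rep(NA_real_, length(y))
    if (nf >= 2) {
      foldid <- stratified_folds(y, nf, seed)
      for (k in seq_len(nf)) {
        tr <- foldid != k
        if (length(unique(y[tr])) < 2) next
        Kk <- K[tr, tr]
        sk <- .smo(Kk, ypm[tr], C)
        d_oof[!tr] <- as.numeric(K[!tr, tr, drop = FALSE] %*%
                                   (sk$alpha * ypm[tr]) + sk$b)
      }
    }
    ok <- !is.na(d_oof)
    if (sum(ok) >= 4 && length(unique(y[ok])) == 2) {
      model$platt <- suppressWarnings(
        stats::glm(y[ok] ~ d_oof[ok], family = stats::binomial())$coefficients)
    }
  }
  model
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> RBF (sigma = %g, C = %g), %d SV / %d samples\n",
              x$sigma, x$C, sum(x$alpha > 1e-8), length(x$y)))
  invisible(x)
}

#' Predict from an RBF-SVM
#'
#' @param object an \code{svm_model}.
#' @param newdata matrix with the training columns.
#' @param type "decision" (default) or "prob" (Platt-calibrated; falls
#'   back to a logistic squash of the decision value if no calibration was
#'   fitted).
#' @param ... unused.
#' @export
predict.svm_model <- function(object, newdata, type = c("decision", "prob"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) newdata <- newdata[, object$features,
                                                    drop = FALSE]
  Kx <- .rbf_kernel(newdata, object$X, object$sigma,
                    object$sigma_convention)
  d <- as.numeric(Kx %*% (object$alpha * ifelse(object$y == 1, 1, -1)) +
                    object$b)
  if (type == "decision") return(d)
  cf <- object$platt
  if (is.null(cf)) cf <- c(0, 1)
  stats::plogis(cf[1] + cf[2] * d)
}

#' Stratified 80/20 cohort split
#'
#' Disjoint and exhaustive; class proportions preserved to within one
#' patient per class (training size = round(fraction x class size)).
#'
#' @param y binary labels (or a \code{ceus_cohort}).
#' @param train_fraction fraction in the training set (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and
#'   \code{validation}.
#' @export
split_cohort <- function(y, train_fraction = 0.8, seed = 1L) {
  if (inherits(y, "ceus_cohort")) y <- cohort_labels(y)
  if (min(table(y)) < 2) stop("each class needs >= 2 patients to stratify")
  if (min(table(y)) < 5)
    warning("fewer than 5 patients in a class; stratified split is fragile")
  with_seed(seed, {
    train <- integer(0)
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, validation = setdiff(seq_along(y), train))
  })
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Trains on k-1 folds, scores the held-out fold, and pools the
#' out-of-fold decision values into a single AUC (plus per-fold AUCs).
#'
#' @param X design matrix, \code{y} binary labels.
#' @param y binary labels.
#' @param C,sigma,sigma_convention SVM parameters.
#' @param n_folds number of folds (default 10; must not exceed the
#'   minority class size).
#' @param seed fold seed.
#' @return list(pooled_auc, fold_aucs, oof_scores, foldid).
#' @export
crossvalidate_svm <- function(X, y, C = 1, sigma = 0.012,
                              sigma_convention = "scale", n_folds = 10,
                              seed = 1L) {
  y <- as.integer(y)
  if (n_folds > min(table(y))) stop("n_folds exceeds the minority class size")
  foldid <- stratified_folds(y, n_folds, seed)
  oof <- rep(NA_real_, length(y))
  fold_aucs <- rep(NA_real_, n_folds)
  for (k in seq_len(n_folds)) {
    tr <- foldid != k
    m <- svm_rbf(X[tr, , drop = FALSE], y[tr], C = C, sigma = sigma,
                 sigma_convention = sigma_convention, calibrate = FALSE)
    oof[!tr] <- predict(m, X[!tr, , drop = FALSE])
    if (length(unique(y[!tr])) == 2)
      fold_aucs[k] <- univariate_auc(oof[!tr], y[!tr], fold = FALSE)
  }
  list(pooled_auc = univariate_auc(oof, y, fold = FALSE),
       fold_aucs = fold_aucs, oof_scores = oof, foldid = foldid)
}

#' Repeated hold-out experiment for one predictor set
#'
#' For each of \code{n_repeats} repetitions: stratified 80/20 split,
#' feature selection on the training split only (for predictor sets that
#' use ultrasomics features), SVM training, and evaluation on the held-out
#' validation split.  The model with the highest validation AUC is flagged
#' as the best model (ties broken toward the lower repeat index).  A
#' repeat whose selection returns no features falls back to the reader
#' score and is flagged.
#'
#' @param X patients x features ultrasomics matrix (raw scale), or NULL
#'   for the reader-score-only model.
#' @param y binary labels.
#' @param score per-patient reader grade (1/2/3), required for
#'   "reader_score" and "combined".
#' @param predictor_set "ultrasomics", "reader_score" or "combined".
#' @param C,sigma,sigma_convention SVM parameters.
#' @param n_repeats hold-out repetitions (default 10).
#' @param train_fraction default 0.8.
#' @param cv_folds folds for the within-training CV AUC (default 10).
#' @param selection list of overrides for [select_features()]
#'   (corr_threshold, min_auc, n_folds, n_repeats).
#' @param master_seed master seed; all repeat seeds derive from it.
#' @param keep_models store fitted models (default TRUE).
#' @return object of class \code{model_report}.
#' @export
run_experiment <- function(X, y, score = NULL,
                           predictor_set = c("ultrasomics", "reader_score",
                                             "combined"),
                           C = 1, sigma = 0.012, sigma_convention = "scale",
                           n_repeats = 10, train_fraction = 0.8,
                           cv_folds = 10, selection = list(),
                           master_seed = 1L, keep_models = TRUE) {
  predictor_set <- match.arg(predictor_set)
  y <- as.integer(y)
  needs_feats <- predictor_set %in% c("ultrasomics", "combined")
  needs_score <- predictor_set %in% c("reader_score", "combined")
  if (needs_feats && is.null(X)) stop("feature matrix required")
  if (needs_score && is.null(score)) stop("reader score required")
  sel_args <- utils::modifyList(list(corr_threshold = 0.95, min_auc = 0.6,
                                     n_folds = 10, n_repeats = 50),
                                selection)
  per_repeat <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- split_cohort(y, train_fraction, seed = sub_seed(master_seed, r, 11L))
    tr <- sp$train; va <- sp$validation
    sel <- NULL
    fallback <- FALSE
    cols <- list()
    if (needs_feats) {
      sel <- suppressWarnings(suppressMessages(select_features(
        X[tr, , drop = FALSE], y[tr],
        corr_threshold = sel_args$corr_threshold, min_auc = sel_args$min_auc,
        n_folds = sel_args$n_folds, n_repeats = sel_args$n_repeats,
        seed = sub_seed(master_seed, r, 13L))))
      if (sel$empty || length(sel$lasso_selected) == 0) {
        fallback <- TRUE
        if (is.null(score))
          stop("selection returned no features and no reader score is ",
               "available for fallback (repeat ", r, ")")
      } else {
        pars <- sel$normalization_params
        pars <- pars[pars$feature %in% sel$lasso_selected, , drop = FALSE]
        cols$feats_train <- apply_normalization(X[tr, , drop = FALSE], pars)
        cols$feats_val <- apply_normalization(X[va, , drop = FALSE], pars)
      }
    }
    use_score <- needs_score || fallback
    if (use_score) {
      mu_s <- mean(score[tr]); sd_s <- stats::sd(score[tr])
      if (is.na(sd_s) || sd_s == 0) sd_s <- 1
      cols$score_train <- matrix((score[tr] - mu_s) / sd_s,
                                 dimnames = list(NULL, "reader_score"))
      cols$score_val <- matrix((score[va] - mu_s) / sd_s,
                               dimnames = list(NULL, "reader_score"))
    }
    Xtr <- do.call(cbind, cols[grep("_train$", names(cols))])
    Xva <- do.call(cbind, cols[grep("_val$", names(cols))])
    model <- svm_rbf(Xtr, y[tr], C = C, sigma = sigma,
                     sigma_convention = sigma_convention,
                     seed = sub_seed(master_seed, r, 17L))
    d_tr <- predict(model, Xtr)
    d_va <- predict(model, Xva)
    p_va <- predict(model, Xva, type = "prob")
    cv <- tryCatch(
      crossvalidate_svm(Xtr, y[tr], C = C, sigma = sigma,
                        sigma_convention = sigma_convention,
                        n_folds = min(cv_folds, min(table(y[tr]))),
                        seed = sub_seed(master_seed, r, 19L)),
      error = function(e) list(pooled_auc = NA_real_))
    per_repeat[[r]] <- list(
      repeat_index = r, split = sp, selection = sel, fallback = fallback,
      n_selected = if (!is.null(sel)) length(sel$lasso_selected) else 0L,
      model = if (keep_models) model else NULL,
      train_auc = univariate_auc(d_tr, y[tr], fold = FALSE),
      cv_auc = cv$pooled_auc,
      validation_auc = univariate_auc(d_va, y[va], fold = FALSE),
      validation_scores = d_va, validation_probs = p_va,
      train_scores = d_tr)
  }
  val_aucs <- vapply(per_repeat, function(z) z$validation_auc, 0)
  best <- which.max(val_aucs)  # which.max takes the first maximum
  structure(list(predictor_set = predictor_set, per_repeat = per_repeat,
                 best_repeat_index = best,
                 mean_validation_auc = mean(val_aucs),
                 validation_aucs = val_aucs,
                 selected_features =
                   if (!is.null(per_repeat[[best]]$selection))
                     per_repeat[[best]]$selection$lasso_selected
                   else character(0),
                 C = C, sigma = sigma, n_repeats = n_repeats,
                 master_seed = master_seed),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s: mean validation AUC %.3f over %d repeats (best %.3f at repeat %d)\n",
              x$predictor_set, x$mean_validation_auc, x$n_repeats,
              max(x$validation_aucs), x$best_repeat_index))
  invisible(x)
}
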