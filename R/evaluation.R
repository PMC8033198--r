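# Diagnostic-performance statistics: ROC/AUC, Youden operating point,
# confusion-matrix metrics with exact or bootstrap CIs, DeLong and
# Wilcoxon model comparisons, agreement statistics (weighted kappa, ICC),
# decision curve analysis, subgroup evaluation and baseline-table tests.
# Positive class is HCC = 1 throughout; a "positive test" is a model
# output at or above the operating threshold.

#' ROC curve and AUC
#'
#' Thresholds sweep the distinct score values; sensitivity/specificity are
#' computed calling positive when score >= threshold.  The AUC is the
#' Mann-Whitney statistic (ties counted 1/2), which equals the trapezoidal
#' area under the empirical ROC.
#'
#' @param scores numeric scores, higher = more disease-like.
#' @param labels binary labels (0/1), both classes present.
#' @return object of class \code{roc_result}: thresholds, sensitivities,
#'   specificities, auc, n_pos, n_neg.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n0, 0)
  auc <- univariate_auc(scores, labels, fold = FALSE)
  structure(list(thresholds = thr, sensitivities = sens,
                 specificities = spec, auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d pos / %d neg, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Youden-optimal operating threshold
#'
#' Maximizes sensitivity + specificity - 1; ties are broken toward higher
#' specificity.
#'
#' @param roc a \code{roc_result}.
#' @return list(threshold, sensitivity, specificity, youden).
#' @export
youden_threshold <- function(roc) {
  j <- roc$sensitivities + roc$specificities - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(roc$specificities[best])]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivities[best],
       specificity = roc$specificities[best],
       youden = j[best])
}

#' Confusion-matrix diagnostics (point estimates)
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return list with sensitivity, specificity, ppv, npv, plr, nlr,
#'   accuracy; metrics with a zero denominator are NA with a
#'   \code{flagged} entry naming them.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  out <- list(
    sensitivity = sens,
    specificity = spec,
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    plr = if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec)
          else NA_real_,
    nlr = if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec
          else NA_real_,
    accuracy = div(tp + tn, tp + fp + tn + fn),
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
  out$flagged <- names(out)[vapply(out[1:7], function(v)
    length(v) == 1 && is.na(v), TRUE)]
  out
}

#' Exact (Clopper-Pearson) confidence interval for a proportion
#'
#' @param k successes, \code{n} trials, \code{level} confidence level.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return c(lower, upper).
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Stratified percentile bootstrap CI
#'
#' Resamples within each class independently and returns the percentile
#' interval of \code{metric_fn(scores, labels)}.
#'
#' @param metric_fn function(scores, labels) -> scalar.
#' @param scores,labels data.
#' @param B bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return c(lower, upper).
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 2000, seed = 1L,
                         level = 0.95) {
  stopifnot(B >= 100)
  labels <- as.integer(labels)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  with_seed(seed, {
    stat <- vapply(seq_len(B), function(b) {
      idx <- c(i1[sample.int(length(i1), replace = TRUE)],
               i0[sample.int(length(i0), replace = TRUE)])
      metric_fn(scores[idx], labels[idx])
    }, 0)
    a <- 1 - level
    q <- stats::quantile(stat, c(a / 2, 1 - a / 2), na.rm = TRUE, names = FALSE)
    c(lower = q[1], upper = q[2])
  })
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors on the same
#' patients, using placement-value covariance and a two-sided normal
#' approximation.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary labels.
#' @return list(auc_a, auc_b, auc_diff, var_a, var_b, z, p, degenerate).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  placements <- function(s) {
    # V10_i: fraction of negatives below positive i (ties 1/2); V01_j sym.
    sp <- s[pos]; sn <- s[neg]
    v10 <- vapply(sp, function(x) (sum(x > sn) + 0.5 * sum(x == sn)) / n, 0)
    v01 <- vapply(sn, function(x) (sum(sp > x) + 0.5 * sum(sp == x)) / m, 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  # a class with a single member contributes no covariance information
  s10 <- if (m >= 2) stats::cov(cbind(pa$v10, pb$v10)) else matrix(0, 2, 2)
  s01 <- if (n >= 2) stats::cov(cbind(pa$v01, pb$v01)) else matrix(0, 2, 2)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  z <- if (degenerate) 0 else (pa$auc - pb$auc) / sqrt(var_diff)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = pa$auc - pb$auc,
       var_a = s10[1, 1] / m + s01[1, 1] / n,
       var_b = s10[2, 2] / m + s01[2, 2] / n,
       z = z, p = p, degenerate = degenerate)
}

#' Two-sided Wilcoxon signed-rank test on paired values
#'
#' Zero differences are dropped; the exact null distribution is used for
#' up to 25 non-zero pairs without ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b paired numeric vectors.
#' @return list(W, p, n_nonzero, flagged).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(W = NA_real_, p = 1, n_nonzero = 0L, flagged = TRUE))
  if (length(d) < 5)
    warning("fewer than 5 non-zero differences; test has little power")
  use_exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = FALSE))
  list(W = unname(ht$statistic), p = ht$p.value,
       n_nonzero = length(d), flagged = FALSE)
}

#' Weighted kappa for two ordinal raters
#'
#' \eqn{\kappa_w = 1 - \sum w O / \sum w E} with linear weights
#' \eqn{w_{ij} = |i - j| / (K - 1)} (or quadratic).
#'
#' @param ratings_a,ratings_b integer ratings on 1..K.
#' @param weights "linear" (default) or "quadratic".
#' @param K number of categories (default: max observed).
#' @return kappa value; NA with a warning if both raters use a single
#'   category.
#' @export
weighted_kappa <- function(ratings_a, ratings_b, weights = c("linear", "quadratic"),
                           K = NULL) {
  weights <- match.arg(weights)
  stopifnot(length(ratings_a) == length(ratings_b))
  if (is.null(K)) K <- max(ratings_a, ratings_b)
  if (length(unique(ratings_a)) == 1 && length(unique(ratings_b)) == 1) {
    warning("both raters used a single category; kappa undefined")
    return(NA_real_)
  }
  O <- matrix(0, K, K)
  for (i in seq_along(ratings_a))
    O[ratings_a[i], ratings_b[i]] <- O[ratings_a[i], ratings_b[i]] + 1
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  w <- abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
  if (weights == "quadratic") w <- w^2
  1 - sum(w * O) / sum(w * E)
}

#' ICC(2,1): two-way random effects, absolute agreement, single rater
#'
#' @param measurements subjects x raters numeric matrix (>= 5 subjects,
#'   >= 2 raters).
#' @return icc value; flagged NA if between-subject variance is zero.
#' @export
icc_2_1 <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 5, k >= 2)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= mse && denom <= 0) {
    warning("zero between-subject variance; ICC undefined")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Decision curve analysis (net benefit)
#'
#' \eqn{NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)}, calling positive when
#' the predicted probability is at or above the threshold.  Includes the
#' treat-all and treat-none reference policies.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels binary labels.
#' @param thresholds probability grid (default 0.01..0.99 by 0.01; 1 is
#'   excluded).
#' @return object of class \code{dca_result}: thresholds,
#'   net_benefit_model, net_benefit_all, net_benefit_none.
#' @export
net_benefit_curve <- function(probs, labels,
                              thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(probs >= 0 & probs <= 1), all(thresholds < 1),
            all(thresholds > 0))
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels == 1)
  nb <- vapply(thresholds, function(pt) {
    tp <- sum(probs >= pt & labels == 1)
    fp <- sum(probs >= pt & labels == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  structure(list(thresholds = thresholds, net_benefit_model = nb,
                 net_benefit_all = nb_all,
                 net_benefit_none = rep(0, length(thresholds)),
                 prevalence = prev),
            class = "dca_result")
}

#' Diagnostics row at an operating threshold
#'
#' Computes the full Table-2-style row (sens/spec/PPV/NPV/+LR/-LR with
#' 95% CIs, AUC with CI) for one score vector at one threshold.
#' Proportion CIs are Clopper-Pearson; AUC and likelihood-ratio CIs are
#' stratified percentile bootstrap.
#'
#' @param scores model outputs.
#' @param labels binary labels.
#' @param threshold operating threshold (positive when score >=
#'   threshold); default = Youden-optimal.
#' @param B bootstrap replicates (default 2000).
#' @param seed bootstrap seed.
#' @return list of point estimates and CI pairs, plus counts.
#' @export
diagnostics_row <- function(scores, labels, threshold = NULL, B = 2000,
                            seed = 1L) {
  labels <- as.integer(labels)
  roc <- roc_auc(scores, labels)
  if (is.null(threshold)) threshold <- youden_threshold(roc)$threshold
  tp <- sum(scores >= threshold & labels == 1)
  fn <- sum(scores < threshold & labels == 1)
  tn <- sum(scores < threshold & labels == 0)
  fp <- sum(scores >= threshold & labels == 0)
  cm <- confusion_metrics(tp, fp, tn, fn)
  lr_fn <- function(which) function(s, l) {
    t <- sum(s >= threshold & l == 1); f <- sum(s < threshold & l == 1)
    tn2 <- sum(s < threshold & l == 0); fp2 <- sum(s >= threshold & l == 0)
    m <- confusion_metrics(t, fp2, tn2, f)
    m[[which]]
  }
  safe_ci <- function(k, n) if (n > 0) proportion_ci(k, n) else
    c(lower = NA_real_, upper = NA_real_)
  list(threshold = threshold,
       sensitivity = cm$sensitivity,
       sensitivity_ci = safe_ci(tp, tp + fn),
       specificity = cm$specificity,
       specificity_ci = safe_ci(tn, tn + fp),
       ppv = cm$ppv, ppv_ci = safe_ci(tp, tp + fp),
       npv = cm$npv, npv_ci = safe_ci(tn, tn + fn),
       plr = cm$plr,
       plr_ci = bootstrap_ci(lr_fn("plr"), scores, labels, B, seed),
       nlr = cm$nlr,
       nlr_ci = bootstrap_ci(lr_fn("nlr"), scores, labels, B, seed),
       auc = roc$auc,
       auc_ci = bootstrap_ci(function(s, l) univariate_auc(s, l, fold = FALSE),
                             scores, labels, B, seed),
       counts = cm$counts)
}

#' Diagnostics table for several models
#'
#' @param scores_list named list of score vectors on the same patients.
#' @param labels binary labels.
#' @param thresholds optional named thresholds (default: per-model
#'   Youden).
#' @param B,seed bootstrap parameters.
#' @return data.frame mirroring the published table layout (one row per
#'   model, formatted percentage strings plus numeric columns).
#' @export
diagnostics_table <- function(scores_list, labels, thresholds = NULL,
                              B = 2000, seed = 1L) {
  rows <- lapply(names(scores_list), function(nm) {
    thr <- if (!is.null(thresholds)) thresholds[[nm]] else NULL
    r <- diagnostics_row(scores_list[[nm]], labels, threshold = thr,
                         B = B, seed = seed)
    pct <- function(x) round(100 * x, 1)
    data.frame(model = nm,
               sensitivity = pct(r$sensitivity),
               sensitivity_lo = pct(r$sensitivity_ci[1]),
               sensitivity_hi = pct(r$sensitivity_ci[2]),
               specificity = pct(r$specificity),
               specificity_lo = pct(r$specificity_ci[1]),
               specificity_hi = pct(r$specificity_ci[2]),
               ppv = pct(r$ppv), npv = pct(r$npv),
               plr = round(r$plr, 1), nlr = round(r$nlr, 1),
               auc = round(r$auc, 2),
               auc_lo = round(r$auc_ci[1], 2), auc_hi = round(r$auc_ci[2], 2),
               threshold = r$threshold,
               tp = r$counts["tp"], fp = r$counts["fp"],
               tn = r$counts["tn"], fn = r$counts["fn"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' AFP-normal subgroup indices
#'
#' The clinically interesting subgroup: HCC patients with normal AFP
#' (band "<20") plus all FNH patients.
#'
#' @param labels binary labels.
#' @param afp_band character vector of AFP bands per patient.
#' @return integer indices of subgroup members.
#' @export
afp_normal_subset <- function(labels, afp_band) {
  which(labels == 0 | (labels == 1 & afp_band == "<20"))
}

#' Subgroup re-evaluation of already-fitted models
#'
#' Re-evaluates score vectors on a patient subgroup without refitting,
#' keeping the operating thresholds chosen on the full cohort.
#'
#' @param scores_list named list of full-cohort score vectors.
#' @param labels full-cohort labels.
#' @param subset_idx indices of the subgroup (must contain both classes).
#' @param thresholds named list of operating thresholds (from the
#'   full-cohort evaluation).
#' @param B,seed bootstrap parameters.
#' @return diagnostics table for the subgroup.
#' @export
subgroup_eval <- function(scores_list, labels, subset_idx, thresholds,
                          B = 2000, seed = 1L) {
  ls <- labels[subset_idx]
  if (length(unique(ls)) < 2) stop("subgroup does not contain both classes")
  diagnostics_table(lapply(scores_list, function(s) s[subset_idx]), ls,
                    thresholds = thresholds, B = B, seed = seed)
}

#' Baseline characteristics table with group tests
#'
#' Continuous covariates: Welch t test when both groups look approximately
#' normal (Shapiro-Wilk p > 0.05), Mann-Whitney otherwise.  Categorical
#' covariates: Pearson chi-squared unless any expected cell is below 5,
#' then Fisher's exact test.
#'
#' @param covariates data.frame of covariates (no id/label columns).
#' @param labels binary group labels.
#' @return data.frame: covariate, type, test, statistic, p.
#' @export
baseline_table <- function(covariates, labels) {
  labels <- as.integer(labels)
  rows <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    if (is.numeric(x)) {
      if (stats::sd(x) == 0)
        return(data.frame(covariate = nm, type = "continuous",
                          test = "none (constant)", statistic = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      normal <- tryCatch(
        stats::shapiro.test(x[labels == 0])$p.value > 0.05 &&
          stats::shapiro.test(x[labels == 1])$p.value > 0.05,
        error = function(e) FALSE)
      if (normal) {
        ht <- stats::t.test(x ~ labels)
        data.frame(covariate = nm, type = "continuous", test = "welch_t",
                   statistic = unname(ht$statistic), p = ht$p.value,
                   stringsAsFactors = FALSE)
      } else {
        ht <- suppressWarnings(stats::wilcox.test(x ~ labels))
        data.frame(covariate = nm, type = "continuous", test = "mann_whitney",
                   statistic = unname(ht$statistic), p = ht$p.value,
                   stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(factor(x), labels)
      if (length(unique(x)) < 2)
        return(data.frame(covariate = nm, type = "categorical",
                          test = "none (constant)", statistic = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ht <- stats::fisher.test(tab, workspace = 2e6)
        data.frame(covariate = nm, type = "categorical", test = "fisher",
                   statistic = NA_real_, p = ht$p.value,
                   stringsAsFactors = FALSE)
      } else {
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        data.frame(covariate = nm, type = "categorical", test = "chi_squared",
                   statistic = unname(ht$statistic), p = ht$p.value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
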