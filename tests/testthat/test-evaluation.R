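test_that("roc_auc matches pair counting and complement symmetry", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))$auc, 0.875)
  r <- roc_auc(c(1, 2, 2, 3), c(1, 1, 0, 0))
  expect_equal(r$auc, 1 - 0.875)
  expect_error(roc_auc(1:4, rep(0, 4)), "both classes")
})

test_that("trapezoidal ROC area equals the Mann-Whitney AUC", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, mean = y), sample(c(0, 1, 3), 1))  # induce ties
    r <- roc_auc(s, y)
    fpr <- 1 - r$specificities
    trap <- sum(diff(rev(fpr)) * (rev(r$sensitivities)[-1] +
                                    rev(r$sensitivities)[-length(fpr)]) / 2)
    expect_lt(abs(trap - r$auc), 1e-10)
  }
})

test_that("youden_threshold maximizes J and recovers planted cutoffs", {
  r <- roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))
  yt <- youden_threshold(r)
  expect_equal(yt$youden, 1.0)
  expect_gt(yt$threshold, 2); expect_lte(yt$threshold, 10)

  set.seed(8)
  n <- 1000
  y <- rbinom(n, 1, 0.5)
  s <- y + rnorm(n, sd = 0.1)
  yt2 <- youden_threshold(roc_auc(s, y))
  expect_gt(yt2$sensitivity, 0.95)
  expect_gt(yt2$specificity, 0.95)

  # random scores: Youden index stays near zero
  yt3 <- youden_threshold(roc_auc(rnorm(n), y))
  expect_lt(yt3$youden, 0.15)
})

test_that("confusion metrics reproduce the published arithmetic", {
  # 83 correct FNH / 36 false positives: 83/119 = 69.7479..., i.e. 69.7%
  # to one decimal (the published table prints 69.8, a rounding slip of
  # 0.05; see the decisions ledger)
  expect_equal(round(100 * confusion_metrics(0, 36, 83, 0)$specificity, 1),
               69.7)
  expect_lt(abs(confusion_metrics(0, 36, 83, 0)$specificity - 0.698), 0.001)
  # 100 correct FNH / 19 false positives -> specificity 84.0%
  expect_equal(round(100 * confusion_metrics(0, 19, 100, 0)$specificity, 1),
               84.0)
  # radiologist column: tp = 101, fn = 6 (sens 94.4% of 107), fp = 36,
  # tn = 83 -> PPV 73.7, NPV 93.3, +LR 3.1, -LR 0.1
  cm <- confusion_metrics(101, 36, 83, 6)
  expect_equal(round(100 * cm$sensitivity, 1), 94.4)
  expect_equal(round(100 * cm$ppv, 1), 73.7)
  expect_equal(round(100 * cm$npv, 1), 93.3)
  expect_equal(round(cm$plr, 1), 3.1)
  expect_equal(round(cm$nlr, 1), 0.1)

  # zero denominators are flagged, not silently zero
  cm0 <- confusion_metrics(0, 0, 5, 5)
  expect_true("ppv" %in% cm0$flagged)
  expect_true(is.na(cm0$ppv))
})

test_that("Clopper-Pearson intervals match closed forms", {
  expect_equal(unname(proportion_ci(10, 10)["upper"]), 1.0)
  ci0 <- proportion_ci(0, 10)
  expect_equal(unname(ci0["lower"]), 0)
  expect_equal(unname(ci0["upper"]), 1 - 0.025^(1 / 10), tolerance = 1e-10)
  expect_error(proportion_ci(3, 0))
})

test_that("bootstrap CI degenerates on perfectly separated data", {
  s <- c(1, 2, 3, 10, 11, 12); y <- rep(c(0, 1), each = 3)
  ci <- bootstrap_ci(function(sc, l) univariate_auc(sc, l, fold = FALSE),
                     s, y, B = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))
})

test_that("DeLong test: identity, rank invariance, bootstrap agreement", {
  set.seed(17)
  y <- rep(c(0, 1), each = 30)
  a <- rnorm(60) + y
  d0 <- delong_test(a, a, y)
  expect_equal(d0$z, 0); expect_equal(d0$p, 1)
  expect_true(d0$degenerate)

  # monotone transform changes nothing
  d1 <- delong_test(a, exp(a) + 5, y)
  expect_equal(d1$auc_a, d1$auc_b)
  expect_equal(d1$p, 1)

  # DeLong variance close to the bootstrap variance of the AUC
  ok <- 0
  for (rep in 1:10) {
    set.seed(100 + rep)
    yv <- rep(c(0, 1), each = 30)
    s <- rnorm(60) + 0.8 * yv
    dv <- delong_test(s, rnorm(60) + 0.5 * yv, yv)$var_a
    bs <- with(list(i1 = which(yv == 1), i0 = which(yv == 0)), {
      stats <- vapply(1:2000, function(b) {
        idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
        univariate_auc(s[idx], yv[idx], fold = FALSE)
      }, 0)
      stats::var(stats)
    })
    if (abs(dv - bs) / bs < 0.15) ok <- ok + 1
  }
  expect_gte(ok, 8)  # agreement within 15% in the large majority
})

test_that("Wilcoxon signed-rank matches exact enumeration", {
  expect_equal(wilcoxon_signed_rank(1:6, 1:6)$p, 1)  # all-zero differences
  # five all-positive differences: two-sided exact p = 2/32
  r <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(r$p, 1 / 16)
  # invariant to pair order permutation
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12)
  o <- sample(12)
  expect_equal(wilcoxon_signed_rank(a, b)$p,
               wilcoxon_signed_rank(a[o], b[o])$p)
})

test_that("weighted kappa matches hand computation and the null", {
  expect_equal(weighted_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)
  a <- c(rep(1, 50), rep(2, 50))
  b <- c(rep(1, 45), rep(2, 5), rep(1, 5), rep(2, 45))
  expect_equal(weighted_kappa(a, b, K = 2), 0.8)
  set.seed(6)
  ra <- sample(1:3, 500, TRUE); rb <- sample(1:3, 500, TRUE)
  expect_lt(abs(weighted_kappa(ra, rb)), 0.1)
  expect_warning(weighted_kappa(rep(1, 10), rep(1, 10)), "single category")
})

test_that("ICC(2,1) matches the variance-component closed form", {
  m <- cbind(1:10, 1:10)
  expect_equal(icc_2_1(m), 1)

  # rater2 = rater1 + bias: with two raters the ANOVA rater-variance
  # component is (sample variance of the rater effects, divisor k - 1) =
  # bias^2 / 2, so population ICC = tau^2/(tau^2 + bias^2/2 + s^2)
  set.seed(9)
  n <- 2000; tau <- 5; s <- 1; bias <- 3
  subj <- rnorm(n, sd = tau)
  mm <- cbind(subj + rnorm(n, sd = s), subj + bias + rnorm(n, sd = s))
  pop <- tau^2 / (tau^2 + bias^2 / 2 + s^2)
  expect_lt(abs(icc_2_1(mm) - pop), 0.02)
  expect_lt(icc_2_1(mm), 1)

  # independent raters: ICC near zero
  mi <- cbind(rnorm(50), rnorm(50))
  expect_lt(abs(icc_2_1(mi)), 0.15)
})

test_that("net benefit matches the worked example and its envelopes", {
  # 10 patients, 5 diseased; classifier flags the 5 diseased + 1 healthy
  probs <- c(rep(0.9, 5), 0.9, rep(0.05, 4))
  labs <- c(rep(1, 5), rep(0, 5))
  nb <- net_benefit_curve(probs, labs, thresholds = 0.2)
  expect_equal(nb$net_benefit_model, 5 / 10 - (1 / 10) * (0.2 / 0.8))
  expect_true(all(nb$net_benefit_none == 0))
  # treat-all at pt = prevalence = 0.5 is zero
  nb2 <- net_benefit_curve(probs, labs, thresholds = 0.5)
  expect_equal(nb2$net_benefit_all, 0)

  # model curve never exceeds the perfect-classifier envelope
  set.seed(10)
  y <- rbinom(300, 1, 0.4)
  p <- plogis(rnorm(300) + y)
  d <- net_benefit_curve(p, y)
  expect_true(all(d$net_benefit_model <= d$prevalence + 1e-12))
  # random classifier stays near max(0, treat-all)
  pr <- runif(300)
  dr <- net_benefit_curve(pr, y)
  expect_true(all(dr$net_benefit_model <=
                    pmax(0, dr$net_benefit_all) + 0.1))
})

test_that("diagnostics rows/tables assemble consistent Table-2-style output", {
  set.seed(23)
  y <- rep(c(0, 1), each = 60)
  s1 <- rnorm(120) + 1.5 * y
  s2 <- rnorm(120) + 0.8 * y
  tab <- diagnostics_table(list(a = s1, b = s2), y, B = 200, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("sensitivity", "specificity", "ppv", "npv", "plr",
                    "nlr", "auc") %in% names(tab)))
  # internal consistency of the reported counts and percentages
  expect_equal(tab$sensitivity,
               round(100 * tab$tp / (tab$tp + tab$fn), 1))
  expect_equal(tab$specificity,
               round(100 * tab$tn / (tab$tn + tab$fp), 1))
  expect_gt(tab$auc[tab$model == "a"], tab$auc[tab$model == "b"])
})

test_that("subgroup evaluation matches Bayes arithmetic and the identity case", {
  set.seed(29)
  y <- rep(c(0, 1), each = 80)
  s <- rnorm(160) + 1.2 * y
  tab_full <- diagnostics_table(list(m = s), y, B = 200, seed = 3)
  thr <- list(m = tab_full$threshold[1])
  # predicate selecting everyone reproduces the full table
  tab_all <- subgroup_eval(list(m = s), y, seq_along(y), thr, B = 200,
                           seed = 3)
  expect_equal(tab_all, tab_full)

  # lower-prevalence subgroup: PPV drops for the same operating point
  sub <- c(which(y == 0), which(y == 1)[1:20])
  tab_sub <- subgroup_eval(list(m = s), y, sub, thr, B = 200, seed = 3)
  expect_lt(tab_sub$ppv[1], tab_full$ppv[1])
  sens <- tab_sub$sensitivity[1] / 100; spec <- tab_sub$specificity[1] / 100
  pi_sub <- mean(y[sub])
  ppv_bayes <- sens * pi_sub / (sens * pi_sub + (1 - spec) * (1 - pi_sub))
  expect_lt(abs(tab_sub$ppv[1] / 100 - ppv_bayes), 0.01)

  expect_error(subgroup_eval(list(m = s), y, which(y == 0), thr), "both classes")
})

test_that("afp_normal_subset picks FNH plus AFP-normal HCC", {
  y <- c(0, 0, 1, 1, 1)
  afp <- c(">400", "<20", "<20", "20-400", "<20")
  expect_equal(afp_normal_subset(y, afp), c(1L, 2L, 3L, 5L))
})

test_that("baseline_table chooses tests sensibly", {
  set.seed(35)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  cov <- data.frame(
    gauss_shift = rnorm(n, mean = 3 * y),          # huge effect, normal
    skewed = exp(rnorm(n)),                        # non-normal, no effect
    cat_bal = rep(c("a", "b"), n / 2),             # identical in both groups
    cat_rare = c(rep("x", n - 3), "y", "y", "y"))  # sparse -> Fisher
  bt <- baseline_table(cov, y)
  expect_equal(bt$test[bt$covariate == "gauss_shift"], "welch_t")
  expect_lt(bt$p[bt$covariate == "gauss_shift"], 1e-10)
  expect_equal(bt$test[bt$covariate == "skewed"], "mann_whitney")
  expect_equal(bt$test[bt$covariate == "cat_rare"], "fisher")
  expect_equal(bt$p[bt$covariate == "cat_bal"], 1)
})
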