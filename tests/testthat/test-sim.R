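test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_fnh = 0))
  expect_error(sim_config(reader_grade_probs = list(fnh = c(0.5, 0.5, 0.5),
                                                    hcc = c(0, 0, 1))),
               "summing to 1")
  expect_error(sim_config(noise_sd = -1))
})

test_that("lesion images are deterministic and respect the noiseless limit", {
  cfg <- sim_config()
  a <- simulate_lesion_image(1, "arterial", cfg, seed = 5)
  b <- simulate_lesion_image(1, "arterial", cfg, seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$roi_polygon, b$roi_polygon)
  expect_false(identical(
    a$pixels, simulate_lesion_image(1, "arterial", cfg, seed = 6)$pixels))

  # noiseless homogeneous limit: constant interior
  cfg0 <- sim_config(noise_sd = 0, texture_contrast_gap = 0)
  im <- simulate_lesion_image(0, "arterial", cfg0, seed = 3)
  expect_equal(stats::var(im$pixels[im$mask]), 0)
  expect_equal(unique(as.vector(im$pixels[im$mask])),
               unname(cfg0$enhancement_means["fnh", "arterial"]))

  # oversized lesion axes are rejected
  expect_error(simulate_lesion_image(0, "baseline",
                                     sim_config(lesion_axes_range = c(60, 80)),
                                     seed = 1),
               "exceed image bounds")
})

test_that("arterial phase is hyper-enhanced relative to baseline", {
  cfg <- sim_config()
  for (lbl in 0:1) {
    bl <- simulate_lesion_image(lbl, "baseline", cfg, seed = 7 + lbl)
    ap <- simulate_lesion_image(lbl, "arterial", cfg, seed = 107 + lbl)
    expect_gt(mean(ap$pixels[ap$mask]), mean(bl$pixels[bl$mask]))
  }
})

test_that("HCC interiors have higher d=1 GLCM contrast than FNH", {
  # scaled-down Monte Carlo version of the 200-vs-200 contract (n = 60
  # per class keeps runtime modest; the test statistic is far from the
  # boundary)
  cfg <- sim_config()
  contrast1 <- function(lbl, seed) {
    im <- simulate_lesion_image(lbl, "arterial", cfg, seed = seed)
    q <- quantize(im$pixels, im$mask, 32)
    glcm_features(compute_glcm(q, 1, 0))[["glcm_contrast"]]
  }
  cf <- vapply(1:60, function(s) contrast1(0, s), 0)
  ch <- vapply(1:60, function(s) contrast1(1, 5000 + s), 0)
  expect_gt(mean(ch), mean(cf))
  expect_lt(stats::wilcox.test(ch, cf, alternative = "greater")$p.value, 0.01)
})

test_that("class separation in within-ROI variance is monotone in the gap", {
  roi_var <- function(gap, lbl, seed) {
    cfg <- sim_config(texture_contrast_gap = gap)
    im <- simulate_lesion_image(lbl, "portal", cfg, seed = seed)
    stats::var(im$pixels[im$mask])
  }
  gaps <- c(0, 1, 2)
  sep <- vapply(gaps, function(g) {
    vf <- mean(vapply(1:12, function(s) roi_var(g, 0, s), 0))
    vh <- mean(vapply(1:12, function(s) roi_var(g, 1, 900 + s), 0))
    vh - vf
  }, 0)
  expect_true(all(diff(sep) > -1))  # non-decreasing up to Monte Carlo noise
  expect_gt(sep[3], sep[1])
})

test_that("reader scores follow the class grade distributions", {
  labels <- c(rep(0, 10), rep(1, 10))
  s <- simulate_reader_scores(labels, list(fnh = c(1, 0, 0),
                                           hcc = c(0, 0, 1)), seed = 1)
  expect_true(all(s[labels == 0] == 1))
  expect_true(all(s[labels == 1] == 3))
  expect_equal(univariate_auc(s, labels, fold = FALSE), 1.0)
  expect_identical(s, simulate_reader_scores(labels,
                                             list(fnh = c(1, 0, 0),
                                                  hcc = c(0, 0, 1)), seed = 1))
  expect_error(simulate_reader_scores(labels, list(fnh = c(0.5, 0.5),
                                                   hcc = c(0, 0, 1))),
               "triple")
})

test_that("mean score-only AUC matches its closed form", {
  # closed form sum_g sum_{h>g} pF(g) pH(h) + 1/2 sum_g pF(g) pH(g),
  # recomputed independently here = 0.8775 for the default triples
  pf <- c(0.65, 0.20, 0.15); ph <- c(0.05, 0.10, 0.85)
  closed <- 0
  for (g in 1:3) for (h in 1:3)
    closed <- closed + pf[g] * ph[h] * (if (h > g) 1 else if (h == g) 0.5 else 0)
  expect_equal(closed, 0.8775)

  labels <- c(rep(0, 119), rep(1, 107))
  probs <- list(fnh = pf, hcc = ph)
  aucs <- vapply(1:500, function(r) {
    s <- simulate_reader_scores(labels, probs, seed = 10000 + r)
    univariate_auc(s, labels, fold = FALSE)
  }, 0)
  expect_lt(abs(mean(aucs) - closed), 0.03)
})

test_that("simulate_cohort assembles the stated cohort", {
  cfg <- sim_config(seed = 2)
  co <- simulate_cohort(cfg, images = FALSE)
  y <- cohort_labels(co)
  expect_length(y, 226)
  expect_equal(sum(y == 0), 119)
  expect_equal(sum(y == 1), 107)

  tiny <- simulate_cohort(sim_config(n_fnh = 1, n_hcc = 1, seed = 3),
                          images = FALSE)
  expect_equal(sort(cohort_labels(tiny)), c(0L, 1L))

  # covariate marginals: AFP "<20" among simulated HCC ~ 35.5%
  big <- simulate_cohort(sim_config(n_fnh = 1, n_hcc = 1000, seed = 4),
                         images = FALSE)
  cov <- cohort_covariates(big)
  frac <- mean(cov$afp_band[cov$label == 1] == "<20")
  expect_lt(abs(frac - 0.355), 0.04)
})

test_that("cohorts are byte-identical given (cfg, seed) and images validate", {
  cfg <- sim_config(n_fnh = 3, n_hcc = 3, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  for (p in c1$patients) {
    expect_length(p$triplet, 3)
    expect_identical(vapply(p$triplet, function(im) im$phase, ""),
                     c("baseline", "arterial", "portal"))
    for (im in p$triplet) expect_gte(sum(im$mask), 16)
    expect_true(p$reader_score %in% 1:3)
  }
  # different master seed changes the images
  c3 <- simulate_cohort(sim_config(n_fnh = 3, n_hcc = 3, seed = 10))
  expect_false(identical(c1$patients[[1]]$triplet[[1]]$pixels,
                         c3$patients[[1]]$triplet[[1]]$pixels))
})

test_that("cohort round-trips through the directory layout", {
  cfg <- sim_config(n_fnh = 2, n_hcc = 2, image_size = c(64, 64),
                    lesion_axes_range = c(10, 18), seed = 31)
  co <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir, format = "pgm")
  expect_true(file.exists(file.path(dir, "patients.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- read_cohort(dir)
  expect_equal(cohort_labels(back), cohort_labels(co))
  expect_equal(cohort_scores(back), cohort_scores(co))
  # PGM stores rounded intensities; masks must match exactly
  p1 <- co$patients[[1]]$triplet[[2]]
  p2 <- back$patients[[1]]$triplet[[2]]
  expect_identical(p1$mask, p2$mask)
  expect_lt(max(abs(p1$pixels - p2$pixels)), 0.5 + 1e-9)
  unlink(dir, recursive = TRUE)
})
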