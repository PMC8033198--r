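# Synthetic three-phase CEUS cohort generator.  The generator emulates the
# statistical structure the downstream analysis assumes: a two-class cohort
# (benign FNH vs atypical HCC), class-dependent lesion texture and
# enhancement in the baseline/arterial/portal phases, ordinal reader scores
# stochastically concordant with class, and clinical covariates drawn from
# the published cohort marginals.  It makes no attempt at acoustic or
# speckle physics; its purpose is to make every pipeline stage testable.

#' Simulation configuration
#'
#' Defaults encode the reference cohort: 119 FNH and 107 HCC patients,
#' 128 x 128 images, arterial-phase hyper-enhancement in both classes,
#' homogeneous FNH interiors vs patchy heterogeneous HCC interiors, reader
#' grade distributions giving a score-only AUC of about 0.89, and
#' covariate marginals matching the published baseline table.
#'
#' @param n_fnh,n_hcc class sizes (>= 1).
#' @param image_size c(rows, cols) in pixels.
#' @param lesion_axes_range range of lesion semi-axes in pixels.
#' @param texture_contrast_gap dimensionless effect size scaling every
#'   class-dependent texture component; 0 gives texture-free lesions.
#' @param enhancement_means 2 x 3 matrix (rows FNH, HCC; columns baseline,
#'   arterial, portal) of mean interior intensity on the 0-255 scale.
#' @param noise_sd additive Gaussian pixel noise SD (intensity units, > 0
#'   for realistic images; 0 is allowed for degenerate tests).
#' @param reader_grade_probs list with elements \code{fnh} and \code{hcc},
#'   each a probability triple over grades 1 (FNH-like), 2 (indeterminate),
#'   3 (HCC-like).
#' @param covariate_marginals per-class covariate parameters; see
#'   [default_covariate_marginals()].
#' @param seed master seed; all randomness derives from it via per-patient
#'   sub-seeds.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_fnh = 119L, n_hcc = 107L,
                       image_size = c(128L, 128L),
                       lesion_axes_range = c(18, 40),
                       texture_contrast_gap = 1.0,
                       enhancement_means = rbind(fnh = c(90, 180, 160),
                                                 hcc = c(90, 170, 150)),
                       noise_sd = 4,
                       reader_grade_probs = list(fnh = c(0.65, 0.20, 0.15),
                                                 hcc = c(0.05, 0.10, 0.85)),
                       covariate_marginals = default_covariate_marginals(),
                       seed = 1L) {
  stopifnot(n_fnh >= 1, n_hcc >= 1, length(image_size) == 2,
            all(image_size >= 32), length(lesion_axes_range) == 2,
            lesion_axes_range[1] <= lesion_axes_range[2],
            lesion_axes_range[1] >= 3,
            texture_contrast_gap >= 0, noise_sd >= 0,
            is.matrix(enhancement_means), nrow(enhancement_means) == 2,
            ncol(enhancement_means) == 3)
  for (cls in c("fnh", "hcc")) {
    p <- reader_grade_probs[[cls]]
    if (length(p) != 3 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stop("reader_grade_probs$", cls,
           " must be a probability triple summing to 1")
  }
  dimnames(enhancement_means) <- list(c("fnh", "hcc"),
                                      c("baseline", "arterial", "portal"))
  structure(list(n_fnh = as.integer(n_fnh), n_hcc = as.integer(n_hcc),
                 image_size = as.integer(image_size),
                 lesion_axes_range = lesion_axes_range,
                 texture_contrast_gap = texture_contrast_gap,
                 enhancement_means = enhancement_means,
                 noise_sd = noise_sd,
                 reader_grade_probs = reader_grade_probs,
                 covariate_marginals = covariate_marginals,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Null (no-signal) simulation configuration
#'
#' Convenience wrapper: no texture gap, identical enhancement means and
#' reader grade distributions across classes.  An end-to-end pipeline run
#' on such a cohort should perform at chance level.
#'
#' @param ... passed to [sim_config()] (e.g. n_fnh, n_hcc, seed).
#' @export
null_sim_config <- function(...) {
  sim_config(texture_contrast_gap = 0,
             enhancement_means = rbind(fnh = c(90, 180, 160),
                                       hcc = c(90, 180, 160)),
             reader_grade_probs = list(fnh = c(1, 1, 1) / 3,
                                       hcc = c(1, 1, 1) / 3),
             ...)
}

#' Default per-class covariate marginals
#'
#' Categorical probabilities and continuous moments per class, matching
#' the published baseline characteristics of the 119 FNH / 107 aHCC
#' cohort (gender, age, hepatitis serology bands, AFP bands, tumor number,
#' tumor size).
#'
#' @return nested list: \code{$fnh} and \code{$hcc}.
#' @export
default_covariate_marginals <- function() {
  list(
    fnh = list(
      p_male = 61 / 119,
      age_mean = 34.5, age_sd = 11.7,
      hbsag = c("<=0.05" = 116, "0.05-250" = 1, ">250" = 2) / 119,
      hbvdna = c("<100" = 118, "100-1e5" = 0, ">1e5" = 1) / 119,
      hcvab = c("<1.0" = 119, ">=1.0" = 0) / 119,
      afp = c("<20" = 117, "20-400" = 2, ">400" = 0) / 119,
      tumor_number = c("1" = 112, "2" = 4, ">=3" = 3) / 119,
      size_mean = 3.34, size_sd = 1.80),
    hcc = list(
      p_male = 92 / 107,
      age_mean = 54.0, age_sd = 11.9,
      hbsag = c("<=0.05" = 15, "0.05-250" = 34, ">250" = 58) / 107,
      hbvdna = c("<100" = 46, "100-1e5" = 44, ">1e5" = 17) / 107,
      hcvab = c("<1.0" = 105, ">=1.0" = 2) / 107,
      afp = c("<20" = 38, "20-400" = 40, ">400" = 29) / 107,
      tumor_number = c("1" = 92, "2" = 8, ">=3" = 7) / 107,
      size_mean = 4.76, size_sd = 3.35)
  )
}

# run `expr` under a local Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister")
  expr
}

# deterministic sub-seed derivation: patient i (1-based), stream k
sub_seed <- function(master, i, k = 0L) {
  (as.numeric(master) * 100003 + as.numeric(i) * 613 + as.numeric(k)) %%
    2147483629
}

# isotropic Gaussian random field: white noise smoothed by a separable
# Gaussian kernel (circular convolution), rescaled to unit empirical SD
smooth_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv_circ <- function(v) as.numeric(stats::filter(v, k, circular = TRUE))
  z <- apply(z, 2, conv_circ)
  z <- t(apply(z, 1, conv_circ))
  s <- stats::sd(as.vector(z))
  if (s > 0) z / s else z
}

#' Simulate one lesion image with its ROI
#'
#' Draws an elliptical lesion on a speckled background.  The interior
#' intensity distribution depends on (class, phase): FNH interiors are a
#' smooth, long-correlation-length Gaussian field (homogeneous); HCC
#' interiors add a binary bright/dark patch mixture (heterogeneous, higher
#' GLCM contrast).  Arterial-phase mean intensity exceeds baseline for
#' both classes under the default configuration.  The ROI polygon has 36
#' vertices on the ellipse with small inward radial jitter, so the mask is
#' contained in the lesion interior.  Generation is a pure function of
#' (arguments, seed).
#'
#' @param class_label 0 = FNH, 1 = HCC.
#' @param phase "baseline", "arterial" or "portal".
#' @param cfg a [sim_config()].
#' @param seed integer seed for this image.
#' @return an [image_roi()].
#' @export
simulate_lesion_image <- function(class_label,
                                  phase = c("baseline", "arterial", "portal"),
                                  cfg = sim_config(), seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(class_label %in% c(0, 1))
  cls <- if (class_label == 1) "hcc" else "fnh"
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  if (cfg$lesion_axes_range[2] > min(nr, nc) / 2 - 4)
    stop("lesion axes exceed image bounds: max semi-axis ",
         cfg$lesion_axes_range[2], " for a ", nr, "x", nc, " image")
  gap <- cfg$texture_contrast_gap
  mu <- cfg$enhancement_means[cls, phase]

  with_seed(seed, {
    ax <- stats::runif(2, cfg$lesion_axes_range[1], cfg$lesion_axes_range[2])
    theta <- stats::runif(1, 0, pi)
    cx <- nc / 2 + stats::runif(1, -3, 3)
    cy <- nr / 2 + stats::runif(1, -3, 3)

    # background: dim tissue speckle
    img <- matrix(60, nr, nc) + smooth_field(nr, nc, 1.5) * cfg$noise_sd

    # elliptical interior membership for every pixel centre
    xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
    xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
    yr <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
    inside <- (xr / ax[1])^2 + (yr / ax[2])^2 <= 1

    # FNH: smooth long-correlation field only (homogeneous interior).
    # HCC: same smooth component plus a fine-grained bright/dark patch
    # mixture; the short correlation length puts the heterogeneity at the
    # pixel scale, where the GLCM (d = 1) sees it even after ROI-relative
    # min-max quantization.
    interior <- matrix(mu, nr, nc) + smooth_field(nr, nc, 6) * (4 * gap)
    if (cls == "hcc") {
      patches <- smooth_field(nr, nc, 1.2) > 0
      interior <- interior + ifelse(patches, 20 * gap, -20 * gap)
    }
    img[inside] <- interior[inside]
    img <- img + matrix(stats::rnorm(nr * nc), nr, nc) * cfg$noise_sd
    img <- pmin(pmax(img, 0), 255)

    # 36-vertex polygon on the ellipse, small inward radial jitter
    ang <- seq(0, 2 * pi, length.out = 37)[-37]
    shrink <- 1 - stats::runif(36, 0.005, 0.04)
    px <- cx + ax[1] * shrink * cos(ang) * cos(theta) -
      ax[2] * shrink * sin(ang) * sin(theta)
    py <- cy + ax[1] * shrink * cos(ang) * sin(theta) +
      ax[2] * shrink * sin(ang) * cos(theta)
    image_roi(img, cbind(x = px, y = py), phase = phase)
  })
}

#' Simulate reader scores concordant with class
#'
#' Each patient's ordinal grade (1, 2, 3) is drawn independently from the
#' grade distribution of its class.
#'
#' @param labels binary vector (0 = FNH, 1 = HCC).
#' @param grade_probs list with \code{fnh} and \code{hcc} probability
#'   triples.
#' @param seed integer seed.
#' @return integer vector of grades in {1, 2, 3}.
#' @export
simulate_reader_scores <- function(labels, grade_probs, seed = 1L) {
  for (cls in c("fnh", "hcc")) {
    p <- grade_probs[[cls]]
    if (is.null(p) || length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("grade_probs$", cls, " must be a probability triple summing to 1")
  }
  with_seed(seed, {
    vapply(labels, function(l) {
      p <- if (l == 1) grade_probs$hcc else grade_probs$fnh
      sample.int(3L, 1L, prob = p)
    }, integer(1))
  })
}

# expected AUC of the score-only classifier given two discrete grade
# distributions (ties count 1/2)
expected_score_auc <- function(p_fnh, p_hcc) {
  a <- 0
  for (g in 1:3) for (h in 1:3) {
    if (h > g) a <- a + p_fnh[g] * p_hcc[h]
    if (h == g) a <- a + 0.5 * p_fnh[g] * p_hcc[h]
  }
  a
}

.sample_cat <- function(probs) {
  names(probs)[sample.int(length(probs), 1L, prob = probs)]
}

#' Simulate a full synthetic cohort
#'
#' Assembles \code{n_fnh + n_hcc} patients: three-phase image triplets,
#' reader scores, and clinical covariates drawn from the per-class
#' marginals.  All randomness derives from \code{cfg$seed} through
#' documented per-patient sub-seeds, so regeneration is stable.
#'
#' @param cfg a [sim_config()].
#' @param images if FALSE, skip image synthesis (labels/scores/covariates
#'   only; useful for statistical tests that do not touch pixels).
#' @return object of class \code{ceus_cohort}: list with \code{patients}
#'   (each with id, label, triplet, reader_score, covariates) and
#'   \code{config}.
#' @export
simulate_cohort <- function(cfg = sim_config(), images = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_fnh + cfg$n_hcc
  labels <- c(rep(0L, cfg$n_fnh), rep(1L, cfg$n_hcc))
  scores <- simulate_reader_scores(labels, cfg$reader_grade_probs,
                                   seed = sub_seed(cfg$seed, 0L, 7L))
  phases <- c("baseline", "arterial", "portal")
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (labels[i] == 1) "hcc" else "fnh"
    m <- cfg$covariate_marginals[[cls]]
    cov <- with_seed(sub_seed(cfg$seed, i, 5L), {
      lm2 <- log(m$size_mean^2 / sqrt(m$size_mean^2 + m$size_sd^2))
      ls2 <- sqrt(log(1 + m$size_sd^2 / m$size_mean^2))
      list(age = round(max(18, min(85, stats::rnorm(1, m$age_mean, m$age_sd)))),
           gender = if (stats::runif(1) < m$p_male) "male" else "female",
           hbsag_band = .sample_cat(m$hbsag),
           hbvdna_band = .sample_cat(m$hbvdna),
           hcvab_band = .sample_cat(m$hcvab),
           afp_band = .sample_cat(m$afp),
           tumor_number = .sample_cat(m$tumor_number),
           tumor_size = round(min(18.6, max(0.8, stats::rlnorm(1, lm2, ls2))), 1))
    })
    triplet <- NULL
    if (images) {
      triplet <- lapply(seq_along(phases), function(k)
        simulate_lesion_image(labels[i], phases[k], cfg,
                              seed = sub_seed(cfg$seed, i, k)))
    }
    patients[[i]] <- structure(
      list(id = sprintf("P%04d", i), label = labels[i], triplet = triplet,
           reader_score = scores[i], covariates = cov),
      class = "synthetic_patient")
  }
  structure(list(patients = patients, config = cfg), class = "ceus_cohort")
}

#' @export
print.ceus_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  seed <- if (!is.null(x$config$seed)) x$config$seed else NA
  cat(sprintf("<ceus_cohort> %d patients (%d FNH, %d HCC), seed %s\n",
              length(lab), sum(lab == 0), sum(lab == 1), seed))
  invisible(x)
}

#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$patients, function(p) p$label, integer(1))
}

#' @export
cohort_scores <- function(cohort) {
  vapply(cohort$patients, function(p) p$reader_score, integer(1))
}

#' Covariate table of a cohort
#'
#' @param cohort a \code{ceus_cohort}.
#' @return data.frame with one row per patient (id, label, reader_score,
#'   clinical covariates).
#' @export
cohort_covariates <- function(cohort) {
  rows <- lapply(cohort$patients, function(p)
    data.frame(id = p$id, label = p$label, reader_score = p$reader_score,
               as.data.frame(p$covariates, stringsAsFactors = FALSE),
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Extract the feature matrix of a whole cohort
#'
#' @param cohort a \code{ceus_cohort} with images.
#' @param catalogue optional [feature_catalogue()].
#' @param verbose print progress every 25 patients.
#' @return numeric matrix, patients x features, rownames = patient ids.
#' @export
extract_cohort_features <- function(cohort, catalogue = NULL, verbose = FALSE) {
  if (is.null(catalogue)) catalogue <- default_catalogue()
  n <- length(cohort$patients)
  res <- matrix(NA_real_, n, 3L * nrow(catalogue$entries))
  rownames(res) <- vapply(cohort$patients, function(p) p$id, "")
  for (i in seq_len(n)) {
    v <- extract_features(cohort$patients[[i]]$triplet, catalogue)
    if (i == 1) colnames(res) <- names(v)
    res[i, ] <- v
    if (verbose && i %% 25 == 0) message("  extracted ", i, "/", n)
  }
  res
}

## ---- on-disk cohort interchange ---------------------------------------

#' Write a cohort to a directory
#'
#' Layout: one grayscale image per phase per patient
#' (\code{<id>_<phase>.png} 8-bit, or \code{.pgm} plain text), ROI polygons
#' in \code{rois.csv} (patient_id, phase, vertex_index, x, y; 0-based pixel
#' coordinates, x = column), labels/scores/covariates in
#' \code{patients.csv}, and a JSON sidecar \code{config.json} recording the
#' simulation configuration and seed.
#'
#' @param cohort a \code{ceus_cohort} with images.
#' @param dir output directory (created if needed).
#' @param format "png" or "pgm".
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("png", "pgm")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roi_rows <- list()
  for (p in cohort$patients) {
    for (im in p$triplet) {
      fn <- file.path(dir, paste0(p$id, "_", im$phase, ".", format))
      if (format == "png") {
        png::writePNG(round(im$pixels) / 255, fn)
      } else {
        write_image_pgm(im$pixels, fn)
      }
      roi_rows[[length(roi_rows) + 1]] <- data.frame(
        patient_id = p$id, phase = im$phase,
        vertex_index = seq_len(nrow(im$roi_polygon)) - 1L,
        x = im$roi_polygon[, 1], y = im$roi_polygon[, 2])
    }
  }
  utils::write.csv(do.call(rbind, roi_rows), file.path(dir, "rois.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_covariates(cohort), file.path(dir, "patients.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg_json <- list(n_fnh = cfg$n_fnh, n_hcc = cfg$n_hcc,
                   image_size = cfg$image_size,
                   lesion_axes_range = cfg$lesion_axes_range,
                   texture_contrast_gap = cfg$texture_contrast_gap,
                   enhancement_means = as.data.frame(cfg$enhancement_means),
                   noise_sd = cfg$noise_sd,
                   reader_grade_probs = cfg$reader_grade_probs,
                   seed = cfg$seed)
  jsonlite::write_json(cfg_json, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Also accepts externally assembled directories with the same layout
#' (images + rois.csv + patients.csv); \code{config.json} is optional.
#'
#' @param dir directory path.
#' @return a \code{ceus_cohort} (config NULL when no sidecar present).
#' @export
read_cohort <- function(dir) {
  pat <- utils::read.csv(file.path(dir, "patients.csv"),
                         stringsAsFactors = FALSE)
  rois <- utils::read.csv(file.path(dir, "rois.csv"), stringsAsFactors = FALSE)
  patients <- lapply(seq_len(nrow(pat)), function(i) {
    id <- pat$id[i]
    triplet <- lapply(c("baseline", "arterial", "portal"), function(ph) {
      base <- file.path(dir, paste0(id, "_", ph))
      fn <- if (file.exists(paste0(base, ".png"))) paste0(base, ".png")
            else if (file.exists(paste0(base, ".pgm"))) paste0(base, ".pgm")
            else stop("missing image for ", id, " phase ", ph)
      img <- read_image(fn)
      rr <- rois[rois$patient_id == id & rois$phase == ph, ]
      rr <- rr[order(rr$vertex_index), ]
      image_roi(img, cbind(x = rr$x, y = rr$y), phase = ph)
    })
    cov_cols <- setdiff(names(pat), c("id", "label", "reader_score"))
    structure(list(id = id, label = as.integer(pat$label[i]),
                   triplet = triplet,
                   reader_score = as.integer(pat$reader_score[i]),
                   covariates = as.list(pat[i, cov_cols])),
              class = "synthetic_patient")
  })
  cfg <- NULL
  if (file.exists(file.path(dir, "config.json")))
    cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  structure(list(patients = patients, config = cfg), class = "ceus_cohort")
}
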