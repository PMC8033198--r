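# Texture feature families.  The per-image catalogue is composed of five
# families -- histogram (42), form factor (12), gradient texture (18),
# grey-level co-occurrence (780) and run-length (192) -- for a total of
# 1,044 features per image and 3,132 per three-phase patient triplet.
# Percentiles use linear interpolation between order statistics
# (stats::quantile type 7); moments are population moments (divide by n);
# all entropies are in bits with the 0*log(0) = 0 convention.

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.pop_moments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- sum(d^2) / n
  list(mu = mu, m2 = m2, m3 = sum(d^3) / n, m4 = sum(d^4) / n)
}

#' First-order (histogram) features of in-mask intensities
#'
#' 42 statistics of the raw intensity distribution inside the ROI:
#' 19 percentiles (P5..P95 in steps of 5, linear-interpolation rule) plus 23
#' location/dispersion/shape/histogram statistics.  Histogram-based entries
#' (entropy, uniformity, mode) use a 64-bin equal-width histogram over the
#' in-mask range; a constant ROI has entropy 0 and uniformity 1.  Shape
#' statistics of a constant ROI (skewness, kurtosis, CV, SNR) are defined
#' as 0.
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix, >= 16 in-mask pixels.
#' @return named numeric vector of length 42 (names prefixed "hist_").
#' @export
first_order_features <- function(image, mask) {
  x <- image[mask]
  if (length(x) < 16) stop("mask too small for first-order features")
  n <- length(x)
  probs <- seq(0.05, 0.95, by = 0.05)
  pct <- stats::quantile(x, probs, type = 7, names = FALSE)
  names(pct) <- paste0("hist_p", probs * 100)

  mom <- .pop_moments(x)
  sd_pop <- sqrt(mom$m2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  iqr <- q[3] - q[2]
  qcd <- if ((q[3] + q[2]) != 0) (q[3] - q[2]) / (q[3] + q[2]) else 0

  nbin <- 64L
  if (max(x) > min(x)) {
    counts <- tabulate(pmin(floor((x - min(x)) / ((max(x) - min(x)) / nbin)) + 1,
                            nbin), nbins = nbin)
    mids <- min(x) + ((seq_len(nbin)) - 0.5) * (max(x) - min(x)) / nbin
  } else {
    counts <- c(n, rep(0L, nbin - 1))
    mids <- rep(x[1], nbin)
  }
  ph <- counts / n

  stats42 <- c(
    hist_mean = mean(x),
    hist_median = stats::median(x),
    hist_trimmed_mean10 = mean(x, trim = 0.10),
    hist_min = min(x),
    hist_max = max(x),
    hist_range = max(x) - min(x),
    hist_interdecile_range = q[4] - q[1],
    hist_iqr = iqr,
    hist_variance = mom$m2,
    hist_sd = sd_pop,
    hist_cv = if (mean(x) != 0 && sd_pop > 0) sd_pop / mean(x) else 0,
    hist_qcd = qcd,
    hist_mad = mean(abs(x - mean(x))),
    hist_medad = stats::median(abs(x - stats::median(x))),
    hist_rms = sqrt(mean(x^2)),
    hist_energy = sum(x^2),
    hist_skewness = if (mom$m2 > 0) mom$m3 / mom$m2^1.5 else 0,
    hist_kurtosis = if (mom$m2 > 0) mom$m4 / mom$m2^2 else 0,
    hist_excess_kurtosis = if (mom$m2 > 0) mom$m4 / mom$m2^2 - 3 else 0,
    hist_entropy = entropy_bits(ph),
    hist_uniformity = sum(ph^2),
    hist_mode = mids[which.max(counts)],
    hist_snr = if (sd_pop > 0) mean(x) / sd_pop else 0
  )
  out <- c(stats42, pct)
  stopifnot(length(out) == 42L)
  out
}

## ---- shape (form factor) ----------------------------------------------

# 8-connected flood fill; returns number of connected components.
.n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          p <- (cc - 1L) * nr + rr
          if (mask[p] && lab[p] == 0L) {
            lab[p] <- comp
            queue <- c(queue, p)
          }
        }
      }
    }
  }
  comp
}

# Moore-neighbour boundary trace with Jacob's stopping criterion; returns
# the 8-connected chain code (direction indices into the clockwise Moore
# order) around the component containing the first in-mask pixel.
.boundary_chain <- function(mask) {
  if (sum(mask) == 1) return(integer(0))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  # clockwise Moore order in screen coordinates (row increases downwards)
  drs <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)   # W NW N NE E SE S SW
  dcs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  # first in-mask pixel in row-major order: its W neighbour is background
  hit <- which(t(pad))[1]
  pr <- (hit - 1L) %/% (nc + 2L) + 1L
  pc <- (hit - 1L) %% (nc + 2L) + 1L
  chain <- integer(0)
  r <- pr; c <- pc
  back <- 1L  # index of the background neighbour we entered from (W)
  max_steps <- 4L * (sum(mask) + 4L)
  for (step in seq_len(max_steps)) {
    found <- FALSE
    for (k in 1:8) {
      d <- ((back - 1L + k - 1L) %% 8L) + 1L
      rr <- r + drs[d]; cc <- c + dcs[d]
      if (pad[rr, cc]) {
        chain <- c(chain, d)
        # new backtrack: the neighbour examined just before the hit,
        # expressed relative to the new position
        prev_d <- ((back - 1L + k - 2L) %% 8L) + 1L
        br <- r + drs[prev_d]; bc <- c + dcs[prev_d]
        r <- rr; c <- cc
        # direction index from new pixel back to (br, bc)
        back <- which(drs == (br - r) & dcs == (bc - c))[1]
        found <- TRUE
        break
      }
    }
    if (!found) return(integer(0))  # isolated pixel (cannot happen here)
    if (r == pr && c == pc && length(chain) > 1) break
  }
  chain
}

# Corner-corrected chain-code perimeter (Vossepoel & Smeulders weights):
# 0.980 per axial move, 1.406 per diagonal move, -0.091 per direction change.
.chain_perimeter <- function(chain) {
  if (length(chain) == 0) return(4 * 0.980)  # single pixel
  diag <- chain %% 2L == 0L  # even Moore indices are diagonal moves
  n_corner <- sum(chain != c(chain[-1], chain[1]))
  0.980 * sum(!diag) + 1.406 * sum(diag) - 0.091 * n_corner
}

.shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Form factor (shape) features of the ROI mask
#'
#' 12 geometric descriptors: area, perimeter, perimeter^2/area, circularity
#' (4 pi A / P^2), compactness (P^2 / (4 pi A)), equivalent diameter, major
#' and minor axis lengths (4 sqrt(eigenvalue) of the pixel-centre
#' covariance), eccentricity, elongation (major/minor), extent
#' (area / bounding box) and solidity (area / convex hull of pixel corners).
#' Perimeter uses a corner-corrected chain-code estimator on the traced
#' boundary, accurate to about 1 percent on digital disks.  Lengths are in
#' pixels unless \code{spacing} is given (then mm, assuming square pixels).
#'
#' @param mask logical matrix; must be a single 8-connected component.
#' @param spacing optional scalar mm/pixel.
#' @return named numeric vector of length 12 (names prefixed "shape_").
#' @export
shape_features <- function(mask, spacing = NULL) {
  if (sum(mask) < 1) stop("empty mask")
  if (.n_components(mask) != 1)
    stop("mask has multiple connected components; select the largest ",
         "component upstream before computing shape features")
  s <- if (is.null(spacing)) 1 else spacing[1]
  area <- sum(mask) * s^2
  chain <- .boundary_chain(mask)
  perim <- .chain_perimeter(chain) * s

  rc <- which(mask, arr.ind = TRUE)
  ys <- rc[, 1] - 0.5; xs <- rc[, 2] - 0.5  # pixel centres, corner origin
  cx <- stats::cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs)
  ev <- sort(eigen(cx, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1]) * s
  minor <- 4 * sqrt(ev[2]) * s
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  elong <- if (minor > 0) major / minor else Inf

  bbox_area <- (diff(range(rc[, 1])) + 1) * (diff(range(rc[, 2])) + 1) * s^2
  # convex hull over the 4 corners of every in-mask pixel
  corners <- rbind(cbind(xs - 0.5, ys - 0.5), cbind(xs + 0.5, ys - 0.5),
                   cbind(xs - 0.5, ys + 0.5), cbind(xs + 0.5, ys + 0.5))
  h <- grDevices::chull(corners)
  hull_area <- .shoelace(corners[h, , drop = FALSE]) * s^2

  c(shape_area = area,
    shape_perimeter = perim,
    shape_perimeter2_area = perim^2 / area,
    shape_circularity = 4 * pi * area / perim^2,
    shape_compactness = perim^2 / (4 * pi * area),
    shape_equiv_diameter = 2 * sqrt(area / pi),
    shape_major_axis = major,
    shape_minor_axis = minor,
    shape_eccentricity = ecc,
    shape_elongation = elong,
    shape_extent = area / bbox_area,
    shape_solidity = area / hull_area)
}

## ---- gradient texture --------------------------------------------------

.erode1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    out <- out & pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

#' Gradient-magnitude texture features
#'
#' 18 first-order statistics of the Sobel gradient magnitude inside the
#' ROI.  The gradient is computed on the full image (3x3 Sobel, normalised
#' so an ideal step of height h has magnitude h) and the mask is eroded by
#' one pixel before pooling, so the lesion boundary itself does not
#' contribute.
#'
#' @inheritParams first_order_features
#' @return named numeric vector of length 18 (names prefixed "grad_").
#' @export
gradient_features <- function(image, mask) {
  if (sum(mask) < 16) stop("mask too small for gradient features")
  er <- .erode1(mask)
  if (sum(er) == 0) stop("mask vanished after 1-pixel erosion")
  g <- cpp_sobel_magnitude(image)[er]
  n <- length(g)
  mom <- .pop_moments(g)
  sd_pop <- sqrt(mom$m2)
  q <- stats::quantile(g, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  nbin <- 64L
  if (max(g) > min(g)) {
    counts <- tabulate(pmin(floor((g - min(g)) / ((max(g) - min(g)) / nbin)) + 1,
                            nbin), nbins = nbin)
  } else {
    counts <- c(n, rep(0L, nbin - 1))
  }
  ph <- counts / n
  out <- c(
    grad_mean = mean(g),
    grad_median = stats::median(g),
    grad_min = min(g),
    grad_max = max(g),
    grad_range = max(g) - min(g),
    grad_variance = mom$m2,
    grad_sd = sd_pop,
    grad_cv = if (mean(g) != 0 && sd_pop > 0) sd_pop / mean(g) else 0,
    grad_skewness = if (mom$m2 > 0) mom$m3 / mom$m2^1.5 else 0,
    grad_kurtosis = if (mom$m2 > 0) mom$m4 / mom$m2^2 else 0,
    grad_energy = sum(g^2),
    grad_rms = sqrt(mean(g^2)),
    grad_entropy = entropy_bits(ph),
    grad_uniformity = sum(ph^2),
    grad_mad = mean(abs(g - mean(g))),
    grad_p10 = q[1],
    grad_p90 = q[4],
    grad_iqr = q[3] - q[2]
  )
  stopifnot(length(out) == 18L)
  out
}

## ---- GLCM --------------------------------------------------------------

.angle_offset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("angle must be one of 0, 45, 90, 135"))
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered in-mask pixel pairs at the given offset, symmetrises
#' (both directions contribute) and normalises to sum 1.  Offsets follow
#' the image convention row-down: angle 0 is (drow, dcol) = (0, d),
#' 45 is (-d, d), 90 is (-d, 0), 135 is (-d, -d).
#'
#' @param q a \code{quantized_roi} from [quantize()].
#' @param distance offset length in pixels (>= 1).
#' @param angle one of 0, 45, 90, 135 degrees.
#' @return object of class \code{glc_matrix}: fields \code{probs} (Ng x Ng,
#'   symmetric, sums to 1), \code{counts}, \code{distance}, \code{angle},
#'   \code{levels}.
#' @export
compute_glcm <- function(q, distance = 1L, angle = 0) {
  stopifnot(inherits(q, "quantized_roi"), distance >= 1)
  off <- .angle_offset(angle, as.integer(distance))
  cnt <- cpp_glcm_counts(q$quantized, q$levels, off[1], off[2])
  tot <- sum(cnt)
  if (tot == 0) stop("no valid in-mask pixel pair for distance ", distance,
                     ", angle ", angle)
  structure(list(probs = cnt / tot, counts = cnt,
                 distance = as.integer(distance), angle = angle,
                 levels = q$levels),
            class = "glc_matrix")
}

#' Haralick-style features of a normalised GLCM
#'
#' 13 features: energy, contrast, correlation, entropy, homogeneity
#' (inverse difference moment), inverse difference, dissimilarity, maximum
#' probability, cluster shade, cluster prominence, sum average, sum entropy
#' and difference entropy.  Logs are base 2 with 0 log 0 = 0; correlation
#' uses the marginal means/SDs of the symmetrised matrix and is defined as
#' 1 for a degenerate (zero-variance) matrix.
#'
#' @param m a \code{glc_matrix} (or a plain normalised matrix).
#' @return named numeric vector of length 13 (names prefixed "glcm_").
#' @export
glcm_features <- function(m) {
  p <- if (inherits(m, "glc_matrix")) m$probs else as.matrix(m)
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM is not normalised")
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(ng) * px)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)
  # symmetric matrix: marginals coincide
  corr <- if (var_x > 0) sum(p * (i - mu_x) * (j - mu_x)) / var_x else 1

  # sum and difference distributions (rowsum groups in C, keeps this fast)
  psum <- as.vector(rowsum(as.vector(p), as.vector(i + j)))      # k = 2..2Ng
  pdiff <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j)))) # k = 0..Ng-1

  c(glcm_energy = sum(p^2),
    glcm_contrast = sum(p * (i - j)^2),
    glcm_correlation = corr,
    glcm_entropy = entropy_bits(as.vector(p)),
    glcm_homogeneity = sum(p / (1 + (i - j)^2)),
    glcm_inverse_difference = sum(p / (1 + abs(i - j))),
    glcm_dissimilarity = sum(p * abs(i - j)),
    glcm_max_probability = max(p),
    glcm_cluster_shade = sum(p * (i + j - 2 * mu_x)^3),
    glcm_cluster_prominence = sum(p * (i + j - 2 * mu_x)^4),
    glcm_sum_average = sum((2:(2 * ng)) * psum),
    glcm_sum_entropy = entropy_bits(psum),
    glcm_difference_entropy = entropy_bits(pdiff))
}

## ---- GLRLM -------------------------------------------------------------

#' Grey-level run-length matrix
#'
#' Maximal runs of equal grey level along the direction, counted within
#' the mask; out-of-mask pixels and image edges break runs.  Direction
#' offsets follow the GLCM convention.
#'
#' @param q a \code{quantized_roi}.
#' @param direction one of 0, 45, 90, 135 degrees.
#' @return object of class \code{rl_matrix}: fields \code{counts} (Ng x
#'   Lmax), \code{direction}, \code{n_pixels}, \code{levels}.
#' @export
compute_glrlm <- function(q, direction = 0) {
  stopifnot(inherits(q, "quantized_roi"))
  if (q$n_pixels == 0) stop("empty mask")
  off <- .angle_offset(direction, 1L)
  cnt <- cpp_glrlm_counts(q$quantized, q$levels, off[1], off[2])
  structure(list(counts = cnt, direction = direction,
                 n_pixels = q$n_pixels, levels = q$levels),
            class = "rl_matrix")
}

#' Run-length features of a GLRLM
#'
#' The 16 standard run-length features: SRE, LRE, GLN, GLNN, RLN, RLNN,
#' RP, LGLRE, HGLRE, SRLGLE, SRHGLE, LRLGLE, LRHGLE, GLV, RLV and run
#' entropy (bits).
#'
#' @param r an \code{rl_matrix} from [compute_glrlm()].
#' @return named numeric vector of length 16 (names prefixed "rlm_").
#' @export
glrlm_features <- function(r) {
  cnt <- r$counts
  nr_runs <- sum(cnt)
  if (nr_runs == 0) stop("run-length matrix has no runs")
  ng <- nrow(cnt); lmax <- ncol(cnt)
  lv <- matrix(seq_len(ng), ng, lmax)        # grey level of each cell
  rl <- matrix(seq_len(lmax), ng, lmax, byrow = TRUE)  # run length
  pn <- cnt / nr_runs
  mu_l <- sum(pn * lv)
  mu_r <- sum(pn * rl)
  c(rlm_sre = sum(cnt / rl^2) / nr_runs,
    rlm_lre = sum(cnt * rl^2) / nr_runs,
    rlm_gln = sum(rowSums(cnt)^2) / nr_runs,
    rlm_glnn = sum(rowSums(cnt)^2) / nr_runs^2,
    rlm_rln = sum(colSums(cnt)^2) / nr_runs,
    rlm_rlnn = sum(colSums(cnt)^2) / nr_runs^2,
    rlm_rp = nr_runs / r$n_pixels,
    rlm_lglre = sum(cnt / lv^2) / nr_runs,
    rlm_hglre = sum(cnt * lv^2) / nr_runs,
    rlm_srlgle = sum(cnt / (lv^2 * rl^2)) / nr_runs,
    rlm_srhgle = sum(cnt * lv^2 / rl^2) / nr_runs,
    rlm_lrlgle = sum(cnt * rl^2 / lv^2) / nr_runs,
    rlm_lrhgle = sum(cnt * rl^2 * lv^2) / nr_runs,
    rlm_glv = sum(pn * (lv - mu_l)^2),
    rlm_rlv = sum(pn * (rl - mu_r)^2),
    rlm_run_entropy = entropy_bits(as.vector(pn)))
}

## ---- catalogue and extraction -----------------------------------------

#' The default ultrasomics feature catalogue
#'
#' Defines the full per-image feature set: 42 histogram + 12 form factor +
#' 18 gradient + 780 GLCM (13 features x 5 distances x 6 angular slots
#' [0, 45, 90, 135, angular mean, angular range] x 2 grey-level settings
#' [32, 64]) + 192 RLM (16 features x 6 directional slots x 2 level
#' settings) = 1,044 features.
#'
#' @param glcm_distances offset distances in pixels.
#' @param levels grey-level quantization settings.
#' @return object of class \code{feature_catalogue} with an \code{entries}
#'   data.frame (name, family) and the generating parameters.
#' @export
feature_catalogue <- function(glcm_distances = 1:5, levels = c(32L, 64L)) {
  angles <- c(0, 45, 90, 135)
  slots <- c(paste0("a", angles), "amean", "arange")
  glcm_base <- sub("^glcm_", "", names(glcm_features(diag(2) / 2)))
  rlm_base <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "lglre",
                "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle", "glv",
                "rlv", "run_entropy")
  glcm_names <- character(0)
  rlm_names <- character(0)
  for (L in levels) {
    for (d in glcm_distances) for (s in slots)
      glcm_names <- c(glcm_names,
                      paste0("glcm_L", L, "_d", d, "_", s, "_", glcm_base))
    for (s in slots)
      rlm_names <- c(rlm_names, paste0("rlm_L", L, "_", s, "_", rlm_base))
  }

  first_names <- names(first_order_features(matrix(rep(1:4, 5), 4, 5),
                                            matrix(TRUE, 4, 5)))
  shape_names <- names(shape_features(matrix(TRUE, 4, 5)))
  grad_names <- names(gradient_features(matrix(rep(1:6, 6), 6, 6),
                                        matrix(TRUE, 6, 6)))
  entries <- data.frame(
    name = c(first_names, shape_names, grad_names, glcm_names, rlm_names),
    family = rep(c("histogram", "form_factor", "textural", "glcm", "rlm"),
                 c(length(first_names), length(shape_names),
                   length(grad_names), length(glcm_names),
                   length(rlm_names))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(entries$name)) stop("catalogue names are not unique")
  stopifnot(nrow(entries) == 42L + 12L + 18L +
              13L * length(glcm_distances) * 6L * length(levels) +
              16L * 6L * length(levels))
  structure(list(entries = entries, glcm_distances = glcm_distances,
                 levels = levels, angles = angles),
            class = "feature_catalogue")
}

.catalogue_cache <- new.env(parent = emptyenv())

# memoized default catalogue (used whenever `catalogue = NULL`)
default_catalogue <- function() {
  if (is.null(.catalogue_cache$default))
    .catalogue_cache$default <- feature_catalogue()
  .catalogue_cache$default
}

#' @export
print.feature_catalogue <- function(x, ...) {
  cat("<feature_catalogue>", nrow(x$entries), "features per image:\n")
  print(table(x$entries$family))
  invisible(x)
}

#' Extract the full feature set from one image + ROI
#'
#' @param img an \code{image_roi}.
#' @param catalogue a \code{feature_catalogue} (default catalogue if NULL).
#' @return named numeric vector with one value per catalogue entry
#'   (1,044 for the default catalogue).
#' @export
extract_image_features <- function(img, catalogue = NULL) {
  stopifnot(inherits(img, "image_roi"))
  if (is.null(catalogue)) catalogue <- default_catalogue()
  angles <- catalogue$angles
  out <- c(
    first_order_features(img$pixels, img$mask),
    shape_features(img$mask, img$spacing),
    gradient_features(img$pixels, img$mask)
  )
  for (L in catalogue$levels) {
    q <- quantize(img$pixels, img$mask, L)
    for (d in catalogue$glcm_distances) {
      fa <- vapply(angles, function(a)
        glcm_features(compute_glcm(q, d, a)), numeric(13L))
      agg <- cbind(fa, amean = rowMeans(fa),
                   arange = apply(fa, 1, max) - apply(fa, 1, min))
      colnames(agg) <- c(paste0("a", angles), "amean", "arange")
      for (s in colnames(agg)) {
        v <- agg[, s]
        names(v) <- paste0("glcm_L", L, "_d", d, "_", s, "_",
                           sub("^glcm_", "", names(v)))
        out <- c(out, v)
      }
    }
    fr <- vapply(angles, function(a)
      glrlm_features(compute_glrlm(q, a)), numeric(16L))
    aggr <- cbind(fr, amean = rowMeans(fr),
                  arange = apply(fr, 1, max) - apply(fr, 1, min))
    colnames(aggr) <- c(paste0("a", angles), "amean", "arange")
    for (s in colnames(aggr)) {
      v <- aggr[, s]
      names(v) <- paste0("rlm_L", L, "_", s, "_", sub("^rlm_", "", names(v)))
      out <- c(out, v)
    }
  }
  miss <- setdiff(catalogue$entries$name, names(out))
  if (length(miss)) stop("extraction is missing features: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  out <- out[catalogue$entries$name]
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(utils::head(names(out)[!is.finite(out)], 5), collapse = ", "))
  out
}

#' Extract the per-patient feature vector from a three-phase triplet
#'
#' Applies the catalogue to the baseline, arterial and portal images and
#' concatenates the results with phase prefixes \code{BL_}, \code{AP_},
#' \code{PP_} (3 x 1,044 = 3,132 values for the default catalogue).
#'
#' @param triplet list of three \code{image_roi} objects with phases
#'   baseline, arterial, portal (in any order; matched by phase).
#' @param catalogue a \code{feature_catalogue} or NULL for the default.
#' @return named numeric vector of length 3 x catalogue size.
#' @export
extract_features <- function(triplet, catalogue = NULL) {
  if (is.null(catalogue)) catalogue <- default_catalogue()
  phases <- vapply(triplet, function(im) im$phase, "")
  need <- c("baseline", "arterial", "portal")
  if (length(triplet) != 3 || !setequal(phases, need))
    stop("triplet must contain exactly the baseline, arterial and portal phases")
  prefix <- c(baseline = "BL_", arterial = "AP_", portal = "PP_")
  out <- unlist(lapply(need, function(ph) {
    v <- extract_image_features(triplet[[which(phases == ph)]], catalogue)
    names(v) <- paste0(prefix[[ph]], names(v))
    v
  }))
  out
}
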