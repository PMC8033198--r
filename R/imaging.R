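#' @useDynLib ceusomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate convention used throughout the package: 0-based pixel indices,
# x = column, y = row, origin at the top-left *corner* of the image.  The
# centre of pixel (row r, col c) is therefore at (x, y) = (c + 0.5, r + 0.5).

#' Read a 2D grayscale image
#'
#' Reads a single-frame image and returns a numeric intensity matrix
#' (rows x columns).  RGB inputs are collapsed to luminance
#' (0.299 R + 0.587 G + 0.114 B).  For DICOM inputs the rescale
#' transformation (slope/intercept) is applied when the tags are present.
#'
#' Supported formats: PNG (8- or 16-bit, via the \pkg{png} package),
#' single-frame little-endian DICOM (explicit or implicit VR, monochrome or
#' interleaved RGB), and plain-text PGM (P2).  TIFF is not supported in this
#' build and raises an error.
#'
#' @param path path to the image file.
#' @param format one of \code{"auto"}, \code{"png"}, \code{"dicom"},
#'   \code{"pgm"}, \code{"tiff"}.  \code{"auto"} sniffs the file signature.
#' @return a numeric matrix of intensities; if pixel spacing is available
#'   (DICOM PixelSpacing) it is attached as attribute \code{"spacing"}
#'   (mm/pixel, c(row, col)).
#' @export
read_image <- function(path, format = c("auto", "png", "dicom", "pgm", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") format <- sniff_format(path)
  switch(format,
    png   = read_image_png(path),
    dicom = read_image_dicom(path),
    pgm   = read_image_pgm(path),
    tiff  = stop("TIFF reading is not supported in this build; ",
                 "convert to PNG or DICOM"),
    stop("unrecognised image format for ", path)
  )
}

sniff_format <- function(path) {
  hdr <- readBin(path, "raw", n = 160)
  if (length(hdr) >= 8 &&
      identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    return("png")
  if (length(hdr) >= 132 && rawToChar(hdr[129:132]) == "DICM") return("dicom")
  if (length(hdr) >= 2 && rawToChar(hdr[1:2]) %in% c("P2", "P5")) return("pgm")
  if (length(hdr) >= 4 && (identical(hdr[1:2], as.raw(c(0x49, 0x49))) ||
                           identical(hdr[1:2], as.raw(c(0x4d, 0x4d)))))
    return("tiff")
  # fall back on extension
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) return("dicom")
  stop("cannot determine image format of ", path)
}

read_image_png <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  scale <- 2^depth - 1
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      g <- arr[, , 1]
    }
  } else {
    g <- arr
  }
  g * scale
}

read_image_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only plain-text (P2) PGM is supported")
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: pixel count mismatch")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write a matrix as a plain-text PGM (P2) image
#'
#' Intensities are rounded and clamped to \code{[0, maxval]}.  Used by the
#' cohort writer as a portable text representation of synthetic images.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @param maxval maximum grey value recorded in the header.
#' @export
write_image_pgm <- function(img, path, maxval = 255L) {
  v <- pmin(pmax(round(img), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

## ---- minimal single-frame DICOM reader --------------------------------

dcm_uint <- function(raw, signed = FALSE) {
  n <- length(raw)
  if (n == 2) {
    v <- as.integer(raw[1]) + 256L * as.integer(raw[2])
    if (signed && v >= 32768L) v <- v - 65536L
    v
  } else {
    v <- sum(as.numeric(raw) * 256^(0:(n - 1)))
    v
  }
}

read_image_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(bytes) >= 132 && rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  transfer_syntax <- NULL
  tags <- list()
  n <- length(bytes)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  read_elem <- function(pos, explicit) {
    group <- dcm_uint(bytes[pos:(pos + 1)])
    elem  <- dcm_uint(bytes[(pos + 2):(pos + 3)])
    pos <- pos + 4L
    vr <- NA_character_
    if (explicit || group == 0x0002) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      if (vr %in% long_vrs) {
        len <- dcm_uint(bytes[(pos + 4):(pos + 7)])
        pos <- pos + 8L
      } else {
        len <- dcm_uint(bytes[(pos + 2):(pos + 3)])
        pos <- pos + 4L
      }
    } else {
      len <- dcm_uint(bytes[pos:(pos + 3)])
      pos <- pos + 4L
    }
    list(group = group, elem = elem, vr = vr, len = len, data_pos = pos)
  }

  while (pos + 7L <= n) {
    in_meta <- dcm_uint(bytes[pos:(pos + 1)]) == 0x0002
    el <- read_elem(pos, explicit || in_meta)
    if (el$len == 0xFFFFFFFF)
      stop("unsupported DICOM: undefined-length element (sequences/encapsulated ",
           "pixel data are not supported)")
    key <- sprintf("%04x,%04x", el$group, el$elem)
    val_raw <- if (el$len > 0) bytes[el$data_pos:(el$data_pos + el$len - 1)] else raw(0)
    tags[[key]] <- list(vr = el$vr, raw = val_raw)
    pos <- el$data_pos + el$len
    if (key == "0002,0010") {
      transfer_syntax <- trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
      explicit <- !identical(transfer_syntax, "1.2.840.10008.1.2")
      if (!is.null(transfer_syntax) &&
          !transfer_syntax %in% c("1.2.840.10008.1.2",      # implicit LE
                                  "1.2.840.10008.1.2.1"))   # explicit LE
        stop("unsupported DICOM transfer syntax: ", transfer_syntax)
    }
    if (key == "7fe0,0010") break
  }

  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$raw[t$raw != as.raw(0)]))
  }
  get_us <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    dcm_uint(t$raw[1:2])
  }

  nframes <- get_str("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1)
    stop("unsupported DICOM: multi-frame images are not supported")
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols) || is.null(tags[["7fe0,0010"]]))
    stop("not an image DICOM: missing Rows/Columns/PixelData")
  bits <- get_us("0028,0100", 8L)
  spp  <- get_us("0028,0002", 1L)
  pixrep <- get_us("0028,0103", 0L)
  if (!bits %in% c(8L, 16L)) stop("unsupported DICOM bit depth: ", bits)

  pd <- tags[["7fe0,0010"]]$raw
  need <- rows * cols * spp * (bits / 8)
  if (length(pd) < need) stop("corrupt DICOM: truncated pixel data")
  if (bits == 8L) {
    vals <- as.numeric(pd[seq_len(need)])
  } else {
    m <- matrix(as.numeric(pd[seq_len(need)]), nrow = 2)
    vals <- m[1, ] + 256 * m[2, ]
    if (pixrep == 1L) vals <- ifelse(vals >= 32768, vals - 65536, vals)
  }
  if (spp >= 3L) {
    # interleaved RGB -> luminance
    dim(vals) <- c(spp, rows * cols)
    vals <- 0.299 * vals[1, ] + 0.587 * vals[2, ] + 0.114 * vals[3, ]
  }
  img <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  slope <- get_str("0028,1053"); intercept <- get_str("0028,1052")
  if (!is.null(slope) || !is.null(intercept)) {
    s <- if (is.null(slope)) 1 else as.numeric(slope)
    b <- if (is.null(intercept)) 0 else as.numeric(intercept)
    img <- img * s + b
  }
  spacing <- get_str("0028,0030")
  if (!is.null(spacing)) {
    sp <- as.numeric(strsplit(spacing, "\\\\")[[1]])
    attr(img, "spacing") <- sp
  }
  img
}

## ---- ROI polygons ------------------------------------------------------

#' Test a polygon for self-intersection
#'
#' @param polygon two-column matrix of (x, y) vertices (closed implicitly).
#' @return TRUE if any two non-adjacent edges intersect.
#' @keywords internal
polygon_self_intersects <- function(polygon) {
  v <- as.matrix(polygon)
  nv <- nrow(v)
  if (nv < 4) return(FALSE)
  seg <- cbind(v, v[c(2:nv, 1), , drop = FALSE])  # x1 y1 x2 y2
  ccw <- function(ax, ay, bx, by, cx, cy) (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(nv - 2)) {
    jmax <- if (i == 1) nv - 1 else nv
    for (j in (i + 2):jmax) {
      d1 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize an ROI polygon to a boolean mask
#'
#' A pixel belongs to the mask iff its centre, at \code{(col + 0.5,
#' row + 0.5)} in corner-origin coordinates, lies inside the polygon under
#' the even-odd rule.  Boundary-grazing centres are resolved by the
#' half-open convention of the crossing test (edges on the left/top count
#' as inside, right/bottom as outside), so adjacent polygons tile without
#' double-counting pixels.
#'
#' @param polygon two-column matrix or data.frame of (x, y) vertices in
#'   pixel coordinates (0-based, x = column).  The polygon is closed
#'   implicitly (last vertex connects back to the first).
#' @param shape integer vector c(rows, cols).
#' @return logical matrix of dimension \code{shape}.
#' @export
rasterize_roi <- function(polygon, shape) {
  v <- as.matrix(polygon)
  if (ncol(v) != 2 || nrow(v) < 3) stop("polygon must have >= 3 (x, y) vertices")
  if (anyNA(v)) stop("polygon contains NA vertices")
  if (any(v[, 1] < 0 | v[, 1] > shape[2] | v[, 2] < 0 | v[, 2] > shape[1]))
    stop("polygon vertices outside image bounds")
  if (polygon_self_intersects(v)) stop("polygon is self-intersecting")
  nr <- shape[1]; nc <- shape[2]
  px <- rep(seq_len(nc) - 0.5, each = nr)   # x of pixel centres, col-major
  py <- rep(seq_len(nr) - 0.5, times = nc)  # y of pixel centres
  inside <- rep(FALSE, nr * nc)
  nv <- nrow(v)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      hit <- px[crosses] < xint
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    j <- i
  }
  matrix(inside, nrow = nr, ncol = nc)
}

#' Construct an image + ROI container
#'
#' Bundles one 2D intensity image with its ROI polygon, the rasterized
#' mask, and the acquisition phase.  Validates the invariants required by
#' the texture extractor (matching shapes, at least 16 in-mask pixels,
#' simple polygon).
#'
#' @param pixels numeric intensity matrix (non-negative).
#' @param roi_polygon (x, y) vertex matrix, see [rasterize_roi()].
#' @param phase one of "baseline", "arterial", "portal".
#' @param spacing optional mm/pixel.
#' @param min_pixels minimum in-mask pixel count (default 16).
#' @return an object of class \code{image_roi}.
#' @export
image_roi <- function(pixels, roi_polygon, phase = c("baseline", "arterial", "portal"),
                      spacing = NULL, min_pixels = 16L) {
  phase <- match.arg(phase)
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  mask <- rasterize_roi(roi_polygon, dim(pixels))
  if (sum(mask) < min_pixels)
    stop("ROI too small: ", sum(mask), " pixels in mask (minimum ", min_pixels, ")")
  structure(list(pixels = pixels, roi_polygon = as.matrix(roi_polygon),
                 mask = mask, phase = phase, spacing = spacing),
            class = "image_roi")
}

#' @export
print.image_roi <- function(x, ...) {
  cat(sprintf("<image_roi> %dx%d pixels, %s phase, %d in-mask pixels\n",
              nrow(x$pixels), ncol(x$pixels), x$phase, sum(x$mask)))
  invisible(x)
}

## ---- quantization ------------------------------------------------------

#' Quantize in-mask intensities to discrete grey levels
#'
#' Equal-width binning over the in-mask intensity range: level k covers
#' \code{[min + (k-1) w, min + k w)} with \code{w = (max - min)/levels};
#' the maximum maps to level \code{levels}.  A constant ROI maps entirely
#' to level 1.  Binning is ROI-relative, so the result is invariant to
#' affine intensity rescaling (gain/offset) that preserves ordering.
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix of the same shape.
#' @param levels number of grey levels Ng (>= 2).
#' @return an object of class \code{quantized_roi} with fields
#'   \code{levels}, \code{quantized} (integer matrix, 1..Ng inside the
#'   mask, 0 outside), \code{mask}, and \code{n_pixels}.
#' @export
quantize <- function(image, mask, levels = 32L) {
  if (!all(dim(image) == dim(mask))) stop("image/mask shape mismatch")
  if (levels < 2) stop("levels must be >= 2")
  vals <- image[mask]
  if (length(vals) == 0) stop("empty mask")
  lo <- min(vals); hi <- max(vals)
  q <- matrix(0L, nrow(image), ncol(image))
  if (hi == lo) {
    q[mask] <- 1L
  } else {
    w <- (hi - lo) / levels
    k <- pmin(floor((vals - lo) / w) + 1, levels)
    q[mask] <- as.integer(k)
  }
  structure(list(levels = as.integer(levels), quantized = q, mask = mask,
                 n_pixels = sum(mask)),
            class = "quantized_roi")
}
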