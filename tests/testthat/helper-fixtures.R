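# Shared fixtures, built in code at test time.

# wrap a plain integer matrix as a quantized_roi (mask = nonzero entries)
as_quantized <- function(m, levels = max(m)) {
  m <- as.matrix(m)
  structure(list(levels = as.integer(levels),
                 quantized = matrix(as.integer(m), nrow(m), ncol(m)),
                 mask = m != 0L, n_pixels = sum(m != 0L)),
            class = "quantized_roi")
}

# circle polygon (x, y) around centre with radius r
circle_polygon <- function(cx, cy, r, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# an image_roi with controllable interior; intensities default to a
# deterministic gradient so texture features are non-degenerate
toy_image_roi <- function(size = 48, r = 16, phase = "baseline",
                          pixels = NULL) {
  if (is.null(pixels)) {
    pixels <- outer(seq_len(size), seq_len(size),
                    function(i, j) (i * 3 + j * 5) %% 97 + 10)
  }
  image_roi(pixels, circle_polygon(size / 2, size / 2, r), phase = phase)
}

# minimal explicit-VR little-endian DICOM writer (monochrome, 8- or
# 16-bit, single frame) -- only what the reader tests need
write_test_dicom <- function(path, pixels, bits = 16L,
                             slope = NULL, intercept = NULL) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  elem_str <- function(group, elem, vr, value) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1) value <- c(value, charToRaw(" "))
    u16(group); u16(elem); writeChar(vr, con, eos = NULL)
    u16(length(value)); writeBin(value, con)
  }
  elem_us <- function(group, elem, value) {
    u16(group); u16(elem); writeChar("US", con, eos = NULL)
    u16(2L); u16(value)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta (group 0002, explicit VR)
  elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  elem_str(0x0008, 0x0060, "CS", "US")
  elem_us(0x0028, 0x0002, 1L)                 # SamplesPerPixel
  elem_str(0x0028, 0x0004, "CS", "MONOCHROME2")
  elem_us(0x0028, 0x0010, nrow(pixels))       # Rows
  elem_us(0x0028, 0x0011, ncol(pixels))       # Columns
  elem_us(0x0028, 0x0100, bits)               # BitsAllocated
  elem_us(0x0028, 0x0103, 0L)                 # PixelRepresentation
  if (!is.null(slope)) elem_str(0x0028, 0x1053, "DS", as.character(slope))
  if (!is.null(intercept))
    elem_str(0x0028, 0x1052, "DS", as.character(intercept))
  vals <- as.integer(t(pixels))               # row-major pixel order
  u16(0x7fe0); u16(0x0010); writeChar("OW", con, eos = NULL)
  u16(0L); u32(length(vals) * 2L)
  writeBin(vals, con, size = 2, endian = "little")
  invisible(path)
}

# independent GLCM/GLRLM reference: scikit-image graycomatrix plus a naive
# numpy run-length counter, run through the system python
python_texture_reference <- function(qmat, levels) {
  qfile <- tempfile(fileext = ".csv")
  ofile <- tempfile(fileext = ".json")
  utils::write.table(qmat, qfile, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  script <- tempfile(fileext = ".py")
  writeLines(sprintf('
import json, numpy as np
from skimage.feature import graycomatrix, graycoprops
q = np.loadtxt("%s", delimiter=",").astype(int)
ng = %d
out = {}
angle_offsets = {0: (0, 1), 45: (-1, 1), 90: (-1, 0), 135: (-1, -1)}
# skimage offsets are (round(sin a) * d, round(cos a) * d) downward-row;
# under symmetrization its pi/4 equals this package 135-degree offset
for ang, rad in [(0, 0.0), (45, 3*np.pi/4), (90, np.pi/2), (135, np.pi/4)]:
    for d in (1, 2):
        g = graycomatrix(q - 1, distances=[d], angles=[rad], levels=ng,
                         symmetric=True, normed=True)
        key = f"glcm_{ang}_{d}"
        out[key] = {
            "contrast": float(graycoprops(g, "contrast")[0, 0]),
            "dissimilarity": float(graycoprops(g, "dissimilarity")[0, 0]),
            "homogeneity": float(graycoprops(g, "homogeneity")[0, 0]),
            "asm": float(graycoprops(g, "ASM")[0, 0]),
            "correlation": float(graycoprops(g, "correlation")[0, 0]),
        }
# naive run-length matrices (maximal equal-level runs along each direction)
def rlm(q, dr, dc):
    nr, nc = q.shape
    counts = {}
    starts = [(r, c) for r in range(nr) for c in range(nc)
              if not (0 <= r - dr < nr and 0 <= c - dc < nc)]
    for (r, c) in starts:
        cur, ln = 0, 0
        while 0 <= r < nr and 0 <= c < nc:
            v = q[r, c]
            if v == cur:
                ln += 1
            else:
                if cur:
                    counts[(cur, ln)] = counts.get((cur, ln), 0) + 1
                cur, ln = v, 1
            r += dr; c += dc
        if cur:
            counts[(cur, ln)] = counts.get((cur, ln), 0) + 1
    return counts
for ang, (dr, dc) in angle_offsets.items():
    counts = rlm(q, dr, dc)
    nruns = sum(counts.values())
    npix = int((q > 0).sum())
    sre = sum(n / (l * l) for (g, l), n in counts.items()) / nruns
    lre = sum(n * l * l for (g, l), n in counts.items()) / nruns
    gln_marg = {}
    for (g, l), n in counts.items():
        gln_marg[g] = gln_marg.get(g, 0) + n
    gln = sum(v * v for v in gln_marg.values()) / nruns
    hglre = sum(n * g * g for (g, l), n in counts.items()) / nruns
    out[f"rlm_{ang}"] = {"sre": sre, "lre": lre, "gln": gln,
                         "hglre": hglre, "rp": nruns / npix}
with open("%s", "w") as fh:
    json.dump(out, fh)
', qfile, levels, ofile), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python reference extractor failed")
  jsonlite::read_json(ofile, simplifyVector = TRUE)
}
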