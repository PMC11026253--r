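## Synthetic picrosirius-red-style section images: red collagen speckle on
## yellow myocardium, white background strip and white tissue gaps, and a
## dark-red endocardial collagen band along one edge. The pixel-level label
## mask is returned alongside the image, and the collagen fraction within
## the analysable area is exact by construction (a fixed pixel count is
## sampled), so the quantifier can be validated against known truth.

## mask labels
.HIST_BG <- 0L; .HIST_MYO <- 1L; .HIST_COLLAGEN <- 2L
.HIST_ENDO <- 3L; .HIST_GAP <- 4L

#' Ground-truth description of a synthetic histology section
#'
#' @param collagen_fraction true fibrosis fraction within the analysable
#'   area (0..1).
#' @param endocardium_band_px thickness in pixels of the excluded
#'   endocardial collagen band along the left edge (0 disables it).
#' @param gap_fraction fraction of the tissue area covered by
#'   background-coloured gaps.
#' @return an object of class `histology_truth`.
#' @export
histology_truth <- function(collagen_fraction, endocardium_band_px = 10,
                            gap_fraction = 0.05) {
  check_that(collagen_fraction >= 0 && collagen_fraction <= 1,
             "collagen_fraction must lie in [0, 1] (got %g)", collagen_fraction)
  check_that(gap_fraction >= 0 && gap_fraction <= 1,
             "gap_fraction must lie in [0, 1]")
  check_that(endocardium_band_px >= 0, "endocardium_band_px must be >= 0")
  structure(list(collagen_fraction = collagen_fraction,
                 endocardium_band_px = endocardium_band_px,
                 gap_fraction = gap_fraction),
            class = "histology_truth")
}

.hist_palette <- list(
  bg = c(250, 250, 250), myo = c(230, 200, 60),
  collagen = c(200, 40, 50), endo = c(140, 20, 30))

#' Generate a synthetic stained-section image with ground-truth mask
#'
#' Tissue fills the image except a white background strip on the right
#' edge. The endocardial band occupies the leftmost columns (touching the
#' image border, as endocardium does in sections laid flat), separated from
#' the interstitial collagen by a two-pixel myocardial buffer so the band
#' remains its own connected component. Gaps are white circular dropouts.
#' Exactly `round(collagen_fraction * analysable_pixels)` analysable pixels
#' are labelled collagen.
#'
#' @param truth a [histology_truth()].
#' @param width_px,height_px image size in pixels.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param colour_jitter per-channel uniform colour jitter (0..255 scale)
#'   applied to tissue pixels.
#' @return list with `image` (height x width x 3 array in \[0,1\]), `mask`
#'   (integer matrix: 0 background, 1 myocardium, 2 collagen,
#'   3 endocardium, 4 gap), and `truth`.
#' @export
generate_histology_image <- function(truth, width_px = 400, height_px = 400,
                                     seed = 1, colour_jitter = 10) {
  stopifnot(inherits(truth, "histology_truth"))
  band <- as.integer(truth$endocardium_band_px)
  margin <- max(8L, as.integer(round(0.03 * width_px)))
  check_that(width_px > band + margin + 20,
             "image too narrow (%d px) for a %d px endocardial band", width_px, band)
  set.seed(seed)

  m <- matrix(.HIST_MYO, nrow = height_px, ncol = width_px)
  m[, (width_px - margin + 1L):width_px] <- .HIST_BG
  if (band > 0) {
    m[, seq_len(band)] <- .HIST_ENDO
    m[, band + 1:2] <- .HIST_MYO          # buffer: keep band a separate component
  }
  buffer_cols <- if (band > 0) band + 1:2 else integer(0)

  ## circular white gaps within the tissue interior
  tissue_cols <- (band + 3L):(width_px - margin)
  n_tissue <- height_px * length(tissue_cols)
  if (truth$gap_fraction > 0) {
    r0 <- max(3L, as.integer(round(0.015 * min(height_px, width_px))))
    k <- as.integer(round(truth$gap_fraction * n_tissue / (pi * r0^2)))
    if (k > 0) {
      cy <- sample(seq(r0 + 1L, height_px - r0), k, replace = TRUE)
      cx <- sample(seq(min(tissue_cols) + r0, max(tissue_cols) - r0),
                   k, replace = TRUE)
      off <- expand.grid(dy = -r0:r0, dx = -r0:r0)
      off <- off[off$dy^2 + off$dx^2 <= r0^2, ]
      for (j in seq_len(k)) {
        yy <- cy[j] + off$dy
        xx <- cx[j] + off$dx
        m[cbind(yy, xx)] <- .HIST_GAP
      }
    }
  }

  ## collagen speckle: exact pixel count within the analysable area
  speckle <- which(m == .HIST_MYO &
                     col(m) >= min(tissue_cols) & col(m) <= max(tissue_cols))
  n_analysable <- length(speckle) + length(buffer_cols) * height_px
  n_col <- as.integer(round(truth$collagen_fraction * n_analysable))
  check_that(n_col <= length(speckle),
             "collagen_fraction %.2f too high for the configured layout",
             truth$collagen_fraction)
  if (n_col > 0) m[sample(speckle, n_col)] <- .HIST_COLLAGEN

  ## render to RGB with per-pixel jitter
  pal <- .hist_palette
  img <- array(0, dim = c(height_px, width_px, 3))
  base <- list(pal$bg, pal$myo, pal$collagen, pal$endo, pal$bg)  # labels 0..4
  jit <- c(3, colour_jitter, colour_jitter, 6, 3)
  for (ch in 1:3) {
    plane <- matrix(0, height_px, width_px)
    for (lab in 0:4) {
      idx <- which(m == lab)
      if (!length(idx)) next
      plane[idx] <- base[[lab + 1L]][ch] +
        stats::runif(length(idx), -jit[lab + 1L], jit[lab + 1L])
    }
    img[, , ch] <- pmin(255, pmax(0, plane)) / 255
  }

  list(image = img, mask = m, truth = truth,
       analysable_px = n_analysable, collagen_px = n_col)
}

#' Write a synthetic section (and optional mask) as PNG
#'
#' The label mask is stored as an 8-bit grayscale PNG with the label value
#' in each pixel (0 background, 1 myocardium, 2 collagen, 3 endocardium,
#' 4 gap).
#'
#' @param section result of [generate_histology_image()].
#' @param path output PNG path for the RGB image.
#' @param mask_path optional output PNG path for the label mask.
#' @return invisibly, the written paths.
#' @export
write_histology_image <- function(section, path, mask_path = NULL) {
  png::writePNG(section$image, path)
  if (!is.null(mask_path))
    png::writePNG(section$mask / 255, mask_path)
  invisible(c(image = path, mask = mask_path))
}

#' Read a section image (PNG or TIFF) as an RGB array
#'
#' @param path image path; format chosen by extension.
#' @return height x width x 3 numeric array in \[0, 1\].
#' @export
read_histology_image <- function(path) {
  check_that(file.exists(path), "image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    check_that(requireNamespace("tiff", quietly = TRUE),
               "reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  check_that(length(dim(img)) == 3 && dim(img)[3] == 3,
             "expected an RGB image: %s", path)
  img
}
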