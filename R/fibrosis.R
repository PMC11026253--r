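## Percent-fibrosis quantification from picrosirius-red-stained sections:
## hue/saturation/value pixel classification (collagen red, myocardium
## yellow), morphological exclusion of background, tissue gaps and the
## thickened endocardial collagen band, and patient-level aggregation.

#' Classify section pixels as collagen / myocardium / candidate-excluded
#'
#' Pixels are classified in HSV space: low saturation or very high value is
#' background or a tissue gap (candidate for exclusion); among saturated
#' pixels, hues in the red band are collagen and hues in the yellow band
#' myocardium. The rule is deterministic; thresholds are exposed because
#' staining intensity varies between batches.
#'
#' @param image height x width x 3 RGB array in \[0, 1\].
#' @param collagen_hue red hue band in degrees, wrapping through 0
#'   (`c(330, 25)` means \[330, 360) U \[0, 25\]).
#' @param myocardium_hue yellow hue band in degrees (upper-bounded interval).
#' @param min_saturation minimum saturation for a tissue pixel.
#' @param max_value value at or above which a pixel counts as background.
#' @return integer matrix with labels 0 (candidate excluded),
#'   1 (myocardium), 2 (collagen).
#' @export
classify_pixels <- function(image, collagen_hue = c(330, 25),
                            myocardium_hue = c(25, 90),
                            min_saturation = 0.25, max_value = 0.95) {
  check_that(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3,
             "classify_pixels needs an RGB array (height x width x 3)")
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                  as.vector(image[, , 2]),
                                  as.vector(image[, , 3])),
                            maxColorValue = 1)
  h <- hsv[1, ] * 360
  s <- hsv[2, ]
  v <- hsv[3, ]
  lab <- integer(length(h))                           # 0 = candidate excluded
  tissue <- s >= min_saturation & v < max_value
  red <- tissue & (h >= collagen_hue[1] | h <= collagen_hue[2])
  yellow <- tissue & h > myocardium_hue[1] & h <= myocardium_hue[2]
  lab[yellow] <- 1L
  lab[red] <- 2L
  matrix(lab, nrow = d[1], ncol = d[2])
}

#' Exclude background, gaps and border-adjacent thick collagen structures
#'
#' Candidate-excluded pixels (background, gaps) become excluded outright.
#' Connected collagen components that touch the image border and have local
#' thickness of at least `min_thickness_px` (they survive erosion with a
#' disc of that diameter) are treated as thickened endocardium / other
#' non-myocardial collagen and excluded; thin interstitial collagen is
#' retained. The remainder is the area analysed for percent-fibrosis.
#'
#' @param label_mask output of [classify_pixels()].
#' @param min_thickness_px minimal local thickness (pixels) for a
#'   border-touching collagen component to count as endocardium.
#' @return integer matrix with labels 0 (excluded), 1 (myocardium),
#'   2 (collagen); attribute `"usable"` is `FALSE` when nothing analysable
#'   remains.
#' @export
build_exclusion_mask <- function(label_mask, min_thickness_px = 8) {
  stopifnot(is.matrix(label_mask))
  out <- label_mask
  collagen <- label_mask == 2L
  if (any(collagen)) {
    cc <- EBImage::bwlabel(collagen)
    nr <- nrow(cc); nc <- ncol(cc)
    border_ids <- unique(c(cc[1, ], cc[nr, ], cc[, 1], cc[, nc]))
    border_ids <- border_ids[border_ids > 0]
    if (length(border_ids)) {
      brush_size <- 2L * (as.integer(min_thickness_px) %/% 2L) + 1L
      eroded <- EBImage::erode(collagen,
                               EBImage::makeBrush(brush_size, shape = "disc"))
      thick_ids <- unique(cc[eroded > 0])
      excl_ids <- intersect(border_ids, thick_ids)
      if (length(excl_ids)) out[cc %in% excl_ids] <- 0L
    }
  }
  usable <- any(out > 0L)
  if (!usable) warning("section entirely excluded; flagged unusable")
  attr(out, "usable") <- usable
  out
}

#' Percent-fibrosis of an analysed section mask
#'
#' @param section_mask output of [build_exclusion_mask()].
#' @return percent-fibrosis, `100 * collagen / (collagen + myocardium)`
#'   within the analysed area; `NA` (with a warning) when the analysable
#'   area is zero.
#' @export
percent_fibrosis <- function(section_mask) {
  col_px <- sum(section_mask == 2L)
  myo_px <- sum(section_mask == 1L)
  if (col_px + myo_px == 0L) {
    warning("zero analysable area; section unusable")
    return(NA_real_)
  }
  100 * col_px / (col_px + myo_px)
}

#' Quantify one section image end to end
#'
#' Runs [classify_pixels()], [build_exclusion_mask()] and
#' [percent_fibrosis()] and returns the per-section pixel accounting. The
#' three pixel classes partition the image:
#' `collagen_px + myocardium_px + excluded_px == total_px`.
#'
#' @param image RGB array or a file path readable by
#'   [read_histology_image()].
#' @param section_id identifier copied into the output row.
#' @param ... passed to [classify_pixels()] and [build_exclusion_mask()]
#'   (matched by name).
#' @return one-row data.frame: `section_id`, `collagen_px`,
#'   `myocardium_px`, `excluded_px`, `percent_fibrosis`, `usable`.
#' @export
quantify_section <- function(image, section_id = "S01", ...) {
  if (is.character(image)) image <- read_histology_image(image)
  dots <- list(...)
  cl_args <- dots[names(dots) %in% names(formals(classify_pixels))]
  ex_args <- dots[names(dots) %in% names(formals(build_exclusion_mask))]
  lab <- do.call(classify_pixels, c(list(image), cl_args))
  mask <- suppressWarnings(do.call(build_exclusion_mask, c(list(lab), ex_args)))
  pf <- suppressWarnings(percent_fibrosis(mask))
  data.frame(section_id = section_id,
             collagen_px = sum(mask == 2L),
             myocardium_px = sum(mask == 1L),
             excluded_px = sum(mask == 0L),
             percent_fibrosis = pf,
             usable = isTRUE(attr(mask, "usable")))
}

#' Aggregate section percent-fibrosis to the patient level
#'
#' @param section_values numeric vector of per-section percent-fibrosis
#'   (NAs = unusable sections, dropped).
#' @param min_sections minimal number of usable sections expected per
#'   patient; a warning is issued below this.
#' @return one-row data.frame: `percent_fibrosis` (unweighted mean over
#'   usable sections), `sd`, `n_sections`. Zero usable sections give an
#'   `NA` mean with a warning.
#' @export
aggregate_patient <- function(section_values, min_sections = 30) {
  x <- section_values[!is.na(section_values)]
  if (!length(x)) {
    warning("no usable sections; patient excluded from fibrosis summary")
    return(data.frame(percent_fibrosis = NA_real_, sd = NA_real_,
                      n_sections = 0L))
  }
  if (length(x) < min_sections)
    warning(sprintf("only %d usable sections (expected >= %d)",
                    length(x), min_sections))
  data.frame(percent_fibrosis = mean(x),
             sd = if (length(x) > 1) stats::sd(x) else NA_real_,
             n_sections = length(x))
}
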