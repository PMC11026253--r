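test_that("pixel classification follows the hue/saturation rules", {
  px <- function(r, g, b) array(c(r, g, b) / 255, dim = c(1, 1, 3))
  expect_equal(as.integer(classify_pixels(px(220, 30, 40))), 2L)   # red: collagen
  expect_equal(as.integer(classify_pixels(px(230, 200, 40))), 1L)  # yellow: myocardium
  expect_equal(as.integer(classify_pixels(px(250, 250, 250))), 0L) # white: background
  expect_equal(as.integer(classify_pixels(px(140, 20, 30))), 2L)   # dark red: collagen
  expect_error(classify_pixels(matrix(0, 3, 3)), "RGB")
})

test_that("pixel classes partition every generated image", {
  for (f in c(0, 0.3)) {
    sec <- generate_histology_image(histology_truth(f), 200, 200, seed = 1)
    lab <- classify_pixels(sec$image)
    mask <- suppressWarnings(build_exclusion_mask(lab))
    expect_equal(sum(mask == 0) + sum(mask == 1) + sum(mask == 2), 200 * 200)
  }
})

test_that("exclusion: endocardial band out, interior collagen kept, gaps out", {
  sec <- generate_histology_image(histology_truth(0.2, endocardium_band_px = 12,
                                                  gap_fraction = 0.08),
                                  300, 300, seed = 2)
  lab <- classify_pixels(sec$image)
  mask <- build_exclusion_mask(lab)
  # the whole band is excluded
  expect_true(all(mask[, 1:12] == 0))
  # interior collagen speckle survives
  expect_gt(sum(mask == 2), 0)
  # gap pixels (white) are excluded
  expect_true(all(mask[sec$mask == 4L] == 0))
  expect_true(attr(mask, "usable"))

  # image with no tissue at all is flagged unusable
  blank <- array(250 / 255, dim = c(50, 50, 3))
  expect_warning(m0 <- build_exclusion_mask(classify_pixels(blank)),
                 "unusable")
  expect_false(attr(m0, "usable"))
})

test_that("percent-fibrosis arithmetic and degenerate inputs", {
  m <- matrix(c(rep(2L, 300), rep(1L, 700)), 25, 40)
  expect_equal(percent_fibrosis(m), 30)
  expect_equal(percent_fibrosis(matrix(1L, 10, 10)), 0)
  expect_warning(expect_true(is.na(percent_fibrosis(matrix(0L, 5, 5)))),
                 "unusable")
})

test_that("recovery: estimated percent-fibrosis within 1 point of truth", {
  for (f in c(0, 0.05, 0.159, 0.3, 0.6)) {
    sec <- generate_histology_image(histology_truth(f), 400, 400, seed = 11)
    q <- quantify_section(sec$image)
    expect_lt(abs(q$percent_fibrosis - 100 * f), 1)
    expect_equal(q$collagen_px + q$myocardium_px + q$excluded_px, 400 * 400)
  }
})

test_that("doubling resolution of the same scene barely moves the estimate", {
  sec <- generate_histology_image(histology_truth(0.2), 200, 200, seed = 5)
  q1 <- quantify_section(sec$image)
  up <- array(0, dim = c(400, 400, 3))
  for (ch in 1:3) {
    k <- sec$image[, , ch][rep(1:200, each = 2), rep(1:200, each = 2)]
    up[, , ch] <- k
  }
  q2 <- quantify_section(up)
  expect_lt(abs(q1$percent_fibrosis - q2$percent_fibrosis), 0.5)
})

test_that("PNG round trip preserves the quantification", {
  sec <- generate_histology_image(histology_truth(0.159), 200, 200, seed = 7)
  p <- file.path(tempdir(), "section.png")
  write_histology_image(sec, p)
  q_mem <- quantify_section(sec$image)
  q_disk <- quantify_section(p)
  expect_equal(q_disk$percent_fibrosis, q_mem$percent_fibrosis, tolerance = 0.2)
})

test_that("patient aggregation means sections and warns when sparse", {
  expect_equal(aggregate_patient(rep(20, 30))$percent_fibrosis, 20)
  expect_warning(a <- aggregate_patient(c(10, 20, 30)), "3 usable")
  expect_equal(a$percent_fibrosis, 20)
  expect_warning(z <- aggregate_patient(c(NA, NA)), "no usable")
  expect_true(is.na(z$percent_fibrosis))
})

test_that("generator rejects impossible truth configurations", {
  expect_error(histology_truth(1.2), "collagen_fraction")
  expect_error(histology_truth(-0.1), "collagen_fraction")
  expect_error(generate_histology_image(histology_truth(0.1,
                                                        endocardium_band_px = 300),
                                        320, 100, seed = 1),
               "too narrow")
})
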