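disc_contour <- function(r, center = c(0, 0), n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# disc with a semicircular bite, emulating the heat-sink defect
bitten_contour <- function(r = 20, bite_r = 8, n = 512L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(r * cos(th), r * sin(th))
  keep <- sqrt((pts[, 1] - r)^2 + pts[, 2]^2) > bite_r
  pts <- pts[keep, ]
  # insert the bite arc (centered on the rim at (r, 0))
  phi <- seq(asin(min(1, bite_r / r)) + pi / 2, 3 * pi / 2 -
               asin(min(1, bite_r / r)), length.out = 120L)
  bite <- cbind(r + bite_r * cos(phi + pi), bite_r * sin(phi + pi))
  bite <- bite[sqrt(rowSums(bite^2)) < r + 1e-9, , drop = FALSE]
  # order all points by angle for a simple closed polygon
  all <- rbind(pts, bite)
  all[order(atan2(all[, 2], all[, 1])), ]
}

test_that("level-set segmentation recovers a noisy disc to sub-pixel", {
  truth <- disc_contour(20)
  fx <- make_slice_image(truth, spacing = 0.25, noise_sd = 0.05,
                         blur_px = 1, seed = 13)
  got <- segment_boundary(fx$scan)
  ctr <- colMeans(fx$truth)
  radii <- sqrt((got[, 1] - ctr[1])^2 + (got[, 2] - ctr[2])^2)
  rms_px <- sqrt(mean((radii - 20)^2)) / fx$scan$spacing
  expect_lt(rms_px, 0.5)
})

test_that("segmentation reproduces a heat-sink bite within 2% area", {
  truth <- bitten_contour()
  fx <- make_slice_image(truth, spacing = 0.25, noise_sd = 0.05,
                         blur_px = 1, seed = 7)
  got <- segment_boundary(fx$scan)
  a_true <- abs(polygon_area(fx$truth))
  a_got <- abs(polygon_area(got))
  expect_equal(a_got, a_true, tolerance = 0.02)
  # the concavity is reproduced: some boundary points lie well inside
  # the convex disc radius near the bite
  ctr <- colMeans(disc_contour(20) + 0)
  expect_lt(min(surface_error(got, fx$truth)$mean_error), 0.5)
})

test_that("blank images are a segmentation error", {
  blank <- slice_scan(matrix(0.5, 80, 80), spacing = 0.25)
  expect_error(segment_boundary(blank), "segmentation error")
})

test_that("synthetic slice images are deterministic with known area", {
  truth <- disc_contour(15)
  a <- make_slice_image(truth, spacing = 0.1, noise_sd = 0.05, seed = 7)
  b <- make_slice_image(truth, spacing = 0.1, noise_sd = 0.05, seed = 7)
  expect_identical(a$scan$image, b$scan$image)

  # rasterised area matches the polygon area at fine pixels
  clean <- make_slice_image(truth, spacing = 0.1, noise_sd = 0,
                            blur_px = 0, seed = 1)
  frac <- mean(clean$scan$image > 0.5)
  a_px <- frac * prod(dim(clean$scan$image)) * 0.1^2
  expect_equal(a_px, abs(polygon_area(truth)), tolerance = 0.01)
})

test_that("slice scans round-trip through PNG with spacing sidecar", {
  truth <- disc_contour(10)
  fx <- make_slice_image(truth, spacing = 0.25, noise_sd = 0.03, seed = 3)
  f <- tempfile(fileext = ".png")
  write_slice_scan(fx$scan, f)
  back <- read_slice_scan(f)
  expect_equal(back$spacing, 0.25)
  expect_equal(back$plane, fx$scan$plane)
  # 16-bit PNG quantisation
  expect_lt(max(abs(back$image - fx$scan$image)), 1 / 255)
  expect_equal(dim(back$image), dim(fx$scan$image))
})
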