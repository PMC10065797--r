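test_that("slice selection picks the 25/50/75% planes with half-up rounding", {
  # oracle: 0-based round(q*(n-1)) half-up, returned 1-based
  oracle <- function(n) as.integer(floor(c(0.25, 0.5, 0.75) * (n - 1) + 0.5)) + 1L
  for (n in 5:60) {
    got <- select_slices(n)
    expect_identical(got, oracle(n))
    expect_true(all(diff(got) > 0))
    expect_gte(got[1], 1L)
    expect_lte(got[3], n)
  }
  expect_identical(select_slices(21), c(6L, 11L, 16L))
  expect_error(select_slices(3), "at least 4")
  expect_error(select_slices(4), "collide")
})

test_that("LoG quality is unit-calibrated on a matched Gaussian blob", {
  sigma <- 13 / (2 * sqrt(2))
  xs <- matrix(rep(0:63, each = 64), 64)
  ys <- t(xs)
  blob <- exp(-((xs - 32)^2 + (ys - 32)^2) / (2 * sigma^2))
  img <- array(c(blob, 0 * blob), dim = c(64, 64, 2))  # unit peak, green only
  det <- detect_nuclei(img, diameter_px = 13)
  expect_equal(nrow(det), 1)
  expect_equal(det$quality, 1, tolerance = 0.01)
  expect_equal(det$x_px, 32)
  expect_equal(det$y_px, 32)
  # quality scales linearly with peak intensity
  det5 <- detect_nuclei(array(c(5 * blob, 0 * blob), dim = c(64, 64, 2)),
                        diameter_px = 13)
  expect_equal(det5$quality, 5 * det$quality, tolerance = 1e-9)
  # matrix input is duplicated into both channels, so the summed response
  # doubles
  detm <- detect_nuclei(blob, diameter_px = 13)
  expect_equal(detm$quality, 2 * det$quality, tolerance = 1e-9)
})

test_that("detection recovers a planted grid of cells with channel means ordered", {
  set.seed(12)
  gx <- rep(seq(20, 230, by = 30), times = 8)
  gy <- rep(seq(20, 230, by = 30), each = 8)
  cells <- data.frame(x = gx + runif(64, -3, 3), y = gy + runif(64, -3, 3),
                      green = runif(64, 80, 120), red = runif(64, 20, 60))
  sim <- simulate_lg_image(cells, shape = c(256, 256), blob_sigma_px = 4.6,
                           noise_sd = 2, seed = 3)
  det <- detect_nuclei(sim$image, diameter_px = 13, quality_threshold = 10)
  expect_equal(nrow(det), 64)
  # match detections to truth by nearest centroid; all within 2 px
  for (i in seq_len(64)) {
    d2 <- (det$x_px - cells$x[i])^2 + (det$y_px - cells$y[i])^2
    j <- which.min(d2)
    expect_lt(sqrt(d2[j]), 2)
    # disc means preserve the channel ordering (green brighter than red here)
    expect_gt(det$green[j], det$red[j])
  }
  # blank image and flat image give no detections
  expect_equal(nrow(detect_nuclei(matrix(0, 64, 64))), 0)
  expect_equal(nrow(detect_nuclei(matrix(7, 64, 64), quality_threshold = 0.2)),
               0)
  expect_error(detect_nuclei(matrix(1, 10, 10), diameter_px = 2), ">= 3")
  expect_error(detect_nuclei(matrix(1, 10, 10), diameter_px = 12), "exceeds")
})

test_that("non-maximum suppression keeps one detection per touching pair", {
  sigma <- 13 / (2 * sqrt(2))
  cells <- data.frame(x = c(30, 33), y = c(30, 30),
                      green = c(100, 90), red = c(10, 10))
  sim <- simulate_lg_image(cells, shape = c(64, 64), blob_sigma_px = sigma)
  det <- detect_nuclei(sim$image, diameter_px = 13, quality_threshold = 10)
  expect_equal(nrow(det), 1)
  # well-separated pair stays two
  cells2 <- data.frame(x = c(15, 45), y = c(30, 30),
                       green = c(100, 90), red = c(10, 10))
  sim2 <- simulate_lg_image(cells2, shape = c(64, 64), blob_sigma_px = sigma)
  expect_equal(nrow(detect_nuclei(sim2$image, diameter_px = 13,
                                  quality_threshold = 10)), 2)
})

test_that("subsampling is a seeded uniform draw without replacement", {
  rec <- data.frame(cell_id = 1:100, green = runif(100), red = runif(100))
  a <- subsample_cells(rec, 30, seed = 4)
  b <- subsample_cells(rec, 30, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 30)
  expect_false(any(duplicated(a$cell_id)))
  expect_true(all(a$cell_id %in% rec$cell_id))
  c2 <- subsample_cells(rec, 30, seed = 5)
  expect_false(identical(a$cell_id, c2$cell_id))
  expect_error(subsample_cells(rec, 101), "available")
  # uniformity: each record selected ~n/N of the time across seeds
  hits <- integer(100)
  for (s in 1:400) {
    hits[subsample_cells(rec, 30, seed = s)$cell_id] <-
      hits[subsample_cells(rec, 30, seed = s)$cell_id] + 1L
  }
  expect_true(all(hits > 60 & hits < 180))  # binomial(400, 0.3) bounds
})

test_that("Otsu threshold separates two well-separated modes", {
  set.seed(14)
  x <- c(rnorm(400, 10, 1), rnorm(400, 50, 2))
  thr <- otsu_threshold(x)
  expect_gt(thr, 15)
  expect_lt(thr, 45)
  expect_equal(otsu_threshold(rep(3, 10)), 3)
})

test_that("quadrant gating counts match a vector oracle and sum to n", {
  set.seed(15)
  rec <- data.frame(green = 10^runif(500, 0, 3), red = 10^runif(500, 0, 3))
  gt <- 40; rt <- 100
  out <- classify_quadrants(rec, gt, rt)
  expect_equal(sum(out$counts), 500)
  expect_equal(unname(out$counts["GhighRlow"]),
               sum(rec$green >= gt & rec$red < rt))
  expect_equal(unname(out$counts["GhighRhigh"]),
               sum(rec$green >= gt & rec$red >= rt))
  expect_equal(unname(out$counts["GlowRhigh"]),
               sum(rec$green < gt & rec$red >= rt))
  expect_equal(unname(out$counts["GlowRlow"]),
               sum(rec$green < gt & rec$red < rt))
  # "high" is boundary-inclusive
  one <- classify_quadrants(data.frame(green = 40, red = 99), gt, rt)
  expect_identical(one$records$quadrant, "GhighRlow")
  expect_error(classify_quadrants(rec, -1, 10), "> 0")
})

test_that("Otsu-derived gates split a bimodal population as labeled", {
  set.seed(16)
  n <- 200
  truth <- sample(c("GhighRlow", "GlowRhigh"), n, replace = TRUE)
  rec <- data.frame(
    green = ifelse(truth == "GhighRlow", 10^rnorm(n, 2.5, 0.1),
                   10^rnorm(n, 0.5, 0.1)),
    red = ifelse(truth == "GlowRhigh", 10^rnorm(n, 2.5, 0.1),
                 10^rnorm(n, 0.5, 0.1)))
  out <- classify_quadrants(rec)  # thresholds from Otsu on log10
  expect_identical(out$records$quadrant, truth)
  expect_gt(out$thresholds[["g_threshold"]], 10)
  expect_lt(out$thresholds[["g_threshold"]], 100)
})

test_that("the full histo-cytometry chain preserves population proportions", {
  # plant 2 well-separated populations, detect, subsample, gate
  set.seed(17)
  xs <- rep(seq(20, 230, by = 30), times = 8)
  ys <- rep(seq(20, 230, by = 30), each = 8)
  is_prog <- rep(c(TRUE, FALSE), length.out = 64)   # progenitor: green-high
  cells <- data.frame(x = xs, y = ys,
                      green = ifelse(is_prog, 120, 8),
                      red = ifelse(is_prog, 8, 120))
  sim <- simulate_lg_image(cells, shape = c(256, 256), blob_sigma_px = 4.6,
                           noise_sd = 1, seed = 2)
  det <- detect_nuclei(sim$image, diameter_px = 13, quality_threshold = 5)
  expect_equal(nrow(det), 64)
  sub <- subsample_cells(det, 40, seed = 3)
  out <- classify_quadrants(sub)
  expect_equal(sum(out$counts), 40)
  expect_equal(unname(out$counts["GhighRhigh"]), 0)
  expect_equal(unname(out$counts["GlowRlow"]), 0)
  expect_gt(min(out$counts[c("GhighRlow", "GlowRhigh")]), 10)
})
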