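# Histo-cytometry: slice selection, LoG nucleus detection on two-channel
# images, seeded random subsampling and high/low quadrant gating.

#' Select the 25/50/75% slices of a z-stack
#'
#' Unbiased slice choice across samples: the slices at 25%, 50% and 75% of
#' the stack thickness, i.e. indices \code{round(q * (n - 1))} (half-up
#' rounding, 0-based) converted to R's 1-based indexing. Errors when the
#' three quantile indices collide (n < 5).
#'
#' @param n_slices number of z slices (>= 4).
#' @return strictly increasing integer vector of three 1-based indices.
#' @export
select_slices <- function(n_slices) {
  if (n_slices < 4) stop("need at least 4 slices, got ", n_slices)
  idx0 <- floor(c(0.25, 0.5, 0.75) * (n_slices - 1) + 0.5)
  if (any(diff(idx0) <= 0))
    stop("quantile slice indices collide for n_slices = ", n_slices,
         "; need n_slices >= 5")
  as.integer(idx0 + 1L)
}

# analytic LoG kernel scaled so a matched unit-peak Gaussian blob scores 1
.log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  g <- seq(-r, r)
  xs <- matrix(rep(g, each = length(g)), length(g))
  ys <- t(xs)
  r2 <- xs^2 + ys^2
  gauss <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  k <- -2 * sigma^2 * ((r2 - 2 * sigma^2) / sigma^4) * gauss
  k - mean(k)  # zero-sum: flat background gives zero response
}

#' Detect nuclei with a Laplacian-of-Gaussian blob detector
#'
#' Runs scale-normalized LoG detection at \code{sigma = diameter / (2 sqrt 2)}
#' on the channel sum (so dim-green/bright-red cells are not missed),
#' keeps local maxima at or above \code{quality_threshold}, applies
#' radius-based non-maximum suppression (minimum separation diameter/2),
#' and measures per-cell channel means within a disc of radius diameter/2.
#' Quality is unit-normalized: an ideal Gaussian blob of matched sigma and
#' unit peak scores 1 (this scale is not equivalent to other software's
#' quality values).
#'
#' @param image height x width x 2 array (channels green, red), or a matrix
#'   (single channel used for both detection and measurement).
#' @param diameter_px blob diameter in pixels (>= 3, default 13).
#' @param quality_threshold minimum detector response (default 0.2 per unit
#'   peak intensity; absolute on the image's intensity scale).
#' @param slice_index value recorded in the output's slice column.
#' @return data frame of cell records: cell_id, slice_index, x_px, y_px
#'   (0-based pixel coordinates), green, red, quality.
#' @export
detect_nuclei <- function(image, diameter_px = 13, quality_threshold = 0.2,
                          slice_index = 1L) {
  if (is.matrix(image)) image <- array(rep(image, 2),
                                       dim = c(dim(image), 2))
  h <- dim(image)[1]; w <- dim(image)[2]
  empty <- data.frame(cell_id = integer(0), slice_index = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      green = numeric(0), red = numeric(0),
                      quality = numeric(0))
  if (diameter_px < 3) stop("parameter error: diameter must be >= 3 px")
  if (diameter_px > min(h, w))
    stop("parameter error: diameter exceeds image side")
  chsum <- image[, , 1] + image[, , 2]
  if (all(chsum == 0)) return(empty)
  sigma <- diameter_px / (2 * sqrt(2))
  resp <- EBImage::filter2(chsum, .log_kernel(sigma), boundary = "replicate")
  # strict 8-neighbour local maxima above threshold
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- resp
  ismax <- resp >= quality_threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    ismax <- ismax & (resp > nb | (resp == nb & (dy > 0 | (dy == 0 & dx > 0))))
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  q <- resp[ismax]
  ord <- order(q, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; q <- q[ord]
  # greedy non-maximum suppression at radius diameter/2
  keep <- logical(nrow(idx))
  min_sep2 <- (diameter_px / 2)^2
  for (i in seq_len(nrow(idx))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- idx[keep, , drop = FALSE]
      d2 <- (kept[, 1] - idx[i, 1])^2 + (kept[, 2] - idx[i, 2])^2
      ok <- all(d2 >= min_sep2)
    }
    keep[i] <- ok
  }
  idx <- idx[keep, , drop = FALSE]; q <- q[keep]
  # per-cell channel means within a disc of radius diameter/2
  rad <- diameter_px / 2
  meas <- t(vapply(seq_len(nrow(idx)), function(i) {
    cy <- idx[i, 1]; cx <- idx[i, 2]
    yy <- max(1, floor(cy - rad)):min(h, ceiling(cy + rad))
    xx <- max(1, floor(cx - rad)):min(w, ceiling(cx + rad))
    dd <- outer((yy - cy)^2, (xx - cx)^2, `+`)
    sel <- dd <= rad^2
    c(mean(image[yy, xx, 1][sel]), mean(image[yy, xx, 2][sel]))
  }, numeric(2)))
  data.frame(cell_id = seq_len(nrow(idx)),
             slice_index = slice_index,
             x_px = idx[, 2] - 1, y_px = idx[, 1] - 1,
             green = meas[, 1], red = meas[, 2],
             quality = q)
}

#' Random subsample of cell records
#'
#' Uniform subset without replacement drawn through a seeded shuffle; the
#' returned rows are in randomized order and the draw is deterministic per
#' seed.
#'
#' @param records data frame of cell records.
#' @param n subset size (<= nrow(records)).
#' @param seed RNG seed.
#' @return \code{n} rows of \code{records} in random order.
#' @export
subsample_cells <- function(records, n, seed = 1) {
  if (n > nrow(records))
    stop("requested ", n, " cells but only ", nrow(records), " available")
  with_seed(seed, records[sample(nrow(records), n), , drop = FALSE])
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based Otsu threshold (maximum between-class variance) used to
#' derive data-driven high/low gates.
#'
#' @param x numeric values.
#' @param nbins histogram resolution.
#' @return threshold value on the scale of \code{x}.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  # the between-class variance is flat across any empty gap between modes;
  # take the centre of the maximizing plateau, not its first bin
  mean(mids[bcv >= max(bcv) - 1e-12 * max(bcv)])
}

#' Gate cells into the four expression quadrants
#'
#' Assigns each cell to GFP-high/low x dsRed-high/low by thresholding the
#' channel means ("high" means at or above the threshold). When a threshold
#' is NA/NULL it is derived as the Otsu threshold on log10 intensities of
#' that channel (pooled over whatever records are passed, so conditions
#' compared together share gates).
#'
#' @param records data frame with \code{green} and \code{red} columns.
#' @param g_threshold,r_threshold gate values (a.u.), or NA/NULL for Otsu.
#' @return list with \code{records} (adding a \code{quadrant} column),
#'   \code{counts} (named vector: GhighRlow, GhighRhigh, GlowRhigh,
#'   GlowRlow), and \code{thresholds}.
#' @export
classify_quadrants <- function(records, g_threshold = NULL,
                               r_threshold = NULL) {
  derive <- function(v, thr) {
    if (is.null(thr) || is.na(thr)) {
      eps <- min(v[v > 0], 1) / 2
      10^otsu_threshold(log10(pmax(v, eps)))
    } else thr
  }
  gt <- derive(records$green, g_threshold)
  rt <- derive(records$red, r_threshold)
  if (gt <= 0 || rt <= 0) stop("thresholds must be > 0")
  gh <- records$green >= gt
  rh <- records$red >= rt
  records$quadrant <- ifelse(gh & !rh, "GhighRlow",
                      ifelse(gh & rh, "GhighRhigh",
                      ifelse(!gh & rh, "GlowRhigh", "GlowRlow")))
  counts <- vapply(c("GhighRlow", "GhighRhigh", "GlowRhigh", "GlowRlow"),
                   function(qd) sum(records$quadrant == qd), numeric(1))
  list(records = records, counts = counts,
       thresholds = c(g_threshold = gt, r_threshold = rt))
}
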