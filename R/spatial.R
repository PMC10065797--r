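# Lobe alignment to the heart tube, 5x5 proportional binning of event
# locations, heat-map combination and correlation-category comparison.

#' Align a lobe and its event points to the heart tube
#'
#' Rotates points and boundary (smallest-magnitude rotation) so the heart
#' tube runs along the y-axis, then mirrors about the tube line if needed so
#' the lobe faces right (+x) and the tube sits on the left. The transform
#' (pivot, rotation angle, flip flag) is recorded and invertible.
#'
#' @param points n x 2 (or n x 3; z dropped) matrix of event positions (um).
#' @param geometry \code{\link{lg_geometry}}.
#' @return list with \code{points} (aligned n x 2), \code{boundary}
#'   (aligned polygon), \code{transform} (list pivot, angle_rad, flip).
#' @export
align_lobe <- function(points, geometry) {
  pts <- as.matrix(points)
  if (ncol(pts) > 2) pts <- pts[, 1:2, drop = FALSE]
  if (nrow(pts) < 1) stop("need at least one point")
  td <- geometry$tube_dir[1:2]
  if (sqrt(sum(td^2)) < 1e-9)
    stop("tube axis has no in-plane component")
  phi <- atan2(td[2], td[1])
  wrap <- function(a) atan2(sin(a), cos(a))
  cand <- c(wrap(pi / 2 - phi), wrap(-pi / 2 - phi))
  ang <- cand[which.min(abs(cand))]
  pivot <- geometry$tube_point[1:2]
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  xf <- function(m) sweep(sweep(m, 2, pivot) %*% t(rot), 2, pivot, `+`)
  ptsr <- xf(pts)
  bndr <- xf(geometry$lobe_boundary)
  flip <- mean(bndr[, 1]) < pivot[1]
  if (flip) {
    ptsr[, 1] <- 2 * pivot[1] - ptsr[, 1]
    bndr[, 1] <- 2 * pivot[1] - bndr[, 1]
  }
  list(points = ptsr, boundary = bndr,
       transform = list(pivot = pivot, angle_rad = ang, flip = flip))
}

#' Apply (or invert) an alignment transform to planar points
#'
#' @param points n x 2 matrix.
#' @param transform a transform from \code{\link{align_lobe}}.
#' @param inverse apply the inverse map.
#' @return transformed n x 2 matrix.
#' @export
apply_lobe_transform <- function(points, transform, inverse = FALSE) {
  m <- as.matrix(points)
  pivot <- transform$pivot
  rotm <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  doflip <- function(p) { p[, 1] <- 2 * pivot[1] - p[, 1]; p }
  if (!inverse) {
    m <- sweep(sweep(m, 2, pivot) %*% t(rotm(transform$angle_rad)), 2,
               pivot, `+`)
    if (transform$flip) m <- doflip(m)
  } else {
    if (transform$flip) m <- doflip(m)
    m <- sweep(sweep(m, 2, pivot) %*% t(rotm(-transform$angle_rad)), 2,
               pivot, `+`)
  }
  m
}

# signed polygon area (shoelace)
.polygon_area <- function(b) {
  x <- b[, 1]; y <- b[, 2]
  j <- c(2:nrow(b), 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Bin aligned event locations into a proportional grid heat map
#'
#' The bounding box of the (aligned) lobe boundary is divided into
#' \code{grid_n} equal segments per side (20% each for the default 5x5
#' grid). Bins are half-open \code{[k*w/n, (k+1)*w/n)} with the last bin
#' closed. Points outside the boundary polygon are excluded and counted.
#' Rows index distance from the heart tube (row 1 nearest the tube, i.e.
#' smallest x after alignment); columns index position along the tube (y).
#'
#' @param points aligned n x 2 event positions (um).
#' @param boundary aligned lobe-boundary polygon.
#' @param grid_n grid size (default 5).
#' @param transform optional alignment transform to record.
#' @return object of class \code{"lg_heatmap"}: \code{counts}
#'   (grid_n x grid_n), \code{bbox} (xmin, xmax, ymin, ymax),
#'   \code{transform}, \code{n_events_in}, \code{n_events_excluded},
#'   \code{grid_n}.
#' @export
build_heatmap <- function(points, boundary, grid_n = 5, transform = NULL) {
  if (grid_n < 1) stop("grid_n must be >= 1")
  pts <- as.matrix(points)
  bnd <- as.matrix(boundary)
  if (abs(.polygon_area(bnd)) < 1e-9)
    stop("geometry error: degenerate (zero-area) boundary polygon")
  bbox <- c(xmin = min(bnd[, 1]), xmax = max(bnd[, 1]),
            ymin = min(bnd[, 2]), ymax = max(bnd[, 2]))
  inside <- pracma::inpolygon(pts[, 1], pts[, 2], bnd[, 1], bnd[, 2],
                              boundary = TRUE)
  counts <- matrix(0L, grid_n, grid_n)
  binof <- function(v, lo, hi) {
    k <- floor((v - lo) / (hi - lo) * grid_n) + 1L
    pmin.int(pmax.int(k, 1L), grid_n)  # closed last bin; clamp fp edge cases
  }
  if (any(inside)) {
    ix <- binof(pts[inside, 1], bbox["xmin"], bbox["xmax"])
    iy <- binof(pts[inside, 2], bbox["ymin"], bbox["ymax"])
    for (i in seq_along(ix))
      counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  }
  structure(list(counts = counts, bbox = bbox, transform = transform,
                 n_events_in = sum(inside),
                 n_events_excluded = sum(!inside),
                 grid_n = grid_n),
            class = "lg_heatmap")
}

#' @export
print.lg_heatmap <- function(x, ...) {
  cat("<lg_heatmap>", x$grid_n, "x", x$grid_n, "grid,", x$n_events_in,
      "events binned,", x$n_events_excluded, "excluded\n")
  print(x$counts)
  invisible(x)
}

#' Combine per-video heat maps by element-wise summation
#'
#' @param maps list of \code{lg_heatmap} with identical grid size.
#' @return combined \code{lg_heatmap} (raw count sum; bbox/transform of the
#'   inputs are not carried over).
#' @export
combine_heatmaps <- function(maps) {
  if (!length(maps)) stop("no heat maps to combine")
  gn <- unique(vapply(maps, function(m) m$grid_n, numeric(1)))
  if (length(gn) != 1) stop("shape error: mismatched grid sizes")
  counts <- Reduce(`+`, lapply(maps, function(m) m$counts))
  structure(list(counts = counts, bbox = NULL, transform = NULL,
                 n_events_in = sum(vapply(maps, function(m) m$n_events_in,
                                          numeric(1))),
                 n_events_excluded = sum(vapply(maps,
                                                function(m) m$n_events_excluded,
                                                numeric(1))),
                 grid_n = gn),
            class = "lg_heatmap")
}

#' Compare two heat maps by Pearson correlation
#'
#' Computes the correlation of the flattened count grids and assigns the
#' conventional category: [0, 0.25) none, [0.25, 0.5) weak, [0.5, 0.75)
#' moderate, [0.75, 1] strong (boundaries assigned upward). A negative r is
#' reported as-is with category "none".
#'
#' @param a,b \code{lg_heatmap} with identical grid size and positive totals.
#' @return object of class \code{"correlation_report"}: \code{r},
#'   \code{category}.
#' @export
compare_heatmaps <- function(a, b) {
  if (a$grid_n != b$grid_n) stop("shape error: mismatched grid sizes")
  if (a$n_events_in == 0 || b$n_events_in == 0)
    stop("both heat maps must contain events")
  va <- as.numeric(a$counts); vb <- as.numeric(b$counts)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("undefined correlation: a map has zero variance across cells")
  r <- stats::cor(va, vb)
  category <- if (r < 0.25) "none" else if (r < 0.5) "weak"
  else if (r < 0.75) "moderate" else "strong"
  structure(list(r = r, category = category), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> r = %.3f (%s)\n", x$r, x$category))
  invisible(x)
}

#' Area-normalized lobe intensity
#'
#' Total reporter intensity (e.g. the gstD-GFP oxidative-stress reporter)
#' divided by the ROI or lobe area.
#'
#' @param total_intensity summed intensity (a.u.).
#' @param roi_area_um2 area (um^2, > 0).
#' @return intensity per um^2.
#' @export
area_normalized_intensity <- function(total_intensity, roi_area_um2) {
  if (any(roi_area_um2 <= 0)) stop("area must be > 0")
  total_intensity / roi_area_um2
}

#' Write a heat map to JSON
#' @param map \code{lg_heatmap}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_heatmap <- function(map, path) {
  jsonlite::write_json(list(
    counts = map$counts, bbox = map$bbox,
    transform = map$transform, n_events_in = map$n_events_in,
    n_events_excluded = map$n_events_excluded, grid_n = map$grid_n
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a heat map from JSON
#' @param path JSON path written by \code{\link{write_heatmap}}
#' @return \code{lg_heatmap}
#' @export
read_heatmap <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- if (is.matrix(j$counts)) j$counts else
    matrix(unlist(j$counts), j$grid_n, j$grid_n, byrow = TRUE)
  structure(list(counts = cm,
                 bbox = if (is.null(j$bbox)) NULL else unlist(j$bbox),
                 transform = j$transform,
                 n_events_in = j$n_events_in,
                 n_events_excluded = j$n_events_excluded,
                 grid_n = j$grid_n),
            class = "lg_heatmap")
}
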