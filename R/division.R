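# Mitosis kinetics (duration, critical size, daughter growth) and spatial
# orientation (rho/z class, angle to the heart tube, Q-Q normality,
# distances, mitotic index) in the cylindrical organ frame.

#' Duration of a mitotic event
#'
#' The onset of mitosis is defined as a fixed number of frames (default 40,
#' i.e. 10 min at 15 s frames) before nuclear-envelope breakdown, so the
#' reported duration is the breakdown-to-completion interval plus that
#' onset offset.
#'
#' @param t_breakdown_min nuclear-envelope-breakdown time (min).
#' @param t_complete_min time daughter nuclei are reformed (min).
#' @param config \code{\link{lg_config}} (uses \code{onset_offset_frames},
#'   \code{frame_interval_s}).
#' @return duration in minutes.
#' @export
division_duration <- function(t_breakdown_min, t_complete_min,
                              config = lg_config()) {
  if (any(t_complete_min <= t_breakdown_min))
    stop("data error: completion must be after breakdown")
  (t_complete_min - t_breakdown_min) +
    config$onset_offset_frames * config$frame_interval_s / 60
}

# rows of m normalized to unit length; zero rows are an error
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12)) stop("data error: zero-length axis vector")
  m / nrm
}

.as_axis_matrix <- function(axis_vec) {
  if (is.matrix(axis_vec)) axis_vec else matrix(axis_vec, nrow = 1)
}

#' Classify division axes as rho- or z-mitosis
#'
#' A division is a z-mitosis when its axis lies within a cone about the
#' dorsal-ventral axis: with \code{alpha = acos(|axis . z_dir|)}, the event
#' is \code{"z"} when \code{alpha <= rho_z_angle_threshold_deg} (boundary
#' inclusive to z, default 45 degrees) and \code{"rho"} otherwise.
#'
#' @param axis_vec length-3 vector or n x 3 matrix of division axes.
#' @param geometry \code{\link{lg_geometry}}.
#' @param config \code{\link{lg_config}}.
#' @return character vector of \code{"rho"} / \code{"z"}.
#' @export
classify_division_axis <- function(axis_vec, geometry, config = lg_config()) {
  m <- .unit_rows(.as_axis_matrix(axis_vec))
  d <- abs(m %*% geometry$z_dir)
  alpha <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  as.character(ifelse(alpha <= config$rho_z_angle_threshold_deg, "z", "rho"))
}

#' Orientation of a rho-mitosis relative to the heart tube
#'
#' The directed daughter1-to-daughter2 axis is projected onto the rho-phi
#' plane (perpendicular to the dorsal-ventral axis) and the angle to the
#' heart-tube direction is reported in degrees, folded to [0, 180):
#' an axis parallel to the tube gives 0, perpendicular in-plane gives 90,
#' and anti-parallel folds to 0. Relabeling the daughters maps
#' \code{theta} to \code{180 - theta}.
#'
#' @param axis_vec length-3 vector or n x 3 matrix (rho-classified axes).
#' @param geometry \code{\link{lg_geometry}}.
#' @return numeric angle(s) in degrees in [0, 180).
#' @export
orientation_to_heart_tube <- function(axis_vec, geometry) {
  m <- .unit_rows(.as_axis_matrix(axis_vec))
  z <- geometry$z_dir
  proj <- m - (m %*% z) %*% t(z)
  pn <- sqrt(rowSums(proj^2))
  if (any(pn < 1e-6))
    stop("numerically vertical axis: in-plane projection shorter than 1e-6")
  cosang <- (proj %*% geometry$tube_dir) / pn
  theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  theta <- as.numeric(theta)
  theta[theta >= 180 - 1e-9] <- 0  # fold the closed endpoint onto 0
  theta
}

#' Q-Q normality report for orientation angles
#'
#' Compares sample quantiles of the angles against the quantiles of a
#' normal with the sample mean and SD, with a reference line through the
#' first/third-quartile pairs (as \code{qqline} draws it). Linearity of the
#' points about that line is summarized as
#' \code{r_squared = 1 - SS_resid / SS_total}, clamped to [0, 1]; values
#' near 1 are consistent with a normal orientation distribution.
#'
#' @param theta_list numeric angles in degrees (>= 5 values, not all equal).
#' @return object of class \code{"qq_report"}: \code{sample_quantiles},
#'   \code{theoretical_quantiles}, \code{line_intercept}, \code{line_slope},
#'   \code{r_squared}.
#' @export
qq_orientation_bias <- function(theta_list) {
  n <- length(theta_list)
  if (n < 5) stop("need at least 5 angles, got ", n)
  if (stats::sd(theta_list) == 0)
    stop("degenerate sample: all angles identical")
  s <- sort(theta_list)
  tq <- stats::qnorm(stats::ppoints(n), mean(theta_list),
                     stats::sd(theta_list))
  qs <- stats::quantile(s, c(0.25, 0.75), names = FALSE, type = 7)
  qt <- stats::qnorm(c(0.25, 0.75), mean(theta_list), stats::sd(theta_list))
  slope <- (qs[2] - qs[1]) / (qt[2] - qt[1])
  intercept <- qs[1] - slope * qt[1]
  pred <- intercept + slope * tq
  r2 <- 1 - sum((s - pred)^2) / sum((s - mean(s))^2)
  structure(list(sample_quantiles = s, theoretical_quantiles = tq,
                 line_intercept = intercept, line_slope = slope,
                 r_squared = min(1, max(0, r2))),
            class = "qq_report")
}

#' @export
print.qq_report <- function(x, ...) {
  cat("<qq_report>", length(x$sample_quantiles), "angles, r^2 =",
      sprintf("%.4f", x$r_squared), "\n")
  invisible(x)
}

#' Critical-size metrics of a division event
#'
#' Reports the mother area 10 min before mitosis, the combined area of the
#' two daughters at the frame nearest 3 h post-mitosis, and each daughter's
#' fractional growth over the first 4 h. Missing daughter series yield NA
#' fields rather than an error.
#'
#' @param event a \code{division_event} (see
#'   \code{\link{simulate_division_cohort}}) with fields
#'   \code{mother_area_pre_um2}, \code{daughter_times_min},
#'   \code{daughter_areas_um2} (2 x n matrix).
#' @return list with \code{mother_area_pre_um2},
#'   \code{combined_daughter_area_3h_um2}, \code{growth_fraction_4h}
#'   (length 2).
#' @export
critical_size_metrics <- function(event) {
  out <- list(mother_area_pre_um2 = event$mother_area_pre_um2,
              combined_daughter_area_3h_um2 = NA_real_,
              growth_fraction_4h = c(NA_real_, NA_real_))
  tt <- event$daughter_times_min
  aa <- event$daughter_areas_um2
  if (is.null(tt) || is.null(aa)) return(out)
  if (max(tt) >= 180) {
    k3 <- which.min(abs(tt - 180))
    out$combined_daughter_area_3h_um2 <- sum(aa[, k3])
  }
  k0 <- which.min(abs(tt - 0))
  k4 <- which.min(abs(tt - 240))
  out$growth_fraction_4h <- (aa[, k4] - aa[, k0]) / aa[, k0]
  out
}

#' Mitotic index
#'
#' Fraction of progenitors in mitosis: pH3-positive progenitors divided by
#' all progenitors.
#'
#' @param n_ph3_pos_progenitors count of pH3+ dome+ cells.
#' @param n_progenitors count of dome+ cells (> 0).
#' @return exact ratio.
#' @export
mitotic_index <- function(n_ph3_pos_progenitors, n_progenitors) {
  if (n_progenitors <= 0) stop("undefined index: no progenitors counted")
  if (n_ph3_pos_progenitors < 0 || n_ph3_pos_progenitors > n_progenitors)
    stop("invalid counts: need 0 <= numerator <= denominator")
  n_ph3_pos_progenitors / n_progenitors
}

#' Distances of an event to the heart tube and the posterior end
#'
#' Perpendicular point-to-line distance to the heart-tube axis and the
#' Euclidean distance to the posterior end of the gland (the PSC position).
#'
#' @param event_position length-3 point or n x 3 matrix (um).
#' @param geometry \code{\link{lg_geometry}}.
#' @return list with numeric \code{dist_tube_um}, \code{dist_posterior_um}.
#' @export
event_distances <- function(event_position, geometry) {
  m <- .as_axis_matrix(event_position)
  rel <- sweep(m, 2, geometry$tube_point)
  along <- rel %*% geometry$tube_dir
  perp <- rel - along %*% t(geometry$tube_dir)
  relp <- sweep(m, 2, geometry$posterior_end)
  list(dist_tube_um = as.numeric(sqrt(rowSums(perp^2))),
       dist_posterior_um = as.numeric(sqrt(rowSums(relp^2))))
}

#' Flatten division events into a per-event table
#'
#' @param events list of \code{division_event}.
#' @return data frame with one row per event (timing, position, axis
#'   components, mother area, generative class if present).
#' @export
division_table <- function(events) {
  rows <- lapply(events, function(e) {
    data.frame(event_id = e$event_id,
               t_breakdown_min = e$t_breakdown_min,
               t_complete_min = e$t_complete_min,
               x_um = e$position_um[1], y_um = e$position_um[2],
               z_um = e$position_um[3],
               axis_x = e$axis_vec[1], axis_y = e$axis_vec[2],
               axis_z = e$axis_vec[3],
               mother_area_pre_um2 = e$mother_area_pre_um2 %||% NA_real_,
               true_class = e$true_class %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a division-event table from CSV
#'
#' Expected columns: event_id, t_breakdown_min, t_complete_min, x_um, y_um,
#' z_um, axis_x, axis_y, axis_z (optional mother_area_pre_um2, true_class).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_division_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "t_breakdown_min", "t_complete_min",
            "x_um", "y_um", "z_um", "axis_x", "axis_y", "axis_z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Per-event quantification and cohort summary of division events
#'
#' Computes, for each event, the mitosis duration, rho/z class, orientation
#' to the heart tube (rho-events only), and distances to the heart tube and
#' the posterior end; then summarizes the cohort (rho fraction and percent,
#' duration mean/SD overall and per class, mean mother area).
#'
#' @param events data frame as from \code{\link{division_table}} /
#'   \code{\link{read_division_events}}, or a list of division events.
#' @param geometry \code{\link{lg_geometry}}.
#' @param config \code{\link{lg_config}}.
#' @return list with \code{events} (per-event data frame adding
#'   duration_min, axis_class, theta_deg, dist_tube_um, dist_posterior_um)
#'   and \code{summary} (named list of cohort statistics).
#' @export
division_summary <- function(events, geometry = default_geometry(),
                             config = lg_config()) {
  df <- if (is.data.frame(events)) events else division_table(events)
  axes <- as.matrix(df[, c("axis_x", "axis_y", "axis_z")])
  df$duration_min <- division_duration(df$t_breakdown_min,
                                       df$t_complete_min, config)
  df$axis_class <- classify_division_axis(axes, geometry, config)
  df$theta_deg <- NA_real_
  is_rho <- df$axis_class == "rho"
  if (any(is_rho))
    df$theta_deg[is_rho] <-
      orientation_to_heart_tube(axes[is_rho, , drop = FALSE], geometry)
  d <- event_distances(as.matrix(df[, c("x_um", "y_um", "z_um")]), geometry)
  df$dist_tube_um <- d$dist_tube_um
  df$dist_posterior_um <- d$dist_posterior_um
  n <- nrow(df)
  smry <- list(
    n_events = n,
    n_rho = sum(is_rho), n_z = sum(!is_rho),
    rho_fraction = mean(is_rho),
    rho_percent = 100 * mean(is_rho),
    duration_mean_min = mean(df$duration_min),
    duration_sd_min = stats::sd(df$duration_min),
    duration_mean_rho_min = if (any(is_rho))
      mean(df$duration_min[is_rho]) else NA_real_,
    duration_mean_z_min = if (any(!is_rho))
      mean(df$duration_min[!is_rho]) else NA_real_,
    mother_area_mean_um2 = if ("mother_area_pre_um2" %in% names(df))
      mean(df$mother_area_pre_um2, na.rm = TRUE) else NA_real_
  )
  list(events = df, summary = smry)
}
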