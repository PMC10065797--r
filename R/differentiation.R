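# Normalization, dsRed:GFP ratio, sigmoid/linear trajectory classification
# and differentiation-rate estimation for dual-reporter tracks.

#' Jointly min-max normalize a dual-channel track
#'
#' Both channels are scaled by the same affine map,
#' \code{Norm.X_t = (X_t - min(G, R)) / (max(G, R) - min(G, R))}, where the
#' minimum and maximum are taken across the two markers jointly, so the
#' relative ordering within and between channels is preserved. The per-frame
#' dsRed:GFP ratio is \code{norm_red / max(norm_green, ratio_floor)}; the
#' floor (default 0.01) prevents division blow-ups once the green reporter
#' has decayed to the joint minimum.
#'
#' @param track an \code{\link{intensity_track}}.
#' @param ratio_floor lower bound on the normalized green denominator.
#' @return object of class \code{"normalized_track"} with fields
#'   \code{cell_id}, \code{times_min}, \code{norm_green}, \code{norm_red},
#'   \code{ratio}, \code{norm_min}, \code{norm_max}, \code{label}.
#' @export
normalize_dual_channel <- function(track, ratio_floor = 0.01) {
  validate_track(track)
  mn <- min(track$green, track$red)
  mx <- max(track$green, track$red)
  if (mx <= mn)
    stop("degenerate track '", track$cell_id,
         "': constant equal channels (max = min)")
  ng <- (track$green - mn) / (mx - mn)
  nr <- (track$red - mn) / (mx - mn)
  structure(list(
    cell_id = track$cell_id,
    times_min = track$times_min,
    norm_green = ng, norm_red = nr,
    ratio = nr / pmax(ng, ratio_floor),
    norm_min = mn, norm_max = mx,
    label = track$label
  ), class = "normalized_track")
}

#' @export
print.normalized_track <- function(x, ...) {
  cat("<normalized_track> cell", x$cell_id, "-", length(x$times_min),
      "frames, ratio range",
      sprintf("[%.3g, %.3g]", min(x$ratio), max(x$ratio)), "\n")
  invisible(x)
}

# small-sample corrected AIC from a residual sum of squares; the RSS floor
# keeps exact (noiseless) fits comparable instead of driving log(RSS) to -Inf
.aicc <- function(rss, n, k) {
  rss <- max(rss, n * 1e-24)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# least-squares 4-parameter logistic fit of ratio vs time; NULL on failure
fit_logistic_ratio <- function(t, y) {
  b0 <- min(y); A0 <- max(y) - min(y)
  half <- b0 + A0 / 2
  above <- which(y >= half)
  t00 <- if (length(above)) t[above[1]] else stats::median(t)
  start <- list(b = b0, A = max(A0, 1e-6), t0 = t00,
                tau = (max(t) - min(t)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + A / (1 + exp(-(t - t0) / tau)),
                      start = start,
                      lower = c(b = -Inf, A = 0, t0 = -Inf, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  list(pars = p, rss = sum(stats::resid(fit)^2),
       resid_sd = sqrt(sum(stats::resid(fit)^2) / max(1, length(y) - 4)))
}

#' Classify a differentiation trajectory as sigmoid or linear
#'
#' Fits both a straight line and a 4-parameter logistic
#' \code{b + A / (1 + exp(-(t - t0) / tau))} to the dsRed:GFP ratio versus
#' time by least squares and selects the class by corrected AIC with an
#' ambiguity margin: among tracks where the logistic is a valid sigmoid
#' candidate, \code{|AICc_lin - AICc_log| < margin} yields
#' \code{"ambiguous"}. The logistic is a valid candidate only when its
#' midpoint and its whole 10-90% fast phase lie inside the observed time
#' window and its amplitude exceeds twice the logistic residual SD;
#' otherwise the track is called linear (a ratio rising without an
#' in-window switch and saturation is constant-rate differentiation, not a
#' sigmoid switch). A non-convergent logistic falls back to linear with a
#' warning. The differentiation rate is then estimated with
#' \code{\link{fit_differentiation_rate}}.
#'
#' @param norm a \code{\link{normalize_dual_channel}} result.
#' @param config an \code{\link{lg_config}} (uses \code{aicc_margin},
#'   \code{fast_phase_quantiles}, \code{smoothing_window}).
#' @return object of class \code{"trajectory_fit"}: fields \code{cell_id},
#'   \code{class} (sigmoid/linear/ambiguous), \code{logistic} (named vector
#'   b, A, t0, tau or NULL), \code{linear} (intercept, slope),
#'   \code{delta_aicc} (linear AICc minus logistic AICc; NA on fallback),
#'   \code{rate}, \code{fast_phase}, \code{resid_sd}, \code{t_range}.
#' @export
classify_trajectory <- function(norm, config = lg_config()) {
  t <- norm$times_min
  y <- norm$ratio
  if (length(t) < 10)
    stop("insufficient data: need >= 10 frames, got ", length(t))
  w <- config$smoothing_window
  if (w > 1) {
    k <- rep(1 / w, w)
    y <- stats::filter(y, k, sides = 2)
    keep <- !is.na(y)
    y <- as.numeric(y[keep]); t <- t[keep]
  }
  n <- length(y)
  lin <- stats::lm.fit(cbind(1, t), y)
  lin_rss <- sum(lin$residuals^2)
  lin_sd <- sqrt(lin_rss / max(1, n - 2))
  log_fit <- fit_logistic_ratio(t, y)

  cls <- "linear"; delta <- NA_real_
  if (is.null(log_fit)) {
    warning("logistic fit did not converge for cell '", norm$cell_id,
            "'; falling back to linear")
  } else {
    delta <- .aicc(lin_rss, n, 3) - .aicc(log_fit$rss, n, 5)
    p <- log_fit$pars
    q <- config$fast_phase_quantiles
    cross <- p[["t0"]] + p[["tau"]] * log(q / (1 - q))
    # a genuine sigmoid shows its slow phase, switch and saturation inside
    # the recording: midpoint and the full fast phase must lie in-window,
    # and the amplitude must rise above the fit noise
    sane <- p[["t0"]] >= min(t) && p[["t0"]] <= max(t) &&
      p[["A"]] > 2 * log_fit$resid_sd &&
      cross[1] >= min(t) && cross[2] <= max(t)
    cls <- if (!sane) "linear"
    else if (abs(delta) < config$aicc_margin) "ambiguous"
    else if (delta > 0) "sigmoid" else "linear"
  }

  fit <- structure(list(
    cell_id = norm$cell_id,
    class = cls,
    logistic = if (is.null(log_fit)) NULL else log_fit$pars,
    linear = c(intercept = unname(lin$coefficients[1]),
               slope = unname(lin$coefficients[2])),
    delta_aicc = delta,
    rate = NA_real_,
    fast_phase = NULL,
    resid_sd = if (cls == "sigmoid") log_fit$resid_sd else lin_sd,
    t_range = range(t)
  ), class = "trajectory_fit")

  if (cls == "sigmoid")
    fit$fast_phase <- fast_phase_bounds(fit, config)
  if (cls != "ambiguous")
    fit$rate <- fit_differentiation_rate(norm, fit)
  fit
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit> cell", x$cell_id, "- class:", x$class,
      if (!is.na(x$rate)) sprintf("rate %.4g per min", x$rate) else "",
      "\n")
  invisible(x)
}

#' Fast-phase bounds of a sigmoid trajectory
#'
#' The fast phase is the 10-90% amplitude window of the fitted logistic:
#' the crossing of \code{b + q*A} is at \code{t0 + tau * log(q / (1 - q))},
#' so with the default quantiles the duration is \code{log(81) * tau}
#' exactly. Bounds falling outside the observed window are clipped with a
#' warning.
#'
#' @param fit a \code{trajectory_fit} with \code{class = "sigmoid"}.
#' @param config \code{\link{lg_config}} (uses \code{fast_phase_quantiles}).
#' @return numeric \code{c(t_start, t_end)} in minutes.
#' @export
fast_phase_bounds <- function(fit, config = lg_config()) {
  if (!identical(fit$class, "sigmoid") || is.null(fit$logistic))
    stop("fast_phase_bounds requires a fitted logistic (sigmoid class)")
  p <- fit$logistic
  q <- config$fast_phase_quantiles
  bounds <- p[["t0"]] + p[["tau"]] * log(q / (1 - q))
  if (!is.null(fit$t_range) &&
      (bounds[1] < fit$t_range[1] || bounds[2] > fit$t_range[2])) {
    warning("fast phase clipped to the observed time window for cell '",
            fit$cell_id, "'")
    bounds <- pmin(pmax(bounds, fit$t_range[1]), fit$t_range[2])
  }
  c(t_start = bounds[1], t_end = bounds[2])
}

#' Fold change of per-video differentiation-activation rates
#'
#' Differentiation activation is counted as events per video; the fold
#' change is the test-group rate divided by the reference rate (e.g. 25
#' events over 6 videos vs 11 events over 8 videos gives a fold change of
#' about 3.03).
#'
#' @param n_events_test,n_videos_test event and video counts, test group.
#' @param n_events_ref,n_videos_ref event and video counts, reference group.
#' @return list with \code{rate_test}, \code{rate_ref} (events per video)
#'   and \code{fold_change}.
#' @export
activation_fold_change <- function(n_events_test, n_videos_test,
                                   n_events_ref, n_videos_ref) {
  if (n_videos_test <= 0 || n_videos_ref <= 0)
    stop("video counts must be > 0")
  if (n_events_test < 0 || n_events_ref < 0)
    stop("event counts must be >= 0")
  if (n_events_ref == 0)
    stop("undefined fold change: reference group has no events")
  rate_test <- n_events_test / n_videos_test
  rate_ref <- n_events_ref / n_videos_ref
  list(rate_test = rate_test, rate_ref = rate_ref,
       fold_change = rate_test / rate_ref)
}

#' Differentiation rate (slope of the ratio curve)
#'
#' \code{Slope = d(dsRed:GFP ratio) / dt}: the ordinary least-squares slope
#' of ratio versus time, restricted to the fast phase for sigmoid tracks
#' and taken over the whole track for linear ones (ratio units per minute).
#'
#' @param norm the \code{normalized_track} the fit was computed from.
#' @param fit its \code{trajectory_fit} (class must not be ambiguous).
#' @return slope in ratio units per minute.
#' @export
fit_differentiation_rate <- function(norm, fit) {
  if (fit$class == "ambiguous")
    stop("rate is undefined for ambiguous trajectories")
  t <- norm$times_min; y <- norm$ratio
  if (fit$class == "sigmoid") {
    fp <- fit$fast_phase
    keep <- t >= fp[1] & t <= fp[2]
    if (sum(keep) < 3)
      stop("insufficient data: fast phase covers fewer than 3 frames")
    t <- t[keep]; y <- y[keep]
  }
  unname(stats::lm.fit(cbind(1, t), y)$coefficients[2])
}
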