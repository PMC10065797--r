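# Labeled synthetic inputs emulating the statistical structure of the
# live-imaging recordings: dual-reporter differentiation trajectories,
# mitosis cohorts in a lobe-shaped volume, nucleus blob images and FUCCI
# traces. Every generator is a pure function of (parameters, seed).

#' Evaluate code under a fixed RNG seed
#'
#' Runs \code{code} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded simulations never disturb the
#' surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# inverse-CDF draw from N(mean, sd) truncated to [lo, hi]
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# parent (mu, sigma) such that N(mu, sigma) truncated below at `lo` has the
# requested mean and sd; keeps published sample moments reproducible even
# when the truncation is not negligible
trunc_norm_params <- function(mean, sd, lo = 0) {
  if (sd == 0) return(c(mu = mean, sigma = 0))
  if (stats::pnorm(lo, mean, sd) < 1e-8) return(c(mu = mean, sigma = sd))
  moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma
    lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, sqrt(v))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    sum((mm - c(mean, sd))^2)
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Differentiation trajectory model
#'
#' Parameterizes the noiseless dual-reporter time course of one
#' differentiating progenitor. Sigmoid kinds: green declines as a logistic
#' centred at \code{t_mid} with timescale \code{tau}; red rises as a delayed
#' logistic (\code{delay} minutes after the green midpoint, plus an extra
#' low/low plateau of \code{intermediary_min} minutes for
#' \code{sigmoid_infected}). Linear kinds: green declines linearly and red
#' is constructed so that the jointly-normalized dsRed:GFP ratio rises at an
#' exactly constant rate, ending at \code{(R1-R0)/(G1-R0)}; the
#' \code{linear_infected} defaults put that end ratio at 1.5x the wild-type
#' one (the ~50% higher dsRed:GFP seen after infection) with red completing
#' most of its rise early.
#'
#' @param kind one of \code{"sigmoid_wt"}, \code{"sigmoid_infected"},
#'   \code{"linear_wt"}, \code{"linear_infected"}.
#' @param G0,G1 start/end green levels (a.u.); \code{G0 > G1}.
#' @param R0,R1 start/end red levels (a.u.); linear kinds require
#'   \code{R0 >= 0.5 * G0} (cells already co-express both reporters).
#' @param t_mid green logistic midpoint (min; sigmoid kinds).
#' @param tau logistic timescale (min, > 0).
#' @param delay red-onset lag after the green midpoint (min).
#' @param intermediary_min extra low/low plateau before the red rise (min;
#'   \code{sigmoid_infected}).
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   intensity noise (>= 0).
#' @return object of class \code{"differentiation_model"}.
#' @export
differentiation_model <- function(kind = c("sigmoid_wt", "sigmoid_infected",
                                           "linear_wt", "linear_infected"),
                                  G0 = NULL, G1 = NULL, R0 = NULL, R1 = NULL,
                                  t_mid = 150, tau = 15, delay = 25,
                                  intermediary_min = NULL, noise_cv = 0.1) {
  kind <- match.arg(kind)
  sig <- startsWith(kind, "sigmoid")
  if (is.null(G0)) G0 <- 100
  if (is.null(G1)) G1 <- if (sig) 10 else 80
  if (is.null(R0)) R0 <- if (sig) 6 else 50
  if (is.null(R1)) R1 <- if (sig) 90 else if (kind == "linear_wt") 80 else 95
  if (is.null(intermediary_min))
    intermediary_min <- if (kind == "sigmoid_infected") 60 else 0
  m <- structure(list(kind = kind, G0 = G0, G1 = G1, R0 = R0, R1 = R1,
                      t_mid = t_mid, tau = tau, delay = delay,
                      intermediary_min = intermediary_min,
                      noise_cv = noise_cv),
                 class = "differentiation_model")
  if (tau <= 0) stop("parameter error: tau must be > 0")
  if (noise_cv < 0) stop("parameter error: noise_cv must be >= 0")
  if (G0 <= G1) stop("parameter error: G0 must exceed G1")
  if (!sig && R0 < 0.5 * G0)
    stop("parameter error: linear kinds need R0 >= 0.5 * G0")
  if (!sig && R0 >= G1)
    stop("parameter error: linear kinds need R0 < G1 so the ratio stays finite")
  m
}

# noiseless channel curves of a differentiation model on a time grid (min)
differentiation_curves <- function(model, times_min) {
  t <- times_min
  if (startsWith(model$kind, "sigmoid")) {
    g <- model$G1 + (model$G0 - model$G1) /
      (1 + exp((t - model$t_mid) / model$tau))
    t_red <- model$t_mid + model$delay + model$intermediary_min
    r <- model$R0 + (model$R1 - model$R0) /
      (1 + exp(-(t - t_red) / model$tau))
  } else {
    total <- max(t) - min(t)
    u <- (t - min(t)) / total
    g <- model$G0 + (model$G1 - model$G0) * u
    # red chosen so (R - R0)/(G - R0) = u * ratio_end exactly
    ratio_end <- (model$R1 - model$R0) / (model$G1 - model$R0)
    r <- model$R0 + ratio_end * u * (g - model$R0)
  }
  list(green = g, red = r)
}

#' Simulate one labeled differentiation track
#'
#' Evaluates the model's noiseless channel curves on a uniform frame grid and
#' applies multiplicative Gaussian noise, \code{x * (1 + N(0, cv^2))},
#' clipped at zero. The returned track is labeled with the model kind.
#'
#' @param model a \code{\link{differentiation_model}}.
#' @param n_frames number of frames (>= 10; default 1320, i.e. 5.5 h at 15 s).
#' @param seed RNG seed.
#' @param frame_interval_s seconds per frame (default 15).
#' @param cell_id track identifier.
#' @return an \code{\link{intensity_track}} with \code{label = model$kind}.
#' @export
simulate_differentiation_track <- function(model, n_frames = 1320, seed = 1,
                                           frame_interval_s = 15,
                                           cell_id = "sim1") {
  if (!inherits(model, "differentiation_model"))
    stop("parameter error: model must be a differentiation_model")
  if (n_frames < 10) stop("parameter error: n_frames must be >= 10")
  frames <- seq_len(n_frames) - 1L
  times <- frames * frame_interval_s / 60
  cv <- differentiation_curves(model, times)
  with_seed(seed, {
    g <- pmax(0, cv$green * (1 + stats::rnorm(n_frames, 0, model$noise_cv)))
    r <- pmax(0, cv$red * (1 + stats::rnorm(n_frames, 0, model$noise_cv)))
    intensity_track(cell_id, frames, g, r,
                    frame_interval_s = frame_interval_s, label = model$kind)
  })
}

#' Division cohort model
#'
#' Statistical model of a cohort of progenitor mitoses: fraction of
#' rho-oriented divisions, mitosis duration and critical-size distributions
#' (moment-matched normals truncated at zero, so the sampled mean/SD match
#' the stated values), orientation-angle distribution for rho-events, and
#' the lobe's ellipsoidal semi-axes. Defaults reproduce the study's reported
#' statistics: 90% rho divisions, duration 57.74 +/- 27.58 min, critical
#' area 71.96 +/- 10.00 um^2, a 300 x 150 x 50 um lobe (semi-axes
#' 150 x 75 x 25).
#'
#' @param n_events number of mitoses.
#' @param p_rho probability a division is rho-oriented (default 0.9).
#' @param duration_mean_min,duration_sd_min mitosis duration moments
#'   (defaults 57.74, 27.58).
#' @param duration_mean_rho,duration_mean_z optional per-class duration means
#'   (e.g. 53.90 and 75.04 min); when NULL the shared mean is used.
#' @param critical_area_mean_um2,critical_area_sd_um2 pre-mitotic mother
#'   area moments (defaults 71.96, 10.00).
#' @param angle_mean_deg,angle_sd_deg truncated-normal orientation of
#'   rho-events on [0, 180) (defaults 90, 30).
#' @param lobe_semi_axes_um ellipsoid semi-axes (default c(150, 75, 25)).
#' @return object of class \code{"division_cohort_model"}.
#' @export
division_cohort_model <- function(n_events = 100, p_rho = 0.9,
                                  duration_mean_min = 57.74,
                                  duration_sd_min = 27.58,
                                  duration_mean_rho = NULL,
                                  duration_mean_z = NULL,
                                  critical_area_mean_um2 = 71.96,
                                  critical_area_sd_um2 = 10,
                                  angle_mean_deg = 90, angle_sd_deg = 30,
                                  lobe_semi_axes_um = c(150, 75, 25)) {
  if (p_rho < 0 || p_rho > 1) stop("parameter error: p_rho must be in [0, 1]")
  if (duration_sd_min < 0 || critical_area_sd_um2 < 0 || angle_sd_deg < 0)
    stop("parameter error: standard deviations must be >= 0")
  structure(as.list(environment()), class = "division_cohort_model")
}

#' Default lymph-gland geometry for simulation
#'
#' Heart tube along x through the origin, posterior end (PSC) at
#' \code{(150, 0, 0)}, dorsal-ventral axis along z, and an elliptical lobe
#' boundary adjacent to the tube with the given planar semi-axes.
#'
#' @param semi_axes_um planar semi-axes of the lobe (default c(150, 75)).
#' @param n_vertices boundary polygon resolution.
#' @return \code{\link{lg_geometry}}
#' @export
default_geometry <- function(semi_axes_um = c(150, 75), n_vertices = 72) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  boundary <- cbind(semi_axes_um[1] * cos(th),
                    75 + semi_axes_um[2] * sin(th))
  lg_geometry(tube_point = c(0, 0, 0), tube_dir = c(1, 0, 0),
              posterior_end = c(150, 0, 0), z_dir = c(0, 0, 1),
              lobe_boundary = boundary)
}

#' Simulate a cohort of division events
#'
#' Draws event positions uniformly inside the lobe ellipsoid (centred on the
#' lobe-boundary centroid), samples rho/z class, duration, mother area,
#' daughter growth and division-axis vectors. Rho-event axes lie near the
#' rho-phi plane (small dorsal-ventral tilt) at a truncated-normal angle to
#' the heart tube; z-event axes lie near the dorsal-ventral axis.
#'
#' @param model a \code{\link{division_cohort_model}}.
#' @param geometry an \code{\link{lg_geometry}}.
#' @param seed RNG seed.
#' @return list of division events (class \code{"division_event"}), each with
#'   timing, position, axis vector, mother area, daughter area series (5-min
#'   steps over 4 h), ring-pole distances, daughter reporter intensities and
#'   the generative class label (\code{true_class}).
#' @export
simulate_division_cohort <- function(model, geometry = default_geometry(),
                                     seed = 1) {
  n <- model$n_events
  if (n == 0) return(list())
  ctr <- c(colMeans(geometry$lobe_boundary), 0)
  ax <- model$lobe_semi_axes_um
  # durations must exceed the 10-min onset offset; match moments at that bound
  dur_all <- trunc_norm_params(model$duration_mean_min, model$duration_sd_min,
                               lo = 10.01)
  dur_rho <- if (is.null(model$duration_mean_rho)) dur_all else
    trunc_norm_params(model$duration_mean_rho, model$duration_sd_min,
                      lo = 10.01)
  dur_z <- if (is.null(model$duration_mean_z)) dur_all else
    trunc_norm_params(model$duration_mean_z, model$duration_sd_min,
                      lo = 10.01)
  area_p <- trunc_norm_params(model$critical_area_mean_um2,
                              model$critical_area_sd_um2, lo = 1)
  with_seed(seed, {
    events <- vector("list", n)
    for (i in seq_len(n)) {
      # uniform position in the ellipsoid by rejection
      repeat {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      pos <- ctr + u * ax
      is_rho <- stats::runif(1) < model$p_rho
      if (is_rho) {
        theta <- rtrunc_norm(1, model$angle_mean_deg, model$angle_sd_deg,
                             0, 180) * pi / 180
        tilt <- rtrunc_norm(1, 0, 10, -40, 40) * pi / 180
      } else {
        theta <- stats::runif(1, 0, 2 * pi)
        tilt <- (90 - abs(rtrunc_norm(1, 0, 10, -40, 40))) * pi / 180
      }
      # orthonormal in-plane frame: tube direction and its in-plane normal
      e1 <- geometry$tube_dir
      e3 <- geometry$z_dir
      e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
              e3[3] * e1[1] - e3[1] * e1[3],
              e3[1] * e1[2] - e3[2] * e1[1])
      axis <- cos(tilt) * (cos(theta) * e1 + sin(theta) * e2) +
        sin(tilt) * e3
      axis <- axis / sqrt(sum(axis^2))
      p <- if (is_rho) dur_rho else dur_z
      duration <- rtrunc_norm(1, p["mu"], p["sigma"], lo = 10.01)
      t_bd <- stats::runif(1, 0, 600)
      t_cp <- t_bd + duration - 10  # 40-frame (10 min) onset offset
      mother <- rtrunc_norm(1, area_p["mu"], area_p["sigma"], lo = 1)
      a0 <- mother / 2 * (1 + stats::rnorm(2, 0, 0.05))
      growth <- stats::runif(2, 0.20, 0.30)
      dt <- seq(0, 240, by = 5)
      areas <- rbind(a0[1] * (1 + growth[1] * dt / 240),
                     a0[2] * (1 + growth[2] * dt / 240))
      ring <- mother / 10 * (1 + stats::rnorm(2, 0, 0.03))
      events[[i]] <- structure(list(
        event_id = sprintf("ev%04d", i),
        t_breakdown_min = t_bd, t_complete_min = t_cp,
        position_um = pos, axis_vec = axis,
        mother_area_pre_um2 = mother,
        daughter_times_min = dt, daughter_areas_um2 = areas,
        ring_pole_distances_um = ring,
        daughter_jakstat = stats::rnorm(2, 100, 8),
        true_class = if (is_rho) "rho" else "z"
      ), class = "division_event")
    }
    events
  })
}

#' Simulate a two-channel nucleus blob image
#'
#' Renders each nucleus as an isotropic Gaussian spot of the given peak
#' intensities in both channels, adds Gaussian background noise, and clips
#' at zero. Overlapping (even identical) centroids are allowed and simply
#' sum. Returns the image with its ground-truth table.
#'
#' @param cells data frame with columns \code{x}, \code{y} (0-based pixel
#'   centroids), \code{green}, \code{red} (peak intensities).
#' @param shape image size \code{c(height, width)} in pixels.
#' @param blob_sigma_px Gaussian spot scale (> 0).
#' @param noise_sd additive noise SD (a.u.).
#' @param seed RNG seed.
#' @return list with \code{image} (height x width x 2 array, channels
#'   green, red) and \code{truth} (the input table with a cell_id column).
#' @export
simulate_lg_image <- function(cells, shape = c(256, 256), blob_sigma_px = 4,
                              noise_sd = 0, seed = 1) {
  if (blob_sigma_px <= 0) stop("parameter error: blob_sigma_px must be > 0")
  h <- shape[1]; w <- shape[2]
  img <- array(0, dim = c(h, w, 2))
  if (nrow(cells) > 0) {
    if (any(cells$x < 0 | cells$x > w - 1 | cells$y < 0 | cells$y > h - 1))
      stop("parameter error: centroid outside image shape")
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    ys <- matrix(rep(0:(h - 1), times = w), h, w)
    for (i in seq_len(nrow(cells))) {
      g2 <- exp(-((xs - cells$x[i])^2 + (ys - cells$y[i])^2) /
                  (2 * blob_sigma_px^2))
      img[, , 1] <- img[, , 1] + cells$green[i] * g2
      img[, , 2] <- img[, , 2] + cells$red[i] * g2
    }
  }
  if (noise_sd > 0) {
    img <- with_seed(seed,
                     img + array(stats::rnorm(length(img), 0, noise_sd),
                                 dim = dim(img)))
    img[img < 0] <- 0
  }
  truth <- if (nrow(cells)) cbind(cell_id = seq_len(nrow(cells)), cells) else
    cells
  list(image = img, truth = truth)
}

#' Simulate a FUCCI trace from a phase plan
#'
#' Generates E2f1-GFP / CycB-RFP intensity series following the degron
#' logic: E2f1-GFP high in G1 and G2, low in S; CycB-RFP high in S and G2,
#' low in G1; both low during M (nuclear-envelope breakdown). Frames are
#' assigned to phases over half-open duration intervals.
#'
#' @param phase_plan data frame with columns \code{phase} (G1, S, G2, M) and
#'   \code{duration_min} (> 0).
#' @param levels named list mapping each phase to \code{c(green, red)} mean
#'   levels.
#' @param noise_cv multiplicative noise CV.
#' @param seed RNG seed.
#' @param frame_interval_s seconds per frame (default 15).
#' @param cell_id trace identifier.
#' @return a \code{\link{fucci_trace}} whose \code{phases} field holds the
#'   true phase per frame.
#' @export
simulate_fucci_trace <- function(phase_plan,
                                 levels = list(G1 = c(100, 5), S = c(5, 100),
                                               G2 = c(100, 100), M = c(5, 5)),
                                 noise_cv = 0, seed = 1,
                                 frame_interval_s = 15, cell_id = "fucci1") {
  if (nrow(phase_plan) == 0)
    return(fucci_trace(cell_id, numeric(0), numeric(0), numeric(0),
                       character(0)))
  bad <- setdiff(unique(phase_plan$phase), c("G1", "S", "G2", "M"))
  if (length(bad))
    stop("parameter error: unknown phase label ", paste(bad, collapse = ", "))
  if (any(phase_plan$duration_min <= 0))
    stop("parameter error: durations must be > 0")
  dt_min <- frame_interval_s / 60
  n_per <- round(phase_plan$duration_min / dt_min)
  phases <- rep(phase_plan$phase, n_per)
  n <- length(phases)
  times <- (seq_len(n) - 1) * dt_min
  mu <- t(vapply(phases, function(p) levels[[p]], numeric(2)))
  with_seed(seed, {
    g <- pmax(0, mu[, 1] * (1 + stats::rnorm(n, 0, noise_cv)))
    r <- pmax(0, mu[, 2] * (1 + stats::rnorm(n, 0, noise_cv)))
    fucci_trace(cell_id, times, g, r, phases)
  })
}
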