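# programmatic fixtures shared across test files

# random valid tracks for oracle comparisons
random_tracks <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- sample(10:50, 1)
    intensity_track(paste0("r", i), seq_len(len) - 1,
                    runif(len, 0, 200), runif(len, 0, 200))
  })
}

# a noiseless track whose ratio is an exact logistic in time
logistic_ratio_track <- function(A = 1, t0 = 100, tau = 10, b = 0,
                                 n_frames = 800, dt_min = 0.25) {
  t <- (seq_len(n_frames) - 1) * dt_min
  ratio <- b + A / (1 + exp(-(t - t0) / tau))
  # green constant at joint max, red = ratio * green * floor-free scaling:
  # choose channels so norm_green == 1 and norm_red == ratio / max_ratio
  # is awkward; instead construct norm directly
  structure(list(cell_id = "logi", times_min = t,
                 norm_green = rep(1, n_frames),
                 norm_red = ratio, ratio = ratio,
                 norm_min = 0, norm_max = 1, label = NULL),
            class = "normalized_track")
}

# normalized track with an exactly linear ratio
linear_ratio_track <- function(slope = 0.01, n_frames = 400, dt_min = 0.25,
                               intercept = 0) {
  t <- (seq_len(n_frames) - 1) * dt_min
  ratio <- intercept + slope * t
  structure(list(cell_id = "line", times_min = t,
                 norm_green = rep(1, n_frames),
                 norm_red = ratio, ratio = ratio,
                 norm_min = 0, norm_max = 1, label = NULL),
            class = "normalized_track")
}

# heat map with prescribed counts
heatmap_from_counts <- function(counts) {
  structure(list(counts = counts, bbox = NULL, transform = NULL,
                 n_events_in = sum(counts), n_events_excluded = 0,
                 grid_n = nrow(counts)),
            class = "lg_heatmap")
}

# pair of 5x5 maps whose flattened correlation is exactly r (constructed by
# mixing a map with a standardized orthogonal perturbation)
heatmap_pair_with_r <- function(r, seed = 1) {
  set.seed(seed)
  a <- rnorm(25)
  e <- rnorm(25)
  e <- resid(lm(e ~ a))
  std <- function(v) (v - mean(v)) / sd(v)
  b <- r * std(a) + sqrt(1 - r^2) * std(e)
  list(a = heatmap_from_counts(matrix(a + 10, 5, 5)),
       b = heatmap_from_counts(matrix(b + 10, 5, 5)))
}

# random proper 3D rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
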