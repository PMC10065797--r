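test_that("mitosis duration adds the 10-minute onset offset", {
  # 40 frames at 15 s = 10 min before nuclear-envelope breakdown
  expect_equal(division_duration(100, 147.74), 57.74)
  expect_equal(division_duration(c(0, 10), c(5, 30)), c(15, 30))
  cfg <- lg_config(onset_offset_frames = 0)
  expect_equal(division_duration(100, 147.74, cfg), 47.74)
  expect_error(division_duration(10, 10), "after breakdown")
})

test_that("axis classification matches the 45-degree cone about z", {
  geom <- default_geometry()
  deg <- function(a) a * pi / 180
  axis_at <- function(alpha_deg) c(sin(deg(alpha_deg)), 0, cos(deg(alpha_deg)))
  expect_identical(classify_division_axis(c(0, 0, 1), geom), "z")
  expect_identical(classify_division_axis(c(1, 0, 0), geom), "rho")
  expect_identical(classify_division_axis(axis_at(45), geom), "z")     # boundary
  expect_identical(classify_division_axis(axis_at(45.001), geom), "rho")
  expect_identical(classify_division_axis(axis_at(44.999), geom), "z")
  # sign of the axis is irrelevant (undirected axis)
  expect_identical(classify_division_axis(-axis_at(30), geom), "z")
  expect_identical(classify_division_axis(7 * axis_at(60), geom), "rho")
  m <- rbind(axis_at(10), axis_at(80))
  expect_identical(classify_division_axis(m, geom), c("z", "rho"))
  expect_error(classify_division_axis(c(0, 0, 0), geom), "zero-length")
  cfg <- lg_config(rho_z_angle_threshold_deg = 60)
  expect_identical(classify_division_axis(axis_at(55), geom, cfg), "z")
})

test_that("classification is invariant under rotations applied to both axis and frame", {
  geom <- default_geometry()
  set.seed(4)
  for (s in 1:10) {
    R <- random_rotation(seed = s)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    rotated_geom <- lg_geometry(as.numeric(R %*% geom$tube_point),
                                as.numeric(R %*% geom$tube_dir),
                                as.numeric(R %*% geom$posterior_end),
                                as.numeric(R %*% geom$z_dir),
                                geom$lobe_boundary)
    expect_identical(classify_division_axis(as.numeric(R %*% v), rotated_geom),
                     classify_division_axis(v, geom))
  }
})

test_that("orientation to the heart tube folds correctly on [0, 180)", {
  geom <- default_geometry()  # tube along x, z up
  th <- function(v) orientation_to_heart_tube(v, geom)
  expect_equal(th(c(1, 0, 0)), 0)
  expect_equal(th(c(0, 1, 0)), 90)
  expect_equal(th(c(-1, 0, 0)), 0)          # anti-parallel folds to 0
  expect_equal(th(c(1, 1, 0)), 45)
  expect_equal(th(c(-1, 1, 0)), 135)
  # relabeling daughters (negating the axis) maps theta to 180 - theta
  set.seed(2)
  for (i in 1:20) {
    v <- c(rnorm(2), rnorm(1, 0, 0.2))
    a <- th(v); b <- th(-v)
    expect_equal((a + b) %% 180, 0, tolerance = 1e-9)
  }
  # the z-component never matters (projection onto the rho-phi plane)
  expect_equal(th(c(1, 1, 5)), 45, tolerance = 1e-9)
  expect_error(th(c(0, 0, 1)), "vertical")
  expect_true(all(th(rbind(c(1, 2, 0), c(3, -1, 1))) >= 0))
})

test_that("Q-Q report is exactly linear for normal quantile data", {
  theta <- qnorm(ppoints(100), 90, 30)
  rep <- qq_orientation_bias(theta)
  expect_gt(rep$r_squared, 0.999)
  expect_equal(rep$line_slope, 1, tolerance = 0.05)
  # shape statistics should be location/scale equivariant in r^2
  rep2 <- qq_orientation_bias(2 * theta + 7)
  expect_equal(rep2$r_squared, rep$r_squared, tolerance = 1e-9)
  expect_error(qq_orientation_bias(c(1, 2, 3)), "at least 5")
  expect_error(qq_orientation_bias(rep(90, 10)), "identical")
})

test_that("Q-Q r^2 separates normal cohorts from a bimodal edge-biased one", {
  # pinned calibration: the null 5th percentile of r^2 at n = 50 is ~0.90
  set.seed(31)
  null_r2 <- replicate(200, qq_orientation_bias(rnorm(50, 90, 30))$r_squared)
  expect_lt(mean(null_r2 < 0.90), 0.12)
  bimodal_r2 <- replicate(50, qq_orientation_bias(
    c(rnorm(25, 5, 3), rnorm(25, 175, 3)))$r_squared)
  expect_true(all(bimodal_r2 < 0.90))
})

test_that("critical-size metrics read the daughter growth series", {
  tt <- seq(0, 240, by = 5)
  aa <- rbind(40 * (1 + 0.25 * tt / 240), 36 * (1 + 0.20 * tt / 240))
  ev <- list(mother_area_pre_um2 = 72, daughter_times_min = tt,
             daughter_areas_um2 = aa)
  m <- critical_size_metrics(ev)
  expect_equal(m$mother_area_pre_um2, 72)
  expect_equal(m$combined_daughter_area_3h_um2,
               40 * 1.1875 + 36 * 1.15)
  expect_equal(m$growth_fraction_4h, c(0.25, 0.20))
  bare <- critical_size_metrics(list(mother_area_pre_um2 = 70))
  expect_true(is.na(bare$combined_daughter_area_3h_um2))
})

test_that("mitotic index is an exact guarded ratio", {
  expect_equal(mitotic_index(3, 120), 0.025)
  expect_equal(mitotic_index(0, 50), 0)
  expect_error(mitotic_index(1, 0), "no progenitors")
  expect_error(mitotic_index(5, 3), "invalid counts")
})

test_that("event distances match hand-computed geometry", {
  geom <- default_geometry()  # tube: x-axis through origin; posterior (150,0,0)
  d <- event_distances(c(10, 3, 4), geom)
  expect_equal(d$dist_tube_um, 5)                # perpendicular to the x-axis
  expect_equal(d$dist_posterior_um, sqrt(140^2 + 3^2 + 4^2))
  d2 <- event_distances(rbind(c(0, 1, 0), c(5, 0, 0)), geom)
  expect_equal(d2$dist_tube_um, c(1, 0))
  # invariance along the tube axis
  expect_equal(event_distances(c(99, 3, 4), geom)$dist_tube_um, 5)
})

test_that("division summary aggregates a constructed cohort exactly", {
  geom <- default_geometry()
  mk <- function(id, axis, tb, tc, area) {
    list(event_id = id, t_breakdown_min = tb, t_complete_min = tc,
         position_um = c(0, 40, 0), axis_vec = axis,
         mother_area_pre_um2 = area, true_class = NULL)
  }
  ev <- list(mk("e1", c(1, 0, 0), 0, 30, 70),    # rho, duration 40
             mk("e2", c(0, 1, 0), 0, 50, 74),    # rho, duration 60
             mk("e3", c(0, 0, 1), 0, 80, 78))    # z,   duration 90
  s <- division_summary(ev, geom)
  expect_equal(s$summary$n_events, 3)
  expect_equal(s$summary$n_rho, 2)
  expect_equal(s$summary$rho_percent, 200 / 3)
  expect_equal(s$summary$duration_mean_min, mean(c(40, 60, 90)))
  expect_equal(s$summary$duration_mean_rho_min, 50)
  expect_equal(s$summary$duration_mean_z_min, 90)
  expect_equal(s$summary$mother_area_mean_um2, 74)
  expect_equal(s$events$theta_deg[1:2], c(0, 90))
  expect_true(is.na(s$events$theta_deg[3]))
  expect_equal(s$events$dist_tube_um, rep(40, 3))
})

test_that("division-event CSV reading validates its columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ev <- simulate_division_cohort(division_cohort_model(n_events = 10), seed = 2)
  df <- division_table(ev)
  write.csv(df, tmp, row.names = FALSE)
  back <- read_division_events(tmp)
  expect_equal(back$t_breakdown_min, df$t_breakdown_min)
  s1 <- division_summary(df)$summary
  s2 <- division_summary(back)$summary
  expect_equal(s2, s1)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("event_id,t_breakdown_min", bad)
  expect_error(read_division_events(bad), "missing column")
  expect_error(read_division_events("/nope.csv"), "not found")
})

test_that("per-class duration means are recovered when the generator separates them", {
  model <- division_cohort_model(n_events = 4000, duration_mean_rho = 53.90,
                                 duration_mean_z = 75.04)
  s <- division_summary(simulate_division_cohort(model, seed = 7))$summary
  expect_lt(abs(s$duration_mean_rho_min - 53.90), 1.5)
  expect_lt(abs(s$duration_mean_z_min - 75.04), 3)
  expect_gt(s$duration_mean_z_min, s$duration_mean_rho_min)
})
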