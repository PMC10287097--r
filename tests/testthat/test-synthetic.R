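test_that("generators are deterministic per seed", {
  cfg <- scenario_config(n_points = 800, duration = 5, outlier_fraction = 0.1,
                         occlusion_fraction = 0.1, nonrigid_amplitude = 0.5,
                         seed = 13)
  expect_identical(make_face_cloud(cfg), make_face_cloud(cfg))
  t1 <- make_truth_trace(cfg)
  t2 <- make_truth_trace(cfg)
  expect_identical(t1$trace, t2$trace)
  ref <- make_face_cloud(cfg)
  expect_identical(render_frames(ref, t1, cfg), render_frames(ref, t2, cfg))
  expect_identical(make_respiration(t1, cfg)$values,
                   make_respiration(t2, cfg)$values)
  # generators do not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(make_face_cloud(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("the face patch makes all six degrees of freedom observable", {
  cfg <- scenario_config(n_points = 1500, seed = 7)
  ref <- make_face_cloud(cfg)
  obs <- cloud_observability(ref)
  expect_true(obs$ok)
  expect_lt(obs$condition, 1e3)
  # a perturbed self-registration recovers the identity
  set.seed(2)
  init <- random_transform(1, 1)
  r <- register(ref, ref, init = init, preprocess = TRUE)
  expect_lt(hpd(r$transform, rt_identity()), 1e-6)
  # the flat-plane debug variant is flagged degenerate
  flat <- make_face_cloud(cfg, flat = TRUE)
  expect_false(cloud_observability(flat)$ok)
})

test_that("ground-truth motion composes its components as configured", {
  # all amplitudes zero: identity trace
  cfg0 <- scenario_config(duration = 5, breathing_amplitude = 0,
                          rot_walk_disp_sd = 0, seed = 3)
  tr0 <- make_truth_trace(cfg0)$trace
  expect_lt(max(abs(tr0$translation)), 1e-12)
  expect_true(all(abs(tr0$quaternion[, 1]) == 1))
  # breathing only: translation norm is the stated sinusoid
  cfg1 <- scenario_config(duration = 10, breathing_amplitude = 0.2,
                          rot_walk_disp_sd = 0, timing_jitter_sd = 0,
                          seed = 3)
  t1 <- make_truth_trace(cfg1)
  expect_equal(sqrt(rowSums(t1$trace$translation^2)),
               abs(0.2 * sin(2 * pi * cfg1$breathing_freq * t1$times)),
               tolerance = 1e-9)
  # the pose at t = 0 is the identity
  expect_lt(hpd(trace_pose(t1$trace, 1), rt_identity()), 1e-12)
})

test_that("burst events follow the configured Poisson rate", {
  counts <- vapply(1:60, function(s)
    nrow(make_truth_trace(scenario_config(duration = 600, burst_rate = 2,
                                          rot_walk_disp_sd = 0,
                                          seed = s))$bursts), numeric(1))
  lambda <- 2 / 60 * 600
  se <- sqrt(lambda / 60)
  expect_lt(abs(mean(counts) - lambda), 4 * se)
})

test_that("the rotational walk honours its displacement calibration", {
  cfg <- scenario_config(duration = 300, breathing_amplitude = 0,
                         timing_jitter_sd = 0, seed = 17)
  tr <- make_truth_trace(cfg)$trace
  ball <- ball_model()
  steps <- hpd_consecutive(tr$quaternion, tr$translation, ball)
  # per-step displacement sd matches the configured 5/30 mm calibration
  expect_equal(sqrt(mean(steps^2)), cfg$rot_walk_disp_sd, tolerance = 0.1)
})

test_that("rendered frames honour corruption settings", {
  cfg <- scenario_config(n_points = 1000, duration = 2, noise_sd = 0,
                         breathing_amplitude = 0.05, rot_walk_disp_sd = 0.01,
                         seed = 23)
  ref <- make_face_cloud(cfg)
  truth <- make_truth_trace(cfg)
  clean <- render_frames(ref, truth, cfg)
  expect_length(clean, floor(2 * 8))
  # zero corruption: frames are exactly the inverse-posed reference
  k <- 7
  expect_equal(clean[[k]]$points,
               rt_apply(rt_invert(trace_pose(truth$trace, k)), ref$points),
               tolerance = 1e-12)
  expect_identical(clean[[k]]$timestamp, truth$times[k])
  # occlusion removes a contiguous patch; outliers are appended
  cfg2 <- scenario_config(n_points = 1000, duration = 2,
                          occlusion_fraction = 0.3, outlier_fraction = 0.2,
                          seed = 23)
  fr <- render_frames(ref, make_truth_trace(cfg2), cfg2)[[1]]
  n_kept <- round(1000 * 0.7)
  m <- round(0.2 / 0.8 * n_kept)
  expect_equal(nrow(fr$points), n_kept + m)
  expect_equal(sum(fr$grid_index > 1000), m)
})

test_that("camera and respiration sampling honour the configured rates", {
  cfg <- scenario_config(duration = 60, seed = 5)
  times <- make_camera_times(cfg)
  expect_equal(length(times), 480)
  expect_true(all(diff(times) > 0))
  expect_equal(mean(diff(times)), 0.125, tolerance = 0.01)
  expect_gt(sd(diff(times)), 0)  # non-equidistant
  truth <- make_truth_trace(cfg)
  resp <- make_respiration(truth, cfg)
  expect_equal(mean(diff(resp$time)), 1 / 256, tolerance = 1e-9)
  # zero gain leaves pure sensor noise
  cfg0 <- scenario_config(duration = 10, resp_gain = 0, resp_noise_sd = 0.05,
                          seed = 5)
  r0 <- make_respiration(make_truth_trace(cfg0), cfg0)
  expect_lt(abs(cor(r0$values,
                    sin(2 * pi * cfg0$breathing_freq * r0$time))), 0.1)
})

test_that("the fmri-like trace equals frame averages and round-trips", {
  cfg <- scenario_config(duration = 10, seed = 9, rot_walk_disp_sd = 0.05)
  truth <- make_truth_trace(cfg)
  fm <- make_fmri_like_trace(truth)
  ref_avg <- fmri_frame_average(truth$trace,
                                seq(0, 10 - 0.53, by = 0.53), 0.53)
  expect_equal(fm$translation, ref_avg$translation, tolerance = 1e-12)
  # .par round trip is lossless to high precision
  path <- tempfile(fileext = ".par")
  write_par(fm, path)
  back <- read_par(path, frame_duration = 0.53, t0 = 0)
  expect_equal(back$time, fm$time, tolerance = 1e-9)
  expect_equal(back$translation, fm$translation, tolerance = 1e-9)
  expect_lt(max(abs(abs(rowSums(back$quaternion * fm$quaternion)) - 1)), 1e-9)
})

test_that("the cohort generator reflects its coefficients", {
  d <- make_cohort(n_subjects = 60, n_times = 200, sd_noise = 0.02,
                   sd_intercept = 0.05, seed = 4)
  expect_equal(nrow(d), 60 * 200)
  expect_equal(mean(d$bmi_c), 0, tolerance = 1e-9)
  expect_equal(mean(d$age_c), 0, tolerance = 1e-9)
  expect_identical(levels(d$sex), c("female", "male"))
  # per-subject OLS slopes concentrate around the time coefficient
  # (plus small interaction contributions)
  slopes <- vapply(split(d, d$subject_id), function(s)
    coef(lm(motion ~ time, s))[2], numeric(1))
  expect_equal(mean(slopes), 0.001751, tolerance = 0.3)
  # betas zero and no noise: motion constant per subject
  d0 <- make_cohort(n_subjects = 5, n_times = 10,
                    betas = c(0.3, 0, 0, 0, 0, 0, 0, 0),
                    sd_intercept = 0.1, sd_noise = 0, seed = 1)
  spread <- vapply(split(d0$motion, d0$subject_id), sd, numeric(1))
  expect_lt(max(spread), 1e-12)
})
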