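test_that("robust criterion values match their definitions", {
  # Huber: quadratic branch, continuity at the bound, linear branch
  expect_equal(criterion_value(1, 2, "huber"), 0.5)
  expect_equal(criterion_value(2, 2, "huber"), 2.0)
  expect_equal(criterion_value(2 + 1e-12, 2, "huber"), 2.0, tolerance = 1e-9)
  expect_equal(criterion_value(4, 2, "huber"), 6.0)
  expect_equal(criterion_value(4, 2, "identity"), 8.0)
  # all criteria agree with the quadratic at small residuals
  for (kind in c("huber", "tukey", "cauchy", "welsch"))
    expect_equal(criterion_value(1e-4, 2, kind), 0.5 * 1e-8,
                 tolerance = 1e-4)
  expect_error(criterion_value(1, 2, "nope"), "unknown")
})

test_that("IRLS weights are normalized and monotone non-increasing", {
  expect_equal(irls_weight(1, 2, "huber"), 1)
  expect_equal(irls_weight(4, 2, "huber"), 0.5)
  expect_equal(irls_weight(100, 2, "tukey"), 0)
  for (kind in c("huber", "tukey", "cauchy", "welsch", "identity")) {
    w <- irls_weight(seq(0, 20, by = 0.1), 2, kind)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(w[1], 1)
  }
})

test_that("robust bound is the scaled median", {
  expect_equal(robust_bound(c(1, 2, 3), 0.2), 2.4)
  expect_equal(robust_bound(c(1, 2, 3, 4), 0), 2.5)  # even-count midpoint
  expect_equal(robust_bound(5, 0), 5)
  expect_equal(robust_bound(c(0, 0, 0), 0.2), 0)
  expect_error(robust_bound(numeric(0)), "degenerate")
})

test_that("distant-outlier removal keeps exactly the close points", {
  cfg <- scenario_config(n_points = 800, seed = 3)
  ref <- make_face_cloud(cfg)
  n <- nrow(ref$points)
  set.seed(9)
  bad <- sort(sample(n, n %/% 10))
  pts <- ref$points
  # push outliers along +z (towards the camera, well clear of the surface)
  pts[bad, 3] <- pts[bad, 3] + 20
  cloud <- point_cloud(pts, grid_index = seq_len(n))
  out <- remove_distant_outliers(cloud, ref, cutoff = 5)
  expect_identical(out$grid_index, setdiff(seq_len(n), bad))
  # aligned cloud with tiny noise: everything kept
  near <- point_cloud(ref$points + 0.01)
  expect_equal(nrow(remove_distant_outliers(near, ref, 5)$points), n)
  # degenerate cutoff: everything removed is an error
  far <- point_cloud(ref$points + 200)
  expect_error(remove_distant_outliers(far, ref, 5), "tracking loss")
})

test_that("grid under-sampling strides the raster deterministically", {
  pts <- cbind(seq_len(999), 0, 0)
  cloud <- point_cloud(pts, grid_index = seq_len(999))
  expect_equal(nrow(grid_undersample(cloud, 3)$points), 333)
  expect_identical(grid_undersample(cloud, 1), cloud)
  expect_equal(nrow(grid_undersample(cloud, 2000)$points), 1)
  # stride follows grid order, not storage order
  perm <- sample(999)
  shuffled <- point_cloud(pts[perm, ], grid_index = perm)
  a <- grid_undersample(shuffled, 3)
  expect_setequal(a$grid_index, seq(1, 999, by = 3))
})

test_that("self-registration returns the identity with unit weights", {
  cfg <- scenario_config(n_points = 1000, seed = 5)
  ref <- make_face_cloud(cfg)
  r <- register(ref, ref)
  expect_lt(hpd(r$transform, rt_identity()), 1e-9)
  expect_true(all(r$per_point_weight == 1))
  expect_lt(r$final_rms_residual, 1e-12)
})

test_that("a known pose is recovered exactly on noise-free data", {
  cfg <- scenario_config(n_points = 2000, seed = 7)
  ref <- make_face_cloud(cfg)
  pose <- rt_compose(rt_translate(1, -0.5, 0.3),
                     rt_rotate(pi / 180, c(0.2, 1, 0.3)))
  frame <- make_posed_frame(ref, pose)
  r <- register(frame, ref, preprocess = TRUE)
  expect_lt(hpd(r$transform, pose), 1e-3)
})

test_that("the robust criterion beats plain least squares under outliers", {
  cfg <- scenario_config(n_points = 2000, seed = 2)
  ref <- make_face_cloud(cfg)
  set.seed(21)
  pose <- random_transform(1, 1)
  frame <- make_posed_frame(ref, pose, noise_sd = 0.1)
  m <- round(0.25 * nrow(frame$points))
  extra <- frame$points[sample(nrow(frame$points), m, TRUE), ] +
    matrix(runif(3 * m, -15, 15), m, 3)
  frame <- point_cloud(rbind(frame$points, extra),
                       grid_index = c(ref$grid_index,
                                      max(ref$grid_index) + seq_len(m)))
  e_huber <- hpd(register(frame, ref, preprocess = TRUE)$transform, pose)
  e_id <- hpd(register(frame, ref,
                       config = robust_config(criterion = "identity"),
                       preprocess = TRUE)$transform, pose)
  expect_lt(e_huber, 0.1)
  expect_gt(e_id, e_huber)
})

test_that("registration is equivariant under a common frame transform", {
  cfg <- scenario_config(n_points = 1500, seed = 4)
  ref <- make_face_cloud(cfg)
  set.seed(33)
  pose <- random_transform(1, 1)
  frame <- make_posed_frame(ref, pose, noise_sd = 0.05)
  r0 <- register(frame, ref, preprocess = TRUE)
  for (i in 1:5) {
    g <- random_transform(2, 2)
    moved <- point_cloud(rt_apply(g, frame$points),
                         grid_index = frame$grid_index)
    rg <- register(moved, ref, init = rt_compose(r0$transform, rt_invert(g)),
                   preprocess = TRUE)
    expect_lt(hpd(rt_compose(rg$transform, g), r0$transform), 1e-4)
  }
})

test_that("the weighted objective never increases within an inner solve", {
  cfg <- scenario_config(n_points = 1200, seed = 6)
  ref <- make_face_cloud(cfg)
  set.seed(8)
  frame <- make_posed_frame(ref, random_transform(1.5, 1.5), noise_sd = 0.1)
  r <- register(frame, ref, anchor = c(0, 0, -82.5), preprocess = TRUE,
                trace_objective = TRUE)
  expect_true(all(r$objective[, "after"] <= r$objective[, "before"] + 1e-9))
})

test_that("registration is deterministic", {
  cfg <- scenario_config(n_points = 1000, seed = 10)
  ref <- make_face_cloud(cfg)
  set.seed(3)
  frame <- make_posed_frame(ref, random_transform(1, 1), noise_sd = 0.1)
  r1 <- register(frame, ref, preprocess = TRUE)
  r2 <- register(frame, ref, preprocess = TRUE)
  expect_identical(r1$transform, r2$transform)
  expect_identical(r1$per_point_weight, r2$per_point_weight)
})

test_that("register refuses degenerate input", {
  ref <- make_face_cloud(scenario_config(n_points = 600, seed = 1))
  tiny <- point_cloud(ref$points[1:2, ], timestamp = 4.5)
  expect_error(register(tiny, ref), "tracking loss.*4.5")
})

test_that("sequence tracking warm-starts and records tracking loss", {
  cfg <- scenario_config(n_points = 900, duration = 4, noise_sd = 0.05,
                         breathing_amplitude = 0, rot_walk_disp_sd = 0,
                         seed = 12)
  ref <- make_face_cloud(cfg)
  truth <- make_truth_trace(cfg)
  frames <- render_frames(ref, truth, cfg)
  # static scene: all poses at the noise floor of the identity
  tk <- track_sequence(frames, ref)
  expect_true(all(tk$trace$valid))
  errs <- vapply(seq_along(frames), function(k)
    hpd(trace_pose(tk$trace, k), rt_identity()), numeric(1))
  expect_lt(max(errs), 0.05)
  expect_identical(tk$trace$time, truth$times)

  # corrupt one frame far beyond the outlier cutoff: flagged, not fatal
  frames[[5]] <- point_cloud(frames[[5]]$points + 100,
                             grid_index = frames[[5]]$grid_index,
                             timestamp = frames[[5]]$timestamp)
  tk2 <- track_sequence(frames, ref)
  expect_false(tk2$trace$valid[5])
  expect_true(all(tk2$trace$valid[-5]))

  # unordered timestamps are rejected
  expect_error(track_sequence(rev(frames), ref), "increasing")
})

test_that("a tracked breathing trace correlates with the ground truth", {
  cfg <- scenario_config(n_points = 1200, duration = 15,
                         rot_walk_disp_sd = 0, seed = 11)
  ref <- make_face_cloud(cfg)
  truth <- make_truth_trace(cfg)
  frames <- render_frames(ref, truth, cfg)
  tk <- track_sequence(frames, ref)
  cc <- cor(tk$trace$translation[, 3], truth$trace$translation[, 3])
  expect_gt(cc, 0.99)
})
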