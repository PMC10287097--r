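test_that("motion trace construction validates its input", {
  expect_error(motion_trace(c(0, 0.1, 0.1), matrix(0, 3, 3),
                            matrix(rep(c(1, 0, 0, 0), 3), 3, 4, byrow = TRUE)),
               "strictly increasing")
  expect_error(motion_trace(c(0, 1), matrix(0, 2, 3),
                            matrix(c(2, 0, 0, 0, 1, 0, 0, 0), 2, 4,
                                   byrow = TRUE)),
               "unit")
  tr <- drift_trace(0:5)
  expect_equal(n_valid(tr), 6)
  expect_equal(trace_pose(tr, 3)$translation, c(0, 0, 2))
})

test_that("resampling reproduces constant and sign-flipped traces", {
  times <- seq(0, 10, by = 0.125)
  pose <- rt_compose(rt_translate(1, 2, 3), rt_rotate(0.3, c(1, 1, 0)))
  q <- as_quaternion(pose)
  n <- length(times)
  const <- motion_trace(times, matrix(pose$translation, n, 3, byrow = TRUE),
                        matrix(q, n, 4, byrow = TRUE))
  for (params in list(c(9, 0.1), c(3, 0), c(1, 2))) {
    rs <- resample_trace(const, rate = 8, window = params[1], slope = params[2])
    expect_lt(max(abs(sweep(rs$translation, 2, pose$translation))), 1e-12)
    expect_lt(max(abs(abs(rs$quaternion %*% q) - 1)), 1e-12)
  }
  # alternating q and -q encode one fixed rotation; sign alignment fixes it
  qalt <- matrix(q, n, 4, byrow = TRUE) * rep_len(c(1, -1), n)
  alt <- motion_trace(times, matrix(0, n, 3), qalt)
  rs <- resample_trace(alt, rate = 8, window = 5, slope = 0)
  expect_lt(max(abs(abs(rs$quaternion %*% q) - 1)), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(rs$quaternion^2)) - 1)), 1e-9)
})

test_that("symmetric windows preserve linear drift at interior times", {
  times <- seq(0, 20, by = 0.125)
  v <- c(0.3, -0.2, 0.5)
  tr <- drift_trace(times, v)
  out_t <- seq(2, 18, by = 0.25)
  rs <- resample_trace(tr, times = out_t, window = 9, slope = 0)
  expect_lt(max(abs(rs$translation - outer(out_t, v))), 1e-9)
  # with a triangular slope the weights stay symmetric: still exact
  rs2 <- resample_trace(tr, times = out_t, window = 9, slope = 0.1)
  expect_lt(max(abs(rs2$translation - outer(out_t, v))), 1e-9)
})

test_that("resampling is time-shift equivariant and skips invalid samples", {
  set.seed(5)
  times <- cumsum(runif(100, 0.1, 0.15))
  q <- t(vapply(seq_len(100), function(i)
    as_quaternion(rt_rotate(0.01 * i, c(0, 1, 0))), numeric(4)))
  tr <- motion_trace(times, matrix(rnorm(300), 100, 3), q)
  out_t <- seq(2, 10, by = 0.5)
  a <- resample_trace(tr, times = out_t, window = 5, slope = 0.2)
  shifted <- motion_trace(times + 100, tr$translation, tr$quaternion)
  b <- resample_trace(shifted, times = out_t + 100, window = 5, slope = 0.2)
  expect_equal(a$translation, b$translation, tolerance = 1e-9)
  expect_equal(abs(rowSums(a$quaternion * b$quaternion)), rep(1, nrow(a$quaternion)),
               tolerance = 1e-9)
  # invalid samples are excluded from windows
  tr2 <- motion_trace(times, tr$translation, tr$quaternion,
                      valid = rep_len(c(TRUE, TRUE, TRUE, FALSE), 100))
  expect_silent(resample_trace(tr2, times = out_t, window = 5))
  expect_error(resample_trace(motion_trace(1:4, matrix(0, 4, 3),
                                           matrix(rep(c(1, 0, 0, 0), 4),
                                                  4, 4, byrow = TRUE)),
                              rate = 8, window = 9), "fewer valid samples")
})

test_that("equidistant output grids are exactly equidistant", {
  set.seed(6)
  times <- cumsum(runif(200, 0.1, 0.15))
  tr <- motion_trace(times, matrix(0, 200, 3),
                     matrix(rep(c(1, 0, 0, 0), 200), 200, 4, byrow = TRUE))
  rs <- resample_trace(tr, rate = 8, window = 9)
  expect_equal(diff(rs$time), rep(0.125, length(rs$time) - 1),
               tolerance = 1e-12)
})

test_that("synchronization recovers injected offsets", {
  cfg <- scenario_config(duration = 60, breathing_amplitude = 0.3,
                         rot_walk_disp_sd = 0.05, drift_rate = 0.01,
                         seed = 19)
  tr <- make_truth_trace(cfg)$trace
  # a trace against itself
  s0 <- synchronize_traces(tr, tr, max_offset = 5)
  expect_lt(abs(s0$offset), 0.125)
  # against a +3 s shifted copy of itself
  shifted <- motion_trace(tr$time + 3, tr$translation, tr$quaternion)
  s3 <- synchronize_traces(tr, shifted, max_offset = 10)
  expect_lt(abs(s3$offset - 3), 0.125)
  expect_false(s3$at_boundary)
  # offsets beyond the window clamp at the boundary with a warning;
  # use an aperiodic trace so the objective has no breathing aliases
  cfg2 <- scenario_config(duration = 60, breathing_amplitude = 0,
                          rot_walk_disp_sd = 0.05, drift_rate = 0.02,
                          seed = 20)
  tr2 <- make_truth_trace(cfg2)$trace
  far <- motion_trace(tr2$time + 20, tr2$translation, tr2$quaternion)
  expect_warning(sfar <- synchronize_traces(tr2, far, max_offset = 15),
                 "boundary")
  expect_true(sfar$at_boundary)
  expect_equal(abs(sfar$offset), 15)
})

test_that("space mapping conjugates poses", {
  tr <- drift_trace(0:5, c(1, 0, 0))
  expect_equal(map_trace(tr, rt_identity())$translation, tr$translation)
  # pure translation conjugated by a rotation: translation rotates
  M <- rt_rotate(pi / 2, c(0, 0, 1))
  mapped <- map_trace(tr, M)
  expect_equal(mapped$translation[6, ], c(0, 5, 0), tolerance = 1e-12)
  expect_equal(mapped$quaternion[6, ], c(1, 0, 0, 0), tolerance = 1e-12)
  # hpd is preserved when the ball center is co-mapped
  set.seed(23)
  for (i in 1:10) {
    M <- random_transform(20, 90)
    ball <- ball_model(c(0, 5, -20))
    a <- random_transform(2, 2)
    b <- random_transform(2, 2)
    conj <- function(t) rt_compose(M, rt_compose(t, rt_invert(M)))
    ball2 <- ball_model(rt_apply(M, ball$center), ball$radius)
    expect_equal(hpd(conj(a), conj(b), ball2), hpd(a, b, ball),
                 tolerance = 1e-9)
  }
})

test_that("sequence annotation assigns samples and breaks", {
  tr <- drift_trace(seq(0, 30, by = 0.5))
  expect_true(all(annotate_trace(tr, sequence_table(character(0),
                                                    numeric(0),
                                                    numeric(0))) == "break"))
  all_in <- sequence_table("t1w", -1, 31)
  expect_true(all(annotate_trace(tr, all_in) == "t1w"))
  tab <- sequence_table(c("a", "b", "c"), c(0, 12, 24), c(10, 20, 28))
  lab <- annotate_trace(tr, tab)
  expect_equal(sum(lab == "a"), sum(tr$time >= 0 & tr$time < 10))
  expect_equal(sum(lab == "b"), sum(tr$time >= 12 & tr$time < 20))
  expect_equal(sum(lab == "c"), sum(tr$time >= 24 & tr$time < 28))
  expect_equal(sum(lab == "break"), length(tr$time) - sum(lab != "break"))
  expect_error(sequence_table(c("a", "b"), c(0, 5), c(6, 10)), "overlap")
  expect_error(sequence_table("a", 5, 5), "precede")
})
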