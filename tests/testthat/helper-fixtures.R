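# shared fixtures and independent oracles

# random rigid transform with bounded magnitude
random_transform <- function(max_trans = 2, max_angle_deg = 2,
                             center = c(0, 0, 0)) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  tv <- runif(3, -1, 1)
  tv <- tv / sqrt(sum(tv^2)) * runif(1, 0, max_trans)
  rt_compose(rt_translate(tv),
             rt_rotate(runif(1, -max_angle_deg, max_angle_deg) * pi / 180,
                       ax, center))
}

random_rotation_matrix <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rt_rotate(runif(1, -pi, pi), ax)$rotation
}

# Monte-Carlo oracle for hpd: RMS displacement of points sampled uniformly
# in the ball under the relative transform b o a^-1
hpd_mc_oracle <- function(a, b, ball, n = 2e5) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * (ball$radius * runif(n)^(1 / 3))
  p <- sweep(u, 2, ball$center, "+")
  D <- rt_compose(b, rt_invert(a))
  sqrt(mean(rowSums((rt_apply(D, p) - p)^2)))
}

# frame rendered from a reference by a known pose (frame -> reference
# convention), optional Gaussian noise
make_posed_frame <- function(ref, pose, noise_sd = 0) {
  pts <- rt_apply(rt_invert(pose), ref$points)
  if (noise_sd > 0) pts <- pts + matrix(rnorm(length(pts), 0, noise_sd),
                                        ncol = 3)
  point_cloud(pts, grid_index = ref$grid_index)
}

# simple deterministic trace: constant-velocity translation drift
drift_trace <- function(times, velocity = c(0, 0, 1)) {
  n <- length(times)
  motion_trace(times, outer(times, velocity),
               matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE))
}

# trace rotating at constant angular rate about `center`
rotation_drift_trace <- function(times, omega, axis = c(0, 0, 1),
                                 center = c(0, 0, 0)) {
  poses <- lapply(times, function(t) rt_rotate(omega * t, axis, center))
  motion_trace(times,
               t(vapply(poses, function(p) p$translation, numeric(3))),
               t(vapply(poses, as_quaternion, numeric(4))))
}

# right-compose every pose of a trace with a fixed transform (reference
# pose change)
right_compose_trace <- function(trace, g) {
  n <- length(trace$time)
  q <- trace$quaternion; tr <- trace$translation
  for (i in seq_len(n)) {
    if (!trace$valid[i]) next
    Tn <- rt_compose(trace_pose(trace, i), g)
    q[i, ] <- as_quaternion(Tn); tr[i, ] <- Tn$translation
  }
  motion_trace(trace$time, tr, q, trace$valid, trace$space, trace$note)
}

# brute-force exact two-sided p for the paired Wilcoxon signed-rank test
# by enumerating all sign assignments (no ties/zeros assumed)
wilcoxon_exact_enum <- function(x, y) {
  d <- x - y
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mean_v <- n * (n + 1) / 4
  p <- mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-12)
  list(statistic = v_obs, p.value = min(1, p))
}
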