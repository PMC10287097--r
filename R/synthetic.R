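#' Synthetic scan-scenario configuration
#'
#' Describes a simulated acquisition: a depth camera observing a face patch
#' at a nominal 8 Hz with timing jitter, sub-millimetre head motion composed
#' of breathing, drift, occasional bursts and a slow rotational wander, plus
#' a 256 Hz chest respiration channel. Defaults mirror the acquisition the
#' pipeline targets; see the package vignette for the rationale behind each
#' value.
#'
#' @param n_points points in the reference face cloud.
#' @param camera_rate nominal camera rate (Hz).
#' @param timing_jitter_sd per-frame timing jitter sd (s).
#' @param noise_sd isotropic sensor noise sd (mm).
#' @param outlier_fraction fraction of frame points that are distant
#'   outliers, in `[0, 1)`.
#' @param occlusion_fraction fraction of the face patch occluded, `[0, 1)`.
#' @param nonrigid_amplitude amplitude of the localized non-rigid facial
#'   perturbation (mm).
#' @param breathing_amplitude,breathing_freq breathing translation amplitude
#'   (mm) and frequency (Hz).
#' @param drift_rate linear drift speed (mm/s).
#' @param burst_rate,burst_magnitude,burst_duration Poisson burst events per
#'   minute, their displacement (mm) and duration (s).
#' @param rot_walk_disp_sd per-frame-step sd of the displacement induced by
#'   the rotational random walk, in mm. The default 5/30 mm calibrates the
#'   walk so that 5 mm corresponds to 30 standard deviations of the motion
#'   occurring in one 125 ms frame interval.
#' @param resp_rate_hz respiration sampling rate (Hz).
#' @param resp_gain,resp_noise_sd,resp_lag respiration channel gain, noise
#'   sd (sensor units) and lag (s) relative to the breathing latent.
#' @param duration scenario length (s).
#' @param seed integer RNG seed; every generator output is deterministic
#'   given the config.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_points = 2000, camera_rate = 8,
                            timing_jitter_sd = 0.005, noise_sd = 0.1,
                            outlier_fraction = 0, occlusion_fraction = 0,
                            nonrigid_amplitude = 0,
                            breathing_amplitude = 0.1, breathing_freq = 0.3,
                            drift_rate = 0,
                            burst_rate = 0, burst_magnitude = 1,
                            burst_duration = 0.3,
                            rot_walk_disp_sd = 5 / 30,
                            resp_rate_hz = 256, resp_gain = 1,
                            resp_noise_sd = 0.05, resp_lag = 0,
                            duration = 60, seed = 1L) {
  cfg <- list(n_points = as.integer(n_points), camera_rate = camera_rate,
              timing_jitter_sd = timing_jitter_sd, noise_sd = noise_sd,
              outlier_fraction = outlier_fraction,
              occlusion_fraction = occlusion_fraction,
              nonrigid_amplitude = nonrigid_amplitude,
              breathing_amplitude = breathing_amplitude,
              breathing_freq = breathing_freq, drift_rate = drift_rate,
              burst_rate = burst_rate, burst_magnitude = burst_magnitude,
              burst_duration = burst_duration,
              rot_walk_disp_sd = rot_walk_disp_sd,
              resp_rate_hz = resp_rate_hz, resp_gain = resp_gain,
              resp_noise_sd = resp_noise_sd, resp_lag = resp_lag,
              duration = duration, seed = as.integer(seed))
  rates <- cfg[c("camera_rate", "timing_jitter_sd", "noise_sd",
                 "nonrigid_amplitude", "breathing_amplitude",
                 "breathing_freq", "burst_rate", "burst_magnitude",
                 "burst_duration", "rot_walk_disp_sd", "resp_rate_hz",
                 "resp_noise_sd", "duration")]
  stopifnot(all(unlist(rates) >= 0),
            cfg$outlier_fraction >= 0, cfg$outlier_fraction < 1,
            cfg$occlusion_fraction >= 0, cfg$occlusion_fraction < 1)
  structure(cfg, class = "scenario_config")
}

# breathing translation axis: mostly along the camera (z) axis with a small
# superior component, as chest-driven head motion mainly pushes the head
# along the body axis seen obliquely by the camera
.breathing_axis <- c(0, 0.3, 1) / sqrt(1.09)
.drift_axis <- c(1, 0.5, -0.25) / sqrt(1.3125)

#' Synthetic face-patch reference cloud
#'
#' Samples a raster grid on a half-ellipsoid facial patch (head center at
#' the origin, face pointing towards +z at the population-average 82.5 mm)
#' with a nose-like ridge and brow curvature, so that all six rigid degrees
#' of freedom are observable from the surface geometry. `grid_index` is
#' assigned in raster order. The `flat` debug variant returns a plane, whose
#' registration Jacobian is rank-deficient (see [cloud_observability()]).
#'
#' @param config A [scenario_config()] (uses `n_points` and `seed`).
#' @param flat if `TRUE`, produce the degenerate flat-plane variant.
#' @return A [point_cloud()].
#' @export
make_face_cloud <- function(config = scenario_config(), flat = FALSE) {
  stopifnot(config$n_points >= 500)
  nx <- round(sqrt(config$n_points * 90 / 105))
  ny <- ceiling(config$n_points / nx)
  xs <- seq(-45, 45, length.out = nx)
  ys <- seq(-55, 50, length.out = ny)
  g <- expand.grid(x = xs, y = ys)            # raster: x fastest
  g <- g[seq_len(config$n_points), ]
  .local_seed(config$seed, {
    x <- g$x + rnorm(nrow(g), 0, 0.8)
    y <- g$y + rnorm(nrow(g), 0, 0.8)
    z <- if (flat) rep(82.5, nrow(g)) else {
      82.5 * sqrt(pmax(0, 1 - (x / 75)^2 - (y / 95)^2)) +
        15 * exp(-(x / 7)^2 - ((y + 12) / 16)^2) +                  # nose
        5 * exp(-(x / 26)^2 - ((y - 22) / 7)^2) -                   # brow
        4 * exp(-((x - 18) / 8)^2 - ((y - 8) / 6)^2) -              # orbit R
        4 * exp(-((x + 18) / 8)^2 - ((y - 8) / 6)^2) -              # orbit L
        3 * exp(-(x / 16)^2 - ((y + 38) / 5)^2) +                   # lips
        3 * exp(-((x - 28) / 10)^2 - (y / 12)^2) +                  # cheek R
        3 * exp(-((x + 28) / 10)^2 - (y / 12)^2)                    # cheek L
    }
    point_cloud(cbind(x, y, z), grid_index = seq_len(nrow(g)))
  })
}

#' Rigid-registration observability of a cloud
#'
#' Diagnoses whether a surface constrains all six rigid degrees of freedom.
#' Per-point surface normals are estimated by local PCA (10 nearest
#' neighbours); each point contributes the point-to-plane Jacobian row
#' `[(q x n)', n']` with `q` the centroid-centered, RMS-normalized
#' coordinates. The condition number of the 6x6 Gram matrix is small for
#' curved patches and effectively infinite for a plane, where in-plane
#' translations and the rotation about the normal are unobservable.
#'
#' @param cloud A [point_cloud()].
#' @param max_condition threshold above which the cloud is flagged
#'   degenerate.
#' @return A list with `condition` and `ok`.
#' @export
cloud_observability <- function(cloud, max_condition = 1e3) {
  p <- cloud$points
  n <- nrow(p)
  kn <- RANN::nn2(p, p, k = min(10, n))
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- p[kn$nn.idx[i, ], , drop = FALSE]
    ev <- eigen(stats::cov(nb), symmetric = TRUE)
    normals[i, ] <- ev$vectors[, 3]
  }
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  q <- q / sqrt(mean(rowSums(q^2)))
  crossv <- cbind(q[, 2] * normals[, 3] - q[, 3] * normals[, 2],
                  q[, 3] * normals[, 1] - q[, 1] * normals[, 3],
                  q[, 1] * normals[, 2] - q[, 2] * normals[, 1])
  J <- cbind(crossv, normals)
  ev <- eigen(crossprod(J), symmetric = TRUE, only.values = TRUE)$values
  condition <- if (ev[6] <= 0) Inf else ev[1] / ev[6]
  list(condition = condition, ok = is.finite(condition) &&
         condition < max_condition)
}

#' Camera sampling times for a scenario
#'
#' Nominal-rate timestamps with Gaussian timing jitter (non-equidistant,
#' strictly increasing, starting at 0).
#'
#' @param config A [scenario_config()].
#' @return Numeric vector of seconds.
#' @export
make_camera_times <- function(config = scenario_config()) {
  n <- floor(config$duration * config$camera_rate)
  .local_seed(config$seed + 1L, {
    t <- (seq_len(n) - 1) / config$camera_rate +
      c(0, rnorm(n - 1, 0, config$timing_jitter_sd))
    t <- sort(t)
    # enforce strict increase without moving the origin
    dt <- diff(t)
    dt[dt < 1e-4] <- 1e-4
    c(t[1], t[1] + cumsum(dt))
  })
}

#' Ground-truth head motion
#'
#' Composes four motion components at the camera sampling times:
#' a sinusoidal breathing translation, a linear drift, Poisson-timed
#' transient bursts with a raised-cosine displacement profile, and a small
#' rotational random walk about the head-ball center whose per-step
#' displacement sd is `rot_walk_disp_sd`. The pose at the first sample is
#' the identity.
#'
#' @param config A [scenario_config()].
#' @param times camera timestamps; defaults to [make_camera_times()].
#' @param ball A [ball_model()]; the rotational walk pivots about its
#'   center and is calibrated against its radius.
#' @return A list of class `ground_truth`: `trace` (a [motion_trace()]),
#'   `times`, `breathing_latent` (unit-amplitude function of time),
#'   `bursts` (data.frame of event times), and `config`.
#' @export
make_truth_trace <- function(config = scenario_config(),
                             times = make_camera_times(config),
                             ball = ball_model()) {
  n <- length(times)
  f <- config$breathing_freq
  latent <- function(t) sin(2 * pi * f * t)
  .local_seed(config$seed + 2L, {
    disp <- outer(config$breathing_amplitude * latent(times), .breathing_axis) +
      outer(config$drift_rate * times, .drift_axis)
    nb <- rpois(1, config$burst_rate / 60 * config$duration)
    bursts <- data.frame(time = sort(runif(nb, 0, config$duration)))
    for (tb in bursts$time) {
      u <- (times - tb) / max(config$burst_duration, 1e-6)
      prof <- ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      disp <- disp + outer(config$burst_magnitude * prof, dirv)
    }
    sd_theta <- config$rot_walk_disp_sd / (ball$radius * sqrt(2 / 5))
    qmat <- matrix(NA_real_, n, 4)
    tmat <- matrix(NA_real_, n, 3)
    R <- diag(3)
    for (k in seq_len(n)) {
      if (k > 1 && sd_theta > 0) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        dR <- rt_rotate(rnorm(1, 0, sd_theta), ax)$rotation
        R <- dR %*% R
      }
      tk <- ball$center - as.numeric(R %*% ball$center) + disp[k, ]
      qmat[k, ] <- quat_from_rotation(R)
      tmat[k, ] <- tk
    }
    structure(list(trace = motion_trace(times, tmat, qmat, valid = TRUE,
                                        space = "camera",
                                        note = "synthetic ground truth"),
                   times = times, breathing_latent = latent,
                   bursts = bursts, config = config),
              class = "ground_truth")
  })
}

#' Render noisy depth frames from the ground truth
#'
#' Each frame applies the true pose to the reference cloud and then
#' corrupts it with: a smooth, spatially localized non-rigid displacement
#' bump (emulating eye/skin motion), isotropic Gaussian sensor noise,
#' removal of a contiguous occluded patch, and uniformly scattered distant
#' outlier points within 30 mm of the face. The occlusion patch and
#' non-rigid bump location are fixed per scenario.
#'
#' @param reference the reference [point_cloud()].
#' @param truth a [make_truth_trace()] result.
#' @param config A [scenario_config()].
#' @return List of [point_cloud()] frames carrying the truth timestamps.
#' @export
render_frames <- function(reference, truth, config = scenario_config()) {
  n <- length(truth$times)
  p0 <- reference$points
  npt <- nrow(p0)
  .local_seed(config$seed + 3L, {
    bump_center <- p0[sample.int(npt, 1), ]
    bump_w <- exp(-rowSums(sweep(p0, 2, bump_center)^2) / (2 * 8^2))
    occ_keep <- rep(TRUE, npt)
    if (config$occlusion_fraction > 0) {
      occ_center <- p0[sample.int(npt, 1), ]
      d2 <- rowSums(sweep(p0, 2, occ_center)^2)
      n_occ <- round(config$occlusion_fraction * npt)
      occ_keep[order(d2)[seq_len(n_occ)]] <- FALSE
    }
    lapply(seq_len(n), function(k) {
      t <- truth$times[k]
      pts <- p0
      if (config$nonrigid_amplitude > 0)
        pts[, 3] <- pts[, 3] +
          config$nonrigid_amplitude * bump_w * sin(2 * pi * 0.4 * t)
      pts <- pts[occ_keep, , drop = FALSE]
      gidx <- reference$grid_index[occ_keep]
      # poses map frame -> reference, so the rendered frame applies the
      # inverse pose to the reference surface
      pts <- rt_apply(rt_invert(trace_pose(truth$trace, k)), pts)
      if (config$noise_sd > 0)
        pts <- pts + matrix(rnorm(length(pts), 0, config$noise_sd),
                            ncol = 3)
      if (config$outlier_fraction > 0) {
        m <- round(config$outlier_fraction / (1 - config$outlier_fraction) *
                     nrow(pts))
        base <- pts[sample.int(nrow(pts), m, replace = TRUE), , drop = FALSE]
        off <- matrix(runif(3 * m, -30, 30), m, 3)
        small <- sqrt(rowSums(off^2)) < 8
        off[small, ] <- off[small, , drop = FALSE] +
          8 * sign(off[small, , drop = FALSE])
        pts <- rbind(pts, base + off)
        gidx <- c(gidx, max(reference$grid_index) + seq_len(m))
      }
      point_cloud(pts, grid_index = gidx, timestamp = t)
    })
  })
}

#' Synthetic respiration channel
#'
#' `resp(t) = gain * breathing_latent(t - lag) + noise`, sampled at
#' `resp_rate_hz`.
#'
#' @param truth a [make_truth_trace()] result.
#' @param config A [scenario_config()].
#' @return A [respiration_signal()].
#' @export
make_respiration <- function(truth, config = scenario_config()) {
  times <- seq(0, config$duration, by = 1 / config$resp_rate_hz)
  .local_seed(config$seed + 4L, {
    v <- config$resp_gain * truth$breathing_latent(times - config$resp_lag) +
      rnorm(length(times), 0, config$resp_noise_sd)
    respiration_signal(times, v)
  })
}

#' Synthetic fMRI-like comparison trace
#'
#' Emulates the per-frame rigid motion estimates of an fMRI realignment
#' tool: the ground-truth trace averaged over each frame window, plus
#' optional small pose noise (`noise_sd_pose` mm of translation noise and a
#' matched rotation noise scaled by the ball radius).
#'
#' @param truth a [make_truth_trace()] result.
#' @param frame_times frame start times; default tiles the scenario
#'   duration.
#' @param frame_duration frame length in seconds.
#' @param noise_sd_pose pose noise scale in mm (0 for none).
#' @param ball A [ball_model()].
#' @return A [motion_trace()] with one sample per frame.
#' @export
make_fmri_like_trace <- function(truth, frame_times = NULL,
                                 frame_duration = 0.53, noise_sd_pose = 0,
                                 ball = ball_model()) {
  if (is.null(frame_times))
    frame_times <- seq(0, truth$config$duration - frame_duration,
                       by = frame_duration)
  avg <- fmri_frame_average(truth$trace, frame_times, frame_duration)
  if (noise_sd_pose > 0) {
    avg <- .local_seed(truth$config$seed + 5L, {
      n <- length(avg$time)
      q <- avg$quaternion; tr <- avg$translation
      for (i in seq_len(n)) {
        if (!avg$valid[i]) next
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        dR <- rt_rotate(rnorm(1, 0, noise_sd_pose / ball$radius), ax)
        Tn <- rt_compose(dR, trace_pose(avg, i))
        Tn$translation <- Tn$translation + rnorm(3, 0, noise_sd_pose)
        q[i, ] <- as_quaternion(Tn); tr[i, ] <- Tn$translation
      }
      motion_trace(avg$time, tr, q, avg$valid, avg$space, avg$note)
    })
  }
  avg
}

#' Synthetic longitudinal cohort
#'
#' Generates per-subject motion samples following the random-intercept
#' model used for session-time analysis: for subject `i` at session time
#' `t_ij` (minutes),
#'
#'   `Y_ij = b1 + b2 t + b3 BMI_c + b4 age_c + b5 male + b6 t*BMI_c
#'           + b7 t*age_c + b8 t*male + u_i + e_ij`
#'
#' with `u_i ~ N(0, sd_intercept^2)` and `e_ij ~ N(0, sd_noise^2)`. BMI and
#' age are drawn from realistic adult-cohort distributions and centered;
#' sex is balanced binary with female as reference level. Samples are at
#' 1-second intervals.
#'
#' @param n_subjects number of subjects.
#' @param n_times samples per subject (1 s apart).
#' @param betas length-8 coefficient vector in the order above; defaults
#'   are the session-time effects the analysis module targets (mm/s units,
#'   time in minutes).
#' @param sd_intercept,sd_noise random-intercept and residual sd (mm/s).
#' @param seed RNG seed.
#' @return A `data.frame` with columns `subject_id`, `time` (minutes),
#'   `motion` (mm/s), `bmi_c`, `age_c`, `sex`.
#' @export
make_cohort <- function(n_subjects = 200, n_times = 300,
                        betas = c(0.29, 0.001751, 0.004397, 0.002077, 0,
                                  0.000060, 0.000002, -0.000199),
                        sd_intercept = 0.08, sd_noise = 0.05, seed = 1L) {
  stopifnot(length(betas) == 8, n_subjects >= 2, n_times >= 2)
  .local_seed(seed, {
    bmi <- rnorm(n_subjects, 26.5, 4)
    age <- rnorm(n_subjects, 55, 12)
    sex <- rep_len(c(0L, 1L), n_subjects)[sample.int(n_subjects)]
    u <- rnorm(n_subjects, 0, sd_intercept)
    bmi_c <- bmi - mean(bmi)
    age_c <- age - mean(age)
    t_min <- (seq_len(n_times) - 1) / 60
    d <- data.frame(
      subject_id = factor(rep(seq_len(n_subjects), each = n_times)),
      time = rep(t_min, n_subjects),
      bmi_c = rep(bmi_c, each = n_times),
      age_c = rep(age_c, each = n_times),
      sex = factor(rep(ifelse(sex == 1, "male", "female"), each = n_times),
                   levels = c("female", "male")))
    male <- as.numeric(d$sex == "male")
    mu <- betas[1] + betas[2] * d$time + betas[3] * d$bmi_c +
      betas[4] * d$age_c + betas[5] * male + betas[6] * d$time * d$bmi_c +
      betas[7] * d$time * d$age_c + betas[8] * d$time * male
    d$motion <- mu + rep(u, each = n_times) +
      rnorm(nrow(d), 0, sd_noise)
    d[, c("subject_id", "time", "motion", "bmi_c", "age_c", "sex")]
  })
}
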