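# vectorized quaternion -> row-major 3x3 rotation (N x 9), scalar-first input
.quat_to_rot9 <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# run code under a temporary RNG state without disturbing the caller's
.local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Per-interval motion score
#'
#' Summarizes a motion trace as average head displacement per second
#' (mm/s): the trace is resampled to exactly `rate` Hz with a triangular
#' window (defaults: slope 0.1 /s, window 9 samples), the head pose
#' difference ([hpd()]) between consecutive poses is summed within each
#' one-second bin, and the bin sums are averaged over the interval. Bins
#' are aligned to the interval start; a final partial bin is dropped.
#'
#' @param trace A [motion_trace()].
#' @param interval `c(start, end)` in seconds; defaults to the valid
#'   support of the trace. Must lie inside the trace support.
#' @param ball A [ball_model()].
#' @param rate resampling rate in Hz.
#' @param window,slope resampling parameters, see [resample_trace()].
#' @return A list of class `motion_score`: `value` (mm/s), `interval`, and
#'   `n_seconds_used` (number of complete one-second bins).
#' @export
motion_score <- function(trace, interval = NULL, ball = ball_model(),
                         rate = 8, window = 9, slope = 0.1) {
  tv <- trace$time[trace$valid]
  if (is.null(interval)) interval <- c(tv[1], tv[length(tv)])
  if (interval[1] < tv[1] - 1e-9 || interval[2] > tv[length(tv)] + 1e-9)
    stop("motion_score: interval outside trace support")
  nb <- floor((interval[2] - interval[1]) + 1e-9)
  if (nb < 1) stop("motion_score: interval shorter than one second")
  times <- interval[1] + seq(0, by = 1 / rate,
                             length.out = floor((interval[2] - interval[1]) * rate + 1e-9) + 1)
  rs <- resample_trace(trace, times = times, window = window, slope = slope)
  d <- hpd_consecutive(rs$quaternion, rs$translation, ball)
  left <- times[-length(times)] - interval[1]
  bin <- floor(left + 1e-9)
  keep <- bin < nb
  sums <- vapply(seq_len(nb) - 1,
                 function(b) sum(d[keep & bin == b]), numeric(1))
  structure(list(value = mean(sums), interval = interval,
                 n_seconds_used = nb),
            class = "motion_score")
}

#' @export
print.motion_score <- function(x, ...) {
  cat(sprintf("<motion_score> %.5f mm/s over [%.1f, %.1f] s (%d bins)\n",
              x$value, x$interval[1], x$interval[2], x$n_seconds_used))
  invisible(x)
}

#' Motion trace difference (MTD)
#'
#' Reference-pose-free comparison of two motion traces sampled at the same
#' timestamps. For every ordered sample pair `i < j` the within-method
#' relative transforms `D^A_ij = T^A_j o inv(T^A_i)` and `D^B_ij` are
#' formed and their [hpd()] averaged over all pairs. Because only relative
#' transforms enter, the result is unchanged when either trace is
#' right-composed with a fixed transform (a change of that method's
#' reference pose), and the metric is symmetric.
#'
#' @param trace_a,trace_b [motion_trace()] objects with identical
#'   timestamps (resample/synchronize first). Only samples valid in both
#'   are used; at least 2 are required.
#' @param ball A [ball_model()].
#' @param stride optional pair stride `> 1` to approximate the mean on very
#'   long traces.
#' @return Mean HPD over pairs, in mm.
#' @export
mtd <- function(trace_a, trace_b, ball = ball_model(), stride = 1) {
  if (length(trace_a$time) != length(trace_b$time) ||
      max(abs(trace_a$time - trace_b$time)) > 1e-9)
    stop("mtd: traces must share timestamps")
  ok <- trace_a$valid & trace_b$valid
  if (sum(ok) < 2) stop("mtd: fewer than 2 common valid samples")
  qa <- trace_a$quaternion[ok, , drop = FALSE]
  qb <- trace_b$quaternion[ok, , drop = FALSE]
  .mtd_cpp(.quat_to_rot9(qa), trace_a$translation[ok, , drop = FALSE],
           .quat_to_rot9(qb), trace_b$translation[ok, , drop = FALSE],
           ball$center, ball$radius, as.integer(stride))
}

#' Average a motion trace over fMRI frames
#'
#' Produces one pose per fMRI frame: the uniform (slope-0) average of all
#' trace samples within the frame window centered on the frame midpoint.
#' Frames containing no samples are marked invalid.
#'
#' @param trace A [motion_trace()].
#' @param frame_times frame start times in seconds.
#' @param frame_duration frame length in seconds (default 0.53, the
#'   repetition time of the comparison fMRI protocol; see the package
#'   vignette for the 0.53 vs 0.57 s discrepancy).
#' @return A `motion_trace` with one sample per frame at the frame
#'   midpoints.
#' @export
fmri_frame_average <- function(trace, frame_times, frame_duration = 0.53) {
  mids <- frame_times + frame_duration / 2
  n <- length(mids)
  q_out <- matrix(NA_real_, n, 4)
  t_out <- matrix(NA_real_, n, 3)
  valid <- logical(n)
  tv <- trace$time
  for (i in seq_len(n)) {
    inw <- which(trace$valid & abs(tv - mids[i]) <= frame_duration / 2 + 1e-12)
    if (length(inw) == 0) next
    t_out[i, ] <- colMeans(trace$translation[inw, , drop = FALSE])
    q <- trace$quaternion[inw, , drop = FALSE]
    sgn <- sign(q %*% q[1, ])
    sgn[sgn == 0] <- 1
    qm <- colSums(q * as.numeric(sgn)) / length(inw)
    q_out[i, ] <- qm / sqrt(sum(qm^2))
    valid[i] <- TRUE
  }
  motion_trace(mids, t_out, q_out, valid = valid,
               space = trace$space, note = "frame-averaged")
}

#' Respiration signal
#'
#' @param time increasing timestamps in seconds.
#' @param values finite sensor readings (arbitrary units).
#' @return An object of class `respiration_signal`.
#' @export
respiration_signal <- function(time, values) {
  time <- as.numeric(time); values <- as.numeric(values)
  stopifnot(length(time) == length(values), all(is.finite(values)))
  if (is.unsorted(time, strictly = TRUE))
    stop("respiration_signal: timestamps must be strictly increasing")
  structure(list(time = time, values = values), class = "respiration_signal")
}

#' Kraskov k-nearest-neighbour mutual information
#'
#' KSG estimator (variant 1) of the mutual information between two scalar
#' series, in nats. Ties should be broken by the caller with a tiny jitter
#' (as [respiration_mi()] does); the estimate can be slightly negative for
#' independent data.
#'
#' @param x,y numeric vectors of equal length.
#' @param k number of neighbours (default 3).
#' @return Estimated mutual information in nats.
#' @export
ksg_mi <- function(x, y, k = 3) {
  .ksg_mi_cpp(as.numeric(x), as.numeric(y), as.integer(k))
}

#' Mutual information between head motion and respiration
#'
#' Sensitivity check asking how much of a densely sampled chest-sensor
#' respiration signal is contained in a motion trace. The trace is
#' resampled to `rate` Hz (defaults: slope 0.1 /s, window 3 samples), the
#' respiration signal linearly interpolated to the same timestamps, and the
#' poses decomposed into 7 scalar series: 3 translation components and 4
#' quaternion components with sequence-wide sign continuity (each
#' quaternion flipped if its dot product with its predecessor is negative).
#' The KSG estimator (`k = 3`, seeded 1e-10 jitter against ties) gives one
#' MI value per component; negatives are clipped to zero and the total is
#' their sum. A constant component (or constant respiration) contributes 0.
#'
#' @param trace A [motion_trace()].
#' @param resp A [respiration_signal()].
#' @param k neighbours for the KSG estimator.
#' @param rate,window,slope resampling parameters.
#' @param seed seed for the tie-breaking jitter.
#' @param min_overlap minimum common time support in seconds.
#' @return A list with `total` (nats) and `components`, a named length-7
#'   vector (`tx`, `ty`, `tz`, `qw`, `qx`, `qy`, `qz`).
#' @export
respiration_mi <- function(trace, resp, k = 3, rate = 8, window = 3,
                           slope = 0.1, seed = 1L, min_overlap = 60) {
  tv <- trace$time[trace$valid]
  lo <- max(tv[1], resp$time[1])
  hi <- min(tv[length(tv)], resp$time[length(resp$time)])
  if (hi - lo < min_overlap)
    stop(sprintf("respiration_mi: common support %.1f s is below %.0f s",
                 hi - lo, min_overlap))
  times <- seq(lo, hi, by = 1 / rate)
  rs <- resample_trace(trace, times = times, window = window, slope = slope)
  r <- approx(resp$time, resp$values, xout = times)$y

  q <- rs$quaternion
  n <- nrow(q)
  if (n > 1) {
    d <- rowSums(q[-1, , drop = FALSE] * q[-n, , drop = FALSE])
    flip <- cumprod(ifelse(d < 0, -1, 1))
    q[-1, ] <- q[-1, , drop = FALSE] * flip
  }
  comps <- cbind(tx = rs$translation[, 1], ty = rs$translation[, 2],
                 tz = rs$translation[, 3],
                 qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  mi <- .local_seed(seed, {
    rj <- r + rnorm(n, 0, 1e-10)
    vapply(colnames(comps), function(nm) {
      x <- comps[, nm]
      if (sd(x) == 0 || sd(r) == 0) return(0)
      max(0, ksg_mi(x + rnorm(n, 0, 1e-10), rj, k))
    }, numeric(1))
  })
  list(total = sum(mi), components = mi)
}
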