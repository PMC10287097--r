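#' Motion trace
#'
#' A time-stamped sequence of head poses relative to a reference pose.
#' Poses are stored as translations (mm) plus scalar-first unit quaternions;
#' samples flagged invalid (tracking loss) carry `NA` poses and are skipped
#' by downstream resampling.
#'
#' @param time strictly increasing timestamps in seconds.
#' @param translation N x 3 matrix of translations (mm).
#' @param quaternion N x 4 matrix of unit quaternions, scalar first.
#' @param valid logical vector; defaults to all `TRUE`.
#' @param space label of the coordinate space, e.g. `"camera"` or
#'   `"anatomical"`.
#' @param note free-text note on the reference pose.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(time, translation, quaternion, valid = TRUE,
                         space = "camera", note = "") {
  time <- as.numeric(time)
  translation <- matrix(as.numeric(translation), length(time), 3)
  quaternion <- matrix(as.numeric(quaternion), length(time), 4)
  valid <- rep_len(as.logical(valid), length(time))
  if (is.unsorted(time, strictly = TRUE))
    stop("motion_trace: timestamps must be strictly increasing")
  ok <- valid & !is.na(quaternion[, 1])
  if (any(ok)) {
    nq <- sqrt(rowSums(quaternion[ok, , drop = FALSE]^2))
    if (any(abs(nq - 1) > 1e-6))
      stop("motion_trace: quaternions of valid samples must be unit")
  }
  structure(list(time = time, translation = translation,
                 quaternion = quaternion, valid = valid,
                 space = space, note = note),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d samples (%d valid), %.2f-%.2f s, space '%s'\n",
              length(x$time), sum(x$valid), min(x$time), max(x$time), x$space))
  invisible(x)
}

#' @rdname motion_trace
#' @param trace A `motion_trace`.
#' @param i sample index.
#' @return `trace_pose` returns the pose at sample `i` as a
#'   [rigid_transform()] (error if the sample is invalid).
#' @export
trace_pose <- function(trace, i) {
  if (!trace$valid[i]) stop("trace_pose: sample ", i, " is invalid")
  from_quaternion(trace$quaternion[i, ], trace$translation[i, ])
}

#' @rdname motion_trace
#' @return `n_valid` returns the number of valid samples.
#' @export
n_valid <- function(trace) sum(trace$valid)

#' Resample a motion trace with a triangular sliding window
#'
#' For each output time `t` the `window` valid samples nearest in time are
#' averaged with weights `max(0, 1 - slope * |t_sample - t|)`, renormalized
#' to sum 1 (`slope = 0` gives a plain average over the window).
#' Translations use the weighted arithmetic mean; quaternions are
#' sign-aligned to the window's first sample, averaged, and renormalized —
#' valid for the small angular spreads of within-window head motion. Near
#' the trace ends the nearest window is asymmetric, which breaks exact
#' preservation of linear signals there.
#'
#' @param trace A [motion_trace()].
#' @param rate output rate in Hz; output timestamps are exactly equidistant
#'   from the first valid sample. Ignored when `times` is given.
#' @param times explicit output timestamps (seconds).
#' @param window window size in samples (positive integer).
#' @param slope triangular slope in 1/s, `>= 0`.
#' @return A resampled `motion_trace` (all samples valid).
#' @export
resample_trace <- function(trace, rate = NULL, times = NULL,
                           window = 9, slope = 0.1) {
  window <- as.integer(window)
  stopifnot(window >= 1, slope >= 0)
  keep <- trace$valid
  tin <- trace$time[keep]
  n <- length(tin)
  if (n < window)
    stop("resample_trace: fewer valid samples than the window size")
  tr <- trace$translation[keep, , drop = FALSE]
  q <- trace$quaternion[keep, , drop = FALSE]
  if (is.null(times)) {
    if (is.null(rate)) stop("resample_trace: give `rate` or `times`")
    m <- floor((tin[n] - tin[1]) * rate) + 1
    times <- tin[1] + (seq_len(m) - 1) / rate
  }
  times <- as.numeric(times)
  m <- length(times)

  # the k nearest samples to t are contiguous in time order; pick the
  # contiguous block minimizing the larger endpoint distance
  j <- findInterval(times, tin)
  smin <- pmin(pmax(j - window + 1L, 1L), n - window + 1L)
  smax <- pmin(pmax(j + 1L, 1L), n - window + 1L)
  best <- smin
  bestcost <- pmax(abs(tin[smin] - times), abs(tin[smin + window - 1L] - times))
  s <- smin
  repeat {
    s <- pmin(s + 1L, smax)
    cost <- pmax(abs(tin[s] - times), abs(tin[s + window - 1L] - times))
    upd <- cost < bestcost & s <= smax
    best[upd] <- s[upd]
    bestcost[upd] <- cost[upd]
    if (all(s >= smax)) break
  }
  idx <- outer(best, 0:(window - 1L), "+")       # m x window gather matrix
  dt <- abs(matrix(tin[idx], m, window) - times)
  w <- 1 - slope * dt
  w[w < 0] <- 0
  sw <- rowSums(w)
  if (any(sw <= 0))
    stop("resample_trace: all-zero triangular weights at some output time")
  w <- w / sw

  t_out <- matrix(0, m, 3)
  for (c in 1:3)
    t_out[, c] <- rowSums(w * matrix(tr[idx, c], m, window))

  q1 <- q[idx[, 1], , drop = FALSE]              # window's first quaternion
  q_out <- matrix(0, m, 4)
  for (o in seq_len(window)) {
    qo <- q[idx[, o], , drop = FALSE]
    sgn <- sign(rowSums(qo * q1))
    sgn[sgn == 0] <- 1
    q_out <- q_out + (w[, o] * sgn) * qo
  }
  q_out <- q_out / sqrt(rowSums(q_out^2))

  motion_trace(times, t_out, q_out, valid = TRUE,
               space = trace$space, note = trace$note)
}

#' Synchronize two motion traces
#'
#' Finds the clock offset (within `max_offset` seconds) that, applied to
#' `trace_a`'s timestamps, minimizes the motion trace difference ([mtd()])
#' between the two traces resampled to common timestamps. The MTD is
#' reference-pose-free, so differing reference poses between methods cannot
#' bias the offset. A coarse grid search (default step 0.125 s) is followed
#' by golden-section refinement.
#'
#' @param trace_a,trace_b [motion_trace()] objects with overlapping support.
#' @param max_offset search half-width in seconds.
#' @param ball A [ball_model()].
#' @param step coarse grid step in seconds.
#' @param rate common resampling rate (Hz).
#' @param window,slope resampling parameters, see [resample_trace()].
#' @return A list with `offset` (s), `mtd` (mm) at the optimum, and
#'   `at_boundary` (`TRUE` when the search was clamped at `max_offset`).
#' @export
synchronize_traces <- function(trace_a, trace_b, max_offset = 15,
                               ball = ball_model(), step = 0.125,
                               rate = 8, window = 3, slope = 0.1) {
  objective <- function(delta) {
    ta <- trace_a$time + delta
    lo <- max(min(ta[trace_a$valid]), min(trace_b$time[trace_b$valid]))
    hi <- min(max(ta[trace_a$valid]), max(trace_b$time[trace_b$valid]))
    if (hi - lo < (window + 1) / rate) return(NA_real_)
    times <- seq(lo, hi, by = 1 / rate)
    a_s <- motion_trace(ta, trace_a$translation, trace_a$quaternion,
                        trace_a$valid, trace_a$space, trace_a$note)
    ra <- resample_trace(a_s, times = times, window = window, slope = slope)
    rb <- resample_trace(trace_b, times = times, window = window, slope = slope)
    mtd(ra, rb, ball)
  }
  grid <- seq(-max_offset, max_offset, by = step)
  vals <- vapply(grid, objective, numeric(1))
  if (all(is.na(vals)))
    stop("synchronize_traces: traces do not overlap within the search window")
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(d) {
    v <- objective(d)
    if (is.na(v)) Inf else v
  }, c(lo, hi), tol = 1e-3)
  offset <- opt$minimum
  at_boundary <- i == 1 || i == length(grid)
  if (at_boundary) {
    offset <- grid[i]
    warning("synchronize_traces: optimum at the search boundary")
  }
  list(offset = offset,
       mtd = if (at_boundary) vals[i] else opt$objective,
       at_boundary = at_boundary)
}

#' Map a motion trace to another coordinate space
#'
#' Poses are space-relative motions, not points, so a rigid mapping `M`
#' from the source to the target space acts by conjugation:
#' each pose `T` becomes `M o T o M^-1`. Timestamps are unchanged.
#'
#' @param trace A [motion_trace()].
#' @param mapping [rigid_transform()] from the trace's space to the target
#'   space (e.g. camera to anatomical).
#' @param new_label space label of the result.
#' @return The mapped `motion_trace`.
#' @export
map_trace <- function(trace, mapping, new_label = "anatomical") {
  minv <- rt_invert(mapping)
  n <- length(trace$time)
  q <- trace$quaternion
  tr <- trace$translation
  for (i in seq_len(n)) {
    if (!trace$valid[i]) next
    Tn <- rt_compose(mapping, rt_compose(trace_pose(trace, i), minv))
    q[i, ] <- as_quaternion(Tn)
    tr[i, ] <- Tn$translation
  }
  motion_trace(trace$time, tr, q, trace$valid, space = new_label,
               note = trace$note)
}

#' Sequence interval table
#'
#' Rows of `(sequence, start_s, end_s)` describing when each MR sequence
#' ran; intervals must be non-overlapping with `start_s < end_s`.
#'
#' @param sequence character sequence names.
#' @param start_s,end_s interval bounds in seconds.
#' @return A validated `data.frame` of class `sequence_table`.
#' @export
sequence_table <- function(sequence, start_s, end_s) {
  d <- data.frame(sequence = as.character(sequence),
                  start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  if (any(d$start_s >= d$end_s)) stop("sequence_table: start must precede end")
  if (nrow(d) > 1) {
    o <- order(d$start_s)
    if (any(d$end_s[o][-nrow(d)] > d$start_s[o][-1]))
      stop("sequence_table: intervals overlap")
  }
  class(d) <- c("sequence_table", "data.frame")
  d
}

#' Annotate trace samples with their MR sequence
#'
#' Each sample is assigned to the sequence whose `[start_s, end_s)` interval
#' contains its timestamp; samples between sequences are labelled
#' `"break"`.
#'
#' @param trace A [motion_trace()].
#' @param table A [sequence_table()].
#' @return Character vector of labels, one per sample.
#' @export
annotate_trace <- function(trace, table) {
  lab <- rep("break", length(trace$time))
  for (r in seq_len(nrow(table))) {
    inr <- trace$time >= table$start_s[r] & trace$time < table$end_s[r]
    lab[inr] <- table$sequence[r]
  }
  lab
}
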