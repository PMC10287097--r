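#' Point cloud
#'
#' @param points N x 3 numeric matrix of coordinates (mm).
#' @param grid_index optional integer vector giving each point's position in
#'   the original depth-image raster; used by [grid_undersample()].
#' @param timestamp optional acquisition time (seconds).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, grid_index = NULL, timestamp = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("point_cloud: points must be N x 3")
  if (!all(is.finite(points))) stop("point_cloud: non-finite coordinates")
  if (!is.null(grid_index)) {
    grid_index <- as.integer(grid_index)
    stopifnot(length(grid_index) == nrow(points))
  }
  structure(list(points = points, grid_index = grid_index,
                 timestamp = timestamp),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", nrow(x$points),
              if (!is.null(x$timestamp)) sprintf(" @ t=%.3f s", x$timestamp) else ""))
  invisible(x)
}

#' Robust registration configuration
#'
#' @param criterion robust criterion: `"huber"` (default), `"tukey"`,
#'   `"cauchy"`, `"welsch"`, or `"identity"` (plain least squares).
#' @param r_b relative robust-bound margin; the bound is
#'   `Z = (1 + r_b) * median(residuals)`.
#' @param alpha anchor weight as a fraction of the summed data weights.
#' @param max_iter maximum IRLS/ICP iterations per frame.
#' @param undersample_factor keep every `factor`-th point in raster order.
#' @param outlier_cutoff pre-optimizer distance cutoff in mm.
#' @param convergence_tol stop when the inter-iteration pose change (HPD
#'   over the session ball) falls below this, in mm.
#' @param anchor_mode `"weight_sum"` scales the anchor by `alpha * sum(w)`
#'   (default); `"criterion_sum"` by `alpha * sum(psi(res))`.
#' @return An object of class `robust_config`.
#' @export
robust_config <- function(criterion = c("huber", "tukey", "cauchy", "welsch",
                                        "identity"),
                          r_b = 0.2, alpha = 0.03, max_iter = 30,
                          undersample_factor = 3, outlier_cutoff = 5,
                          convergence_tol = 1e-4,
                          anchor_mode = c("weight_sum", "criterion_sum")) {
  criterion <- match.arg(criterion)
  anchor_mode <- match.arg(anchor_mode)
  stopifnot(r_b >= 0, alpha >= 0, max_iter >= 1, undersample_factor >= 1,
            outlier_cutoff > 0, convergence_tol >= 0)
  structure(list(criterion = criterion, r_b = r_b, alpha = alpha,
                 max_iter = as.integer(max_iter),
                 undersample_factor = as.integer(undersample_factor),
                 outlier_cutoff = outlier_cutoff,
                 convergence_tol = convergence_tol,
                 anchor_mode = anchor_mode),
            class = "robust_config")
}

# Scale constants giving each criterion the same asymptotic variance as
# Huber at its bound (95% relative-efficiency tuning constants from the
# robust-statistics literature): Huber 1.345, Tukey 4.685, Cauchy 2.385,
# Welsch 2.985. Given a Huber bound Z, the others use c = Z * const/1.345.
.crit_scale <- function(kind, bound) {
  switch(kind,
         huber = bound,
         tukey = bound * 4.685 / 1.345,
         cauchy = bound * 2.385 / 1.345,
         welsch = bound * 2.985 / 1.345,
         identity = bound,
         stop("unknown robust criterion: ", kind))
}

#' Robust criterion value
#'
#' Penalty assigned to a residual. Huber is quadratic up to the bound `Z`
#' and linear beyond (`Z*res - Z^2/2`), continuous and once-differentiable
#' at `Z`. Tukey/Cauchy/Welsch are scale-matched to the same asymptotic
#' variance as Huber at bound `Z`; `identity` returns `res^2/2` always.
#'
#' @param res non-negative residual(s) in mm.
#' @param bound robust bound `Z` in mm (positive).
#' @param kind criterion name, see [robust_config()].
#' @return Penalty value(s), same length as `res`.
#' @export
criterion_value <- function(res, bound, kind = "huber") {
  stopifnot(all(res >= 0), bound > 0)
  c0 <- .crit_scale(kind, bound)
  switch(kind,
         identity = 0.5 * res^2,
         huber = ifelse(res <= bound, 0.5 * res^2, bound * res - bound^2 / 2),
         tukey = {
           u <- pmin(res / c0, 1)
           c0^2 / 6 * (1 - (1 - u^2)^3)
         },
         cauchy = c0^2 / 2 * log1p((res / c0)^2),
         welsch = c0^2 / 2 * (1 - exp(-(res / c0)^2)))
}

#' IRLS weight of a residual
#'
#' `criterion'(res)/res`, normalized so the weight at zero residual is 1.
#' Monotone non-increasing in the residual; Tukey and Welsch are
#' redescending (weight tends to 0 for large residuals).
#'
#' @inheritParams criterion_value
#' @return Weight(s) in `[0, 1]`.
#' @export
irls_weight <- function(res, bound, kind = "huber") {
  stopifnot(all(res >= 0), bound > 0)
  c0 <- .crit_scale(kind, bound)
  switch(kind,
         identity = rep(1, length(res)),
         huber = ifelse(res <= bound, 1, bound / res),
         tukey = ifelse(res <= c0, (1 - (res / c0)^2)^2, 0),
         cauchy = 1 / (1 + (res / c0)^2),
         welsch = exp(-(res / c0)^2))
}

#' Robust bound from residuals
#'
#' `Z = (1 + r_b) * median(residuals)`. A zero bound (all residuals zero)
#' is returned as-is; [register()] guards it by using unit weights.
#'
#' @param residuals vector of non-negative residuals (mm), at least one.
#' @param r_b relative margin, `>= 0`.
#' @return The bound `Z` in mm.
#' @export
robust_bound <- function(residuals, r_b = 0.2) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) == 0)
    stop("robust_bound: no finite residuals (degenerate registration input)")
  (1 + r_b) * median(residuals)
}

# nearest-neighbour indices + distances from query rows into ref rows
.nn <- function(query, ref) {
  res <- RANN::nn2(ref, query, k = 1)
  list(idx = as.integer(res$nn.idx[, 1]), dist = as.numeric(res$nn.dists[, 1]))
}

#' Discard distant outlier points
#'
#' Removes points whose nearest-neighbour distance to the reference, after
#' applying the warm-start pose `init`, exceeds `cutoff` (default 5 mm).
#' Applied before the optimizer so that far-off points cannot inflate the
#' residual median that sets the robust bound.
#'
#' @param cloud,reference `point_cloud` objects.
#' @param cutoff distance cutoff in mm.
#' @param init warm-start `rigid_transform` (pose of `cloud`).
#' @return The filtered `point_cloud`, point order preserved.
#' @export
remove_distant_outliers <- function(cloud, reference, cutoff = 5,
                                    init = rt_identity()) {
  d <- .nn(rt_apply(init, cloud$points), reference$points)$dist
  keep <- d <= cutoff
  if (!any(keep))
    stop("remove_distant_outliers: no points within cutoff (tracking loss)")
  point_cloud(cloud$points[keep, , drop = FALSE],
              grid_index = cloud$grid_index[keep],
              timestamp = cloud$timestamp)
}

#' Under-sample a point cloud on its raster grid
#'
#' Keeps every `factor`-th point in `grid_index` (raster) order; points
#' without a grid index are taken in storage order. Deterministic;
#' `factor = 1` is the identity.
#'
#' @param cloud A `point_cloud`.
#' @param factor positive integer stride.
#' @return The under-sampled `point_cloud`.
#' @export
grid_undersample <- function(cloud, factor = 3) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(cloud)
  ord <- if (is.null(cloud$grid_index)) seq_len(nrow(cloud$points))
         else order(cloud$grid_index)
  keep <- ord[seq(1L, length(ord), by = factor)]
  keep <- sort(keep)
  point_cloud(cloud$points[keep, , drop = FALSE],
              grid_index = cloud$grid_index[keep],
              timestamp = cloud$timestamp)
}

# weighted Kabsch: minimize sum w_i ||R x_i + t - y_i||^2
.weighted_kabsch <- function(x, y, w) {
  sw <- sum(w)
  xb <- colSums(x * w) / sw
  yb <- colSums(y * w) / sw
  xc <- sweep(x, 2, xb)
  yc <- sweep(y, 2, yb)
  H <- crossprod(xc * w, yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- yb - as.numeric(R %*% xb)
  rigid_transform(R, t)
}

#' Robust rigid registration of a frame to the reference
#'
#' Estimates the rigid transform aligning `frame` to `reference` by
#' iteratively reweighted ICP: each iteration finds nearest-neighbour
#' correspondences of the transformed frame points in the reference, sets
#' the robust bound `Z = (1 + r_b) * median(res)` from the current
#' residuals, converts residuals to IRLS weights under the configured
#' criterion, and solves the weighted Procrustes problem in closed form
#' (weighted Kabsch). An optional back-of-head anchor point enters the
#' solve as one pseudo-correspondence (anchor mapped to itself) with weight
#' `alpha` times the summed data weights, discouraging solutions that move
#' the occiput. Iteration stops at `max_iter` or when the pose change
#' between iterations (HPD over `ball`) drops below `convergence_tol`.
#'
#' @param frame,reference `point_cloud` objects. The reference is assumed
#'   cleaned and fixed for the session.
#' @param init warm-start pose (`rigid_transform`), typically the previous
#'   frame's result.
#' @param anchor optional length-3 anchor position (mm, reference space), or
#'   `NULL` for no regularization.
#' @param config A [robust_config()].
#' @param ball A [ball_model()], used for the convergence criterion.
#' @param preprocess if `TRUE`, apply [grid_undersample()] and
#'   [remove_distant_outliers()] (with `init`) before optimizing.
#' @param trace_objective if `TRUE`, record per-iteration objective values.
#' @return A list of class `registration_result`: `transform`,
#'   `iterations_used`, `final_rms_residual` (mm), `per_point_weight`,
#'   `n_points_used`, and (optionally) `objective`, a matrix with the
#'   weighted least-squares objective before and after each inner solve.
#' @export
register <- function(frame, reference, init = rt_identity(), anchor = NULL,
                     config = robust_config(), ball = ball_model(),
                     preprocess = FALSE, trace_objective = FALSE) {
  if (preprocess) {
    frame <- grid_undersample(frame, config$undersample_factor)
    frame <- remove_distant_outliers(frame, reference, config$outlier_cutoff,
                                     init)
  }
  x <- frame$points
  n <- nrow(x)
  if (n < 3)
    stop(sprintf("register: fewer than 3 usable points (tracking loss%s)",
                 if (!is.null(frame$timestamp))
                   sprintf(" at t=%.3f s", frame$timestamp) else ""))
  Tcur <- init
  w <- rep(1, n)
  obj <- if (trace_objective) matrix(NA_real_, config$max_iter, 2,
                                     dimnames = list(NULL, c("before", "after")))
         else NULL
  iters <- 0L
  res <- numeric(n)
  for (it in seq_len(config$max_iter)) {
    iters <- it
    xt <- rt_apply(Tcur, x)
    nn <- .nn(xt, reference$points)
    y <- reference$points[nn$idx, , drop = FALSE]
    res <- nn$dist
    Z <- robust_bound(res, config$r_b)
    w <- if (Z <= 0) rep(1, n) else irls_weight(res, Z, config$criterion)
    if (sum(w) <= 0)
      stop("register: all IRLS weights are zero (degenerate frame)")
    if (!is.null(anchor) && config$alpha > 0) {
      wa <- config$alpha * (if (config$anchor_mode == "weight_sum") sum(w)
                            else sum(criterion_value(res, max(Z, .Machine$double.eps),
                                                     config$criterion)))
      xs <- rbind(x, anchor)
      ys <- rbind(y, anchor)
      ws <- c(w, wa)
    } else {
      xs <- x; ys <- y; ws <- w
    }
    if (trace_objective) {
      rcur <- sqrt(rowSums((rt_apply(Tcur, xs) - ys)^2))
      obj[it, 1] <- sum(ws * rcur^2)
    }
    Tnew <- .weighted_kabsch(xs, ys, ws)
    if (!all(is.finite(Tnew$rotation)) || !all(is.finite(Tnew$translation)))
      stop("register: non-finite solve")
    if (trace_objective) {
      rnew <- sqrt(rowSums((rt_apply(Tnew, xs) - ys)^2))
      obj[it, 2] <- sum(ws * rnew^2)
    }
    delta <- hpd(Tcur, Tnew, ball)
    Tcur <- Tnew
    if (delta < config$convergence_tol) break
  }
  # residuals at the final pose
  nnf <- .nn(rt_apply(Tcur, x), reference$points)
  structure(list(transform = Tcur, iterations_used = iters,
                 final_rms_residual = sqrt(mean(nnf$dist^2)),
                 per_point_weight = w, n_points_used = n,
                 objective = if (trace_objective) obj[seq_len(iters), , drop = FALSE]
                             else NULL),
            class = "registration_result")
}

#' Track a sequence of frames against the reference
#'
#' Registers time-ordered frames sequentially, warm-starting each frame with
#' the previous frame's pose (the first with the identity). Each frame is
#' grid-under-sampled and outlier-filtered before optimization. A frame that
#' fails (too few points after filtering) is marked invalid and tracking
#' resumes from the last good pose; an error is raised only if more than
#' half of the frames fail.
#'
#' @param frames list of `point_cloud` objects with timestamps, time-ordered.
#' @param reference cleaned reference `point_cloud`.
#' @inheritParams register
#' @return A list with `trace` (a [motion_trace()] in the reference/camera
#'   space, invalid frames flagged) and `results` (per-frame
#'   `registration_result` or `NULL` for failed frames).
#' @export
track_sequence <- function(frames, reference, anchor = NULL,
                           config = robust_config(), ball = ball_model()) {
  n <- length(frames)
  stopifnot(n >= 1)
  times <- vapply(frames, function(f) {
    if (is.null(f$timestamp)) stop("track_sequence: frames need timestamps")
    f$timestamp
  }, numeric(1))
  if (is.unsorted(times, strictly = TRUE))
    stop("track_sequence: frame timestamps must be strictly increasing")
  qmat <- matrix(NA_real_, n, 4)
  tmat <- matrix(NA_real_, n, 3)
  valid <- logical(n)
  results <- vector("list", n)
  last <- rt_identity()
  nfail <- 0L
  for (k in seq_len(n)) {
    r <- tryCatch(
      register(frames[[k]], reference, init = last, anchor = anchor,
               config = config, ball = ball, preprocess = TRUE),
      error = function(e) e)
    if (inherits(r, "error")) {
      nfail <- nfail + 1L
      results[[k]] <- NULL
    } else {
      results[[k]] <- r
      last <- r$transform
      qmat[k, ] <- as_quaternion(last)
      tmat[k, ] <- last$translation
      valid[k] <- TRUE
    }
  }
  if (nfail > n / 2)
    stop(sprintf("track_sequence: %d of %d frames failed", nfail, n))
  list(trace = motion_trace(times, tmat, qmat, valid = valid,
                            space = "camera",
                            note = "registered to session reference"),
       results = results)
}
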