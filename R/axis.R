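# Central-axis fitting.  Random points are sampled inside a bone contour and
# a line y = m x + b is fitted by gradient descent on the sum of
# smoothed-Manhattan residuals f(d) = 2 (sqrt(1 + d^2/2) - 1): quadratic
# near zero (Euclidean smoothness), linear in the tails (Manhattan
# robustness).  Because bone shafts are near-vertical, the fit runs in a
# swapped frame (x as a function of y) whenever the point cloud's vertical
# extent dominates; the reported direction angle is frame-independent.

#' Axis-fit configuration
#'
#' @param n_points Number of random interior points (>= 10).
#' @param seed RNG seed for the interior sampling.
#' @param alpha Initial gradient-descent learning rate.
#' @param max_iter Iteration cap.
#' @param tol Stop when the relative loss improvement falls below this.
#' @param backtracking Use backtracking line search (guarantees a
#'   non-increasing loss). `FALSE` reproduces the raw fixed-step update.
#' @return List of class `axis_fit_config`.
#' @export
axis_fit_config <- function(n_points = 500L, seed = 1L, alpha = 1e-3,
                            max_iter = 5000L, tol = 1e-8, backtracking = TRUE) {
  stopifnot(n_points >= 10, alpha > 0, max_iter >= 1, tol >= 0)
  structure(list(n_points = as.integer(n_points), seed = as.integer(seed),
                 alpha = alpha, max_iter = as.integer(max_iter), tol = tol,
                 backtracking = backtracking),
            class = "axis_fit_config")
}

#' Smoothed-Manhattan (pseudo-Huber-style) residual penalty
#'
#' `f(d) = 2 (sqrt(1 + d^2 / 2) - 1)`: even, `f(0) = 0`, `f(d) ~ d^2/2` as
#' `d -> 0` and `f(d) ~ sqrt(2) |d|` as `|d| -> Inf`.
#'
#' @param d Signed residual(s).
#' @return Non-negative value(s).
#' @export
smoothed_distance <- function(d) {
  2 * (sqrt(1 + d^2 / 2) - 1)
}

# derivative of smoothed_distance
smoothed_distance_grad <- function(d) d / sqrt(1 + d^2 / 2)

#' Axis loss of a candidate line
#'
#' Sum over points of [smoothed_distance()] applied to the vertical residual
#' `d_i = y_i - (m x_i + b)` in the fitting frame.
#'
#' @param points n x 2 matrix of (x, y).
#' @param m,b Line slope and intercept.
#' @return Non-negative scalar; 0 iff all points lie on the line.
#' @export
axis_loss <- function(points, m, b) {
  d <- points[, 2] - (m * points[, 1] + b)
  sum(smoothed_distance(d))
}

#' Sample random points strictly inside a contour
#'
#' Rejection sampling over the bounding box with an even-odd
#' point-in-polygon test; reproducible for a fixed seed.
#'
#' @param contour A [new_contour()].
#' @param cfg An [axis_fit_config()].
#' @return n x 2 matrix of (x, y) points.
#' @export
sample_interior_points <- function(contour, cfg = axis_fit_config()) {
  v <- contour$vertices
  if (contour$area < 100) stop("contour too small to sample interior points")
  xr <- range(v[, 1]); yr <- range(v[, 2])
  n <- cfg$n_points
  with_seed(cfg$seed, {
    out <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(out) < n) {
      m <- max(2L * n, 256L)
      px <- stats::runif(m, xr[1], xr[2])
      py <- stats::runif(m, yr[1], yr[2])
      keep <- points_in_polygon(px, py, v)
      out <- rbind(out, cbind(px[keep], py[keep]))
      tries <- tries + 1L
      if (tries > 200L) stop("contour too small to host interior points")
    }
    out[seq_len(n), , drop = FALSE]
  })
}

# Build an axis_line object from in-frame slope/intercept.
new_axis_line <- function(m, b, frame = c("xy", "swapped"), loss = NA_real_,
                          converged = TRUE) {
  frame <- match.arg(frame)
  if (frame == "xy") {
    dir <- c(1, m)
    point <- c(0, b)
  } else {  # x = m y + b
    dir <- c(m, 1)
    point <- c(b, 0)
  }
  theta <- direction_theta(dir[1], dir[2])
  structure(list(m = m, b = b, frame = frame, theta = theta,
                 point = point, dir = dir / sqrt(sum(dir^2)),
                 loss = loss, converged = converged),
            class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("<axis_line theta=%.2f deg (%s frame: m=%.4f b=%.2f), loss=%.4g%s>\n",
              x$theta, x$frame, x$m, x$b, x$loss,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Unit direction of an axis pointing distally (toward smaller row)
#' @param axis An `axis_line`.
#' @return Length-2 unit vector.
#' @export
axis_unit_distal <- function(axis) theta_unit_distal(axis$theta)

#' Fit the central axis of a point cloud
#'
#' Gradient descent on [axis_loss()], starting from slope 0 and intercept at
#' the cloud centroid.  With backtracking (default) the loss sequence is
#' non-increasing.  The fitting frame is chosen so the slope stays O(1):
#' `y = m x + b` for horizontally extended clouds, `x = m y + b` for
#' vertically extended ones.
#'
#' @param points n x 2 matrix of (x, y) points (>= 10, not all coincident).
#' @param cfg An [axis_fit_config()].
#' @return An `axis_line` (with `converged = FALSE` and a warning if the
#'   iteration cap was reached before the tolerance).
#' @export
fit_axis <- function(points, cfg = axis_fit_config()) {
  stopifnot(nrow(points) >= 10)
  if (max(apply(points, 2, function(z) diff(range(z)))) < 1e-9)
    stop("all points coincident")
  swapped <- diff(range(points[, 2])) > diff(range(points[, 1]))
  u <- if (swapped) points[, 2] else points[, 1]
  w <- if (swapped) points[, 1] else points[, 2]
  # centre and scale the abscissa: plain gradient descent on (m, b) is
  # badly conditioned when u spans hundreds of px; in the standardised
  # frame both gradients live on comparable scales
  uc <- mean(u)
  su <- stats::sd(u); if (!is.finite(su) || su < 1e-9) su <- 1
  us <- (u - uc) / su
  m <- 0; b <- mean(w)
  loss <- sum(smoothed_distance(w - (m * us + b)))
  alpha <- cfg$alpha
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    d <- w - (m * us + b)
    g <- smoothed_distance_grad(d)
    gm <- -sum(g * us)
    gb <- -sum(g)
    if (cfg$backtracking) {
      step_ok <- FALSE
      for (bt in 1:60) {
        m2 <- m - alpha * gm; b2 <- b - alpha * gb
        l2 <- sum(smoothed_distance(w - (m2 * us + b2)))
        if (l2 <= loss) { step_ok <- TRUE; break }
        alpha <- alpha / 2
      }
      if (!step_ok) { converged <- TRUE; break }
      improved <- loss - l2
      m <- m2; b <- b2; loss <- l2
      alpha <- min(alpha * 1.25, 1)
      if (improved < cfg$tol * max(1, loss)) { converged <- TRUE; break }
    } else {
      m <- m - alpha * gm; b <- b - alpha * gb
      l2 <- sum(smoothed_distance(w - (m * us + b)))
      if (abs(loss - l2) < cfg$tol * max(1, l2)) { loss <- l2; converged <- TRUE; break }
      loss <- l2
    }
  }
  if (!converged)
    warning("axis fit reached max_iter without meeting tolerance", call. = FALSE)
  m <- m / su            # undo scaling
  b_full <- b - m * uc   # undo centering
  new_axis_line(m, b_full, frame = if (swapped) "swapped" else "xy",
                loss = loss, converged = converged)
}

#' Brute-force grid oracle for the axis fit
#'
#' Independent check of [fit_axis()]: evaluates [axis_loss()] on a dense
#' grid of line angles (default 0.1 degree steps) and offsets (default
#' 0.5 px steps spanning the feasible intercept range of the cloud) in the
#' same fitting frame the fitter would use, and returns the grid minimum.
#'
#' @param points n x 2 matrix.
#' @param angle_step Grid step in degrees.
#' @param offset_step Grid step in px.
#' @return List with `loss`, `m`, `b`, `frame`, `theta`.
#' @export
axis_grid_oracle <- function(points, angle_step = 0.1, offset_step = 0.5) {
  swapped <- diff(range(points[, 2])) > diff(range(points[, 1]))
  u <- if (swapped) points[, 2] else points[, 1]
  w <- if (swapped) points[, 1] else points[, 2]
  uc <- mean(u); us <- u - uc
  best <- list(loss = Inf, m = NA, b = NA)
  # in-frame slopes limited to |m| <= tan(60 deg); the frame choice keeps
  # the optimum well inside this
  angles <- seq(-60, 60, by = angle_step)
  for (a in angles) {
    m <- tan(deg2rad(a))
    r <- w - m * us
    bs <- seq(min(r), max(r), by = offset_step)
    # loss for all offsets at once
    fo <- colSums(smoothed_distance(outer(r, bs, `-`)))
    i <- which.min(fo)
    if (fo[i] < best$loss) best <- list(loss = fo[i], m = m, b = bs[i])
  }
  b_full <- best$b - best$m * uc
  frame <- if (swapped) "swapped" else "xy"
  dir <- if (swapped) c(best$m, 1) else c(1, best$m)
  list(loss = best$loss, m = best$m, b = b_full, frame = frame,
       theta = direction_theta(dir[1], dir[2]))
}

#' Reference (baseline) axis of a view
#'
#' Composes contour extraction and axis fitting on the designated shaft
#' part: the ulnar diaphysis in the AP view, the proximal radial diaphysis
#' in the LAT view — the parts least affected by the fracture.
#'
#' @param mask A [label_mask()].
#' @param cfg An [axis_fit_config()].
#' @param contour_cfg A [contour_config()].
#' @return An `axis_line`.
#' @export
reference_axis <- function(mask, cfg = axis_fit_config(),
                           contour_cfg = contour_config()) {
  part <- if (mask$view == "AP") "ulna" else "proximal_radius"
  ct <- part_contour(mask, part, contour_cfg)
  pts <- sample_interior_points(ct, cfg)
  fit_axis(pts, cfg)
}
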