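# Low-level planar geometry helpers.
#
# Coordinate convention used throughout the package: image coordinates with
# x = column index and y = row index, origin at the top-left, y increasing
# DOWNWARD.  "Distal" (toward the hand) is up, i.e. smaller y.  Angles of
# undirected lines live in [0, 180) degrees and are measured so that a line
# with direction angle theta has unit direction (cos(theta), -sin(theta)):
# theta = 90 is vertical, theta = 0 horizontal.  A positive rotation `rot_cw`
# is clockwise as seen on screen.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' @noRd
wrap_angle_180 <- function(deg) {
  a <- deg %% 180
  a[a < 0] <- a[a < 0] + 180
  a
}

# Direction angle (degrees, [0,180)) of an undirected direction vector in
# image (y-down) coordinates.
direction_theta <- function(dx, dy) {
  wrap_angle_180(rad2deg(atan2(-dy, dx)))
}

# Unit vector pointing DISTALLY (y component <= 0) along a line of angle theta.
theta_unit_distal <- function(theta_deg) {
  u <- c(cos(deg2rad(theta_deg)), -sin(deg2rad(theta_deg)))
  if (u[2] > 1e-12) u <- -u
  u
}

#' Rotate points clockwise on screen
#'
#' Rotates points (n x 2 matrix or a length-2 vector) by `deg` degrees about
#' `center`, clockwise as seen on screen (the standard positive rotation in
#' y-down image coordinates).
#'
#' @param pts Points to rotate.
#' @param deg Angle in degrees.
#' @param center Rotation centre.
#' @return Rotated points, same shape as the input.
#' @export
rot_cw <- function(pts, deg, center = c(0, 0)) {
  one <- is.null(dim(pts))
  p <- if (one) matrix(pts, ncol = 2) else pts
  th <- deg2rad(deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- sweep(p, 2, center) %*% t(R)
  out <- sweep(out, 2, center, `+`)
  if (one) drop(out) else out
}

# Signed shoelace area of a polygon given as an n x 2 matrix of vertices
# (closed implicitly; a duplicated last vertex is tolerated).
shoelace_area <- function(v) {
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_area <- function(v) abs(shoelace_area(v))

polygon_centroid <- function(v) {
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Even-odd point-in-polygon test
#'
#' Vectorised over query points; `poly` is an n x 2 vertex matrix (open or
#' closed).
#'
#' @param px,py Coordinates of the query points.
#' @param poly Polygon vertex matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  inside <- logical(length(px))
  xj <- poly[n, 1]; yj <- poly[n, 2]
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- (xj - xi) * (py[crosses] - yi) / (yj - yi) + xi
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
    xj <- xi; yj <- yi
  }
  inside
}

# Intersections of the undirected line {center + t * dir} with the closed
# polyline `verts` (n x 2).  Returns a data.frame with columns t, x, y
# (t is the signed parameter along `dir`; distance = |t| for unit dir).
line_polyline_intersections <- function(center, dir, verts, closed = TRUE) {
  v <- verts
  if (closed && !all(v[1, ] == v[nrow(v), ])) v <- rbind(v, v[1, ])
  ax <- v[-nrow(v), 1]; ay <- v[-nrow(v), 2]
  bx <- v[-1, 1];       by <- v[-1, 2]
  ex <- bx - ax; ey <- by - ay
  # solve center + t*dir = a + s*e,  s in [0,1)
  den <- dir[1] * ey - dir[2] * ex
  ok <- abs(den) > 1e-12
  t <- ((ax - center[1]) * ey - (ay - center[2]) * ex) / den
  s <- ((ax - center[1]) * dir[2] - (ay - center[2]) * dir[1]) / den
  keep <- ok & s >= 0 & s < 1 & is.finite(t)
  data.frame(t = t[keep],
             x = center[1] + t[keep] * dir[1],
             y = center[2] + t[keep] * dir[2])
}

# Resample a closed polygon at approximately `spacing` arc-length steps.
resample_polygon <- function(v, spacing = 1.5) {
  if (!all(v[1, ] == v[nrow(v), ])) v <- rbind(v, v[1, ])
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n <- max(8L, ceiling(total / spacing))
  at <- seq(0, total, length.out = n + 1)[-(n + 1)]
  x <- stats::approx(cum, v[, 1], xout = at)$y
  y <- stats::approx(cum, v[, 2], xout = at)$y
  cbind(x, y)
}

# Outward unit normals of a closed polygon's vertices (averaged edge normals).
polygon_outward_normals <- function(v) {
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  prv <- rbind(v[n, , drop = FALSE], v[-n, , drop = FALSE])
  t1 <- nxt - v; t2 <- v - prv
  tang <- t1 / pmax(sqrt(rowSums(t1^2)), 1e-12) + t2 / pmax(sqrt(rowSums(t2^2)), 1e-12)
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  nrm <- cbind(-tang[, 2], tang[, 1])
  # orient outward: for a polygon with positive shoelace sign in y-down
  # coordinates the left normal points inward, so flip by the area sign.
  if (shoelace_area(v) > 0) nrm <- -nrm
  nrm
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the global RNG state afterwards, so seeded helpers do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
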