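# Rotating-line detection of the five anatomical landmarks.
#
# Canonical frame (right wrist after read-time canonicalisation): distal is
# up; in the AP view the radius lies on the LEFT (radial = smaller x, ulnar
# = larger x); in the LAT view volar is the LEFT (-x) side.  All sweeps are
# "screen" rotations in y-down coordinates: clockwise means the right arm
# of the line dips downward.

#' Rotating-line search configuration
#'
#' @param step_deg Rotation increment in degrees (default 0.01).
#' @param min_dist_frac "Significantly distant" threshold, as a fraction of
#'   the swept contour's bounding-box width.
#' @param max_sweep_deg Sweep cap guaranteeing termination.
#' @return List of class `rotating_line_config`.
#' @export
rotating_line_config <- function(step_deg = 0.01, min_dist_frac = 0.25,
                                 max_sweep_deg = 180) {
  stopifnot(step_deg > 0, step_deg <= 1, min_dist_frac > 0, min_dist_frac < 1)
  structure(list(step_deg = step_deg, min_dist_frac = min_dist_frac,
                 max_sweep_deg = max_sweep_deg),
            class = "rotating_line_config")
}

contour_bbox_width <- function(contour) diff(range(contour$vertices[, 1]))

# Sweep an undirected line anchored at `center`, starting horizontal, in
# `sense` ("cw"/"ccw") steps of step_deg, and return the first intersection
# with the contour at distance >= min_dist from the center.
# Implementation: every contour vertex is first touched at the sweep angle
# that aligns the line with it; the earliest qualifying vertex fixes the
# sweep step, and the exact hit is the nearest qualifying line/edge
# intersection at that step.
rotating_first_hit <- function(contour, center, sense = c("cw", "ccw"),
                               cfg = rotating_line_config(),
                               min_dist = NULL) {
  sense <- match.arg(sense)
  v <- contour$vertices
  if (is.null(min_dist)) min_dist <- cfg$min_dist_frac * contour_bbox_width(contour)
  wx <- v[, 1] - center[1]; wy <- v[, 2] - center[2]
  dist <- sqrt(wx^2 + wy^2)
  ang <- rad2deg(atan2(wy, wx)) %% 180  # undirected line angle touching vertex
  psi <- if (sense == "cw") ang else (-ang) %% 180
  ok <- dist >= min_dist
  if (!any(ok)) return(NULL)
  psi_star <- min(psi[ok])
  if (psi_star > cfg$max_sweep_deg) return(NULL)
  # discrete sweep lands on the first multiple of step_deg at/after psi_star
  phi <- ceiling((psi_star - 1e-9) / cfg$step_deg) * cfg$step_deg
  # At the touch angle the line is tangent to the contour, so on a
  # pixelated contour the touch point is a vertex and all qualifying
  # vertices inside the current sweep step belong to the grazed corner
  # cluster; the FARTHEST of them is the stable estimate of the touch
  # point (nearer ones are staircase pixels the discretised line clips on
  # the way in).
  cand <- which(ok & psi <= phi + 1e-9)
  i <- cand[which.max(dist[cand])]
  list(point = c(x = unname(v[i, 1]), y = unname(v[i, 2])), sweep_deg = phi)
}

# Topmost vertex of a contour with a side-aware tie-break.
topmost_vertex <- function(contour, tie = c("min_x", "max_x")) {
  tie <- match.arg(tie)
  v <- contour$vertices
  ymin <- min(v[, 2])
  cand <- v[abs(v[, 2] - ymin) < 1e-9, , drop = FALSE]
  i <- if (tie == "min_x") which.min(cand[, 1]) else which.max(cand[, 1])
  cand[i, ]
}

#' Detect the styloid tip (ST)
#'
#' The vertex of the AP distal-radius contour with the smallest row
#' coordinate; ties break toward the radial side (smaller x in the
#' canonical frame).
#'
#' @param radius_contour AP distal-radius contour.
#' @return Named (x, y) point.
#' @export
detect_ST <- function(radius_contour) {
  p <- topmost_vertex(radius_contour, tie = "min_x")
  c(x = unname(p[1]), y = unname(p[2]))
}

#' Detect the ulnar border of the radius (UBR)
#'
#' A line anchored at ST starts at slope 0 and rotates clockwise in
#' `step_deg` increments; the first intersection with the distal-radius
#' contour at distance >= `min_dist_frac` x contour width is UBR.
#'
#' @param radius_contour AP distal-radius contour.
#' @param ST The styloid tip.
#' @param ref_axis Reference axis (unused by the sweep itself; kept for the
#'   module contract).
#' @param cfg A [rotating_line_config()].
#' @return Named (x, y) point; errors if the sweep exhausts `max_sweep_deg`.
#' @export
detect_UBR <- function(radius_contour, ST, ref_axis = NULL,
                       cfg = rotating_line_config()) {
  # the articular surface lies within ~60 deg of the perpendicular to the
  # shaft; a sweep past that would be grabbing the far cortex
  cfg$max_sweep_deg <- min(cfg$max_sweep_deg, 60)
  hit <- rotating_first_hit(radius_contour, ST, "cw", cfg)
  if (is.null(hit)) stop("UBR not found", call. = FALSE)
  c(x = unname(hit$point[1]), y = unname(hit$point[2]))
}

#' Detect the ulnar height point (UH) and ul_UBR
#'
#' From the topmost vertex of the ulna contour a line rotates
#' counterclockwise until it first meets the contour at qualifying distance
#' (falling back to a clockwise sweep, with a warning, when global rotation
#' puts the far corner on the other side).  The fitted ulna axis is
#' intersected with the distal contour; of the two flat-surface endpoints
#' the one farther from that intersection is ul_UBR, and UH is the
#' vertex-index midpoint of the (shorter) contour arc between the axis
#' intersection and ul_UBR — the centre of the flat distal joint surface.
#'
#' @param ulna_contour AP ulna contour (dense).
#' @param ulna_axis Fitted ulna `axis_line`.
#' @param cfg A [rotating_line_config()].
#' @return List with points `UH` and `ul_UBR`.
#' @export
detect_UH <- function(ulna_contour, ulna_axis, cfg = rotating_line_config()) {
  v <- ulna_contour$vertices
  C <- topmost_vertex(ulna_contour, tie = "max_x")
  # the flat distal surface is near-perpendicular to the shaft; cap the
  # sweep so it can never wrap around onto the diaphysis
  cfg$max_sweep_deg <- min(cfg$max_sweep_deg, 45)
  hit <- rotating_first_hit(ulna_contour, C, "ccw", cfg)
  if (is.null(hit)) {
    warning("counterclockwise sweep found no qualifying point; sweeping clockwise",
            call. = FALSE)
    hit <- rotating_first_hit(ulna_contour, C, "cw", cfg)
  }
  if (is.null(hit)) stop("ul_UBR not found", call. = FALSE)
  S <- hit$point
  # most distal intersection of the axis with the contour
  ints <- line_polyline_intersections(ulna_axis$point, ulna_axis$dir, v)
  if (nrow(ints) == 0) stop("ulna axis does not intersect the contour", call. = FALSE)
  I <- c(ints$x[which.min(ints$y)], ints$y[which.min(ints$y)])
  dC <- sum((C - I)^2); dS <- sum((S - I)^2)
  ul_UBR <- if (dS >= dC) S else C
  # vertex-index midpoint of the shorter arc between I and ul_UBR
  iI <- nearest_vertex_index(v, I)
  iU <- nearest_vertex_index(v, ul_UBR)
  UH <- arc_midpoint(v, iI, iU)
  list(UH = c(x = unname(UH[1]), y = unname(UH[2])),
       ul_UBR = c(x = unname(ul_UBR[1]), y = unname(ul_UBR[2])))
}

nearest_vertex_index <- function(v, p) {
  which.min((v[, 1] - p[1])^2 + (v[, 2] - p[2])^2)
}

# Midpoint (by vertex index) of the shorter closed-contour arc between
# vertex indices i and j; invariant to vertex-order reversal.
arc_midpoint <- function(v, i, j) {
  n <- nrow(v)
  fwd <- (j - i) %% n   # i -> j walking forward
  bwd <- (i - j) %% n
  if (fwd <= bwd) {
    k <- (i - 1 + fwd %/% 2) %% n + 1
    if (fwd %% 2 == 1) {
      k2 <- (i - 1 + fwd %/% 2 + 1) %% n + 1
      return((v[k, ] + v[k2, ]) / 2)
    }
    v[k, ]
  } else {
    k <- (j - 1 + bwd %/% 2) %% n + 1
    if (bwd %% 2 == 1) {
      k2 <- (j - 1 + bwd %/% 2 + 1) %% n + 1
      return((v[k, ] + v[k2, ]) / 2)
    }
    v[k, ]
  }
}

#' Detect the dorsal joint rim (DJ)
#'
#' Topmost vertex of the LAT distal-radius contour; ties break toward the
#' dorsal side (larger x in the canonical frame, volar being -x).  Under
#' dorsal tilt the anatomically highest point is the volar rim; the
#' pipeline re-assigns DJ/VJB names by canonical side after the sweep.
#'
#' @param lat_radius_contour LAT distal-radius contour.
#' @return Named (x, y) point.
#' @export
detect_DJ <- function(lat_radius_contour) {
  p <- topmost_vertex(lat_radius_contour, tie = "max_x")
  c(x = unname(p[1]), y = unname(p[2]))
}

#' Classify the displacement of the distal fragment
#'
#' Volar if the distal fragment's centroid lies on the volar side of the
#' proximal radial shaft axis, dorsal otherwise; a centroid within 0.5 px
#' of the axis returns dorsal with a warning.
#'
#' @param lat_radius_contour LAT distal-radius contour.
#' @param lat_axis Proximal-radius `axis_line`.
#' @return `"volar"` or `"dorsal"`.
#' @export
classify_displacement <- function(lat_radius_contour, lat_axis) {
  cen <- polygon_centroid(lat_radius_contour$vertices)
  vol <- volar_unit(lat_axis)
  off <- sum((cen - lat_axis$point) * vol)
  if (abs(off) <= 0.5) {
    warning("fragment centroid ambiguous (within 0.5 px of the axis); calling dorsal",
            call. = FALSE)
    return("dorsal")
  }
  if (off > 0) "volar" else "dorsal"
}

# Unit vector perpendicular to the axis pointing toward the canonical volar
# side (-x half-plane).
volar_unit <- function(axis) {
  u <- axis_unit_distal(axis)
  v <- c(u[2], -u[1])
  if (v[1] > 0) v <- -v
  v
}

#' Detect the volar joint border (VJB)
#'
#' With DJ as rotation centre the line rotates counterclockwise for volar
#' displacement and clockwise for dorsal displacement until the first
#' qualifying intersection with the contour (same minimum-distance rule as
#' UBR).
#'
#' @param lat_radius_contour LAT distal-radius contour.
#' @param DJ Rotation centre (the topmost rim point).
#' @param displacement `"volar"` or `"dorsal"`.
#' @param cfg A [rotating_line_config()].
#' @return Named (x, y) point; errors if no qualifying intersection.
#' @export
detect_VJB <- function(lat_radius_contour, DJ,
                       displacement = c("volar", "dorsal"),
                       cfg = rotating_line_config()) {
  displacement <- match.arg(displacement)
  sense <- if (displacement == "volar") "ccw" else "cw"
  cfg$max_sweep_deg <- min(cfg$max_sweep_deg, 60)
  hit <- rotating_first_hit(lat_radius_contour, DJ, sense, cfg)
  if (is.null(hit)) stop("VJB not found", call. = FALSE)
  p <- hit$point
  if (sum((p - DJ)^2) < 1e-12) stop("VJB not found", call. = FALSE)
  c(x = unname(p[1]), y = unname(p[2]))
}

#' Assemble a landmark set
#'
#' @param ST,UBR,UH,ul_UBR AP-view points.
#' @param DJ,VJB LAT-view points.
#' @param displacement `"volar"` or `"dorsal"`.
#' @return List of class `landmark_set`.
#' @export
landmark_set <- function(ST, UBR, UH, ul_UBR, DJ, VJB,
                         displacement = c("volar", "dorsal")) {
  displacement <- match.arg(displacement)
  structure(list(ST = ST, UBR = UBR, UH = UH, ul_UBR = ul_UBR,
                 DJ = DJ, VJB = VJB, displacement = displacement),
            class = "landmark_set")
}
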