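# Radiographic parameters from landmarks and reference axes.
#
# Sign conventions (radiology convention, canonical right-wrist frame):
#   RA > 0 when the styloid tip is distal to the ulnar border of the radius
#          (normal anatomy);
#   UV > 0 when the ulnar head surface is distal to UBR (ulna relatively
#          long, "ulnar-positive variance");
#   PT > 0 for volar tilt (volar rim proximal to the dorsal rim), negative
#          for dorsal tilt.
# RL is always non-negative.  Lengths are multiplied by the pixel spacing;
# angles are calibration-free.

#' Signed projection of P - Q on an axis direction
#'
#' `(P - Q) . u` where `u` is the axis unit direction pointing distally
#' (toward smaller row).  Its absolute value equals the distance between the
#' two lines perpendicular to the axis through P and through Q.
#'
#' @param P,Q (x, y) points.
#' @param axis An `axis_line`.
#' @return Signed scalar (px).
#' @export
perpendicular_projection_distance <- function(P, Q, axis) {
  u <- axis_unit_distal(axis)
  if (any(!is.finite(u))) stop("degenerate axis")
  sum((as.numeric(P) - as.numeric(Q))[1:2] * u)
}

#' Radial angle (RA, degrees)
#'
#' Angle between the segment ST-UBR and the line perpendicular to the
#' baseline axis (erected through UBR), wrapped to (-90, 90]; positive when
#' ST is distal to UBR along the baseline direction.
#'
#' @param ST,UBR (x, y) landmarks.
#' @param ref_axis Baseline `axis_line` (AP ulnar diaphysis).
#' @return Degrees.
#' @export
compute_RA <- function(ST, UBR, ref_axis) {
  w <- as.numeric(ST)[1:2] - as.numeric(UBR)[1:2]
  if (sum(w^2) < 1e-18) stop("ST and UBR coincide")
  u <- axis_unit_distal(ref_axis)
  v <- c(u[2], -u[1])  # perpendicular of the baseline
  rad2deg(atan2(sum(w * u), abs(sum(w * v))))
}

#' Radial length (RL)
#'
#' Distance between the two perpendiculars to the baseline axis through ST
#' and through UBR, i.e. the projection of ST-UBR on the axis direction,
#' scaled to mm when spacing is given.
#'
#' @inheritParams compute_RA
#' @param spacing mm per px (1 = report px).
#' @return Non-negative length.
#' @export
compute_RL <- function(ST, UBR, ref_axis, spacing = 1.0) {
  abs(perpendicular_projection_distance(ST, UBR, ref_axis)) * spacing
}

#' Ulnar variance (UV)
#'
#' Signed projection of UH-UBR on the baseline axis: positive when the
#' distal ulnar surface is distal to the radius' sigmoid-notch level.
#'
#' @param UH,UBR (x, y) landmarks.
#' @param ref_axis Baseline `axis_line`.
#' @param spacing mm per px.
#' @return Signed length.
#' @export
compute_UV <- function(UH, UBR, ref_axis, spacing = 1.0) {
  perpendicular_projection_distance(UH, UBR, ref_axis) * spacing
}

#' Palmar (volar) tilt (PT, degrees)
#'
#' Angle between the articular rim line (volar rim to dorsal rim) and the
#' perpendicular to the LAT proximal-radius axis, wrapped to (-90, 90];
#' positive = volar tilt.  The endpoints may be passed in either order: they
#' are assigned to volar/dorsal by their position along the canonical volar
#' direction.
#'
#' @param VJB,DJ Rim landmarks (volar and dorsal joint border).
#' @param lat_axis LAT proximal-radius `axis_line`.
#' @return Degrees.
#' @export
compute_PT <- function(VJB, DJ, lat_axis) {
  p1 <- as.numeric(VJB)[1:2]; p2 <- as.numeric(DJ)[1:2]
  if (sum((p1 - p2)^2) < 1e-18) stop("VJB and DJ coincide")
  u <- axis_unit_distal(lat_axis)
  vol <- volar_unit(lat_axis)
  # volar-most endpoint minus dorsal-most endpoint
  if (sum(p1 * vol) < sum(p2 * vol)) { tmp <- p1; p1 <- p2; p2 <- tmp }
  w <- p1 - p2
  rad2deg(atan2(-sum(w * u), sum(w * vol)))
}

#' Assemble the four radiographic parameters
#'
#' @param landmarks A [landmark_set()].
#' @param ap_ref AP baseline `axis_line` (ulnar diaphysis).
#' @param lat_ref LAT reference `axis_line` (proximal radial diaphysis).
#' @param spacing mm per px; 1.0 reports px units.
#' @return List of class `radiographic_params` with fields `RA`, `RL`, `UV`,
#'   `PT`, `reference_angle`, `units`.
#' @export
assemble_params <- function(landmarks, ap_ref, lat_ref, spacing = 1.0) {
  for (nm in c("ST", "UBR", "UH", "DJ", "VJB")) {
    if (is.null(landmarks[[nm]]) || any(!is.finite(landmarks[[nm]])))
      stop("missing landmark '", nm, "'", call. = FALSE)
  }
  ra <- compute_RA(landmarks$ST, landmarks$UBR, ap_ref)
  rl <- compute_RL(landmarks$ST, landmarks$UBR, ap_ref, spacing)
  uv <- compute_UV(landmarks$UH, landmarks$UBR, ap_ref, spacing)
  pt <- compute_PT(landmarks$VJB, landmarks$DJ, lat_ref)
  structure(list(RA = ra, RL = rl, UV = uv, PT = pt,
                 reference_angle = ap_ref$theta,
                 units = if (spacing == 1.0) "px" else "mm",
                 spacing = spacing),
            class = "radiographic_params")
}

#' @export
print.radiographic_params <- function(x, ...) {
  cat(sprintf("RA = %.2f deg | RL = %.2f %s | UV = %+.2f %s | PT = %+.2f deg\n",
              x$RA, x$RL, x$units, x$UV, x$units, x$PT))
  cat(sprintf("(baseline axis %.2f deg, spacing %.3g mm/px)\n",
              x$reference_angle, x$spacing))
  invisible(x)
}
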