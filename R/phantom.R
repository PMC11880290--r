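# Synthetic biplane wrist phantom with exact ground truth.
#
# The phantom states the geometry the landmark procedures assume: stylised
# near-vertical bone silhouettes with (AP) a styloid apex on the distal
# radius, a proximally-bowed articular edge running from ST down to UBR,
# and an ulnar head whose gently sagging distal surface spans from the
# shaft axis to its radial corner (ul_UBR); and (LAT) a distal fragment
# whose articular rim line joins the dorsal (DJ) and volar (VJB) rims at
# the prescribed palmar tilt, displaced volarly or dorsally off the
# proximal shaft axis.  Parameters RA/RL/UV/PT are built in analytically,
# so recomputing them from the truth landmarks reproduces the spec exactly.

#' Phantom specification
#'
#' @param RA_true Radial angle in degrees (5 to 45; smaller angles push the
#'   articular width out of frame).
#' @param RL_true Radial length in px (2 to 30).
#' @param UV_true Signed ulnar variance in px (|UV| <= 10).
#' @param PT_true Palmar tilt in degrees (|PT| <= 35).
#' @param displacement `"volar"` or `"dorsal"`; default pairs with the tilt
#'   sign (volar displacement with volar tilt, the Smith/Colles pairing) and
#'   an inconsistent explicit combination is rejected, because the
#'   rotating-line sweep direction is keyed to the displacement side.
#' @param shaft_angle_deg Global bone direction (90 = vertical).
#' @param image_size (rows, cols).
#' @param noise_px Boundary jitter amplitude in px (0 = clean).
#' @param seed RNG seed for the jitter.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(RA_true = 22, RL_true = 11, UV_true = 0, PT_true = 11,
                         displacement = NULL, shaft_angle_deg = 90,
                         image_size = c(512L, 512L), noise_px = 0, seed = 1L) {
  stopifnot(RA_true >= 5, RA_true <= 45, RL_true >= 2, RL_true <= 30,
            abs(UV_true) <= 10, abs(PT_true) <= 35, noise_px >= 0)
  tilt_side <- if (PT_true >= 0) "volar" else "dorsal"
  if (is.null(displacement)) displacement <- tilt_side
  displacement <- match.arg(displacement, c("volar", "dorsal"))
  if (displacement != tilt_side)
    stop("displacement '", displacement, "' inconsistent with PT_true = ",
         PT_true, " (volar displacement pairs with volar tilt)", call. = FALSE)
  structure(list(RA_true = RA_true, RL_true = RL_true, UV_true = UV_true,
                 PT_true = PT_true, displacement = displacement,
                 shaft_angle_deg = shaft_angle_deg,
                 image_size = as.integer(image_size),
                 noise_px = noise_px, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Parabolically sagging edge from a to b (sag toward +n, the proximal side),
# sampled without its endpoints.
sag_edge <- function(a, b, sag, n_pts = 24) {
  t <- seq(0, 1, length.out = n_pts + 2)[-c(1, n_pts + 2)]
  chord <- rbind(b - a)
  nrm <- c(-(b - a)[2], (b - a)[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  if (nrm[2] < 0) nrm <- -nrm  # sag downward/proximal in the upright frame
  cbind(a[1] + t * chord[1] + 4 * sag * t * (1 - t) * nrm[1],
        a[2] + t * chord[2] + 4 * sag * t * (1 - t) * nrm[2])
}

#' Axis line through a point at a given direction angle
#'
#' @param point (x, y) point on the line.
#' @param theta_deg Direction angle in degrees, [0, 180).
#' @return An `axis_line`.
#' @export
axis_line_from <- function(point, theta_deg) {
  d <- c(cos(deg2rad(theta_deg)), -sin(deg2rad(theta_deg)))
  if (abs(d[2]) >= abs(d[1])) {
    m <- d[1] / d[2]
    new_axis_line(m, point[1] - m * point[2], frame = "swapped", loss = 0)
  } else {
    m <- d[2] / d[1]
    new_axis_line(m, point[2] - m * point[1], frame = "xy", loss = 0)
  }
}

# Rasterise polygons into a label image. `polys` is a list of n x 2
# matrices, `codes` the label value of each.
rasterize_polygons <- function(polys, codes, size) {
  img <- matrix(0L, size[1], size[2])
  for (k in seq_along(polys)) {
    v <- polys[[k]]
    cs <- max(1L, floor(min(v[, 1]))):min(size[2], ceiling(max(v[, 1])))
    rs <- max(1L, floor(min(v[, 2]))):min(size[1], ceiling(max(v[, 2])))
    px <- rep(cs, times = length(rs))
    py <- rep(rs, each = length(cs))
    inside <- points_in_polygon(px, py, v)
    img[cbind(py[inside], px[inside])] <- codes[k]
  }
  img
}

jitter_polygon <- function(v, noise_px) {
  if (noise_px <= 0) return(v)
  dense <- resample_polygon(v, spacing = 2)
  nrm <- polygon_outward_normals(dense)
  off <- stats::runif(nrow(dense), -noise_px, noise_px)
  dense + nrm * off
}

#' Generate a synthetic biplane wrist phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `ap` and `lat` [label_mask()]s and `truth`, a list
#'   holding the exact landmark coordinates, true shaft directions, per-part
#'   silhouette areas and the analytically reconstructed
#'   [assemble_params()] record.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- spec$image_size[1]; cols <- spec$image_size[2]
  center <- c((cols + 1) / 2, (rows + 1) / 2)
  rot <- 90 - spec$shaft_angle_deg   # screen-clockwise rotation to apply

  ## ---- AP view (upright frame; radius left, ulna right) ----
  RA <- spec$RA_true; RL <- spec$RL_true; UV <- spec$UV_true
  y_ubr <- 150; xs <- 160
  dx <- RL / tan(deg2rad(RA))
  ST  <- c(xs, y_ubr - RL)
  UBR <- c(xs + dx, y_ubr)
  chord_ap <- sqrt(sum((UBR - ST)^2))
  dr_poly <- rbind(
    ST,
    sag_edge(ST, UBR, sag = max(4, 0.15 * chord_ap)),
    UBR,
    c(UBR[1] + 4, y_ubr + 30),
    c(UBR[1], y_ubr + 70),
    c(xs - 10, y_ubr + 70),
    c(xs - 10, ST[2] + 25)
  )
  pr_poly <- rbind(c(xs - 5, y_ubr + 78), c(xs + 35, y_ubr + 78),
                   c(xs + 38, 350), c(xs + 35, rows - 57),
                   c(xs - 5, rows - 57), c(xs - 8, 350))
  x_su <- 330; hw <- 20; s_u <- 2.5
  y_uh <- y_ubr - UV              # centre of the flat distal ulnar surface
  y_c <- y_uh - s_u               # its corner height
  UH <- c(x_su - 22, y_uh)
  A <- c(x_su - 44, y_c)          # radial corner of the head = ul_UBR
  B <- c(x_su, y_c)               # corner on the shaft axis
  ulna_poly <- rbind(
    B,
    c(x_su + 16, y_c + 4),            # ulnar-side dome of the head knob
    c(x_su + 30, y_c + 12),
    c(x_su + 32, y_c + 26),
    c(x_su + hw, y_c + 44),
    c(x_su + hw, rows - 57),
    c(x_su - hw, rows - 57),
    c(x_su - hw, y_c + 30),
    c(x_su - 44, y_c + 8),
    A,
    sag_edge(A, B, sag = s_u)
  )

  ## ---- LAT view (upright frame; volar = -x) ----
  PT <- spec$PT_true
  x_pl <- 256; hw_l <- 22
  off <- if (spec$displacement == "volar") -8 else 8
  xmid <- x_pl + off; ymid <- 125; Lr <- 20
  DJ  <- c(xmid + Lr * cos(deg2rad(PT)), ymid - Lr * sin(deg2rad(PT)))
  VJB <- c(xmid - Lr * cos(deg2rad(PT)), ymid + Lr * sin(deg2rad(PT)))
  y_bot <- max(DJ[2], VJB[2]) + 50
  ldr_poly <- rbind(
    DJ,
    sag_edge(DJ, VJB, sag = 8),
    VJB,
    c(VJB[1] - 4, VJB[2] + 20),
    c(VJB[1] - 2, y_bot),
    c(DJ[1] + 2, y_bot),
    c(DJ[1] + 4, DJ[2] + 20)
  )
  lpr_poly <- rbind(c(x_pl - hw_l, 200), c(x_pl + hw_l, 200),
                    c(x_pl + hw_l, rows - 57), c(x_pl - hw_l, rows - 57))

  ## ---- global rotation and rasterisation ----
  ap_polys <- lapply(list(dr_poly, pr_poly, ulna_poly), rot_cw,
                     deg = rot, center = center)
  lat_polys <- lapply(list(ldr_poly, lpr_poly), rot_cw,
                      deg = rot, center = center)
  allv <- do.call(rbind, c(ap_polys, lat_polys))
  if (min(allv) < 11 || max(allv[, 1]) > cols - 10 || max(allv[, 2]) > rows - 10)
    stop("phantom does not fit inside the image with a 10 px margin",
         call. = FALSE)
  areas <- list(
    ap = vapply(ap_polys, polygon_area, numeric(1)),
    lat = vapply(lat_polys, polygon_area, numeric(1))
  )
  names(areas$ap) <- c("distal_radius", "proximal_radius", "ulna")
  names(areas$lat) <- c("distal_radius", "proximal_radius")
  if (spec$noise_px > 0) {
    ap_polys <- with_seed(spec$seed, lapply(ap_polys, jitter_polygon, spec$noise_px))
    lat_polys <- with_seed(spec$seed + 1L, lapply(lat_polys, jitter_polygon, spec$noise_px))
  }
  ap_img <- rasterize_polygons(ap_polys, codes = c(1L, 2L, 3L), c(rows, cols))
  lat_img <- rasterize_polygons(lat_polys, codes = c(1L, 2L), c(rows, cols))

  rp <- function(p) rot_cw(p, rot, center)
  theta <- spec$shaft_angle_deg %% 180
  ap_axis <- axis_line_from(rp(c(x_su, 300)), theta)
  lat_axis <- axis_line_from(rp(c(x_pl, 300)), theta)
  lm <- landmark_set(ST = rp(ST), UBR = rp(UBR), UH = rp(UH),
                     ul_UBR = rp(A), DJ = rp(DJ), VJB = rp(VJB),
                     displacement = spec$displacement)
  truth <- list(landmarks = lm, ap_axis_theta = theta, lat_axis_theta = theta,
                ap_axis = ap_axis, lat_axis = lat_axis,
                silhouette_areas = areas,
                params = assemble_params(lm, ap_axis, lat_axis, spacing = 1.0))
  list(ap = label_mask(ap_img, "AP"), lat = label_mask(lat_img, "LAT"),
       truth = truth, spec = spec)
}

#' Generate a reproducible batch of phantoms
#'
#' Parameters are drawn uniformly within `ranges`; displacement follows the
#' tilt sign.
#'
#' @param n Number of cases (>= 1).
#' @param ranges Named list of `c(lo, hi)` intervals for `RA`, `RL`, `UV`,
#'   `PT`, `shaft_angle`, `noise_px`.
#' @param seed RNG seed.
#' @return List of `n` phantoms (each as returned by [generate_phantom()]).
#' @export
generate_batch <- function(n,
                           ranges = list(RA = c(10, 30), RL = c(8, 14),
                                         UV = c(-3, 3), PT = c(-20, 20),
                                         shaft_angle = c(90, 90),
                                         noise_px = c(0, 0)),
                           seed = 42L) {
  stopifnot(n >= 1)
  defaults <- list(RA = c(10, 30), RL = c(8, 14), UV = c(-3, 3),
                   PT = c(-20, 20), shaft_angle = c(90, 90), noise_px = c(0, 0))
  for (nm in names(defaults)) ranges[[nm]] <- ranges[[nm]] %||% defaults[[nm]]
  for (nm in names(ranges)) {
    if (length(ranges[[nm]]) != 2 || ranges[[nm]][1] > ranges[[nm]][2])
      stop("invalid range for ", nm)
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(RA = stats::runif(1, ranges$RA[1], ranges$RA[2]),
           RL = stats::runif(1, ranges$RL[1], ranges$RL[2]),
           UV = stats::runif(1, ranges$UV[1], ranges$UV[2]),
           PT = stats::runif(1, ranges$PT[1], ranges$PT[2]),
           sa = stats::runif(1, ranges$shaft_angle[1], ranges$shaft_angle[2]),
           np = stats::runif(1, ranges$noise_px[1], ranges$noise_px[2]),
           sd = sample.int(.Machine$integer.max %/% 4L, 1))
    })
  })
  lapply(draws, function(d) {
    generate_phantom(phantom_spec(RA_true = d$RA, RL_true = d$RL,
                                  UV_true = d$UV, PT_true = d$PT,
                                  shaft_angle_deg = d$sa, noise_px = d$np,
                                  seed = d$sd))
  })
}
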