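test_that("detect_ST finds the styloid apex with radial tie-break", {
  ph <- default_phantom()
  ct <- part_contour(ph$ap, "distal_radius")
  ST <- detect_ST(ct)
  expect_lt(sqrt(sum((ST - as.numeric(ph$truth$landmarks$ST))^2)), 3)
  # ties break toward the radial side (smaller x in the canonical frame)
  sq <- new_contour(rbind(c(10, 10), c(30, 10), c(30, 40), c(10, 40)))
  expect_equal(unname(detect_ST(sq)), c(10, 10))
  # translation equivariance
  sq2 <- new_contour(sq$vertices + 10)
  expect_equal(detect_ST(sq2), detect_ST(sq) + 10)
})

test_that("detect_UBR follows the clockwise sweep with the distance rule", {
  ph <- default_phantom()
  ct <- part_contour(ph$ap, "distal_radius")
  ST <- detect_ST(ct)
  UBR <- detect_UBR(ct, ST, cfg = rotating_line_config())
  expect_lt(sqrt(sum((UBR - as.numeric(ph$truth$landmarks$UBR))^2)), 3)
  # an impossible distance threshold exhausts the sweep cap
  expect_error(detect_UBR(ct, ST, cfg = rotating_line_config(min_dist_frac = 0.99,
                                                             max_sweep_deg = 40)),
               "UBR not found")
})

test_that("UBR on a circle matches chord geometry", {
  # centre (100,100), r = 50, rotation centre at the top (100, 50): a line
  # through ST at clockwise angle phi intersects the circle at chord length
  # 2 r sin(phi); the first qualifying chord has 2 r sin(phi) = min_dist, and
  # the hit sits at ST + chord * (cos phi, sin phi).
  ct <- circle_contour(c(100, 100), 50, n = 2000)
  ST <- c(100, 50)
  cfg <- rotating_line_config(step_deg = 0.01, min_dist_frac = 0.3)
  min_dist <- 0.3 * diff(range(ct$vertices[, 1]))
  phi <- asin(min_dist / (2 * 50))
  chord <- 2 * 50 * sin(phi)
  expected <- ST + chord * c(cos(phi), sin(phi))
  UBR <- detect_UBR(ct, ST, cfg = cfg)
  expect_lt(sqrt(sum((UBR - expected)^2)), 0.5)
})

test_that("detect_UH finds the centre of the flat ulnar surface", {
  ph <- default_phantom()
  ct <- part_contour(ph$ap, "ulna")
  ax <- fit_axis(sample_interior_points(ct, axis_fit_config()), axis_fit_config())
  uh <- detect_UH(ct, ax, rotating_line_config())
  expect_lt(sqrt(sum((uh$UH - as.numeric(ph$truth$landmarks$UH))^2)), 3)
  expect_lt(sqrt(sum((uh$ul_UBR - as.numeric(ph$truth$landmarks$ul_UBR))^2)), 3)
})

test_that("UH lies on the symmetry axis of a symmetric stylized ulna", {
  # T-shaped bone: flat top spanning the full head, symmetric about x = 60
  poly <- rbind(c(30, 50), c(90, 50), c(90, 70), c(75, 80), c(75, 200),
                c(45, 200), c(45, 80), c(30, 70))
  img <- drfparams:::rasterize_polygons(list(poly), 1L, c(256, 256))
  ct <- extract_largest_contour(img)
  ax <- axis_line_from(c(60, 100), 90)
  uh <- detect_UH(ct, ax, rotating_line_config())
  # the contract midpoints the arc between the axis intersection (60, 50)
  # and ul_UBR (the radial corner, 30, 50): the quarter point of the surface
  expect_equal(unname(uh$ul_UBR), c(30, 50))
  expect_lt(abs(uh$UH[1] - 45), 2)
  expect_equal(unname(round(uh$UH[2])), 50)
})

test_that("arc midpoint is invariant to contour vertex-order reversal", {
  v <- circle_contour(c(50, 50), 20, n = 100)$vertices
  i <- 10L; j <- 40L
  m1 <- drfparams:::arc_midpoint(v, i, j)
  vr <- v[rev(seq_len(nrow(v))), ]
  ir <- nrow(v) + 1L - i; jr <- nrow(v) + 1L - j
  m2 <- drfparams:::arc_midpoint(vr, ir, jr)
  expect_equal(unname(m1), unname(m2))
})

test_that("detect_DJ finds the rim apex and rotates with the contour", {
  ph <- default_phantom()
  ct <- part_contour(ph$lat, "distal_radius")
  DJ <- detect_DJ(ct)
  expect_lt(sqrt(sum((DJ - as.numeric(ph$truth$landmarks$DJ))^2)), 3)
  # rectangle: topmost row ties break toward dorsal (larger x)
  sq <- new_contour(rbind(c(10, 10), c(30, 10), c(30, 40), c(10, 40)))
  expect_equal(unname(detect_DJ(sq)), c(30, 10))
  # rotating the contour moves the apex to the rotated extreme
  rot <- new_contour(rot_cw(ct$vertices, 5, c(256, 256)))
  DJ2 <- detect_DJ(rot)
  expect_lt(min(sqrt(rowSums(sweep(rot$vertices, 2, DJ2)^2))), 1e-9)
  expect_equal(min(rot$vertices[, 2]), DJ2[["y"]])
})

test_that("displacement classification follows the fragment centroid side", {
  vol <- generate_phantom(phantom_spec(PT_true = 10, displacement = "volar"))
  dor <- generate_phantom(phantom_spec(PT_true = -10, displacement = "dorsal"))
  for (case in list(list(ph = vol, want = "volar"), list(ph = dor, want = "dorsal"))) {
    ct <- part_contour(case$ph$lat, "distal_radius")
    ax <- reference_axis(case$ph$lat)
    expect_identical(classify_displacement(ct, ax), case$want)
  }
  # centroid on the axis: ambiguous, called dorsal with a warning
  sym <- new_contour(rbind(c(240, 100), c(272, 100), c(272, 180), c(240, 180)))
  ax <- axis_line_from(c(256, 150), 90)
  expect_warning(cls <- classify_displacement(sym, ax), "ambiguous")
  expect_identical(cls, "dorsal")
})

test_that("detect_VJB sweeps toward the displaced side and rejects degenerates", {
  for (pt in c(12, -12)) {
    ph <- generate_phantom(phantom_spec(PT_true = pt))
    ct <- part_contour(ph$lat, "distal_radius")
    disp <- ph$truth$landmarks$displacement
    top <- drfparams:::topmost_vertex(ct, if (disp == "volar") "max_x" else "min_x")
    swept <- detect_VJB(ct, top, disp, rotating_line_config())
    truth <- if (disp == "volar") ph$truth$landmarks$VJB else ph$truth$landmarks$DJ
    expect_lt(sqrt(sum((swept - as.numeric(truth))^2)), 3)
  }
  ph <- default_phantom()
  ct <- part_contour(ph$lat, "distal_radius")
  DJ <- detect_DJ(ct)
  expect_error(detect_VJB(ct, DJ, "volar",
                          rotating_line_config(min_dist_frac = 0.99,
                                               max_sweep_deg = 20)),
               "VJB not found")
})

test_that("rotating-line detections are translation equivariant", {
  ph <- default_phantom()
  ct <- part_contour(ph$ap, "distal_radius")
  ST <- detect_ST(ct)
  UBR <- detect_UBR(ct, ST, cfg = rotating_line_config())
  sh <- new_contour(sweep(ct$vertices, 2, c(17, -23), `+`))
  ST2 <- detect_ST(sh)
  expect_equal(unname(ST2), unname(ST + c(17, -23)))
  UBR2 <- detect_UBR(sh, ST2, cfg = rotating_line_config())
  expect_equal(unname(UBR2), unname(UBR + c(17, -23)))
})

test_that("halving the sweep step moves UBR and VJB by at most 1 px", {
  ph <- default_phantom()
  ap <- part_contour(ph$ap, "distal_radius")
  lat <- part_contour(ph$lat, "distal_radius")
  ST <- detect_ST(ap); DJ <- detect_DJ(lat)
  for (cfgs in list(c(0.01, 0.005))) {
    u1 <- detect_UBR(ap, ST, cfg = rotating_line_config(step_deg = cfgs[1]))
    u2 <- detect_UBR(ap, ST, cfg = rotating_line_config(step_deg = cfgs[2]))
    expect_lte(sqrt(sum((u1 - u2)^2)), 1)
    v1 <- detect_VJB(lat, DJ, "volar", rotating_line_config(step_deg = cfgs[1]))
    v2 <- detect_VJB(lat, DJ, "volar", rotating_line_config(step_deg = cfgs[2]))
    expect_lte(sqrt(sum((v1 - v2)^2)), 1)
  }
})
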