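test_that("smoothed distance matches the closed form and its limits", {
  expect_identical(smoothed_distance(0), 0)
  expect_equal(smoothed_distance(sqrt(2)), 2 * (sqrt(2) - 1))
  for (d in c(0.5, 1, 3, 10))
    expect_identical(smoothed_distance(-d), smoothed_distance(d))
  # quadratic near zero: f(d)/d^2 -> 1/2
  expect_equal(smoothed_distance(1e-4) / 1e-8, 0.5, tolerance = 1e-6)
  # linear in the tails: f(d)/|d| -> sqrt(2); at d = 1e6 the deviation is
  # exactly ~2/d = 2e-6 (the -2 offset), so the 1e-6 bound is checked at 1e7
  expect_equal(smoothed_distance(1e6) / 1e6, sqrt(2) - 2e-6, tolerance = 1e-7)
  expect_equal(smoothed_distance(1e7) / 1e7, sqrt(2), tolerance = 1e-6)
  # strictly increasing in |d|
  g <- seq(0, 20, by = 0.5)
  expect_true(all(diff(smoothed_distance(g)) > 0))
})

test_that("axis loss matches hand evaluation and is additive", {
  pts <- cbind(c(0, 1, 5), c(1, 3, 11))      # on y = 2x + 1
  expect_equal(axis_loss(pts, 2, 1), 0)
  expect_equal(axis_loss(cbind(0, 1), 0, 0), 2 * (sqrt(1.5) - 1))
  a <- matrix(stats::runif(10), 5, 2); b <- matrix(stats::runif(10), 5, 2)
  expect_equal(axis_loss(rbind(a, b), 0.3, 2),
               axis_loss(a, 0.3, 2) + axis_loss(b, 0.3, 2))
})

test_that("interior sampling is contained, reproducible and unbiased", {
  rect <- new_contour(rbind(c(10, 20), c(110, 20), c(110, 220), c(10, 220)))
  cfg <- axis_fit_config(n_points = 500, seed = 9)
  pts <- sample_interior_points(rect, cfg)
  expect_identical(nrow(pts), 500L)
  expect_true(all(points_in_polygon(pts[, 1], pts[, 2], rect$vertices)))
  expect_identical(sample_interior_points(rect, cfg), pts)
  big <- sample_interior_points(rect, axis_fit_config(n_points = 10000, seed = 1))
  expect_equal(colMeans(big), c(60, 120), tolerance = 0.02)
  tiny <- new_contour(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)))
  expect_error(sample_interior_points(tiny, cfg), "too small")
})

test_that("exact collinear points are recovered to 1e-6", {
  x <- seq(0, 100, length.out = 25)
  pts <- cbind(x, 0.4 * x + 7)
  fit <- fit_axis(pts, axis_fit_config(tol = 1e-14, max_iter = 20000))
  expect_equal(fit$m, 0.4, tolerance = 1e-6)
  expect_equal(fit$b, 7, tolerance = 1e-4)
  expect_lt(fit$loss, 1e-10)
})

test_that("jittered line fit stays near truth and beats the grid oracle", {
  pts <- with_seed(21, {
    x <- stats::runif(200, 0, 200)
    cbind(x, 0.1 * x + 5 + stats::runif(200, -1, 1))
  })
  fit <- fit_axis(pts, axis_fit_config())
  expect_lt(abs(fit$m - 0.1), 0.02)
  orc <- axis_grid_oracle(pts)
  expect_lte(fit$loss, orc$loss * (1 + 1e-3))
})

test_that("fixed-step descent (no backtracking) still reduces the loss", {
  pts <- with_seed(3, cbind(stats::runif(50, 0, 50),
                            stats::runif(50, 0, 50) * 0.2 + 3))
  cfg <- axis_fit_config(alpha = 1e-5, max_iter = 2000, backtracking = FALSE)
  fit <- suppressWarnings(fit_axis(pts, cfg))
  expect_lt(fit$loss, axis_loss(pts, 0, mean(pts[, 2])))
})

test_that("rotating the cloud rotates the fitted direction", {
  ph <- default_phantom()
  ct <- part_contour(ph$ap, "ulna")
  pts <- sample_interior_points(ct, axis_fit_config(seed = 5))
  base <- fit_axis(pts, axis_fit_config())$theta
  for (phi in c(-10, -5, 5, 10)) {
    rot <- rot_cw(pts, phi, center = c(256, 256))
    th <- fit_axis(rot, axis_fit_config())$theta
    d <- ((base - phi) - th + 90) %% 180 - 90
    expect_lt(abs(d), 0.5)
  }
})

test_that("doubling n_points barely moves the fitted direction", {
  ph <- default_phantom()
  ct <- part_contour(ph$ap, "ulna")
  t1 <- fit_axis(sample_interior_points(ct, axis_fit_config(n_points = 1000, seed = 2)),
                 axis_fit_config(n_points = 1000))$theta
  t2 <- fit_axis(sample_interior_points(ct, axis_fit_config(n_points = 2000, seed = 3)),
                 axis_fit_config(n_points = 2000))$theta
  expect_lt(abs(t1 - t2), 0.5)
})

test_that("reference_axis recovers the shaft direction on both views", {
  ph <- default_phantom()  # shaft at 90 degrees
  expect_lt(abs(reference_axis(ph$ap)$theta - 90), 1)
  ph85 <- fixture("ph85", function() generate_phantom(phantom_spec(shaft_angle_deg = 85)))
  expect_lt(abs(reference_axis(ph85$lat)$theta - 85), 1)
  no_ulna <- ph$ap
  no_ulna$pixels[no_ulna$pixels == 3L] <- 0L
  expect_error(reference_axis(no_ulna), "empty part")
})

test_that("degenerate clouds are rejected", {
  expect_error(fit_axis(matrix(1, 12, 2)), "coincident")
  expect_error(fit_axis(cbind(1:5, 1:5)), "nrow")
})
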