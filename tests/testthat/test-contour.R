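test_that("binarize_part indicates the requested code and rejects empty parts", {
  ph <- default_phantom()
  bin <- binarize_part(ph$ap, "ulna")
  expect_identical(sum(bin), sum(ph$ap$pixels == 3L))
  no_ulna <- ph$ap
  no_ulna$pixels[no_ulna$pixels == 3L] <- 0L
  expect_error(binarize_part(no_ulna, "ulna"), "empty part")
  expect_error(binarize_part(ph$lat, "ulna"), "not declared")
})

test_that("fill_holes turns a ring into a disk and is idempotent", {
  img <- matrix(0L, 80, 80)
  d2 <- outer((1:80 - 40)^2, (1:80 - 40)^2, `+`)
  img[d2 <= 30^2 & d2 >= 18^2] <- 1L
  filled <- fill_holes(img)
  expect_identical(sum(filled), sum(d2 <= 30^2))
  expect_true(all(filled >= img))                 # never shrinks
  expect_identical(fill_holes(filled), filled)    # idempotent
  expect_identical(max(label_components(filled)), 1L)
  # holes of the complement all gone: interior is solid
  expect_identical(sum(filled[d2 <= 18^2]), sum(d2 <= 18^2))
  # no-op cases
  rect <- matrix(0L, 70, 70); rect[20:50, 20:40] <- 1L
  expect_identical(fill_holes(rect), rect)
  expect_identical(fill_holes(matrix(0L, 64, 64)), matrix(0L, 64, 64))
})

test_that("gaussian kernel is the impulse response and preserves constants", {
  cfg <- contour_config(gaussian_sigma = 1)
  img <- matrix(0, 11, 11); img[6, 6] <- 1
  out <- gaussian_denoise(img, cfg)
  expect_equal(out[5:7, 5:7], gaussian_kernel3(1))
  expect_equal(sum(gaussian_kernel3(2.5)), 1)
  ones <- matrix(1, 9, 9)
  expect_equal(gaussian_denoise(ones, cfg), ones)
  # single-pixel speckle falls below the 0.5 threshold
  expect_lt(max(out), 0.5)
})

test_that("sobel kernels equal the printed matrices and respond to steps", {
  k <- sobel_kernels()
  expect_identical(k$gx, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE))
  expect_identical(k$gy, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE))
  expect_equal(sobel_edges(matrix(0.7, 15, 15)), matrix(0, 15, 15))
  # vertical 0 -> 1 step: |Gx| = 4 on the two columns flanking the step
  step <- cbind(matrix(0, 10, 5), matrix(1, 10, 5))
  gx <- drfparams:::conv3(step, k$gx)
  expect_true(all(abs(gx[, 5:6]) == 4))
  expect_true(all(gx[, c(1:4, 7:10)] == 0))
  gy <- drfparams:::conv3(step, k$gy)
  expect_true(all(gy == 0))
})

test_that("largest contour wins and small blobs are ignored", {
  img <- matrix(0L, 100, 100)
  img[10:29, 10:29] <- 1L   # 400 px
  img[60:64, 60:64] <- 1L   # 25 px, below min_area 50
  ct <- extract_largest_contour(img, contour_config())
  expect_true(all(ct$vertices[, 1] <= 30 & ct$vertices[, 2] <= 30))
  # adding sub-threshold speckle leaves the winner unchanged
  img2 <- img; img2[80:82, 15:17] <- 1L
  ct2 <- extract_largest_contour(img2, contour_config())
  expect_identical(ct$vertices, ct2$vertices)
  expect_error(extract_largest_contour(matrix(0L, 64, 64)), "no valid contour")
  # 10x10 square: pixel-centre shoelace area is 81
  sq <- matrix(0L, 30, 30); sq[11:20, 11:20] <- 1L
  expect_equal(extract_largest_contour(sq)$area, 81)
})

test_that("simplification reduces a traced rectangle to its 4 corners", {
  img <- matrix(0L, 120, 120)
  img[20:99, 30:89] <- 1L
  ct <- extract_largest_contour(img)
  expect_gt(nrow(ct$vertices), 250)
  simp <- simplify_contour(ct, contour_config())
  expect_identical(nrow(simp$vertices), 4L)
  expect_lt(abs(simp$area - ct$area) / ct$area, 0.02)
  expect_true(simp$simplified)
  expect_identical(nrow(simp$deltas), 4L)
  # already-minimal polygons are fixed points
  tri <- new_contour(rbind(c(0, 0), c(40, 5), c(10, 30)))
  expect_equal(simplify_contour(tri, contour_config())$vertices, tri$vertices)
})

test_that("noisy circle simplification stays within tolerance", {
  set.seed(5)
  a <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- 50 + stats::runif(360, -1, 1)
  ct <- new_contour(cbind(100 + r * cos(a), 100 + r * sin(a)))
  simp <- simplify_contour(ct, contour_config(simplify_tolerance = 1.0))
  # jitter of the same magnitude as the tolerance caps how hard a
  # deviation-bounded simplifier may compress; ~36% of vertices remain
  expect_lt(nrow(simp$vertices), 0.40 * nrow(ct$vertices))
  # every removed vertex lies within ~tolerance of the simplified polyline
  kept <- simp$vertices
  seg_dist <- function(p) {
    n <- nrow(kept); mins <- Inf
    for (i in seq_len(n)) {
      a1 <- kept[i, ]; b1 <- kept[i %% n + 1, ]
      e <- b1 - a1; t <- sum((p - a1) * e) / sum(e^2)
      t <- min(max(t, 0), 1)
      mins <- min(mins, sqrt(sum((p - (a1 + t * e))^2)))
    }
    mins
  }
  dmax <- max(apply(ct$vertices, 1, seg_dist))
  expect_lt(dmax, 1.0 + 0.6)  # tolerance plus chord curvature slack
  expect_lt(abs(simp$area - ct$area) / ct$area, 0.02)
  # idempotent at fixed tolerance
  again <- simplify_contour(simp, contour_config(simplify_tolerance = 1.0))
  expect_equal(again$vertices, simp$vertices)
})

test_that("pipeline contour area matches the generator silhouette within 5%", {
  ph <- default_phantom()
  for (part in c("ulna", "distal_radius")) {
    ct <- part_contour(ph$ap, part, contour_config())
    truth_area <- ph$truth$silhouette_areas$ap[[part]]
    expect_lt(abs(ct$area - truth_area) / truth_area, 0.05)
  }
  ct <- part_contour(ph$lat, "proximal_radius", contour_config())
  expect_lt(abs(ct$area - ph$truth$silhouette_areas$lat[["proximal_radius"]]) /
              ph$truth$silhouette_areas$lat[["proximal_radius"]], 0.05)
})

test_that("sobel support coincides with the traced boundary region", {
  ph <- default_phantom()
  bin <- fill_holes(binarize_part(ph$ap, "ulna"))
  sm <- (gaussian_denoise(bin, contour_config()) > 0.5) * 1L
  edges <- sobel_edges(sm, contour_config())
  ct <- extract_largest_contour(sm, contour_config())
  on_edge <- edges[cbind(ct$vertices[, 2], ct$vertices[, 1])]
  expect_true(all(on_edge > 0))
})
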