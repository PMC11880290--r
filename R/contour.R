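# Contour extraction from per-part binary masks: binarize, close holes by
# flood fill + inversion, smooth with a 3x3 Gaussian, Sobel edges, trace the
# largest closed contour, simplify it by iterative triangle elimination.

#' Contour extraction configuration
#'
#' @param gaussian_sigma Standard deviation (px) of the 3x3 sampled Gaussian
#'   denoising kernel.
#' @param min_area_px Smallest contour area (px^2, shoelace) kept.
#' @param simplify_tolerance Maximum deviation (px) of removed vertices from
#'   the simplified polyline.
#' @return List of class `contour_config`.
#' @export
contour_config <- function(gaussian_sigma = 1.0, min_area_px = 50,
                           simplify_tolerance = 1.0) {
  stopifnot(gaussian_sigma > 0, min_area_px >= 0, simplify_tolerance >= 0)
  structure(list(gaussian_sigma = gaussian_sigma, kernel_size = 3L,
                 sobel_gx = sobel_kernels()$gx, sobel_gy = sobel_kernels()$gy,
                 min_area_px = min_area_px,
                 simplify_tolerance = simplify_tolerance),
            class = "contour_config")
}

#' The 3x3 Sobel kernels
#' @return List with integer matrices `gx` and `gy`.
#' @export
sobel_kernels <- function() {
  list(gx = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
       gy = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE))
}

#' Binary indicator image of one anatomic part
#'
#' @param mask A [label_mask()].
#' @param part Part name declared in `mask$labels`.
#' @return 0/1 integer matrix.
#' @export
binarize_part <- function(mask, part) {
  stopifnot(inherits(mask, "label_mask"))
  if (!part %in% names(mask$labels)) stop("part '", part, "' not declared")
  bin <- (mask$pixels == mask$labels[[part]]) * 1L
  if (!any(bin == 1L)) stop("empty part '", part, "'", call. = FALSE)
  bin
}

# Run-length connected-component labelling with union-find.
# Returns an integer matrix of labels (0 = background), labels 1..k.
label_components <- function(bin, connectivity = 8L) {
  nr <- nrow(bin); nc <- ncol(bin)
  parent <- integer(0)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  run_row <- integer(0); run_cs <- integer(0); run_ce <- integer(0)
  prev_idx <- integer(0)  # indices of runs in previous row
  for (r in seq_len(nr)) {
    row <- bin[r, ]
    d <- diff(c(0L, row, 0L))
    cs <- which(d == 1L); ce <- which(d == -1L) - 1L
    cur_idx <- integer(length(cs))
    for (k in seq_along(cs)) {
      id <- length(parent) + 1L
      parent[id] <- id
      run_row[id] <- r; run_cs[id] <- cs[k]; run_ce[id] <- ce[k]
      cur_idx[k] <- id
      for (p in prev_idx) {
        if (run_ce[p] >= cs[k] - slack && run_cs[p] <= ce[k] + slack) {
          rp <- uf_find(p); rc <- uf_find(id)
          if (rp != rc) parent[rc] <- rp
        }
      }
    }
    prev_idx <- cur_idx
  }
  lab <- matrix(0L, nr, nc)
  if (length(parent) == 0) return(lab)
  roots <- vapply(seq_along(parent), uf_find, integer(1))
  compact <- match(roots, unique(roots))
  for (i in seq_along(parent)) {
    lab[run_row[i], run_cs[i]:run_ce[i]] <- compact[i]
  }
  lab
}

#' Fill enclosed holes in a binary image
#'
#' Classic flood-fill trick: pad one background ring, flood the background
#' from the origin, invert the fill and OR it with the input.  Foreground
#' never shrinks; idempotent.
#'
#' @param binary 0/1 matrix.
#' @return 0/1 integer matrix with holes filled.
#' @export
fill_holes <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- (binary > 0) * 1L
  comp <- 1L - pad
  lab <- label_components(comp, connectivity = 4L)
  outside <- lab[1L, 1L]
  holes <- (comp == 1L) & (lab != outside)
  out <- pad
  out[holes] <- 1L
  out[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

# 3x3 cross-correlation with edge-replicated padding.
conv3 <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  pad[1, ] <- pad[2, ]; pad[nr + 2, ] <- pad[nr + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nc + 2] <- pad[, nc + 1]
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w != 0)
      out <- out + w * pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

#' Normalised 3x3 sampled Gaussian kernel
#' @param sigma Standard deviation in px.
#' @return 3x3 matrix summing to 1.
#' @export
gaussian_kernel3 <- function(sigma = 1.0) {
  g <- outer(-1:1, -1:1, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

#' Gaussian denoising of a binary mask
#'
#' Cross-correlation with the normalised 3x3 sampled Gaussian.  The output
#' is real-valued; the pipeline re-thresholds it at 0.5 before edge
#' detection and contour tracing, which removes single-pixel speckle.
#'
#' @param binary 0/1 matrix.
#' @param cfg A [contour_config()].
#' @return Real-valued matrix of the same shape.
#' @export
gaussian_denoise <- function(binary, cfg = contour_config()) {
  conv3(binary, gaussian_kernel3(cfg$gaussian_sigma))
}

#' Sobel edge magnitude
#'
#' Gradients from the standard 3x3 Sobel kernels;
#' magnitude `sqrt(Gx^2 + Gy^2)`.  Zero on constant regions.
#'
#' @param binary Binary (post-threshold) matrix.
#' @param cfg A [contour_config()].
#' @return Edge-magnitude matrix.
#' @export
sobel_edges <- function(binary, cfg = contour_config()) {
  gx <- conv3(binary, cfg$sobel_gx)
  gy <- conv3(binary, cfg$sobel_gy)
  sqrt(gx^2 + gy^2)
}

#' Construct a contour object
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates forming a closed
#'   polyline (first/last implicitly connected).
#' @param part Name of the bone part the contour bounds.
#' @param simplified Logical flag.
#' @param deltas Optional per-edge (direction, length) encoding.
#' @return Object of class `drf_contour`.
#' @export
new_contour <- function(vertices, part = NA_character_, simplified = FALSE,
                        deltas = NULL) {
  v <- as.matrix(vertices)
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) stop("contour needs at least 3 vertices")
  if (shoelace_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  a <- shoelace_area(v)
  if (a <= 0) stop("degenerate contour (area 0)")
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, area = a, part = part,
                 simplified = simplified, deltas = deltas),
            class = "drf_contour")
}

#' @export
print.drf_contour <- function(x, ...) {
  cat(sprintf("<contour %s: %d vertices, area %.1f px^2%s>\n",
              x$part, nrow(x$vertices), x$area,
              if (x$simplified) ", simplified" else ""))
  invisible(x)
}

# Moore-neighbour boundary tracing of the component containing `start`
# (row, col).  Returns an ordered matrix of boundary pixel centres (x, y).
moore_trace <- function(bin, start) {
  # neighbour offsets (dr, dc) in screen-clockwise order starting at N
  off <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                  1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                ncol = 2, byrow = TRUE)
  nr <- nrow(bin); nc <- ncol(bin)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && bin[r, c] > 0
  cr <- start[1]; cc <- start[2]
  # backtrack starts at W neighbour (background by row-major scan order)
  bdir <- 7L
  cap <- 4096L
  path_r <- integer(cap); path_c <- integer(cap); np <- 0L
  first_r <- cr; first_c <- cc; first_b <- bdir
  start_visits <- 0L
  maxit <- 16L * (nr + nc) + 8L * sum(bin > 0)
  for (it in seq_len(maxit)) {
    np <- np + 1L
    if (np > cap) {
      cap <- cap * 2L
      path_r <- c(path_r, integer(cap %/% 2L))
      path_c <- c(path_c, integer(cap %/% 2L))
    }
    path_r[np] <- cr; path_c[np] <- cc
    found <- FALSE
    d <- bdir
    for (k in seq_len(8)) {
      d <- (d %% 8L) + 1L  # next clockwise
      rr <- cr + off[d, 1]; cc2 <- cc + off[d, 2]
      if (fg(rr, cc2)) {
        # new backtrack: the neighbour just before d, relative to new pixel
        prevd <- ((d - 2L) %% 8L) + 1L
        pr <- cr + off[prevd, 1]; pc <- cc + off[prevd, 2]
        # direction from new pixel to that background pixel
        ndr <- pr - rr; ndc <- pc - cc2
        bdir <- which(off[, 1] == ndr & off[, 2] == ndc)
        cr <- rr; cc <- cc2
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cr == first_r && cc == first_c) {
      # Jacob's stopping criterion, with a visit cap as a safety net on
      # contours whose start sits on a one-pixel-wide appendage
      start_visits <- start_visits + 1L
      if (bdir == first_b || start_visits >= 3L) break
    }
  }
  cbind(x = path_c[seq_len(np)], y = path_r[seq_len(np)])
}

#' Extract the largest closed contour of a binary (or edge) image
#'
#' Thresholds at 0.5, labels 8-connected components, traces the outer
#' boundary of each and returns the contour with maximal shoelace area.
#' Ties are broken toward the contour whose first vertex is topmost, then
#' leftmost.
#'
#' @param img Binary or real-valued matrix (foreground > 0.5).
#' @param cfg A [contour_config()].
#' @param part Part name stored on the contour.
#' @return A [new_contour()] with dense (pixel-centre) vertices.
#' @export
extract_largest_contour <- function(img, cfg = contour_config(), part = NA_character_) {
  bin <- (img > 0.5) * 1L
  lab <- label_components(bin, connectivity = 8L)
  k <- max(lab)
  if (k == 0) stop("no valid contour", call. = FALSE)
  best <- NULL; best_area <- -Inf
  for (comp in seq_len(k)) {
    idx <- which(lab == comp, arr.ind = TRUE)
    if (nrow(idx) < 3) next
    ord <- order(idx[, 1], idx[, 2])
    tr <- moore_trace(lab == comp, idx[ord[1], ])
    if (nrow(tr) < 3) next
    a <- abs(shoelace_area(tr))
    if (a < cfg$min_area_px) next
    if (a > best_area + 1e-9 ||
        (abs(a - best_area) <= 1e-9 && !is.null(best) &&
         (tr[1, 2] < best[1, 2] || (tr[1, 2] == best[1, 2] && tr[1, 1] < best[1, 1])))) {
      best <- tr; best_area <- a
    }
  }
  if (is.null(best)) stop("no valid contour", call. = FALSE)
  new_contour(best, part = part)
}

#' Simplify a contour by iterative triangle elimination
#'
#' Visvalingam-style: repeatedly delete the vertex whose triangle with its
#' neighbours has the smallest height (deviation from the chord), while the
#' deviation stays within `simplify_tolerance` and the enclosed area changes
#' by at most 2\%.  The result stores the per-edge (direction, length) chain
#' encoding as metadata.  Idempotent at fixed tolerance.
#'
#' @param contour A [new_contour()].
#' @param cfg A [contour_config()].
#' @return Simplified contour.
#' @export
simplify_contour <- function(contour, cfg = contour_config()) {
  v <- contour$vertices
  n0 <- nrow(v)
  area0 <- abs(shoelace_area(v))
  tol <- cfg$simplify_tolerance
  n <- nrow(v)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  alive <- rep(TRUE, n)
  tri_height <- function(i) {
    p <- v[prv[i], ]; q <- v[i, ]; r <- v[nxt[i], ]
    base <- sqrt(sum((r - p)^2))
    a2 <- abs((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
    if (base < 1e-12) return(0)
    a2 / base  # 2*area/base = deviation of q from chord p-r
  }
  h <- vapply(seq_len(n), tri_height, numeric(1))
  nalive <- n
  area_now <- area0
  while (nalive > 3L) {
    cand <- which(alive)
    i <- cand[which.min(h[cand])]
    if (h[i] > tol) break
    p <- prv[i]; q <- nxt[i]
    tri_a <- h[i] * sqrt(sum((v[q, ] - v[p, ])^2)) / 2
    if (abs(area_now - area0) + tri_a > 0.02 * area0) break
    alive[i] <- FALSE; nalive <- nalive - 1L
    nxt[p] <- q; prv[q] <- p
    # area bookkeeping: recompute exactly every removal is O(n); a signed
    # update is enough here since tri_a bounds the change.
    area_now <- abs(shoelace_area(v[alive, , drop = FALSE]))
    h[p] <- tri_height(p); h[q] <- tri_height(q)
  }
  keep <- v[alive, , drop = FALSE]
  if (abs(shoelace_area(keep)) <= 0) stop("degenerate contour after simplification")
  m <- nrow(keep)
  e <- rbind(keep[-1, , drop = FALSE], keep[1, , drop = FALSE]) - keep
  deltas <- cbind(direction_deg = (rad2deg(atan2(e[, 2], e[, 1]))) %% 360,
                  length_px = sqrt(rowSums(e^2)))
  out <- new_contour(keep, part = contour$part, simplified = TRUE, deltas = deltas)
  out
}

#' Full per-part contour pipeline
#'
#' binarize -> fill holes -> Gaussian denoise -> 0.5 threshold -> largest
#' contour.  Sobel edges are computed for validation (their support must
#' coincide with the traced boundary) but tracing runs on the filled,
#' thresholded mask, which is unambiguous.
#'
#' @param mask A [label_mask()].
#' @param part Part name.
#' @param cfg A [contour_config()].
#' @param simplify Also simplify the contour? (landmark detection prefers
#'   the dense contour; simplification is for serialisation).
#' @return Dense contour (with `$simplified_contour` attached if requested).
#' @export
part_contour <- function(mask, part, cfg = contour_config(), simplify = FALSE) {
  bin <- binarize_part(mask, part)
  filled <- fill_holes(bin)
  smooth <- gaussian_denoise(filled, cfg)
  binned <- (smooth > 0.5) * 1L
  ct <- extract_largest_contour(binned, cfg, part = part)
  if (simplify) ct$simplified_contour <- simplify_contour(ct, cfg)
  ct
}
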