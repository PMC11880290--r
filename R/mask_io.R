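#' Label codes for each radiographic view
#'
#' The AP (anteroposterior) segmentation distinguishes background, distal
#' radius, proximal radius and ulna; the LAT (lateral) segmentation
#' distinguishes background, distal radius and proximal radius.
#'
#' @param view `"AP"` or `"LAT"`.
#' @return Named integer vector mapping part name to label code.
#' @export
view_labels <- function(view = c("AP", "LAT")) {
  view <- match.arg(view)
  if (view == "AP") {
    c(background = 0L, distal_radius = 1L, proximal_radius = 2L, ulna = 3L)
  } else {
    c(background = 0L, distal_radius = 1L, proximal_radius = 2L)
  }
}

#' Construct a label mask
#'
#' A `label_mask` is the container consumed by the whole pipeline: a 2D
#' integer image (row 1 at the top, y increasing downward) whose values code
#' anatomic parts, together with its view, pixel spacing and laterality.
#'
#' @param pixels Integer matrix (rows x cols) of label codes.
#' @param view `"AP"` or `"LAT"`.
#' @param pixel_spacing Isotropic pixel spacing in mm/px (> 0). When left at
#'   the default `1.0`, lengths are reported in px units.
#' @param laterality `"right"`, `"left"` or `"unknown"`.
#' @param labels Named integer vector of part codes; defaults to
#'   [view_labels()] for the view.
#' @param mirrored Logical; whether the pixels were mirrored at read time to
#'   canonical right-wrist orientation.
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(pixels, view, pixel_spacing = 1.0,
                       laterality = c("unknown", "right", "left"),
                       labels = view_labels(view), mirrored = FALSE) {
  view <- match.arg(view, c("AP", "LAT"))
  laterality <- match.arg(laterality)
  stopifnot(is.matrix(pixels), nrow(pixels) >= 64, ncol(pixels) >= 64,
            pixel_spacing > 0)
  storage.mode(pixels) <- "integer"
  bad <- setdiff(unique(as.vector(pixels)), unname(labels))
  if (length(bad) > 0)
    stop("unknown label ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(pixels = pixels, view = view, labels = labels,
                 pixel_spacing = pixel_spacing, laterality = laterality,
                 mirrored = mirrored),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cnt <- vapply(x$labels, function(code) sum(x$pixels == code), integer(1))
  cat(sprintf("<label_mask %s %dx%d, %.3g mm/px, %s>\n", x$view,
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$laterality))
  print(cnt)
  invisible(x)
}

# First `n` entries of the standard VOC segmentation palette (bit-reversal
# construction); rows are 0-based palette indices, columns R,G,B in 0..255.
voc_palette <- function(n = 256L) {
  pal <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    id <- i - 1L; r <- g <- b <- 0L
    for (j in 0:7) {
      r <- bitwOr(r, bitwShiftL(bitwAnd(bitwShiftR(id, 0L), 1L), 7L - j))
      g <- bitwOr(g, bitwShiftL(bitwAnd(bitwShiftR(id, 1L), 1L), 7L - j))
      b <- bitwOr(b, bitwShiftL(bitwAnd(bitwShiftR(id, 2L), 1L), 7L - j))
      id <- bitwShiftR(id, 3L)
    }
    pal[i, ] <- c(r, g, b)
  }
  pal
}

#' Write a label mask as a VOC-palette PNG
#'
#' Pixels are stored as RGB using the exact colours of the VOC palette
#' (background black, class 1 dark red, ...), which [read_label_mask()]
#' inverts exactly.
#'
#' @param mask A [label_mask()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  pal <- voc_palette(max(mask$labels) + 1L) / 255
  px <- mask$pixels
  arr <- array(0, dim = c(nrow(px), ncol(px), 3))
  for (k in 1:3) arr[, , k] <- matrix(pal[px + 1L, k], nrow(px), ncol(px))
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Write sidecar metadata for a mask pair
#'
#' @param path JSON file path.
#' @param pixel_spacing_mm mm per pixel.
#' @param laterality `"left"`, `"right"` or `"unknown"`.
#' @param view Optional view tag.
#' @return `path`, invisibly.
#' @export
write_mask_meta <- function(path, pixel_spacing_mm = 1.0,
                            laterality = "unknown", view = NULL) {
  rec <- list(pixel_spacing_mm = pixel_spacing_mm, laterality = laterality)
  if (!is.null(view)) rec$view <- view
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label mask from PNG
#'
#' Accepts either an RGB PNG in VOC palette colours or a single-channel PNG
#' holding raw label codes.  On read the mask is canonicalised: if the
#' distal radius centroid sits below the proximal radius centroid the image
#' is flipped vertically (distal end up), and left-wrist images are mirrored
#' horizontally so downstream sign conventions always see a right wrist.
#'
#' @param path PNG file path.
#' @param view `"AP"` or `"LAT"`.
#' @param meta Optional metadata record: either the path to a sidecar JSON
#'   file (fields `pixel_spacing_mm`, `laterality`) or a list with those
#'   fields.  Defaults to spacing 1 (px units, with a warning) and unknown
#'   laterality.
#' @param require_complete If `TRUE` (default), every declared part must
#'   have at least one pixel.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, view, meta = NULL, require_complete = TRUE) {
  stopifnot(file.exists(path))
  labels <- view_labels(view)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    codes <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  } else {
    rgb <- round(img[, , 1:3] * 255)
    key <- rgb[, , 1] * 65536 + rgb[, , 2] * 256 + rgb[, , 3]
    pal <- voc_palette(max(labels) + 1L)
    palkey <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
    codes <- matrix(match(as.vector(key), palkey) - 1L, nrow(key), ncol(key))
    if (anyNA(codes)) {
      bad <- unique(key[is.na(codes)])[1]
      stop(sprintf("unknown label colour #%06X", bad), call. = FALSE)
    }
  }
  bad <- setdiff(unique(as.vector(codes)), unname(labels))
  if (length(bad) > 0)
    stop("unknown label ", paste(sort(bad), collapse = ", "), call. = FALSE)
  if (require_complete) {
    for (nm in names(labels)) {
      if (!any(codes == labels[[nm]]))
        stop("missing required part '", nm, "'", call. = FALSE)
    }
  }
  if (is.character(meta)) meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  spacing <- meta$pixel_spacing_mm %||% NA_real_
  if (is.na(spacing)) {
    warning("no pixel spacing in metadata; lengths will be reported in px",
            call. = FALSE)
    spacing <- 1.0
  }
  laterality <- tolower(meta$laterality %||% "unknown")
  mirrored <- FALSE
  if (identical(laterality, "left")) {
    codes <- codes[, rev(seq_len(ncol(codes))), drop = FALSE]
    mirrored <- TRUE
  }
  codes <- normalize_orientation_pixels(codes, labels)
  label_mask(codes, view, pixel_spacing = spacing,
             laterality = if (laterality %in% c("left", "right")) laterality else "unknown",
             labels = labels, mirrored = mirrored)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flip the image vertically if the distal radius lies below the proximal
# radius; applying the normaliser twice equals applying it once.
normalize_orientation_pixels <- function(codes, labels) {
  if (!all(c("distal_radius", "proximal_radius") %in% names(labels))) return(codes)
  rd <- which(codes == labels[["distal_radius"]], arr.ind = TRUE)
  rp <- which(codes == labels[["proximal_radius"]], arr.ind = TRUE)
  if (nrow(rd) == 0 || nrow(rp) == 0) return(codes)
  if (mean(rd[, 1]) > mean(rp[, 1]))
    codes <- codes[rev(seq_len(nrow(codes))), , drop = FALSE]
  codes
}

#' Orientation normalisation of a label mask
#'
#' @param mask A [label_mask()].
#' @return The mask, vertically flipped if the distal direction pointed down.
#' @export
normalize_orientation <- function(mask) {
  mask$pixels <- normalize_orientation_pixels(mask$pixels, mask$labels)
  mask
}

#' Global histogram equalization
#'
#' Classic cumulative-distribution remapping of an 8-bit grayscale image:
#' `h(v) = round(255 * (cdf(v) - cdf_min) / (N - cdf_min))`. Constant images
#' are returned unchanged. Rank order of distinct input intensities is
#' preserved.
#'
#' @param img Integer matrix with values in 0..255.
#' @return Integer matrix of the same shape, values in 0..255.
#' @export
equalize_histogram <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0)
  v <- as.integer(img)
  if (any(v < 0 | v > 255)) stop("intensities must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(v)
  if (n == cdf_min) return(img)  # single grey level
  lut <- as.integer(round(255 * (cdf - cdf_min) / (n - cdf_min)))
  lut[lut < 0L] <- 0L
  matrix(lut[v + 1L], nrow(img), ncol(img))
}
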