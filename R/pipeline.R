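# End-to-end orchestration: contours -> axes -> landmarks -> parameters for
# a biplane case, plus batch processing with error summaries.

#' Pipeline configuration
#'
#' @param contour A [contour_config()].
#' @param axis An [axis_fit_config()].
#' @param rotating A [rotating_line_config()].
#' @param spacing mm per px (1.0 = report px units).
#' @param emit_overlays Write annotated overlay PNGs in [run_batch()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(contour = contour_config(),
                            axis = axis_fit_config(),
                            rotating = rotating_line_config(),
                            spacing = 1.0, emit_overlays = FALSE) {
  stopifnot(inherits(contour, "contour_config"),
            inherits(axis, "axis_fit_config"),
            inherits(rotating, "rotating_line_config"), spacing > 0)
  structure(list(contour = contour, axis = axis, rotating = rotating,
                 spacing = spacing, emit_overlays = emit_overlays),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the config constructors, e.g.
#' `contour: {gaussian_sigma: 1.0}`, `axis: {n_points: 500, seed: 1}`,
#' `rotating: {step_deg: 0.01}`, `spacing: 1.0`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    contour = do.call(contour_config, y$contour %||% list()),
    axis = do.call(axis_fit_config, y$axis %||% list()),
    rotating = do.call(rotating_line_config, y$rotating %||% list()),
    spacing = y$spacing %||% 1.0,
    emit_overlays = isTRUE(y$emit_overlays)
  )
}

#' Run the full biplane pipeline on one case
#'
#' Steps: per-part contour extraction; ulnar (AP) and proximal-radius (LAT)
#' reference-axis fits; rotating-line landmark detection (ST, UBR, UH with
#' ul_UBR, DJ, VJB with displacement classification); parameter assembly.
#' Landmarks are detected on the dense traced contours; simplified contours
#' are attached for serialisation.  Deterministic given the config seeds.
#'
#' @param ap AP [label_mask()].
#' @param lat LAT [label_mask()].
#' @param cfg A [pipeline_config()]. The mask's `pixel_spacing` overrides
#'   `cfg$spacing` when it is not 1.
#' @return List of class `case_result` with `params`, `landmarks`, `axes`,
#'   `contours`, `timings`, `warnings` (and `error` on failure).
#' @export
run_case <- function(ap, lat, cfg = pipeline_config()) {
  stopifnot(inherits(ap, "label_mask"), inherits(lat, "label_mask"),
            ap$view == "AP", lat$view == "LAT")
  warnings <- character(0)
  wh <- function(w) { warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning") }
  t0 <- proc.time()[["elapsed"]]
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  res <- tryCatch(withCallingHandlers({
    spacing <- if (ap$pixel_spacing != 1) ap$pixel_spacing else cfg$spacing

    t <- tic()
    ap_ulna <- part_contour(ap, "ulna", cfg$contour)
    ap_dr <- part_contour(ap, "distal_radius", cfg$contour)
    lat_pr <- part_contour(lat, "proximal_radius", cfg$contour)
    lat_dr <- part_contour(lat, "distal_radius", cfg$contour)
    timings["contours"] <- tic() - t

    t <- tic()
    ap_axis <- fit_axis(sample_interior_points(ap_ulna, cfg$axis), cfg$axis)
    lat_axis_cfg <- cfg$axis; lat_axis_cfg$seed <- cfg$axis$seed + 1L
    lat_axis <- fit_axis(sample_interior_points(lat_pr, lat_axis_cfg), lat_axis_cfg)
    timings["axes"] <- tic() - t

    t <- tic()
    ST <- detect_ST(ap_dr)
    UBR <- detect_UBR(ap_dr, ST, ap_axis, cfg$rotating)
    uh <- detect_UH(ap_ulna, ap_axis, cfg$rotating)
    displacement <- classify_displacement(lat_dr, lat_axis)
    # under dorsal displacement the highest rim is the volar one: break the
    # topmost tie toward the side the sweep leaves from
    top <- topmost_vertex(lat_dr, tie = if (displacement == "volar") "max_x" else "min_x")
    swept <- detect_VJB(lat_dr, top, displacement, cfg$rotating)
    # assign rim names by canonical side: volar-most point is VJB
    vol <- volar_unit(lat_axis)
    if (sum(top * vol) > sum(swept * vol)) {
      VJB <- top; DJ <- swept
    } else {
      VJB <- swept; DJ <- top
    }
    lm <- landmark_set(ST = ST, UBR = UBR, UH = uh$UH, ul_UBR = uh$ul_UBR,
                       DJ = c(x = unname(DJ[1]), y = unname(DJ[2])),
                       VJB = c(x = unname(VJB[1]), y = unname(VJB[2])),
                       displacement = displacement)
    timings["landmarks"] <- tic() - t

    t <- tic()
    params <- assemble_params(lm, ap_axis, lat_axis, spacing)
    timings["params"] <- tic() - t

    list(params = params, landmarks = lm,
         axes = list(ap = ap_axis, lat = lat_axis),
         contours = list(ap_ulna = ap_ulna, ap_distal_radius = ap_dr,
                         lat_proximal_radius = lat_pr, lat_distal_radius = lat_dr),
         error = NULL)
  }, warning = wh),
  error = function(e) list(params = NULL, landmarks = NULL, axes = NULL,
                           contours = NULL, error = conditionMessage(e)))
  timings["total"] <- tic() - t0
  res$timings <- timings
  res$warnings <- warnings
  class(res) <- "case_result"
  res
}

#' @export
print.case_result <- function(x, ...) {
  if (!is.null(x$error)) {
    cat("<case_result: ERROR:", x$error, ">\n")
  } else {
    print(x$params)
    cat(sprintf("displacement: %s | total %.2fs\n",
                x$landmarks$displacement, x$timings[["total"]]))
  }
  invisible(x)
}

#' Serialise a case result to JSON
#'
#' @param result A `case_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_case_result <- function(result, path) {
  lm <- result$landmarks
  out <- list(
    params = if (is.null(result$params)) NULL else
      list(RA_deg = result$params$RA, RL = result$params$RL,
           UV = result$params$UV, PT_deg = result$params$PT,
           units = result$params$units,
           reference_angle_deg = result$params$reference_angle),
    landmarks = if (is.null(lm)) NULL else
      lapply(lm[c("ST", "UBR", "UH", "ul_UBR", "DJ", "VJB")], as.numeric),
    displacement = if (is.null(lm)) NULL else lm$displacement,
    axes = if (is.null(result$axes)) NULL else
      lapply(result$axes, function(a) list(theta_deg = a$theta, m = a$m,
                                           b = a$b, frame = a$frame,
                                           loss = a$loss)),
    warnings = result$warnings,
    error = result$error
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the pipeline over a directory of cases
#'
#' Cases are file triples `<id>_ap.png`, `<id>_lat.png`, `<id>_meta.json`
#' (optional) and, when present, `<id>_truth.json` with true parameter
#' values for error summaries.  Unpaired cases are skipped with a warning;
#' per-case failures are recorded and do not abort the batch.
#'
#' @param case_dir Directory of paired masks.
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory for per-case JSON, overlays and the batch
#'   CSV (default: `case_dir`).
#' @return Invisibly, a data.frame with one row per case (parameters and,
#'   when truth is available, signed errors) plus attributes `summary`
#'   (mean/SD of signed errors).
#' @export
run_batch <- function(case_dir, cfg = pipeline_config(), out_dir = case_dir) {
  aps <- sort(list.files(case_dir, pattern = "_ap\\.png$"))
  ids <- sub("_ap\\.png$", "", aps)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (id in ids) {
    lat_path <- file.path(case_dir, paste0(id, "_lat.png"))
    if (!file.exists(lat_path)) {
      warning("unpaired case '", id, "' skipped", call. = FALSE)
      next
    }
    meta_path <- file.path(case_dir, paste0(id, "_meta.json"))
    meta <- if (file.exists(meta_path)) meta_path else NULL
    row <- tryCatch({
      ap <- read_label_mask(file.path(case_dir, paste0(id, "_ap.png")), "AP", meta)
      lat <- read_label_mask(lat_path, "LAT", meta)
      res <- run_case(ap, lat, cfg)
      write_case_result(res, file.path(out_dir, paste0(id, "_result.json")))
      if (isTRUE(cfg$emit_overlays) && is.null(res$error))
        write_case_overlay(ap, res, file.path(out_dir, paste0(id, "_overlay.png")))
      if (!is.null(res$error)) {
        data.frame(id = id, status = res$error, RA = NA, RL = NA, UV = NA, PT = NA)
      } else {
        data.frame(id = id, status = "ok", RA = res$params$RA, RL = res$params$RL,
                   UV = res$params$UV, PT = res$params$PT)
      }
    }, error = function(e) data.frame(id = id, status = conditionMessage(e),
                                      RA = NA, RL = NA, UV = NA, PT = NA))
    truth_path <- file.path(case_dir, paste0(id, "_truth.json"))
    if (file.exists(truth_path) && !is.na(row$RA)) {
      tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
      row$RA_err <- row$RA - tr$RA; row$RL_err <- row$RL - tr$RL
      row$UV_err <- row$UV - tr$UV; row$PT_err <- row$PT - tr$PT
    }
    rows[[id]] <- row
  }
  if (length(rows)) {
    cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    tab <- data.frame(id = character(0), status = character(0))
  }
  if (nrow(tab) == 0) warning("no cases found in ", case_dir, call. = FALSE)
  err_cols <- intersect(c("RA_err", "RL_err", "UV_err", "PT_err"), names(tab))
  if (length(err_cols)) {
    summ <- data.frame(
      parameter = sub("_err$", "", err_cols),
      mean_error = vapply(err_cols, function(cn) mean(tab[[cn]], na.rm = TRUE), numeric(1)),
      sd_error = vapply(err_cols, function(cn) stats::sd(tab[[cn]], na.rm = TRUE), numeric(1))
    )
    attr(tab, "summary") <- summ
    utils::write.csv(summ, file.path(out_dir, "batch_summary.csv"), row.names = FALSE)
  }
  utils::write.csv(tab, file.path(out_dir, "batch_results.csv"), row.names = FALSE)
  invisible(tab)
}

#' Write an annotated overlay PNG
#'
#' Draws the traced contours (red), fitted AP axis (green) and landmark
#' crosses (blue) over the label mask — the "auto-scribing" debug view.
#'
#' @param mask The AP [label_mask()] used as the backdrop.
#' @param result A successful `case_result`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_case_overlay <- function(mask, result, path) {
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  base <- (mask$pixels > 0) * 0.35
  img <- array(rep(base, 3), dim = c(nr, nc, 3))
  put <- function(x, y, rgbv) {
    x <- round(x); y <- round(y)
    ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
    for (k in 1:3) img[cbind(y[ok], x[ok], k)] <<- rgbv[k]
  }
  for (ct in result$contours[c("ap_ulna", "ap_distal_radius")])
    if (!is.null(ct)) put(ct$vertices[, 1], ct$vertices[, 2], c(1, 0.2, 0.2))
  ax <- result$axes$ap
  if (!is.null(ax)) {
    tt <- seq(-nr, nr, by = 0.5)
    put(ax$point[1] + tt * ax$dir[1], ax$point[2] + tt * ax$dir[2], c(0.2, 1, 0.2))
  }
  for (nm in c("ST", "UBR", "UH", "ul_UBR")) {
    p <- result$landmarks[[nm]]
    if (is.null(p)) next
    put(p[1] + (-3:3), rep(p[2], 7), c(0.3, 0.5, 1))
    put(rep(p[1], 7), p[2] + (-3:3), c(0.3, 0.5, 1))
  }
  png::writePNG(img, target = path)
  invisible(path)
}

#' Write a phantom case (masks + metadata + truth) to disk
#'
#' Produces the `<id>_ap.png`, `<id>_lat.png`, `<id>_meta.json`,
#' `<id>_truth.json` layout consumed by [run_batch()].
#'
#' @param ph A phantom from [generate_phantom()].
#' @param dir Output directory.
#' @param id Case identifier.
#' @return The four paths, invisibly.
#' @export
write_phantom_case <- function(ph, dir, id = "case") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- write_label_mask(ph$ap, file.path(dir, paste0(id, "_ap.png")))
  p2 <- write_label_mask(ph$lat, file.path(dir, paste0(id, "_lat.png")))
  p3 <- write_mask_meta(file.path(dir, paste0(id, "_meta.json")),
                        pixel_spacing_mm = 1.0, laterality = "right")
  tr <- ph$truth$params
  p4 <- file.path(dir, paste0(id, "_truth.json"))
  jsonlite::write_json(list(RA = tr$RA, RL = tr$RL, UV = tr$UV, PT = tr$PT,
                            displacement = ph$truth$landmarks$displacement),
                       p4, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4))
}
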