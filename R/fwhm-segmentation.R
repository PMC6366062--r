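# ---- polygon helpers (closed polygons given as x/y vectors, last point
# ---- not repeated) ----

# signed shoelace area
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(seq.int(2L, n), 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# even-odd crossing test
point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  crosses <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(crosses) %% 2L == 1L
}

# mean over stack sections, without apply() overhead
stack_mean <- function(pixels) {
  d <- dim(pixels)
  if (d[3] == 0) return(matrix(0, d[1], d[2]))
  matrix(rowMeans(matrix(pixels, d[1] * d[2], d[3])), d[1], d[2])
}

#' Detect hole centres in an image stack
#'
#' Two-stage automatic detection: (1) the rigid global shift between the
#' layout and the image is estimated by circular cross-correlation of the
#' noiseless layout template with the section-averaged image; (2) each
#' hole's centre is refined to subpixel precision as the intensity centroid
#' (above the local median) within a search window of radius one hole
#' diameter around the shifted layout position.
#'
#' @param stack An `image_stack`.
#' @param layout The [phantom_layout()] imaged in the stack.
#' @param corr_threshold Minimum normalized correlation peak; below it the
#'   stack is declared "phantom not found".
#' @param snr_floor A hole whose local contrast (peak minus local median)
#'   falls below `snr_floor` times the background noise SD of the averaged
#'   image is flagged undetected.
#' @return data.frame: `hole_id`, `row_px`, `col_px` (subpixel centre),
#'   `detected`; attribute `shift_px` holds the estimated global shift.
#' @export
detect_hole_centers <- function(stack, layout, corr_threshold = 0.2,
                                snr_floor = 3) {
  stopifnot(inherits(stack, "image_stack"), inherits(layout, "phantom_layout"))
  img <- stack_mean(stack$pixels)
  n <- nrow(img)
  if (stats::sd(img) == 0) stop("phantom not found", call. = FALSE)

  psf <- if (!is.null(stack$protocol)) stack$protocol$psf_fwhm_mm else 0.8
  tmpl <- psf_blur(rasterize_layout(layout, stack$pixel_mm, supersample = 4,
                                    extent_mm = n * stack$pixel_mm),
                   psf, stack$pixel_mm)
  A <- img - mean(img)
  B <- tmpl - mean(tmpl)
  C <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) /
    length(A)
  peak <- which(C == max(C), arr.ind = TRUE)[1, ]
  norm_corr <- max(C) / sqrt(sum(A^2) * sum(B^2))
  if (!is.finite(norm_corr) || norm_corr < corr_threshold) {
    stop("phantom not found", call. = FALSE)
  }
  wrap <- function(s, n) ifelse(s > n / 2, s - n, s)
  shift <- c(wrap(peak[1] - 1L, n), wrap(peak[2] - 1L, n))

  # background noise level of the averaged image
  roi <- stack$background_roi
  noise_sd <- stats::sd(img[roi$rows, roi$cols])

  ctr <- (n + 1) / 2
  out <- data.frame(hole_id = layout$hole_id,
                    row_px = NA_real_, col_px = NA_real_,
                    detected = FALSE, stringsAsFactors = FALSE)
  for (h in seq_len(nrow(layout))) {
    r0 <- layout$center_y_mm[h] / stack$pixel_mm + ctr + shift[1]
    c0 <- layout$center_x_mm[h] / stack$pixel_mm + ctr + shift[2]
    rad <- layout$diameter_mm[h] / stack$pixel_mm
    rows <- max(1L, floor(r0 - rad)):min(n, ceiling(r0 + rad))
    cols <- max(1L, floor(c0 - rad)):min(n, ceiling(c0 + rad))
    patch <- img[rows, cols, drop = FALSE]
    bg <- stats::median(patch)
    if (noise_sd > 1e-9 && (max(patch) - bg) < snr_floor * noise_sd) {
      next  # flagged undetected
    }
    w <- pmax(patch - bg, 0)
    if (sum(w) <= 0) next
    out$row_px[h] <- sum(w * rows) / sum(w)          # rows recycle down cols
    out$col_px[h] <- sum(t(w) * cols) / sum(w)
    out$detected[h] <- TRUE
  }
  attr(out, "shift_px") <- shift
  out
}

#' Segment one hole with the full-width-at-half-maximum criterion
#'
#' Estimates the local peak (mean of the top intensity decile within
#' 0.5 mm of the centre) and the local background (median in the annulus
#' `[1.5, 2.5] * r_max_mm`), sets the half-maximum level midway between
#' them, and extracts the subpixel iso-contour at that level by linear
#' interpolation on pixel edges (marching squares). The unique closed
#' contour enclosing the centre (innermost, if several) defines the lumen:
#' CSA by the shoelace formula, perimeter by polyline length, circularity
#' as `4 pi A / L^2`. FWHM contouring is invariant under affine intensity
#' rescaling.
#'
#' @param image 2D numeric matrix (one section/frame).
#' @param center_px Numeric `c(row, col)` subpixel centre estimate.
#' @param pixel_mm Pixel spacing (mm).
#' @param window_mm Analysis window side length; must contain the hole plus
#'   background annulus (default three times the largest drilled diameter).
#' @param r_max_mm Largest expected lumen radius (mm); scales the
#'   background annulus.
#' @param presmooth_sigma_px Optional Gaussian pre-smoothing SD in pixels
#'   (0 = off).
#' @return A `segmented_hole` list: `contour` (data.frame `row_px`,
#'   `col_px`), `csa_mm2`, `perimeter_mm`, `circularity`,
#'   `mean_lumen_signal`, `peak_signal`, `background_level`,
#'   `half_max_level`.
#' @export
segment_hole_fwhm <- function(image, center_px, pixel_mm,
                              window_mm = 3 * 3.42, r_max_mm = 1.71,
                              presmooth_sigma_px = 0) {
  n <- nrow(image)
  m <- ncol(image)
  half <- ceiling(window_mm / 2 / pixel_mm)
  r0 <- max(1L, round(center_px[1]) - half)
  r1 <- min(n, round(center_px[1]) + half)
  c0 <- max(1L, round(center_px[2]) - half)
  c1 <- min(m, round(center_px[2]) + half)
  win <- image[r0:r1, c0:c1, drop = FALSE]
  if (presmooth_sigma_px > 0) {
    k <- gaussian_kernel_1d(presmooth_sigma_px)
    win <- conv_sep(win, kr = k, kc = k)
  }
  rows <- r0:r1
  cols <- c0:c1
  dist_mm <- sqrt(outer((rows - center_px[1])^2,
                        (cols - center_px[2])^2, `+`)) * pixel_mm

  core <- win[dist_mm <= 0.5]
  if (!length(core)) core <- win[which.min(dist_mm)]
  core <- sort(core, decreasing = TRUE)
  peak <- mean(core[seq_len(max(1L, ceiling(length(core) / 10)))])
  ann <- win[dist_mm >= 1.5 * r_max_mm & dist_mm <= 2.5 * r_max_mm]
  if (!length(ann)) stop("window too small", call. = FALSE)
  bg <- stats::median(ann)
  if (!(peak > bg)) stop("segmentation failed (low contrast)", call. = FALSE)
  half_level <- bg + (peak - bg) / 2
  # half-open convention: pixels exactly at the level count as below it
  level <- half_level + 1e-9 * (peak - bg)

  cl <- grDevices::contourLines(rows, cols, win, levels = level)
  if (!length(cl)) stop("segmentation failed (low contrast)", call. = FALSE)
  eps <- 1e-8
  on_boundary <- function(cc) {
    any(cc$x < rows[1] + eps | cc$x > rows[length(rows)] - eps |
        cc$y < cols[1] + eps | cc$y > cols[length(cols)] - eps)
  }
  enclosing <- list()
  boundary_hit <- FALSE
  for (cc in cl) {
    np <- length(cc$x)
    closed <- np > 3 && abs(cc$x[1] - cc$x[np]) < eps &&
      abs(cc$y[1] - cc$y[np]) < eps
    if (on_boundary(cc)) boundary_hit <- TRUE
    if (!closed) next
    x <- cc$x[-np]
    y <- cc$y[-np]
    if (point_in_polygon(center_px[1], center_px[2], x, y)) {
      if (on_boundary(cc)) stop("window too small", call. = FALSE)
      enclosing[[length(enclosing) + 1L]] <- list(x = x, y = y)
    }
  }
  if (!length(enclosing)) {
    if (boundary_hit) stop("window too small", call. = FALSE)
    stop("segmentation failed (low contrast)", call. = FALSE)
  }
  areas <- vapply(enclosing, function(p) abs(polygon_area(p$x, p$y)),
                  numeric(1))
  if (length(enclosing) > 1L) {
    warning("multiple enclosing contours; innermost chosen", call. = FALSE)
  }
  poly <- enclosing[[which.min(areas)]]
  area_px <- min(areas)
  csa <- area_px * pixel_mm^2
  perim <- polygon_perimeter(poly$x, poly$y) * pixel_mm
  # lumen mean over the contour core (within 60% of the equivalent radius
  # of the contour centroid), keeping partial-volume edge pixels out of the
  # signal estimate
  cen_r <- mean(poly$x)
  cen_c <- mean(poly$y)
  r_eq_px <- sqrt(area_px / pi)
  core_d <- sqrt(outer((rows - cen_r)^2, (cols - cen_c)^2, `+`))
  core_px <- win[core_d <= 0.6 * r_eq_px]
  mean_lumen <- if (length(core_px)) mean(core_px) else peak

  structure(list(contour = data.frame(row_px = poly$x, col_px = poly$y),
                 csa_mm2 = csa, perimeter_mm = perim,
                 circularity = 4 * pi * csa / perim^2,
                 mean_lumen_signal = mean_lumen, peak_signal = peak,
                 background_level = bg, half_max_level = half_level),
            class = "segmented_hole")
}

# condition message -> measurement status code
failure_status <- function(msg) {
  if (grepl("window too small", msg)) "window_too_small"
  else if (grepl("low contrast", msg)) "low_contrast"
  else "failed"
}

#' Protocol identifier string
#'
#' Stable condition key: `ct_{kvp}kVp_{ctdi}mGy_{asirv}asirv_{iodine}pct`
#' or `mr_{gd}mmol`, with suffix `_moving` when motion is present.
#'
#' @param protocol A `ct_protocol` or `mr_protocol`.
#' @param moving Is the phantom moving?
#' @return Character scalar.
#' @export
protocol_id <- function(protocol, moving = FALSE) {
  id <- if (inherits(protocol, "ct_protocol")) {
    sprintf("ct_%gkVp_%gmGy_%gasirv_%gpct", protocol$kvp, protocol$ctdi_mgy,
            protocol$asirv_pct, protocol$iodine_pct)
  } else {
    sprintf("mr_%.2fmmol", protocol$gd_mmol_l)
  }
  if (moving) id <- paste0(id, "_moving")
  id
}

#' Segment every hole in every section of a stack
#'
#' Runs [detect_hole_centers()] once on the section-averaged stack, then
#' applies [segment_hole_fwhm()] to each (hole, section) pair. Failed
#' segmentations are kept as rows with a `status` code and `NA` metrics so
#' they can be counted, but are excluded from downstream summaries. With
#' the full 110-hole layout and 20 sections this yields 100 measurements
#' per drilled diameter.
#'
#' @param stack An `image_stack`.
#' @param layout The imaged [phantom_layout()].
#' @param window_mm Analysis window passed to [segment_hole_fwhm()].
#' @param presmooth_sigma_px Pre-smoothing SD in pixels; default 0 for CT
#'   and 0.5 for MR.
#' @param ... Passed to [detect_hole_centers()].
#' @return A `measurement_table` data.frame: `protocol_id`, `hole_id`,
#'   `diameter_mm`, `section_index`, `csa_mm2`, `perimeter_mm`,
#'   `circularity`, `mean_lumen_signal`, `status`.
#' @export
segment_stack <- function(stack, layout, window_mm = 3 * 3.42,
                          presmooth_sigma_px = NULL, ...) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(presmooth_sigma_px)) {
    presmooth_sigma_px <- if (identical(stack$modality, "MR")) 0.5 else 0
  }
  ns <- dim(stack$pixels)[3]
  pid <- if (!is.null(stack$protocol)) {
    protocol_id(stack$protocol, moving = !is.null(stack$motion))
  } else "unknown"
  empty <- data.frame(protocol_id = character(), hole_id = character(),
                      diameter_mm = numeric(), section_index = integer(),
                      csa_mm2 = numeric(), perimeter_mm = numeric(),
                      circularity = numeric(), mean_lumen_signal = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  if (ns == 0) {
    return(structure(empty, class = c("measurement_table", "data.frame")))
  }
  centers <- detect_hole_centers(stack, layout, ...)
  res <- vector("list", ns * nrow(layout))
  k <- 0L
  for (s in seq_len(ns)) {
    img <- stack$pixels[, , s]
    for (h in seq_len(nrow(layout))) {
      k <- k + 1L
      row <- data.frame(protocol_id = pid, hole_id = layout$hole_id[h],
                        diameter_mm = layout$diameter_mm[h],
                        section_index = s, csa_mm2 = NA_real_,
                        perimeter_mm = NA_real_, circularity = NA_real_,
                        mean_lumen_signal = NA_real_, status = "undetected",
                        stringsAsFactors = FALSE)
      if (centers$detected[h]) {
        seg <- tryCatch(
          segment_hole_fwhm(img, c(centers$row_px[h], centers$col_px[h]),
                            stack$pixel_mm, window_mm = window_mm,
                            presmooth_sigma_px = presmooth_sigma_px),
          error = function(e) e)
        if (inherits(seg, "segmented_hole")) {
          row$csa_mm2 <- seg$csa_mm2
          row$perimeter_mm <- seg$perimeter_mm
          row$circularity <- seg$circularity
          row$mean_lumen_signal <- seg$mean_lumen_signal
          row$status <- "ok"
        } else {
          row$status <- failure_status(conditionMessage(seg))
        }
      }
      res[[k]] <- row
    }
  }
  out <- do.call(rbind, res)
  structure(out, class = c("measurement_table", "data.frame"))
}

#' Write a measurement table to CSV
#'
#' @param table A `measurement_table`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
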