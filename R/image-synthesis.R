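#' Rasterize a phantom layout to a coverage field
#'
#' Renders the drilled holes as an anti-aliased binary field: each pixel
#' value is the fraction of its area covered by a hole, estimated by
#' `supersample^2` uniform subsamples per pixel. The image is square, the
#' block centre maps to the image centre, and rows index +y.
#'
#' @param layout A [phantom_layout()].
#' @param pixel_mm Pixel spacing (mm).
#' @param supersample Subsamples per pixel edge (>= 4).
#' @param extent_mm Image side length (mm); default block diameter + 2 mm.
#' @return Matrix in `[0, 1]` with attributes `pixel_mm` and `extent_mm`.
#' @export
rasterize_layout <- function(layout, pixel_mm, supersample = 8,
                             extent_mm = NULL) {
  stopifnot(inherits(layout, "phantom_layout"), pixel_mm > 0)
  if (supersample < 4) stop("supersample must be >= 4", call. = FALSE)
  if (is.null(extent_mm)) extent_mm <- attr(layout, "block_diameter_mm") + 2
  n <- ceiling(extent_mm / pixel_mm)
  field <- matrix(0, n, n)

  # pixel-centre coordinates (mm), block centre at image centre
  coord <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  off <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * pixel_mm

  for (h in seq_len(nrow(layout))) {
    cx <- layout$center_x_mm[h]
    cy <- layout$center_y_mm[h]
    r <- layout$diameter_mm[h] / 2
    rows <- which(abs(coord - cy) <= r + pixel_mm)
    cols <- which(abs(coord - cx) <= r + pixel_mm)
    if (!length(rows) || !length(cols)) next
    # squared subsample coordinates relative to the hole centre
    dy2 <- (outer(coord[rows], off, `+`) - cy)^2  # |rows| x s
    dx2 <- (outer(coord[cols], off, `+`) - cx)^2  # |cols| x s
    # coverage[i, j] = mean over subsample pairs of (dy2 + dx2 <= r^2)
    cov <- matrix(0, length(rows), length(cols))
    for (a in seq_len(supersample)) {
      for (b in seq_len(supersample)) {
        cov <- cov + outer(dy2[, a], dx2[, b], function(u, v) (u + v) <= r^2)
      }
    }
    field[rows, cols] <- field[rows, cols] + cov / supersample^2
  }
  field <- pmin(field, 1)
  attr(field, "pixel_mm") <- pixel_mm
  attr(field, "extent_mm") <- extent_mm
  field
}

# separable convolution of matrix M with 1-D kernels (zero padding);
# kr applied along rows (y), kc along columns (x)
conv_sep <- function(M, kr = NULL, kc = NULL) {
  band <- function(n, k) {
    r <- (length(k) - 1L) / 2L
    K <- matrix(0, n, n)
    for (t in seq_along(k)) {
      o <- t - r - 1L
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[t]
    }
    K
  }
  if (!is.null(kr)) M <- band(nrow(M), kr) %*% M
  if (!is.null(kc)) M <- M %*% t(band(ncol(M), kc))
  M
}

gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Gaussian PSF blur of a field, FWHM given in mm
psf_blur <- function(M, psf_fwhm_mm, pixel_mm) {
  if (psf_fwhm_mm <= 0) return(M)
  sigma_px <- psf_fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_mm
  k <- gaussian_kernel_1d(sigma_px)
  conv_sep(M, kr = k, kc = k)
}

#' Motion-blur kernel of a sinusoidal rigid motion
#'
#' Occupancy histogram of the phantom position `x(t) = A sin(2 pi t / T)`
#' over the acquisition window `[t' - w/2, t' + w/2]`, relative to the
#' position at the window centre `x(t')`, binned at the pixel pitch. The
#' kernel sums to one and its support width equals the analytic worst-case
#' in-window displacement ([window_displacement()]) to within one pixel.
#'
#' @param motion A [motion_state()].
#' @param window_s Acquisition window duration (s); must be < the period.
#' @param pixel_mm Pixel pitch used for binning (mm).
#' @param n_samples Time samples across the window.
#' @return Numeric kernel with attribute `offset_px` (bin offsets, pixels).
#' @export
motion_density_kernel <- function(motion, window_s, pixel_mm,
                                  n_samples = 2001) {
  stopifnot(inherits(motion, "motion_state"), pixel_mm > 0)
  if (window_s < 0 || window_s >= motion$period_s) {
    stop("window_s must lie in [0, period)", call. = FALSE)
  }
  if (window_s == 0 || motion$amplitude_mm == 0) {
    k <- 1
    attr(k, "offset_px") <- 0L
    return(k)
  }
  w <- 2 * pi / motion$period_s
  tc <- motion$center_time_s
  t <- seq(tc - window_s / 2, tc + window_s / 2, length.out = n_samples)
  x <- motion$amplitude_mm * (sin(w * t) - sin(w * tc))  # mm, rel. to centre
  bins <- round(x / pixel_mm)
  lo <- min(bins); hi <- max(bins)
  k <- tabulate(bins - lo + 1L, nbins = hi - lo + 1L) / length(bins)
  attr(k, "offset_px") <- seq.int(lo, hi)
  k
}

# convolve field with a motion kernel along the motion axis
apply_motion_kernel <- function(M, kernel, axis) {
  off <- attr(kernel, "offset_px")
  if (is.null(off)) off <- seq_along(kernel) - (length(kernel) + 1L) / 2
  r <- max(abs(range(off)))
  full <- numeric(2 * r + 1)
  full[off + r + 1L] <- kernel
  if (abs(axis[1]) > 0.5) conv_sep(M, kc = full) else conv_sep(M, kr = full)
}

# corner background ROI: a square patch in the image corner, outside the
# block and therefore guaranteed clear of every hole and its blur support
corner_roi <- function(n, pixel_mm, roi_mm = 8, inset_px = 2L) {
  side <- max(10L, ceiling(roi_mm / pixel_mm))
  list(rows = seq.int(inset_px + 1L, inset_px + side),
       cols = seq.int(inset_px + 1L, inset_px + side))
}

new_image_stack <- function(pixels, pixel_mm, modality, background_roi,
                            layout, protocol, motion, seed, noiseless) {
  structure(list(pixels = pixels, pixel_mm = pixel_mm, modality = modality,
                 background_roi = background_roi, layout = layout,
                 protocol = protocol, motion = motion, seed = seed,
                 noiseless = noiseless),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: %s, %d x %d px, %d %s, %.3g mm pixels, seed %s\n",
              x$modality, d[1], d[2], d[3],
              if (x$modality == "CT") "sections" else "frames",
              x$pixel_mm, as.character(x$seed)))
  invisible(x)
}

# noiseless 2D signal common to both modalities: blurred coverage field,
# optionally motion blurred
noiseless_signal <- function(layout, pixel_mm, psf_fwhm_mm, motion,
                             window_s, supersample = 8) {
  field <- rasterize_layout(layout, pixel_mm, supersample = supersample)
  sig <- psf_blur(field, psf_fwhm_mm, pixel_mm)
  if (!is.null(motion) && motion$amplitude_mm > 0 && window_s > 0) {
    k <- motion_density_kernel(motion, window_s, pixel_mm)
    sig <- apply_motion_kernel(sig, k, motion$axis)
  }
  sig
}

#' Simulate a CT-like axial stack of the phantom
#'
#' Noiseless signal: `background_hu + delta_hu * blur(coverage)`, where the
#' blur is the system PSF convolved, under motion, with the 1-D
#' motion-density kernel of the half-revolution acquisition window. Each
#' section adds an independent Gaussian noise realization whose SD follows
#' the dose / tube-potential / reconstruction-strength scaling of
#' [ct_noise_sd()]. 5-mm sections average eight contiguous 0.625-mm noise
#' realizations (SD reduced by sqrt(8)).
#'
#' @param layout A [phantom_layout()].
#' @param protocol A [ct_protocol()].
#' @param motion Optional [motion_state()]; `NULL` for the static phantom.
#' @param seed Integer seed; identical seeds give identical stacks.
#' @param supersample Rasterization supersampling factor.
#' @return An `image_stack` (pixels: rows x cols x sections, HU).
#' @export
simulate_ct_stack <- function(layout, protocol, motion = NULL, seed = 1,
                              supersample = 8) {
  stopifnot(inherits(protocol, "ct_protocol"))
  window_s <- ct_window(protocol$revolution_s)
  sig <- noiseless_signal(layout, protocol$pixel_mm, protocol$psf_fwhm_mm,
                          motion, window_s, supersample)
  base <- protocol$background_hu + protocol$delta_hu * sig
  n <- nrow(base)
  ns <- protocol$n_sections
  sd <- ct_noise_sd(protocol)
  pix <- with_seed(seed, {
    noise <- if (sd > 0 && ns > 0) {
      array(stats::rnorm(n * n * ns, sd = sd), dim = c(n, n, ns))
    } else array(0, dim = c(n, n, max(ns, 0)))
    array(base, dim = c(n, n, ns)) + noise
  })
  new_image_stack(pix, protocol$pixel_mm, "CT",
                  corner_roi(n, protocol$pixel_mm),
                  layout, protocol, motion, as.integer(seed), base)
}

#' Simulate an MR-like cine of the phantom
#'
#' Noiseless signal: `S * blur(coverage)` with `S` the target SNR for the
#' protocol's gadolinium concentration; the PMMA background gives zero
#' signal. Noise is Rician (magnitude of complex Gaussian noise added to
#' the signal) with the underlying Gaussian SD chosen so the background
#' magnitude (Rayleigh) has unit SD; the measured SNR
#' (mean lumen / background SD) then matches the calibration table. Under
#' motion each frame is blurred by the motion-density kernel of the
#' `views_per_segment * tr_ms` acquisition window, plus an optional
#' per-heartbeat repositioning jitter.
#'
#' @param layout A [phantom_layout()].
#' @param protocol An [mr_protocol()].
#' @param motion Optional [motion_state()].
#' @param seed Integer seed.
#' @param supersample Rasterization supersampling factor.
#' @param reposition_sd_mm Per-heartbeat repositioning jitter SD (mm);
#'   applied as an extra Gaussian blur along the motion axis (default 0,
#'   beat-to-beat repositioning is sub-millimetre).
#' @param noiseless If `TRUE`, return the pure signal (no Rician noise).
#' @return An `image_stack` (pixels: rows x cols x frames).
#' @export
simulate_mr_cine <- function(layout, protocol, motion = NULL, seed = 1,
                             supersample = 8, reposition_sd_mm = 0,
                             noiseless = FALSE) {
  stopifnot(inherits(protocol, "mr_protocol"))
  window_s <- mr_window(protocol$views_per_segment, protocol$tr_ms)
  sig <- noiseless_signal(layout, protocol$pixel_mm, protocol$psf_fwhm_mm,
                          motion, window_s, supersample)
  if (!is.null(motion) && motion$amplitude_mm > 0 && reposition_sd_mm > 0) {
    k <- gaussian_kernel_1d(reposition_sd_mm / protocol$pixel_mm)
    sig <- if (abs(motion$axis[1]) > 0.5) conv_sep(sig, kc = k) else
      conv_sep(sig, kr = k)
  }
  S <- protocol$target_snr
  base <- S * sig
  n <- nrow(base)
  nf <- protocol$n_frames
  # Gaussian SD such that the background Rayleigh magnitude has unit SD
  sigma_g <- 1 / sqrt(2 - pi / 2)
  pix <- with_seed(seed, {
    if (noiseless || nf == 0) {
      array(base, dim = c(n, n, max(nf, 0)))
    } else {
      re <- array(stats::rnorm(n * n * nf, sd = sigma_g), c(n, n, nf))
      im <- array(stats::rnorm(n * n * nf, sd = sigma_g), c(n, n, nf))
      sqrt((array(base, c(n, n, nf)) + re)^2 + im^2)
    }
  })
  new_image_stack(pix, protocol$pixel_mm, "MR",
                  corner_roi(n, protocol$pixel_mm),
                  layout, protocol, motion, as.integer(seed), base)
}

#' Write / read a synthetic image stack
#'
#' Stores the pixel data as a multi-page 32-bit float TIFF (requires the
#' tiff package) with a JSON sidecar (`<path>.json`) holding pixel spacing,
#' modality, seed, and the background ROI.
#'
#' @param stack An `image_stack`.
#' @param path TIFF path.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   an `image_stack` (without layout/protocol provenance).
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF stacks requires the tiff package", call. = FALSE)
  }
  d <- dim(stack$pixels)
  # TIFF samples live in [0, 1]; store an affine rescale in the sidecar
  lo <- min(stack$pixels)
  hi <- max(stack$pixels)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(s) {
    (stack$pixels[, , s] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_mm = stack$pixel_mm, modality = stack$modality,
               seed = stack$seed, intensity_offset = lo,
               intensity_scale = scale,
               background_roi = lapply(stack$background_roi, range))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF stacks requires the tiff package", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  pix <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pix <- pix * meta$intensity_scale + meta$intensity_offset
  roi <- lapply(meta$background_roi, function(r) seq.int(r[1], r[2]))
  new_image_stack(pix, meta$pixel_mm, meta$modality, roi,
                  layout = NULL, protocol = NULL, motion = NULL,
                  seed = meta$seed, noiseless = NULL)
}
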