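# shared fixtures, built in code at test time

# single- or few-hole reduced layout in a small block (fast raster/segment)
mini_layout <- function(diameters = 3.0, spacing = 8) {
  n <- length(diameters)
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  phantom_layout(
    data.frame(hole_id = sprintf("h%03d", seq_len(n)),
               diameter_mm = diameters, center_x_mm = xs, center_y_mm = 0,
               replicate_index = 1L, stringsAsFactors = FALSE),
    block_diameter_mm = n * spacing + 18, block_thickness_mm = 20,
    min_spacing_mm = max(4, spacing), margin_mm = 3, complete = FALSE)
}

# the standard full layout, built once per test run
full_layout <- local({
  lay <- NULL
  function() {
    if (is.null(lay)) lay <<- build_layout(seed = 1)
    lay
  }
})

# independent level-set oracle for a blurred disk: render the disk on a
# fine grid (pixel_mm / factor), blur with an explicitly-built Gaussian
# kernel by direct 2D convolution, and count fine pixels above half the
# centre value. Deliberately re-implements rendering and blurring.
oracle_halfmax_area <- function(diameter_mm, pixel_mm, psf_fwhm_mm,
                                factor = 20) {
  fine <- pixel_mm / factor
  half_extent <- diameter_mm / 2 + 4 * psf_fwhm_mm
  g <- seq(-half_extent, half_extent, by = fine)
  disk <- outer(g^2, g^2, `+`) <= (diameter_mm / 2)^2
  sigma <- psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma / fine)
  k1 <- exp(-((-r):r * fine)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  # separable convolution via explicit shift-and-add
  conv1 <- function(M, k, along_rows) {
    out <- matrix(0, nrow(M), ncol(M))
    n <- if (along_rows) nrow(M) else ncol(M)
    for (t in seq_along(k)) {
      o <- t - r - 1L
      src <- seq_len(n) - o
      ok <- src >= 1 & src <= n
      if (along_rows) {
        out[which(ok), ] <- out[which(ok), ] + k[t] * M[src[ok], ]
      } else {
        out[, which(ok)] <- out[, which(ok)] + k[t] * M[, src[ok]]
      }
    }
    out
  }
  blurred <- conv1(conv1(disk * 1, k1, TRUE), k1, FALSE)
  centre <- blurred[(length(g) + 1) / 2, (length(g) + 1) / 2]
  sum(blurred > centre / 2) * fine^2
}

# noiseless CT stack of a layout (quick defaults for tests)
noiseless_ct <- function(layout, n_sections = 1, psf_fwhm_mm = 0.6,
                         supersample = 8, ...) {
  p <- ct_protocol(noise_sd_ref_hu = 0, n_sections = n_sections,
                   psf_fwhm_mm = psf_fwhm_mm, ...)
  simulate_ct_stack(layout, p, seed = 1, supersample = supersample)
}
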