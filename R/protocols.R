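#' Lumen-to-background contrast for a CT protocol
#'
#' Attenuation difference (HU) between the iodinated lumen and the PMMA
#' block, tabulated by iodine concentration and tube potential. Lower tube
#' potential increases iodine attenuation, so contrast rises at 100 kVp.
#'
#' @param iodine_pct Iodine concentration, one of 3, 4, 5, 6 (percent).
#' @param kvp Tube potential, 100 or 120 (kVp).
#' @return Contrast in HU.
#' @export
delta_hu <- function(iodine_pct, kvp) {
  tab <- list(`120` = c(`3` = 170, `4` = 260, `5` = 330, `6` = 390),
              `100` = c(`3` = 250, `4` = 370, `5` = 460, `6` = 560))
  k <- as.character(kvp)
  i <- as.character(iodine_pct)
  if (!k %in% names(tab) || !i %in% names(tab[[k]])) {
    stop("no contrast entry for iodine ", iodine_pct, "% at ", kvp, " kVp",
         call. = FALSE)
  }
  unname(tab[[k]][i])
}

# noise multiplier of the iterative-reconstruction strength; the algorithm
# is modelled purely as first-order noise reduction
asirv_factor <- function(asirv_pct) {
  f <- c(`0` = 1.00, `50` = 0.70, `90` = 0.40)
  a <- as.character(asirv_pct)
  if (!a %in% names(f)) {
    stop("asirv_pct must be one of 0, 50, 90", call. = FALSE)
  }
  unname(f[a])
}

# relative noise penalty of the lower tube potential at matched dose
kvp_noise_factor <- function(kvp) {
  if (kvp == 120) 1.0 else if (kvp == 100) 1.15 else
    stop("kvp must be 100 or 120", call. = FALSE)
}

#' CT acquisition/reconstruction protocol
#'
#' Bundles the axial CT parameters that drive the synthetic stack: contrast
#' (iodine x kVp), noise (dose, kVp, reconstruction strength, section
#' thickness), sampling (pixel and section size) and system blur. The noise
#' model is stationary Gaussian with standard deviation
#' `noise_sd_ref_hu * sqrt(ctdi_ref_mgy / ctdi_mgy) * kvp_factor * asirv_factor`,
#' divided by `sqrt(8)` for 5-mm sections (average of eight contiguous
#' 0.625-mm sections).
#'
#' @param kvp Tube potential (100 or 120).
#' @param ctdi_mgy Volume CT dose index (mGy), e.g. 5, 10 or 20.
#' @param revolution_s Gantry revolution time (s).
#' @param asirv_pct Iterative-reconstruction strength: 0, 50 or 90 (percent).
#' @param iodine_pct Iodine concentration: 3, 4, 5 or 6 (percent).
#' @param pixel_mm In-plane pixel spacing (mm).
#' @param section_mm Section thickness, 0.625 or 5.0 (mm).
#' @param psf_fwhm_mm System point-spread-function FWHM (mm).
#' @param background_hu Block attenuation (HU).
#' @param noise_sd_ref_hu Noise SD at `ctdi_ref_mgy`, 120 kVp, 0% strength.
#' @param ctdi_ref_mgy Reference dose for the noise scaling (mGy).
#' @param n_sections Number of sections to synthesize.
#' @return A `ct_protocol` list.
#' @export
ct_protocol <- function(kvp = 100, ctdi_mgy = 20, revolution_s = 0.28,
                        asirv_pct = 90, iodine_pct = 6,
                        pixel_mm = 0.39, section_mm = 0.625,
                        psf_fwhm_mm = 0.6, background_hu = 120,
                        noise_sd_ref_hu = 20, ctdi_ref_mgy = 20,
                        n_sections = 20) {
  stopifnot(ctdi_mgy > 0, revolution_s > 0, pixel_mm > 0,
            section_mm %in% c(0.625, 5.0), psf_fwhm_mm >= 0,
            noise_sd_ref_hu >= 0, n_sections >= 0)
  dhu <- delta_hu(iodine_pct, kvp)  # validates the pair
  p <- list(modality = "CT", kvp = kvp, ctdi_mgy = ctdi_mgy,
            revolution_s = revolution_s, asirv_pct = asirv_pct,
            iodine_pct = iodine_pct, delta_hu = dhu, pixel_mm = pixel_mm,
            section_mm = section_mm, psf_fwhm_mm = psf_fwhm_mm,
            background_hu = background_hu,
            noise_sd_ref_hu = noise_sd_ref_hu, ctdi_ref_mgy = ctdi_ref_mgy,
            n_sections = as.integer(n_sections))
  class(p) <- c("ct_protocol", "imaging_protocol")
  p
}

#' Noise standard deviation of a CT protocol
#'
#' @param protocol A [ct_protocol()].
#' @return Gaussian noise SD in HU for one reconstructed section.
#' @export
ct_noise_sd <- function(protocol) {
  sd <- protocol$noise_sd_ref_hu *
    sqrt(protocol$ctdi_ref_mgy / protocol$ctdi_mgy) *
    kvp_noise_factor(protocol$kvp) *
    asirv_factor(protocol$asirv_pct)
  if (protocol$section_mm == 5.0) sd <- sd / sqrt(8)
  sd
}

#' Default gadolinium-to-SNR calibration
#'
#' Expected image SNR for each investigated gadolinium concentration
#' (mmol/L). Values interpolate linearly between SNR 22 at 0.17 mmol/L and
#' SNR 73 at 1.66 mmol/L; undoped water retains a small in-flow signal
#' (SNR 10). SNR ~50 is reached near 1.0 mmol/L.
#'
#' @return Named numeric vector, names = concentrations in mmol/L.
#' @export
default_snr_map <- function() {
  conc <- c(0.00, 0.17, 0.33, 0.50, 0.67, 1.00, 1.33, 1.66)
  snr <- 22 + (conc - 0.17) * (73 - 22) / (1.66 - 0.17)
  snr[1] <- 10  # undoped water: weak residual in-flow signal
  names(snr) <- sprintf("%.2f", conc)
  round(snr, 1)
}

#' Cine MR acquisition protocol
#'
#' Parameters of the retrospectively-gated radial cine acquisition used to
#' image the phantom. Image SNR is set by the gadolinium concentration via
#' a configuration table (`target_snr_by_conc`); no signal equation is
#' fitted. The PMMA block gives no MR signal, so the background is zero
#' before noise. Noise is Rician: the magnitude of the complex signal plus
#' Gaussian noise, with the Gaussian SD chosen so that the *magnitude*
#' background (Rayleigh) has unit SD — the quantity entering the SNR
#' definition — making the measured SNR match the calibration table.
#'
#' @param gd_mmol_l Gadolinium concentration (mmol/L); must be a name of
#'   `target_snr_by_conc`.
#' @param pixel_mm In-plane pixel spacing (mm).
#' @param slice_mm Slice thickness (mm); bookkeeping only.
#' @param tr_ms Repetition (echo-spacing) time (ms).
#' @param views_per_segment Radial views acquired per cardiac cycle.
#' @param radial_views Total radial views per cardiac phase.
#' @param psf_fwhm_mm System point-spread-function FWHM (mm).
#' @param target_snr_by_conc Named vector mapping concentration (mmol/L,
#'   2-decimal names) to expected SNR; non-decreasing in concentration.
#' @param n_frames Number of cine frames to synthesize.
#' @return An `mr_protocol` list.
#' @export
mr_protocol <- function(gd_mmol_l = 1.66, pixel_mm = 0.625, slice_mm = 6.5,
                        tr_ms = 4.9, views_per_segment = 19,
                        radial_views = 247, psf_fwhm_mm = 0.8,
                        target_snr_by_conc = default_snr_map(),
                        n_frames = 20) {
  stopifnot(pixel_mm > 0, tr_ms > 0, views_per_segment > 0,
            radial_views > 0, psf_fwhm_mm >= 0, n_frames >= 0)
  key <- sprintf("%.2f", gd_mmol_l)
  if (!key %in% names(target_snr_by_conc)) {
    stop("gadolinium concentration ", gd_mmol_l,
         " mmol/L is not in the SNR calibration table", call. = FALSE)
  }
  if (is.unsorted(target_snr_by_conc) || any(target_snr_by_conc <= 0)) {
    stop("target SNR must be positive and non-decreasing in concentration",
         call. = FALSE)
  }
  p <- list(modality = "MR", gd_mmol_l = gd_mmol_l, pixel_mm = pixel_mm,
            slice_mm = slice_mm, tr_ms = tr_ms,
            views_per_segment = as.integer(views_per_segment),
            radial_views = as.integer(radial_views),
            psf_fwhm_mm = psf_fwhm_mm,
            target_snr = unname(target_snr_by_conc[key]),
            target_snr_by_conc = target_snr_by_conc,
            n_frames = as.integer(n_frames))
  class(p) <- c("mr_protocol", "imaging_protocol")
  p
}

#' Rigid sinusoidal motion state
#'
#' Unidirectional rigid motion `x(t) = A sin(2 pi t / T)` emulating a
#' cardiac rhythm: 60 beats per minute (T = 1 s) with 3 cm peak-to-peak
#' displacement (A = 15 mm). Acquisition windows are centred at the extreme
#' position `t' = T/4`, where the phantom moves least.
#'
#' @param amplitude_mm Displacement amplitude A (mm); peak-to-peak is 2A.
#' @param period_s Cardiac period T (s).
#' @param axis Unit 2-vector of the motion direction; must be axis-aligned
#'   (`c(1, 0)` = image x/columns, `c(0, 1)` = image y/rows).
#' @param center_time_s Window centre t' within the cycle (s).
#' @return A `motion_state` list.
#' @export
motion_state <- function(amplitude_mm = 15, period_s = 1.0,
                         axis = c(1, 0), center_time_s = period_s / 4) {
  stopifnot(amplitude_mm >= 0, period_s > 0, length(axis) == 2)
  axis <- axis / sqrt(sum(axis^2))
  if (!(all(abs(axis - c(1, 0)) < 1e-9) || all(abs(axis - c(0, 1)) < 1e-9))) {
    stop("axis must be c(1, 0) or c(0, 1) (axis-aligned motion)",
         call. = FALSE)
  }
  structure(list(amplitude_mm = amplitude_mm, period_s = period_s,
                 axis = axis, center_time_s = center_time_s),
            class = "motion_state")
}

#' Read a protocol configuration file
#'
#' Reads a YAML or JSON file with optional blocks `ct:`, `mr:` and
#' `motion:`, whose entries override the corresponding constructor
#' defaults.
#'
#' @param path Config file; `.yaml`/`.yml` needs the yaml package.
#' @return List with elements `ct`, `mr`, `motion` (those present), each a
#'   constructed protocol/motion object.
#' @export
read_protocol_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- list()
  if (!is.null(cfg$ct)) out$ct <- do.call(ct_protocol, cfg$ct)
  if (!is.null(cfg$mr)) out$mr <- do.call(mr_protocol, cfg$mr)
  if (!is.null(cfg$motion)) out$motion <- do.call(motion_state, cfg$motion)
  out
}
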