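#' CT acquisition window
#'
#' Effective data window of an axial CT acquisition with a 180-degree
#' acquisition angle: half the gantry revolution time.
#'
#' @param revolution_s Gantry revolution time (s), > 0.
#' @return Window duration (s).
#' @examples
#' ct_window(0.28)  # 0.14 s
#' @export
ct_window <- function(revolution_s) {
  stopifnot(revolution_s > 0)
  revolution_s / 2
}

#' Cine MR acquisition window
#'
#' Per-heartbeat data window of a segmented cine acquisition: views per
#' segment times the echo spacing.
#'
#' @param views_per_segment Views acquired per cardiac cycle, > 0.
#' @param tr_ms Echo spacing / repetition time (ms), > 0. The analytic
#'   default of 5 ms gives the round 95-ms window; the acquisition table
#'   value is 4.9 ms.
#' @return Window duration (s).
#' @examples
#' mr_window(19, 5)  # 0.095 s
#' @export
mr_window <- function(views_per_segment, tr_ms = 5) {
  stopifnot(views_per_segment > 0, tr_ms > 0)
  views_per_segment * tr_ms / 1000
}

#' Acquisition window descriptor
#'
#' @param duration_s Window duration (s), `0 <= duration < period`.
#' @param center_time_s Window centre within the cardiac cycle (s).
#' @return An `acquisition_window` list.
#' @export
acquisition_window <- function(duration_s, center_time_s = 0.25) {
  stopifnot(duration_s >= 0)
  structure(list(duration_s = duration_s, center_time_s = center_time_s),
            class = "acquisition_window")
}

#' Worst-case in-window displacement of the sinusoidal phantom
#'
#' For motion `x(t) = A sin(omega t)` and a window of duration `T_w`
#' centred at `t'`, the displacement between the window centre and its
#' endpoints is `A |sin(omega (t' +/- T_w/2)) - sin(omega t')|`; the larger
#' endpoint is returned. With the window centred at the extreme position
#' (`t' = T/4`, where the phantom moves least) both endpoints coincide and
#' the displacement reduces to `A (1 - cos(omega T_w / 2))`.
#'
#' @param motion A [motion_state()].
#' @param window An [acquisition_window()] or a plain duration in seconds.
#' @return Displacement in mm.
#' @examples
#' m <- motion_state()
#' window_displacement(m, ct_window(0.28))  # 1.43 mm
#' window_displacement(m, mr_window(19, 5)) # 0.66 mm
#' @export
window_displacement <- function(motion, window) {
  stopifnot(inherits(motion, "motion_state"))
  if (inherits(window, "acquisition_window")) {
    tw <- window$duration_s
    tc <- window$center_time_s
  } else {
    tw <- window
    tc <- motion$center_time_s
  }
  if (tw < 0 || tw >= motion$period_s) {
    stop("window duration must lie in [0, period)", call. = FALSE)
  }
  w <- 2 * pi / motion$period_s
  A <- motion$amplitude_mm
  A * max(abs(sin(w * (tc + tw / 2)) - sin(w * tc)),
          abs(sin(w * (tc - tw / 2)) - sin(w * tc)))
}

#' Area error from slice misalignment
#'
#' A cut tilted by `theta` from the perpendicular cross-section intersects
#' a cylinder in an ellipse whose area exceeds the true CSA by the factor
#' `1 / cos(theta)`; the fractional overestimation is `1/cos(theta) - 1`.
#'
#' @param theta_deg Tilt angle in degrees, `0 <= theta < 90`.
#' @return Fractional area error (0.03 = 3 percent).
#' @examples
#' misalignment_area_error(14)  # ~0.031
#' @export
misalignment_area_error <- function(theta_deg) {
  if (any(theta_deg < 0) || any(theta_deg >= 90)) {
    stop("theta must lie in [0, 90) degrees", call. = FALSE)
  }
  1 / cos(theta_deg * pi / 180) - 1
}

#' Heartbeats required to fill a segmented acquisition
#'
#' @param radial_views Total views per cardiac phase.
#' @param views_per_segment Views acquired per heartbeat.
#' @return Integer number of R-R intervals, `ceiling(views / per_segment)`.
#' @examples
#' heartbeats_required(247, 19)  # 13
#' @export
heartbeats_required <- function(radial_views, views_per_segment) {
  stopifnot(radial_views > 0, views_per_segment > 0)
  as.integer(ceiling(radial_views / views_per_segment))
}

#' Tube current needed to reach a dose in a given exposure time
#'
#' With a normalized dose coefficient `nCTDI` (mGy per mAs), reaching
#' `CTDIvol` within an exposure of `t` seconds requires
#' `CTDIvol / (nCTDI * t)` milliamperes.
#'
#' @param ctdi_mgy Target volume CT dose index (mGy).
#' @param nctdi_mgy_per_mas Normalized dose coefficient (mGy per mAs).
#' @param exposure_s Exposure time (s).
#' @return Required tube current (mA).
#' @examples
#' required_tube_current(20, 0.1, 0.14)  # ~1429 mA
#' @export
required_tube_current <- function(ctdi_mgy, nctdi_mgy_per_mas = 0.1,
                                  exposure_s = 0.14) {
  stopifnot(ctdi_mgy > 0, nctdi_mgy_per_mas > 0, exposure_s > 0)
  ctdi_mgy / (nctdi_mgy_per_mas * exposure_s)
}

#' Protocol timing report
#'
#' Tabulates, for the CT and MR acquisition timings, the effective window,
#' the worst-case in-window displacement of the standard sinusoidal motion,
#' the heartbeats needed to fill the MR acquisition, and the tube current
#' required to deliver the CT dose within a single window.
#'
#' @param revolution_s CT gantry revolution time (s).
#' @param views_per_segment,tr_ms,radial_views MR segmentation timing
#'   (analytic `tr_ms` default 5 ms).
#' @param ctdi_mgy CT dose (mGy).
#' @param nctdi_mgy_per_mas Normalized dose coefficient (mGy per mAs).
#' @param motion A [motion_state()].
#' @return data.frame, one row per modality: `modality`, `window_s`,
#'   `displacement_mm`, `heartbeats`, `tube_current_ma`.
#' @export
protocol_timing_report <- function(revolution_s = 0.28,
                                   views_per_segment = 19, tr_ms = 5,
                                   radial_views = 247, ctdi_mgy = 20,
                                   nctdi_mgy_per_mas = 0.1,
                                   motion = motion_state()) {
  wct <- ct_window(revolution_s)
  wmr <- mr_window(views_per_segment, tr_ms)
  data.frame(
    modality = c("CT", "MR"),
    window_s = c(wct, wmr),
    displacement_mm = c(window_displacement(motion, wct),
                        window_displacement(motion, wmr)),
    heartbeats = c(1L, heartbeats_required(radial_views, views_per_segment)),
    tube_current_ma = c(required_tube_current(ctdi_mgy, nctdi_mgy_per_mas,
                                              wct), NA_real_),
    stringsAsFactors = FALSE)
}
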