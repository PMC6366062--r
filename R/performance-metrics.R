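valid_rows <- function(table) {
  ok <- !is.na(table$csa_mm2)
  if ("status" %in% names(table)) ok <- ok & table$status == "ok"
  table[ok, , drop = FALSE]
}

#' Accuracy (bias) of CSA measurements
#'
#' Per drilled diameter: mean measured CSA minus the nominal drilled CSA.
#' The summary is the mean and SD of these per-diameter biases.
#'
#' @param table A `measurement_table` (needs `diameter_mm`, `csa_mm2`).
#' @return List: `per_diameter` (data.frame `diameter_mm`, `bias_mm2`, `n`)
#'   and `mean`, `sd` across diameters.
#' @export
csa_accuracy <- function(table) {
  tab <- valid_rows(table)
  if (!nrow(tab)) stop("no valid measurements", call. = FALSE)
  agg <- stats::aggregate(csa_mm2 ~ diameter_mm, tab, mean)
  agg$bias_mm2 <- agg$csa_mm2 - nominal_csa(agg$diameter_mm)
  agg$n <- stats::aggregate(csa_mm2 ~ diameter_mm, tab, length)$csa_mm2
  per <- agg[, c("diameter_mm", "bias_mm2", "n")]
  list(per_diameter = per, mean = mean(per$bias_mm2),
       sd = stats::sd(per$bias_mm2))
}

#' Precision of CSA measurements
#'
#' Per drilled diameter: sample SD (n - 1 denominator) of the repeated CSA
#' measurements. Diameters with fewer than two valid measurements are
#' excluded with a warning. The summary is the mean and SD of the
#' per-diameter SDs.
#'
#' @inheritParams csa_accuracy
#' @return List: `per_diameter` (data.frame `diameter_mm`, `sd_mm2`, `n`)
#'   and `mean`, `sd` across diameters.
#' @export
csa_precision <- function(table) {
  tab <- valid_rows(table)
  if (!nrow(tab)) stop("no valid measurements", call. = FALSE)
  cnt <- stats::aggregate(csa_mm2 ~ diameter_mm, tab, length)
  if (any(cnt$csa_mm2 < 2)) {
    warning("diameters with a single measurement excluded from precision",
            call. = FALSE)
    keep <- cnt$diameter_mm[cnt$csa_mm2 >= 2]
    tab <- tab[tab$diameter_mm %in% keep, , drop = FALSE]
    if (!nrow(tab)) stop("no diameter has >= 2 measurements", call. = FALSE)
  }
  agg <- stats::aggregate(csa_mm2 ~ diameter_mm, tab, stats::sd)
  names(agg)[2] <- "sd_mm2"
  agg$n <- stats::aggregate(csa_mm2 ~ diameter_mm, tab, length)$csa_mm2
  list(per_diameter = agg, mean = mean(agg$sd_mm2),
       sd = stats::sd(agg$sd_mm2))
}

#' ROC area under the curve (Mann-Whitney statistic)
#'
#' Probability that a random draw from `samples_high` exceeds one from
#' `samples_low`, counting ties as one half:
#' `AUC = (#\{b > a\} + 0.5 #\{b = a\}) / (n_low n_high)`.
#' Antisymmetric: `roc_auc(x, y) + roc_auc(y, x) = 1`.
#'
#' @param samples_low,samples_high Nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 2), c(3, 4))  # 1
#' roc_auc(c(1, 3), c(2, 4))  # 0.75
#' @export
roc_auc <- function(samples_low, samples_high) {
  if (!length(samples_low) || !length(samples_high)) {
    stop("both sample sets must be nonempty", call. = FALSE)
  }
  # rank-based Mann-Whitney with midranks (exact for ties)
  r <- rank(c(samples_high, samples_low))
  n1 <- length(samples_high)
  n0 <- length(samples_low)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Limit of detection of CSA differences
#'
#' Smallest nominal CSA difference whose measurement distributions are
#' separable at `AUC >= auc_threshold`. For each reference diameter `d_i`,
#' the AUC between its measurements and those of every larger diameter
#' `d_j` is computed; the reference's LOD is the smallest nominal
#' difference such that this pair *and all larger differences from the same
#' reference* clear the threshold (monotone closure). A reference whose
#' largest available difference fails the threshold gets no LOD. The
#' summary averages the per-reference LODs; `frac_undefined` reports the
#' fraction of references without one. If no reference separates, the
#' result carries status `"LOD undetectable"`.
#'
#' @param table A `measurement_table`.
#' @param auc_threshold Separability threshold (default 0.95).
#' @return List: `per_reference` (data.frame `diameter_mm`, `lod_mm2`),
#'   `mean`, `sd`, `lod_pct_mean`, `lod_pct_sd` (relative to a 3-mm
#'   lumen), `frac_undefined`, `status`.
#' @export
csa_lod <- function(table, auc_threshold = 0.95) {
  tab <- valid_rows(table)
  diams <- sort(unique(tab$diameter_mm))
  if (length(diams) < 2) {
    stop("need >= 2 diameters with valid measurements", call. = FALSE)
  }
  # a diameter with < 50% valid measurements is unusable for LOD
  if ("status" %in% names(table)) {
    tot <- table(table$diameter_mm)
    ok <- table(tab$diameter_mm)
    usable <- names(ok)[ok / tot[names(ok)] >= 0.5]
    diams <- diams[as.character(diams) %in% usable]
  }
  meas <- split(tab$csa_mm2, tab$diameter_mm)
  nom <- nominal_csa(diams)
  lods <- rep(NA_real_, length(diams) - 1L)
  for (i in seq_len(length(diams) - 1L)) {
    js <- seq.int(i + 1L, length(diams))
    aucs <- vapply(js, function(j) {
      roc_auc(meas[[as.character(diams[i])]], meas[[as.character(diams[j])]])
    }, numeric(1))
    pass <- aucs >= auc_threshold
    if (!pass[length(pass)]) next  # largest difference not detectable
    # monotone closure: smallest delta from which all larger deltas pass
    fails <- which(!pass)
    first_ok <- if (length(fails)) max(fails) + 1L else 1L
    lods[i] <- nom[js[first_ok]] - nom[i]
  }
  per <- data.frame(diameter_mm = diams[seq_along(lods)], lod_mm2 = lods)
  defined <- !is.na(lods)
  if (!any(defined)) {
    return(list(per_reference = per, mean = NA_real_, sd = NA_real_,
                lod_pct_mean = NA_real_, lod_pct_sd = NA_real_,
                frac_undefined = 1, status = "LOD undetectable"))
  }
  m <- mean(lods[defined])
  s <- stats::sd(lods[defined])
  list(per_reference = per, mean = m, sd = s,
       lod_pct_mean = csa_percent(m), lod_pct_sd = csa_percent(s),
       frac_undefined = mean(!defined), status = "ok")
}

#' CSA difference as a percentage of a reference lumen
#'
#' Expresses an absolute CSA difference relative to the area of a nominal
#' reference-diameter lumen (default 3 mm, the smallest drilled size).
#'
#' @param delta_mm2 CSA difference(s) in mm^2.
#' @param reference_diameter_mm Reference lumen diameter (mm), > 0.
#' @return Percentage(s): `100 * delta_mm2 / (pi (ref/2)^2)`.
#' @examples
#' csa_percent(0.16)  # 2.26 %
#' csa_percent(0.52)  # 7.36 %
#' @export
csa_percent <- function(delta_mm2, reference_diameter_mm = 3.0) {
  if (reference_diameter_mm <= 0) {
    stop("reference diameter must be > 0", call. = FALSE)
  }
  100 * delta_mm2 / (pi * (reference_diameter_mm / 2)^2)
}

#' Signal-to-noise ratio of segmented holes
#'
#' SNR of each valid measurement: mean lumen intensity divided by the SD of
#' the stack's signal-free background region in the same section.
#'
#' @param stack The `image_stack` the measurements came from.
#' @param table The `measurement_table` from [segment_stack()].
#' @return List: `per_measurement` (the valid rows with an `snr` column)
#'   and `mean`, `sd` across measurements.
#' @export
measure_snr <- function(stack, table) {
  tab <- valid_rows(table)
  if (!nrow(tab)) stop("no valid measurements", call. = FALSE)
  roi <- stack$background_roi
  ns <- dim(stack$pixels)[3]
  bg_sd <- vapply(seq_len(ns), function(s) {
    stats::sd(stack$pixels[roi$rows, roi$cols, s])
  }, numeric(1))
  if (any(bg_sd[unique(tab$section_index)] == 0)) {
    stop("zero background SD: noiseless input has no defined SNR",
         call. = FALSE)
  }
  tab$snr <- tab$mean_lumen_signal / bg_sd[tab$section_index]
  list(per_measurement = tab, mean = mean(tab$snr), sd = stats::sd(tab$snr))
}

#' Regression of measured against drilled CSA
#'
#' Ordinary least squares of measured CSA on nominal drilled CSA over all
#' valid measurements.
#'
#' @param table A `measurement_table` with >= 3 distinct diameters.
#' @return List: `slope`, `intercept_mm2`, `r2`, `n`.
#' @export
csa_regression <- function(table) {
  tab <- valid_rows(table)
  if (length(unique(tab$diameter_mm)) < 3) {
    stop("need >= 3 distinct diameters", call. = FALSE)
  }
  x <- nominal_csa(tab$diameter_mm)
  if (stats::var(x) == 0) stop("degenerate nominal-CSA variance",
                               call. = FALSE)
  fit <- stats::lm(tab$csa_mm2 ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept_mm2 = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared, n = nrow(tab))
}

#' One-row performance summary of a protocol condition
#'
#' Accuracy, precision, LOD (mm^2 and % of a 3-mm lumen), SNR, circularity
#' and measurement counts for one measurement table, in the column layout
#' used by [run_sweep()].
#'
#' @param table A `measurement_table`.
#' @param stack The originating `image_stack` (for the SNR background
#'   region); if `NULL`, SNR columns are `NA`.
#' @param auc_threshold LOD separability threshold.
#' @return One-row data.frame.
#' @export
summarize_performance <- function(table, stack = NULL,
                                  auc_threshold = 0.95) {
  tab <- valid_rows(table)
  pid <- if (nrow(table)) table$protocol_id[1] else NA_character_
  acc <- csa_accuracy(table)
  prec <- csa_precision(table)
  lod <- csa_lod(table, auc_threshold)
  snr <- if (!is.null(stack)) {
    tryCatch(measure_snr(stack, table), error = function(e) NULL)
  }
  data.frame(
    protocol_id = pid,
    accuracy_mean = acc$mean, accuracy_sd = acc$sd,
    precision_mean = prec$mean, precision_sd = prec$sd,
    lod_mm2_mean = lod$mean, lod_mm2_sd = lod$sd,
    lod_pct_mean = lod$lod_pct_mean, lod_pct_sd = lod$lod_pct_sd,
    lod_status = lod$status,
    snr_mean = if (is.null(snr)) NA_real_ else snr$mean,
    snr_sd = if (is.null(snr)) NA_real_ else snr$sd,
    circ_mean = mean(tab$circularity), circ_sd = stats::sd(tab$circularity),
    n_valid = nrow(tab), n_failed = nrow(table) - nrow(tab),
    stringsAsFactors = FALSE)
}
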