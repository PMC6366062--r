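#' Define one sweep condition
#'
#' @param protocol A [ct_protocol()] or [mr_protocol()].
#' @param motion Optional [motion_state()] (`NULL` = static phantom).
#' @param seed Seed for this condition's simulation.
#' @return A `sweep_condition` list with its `protocol_id`.
#' @export
sweep_condition <- function(protocol, motion = NULL, seed = 1) {
  stopifnot(inherits(protocol, "imaging_protocol"))
  structure(list(protocol = protocol, motion = motion,
                 seed = as.integer(seed),
                 protocol_id = protocol_id(protocol, !is.null(motion))),
            class = "sweep_condition")
}

#' Build the factorial CT sweep
#'
#' All combinations of the requested dose levels, tube potentials, iodine
#' concentrations and reconstruction strengths (the full design is
#' 3 doses x 2 kVp x 4 concentrations = 24 acquisitions, times 3
#' reconstruction strengths = 72 image stacks).
#'
#' @param ctdi_mgy,kvp,iodine_pct,asirv_pct Factor levels.
#' @param seed Base seed; each acquisition (dose x kVp x iodine) gets its
#'   own derived seed, shared across its reconstruction strengths.
#' @param ... Further arguments to [ct_protocol()] (e.g. `n_sections`).
#' @return List of [sweep_condition()]s.
#' @export
ct_factorial_sweep <- function(ctdi_mgy = c(5, 10, 20), kvp = c(100, 120),
                               iodine_pct = 3:6, asirv_pct = c(0, 50, 90),
                               seed = 1, ...) {
  grid <- expand.grid(ctdi = ctdi_mgy, kvp = kvp, iodine = iodine_pct)
  conds <- list()
  for (g in seq_len(nrow(grid))) {
    for (a in asirv_pct) {
      p <- ct_protocol(kvp = grid$kvp[g], ctdi_mgy = grid$ctdi[g],
                       iodine_pct = grid$iodine[g], asirv_pct = a, ...)
      conds[[length(conds) + 1L]] <- sweep_condition(p, seed = seed + g)
    }
  }
  conds
}

#' Run a protocol sweep end-to-end
#'
#' For each condition: simulate the stack, segment every hole, and
#' summarize performance. Per-condition measurement tables are written as
#' CSV (named by `protocol_id`) together with one combined summary CSV.
#' Conditions whose analysis fails are logged and reported with `NA`
#' metrics; the sweep continues. Deterministic for fixed seeds.
#'
#' @param conditions List of [sweep_condition()]s (may be empty).
#' @param layout The [phantom_layout()] to image.
#' @param out_dir Output directory (`NULL` = write nothing).
#' @param quiet Suppress per-condition progress on stderr?
#' @param ... Passed to [segment_stack()].
#' @return Combined summary data.frame, one row per condition, ordered by
#'   `protocol_id`.
#' @export
run_sweep <- function(conditions, layout, out_dir = NULL, quiet = FALSE,
                      ...) {
  if (!length(conditions)) {
    return(data.frame(protocol_id = character(), accuracy_mean = numeric(),
                      accuracy_sd = numeric(), precision_mean = numeric(),
                      precision_sd = numeric(), lod_mm2_mean = numeric(),
                      lod_mm2_sd = numeric(), lod_pct_mean = numeric(),
                      lod_pct_sd = numeric(), lod_status = character(),
                      snr_mean = numeric(), snr_sd = numeric(),
                      circ_mean = numeric(), circ_sd = numeric(),
                      n_valid = integer(), n_failed = integer(),
                      stringsAsFactors = FALSE))
  }
  ids <- vapply(conditions, function(cc) cc$protocol_id, character(1))
  if (anyDuplicated(ids)) {
    stop("sweep conditions must have unique protocol ids; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- vector("list", length(conditions))
  for (k in order(ids)) {
    cc <- conditions[[k]]
    t0 <- proc.time()[3]
    res <- tryCatch({
      stack <- if (inherits(cc$protocol, "ct_protocol")) {
        simulate_ct_stack(layout, cc$protocol, cc$motion, seed = cc$seed)
      } else {
        simulate_mr_cine(layout, cc$protocol, cc$motion, seed = cc$seed)
      }
      tab <- segment_stack(stack, layout, ...)
      if (!is.null(out_dir)) {
        write_measurements(tab, file.path(out_dir,
                                          paste0(cc$protocol_id, ".csv")))
      }
      summarize_performance(tab, stack)
    }, error = function(e) {
      if (!quiet) message(cc$protocol_id, " failed: ", conditionMessage(e))
      data.frame(protocol_id = cc$protocol_id, accuracy_mean = NA_real_,
                 accuracy_sd = NA_real_, precision_mean = NA_real_,
                 precision_sd = NA_real_, lod_mm2_mean = NA_real_,
                 lod_mm2_sd = NA_real_, lod_pct_mean = NA_real_,
                 lod_pct_sd = NA_real_, lod_status = "error",
                 snr_mean = NA_real_, snr_sd = NA_real_,
                 circ_mean = NA_real_, circ_sd = NA_real_,
                 n_valid = 0L, n_failed = 0L, stringsAsFactors = FALSE)
    })
    if (!quiet) {
      message(sprintf("[%s] done in %.1f s", cc$protocol_id,
                      proc.time()[3] - t0))
    }
    rows[[k]] <- res
  }
  summary <- do.call(rbind, rows[order(ids)])
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "performance_summary.csv"),
                     row.names = FALSE)
  }
  summary
}

#' Plot metric curves across sweep conditions
#'
#' Emits accuracy, precision, LOD, SNR and circularity versus contrast
#' concentration as mean +/- SD line plots (one panel per metric, one line
#' per residual condition group), plus the underlying tidy CSV. Conditions
#' with an undetectable LOD appear as gaps in the LOD panel and carry their
#' status in the CSV.
#'
#' @param summary Output of [run_sweep()] (nonempty).
#' @param out_dir Directory for `metric_curves.png` and
#'   `metric_curves.csv`.
#' @return Invisibly, the tidy data.frame behind the plot.
#' @export
report_curves <- function(summary, out_dir) {
  if (!nrow(summary)) stop("empty summary", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  parse_conc <- function(id) {
    m <- regmatches(id, regexec("^ct_[0-9]+kVp_[0-9.]+mGy_[0-9]+asirv_([0-9.]+)pct", id))[[1]]
    if (length(m) == 2) return(as.numeric(m[2]))
    m <- regmatches(id, regexec("^mr_([0-9.]+)mmol", id))[[1]]
    if (length(m) == 2) return(as.numeric(m[2]))
    NA_real_
  }
  strip_conc <- function(id) {
    id <- sub("_[0-9.]+pct", "", id)
    sub("_[0-9.]+mmol", "_mr", id)
  }
  tidy <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    data.frame(protocol_id = s$protocol_id,
               group = strip_conc(s$protocol_id),
               concentration = parse_conc(s$protocol_id),
               metric = c("accuracy_mm2", "precision_mm2", "lod_mm2",
                          "snr", "circularity"),
               mean = c(s$accuracy_mean, s$precision_mean, s$lod_mm2_mean,
                        s$snr_mean, s$circ_mean),
               sd = c(s$accuracy_sd, s$precision_sd, s$lod_mm2_sd,
                      s$snr_sd, s$circ_sd),
               status = s$lod_status,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tidy, file.path(out_dir, "metric_curves.csv"),
                   row.names = FALSE)
  p <- ggplot2::ggplot(tidy, ggplot2::aes(x = concentration, y = mean,
                                          colour = group, group = group)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - sd,
                                          ymax = mean + sd), na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "contrast concentration (% iodine / mmol Gd per L)",
                  y = "mean ± SD") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file.path(out_dir, "metric_curves.png"), p,
                  width = 10, height = 6, dpi = 120)
  invisible(tidy)
}
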