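#' Nominal cross-sectional area of a drilled hole
#'
#' Circle area from the drilled diameter. This is the ground truth against
#' which every measured CSA is compared.
#'
#' @param diameter_mm Hole diameter(s) in mm; must be strictly positive.
#' @return Area(s) in mm^2, `pi * (diameter_mm / 2)^2`.
#' @examples
#' nominal_csa(3.00)  # 7.0686 mm^2
#' @export
nominal_csa <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || any(!is.finite(diameter_mm)) ||
      any(diameter_mm <= 0)) {
    stop("diameter_mm must be finite and > 0", call. = FALSE)
  }
  pi * (diameter_mm / 2)^2
}

#' Diameter ladder of the resolution phantom
#'
#' The 22 drilled diameters, 3.00 mm to 3.42 mm in 0.02-mm steps. The ladder
#' spans the range of lumen calibres expected from coronary vasomotor
#' responses around a 3-mm baseline vessel.
#'
#' @return Numeric vector of length 22 (mm).
#' @export
phantom_diameters <- function() {
  3.00 + 0.02 * (0:21)
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Construct a phantom layout from a hole table
#'
#' Low-level constructor used by [build_layout()] and by tests that need
#' reduced layouts (e.g. a single hole). Validates geometric invariants:
#' holes inside the block, pairwise spacing, and consistency of the nominal
#' CSA column. When `complete = TRUE` the full drilled design is also
#' enforced: exactly 22 diameters x 5 replicates = 110 holes on the
#' 0.02-mm ladder.
#'
#' @param holes data.frame with columns `hole_id`, `diameter_mm`,
#'   `center_x_mm`, `center_y_mm`, `replicate_index` (and optionally
#'   `nominal_csa_mm2`, recomputed if absent).
#' @param block_diameter_mm Block diameter (mm).
#' @param block_thickness_mm Block thickness (mm); bookkeeping only, the
#'   layout is a 2D cross-section.
#' @param min_spacing_mm Minimum allowed centre-to-centre distance (mm).
#' @param margin_mm Clearance between any hole edge and the block edge (mm).
#' @param seed Seed recorded with the layout (or NA for hand-built layouts).
#' @param complete Enforce the full 110-hole drilled design?
#' @return A `phantom_layout`: the hole data.frame with geometry attributes.
#' @export
phantom_layout <- function(holes,
                           block_diameter_mm = 100,
                           block_thickness_mm = 20,
                           min_spacing_mm = 6,
                           margin_mm = 5,
                           seed = NA_integer_,
                           complete = TRUE) {
  need <- c("hole_id", "diameter_mm", "center_x_mm", "center_y_mm",
            "replicate_index")
  if (!all(need %in% names(holes))) {
    stop("holes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  holes <- as.data.frame(holes, stringsAsFactors = FALSE)
  holes$nominal_csa_mm2 <- nominal_csa(holes$diameter_mm)

  r_block <- block_diameter_mm / 2
  reach <- sqrt(holes$center_x_mm^2 + holes$center_y_mm^2) +
    holes$diameter_mm / 2 + margin_mm
  if (any(reach > r_block + 1e-9)) {
    stop("hole(s) extend beyond the block margin", call. = FALSE)
  }
  if (nrow(holes) > 1) {
    d <- as.matrix(stats::dist(holes[, c("center_x_mm", "center_y_mm")]))
    diag(d) <- Inf
    if (min(d) < min_spacing_mm - 1e-9) {
      stop("hole centres closer than min_spacing_mm", call. = FALSE)
    }
  }
  if (nrow(holes) && min_spacing_mm <= max(holes$diameter_mm)) {
    stop("min_spacing_mm must exceed the largest hole diameter",
         call. = FALSE)
  }
  if (complete) {
    dl <- sort(unique(holes$diameter_mm))
    if (length(dl) != 22L || nrow(holes) != 110L ||
        max(abs(dl - phantom_diameters())) > 1e-12 ||
        !all(table(holes$diameter_mm) == 5L)) {
      stop("complete layout requires 22 diameters x 5 replicates on the ",
           "3.00..3.42 mm ladder", call. = FALSE)
    }
  }
  structure(holes,
            block_diameter_mm = block_diameter_mm,
            block_thickness_mm = block_thickness_mm,
            min_spacing_mm = min_spacing_mm,
            margin_mm = margin_mm,
            seed = seed,
            class = c("phantom_layout", "data.frame"))
}

#' Generate a randomized collision-free phantom layout
#'
#' Places the full drilled design (22 diameters x 5 replicates) at seeded
#' random sites of a regular grid of pitch `min_spacing_mm`, so that every
#' pair of holes is at least `min_spacing_mm` apart and every hole clears
#' the block edge by `margin_mm`. Only the diameter ground truth enters the
#' downstream metrics, so hole positions are nuisance parameters and any
#' collision-free arrangement is acceptable.
#'
#' @param seed Integer seed; identical seeds give identical layouts.
#' @param min_spacing_mm Grid pitch and minimum centre spacing (mm); must
#'   exceed the largest drilled diameter (3.42 mm).
#' @param margin_mm Hole-edge to block-edge clearance (mm).
#' @param block_diameter_mm,block_thickness_mm Block geometry (mm).
#' @return A [phantom_layout()] with 110 holes.
#' @examples
#' lay <- build_layout(seed = 1)
#' nrow(lay)                      # 110
#' length(unique(lay$diameter_mm)) # 22
#' @export
build_layout <- function(seed = 1,
                         min_spacing_mm = 6,
                         margin_mm = 5,
                         block_diameter_mm = 100,
                         block_thickness_mm = 20) {
  if (min_spacing_mm <= 3.42) {
    stop("min_spacing_mm must exceed the largest diameter (3.42 mm)",
         call. = FALSE)
  }
  diam <- phantom_diameters()
  r_max <- max(diam) / 2
  r_limit <- block_diameter_mm / 2 - margin_mm - r_max

  # candidate sites: regular grid of pitch min_spacing_mm within r_limit
  g <- seq(-floor(r_limit / min_spacing_mm),
           floor(r_limit / min_spacing_mm)) * min_spacing_mm
  sites <- expand.grid(x = g, y = g)
  sites <- sites[sqrt(sites$x^2 + sites$y^2) <= r_limit, , drop = FALSE]

  n_holes <- length(diam) * 5L
  if (nrow(sites) < n_holes) {
    stop("layout infeasible: only ", nrow(sites), " grid sites fit for ",
         n_holes, " holes", call. = FALSE)
  }
  holes <- with_seed(seed, {
    pick <- sites[sample.int(nrow(sites), n_holes), ]
    data.frame(
      hole_id = sprintf("h%03d", seq_len(n_holes)),
      diameter_mm = rep(diam, each = 5L),
      center_x_mm = pick$x,
      center_y_mm = pick$y,
      replicate_index = rep(1:5, times = length(diam)),
      stringsAsFactors = FALSE
    )
  })
  phantom_layout(holes,
                 block_diameter_mm = block_diameter_mm,
                 block_thickness_mm = block_thickness_mm,
                 min_spacing_mm = min_spacing_mm,
                 margin_mm = margin_mm,
                 seed = as.integer(seed),
                 complete = TRUE)
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf(
    "phantom_layout: %d holes, %d diameters [%.2f..%.2f mm], block %g mm, seed %s\n",
    nrow(x), length(unique(x$diameter_mm)), min(x$diameter_mm),
    max(x$diameter_mm), attr(x, "block_diameter_mm"),
    as.character(attr(x, "seed"))))
  utils::str(as.data.frame(x)[, c("hole_id", "diameter_mm", "center_x_mm",
                                  "center_y_mm", "replicate_index")],
             give.attr = FALSE)
  invisible(x)
}

#' Write / read a phantom layout
#'
#' Serializes the hole table to CSV plus a JSON sidecar (`<path>.json`)
#' holding the block geometry, spacing, margin, and seed.
#'
#' @param layout A `phantom_layout`.
#' @param path CSV path.
#' @return `write_layout` returns `path` invisibly; `read_layout` the layout.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "phantom_layout"))
  utils::write.csv(as.data.frame(layout)[, c(
    "hole_id", "diameter_mm", "center_x_mm", "center_y_mm",
    "replicate_index")], path, row.names = FALSE)
  meta <- list(block_diameter_mm = attr(layout, "block_diameter_mm"),
               block_thickness_mm = attr(layout, "block_thickness_mm"),
               min_spacing_mm = attr(layout, "min_spacing_mm"),
               margin_mm = attr(layout, "margin_mm"),
               seed = attr(layout, "seed"),
               complete = nrow(layout) == 110L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  holes <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  phantom_layout(holes,
                 block_diameter_mm = meta$block_diameter_mm,
                 block_thickness_mm = meta$block_thickness_mm,
                 min_spacing_mm = meta$min_spacing_mm,
                 margin_mm = meta$margin_mm,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                 complete = isTRUE(meta$complete))
}
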