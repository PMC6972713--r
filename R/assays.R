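#' @title Functional-assay quantification
#' @description
#' The scalar quantifications used to compare CAF-S1 and CAF-S4 phenotypes:
#' collagen-gel contraction, spheroid invasion index, migration-track
#' metrics, SHG collagen density, inverted-Transwell invasion statistics,
#' doubling time and cytokine spot ratios. Traction-force quantities live in
#' the TFM module.
#' @name assays
NULL

#' Collagen-gel contraction percentage
#'
#' `100 * (Area_well - mean(Area_gel over replicates)) / Area_well`.
#'
#' @param area_well Well area (> 0).
#' @param gel_areas Numeric vector of replicate gel areas (>= 0), typically
#'   triplicates.
#' @return Percentage (<= 100).
#' @examples
#' contraction_percent(100, c(60, 60, 60))  # 40
#' @export
contraction_percent <- function(area_well, gel_areas) {
  if (length(gel_areas) == 0) stop("empty replicate list")
  if (area_well <= 0 || any(gel_areas < 0)) stop("areas must be positive")
  100 * (area_well - mean(gel_areas)) / area_well
}

#' Spheroid invasion index
#'
#' Total area covered by CAFs (spheroid plus escaped cells) divided by the
#' spheroid core area; >= 1 when the total encompasses the core.
#'
#' @param total_caf_area Total covered area (>= core).
#' @param core_area Spheroid core area (> 0).
#' @export
invasion_index <- function(total_caf_area, core_area) {
  if (any(core_area <= 0)) stop("core_area must be > 0")
  if (any(total_caf_area < core_area)) stop("total area must be >= core area")
  total_caf_area / core_area
}

#' Velocity, persistence and directionality of a cell track
#'
#' Velocity is the mean per-step displacement divided by the sampling
#' interval (um/h). Persistence is the end-to-end distance `d` over the
#' contour length `l` of the trajectory (in `[0, 1]`). Direction is the mean
#' per-step `|sin(alpha)|` where `alpha` is the angle between the step
#' velocity and the initial cell-free-zone border (1 = perpendicular
#' migration into the free zone).
#'
#' @param track Data frame `t, x, y` for one cell, uniform sampling,
#'   strictly increasing `t`, >= 2 rows.
#' @param border_normal Unit vector normal to the border; the border line
#'   direction is its perpendicular. Taken from the track attribute if
#'   absent.
#' @return List: `velocity` (um/h), `persistence` (NA-flagged when the
#'   contour length is zero), `direction`.
#' @examples
#' tr <- data.frame(t = 0:3, x = c(0, 10, 20, 30), y = 0)
#' track_metrics(tr, border_normal = c(1, 0))
#' @export
track_metrics <- function(track, border_normal = attr(track, "border_normal")) {
  if (nrow(track) < 2L) stop("track needs at least 2 samples")
  dt <- diff(track$t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  dx <- diff(track$x); dy <- diff(track$y)
  step <- sqrt(dx^2 + dy^2)
  velocity <- mean(step / dt)
  contour <- sum(step)
  d <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
              (track$y[nrow(track)] - track$y[1])^2)
  persistence <- if (contour == 0) NA_real_ else d / contour
  direction <- NA_real_
  if (!is.null(border_normal)) {
    bn <- border_normal / sqrt(sum(border_normal^2))
    border <- c(-bn[2], bn[1])  # border line direction
    moving <- step > 0
    if (any(moving)) {
      # |sin(angle to border)| = |cross(step, border)| / |step|
      direction <- mean(abs(dx[moving] * border[2] - dy[moving] * border[1]) /
                          step[moving])
    }
  }
  list(velocity = velocity, persistence = persistence, direction = direction)
}

#' Track metrics for a whole track table
#'
#' @param tracks Data frame `cell_id, t, x, y` (e.g. from
#'   [simulate_trajectories()]).
#' @inheritParams track_metrics
#' @return Data frame with one row per cell: `cell_id`, `velocity`,
#'   `persistence`, `direction`.
#' @export
track_metrics_table <- function(tracks,
                                border_normal = attr(tracks, "border_normal")) {
  ids <- unique(tracks$cell_id)
  rows <- lapply(ids, function(id) {
    m <- track_metrics(tracks[tracks$cell_id == id, , drop = FALSE],
                       border_normal)
    data.frame(cell_id = id, velocity = m$velocity,
               persistence = m$persistence, direction = m$direction)
  })
  do.call(rbind, rows)
}

#' Collagen density from an SHG mask stack
#'
#' `d = sum_i(dz * covered_area(i)) / V_stack`, the collagen-covered volume
#' fraction of the stack; with constant slice geometry this is the mean
#' areal coverage.
#'
#' @param masks List of logical/0-1 matrices (one per slice, equal dims).
#' @param dz Step between slices (> 0), same unit as implied by the volume.
#' @return Density in `[0, 1]`.
#' @export
collagen_density <- function(masks, dz = 1) {
  if (length(masks) == 0) stop("empty stack")
  if (dz <= 0) stop("dz must be > 0")
  dm <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == dm), logical(1)))) {
    stop("inconsistent slice dimensions")
  }
  covered <- vapply(masks, function(m) sum(m != 0), numeric(1))
  sum(dz * covered) / (dz * length(masks) * prod(dm))
}

#' Invasion statistics of a 3D z-stack
#'
#' Frequency profile of cell depth in fixed bins (default 10 um from the
#' membrane up to 200 um, normalized to the number of detected cells in the
#' stack), maximal invasion distance (the depth of the shallowest cell among
#' the deepest `tail` fraction, default 1%: sorted-z rank
#' `floor((1 - tail) * n) + 1`), and the fraction of cells beyond a depth
#' threshold (default 50 um).
#'
#' @param z Numeric vector of per-cell invasion depths (um, >= 0), or a data
#'   frame with a `z` column.
#' @param bin_width Profile bin width, um.
#' @param z_range Profile range, um.
#' @param z0 Depth threshold for `fraction_above`, um.
#' @param tail Tail fraction defining the maximal distance (default 0.01).
#' @return List: `profile` (data frame `z_lo, z_hi, frequency`),
#'   `max_distance`, `fraction_above`, `n`.
#' @examples
#' invasion_stats(c(rep(5, 990), rep(150, 10)))$max_distance  # 150
#' @export
invasion_stats <- function(z, bin_width = 10, z_range = c(0, 200), z0 = 50,
                           tail = 0.01) {
  if (is.data.frame(z)) z <- z$z
  n <- length(z)
  if (n < 1) stop("need at least one cell")
  if (any(z < 0)) stop("negative invasion depth")
  breaks <- seq(z_range[1], z_range[2], by = bin_width)
  counts <- hist(pmin(z, z_range[2]), breaks = breaks, plot = FALSE,
                 right = FALSE)$counts
  # hist(right = FALSE) puts the final closed bin at z_max; fold it in
  counts[length(counts)] <- counts[length(counts)] + sum(z >= z_range[2])
  profile <- data.frame(z_lo = breaks[-length(breaks)], z_hi = breaks[-1],
                        frequency = counts / n)
  zs <- sort(z)
  rank <- min(n, floor((1 - tail) * n) + 1L)
  list(profile = profile, max_distance = zs[rank],
       fraction_above = sum(z > z0) / n, n = n)
}

#' Population doubling time from a growth series
#'
#' Least-squares slope of `log2(count)` against time; doubling time is the
#' reciprocal slope. A non-positive slope (non-growing culture) is flagged
#' with `NA` and a warning.
#'
#' @param t Time points (>= 2), e.g. days.
#' @param n Cell counts (> 0), same length.
#' @return Doubling time in the unit of `t`, or `NA` if non-growing.
#' @examples
#' doubling_time(0:3, c(1, 2, 4, 8))  # 1
#' @export
doubling_time <- function(t, n) {
  if (length(t) < 2 || length(t) != length(n)) stop("need >= 2 paired counts")
  if (any(n <= 0)) stop("counts must be positive")
  slope <- stats::coef(stats::lm(log2(n) ~ t))[["t"]]
  if (slope <= 0) {
    warning("non-positive growth slope; culture flagged as non-growing")
    return(NA_real_)
  }
  1 / slope
}

#' Cytokine spot ratio
#'
#' Mean of the duplicate cytokine spot intensities divided by the mean of
#' the internal control spots, correcting for hybridization efficiency.
#'
#' @param spot_intensities Cytokine spot intensities (typically 2).
#' @param control_intensities Control spot intensities (typically 3).
#' @return Ratio.
#' @export
cytokine_ratio <- function(spot_intensities, control_intensities) {
  if (length(control_intensities) == 0 || mean(control_intensities) <= 0) {
    stop("control mean must be > 0")
  }
  mean(spot_intensities) / mean(control_intensities)
}
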