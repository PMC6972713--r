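#' Learn quartile thresholds from a reference marker table
#'
#' The decision tree cuts each marker at the first quartile, median and third
#' quartile of a learning dataset. Quantiles use linear interpolation between
#' order statistics (`stats::quantile()` type 7).
#'
#' @param cells Data frame with one numeric column per panel marker (extra
#'   columns such as `cell_id`, `tissue`, `true_subset` are ignored).
#' @param markers Character vector of panel markers; defaults to every column
#'   of `cells` matching a known marker name.
#' @return Data frame of class `caf_thresholds` with columns
#'   `marker`, `q1`, `median`, `q3` and attribute `provenance`.
#' @examples
#' learn_thresholds(data.frame(FAP = c(1, 2, 3, 4)), markers = "FAP")
#' @export
learn_thresholds <- function(cells, markers = NULL) {
  if (is.null(markers)) {
    markers <- intersect(union(caf_panel("FACS"), caf_panel("IHC")), names(cells))
  }
  if (nrow(cells) == 0L) stop("empty marker table")
  if (nrow(cells) < 4L) stop("need at least 4 observations to learn quartiles")
  missing <- setdiff(markers, names(cells))
  if (length(missing)) stop("missing marker columns: ", paste(missing, collapse = ", "))
  qs <- vapply(markers, function(m) {
    v <- cells[[m]]
    if (anyNA(v) || any(!is.finite(v))) stop("non-finite values in marker ", m)
    if (length(unique(v)) == 1L) {
      warning("marker ", m, " is constant; all thresholds equal")
    }
    stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  }, numeric(3))
  out <- data.frame(marker = markers, q1 = qs[1, ], median = qs[2, ],
                    q3 = qs[3, ], row.names = NULL)
  stopifnot(all(out$q1 <= out$median & out$median <= out$q3))
  structure(out, class = c("caf_thresholds", "data.frame"), provenance = "learned")
}

#' Transpose thresholds onto another modality
#'
#' Thresholds learned on FACS intensities are carried to another modality
#' (IHC H-scores, tile DAB densities) by recomputing the quartiles at the
#' same quantile positions on the target distribution. Marker names can be
#' remapped on the way; the default map replaces PDPN by FSP1, the IHC
#' surrogate marker.
#'
#' @param reference Data frame of the target modality (H-score table, tile
#'   density table, ...).
#' @param markers Markers to compute on the target; defaults to known marker
#'   columns of `reference`.
#' @param marker_map Named character vector mapping source marker names to
#'   target columns, e.g. `c(PDPN = "FSP1")`.
#' @return `caf_thresholds` data frame with `provenance = "transposed"`.
#' @export
transpose_thresholds <- function(reference, markers = NULL,
                                 marker_map = c(PDPN = "FSP1")) {
  if (is.null(markers)) {
    markers <- intersect(union(caf_panel("FACS"), caf_panel("IHC")), names(reference))
  }
  mapped <- ifelse(markers %in% names(marker_map), marker_map[markers], markers)
  missing <- setdiff(mapped, names(reference))
  if (length(missing)) stop("missing mapped marker columns: ",
                            paste(missing, collapse = ", "))
  th <- learn_thresholds(reference, markers = unique(mapped))
  attr(th, "provenance") <- "transposed"
  th
}

#' Discretize a marker value into an ordinal level
#'
#' Bands are left-closed: value < Q1 -> Neg (0); Q1 <= value < median ->
#' Low (1); median <= value < Q3 -> Med (2); value >= Q3 -> High (3). A value
#' equal to a threshold therefore enters the upper band.
#'
#' @param value Numeric vector of marker values.
#' @param marker Marker name, matched against `thresholds$marker`.
#' @param thresholds A [learn_thresholds()] result.
#' @return Integer vector of levels in 0:3.
#' @examples
#' th <- learn_thresholds(data.frame(FAP = c(1, 2, 3, 4)), "FAP")
#' discretize_level(c(0, 1.8, 2.5, 9), "FAP", th)
#' @export
discretize_level <- function(value, marker, thresholds) {
  i <- match(marker, thresholds$marker)
  if (is.na(i)) stop("no thresholds for marker ", marker)
  (value >= thresholds$q1[i]) + (value >= thresholds$median[i]) +
    (value >= thresholds$q3[i])
}

# Distance from an observed level to the nearest admissible level of a profile.
ordinal_distance <- function(levels, profile, markers) {
  sum(vapply(markers, function(m) min(abs(levels[[m]] - profile[[m]])), numeric(1)))
}

#' Classify a single record into a CAF subset
#'
#' Each marker value is discretized against the quartile thresholds; the
#' record is scored against each subset profile by the number of markers whose
#' level falls in the subset's admissible set. The subset with the highest
#' match score wins; ties are broken by minimal total ordinal distance to the
#' profile (sum over markers of distance to the nearest admissible level),
#' then by a fixed priority, and flagged as ambiguous.
#'
#' @param values Named numeric vector or one-row list: marker -> intensity,
#'   H-score or tile density. Alternatively, pre-discretized integer levels
#'   with `discretized = TRUE`.
#' @param thresholds A [learn_thresholds()] result (ignored when
#'   `discretized = TRUE`).
#' @param profiles Subset profiles, see [caf_profiles()].
#' @param priority Tie-break order of subset labels.
#' @param discretized If `TRUE`, `values` are already ordinal levels in 0:3.
#' @return List with `label`, `match_score` (0..panel size), `ambiguous`
#'   (TRUE when two or more subsets tie on score and distance) and `levels`.
#' @examples
#' pr <- caf_profiles("FACS")
#' classify_record(c(FAP = 3, CD29 = 3, SMA = 3, PDPN = 3, PDGFRB = 3),
#'                 profiles = pr, discretized = TRUE)$label  # CAF-S1
#' @export
classify_record <- function(values, thresholds = NULL, profiles = caf_profiles(),
                            priority = caf_priority_default(),
                            discretized = FALSE) {
  markers <- names(profiles[[1]])
  values <- unlist(values[markers])
  if (anyNA(values)) {
    stop("panel mismatch: record lacks markers ",
         paste(setdiff(markers, names(values)[!is.na(values)]), collapse = ", "))
  }
  if (discretized) {
    levels <- as.list(as.integer(values))
    names(levels) <- markers
    stopifnot(all(unlist(levels) %in% 0:3))
  } else {
    if (is.null(thresholds)) stop("thresholds required for raw values")
    levels <- lapply(markers, function(m) discretize_level(values[[m]], m, thresholds))
    names(levels) <- markers
  }
  scores <- vapply(profiles, function(p) {
    sum(vapply(markers, function(m) levels[[m]] %in% p[[m]], logical(1)))
  }, numeric(1))
  best <- names(scores)[scores == max(scores)]
  ambiguous <- length(best) > 1L
  if (ambiguous) {
    d <- vapply(profiles[best], ordinal_distance, numeric(1),
                levels = levels, markers = markers)
    best <- best[d == min(d)]
    ambiguous <- length(best) > 1L
    best <- best[order(match(best, priority))]
  }
  list(label = best[[1L]], match_score = as.integer(max(scores)),
       ambiguous = ambiguous, levels = unlist(levels))
}

#' Classify every row of a marker table
#'
#' Vectorized wrapper around the decision tree: discretizes all panel markers
#' of a cell table (or H-score / tile density table) and assigns a subset
#' label per row.
#'
#' @inheritParams classify_record
#' @param cells Data frame with one numeric column per profile marker.
#' @return Data frame with columns `label`, `match_score`, `ambiguous` and
#'   one `level_<marker>` column per marker, one row per input row.
#' @export
classify_cells <- function(cells, thresholds, profiles = caf_profiles(),
                           priority = caf_priority_default()) {
  markers <- names(profiles[[1]])
  lv <- vapply(markers, function(m) discretize_level(cells[[m]], m, thresholds),
               integer(nrow(cells)))
  lv <- matrix(lv, nrow = nrow(cells),
               dimnames = list(NULL, markers))  # guard n = 1 drop
  # score all rows against all profiles at once
  scores <- vapply(profiles, function(p) {
    rowSums(vapply(markers, function(m) lv[, m] %in% p[[m]],
                   logical(nrow(cells))) |>
              matrix(nrow = nrow(cells)))
  }, numeric(nrow(cells))) |> matrix(ncol = length(profiles),
                                     dimnames = list(NULL, names(profiles)))
  dists <- vapply(profiles, function(p) {
    rowSums(vapply(markers, function(m) {
      vapply(lv[, m], function(l) min(abs(l - p[[m]])), numeric(1))
    }, numeric(nrow(cells))) |> matrix(nrow = nrow(cells)))
  }, numeric(nrow(cells))) |> matrix(ncol = length(profiles))
  prio <- match(names(profiles), priority)
  n <- nrow(cells)
  label <- character(n); ambiguous <- logical(n)
  top <- apply(scores, 1L, max)
  for (i in seq_len(n)) {
    cand <- which(scores[i, ] == top[i])
    if (length(cand) > 1L) {
      cand <- cand[dists[i, cand] == min(dists[i, cand])]
      ambiguous[i] <- length(cand) > 1L
      cand <- cand[order(prio[cand])]
    }
    label[i] <- names(profiles)[cand[[1L]]]
  }
  out <- data.frame(label = label, match_score = as.integer(top),
                    ambiguous = ambiguous)
  out[paste0("level_", markers)] <- as.data.frame(lv)
  out
}

#' Histological score from intensity-bin fractions
#'
#' H-score = sum over intensity bins (0..4) of bin value x 100 x fraction of
#' fibroblasts in the bin; range 0 to 400. The common single-intensity
#' product (intensity x percent stained) is the degenerate two-bin case.
#'
#' @param fractions Named numeric vector: names are intensity bins "0".."4",
#'   values the fraction of fibroblasts per bin; must sum to 1.
#' @return H-score in `[0, 400]`.
#' @examples
#' compute_hscore(c("1" = 0.5, "3" = 0.5))  # 200
#' @export
compute_hscore <- function(fractions) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  bins <- as.numeric(names(fractions))
  if (anyNA(bins) || any(bins < 0 | bins > 4)) stop("bins must be 0..4")
  sum(bins * 100 * fractions)
}

#' Percentage of stroma in a section
#'
#' Fibroblastic area times 100 divided by the total sample area.
#'
#' @param fibroblastic_area,total_area Non-negative areas, same units.
#' @return Percentage in `[0, 100]`.
#' @export
stroma_percent <- function(fibroblastic_area, total_area) {
  if (any(total_area <= 0)) stop("total_area must be positive")
  if (any(fibroblastic_area < 0 | fibroblastic_area > total_area)) {
    stop("fibroblastic_area must lie in [0, total_area]")
  }
  100 * fibroblastic_area / total_area
}

#' Call per-sample CAF enrichment from an H-score table
#'
#' Applies the decision tree to IHC H-scores: each sample's marker H-scores
#' are discretized against thresholds transposed onto the H-score
#' distribution and matched against the subset profiles (IHC panel, FSP1
#' replacing PDPN).
#'
#' @param hscores Data frame with one column per IHC panel marker.
#' @param thresholds Thresholds on the H-score scale (see
#'   [transpose_thresholds()]).
#' @param profiles Profiles on the IHC panel.
#' @inheritParams classify_record
#' @return As [classify_cells()].
#' @export
call_sample_enrichment <- function(hscores, thresholds,
                                   profiles = caf_profiles("IHC"),
                                   priority = caf_priority_default()) {
  classify_cells(hscores, thresholds, profiles, priority)
}
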