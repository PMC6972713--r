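#' @title Synthetic-data generators
#' @description
#' Every input the pipeline consumes has a generator with known ground truth:
#' FACS-like marker-intensity cohorts, IHC H-score cohorts, serial-section
#' stain images with landmarks, elastic-substrate displacement fields,
#' persistent random-walk tracks, 3D invasion point clouds and
#' proportional-hazards survival cohorts. All generators are pure functions
#' of their parameters and a seed.
#' @name simulate
NULL

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(code)
}

# Default quantitative spacing of the ordinal levels on the FACS (log2) and
# IHC (H-score) scales. The profiles are ordinal only; these means place the
# four levels in well-separated bands.
facs_level_means <- function() c(2, 4, 6, 8)     # log2 intensity per level 0:3
ihc_level_means  <- function() c(50, 150, 250, 350)  # H-score per level 0:3

#' Simulate a FACS-like CAF cohort with known subsets
#'
#' Each cell is assigned a true subset; for every panel marker a level is
#' sampled uniformly from that subset's admissible set and the intensity is
#' drawn log-normally: `2^N(mean[level], sd)` with strictly increasing
#' level means.
#'
#' @param n_cells Total number of cells.
#' @param proportions Simplex weights over CAF-S1..S4 (sum to 1).
#' @param level_means Log2-intensity mean per level 0:3, strictly increasing.
#' @param level_sd Log2-intensity SD within a level.
#' @param tissue Tissue tag, `"PT"` or `"LN"` (stored per cell).
#' @param panel Marker panel, see [caf_panel()].
#' @param seed Integer seed; fully determines the output.
#' @return Data frame: `cell_id`, `tissue`, `true_subset`, one intensity
#'   column per marker.
#' @export
simulate_facs_cohort <- function(n_cells = 4000,
                                 proportions = rep(0.25, 4),
                                 level_means = facs_level_means(),
                                 level_sd = 0.5,
                                 tissue = "PT",
                                 panel = "FACS",
                                 seed = NULL) {
  if (n_cells <= 0) stop("n_cells must be positive")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (any(diff(level_means) <= 0)) stop("level_means must be strictly increasing")
  profiles <- caf_profiles(panel)
  markers <- caf_panel(panel)
  with_seed(seed, {
    subset <- sample(caf_subsets(), n_cells, replace = TRUE, prob = proportions)
    out <- data.frame(cell_id = sprintf("c%05d", seq_len(n_cells)),
                      tissue = tissue, true_subset = subset)
    for (m in markers) {
      adm <- lapply(profiles, `[[`, m)
      if (any(lengths(adm) == 0)) stop("empty admissible set for marker ", m)
      lev <- vapply(subset, function(s) {
        a <- adm[[s]]
        a[sample.int(length(a), 1L)]
      }, integer(1))
      out[[m]] <- 2^stats::rnorm(n_cells, level_means[lev + 1L], level_sd)
    }
    out
  })
}

#' Simulate a balanced learning dataset for threshold calibration
#'
#' A reference fibroblast population in which every marker occupies each of
#' the four ordinal levels with equal probability, so that its empirical
#' quartiles estimate the level-band boundaries. This plays the role of the
#' learning dataset on which quartile thresholds are defined before being
#' applied to study cohorts.
#'
#' @inheritParams simulate_facs_cohort
#' @param n Number of reference cells.
#' @return Data frame with one intensity column per marker plus the true
#'   level columns `level_<marker>`.
#' @export
simulate_reference_cells <- function(n = 4000,
                                     level_means = facs_level_means(),
                                     level_sd = 0.5,
                                     panel = "FACS",
                                     seed = NULL) {
  markers <- caf_panel(panel)
  with_seed(seed, {
    out <- data.frame(cell_id = sprintf("r%05d", seq_len(n)))
    for (m in markers) {
      lev <- sample(rep(0:3, length.out = n))  # exactly balanced occupancy
      out[[m]] <- 2^stats::rnorm(n, level_means[lev + 1L], level_sd)
      out[[paste0("level_", m)]] <- lev
    }
    out
  })
}

#' Simulate an IHC cohort of per-sample H-scores
#'
#' Each sample is assigned a true enrichment subset; marker H-scores are
#' drawn normally around the level mean of a level sampled from the subset's
#' admissible set (IHC panel, FSP1 in place of PDPN), truncated to
#' `[0, 400]`. Stromal percentage and BC subtype covariates are attached.
#'
#' @param n_samples Number of samples.
#' @param enrichment_mix Simplex over CAF-S1..S4 true enrichments.
#' @param level_means H-score mean per level 0:3.
#' @param level_sd Within-level H-score SD.
#' @param seed Integer seed.
#' @return Data frame: `sample_id`, `true_enrichment`, marker H-scores,
#'   `stroma_percent`, `subtype`.
#' @export
simulate_ihc_cohort <- function(n_samples = 200,
                                enrichment_mix = rep(0.25, 4),
                                level_means = ihc_level_means(),
                                level_sd = 25,
                                seed = NULL) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (abs(sum(enrichment_mix) - 1) > 1e-9) stop("enrichment_mix must sum to 1")
  profiles <- caf_profiles("IHC")
  markers <- caf_panel("IHC")
  with_seed(seed, {
    subset <- sample(caf_subsets(), n_samples, replace = TRUE, prob = enrichment_mix)
    out <- data.frame(sample_id = sprintf("s%04d", seq_len(n_samples)),
                      true_enrichment = subset)
    for (m in markers) {
      adm <- lapply(profiles, `[[`, m)
      lev <- vapply(subset, function(s) {
        a <- adm[[s]]
        a[sample.int(length(a), 1L)]
      }, integer(1))
      out[[m]] <- pmin(400, pmax(0, stats::rnorm(n_samples,
                                                 level_means[lev + 1L], level_sd)))
    }
    # invaded-LN stroma is around 25-30% of the lesion area
    out$stroma_percent <- pmin(80, pmax(5, stats::rnorm(n_samples, 27.5, 8)))
    out$subtype <- sample(c("LumA", "LumB", "HER2", "TN"), n_samples,
                          replace = TRUE)
    out
  })
}

#' Balanced H-score reference table
#'
#' IHC analogue of [simulate_reference_cells()]: every marker occupies each
#' ordinal level with equal probability on the H-score scale, for transposing
#' quartile thresholds onto IHC data.
#'
#' @inheritParams simulate_ihc_cohort
#' @param n Number of reference samples.
#' @export
simulate_reference_hscores <- function(n = 400,
                                       level_means = ihc_level_means(),
                                       level_sd = 25,
                                       seed = NULL) {
  markers <- caf_panel("IHC")
  with_seed(seed, {
    out <- data.frame(sample_id = sprintf("hr%04d", seq_len(n)))
    for (m in markers) {
      lev <- sample(rep(0:3, length.out = n))  # exactly balanced occupancy
      out[[m]] <- pmin(400, pmax(0, stats::rnorm(n, level_means[lev + 1L], level_sd)))
      out[[paste0("level_", m)]] <- lev
    }
    out
  })
}

#' Default serial-section demo layout
#'
#' A 300 x 300 um scene tiled at 15 um (20 x 20 tiles): four subset quadrants
#' (CAF-S1 top-left, CAF-S2 top-right, CAF-S3 bottom-left, CAF-S4
#' bottom-right) with a central epithelial block. Each region carries an
#' explicit marker-level vector chosen so that, per marker, level occupancy
#' is as balanced as the subset profiles allow.
#'
#' @param n_tiles Tiles per side.
#' @return List with `tiles` (character label matrix) and `levels` (named
#'   list: label -> named integer levels for FAP, CD29, SMA, FSP1, EPCAM).
#' @export
demo_section_layout <- function(n_tiles = 20) {
  tiles <- matrix("CAF-S1", n_tiles, n_tiles)
  half <- n_tiles %/% 2
  tiles[seq_len(half), (half + 1):n_tiles] <- "CAF-S2"
  tiles[(half + 1):n_tiles, seq_len(half)] <- "CAF-S3"
  tiles[(half + 1):n_tiles, (half + 1):n_tiles] <- "CAF-S4"
  q <- max(1L, n_tiles %/% 5)
  mid <- (half - q + 1):(half + q)
  tiles[mid, mid] <- "epithelium"
  levels <- list(
    "CAF-S1"    = c(FAP = 3L, CD29 = 3L, SMA = 3L, FSP1 = 3L, EPCAM = 0L),
    "CAF-S2"    = c(FAP = 0L, CD29 = 1L, SMA = 0L, FSP1 = 1L, EPCAM = 0L),
    "CAF-S3"    = c(FAP = 1L, CD29 = 2L, SMA = 1L, FSP1 = 1L, EPCAM = 0L),
    "CAF-S4"    = c(FAP = 2L, CD29 = 3L, SMA = 3L, FSP1 = 1L, EPCAM = 0L),
    "epithelium" = c(FAP = 0L, CD29 = 0L, SMA = 0L, FSP1 = 0L, EPCAM = 3L)
  )
  list(tiles = tiles, levels = levels)
}

#' Simulate serial-section stain images with landmarks
#'
#' Renders one RGB image per marker from a tile-level layout: each region's
#' marker level sets the DAB optical density (level x `od_per_level`), a
#' uniform hematoxylin counterstain is added, and RGB is produced by
#' Beer-Lambert mixing with the standard H-DAB stain vectors. Each marker
#' section is then warped by a small random affine (the serial-section
#' misalignment); matched landmark pairs are emitted per section.
#'
#' @param layout As returned by [demo_section_layout()].
#' @param px_per_um Pixels per micron (default 1).
#' @param tile_um Tile side in um (default 15, i.e. 225 um^2 tiles); must map
#'   to a whole number of pixels.
#' @param misalignment Maximum translation of the random warp, in px
#'   (rotation up to `misalignment / image size` radians is added). 0 gives
#'   identity warps.
#' @param od_per_level DAB optical density per ordinal level step.
#' @param noise_sd Pixelwise OD noise SD.
#' @param n_landmarks Landmarks per side of the landmark grid.
#' @param seed Integer seed.
#' @return List with `images` (named list of H x W x 3 arrays in `[0, 1]`),
#'   `landmarks` (named list of data frames `x_ref, y_ref, x_mov, y_mov`,
#'   0-based px, origin top-left), `truth` (tile label matrix),
#'   `transforms` (true affine matrices, moving -> reference), `px_per_um`,
#'   `tile_um`.
#' @export
simulate_tissue_sections <- function(layout = demo_section_layout(),
                                     px_per_um = 1,
                                     tile_um = 15,
                                     misalignment = 2,
                                     od_per_level = 0.25,
                                     noise_sd = 0.02,
                                     n_landmarks = 4,
                                     seed = NULL) {
  tile_px <- tile_um * px_per_um
  if (abs(tile_px - round(tile_px)) > 1e-9) {
    stop("tile side of ", tile_um, " um is not a whole number of pixels at ",
         px_per_um, " px/um; use px_per_um so that tile_um * px_per_um is integer")
  }
  tile_px <- as.integer(round(tile_px))
  tiles <- layout$tiles
  markers <- setdiff(names(layout$levels[[1]]), NULL)
  h <- nrow(tiles) * tile_px
  w <- ncol(tiles) * tile_px
  sv <- stain_vectors_hdab()
  with_seed(seed, {
    images <- list(); landmarks <- list(); transforms <- list()
    # landmark grid in reference coordinates (0-based px)
    gx <- seq(0.1, 0.9, length.out = n_landmarks) * (w - 1)
    gy <- seq(0.1, 0.9, length.out = n_landmarks) * (h - 1)
    ref_pts <- as.matrix(expand.grid(x = gx, y = gy))
    for (m in markers) {
      lev <- matrix(vapply(tiles, function(lab) layout$levels[[lab]][[m]],
                           integer(1)), nrow(tiles), ncol(tiles))
      od_dab <- lev[rep(seq_len(nrow(lev)), each = tile_px),
                    rep(seq_len(ncol(lev)), each = tile_px)] * od_per_level
      od_dab <- pmax(0, od_dab + stats::rnorm(length(od_dab), 0, noise_sd))
      od_hem <- pmax(0, 0.3 + stats::rnorm(length(od_dab), 0, noise_sd))
      img <- array(0, c(h, w, 3))
      for (ch in 1:3) {
        img[, , ch] <- 10^-(od_hem * sv[1, ch] + matrix(od_dab, h, w) * sv[2, ch])
      }
      # random misalignment affine, moving -> reference
      if (misalignment > 0) {
        ang <- stats::runif(1, -1, 1) * misalignment / max(h, w)
        tr <- stats::runif(2, -misalignment, misalignment)
        A <- affine_matrix(angle = ang, tx = tr[1], ty = tr[2],
                           center = c((w - 1) / 2, (h - 1) / 2))
      } else {
        A <- diag(3)
      }
      # moving image shows scene location A(q) at moving pixel q
      images[[m]] <- warp_image(img, function(p) affine_apply(A, p), c(h, w))
      Ainv <- solve(A)
      mov_pts <- affine_apply(Ainv, ref_pts)
      landmarks[[m]] <- data.frame(x_ref = ref_pts[, 1], y_ref = ref_pts[, 2],
                                   x_mov = mov_pts[, 1], y_mov = mov_pts[, 2])
      transforms[[m]] <- A
    }
    list(images = images, landmarks = landmarks, truth = tiles,
         transforms = transforms, px_per_um = px_per_um, tile_um = tile_um)
  })
}

#' Simulate a substrate displacement field from a known traction pattern
#'
#' Applies the forward Boussinesq operator ([tfm_forward()]) to a
#' zero-net-force traction field and optionally adds bead-sampling noise.
#'
#' @param traction A `vector_field` in Pa (net force is removed by the
#'   forward operator).
#' @param noise_sd SD of additive Gaussian displacement noise, um.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A displacement `vector_field` in um.
#' @export
simulate_displacement_field <- function(traction, noise_sd = 0, seed = NULL) {
  u <- tfm_forward(traction)
  if (noise_sd > 0) {
    u <- with_seed(seed, {
      vector_field(u$vx + stats::rnorm(length(u$vx), 0, noise_sd),
                   u$vy + stats::rnorm(length(u$vy), 0, noise_sd),
                   u$spacing, u$E, u$nu, u$mask, "um")
    })
  }
  u
}

#' Gaussian traction dipole
#'
#' A classic synthetic cell: two opposing Gaussian traction spots along x,
#' net-force free by construction. Used as ground truth for FTTC round
#' trips.
#'
#' @param n Grid side (nodes).
#' @param spacing Grid spacing, um.
#' @param amplitude Peak traction, Pa.
#' @param sigma Gaussian width, um.
#' @param separation Centre-to-centre distance, um.
#' @param E,nu Substrate constants.
#' @return A traction `vector_field` in Pa with a mask covering the dipole.
#' @export
gaussian_traction_dipole <- function(n = 128, spacing = 1, amplitude = 200,
                                     sigma = 6, separation = 24,
                                     E = 25000, nu = 0.5) {
  xy <- (seq_len(n) - 1) * spacing
  cx <- xy[n %/% 2 + 1]
  x <- matrix(xy, n, n, byrow = TRUE); y <- matrix(xy, n, n)
  g1 <- exp(-((x - cx + separation / 2)^2 + (y - cx)^2) / (2 * sigma^2))
  g2 <- exp(-((x - cx - separation / 2)^2 + (y - cx)^2) / (2 * sigma^2))
  tx <- amplitude * (g1 - g2)  # spots pull toward each other
  tx <- tx - mean(tx)
  mask <- (g1 + g2) > 0.01
  vector_field(tx, matrix(0, n, n), spacing, E, nu, mask, "Pa")
}

#' Simulate persistent random-walk cell tracks
#'
#' Cells step at interval `dt` with fixed speed; the step direction is a
#' persistence-weighted blend of the previous direction and a fresh uniform
#' direction: `d_t = normalize(p * d_(t-1) + (1 - p) * eta_t)`. `p = 1`
#' gives straight tracks, `p = 0` an isotropic random walk.
#'
#' @param n_cells Number of cells (the exclusion-zone assay tracked 40 per
#'   condition).
#' @param speed Cell speed, um/h.
#' @param persistence_param Persistence `p` in `[0, 1]`.
#' @param border_normal Unit vector normal to the initial cell-free-zone
#'   border (stored as an attribute for the direction metric).
#' @param dt Sampling interval, h.
#' @param duration Track duration, h (hourly frames over 24 h in the assay).
#' @param seed Integer seed.
#' @return Data frame `cell_id, t, x, y` with attribute `border_normal`.
#' @export
simulate_trajectories <- function(n_cells = 40, speed = 20,
                                  persistence_param = 0.5,
                                  border_normal = c(1, 0),
                                  dt = 1, duration = 24, seed = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (persistence_param < 0 || persistence_param > 1) {
    stop("persistence_param must lie in [0, 1]")
  }
  n_steps <- max(1L, as.integer(round(duration / dt)))
  with_seed(seed, {
    tracks <- lapply(seq_len(n_cells), function(i) {
      th0 <- stats::runif(1, 0, 2 * pi)
      d <- c(cos(th0), sin(th0))
      pos <- matrix(0, n_steps + 1L, 2L)
      for (s in seq_len(n_steps)) {
        thn <- stats::runif(1, 0, 2 * pi)
        v <- persistence_param * d + (1 - persistence_param) * c(cos(thn), sin(thn))
        nv <- sqrt(sum(v^2))
        if (nv < 1e-12) { v <- c(cos(thn), sin(thn)); nv <- 1 }
        d <- v / nv
        pos[s + 1L, ] <- pos[s, ] + speed * dt * d
      }
      data.frame(cell_id = sprintf("t%03d", i),
                 t = (0:n_steps) * dt, x = pos[, 1], y = pos[, 2])
    })
    out <- do.call(rbind, tracks)
    attr(out, "border_normal") <- border_normal / sqrt(sum(border_normal^2))
    out
  })
}

#' Simulate a 3D invasion z-stack point cloud
#'
#' Per-cell (x, y, z) positions emulating an inverted Transwell stack:
#' a non-invasive bulk decaying exponentially from the membrane plus an
#' invasive tail at depth. The default stack holds ~500 cells, mostly within
#' 30 um of the membrane.
#'
#' @param n_cells Cells in the stack.
#' @param z_law List: `bulk_mean` (um, exponential mean of the bulk),
#'   `tail_mass` (fraction of cells in the invasive tail), `tail_min`,
#'   `tail_max` (um, uniform tail support), `z_max` (um, stack depth, bulk
#'   draws are truncated to it).
#' @param xy_size Lateral stack size, um.
#' @param seed Integer seed.
#' @return Data frame `cell_id, x, y, z` (um, z >= 0).
#' @export
simulate_invasion_stack <- function(n_cells = 500,
                                    z_law = list(bulk_mean = 15, tail_mass = 0.05,
                                                 tail_min = 50, tail_max = 150,
                                                 z_max = 200),
                                    xy_size = 566.8, seed = NULL) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  zl <- utils::modifyList(list(bulk_mean = 15, tail_mass = 0.05, tail_min = 50,
                               tail_max = 150, z_max = 200), z_law)
  if (zl$tail_mass < 0 || zl$tail_mass > 1) stop("tail_mass must lie in [0, 1]")
  with_seed(seed, {
    in_tail <- stats::runif(n_cells) < zl$tail_mass
    z <- numeric(n_cells)
    nb <- sum(!in_tail)
    if (nb > 0) {
      zb <- if (zl$bulk_mean <= 0) rep(0, nb) else
        stats::rexp(nb, rate = 1 / zl$bulk_mean)
      z[!in_tail] <- pmin(zb, zl$z_max)
    }
    nt <- sum(in_tail)
    if (nt > 0) z[in_tail] <- stats::runif(nt, zl$tail_min, zl$tail_max)
    data.frame(cell_id = sprintf("z%04d", seq_len(n_cells)),
               x = stats::runif(n_cells, 0, xy_size),
               y = stats::runif(n_cells, 0, xy_size), z = z)
  })
}

#' Simulate a proportional-hazards survival cohort
#'
#' Covariates mirror the clinical table structure: stromal percentage,
#' CAF-subset enrichment, N-stage and BC subtype. Event times are exponential
#' under proportional hazards with the supplied log-hazard ratios; censoring
#' is independent exponential.
#'
#' @param n Patients.
#' @param strata_effects Named numeric log-HRs; recognized names:
#'   `stromal_high` (stromal percentage above 30), `CAF-S1`, `CAF-S4`
#'   (enrichment indicators), `N2`, `N3`, `LumB`, `HER2`, `TN`.
#' @param baseline_rate Baseline hazard, events/month.
#' @param censor_rate Censoring hazard, /month (0 = no censoring).
#' @param enrichment_mix Simplex over CAF-S1..S4.
#' @param seed Integer seed.
#' @return Data frame: `patient_id`, `time` (months), `event` (1/0),
#'   `stromal_percent`, `enrichment`, `n_stage`, `subtype`.
#' @export
simulate_survival_cohort <- function(n = 120,
                                     strata_effects = c(),
                                     baseline_rate = 0.02,
                                     censor_rate = 0.01,
                                     enrichment_mix = c(0.4, 0.05, 0.05, 0.5),
                                     seed = NULL) {
  if (!is.finite(baseline_rate) || baseline_rate <= 0) {
    stop("baseline_rate must be positive and finite")
  }
  if (!is.finite(censor_rate) || censor_rate < 0) {
    stop("censor_rate must be non-negative and finite")
  }
  with_seed(seed, {
    stromal <- pmin(80, pmax(5, stats::rnorm(n, 30, 12)))
    enrich <- sample(caf_subsets(), n, replace = TRUE, prob = enrichment_mix)
    n_stage <- sample(c("N1", "N2", "N3"), n, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
    subtype <- sample(c("LumA", "LumB", "HER2", "TN"), n, replace = TRUE,
                      prob = c(0.4, 0.25, 0.15, 0.2))
    design <- cbind(stromal_high = as.numeric(stromal > 30),
                    "CAF-S1" = as.numeric(enrich == "CAF-S1"),
                    "CAF-S4" = as.numeric(enrich == "CAF-S4"),
                    N2 = as.numeric(n_stage == "N2"),
                    N3 = as.numeric(n_stage == "N3"),
                    LumB = as.numeric(subtype == "LumB"),
                    HER2 = as.numeric(subtype == "HER2"),
                    TN = as.numeric(subtype == "TN"))
    lp <- numeric(n)
    if (length(strata_effects)) {
      bad <- setdiff(names(strata_effects), colnames(design))
      if (length(bad)) stop("unknown strata_effects: ", paste(bad, collapse = ", "))
      if (any(!is.finite(strata_effects))) stop("strata_effects must be finite")
      lp <- drop(design[, names(strata_effects), drop = FALSE] %*% strata_effects)
    }
    t_event <- stats::rexp(n, rate = baseline_rate * exp(lp))
    t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else Inf
    data.frame(patient_id = sprintf("p%04d", seq_len(n)),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stromal_percent = stromal, enrichment = enrich,
               n_stage = n_stage, subtype = subtype)
  })
}
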