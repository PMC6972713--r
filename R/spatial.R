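#' @title Spatial CAF-subset mapping on serial sections
#' @description
#' Landmark registration of serial marker sections, colour deconvolution,
#' 225 um^2 tiling with DAB densitometry, tile classification through the
#' quartile decision tree, and colour-coded map rendering.
#' @name spatial
NULL

# 3x3 homogeneous affine from rotation + translation about a centre (px).
affine_matrix <- function(angle = 0, tx = 0, ty = 0, scale = 1,
                          center = c(0, 0)) {
  R <- scale * matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)),
                      2, 2, byrow = TRUE)
  t0 <- c(tx, ty) + center - R %*% center
  rbind(cbind(R, t0), c(0, 0, 1))
}

# Apply a 3x3 affine to an N x 2 matrix of (x, y) points.
affine_apply <- function(A, pts) {
  pts <- matrix(pts, ncol = 2)
  out <- cbind(pts, 1) %*% t(A[1:2, ])
  colnames(out) <- c("x", "y")
  out
}

#' Fit a landmark transform between serial sections
#'
#' Least-squares landmark registration. The fitted transform maps reference
#' coordinates to moving-section coordinates (the resampling direction used
#' by [warp_image()]): registering a moving section means sampling it at the
#' transformed reference coordinates. Models: `affine` (>= 3 non-collinear
#' pairs, closed-form least squares) or `tps` (thin-plate spline, >= 4
#' non-collinear pairs, exact interpolation).
#'
#' @param landmarks Data frame with columns `x_ref, y_ref, x_mov, y_mov`
#'   (0-based pixels, origin top-left).
#' @param model `"affine"` or `"tps"`.
#' @return List of class `landmark_transform`: `model`, `predict` (function
#'   mapping N x 2 reference points to moving coordinates), `residual` (RMS
#'   landmark residual, px), and for affine the 3x3 `matrix`.
#' @export
fit_landmark_transform <- function(landmarks, model = c("affine", "tps")) {
  model <- match.arg(model)
  need <- c("x_ref", "y_ref", "x_mov", "y_mov")
  if (!all(need %in% names(landmarks))) {
    stop("landmarks must have columns ", paste(need, collapse = ", "))
  }
  P <- as.matrix(landmarks[, c("x_ref", "y_ref")])
  Q <- as.matrix(landmarks[, c("x_mov", "y_mov")])
  n <- nrow(P)
  min_n <- if (model == "affine") 3L else 4L
  if (n < min_n) stop("need at least ", min_n, " landmark pairs for ", model)
  X <- cbind(1, P)
  if (qr(X)$rank < 3L) stop("degenerate (collinear) landmarks")
  if (model == "affine") {
    # columns: coefficients for x_mov and y_mov
    B <- qr.solve(X, Q)
    A <- rbind(t(B)[, c(2, 3, 1)], c(0, 0, 1))
    dimnames(A) <- NULL
    pred <- function(pts) affine_apply(A, pts)
    fitted <- pred(P)
    res <- sqrt(mean(rowSums((fitted - Q)^2)))
    structure(list(model = "affine", matrix = A, predict = pred,
                   residual = res), class = "landmark_transform")
  } else {
    # thin-plate spline, one spline per output coordinate
    U <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2)) / 2
    d2 <- as.matrix(stats::dist(P))^2
    K <- U(d2)
    L <- rbind(cbind(K, X), cbind(t(X), matrix(0, 3, 3)))
    rhs <- rbind(Q, matrix(0, 3, 2))
    co <- tryCatch(solve(L, rhs), error = function(e)
      stop("degenerate landmarks for TPS: ", conditionMessage(e)))
    W <- co[seq_len(n), , drop = FALSE]
    Aff <- co[n + 1:3, , drop = FALSE]  # rows: 1, x, y
    pred <- function(pts) {
      pts <- matrix(pts, ncol = 2)
      d2p <- outer(rowSums(pts^2), rowSums(P^2), "+") - 2 * pts %*% t(P)
      d2p[d2p < 0] <- 0
      out <- cbind(1, pts) %*% Aff + U(d2p) %*% W
      colnames(out) <- c("x", "y")
      out
    }
    fitted <- pred(P)
    res <- sqrt(mean(rowSums((fitted - Q)^2)))
    structure(list(model = "tps", predict = pred, residual = res),
              class = "landmark_transform")
  }
}

#' Warp an image by inverse mapping with bilinear interpolation
#'
#' For each output pixel (0-based centre coordinates, x rightward, y
#' downward), `map` gives the input-image coordinates to sample; values are
#' bilinearly interpolated, out-of-bounds samples get `fill`.
#'
#' @param img Matrix (H x W) or array (H x W x C) with values in `[0, 1]`.
#' @param map Function taking an N x 2 matrix of (x, y) output coordinates
#'   and returning N x 2 input coordinates; or a `landmark_transform`.
#' @param dims_out `c(height, width)` of the output; defaults to input size.
#' @param fill Fill value outside the input domain.
#' @return Warped image, same number of channels.
#' @export
warp_image <- function(img, map, dims_out = NULL, fill = 1) {
  if (inherits(map, "landmark_transform")) map <- map$predict
  dm <- dim(img)
  h_in <- dm[1]; w_in <- dm[2]
  nc <- if (length(dm) == 3L) dm[3] else 1L
  if (is.null(dims_out)) dims_out <- c(h_in, w_in)
  h <- dims_out[1]; w <- dims_out[2]
  grid <- cbind(x = rep(0:(w - 1), each = h), y = rep(0:(h - 1), times = w))
  src <- map(grid)
  x <- src[, 1]; y <- src[, 2]
  x0 <- floor(x); y0 <- floor(y)
  dx <- x - x0; dy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= w_in - 1 & y0 <= h_in - 1
  x1 <- pmin(x0 + 1, w_in - 1); y1 <- pmin(y0 + 1, h_in - 1)
  out <- array(fill, c(h, w, nc))
  img <- array(img, c(h_in, w_in, nc))
  idx <- function(yy, xx) cbind(yy + 1, xx + 1)
  for (ch in seq_len(nc)) {
    plane <- img[, , ch]
    v <- rep(fill, nrow(grid))
    ii <- which(inside)
    v[ii] <- (1 - dx[ii]) * (1 - dy[ii]) * plane[idx(y0[ii], x0[ii])] +
      dx[ii] * (1 - dy[ii]) * plane[idx(y0[ii], x1[ii])] +
      (1 - dx[ii]) * dy[ii] * plane[idx(y1[ii], x0[ii])] +
      dx[ii] * dy[ii] * plane[idx(y1[ii], x1[ii])]
    out[, , ch] <- matrix(v, h, w)
  }
  if (nc == 1L) out[, , 1] else out
}

#' Standard H-DAB stain vectors
#'
#' Published hematoxylin/DAB optical-density vectors (rows hematoxylin, DAB
#' and their residual complement), each row normalized to unit length.
#'
#' @return 3 x 3 numeric matrix, rows = stains, columns = R, G, B.
#' @export
stain_vectors_hdab <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Colour deconvolution of an RGB stain image
#'
#' Converts RGB transmission to optical density `OD = -log10(I / I0)` (I
#' floored at 1/255 so black pixels cap at the maximal OD) and unmixes the
#' per-pixel OD vector with the inverse stain matrix. Negative unmixed
#' densities are clipped at 0.
#'
#' @param rgb H x W x 3 array in `[0, 1]` (or 0..255, auto-scaled).
#' @param stain_vectors 3 x 3 matrix, rows = stain OD vectors; must be
#'   non-singular. Default published H-DAB vectors.
#' @return Named list of H x W optical-density matrices, one per stain row.
#' @export
color_deconvolve <- function(rgb, stain_vectors = stain_vectors_hdab()) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (max(rgb) > 1) rgb <- rgb / 255
  if (abs(det(stain_vectors)) < 1e-8) stop("singular stain matrix")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  I <- pmax(matrix(rgb, h * w, 3), 1 / 255)
  od <- -log10(I)
  conc <- od %*% solve(stain_vectors)  # od rows = conc rows %*% stain_vectors
  conc[conc < 0] <- 0
  stains <- rownames(stain_vectors)
  out <- lapply(seq_len(3), function(s) matrix(conc[, s], h, w))
  names(out) <- stains
  out
}

#' Tile-level DAB densitometry
#'
#' Divides registered DAB optical-density images into square tiles
#' (default 15 um side, 225 um^2, the approximate footprint of one
#' fibroblast) and integrates the OD per tile and marker. Partial edge tiles
#' are dropped rather than padded, since partial tiles would bias the
#' integrated density.
#'
#' @param od_images Named list of equal-sized OD matrices, one per marker.
#' @param tile_um Tile side, um.
#' @param px_per_um Pixels per micron; `tile_um * px_per_um` must be a whole
#'   number of pixels.
#' @return Data frame with `row`, `col` (1-based tile indices) and one
#'   integrated-density column per marker; attribute `tile_px`.
#' @export
tile_densitometry <- function(od_images, tile_um = 15, px_per_um = 1) {
  tile_px <- tile_um * px_per_um
  if (abs(tile_px - round(tile_px)) > 1e-9) {
    cands <- c(1, 2, 4) / tile_um * round(tile_um)  # suggest integer-px sizes
    stop("tile side of ", tile_um, " um is not a whole number of pixels at ",
         px_per_um, " px/um; choose px_per_um with integer tile_um * px_per_um ",
         "(e.g. ", paste(round(cands, 3), collapse = ", "), " px/um)")
  }
  tile_px <- as.integer(round(tile_px))
  dm <- dim(od_images[[1]])
  stopifnot(all(vapply(od_images, function(m) all(dim(m) == dm), logical(1))))
  n_r <- dm[1] %/% tile_px
  n_c <- dm[2] %/% tile_px
  if (n_r == 0 || n_c == 0) stop("image smaller than one tile")
  grid <- expand.grid(row = seq_len(n_r), col = seq_len(n_c))
  out <- grid
  for (m in names(od_images)) {
    img <- od_images[[m]][seq_len(n_r * tile_px), seq_len(n_c * tile_px)]
    # block sums via row/col aggregation
    rs <- rowsum(img, rep(seq_len(n_r), each = tile_px))
    cs <- t(rowsum(t(rs), rep(seq_len(n_c), each = tile_px)))
    out[[m]] <- cs[cbind(grid$row, grid$col)]
  }
  attr(out, "tile_px") <- tile_px
  attr(out, "dims") <- c(n_r, n_c)
  out
}

#' Otsu threshold
#'
#' Maximizes between-class variance on a histogram of the values; used to
#' separate epithelial (EPCAM-high) tiles from stromal tiles.
#'
#' @param x Numeric vector.
#' @param n_bins Histogram bins.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mid <- h$mids
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mid)
  mu_t <- mu0[length(mu0)]
  bc <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  mid[which.max(bc)]
}

#' Classify tiles into CAF subsets and epithelium
#'
#' Tiles whose EPCAM integrated density exceeds the epithelial threshold are
#' labeled `epithelium`; the remaining tiles are classified by the quartile
#' decision tree on the tile panel (FAP, CD29, SMA, FSP1), with thresholds
#' transposed onto the per-section tile-density distribution of stromal
#' tiles unless supplied.
#'
#' The default EPCAM threshold is an absolute optical-density floor: a tile
#' is epithelial when its mean DAB OD per pixel exceeds `epcam_od_floor`
#' (anything below that is counterstain background). An absolute criterion
#' stays correct on degenerate sections that are entirely epithelial or
#' entirely stromal, where data-driven cuts such as [otsu_threshold()] would
#' split noise.
#'
#' @param tiles Output of [tile_densitometry()] including an `EPCAM` column.
#' @param thresholds Optional `caf_thresholds` on the tile-density scale;
#'   `NULL` transposes quartiles per section.
#' @param profiles Profiles on the tile panel.
#' @param epcam_threshold Optional numeric integrated-density threshold;
#'   overrides the OD floor.
#' @param epcam_od_floor Mean per-pixel DAB OD marking epithelial staining.
#' @return `tiles` with a `label` column; attribute `label_matrix`.
#' @export
classify_tiles <- function(tiles, thresholds = NULL,
                           profiles = caf_profiles("tile"),
                           epcam_threshold = NULL, epcam_od_floor = 0.125) {
  if (!"EPCAM" %in% names(tiles)) stop("tiles must include an EPCAM column")
  if (is.null(epcam_threshold)) {
    tile_px <- attr(tiles, "tile_px")
    if (is.null(tile_px)) stop("epcam_threshold required when tiles carry no tile_px")
    epcam_threshold <- epcam_od_floor * tile_px^2
  }
  epi <- tiles$EPCAM > epcam_threshold
  markers <- names(profiles[[1]])
  stromal <- tiles[!epi, , drop = FALSE]
  label <- rep("epithelium", nrow(tiles))
  if (nrow(stromal) > 0) {
    if (is.null(thresholds)) {
      thresholds <- transpose_thresholds(stromal, markers = markers,
                                         marker_map = c())
    }
    calls <- classify_cells(stromal, thresholds, profiles)
    label[!epi] <- calls$label
  }
  tiles$label <- label
  dims <- attr(tiles, "dims")
  if (!is.null(dims)) {
    lm <- matrix(NA_character_, dims[1], dims[2])
    lm[cbind(tiles$row, tiles$col)] <- label
    attr(tiles, "label_matrix") <- lm
  }
  tiles
}

#' Render a labeled tile grid as an RGB map
#'
#' One square pixel block per tile, fixed palette: CAF-S1 red, CAF-S2
#' orange, CAF-S3 green, CAF-S4 blue, epithelium black.
#'
#' @param labels Character matrix of tile labels (or a [classify_tiles()]
#'   result carrying a `label_matrix` attribute).
#' @param tile_px Pixels per tile side in the rendered image.
#' @param palette Named colours, see [caf_palette()].
#' @return H x W x 3 array in `[0, 1]`.
#' @export
render_map <- function(labels, tile_px = 1, palette = caf_palette()) {
  if (is.data.frame(labels)) labels <- attr(labels, "label_matrix")
  stopifnot(is.matrix(labels))
  unknown <- setdiff(unique(as.vector(labels)), names(palette))
  if (length(unknown)) stop("labels without palette entry: ",
                            paste(unknown, collapse = ", "))
  rgb <- grDevices::col2rgb(palette[as.vector(labels)]) / 255
  h <- nrow(labels) * tile_px; w <- ncol(labels) * tile_px
  out <- array(0, c(h, w, 3))
  ri <- rep(seq_len(nrow(labels)), each = tile_px)
  ci <- rep(seq_len(ncol(labels)), each = tile_px)
  for (ch in 1:3) {
    plane <- matrix(rgb[ch, ], nrow(labels), ncol(labels))
    out[, , ch] <- plane[ri, ci, drop = FALSE]
  }
  out
}

#' Decode a rendered map back to tile labels
#'
#' Inverse of [render_map()] for `tile_px = 1` blocks: exact palette lookup.
#'
#' @param img H x W x 3 array produced by [render_map()].
#' @param tile_px Pixels per tile in `img`.
#' @inheritParams render_map
#' @return Character label matrix.
#' @export
decode_map <- function(img, tile_px = 1, palette = caf_palette()) {
  pal_rgb <- grDevices::col2rgb(palette) / 255
  n_r <- dim(img)[1] %/% tile_px; n_c <- dim(img)[2] %/% tile_px
  rows <- (seq_len(n_r) - 1) * tile_px + 1
  cols <- (seq_len(n_c) - 1) * tile_px + 1
  px <- rbind(R = as.vector(img[rows, cols, 1]),
              G = as.vector(img[rows, cols, 2]),
              B = as.vector(img[rows, cols, 3]))
  idx <- apply(px, 2, function(v) which.min(colSums((pal_rgb - v)^2)))
  if (any(colSums((pal_rgb[, idx, drop = FALSE] - px)^2) > 1e-4)) {
    stop("image contains colours outside the palette")
  }
  matrix(names(palette)[idx], n_r, n_c)
}

#' End-to-end section mapping
#'
#' Registers each marker section to the reference frame with its landmarks,
#' colour-deconvolves the registered images, integrates DAB density per
#' 225 um^2 tile and classifies the tiles, returning the labeled grid and a
#' rendered map.
#'
#' @param sections As returned by [simulate_tissue_sections()]: named lists
#'   `images` and `landmarks`, plus `px_per_um` and `tile_um`.
#' @param model Registration model, `"affine"` or `"tps"`.
#' @param render_px Pixels per tile in the rendered map.
#' @return List: `tiles` (labeled density data frame), `labels` (matrix),
#'   `map` (RGB array), `registration` (per-marker transform fits).
#' @export
map_section <- function(sections, model = "affine", render_px = 15) {
  fits <- lapply(sections$landmarks, fit_landmark_transform, model = model)
  od <- lapply(names(sections$images), function(m) {
    reg <- warp_image(sections$images[[m]], fits[[m]],
                      dims_out = dim(sections$images[[m]])[1:2])
    color_deconvolve(reg)$dab
  })
  names(od) <- names(sections$images)
  tiles <- tile_densitometry(od, tile_um = sections$tile_um,
                             px_per_um = sections$px_per_um)
  tiles <- classify_tiles(tiles)
  labels <- attr(tiles, "label_matrix")
  list(tiles = tiles, labels = labels,
       map = render_map(labels, tile_px = render_px), registration = fits)
}
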