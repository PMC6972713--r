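#' Regular-grid 2D vector field
#'
#' Container for displacement (um) or traction (Pa) fields on a regular grid
#' over an elastic substrate, as used by traction-force microscopy.
#'
#' @param vx,vy Numeric matrices, x/y components (equal dimensions).
#' @param spacing Grid spacing in um (> 0).
#' @param E Substrate Young's modulus in Pa; the hydrogels emulated here are
#'   25 kPa.
#' @param nu Poisson ratio in `[0, 0.5]`; 0.5 (incompressible) is the usual
#'   TFM convention.
#' @param mask Optional logical matrix marking the cell footprint.
#' @param unit `"um"` for displacements, `"Pa"` for tractions.
#' @return List of class `vector_field`.
#' @export
vector_field <- function(vx, vy, spacing, E = 25000, nu = 0.5, mask = NULL,
                         unit = c("um", "Pa")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(vx), is.matrix(vy), all(dim(vx) == dim(vy)))
  if (spacing <= 0) stop("grid spacing must be > 0")
  if (nu < 0 || nu > 0.5) stop("Poisson ratio must lie in [0, 0.5]")
  if (!is.finite(E) || E <= 0) stop("Young's modulus must be positive")
  if (!is.null(mask)) stopifnot(is.logical(mask), all(dim(mask) == dim(vx)))
  structure(list(vx = vx, vy = vy, spacing = spacing, E = E, nu = nu,
                 mask = mask, unit = unit), class = "vector_field")
}

# Fourier-space Boussinesq Green tensor components for a semi-infinite
# elastic substrate, evaluated on the FFT frequency grid. Returns a, b, c of
# the symmetric 2x2 tensor [[a, b], [b, c]]; the singular k = 0 mode is left
# as zero (zero-net-force convention).
green_tensor <- function(nrow, ncol, spacing, E, nu) {
  fx <- c(0:floor((ncol - 1) / 2), -(ceiling((ncol - 1) / 2):1)) / (ncol * spacing)
  fy <- c(0:floor((nrow - 1) / 2), -(ceiling((nrow - 1) / 2):1)) / (nrow * spacing)
  kx <- matrix(2 * pi * fx, nrow, ncol, byrow = TRUE)
  ky <- matrix(2 * pi * fy, nrow, ncol)
  k2 <- kx^2 + ky^2
  k <- sqrt(k2)
  pref <- 2 * (1 + nu) / (E * k^3)
  pref[1, 1] <- 0  # DC mode
  list(a = pref * ((1 - nu) * k2 + nu * ky^2),
       b = pref * (-nu * kx * ky),
       c = pref * ((1 - nu) * k2 + nu * kx^2))
}

#' Forward elastic half-space operator: traction to displacement
#'
#' Computes the substrate surface displacement produced by a tangential
#' traction field, by Fourier-domain convolution with the Boussinesq Green
#' tensor for Young's modulus `E` and Poisson ratio `nu`. The k = 0 mode is
#' dropped, so the traction must be (and is made) net-force free by
#' subtracting its mean.
#'
#' @param traction A `vector_field` in Pa.
#' @return A `vector_field` of displacements in um (same grid and constants).
#' @export
tfm_forward <- function(traction) {
  stopifnot(inherits(traction, "vector_field"))
  tx <- traction$vx - mean(traction$vx)
  ty <- traction$vy - mean(traction$vy)
  G <- green_tensor(nrow(tx), ncol(tx), traction$spacing, traction$E, traction$nu)
  txh <- stats::fft(tx); tyh <- stats::fft(ty)
  uxh <- G$a * txh + G$b * tyh
  uyh <- G$b * txh + G$c * tyh
  n <- length(tx)
  vector_field(Re(stats::fft(uxh, inverse = TRUE)) / n,
               Re(stats::fft(uyh, inverse = TRUE)) / n,
               traction$spacing, traction$E, traction$nu, traction$mask, "um")
}

#' Fourier-transform traction cytometry inverse
#'
#' Recovers the tangential traction field from a measured substrate
#' displacement field by Tikhonov-regularized inversion of the Boussinesq
#' Green tensor in Fourier space: `T = (G'G + lambda^2 I)^-1 G' u` per wave
#' vector, with the k = 0 (net force) mode set to zero.
#'
#' @param displacement A `vector_field` in um, with `E` and `nu` set.
#' @param lambda Tikhonov regularization parameter (>= 0); 0 is the plain
#'   inverse, appropriate for noise-free fields.
#' @return A `vector_field` of tractions in Pa.
#' @examples
#' # round trip: see tfm_forward()
#' @export
fttc_inverse <- function(displacement, lambda = 0) {
  stopifnot(inherits(displacement, "vector_field"))
  if (lambda < 0) stop("lambda must be >= 0")
  ux <- displacement$vx; uy <- displacement$vy
  G <- green_tensor(nrow(ux), ncol(ux), displacement$spacing,
                    displacement$E, displacement$nu)
  uxh <- stats::fft(ux); uyh <- stats::fft(uy)
  # v = G u (G symmetric), then solve (G^2 + lambda^2 I) T = v
  vx <- G$a * uxh + G$b * uyh
  vy <- G$b * uxh + G$c * uyh
  m11 <- G$a^2 + G$b^2 + lambda^2
  m12 <- G$b * (G$a + G$c)
  m22 <- G$b^2 + G$c^2 + lambda^2
  det <- m11 * m22 - m12^2
  det[1, 1] <- Inf  # keep DC at zero
  det[det == 0] <- Inf
  txh <- (m22 * vx - m12 * vy) / det
  tyh <- (m11 * vy - m12 * vx) / det
  n <- length(ux)
  vector_field(Re(stats::fft(txh, inverse = TRUE)) / n,
               Re(stats::fft(tyh, inverse = TRUE)) / n,
               displacement$spacing, displacement$E, displacement$nu,
               displacement$mask, "Pa")
}

mask_or_all <- function(field) {
  if (is.null(field$mask)) array(TRUE, dim(field$vx)) else field$mask
}

#' Strain energy transferred to the substrate
#'
#' `SE = 1/2 * integral over the cell of T(r) . u(r) d2r`, discretized as
#' half the sum of the traction-displacement dot product over masked nodes
#' times the node area. With tractions in Pa, displacements in um and node
#' areas in um^2 the sum is in Pa um^3 = 1e-18 J; the value is returned in
#' Joules.
#'
#' @param traction,displacement Paired `vector_field`s on the same grid.
#' @return Strain energy in J.
#' @examples
#' # single node at T = (100, 0) Pa, u = (0.1, 0) um, 1 um^2 -> 5e-18 J
#' @export
strain_energy <- function(traction, displacement) {
  stopifnot(inherits(traction, "vector_field"),
            inherits(displacement, "vector_field"))
  if (!all(dim(traction$vx) == dim(displacement$vx)) ||
      traction$spacing != displacement$spacing) {
    stop("traction and displacement grids do not match")
  }
  m <- mask_or_all(traction)
  dot <- traction$vx * displacement$vx + traction$vy * displacement$vy
  0.5 * sum(dot[m]) * traction$spacing^2 * 1e-18
}

#' Strain energy density
#'
#' Strain energy per unit cell area (J/m^2).
#'
#' @param se Strain energy in J.
#' @param cell_area Cell area in m^2 (> 0).
#' @export
strain_energy_density <- function(se, cell_area) {
  if (any(cell_area <= 0)) stop("cell_area must be positive")
  se / cell_area
}

#' Mean traction stress amplitude
#'
#' Average magnitude |T| over the masked (cell) nodes, in Pa.
#'
#' @param traction A `vector_field` in Pa.
#' @export
mean_traction <- function(traction) {
  stopifnot(inherits(traction, "vector_field"))
  m <- mask_or_all(traction)
  mean(sqrt(traction$vx[m]^2 + traction$vy[m]^2))
}
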