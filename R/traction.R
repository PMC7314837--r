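# Fourier-transform traction microscopy on an elastic half-space.
#
# For each Fourier mode k of the surface fields, the tangential surface
# displacement u and traction T are related by the Boussinesq solution
#   u(k) = G(k) T(k),
#   G(k) = 2(1+nu) / (E k^3) * [ (1-nu) k^2 + nu ky^2,  -nu kx ky
#                                -nu kx ky,  (1-nu) k^2 + nu kx^2 ]
# which stays finite for nu = 0.5. The zero mode is indeterminate (rigid
# translation) and is set to zero in both directions.

fttc_kernel <- function(nx, ny, spacing, sub) {
  E <- sub$youngs_modulus_E; nu <- sub$poisson_ratio
  kx <- 2 * pi * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / (nx * spacing)
  ky <- 2 * pi * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / (ny * spacing)
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  KY <- matrix(ky, ny, nx)
  K <- sqrt(KX^2 + KY^2)
  K[1, 1] <- 1  # avoid 0/0; the zero mode is zeroed downstream
  pref <- 2 * (1 + nu) / (E * K^3)
  Gxy <- pref * (-nu * KX * KY)
  # the unpaired Nyquist frequency has no conjugate partner; the odd shear
  # coupling is zeroed there so real fields map to real fields exactly
  if (nx %% 2 == 0) Gxy[, nx %/% 2 + 1] <- 0
  if (ny %% 2 == 0) Gxy[ny %/% 2 + 1, ] <- 0
  list(Gxx = pref * ((1 - nu) * K^2 + nu * KY^2),
       Gyy = pref * ((1 - nu) * K^2 + nu * KX^2),
       Gxy = Gxy)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) Re(stats::fft(m, inverse = TRUE)) / length(m)

# pad may be FALSE (none), TRUE (factor 2), or an integer factor >= 1
pad_factor <- function(pad) {
  if (isFALSE(pad)) 1L else if (isTRUE(pad)) 2L else as.integer(pad)
}

pad_field <- function(m, pad) {
  k <- pad_factor(pad)
  if (k <= 1L) return(m)
  out <- matrix(0, k * nrow(m), k * ncol(m))
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

crop_field <- function(m, ny, nx, pad) {
  if (pad_factor(pad) <= 1L) m else m[seq_len(ny), seq_len(nx)]
}

taper_window <- function(ny, nx, frac = 0.1) {
  ramp <- function(n) {
    w <- rep(1, n)
    m <- max(2L, round(frac * n))
    t <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / (m - 1)))
    w[seq_len(m)] <- t
    w[n + 1 - seq_len(m)] <- t
    w
  }
  outer(ramp(ny), ramp(nx))
}

#' Forward half-space operator: traction to substrate surface displacement
#'
#' Multiplies the traction field by the Boussinesq half-space kernel in
#' Fourier space. The zero-frequency mode (rigid translation) is set to
#' zero.
#'
#' @param traction A complete (no missing values) `gridded_field` of
#'   tractions in Pa.
#' @param sub A [substrate()].
#' @param pad Zero-padding before the FFT to suppress wrap-around: `FALSE`
#'   (none, the default — synthetic islands already carry a zero margin),
#'   `TRUE` (double the grid), or an integer padding factor.
#' @param window Apply a cosine-taper border window first (default
#'   `FALSE`).
#' @return A `gridded_field` of displacements in µm, with metadata
#'   attributes recording the kernel options.
#' @export
fttc_forward <- function(traction, sub, pad = FALSE, window = FALSE) {
  fttc_apply(traction, sub, pad, window, inverse = FALSE, lambda = 0)
}

#' Inverse half-space operator: substrate displacement to traction
#'
#' Inverts the Boussinesq kernel mode by mode. With `lambda > 0` the
#' per-mode solve is Tikhonov-regularized,
#' \eqn{T = (G^T G + \lambda^2 I)^{-1} G^T u}, damping noise-dominated high
#' frequencies; with `lambda = 0` the inverse is exact and
#' `fttc_inverse(fttc_forward(T))` reproduces `T` on the same grid to
#' machine precision.
#'
#' @param displacement A complete `gridded_field` of displacements in µm.
#' @param sub A [substrate()].
#' @param lambda Tikhonov regularization parameter (µm/Pa units of the
#'   kernel; 0 disables regularization).
#' @inheritParams fttc_forward
#' @return A `gridded_field` of tractions in Pa.
#' @export
fttc_inverse <- function(displacement, sub, lambda = 0, pad = FALSE,
                         window = FALSE) {
  if (lambda < 0) stop("lambda must be non-negative")
  fttc_apply(displacement, sub, pad, window, inverse = TRUE, lambda = lambda)
}

fttc_apply <- function(field, sub, pad, window, inverse, lambda) {
  if (anyNA(field$u) || anyNA(field$v))
    stop("field has missing values; inpaint before the Fourier operator")
  ny <- nrow(field$u); nx <- ncol(field$u)
  u <- field$u; v <- field$v
  if (window) {
    w <- taper_window(ny, nx)
    u <- u * w; v <- v * w
  }
  up <- pad_field(u, pad); vp <- pad_field(v, pad)
  G <- fttc_kernel(ncol(up), nrow(up), field$spacing, sub)
  U <- fft2(up); V <- fft2(vp)
  if (!inverse) {
    X <- G$Gxx * U + G$Gxy * V
    Y <- G$Gxy * U + G$Gyy * V
  } else {
    if (lambda == 0) {
      det <- G$Gxx * G$Gyy - G$Gxy^2
      X <- (G$Gyy * U - G$Gxy * V) / det
      Y <- (-G$Gxy * U + G$Gxx * V) / det
    } else {
      # (G'G + lambda^2 I)^{-1} G' u for the symmetric 2x2 kernel
      A11 <- G$Gxx^2 + G$Gxy^2 + lambda^2
      A22 <- G$Gyy^2 + G$Gxy^2 + lambda^2
      A12 <- G$Gxy * (G$Gxx + G$Gyy)
      b1 <- G$Gxx * U + G$Gxy * V
      b2 <- G$Gxy * U + G$Gyy * V
      det <- A11 * A22 - A12^2
      X <- (A22 * b1 - A12 * b2) / det
      Y <- (-A12 * b1 + A11 * b2) / det
    }
  }
  X[1, 1] <- 0; Y[1, 1] <- 0
  out_u <- crop_field(ifft2(X), ny, nx, pad)
  out_v <- crop_field(ifft2(Y), ny, nx, pad)
  out <- gridded_field(out_u, out_v, field$spacing,
                       units = if (inverse) "Pa" else "um",
                       x = field$x, y = field$y)
  attr(out, "fttc") <- list(E = sub$youngs_modulus_E,
                            nu = sub$poisson_ratio,
                            half_space = TRUE, pad = pad, window = window,
                            lambda = if (inverse) lambda else NA_real_)
  out
}

#' Enforce force and moment equilibrium of a traction field
#'
#' An island in mechanical equilibrium must carry zero net force and zero
#' net moment; measurement noise leaves small residuals. This applies the
#' minimal least-squares correction supported on the mask — a combination of
#' the two uniform translations and the unit solid-rotation field about the
#' island centroid — that zeroes both components of the net force and the
#' net moment exactly.
#'
#' @param traction A `gridded_field` of tractions (Pa).
#' @param domain The [island_domain()]; the correction acts only on mask
#'   nodes and the moment is taken about the mask centroid.
#' @return The corrected `gridded_field`, with attribute `"equilibrium"`
#'   listing the pre/post net force and moment and the RMS magnitude of the
#'   applied correction.
#' @export
enforce_equilibrium <- function(traction, domain) {
  mask <- domain$mask
  if (!any(mask)) stop("mask is empty")
  if (!all(dim(traction$u) == dim(mask)))
    stop("traction field and mask are on different grids")
  X <- domain$X[mask]; Y <- domain$Y[mask]
  xc <- mean(X); yc <- mean(Y)
  tx <- traction$u[mask]; ty <- traction$v[mask]
  Fx <- sum(tx); Fy <- sum(ty)
  M <- sum((X - xc) * ty - (Y - yc) * tx)
  n <- length(tx)
  r2 <- sum((X - xc)^2 + (Y - yc)^2)
  # minimal-norm correction: translations + solid rotation about centroid
  a <- Fx / n; b <- Fy / n; cc <- M / r2
  u <- traction$u; v <- traction$v
  u[mask] <- tx - a + cc * (Y - yc)
  v[mask] <- ty - b - cc * (X - xc)
  out <- gridded_field(u, v, traction$spacing, units = traction$units,
                       x = traction$x, y = traction$y)
  corr_rms <- sqrt(mean((a - cc * (Y - yc))^2 + (b + cc * (X - xc))^2))
  attr(out, "equilibrium") <- list(
    force_before = c(Fx, Fy), moment_before = M,
    force_after = c(sum(u[mask]), sum(v[mask])),
    moment_after = sum((X - xc) * v[mask] - (Y - yc) * u[mask]),
    correction_rms = corr_rms)
  out
}

# Net force (sum of vectors) and net moment about the mask centroid.
net_force_moment <- function(traction, domain) {
  mask <- domain$mask
  X <- domain$X[mask]; Y <- domain$Y[mask]
  xc <- mean(X); yc <- mean(Y)
  tx <- traction$u[mask]; ty <- traction$v[mask]
  list(force = c(sum(tx), sum(ty)),
       moment = sum((X - xc) * ty - (Y - yc) * tx))
}
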