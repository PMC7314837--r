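#' Smooth random velocity field on an island
#'
#' Low-pass-filtered Gaussian white noise, tapered smoothly to zero toward
#' the island edge so that all derived quantities (strain rate, stress,
#' traction) vanish before the mask boundary. The field is renormalized so
#' that the RMS vector magnitude over the island equals `amplitude`.
#'
#' @param domain An [island_domain()].
#' @param amplitude Target RMS speed inside the mask (µm/min). Zero gives
#'   the zero field.
#' @param correlation_length Smoothing length in µm; must be at least two
#'   grid spacings.
#' @param seed Integer seed; the field is reproducible given the seed.
#' @param taper_fraction Fraction of the island radius over which the field
#'   ramps to zero at the edge (default 0.3).
#' @param edge_margin Pixels between the end of the taper and the mask
#'   boundary (default 3), so stress and traction vanish identically on a
#'   band inside the mask and finite-difference stencils never straddle it.
#' @return A `gridded_field` with units µm/min.
#' @export
sample_velocity_field <- function(domain, amplitude, correlation_length,
                                  seed = 1L, taper_fraction = 0.3,
                                  edge_margin = 3) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  px <- domain$pixel_size
  if (amplitude == 0) {
    z <- matrix(0, nrow(domain$mask), ncol(domain$mask))
    return(gridded_field(z, z, px, units = "um/min"))
  }
  if (correlation_length < 2 * px)
    stop("correlation_length must be at least 2 grid spacings")
  ny <- nrow(domain$mask); nx <- ncol(domain$mask)
  set.seed(seed)
  u <- gaussian_smooth(matrix(stats::rnorm(ny * nx), ny, nx),
                       correlation_length / px)
  v <- gaussian_smooth(matrix(stats::rnorm(ny * nx), ny, nx),
                       correlation_length / px)
  rr <- domain_radius(domain)
  r_out <- domain$radius - edge_margin * px
  w <- cos_taper(rr$r, r_out - taper_fraction * domain$radius, r_out)
  w[!domain$mask] <- 0
  u <- u * w; v <- v * w
  rms <- sqrt(mean((u^2 + v^2)[domain$mask]))
  if (rms > 0) { u <- u * amplitude / rms; v <- v * amplitude / rms }
  gridded_field(u, v, px, units = "um/min")
}

# Periodic Gaussian low-pass filter, sigma in pixels.
gaussian_smooth <- function(m, sigma) {
  ny <- nrow(m); nx <- ncol(m)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  gy <- exp(-2 * (pi * sigma * fy)^2)
  gx <- exp(-2 * (pi * sigma * fx)^2)
  Re(stats::fft(stats::fft(m) * outer(gy, gx), inverse = TRUE)) / (ny * nx)
}

#' Strain-rate tensor of a gridded velocity field
#'
#' Centered finite differences in the interior, one-sided at the borders.
#' The shear component is stored once (the tensor is symmetric by
#' construction).
#'
#' @param velocity A `gridded_field` of velocities (µm/min).
#' @return A `strain_rate_field` with components `exx`, `eyy`, `exy`
#'   (1/min).
#' @export
strainrate_from_velocity <- function(velocity) {
  h <- velocity$spacing
  structure(list(exx = ddx(velocity$u, h),
                 eyy = ddy(velocity$v, h),
                 exy = 0.5 * (ddy(velocity$u, h) + ddx(velocity$v, h)),
                 spacing = h, x = velocity$x, y = velocity$y),
            class = "strain_rate_field")
}

#' Stress from strain rate (homogeneous viscous fluid)
#'
#' Pointwise constitutive law
#' \deqn{\sigma_{ij} = (K_1 - \tfrac{2}{3}K_2)\,\dot\varepsilon_{kk}
#'   \,\delta_{ij} + 2K_2\,\dot\varepsilon_{ij}}
#' with the two-dimensional trace
#' \eqn{\dot\varepsilon_{kk} = \dot\varepsilon_{xx} +
#' \dot\varepsilon_{yy}} (plane-stress reading).
#'
#' @param strain_rate A `strain_rate_field`.
#' @param mono A [monolayer()] supplying `K1`, `K2`.
#' @return A [stress_field()].
#' @export
stress_from_strainrate <- function(strain_rate, mono) {
  e <- strain_rate
  if (!all(dim(e$exx) == dim(e$eyy)) || !all(dim(e$exx) == dim(e$exy)))
    stop("strain-rate components must share one grid")
  lam <- mono$K1 - 2 * mono$K2 / 3
  tr <- e$exx + e$eyy
  stress_field(sxx = lam * tr + 2 * mono$K2 * e$exx,
               syy = lam * tr + 2 * mono$K2 * e$eyy,
               sxy = 2 * mono$K2 * e$exy,
               spacing = e$spacing, x = e$x, y = e$y)
}

#' Traction implied by a monolayer stress field
#'
#' In-plane force balance of the sheet: the traction the cells exert on the
#' substrate is \eqn{T = h\,\nabla\cdot\sigma}. With this convention an
#' island under tension (positive stress decaying to zero at the edge) pulls
#' radially inward on the substrate at its edge, the behavior observed for
#' contractile monolayers. Divergence by centered finite differences;
#' the result is forced to zero outside the mask.
#'
#' @param stress A [stress_field()] covering the domain grid, tapered to
#'   zero at the island edge.
#' @param mono A [monolayer()] (supplies the height `h`).
#' @param domain The [island_domain()].
#' @return A `gridded_field` of tractions in Pa (σ in Pa, h and grid in µm).
#' @export
traction_from_stress <- function(stress, mono, domain) {
  if (!all(dim(stress$sxx) == dim(domain$mask)))
    stop("stress field does not cover the domain grid")
  h <- mono$height_h; d <- stress$spacing
  tx <- h * (ddx(stress$sxx, d) + ddy(stress$sxy, d))
  ty <- h * (ddx(stress$sxy, d) + ddy(stress$syy, d))
  tx[!domain$mask] <- 0
  ty[!domain$mask] <- 0
  gridded_field(tx, ty, d, units = "Pa", x = stress$x, y = stress$y)
}

#' Render a speckle-image pair from a displacement field
#'
#' Emulates the fluorescent-particle channel: the first image is a random
#' set of Gaussian spots, the second shows the same spots displaced by the
#' (bilinearly interpolated) displacement field evaluated at each particle.
#' Spots are rendered analytically, so the pair carries no resampling
#' artifacts.
#'
#' @param displacement A `gridded_field` of displacements in µm on the image
#'   grid.
#' @param density Particles per pixel² (default 0.03).
#' @param spot_sigma Gaussian spot width in pixels (default 1.2).
#' @param seed Integer seed for particle positions and brightness.
#' @param pixel_size µm per image pixel; defaults to the field spacing.
#' @return List of two `speckle_image` objects (`reference`, `deformed`),
#'   each a non-negative intensity matrix with attributes.
#' @export
render_speckle_pair <- function(displacement, density = 0.03,
                                spot_sigma = 1.2, seed = 1L,
                                pixel_size = displacement$spacing) {
  ny <- nrow(displacement$u); nx <- ncol(displacement$u)
  npart <- round(density * nx * ny)
  if (npart < 20)
    warning("particle density very low; correlation subsets may be empty")
  set.seed(seed)
  px <- stats::runif(npart, 0, nx - 1)
  py <- stats::runif(npart, 0, ny - 1)
  amp <- stats::runif(npart, 0.5, 1)
  # displacement (µm) at each particle, converted to image pixels
  ux <- bilinear(displacement$u, displacement$x, displacement$y,
                 px * pixel_size, py * pixel_size) / pixel_size
  uy <- bilinear(displacement$v, displacement$x, displacement$y,
                 px * pixel_size, py * pixel_size) / pixel_size
  maxdisp <- max(sqrt(ux^2 + uy^2))
  if (maxdisp > min(nx, ny) / 4)
    stop("displacement magnitudes must be small compared to the image size")
  img1 <- render_spots(nx, ny, px, py, amp, spot_sigma)
  img2 <- render_spots(nx, ny, px + ux, py + uy, amp, spot_sigma)
  mk <- function(img) structure(img, class = "speckle_image",
                                pixel_size = pixel_size,
                                density = density, spot_sigma = spot_sigma)
  list(reference = mk(img1), deformed = mk(img2))
}

render_spots <- function(nx, ny, px, py, amp, sigma) {
  img <- matrix(0, ny, nx)
  w <- ceiling(4 * sigma)
  for (k in seq_along(px)) {
    j0 <- max(1, floor(px[k]) - w + 1); j1 <- min(nx, floor(px[k]) + w + 1)
    i0 <- max(1, floor(py[k]) - w + 1); i1 <- min(ny, floor(py[k]) + w + 1)
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-((j0:j1 - 1 - px[k])^2) / (2 * sigma^2))
    gy <- exp(-((i0:i1 - 1 - py[k])^2) / (2 * sigma^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp[k] * outer(gy, gx)
  }
  img
}

#' Generate a fully ground-truthed synthetic island
#'
#' Runs the forward model end to end: a velocity field on the island, its
#' strain rate, the monolayer stress via the constitutive law, the traction
#' via the force balance, and (optionally) the substrate surface
#' displacement via the half-space forward operator. Every inverse stage of
#' the pipeline can be checked against the returned ground truth.
#'
#' Two flow modes are provided. `"random"` derives the stress from a smooth
#' random velocity field through the passive constitutive law; such a
#' stress is exactly compatible, which makes it the reference input for the
#' stress-recovery checks. `"contractile"` emulates a contractile island:
#' cells drift slowly inward (the returned velocity field) while the
#' actomyosin machinery maintains an active, radially decaying isotropic
#' tension \eqn{p(r) = \sigma_0 \tfrac12 (1 + \cos(\pi r / R_e))} that is
#' prescribed directly rather than derived from the flow (active stress is
#' set by contractility, not by the slow passive flow; note that any stress
#' derived from a velocity field vanishing at the edge would integrate to
#' zero mean tension). The implied tractions point radially inward at the
#' edge and the tension is positive, the signature of real islands.
#'
#' @param domain An [island_domain()].
#' @param mono A [monolayer()].
#' @param flow `"random"` or `"contractile"`.
#' @param amplitude RMS speed (random mode) or peak inward drift speed
#'   (contractile mode), µm/min.
#' @param correlation_length Smoothing length (µm) for the random mode.
#' @param seed Integer seed.
#' @param tension Peak active tension \eqn{\sigma_0} in Pa for the
#'   contractile mode (default 200, a typical monolayer value).
#' @param substrate Optional [substrate()]; if given, the substrate surface
#'   displacement under the traction is included.
#' @return List with `domain`, `mono`, `velocity`, `strain_rate`, `stress`,
#'   `traction`, and `displacement` (NULL unless a substrate is given).
#' @export
synthesize_island <- function(domain, mono = monolayer(),
                              flow = c("random", "contractile"),
                              amplitude = 0.2, correlation_length = 60,
                              seed = 1L, tension = 200, substrate = NULL) {
  flow <- match.arg(flow)
  if (flow == "random") {
    vel <- sample_velocity_field(domain, amplitude, correlation_length, seed)
    sr <- strainrate_from_velocity(vel)
    stress <- stress_from_strainrate(sr, mono)
  } else {
    rr <- domain_radius(domain)
    R <- domain$radius
    r_out <- R - 3 * domain$pixel_size
    # slow inward collapse: v_r = -a * (r/R) * taper, zero before the edge
    prof <- (rr$r / R) * cos_taper(rr$r, 0.6 * R, r_out)
    prof[!domain$mask] <- 0
    vel <- gridded_field(-amplitude * prof * rr$rhat_x,
                         -amplitude * prof * rr$rhat_y,
                         domain$pixel_size, units = "um/min")
    sr <- strainrate_from_velocity(vel)
    # active isotropic tension, smooth and zero on a band inside the edge
    p <- tension * cos_taper(rr$r, 0, r_out)
    p[!domain$mask] <- 0
    z <- matrix(0, nrow(p), ncol(p))
    stress <- stress_field(p, p, z, spacing = domain$pixel_size)
  }
  traction <- traction_from_stress(stress, mono, domain)
  disp <- if (!is.null(substrate)) fttc_forward(traction, substrate) else NULL
  list(domain = domain, mono = mono, velocity = vel, strain_rate = sr,
       stress = stress, traction = traction, displacement = disp,
       flow = flow, seed = seed)
}
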