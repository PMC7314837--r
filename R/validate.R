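# Technical-validation metrics: reusable quantitative checks applied to a
# processed island. Tractions should localize to the cell-covered region,
# point radially inward at the island edge, and the contractile tension of
# a treated island should be compared on the scale of its pre-treatment
# mean.

#' Ratio of RMS traction outside vs. inside the island
#'
#' Regions with no cells should carry no traction; the ratio of the
#' root-mean-square traction magnitude outside the island to that inside
#' quantifies systematic error and noise (0.03 is typical of good
#' experimental data; a noise-free forward model gives < 0.01). Nodes
#' within `margin` grid nodes of the boundary are excluded from both
#' regions to avoid edge bleed.
#'
#' @param traction A `gridded_field` of tractions on the domain grid.
#' @param domain An [island_domain()].
#' @param margin Boundary exclusion half-width in grid nodes (default 2).
#' @return Scalar `RMS(outside) / RMS(inside)`; scale-invariant in the
#'   traction magnitude.
#' @export
rms_traction_ratio <- function(traction, domain, margin = 2) {
  mask <- domain$mask
  if (!all(dim(traction$u) == dim(mask)))
    stop("traction and mask grids differ")
  grown <- shrunk <- mask
  for (k in seq_len(margin)) {
    grown <- dilate4(grown)
    shrunk <- !dilate4(!shrunk)
  }
  inside <- shrunk
  outside <- !grown
  if (!any(inside) || !any(outside))
    stop("margin leaves an empty inside or outside region")
  m2 <- traction$u^2 + traction$v^2
  sqrt(mean(m2[outside], na.rm = TRUE) / mean(m2[inside], na.rm = TRUE))
}

#' Mean radial traction near the island edge
#'
#' Average of the radial traction component over the outer 20% annulus of
#' the island. Cells at a free edge pull themselves toward the free space,
#' so a healthy contractile island gives a negative (inward) value.
#'
#' @param traction A `gridded_field` of tractions on the domain grid.
#' @param domain An [island_domain()].
#' @param annulus_fraction Fraction of the radius forming the edge annulus
#'   (default 0.2).
#' @return Scalar mean radial traction (Pa); negative = inward.
#' @export
edge_traction_sign <- function(traction, domain, annulus_fraction = 0.2) {
  rr <- domain_radius(domain)
  ann <- domain$mask & rr$r >= (1 - annulus_fraction) * domain$radius
  if (!any(ann)) return(0)
  tr <- traction$u * rr$rhat_x + traction$v * rr$rhat_y
  mean(tr[ann], na.rm = TRUE)
}

#' Normalize a contractile-tension time series by its pre-treatment mean
#'
#' Divides the series by the mean of all samples with `time <
#' treatment_time`, so the pre-treatment level reads 1 and post-treatment
#' values read as fold changes (e.g. an actomyosin inhibitor that removes
#' 80% of the tension plateaus near 0.2).
#'
#' @param series Data frame with columns `time` (min) and `tension` (Pa),
#'   or a numeric vector with a `time` attribute.
#' @param treatment_time Time of treatment (min); times are reported
#'   relative to it (0 = treatment).
#' @return A data frame of class `tension_series` with columns `time`
#'   (shifted so treatment is at 0), `tension`, and `normalized`.
#' @export
normalize_tension <- function(series, treatment_time = 0) {
  if (!is.data.frame(series))
    series <- data.frame(time = attr(series, "time") %||%
                           seq_along(series) - 1, tension = as.numeric(series))
  pre <- series$time < treatment_time
  if (!any(pre)) stop("no samples before the treatment time")
  base <- mean(series$tension[pre])
  out <- data.frame(time = series$time - treatment_time,
                    tension = series$tension,
                    normalized = series$tension / base)
  class(out) <- c("tension_series", class(out))
  out
}

#' Full validation report for a processed island
#'
#' Bundles the technical-validation metrics: traction localization ratio,
#' edge-traction direction, net force/moment residuals, and the
#' island-average contractile tension with its spatial smoothness (maximum
#' node-to-neighbor jump relative to the field range).
#'
#' @param traction A `gridded_field` of tractions on the domain grid.
#' @param stress A [stress_field()] from [solve_stress()].
#' @param domain The [island_domain()].
#' @return A list of class `island_report`.
#' @export
validate_island <- function(traction, stress, domain) {
  fm <- net_force_moment(traction, domain)
  tens <- contractile_tension(stress)
  rng <- diff(range(tens$field, na.rm = TRUE))
  jump <- max(pmax(abs(diff_na(tens$field, 1)), 0), na.rm = TRUE)
  structure(list(
    rms_traction_ratio = rms_traction_ratio(traction, domain),
    mean_edge_radial_traction = edge_traction_sign(traction, domain),
    net_force = fm$force, net_moment = fm$moment,
    mean_contractile_tension = tens$average,
    max_relative_tension_jump = if (rng > 0) jump / rng else 0),
    class = "island_report")
}

# max |neighbor difference| matrix helper (NA-safe)
diff_na <- function(m, lag) {
  d1 <- abs(m[-1, ] - m[-nrow(m), ])
  d2 <- abs(m[, -1] - m[, -ncol(m)])
  c(d1[!is.na(d1)], d2[!is.na(d2)])
}

#' @export
print.island_report <- function(x, ...) {
  cat("<island_report>\n")
  cat(sprintf("  RMS traction ratio (out/in):   %.4g\n", x$rms_traction_ratio))
  cat(sprintf("  mean edge radial traction:     %.4g Pa (negative = inward)\n",
              x$mean_edge_radial_traction))
  cat(sprintf("  net force: (%.3g, %.3g); net moment: %.3g\n",
              x$net_force[1], x$net_force[2], x$net_moment))
  cat(sprintf("  mean contractile tension:      %.4g Pa\n",
              x$mean_contractile_tension))
  cat(sprintf("  max relative tension jump:     %.4g\n",
              x$max_relative_tension_jump))
  invisible(x)
}
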