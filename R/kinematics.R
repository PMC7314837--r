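#' Radial and tangential components of a vector field about a center
#'
#' Decomposes a gridded field along the unit radial vector from the given
#' center (image convention: y down, so positive tangential is clockwise on
#' screen). At the center node the direction is undefined and both
#' components are set to 0.
#'
#' @param field A `gridded_field`.
#' @param center Length-2 `(x, y)` in µm; defaults to the grid center.
#' @return List of matrices `radial` and `tangential`;
#'   `radial^2 + tangential^2 = |v|^2`.
#' @export
radial_component <- function(field, center = NULL) {
  center <- center %||% c(mean(range(field$x)), mean(range(field$y)))
  cm <- coord_mats(field$x, field$y)
  dx <- cm$X - center[1]; dy <- cm$Y - center[2]
  r <- sqrt(dx^2 + dy^2)
  rx <- ifelse(r > 0, dx / r, 0)
  ry <- ifelse(r > 0, dy / r, 0)
  list(radial = field$u * rx + field$v * ry,
       tangential = -field$u * ry + field$v * rx)
}

#' Integrate velocity fields into cell trajectories
#'
#' Forward Euler with one step per frame: each trajectory point advances by
#' `dt` times the velocity of its current frame, bilinearly interpolated at
#' the current position. The 10-minute sampling of the experiments does not
#' support sub-frame information, so no higher-order scheme is used; between
#' frames the velocity is piecewise constant in time.
#'
#' @param velocity_sequence List of `gridded_field`s (µm/min) on one grid.
#' @param seeds Two-column matrix of seed positions `(x, y)` in µm;
#'   defaults to every 4th grid node inside `mask` (or the whole grid).
#' @param dt Frame interval in minutes (default 10).
#' @param mask Optional logical matrix on the velocity grid; trajectories
#'   leaving it (or the grid) are truncated and flagged.
#' @return A data frame (class `trajectory_set`) with columns
#'   `trajectory_id`, `t`, `x`, `y`, plus a logical `truncated` attribute
#'   per trajectory.
#' @export
compute_trajectories <- function(velocity_sequence, seeds = NULL, dt = 10,
                                 mask = NULL) {
  if (!length(velocity_sequence)) stop("empty velocity sequence")
  g <- velocity_sequence[[1]]
  if (is.null(seeds)) {
    ix <- seq(1, length(g$x), by = 4); iy <- seq(1, length(g$y), by = 4)
    cm <- coord_mats(g$x[ix], g$y[iy])
    keep <- if (is.null(mask)) rep(TRUE, length(cm$X))
            else c(mask[iy, ix, drop = FALSE])
    seeds <- cbind(c(cm$X)[keep], c(cm$Y)[keep])
  }
  seeds <- matrix(seeds, ncol = 2)
  inside <- seeds[, 1] >= min(g$x) & seeds[, 1] <= max(g$x) &
    seeds[, 2] >= min(g$y) & seeds[, 2] <= max(g$y)
  if (any(!inside)) {
    warning(sprintf("skipping %d seed(s) outside the grid", sum(!inside)))
    seeds <- seeds[inside, , drop = FALSE]
  }
  ns <- nrow(seeds); nf <- length(velocity_sequence)
  X <- matrix(NA_real_, nf + 1, ns); Y <- matrix(NA_real_, nf + 1, ns)
  X[1, ] <- seeds[, 1]; Y[1, ] <- seeds[, 2]
  alive <- rep(TRUE, ns)
  truncated <- rep(FALSE, ns)
  for (k in seq_len(nf)) {
    fld <- velocity_sequence[[k]]
    xs <- X[k, alive]; ys <- Y[k, alive]
    if (!length(xs)) break
    vx <- bilinear(fld$u, fld$x, fld$y, xs, ys)
    vy <- bilinear(fld$v, fld$x, fld$y, xs, ys)
    nx <- xs + dt * vx; nyy <- ys + dt * vy
    ok <- nx >= min(fld$x) & nx <= max(fld$x) &
      nyy >= min(fld$y) & nyy <= max(fld$y)
    if (!is.null(mask)) {
      gi <- pmin(pmax(round(nyy / g$spacing) + 1, 1), nrow(mask))
      gj <- pmin(pmax(round(nx / g$spacing) + 1, 1), ncol(mask))
      ok <- ok & mask[cbind(gi, gj)]
    }
    ids <- which(alive)
    X[k + 1, ids[ok]] <- nx[ok]; Y[k + 1, ids[ok]] <- nyy[ok]
    truncated[ids[!ok]] <- TRUE
    alive[ids[!ok]] <- FALSE
  }
  out <- do.call(rbind, lapply(seq_len(ns), function(s) {
    keep <- !is.na(X[, s])
    data.frame(trajectory_id = s, t = (which(keep) - 1) * dt,
               x = X[keep, s], y = Y[keep, s])
  }))
  attr(out, "truncated") <- truncated
  class(out) <- c("trajectory_set", class(out))
  out
}
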