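# Monolayer stress microscopy: recover the in-plane stress tensor of the
# cell sheet from the measured tractions.
#
# The force balance of the sheet gives two equations for the three stress
# components; compatibility closed with a linear constitutive law supplies
# the third. The system is solved with bilinear quadrilateral plane-stress
# finite elements on the island mask. Because stresses are obtained by
# applying K^-1 and then K, the stiffness scale (K1, K2 magnitude) cancels;
# only the Poisson-like ratio nu_m enters, and its influence is modest.

#' Build a quadrilateral finite-element mesh on the island mask
#'
#' One square bilinear element per retained grid cell; element corners live
#' on the dual (corner) lattice. A disconnected mask is reduced to its
#' largest 4-connected component with a warning.
#'
#' @param domain An [island_domain()] whose grid matches the traction grid.
#' @param spacing Element size in µm; defaults to the domain pixel size.
#'   When larger, the mask is subsampled at element centers.
#' @return An object of class `fe_mesh`: element table, node coordinates,
#'   and the element-center grid indices.
#' @export
build_mesh <- function(domain, spacing = domain$pixel_size) {
  step <- max(1L, round(spacing / domain$pixel_size))
  mask <- domain$mask
  if (step > 1L)
    mask <- mask[seq(1L, nrow(mask), by = step),
                 seq(1L, ncol(mask), by = step), drop = FALSE]
  if (!any(mask)) stop("mask is empty")
  comp <- largest_component(mask)
  if (sum(comp) < sum(mask))
    warning(sprintf("mask is disconnected; keeping largest component (%d of %d cells)",
                    sum(comp), sum(mask)))
  mask <- comp
  h <- domain$pixel_size * step
  ny <- nrow(mask); nx <- ncol(mask)
  cell <- which(mask, arr.ind = TRUE)  # element (i, j): row = y, col = x
  # corner lattice (ny+1) x (nx+1); element (i,j) has corners
  # (i,j), (i,j+1), (i+1,j+1), (i+1,j)  [counter-clockwise in x-right/y-down]
  cid <- function(i, j) (j - 1L) * (ny + 1L) + i
  c1 <- cid(cell[, 1], cell[, 2])
  c2 <- cid(cell[, 1], cell[, 2] + 1L)
  c3 <- cid(cell[, 1] + 1L, cell[, 2] + 1L)
  c4 <- cid(cell[, 1] + 1L, cell[, 2])
  corner_ids <- sort(unique(c(c1, c2, c3, c4)))
  remap <- integer((ny + 1L) * (nx + 1L))
  remap[corner_ids] <- seq_along(corner_ids)
  conn <- cbind(remap[c1], remap[c2], remap[c3], remap[c4])
  ci <- (corner_ids - 1L) %% (ny + 1L) + 1L
  cj <- (corner_ids - 1L) %/% (ny + 1L) + 1L
  # corner (i, j) sits at pixel-center (i-1, j-1) minus half a cell
  nodes <- cbind(x = (cj - 1.5) * h, y = (ci - 1.5) * h)
  structure(list(conn = conn, nodes = nodes, h = h, mask = mask,
                 cell = cell, ny = ny, nx = nx,
                 center_x = (cell[, 2] - 1) * h,
                 center_y = (cell[, 1] - 1) * h),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d bilinear quad elements, %d nodes, element size %.3g um\n",
              nrow(x$conn), nrow(x$nodes), x$h))
  invisible(x)
}

largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  repeat {
    seed <- which(mask & lab == 0L)
    if (!length(seed)) break
    cur <- cur + 1L
    front <- matrix(FALSE, nrow(mask), ncol(mask))
    front[seed[1]] <- TRUE
    grown <- front
    repeat {
      d <- dilate4(grown) & mask & lab == 0L
      if (!any(d & !grown)) break
      grown <- d | grown
    }
    lab[grown] <- cur
  }
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

dilate4 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-ny, ]
  out[-ny, ] <- out[-ny, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nx]
  out[, -nx] <- out[, -nx] | m[, -1]
  out
}

# Plane-stress constitutive matrix for stiffness scale E (arbitrary) and
# Poisson-like ratio nu.
plane_stress_D <- function(Escale, nu) {
  Escale / (1 - nu^2) *
    matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
}

# 8x8 stiffness of a square bilinear quad of side h (2x2 Gauss), and the
# strain-displacement matrix at the element center.
quad_stiffness <- function(D, h) {
  gp <- c(-1, 1) / sqrt(3)
  Ke <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    B <- quad_B(xi, eta, h)
    Ke <- Ke + t(B) %*% D %*% B * (h / 2)^2
  }
  Ke
}

# Local corner order: (-1,-1), (1,-1), (1,1), (-1,1) matching mesh corners
# (i,j), (i,j+1), (i+1,j+1), (i+1,j) in x-right / y-down coordinates.
quad_B <- function(xi, eta, h) {
  xs <- c(-1, 1, 1, -1); es <- c(-1, -1, 1, 1)
  dNdx <- xs * (1 + es * eta) / 4 * (2 / h)
  dNdy <- es * (1 + xs * xi) / 4 * (2 / h)
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNdx
  B[2, seq(2, 8, 2)] <- dNdy
  B[3, seq(1, 8, 2)] <- dNdy
  B[3, seq(2, 8, 2)] <- dNdx
  B
}

#' Solve for monolayer stresses from tractions
#'
#' Assembles the plane-stress stiffness on the island mesh, loads nodal
#' forces from `-T/h` (tractions are taken element-wise constant, so each
#' element distributes its load equally to its four corners, which preserves
#' net force and moment exactly), pins three degrees of freedom (vertical at
#' the leftmost node, both at the rightmost node, as in the original
#' analysis), solves the sparse symmetric system, and evaluates element
#' stresses at element centers through the constitutive matrix. Because the
#' island is self-equilibrated the pinned nodes carry no load and their
#' placement does not affect the stresses.
#'
#' @param traction A balanced `gridded_field` of tractions (Pa) on the mesh
#'   grid; run [enforce_equilibrium()] first.
#' @param mesh A [build_mesh()] result on the same grid.
#' @param mono A [monolayer()]; supplies the height `h` and, unless
#'   `ratio_nu_m` is given, the constitutive ratio via [k_to_nu()].
#' @param ratio_nu_m Poisson-like ratio of the closure, overriding the
#'   monolayer's (K1, K2); the stress depends only on this ratio, not on the
#'   stiffness magnitude.
#' @param stiffness_scale Arbitrary stiffness magnitude (cancels in the
#'   result; exposed to demonstrate that it does).
#' @param bc_nodes Optional integer vector of three constrained degrees of
#'   freedom (dof indices `2*node-1` = x, `2*node` = y) overriding the
#'   default leftmost/rightmost choice; stresses are invariant to it.
#' @param balance_tol Reject tractions whose net force or moment exceeds
#'   this fraction of the RMS traction scale (default 1e-6).
#' @return A [stress_field()] on the element-center grid (`NA` outside the
#'   mask), with attribute `"fem"` holding the solution metadata.
#' @export
solve_stress <- function(traction, mesh, mono = monolayer(),
                         ratio_nu_m = NULL, stiffness_scale = 1,
                         bc_nodes = NULL, balance_tol = 1e-6) {
  nu <- ratio_nu_m %||% k_to_nu(mono = mono)
  ne <- nrow(mesh$conn); nn <- nrow(mesh$nodes)
  # element-center traction values
  tx <- traction$u[cbind(mesh$cell[, 1], mesh$cell[, 2])]
  ty <- traction$v[cbind(mesh$cell[, 1], mesh$cell[, 2])]
  if (anyNA(tx) || anyNA(ty))
    stop("traction field has missing values on the mesh; inpaint first")
  scale <- sqrt(mean(tx^2 + ty^2))
  if (scale > 0) {
    relF <- sqrt(sum(tx)^2 + sum(ty)^2) / (scale * ne)
    xc <- mean(mesh$center_x); yc <- mean(mesh$center_y)
    r2 <- sum((mesh$center_x - xc)^2 + (mesh$center_y - yc)^2)
    relM <- abs(sum((mesh$center_x - xc) * ty - (mesh$center_y - yc) * tx)) /
      (scale * sqrt(r2 * ne))
    if (relF > balance_tol || relM > balance_tol)
      stop(sprintf(
        "traction not in equilibrium (rel. force %.2e, rel. moment %.2e); run enforce_equilibrium() first",
        relF, relM))
  }
  h <- mesh$h
  D <- plane_stress_D(stiffness_scale, nu)
  Ke <- quad_stiffness(D, h)
  edof <- matrix(0L, ne, 8)
  edof[, seq(1, 8, 2)] <- 2L * mesh$conn - 1L
  edof[, seq(2, 8, 2)] <- 2L * mesh$conn
  ii <- edof[, rep(1:8, times = 8)]
  jj <- edof[, rep(1:8, each = 8)]
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = rep(as.vector(Ke), each = ne),
                            dims = c(2 * nn, 2 * nn))
  # load: body force b = -T/h_mono, element-wise constant, quarter per corner
  fe_x <- -tx / mono$height_h * h^2 / 4
  fe_y <- -ty / mono$height_h * h^2 / 4
  f <- numeric(2 * nn)
  for (a in 1:4) {
    f <- f + tabulate_add(2L * mesh$conn[, a] - 1L, fe_x, 2 * nn)
    f <- f + tabulate_add(2L * mesh$conn[, a], fe_y, 2 * nn)
  }
  fixed <- bc_nodes %||% default_bc_dofs(mesh)
  keep <- setdiff(seq_len(2 * nn), fixed)
  Kr <- K[keep, keep]
  sol <- Matrix::solve(Matrix::forceSymmetric(Kr), f[keep])
  u <- numeric(2 * nn)
  u[keep] <- as.numeric(sol)
  # element-center stresses
  B0 <- quad_B(0, 0, h)
  ue <- matrix(u[edof], ne, 8)
  se <- ue %*% t(D %*% B0)  # ne x 3: sxx, syy, sxy
  put <- function(vals) {
    m <- matrix(NA_real_, mesh$ny, mesh$nx)
    m[mesh$cell] <- vals
    m
  }
  out <- stress_field(put(se[, 1]), put(se[, 2]), put(se[, 3]), spacing = h)
  attr(out, "fem") <- list(nu_m = nu, height_h = mono$height_h,
                           n_elements = ne, n_nodes = nn,
                           fixed_dofs = fixed,
                           residual = sqrt(sum((K %*% u - f)[keep]^2)) /
                             max(sqrt(sum(f^2)), .Machine$double.eps))
  out
}

tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

default_bc_dofs <- function(mesh) {
  left <- which.min(mesh$nodes[, "x"] * 1e6 + mesh$nodes[, "y"])
  right <- which.max(mesh$nodes[, "x"] * 1e6 - mesh$nodes[, "y"])
  c(2L * left, 2L * right - 1L, 2L * right)  # left: no vertical; right: pinned
}

#' Principal stresses, orientation, and stress-ellipse descriptors
#'
#' Eigen-decomposition of the 2x2 symmetric tensor per node:
#' \eqn{\sigma_{1,2} = \bar\sigma \pm \sqrt{((\sigma_{xx}-\sigma_{yy})/2)^2
#' + \sigma_{xy}^2}} with \eqn{\sigma_1 \ge \sigma_2}, and the first
#' principal direction \eqn{\theta = \tfrac12\,\mathrm{atan2}(2\sigma_{xy},
#' \sigma_{xx}-\sigma_{yy})}. The isotropic case returns \eqn{\theta = 0}.
#' Ellipses drawn with major axis ∝ |σ1|, minor ∝ |σ2| at angle θ summarize
#' the local stress state.
#'
#' @param stress A [stress_field()].
#' @return The input with components `s1`, `s2`, `theta` added.
#' @export
principal_stresses <- function(stress) {
  mid <- (stress$sxx + stress$syy) / 2
  rad <- sqrt(((stress$sxx - stress$syy) / 2)^2 + stress$sxy^2)
  stress$s1 <- mid + rad
  stress$s2 <- mid - rad
  stress$theta <- 0.5 * atan2(2 * stress$sxy, stress$sxx - stress$syy)
  stress$theta[rad == 0] <- 0
  stress
}

#' Contractile tension field and island average
#'
#' The average of the principal stresses, \eqn{(\sigma_1+\sigma_2)/2 =
#' (\sigma_{xx}+\sigma_{yy})/2}: positive for a sheet under tension. The
#' island average weights every element equally (elements share one size).
#'
#' @param stress A [stress_field()] (principal components not required; the
#'   trace identity is used).
#' @return List with `field` (matrix, Pa) and `average` (scalar, Pa over
#'   non-missing nodes).
#' @export
contractile_tension <- function(stress) {
  tens <- (stress$sxx + stress$syy) / 2
  list(field = tens, average = mean(tens, na.rm = TRUE))
}
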