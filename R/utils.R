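# Grid calculus helpers shared by the generator, traction and stress modules.
# All operate on image-style matrices (rows = y, cols = x) with uniform
# physical spacing; centered differences inside, one-sided at the borders.

# d/dx along columns
ddx <- function(m, spacing) {
  nx <- ncol(m)
  if (nx < 2L) stop("need at least 2 columns for a derivative")
  out <- m
  out[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / (2 * spacing)
  out[, 1] <- (m[, 2] - m[, 1]) / spacing
  out[, nx] <- (m[, nx] - m[, nx - 1]) / spacing
  out
}

# d/dy along rows (y increases with row index, image convention)
ddy <- function(m, spacing) {
  ny <- nrow(m)
  if (ny < 2L) stop("need at least 2 rows for a derivative")
  out <- m
  out[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * spacing)
  out[1, ] <- (m[2, ] - m[1, ]) / spacing
  out[ny, ] <- (m[ny, ] - m[ny - 1, ]) / spacing
  out
}

# Bilinear interpolation of matrix m at physical coordinates (px, py) given
# grid coordinate vectors gx (columns) and gy (rows). Points outside the grid
# are clamped to the border value.
bilinear <- function(m, gx, gy, px, py) {
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  fx <- (px - gx[1]) / dx
  fy <- (py - gy[1]) / dy
  fx <- pmin(pmax(fx, 0), length(gx) - 1)
  fy <- pmin(pmax(fy, 0), length(gy) - 1)
  j0 <- pmin(floor(fx), length(gx) - 2); i0 <- pmin(floor(fy), length(gy) - 2)
  tx <- fx - j0; ty <- fy - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # to 1-based
  n <- nrow(m)
  idx <- function(i, j) (j - 1) * n + i
  v00 <- m[idx(i0, j0)];     v01 <- m[idx(i0, j0 + 1)]
  v10 <- m[idx(i0 + 1, j0)]; v11 <- m[idx(i0 + 1, j0 + 1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

# Smooth cosine ramp from 1 (inside) to 0 across [r0, r1] as a function of r.
cos_taper <- function(r, r0, r1) {
  t <- (r - r0) / (r1 - r0)
  t <- pmin(pmax(t, 0), 1)
  0.5 * (1 + cos(pi * t))
}

# Matrices of x and y coordinates (µm) for an ny x nx grid.
coord_mats <- function(x, y) {
  list(X = matrix(x, nrow = length(y), ncol = length(x), byrow = TRUE),
       Y = matrix(y, nrow = length(y), ncol = length(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
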