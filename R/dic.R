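# Subset-based digital image correlation.
#
# For each node of a regular grid, a square subset of the first image is
# matched against a search window of the second by normalized
# cross-correlation (computed via FFT with integral-image normalization);
# the correlation peak is refined to subpixel precision by a 3-point
# Gaussian fit per axis. Parameter defaults mirror the experimental
# analysis: 48 px subsets / 12 px spacing for cell images, 32 px / 8 px for
# particle images.

#' Correlate an image pair into a gridded displacement field
#'
#' @param image_a,image_b Numeric matrices (same dimensions); `image_a` is
#'   the reference, displacements map features of `image_a` to `image_b`.
#' @param subset_size Square subset side in pixels (≥ 16).
#' @param spacing Grid spacing between subset centers, pixels
#'   (≤ `subset_size`).
#' @param pixel_size µm per pixel; output displacements are in µm.
#' @param search Half-width of the integer search range in pixels
#'   (default `subset_size %/% 4`).
#' @param quality_threshold Nodes whose peak normalized correlation falls
#'   below this are flagged missing (`NA`); default 0.5.
#' @param refine If `TRUE`, run a second warp-and-recorrelate pass: the
#'   second image is warped back by the interpolated first-pass field and
#'   the residual displacement is added. Default `FALSE` (single pass).
#' @return A `gridded_field` (units µm) with a per-node `quality` matrix.
#' @export
correlate_pair <- function(image_a, image_b, subset_size = 32,
                           spacing = 8, pixel_size = 0.65,
                           search = subset_size %/% 4,
                           quality_threshold = 0.5, refine = FALSE) {
  image_a <- as.matrix(image_a); image_b <- as.matrix(image_b)
  if (!all(dim(image_a) == dim(image_b)))
    stop("images must have identical dimensions")
  if (subset_size < 16) stop("subset_size must be at least 16 pixels")
  if (spacing > subset_size) stop("spacing must not exceed subset_size")
  if (subset_size + 2 * search >= min(dim(image_a)))
    stop("subset plus search range larger than the image")

  res <- dic_pass(image_a, image_b, subset_size, spacing, search)
  if (refine) {
    # warp image_b back by the current estimate and correlate the residual
    filled <- inpaint_matrix(res$u); filledv <- inpaint_matrix(res$v)
    ny <- nrow(image_a); nx <- ncol(image_a)
    cm <- coord_mats(0:(nx - 1), 0:(ny - 1))
    wu <- bilinear(filled, res$nodes_x, res$nodes_y, c(cm$X), c(cm$Y))
    wv <- bilinear(filledv, res$nodes_x, res$nodes_y, c(cm$X), c(cm$Y))
    bw <- matrix(bicubic(image_b, c(cm$X) + wu, c(cm$Y) + wv), ny, nx)
    res2 <- dic_pass(image_a, bw, subset_size, spacing, search)
    res$u <- filled + res2$u
    res$v <- filledv + res2$v
    res$quality <- res2$quality
  }
  u <- res$u; v <- res$v
  bad <- res$quality < quality_threshold
  u[bad] <- NA_real_; v[bad] <- NA_real_
  gridded_field(u * pixel_size, v * pixel_size,
                spacing = spacing * pixel_size, units = "um",
                x = res$nodes_x * pixel_size, y = res$nodes_y * pixel_size,
                quality = res$quality)
}

dic_pass <- function(a, b, subset, spacing, search) {
  ny <- nrow(a); nx <- ncol(a)
  hw <- subset %/% 2
  m0 <- hw + search  # margin so template and window fit
  nodes_x <- seq(m0, nx - 1 - m0 - (subset %% 2), by = spacing)
  nodes_y <- seq(m0, ny - 1 - m0 - (subset %% 2), by = spacing)
  if (!length(nodes_x) || !length(nodes_y))
    stop("image too small for the requested subset/search")
  P <- subset + 2 * search
  u <- v <- q <- matrix(NA_real_, length(nodes_y), length(nodes_x))
  for (iy in seq_along(nodes_y)) {
    for (ix in seq_along(nodes_x)) {
      cx <- nodes_x[ix]; cy <- nodes_y[iy]
      ti <- (cy - hw + 1):(cy - hw + subset)
      tj <- (cx - hw + 1):(cx - hw + subset)
      tmpl <- a[ti, tj]
      win <- b[(cy - hw - search + 1):(cy - hw - search + P),
               (cx - hw - search + 1):(cx - hw - search + P)]
      pk <- ncc_peak(tmpl, win, subset, search)
      u[iy, ix] <- pk[1]; v[iy, ix] <- pk[2]; q[iy, ix] <- pk[3]
    }
  }
  list(u = u, v = v, quality = q, nodes_x = nodes_x, nodes_y = nodes_y)
}

# Normalized cross-correlation of a subset template against a search window
# (window side = subset + 2*search); returns c(dx, dy, peak_ncc) with
# subpixel 3-point Gaussian refinement.
ncc_peak <- function(tmpl, win, subset, search) {
  tz <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(tz^2))
  if (tnorm == 0) return(c(0, 0, 0))
  P <- subset + 2 * search
  tp <- matrix(0, P, P)
  tp[seq_len(subset), seq_len(subset)] <- tz
  num <- Re(stats::fft(stats::fft(win) * Conj(stats::fft(tp)),
                       inverse = TRUE)) / (P * P)
  # window sums over subset-sized patches via integral images
  s1 <- patch_sums(win, subset)
  s2 <- patch_sums(win * win, subset)
  varw <- pmax(s2 - s1^2 / (subset * subset), 0)
  L <- 2 * search + 1
  C <- num[seq_len(L), seq_len(L)] /
    (tnorm * sqrt(varw[seq_len(L), seq_len(L)]) + 1e-12)
  pk <- arrayInd(which.max(C), dim(C))
  py <- pk[1]; px <- pk[2]
  peak <- C[py, px]
  dx <- px - 1 - search; dy <- py - 1 - search
  sx <- subpixel_offset(C, py, px, axis = "x")
  sy <- subpixel_offset(C, py, px, axis = "y")
  c(dx + sx, dy + sy, peak)
}

# Sums of all s x s patches of m, indexed by the (1-based) patch top-left
# corner, via an integral image.
patch_sums <- function(m, s) {
  n1 <- nrow(m); n2 <- ncol(m)
  Z <- matrix(0, n1 + 1, n2 + 1)
  Z[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  k1 <- n1 - s + 1; k2 <- n2 - s + 1
  Z[(1 + s):(n1 + 1), (1 + s):(n2 + 1)] -
    Z[1:k1, (1 + s):(n2 + 1)] -
    Z[(1 + s):(n1 + 1), 1:k2] +
    Z[1:k1, 1:k2]
}

# 3-point Gaussian (log-parabola) peak interpolation along one axis;
# falls back to parabolic fit when neighbors are non-positive, and to 0 at
# the search-range border.
subpixel_offset <- function(C, py, px, axis) {
  if (axis == "x") {
    if (px <= 1 || px >= ncol(C)) return(0)
    c0 <- C[py, px - 1]; c1 <- C[py, px]; c2 <- C[py, px + 1]
  } else {
    if (py <= 1 || py >= nrow(C)) return(0)
    c0 <- C[py - 1, px]; c1 <- C[py, px]; c2 <- C[py + 1, px]
  }
  if (c0 > 0 && c1 > 0 && c2 > 0) {
    l0 <- log(c0); l1 <- log(c1); l2 <- log(c2)
    den <- 2 * l0 - 4 * l1 + 2 * l2
    if (den < 0) return(max(-1, min(1, (l0 - l2) / den)))
  }
  den <- 2 * (c0 - 2 * c1 + c2)
  if (den < 0) max(-1, min(1, (c0 - c2) / den)) else 0
}

#' Correlate a time-lapse stack into a sequence of fields
#'
#' In `"consecutive"` mode frame pairs (i, i+1) are correlated and divided
#' by `dt` to give velocities (cell images). In `"fixed-reference"` mode
#' every frame is correlated against a single reference image (particle
#' images vs. the traction-free reference), giving displacements.
#'
#' @param stack List of image matrices (≥ 2 frames in consecutive mode).
#' @param reference_mode `"consecutive"` or `"fixed-reference"`.
#' @param reference Reference image for fixed-reference mode; defaults to
#'   the first frame.
#' @param dt Frame interval in minutes (default 10).
#' @inheritParams correlate_pair
#' @return List of `gridded_field`s; units µm/min (consecutive) or µm
#'   (fixed-reference).
#' @export
correlate_stack <- function(stack, reference_mode = c("consecutive",
                                                      "fixed-reference"),
                            subset_size = 48, spacing = 12,
                            pixel_size = 0.65, dt = 10,
                            reference = NULL, ...) {
  reference_mode <- match.arg(reference_mode)
  if (reference_mode == "consecutive") {
    if (length(stack) < 2) stop("need at least 2 frames")
    out <- vector("list", length(stack) - 1)
    for (i in seq_along(out)) {
      f <- correlate_pair(stack[[i]], stack[[i + 1]], subset_size, spacing,
                          pixel_size, ...)
      f$u <- f$u / dt; f$v <- f$v / dt
      f$units <- "um/min"; f$time <- (i - 1) * dt
      out[[i]] <- f
    }
  } else {
    if (length(stack) < 1) stop("need at least 1 frame")
    reference <- reference %||% stack[[1]]
    out <- vector("list", length(stack))
    for (i in seq_along(stack)) {
      f <- correlate_pair(reference, stack[[i]], subset_size, spacing,
                          pixel_size, ...)
      f$time <- (i - 1) * dt
      out[[i]] <- f
    }
  }
  out
}

# Fill NA nodes by iterated local averaging of available neighbors.
inpaint_matrix <- function(m, max_iter = 200) {
  if (!anyNA(m)) return(m)
  for (it in seq_len(max_iter)) {
    nas <- which(is.na(m), arr.ind = TRUE)
    if (!nrow(nas)) break
    vals <- numeric(nrow(nas)); ok <- logical(nrow(nas))
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      nb <- m[max(1, i - 1):min(nrow(m), i + 1),
              max(1, j - 1):min(ncol(m), j + 1)]
      nb <- nb[!is.na(nb)]
      if (length(nb)) { vals[k] <- mean(nb); ok[k] <- TRUE }
    }
    m[nas[ok, , drop = FALSE]] <- vals[ok]
    if (all(ok)) break
  }
  m[is.na(m)] <- 0
  m
}

#' Fill flagged (missing) nodes of a gridded field by neighbor averaging
#'
#' The Fourier traction inverse needs complete fields; nodes flagged by the
#' correlation quality threshold are filled with the iterated mean of their
#' valid neighbors.
#'
#' @param field A `gridded_field` possibly containing `NA` nodes.
#' @return The field with all nodes finite.
#' @export
inpaint_field <- function(field) {
  field$u <- inpaint_matrix(field$u)
  field$v <- inpaint_matrix(field$v)
  field
}

# Keys bicubic (a = -0.5) interpolation of matrix m at 0-based pixel
# coordinates (px, py); coordinates are clamped to the valid interior.
bicubic <- function(m, px, py) {
  ny <- nrow(m); nx <- ncol(m)
  px <- pmin(pmax(px, 1), nx - 2.001)
  py <- pmin(pmax(py, 1), ny - 2.001)
  j0 <- floor(px); i0 <- floor(py)
  tx <- px - j0; ty <- py - i0
  wk <- function(t) {
    # cubic convolution weights for offsets -1, 0, 1, 2
    cbind(((-0.5 * t + 1) * t - 0.5) * t,
          (1.5 * t - 2.5) * t * t + 1,
          ((-1.5 * t + 2) * t + 0.5) * t,
          (0.5 * t - 0.5) * t * t)
  }
  wx <- wk(tx); wy <- wk(ty)
  out <- numeric(length(px))
  for (a in 1:4) {
    row_acc <- numeric(length(px))
    for (b in 1:4) {
      idx <- (j0 + b - 2) * ny + (i0 + a - 2)  # 0-based row/col -> linear
      row_acc <- row_acc + wx[, b] * m[idx + 1]
    }
    out <- out + wy[, a] * row_acc
  }
  out
}
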