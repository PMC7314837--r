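#' Gridded two-component vector field
#'
#' The common container for displacement, velocity and traction fields: two
#' component matrices sampled on a regular grid with physical coordinates.
#' Matrices are stored image-style, rows indexing y (increasing downward) and
#' columns indexing x; coordinates are pixel centers starting at 0.
#'
#' @param u,v Component matrices (identical dimensions), `u` along x, `v`
#'   along y.
#' @param spacing Physical grid spacing in µm between adjacent nodes.
#' @param units Unit string for the components (e.g. `"um"`, `"um/min"`,
#'   `"Pa"`).
#' @param x,y Optional coordinate vectors (µm); defaults to
#'   `0:(n-1) * spacing`.
#' @param quality Optional matrix of per-node correlation quality in
#'   \[-1, 1\]; `NA` components mark flagged/missing nodes.
#' @param time Optional time stamp (minutes) of the field.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(u, v, spacing, units = "um", x = NULL, y = NULL,
                          quality = NULL, time = NA_real_) {
  u <- as.matrix(u); v <- as.matrix(v)
  if (!all(dim(u) == dim(v))) stop("u and v must have identical dimensions")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number")
  ny <- nrow(u); nx <- ncol(u)
  if (is.null(x)) x <- (seq_len(nx) - 1) * spacing
  if (is.null(y)) y <- (seq_len(ny) - 1) * spacing
  if (length(x) != nx || length(y) != ny)
    stop("coordinate vectors do not match matrix dimensions")
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    if (!all(dim(quality) == dim(u))) stop("quality must match field dimensions")
  }
  structure(list(x = x, y = y, u = u, v = v, spacing = spacing,
                 units = units, quality = quality, time = time),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %d x %d nodes, spacing %.4g um, units %s\n",
              nrow(x$u), ncol(x$u), x$spacing, x$units))
  m <- field_magnitude(x)
  cat(sprintf("  |field|: rms %.4g, max %.4g; missing nodes: %d\n",
              sqrt(mean(m^2, na.rm = TRUE)), max(m, na.rm = TRUE),
              sum(is.na(x$u) | is.na(x$v))))
  invisible(x)
}

#' Magnitude of a gridded vector field
#' @param field A `gridded_field`.
#' @return Matrix of `sqrt(u^2 + v^2)`.
#' @export
field_magnitude <- function(field) sqrt(field$u^2 + field$v^2)

#' Root-mean-square magnitude of a field, optionally restricted to a mask
#' @param field A `gridded_field`.
#' @param mask Optional logical matrix selecting nodes.
#' @return Scalar RMS of the vector magnitude over the selected nodes.
#' @export
field_rms <- function(field, mask = NULL) {
  m2 <- field$u^2 + field$v^2
  if (!is.null(mask)) m2 <- m2[mask]
  sqrt(mean(m2, na.rm = TRUE))
}

#' In-plane symmetric stress tensor field
#'
#' Stores the three independent components of the 2D stress tensor on a grid,
#' in the same image-style layout as [gridded_field()].
#'
#' @param sxx,syy,sxy Component matrices (Pa).
#' @param spacing Grid spacing (µm).
#' @param x,y Optional coordinate vectors (µm).
#' @return An object of class `stress_field`.
#' @export
stress_field <- function(sxx, syy, sxy, spacing, x = NULL, y = NULL) {
  sxx <- as.matrix(sxx); syy <- as.matrix(syy); sxy <- as.matrix(sxy)
  if (!all(dim(sxx) == dim(syy)) || !all(dim(sxx) == dim(sxy)))
    stop("stress components must have identical dimensions")
  ny <- nrow(sxx); nx <- ncol(sxx)
  if (is.null(x)) x <- (seq_len(nx) - 1) * spacing
  if (is.null(y)) y <- (seq_len(ny) - 1) * spacing
  structure(list(x = x, y = y, sxx = sxx, syy = syy, sxy = sxy,
                 spacing = spacing),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  tens <- (x$sxx + x$syy) / 2
  cat(sprintf("<stress_field> %d x %d nodes, spacing %.4g um\n",
              nrow(x$sxx), ncol(x$sxx), x$spacing))
  cat(sprintf("  mean tension (sxx+syy)/2: %.4g Pa (range %.4g to %.4g)\n",
              mean(tens, na.rm = TRUE), min(tens, na.rm = TRUE),
              max(tens, na.rm = TRUE)))
  invisible(x)
}

# Relative RMS difference between two fields given as matrices (or lists of
# matrices); denominator is the RMS of the reference.
relative_rms <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  sqrt(sum((a - b)^2) / sum(b^2))
}
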