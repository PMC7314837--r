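#' Circular micropatterned island domain
#'
#' Holds the binary mask of the cell island, its center and radius, in the
#' image coordinate convention (pixel centers at 0, 1, ... times
#' `pixel_size`; y increases downward).
#'
#' @param mask Logical matrix, `TRUE` where cells are present.
#' @param center Numeric length-2, island center `(x, y)` in µm.
#' @param radius Island radius in µm.
#' @param pixel_size µm per pixel.
#' @return An object of class `island_domain`.
#' @export
island_domain <- function(mask, center, radius, pixel_size) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask is empty")
  cm <- coord_mats((seq_len(ncol(mask)) - 1) * pixel_size,
                   (seq_len(nrow(mask)) - 1) * pixel_size)
  ic <- round(center[2] / pixel_size) + 1; jc <- round(center[1] / pixel_size) + 1
  if (ic < 1 || ic > nrow(mask) || jc < 1 || jc > ncol(mask) || !mask[ic, jc])
    stop("center must lie inside the mask")
  structure(list(mask = mask, center = center, radius = radius,
                 pixel_size = pixel_size, X = cm$X, Y = cm$Y),
            class = "island_domain")
}

#' @export
print.island_domain <- function(x, ...) {
  cat(sprintf(
    "<island_domain> %d x %d px, radius %.3g um, center (%.3g, %.3g) um, %.3g um/px\n",
    nrow(x$mask), ncol(x$mask), x$radius, x$center[1], x$center[2],
    x$pixel_size))
  invisible(x)
}

#' Construct a centered circular island mask
#'
#' Emulates the micropatterned geometry of the experiments: a circular
#' adhesive island (1 mm diameter in the original assay) surrounded by
#' cell-free substrate. A margin of at least 10% of the image extent must
#' separate the island edge from the image border so that downstream Fourier
#' and finite-difference operators see a zero surround.
#'
#' @param radius_um Island radius (µm).
#' @param pixel_size µm per pixel (the experimental optics give ≈ 0.65).
#' @param image_size Image side length in pixels (square grid).
#' @return An [island_domain()].
#' @examples
#' dom <- make_island(radius_um = 50 * 0.65, pixel_size = 0.65,
#'                    image_size = 128)
#' sum(dom$mask) / (pi * 50^2)  # close to 1
#' @export
make_island <- function(radius_um, pixel_size = 0.65, image_size = 256) {
  if (radius_um <= 0) stop("radius_um must be positive")
  extent <- image_size * pixel_size
  if (radius_um > extent / 2 - 0.1 * extent)
    stop(sprintf(
      "island radius %.3g um does not fit in a %.3g um image with a 10%% margin",
      radius_um, extent))
  cx <- (image_size - 1) / 2 * pixel_size
  cm <- coord_mats((seq_len(image_size) - 1) * pixel_size,
                   (seq_len(image_size) - 1) * pixel_size)
  r <- sqrt((cm$X - cx)^2 + (cm$Y - cx)^2)
  island_domain(r <= radius_um, center = c(cx, cx), radius = radius_um,
                pixel_size = pixel_size)
}

# Radius matrix (µm from center) and unit radial vectors for a domain.
domain_radius <- function(domain) {
  dx <- domain$X - domain$center[1]
  dy <- domain$Y - domain$center[2]
  r <- sqrt(dx^2 + dy^2)
  rhat_x <- ifelse(r > 0, dx / r, 0)
  rhat_y <- ifelse(r > 0, dy / r, 0)
  list(r = r, rhat_x = rhat_x, rhat_y = rhat_y)
}
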