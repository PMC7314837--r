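# Readers and writers for the interchange formats of the pipeline: gridded
# field tables (TSV with a key-value metadata header), TIFF images/masks,
# the standard per-island folder layout of public island datasets, and
# MAT-file export for parity with MATLAB-format deposits.

write_meta_header <- function(con, meta) {
  for (nm in names(meta))
    cat(sprintf("# %s: %s\n", nm, paste(meta[[nm]], collapse = " ")),
        file = con)
}

read_meta_header <- function(path) {
  lines <- readLines(path, n = 100)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in hdr) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  meta
}

#' Write a gridded vector field as a delimited table
#'
#' TSV columns `x`, `y`, `u`, `v` (and `quality` when present) preceded by
#' `# key: value` metadata lines recording spacing, units and the
#' coordinate convention (pixel centers at 0, y downward).
#'
#' @param field A `gridded_field`.
#' @param path Output path.
#' @param extra Optional named list merged into the metadata header.
#' @export
write_field <- function(field, path, extra = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(format = "islandmech gridded_field v1",
                 spacing_um = field$spacing, units = field$units,
                 ny = nrow(field$u), nx = ncol(field$u),
                 time_min = field$time,
                 convention = "x right, y down, origin at first pixel center"),
            extra)
  write_meta_header(con, meta)
  cm <- coord_mats(field$x, field$y)
  df <- data.frame(x = c(cm$X), y = c(cm$Y), u = c(field$u), v = c(field$v))
  if (!is.null(field$quality)) df$quality <- c(field$quality)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gridded vector field table written by [write_field()]
#' @param path Input path.
#' @return A `gridded_field`.
#' @export
read_field <- function(path) {
  meta <- read_meta_header(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ny <- as.integer(meta$ny); nx <- as.integer(meta$nx)
  gridded_field(matrix(df$u, ny, nx), matrix(df$v, ny, nx),
                spacing = as.numeric(meta$spacing_um),
                units = meta$units %||% "um",
                x = unique(df$x), y = unique(df$y),
                quality = if ("quality" %in% names(df))
                  matrix(df$quality, ny, nx),
                time = suppressWarnings(as.numeric(meta$time_min %||% NA)))
}

#' Write a stress tensor field as a delimited table
#' @param stress A [stress_field()].
#' @param path Output path.
#' @param extra Optional extra metadata.
#' @export
write_stress <- function(stress, path, extra = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, c(list(format = "islandmech stress_field v1",
                                spacing_um = stress$spacing,
                                units = "Pa",
                                ny = nrow(stress$sxx), nx = ncol(stress$sxx)),
                           extra))
  cm <- coord_mats(stress$x, stress$y)
  df <- data.frame(x = c(cm$X), y = c(cm$Y), sxx = c(stress$sxx),
                   syy = c(stress$syy), sxy = c(stress$sxy))
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stress field table written by [write_stress()]
#' @param path Input path.
#' @return A [stress_field()].
#' @export
read_stress <- function(path) {
  meta <- read_meta_header(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ny <- as.integer(meta$ny); nx <- as.integer(meta$nx)
  stress_field(matrix(df$sxx, ny, nx), matrix(df$syy, ny, nx),
               matrix(df$sxy, ny, nx),
               spacing = as.numeric(meta$spacing_um),
               x = unique(df$x), y = unique(df$y))
}

#' Read a (possibly multi-page) TIFF as a list of matrices
#' @param path TIFF path.
#' @return List of numeric matrices scaled to the native integer range.
#' @export
read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(im) {
    if (length(dim(im)) == 3) im <- im[, , 1]
    matrix(as.numeric(im), nrow(im), ncol(im))
  })
}

#' Write images as a 16-bit (multi-page) TIFF
#' @param images Matrix or list of matrices; rescaled to the 16-bit range.
#' @param path Output path.
#' @export
write_tiff16 <- function(images, path) {
  if (!is.list(images)) images <- list(images)
  hi <- max(vapply(images, max, 0), 1e-12)
  tiff::writeTIFF(lapply(images, function(m) pmax(m, 0) / hi),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Island record: the per-island folder layout of the public dataset
#'
#' Locates the particle stack (`c1_island#.tif`), cell stack
#' (`c2_island#.tif`), traction-free reference (`c1_tryp_island#.tif`) and
#' boundary mask (`domain.tif`) in a folder, checks dimensional
#' consistency, and attaches frame timing (frame interval, number of
#' pre-treatment frames, post-treatment time mapping).
#'
#' @param folder Folder containing one island's files.
#' @param dt Frame interval in minutes (default 10).
#' @param pre_frames Number of frames acquired before treatment (default
#'   `NA`, untreated).
#' @param post_times Optional vector of post-treatment times (min) for the
#'   remaining frames (e.g. drug experiments map them to 60–220 min).
#' @param patterns Named list of glob patterns overriding the default file
#'   names.
#' @return A list of class `island_record` with element paths and timing.
#' @export
read_island_record <- function(folder, dt = 10, pre_frames = NA_integer_,
                               post_times = NULL, patterns = list()) {
  pat <- utils::modifyList(list(particles = "c1_island*.tif",
                                cells = "c2_island*.tif",
                                reference = "c1_tryp_island*.tif",
                                mask = "domain.tif"), patterns)
  find1 <- function(p, required = TRUE) {
    hit <- Sys.glob(file.path(folder, p))
    if (!length(hit)) {
      if (required) stop(sprintf("missing required file '%s' in %s", p, folder))
      warning(sprintf("optional file '%s' not found in %s", p, folder))
      return(NA_character_)
    }
    hit[1]
  }
  rec <- list(particles = find1(pat$particles),
              cells = find1(pat$cells, required = FALSE),
              reference = find1(pat$reference),
              mask = find1(pat$mask),
              dt = dt, pre_frames = pre_frames, post_times = post_times,
              folder = folder)
  dims <- lapply(rec[c("particles", "reference", "mask")], function(p) {
    if (is.na(p)) return(NULL)
    dim(read_tiff_stack(p)[[1]])
  })
  dims <- dims[!vapply(dims, is.null, TRUE)]
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1)
    stop("island record images have inconsistent dimensions")
  n_frames <- length(read_tiff_stack(rec$particles))
  rec$times <- if (!is.na(pre_frames) && !is.null(post_times)) {
    c(seq(-pre_frames, -1) * dt, post_times)
  } else (seq_len(n_frames) - 1) * dt
  if (length(rec$times) != n_frames)
    stop(sprintf("timing metadata covers %d frames but the stack has %d",
                 length(rec$times), n_frames))
  class(rec) <- "island_record"
  rec
}

#' Map a results MAT-file into package field objects
#'
#' Discovers variables defensively: known name sets are tried first, then
#' any pair of equally-shaped 2D/3D arrays whose names end in x/y. Unknown
#' layouts produce an error listing the variable names found.
#'
#' @param path MAT-file path.
#' @param kind One of `"displacements"`, `"tractions"`, `"stresses"`.
#' @param spacing Grid spacing in µm for the reconstructed fields
#'   (default 5.2, the 8-pixel traction grid).
#' @return For vector kinds, a list of `gridded_field`s (one per frame);
#'   for `"stresses"`, a list of [stress_field()]s.
#' @export
read_mat_fields <- function(path, kind = c("displacements", "tractions",
                                           "stresses"),
                            spacing = 5.2) {
  kind <- match.arg(kind)
  vars <- read_mat(path)
  nms <- names(vars)
  pick <- function(cands) {
    hit <- cands[cands %in% nms]
    if (length(hit)) vars[[hit[1]]] else NULL
  }
  per_frame <- function(a) {
    if (is.null(dim(a)) || length(dim(a)) == 2) list(as.matrix(a))
    else lapply(seq_len(dim(a)[3]), function(k) a[, , k])
  }
  if (kind == "stresses") {
    sxx <- pick(c("sxx", "Sxx", "stress_xx", "sigma_xx"))
    syy <- pick(c("syy", "Syy", "stress_yy", "sigma_yy"))
    sxy <- pick(c("sxy", "Sxy", "stress_xy", "sigma_xy"))
    if (is.null(sxx) || is.null(syy) || is.null(sxy))
      stop(sprintf("unrecognized stress layout in %s; variables found: %s",
                   path, paste(nms, collapse = ", ")))
    return(Map(function(a, b, c3) stress_field(a, b, c3, spacing = spacing),
               per_frame(sxx), per_frame(syy), per_frame(sxy)))
  }
  ux_names <- if (kind == "tractions")
    c("tract_x", "tx", "Tx", "traction_x", "ux") else
    c("ux", "u", "displ_x", "disp_x", "cell_dx")
  uy_names <- if (kind == "tractions")
    c("tract_y", "ty", "Ty", "traction_y", "uy") else
    c("uy", "v", "displ_y", "disp_y", "cell_dy")
  ux <- pick(ux_names); uy <- pick(uy_names)
  if (is.null(ux) || is.null(uy)) {
    # fallback: any two equally shaped arrays named *x / *y
    xs <- nms[grepl("x$", nms)]; ys <- sub("x$", "y", xs)
    ok <- ys %in% nms
    if (any(ok)) { ux <- vars[[xs[ok][1]]]; uy <- vars[[ys[ok][1]]] }
  }
  if (is.null(ux) || is.null(uy))
    stop(sprintf("unrecognized %s layout in %s; variables found: %s",
                 kind, path, paste(nms, collapse = ", ")))
  units <- if (kind == "tractions") "Pa" else "um"
  Map(function(a, b) gridded_field(a, b, spacing = spacing, units = units),
      per_frame(ux), per_frame(uy))
}

#' Write a synthetic island ground-truth bundle
#'
#' Writes the mask (TIFF), every generated field (delimited tables), the
#' speckle image pair (16-bit TIFF) and a flat key-value metadata file, in
#' a layout any downstream module (or other language) can consume.
#'
#' @param synth Result of [synthesize_island()].
#' @param dir Output directory (created if needed).
#' @param speckle Optional result of [render_speckle_pair()].
#' @param mat Also write a `tract_results.mat` for MAT-layout parity
#'   (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_island_bundle <- function(synth, dir, speckle = NULL, mat = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- synth$domain
  tiff::writeTIFF(matrix(as.numeric(dm$mask), nrow(dm$mask)),
                  file.path(dir, "domain.tif"), bits.per.sample = 8L)
  write_field(synth$velocity, file.path(dir, "velocity.tsv"))
  write_field(synth$traction, file.path(dir, "traction.tsv"))
  write_stress(synth$stress, file.path(dir, "stress.tsv"))
  if (!is.null(synth$displacement))
    write_field(synth$displacement, file.path(dir, "displacement.tsv"))
  if (!is.null(speckle)) {
    write_tiff16(speckle$reference, file.path(dir, "c1_tryp_island1.tif"))
    write_tiff16(speckle$deformed, file.path(dir, "c1_island1.tif"))
  }
  meta <- c(generator = "islandmech synthesize_island",
            flow = synth$flow, seed = synth$seed,
            pixel_size_um = dm$pixel_size, radius_um = dm$radius,
            center_um = paste(dm$center, collapse = " "),
            height_h_um = synth$mono$height_h,
            K1 = synth$mono$K1, K2 = synth$mono$K2,
            nu_m = k_to_nu(mono = synth$mono))
  writeLines(sprintf("%s: %s", names(meta), unlist(meta)),
             file.path(dir, "meta.txt"))
  if (mat) {
    write_mat(file.path(dir, "tract_results.mat"),
              list(tract_x = synth$traction$u, tract_y = synth$traction$v))
  }
  invisible(dir)
}

#' Read a synthetic ground-truth bundle written by [write_island_bundle()]
#' @param dir Bundle directory.
#' @return List mirroring the [synthesize_island()] structure.
#' @export
read_island_bundle <- function(dir) {
  meta_lines <- readLines(file.path(dir, "meta.txt"))
  meta <- stats::setNames(trimws(sub("^[^:]*:", "", meta_lines)),
                          sub(":.*$", "", meta_lines))
  mask <- read_tiff_stack(file.path(dir, "domain.tif"))[[1]] > 0
  ctr <- as.numeric(strsplit(meta[["center_um"]], " ")[[1]])
  dom <- island_domain(mask, center = ctr,
                       radius = as.numeric(meta[["radius_um"]]),
                       pixel_size = as.numeric(meta[["pixel_size_um"]]))
  disp_path <- file.path(dir, "displacement.tsv")
  list(domain = dom,
       mono = monolayer(height_h = as.numeric(meta[["height_h_um"]]),
                        K1 = as.numeric(meta[["K1"]]),
                        K2 = as.numeric(meta[["K2"]])),
       velocity = read_field(file.path(dir, "velocity.tsv")),
       traction = read_field(file.path(dir, "traction.tsv")),
       stress = read_stress(file.path(dir, "stress.tsv")),
       displacement = if (file.exists(disp_path)) read_field(disp_path),
       flow = meta[["flow"]], seed = as.integer(meta[["seed"]]))
}
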