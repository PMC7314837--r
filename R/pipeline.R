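#' Run the full force-and-motion pipeline on one island
#'
#' Orchestrates the stages end to end: substrate displacements (given
#' directly, or correlated from particle/reference images), traction
#' inversion with equilibrium correction, monolayer stress recovery,
#' optional velocity/trajectory kinematics, and the technical-validation
#' report. Every stage's parameters are collected into a run manifest that
#' fully determines the outputs.
#'
#' @param domain An [island_domain()] on the working grid.
#' @param displacement Substrate displacement `gridded_field` (µm), or
#'   `NULL` to correlate `particle_images` against `reference_image`.
#' @param particle_images,reference_image Optional particle frames (list of
#'   matrices) and traction-free reference for the DIC stage.
#' @param velocity_stack Optional list of cell-image matrices for the
#'   velocity/trajectory stage (consecutive-mode DIC).
#' @param sub A [substrate()].
#' @param mono A [monolayer()].
#' @param lambda Tikhonov parameter for the traction inversion (default 0).
#' @param dic_args List of extra arguments to [correlate_pair()] for the
#'   particle DIC stage (subset 32 / spacing 8 by default).
#' @param dt Frame interval in minutes.
#' @param out_dir Optional directory; when given, fields, report and
#'   manifest are written there.
#' @return List of class `island_run`: `displacement`, `traction`,
#'   `stress`, `tension`, `velocities`, `trajectories`, `report`,
#'   `manifest`.
#' @export
run_pipeline <- function(domain, displacement = NULL,
                         particle_images = NULL, reference_image = NULL,
                         velocity_stack = NULL,
                         sub = substrate(), mono = monolayer(),
                         lambda = 0, dic_args = list(), dt = 10,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(displacement)) {
    if (is.null(particle_images) || is.null(reference_image))
      stop("provide either a displacement field or particle + reference images")
    displacement <- stage("dic", {
      args <- utils::modifyList(list(subset_size = 32, spacing = 8,
                                     pixel_size = domain$pixel_size),
                                dic_args)
      fields <- lapply(particle_images, function(fr)
        do.call(correlate_pair, c(list(reference_image, fr), args)))
      lapply(fields, inpaint_field)
    })
    if (!is.list(displacement) || inherits(displacement, "gridded_field"))
      displacement <- list(displacement)
  } else if (inherits(displacement, "gridded_field")) {
    displacement <- list(displacement)
  }
  # the stress mesh lives on the displacement grid; resample the mask there
  grid_dom <- stage("regrid", resample_domain(domain, displacement[[1]]))
  tractions <- stage("traction", lapply(displacement, function(d)
    enforce_equilibrium(fttc_inverse(inpaint_field(d), sub, lambda = lambda),
                        grid_dom)))
  mesh <- stage("mesh", build_mesh(grid_dom))
  stresses <- stage("stress", lapply(tractions, function(tr)
    solve_stress(tr, mesh, mono)))
  tension <- data.frame(
    time = (seq_along(stresses) - 1) * dt,
    tension = vapply(stresses, function(s) contractile_tension(s)$average, 0))
  velocities <- trajectories <- NULL
  if (!is.null(velocity_stack) && length(velocity_stack) >= 2) {
    velocities <- stage("kinematics", correlate_stack(
      velocity_stack, "consecutive", subset_size = 48, spacing = 12,
      pixel_size = domain$pixel_size, dt = dt))
    velocities <- lapply(velocities, inpaint_field)
    trajectories <- stage("trajectories",
                          compute_trajectories(velocities, dt = dt))
  }
  report <- stage("validate",
                  validate_island(tractions[[1]], stresses[[1]], grid_dom))
  manifest <- list(
    package_version = as.character(utils::packageVersion("islandmech")),
    youngs_modulus_E = sub$youngs_modulus_E, poisson_ratio = sub$poisson_ratio,
    height_h = mono$height_h, K1 = mono$K1, K2 = mono$K2,
    nu_m = k_to_nu(mono = mono), lambda = lambda, dt = dt,
    pixel_size = domain$pixel_size, grid_spacing = displacement[[1]]$spacing,
    n_frames = length(displacement))
  out <- structure(list(displacement = displacement, traction = tractions,
                        stress = stresses, tension = tension,
                        velocities = velocities, trajectories = trajectories,
                        report = report, manifest = manifest),
                   class = "island_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_field(tractions[[1]], file.path(out_dir, "traction_t0.tsv"))
    write_stress(stresses[[1]], file.path(out_dir, "stress_t0.tsv"))
    utils::write.table(tension, file.path(out_dir, "tension.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf("%s: %s", names(manifest),
                       vapply(manifest, paste, "", collapse = " ")),
               file.path(out_dir, "manifest.txt"))
  }
  out
}

#' Resample an island domain onto a field's grid
#'
#' DIC fields live on the subset-center grid (e.g. every 8th pixel), while
#' masks are stored at full image resolution; this samples the mask at the
#' field's node positions and rebuilds the domain in field-grid
#' coordinates.
#'
#' @param domain An [island_domain()] at image resolution.
#' @param field A `gridded_field` whose grid the mask should follow.
#' @return An [island_domain()] on the field grid.
#' @export
resample_domain <- function(domain, field) {
  if (isTRUE(all.equal(field$spacing, domain$pixel_size)) &&
      all(dim(domain$mask) == dim(field$u)))
    return(domain)
  gi <- pmin(pmax(round(field$y / domain$pixel_size) + 1, 1),
             nrow(domain$mask))
  gj <- pmin(pmax(round(field$x / domain$pixel_size) + 1, 1),
             ncol(domain$mask))
  mask <- domain$mask[gi, gj, drop = FALSE]
  # field coordinates are offset from the image origin; rebuild the domain
  # in field-grid coordinates
  ctr_x <- domain$center[1] - field$x[1]
  ctr_y <- domain$center[2] - field$y[1]
  dom <- island_domain(mask, center = c(ctr_x, ctr_y),
                       radius = domain$radius, pixel_size = field$spacing)
  dom
}

#' @export
print.island_run <- function(x, ...) {
  cat(sprintf("<island_run> %d frame(s)\n", length(x$traction)))
  print(x$report)
  invisible(x)
}
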