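# Shared fixtures, built once per test run. Sizes are desk-scale stand-ins
# for the 1 mm experimental islands: a 128 px grid at 1 um/px with a 40 um
# island keeps every stage fast while leaving a clear zero margin.

fix_domain <- function(n = 128, radius = 0.31 * n, px = 1) {
  make_island(radius_um = radius * px, pixel_size = px, image_size = n)
}

# cached random-flow island (compatible stress; reference for recovery)
the_random_island <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dom <- fix_domain()
      cache <<- synthesize_island(dom, flow = "random", amplitude = 0.3,
                                  correlation_length = 10, seed = 2)
    }
    cache
  }
})

# cached contractile island (tensile stress, inward edge tractions)
the_contractile_island <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dom <- fix_domain()
      cache <<- synthesize_island(dom, flow = "contractile",
                                  amplitude = 0.1, tension = 200)
    }
    cache
  }
})

# relative RMS difference of two lists of matrices/vectors
rel_rms <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  sqrt(sum((a - b)^2) / sum(b^2))
}

# stress recovery error of the full synthetic loop at grid size n
msm_recovery_error <- function(n, seed = 2) {
  dom <- fix_domain(n)
  syn <- synthesize_island(dom, flow = "random", amplitude = 0.3,
                           correlation_length = 0.25 * 0.31 * n, seed = seed)
  tb <- enforce_equilibrium(syn$traction, dom)
  st <- solve_stress(tb, build_mesh(dom), syn$mono)
  m <- !is.na(st$sxx)
  rel_rms(list(st$sxx[m], st$syy[m], st$sxy[m]),
          list(syn$stress$sxx[m], syn$stress$syy[m], syn$stress$sxy[m]))
}

# sinusoidal smooth warp of given pixel amplitude on an n x n grid
make_warp_field <- function(n, amplitude = 2) {
  cm <- islandmech:::coord_mats(0:(n - 1), 0:(n - 1))
  gridded_field(amplitude * sin(2 * pi * cm$X / n) * cos(2 * pi * cm$Y / n),
                -amplitude * cos(2 * pi * cm$X / n) * sin(2 * pi * cm$Y / n),
                spacing = 1)
}

# true warp values at DIC node positions (pixel units)
warp_truth_at_nodes <- function(warp, field) {
  gi <- round(field$y / warp$spacing) + 1
  gj <- round(field$x / warp$spacing) + 1
  list(u = warp$u[gi, gj, drop = FALSE], v = warp$v[gi, gj, drop = FALSE])
}
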