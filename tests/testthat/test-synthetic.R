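test_that("sampled velocity fields are reproducible, masked, and scaled", {
  dom <- fix_domain(64)
  expect_error(sample_velocity_field(dom, -1, 10), "non-negative")
  expect_error(sample_velocity_field(dom, 0.2, 1), "correlation_length")

  z <- sample_velocity_field(dom, 0, 10)
  expect_true(all(z$u == 0) && all(z$v == 0))

  a <- sample_velocity_field(dom, 0.3, 8, seed = 5)
  b <- sample_velocity_field(dom, 0.3, 8, seed = 5)
  expect_identical(a$u, b$u)
  expect_identical(a$v, b$v)
  expect_false(identical(a$u, sample_velocity_field(dom, 0.3, 8, seed = 6)$u))

  expect_true(all(a$u[!dom$mask] == 0))
  # RMS over the island tracks the requested amplitude across seeds
  rmss <- vapply(1:8, function(s)
    field_rms(sample_velocity_field(dom, 0.3, 8, seed = s), dom$mask), 0)
  expect_true(all(abs(rmss - 0.3) / 0.3 < 0.2))
})

test_that("the constitutive law reproduces closed-form cases and is linear", {
  mono <- monolayer(K1 = 2, K2 = 1.5)
  mk <- function(exx, eyy, exy)
    structure(list(exx = matrix(exx, 2, 2), eyy = matrix(eyy, 2, 2),
                   exy = matrix(exy, 2, 2), spacing = 1),
              class = "strain_rate_field")
  # equibiaxial strain rate
  e <- 0.07
  s <- stress_from_strainrate(mk(e, e, 0), mono)
  expect_equal(s$sxx[1, 1], (mono$K1 - 2 / 3 * mono$K2) * 2 * e +
                 2 * mono$K2 * e)
  expect_equal(s$syy[1, 1], s$sxx[1, 1])
  expect_equal(s$sxy[1, 1], 0)
  # pure shear
  g <- 0.11
  s2 <- stress_from_strainrate(mk(0, 0, g), mono)
  expect_equal(s2$sxy[1, 1], 2 * mono$K2 * g)
  expect_equal(s2$sxx[1, 1], 0)
  expect_equal(s2$syy[1, 1], 0)
  # linearity: doubling the strain rate doubles the stress
  set.seed(42)
  sr <- mk(rnorm(1), rnorm(1), rnorm(1))
  sr2 <- mk(2 * sr$exx[1, 1], 2 * sr$eyy[1, 1], 2 * sr$exy[1, 1])
  expect_equal(stress_from_strainrate(sr2, mono)$sxx,
               2 * stress_from_strainrate(sr, mono)$sxx)
})

test_that("tractions follow the analytic divergence of an isotropic tension", {
  # sigma_rr = sigma_tt = s0 (1 - r^2/R^2): |T| = 2 h s0 r / R^2, inward
  n <- 128; px <- 1
  dom <- make_island(50, px, n)
  mono <- monolayer(height_h = 5)
  rr <- islandmech:::domain_radius(dom)
  p <- 30 * pmax(1 - rr$r^2 / dom$radius^2, 0)
  z <- matrix(0, n, n)
  st <- stress_field(p, p, z, spacing = px)
  tr <- traction_from_stress(st, mono, dom)
  t_rad <- tr$u * rr$rhat_x + tr$v * rr$rhat_y
  sel <- dom$mask & rr$r > 10 & rr$r < 40
  expected <- -2 * mono$height_h * 30 * rr$r / dom$radius^2
  expect_lt(max(abs(t_rad[sel] - expected[sel])), 0.02 * max(abs(expected[sel])))
  # edge tractions point radially inward for a tensile island
  edge <- dom$mask & rr$r > 40
  expect_true(all(t_rad[edge] < 0))
  # uniform stress in the interior produces no traction there
  su <- stress_field(z + 7, z + 7, z + 3, spacing = px)
  tu <- traction_from_stress(su, mono, dom)
  interior <- dom$mask & rr$r < 40
  expect_equal(max(abs(tu$u[interior]), abs(tu$v[interior])), 0)
  # doubling the monolayer height doubles the traction
  tr2 <- traction_from_stress(st, monolayer(height_h = 10), dom)
  expect_equal(tr2$u, 2 * tr$u)
})

test_that("generated strain rates satisfy compatibility", {
  n <- 256
  dom <- fix_domain(n)
  syn <- synthesize_island(dom, flow = "random", amplitude = 0.3,
                           correlation_length = 0.25 * 0.31 * n, seed = 3)
  e <- syn$strain_rate
  rr <- islandmech:::domain_radius(dom)
  resid_at <- function(k) {
    # strain rate sampled every k-th node; residual of the compatibility
    # relation by centered differences on that grid
    idx <- seq(1, n, k); h <- k * e$spacing
    exx <- e$exx[idx, idx]; eyy <- e$eyy[idx, idx]; exy <- e$exy[idx, idx]
    r <- islandmech:::ddy(islandmech:::ddy(exx, h), h) +
      islandmech:::ddx(islandmech:::ddx(eyy, h), h) -
      2 * islandmech:::ddx(islandmech:::ddy(exy, h), h)
    sel <- rr$r[idx, idx] < 0.5 * dom$radius
    sqrt(mean(r[sel]^2)) / sqrt(mean((exx^2 + eyy^2 + 2 * exy^2)[sel]))
  }
  # on the generating grid the discrete residual is identically zero
  # (the centered difference operators commute)
  expect_lt(resid_at(1), 1e-12)
  # on coarser sampling the residual is finite and shrinks as O(h^2)
  expect_gt(resid_at(4) / resid_at(2), 2.5)
  expect_lt(resid_at(4) / resid_at(2), 6)
})

test_that("speckle pairs encode the displacement field analytically", {
  n <- 96
  z <- gridded_field(matrix(0, n, n), matrix(0, n, n), 1)
  pr0 <- render_speckle_pair(z, density = 0.05, seed = 4)
  expect_identical(unclass(pr0$reference)[, ], unclass(pr0$deformed)[, ])
  expect_true(all(pr0$reference >= 0))
  # determinism
  pr0b <- render_speckle_pair(z, density = 0.05, seed = 4)
  expect_identical(unclass(pr0$reference)[, ], unclass(pr0b$reference)[, ])
  # uniform integer shift: second image is the first, translated
  sh <- gridded_field(matrix(3, n, n), matrix(5, n, n), 1)
  pr <- render_speckle_pair(sh, density = 0.05, seed = 4)
  a <- unclass(pr$reference); b <- unclass(pr$deformed)
  expect_equal(b[26:(n - 10), 24:(n - 10)], a[21:(n - 15), 21:(n - 13)],
               tolerance = 1e-10)
  expect_warning(render_speckle_pair(z, density = 6e-4, seed = 1), "density")
})

test_that("contractile islands are tensile with inward flow and tractions", {
  syn <- the_contractile_island()
  dom <- syn$domain
  rr <- islandmech:::domain_radius(dom)
  vr <- radial_component(syn$velocity, dom$center)
  expect_lt(mean(vr$radial[dom$mask & rr$r > 5]), 0)        # inward flow
  expect_gt(mean(((syn$stress$sxx + syn$stress$syy) / 2)[dom$mask]), 0)
  expect_lt(edge_traction_sign(syn$traction, dom), 0)       # inward pull
})
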