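test_that("meshes count elements and nodes like the mask geometry", {
  m <- matrix(FALSE, 10, 12); m[3:6, 4:9] <- TRUE  # 4 x 6 rectangle
  dom <- island_domain(m, center = c(6, 4), radius = 3, pixel_size = 1)
  mesh <- build_mesh(dom)
  expect_equal(nrow(mesh$conn), 4 * 6)
  expect_equal(nrow(mesh$nodes), 5 * 7)

  dom2 <- fix_domain(128, radius = 50)
  mesh2 <- build_mesh(dom2)
  expect_equal(nrow(mesh2$conn), pi * 50^2, tolerance = 0.05)

  m1 <- matrix(FALSE, 8, 8); m1[4, 4] <- TRUE
  dom1 <- island_domain(m1, center = c(3, 3), radius = 0.5, pixel_size = 1)
  mesh1 <- build_mesh(dom1)
  expect_equal(nrow(mesh1$conn), 1)
  expect_equal(nrow(mesh1$nodes), 4)

  # disconnected masks are reduced to the largest component
  md <- matrix(FALSE, 16, 16); md[3:10, 3:10] <- TRUE; md[14:15, 14:15] <- TRUE
  domd <- island_domain(md, center = c(6, 6), radius = 4, pixel_size = 1)
  expect_warning(meshd <- build_mesh(domd), "largest component")
  expect_equal(nrow(meshd$conn), 64)
})

test_that("stress recovery closes the synthetic loop and refines", {
  e64 <- msm_recovery_error(64)
  e128 <- msm_recovery_error(128)
  expect_lt(e128, 0.02)
  expect_lt(e128, e64 / 2)  # error decreases under grid refinement
})

test_that("stresses ignore the stiffness magnitude and the pinned nodes", {
  syn <- the_random_island()
  dom <- syn$domain
  tb <- enforce_equilibrium(syn$traction, dom)
  mesh <- build_mesh(dom)
  s1 <- solve_stress(tb, mesh, syn$mono)
  m <- !is.na(s1$sxx)
  # (K1, K2) -> 1000 (K1, K2)
  mono_k <- monolayer(height_h = syn$mono$height_h, K1 = 1000 * syn$mono$K1,
                      K2 = 1000 * syn$mono$K2)
  s2 <- solve_stress(tb, mesh, mono_k)
  expect_lt(rel_rms(list(s2$sxx[m], s2$syy[m], s2$sxy[m]),
                    list(s1$sxx[m], s1$syy[m], s1$sxy[m])), 1e-10)
  s3 <- solve_stress(tb, mesh, syn$mono, stiffness_scale = 1e4)
  expect_lt(rel_rms(list(s3$sxx[m], s3$syy[m], s3$sxy[m]),
                    list(s1$sxx[m], s1$syy[m], s1$sxy[m])), 1e-10)
  # relocate the three pinned degrees of freedom to other boundary nodes
  nd <- mesh$nodes
  top <- which.min(nd[, "y"] * 1e6 + nd[, "x"])
  bot <- which.max(nd[, "y"] * 1e6 + nd[, "x"])
  s4 <- solve_stress(tb, mesh, syn$mono,
                     bc_nodes = c(2L * top, 2L * bot - 1L, 2L * bot))
  expect_lt(rel_rms(list(s4$sxx[m], s4$syy[m], s4$sxy[m]),
                    list(s1$sxx[m], s1$syy[m], s1$sxy[m])), 1e-8)
})

test_that("unbalanced tractions are rejected with guidance", {
  syn <- the_random_island()
  toff <- syn$traction
  toff$u <- toff$u + ifelse(syn$domain$mask, 0.2 * field_rms(toff), 0)
  mesh <- build_mesh(syn$domain)
  expect_error(solve_stress(toff, mesh, syn$mono), "enforce_equilibrium")
})

test_that("tension depends only weakly on the closure ratio", {
  syn <- the_random_island()
  tb <- enforce_equilibrium(syn$traction, syn$domain)
  mesh <- build_mesh(syn$domain)
  tens <- vapply(c(0.2, 0.35, 0.5), function(nu)
    contractile_tension(solve_stress(tb, mesh, syn$mono,
                                     ratio_nu_m = nu))$average, 0)
  # report-style bound: varying nu_m over [0.2, 0.5] moves the island
  # average by a bounded fraction of the stress scale
  scale <- sqrt(mean(((syn$stress$sxx + syn$stress$syy) / 2)[syn$domain$mask]^2))
  expect_lt(diff(range(tens)), 0.5 * scale)
})

test_that("principal stresses match the closed forms and the eigen oracle", {
  s_iso <- stress_field(matrix(3, 2, 2), matrix(3, 2, 2), matrix(0, 2, 2), 1)
  p <- principal_stresses(s_iso)
  expect_equal(p$s1, p$s2)
  expect_equal(p$s1[1, 1], 3)
  expect_equal(p$theta[1, 1], 0)  # isotropic: orientation by convention

  s_sh <- stress_field(matrix(0, 1, 1), matrix(0, 1, 1), matrix(2, 1, 1), 1)
  p2 <- principal_stresses(s_sh)
  expect_equal(p2$s1[1, 1], 2)
  expect_equal(p2$s2[1, 1], -2)
  expect_equal(p2$theta[1, 1], pi / 4)

  set.seed(8)
  for (k in 1:25) {
    sxx <- rnorm(1); syy <- rnorm(1); sxy <- rnorm(1)
    p3 <- principal_stresses(stress_field(matrix(sxx, 1, 1),
                                          matrix(syy, 1, 1),
                                          matrix(sxy, 1, 1), 1))
    ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
    expect_equal(p3$s1[1, 1], ev$values[1], tolerance = 1e-12)
    expect_equal(p3$s2[1, 1], ev$values[2], tolerance = 1e-12)
    # orientation maps onto the first eigenvector (up to sign)
    v <- c(cos(p3$theta[1, 1]), sin(p3$theta[1, 1]))
    expect_equal(abs(sum(v * ev$vectors[, 1])), 1, tolerance = 1e-9)
  }
})

test_that("contractile tension equals the tensor trace half", {
  set.seed(10)
  s <- stress_field(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8),
                    matrix(rnorm(64), 8, 8), 1)
  ct <- contractile_tension(s)
  p <- principal_stresses(s)
  expect_equal(ct$field, (p$s1 + p$s2) / 2, tolerance = 1e-14)
  expect_equal(ct$average, mean((s$sxx + s$syy) / 2))
  # pure shear carries no tension
  sh <- stress_field(matrix(0, 2, 2), matrix(0, 2, 2), matrix(5, 2, 2), 1)
  expect_equal(contractile_tension(sh)$average, 0)
})
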