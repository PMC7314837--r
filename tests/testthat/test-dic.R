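test_that("correlation recovers identity and integer shifts", {
  n <- 128
  z <- gridded_field(matrix(0, n, n), matrix(0, n, n), 1)
  a <- unclass(render_speckle_pair(z, density = 0.05, seed = 7)$reference)[, ]
  f0 <- correlate_pair(a, a, subset_size = 32, spacing = 8, pixel_size = 1)
  expect_lt(max(abs(f0$u), abs(f0$v)), 0.05)
  expect_true(all(f0$quality > 0.99))
  # pattern translated by (3, 5) pixels
  b <- matrix(0, n, n); b[6:n, 4:n] <- a[1:(n - 5), 1:(n - 3)]
  f <- correlate_pair(a, b, 32, 8, pixel_size = 1)
  expect_true(all(round(f$u) == 3) && all(round(f$v) == 5))
  expect_lt(max(abs(f$u - 3), abs(f$v - 5)), 0.05)
  # displacements scale with the physical pixel size
  f2 <- correlate_pair(a, b, 32, 8, pixel_size = 0.65)
  expect_equal(f2$u, f$u * 0.65, tolerance = 1e-12)
})

test_that("input validation rejects mismatched or tiny configurations", {
  a <- matrix(runif(64^2), 64, 64)
  expect_error(correlate_pair(a, a[1:32, 1:32]), "dimensions")
  expect_error(correlate_pair(a, a, subset_size = 8), "at least 16")
  expect_error(correlate_pair(a, a, subset_size = 32, spacing = 40),
               "spacing")
  expect_error(correlate_pair(a, a, subset_size = 64, search = 16), "larger")
})

test_that("smooth warps are recovered and correlation is antisymmetric", {
  n <- 192
  warp <- make_warp_field(n, amplitude = 1.5)
  pr <- render_speckle_pair(warp, density = 0.08, spot_sigma = 1.2, seed = 11)
  a <- unclass(pr$reference)[, ]; b <- unclass(pr$deformed)[, ]
  fab <- correlate_pair(a, b, 32, 16, pixel_size = 1)
  tru <- warp_truth_at_nodes(warp, fab)
  err <- sqrt(mean((fab$u - tru$u)^2 + (fab$v - tru$v)^2, na.rm = TRUE))
  expect_lt(err, 0.25)  # single pass, moderate wavelength
  fba <- correlate_pair(b, a, 32, 16, pixel_size = 1)
  expect_lt(sqrt(mean((fab$u + fba$u)^2 + (fab$v + fba$v)^2, na.rm = TRUE)),
            0.2)
})

test_that("quality flagging is monotone in the threshold and inpaintable", {
  n <- 128
  set.seed(9)
  a <- matrix(runif(n * n), n, n)
  b <- matrix(runif(n * n), n, n)  # unrelated images: low correlation
  counts <- vapply(c(0.2, 0.5, 0.8), function(th)
    sum(is.na(correlate_pair(a, b, 32, 16, 1, quality_threshold = th)$u)), 0L)
  expect_true(all(diff(counts) >= 0))
  f <- correlate_pair(a, b, 32, 16, 1, quality_threshold = 0.99)
  filled <- inpaint_field(f)
  expect_false(anyNA(filled$u) || anyNA(filled$v))
})

test_that("stacks correlate in consecutive and fixed-reference modes", {
  n <- 128
  z <- gridded_field(matrix(0, n, n), matrix(0, n, n), 1)
  base <- unclass(render_speckle_pair(z, density = 0.06, seed = 13)$reference)[, ]
  shift_img <- function(img, d) {
    # subpixel x-translation via the analytic generator
    sh <- gridded_field(matrix(d, n, n), matrix(0, n, n), 1)
    unclass(render_speckle_pair(sh, density = 0.06, seed = 13)$deformed)[, ]
  }
  stack <- lapply((0:2) * 1.3, function(d) shift_img(base, d))
  expect_error(correlate_stack(stack[1], "consecutive"), "2 frames")
  vel <- correlate_stack(stack, "consecutive", subset_size = 32, spacing = 16,
                         pixel_size = 1, dt = 10)
  expect_length(vel, 2)
  expect_equal(vel[[1]]$units, "um/min")
  # translating 1.3 px/frame at 1 um/px and dt = 10 min -> 0.13 um/min
  expect_equal(mean(vel[[1]]$u, na.rm = TRUE), 0.13, tolerance = 0.05)
  expect_lt(max(abs(vel[[2]]$v), na.rm = TRUE), 0.01)

  fixed <- correlate_stack(stack, "fixed-reference", reference = stack[[1]],
                           subset_size = 32, spacing = 16, pixel_size = 1)
  expect_length(fixed, 3)
  expect_lt(max(abs(fixed[[1]]$u), na.rm = TRUE), 0.05)  # frame 0 vs itself
  expect_equal(mean(fixed[[3]]$u, na.rm = TRUE), 2.6, tolerance = 0.05)
})
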