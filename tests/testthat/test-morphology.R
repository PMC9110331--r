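test_that("max_diameter matches the all-pairs oracle and trivial cases", {
  expect_equal(max_diameter(rbind(c(0, 0, 0), c(5, 0, 0))), 5)
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 3 * sqrt(3) / 2, 0))
  expect_equal(max_diameter(tri), 3)
  expect_equal(max_diameter(matrix(1, 1, 3)), 0)
  set.seed(8)
  pts <- matrix(rnorm(150), 50, 3)
  brute <- max(vapply(1:49, function(i)
    max(sqrt(colSums((t(pts[(i + 1):50, , drop = FALSE]) - pts[i, ])^2))),
    numeric(1)))
  expect_equal(max_diameter(pts), brute)
})

test_that("clusters spanning the periodic wall are unwrapped before geometry", {
  cage <- build_theta_cage(c(2, 2, 3))
  fr0 <- cage$frame
  g0 <- detect_hbonds(fr0)
  sh0 <- cluster_shapes(run_pipeline(fr0, stages = "shapes")$frames[[1]]$clusters,
                        fr0, g0, alpha_radius = Inf)
  # shift the cage across the box corner; wrapped coordinates fragment it
  fr1 <- translate_frame(fr0, c(14.5, 14.5, 14.5))
  fr1$oxygen <- aquaclust:::wrap_positions(fr1$oxygen, fr1$box)
  fr1$hydrogen <- aquaclust:::wrap_positions(fr1$hydrogen, fr1$box)
  g1 <- detect_hbonds(fr1)
  cl1 <- run_pipeline(fr1, stages = "shapes")$frames[[1]]$clusters
  sh1 <- cluster_shapes(cl1, fr1, g1, alpha_radius = Inf)
  expect_equal(sh1$L, sh0$L, tolerance = 1e-9)
  expect_equal(sh1$V, sh0$V, tolerance = 1e-9)
})

test_that("analytic shape factors match their closed forms", {
  expect_equal(shape_factor_reference("sphere"), 1.576, tolerance = 1e-3)
  expect_equal(shape_factor_reference("cube"), 1.792, tolerance = 1e-3)
  expect_equal(shape_factor_reference("tetrahedron"), 1.976, tolerance = 1e-3)
  expect_error(shape_factor_reference("torus"))
})

test_that("surface-volume fit recovers ideal-sphere scaling exactly", {
  rr <- c(1.5, 2, 3, 8, 16, 32)
  shapes <- data.frame(V = 4 / 3 * pi * rr^3, A = 4 * pi * rr^2)
  f <- surface_volume_fit(shapes, split_volume = 150)
  expect_equal(f$small$a, 2 / 3, tolerance = 1e-9)
  expect_equal(f$small$b, shape_factor_reference("sphere"), tolerance = 1e-9)
  expect_equal(f$large$a, 2 / 3, tolerance = 1e-9)
  # synthetic line with tiny noise
  set.seed(3)
  lv <- runif(40, 0, 8)
  shapes2 <- data.frame(V = exp(lv), A = exp(0.7 * lv + 0.5 + rnorm(40, 0, 1e-4)))
  f2 <- surface_volume_fit(shapes2, split_volume = 100)
  expect_equal(f2$small$a, 0.7, tolerance = 1e-3)
  expect_equal(f2$small$b, 0.5, tolerance = 1e-3)
  expect_equal(f2$large$a, 0.7, tolerance = 1e-3)
  # a regime with a single point is skipped with a warning
  expect_warning(f3 <- surface_volume_fit(shapes[1:3, ], split_volume = 150),
                 "skipped")
  expect_null(f3$large)
})

test_that("power-law exponent recovery has small bias across tau", {
  for (tau in c(2.0, 2.44, 3.0)) {
    s <- sample_cluster_sizes(tau, s_min = 10, n = 1e5, seed = 31 + tau * 10)
    est <- powerlaw_exponent(s, fit_min_size = 10)
    expect_equal(est$tau, tau, tolerance = 0.05 / tau)  # bias < 0.05
    est_mle <- powerlaw_exponent(s, fit_min_size = 10, method = "mle")
    expect_equal(est_mle$tau, tau, tolerance = 0.02 / tau)
  }
  expect_error(powerlaw_exponent(rep(7L, 100), fit_min_size = 1), "fit error")
})

test_that("radius scaling of ideal spheres gives d_V = 3 and d_S = 2", {
  rr <- c(1, 2, 4, 8)
  shapes <- data.frame(V = 4 / 3 * pi * rr^3, A = 4 * pi * rr^2, r = rr)
  f <- radius_scaling_fit(shapes)
  expect_equal(f$d_V, 3, tolerance = 1e-9)
  expect_equal(f$d_S, 2, tolerance = 1e-9)
  # synthetic exponent
  shapes2 <- data.frame(V = rr^2.9, A = rr^2.1, r = rr)
  f2 <- radius_scaling_fit(shapes2)
  expect_equal(f2$d_V, 2.9, tolerance = 1e-9)
  expect_error(radius_scaling_fit(shapes[1, ]), "fit error")
  expect_error(radius_scaling_fit(data.frame(V = 1:4, A = 1:4, r = rep(2, 4))),
               "degenerate")
})

test_that("distribution crossings locate the isosbestic point", {
  x <- seq(-4, 6, by = 0.01)
  g1 <- dnorm(x, 0, 1)
  g2 <- dnorm(x, 2, 1)
  cr <- distribution_crossing(x, g1, g2, smooth_window = 1)
  expect_length(cr$crossings, 1L)
  expect_equal(cr$crossings, 1.0, tolerance = 1e-3)
  # identical distributions: nothing found
  expect_length(distribution_crossing(x, g1, g1)$crossings, 0L)
  # constant ratio: no crossing either
  expect_length(distribution_crossing(x, g1, 2 * g1)$crossings, 0L)
  # smoothing suppresses single-bin noise flips
  set.seed(5)
  noisy1 <- g1 + rnorm(length(x), 0, 1e-4)
  cr2 <- distribution_crossing(x, noisy1, g2, smooth_window = 9)
  expect_true(any(abs(cr2$crossings - 1.0) < 0.05))
})
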