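test_that("LSI reproduces the hand-evaluated gap variance", {
  # four neighbors at 2.8 A and the next at 4.5 A:
  # gaps (0, 0, 0, 1.7), mean 0.425, variance 0.541875
  o <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(0, 2.8, 0), c(-2.8, 0, 0),
             c(0, -2.8, 0), c(0, 0, 4.5))
  fr <- frame_from_oxygens(o, box = c(60, 60, 60))
  res <- lsi(fr, 1)
  expect_equal(res$n, 4L)
  expect_equal(res$lsi, 0.541875, tolerance = 1e-12)
  expect_equal(res$mean_gap, 0.425, tolerance = 1e-12)
  # ordering invariant r_1 < ... <= r_n < cutoff
  expect_true(all(diff(res$r) >= 0))
})

test_that("LSI degenerate shells behave as defined", {
  # evenly spaced shell: all gaps equal (including the one straddling the
  # cutoff), variance 0
  o <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(0, 3.0, 0), c(-3.2, 0, 0),
             c(0, -3.4, 0), c(0, 0, 3.6), c(0, 0, -3.8))
  fr <- frame_from_oxygens(o, box = c(60, 60, 60))
  expect_equal(lsi(fr, 1)$lsi, 0, tolerance = 1e-12)
  # a single neighbor inside the shell: one gap equals its mean
  o2 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 0, 6))
  expect_equal(lsi(frame_from_oxygens(o2, box = c(60, 60, 60)), 1)$lsi, 0)
  # no neighbor inside the cutoff: undefined
  o3 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  expect_null(lsi(frame_from_oxygens(o3, box = c(60, 60, 60)), 1))
  expect_true(is.na(lsi_profile(frame_from_oxygens(o3, c(60, 60, 60)))[1]))
})

test_that("probe-sphere counts on a lattice equal the direct lattice count", {
  # simple cubic lattice at spacing a (bulk density 0.0334): every probe
  # centered on a site sees the same periodic environment, so rho_local is
  # uniform and equals (direct count inside the sphere) / probe volume
  a <- (1 / 0.0334)^(1 / 3)
  lat <- as.matrix(expand.grid(0:9, 0:9, 0:9)) * a
  fr <- frame_from_oxygens(lat, box = rep(10 * a, 3))
  g <- detect_hbonds(fr)
  prof <- local_density_profile(fr, seq_len(125), g, probe_radius = 4.6,
                                bin_width = 2)
  # independent count: lattice offsets within 4.6/a units of a site
  offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  count <- sum(sqrt(rowSums(offs^2)) * a < 4.6)
  rho_want <- count / (4 / 3 * pi * 4.6^3)
  expect_true(all(abs(prof$rho_local - rho_want) < 1e-9))
  # continuum check: probes at generic off-lattice positions see ~bulk
  set.seed(3)
  shift_fr <- fr
  probes_ok <- vapply(1:40, function(k) {
    p <- runif(3) * fr$box
    d <- sqrt(rowSums(minimum_image_displacement(
      matrix(p, nrow(lat), 3, byrow = TRUE), lat, fr$box)^2))
    sum(d < 4.6)
  }, numeric(1))
  expect_equal(mean(probes_ok) / (4 / 3 * pi * 4.6^3), 0.0334,
               tolerance = 0.1)
  # probe radius beyond half box
  expect_error(local_density_profile(fr, 1:8, g, probe_radius = 200),
               "half")
})

test_that("doubling coordinates and box scales probe density by 1/8", {
  cage <- build_theta_cage(c(2, 2, 3))
  fr <- cage$frame
  g <- detect_hbonds(fr)
  p1 <- local_density_profile(fr, 1:6, g, probe_radius = 4.6, bin_width = 10)
  fr2 <- fr
  fr2$oxygen <- fr$oxygen * 2
  fr2$hydrogen <- fr$hydrogen * 2
  fr2$box <- fr$box * 2
  g2 <- detect_hbonds(fr2)  # bonds break, but probes only need oxygens
  p2 <- local_density_profile(fr2, 1:6, hbond_graph_from_edges(6, NULL),
                              probe_radius = 9.2, bin_width = 20)
  # same oxygen counts in a probe of doubled radius: density / 8
  expect_equal(sum(p2$rho_local * p2$n_probes) / sum(p2$n_probes),
               sum(p1$rho_local * p1$n_probes) / sum(p1$n_probes) / 8,
               tolerance = 1e-9)
})

test_that("rdf of an ideal-gas configuration is flat at 1", {
  set.seed(12)
  box <- c(25, 25, 25)
  pts <- matrix(runif(3 * 1500), 1500, 3) * 25
  g <- rdf(NULL, pts, r_max = 10, bin_width = 0.5, box = box)
  expect_true(all(abs(g$g[g$r > 2] - 1) < 0.15))
  # integral test: expected neighbor count within r_max
  rho <- 1500 / prod(box)
  neigh <- sum(g$g * rho * 4 * pi * g$r^2 * 0.5)
  expect_equal(neigh, rho * 4 / 3 * pi * 10^3, tolerance = 0.05)
})

test_that("rdf of a cubic lattice peaks at the lattice spacing", {
  lat <- as.matrix(expand.grid(0:5, 0:5, 0:5)) * 3
  g <- rdf(NULL, lat, r_max = 8.5, bin_width = 0.25, box = c(18, 18, 18))
  first_peak <- g$r[which(g$g > 0)[1]]
  expect_lt(abs(first_peak - 3), 0.25)
  expect_error(rdf(NULL, lat[1, , drop = FALSE], r_max = 8,
                   box = c(18, 18, 18)), "empty selection")
})
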