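test_that("water_frame enforces composition and box invariants", {
  o <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  h6 <- matrix(rnorm(18, sd = 0.1), 6, 3) +
    o[rep(1:3, each = 2), ] + c(0.9)
  fr <- water_frame(o, h6, rep(1:3, each = 2), c(10, 10, 10))
  expect_s3_class(fr, "water_frame")
  expect_equal(n_molecules(fr), 3L)
  # 5 hydrogens for 3 oxygens
  expect_error(water_frame(o, h6[1:5, ], c(1, 1, 2, 2, 3), c(10, 10, 10)),
               "composition")
  # wrong per-molecule ownership
  expect_error(water_frame(o, h6, c(1, 1, 1, 1, 3, 3), c(10, 10, 10)),
               "composition")
  expect_error(water_frame(o, h6, rep(1:3, each = 2), c(10, -1, 10)),
               "box")
})

test_that("minimum image wraps into [-box/2, box/2) and matches the 27-image oracle", {
  box <- c(10, 10, 10)
  expect_equal(minimum_image_displacement(c(1, 0, 0), c(9, 0, 0), box),
               c(-2, 0, 0))
  expect_equal(minimum_image_displacement(c(3, 4, 5), c(3, 4, 5), box),
               c(0, 0, 0))
  set.seed(11)
  for (k in 1:1000) {
    bx <- runif(3, 4, 15)
    p <- runif(3) * bx
    q <- runif(3) * bx
    got <- minimum_image_displacement(p, q, bx)
    want <- oracle_min_image(p, q, bx)
    expect_equal(sqrt(sum(got^2)), sqrt(sum(want^2)), tolerance = 1e-12)
    expect_true(all(got >= -bx / 2 - 1e-12) && all(got < bx / 2 + 1e-12))
    expect_lte(sqrt(sum(got^2)), sqrt(3) / 2 * max(bx) + 1e-12)
  }
})

test_that("trajectory round-trips preserve coordinates to format precision", {
  cage <- build_theta_cage(c(2, 2, 3))
  tol <- c(xyz = 1e-6, gro = 0.006, `lammps-dump` = 1e-6)
  for (fmt in c("xyz", "gro", "lammps-dump")) {
    f <- tempfile()
    write_frames(cage$frame, f, fmt)
    back <- read_frames(f, fmt)
    expect_length(back, 1L)
    fr2 <- back[[1]]
    expect_equal(n_molecules(fr2), 6L)
    # reader may reorder hydrogens; compare oxygens and the H multiset
    expect_lt(max(abs(fr2$oxygen - cage$frame$oxygen)), tol[[fmt]])
    expect_equal(fr2$box, cage$frame$box, tolerance = 1e-6)
    d1 <- sort(round(as.vector(fr2$hydrogen), 2))
    d2 <- sort(round(as.vector(cage$frame$hydrogen), 2))
    expect_equal(d1, d2, tolerance = 0.02)
  }
})

test_that("malformed trajectory files fail with informative parse errors", {
  f <- tempfile()
  writeLines(c("3", "box 10 10 10", "O 0 0 0", "H 1 0 0"), f)
  expect_error(read_frames(f, "xyz"), "truncated|parse")
  # 3 O and 5 H: composition error
  writeLines(c("8", "box 20 20 20",
               "O 0 0 0", "O 3 0 0", "O 0 3 0",
               "H 0.9 0 0", "H -0.3 0.9 0", "H 3.9 0 0", "H 2.7 0.9 0",
               "H 0.9 3 0"), f)
  expect_error(read_frames(f, "xyz"), "composition")
  # xyz without box anywhere
  writeLines(c("1", "no numbers here", "O 0 0 0"), f)
  expect_error(read_frames(f, "xyz"), "box")
  # triclinic gro
  writeLines(c("t", "1", sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                 1L, "SOL", "OW", 1L, 0.5, 0.5, 0.5),
              "2.0 2.0 2.0 0.0 0.0 0.5 0.0 0.0 0.0"), f)
  expect_error(read_frames(f, "gro"), "riclinic")
})

test_that("hydrogens are assigned to the nearest oxygen under minimum image", {
  # molecule straddling the periodic boundary: H near 0, O near box edge
  o <- rbind(c(9.8, 5, 5), c(5, 5, 5))
  h <- rbind(c(0.3, 5, 5),        # belongs to molecule 1 through the wall
             c(9.8, 5.9, 5), c(5.9, 5, 5), c(5, 5.9, 5))
  f <- tempfile()
  writeLines(c("6", "box 10 10 10",
               sprintf("O %f %f %f", o[, 1], o[, 2], o[, 3]),
               sprintf("H %f %f %f", h[, 1], h[, 2], h[, 3])), f)
  fr <- read_frames(f, "xyz")[[1]]
  expect_equal(fr$h_owner, c(1L, 1L, 2L, 2L))
})

test_that("rigid translation leaves the downstream bond graph unchanged", {
  cage <- build_theta_cage(c(3, 3, 4))
  g0 <- detect_hbonds(cage$frame)
  for (shift in list(c(30, 0, 0), c(-30, 30, 30), c(7.7, -13.2, 4.1))) {
    g1 <- detect_hbonds(translate_frame(cage$frame, shift))
    expect_equal(g1$edges[, c("i", "j")], g0$edges[, c("i", "j")])
  }
})

test_that("trajectory_settings validates its thresholds", {
  s <- trajectory_settings()
  expect_equal(s$hb_cutoff, 2.5)
  expect_equal(s$frame_interval, 10.0)
  expect_equal(s$alpha_radius, 3.5)
  expect_error(trajectory_settings(max_ring_size = 2), "max_ring_size")
  expect_error(trajectory_settings(hb_cutoff = -1), "positive")
})
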