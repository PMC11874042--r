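test_that("two-sphere union handles containment, overlap and disjoint limits", {
  r <- 2.7
  expect_equal(two_sphere_union_volume(r, r, 0), 4 / 3 * pi * r^3)
  expect_equal(two_sphere_union_volume(r, r, 2 * r), 2 * 4 / 3 * pi * r^3)
  expect_equal(two_sphere_union_volume(r, r, 5 * r), 2 * 4 / 3 * pi * r^3)
  # lens formula for equal radii: pi (4r + d) (2r - d)^2 / 12
  expect_equal(two_sphere_union_volume(2.7, 2.7, 2.7),
               2 * 4 / 3 * pi * 2.7^3 -
                 pi * (4 * 2.7 + 2.7) * (2 * 2.7 - 2.7)^2 / 12)
  expect_equal(two_sphere_union_volume(2.7, 2.7, 2.7), 139.1309,
               tolerance = 1e-6)
  # asymmetric containment
  expect_equal(two_sphere_union_volume(3, 1, 0.5), 4 / 3 * pi * 27)
  # continuity at the touching point
  expect_equal(two_sphere_union_volume(2, 1, 3 - 1e-9),
               two_sphere_union_volume(2, 1, 3), tolerance = 1e-7)
  expect_error(two_sphere_union_volume(-1, 1, 1), "must be")
})

test_that("Monte-Carlo estimator is unbiased against analytic unions", {
  m <- mc_volume(h_atom(), n_samples = 1e6, seed = 5)
  expect_equal(m$value, 4 / 3 * pi * R_H^3, tolerance = 0.01)
  expect_lt(abs(m$value - 4 / 3 * pi * R_H^3), 3 * m$stderr)
  # deterministic per seed, and does not disturb the caller RNG
  set.seed(99); before <- runif(1)
  m2 <- mc_volume(h_atom(), n_samples = 1e5, seed = 12)
  m3 <- mc_volume(h_atom(), n_samples = 1e5, seed = 12)
  expect_identical(m2$value, m3$value)
  set.seed(99)
  expect_identical(runif(1), before)
  # within 3 sigma in most repeats on the lens case
  ok <- vapply(1:20, function(sd) {
    mm <- mc_volume(h_pair(2.7), n_samples = 1e5, seed = sd)
    abs(mm$value - two_sphere_union_volume(R_H, R_H, 2.7)) <= 3 * mm$stderr
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("finite-difference gradient is exact for linear probes", {
  m <- random_cluster(4, seed = 1)
  expect_equal(fd_gradient(function(x) 42, m), matrix(0, 4, 3))
  a <- matrix(seq(0.1, 1.2, length.out = 12), 4, 3)
  expect_equal(fd_gradient(function(x) sum(a * x$coords), m), a,
               tolerance = 1e-9)
})

test_that("geometry builders reproduce their internal coordinates", {
  for (case in list(list("trans", 180), list("gauche", 68))) {
    m <- build_dce(case[[1]])
    expect_equal(abs(measure_dihedral(m, 3, 1, 2, 4)), case[[2]],
                 tolerance = 1e-8)
    d <- function(i, j) sqrt(sum((m$coords[i, ] - m$coords[j, ])^2))
    expect_equal(d(1, 2), 1.52, tolerance = 1e-10)
    expect_equal(d(1, 3), 1.79, tolerance = 1e-10)
    expect_equal(d(2, 7), 1.09, tolerance = 1e-10)
  }
  expect_equal(measure_dihedral(build_dce(dihedral_override = 120),
                                3, 1, 2, 4), 120, tolerance = 1e-8)
  b <- build_butane(60)
  expect_equal(measure_dihedral(b, 1, 2, 3, 4), 60, tolerance = 1e-8)
})

test_that("random clusters are dense, well-separated and reproducible", {
  for (n in c(2, 8, 20)) {
    cl <- random_cluster(n, seed = 3)
    expect_equal(n_atoms(cl), n)
    if (n > 1) {
      dm <- as.matrix(dist(cl$coords))
      expect_gte(min(dm[upper.tri(dm)]), 1.0)
      # dense enough that solvent-accessible spheres overlap
      r <- solvent_accessible_radius(cl$symbols, probe = 1.5)
      touch <- outer(r, r, "+")
      expect_true(any(dm[upper.tri(dm)] < touch[upper.tri(touch)]))
    }
    expect_identical(random_cluster(n, seed = 3)$coords, cl$coords)
  }
})

test_that("rigid bond rotation changes only the requested dihedral", {
  b <- build_butane(180)
  rot <- rotate_about_bond(b, 2, 3, c(4, 12, 13, 14), -120)
  expect_equal(measure_dihedral(rot, 1, 2, 3, 4), 60, tolerance = 1e-8)
  # bond lengths preserved
  d34 <- function(m) sqrt(sum((m$coords[3, ] - m$coords[4, ])^2))
  expect_equal(d34(rot), d34(b), tolerance = 1e-12)
  # untouched atoms identical
  expect_identical(rot$coords[1:3, ], b$coords[1:3, ])
})

test_that("torsion-scan noise falls with grid density", {
  b <- build_butane()
  res <- torsion_scan_noise(b, c(1, 2, 3, 4), moving = c(4, 12, 13, 14),
                            grid_orders = c(110, 302),
                            model = pressure_model(pressure = 5),
                            step_deg = 15)
  expect_named(res$noise, c("110", "302"))
  expect_gt(res$noise[["110"]], res$noise[["302"]])
  expect_true(all(res$profiles >= 0))
  expect_equal(ncol(res$profiles), 2L)
})
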