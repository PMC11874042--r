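test_that("switching function honors boundary, midpoint and cubic values", {
  r <- 2.7; w <- 0.3
  expect_equal(switching_value(r - w, r, w)$value, 0)
  expect_equal(switching_value(r + w, r, w)$value, 1)
  expect_equal(switching_value(r, r, w)$value, 0.5)
  expect_equal(switching_value(2.85, 2.7, 0.3)$value, 0.84375)
  expect_equal(switching_value(c(0, r, 10), r, w)$value, c(0, 0.5, 1))
  # plateau derivatives vanish; interior derivative matches the cubic
  expect_equal(switching_value(c(0, 10), r, w)$deriv, c(0, 0))
  x <- seq(r - w + 1e-3, r + w - 1e-3, length.out = 11)
  fd <- (switching_value(x + 1e-7, r, w)$value -
           switching_value(x - 1e-7, r, w)$value) / 2e-7
  expect_lt(max(abs(switching_value(x, r, w)$deriv - fd)), 1e-6)
})

test_that("surface grids tile each atomic sphere exactly", {
  mol <- build_dce("gauche")
  surf <- build_surface(mol, n_points = 302)
  expect_equal(length(surf$owner), 8 * 302)
  expect_setequal(unique(surf$owner), 1:8)
  for (j in seq_len(n_atoms(mol))) {
    sel <- surf$owner == j
    expect_equal(sum(surf$area[sel]), 4 * pi * surf$r_sa[j]^2,
                 tolerance = 1e-10)
    d <- sqrt(rowSums((surf$points[sel, ] -
                         matrix(mol$coords[j, ], sum(sel), 3, TRUE))^2))
    expect_lt(max(abs(d - surf$r_sa[j])), 1e-12)
  }
})

test_that("probe radius rescales positions but not normals", {
  m <- h_atom()
  s0 <- build_surface(m, probe = 0, n_points = 110)
  s1 <- build_surface(m, probe = 1.5, n_points = 110)
  expect_equal(s0$normals, s1$normals)
  expect_equal(s1$points / 2.70, s0$points / 1.20, tolerance = 1e-12)
})

test_that("exposure of an isolated atom is total and of a buried point zero", {
  s <- build_surface(h_atom(), n_points = 302)
  e <- exposure(s)
  expect_true(all(e$H == 1))
  expect_equal(e$sasa, 4 * pi * R_H^2, tolerance = 1e-12)
  # a tiny sphere fully inside a big one: every small-sphere point buried
  big <- radii_set("custom", custom = c(A = 5, B = 0.5))
  m <- molecule(c("A", "B"), matrix(0, 2, 3))
  s2 <- build_surface(m, radii = big, probe = 0, n_points = 110)
  e2 <- exposure(s2)
  expect_true(all(e2$H[s2$owner == 2] == 0))
  expect_true(all(e2$H[s2$owner == 1] == 1))
})

test_that("two coincident identical atoms give exposure one half everywhere", {
  s <- build_surface(molecule(c("H", "H"), matrix(0, 2, 3)), n_points = 590)
  e <- exposure(s)
  # every point sits at distance r_SA (to rounding) from the other center
  expect_lt(max(abs(e$H - 0.5)), 1e-12)
})

test_that("neighbor cutoff changes nothing", {
  for (seed in c(3, 17)) {
    cl <- random_cluster(6, seed = seed)
    s <- build_surface(cl, n_points = 110)
    expect_lt(max(abs(exposure(s, use_cutoff = TRUE)$H -
                        exposure(s, use_cutoff = FALSE)$H)), 1e-14)
  }
})

test_that("SASA decreases monotonically as two atoms approach", {
  dists <- seq(2 * R_H + 0.3, 0.05, length.out = 20)
  sasas <- vapply(dists, function(d) grid_sasa(h_pair(d), n_points = 302),
                  numeric(1))
  expect_true(all(diff(sasas) <= 1e-10))
  expect_equal(sasas[1], 2 * 4 * pi * R_H^2, tolerance = 1e-12)
})

test_that("analytical SASA gradient matches finite differences", {
  for (case in list(list(n = 2, seed = 21), list(n = 3, seed = 11))) {
    cl <- random_cluster(case$n, seed = case$seed)
    surf <- build_surface(cl, n_points = 302)
    expo <- exposure(surf)
    fd <- fd_gradient(function(m) grid_sasa(m, n_points = 302), cl, h = 1e-4)
    expect_lt(max(abs(sasa_gradient(surf, expo) - fd)), 1e-5)
  }
})
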