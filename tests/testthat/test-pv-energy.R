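test_that("isolated spheres integrate to exact volume and area", {
  for (el in c("H", "C", "O", "Cl")) {
    r <- solvent_accessible_radius(el, probe = 1.5)
    m <- molecule(el, matrix(c(1, -2, 0.5), 1, 3))
    for (np in c(110, 1202)) {
      surf <- build_surface(m, probe = 1.5, n_points = np)
      expo <- exposure(surf)
      expect_equal(sav_volume(surf, expo), 4 / 3 * pi * r^3,
                   tolerance = 1e-10)
      expect_equal(expo$sasa, 4 * pi * r^2, tolerance = 1e-10)
    }
  }
})

test_that("far-separated atoms add volumes; coincident ones do not", {
  v1 <- grid_volume(h_atom())
  expect_equal(grid_volume(h_pair(2 * R_H + 0.7)), 2 * v1, tolerance = 1e-10)
  expect_equal(grid_volume(molecule(c("H", "H"), matrix(0, 2, 3))), v1,
               tolerance = 1e-10)
})

test_that("overlapping pair volume matches the closed-form union", {
  v <- grid_volume(h_pair(2.7))
  expect_equal(v, two_sphere_union_volume(R_H, R_H, 2.7), tolerance = 0.015)
})

test_that("grid volume agrees with hard-sphere Monte Carlo on clusters", {
  for (sd in c(1, 4, 9)) {
    cl <- random_cluster(2 + sd %% 5, seed = 40 + sd)
    v <- grid_volume(cl)
    mc <- mc_volume(cl, n_samples = 2e5, seed = 70 + sd)
    expect_lt(abs(v - mc$value), 3 * mc$stderr + 0.02 * v)
  }
})

test_that("analytic volume gradient matches finite differences", {
  cases <- expand.grid(np = c(302, 1202), w = c(0.1, 0.3))
  for (k in seq_len(nrow(cases))) {
    np <- cases$np[k]; w <- cases$w[k]
    cl <- random_cluster(5, seed = 7)
    surf <- build_surface(cl, n_points = np)
    expo <- exposure(surf, w = w)
    fd <- fd_gradient(function(m) grid_volume(m, n_points = np, w = w), cl)
    g <- sav_volume_gradient(surf, expo)
    expect_lt(max(abs(g - fd)), 1e-5)
    expect_lt(max(abs(colSums(g))), 1e-10)       # translation invariance
  }
  # isolated atom: zero gradient by symmetry
  s <- build_surface(h_atom(), n_points = 302)
  expect_lt(max(abs(sav_volume_gradient(s, exposure(s)))), 1e-12)
})

test_that("volume is rotation invariant and monotone in the probe radius", {
  cl <- random_cluster(10, seed = 5)
  v0 <- grid_volume(cl)
  set.seed(42)
  for (k in 1:10) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    rot <- cl; rot$coords <- cl$coords %*% q
    expect_lt(abs(grid_volume(rot) - v0) / v0, 1e-3)
  }
  vols <- vapply(c(0.5, 1.0, 1.5), function(p) grid_volume(cl, probe = p),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("X-HCFF gradient is the exposure-weighted surface force", {
  s <- build_surface(h_atom(), n_points = 302)
  e <- exposure(s)
  expect_lt(max(abs(xhcff_gradient(s, e, 3))), 1e-12)   # symmetry
  expect_equal(xhcff_gradient(s, e, 0), matrix(0, 1, 3)) # P = 0
  # on overlapping clusters it approximates the PV gradient with a
  # characteristic 10-30 percent mean per-atom norm deviation
  devs <- vapply(1:4, function(sd) {
    cl <- random_cluster(20, seed = sd)
    s <- build_surface(cl); e <- exposure(s)
    gx <- xhcff_gradient(s, e, 1)
    gp <- pv_units$gpa_A3_to_hartree * sav_volume_gradient(s, e)
    mean(sqrt(rowSums((gx - gp)^2)) / sqrt(rowSums(gp^2)))
  }, numeric(1))
  expect_true(all(devs > 0.05 & devs < 0.35))
})

test_that("pv_terms assembles energy, gradient and metadata per mode", {
  h <- h_atom()
  res0 <- pv_terms(h, pressure_model(pressure = 0))
  expect_equal(res0$pv_energy, 0)
  expect_equal(res0$gradient, matrix(0, 1, 3))
  expect_gt(res0$volume, 0)

  res1 <- pv_terms(h, pressure_model(pressure = 1))
  expect_equal(res1$pv_energy, 82.4477 * 2.293712e-4, tolerance = 1e-5)
  expect_equal(res1$pv_energy, convert_pv_energy(res1$volume))

  resx <- pv_terms(h, pressure_model(pressure = 1, mode = "xhcff"))
  expect_equal(resx$volume, res1$volume)
  expect_lt(max(abs(resx$gradient)), 1e-12)

  # modes differ on an overlapping dimer but share the volume
  dim2 <- h_pair(2.7)
  ra <- pv_terms(dim2, pressure_model(pressure = 2, n_points = 302))
  rx <- pv_terms(dim2, pressure_model(pressure = 2, n_points = 302,
                                      mode = "xhcff"))
  expect_equal(ra$volume, rx$volume)
  expect_gt(max(abs(ra$gradient - rx$gradient)), 1e-6)
})

test_that("enthalpy couples the PV term to a pluggable backend", {
  h <- h_atom()
  r0 <- enthalpy_with_backend(h, pressure_model(pressure = 0))
  expect_equal(r0$enthalpy, 0)
  r1 <- enthalpy_with_backend(h, pressure_model(pressure = 1))
  expect_equal(r1$enthalpy, 1.8911e-2, tolerance = 1e-4)
  expect_equal(r1$enthalpy, r1$e_el + r1$pv$pv_energy)

  expect_error(enthalpy_with_backend(h, pressure_model(),
                                     backend = function(m) stop("boom")),
               "backend failed")
  expect_error(enthalpy_with_backend(h, pressure_model(),
                                     backend = function(m) list(a = 1)),
               "must return")
})

test_that("pressure compresses a harmonic dimer below its zero-P minimum", {
  k <- 0.1; d0 <- 3.0
  backend <- function(m) {
    dv <- m$coords[2, ] - m$coords[1, ]
    d <- sqrt(sum(dv^2)); u <- dv / d
    g <- k * (d - d0)
    list(energy = 0.5 * k * (d - d0)^2, gradient = rbind(-g * u, g * u))
  }
  ds <- seq(2.0, 3.5, by = 0.05)
  argmin_d <- function(P) {
    hs <- vapply(ds, function(d) {
      enthalpy_with_backend(h_pair(d),
                            pressure_model(pressure = P, n_points = 302),
                            backend)$enthalpy
    }, numeric(1))
    ds[which.min(hs)]
  }
  expect_equal(argmin_d(0), d0)
  expect_lt(argmin_d(5), d0)
})

test_that("numerical PV Hessian is symmetric and translation invariant", {
  tri <- random_cluster(3, seed = 2)
  model <- pressure_model(pressure = 1, n_points = 302)
  expect_error(pv_hessian(tri, pressure_model(mode = "xhcff", pressure = 1)),
               "pv_analytic")
  hz <- pv_hessian(tri, pressure_model(pressure = 0, n_points = 110))
  expect_equal(max(abs(hz)), 0)
  hess <- pv_hessian(tri, model)
  expect_equal(hess, t(hess))
  expect_true(is.numeric(attr(hess, "max_asymmetry")))
  # rigid translations are zero modes: row sums over same-axis blocks vanish
  for (d in 1:3)
    expect_lt(max(abs(rowSums(hess[, seq(d, ncol(hess), by = 3)]))), 1e-6)
})
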