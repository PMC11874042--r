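test_that("XYZ parsing handles minimal, malformed and multi-frame input", {
  m <- read_xyz(c("1", "lone hydrogen", "H 0 0 0"))
  expect_equal(n_atoms(m), 1L)
  expect_equal(m$symbols, "H")
  expect_equal(m$comment, "lone hydrogen")

  expect_error(read_xyz(c("3", "", "H 0 0 0", "H 1 0 0")), "atom lines")
  expect_error(read_xyz(c("2", "", "H 0 0 0", "H 1 0 zzz")), "non-numeric")
  expect_error(read_xyz(c("x", "", "H 0 0 0")), "atom count")
  expect_error(read_xyz(c("1", "", "1.0 0 0 0")), "symbol")

  expect_warning(read_xyz(c("1", "f1", "H 0 0 0", "1", "f2", "He 0 0 0")),
                 "first frame")
})

test_that("XYZ write/read round-trips coordinates and comments", {
  set.seed(1)
  for (rep in 1:3) {
    m <- molecule(sample(c("H", "C", "O", "Cl"), 20, replace = TRUE),
                  matrix(rnorm(60, sd = 4), 20, 3), comment = "round trip")
    back <- read_xyz(write_xyz(m))
    expect_identical(back$symbols, m$symbols)
    expect_identical(back$comment, m$comment)
    expect_lt(max(abs(back$coords - m$coords)), 1e-9)
  }
  dce <- build_dce("gauche")
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(dce, f)
  expect_lt(max(abs(read_xyz(f)$coords - dce$coords)), 1e-9)
})

test_that("molecule constructor rejects degenerate input", {
  expect_error(molecule(character(), matrix(0, 0, 3)), "at least one atom")
  expect_error(molecule("", matrix(0, 1, 3)), "empty")
  expect_error(molecule("H", matrix(Inf, 1, 3)), "finite")
  expect_error(molecule(c("H", "H"), matrix(0, 1, 3)), "N x 3")
})

test_that("solvent-accessible radius is r_vdW + probe and fails for unknowns", {
  b <- radii_set("bondi")
  expect_equal(solvent_accessible_radius("H", b, 1.5), 2.70)
  expect_equal(solvent_accessible_radius("C", b, 0), 1.70)
  expect_equal(solvent_accessible_radius(c("O", "Cl"), b, 1.0),
               c(1.52 + 1, 1.75 + 1))
  expect_error(solvent_accessible_radius("Xx", b), "supported")
  expect_error(radii_set("custom", custom = c(H = -1)), "positive")
  custom <- radii_set("custom", custom = c(Q = 2.0))
  expect_equal(solvent_accessible_radius("Q", custom, 0.5), 2.5)
})

test_that("unit conversions carry CODATA values and are linear", {
  expect_equal(convert_pv_energy(0), 0)
  expect_equal(convert_pv_energy(1), 2.293712e-4, tolerance = 1e-6)
  expect_equal(convert_pv_energy(100), 100 * convert_pv_energy(1))
  # invertibility
  x <- c(0.1, 1, 82.45, 1e4)
  expect_lt(max(abs(convert_pv_energy(x) / pv_units$gpa_A3_to_hartree - x) / x),
            1e-12)
  expect_equal(100 * pv_units$A3_to_cm3_per_mol, 60.2214076, tolerance = 1e-7)
})
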