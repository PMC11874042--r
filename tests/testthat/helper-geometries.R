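# Shared helpers: short-hand constructors and a one-call volume/SASA
# pipeline used across the test files.

h_atom <- function() molecule("H", matrix(0, 1, 3))

h_pair <- function(d) molecule(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))

grid_volume <- function(mol, probe = 1.5, n_points = 1202, w = 0.3) {
  surf <- build_surface(mol, probe = probe, n_points = n_points)
  sav_volume(surf, exposure(surf, w = w))
}

grid_sasa <- function(mol, probe = 1.5, n_points = 1202, w = 0.3) {
  surf <- build_surface(mol, probe = probe, n_points = n_points)
  exposure(surf, w = w)$sasa
}

# solvent-accessible radius of hydrogen at the default probe
R_H <- 1.20 + 1.5
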