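# Independent references and synthetic geometry generators.  Everything
# here is deliberately naive (hard sphere boundaries, brute-force finite
# differences) so it can serve as an oracle for the smooth grid machinery
# without sharing any code path with it.

#' Monte-Carlo volume of a union of hard spheres
#'
#' Uniform rejection sampling in the bounding box of all solvent-accessible
#' spheres; a sample is a hit when it falls inside any sphere (hard
#' boundary, no switching).  The estimate is box volume times hit fraction
#' with a binomial standard error.  Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param mol a \code{molecule}.
#' @param radii a \code{radii_set}.
#' @param probe probe radius, Angstrom.
#' @param n_samples number of samples (>= 1e4).
#' @param seed integer seed.
#' @return list of class \code{mc_estimate}: \code{value}, \code{stderr}
#'   (Angstrom^3), \code{n_samples}, \code{seed}.
#' @export
mc_volume <- function(mol, radii = radii_set("bondi"), probe = 1.5,
                      n_samples = 1e5, seed = 1) {
  stopifnot(inherits(mol, "molecule"), n_samples >= 1e4)
  r <- solvent_accessible_radius(mol$symbols, radii, probe)
  lo <- apply(mol$coords - r, 2, min)
  hi <- apply(mol$coords + r, 2, max)
  box <- prod(hi - lo)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n_samples <- as.integer(n_samples)
  pts <- cbind(stats::runif(n_samples, lo[1], hi[1]),
               stats::runif(n_samples, lo[2], hi[2]),
               stats::runif(n_samples, lo[3], hi[3]))
  hit <- rep(FALSE, n_samples)
  for (i in seq_len(n_atoms(mol))) {
    miss <- which(!hit)
    if (!length(miss)) break
    d2 <- (pts[miss, 1] - mol$coords[i, 1])^2 +
      (pts[miss, 2] - mol$coords[i, 2])^2 +
      (pts[miss, 3] - mol$coords[i, 3])^2
    hit[miss[d2 < r[i]^2]] <- TRUE
  }
  p <- mean(hit)
  structure(list(value = box * p,
                 stderr = box * sqrt(p * (1 - p) / n_samples),
                 n_samples = n_samples, seed = seed),
            class = "mc_estimate")
}

#' Exact union volume of two spheres
#'
#' Closed-form reference: sum of sphere volumes minus the lens volume
#' \code{pi (r1 + r2 - d)^2 (d^2 + 2 d (r1 + r2) - 3 (r1 - r2)^2) / (12 d)},
#' with the containment (d <= |r1 - r2|) and disjoint (d >= r1 + r2)
#' branches handled exactly.
#'
#' @param r1,r2 sphere radii (> 0), Angstrom.
#' @param d center separation (>= 0), Angstrom.
#' @return union volume, Angstrom^3.
#' @export
two_sphere_union_volume <- function(r1, r2, d) {
  if (r1 <= 0 || r2 <= 0 || d < 0) stop("radii must be > 0 and d >= 0")
  v <- 4 / 3 * pi * (r1^3 + r2^3)
  if (d >= r1 + r2) return(v)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * max(r1, r2)^3)
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  v - lens
}

#' Central finite-difference gradient of a scalar geometry function
#'
#' @param scalar_fn function taking a \code{molecule} and returning a scalar.
#' @param mol a \code{molecule}.
#' @param h step, Angstrom (default 1e-4).
#' @return N x 3 matrix of central differences.
#' @export
fd_gradient <- function(scalar_fn, mol, h = 1e-4) {
  stopifnot(h > 0)
  n <- n_atoms(mol)
  g <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    for (d in 1:3) {
      mp <- mm <- mol
      mp$coords[a, d] <- mp$coords[a, d] + h
      mm$coords[a, d] <- mm$coords[a, d] - h
      g[a, d] <- (scalar_fn(mp) - scalar_fn(mm)) / (2 * h)
    }
  }
  g
}

# NeRF-style placement: new atom X at |X - A| = dist, angle X-A-B =
# angle_deg, dihedral X-A-B-C = dihedral_deg.
.zmat_place <- function(A, B, C, dist, angle_deg, dihedral_deg) {
  ang <- angle_deg * pv_units$deg_to_rad
  tor <- dihedral_deg * pv_units$deg_to_rad
  bc <- A - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - C; ab <- ab / sqrt(sum(ab^2))
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  local <- dist * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  A + local[1] * bc + local[2] * m + local[3] * n
}

#' Build a 1,2-dichloroethane conformer
#'
#' Idealized CH2Cl-CH2Cl geometry from standard internal coordinates
#' (C-C 1.52, C-Cl 1.79, C-H 1.09 Angstrom, tetrahedral angles), with the
#' Cl-C-C-Cl dihedral set to 68 degrees (gauche) or 180 degrees (trans)
#' unless overridden.  Atom order: C, C, Cl, Cl, H, H, H, H.
#'
#' @param conformer \code{"gauche"} or \code{"trans"}.
#' @param dihedral_override optional Cl-C-C-Cl dihedral in degrees.
#' @return an 8-atom \code{molecule}.
#' @examples
#' m <- build_dce("trans")
#' measure_dihedral(m, 3, 1, 2, 4)   # 180
#' @export
build_dce <- function(conformer = c("gauche", "trans"),
                      dihedral_override = NULL) {
  conformer <- match.arg(conformer)
  chi <- if (!is.null(dihedral_override)) dihedral_override
  else if (conformer == "gauche") 68 else 180
  cc <- 1.52; ccl <- 1.79; ch <- 1.09; tet <- 109.471
  C1 <- c(0, 0, 0)
  C2 <- c(cc, 0, 0)
  a <- tet * pv_units$deg_to_rad
  Cl1 <- C1 + ccl * c(cos(pi - a), sin(pi - a), 0)  # angle Cl1-C1-C2 = tet
  Cl2 <- .zmat_place(C2, C1, Cl1, ccl, tet, chi)
  H1a <- .zmat_place(C1, C2, Cl1, ch, tet, 120)
  H1b <- .zmat_place(C1, C2, Cl1, ch, tet, -120)
  H2a <- .zmat_place(C2, C1, Cl1, ch, tet, chi + 120)
  H2b <- .zmat_place(C2, C1, Cl1, ch, tet, chi - 120)
  molecule(c("C", "C", "Cl", "Cl", "H", "H", "H", "H"),
           rbind(C1, C2, Cl1, Cl2, H1a, H1b, H2a, H2b),
           comment = sprintf("DCE %s, Cl-C-C-Cl = %g deg", conformer, chi))
}

#' Build an idealized n-butane chain
#'
#' CH3-CH2-CH2-CH3 from standard internal coordinates (C-C 1.53, C-H 1.09
#' Angstrom, tetrahedral angles).  Atoms 1-4 are the carbon backbone; the
#' central C-C-C-C dihedral is set by \code{dihedral} (default 180,
#' anti).  Used as the torsion-scan test chain.
#'
#' @param dihedral backbone dihedral C1-C2-C3-C4 in degrees.
#' @return a 14-atom \code{molecule}.
#' @export
build_butane <- function(dihedral = 180) {
  cc <- 1.53; ch <- 1.09; tet <- 109.471
  C2 <- c(0, 0, 0)
  C3 <- c(cc, 0, 0)
  a <- tet * pv_units$deg_to_rad
  C1 <- C2 + cc * c(cos(pi - a), sin(pi - a), 0)
  C4 <- .zmat_place(C3, C2, C1, cc, tet, dihedral)
  H1 <- lapply(c(60, 180, -60), function(t) .zmat_place(C1, C2, C3, ch, tet, t))
  H2 <- lapply(c(120, -120), function(t) .zmat_place(C2, C3, C4, ch, tet, t))
  H3 <- lapply(c(120, -120), function(t) .zmat_place(C3, C2, C1, ch, tet, t))
  H4 <- lapply(c(60, 180, -60), function(t) .zmat_place(C4, C3, C2, ch, tet, t))
  molecule(c("C", "C", "C", "C", rep("H", 10)),
           do.call(rbind, c(list(C1, C2, C3, C4), H1, H2, H3, H4)),
           comment = sprintf("butane, C-C-C-C = %g deg", dihedral))
}

#' Random overlapping atom cluster
#'
#' Draws atoms from a small organic element set inside a cube whose side
#' scales with n^(1/3) at a density dense enough that solvent-accessible
#' spheres always overlap (exercising the switching region), while
#' rejecting pairs closer than 1 Angstrom.  Deterministic per seed; the
#' caller's RNG state is preserved.
#'
#' @param n_atoms_ number of atoms.
#' @param seed integer seed.
#' @param elements symbols to draw from.
#' @return a \code{molecule}.
#' @export
random_cluster <- function(n_atoms_, seed = 1,
                           elements = c("H", "C", "N", "O", "Cl")) {
  stopifnot(n_atoms_ >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  side <- 2.0 * n_atoms_^(1 / 3)
  coords <- matrix(0, n_atoms_, 3)
  i <- 1L
  tries <- 0L
  while (i <= n_atoms_) {
    cand <- stats::runif(3, 0, side)
    ok <- i == 1L ||
      min(sqrt(rowSums(sweep(coords[seq_len(i - 1L), , drop = FALSE],
                             2, cand)^2))) >= 1.0
    tries <- tries + 1L
    if (tries > 1e5) stop("could not place atoms at the requested density")
    if (ok) {
      coords[i, ] <- cand
      i <- i + 1L
    }
  }
  molecule(sample(elements, n_atoms_, replace = TRUE), coords,
           comment = sprintf("random cluster seed %d", seed))
}

#' Rigidly rotate part of a molecule about a bond
#'
#' Rotates the atoms in \code{moving} about the axis through atoms
#' \code{j -> k} by \code{angle_deg} (right-hand rule looking from j to k).
#'
#' @param mol a \code{molecule}.
#' @param j,k axis atom indices.
#' @param moving indices of the atoms to rotate.
#' @param angle_deg rotation angle, degrees.
#' @export
rotate_about_bond <- function(mol, j, k, moving, angle_deg) {
  axis <- mol$coords[k, ] - mol$coords[j, ]
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pv_units$deg_to_rad
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  p <- sweep(mol$coords[moving, , drop = FALSE], 2, mol$coords[j, ])
  mol$coords[moving, ] <- p %*% t(R) +
    matrix(mol$coords[j, ], length(moving), 3, byrow = TRUE)
  mol
}

#' Quadrature noise of a PV torsion scan
#'
#' Rigid scan of a dihedral over 0-360 degrees: at each step the PV energy
#' is evaluated on each requested grid order, each profile is shifted to its
#' minimum, and the noise metric is the RMS of second differences of the
#' profile.  Coarse grids leave quadrature noise on top of the smooth
#' torsional profile, which shows up as an inflated metric (and, on a
#' pressure-modified energy surface, as artifact minima).
#'
#' @param mol the chain molecule to scan.
#' @param dihedral length-4 index vector (i, j, k, l); rotation is about
#'   the j-k bond.
#' @param moving atom indices rotated rigidly with l.
#' @param grid_orders two or more Lebedev orders to compare.
#' @param model a \code{pressure_model} (its \code{n_points} is overridden
#'   per order); pressure must be > 0 for a nonzero profile.
#' @param step_deg scan step, degrees (default 5).
#' @return list with \code{angles}, \code{profiles} (matrix, one column per
#'   order, Hartree, min-shifted), and \code{noise} (named numeric, RMS of
#'   second differences per order).
#' @export
torsion_scan_noise <- function(mol, dihedral, moving,
                               grid_orders = c(110, 1202),
                               model = pressure_model(pressure = 5),
                               step_deg = 5) {
  stopifnot(length(dihedral) == 4L, length(grid_orders) >= 2L)
  angles <- seq(0, 360 - step_deg, by = step_deg)
  geoms <- lapply(angles, function(a) {
    rotate_about_bond(mol, dihedral[2], dihedral[3], moving, a)
  })
  profiles <- sapply(grid_orders, function(ord) {
    m <- model
    m$n_points <- ord
    e <- vapply(geoms, function(g) pv_terms(g, m)$pv_energy, numeric(1))
    e - min(e)
  })
  colnames(profiles) <- as.character(grid_orders)
  noise <- apply(profiles, 2, function(e) sqrt(mean(diff(e, differences = 2)^2)))
  list(angles = angles, profiles = profiles, noise = noise)
}
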