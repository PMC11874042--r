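#' Cubic switching function
#'
#' The smooth volume-exclusion primitive: 0 deep inside a sphere of radius
#' \code{r}, 1 well outside it, with a C1-continuous cubic ramp across the
#' band \code{[r - w, r + w]},
#' \deqn{h(x) = 1/2 + 3(x-r)/(4w) - (x-r)^3/(4w^3).}
#' The band half-width \code{w} (default 0.3 Angstrom) sets how sharply
#' exposure switches off as a surface point dips inside a neighboring
#' sphere; it is what makes SASA and SAV differentiable in the nuclear
#' coordinates.
#'
#' @param x distance(s) from the sphere center, Angstrom.
#' @param r sphere radius, Angstrom (> 0).
#' @param w switching half-width, Angstrom (> 0).
#' @return list with components \code{value} in [0, 1] and \code{deriv}
#'   (d value / d x), both vectorized over \code{x}.
#' @examples
#' switching_value(2.7, r = 2.7)$value   # exactly 0.5 on the sphere
#' @export
switching_value <- function(x, r, w = 0.3) {
  stopifnot(all(r > 0), w > 0)
  u <- (x - r) / w
  inside <- u <= -1
  outside <- u >= 1
  band <- !(inside | outside)
  value <- ifelse(outside, 1, 0)
  deriv <- numeric(length(u))
  if (any(band)) {
    ub <- u[band]
    value[band] <- 0.5 + 0.75 * ub - 0.25 * ub^3
    deriv[band] <- 0.75 * (1 - ub^2) / w
  }
  list(value = value, deriv = deriv)
}

#' Discretize the solvent-accessible surface of a molecule
#'
#' Places one Lebedev grid on the solvent-accessible sphere of every atom.
#' Each discretization point t carries its owner atom, the grid unit vector
#' as outward normal \code{n_t}, the position \code{r_t = R_owner +
#' r_SA * n_t}, and an area element \code{a_t = w_angular * 4 pi r_SA^2}
#' (the radial weight is realized as the r_SA^2 scale factor).  Per atom the
#' area elements therefore sum exactly to the full sphere area.
#'
#' @param mol a \code{molecule}.
#' @param radii a \code{radii_set}; every element of \code{mol} must be
#'   resolvable in it.
#' @param probe probe radius in Angstrom (>= 0), default 1.5.
#' @param n_points requested Lebedev points per atom, default 1202.
#' @return object of class \code{sas_surface}: \code{owner} (atom index per
#'   point), \code{normals}, \code{points} (M x 3), \code{area} (M),
#'   \code{r_sa} (per atom), \code{order}, plus the source molecule.
#' @export
build_surface <- function(mol, radii = radii_set("bondi"), probe = 1.5,
                          n_points = 1202) {
  stopifnot(inherits(mol, "molecule"))
  r_sa <- solvent_accessible_radius(mol$symbols, radii, probe)
  if (any(r_sa <= 0)) stop("zero or negative solvent-accessible radius")
  grid <- lebedev_points(n_points)
  n <- n_atoms(mol)
  m <- grid$order
  owner <- rep(seq_len(n), each = m)
  normals <- grid$units[rep(seq_len(m), times = n), , drop = FALSE]
  points <- mol$coords[owner, , drop = FALSE] + normals * r_sa[owner]
  area <- rep(grid$weights, times = n) * 4 * pi * r_sa[owner]^2
  structure(list(owner = owner, normals = normals, points = points,
                 area = area, r_sa = r_sa, order = m, mol = mol),
            class = "sas_surface")
}

#' @export
print.sas_surface <- function(x, ...) {
  cat(sprintf("<sas_surface: %d atoms x %d points, total area %.3f A^2>\n",
              n_atoms(x$mol), x$order, sum(x$area)))
  invisible(x)
}

#' Evaluate the volume-exclusion function on a surface grid
#'
#' For each discretization point t the exposure is the product of switching
#' values over all atoms other than the owner,
#' \deqn{H_t = \prod_{i \ne owner(t)} h(|r_t - R_i|; r_i^{SA}, w),}
#' so \code{H_t = 1} for a fully exposed point and \code{H_t = 0} for a
#' point buried inside a neighbor.  The owner atom is excluded from the
#' product: every point sits exactly on its own sphere, where h = 1/2, and
#' including it would simply halve all areas and break the single-sphere
#' limit.  Atoms farther than \code{r_i^SA + w} from a point contribute a
#' factor of exactly 1 and are skipped (\code{use_cutoff}); the skip is an
#' exact identity, not an approximation.
#'
#' The solvent-accessible surface area is \code{SASA = sum_t H_t a_t}.
#'
#' @param surf a \code{sas_surface}.
#' @param w switching half-width, Angstrom; default 0.3.
#' @param use_cutoff skip atom/point blocks that cannot interact (results
#'   are identical with or without; default TRUE).
#' @return object of class \code{sas_exposure}: \code{H} (per point),
#'   \code{sasa} (Angstrom^2), and cached factor/derivative matrices reused
#'   by the gradient routines.
#' @export
exposure <- function(surf, w = 0.3, use_cutoff = TRUE) {
  stopifnot(inherits(surf, "sas_surface"), w > 0)
  mol <- surf$mol
  n <- n_atoms(mol)
  m_tot <- length(surf$owner)
  fac <- matrix(1, m_tot, n)     # switching factor of atom i at point t
  dfac <- matrix(0, m_tot, n)    # its radial derivative
  centers <- mol$coords
  # pair-level prefilter: points owned by j can feel atom i only if the
  # spheres come within w of touching
  if (use_cutoff && n > 1L) {
    dmat <- as.matrix(stats::dist(centers))
    reach <- outer(surf$r_sa, surf$r_sa, "+") + w
  }
  for (i in seq_len(n)) {
    affected <- if (use_cutoff && n > 1L)
      which(surf$owner != i & (dmat[surf$owner, i] < reach[surf$owner, i]))
    else which(surf$owner != i)
    if (!length(affected)) next
    d <- sqrt(rowSums((surf$points[affected, , drop = FALSE] -
                         matrix(centers[i, ], length(affected), 3,
                                byrow = TRUE))^2))
    sw <- switching_value(d, surf$r_sa[i], w)
    fac[affected, i] <- sw$value
    dfac[affected, i] <- sw$deriv
  }
  # zero-safe product: track the number of exactly-zero factors separately
  # so that partial products (needed for gradients) never divide by zero
  nzero <- integer(m_tot)
  prod_nz <- rep(1, m_tot)
  for (i in seq_len(n)) {
    z <- fac[, i] == 0
    nzero <- nzero + z
    prod_nz <- prod_nz * ifelse(z, 1, fac[, i])
  }
  H <- ifelse(nzero > 0L, 0, prod_nz)
  structure(list(H = H, sasa = sum(H * surf$area), w = w,
                 fac = fac, dfac = dfac, nzero = nzero, prod_nz = prod_nz),
            class = "sas_exposure")
}

#' @export
print.sas_exposure <- function(x, ...) {
  cat(sprintf("<sas_exposure: SASA %.4f A^2, mean H %.3f>\n",
              x$sasa, mean(x$H)))
  invisible(x)
}

#' Solvent-accessible surface area
#' @param expo a \code{sas_exposure}.
#' @return SASA in Angstrom^2.
#' @export
sasa <- function(expo) {
  stopifnot(inherits(expo, "sas_exposure"))
  expo$sasa
}

# Accumulate sum_t coef_t * dH_t/dR_k over all points, returning an N x 3
# matrix.  Each switching factor h(|r_t - R_i|) depends on R_i (moving the
# neighbor) and on R_owner(t) (the point rides on its owner's sphere); the
# two contributions are equal and opposite, so every row block conserves
# translation invariance exactly.
.exposure_grad_accumulate <- function(surf, expo, coef) {
  mol <- surf$mol
  n <- n_atoms(mol)
  g <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    sel <- which(expo$dfac[, i] != 0)
    if (!length(sel)) next
    f <- expo$fac[sel, i]
    nz <- expo$nzero[sel]
    # partial product excluding atom i, without dividing by zero factors
    H_ex <- ifelse(nz == 0L, expo$prod_nz[sel] / f,
                   ifelse(nz == 1L & f == 0, expo$prod_nz[sel], 0))
    live <- H_ex != 0
    if (!any(live)) next
    sel <- sel[live]
    H_ex <- H_ex[live]
    diff <- surf$points[sel, , drop = FALSE] -
      matrix(mol$coords[i, ], length(sel), 3, byrow = TRUE)
    dirs <- diff / sqrt(rowSums(diff^2))
    contrib <- coef[sel] * H_ex * expo$dfac[sel, i]
    vec <- contrib * dirs
    g[i, ] <- g[i, ] - colSums(vec)
    by_owner <- rowsum(vec, group = surf$owner[sel])
    idx <- as.integer(rownames(by_owner))
    g[idx, ] <- g[idx, ] + by_owner
  }
  g
}

#' Analytical SASA gradient
#'
#' d SASA / d R as an N x 3 matrix (Angstrom^2 per Angstrom), accumulated
#' from the cached switching derivatives.  Matches central finite
#' differences of \code{sasa(exposure(build_surface(...)))}.
#'
#' @param surf a \code{sas_surface}.
#' @param expo the matching \code{sas_exposure}.
#' @export
sasa_gradient <- function(surf, expo) {
  .exposure_grad_accumulate(surf, expo, surf$area)
}
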