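#' Solvent-accessible volume from a discretized surface
#'
#' Divergence-theorem surface sum: with coordinates recentered to the
#' centroid, \deqn{V = (1/3) \sum_t H_t a_t (n_t \cdot r_t).}
#' For a single sphere every \code{n_t . r_t} equals r_SA, so the sum
#' telescopes to the exact sphere volume (4/3) pi r_SA^3.  Recentering makes
#' the discretized V exactly translation invariant; the matching chain-rule
#' correction is applied in [sav_volume_gradient()].
#'
#' @param surf a \code{sas_surface}.
#' @param expo the matching \code{sas_exposure}.
#' @return volume in Angstrom^3.
#' @export
sav_volume <- function(surf, expo) {
  stopifnot(inherits(surf, "sas_surface"), inherits(expo, "sas_exposure"))
  centroid <- colMeans(surf$mol$coords)
  rc <- sweep(surf$points, 2, centroid)
  sum(expo$H * surf$area * rowSums(surf$normals * rc)) / 3
}

#' Analytical gradient of the solvent-accessible volume
#'
#' Exact derivative of the discretized, centroid-recentered volume with
#' respect to the atomic positions: the direct term
#' \code{(1/3) sum_{t in k} H_t a_t n_t} (each point rides on its owner's
#' sphere with a position-independent normal), the exclusion term carrying
#' \code{dH_t/dR_k} through the switching factors, and the recentering
#' correction \code{g_k <- g_k - mean(g)}.  By construction the rows sum to
#' the zero vector (translation invariance) and the result matches central
#' finite differences of [sav_volume()].
#'
#' @inheritParams sav_volume
#' @return N x 3 matrix, Angstrom^3 per Angstrom.
#' @export
sav_volume_gradient <- function(surf, expo) {
  stopifnot(inherits(surf, "sas_surface"), inherits(expo, "sas_exposure"))
  mol <- surf$mol
  n <- n_atoms(mol)
  centroid <- colMeans(mol$coords)
  rc <- sweep(surf$points, 2, centroid)
  # direct term: points move rigidly with their owner
  w_dir <- expo$H * surf$area / 3
  g <- unname(rowsum(surf$normals * w_dir, group = surf$owner))
  # exclusion term: exposure changes as neighbors move
  coef <- surf$area * rowSums(surf$normals * rc) / 3
  g <- g + .exposure_grad_accumulate(surf, expo, coef)
  # recentering correction (exact: see sav_volume)
  sweep(g, 2, colMeans(g))
}

#' X-HCFF approximate pressure gradient
#'
#' The extended hydrostatic compression force field applies the pressure as
#' a force \code{P a_t n_t} on every exposed surface element and sums the
#' forces onto the owning atoms:
#' \deqn{g_k = P \sum_{t \in k} H_t a_t n_t,}
#' converted to Hartree/Angstrom.  This equals the direct term of the
#' analytic PV gradient and omits the exposure- and area-derivative terms,
#' so it is cheap but non-integrable: there is no energy function whose
#' exact gradient it is.  Use it as an approximation to
#' \code{P * sav_volume_gradient()}; deviations of order 10-30 percent in
#' the gradient norm are typical for overlapping clusters.
#'
#' @inheritParams sav_volume
#' @param pressure pressure in GPa.
#' @return N x 3 matrix, Hartree per Angstrom.
#' @export
xhcff_gradient <- function(surf, expo, pressure) {
  stopifnot(pressure >= 0)
  w_dir <- expo$H * surf$area
  g <- unname(rowsum(surf$normals * w_dir, group = surf$owner))
  g * pressure * pv_units$gpa_A3_to_hartree
}

#' Pressure model configuration
#'
#' Bundles every knob of a PV calculation: pressure, probe radius, grid
#' density, radii set, switching width and gradient mode.
#'
#' @param pressure hydrostatic pressure in GPa (>= 0); default 0.
#' @param probe probe radius in Angstrom (>= 0); default 1.5 (approximately
#'   a water molecule).  The probe directly scales the SAV and hence the
#'   energy penalty per conformer; conservative values are advisable.
#' @param n_points Lebedev points per atom; default 1202.  Coarse grids make
#'   the pressure-modified energy surface noisy (artifact minima); fewer
#'   than ~1000 points per atom is discouraged.
#' @param radii a \code{radii_set} or a name accepted by [radii_set()].
#' @param mode \code{"pv_analytic"} (exact PV gradient) or \code{"xhcff"}
#'   (approximate surface-force gradient).
#' @param w switching half-width in Angstrom; default 0.3.
#' @return object of class \code{pressure_model}.
#' @export
pressure_model <- function(pressure = 0, probe = 1.5, n_points = 1202,
                           radii = radii_set("bondi"),
                           mode = c("pv_analytic", "xhcff"), w = 0.3) {
  mode <- match.arg(mode)
  if (is.character(radii)) radii <- radii_set(radii)
  stopifnot(inherits(radii, "radii_set"),
            is.numeric(pressure), length(pressure) == 1L, pressure >= 0,
            is.numeric(probe), probe >= 0, n_points >= 6, w > 0)
  structure(list(pressure = pressure, probe = probe, n_points = n_points,
                 radii = radii, mode = mode, w = w),
            class = "pressure_model")
}

#' @export
print.pressure_model <- function(x, ...) {
  cat(sprintf(
    "<pressure_model: P = %g GPa, probe %g A, %d pts, radii '%s', mode %s, w %g A>\n",
    x$pressure, x$probe, as.integer(x$n_points), x$radii$name, x$mode, x$w))
  invisible(x)
}

#' Compute the PV terms of a molecule
#'
#' Builds the surface and exposure once, then reports the solvent-accessible
#' volume, SASA, the PV energy \code{P * V} (in Hartree) and the gradient in
#' the requested mode: \code{pv_analytic} differentiates \code{P * V}
#' exactly, \code{xhcff} substitutes the approximate surface-force gradient
#' while still reporting \code{P * V} as the energy.
#'
#' @param mol a \code{molecule}.
#' @param model a \code{pressure_model}.
#' @return object of class \code{pv_result}: \code{volume} (A^3),
#'   \code{sasa} (A^2), \code{pv_energy} (Hartree), \code{gradient}
#'   (N x 3, Hartree/A), \code{mode}, \code{model}.
#' @examples
#' h <- molecule("H", matrix(0, 1, 3))
#' pv_terms(h, pressure_model(pressure = 1))
#' @export
pv_terms <- function(mol, model = pressure_model()) {
  stopifnot(inherits(mol, "molecule"), inherits(model, "pressure_model"))
  surf <- build_surface(mol, model$radii, model$probe, model$n_points)
  expo <- exposure(surf, model$w)
  vol <- sav_volume(surf, expo)
  grad <- if (model$mode == "xhcff")
    xhcff_gradient(surf, expo, model$pressure)
  else
    model$pressure * pv_units$gpa_A3_to_hartree * sav_volume_gradient(surf, expo)
  structure(list(volume = vol, sasa = expo$sasa,
                 pv_energy = convert_pv_energy(model$pressure * vol),
                 gradient = grad, mode = model$mode, model = model,
                 order = surf$order),
            class = "pv_result")
}

#' @export
print.pv_result <- function(x, ...) {
  cat(sprintf("<pv_result (%s, %d pts/atom)>\n", x$mode, as.integer(x$order)))
  cat(sprintf("  V    = %.4f A^3  (%.4f cm^3/mol)\n",
              x$volume, x$volume * pv_units$A3_to_cm3_per_mol))
  cat(sprintf("  SASA = %.4f A^2\n", x$sasa))
  cat(sprintf("  P*V  = %.6e Hartree  (%.4f kJ/mol)\n",
              x$pv_energy, x$pv_energy * pv_units$hartree_to_kj_per_mol))
  invisible(x)
}

#' PV-extended enthalpy with a pluggable electronic-energy backend
#'
#' Evaluates \code{H = E_el + P * V}: the backend supplies the electronic
#' energy and its gradient, the PV machinery supplies the pressure term, and
#' the two are summed.  A backend is any function
#' \code{function(mol) list(energy = <Hartree>, gradient = <N x 3>)};
#' adapters for external quantum-chemistry calculators can be wrapped the
#' same way.
#'
#' @param mol a \code{molecule}.
#' @param model a \code{pressure_model}.
#' @param backend backend callable (see above); \code{zero_backend} gives a
#'   pure-PV enthalpy.
#' @return object of class \code{enthalpy_result}: \code{enthalpy},
#'   \code{e_el} (both Hartree), \code{pv} (the \code{pv_result}),
#'   \code{gradient} (total, N x 3 Hartree/A).
#' @export
enthalpy_with_backend <- function(mol, model, backend = zero_backend) {
  stopifnot(is.function(backend))
  res <- tryCatch(backend(mol), error = function(e)
    stop("energy backend failed: ", conditionMessage(e), call. = FALSE))
  if (!is.list(res) || is.null(res$energy) || is.null(res$gradient))
    stop("backend must return list(energy = <Hartree>, gradient = <N x 3>)")
  grad_el <- as.matrix(res$gradient)
  if (!identical(dim(grad_el), c(n_atoms(mol), 3L)) &&
      !identical(dim(grad_el), as.integer(c(n_atoms(mol), 3))))
    stop("backend gradient must be N x 3")
  pv <- pv_terms(mol, model)
  structure(list(enthalpy = res$energy + pv$pv_energy, e_el = res$energy,
                 pv = pv, gradient = grad_el + pv$gradient),
            class = "enthalpy_result")
}

#' @rdname enthalpy_with_backend
#' @export
zero_backend <- function(mol) {
  list(energy = 0, gradient = matrix(0, n_atoms(mol), 3))
}

#' @export
print.enthalpy_result <- function(x, ...) {
  cat(sprintf("<enthalpy_result: H = %.8f Ha (E_el %.8f + PV %.6e)>\n",
              x$enthalpy, x$e_el, x$pv$pv_energy))
  invisible(x)
}

#' Numerical Hessian of the PV term
#'
#' Central finite differences of the analytic PV gradient, symmetrized as
#' (H + H^T)/2; intended to be added to an electronic Hessian for
#' pressure-modified frequency calculations.  The default step of 5e-3
#' Angstrom balances truncation against cancellation error for surface sums.
#'
#' @param mol a \code{molecule}.
#' @param model a \code{pressure_model} with \code{mode = "pv_analytic"}.
#' @param step displacement step in Angstrom.
#' @return 3N x 3N matrix (Hartree/Angstrom^2), coordinate order
#'   (x1, y1, z1, x2, ...), with attribute \code{max_asymmetry} holding the
#'   largest absolute asymmetry before symmetrization.
#' @export
pv_hessian <- function(mol, model, step = 5e-3) {
  stopifnot(inherits(model, "pressure_model"), step > 0)
  if (model$mode != "pv_analytic")
    stop("pv_hessian requires mode = 'pv_analytic'")
  n <- n_atoms(mol)
  hess <- matrix(0, 3 * n, 3 * n)
  grad_flat <- function(m) as.vector(t(pv_terms(m, model)$gradient))
  for (a in seq_len(n)) {
    for (d in 1:3) {
      col <- 3L * (a - 1L) + d
      mp <- mm <- mol
      mp$coords[a, d] <- mp$coords[a, d] + step
      mm$coords[a, d] <- mm$coords[a, d] - step
      hess[, col] <- (grad_flat(mp) - grad_flat(mm)) / (2 * step)
    }
  }
  asym <- max(abs(hess - t(hess)))
  hess <- (hess + t(hess)) / 2
  attr(hess, "max_asymmetry") <- asym
  hess
}
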