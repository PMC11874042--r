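---
title: "Pressure-volume enthalpy terms from smooth solvent-accessible volumes"
author: "pvolr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-volume enthalpy terms from smooth solvent-accessible volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvolr)
```

## The model

Hydrostatic pressure in the GPa regime changes which conformers of a
molecule are thermodynamically accessible.  pvolr models this by extending
the electronic energy of a molecule to a constant-pressure enthalpy,

$$ H = E_{el} + P \, V_{mol}, $$

where $P$ is a user-defined pressure and $V_{mol}$ is the
solvent-accessible volume (SAV): the volume enclosed by the union of atomic
spheres of radius

$$ r^{SA}_i = r^{vdW}_i + r_{probe}. $$

Geometry optimization or conformational sampling on this pressure-modified
energy surface then favors compact conformers, because every cubic
Angstrom of molecular volume costs $P \cdot 1\,\mathrm{GPa\,\AA^3} =
2.2937\times 10^{-4}$ Hartree of enthalpy per GPa.

$V_{mol}$ is evaluated by numerical quadrature of the solvent-accessible
surface.  Each atom carries a Lebedev--Laikov grid scaled to its
solvent-accessible sphere; a discretization point $t$ owned by atom $j$ has
outward normal $\vec n_t$ (the grid unit vector), position $\vec r_t = \vec
R_j + r^{SA}_j \vec n_t$ and area element $a_t = w_a \, 4\pi (r^{SA}_j)^2$,
with $w_a$ the angular weight (the radial weight is realized as the
$(r^{SA}_j)^2$ scale factor).  The divergence theorem turns the volume into
a surface sum over all points,

$$ V_{mol} = \tfrac13 \sum_t H_t \, a_t \, (\vec n_t \cdot \vec r_t), $$

where the coordinates entering $\vec r_t$ are first recentered to the
molecular centroid (see *Numerical choices*).

The exposure $H_t \in [0,1]$ is a smooth volume-exclusion function: the
product over all atoms $i$ other than the owner of a switching factor

$$ h(x) = \begin{cases} 0 & x \le r - w \\
\tfrac12 + \tfrac{3(x-r)}{4w} - \tfrac{(x-r)^3}{4w^3} & |x - r| < w \\
1 & x \ge r + w \end{cases} $$

evaluated at $x = |\vec r_t - \vec R_i|$, $r = r^{SA}_i$.  The cubic ramp
is $C^1$-continuous, which makes SASA and SAV differentiable in the
nuclear coordinates — the property the whole package is built around.  The
owner atom is *excluded* from the product: every point sits exactly on its
own sphere where $h = 1/2$, so including it would halve all areas and
volumes and break the exact single-sphere limit.

### Gradients

The analytic volume gradient has three parts: a *direct* term
$\tfrac13 \sum_{t \in k} H_t a_t \vec n_t$ (points ride rigidly on their
owner's sphere and the normals are position-independent), an *exclusion*
term carrying $\partial H_t / \partial \vec R_k$ through the switching
factors, and the centroid-recentering chain-rule correction, which reduces
to subtracting the mean row (see below).  The result is exact for the
discretized volume: it matches central finite differences to the oracle's
own accuracy, and its rows sum to the zero vector identically.

The X-HCFF (extended hydrostatic compression force field) mode instead
applies the pressure as a surface force $P \, a_t \vec n_t$ on every
exposed element and sums forces onto the owning atoms:

$$ \vec g_k = P \sum_{t \in k} H_t \, a_t \, \vec n_t. $$

This is exactly the direct term of the analytic PV gradient times $P$; the
exposure-derivative contribution is dropped.  The resulting field is not
integrable — no energy function has it as an exact gradient — so
`pv_terms(mode = "xhcff")` reports $P V_{mol}$ as the energy while using
the approximate gradient, and is labeled accordingly.  On dense random
clusters the per-atom force norms deviate from the analytic PV gradient by
10--30 % on average (the package's acceptance suite measures this band);
the payoff is that no area or exposure derivatives need to be computed.

### Hessian

`pv_hessian()` differentiates the analytic PV gradient by central finite
differences (default step 5e-3 Angstrom, balancing truncation against
cancellation for surface sums), symmetrizes the result and reports the
pre-symmetrization asymmetry.  It is intended to be added to an electronic
Hessian for vibrational analysis on the pressure-modified surface.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `pressure` | 0 | GPa | scales the PV term; typical studies use 0--6 |
| `probe` | 1.5 | Angstrom | sphere inflation; 1.5 is roughly a water radius.  The probe directly scales the SAV and hence the energy added per conformer, so conservative values are advisable; 1.0 mimics close-packed solid-state contacts |
| `n_points` | 1202 | — | Lebedev points per atom.  Below ~1000 the quadrature error makes the pressure-modified surface noisy and can create artifact minima (see below) |
| `w` | 0.3 | Angstrom | switching half-width; smaller values sharpen the surface but concentrate the gradient in a narrower band |
| `radii` | `"bondi"` | — | van der Waals radii set (H--Ar); custom named vectors are accepted |

The configuration layer (`parse_config()`, TOML section `[calculation]`
with keys `method`, `pressure`, `proberad`, `gridpts`, `vdwset`, `w`)
validates all of these before any computation.  Because no established
TOML key schema exists for this file type in R, the key names above are
defined (and documented) by this package.

## Quadrature grids

The Lebedev--Laikov orbit parameters for the 20 tabulated orders
(26--2030 points) are ported from the canonical published tables and
expanded deterministically from their octahedral symmetry classes at run
time; grids are cached per order.  Weights are stored normalized to 1.
Test invariants: weights sum to 1 within 1e-12, all points are unit
vectors, odd moments vanish, and $\sum w u_x^2 = 1/3$ and $\sum w u_x^2
u_y^2 = 1/15$ hold to 1e-10 for every order.  Three of the canonical
tables (74, 230 and 266 points) contain one negative-weight orbit; this is
a property of the published grids, documented rather than "repaired", and
is one reason the low orders are not recommended for production use.

## Numerical choices

* **Centroid recentering.**  The divergence-theorem sum depends on the
  coordinate origin at finite grid resolution.  Recentering to the
  centroid makes $V$ exactly translation invariant, and the corresponding
  chain-rule term in the gradient reduces to subtracting the mean gradient
  row, preserving exact analytic/finite-difference consistency.
* **Sign convention.**  The PV gradient is the gradient of the
  *enthalpy*: positive along outward normals, so the implied force pushes
  atoms inward.  X-HCFF mode follows the same convention.
* **Zero-safe products.**  When accumulating $\partial H_t/\partial \vec
  R_k$ the partial product excluding one atom is needed.  Factors exactly
  equal to zero are counted separately so the partial product is formed
  without ever dividing by zero.
* **Neighbor cutoff.**  Atoms farther than $r^{SA}_i + w$ from a point
  contribute a factor of exactly 1; a per-atom-pair prefilter skips such
  blocks.  The skip is an identity, verified to 1e-14 against the
  all-pairs product.
* **Degenerate inputs.**  Coincident atoms are legal (two superposed
  identical spheres reproduce one sphere's volume to 1e-10 relative);
  zero-atom molecules are an error.  Exact coincidence of a grid point
  with a band edge is measure-zero and handled by the closed-form plateau
  branches.
* **Finite-difference oracles.**  The switching function is only $C^1$:
  its curvature jumps at the band edges.  A central difference with step
  $h$ that straddles such an edge picks up an $O(h)$ error *in the
  oracle*; the acceptance checks therefore use $h = 10^{-5}$ Angstrom,
  for which this contamination is negligible while roundoff remains
  below 1e-8.

## What the synthetic generators emulate

All tests run on programmatically generated geometries:

* `build_dce()` — idealized 1,2-dichloroethane with standard bond lengths
  and tetrahedral angles, and a configurable Cl--C--C--Cl dihedral (68
  degrees gauche, 180 trans).  The gauche conformer has the smaller SAV
  (about -4.4 cm^3/mol at probe 1.5), consistent in sign with the
  experimentally observed pressure-driven shift toward gauche.
* `build_butane()` — an idealized alkane chain used for rigid torsion
  scans; `torsion_scan_noise()` quantifies quadrature noise as the RMS of
  second differences of the PV profile along the scan, which strictly
  decreases from the 110-point to the 1202-point grid.
* `random_cluster()` — 2--20 atoms drawn from H/C/N/O/Cl in a box dense
  enough that solvent-accessible spheres always overlap (minimum pair
  distance 1 Angstrom), exercising the switching region rather than
  trivial disjoint spheres.

These generators use idealized internal coordinates and uniform random
packing; they do not emulate real covalent connectivity, electronic
structure, or the conformational ensembles a sampling engine would
produce.  Passing tests therefore validate the *volume machinery* — sphere
limits, union volumes against Monte-Carlo and closed-form oracles,
gradient consistency, invariances and grid convergence — not the
quantitative enthalpy ordering of real conformer ensembles, which
additionally depends on the electronic-energy backend plugged into
`enthalpy_with_backend()`.

Problem sizes were chosen so the full suite runs in well under a minute of
desk time: 302-point grids for gradient cross-checks (with one 1202-point
case), 2e5 Monte-Carlo samples per cluster (3-sigma bands then sit near
0.5 % of the volume), and 5-degree torsion steps.

## Design decisions taken where the design was open

* **Radii sets.**  Only the Bondi set ships with the package.  A
  D3-derived set is a common alternative in tight-binding contexts, but no
  trustworthy tabulation was available to bundle, and shipping guessed
  radii would silently change every volume; `radii_set("custom", ...)`
  accepts any externally sourced table instead, and unknown elements fail
  loudly rather than defaulting.
* **Area elements.**  $a_t$ is position-independent
  ($w_a 4\pi (r^{SA})^2$); all position dependence of the surface
  integrand is routed through $H_t$.  This keeps per-atom areas summing
  exactly to the sphere area and makes the single-sphere limit exact by
  construction.
* **X-HCFF normalization.**  The X-HCFF force is defined as
  $P \sum H a \vec n$ per atom — the geometrically consistent first-order
  volume change per atom displacement — with no 1/3 divergence factor
  (that factor belongs to the volume sum, not to the per-atom surface
  force).  Defining it otherwise would triple the documented deviation
  from the analytic gradient.
* **Exposure caching.**  `exposure()` caches the full factor and
  derivative matrices so the gradient routines reuse them; for the
  package's target sizes (tens of atoms) the memory cost is a few
  megabytes and the double evaluation it avoids dominates runtime.

## Known limitations

* No reentrant (solvent-excluded) surface and no per-atom SASA
  decomposition; totals only.
* The electronic side of the enthalpy is entirely delegated to the
  backend contract; the package ships only a zero backend and test toys.
  Conformer-ensemble bookkeeping, Boltzmann weighting and spectra are out
  of scope.
* Periodic boundary conditions are not supported; the SAV is only
  meaningful for isolated molecules and small clusters.
* The PV Hessian is numerical; an analytic second derivative of the
  surface sum is not implemented.
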