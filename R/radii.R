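# van der Waals radii (Angstrom), Bondi's compilation for H-Ar with the
# standard extension for Be, B and Al (which Bondi's original table omits).
.bondi_radii <- c(
  H = 1.20, He = 1.40,
  Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
  F = 1.47, Ne = 1.54,
  Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80,
  Cl = 1.75, Ar = 1.88
)

#' van der Waals radii sets
#'
#' Returns the named radii set used to build solvent-accessible spheres.
#' The built-in \code{"bondi"} set covers H through Ar.  A custom set can be
#' supplied as a named numeric vector (element symbol to radius in Angstrom),
#' e.g. to use D3-derived radii exported from another program.
#'
#' @param name \code{"bondi"} or \code{"custom"}.
#' @param custom named numeric vector of radii, required for
#'   \code{name = "custom"}; all radii must be strictly positive.
#' @return an object of class \code{radii_set} with fields \code{name} and
#'   \code{radii}.
#' @examples
#' radii_set("bondi")$radii[["H"]]   # 1.20
#' @export
radii_set <- function(name = c("bondi", "custom"), custom = NULL) {
  name <- match.arg(name)
  radii <- if (name == "bondi") .bondi_radii else {
    if (is.null(custom) || is.null(names(custom)))
      stop("name = 'custom' requires a named numeric vector of radii")
    custom
  }
  if (!is.numeric(radii) || any(!is.finite(radii)) || any(radii <= 0))
    stop("all van der Waals radii must be finite and strictly positive")
  structure(list(name = name, radii = radii), class = "radii_set")
}

#' @export
print.radii_set <- function(x, ...) {
  cat(sprintf("<radii_set '%s': %d elements>\n", x$name, length(x$radii)))
  invisible(x)
}

#' Solvent-accessible radius of an element
#'
#' The solvent-accessible radius is the van der Waals radius extended by the
#' probe radius, \code{r_SA = r_vdW + r_probe}.  The probe (default 1.5
#' Angstrom, approximately a water molecule) inflates every atomic sphere
#' before the union surface is discretized.
#'
#' @param element element symbol or vector of symbols.
#' @param radii a \code{radii_set}.
#' @param probe probe radius in Angstrom, \code{>= 0}.
#' @return numeric vector of radii in Angstrom.
#' @export
solvent_accessible_radius <- function(element, radii = radii_set("bondi"),
                                      probe = 1.5) {
  stopifnot(inherits(radii, "radii_set"), is.numeric(probe), probe >= 0)
  unknown <- setdiff(element, names(radii$radii))
  if (length(unknown))
    stop("element(s) not in radii set '", radii$name, "': ",
         paste(unknown, collapse = ", "),
         "; supported: ", paste(names(radii$radii), collapse = " "))
  unname(radii$radii[element]) + probe
}
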