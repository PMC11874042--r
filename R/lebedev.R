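# Grid cache: orbit expansion is deterministic, so each order is built once
# per session.
.lebedev_cache <- new.env(parent = emptyenv())

#' Lebedev-Laikov angular quadrature grid
#'
#' Returns an octahedrally symmetric quadrature grid on the unit sphere with
#' weights normalized to sum to 1 (the surface measure 4*pi*r^2 is applied
#' later, when area elements are assigned to atomic spheres).  Grids are
#' exact for spherical harmonics up to an order-dependent degree; coarse
#' grids introduce quadrature noise into surface integrals, which is why the
#' package default is the dense 1202-point grid.
#'
#' If \code{n_requested} is not a tabulated order, the next larger supported
#' order is used and a warning is emitted.
#'
#' @param n_requested requested number of points per sphere (>= 6).
#' @return a list of class \code{lebedev_grid}: \code{order} (actual point
#'   count), \code{units} (order x 3 matrix of unit vectors), \code{weights}
#'   (summing to 1; strictly positive except for one negative-weight orbit
#'   in the canonical 74-, 230- and 266-point tables).
#' @examples
#' g <- lebedev_points(1202)
#' sum(g$weights)                     # 1
#' colSums(g$weights * g$units)       # numerically the zero vector
#' @export
lebedev_points <- function(n_requested) {
  stopifnot(is.numeric(n_requested), length(n_requested) == 1L,
            is.finite(n_requested))
  if (n_requested < 6)
    stop("n_requested must be >= 6")
  sup <- .lebedev_supported
  if (n_requested > max(sup))
    stop("largest supported Lebedev order is ", max(sup))
  order <- min(sup[sup >= n_requested])
  if (order != n_requested)
    warning(sprintf("no %d-point Lebedev grid; using the next larger order %d",
                    as.integer(n_requested), order))
  key <- as.character(order)
  if (!is.null(.lebedev_cache[[key]])) return(.lebedev_cache[[key]])
  rows <- .lebedev_orbits[.lebedev_orbits[, "order"] == order, , drop = FALSE]
  pts <- vector("list", nrow(rows))
  wts <- vector("list", nrow(rows))
  for (r in seq_len(nrow(rows))) {
    p <- .lebedev_orbit_points(rows[r, "code"], rows[r, "a"], rows[r, "b"])
    pts[[r]] <- p
    wts[[r]] <- rep(rows[r, "v"], nrow(p))
  }
  grid <- structure(list(order = order,
                         units = do.call(rbind, pts),
                         weights = unlist(wts)),
                    class = "lebedev_grid")
  stopifnot(nrow(grid$units) == order)
  .lebedev_cache[[key]] <- grid
  grid
}

#' Supported Lebedev grid orders
#' @return integer vector of tabulated point counts.
#' @export
lebedev_orders <- function() as.integer(.lebedev_supported)

# Expand one symmetry orbit of the octahedral group.  Codes follow the
# classic generator classes: 1 vertex, 2 edge-midpoint, 3 face-center
# orbits (fixed geometry), then the parameterized (a,a,b), (a,b,0) and
# (a,b,c) classes.  Points are renormalized so |u| = 1 to machine precision.
.lebedev_orbit_points <- function(code, a, b) {
  signs2 <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1)))
  signs3 <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1)))
  pts <- switch(as.character(code),
    "1" = rbind(diag(3), -diag(3)),
    "2" = {
      s <- 1 / sqrt(2)
      out <- matrix(0, 12, 3)
      r <- 0L
      for (zero_at in 1:3) {
        ij <- setdiff(1:3, zero_at)
        for (k in 1:4) {
          r <- r + 1L
          out[r, ij] <- s * signs2[k, ]
        }
      }
      out
    },
    "3" = signs3 / sqrt(3),
    "4" = {
      bb <- sqrt(max(1 - 2 * a^2, 0))
      if (b > 0) bb <- b   # stored value, avoids loss when b is small
      out <- matrix(0, 24, 3)
      r <- 0L
      for (b_at in 1:3) {
        base <- c(a, a, a); base[b_at] <- bb
        for (k in 1:8) {
          r <- r + 1L
          out[r, ] <- base * signs3[k, ]
        }
      }
      out
    },
    "5" = {
      out <- matrix(0, 24, 3)
      r <- 0L
      for (zero_at in 1:3) {
        ij <- setdiff(1:3, zero_at)
        for (ord in list(c(a, b), c(b, a))) {
          for (k in 1:4) {
            r <- r + 1L
            out[r, ij] <- ord * signs2[k, ]
          }
        }
      }
      out
    },
    "6" = {
      cc <- sqrt(max(1 - a^2 - b^2, 0))
      perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      abc <- c(a, b, cc)
      out <- matrix(0, 48, 3)
      r <- 0L
      for (p in 1:6) {
        base <- abc[perms[p, ]]
        for (k in 1:8) {
          r <- r + 1L
          out[r, ] <- base * signs3[k, ]
        }
      }
      out
    },
    stop("unknown orbit code ", code))
  pts / sqrt(rowSums(pts^2))
}
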