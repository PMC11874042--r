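#' Construct a molecule
#'
#' The minimal geometric data model used throughout pvolr: element symbols
#' plus Cartesian coordinates in Angstrom.  No connectivity, charge or
#' multiplicity semantics are attached.
#'
#' @param symbols character vector of element symbols (e.g. \code{"C"}, \code{"Cl"}).
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param comment free-text comment carried to/from the XYZ comment line.
#' @return An object of class \code{molecule}: a list with fields
#'   \code{symbols}, \code{coords}, \code{comment}.
#' @examples
#' m <- molecule("H", matrix(0, 1, 3))
#' n_atoms(m)
#' @export
molecule <- function(symbols, coords, comment = "") {
  symbols <- as.character(symbols)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(symbols) < 1L)
    stop("a molecule needs at least one atom")
  if (any(!nzchar(symbols)) || anyNA(symbols))
    stop("empty or missing element symbol")
  if (ncol(coords) != 3L || nrow(coords) != length(symbols))
    stop("coords must be an N x 3 matrix matching length(symbols)")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  dimnames(coords) <- NULL
  structure(list(symbols = symbols, coords = coords,
                 comment = as.character(comment)[1]),
            class = "molecule")
}

#' @rdname molecule
#' @param mol a \code{molecule}.
#' @export
n_atoms <- function(mol) length(mol$symbols)

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms [%s]>\n", n_atoms(x),
              paste(unique(x$symbols), collapse = " ")))
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Parses plain (single-frame) XYZ: a count line, a comment line, then one
#' \code{symbol x y z} line per atom.  If the file contains further frames
#' after the first, they are ignored with a warning.
#'
#' @param source path to an XYZ file, or a character vector of lines.
#' @return a \code{molecule}; the comment line is preserved verbatim.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  if (length(lines) < 1L) stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("line 1: malformed atom count: ", sQuote(trimws(lines[1])))
  if (length(lines) < n + 2L)
    stop(sprintf("expected %d atom lines but input ends at line %d",
                 n, length(lines)))
  comment <- if (length(lines) >= 2L) lines[2] else ""
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- n_line <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop(sprintf("line %d: expected 'symbol x y z', got %s",
                   n_line, sQuote(lines[ln])))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop(sprintf("line %d: non-numeric coordinate in %s",
                   n_line, sQuote(lines[ln])))
    if (grepl("^[0-9.+-]", tok[1]))
      stop(sprintf("line %d: element token %s does not look like a symbol",
                   n_line, sQuote(tok[1])))
    symbols[i] <- tok[1]
    coords[i, ] <- xyz
  }
  if (length(lines) > n + 2L &&
      any(nzchar(trimws(lines[(n + 3L):length(lines)]))))
    warning("multi-frame XYZ input: only the first frame was read")
  molecule(symbols, coords, comment)
}

#' Write a molecule as XYZ text
#'
#' @param mol a \code{molecule}.
#' @param file optional path; when \code{NULL} the XYZ text is returned as a
#'   character vector of lines.
#' @return the lines, invisibly when written to a file.  Coordinates are
#'   printed with 12 significant digits so that a read/write round trip
#'   preserves them to well below 1e-9 Angstrom.
#' @export
write_xyz <- function(mol, file = NULL) {
  stopifnot(inherits(mol, "molecule"))
  body <- sprintf("%-3s %18.12f %18.12f %18.12f",
                  mol$symbols, mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  out <- c(as.character(n_atoms(mol)), mol$comment, body)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Measure a dihedral angle
#'
#' Signed dihedral i-j-k-l in degrees, in (-180, 180], using the standard
#' atan2 convention.
#'
#' @param mol a \code{molecule}.
#' @param i,j,k,l 1-based atom indices.
#' @export
measure_dihedral <- function(mol, i, j, k, l) {
  p <- mol$coords
  b1 <- p[j, ] - p[i, ]
  b2 <- p[k, ] - p[j, ]
  b3 <- p[l, ] - p[k, ]
  c12 <- .cross3(b1, b2)
  c23 <- .cross3(b2, b3)
  y <- sum(.cross3(c12, c23) * b2 / sqrt(sum(b2^2)))
  x <- sum(c12 * c23)
  atan2(y, x) * pv_units$rad_to_deg
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
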