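# Minimal TOML reader covering the flat `[section] / key = value` subset
# used by run configurations: quoted strings, numbers, booleans, `#`
# comments.  (No installed R package parses TOML, and the configuration
# grammar needed here is deliberately tiny.)
parse_toml <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  out <- list()
  section <- NULL
  for (k in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[k])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop(sprintf("TOML parse error at line %d: %s", k, sQuote(lines[k])))
    key <- m[2]
    raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw) || grepl("^'.*'$", raw)) {
      substr(raw, 2, nchar(raw) - 1)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      num <- suppressWarnings(as.numeric(raw))
      if (is.na(num))
        stop(sprintf("TOML parse error at line %d: cannot read value %s",
                     k, sQuote(raw)))
      num
    }
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

.config_defaults <- list(method = "pvol", pressure = 0, proberad = 1.5,
                         gridpts = 1202, vdwset = "bondi", w = 0.3)

.config_error <- function(msg) {
  stop(structure(class = c("pvolr_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Parse a run configuration
#'
#' Reads the \code{[calculation]} section of a TOML document with keys
#' \code{method} ("pvol" or "xhcff"), \code{pressure} (GPa),
#' \code{proberad} (Angstrom), \code{gridpts}, \code{vdwset} and \code{w}
#' (Angstrom).  Values given in \code{overrides} (e.g. from CLI flags) take
#' precedence over the file; anything left unset falls back to the
#' defaults: pressure 0, probe 1.5, 1202 grid points, Bondi radii, w 0.3.
#'
#' @param toml_text TOML document as a string or lines, or \code{NULL}.
#' @param overrides named list overriding file values.
#' @return a validated list of class \code{run_config} with elements
#'   \code{method}, \code{pressure}, \code{proberad}, \code{gridpts},
#'   \code{vdwset}, \code{w}, and \code{mode} (the \code{pressure_model}
#'   mode implied by \code{method}).
#' @examples
#' parse_config("[calculation]\npressure = 2.5\nmethod = \"xhcff\"")
#' @export
parse_config <- function(toml_text = NULL, overrides = list()) {
  cfg <- .config_defaults
  if (!is.null(toml_text)) {
    doc <- tryCatch(parse_toml(toml_text),
                    error = function(e) .config_error(conditionMessage(e)))
    calc <- doc[["calculation"]]
    if (!is.null(calc)) {
      bad <- setdiff(names(calc), names(.config_defaults))
      if (length(bad))
        .config_error(paste0("unknown key(s) in [calculation]: ",
                             paste(bad, collapse = ", "), "; valid keys: ",
                             paste(names(.config_defaults), collapse = ", ")))
      cfg[names(calc)] <- calc
    }
  }
  bad <- setdiff(names(overrides), names(.config_defaults))
  if (length(bad))
    .config_error(paste0("unknown option(s): ", paste(bad, collapse = ", ")))
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  for (key in c("pressure", "proberad", "gridpts", "w"))
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        !is.finite(cfg[[key]]))
      .config_error(sprintf("key '%s' must be a single finite number", key))
  if (!is.character(cfg$method) || !cfg$method %in% c("pvol", "xhcff"))
    .config_error("method must be \"pvol\" or \"xhcff\"")
  if (cfg$pressure < 0) .config_error("pressure must be >= 0")
  if (cfg$proberad < 0) .config_error("proberad must be >= 0")
  if (cfg$gridpts < 6) .config_error("gridpts must be >= 6")
  if (cfg$w <= 0) .config_error("w must be > 0")
  if (!cfg$vdwset %in% "bondi")
    .config_error("vdwset must be \"bondi\" (or supply a custom radii_set via the API)")
  cfg$mode <- if (cfg$method == "xhcff") "xhcff" else "pv_analytic"
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config: method %s, P %g GPa, probe %g A, %d pts, vdw %s, w %g A>\n",
    x$method, x$pressure, x$proberad, as.integer(x$gridpts), x$vdwset, x$w))
  invisible(x)
}

# run_config -> pressure_model
.config_model <- function(cfg) {
  pressure_model(pressure = cfg$pressure, probe = cfg$proberad,
                 n_points = cfg$gridpts, radii = cfg$vdwset,
                 mode = cfg$mode, w = cfg$w)
}
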