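#' Raw digitized spectrum
#'
#' A two-column spectrum as digitized from a published figure: a strictly
#' monotone abscissa (wavelength in nm, or energy in eV after conversion)
#' with arbitrary-unit intensities.
#'
#' @param abscissa numeric, strictly monotone after sorting
#' @param intensity numeric, finite, same length
#' @param label free-text identifier
#' @param domain `"wavelength"` (nm) or `"energy"` (eV)
#' @return an object of class `raw_spectrum`
#' @export
raw_spectrum <- function(abscissa, intensity, label = "",
                         domain = c("wavelength", "energy")) {
  domain <- match.arg(domain)
  if (length(abscissa) != length(intensity)) {
    stop("abscissa and intensity must have equal length", call. = FALSE)
  }
  if (length(abscissa) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(abscissa)) || any(!is.finite(intensity))) {
    stop("abscissa and intensity must be finite", call. = FALSE)
  }
  # average duplicated abscissa values, then sort ascending
  if (anyDuplicated(abscissa)) {
    intensity <- as.numeric(tapply(intensity, abscissa, mean))
    abscissa <- sort(unique(abscissa))
  }
  o <- order(abscissa)
  structure(
    list(abscissa = abscissa[o], intensity = intensity[o],
         label = label, domain = domain),
    class = "raw_spectrum"
  )
}

#' Read a two-column XY spectrum from delimited text
#'
#' Lines starting with `#` are comments. Rows out of order are sorted to a
#' monotone abscissa; duplicated abscissa values are averaged.
#'
#' @param path file path
#' @param sep column separator: `""` for whitespace, or e.g. `","`
#' @param domain abscissa unit, see [raw_spectrum()]
#' @param label identifier; defaults to the file name
#' @return a [raw_spectrum()]
#' @export
read_xy_spectrum <- function(path, sep = "", domain = "wavelength",
                             label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 2) stop("need at least 2 data points: ", path,
                              call. = FALSE)
  split_fun <- if (identical(sep, "")) {
    function(l) strsplit(trimws(l), "[[:space:]]+")[[1]]
  } else {
    function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1]])
  }
  xy <- matrix(NA_real_, nrow = length(lines), ncol = 2)
  for (i in seq_along(lines)) {
    fields <- split_fun(lines[[i]])
    if (length(fields) < 2) {
      stop("line ", lineno[i], ": expected >= 2 columns", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      stop("line ", lineno[i], ": non-numeric value", call. = FALSE)
    }
    xy[i, ] <- vals
  }
  raw_spectrum(xy[, 1], xy[, 2], label = label, domain = domain)
}

#' Convert a wavelength-domain spectrum to the energy domain
#'
#' Applies E = hc/lambda to the abscissa and the Jacobian factor to the
#' intensity so that integrated band areas are preserved:
#' I(E) dE = I(lambda) dlambda implies I(E) = I(lambda) * lambda^2 / hc.
#'
#' @param raw a [raw_spectrum()] in the wavelength domain
#' @inheritParams ev_from_nm
#' @return a [raw_spectrum()] in the energy domain, ascending in energy
#' @export
wavelength_to_energy <- function(raw, hc = HC_EV_NM) {
  stopifnot(inherits(raw, "raw_spectrum"))
  if (!identical(raw$domain, "wavelength")) {
    stop("spectrum is not in the wavelength domain", call. = FALSE)
  }
  lambda <- raw$abscissa
  e <- ev_from_nm(lambda, hc)
  jac <- lambda^2 / hc           # |dlambda/dE| = hc/E^2 = lambda^2/hc
  raw_spectrum(e, raw$intensity * jac, label = raw$label, domain = "energy")
}

#' Convert an energy-domain spectrum back to the wavelength domain
#'
#' Inverse of [wavelength_to_energy()]; exists mainly to assert round trips.
#'
#' @param raw a [raw_spectrum()] in the energy domain
#' @inheritParams ev_from_nm
#' @return a [raw_spectrum()] in the wavelength domain
#' @export
energy_to_wavelength <- function(raw, hc = HC_EV_NM) {
  stopifnot(inherits(raw, "raw_spectrum"))
  if (!identical(raw$domain, "energy")) {
    stop("spectrum is not in the energy domain", call. = FALSE)
  }
  e <- raw$abscissa
  lambda <- nm_from_ev(e, hc)
  jac <- e^2 / hc
  raw_spectrum(lambda, raw$intensity * jac, label = raw$label,
               domain = "wavelength")
}

#' Conditioned spectrum on a uniform energy grid
#'
#' The working representation for similarity scoring: non-negative,
#' max-normalized intensities on a uniform eV grid inside an energy window.
#'
#' @param energies ascending uniform grid (eV)
#' @param intensities non-negative values; max-normalized on construction
#' @param window `c(E1, E2)` in eV
#' @param provenance `"experimental"`, `"computed"` or `"synthetic"`
#' @param label identifier
#' @param normalize max-normalize on construction (default TRUE)
#' @return an object of class `spectrum`
#' @export
new_spectrum <- function(energies, intensities, window = range(energies),
                         provenance = c("experimental", "computed",
                                        "synthetic"),
                         label = "", normalize = TRUE) {
  provenance <- match.arg(provenance)
  if (length(energies) != length(intensities)) {
    stop("energies and intensities must have equal length", call. = FALSE)
  }
  if (length(energies) >= 2) {
    d <- diff(energies)
    if (any(d <= 0)) stop("energies must be ascending", call. = FALSE)
    if (max(d) - min(d) > 1e-9) {
      stop("energy grid must be uniform to 1e-9 eV", call. = FALSE)
    }
  }
  if (any(intensities < 0)) stop("intensities must be non-negative",
                                 call. = FALSE)
  m <- max(intensities)
  if (normalize) {
    if (m <= 0) stop("degenerate spectrum: all intensities zero",
                     call. = FALSE)
    intensities <- intensities / m
  }
  structure(
    list(energies = energies, intensities = intensities,
         window = as.numeric(window), provenance = provenance,
         label = label),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> %s: %d points, window [%.3f, %.3f] eV, provenance %s\n",
    if (nzchar(x$label)) x$label else "(unlabeled)",
    length(x$energies), x$window[1], x$window[2], x$provenance))
  invisible(x)
}

#' Grid spacing of a conditioned spectrum
#' @param spec a [new_spectrum()] object
#' @return grid step in eV
#' @export
grid_spacing <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  if (length(spec$energies) < 2) return(NA_real_)
  mean(diff(spec$energies))
}

#' Condition an energy-domain spectrum onto a uniform grid
#'
#' Smooths (optionally), interpolates to a uniform grid of the requested
#' spacing covering the window, clips negatives to zero, and max-normalizes.
#' The default spacing is 100 cm^-1 (~0.0124 eV). The default smoother is a
#' Savitzky-Golay moving-window polynomial filter; pass
#' `smoothing = NULL` to disable it or a function `f(y) -> y` to replace it.
#'
#' @param raw a [raw_spectrum()] in the energy domain
#' @param spacing grid step in eV (> 0)
#' @param window `c(E1, E2)` in eV; must lie inside the data range
#' @param smoothing `NULL`, a list `list(window =, order =)` for
#'   Savitzky-Golay, or a function applied to the intensity vector
#' @param interpolation `"linear"` (default) or `"cubic"` (spline)
#' @param provenance passed to [new_spectrum()]
#' @return a [new_spectrum()] object
#' @export
condition <- function(raw, spacing = cm1_to_ev(100),
                      window = range(raw$abscissa),
                      smoothing = list(window = 5, order = 2),
                      interpolation = c("linear", "cubic"),
                      provenance = "experimental") {
  stopifnot(inherits(raw, "raw_spectrum"))
  interpolation <- match.arg(interpolation)
  if (!identical(raw$domain, "energy")) {
    stop("condition() expects an energy-domain spectrum; ",
         "apply wavelength_to_energy() first", call. = FALSE)
  }
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  window <- sort(as.numeric(window))
  rng <- range(raw$abscissa)
  # an overshoot below one grid step is rounding (digitized endpoints,
  # round-tripped files); anything larger means the data do not cover the
  # requested window
  if (window[1] < rng[1] - spacing || window[2] > rng[2] + spacing) {
    stop(sprintf("window [%g, %g] outside data range [%g, %g]",
                 window[1], window[2], rng[1], rng[2]), call. = FALSE)
  }
  window <- c(max(window[1], rng[1]), min(window[2], rng[2]))
  y <- raw$intensity
  if (is.function(smoothing)) {
    y <- smoothing(y)
  } else if (is.list(smoothing)) {
    n <- smoothing$window %||% 5
    p <- smoothing$order %||% 2
    if (n %% 2 == 0) n <- n + 1
    if (length(y) > n && p < n) {
      y <- signal::sgolayfilt(y, p = p, n = n)
    }
  } else if (!is.null(smoothing)) {
    stop("smoothing must be NULL, a list, or a function", call. = FALSE)
  }
  n_steps <- floor((window[2] - window[1]) / spacing + 1e-9)
  grid <- window[1] + spacing * seq.int(0, n_steps)
  yi <- if (interpolation == "linear") {
    stats::approx(raw$abscissa, y, xout = grid, rule = 2)$y
  } else {
    stats::spline(raw$abscissa, y, xout = grid, method = "natural")$y
  }
  yi[yi < 0] <- 0
  if (max(yi) <= 0) stop("degenerate spectrum: all zero inside window",
                         call. = FALSE)
  new_spectrum(grid, yi, window = window, provenance = provenance,
               label = raw$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stick spectrum of vertical electronic transitions
#'
#' The discrete set of transitions for one compound/method: pairs of
#' transition energy (eV) and dimensionless oscillator strength, stored
#' sorted ascending in energy. Zero-strength rows are retained (they
#' contribute nothing once broadened).
#'
#' @param energies transition energies in eV, all > 0
#' @param strengths oscillator strengths, all >= 0
#' @param label method/compound identifier
#' @return an object of class `stick_spectrum`
#' @export
stick_spectrum <- function(energies, strengths, label = "") {
  if (length(energies) != length(strengths)) {
    stop("energies and strengths must have equal length", call. = FALSE)
  }
  if (length(energies) < 1) stop("need at least one transition",
                                 call. = FALSE)
  if (any(!is.finite(energies)) || any(energies <= 0)) {
    stop("transition energies must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(strengths)) || any(strengths < 0)) {
    stop("oscillator strengths must be finite and non-negative",
         call. = FALSE)
  }
  o <- order(energies)
  structure(
    list(energies = energies[o], strengths = strengths[o], label = label),
    class = "stick_spectrum"
  )
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> %s: %d transitions in [%.3f, %.3f] eV%s\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$energies), min(x$energies), max(x$energies),
              if (all(x$strengths == 0)) " [zero intensity]" else ""))
  invisible(x)
}

#' Does a stick spectrum carry any intensity?
#' @param sticks a [stick_spectrum()]
#' @return TRUE if at least one oscillator strength is positive
#' @export
has_intensity <- function(sticks) {
  stopifnot(inherits(sticks, "stick_spectrum"))
  any(sticks$strengths > 0)
}

#' Read a stick spectrum from two-column text
#'
#' Canonical format: whitespace- or comma-delimited rows of
#' (energy eV, oscillator strength), `#` comments allowed.
#'
#' @inheritParams read_xy_spectrum
#' @return a [stick_spectrum()]
#' @export
read_stick_spectrum <- function(path, sep = "", label = basename(path)) {
  raw <- tryCatch(
    read_xy_spectrum(path, sep = sep, label = label),
    error = function(e) {
      # a single-transition file is legal for sticks but not for spectra
      if (grepl("at least 2 data points", conditionMessage(e))) {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[!grepl("^\\s*(#|$)", lines)]
        if (length(lines) == 1) {
          f <- suppressWarnings(as.numeric(
            strsplit(trimws(lines), "[[:space:],]+")[[1]][1:2]))
          if (!anyNA(f)) return(list(abscissa = f[1], intensity = f[2]))
        }
      }
      stop(e)
    })
  stick_spectrum(raw$abscissa, raw$intensity, label = label)
}

#' Write a stick spectrum as two-column text
#' @param sticks a [stick_spectrum()]
#' @param path output file path
#' @export
write_stick_spectrum <- function(sticks, path) {
  stopifnot(inherits(sticks, "stick_spectrum"))
  writeLines(c("# energy_eV oscillator_strength",
               sprintf("%.8f %.8f", sticks$energies, sticks$strengths)),
             path)
  invisible(path)
}

#' Write a spectrum as two-column text
#' @param spec a [new_spectrum()] or [raw_spectrum()] object
#' @param path output file path
#' @export
write_xy_spectrum <- function(spec, path) {
  if (inherits(spec, "spectrum")) {
    x <- spec$energies; y <- spec$intensities
    hdr <- "# energy_eV intensity"
  } else if (inherits(spec, "raw_spectrum")) {
    x <- spec$abscissa; y <- spec$intensity
    hdr <- sprintf("# %s intensity", spec$domain)
  } else stop("not a spectrum object", call. = FALSE)
  writeLines(c(hdr, sprintf("%.10g %.10g", x, y)), path)
  invisible(path)
}

#' Molecular structure with a designated metal center
#'
#' Element symbols plus Cartesian coordinates in Angstrom; one atom is the
#' metal center around which coordination bonds are measured.
#'
#' @param elements character vector of element symbols
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom)
#' @param metal_index index of the metal atom; `NA` to auto-detect the
#'   unique transition-metal symbol
#' @param label identifier
#' @return an object of class `mol_structure`
#' @export
mol_structure <- function(elements, coords, metal_index = NA_integer_,
                          label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be n x 3", call. = FALSE)
  if (length(elements) != nrow(coords)) {
    stop("elements and coords lengths differ", call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite",
                                    call. = FALSE)
  if (is.na(metal_index)) {
    cand <- which(elements %in% TRANSITION_METALS)
    if (length(cand) == 0) {
      stop("no transition-metal atom found; supply metal_index",
           call. = FALSE)
    }
    if (length(cand) > 1) {
      stop("multiple metal candidates (", paste(cand, collapse = ", "),
           "); supply metal_index", call. = FALSE)
    }
    metal_index <- cand
  }
  metal_index <- as.integer(metal_index)
  if (metal_index < 1 || metal_index > length(elements)) {
    stop("metal_index out of range", call. = FALSE)
  }
  if (!elements[metal_index] %in% TRANSITION_METALS) {
    stop("atom at metal_index (", elements[metal_index],
         ") is not a transition metal", call. = FALSE)
  }
  dimnames(coords) <- NULL
  structure(
    list(elements = as.character(elements), coords = coords,
         metal_index = metal_index, label = label),
    class = "mol_structure"
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure> %s: %d atoms, metal %s at index %d\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$elements), x$elements[x$metal_index],
              x$metal_index))
  invisible(x)
}

#' Read a structure from a standard XYZ file
#'
#' Layout: atom count line, comment line, then `element x y z` rows.
#' Coordinates are taken as Angstrom.
#'
#' @param path file path
#' @param metal_index optional override of metal auto-detection
#' @return a [mol_structure()]
#' @export
read_xyz <- function(path, metal_index = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("not a valid XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("invalid atom count line in ", path,
                              call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("atom count mismatch in %s: header says %d, found %d rows",
                 path, n, length(body)), call. = FALSE)
  }
  body <- body[seq_len(n)]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(f) < 4) stop("malformed atom row ", i, " in ", path,
                            call. = FALSE)
    elements[i] <- f[1]
    coords[i, ] <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(coords[i, ])) stop("non-numeric coordinate in row ", i,
                                 " of ", path, call. = FALSE)
  }
  mol_structure(elements, coords, metal_index = metal_index,
                label = trimws(lines[2]))
}

#' Write a structure as a standard XYZ file
#' @param structure a [mol_structure()]
#' @param path output file path
#' @param comment comment line; defaults to the structure label
#' @export
write_xyz <- function(structure, path, comment = structure$label) {
  stopifnot(inherits(structure, "mol_structure"))
  n <- length(structure$elements)
  rows <- sprintf("%-3s %14.8f %14.8f %14.8f", structure$elements,
                  structure$coords[, 1], structure$coords[, 2],
                  structure$coords[, 3])
  writeLines(c(as.character(n), comment, rows), path)
  invisible(path)
}
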