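#' Composite Simpson quadrature weights on a uniform grid
#'
#' Returns weights `w` such that `sum(w * y)` approximates the integral of
#' `y` sampled at `n` uniformly spaced points with step `h`. Composite
#' Simpson needs an even number of intervals; when `n - 1` is odd the final
#' interval is handled by the trapezoid rule.
#'
#' @param n number of grid points (>= 2)
#' @param h grid step
#' @return numeric weight vector of length `n`
#' @export
simpson_weights <- function(n, h) {
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (h <= 0) stop("step must be positive", call. = FALSE)
  if (n == 2) return(c(h / 2, h / 2))
  m <- if ((n - 1) %% 2 == 0) n else n - 1  # points covered by Simpson
  w <- numeric(n)
  ws <- rep(c(4, 2), length.out = m - 2)
  w[1:m] <- c(1, ws, 1) * h / 3
  if (m < n) {  # trapezoid tail over the last interval
    w[n - 1] <- w[n - 1] + h / 2
    w[n] <- w[n] + h / 2
  }
  w
}

#' Cosine similarity between two spectra (Simpson quadrature)
#'
#' S = int(I_a I_b) / sqrt(int(I_a^2) int(I_b^2)) over the shared window,
#' each integral by composite Simpson quadrature on the shared uniform
#' grid. S is 1 for identical shapes and 0 for non-overlapping ones, and is
#' invariant to positive rescaling of either spectrum.
#'
#' @param a,b [new_spectrum()] objects on the identical energy grid
#' @return similarity in \[0, 1\]
#' @export
similarity <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (length(a$energies) != length(b$energies) ||
      max(abs(a$energies - b$energies)) > 1e-9) {
    stop("spectra are not on the identical energy grid", call. = FALSE)
  }
  ya <- a$intensities
  yb <- b$intensities
  if (max(ya) <= 0 || max(yb) <= 0) {
    stop("degenerate spectrum: identically zero operand", call. = FALSE)
  }
  w <- simpson_weights(length(ya), mean(diff(a$energies)))
  num <- sum(w * ya * yb)
  den <- sqrt(sum(w * ya * ya) * sum(w * yb * yb))
  min(1, max(0, num / den))
}

# similarity of broadened sticks against exp at (delta, sigma); exp grid is
# reused so the integrand is pointwise-aligned, and the normalization of the
# broadened spectrum is recomputed at every parameter value
similarity_at <- function(exp_spec, sticks, delta, sigma) {
  y <- broaden_raw(sticks$energies, sticks$strengths, delta, sigma,
                   exp_spec$energies)
  m <- max(y)
  if (m <= 0) return(0)
  w <- simpson_weights(length(y), mean(diff(exp_spec$energies)))
  ye <- exp_spec$intensities
  num <- sum(w * ye * y)
  den <- sqrt(sum(w * ye * ye) * sum(w * y * y))
  min(1, max(0, num / den))
}

#' Default (delta, sigma) constraint box
#'
#' Shift bounded in \[-1.5, 1.5\] eV; width in (0, 0.5\] eV with a small
#' positive floor (sigma = 0 is singular in the broadening model).
#'
#' @param delta_min,delta_max shift bounds in eV
#' @param sigma_min,sigma_max width bounds in eV
#' @return a list with the four bounds
#' @export
default_bounds <- function(delta_min = -1.5, delta_max = 1.5,
                           sigma_min = 0.005, sigma_max = 0.5) {
  if (delta_min >= delta_max || sigma_min >= sigma_max || sigma_min <= 0) {
    stop("invalid constraint box", call. = FALSE)
  }
  list(delta_min = delta_min, delta_max = delta_max,
       sigma_min = sigma_min, sigma_max = sigma_max)
}

clip_to_box <- function(p, bounds) {
  c(min(max(p[1], bounds$delta_min), bounds$delta_max),
    min(max(p[2], bounds$sigma_min), bounds$sigma_max))
}

#' Maximize spectral similarity over shift and broadening
#'
#' Finds the (delta, sigma) maximizing the cosine similarity between the
#' broadened stick spectrum and the experimental spectrum, by Nelder-Mead
#' restarted from a coarse grid of initial points inside the constraint
#' box. The box is enforced by clipping proposed points to it plus a
#' quadratic penalty outside it, which preserves simplex behavior near the
#' boundary. Ties across restarts are broken by higher similarity, then
#' smaller |delta|, then smaller sigma.
#'
#' @param exp_spec the conditioned experimental [new_spectrum()]
#' @param sticks a [stick_spectrum()] with at least one positive strength
#' @param bounds constraint box from [default_bounds()]
#' @param n_starts starts per axis of the restart grid (default 3, i.e. a
#'   3 x 3 grid of initial points)
#' @param reltol Nelder-Mead relative convergence tolerance
#' @param maxit iteration cap per restart
#' @return a `similarity_result`: list with `s_max`, `delta_opt`,
#'   `sigma_opt`, `fwhm_opt`, `abs_shift`, `apparent_band_shift` (= -delta),
#'   `window`, and `diagnostics` (per-restart counts, convergence flag)
#' @export
optimize_similarity <- function(exp_spec, sticks, bounds = default_bounds(),
                                n_starts = 3, reltol = 1e-10,
                                maxit = 500) {
  stopifnot(inherits(exp_spec, "spectrum"), inherits(sticks, "stick_spectrum"))
  if (!has_intensity(sticks)) {
    stop("degenerate stick spectrum: all oscillator strengths zero",
         call. = FALSE)
  }
  penalty <- 1e4
  objective <- function(p) {
    q <- clip_to_box(p, bounds)
    -similarity_at(exp_spec, sticks, q[1], q[2]) +
      penalty * sum((p - q)^2)
  }
  deltas <- seq(bounds$delta_min, bounds$delta_max,
                length.out = n_starts + 2)[-c(1, n_starts + 2)]
  sigmas <- seq(bounds$sigma_min, bounds$sigma_max,
                length.out = n_starts + 2)[-c(1, n_starts + 2)]
  starts <- expand.grid(delta = deltas, sigma = sigmas)

  best <- NULL
  evals <- 0L
  any_converged <- FALSE
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[k, ]), objective,
                        method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    evals <- evals + fit$counts[["function"]]
    p <- clip_to_box(fit$par, bounds)
    s <- similarity_at(exp_spec, sticks, p[1], p[2])
    conv <- fit$convergence == 0
    any_converged <- any_converged || conv
    cand <- list(s = s, delta = p[1], sigma = p[2])
    if (is.null(best) || better_fit(cand, best)) best <- cand
  }
  structure(
    list(
      s_max = best$s,
      delta_opt = best$delta,
      sigma_opt = best$sigma,
      fwhm_opt = fwhm_from_sigma(best$sigma),
      abs_shift = abs(best$delta),
      apparent_band_shift = -best$delta,
      window = exp_spec$window,
      diagnostics = list(restarts = nrow(starts), fn_evals = evals,
                         converged = any_converged)
    ),
    class = "similarity_result"
  )
}

# tie-breaking: higher S, then smaller |delta|, then smaller sigma
better_fit <- function(a, b, tol = 1e-10) {
  if (a$s > b$s + tol) return(TRUE)
  if (a$s < b$s - tol) return(FALSE)
  if (abs(a$delta) < abs(b$delta) - tol) return(TRUE)
  if (abs(a$delta) > abs(b$delta) + tol) return(FALSE)
  a$sigma < b$sigma
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    paste0("<similarity_result> S_max = %.4f (%.1f%%)\n",
           "  shift delta = %+.4f eV (apparent band shift %+.4f eV)\n",
           "  width sigma = %.4f eV (FWHM %.4f eV)\n",
           "  window [%.3f, %.3f] eV, converged: %s\n"),
    x$s_max, 100 * x$s_max, x$delta_opt, x$apparent_band_shift,
    x$sigma_opt, x$fwhm_opt, x$window[1], x$window[2],
    x$diagnostics$converged))
  invisible(x)
}

#' Exhaustive grid scan of the similarity surface
#'
#' Evaluates S(delta, sigma) on a regular grid over the constraint box and
#' returns the best point. Slow but assumption-free; serves as a
#' brute-force reference for the Nelder-Mead search.
#'
#' @inheritParams optimize_similarity
#' @param delta_step,sigma_step scan resolution in eV
#' @return list with `s_max`, `delta_opt`, `sigma_opt`
#' @export
scan_similarity <- function(exp_spec, sticks, bounds = default_bounds(),
                            delta_step = 0.01, sigma_step = 0.005) {
  deltas <- seq(bounds$delta_min, bounds$delta_max, by = delta_step)
  sigmas <- seq(bounds$sigma_min, bounds$sigma_max, by = sigma_step)
  best <- list(s = -Inf, delta = NA_real_, sigma = NA_real_)
  ye <- exp_spec$intensities
  w <- simpson_weights(length(ye), mean(diff(exp_spec$energies)))
  we2 <- sum(w * ye * ye)
  # grid-to-stick distance matrix is reused across all scan points
  d0 <- outer(exp_spec$energies, sticks$energies, "-")
  for (sg in sigmas) {
    for (dl in deltas) {
      z <- (d0 + dl) / sg
      y <- as.numeric(exp(-0.5 * z * z) %*% sticks$strengths)
      if (max(y) <= 0) next
      s <- sum(w * ye * y) / sqrt(we2 * sum(w * y * y))
      if (s > best$s) best <- list(s = s, delta = dl, sigma = sg)
    }
  }
  list(s_max = min(1, best$s), delta_opt = best$delta,
       sigma_opt = best$sigma)
}
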