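#' Generate a random stick spectrum
#'
#' Transition energies are drawn uniformly over the range; oscillator
#' strengths follow a log-uniform law spanning `decades` orders of
#' magnitude by default, so a few transitions dominate the band shape as
#' in typical vertical-excitation calculations.
#'
#' @param n number of transitions (>= 1)
#' @param energy_range `c(lo, hi)` in eV, lo < hi, lo > 0
#' @param strength_law `"loguniform"` or `"uniform"`
#' @param decades dynamic range of the log-uniform law (default 2)
#' @param seed integer; fixes all randomness
#' @param label identifier
#' @return a [stick_spectrum()]
#' @export
gen_sticks <- function(n, energy_range = c(1.4, 6.2),
                       strength_law = c("loguniform", "uniform"),
                       decades = 2, seed, label = "synthetic") {
  strength_law <- match.arg(strength_law)
  if (n < 1) stop("need at least one transition", call. = FALSE)
  if (energy_range[1] <= 0 || energy_range[1] >= energy_range[2]) {
    stop("invalid energy range", call. = FALSE)
  }
  withr::with_seed(seed, {
    e <- stats::runif(n, energy_range[1], energy_range[2])
    f <- switch(strength_law,
      loguniform = 10^stats::runif(n, -decades, 0),
      uniform = stats::runif(n)
    )
    stick_spectrum(e, f, label = label)
  })
}

#' Define a pseudo-experimental spectrum scenario
#'
#' Bundles the ground truth for closed-loop testing: the underlying stick
#' spectrum, the true shift and broadening, the noise level and the window.
#'
#' @param sticks_true a [stick_spectrum()]
#' @param delta_true true shift in eV, inside \[-1.5, 1.5\]
#' @param sigma_true true width in eV, inside (0, 0.5\]
#' @param noise_level relative multiplicative noise fraction (sd of the
#'   zero-mean relative perturbation)
#' @param baseline additive baseline offset as a fraction of the maximum
#'   (default 0)
#' @param window `c(E1, E2)` in eV
#' @param seed integer; fixes all randomness
#' @return an object of class `spectrum_scenario`
#' @export
spectrum_scenario <- function(sticks_true, delta_true, sigma_true,
                              noise_level = 0, baseline = 0,
                              window, seed) {
  stopifnot(inherits(sticks_true, "stick_spectrum"))
  if (delta_true < -1.5 || delta_true > 1.5) {
    stop("delta_true outside [-1.5, 1.5] eV", call. = FALSE)
  }
  if (sigma_true <= 0 || sigma_true > 0.5) {
    stop("sigma_true outside (0, 0.5] eV", call. = FALSE)
  }
  structure(
    list(sticks_true = sticks_true, delta_true = delta_true,
         sigma_true = sigma_true, noise_level = noise_level,
         baseline = baseline, window = sort(as.numeric(window)),
         seed = as.integer(seed)),
    class = "spectrum_scenario"
  )
}

#' Generate a pseudo-experimental spectrum with known ground truth
#'
#' Broadens the scenario's stick spectrum with the true (delta, sigma),
#' multiplies each point by `1 + noise_level * u` with seeded zero-mean
#' Gaussian `u`, adds any baseline fraction, clips negatives and
#' max-normalizes on the uniform grid. The returned spectrum carries the
#' scenario as attribute `"truth"`.
#'
#' @param scenario a [spectrum_scenario()]
#' @param spacing grid step in eV (default 100 cm^-1)
#' @return a [new_spectrum()] with provenance `"synthetic"`
#' @export
gen_experimental <- function(scenario, spacing = cm1_to_ev(100)) {
  stopifnot(inherits(scenario, "spectrum_scenario"))
  w <- scenario$window
  n_steps <- floor((w[2] - w[1]) / spacing + 1e-9)
  grid <- w[1] + spacing * seq.int(0, n_steps)
  y <- broaden_raw(scenario$sticks_true$energies,
                   scenario$sticks_true$strengths,
                   scenario$delta_true, scenario$sigma_true, grid)
  if (max(y) <= 0) stop("scenario broadens to zero over the window",
                        call. = FALSE)
  y <- y / max(y)
  if (scenario$noise_level > 0 || scenario$baseline != 0) {
    y <- withr::with_seed(scenario$seed, {
      y * (1 + scenario$noise_level * stats::rnorm(length(y))) +
        scenario$baseline
    })
    y[y < 0] <- 0
    if (max(y) <= 0) stop("noise drove the spectrum to zero",
                          call. = FALSE)
    y <- y / max(y)
  }
  out <- new_spectrum(grid, y, window = w, provenance = "synthetic",
                      label = scenario$sticks_true$label,
                      normalize = FALSE)
  attr(out, "truth") <- scenario
  out
}

#' Ideal metal-ligand coordination toy structure
#'
#' Metal at the origin with ligand donor atoms at ideal polyhedron
#' vertices: tetrahedron (4), trigonal bipyramid (5) or octahedron (6).
#'
#' @param bond_length metal-donor distance in Angstrom
#' @param n_ligands coordination number, one of 4, 5, 6
#' @param metal metal element symbol (default `"Fe"`)
#' @param donor donor element symbol (default `"N"`)
#' @param label identifier
#' @return a [mol_structure()]
#' @export
gen_octahedral_toy <- function(bond_length = 2.0, n_ligands = 6,
                               metal = "Fe", donor = "N",
                               label = "toy") {
  dirs <- switch(as.character(n_ligands),
    "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3),
    "5" = rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)),
    "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)),
    stop("unsupported coordination number: ", n_ligands, call. = FALSE)
  )
  coords <- rbind(c(0, 0, 0), dirs * bond_length)
  mol_structure(c(metal, rep(donor, n_ligands)), coords,
                metal_index = 1L, label = label)
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) by QR of a Gaussian matrix with sign fixing and a
#' determinant correction.
#'
#' @param seed integer seed
#' @return 3 x 3 proper rotation matrix
#' @export
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qrd <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qrd)
    q <- q %*% diag(sign(diag(qr.R(qrd))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

#' Define a perturbed-structure scenario
#'
#' @param base a [mol_structure()] with a valid metal center
#' @param bond_deltas per-bond signed stretches in Angstrom, one per
#'   detected metal-ligand bond
#' @param jitter isotropic Gaussian displacement scale (Angstrom) applied
#'   to atoms outside the coordination sphere
#' @param seed integer; fixes the jitter and the rigid motion
#' @param tolerance covalent-radius tolerance for bond detection
#' @return an object of class `structure_scenario`
#' @export
structure_scenario <- function(base, bond_deltas, jitter = 0, seed,
                               tolerance = 1.3) {
  stopifnot(inherits(base, "mol_structure"))
  bonds <- detect_metal_bonds(base, tolerance)
  if (length(bond_deltas) != bonds$n) {
    stop("bond_deltas length (", length(bond_deltas),
         ") does not match detected bonds (", bonds$n, ")", call. = FALSE)
  }
  structure(
    list(base = base, bonds = bonds, bond_deltas = as.numeric(bond_deltas),
         jitter = jitter, seed = as.integer(seed)),
    class = "structure_scenario"
  )
}

#' Generate a computed-like / reference-like structure pair
#'
#' The reference is the base structure. The computed-like copy stretches
#' each metal-ligand bond along its bond vector by the scenario's signed
#' deltas, jitters atoms outside the coordination sphere, then applies a
#' seeded rigid motion (proper rotation + translation). With zero jitter
#' the ground-truth bond MUE/MSE are exactly `mean(abs(bond_deltas))` and
#' `mean(bond_deltas)`.
#'
#' @param scenario a [structure_scenario()]
#' @return list with `comp`, `ref`, `bonds`, `mue_true`, `mse_true`
#' @export
gen_structure_pair <- function(scenario) {
  stopifnot(inherits(scenario, "structure_scenario"))
  base <- scenario$base
  bonds <- scenario$bonds
  coords <- base$coords
  xm <- coords[bonds$metal_index, ]
  for (k in seq_len(bonds$n)) {
    i <- bonds$ligand_indices[k]
    v <- coords[i, ] - xm
    len <- sqrt(sum(v * v))
    coords[i, ] <- xm + v * (len + scenario$bond_deltas[k]) / len
  }
  moved <- withr::with_seed(scenario$seed, {
    if (scenario$jitter > 0) {
      outside <- setdiff(seq_len(nrow(coords)),
                         c(bonds$metal_index, bonds$ligand_indices))
      if (length(outside)) {
        coords[outside, ] <- coords[outside, ] +
          matrix(stats::rnorm(3 * length(outside), sd = scenario$jitter),
                 ncol = 3)
      }
    }
    rot <- {
      qrd <- qr(matrix(stats::rnorm(9), 3, 3))
      q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      q
    }
    shift <- stats::runif(3, -5, 5)
    sweep(coords %*% rot, 2, shift, "+")
  })
  comp <- mol_structure(base$elements, moved,
                        metal_index = base$metal_index,
                        label = paste0(base$label, "_computed"))
  list(comp = comp, ref = base, bonds = bonds,
       mue_true = mean(abs(scenario$bond_deltas)),
       mse_true = mean(scenario$bond_deltas))
}

#' Write a complete synthetic benchmark to disk
#'
#' Emits, for `n_compounds` x `n_methods`, the pseudo-experimental spectra,
#' per-method stick spectra and structures, per-compound reference
#' structures, a YAML manifest consumable by [run_benchmark()], and a
#' ground-truth sidecar table. Every file is plain text; the whole bundle
#' is a pure function of the seed.
#'
#' Each compound's "true" method applies a compound-specific shift and
#' width; the other methods perturb the stick energies and strengths so
#' their recovered shifts and similarities spread realistically.
#'
#' @param dir output directory (created if needed)
#' @param n_compounds number of synthetic compounds
#' @param n_methods number of synthetic methods
#' @param n_transitions vertical states per stick spectrum (default 40)
#' @param noise_level relative noise on the pseudo-experimental spectra
#' @param seed integer master seed
#' @return invisibly, the manifest path
#' @export
simulate_benchmark <- function(dir, n_compounds = 4, n_methods = 3,
                               n_transitions = 40, noise_level = 0.02,
                               seed = 20260921) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pars <- withr::with_seed(seed, {
    list(
      delta = stats::runif(n_compounds, -0.6, 0.6),
      sigma = stats::runif(n_compounds, 0.1, 0.35),
      window_lo = stats::runif(n_compounds, 1.4, 2.2),
      window_width = stats::runif(n_compounds, 2.0, 3.0),
      bond_len = stats::runif(n_compounds, 1.9, 2.2)
    )
  })
  compounds <- list()
  truth_rows <- list()
  for (i in seq_len(n_compounds)) {
    id <- sprintf("cpd%02d", i)
    w <- c(pars$window_lo[i], pars$window_lo[i] + pars$window_width[i])
    sticks <- gen_sticks(n_transitions, energy_range = w + c(0.2, -0.2),
                         seed = seed + 100 * i, label = id)
    scen <- spectrum_scenario(sticks, delta_true = pars$delta[i],
                              sigma_true = pars$sigma[i],
                              noise_level = noise_level, window = w,
                              seed = seed + 100 * i + 1)
    exp_spec <- gen_experimental(scen)
    exp_path <- file.path(dir, paste0(id, "_exp.txt"))
    write_xy_spectrum(exp_spec, exp_path)

    base <- gen_octahedral_toy(bond_length = pars$bond_len[i],
                               n_ligands = 6, label = id)
    ref_path <- file.path(dir, paste0(id, "_ref.xyz"))
    write_xyz(base, ref_path)

    methods <- list()
    for (j in seq_len(n_methods)) {
      mname <- sprintf("method%02d", j)
      mseed <- seed + 100 * i + 10 * j
      msticks <- withr::with_seed(mseed, {
        stick_spectrum(
          sticks$energies + stats::rnorm(n_transitions, sd = 0.05 * j),
          sticks$strengths *
            exp(stats::rnorm(n_transitions, sd = 0.1 * j)),
          label = paste(id, mname))
      })
      stk_path <- file.path(dir, paste0(id, "_", mname, ".stk"))
      write_stick_spectrum(msticks, stk_path)

      sscen <- structure_scenario(
        base,
        bond_deltas = withr::with_seed(mseed + 1,
                                       stats::rnorm(6, sd = 0.02 * j)),
        jitter = 0, seed = mseed + 2)
      pair <- gen_structure_pair(sscen)
      xyz_path <- file.path(dir, paste0(id, "_", mname, ".xyz"))
      write_xyz(pair$comp, xyz_path)

      methods[[mname]] <- list(sticks = basename(stk_path),
                               structure = basename(xyz_path))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        compound = id, method = mname,
        delta_true = pars$delta[i], sigma_true = pars$sigma[i],
        mue_true = pair$mue_true, mse_true = pair$mse_true)
    }
    compounds[[i]] <- list(id = id, window = w,
                           exp_spectrum = basename(exp_path),
                           ref_structure = basename(ref_path),
                           solvent = "synthetic", methods = methods)
  }
  manifest <- list(compounds = compounds, spacing_ev = cm1_to_ev(100))
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path, precision = 12)
  write_tsv_stable(do.call(rbind, truth_rows),
                   file.path(dir, "ground_truth.tsv"))
  invisible(manifest_path)
}
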