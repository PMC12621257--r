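#' Optimal rigid-body superposition RMSE between two structures
#'
#' Superposes the computed structure onto the reference by centroid
#' alignment plus the optimal proper rotation (Kabsch/SVD with a
#' determinant correction so no reflection is applied), then evaluates
#'
#'   RMSE = sqrt( (1/N) sum_i |r_i^comp - r_i^ref|^2 )
#'
#' Atom correspondence is positional (index by index); hydrogen atoms are
#' excluded by default because their crystallographic positions are
#' unreliable. A strict element-sequence check guards against misordered
#' files.
#'
#' @param comp,ref [mol_structure()] objects with matching element sequences
#' @param exclude_h drop hydrogen atoms before superposition (default TRUE)
#' @return minimal RMSE in Angstrom
#' @export
superpose_rmse <- function(comp, ref, exclude_h = TRUE) {
  stopifnot(inherits(comp, "mol_structure"), inherits(ref, "mol_structure"))
  ec <- comp$elements
  er <- ref$elements
  xc <- comp$coords
  xr <- ref$coords
  if (exclude_h) {
    kc <- ec != "H"
    kr <- er != "H"
    ec <- ec[kc]; xc <- xc[kc, , drop = FALSE]
    er <- er[kr]; xr <- xr[kr, , drop = FALSE]
  }
  if (length(ec) != length(er) || any(ec != er)) {
    stop("element sequences do not correspond (index-by-index mapping)",
         call. = FALSE)
  }
  n <- nrow(xc)
  if (n < 3) stop("need at least 3 atoms for superposition", call. = FALSE)
  xc <- sweep(xc, 2, colMeans(xc))
  xr <- sweep(xr, 2, colMeans(xr))
  if (qr(xc)$rank < 2 || qr(xr)$rank < 2) {
    stop("ill-posed superposition: atoms are collinear", call. = FALSE)
  }
  rot <- kabsch_rotation(xc, xr)
  d <- xr - xc %*% rot
  sqrt(sum(d * d) / n)
}

# optimal proper rotation R minimizing |B - A R|_F (Kabsch via SVD)
kabsch_rotation <- function(a, b) {
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose one structure onto another
#'
#' Returns `comp` rigidly moved onto `ref` by the transform that minimizes
#' the (hydrogen-excluded, by default) RMSE. All atoms are moved, including
#' any excluded from the fit.
#'
#' @inheritParams superpose_rmse
#' @return the transformed [mol_structure()]
#' @export
superpose <- function(comp, ref, exclude_h = TRUE) {
  stopifnot(inherits(comp, "mol_structure"), inherits(ref, "mol_structure"))
  keep_c <- if (exclude_h) comp$elements != "H" else
    rep(TRUE, length(comp$elements))
  keep_r <- if (exclude_h) ref$elements != "H" else
    rep(TRUE, length(ref$elements))
  xc <- comp$coords[keep_c, , drop = FALSE]
  xr <- ref$coords[keep_r, , drop = FALSE]
  if (nrow(xc) != nrow(xr)) {
    stop("element sequences do not correspond", call. = FALSE)
  }
  cc <- colMeans(xc)
  cr <- colMeans(xr)
  rot <- kabsch_rotation(sweep(xc, 2, cc), sweep(xr, 2, cr))
  moved <- sweep(sweep(comp$coords, 2, cc) %*% rot, 2, cr, "+")
  mol_structure(comp$elements, moved, metal_index = comp$metal_index,
                label = comp$label)
}

#' Detect the metal coordination sphere by covalent-radius cutoff
#'
#' A non-hydrogen atom X is bonded to the metal M when
#' `dist(M, X) <= tolerance * (r_cov(M) + r_cov(X))`. Detection should run
#' on the reference (crystallographic) structure; the same index pairs are
#' then applied to the computed one so both measure the same bonds.
#'
#' @param structure a [mol_structure()]
#' @param tolerance dimensionless scale on the covalent-radius sum
#'   (default 1.3)
#' @return a `bond_set`: list with `metal_index`, `ligand_indices`,
#'   `elements` (ligand element symbols) and `n`
#' @export
detect_metal_bonds <- function(structure, tolerance = 1.3) {
  stopifnot(inherits(structure, "mol_structure"))
  m <- structure$metal_index
  xm <- structure$coords[m, ]
  rm_ <- covalent_radius(structure$elements[m])
  idx <- integer(0)
  for (i in seq_along(structure$elements)) {
    if (i == m) next
    el <- structure$elements[i]
    if (el == "H") next
    d <- sqrt(sum((structure$coords[i, ] - xm)^2))
    if (d <= tolerance * (rm_ + covalent_radius(el))) idx <- c(idx, i)
  }
  if (length(idx) == 0) {
    stop("no metal-ligand bonds detected; check tolerance or geometry",
         call. = FALSE)
  }
  bond_set(m, idx, structure$elements[idx])
}

#' Construct an explicit metal-ligand bond set
#'
#' Use this to override automatic detection with a curated coordination
#' sphere (e.g. from a benchmark manifest).
#'
#' @param metal_index index of the metal atom
#' @param ligand_indices indices of the directly coordinated non-hydrogen
#'   atoms
#' @param elements optional ligand element symbols (bookkeeping only)
#' @return an object of class `bond_set`
#' @export
bond_set <- function(metal_index, ligand_indices, elements = NULL) {
  ligand_indices <- as.integer(ligand_indices)
  if (length(ligand_indices) < 1) stop("need at least one bond",
                                       call. = FALSE)
  if (anyDuplicated(ligand_indices) ||
      metal_index %in% ligand_indices) {
    stop("bond pairs must be distinct", call. = FALSE)
  }
  structure(
    list(metal_index = as.integer(metal_index),
         ligand_indices = ligand_indices,
         elements = elements, n = length(ligand_indices)),
    class = "bond_set"
  )
}

metal_ligand_distances <- function(structure, bonds) {
  xm <- structure$coords[bonds$metal_index, ]
  apply(structure$coords[bonds$ligand_indices, , drop = FALSE], 1,
        function(x) sqrt(sum((x - xm)^2)))
}

#' Metal-ligand bond-length errors (MUE and MSE)
#'
#' For each bond in `bonds`, the signed error is
#' `R^comp - R^ref` (Angstrom). MUE is the mean absolute error; MSE the
#' mean signed error, whose sign reveals systematic over- or
#' under-estimation of the coordination sphere. Distances are
#' superposition-independent.
#'
#' @param comp,ref [mol_structure()] objects sharing the atom ordering
#' @param bonds a `bond_set` (detected on `ref` or supplied explicitly)
#' @return a `structure_errors` list with `mue`, `mse`, `per_bond`, `n`
#' @export
bond_errors <- function(comp, ref, bonds) {
  stopifnot(inherits(comp, "mol_structure"), inherits(ref, "mol_structure"),
            inherits(bonds, "bond_set"))
  nmax <- min(length(comp$elements), length(ref$elements))
  if (bonds$metal_index > nmax || any(bonds$ligand_indices > nmax)) {
    stop("bond indices out of range for the structures", call. = FALSE)
  }
  per_bond <- metal_ligand_distances(comp, bonds) -
    metal_ligand_distances(ref, bonds)
  structure(
    list(mue = mean(abs(per_bond)), mse = mean(per_bond),
         per_bond = unname(per_bond), n = bonds$n),
    class = "structure_errors"
  )
}

#' All three structure metrics for one computed/reference pair
#'
#' Convenience wrapper: superposition RMSE plus bond MUE/MSE with bonds
#' detected on the reference (or supplied).
#'
#' @inheritParams bond_errors
#' @param tolerance covalent-radius tolerance for bond detection
#' @param bonds optional explicit `bond_set`; detected on `ref` if missing
#' @return list with `rmse`, `mue`, `mse`, `per_bond`, `n_bonds`
#' @export
structure_metrics <- function(comp, ref, tolerance = 1.3, bonds = NULL) {
  if (is.null(bonds)) bonds <- detect_metal_bonds(ref, tolerance)
  be <- bond_errors(comp, ref, bonds)
  list(rmse = superpose_rmse(comp, ref), mue = be$mue, mse = be$mse,
       per_bond = be$per_bond, n_bonds = be$n)
}
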