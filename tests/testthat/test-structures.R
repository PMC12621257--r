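test_that("superposition RMSE is zero for identical and rigidly moved copies", {
  toy <- gen_octahedral_toy(2.0, 6)
  expect_lt(superpose_rmse(toy, toy), 1e-10)

  for (seed in 1:5) {
    rot <- random_rotation(seed)
    moved <- mol_structure(toy$elements,
                           sweep(toy$coords %*% rot, 2,
                                 c(3.2, -1.1, 0.7) * seed, "+"),
                           metal_index = 1L)
    expect_lt(superpose_rmse(moved, toy), 1e-8)
  }
})

test_that("superposition RMSE matches a brute-force rigid-motion search", {
  # 4-atom toy with one atom displaced 0.30 Angstrom
  ref <- mol_structure(c("Fe", "N", "N", "N"),
                       rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
                             c(0, 0, 2)), metal_index = 1L)
  comp_coords <- ref$coords
  comp_coords[2, ] <- comp_coords[2, ] + c(0.3, 0, 0)
  comp <- mol_structure(ref$elements, comp_coords, metal_index = 1L)
  mine <- superpose_rmse(comp, ref)
  oracle <- brute_force_rmse(comp$coords, ref$coords)
  expect_equal(mine, oracle, tolerance = 1e-4)

  for (seed in c(31, 32, 33)) {
    a <- random_toy_structure(7, seed)
    b <- random_toy_structure(7, seed + 100)
    b <- mol_structure(a$elements, b$coords, metal_index = 1L)
    expect_equal(superpose_rmse(a, b, exclude_h = FALSE),
                 brute_force_rmse(a$coords, b$coords), tolerance = 1e-4)
  }
})

test_that("superposition RMSE agrees with bio3d's fitted RMSD", {
  skip_if_not_installed("bio3d")
  toy <- gen_octahedral_toy(2.05, 6)
  scen <- structure_scenario(toy,
                             bond_deltas = c(0.05, -0.1, 0, 0.02,
                                             -0.03, 0.01),
                             jitter = 0.05, seed = 9)
  pair <- gen_structure_pair(scen)
  mine <- superpose_rmse(pair$comp, pair$ref, exclude_h = FALSE)
  b3d <- bio3d::rmsd(as.numeric(t(pair$ref$coords)),
                     as.numeric(t(pair$comp$coords)), fit = TRUE)
  expect_equal(round(mine, 3), b3d)  # bio3d prints rounded to 3 digits
})

test_that("RMSE is symmetric, rigid-motion invariant, and H-excluding", {
  a <- random_toy_structure(9, 51)
  bshift <- random_toy_structure(9, 52)
  b <- mol_structure(a$elements, bshift$coords, metal_index = 1L)
  expect_equal(superpose_rmse(a, b), superpose_rmse(b, a),
               tolerance = 1e-10)

  rot <- random_rotation(77)
  a2 <- mol_structure(a$elements, sweep(a$coords %*% rot, 2, 1:3, "+"),
                      metal_index = 1L)
  b2 <- mol_structure(b$elements, sweep(b$coords %*% rot, 2, 1:3, "+"),
                      metal_index = 1L)
  expect_equal(superpose_rmse(a2, b2), superpose_rmse(a, b),
               tolerance = 1e-8)

  # hydrogens ignored by default: moving one leaves the RMSE unchanged
  el <- c("Fe", "N", "N", "N", "H")
  xa <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(1, 1, 1))
  xb <- xa; xb[2, 1] <- 2.4; xb[5, ] <- c(9, 9, 9)
  sa <- mol_structure(el, xa, metal_index = 1L)
  sb <- mol_structure(el, xb, metal_index = 1L)
  sb_hfixed <- mol_structure(el, {x <- xb; x[5, ] <- xa[5, ]; x},
                             metal_index = 1L)
  expect_equal(superpose_rmse(sa, sb), superpose_rmse(sa, sb_hfixed),
               tolerance = 1e-12)

  bad <- mol_structure(c("Fe", "O", "N", "N"), xa[1:4, ],
                       metal_index = 1L)
  expect_error(superpose_rmse(bad, mol_structure(c("Fe", "N", "N", "N"),
                                                 xa[1:4, ],
                                                 metal_index = 1L)),
               "element sequences")
})

test_that("bond detection finds the coordination sphere and excludes H", {
  toy <- gen_octahedral_toy(2.0, 6)
  b <- detect_metal_bonds(toy)
  expect_equal(b$n, 6L)
  expect_setequal(b$ligand_indices, 2:7)

  # one ligand pulled out of the coordination sphere
  far <- toy$coords; far[3, ] <- far[3, ] / 2.0 * 3.5
  toy_far <- mol_structure(toy$elements, far, metal_index = 1L)
  expect_equal(detect_metal_bonds(toy_far, tolerance = 1.3)$n, 5L)

  # hydrogen close to the metal is never a bond
  el <- c(toy$elements, "H")
  xh <- rbind(toy$coords, c(1.6, 0, 0) / sqrt(1) * 1)
  toy_h <- mol_structure(el, xh, metal_index = 1L)
  expect_false(8L %in% detect_metal_bonds(toy_h)$ligand_indices)

  lone <- mol_structure(c("Fe", "N"), rbind(c(0, 0, 0), c(9, 0, 0)),
                        metal_index = 1L)
  expect_error(detect_metal_bonds(lone), "no metal-ligand bonds")
})

test_that("bond errors reproduce hand-computed MUE/MSE", {
  toy <- gen_octahedral_toy(2.0, 6)
  bonds <- detect_metal_bonds(toy)

  stretch <- function(deltas) {
    x <- toy$coords
    for (k in seq_along(deltas)) {
      i <- bonds$ligand_indices[k]
      v <- x[i, ]; x[i, ] <- v * (2.0 + deltas[k]) / 2.0
    }
    mol_structure(toy$elements, x, metal_index = 1L)
  }

  e1 <- bond_errors(stretch(rep(0.02, 6)), toy, bonds)
  expect_equal(e1$mue, 0.02, tolerance = 1e-12)
  expect_equal(e1$mse, 0.02, tolerance = 1e-12)

  e2 <- bond_errors(stretch(c(0.02, 0.02, 0.02, -0.02, -0.02, -0.02)),
                    toy, bonds)
  expect_equal(e2$mue, 0.02, tolerance = 1e-12)
  expect_equal(e2$mse, 0, tolerance = 1e-12)

  # two-bond hand case: 2.00->2.05 and 2.10->2.00
  ref <- mol_structure(c("Fe", "N", "O"),
                       rbind(c(0, 0, 0), c(2.00, 0, 0), c(0, 2.10, 0)),
                       metal_index = 1L)
  comp <- mol_structure(c("Fe", "N", "O"),
                        rbind(c(0, 0, 0), c(2.05, 0, 0), c(0, 2.00, 0)),
                        metal_index = 1L)
  e3 <- bond_errors(comp, ref, bond_set(1, c(2, 3)))
  expect_equal(e3$per_bond, c(0.05, -0.10), tolerance = 1e-12)
  expect_equal(e3$mue, 0.075, tolerance = 1e-12)
  expect_equal(e3$mse, -0.025, tolerance = 1e-12)
})

test_that("bond errors are orientation-independent and obey mue >= |mse|", {
  toy <- gen_octahedral_toy(2.1, 6)
  for (seed in 1:20) {
    deltas <- withr::with_seed(seed, stats::rnorm(6, sd = 0.05))
    pair <- gen_structure_pair(
      structure_scenario(toy, deltas, jitter = 0, seed = seed + 500))
    e <- bond_errors(pair$comp, pair$ref, pair$bonds)
    expect_equal(e$mue, mean(abs(deltas)), tolerance = 1e-9)
    expect_equal(e$mse, mean(deltas), tolerance = 1e-9)
    expect_gte(e$mue, abs(e$mse) - 1e-12)
  }
})
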