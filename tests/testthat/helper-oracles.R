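# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# closed-form cosine similarity of two unit-height Gaussians with common
# width sigma and center separation d (infinite-domain overlap integrals)
gaussian_overlap_similarity <- function(d, sigma) {
  exp(-d^2 / (4 * sigma^2))
}

euler_rotation <- function(a, b, c) {
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  rz %*% ry %*% rx
}

# brute-force rigid-motion RMSD minimizer: numerical search over the three
# Euler angles and the translation vector, multi-started; knows nothing of
# the SVD-based superposition it is used to validate
brute_force_rmse <- function(xa, xb, n_starts = 12, seed = 1) {
  obj <- function(p) {
    r <- euler_rotation(p[1], p[2], p[3])
    d <- xb - (xa %*% t(r) + matrix(p[4:6], nrow(xa), 3, byrow = TRUE))
    sqrt(sum(d * d) / nrow(xa))
  }
  best <- Inf
  starts <- withr::with_seed(seed, {
    cbind(matrix(stats::runif(3 * n_starts, -pi, pi), ncol = 3),
          matrix(stats::rnorm(3 * n_starts, sd = 2), ncol = 3))
  })
  starts[1, ] <- c(0, 0, 0, colMeans(xb) - colMeans(xa))
  for (k in seq_len(n_starts)) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (fit$value < best) best <- fit$value
  }
  best
}

# random non-degenerate toy structure: Fe center plus n scattered atoms
random_toy_structure <- function(n_atoms, seed, spread = 2.5) {
  withr::with_seed(seed, {
    elements <- c("Fe", sample(c("N", "O", "C", "Cl"), n_atoms - 1,
                               replace = TRUE))
    coords <- matrix(stats::rnorm(3 * n_atoms, sd = spread), ncol = 3)
    mol_structure(elements, coords, metal_index = 1L)
  })
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
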