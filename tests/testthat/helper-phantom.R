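# desk-scale specs shared across tests: small grid and direction count keep
# each tensor fit well under a second while staying full-rank and bilateral

small_spec <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L, 12L), n_dirs_per_shell = 24L, ...)
}

# uniform isotropic phantom: identical tensor everywhere, no landmark
iso_spec <- function(d = 0.7e-3, ...) {
  small_spec(lambda_parallel = d, lambda_perp = d, d_perivascular = 0,
             background_diffusivity = d, csf_diffusivity = d, ...)
}

# synthesise signals from an explicit single tensor (components xx,yy,zz,xy,xz,yz)
single_voxel_dwi <- function(D6, bvals, bvecs, S0 = 1000) {
  q <- bvals * (D6[1] * bvecs[, 1]^2 + D6[2] * bvecs[, 2]^2 +
                  D6[3] * bvecs[, 3]^2 +
                  2 * (D6[4] * bvecs[, 1] * bvecs[, 2] +
                         D6[5] * bvecs[, 1] * bvecs[, 3] +
                         D6[6] * bvecs[, 2] * bvecs[, 3]))
  S0 * exp(-q)
}

# wrap a voxel grid of explicit tensors into a dwi_volume
dwi_from_tensors <- function(D, bvals, bvecs, S0 = 1000, voxel_size_mm = 1.5) {
  dims <- dim(D)[1:3]
  n <- prod(dims)
  Dm <- matrix(D, n, 6L)
  sig <- vapply(seq_len(n), function(i) single_voxel_dwi(Dm[i, ], bvals, bvecs, S0),
                numeric(length(bvals)))
  structure(list(signal = array(t(sig), c(dims, length(bvals))),
                 bvals = bvals, bvecs = bvecs, voxel_size_mm = voxel_size_mm,
                 axis_convention = c(x = "right-left", y = "anterior-posterior",
                                     z = "inferior-superior")),
            class = "dwi_volume")
}

test_gradient_table <- function(n_dirs = 24L, bshells = c(1500, 3000), n_b0 = 1L) {
  dirs <- fibonacci_directions(n_dirs)
  list(bvals = c(rep(0, n_b0), rep(bshells, each = n_dirs)),
       bvecs = rbind(matrix(0, n_b0, 3), do.call(rbind, rep(list(dirs), length(bshells)))))
}

# random symmetric positive-definite tensor with eigenvalues in a WM-like range
random_spd_tensor <- function() {
  lam <- sort(runif(3, 0.2e-3, 2.5e-3), decreasing = TRUE)
  a <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(a))
  M <- q %*% diag(lam) %*% t(q)
  c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# deterministic text rendering of a cohort report, for reproducibility checks
report_snapshot <- function(r) capture.output(print(r))
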