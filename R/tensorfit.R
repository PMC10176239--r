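## tensor component order used throughout: xx, yy, zz, xy, xz, yz
TENSOR_COMP <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")

tensor_from_components <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

#' Construct a tensor field from per-voxel tensor components
#'
#' Computes the eigensystem, fractional anisotropy (FA), mean diffusivity
#' (MD) and the scanner-frame diagonal diffusivities Dxx/Dyy/Dzz at every
#' masked voxel. Negative eigenvalues are clamped to `clamp_floor`
#' (in mm^2/s) and the number of clamped voxels recorded.
#'
#' @param D 4D numeric array `[x, y, z, 6]` with components ordered
#'   xx, yy, zz, xy, xz, yz (mm^2/s).
#' @param mask 3D logical array of voxels to process.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param clamp_floor eigenvalue floor in mm^2/s.
#' @return A `tensor_field`: list with `D`, `evals` (`[x,y,z,3]`,
#'   descending), `v1` (`[x,y,z,3]`, unit principal eigenvector), `fa`,
#'   `md`, `Dxx`, `Dyy`, `Dzz`, `mask`, `voxel_size_mm`, `n_clamped`.
#' @export
tensor_field <- function(D, mask, voxel_size_mm, clamp_floor = 1e-6) {
  d4 <- dim(D)
  if (length(d4) != 4L || d4[4] != 6L)
    fail("D must be a 4D array with 6 tensor components on the last axis")
  dims <- d4[1:3]
  if (!identical(dim(mask), dims)) fail("mask grid does not match tensor grid")
  evals <- array(NA_real_, c(dims, 3L))
  v1 <- array(NA_real_, c(dims, 3L))
  fa <- array(NA_real_, dims)
  md <- array(NA_real_, dims)
  idx <- which(mask)
  nvox <- prod(dims)
  Dm <- matrix(D, nvox, 6L)
  n_clamped <- 0L
  ev_store <- matrix(NA_real_, length(idx), 3L)
  v1_store <- matrix(NA_real_, length(idx), 3L)
  for (k in seq_along(idx)) {
    e <- eigen(tensor_from_components(Dm[idx[k], ]), symmetric = TRUE)
    lam <- e$values
    if (any(lam < clamp_floor)) {
      lam <- pmax(lam, clamp_floor)
      n_clamped <- n_clamped + 1L
    }
    ev_store[k, ] <- lam
    v <- e$vectors[, 1L]
    ## sign convention: first nonzero component positive
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) v <- -v
    v1_store[k, ] <- v
  }
  for (j in 1:3) {
    sl <- array(NA_real_, dims); sl[idx] <- ev_store[, j]
    evals[, , , j] <- sl
    sl[idx] <- v1_store[, j]
    v1[, , , j] <- sl
  }
  mdv <- rowMeans(ev_store)
  dev <- ev_store - mdv
  num <- sqrt(rowSums(dev^2))
  den <- sqrt(rowSums(ev_store^2))
  fav <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa[idx] <- fav
  md[idx] <- mdv
  comp <- function(j) {
    sl <- array(NA_real_, dims); sl[idx] <- Dm[idx, j]; sl
  }
  structure(list(
    D = D, evals = evals, v1 = v1, fa = fa, md = md,
    Dxx = comp(1L), Dyy = comp(2L), Dzz = comp(3L),
    mask = mask, voxel_size_mm = voxel_size_mm,
    n_clamped = n_clamped
  ), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("Diffusion tensor field:", paste(dim(x$mask), collapse = " x "),
      "voxels,", sum(x$mask), "fitted\n")
  cat(sprintf("  FA range %.3f-%.3f, MD median %.2e mm^2/s, %d clamped voxels\n",
              min(x$fa[x$mask]), max(x$fa[x$mask]),
              stats::median(x$md[x$mask]), x$n_clamped))
  invisible(x)
}

## design matrix of the log-linear tensor model:
## ln S = ln S0 - b g' D g  =>  row [1, -b gx^2, -b gy^2, -b gz^2,
##                                  -2b gx gy, -2b gx gz, -2b gy gz]
tensor_design <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

check_design_rank <- function(X) {
  sv <- svd(X)
  r <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (r < 7L) {
    null_load <- abs(sv$v[, (r + 1):7, drop = FALSE])
    bad <- c("S0", TENSOR_COMP)[rowSums(null_load) > 1e-8]
    fail(paste0("rank-deficient gradient scheme (rank %d < 7): components ",
                "not identifiable: %s; add non-collinear directions"),
         r, paste(bad, collapse = ", "))
  }
  invisible(r)
}

#' Fit diffusion tensors by weighted log-linear least squares
#'
#' Per masked voxel, solves `ln S = ln S0 - b g' D g` by ordinary least
#' squares on the log signal followed by one reweighted pass with weights
#' equal to the squared predicted signal (the standard WLS estimator for
#' log-transformed Rician-corrupted magnitude data). S0 is estimated as the
#' intercept of the same fit. Non-positive measurements are excluded
#' per voxel; a voxel left with fewer than 7 usable volumes is flagged
#' unfitted rather than zeroed.
#'
#' @param dwi a `dwi_volume` (see [generate_phantom()] or [read_dwi()]).
#' @param mask 3D logical array; default all voxels.
#' @param shells optional numeric vector of b-values to keep (b = 0 always
#'   kept), e.g. `1500` to restrict a two-shell acquisition to its lower
#'   shell.
#' @param clamp_floor eigenvalue floor in mm^2/s.
#' @return A [tensor_field()] whose `mask` marks successfully fitted voxels;
#'   attribute `n_unfitted` counts voxels dropped for insufficient usable
#'   measurements.
#' @export
fit_tensor <- function(dwi, mask = NULL, shells = NULL, clamp_floor = 1e-6) {
  stopifnot(inherits(dwi, "dwi_volume"))
  dims <- dim(dwi$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), dims)) fail("mask grid does not match DWI grid")
  keep <- rep(TRUE, length(dwi$bvals))
  if (!is.null(shells)) keep <- dwi$bvals == 0 | dwi$bvals %in% shells
  bvals <- dwi$bvals[keep]
  bvecs <- dwi$bvecs[keep, , drop = FALSE]
  if (length(bvals) < 7L)
    fail("need at least 7 volumes (6 directions + baseline), got %d", length(bvals))
  X <- tensor_design(bvals, bvecs)
  check_design_rank(X)
  idx <- which(mask)
  S <- matrix(aperm(dwi$signal[, , , keep, drop = FALSE], c(4, 1, 2, 3)),
              nrow = length(bvals))[, idx, drop = FALSE]
  nvol <- length(bvals)
  beta <- matrix(NA_real_, 7L, length(idx))
  ok_all <- colSums(S > 0) == nvol
  XtXi <- NULL
  if (any(ok_all)) {
    ## fast path: every measurement usable -> shared OLS projector
    L <- log(S[, ok_all, drop = FALSE])
    beta[, ok_all] <- solve(crossprod(X), crossprod(X, L))
  }
  fitted_mask <- rep(TRUE, length(idx))
  n_unfit <- 0L
  for (k in which(!ok_all)) {
    use <- S[, k] > 0
    if (sum(use) < 7L) { fitted_mask[k] <- FALSE; n_unfit <- n_unfit + 1L; next }
    Xk <- X[use, , drop = FALSE]
    if (qr(Xk)$rank < 7L) { fitted_mask[k] <- FALSE; n_unfit <- n_unfit + 1L; next }
    beta[, k] <- solve(crossprod(Xk), crossprod(Xk, log(S[use, k])))
  }
  if (!any(fitted_mask))
    fail("no voxel has enough positive measurements for a tensor fit")
  ## one reweighting pass, weights = squared predicted signal
  for (k in which(fitted_mask)) {
    use <- S[, k] > 0
    Xk <- X[use, , drop = FALSE]
    w <- exp(2 * drop(Xk %*% beta[, k]))
    beta[, k] <- solve(crossprod(Xk, w * Xk), crossprod(Xk, w * log(S[use, k])))
  }
  if (n_unfit > 0L)
    warning(sprintf("%d voxel(s) had too few positive measurements and were left unfitted",
                    n_unfit), call. = FALSE)
  fmask <- array(FALSE, dims)
  fmask[idx[fitted_mask]] <- TRUE
  D <- array(0, c(dims, 6L))
  for (j in 1:6) {
    sl <- array(0, dims)
    sl[idx[fitted_mask]] <- beta[j + 1L, fitted_mask]
    D[, , , j] <- sl
  }
  tf <- tensor_field(D, fmask, dwi$voxel_size_mm, clamp_floor = clamp_floor)
  attr(tf, "n_unfitted") <- n_unfit
  tf
}

#' Direction-encoded colour (DEC) map
#'
#' The conventional RGB encoding of fibre orientation: per voxel
#' `(|v1x|, |v1y|, |v1z|) * FA`, so red marks right-left, green
#' anterior-posterior and blue inferior-superior fibres. Used for ROI
#' placement and QC figures.
#'
#' @param tf a [tensor_field()].
#' @return 4D array `[x, y, z, 3]`; unfitted voxels are 0.
#' @export
direction_encoded_map <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$mask)
  out <- array(0, c(dims, 3L))
  for (j in 1:3) {
    sl <- abs(tf$v1[, , , j]) * tf$fa
    sl[!tf$mask] <- 0
    sl[is.na(sl)] <- 0
    out[, , , j] <- sl
  }
  out
}
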