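#' Write a volume as NIfTI-1
#'
#' @param vol 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(vol * 1)
  pd <- rep(1, length(dim(vol)))
  pd[1:min(3L, length(pd))] <- voxel_size_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return List: `data` (array), `voxel_size_mm` (first pixdim).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), voxel_size_mm = RNifti::pixdim(img)[1])
}

#' Write FSL-dialect bval/bvec text files
#'
#' One whitespace-separated row of b-values; three rows of gradient vector
#' components (x, y, z), one column per volume.
#'
#' @param bvals numeric vector.
#' @param bvecs n x 3 matrix.
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, `c(bval_path, bvec_path)`.
#' @export
write_bvalbvec <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read FSL-dialect bval/bvec text files
#'
#' @param bval_path,bvec_path input paths.
#' @return List: `bvals` (vector), `bvecs` (n x 3 matrix, rows renormalised
#'   to unit length for b > 0 volumes).
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  if (length(rows) != 3L) fail("bvec file must have exactly 3 rows")
  bvecs <- t(do.call(rbind, rows))
  if (nrow(bvecs) != length(bvals))
    fail("bval (%d) and bvec (%d) volume counts differ", length(bvals), nrow(bvecs))
  nrm <- sqrt(rowSums(bvecs^2))
  fix <- bvals > 0 & nrm > 0
  bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  list(bvals = bvals, bvecs = bvecs)
}

#' Assemble a DWI volume from NIfTI + bval/bvec files
#'
#' @param nifti_path 4D NIfTI file.
#' @param bval_path,bvec_path FSL-dialect gradient table.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  for (p in c(nifti_path, bval_path, bvec_path))
    if (!file.exists(p)) fail("input file not found: %s", p)
  vol <- read_nifti_volume(nifti_path)
  gt <- read_bvalbvec(bval_path, bvec_path)
  if (length(dim(vol$data)) != 4L) fail("DWI NIfTI must be 4D")
  if (dim(vol$data)[4] != length(gt$bvals))
    fail("volume count (%d) does not match gradient table (%d)",
         dim(vol$data)[4], length(gt$bvals))
  if (any(vol$data < 0)) fail("DWI signal must be non-negative")
  structure(list(signal = vol$data, bvals = gt$bvals, bvecs = gt$bvecs,
                 voxel_size_mm = vol$voxel_size_mm,
                 axis_convention = c(x = "right-left",
                                     y = "anterior-posterior",
                                     z = "inferior-superior")),
            class = "dwi_volume")
}

#' Write a DWI volume as NIfTI plus bval/bvec
#'
#' @param dwi a `dwi_volume`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return Invisibly, the three paths.
#' @export
write_dwi <- function(dwi, prefix) {
  nii <- paste0(prefix, ".nii.gz")
  write_nifti_volume(dwi$signal, nii, dwi$voxel_size_mm)
  write_bvalbvec(dwi$bvals, dwi$bvecs, paste0(prefix, ".bval"),
                 paste0(prefix, ".bvec"))
  invisible(c(nii, paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}
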