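#' Enhance perivascular-space contrast from a T1w/T2w pair
#'
#' Perivascular spaces carry CSF: bright on T2w, dark on T1w. Dividing an
#' edge-preserving-denoised T2w by the matching T1w therefore multiplies the
#' two contrasts, boosting PVS against white matter. The denominator is
#' guarded against near-zero values.
#'
#' Denoising uses a selective median filter that replaces a voxel by its
#' neighbourhood median only when the deviation is within 3 robust noise
#' SDs: noise is suppressed while 1-voxel-thin tubules keep their full
#' contrast, and noise-free volumes pass through unchanged.
#'
#' @param structural a `structural_pair` (fields `t1w`, `t2w` on one grid).
#' @param smooth apply the selective median denoiser before the division.
#'   Disable for analytic checks.
#' @return 3D array of enhanced PVS contrast.
#' @export
enhance_pvs <- function(structural, smooth = TRUE) {
  t1 <- structural$t1w; t2 <- structural$t2w
  if (!identical(dim(t1), dim(t2))) fail("T1w and T2w grids differ")
  if (all(t1 == 0)) fail("T1w volume is all zero")
  if (smooth) {
    t1 <- selective_median(t1)
    t2 <- selective_median(t2)
  }
  pos <- t1[t1 > 0]
  eps <- 0.05 * stats::median(pos)
  t2 / pmax(t1, eps)
}

## eigenvalues of many symmetric 3x3 matrices, rows = (xx,yy,zz,xy,xz,yz),
## via the closed-form trigonometric solution (ascending order)
sym3_eigenvalues <- function(H) {
  a <- H[, 1]; b <- H[, 2]; c <- H[, 3]
  d <- H[, 4]; e <- H[, 5]; f <- H[, 6]
  q <- (a + b + c) / 3
  p1 <- d^2 + e^2 + f^2
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- l3 <- q
  nz <- p > 1e-30
  if (any(nz)) {
    aa <- (a[nz] - q[nz]) / p[nz]; bb <- (b[nz] - q[nz]) / p[nz]
    cc <- (c[nz] - q[nz]) / p[nz]
    dd <- d[nz] / p[nz]; ee <- e[nz] / p[nz]; ff <- f[nz] / p[nz]
    detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
      ee * (dd * ff - bb * ee)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)  # smallest
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi)               # largest
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

## scale-normalised Hessian components of a Gaussian-smoothed volume
hessian_components <- function(vol, sigma) {
  g <- gauss_smooth(vol, sigma)
  d2 <- function(ax) {
    o1 <- integer(3); o1[ax] <- 1L
    shift_array(g, o1) - 2 * g + shift_array(g, -o1)
  }
  dcross <- function(a1, a2) {
    op <- integer(3); op[a1] <- 1L
    oq <- integer(3); oq[a2] <- 1L
    (shift_array(g, op + oq) - shift_array(g, op - oq) -
       shift_array(g, oq - op) + shift_array(g, -op - oq)) / 4
  }
  s2 <- sigma^2
  cbind(as.vector(d2(1L)), as.vector(d2(2L)), as.vector(d2(3L)),
        as.vector(dcross(1L, 2L)), as.vector(dcross(1L, 3L)),
        as.vector(dcross(2L, 3L))) * s2
}

#' Multiscale Hessian tubularity (vesselness) filter
#'
#' Frangi-style vesselness for bright tubular structures: per voxel and
#' scale, Hessian eigenvalues sorted by magnitude `|l1| <= |l2| <= |l3|`
#' give the plate/blob/structure ratios
#' `Ra = |l2|/|l3|`, `Rb = |l1|/sqrt(|l2 l3|)`, `S = sqrt(l1^2+l2^2+l3^2)`;
#' the response `(1 - exp(-Ra^2/2a^2)) * exp(-Rb^2/2b^2) *
#' (1 - exp(-S^2/2c^2))` (zero unless `l2, l3 < 0`) is maximised over
#' scales.
#'
#' @param vol 3D numeric array.
#' @param scales Gaussian scales in voxels (tubule radius range).
#' @param alpha,beta Frangi plate/blob sensitivity parameters.
#' @param c_frac structure-sensitivity parameter as a fraction of the
#'   maximum Hessian norm at each scale.
#' @return 3D array in `[0, 1]`.
#' @export
vesselness <- function(vol, scales = c(1, 1.6), alpha = 0.5, beta = 0.5,
                       c_frac = 0.5) {
  d <- dim(vol)
  out <- array(0, d)
  for (s in scales) {
    H <- hessian_components(vol, s)
    ev <- sym3_eigenvalues(H)
    ## sort by absolute value per row
    o <- t(apply(abs(ev), 1L, order))
    n <- nrow(ev)
    l1 <- ev[cbind(seq_len(n), o[, 1])]
    l2 <- ev[cbind(seq_len(n), o[, 2])]
    l3 <- ev[cbind(seq_len(n), o[, 3])]
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cc <- c_frac * max(S)
    if (cc <= 0) next
    Ra <- abs(l2) / pmax(abs(l3), 1e-30)
    Rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-30)
    v <- (1 - exp(-Ra^2 / (2 * alpha^2))) * exp(-Rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * cc^2)))
    v[l2 >= 0 | l3 >= 0] <- 0  # bright tubes only
    out <- pmax(out, array(v, d))
  }
  out
}

#' Segment perivascular spaces from an enhanced-contrast volume
#'
#' Thresholds the multiscale vesselness of the enhanced volume inside the
#' white-matter mask, removes 26-connected components smaller than
#' `min_size` voxels, and reports volume both in mL and as a percentage of
#' intracranial volume. The outermost 1-voxel rim of the white-matter mask
#' is excluded from candidates: partial-volume CSF edges (ventricle walls,
#' cortical boundary) produce spurious tubular responses there.
#'
#' @param enhanced 3D array from [enhance_pvs()].
#' @param wm_mask 3D logical white-matter mask.
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param threshold vesselness threshold.
#' @param min_size minimum component size in voxels.
#' @param scales vesselness scales in voxels.
#' @param icv_mask intracranial-volume mask for the percentage; defaults to
#'   the whole grid.
#' @return List: `pvs_mask`, `pvs_volume_ml`, `pvs_volume_pct`,
#'   `n_components`.
#' @export
segment_pvs <- function(enhanced, wm_mask, voxel_size_mm,
                        threshold = 0.08, min_size = 5L,
                        scales = c(1, 1.6), icv_mask = NULL) {
  if (!identical(dim(enhanced), dim(wm_mask)))
    fail("enhanced volume and wm_mask grids differ")
  if (!any(wm_mask)) fail("white-matter mask is empty")
  v <- vesselness(enhanced, scales = scales)
  core <- erode1(wm_mask, 6L)
  if (!any(core)) core <- wm_mask
  cand <- (v >= threshold) & core
  lab <- label_components(cand, connectivity = 26L)
  keep <- which(tabulate(lab[lab > 0L]) >= min_size)
  mask <- array(lab %in% keep, dim(lab))
  nvox <- sum(mask)
  icv <- if (is.null(icv_mask)) length(mask) else sum(icv_mask)
  list(pvs_mask = mask,
       pvs_volume_ml = nvox * voxel_size_mm^3 / 1000,
       pvs_volume_pct = 100 * nvox / icv,
       n_components = length(keep))
}

#' Count PVS cross-sections on one axial slice
#'
#' The conventional manual count: number of in-plane (8-connected) connected
#' components of the PVS mask restricted to a single axial slice in the
#' centrum semiovale, one slice above the superior extent of the lateral
#' ventricle.
#'
#' @param pvs_mask 3D logical mask.
#' @param slice_index axial slice (1-based).
#' @return Integer count.
#' @export
count_pvs_slice <- function(pvs_mask, slice_index) {
  d <- dim(pvs_mask)
  if (length(d) != 3L) fail("pvs_mask must be 3D")
  if (slice_index < 1L || slice_index > d[3])
    fail("slice_index %d out of range 1..%d", slice_index, d[3])
  sl <- pvs_mask[, , slice_index]
  dim(sl) <- d[1:2]
  max(label_components(sl, connectivity = 8L))
}

#' Ordinal 0-4 PVS severity score from a slice count
#'
#' Standard visual-rating bins: 0 for no PVS, 1 for 1-10, 2 for 11-20,
#' 3 for 21-40, 4 for more than 40.
#'
#' @param count non-negative integer PVS count.
#' @param bins upper edges of score categories 1..3.
#' @return Integer score in 0..4, non-decreasing in `count`.
#' @export
severity_score <- function(count, bins = c(10, 20, 40)) {
  if (length(count) != 1L || is.na(count) || count < 0 || count != round(count))
    fail("count must be a single non-negative integer")
  if (is.unsorted(bins, strictly = TRUE) || length(bins) != 3L)
    fail("bins must be 3 strictly increasing upper edges")
  if (count == 0) return(0)
  as.numeric(findInterval(count, c(bins + 1)) + 1)
}

#' Full PVS quantification for one subject
#'
#' Runs enhancement, segmentation, slice counting and severity scoring on a
#' structural pair.
#'
#' @param structural a `structural_pair`.
#' @param slice_index axial slice for the count; defaults to the pair's
#'   `count_slice` landmark (one slice above the ventricle proxy).
#' @param bins severity-score bin edges, see [severity_score()].
#' @param ... passed to [segment_pvs()].
#' @return A `pvs_result`: `pvs_mask`, `pvs_volume_ml`, `pvs_volume_pct`,
#'   `slice_count`, `severity_score`, `slice_index`.
#' @export
quantify_pvs <- function(structural, slice_index = NULL,
                         bins = c(10, 20, 40), ...) {
  if (is.null(slice_index)) slice_index <- structural$count_slice
  if (is.null(slice_index))
    fail("no count slice available; supply slice_index")
  enh <- enhance_pvs(structural)
  seg <- segment_pvs(enh, structural$wm_mask, structural$voxel_size_mm, ...)
  cnt <- count_pvs_slice(seg$pvs_mask, slice_index)
  structure(list(pvs_mask = seg$pvs_mask,
                 pvs_volume_ml = seg$pvs_volume_ml,
                 pvs_volume_pct = seg$pvs_volume_pct,
                 slice_count = cnt,
                 severity_score = severity_score(cnt, bins = bins),
                 slice_index = as.integer(slice_index)),
            class = "pvs_result")
}

#' @export
print.pvs_result <- function(x, ...) {
  cat(sprintf("PVS: %.3f mL (%.3f%% ICV), slice %d count %d, severity %d\n",
              x$pvs_volume_ml, x$pvs_volume_pct, x$slice_index,
              x$slice_count, x$severity_score))
  invisible(x)
}
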