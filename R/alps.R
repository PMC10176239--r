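## ROI edge in voxels: nearest odd count to roi_size_mm, so the square has a
## well-defined center voxel
roi_edge_vox <- function(roi_size_mm, voxel_size_mm) {
  n <- max(1L, round(roi_size_mm / voxel_size_mm))
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}

roi_square <- function(dims, center, slice, edge) {
  h <- (edge - 1L) %/% 2L
  xr <- (center[1] - h):(center[1] + h)
  yr <- (center[2] - h):(center[2] + h)
  if (min(xr) < 1L || max(xr) > dims[1] || min(yr) < 1L || max(yr) > dims[2] ||
      slice < 1L || slice > dims[3])
    fail("ROI at (%d, %d) slice %d extends outside the %s grid",
         center[1], center[2], slice, paste(dims, collapse = "x"))
  m <- array(FALSE, dims)
  m[xr, yr, slice] <- TRUE
  m
}

ROI_NAMES <- c("projection_left", "projection_right",
               "association_left", "association_right")

#' Place the four ALPS regions of interest
#'
#' Mimics the conventional manual placement on a direction-encoded colour FA
#' map at the level of the lateral ventricle: in each hemisphere, the
#' projection-area ROI centres on the voxel maximising `|v1z| * FA`
#' (inferior-superior fibres) and the association-area ROI on the voxel
#' maximising `|v1y| * FA` (anterior-posterior fibres), among voxels whose
#' dominant eigenvector component exceeds `dominance`. ROIs are in-plane
#' squares of `roi_size_mm` edge on one axial slice. Manual centres override
#' the search entirely.
#'
#' @param tf a [tensor_field()].
#' @param slice axial slice index; if `NULL`, taken as the slice with the
#'   most CSF-like voxels (FA < 0.2 and MD > 1.5e-3), i.e. the ventricle
#'   level.
#' @param centers optional named list
#'   (`projection_left/right`, `association_left/right`) of in-plane
#'   `(x, y)` centres for manual placement; requires `slice`.
#' @param roi_size_mm in-plane square edge, default 5 mm.
#' @param dominance minimum `|v1|` component for a candidate voxel.
#' @param midline_margin half-width (voxels) of the excluded midline band.
#' @return An `roi_set`: four logical masks, `slice`, `roi_size_mm`,
#'   `placement_mode`, `centers`.
#' @export
place_rois <- function(tf, slice = NULL, centers = NULL, roi_size_mm = 5,
                       dominance = 0.7, midline_margin = 1L) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$mask)
  edge <- roi_edge_vox(roi_size_mm, tf$voxel_size_mm)
  if (!is.null(centers)) {
    if (is.null(slice)) fail("manual placement requires an explicit slice")
    if (!all(ROI_NAMES %in% names(centers)))
      fail("centers must name all of: %s", paste(ROI_NAMES, collapse = ", "))
    rois <- lapply(ROI_NAMES, function(nm)
      roi_square(dims, as.integer(centers[[nm]]), as.integer(slice), edge))
    names(rois) <- ROI_NAMES
    mode <- "manual"
  } else {
    if (is.null(slice)) {
      ## ventricle landmark: fitted MD outside the plausible parenchyma band.
      ## True CSF sits above it; at finite SNR the high-b CSF signal hits the
      ## Rician noise floor and the fitted MD collapses toward zero instead,
      ## so both tails mark non-tissue.
      csf <- tf$mask & !is.na(tf$md) & (tf$md > 1.5e-3 | tf$md < 0.3e-3)
      counts <- apply(csf, 3L, sum)
      if (max(counts) == 0L)
        fail("no CSF-like ventricle landmark found; supply slice explicitly")
      slice <- which.max(counts)
    }
    slice <- as.integer(slice)
    if (slice < 1L || slice > dims[3]) fail("slice %d out of range", slice)
    mid <- (dims[1] + 1) / 2
    hemi <- list(left = which(seq_len(dims[1]) < mid - midline_margin),
                 right = which(seq_len(dims[1]) > mid + midline_margin))
    h <- (edge - 1L) %/% 2L
    box_mean <- function(m) {
      out <- array(0, dim(m))
      for (dx in -h:h) for (dy in -h:h)
        out <- out + shift_array(m, c(dx, dy))
      out / edge^2
    }
    mask2d <- tf$mask[, , slice]
    dim(mask2d) <- dims[1:2]
    roi_fits <- box_mean(mask2d * 1) >= 1 - 1e-12   # whole ROI inside mask
    roi_fits[c(seq_len(h), dims[1] + 1L - seq_len(h)), ] <- FALSE
    roi_fits[, c(seq_len(h), dims[2] + 1L - seq_len(h))] <- FALSE
    pick <- function(xs, axis) {
      comp <- abs(tf$v1[, , slice, axis, drop = TRUE])
      sc <- comp * tf$fa[, , slice]
      cand <- mask2d & !is.na(sc) & comp > dominance
      sc[!cand] <- 0
      ## place the ROI where its *mean* dominance score is highest: the
      ## box-filtered score is what a rater optimises when centring a square
      ## ROI on a homogeneous tract, and it is robust to single-voxel noise
      boxed <- box_mean(sc)
      ok <- cand & roi_fits
      ok[setdiff(seq_len(dims[1]), xs), ] <- FALSE
      if (!any(ok))
        fail(paste0("no voxel with |v1 %s-component| > %.2f on slice %d; ",
                    "place ROIs manually via 'centers'"),
             c("x", "y", "z")[axis], dominance, slice)
      best <- max(boxed[ok])
      top <- which(ok & boxed >= best - 1e-12, arr.ind = TRUE)
      ctr <- colMeans(top)
      d2 <- (top[, 1] - ctr[1])^2 + (top[, 2] - ctr[2])^2
      as.integer(top[which.min(d2), ])
    }
    cen <- list(
      projection_left = pick(hemi$left, 3L),
      projection_right = pick(hemi$right, 3L),
      association_left = pick(hemi$left, 2L),
      association_right = pick(hemi$right, 2L)
    )
    rois <- lapply(cen, roi_square, dims = dims, slice = slice, edge = edge)
    centers <- cen
    mode <- "auto"
  }
  ## contract checks: non-empty, disjoint, within fitted mask, bilateral
  tot <- Reduce(`+`, lapply(rois, function(m) m * 1L))
  if (any(tot > 1L)) fail("ROIs overlap; enlarge the grid or move centers")
  for (nm in ROI_NAMES)
    if (!all(tf$mask[rois[[nm]]]))
      fail("ROI %s extends outside the fitted mask", nm)
  mid <- (dims[1] + 1) / 2
  xs <- vapply(centers, function(c) c[1], numeric(1))
  if (!(xs[["projection_left"]] < mid && xs[["association_left"]] < mid &&
        xs[["projection_right"]] > mid && xs[["association_right"]] > mid))
    fail("left/right ROIs must lie on opposite sides of the midline")
  structure(list(rois = rois, slice = as.integer(slice),
                 roi_size_mm = roi_size_mm, placement_mode = mode,
                 centers = centers),
            class = "roi_set")
}

#' Compute the ALPS index
#'
#' The diffusion-along-the-perivascular-space index: with Dxx the
#' right-left diffusivity (parallel to the periventricular medullary-vein
#' perivascular spaces) and the projection/association areas dominated by
#' z- and y-oriented fibres respectively,
#' \deqn{ALPS = \frac{mean(Dxx_{proj}, Dxx_{assoc})}{mean(Dyy_{proj}, Dzz_{assoc})}}
#' computed per hemisphere from ROI-mean diffusivities and then averaged
#' across hemispheres. An index near 1.0 indicates minimal perivascular
#' diffusion; higher values indicate greater diffusivity along the
#' perivascular space.
#'
#' @param tf a [tensor_field()].
#' @param rois an `roi_set` from [place_rois()].
#' @return An `alps_result`: per-hemisphere ROI-mean diffusivities
#'   (`dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc`), `alps_left`,
#'   `alps_right`, `alps_mean`, and ROI-mean FA/MD per area for QC.
#' @export
compute_alps <- function(tf, rois) {
  stopifnot(inherits(tf, "tensor_field"), inherits(rois, "roi_set"))
  roi_mean <- function(vol, nm) {
    m <- rois$rois[[nm]]
    if (!any(m)) fail("ROI %s is empty", nm)
    v <- vol[m]
    if (anyNA(v)) fail("ROI %s contains unfitted voxels", nm)
    mean(v)
  }
  side <- function(sfx) {
    dxx_p <- roi_mean(tf$Dxx, paste0("projection_", sfx))
    dxx_a <- roi_mean(tf$Dxx, paste0("association_", sfx))
    dyy_p <- roi_mean(tf$Dyy, paste0("projection_", sfx))
    dzz_a <- roi_mean(tf$Dzz, paste0("association_", sfx))
    if (min(dxx_p, dxx_a, dyy_p, dzz_a) <= 0)
      fail("non-positive ROI-mean diffusivity on %s side", sfx)
    list(dxx_proj = dxx_p, dxx_assoc = dxx_a, dyy_proj = dyy_p,
         dzz_assoc = dzz_a,
         alps = mean(c(dxx_p, dxx_a)) / mean(c(dyy_p, dzz_a)),
         fa_proj = roi_mean(tf$fa, paste0("projection_", sfx)),
         fa_assoc = roi_mean(tf$fa, paste0("association_", sfx)),
         md_proj = roi_mean(tf$md, paste0("projection_", sfx)),
         md_assoc = roi_mean(tf$md, paste0("association_", sfx)))
  }
  L <- side("left"); R <- side("right")
  structure(list(
    left = L, right = R,
    alps_left = L$alps, alps_right = R$alps,
    alps_mean = (L$alps + R$alps) / 2,
    fa_proj = (L$fa_proj + R$fa_proj) / 2,
    fa_assoc = (L$fa_assoc + R$fa_assoc) / 2,
    md_proj = (L$md_proj + R$md_proj) / 2,
    md_assoc = (L$md_assoc + R$md_assoc) / 2,
    slice = rois$slice, placement_mode = rois$placement_mode
  ), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("ALPS index: %.4f (left %.4f, right %.4f), %s placement, slice %d\n",
              x$alps_mean, x$alps_left, x$alps_right, x$placement_mode, x$slice))
  cat(sprintf("  ROI-mean FA proj/assoc: %.3f/%.3f, MD proj/assoc: %.2e/%.2e\n",
              x$fa_proj, x$fa_assoc, x$md_proj, x$md_assoc))
  invisible(x)
}

#' @export
as.data.frame.alps_result <- function(x, ...) {
  data.frame(alps_mean = x$alps_mean, alps_left = x$alps_left,
             alps_right = x$alps_right,
             dxx_proj = (x$left$dxx_proj + x$right$dxx_proj) / 2,
             dxx_assoc = (x$left$dxx_assoc + x$right$dxx_assoc) / 2,
             dyy_proj = (x$left$dyy_proj + x$right$dyy_proj) / 2,
             dzz_assoc = (x$left$dzz_assoc + x$right$dzz_assoc) / 2,
             fa_proj = x$fa_proj, fa_assoc = x$fa_assoc,
             md_proj = x$md_proj, md_assoc = x$md_assoc)
}
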