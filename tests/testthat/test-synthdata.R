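test_that("noise-free signals follow the tensor closed form at every voxel", {
  sp <- small_spec(d_perivascular = 0.3e-3)
  ph <- generate_phantom(sp)
  ## independent closed form: S = S0 exp(-b g' D g) from the truth tensors
  dims <- sp$grid_shape
  Dm <- matrix(ph$truth$D, prod(dims), 6L)
  idx <- round(seq(1, prod(dims), length.out = 50))
  Smat <- matrix(aperm(ph$dwi$signal, c(4, 1, 2, 3)), nrow = length(ph$dwi$bvals))
  for (i in idx) {
    expected <- single_voxel_dwi(Dm[i, ], ph$dwi$bvals, ph$dwi$bvecs, sp$S0)
    expect_equal(Smat[, i], expected, tolerance = 1e-12)
  }
})

test_that("isotropic spec with no perivascular term gives the isotropic closed form", {
  d <- 0.7e-3
  sp <- iso_spec(d)
  ph <- generate_phantom(sp)
  b <- ph$dwi$bvals
  for (j in which(b > 0)[c(1, 10, 30)]) {
    expect_equal(ph$dwi$signal[, , , j],
                 array(sp$S0 * exp(-b[j] * d), sp$grid_shape),
                 tolerance = 1e-12)
  }
  ## every truth tensor isotropic
  expect_true(all(abs(ph$truth$fa) < 1e-12))
})

test_that("on-axis signal matches S0 exp(-b lambda_parallel) in projection fibres", {
  ## z-gradient through a z-fibre sees the parallel eigenvalue
  sp <- small_spec(d_perivascular = 0)
  gt <- list(bvals = c(0, 1500), bvecs = rbind(c(0, 0, 0), c(0, 0, 1)))
  layout <- dtialps:::phantom_layout(sp)
  D <- dtialps:::phantom_truth_components(sp, layout)
  vox <- which(layout$projection_left, arr.ind = TRUE)[1, ]
  S <- single_voxel_dwi(D[vox[1], vox[2], vox[3], ], gt$bvals, gt$bvecs, sp$S0)
  expect_equal(S[2], sp$S0 * exp(-1500 * sp$lambda_parallel), tolerance = 1e-12)
})

test_that("perivascular diffusivity is added to Dxx in both fibre areas only", {
  sp <- small_spec(d_perivascular = 0.3e-3)
  ph <- generate_phantom(sp)
  lay <- ph$layout
  expect_equal(unique(ph$truth$Dxx[lay$projection_left]),
               sp$lambda_perp + 0.3e-3)
  expect_equal(unique(ph$truth$Dxx[lay$association_right]),
               sp$lambda_perp + 0.3e-3)
  expect_equal(unique(ph$truth$Dyy[lay$projection_left]), sp$lambda_perp)
  expect_equal(unique(ph$truth$Dzz[lay$projection_left]), sp$lambda_parallel)
  bg <- !(lay$projection_left | lay$projection_right |
            lay$association_left | lay$association_right | lay$ventricle)
  expect_equal(unique(ph$truth$Dxx[bg]), sp$background_diffusivity)
})

test_that("Rician noise converges to the noise-free signal and is positively biased", {
  base <- small_spec(noise_sigma = 0)
  clean <- generate_phantom(base)$dwi$signal
  ## convergence as sigma -> 0: relative error shrinks proportionally
  err <- vapply(c(0.02, 0.002), function(sig) {
    noisy <- generate_phantom(small_spec(noise_sigma = sig, seed = 11))$dwi$signal
    mean(abs(noisy - clean)) / mean(clean)
  }, numeric(1))
  expect_lt(err[2], err[1] / 5)
  expect_lt(err[2], 0.01)
  ## Rician bias: at high sigma the mean over repeats exceeds the clean value
  ## where the clean signal is weak (high-b CSF voxels)
  lay <- dtialps:::phantom_layout(base)
  vent <- which(lay$ventricle)[1]
  hi_b <- which(generate_phantom(base)$dwi$bvals == 3000)[1]
  reps <- vapply(1:40, function(s) {
    arr <- generate_phantom(small_spec(noise_sigma = 0.2, seed = s))$dwi$signal
    arr[vent + (hi_b - 1) * prod(base$grid_shape)]
  }, numeric(1))
  expect_gt(mean(reps), clean[vent + (hi_b - 1) * prod(base$grid_shape)])
})

test_that("phantom generation is a pure function of spec and seed", {
  a <- generate_phantom(small_spec(noise_sigma = 0.05, seed = 42))
  b <- generate_phantom(small_spec(noise_sigma = 0.05, seed = 42))
  expect_identical(a$dwi$signal, b$dwi$signal)
  c <- generate_phantom(small_spec(noise_sigma = 0.05, seed = 43))
  expect_false(identical(a$dwi$signal, c$dwi$signal))
})

test_that("phantom spec validation rejects impossible parameters", {
  expect_error(phantom_spec(grid_shape = c(4, 4, 3)), "too small")
  expect_error(phantom_spec(lambda_perp = 0), "lambda")
  expect_error(phantom_spec(d_perivascular = -1e-4), "d_perivascular")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
  expect_error(phantom_spec(n_b0 = 0), "baseline")
})

test_that("structural phantom places the requested number of separated tubules", {
  sp <- small_spec()
  st0 <- generate_structural(sp, n_tubules = 0)
  expect_false(any(st0$pvs_truth_mask))
  st <- generate_structural(sp, n_tubules = 12, seed = 7)
  lab <- label_components(st$pvs_truth_mask, connectivity = 26L)
  expect_identical(max(lab), 12L)
  ## truth mask inside white matter; CSF-like contrast
  expect_true(all(st$wm_mask[st$pvs_truth_mask]))
  expect_lt(mean(st$t1w[st$pvs_truth_mask]), mean(st$t1w[st$wm_mask & !st$pvs_truth_mask]))
  expect_gt(mean(st$t2w[st$pvs_truth_mask]), mean(st$t2w[st$wm_mask & !st$pvs_truth_mask]))
  ## determinism
  st2 <- generate_structural(sp, n_tubules = 12, seed = 7)
  expect_identical(st$t1w, st2$t1w)
  expect_identical(st$pvs_truth_mask, st2$pvs_truth_mask)
})

test_that("structural generation errors when tubules cannot be placed", {
  sp <- phantom_spec(grid_shape = c(12, 12, 8), n_dirs_per_shell = 6)
  expect_error(generate_structural(sp, n_tubules = 500, seed = 1),
               "bounded retries")
  expect_error(generate_structural(sp, n_tubules = -1), "non-negative")
})

test_that("cohort NfL follows the generative linear model exactly at zero noise", {
  spc <- cohort_spec(n_tbi = 10, n_control = 5,
                     nfl_model = list(intercept = 50, b_alps = -100,
                                      b_age = 0, sd = 0),
                     seed = 2)
  co <- generate_cohort(spc)
  tab <- co$table
  ## two subjects differing by +0.1 in the ALPS parameter differ by -10 in NfL
  fit <- tab$nfl - (50 - 100 * tab$alps_param)
  expect_equal(max(abs(fit)), 0, tolerance = 1e-12)
  d_alps <- tab$alps_param[2] - tab$alps_param[1]
  expect_equal(tab$nfl[2] - tab$nfl[1], -100 * d_alps, tolerance = 1e-12)
})

test_that("equal group means with zero age slope give zero expected group difference", {
  spc <- cohort_spec(n_tbi = 400, n_control = 400,
                     group_alps_means = c(tbi = 1.35, control = 1.35),
                     age_slope_alps = 0, seed = 9)
  tab <- generate_cohort(spc)$table
  d <- mean(tab$alps_param[tab$group == "tbi"]) -
    mean(tab$alps_param[tab$group == "control"])
  expect_lt(abs(d), 3 * 0.14 * sqrt(2 / 400))
})

test_that("cohort matches configured group sizes and covariate structure", {
  co <- generate_cohort(cohort_spec(n_tbi = 37, n_control = 13, seed = 4))
  tab <- co$table
  expect_identical(nrow(tab), 50L)
  expect_identical(sum(tab$group == "tbi"), 37L)
  expect_identical(sum(tab$group == "control"), 13L)
  ## injury-specific fields absent for controls
  expect_true(all(is.na(tab$days_since_injury[tab$group == "control"])))
  expect_true(all(is.na(tab$gcs[tab$group == "control"])))
  expect_true(all(!is.na(tab$days_since_injury[tab$group == "tbi"])))
  ## per-subject phantom specs realise the subject's ALPS parameter
  expect_length(co$phantom_specs, 50L)
  i <- which(tab$alps_param > 1)[1]
  expect_equal(co$phantom_specs[[i]]$d_perivascular,
               (tab$alps_param[i] - 1) * co$phantom_specs[[i]]$lambda_perp)
  ## reproducible under seed
  co2 <- generate_cohort(cohort_spec(n_tbi = 37, n_control = 13, seed = 4))
  expect_identical(tab, co2$table)
})

test_that("degenerate cohort specs are rejected", {
  expect_error(cohort_spec(n_tbi = 1), "2 subjects")
  expect_error(cohort_spec(alps_sd = -1), "SD")
  expect_error(cohort_spec(pvs_tubule_rate = -2), "rate")
})

test_that("ground-truth ALPS from generative tensors equals the analytic ratio", {
  sp <- small_spec(d_perivascular = 0.3e-3)
  ph <- generate_phantom(sp)
  rois <- place_rois(ph$truth, slice = ph$layout$alps_slice,
                     centers = ph$layout$centers)
  res <- compute_alps(ph$truth, rois)
  expect_equal(res$alps_mean, (sp$lambda_perp + 0.3e-3) / sp$lambda_perp,
               tolerance = 1e-12)
})
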