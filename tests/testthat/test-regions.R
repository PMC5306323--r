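test_that("whole-brain mean is the plain average over the mask, CSF included", {
  d <- c(4, 4, 4)
  vox <- c(1.7, 1.7, 1.7)
  mask <- array(TRUE, d)
  expect_equal(whole_brain_mean(cbf_map(array(28, d), mask, vox)), 28)
  two <- array(0, d); two[1] <- 20; two[2] <- 36
  m2 <- array(FALSE, d); m2[1:2] <- TRUE
  expect_equal(whole_brain_mean(cbf_map(two, mask, vox), m2), 28)
  expect_error(whole_brain_mean(cbf_map(two, mask, vox), array(FALSE, d)),
               "empty")
})

test_that("zero-perfusion CSF pulls the whole-brain mean below the GM mean", {
  ph <- build_phantom(small_phantom_config())
  stk <- simulate_asl(ph, noise_sd_fraction = 0)
  cbf <- quantify_cbf(stk)
  wb <- whole_brain_mean(cbf, ph$brain_mask)
  gm_only <- mean(cbf$values[ph$pve_gm > 0.5])
  expect_lt(wb, gm_only)
})

test_that("default phantom regional means land on their calibration values", {
  ph <- build_phantom(phantom_config())
  stk <- simulate_asl(ph, noise_sd_fraction = 0)
  cbf <- quantify_cbf(stk)
  rm <- regional_means(cbf, ph$region_labels)
  target <- c(frontal = 18.7, parietal = 23.9, prcpcc = 30.2,
              temporal = 21.8, occipital = 29.1)
  expect_equal(rm$region, names(target))
  expect_true(all(rm$n_voxels > 0))
  expect_true(all(abs(rm$mean_cbf - target) / target < 0.10))
})

test_that("PVC cortical means exceed uncorrected means in mixed tissue", {
  ph <- build_phantom(phantom_config())
  stk <- simulate_asl(ph, noise_sd_fraction = 0)
  cbf <- quantify_cbf(stk)
  res <- pvc_regress(cbf, ph$pve_gm, ph$pve_wm)
  rm <- regional_means(cbf, ph$region_labels, pvc = res, pve_gm = ph$pve_gm)
  expect_true(all(rm$pvc_cbf > rm$mean_cbf))
  expect_gt(weighted_cortical_mean(res, ph$pve_gm),
            whole_brain_mean(cbf, ph$brain_mask))
})

test_that("permuting label integers permutes the outputs identically", {
  ph <- build_phantom(small_phantom_config())
  stk <- simulate_asl(ph, noise_sd_fraction = 0.2, seed = 8)
  cbf <- quantify_cbf(stk)
  rm1 <- regional_means(cbf, ph$region_labels)
  perm <- c(3L, 1L, 5L, 2L, 4L, 6L)   # new label for old labels 1..6
  lab2 <- ph$region_labels
  lab2[ph$region_labels > 0] <- perm[ph$region_labels[ph$region_labels > 0]]
  rm2 <- regional_means(cbf, lab2, region_ids = perm[1:5])
  expect_equal(rm2$mean_cbf, rm1$mean_cbf)
  expect_equal(rm2$n_voxels, rm1$n_voxels)
})

test_that("regions absent from the label map are reported missing, not zero", {
  ph <- build_phantom(small_phantom_config())
  stk <- simulate_asl(ph, noise_sd_fraction = 0)
  cbf <- quantify_cbf(stk)
  lab <- ph$region_labels
  lab[lab == 3L] <- 6L   # erase PRCPCC
  rm <- regional_means(cbf, lab)
  expect_identical(rm$n_voxels[rm$region == "prcpcc"], 0L)
  expect_true(is.na(rm$mean_cbf[rm$region == "prcpcc"]))
  expect_true(all(!is.na(rm$mean_cbf[rm$region != "prcpcc"])))
})

test_that("whole-brain mean decomposes over a tiling label partition", {
  ph <- build_phantom(small_phantom_config())
  stk <- simulate_asl(ph, noise_sd_fraction = 0.1, seed = 2)
  cbf <- quantify_cbf(stk)
  rm <- regional_means(cbf, ph$region_labels, region_ids = 1:6,
                       region_names = c(asl_regions, "other"))
  wb <- whole_brain_mean(cbf, ph$brain_mask)
  expect_equal(sum(rm$mean_cbf * rm$n_voxels) / sum(rm$n_voxels), wb,
               tolerance = 1e-12)
})

test_that("regional statistics are bit-identical after a write/read cycle", {
  ph <- build_phantom(small_phantom_config())
  stk <- simulate_asl(ph, noise_sd_fraction = 0.1, seed = 4)
  cbf <- quantify_cbf(stk)
  tmp <- withr::local_tempdir()
  f_cbf <- file.path(tmp, "cbf.nii.gz")
  f_lab <- file.path(tmp, "labels.nii.gz")
  write_volume(cbf$values, f_cbf, cbf$voxel_size_mm)
  write_volume(ph$region_labels, f_lab, cbf$voxel_size_mm)
  v <- read_volume(f_cbf)
  lab <- read_volume(f_lab)
  cbf2 <- cbf_map(array(as.numeric(v), dim(v)), cbf$mask,
                  attr(v, "voxel_size_mm"))
  rm1 <- regional_means(cbf, ph$region_labels)
  rm2 <- regional_means(cbf2, array(as.integer(lab), dim(lab)))
  expect_identical(rm1$mean_cbf, rm2$mean_cbf)
})
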