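test_that("gaussian weight stencil has the closed-form sigma and is normalized", {
  w <- gaussian_weights(kernel_spec(9.5), c(1.7, 1.7, 1.7))
  # sigma = fwhm / (2 sqrt(2 ln 2)) = 9.5/2.3548/1.7 voxels
  expect_equal(unname(w$sigma_vox), rep(2.3731050302, 3), tolerance = 1e-9)
  expect_equal(sum(w$stencil), 1, tolerance = 1e-12)
  ctr <- (dim(w$stencil) + 1) / 2
  expect_equal(max(w$stencil), w$stencil[ctr[1], ctr[2], ctr[3]])
  # reflection symmetry for isotropic voxels
  expect_equal(w$stencil, w$stencil[rev(seq_len(dim(w$stencil)[1])), , ],
               tolerance = 1e-15)
  expect_equal(aperm(w$stencil, c(2, 1, 3)), w$stencil, tolerance = 1e-15)
})

test_that("anisotropic voxels give an anisotropic stencil", {
  w <- gaussian_weights(kernel_spec(9.5), c(1.7, 1.7, 5.0))
  expect_equal(unname(w$radius), c(7, 7, 2))
  expect_warning(gaussian_weights(kernel_spec(9.5), c(20, 20, 20)),
                 "single-voxel")
})

test_that("kernel regression matches the brute-force per-voxel solve", {
  d <- c(16, 16, 16)
  set.seed(31)
  pv <- smooth_pve_pair(d)
  y <- 43 * pv$G + 20 * pv$W + array(rnorm(prod(d), 0, 3), d)
  for (vox in list(c(3.4, 3.4, 3.4), c(1.7, 1.7, 5.0))) {
    cbf <- cbf_map(y, array(TRUE, d), vox)
    res <- pvc_regress(cbf, pv$G, pv$W, kernel_spec(9.5), gm_guard = 0)
    ora <- brute_pvc(y, pv$G, pv$W, 9.5, vox)
    expect_identical(res$rank2_mask, ora$rank2)
    both <- res$rank2_mask & ora$rank2
    expect_gt(sum(both), 1000)
    scale <- pmax(abs(ora$gm[both]), 1)
    expect_lt(max(abs(res$gm_cbf[both] - ora$gm[both]) / scale), 1e-10)
    expect_lt(max(abs(res$wm_cbf[both] - ora$wm[both]) /
                    pmax(abs(ora$wm[both]), 1)), 1e-10)
  }
})

test_that("noise-free two-tissue mixtures are recovered exactly at rank-2 voxels", {
  d <- c(16, 16, 16)
  set.seed(17)
  pv <- smooth_pve_pair(d)
  y <- 43 * pv$G + 20 * pv$W
  cbf <- cbf_map(y, array(TRUE, d), c(3.4, 3.4, 3.4))
  res <- pvc_regress(cbf, pv$G, pv$W)
  expect_gt(sum(res$valid_mask), 1000)
  expect_lt(max(abs(res$gm_cbf[res$valid_mask] - 43) / 43), 1e-6)
  expect_lt(max(abs(res$wm_cbf[res$valid_mask] - 20) / 20), 1e-6)
  # global unweighted least squares as an independent check on the truth
  glob <- coef(lm(as.vector(y) ~ 0 + as.vector(pv$G) + as.vector(pv$W)))
  expect_equal(unname(glob), c(43, 20), tolerance = 1e-8)
})

test_that("pure gray matter leaves a uniform map unchanged", {
  d <- c(12, 12, 12)
  G <- array(1, d)
  W <- array(0, d)
  y <- array(43, d)
  cbf <- cbf_map(y, array(TRUE, d), c(1.7, 1.7, 1.7))
  res <- pvc_regress(cbf, G, W)
  # single-tissue windows are rank deficient: dominant-tissue fallback
  # reproduces the uniform perfusion everywhere
  expect_equal(unname(res$gm_cbf), unname(y), tolerance = 1e-9)
  # single-tissue windows must be flagged, never silently accepted
  expect_true(all(res$diagnostics == 2L))
  expect_equal(sum(res$valid_mask), 0)
})

test_that("PVC estimates are unbiased under acquisition noise", {
  cfg <- small_phantom_config(noise_sd_fraction = 0.2)
  gm_u <- c(frontal = 43, parietal = 43, prcpcc = 43, temporal = 43,
            occipital = 43, other = 43)
  ph <- build_phantom(small_phantom_config(
    true_gm_cbf_by_region = gm_u, true_wm_cbf = 20))
  p <- kinetic_params()
  sel <- NULL
  est <- vapply(1:200, function(i) {
    stk <- simulate_asl(ph, p, noise_sd_fraction = 0.2, seed = 5000 + i)
    cbf <- quantify_cbf(stk, p)
    res <- pvc_regress(cbf, ph$pve_gm, ph$pve_wm)
    if (is.null(sel))
      sel <<- res$valid_mask & ph$pve_gm > 0.3 & ph$pve_gm < 0.9
    mean(res$gm_cbf[sel])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 43), 3 * mc_se)
})

test_that("weighted cortical mean reduces to the expected closed forms", {
  d <- c(3, 1, 1)
  gm <- array(c(40, 50, 60), d)
  # hand-computed: (0.2*40 + 0.5*50 + 1.0*60) / 1.7
  expect_equal(weighted_cortical_mean(gm, array(c(0.2, 0.5, 1.0), d)),
               54.7058823529, tolerance = 1e-10)
  # constant map -> the constant, any positive weights
  expect_equal(weighted_cortical_mean(array(33, d), array(c(0.1, 0.9, 0.4), d)),
               33)
  # equal weights -> arithmetic mean
  expect_equal(weighted_cortical_mean(gm, array(0.5, d)), 50)
  expect_error(weighted_cortical_mean(gm, array(0, d)), "empty cortical ROI")
})

test_that("guarded and degenerate voxels are excluded from the valid mask", {
  d <- c(12, 12, 12)
  set.seed(4)
  pv <- smooth_pve_pair(d)
  y <- 43 * pv$G + 20 * pv$W
  cbf <- cbf_map(y, array(TRUE, d), c(3.4, 3.4, 3.4))
  res <- pvc_regress(cbf, pv$G, pv$W, gm_guard = 0.5)
  expect_true(all(pv$G[res$valid_mask] >= 0.5))
  expect_true(all(res$diagnostics[res$valid_mask] == 0L))
  # all-zero tissue windows are invalid
  res0 <- pvc_regress(cbf_map(y, array(TRUE, d), c(3.4, 3.4, 3.4)),
                      array(0, d), array(0, d))
  expect_equal(sum(res0$valid_mask), 0)
})
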