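#' Gaussian kernel specification for partial-volume correction
#'
#' @param fwhm_mm Full width at half maximum of the 3-D Gaussian kernel in
#'   mm (default 9.5, a common choice for pcASL at ~1.7 mm reconstructed
#'   in-plane resolution).
#' @param truncation_sigmas Cutoff radius of the discrete stencil, in
#'   sigma units (default 3).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(fwhm_mm = 9.5, truncation_sigmas = 3) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  if (truncation_sigmas <= 0) stop("truncation_sigmas must be positive")
  structure(list(fwhm_mm = fwhm_mm, truncation_sigmas = truncation_sigmas),
            class = "kernel_spec")
}

#' Discrete Gaussian weight stencil
#'
#' Converts the kernel FWHM to a per-axis sigma in voxel units
#' (`sigma = fwhm / (2 sqrt(2 log 2)) / spacing`, so anisotropic voxels
#' give an anisotropic stencil), truncates each axis at
#' `truncation_sigmas * sigma`, and returns the separable stencil
#' normalized to sum 1.
#'
#' @param kernel A [kernel_spec()].
#' @param voxel_size_mm Numeric length-3 voxel spacing in mm.
#' @return A list with `stencil` (3-D array summing to 1), `axis_kernels`
#'   (unnormalized per-axis weights), `radius` (per-axis half-width in
#'   voxels), `sigma_mm` and `sigma_vox`.
#' @examples
#' w <- gaussian_weights(kernel_spec(9.5), c(1.7, 1.7, 1.7))
#' w$sigma_vox  # about 2.373 voxels per axis
#' @export
gaussian_weights <- function(kernel, voxel_size_mm) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive spacings")
  sigma_mm <- kernel$fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / voxel_size_mm
  radius <- floor(kernel$truncation_sigmas * sigma_vox)
  if (any(radius < 1)) {
    warning("kernel narrower than one voxel on some axis; ",
            "using a degenerate single-voxel stencil there")
    radius <- pmax(radius, 0)
  }
  axis_kernels <- lapply(1:3, function(k) {
    off <- seq(-radius[k], radius[k])
    exp(-off^2 / (2 * sigma_vox[k]^2))
  })
  stencil <- outer(outer(axis_kernels[[1]], axis_kernels[[2]]),
                   axis_kernels[[3]])
  stencil <- stencil / sum(stencil)
  list(stencil = stencil, axis_kernels = axis_kernels, radius = radius,
       sigma_mm = sigma_mm, sigma_vox = sigma_vox)
}

# banded matrix applying a 1-D kernel along one dimension with zero padding
.band_matrix <- function(n, kern, r) {
  M <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- kern[o + r + 1]
  }
  M
}

# separable 3-D convolution with zero padding (equivalent to clipping the
# stencil at the volume boundary, since padded voxels carry zero signal
# and zero tissue fraction)
.conv3d <- function(a, weights) {
  d <- dim(a)
  B <- lapply(1:3, function(k)
    .band_matrix(d[k], weights$axis_kernels[[k]], weights$radius[k]))
  a <- array(B[[1]] %*% matrix(a, d[1]), d)
  a <- aperm(array(B[[2]] %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  a <- aperm(array(B[[3]] %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
                   c(d[3], d[1], d[2])), c(2, 3, 1))
  a
}

#' Partial-volume correction by locally weighted two-tissue regression
#'
#' At each brain voxel v, solves the weighted least-squares problem
#' \deqn{cbf(u) \approx P_{GM}(u)\, c_{GM} + P_{WM}(u)\, c_{WM}}
#' over the Gaussian-kernel neighbourhood of v (no intercept; CSF
#' perfusion is assumed zero), yielding maps of pure-tissue gray- and
#' white-matter perfusion. The per-voxel normal equations are assembled by
#' separable Gaussian convolution of the product images, which is
#' algebraically identical to the per-voxel stencil solve (weight
#' normalization cancels in the solution). The stencil is clipped at the
#' volume boundary.
#'
#' Voxels whose local 2x2 design is rank-deficient (condition number above
#' `cond_threshold`, e.g. windows containing a single tissue) are excluded
#' from `valid_mask`; for these a dominant-tissue fallback
#' `sum(w * cbf) / sum(w * P_dom)` is recorded in the dominant tissue's
#' map and flagged in `diagnostics`. The cortical map is additionally
#' reported only where the central `pve_gm >= gm_guard`.
#'
#' @param cbf A [cbf_map()] of kind `"uncorrected"`.
#' @param pve_gm,pve_wm 3-D partial-volume maps congruent with `cbf`.
#' @param kernel A [kernel_spec()]; default 9.5 mm FWHM.
#' @param cond_threshold Condition-number limit for the local design.
#' @param gm_guard Minimum central GM fraction for a voxel to enter the
#'   reported cortical map (numerical guard; default 0.05).
#' @return An object of class `pvc_result`: `gm_cbf` and `wm_cbf` maps
#'   (NA where no estimate exists), `valid_mask`, and `diagnostics`
#'   (0 = regression valid; 1 = valid fit but `pve_gm` below `gm_guard`;
#'   2 = rank-deficient, fallback recorded; 3 = empty tissue window;
#'   -1 = outside brain).
#' @export
pvc_regress <- function(cbf, pve_gm, pve_wm, kernel = kernel_spec(),
                        cond_threshold = 1e8, gm_guard = 0.05) {
  stopifnot(inherits(cbf, "cbf_map"))
  if (cbf$kind != "uncorrected")
    stop("pvc_regress expects an uncorrected CBF map")
  if (!identical(dim(pve_gm), dim(cbf$values)) ||
      !identical(dim(pve_wm), dim(cbf$values)))
    stop("PVE maps must be congruent with the CBF map")
  w <- gaussian_weights(kernel, cbf$voxel_size_mm)
  y <- cbf$values
  G <- pve_gm; W <- pve_wm

  S_gg <- .conv3d(G * G, w)
  S_gw <- .conv3d(G * W, w)
  S_ww <- .conv3d(W * W, w)
  S_gy <- .conv3d(G * y, w)
  S_wy <- .conv3d(W * y, w)
  S_g <- .conv3d(G, w)
  S_w <- .conv3d(W, w)
  S_y <- .conv3d(y, w)

  # eigenvalues of the symmetric 2x2 normal matrix [[a,b],[b,c]]
  tr <- S_gg + S_ww
  disc <- sqrt(pmax((S_gg - S_ww)^2 + 4 * S_gw^2, 0))
  lam_max <- (tr + disc) / 2
  lam_min <- (tr - disc) / 2
  det <- S_gg * S_ww - S_gw^2

  mask <- cbf$mask
  empty <- mask & (lam_max <= 0)
  rank2 <- mask & !empty & (lam_min > 0) & (lam_max / pmax(lam_min, .Machine$double.xmin) <= cond_threshold)
  deficient <- mask & !empty & !rank2

  d <- dim(y)
  gm <- array(NA_real_, d)
  wm <- array(NA_real_, d)
  gm[rank2] <- (S_ww[rank2] * S_gy[rank2] - S_gw[rank2] * S_wy[rank2]) / det[rank2]
  wm[rank2] <- (S_gg[rank2] * S_wy[rank2] - S_gw[rank2] * S_gy[rank2]) / det[rank2]

  # dominant-tissue fallback on rank-deficient voxels
  gm_dom <- deficient & (S_g >= S_w) & (S_g > 0)
  wm_dom <- deficient & (S_w > S_g) & (S_w > 0)
  gm[gm_dom] <- S_y[gm_dom] / S_g[gm_dom]
  wm[wm_dom] <- S_y[wm_dom] / S_w[wm_dom]

  diagnostics <- array(-1L, d)
  diagnostics[mask] <- 3L
  diagnostics[deficient] <- 2L
  diagnostics[rank2 & pve_gm < gm_guard] <- 1L
  diagnostics[rank2 & pve_gm >= gm_guard] <- 0L

  structure(list(gm_cbf = gm, wm_cbf = wm,
                 valid_mask = rank2 & pve_gm >= gm_guard,
                 rank2_mask = rank2,
                 diagnostics = diagnostics,
                 voxel_size_mm = cbf$voxel_size_mm,
                 kernel = kernel, gm_guard = gm_guard),
            class = "pvc_result")
}

#' @export
print.pvc_result <- function(x, ...) {
  cat(sprintf("<pvc_result> %d valid voxels, mean cortical %.2f mL/100g/min (fwhm %.1f mm)\n",
              sum(x$valid_mask), mean(x$gm_cbf[x$valid_mask]),
              x$kernel$fwhm_mm))
  invisible(x)
}

#' PVE-weighted cortical mean perfusion
#'
#' Summarizes a corrected cortical map over a region of interest using the
#' gray-matter partial-volume estimates as weights:
#' `sum(P_GM * gm_cbf) / sum(P_GM)` over valid ROI voxels. Invalid voxels
#' (failed or guarded regression) are excluded.
#'
#' @param result A [pvc_regress()] result, or a plain numeric 3-D array of
#'   cortical perfusion (then finiteness defines validity).
#' @param pve_gm Gray-matter PVE map (the weights).
#' @param roi_mask Optional logical array restricting the summary; default
#'   whole volume.
#' @return Scalar weighted mean (mL/100 g/min).
#' @export
weighted_cortical_mean <- function(result, pve_gm, roi_mask = NULL) {
  if (inherits(result, "pvc_result")) {
    gm <- result$gm_cbf
    valid <- result$valid_mask
  } else {
    gm <- result
    valid <- is.finite(gm)
  }
  stopifnot(identical(dim(gm), dim(pve_gm)))
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim(gm))
  sel <- valid & roi_mask
  wsum <- sum(pve_gm[sel])
  if (!is.finite(wsum) || wsum <= 0)
    stop("empty cortical ROI: no valid voxels with positive GM fraction")
  sum(pve_gm[sel] * gm[sel]) / wsum
}
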