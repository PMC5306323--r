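# Default ground-truth gray-matter perfusion per region (mL/100 g/min),
# calibrated once against the default phantom geometry so that the
# *uncorrected* regional means (GM/WM/CSF-mixed voxels) land at typical
# memory-clinic values: frontal 18.7, parietal 23.9, PRCPCC 30.2,
# temporal 21.8, occipital 29.1 mL/100 g/min.
.default_gm_cbf <- c(frontal = 23.5, parietal = 30.2, prcpcc = 38.3,
                     temporal = 27.5, occipital = 36.7, other = 25.0)

#' Configuration of the synthetic brain phantom
#'
#' The phantom is a set of concentric ellipsoids on a regular grid: a
#' central CSF "ventricle", a white-matter core, and an outer gray-matter
#' shell, with smooth partial-volume transitions between compartments.
#' Angular sectors of the shell are labelled as the five cortical regions.
#' Anatomical realism is explicitly not a goal; the phantom exists to give
#' every downstream stage inputs with known ground truth.
#'
#' @param grid_shape Integer length-3, voxels per axis (all >= 8).
#' @param voxel_size_mm Numeric length-3, spacing in mm (all > 0).
#' @param true_gm_cbf_by_region Named vector of ground-truth GM perfusion
#'   (mL/100 g/min) for `frontal`, `parietal`, `prcpcc`, `temporal`,
#'   `occipital` and `other` (non-cortical brain). Defaults are calibrated
#'   so uncorrected regional means of the default phantom fall at typical
#'   clinical values.
#' @param true_wm_cbf Ground-truth white-matter perfusion (mL/100 g/min).
#' @param noise_sd_fraction Gaussian noise SD applied to the simulated ASL
#'   difference image, as a fraction of the mean |dS| over brain voxels.
#' @param seed Integer seed for the ASL noise.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L),
                           voxel_size_mm = c(1.7, 1.7, 1.7),
                           true_gm_cbf_by_region = .default_gm_cbf,
                           true_wm_cbf = 20,
                           noise_sd_fraction = 0.1,
                           seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("grid_shape must give at least 8 voxels per axis")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive spacings")
  need <- c(asl_regions, "other")
  gm <- true_gm_cbf_by_region
  if (is.null(names(gm)) || !all(need %in% names(gm))) {
    if (!all(asl_regions %in% names(gm)))
      stop("true_gm_cbf_by_region must name: ", paste(need, collapse = ", "))
    gm <- c(gm, other = unname(mean(gm[asl_regions])))
  }
  if (any(gm < 0) || true_wm_cbf < 0)
    stop("ground-truth CBF values must be non-negative")
  if (noise_sd_fraction < 0)
    stop("noise_sd_fraction must be non-negative")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 true_gm_cbf_by_region = gm[need],
                 true_wm_cbf = true_wm_cbf,
                 noise_sd_fraction = noise_sd_fraction,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# cubic smoothstep on [0,1]
.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Build the synthetic multi-tissue phantom
#'
#' Constructs partial-volume estimate (PVE) maps for gray matter, white
#' matter and CSF, a region label map, and the voxelwise ground-truth CBF
#' map obeying the two-tissue mixing law
#' `true_cbf = pve_gm * c_GM(region) + pve_wm * c_WM`
#' (CSF perfusion is zero). Compartment boundaries are smoothed over about
#' 2.5 voxels so mixed-tissue voxels exist everywhere the partial-volume
#' correction needs them.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_truth` with elements `pve_gm`,
#'   `pve_wm`, `pve_csf`, `region_labels` (0 background, 1..5 cortical
#'   sectors, 6 other brain), `true_cbf`, `brain_mask`, `voxel_size_mm`
#'   and the originating `config`.
#' @export
build_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  vox <- config$voxel_size_mm

  # physical coordinates centred on the grid
  ax <- lapply(1:3, function(k) (seq_len(d[k]) - (d[k] + 1) / 2) * vox[k])
  X1 <- array(ax[[1]], d)
  X2 <- array(rep(ax[[2]], each = d[1]), d)
  X3 <- array(rep(ax[[3]], each = d[1] * d[2]), d)

  # ellipsoid semi-axes: 90 % of the half-extent per axis
  semi <- 0.45 * d * vox
  rho <- sqrt((X1 / semi[1])^2 + (X2 / semi[2])^2 + (X3 / semi[3])^2)

  rho_wm <- 0.66     # GM/WM boundary (fraction of brain radius)
  rho_csf <- 0.26    # WM/CSF boundary
  t_mm <- 2.5 * mean(vox)            # transition width, >= 2 voxels
  w_rho <- t_mm / mean(semi)
  if ((rho_wm - rho_csf) * mean(semi) < t_mm ||
      (1 - rho_wm) * mean(semi) < t_mm)
    stop("grid too small to contain three tissue compartments at this voxel size")

  inside <- function(r0) .smoothstep((r0 - rho) / w_rho + 0.5)
  s_brain <- inside(1)
  s_wm <- inside(rho_wm)
  s_csf <- inside(rho_csf)

  pve_csf <- s_csf
  pve_wm <- s_wm - s_csf
  pve_gm <- s_brain - s_wm

  pve_sum <- pve_gm + pve_wm + pve_csf
  brain_mask <- pve_sum > 0

  # angular sectors (azimuth in the first two axes) name the five regions
  theta <- atan2(X2, X1)
  sector <- pmin(floor((theta + pi) / (2 * pi / 5)) + 1, 5)
  labels <- array(0L, d)
  labels[brain_mask] <- ifelse(rho[brain_mask] < rho_wm, 6L,
                               as.integer(sector[brain_mask]))

  gm_lut <- c(config$true_gm_cbf_by_region[asl_regions],
              config$true_gm_cbf_by_region[["other"]])
  c_gm <- array(0, d)
  c_gm[brain_mask] <- gm_lut[labels[brain_mask]]
  true_cbf <- pve_gm * c_gm + pve_wm * config$true_wm_cbf

  structure(list(pve_gm = pve_gm, pve_wm = pve_wm, pve_csf = pve_csf,
                 region_labels = labels, true_cbf = true_cbf,
                 brain_mask = brain_mask, voxel_size_mm = vox,
                 config = config),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> grid %s, %d brain voxels, GM truth %s\n",
              paste(dim(x$true_cbf), collapse = "x"), sum(x$brain_mask),
              paste(sprintf("%s=%.1f", asl_regions,
                            x$config$true_gm_cbf_by_region[asl_regions]),
                    collapse = " ")))
  invisible(x)
}

#' Simulate an ASL acquisition from phantom ground truth
#'
#' Inverts the single-compartment quantification equation: the noise-free
#' difference signal is `delta_s = true_cbf * s0 / quantification_factor`,
#' so that quantification of the noise-free stack recovers `true_cbf`
#' exactly. Gaussian noise (seeded) is added to `delta_s` only; the
#' proton-density reference stays noise-free, which keeps the noise model
#' of the quantified CBF analytically simple (SD = factor * sigma_dS / S0).
#'
#' @param truth A [build_phantom()] result.
#' @param params [kinetic_params()] used for the inversion.
#' @param noise_sd_fraction Noise SD on `delta_s` as a fraction of the mean
#'   |dS| over brain voxels; defaults to the phantom config value.
#' @param seed Integer seed; defaults to the phantom config seed.
#' @param s0_value Reference-image intensity on the brain (scanner units).
#' @return A [volume_stack()] carrying the PVE maps and labels.
#' @export
simulate_asl <- function(truth, params = kinetic_params(),
                         noise_sd_fraction = NULL, seed = NULL,
                         s0_value = 1000) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(noise_sd_fraction))
    noise_sd_fraction <- truth$config$noise_sd_fraction
  if (is.null(seed)) seed <- truth$config$seed
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be non-negative")
  f <- quantification_factor(params)
  d <- dim(truth$true_cbf)
  mask <- truth$brain_mask
  s0 <- array(0, d)
  s0[mask] <- s0_value
  delta_s <- array(0, d)
  delta_s[mask] <- truth$true_cbf[mask] * s0_value / f
  if (noise_sd_fraction > 0) {
    sd_n <- noise_sd_fraction * mean(abs(delta_s[mask]))
    set.seed(seed)
    delta_s[mask] <- delta_s[mask] + stats::rnorm(sum(mask), 0, sd_n)
  }
  volume_stack(delta_s, s0, truth$voxel_size_mm,
               pve_gm = truth$pve_gm, pve_wm = truth$pve_wm,
               pve_csf = truth$pve_csf, labels = truth$region_labels,
               brain_mask = mask)
}
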