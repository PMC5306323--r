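#' Kinetic parameters for single-compartment CBF quantification
#'
#' Bundles the constants of the single-compartment pcASL quantification
#' equation. Defaults correspond to a 3T background-suppressed 3D-FSE pcASL
#' protocol: post-label delay 2.0 s, labelling duration 1.5 s, blood-tissue
#' water partition coefficient 0.9 mL/g, combined labelling and
#' background-suppression efficiency 0.8 * 0.75 = 0.6, T1 of arterial blood
#' 1.4 s, and a saturation-recovery correction of the proton-density
#' reference image (TSAT = 2.0 s recovered with T1 = 1.2 s).
#'
#' @param w Post-label delay (s).
#' @param tau Labelling duration (s).
#' @param lam Blood-tissue water partition coefficient (mL/g).
#' @param eps Labelling efficiency (dimensionless, <= 1). The default folds
#'   label efficiency and background-suppression losses into one constant.
#' @param t1b Longitudinal relaxation time of arterial blood (s).
#' @param t_sat Saturation-recovery time of the proton-density reference (s).
#' @param t1gm Tissue T1 used for the saturation-recovery correction (s).
#' @param unit_factor Scale from mL/g/s to output units. The default 6000
#'   converts to the conventional mL/100 g/min.
#' @return An object of class `kinetic_params`.
#' @seealso [quantify_cbf()], [quantification_factor()]
#' @examples
#' p <- kinetic_params()
#' quantification_factor(p)
#' @export
kinetic_params <- function(w = 2.0, tau = 1.5, lam = 0.9, eps = 0.8 * 0.75,
                           t1b = 1.4, t_sat = 2.0, t1gm = 1.2,
                           unit_factor = 6000) {
  p <- list(w = w, tau = tau, lam = lam, eps = eps, t1b = t1b,
            t_sat = t_sat, t1gm = t1gm, unit_factor = unit_factor)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetic parameters must be finite and strictly positive")
  if (eps > 1)
    stop("labelling efficiency 'eps' cannot exceed 1")
  structure(p, class = "kinetic_params")
}

#' Scalar multiplier of the quantification equation
#'
#' The single-compartment model expresses CBF as a fixed multiple of the
#' ASL signal ratio:
#' \deqn{CBF = F \cdot \Delta S / S_0,\qquad
#'   F = u \cdot \frac{\lambda (1 - e^{-T_{SAT}/T_{1GM}})\, e^{w/T_{1B}}}
#'            {2 T_{1B} (1 - e^{-\tau/T_{1B}})\, \varepsilon}}
#' with `u` the unit conversion. This factor is exposed separately because
#' many properties of the pipeline (linearity, noise propagation, phantom
#' round trips) are statements about it.
#'
#' @param params A [kinetic_params()] object.
#' @return Positive scalar, in output units (mL/100 g/min by default) per
#'   unit of \eqn{\Delta S / S_0}.
#' @export
quantification_factor <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  with(params,
       unit_factor * lam * (1 - exp(-t_sat / t1gm)) * exp(w / t1b) /
         (2 * t1b * (1 - exp(-tau / t1b)) * eps))
}

#' Construct a co-registered volume stack
#'
#' Holds the ASL difference image and the proton-density reference on a
#' common grid, optionally carrying tissue partial-volume estimates and a
#' region label map through the pipeline.
#'
#' @param delta_s 3-D array, ASL control-minus-label difference signal.
#' @param s0 3-D array, proton-density reference; must be positive on the
#'   brain mask.
#' @param voxel_size_mm Numeric length-3, voxel spacing in mm.
#' @param pve_gm,pve_wm,pve_csf Optional 3-D partial-volume maps in [0, 1].
#' @param labels Optional 3-D integer region label map.
#' @param brain_mask Optional logical 3-D array; defaults to `s0 > 0`.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(delta_s, s0, voxel_size_mm,
                         pve_gm = NULL, pve_wm = NULL, pve_csf = NULL,
                         labels = NULL, brain_mask = NULL) {
  if (!identical(dim(delta_s), dim(s0)))
    stop("delta_s and s0 must share one grid")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive spacings")
  if (is.null(brain_mask)) brain_mask <- s0 > 0
  for (m in list(pve_gm, pve_wm, pve_csf, labels, brain_mask))
    if (!is.null(m) && !identical(dim(m), dim(delta_s)))
      stop("all volumes in a stack must share one grid")
  structure(list(delta_s = delta_s, s0 = s0,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 pve_gm = pve_gm, pve_wm = pve_wm, pve_csf = pve_csf,
                 labels = labels, brain_mask = brain_mask),
            class = "volume_stack")
}

#' Construct a CBF map
#'
#' @param values 3-D array of perfusion values (mL/100 g/min), zero outside
#'   the mask.
#' @param mask Logical 3-D array of brain support.
#' @param voxel_size_mm Numeric length-3 voxel spacing (mm).
#' @param kind Either `"uncorrected"` or `"pvc_cortical"`.
#' @return An object of class `cbf_map`.
#' @export
cbf_map <- function(values, mask, voxel_size_mm,
                    kind = c("uncorrected", "pvc_cortical")) {
  kind <- match.arg(kind)
  stopifnot(identical(dim(values), dim(mask)))
  if (any(!is.finite(values[mask])))
    stop("CBF values must be finite on the mask")
  structure(list(values = values, mask = mask,
                 voxel_size_mm = as.numeric(voxel_size_mm), kind = kind),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  cat(sprintf("<cbf_map> %s, grid %s, %d brain voxels, mean %.2f mL/100g/min\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              sum(x$mask), mean(x$values[x$mask])))
  invisible(x)
}

#' Voxelwise CBF quantification (single-compartment model)
#'
#' Applies the single-compartment quantification equation voxelwise:
#' `values = quantification_factor(params) * delta_s / s0` on the brain
#' mask, zero outside. Negative values (pure noise propagation) are kept;
#' no clipping is applied, so downstream ROI means reflect the raw
#' quantification.
#'
#' @param stack A [volume_stack()] with `delta_s` and `s0`.
#' @param params A [kinetic_params()] object.
#' @param mask Optional logical mask overriding `stack$brain_mask`.
#' @return A [cbf_map()] of kind `"uncorrected"`.
#' @examples
#' d <- c(8, 8, 8)
#' s0 <- array(1000, d)
#' ds <- array(10, d)
#' stk <- volume_stack(ds, s0, c(1.7, 1.7, 1.7))
#' cbf <- quantify_cbf(stk, kinetic_params())
#' mean(cbf$values)  # = factor * 0.01, about 165.5
#' @export
quantify_cbf <- function(stack, params = kinetic_params(), mask = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  if (is.null(mask)) mask <- stack$brain_mask
  n_bad <- sum(stack$s0[mask] <= 0)
  if (n_bad > 0)
    stop(sprintf("invalid reference image: S0 <= 0 at %d voxel(s) inside the mask",
                 n_bad))
  f <- quantification_factor(params)
  values <- array(0, dim(stack$delta_s))
  values[mask] <- f * stack$delta_s[mask] / stack$s0[mask]
  cbf_map(values, mask, stack$voxel_size_mm, kind = "uncorrected")
}
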