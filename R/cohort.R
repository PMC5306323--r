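#' CBF measure names available in simulated cohorts
#'
#' Uncorrected whole-brain and regional measures plus their
#' partial-volume-corrected (PVC) cortical counterparts. Cohort tables
#' store each as a column `cbf_<name>`, constant within subject (baseline
#' imaging).
#' @export
cbf_measures <- c("whole_brain", asl_regions,
                  "pvc_cortical", paste0("pvc_", asl_regions))

# Typical memory-clinic means and SDs (mL/100 g/min) for each measure,
# used as simulation defaults.
.default_cbf_means <- c(whole_brain = 28.0, frontal = 18.7, parietal = 23.9,
                        prcpcc = 30.2, temporal = 21.8, occipital = 29.1,
                        pvc_cortical = 43.0, pvc_frontal = 43.2,
                        pvc_parietal = 47.3, pvc_prcpcc = 53.8,
                        pvc_temporal = 39.0, pvc_occipital = 48.7)
.default_cbf_sds <- c(whole_brain = 5.6, frontal = 4.7, parietal = 5.9,
                      prcpcc = 6.8, temporal = 5.1, occipital = 7.7,
                      pvc_cortical = 8.7, pvc_frontal = 10.0,
                      pvc_parietal = 10.9, pvc_prcpcc = 11.8,
                      pvc_temporal = 8.3, pvc_occipital = 10.7)

#' Configuration of the longitudinal cohort simulator
#'
#' The simulator is the generative twin of the analysis model: MMSE
#' trajectories follow a linear mixed model with a per-subject random
#' intercept and random slope on time,
#' \deqn{MMSE_{ij} = \beta_0 + b_{0i} + (\beta_t + b_{1i}) t_{ij}
#'   + \beta_c z_i + \beta_{ct} z_i t_{ij} + x_i'\gamma + \epsilon_{ij}}
#' where \eqn{z_i} is the subject's baseline CBF standardized and inverted
#' (higher z = lower perfusion) and all random terms are independent
#' zero-mean Gaussians.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param effect_baseline Fixed intercept \eqn{\beta_0} (MMSE points).
#' @param effect_time Fixed annual change \eqn{\beta_t} (points/year).
#' @param effect_cbf Baseline CBF effect \eqn{\beta_c} (points per SD of
#'   inverted CBF).
#' @param effect_cbf_time CBF-by-time interaction \eqn{\beta_{ct}}
#'   (points/year per SD).
#' @param covariate_effects Named numeric vector of fixed effects for
#'   covariate columns (e.g. `c(age_years = -0.05)`); default none.
#' @param sd_random_intercept,sd_random_slope,sd_residual Dispersions
#'   (MMSE points; slope SD in points/year). Must be non-negative.
#' @param visit_count_range Integer `c(min, max)` visits per subject,
#'   within [2, 8]; counts are drawn uniformly.
#' @param mean_visit_interval_years Mean gap between visits; actual gaps
#'   are uniform on 0.7-1.3 times this value.
#' @param clamp_mmse If `TRUE`, round scores to integers and clamp to
#'   [0, 30]. Off by default: clamping biases slope recovery and is only
#'   wanted for realism studies.
#' @param cbf_measure Which measure drives the MMSE model (default
#'   whole-brain).
#' @param cbf_means,cbf_sds Named per-measure means/SDs (mL/100 g/min) for
#'   the simulated baseline CBF values; see [cbf_measures].
#' @param cbf_cor Correlation of each measure with a shared per-subject
#'   perfusion factor (measures are equicorrelated at `cbf_cor^2`).
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 88L,
                          effect_baseline = 22,
                          effect_time = -2.11,
                          effect_cbf = -0.42,
                          effect_cbf_time = -0.50,
                          covariate_effects = numeric(0),
                          sd_random_intercept = 3,
                          sd_random_slope = 1.5,
                          sd_residual = 1.5,
                          visit_count_range = c(2L, 8L),
                          mean_visit_interval_years = 1.0,
                          clamp_mmse = FALSE,
                          cbf_measure = "whole_brain",
                          cbf_means = .default_cbf_means,
                          cbf_sds = .default_cbf_sds,
                          cbf_cor = 0.7,
                          seed = 1L) {
  if (n_subjects < 4) stop("n_subjects must be at least 4")
  if (sd_random_intercept < 0 || sd_random_slope < 0 || sd_residual < 0)
    stop("dispersion parameters must be non-negative")
  vr <- as.integer(visit_count_range)
  if (length(vr) != 2L || vr[1] > vr[2] || vr[1] < 2 || vr[2] > 8)
    stop("visit_count_range must lie within [2, 8]")
  if (mean_visit_interval_years <= 0)
    stop("mean_visit_interval_years must be positive")
  cbf_measure <- match.arg(cbf_measure, cbf_measures)
  if (!all(cbf_measures %in% names(cbf_means)) ||
      !all(cbf_measures %in% names(cbf_sds)))
    stop("cbf_means and cbf_sds must name every measure in `cbf_measures`")
  if (cbf_cor < 0 || cbf_cor > 1) stop("cbf_cor must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 effect_baseline = effect_baseline,
                 effect_time = effect_time,
                 effect_cbf = effect_cbf,
                 effect_cbf_time = effect_cbf_time,
                 covariate_effects = covariate_effects,
                 sd_random_intercept = sd_random_intercept,
                 sd_random_slope = sd_random_slope,
                 sd_residual = sd_residual,
                 visit_count_range = vr,
                 mean_visit_interval_years = mean_visit_interval_years,
                 clamp_mmse = isTRUE(clamp_mmse),
                 cbf_measure = cbf_measure,
                 cbf_means = cbf_means[cbf_measures],
                 cbf_sds = cbf_sds[cbf_measures],
                 cbf_cor = cbf_cor,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a longitudinal memory-clinic cohort
#'
#' Draws baseline covariates matching typical memory-clinic distributions
#' (age 65 +/- 7 years, half women, Verhage education 5 +/- 1, normalized
#' gray matter volume 715.8 +/- 44.6 mL, medial temporal atrophy in half
#' steps 0-4, Fazekas white-matter score 0-3, zero-inflated counts of
#' microbleeds and lacunes), correlated baseline CBF values for every
#' measure, visit schedules (baseline at time 0, then 2-8 visits roughly a
#' year apart), and MMSE trajectories from the mixed model described in
#' [cohort_config()]. Covariates are drawn independently of one another
#' and of CBF.
#'
#' @param config A [cohort_config()].
#' @return A long-format `data.frame` (one row per visit) with columns
#'   `subject_id`, `visit`, `visit_time_years`, `mmse`, baseline covariates
#'   (`age_years`, `sex`, `education`, `ngmv_ml`, `mta`, `wmh_fazekas`,
#'   `n_microbleeds`, `n_lacunes`) and one `cbf_<measure>` column per
#'   measure, all baseline columns constant within subject.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects

  age <- stats::rnorm(n, 65, 7)
  sex <- stats::rbinom(n, 1, 0.5)
  education <- pmin(pmax(round(stats::rnorm(n, 5, 1)), 1), 7)
  ngmv <- stats::rnorm(n, 715.8, 44.6)
  mta <- pmin(pmax(round(2 * stats::rnorm(n, 1.5, 0.8)) / 2, 0), 4)
  wmh <- sample(0:3, n, replace = TRUE, prob = c(0.30, 0.35, 0.20, 0.15))
  microbleeds <- ifelse(stats::runif(n) < 0.65, 0L,
                        stats::rpois(n, 1.5))
  lacunes <- pmin(ifelse(stats::runif(n) < 0.80, 0L,
                         stats::rpois(n, 0.7)), 4L)

  # shared per-subject perfusion factor induces cross-measure correlation
  u <- stats::rnorm(n)
  rho <- config$cbf_cor
  cbf <- sapply(cbf_measures, function(m) {
    config$cbf_means[[m]] + config$cbf_sds[[m]] *
      (rho * u + sqrt(1 - rho^2) * stats::rnorm(n))
  })
  colnames(cbf) <- paste0("cbf_", cbf_measures)

  z <- standardize_invert(cbf[, paste0("cbf_", config$cbf_measure)])

  b0 <- stats::rnorm(n, 0, config$sd_random_intercept)
  b1 <- stats::rnorm(n, 0, config$sd_random_slope)
  vr <- config$visit_count_range
  nvis <- vr[1] + sample.int(vr[2] - vr[1] + 1L, n, replace = TRUE) - 1L

  cov_term <- rep(0, n)
  if (length(config$covariate_effects)) {
    covs <- data.frame(age_years = age, sex = sex, education = education,
                       ngmv_ml = ngmv, mta = mta, wmh_fazekas = wmh,
                       n_microbleeds = microbleeds, n_lacunes = lacunes)
    for (nm in names(config$covariate_effects)) {
      if (!nm %in% names(covs))
        stop("unknown covariate in covariate_effects: ", nm)
      cov_term <- cov_term + config$covariate_effects[[nm]] * covs[[nm]]
    }
  }

  rows <- lapply(seq_len(n), function(i) {
    gaps <- stats::runif(nvis[i] - 1, 0.7, 1.3) * config$mean_visit_interval_years
    t_i <- cumsum(c(0, gaps))
    mmse <- config$effect_baseline + b0[i] +
      (config$effect_time + b1[i]) * t_i +
      config$effect_cbf * z[i] +
      config$effect_cbf_time * z[i] * t_i +
      cov_term[i] +
      stats::rnorm(nvis[i], 0, config$sd_residual)
    if (config$clamp_mmse) mmse <- pmin(pmax(round(mmse), 0), 30)
    data.frame(subject_id = sprintf("S%03d", i),
               visit = seq_len(nvis[i]),
               visit_time_years = t_i,
               mmse = mmse,
               age_years = age[i], sex = sex[i], education = education[i],
               ngmv_ml = ngmv[i], mta = mta[i], wmh_fazekas = wmh[i],
               n_microbleeds = microbleeds[i], n_lacunes = lacunes[i])
  })
  out <- do.call(rbind, rows)
  idx <- rep(seq_len(n), nvis)
  out <- cbind(out, as.data.frame(cbf)[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}
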