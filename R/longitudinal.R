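#' Apply the longitudinal inclusion filter
#'
#' Retains subjects with at least `min_visits` non-missing MMSE scores
#' spread over at least `min_span_years` of follow-up (last minus first
#' visit time), the usual entry criterion for decline analyses. Counts of
#' included and excluded subjects are reported via `message()`.
#'
#' @param cohort Long-format cohort `data.frame` with `subject_id`,
#'   `visit_time_years` and `mmse` columns.
#' @param min_visits Minimum number of MMSE scores (default 2).
#' @param min_span_years Minimum follow-up span in years (default 1).
#' @return The filtered cohort, same columns.
#' @export
apply_inclusion <- function(cohort, min_visits = 2, min_span_years = 1) {
  .check_cohort(cohort)
  keep_rows <- !is.na(cohort$mmse)
  d <- cohort[keep_rows, , drop = FALSE]
  span <- tapply(d$visit_time_years, d$subject_id, function(t) diff(range(t)))
  nvis <- tapply(d$mmse, d$subject_id, length)
  ok <- names(span)[nvis >= min_visits & span >= min_span_years]
  out <- cohort[cohort$subject_id %in% ok, , drop = FALSE]
  n_all <- length(unique(cohort$subject_id))
  message(sprintf("inclusion filter (>= %d MMSE over >= %g y): %d of %d subjects retained",
                  min_visits, min_span_years, length(ok), n_all))
  if (nrow(out) == 0)
    stop(sprintf("no subject satisfies the inclusion filter (>= %d MMSE scores over >= %g year(s))",
                 min_visits, min_span_years))
  rownames(out) <- NULL
  out
}

#' Standardize and invert a CBF measure
#'
#' Maps per-subject baseline CBF to z-scores per standard-deviation
#' *decrease*: `z = (mean(x) - x) / sd(x)` with the sample SD (n - 1
#' denominator). The output has mean 0 and SD 1, and a higher z means
#' lower perfusion, so negative regression coefficients read "worse
#' perfusion, worse outcome".
#'
#' @param x Numeric vector of per-subject baseline CBF values.
#' @param invert If `FALSE`, return ordinary z-scores `(x - mean) / sd`.
#' @return Numeric vector of z-scores.
#' @export
standardize_invert <- function(x, invert = TRUE) {
  x <- as.numeric(x)
  if (length(unique(x[!is.na(x)])) < 2)
    stop("need at least two distinct values to standardize")
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero standard deviation")
  z <- (x - mean(x, na.rm = TRUE)) / s
  if (invert) -z else z
}

.model_covariates <- function(model, pvc) {
  model <- as.character(model)
  covs <- switch(model,
                 "0" = character(0),
                 "1" = c("age_years", "sex", "education"),
                 "2" = c("age_years", "sex", "education", "ngmv_ml", "mta",
                         "wmh_fazekas", "n_microbleeds", "n_lacunes"),
                 stop("model must be 0 (unadjusted), 1, or 2"))
  # PVC cortical CBF is itself GM-volume-normalized, so the gray-matter
  # volume covariate is dropped from model 2 in PVC analyses
  if (pvc && model == "2") covs <- setdiff(covs, "ngmv_ml")
  covs
}

.check_cohort <- function(cohort) {
  need <- c("subject_id", "visit_time_years", "mmse")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

.cbf_column <- function(measure, pvc) {
  measure <- match.arg(measure, c("whole_brain", asl_regions))
  if (pvc) {
    if (measure == "whole_brain") "cbf_pvc_cortical"
    else paste0("cbf_pvc_", measure)
  } else paste0("cbf_", measure)
}

.empty_lmm_result <- function(measure, model, pvc, reml, msg) {
  structure(list(beta = NULL, se = NULL, p = NULL, varcomp = NULL,
                 n_subjects = 0L, n_observations = 0L,
                 converged = FALSE, singular = NA,
                 measure = measure, model = model, pvc = pvc,
                 reml = reml, message = msg),
            class = "lmm_result")
}

# fit a random-intercept/random-slope model and package the result
.fit_rirs <- function(data, fixed_rhs, measure, model, pvc, reml) {
  fml <- stats::as.formula(paste("mmse ~", fixed_rhs,
                                 "+ (1 + visit_time_years | subject_id)"))
  warn <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(fml, data = data, REML = reml,
                 control = lme4::lmerControl(calc.derivs = TRUE)),
      error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (inherits(fit, "error"))
    return(.empty_lmm_result(measure, model, pvc, reml, conditionMessage(fit)))

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  p <- 2 * stats::pnorm(-abs(beta / se))
  vc <- lme4::VarCorr(fit)$subject_id
  varcomp <- c(var_intercept = unname(vc[1, 1]),
               var_slope = unname(vc[2, 2]),
               cov_intercept_slope = unname(vc[1, 2]),
               var_residual = stats::sigma(fit)^2)
  opt_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  lme4_msgs <- fit@optinfo$conv$lme4$messages
  structure(list(beta = beta, se = se, p = p, varcomp = varcomp,
                 n_subjects = length(unique(data$subject_id)),
                 n_observations = nrow(data),
                 converged = opt_ok && is.null(lme4_msgs),
                 singular = lme4::isSingular(fit),
                 measure = measure, model = model, pvc = pvc, reml = reml,
                 formula = paste(deparse(fml), collapse = ""),
                 warnings = warn, fit = fit),
            class = "lmm_result")
}

#' Mixed model of MMSE decline on baseline CBF
#'
#' Fits the longitudinal analysis model: a linear mixed model of all MMSE
#' scores on standardized-and-inverted baseline CBF (`cbf`), time in years
#' (`time`), their interaction, and model covariates, with a per-subject
#' random intercept and random slope on time (unstructured 2x2
#' random-effects covariance). The `cbf` main effect estimates the
#' baseline MMSE difference per SD decrease in CBF; the `cbf:time`
#' interaction estimates the additional annual MMSE change per SD
#' decrease. Model 1 adjusts for age, sex and education; model 2
#' additionally for normalized gray matter volume, medial temporal
#' atrophy, white-matter hyperintensities, microbleeds and lacunes (the
#' volume term is dropped in PVC analyses); model 0 is unadjusted.
#'
#' Standardization of the CBF measure uses the analysis sample actually
#' fitted (after inclusion filtering and complete-case covariate
#' handling). Subjects with missing covariates are dropped with a message.
#' Inference is by Wald tests against a normal reference; non-convergence
#' is flagged in the result, never raised.
#'
#' @param cohort Filtered cohort table (see [apply_inclusion()]).
#' @param measure One of `"whole_brain"` or the five regions in
#'   [asl_regions].
#' @param pvc Use the PVC cortical counterpart of the measure?
#' @param model Covariate set: 0 (unadjusted), 1, or 2.
#' @param reml Use REML (default) or ML.
#' @param invert Analyse per SD *decrease* (default, the clinical
#'   convention "higher is worse"); `FALSE` flips every CBF coefficient's
#'   sign.
#' @return An object of class `lmm_result` with fields `beta`, `se`, `p`,
#'   `varcomp` (random-intercept/slope variances, their covariance, and
#'   residual variance), `n_subjects`, `n_observations`, `converged`,
#'   `singular`.
#' @export
fit_lmm <- function(cohort, measure = "whole_brain", pvc = FALSE,
                    model = 1, reml = TRUE, invert = TRUE) {
  .check_cohort(cohort)
  col <- .cbf_column(measure, pvc)
  if (!col %in% names(cohort))
    stop("cohort table has no column ", col)
  covs <- .model_covariates(model, pvc)
  miss_cov <- setdiff(covs, names(cohort))
  if (length(miss_cov))
    stop("cohort table is missing covariate column(s): ",
         paste(miss_cov, collapse = ", "))

  d <- cohort[, c("subject_id", "visit_time_years", "mmse", col, covs),
              drop = FALSE]
  names(d)[4] <- "cbf_raw"
  cc <- stats::complete.cases(d)
  dropped <- unique(d$subject_id[!cc])
  d <- d[cc, , drop = FALSE]
  if (length(dropped))
    message(sprintf("dropped %d subject-visit row(s) from %d subject(s) with missing values (complete-case)",
                    sum(!cc), length(dropped)))
  if (length(unique(d$subject_id)) < 4)
    return(.empty_lmm_result(measure, model, pvc, reml,
                             "fewer than 4 complete-case subjects"))

  # standardize on the analysis sample: one baseline value per subject
  first <- !duplicated(d$subject_id)
  zsub <- standardize_invert(d$cbf_raw[first], invert = invert)
  names(zsub) <- d$subject_id[first]
  d$cbf <- unname(zsub[d$subject_id])

  rhs <- paste(c("cbf", "visit_time_years", "cbf:visit_time_years", covs),
               collapse = " + ")
  res <- .fit_rirs(d, rhs, measure, model, pvc, reml)
  if (!is.null(res$beta)) {
    nm <- names(res$beta)
    nm[nm == "visit_time_years"] <- "time"
    nm[nm == "cbf:visit_time_years"] <- "cbf:time"
    names(res$beta) <- names(res$se) <- names(res$p) <- nm
  }
  res
}

#' Unadjusted annual change in MMSE
#'
#' Fits the random-intercept/random-slope model with time as the only
#' fixed effect; the `time` coefficient is the unadjusted mean annual
#' change in MMSE across the sample.
#'
#' @param cohort Filtered cohort table.
#' @param reml Use REML (default) or ML.
#' @return An `lmm_result` (see [fit_lmm()]).
#' @export
annual_change <- function(cohort, reml = TRUE) {
  .check_cohort(cohort)
  d <- cohort[stats::complete.cases(cohort[, c("subject_id", "visit_time_years", "mmse")]),
              c("subject_id", "visit_time_years", "mmse"), drop = FALSE]
  res <- .fit_rirs(d, "visit_time_years", measure = "time_only",
                   model = "unadjusted", pvc = FALSE, reml = reml)
  if (!is.null(res$beta)) {
    nm <- names(res$beta)
    nm[nm == "visit_time_years"] <- "time"
    names(res$beta) <- names(res$se) <- names(res$p) <- nm
  }
  res
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> measure=%s model=%s %s (%s)\n", x$measure,
              x$model, if (isTRUE(x$pvc)) "PVC" else "uncorrected",
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (is.null(x$beta)) {
    cat("  no fit:", x$message, "\n")
    return(invisible(x))
  }
  tab <- data.frame(beta = x$beta, se = x$se, p = x$p)
  print(round(tab, 4))
  cat(sprintf("  subjects %d, observations %d; var(b0)=%.3f var(b1)=%.3f resid=%.3f\n",
              x$n_subjects, x$n_observations, x$varcomp["var_intercept"],
              x$varcomp["var_slope"], x$varcomp["var_residual"]))
  invisible(x)
}
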