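.fmt_beta_se <- function(beta, se, p, p_star = 0.05, p_trend = 0.06) {
  if (is.na(beta)) return("")
  mark <- if (!is.na(p) && p <= p_star) "*"
          else if (!is.na(p) && p <= p_trend) "¥" else ""
  sprintf("%.2f ± %.2f%s", beta, se, mark)
}

#' Cohort-characteristics and model-results tables
#'
#' Assembles the two standard reporting tables of a longitudinal CBF
#' study. The cohort table gives demographics, MRI characteristics and
#' perfusion values as mean +/- SD or median (range). The results grid has
#' one row per CBF measure and, for each covariate model, the estimated
#' baseline MMSE effect (the `cbf` main effect) and the estimated annual
#' change effect (the `cbf:time` interaction), formatted as "beta +/- SE"
#' with `*` at p <= `p_star` and a trend mark at p <= `p_trend`. Missing
#' cells stay empty; nothing is imputed.
#'
#' @param results List of [fit_lmm()] results (any order; rows and columns
#'   are organized from each result's `measure`, `model` and `pvc` fields).
#' @param cohort Optional cohort table for the characteristics summary.
#' @param p_star Significance threshold for the star mark (default 0.05).
#' @param p_trend Threshold for the trend mark (default 0.06).
#' @return A list with `cohort_summary` (a `data.frame`, `NULL` if no
#'   cohort given) and `results_grid` (a `data.frame` with one row per
#'   measure x correction and formatted columns per model).
#' @export
report_tables <- function(results, cohort = NULL, p_star = 0.05,
                          p_trend = 0.06) {
  stopifnot(is.list(results))
  results <- Filter(function(r) inherits(r, "lmm_result") && !is.null(r$beta),
                    results)

  models <- sort(unique(vapply(results, function(r) as.character(r$model),
                               "")))
  if (!length(models)) models <- character(0)
  cols <- c("measure", "correction",
            as.vector(t(outer(paste0("model", models),
                              c("baseline_mmse", "annual_change"),
                              paste, sep = "_"))))
  grid <- data.frame(matrix(character(0), nrow = 0, ncol = length(cols),
                            dimnames = list(NULL, cols)),
                     stringsAsFactors = FALSE, check.names = FALSE)

  key <- vapply(results, function(r)
    paste(r$measure, if (isTRUE(r$pvc)) "PVC" else "uncorrected"), "")
  for (k in unique(key)) {
    sub <- results[key == k]
    row <- stats::setNames(as.list(rep("", length(cols))), cols)
    row$measure <- sub[[1]]$measure
    row$correction <- if (isTRUE(sub[[1]]$pvc)) "PVC" else "uncorrected"
    for (r in sub) {
      m <- as.character(r$model)
      if ("cbf" %in% names(r$beta))
        row[[paste0("model", m, "_baseline_mmse")]] <-
          .fmt_beta_se(r$beta["cbf"], r$se["cbf"], r$p["cbf"],
                       p_star, p_trend)
      if ("cbf:time" %in% names(r$beta))
        row[[paste0("model", m, "_annual_change")]] <-
          .fmt_beta_se(r$beta["cbf:time"], r$se["cbf:time"],
                       r$p["cbf:time"], p_star, p_trend)
    }
    grid <- rbind(grid, as.data.frame(row, stringsAsFactors = FALSE,
                                      check.names = FALSE))
  }

  cohort_summary <- NULL
  if (!is.null(cohort)) {
    base <- cohort[!duplicated(cohort$subject_id), , drop = FALSE]
    bl <- cohort[cohort$visit_time_years == 0, , drop = FALSE]
    fu <- tapply(cohort$visit_time_years, cohort$subject_id, max)
    nv <- tapply(cohort$mmse, cohort$subject_id, function(x) sum(!is.na(x)))
    msd <- function(x) sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE),
                               stats::sd(x, na.rm = TRUE))
    mrng <- function(x) sprintf("%g (%g - %g)", stats::median(x, na.rm = TRUE),
                                min(x, na.rm = TRUE), max(x, na.rm = TRUE))
    rows <- list(
      c("n", as.character(nrow(base))),
      c("Age (years)", msd(base$age_years)),
      c("Female sex, n (%)", sprintf("%d (%.0f %%)", sum(base$sex == 1),
                                     100 * mean(base$sex == 1))),
      c("Follow-up time (years)", msd(as.numeric(fu))),
      c("Level of education (Verhage scale)", msd(base$education)),
      c("Baseline MMSE score", msd(bl$mmse)),
      c("Number of MMSEs, median (range)", mrng(as.numeric(nv))),
      c("Normalized gray matter volume (ml)", msd(base$ngmv_ml)),
      c("Medial temporal lobe atrophy, median (range)", mrng(base$mta)),
      c("White matter hyperintensities, median (range)",
        mrng(base$wmh_fazekas)),
      c("Microbleeds, median (range)", mrng(base$n_microbleeds)),
      c("Lacunes, median (range)", mrng(base$n_lacunes)))
    for (m in cbf_measures) {
      col <- paste0("cbf_", m)
      if (col %in% names(base))
        rows <- c(rows, list(c(sprintf("CBF %s (mL/100 g/min)", m),
                               msd(base[[col]]))))
    }
    cohort_summary <- data.frame(characteristic = vapply(rows, `[`, "", 1),
                                 value = vapply(rows, `[`, "", 2),
                                 stringsAsFactors = FALSE)
  }

  list(cohort_summary = cohort_summary, results_grid = grid)
}

#' Flatten fitted models into a long results table
#'
#' One row per fixed effect per model: convenient machine-readable output
#' alongside the formatted grid of [report_tables()].
#'
#' @param results List of `lmm_result` objects.
#' @return A `data.frame` with columns `measure`, `correction`, `model`,
#'   `term`, `beta`, `se`, `p`, `n_subjects`, `n_observations`,
#'   `converged`.
#' @export
results_long <- function(results) {
  rows <- lapply(results, function(r) {
    if (!inherits(r, "lmm_result") || is.null(r$beta)) return(NULL)
    data.frame(measure = r$measure,
               correction = if (isTRUE(r$pvc)) "PVC" else "uncorrected",
               model = as.character(r$model),
               term = names(r$beta),
               beta = unname(r$beta), se = unname(r$se), p = unname(r$p),
               n_subjects = r$n_subjects,
               n_observations = r$n_observations,
               converged = r$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(measure = character(0), correction = character(0),
                      model = character(0), term = character(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      n_subjects = integer(0), n_observations = integer(0),
                      converged = logical(0))
  rownames(out) <- NULL
  out
}
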