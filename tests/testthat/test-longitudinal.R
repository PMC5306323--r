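test_that("inclusion filter keeps exactly the rule-satisfying subjects", {
  fx <- inclusion_fixture()
  kept <- suppressMessages(apply_inclusion(fx))
  # >= 2 MMSE scores over >= 1 year: the exact-year boundary is included,
  # a missing MMSE does not count as a score
  expect_setequal(unique(kept$subject_id),
                  c("exact_year", "long_span"))
  expect_error(suppressMessages(
    apply_inclusion(fx, min_span_years = 100)), "inclusion")
  expect_error(apply_inclusion(data.frame(subject_id = 1)),
               "visit_time_years")
})

test_that("standardize_invert produces inverted unit-variance z-scores", {
  expect_equal(standardize_invert(c(1, 2, 3)), c(1, 0, -1))
  set.seed(12)
  x <- rnorm(50, 30, 6)
  z <- standardize_invert(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_true(all(order(z) == order(-x)))   # higher z = lower perfusion
  expect_equal(standardize_invert(x, invert = FALSE), -z)
  expect_error(standardize_invert(c(2, 2, 2)), "distinct")
})

test_that("noise-free cohorts reproduce the generating coefficients exactly", {
  cfg <- cohort_config(n_subjects = 20, effect_cbf = 0, effect_cbf_time = 0,
                       sd_random_intercept = 0, sd_random_slope = 0,
                       sd_residual = 0, visit_count_range = c(3, 5), seed = 6)
  co <- suppressMessages(apply_inclusion(simulate_cohort(cfg)))
  a <- annual_change(co)
  expect_equal(unname(a$beta["(Intercept)"]), 22, tolerance = 1e-8)
  expect_equal(unname(a$beta["time"]), -2.11, tolerance = 1e-8)
  expect_lt(a$varcomp[["var_residual"]], 1e-8)
})

test_that("shifting all scores by a constant moves only the intercept", {
  co <- suppressMessages(apply_inclusion(
    simulate_cohort(cohort_config(n_subjects = 40, seed = 21))))
  a1 <- annual_change(co)
  co2 <- co
  co2$mmse <- co2$mmse + 5
  a2 <- annual_change(co2)
  expect_equal(unname(a2$beta["(Intercept)"] - a1$beta["(Intercept)"]), 5,
               tolerance = 1e-6)
  expect_equal(unname(a2$beta["time"]), unname(a1$beta["time"]),
               tolerance = 1e-6)
})

test_that("subject order does not affect the estimates", {
  co <- suppressMessages(apply_inclusion(
    simulate_cohort(cohort_config(n_subjects = 40, seed = 31))))
  f1 <- fit_lmm(co, "whole_brain", model = 1)
  set.seed(1)
  ids <- unique(co$subject_id)
  co2 <- do.call(rbind, split(co, co$subject_id)[sample(ids)])
  f2 <- fit_lmm(co2, "whole_brain", model = 1)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("turning off the inversion flips every CBF coefficient sign", {
  co <- suppressMessages(apply_inclusion(
    simulate_cohort(cohort_config(seed = 41))))
  f_inv <- fit_lmm(co, "parietal", model = 1, invert = TRUE)
  f_raw <- fit_lmm(co, "parietal", model = 1, invert = FALSE)
  expect_equal(unname(f_inv$beta["cbf"]), -unname(f_raw$beta["cbf"]),
               tolerance = 1e-6)
  expect_equal(unname(f_inv$beta["cbf:time"]),
               -unname(f_raw$beta["cbf:time"]), tolerance = 1e-6)
  expect_equal(unname(f_inv$beta["time"]), unname(f_raw$beta["time"]),
               tolerance = 1e-6)
})

test_that("null covariates leave the interaction essentially unchanged", {
  co <- suppressMessages(apply_inclusion(
    simulate_cohort(cohort_config(seed = 51))))
  f0 <- fit_lmm(co, "whole_brain", model = 0)
  f2 <- fit_lmm(co, "whole_brain", model = 2)
  expect_lt(abs(f0$beta["cbf:time"] - f2$beta["cbf:time"]),
            0.5 * f0$se["cbf:time"])
})

test_that("model 2 covariate sets follow the PVC convention", {
  co <- suppressMessages(apply_inclusion(
    simulate_cohort(cohort_config(seed = 61))))
  f_unc <- fit_lmm(co, "whole_brain", pvc = FALSE, model = 2)
  f_pvc <- fit_lmm(co, "whole_brain", pvc = TRUE, model = 2)
  expect_true("ngmv_ml" %in% names(f_unc$beta))
  expect_false("ngmv_ml" %in% names(f_pvc$beta))  # GM-normalized already
  expect_true(all(c("mta", "wmh_fazekas", "n_microbleeds", "n_lacunes")
                  %in% names(f_pvc$beta)))
})

test_that("subjects with missing covariates are dropped complete-case", {
  co <- suppressMessages(apply_inclusion(
    simulate_cohort(cohort_config(seed = 71))))
  victim <- unique(co$subject_id)[1]
  co$education[co$subject_id == victim] <- NA
  expect_message(f <- fit_lmm(co, "whole_brain", model = 1), "missing")
  f0 <- suppressMessages(fit_lmm(co, "whole_brain", model = 0))
  expect_equal(f0$n_subjects, f$n_subjects + 1)
})

test_that("non-convergence and degenerate samples are flagged, not thrown", {
  co <- suppressMessages(apply_inclusion(
    simulate_cohort(cohort_config(seed = 81))))
  tiny <- co[co$subject_id %in% unique(co$subject_id)[1:3], ]
  f <- fit_lmm(tiny, "whole_brain", model = 0)
  expect_s3_class(f, "lmm_result")
  expect_false(f$converged)
  expect_null(f$beta)
})

test_that("fitted variance components track the generating dispersions", {
  cfg <- cohort_config(n_subjects = 200, sd_random_intercept = 3,
                       sd_random_slope = 1.5, sd_residual = 1.5,
                       effect_cbf = 0, effect_cbf_time = 0,
                       visit_count_range = c(4, 8), seed = 91)
  co <- suppressMessages(apply_inclusion(simulate_cohort(cfg)))
  a <- annual_change(co)
  expect_lt(abs(a$varcomp[["var_intercept"]] - 9) / 9, 0.35)
  expect_lt(abs(a$varcomp[["var_slope"]] - 2.25) / 2.25, 0.35)
  expect_lt(abs(a$varcomp[["var_residual"]] - 2.25) / 2.25, 0.25)
})
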