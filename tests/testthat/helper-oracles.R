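# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written from first principles, not by
# calling the package's own implementation paths.

# log-space re-derivation of the single-compartment quantification factor
oracle_factor <- function(p) {
  p$unit_factor * exp(log(p$lam) + log1p(-exp(-p$t_sat / p$t1gm)) +
                        p$w / p$t1b - log(2) - log(p$t1b) -
                        log1p(-exp(-p$tau / p$t1b)) - log(p$eps))
}

random_kinetic_params <- function() {
  kinetic_params(w = runif(1, 0.5, 3), tau = runif(1, 0.5, 3),
                 lam = runif(1, 0.3, 1.2), eps = runif(1, 0.3, 1),
                 t1b = runif(1, 0.8, 2.5), t_sat = runif(1, 0.5, 3),
                 t1gm = runif(1, 0.8, 2), unit_factor = runif(1, 1, 10000))
}

# smooth random field in [lo, hi]: iterated 6-neighbour averaging
smooth_field <- function(d, lo = 0, hi = 1, iters = 6) {
  a <- array(runif(prod(d)), d)
  for (it in seq_len(iters)) {
    b <- a
    b[-1, , ] <- b[-1, , ] + a[-d[1], , ]
    b[-d[1], , ] <- b[-d[1], , ] + a[-1, , ]
    b[, -1, ] <- b[, -1, ] + a[, -d[2], ]
    b[, -d[2], ] <- b[, -d[2], ] + a[, -1, ]
    b[, , -1] <- b[, , -1] + a[, , -d[3]]
    b[, , -d[3]] <- b[, , -d[3]] + a[, , -1]
    a <- b / 7
  }
  rng <- range(a)
  lo + (hi - lo) * (a - rng[1]) / (rng[2] - rng[1])
}

# two smooth tissue-fraction fields with G + W <= 1
smooth_pve_pair <- function(d) {
  g <- smooth_field(d, 0.05, 0.9)
  w <- (1 - g) * smooth_field(d, 0.05, 0.9)
  list(G = g, W = w)
}

# brute-force weighted normal-equations PVC, one voxel at a time
brute_pvc <- function(values, G, W, fwhm_mm, voxel_size_mm,
                      truncation_sigmas = 3, cond_threshold = 1e8) {
  d <- dim(values)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- floor(truncation_sigmas * sigma_vox)
  k1 <- exp(-(-r[1]:r[1])^2 / (2 * sigma_vox[1]^2))
  k2 <- exp(-(-r[2]:r[2])^2 / (2 * sigma_vox[2]^2))
  k3 <- exp(-(-r[3]:r[3])^2 / (2 * sigma_vox[3]^2))
  gm <- array(NA_real_, d)
  wm <- array(NA_real_, d)
  rank2 <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    ii <- max(1, i - r[1]):min(d[1], i + r[1])
    jj <- max(1, j - r[2]):min(d[2], j + r[2])
    kk <- max(1, k - r[3]):min(d[3], k + r[3])
    wts <- outer(outer(k1[ii - i + r[1] + 1], k2[jj - j + r[2] + 1]),
                 k3[kk - k + r[3] + 1])
    g <- G[ii, jj, kk]; ww <- W[ii, jj, kk]; y <- values[ii, jj, kk]
    A <- matrix(c(sum(wts * g * g), sum(wts * g * ww),
                  sum(wts * g * ww), sum(wts * ww * ww)), 2, 2)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] > 0 && ev[1] / ev[2] <= cond_threshold) {
      b <- c(sum(wts * g * y), sum(wts * ww * y))
      sol <- solve(A, b)
      gm[i, j, k] <- sol[1]
      wm[i, j, k] <- sol[2]
      rank2[i, j, k] <- TRUE
    }
  }
  list(gm = gm, wm = wm, rank2 = rank2)
}

# phantom-truth stand-in with uniform ground truth, for noise-model tests
uniform_truth <- function(d = c(16, 16, 16), cbf = 40,
                          noise_sd_fraction = 0.5, seed = 1L,
                          voxel_size_mm = c(1.7, 1.7, 1.7)) {
  mask <- array(TRUE, d)
  structure(list(true_cbf = array(cbf, d), brain_mask = mask,
                 pve_gm = array(1, d), pve_wm = array(0, d),
                 pve_csf = array(0, d),
                 region_labels = array(1L, d),
                 voxel_size_mm = voxel_size_mm,
                 config = list(noise_sd_fraction = noise_sd_fraction,
                               seed = seed)),
            class = "phantom_truth")
}

# small phantom used across imaging tests (smallest grid that holds
# three compartments with >= 2-voxel transitions)
small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(20, 20, 20),
                 voxel_size_mm = c(3.4, 3.4, 3.4), ...)
}

# six-subject inclusion fixture covering each boundary case
inclusion_fixture <- function() {
  mk <- function(id, times, mmse = NULL) {
    if (is.null(mmse)) mmse <- rep(25, length(times))
    data.frame(subject_id = id, visit = seq_along(times),
               visit_time_years = times, mmse = mmse)
  }
  rbind(mk("one_visit", 0),
        mk("short_span", c(0, 0.5)),
        mk("exact_year", c(0, 1.0)),
        mk("long_span", c(0, 1.2)),
        mk("many_short", c(0, 0.4, 0.9)),
        mk("na_mmse", c(0, 1.5), mmse = c(24, NA)))
}

# per-subject OLS slopes, closed form
ols_slopes <- function(cohort) {
  vapply(split(cohort, cohort$subject_id), function(d) {
    t <- d$visit_time_years; y <- d$mmse
    sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  }, numeric(1))
}
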