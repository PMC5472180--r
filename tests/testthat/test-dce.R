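mk_series <- function(t, e, tissue = "nawm") {
  data.frame(tissue = tissue, time_min = t, enhancement = e, n_vox = 10L)
}

test_that("enhancement extraction: null, linear, and exclusion cases", {
  d <- c(5, 5, 5); nt <- 6
  t <- seq_len(nt) * 1.2
  lab <- array(0L, d); lab[1:40] <- 2L; lab[41:60] <- 4L
  base <- array(100, d)
  # S(t) = S_pre: all enhancements zero
  dce <- array(100, c(d, nt))
  e0 <- extract_enhancement(dce, lab, base, t)
  expect_true(all(abs(e0$enhancement) < 1e-14))
  # exact linear growth: enhancement = 0.001 t
  dce1 <- array(rep(100 * (1 + 0.001 * t), each = prod(d)), c(d, nt))
  e1 <- extract_enhancement(dce1, lab, base, t)
  expect_equal(e1$enhancement[e1$tissue == "nawm"], 0.001 * t,
               tolerance = 1e-12)
  expect_identical(unique(e1$n_vox[e1$tissue == "nawm"]), 40L)
  # non-positive baseline voxels are excluded and counted
  base2 <- base; base2[1:5] <- 0
  e2 <- extract_enhancement(dce1, lab, base2, t)
  expect_identical(attr(e2, "n_excluded"), 5L)
  expect_identical(unique(e2$n_vox[e2$tissue == "nawm"]), 35L)
  expect_error(extract_enhancement(dce1, array(0L, c(4, 5, 5)), base, t),
               "different grids")
})

test_that("slope estimator: exact linear, zero constant, window, guards", {
  t <- seq_len(20) * 1.2
  expect_equal(estimate_slope(mk_series(t, 0.002 * t)), 0.002,
               tolerance = 1e-12)
  expect_equal(estimate_slope(mk_series(t, rep(0.5, 20))), 0)
  # the default window drops the bolus frame: a spike there is ignored
  e <- 0.001 * t; e[1] <- 10
  expect_equal(estimate_slope(mk_series(t, e)), 0.001, tolerance = 1e-12)
  # explicit window
  expect_equal(estimate_slope(mk_series(t, 0.003 * t),
                              fit_window_min = c(6, 24)), 0.003,
               tolerance = 1e-12)
  expect_error(estimate_slope(mk_series(t[1:3], c(0, 1, 2))), "fewer than 3")
})

test_that("slope estimator is unbiased under additive noise", {
  set.seed(55)
  t <- seq_len(20) * 1.2
  true_slope <- 0.0004
  est <- replicate(400, estimate_slope(
    mk_series(t, true_slope * t + rnorm(20, 0, 0.002))))
  ci <- mean(est) + c(-1, 1) * qnorm(0.975) * sd(est) / sqrt(length(est))
  expect_gt(true_slope, ci[1]); expect_lt(true_slope, ci[2])
})

test_that("late-window slope is proportional to Ktrans (quadrature oracle)", {
  cfg <- cohort_config()
  t <- dce_times(cfg)
  ks <- c(0.5, 1, 2) * 1e-4
  slopes <- vapply(ks, function(k) {
    e <- quadrature_enhancement(k, 0, 900, 1000, cfg, t)
    estimate_slope(mk_series(t, e))
  }, numeric(1))
  # package forward model agrees with the independent quadrature oracle
  expect_equal(slopes[2], forward_slope(1e-4, 0, 900, 1000, cfg),
               tolerance = 1e-6)
  # proportionality in Ktrans, to within mild SPGR saturation (~1%)
  expect_equal(slopes[2] / slopes[1], 2, tolerance = 0.02)
  expect_equal(slopes[3] / slopes[1], 4, tolerance = 0.02)
})

test_that("VIF extraction: decline after peak, trivial masks, empty guard", {
  cfg <- cohort_config(seed = 12)
  anat <- generate_anatomy(cfg, 1, fazekas = 3)
  sim <- simulate_dce(anat, tissue_truth(cfg), cfg)
  sinus <- array(as.vector(anat) == 9L, dim(anat))
  vif <- extract_vif(sim, sinus)
  e <- vif$series$enhancement
  expect_true(all(diff(e[which.max(e):length(e)]) < 0))
  # tissue rises while the blood pool declines
  enh <- extract_enhancement(sim, anat)
  e_n <- enh$enhancement[enh$tissue == "nawm"]
  expect_true(all(diff(e_n[-1]) > 0))
  # one-voxel mask equals that voxel's enhancement
  one <- array(FALSE, dim(anat)); one[which(sinus)[1]] <- TRUE
  v1 <- extract_vif(sim, one)
  expect_equal(v1$series$enhancement, e, tolerance = 1e-12)
  expect_error(extract_vif(sim, array(FALSE, dim(anat))), "empty")
  # constant series: level equals the constant, slope zero
  cs <- mk_series(dce_times(cfg), rep(0.3, cfg$n_dynamics))
  expect_equal(estimate_slope(cs), 0)
})

test_that("slope table assembly: row counts, missing covariates, guards", {
  slopes <- expand.grid(patient = 1:2,
                        tissue = c("nawm", "dgm", "csf", "wmh",
                                   "index_infarct", "old_infarct"),
                        stringsAsFactors = FALSE)
  slopes$slope <- rnorm(12, 0, 1e-4)
  cov <- data.frame(patient = 1:2, age = c(60, 70), fazekas = c(2, NA))
  tab <- build_slope_table(slopes, cov)
  expect_identical(nrow(tab), 12L)
  expect_identical(attr(tab, "n_missing"), 6L)
  expect_true(all(is.na(tab$fazekas[tab$patient == 2])))
  expect_error(build_slope_table(rbind(slopes, slopes[1, ]), cov), "duplicate")
  # recount oracle on a generated cohort: one row per nonempty label
  co <- generate_cohort(cohort_config(n_patients = 20, seed = 31))
  st <- simulate_cohort_slopes(co)
  expect_identical(nrow(st), nrow(co$truth))
  # Fazekas-0 patients carry no WMH or contour rows but keep distant NAWM
  p0 <- co$covariates$patient[co$covariates$fazekas == 0]
  if (length(p0)) {
    t0 <- st$tissue[st$patient == p0[1]]
    expect_false(any(grepl("^(wmh|contour_)", t0)))
    expect_true("nawm_distant" %in% t0)
  }
})
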