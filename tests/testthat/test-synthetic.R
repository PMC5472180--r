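test_that("configuration invariants are enforced with the field named", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(n_dynamics = 2), "n_dynamics")
  expect_error(cohort_config(flip_angles_deg = c(12, 12)), "flip_angles_deg")
  expect_error(cohort_config(flip_angles_deg = c(0, 12)), "flip_angles_deg")
  expect_error(cohort_config(tr_ms = -1), "tr_ms")
  expect_error(cohort_config(voxel_size_mm = c(1, 1, 0)), "voxel_size_mm")
  expect_error(cohort_config(hematocrit = 1.2), "hematocrit")
  cfg <- cohort_config()
  expect_identical(cfg$n_dynamics, 20L)
  expect_equal(max(dce_times(cfg)), 24)
  expect_equal(cfg$flip_angles_deg, c(2, 12))
})

test_that("cohort generation: size guard, null effects, reproducibility", {
  expect_error(generate_cohort(cohort_config(n_patients = 1)), ">= 2")
  # all-zero effects and variance: per-tissue Ktrans identical across patients
  eff0 <- null_effects(patient_sd = 0, tissue_sd = 0, t10_jitter_sd = 0,
                       vif_amplitude_sd = 0)
  co <- generate_cohort(cohort_config(n_patients = 50, seed = 4), eff0)
  for (tis in c("nawm", "wmh", "csf")) {
    k <- co$truth$ktrans_true[co$truth$tissue == tis]
    expect_lt(diff(range(k)), 1e-15)
  }
  # identical seed + config: bit-identical cohort
  co1 <- generate_cohort(cohort_config(n_patients = 12, seed = 99))
  co2 <- generate_cohort(cohort_config(n_patients = 12, seed = 99))
  expect_identical(co1, co2)
  co3 <- generate_cohort(cohort_config(n_patients = 12, seed = 100))
  expect_false(identical(co3$covariates$age, co1$covariates$age))
})

test_that("generated truth recovers the nominal Fazekas effect by regression", {
  co <- generate_cohort(cohort_config(n_patients = 400, seed = 1))
  d <- merge(co$truth[co$truth$tissue == "nawm", ], co$covariates)
  d$age5 <- d$age / 5; d$lac <- as.numeric(d$subtype == "lacunar")
  fit <- lm(slope_true ~ fazekas + age5 + lac + hypertension + map +
              pulse_pressure + smoker, data = d)
  ci <- confint(fit)["fazekas", ]
  expect_gt(0.024e-3, ci[1]); expect_lt(0.024e-3, ci[2])
  expect_equal(unname(coef(fit)["fazekas"]), 0.024e-3, tolerance = 0.35)
})

test_that("anatomy: WMH scales with Fazekas, labels partition the brain", {
  cfg <- cohort_config()
  a0 <- generate_anatomy(cfg, 1, fazekas = 0, old_infarct = FALSE)
  leg <- bbb_label_legend()
  expect_identical(sum(a0 %in% leg[c("wmh_intense", "wmh_less")]), 0L)
  expect_gt(sum(a0 == leg[["nawm"]]), 0L)
  a1 <- generate_anatomy(cfg, 1, fazekas = 1)
  a6 <- generate_anatomy(cfg, 1, fazekas = 6)
  wmh_n <- function(a) sum(a %in% leg[c("wmh_intense", "wmh_less")])
  expect_gt(wmh_n(a6), wmh_n(a1))
  # every non-background voxel carries exactly one known label
  expect_true(all(as.vector(a6) %in% c(0L, unname(leg))))
  # grid too small for the required NAWM margin
  expect_error(generate_anatomy(cohort_config(grid_shape = c(24, 24, 24)),
                                1, fazekas = 6), "margin")
})

test_that("DCE simulator: constant when inert, sinus pass-through, WMH > NAWM", {
  cfg <- cohort_config(seed = 8)
  anat <- generate_anatomy(cfg, 1, fazekas = 4)
  # no transfer, no plasma volume: signal constant over time
  tt <- tissue_truth(cfg)
  tt$ktrans_per_min[] <- 0; tt$vp[] <- 0
  sim <- simulate_dce(anat, tt, cfg)
  v <- matrix(sim$dce, ncol = cfg$n_dynamics)
  nz <- as.vector(anat) > 0L & as.vector(anat) != 9L
  expect_lt(max(abs(v[nz, ] - v[nz, 1])), 1e-12)
  # sinus carries the blood-pool concentration through the SPGR equation
  tb <- tissue_truth(cfg)
  sim2 <- simulate_dce(anat, tb, cfg)
  sin_i <- which(as.vector(anat) == 9L)[1]
  s <- matrix(sim2$dce, ncol = cfg$n_dynamics)[sin_i, ]
  cb <- plasma_curve(dce_times(cfg), cfg) * (1 - cfg$hematocrit)
  row <- tb[tb$tissue == "sinus", ]
  r1 <- 1 / row$t10_ms + cfg$r1_relaxivity * cb * 1e-3
  expect_equal(s, spgr_signal(row$m0, 1 / r1, cfg$tr_ms,
                              cfg$flip_angles_deg[2]), tolerance = 1e-12)
  # higher Ktrans in WMH than NAWM: more late enhancement at every frame
  enh <- extract_enhancement(sim2, anat)
  e_w <- enh$enhancement[enh$tissue == "wmh_less"]
  e_n <- enh$enhancement[enh$tissue == "nawm"]
  expect_true(all((e_w - e_n)[-1] > 0))
})

test_that("cognition scores respect truncation and determinism", {
  cfg <- cohort_config(n_patients = 200, seed = 21)
  co <- generate_cohort(cfg)
  expect_true(all(co$covariates$acer_baseline >= 0 &
                    co$covariates$acer_baseline <= 100))
  expect_true(all(co$covariates$acer_1yr >= 0 & co$covariates$acer_1yr <= 100))
  # zero leakage coefficient and zero noise: 1-year score is a deterministic
  # function of baseline, NART and Fazekas only
  eff <- covariate_effects(beta_leak_on_acer_change = 0, acer_noise_sd = 0)
  set.seed(1)
  cov <- co$covariates
  g1 <- simulate_cognition(cov, wmh_leak = rnorm(nrow(cov)),
                           leak_patient = cov$patient, effects = eff)
  pred <- 4.5 + 0.95 * g1$acer_baseline + 0.05 * (cov$nart - 112) -
    0.3 * (cov$fazekas - 2.5)
  expect_equal(g1$acer_1yr, pmin(pmax(pred, 0), 100), tolerance = 1e-12)
})

test_that("forward-model consistency: slope order tracks any Ktrans order", {
  # random orderings painted on equal-relaxometry compartments; noiseless
  # voxel pipeline must recover the ordering of estimated slopes
  cfg <- cohort_config(seed = 14)
  anat <- generate_anatomy(cfg, 1, fazekas = 4)
  keep <- c("csf", "nawm", "dgm", "wmh_less", "wmh_intense", "index_infarct")
  set.seed(14)
  for (rep in 1:3) {
    kt <- sample(c(0.5, 1, 2, 4, 6, 8)) * 1e-4
    tt <- flat_truth(c(keep, "old_infarct", "sinus"), c(kt, 1e-4, 0))
    sim <- simulate_dce(anat, tt, cfg)
    enh <- extract_enhancement(sim, anat)
    sl <- vapply(keep, function(nm)
      estimate_slope(enh[enh$tissue == nm, ]), numeric(1))
    expect_identical(order(sl), order(kt))
  }
})
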