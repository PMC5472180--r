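test_that("model guards: patients, strata, rank, cognition coverage", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 2))
  st <- simulate_cohort_slopes(co)
  expect_error(fit_leakage_model(st[st$patient == 1, ]), "2 patients")
  expect_error(fit_leakage_model(st, tissues = "nawm"), "single_stratum")
  # a constant covariate is collinear with the tissue intercepts
  st2 <- st; st2$map <- 100
  expect_error(suppressMessages(fit_leakage_model(st2, focus = "fazekas")),
               "collinear")
  expect_error(fit_contour_gradient(st[!grepl("contour", st$tissue), ]),
               "contour levels")
  two <- st[st$tissue %in% c("contour_1", "contour_2"), ]
  expect_error(fit_contour_gradient(two), "contour levels")
  expect_error(fit_cognition_model(st[st$patient %in% 1:10, ]),
               "< 20 required")
  # single-stratum fit runs as declared OLS
  f1 <- fit_leakage_model(st, focus = "fazekas", tissues = "wmh",
                          single_stratum = TRUE)
  expect_identical(nrow(as.data.frame(f1)), 1L)
})

test_that("coefficient tables satisfy their structural invariants", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 5))
  st <- simulate_cohort_slopes(co)
  tab <- suppressMessages(fit_leakage_model(st))
  d <- as.data.frame(tab)
  expect_true(all(d$ci95_low <= d$estimate & d$estimate <= d$ci95_high))
  expect_false(anyDuplicated(d[, c("term", "stratum")]) > 0)
  expect_setequal(unique(d$term), c("age", "fazekas", "subtype"))
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
  expect_output(print(tab), "beta x 10\\^3")
})

test_that("coefficients are exactly equivariant under slope rescaling", {
  co <- generate_cohort(cohort_config(n_patients = 50, seed = 6))
  st <- simulate_cohort_slopes(co)
  f1 <- suppressMessages(fit_leakage_model(st, focus = "fazekas"))
  st2 <- st; st2$slope <- st2$slope * 1000
  f2 <- suppressMessages(fit_leakage_model(st2, focus = "fazekas"))
  expect_equal(f2$estimate, f1$estimate * 1000, tolerance = 1e-6)
  g1 <- suppressMessages(fit_contour_gradient(st))
  g2 <- suppressMessages(fit_contour_gradient(st2))
  expect_equal(g2$estimate, g1$estimate * 1000, tolerance = 1e-6)
})

test_that("null effects keep type-I error near nominal for tissue terms", {
  set.seed(77)
  eff0 <- null_effects()
  nrep <- 150
  rej <- matrix(NA, nrep, 6)
  for (r in seq_len(nrep)) {
    co <- generate_cohort(cohort_config(n_patients = 100, seed = 5000 + r),
                          eff0)
    st <- simulate_cohort_slopes(co)
    fl <- suppressMessages(fit_leakage_model(st, focus = "fazekas"))
    rej[r, ] <- fl$p_value[fl$term == "fazekas"] < 0.05
  }
  rate <- colMeans(rej, na.rm = TRUE)
  expect_true(all(rate <= 0.075 + 2 * sqrt(0.05 * 0.95 / nrep)))
  expect_lt(mean(rate), 0.075)
})

test_that("flat contour truth yields a gradient CI covering zero", {
  cfg <- cohort_config(n_patients = 120, seed = 9)
  truth0 <- tissue_truth(cfg, contour_gradient_slope = 0)
  co <- generate_cohort(cfg, covariate_effects(), truth = truth0)
  st <- simulate_cohort_slopes(co)
  g <- suppressMessages(fit_contour_gradient(st))
  expect_gt(0, g$ci95_low[1] - 1e-9)
  expect_lt(0, g$ci95_high[1] + 1e-9)
})

test_that("estimator RMSE shrinks with cohort size", {
  set.seed(101)
  rmse_at <- function(n, reps) {
    e <- replicate(reps, {
      co <- generate_cohort(cohort_config(n_patients = n,
                                          seed = sample.int(1e6, 1)))
      st <- simulate_cohort_slopes(co)
      fl <- suppressMessages(fit_leakage_model(st, focus = "fazekas"))
      fl$estimate[fl$term == "fazekas" & fl$stratum == "nawm"]
    })
    sqrt(mean((e - 0.024e-3)^2))
  }
  r50 <- rmse_at(50, 12); r200 <- rmse_at(200, 12); r800 <- rmse_at(800, 8)
  expect_lt(r200, r50)
  expect_lt(r800, r200)
})

test_that("two-stage and longitudinal routes agree on synthetic curves", {
  set.seed(19)
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 19))
  st <- simulate_cohort_slopes(co)
  st <- st[st$tissue %in% c("nawm", "wmh"), ]
  t <- dce_times(co$config)
  # build enhancement curves whose slope is the measured slope
  enh <- st[rep(seq_len(nrow(st)), each = length(t)), ]
  enh$time_min <- rep(t, nrow(st))
  enh$enhancement <- enh$slope * enh$time_min +
    rnorm(nrow(enh), 0, 1e-5)
  lon <- fit_leakage_longitudinal(enh, focus = "fazekas",
                                  adjust = c("age", "subtype"))
  for (tis in c("nawm", "wmh")) {
    two <- suppressMessages(
      fit_leakage_model(st[st$tissue == tis, ], focus = "fazekas",
                        adjust = c("age", "subtype"), tissues = tis,
                        single_stratum = TRUE))
    a <- two$estimate
    b <- lon$estimate[lon$stratum == tis]
    expect_identical(sign(a), sign(b))
    expect_lt(abs(b - a) / abs(a), 0.2)
  }
})

test_that("Fazekas-group profiles: grouping guard, null indistinguishability", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 23))
  st <- simulate_cohort_slopes(co)
  expect_error(profile_by_fazekas_group(st, groups = list(low = 0:2,
                                                          high = 5:6)),
               "cover")
  pr <- profile_by_fazekas_group(st, metrics = c("slope", "t10_ms"))
  expect_true(all(c("stratum", "metric", "group", "adj_mean") %in% names(pr)))
  # identical truth across groups: overlapping CIs in most contours
  eff0 <- null_effects()
  co0 <- generate_cohort(cohort_config(n_patients = 90, seed = 24), eff0)
  st0 <- simulate_cohort_slopes(co0)
  pr0 <- profile_by_fazekas_group(st0, metrics = "slope")
  cs <- pr0[grepl("^contour_", pr0$stratum), ]
  overlap <- vapply(split(cs, cs$stratum), function(g) {
    lo <- g[g$group == "low", ]; hi <- g[g$group == "high", ]
    nrow(lo) == 0 || nrow(hi) == 0 ||
      (lo$ci95_low <= hi$ci95_high && hi$ci95_low <= lo$ci95_high)
  }, logical(1))
  expect_gte(mean(overlap), 0.9)
})

test_that("subtype-specific cognition effects recover the sign pattern", {
  set.seed(31)
  eff <- covariate_effects(beta_leak_by_subtype = c(lacunar = -3.52,
                                                    cortical = 0.03))
  hit_lac <- hit_cor <- logical(12)
  for (r in seq_len(12)) {
    co <- generate_cohort(cohort_config(n_patients = 200, seed = 7000 + r),
                          eff)
    st <- simulate_cohort_slopes(co)
    fc <- fit_cognition_model(st, include_baseline = FALSE, by_subtype = TRUE)
    d <- as.data.frame(fc)
    lac <- d[d$term == "leak_z:lacunar", ]
    cor <- d[d$term == "leak_z:cortical", ]
    hit_lac[r] <- lac$ci95_high < 0            # CI excludes zero, negative
    hit_cor[r] <- cor$ci95_low < 0 & cor$ci95_high > 0  # CI covers zero
  }
  expect_gt(mean(hit_lac), 0.5)
  expect_gt(mean(hit_cor), 0.5)
})
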