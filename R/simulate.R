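#' Generate a synthetic patient cohort with known ground truth
#'
#' Draws clinical covariates from documented distributions (age uniform on
#' [34, 97]; 46\% lacunar stroke; Fazekas 0-6 weighted toward low-moderate
#' burden; hypertension 60\%; smoking 25\%; blood pressure and NART roughly
#' normal), then builds the per-patient, per-tissue leakage truth: the
#' biological enhancement slope of each compartment equals its tissue base
#' value plus the linear covariate effects in `effects`, a patient-level
#' random intercept shared across tissues, and a patient-by-tissue
#' deviation. Slopes are converted to Patlak transfer constants through the
#' forward-model sensitivity so that the printed effect sizes are exact on
#' the reported slope scale. Cognition (baseline and 1-year ACE-R) is
#' simulated from the standardized true WMH leakage via
#' [simulate_cognition()]. Patients with Fazekas 0 carry no WMH or contour
#' compartments.
#'
#' @param config a [cohort_config()] with `n_patients >= 2`.
#' @param effects a [covariate_effects()] object.
#' @param truth optional [tissue_truth()] table (default built from
#'   `config`).
#' @return object of class `bbb_cohort`: list with `config`, `effects`,
#'   `covariates` (one row per patient), `tissue_table` and `truth`
#'   (long patient x tissue table with `slope_true`, `ktrans_true`,
#'   `t10_true_ms`).
#' @export
generate_cohort <- function(config, effects = covariate_effects(),
                            truth = tissue_truth(config)) {
  validate_config(config)
  if (config$n_patients < 2L)
    stop("invalid configuration: field 'n_patients' must be >= 2 for a cohort")
  set.seed(config$seed)
  n <- config$n_patients
  cov <- data.frame(
    patient = seq_len(n),
    age = runif(n, 34, 97),
    fazekas = sample(0:6, n, replace = TRUE,
                     prob = c(0.08, 0.18, 0.22, 0.20, 0.16, 0.10, 0.06)),
    subtype = ifelse(rbinom(n, 1, 0.46) == 1, "lacunar", "cortical"),
    hypertension = rbinom(n, 1, 0.60),
    map = rnorm(n, 100, 12),
    pulse_pressure = rnorm(n, 60, 14),
    smoker = rbinom(n, 1, 0.25),
    nart = rnorm(n, 112, 9),
    vif_amplitude = pmax(rnorm(n, 1, effects$vif_amplitude_sd), 0.5),
    stringsAsFactors = FALSE
  )
  cov$has_old_infarct <- cov$patient %% 2L == 0L
  cohort_from_covariates(config, effects, cov, truth)
}

#' Build a cohort from explicitly supplied covariates
#'
#' The deterministic core of [generate_cohort()]: given a covariate table,
#' constructs the per-patient, per-tissue truth (biological slope, Ktrans,
#' tissue T1) and simulates cognition. Random components (patient
#' intercept, patient-by-tissue deviation, T1 jitter, cognition noise) are
#' drawn from the current RNG state and vanish when the corresponding
#' `effects` standard deviations are zero.
#'
#' @inheritParams generate_cohort
#' @param covariates data.frame with one row per patient and the columns of
#'   the standard covariate table (`patient`, `age`, `fazekas`, `subtype`,
#'   `hypertension`, `map`, `pulse_pressure`, `smoker`, `nart`,
#'   `vif_amplitude`, `has_old_infarct`).
#' @return a `bbb_cohort`.
#' @export
cohort_from_covariates <- function(config, effects, covariates,
                                   truth = tissue_truth(config)) {
  cov <- covariates
  n <- nrow(cov)
  tissues <- setdiff(truth$tissue, "sinus")
  grid <- expand.grid(patient = cov$patient, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$patient), ]
  ti <- match(grid$tissue, truth$tissue)
  ei <- match(effect_tissue(grid$tissue), effects$table$tissue)
  pi <- match(grid$patient, cov$patient)

  lac <- as.numeric(cov$subtype == "lacunar")
  xc <- cbind(
    age_per5 = (cov$age - .bbb_ref$age) / 5,
    fazekas = cov$fazekas - .bbb_ref$fazekas,
    lacunar = lac,
    hypertension = cov$hypertension,
    map = cov$map - .bbb_ref$map,
    pulse_pressure = cov$pulse_pressure - .bbb_ref$pulse_pressure,
    smoker = cov$smoker
  )
  # per-patient true tissue T1: base + Fazekas-linked water increase in WM
  # compartments + idiosyncratic patient deviation
  is_wm <- grepl("^(contour_|nawm|wmh)", grid$tissue)
  t10_true <- truth$t10_ms[ti] +
    ifelse(is_wm, effects$t10_per_fazekas_ms *
             (cov$fazekas[pi] - .bbb_ref$fazekas), 0) +
    rnorm(nrow(grid), 0, effects$t10_jitter_sd)
  t10_true <- pmax(t10_true, 300)
  x_t10 <- (t10_true - truth$t10_ms[ti]) / 1000  # seconds, vs tissue base

  beta <- as.matrix(effects$table[, colnames(xc)])
  lin <- rowSums(xc[pi, , drop = FALSE] * beta[ei, , drop = FALSE]) +
    effects$table$t10_per_s[ei] * x_t10
  u <- rnorm(n, 0, effects$patient_sd)
  eps <- rnorm(nrow(grid), 0, effects$tissue_sd)
  slope_true <- truth$slope_base[ti] + lin + u[pi] + eps

  base_off <- truth$slope_base[ti] - truth$kappa[ti] * truth$ktrans_per_min[ti]
  ktrans_true <- (slope_true - base_off) / truth$kappa[ti]

  tr <- data.frame(patient = grid$patient, tissue = grid$tissue,
                   slope_true = slope_true, ktrans_true = ktrans_true,
                   t10_true_ms = t10_true, stringsAsFactors = FALSE)
  # Fazekas-0 patients carry no WMH and hence no contours; the old-infarct
  # compartment exists only for patients with an old infarct
  no_wmh <- cov$patient[cov$fazekas == 0]
  drop <- (tr$patient %in% no_wmh & grepl("^(wmh|contour_)", tr$tissue)) |
    (tr$tissue == "old_infarct" &
       !cov$has_old_infarct[match(tr$patient, cov$patient)])
  tr <- tr[!drop, ]

  cog <- simulate_cognition(cov, wmh_leak = tr$slope_true[tr$tissue == "wmh"],
                            leak_patient = tr$patient[tr$tissue == "wmh"],
                            effects = effects)
  cov$acer_baseline <- cog$acer_baseline
  cov$acer_1yr <- cog$acer_1yr

  structure(list(config = config, effects = effects,
                 covariates = cov, tissue_table = truth, truth = tr),
            class = "bbb_cohort")
}

#' @export
print.bbb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d tissue compartments, seed %d\n",
              nrow(x$covariates), length(unique(x$truth$tissue)),
              x$config$seed))
  invisible(x)
}

#' Simulate cognition from WMH leakage
#'
#' Baseline ACE-R depends on age (negatively) and premorbid intelligence
#' (NART, positively). One-year ACE-R depends on baseline ACE-R, NART, WMH
#' burden and - the effect of interest - the standardized true WMH leakage
#' slope, with coefficient `effects$beta_leak_on_acer_change` (default
#' -1.89 ACE-R points per SD of leakage) or subtype-specific coefficients
#' if `effects$beta_leak_by_subtype` is set. Scores are truncated to
#' [0, 100]. Patients without WMH contribute at the cohort-mean leakage.
#'
#' @param covariates cohort covariate data.frame (needs `patient`, `age`,
#'   `nart`, `fazekas`, `subtype`).
#' @param wmh_leak true WMH leakage slopes for the patients in
#'   `leak_patient`.
#' @param leak_patient patient ids matching `wmh_leak`.
#' @param effects a [covariate_effects()] object.
#' @return data.frame with `acer_baseline` and `acer_1yr` (one row per
#'   patient in `covariates`).
#' @export
simulate_cognition <- function(covariates, wmh_leak, leak_patient, effects) {
  stopifnot(is.finite(effects$beta_leak_on_acer_change))
  n <- nrow(covariates)
  z <- rep(0, n)
  if (length(wmh_leak) > 1) {
    zl <- as.numeric(scale(wmh_leak))
    z[match(leak_patient, covariates$patient)] <- zl
  }
  # score location sits clear of the instrument ceiling so that the
  # linear generative model is faithful after [0, 100] truncation
  base <- 87 - 0.15 * (covariates$age - .bbb_ref$age) +
    0.25 * (covariates$nart - .bbb_ref$nart) + rnorm(n, 0, 3)
  base <- pmin(pmax(base, 0), 100)
  bl <- effects$beta_leak_on_acer_change
  beta_leak <- if (!is.null(effects$beta_leak_by_subtype)) {
    ifelse(covariates$subtype == "lacunar",
           effects$beta_leak_by_subtype[["lacunar"]],
           effects$beta_leak_by_subtype[["cortical"]])
  } else rep(bl, n)
  yr1 <- 4.5 + 0.95 * base + 0.05 * (covariates$nart - .bbb_ref$nart) -
    0.3 * (covariates$fazekas - .bbb_ref$fazekas) + beta_leak * z +
    rnorm(n, 0, effects$acer_noise_sd)
  data.frame(acer_baseline = base, acer_1yr = pmin(pmax(yr1, 0), 100))
}

#' Fast tissue-level measurement simulation of a cohort
#'
#' Produces the measured slope table of a cohort without voxel grids: for
#' every patient x compartment the noiseless mean enhancement curve is
#' evaluated through the same Patlak + spoiled-gradient-echo forward model
#' used for voxel simulation (scaled by the patient's bolus amplitude), the
#' default-window OLS slope is taken, and ROI-mean measurement noise is
#' added. This is the route used for replicate-heavy parameter-recovery
#' studies; the voxelwise route ([simulate_dce()] + the image pipeline)
#' measures the same quantities from full volumes.
#'
#' @param cohort a [generate_cohort()] result.
#' @return a long `SlopeRecord` data.frame: `patient`, `tissue`, `slope`,
#'   `sinus`, `t10_ms`, joined with the patient covariates (via
#'   [build_slope_table()]).
#' @export
simulate_cohort_slopes <- function(cohort) {
  cfg <- cohort$config
  eff <- cohort$effects
  tr <- cohort$truth
  tt <- cohort$tissue_table
  ti <- match(tr$tissue, tt$tissue)
  pi <- match(tr$patient, cohort$covariates$patient)
  amp <- cohort$covariates$vif_amplitude[pi]

  t <- dce_times(cfg)
  cp <- plasma_curve(t, cfg)      # nominal amplitude; scaled per patient
  ip <- plasma_curve_integral(t, cfg)
  conc <- (tr$ktrans_true %o% ip + tt$vp[ti] %o% cp) * amp
  t10 <- tr$t10_true_ms
  m0 <- tt$m0[ti]
  s0 <- spgr_signal(m0, t10, cfg$tr_ms, cfg$flip_angles_deg[2])
  r1 <- 1 / t10 + cfg$r1_relaxivity * conc * 1e-3
  s <- spgr_signal(m0, 1 / r1, cfg$tr_ms, cfg$flip_angles_deg[2])
  enh <- (s - s0) / s0
  win <- seq_along(t)[-1L]
  w <- t[win] - mean(t[win]); w <- w / sum(w^2)
  slope <- as.vector(enh[, win, drop = FALSE] %*% w) +
    rnorm(nrow(tr), 0, eff$measurement_sd)

  sinus <- vif_reference_level(cfg) * cohort$covariates$vif_amplitude
  slopes <- data.frame(patient = tr$patient, tissue = tr$tissue,
                       slope = slope,
                       sinus = sinus[pi],
                       t10_ms = tr$t10_true_ms +
                         rnorm(nrow(tr), 0, eff$t10_measure_sd),
                       stringsAsFactors = FALSE)
  build_slope_table(slopes, cohort$covariates)
}

#' Post-bolus blood-pool enhancement level
#'
#' The sagittal-sinus reference covariate: mean relative enhancement of the
#' blood pool over the post-bolus frames, from the forward model.
#'
#' @param config a [cohort_config()].
#' @param amplitude bolus amplitude multiplier.
#' @return scalar enhancement level.
#' @export
vif_reference_level <- function(config, amplitude = 1) {
  t <- dce_times(config)
  cb <- plasma_curve(t, config, amplitude) * (1 - config$hematocrit)
  t10 <- 1400; m0 <- 1100  # blood
  s0 <- spgr_signal(m0, t10, config$tr_ms, config$flip_angles_deg[2])
  r1 <- 1 / t10 + config$r1_relaxivity * cb * 1e-3
  s <- spgr_signal(m0, 1 / r1, config$tr_ms, config$flip_angles_deg[2])
  mean((s - s0) / s0)
}

#' Per-patient compartment truth for voxel simulation
#'
#' Extracts one patient's compartment parameter table (Ktrans from the
#' cohort truth; T1 including the patient's deviations; MD/FA with the
#' Fazekas-linked white matter modifiers) in the format [simulate_dce()]
#' and [simulate_dwi()] consume.
#'
#' @param cohort a [generate_cohort()] result.
#' @param patient patient id.
#' @return data.frame with columns `tissue`, `t10_ms`, `m0`,
#'   `ktrans_per_min`, `vp`, `md`, `fa`.
#' @export
patient_truth <- function(cohort, patient) {
  tt <- cohort$tissue_table
  tr <- cohort$truth[cohort$truth$patient == patient, ]
  cv <- cohort$covariates[cohort$covariates$patient == patient, ]
  if (!nrow(cv)) stop("unknown patient id: ", patient)
  eff <- cohort$effects
  out <- tt[, c("tissue", "t10_ms", "m0", "vp", "md", "fa")]
  i <- match(out$tissue, tr$tissue)
  have <- !is.na(i)
  out$ktrans_per_min <- ifelse(have, tr$ktrans_true[i], 0)
  out$t10_ms[have] <- tr$t10_true_ms[i[have]]
  dfz <- cv$fazekas - .bbb_ref$fazekas
  is_wm <- grepl("^(contour_|nawm|wmh)", out$tissue)
  out$md[is_wm] <- out$md[is_wm] + eff$md_per_fazekas * dfz
  out$fa[is_wm] <- pmin(pmax(out$fa[is_wm] + eff$fa_per_fazekas * dfz, 0.01), 0.99)
  out$ktrans_per_min[out$tissue == "sinus"] <- 0
  out
}

#' Replace NAWM labels by contour-resolved labels
#'
#' Computes the concentric contour rings on a generated anatomy and returns
#' a label map in which NAWM voxels carry their contour (or distant-NAWM)
#' code, so spatially graded truth can be painted onto the white matter.
#'
#' @param anatomy a [generate_anatomy()] label map.
#' @param n_contours,width_voxels,connectivity passed to [make_contours()].
#' @return integer label map.
#' @export
paint_contour_labels <- function(anatomy, n_contours = 10L, width_voxels = 2L,
                                 connectivity = 6L) {
  wmh <- label_mask(anatomy, c("wmh_intense", "wmh_less"), n_contours)
  nawm <- label_mask(anatomy, "nawm", n_contours)
  rings <- suppressWarnings(
    make_contours(wmh, nawm, n_contours, width_voxels, connectivity))
  lab <- array(as.vector(anatomy), dim(anatomy))
  sel <- nawm & rings > 0L
  lab[sel] <- rings[sel]
  lab
}

#' Simulate a DCE-MRI acquisition from labelled anatomy
#'
#' Forward model per compartment: Patlak tissue concentration
#' \eqn{C(t) = K^{trans} \int_0^t C_p + v_p C_p(t)} (sagittal-sinus voxels
#' carry the whole-blood concentration \eqn{(1-Hct) C_p} directly),
#' converted to signal through the spoiled-gradient-echo equation with
#' \eqn{1/T_1(t) = 1/T_{10} + r_1 C(t)}. Also emits the two pre-contrast
#' flip-angle volumes from the same T10/M0 truth. Negative concentrations
#' (possible when a covariate-extrapolated Ktrans is negative) are clipped
#' at zero and counted. Noise is Rician (Gaussian on the complex channels)
#' or Gaussian at the configured SNR, referenced to the mean pre-contrast
#' brain signal at the dynamic flip angle.
#'
#' @param anatomy integer label map (e.g. [paint_contour_labels()]).
#' @param truth compartment parameter table (see [patient_truth()] /
#'   [tissue_truth()]); every label present in `anatomy` must have a row.
#' @param config a [cohort_config()].
#' @param amplitude bolus amplitude multiplier for this patient.
#' @return list of class `bbb_dce`: `dce` (4D array x,y,z,t), `times_min`,
#'   `pre_low`, `pre_high` (pre-contrast flip-angle volumes), `baseline`
#'   (pre-contrast volume at the dynamic flip angle), `n_clipped`.
#' @export
simulate_dce <- function(anatomy, truth, config, amplitude = 1) {
  t <- dce_times(config)
  nt <- length(t)
  d <- dim(anatomy)
  labv <- as.vector(anatomy)
  legend <- bbb_label_legend(sum(grepl("^contour_", truth$tissue)) %||% 10L)
  present <- sort(unique(labv[labv > 0L]))
  name_of <- setNames(names(legend), legend)
  miss <- setdiff(as.character(present), names(name_of))
  if (length(miss)) stop("labels without legend entry: ", paste(miss, collapse = ", "))
  need <- name_of[as.character(present)]
  absent <- setdiff(need, truth$tissue)
  if (length(absent)) stop("no truth parameters for compartment(s): ",
                           paste(absent, collapse = ", "))
  cp <- plasma_curve(t, config, amplitude)
  ip <- plasma_curve_integral(t, config, amplitude)
  n_clipped <- 0L
  sig <- matrix(0, length(labv), nt)
  pre_lo <- pre_hi <- base <- numeric(length(labv))
  for (nm in need) {
    row <- truth[truth$tissue == nm, ]
    conc <- if (nm == "sinus") (1 - config$hematocrit) * cp
            else row$ktrans_per_min * ip + row$vp * cp
    if (any(conc < 0)) { n_clipped <- n_clipped + 1L; conc <- pmax(conc, 0) }
    r1 <- 1 / row$t10_ms + config$r1_relaxivity * conc * 1e-3
    s <- spgr_signal(row$m0, 1 / r1, config$tr_ms, config$flip_angles_deg[2])
    vox <- labv == legend[[nm]]
    sig[vox, ] <- rep(s, each = sum(vox))
    pre_lo[vox] <- spgr_signal(row$m0, row$t10_ms, config$tr_ms,
                               config$flip_angles_deg[1])
    b <- spgr_signal(row$m0, row$t10_ms, config$tr_ms,
                     config$flip_angles_deg[2])
    pre_hi[vox] <- b
    base[vox] <- b
  }
  if (n_clipped > 0L)
    warning(sprintf("simulate_dce: negative concentrations clipped in %d compartment(s)",
                    n_clipped))
  if (is.finite(config$snr)) {
    sigma <- mean(base[labv > 0L]) / config$snr
    sig <- add_mri_noise(sig, sigma, config$noise_model)
    pre_lo <- add_mri_noise(pre_lo, sigma, config$noise_model)
    pre_hi <- add_mri_noise(pre_hi, sigma, config$noise_model)
    base <- add_mri_noise(base, sigma, config$noise_model)
  }
  structure(list(dce = array(sig, c(d, nt)), times_min = t,
                 pre_low = array(pre_lo, d), pre_high = array(pre_hi, d),
                 baseline = array(base, d), n_clipped = n_clipped),
            class = "bbb_dce")
}

add_mri_noise <- function(x, sigma, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (model == "gaussian") return(x + rnorm(length(x), 0, sigma))
  out <- sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
  dim(out) <- dim(x)
  out
}

#' Simulate diffusion-weighted volumes from labelled anatomy
#'
#' Builds an axisymmetric diffusion tensor per compartment matching its
#' target MD and FA exactly (see [axisym_tensor()]) and evaluates
#' \eqn{S = S_0 \exp(-b\, g^T D g)} per direction. Requires at least six
#' non-collinear gradient directions plus one b=0 volume.
#'
#' @param anatomy integer label map.
#' @param truth compartment parameter table with `md` (1e-3 mm^2/s), `fa`,
#'   `m0`.
#' @param bvals numeric b-values (s/mm^2), at least one zero.
#' @param bvecs 3 x n or n x 3 unit gradient directions.
#' @param snr optional SNR for Rician noise (Inf = noiseless).
#' @param axis principal diffusion axis applied to anisotropic compartments.
#' @return list of class `bbb_dwi`: `dwi` (4D array), `bvals`, `bvecs`
#'   (3 x n).
#' @export
simulate_dwi <- function(anatomy, truth, bvals, bvecs, snr = Inf,
                         axis = c(1, 0, 0)) {
  bvecs <- as_bvec_matrix(bvecs, length(bvals))
  dw <- bvals > 0
  if (sum(!dw) < 1L) stop("at least one b=0 volume is required")
  g <- t(bvecs[, dw, drop = FALSE])
  if (qr(g)$rank < 3L || sum(dw) < 6L)
    stop("at least 6 non-collinear diffusion directions are required")
  bt <- btensor_design(bvals, bvecs)
  if (qr(bt[dw, , drop = FALSE])$rank < 6L)
    stop("gradient scheme does not determine a tensor: ",
         "6 independent directions are required")
  d <- dim(anatomy)
  labv <- as.vector(anatomy)
  legend <- bbb_label_legend(10L)
  present <- sort(unique(labv[labv > 0L]))
  name_of <- setNames(names(legend), legend)
  need <- name_of[as.character(present)]
  sig <- matrix(0, length(labv), length(bvals))
  for (nm in need) {
    row <- truth[truth$tissue == nm, ]
    if (!nrow(row)) stop("no truth parameters for compartment: ", nm)
    D <- axisym_tensor(row$md * 1e-3, row$fa, axis)
    s <- row$m0 * exp(-as.vector(bt %*% tensor_to_vec(D)))
    vox <- labv == legend[[nm]]
    sig[vox, ] <- rep(s, each = sum(vox))
  }
  if (is.finite(snr)) {
    sigma <- mean(sig[labv > 0L, !dw]) / snr
    sig <- add_mri_noise(sig, sigma, "rician")
  }
  structure(list(dwi = array(sig, c(d, length(bvals))), bvals = bvals,
                 bvecs = bvecs), class = "bbb_dwi")
}

#' Deterministic cohort preset for spatial-ordering checks
#'
#' A small cohort designed to expose the spatial and WMH-burden gradients
#' without sampling noise: covariates are identical across patients except
#' Fazekas score (one pair per burden group by default) and age (spread so
#' age adjustment is estimable), and every variance component of the
#' generator is zero. On this preset the recovered contour profiles of
#' leakage, MD, FA and T1 are deterministic functions of the truth tables,
#' so monotonicity toward the lesion and ordering across Fazekas groups
#' hold exactly.
#'
#' The default scores sample the three burden groups at 2, 4 and 6: below
#' a score of ~2 the per-tissue Fazekas coefficients imply WMH leakage at
#' or below the adjacent contour level (the lesion converges to NAWM as
#' burden vanishes), so strict monotonicity into the WMH is a
#' moderate-to-high-burden property.
#'
#' @param config a [cohort_config()]; `n_patients` is overridden by the
#'   length of `fazekas`.
#' @param fazekas Fazekas score per patient.
#' @param age age per patient (recycled).
#' @return a `bbb_cohort` with zero-variance effects.
#' @export
preset_ordering_cohort <- function(config, fazekas = c(2, 2, 4, 4, 6, 6),
                                   age = c(58, 74)) {
  n <- length(fazekas)
  config$n_patients <- as.integer(n)
  eff <- covariate_effects(patient_sd = 0, tissue_sd = 0, measurement_sd = 0,
                           vif_amplitude_sd = 0, t10_jitter_sd = 0,
                           t10_measure_sd = 0, acer_noise_sd = 0)
  cov <- data.frame(
    patient = seq_len(n), age = rep_len(age, n), fazekas = fazekas,
    subtype = "cortical", hypertension = 0L, map = 100, pulse_pressure = 60,
    smoker = 0L, nart = 112, vif_amplitude = 1, has_old_infarct = FALSE,
    stringsAsFactors = FALSE
  )
  set.seed(config$seed)
  cohort_from_covariates(config, eff, cov)
}

#' Default diffusion gradient scheme
#'
#' One b=0 volume plus `n_dir` directions at the given b-value: the classic
#' six-direction tensor scheme for the minimum case (a six-point golden
#' spiral does not determine the tensor), a golden-spiral spread otherwise.
#'
#' @param n_dir number of diffusion-weighted directions (>= 6).
#' @param b b-value in s/mm^2.
#' @return list with `bvals` and `bvecs` (3 x (n_dir + 1)).
#' @export
default_dwi_scheme <- function(n_dir = 12L, b = 1000) {
  stopifnot(n_dir >= 6L)
  g <- if (n_dir == 6L) {
    t(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
            c(1, -1, 0), c(1, 0, -1), c(0, 1, -1))) / sqrt(2)
  } else {
    i <- seq_len(n_dir) - 0.5
    phi <- acos(1 - 2 * i / n_dir)
    theta <- pi * (1 + sqrt(5)) * i
    rbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  list(bvals = c(0, rep(b, n_dir)), bvecs = cbind(c(0, 0, 0), g))
}
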