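#' Per-compartment ground-truth tissue parameters
#'
#' Builds the table of relaxometry, pharmacokinetic and diffusion parameters
#' that drives the synthetic cohort. Each compartment carries a pre-contrast
#' T1 (`t10_ms`), equilibrium signal (`m0`), Patlak transfer constant
#' (`ktrans_per_min`), plasma volume fraction (`vp`), mean diffusivity
#' (`md`, in 1e-3 mm^2/s) and fractional anisotropy (`fa`).
#'
#' The leakage preset is specified on the *enhancement-slope* scale - the
#' scale on which leakage is reported (slope of relative enhancement per
#' minute) - and converted to Ktrans via a per-compartment sensitivity
#' factor computed from the forward model (see [slope_ktrans_sensitivity()]).
#' The preset encodes the expected spatial gradient: leakage rises from
#' distant NAWM through the 10 contours (0.0099e-3 per contour step toward
#' the WMH) into less-intense and then intense WMH; MD and T1 rise and FA
#' falls along the same path; CSF and infarcts leak more than NAWM and deep
#' grey matter less.
#'
#' @param config a [cohort_config()].
#' @param slope_targets named numeric vector of target enhancement slopes
#'   (per minute) at reference covariates, overriding the preset per
#'   compartment.
#' @param contour_gradient_slope leakage increment per contour step toward
#'   the WMH edge, on the slope scale (default 0.0099e-3 per minute).
#' @param n_contours number of NAWM contour compartments.
#' @return data.frame of class `bbb_truth`, one row per compartment, with
#'   columns `tissue`, `t10_ms`, `m0`, `vp`, `md`, `fa`, `slope_base`,
#'   `kappa` (slope per unit Ktrans) and `ktrans_per_min`.
#' @export
tissue_truth <- function(config,
                         slope_targets = NULL,
                         contour_gradient_slope = 0.0099e-3,
                         n_contours = 10L) {
  cn <- contour_names(n_contours)
  k <- seq_len(n_contours)
  prox <- n_contours + 1L - k  # contour_1 is nearest the WMH edge
  tissue <- c("csf", "nawm", "nawm_distant", cn, "dgm", "wmh",
              "wmh_less", "wmh_intense", "index_infarct", "old_infarct",
              "sinus")
  # Relaxometry at 1.5 T; contour T1 rises toward the WMH edge.
  t10 <- c(csf = 3800, nawm = 720, nawm_distant = 700,
           setNames(700 + 6 * prox, cn), dgm = 1100, wmh = 1000,
           wmh_less = 950, wmh_intense = 1050,
           index_infarct = 1200, old_infarct = 1150, sinus = 1400)
  m0 <- c(csf = 1400, nawm = 1000, nawm_distant = 1000,
          setNames(rep(1000, n_contours), cn), dgm = 1050, wmh = 1025,
          wmh_less = 1020, wmh_intense = 1030,
          index_infarct = 1050, old_infarct = 1040, sinus = 1100)
  vp <- c(csf = 0, nawm = 0.008, nawm_distant = 0.008,
          setNames(rep(0.008, n_contours), cn), dgm = 0.015, wmh = 0.0055,
          wmh_less = 0.006, wmh_intense = 0.005,
          index_infarct = 0.01, old_infarct = 0.01, sinus = 1)
  md <- c(csf = 3.0, nawm = 0.76, nawm_distant = 0.75,
          setNames(0.75 + 0.010 * prox, cn), dgm = 0.80, wmh = 1.05,
          wmh_less = 1.00, wmh_intense = 1.15,
          index_infarct = 1.30, old_infarct = 1.25, sinus = 1.5)
  fa <- c(csf = 0.05, nawm = 0.44, nawm_distant = 0.45,
          setNames(0.45 - 0.010 * prox, cn), dgm = 0.15, wmh = 0.25,
          wmh_less = 0.28, wmh_intense = 0.20,
          index_infarct = 0.15, old_infarct = 0.16, sinus = 0.05)
  # Leakage preset on the enhancement-slope scale (per minute), at the
  # cohort reference covariates. Ordering follows the observed tissue
  # hierarchy: infarcts > CSF > intense WMH > less-intense WMH >
  # contour_1 > ... > contour_10 > distant NAWM > DGM.
  slope <- c(csf = 0.55e-3, nawm = 0.16e-3, nawm_distant = 0.15e-3,
             setNames(0.15e-3 + contour_gradient_slope * prox, cn),
             dgm = 0.10e-3, wmh = 0.33e-3,
             wmh_less = 0.30e-3, wmh_intense = 0.38e-3,
             index_infarct = 0.80e-3, old_infarct = 0.70e-3,
             sinus = NA_real_)
  if (!is.null(slope_targets)) {
    bad <- setdiff(names(slope_targets), tissue)
    if (length(bad)) stop("unknown tissue in slope_targets: ",
                          paste(bad, collapse = ", "))
    slope[names(slope_targets)] <- slope_targets
  }
  out <- data.frame(tissue = tissue,
                    t10_ms = t10[tissue], m0 = m0[tissue], vp = vp[tissue],
                    md = md[tissue], fa = fa[tissue],
                    slope_base = slope[tissue],
                    row.names = NULL, stringsAsFactors = FALSE)
  sens <- vapply(seq_len(nrow(out)), function(i) {
    if (out$tissue[i] == "sinus") return(NA_real_)
    slope_ktrans_sensitivity(out$t10_ms[i], out$m0[i], out$vp[i], config)
  }, numeric(1))
  out$kappa <- sens
  base_off <- vapply(seq_len(nrow(out)), function(i) {
    if (out$tissue[i] == "sinus") return(NA_real_)
    forward_slope(0, out$vp[i], out$t10_ms[i], out$m0[i], config)
  }, numeric(1))
  out$ktrans_per_min <- ifelse(out$tissue == "sinus", 0,
                               (out$slope_base - base_off) / sens)
  class(out) <- c("bbb_truth", "data.frame")
  out
}

#' Noiseless enhancement slope implied by the forward model
#'
#' Evaluates the Patlak + SPGR forward model for one compartment at the
#' configured dynamic times and returns the ordinary least-squares slope of
#' relative enhancement over the default fit window (all frames after the
#' first, which carries the bolus first pass).
#'
#' @param ktrans_per_min transfer constant.
#' @param vp plasma volume fraction.
#' @param t10_ms,m0 pre-contrast relaxometry of the compartment.
#' @param config a [cohort_config()].
#' @param amplitude bolus amplitude multiplier.
#' @return slope of relative enhancement per minute.
#' @export
forward_slope <- function(ktrans_per_min, vp, t10_ms, m0, config,
                          amplitude = 1) {
  t <- dce_times(config)
  conc <- ktrans_per_min * plasma_curve_integral(t, config, amplitude) +
    vp * plasma_curve(t, config, amplitude)
  s0 <- spgr_signal(m0, t10_ms, config$tr_ms, config$flip_angles_deg[2])
  r1 <- 1 / t10_ms + config$r1_relaxivity * conc * 1e-3  # per ms
  s <- spgr_signal(m0, 1 / r1, config$tr_ms, config$flip_angles_deg[2])
  enh <- (s - s0) / s0
  win <- -1L  # drop the bolus frame
  ols_slope(t[win], enh[win])
}

#' Slope-per-Ktrans sensitivity of a compartment
#'
#' Finite-difference derivative of the noiseless enhancement slope with
#' respect to Ktrans, used to convert leakage effects specified on the
#' reported slope scale into Ktrans increments (the forward model is nearly
#' linear in Ktrans at the low concentrations of intact-BBB tissue).
#'
#' @inheritParams forward_slope
#' @param k_ref reference Ktrans for the finite difference.
#' @return d(slope)/d(Ktrans), dimensionless per-minute ratio.
#' @export
slope_ktrans_sensitivity <- function(t10_ms, m0, vp, config, k_ref = 1e-4) {
  (forward_slope(k_ref, vp, t10_ms, m0, config) -
     forward_slope(0, vp, t10_ms, m0, config)) / k_ref
}

# Plain OLS slope of y on x.
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Default covariate effects on leakage slopes
#'
#' Per-tissue linear effects of clinical covariates on the enhancement
#' slope, on the natural slope scale (multiply by 1e3 for the conventional
#' reporting scale). Defaults reproduce the coefficient structure observed
#' in the target cohort: leakage rises with age (per 5-year increment),
#' WMH burden (per Fazekas point), hypertension and pre-contrast tissue T1,
#' and differs between lacunar and cortical stroke (negative = lower in
#' lacunar). Contour compartments inherit the NAWM effects; the WMH
#' intensity subclasses inherit the WMH effects.
#'
#' @param beta_leak_on_acer_change effect of one standard deviation of WMH
#'   leakage on 1-year cognitive score (ACE-R points), used by
#'   [simulate_cognition()]; default -1.89.
#' @param beta_leak_by_subtype optional named pair
#'   `c(lacunar = ..., cortical = ...)` replacing the common leakage effect
#'   with subtype-specific ones.
#' @param patient_sd standard deviation of the patient-level random
#'   intercept shared across tissues (slope scale).
#' @param tissue_sd standard deviation of the biological patient-by-tissue
#'   deviation (slope scale), common to all compartments.
#' @param measurement_sd standard deviation of the measurement error on an
#'   ROI-mean slope (slope scale; small because ROI means average many
#'   voxels).
#' @param vif_amplitude_sd per-patient relative spread of the bolus
#'   amplitude (drives the sagittal-sinus covariate).
#' @param t10_jitter_sd per-patient biological spread of tissue T1 (ms).
#' @param t10_measure_sd measurement error of the tissue-mean T1 covariate
#'   (ms).
#' @param acer_noise_sd residual SD of the 1-year cognitive score.
#' @return object of class `bbb_effects`: list with the per-tissue effect
#'   table (`table`), variance components and cognition coefficients.
#' @export
covariate_effects <- function(beta_leak_on_acer_change = -1.89,
                              beta_leak_by_subtype = NULL,
                              patient_sd = 0.10e-3,
                              tissue_sd = 0.25e-3,
                              measurement_sd = 0.02e-3,
                              vif_amplitude_sd = 0.05,
                              t10_jitter_sd = 30,
                              t10_measure_sd = 5,
                              acer_noise_sd = 3) {
  tis <- c("nawm", "dgm", "csf", "wmh", "index_infarct", "old_infarct")
  tab <- data.frame(
    tissue = tis,
    age_per5 = c(0.016, 0.025, 0.219, 0.059, 0.045, 0.049) * 1e-3,
    fazekas = c(0.024, 0.059, 0.205, 0.104, 0.017, 0.041) * 1e-3,
    lacunar = c(-0.110, -0.11, 0.363, -0.040, -0.520, -0.430) * 1e-3,
    hypertension = c(0.206, 0.233, 0.338, 0.256, 0.677, 0.472) * 1e-3,
    map = c(-0.00105, 0.00017, 0.016, 0.000368, -0.00298, 0.016) * 1e-3,
    pulse_pressure = c(0.00121, 0.0038, 0.017, 0.00333, -0.00203, 0.00261) * 1e-3,
    smoker = c(-0.050, 0.035, -0.30, -0.110, -0.040, -0.40) * 1e-3,
    t10_per_s = c(0.46, 0.365, 1.107, 0.536, 1.617, 0.773) * 1e-3,
    stringsAsFactors = FALSE
  )
  if (!is.null(beta_leak_by_subtype) &&
      !all(c("lacunar", "cortical") %in% names(beta_leak_by_subtype)))
    stop("beta_leak_by_subtype needs named 'lacunar' and 'cortical' entries")
  structure(list(
    table = tab,
    beta_leak_on_acer_change = beta_leak_on_acer_change,
    beta_leak_by_subtype = beta_leak_by_subtype,
    patient_sd = patient_sd,
    tissue_sd = tissue_sd,
    measurement_sd = measurement_sd,
    vif_amplitude_sd = vif_amplitude_sd,
    t10_jitter_sd = t10_jitter_sd,
    t10_measure_sd = t10_measure_sd,
    acer_noise_sd = acer_noise_sd,
    # structural modifiers of the WM microenvironment per Fazekas point
    md_per_fazekas = 0.015,     # 1e-3 mm^2/s
    t10_per_fazekas_ms = 8,
    fa_per_fazekas = -0.008
  ), class = "bbb_effects")
}

#' Zeroed covariate effects
#'
#' Convenience null-effect configuration: all covariate effects are zero
#' (variance components unchanged unless overridden). Used for null
#' simulations and type-I error checks.
#'
#' @param ... overrides passed to [covariate_effects()].
#' @return a `bbb_effects` object with a zero effect table.
#' @export
null_effects <- function(...) {
  eff <- covariate_effects(beta_leak_on_acer_change = 0, ...)
  eff$table[, -1] <- 0
  eff$md_per_fazekas <- 0
  eff$t10_per_fazekas_ms <- 0
  eff$fa_per_fazekas <- 0
  eff
}

# Map any compartment label to the effect-table row it inherits.
effect_tissue <- function(tissue) {
  out <- tissue
  out[grepl("^contour_", tissue) | tissue %in% c("nawm_distant")] <- "nawm"
  out[tissue %in% c("wmh_intense", "wmh_less")] <- "wmh"
  out
}

# Reference covariate values at which slope_base applies (effects are
# applied to covariates centred here, so the base is the cohort mean).
.bbb_ref <- list(age = 66, fazekas = 2.5, map = 100, pulse_pressure = 60,
                 nart = 112, t10_s_delta = 0)
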