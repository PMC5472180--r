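#' Cohort / acquisition configuration for the synthetic generator
#'
#' Bundles the acquisition protocol (two pre-contrast spoiled-gradient-echo
#' flip angles, dynamic timing), the simulation grid, the contrast-agent
#' model (bolus amplitude and bi-exponential washout of the blood pool,
#' relaxivity, haematocrit) and the noise model. Defaults follow the study
#' protocol this pipeline targets: flip angles 2 and 12 degrees, 20 dynamic
#' frames spanning 24 minutes, gadolinium-class relaxivity at 1.5 T.
#'
#' @param n_patients number of patients in the cohort.
#' @param grid_shape integer vector of 3 voxel counts. The default holds a
#'   Fazekas-6 WMH plus the 12-voxel NAWM margin the anatomy generator
#'   requires.
#' @param voxel_size_mm physical voxel size per axis (mm).
#' @param n_dynamics number of post-contrast dynamic frames (>= 3).
#' @param dynamic_interval_min spacing between dynamic frames in minutes
#'   (1.2 min x 20 frames = 24 min). Frame k is acquired at k * interval.
#' @param flip_angles_deg two distinct flip angles in (0, 90): low then high.
#'   The dynamic series is acquired at the high flip angle.
#' @param tr_ms repetition time of the spoiled-gradient-echo readout (ms).
#' @param r1_relaxivity longitudinal relaxivity of the contrast agent
#'   (per mM per s).
#' @param hematocrit blood haematocrit used to convert between plasma and
#'   whole-blood concentration (sagittal sinus carries whole blood).
#' @param cp_peak_mM peak plasma concentration of the bolus (mM).
#' @param bolus_peak_min time of the bolus peak (minutes after injection);
#'   concentration rises linearly from zero to the peak.
#' @param washout_frac fraction of the peak decaying at the fast rate; the
#'   remainder decays at the slow rate (bi-exponential washout).
#' @param washout_fast_per_min,washout_slow_per_min fast/slow decay rates.
#' @param snr signal-to-noise ratio of the simulated magnitude images
#'   (reference: mean pre-contrast brain signal at the high flip angle).
#'   Use `Inf` for noiseless simulation.
#' @param noise_model "rician" (Gaussian noise on complex channels, then
#'   magnitude) or "gaussian".
#' @param seed integer seed; every random draw in the generator derives
#'   from it.
#' @return object of class `bbb_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 30L,
                          grid_shape = c(44L, 44L, 28L),
                          voxel_size_mm = c(1, 1, 1),
                          n_dynamics = 20L,
                          dynamic_interval_min = 1.2,
                          flip_angles_deg = c(2, 12),
                          tr_ms = 8.2,
                          r1_relaxivity = 3.6,
                          hematocrit = 0.45,
                          cp_peak_mM = 5,
                          bolus_peak_min = 1,
                          washout_frac = 0.5,
                          washout_fast_per_min = 5,
                          washout_slow_per_min = 0.003,
                          snr = Inf,
                          noise_model = c("rician", "gaussian"),
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    n_dynamics = as.integer(n_dynamics),
    dynamic_interval_min = as.numeric(dynamic_interval_min),
    flip_angles_deg = as.numeric(flip_angles_deg),
    tr_ms = as.numeric(tr_ms),
    r1_relaxivity = as.numeric(r1_relaxivity),
    hematocrit = as.numeric(hematocrit),
    cp_peak_mM = as.numeric(cp_peak_mM),
    bolus_peak_min = as.numeric(bolus_peak_min),
    washout_frac = as.numeric(washout_frac),
    washout_fast_per_min = as.numeric(washout_fast_per_min),
    washout_slow_per_min = as.numeric(washout_slow_per_min),
    snr = as.numeric(snr),
    noise_model = match.arg(noise_model),
    seed = as.integer(seed)
  )
  class(cfg) <- "bbb_config"
  validate_config(cfg)
  cfg
}

cfg_fail <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

validate_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L)
    cfg_fail("n_patients", "must be a positive integer")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    cfg_fail("grid_shape", "must be three positive voxel counts")
  if (length(cfg$voxel_size_mm) != 3L || any(cfg$voxel_size_mm <= 0))
    cfg_fail("voxel_size_mm", "must be three positive lengths")
  if (is.na(cfg$n_dynamics) || cfg$n_dynamics < 3L)
    cfg_fail("n_dynamics", "must be >= 3")
  fa <- cfg$flip_angles_deg
  if (length(fa) != 2L || anyNA(fa) || any(fa <= 0) || any(fa >= 90) ||
      fa[1] == fa[2])
    cfg_fail("flip_angles_deg", "must be two distinct angles in (0, 90)")
  for (f in c("dynamic_interval_min", "tr_ms", "r1_relaxivity", "cp_peak_mM",
              "bolus_peak_min", "washout_fast_per_min")) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0) cfg_fail(f, "must be strictly positive")
  }
  if (cfg$washout_slow_per_min < 0) cfg_fail("washout_slow_per_min", "must be >= 0")
  if (cfg$hematocrit <= 0 || cfg$hematocrit >= 1)
    cfg_fail("hematocrit", "must lie in (0, 1)")
  if (cfg$washout_frac < 0 || cfg$washout_frac > 1)
    cfg_fail("washout_frac", "must lie in [0, 1]")
  if (is.na(cfg$snr) || cfg$snr <= 0) cfg_fail("snr", "must be positive (Inf allowed)")
  invisible(cfg)
}

#' Dynamic acquisition times
#'
#' @param config a [cohort_config()].
#' @return times (minutes after injection) of the dynamic frames.
#' @export
dce_times <- function(config) {
  seq_len(config$n_dynamics) * config$dynamic_interval_min
}

#' Plasma concentration curve of the contrast bolus
#'
#' Linear upslope to the bolus peak followed by bi-exponential washout; the
#' observed blood-pool signal therefore declines after the first pass while
#' leaky tissue keeps enhancing.
#'
#' @param t_min time(s) in minutes after injection.
#' @param config a [cohort_config()].
#' @param amplitude multiplicative bolus amplitude (per-patient variation
#'   in dose/cardiac output; 1 = nominal).
#' @return plasma concentration in mM at `t_min`.
#' @export
plasma_curve <- function(t_min, config, amplitude = 1) {
  tp <- config$bolus_peak_min
  f1 <- config$washout_frac
  a1 <- config$washout_fast_per_min
  a2 <- config$washout_slow_per_min
  peak <- config$cp_peak_mM * amplitude
  up <- t_min <= tp
  out <- numeric(length(t_min))
  out[up] <- peak * pmax(t_min[up], 0) / tp
  td <- t_min[!up] - tp
  out[!up] <- peak * (f1 * exp(-a1 * td) + (1 - f1) * exp(-a2 * td))
  out
}

#' Running integral of the plasma curve
#'
#' Closed-form integral of [plasma_curve()] from injection to `t_min`
#' (mM * min), the Patlak accumulation term.
#'
#' @inheritParams plasma_curve
#' @return integral values at `t_min`.
#' @export
plasma_curve_integral <- function(t_min, config, amplitude = 1) {
  tp <- config$bolus_peak_min
  f1 <- config$washout_frac
  a1 <- config$washout_fast_per_min
  a2 <- config$washout_slow_per_min
  peak <- config$cp_peak_mM * amplitude
  up <- t_min <= tp
  out <- numeric(length(t_min))
  out[up] <- peak * pmax(t_min[up], 0)^2 / (2 * tp)
  td <- t_min[!up] - tp
  slow <- if (a2 > 0) (1 - f1) / a2 * (1 - exp(-a2 * td)) else (1 - f1) * td
  out[!up] <- peak * (tp / 2 + f1 / a1 * (1 - exp(-a1 * td)) + slow)
  out
}
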