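#' Run the full simulate-then-analyse pipeline
#'
#' Orchestrates one reproducible end-to-end run: cohort generation, per
#' patient voxel simulation (DCE + pre-contrast pair + DWI), VFA T1
#' mapping, contour labelling, enhancement extraction and slope
#' quantification, diffusion MD/FA extraction, model fitting (per-tissue
#' leakage model, contour gradient, cognition), and a manifest with an MD5
#' checksum of every artifact. Identical config + seed yields an identical
#' manifest. A stage failure halts the run with the stage name; artifacts
#' written before the failure are preserved.
#'
#' @param config a [cohort_config()] (or path to a YAML written by
#'   [write_config()]).
#' @param out_dir output directory (created if needed).
#' @param effects a [covariate_effects()] object.
#' @param n_contours,width_voxels contour scheme.
#' @param save_volumes write NIfTI volumes for the first patient
#'   (`"first"`, default), all patients (`"all"`) or none (`"none"`).
#' @param dwi_scheme gradient scheme (see [default_dwi_scheme()]).
#' @param fit_models fit the statistical models (needs enough patients and
#'   tissue coverage; disable for tiny smoke runs).
#' @return list of class `bbb_run`: `dir`, `manifest` (data.frame of file
#'   + md5), `slopes`, and (if fitted) `leakage`, `gradient`, `cognition`
#'   coefficient tables.
#' @export
run_pipeline <- function(config, out_dir, effects = covariate_effects(),
                         n_contours = 10L, width_voxels = 2L,
                         save_volumes = c("first", "all", "none"),
                         dwi_scheme = default_dwi_scheme(),
                         fit_models = TRUE) {
  save_volumes <- match.arg(save_volumes)
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  files <- character()
  add <- function(p) { files[[length(files) + 1L]] <<- p; p }

  cohort <- stage("simulate", generate_cohort(config, effects))
  write.csv(cohort$covariates, add(file.path(out_dir, "covariates.csv")),
            row.names = FALSE)
  write_config(config, add(file.path(out_dir, "config.yaml")))

  slope_rows <- list(); enh_rows <- list()
  for (p in cohort$covariates$patient) {
    cv <- cohort$covariates[cohort$covariates$patient == p, ]
    set.seed(config$seed + p)
    anat <- stage("anatomy",
                  generate_anatomy(config, p, fazekas = cv$fazekas,
                                   old_infarct = cv$has_old_infarct))
    lab <- stage("contours",
                 paint_contour_labels(anat, n_contours, width_voxels))
    truth_p <- patient_truth(cohort, p)
    sim <- stage("dce", simulate_dce(lab, truth_p, config,
                                     amplitude = cv$vif_amplitude))
    t10 <- stage("t1map", fit_t10_vfa(sim$pre_low, sim$pre_high,
                                      config$flip_angles_deg, config$tr_ms))
    q <- stage("quantify", quantify_patient(sim, lab, t10))
    dwi <- stage("dwi", simulate_dwi(lab, truth_p, dwi_scheme$bvals,
                                     dwi_scheme$bvecs,
                                     snr = config$snr))
    tens <- stage("dti", fit_tensor(dwi$dwi, dwi$bvals, dwi$bvecs,
                                    mask = lab > 0L))
    mdv <- compute_md(tens); fav <- compute_fa(tens)
    labv <- as.vector(lab)
    q$md <- vapply(q$tissue, function(nm)
      mean(mdv[labv == label_code(nm, n_contours)], na.rm = TRUE) * 1e3,
      numeric(1))
    q$fa <- vapply(q$tissue, function(nm)
      mean(fav[labv == label_code(nm, n_contours)], na.rm = TRUE), numeric(1))
    q$patient <- p
    slope_rows[[p]] <- q
    enh <- extract_enhancement(sim, lab)
    enh$patient <- p
    enh_rows[[p]] <- as.data.frame(enh)
    if (save_volumes == "all" || (save_volumes == "first" && p == cohort$covariates$patient[1])) {
      vs <- config$voxel_size_mm
      write_volume(lab, add(file.path(out_dir, sprintf("patient%03d_labels.nii.gz", p))), vs)
      write_volume(ifelse(is.na(t10$t10_ms), 0, t10$t10_ms),
                   add(file.path(out_dir, sprintf("patient%03d_t10.nii.gz", p))), vs)
      write_volume(sim$dce, add(file.path(out_dir, sprintf("patient%03d_dce.nii.gz", p))), vs)
      write_volume(dwi$dwi, add(file.path(out_dir, sprintf("patient%03d_dwi.nii.gz", p))), vs)
      write_bvalbvec(dwi$bvals, dwi$bvecs,
                     file.path(out_dir, sprintf("patient%03d", p)))
      add(file.path(out_dir, sprintf("patient%03d.bval", p)))
      add(file.path(out_dir, sprintf("patient%03d.bvec", p)))
    }
  }
  slopes <- stage("slope_table",
                  build_slope_table(do.call(rbind, slope_rows),
                                    cohort$covariates))
  write.csv(slopes, add(file.path(out_dir, "slopes.csv")), row.names = FALSE)
  write.csv(do.call(rbind, enh_rows),
            add(file.path(out_dir, "enhancement.csv")), row.names = FALSE)

  out <- list(dir = out_dir, slopes = slopes, cohort = cohort)
  if (fit_models) {
    # voxel-derived tables have contour + split-WMH strata; give the
    # Table-1-style model its six classical compartments
    s2 <- slopes
    s2$tissue[s2$tissue == "nawm_distant"] <- "nawm"
    wmh_rows <- s2[s2$tissue %in% c("wmh_intense", "wmh_less"), ]
    if (nrow(wmh_rows)) {
      agg <- aggregate(cbind(slope, t10_ms, md, fa) ~ patient, wmh_rows, mean)
      agg$tissue <- "wmh"
      agg <- build_slope_table(
        merge(agg, unique(wmh_rows[, c("patient", "sinus")]), by = "patient"),
        cohort$covariates)
      s2 <- rbind(s2[!s2$tissue %in% c("wmh_intense", "wmh_less"),
                     names(agg)], agg)
    }
    fit_or_warn <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        warning(sprintf("model '%s' not fitted: %s", name,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    }
    out$leakage <- fit_or_warn("leakage", fit_leakage_model(s2))
    out$gradient <- fit_or_warn("contour_gradient", fit_contour_gradient(slopes))
    out$cognition <- fit_or_warn("cognition", fit_cognition_model(s2))
    if (!is.null(out$leakage))
      write.csv(as.data.frame(out$leakage),
                add(file.path(out_dir, "coefficients_leakage.csv")),
                row.names = FALSE)
    if (!is.null(out$gradient))
      write.csv(as.data.frame(out$gradient),
                add(file.path(out_dir, "coefficients_gradient.csv")),
                row.names = FALSE)
    if (!is.null(out$cognition))
      write.csv(as.data.frame(out$cognition),
                add(file.path(out_dir, "coefficients_cognition.csv")),
                row.names = FALSE)
  }
  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = unname(tools::md5sum(unlist(files))),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  out$manifest <- manifest
  class(out) <- "bbb_run"
  out
}

#' @export
print.bbb_run <- function(x, ...) {
  cat(sprintf("Pipeline run in %s: %d artifacts, %d slope rows\n",
              x$dir, nrow(x$manifest), nrow(x$slopes)))
  invisible(x)
}
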