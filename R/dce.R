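#' Per-tissue enhancement time courses from a dynamic series
#'
#' For every nonempty compartment label, computes the relative enhancement
#' \eqn{(S(t) - S_{pre}) / S_{pre}} per voxel and averages it within the
#' label (tissue-mean-then-slope is the default leakage route; raw
#' difference is available for diagnostics). Voxels with non-positive
#' baseline signal are excluded and counted; labels with no usable voxel
#' are omitted.
#'
#' @param dce a `bbb_dce` object, or a 4D array with a `times_min`
#'   argument.
#' @param labels integer label map on the same grid (a [merge_tissues()] /
#'   [paint_contour_labels()] result).
#' @param baseline pre-contrast volume at the dynamic flip angle; defaults
#'   to `dce$baseline`.
#' @param times_min acquisition times when `dce` is a plain array.
#' @param normalize "relative" (default) divides by baseline; "difference"
#'   returns raw signal change.
#' @return data.frame of class `bbb_enhancement`: one row per label x
#'   timepoint with `tissue`, `time_min`, `enhancement`, `n_vox`;
#'   attribute `n_excluded` counts baseline-invalid voxels.
#' @export
extract_enhancement <- function(dce, labels, baseline = NULL,
                                times_min = NULL,
                                normalize = c("relative", "difference")) {
  normalize <- match.arg(normalize)
  if (inherits(dce, "bbb_dce")) {
    if (is.null(baseline)) baseline <- dce$baseline
    times_min <- dce$times_min
    dce <- dce$dce
  }
  if (is.null(times_min)) stop("times_min is required for a plain array")
  d <- dim(dce)
  if (!identical(d[1:3], dim(labels)))
    stop("dce and labels are on different grids")
  if (!identical(dim(baseline), dim(labels)))
    stop("baseline and labels are on different grids")
  nt <- d[4]
  if (length(times_min) != nt) stop("times_min must match the 4th dimension")
  sig <- matrix(dce, prod(d[1:3]), nt)
  labv <- as.vector(labels)
  basev <- as.vector(baseline)
  usable <- labv > 0L & basev > 0
  n_excluded <- sum(labv > 0L & basev <= 0)
  legend <- bbb_label_legend(20L)
  name_of <- setNames(names(legend), legend)
  out <- list()
  for (code in sort(unique(labv[usable]))) {
    vox <- usable & labv == code
    e <- sig[vox, , drop = FALSE]
    if (normalize == "relative") e <- e / basev[vox] - 1
    else e <- e - basev[vox]
    nm <- name_of[[as.character(code)]] %||% paste0("label_", code)
    out[[nm]] <- data.frame(tissue = nm, time_min = times_min,
                            enhancement = colMeans(e), n_vox = sum(vox),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("bbb_enhancement", "data.frame")
  res
}

#' Blood-pool (vascular input) enhancement from the sagittal sinus
#'
#' Extracts the sagittal-sinus enhancement series - the intravascular
#' reference the leakage models adjust for - and summarises it as the mean
#' post-bolus enhancement level. An empty sinus mask is an error: the
#' intravascular correction is mandatory.
#'
#' @param dce a `bbb_dce` object or 4D array.
#' @param sinus_mask logical array of sagittal-sinus voxels.
#' @param baseline,times_min as in [extract_enhancement()].
#' @param level_window_min time window over which the reference level is
#'   averaged; default all frames after the first.
#' @return list with `series` (a one-tissue `bbb_enhancement`) and `level`
#'   (scalar sinus covariate).
#' @export
extract_vif <- function(dce, sinus_mask, baseline = NULL, times_min = NULL,
                        level_window_min = NULL) {
  if (!any(sinus_mask))
    stop("sinus mask is empty: intravascular correction requires sinus voxels")
  lab <- array(0L, dim(sinus_mask))
  lab[sinus_mask] <- .bbb_labels[["sinus"]]
  ser <- extract_enhancement(dce, lab, baseline, times_min)
  if (is.null(level_window_min))
    level_window_min <- c(ser$time_min[2], Inf)
  inwin <- ser$time_min >= level_window_min[1] & ser$time_min <= level_window_min[2]
  list(series = ser, level = mean(ser$enhancement[inwin]))
}

#' Enhancement slope of a tissue time course
#'
#' Ordinary least-squares slope of enhancement against time over the fit
#' window. The default window drops the first post-injection frame, which
#' is dominated by the bolus first pass, and uses everything after it.
#' Requires at least three timepoints in the window.
#'
#' @param series a `bbb_enhancement` row set for one tissue (columns
#'   `time_min`, `enhancement`), or a data.frame with those columns.
#' @param fit_window_min numeric `c(from, to)` in minutes (closed
#'   interval); `NULL` = all frames after the first.
#' @return slope in enhancement units per minute (multiply by 1e3 for the
#'   conventional reporting scale).
#' @export
estimate_slope <- function(series, fit_window_min = NULL) {
  t <- series$time_min
  y <- series$enhancement
  if (is.null(t) || is.null(y)) stop("series needs time_min and enhancement")
  if (length(unique(series$tissue %||% "x")) > 1L)
    stop("estimate_slope expects a single tissue series")
  keep <- if (is.null(fit_window_min)) seq_along(t)[-1L]
          else which(t >= fit_window_min[1] & t <= fit_window_min[2])
  if (length(keep) < 3L)
    stop("fewer than 3 timepoints in the fit window")
  ols_slope(t[keep], y[keep])
}

#' Assemble the long slope table a cohort's models consume
#'
#' One row per patient x tissue/contour, joining the slope estimates with
#' the sinus reference level, the tissue-mean pre-contrast T1 and the
#' patient covariates. Rows whose covariates are missing are retained with
#' NA markers and counted (models are complete-case per fit).
#'
#' @param slopes data.frame with `patient`, `tissue`, `slope` and
#'   optionally `sinus`, `t10_ms`.
#' @param covariates per-patient covariate data.frame keyed by `patient`.
#' @return data.frame of class `bbb_slopetable`; attribute `n_missing`
#'   counts rows with at least one missing covariate.
#' @export
build_slope_table <- function(slopes, covariates) {
  need <- c("patient", "tissue", "slope")
  if (!all(need %in% names(slopes)))
    stop("slopes must have columns: ", paste(need, collapse = ", "))
  if (!nrow(slopes)) stop("empty slope table")
  if (!all(table(slopes$patient) >= 1L))
    stop("every patient needs at least one tissue slope")
  if (anyDuplicated(slopes[, c("patient", "tissue")]))
    stop("duplicate patient x tissue rows")
  out <- merge(slopes, covariates, by = "patient", all.x = TRUE,
               sort = FALSE)
  out <- out[order(out$patient, out$tissue), ]
  rownames(out) <- NULL
  ccols <- setdiff(names(out), c("patient", "tissue", "slope"))
  n_missing <- sum(!complete.cases(out[, ccols, drop = FALSE]))
  if (n_missing) message(sprintf("build_slope_table: %d row(s) carry missing covariates", n_missing))
  attr(out, "n_missing") <- n_missing
  class(out) <- c("bbb_slopetable", "data.frame")
  out
}

#' Per-tissue slopes for one patient's imaging session
#'
#' Convenience wrapper over the voxel pipeline: contour-resolved label
#' extraction, sinus reference, slope per compartment, and tissue-mean T1
#' from a fitted T1 map.
#'
#' @param dce a `bbb_dce` object.
#' @param labels contour-resolved label map.
#' @param t10map optional `bbb_t10map` for tissue-mean T1 covariates.
#' @param fit_window_min passed to [estimate_slope()].
#' @return data.frame with one row per nonempty compartment: `tissue`,
#'   `slope`, `sinus`, `t10_ms`, `n_vox`.
#' @export
quantify_patient <- function(dce, labels, t10map = NULL,
                             fit_window_min = NULL) {
  enh <- extract_enhancement(dce, labels)
  sinus_mask <- array(as.vector(labels) == .bbb_labels[["sinus"]], dim(labels))
  lev <- if (any(sinus_mask)) extract_vif(dce, sinus_mask)$level else NA_real_
  tis <- setdiff(unique(enh$tissue), "sinus")
  labv <- as.vector(labels)
  t10v <- if (!is.null(t10map)) as.vector(t10map$t10_ms) else NULL
  rows <- lapply(tis, function(nm) {
    ser <- enh[enh$tissue == nm, ]
    t10 <- if (is.null(t10v)) NA_real_ else
      mean(t10v[labv == label_code(nm, 20L)], na.rm = TRUE)
    data.frame(tissue = nm, slope = estimate_slope(ser, fit_window_min),
               sinus = lev, t10_ms = t10, n_vox = ser$n_vox[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
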