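#' Synthetic head anatomy for one patient
#'
#' Lays out nested compartments on the configured grid: a central WMH blob
#' (intense core inside a less-intense shell) whose size scales with the
#' Fazekas score, surrounded by NAWM, with a deep grey matter blob, a CSF
#' rim, an index-infarct blob, an optional old-infarct blob and a tubular
#' sagittal-sinus region. Labels are mutually exclusive. A Fazekas score of
#' zero produces no WMH.
#'
#' @param config a [cohort_config()]; `grid_shape` must leave at least
#'   `min_margin` voxels of NAWM beyond the WMH edge along +x.
#' @param patient_index 1-based patient number (controls the presence of an
#'   old infarct unless overridden).
#' @param fazekas WMH burden score 0-6 driving WMH size.
#' @param old_infarct include an old-infarct blob (default: every second
#'   patient).
#' @param min_margin required NAWM margin (voxels) between the WMH edge and
#'   the nearest non-NAWM tissue along +x; 12 guarantees room for six
#'   2-voxel contours.
#' @return integer label array (codes per [bbb_label_legend()]) with class
#'   `bbb_anatomy` and attribute `fazekas`.
#' @export
generate_anatomy <- function(config, patient_index = 1L, fazekas = 2L,
                             old_infarct = (patient_index %% 2L == 0L),
                             min_margin = 12L) {
  g <- config$grid_shape
  stopifnot(fazekas %in% 0:6)
  ctr <- (g + 1) / 2
  brain_semi <- (g - 2) / 2          # ellipsoid semi-axes incl. CSF rim
  inner_semi <- brain_semi - 2       # parenchyma inside the CSF rim
  wmh_r <- if (fazekas == 0) 0 else 1.5 + 0.55 * fazekas
  margin <- inner_semi[1] - wmh_r
  if (margin < min_margin)
    stop(sprintf(paste0("grid too small: NAWM margin along +x is %.1f voxels, ",
                        "need >= %d (enlarge grid_shape or reduce min_margin)"),
                 margin, min_margin))
  idx <- arrayInd(seq_len(prod(g)), g)
  # normalised ellipsoid coordinates helpers
  edist <- function(centre, semi) {
    sqrt(((idx[, 1] - centre[1]) / semi[1])^2 +
         ((idx[, 2] - centre[2]) / semi[2])^2 +
         ((idx[, 3] - centre[3]) / semi[3])^2)
  }
  rdist <- function(centre) {
    sqrt((idx[, 1] - centre[1])^2 + (idx[, 2] - centre[2])^2 +
         (idx[, 3] - centre[3])^2)
  }
  brain <- edist(ctr, brain_semi) <= 1
  inner <- edist(ctr, inner_semi) <= 1
  csf <- brain & !inner
  wmh <- if (wmh_r > 0) rdist(ctr) <= wmh_r else rep(FALSE, prod(g))
  wmh_core <- if (wmh_r > 0) rdist(ctr) <= 0.55 * wmh_r else wmh
  dgm <- rdist(ctr + c(-round(0.45 * inner_semi[1]), 0, 0)) <= 3 & inner
  sinus <- (sqrt((idx[, 1] - ctr[1])^2 +
                 (idx[, 2] - (ctr[2] + inner_semi[2] - 2))^2) <= 1.4) & inner
  index_inf <- rdist(ctr + c(round(0.3 * inner_semi[1]),
                             -round(0.45 * inner_semi[2]), 0)) <= 2 & inner
  old_inf <- if (old_infarct) {
    rdist(ctr + c(round(0.3 * inner_semi[1]),
                  round(0.45 * inner_semi[2]), 0)) <= 2 & inner
  } else rep(FALSE, prod(g))
  nawm <- inner & !wmh
  to_arr <- function(v) array(v, g)
  lab <- merge_tissues(csf = to_arr(csf), nawm = to_arr(nawm),
                       dgm = to_arr(dgm), wmh = to_arr(wmh),
                       index_infarct = to_arr(index_inf),
                       old_infarct = to_arr(old_inf),
                       sinus = to_arr(sinus), quiet = TRUE)
  # split the WMH into intense core / less-intense shell
  core <- to_arr(wmh_core) & lab == .bbb_labels[["wmh"]]
  shell <- lab == .bbb_labels[["wmh"]] & !core
  lab[core] <- .bbb_labels[["wmh_intense"]]
  lab[shell] <- .bbb_labels[["wmh_less"]]
  structure(lab, fazekas = fazekas, class = c("bbb_anatomy", class(lab)))
}

# Logical mask of one or more named compartments.
label_mask <- function(label_map, tissues, n_contours = 10L) {
  codes <- label_code(tissues, n_contours)
  array(as.vector(label_map) %in% codes, dim(label_map))
}
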