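#' Spoiled-gradient-echo steady-state signal
#'
#' The SPGR/FSPGR signal equation
#' \deqn{S = M_0 \sin\alpha \, (1 - E_1) / (1 - E_1 \cos\alpha), \quad
#'       E_1 = \exp(-TR/T_1).}
#'
#' @param m0 equilibrium signal scale (proportional to proton density and
#'   coil gain). Recycled against `t1_ms`.
#' @param t1_ms longitudinal relaxation time(s) in ms; must be > 0.
#' @param tr_ms repetition time in ms; must be > 0.
#' @param flip_deg flip angle in degrees, in [0, 90].
#' @return signal, same shape as the broadcast of `m0` and `t1_ms`.
#' @export
spgr_signal <- function(m0, t1_ms, tr_ms, flip_deg) {
  if (any(t1_ms <= 0, na.rm = TRUE)) stop("t1_ms must be strictly positive")
  if (any(tr_ms <= 0)) stop("tr_ms must be strictly positive")
  if (any(flip_deg < 0 | flip_deg > 90)) stop("flip_deg must lie in [0, 90]")
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Variable-flip-angle T1 mapping from two pre-contrast SPGR volumes
#'
#' Solves the exactly-determined two-point linearised VFA system per voxel:
#' regressing \eqn{S/\sin\alpha} on \eqn{S/\tan\alpha} across the two flip
#' angles gives slope \eqn{E_1 = \exp(-TR/T_1)} and intercept
#' \eqn{M_0 (1-E_1)}. Voxels whose slope falls outside (0, 1), or whose T1
#' falls outside the admissible physiological bracket, are flagged invalid
#' rather than silently zeroed. No B1 inhomogeneity correction is applied.
#'
#' @param signal_lowflip,signal_highflip arrays (any matching shape) of the
#'   two pre-contrast acquisitions, low flip angle first.
#' @param flips_deg the two flip angles in degrees (low, high); distinct.
#' @param tr_ms repetition time in ms. There is no default: the TR of the
#'   acquisition must be supplied explicitly.
#' @param t1_bounds_ms admissible T1 range; defaults bracket brain tissue
#'   and CSF.
#' @return object of class `bbb_t10map`: list with `t10_ms`, `m0`, `valid`
#'   (same shape as the inputs; invalid voxels are NA in `t10_ms`/`m0`) and
#'   `n_invalid`.
#' @export
fit_t10_vfa <- function(signal_lowflip, signal_highflip, flips_deg, tr_ms,
                        t1_bounds_ms = c(50, 10000)) {
  if (!identical(dim(signal_lowflip) %||% length(signal_lowflip),
                 dim(signal_highflip) %||% length(signal_highflip)))
    stop("flip-angle volumes are on different grids")
  if (length(flips_deg) != 2L || flips_deg[1] == flips_deg[2])
    stop("flips_deg must be two distinct angles")
  if (missing(tr_ms) || is.null(tr_ms) || tr_ms <= 0)
    stop("tr_ms must be supplied and positive")
  a <- flips_deg * pi / 180
  y1 <- signal_lowflip / sin(a[1]); x1 <- signal_lowflip / tan(a[1])
  y2 <- signal_highflip / sin(a[2]); x2 <- signal_highflip / tan(a[2])
  e1 <- (y2 - y1) / (x2 - x1)
  valid <- is.finite(e1) & e1 > 0 & e1 < 1
  t1 <- rep(NA_real_, length(e1))
  t1[valid] <- -tr_ms / log(e1[valid])
  valid <- valid & !is.na(t1) & t1 >= t1_bounds_ms[1] & t1 <= t1_bounds_ms[2]
  t1[!valid] <- NA_real_
  m0 <- rep(NA_real_, length(e1))
  m0[valid] <- (y1[valid] - e1[valid] * x1[valid]) / (1 - e1[valid])
  dm <- dim(signal_lowflip)
  if (!is.null(dm)) {
    dim(t1) <- dm; dim(m0) <- dm; dim(valid) <- dm
  }
  structure(list(t10_ms = t1, m0 = m0, valid = valid,
                 n_invalid = sum(!valid)),
            class = "bbb_t10map")
}

#' @export
print.bbb_t10map <- function(x, ...) {
  n <- length(x$valid)
  cat(sprintf("VFA T1 map: %d voxels, %d invalid (%.1f%%)\n",
              n, x$n_invalid, 100 * x$n_invalid / max(n, 1)))
  if (any(x$valid))
    cat(sprintf("  T1 range on valid voxels: %.0f-%.0f ms\n",
                min(x$t10_ms, na.rm = TRUE), max(x$t10_ms, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
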