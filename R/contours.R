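#' Binary morphological dilation on a 3D lattice
#'
#' One-step dilation of a logical 3D array under face (6) or full (26)
#' connectivity, implemented by array shifts.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face neighbours) or 26.
#' @return logical array of the same shape.
#' @export
dilate_mask <- function(mask, connectivity = 6L) {
  stopifnot(length(dim(mask)) == 3L)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  offs <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  out <- mask
  for (i in seq_len(nrow(offs))) out <- out | shift_mask(mask, offs[i, ])
  out
}

# Shift a 3D logical array by an integer offset, padding with FALSE.
shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { src[[ax]] <- seq_len(d[ax] - o); dst[[ax]] <- src[[ax]] + o }
    else        { src[[ax]] <- seq(1 - o, d[ax]);  dst[[ax]] <- src[[ax]] + o }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Merge binary tissue masks into one exclusive label map
#'
#' Overlaps are resolved by fixed precedence: index infarct > old infarct >
#' WMH > deep grey matter > CSF > sagittal sinus > NAWM. Overlap counts are
#' reported via the `overlaps` attribute and a message.
#'
#' @param csf,nawm,dgm,wmh,index_infarct,old_infarct,sinus logical 3D arrays
#'   on one grid; missing compartments may be `NULL`.
#' @param quiet suppress the overlap message.
#' @return integer label array (codes per [bbb_label_legend()]), with
#'   attribute `overlaps` (voxels claimed by more than one mask).
#' @export
merge_tissues <- function(csf = NULL, nawm = NULL, dgm = NULL, wmh = NULL,
                          index_infarct = NULL, old_infarct = NULL,
                          sinus = NULL, quiet = FALSE) {
  masks <- list(nawm = nawm, sinus = sinus, csf = csf, dgm = dgm, wmh = wmh,
                old_infarct = old_infarct, index_infarct = index_infarct)
  masks <- Filter(Negate(is.null), masks)
  if (!length(masks)) stop("at least one mask is required")
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d))
      stop("mask '", nm, "' is on a different grid")
  }
  lab <- array(0L, d)
  claimed <- array(0L, d)
  # assign lowest-precedence first; later assignments overwrite
  for (nm in names(masks)) {
    m <- masks[[nm]]
    lab[m] <- .bbb_labels[[nm]]
    claimed <- claimed + m
  }
  n_over <- sum(claimed > 1L)
  if (n_over && !quiet)
    message(sprintf("merge_tissues: %d voxel(s) in >1 mask resolved by precedence", n_over))
  attr(lab, "overlaps") <- n_over
  lab
}

#' Split a WMH mask into intense and less-intense components
#'
#' Thresholds FLAIR intensity within the WMH mask at a configurable
#' quantile (default the median). Voxels strictly above the threshold are
#' "intense"; ties go to "less intense", so a uniform-intensity WMH is
#' entirely less-intense.
#'
#' @param wmh_mask logical 3D array.
#' @param flair numeric array on the same grid.
#' @param prob quantile defining the threshold (default 0.5).
#' @return list with logical arrays `intense` and `less` (a partition of
#'   `wmh_mask`) and the `threshold` used.
#' @export
split_wmh_intensity <- function(wmh_mask, flair, prob = 0.5) {
  if (!identical(dim(wmh_mask), dim(flair)))
    stop("wmh_mask and flair are on different grids")
  if (!any(wmh_mask)) {
    warning("empty WMH mask: both intensity classes are empty")
    return(list(intense = wmh_mask, less = wmh_mask, threshold = NA_real_))
  }
  thr <- quantile(flair[wmh_mask], probs = prob, names = FALSE)
  intense <- wmh_mask & flair > thr
  list(intense = intense, less = wmh_mask & !intense, threshold = thr)
}

#' Concentric NAWM contours around the WMH edge
#'
#' Divides NAWM into `n_contours` rings of `width_voxels` voxels expanding
#' outward from the WMH edge, by iterated morphological dilation restricted
#' to the NAWM mask at every step (so rings grow through white matter only
#' and never leak across CSF or grey matter and re-enter). Ring k holds the
#' NAWM voxels whose in-mask chamfer distance d from the WMH set satisfies
#' (k-1)*width < d <= k*width. NAWM beyond the last ring - or unreachable
#' from the WMH through NAWM - is labelled distant NAWM.
#'
#' @param wmh_mask,nawm_mask logical 3D arrays on one grid. An empty WMH
#'   mask (a Fazekas-0 patient) labels all NAWM distant, with a warning.
#' @param n_contours number of rings (default 10).
#' @param width_voxels ring width in voxels (default 2, approximately 2 mm
#'   on a 1 mm grid).
#' @param connectivity lattice connectivity for the dilation, 6 or 26.
#' @return object of class `bbb_contours`: integer label array using the
#'   contour codes of [bbb_label_legend()], with attributes `counts` (named
#'   voxel counts) and `legend`.
#' @export
make_contours <- function(wmh_mask, nawm_mask, n_contours = 10L,
                          width_voxels = 2L, connectivity = 6L) {
  if (!identical(dim(wmh_mask), dim(nawm_mask)))
    stop("wmh_mask and nawm_mask are on different grids")
  n_contours <- as.integer(n_contours)
  width_voxels <- as.integer(width_voxels)
  stopifnot(n_contours >= 1L, width_voxels >= 1L)
  nawm_only <- nawm_mask & !wmh_mask
  lab <- array(0L, dim(wmh_mask))
  if (!any(wmh_mask)) {
    warning("empty WMH mask: all NAWM labelled distant")
    lab[nawm_only] <- .bbb_labels[["nawm_distant"]]
  } else {
    dist <- array(NA_integer_, dim(wmh_mask))
    region <- wmh_mask
    for (step in seq_len(n_contours * width_voxels)) {
      grown <- dilate_mask(region, connectivity) & nawm_only & !region
      if (!any(grown)) break
      dist[grown] <- step
      region <- region | grown
    }
    for (k in seq_len(n_contours)) {
      in_k <- !is.na(dist) & dist > (k - 1L) * width_voxels & dist <= k * width_voxels
      lab[in_k] <- 10L + k
    }
    lab[nawm_only & is.na(dist)] <- .bbb_labels[["nawm_distant"]]
  }
  legend <- bbb_label_legend(n_contours)
  keep <- c(contour_names(n_contours), "nawm_distant")
  counts <- vapply(keep, function(nm) sum(lab == legend[[nm]]), integer(1))
  structure(lab, counts = counts, legend = legend,
            n_contours = n_contours, width_voxels = width_voxels,
            class = c("bbb_contours", class(lab)))
}

#' Euclidean distance transform of a 3D mask
#'
#' Exact squared-Euclidean distance (Felzenszwalb-Huttenlocher separable
#' lower-envelope algorithm) from every voxel to the nearest `TRUE` voxel,
#' in physical units. Supports the physical-distance contour mode on
#' anisotropic grids; note it is an unrestricted (straight-line) distance,
#' unlike the in-mask chamfer distance of [make_contours()].
#'
#' @param mask logical 3D array (at least one `TRUE` voxel).
#' @param voxel_size_mm voxel dimensions (mm).
#' @return numeric array of distances in mm.
#' @export
distance_transform <- function(mask, voxel_size_mm = c(1, 1, 1)) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  if (!any(mask)) stop("mask has no foreground voxel")
  f <- array(ifelse(mask, 0, Inf), d)
  f <- apply(f, c(2, 3), edt_1d, w = voxel_size_mm[1])
  f <- aperm(apply(f, c(1, 3), edt_1d, w = voxel_size_mm[2]), c(2, 1, 3))
  f <- aperm(apply(f, c(1, 2), edt_1d, w = voxel_size_mm[3]), c(2, 3, 1))
  sqrt(f)
}

# 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher),
# built over the finite parabolas only.
edt_1d <- function(f, w = 1) {
  n <- length(f)
  x <- (seq_len(n) - 1) * w
  idx <- which(is.finite(f))
  if (!length(idx)) return(rep(Inf, n))
  v <- integer(length(idx)); z <- numeric(length(idx) + 1L)
  k <- 1L; v[1] <- idx[1]; z[1] <- -Inf; z[2] <- Inf
  if (length(idx) > 1L) {
    for (q in idx[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
        if (k > 1L && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}
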