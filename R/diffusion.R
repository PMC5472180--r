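#' Axisymmetric diffusion tensor with exact MD and FA
#'
#' Constructs a prolate axisymmetric tensor with eigenvalues
#' \eqn{\lambda_1 = MD(1 + 2\delta)}, \eqn{\lambda_{2,3} = MD(1 - \delta)}
#' where \eqn{\delta = FA / \sqrt{3 - 2 FA^2}}, which reproduces the target
#' mean diffusivity and fractional anisotropy exactly for FA in [0, 1).
#'
#' @param md target mean diffusivity (any diffusivity unit; eigenvalues
#'   come out in the same unit).
#' @param fa target fractional anisotropy in [0, 1).
#' @param axis principal eigenvector (need not be normalised).
#' @return symmetric 3 x 3 tensor.
#' @export
axisym_tensor <- function(md, fa, axis = c(1, 0, 0)) {
  stopifnot(md > 0, fa >= 0, fa < 1)
  delta <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * delta)
  l2 <- md * (1 - delta)
  v <- axis / sqrt(sum(axis^2))
  diag(rep(l2, 3)) + (l1 - l2) * tcrossprod(v)
}

# Pack a symmetric tensor as (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_to_vec <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])

vec_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

as_bvec_matrix <- function(bvecs, n) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != n)
    stop("bvecs must be 3 x n (or n x 3) with one column per b-value")
  nrm <- sqrt(colSums(bvecs^2))
  bvecs[, nrm > 0] <- sweep(bvecs[, nrm > 0, drop = FALSE], 2, nrm[nrm > 0], "/")
  bvecs
}

# Vectorised eigenvalues of symmetric 3x3 tensors in packed form
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), one row per tensor; returns a matrix of
# eigenvalues sorted descending (closed-form trigonometric solution).
sym3_eigenvalues <- function(v) {
  v <- matrix(v, ncol = 6)
  a11 <- v[, 1]; a22 <- v[, 2]; a33 <- v[, 3]
  a12 <- v[, 4]; a13 <- v[, 5]; a23 <- v[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  iso <- p2 <= 0 | p < .Machine$double.eps * pmax(abs(q), 1)
  b11 <- (a11 - q); b22 <- (a22 - q); b33 <- (a33 - q)
  detb <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(iso, 0, detb / (2 * p^3))
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out <- cbind(e1, e2, e3)
  out[iso, ] <- q[iso]
  out
}

# Design matrix of the log-linear tensor model: row i is
# b_i * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz).
btensor_design <- function(bvals, bvecs) {
  g <- t(bvecs)
  bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

#' Log-linear diffusion tensor fit
#'
#' Fits the diffusion tensor per voxel by ordinary least squares on
#' \eqn{\ln(S/S_0) = -b \, g^T D g}, using the mean of the b=0 volumes as
#' \eqn{S_0}. Voxels with any non-positive signal are flagged invalid and
#' excluded. Eigenvalues are returned sorted descending; voxels with a
#' negative eigenvalue remain in the tensor map but are flagged so that
#' scalar-metric extraction can exclude them (flag-and-exclude, not clip).
#'
#' @param dwi 4D array (x, y, z, volume) or matrix (voxel x volume).
#' @param bvals,bvecs gradient scheme; at least one b=0 and >= 6
#'   non-collinear directions.
#' @param mask optional logical array restricting the fit.
#' @return object of class `bbb_tensormap`: list with `evals` (voxel x 3,
#'   descending), `tensor` (voxel x 6 packed), `valid` and `neg_eig`
#'   flags, `n_invalid`, `n_neg_eig`, and `dim` of the spatial grid (for
#'   4D input).
#' @export
fit_tensor <- function(dwi, bvals, bvecs, mask = NULL) {
  bvecs <- as_bvec_matrix(bvecs, length(bvals))
  if (sum(bvals == 0) < 1L) stop("at least one b=0 volume is required")
  dw <- bvals > 0
  if (sum(dw) < 6L) stop("at least 6 diffusion directions are required")
  X <- btensor_design(bvals, bvecs)[dw, , drop = FALSE]
  if (qr(X)$rank < 6L) stop("gradient directions are collinear: tensor not identifiable")
  spat <- NULL
  if (length(dim(dwi)) == 4L) {
    spat <- dim(dwi)[1:3]
    dwi <- matrix(dwi, prod(spat), dim(dwi)[4])
  }
  nv <- nrow(dwi)
  sel <- if (is.null(mask)) rep(TRUE, nv) else as.vector(mask)
  s0 <- rowMeans(dwi[, !dw, drop = FALSE])
  pos <- sel & s0 > 0 & rowSums(dwi[, dw, drop = FALSE] <= 0) == 0
  y <- -log(sweep(dwi[pos, dw, drop = FALSE], 1, s0[pos], "/"))
  # one shared least-squares solve for all voxels
  beta <- t(qr.coef(qr(X), t(y)))   # voxel x 6
  evals <- matrix(NA_real_, nv, 3)
  neg <- rep(FALSE, nv)
  tens <- matrix(NA_real_, nv, 6)
  tens[pos, ] <- beta
  evals[pos, ] <- sym3_eigenvalues(beta)
  neg[pos] <- evals[pos, 3] < 0
  structure(list(evals = evals, tensor = tens, valid = pos, neg_eig = neg,
                 n_invalid = sum(sel) - sum(pos), n_neg_eig = sum(neg),
                 dim = spat),
            class = "bbb_tensormap")
}

#' Mean diffusivity from eigenvalues
#'
#' \eqn{MD = (\lambda_1 + \lambda_2 + \lambda_3) / 3} (equivalently
#' trace/3), in the unit of the eigenvalues.
#'
#' @param evals numeric vector of 3 eigenvalues, or a voxel x 3 matrix / a
#'   `bbb_tensormap`.
#' @param exclude_negative for tensor maps: drop voxels flagged with a
#'   negative eigenvalue (default TRUE).
#' @return MD value(s); NA for invalid/excluded voxels of a map.
#' @export
compute_md <- function(evals, exclude_negative = TRUE) {
  if (inherits(evals, "bbb_tensormap")) {
    out <- rowMeans(evals$evals)
    if (exclude_negative) out[evals$neg_eig] <- NA_real_
    if (!is.null(evals$dim)) dim(out) <- evals$dim
    return(out)
  }
  if (is.matrix(evals)) return(rowMeans(evals))
  mean(evals)
}

#' Fractional anisotropy from eigenvalues
#'
#' \deqn{FA = \sqrt{3/2} \; \frac{\|\lambda - \bar\lambda\|}{\|\lambda\|}}
#' which lies in [0, 1]; all-zero eigenvalues are undefined and flagged NA.
#'
#' @inheritParams compute_md
#' @return FA value(s) in [0, 1]; NA where undefined or excluded.
#' @export
compute_fa <- function(evals, exclude_negative = TRUE) {
  fa_of <- function(m) {
    mn <- rowMeans(m)
    num <- sqrt(rowSums((m - mn)^2))
    den <- sqrt(rowSums(m^2))
    out <- sqrt(1.5) * num / den
    out[den == 0] <- NA_real_
    pmin(out, 1)
  }
  if (inherits(evals, "bbb_tensormap")) {
    out <- fa_of(evals$evals)
    if (exclude_negative) out[evals$neg_eig] <- NA_real_
    if (!is.null(evals$dim)) dim(out) <- evals$dim
    return(out)
  }
  if (is.matrix(evals)) return(fa_of(evals))
  unname(fa_of(matrix(evals, 1)))
}

#' @export
print.bbb_tensormap <- function(x, ...) {
  cat(sprintf("Diffusion tensor map: %d voxels fitted, %d invalid, %d with negative eigenvalues\n",
              sum(x$valid), x$n_invalid, x$n_neg_eig))
  invisible(x)
}
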