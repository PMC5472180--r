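#' Write a 3D/4D volume as NIfTI-1
#'
#' @param x numeric/integer array (3D or 4D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel dimensions (mm), applied to the spatial axes.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(x)
  nd <- length(dim(x))
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, nd - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file.
#' @return plain array with attribute `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  out <- array(as.vector(img), dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  out
}

#' Write FSL-style bval/bvec text files
#'
#' @param bvals numeric b-values.
#' @param bvecs 3 x n gradient directions.
#' @param prefix path prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return the two paths, invisibly.
#' @export
write_bvalbvec <- function(bvals, bvecs, prefix) {
  bvecs <- as_bvec_matrix(bvecs, length(bvals))
  pv <- paste0(prefix, ".bval"); pg <- paste0(prefix, ".bvec")
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), pv)
  writeLines(apply(bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), pg)
  invisible(c(pv, pg))
}

#' Read FSL-style bval/bvec text files
#'
#' @param prefix path prefix of `<prefix>.bval` / `<prefix>.bvec`.
#' @return list with `bvals` and `bvecs` (3 x n).
#' @export
read_bvalbvec <- function(prefix) {
  pv <- paste0(prefix, ".bval"); pg <- paste0(prefix, ".bvec")
  for (p in c(pv, pg)) if (!file.exists(p)) stop("missing file: ", p)
  bvals <- scan(pv, quiet = TRUE)
  g <- do.call(rbind, lapply(readLines(pg), function(l)
    scan(text = l, quiet = TRUE)))
  if (nrow(g) != 3L || ncol(g) != length(bvals))
    stop("malformed bvec file: ", pg, " (expected 3 rows x ", length(bvals),
         " values)")
  list(bvals = bvals, bvecs = g)
}

#' Read a tidy CSV table with schema checking
#'
#' Unknown columns are preserved with a warning; missing expected columns
#' are an error.
#'
#' @param path CSV file.
#' @param expected character vector of required columns (optional).
#' @return data.frame.
#' @export
read_table_csv <- function(path, expected = NULL) {
  if (!file.exists(path)) stop("cannot read table: file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(expected)) {
    miss <- setdiff(expected, names(d))
    if (length(miss)) stop("table ", path, " lacks column(s): ",
                           paste(miss, collapse = ", "))
    extra <- setdiff(names(d), expected)
    if (length(extra))
      warning("table ", path, " has unknown column(s) (preserved): ",
              paste(extra, collapse = ", "))
  }
  d
}

#' Serialise / restore a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @return `write_config`: the path invisibly; `read_config`: a validated
#'   `bbb_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$snr <- if (is.finite(x$snr)) x$snr else "Inf"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  if (!is.null(x$snr) && identical(x$snr, "Inf")) x$snr <- Inf
  do.call(cohort_config, x)
}
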