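test_that("tissue merge respects precedence and conserves voxels", {
  d <- c(8, 8, 8)
  mk <- function(sel) { m <- array(FALSE, d); m[sel] <- TRUE; m }
  csf <- mk(1:50); nawm <- mk(100:300); wmh <- mk(150:200); idx <- mk(180:220)
  lab <- suppressMessages(merge_tissues(csf = csf, nawm = nawm, wmh = wmh,
                                        index_infarct = idx))
  leg <- bbb_label_legend()
  # voxel claimed by both WMH and index infarct goes to the infarct
  expect_true(all(lab[180:200] == leg[["index_infarct"]]))
  expect_true(all(lab[150:179] == leg[["wmh"]]))
  # brute-force per-voxel check: labelled voxels equal the mask union
  expect_identical(sum(lab > 0L), sum(csf | nawm | wmh | idx))
  # disjoint masks come through unchanged
  lab2 <- merge_tissues(csf = mk(1:10), dgm = mk(20:30), quiet = TRUE)
  expect_identical(sum(lab2 == leg[["csf"]]), 10L)
  expect_identical(sum(lab2 == leg[["dgm"]]), 11L)
  expect_error(merge_tissues(csf = csf, nawm = array(FALSE, c(2, 2, 2))),
               "different grid")
})

test_that("WMH intensity split partitions the mask with documented ties", {
  d <- c(6, 6, 6)
  wmh <- array(FALSE, d); wmh[1:100] <- TRUE
  # uniform FLAIR: ties go to less-intense
  fl <- array(1, d)
  sp <- split_wmh_intensity(wmh, fl)
  expect_identical(sum(sp$intense), 0L)
  expect_identical(sp$less, wmh)
  # two-level with equal counts: the brighter half is intense
  fl2 <- array(0, d); fl2[1:50] <- 1; fl2[51:100] <- 2
  sp2 <- split_wmh_intensity(wmh, fl2)
  expect_identical(which(sp2$intense), 51:100)
  expect_identical(sp2$intense | sp2$less, wmh)
  expect_identical(sum(sp2$intense & sp2$less), 0L)
  expect_warning(split_wmh_intensity(array(FALSE, d), fl), "empty")
})

test_that("median split agrees with a sorting oracle on random intensities", {
  set.seed(7)
  d <- c(10, 10, 10)
  wmh <- array(TRUE, d)
  fl <- array(rnorm(1000), d)
  sp <- split_wmh_intensity(wmh, fl)
  expect_true(sum(sp$intense) %in% c(500L, 501L))
  # sorting oracle: intense voxels are exactly the top values
  ord <- order(fl[wmh], decreasing = TRUE)
  top <- sort(fl[wmh], decreasing = TRUE)[seq_len(sum(sp$intense))]
  expect_setequal(fl[sp$intense], top)
})

test_that("contours around a point source match exhaustive distance binning", {
  d <- c(11, 11, 11)
  wmh <- array(FALSE, d); wmh[6, 6, 6] <- TRUE
  nawm <- array(TRUE, d); nawm[6, 6, 6] <- FALSE
  ct <- make_contours(wmh, nawm, n_contours = 3, width_voxels = 2)
  # brute-force city-block distance from the source
  idx <- arrayInd(seq_len(prod(d)), d)
  dist <- abs(idx[, 1] - 6) + abs(idx[, 2] - 6) + abs(idx[, 3] - 6)
  for (k in 1:3) {
    expected <- sum(dist > (k - 1) * 2 & dist <= k * 2)
    expect_identical(sum(ct == 10L + k), expected)
  }
  expect_identical(sum(ct == 30L), sum(dist > 6))
})

test_that("contour bookkeeping: conservation, empty inputs, NAWM restriction", {
  d <- c(12, 12, 12)
  set.seed(11)
  wmh <- random_blob_mask(d, 2, c(1, 2.5))
  nawm <- random_blob_mask(d, 3, c(3, 5))
  ct <- make_contours(wmh, nawm, n_contours = 4, width_voxels = 2)
  counts <- attr(ct, "counts")
  expect_identical(sum(counts), sum(nawm & !wmh))
  # contour labels only inside NAWM
  expect_true(all(ct[!nawm | wmh] %in% 0L))
  # later ring empty only if earlier empty or NAWM exhausted
  ring_n <- counts[paste0("contour_", 1:4)]
  if (any(ring_n == 0)) {
    first0 <- min(which(ring_n == 0))
    expect_true(all(ring_n[first0:4] == 0) || counts[["nawm_distant"]] == 0)
  }
  # empty NAWM: everything empty
  ct2 <- make_contours(wmh, array(FALSE, d), 4, 2)
  expect_identical(sum(attr(ct2, "counts")), 0L)
  # empty WMH: warning and all NAWM distant (the Fazekas-0 case)
  expect_warning(ct3 <- make_contours(array(FALSE, d), nawm, 4, 2), "distant")
  expect_identical(sum(ct3 == 30L), sum(nawm))
})

test_that("dilation rings equal geodesic distance-transform binning", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (rep in 1:8) {
    d <- c(16, 16, 16)
    wmh <- random_blob_mask(d, 2, c(1, 3))
    nawm <- random_blob_mask(d, 3, c(3, 6))
    for (w in 1:2) {
      ct <- suppressWarnings(make_contours(wmh, nawm, 10, w))
      or <- oracle_rings(wmh, nawm, 10, w)
      expect_identical(as.integer(ct), as.integer(or))
    }
  }
})

test_that("width-1 rings are connected: each ring touches the previous one", {
  set.seed(31)
  d <- c(14, 14, 14)
  wmh <- random_blob_mask(d, 1, c(1.5, 2.5))
  nawm <- array(TRUE, d) & !wmh
  ct <- suppressWarnings(make_contours(wmh, nawm, 5, 1))
  prev <- wmh
  for (k in 1:5) {
    ring <- array(ct == 10L + k, d)
    if (!any(ring)) break
    expect_true(all(ring[!dilate_mask(prev)] == FALSE))
    prev <- ring
  }
})

test_that("Euclidean distance transform matches brute force on small grids", {
  set.seed(5)
  d <- c(9, 8, 7)
  m <- random_blob_mask(d, 2, c(1, 2))
  vs <- c(1, 1.5, 2)
  dt <- distance_transform(m, vs)
  idx <- arrayInd(seq_len(prod(d)), d)
  fg <- idx[as.vector(m), , drop = FALSE]
  brute <- vapply(seq_len(prod(d)), function(i) {
    sqrt(min(colSums((t(fg) * vs - idx[i, ] * vs)^2)))
  }, numeric(1))
  expect_equal(as.vector(dt), brute, tolerance = 1e-10)
  expect_error(distance_transform(array(FALSE, d)), "foreground")
})
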