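## Nuclear-segmentation preprocessing, the hierarchical watershed and the
## mask post-processing rules.

test_that("mean-slice insertion doubles the z sampling", {
  A <- matrix(10, 4, 4)
  B <- matrix(30, 4, 4)
  ex <- insert_mean_slices(list(A, A))
  expect_length(ex$slices, 3L)
  expect_equal(ex$flags, c("real", "artificial", "real"))
  expect_equal(ex$slices[[2]], A)
  ex2 <- insert_mean_slices(list(A, B))
  expect_equal(ex2$slices[[2]], matrix(20, 4, 4))
  ## n real slices -> 2n - 1 planes (152 sections -> 303)
  many <- insert_mean_slices(replicate(152, matrix(0, 2, 2),
                                       simplify = FALSE))
  expect_length(many$slices, 303L)
  expect_error(insert_mean_slices(list(A)), "at least 2")
})

test_that("clipping caps outliers before equalization", {
  img <- matrix(c(rep(0, 90), rep(10, 8), 50, 120), 10, 10)
  eq <- clip_and_equalize(img, preprocess_params(clip_cap = 50))
  ## 120 clipped to 50: both map to the same output value
  expect_equal(eq[img == 120], eq[img == 50])
  ## mapping is monotone over the original values
  expect_true(eq[img == 10][1] > eq[img == 0][1])
  expect_true(eq[img == 50][1] >= eq[img == 10][1])
})

test_that("equalization handles constant input and preserves two-level order", {
  expect_equal(clip_and_equalize(matrix(7, 5, 5)), matrix(32768, 5, 5))
  two <- matrix(c(rep(2, 20), rep(9, 5)), 5, 5)
  eq <- clip_and_equalize(two)
  expect_length(unique(as.vector(eq)), 2L)
  expect_true(eq[two == 9][1] > eq[two == 2][1])
})

test_that("background suppression needs an explicit cutoff", {
  img <- matrix(1:9, 3, 3)
  expect_error(suppress_background(img), "cutoff")
  expect_error(suppress_background(img, NULL), "cutoff")
  expect_equal(suppress_background(img, 0), img)
  expect_equal(suppress_background(img, 5), ifelse(img < 5, 0, img))
  expect_equal(suppress_background(img, 100), matrix(0, 3, 3))
})

test_that("local normalisation equalizes dim and bright nuclei", {
  ## two identical Gaussian nuclei, one at 30% brightness
  d <- 80
  xs <- seq_len(d)
  blob <- function(cx, cy, a) a * outer(exp(-(xs - cy)^2 / 18),
                                        exp(-(xs - cx)^2 / 18))
  img <- (blob(20, 40, 1) + blob(60, 40, 0.3)) * 50000
  out <- local_normalize(img, preprocess_params())
  p1 <- max(out[, 1:40]); p2 <- max(out[, 41:80])
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.2)
  ## degenerate inputs pass through
  expect_equal(local_normalize(matrix(0, 20, 20)), matrix(0, 20, 20))
  expect_equal(local_normalize(matrix(3, 20, 20)), matrix(3, 20, 20))
})

test_that("median + DoG sharpens blobs and kills isolated voxels", {
  ## constant stack: DoG identically zero
  expect_equal(smooth_and_dog(array(5, c(10, 10, 6))),
               array(0, c(10, 10, 6)))
  ## single bright voxel is removed by the 3x3x3 median
  vol <- array(0, c(9, 9, 9))
  vol[5, 5, 5] <- 1000
  med <- imc3d:::.median3_cpp(vol, dim(vol))
  expect_equal(max(med), 0)
  ## a Gaussian blob of sigma ~2.5 peaks at the blob centre after DoG
  d <- 21
  xs <- seq_len(d)
  g <- exp(-(xs - 11)^2 / (2 * 2.5^2))
  vol2 <- array(0, c(d, d, 7))
  for (z in 1:7) vol2[, , z] <- outer(g, g) * exp(-(z - 4)^2 / (2 * 2.5^2)) * 1e4
  land <- smooth_and_dog(vol2)
  peak <- arrayInd(which.max(land), dim(land))
  expect_equal(peak[1, 1:2], c(11L, 11L))
})

test_that("h-watershed separates two blobs and keeps each seed in its object", {
  d <- c(24, 24, 12)
  xs <- seq_len(24)
  vol <- array(0, d)
  for (z in 1:12) {
    pl <- outer(exp(-(xs - 7)^2 / 8), exp(-(xs - 7)^2 / 8)) +
      outer(exp(-(xs - 17)^2 / 8), exp(-(xs - 17)^2 / 8))
    vol[, , z] <- pl * exp(-(z - 6)^2 / 8) * 65535
  }
  labs <- h_watershed_3d(vol, watershed_params())
  expect_equal(sort(unique(as.vector(labs))), 0:2)
  expect_true(labs[7, 7, 6] > 0)
  expect_true(labs[17, 17, 6] > 0)
  expect_true(labs[7, 7, 6] != labs[17, 17, 6])
  ## every object contains exactly one seed
  seeds <- attr(labs, "seeds")
  expect_equal(sort(unique(labs[seeds])), 1:2)
})

test_that("flooding at 100% keeps the whole above-threshold basin", {
  d <- c(16, 16, 8)
  xs <- seq_len(16)
  vol <- array(0, d)
  for (z in 1:8)
    vol[, , z] <- outer(exp(-(xs - 8)^2 / 10), exp(-(xs - 8)^2 / 10)) *
      exp(-(z - 4)^2 / 6) * 65535
  full <- h_watershed_3d(vol, watershed_params(flooding_percent = 100))
  expect_equal(sum(full > 0), sum(vol > 500))
  ## a uniform image below the background threshold yields no label
  expect_warning(
    empty <- h_watershed_3d(array(100, c(8, 8, 4)), watershed_params()),
    "no watershed seed")
  expect_equal(max(empty), 0L)
})

test_that("watershed agrees with the brute-force priority-flood oracle", {
  for (seed in 1:5) {
    land <- random_landscape(seed)
    mine <- h_watershed_3d(land, watershed_params())
    orac <- oracle_hwatershed(land, 0.05 * 65535, 500, 0.9)
    expect_true(labels_agree_up_to_renaming(mine, orac),
                label = sprintf("landscape seed %d", seed))
  }
})

test_that("finalize drops small, disconnected and dim objects in order", {
  d <- c(12, 12, 7)  # planes alternate real/artificial
  flags <- rep(c("real", "artificial"), length.out = 7)
  labs <- array(0L, d)
  ## object 1: a healthy cube on real planes 1, 3, 5 (plus artificial)
  labs[2:5, 2:5, 1:5] <- 1L
  ## object 2: <= 10 voxels on the real planes
  labs[9:10, 9:10, 3] <- 2L
  raw <- array(5, c(12, 12, 4))
  out <- finalize_mask(labs, flags, raw, NULL)
  expect_equal(dim(out)[3], 4L)       # artificial planes gone
  expect_equal(sort(unique(out[out > 0])), 1L)
  ## the survivor grew by one pixel in-plane (cross-shaped expansion)
  expect_true(all(out[1:6, 2:5, 1:3] == 1L))
  expect_true(all(out[2:5, 1:6, 1:3] == 1L))
})

test_that("a 20-voxel object after dilation is removed by the size rule", {
  d <- c(9, 9, 3)
  labs <- array(0L, d)
  labs[4:5, 4:5, 1:3] <- 1L  # 12 voxels, dilates to 3 * (4 + 8) = 36... use 1 plane
  labs <- array(0L, d)
  labs[4, 4:5, 2] <- 1L  # 2 voxels on one plane: > 10 fails first
  labs[4:6, 4:7, 2] <- 1L  # 12 voxels; after +1 px dilation: 12 + ring
  raw <- array(0, d)      # mean nuclear 0 < 1: rule 5 would remove anyway
  out <- finalize_mask(labs, NULL, NULL, NULL)
  ## 12 voxels dilated in-plane by 1 px (cross) -> 12 + 14 = 26 >= 21: kept
  expect_equal(max(out), 1L)
  out2 <- finalize_mask(labs, NULL, raw, NULL)  # dim object: removed
  expect_equal(max(out2), 0L)
})

test_that("an object of exactly 10 voxels is removed", {
  labs <- array(0L, c(8, 8, 3))
  labs[2:6, 3, 2] <- 1L
  labs[2:6, 4, 2] <- 1L  # 10 voxels
  out <- finalize_mask(labs, NULL, NULL, NULL)
  expect_equal(max(out), 0L)
})

test_that("dilation never lets one label overwrite another", {
  labs <- array(0L, c(10, 10, 1))
  labs[3:5, 3:4, 1] <- 1L
  labs[3:5, 6:7, 1] <- 2L  # one background column between them
  ## pad with enough mass to survive size rules: use 3 planes
  labs <- array(labs, c(10, 10, 3))
  out <- finalize_mask(labs, NULL, NULL, NULL)
  expect_equal(sort(unique(out[out > 0])), c(1L, 2L))
  ## contested column went to the lower label id, objects stay disjoint
  expect_true(all(out[3:5, 5, ] == 1L))
  v1 <- which(out == 1L); v2 <- which(out == 2L)
  expect_length(intersect(v1, v2), 0L)
})

test_that("disconnected in-plane parts keep only the largest per slice", {
  labs <- array(0L, c(10, 10, 3))
  labs[2:5, 2:5, 1:3] <- 1L    # big part
  labs[8:9, 8:9, 1:3] <- 1L    # small far part, same label
  out <- finalize_mask(labs, NULL, NULL, NULL)
  expect_equal(sort(unique(out[out > 0])), 1L)
  expect_true(all(out[8:9, 8:9, ] == 0L))
})

test_that("footprints are connected per slice after finalization", {
  labs <- default_segmentation()
  for (z in seq_len(dim(labs)[3])) {
    pl <- labs[, , z]
    if (!any(pl > 0)) next
    cc <- imc3d:::.label2d_cpp(pl, 8L)
    per_label <- tapply(cc[cc > 0], pl[cc > 0],
                        function(v) length(unique(v)))
    expect_true(all(per_label == 1))
  }
})

test_that("quality report: spheres have comparable x-y and x-z axes", {
  ## synthetic 4-um-radius spheres on a 1 x 1 x 2 um grid
  labs <- array(0L, c(30, 30, 9))
  for (ctr in list(c(8, 8, 5), c(22, 22, 5))) {
    for (z in 1:9) for (y in 1:30) for (x in 1:30) {
      if ((x - ctr[1])^2 + (y - ctr[2])^2 + (2 * z - 2 * ctr[3])^2 <= 16)
        labs[y, x, z] <- if (ctr[1] == 8) 1L else 2L
    }
  }
  rep <- mask_quality_report(labs, spacing = c(1, 1, 2))
  expect_equal(nrow(rep$per_object), 2L)
  rel <- abs(rep$per_object$axis_xy - rep$per_object$axis_xz) /
    rep$per_object$axis_xy
  expect_true(all(rel < 0.15))
  ## a single-slice pancake is counted in the single-slice fraction
  labs2 <- array(0L, c(12, 12, 5))
  labs2[4:8, 4:8, 3] <- 1L
  rep2 <- mask_quality_report(labs2)
  expect_equal(rep2$single_slice$n_single[rep2$single_slice$slice == 3], 1L)
  ## empty mask: empty report
  rep3 <- mask_quality_report(array(0L, c(4, 4, 3)))
  expect_equal(nrow(rep3$per_object), 0L)
})
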