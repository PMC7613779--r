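## Vessel masks, 3D/2D distance measurements and neighbour proportions.

test_that("entropy threshold separates a two-level image", {
  img <- matrix(10, 40, 40)
  img[15:25, 15:25] <- 200
  thr <- renyi_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  ## kapur mode agrees with an exhaustive Shannon-entropy scan oracle
  thr_k <- renyi_threshold(img, method = "kapur")
  oracle <- local({
    v <- as.vector(img); rng <- range(v)
    b <- pmin(floor((v - rng[1]) / diff(rng) * 256), 255)
    h <- tabulate(b + 1L, 256); p <- h / sum(h)
    best <- -Inf; tb <- 0
    for (t in 0:254) {
      P1 <- sum(p[1:(t + 1)]); P2 <- 1 - P1
      if (P1 <= 0 || P2 <= 0) next
      pa <- p[1:(t + 1)] / P1; pb <- p[(t + 2):256] / P2
      e <- -sum(pa[pa > 0] * log(pa[pa > 0])) -
        sum(pb[pb > 0] * log(pb[pb > 0]))
      if (e > best) { best <- e; tb <- t }
    }
    ## threshold at the upper edge of the background's last bin
    rng[1] + (tb + 1) / 256 * diff(rng)
  })
  expect_equal(thr_k, oracle)
})

test_that("structure masks capture a bright tube and ignore blank slices", {
  slices <- list(matrix(5, 30, 30), matrix(5, 30, 30))
  slices[[1]][, 14:17] <- 180  # vertical tube
  mask <- make_structure_mask(slices)
  expect_true(all(mask[, 15:16, 1]))
  expect_false(any(mask[, c(1:8, 24:30), 1]))
  expect_false(any(mask[, , 2]))   # constant slice -> empty plane
})

test_that("centroid-to-mask distances follow Euclidean geometry with spacing", {
  mask <- array(FALSE, c(10, 10, 3))
  mask[5, 4, 1] <- TRUE  # y = 4 um, x = 3 um, z = 0 um
  cat <- data.frame(cell_id = 1:2,
                    centroid_x = c(3, 0), centroid_y = c(4, 0),
                    centroid_z = c(0, 0))
  d3 <- distance_to_structure(cat, NULL, mask, "3d", spacing = c(1, 1, 2))
  expect_equal(d3$distance[1], 0)     # centroid on a mask voxel
  expect_equal(d3$distance[2], 5)     # 3-4-5 triangle in-plane
  ## empty mask in 3d mode is an error
  expect_error(distance_to_structure(cat, NULL, array(FALSE, c(5, 5, 2)),
                                     "3d"), "empty")
})

test_that("2d distances use per-slice footprints and exclude empty planes", {
  labs <- array(0L, c(12, 12, 3))
  labs[6, 6, 1] <- 1L   # on slice 1 with mask
  labs[6, 6, 2] <- 1L   # slice 2 has an empty mask plane
  labs[2, 2, 3] <- 2L   # only on the empty-mask slice
  mask <- array(FALSE, c(12, 12, 3))
  mask[6, 9, 1] <- TRUE
  mask[2, 2, 3] <- FALSE
  cat <- data.frame(cell_id = 1:2, centroid_x = c(5, 1),
                    centroid_y = c(5, 1), centroid_z = c(0, 4))
  d2 <- distance_to_structure(cat, labs, mask, "2d", spacing = c(1, 1, 2))
  expect_equal(d2$distance[1], 3)     # x: 5 -> 8 in slice 1
  expect_true(is.na(d2$distance[2]))  # every slice excluded -> missing
})

test_that("neighbour proportions: two touching cells see only each other", {
  labs <- array(0L, c(4, 6, 2))
  labs[2:3, 2:3, ] <- 1L
  labs[2:3, 4:5, ] <- 2L
  cl <- c(`1` = 1L, `2` = 2L)
  p3 <- neighbor_proportions(labs, cl, "3d")
  expect_equal(p3["1", "2"], 1)
  expect_equal(p3["2", "1"], 1)
  expect_equal(p3["1", "1"], 0)
  p2 <- neighbor_proportions(labs, cl, "2d")
  expect_equal(p2["1", "2"], 1)
})

test_that("a 3D checkerboard of two clusters is fully heterotypic", {
  d <- c(6, 6, 6)
  labs <- array(0L, d)
  idx <- arrayInd(seq_len(prod(d)), d)
  ## 2x2x2 blocks labelled uniquely, block parity gives the cluster
  bid <- (idx[, 1] - 1) %/% 2 + 3 * ((idx[, 2] - 1) %/% 2) +
    9 * ((idx[, 3] - 1) %/% 2)
  labs[] <- bid + 1L
  parity <- ((idx[, 1] - 1) %/% 2 + (idx[, 2] - 1) %/% 2 +
               (idx[, 3] - 1) %/% 2) %% 2
  cl <- tapply(parity, bid + 1L, `[`, 1L) + 1L
  names(cl) <- sort(unique(as.vector(labs)))
  p3 <- neighbor_proportions(labs, cl, "3d")
  expect_equal(p3["1", "2"], 1)
  expect_equal(p3["2", "1"], 1)
})

test_that("rows with neighbours sum to one; isolated cells drop out", {
  labs <- array(0L, c(8, 8, 2))
  labs[2:3, 2:3, ] <- 1L
  labs[2:3, 4:5, ] <- 2L
  labs[6:7, 6:7, ] <- 3L   # isolated
  cl <- c(`1` = 1L, `2` = 2L, `3` = 3L)
  for (mode in c("3d", "2d")) {
    p <- neighbor_proportions(labs, cl, mode)
    sums <- rowSums(p)
    expect_equal(unname(sums[c("1", "2")]), c(1, 1), tolerance = 1e-9)
    expect_true(all(is.na(p["3", ])))
  }
  expect_error(neighbor_proportions(labs, c(`1` = 1L, `2` = 2L), "3d"),
               "label")
})

test_that("proportion differences subtract elementwise and cancel rowwise", {
  p3 <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE,
               dimnames = list(1:2, 1:2))
  p2 <- matrix(c(0.5, 0.5, 0.4, 0.6), 2, 2, byrow = TRUE,
               dimnames = list(1:2, 1:2))
  dd <- proportion_difference(p3, p2)
  expect_equal(dd["1", "1"], 0.1)
  expect_equal(unname(rowSums(dd)), c(0, 0), tolerance = 1e-12)
  expect_true(all(abs(dd) <= 1))
  expect_equal(proportion_difference(p3, p3),
               matrix(0, 2, 2, dimnames = dimnames(p3)))
})

test_that("microenvironment radius rule is inclusive and never self-returns", {
  cat <- data.frame(cell_id = 1:3,
                    centroid_x = c(0, 49, 51),
                    centroid_y = 0, centroid_z = 0, cluster = c(1, 2, 2))
  me <- microenvironment(cat, 1, radius = 50)
  expect_equal(me$ids, 2L)                 # 49 in, 51 out
  expect_equal(as.integer(me$composition["2"]), 1L)
  expect_false(1L %in% me$ids)
  expect_length(microenvironment(cat, 1, radius = 0)$ids, 0L)
  expect_error(microenvironment(cat, 99, 50), "unknown")
})

test_that("marker gating is strictly greater-than", {
  cat <- data.frame(cell_id = 1:3)
  nm <- matrix(c(0.19, 0.2, 0.21), 3, 1, dimnames = list(NULL, "panCK"))
  expect_equal(select_cells_by_marker(cat, nm, "panCK", 0.2), 3L)
  expect_equal(select_cells_by_marker(cat, nm, "panCK", 0),
               1:3)                       # all positive cells
  expect_length(select_cells_by_marker(cat, nm, "panCK", 1.0), 0L)
})

test_that("vessel distances are shorter in 3D than in 2D on the phantom", {
  ph <- default_phantom()
  labs <- default_segmentation()
  vols <- list(vWF = stack_channel(zero_pad_to_common_size(ph$stack), "vWF"))
  mask <- make_structure_mask(vols$vWF)
  cat <- measure_cells(labs, list(Ir191 = stack_channel(
    zero_pad_to_common_size(ph$stack), "Ir191")))
  d3 <- distance_to_structure(cat, labs, mask, "3d", c(1, 1, 2))
  d2 <- distance_to_structure(cat, labs, mask, "2d", c(1, 1, 2))
  ok <- !is.na(d2$distance)
  ## per-cell, the 3D distance can never exceed the same cell's 2D distance
  ## by construction only on average; assert the mean relation
  expect_lte(mean(d3$distance[ok]), mean(d2$distance[ok]))
})
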