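## Hot-pixel suppression, per-cell statistics and spillover compensation.

test_that("isolated hot pixels are set to the local neighbour maximum", {
  img <- matrix(10, 9, 9)
  img[5, 5] <- 200
  out <- remove_hot_pixels(img, delta = 50)
  expect_equal(out[5, 5], 10)
  expect_equal(out[-5, ], img[-5, ])
  ## an excess of 45 <= 50 is not hot
  img2 <- matrix(10, 9, 9); img2[5, 5] <- 55
  expect_identical(remove_hot_pixels(img2, 50), img2)
  ## corner pixels use the available neighbours
  img3 <- matrix(10, 5, 5); img3[1, 1] <- 500
  expect_equal(remove_hot_pixels(img3, 50)[1, 1], 10)
})

test_that("hot-pixel removal is idempotent and never increases a pixel", {
  set.seed(8)
  for (i in 1:10) {
    img <- matrix(rpois(400, 5), 20, 20)
    img[sample(400, 5)] <- 300
    once <- remove_hot_pixels(img, 50)
    expect_identical(remove_hot_pixels(once, 50), once)
    expect_true(all(once <= img))
  }
})

test_that("hot-pixel removal touches only around the planted pixels", {
  set.seed(9)
  img <- matrix(rpois(900, 8), 30, 30)
  base <- remove_hot_pixels(img, 50)          # clean of natural hot pixels
  planted <- sample(900, 10)
  img2 <- base
  img2[planted] <- img2[planted] + 400
  out <- remove_hot_pixels(img2, 50)
  changed <- which(out != img2)
  expect_true(all(changed %in% planted))
  expect_equal(length(changed), 10L)
})

toy_labels <- function() {
  labs <- array(0L, c(6, 6, 4))
  labs[2:3, 2:3, 1:2] <- 1L          # 8-voxel cube-ish
  labs[5, 5, 3] <- 2L
  labs[5, 6, 3] <- 2L
  labs
}

test_that("per-cell means, centroids and volumes are exact", {
  labs <- toy_labels()
  ch <- array(7, dim(labs))
  cat1 <- measure_cells(labs, list(marker = ch), spacing = c(1, 1, 2))
  expect_equal(cat1$marker, c(7, 7))
  expect_equal(cat1$volume, c(8L, 2L))
  ## 2-voxel cell with values 3 and 5 -> mean 4
  ch[5, 5, 3] <- 3; ch[5, 6, 3] <- 5
  cat2 <- measure_cells(labs, list(marker = ch))
  expect_equal(cat2$marker[2], 4)
  ## centroid of the symmetric cube is the cube centre, in micrometres
  expect_equal(cat2$centroid_x[1], mean(c(1, 2)))  # cols 2:3 -> 0-based 1:2
  expect_equal(cat2$centroid_y[1], 1.5)
  expect_equal(cat2$centroid_z[1], 1)              # planes 1:2 -> (0 + 2)/2
})

test_that("measurement is invariant to label renumbering", {
  labs <- toy_labels()
  set.seed(10)
  ch <- array(rpois(prod(dim(labs)), 20), dim(labs))
  a <- measure_cells(labs, list(m = ch))
  relab <- labs
  relab[labs == 1L] <- 7L
  relab[labs == 2L] <- 3L
  b <- measure_cells(relab, list(m = ch))
  expect_equal(sort(a$m), sort(b$m))
  expect_equal(sort(a$volume), sort(b$volume))
})

test_that("spillover compensation inverts forward mixing exactly", {
  S <- matrix(c(1, 0.04, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  truth <- c(A = 100, B = 10)
  observed <- as.vector(truth %*% S)
  cat <- data.frame(cell_id = 1L, volume = 30L, A = observed[1],
                    B = observed[2])
  attr(cat, "channels") <- c("A", "B")
  comp <- compensate_spillover(cat, S)
  expect_equal(c(comp$A, comp$B), unname(truth), tolerance = 1e-6)
  ## identity matrix: unchanged
  id <- diag(2); dimnames(id) <- dimnames(S)
  expect_equal(compensate_spillover(cat, id)$A, cat$A)
})

test_that("compensation round-trips random non-negative expression tables", {
  set.seed(11)
  chans <- c("A", "B", "C", "D")
  S <- diag(4)
  S[cbind(1:3, 2:4)] <- runif(3, 0.01, 0.06)
  S[cbind(2:4, 1:3)] <- runif(3, 0.005, 0.02)
  dimnames(S) <- list(chans, chans)
  X <- matrix(runif(200 * 4, 0, 50), 200, 4, dimnames = list(NULL, chans))
  O <- X %*% S
  cat <- data.frame(cell_id = 1:200, volume = 25L)
  for (j in seq_along(chans)) cat[[chans[j]]] <- O[, j]
  attr(cat, "channels") <- chans
  comp <- compensate_spillover(cat, S)
  expect_equal(as.matrix(comp[, chans]), X, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("invalid compensation inputs are rejected", {
  S <- diag(2); dimnames(S) <- list(c("A", "B"), c("A", "B"))
  cat <- data.frame(cell_id = 1L, A = -1, B = 2)
  attr(cat, "channels") <- c("A", "B")
  expect_error(compensate_spillover(cat, S), "non-negative")
  Ssing <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(validate_spillover(Ssing), "")
})

test_that("catalogs round-trip through CSV at full precision", {
  set.seed(12)
  cat <- data.frame(cell_id = 1:500,
                    volume = sample(21:200, 500, replace = TRUE),
                    centroid_x = runif(500, 0, 150),
                    Ir191 = rexp(500, 1 / 20))
  attr(cat, "channels") <- "Ir191"
  path <- withr::local_tempfile(fileext = ".csv")
  export_catalog(cat, path)
  back <- read_catalog(path)
  expect_equal(back$centroid_x, cat$centroid_x)
  expect_identical(back$cell_id, cat$cell_id)
  expect_equal(attr(back, "channels"), "Ir191")
  ## empty catalog: header-only CSV
  empty <- measure_cells(array(0L, c(3, 3, 2)), list(Ir191 = array(0, c(3, 3, 2))))
  export_catalog(empty, path)
  expect_equal(nrow(read_catalog(path)), 0L)
})
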