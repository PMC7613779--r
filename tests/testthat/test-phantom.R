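## The synthetic tissue phantom and object matching.

test_that("the phantom is bit-identical under the same seed", {
  sp <- phantom_spec(dim_um = c(x = 60, y = 60, z = 12), n_cells = 40)
  a <- generate_phantom(sp, seed = 3)
  b <- generate_phantom(sp, seed = 3)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$labels_um, b$truth$labels_um)
  c <- generate_phantom(sp, seed = 4)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("ground-truth cell count equals the label count", {
  ph <- generate_phantom(phantom_spec(dim_um = c(x = 60, y = 60, z = 12),
                                      n_cells = 40), seed = 5)
  expect_equal(nrow(ph$truth$cells), 40L)
  expect_equal(max(ph$truth$labels_um), 40L)
  expect_setequal(unique(as.vector(ph$truth$labels_um[ph$truth$labels_um > 0])),
                  ph$truth$cells$cell_id)
  ## nuclei are disjoint: nuclear truth is contained in the cell truth
  on <- ph$truth$labels_um > 0
  expect_true(all(ph$truth$cell_labels_um[on] == ph$truth$labels_um[on]))
})

test_that("a noiseless single-cell phantom matches the analytic ellipsoid volume", {
  ct <- default_cell_types()[1, ]
  ct$freq <- 1
  S <- diag(6)
  dimnames(S) <- list(default_phantom_panel()$channel_id,
                      default_phantom_panel()$channel_id)
  sp <- phantom_spec(dim_um = c(x = 40, y = 40, z = 20), n_cells = 1,
                     cell_types = ct, vessels = list(n = 0, radius_um = 0,
                                                     intensity = numeric()),
                     background = 0, gain_jitter = c(1, 1),
                     spillover = S, noise = "none")
  ph <- generate_phantom(sp, seed = 6)
  ## total nuclear signal: sum over sections x 2 planes / intensity
  tot <- sum(vapply(ph$stack$data$Ir191, sum, 1)) * 2
  i0 <- ct$Ir191
  cells <- ph$truth$cells
  vol_analytic <- 4 / 3 * pi * cells$r_x * cells$r_y * cells$r_z
  expect_equal(tot / i0, vol_analytic, tolerance = 0.1)
  ## rasterised truth volume agrees with the analytic ellipsoid volume
  expect_equal(ph$truth$cells$volume_um3, vol_analytic, tolerance = 0.1)
})

test_that("with hot pixels disabled no pixel exceeds its local maximum by > 50", {
  sp <- phantom_spec(dim_um = c(x = 60, y = 60, z = 12), n_cells = 40,
                     hot_pixel_rate = 0)
  ph <- generate_phantom(sp, seed = 7)
  for (img in ph$stack$data$Ir191)
    expect_identical(remove_hot_pixels(img, 50), img)
})

test_that("planted hot pixels are all removed at delta 50", {
  sp <- phantom_spec(dim_um = c(x = 80, y = 80, z = 16), n_cells = 40,
                     hot_pixel_rate = 3e-4)
  ph <- generate_phantom(sp, seed = 8)
  base <- generate_phantom(phantom_spec(dim_um = c(x = 80, y = 80, z = 16),
                                        n_cells = 40, hot_pixel_rate = 0),
                           seed = 8)
  is_hot <- function(img) {
    m <- NULL
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      s <- imc3d:::.shift2d(img, dy, dx, fill = -Inf)
      m <- if (is.null(m)) s else pmax(m, s)
    }
    img - m > 50
  }
  n_hot <- 0; n_left <- 0
  for (ch in ph$stack$channels) for (s in seq_along(ph$stack$data[[ch]])) {
    planted <- which(ph$stack$data[[ch]][[s]] != base$stack$data[[ch]][[s]])
    n_hot <- n_hot + length(planted)
    cleaned <- remove_hot_pixels(ph$stack$data[[ch]][[s]], 50)
    ## every planted artifact loses its hot classification, and cleaning
    ## never increases a pixel
    n_left <- n_left + sum(is_hot(cleaned)[planted])
    expect_true(all(cleaned <= ph$stack$data[[ch]][[s]]))
  }
  expect_gt(n_hot, 0)
  expect_equal(n_left, 0)
})

test_that("object matching is exact for identity and renumbering", {
  ph <- generate_phantom(phantom_spec(dim_um = c(x = 60, y = 60, z = 14),
                                      n_cells = 25), seed = 9)
  tr <- ph$truth$labels_sections
  m <- match_objects(tr, tr, 0.5)
  expect_equal(m$metrics$recall, 1)
  expect_equal(m$metrics$precision, 1)
  expect_equal(m$metrics$mean_iou, 1)
  perm <- tr
  ids <- sort(unique(tr[tr > 0]))
  lut <- integer(max(ids)); lut[ids] <- rev(seq_along(ids))
  perm[tr > 0] <- lut[tr[tr > 0]]
  m2 <- match_objects(tr, perm, 0.5)
  expect_equal(m2$metrics, m$metrics)
})

test_that("a split object is recorded once and matched once", {
  tr <- array(0L, c(10, 10, 2))
  tr[2:9, 2:9, ] <- 1L
  pred <- array(0L, c(10, 10, 2))
  pred[2:9, 2:5, ] <- 1L
  pred[2:9, 6:9, ] <- 2L
  m <- match_objects(tr, pred, 0.3)
  expect_equal(m$metrics$splits, 1)
  expect_equal(nrow(m$matches), 1L)       # best half only
  expect_equal(m$metrics$recall, 1)       # the one truth object is matched
  expect_equal(m$metrics$precision, 0.5)
})

test_that("overcrowded phantoms fail with a density hint", {
  sp <- phantom_spec(dim_um = c(x = 30, y = 30, z = 10), n_cells = 200)
  expect_error(generate_phantom(sp, seed = 1), "density|lower")
})

test_that("the expression phantom is deterministic and type-balanced", {
  a <- generate_expression_phantom(n = 500, seed = 2)
  b <- generate_expression_phantom(n = 500, seed = 2)
  expect_identical(a$expr, b$expr)
  expect_equal(sort(unique(a$type)), sort(default_cell_types()$type))
})
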