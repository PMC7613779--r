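## Feature-based pairwise registration, overlap cropping and the
## alignment-error sweep.

test_that("registering an image against itself yields the identity", {
  img <- blob_image(seed = 5)
  set.seed(1)
  tf <- estimate_pairwise_transform(img, img, registration_params(refine = FALSE))
  expect_lt(abs(tf$theta) * 180 / pi, 0.1)
  expect_lt(sqrt(tf$tx^2 + tf$ty^2), 0.1)
  expect_equal(tf$scale, 1, tolerance = 1e-3)
})

test_that("a known similarity corruption is recovered", {
  img <- blob_image(seed = 6)
  truth <- similarity_transform(5 * pi / 180, 1, 7, -3)
  centre <- c(ncol(img) + 1, nrow(img) + 1) / 2
  ## rotate about the centre, then translate
  corr <- compose_transform(similarity_transform(0, 1, 7, -3),
                            imc3d:::.similarity_about(5 * pi / 180, 1, 0, 0,
                                                      centre))
  moving <- warp_image(img, corr)
  set.seed(2)
  est <- estimate_pairwise_transform(img, moving, registration_params())
  rec <- compose_transform(est, corr)  # should be the identity
  expect_lt(abs(rec$theta) * 180 / pi, 0.5)
  off <- apply_transform(rec, centre) - rbind(centre)
  expect_lt(sqrt(sum(off^2)), 1)
})

test_that("pure noise pairs fail with a consensus error", {
  set.seed(3)
  a <- matrix(runif(90 * 90), 90, 90)
  b <- matrix(runif(90 * 90), 90, 90)
  expect_error(estimate_pairwise_transform(a, b, registration_params(),
                                           pair_label = "(1, 2)"),
               "alignment failed for slice pair")
})

test_that("overlap crop covers the full canvas for identity transforms", {
  tfs <- replicate(3, similarity_transform(), simplify = FALSE)
  box <- compute_overlap_crop(tfs, c(100, 100))
  expect_equal(unlist(box), c(x0 = 1, y0 = 1, x1 = 100, y1 = 100))
})

test_that("a translated slice shrinks the overlap box accordingly", {
  tfs <- list(similarity_transform(),
              similarity_transform(0, 1, 10, 0))
  box <- compute_overlap_crop(tfs, c(100, 100))
  expect_equal(box$x1 - box$x0 + 1, 90)
  expect_equal(box$y1 - box$y0 + 1, 100)
  ## opposite translations beyond the width: empty intersection
  far <- list(similarity_transform(0, 1, -80, 0),
              similarity_transform(0, 1, 80, 0))
  expect_error(compute_overlap_crop(far, c(100, 100)), "empty")
})

test_that("manual crop override is honoured", {
  tfs <- list(similarity_transform())
  box <- compute_overlap_crop(tfs, c(50, 50),
                              override = list(x0 = 5, y0 = 6, x1 = 20,
                                              y1 = 21))
  expect_equal(box$x0, 5)
  expect_equal(box$y1, 21)
})

test_that("warp_stack warps every channel onto one canvas", {
  a <- matrix(runif(400, 1, 9), 20, 20)
  st <- image_stack(list(Ir191 = list(a, a), SMA = list(a * 2, a * 2)),
                    c("Ir191", "SMA"))
  tfs <- list(similarity_transform(), similarity_transform(0, 1, 4, 0))
  w <- warp_stack(st, tfs, registration_params(interpolation = "nearest"))
  expect_equal(stack_dims(w$stack), c(20, 24))
  ## slice 2 content moved 4 px right on both channels
  expect_equal(w$stack$data$Ir191[[2]][, 5:24], a)
  expect_equal(w$stack$data$SMA[[2]][, 5:24], a * 2)
})

test_that("epsilon sweep prefers the better-correlating candidate and breaks ties low", {
  ## perfectly aligned stack: scores tie within tolerance -> smallest wins
  img <- blob_image(seed = 8, n = 30, d = 100)
  slices <- list(img, img + matrix(rnorm(length(img), 0, 0.5), nrow(img)),
                 img + matrix(rnorm(length(img), 0, 0.5), nrow(img)))
  st <- image_stack(list(SMA = slices, Ir191 = slices),
                    c("SMA", "Ir191"))
  set.seed(4)
  sel <- select_max_epsilon(c(2, 10), st, "SMA", "Ir191",
                            registration_params(refine = FALSE,
                                                ransac_iter = 300))
  expect_equal(sel$max_epsilon, 2)
  expect_true(all(is.finite(sel$scores)))
  ## single candidate: returned as-is
  sel1 <- select_max_epsilon(5, st, "SMA", "Ir191",
                             registration_params(refine = FALSE,
                                                 ransac_iter = 300))
  expect_equal(sel1$max_epsilon, 5)
})

test_that("aligned-minus-unaligned correlation improves on a misaligned phantom", {
  sp <- phantom_spec(dim_um = c(x = 100, y = 100, z = 16), n_cells = 100,
                     misalign = list(theta_deg = 5, trans_px = 8,
                                     scale = c(0.99, 1.01)))
  ph <- generate_phantom(sp, seed = 31)
  set.seed(5)
  reg <- register_stack(ph$stack, "SMA", registration_params(),
                        chain_span = 1)
  w <- warp_stack(ph$stack, reg$global)
  cc_al <- mean_consecutive_cc(stack_channel(w$stack, "Ir191"))
  cc_un <- mean_consecutive_cc(stack_channel(zero_pad_to_common_size(ph$stack),
                                             "Ir191"))
  expect_gt(cc_al, cc_un)
})

test_that("an aligned phantom yields near-identity transforms", {
  sp <- phantom_spec(dim_um = c(x = 100, y = 100, z = 12), n_cells = 70)
  ph <- generate_phantom(sp, seed = 13)
  set.seed(6)
  reg <- register_stack(ph$stack, "SMA",
                        registration_params(refine = TRUE), chain_span = 1)
  for (tf in reg$global) {
    expect_lt(abs(tf$theta) * 180 / pi, 0.2)
    expect_lt(sqrt(tf$tx^2 + tf$ty^2), 0.5)
  }
})
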