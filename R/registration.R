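## Serial-section registration: per-slice similarity transforms estimated on
## an equalized reference channel, composed to the first slice, selected by
## nuclear-channel cross-correlation, and applied to every channel.

#' Registration parameters
#'
#' @param max_octave_size images larger than this (longest side, pixels) are
#'   downscaled before feature extraction.
#' @param min_inlier_ratio minimal fraction of matches that must agree with
#'   the consensus transform.
#' @param rod ratio-of-distances threshold for descriptor matching
#'   (closest / second-closest).
#' @param max_epsilon maximal allowed alignment error in pixels (RANSAC
#'   inlier residual).
#' @param interpolation `"linear"` or `"nearest"` for intensity warping.
#' @param ransac_iter number of RANSAC hypotheses.
#' @param refine if `TRUE`, polish each pairwise transform by maximising the
#'   intensity correlation between the warped moving and the fixed image.
#' @param roi_frac centred fraction of each dimension used as the
#'   cross-correlation region for alignment-error selection.
#' @return list of class `registration_params`.
#' @export
registration_params <- function(max_octave_size = 1200,
                                min_inlier_ratio = 0.05,
                                rod = 0.86,
                                max_epsilon = 10,
                                interpolation = "linear",
                                ransac_iter = 1000,
                                refine = TRUE,
                                roi_frac = 0.25) {
  stopifnot(rod > 0, rod < 1, max_epsilon > 0, min_inlier_ratio >= 0)
  structure(list(max_octave_size = max_octave_size,
                 min_inlier_ratio = min_inlier_ratio, rod = rod,
                 max_epsilon = max_epsilon, interpolation = interpolation,
                 ransac_iter = ransac_iter, refine = refine,
                 roi_frac = roi_frac),
            class = "registration_params")
}

#' Per-slice histogram equalization of a reference channel
#'
#' Each slice is equalized independently with the classic cumulative
#' histogram mapping onto the 16-bit range; the mapping is monotone, so the
#' pixel rank order within a slice is preserved. Constant slices are returned
#' unchanged.
#'
#' @param slices list of numeric matrices (one per slice).
#' @return list of equalized matrices.
#' @export
equalize_reference <- function(slices) {
  if (!length(slices)) .stopf("empty slice list")
  lapply(slices, function(img) {
    if (is.null(img)) return(NULL)
    v <- as.vector(img)
    if (max(v) <= min(v)) return(img)
    r <- rank(v, ties.method = "max")
    out <- (r - min(r)) / (length(v) - min(r)) * 65535
    matrix(out, nrow(img), ncol(img))
  })
}

#' Least-squares similarity fit from point correspondences
#' @noRd
.fit_similarity <- function(p, q) {
  zp <- complex(real = p[, 1], imaginary = p[, 2])
  zq <- complex(real = q[, 1], imaginary = q[, 2])
  mp <- mean(zp); mq <- mean(zq)
  zp0 <- zp - mp; zq0 <- zq - mq
  a <- sum(zq0 * Conj(zp0)) / sum(Mod(zp0)^2)
  b <- mq - a * mp
  similarity_transform(Arg(a), Mod(a), Re(b), Im(b))
}

#' Rigid transform from two correspondences (matching model)
#' @noRd
.rigid_from_two <- function(p, q) {
  ang <- Arg(complex(real = q[2, 1] - q[1, 1], imaginary = q[2, 2] - q[1, 2])) -
    Arg(complex(real = p[2, 1] - p[1, 1], imaginary = p[2, 2] - p[1, 2]))
  a <- complex(modulus = 1, argument = ang)
  b <- complex(real = q[1, 1], imaginary = q[1, 2]) -
    a * complex(real = p[1, 1], imaginary = p[1, 2])
  similarity_transform(ang, 1, Re(b), Im(b))
}

#' Estimate the similarity transform mapping `moving` onto `fixed`
#'
#' Blob keypoints with orientation-normalised descriptors are matched by the
#' ratio-of-distances rule, a rigid consensus model is found by RANSAC with
#' inlier residual `max_epsilon`, and the final similarity transform is a
#' least-squares fit to the consensus set (optionally polished by intensity
#' correlation).
#'
#' @param fixed,moving numeric matrices of equal size.
#' @param params a [registration_params()] list.
#' @param pair_label used in error messages, e.g. `"(3, 4)"`.
#' @return a [similarity_transform()] with attribute `n_inliers`.
#' @export
estimate_pairwise_transform <- function(fixed, moving,
                                        params = registration_params(),
                                        pair_label = "") {
  if (!all(dim(fixed) == dim(moving)))
    .stopf("fixed and moving images must have equal size")
  sc <- 1
  fixed_s <- fixed; moving_s <- moving
  longest <- max(dim(fixed))
  if (longest > params$max_octave_size) {
    sc <- params$max_octave_size / longest
    fixed_s <- as.matrix(EBImage::resize(.blur2d(fixed, 0.5 / sc),
                                         w = round(nrow(fixed) * sc),
                                         h = round(ncol(fixed) * sc)))
    moving_s <- as.matrix(EBImage::resize(.blur2d(moving, 0.5 / sc),
                                          w = round(nrow(moving) * sc),
                                          h = round(ncol(moving) * sc)))
  }
  da <- .describe_keypoints(.detect_keypoints(moving_s))
  db <- .describe_keypoints(.detect_keypoints(fixed_s))
  .pairwise_from_descriptors(fixed, moving, da, db, sc, params, pair_label)
}

#' Pairwise estimation from precomputed keypoint descriptors
#' @noRd
.pairwise_from_descriptors <- function(fixed, moving, da, db, sc = 1,
                                       params = registration_params(),
                                       pair_label = "") {
  matches <- .match_descriptors(da, db, params$rod)
  fail <- function() .stopf("alignment failed for slice pair %s: %s",
                            pair_label, "fewer than 3 consensual correspondences")
  if (is.null(matches) || nrow(matches) < 3) fail()
  p <- da$kp[matches[, 1], c("x", "y"), drop = FALSE]
  q <- db$kp[matches[, 2], c("x", "y"), drop = FALSE]
  n <- nrow(p)
  eps2 <- params$max_epsilon^2
  best_in <- NULL; best_score <- -Inf
  for (it in seq_len(params$ransac_iter)) {
    s <- sample.int(n, 2L)
    if (sum((p[s[1], ] - p[s[2], ])^2) < 4) next
    tf <- .rigid_from_two(p[s, , drop = FALSE], q[s, , drop = FALSE])
    pr <- apply_transform(tf, p)
    r2 <- rowSums((pr - q)^2)
    inl <- r2 <= eps2
    score <- sum(inl) - mean(sqrt(r2[inl])) / (10 * params$max_epsilon)
    if (sum(inl) >= 3 && score > best_score) {
      best_score <- score
      best_in <- inl
    }
  }
  if (is.null(best_in) ||
      sum(best_in) < max(3, ceiling(params$min_inlier_ratio * n))) fail()
  tf <- .fit_similarity(p[best_in, , drop = FALSE], q[best_in, , drop = FALSE])
  for (round in 1:2) {
    pr <- apply_transform(tf, p)
    inl <- rowSums((pr - q)^2) <= eps2
    if (sum(inl) < 3) break
    best_in <- inl
    tf <- .fit_similarity(p[inl, , drop = FALSE], q[inl, , drop = FALSE])
  }
  ## guided re-matching: with a transform in hand, every keypoint pair that
  ## lands within a tight radius is a correspondence regardless of
  ## descriptor ambiguity; refitting on all of them sharply reduces the
  ## fit noise of the few ratio-test survivors
  tf <- .guided_refit(da, db, tf)
  if (sc != 1) {
    ## transform estimated on the downscaled grid; conjugate back
    up <- similarity_transform(0, 1 / sc, 0, 0)
    dn <- similarity_transform(0, sc, 0, 0)
    tf <- compose_transform(compose_transform(up, tf), dn)
  }
  n_in <- sum(best_in)
  if (isTRUE(params$refine)) {
    ## the correlation polish mainly serves to re-seat the estimate when
    ## the consensus set was poor; the final parameters always come from a
    ## guided point refit, whose exact blob-centre correspondences are
    ## unbiased
    polished <- .refine_by_correlation(fixed, moving, tf)
    tf <- polished
    if (sc == 1) {   # keypoints share the full-resolution frame
      final <- .guided_refit(da, db, polished)
      if ((attr(final, "n_guided") %||% 0L) >= 3L) {
        attr(final, "ncc") <- .overlap_cc(fixed, moving, final)
        tf <- final
      }
    }
  } else {
    attr(tf, "ncc") <- .overlap_cc(fixed, moving, tf)
  }
  attr(tf, "n_inliers") <- n_in
  tf
}

#' Proximity re-matching of all keypoints under a current estimate,
#' one-to-one by distance, followed by a least-squares similarity refit
#' @noRd
.guided_refit <- function(da, db, tf, radius = 2) {
  pa <- da$kp[, c("x", "y"), drop = FALSE]
  pb <- db$kp[, c("x", "y"), drop = FALSE]
  n_kept <- 0L
  for (it in 1:2) {
    pr <- apply_transform(tf, pa)
    d2 <- outer(rowSums(pr^2), rowSums(pb^2), "+") - 2 * tcrossprod(pr, pb)
    nn <- max.col(-d2)
    dd <- sqrt(pmax(d2[cbind(seq_len(nrow(pr)), nn)], 0))
    ok <- which(dd <= radius)
    if (length(ok) < 3) break
    ok <- ok[order(dd[ok])]
    used <- logical(nrow(pb))
    keep <- integer(0)
    for (i in ok) {
      if (!used[nn[i]]) {
        used[nn[i]] <- TRUE
        keep <- c(keep, i)
      }
    }
    if (length(keep) < 3) break
    tf <- .fit_similarity(pa[keep, , drop = FALSE],
                          pb[nn[keep], , drop = FALSE])
    n_kept <- length(keep)
  }
  attr(tf, "n_guided") <- n_kept
  tf
}

#' Masked overlap correlation of moving warped onto fixed
#' @noRd
.overlap_cc <- function(fixed, moving, tf) {
  w <- warp_image(moving, tf, dim(fixed), "linear")
  on <- warp_image(matrix(1, nrow(moving), ncol(moving)), tf,
                   dim(fixed), "nearest") > 0.5
  if (sum(on) < 100) return(-1)
  a <- w[on]; b <- fixed[on]
  if (sd(a) < 1e-9 || sd(b) < 1e-9) return(-1)
  cor(a, b)
}

#' Local intensity-correlation polish of a transform estimate; the result
#' carries its achieved overlap correlation as attribute "ncc"
#' @noRd
.refine_by_correlation <- function(fixed, moving, tf) {
  obj <- function(par)
    -.overlap_cc(fixed, moving,
                 similarity_transform(par[1], exp(par[2]), par[3], par[4]))
  start <- c(tf$theta, log(tf$scale), tf$tx, tf$ty)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10,
                              parscale = c(0.02, 0.02, 2, 2)))
  v0 <- obj(start)
  if (fit$value <= v0) {
    out <- similarity_transform(fit$par[1], exp(fit$par[2]), fit$par[3],
                                fit$par[4])
    attr(out, "ncc") <- -fit$value
  } else {
    out <- tf
    attr(out, "ncc") <- -v0
  }
  out
}

#' Compose consecutive pairwise transforms to the first-slice frame
#'
#' Pairwise transform i maps slice i+1 onto slice i; the global transform of
#' slice i is the composition of pairwise transforms 1..i-1 and slice 1 gets
#' the identity.
#'
#' @param pairwise list of n-1 `similarity_transform`s for n slices.
#' @return list of n global `similarity_transform`s.
#' @export
compose_to_reference <- function(pairwise) {
  out <- vector("list", length(pairwise) + 1L)
  out[[1]] <- similarity_transform()
  for (i in seq_along(pairwise))
    out[[i + 1]] <- compose_transform(out[[i]], pairwise[[i]])
  out
}

#' Estimate global transforms for every real slice of a stack
#'
#' The reference channel is equalized per slice and consecutive real slices
#' are registered pairwise. With `chain_span = 1` the pairwise transforms
#' are simply composed to the frame of the first real slice. With
#' `chain_span = 2` (default), next-nearest slice pairs are additionally
#' registered and the whole transform chain is adjusted by least squares
#' (rotation/scale in complex-log space, then translations), which strongly
#' damps the drift that plain composition accumulates. Missing slices are
#' skipped: the pair straddling a gap is registered directly.
#'
#' @param stack a padded `ImageStack`.
#' @param ref_channel reference channel id.
#' @param params a [registration_params()].
#' @param chain_span largest slice offset registered for the chain
#'   adjustment (1 = plain composition).
#' @return list with `pairwise` and `global` transform lists (one global
#'   transform per real slice, in slice order).
#' @export
register_stack <- function(stack, ref_channel, params = registration_params(),
                           chain_span = 2) {
  real <- which(stack$flags == "real")
  n <- length(real)
  if (n < 2) .stopf("need at least two real slices")
  eq <- equalize_reference(stack$data[[ref_channel]][real])
  ## keypoints and descriptors are computed once per slice and shared by
  ## every pair that involves the slice
  det <- lapply(eq, function(img) .describe_keypoints(.detect_keypoints(img)))
  pairwise <- vector("list", n - 1L)
  centre0 <- rev(dim(eq[[1]]) + 1) / 2
  for (i in seq_len(n - 1L)) {
    label <- sprintf("(%d, %d)", stack$sections[real[i]],
                     stack$sections[real[i + 1]])
    est <- tryCatch(.pairwise_from_descriptors(
      eq[[i]], eq[[i + 1]], det[[i + 1]], det[[i]], 1, params, label),
      error = function(e) e)
    if (inherits(est, "error")) {
      ## matching found no consensus: relax the ratio test, then fall back
      ## to a coarse rotation sweep refined by correlation; only accept a
      ## fallback that actually correlates
      px <- params; px$rod <- min(0.95, params$rod + 0.1)
      est <- tryCatch(.pairwise_from_descriptors(
        eq[[i]], eq[[i + 1]], det[[i + 1]], det[[i]], 1, px, label),
        error = function(e) e)
      if (inherits(est, "error")) {
        best <- NULL
        for (dth in seq(-20, 20, by = 5) * pi / 180) {
          cand <- .refine_by_correlation(
            eq[[i]], eq[[i + 1]],
            .similarity_about(dth, 1, 0, 0, centre0))
          if (is.null(best) ||
              (attr(cand, "ncc") %||% -1) > (attr(best, "ncc") %||% -1))
            best <- cand
        }
        if ((attr(best, "ncc") %||% -1) < 0.2) stop(est)
        est <- best
      }
    }
    pairwise[[i]] <- est
  }
  ## an adjacent estimate whose overlap correlation falls far below the
  ## stack's typical value is a false feature consensus; rescue it with a
  ## coarse rotation sweep refined by correlation
  nccs <- vapply(pairwise, function(tf) attr(tf, "ncc") %||% NA_real_, 1)
  if (sum(is.finite(nccs)) >= 3) {
    floor_cc <- max(0.25, 0.6 * stats::median(nccs, na.rm = TRUE))
    for (i in which(is.finite(nccs) & nccs < floor_cc)) {
      best <- pairwise[[i]]
      centre <- rev(dim(eq[[i]]) + 1) / 2
      for (dth in seq(-24, 24, by = 4) * pi / 180) {
        init <- compose_transform(
          pairwise[[i]], .similarity_about(dth, 1, 0, 0, centre))
        cand <- .refine_by_correlation(eq[[i]], eq[[i + 1]], init)
        if ((attr(cand, "ncc") %||% -1) > (attr(best, "ncc") %||% -1))
          best <- cand
      }
      pairwise[[i]] <- best
    }
  }
  meas <- lapply(seq_len(n - 1L), function(i)
    list(i = i, j = i + 1L, tf = pairwise[[i]]))
  if (chain_span >= 2 && n > 2) {
    ## skip-2 measurements are redundant constraints that damp composition
    ## drift; only feature-based estimates whose overlap correlation is
    ## credible relative to the adjacent pairs are admitted
    floor_cc <- max(0.25, 0.5 * stats::median(nccs, na.rm = TRUE))
    for (i in seq_len(n - 2L)) {
      tf <- tryCatch(.pairwise_from_descriptors(
        eq[[i]], eq[[i + 2]], det[[i + 2]], det[[i]], 1, params,
        pair_label = sprintf("(%d, %d)", stack$sections[real[i]],
                             stack$sections[real[i + 2]])),
        error = function(e) NULL)
      if (is.null(tf)) next
      cc <- attr(tf, "ncc") %||% -1
      if (is.finite(cc) && cc >= floor_cc)
        meas[[length(meas) + 1L]] <- list(i = i, j = i + 2L, tf = tf)
    }
  }
  global <- if (chain_span >= 2 && n > 2) .adjust_chain(n, meas)
  else compose_to_reference(pairwise)
  list(pairwise = pairwise, global = global)
}

#' Least-squares adjustment of a transform chain
#'
#' Measurements tf(i -> j) satisfy G_j = G_i o tf; writing the
#' rotation/scale part as a complex number a and the translation as b, the
#' relations log a_j - log a_i = log a_tf and b_j - b_i = a_i b_tf are both
#' linear and solved in two stages with G_1 fixed to the identity.
#' @noRd
.adjust_chain <- function(n, meas) {
  m <- length(meas)
  A <- matrix(0, m, n - 1L)
  rot <- complex(m); tr <- complex(m)
  for (k in seq_len(m)) {
    e <- meas[[k]]
    if (e$i > 1) A[k, e$i - 1L] <- -1
    A[k, e$j - 1L] <- 1
    rot[k] <- log(complex(modulus = e$tf$scale, argument = e$tf$theta))
    tr[k] <- complex(real = e$tf$tx, imaginary = e$tf$ty)
  }
  qa <- qr(A)
  lsq <- function(rhs2) qr.coef(qa, cbind(Re(rhs2), Im(rhs2)))
  u <- lsq(rot)
  a <- c(1 + 0i, exp(complex(real = u[, 1], imaginary = u[, 2])))
  rhs_b <- tr * a[vapply(meas, `[[`, 1L, "i")]
  v <- lsq(rhs_b)
  b <- c(0 + 0i, complex(real = v[, 1], imaginary = v[, 2]))
  lapply(seq_len(n), function(i)
    similarity_transform(Arg(a[i]), Mod(a[i]), Re(b[i]), Im(b[i])))
}

#' Warp every channel of a stack with per-slice global transforms
#'
#' All channels are warped with the same per-slice transforms onto a common
#' canvas (the union bounding box of all warped slice footprints);
#' out-of-canvas regions are zero.
#'
#' @param stack a padded `ImageStack`.
#' @param transforms list of global `similarity_transform`s, one per real
#'   slice.
#' @param params a [registration_params()] (interpolation setting).
#' @return list with the warped `ImageStack` (`stack`), the canvas offset
#'   applied (`offset`), and the offset-adjusted transforms (`transforms`).
#' @export
warp_stack <- function(stack, transforms, params = registration_params()) {
  real <- which(stack$flags == "real")
  if (length(transforms) != length(real))
    .stopf("need one global transform per real slice")
  d <- stack_dims(stack)
  corners <- cbind(x = c(1, d[2], d[2], 1), y = c(1, 1, d[1], d[1]))
  wc <- do.call(rbind, lapply(transforms, apply_transform, pts = corners))
  x0 <- floor(min(wc[, 1])); y0 <- floor(min(wc[, 2]))
  x1 <- ceiling(max(wc[, 1])); y1 <- ceiling(max(wc[, 2]))
  shift <- similarity_transform(0, 1, 1 - x0, 1 - y0)
  adj <- lapply(transforms, function(tf) compose_transform(shift, tf))
  out_dim <- c(y1 - y0 + 1L, x1 - x0 + 1L)
  interp <- if (identical(params$interpolation, "nearest")) "nearest" else "linear"
  newdata <- lapply(stack$data, function(ch) {
    out <- vector("list", length(ch))
    for (k in seq_along(real)) {
      i <- real[k]
      out[[i]] <- warp_image(ch[[i]], adj[[k]], out_dim, interp)
    }
    out
  })
  names(newdata) <- stack$channels
  warped <- image_stack(newdata, stack$channels, stack$sections, stack$flags,
                        stack$spacing)
  list(stack = warped, offset = c(x = 1 - x0, y = 1 - y0), transforms = adj)
}

#' Maximal axis-aligned box inside the intersection of warped footprints
#'
#' Rasterizes every warped slice footprint onto the canvas, intersects them,
#' and returns the largest axis-aligned rectangle contained in the
#' intersection. A manual override box is accepted and validated against the
#' canvas only.
#'
#' @param transforms offset-adjusted global transforms (as returned in
#'   `warp_stack()$transforms`).
#' @param canvas canvas size (rows, cols).
#' @param slice_dim original slice size (rows, cols); defaults to `canvas`.
#' @param override optional manual box `list(x0, y0, x1, y1)`.
#' @return box `list(x0, y0, x1, y1)` in canvas pixel coordinates.
#' @export
compute_overlap_crop <- function(transforms, canvas, slice_dim = canvas,
                                 override = NULL) {
  if (!is.null(override)) {
    stopifnot(override$x0 >= 1, override$y0 >= 1,
              override$x1 <= canvas[2], override$y1 <= canvas[1],
              override$x0 <= override$x1, override$y0 <= override$y1)
    return(override)
  }
  inter <- matrix(TRUE, canvas[1], canvas[2])
  ones <- matrix(1, slice_dim[1], slice_dim[2])
  for (tf in transforms)
    inter <- inter & (warp_image(ones, tf, canvas, "nearest") > 0.5)
  if (!any(inter)) .stopf("warped slice footprints have empty intersection")
  r <- .largest_rect_cpp(inter)
  list(x0 = r[2], y0 = r[1], x1 = r[2] + r[4] - 1L, y1 = r[1] + r[3] - 1L)
}

#' Select the alignment-error tolerance by nuclear cross-correlation
#'
#' For each candidate `max_epsilon`, the full alignment is run and the mean
#' Pearson correlation between consecutive aligned nuclear-channel slices is
#' computed over a centred region of interest. The candidate with the highest
#' mean correlation wins; near-ties (within `tol`) go to the smallest
#' epsilon. Candidates for which registration fails are skipped.
#'
#' @param candidates numeric vector of max_epsilon values (pixels).
#' @param stack a padded `ImageStack`.
#' @param ref_channel channel used for registration.
#' @param nuclear_channel channel used for the correlation score.
#' @param params a [registration_params()].
#' @param tol tie tolerance on the mean correlation.
#' @return list: `max_epsilon` (selected), `scores` (named vector of mean
#'   correlations, `NA` where alignment failed).
#' @export
select_max_epsilon <- function(candidates, stack, ref_channel,
                               nuclear_channel,
                               params = registration_params(),
                               tol = 1e-6) {
  if (!length(candidates)) .stopf("no max_epsilon candidates")
  candidates <- sort(candidates)
  scores <- rep(NA_real_, length(candidates))
  names(scores) <- candidates
  for (i in seq_along(candidates)) {
    pi <- params
    pi$max_epsilon <- candidates[i]
    reg <- tryCatch(register_stack(stack, ref_channel, pi),
                    error = function(e) NULL)
    if (is.null(reg)) next
    w <- warp_stack(stack, reg$global, pi)
    vol <- stack_channel(w$stack, nuclear_channel, "real")
    scores[i] <- mean_consecutive_cc(vol, roi_frac = params$roi_frac)
  }
  if (all(is.na(scores))) .stopf("alignment failed for all candidates")
  best <- max(scores, na.rm = TRUE)
  sel <- candidates[which(!is.na(scores) & scores >= best - tol)[1]]
  list(max_epsilon = sel, scores = scores)
}

#' Mean Pearson correlation of consecutive slices over a centred ROI
#'
#' Constant-image pairs contribute 0.
#'
#' @param vol (y, x, z) volume.
#' @param roi_frac centred fraction of each in-plane dimension.
#' @return mean correlation over all consecutive slice pairs.
#' @export
mean_consecutive_cc <- function(vol, roi_frac = 0.25) {
  d <- dim(vol)
  ry <- max(1, floor(d[1] * (1 - roi_frac) / 2)) + seq_len(max(1, round(d[1] * roi_frac)))
  rx <- max(1, floor(d[2] * (1 - roi_frac) / 2)) + seq_len(max(1, round(d[2] * roi_frac)))
  ry <- ry[ry <= d[1]]; rx <- rx[rx <= d[2]]
  ccs <- vapply(seq_len(d[3] - 1L), function(z) {
    a <- as.vector(vol[ry, rx, z]); b <- as.vector(vol[ry, rx, z + 1])
    if (sd(a) < 1e-12 || sd(b) < 1e-12) return(0)
    cor(a, b)
  }, 1)
  mean(ccs)
}

#' Serialize transforms to JSON (per slice: theta_deg, scale, tx, ty)
#' @param transforms list of `similarity_transform`s.
#' @param path output JSON path.
#' @export
write_transforms <- function(transforms, path) {
  x <- lapply(transforms, function(tf)
    list(theta_deg = tf$theta * 180 / pi, scale = tf$scale,
         tx = tf$tx, ty = tf$ty))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(e)
    similarity_transform(e$theta_deg * pi / 180, e$scale, e$tx, e$ty))
}
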