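## 3D nuclear segmentation of the aligned iridium channel: artificial mean
## slices for ~1 um isotropic voxels, clipping + sqrt-histogram equalization,
## background cutoff, CLAHE + local contrast normalisation, 3D median +
## Gaussian smoothing, per-slice difference of Gaussians, hierarchical
## watershed, and rule-based mask post-processing.

#' Preprocessing parameters for nuclear segmentation
#'
#' @param clip_cap raw ion counts are clipped at this value before
#'   equalization (suppresses bright outliers).
#' @param heq_noise fraction of the brightest pixel mass saturated during
#'   sqrt-histogram equalization.
#' @param background_cutoff intensity (16-bit scale, after equalization)
#'   below which pixels are zeroed. Dataset-specific; no default — it must be
#'   chosen by inspecting the equalized image.
#' @param clahe_block,clahe_slope,clahe_bins CLAHE tile size (px), clip
#'   slope and histogram bins.
#' @param lcn_block,lcn_sd local-contrast-normalisation block radius (px)
#'   and the number of standard deviations mapped to the output range.
#' @param gauss_sigma sigma (px) of the 3D Gaussian blur after the 3x3x3
#'   median filter.
#' @param dog_sigma_low,dog_sigma_high sigmas of the per-slice difference of
#'   Gaussians fed to the watershed.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(clip_cap = 50, heq_noise = 0.003,
                              background_cutoff = NULL,
                              clahe_block = 29, clahe_slope = 10,
                              clahe_bins = 256,
                              lcn_block = 10, lcn_sd = 3,
                              gauss_sigma = 1,
                              dog_sigma_low = 2, dog_sigma_high = 3) {
  stopifnot(dog_sigma_low < dog_sigma_high, clip_cap > 0, heq_noise >= 0)
  structure(list(clip_cap = clip_cap, heq_noise = heq_noise,
                 background_cutoff = background_cutoff,
                 clahe_block = clahe_block, clahe_slope = clahe_slope,
                 clahe_bins = clahe_bins, lcn_block = lcn_block,
                 lcn_sd = lcn_sd, gauss_sigma = gauss_sigma,
                 dog_sigma_low = dog_sigma_low,
                 dog_sigma_high = dog_sigma_high),
            class = "preprocess_params")
}

#' Watershed parameters
#'
#' @param background_threshold watershed background level on the 16-bit
#'   landscape scale; only voxels above it are flooded.
#' @param flooding_percent basin flooding percentage: a basin with seed peak
#'   p keeps voxels with intensity >= p - f/100 * (p - background).
#' @param seed_dynamics_h h-maxima dynamics for seed suppression; default 5%
#'   of the 16-bit range.
#' @return list of class `watershed_params`.
#' @export
watershed_params <- function(background_threshold = 500,
                             flooding_percent = 90,
                             seed_dynamics_h = 0.05 * 65535) {
  stopifnot(flooding_percent > 0, flooding_percent <= 100)
  structure(list(background_threshold = background_threshold,
                 flooding_percent = flooding_percent,
                 seed_dynamics_h = seed_dynamics_h),
            class = "watershed_params")
}

#' Insert artificial mean slices between consecutive real slices
#'
#' Between each pair of consecutive real 2-um sections an artificial slice
#' equal to their voxelwise mean is inserted, yielding an approximately
#' isotropic ~1 um stack for segmentation (n real slices become 2n - 1).
#' Artificial slices are used for segmentation only, never for measurement.
#'
#' @param slices list of real-slice matrices (no missing entries).
#' @return list with `slices` (expanded list) and `flags`
#'   (`"real"`/`"artificial"` per slice).
#' @export
insert_mean_slices <- function(slices) {
  n <- length(slices)
  if (n < 2) .stopf("need at least 2 real slices for 3D context")
  out <- vector("list", 2L * n - 1L)
  flags <- rep(c("real", "artificial"), length.out = 2L * n - 1L)
  for (i in seq_len(n)) out[[2L * i - 1L]] <- slices[[i]]
  for (i in seq_len(n - 1L))
    out[[2L * i]] <- (slices[[i]] + slices[[i + 1L]]) / 2
  list(slices = out, flags = flags)
}

#' Clip and sqrt-histogram equalize
#'
#' Intensities are clipped at `clip_cap`, then equalized with a cumulative
#' mapping built on the square roots of the histogram counts — a compromise
#' between classical equalization and no equalization that enhances detail
#' without extreme stretching. The brightest `heq_noise` fraction of the
#' pixel mass saturates at the top of the 16-bit output range. One histogram
#' is built over the whole input (2D image or 3D stack), so slices keep
#' their relative brightness. The mapping is monotone non-decreasing.
#'
#' @param x numeric matrix or 3D array of non-negative counts.
#' @param params a [preprocess_params()].
#' @return equalized array on the 16-bit scale, same shape as `x`.
#' @export
clip_and_equalize <- function(x, params = preprocess_params()) {
  v <- pmin(x, params$clip_cap)
  vals <- sort(unique(as.vector(v)))
  if (length(vals) == 1L) return(v * 0 + 32768)
  h <- tabulate(match(as.vector(v), vals), nbins = length(vals))
  ## saturate the brightest heq_noise fraction of pixel mass
  upper_mass <- rev(cumsum(rev(h))) / sum(h)
  sat <- upper_mass <= params$heq_noise
  hs <- sqrt(h)
  hs[sat] <- 0
  cdf <- cumsum(hs)
  if (max(cdf) == 0) return(v * 0 + 32768)
  map <- cdf / max(cdf) * 65535
  map[sat] <- 65535
  out <- map[match(as.vector(v), vals)]
  array(out, dim = if (is.null(dim(x))) length(x) else dim(x))
}

#' Zero all pixels below a background cutoff
#'
#' Equalization amplifies background noise; pixels below the cutoff are set
#' to zero and pixels at or above it are unchanged. The cutoff is
#' dataset-specific (chosen by inspecting the equalized image) and must be
#' supplied explicitly.
#'
#' @param x numeric array (any shape).
#' @param cutoff intensity threshold on the equalized 16-bit scale.
#' @return array with sub-cutoff pixels zeroed.
#' @export
suppress_background <- function(x, cutoff) {
  if (missing(cutoff) || is.null(cutoff) || !is.finite(cutoff))
    .stopf(paste("background_cutoff is required: inspect the equalized",
                 "nuclear channel and supply an explicit cutoff",
                 "(there is no safe default)"))
  x[x < cutoff] <- 0
  x
}

#' CLAHE followed by local contrast normalisation
#'
#' Contrast-limited adaptive histogram equalization (tile size
#' `clahe_block`, clip slope `clahe_slope`, `clahe_bins` bins) flattens
#' slice-to-slice staining variation; the subsequent local contrast
#' normalisation maps, per pixel, the band mean +/- `lcn_sd` local standard
#' deviations (box radius `lcn_block`) onto the 16-bit range, clamped.
#' Pixels in perfectly flat neighbourhoods are returned unchanged.
#'
#' @param img numeric matrix on the 16-bit scale.
#' @param params a [preprocess_params()].
#' @return normalised matrix on the 16-bit scale.
#' @export
local_normalize <- function(img, params = preprocess_params()) {
  if (max(img) <= min(img)) return(img)
  x <- img / 65535
  nx <- max(2L, round(ncol(img) / params$clahe_block))
  ny <- max(2L, round(nrow(img) / params$clahe_block))
  ## EBImage images are (x, y); transpose in and out
  cl <- tryCatch(
    t(as.matrix(EBImage::clahe(t(x), nx = nx, ny = ny,
                               bins = params$clahe_bins,
                               limit = params$clahe_slope))),
    error = function(e) x)
  cl <- pmin(pmax(cl, 0), 1) * 65535
  ## local contrast normalisation with box statistics
  r <- params$lcn_block
  box <- function(m) {
    k <- rep(1 / (2 * r + 1), 2 * r + 1)
    .conv_margin(.conv_margin(m, k, 1L), k, 2L)
  }
  mu <- box(cl)
  sg <- sqrt(pmax(box(cl^2) - mu^2, 0))
  lo <- mu - params$lcn_sd * sg
  span <- 2 * params$lcn_sd * sg
  out <- ifelse(span > 1e-9, (cl - lo) / span * 65535, cl)
  pmin(pmax(out, 0), 65535)
}

#' 3D median + Gaussian smoothing, then per-slice difference of Gaussians
#'
#' A 3x3x3 median filter and a 3D Gaussian blur (`gauss_sigma`) integrate
#' information across the ~1 um isotropic stack; the per-slice difference of
#' Gaussians (`dog_sigma_low` minus `dog_sigma_high`) then produces the
#' blob-enhancing landscape for the watershed. Negative DoG responses are
#' clamped to zero and the result is rescaled per volume so its maximum hits
#' the top of the 16-bit range (keeping the watershed background threshold
#' meaningful).
#'
#' @param vol (y, x, z) volume (expanded, approximately isotropic).
#' @param params a [preprocess_params()].
#' @return landscape volume on the 16-bit scale.
#' @export
smooth_and_dog <- function(vol, params = preprocess_params()) {
  sm <- .median3_cpp(vol, dim(vol))
  sm <- .blur3d(sm, params$gauss_sigma)
  dog <- array(0, dim(vol))
  for (z in seq_len(dim(vol)[3])) {
    s <- sm[, , z]
    dog[, , z] <- .blur2d(s, params$dog_sigma_low) -
      .blur2d(s, params$dog_sigma_high)
  }
  ## clamp negatives and floating-point residue of the separable filters
  dog[dog < 1e-9 * max(abs(sm), 1)] <- 0
  mx <- max(dog)
  if (mx > 0) dog <- dog / mx * 65535
  dog
}

#' Hierarchical 3D watershed
#'
#' Seeds are regional maxima of the landscape that survive h-maxima
#' suppression (dynamics >= `seed_dynamics_h`) and exceed the background
#' threshold. Watershed-by-flooding assigns every above-background voxel to a
#' seed's catchment basin (6-connectivity); each basin is then restricted by
#' the flooding rule: voxel v is kept iff I(v) >= p - f * (p - bg), with p
#' the seed peak intensity and f the flooding fraction. Every returned
#' object contains exactly one seed.
#'
#' @param landscape (y, x, z) numeric volume on the 16-bit scale.
#' @param params a [watershed_params()].
#' @return integer label volume, attribute `seeds` = linear indices of
#'   seeds; empty (with a warning) when no seed is found.
#' @export
h_watershed_3d <- function(landscape, params = watershed_params()) {
  labs <- .hwatershed_cpp(landscape, dim(landscape),
                          params$seed_dynamics_h,
                          params$background_threshold,
                          params$flooding_percent / 100)
  if (!length(attr(labs, "seeds")))
    warning("no watershed seed found above the background threshold")
  labs
}

#' Post-process a watershed label volume into the final cell mask
#'
#' Artificial-slice planes are dropped first, then five rules are applied in
#' order on the real-slice volume: (1) objects with <= 10 voxels are
#' removed; (2) objects disconnected in-plane keep only the largest
#' component per slice; (3) all labels are expanded by 1 pixel in-plane into
#' background (collisions go to the nearest label, ties to the lower id);
#' (4) objects smaller than 21 voxels are removed; (5) objects whose mean
#' raw nuclear signal is below 1 count are removed. Finally the volume is
#' cropped to the stack overlap box and labels are renumbered contiguously.
#'
#' @param labels integer (y, x, z) label volume on the expanded stack.
#' @param flags per-slice flags of the expanded stack
#'   (`"real"`/`"artificial"`).
#' @param raw_nuclear (y, x, z) raw aligned nuclear-channel volume on the
#'   real slices (unprocessed counts; used by rule 5).
#' @param crop overlap box `list(x0, y0, x1, y1)` or `NULL` for no crop.
#' @return final integer label volume on the real slices.
#' @export
finalize_mask <- function(labels, flags = NULL, raw_nuclear = NULL,
                          crop = NULL) {
  if (!is.null(flags)) {
    if (length(flags) != dim(labels)[3])
      .stopf("flags length must match the number of planes")
    labels <- labels[, , flags == "real", drop = FALSE]
  }
  d <- dim(labels)
  ## rule 1: drop objects of <= 10 voxels
  labels <- .drop_small(labels, min_vox = 11L)
  ## rule 2: keep only the largest in-plane component per object per slice
  for (z in seq_len(d[3])) {
    pl <- labels[, , z]
    if (!any(pl > 0)) next
    cc <- .label2d_cpp(pl, 8L)
    ncc <- max(cc)
    if (ncc == 0) next
    csize <- tabulate(cc[cc > 0], nbins = ncc)
    clab <- integer(ncc)
    clab[cc[cc > 0]] <- pl[cc > 0]              # label of each component
    keep <- tapply(seq_len(ncc), clab, function(ii) ii[which.max(csize[ii])])
    drop_comp <- setdiff(seq_len(ncc), unlist(keep))
    if (length(drop_comp)) {
      pl[cc %in% drop_comp] <- 0L
      labels[, , z] <- pl
    }
  }
  ## rule 3: expand labels by 1 px in-plane into background; nearest label
  ## wins and at equal distance the lower label id wins
  for (z in seq_len(d[3])) {
    pl <- labels[, , z]
    if (!any(pl > 0)) next
    cand <- matrix(Inf, d[1], d[2])
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      s <- .shift2d(pl, sh[1], sh[2], fill = 0)
      s[s == 0] <- Inf
      cand <- pmin(cand, s)
    }
    grow <- pl == 0 & is.finite(cand)
    pl[grow] <- as.integer(cand[grow])
    labels[, , z] <- pl
  }
  ## rule 4: drop objects below 21 voxels
  labels <- .drop_small(labels, min_vox = 21L)
  ## rule 5: drop objects with raw mean nuclear signal below 1
  if (!is.null(raw_nuclear)) {
    if (!all(dim(raw_nuclear) == dim(labels)))
      .stopf("raw nuclear volume must match the real-slice label volume")
    idx <- which(labels > 0)
    if (length(idx)) {
      l <- labels[idx]
      mns <- rowsum(raw_nuclear[idx], l) / as.vector(table(l))
      bad <- as.integer(rownames(mns))[mns[, 1] < 1]
      if (length(bad)) labels[labels %in% bad] <- 0L
    }
  }
  ## crop to the overlap box
  if (!is.null(crop)) {
    if (crop$x1 < crop$x0 || crop$y1 < crop$y0) .stopf("empty crop box")
    labels <- labels[crop$y0:crop$y1, crop$x0:crop$x1, , drop = FALSE]
  }
  labels <- .renumber(labels)
  storage.mode(labels) <- "integer"
  labels
}

#' @noRd
.drop_small <- function(labels, min_vox) {
  if (!any(labels > 0)) return(labels)
  sizes <- table(labels[labels > 0])
  bad <- as.integer(names(sizes))[sizes < min_vox]
  if (length(bad)) labels[labels %in% bad] <- 0L
  labels
}

#' @noRd
.renumber <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(labels)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  pos <- labels > 0
  labels[pos] <- lut[labels[pos]]
  labels
}

#' Segmentation quality diagnostics
#'
#' Reports, per object: voxel volume, z extent, and the mean of the
#' major/minor axis lengths of the second-moment ellipse in the x-y and the
#' x-z planes (z converted to micrometres with the slice spacing). Also
#' reports, per slice (excluding the first and last), the fraction of
#' objects confined to that single slice — objects should normally extend
#' over several 2-um sections.
#'
#' @param labels final (y, x, z) label volume on the real slices.
#' @param spacing `(dx, dy, dz)` in micrometres.
#' @return list with `per_object` and `single_slice` data.frames.
#' @export
mask_quality_report <- function(labels, spacing = c(1, 1, 2)) {
  idx <- which(labels > 0)
  if (!length(idx))
    return(list(per_object = data.frame(), single_slice = data.frame()))
  d <- dim(labels)
  ai <- arrayInd(idx, d)
  l <- labels[idx]
  xu <- (ai[, 2] - 1) * spacing[1]
  yu <- (ai[, 1] - 1) * spacing[2]
  zu <- (ai[, 3] - 1) * spacing[3]
  n <- as.vector(table(l))
  ids <- as.integer(names(table(l)))
  sum_by <- function(v) rowsum(v, l)[, 1]
  axy <- .axis_lengths(sum_by(xu), sum_by(yu), sum_by(xu^2), sum_by(yu^2),
                       sum_by(xu * yu), n)
  axz <- .axis_lengths(sum_by(xu), sum_by(zu), sum_by(xu^2), sum_by(zu^2),
                       sum_by(xu * zu), n)
  zmin <- tapply(ai[, 3], l, min)
  zmax <- tapply(ai[, 3], l, max)
  per_object <- data.frame(
    cell_id = ids, volume = n,
    axis_xy = rowMeans(axy), axis_xz = rowMeans(axz),
    z_min = as.integer(zmin), z_max = as.integer(zmax))
  interior <- seq_len(d[3])[-c(1, d[3])]
  single <- per_object$z_min == per_object$z_max
  single_slice <- do.call(rbind, lapply(interior, function(z) {
    on <- per_object$z_min <= z & per_object$z_max >= z
    data.frame(slice = z, n_objects = sum(on),
               n_single = sum(on & single & per_object$z_min == z),
               fraction_single = if (any(on))
                 sum(on & single & per_object$z_min == z) / sum(on) else 0)
  }))
  list(per_object = per_object, single_slice = single_slice)
}

#' Run the full nuclear-segmentation recipe on an aligned nuclear channel
#'
#' Convenience orchestrator: mean-slice insertion, clipping + equalization,
#' background suppression, per-slice CLAHE + local contrast normalisation,
#' 3D median + Gaussian smoothing, per-slice difference of Gaussians,
#' hierarchical watershed and mask finalization.
#'
#' @param nuclear_slices list of aligned raw nuclear-channel matrices (real
#'   slices, in order).
#' @param pre a [preprocess_params()] with an explicit `background_cutoff`.
#' @param ws a [watershed_params()].
#' @param crop optional overlap box for [finalize_mask()].
#' @return final integer label volume (y, x, z) on the real slices.
#' @export
segment_nuclei <- function(nuclear_slices, pre = preprocess_params(),
                           ws = watershed_params(), crop = NULL) {
  exp_ <- insert_mean_slices(nuclear_slices)
  d <- dim(exp_$slices[[1]])
  vol <- array(unlist(exp_$slices, use.names = FALSE),
               c(d, length(exp_$slices)))
  vol <- clip_and_equalize(vol, pre)
  vol <- suppress_background(vol, pre$background_cutoff)
  for (z in seq_len(dim(vol)[3]))
    vol[, , z] <- local_normalize(vol[, , z], pre)
  landscape <- smooth_and_dog(vol, pre)
  labs <- h_watershed_3d(landscape, ws)
  raw <- array(unlist(nuclear_slices, use.names = FALSE),
               c(d, length(nuclear_slices)))
  finalize_mask(labs, exp_$flags, raw, crop)
}
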