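## Synthetic serial-section tissue phantom with full ground truth.
## The phantom emulates the structure of measured serial-section IMC data:
## ellipsoidal nuclei of several cell types with type-specific marker
## signatures and a cytoplasmic halo, tubular vessels emitting in the vessel
## channels, integration of the 1-um voxel volume into 2-um sections,
## per-slice gain jitter and rigid/similarity misalignment, channel
## spillover, Poisson count noise and isolated hot pixels.

#' Default six-channel phantom panel
#'
#' Iridium DNA intercalator (nuclear), smooth muscle actin (registration
#' reference), a combined vWF/CD31 endothelial channel (vessels) and three
#' lineage markers.
#'
#' @return an `imc_panel`.
#' @export
default_phantom_panel <- function() {
  panel(channel_id = c("Ir191", "SMA", "vWF", "panCK", "CD45", "CD68"),
        metal_tag = c("Ir191", "Pr141", "Yb173", "Lu175", "Sm152", "Tb159"),
        target = c("DNA", "SMA", "vWF_CD31", "panCK", "CD45", "CD68"),
        role = c("nuclear", "reference", "vessel", "marker", "marker",
                 "marker"))
}

#' Default phantom cell-type table
#'
#' Four types with breast-carcinoma-like frequencies and marker signatures
#' (mean ion counts in the marker-bearing region): panCK+ epithelial, SMA+
#' stromal, CD45+ lymphocyte and CD45+CD68+ macrophage. All types share the
#' iridium nuclear signal.
#'
#' @return data.frame with columns `type`, `freq`, `r_min`, `r_max`
#'   (nucleus radius range, micrometres) and one column per channel.
#' @export
default_cell_types <- function() {
  data.frame(
    type = c("epithelial", "stromal", "lymphocyte", "macrophage"),
    freq = c(0.45, 0.30, 0.18, 0.07),
    r_min = c(3.0, 2.6, 2.2, 2.4),
    r_max = c(4.2, 3.6, 3.0, 3.4),
    Ir191 = c(30, 30, 30, 30),
    SMA = c(0.4, 20, 0.3, 0.4),
    vWF = c(0.2, 0.3, 0.2, 0.3),
    panCK = c(25, 0.3, 0.2, 0.3),
    CD45 = c(0.3, 0.4, 22, 12),
    CD68 = c(0.2, 0.3, 1.5, 18))
}

#' Default phantom spillover matrix
#'
#' Small nearest-neighbour channel crosstalk (4% up, 1% down in panel
#' order), the magnitude typical of adjacent metal isotopes.
#'
#' @param channels channel ids.
#' @return square spillover matrix.
#' @export
default_phantom_spillover <- function(channels = default_phantom_panel()$channel_id) {
  n <- length(channels)
  S <- diag(n)
  dimnames(S) <- list(channels, channels)
  for (i in seq_len(n - 1)) {
    S[i, i + 1] <- 0.04
    S[i + 1, i] <- 0.01
  }
  S
}

#' Phantom specification
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package tests: a 150 x 150 x 44 um volume (22 sections of 2 um at 1 um
#' in-plane pixels) holding 700 nuclei — a confluent-tissue density
#' (nuclear volume fraction ~11%) at which neighbouring cells touch, as the
#' direct-neighbour statistics presuppose — plus two vessel tubes, moderate
#' per-slice gain jitter, adjacent-isotope spillover and Poisson counting
#' noise. Misalignment and hot pixels default to off; registration and
#' hot-pixel stress tests enable them explicitly.
#'
#' @param dim_um volume size `(x, y, z)` in micrometres; `z` must be an even
#'   number (2-um sections).
#' @param n_cells number of nuclei.
#' @param panel an `imc_panel`.
#' @param cell_types see [default_cell_types()].
#' @param halo_um cytoplasmic halo thickness around the nucleus carrying
#'   marker (non-nuclear) signal.
#' @param min_gap_um minimal surface gap between nuclei.
#' @param vessels list `n`, `radius_um`, `intensity` (named counts added in
#'   the named channels inside the tube).
#' @param background baseline expected counts in every channel.
#' @param gain_jitter per-slice multiplicative gain range.
#' @param misalign list `theta_deg`, `trans_px`, `scale` (= range
#'   `c(lo, hi)`): per-slice similarity corruption ranges (slice 1 stays
#'   identity).
#' @param hot_pixel_rate per-pixel probability of a planted hot pixel.
#' @param hot_pixel_amp added counts range for hot pixels.
#' @param spillover square spillover matrix over the panel channels.
#' @param noise `"poisson"` or `"none"`.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim_um = c(x = 150, y = 150, z = 44),
                         n_cells = 700,
                         panel = default_phantom_panel(),
                         cell_types = default_cell_types(),
                         halo_um = 1.5,
                         min_gap_um = 0.7,
                         vessels = list(n = 2, radius_um = 4,
                                        intensity = c(vWF = 25, SMA = 12)),
                         background = 0.1,
                         gain_jitter = c(0.85, 1.15),
                         misalign = list(theta_deg = 0, trans_px = 0,
                                         scale = c(1, 1)),
                         hot_pixel_rate = 0,
                         hot_pixel_amp = c(150, 300),
                         spillover = default_phantom_spillover(panel$channel_id),
                         noise = "poisson") {
  stopifnot(dim_um[["z"]] %% 2 == 0, n_cells > 0,
            all(cell_types$r_min <= cell_types$r_max),
            abs(sum(cell_types$freq) - 1) < 1e-6)
  structure(list(dim_um = dim_um, n_cells = n_cells, panel = panel,
                 cell_types = cell_types, halo_um = halo_um,
                 min_gap_um = min_gap_um, vessels = vessels,
                 background = background, gain_jitter = gain_jitter,
                 misalign = misalign, hot_pixel_rate = hot_pixel_rate,
                 hot_pixel_amp = hot_pixel_amp, spillover = spillover,
                 noise = noise),
            class = "phantom_spec")
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' @param spec a [phantom_spec()].
#' @param seed mandatory RNG seed; the phantom is deterministic given the
#'   seed.
#' @return list: `stack` (an `ImageStack` of 2-um sections), `truth` (list
#'   with `labels_um` 1-um nuclear label volume, `labels_sections` nuclei
#'   sampled on the section grid, `cell_labels_um` / `cell_labels_sections`
#'   whole-cell ground truth (nucleus plus cytoplasmic halo, contested halo
#'   voxels assigned to the nearest nucleus) matching what the segmentation
#'   pipeline delineates, `cells` table, `transforms` true alignment
#'   transforms per section, `vessel_mask_sections`, `panel`, `spillover`).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed) {
  if (missing(seed)) .stopf("a seed is mandatory for phantom generation")
  set.seed(seed)
  nx <- as.integer(spec$dim_um[["x"]])
  ny <- as.integer(spec$dim_um[["y"]])
  nzu <- as.integer(spec$dim_um[["z"]])
  nsec <- nzu %/% 2L
  ct <- spec$cell_types
  chans <- spec$panel$channel_id
  nuclear <- panel_channels(spec$panel, "nuclear")
  ma <- spec$misalign
  corrupt <- ma$theta_deg > 0 || ma$trans_px > 0 ||
    diff(range(ma$scale)) > 0
  ## with misalignment, the imaged field of view is a window onto larger
  ## tissue: generate on an extended canvas, corrupt there, crop at the
  ## end, so observed slices are full-field (no empty warp wedges)
  margin <- if (corrupt) {
    as.integer(ceiling(ma$trans_px +
                         sin(ma$theta_deg * pi / 180) * max(nx, ny) / 2 +
                         max(abs(ma$scale - 1)) * max(nx, ny) / 2) + 4L)
  } else 0L
  nxe <- nx + 2L * margin
  nye <- ny + 2L * margin
  n_place <- as.integer(round(spec$n_cells * (nxe * nye) / (nx * ny)))

  ## --- place ellipsoidal nuclei without overlap ------------------------
  type_idx <- sample.int(nrow(ct), n_place, replace = TRUE,
                         prob = ct$freq)
  r0 <- runif(n_place, ct$r_min[type_idx], ct$r_max[type_idx])
  fax <- matrix(runif(3 * n_place, 0.85, 1.2), ncol = 3)
  radii <- r0 * fax  # columns: rx, ry, rz
  rmax <- apply(radii, 1, max)
  centers <- matrix(NA_real_, n_place, 3)  # (x, y, z) voxel coords
  for (i in seq_len(n_place)) {
    placed <- FALSE
    for (try in seq_len(600L)) {
      cand <- c(runif(1, rmax[i] + 1, nxe - rmax[i]),
                runif(1, rmax[i] + 1, nye - rmax[i]),
                runif(1, 1.5, nzu - 0.5))
      if (i > 1) {
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        d <- sqrt(rowSums(sweep(prev, 2, cand)^2))
        if (any(d < rmax[seq_len(i - 1)] + rmax[i] + spec$min_gap_um))
          next
      }
      centers[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      .stopf(paste("could not place %d non-overlapping nuclei in the",
                   "phantom volume; lower n_cells or the radii"),
             n_place)
  }

  ## --- rasterize nuclei, halos and expected intensities ----------------
  labels_um <- array(0L, c(nye, nxe, nzu))
  cell_labels_um <- array(0L, c(nye, nxe, nzu)) # nucleus + cytoplasmic halo
  cell_q <- array(Inf, c(nye, nxe, nzu))        # contested halo voxels go to
                                                # the nearest nucleus
  E <- lapply(stats::setNames(chans, chans),
              function(ch) array(spec$background, c(nye, nxe, nzu)))
  marker_chans <- setdiff(chans, nuclear)
  for (i in seq_len(n_place)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; cz <- centers[i, 3]
    rx <- radii[i, 1]; ry <- radii[i, 2]; rz <- radii[i, 3]
    hx <- rx + spec$halo_um; hy <- ry + spec$halo_um; hz <- rz + spec$halo_um
    xs <- max(1, floor(cx - hx)):min(nxe, ceiling(cx + hx))
    ys <- max(1, floor(cy - hy)):min(nye, ceiling(cy + hy))
    zs <- max(1, floor(cz - hz)):min(nzu, ceiling(cz + hz))
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    box_n <- length(xs) * length(ys)
    for (z in zs) {
      q_n <- ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 + ((z - cz) / rz)^2
      q_h <- ((gx - cx) / hx)^2 + ((gy - cy) / hy)^2 + ((z - cz) / hz)^2
      in_n <- q_n <= 1
      in_h <- q_h <= 1
      if (any(in_n)) {
        idx <- cbind(gy[in_n], gx[in_n], z)
        labels_um[idx] <- i
        E[[nuclear]][idx] <- E[[nuclear]][idx] + ct[[nuclear]][type_idx[i]]
      }
      if (any(in_h)) {
        idx <- cbind(gy[in_h], gx[in_h], z)
        for (ch in marker_chans)
          E[[ch]][idx] <- E[[ch]][idx] + ct[[ch]][type_idx[i]]
        closer <- q_h[in_h] < cell_q[idx]
        if (any(closer)) {
          idc <- idx[closer, , drop = FALSE]
          cell_q[idc] <- q_h[in_h][closer]
          cell_labels_um[idc] <- i
        }
      }
    }
  }

  ## --- vessel tubes ----------------------------------------------------
  vessel_mask <- array(FALSE, c(nye, nxe, nzu))
  if (spec$vessels$n > 0) {
    for (v in seq_len(spec$vessels$n)) {
      nway <- 4L
      wx <- seq(1, nxe, length.out = nway)
      wy <- runif(nway, 0.25 * nye, 0.75 * nye)
      wz <- runif(nway, 0.25 * nzu, 0.75 * nzu)
      yc <- approx(wx, wy, xout = seq_len(nxe))$y
      zc <- approx(wx, wz, xout = seq_len(nxe))$y
      rr <- spec$vessels$radius_um
      for (x in seq_len(nxe)) {
        ys <- max(1, floor(yc[x] - rr)):min(nye, ceiling(yc[x] + rr))
        zs <- max(1, floor(zc[x] - rr)):min(nzu, ceiling(zc[x] + rr))
        gy <- rep(ys, times = length(zs))
        gz <- rep(zs, each = length(ys))
        inside <- (gy - yc[x])^2 + (gz - zc[x])^2 <= rr^2
        if (any(inside)) {
          idx <- cbind(gy[inside], x, gz[inside])
          vessel_mask[idx] <- TRUE
          for (ch in names(spec$vessels$intensity))
            E[[ch]][idx] <- E[[ch]][idx] + spec$vessels$intensity[[ch]]
        }
      }
    }
  }

  ## --- integrate 1-um planes into 2-um sections ------------------------
  secs <- lapply(E, function(vol) {
    lapply(seq_len(nsec), function(s)
      (vol[, , 2 * s - 1] + vol[, , 2 * s]) / 2)
  })

  ## --- per-slice gain jitter -------------------------------------------
  gains <- runif(nsec, spec$gain_jitter[1], spec$gain_jitter[2])
  for (ch in chans) for (s in seq_len(nsec))
    secs[[ch]][[s]] <- secs[[ch]][[s]] * gains[s]

  ## --- per-slice similarity misalignment -------------------------------
  centre <- c((nxe + 1) / 2, (nye + 1) / 2)
  shift_in <- similarity_transform(0, 1, margin, margin)
  shift_out <- similarity_transform(0, 1, -margin, -margin)
  transforms <- vector("list", nsec)
  for (s in seq_len(nsec)) {
    if (s == 1 || !corrupt) {
      transforms[[s]] <- similarity_transform()
      next
    }
    th <- runif(1, -ma$theta_deg, ma$theta_deg) * pi / 180
    tr <- runif(2, -ma$trans_px, ma$trans_px)
    sc <- runif(1, ma$scale[1], ma$scale[2])
    C <- .similarity_about(th, sc, tr[1], tr[2], centre)
    for (ch in chans)
      secs[[ch]][[s]] <- warp_image(secs[[ch]][[s]], C, c(nye, nxe),
                                    "linear")
    ## alignment truth in field-of-view coordinates
    transforms[[s]] <- compose_transform(
      shift_out, compose_transform(invert_transform(C), shift_in))
  }

  ## --- spillover mixing -------------------------------------------------
  S <- spec$spillover[chans, chans]
  mixed <- lapply(stats::setNames(chans, chans), function(ch) {
    lapply(seq_len(nsec), function(s) {
      out <- 0
      for (src in chans) if (S[src, ch] != 0)
        out <- out + S[src, ch] * secs[[src]][[s]]
      out
    })
  })

  ## --- count noise, then hot pixels (separate RNG phases, so a phantom
  ## with hot pixels disabled shares the noise realisation) ---------------
  for (ch in chans) for (s in seq_len(nsec)) {
    img <- mixed[[ch]][[s]]
    if (identical(spec$noise, "poisson"))
      img <- matrix(as.double(rpois(length(img), pmax(img, 0))), nye, nxe)
    mixed[[ch]][[s]] <- img
  }
  if (spec$hot_pixel_rate > 0) {
    for (ch in chans) for (s in seq_len(nsec)) {
      img <- mixed[[ch]][[s]]
      hot <- which(runif(length(img)) < spec$hot_pixel_rate)
      if (length(hot))
        img[hot] <- img[hot] + round(runif(length(hot),
                                           spec$hot_pixel_amp[1],
                                           spec$hot_pixel_amp[2]))
      mixed[[ch]][[s]] <- img
    }
  }

  ## --- crop the field of view out of the extended canvas ---------------
  fov_y <- margin + seq_len(ny)
  fov_x <- margin + seq_len(nx)
  if (margin > 0) {
    mixed <- lapply(mixed, function(ch)
      lapply(ch, function(img) img[fov_y, fov_x]))
    labels_um <- labels_um[fov_y, fov_x, , drop = FALSE]
    cell_labels_um <- cell_labels_um[fov_y, fov_x, , drop = FALSE]
    vessel_mask <- vessel_mask[fov_y, fov_x, , drop = FALSE]
  }
  stack <- image_stack(mixed, chans, seq_len(nsec),
                       rep("real", nsec), c(1, 1, 2))

  ## --- ground truth -----------------------------------------------------
  sec_planes <- seq(1, 2 * nsec, by = 2)
  idx <- which(labels_um > 0)
  l <- labels_um[idx]
  ai <- arrayInd(idx, dim(labels_um))
  nvox <- as.vector(table(l))
  cells <- data.frame(
    cell_id = sort(unique(l)),
    type = ct$type[type_idx[sort(unique(l))]],
    centroid_x = (rowsum(ai[, 2], l)[, 1] / nvox - 1),
    centroid_y = (rowsum(ai[, 1], l)[, 1] / nvox - 1),
    centroid_z = (rowsum(ai[, 3], l)[, 1] / nvox - 1),
    volume_um3 = nvox,
    r_x = radii[sort(unique(l)), 1],
    r_y = radii[sort(unique(l)), 2],
    r_z = radii[sort(unique(l)), 3])
  truth <- list(labels_um = labels_um,
                labels_sections = labels_um[, , sec_planes, drop = FALSE],
                cell_labels_um = cell_labels_um,
                cell_labels_sections = cell_labels_um[, , sec_planes,
                                                      drop = FALSE],
                cells = cells,
                transforms = transforms,
                gains = gains,
                vessel_mask_sections = vessel_mask[, , sec_planes,
                                                   drop = FALSE],
                panel = spec$panel,
                spillover = S)
  list(stack = stack, truth = truth)
}

#' Planted expression phantom for clustering tests
#'
#' Draws `n` cells from the phantom cell types and simulates the quantity a
#' cell catalog actually holds: the per-cell *mean* ion count per channel,
#' i.e. a Poisson total over the cell's voxels divided by the voxel count.
#' A per-cell log-normal size factor models staining heterogeneity. (Raw
#' single-pixel draws would be heavily tied integers; means over tens of
#' voxels are quasi-continuous, like measured catalogs.)
#'
#' @param n number of cells.
#' @param seed RNG seed.
#' @param cell_types see [default_cell_types()].
#' @param channels channels to simulate (default: all type channels).
#' @param size_factor_sd standard deviation of the log size factor.
#' @param volume_range per-cell voxel-count range (uniform).
#' @return list: `expr` (cells x channels matrix of mean counts), `type`
#'   (true type per cell).
#' @export
generate_expression_phantom <- function(n = 2000, seed,
                                        cell_types = default_cell_types(),
                                        channels = NULL,
                                        size_factor_sd = 0.25,
                                        volume_range = c(40, 200)) {
  if (missing(seed)) .stopf("a seed is mandatory")
  set.seed(seed)
  if (is.null(channels))
    channels <- setdiff(names(cell_types),
                        c("type", "freq", "r_min", "r_max"))
  type_idx <- sample.int(nrow(cell_types), n, replace = TRUE,
                         prob = cell_types$freq)
  sf <- exp(rnorm(n, 0, size_factor_sd))
  vol <- round(runif(n, volume_range[1], volume_range[2]))
  mu <- as.matrix(cell_types[type_idx, channels]) * sf * vol
  expr <- matrix(rpois(length(mu), mu), n, length(channels)) / vol
  colnames(expr) <- channels
  list(expr = expr, type = cell_types$type[type_idx])
}

#' Match predicted against ground-truth objects
#'
#' Greedy one-to-one matching by descending intersection-over-union.
#' Reports object-level recall, precision, mean matched IoU, and split /
#' merge counts (a truth object is split when two or more predictions reach
#' the IoU threshold with it, and vice versa for merges).
#'
#' @param truth,predicted integer label volumes of equal shape.
#' @param iou_threshold minimal IoU for a valid match.
#' @return list: `metrics` (recall, precision, mean_iou, n_truth, n_pred,
#'   splits, merges), `matches` (data.frame truth_id, pred_id, iou).
#' @export
match_objects <- function(truth, predicted, iou_threshold = 0.3) {
  stopifnot(all(dim(truth) == dim(predicted)))
  tsz <- table(truth[truth > 0])
  psz <- table(predicted[predicted > 0])
  both <- which(truth > 0 & predicted > 0)
  empty <- list(metrics = list(recall = 0, precision = 0, mean_iou = NA,
                               n_truth = length(tsz), n_pred = length(psz),
                               splits = 0, merges = 0),
                matches = data.frame(truth_id = integer(),
                                     pred_id = integer(), iou = numeric()))
  if (!length(both)) return(empty)
  ov <- table(truth[both], predicted[both])
  iou <- matrix(0, nrow(ov), ncol(ov), dimnames = dimnames(ov))
  tn <- as.numeric(tsz[rownames(ov)])
  pn <- as.numeric(psz[colnames(ov)])
  iou <- ov / (outer(tn, pn, `+`) - ov)
  cand <- which(iou >= iou_threshold, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-iou[cand]), , drop = FALSE]
  used_t <- used_p <- character(0)
  matches <- NULL
  for (i in seq_len(nrow(cand))) {
    tr <- rownames(iou)[cand[i, 1]]
    pr <- colnames(iou)[cand[i, 2]]
    if (tr %in% used_t || pr %in% used_p) next
    used_t <- c(used_t, tr)
    used_p <- c(used_p, pr)
    matches <- rbind(matches,
                     data.frame(truth_id = as.integer(tr),
                                pred_id = as.integer(pr),
                                iou = iou[cand[i, 1], cand[i, 2]]))
  }
  hits_per_truth <- table(rownames(iou)[cand[, 1]])
  hits_per_pred <- table(colnames(iou)[cand[, 2]])
  list(metrics = list(recall = nrow(matches) / length(tsz),
                      precision = nrow(matches) / length(psz),
                      mean_iou = mean(matches$iou),
                      n_truth = length(tsz), n_pred = length(psz),
                      splits = sum(hits_per_truth >= 2),
                      merges = sum(hits_per_pred >= 2)),
       matches = matches)
}
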