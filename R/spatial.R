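## 3D-versus-2D spatial statistics: vessel masks by automatic entropy
## thresholding, centroid-to-structure distances, region-adjacency-graph
## neighbour proportions, and radius-based microenvironment queries.

#' Automatic threshold maximising Renyi entropy
#'
#' Implements the three-estimate procedure of Sahoo et al. (1997), the
#' algorithm behind the ImageJ "RenyiEntropy" auto-threshold: entropic
#' thresholds for Renyi orders 0.5, 1 (Shannon/Kapur limit) and 2 are
#' combined with the published weighting. A pure Kapur mode using only the
#' Shannon threshold is available as an alternative.
#'
#' @param x numeric vector/array of intensities.
#' @param bins number of histogram bins.
#' @param method `"sahoo"` (default) or `"kapur"`.
#' @return threshold on the intensity scale of `x`: foreground is `x >`
#'   threshold.
#' @export
renyi_threshold <- function(x, bins = 256, method = c("sahoo", "kapur")) {
  method <- match.arg(method)
  v <- as.vector(x)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[2])  # constant input: empty foreground
  b <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins), bins - 1)
  h <- tabulate(b + 1L, nbins = bins)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P2 <- 1 - P1
  nz <- which(p > 0)
  first <- min(nz); last <- max(nz)
  it_range <- first:last
  it_range <- it_range[P1[it_range] > 1e-12 & P2[it_range] > 1e-12]
  if (!length(it_range)) return(rng[2])
  ent <- function(alpha) {
    best <- -Inf; tbest <- it_range[1]
    for (t in it_range) {
      pa <- p[1:t] / P1[t]
      pb <- p[(t + 1):bins] / P2[t]
      pa <- pa[pa > 0]; pb <- pb[pb > 0]
      tot <- if (alpha == 1) {
        -sum(pa * log(pa)) - sum(pb * log(pb))
      } else {
        1 / (1 - alpha) * (log(sum(pa^alpha)) + log(sum(pb^alpha)))
      }
      if (tot > best) { best <- tot; tbest <- t }
    }
    tbest
  }
  t_shannon <- ent(1)
  tbin <- if (method == "kapur") {
    t_shannon
  } else {
    ts <- sort(c(ent(0.5), t_shannon, ent(2)))
    t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
    betas <- if (abs(t1 - t2) <= 5 && abs(t2 - t3) <= 5) c(1, 2, 1)
    else if (abs(t1 - t2) > 5 && abs(t2 - t3) > 5) c(1, 2, 1)
    else if (abs(t1 - t2) <= 5) c(0, 1, 3)
    else c(3, 1, 0)
    omega <- P1[t3] - P1[t1]
    floor(t1 * (P1[t1] + 0.25 * omega * betas[1]) +
            0.25 * t2 * omega * betas[2] +
            t3 * (P2[t3] + 0.25 * omega * betas[3]))
  }
  rng[1] + tbin / bins * (rng[2] - rng[1])
}

#' Binary structure (vessel) mask from a summed channel image stack
#'
#' Per slice: min-max normalisation to the 16-bit range, Gaussian blur
#' (sigma 1), automatic Renyi-entropy threshold, binarisation. Constant
#' (blank) slices yield an empty mask plane. Slices are stacked into a 3D
#' logical volume aligned with the label volume.
#'
#' @param slices list of per-real-slice matrices (e.g. the sum of the
#'   configured vessel channels), or a (y, x, z) volume.
#' @param sigma Gaussian blur sigma in pixels.
#' @param method threshold flavour, see [renyi_threshold()].
#' @return logical (y, x, z) array.
#' @export
make_structure_mask <- function(slices, sigma = 1, method = "sahoo") {
  if (is.array(slices) && length(dim(slices)) == 3L)
    slices <- lapply(seq_len(dim(slices)[3]), function(z) slices[, , z])
  planes <- lapply(slices, function(img) {
    if (max(img) <= min(img)) return(matrix(FALSE, nrow(img), ncol(img)))
    nrm <- .rescale(img, 0, 65535)
    bl <- .blur2d(nrm, sigma)
    bl > renyi_threshold(bl, method = method)
  })
  array(unlist(planes, use.names = FALSE),
        c(dim(planes[[1]]), length(planes)))
}

#' Distance from each cell to the nearest structure voxel
#'
#' In `"3d"` mode the Euclidean distance (with voxel spacing applied) from
#' the 3D centroid to the nearest true mask voxel. In `"2d"` mode, for every
#' slice a cell occupies, the distance from that slice's 2D footprint
#' centroid to the nearest mask pixel in the same slice, minimised over the
#' cell's slices; slices with an empty mask plane are excluded (a cell whose
#' slices are all excluded gets `NA`).
#'
#' @param catalog a [measure_cells()] catalog (used in 3d mode).
#' @param labels the label volume (used in 2d mode for per-slice footprints).
#' @param mask logical structure mask, same shape as `labels`.
#' @param mode `"3d"` or `"2d"`.
#' @param spacing `(dx, dy, dz)` micrometres; use `c(1, 1, 1)` for
#'   pixel-index geometry.
#' @return data.frame `cell_id`, `distance`.
#' @export
distance_to_structure <- function(catalog, labels, mask,
                                  mode = c("3d", "2d"),
                                  spacing = c(1, 1, 2)) {
  mode <- match.arg(mode)
  d <- dim(mask)
  if (mode == "3d") {
    if (!any(mask)) .stopf("structure mask is empty")
    mi <- arrayInd(which(mask), d)
    mxyz <- cbind((mi[, 2] - 1) * spacing[1], (mi[, 1] - 1) * spacing[2],
                  (mi[, 3] - 1) * spacing[3])
    cxyz <- as.matrix(catalog[, c("centroid_x", "centroid_y", "centroid_z")])
    dist <- vapply(seq_len(nrow(cxyz)), function(i) {
      sqrt(min((mxyz[, 1] - cxyz[i, 1])^2 + (mxyz[, 2] - cxyz[i, 2])^2 +
                 (mxyz[, 3] - cxyz[i, 3])^2))
    }, 1)
    return(data.frame(cell_id = catalog$cell_id, distance = dist))
  }
  ## 2d: per-slice footprint centroids against same-slice mask pixels
  ids <- catalog$cell_id
  best <- rep(Inf, length(ids))
  for (z in seq_len(d[3])) {
    mz <- mask[, , z]
    if (!any(mz)) next  # empty mask plane: slice excluded
    pz <- labels[, , z]
    on <- which(pz > 0)
    if (!length(on)) next
    rc <- arrayInd(on, d[1:2])
    l <- pz[on]
    sx <- rowsum(rc[, 2], l); n <- as.vector(table(l))
    lab_here <- as.integer(rownames(sx))
    cx <- (sx[, 1] / n - 1) * spacing[1]
    cy <- (rowsum(rc[, 1], l)[, 1] / n - 1) * spacing[2]
    mrc <- arrayInd(which(mz), d[1:2])
    mx <- (mrc[, 2] - 1) * spacing[1]
    my <- (mrc[, 1] - 1) * spacing[2]
    dz <- vapply(seq_along(lab_here), function(i)
      sqrt(min((mx - cx[i])^2 + (my - cy[i])^2)), 1)
    m <- match(lab_here, ids)
    ok <- !is.na(m)
    best[m[ok]] <- pmin(best[m[ok]], dz[ok])
  }
  data.frame(cell_id = ids,
             distance = ifelse(is.finite(best), best, NA_real_))
}

#' Unique touching label pairs of a volume (6-connectivity faces)
#' @noRd
.adjacent_pairs_3d <- function(labels) {
  d <- dim(labels)
  pairs <- NULL
  grab <- function(a, b) {
    ok <- a > 0 & b > 0 & a != b
    if (!any(ok)) return(NULL)
    cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))
  }
  pairs <- rbind(
    grab(labels[-d[1], , , drop = FALSE], labels[-1, , , drop = FALSE]),
    grab(labels[, -d[2], , drop = FALSE], labels[, -1, , drop = FALSE]),
    if (d[3] > 1)
      grab(labels[, , -d[3], drop = FALSE], labels[, , -1, drop = FALSE]))
  if (is.null(pairs)) return(matrix(integer(), 0, 2))
  unique(pairs)
}

#' @noRd
.adjacent_pairs_2d <- function(plane) {
  d <- dim(plane)
  grab <- function(a, b) {
    ok <- a > 0 & b > 0 & a != b
    if (!any(ok)) return(NULL)
    cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))
  }
  pairs <- rbind(grab(plane[-d[1], , drop = FALSE], plane[-1, , drop = FALSE]),
                 grab(plane[, -d[2], drop = FALSE], plane[, -1, drop = FALSE]))
  if (is.null(pairs)) return(matrix(integer(), 0, 2))
  unique(pairs)
}

#' Per-cluster direct-neighbour proportions from the region adjacency graph
#'
#' Direct neighbours are labels with touching voxels (face connectivity: 6
#' neighbours in 3D, 4 in-plane in 2D); background never counts. In `"3d"`
#' mode adjacency is evaluated once on the whole volume. In `"2d"` mode
#' adjacency is evaluated on every slice plane of the same 3D mask and the
#' neighbour counts are accumulated over slices before normalisation. Entry
#' (a, b) is the proportion of all touching neighbours of cluster-a cells
#' that belong to cluster b; rows with at least one neighbour sum to 1.
#'
#' @param labels the (y, x, z) label volume.
#' @param clusters named integer vector or data.frame (`cell_id`,
#'   `cluster`): cluster assignment for every label in the volume.
#' @param mode `"3d"` or `"2d"`.
#' @return clusters x clusters proportion matrix (rows with no neighbours
#'   are `NA`).
#' @export
neighbor_proportions <- function(labels, clusters, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  if (is.data.frame(clusters))
    clusters <- stats::setNames(clusters$cluster, clusters$cell_id)
  present <- sort(unique(labels[labels > 0]))
  unassigned <- setdiff(as.character(present), names(clusters))
  if (length(unassigned))
    .stopf("no cluster assignment for label(s): %s",
           paste(unassigned, collapse = ", "))
  cl_levels <- sort(unique(as.integer(clusters[as.character(present)])))
  counts <- matrix(0, length(cl_levels), length(cl_levels),
                   dimnames = list(cl_levels, cl_levels))
  tally <- function(pairs) {
    if (!nrow(pairs)) return(invisible(NULL))
    ca <- factor(clusters[as.character(pairs[, 1])], levels = cl_levels)
    cb <- factor(clusters[as.character(pairs[, 2])], levels = cl_levels)
    tt <- table(ca, cb)
    counts <<- counts + tt + t(tt)  # each pair counts for both members
  }
  if (mode == "3d") {
    tally(.adjacent_pairs_3d(labels))
  } else {
    for (z in seq_len(dim(labels)[3]))
      tally(.adjacent_pairs_2d(labels[, , z]))
  }
  tot <- rowSums(counts)
  out <- counts / ifelse(tot > 0, tot, NA)
  out
}

#' Difference between 3D and 2D neighbour proportions
#'
#' Elementwise `p3d - p2d` over the union of clusters; entries missing in
#' either matrix are `NA`.
#'
#' @param p3d,p2d proportion matrices from [neighbor_proportions()].
#' @return difference matrix, entries in `[-1, 1]`.
#' @export
proportion_difference <- function(p3d, p2d) {
  cl <- sort(unique(as.integer(c(rownames(p3d), rownames(p2d)))))
  out <- matrix(NA_real_, length(cl), length(cl),
                dimnames = list(cl, cl))
  common_r <- intersect(rownames(p3d), rownames(p2d))
  common_c <- intersect(colnames(p3d), colnames(p2d))
  out[common_r, common_c] <- p3d[common_r, common_c] - p2d[common_r, common_c]
  out
}

#' Microenvironment of a query cell set
#'
#' Returns all non-query cells whose centroid lies within `radius` of the
#' centroid of at least one query cell, together with the per-cluster
#' composition of that neighbourhood. A query cell is never its own
#' neighbour.
#'
#' @param catalog a cell catalog with centroid columns (and optionally a
#'   `cluster` column for the composition table).
#' @param query_ids cell ids of the query set.
#' @param radius search radius; inclusion is `distance <= radius`.
#' @param spacing `(dx, dy, dz)` applied to centroid coordinates before the
#'   distance computation; the catalog centroids are already in micrometres,
#'   so use `c(1, 1, 1)` for a micrometre radius or `c(1, 1, 1/dz)`-style
#'   factors to reproduce pixel-index geometry.
#' @return list: `ids` (neighbour cell ids), `composition` (per-cluster
#'   counts, when a `cluster` column exists).
#' @export
microenvironment <- function(catalog, query_ids, radius = 50,
                             spacing = c(1, 1, 1)) {
  unknown <- setdiff(query_ids, catalog$cell_id)
  if (length(unknown))
    .stopf("unknown query cell id(s): %s", paste(unknown, collapse = ", "))
  xyz <- as.matrix(catalog[, c("centroid_x", "centroid_y", "centroid_z")])
  xyz <- sweep(xyz, 2, spacing, `*`)
  isq <- catalog$cell_id %in% query_ids
  q <- xyz[isq, , drop = FALSE]
  rest <- xyz[!isq, , drop = FALSE]
  rest_ids <- catalog$cell_id[!isq]
  if (!nrow(rest) || radius <= 0)
    return(list(ids = integer(0),
                composition = table(integer(0))))
  near <- rep(FALSE, nrow(rest))
  for (i in seq_len(nrow(q))) {
    d2 <- (rest[, 1] - q[i, 1])^2 + (rest[, 2] - q[i, 2])^2 +
      (rest[, 3] - q[i, 3])^2
    near <- near | d2 <= radius^2
  }
  ids <- rest_ids[near]
  comp <- if ("cluster" %in% names(catalog))
    table(catalog$cluster[match(ids, catalog$cell_id)])
  else table(integer(0))
  list(ids = ids, composition = comp)
}

#' Select cells whose normalised marker expression exceeds a cutoff
#'
#' Machine support for manual curation of e.g. putative invasive cells:
#' returns the ids of cells with normalised (99th-percentile range) marker
#' value strictly above the cutoff.
#'
#' @param catalog cell catalog.
#' @param normalized cells x channels matrix of normalised expression
#'   aligned with `catalog` rows (see [normalize_p99()]).
#' @param marker channel name.
#' @param cutoff strict lower cutoff (e.g. 0.2).
#' @return integer vector of cell ids.
#' @export
select_cells_by_marker <- function(catalog, normalized, marker, cutoff) {
  if (!marker %in% colnames(normalized))
    .stopf("marker '%s' not in the normalised matrix", marker)
  catalog$cell_id[normalized[, marker] > cutoff]
}
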