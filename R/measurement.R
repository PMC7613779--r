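## Per-cell marker quantification: hot-pixel suppression, per-object channel
## means, spillover compensation of the means, and catalog export.

#' Suppress isolated hot pixels
#'
#' A pixel is classified hot when it exceeds the maximum of its 8 neighbours
#' (centre excluded, boundary pixels use their available neighbours) by more
#' than `delta` counts; hot pixels are set to that local maximum. The
#' operation never increases a pixel and is idempotent.
#'
#' @param img numeric 2D matrix of ion counts.
#' @param delta counts above the local neighbour maximum that flag a pixel
#'   as hot.
#' @return cleaned matrix.
#' @export
remove_hot_pixels <- function(img, delta = 50) {
  m <- NULL
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- .shift2d(img, dy, dx, fill = -Inf)
    m <- if (is.null(m)) s else pmax(m, s)
  }
  hot <- img - m > delta
  img[hot] <- m[hot]
  img
}

#' Hot-pixel cleaning of every channel of a stack
#' @param stack an `ImageStack`.
#' @param delta see [remove_hot_pixels()].
#' @return the cleaned `ImageStack`.
#' @export
clean_stack_hot_pixels <- function(stack, delta = 50) {
  stack$data <- lapply(stack$data, function(ch)
    lapply(ch, function(img) if (is.null(img)) NULL
           else remove_hot_pixels(img, delta)))
  names(stack$data) <- stack$channels
  stack
}

#' Measure the single-cell catalog from a label volume
#'
#' For every labelled object: mean ion counts per channel over the object's
#' voxels, centroid in physical micrometres, voxel volume and
#' second-moment axis lengths in the x-y and x-z planes.
#'
#' @param labels integer (y, x, z) label volume on the real slices.
#' @param volumes named list of channel volumes with the same dimensions
#'   (real slices, hot-pixel-cleaned), or a padded `ImageStack`.
#' @param spacing `(dx, dy, dz)` micrometres (taken from the stack when one
#'   is given).
#' @return `data.frame` with columns `cell_id`, `volume`, `centroid_x/y/z`,
#'   `axis_xy`, `axis_xz`, `z_min`, `z_max` and one mean-intensity column
#'   per channel; attribute `channels` lists the channel columns.
#' @export
measure_cells <- function(labels, volumes, spacing = c(1, 1, 2)) {
  if (inherits(volumes, "ImageStack")) {
    spacing <- volumes$spacing
    volumes <- lapply(stats::setNames(volumes$channels, volumes$channels),
                      function(ch) stack_channel(volumes, ch, "real"))
  }
  for (ch in names(volumes))
    if (!all(dim(volumes[[ch]]) == dim(labels)))
      .stopf("channel '%s' does not share the label-volume geometry", ch)
  idx <- which(labels > 0)
  if (!length(idx)) {
    out <- data.frame(cell_id = integer(), volume = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      centroid_z = numeric(), axis_xy = numeric(),
                      axis_xz = numeric(), z_min = integer(),
                      z_max = integer())
    for (ch in names(volumes)) out[[ch]] <- numeric()
    attr(out, "channels") <- names(volumes)
    return(out)
  }
  l <- labels[idx]
  ids <- sort(unique(l))
  n <- as.vector(table(l))
  ai <- arrayInd(idx, dim(labels))
  xu <- (ai[, 2] - 1) * spacing[1]
  yu <- (ai[, 1] - 1) * spacing[2]
  zu <- (ai[, 3] - 1) * spacing[3]
  sum_by <- function(v) rowsum(v, l)[, 1]
  axy <- .axis_lengths(sum_by(xu), sum_by(yu), sum_by(xu^2), sum_by(yu^2),
                       sum_by(xu * yu), n)
  axz <- .axis_lengths(sum_by(xu), sum_by(zu), sum_by(xu^2), sum_by(zu^2),
                       sum_by(xu * zu), n)
  out <- data.frame(cell_id = ids, volume = n,
                    centroid_x = sum_by(xu) / n,
                    centroid_y = sum_by(yu) / n,
                    centroid_z = sum_by(zu) / n,
                    axis_xy = rowMeans(axy), axis_xz = rowMeans(axz),
                    z_min = as.integer(tapply(ai[, 3], l, min)),
                    z_max = as.integer(tapply(ai[, 3], l, max)))
  for (ch in names(volumes)) out[[ch]] <- sum_by(volumes[[ch]][idx]) / n
  rownames(out) <- NULL
  attr(out, "channels") <- names(volumes)
  out
}

#' Read a spillover matrix from CSV
#'
#' Rows are source channels, the header names the receiving channels (the
#' mass-cytometry convention). The diagonal must be 1, off-diagonal entries
#' in `[0, 1)`.
#'
#' @param path CSV path; the first column holds the source channel names.
#' @return square numeric matrix with channel dimnames.
#' @export
read_spillover <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  rn <- x[[1]]
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- rn
  validate_spillover(m)
}

#' @rdname read_spillover
#' @param S a square matrix to validate.
#' @export
validate_spillover <- function(S) {
  if (nrow(S) != ncol(S) || is.null(rownames(S)) || is.null(colnames(S)))
    .stopf("spillover matrix must be square with channel dimnames")
  S <- S[, rownames(S), drop = FALSE]
  if (any(abs(diag(S) - 1) > 1e-9)) .stopf("spillover diagonal must be 1")
  off <- S[row(S) != col(S)]
  if (any(off < 0 | off >= 1))
    .stopf("off-diagonal spillover must be in [0, 1)")
  if (abs(det(S)) < 1e-12) .stopf("spillover matrix is singular")
  S
}

#' Compensate per-cell mean intensities for channel spillover
#'
#' Each cell's observed mean row vector o is replaced by the non-negative
#' least-squares solution x of x S = o, so a small cross-contamination
#' fraction S\[i, j\] of channel i counted in channel j is removed while
#' compensated means stay non-negative. With S = identity the catalog is
#' returned unchanged. Channels absent from S pass through unchanged.
#'
#' @param catalog a [measure_cells()] catalog.
#' @param S spillover matrix (see [read_spillover()]).
#' @return the compensated catalog.
#' @export
compensate_spillover <- function(catalog, S) {
  S <- validate_spillover(S)
  chans <- intersect(attr(catalog, "channels"), rownames(S))
  if (!length(chans)) return(catalog)
  Ss <- S[chans, chans, drop = FALSE]
  O <- as.matrix(catalog[, chans, drop = FALSE])
  if (any(O < 0)) .stopf("observed mean intensities must be non-negative")
  A <- t(Ss)  # solve A x = o per cell
  X <- t(apply(O, 1, function(o) pracma::lsqnonneg(A, o)$x))
  if (nrow(O) == 1L) X <- matrix(X, nrow = 1)
  catalog[, chans] <- X
  catalog
}

#' Export / read the cell catalog as CSV
#'
#' Numeric values round-trip at full precision.
#'
#' @param catalog a cell catalog data.frame.
#' @param path CSV path.
#' @export
export_catalog <- function(catalog, path) {
  chans <- attr(catalog, "channels")
  data.table::fwrite(catalog, path)
  if (!is.null(chans))
    writeLines(jsonlite::toJSON(list(channels = chans)),
               paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname export_catalog
#' @export
read_catalog <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  meta <- paste0(path, ".meta.json")
  if (file.exists(meta))
    attr(out, "channels") <- unlist(jsonlite::read_json(meta)$channels)
  out
}
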