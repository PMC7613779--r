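## Reading, writing and geometric normalisation of serial-section
## multichannel ion-count image stacks.

#' Construct and validate a channel panel
#'
#' The panel describes every measured channel: a unique identifier, the metal
#' tag of the conjugated antibody (or intercalator), the biological target and
#' a role. Exactly one channel must carry the `nuclear` role (the iridium DNA
#' intercalator used for segmentation) and at least one channel must carry the
#' `reference` role (used for registration).
#'
#' @param channel_id character, unique channel identifiers.
#' @param metal_tag character, metal isotope tags (e.g. `"Ir191"`).
#' @param target character, biological target names (e.g. `"panCK"`).
#' @param role character, one of `"nuclear"`, `"reference"`, `"vessel"`,
#'   `"marker"` per channel.
#' @return A `data.frame` of class `imc_panel`.
#' @export
panel <- function(channel_id, metal_tag, target, role) {
  p <- data.frame(channel_id = as.character(channel_id),
                  metal_tag = as.character(metal_tag),
                  target = as.character(target),
                  role = as.character(role),
                  stringsAsFactors = FALSE)
  validate_panel(p)
}

#' @rdname panel
#' @param x a data.frame with the four panel columns.
#' @export
validate_panel <- function(x) {
  need <- c("channel_id", "metal_tag", "target", "role")
  if (!all(need %in% names(x)))
    .stopf("panel must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(x$channel_id))
    .stopf("duplicate channel_id in panel: %s",
           paste(unique(x$channel_id[duplicated(x$channel_id)]), collapse = ", "))
  bad <- setdiff(x$role, c("nuclear", "reference", "vessel", "marker"))
  if (length(bad)) .stopf("unknown panel role(s): %s", paste(bad, collapse = ", "))
  if (sum(x$role == "nuclear") != 1L)
    .stopf("panel must flag exactly one nuclear channel, found %d",
           sum(x$role == "nuclear"))
  if (!any(x$role == "reference"))
    .stopf("panel must contain at least one reference channel for registration")
  class(x) <- c("imc_panel", "data.frame")
  x
}

#' @rdname panel
#' @param path path of a CSV file with columns channel_id, metal_tag, target,
#'   role.
#' @export
read_panel <- function(path) {
  validate_panel(as.data.frame(data.table::fread(path)))
}

#' @rdname panel
#' @export
write_panel <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' Channel id for a panel role
#' @param panel an `imc_panel`.
#' @param role the role to look up.
#' @return character vector of channel ids.
#' @export
panel_channels <- function(panel, role) panel$channel_id[panel$role == role]

#' Construct an ImageStack
#'
#' An `ImageStack` holds one 2D intensity image per channel per slice, along
#' with voxel spacing and per-slice provenance flags. Slices flagged
#' `"missing"` carry no data and are excluded from downstream computation;
#' slices flagged `"artificial"` are interpolated planes inserted during
#' segmentation preprocessing only.
#'
#' @param data list over channels (named by channel id), each a list over
#'   slices of numeric matrices (`NULL` for missing slices).
#' @param channels character vector of channel ids.
#' @param sections integer section indices, strictly increasing.
#' @param flags per-slice flag: `"real"`, `"artificial"` or `"missing"`.
#' @param spacing numeric `(dx, dy, dz)` voxel spacing in micrometres.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, channels = names(data), sections = NULL,
                        flags = NULL, spacing = c(1, 1, 2)) {
  nslice <- length(data[[1]])
  if (is.null(sections)) sections <- seq_len(nslice)
  if (is.null(flags)) flags <- rep("real", nslice)
  stopifnot(length(channels) == length(data),
            all(vapply(data, length, 1L) == nslice),
            length(sections) == nslice, length(flags) == nslice,
            all(diff(sections) > 0))
  names(data) <- channels
  s <- structure(list(data = data, channels = channels,
                      sections = as.integer(sections),
                      flags = as.character(flags),
                      spacing = as.numeric(spacing)),
                 class = "ImageStack")
  s
}

#' @export
print.ImageStack <- function(x, ...) {
  dims <- stack_dims(x)
  cat(sprintf("ImageStack: %d channel(s) x %d slice(s) (%d real, %d artificial, %d missing)\n",
              length(x$channels), length(x$flags),
              sum(x$flags == "real"), sum(x$flags == "artificial"),
              sum(x$flags == "missing")))
  cat(sprintf("  size: up to %d x %d px, spacing (%.3g, %.3g, %.3g) um\n",
              dims[2], dims[1], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Maximum (rows, cols) over all present slice images
#' @param stack an `ImageStack`.
#' @return integer `(rows, cols)`.
#' @export
stack_dims <- function(stack) {
  dd <- lapply(unlist(stack$data, recursive = FALSE), dim)
  dd <- dd[!vapply(dd, is.null, TRUE)]
  if (!length(dd)) return(c(0L, 0L))
  c(max(vapply(dd, `[`, 1L, 1L)), max(vapply(dd, `[`, 1L, 2L)))
}

#' Load a serial-section multichannel stack from per-slice per-channel files
#'
#' Reads single-channel TIFF files listed in a manifest, orders them by
#' section index and validates completeness. Section indices absent from a
#' contiguous `min(section)..max(section)` range are recorded as missing
#' slices (flag `"missing"`); they carry no pixel data and are skipped by all
#' downstream 3D computation. Intensities are preserved bit-exactly.
#'
#' @param manifest data.frame with columns `path`, `section`, `channel_id`
#'   (one row per file), or the path of a CSV file with those columns.
#' @param panel an `imc_panel`; every present section must provide every
#'   panel channel.
#' @param spacing voxel spacing `(dx, dy, dz)` in micrometres.
#' @return An `ImageStack`.
#' @export
load_stack <- function(manifest, panel, spacing = c(1, 1, 2)) {
  if (is.character(manifest))
    manifest <- as.data.frame(data.table::fread(manifest))
  panel <- validate_panel(panel)
  need <- c("path", "section", "channel_id")
  if (!all(need %in% names(manifest)))
    .stopf("manifest must have columns %s", paste(need, collapse = ", "))
  manifest$section <- as.integer(manifest$section)
  key <- paste(manifest$section, manifest$channel_id)
  if (anyDuplicated(key))
    .stopf("duplicate section/channel entries in manifest: %s",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  extra <- setdiff(manifest$channel_id, panel$channel_id)
  if (length(extra))
    .stopf("manifest channels not in panel: %s", paste(extra, collapse = ", "))
  secs <- sort(unique(manifest$section))
  all_secs <- seq(min(secs), max(secs))
  for (s in secs) {
    miss <- setdiff(panel$channel_id, manifest$channel_id[manifest$section == s])
    if (length(miss))
      .stopf("section %d present but channel(s) %s missing", s,
             paste(miss, collapse = ", "))
  }
  missing <- file.exists(manifest$path)
  if (!all(missing))
    .stopf("file(s) not found: %s",
           paste(manifest$path[!missing], collapse = ", "))
  flags <- ifelse(all_secs %in% secs, "real", "missing")
  data <- lapply(panel$channel_id, function(ch) {
    lapply(all_secs, function(s) {
      if (!(s %in% secs)) return(NULL)
      p <- manifest$path[manifest$section == s & manifest$channel_id == ch]
      img <- tiff::readTIFF(p, as.is = TRUE)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      storage.mode(img) <- "double"
      img
    })
  })
  names(data) <- panel$channel_id
  image_stack(data, panel$channel_id, all_secs, flags, spacing)
}

#' Zero-pad all slice images to a common size
#'
#' Pads every present image with zeros at the bottom/right so that all slices
#' share the maximal (rows, cols) over the stack. Original pixels (and hence
#' per-image intensity sums) are unchanged.
#'
#' @param stack an `ImageStack`.
#' @return The padded `ImageStack`.
#' @export
zero_pad_to_common_size <- function(stack) {
  if (!length(stack$flags) || all(stack$flags == "missing"))
    .stopf("stack has no present slices")
  dims <- stack_dims(stack)
  stack$data <- lapply(stack$data, function(ch) {
    lapply(ch, function(img) {
      if (is.null(img)) return(NULL)
      if (all(dim(img) == dims)) return(img)
      out <- matrix(0, dims[1], dims[2])
      out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
      out
    })
  })
  stack
}

#' Extract one channel of a stack as a (y, x, z) volume
#'
#' @param stack a padded `ImageStack` (all present slices share one size).
#' @param channel channel id.
#' @param slices which slices to include: `"real"` (default), `"present"`
#'   (real + artificial), or an integer vector of slice positions.
#' @return 3D numeric array (y, x, z).
#' @export
stack_channel <- function(stack, channel, slices = "real") {
  if (!channel %in% stack$channels) .stopf("unknown channel '%s'", channel)
  idx <- if (is.character(slices)) {
    switch(slices,
           real = which(stack$flags == "real"),
           present = which(stack$flags != "missing"),
           .stopf("unknown slice selector '%s'", slices))
  } else as.integer(slices)
  imgs <- stack$data[[channel]][idx]
  if (!length(imgs)) .stopf("no slices selected")
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(m) all(dim(m) == d), TRUE)))
    .stopf("slices differ in size; call zero_pad_to_common_size() first")
  array(unlist(imgs, use.names = FALSE), c(d, length(imgs)))
}

#' Write / read a 3D integer label volume as a multi-page TIFF
#'
#' Labels up to 65535 are stored as 16-bit unsigned integers; larger label
#' ranges (up to 2^24) as 32-bit samples. Round trips are bit-exact.
#'
#' @param labels integer 3D array (y, x, z), 0 = background.
#' @param path output file.
#' @param bits `"auto"` (default), `16` or `32`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path, bits = "auto") {
  mx <- max(labels)
  if (identical(bits, "auto")) bits <- if (mx > 65535) 32L else 16L
  bits <- as.integer(bits)
  if (bits == 16L && mx > 65535)
    .stopf("%d labels exceed the 16-bit range; use bits = 32", mx)
  if (mx > 2^24)
    .stopf("label ids above 2^24 cannot be stored exactly")
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  nz <- dim(labels)[3]
  ## the tiff writer maps [0, 1] onto the full unsigned integer range of
  ## the chosen sample width; dividing by that range stores the labels as
  ## exact integers
  pages <- lapply(seq_len(nz), function(z) {
    m <- labels[, , z]
    if (bits == 16L) m / 65535 else m / (2^32 - 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  vol <- array(as.integer(round(unlist(pages, use.names = FALSE))),
               c(d[1], d[2], length(pages)))
  vol
}

#' Write one channel stack (real slices) as a multi-page 16-bit TIFF
#' @param vol numeric (y, x, z) volume of non-negative intensities
#'   (clamped to the 16-bit range on write).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intensity_volume <- function(vol, path) {
  pages <- lapply(seq_len(dim(vol)[3]), function(z)
    pmin(pmax(vol[, , z], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  reduce = FALSE, compression = "none")
  invisible(path)
}
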