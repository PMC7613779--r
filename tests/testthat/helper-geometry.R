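## Constructed label geometries for the 3D-versus-2D neighbour statistics.

## Tall same-type columns in lateral contact over every slice, plus small
## single-slice heterotypic contacts: slice-accumulated 2D counting then
## inflates homotypic proportions relative to unique-pair 3D counting.
zcolumn_labels <- function(nz = 10) {
  d <- c(14, 14, nz)
  labs <- array(0L, d)
  id <- 0L
  cl <- integer(0)
  for (gy in 0:3) for (gx in 0:3) {
    id <- id + 1L
    labs[gy * 3 + 2:4 - 1, gx * 3 + 2:4 - 1, ] <- id
    cl[id] <- 1L                       # type A: tall columns
  }
  ## type B: one-slice cubes touching a column face on a single plane
  for (k in 1:3) {
    id <- id + 1L
    labs[13:14, k * 3, k] <- id
    cl[id] <- 2L
  }
  names(cl) <- seq_len(id)
  list(labels = labs, clusters = cl)
}
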