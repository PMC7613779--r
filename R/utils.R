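## Internal numeric helpers shared across modules.

#' 1D Gaussian kernel truncated at 3 sigma
#' @noRd
.gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Convolve a matrix along one margin with a centred kernel, zero padding
#' with edge renormalisation (the kernel is renormalised over its in-image
#' support so flat regions stay flat at the borders).
#' @noRd
.conv_margin <- function(m, k, margin) {
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  wsum <- matrix(0, nrow(m), ncol(m))
  n <- if (margin == 1L) nrow(m) else ncol(m)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (margin == 1L) {
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
      wsum[ok, ] <- wsum[ok, ] + k[j]
    } else {
      out[, ok] <- out[, ok] + k[j] * m[, src[ok], drop = FALSE]
      wsum[, ok] <- wsum[, ok] + k[j]
    }
  }
  out / wsum
}

#' Separable 2D Gaussian blur of a matrix
#' @noRd
.blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- .gauss_kernel(sigma)
  .conv_margin(.conv_margin(m, k, 1L), k, 2L)
}

#' Separable Gaussian blur of a (y, x, z) volume; sigma may be scalar or
#' length 3 (sy, sx, sz). A zero sigma skips that axis.
#' @noRd
.blur3d <- function(vol, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(vol)
  out <- vol
  ## convolve along each axis by permuting it to the first margin of a matrix
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- .gauss_kernel(sigma[ax])
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(out, perm), nrow = d[ax])
    m <- .conv_margin(m, k, 1L)
    out <- aperm(array(m, d[perm]), order(perm))
  }
  out
}

#' Shifted copy of a matrix (dy, dx), vacated cells filled with `fill`
#' @noRd
.shift2d <- function(m, dy, dx, fill = -Inf) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx], drop = FALSE]
  out
}

#' Linear rescale to [lo, hi]; constant input maps to lo
#' @noRd
.rescale <- function(x, lo = 0, hi = 1) {
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    out <- x
    out[] <- lo
    return(out)
  }
  lo + (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Axis lengths from second moments of a 2D point cloud: lengths of the
#' major/minor axes of the ellipse with the same second moments
#' (4 * sqrt(eigenvalue), the regionprops convention).
#' @noRd
.axis_lengths <- function(sx, sy, sxx, syy, sxy, n) {
  mx <- sx / n; my <- sy / n
  a <- sxx / n - mx^2
  c <- syy / n - my^2
  b <- sxy / n - mx * my
  disc <- sqrt(pmax(((a - c) / 2)^2 + b^2, 0))
  e1 <- pmax((a + c) / 2 + disc, 0)
  e2 <- pmax((a + c) / 2 - disc, 0)
  cbind(major = 4 * sqrt(e1), minor = 4 * sqrt(e2))
}

#' @noRd
.stopf <- function(...) stop(sprintf(...), call. = FALSE)
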