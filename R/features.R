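## Scale-invariant blob keypoints with orientation-normalised gradient
## descriptors, used for feature-based slice-to-slice registration.
## Keypoints are difference-of-Gaussian extrema across a small scale pyramid;
## descriptors follow the classic 4 x 4 spatial x 8 orientation histogram
## layout with ratio-of-distances matching.

#' @noRd
.detect_keypoints <- function(img, n_levels = 6, sigma0 = 1.6,
                              response_frac = 0.02, max_keypoints = 250) {
  img <- img / max(max(img), 1e-12)
  sigmas <- sigma0 * 2^((seq_len(n_levels) - 1) / 2)
  G <- lapply(sigmas, function(s) .blur2d(img, s))
  D <- lapply(seq_len(n_levels - 1), function(i) G[[i]] - G[[i + 1]])
  kp <- NULL
  dmax <- max(vapply(D, function(m) max(abs(m)), 1))
  thresh <- response_frac * dmax
  for (i in 2:(length(D) - 1)) {
    cur <- D[[i]]
    ## local extremum over the 3x3x3 (x, y, scale) neighbourhood
    neigh_max <- neigh_min <- NULL
    for (lev in (i - 1):(i + 1)) {
      m <- D[[lev]]
      for (dy in -1:1) for (dx in -1:1) {
        if (lev == i && dy == 0 && dx == 0) next
        s <- .shift2d(m, dy, dx, fill = -Inf)
        neigh_max <- if (is.null(neigh_max)) s else pmax(neigh_max, s)
        s2 <- .shift2d(m, dy, dx, fill = Inf)
        neigh_min <- if (is.null(neigh_min)) s2 else pmin(neigh_min, s2)
      }
    }
    is_max <- cur > neigh_max & cur > thresh
    is_min <- cur < neigh_min & cur < -thresh
    idx <- which(is_max | is_min)
    if (!length(idx)) next
    rc <- arrayInd(idx, dim(cur))
    keep <- rc[, 1] > 2 & rc[, 1] < nrow(cur) - 1 &
      rc[, 2] > 2 & rc[, 2] < ncol(cur) - 1
    rc <- rc[keep, , drop = FALSE]
    if (!nrow(rc)) next
    ## sub-pixel quadratic refinement in (x, y)
    gx <- (cur[cbind(rc[, 1], rc[, 2] + 1)] - cur[cbind(rc[, 1], rc[, 2] - 1)]) / 2
    gy <- (cur[cbind(rc[, 1] + 1, rc[, 2])] - cur[cbind(rc[, 1] - 1, rc[, 2])]) / 2
    hxx <- cur[cbind(rc[, 1], rc[, 2] + 1)] + cur[cbind(rc[, 1], rc[, 2] - 1)] -
      2 * cur[cbind(rc[, 1], rc[, 2])]
    hyy <- cur[cbind(rc[, 1] + 1, rc[, 2])] + cur[cbind(rc[, 1] - 1, rc[, 2])] -
      2 * cur[cbind(rc[, 1], rc[, 2])]
    hxy <- (cur[cbind(rc[, 1] + 1, rc[, 2] + 1)] + cur[cbind(rc[, 1] - 1, rc[, 2] - 1)] -
              cur[cbind(rc[, 1] + 1, rc[, 2] - 1)] - cur[cbind(rc[, 1] - 1, rc[, 2] + 1)]) / 4
    det <- hxx * hyy - hxy^2
    ox <- ifelse(abs(det) > 1e-12, -(hyy * gx - hxy * gy) / det, 0)
    oy <- ifelse(abs(det) > 1e-12, -(hxx * gy - hxy * gx) / det, 0)
    ox <- pmax(pmin(ox, 0.6), -0.6); oy <- pmax(pmin(oy, 0.6), -0.6)
    kp <- rbind(kp, cbind(x = rc[, 2] + ox, y = rc[, 1] + oy,
                          sigma = sqrt(sigmas[i] * sigmas[i + 1]),
                          level = i,
                          response = cur[cbind(rc[, 1], rc[, 2])]))
  }
  if (is.null(kp) || !nrow(kp)) return(list(kp = NULL, G = G, sigmas = sigmas))
  kp <- kp[order(-abs(kp[, "response"])), , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]
  list(kp = kp, G = G, sigmas = sigmas)
}

#' Bilinear sampling of a matrix at (x, y) positions; outside -> 0
#' @noRd
.sample_bilinear <- function(m, px, py) {
  iy <- nrow(m); ix <- ncol(m)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  out <- numeric(length(px))
  for (corner in 1:4) {
    cx <- x0 + (corner == 2 | corner == 4)
    cy <- y0 + (corner >= 3)
    w <- (if (corner %in% c(2, 4)) fx else 1 - fx) *
      (if (corner >= 3) fy else 1 - fy)
    ok <- cx >= 1 & cx <= ix & cy >= 1 & cy <= iy & w > 0
    if (any(ok)) out[ok] <- out[ok] + w[ok] * m[cbind(cy[ok], cx[ok])]
  }
  out
}

#' @noRd
.describe_keypoints <- function(det) {
  kp <- det$kp
  if (is.null(kp)) return(NULL)
  ## per-level gradients of the Gaussian-smoothed image
  grads <- lapply(det$G, function(g) {
    gx <- (.shift2d(g, 0, -1, 0) - .shift2d(g, 0, 1, 0)) / 2
    gy <- (.shift2d(g, -1, 0, 0) - .shift2d(g, 1, 0, 0)) / 2
    list(gx = gx, gy = gy)
  })
  nbin_sp <- 4L; nbin_or <- 8L
  nsamp <- 16L
  off <- (seq_len(nsamp) - (nsamp + 1) / 2) / nsamp  # in [-0.47, 0.47]
  grid <- expand.grid(u = off, v = off)
  desc <- matrix(0, nrow(kp), nbin_sp * nbin_sp * nbin_or)
  theta_kp <- numeric(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    lev <- kp[i, "level"]
    g <- grads[[lev]]
    s <- kp[i, "sigma"]
    cx <- kp[i, "x"]; cy <- kp[i, "y"]
    ## orientation: dominant gradient direction in a 3-sigma window
    r <- max(2, round(3 * s))
    xs <- round(cx) + (-r:r); ys <- round(cy) + (-r:r)
    xs <- xs[xs >= 1 & xs <= ncol(g$gx)]; ys <- ys[ys >= 1 & ys <= nrow(g$gx)]
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    vx <- g$gx[cbind(py, px)]; vy <- g$gy[cbind(py, px)]
    mag <- sqrt(vx^2 + vy^2)
    wgt <- mag * exp(-((px - cx)^2 + (py - cy)^2) / (2 * (1.5 * s)^2))
    ang <- atan2(vy, vx) %% (2 * pi)
    hb <- floor(ang / (2 * pi) * 36) %% 36
    hist36 <- vapply(0:35, function(b) sum(wgt[hb == b]), 1)
    for (sm in 1:3)
      hist36 <- (hist36 + c(tail(hist36, 1), head(hist36, -1)) +
                   c(tail(hist36, -1), head(hist36, 1))) / 3
    pk <- which.max(hist36) - 1
    lo <- hist36[(pk - 1) %% 36 + 1]; hi <- hist36[(pk + 1) %% 36 + 1]
    ctr <- hist36[pk + 1]
    denom <- lo - 2 * ctr + hi
    shift <- if (abs(denom) > 1e-12) 0.5 * (lo - hi) / denom else 0
    th <- ((pk + shift) / 36) * 2 * pi
    theta_kp[i] <- th
    ## descriptor: rotated sampling grid of half-width 6 sigma
    half <- 6 * s
    du <- grid$u * 2 * half; dv <- grid$v * 2 * half
    rx <- cos(th) * du - sin(th) * dv
    ry <- sin(th) * du + cos(th) * dv
    sx <- cx + rx; sy <- cy + ry
    vx <- .sample_bilinear(g$gx, sx, sy)
    vy <- .sample_bilinear(g$gy, sx, sy)
    mag <- sqrt(vx^2 + vy^2)
    wgt <- mag * exp(-(du^2 + dv^2) / (2 * half^2))
    ang <- (atan2(vy, vx) - th) %% (2 * pi)
    ob <- floor(ang / (2 * pi) * nbin_or) %% nbin_or
    ub <- pmin(pmax(floor((grid$u + 0.5) * nbin_sp), 0), nbin_sp - 1)
    vb <- pmin(pmax(floor((grid$v + 0.5) * nbin_sp), 0), nbin_sp - 1)
    bin <- 1 + ob + nbin_or * (ub + nbin_sp * vb)
    d <- vapply(seq_len(nbin_sp * nbin_sp * nbin_or),
                function(b) sum(wgt[bin == b]), 1)
    nrm <- sqrt(sum(d^2))
    if (nrm > 1e-12) {
      d <- pmin(d / nrm, 0.2)
      d <- d / sqrt(sum(d^2))
    }
    desc[i, ] <- d
  }
  list(kp = kp, desc = desc, theta = theta_kp)
}

#' Ratio-of-distances descriptor matching
#' @noRd
.match_descriptors <- function(da, db, rod) {
  if (is.null(da) || is.null(db) || nrow(da$desc) < 2 || nrow(db$desc) < 2)
    return(NULL)
  a <- da$desc; b <- db$desc
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  nn1 <- apply(d2, 1, which.min)
  best <- d2[cbind(seq_len(nrow(a)), nn1)]
  d2[cbind(seq_len(nrow(a)), nn1)] <- Inf
  second <- apply(d2, 1, min)
  keep <- sqrt(best) <= rod * sqrt(second)
  if (!any(keep)) return(NULL)
  cbind(a_idx = which(keep), b_idx = nn1[keep])
}
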