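## Independent brute-force oracle for the hierarchical 3D watershed:
## seed dynamics are computed from max-min path values by vectorised
## fixpoint relaxation, and the flooding is a plain-R frontier loop that
## extracts the highest-intensity frontier voxel one at a time.

shift3 <- function(a, dy, dx, dz, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  ys <- seq_len(d[1]) - dy; xs <- seq_len(d[2]) - dx; zs <- seq_len(d[3]) - dz
  oy <- ys >= 1 & ys <= d[1]; ox <- xs >= 1 & xs <= d[2]
  oz <- zs >= 1 & zs <= d[3]
  out[oy, ox, oz] <- a[ys[oy], xs[ox], zs[oz], drop = FALSE]
  out
}

.shifts6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))

## local maxima under 6-connectivity (>= all face neighbours)
oracle_local_maxima <- function(land) {
  mx <- NULL
  for (s in .shifts6) {
    sh <- shift3(land, s[1], s[2], s[3], fill = -Inf)
    mx <- if (is.null(mx)) sh else pmax(mx, sh)
  }
  which(land >= mx)
}

## dynamics of one maximum: peak value minus the best bottleneck (max-min
## path value) to any strictly higher voxel, by fixpoint relaxation of
## B(v) = max over neighbours u of min(B(u), I(v)). When only the
## comparison against a suppression level h matters, the relaxation can
## stop as soon as the bound drops below h (the bottleneck only improves,
## so the classification is already settled).
oracle_dynamics <- function(land, m, h_stop = Inf) {
  B <- array(-Inf, dim(land))
  B[m] <- land[m]
  higher <- land > land[m]
  if (!any(higher)) return(Inf)
  repeat {
    up <- NULL
    for (s in .shifts6) {
      sh <- shift3(B, s[1], s[2], s[3], fill = -Inf)
      up <- if (is.null(up)) sh else pmax(up, sh)
    }
    Bn <- pmax(B, pmin(up, land))
    best <- suppressWarnings(max(Bn[higher]))
    if (is.finite(best) && land[m] - best < h_stop)
      return(land[m] - best)
    if (all(Bn == B)) break
    B <- Bn
  }
  land[m] - max(B[higher])
}

## full oracle: seeds, frontier flood, flooding restriction
oracle_hwatershed <- function(land, h, bg, flood_frac) {
  maxima <- oracle_local_maxima(land)
  dyn <- vapply(maxima, function(m) oracle_dynamics(land, m, h_stop = h), 1)
  seeds <- maxima[land[maxima] > bg & dyn >= h]
  seeds <- seeds[order(-land[seeds], seeds)]
  d <- dim(land)
  n <- length(land)
  labels <- integer(n)
  if (length(seeds)) {
    ## precomputed 6-neighbour table (NA outside the volume)
    ai <- arrayInd(seq_len(n), d)
    nb_tab <- matrix(NA_integer_, n, 6)
    for (j in seq_along(.shifts6)) {
      s <- .shifts6[[j]]
      p1 <- ai[, 1] + s[1]; p2 <- ai[, 2] + s[2]; p3 <- ai[, 3] + s[3]
      ok <- p1 >= 1 & p1 <= d[1] & p2 >= 1 & p2 <= d[2] &
        p3 >= 1 & p3 <= d[3]
      nb_tab[ok, j] <- p1[ok] + d[1] * (p2[ok] - 1) +
        d[1] * d[2] * (p3[ok] - 1)
    }
    neighbours <- function(idx) {
      v <- nb_tab[idx, ]
      v[!is.na(v)]
    }
    offer <- integer(n)    # first label offered to a voxel wins
    inq <- logical(n)
    offer[seeds] <- seq_along(seeds)
    inq[seeds] <- TRUE
    while (any(inq)) {
      fr <- which(inq)
      v <- fr[which.max(land[fr])]
      inq[v] <- FALSE
      labels[v] <- offer[v]
      for (u in neighbours(v)) {
        if (labels[u] == 0L && offer[u] == 0L && land[u] > bg) {
          offer[u] <- labels[v]
          inq[u] <- TRUE
        }
      }
    }
    level <- land[seeds] - flood_frac * (land[seeds] - bg)
    cut <- labels > 0 & land < level[pmax(labels, 1)]
    labels[cut] <- 0L
  }
  array(labels, d)
}

## random blobby landscape on the 16-bit scale (distinct values w.p. 1)
random_landscape <- function(seed, d = c(16, 16, 16), n_blobs = 4) {
  set.seed(seed)
  land <- array(0, d)
  xs <- seq_len(d[2]); ys <- seq_len(d[1]); zs <- seq_len(d[3])
  for (i in seq_len(n_blobs)) {
    c0 <- c(runif(1, 3, d[1] - 2), runif(1, 3, d[2] - 2),
            runif(1, 3, d[3] - 2))
    s <- runif(1, 1.5, 3)
    a <- runif(1, 0.3, 1)
    bl <- a * outer(exp(-(ys - c0[1])^2 / (2 * s^2)),
                    exp(-(xs - c0[2])^2 / (2 * s^2)))
    for (z in zs)
      land[, , z] <- land[, , z] + bl * exp(-(z - c0[3])^2 / (2 * s^2))
  }
  land <- land + array(runif(prod(d), 0, 0.03), d)
  land / max(land) * 65535
}

## do two label volumes agree up to a renaming of labels?
labels_agree_up_to_renaming <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  on <- a > 0
  if (!any(on)) return(TRUE)
  map_ab <- tapply(b[on], a[on], function(v) length(unique(v)))
  map_ba <- tapply(a[on], b[on], function(v) length(unique(v)))
  all(map_ab == 1) && all(map_ba == 1)
}
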