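## 2D similarity transforms: q = s * R(theta) %*% p + t, acting on (x, y)
## pixel coordinates (pixel centres at integer positions, origin at (1, 1)).

#' 2D similarity transform
#'
#' @param theta rotation in radians (counter-clockwise in (x, y)).
#' @param scale isotropic scale factor, > 0.
#' @param tx,ty translation in pixels.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(theta = 0, scale = 1, tx = 0, ty = 0) {
  if (scale <= 0) .stopf("similarity scale must be positive")
  structure(list(theta = theta, scale = scale, tx = tx, ty = ty),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity: theta %.4f deg, scale %.5f, t (%.3f, %.3f) px\n",
              x$theta * 180 / pi, x$scale, x$tx, x$ty))
  invisible(x)
}

#' @rdname similarity_transform
#' @param tf a `similarity_transform`.
#' @return `transform_matrix`: the 3x3 homogeneous matrix acting on column
#'   vectors (x, y, 1).
#' @export
transform_matrix <- function(tf) {
  cs <- tf$scale * cos(tf$theta); sn <- tf$scale * sin(tf$theta)
  matrix(c(cs, sn, 0, -sn, cs, 0, tf$tx, tf$ty, 1), 3, 3)
}

#' Compose two similarity transforms: (a %then% b)(p) = a(b(p))
#' @param a,b `similarity_transform`s.
#' @return their composition, a `similarity_transform`.
#' @export
compose_transform <- function(a, b) {
  ca <- complex(modulus = a$scale, argument = a$theta)
  cb <- complex(modulus = b$scale, argument = b$theta)
  tb <- complex(real = b$tx, imaginary = b$ty)
  ta <- complex(real = a$tx, imaginary = a$ty)
  cc <- ca * cb
  tt <- ca * tb + ta
  similarity_transform(Arg(cc), Mod(cc), Re(tt), Im(tt))
}

#' Inverse of a similarity transform
#' @param tf a `similarity_transform`.
#' @export
invert_transform <- function(tf) {
  ci <- complex(modulus = 1 / tf$scale, argument = -tf$theta)
  tt <- -ci * complex(real = tf$tx, imaginary = tf$ty)
  similarity_transform(Arg(ci), Mod(ci), Re(tt), Im(tt))
}

#' Apply a similarity transform to (x, y) points
#' @param tf a `similarity_transform`.
#' @param pts numeric n x 2 matrix of (x, y) coordinates.
#' @return transformed n x 2 matrix.
#' @export
apply_transform <- function(tf, pts) {
  pts <- rbind(pts)  # accept a single point as a vector
  z <- complex(real = pts[, 1], imaginary = pts[, 2])
  w <- complex(modulus = tf$scale, argument = tf$theta) * z +
    complex(real = tf$tx, imaginary = tf$ty)
  cbind(Re(w), Im(w))
}

#' Rotation/scale about a given centre expressed in absolute coordinates
#' @noRd
.similarity_about <- function(theta, scale, tx, ty, centre) {
  a <- complex(modulus = scale, argument = theta)
  c0 <- complex(real = centre[1], imaginary = centre[2])
  t0 <- c0 - a * c0 + complex(real = tx, imaginary = ty)
  similarity_transform(theta, scale, Re(t0), Im(t0))
}

#' Warp an image with a similarity transform
#'
#' The transform maps input (moving) coordinates to output (fixed/canvas)
#' coordinates; each output pixel is sampled at the inverse-mapped input
#' position. Out-of-canvas samples are zero.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param tf `similarity_transform` mapping input to output coordinates.
#' @param out_dim output (rows, cols); default same as input.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return warped matrix of size `out_dim`.
#' @export
warp_image <- function(img, tf, out_dim = dim(img),
                       interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  inv <- invert_transform(tf)
  ny <- out_dim[1]; nx <- out_dim[2]
  qx <- rep(seq_len(nx), each = ny)
  qy <- rep(seq_len(ny), times = nx)
  a <- complex(modulus = inv$scale, argument = inv$theta)
  p <- a * complex(real = qx, imaginary = qy) +
    complex(real = inv$tx, imaginary = inv$ty)
  px <- Re(p); py <- Im(p)
  iy <- nrow(img); ix <- ncol(img)
  out <- numeric(ny * nx)
  if (interpolation == "nearest") {
    rx <- round(px); ry <- round(py)
    ok <- rx >= 1 & rx <= ix & ry >= 1 & ry <= iy
    out[ok] <- img[cbind(ry[ok], rx[ok])]
  } else {
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    for (corner in 1:4) {
      cx <- x0 + (corner == 2 | corner == 4)
      cy <- y0 + (corner >= 3)
      w <- (if (corner %in% c(2, 4)) fx else 1 - fx) *
        (if (corner >= 3) fy else 1 - fy)
      ok <- cx >= 1 & cx <= ix & cy >= 1 & cy <= iy & w > 0
      if (any(ok)) out[ok] <- out[ok] + w[ok] * img[cbind(cy[ok], cx[ok])]
    }
  }
  matrix(out, ny, nx)
}
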