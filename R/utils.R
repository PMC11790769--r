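`%||%` <- function(a, b) if (is.null(a)) b else a

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Axis-aligned rectangle as a polygon
#'
#' Convenience constructor for arena and ROI polygons.
#'
#' @param x0,y0,x1,y1 opposite corners in pixels.
#' @return a 4 x 2 vertex matrix (columns x, y, counterclockwise in image
#'   coordinates).
#' @export
rectPolygon <- function(x0, y0, x1, y1) {
  stopifnot(x0 < x1, y0 < y1)
  m <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  colnames(m) <- c("x", "y")
  m
}

#' Point-in-polygon test with inclusive boundary
#'
#' Ray-casting test used for ROI membership.  Points exactly on a polygon
#' edge or vertex count as inside: the membership tie rule is that boundary
#' points belong to the explicitly drawn ROI, not its complement.
#'
#' @param pts n x 2 matrix of points (columns x, y).
#' @param poly m x 2 vertex matrix (open ring; the closing edge is implied).
#' @return logical vector of length n.
#' @export
pointInPolygon <- function(pts, poly) {
  pts <- rbind(pts)
  px <- pts[, 1]; py <- pts[, 2]
  m <- nrow(poly)
  inside <- logical(length(px))
  onb <- logical(length(px))
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    eps <- 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    onseg <- abs(cross) <= eps &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onb <- onb | onseg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onb
}

# Binary mask of pixels (0-based pixel-center coordinates) inside a polygon,
# over the polygon's integer bounding box.  Returns list(mask, x0, y0) with
# mask[row, col] covering y = y0 + row - 1, x = x0 + col - 1.
polygonPixelMask <- function(poly, frameWidth, frameHeight) {
  x0 <- max(0L, floor(min(poly[, 1])))
  x1 <- min(frameWidth - 1L, ceiling(max(poly[, 1])))
  y0 <- max(0L, floor(min(poly[, 2])))
  y1 <- min(frameHeight - 1L, ceiling(max(poly[, 2])))
  xs <- x0:x1; ys <- y0:y1
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  inside <- pointInPolygon(grid, poly)
  mask <- matrix(inside, nrow = length(ys), ncol = length(xs))
  list(mask = mask, x0 = x0, y0 = y0)
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits.  Used to stamp
# output files with a fingerprint of the run configuration.  Arithmetic is
# done on doubles split into 16-bit halves so the 32-bit product never loses
# precision.
fnv1a32 <- function(text) {
  bytes <- utf8ToInt(enc2utf8(paste(text, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # XOR the low byte of h with b
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h <- (h * prime) mod 2^32
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
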