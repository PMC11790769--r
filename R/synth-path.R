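#' Create a scripted path
#'
#' @param waypoints numeric matrix (or 2-column data.frame) of pixel
#'   waypoints, columns x and y.
#' @param durationS duration of the clip in seconds.
#' @param fps frames per second.
#' @return a [ScriptedPath-class] object.
#' @examples
#' p <- scriptedPath(rbind(c(0, 0), c(10, 0)), durationS = 1, fps = 5)
#' sampleScriptedPath(p)
#' @export
scriptedPath <- function(waypoints, durationS, fps) {
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 1L) stop("waypoints must contain at least one point")
  storage.mode(waypoints) <- "double"
  colnames(waypoints) <- c("x", "y")
  new("ScriptedPath", waypoints = waypoints, durationS = as.numeric(durationS),
      fps = as.numeric(fps))
}

#' Analytic length of a scripted path
#'
#' @param path a [ScriptedPath-class].
#' @return the polyline length in pixels (0 for a single waypoint).
#' @export
pathLength <- function(path) {
  w <- path@waypoints
  if (nrow(w) < 2L) return(0)
  sum(sqrt(rowSums(diff(w)^2)))
}

#' Sample a scripted path at its frame times
#'
#' The polyline is traversed at constant speed over the path duration and
#' sampled once per frame, so consecutive samples are equally spaced in arc
#' length.  The first and last samples coincide with the first and last
#' waypoints.
#'
#' @param path a [ScriptedPath-class].
#' @return matrix of `round(durationS * fps)` rows with columns x, y; the
#'   analytic path length is attached as attribute `pathLength`.
#' @export
sampleScriptedPath <- function(path) {
  w <- path@waypoints
  n <- round(path@durationS * path@fps)
  if (n < 1L) stop("durationS * fps must round to at least one frame")
  total <- pathLength(path)
  if (nrow(w) < 2L || total == 0) {
    out <- matrix(rep(w[1L, ], each = n), ncol = 2L)
  } else {
    seg <- sqrt(rowSums(diff(w)^2))
    cum <- c(0, cumsum(seg))
    s <- if (n == 1L) 0 else total * (seq_len(n) - 1L) / (n - 1L)
    idx <- findInterval(s, cum, rightmost.closed = TRUE)
    idx <- pmin(idx, length(seg))
    frac <- (s - cum[idx]) / seg[idx]
    frac[seg[idx] == 0] <- 0
    out <- w[idx, , drop = FALSE] +
      frac * (w[idx + 1L, , drop = FALSE] - w[idx, , drop = FALSE])
  }
  colnames(out) <- c("x", "y")
  attr(out, "pathLength") <- total
  out
}
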