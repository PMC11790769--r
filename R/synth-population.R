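#' Built-in trajectory archetypes
#'
#' Four parametric 2-D curves in the unit square emulating qualitatively
#' distinct exploration styles: a straight diagonal crossing, a left-curving
#' and a right-curving arc, and an inward spiral.  Each archetype is a
#' function of a time vector `t` in `[0, 1]` returning an `length(t)` x 2
#' matrix of (x, y) positions.
#'
#' @return named list of vectorized archetype functions.
#' @seealso [simulatePopulation()]
#' @export
trajectoryArchetypes <- function() {
  list(
    line = function(t) cbind(0.1 + 0.8 * t, 0.1 + 0.8 * t),
    arcLeft = function(t) {
      th <- pi * t
      cbind(0.5 + 0.35 * cos(th), 0.5 - 0.35 * sin(th))
    },
    arcRight = function(t) {
      th <- pi * t
      cbind(0.5 + 0.35 * cos(th), 0.5 + 0.35 * sin(th))
    },
    spiral = function(t) {
      th <- 4 * pi * t
      r <- 0.4 * (1 - 0.8 * t)
      cbind(0.5 + r * cos(th), 0.5 + r * sin(th))
    }
  )
}

#' Built-in heading-angle archetypes
#'
#' Three 1-D heading profiles (degrees, unwrapped scale): a constant heading
#' (straight runner), a linear ramp through a full turn (circler), and an
#' oscillation (zig-zagger).  Each is a function of `t` in `[0, 1]`
#' returning a numeric vector.
#'
#' @return named list of vectorized archetype functions.
#' @seealso [simulatePopulation()]
#' @export
angleArchetypes <- function() {
  list(
    constant = function(t) rep(0, length(t)),
    ramp = function(t) 360 * t,
    oscillation = function(t) 45 * sin(4 * pi * t)
  )
}

#' Simulate a population of series with planted cluster structure
#'
#' Evaluates each archetype at `length` uniformly spaced times in `[0, 1]`
#' and adds independent Gaussian noise to produce `nPerCluster` members per
#' archetype.  With `noiseSigma = 0` every member equals its archetype
#' exactly, so within-cluster dissimilarity is zero under any metric.
#' Labels are 0-based in generation order, matching the k-means naming of
#' clusters 0, 1, 2, ...
#'
#' @param archetypes named list of archetype functions (see
#'   [trajectoryArchetypes()], [angleArchetypes()]); at least two.
#' @param nPerCluster members per archetype (>= 1).
#' @param length samples per series.
#' @param noiseSigma Gaussian noise standard deviation, in the units of the
#'   archetype (unit-square coordinates for trajectories, degrees for
#'   angles).
#' @param seed integer seed.
#' @param kind `"trajectory2d"` or `"angle1d"`; checked against what the
#'   archetypes return.
#' @return list with `series` (named list of matrices or vectors), `labels`
#'   (0-based integer, named by subject), and `archetype` (character, named
#'   by subject).
#' @export
simulatePopulation <- function(archetypes, nPerCluster, length = 100L,
                               noiseSigma = 0, seed = 1L,
                               kind = c("trajectory2d", "angle1d")) {
  kind <- match.arg(kind)
  stopifnot(length(archetypes) >= 2L, nPerCluster >= 1L, length >= 2L,
            noiseSigma >= 0)
  if (is.null(names(archetypes))) names(archetypes) <- paste0("arch", seq_along(archetypes) - 1L)
  tgrid <- seq(0, 1, length.out = length)
  series <- list(); labels <- integer(); arch <- character()
  withr::with_seed(as.integer(seed), {
    for (ci in seq_along(archetypes)) {
      base <- archetypes[[ci]](tgrid)
      if (kind == "trajectory2d") {
        if (is.null(dim(base)) || ncol(base) != 2L)
          stop("trajectory2d archetypes must return a two-column matrix")
      } else {
        if (!is.null(dim(base))) stop("angle1d archetypes must return a vector")
      }
      for (j in seq_len(nPerCluster)) {
        id <- sprintf("s%02d_%s", length(series) + 1L, names(archetypes)[ci])
        noisy <- base + if (noiseSigma > 0) {
          if (kind == "trajectory2d")
            matrix(stats::rnorm(2L * nrow(base), 0, noiseSigma), ncol = 2L)
          else stats::rnorm(length(base), 0, noiseSigma)
        } else 0
        series[[id]] <- noisy
        labels[id] <- ci - 1L
        arch[id] <- names(archetypes)[ci]
      }
    }
  })
  list(series = series, labels = labels, archetype = arch)
}
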