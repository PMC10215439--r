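#' Pulsatile wall shear stress field on a surface mesh
#'
#' Per-vertex WSS vector time series over one cardiac cycle. Vectors should
#' be tangent to the wall; a tangency residual above `tangency_tol` (relative
#' to the local WSS magnitude) raises a data-quality warning, since WSS is by
#' definition the tangential traction.
#'
#' @param mesh a [surface_mesh()] with outward unit normals.
#' @param times K strictly increasing sample times in `[0, period)` (s).
#' @param period cardiac cycle period T (s).
#' @param vectors K x N x 3 array of WSS samples (Pa); `vectors[k, i, ]` is
#'   the WSS vector at vertex i, time `times[k]`.
#' @param tangency_tol warn when `|wss . n| / |wss|` exceeds this anywhere
#'   the magnitude is positive (default 0.05).
#' @return object of class `wss_field`.
#' @export
wss_field <- function(mesh, times, period, vectors, tangency_tol = 0.05) {
  stopifnot(inherits(mesh, "surface_mesh"))
  times <- as.numeric(times)
  K <- length(times)
  if (K < 2L) stop("need at least 2 time samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1L] < 0 || times[K] >= period) stop("times must lie in [0, period)")
  n <- nrow(mesh$vertices)
  if (!is.array(vectors) || length(dim(vectors)) != 3L ||
      !all(dim(vectors) == c(K, n, 3L))) {
    stop(sprintf("vectors must be a %d x %d x 3 array (K x N x 3)", K, n))
  }
  storage.mode(vectors) <- "double"
  # tangency residual at peak-magnitude samples only is not enough; check all
  dot_n <- vapply(1:3, function(c3) vectors[, , c3] * rep(mesh$normals[, c3], each = K),
                  matrix(0, K, n))
  dot_n <- dot_n[, , 1L] + dot_n[, , 2L] + dot_n[, , 3L]
  mag <- sqrt(vectors[, , 1L]^2 + vectors[, , 2L]^2 + vectors[, , 3L]^2)
  pos <- mag > 0
  if (any(pos) && max(abs(dot_n[pos]) / mag[pos]) > tangency_tol) {
    warning(sprintf(
      "WSS vectors deviate from the tangent plane by up to %.1f%% of their magnitude",
      100 * max(abs(dot_n[pos]) / mag[pos])))
  }
  structure(list(mesh = mesh, times = times, period = period, vectors = vectors),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("wss_field: %d time samples over T = %g s on %d vertices\n",
              length(x$times), x$period, nrow(x$mesh$vertices)))
  invisible(x)
}

#' Periodic trapezoidal quadrature weights
#'
#' Weights for cycle integrals \eqn{\int_0^T f\,dt} from samples at
#' `times` in `[0, T)`: the cycle is closed by wrapping the first sample, so
#' the weights sum to T and the rule is exact for periodic linear
#' interpolants. Sampling need not be uniform.
#'
#' @param times strictly increasing sample times in `[0, period)`.
#' @param period cycle period T (s).
#' @return numeric vector of weights summing to `period`.
#' @export
cycle_weights <- function(times, period) {
  K <- length(times)
  if (K < 2L) stop("need at least 2 time samples")
  prev <- c(times[K] - period, times[-K])
  nxt <- c(times[-1L], times[1L] + period)
  (nxt - prev) / 2
}

# weighted cycle mean of a K x N matrix of per-time per-vertex scalars
cycle_mean <- function(mat, times, period) {
  w <- cycle_weights(times, period)
  as.numeric(crossprod(mat, w)) / period
}
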