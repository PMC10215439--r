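#' Numerical configuration for index computation
#'
#' Floors and caps controlling the degenerate-vertex policy: vertices where
#' TAWSS or the cycle-mean WSS vector nearly vanish are flagged and given
#' capped/zero values rather than NaN, so downstream statistics stay
#' computable.
#'
#' @param tawss_floor TAWSS (Pa) below which OSI/ECAP are treated as
#'   degenerate.
#' @param mean_floor cycle-mean WSS magnitude (Pa) below which the mean
#'   direction — and hence TransWSS — is treated as undefined.
#' @param rrt_denominator_floor denominator floor (Pa) for RRT.
#' @param rrt_cap RRT ceiling (1/Pa) applied at flagged vertices.
#' @param ecap_cap ECAP ceiling (1/Pa) applied at flagged vertices.
#' @return a list of class `index_config`.
#' @export
index_config <- function(tawss_floor = 1e-6, mean_floor = 1e-9,
                         rrt_denominator_floor = 1e-6,
                         rrt_cap = 1e6, ecap_cap = 1e6) {
  structure(list(tawss_floor = tawss_floor, mean_floor = mean_floor,
                 rrt_denominator_floor = rrt_denominator_floor,
                 rrt_cap = rrt_cap, ecap_cap = ecap_cap),
            class = "index_config")
}

#' Cycle-averaged WSS vector
#'
#' \eqn{(1/T)\int_0^T \vec{wss}\,dt} per vertex, by periodic trapezoidal
#' quadrature (the cycle is closed by wrapping the first sample).
#'
#' @param field a [wss_field()].
#' @return N x 3 matrix of mean WSS vectors (Pa).
#' @export
time_average_vector <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  vapply(1:3, function(c3) cycle_mean(field$vectors[, , c3], field$times, field$period),
         numeric(nrow(field$mesh$vertices)))
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' \eqn{\mathrm{TAWSS} = (1/T)\int_0^T \lVert\vec{wss}\rVert\,dt} per vertex.
#'
#' @param field a [wss_field()].
#' @return numeric vector of TAWSS (Pa), nonnegative.
#' @export
compute_tawss <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  mag <- sqrt(field$vectors[, , 1L]^2 + field$vectors[, , 2L]^2 +
              field$vectors[, , 3L]^2)
  cycle_mean(mag, field$times, field$period)
}

#' Oscillatory shear index (OSI)
#'
#' \eqn{\mathrm{OSI} = \tfrac12\left(1 -
#'   \lVert(1/T)\int\vec{wss}\,dt\rVert / \mathrm{TAWSS}\right)},
#' clipped to `[0, 0.5]`. 0 means purely unidirectional shear, 0.5 fully
#' oscillatory (zero cycle-mean vector). Vertices with TAWSS below
#' `config$tawss_floor` are set to 0 and flagged (attribute `flag`).
#'
#' @param field a [wss_field()].
#' @param config an [index_config()].
#' @return numeric OSI vector with logical attribute `flag` marking
#'   degenerate (near-zero TAWSS) vertices.
#' @export
compute_osi <- function(field, config = index_config()) {
  tawss <- compute_tawss(field)
  mean_mag <- sqrt(rowSums(time_average_vector(field)^2))
  flag <- tawss < config$tawss_floor
  osi <- numeric(length(tawss))
  osi[!flag] <- 0.5 * (1 - mean_mag[!flag] / tawss[!flag])
  osi <- pmin(pmax(osi, 0), 0.5)
  attr(osi, "flag") <- flag
  osi
}

#' Relative residence time (RRT)
#'
#' \eqn{\mathrm{RRT} = 1/[(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}]}; the
#' denominator equals the cycle-mean WSS vector magnitude, so RRT is large
#' where shear is low and oscillatory. Where the denominator falls below
#' `config$rrt_denominator_floor` the value is capped at `config$rrt_cap`
#' and flagged.
#'
#' @param tawss per-vertex TAWSS (Pa).
#' @param osi per-vertex OSI.
#' @param config an [index_config()].
#' @return numeric RRT vector (1/Pa) with logical attribute `flag`.
#' @export
compute_rrt <- function(tawss, osi, config = index_config()) {
  denom <- (1 - 2 * as.numeric(osi)) * as.numeric(tawss)
  flag <- denom < config$rrt_denominator_floor
  rrt <- ifelse(flag, config$rrt_cap, 1 / denom)
  attr(rrt, "flag") <- flag
  rrt
}

#' Endothelial cell activation potential (ECAP)
#'
#' \eqn{\mathrm{ECAP} = \mathrm{OSI}/\mathrm{TAWSS}} (1/Pa): high where shear
#' is simultaneously low and oscillatory, i.e. thrombogenically favorable.
#' Vertices with TAWSS below the floor are capped and flagged.
#'
#' @inheritParams compute_rrt
#' @return numeric ECAP vector (1/Pa) with logical attribute `flag`.
#' @export
compute_ecap <- function(tawss, osi, config = index_config()) {
  tawss <- as.numeric(tawss); osi <- as.numeric(osi)
  flag <- tawss < config$tawss_floor
  ecap <- ifelse(flag, ifelse(osi > 0, config$ecap_cap, 0), osi / pmax(tawss, config$tawss_floor))
  attr(ecap, "flag") <- flag
  ecap
}

#' Transverse wall shear stress (TransWSS)
#'
#' \eqn{\mathrm{TransWSS} = (1/T)\int_0^T
#'   \lvert \vec{wss}\cdot(\hat n \times \hat e_{mean}) \rvert \, dt},
#' the time-averaged magnitude of the WSS component perpendicular (within
#' the tangent plane) to the cycle-mean WSS direction \eqn{\hat e_{mean}}.
#' It separates multidirectional from uniaxial near-wall flow. WSS vectors
#' are projected onto the tangent plane first. Vertices whose cycle-mean
#' vector magnitude is below `config$mean_floor` have no defined mean
#' direction; they are set to 0 and flagged.
#'
#' @param field a [wss_field()].
#' @param config an [index_config()].
#' @return numeric TransWSS vector (Pa) with logical attribute `flag`.
#' @export
compute_transwss <- function(field, config = index_config()) {
  stopifnot(inherits(field, "wss_field"))
  nrm <- field$mesh$normals
  K <- length(field$times)
  nvert <- nrow(nrm)
  # tangent-plane projection: wss_t = wss - (wss . n) n
  vx <- field$vectors[, , 1L]; vy <- field$vectors[, , 2L]; vz <- field$vectors[, , 3L]
  nx <- rep(nrm[, 1L], each = K); ny <- rep(nrm[, 2L], each = K); nz <- rep(nrm[, 3L], each = K)
  dn <- vx * nx + vy * ny + vz * nz
  vx <- vx - dn * nx; vy <- vy - dn * ny; vz <- vz - dn * nz
  mean_vec <- cbind(cycle_mean(vx, field$times, field$period),
                    cycle_mean(vy, field$times, field$period),
                    cycle_mean(vz, field$times, field$period))
  mean_mag <- sqrt(rowSums(mean_vec^2))
  flag <- mean_mag < config$mean_floor
  e_mean <- mean_vec / ifelse(mean_mag > 0, mean_mag, 1)
  # q = n x e_mean, the transverse tangent direction
  q <- cbind(nrm[, 2L] * e_mean[, 3L] - nrm[, 3L] * e_mean[, 2L],
             nrm[, 3L] * e_mean[, 1L] - nrm[, 1L] * e_mean[, 3L],
             nrm[, 1L] * e_mean[, 2L] - nrm[, 2L] * e_mean[, 1L])
  proj <- abs(vx * rep(q[, 1L], each = K) + vy * rep(q[, 2L], each = K) +
              vz * rep(q[, 3L], each = K))
  tw <- cycle_mean(proj, field$times, field$period)
  tw[flag] <- 0
  attr(tw, "flag") <- flag
  tw
}

#' Normalize TransWSS by its regional maximum
#'
#' NTransWSS = TransWSS / max(TransWSS over the mask), the per-subject
#' normalization that makes multidirectionality comparable across patients.
#'
#' @param transwss per-vertex TransWSS (Pa).
#' @param mask optional [region_mask()] or logical vector defining the
#'   normalization region (typically the aneurysm ROI); default all vertices.
#' @return NTransWSS in `[0, 1]` (values outside the mask are divided by the
#'   same maximum and may exceed 1 only if the field exceeds its masked
#'   maximum there; within the mask the range is `[0, 1]`).
#' @export
normalize_transwss <- function(transwss, mask = NULL) {
  transwss <- as.numeric(transwss)
  sel <- if (is.null(mask)) rep(TRUE, length(transwss)) else as_mask_logical(mask, length(transwss))
  m <- max(transwss[sel])
  if (!is.finite(m) || m <= 0) stop("TransWSS maximum over the mask is not positive; normalization undefined")
  transwss / m
}

#' Compute the full hemodynamic index bundle
#'
#' TAWSS, OSI, TransWSS, NTransWSS, RRT and ECAP per vertex, with degeneracy
#' flags. Deterministic given the field and configuration.
#'
#' @param field a [wss_field()].
#' @param config an [index_config()].
#' @param roi optional [region_mask()] used as the NTransWSS normalization
#'   domain (default: whole mesh).
#' @return object of class `hemodynamic_indices`: a list with numeric
#'   vectors `tawss`, `osi`, `transwss`, `ntranswss`, `rrt`, `ecap` and a
#'   data frame `flags` (`low_tawss`, `zero_mean`, `rrt_capped`).
#' @export
compute_all_indices <- function(field, config = index_config(), roi = NULL) {
  tawss <- compute_tawss(field)
  osi <- compute_osi(field, config)
  transwss <- compute_transwss(field, config)
  rrt <- compute_rrt(tawss, osi, config)
  ecap <- compute_ecap(tawss, osi, config)
  ntranswss <- normalize_transwss(transwss, roi)
  flags <- data.frame(low_tawss = attr(osi, "flag"),
                      zero_mean = attr(transwss, "flag"),
                      rrt_capped = attr(rrt, "flag"))
  structure(list(tawss = tawss, osi = as.numeric(osi),
                 transwss = as.numeric(transwss),
                 ntranswss = as.numeric(ntranswss),
                 rrt = as.numeric(rrt), ecap = as.numeric(ecap),
                 flags = flags, config = config),
            class = "hemodynamic_indices")
}

#' @export
print.hemodynamic_indices <- function(x, ...) {
  cat(sprintf("hemodynamic_indices on %d vertices\n", length(x$tawss)))
  cat(sprintf("  TAWSS [Pa]: median %.3g | OSI: median %.3g | TransWSS [Pa]: median %.3g\n",
              stats::median(x$tawss), stats::median(x$osi), stats::median(x$transwss)))
  cat(sprintf("  flagged: %d low-TAWSS, %d zero-mean\n",
              sum(x$flags$low_tawss), sum(x$flags$zero_mean)))
  invisible(x)
}

#' @export
as.data.frame.hemodynamic_indices <- function(x, ...) {
  data.frame(vertex_id = seq_along(x$tawss), tawss = x$tawss, osi = x$osi,
             transwss = x$transwss, ntranswss = x$ntranswss,
             rrt = x$rrt, ecap = x$ecap,
             flag_low_tawss = x$flags$low_tawss,
             flag_zero_mean = x$flags$zero_mean,
             flag_rrt_capped = x$flags$rrt_capped)
}
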