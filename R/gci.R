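#' Three-grid refinement study
#'
#' Holds the scalar quantity of interest on coarse, medium and fine meshes
#' together with the (constant) refinement ratio, for Richardson-style
#' convergence verification.
#'
#' @param f_coarse,f_medium,f_fine quantity values on the three grids.
#' @param r refinement ratio between successive grids (> 1).
#' @param fs safety factor for the GCI (1.25 is standard for three-grid
#'   studies).
#' @return object of class `grid_triplet`.
#' @export
grid_triplet <- function(f_coarse, f_medium, f_fine, r = 2, fs = 1.25) {
  vals <- c(f_coarse, f_medium, f_fine, r, fs)
  if (any(!is.finite(vals))) stop("all values must be finite")
  if (r <= 1) stop("refinement ratio must exceed 1")
  structure(list(f_coarse = f_coarse, f_medium = f_medium, f_fine = f_fine,
                 r = r, fs = fs),
            class = "grid_triplet")
}

#' Observed order of convergence
#'
#' Richardson estimate
#' \eqn{p = \ln\left|\frac{f_c - f_m}{f_m - f_f}\right| / \ln r} from a
#' three-grid triplet. Requires monotone convergence: both successive
#' differences nonzero and of the same sign; oscillatory or stalled
#' sequences are flagged and no order is reported.
#'
#' @param t a [grid_triplet()].
#' @return list with `p` (NA when flagged), `monotone` (logical) and the
#'   successive differences `e_cm`, `e_mf`.
#' @export
observed_order <- function(t) {
  stopifnot(inherits(t, "grid_triplet"))
  e_cm <- t$f_coarse - t$f_medium
  e_mf <- t$f_medium - t$f_fine
  monotone <- e_cm != 0 && e_mf != 0 && sign(e_cm) == sign(e_mf) &&
    abs(e_cm) > abs(e_mf)
  p <- if (monotone) log(abs(e_cm / e_mf)) / log(t$r) else NA_real_
  list(p = p, monotone = monotone, e_cm = e_cm, e_mf = e_mf)
}

#' Grid convergence index
#'
#' Roache's GCI on the fine grid,
#' \eqn{\mathrm{GCI}_{fine} = F_s\,\frac{|(f_m - f_f)/f_f|}{r^p - 1}\times 100\%},
#' with the asymptotic-range check
#' \eqn{\mathrm{GCI}_{coarse} / (r^p\,\mathrm{GCI}_{fine})}, which is ~1
#' when the three grids are in the asymptotic convergence range. When
#' `f_fine` is zero the relative form is undefined and the absolute-error
#' form is returned (`relative = FALSE` in the result).
#'
#' @param t a [grid_triplet()].
#' @param p convergence order; default the [observed_order()] estimate.
#' @return list with `gci_fine_pct`, `gci_coarse_pct`, `asymptotic_ratio`,
#'   `p`, `relative`.
#' @export
gci <- function(t, p = NULL) {
  stopifnot(inherits(t, "grid_triplet"))
  if (is.null(p)) {
    oo <- observed_order(t)
    if (!oo$monotone) stop("oscillatory/stalled convergence: supply p explicitly or refine further")
    p <- oo$p
  }
  if (!(is.numeric(p) && p > 0)) stop("convergence order p must be positive")
  rel <- t$f_fine != 0
  denom_f <- if (rel) abs(t$f_fine) else 1
  denom_m <- if (t$f_medium != 0) abs(t$f_medium) else 1
  eps_mf <- abs(t$f_medium - t$f_fine) / denom_f
  eps_cm <- abs(t$f_coarse - t$f_medium) / denom_m
  fac <- t$r^p - 1
  gci_fine <- t$fs * eps_mf / fac * 100
  gci_coarse <- t$fs * eps_cm / fac * 100
  ratio <- if (gci_fine > 0) gci_coarse / (t$r^p * gci_fine) else NA_real_
  list(gci_fine_pct = gci_fine, gci_coarse_pct = gci_coarse,
       asymptotic_ratio = ratio, p = p, relative = rel)
}
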