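#' Specification for the synthetic aneurysm scenario
#'
#' Parameters of the idealized fusiform aneurysm and its synthetic pulsatile
#' WSS field, intraluminal thrombus and inflow waveform. The defaults define
#' the package's reference scenario: a 10 mm radius infrarenal tube with a
#' fusiform sac (15 mm bulge, Gaussian profile), a posterior sac patch of
#' low, purely oscillatory shear co-located with a thick thrombus bump
#' (19 mm peak), an anterior patch of steady flow with a transverse
#' component, steady uniaxial shear of 1.2 Pa elsewhere, a 2 mm wall and a
#' 1 s cardiac cycle.
#'
#' @param seed integer RNG seed (generation is deterministic given it).
#' @param r0 parent-tube radius (mm).
#' @param dr bulge amplitude (mm).
#' @param z0 bulge center along the axis (mm).
#' @param sigma bulge axial standard deviation (mm).
#' @param length axial extent (mm).
#' @param n_theta,n_z grid resolution (both >= 8).
#' @param period cardiac cycle T (s).
#' @param wss_base steady WSS magnitude outside the patches (Pa).
#' @param wss_pulsatility relative cosine modulation of the steady regime
#'   (kept below 1 so the shear never reverses there).
#' @param osc_peak peak oscillation amplitude in the posterior patch (Pa).
#' @param trans_mean,trans_peak steady magnitude and peak transverse
#'   amplitude in the anterior patch (Pa).
#' @param ilt_peak peak ILT thickness (mm).
#' @param wall_offset wall thickness added between lumen and outer ILT
#'   surface (mm).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, r0 = 10, dr = 15, z0 = 60, sigma = 15,
                           length = 120, n_theta = 64L, n_z = 120L,
                           period = 1, wss_base = 1.2, wss_pulsatility = 0.3,
                           osc_peak = 0.6, trans_mean = 0.5, trans_peak = 0.3,
                           ilt_peak = 19, wall_offset = 2) {
  if (r0 <= 0 || dr < 0) stop("need r0 > 0 and dr >= 0")
  if (n_theta < 8L || n_z < 8L) stop("resolution must be >= 8 in both directions")
  if (period <= 0) stop("period must be positive")
  if (any(c(wss_base, osc_peak, trans_mean, trans_peak) < 0)) {
    stop("WSS magnitudes must be nonnegative")
  }
  if (wss_pulsatility < 0 || wss_pulsatility >= 1) {
    stop("wss_pulsatility must lie in [0, 1) so the steady regime never reverses")
  }
  structure(list(seed = as.integer(seed), r0 = r0, dr = dr, z0 = z0,
                 sigma = sigma, length = length,
                 n_theta = as.integer(n_theta), n_z = as.integer(n_z),
                 period = period, wss_base = wss_base,
                 wss_pulsatility = wss_pulsatility, osc_peak = osc_peak,
                 trans_mean = trans_mean, trans_peak = trans_peak,
                 ilt_peak = ilt_peak, wall_offset = wall_offset),
            class = "synthetic_spec")
}

sac_radius <- function(z, spec) {
  spec$r0 + spec$dr * exp(-(z - spec$z0)^2 / (2 * spec$sigma^2))
}

sac_radius_deriv <- function(z, spec) {
  -spec$dr * (z - spec$z0) / spec$sigma^2 * exp(-(z - spec$z0)^2 / (2 * spec$sigma^2))
}

#' Idealized fusiform aneurysm surface
#'
#' Surface of revolution with radius profile
#' \eqn{R(z) = R_0 + \Delta R\,e^{-(z-z_0)^2/(2\sigma^2)}}, triangulated on
#' an `n_theta` x `n_z` grid, with exact analytic outward normals. Vertices
#' where the local radius exceeds the parent-tube radius by more than 5% of
#' the bulge amplitude are tagged as sac (point-data array `sac`, 0/1).
#'
#' @param spec a [synthetic_spec()].
#' @param closed when TRUE, the tube ends are capped with triangle fans
#'   (used for orientation checks via signed volume); capped meshes are for
#'   geometry only — tangent frames are degenerate at the apexes.
#' @return a [surface_mesh()] with point-data arrays `sac` and `z`.
#' @export
make_aneurysm_mesh <- function(spec = synthetic_spec(), closed = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nt <- spec$n_theta; nz <- spec$n_z
  theta <- seq(0, 2 * pi, length.out = nt + 1L)[seq_len(nt)]
  z <- seq(0, spec$length, length.out = nz)
  R <- sac_radius(z, spec)
  Rp <- sac_radius_deriv(z, spec)
  # vertex (i_theta, i_z) -> index i_theta + nt * (i_z - 1)
  ct <- cos(theta); st <- sin(theta)
  verts <- cbind(as.vector(outer(ct, R)), as.vector(outer(st, R)),
                 rep(z, each = nt))
  # outward normal of a revolution surface: (cos, sin, -R'(z)) normalized
  nrm <- cbind(as.vector(outer(ct, rep(1, nz))), as.vector(outer(st, rep(1, nz))),
               rep(-Rp, each = nt))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  idx <- function(it, iz) ((it - 1L) %% nt) + 1L + nt * (iz - 1L)
  it <- rep(seq_len(nt), nz - 1L)
  iz <- rep(seq_len(nz - 1L), each = nt)
  v00 <- idx(it, iz); v10 <- idx(it + 1L, iz)
  v01 <- idx(it, iz + 1L); v11 <- idx(it + 1L, iz + 1L)
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  sac <- as.numeric(rep(R - spec$r0 > 0.05 * spec$dr, each = nt))
  zcol <- rep(z, each = nt)
  if (closed) {
    c0 <- nrow(verts) + 1L; c1 <- nrow(verts) + 2L
    verts <- rbind(verts, c(0, 0, 0), c(0, 0, spec$length))
    nrm <- rbind(nrm, c(0, 0, -1), c(0, 0, 1))
    ring0 <- idx(seq_len(nt), 1L); ring1 <- idx(seq_len(nt), nz)
    faces <- rbind(faces,
                   cbind(c0, ring0[c(2:nt, 1L)], ring0),
                   cbind(c1, ring1, ring1[c(2:nt, 1L)]))
    sac <- c(sac, 0, 0); zcol <- c(zcol, 0, spec$length)
  }
  mesh <- surface_mesh(verts, faces, normals = nrm,
                       point_data = list(sac = sac, z = zcol))
  if (closed && signed_volume(mesh) <= 0) {
    stop("internal error: closed synthetic mesh is not outward oriented")
  }
  mesh
}

# smooth bump in (theta, z): 1 at the patch center, Gaussian falloff;
# periodic in theta via the angular distance
patch_bump <- function(theta, z, theta_c, z_c, s_theta, s_z) {
  dth <- atan2(sin(theta - theta_c), cos(theta - theta_c))
  exp(-dth^2 / (2 * s_theta^2) - (z - z_c)^2 / (2 * s_z^2))
}

#' Synthetic pulsatile WSS field with closed-form ground truth
#'
#' Builds a per-vertex WSS time series
#' \eqn{\vec{wss}(t) = (m + a\cos\omega t)\,\hat e_{ax}
#'   + b\sin(\omega t)\,\hat e_{circ}}
#' in the local tangent frame (\eqn{\hat e_{ax}}: axial direction projected
#' to the tangent plane; \eqn{\hat e_{circ} = \hat n \times \hat e_{ax}}).
#' Each vertex belongs to one of three exact regimes so every vertex has a
#' closed-form ground truth:
#' \describe{
#'   \item{steady}{`b = 0`, `a = pulsatility * m <= m`: TAWSS = m, OSI = 0,
#'     TransWSS = 0. The default regime; `m` dips smoothly inside the sac.}
#'   \item{oscillatory}{`m = b = 0`, `a > 0` (posterior sac patch):
#'     TAWSS = (2/pi) a, OSI = 0.5; the cycle-mean vector vanishes, so the
#'     TransWSS direction is undefined (ground truth `NA`, value flagged).}
#'   \item{transverse}{`a = 0`, `m, b > 0` (anterior sac patch):
#'     TransWSS = (2/pi) b; TAWSS and OSI have no elementary closed form
#'     (`NA` in the ground truth).}
#' }
#' Magnitudes vary smoothly within each regime; regime boundaries are sharp
#' so the closed forms hold exactly per vertex.
#'
#' @param mesh a [make_aneurysm_mesh()] surface (uncapped).
#' @param spec the [synthetic_spec()] used to build the mesh.
#' @param n_time number of uniform time samples over the cycle (>= 16).
#' @return list with `field` (a [wss_field()]) and `truth` (data frame:
#'   `regime`, `m`, `a`, `b`, `tawss`, `osi`, `transwss`; `NA` where no
#'   closed form exists).
#' @export
make_wss_field <- function(mesh, spec = synthetic_spec(), n_time = 360L) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(spec, "synthetic_spec"))
  n_time <- as.integer(n_time)
  if (n_time < 16L) stop("need at least 16 time samples")
  n <- nrow(mesh$vertices)
  nrm <- mesh$normals
  # tangent frame from the tube axis ez
  ax <- cbind(-nrm[, 3L] * nrm[, 1L], -nrm[, 3L] * nrm[, 2L], 1 - nrm[, 3L]^2)
  axn <- sqrt(rowSums(ax^2))
  if (any(axn < 1e-8)) stop("degenerate tangent frame (normal parallel to the axis); use an uncapped tube")
  ax <- ax / axn
  circ <- cbind(nrm[, 2L] * ax[, 3L] - nrm[, 3L] * ax[, 2L],
                nrm[, 3L] * ax[, 1L] - nrm[, 1L] * ax[, 3L],
                nrm[, 1L] * ax[, 2L] - nrm[, 2L] * ax[, 1L])
  theta <- atan2(mesh$vertices[, 2L], mesh$vertices[, 1L])
  z <- mesh$vertices[, 3L]
  sac <- mesh$point_data$sac > 0
  # posterior oscillatory patch (theta ~ pi), anterior transverse (theta ~ 0)
  bump_osc <- patch_bump(theta, z, pi, spec$z0, 0.9, 0.8 * spec$sigma)
  bump_trn <- patch_bump(theta, z, 0, spec$z0, 0.9, 0.8 * spec$sigma)
  regime <- rep("steady", n)
  regime[sac & bump_osc > 0.3] <- "oscillatory"
  regime[sac & bump_trn > 0.3 & regime == "steady"] <- "transverse"
  m <- a <- b <- numeric(n)
  st <- regime == "steady"
  # steady magnitude dips inside the sac (slow recirculating near-wall flow)
  m[st] <- spec$wss_base * (1 - 0.6 * ifelse(sac[st], 1, 0) *
                              exp(-(z[st] - spec$z0)^2 / (2 * spec$sigma^2)))
  a[st] <- spec$wss_pulsatility * m[st]
  os <- regime == "oscillatory"
  a[os] <- spec$osc_peak * pmax(bump_osc[os], 0.3)
  tr <- regime == "transverse"
  m[tr] <- spec$trans_mean
  b[tr] <- spec$trans_peak * pmax(bump_trn[tr], 0.3)
  times <- seq(0, spec$period, length.out = n_time + 1L)[seq_len(n_time)]
  cosw <- cos(2 * pi * times / spec$period)
  sinw <- sin(2 * pi * times / spec$period)
  vectors <- array(0, dim = c(n_time, n, 3L))
  for (c3 in 1:3) {
    # K x N: (m + a cos) * ax + b sin * circ, built by outer products
    vectors[, , c3] <- outer(rep(1, n_time), m * ax[, c3]) +
      outer(cosw, a * ax[, c3]) + outer(sinw, b * circ[, c3])
  }
  truth <- data.frame(
    regime = regime, m = m, a = a, b = b,
    tawss = ifelse(st, m, ifelse(os, (2 / pi) * a, NA_real_)),
    osi = ifelse(st, 0, ifelse(os, 0.5, NA_real_)),
    transwss = ifelse(st, 0, ifelse(tr, (2 / pi) * b, NA_real_)))
  list(field = wss_field(mesh, times, spec$period, vectors), truth = truth)
}

#' Ground-truth ILT thickness profile
#'
#' Gaussian bump co-located with the posterior (oscillatory, low-shear) sac
#' patch, peaking at `spec$ilt_peak` mm and truncated to exactly zero in the
#' far field, so ILT-free regions exist by construction.
#'
#' @param mesh a [make_aneurysm_mesh()] surface.
#' @param spec a [synthetic_spec()].
#' @return numeric vector of per-vertex thickness (mm, >= 0).
#' @export
ground_truth_thickness <- function(mesh, spec = synthetic_spec()) {
  theta <- atan2(mesh$vertices[, 2L], mesh$vertices[, 1L])
  z <- mesh$vertices[, 3L]
  bump <- patch_bump(theta, z, pi, spec$z0, 1.3, spec$sigma)
  pmax((spec$ilt_peak + 0.3) * bump - 0.3, 0)
}

#' Outer ILT surface offset from the lumen
#'
#' Displaces each lumen vertex outward along its normal by the ground-truth
#' thickness plus the wall offset, emulating the segmented outer ILT/wall
#' surface. Warns when the offset exceeds the local axial curvature radius
#' (potential self-intersection at concave shoulders).
#'
#' @param mesh lumen [surface_mesh()] from [make_aneurysm_mesh()].
#' @param spec a [synthetic_spec()].
#' @param thickness optional per-vertex thickness (mm); default
#'   [ground_truth_thickness()].
#' @return list with `outer` (a [surface_mesh()]) and `thickness`
#'   (the ground truth used).
#' @export
make_ilt_surfaces <- function(mesh, spec = synthetic_spec(), thickness = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(thickness)) thickness <- ground_truth_thickness(mesh, spec)
  if (any(thickness < 0)) stop("thickness profile must be nonnegative")
  offset <- thickness + spec$wall_offset
  z <- mesh$vertices[, 3L]
  # outward offsets can only self-intersect where the surface is concave
  # along the axis (R'' > 0, the neck shoulders); the convex sac apex is safe
  h <- 1e-4
  Rpp <- (sac_radius(z + h, spec) - 2 * sac_radius(z, spec) + sac_radius(z - h, spec)) / h^2
  kappa <- pmax(Rpp, 0) / (1 + sac_radius_deriv(z, spec)^2)^1.5
  if (any(offset * kappa > 1)) {
    warning("offset exceeds the local curvature radius somewhere; outer surface may self-intersect")
  }
  verts <- mesh$vertices + mesh$normals * offset
  outer_mesh <- surface_mesh(verts, mesh$faces)
  list(outer = outer_mesh, thickness = thickness)
}

#' Synthetic triphasic inflow waveform
#'
#' A deterministic infrarenal-style velocity waveform — sharp systolic peak
#' in early cycle, a diastolic reverse-flow lobe, low late-diastolic forward
#' flow — represented exactly as a 10-harmonic Fourier series (fitted by
#' least squares to a smooth generating shape, then kept as the series
#' itself, so it is band-limited by construction). This is a synthetic
#' stand-in shaped like published PC-MRI infrarenal waveforms, not a
#' reproduction of any measured dataset.
#'
#' @param spec a [synthetic_spec()] (only the period is used).
#' @param mean_velocity cycle-mean velocity (m/s).
#' @param peak_velocity approximate systolic peak (m/s).
#' @return a [waveform()] with `K = 10` harmonics, unit `"m/s"`.
#' @export
make_inflow_waveform <- function(spec = synthetic_spec(), mean_velocity = 0.11,
                                 peak_velocity = 0.75) {
  T <- spec$period
  shape <- function(t) {
    u <- (t %% T) / T
    exp(-(u - 0.16)^2 / (2 * 0.055^2)) - 0.35 * exp(-(u - 0.42)^2 / (2 * 0.07^2)) +
      0.08 * exp(-(u - 0.75)^2 / (2 * 0.12^2))
  }
  tt <- seq(0, T, length.out = 257L)[1:256]
  y <- shape(tt)
  # scale to the requested peak and shift to the requested mean
  y <- y * peak_velocity / max(y)
  w <- fit_waveform(tt, y, K = 10L, period = T, unit = "m/s")
  w$a0 <- mean_velocity  # set the DC term; the pulsatile shape is unchanged
  w
}

#' UV sphere mesh
#'
#' Latitude-longitude triangulation of a sphere with exact radial normals;
#' used for analytic distance checks (concentric spheres have a known
#' constant surface separation).
#'
#' @param radius sphere radius (mm).
#' @param n_lat number of latitude bands (>= 3).
#' @param n_lon number of longitude steps (>= 3).
#' @param center length-3 center (mm).
#' @return a [surface_mesh()].
#' @export
uv_sphere <- function(radius, n_lat = 32L, n_lon = 64L, center = c(0, 0, 0)) {
  stopifnot(radius > 0, n_lat >= 3L, n_lon >= 3L)
  phi <- seq(0, pi, length.out = n_lat + 1L)[2:n_lat]  # exclude poles
  lam <- seq(0, 2 * pi, length.out = n_lon + 1L)[seq_len(n_lon)]
  sp <- sin(phi); cp <- cos(phi)
  nrm <- cbind(as.vector(outer(cos(lam), sp)), as.vector(outer(sin(lam), sp)),
               rep(cp, each = n_lon))
  nrm <- rbind(nrm, c(0, 0, 1), c(0, 0, -1))
  verts <- sweep(nrm * radius, 2L, center, `+`)
  nb <- n_lat - 1L  # rings
  idx <- function(il, ir) ((il - 1L) %% n_lon) + 1L + n_lon * (ir - 1L)
  il <- rep(seq_len(n_lon), nb - 1L)
  ir <- rep(seq_len(nb - 1L), each = n_lon)
  v00 <- idx(il, ir); v10 <- idx(il + 1L, ir)
  v01 <- idx(il, ir + 1L); v11 <- idx(il + 1L, ir + 1L)
  top <- n_lon * nb + 1L; bot <- n_lon * nb + 2L
  ring1 <- idx(seq_len(n_lon), 1L); ringb <- idx(seq_len(n_lon), nb)
  faces <- rbind(cbind(v00, v11, v10), cbind(v00, v01, v11),
                 cbind(top, ring1, ring1[c(2:n_lon, 1L)]),
                 cbind(bot, ringb[c(2:n_lon, 1L)], ringb))
  surface_mesh(verts, faces, normals = nrm)
}
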