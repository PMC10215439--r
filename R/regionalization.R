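#' Hemodynamic and thickness thresholds
#'
#' Literature cut-offs separating hemodynamic conditions favorable to ILT
#' deposition from unfavorable ones, plus the thickness cut-offs defining
#' the thickest/thinnest ILT zones. TAWSS below 0.4 Pa, OSI above 0.2 (0.3
#' as the common alternative), ECAP above 1.4 1/Pa and RRT above 10 1/Pa
#' are the favorable conditions; thickness thresholds are in cm as reported
#' clinically (1.7 cm thickest, 0.15 cm thinnest; alternatives 1.5 / 0.3).
#'
#' @param tawss_low Pa; TAWSS below this is favorable.
#' @param osi_high dimensionless; OSI above this is favorable.
#' @param ecap_high 1/Pa; ECAP above this is favorable.
#' @param rrt_high 1/Pa; RRT above this is favorable.
#' @param thick_min cm; ILT at least this thick is "thickest".
#' @param thin_max cm; ILT (positive) up to this is "thinnest".
#' @param ilt_presence_min mm; thickness above this counts as ILT at all
#'   (sub-voxel values are segmentation noise at 1-2 mm CT slice thickness).
#' @param ntranswss_split dimensionless; NTransWSS high/low split.
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(tawss_low = 0.4, osi_high = 0.2, ecap_high = 1.4,
                             rrt_high = 10, thick_min = 1.7, thin_max = 0.15,
                             ilt_presence_min = 0.1, ntranswss_split = 0.5) {
  vals <- c(tawss_low, osi_high, ecap_high, rrt_high, thick_min, thin_max,
            ilt_presence_min, ntranswss_split)
  if (any(!is.finite(vals)) || any(vals <= 0)) stop("all thresholds must be positive")
  if (!(thin_max < thick_min)) stop("thin_max must be below thick_min")
  structure(list(tawss_low = tawss_low, osi_high = osi_high,
                 ecap_high = ecap_high, rrt_high = rrt_high,
                 thick_min = thick_min, thin_max = thin_max,
                 ilt_presence_min = ilt_presence_min,
                 ntranswss_split = ntranswss_split),
            class = "threshold_config")
}

#' Named vertex region on a surface mesh
#'
#' A boolean vertex set together with its vertex count and lumped surface
#' area (one third of the incident face areas per selected vertex).
#'
#' @param mesh a [surface_mesh()].
#' @param selected logical vector, one entry per vertex.
#' @param name region label.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(mesh, selected, name = "region") {
  stopifnot(inherits(mesh, "surface_mesh"))
  selected <- as.logical(selected)
  if (length(selected) != nrow(mesh$vertices)) {
    stop("mask length must equal the vertex count")
  }
  selected[is.na(selected)] <- FALSE
  structure(list(name = name, selected = selected,
                 vertex_count = sum(selected),
                 area_mm2 = sum(vertex_areas(mesh)[selected])),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s': %d vertices, %.1f mm^2\n",
              x$name, x$vertex_count, x$area_mm2))
  invisible(x)
}

as_mask_logical <- function(mask, n) {
  sel <- if (inherits(mask, "region_mask")) mask$selected else as.logical(mask)
  if (length(sel) != n) stop("mask length does not match the field length")
  sel
}

#' Define the aneurysmal region of interest
#'
#' The ROI is the aneurysm sac surface, excluding the parent vessel and the
#' iliac arteries. It is selected either by explicit vertex indices (e.g.
#' generator sac tags or a label file) or by axial z-bounds.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex_ids integer vertex indices, or a logical per-vertex vector.
#' @param z_bounds length-2 numeric `c(zmin, zmax)` (mm); vertices with
#'   `zmin <= z <= zmax` are selected. Ignored when `vertex_ids` is given.
#' @return a [region_mask()] named `"ROI"`.
#' @export
make_roi <- function(mesh, vertex_ids = NULL, z_bounds = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  if (!is.null(vertex_ids)) {
    sel <- if (is.logical(vertex_ids)) vertex_ids else seq_len(n) %in% as.integer(vertex_ids)
  } else if (!is.null(z_bounds)) {
    stopifnot(length(z_bounds) == 2L)
    z <- mesh$vertices[, 3L]
    sel <- z >= z_bounds[1L] & z <= z_bounds[2L]
  } else {
    stop("provide vertex_ids or z_bounds")
  }
  if (!any(sel)) stop("ROI selection is empty")
  region_mask(mesh, sel, "ROI")
}

#' Partition the ROI into ILT and ILT-free regions
#'
#' ILT = ROI vertices with thickness above `ilt_presence_min`; ILT-free is
#' the ROI complement. The two masks partition the ROI exactly.
#'
#' @param thickness a `thickness_field` on the same mesh as `roi`.
#' @param roi the ROI [region_mask()].
#' @param cfg a [threshold_config()].
#' @return list of two [region_mask()]s: `ilt`, `ilt_free`.
#' @export
split_ilt <- function(thickness, roi, cfg = threshold_config()) {
  stopifnot(inherits(thickness, "thickness_field"))
  sel <- as_mask_logical(roi, length(thickness$thickness))
  ilt <- sel & (thickness$thickness > cfg$ilt_presence_min)
  list(ilt = region_mask(thickness$mesh, ilt, "ILT"),
       ilt_free = region_mask(thickness$mesh, sel & !ilt, "ILT-free"))
}

#' Thickest and thinnest ILT zones
#'
#' Thickest: ILT with thickness at least `thick_min` (cm); thinnest: ILT
#' with positive thickness at most `thin_max` (cm). Thickness is carried in
#' mm internally; the cm thresholds are converted explicitly here, in one
#' place, to avoid silent 10x unit errors.
#'
#' @inheritParams split_ilt
#' @param ilt the ILT [region_mask()] from [split_ilt()].
#' @return list of two disjoint [region_mask()]s: `thickest`, `thinnest`.
#' @export
extreme_ilt_regions <- function(thickness, ilt, cfg = threshold_config()) {
  stopifnot(inherits(thickness, "thickness_field"))
  th_mm <- thickness$thickness
  sel <- as_mask_logical(ilt, length(th_mm))
  thick_mm <- cfg$thick_min * 10
  thin_mm <- cfg$thin_max * 10
  list(thickest = region_mask(thickness$mesh, sel & th_mm >= thick_mm, "thickest ILT"),
       thinnest = region_mask(thickness$mesh, sel & th_mm > 0 & th_mm <= thin_mm, "thinnest ILT"))
}

#' Favorable / unfavorable threshold maps per index
#'
#' Boolean maps of the hemodynamic conditions favorable for ILT deposition:
#' low TAWSS (< `tawss_low`), high OSI, high ECAP, high RRT, and their
#' conjunction, all restricted to the ROI.
#'
#' @param indices a `hemodynamic_indices` bundle.
#' @param roi the ROI [region_mask()].
#' @param cfg a [threshold_config()].
#' @param mesh the [surface_mesh()] the indices were computed on.
#' @return named list of [region_mask()]s: `favorable_tawss`,
#'   `favorable_osi`, `favorable_ecap`, `favorable_rrt`, `favorable_all`.
#' @export
threshold_maps <- function(indices, roi, mesh, cfg = threshold_config()) {
  stopifnot(inherits(indices, "hemodynamic_indices"))
  sel <- as_mask_logical(roi, length(indices$tawss))
  f_tawss <- sel & indices$tawss < cfg$tawss_low
  f_osi <- sel & indices$osi > cfg$osi_high
  f_ecap <- sel & indices$ecap > cfg$ecap_high
  f_rrt <- sel & indices$rrt > cfg$rrt_high
  list(favorable_tawss = region_mask(mesh, f_tawss, "TAWSS < low threshold"),
       favorable_osi = region_mask(mesh, f_osi, "OSI > high threshold"),
       favorable_ecap = region_mask(mesh, f_ecap, "ECAP > high threshold"),
       favorable_rrt = region_mask(mesh, f_rrt, "RRT > high threshold"),
       favorable_all = region_mask(mesh, f_tawss & f_osi & f_ecap & f_rrt,
                                   "all favorable"))
}

#' Classify near-wall flow nature into eight compartments
#'
#' Octant labels {low,high}TAWSS x {low,high}OSI x {low,high}NTransWSS:
#' e.g. low TAWSS + high OSI + low NTransWSS is oscillating non-disturbed
#' flow, while high NTransWSS marks multidirectional (disturbed) flow.
#' The eight classes partition the ROI.
#'
#' @inheritParams threshold_maps
#' @return a factor of length N (vertices outside the ROI are `NA`) with
#'   levels `"lT.lO.lN"` ... `"hT.hO.hN"` (l = low, h = high; T = TAWSS,
#'   O = OSI, N = NTransWSS), plus attribute `counts`, a table of per-class
#'   vertex counts over the ROI.
#' @export
classify_flow_nature <- function(indices, roi, cfg = threshold_config()) {
  stopifnot(inherits(indices, "hemodynamic_indices"))
  sel <- as_mask_logical(roi, length(indices$tawss))
  hT <- indices$tawss >= cfg$tawss_low
  hO <- indices$osi > cfg$osi_high
  hN <- indices$ntranswss > cfg$ntranswss_split
  lab <- paste0(ifelse(hT, "hT", "lT"), ".", ifelse(hO, "hO", "lO"), ".",
                ifelse(hN, "hN", "lN"))
  lev <- as.vector(outer(outer(c("lT", "hT"), c("lO", "hO"), paste, sep = "."),
                         c("lN", "hN"), paste, sep = "."))
  lab[!sel] <- NA
  f <- factor(lab, levels = lev)
  attr(f, "counts") <- table(f[sel])
  f
}

#' Summary statistics of a per-vertex field over a region
#'
#' Median, quartiles (linear-interpolation, type 7), IQR, 10th/90th
#' percentiles (box-plot whiskers), min, max and n.
#'
#' @param values per-vertex numeric field.
#' @param mask a [region_mask()] or logical vector.
#' @return one-row data frame with columns `n`, `min`, `p10`, `q1`,
#'   `median`, `q3`, `p90`, `max`, `iqr`.
#' @export
region_summary <- function(values, mask) {
  sel <- as_mask_logical(mask, length(values))
  if (!any(sel)) stop("region is empty; no statistics defined")
  x <- values[sel]
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7, names = FALSE)
  data.frame(n = length(x), min = min(x), p10 = q[1L], q1 = q[2L],
             median = q[3L], q3 = q[4L], p90 = q[5L], max = max(x),
             iqr = q[4L] - q[2L])
}

#' Spearman rank correlation between ILT thickness and an index
#'
#' rho by average-rank Pearson correlation on ranks (ties averaged); the
#' two-sided p-value uses the large-sample t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}, appropriate for the thousands of
#' vertices in a surface region. Spatial autocorrelation between neighboring
#' vertices is ignored, so p-values are anti-conservative; they are reported
#' for compatibility with common practice, not as rigorous inference.
#'
#' @param thickness per-vertex thickness values (mm).
#' @param index per-vertex index values.
#' @param mask a [region_mask()] or logical vector (typically the ILT region).
#' @return list with `rho`, `p_value`, `n`, and logical `degenerate`
#'   (TRUE when either input is constant over the mask, leaving rho
#'   undefined — then `rho` and `p_value` are `NA`).
#' @export
spearman_correlation <- function(thickness, index, mask) {
  sel <- as_mask_logical(mask, length(thickness))
  x <- thickness[sel]; y <- index[sel]
  n <- length(x)
  if (n < 3L) stop("need at least 3 vertices for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

#' Regional co-localization report
#'
#' The package's summary product: for each analysis region (whole ROI, ILT,
#' ILT-free, thickest ILT, thinnest ILT) and each hemodynamic index, the
#' region summary statistics and the fraction of vertices meeting the
#' favorable-deposition threshold; plus, per index, the Spearman correlation
#' of the index with ILT thickness over the ILT region. Deterministic given
#' its inputs.
#'
#' @param indices a `hemodynamic_indices` bundle.
#' @param thickness a `thickness_field` on the same mesh.
#' @param roi the ROI [region_mask()].
#' @param cfg a [threshold_config()].
#' @return list with data frames `summary` (region x index rows) and
#'   `correlation` (one row per index, over the ILT region), and the masks
#'   used (`regions`).
#' @export
growth_potential_report <- function(indices, thickness, roi, cfg = threshold_config()) {
  stopifnot(inherits(indices, "hemodynamic_indices"),
            inherits(thickness, "thickness_field"))
  mesh <- thickness$mesh
  parts <- split_ilt(thickness, roi, cfg)
  ext <- extreme_ilt_regions(thickness, parts$ilt, cfg)
  regions <- list(AAA = roi, ILT = parts$ilt, `ILT-free` = parts$ilt_free,
                  `thickest ILT` = ext$thickest, `thinnest ILT` = ext$thinnest)
  idx <- list(TAWSS = indices$tawss, OSI = indices$osi,
              TransWSS = indices$transwss, NTransWSS = indices$ntranswss,
              ECAP = indices$ecap, RRT = indices$rrt)
  favorable <- list(
    TAWSS = indices$tawss < cfg$tawss_low,
    OSI = indices$osi > cfg$osi_high,
    TransWSS = rep(NA, length(indices$tawss)),  # no literature cut-off
    NTransWSS = indices$ntranswss > cfg$ntranswss_split,
    ECAP = indices$ecap > cfg$ecap_high,
    RRT = indices$rrt > cfg$rrt_high)
  rows <- list()
  for (rn in names(regions)) {
    sel <- regions[[rn]]$selected
    for (ix in names(idx)) {
      if (!any(sel)) {
        row <- data.frame(n = 0L, min = NA, p10 = NA, q1 = NA, median = NA,
                          q3 = NA, p90 = NA, max = NA, iqr = NA)
      } else {
        row <- region_summary(idx[[ix]], sel)
      }
      row$region <- rn
      row$index <- ix
      row$favorable_fraction <- if (any(sel) && !all(is.na(favorable[[ix]]))) {
        mean(favorable[[ix]][sel])
      } else NA_real_
      rows[[length(rows) + 1L]] <- row
    }
  }
  summary_df <- do.call(rbind, rows)
  summary_df <- summary_df[, c("region", "index", "n", "min", "p10", "q1",
                               "median", "q3", "p90", "max", "iqr",
                               "favorable_fraction")]
  cor_rows <- lapply(names(idx), function(ix) {
    if (parts$ilt$vertex_count >= 3L) {
      r <- spearman_correlation(thickness$thickness, idx[[ix]], parts$ilt)
      data.frame(index = ix, rho = r$rho, p_value = r$p_value, n = r$n)
    } else {
      data.frame(index = ix, rho = NA_real_, p_value = NA_real_,
                 n = parts$ilt$vertex_count)
    }
  })
  list(summary = summary_df, correlation = do.call(rbind, cor_rows),
       regions = regions, config = cfg)
}
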