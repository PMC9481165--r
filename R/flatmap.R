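# Flat-map module: interareal connection geometry from a voxel connectome.
#
# The mesoscale voxel model lives on (approximately) a spherical shell.
# Interareal Gaussian profile parameters are estimated by (1) fitting a
# sphere to the voxel positions, (2) projecting each position to a 2D
# "flat map" via two arctan charts scaled by the sphere radius, (3) taking
# convex-hull areas per region, and (4) measuring the weighted spread of
# inbound connection weights per target voxel. All positions are in um
# throughout; voxel-index inputs are converted on ingest (voxel size
# 100 um), which makes the voxel-size factor in the projection a pure unit
# conversion.

#' Construct a voxel connectome
#'
#' @param positions N x 3 matrix of voxel positions. In um by default; if
#'   `unit = "voxel"` the positions are voxel indices and are multiplied by
#'   `voxel_size_um` on ingest.
#' @param labels character vector of region labels, length N
#' @param weights N x N nonnegative matrix; `weights[l, k]` is the
#'   connection strength from source voxel l to target voxel k
#' @param voxel_size_um voxel edge length in um (default 100)
#' @param unit `"um"` or `"voxel"`
#' @return an object of class `mvc_voxel_connectome`
#' @export
voxel_connectome <- function(positions, labels, weights,
                             voxel_size_um = 100, unit = c("um", "voxel")) {
  unit <- match.arg(unit)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop_invalid("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (length(labels) != n)
    stop_invalid("labels must have one entry per voxel")
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(n, n)))
    stop_invalid("weights must be N x N")
  if (any(weights < 0)) stop_invalid("weights must be nonnegative")
  if (unit == "voxel") positions <- positions * voxel_size_um
  structure(list(positions = positions, labels = as.character(labels),
                 weights = weights, voxel_size_um = voxel_size_um),
            class = "mvc_voxel_connectome")
}

#' Read / write a voxel connectome as plain-text CSV
#'
#' Two files: `<stem>_voxels.csv` (x, y, z, label) and
#' `<stem>_weights.csv` (source, target, weight triplets, 1-based indices;
#' absent pairs are zero).
#'
#' @param stem file stem (path without suffix)
#' @param vc an `mvc_voxel_connectome` (for writing)
#' @return `read_voxel_connectome` returns an `mvc_voxel_connectome`
#' @export
write_voxel_connectome <- function(vc, stem) {
  vox <- data.frame(x = vc$positions[, 1], y = vc$positions[, 2],
                    z = vc$positions[, 3], label = vc$labels)
  utils::write.csv(vox, paste0(stem, "_voxels.csv"), row.names = FALSE)
  idx <- which(vc$weights != 0, arr.ind = TRUE)
  tri <- data.frame(source = idx[, 1], target = idx[, 2],
                    weight = vc$weights[idx])
  utils::write.csv(tri, paste0(stem, "_weights.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_voxel_connectome
#' @export
read_voxel_connectome <- function(stem) {
  vox <- utils::read.csv(paste0(stem, "_voxels.csv"))
  tri <- utils::read.csv(paste0(stem, "_weights.csv"))
  n <- nrow(vox)
  w <- matrix(0, n, n)
  w[cbind(tri$source, tri$target)] <- tri$weight
  voxel_connectome(as.matrix(vox[, c("x", "y", "z")]), vox$label, w)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to 3D points by the algebraic linearization
#' `|x|^2 = 2 c . x + (r^2 - |c|^2)`, which is exact for noiseless data,
#' optionally followed by Gauss-Newton refinement of the geometric
#' objective sum(|x - c| - r)^2.
#'
#' @param points N x 3 matrix, N >= 4, not coplanar
#' @param refine logical; run geometric refinement (default TRUE)
#' @return list with `center` (length 3) and `radius`
#' @export
fit_sphere <- function(points, refine = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 4L)
    stop_estimation("sphere fit needs at least 4 points in 3D")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop_estimation("degenerate (coplanar or coincident) points: sphere fit failed")
  sol <- qr.coef(qrA, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0)
    stop_estimation("sphere fit produced nonpositive radius")
  radius <- sqrt(r2)
  if (refine) {
    for (it in 1:20) {
      d <- points - matrix(center, nrow(points), 3, byrow = TRUE)
      dist <- sqrt(rowSums(d^2))
      if (any(dist < .Machine$double.eps)) break
      res <- dist - radius
      J <- cbind(-d / dist, -1)
      step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
      if (is.null(step)) break
      center <- center + step[1:3]
      radius <- radius + step[4]
      if (sqrt(sum(step^2)) < 1e-12 * radius) break
    }
  }
  list(center = as.numeric(center), radius = as.numeric(radius))
}

#' Construct a flat map
#'
#' @param center sphere center (um)
#' @param radius sphere radius (um)
#' @param voxel_size_um voxel edge length (um); used only when ingesting
#'   voxel-index coordinates
#' @return object of class `mvc_flatmap`
#' @export
flatmap <- function(center, radius, voxel_size_um = 100) {
  if (length(center) != 3L || !all(is.finite(center)))
    stop_invalid("center must be a finite length-3 vector")
  assert_scalar_num(radius, "radius")
  if (radius <= 0) stop_invalid("radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius,
                 voxel_size_um = voxel_size_um), class = "mvc_flatmap")
}

#' Project 3D positions to the 2D flat map
#'
#' Azimuth/elevation chart about the sphere center: with u = x - c,
#' `xbar1 = r * atan(u1 / u2)` and
#' `xbar2 = r * atan(u3 / sqrt(u1^2 + u2^2))`, both in um (arc length).
#' The arctan is quadrant-naive, as appropriate for patches confined to a
#' single hemisphere-quadrant; set `quadrant_aware = TRUE` to use atan2 in
#' the azimuth chart.
#'
#' @param points N x 3 matrix of positions (um)
#' @param fm an `mvc_flatmap`
#' @param quadrant_aware use atan2 for azimuth (extension; default FALSE)
#' @return N x 2 matrix of flat positions (um)
#' @export
project_flat <- function(points, fm, quadrant_aware = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  u1 <- points[, 1] - fm$center[1]
  u2 <- points[, 2] - fm$center[2]
  u3 <- points[, 3] - fm$center[3]
  horiz <- sqrt(u1^2 + u2^2)
  sing <- horiz == 0
  if (any(sing))
    stop_estimation("singular projection: point(s) on the chart axis (x1=c1, x2=c2)")
  x1 <- if (quadrant_aware) fm$radius * atan2(u1, u2)
        else fm$radius * atan(u1 / u2)
  x2 <- fm$radius * atan(u3 / horiz)
  cbind(x1, x2, deparse.level = 0)
}

#' Convex-hull surface area of a flat-mapped region
#'
#' @param flat_xy N x 2 matrix of flat positions (um), N >= 3, not collinear
#' @return area in mm^2
#' @export
estimate_area <- function(flat_xy) {
  flat_xy <- as.matrix(flat_xy)
  if (nrow(flat_xy) < 3L)
    stop_estimation("area estimation needs at least 3 points")
  h <- grDevices::chull(flat_xy)
  hx <- flat_xy[h, 1]; hy <- flat_xy[h, 2]
  # shoelace formula
  a_um2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a_um2 <= 0)
    stop_estimation("collinear points: degenerate convex hull")
  a_um2 * 1e-6  # um^2 -> mm^2
}

# Unimodality filter machinery. Target voxels with multi-modal inbound
# weight profiles are excluded from the width average; the criterion:
# Gaussian-smooth the weights over the source flat positions (bandwidth
# in voxel units), then count local maxima above `threshold` * the field
# maximum among neighbourhoods of radius 1.5 voxels.
mode_filter_precompute <- function(src_xy, voxel_size_um = 100,
                                   bandwidth = 1.0) {
  bw <- bandwidth * voxel_size_um
  d2 <- as.matrix(stats::dist(src_xy))^2
  # neighbourhood radius: 1.5 voxels, widened to 1.5 x the median
  # nearest-neighbour spacing when voxels sit on a coarser grid
  nn <- sqrt(apply(d2 + diag(Inf, nrow(d2)), 1, min))
  rad <- 1.5 * max(voxel_size_um, stats::median(nn))
  nb <- apply(d2 <= rad^2, 1, which, simplify = FALSE)
  list(K = exp(-d2 / (2 * bw^2)), nb = nb)
}

count_weight_modes <- function(pre, w, threshold = 0.10) {
  sm <- as.numeric(pre$K %*% w)
  mx <- max(sm)
  is_max <- vapply(seq_along(sm), function(i)
    sm[i] >= max(sm[pre$nb[[i]]]), logical(1))
  sum(is_max & sm > threshold * mx)
}

#' Interareal Gaussian width from a voxel connectome
#'
#' For each target voxel k in region j, the inbound width is the weighted
#' per-axis standard deviation of the source flat positions about their
#' center of mass, `d_k = sqrt(sum_l w_lk d_l^2 / (2 sum_l w_lk))` with
#' d_l the 2D distance to the center of mass; the factor 2 converts the
#' radial second moment to the per-axis width that parameterizes the
#' connection profile `P(r) = d_p exp(-r^2 / (2 d_w^2))` (for an
#' isotropic 2D Gaussian, E[r^2] = 2 d_w^2). The region-level width is
#' the unweighted mean of d_k over target voxels whose inbound profile
#' passes the unimodality filter. The estimate is an upper bound on the
#' true neuron-level width (a voxel pools neurons with partially
#' overlapping input fields).
#'
#' @param vc an `mvc_voxel_connectome`
#' @param source,target region labels
#' @param fm an `mvc_flatmap`; fitted from the voxel positions if NULL
#' @param bandwidth,threshold unimodality-filter parameters (smoothing
#'   bandwidth in voxel units; maxima threshold as a fraction of the peak)
#' @return estimated width d_w (um), with attribute `n_voxels` (targets
#'   used) and `n_excluded` (multi-modal targets dropped)
#' @export
estimate_interareal_width <- function(vc, source, target, fm = NULL,
                                      bandwidth = 1.0, threshold = 0.10) {
  src <- which(vc$labels == source)
  tgt <- which(vc$labels == target)
  if (!length(src) || !length(tgt))
    stop_invalid("unknown region label(s): %s -> %s", source, target)
  W <- vc$weights[src, tgt, drop = FALSE]
  if (all(W == 0))
    stop_estimation("no nonzero weights from %s to %s", source, target)
  if (is.null(fm)) {
    sp <- fit_sphere(vc$positions)
    fm <- flatmap(sp$center, sp$radius, vc$voxel_size_um)
  }
  src_xy <- project_flat(vc$positions[src, , drop = FALSE], fm)
  pre <- if (length(src) > 1)
    mode_filter_precompute(src_xy, vc$voxel_size_um, bandwidth) else NULL
  dk <- numeric(0); excl <- 0L
  for (j in seq_along(tgt)) {
    w <- W[, j]
    tw <- sum(w)
    if (tw == 0) next
    if (!is.null(pre) && count_weight_modes(pre, w, threshold) > 1L) {
      excl <- excl + 1L
      next
    }
    com <- colSums(src_xy * w) / tw
    d2 <- (src_xy[, 1] - com[1])^2 + (src_xy[, 2] - com[2])^2
    dk <- c(dk, sqrt(sum(w * d2) / (2 * tw)))
  }
  if (!length(dk))
    stop_estimation("no target voxels survived the unimodality filter")
  structure(mean(dk), n_voxels = length(dk), n_excluded = excl)
}

#' Interareal Gaussian peak probability
#'
#' Solves the extrinsic in-degree identity
#' `e * w_ij / sum_i w_ij = 2 pi dtw^2 * d_p * c_i` for the peak
#' probability d_p. Raw values above 1 are capped to 1 with a warning
#' (they arise when the source channel count is too small to be consistent
#' with the other constraints).
#'
#' @param w_ij aggregate connection strength from source area i into
#'   target j
#' @param w_total_into_j total inbound strength into j (all sources)
#' @param e extrinsic in-degree (default 1000)
#' @param dtw Gaussian width in target pixels (dtilde_w)
#' @param c_i number of channels in the source area
#' @return d_p in [0, 1]; attribute `raw` keeps the uncapped value
#' @export
estimate_interareal_peak <- function(w_ij, w_total_into_j, e = 1000,
                                     dtw, c_i) {
  for (nm in c("w_ij", "w_total_into_j", "e", "dtw", "c_i"))
    assert_scalar_num(get(nm), nm)
  if (w_total_into_j <= 0 || dtw <= 0 || c_i <= 0 || e <= 0)
    stop_invalid("w_total_into_j, e, dtw and c_i must be > 0")
  if (w_ij < 0) stop_invalid("w_ij must be nonnegative")
  raw <- e * (w_ij / w_total_into_j) / (2 * pi * dtw^2 * c_i)
  dp <- raw
  if (raw > 1) {
    warning(sprintf(
      "interareal peak probability %.3f > 1; capped to 1 for mask generation",
      raw))
    dp <- 1
  }
  structure(dp, raw = raw)
}

#' Full interareal profile estimation over a voxel connectome
#'
#' Convenience wrapper: fits the sphere once, then estimates per-region
#' areas and the width/strength of every directed region pair with any
#' nonzero weight.
#'
#' @param vc an `mvc_voxel_connectome`
#' @inheritParams estimate_interareal_width
#' @return list with `flatmap`, `areas` (named, mm^2), and `profiles`
#'   (data.frame: source, target, w_ij, dw_um)
#' @export
estimate_interareal_profiles <- function(vc, bandwidth = 1.0,
                                         threshold = 0.10) {
  sp <- fit_sphere(vc$positions)
  fm <- flatmap(sp$center, sp$radius, vc$voxel_size_um)
  regs <- unique(vc$labels)
  flat <- project_flat(vc$positions, fm)
  areas <- vapply(regs, function(r)
    estimate_area(flat[vc$labels == r, , drop = FALSE]), numeric(1))
  rows <- list()
  for (si in regs) for (ti in regs) {
    if (si == ti) next
    w <- sum(vc$weights[vc$labels == si, vc$labels == ti])
    if (w == 0) next
    dw <- estimate_interareal_width(vc, si, ti, fm, bandwidth, threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      source = si, target = ti, w_ij = w, dw_um = as.numeric(dw),
      stringsAsFactors = FALSE)
  }
  list(flatmap = fm, areas = areas, profiles = do.call(rbind, rows))
}
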