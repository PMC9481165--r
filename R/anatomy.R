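# Anatomy module: laminar censuses and interlaminar Gaussian statistics.
#
# The printed anatomical tables ship as a versioned YAML config
# (inst/extdata/anatomy.yaml) so that new censuses can be swapped in
# without touching code. The arithmetic here turns excitatory densities
# [neurons/mm^3] and (10 um)^3 voxel counts into per-region neuron counts,
# and cross-species connection statistics into mouse interlaminar Gaussian
# profile parameters (width d_w, peak probability d_p).

LAYERS <- c("L4", "L2/3", "L5")
AREAS  <- c("VISp", "VISal", "VISl", "VISpl", "VISrl", "VISli", "VISpor")
LATERAL_AREAS <- c("VISal", "VISl", "VISli", "VISpl", "VISrl")

#' Load the anatomy configuration
#'
#' Reads the structured anatomical parameter config (densities, voxel
#' counts, interlaminar widths and offset probabilities, surface areas,
#' model constants) and validates its invariants.
#'
#' @param path path to a YAML config; default is the published configuration
#'   shipped with the package.
#' @return a named list with class `mvc_anatomy_config`
#' @export
load_anatomy_config <- function(path = system.file("extdata", "anatomy.yaml",
                                                   package = "mvcnet")) {
  if (!file.exists(path)) stop_config("anatomy config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  required <- c("densities", "voxel_counts", "interlaminar_widths_cat",
                "interlaminar_d75", "dlgn_count", "width_scaling",
                "areas_mm2", "model")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop_config("anatomy config missing section(s): %s",
                paste(missing, collapse = ", "))
  for (a in names(cfg$densities))
    if (any(unlist(cfg$densities[[a]]) <= 0))
      stop_config("densities must be > 0 (area %s)", a)
  if (any(unlist(cfg$voxel_counts) <= 0))
    stop_config("voxel counts must be > 0")
  if (any(unlist(cfg$interlaminar_widths_cat) <= 0))
    stop_config("interlaminar widths must be > 0")
  cfg$path <- path
  class(cfg) <- c("mvc_anatomy_config", "list")
  cfg
}

#' Average excitatory density across areas
#'
#' Areas without their own density measurement are assigned the arithmetic
#' mean of the measured areas, per layer.
#'
#' @param densities numeric vector of per-area densities for one layer
#'   (neurons/mm^3), all positive
#' @return arithmetic mean density
#' @examples
#' average_density(c(106114.7, 93176.9, 86559.9, 106783.0)) # 98158.6
#' @export
average_density <- function(densities) {
  if (length(densities) == 0L || !is.numeric(densities))
    stop_invalid("`densities` must be a nonempty numeric vector")
  if (any(!is.finite(densities)) || any(densities <= 0))
    stop_invalid("densities must be finite and > 0")
  mean(densities)
}

#' Neuron count from density and voxel count
#'
#' Each (10 um)^3 voxel has volume 1e-6 mm^3; counts are rounded
#' half-to-nearest (validated against the printed census, e.g. 9704.6 ->
#' 9705, where flooring would fail).
#'
#' @param density excitatory density, neurons/mm^3 (>= 0)
#' @param voxels number of 10-um voxels (>= 0)
#' @return integer neuron count
#' @examples
#' neuron_count(106114.7, 1023640) # 108623
#' @export
neuron_count <- function(density, voxels) {
  assert_scalar_num(density, "density")
  assert_scalar_num(voxels, "voxels")
  if (density < 0 || voxels < 0)
    stop_invalid("density and voxels must be nonnegative")
  # round() half-to-even differs from half-up at exact .5, which never
  # occurs in the shipped tables; use floor(x + 0.5) to pin the convention.
  as.integer(floor(density * voxels * 1e-6 + 0.5))
}

#' Scale a cat-cortex interlaminar width to mouse
#'
#' Widths measured in cat V1 are scaled by the ratio of the mouse L4->L4
#' reference width to the cat L4->L4 width.
#'
#' @param cat_width Gaussian width in cat cortex (um)
#' @param mouse_ref mouse L4->L4 anchor width (um), default 114
#' @param cat_ref cat L4->L4 width (um), default 180
#' @return mouse-scaled width (um)
#' @examples
#' scale_interlaminar_width(220) # 139.33...
#' @export
scale_interlaminar_width <- function(cat_width, mouse_ref = 114,
                                     cat_ref = 180) {
  if (!is.numeric(cat_width) || any(!is.finite(cat_width)) ||
      any(cat_width <= 0))
    stop_invalid("cat_width must be finite and > 0")
  assert_scalar_num(mouse_ref, "mouse_ref")
  assert_scalar_num(cat_ref, "cat_ref")
  if (mouse_ref <= 0 || cat_ref <= 0)
    stop_invalid("reference widths must be > 0")
  cat_width * mouse_ref / cat_ref
}

#' Gaussian peak probability from the 75-um offset probability
#'
#' Inverts the radial Gaussian profile P(r) = d_p exp(-r^2 / (2 d_w^2)) at
#' the measured offset: d_p = d75 / exp(-offset^2 / (2 d_w^2)). The raw
#' value may exceed 1; capping to 1 happens at mask-generation time, not
#' here.
#'
#' @param d75 connection probability at the offset, in [0, 1]
#' @param dw Gaussian width (um), > 0
#' @param offset measurement offset (um), default 75
#' @return peak probability (possibly > 1)
#' @examples
#' peak_from_offset(0.243, 114) # ~0.302
#' @export
peak_from_offset <- function(d75, dw, offset = 75) {
  if (!is.numeric(d75) || any(!is.finite(d75)) || any(d75 < 0) || any(d75 > 1))
    stop_invalid("d75 must lie in [0, 1]")
  if (!is.numeric(dw) || any(!is.finite(dw)) || any(dw <= 0))
    stop_invalid("dw must be > 0")
  d75 / exp(-offset^2 / (2 * dw^2))
}

#' Per-region excitatory neuron census
#'
#' Recomputes the laminar census for every (area, layer) region from the
#' density and voxel-count tables, using the average-density rule for areas
#' without their own measurements, plus the dLGN count.
#'
#' @param config an `mvc_anatomy_config`
#' @return a data.frame with columns area, layer, density, voxels, n;
#'   attribute `dlgn` carries the dLGN count
#' @export
region_census <- function(config = load_anatomy_config()) {
  measured <- names(config$densities)
  avg <- vapply(LAYERS, function(l)
    average_density(vapply(measured, function(a)
      config$densities[[a]][[l]], numeric(1))), numeric(1))
  rows <- list()
  for (a in names(config$voxel_counts)) {
    for (l in LAYERS) {
      dens <- if (a %in% measured) config$densities[[a]][[l]] else avg[[l]]
      vox <- config$voxel_counts[[a]][[l]]
      rows[[length(rows) + 1L]] <- data.frame(
        area = a, layer = l, density = dens, voxels = vox,
        n = neuron_count(dens, vox), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "dlgn") <- as.integer(config$dlgn_count)
  class(out) <- c("mvc_census", "data.frame")
  out
}

#' Interlaminar Gaussian connection statistics
#'
#' Scales the cat-cortex width table to mouse and recovers the Gaussian
#' peak probability for every (source layer, target layer) pair from the
#' 75-um offset probabilities.
#'
#' @param config an `mvc_anatomy_config`
#' @return data.frame with columns source, target, cat_width, dw (mouse,
#'   um), d75, dp
#' @export
interlaminar_stats <- function(config = load_anatomy_config()) {
  ws <- config$width_scaling
  off <- if (is.null(config$d75_offset_um)) 75 else config$d75_offset_um
  rows <- list()
  for (src in LAYERS) {
    for (tgt in LAYERS) {
      cw <- config$interlaminar_widths_cat[[src]][[tgt]]
      dw <- scale_interlaminar_width(cw, ws$mouse_ref, ws$cat_ref)
      d75 <- config$interlaminar_d75[[src]][[tgt]]
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, target = tgt, cat_width = cw, dw = dw,
        d75 = d75, dp = peak_from_offset(d75, dw, off),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mvc_interlaminar", "data.frame")
  out
}
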