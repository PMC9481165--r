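# Synthetic data generators with known ground truth: spherical-shell toy
# voxel connectomes for the flat-map pipeline, trial-structured response
# tensors with controllable split-half reliability, and grating / 1-over-f
# image sets for the selectivity metrics. All generators are pure
# functions of (spec, seed).

#' Generate a toy voxel connectome on a spherical shell
#'
#' Each region occupies a disjoint angular patch on a sphere; voxels lie
#' on an angular grid with approximately `pitch_um` spacing. Connection
#' weight from source voxel l to target voxel k is
#' `peak * exp(-d_geo^2 / (2 sigma_true^2)) + background`, where d_geo is
#' the geodesic distance from l to target voxel k's corresponding point in
#' the source patch (same patch-relative offset). The geodesic ground
#' truth makes the flat-map small-angle approximation the thing under
#' test.
#'
#' @param regions named list of patches; each patch is
#'   `list(theta0, phi0)` -- the azimuth/elevation center of the patch in
#'   radians -- with an optional per-region `halfwidth` override (e.g. a
#'   source patch much larger than its targets, so that no Gaussian
#'   center sits near a patch edge)
#' @param patch_halfwidth default half-width of each (square) angular
#'   patch, radians
#' @param pitch_um approximate voxel spacing on the shell (um)
#' @param center,radius sphere parameters (um)
#' @param sigma_true Gaussian profile width (um)
#' @param peak,background weight profile parameters
#' @param seed RNG seed (used only for weight jitter, if `jitter > 0`)
#' @param jitter multiplicative weight noise sd (default 0)
#' @return an `mvc_voxel_connectome` with attribute `sigma_true`
#' @export
gen_voxel_connectome <- function(regions,
                                 patch_halfwidth = 0.08,
                                 pitch_um = 100,
                                 center = c(0, 0, 0), radius = 10000,
                                 sigma_true = 200,
                                 peak = 1, background = 0,
                                 seed = 1L, jitter = 0) {
  if (sigma_true <= 0) stop_invalid("sigma_true must be > 0")
  th <- vapply(regions, `[[`, numeric(1), "theta0")
  ph <- vapply(regions, `[[`, numeric(1), "phi0")
  hw <- vapply(regions, function(p) p$halfwidth %||% patch_halfwidth,
               numeric(1))
  if (length(regions) > 1) {
    for (i in seq_along(regions)) for (j in seq_along(regions)) {
      if (i >= j) next
      sep <- max(abs(th[i] - th[j]), abs(ph[i] - ph[j]))
      if (sep < hw[i] + hw[j])
        stop_invalid("overlapping angular patches: %s and %s",
                     names(regions)[i], names(regions)[j])
    }
  }
  dang <- pitch_um / radius                      # angular pitch
  pos <- NULL; lab <- character(0); rel <- NULL
  for (rn in names(regions)) {
    p <- regions[[rn]]
    gr <- seq(-(p$halfwidth %||% patch_halfwidth),
              p$halfwidth %||% patch_halfwidth, by = dang)
    g <- expand.grid(dth = gr, dph = gr)
    theta <- p$theta0 + g$dth; phi <- p$phi0 + g$dph
    xyz <- cbind(radius * cos(phi) * sin(theta),
                 radius * cos(phi) * cos(theta),
                 radius * sin(phi))
    pos <- rbind(pos, sweep(xyz, 2, center, "+"))
    lab <- c(lab, rep(rn, nrow(g)))
    rel <- rbind(rel, as.matrix(g))              # patch-relative offsets
  }
  n <- nrow(pos)
  w <- matrix(0, n, n)
  unit <- function(i) (pos[i, ] - center) / radius
  for (rn_s in names(regions)) for (rn_t in names(regions)) {
    if (rn_s == rn_t) next
    src <- which(lab == rn_s); tgt <- which(lab == rn_t)
    # mirror point of target voxel k inside the source patch: same
    # patch-relative angular offset
    ps <- regions[[rn_s]]
    for (k in tgt) {
      mth <- ps$theta0 + rel[k, 1]; mph <- ps$phi0 + rel[k, 2]
      mu <- c(cos(mph) * sin(mth), cos(mph) * cos(mth), sin(mph))
      u <- sweep(pos[src, , drop = FALSE], 2, center) / radius
      ca <- pmin(1, pmax(-1, as.numeric(u %*% mu)))
      dgeo <- radius * acos(ca)
      w[src, k] <- peak * exp(-dgeo^2 / (2 * sigma_true^2)) + background
    }
  }
  if (jitter > 0)
    w <- with_seed(seed, w * matrix(exp(stats::rnorm(n * n, 0, jitter)),
                                    n, n))
  vc <- voxel_connectome(pos, lab, w)
  attr(vc, "sigma_true") <- sigma_true
  vc
}

#' Generate a trial-structured response tensor
#'
#' `response[i, j, t] = s[i, j] + eps[i, j, t]` with per-(image, neuron)
#' signal of variance `sigma_s^2` (fixed across trials) and i.i.d. trial
#' noise of variance `sigma_n^2`. The implied split-half reliability (two
#' halves of t/2 trials each) is `sigma_s^2 / (sigma_s^2 + 2 sigma_n^2/t)`.
#' Optional rectification gives calcium-like nonnegative responses (note:
#' rectification changes the closed-form reliability).
#'
#' @param n_images,n_neurons,n_trials tensor dimensions
#' @param sigma_s signal standard deviation
#' @param sigma_n trial-noise standard deviation
#' @param rectify clamp responses at zero (default FALSE)
#' @param seed RNG seed
#' @return array images x neurons x trials, attribute
#'   `expected_reliability`
#' @export
gen_responses <- function(n_images = 118L, n_neurons = 50L, n_trials = 50L,
                          sigma_s = 1, sigma_n = 1, rectify = FALSE,
                          seed = 1L) {
  if (sigma_s < 0 || sigma_n < 0) stop_invalid("variances must be >= 0")
  resp <- with_seed(seed, {
    s <- matrix(stats::rnorm(n_images * n_neurons, 0, sigma_s),
                n_images, n_neurons)
    eps <- array(stats::rnorm(n_images * n_neurons * n_trials, 0, sigma_n),
                 c(n_images, n_neurons, n_trials))
    array(s, c(n_images, n_neurons, n_trials)) + eps
  })
  if (rectify) resp <- pmax(resp, 0)
  er <- if (sigma_s == 0 && sigma_n == 0) NA_real_ else
    sigma_s^2 / (sigma_s^2 + 2 * sigma_n^2 / n_trials)
  structure(resp, expected_reliability = er)
}

#' Generate sinusoidal grating stimuli
#'
#' @param directions grating directions in degrees (distinct mod 180 for
#'   orientation analyses)
#' @param sfs spatial frequencies, cycles per image
#' @param phases phases in radians
#' @param size image size in pixels (square)
#' @return list(images = array (n, 1, size, size), labels = data.frame
#'   with direction_deg, sf, phase)
#' @export
gen_gratings <- function(directions = c(0, 30, 60, 90, 120, 150),
                         sfs = 4, phases = 0, size = 64L) {
  grid <- expand.grid(direction = directions, sf = sfs, phase = phases)
  n <- nrow(grid)
  imgs <- array(0, c(n, 1, size, size))
  xy <- (seq_len(size) - 0.5) / size
  for (i in seq_len(n)) {
    th <- grid$direction[i] * pi / 180
    gx <- outer(xy * sin(th), xy * cos(th), `+`)   # row=y, col=x
    imgs[i, 1, , ] <- sin(2 * pi * grid$sf[i] * gx + grid$phase[i])
  }
  list(images = imgs,
       labels = data.frame(direction_deg = grid$direction, sf = grid$sf,
                           phase = grid$phase))
}

#' Generate natural-like (1/f spectrum) images
#'
#' Gaussian noise filtered to a 1/f amplitude spectrum, matching the
#' second-order statistics of natural scenes; grayscale replicated across
#' the requested channel count.
#'
#' @param n number of images (default 118, mirroring the natural-image
#'   protocol size)
#' @param size image size (pixels)
#' @param channels output channels
#' @param seed RNG seed
#' @return array (n, channels, size, size), standardized per image
#' @export
gen_natural_images <- function(n = 118L, size = 64L, channels = 3L,
                               seed = 1L) {
  f <- stats::fft
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  rad <- sqrt(outer(fr^2, fr^2, `+`))
  amp <- 1 / pmax(rad, 1 / size)
  with_seed(seed, {
    out <- array(0, c(n, channels, size, size))
    for (i in seq_len(n)) {
      z <- matrix(stats::rnorm(size * size), size, size)
      img <- Re(f(f(z) * amp, inverse = TRUE)) / size^2
      img <- (img - mean(img)) / stats::sd(img)
      for (ch in seq_len(channels)) out[i, ch, , ] <- img
    }
    out
  })
}
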