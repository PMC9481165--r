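# Shared fixtures: printed-table values frozen as test oracles, a
# brute-force convolution reference, and a toy two-region architecture
# for runtime tests.

# Printed per-region excitatory neuron counts (census table), row order
# area-major, layers L4, L2/3, L5.
printed_census <- data.frame(
  area = rep(c("VISp", "VISal", "VISl", "VISpl", "VISrl", "VISli",
               "VISpor"), each = 3),
  layer = rep(c("L4", "L2/3", "L5"), times = 7),
  n = c(108623, 173253, 134530,  9705, 15760, 15939,
        15501, 22299, 20826,     3912, 17924, 20041,
        14360, 22598, 19173,     5620,  9587, 11611,
        5952, 30576, 30230),
  stringsAsFactors = FALSE)

# Printed channel counts per region (meta-parameter table).
printed_channels <- c(
  dLGN = 5, VISp4 = 26, `VISp2/3` = 42, VISp5 = 32,
  VISal4 = 9, `VISal2/3` = 15, VISal5 = 15,
  VISl4 = 15, `VISl2/3` = 21, VISl5 = 20,
  VISpl4 = 3, `VISpl2/3` = 17, VISpl5 = 19,
  VISrl4 = 14, `VISrl2/3` = 22, VISrl5 = 18,
  VISli4 = 5, `VISli2/3` = 9, VISli5 = 11,
  VISpor4 = 5, `VISpor2/3` = 29, VISpor5 = 29)

# Printed interlaminar Gaussian peak probabilities, by source then target
# layer (order L2/3, L4, L5 within each).
printed_dp <- c(
  "L2/3>L2/3" = 0.184, "L2/3>L4" = 0.264, "L2/3>L5" = 0.167,
  "L4>L2/3" = 0.162, "L4>L4" = 0.302, "L4>L5" = 0.149,
  "L5>L2/3" = 0.029, "L5>L4" = 0.014, "L5>L5" = 0.136)

# Printed mouse-scaled interlaminar widths (um).
printed_dw <- c(
  "L2/3>L2/3" = 142.5, "L2/3>L4" = 31.67, "L2/3>L5" = 63.33,
  "L4>L2/3" = 139.33, "L4>L4" = 114, "L4>L5" = 88.67,
  "L5>L2/3" = 95, "L5>L4" = 63.33, "L5>L5" = 133)

# The two meta-parameter-table cells where the printed kernel size
# disagrees with the width formula applied to the printed areas.
kernel_discrepancies <- data.frame(
  source = c("VISli4", "VISpl4"), target = c("VISli2/3", "VISpl2/3"),
  printed = c(17L, 19L), formula = c(15L, 17L), stringsAsFactors = FALSE)

# Direct (sextuple-loop) convolution used as an independent oracle.
conv_reference <- function(x, w, s, p) {
  d <- dim(x); k <- dim(w)[3]; cout <- dim(w)[1]
  xp <- array(0, c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  xp[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  oh <- (d[3] + 2 * p - k) %/% s + 1; ow <- (d[4] + 2 * p - k) %/% s + 1
  out <- array(0, c(d[1], cout, oh, ow))
  for (n in seq_len(d[1])) for (co in seq_len(cout))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      acc <- 0
      for (ci in seq_len(d[2])) for (u in seq_len(k)) for (v in seq_len(k))
        acc <- acc + xp[n, ci, (i - 1) * s + u, (j - 1) * s + v] *
          w[co, ci, u, v]
      out[n, co, i, j] <- acc
    }
  out
}

# Toy architecture: input (2ch, 8x8) -> A4 -> A5, masked second edge,
# 2-class classifier. Small enough for finite-difference checks.
toy_architecture <- function(dp = 0.8, mask_seed = 42L) {
  regions <- data.frame(
    name = c("A4", "A5"), area = "A", layer = c("L4", "L5"),
    n = c(256, 256), grid = 8L, channels = c(4L, 4L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("input", "A4"), target = c("A4", "A5"),
    cin = c(2L, 4L), cout = c(4L, 4L), k = 3L, stride = 1L, padding = 1L,
    dtw = c(NA, 1.5), dp = c(NA, dp), masked = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  new_architecture(regions, edges, n_classes = 2L, input_size = 8L,
                   input_channels = 2L, mask_seed = mask_seed)
}

# Linearly separable two-class image set for the toy net.
separable_batch <- function(n = 32L, seed = 11L) {
  set.seed(seed)
  x <- array(stats::rnorm(n * 2 * 8 * 8), c(n, 2, 8, 8))
  y <- ifelse(stats::runif(n) > 0.5, 1L, 2L)
  for (i in seq_len(n))
    x[i, 1, , ] <- x[i, 1, , ] + ifelse(y[i] == 1L, 2, -2)
  list(x = x, y = y)
}

# Shared published-configuration objects (built once per test run).
published_config <- load_anatomy_config()
published_arch <- build_graph(published_config, kernels = "formula")
published_arch_verbatim <- build_graph(published_config,
                                       kernels = "published")
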