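# Functional-comparison metrics: representational similarity (similarity
# of similarity matrices), split-half reliability and noise ceilings,
# lifetime sparseness, circular selectivity, Jensen-Shannon distance, and
# the MDS layout / diversity index for layer representations.

#' Image-by-image similarity matrix
#'
#' Pearson correlation between every pair of rows of a representation
#' matrix (images x units). Rows with zero variance cannot be correlated:
#' their entries are set to NA and their count is reported via the
#' `n_excluded` attribute.
#'
#' @param R representation matrix, images x units (>= 2 images)
#' @return n x n symmetric correlation matrix, diagonal 1
#' @export
similarity_matrix <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) < 2L) stop_invalid("need at least 2 images")
  v <- apply(R, 1, stats::var)
  const <- v == 0 | !is.finite(v)
  S <- suppressWarnings(stats::cor(t(R)))
  S[const, ] <- NA_real_; S[, const] <- NA_real_
  diag(S) <- 1
  structure(S, n_excluded = sum(const))
}

flatten_upper <- function(S) S[upper.tri(S, diag = FALSE)]

#' Similarity of similarity matrices (SSM)
#'
#' Spearman rank correlation between the flattened upper triangles
#' (diagonal excluded) of two similarity matrices. Rank-based, hence
#' invariant to strictly monotone transforms of either matrix.
#'
#' @param A,B n x n similarity matrices of the same size
#' @return correlation in [-1, 1]
#' @export
ssm <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    stop_invalid("similarity matrices must have equal size")
  a <- flatten_upper(A); b <- flatten_upper(B)
  ok <- is.finite(a) & is.finite(b)
  stats::cor(a[ok], b[ok], method = "spearman")
}

split_half_indices <- function(t, n_splits, seed) {
  half <- t %/% 2
  with_seed(seed, lapply(seq_len(n_splits), function(i) {
    s <- sample.int(t, half)
    list(a = s, b = setdiff(seq_len(t), s)[seq_len(half)])
  }))
}

#' Split-half reliability per neuron
#'
#' For each neuron, trials are split into two disjoint halves; the
#' across-image Pearson correlation between the two half-averaged
#' responses is computed, and the mean over `n_splits` random splits is
#' the neuron's reliability. Neurons constant across images in any half
#' get NA (recorded missing, not propagated).
#'
#' @param resp array images x neurons x trials
#' @param n_splits number of random splits (default 10)
#' @param seed RNG seed for the splits
#' @return numeric vector of per-neuron reliabilities (NA = undefined),
#'   with attribute `n_excluded`
#' @export
split_half_reliability <- function(resp, n_splits = 10L, seed = 1L) {
  d <- dim(resp)
  if (length(d) != 3L) stop_invalid("resp must be images x neurons x trials")
  if (d[3] < 2L) stop_invalid("need at least 2 trials")
  splits <- split_half_indices(d[3], n_splits, seed)
  acc <- matrix(0, d[2], n_splits)
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    ma <- apply(resp[, , sp$a, drop = FALSE], c(1, 2), mean)
    mb <- apply(resp[, , sp$b, drop = FALSE], c(1, 2), mean)
    for (j in seq_len(d[2])) {
      if (stats::sd(ma[, j]) == 0 || stats::sd(mb[, j]) == 0)
        acc[j, si] <- NA_real_
      else acc[j, si] <- stats::cor(ma[, j], mb[, j])
    }
  }
  rel <- rowMeans(acc)
  structure(rel, n_excluded = sum(!is.finite(rel)))
}

#' SSM noise ceiling of a trial-structured population
#'
#' Trials are split into two disjoint halves; each half yields a
#' trial-averaged representation matrix over the neurons whose split-half
#' reliability passes `threshold`; the SSM between the two matrices is one
#' ceiling estimate. Mean and sd over `n_splits` splits are returned.
#'
#' @param resp array images x neurons x trials
#' @param threshold reliability threshold for neuron inclusion
#'   (-Inf keeps all neurons)
#' @param n_splits number of splits
#' @param seed RNG seed
#' @param reliability optional precomputed [split_half_reliability()]
#' @return list(mean, sd, n_neurons)
#' @export
noise_ceiling <- function(resp, threshold = -Inf, n_splits = 10L, seed = 1L,
                          reliability = NULL) {
  d <- dim(resp)
  if (is.null(reliability))
    reliability <- split_half_reliability(resp, n_splits, seed)
  keep <- which(is.finite(reliability) & reliability >= threshold)
  if (length(keep) < 2L)
    stop_estimation("fewer than 2 neurons pass reliability threshold %g",
                    threshold)
  sub <- resp[, keep, , drop = FALSE]
  splits <- split_half_indices(d[3], n_splits, derive_seed(seed, "ceiling"))
  vals <- vapply(splits, function(sp) {
    ma <- apply(sub[, , sp$a, drop = FALSE], c(1, 2), mean)
    mb <- apply(sub[, , sp$b, drop = FALSE], c(1, 2), mean)
    ssm(similarity_matrix(ma), similarity_matrix(mb))
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), n_neurons = length(keep))
}

#' Best noise ceiling over a threshold grid
#'
#' Evaluates [noise_ceiling()] at each threshold and returns the argmax of
#' the ceiling mean; ties break toward the lower threshold (more neurons).
#'
#' @param resp array images x neurons x trials
#' @param thresholds numeric grid of reliability thresholds
#' @param n_splits,seed passed to [noise_ceiling()]
#' @return list(threshold, ceiling, sd, n_neurons, table)
#' @export
best_noise_ceiling <- function(resp, thresholds, n_splits = 10L, seed = 1L) {
  if (!length(thresholds)) stop_invalid("threshold grid is empty")
  thresholds <- sort(thresholds)
  rel <- split_half_reliability(resp, n_splits, seed)
  rows <- lapply(thresholds, function(th) {
    nc <- tryCatch(noise_ceiling(resp, th, n_splits, seed, reliability = rel),
                   mvcnet_estimation_failure = function(e) NULL)
    if (is.null(nc)) return(NULL)
    data.frame(threshold = th, ceiling = nc$mean, sd = nc$sd,
               n_neurons = nc$n_neurons)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    stop_estimation("no threshold in the grid leaves >= 2 neurons")
  best <- tab[which.max(tab$ceiling), ]  # which.max takes first = lowest th
  list(threshold = best$threshold, ceiling = best$ceiling, sd = best$sd,
       n_neurons = best$n_neurons, table = tab)
}

#' Lifetime sparseness
#'
#' `S_L = (1 - (sum r)^2 / (N sum r^2)) / (1 - 1/N)`: 1 for a unit
#' responding to a single condition, 0 for a uniform response profile.
#'
#' @param r per-condition mean responses (length N >= 2)
#' @param N number of conditions (default `length(r)`)
#' @return S_L in [0, 1], or NA for an all-zero profile (recorded missing)
#' @export
lifetime_sparseness <- function(r, N = length(r)) {
  if (!is.numeric(r) || length(r) < 2L)
    stop_invalid("need responses for at least 2 conditions")
  if (all(r == 0)) return(NA_real_)
  (1 - sum(r)^2 / (N * sum(r^2))) / (1 - 1 / N)
}

#' Circular selectivity index
#'
#' Magnitude of the doubled-angle resultant (one minus circular
#' variance): `S_O = |sum_k r_k exp(2 i theta_k)| / sum_k r_k`. The angle
#' doubling identifies directions 180 degrees apart, making this an
#' orientation (not direction) selectivity measure.
#'
#' @param r per-direction mean responses (nonnegative)
#' @param theta direction angles in radians
#' @return S_O in [0, 1], or NA when responses sum to zero
#' @export
circular_selectivity <- function(r, theta) {
  if (length(r) != length(theta)) stop_invalid("r and theta lengths differ")
  if (any(r < 0)) stop_invalid("responses must be nonnegative")
  s <- sum(r)
  if (s == 0) return(NA_real_)
  Mod(sum(r * exp(2i * theta))) / s
}

#' Jensen-Shannon distance between two samples
#'
#' Histograms on a shared equal-width binning spanning the pooled sample
#' range; JS divergence with base-2 logs; distance is its square root
#' (in [0, 1], with 1 for disjoint supports).
#'
#' @param x,y numeric samples (nonempty)
#' @param bins number of equal-width bins (default 50)
#' @param breaks optional explicit break points (overrides `bins`)
#' @return distance in [0, 1]
#' @export
js_distance <- function(x, y, bins = 50L, breaks = NULL) {
  if (!length(x) || !length(y)) stop_invalid("samples must be nonempty")
  if (is.null(breaks)) {
    rng <- range(c(x, y))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  }
  p <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  q <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}

#' MDS layout and diversity index of layer representations
#'
#' Classical metric multidimensional scaling on distance 1 - SSM between
#' layers, followed by the diversity index: the product of the singular
#' values of the centered 2D coordinate set (equivalently, the product of
#' the principal-component standard deviations times sqrt(n-1) each).
#' Identical layers collapse to a point (diversity 0); collinear layouts
#' also give ~0.
#'
#' @param ssm_mat symmetric matrix of pairwise SSM values, diagonal 1
#' @param k embedding dimension (default 2)
#' @return list(coords, diversity)
#' @export
mds_layout_and_diversity <- function(ssm_mat, k = 2L) {
  ssm_mat <- as.matrix(ssm_mat)
  n <- nrow(ssm_mat)
  if (n < 3L) stop_estimation("need at least 3 layers for an MDS layout")
  if (!isTRUE(all.equal(ssm_mat, t(ssm_mat), tolerance = 1e-8)))
    stop_invalid("SSM matrix must be symmetric")
  D <- 1 - ssm_mat
  diag(D) <- 0
  D[D < 0] <- 0
  # degenerate configurations legitimately have < k positive eigenvalues
  co <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k))
  if (is.null(dim(co)) || ncol(co) < k) {
    # degenerate configurations (all-equal layers): embed at the origin
    co2 <- matrix(0, n, k)
    if (!is.null(dim(co)) && ncol(co) >= 1) co2[, seq_len(ncol(co))] <- co
    co <- co2
  }
  cc <- scale(co, center = TRUE, scale = FALSE)
  sv <- svd(cc)$d[seq_len(k)]
  list(coords = co, diversity = prod(sv))
}
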