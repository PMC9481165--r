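# Network runtime: executes an architecture graph as a convolutional
# network. Activations are base-R 4D arrays (batch, channel, height,
# width). Convolution is im2col + matrix multiply, with a hand-written
# backward pass; each region applies one batch-normalization and ReLU to
# the sum of its inbound convolution outputs. Masked weights are kept
# exactly zero through training by re-applying the binary mask after every
# optimizer step.

pad4 <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  xp[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  xp
}

# im2col: (N, C, Hp, Wp) -> matrix (N*oh*ow, C*k*k); column block for
# kernel offset (u, v) holds the C input channels. Implemented as one
# vectorized gather over precomputed linear indices.
im2col <- function(xp, k, stride, oh, ow) {
  d <- dim(xp); N <- d[1]; C <- d[2]; Hp <- d[3]
  # rows enumerate (n, oh_i, ow_j), n fastest; linear index of xp element
  # (n, c, h, w) is n + N(c-1) + NC(h-1) + NC*Hp(w-1)
  base_h <- rep(rep((seq_len(oh) - 1L) * stride, each = N), times = ow)
  base_w <- rep((seq_len(ow) - 1L) * stride, each = N * oh)
  rowpart <- seq_len(N) + (N * C) * base_h + (N * C * Hp) * base_w
  # cols enumerate (c, v, u), c fastest
  colpart <- as.vector(outer(
    N * (seq_len(C) - 1L),
    as.vector(outer(N * C * Hp * (seq_len(k) - 1L),
                    N * C * (seq_len(k) - 1L), `+`)), `+`))
  idx <- outer(rowpart, colpart, `+`)
  X2 <- xp[idx]
  dim(X2) <- dim(idx)
  X2
}

w_to_mat <- function(w) {
  # (cout, cin, ku, kv) -> (cin*k*k, cout) matching im2col column order
  d <- dim(w)
  m <- aperm(w, c(2, 4, 3, 1))
  dim(m) <- c(d[2] * d[3] * d[4], d[1])
  m
}

mat_to_w <- function(m, cout, cin, k) {
  dim(m) <- c(cin, k, k, cout)
  aperm(m, c(4, 1, 3, 2))
}

conv_out_size <- function(l, k, stride, p) (l + 2 * p - k) %/% stride + 1L

conv_forward <- function(x, w, stride, p, keep_cache = FALSE) {
  d <- dim(x); k <- dim(w)[3]; cout <- dim(w)[1]
  if (dim(w)[2] != d[2])
    stop_invalid("conv input has %d channels, kernel expects %d",
                 d[2], dim(w)[2])
  oh <- conv_out_size(d[3], k, stride, p)
  ow <- conv_out_size(d[4], k, stride, p)
  xp <- pad4(x, p)
  if (keep_cache) {
    # im2col route: the column matrix is reused by the backward pass
    X2 <- im2col(xp, k, stride, oh, ow)
    out2 <- X2 %*% w_to_mat(w)
  } else {
    # shift-and-accumulate: k^2 small matrix products, no giant buffer
    xpp <- aperm(xp, c(1, 3, 4, 2))             # (N, Hp, Wp, C)
    wm <- aperm(w, c(2, 1, 3, 4))               # (C, cout, ku, kv)
    out2 <- matrix(0, d[1] * oh * ow, cout)
    for (u in seq_len(k)) {
      i <- u + (seq_len(oh) - 1L) * stride
      for (v in seq_len(k)) {
        j <- v + (seq_len(ow) - 1L) * stride
        blk <- xpp[, i, j, , drop = FALSE]
        dim(blk) <- c(d[1] * oh * ow, d[2])
        wuv <- wm[, , u, v, drop = FALSE]
        dim(wuv) <- c(d[2], cout)
        out2 <- out2 + blk %*% wuv
      }
    }
  }
  out <- array(out2, c(d[1], oh, ow, cout))
  out <- aperm(out, c(1, 4, 2, 3))
  if (keep_cache)
    attr(out, "cache") <- list(X2 = X2, xdim = d, k = k, stride = stride,
                               p = p, oh = oh, ow = ow)
  out
}

conv_backward <- function(dout, w, cache) {
  d <- cache$xdim; k <- cache$k; s <- cache$stride; p <- cache$p
  oh <- cache$oh; ow <- cache$ow
  N <- d[1]; C <- d[2]; cout <- dim(w)[1]
  dout2 <- matrix(aperm(dout, c(1, 3, 4, 2)), N * oh * ow, cout)
  dW <- mat_to_w(crossprod(cache$X2, dout2), cout, C, k)
  dX2 <- tcrossprod(dout2, w_to_mat(w))
  dxp <- array(0, c(N, C, d[3] + 2 * p, d[4] + 2 * p))
  for (u in seq_len(k)) {
    i <- u + (seq_len(oh) - 1L) * s
    for (v in seq_len(k)) {
      j <- v + (seq_len(ow) - 1L) * s
      cols <- ((u - 1L) * k + (v - 1L)) * C + seq_len(C)
      blk <- array(dX2[, cols], c(N, oh, ow, C))
      dxp[, , i, j] <- dxp[, , i, j] + aperm(blk, c(1, 4, 2, 3))
    }
  }
  dx <- if (p > 0) dxp[, , p + seq_len(d[3]), p + seq_len(d[4]), drop = FALSE]
        else dxp
  list(dx = dx, dW = dW)
}

bn_stats_axes <- function(x) {
  # per-channel mean/var over (batch, height, width)
  d <- dim(x)
  xm <- aperm(x, c(1, 3, 4, 2)); dim(xm) <- c(d[1] * d[3] * d[4], d[2])
  xm
}

bn_forward <- function(x, bn, train, eps = 1e-5) {
  d <- dim(x)
  xm <- bn_stats_axes(x)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- bn$running_mean; v <- bn$running_var
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(v + eps), "/")
  ym <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  y <- array(ym, c(d[1], d[3], d[4], d[2]))
  y <- aperm(y, c(1, 4, 2, 3))
  list(y = y, cache = list(xhat = xhat, mu = mu, v = v, eps = eps, d = d),
       mu = mu, v = v)
}

bn_backward <- function(dy, bn, cache) {
  d <- cache$d
  dym <- bn_stats_axes(dy)
  xhat <- cache$xhat
  m <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  t1 <- sweep(dym, 2, colMeans(dym))
  t2 <- sweep(xhat, 2, colMeans(dym * xhat), "*")
  dxm <- sweep(t1 - t2, 2, bn$gamma / sqrt(cache$v + cache$eps), "*")
  dx <- array(dxm, c(d[1], d[3], d[4], d[2]))
  list(dx = aperm(dx, c(1, 4, 2, 3)), dgamma = dgamma, dbeta = dbeta)
}

avgpool_forward <- function(x, out_size) {
  d <- dim(x); f <- d[3] %/% out_size
  y <- array(0, c(d[1], d[2], out_size, out_size))
  for (a in seq_len(out_size)) for (b in seq_len(out_size)) {
    blk <- x[, , (a - 1) * f + seq_len(f), (b - 1) * f + seq_len(f),
             drop = FALSE]
    dim(blk) <- c(d[1] * d[2], f * f)
    y[, , a, b] <- array(rowMeans(blk), c(d[1], d[2]))
  }
  y
}

avgpool_backward <- function(dy, in_size) {
  d <- dim(dy); f <- in_size %/% d[3]
  dx <- array(0, c(d[1], d[2], in_size, in_size))
  for (a in seq_len(d[3])) for (b in seq_len(d[4])) {
    g <- dy[, , a, b] / f^2
    dx[, , (a - 1) * f + seq_len(f), (b - 1) * f + seq_len(f)] <-
      array(rep(g, f * f), c(d[1], d[2], f, f))
  }
  dx
}

topo_order <- function(arch) {
  nodes <- c("input", arch$regions$name)
  deps <- lapply(nodes, function(n) arch$edges$source[arch$edges$target == n])
  names(deps) <- nodes
  order <- character(0); placed <- character(0)
  while (length(placed) < length(nodes)) {
    ready <- nodes[!nodes %in% placed &
                     vapply(nodes, function(n)
                       all(deps[[n]] %in% placed), logical(1))]
    if (!length(ready)) stop_config("architecture graph has a cycle")
    order <- c(order, ready); placed <- c(placed, ready)
  }
  setdiff(order, "input")
}

#' Initialize a network from an architecture
#'
#' Kernel weights get variance-scaled (He) initialization on the dense
#' kernel, then are multiplied by the sampled binary Gaussian mask (edges
#' without a mask profile stay dense). Convolutions carry no additive
#' bias: every region is immediately batch-normalized.
#'
#' @param arch an `mvc_arch`
#' @param seed integer seed for weight initialization (mask seeds are the
#'   ones recorded in the architecture manifest)
#' @return object of class `mvc_net`
#' @export
net_init <- function(arch, seed = 1L) {
  edges <- arch$edges
  conv <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    cin <- edges$cin[i]; cout <- edges$cout[i]; k <- edges$k[i]
    w <- with_seed(derive_seed(seed, paste0("w/", edges$source[i], ">",
                                            edges$target[i])), {
      array(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
            c(cout, cin, k, k))
    })
    mask <- if (isTRUE(edges$masked[i])) {
      g <- mask_probability_grid(k, edges$dp[i], edges$dtw[i])
      sample_mask(g, cout, cin, edges$mask_seed[i])
    } else array(1, c(cout, cin, k, k))
    conv[[i]] <- list(w = w * mask, mask = mask)
  }
  names(conv) <- paste0(edges$source, ">", edges$target)
  bn <- lapply(arch$regions$channels, function(ch)
    list(gamma = rep(1, ch), beta = rep(0, ch),
         running_mean = rep(0, ch), running_var = rep(1, ch)))
  names(bn) <- arch$regions$name
  cl <- arch$classifier
  Wc <- with_seed(derive_seed(seed, "classifier"), {
    matrix(stats::rnorm(cl$feature_width * cl$n_classes,
                        sd = sqrt(1 / cl$feature_width)),
           cl$feature_width, cl$n_classes)
  })
  structure(list(arch = arch, conv = conv, bn = bn,
                 Wc = Wc, bc = rep(0, cl$n_classes),
                 order = topo_order(arch), seed = seed),
            class = "mvc_net")
}

#' Forward pass for one region
#'
#' Sums the convolution outputs of all inbound edges, then applies the
#' region's batch normalization and ReLU.
#'
#' @param inbound named list of source activations (batch, c, h, w)
#' @param edge_states list (parallel to `inbound`) of
#'   `list(w, stride, padding)` conv states
#' @param bn batch-norm parameter list (gamma, beta, running_mean,
#'   running_var); NULL disables normalization
#' @param train logical; use batch statistics (TRUE) or running (FALSE)
#' @return activation array after ReLU
#' @export
region_forward <- function(inbound, edge_states, bn = NULL, train = FALSE) {
  stopifnot(length(inbound) == length(edge_states))
  s <- NULL
  for (i in seq_along(inbound)) {
    es <- edge_states[[i]]
    o <- conv_forward(inbound[[i]], es$w, es$stride, es$padding)
    if (is.null(s)) s <- o
    else {
      if (!all(dim(s) == dim(o)))
        stop_config("wiring error on inbound edge %s: got %s, expected %s",
                    names(inbound)[i] %||% i,
                    paste(dim(o), collapse = "x"),
                    paste(dim(s), collapse = "x"))
      s <- s + o
    }
  }
  if (!is.null(bn)) s <- bn_forward(s, bn, train)$y
  s * (s > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full forward pass. Returns activations per region, logits, and (when
# train = TRUE or keep_cache) the caches needed for backprop.
net_forward_impl <- function(net, x, train = FALSE, upto = NULL,
                             keep_cache = FALSE) {
  arch <- net$arch
  d <- dim(x)
  if (length(d) != 4L || d[2] != arch$meta$input_channels ||
      d[3] != arch$meta$input_size || d[4] != arch$meta$input_size)
    stop_invalid("input must be batch x %d x %d x %d",
                 arch$meta$input_channels, arch$meta$input_size,
                 arch$meta$input_size)
  order <- net$order
  if (!is.null(upto)) {
    if (!upto %in% arch$regions$name) stop_invalid("unknown region: %s", upto)
    keep <- upto
    repeat {
      parents <- unique(arch$edges$source[arch$edges$target %in% keep])
      new <- setdiff(setdiff(parents, "input"), keep)
      if (!length(new)) break
      keep <- c(keep, new)
    }
    order <- order[order %in% keep]
  }
  act <- list(input = x)
  caches <- list()
  for (r in order) {
    eidx <- which(arch$edges$target == r)
    s <- NULL; ec <- list()
    for (i in eidx) {
      e <- arch$edges[i, ]
      o <- conv_forward(act[[e$source]], net$conv[[i]]$w, e$stride,
                        e$padding, keep_cache = keep_cache || train)
      ec[[as.character(i)]] <- attr(o, "cache")
      attr(o, "cache") <- NULL
      if (is.null(s)) s <- o
      else if (!all(dim(s) == dim(o)))
        stop_config("wiring error on edge %s -> %s", e$source, e$target)
      else s <- s + o
    }
    bnr <- bn_forward(s, net$bn[[r]], train)
    a <- bnr$y
    act[[r]] <- a * (a > 0)
    if (keep_cache || train)
      caches[[r]] <- list(conv = ec, bn = bnr$cache, pre = s,
                          post_bn = bnr$y, mu = bnr$mu, v = bnr$v)
  }
  out <- list(act = act, caches = caches)
  if (is.null(upto)) {
    l5 <- arch$regions$name[arch$regions$layer == "L5"]
    pooled <- list(); feats <- list()
    for (r in l5) {
      pr <- avgpool_forward(act[[r]], arch$classifier$pool)
      pooled[[r]] <- pr
      feats[[r]] <- matrix(pr, d[1], length(pr) / d[1])
    }
    z <- do.call(cbind, feats)
    out$features <- z
    out$logits <- sweep(z %*% net$Wc, 2, net$bc, "+")
    out$pooled_dims <- lapply(pooled, dim)
  }
  out
}

#' Run the network forward
#'
#' @param net an `mvc_net`
#' @param x input batch, array (batch, channels, size, size); the input
#'   is expected already resized to the architecture's input size
#' @param train logical: batch-norm uses batch statistics and caches are
#'   kept
#' @param upto optional region name: compute only that region's ancestors
#'   and stop (no classifier head)
#' @return list with `act` (named activations per region) and, for full
#'   passes, `logits`
#' @export
net_forward <- function(net, x, train = FALSE, upto = NULL) {
  out <- net_forward_impl(net, x, train = train, upto = upto)
  out[c("act", "logits")]
}

#' Calibrate batch-norm running statistics
#'
#' One pass over a probe batch; running statistics are set to the batch
#' statistics, so an untrained network can be analyzed in deterministic
#' eval mode.
#'
#' @param net an `mvc_net`
#' @param x probe batch
#' @return updated `mvc_net`
#' @export
net_calibrate <- function(net, x) {
  out <- net_forward_impl(net, x, train = TRUE)
  for (r in names(out$caches)) {
    net$bn[[r]]$running_mean <- out$caches[[r]]$mu
    net$bn[[r]]$running_var <- out$caches[[r]]$v
  }
  net
}

softmax_xent <- function(logits, labels) {
  # labels: integer in 1..n_classes
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), labels)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), labels)] <-
    dlogits[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dlogits = dlogits / n, p = p)
}

#' One training step (SGD with momentum)
#'
#' Forward in train mode, cross-entropy loss on the classifier logits,
#' full backward pass, momentum-SGD update, then re-application of every
#' binary mask so masked weights remain exactly zero.
#'
#' @param net an `mvc_net`
#' @param x input batch
#' @param y integer labels in 1..n_classes
#' @param lr learning rate
#' @param momentum momentum coefficient
#' @param state optimizer velocity state from the previous step (or NULL)
#' @return list(net, loss, state, logits)
#' @export
train_step <- function(net, x, y, lr = 0.01, momentum = 0.9, state = NULL) {
  arch <- net$arch
  fw <- net_forward_impl(net, x, train = TRUE, keep_cache = TRUE)
  sx <- softmax_xent(fw$logits, y)
  if (!is.finite(sx$loss))
    stop(errorCondition("non-finite training loss",
                        class = c("mvcnet_training_failure", "error")))
  grads <- list(conv = vector("list", nrow(arch$edges)),
                bn = list(), Wc = NULL, bc = NULL)

  # classifier backward
  grads$Wc <- crossprod(fw$features, sx$dlogits)
  grads$bc <- colSums(sx$dlogits)
  dz <- tcrossprod(sx$dlogits, net$Wc)
  # split features back into per-area L5 gradients, un-pool
  l5 <- arch$regions$name[arch$regions$layer == "L5"]
  dact <- list()  # accumulated gradient w.r.t. each region's activation
  off <- 0L
  for (r in l5) {
    pd <- fw$pooled_dims[[r]]
    wlen <- pd[2] * pd[3] * pd[4]
    dpool <- array(dz[, off + seq_len(wlen)], pd)
    off <- off + wlen
    g <- arch$regions$grid[arch$regions$name == r]
    dact[[r]] <- avgpool_backward(dpool, g)
  }

  # walk regions in reverse topological order
  for (r in rev(net$order)) {
    if (is.null(dact[[r]])) next
    cache <- fw$caches[[r]]
    drelu <- dact[[r]] * (cache$post_bn > 0)
    bb <- bn_backward(drelu, net$bn[[r]], cache$bn)
    grads$bn[[r]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
    for (ei in names(cache$conv)) {
      i <- as.integer(ei)
      e <- arch$edges[i, ]
      cb <- conv_backward(bb$dx, net$conv[[i]]$w, cache$conv[[ei]])
      grads$conv[[i]] <- cb$dW
      if (e$source != "input") {
        dact[[e$source]] <- if (is.null(dact[[e$source]])) cb$dx
                            else dact[[e$source]] + cb$dx
      }
    }
  }

  # momentum SGD; masked weights re-zeroed after the step
  if (is.null(state))
    state <- list(conv = vector("list", nrow(arch$edges)),
                  bn = list(), Wc = 0, bc = 0)
  for (i in seq_len(nrow(arch$edges))) {
    if (is.null(grads$conv[[i]])) next
    v <- state$conv[[i]] %||% 0
    v <- momentum * v - lr * grads$conv[[i]]
    state$conv[[i]] <- v
    net$conv[[i]]$w <- (net$conv[[i]]$w + v) * net$conv[[i]]$mask
  }
  for (r in names(grads$bn)) {
    vb <- state$bn[[r]] %||% list(g = 0, b = 0)
    vb$g <- momentum * vb$g - lr * grads$bn[[r]]$dgamma
    vb$b <- momentum * vb$b - lr * grads$bn[[r]]$dbeta
    state$bn[[r]] <- vb
    net$bn[[r]]$gamma <- net$bn[[r]]$gamma + vb$g
    net$bn[[r]]$beta <- net$bn[[r]]$beta + vb$b
    # running statistics track the train-mode batches
    cache <- fw$caches[[r]]
    net$bn[[r]]$running_mean <- 0.9 * net$bn[[r]]$running_mean + 0.1 * cache$mu
    net$bn[[r]]$running_var <- 0.9 * net$bn[[r]]$running_var + 0.1 * cache$v
  }
  state$Wc <- momentum * state$Wc - lr * grads$Wc
  net$Wc <- net$Wc + state$Wc
  state$bc <- momentum * state$bc - lr * grads$bc
  net$bc <- net$bc + state$bc

  list(net = net, loss = sx$loss, state = state, logits = fw$logits)
}

#' Flattened layer activations for a set of images
#'
#' Runs the network in eval mode up to the requested region only (its
#' ancestors are computed, nothing else) and returns one row per image,
#' channels x height x width flattened.
#'
#' @param net an `mvc_net`
#' @param images array (n, channels, size, size)
#' @param region region name
#' @param batch_size images per forward pass
#' @return matrix n_images x (c*h*w)
#' @export
extract_layer_activations <- function(net, images, region,
                                      batch_size = 16L) {
  if (!region %in% net$arch$regions$name)
    stop_invalid("unknown region: %s", region)
  n <- dim(images)[1]
  rows <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- net_forward_impl(net, images[idx, , , , drop = FALSE],
                            train = FALSE, upto = region)
    a <- out$act[[region]]
    m <- matrix(a, length(idx), length(a) / length(idx))
    rows <- rbind(rows, m)
  }
  rows
}
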