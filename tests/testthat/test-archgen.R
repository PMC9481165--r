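test_that("channel_count floors the neurons-per-position ratio", {
  expect_identical(channel_count(108623, 64, 64), 26L)
  expect_identical(channel_count(30576, 32, 32), 29L)  # 29.86 floors, not rounds
  expect_identical(channel_count(4096, 64, 64), 1L)
  expect_error(channel_count(100, 0, 64), class = "mvcnet_invalid_input")
})

test_that("pixel_scale converts mm^2 areas to pixels per um", {
  expect_equal(pixel_scale(64, 64, 4.3271), sqrt(4096 / 4327100),
               tolerance = 1e-12)
  expect_lt(abs(pixel_scale(64, 64, 4.3271) - 0.03077), 1e-4)
  expect_lt(abs(pixel_scale(32, 32, 0.5264) - 0.04411), 1e-4)
  expect_equal(pixel_scale(1, 1, 1e-6), 1)  # area of 1 um^2
  expect_error(pixel_scale(64, 64, 0), class = "mvcnet_invalid_input")
})

test_that("kernel_and_padding reproduces printed interlaminar kernels", {
  s_vp4 <- pixel_scale(64, 64, 4.3271)
  expect_identical(kernel_and_padding(139.33, s_vp4, 1L)$k, 9L)
  s_vp23 <- pixel_scale(64, 64, 4.7406)
  expect_identical(kernel_and_padding(63.33, s_vp23, 1L)$k, 3L)
  # sub-pixel width: 1x1 kernel, no padding at stride 1
  kp <- kernel_and_padding(0.5, 1, 1L)
  expect_identical(c(kp$k, kp$p), c(1L, 0L))
  # stride-2 padding rounds up so output = input/2 exactly
  s_vp4_32 <- pixel_scale(64, 64, 4.3271)
  kp2 <- kernel_and_padding(250, s_vp4_32, 2L)
  expect_identical(kp2$p, as.integer(ceiling((kp2$k - 2) / 2)))
  expect_error(kernel_and_padding(10, 0.1, 3L),
               class = "mvcnet_invalid_input")
})

test_that("mask_probability_grid is radial, capped, and center-peaked", {
  g <- mask_probability_grid(9, 0.302, 4.287)
  expect_identical(dim(g), c(9L, 9L))
  expect_equal(g[5, 5], 0.302)
  # one Gaussian width from center: dp * exp(-1/2)
  gd <- mask_probability_grid(11, 0.5, 3)
  expect_equal(gd[6, 9], 0.5 * exp(-0.5))  # offset (0, 3) = dtw
  expect_equal(gd, t(gd))                  # radial symmetry
  expect_equal(gd, gd[11:1, 11:1])
  gcap <- mask_probability_grid(5, 1.6, 2)
  expect_identical(max(gcap), 1)           # peak > 1 capped
  expect_equal(gcap[1, 1], 1.6 * exp(-1))  # tails uncapped: r2 = 8 = 2 dtw^2
  expect_error(mask_probability_grid(4, 0.5, 1),
               class = "mvcnet_invalid_input")
})

test_that("sample_mask: extremes, reproducibility, binomial concentration", {
  z <- sample_mask(matrix(0, 3, 3), 4, 5, seed = 1)
  expect_identical(sum(z), 0)
  o <- sample_mask(matrix(1, 3, 3), 4, 5, seed = 1)
  expect_identical(sum(o), 4 * 5 * 9)
  g <- mask_probability_grid(7, 0.6, 2.5)
  m1 <- sample_mask(g, 10, 20, seed = 99)
  m2 <- sample_mask(g, 10, 20, seed = 99)
  expect_identical(m1, m2)
  n_draws <- 10 * 20 * 49
  p_bar <- mean(g)
  se <- sqrt(sum(10 * 20 * g * (1 - g))) / n_draws
  expect_lt(abs(mean(m1) - p_bar), 3 * se)
})

test_that("build_graph reproduces the published region table", {
  arch <- published_arch
  expect_identical(nrow(arch$regions), 22L)
  expect_identical(nrow(arch$edges), 49L)
  got <- arch$regions$channels
  names(got) <- arch$regions$name
  expect_equal(got[names(printed_channels)], printed_channels, ignore_attr = TRUE)
  # grids: 64 up to VISp, 32 beyond
  expect_true(all(arch$regions$grid[arch$regions$area %in%
                                      c("dLGN", "VISp")] == 64L))
  expect_true(all(arch$regions$grid[!arch$regions$area %in%
                                      c("dLGN", "VISp")] == 32L))
})

test_that("build_graph strides, subcortical kernels and spatial bookkeeping", {
  e <- published_arch$edges
  area_of <- function(nm) {
    i <- match(nm, published_arch$regions$name)
    ifelse(is.na(i), nm, published_arch$regions$area[i])
  }
  outbound_visp <- area_of(e$source) == "VISp" & area_of(e$target) != "VISp"
  expect_true(all(e$stride[outbound_visp] == 2L))
  expect_true(all(e$stride[!outbound_visp] == 1L))
  expect_identical(e$k[e$source == "input"], 9L)
  expect_identical(e$k[e$source == "dLGN"], 3L)
  expect_false(any(e$masked[e$source %in% c("input", "dLGN")]))
  # output grid = input grid / stride for every edge
  grid_of <- function(nm) ifelse(nm == "input", 64L,
    published_arch$regions$grid[match(nm, published_arch$regions$name)])
  out <- floor((grid_of(e$source) + 2 * e$padding - e$k) / e$stride) + 1
  expect_identical(as.integer(out), grid_of(e$target))
  # kernels always odd
  expect_true(all(e$k %% 2 == 1))
})

test_that("formula and as-published kernels differ in exactly the two flagged cells", {
  ef <- published_arch$edges
  ep <- published_arch_verbatim$edges
  key <- paste(ef$source, ef$target)
  differs <- which(ef$k != ep$k[match(key, paste(ep$source, ep$target))])
  expect_identical(sort(paste(ef$source[differs], ef$target[differs])),
                   sort(paste(kernel_discrepancies$source,
                              kernel_discrepancies$target)))
  for (i in seq_len(nrow(kernel_discrepancies))) {
    d <- kernel_discrepancies[i, ]
    expect_identical(ef$k[ef$source == d$source & ef$target == d$target],
                     d$formula)
    expect_identical(ep$k[ep$source == d$source & ep$target == d$target],
                     d$printed)
  }
})

test_that("interareal peaks: VISal L2/3 and L5 inputs to VISpor4 saturate at 1", {
  e <- published_arch$edges
  sat <- e[e$dp >= 1 & e$masked, c("source", "target")]
  expect_true(all(c("VISal2/3", "VISal5") %in%
                    sat$source[sat$target == "VISpor4"]))
  expect_true(all(e$dp[e$masked] <= 1))
  expect_true(all(e$dp[e$masked] > 0))
})

test_that("count_parameters: dense, classifier, and mask concentration", {
  expect_identical(count_parameters(published_arch, "classifier"), 2305000)
  expect_identical(count_parameters(published_arch_verbatim, "classifier"),
                   2305000)
  # single dense edge: 3 -> 5 channels, k = 9
  one <- new_architecture(
    regions = data.frame(name = "A5", area = "A", layer = "L5", n = 320,
                         grid = 8L, channels = 5L),
    edges = data.frame(source = "input", target = "A5", cin = 3L,
                       cout = 5L, k = 9L, stride = 1L, padding = 4L,
                       dtw = NA, dp = NA, masked = FALSE),
    n_classes = 2L, input_size = 8L, input_channels = 3L)
  expect_identical(count_parameters(one, "dense"), 1215)
  # formula-kernel dense total (the one consistent with the printed 2.1M)
  expect_identical(count_parameters(published_arch, "dense"), 2145097)
  # as-published dense total (two larger kernels)
  expect_identical(count_parameters(published_arch_verbatim, "dense"),
                   2151649)
  # sampled mask count concentrates around the expected count
  exp_ct <- count_parameters(published_arch, "masked-expected")
  smp_ct <- count_parameters(published_arch, "masked-sampled")
  e <- published_arch$edges
  v <- 0
  for (i in which(e$masked)) {
    g <- mask_probability_grid(e$k[i], e$dp[i], e$dtw[i])
    v <- v + e$cin[i] * e$cout[i] * sum(g * (1 - g))
  }
  expect_lt(abs(smp_ct - exp_ct), 3 * sqrt(v))
})

test_that("architecture JSON manifest round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture(published_arch, path)
  back <- read_architecture(path)
  expect_identical(back$regions$channels, published_arch$regions$channels)
  expect_equal(back$edges$dp, published_arch$edges$dp, tolerance = 1e-12)
  expect_identical(back$edges$mask_seed, published_arch$edges$mask_seed)
  expect_equal(back$classifier$feature_width,
               published_arch$classifier$feature_width)
  # counts agree after the round trip
  expect_identical(count_parameters(back, "dense"),
                   count_parameters(published_arch, "dense"))
})

test_that("build_graph fails loudly when a required interareal kernel is missing", {
  cfg <- published_config
  cfg$published_kernels <-
    Filter(function(r) !(r$source == "VISal4" && r$target == "VISpor4"),
           cfg$published_kernels)
  expect_error(build_graph(cfg), class = "mvcnet_config_error")
})
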