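# architectures: parameter accounting, forward contracts, gradients

tinyResnetCfg <- function(drop = FALSE)
  netConfig("resnet", useDropout = drop, fluorChannels = 2L,
            opticsChannels = 2L, collapseChannels = 3L, trunkChannels = 4L,
            headChannels = 3L)

tinyUnetCfg <- function(drop = FALSE)
  netConfig("unet", useDropout = drop, fluorChannels = 2L,
            opticsChannels = 2L, encoderWidths = c(3L, 4L),
            bottleneckChannels = 5L, gateChannels = c(3L, 2L),
            headChannels = 3L)

randomInputs <- function(H = 9, W = 9, N = 2, seed = 42) {
  set.seed(seed)
  list(xf = array(stats::rnorm(6 * H * W * N), c(6, H, W, 1, N)),
       xo = array(stats::rnorm(H * W * 2 * N), c(H, W, 2, N)))
}

test_that("parameter counting is exact and additive", {
  one <- list(w = array(0, c(3, 3, 1, 1)), b = numeric(1))
  expect_equal(countParameters(one), 10)   # 9 weights + 1 bias
  two <- c(one, list(w2 = array(0, c(3, 3, 1, 1)), b2 = numeric(1)))
  expect_equal(countParameters(two), 20)
})

test_that("default configurations reproduce the reference parameter totals", {
  expect_equal(parameterCount(buildNetwork(netConfig("resnet"))), 2000642)
  expect_equal(parameterCount(buildNetwork(netConfig("unet"))), 33145143)
})

test_that("forward passes honour the two-map output contract", {
  for (cfg in list(tinyResnetCfg(), tinyUnetCfg())) {
    sp <- buildNetwork(cfg, seed = 1)
    xf <- array(0, c(6, 13, 13, 1, 1))
    xo <- array(0, c(13, 13, 2, 1))
    fw <- networkForward(sp, xf, xo)
    expect_equal(dim(fw$depth), c(13, 13, 1))
    expect_equal(dim(fw$conc), c(13, 13, 1))
    expect_true(all(is.finite(fw$depth)))
    expect_true(all(is.finite(fw$conc)))
  }
})

test_that("backpropagated gradients match finite differences", {
  eps <- 1e-6
  for (variant in c("resnet", "unet")) {
    cfg <- if (variant == "resnet") tinyResnetCfg(TRUE) else tinyUnetCfg(TRUE)
    sp <- buildNetwork(cfg, seed = 3)
    inp <- randomInputs()
    set.seed(7)
    yd <- array(stats::rnorm(9 * 9 * 2), c(9, 9, 2))
    yc <- array(stats::rnorm(9 * 9 * 2), c(9, 9, 2))
    lossAt <- function(params) {
      s2 <- new("NetworkSpec", config = cfg, params = params,
                parameterCount = sp@parameterCount)
      set.seed(11)  # fixed dropout masks
      fw <- networkForward(s2, inp$xf, inp$xo, training = TRUE)
      mean(abs(fw$depth - yd)) + mean(abs(fw$conc - yc))
    }
    set.seed(11)
    fw <- networkForward(sp, inp$xf, inp$xo, training = TRUE)
    nel <- length(yd)
    gr <- networkBackward(sp, fw, sign(fw$depth - yd) / nel,
                          sign(fw$conc - yc) / nel)
    set.seed(99)
    for (nm in sample(names(sp@params), 10)) {
      p <- sp@params
      k <- sample(length(p[[nm]]), 1)
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- p; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (lossAt(p2) - lossAt(p3)) / (2 * eps)
      ana <- gr[[nm]][k]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-3,
                label = sprintf("%s gradient of %s[%d]", variant, nm, k))
    }
  }
})

test_that("dropout acts in training mode only; evaluation is deterministic", {
  sp <- buildNetwork(tinyUnetCfg(drop = TRUE), seed = 2)
  inp <- randomInputs(N = 1)
  e1 <- networkForward(sp, inp$xf, inp$xo, training = FALSE)
  e2 <- networkForward(sp, inp$xf, inp$xo, training = FALSE)
  expect_identical(e1$depth, e2$depth)
  set.seed(1); t1 <- networkForward(sp, inp$xf, inp$xo, training = TRUE)
  set.seed(2); t2 <- networkForward(sp, inp$xf, inp$xo, training = TRUE)
  expect_gt(max(abs(t1$depth - t2$depth)), 0)  # different masks
})

test_that("attention gate coefficients lie in [0, 1] and scale the skip", {
  sp <- buildNetwork(tinyUnetCfg(), seed = 6)
  set.seed(3)
  x <- array(stats::rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))   # skip (w1 = 3)
  g <- array(stats::rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))   # gate (w2 = 4)
  out <- SFDIdepth:::.attGateForward(x, g, sp@params, 1L, list())
  att <- out$cache$ag1$att
  expect_true(all(att >= 0 & att <= 1))
  ratio <- out$out / x
  for (c in 1:3)
    expect_equal(ratio[, , c, ], att[, , 1, ], tolerance = 1e-12)
})

test_that("the resnet trunk is translation-consistent in its interior", {
  sp <- buildNetwork(tinyResnetCfg(), seed = 9)
  set.seed(21)
  H <- 41
  xf <- array(stats::rnorm(6 * H * H), c(6, H, H, 1, 1))
  xo <- array(stats::rnorm(H * H * 2), c(H, H, 2, 1))
  # shift down by one pixel
  xfs <- array(0, dim(xf)); xfs[, 2:H, , , ] <- xf[, 1:(H - 1), , , ]
  xos <- array(0, dim(xo)); xos[2:H, , , ] <- xo[1:(H - 1), , , ]
  f1 <- networkForward(sp, xf, xo)$depth[, , 1]
  f2 <- networkForward(sp, xfs, xos)$depth[, , 1]
  # interior window beyond the receptive-field reach of both borders
  expect_equal(f2[21:23, 15:27], f1[20:22, 15:27], tolerance = 1e-9)
})

test_that("checkpoints round-trip weights, config and normalization", {
  sp <- buildNetwork(tinyUnetCfg(), seed = 4)
  attr(sp, "norm") <- normalizationScheme()
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(sp, f)
  sp2 <- loadCheckpoint(f)
  expect_equal(sp2@params, sp@params)
  expect_equal(sp2@config, sp@config)
  expect_equal(attr(sp2, "norm"), attr(sp, "norm"))
  inp <- randomInputs(N = 1)
  expect_identical(networkForward(sp, inp$xf, inp$xo)$depth,
                   networkForward(sp2, inp$xf, inp$xo)$depth)
})
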