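# normalization, training loop, prediction, evaluation battery

tinyRecord <- function(seed, H = 9) {
  set.seed(seed)
  list(fluorescence = array(stats::runif(H * H * 6), c(H, H, 6)),
       muA = matrix(stats::runif(H * H, 0.002, 0.01), H, H),
       muSp = matrix(stats::runif(H * H, 0.8, 1.9), H, H),
       depth = matrix(stats::runif(H * H, 0, 12), H, H),
       conc = matrix(stats::runif(H * H, 1, 9), H, H))
}

test_that("normalization round-trips to machine precision", {
  r <- tinyRecord(1)
  sch <- normalizationScheme()
  nr <- normalizeRecord(r, sch)
  expect_equal(nr$yd * sch$depthScale, r$depth, tolerance = 1e-14)
  expect_equal(nr$yc * sch$concScale, r$conc, tolerance = 1e-14)
  expect_equal(nr$xo[, , 1] * diff(sch$muA) + sch$muA[1], r$muA,
               tolerance = 1e-14)
  expect_equal(nr$xo[, , 2] * diff(sch$muSp) + sch$muSp[1], r$muSp,
               tolerance = 1e-14)
  m0 <- max(r$fluorescence[, , 1])
  expect_equal(aperm(array(nr$xf, dim(nr$xf)[1:3]), c(2, 3, 1)) * m0,
               r$fluorescence, tolerance = 1e-14)
})

test_that("perfect and offset predictions give the textbook error metrics", {
  td <- matrix(c(2, 3, 10, 4, 5, 10, 10, 10, 10), 3, 3)
  tc <- matrix(c(5, 5, 1, 5, 5, 1, 1, 1, 1), 3, 3)
  truth <- new("TruthMaps", depthMap = td, concentrationMap = tc,
               backgroundDepth = 10)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                   FALSE), 3, 3)
  perfect <- new("PredMaps", depthMap = td, concentrationMap = tc)
  rep0 <- evaluateMaps(list(perfect, perfect), list(truth, truth),
                       list(mask, mask))
  expect_equal(rep0@depthMAE, 0)
  expect_equal(rep0@concMAE, 0)
  expect_equal(rep0@closestMAE, 0)
  offset <- new("PredMaps", depthMap = td + 1, concentrationMap = tc)
  rep1 <- evaluateMaps(offset, truth, mask)
  expect_equal(rep1@depthMAE, 1)
  expect_equal(rep1@depthSD, 0)
  expect_equal(rep1@perCase$closestErr, 1)
})

test_that("toy 3x3 maps match a hand-computed error table", {
  # tumor pixels: true depths (2, 3, 4, 5), preds (2.5, 3, 4, 6)
  # abs errors (0.5, 0, 0, 1): MAE = 0.375, closest = |2.5 - 2| = 0.5
  td <- matrix(c(2, 3, 10, 4, 5, 10, 10, 10, 10), 3, 3)
  tc <- matrix(c(5, 5, 1, 5, 5, 1, 1, 1, 1), 3, 3)
  pd <- matrix(c(2.5, 3, 9, 4, 6, 10, 11, 10, 10), 3, 3)
  pc <- matrix(c(4, 5, 1, 6, 5, 1, 1, 2, 1), 3, 3)
  truth <- new("TruthMaps", depthMap = td, concentrationMap = tc,
               backgroundDepth = 10)
  pred <- new("PredMaps", depthMap = pd, concentrationMap = pc)
  rep <- evaluateMaps(pred, truth)
  expect_equal(rep@depthMAE, mean(c(0.5, 0, 0, 1)))
  expect_equal(rep@depthSD, stats::sd(c(0.5, 0, 0, 1)))
  expect_equal(rep@concMAE, mean(c(1, 0, 1, 0)))
  expect_equal(rep@perCase$closestErr, 0.5)
  # binned: depths 2, 3, 4 in [0,5); 5 in [5,10)
  expect_equal(unname(rep@binnedMAE["0-5"]), mean(c(0.5, 0, 0)))
  expect_equal(unname(rep@binnedMAE["5-10"]), 1)
})

test_that("binned errors recombine to the overall MAE and metrics are
           invariant to pixel ordering", {
  set.seed(8)
  H <- 12
  td <- matrix(stats::runif(H * H, 0, 14.9), H, H)
  pd <- td + stats::rnorm(H * H)
  truth <- new("TruthMaps", depthMap = td,
               concentrationMap = matrix(5, H, H), backgroundDepth = 10)
  pred <- new("PredMaps", depthMap = pd, concentrationMap = matrix(5, H, H))
  mask <- matrix(TRUE, H, H)
  rep <- evaluateMaps(pred, truth, mask)
  counts <- sapply(list(c(0, 5), c(5, 10), c(10, 15)), function(b)
    sum(td >= b[1] & td < b[2]))
  expect_equal(sum(rep@binnedMAE * counts) / sum(counts), rep@depthMAE)
  # transpose both maps: every statistic unchanged
  truthT <- new("TruthMaps", depthMap = t(td),
                concentrationMap = matrix(5, H, H), backgroundDepth = 10)
  predT <- new("PredMaps", depthMap = t(pd), concentrationMap = matrix(5, H, H))
  repT <- evaluateMaps(predT, truthT, mask)
  expect_equal(repT@depthMAE, rep@depthMAE)
  expect_equal(repT@depthSD, rep@depthSD)
  expect_equal(repT@binnedMAE, rep@binnedMAE)
})

test_that("equality-line R^2 is 1 for perfect ranking and negative for
           anti-correlated closest depths", {
  mk <- function(minDepth) {
    td <- matrix(10, 4, 4); td[2, 2] <- minDepth
    new("TruthMaps", depthMap = td, concentrationMap = matrix(5, 4, 4),
        backgroundDepth = 10)
  }
  mkP <- function(minDepth) {
    pd <- matrix(10, 4, 4); pd[2, 2] <- minDepth
    new("PredMaps", depthMap = pd, concentrationMap = matrix(5, 4, 4))
  }
  truths <- lapply(c(2, 4, 6, 8), mk)
  masks <- rep(list(matrix(TRUE, 4, 4)), 4)
  repGood <- evaluateMaps(lapply(c(2, 4, 6, 8), mkP), truths, masks)
  expect_equal(repGood@r2, 1)
  repBad <- evaluateMaps(lapply(c(8, 6, 4, 2), mkP), truths, masks)
  expect_lt(repBad@r2, 0)   # worse than predicting the mean
})

test_that("model comparison stars follow the printed thresholds", {
  same <- c(1, 2, 3, 4)
  expect_error(compareModels(c(1), c(1, 2)), "2")
  res <- compareModels(same, same)
  expect_equal(res$pValue, 1)
  expect_equal(res$stars, "")
  set.seed(2)
  a <- rep(0, 6) + abs(stats::rnorm(6, sd = 1e-3))
  b <- rep(5, 6) + stats::rnorm(6, sd = 1e-3)
  res2 <- compareModels(a, b)
  expect_lt(res2$pValue, 0.001)
  expect_equal(res2$stars, "***")
  expect_error(compareModels(rep(1, 4), rep(2, 4)), "degenerate")
})

test_that("training reduces loss, tracks a monotone best checkpoint, and
           overfits a single scene", {
  recs <- lapply(1:20, tinyRecord)
  cfg <- netConfig("unet", fluorChannels = 2L, opticsChannels = 2L,
                   encoderWidths = c(4L, 6L), bottleneckChannels = 8L,
                   gateChannels = c(4L, 3L), headChannels = 4L)
  sp <- buildNetwork(cfg, seed = 1)
  fit <- trainNetwork(sp, recs, trainConfig(epochs = 5, batchSize = 8,
                                            seed = 3), verbose = FALSE)
  expect_true(all(diff(fit$history$bestVal) <= 0))
  expect_equal(nrow(fit$history), 5)
  expect_lt(fit$history$train[5], fit$history$train[1])
  # single-scene overfit: a high-capacity fit drives depth error below 0.1 mm
  one <- tinyRecord(99)
  cfgR <- netConfig("resnet", fluorChannels = 2L, opticsChannels = 2L,
                    collapseChannels = 4L, trunkChannels = 8L,
                    headChannels = 6L)
  spR <- buildNetwork(cfgR, seed = 2)
  fitR <- trainNetwork(spR, list(one, one), trainConfig(split = 0.5,
                       batchSize = 1, epochs = 700, lr = 3e-3,
                       lrDecayEpochs = 500, seed = 1),
                       verbose = FALSE)
  pm <- predictMaps(fitR$model, one)
  expect_lt(mean(abs(depthMap(pm) - one$depth)), 0.1)
})

test_that("prediction is deterministic and returns physical units", {
  recs <- lapply(1:4, tinyRecord)
  cfg <- netConfig("unet", fluorChannels = 2L, opticsChannels = 2L,
                   encoderWidths = c(3L, 4L), bottleneckChannels = 5L,
                   gateChannels = c(3L, 2L), headChannels = 3L)
  fit <- trainNetwork(buildNetwork(cfg, seed = 1), recs,
                      trainConfig(epochs = 2, batchSize = 2, seed = 5),
                      verbose = FALSE)
  p1 <- predictMaps(fit$model, recs[[1]])
  p2 <- predictMaps(fit$model, recs[[1]])
  expect_identical(depthMap(p1), depthMap(p2))
  expect_equal(dim(depthMap(p1)), c(9, 9))
  # raw-input interface agrees with the record interface
  p3 <- predictMaps(fit$model, fluorescence = recs[[1]]$fluorescence,
                    opmaps = list(muA = recs[[1]]$muA, muSp = recs[[1]]$muSp))
  expect_equal(depthMap(p3), depthMap(p1))
  # an untrained spec has no normalization scheme attached
  expect_error(predictMaps(buildNetwork(cfg), recs[[1]]), "normalization")
})
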