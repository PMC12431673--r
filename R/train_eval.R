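# Training, inference and the evaluation battery.

#' Normalization scheme
#'
#' Inputs: the fluorescence stack is divided by its per-scene maximum at
#' the lowest spatial frequency (removing the arbitrary simulation source
#' normalization while preserving the cross-frequency decay that encodes
#' depth); optical-property maps are min-max scaled by the training
#' ranges. Targets: depth is scaled by 15 mm (the full bin range) and
#' concentration by 10 ug/ml, so both contribute comparably to the loss.
#' `denormalize(normalize(x)) = x` holds to machine precision.
#'
#' @param optics the training [opticsRanges()].
#' @param depthScale,concScale target scales (mm, ug/ml).
#' @param fluorNorm fluorescence input representation:
#'   \describe{
#'     \item{"scene-max"}{stack divided by its per-scene fx = 0 maximum
#'       (the default): preserves cross-frequency amplitude ratios
#'       linearly, but high-frequency channels become numerically tiny.}
#'     \item{"log"}{scene-max scaling followed by a floored log10 map to
#'       [0, 1]: equalizes channel magnitudes but compresses the spatial
#'       contrast that localizes the inclusion.}
#'     \item{"log-contrast"}{each frequency image normalized to its own
#'       maximum (full spatial contrast in every channel) and rescaled by
#'       1 + log10(max_k / max_0)/|log10(floor)|, so the channel's overall
#'       brightness carries the log-domain decay — the physical depth
#'       cue — while the pattern keeps full contrast.}
#'   }
#' @param logFloor relative floor used by the log-domain representations.
#' @return a scheme list consumed by [normalizeRecord()].
#' @export
normalizationScheme <- function(optics = opticsRanges(), depthScale = 15,
                                concScale = 10,
                                fluorNorm = c("scene-max", "log",
                                              "log-contrast"),
                                logFloor = 1e-7) {
  list(muA = optics$muA, muSp = optics$muSp,
       depthScale = depthScale, concScale = concScale,
       fluorNorm = match.arg(fluorNorm), logFloor = logFloor)
}

#' Normalize a dataset record into network inputs/targets
#'
#' @param record a record list from [simulateRecord()].
#' @param scheme from [normalizationScheme()].
#' @return list with `xf` (nFx, H, W, 1), `xo` (H, W, 2), `yd`, `yc`.
#' @export
normalizeRecord <- function(record, scheme) {
  fl <- record$fluorescence
  m0 <- max(fl[, , 1])
  if (m0 <= 0) m0 <- 1
  mode <- scheme$fluorNorm %||% "scene-max"
  if (mode == "log") {
    lf <- log10(scheme$logFloor)
    fl <- (log10(pmax(fl / m0, scheme$logFloor)) - lf) / (-lf)
  } else if (mode == "log-contrast") {
    lf <- -log10(scheme$logFloor)
    for (k in seq_len(dim(fl)[3])) {
      mk <- max(fl[, , k])
      sk <- if (mk > 0) max(0, 1 + log10(mk / m0) / lf) else 0
      fl[, , k] <- if (mk > 0) fl[, , k] / mk * sk else 0
    }
  } else {
    fl <- fl / m0
  }
  d <- dim(fl)
  xf <- aperm(fl, c(3, 1, 2))
  dim(xf) <- c(d[3], d[1], d[2], 1)
  xo <- array(0, c(d[1], d[2], 2))
  xo[, , 1] <- (record$muA - scheme$muA[1]) / diff(scheme$muA)
  xo[, , 2] <- (record$muSp - scheme$muSp[1]) / diff(scheme$muSp)
  list(xf = xf, xo = xo,
       yd = record$depth / scheme$depthScale,
       yc = record$conc / scheme$concScale,
       tumor = record$depth != 10 | record$conc > min(record$conc))
}

.stackBatch <- function(norms, idx) {
  nfx <- dim(norms[[1]]$xf)[1]
  H <- dim(norms[[1]]$xf)[2]; W <- dim(norms[[1]]$xf)[3]
  n <- length(idx)
  xf <- array(0, c(nfx, H, W, 1, n))
  xo <- array(0, c(H, W, 2, n))
  yd <- array(0, c(H, W, n))
  yc <- array(0, c(H, W, n))
  tm <- array(FALSE, c(H, W, n))
  for (j in seq_along(idx)) {
    r <- norms[[idx[j]]]
    xf[, , , , j] <- r$xf
    xo[, , , j] <- r$xo
    yd[, , j] <- r$yd
    yc[, , j] <- r$yc
    if (!is.null(r$tumor)) tm[, , j] <- r$tumor
  }
  list(xf = xf, xo = xo, yd = yd, yc = yc, tumor = tm)
}

#' Training configuration
#'
#' @param split train fraction of the dataset (validation gets the rest).
#' @param batchSize mini-batch size.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param lossWeights c(depth, concentration) L1 weights.
#' @param tumorWeight relative per-pixel loss weight of tumor-column
#'   pixels vs background (default 1 = uniform). Small inclusions occupy
#'   a tiny pixel fraction; upweighting them keeps the loss sensitive to
#'   the clinically decisive region.
#' @param lrDecayEpochs epochs at which the learning rate is multiplied by
#'   `lrDecayFactor` (step schedule; empty for a constant rate).
#' @param lrDecayFactor multiplicative decay applied at each step.
#' @param seed RNG seed for the split, shuffling and dropout.
#' @return config list.
#' @export
trainConfig <- function(split = 0.9, batchSize = 16L, epochs = 40L,
                        lr = 1e-3, lossWeights = c(depth = 1, conc = 1),
                        tumorWeight = 1,
                        lrDecayEpochs = integer(0), lrDecayFactor = 0.3,
                        seed = 1L) {
  stopifnot(split > 0, split < 1, batchSize >= 1, epochs >= 1, lr > 0,
            tumorWeight >= 1)
  list(split = split, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), lr = lr, lossWeights = lossWeights,
       tumorWeight = tumorWeight,
       lrDecayEpochs = as.integer(lrDecayEpochs),
       lrDecayFactor = lrDecayFactor, seed = as.integer(seed))
}

#' Train a network on a synthetic dataset
#'
#' Minimizes the weighted per-pixel L1 loss on the normalized depth and
#' concentration maps with Adam, tracks validation loss each epoch, and
#' returns the best-validation checkpoint together with the loss history.
#'
#' @param spec a freshly built [NetworkSpec-class].
#' @param dataset a list of records ([loadDataset()]) or a dataset
#'   directory path.
#' @param config from [trainConfig()].
#' @param scheme normalization from [normalizationScheme()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-validation [NetworkSpec-class], with the
#'   normalization scheme attached), `history` (data.frame epoch/train/val/
#'   bestVal).
#' @export
trainNetwork <- function(spec, dataset, config = trainConfig(),
                         scheme = normalizationScheme(),
                         verbose = interactive()) {
  if (is.character(dataset)) dataset <- loadDataset(dataset)
  stopifnot(length(dataset) >= 2)
  set.seed(config$seed)
  norms <- lapply(dataset, normalizeRecord, scheme = scheme)
  n <- length(norms)
  idx <- sample.int(n)
  nTrain <- max(1L, floor(config$split * n))
  trainIdx <- idx[seq_len(nTrain)]
  valIdx <- idx[(nTrain + 1):n]
  if (length(valIdx) == 0L) valIdx <- trainIdx[1]
  params <- spec@params
  mAdam <- lapply(params, function(x) array(0, dim(x) %||% length(x)))
  vAdam <- lapply(params, function(x) array(0, dim(x) %||% length(x)))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  step <- 0L
  wd <- config$lossWeights[[1]]; wc <- config$lossWeights[[2]]
  tw <- config$tumorWeight %||% 1
  pixWeights <- function(bt) {
    w <- array(1, dim(bt$yd))
    if (tw > 1) w[bt$tumor] <- tw
    w / sum(w)
  }
  lossOn <- function(pd, pc, bt) {
    w <- pixWeights(bt)
    wd * sum(w * abs(pd - bt$yd)) + wc * sum(w * abs(pc - bt$yc))
  }
  valLoss <- function(sp) {
    tot <- 0
    for (ch in split(valIdx, ceiling(seq_along(valIdx) / config$batchSize))) {
      bt <- .stackBatch(norms, ch)
      fw <- networkForward(sp, bt$xf, bt$xo, training = FALSE)
      tot <- tot + lossOn(fw$depth, fw$conc, bt) * length(ch)
    }
    tot / length(valIdx)
  }
  best <- list(loss = Inf, params = params)
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric(),
                     bestVal = numeric())
  lrNow <- config$lr
  for (ep in seq_len(config$epochs)) {
    if (ep %in% config$lrDecayEpochs) lrNow <- lrNow * config$lrDecayFactor
    ord <- sample(trainIdx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epLoss <- 0
    for (bidx in batches) {
      bt <- .stackBatch(norms, bidx)
      sp <- new("NetworkSpec", config = spec@config, params = params,
                parameterCount = spec@parameterCount)
      fw <- networkForward(sp, bt$xf, bt$xo, training = TRUE)
      l <- lossOn(fw$depth, fw$conc, bt)
      if (!is.finite(l))
        stop("non-finite loss at epoch ", ep, " (batch of ",
             length(bidx), "; records ", paste(bidx, collapse = ","), ")")
      epLoss <- epLoss + l * length(bidx)
      w <- pixWeights(bt)
      dD <- wd * w * sign(fw$depth - bt$yd)
      dC <- wc * w * sign(fw$conc - bt$yc)
      grads <- networkBackward(sp, fw, dD, dC)
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(params)) {
        gnm <- grads[[nm]]
        if (is.null(gnm)) next
        mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * gnm
        vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * gnm^2
        params[[nm]] <- params[[nm]] -
          lrNow * corr * mAdam[[nm]] / (sqrt(vAdam[[nm]]) + epsA)
      }
    }
    spEval <- new("NetworkSpec", config = spec@config, params = params,
                  parameterCount = spec@parameterCount)
    vl <- valLoss(spEval)
    if (vl < best$loss) best <- list(loss = vl, params = params)
    hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / length(ord),
                                   val = vl, bestVal = best$loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  best %.5f",
                      ep, epLoss / length(ord), vl, best$loss))
  }
  model <- new("NetworkSpec", config = spec@config, params = best$params,
               parameterCount = spec@parameterCount)
  attr(model, "norm") <- scheme
  list(model = model, history = hist)
}

#' Predict margin-distance and concentration maps
#'
#' Evaluation-mode forward pass returning maps in physical units. Accepts
#' either a dataset record or explicit fluorescence stack + optical maps.
#'
#' @param model a trained [NetworkSpec-class] (with attached normalization).
#' @param record a record list, or NULL when giving raw inputs.
#' @param fluorescence (H, W, nFx) stack, used when `record` is NULL.
#' @param opmaps an [OPMaps-class] or list with `muA`, `muSp`.
#' @return a [PredMaps-class].
#' @export
predictMaps <- function(model, record = NULL, fluorescence = NULL,
                        opmaps = NULL) {
  scheme <- attr(model, "norm")
  if (is.null(scheme))
    stop("model carries no normalization scheme; train it first or attach one")
  if (is.null(record)) {
    stopifnot(!is.null(fluorescence), !is.null(opmaps))
    record <- list(fluorescence = fluorescence,
                   muA = if (is(opmaps, "OPMaps")) opmaps@muA else opmaps$muA,
                   muSp = if (is(opmaps, "OPMaps")) opmaps@muSp else opmaps$muSp,
                   depth = matrix(0, dim(fluorescence)[1], dim(fluorescence)[2]),
                   conc = matrix(0, dim(fluorescence)[1], dim(fluorescence)[2]))
  }
  nr <- normalizeRecord(record, scheme)
  d <- dim(nr$xf)
  xf <- array(nr$xf, c(d, 1))
  xo <- array(nr$xo, c(dim(nr$xo), 1))
  fw <- networkForward(model, xf, xo, training = FALSE)
  new("PredMaps",
      depthMap = fw$depth[, , 1] * scheme$depthScale,
      concentrationMap = fw$conc[, , 1] * scheme$concScale)
}

# ---- evaluation ------------------------------------------------------------

.depthBins <- rbind(c(0, 5), c(5, 10), c(10, 15))

#' Evaluate predictions against ground truth
#'
#' Computes the full error battery over one or more cases: per-pixel MAE
#' and SD of depth and concentration restricted to tumor-region pixels
#' (columns containing tumor in the ground truth), MAE/SD by true-depth
#' bin (0-5, 5-10, 10-15 mm), the closest-depth error |min(pred) -
#' min(true)| per case with its MAE/SD, and R^2 of predicted vs true
#' closest depths about the line of equality (1 - SS_res/SS_tot with
#' residuals against y = x), which can be negative.
#'
#' @param preds a [PredMaps-class] or list of them.
#' @param truths a [TruthMaps-class] or list of them (same length).
#' @param tumorMasks optional logical matrix/list; defaults to the columns
#'   whose true concentration exceeds the background, i.e. tumor columns.
#' @return an [EvalReport-class].
#' @examples
#' t <- new("TruthMaps", depthMap = matrix(3, 4, 4),
#'          concentrationMap = matrix(5, 4, 4), backgroundDepth = 10)
#' p <- new("PredMaps", depthMap = matrix(4, 4, 4),
#'          concentrationMap = matrix(5, 4, 4))
#' evaluateMaps(p, t, matrix(TRUE, 4, 4))
#' @export
evaluateMaps <- function(preds, truths, tumorMasks = NULL) {
  if (is(preds, "PredMaps")) preds <- list(preds)
  if (is(truths, "TruthMaps")) truths <- list(truths)
  if (is.matrix(tumorMasks)) tumorMasks <- list(tumorMasks)
  stopifnot(length(preds) == length(truths))
  dErr <- numeric(0); cErr <- numeric(0); trueD <- numeric(0)
  perCase <- data.frame()
  closestT <- numeric(length(preds)); closestP <- numeric(length(preds))
  for (i in seq_along(preds)) {
    pd <- preds[[i]]@depthMap; td <- truths[[i]]@depthMap
    pc <- preds[[i]]@concentrationMap; tc <- truths[[i]]@concentrationMap
    stopifnot(identical(dim(pd), dim(td)))
    mask <- if (!is.null(tumorMasks)) tumorMasks[[i]]
            else td != truths[[i]]@backgroundDepth | tc > min(tc)
    if (!any(mask)) stop("empty tumor mask in case ", i)
    dErr <- c(dErr, abs(pd[mask] - td[mask]))
    cErr <- c(cErr, abs(pc[mask] - tc[mask]))
    trueD <- c(trueD, td[mask])
    closestT[i] <- min(td)
    closestP[i] <- min(pd)
    perCase <- rbind(perCase, data.frame(
      case = i,
      depthMAE = mean(abs(pd[mask] - td[mask])),
      concMAE = mean(abs(pc[mask] - tc[mask])),
      trueClosest = closestT[i], predClosest = closestP[i],
      closestErr = abs(closestP[i] - closestT[i])))
  }
  binnedMAE <- binnedSD <- numeric(nrow(.depthBins))
  names(binnedMAE) <- names(binnedSD) <-
    apply(.depthBins, 1, function(b) sprintf("%g-%g", b[1], b[2]))
  for (k in seq_len(nrow(.depthBins))) {
    inBin <- trueD >= .depthBins[k, 1] & trueD < .depthBins[k, 2]
    binnedMAE[k] <- if (any(inBin)) mean(dErr[inBin]) else NA_real_
    binnedSD[k] <- if (sum(inBin) > 1) stats::sd(dErr[inBin]) else NA_real_
  }
  cErrClosest <- abs(closestP - closestT)
  ssRes <- sum((closestP - closestT)^2)
  ssTot <- sum((closestT - mean(closestT))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  new("EvalReport",
      depthMAE = mean(dErr), depthSD = stats::sd(dErr),
      concMAE = mean(cErr), concSD = stats::sd(cErr),
      binnedMAE = binnedMAE, binnedSD = binnedSD,
      closestMAE = mean(cErrClosest),
      closestSD = if (length(cErrClosest) > 1) stats::sd(cErrClosest) else 0,
      r2 = r2, perCase = perCase)
}

#' Compare two models' per-case errors
#'
#' Two-sided independent (two-sample) t-test on per-case closest-depth
#' errors, with the conventional significance stars (* p<0.05, ** p<0.01,
#' *** p<0.001).
#'
#' @param errorsA,errorsB numeric vectors of per-case errors (>= 2 each).
#' @return list with `statistic`, `pValue`, `stars`.
#' @export
compareModels <- function(errorsA, errorsB) {
  stopifnot(length(errorsA) >= 2, length(errorsB) >= 2)
  if (stats::sd(errorsA) == 0 && stats::sd(errorsB) == 0) {
    if (isTRUE(all.equal(mean(errorsA), mean(errorsB))))
      return(list(statistic = 0, pValue = 1, stars = ""))
    stop("both groups have zero variance but different means; t-test degenerate")
  }
  tt <- stats::t.test(errorsA, errorsB, var.equal = TRUE)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(statistic = unname(tt$statistic), pValue = p, stars = stars)
}
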