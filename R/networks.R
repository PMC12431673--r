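# Dual-branch dense-regression architectures.
#
# Both variants take the six-frequency fluorescence stack (3D filters over
# x, y and the frequency axis) and the two optical-property maps (2D
# filters), and emit two full-resolution maps: margin distance and
# fluorophore concentration. The ResNet variant keeps the lateral
# resolution throughout and encodes with residual blocks; the U-Net
# variant condenses laterally with max pooling and decodes through
# attention-gated skip connections. Every convolution is followed by a
# ReLU except the two linear 1x1 output layers; when dropout is enabled, a
# dropout layer follows each branch convolution before concatenation.
#
# Forward/backward passes are written explicitly against the C++
# primitives; gradients are verified against finite differences in the
# test suite.

#' Network configuration
#'
#' Defaults reproduce the reference architectures exactly: the ResNet
#' variant has 2,000,642 trainable parameters and the attention U-Net
#' 33,145,143. Width arguments allow scaled-down models for desk-scale
#' training experiments.
#'
#' @param variant "resnet" or "unet".
#' @param useDropout add a dropout layer after each branch convolution.
#' @param dropoutRate dropout probability (default 0.2).
#' @param nFx number of spatial frequencies (input depth axis; default 6).
#' @param fluorChannels 3D-branch channel width.
#' @param opticsChannels 2D-branch channel width.
#' @param collapseChannels (resnet) width after collapsing the frequency
#'   axis.
#' @param trunkChannels (resnet) trunk width after concatenation.
#' @param headChannels width of the two output heads.
#' @param encoderWidths (unet) encoder level widths, finest first.
#' @param bottleneckChannels (unet) bottleneck width.
#' @param gateChannels (unet) attention-gate inner widths, coarsest first.
#' @return a config list for [buildNetwork()].
#' @examples
#' cfg <- netConfig("resnet")
#' @export
netConfig <- function(variant = c("resnet", "unet"), useDropout = FALSE,
                      dropoutRate = 0.2, nFx = 6L,
                      fluorChannels = NULL, opticsChannels = NULL,
                      collapseChannels = NULL, trunkChannels = NULL,
                      headChannels = NULL, encoderWidths = NULL,
                      bottleneckChannels = NULL, gateChannels = NULL) {
  variant <- match.arg(variant)
  stopifnot(dropoutRate >= 0, dropoutRate < 1)
  if (variant == "resnet") {
    cfg <- list(variant = variant, useDropout = useDropout,
                dropoutRate = dropoutRate, nFx = as.integer(nFx),
                fluorChannels = fluorChannels %||% 16L,
                opticsChannels = opticsChannels %||% 52L,
                collapseChannels = collapseChannels %||% 182L,
                trunkChannels = trunkChannels %||% 138L,
                headChannels = headChannels %||% 64L)
  } else {
    cfg <- list(variant = variant, useDropout = useDropout,
                dropoutRate = dropoutRate, nFx = as.integer(nFx),
                fluorChannels = fluorChannels %||% 8L,
                opticsChannels = opticsChannels %||% 9L,
                encoderWidths = encoderWidths %||% c(64L, 128L, 256L, 512L),
                bottleneckChannels = bottleneckChannels %||% 1064L,
                gateChannels = gateChannels %||% c(256L, 128L, 65L, 53L),
                headChannels = headChannels %||% 64L)
    stopifnot(length(cfg$gateChannels) == length(cfg$encoderWidths))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# He-normal initialization
.heInit <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dims)
}

.convParams <- function(ci, co, k = 3L) {
  list(w = .heInit(c(k, k, ci, co), ci * k * k), b = numeric(co))
}

.conv3Params <- function(ci, co, k = 3L) {
  list(w = .heInit(c(k, k, k, ci, co), ci * k^3), b = numeric(co))
}

#' Instantiate a network
#'
#' Allocates and initializes all trainable tensors for the configured
#' architecture.
#'
#' @param config from [netConfig()].
#' @param seed RNG seed for weight initialization.
#' @return a [NetworkSpec-class].
#' @examples
#' spec <- buildNetwork(netConfig("resnet"))
#' parameterCount(spec)  # 2000642
#' @export
buildNetwork <- function(config, seed = 1L) {
  set.seed(seed)
  p <- list()
  nfx <- config$nFx
  if (config$variant == "resnet") {
    f1 <- config$fluorChannels; f2 <- config$collapseChannels
    g1 <- config$opticsChannels; tr <- config$trunkChannels
    hd <- config$headChannels
    p$f.in <- .conv3Params(1L, f1)
    p$f.res1 <- .conv3Params(f1, f1)
    p$f.res2 <- .conv3Params(f1, f1)
    p$f.collapse <- .convParams(nfx * f1, f2)
    p$o.in <- .convParams(2L, g1)
    p$o.res1 <- .convParams(g1, g1)
    p$o.res2 <- .convParams(g1, g1)
    cc <- f2 + g1
    p$t.res1 <- .convParams(cc, cc)
    p$t.res2 <- .convParams(cc, cc)
    p$t.conv <- .convParams(cc, tr)
    p$t.res3 <- .convParams(tr, tr)
    p$t.res4 <- .convParams(tr, tr)
    p$hd.conv <- .convParams(tr, hd)
    p$hd.out <- .convParams(hd, 1L, 1L)
    p$hc.conv <- .convParams(tr, hd)
    p$hc.out <- .convParams(hd, 1L, 1L)
  } else {
    a <- config$fluorChannels; b <- config$opticsChannels
    w <- config$encoderWidths; w5 <- config$bottleneckChannels
    fi <- config$gateChannels; hd <- config$headChannels
    L <- length(w)
    p$f.c1 <- .conv3Params(1L, a)
    p$f.c2 <- .conv3Params(a, a)
    p$o.c1 <- .convParams(2L, b)
    p$o.c2 <- .convParams(b, b)
    cin <- nfx * a + b
    for (i in seq_len(L)) {
      p[[sprintf("enc%d.c1", i)]] <- .convParams(cin, w[i])
      p[[sprintf("enc%d.c2", i)]] <- .convParams(w[i], w[i])
      cin <- w[i]
    }
    p$bott.c1 <- .convParams(w[L], w5)
    p$bott.c2 <- .convParams(w5, w5)
    above <- w5
    for (i in rev(seq_len(L))) {  # decoder, coarsest level first
      gi <- fi[L - i + 1L]
      p[[sprintf("ag%d.wg", i)]] <- list(w = .heInit(c(1, 1, above, gi), above),
                                         b = numeric(gi))
      p[[sprintf("ag%d.wx", i)]] <- list(w = .heInit(c(1, 1, w[i], gi), w[i]))
      p[[sprintf("ag%d.psi", i)]] <- list(w = .heInit(c(1, 1, gi, 1L), gi),
                                          b = numeric(1))
      p[[sprintf("dec%d.c1", i)]] <- .convParams(w[i] + above, w[i])
      p[[sprintf("dec%d.c2", i)]] <- .convParams(w[i], w[i])
      above <- w[i]
    }
    p$hd.conv <- .convParams(w[1], hd)
    p$hd.out <- .convParams(hd, 1L, 1L)
    p$hc.conv <- .convParams(w[1], hd)
    p$hc.out <- .convParams(hd, 1L, 1L)
  }
  flat <- list()
  for (nm in names(p)) for (part in names(p[[nm]]))
    flat[[paste(nm, part, sep = ".")]] <- p[[nm]][[part]]
  new("NetworkSpec", config = config, params = flat,
      parameterCount = sum(vapply(flat, length, numeric(1))))
}

#' Count trainable parameters
#'
#' Sum of element counts over all trainable tensors.
#'
#' @param model a [NetworkSpec-class] or a plain list of arrays.
#' @return integer-valued count.
#' @export
countParameters <- function(model) {
  if (is(model, "NetworkSpec")) model <- model@params
  sum(vapply(model, length, numeric(1)))
}

# ---- layer wrappers --------------------------------------------------------

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.conv2 <- function(x, p) .conv2dForwardCpp(x, p$w, p$b)
.conv3 <- function(x, p) .conv3dForwardCpp(x, p$w, p$b)

# dropout mask (inverted scaling); NULL when inactive
.dropMask <- function(dims, rate, active) {
  if (!active || rate <= 0) return(NULL)
  array(stats::rbinom(prod(dims), 1L, 1 - rate) / (1 - rate), dims)
}

.applyMask <- function(x, m) if (is.null(m)) x else x * m

# collapse (nfx, H, W, C, N) -> (H, W, nfx*C, N); channel = (freq, c) pairs
.collapse3d <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(2, 3, 1, 4, 5))
  dim(y) <- c(d[2], d[3], d[1] * d[4], d[5])
  y
}

.uncollapse3d <- function(y, nfx) {
  d <- dim(y)
  dim(y) <- c(d[1], d[2], nfx, d[3] / nfx, d[4])
  aperm(y, c(3, 1, 2, 4, 5))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- forward/backward ------------------------------------------------------

# conv + relu with cache
.cr2 <- function(x, p, cache, nm) {
  pre <- .conv2dForwardCpp(x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]])
  out <- .relu(pre)
  cache[[nm]] <- list(x = x, mask = pre > 0)
  list(out = out, cache = cache)
}

.cr2back <- function(dout, p, cache, nm, grads) {
  d <- dout * cache[[nm]]$mask
  g <- .conv2dBackwardCpp(cache[[nm]]$x, p[[paste0(nm, ".w")]], d)
  grads[[paste0(nm, ".w")]] <- grads[[paste0(nm, ".w")]] %+0% g$dw
  grads[[paste0(nm, ".b")]] <- grads[[paste0(nm, ".b")]] %+0% g$db
  list(dx = g$dx, grads = grads)
}

`%+0%` <- function(a, b) if (is.null(a)) b else a + b

.cr3 <- function(x, p, cache, nm) {
  pre <- .conv3dForwardCpp(x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]])
  out <- .relu(pre)
  cache[[nm]] <- list(x = x, mask = pre > 0)
  list(out = out, cache = cache)
}

.cr3back <- function(dout, p, cache, nm, grads) {
  d <- dout * cache[[nm]]$mask
  g <- .conv3dBackwardCpp(cache[[nm]]$x, p[[paste0(nm, ".w")]], d)
  grads[[paste0(nm, ".w")]] <- grads[[paste0(nm, ".w")]] %+0% g$dw
  grads[[paste0(nm, ".b")]] <- grads[[paste0(nm, ".b")]] %+0% g$db
  list(dx = g$dx, grads = grads)
}

#' Network forward pass
#'
#' Runs the configured architecture on a batch. Inputs follow the package
#' layout: `xf` is the fluorescence stack (nFx, H, W, 1, N) and `xo` the
#' optical-property maps (H, W, 2, N), both already normalized.
#'
#' @param spec a [NetworkSpec-class].
#' @param xf fluorescence input array.
#' @param xo optics input array.
#' @param training enable dropout (and cache retention for backprop).
#' @return list with `depth` and `conc` (H, W, N) arrays and, when
#'   `training`, a `cache` for [networkBackward()].
#' @export
networkForward <- function(spec, xf, xo, training = FALSE) {
  if (spec@config$variant == "resnet")
    .resnetForward(spec, xf, xo, training)
  else
    .unetForward(spec, xf, xo, training)
}

#' Network backward pass
#'
#' Backpropagates loss gradients on the two output maps through the cached
#' forward pass.
#'
#' @param spec a [NetworkSpec-class].
#' @param fwd the list returned by [networkForward()] with `training=TRUE`.
#' @param dDepth,dConc gradients w.r.t. the output maps, (H, W, N).
#' @return named list of parameter gradients (same names as the spec's
#'   params).
#' @export
networkBackward <- function(spec, fwd, dDepth, dConc) {
  if (spec@config$variant == "resnet")
    .resnetBackward(spec, fwd, dDepth, dConc)
  else
    .unetBackward(spec, fwd, dDepth, dConc)
}

.resnetForward <- function(spec, xf, xo, training) {
  p <- spec@params
  cfg <- spec@config
  cache <- list()
  drop <- isTRUE(cfg$useDropout)
  # fluorescence branch (3D)
  s <- .cr3(xf, p, cache, "f.in"); h <- s$out; cache <- s$cache
  cache$m1 <- .dropMask(dim(h), cfg$dropoutRate, drop && training)
  h <- .applyMask(h, cache$m1)
  skip <- h
  s <- .cr3(h, p, cache, "f.res1"); h <- s$out; cache <- s$cache
  pre <- .conv3dForwardCpp(h, p$f.res2.w, p$f.res2.b)
  cache$f.res2 <- list(x = h)
  h <- pre + skip
  cache$f.resmask <- h > 0
  h <- .relu(h)
  h2 <- .collapse3d(h)
  s <- .cr2(h2, p, cache, "f.collapse"); fo <- s$out; cache <- s$cache
  # optics branch (2D)
  s <- .cr2(xo, p, cache, "o.in"); g <- s$out; cache <- s$cache
  cache$m2 <- .dropMask(dim(g), cfg$dropoutRate, drop && training)
  g <- .applyMask(g, cache$m2)
  skipo <- g
  s <- .cr2(g, p, cache, "o.res1"); g <- s$out; cache <- s$cache
  preo <- .conv2dForwardCpp(g, p$o.res2.w, p$o.res2.b)
  cache$o.res2 <- list(x = g)
  g <- preo + skipo
  cache$o.resmask <- g > 0
  g <- .relu(g)
  # concatenate and trunk
  dmf <- dim(fo); dmg <- dim(g)
  cat1 <- array(0, c(dmf[1], dmf[2], dmf[3] + dmg[3], dmf[4]))
  cat1[, , seq_len(dmf[3]), ] <- fo
  cat1[, , dmf[3] + seq_len(dmg[3]), ] <- g
  cache$catSplit <- dmf[3]
  skipt <- cat1
  s <- .cr2(cat1, p, cache, "t.res1"); h <- s$out; cache <- s$cache
  pret <- .conv2dForwardCpp(h, p$t.res2.w, p$t.res2.b)
  cache$t.res2 <- list(x = h)
  h <- pret + skipt
  cache$t.resmask1 <- h > 0
  h <- .relu(h)
  s <- .cr2(h, p, cache, "t.conv"); h <- s$out; cache <- s$cache
  skipt2 <- h
  s <- .cr2(h, p, cache, "t.res3"); h2 <- s$out; cache <- s$cache
  pret2 <- .conv2dForwardCpp(h2, p$t.res4.w, p$t.res4.b)
  cache$t.res4 <- list(x = h2)
  h <- pret2 + skipt2
  cache$t.resmask2 <- h > 0
  h <- .relu(h)
  # heads
  s <- .cr2(h, p, cache, "hd.conv"); hd <- s$out; cache <- s$cache
  outD <- .conv2dForwardCpp(hd, p$hd.out.w, p$hd.out.b)
  cache$hd.out <- list(x = hd)
  s <- .cr2(h, p, cache, "hc.conv"); hc <- s$out; cache <- s$cache
  outC <- .conv2dForwardCpp(hc, p$hc.out.w, p$hc.out.b)
  cache$hc.out <- list(x = hc)
  d <- dim(outD)
  res <- list(depth = array(outD, c(d[1], d[2], d[4])),
              conc = array(outC, c(d[1], d[2], d[4])))
  if (training) res$cache <- cache
  res
}

.resnetBackward <- function(spec, fwd, dDepth, dConc) {
  p <- spec@params
  cache <- fwd$cache
  grads <- list()
  d <- dim(cache$hd.out$x)
  dD <- array(dDepth, c(d[1], d[2], 1, d[4]))
  dC <- array(dConc, c(d[1], d[2], 1, d[4]))
  g <- .conv2dBackwardCpp(cache$hd.out$x, p$hd.out.w, dD)
  grads$hd.out.w <- g$dw; grads$hd.out.b <- g$db
  s <- .cr2back(g$dx, p, cache, "hd.conv", grads); dh1 <- s$dx; grads <- s$grads
  g <- .conv2dBackwardCpp(cache$hc.out$x, p$hc.out.w, dC)
  grads$hc.out.w <- g$dw; grads$hc.out.b <- g$db
  s <- .cr2back(g$dx, p, cache, "hc.conv", grads); dh2 <- s$dx; grads <- s$grads
  dh <- (dh1 + dh2) * cache$t.resmask2
  g <- .conv2dBackwardCpp(cache$t.res4$x, p$t.res4.w, dh)
  grads$t.res4.w <- g$dw; grads$t.res4.b <- g$db
  s <- .cr2back(g$dx, p, cache, "t.res3", grads); grads <- s$grads
  dh <- s$dx + dh  # residual skip
  s <- .cr2back(dh, p, cache, "t.conv", grads); dh <- s$dx; grads <- s$grads
  dh <- dh * cache$t.resmask1
  g <- .conv2dBackwardCpp(cache$t.res2$x, p$t.res2.w, dh)
  grads$t.res2.w <- g$dw; grads$t.res2.b <- g$db
  s <- .cr2back(g$dx, p, cache, "t.res1", grads); grads <- s$grads
  dcat <- s$dx + dh
  ns <- cache$catSplit
  dfo <- dcat[, , seq_len(ns), , drop = FALSE]
  dg <- dcat[, , (ns + 1):dim(dcat)[3], , drop = FALSE]
  # optics branch
  dg <- dg * cache$o.resmask
  g <- .conv2dBackwardCpp(cache$o.res2$x, p$o.res2.w, dg)
  grads$o.res2.w <- g$dw; grads$o.res2.b <- g$db
  s <- .cr2back(g$dx, p, cache, "o.res1", grads); grads <- s$grads
  dgi <- s$dx + dg
  dgi <- .applyMask(dgi, cache$m2)
  s <- .cr2back(dgi, p, cache, "o.in", grads); grads <- s$grads
  # fluorescence branch
  s <- .cr2back(dfo, p, cache, "f.collapse", grads); grads <- s$grads
  dh3 <- .uncollapse3d(s$dx, spec@config$nFx)
  dh3 <- dh3 * cache$f.resmask
  g <- .conv3dBackwardCpp(cache$f.res2$x, p$f.res2.w, dh3)
  grads$f.res2.w <- g$dw; grads$f.res2.b <- g$db
  s <- .cr3back(g$dx, p, cache, "f.res1", grads); grads <- s$grads
  dfi <- s$dx + dh3
  dfi <- .applyMask(dfi, cache$m1)
  s <- .cr3back(dfi, p, cache, "f.in", grads); grads <- s$grads
  grads
}

.attGateForward <- function(x, g, p, lvl, cache) {
  wg <- p[[sprintf("ag%d.wg.w", lvl)]]; bg <- p[[sprintf("ag%d.wg.b", lvl)]]
  wx <- p[[sprintf("ag%d.wx.w", lvl)]]
  wpsi <- p[[sprintf("ag%d.psi.w", lvl)]]; bpsi <- p[[sprintf("ag%d.psi.b", lvl)]]
  a1 <- .conv2dForwardCpp(g, wg, bg)
  a2 <- .conv2dForwardCpp(x, wx, numeric(dim(wx)[4]))
  s <- a1 + a2
  sm <- s > 0
  sr <- .relu(s)
  ps <- .conv2dForwardCpp(sr, wpsi, bpsi)
  att <- .sigmoid(ps)
  d <- dim(x)
  attb <- array(att[, , rep(1, d[3]), ], d)  # broadcast over channels
  out <- x * attb
  cache[[sprintf("ag%d", lvl)]] <- list(x = x, g = g, sm = sm, sr = sr,
                                        att = att)
  list(out = out, cache = cache)
}

.attGateBackward <- function(dout, p, lvl, cache, grads) {
  cc <- cache[[sprintf("ag%d", lvl)]]
  d <- dim(cc$x)
  att <- cc$att
  attb <- array(att[, , rep(1, d[3]), ], d)
  dx <- dout * attb
  datt <- apply(dout * cc$x, c(1, 2, 4), sum)
  dps <- array(datt, dim(att)) * att * (1 - att)
  wpsi <- p[[sprintf("ag%d.psi.w", lvl)]]
  g <- .conv2dBackwardCpp(cc$sr, wpsi, dps)
  grads[[sprintf("ag%d.psi.w", lvl)]] <- g$dw
  grads[[sprintf("ag%d.psi.b", lvl)]] <- g$db
  ds <- g$dx * cc$sm
  wg <- p[[sprintf("ag%d.wg.w", lvl)]]
  gg <- .conv2dBackwardCpp(cc$g, wg, ds)
  grads[[sprintf("ag%d.wg.w", lvl)]] <- gg$dw
  grads[[sprintf("ag%d.wg.b", lvl)]] <- gg$db
  wx <- p[[sprintf("ag%d.wx.w", lvl)]]
  gx <- .conv2dBackwardCpp(cc$x, wx, ds)
  grads[[sprintf("ag%d.wx.w", lvl)]] <- gx$dw
  dx <- dx + gx$dx
  list(dx = dx, dg = gg$dx, grads = grads)
}

.unetForward <- function(spec, xf, xo, training) {
  p <- spec@params
  cfg <- spec@config
  L <- length(cfg$encoderWidths)
  cache <- list()
  drop <- isTRUE(cfg$useDropout)
  s <- .cr3(xf, p, cache, "f.c1"); h <- s$out; cache <- s$cache
  cache$m1 <- .dropMask(dim(h), cfg$dropoutRate, drop && training)
  h <- .applyMask(h, cache$m1)
  s <- .cr3(h, p, cache, "f.c2"); h <- s$out; cache <- s$cache
  cache$m2 <- .dropMask(dim(h), cfg$dropoutRate, drop && training)
  h <- .applyMask(h, cache$m2)
  fo <- .collapse3d(h)
  s <- .cr2(xo, p, cache, "o.c1"); g <- s$out; cache <- s$cache
  cache$m3 <- .dropMask(dim(g), cfg$dropoutRate, drop && training)
  g <- .applyMask(g, cache$m3)
  s <- .cr2(g, p, cache, "o.c2"); g <- s$out; cache <- s$cache
  cache$m4 <- .dropMask(dim(g), cfg$dropoutRate, drop && training)
  g <- .applyMask(g, cache$m4)
  dmf <- dim(fo); dmg <- dim(g)
  x <- array(0, c(dmf[1], dmf[2], dmf[3] + dmg[3], dmf[4]))
  x[, , seq_len(dmf[3]), ] <- fo
  x[, , dmf[3] + seq_len(dmg[3]), ] <- g
  cache$catSplit <- dmf[3]
  enc <- vector("list", L)
  sizes <- vector("list", L)
  for (i in seq_len(L)) {
    s <- .cr2(x, p, cache, sprintf("enc%d.c1", i)); x <- s$out; cache <- s$cache
    s <- .cr2(x, p, cache, sprintf("enc%d.c2", i)); x <- s$out; cache <- s$cache
    enc[[i]] <- x
    sizes[[i]] <- dim(x)
    pl <- .maxpool2ForwardCpp(x)
    cache[[sprintf("pool%d", i)]] <- list(argmax = pl$argmax, xdim = dim(x))
    x <- pl$y
  }
  s <- .cr2(x, p, cache, "bott.c1"); x <- s$out; cache <- s$cache
  s <- .cr2(x, p, cache, "bott.c2"); x <- s$out; cache <- s$cache
  for (i in rev(seq_len(L))) {
    sz <- sizes[[i]]
    up <- .upsampleForwardCpp(x, sz[1], sz[2])
    cache[[sprintf("up%d", i)]] <- dim(x)
    s <- .attGateForward(enc[[i]], up, p, i, cache)
    xg <- s$out; cache <- s$cache
    dmx <- dim(xg); dmu <- dim(up)
    xx <- array(0, c(dmx[1], dmx[2], dmx[3] + dmu[3], dmx[4]))
    xx[, , seq_len(dmx[3]), ] <- xg
    xx[, , dmx[3] + seq_len(dmu[3]), ] <- up
    cache[[sprintf("dcat%d", i)]] <- dmx[3]
    s <- .cr2(xx, p, cache, sprintf("dec%d.c1", i)); x <- s$out; cache <- s$cache
    s <- .cr2(x, p, cache, sprintf("dec%d.c2", i)); x <- s$out; cache <- s$cache
  }
  s <- .cr2(x, p, cache, "hd.conv"); hd <- s$out; cache <- s$cache
  outD <- .conv2dForwardCpp(hd, p$hd.out.w, p$hd.out.b)
  cache$hd.out <- list(x = hd)
  s <- .cr2(x, p, cache, "hc.conv"); hc <- s$out; cache <- s$cache
  outC <- .conv2dForwardCpp(hc, p$hc.out.w, p$hc.out.b)
  cache$hc.out <- list(x = hc)
  d <- dim(outD)
  res <- list(depth = array(outD, c(d[1], d[2], d[4])),
              conc = array(outC, c(d[1], d[2], d[4])))
  if (training) res$cache <- cache
  res
}

.unetBackward <- function(spec, fwd, dDepth, dConc) {
  p <- spec@params
  cfg <- spec@config
  L <- length(cfg$encoderWidths)
  cache <- fwd$cache
  grads <- list()
  d <- dim(cache$hd.out$x)
  dD <- array(dDepth, c(d[1], d[2], 1, d[4]))
  dC <- array(dConc, c(d[1], d[2], 1, d[4]))
  g <- .conv2dBackwardCpp(cache$hd.out$x, p$hd.out.w, dD)
  grads$hd.out.w <- g$dw; grads$hd.out.b <- g$db
  s <- .cr2back(g$dx, p, cache, "hd.conv", grads); dx1 <- s$dx; grads <- s$grads
  g <- .conv2dBackwardCpp(cache$hc.out$x, p$hc.out.w, dC)
  grads$hc.out.w <- g$dw; grads$hc.out.b <- g$db
  s <- .cr2back(g$dx, p, cache, "hc.conv", grads); dx2 <- s$dx; grads <- s$grads
  dx <- dx1 + dx2
  dEnc <- vector("list", L)
  for (i in seq_len(L)) {  # decoder levels, finest first
    s <- .cr2back(dx, p, cache, sprintf("dec%d.c2", i), grads)
    grads <- s$grads
    s <- .cr2back(s$dx, p, cache, sprintf("dec%d.c1", i), grads)
    grads <- s$grads
    ns <- cache[[sprintf("dcat%d", i)]]
    dxx <- s$dx
    dxg <- dxx[, , seq_len(ns), , drop = FALSE]
    dup <- dxx[, , (ns + 1):dim(dxx)[3], , drop = FALSE]
    s <- .attGateBackward(dxg, p, i, cache, grads)
    grads <- s$grads
    dEnc[[i]] <- s$dx
    dup <- dup + s$dg
    dx <- .upsampleBackwardCpp(dup, cache[[sprintf("up%d", i)]])
  }
  s <- .cr2back(dx, p, cache, "bott.c2", grads); grads <- s$grads
  s <- .cr2back(s$dx, p, cache, "bott.c1", grads); grads <- s$grads
  dx <- s$dx
  for (i in rev(seq_len(L))) {  # encoder levels, coarsest first
    pl <- cache[[sprintf("pool%d", i)]]
    dx <- .maxpool2BackwardCpp(dx, pl$argmax, pl$xdim)
    dx <- dx + dEnc[[i]]
    s <- .cr2back(dx, p, cache, sprintf("enc%d.c2", i), grads); grads <- s$grads
    s <- .cr2back(s$dx, p, cache, sprintf("enc%d.c1", i), grads); grads <- s$grads
    dx <- s$dx
  }
  ns <- cache$catSplit
  dfo <- dx[, , seq_len(ns), , drop = FALSE]
  dg <- dx[, , (ns + 1):dim(dx)[3], , drop = FALSE]
  dg <- .applyMask(dg, cache$m4)
  s <- .cr2back(dg, p, cache, "o.c2", grads); grads <- s$grads
  dgi <- .applyMask(s$dx, cache$m3)
  s <- .cr2back(dgi, p, cache, "o.c1", grads); grads <- s$grads
  dh <- .uncollapse3d(dfo, cfg$nFx)
  dh <- .applyMask(dh, cache$m2)
  s <- .cr3back(dh, p, cache, "f.c2", grads); grads <- s$grads
  dfi <- .applyMask(s$dx, cache$m1)
  s <- .cr3back(dfi, p, cache, "f.c1", grads); grads <- s$grads
  grads
}

#' Save / load a model checkpoint
#'
#' Round-trippable single-file weight archive embedding the configuration.
#'
#' @param spec a [NetworkSpec-class].
#' @param path file path.
#' @return `loadCheckpoint` returns the restored [NetworkSpec-class].
#' @export
saveCheckpoint <- function(spec, path) {
  obj <- list(config = spec@config, params = spec@params,
              norm = attr(spec, "norm"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  spec <- new("NetworkSpec", config = obj$config, params = obj$params,
              parameterCount = sum(vapply(obj$params, length, numeric(1))))
  if (!is.null(obj$norm)) attr(spec, "norm") <- obj$norm
  spec
}
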