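# Measured-data processing: three-phase demodulation, reference
# calibration, and two-frequency lookup-table inversion of diffuse
# reflectance into optical-property maps.

#' Three-phase amplitude demodulation
#'
#' Recovers the AC modulation amplitude and DC level from three frames
#' acquired at phase shifts 0, 120 and 240 degrees:
#' AC = (sqrt(2)/3) sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2),
#' DC = (I1+I2+I3)/3. Exact (to machine precision) for a pure sinusoidal
#' pattern and invariant to a global phase offset.
#'
#' @param i1,i2,i3 intensity images (matrices) at the three phases.
#' @return list with `ac` and `dc` matrices.
#' @examples
#' x <- outer(rep(1, 8), seq(0, 2 * pi, length.out = 8))
#' frames <- lapply(c(0, 2, 4) * pi / 3, function(p) 10 * (1 + 0.5 * cos(x + p)))
#' d <- demodulate(frames[[1]], frames[[2]], frames[[3]])
#' max(abs(d$ac - 5))  # ~ 1e-15
#' @export
demodulate <- function(i1, i2, i3) {
  if (!identical(dim(i1), dim(i2)) || !identical(dim(i2), dim(i3)))
    stop("phase frames must share a shape")
  ac <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
  dc <- (i1 + i2 + i3) / 3
  list(ac = ac, dc = dc)
}

#' Reference-phantom reflectance calibration
#'
#' Converts a demodulated sample amplitude image into calibrated diffuse
#' reflectance using a reference phantom of known optical properties imaged
#' under the same illumination:
#' Rd = (AC_sample / AC_reference) * Rd_model(reference).
#'
#' @param acSample demodulated sample amplitude image.
#' @param acReference demodulated reference amplitude image (same shape).
#' @param referenceOp c(muA, muSp) of the reference phantom, 1/mm.
#' @param fx spatial frequency of the acquisition, 1/mm.
#' @param A internal-reflection parameter.
#' @return calibrated reflectance image; pixels where the reference is zero
#'   are set NA with a warning.
#' @export
calibrateReflectance <- function(acSample, acReference, referenceOp, fx,
                                 A = aParameter()) {
  stopifnot(identical(dim(acSample), dim(acReference)), length(referenceOp) == 2)
  rdModel <- analyticRd(referenceOp[1], referenceOp[2], fx, A)
  bad <- acReference == 0
  if (any(bad)) {
    warning(sum(bad), " zero-valued reference pixels masked")
    acReference[bad] <- NA_real_
  }
  acSample / acReference * rdModel
}

#' Build a two-frequency reflectance lookup table
#'
#' Tabulates the model diffuse reflectance pair (Rd(fx1), Rd(fx2)) on a
#' rectangular (muA, muSp') grid via the closed-form homogeneous model
#' ([analyticRd()]). The default frequency pair is (0, 0.2) /mm and the
#' default ranges span the training optical-property domain.
#'
#' @param muARange,muSpRange (min, max) table ranges, 1/mm.
#' @param resolution nodes per axis (default 64).
#' @param fxPair the two spatial frequencies, 1/mm.
#' @param A internal-reflection parameter.
#' @return a [LUTGrid-class].
#' @examples
#' lut <- buildLUT(resolution = 16)
#' @export
buildLUT <- function(muARange = c(0.0015, 0.015), muSpRange = c(0.75, 2),
                     resolution = 64L, fxPair = c(0, 0.2),
                     A = aParameter()) {
  stopifnot(all(muARange > 0), all(muSpRange > 0), resolution >= 2L,
            length(fxPair) == 2L)
  muAs <- seq(muARange[1], muARange[2], length.out = resolution)
  muSps <- seq(muSpRange[1], muSpRange[2], length.out = resolution)
  rd1 <- outer(muAs, muSps, function(a, s) analyticRd(a, s, fxPair[1], A))
  rd2 <- outer(muAs, muSps, function(a, s) analyticRd(a, s, fxPair[2], A))
  new("LUTGrid", muAGrid = muAs, muSpGrid = muSps, rd1 = rd1, rd2 = rd2,
      fxPair = fxPair, A = A)
}

#' Invert reflectance pairs into optical-property maps
#'
#' Per pixel, finds the (muA, muSp') minimizing the Euclidean distance to
#' the measured (Rd1, Rd2) pair in normalized reflectance space (each axis
#' scaled by its table dynamic range), then refines below the node spacing
#' by a bilinear sub-grid search around the best node. Out-of-gamut pixels
#' are clamped to the nearest boundary node and flagged in the validity
#' mask. Equidistant ties break toward lower muA, then lower muSp'.
#'
#' @param rd1Map,rd2Map reflectance images at the table's two frequencies.
#' @param lut a [LUTGrid-class].
#' @param subdivision sub-grid refinement factor per cell (default 10).
#' @return an [OPMaps-class].
#' @export
invertOpticalProperties <- function(rd1Map, rd2Map, lut, subdivision = 10L) {
  if (!identical(dim(rd1Map), dim(rd2Map)))
    stop("reflectance maps must share a shape")
  if (length(lut@muAGrid) < 2L) stop("empty or degenerate lookup table")
  if (diff(range(lut@rd1)) <= 0 || diff(range(lut@rd2)) <= 0)
    stop("degenerate lookup table: reflectance has no dynamic range")
  # invert only the distinct reflectance pairs (images of homogeneous
  # scenes collapse to a handful)
  key <- paste(rd1Map, rd2Map)
  ui <- which(!duplicated(key))
  back <- match(key, key[ui])
  if (length(ui) < length(rd1Map)) {
    sub <- invertOpticalProperties(matrix(rd1Map[ui], ncol = 1),
                                   matrix(rd2Map[ui], ncol = 1),
                                   lut, subdivision)
    dm <- dim(rd1Map)
    return(new("OPMaps",
               muA = matrix(sub@muA[back], dm[1], dm[2]),
               muSp = matrix(sub@muSp[back], dm[1], dm[2]),
               valid = matrix(sub@valid[back], dm[1], dm[2])))
  }
  s1 <- diff(range(lut@rd1)); s2 <- diff(range(lut@rd2))
  nA <- length(lut@muAGrid); nS <- length(lut@muSpGrid)
  n <- length(rd1Map)
  t1 <- as.numeric(lut@rd1) / s1
  t2 <- as.numeric(lut@rd2) / s2
  q1 <- as.numeric(rd1Map) / s1
  q2 <- as.numeric(rd2Map) / s2
  muA <- numeric(n); muSp <- numeric(n); valid <- logical(n)
  # coarse pass: nearest node (ties -> first index = lower muA then lower muSp
  # because the grid is column-major in muA)
  d2 <- outer(t1, q1, function(a, b) (a - b)^2) +
    outer(t2, q2, function(a, b) (a - b)^2)
  best <- max.col(-t(d2), ties.method = "first")
  iA <- ((best - 1L) %% nA) + 1L
  iS <- ((best - 1L) %/% nA) + 1L
  onEdge <- iA == 1L | iA == nA | iS == 1L | iS == nS
  # refine: bilinear interpolation of the table on a fine sub-grid spanning
  # the 2x2 cell neighbourhood of the best node
  sub <- subdivision
  for (p in seq_len(n)) {
    a0 <- max(1L, iA[p] - 1L); a1 <- min(nA, iA[p] + 1L)
    s0 <- max(1L, iS[p] - 1L); s1i <- min(nS, iS[p] + 1L)
    ua <- seq(a0, a1, length.out = (a1 - a0) * sub + 1L)
    us <- seq(s0, s1i, length.out = (s1i - s0) * sub + 1L)
    fa <- floor(ua); fa[fa == nA] <- nA - 1L; wa <- ua - fa
    fs <- floor(us); fs[fs == nS] <- nS - 1L; ws <- us - fs
    # bilinear table values on the sub-grid
    g11 <- lut@rd1[cbind(rep(fa, length(us)), rep(fs, each = length(ua)))]
    g21 <- lut@rd1[cbind(rep(fa + 1L, length(us)), rep(fs, each = length(ua)))]
    g12 <- lut@rd1[cbind(rep(fa, length(us)), rep(fs + 1L, each = length(ua)))]
    g22 <- lut@rd1[cbind(rep(fa + 1L, length(us)), rep(fs + 1L, each = length(ua)))]
    WA <- rep(wa, length(us)); WS <- rep(ws, each = length(ua))
    v1 <- (1 - WA) * (1 - WS) * g11 + WA * (1 - WS) * g21 +
      (1 - WA) * WS * g12 + WA * WS * g22
    h11 <- lut@rd2[cbind(rep(fa, length(us)), rep(fs, each = length(ua)))]
    h21 <- lut@rd2[cbind(rep(fa + 1L, length(us)), rep(fs, each = length(ua)))]
    h12 <- lut@rd2[cbind(rep(fa, length(us)), rep(fs + 1L, each = length(ua)))]
    h22 <- lut@rd2[cbind(rep(fa + 1L, length(us)), rep(fs + 1L, each = length(ua)))]
    v2 <- (1 - WA) * (1 - WS) * h11 + WA * (1 - WS) * h21 +
      (1 - WA) * WS * h12 + WA * WS * h22
    dd <- (v1 / s1 - q1[p])^2 + (v2 / s2 - q2[p])^2
    k <- which.min(dd)
    uaK <- ua[((k - 1L) %% length(ua)) + 1L]
    usK <- us[((k - 1L) %/% length(ua)) + 1L]
    muA[p] <- lut@muAGrid[1] + (uaK - 1) * diff(lut@muAGrid[1:2])
    muSp[p] <- lut@muSpGrid[1] + (usK - 1) * diff(lut@muSpGrid[1:2])
    valid[p] <- !(onEdge[p] &&
                    (uaK %in% c(1, nA) || usK %in% c(1, nS)))
  }
  dm <- dim(rd1Map)
  new("OPMaps", muA = matrix(muA, dm[1], dm[2]),
      muSp = matrix(muSp, dm[1], dm[2]),
      valid = matrix(valid, dm[1], dm[2]))
}
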