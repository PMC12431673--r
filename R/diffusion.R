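# Diffusion-approximation light transport in the spatial frequency domain.
#
# The steady-state diffusion equation with the (2*pi*fx)^2 frequency-modified
# absorption is discretized on the scene voxel grid (7-point finite
# differences, cell-centered). The top surface carries a Robin
# (partial-current) boundary with internal-reflection parameter A; lateral
# and bottom boundaries are zero-flux, with the scene padded by background
# tissue so they sit far from the field of view. Two solver backends share
# the discretization: a spectral path for homogeneous coefficients (lateral
# cosine modes via mirrored FFT, one tridiagonal solve in depth per mode)
# and a general sparse-Cholesky path for per-voxel coefficients.

#' Default spatial-frequency set
#'
#' The six projection frequencies used throughout: 0 to 0.25 /mm in steps
#' of 0.05.
#'
#' @return numeric vector of spatial frequencies, 1/mm.
#' @export
fxDefault <- function() c(0, 0.05, 0.1, 0.15, 0.2, 0.25)

#' Internal-reflection boundary parameter
#'
#' Dimensionless Robin boundary parameter A = (1 + Reff) / (1 - Reff) with
#' the effective reflection coefficient Reff from the Groenhuis polynomial
#' fit in the tissue refractive index.
#'
#' @param nIndex tissue refractive index (default 1.4).
#' @return the boundary parameter A.
#' @examples
#' aParameter()       # about 3.25 for n = 1.4
#' aParameter(1.0)    # 1 for a matched boundary... close to it
#' @export
aParameter <- function(nIndex = 1.4) {
  reff <- -1.440 / nIndex^2 + 0.710 / nIndex + 0.668 + 0.0636 * nIndex
  (1 + reff) / (1 - reff)
}

#' Frequency-dependent effective attenuation
#'
#' mueff'(fx) = sqrt(3 muA (muA + muSp') + (2 pi fx)^2), the decay constant
#' of the modulation envelope at spatial frequency fx.
#'
#' @param muA absorption coefficient, 1/mm.
#' @param muSp reduced scattering coefficient, 1/mm.
#' @param fx spatial frequency, 1/mm.
#' @return effective attenuation, 1/mm.
#' @export
effectiveAttenuation <- function(muA, muSp, fx) {
  sqrt(3 * muA * (muA + muSp) + (2 * pi * fx)^2)
}

#' Closed-form homogeneous diffuse reflectance
#'
#' Semi-infinite diffusion-approximation diffuse reflectance at spatial
#' frequency fx for a collimated beam reduced to a plane source buried at
#' one transport mean free path, with a partial-current boundary. Serves as
#' the independent oracle for the numerical solver and as the forward model
#' behind the optical-property lookup tables.
#'
#' @param muA absorption coefficient, 1/mm (vectorized).
#' @param muSp reduced scattering coefficient, 1/mm.
#' @param fx spatial frequency, 1/mm.
#' @param A internal-reflection parameter; default from [aParameter()].
#' @return diffuse reflectance (unitless, in (0, 1) for tissue-like inputs).
#' @examples
#' analyticRd(0.0045, 1.0, fxDefault())
#' @export
analyticRd <- function(muA, muSp, fx, A = aParameter()) {
  stopifnot(all(muA > 0), all(muSp > 0), all(fx >= 0))
  mut <- muA + muSp
  D <- 1 / (3 * mut)
  mue <- effectiveAttenuation(muA, muSp, fx)
  z0 <- 1 / mut
  gam <- (1 - 2 * A * D * mue) / (1 + 2 * A * D * mue)
  # fluence at the boundary for a unit plane source at z0, divided by 2A
  exp(-mue * z0) * (1 - gam) / (4 * A * D * mue)
}

# ---- solver internals ------------------------------------------------------

# Homogeneous-coefficient FD solve of  -D lap(phi) + mu phi = S  on a
# (ny, nx, nz) cell-centered grid; Robin top, Neumann elsewhere. Spectral
# in the lateral plane (mirrored FFT = Neumann modes), tridiagonal in z;
# identical discretization to the sparse path. Implemented in C++.
.fdSolveHomogeneous <- function(S, D, mu, dx, dz, A) {
  .fdSpectralSolveCpp(S, D, mu, dx, dz, A)
}

# 1D specialization (laterally uniform source in a homogeneous medium)
.fdSolve1D <- function(Sz, D, mu, dz, A) {
  nz <- length(Sz)
  robin <- (2 * D / dz^2) / (1 + 4 * A * D / dz)
  b <- rep(mu + 2 * D / dz^2, nz)
  b[1] <- mu + D / dz^2 + robin
  b[nz] <- mu + D / dz^2
  off <- -D / dz^2
  cp <- numeric(nz); dp <- numeric(nz)
  cp[1] <- off / b[1]; dp[1] <- Sz[1] / b[1]
  for (i in 2:nz) {
    den <- b[i] - off * cp[i - 1]
    cp[i] <- off / den
    dp[i] <- (Sz[i] - off * dp[i - 1]) / den
  }
  x <- numeric(nz)
  x[nz] <- dp[nz]
  for (i in (nz - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# General sparse path: per-voxel D and mu (arrays shaped like S).
.fdSolveSparse <- function(S, Dv, muv, dx, dz, A) {
  dm <- dim(S)
  ny <- dm[1]; nx <- dm[2]; nz <- dm[3]
  n <- ny * nx * nz
  idx <- function(j, i, k) j + ny * (i - 1) + ny * nx * (k - 1)
  hmean <- function(a, b) 2 * a * b / (a + b)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diagv <- as.numeric(muv)
  addFace <- function(from, to, w) {
    ii <<- c(ii, from, to); jj <<- c(jj, to, from); vv <<- c(vv, -w, -w)
    diagv[from] <<- diagv[from] + w
    diagv[to] <<- diagv[to] + w
  }
  grid <- array(seq_len(n), dm)
  # y faces
  if (ny > 1) {
    from <- as.vector(grid[-ny, , , drop = FALSE])
    to <- as.vector(grid[-1, , , drop = FALSE])
    addFace(from, to, hmean(Dv[from], Dv[to]) / dx^2)
  }
  if (nx > 1) {
    from <- as.vector(grid[, -nx, , drop = FALSE])
    to <- as.vector(grid[, -1, , drop = FALSE])
    addFace(from, to, hmean(Dv[from], Dv[to]) / dx^2)
  }
  if (nz > 1) {
    from <- as.vector(grid[, , -nz, drop = FALSE])
    to <- as.vector(grid[, , -1, drop = FALSE])
    addFace(from, to, hmean(Dv[from], Dv[to]) / dz^2)
  }
  top <- as.vector(grid[, , 1, drop = FALSE])
  Dtop <- Dv[top]
  diagv[top] <- diagv[top] + (2 * Dtop / dz^2) / (1 + 4 * A * Dtop / dz)
  M <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(vv, diagv), dims = c(n, n))
  phi <- Matrix::solve(M, as.numeric(S))
  array(as.numeric(phi), dm)
}

# ---- scene-facing API ------------------------------------------------------

.isHomogeneous <- function(scene) {
  length(scene@muA) == 1L && length(scene@muSp) == 1L
}

# geometry of the padded, z-refined solver grid
.solveGeometry <- function(scene, zrefine, padMm, bottomPadMm = padMm) {
  g <- scene@grid
  np <- ceiling(padMm / g@dx)
  dzr <- g@dz / zrefine
  nzr <- g@nz * zrefine + ceiling(bottomPadMm / dzr)
  list(np = np, dzr = dzr, nzr = nzr,
       ny = g@ny + 2L * np, nx = g@nx + 2L * np,
       coreY = np + seq_len(g@ny), coreX = np + seq_len(g@nx),
       coreZ = seq_len(g@nz * zrefine))
}

# delta plane source at depth z0 (mm), apportioned between the two nearest
# cell centers; per-volume density so the depth-integrated strength is 1.
.planeSourceZ <- function(z0, dzr, nzr) {
  Sz <- numeric(nzr)
  ic <- z0 / dzr - 0.5
  i0 <- max(0L, floor(ic))
  w <- ic - i0
  Sz[i0 + 1L] <- (1 - w) / dzr
  if (i0 + 2L <= nzr) Sz[i0 + 2L] <- w / dzr
  Sz
}

#' Solve the excitation diffusion problem
#'
#' Steady-state excitation fluence for planar patterned illumination at one
#' spatial frequency, with the frequency entering through the modified
#' absorption muA + (2 pi fx)^2 D. The illumination is reduced to a diffuse
#' plane source buried at one transport mean free path; incident power is
#' normalized to one per unit area.
#'
#' @param scene a [TissueScene-class].
#' @param fx spatial frequency, 1/mm.
#' @param zrefine integer depth-refinement factor of the solver grid
#'   relative to the scene grid (default 4; the scratch discretization
#'   study behind the default is described in the methods vignette).
#' @param padMm background padding added laterally and below, mm.
#' @return list with `phi` (fluence on the padded refined grid,
#'   ny x nx x nz), `geom` (grid bookkeeping), and `homogeneous` flag.
#' @export
solveExcitation <- function(scene, fx, zrefine = 4L, padMm = 10) {
  stopifnot(fx >= 0)
  geo <- .solveGeometry(scene, zrefine, padMm)
  if (.isHomogeneous(scene)) {
    mut <- scene@muA + scene@muSp
    D <- 1 / (3 * mut)
    mu <- scene@muA + (2 * pi * fx)^2 * D
    Sz <- .planeSourceZ(1 / mut, geo$dzr, geo$nzr)
    prof <- .fdSolve1D(Sz, D, mu, geo$dzr, aParameter())
    phi <- array(rep(prof, each = geo$ny * geo$nx), c(geo$ny, geo$nx, geo$nzr))
    return(list(phi = phi, profile = prof, geom = geo, homogeneous = TRUE,
                D = D, fx = fx))
  }
  vol <- .expandCoefficients(scene, geo, zrefine)
  Dv <- 1 / (3 * (vol$muA + vol$muSp))
  muv <- vol$muA + (2 * pi * fx)^2 * Dv
  mutBar <- mean(vol$muA + vol$muSp)
  Sz <- .planeSourceZ(1 / mutBar, geo$dzr, geo$nzr)
  S <- array(rep(Sz, each = geo$ny * geo$nx), c(geo$ny, geo$nx, geo$nzr))
  phi <- .fdSolveSparse(S, Dv, muv, scene@grid@dx, geo$dzr, aParameter())
  list(phi = phi, geom = geo, homogeneous = FALSE, D = Dv, fx = fx)
}

# per-voxel coefficient arrays on the padded refined grid
.expandCoefficients <- function(scene, geo, zrefine) {
  g <- scene@grid
  expand <- function(x) {
    if (length(x) == 1L) return(array(x, c(geo$ny, geo$nx, geo$nzr)))
    full <- array(NA_real_, c(geo$ny, geo$nx, geo$nzr))
    zz <- rep(seq_len(g@nz), each = zrefine)
    core <- x[, , zz, drop = FALSE]
    bg <- x[1, 1, g@nz]  # padding inherits the deep-corner background value
    full[] <- bg
    full[geo$coreY, geo$coreX, geo$coreZ] <- core
    full
  }
  list(muA = expand(if (length(scene@muA) == 1L) scene@muA else scene@muA),
       muSp = expand(scene@muSp))
}

# outgoing partial current per pixel from the top fluence layer
.surfaceFlux <- function(phiTop, D, dz, A) {
  face <- phiTop * (4 * A * D / dz) / (1 + 4 * A * D / dz)
  face / (2 * A)
}

#' Simulate an SFDI acquisition of a tissue scene
#'
#' For each spatial frequency, solves the excitation problem to produce the
#' diffuse reflectance image, builds the fluorescence emission source
#' q = eta * gamma * C * phi_x, and propagates it to the surface with a
#' second diffusion solve at the same frequency (emission optical
#' properties default to the excitation values; single-wavelength
#' simulation). Images are the surface partial currents per unit incident
#' power, cropped to the scene field of view.
#'
#' @param scene a [TissueScene-class].
#' @param fx spatial-frequency vector (default [fxDefault()]).
#' @param zrefine depth-refinement factor for the solver grid (default 4).
#' @param padMm background padding in mm (default 10).
#' @param gamma concentration-to-absorption calibration constant,
#'   1/mm per ug/ml. The default 1e-5 keeps gamma * C far below muA, so
#'   fluorophore absorption is negligible and the fluorescence stack is
#'   linear in the concentration field.
#' @param noiseSD optional additive Gaussian noise amplitude (fraction of
#'   each image's maximum; 0 disables, the default).
#' @return an [SFDIStack-class].
#' @examples
#' sc <- exampleScene(nx = 21, nz = 24)
#' stk <- simulateStack(sc, fx = c(0, 0.1), zrefine = 2)
#' @export
simulateStack <- function(scene, fx = fxDefault(), zrefine = 4L, padMm = 10,
                          gamma = 1e-5, noiseSD = 0) {
  g <- scene@grid
  A <- aParameter()
  nf <- length(fx)
  refl <- array(0, c(g@ny, g@nx, nf))
  fluo <- array(0, c(g@ny, g@nx, nf))
  geo <- .solveGeometry(scene, zrefine, padMm)
  # concentration field on the refined padded grid
  zz <- rep(seq_len(g@nz), each = zrefine)
  Cfull <- array(scene@cBackground, c(geo$ny, geo$nx, geo$nzr))
  maskZ <- scene@tumorMask[, , zz, drop = FALSE]
  Ccore <- array(scene@cBackground, dim(maskZ))
  Ccore[maskZ] <- scene@cTumor
  Cfull[geo$coreY, geo$coreX, geo$coreZ] <- Ccore
  hom <- .isHomogeneous(scene)
  for (i in seq_len(nf)) {
    ex <- solveExcitation(scene, fx[i], zrefine = zrefine, padMm = padMm)
    if (hom) {
      D <- ex$D
      rd <- .surfaceFlux(ex$profile[1], D, geo$dzr, A)
      refl[, , i] <- rd
      q <- scene@eta * gamma * Cfull *
        array(rep(ex$profile, each = geo$ny * geo$nx), c(geo$ny, geo$nx, geo$nzr))
      mu <- scene@muA + (2 * pi * fx[i])^2 * D
      phim <- .fdSolveHomogeneous(q, D, mu, g@dx, geo$dzr, A)
      fl <- .surfaceFlux(phim[, , 1], D, geo$dzr, A)
    } else {
      Dtop <- ex$D[, , 1]
      refl[, , i] <- .surfaceFlux(ex$phi[, , 1], Dtop, geo$dzr, A)[geo$coreY, geo$coreX]
      q <- scene@eta * gamma * Cfull * ex$phi
      vol <- .expandCoefficients(scene, geo, zrefine)
      Dv <- 1 / (3 * (vol$muA + vol$muSp))
      muv <- vol$muA + (2 * pi * fx[i])^2 * Dv
      phim <- .fdSolveSparse(q, Dv, muv, g@dx, geo$dzr, A)
      fl <- .surfaceFlux(phim[, , 1], Dv[, , 1], geo$dzr, A)
    }
    fluo[, , i] <- fl[geo$coreY, geo$coreX]
  }
  if (noiseSD > 0) {
    refl <- pmax(refl + stats::rnorm(length(refl), sd = noiseSD * max(refl)), 0)
    fluo <- pmax(fluo + stats::rnorm(length(fluo), sd = noiseSD * max(fluo)), 0)
  }
  new("SFDIStack", reflectance = refl, fluorescence = fluo, fx = fx,
      pixelSize = g@dx)
}

#' A small homogeneous example scene
#'
#' Convenience constructor for examples and tests: a buried cuboid tumor in
#' homogeneous tissue.
#'
#' @param nx,nz grid size (lateral count also used for ny).
#' @param dx,dz voxel pitches, mm.
#' @param muA,muSp background optical properties, 1/mm.
#' @param topDepth tumor top-face depth, mm.
#' @param size lateral half-width of the cuboid in voxels.
#' @param thickness tumor thickness in voxels.
#' @param cTumor,cBackground fluorophore concentrations, ug/ml.
#' @return a [TissueScene-class].
#' @export
exampleScene <- function(nx = 33L, nz = 40L, dx = 0.5, dz = 0.5,
                         muA = 0.0045, muSp = 1.0, topDepth = 3,
                         size = 6L, thickness = 8L,
                         cTumor = 5, cBackground = 0.5) {
  g <- voxelGrid(nx = nx, ny = nx, nz = nz, dx = dx, dz = dz)
  mask <- array(FALSE, c(g@ny, g@nx, g@nz))
  cy <- ceiling(g@ny / 2); cx <- ceiling(g@nx / 2)
  k0 <- round(topDepth / dz) + 1L
  mask[(cy - size):(cy + size), (cx - size):(cx + size),
       k0:min(g@nz, k0 + thickness - 1L)] <- TRUE
  new("TissueScene", grid = g, tumorMask = mask, muA = muA, muSp = muSp,
      cTumor = cTumor, cBackground = cBackground, eta = 0.046)
}
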