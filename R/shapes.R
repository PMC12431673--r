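# Synthetic tumor geometry: composite-spherical-harmonic (CSH) shapes,
# triangle-mesh voxelization, scene assembly and ground-truth maps.

# real-form spherical harmonic magnitude envelope: row m of the associated
# Legendre table, scaled later by its maximum so the perturbation amplitude
# has a fixed meaning across (l, m)
.assocLegendreRow <- function(l, m, x) {
  P <- pracma::legendre(l, x)
  if (is.null(dim(P))) P <- matrix(P, ncol = length(x))
  P[m + 1L, ]
}

.maxAbsLegendre <- function(l, m) {
  ct <- cos(seq(0, pi, length.out = 721))
  max(abs(.assocLegendreRow(l, m, ct)))
}

# one star-convex harmonic body in unit space: radius r(theta, phi) =
# 1 + a * Ybar, |Ybar| <= 1
.sampleComponent <- function(params) {
  lo <- params@orderDegreeRange[1]; hi <- params@orderDegreeRange[2]
  l <- sample(lo:hi, 1L)
  m <- sample(lo:l, 1L)
  list(l = l, m = m,
       a = stats::runif(1, params@amplitudeRange[1], params@amplitudeRange[2]),
       form = sample(c("cos", "sin"), 1L),
       phase = stats::runif(1, 0, 2 * pi),
       maxP = .maxAbsLegendre(l, m))
}

.insideComponent <- function(px, py, pz, comp) {
  r <- sqrt(px^2 + py^2 + pz^2)
  ct <- ifelse(r > 0, pmin(1, pmax(-1, pz / r)), 1)
  P <- .assocLegendreRow(comp$l, comp$m, ct)
  ang <- comp$m * atan2(py, px) + comp$phase
  Y <- P / comp$maxP * if (comp$form == "cos") cos(ang) else sin(ang)
  r <= 1 + comp$a * Y
}

# surface point cloud of one component on a dense angular grid
.componentSurface <- function(comp, nTheta = 121L, nPhi = 181L) {
  th <- seq(0, pi, length.out = nTheta)
  ph <- seq(0, 2 * pi, length.out = nPhi)
  P <- .assocLegendreRow(comp$l, comp$m, cos(th)) / comp$maxP
  ang <- outer(rep(1, nTheta), comp$m * ph + comp$phase)
  Y <- P * if (comp$form == "cos") cos(ang) else sin(ang)
  r <- 1 + comp$a * Y                      # (nTheta, nPhi)
  st <- sin(th); ct <- cos(th)
  list(x = as.vector(r * outer(st, cos(ph))),
       y = as.vector(r * outer(st, sin(ph))),
       z = as.vector(r * outer(ct, rep(1, nPhi))))
}

.insideUnion <- function(px, py, pz, comps, offsets) {
  inside <- rep(FALSE, length(px))
  for (k in seq_along(comps)) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- .insideComponent(px[todo] - offsets[k, 1],
                                     py[todo] - offsets[k, 2],
                                     pz[todo] - offsets[k, 3],
                                     comps[[k]])
  }
  inside
}

# 6-connectivity check by iterative frontier dilation
.isConnected <- function(mask) {
  n <- sum(mask)
  if (n == 0L) return(FALSE)
  lab <- array(FALSE, dim(mask))
  seed <- which(mask)[1]
  lab[seed] <- TRUE
  repeat {
    grown <- lab
    grown[-1, , ] <- grown[-1, , ] | lab[-dim(lab)[1], , ]
    grown[-dim(lab)[1], , ] <- grown[-dim(lab)[1], , ] | lab[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | lab[, -dim(lab)[2], ]
    grown[, -dim(lab)[2], ] <- grown[, -dim(lab)[2], ] | lab[, -1, ]
    grown[, , -1] <- grown[, , -1] | lab[, , -dim(lab)[3]]
    grown[, , -dim(lab)[3]] <- grown[, , -dim(lab)[3]] | lab[, , -1]
    grown <- grown & mask
    if (sum(grown) == sum(lab)) break
    lab <- grown
  }
  sum(lab) == n
}

#' Generate a composite-spherical-harmonic tumor mask
#'
#' Builds a synthetic tumor shape as the voxel-space union of several
#' star-convex spherical-harmonic bodies, r(theta, phi) = r0 (1 + a Ybar),
#' with randomized degree/order, perturbation amplitude and lateral
#' offsets. The union is rescaled so its maximum lateral extent equals the
#' sampled width and its axial extent the sampled height, then translated
#' so the shallowest voxel sits at the sampled top depth. Offsets are
#' resampled (up to `retries` times) until the union is 6-connected.
#'
#' @param params a [CSHParams-class]; `seed` fixes all random draws.
#' @param grid the target [VoxelGrid-class].
#' @param seed RNG seed (integer) for reproducible shapes.
#' @param retries resampling cap for the connectivity constraint.
#' @return logical array (ny, nx, nz); TRUE inside the tumor.
#' @examples
#' m <- generateCSHMask(cshParams(), voxelGrid(), seed = 7)
#' sum(m) > 0
#' @export
generateCSHMask <- function(params, grid, seed = NULL, retries = 20L) {
  stopifnot(is(params, "CSHParams"), is(grid, "VoxelGrid"))
  if (!is.null(seed)) set.seed(seed)
  W <- stats::runif(1, params@widthRange[1], params@widthRange[2])
  Hgt <- stats::runif(1, params@heightRange[1], params@heightRange[2])
  dTop <- stats::runif(1, params@topDepthRange[1], params@topDepthRange[2])
  if (W > grid@nx * grid@dx || W > grid@ny * grid@dx)
    stop("sampled width ", signif(W, 3), " mm exceeds the lateral grid (x/y)")
  if (dTop + Hgt > grid@nz * grid@dz)
    stop("sampled top depth + height ", signif(dTop + Hgt, 3),
         " mm exceeds the grid depth (z)")
  comps <- replicate(params@nComponents, .sampleComponent(params),
                     simplify = FALSE)
  for (try in seq_len(retries)) {
    offsets <- cbind(stats::runif(params@nComponents, -0.7, 0.7),
                     stats::runif(params@nComponents, -0.7, 0.7),
                     0)
    offsets[1, ] <- 0
    # union extents from the star-body surfaces sampled on a dense
    # angular grid (the union extreme lies on some component's surface)
    sx <- sy <- sz <- numeric(0)
    for (k in seq_along(comps)) {
      srf <- .componentSurface(comps[[k]])
      sx <- c(sx, srf$x + offsets[k, 1])
      sy <- c(sy, srf$y + offsets[k, 2])
      sz <- c(sz, srf$z + offsets[k, 3])
    }
    rngx <- range(sx); rngy <- range(sy); rngz <- range(sz)
    extLat <- max(diff(rngx), diff(rngy))
    extZ <- diff(rngz)
    sLat <- W / extLat
    sZ <- Hgt / extZ
    # voxel centers in mm -> unit space
    cx <- grid@nx * grid@dx / 2; cy <- grid@ny * grid@dx / 2
    xs <- ((seq_len(grid@nx) - 0.5) * grid@dx - cx) / sLat + mean(rngx)
    ys <- ((seq_len(grid@ny) - 0.5) * grid@dx - cy) / sLat + mean(rngy)
    zs <- ((seq_len(grid@nz) - 0.5) * grid@dz - dTop) / sZ + rngz[1]
    # restrict to the shape's bounding box to keep the dense test small
    keepx <- which(xs >= rngx[1] - 0.1 & xs <= rngx[2] + 0.1)
    keepy <- which(ys >= rngy[1] - 0.1 & ys <= rngy[2] + 0.1)
    keepz <- which(zs >= rngz[1] - 0.1 & zs <= rngz[2] + 0.1)
    if (length(keepx) == 0L || length(keepy) == 0L || length(keepz) == 0L)
      next
    pg <- expand.grid(y = ys[keepy], x = xs[keepx], z = zs[keepz])
    ins <- .insideUnion(pg$x, pg$y, pg$z, comps, offsets)
    mask <- array(FALSE, c(grid@ny, grid@nx, grid@nz))
    sub <- array(ins, c(length(keepy), length(keepx), length(keepz)))
    mask[keepy, keepx, keepz] <- sub
    if (!any(mask)) next
    # translate in z so the shallowest voxel matches the sampled top depth
    kmin <- min(which(apply(mask, 3, any)))
    ktarget <- round(dTop / grid@dz) + 1L
    shift <- ktarget - kmin
    if (shift != 0L) {
      shifted <- array(FALSE, dim(mask))
      src <- seq_len(grid@nz)
      dst <- src + shift
      okz <- dst >= 1L & dst <= grid@nz
      if (any(mask[, , src[!okz]])) next  # fell off the grid; resample
      shifted[, , dst[okz]] <- mask[, , src[okz]]
      mask <- shifted
    }
    if (ktarget < 2L) next  # must stay buried (no voxel at the surface)
    if (.isConnected(mask)) {
      attr(mask, "params") <- list(width = W, height = Hgt, topDepth = dTop,
                                   seed = seed)
      return(mask)
    }
  }
  stop("could not produce a connected composite shape within ", retries,
       " offset resamples")
}

# ---- triangle meshes -------------------------------------------------------

#' Simple triangle-mesh constructors and readers
#'
#' A mesh is a list with `vertices` (n x 3 numeric, mm) and `faces`
#' (m x 3 integer, 1-based). `meshBox` and `meshSphere` build closed test
#' meshes; `readSTL`/`readPLY` read ASCII and binary files.
#'
#' @param size box edge lengths, mm (length-3).
#' @param center box/sphere center, mm.
#' @return a mesh list.
#' @export
meshBox <- function(size = c(10, 10, 5), center = c(0, 0, size[3] / 2)) {
  h <- size / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  v <- sweep(v, 2, center, `+`)
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  list(vertices = v, faces = f)
}

#' @rdname meshBox
#' @param radius sphere radius, mm.
#' @param subdiv icosphere subdivision level.
#' @export
meshSphere <- function(radius = 5, center = c(0, 0, radius), subdiv = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid <- new.env()
    getMid <- function(a, b) {
      k <- edgeKey(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      ab <- getMid(f[i, 1], f[i, 2])
      bc <- getMid(f[i, 2], f[i, 3])
      ca <- getMid(f[i, 3], f[i, 1])
      nf <- rbind(nf, c(f[i, 1], ab, ca), c(f[i, 2], bc, ab),
                  c(f[i, 3], ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, `+`)
  list(vertices = v, faces = f)
}

#' @rdname meshBox
#' @param path file path (.stl or .ply, ASCII or binary).
#' @export
readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fs <- file.size(path)
  if (length(ntri) == 1 && fs == 84 + 50 * ntri) {
    dat <- readBin(con, "raw", 50 * ntri)
    m <- matrix(dat, nrow = 50)
    tri <- matrix(0, ntri * 3, 3)
    for (k in 1:3) {  # vertex k of each triangle (skip the 12-byte normal)
      off <- 12 + (k - 1) * 12
      for (c in 1:3) {
        bytes <- m[off + (c - 1) * 4 + (1:4), , drop = FALSE]
        tri[seq(k, by = 3, length.out = ntri), c] <-
          readBin(as.raw(bytes), "double", ntri, size = 4, endian = "little")
      }
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  }
  .weldVertices(tri)
}

#' @rdname meshBox
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, 1)
    hdr <- c(hdr, ln)
    if (identical(trimws(ln), "end_header")) break
  }
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", hdr, value = TRUE))
  nV <- as.integer(sub(".*vertex\\s+(\\d+).*", "\\1",
                       grep("element vertex", hdr, value = TRUE)))
  nF <- as.integer(sub(".*face\\s+(\\d+).*", "\\1",
                       grep("element face", hdr, value = TRUE)))
  if (fmt == "ascii") {
    v <- matrix(scan(con, n = nV * 3, quiet = TRUE), ncol = 3, byrow = TRUE)
    f <- matrix(0L, nF, 3)
    for (i in seq_len(nF)) {
      rec <- scan(con, n = 4, quiet = TRUE)
      f[i, ] <- as.integer(rec[2:4]) + 1L
    }
  } else {
    endian <- if (grepl("little", fmt)) "little" else "big"
    v <- matrix(readBin(con, "double", nV * 3, size = 4, endian = endian),
                ncol = 3, byrow = TRUE)
    f <- matrix(0L, nF, 3)
    for (i in seq_len(nF)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      idx <- readBin(con, "integer", cnt, size = 4, endian = endian)
      f[i, ] <- idx[1:3] + 1L
    }
  }
  list(vertices = v, faces = f)
}

# weld duplicated vertices of a triangle soup into an indexed mesh
.weldVertices <- function(tri) {
  key <- apply(round(tri, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  list(vertices = tri[uk, , drop = FALSE],
       faces = matrix(idx, ncol = 3, byrow = TRUE))
}

.isWatertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Voxelize a closed triangle mesh into a buried tumor mask
#'
#' The mesh (deep specimen surface already facing the z = 0 plane) is
#' centered laterally on the grid, translated so its shallowest point sits
#' `minMarginMm` below the surface, and voxelized by a center-inclusion
#' parity test along depth columns.
#'
#' @param mesh a mesh list (`vertices`, `faces`), mm units.
#' @param grid the target [VoxelGrid-class].
#' @param minMarginMm minimum margin distance: depth of the mesh top, mm.
#' @return logical array (ny, nx, nz).
#' @examples
#' m <- voxelizeMesh(meshBox(c(10, 10, 5)), voxelGrid(nx = 41, ny = 41), 3)
#' @export
voxelizeMesh <- function(mesh, grid, minMarginMm) {
  stopifnot(minMarginMm > 0)
  if (!.isWatertight(mesh))
    stop("mesh is not watertight (boundary or non-manifold edges present)")
  v <- mesh$vertices
  f <- mesh$faces
  # center laterally, set top depth
  cx <- grid@nx * grid@dx / 2; cy <- grid@ny * grid@dx / 2
  v[, 1] <- v[, 1] - mean(range(v[, 1])) + cx
  v[, 2] <- v[, 2] - mean(range(v[, 2])) + cy
  v[, 3] <- v[, 3] - min(v[, 3]) + minMarginMm
  if (diff(range(v[, 1])) > grid@nx * grid@dx)
    stop("mesh exceeds the lateral grid in x")
  if (diff(range(v[, 2])) > grid@ny * grid@dx)
    stop("mesh exceeds the lateral grid in y")
  if (max(v[, 3]) > grid@nz * grid@dz)
    stop("mesh exceeds the grid in z")
  eps <- 1e-6 * grid@dx
  xs <- (seq_len(grid@nx) - 0.5) * grid@dx + eps
  ys <- (seq_len(grid@ny) - 0.5) * grid@dx + eps * 0.7
  colId <- integer(0); zHit <- numeric(0)
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    xr <- range(p1[1], p2[1], p3[1]); yr <- range(p1[2], p2[2], p3[2])
    ix <- which(xs >= xr[1] & xs <= xr[2])
    iy <- which(ys >= yr[1] & ys <= yr[2])
    if (length(ix) == 0L || length(iy) == 0L) next
    px <- rep(xs[ix], each = length(iy))
    py <- rep(ys[iy], times = length(ix))
    d <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
    if (abs(d) < 1e-12) next  # triangle vertical in z; parity unaffected
    w1 <- ((p2[2] - p3[2]) * (px - p3[1]) + (p3[1] - p2[1]) * (py - p3[2])) / d
    w2 <- ((p3[2] - p1[2]) * (px - p3[1]) + (p1[1] - p3[1]) * (py - p3[2])) / d
    w3 <- 1 - w1 - w2
    hit <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(hit)) next
    zh <- w1[hit] * p1[3] + w2[hit] * p2[3] + w3[hit] * p3[3]
    cid <- rep(iy, times = length(ix))[hit] +
      grid@ny * (rep(ix, each = length(iy))[hit] - 1L)
    colId <- c(colId, cid); zHit <- c(zHit, zh)
  }
  mask <- array(FALSE, c(grid@ny, grid@nx, grid@nz))
  zc <- (seq_len(grid@nz) - 0.5) * grid@dz
  hits <- split(zHit, colId)
  for (nm in names(hits)) {
    cid <- as.integer(nm)
    cz <- sort(hits[[nm]])
    inside <- (findInterval(zc, cz) %% 2L) == 1L
    j <- ((cid - 1L) %% grid@ny) + 1L
    i <- ((cid - 1L) %/% grid@ny) + 1L
    mask[j, i, inside] <- TRUE
  }
  mask
}

# ---- scene assembly --------------------------------------------------------

#' Optical-property sampling ranges
#'
#' The randomized homogeneous tissue conditions of the training corpus:
#' muA in [0.0015, 0.015] /mm, muSp' in [0.75, 2] /mm, tumor PpIX
#' concentration in [1, 10] ug/ml and a background fluorescence fraction in
#' [0.1%, 50%] of the tumor concentration. `lowScatter = TRUE` switches to
#' the low-scattering tissue ranges (muA in [0.01, 0.3], muSp' in
#' [0.3, 0.7] /mm).
#'
#' @param lowScatter use the low-scattering training ranges.
#' @return list of (min, max) ranges plus the quantum efficiency.
#' @export
opticsRanges <- function(lowScatter = FALSE) {
  if (lowScatter)
    list(muA = c(0.01, 0.3), muSp = c(0.3, 0.7),
         cTumor = c(1, 10), bgFraction = c(0.001, 0.5), eta = 0.046)
  else
    list(muA = c(0.0015, 0.015), muSp = c(0.75, 2),
         cTumor = c(1, 10), bgFraction = c(0.001, 0.5), eta = 0.046)
}

#' Assemble a tissue scene around a tumor mask
#'
#' Draws homogeneous optical properties and fluorophore concentrations
#' uniformly from the configured ranges and wraps them with the mask into a
#' [TissueScene-class]. Degenerate (min = max) ranges give deterministic
#' scenes.
#'
#' @param mask logical tumor mask (ny, nx, nz), buried (no surface voxel).
#' @param grid the [VoxelGrid-class] the mask lives on.
#' @param optics sampling ranges from [opticsRanges()].
#' @param seed RNG seed.
#' @return a [TissueScene-class].
#' @export
buildScene <- function(mask, grid, optics = opticsRanges(), seed = NULL) {
  if (!any(mask)) stop("empty tumor mask")
  if (!is.null(seed)) set.seed(seed)
  muA <- stats::runif(1, optics$muA[1], optics$muA[2])
  muSp <- stats::runif(1, optics$muSp[1], optics$muSp[2])
  cT <- stats::runif(1, optics$cTumor[1], optics$cTumor[2])
  frac <- stats::runif(1, optics$bgFraction[1], optics$bgFraction[2])
  new("TissueScene", grid = grid, tumorMask = mask, muA = muA, muSp = muSp,
      cTumor = cT, cBackground = frac * cT, eta = optics$eta)
}

#' Ground-truth maps of a scene
#'
#' Per-pixel margin distance: the depth of the top face of the shallowest
#' tumor voxel in each column; tumor-free columns carry exactly
#' `backgroundDepth` (10 mm by default) so the map minimum always belongs
#' to the tumor body. The concentration map carries the tumor value on
#' every column that intersects tumor and the background value elsewhere.
#'
#' @param scene a [TissueScene-class].
#' @param backgroundDepth depth assigned to tumor-free columns, mm.
#' @return a [TruthMaps-class].
#' @export
truthMaps <- function(scene, backgroundDepth = 10) {
  g <- scene@grid
  m <- scene@tumorMask
  nzv <- g@nz
  # index of shallowest tumor voxel per column (Inf where none)
  kmin <- apply(m, c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  depth <- (kmin - 1) * g@dz
  depth[is.na(kmin)] <- backgroundDepth
  conc <- matrix(scene@cBackground, g@ny, g@nx)
  conc[!is.na(kmin)] <- scene@cTumor
  new("TruthMaps", depthMap = depth, concentrationMap = conc,
      backgroundDepth = backgroundDepth)
}
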