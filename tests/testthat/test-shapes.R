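# composite-spherical-harmonic shapes, mesh voxelization, scenes, truth maps

test_that("CSH masks are deterministic and respect configured extents", {
  g <- voxelGrid(nx = 25, ny = 25, nz = 44, dx = 2, dz = 0.5)
  p <- cshParams()
  m1 <- generateCSHMask(p, g, seed = 7)
  m2 <- generateCSHMask(p, g, seed = 7)
  expect_identical(as.logical(m1), as.logical(m2))
  for (s in 1:15) {
    m <- generateCSHMask(p, g, seed = s)
    sp <- attr(m, "params")
    ij <- which(m, arr.ind = TRUE)
    extLat <- max(diff(range(ij[, 1])), diff(range(ij[, 2]))) * g@dx
    extZ <- diff(range(ij[, 3])) * g@dz
    # voxelized extents may quantize one pitch below/above the continuous ones
    expect_lte(extLat, 40 + g@dx)
    expect_lte(extZ, 10 + g@dz)
    expect_gte(sp$width, 5); expect_lte(sp$width, 40)
    expect_gte(sp$height, 5); expect_lte(sp$height, 10)
    expect_gte(sp$topDepth, 1); expect_lte(sp$topDepth, 10)
    # shallowest voxel sits at the sampled top depth (within half a pitch)
    top <- (min(ij[, 3]) - 1) * g@dz
    expect_lte(abs(top - sp$topDepth), g@dz / 2 + 1e-9)
    expect_true(SFDIdepth:::.isConnected(m))
  }
})

test_that("full-resolution CSH mask respects the default grid contract", {
  m <- generateCSHMask(cshParams(), voxelGrid(), seed = 7)
  ij <- which(m, arr.ind = TRUE)
  expect_lte(max(diff(range(ij[, 1])), diff(range(ij[, 2]))) * 0.5, 40.5)
  expect_lte(diff(range(ij[, 3])) * 0.5, 10.5)
  expect_false(any(m[, , 1]))  # buried
})

test_that("a single zero-amplitude harmonic voxelizes to a sphere", {
  g <- voxelGrid()
  p <- cshParams(nComponents = 1, amplitudeRange = c(0, 0),
                 widthRange = c(10, 10), heightRange = c(10, 10),
                 topDepthRange = c(3, 3))
  m <- generateCSHMask(p, g, seed = 1)
  vol <- sum(m) * g@dx^2 * g@dz
  expect_lt(abs(vol / ((4 / 3) * pi * 5^3) - 1), 0.05)
})

test_that("shapes exceeding the grid raise errors naming the dimension", {
  g <- voxelGrid(nx = 15, ny = 15, nz = 44, dx = 0.5)  # 7.5 mm wide grid
  p <- cshParams(widthRange = c(30, 30))
  expect_error(generateCSHMask(p, g, seed = 1), "x/y")
  g2 <- voxelGrid(nz = 20)  # 10 mm deep grid
  p2 <- cshParams(topDepthRange = c(9, 9), heightRange = c(8, 8))
  expect_error(generateCSHMask(p2, g2, seed = 1), "z")
})

test_that("box meshes voxelize to exact cuboids at the requested margin", {
  g <- voxelGrid(nx = 41, ny = 41, nz = 40)
  m <- voxelizeMesh(meshBox(c(10, 10, 5)), g, 3)
  ij <- which(m, arr.ind = TRUE)
  expect_equal(length(unique(ij[, 1])), 20)
  expect_equal(length(unique(ij[, 2])), 20)
  expect_equal(length(unique(ij[, 3])), 10)   # 5 mm / 0.5 mm
  expect_equal((min(ij[, 3]) - 1) * g@dz, 3)  # top face at z = 3 mm
})

test_that("sphere meshes voxelize to the analytic volume", {
  g <- voxelGrid(nx = 41, ny = 41, nz = 40)
  m <- voxelizeMesh(meshSphere(5, subdiv = 3), g, 2)
  vol <- sum(m) * g@dx^2 * g@dz
  expect_lt(abs(vol / ((4 / 3) * pi * 125) - 1), 0.05)
  # convergence: at 0.25 mm pitch the ratio tightens to 2%
  g2 <- voxelGrid(nx = 81, ny = 81, nz = 80, dx = 0.25, dz = 0.25)
  m2 <- voxelizeMesh(meshSphere(5, subdiv = 3), g2, 2)
  vol2 <- sum(m2) * g2@dx^2 * g2@dz
  expect_lt(abs(vol2 / ((4 / 3) * pi * 125) - 1), 0.02)
})

test_that("margin sweeps place the mesh top at each requested depth", {
  g <- voxelGrid(nx = 41, ny = 41, nz = 44)
  mesh <- meshBox(c(8, 8, 6))
  for (margin in 1:10) {
    m <- voxelizeMesh(mesh, g, margin)
    kmin <- min(which(apply(m, 3, any)))
    expect_equal((kmin - 1) * g@dz, margin)
  }
})

test_that("degenerate meshes are rejected", {
  bad <- meshBox()
  bad$faces <- bad$faces[-1, ]  # open box
  expect_error(voxelizeMesh(bad, voxelGrid(nx = 41, ny = 41), 2),
               "watertight")
  wide <- meshBox(c(60, 10, 5))
  expect_error(voxelizeMesh(wide, voxelGrid(nx = 41, ny = 41), 2),
               "lateral grid in x")
})

test_that("STL and PLY files round-trip through the readers", {
  mesh <- meshBox(c(6, 6, 4))
  # ASCII STL
  stl <- tempfile(fileext = ".stl")
  con <- file(stl, "w")
  writeLines("solid box", con)
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    writeLines("facet normal 0 0 0", con)
    writeLines(" outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("  vertex %g %g %g", tri[k, 1], tri[k, 2], tri[k, 3]), con)
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid box", con)
  close(con)
  m1 <- readSTL(stl)
  expect_true(SFDIdepth:::.isWatertight(m1))
  expect_equal(sort(unique(round(m1$vertices[, 3], 6))),
               sort(unique(round(mesh$vertices[, 3], 6))))
  # ASCII PLY
  ply <- tempfile(fileext = ".ply")
  con <- file(ply, "w")
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in seq_len(nrow(mesh$vertices)))
    writeLines(paste(mesh$vertices[i, ], collapse = " "), con)
  for (i in seq_len(nrow(mesh$faces)))
    writeLines(paste(c(3, mesh$faces[i, ] - 1L), collapse = " "), con)
  close(con)
  m2 <- readPLY(ply)
  expect_equal(m2$vertices, unname(mesh$vertices))
  expect_equal(m2$faces, mesh$faces)
})

test_that("scene assembly samples inside the configured ranges", {
  g <- smallGrid()
  mask <- cuboidScene()@tumorMask
  for (s in 1:10) {
    sc <- buildScene(mask, g, seed = s)
    expect_gte(sc@muA, 0.0015); expect_lte(sc@muA, 0.015)
    expect_gte(sc@muSp, 0.75); expect_lte(sc@muSp, 2)
    expect_gte(sc@cTumor, 1); expect_lte(sc@cTumor, 10)
    expect_gte(sc@cBackground / sc@cTumor, 0.001)
    expect_lte(sc@cBackground / sc@cTumor, 0.5)
  }
  low <- buildScene(mask, g, optics = opticsRanges(lowScatter = TRUE), seed = 1)
  expect_gte(low@muSp, 0.3); expect_lte(low@muSp, 0.7)
  expect_gte(low@muA, 0.01); expect_lte(low@muA, 0.3)
  # degenerate ranges are deterministic
  opt <- opticsRanges()
  opt$muA <- c(0.004, 0.004); opt$muSp <- c(1.2, 1.2)
  opt$cTumor <- c(5, 5); opt$bgFraction <- c(0.1, 0.1)
  sc <- buildScene(mask, g, optics = opt, seed = 99)
  expect_equal(sc@muA, 0.004)
  expect_equal(sc@muSp, 1.2)
  expect_equal(sc@cTumor, 5)
  expect_equal(sc@cBackground, 0.5)
  expect_error(buildScene(array(FALSE, dim(mask)), g), "empty")
})

test_that("truth maps follow the projected shallowest-voxel convention", {
  sc <- cuboidScene(topDepth = 3)
  tm <- truthMaps(sc)
  foot <- apply(sc@tumorMask, c(1, 2), any)
  expect_true(all(depthMap(tm)[foot] == 3))
  expect_true(all(depthMap(tm)[!foot] == 10))
  expect_true(all(concentrationMap(tm)[foot] == sc@cTumor))
  expect_true(all(concentrationMap(tm)[!foot] == sc@cBackground))
  # CSH shape: map minimum equals the placement depth within dz/2
  g <- voxelGrid(nx = 25, ny = 25, nz = 44, dx = 2, dz = 0.5)
  p <- cshParams(topDepthRange = c(2, 2))
  m <- generateCSHMask(p, g, seed = 3)
  sc2 <- buildScene(m, g, seed = 3)
  tm2 <- truthMaps(sc2)
  expect_lte(abs(min(depthMap(tm2)) - 2), g@dz / 2 + 1e-9)
})
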