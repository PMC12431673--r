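# diffusion forward model: closed form, numerical solver, stack simulation

test_that("closed-form reflectance behaves physically", {
  rd <- analyticRd(0.0045, 1.0, fxDefault())
  expect_true(all(diff(rd) < 0))            # attenuation grows with fx
  expect_lt(analyticRd(0.0045, 1.0, 0.25), analyticRd(0.0045, 1.0, 0))
  # absorption limit: Rd -> 0 monotonically as muA grows
  muas <- c(0.005, 0.05, 0.5, 5, 50)
  rda <- analyticRd(muas, 1.0, 0)
  expect_true(all(diff(rda) < 0))
  expect_lt(rda[length(rda)], 0.05)
})

test_that("closed form reproduces the frozen oracle table", {
  # six reflectance values at (muA = 0.0045, muSp' = 1.0), evaluated
  # independently from the semi-infinite Robin-boundary solution and frozen
  frozen <- c(0.7117285717554, 0.4158128114329, 0.2225324547066,
              0.1274369110703, 0.0764727778418, 0.0473949416435)
  expect_equal(analyticRd(0.0045, 1.0, fxDefault()), frozen,
               tolerance = 1e-10)
})

test_that("simulated homogeneous reflectance matches the closed form", {
  for (op in list(c(0.0045, 1), c(0.0015, 2), c(0.015, 0.75))) {
    sc <- exampleScene(nx = 9, nz = 40, muA = op[1], muSp = op[2],
                       size = 2L, thickness = 4L, topDepth = 4)
    stk <- simulateStack(sc, fxDefault(), zrefine = 4)
    num <- apply(reflectance(stk), 3, function(m) m[5, 5])
    an <- analyticRd(op[1], op[2], fxDefault())
    expect_lt(max(abs(num / an - 1)), 0.02)
  }
})

test_that("excitation fluence decays at the effective attenuation rate", {
  sc <- exampleScene(nx = 9, nz = 40, muA = 0.0045, muSp = 1,
                     size = 2L, thickness = 4L)
  for (fx in c(0, 0.1, 0.25)) {
    ex <- solveExcitation(sc, fx, zrefine = 4)
    prof <- ex$profile
    dzr <- ex$geom$dzr
    z <- (seq_along(prof) - 0.5) * dzr
    # fit beyond the source region, before the bottom boundary
    sel <- z > 3 & z < 20
    slope <- stats::coef(stats::lm(log(prof[sel]) ~ z[sel]))[2]
    mue <- effectiveAttenuation(0.0045, 1, fx)
    expect_lt(abs(-slope / mue - 1), 0.05)
  }
})

test_that("higher spatial frequency never increases deep fluence", {
  sc <- exampleScene(nx = 9, nz = 40, size = 2L, thickness = 4L)
  p0 <- solveExcitation(sc, 0, zrefine = 2)$profile
  p25 <- solveExcitation(sc, 0.25, zrefine = 2)$profile
  zsrc <- ceiling((1 / (sc@muA + sc@muSp)) / (0.5 / 2)) + 1L
  deep <- seq(zsrc + 1L, length(p0))
  expect_true(all(p25[deep] <= p0[deep]))
})

test_that("spectral and sparse backends agree on the same discretization", {
  set.seed(4)
  dm <- c(9, 9, 14)
  S <- array(stats::runif(prod(dm)), dm)
  D <- 1 / (3 * 1.2); mu <- 0.01
  a <- SFDIdepth:::.fdSolveHomogeneous(S, D, mu, 0.5, 0.5, aParameter())
  Dv <- array(D, dm); muv <- array(mu, dm)
  b <- SFDIdepth:::.fdSolveSparse(S, Dv, muv, 0.5, 0.5, aParameter())
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-8)
})

test_that("fluorescence is linear in concentration and zero without fluorophore", {
  sc0 <- exampleScene(nx = 13, nz = 32, cTumor = 0, cBackground = 0)
  sc0@cTumor <- 0; sc0@cBackground <- 0
  stk0 <- simulateStack(sc0, c(0, 0.1), zrefine = 2)
  expect_true(all(fluorescence(stk0) == 0))
  expect_gt(min(reflectance(stk0)), 0)
  sc1 <- exampleScene(nx = 13, nz = 32, cTumor = 4, cBackground = 0.4)
  sc2 <- exampleScene(nx = 13, nz = 32, cTumor = 8, cBackground = 0.8)
  s1 <- simulateStack(sc1, c(0, 0.1), zrefine = 2)
  s2 <- simulateStack(sc2, c(0, 0.1), zrefine = 2)
  expect_equal(fluorescence(s2), 2 * fluorescence(s1), tolerance = 1e-10)
  expect_equal(reflectance(s2), reflectance(s1), tolerance = 1e-12)
})

test_that("fluorescence is additive over disjoint inclusions", {
  g <- voxelGrid(nx = 17, ny = 17, nz = 32)
  mk <- function(xrange) {
    m <- array(FALSE, c(17, 17, 32))
    m[7:11, xrange, 9:14] <- TRUE
    m
  }
  mkScene <- function(mask, cbg = 0) {
    sc <- new("TissueScene", grid = g, tumorMask = mask, muA = 0.0045,
              muSp = 1, cTumor = 5, cBackground = cbg, eta = 0.046)
  }
  a <- mk(3:6); b <- mk(11:14)
  fa <- fluorescence(simulateStack(mkScene(a), c(0, 0.2), zrefine = 2))
  fb <- fluorescence(simulateStack(mkScene(b), c(0, 0.2), zrefine = 2))
  fab <- fluorescence(simulateStack(mkScene(a | b), c(0, 0.2), zrefine = 2))
  expect_equal(fab, fa + fb, tolerance = 1e-9)
})

test_that("burying an inclusion deeper strictly reduces fluorescence at every fx", {
  totals <- sapply(c(2, 4, 6, 8), function(d) {
    sc <- exampleScene(nx = 15, nz = 40, topDepth = d, size = 3L,
                       thickness = 6L, cBackground = 0)
    apply(fluorescence(simulateStack(sc, fxDefault(), zrefine = 2)), 3, sum)
  })
  for (i in seq_len(6)) expect_true(all(diff(totals[i, ]) < 0))
})

test_that("reflectance and total fluorescence are non-increasing in fx", {
  sc <- exampleScene(nx = 13, nz = 32)
  stk <- simulateStack(sc, fxDefault(), zrefine = 2)
  r <- reflectance(stk)
  for (i in seq_len(5))
    expect_true(all(r[, , i + 1] <= r[, , i] + 1e-12))
  tot <- apply(fluorescence(stk), 3, sum)
  expect_true(all(diff(tot) < 0))
})

test_that("halving the solver depth step changes reflectance under 1%", {
  sc <- exampleScene(nx = 9, nz = 40, size = 2L)
  r1 <- reflectance(simulateStack(sc, fxDefault(), zrefine = 4))[5, 5, ]
  r2 <- reflectance(simulateStack(sc, fxDefault(), zrefine = 8))[5, 5, ]
  expect_lt(max(abs(r1 / r2 - 1)), 0.01)
})

test_that("dataset generation is deterministic, resumable and complete", {
  g <- voxelGrid(nx = 17, ny = 17, nz = 36, dx = 2, dz = 0.5)
  sp <- cshParams(widthRange = c(5, 25))
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  unlink(c(d1, d2), recursive = TRUE)
  generateDataset(4, d1, seed = 5, grid = g, shapeParams = sp, zrefine = 2,
                  verbose = FALSE)
  generateDataset(4, d2, seed = 5, grid = g, shapeParams = sp, zrefine = 2,
                  verbose = FALSE)
  r1 <- loadDataset(d1); r2 <- loadDataset(d2)
  expect_identical(r1, r2)
  expect_length(r1, 4)
  for (r in r1) {
    bg <- r$depth[r$conc == min(r$conc)]
    if (length(bg)) expect_true(all(bg == 10))
    expect_true(all(r$fluorescence >= 0))
    expect_equal(dim(r$reflectance), c(17, 17, 6))
  }
  # resume: deleting one record and regenerating restores it identically
  files <- sort(dir(d1, pattern = "record", full.names = TRUE))
  file.remove(files[2])
  generateDataset(4, d1, seed = 5, grid = g, shapeParams = sp, zrefine = 2,
                  verbose = FALSE)
  expect_identical(loadDataset(d1), r2)
  # refuse to write into a foreign non-empty directory
  d3 <- file.path(tempdir(), "ds_c")
  dir.create(d3); writeLines("x", file.path(d3, "stranger.txt"))
  expect_error(generateDataset(2, d3, seed = 1, grid = g), "overwrite")
  unlink(c(d1, d2, d3), recursive = TRUE)
})
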