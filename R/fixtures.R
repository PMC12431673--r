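# Deterministic fixture generation for tests and demos.

#' Generate small deterministic fixtures
#'
#' Writes the fixture files used by the test suite and examples. Kinds:
#' \describe{
#'   \item{sinusoid-frames}{three phase-shifted sinusoidal frames whose
#'     demodulated amplitude equals the embedded modulation exactly.}
#'   \item{homogeneous-scene}{a small homogeneous scene plus its simulated
#'     stack, whose reflectance matches the closed-form model.}
#'   \item{toy-maps}{hand-checkable 3x3 truth/prediction map pairs.}
#'   \item{tiny-dataset}{an 8-scene dataset at 33x33 pixels.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed RNG seed.
#' @param outPath output directory.
#' @return invisibly, the written file paths.
#' @export
makeFixtures <- function(kind, seed = 1L, outPath = tempfile("fixtures")) {
  kinds <- c("sinusoid-frames", "homogeneous-scene", "toy-maps",
             "tiny-dataset")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; valid kinds: ",
         paste(kinds, collapse = ", "))
  dir.create(outPath, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  written <- character(0)
  if (kind == "sinusoid-frames") {
    fx <- 0.1; m0 <- 100; mdepth <- 0.42
    x <- outer(rep(1, 32), (0:31) * 0.5)
    frames <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(ph)
      m0 * (1 + mdepth * cos(2 * pi * fx * x + ph)))
    obj <- list(frames = frames, fx = fx, amplitude = m0 * mdepth, dc = m0)
    f <- file.path(outPath, "sinusoid_frames.rds")
    saveRDS(obj, f); written <- f
  } else if (kind == "homogeneous-scene") {
    sc <- exampleScene(nx = 15, nz = 40, cTumor = 5, cBackground = 0.5)
    stk <- simulateStack(sc, zrefine = 4)
    f <- file.path(outPath, "homogeneous_scene.rds")
    saveRDS(list(scene = sc, stack = stk,
                 rdAnalytic = analyticRd(sc@muA, sc@muSp, fxDefault())), f)
    written <- f
  } else if (kind == "toy-maps") {
    truth <- new("TruthMaps",
                 depthMap = matrix(c(2, 3, 10, 4, 5, 10, 10, 10, 10), 3, 3),
                 concentrationMap = matrix(c(5, 5, 1, 5, 5, 1, 1, 1, 1), 3, 3),
                 backgroundDepth = 10)
    pred <- new("PredMaps",
                depthMap = matrix(c(2.5, 3, 9, 4, 6, 10, 11, 10, 10), 3, 3),
                concentrationMap = matrix(c(4, 5, 1, 6, 5, 1, 1, 2, 1), 3, 3))
    f <- file.path(outPath, "toy_maps.rds")
    saveRDS(list(truth = truth, pred = pred), f)
    written <- f
  } else if (kind == "tiny-dataset") {
    g <- voxelGrid(nx = 33L, ny = 33L, nz = 32L, dx = 1.5, dz = 0.5)
    sp <- cshParams(widthRange = c(5, 25), heightRange = c(4, 8),
                    topDepthRange = c(1, 8))
    generateDataset(8L, outPath, seed = seed, grid = g, shapeParams = sp,
                    zrefine = 2L, overwrite = TRUE, verbose = FALSE)
    written <- dir(outPath, full.names = TRUE)
  }
  invisible(written)
}
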