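# Synthetic dataset generation: CSH scene -> SFDI forward simulation ->
# LUT optical-property recovery -> ground-truth maps, one record per scene.

#' Generate a synthetic SFDI training dataset
#'
#' For each scene: draws a composite-spherical-harmonic tumor shape and
#' homogeneous optics, simulates the reflectance/fluorescence stack at the
#' configured spatial frequencies, recovers optical-property maps by
#' two-frequency lookup-table inversion of the simulated reflectance, and
#' stores the record together with its ground-truth depth/concentration
#' maps and sampled parameters. Generation is resumable and deterministic:
#' one master seed spawns an independent child seed per record.
#'
#' @param nScenes number of records.
#' @param outDir output directory (one .rds per record + manifest.json).
#' @param seed master seed.
#' @param grid the scene [VoxelGrid-class].
#' @param shapeParams a [CSHParams-class].
#' @param optics ranges from [opticsRanges()].
#' @param fx spatial-frequency set.
#' @param zrefine solver depth-refinement factor.
#' @param lutFx frequency pair for the optical-property inversion.
#' @param lutRanges ranges spanned by the inversion lookup table; defaults
#'   to the standard training domain ([opticsRanges()]) so that test sets
#'   with fixed scene properties are still processed with the full table.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param verbose print progress.
#' @return invisibly, the manifest list.
#' @export
generateDataset <- function(nScenes, outDir, seed = 1L,
                            grid = voxelGrid(), shapeParams = cshParams(),
                            optics = opticsRanges(), fx = fxDefault(),
                            zrefine = 4L, lutFx = c(0, 0.2),
                            lutRanges = opticsRanges(),
                            overwrite = FALSE, verbose = interactive()) {
  stopifnot(nScenes >= 1)
  if (dir.exists(outDir) && length(dir(outDir)) > 0 && !overwrite) {
    if (!file.exists(file.path(outDir, "manifest.json")))
      stop("output directory ", outDir, " is non-empty; pass overwrite = TRUE")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lut <- buildLUT(muARange = lutRanges$muA, muSpRange = lutRanges$muSp,
                  fxPair = lutFx)
  childSeed <- function(i) as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
  records <- character(nScenes)
  for (i in seq_len(nScenes)) {
    f <- file.path(outDir, sprintf("record_%05d.rds", i))
    records[i] <- basename(f)
    if (file.exists(f) && !overwrite) next  # resumable by record index
    rec <- simulateRecord(childSeed(i), grid = grid,
                          shapeParams = shapeParams, optics = optics,
                          fx = fx, zrefine = zrefine, lut = lut)
    saveRDS(rec, f)
    if (verbose && i %% 25 == 0)
      message(sprintf("  record %d / %d", i, nScenes))
  }
  manifest <- list(nScenes = nScenes, seed = seed,
                   fx = fx, zrefine = zrefine, lutFx = lutFx,
                   optics = optics,
                   grid = list(nx = grid@nx, ny = grid@ny, nz = grid@nz,
                               dx = grid@dx, dz = grid@dz),
                   records = records)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate one complete dataset record
#'
#' @param seed record seed (drives shape, optics and nothing else).
#' @inheritParams generateDataset
#' @param lut a prebuilt [LUTGrid-class] (built from `optics` if NULL).
#' @return list with `fluorescence` and `reflectance` (ny, nx, n_fx)
#'   arrays, `muA`/`muSp` maps, `depth`/`conc` truth maps, and `params`.
#' @export
simulateRecord <- function(seed, grid = voxelGrid(),
                           shapeParams = cshParams(),
                           optics = opticsRanges(), fx = fxDefault(),
                           zrefine = 4L, lut = NULL) {
  if (is.null(lut)) lut <- buildLUT()  # standard training-domain table
  mask <- generateCSHMask(shapeParams, grid, seed = seed)
  scene <- buildScene(mask, grid, optics)  # continues the seeded stream
  stk <- simulateStack(scene, fx = fx, zrefine = zrefine)
  i1 <- which.min(abs(fx - lut@fxPair[1]))
  i2 <- which.min(abs(fx - lut@fxPair[2]))
  op <- invertOpticalProperties(stk@reflectance[, , i1],
                                stk@reflectance[, , i2], lut)
  tm <- truthMaps(scene)
  sp <- attr(mask, "params")
  list(fluorescence = stk@fluorescence,
       reflectance = stk@reflectance,
       muA = op@muA, muSp = op@muSp,
       depth = tm@depthMap, conc = tm@concentrationMap,
       params = list(seed = seed, muA = scene@muA, muSp = scene@muSp,
                     cTumor = scene@cTumor, cBackground = scene@cBackground,
                     width = sp$width, height = sp$height,
                     topDepth = sp$topDepth))
}

#' Load a generated dataset
#'
#' @param dir dataset directory written by [generateDataset()].
#' @param n optionally limit to the first n records.
#' @return list of record lists.
#' @export
loadDataset <- function(dir, n = NULL) {
  files <- sort(dir(dir, pattern = "^record_.*\\.rds$", full.names = TRUE))
  if (!is.null(n)) files <- files[seq_len(min(n, length(files)))]
  lapply(files, readRDS)
}
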