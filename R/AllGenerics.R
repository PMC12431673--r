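#' Accessors for SFDIdepth objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an SFDIdepth S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("depthMap", function(object) standardGeneric("depthMap"))
#' @rdname accessors
#' @export
setGeneric("concentrationMap", function(object) standardGeneric("concentrationMap"))
#' @rdname accessors
#' @export
setGeneric("reflectance", function(object) standardGeneric("reflectance"))
#' @rdname accessors
#' @export
setGeneric("fluorescence", function(object) standardGeneric("fluorescence"))
#' @rdname accessors
#' @export
setGeneric("spatialFrequencies", function(object) standardGeneric("spatialFrequencies"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(object) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setGeneric("muaMap", function(object) standardGeneric("muaMap"))
#' @rdname accessors
#' @export
setGeneric("muspMap", function(object) standardGeneric("muspMap"))
#' @rdname accessors
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))

#' @rdname accessors
#' @export
setMethod("depthMap", "TruthMaps", function(object) object@depthMap)
#' @rdname accessors
#' @export
setMethod("depthMap", "PredMaps", function(object) object@depthMap)
#' @rdname accessors
#' @export
setMethod("concentrationMap", "TruthMaps", function(object) object@concentrationMap)
#' @rdname accessors
#' @export
setMethod("concentrationMap", "PredMaps", function(object) object@concentrationMap)
#' @rdname accessors
#' @export
setMethod("reflectance", "SFDIStack", function(object) object@reflectance)
#' @rdname accessors
#' @export
setMethod("fluorescence", "SFDIStack", function(object) object@fluorescence)
#' @rdname accessors
#' @export
setMethod("spatialFrequencies", "SFDIStack", function(object) object@fx)
#' @rdname accessors
#' @export
setMethod("tumorMask", "TissueScene", function(object) object@tumorMask)
#' @rdname accessors
#' @export
setMethod("muaMap", "OPMaps", function(object) object@muA)
#' @rdname accessors
#' @export
setMethod("muspMap", "OPMaps", function(object) object@muSp)
#' @rdname accessors
#' @export
setMethod("parameterCount", "NetworkSpec", function(object) object@parameterCount)

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels, %.3g mm lateral / %.3g mm depth pitch\n",
              object@nx, object@ny, object@nz, object@dx, object@dz))
})

setMethod("show", "TissueScene", function(object) {
  g <- object@grid
  nt <- sum(object@tumorMask)
  cat(sprintf("TissueScene: %d x %d x %d grid, %d tumor voxels (%.1f mm^3)\n",
              g@nx, g@ny, g@nz, nt, nt * g@dx^2 * g@dz))
  cat(sprintf("  muA = %s /mm, muSp' = %s /mm\n",
              paste(signif(range(object@muA), 3), collapse = "-"),
              paste(signif(range(object@muSp), 3), collapse = "-")))
  cat(sprintf("  C(tumor) = %.3g ug/ml, C(background) = %.3g ug/ml, eta = %.3g\n",
              object@cTumor, object@cBackground, object@eta))
})

setMethod("show", "SFDIStack", function(object) {
  d <- dim(object@reflectance)
  cat(sprintf("SFDIStack: %d x %d px at %.3g mm/px, fx = {%s} /mm\n",
              d[2], d[1], object@pixelSize,
              paste(object@fx, collapse = ", ")))
})

setMethod("show", "TruthMaps", function(object) {
  cat(sprintf("TruthMaps: %d x %d px, closest depth %.2f mm (background = %g mm)\n",
              ncol(object@depthMap), nrow(object@depthMap),
              min(object@depthMap), object@backgroundDepth))
})

setMethod("show", "OPMaps", function(object) {
  cat(sprintf("OPMaps: %d x %d px, muA %.4g-%.4g /mm, muSp' %.3g-%.3g /mm (%d%% in gamut)\n",
              ncol(object@muA), nrow(object@muA), min(object@muA), max(object@muA),
              min(object@muSp), max(object@muSp),
              round(100 * mean(object@valid))))
})

setMethod("show", "LUTGrid", function(object) {
  cat(sprintf("LUTGrid: %d x %d nodes, muA [%g, %g], muSp' [%g, %g], fx = (%g, %g) /mm\n",
              length(object@muAGrid), length(object@muSpGrid),
              min(object@muAGrid), max(object@muAGrid),
              min(object@muSpGrid), max(object@muSpGrid),
              object@fxPair[1], object@fxPair[2]))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: %s%s, %s trainable parameters in %d tensors\n",
              object@config$variant,
              if (isTRUE(object@config$useDropout)) " + dropout" else "",
              format(object@parameterCount, big.mark = ","),
              length(object@params)))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  depth MAE: %.3f +/- %.3f mm (tumor pixels)\n", object@depthMAE, object@depthSD))
  cat(sprintf("  concentration MAE: %.3f +/- %.3f ug/ml\n", object@concMAE, object@concSD))
  for (b in names(object@binnedMAE))
    cat(sprintf("  depth MAE %s mm: %.3f +/- %.3f\n", b, object@binnedMAE[b], object@binnedSD[b]))
  cat(sprintf("  closest-depth MAE: %.3f +/- %.3f mm, R^2 = %.3f (%d cases)\n",
              object@closestMAE, object@closestSD, object@r2, nrow(object@perCase)))
})
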