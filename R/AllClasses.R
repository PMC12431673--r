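#' @import methods
#' @importFrom stats runif rnorm sd t.test
#' @importFrom utils modifyList
#' @useDynLib SFDIdepth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Voxel grid geometry
#'
#' Axis-aligned voxel grid used for tissue scenes. Pixel (1,1) is the image
#' top-left corner; z = 0 is the flat imaging surface and z increases
#' downward into the tissue. Voxel centers sit at (i - 0.5) * pitch.
#'
#' @slot nx,ny lateral voxel counts (image columns/rows).
#' @slot nz depth voxel count.
#' @slot dx lateral voxel pitch in mm.
#' @slot dz depth voxel pitch in mm.
#' @export
setClass("VoxelGrid",
  representation(nx = "integer", ny = "integer", nz = "integer",
                 dx = "numeric", dz = "numeric"),
  prototype(nx = 101L, ny = 101L, nz = 44L, dx = 0.5, dz = 0.5))

setValidity("VoxelGrid", function(object) {
  if (object@nx < 1L || object@ny < 1L || object@nz < 1L)
    return("voxel counts must be >= 1")
  if (object@dx <= 0 || object@dz <= 0)
    return("voxel pitches must be > 0")
  TRUE
})

#' Construct a voxel grid
#'
#' @param nx,ny lateral voxel counts; default 101 x 101.
#' @param nz depth voxel count; the default covers 22 mm at `dz` = 0.5 mm.
#' @param dx lateral pitch, mm (default 0.5).
#' @param dz depth pitch, mm (default 0.5).
#' @return A [VoxelGrid-class] object.
#' @examples
#' voxelGrid(nx = 33, ny = 33, nz = 40)
#' @export
voxelGrid <- function(nx = 101L, ny = 101L, nz = 44L, dx = 0.5, dz = 0.5) {
  new("VoxelGrid", nx = as.integer(nx), ny = as.integer(ny),
      nz = as.integer(nz), dx = dx, dz = dz)
}

#' Composite-spherical-harmonic shape parameters
#'
#' Randomization ranges for synthetic tumor shapes built by merging several
#' randomized spherical-harmonic star-convex bodies.
#'
#' @slot nComponents number of harmonic bodies merged per shape.
#' @slot orderDegreeRange integer range for the harmonic degree l and order m.
#' @slot widthRange lateral extent range of the merged shape, mm.
#' @slot heightRange axial extent range, mm.
#' @slot topDepthRange range of the closest (top) surface depth, mm.
#' @slot amplitudeRange range of the radial perturbation amplitude a in
#'   r(theta, phi) = r0 (1 + a * Ybar); kept below 1 so the radius stays
#'   positive.
#' @export
setClass("CSHParams",
  representation(nComponents = "integer", orderDegreeRange = "integer",
                 widthRange = "numeric", heightRange = "numeric",
                 topDepthRange = "numeric", amplitudeRange = "numeric"),
  prototype(nComponents = 4L, orderDegreeRange = c(2L, 6L),
            widthRange = c(5, 40), heightRange = c(5, 10),
            topDepthRange = c(1, 10), amplitudeRange = c(0.1, 0.5)))

setValidity("CSHParams", function(object) {
  rngs <- list(object@orderDegreeRange, object@widthRange,
               object@heightRange, object@topDepthRange,
               object@amplitudeRange)
  if (object@nComponents < 1L) return("nComponents must be >= 1")
  for (r in rngs) {
    if (length(r) != 2L || r[1] > r[2]) return("ranges must be (min, max) with min <= max")
  }
  if (object@amplitudeRange[2] >= 1) return("amplitude must stay below 1")
  TRUE
})

#' Construct CSH shape parameters
#'
#' Defaults reproduce the randomized training-shape conditions: four merged
#' harmonics, degree/order between 2 and 6, width 5-40 mm, height 5-10 mm,
#' top depth 1-10 mm.
#'
#' @param nComponents number of merged harmonic bodies (default 4).
#' @param orderDegreeRange integer range for degree/order (default c(2, 6)).
#' @param widthRange,lateral extent range in mm (default c(5, 40)).
#' @param heightRange axial extent range in mm (default c(5, 10)).
#' @param topDepthRange top-surface depth range in mm (default c(1, 10)).
#' @param amplitudeRange harmonic perturbation amplitude range
#'   (default c(0.1, 0.5)).
#' @return A [CSHParams-class] object.
#' @export
cshParams <- function(nComponents = 4L, orderDegreeRange = c(2L, 6L),
                      widthRange = c(5, 40), heightRange = c(5, 10),
                      topDepthRange = c(1, 10), amplitudeRange = c(0.1, 0.5)) {
  new("CSHParams", nComponents = as.integer(nComponents),
      orderDegreeRange = as.integer(orderDegreeRange),
      widthRange = as.numeric(widthRange),
      heightRange = as.numeric(heightRange),
      topDepthRange = as.numeric(topDepthRange),
      amplitudeRange = as.numeric(amplitudeRange))
}

#' Voxelized tissue scene
#'
#' A buried fluorescent tumor in homogeneous (or per-voxel) background
#' tissue. Optical coefficients are in 1/mm, fluorophore concentrations in
#' ug/ml.
#'
#' @slot grid the [VoxelGrid-class].
#' @slot tumorMask logical array (ny, nx, nz); TRUE inside the tumor.
#' @slot muA absorption coefficient; scalar (homogeneous) or array matching
#'   the mask.
#' @slot muSp reduced scattering coefficient; scalar or array.
#' @slot cTumor tumor fluorophore concentration, ug/ml.
#' @slot cBackground healthy-tissue fluorophore concentration, ug/ml.
#' @slot eta fluorescence quantum efficiency.
#' @export
setClass("TissueScene",
  representation(grid = "VoxelGrid", tumorMask = "array", muA = "numeric",
                 muSp = "numeric", cTumor = "numeric", cBackground = "numeric",
                 eta = "numeric"))

setValidity("TissueScene", function(object) {
  g <- object@grid
  if (!identical(dim(object@tumorMask), c(g@ny, g@nx, g@nz)))
    return("tumorMask dimensions must match the grid (ny, nx, nz)")
  if (!is.logical(object@tumorMask)) return("tumorMask must be logical")
  if (any(object@muA <= 0) || any(object@muSp <= 0))
    return("muA and muSp must be positive everywhere")
  if (object@cBackground < 0 || object@cBackground > object@cTumor)
    return("need 0 <= cBackground <= cTumor")
  if (object@eta <= 0 || object@eta >= 1) return("eta must lie in (0, 1)")
  if (any(object@tumorMask[, , 1]))
    return("tumor touches the z = 0 surface; the inclusion must be buried")
  TRUE
})

#' Ground-truth margin-distance and concentration maps
#'
#' Per-pixel distance along the imaging axis from the surface to the
#' shallowest tumor voxel (mm), and the projected fluorophore concentration
#' (ug/ml). Columns with no tumor carry the fixed background depth.
#'
#' @slot depthMap numeric matrix (ny, nx), mm.
#' @slot concentrationMap numeric matrix (ny, nx), ug/ml.
#' @slot backgroundDepth depth value assigned to tumor-free columns, mm.
#' @export
setClass("TruthMaps",
  representation(depthMap = "matrix", concentrationMap = "matrix",
                 backgroundDepth = "numeric"),
  prototype(backgroundDepth = 10))

setValidity("TruthMaps", function(object) {
  if (!identical(dim(object@depthMap), dim(object@concentrationMap)))
    return("depth and concentration maps must share a shape")
  if (any(object@depthMap < 0)) return("depths must be >= 0")
  TRUE
})

#' Stack of demodulated SFDI images
#'
#' Co-registered diffuse reflectance and diffuse fluorescence images across
#' the spatial-frequency set. Both are unitless (reflectance is the diffuse
#' reflectance Rd; fluorescence is the surface partial current per unit
#' incident power).
#'
#' @slot reflectance numeric array (ny, nx, n_fx).
#' @slot fluorescence numeric array (ny, nx, n_fx).
#' @slot fx spatial frequencies, 1/mm, strictly increasing.
#' @slot pixelSize lateral pixel pitch, mm.
#' @export
setClass("SFDIStack",
  representation(reflectance = "array", fluorescence = "array",
                 fx = "numeric", pixelSize = "numeric"))

setValidity("SFDIStack", function(object) {
  if (!identical(dim(object@reflectance), dim(object@fluorescence)))
    return("reflectance and fluorescence stacks must share a shape")
  if (dim(object@reflectance)[3] != length(object@fx))
    return("third dimension must index the spatial frequencies")
  if (any(object@fx < 0) || is.unsorted(object@fx, strictly = TRUE))
    return("fx must be non-negative and strictly increasing")
  if (any(object@reflectance < 0) || any(object@fluorescence < 0))
    return("image values must be >= 0")
  TRUE
})

#' Optical-property maps
#'
#' Per-pixel absorption and reduced scattering recovered by lookup-table
#' inversion, with a validity mask flagging in-gamut pixels.
#'
#' @slot muA numeric matrix, 1/mm.
#' @slot muSp numeric matrix, 1/mm.
#' @slot valid logical matrix; FALSE where the measured pair fell outside
#'   the table gamut and was clamped.
#' @export
setClass("OPMaps",
  representation(muA = "matrix", muSp = "matrix", valid = "matrix"))

setValidity("OPMaps", function(object) {
  if (!identical(dim(object@muA), dim(object@muSp)))
    return("muA and muSp maps must share a shape")
  if (any(!is.finite(object@muA)) || any(!is.finite(object@muSp)))
    return("optical-property maps must be finite")
  if (any(object@muA <= 0) || any(object@muSp <= 0))
    return("optical properties must be strictly positive")
  TRUE
})

#' Two-frequency reflectance lookup table
#'
#' Model diffuse reflectance pairs (Rd at fx1, Rd at fx2) tabulated on a
#' rectangular (muA, muSp) grid, used to invert measured reflectance into
#' optical-property maps.
#'
#' @slot muAGrid,muSpGrid grid node coordinates, 1/mm.
#' @slot rd1,rd2 model reflectance at the two frequencies; matrices indexed
#'   (muA node, muSp node).
#' @slot fxPair the two spatial frequencies, 1/mm.
#' @slot A internal-reflection boundary parameter.
#' @export
setClass("LUTGrid",
  representation(muAGrid = "numeric", muSpGrid = "numeric",
                 rd1 = "matrix", rd2 = "matrix", fxPair = "numeric",
                 A = "numeric"))

setValidity("LUTGrid", function(object) {
  if (!identical(dim(object@rd1), c(length(object@muAGrid), length(object@muSpGrid))))
    return("rd tables must be (muA nodes) x (muSp nodes)")
  if (any(object@rd1 <= 0) || any(object@rd1 >= 1) ||
      any(object@rd2 <= 0) || any(object@rd2 >= 1))
    return("model reflectance must lie in (0, 1)")
  if (length(object@fxPair) != 2L) return("fxPair must hold two frequencies")
  TRUE
})

#' Predicted margin-distance and concentration maps
#'
#' Network output in physical units.
#'
#' @slot depthMap numeric matrix, mm.
#' @slot concentrationMap numeric matrix, ug/ml.
#' @export
setClass("PredMaps",
  representation(depthMap = "matrix", concentrationMap = "matrix"))

setValidity("PredMaps", function(object) {
  if (!identical(dim(object@depthMap), dim(object@concentrationMap)))
    return("depth and concentration maps must share a shape")
  if (any(!is.finite(object@depthMap)) || any(!is.finite(object@concentrationMap)))
    return("predicted maps must be finite")
  TRUE
})

#' Evaluation report
#'
#' Masked error statistics over one or more test cases: overall depth and
#' concentration MAE +/- SD inside the tumor regions, MAE binned by true
#' depth (0-5, 5-10, 10-15 mm), closest-depth MAE +/- SD, and the
#' coefficient of determination of predicted vs true closest depths about
#' the line of equality.
#'
#' @slot depthMAE,depthSD overall per-pixel depth error stats, mm.
#' @slot concMAE,concSD concentration error stats, ug/ml.
#' @slot binnedMAE,binnedSD named vectors for the three depth bins.
#' @slot closestMAE,closestSD closest-depth error stats, mm.
#' @slot r2 coefficient of determination about y = x.
#' @slot perCase data.frame with one row per test case.
#' @export
setClass("EvalReport",
  representation(depthMAE = "numeric", depthSD = "numeric",
                 concMAE = "numeric", concSD = "numeric",
                 binnedMAE = "numeric", binnedSD = "numeric",
                 closestMAE = "numeric", closestSD = "numeric",
                 r2 = "numeric", perCase = "data.frame"))

#' Network specification
#'
#' An instantiated trainable model: the architecture configuration, the
#' parameter tensors, and the exact trainable-parameter count.
#'
#' @slot config the configuration list from [netConfig()].
#' @slot params named list of parameter arrays.
#' @slot parameterCount total number of trainable scalars.
#' @export
setClass("NetworkSpec",
  representation(config = "list", params = "list",
                 parameterCount = "numeric"))

setValidity("NetworkSpec", function(object) {
  n <- sum(vapply(object@params, length, numeric(1)))
  if (n != object@parameterCount)
    return("parameterCount must equal the summed element counts")
  TRUE
})
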