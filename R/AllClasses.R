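#' @import methods
NULL

#' Single conformer of a molecule
#'
#' Holds one 3-D structure: element symbols, Cartesian coordinates in
#' Angstrom, per-atom van der Waals radii and a relative energy in
#' kcal/mol. Radii are stored per atom (rather than looked up on demand)
#' so that toy structures and user overrides can carry non-tabulated
#' values.
#'
#' @slot elements character vector of element symbols.
#' @slot coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @slot radii numeric vector of van der Waals radii (Angstrom).
#' @slot energy numeric scalar, energy in kcal/mol (relative energies
#'   are fine; only differences matter for Boltzmann weighting).
#' @slot label character scalar naming the conformer.
#' @export
setClass("Conformer",
  representation(
    elements = "character",
    coords = "matrix",
    radii = "numeric",
    energy = "numeric",
    label = "character"
  )
)

setValidity("Conformer", function(object) {
  msg <- character()
  n <- length(object@elements)
  if (n < 1L) msg <- c(msg, "a conformer needs at least one atom")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n)
    msg <- c(msg, "coords must be a numeric n x 3 matrix matching elements")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@radii) != n || any(!is.finite(object@radii)) ||
      any(object@radii <= 0))
    msg <- c(msg, "radii must be positive and finite, one per atom")
  if (length(object@energy) != 1L || !is.finite(object@energy))
    msg <- c(msg, "energy must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Boltzmann-weighted conformer ensemble
#'
#' A list of \linkS4class{Conformer} objects sharing atom count and
#' element order, with per-conformer Boltzmann probabilities at a stated
#' temperature. Weights are recomputed on construction and always sum to
#' one.
#'
#' @slot conformers list of \linkS4class{Conformer}.
#' @slot temperature numeric, Kelvin.
#' @slot weights numeric vector of per-conformer probabilities.
#' @export
setClass("ConformerEnsemble",
  representation(
    conformers = "list",
    temperature = "numeric",
    weights = "numeric"
  )
)

setValidity("ConformerEnsemble", function(object) {
  msg <- character()
  k <- length(object@conformers)
  if (k < 1L) msg <- c(msg, "ensemble needs at least one conformer")
  if (!all(vapply(object@conformers, is, logical(1), "Conformer")))
    msg <- c(msg, "conformers must all be Conformer objects")
  if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive number (K)")
  if (length(object@weights) != k)
    msg <- c(msg, "one weight per conformer required")
  else {
    if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1 within 1e-9")
  }
  if (k >= 1L && length(msg) == 0L) {
    el <- object@conformers[[1L]]@elements
    same <- vapply(object@conformers, function(cf)
      identical(cf@elements, el), logical(1))
    if (!all(same))
      msg <- c(msg, "all conformers must share atom count and element order")
  }
  if (length(msg)) msg else TRUE
})

#' Axial pocket reference frame
#'
#' Defines one of the two axial reactive sites of a paddlewheel
#' dirhodium core: the binding metal position and a unit axis pointing
#' from the non-binding metal through the binding metal into the pocket.
#'
#' @slot center numeric length-3, binding metal position (Angstrom).
#' @slot axis numeric length-3 unit vector into the pocket.
#' @slot siteId integer, 1 or 2.
#' @export
setClass("PocketFrame",
  representation(center = "numeric", axis = "numeric", siteId = "integer")
)

setValidity("PocketFrame", function(object) {
  msg <- character()
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite 3-vector")
  if (length(object@axis) != 3L || any(!is.finite(object@axis)))
    msg <- c(msg, "axis must be a finite 3-vector")
  else if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9)
    msg <- c(msg, "axis must be a unit vector within 1e-9")
  if (!object@siteId %in% c(1L, 2L)) msg <- c(msg, "siteId must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Probe-sphere cavity specification
#'
#' Geometry of the axial-pocket probe: the probe sphere sits at distance
#' \code{probeOffset} from the binding metal along the pocket axis with
#' radius \code{cavityRadius}; points closer than \code{proximalCutoff}
#' (axial distance from the binding metal) count as proximal; the grid
#' spacing controls the voxel resolution.
#'
#' @slot probeOffset numeric, d in Angstrom (> 0).
#' @slot cavityRadius numeric, R in Angstrom (> 0).
#' @slot proximalCutoff numeric, p in Angstrom, 0 < p < d + R.
#' @slot gridSpacing numeric, h in Angstrom, 0 < h <= R/5.
#' @export
setClass("CavitySpec",
  representation(
    probeOffset = "numeric",
    cavityRadius = "numeric",
    proximalCutoff = "numeric",
    gridSpacing = "numeric"
  )
)

setValidity("CavitySpec", function(object) {
  d <- object@probeOffset; R <- object@cavityRadius
  p <- object@proximalCutoff; h <- object@gridSpacing
  msg <- character()
  ok1 <- function(x) length(x) == 1L && is.finite(x)
  if (!ok1(d) || d <= 0) msg <- c(msg, "probeOffset must be > 0")
  if (!ok1(R) || R <= 0) msg <- c(msg, "cavityRadius must be > 0")
  if (!ok1(p) || p <= 0 || (ok1(d) && ok1(R) && p >= d + R))
    msg <- c(msg, "proximalCutoff must satisfy 0 < p < d + R")
  if (!ok1(h) || h <= 0 || (ok1(R) && h > R / 5))
    msg <- c(msg, "gridSpacing must satisfy 0 < h <= R/5")
  if (length(msg)) msg else TRUE
})

#' Shadow (solid-angle shielding) specification
#'
#' Controls the deterministic Fibonacci-sphere direction set used for
#' G% style shielding descriptors, the center atom the rays emanate
#' from, and the radius rule for the encompassing sphere used by the
#' G% surface descriptor.
#'
#' @slot nDirections integer, number of deterministic directions
#'   (>= 1000; default 20000).
#' @slot centerAtom integer index of the center atom.
#' @slot sphereRadius numeric; \code{NA} means the encompassing rule
#'   (max over atoms of distance-from-center + vdW radius), otherwise a
#'   fixed radius in Angstrom.
#' @slot exclude integer indices of atoms that do not shield (optional).
#' @export
setClass("ShadowSpec",
  representation(
    nDirections = "integer",
    centerAtom = "integer",
    sphereRadius = "numeric",
    exclude = "integer"
  ),
  prototype(nDirections = 20000L, centerAtom = 1L,
            sphereRadius = NA_real_, exclude = integer())
)

setValidity("ShadowSpec", function(object) {
  msg <- character()
  if (length(object@nDirections) != 1L || object@nDirections < 1000L)
    msg <- c(msg, "nDirections must be a single integer >= 1000")
  if (length(object@centerAtom) != 1L || object@centerAtom < 1L)
    msg <- c(msg, "centerAtom must be a positive atom index")
  if (length(object@sphereRadius) != 1L ||
      (!is.na(object@sphereRadius) && object@sphereRadius <= 0))
    msg <- c(msg, "sphereRadius must be NA (encompassing) or > 0")
  if (length(msg)) msg else TRUE
})

#' Configuration of the nonlinear feature expansion and model search
#'
#' @slot rung integer expansion depth (default 2).
#' @slot operators character subset of
#'   \code{c("add","sub","mul","div","sq","inv","sqrt","abs")}.
#' @slot sisSize integer, features screened into the pool per round
#'   (default 50).
#' @slot maxDimension integer, largest model size D searched (default 4).
#' @slot dedupR numeric, |r| above which two features are treated as the
#'   same feature (default 0.9999).
#' @slot maxFeatures integer cap on the expanded feature count.
#' @slot maxSubsets numeric cap on the exhaustive subset search size.
#' @export
setClass("SissoConfig",
  representation(
    rung = "integer",
    operators = "character",
    sisSize = "integer",
    maxDimension = "integer",
    dedupR = "numeric",
    maxFeatures = "integer",
    maxSubsets = "numeric"
  ),
  prototype(
    rung = 2L,
    operators = c("add", "sub", "mul", "div", "sq", "inv", "sqrt", "abs"),
    sisSize = 50L,
    maxDimension = 4L,
    dedupR = 0.9999,
    maxFeatures = 200000L,
    maxSubsets = 5e6
  )
)

setValidity("SissoConfig", function(object) {
  msg <- character()
  allowed <- c("add", "sub", "mul", "div", "sq", "inv", "sqrt", "abs")
  if (object@rung < 0L) msg <- c(msg, "rung must be >= 0")
  if (!length(object@operators) || !all(object@operators %in% allowed))
    msg <- c(msg, paste("operators must be among:",
                        paste(allowed, collapse = ", ")))
  if (object@maxDimension < 1L) msg <- c(msg, "maxDimension must be >= 1")
  if (object@sisSize < object@maxDimension)
    msg <- c(msg, "sisSize must be >= maxDimension")
  if (object@dedupR <= 0 || object@dedupR > 1)
    msg <- c(msg, "dedupR must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Reaction model matrix
#'
#' Rows are catalyst x substrate reactions, columns are role-prefixed
#' descriptors, and the response is the activation free-energy
#' difference in kcal/mol (negative = syn-selective).
#'
#' @slot features numeric matrix (rows = reactions).
#' @slot response numeric vector of ddG values (kcal/mol).
#' @slot catalystId character vector of catalyst ids per row.
#' @slot substrateId character vector of substrate ids per row.
#' @slot meta list: dropped-row log, scaling record, provenance.
#' @export
setClass("ModelMatrix",
  representation(
    features = "matrix",
    response = "numeric",
    catalystId = "character",
    substrateId = "character",
    meta = "list"
  ),
  prototype(meta = list())
)

setValidity("ModelMatrix", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (is.null(colnames(object@features)))
    msg <- c(msg, "feature columns must be named")
  if (length(object@response) != n)
    msg <- c(msg, "response length must equal the number of rows")
  if (length(object@catalystId) != n || length(object@substrateId) != n)
    msg <- c(msg, "catalystId/substrateId must have one entry per row")
  if (anyDuplicated(colnames(object@features)))
    msg <- c(msg, "duplicate feature column names")
  if (length(msg)) msg else TRUE
})

#' Fitted sparse nonlinear selectivity model
#'
#' A small set of generated nonlinear features (expression trees over
#' base descriptors) with ordinary least-squares coefficients, the
#' scaling records needed to predict raw inputs, and training metrics.
#'
#' @slot exprs list of feature expression trees.
#' @slot featureNames character canonical strings, one per feature.
#' @slot coefficients numeric, one per feature (feature-value scale).
#' @slot intercept numeric scalar.
#' @slot baseScaling list with \code{mean} and \code{sd} per base
#'   descriptor column (applied before expression evaluation).
#' @slot dimension integer, number of terms.
#' @slot metrics list: \code{r2_train}, \code{rmse_train}, \code{n}.
#' @slot provenance list: config echo, split id, seed, pool sizes.
#' @export
setClass("SissoModel",
  representation(
    exprs = "list",
    featureNames = "character",
    coefficients = "numeric",
    intercept = "numeric",
    baseScaling = "list",
    dimension = "integer",
    metrics = "list",
    provenance = "list"
  ),
  prototype(metrics = list(), provenance = list())
)

setValidity("SissoModel", function(object) {
  msg <- character()
  d <- object@dimension
  if (length(object@exprs) != d || length(object@coefficients) != d ||
      length(object@featureNames) != d)
    msg <- c(msg, "exprs, featureNames and coefficients must have length = dimension")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Principal-component chemical space map
#'
#' @slot loadings numeric matrix (columns = PCs), deterministic sign
#'   convention: the largest-magnitude element of each loading vector is
#'   positive.
#' @slot scores numeric matrix of projected samples.
#' @slot explained numeric, percent variance per PC over all PCs
#'   (sums to 100).
#' @slot columns character, input column names used.
#' @slot scaling list with per-column center and scale.
#' @export
setClass("ChemSpaceMap",
  representation(
    loadings = "matrix",
    scores = "matrix",
    explained = "numeric",
    columns = "character",
    scaling = "list"
  )
)

setValidity("ChemSpaceMap", function(object) {
  msg <- character()
  if (any(diff(object@explained) > 1e-8))
    msg <- c(msg, "explained variance must be non-increasing across PCs")
  if (abs(sum(object@explained) - 100) > 1e-6)
    msg <- c(msg, "explained variance must sum to 100%")
  if (length(msg)) msg else TRUE
})
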