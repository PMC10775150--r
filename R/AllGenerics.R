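#' @include AllClasses.R
NULL

#' @export
setGeneric("conformers", function(x) standardGeneric("conformers"))
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))
#' @export
setGeneric("weights")
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setGeneric("response", function(x) standardGeneric("response"))

#' Accessors for conformer ensembles
#'
#' \code{conformers} returns the list of \linkS4class{Conformer}
#' objects, \code{nConformers} their number, \code{energies} the
#' per-conformer energies (kcal/mol), \code{temperature} the ensemble
#' temperature (K) and \code{weights} the Boltzmann probabilities.
#'
#' @param x,object a \linkS4class{ConformerEnsemble}.
#' @return See the individual descriptions.
#' @name ensemble-accessors
#' @aliases conformers nConformers energies temperature
#'   weights,ConformerEnsemble-method
NULL

#' @rdname ensemble-accessors
#' @export
setMethod("conformers", "ConformerEnsemble", function(x) x@conformers)

#' @rdname ensemble-accessors
#' @export
setMethod("nConformers", "ConformerEnsemble",
          function(x) length(x@conformers))

#' @rdname ensemble-accessors
#' @export
setMethod("energies", "ConformerEnsemble", function(x)
  vapply(x@conformers, function(cf) cf@energy, numeric(1)))

#' @rdname ensemble-accessors
#' @export
setMethod("temperature", "ConformerEnsemble", function(x) x@temperature)

#' @rdname ensemble-accessors
#' @export
setMethod("weights", "ConformerEnsemble", function(object) object@weights)

#' Accessors for model matrices
#'
#' \code{featureMatrix} returns the descriptor matrix (rows =
#' reactions), \code{response} the ddG vector in kcal/mol.
#'
#' @param x a \linkS4class{ModelMatrix}.
#' @name modelmatrix-accessors
#' @aliases featureMatrix response
NULL

#' @rdname modelmatrix-accessors
#' @export
setMethod("featureMatrix", "ModelMatrix", function(x) x@features)

#' @rdname modelmatrix-accessors
#' @export
setMethod("response", "ModelMatrix", function(x) x@response)

setMethod("show", "Conformer", function(object) {
  cat(sprintf("Conformer '%s': %d atoms, E = %.4f kcal/mol\n",
              object@label, length(object@elements), object@energy))
})

setMethod("show", "ConformerEnsemble", function(object) {
  e <- energies(object)
  cat(sprintf(
    "ConformerEnsemble: %d conformers x %d atoms at %.2f K\n",
    nConformers(object), length(object@conformers[[1]]@elements),
    object@temperature))
  cat(sprintf("  relative energies [%.3f, %.3f] kcal/mol; max weight %.3f\n",
              min(e) - min(e), max(e) - min(e), max(object@weights)))
})

setMethod("show", "PocketFrame", function(object) {
  cat(sprintf("PocketFrame site %d: center (%.3f, %.3f, %.3f), axis (%.3f, %.3f, %.3f)\n",
              object@siteId, object@center[1], object@center[2],
              object@center[3], object@axis[1], object@axis[2],
              object@axis[3]))
})

setMethod("show", "ModelMatrix", function(object) {
  cat(sprintf("ModelMatrix: %d reactions x %d descriptors\n",
              nrow(object@features), ncol(object@features)))
  cat(sprintf("  response ddG in [%.3f, %.3f] kcal/mol\n",
              min(object@response), max(object@response)))
  if (!is.null(object@meta$dropped) && object@meta$dropped > 0)
    cat(sprintf("  %d reactions dropped for missing descriptors\n",
                object@meta$dropped))
})

setMethod("show", "SissoModel", function(object) {
  cat(sprintf("SissoModel with %d term(s); training R2 = %.4f, RMSE = %.4f\n",
              object@dimension,
              object@metrics$r2_train, object@metrics$rmse_train))
  cat(sprintf("  y = %.4g", object@intercept))
  for (i in seq_len(object@dimension))
    cat(sprintf(" %+.4g * %s", object@coefficients[i],
                object@featureNames[i]))
  cat("\n")
})

setMethod("show", "ChemSpaceMap", function(object) {
  cat(sprintf("ChemSpaceMap: %d samples, %d PCs\n",
              nrow(object@scores), ncol(object@scores)))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", object@explained[seq_len(min(4, length(object@explained)))]),
            collapse = ", "), "\n")
})
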