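#' @name accessors
#' @title Accessors for fluxContext classes
#'
#' @description Accessor generics for the package's S4 containers:
#' `reactions()`, `metabolites()`, `modelGenes()`, `objectiveReaction()`,
#' `stoichiometricMatrix()`, `bounds()`, `fluxes()`, `objectiveValue()`,
#' `activeReactions()`, `contextModel()`, `inconsistencyScore()`,
#' `deltaV()`, `alteredReactions()`, `alteredGenes()`, `reactionValues()`.
#'
#' @param object An object of the appropriate class.
#' @return The slot contents (see each class's documentation).
#' @examples
#' m <- exampleChainModel()
#' reactions(m)$id
#' objectiveReaction(m)
NULL

#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @rdname accessors
#' @export
setGeneric("objectiveReaction", function(object) standardGeneric("objectiveReaction"))
#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix", function(object) standardGeneric("stoichiometricMatrix"))
#' @rdname accessors
#' @export
setGeneric("bounds", function(object) standardGeneric("bounds"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("activeReactions", function(object) standardGeneric("activeReactions"))
#' @rdname accessors
#' @export
setGeneric("contextModel", function(object) standardGeneric("contextModel"))
#' @rdname accessors
#' @export
setGeneric("inconsistencyScore", function(object) standardGeneric("inconsistencyScore"))
#' @rdname accessors
#' @export
setGeneric("deltaV", function(object) standardGeneric("deltaV"))
#' @rdname accessors
#' @export
setGeneric("alteredReactions", function(object) standardGeneric("alteredReactions"))
#' @rdname accessors
#' @export
setGeneric("alteredGenes", function(object) standardGeneric("alteredGenes"))
#' @rdname accessors
#' @export
setGeneric("reactionValues", function(object) standardGeneric("reactionValues"))

#' @rdname accessors
setMethod("reactions", "MetabolicModel", function(object) object@reactions)
#' @rdname accessors
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)
#' @rdname accessors
setMethod("modelGenes", "MetabolicModel", function(object) object@genes)
#' @rdname accessors
setMethod("objectiveReaction", "MetabolicModel", function(object) object@objective)
#' @rdname accessors
setMethod("stoichiometricMatrix", "MetabolicModel", function(object) object@stoichiometry)
#' @rdname accessors
setMethod("bounds", "MetabolicModel", function(object) {
  data.frame(id = object@reactions$id,
             lower_bound = object@reactions$lower_bound,
             upper_bound = object@reactions$upper_bound)
})
#' @rdname accessors
setMethod("fluxes", "FluxVector", function(object) object@flux)
#' @rdname accessors
setMethod("objectiveValue", "FluxVector", function(object) object@objectiveValue)
#' @rdname accessors
setMethod("fluxes", "GimmeResult", function(object) object@flux@flux)
#' @rdname accessors
setMethod("activeReactions", "GimmeResult", function(object) object@activeReactions)
#' @rdname accessors
setMethod("contextModel", "GimmeResult", function(object) object@contextModel)
#' @rdname accessors
setMethod("inconsistencyScore", "GimmeResult", function(object) object@inconsistencyScore)
#' @rdname accessors
setMethod("deltaV", "DeltaFluxResult", function(object) object@deltaV)
#' @rdname accessors
setMethod("alteredReactions", "DeltaFluxResult", function(object) object@alteredReactions)
#' @rdname accessors
setMethod("alteredGenes", "DeltaFluxResult", function(object) object@alteredGenes)
#' @rdname accessors
setMethod("reactionValues", "ReactionData", function(object) object@values)

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel '%s': %d reactions, %d metabolites, %d genes\n",
              object@id, nrow(object@reactions), nrow(object@metabolites),
              length(object@genes)))
  cat(sprintf("  objective: %s   GAM: %g mmol ATP/gDW   NGAM: %g mmol ATP/gDW/h\n",
              object@objective, object@gam, object@ngam))
})

setMethod("show", "FluxVector", function(object) {
  cat(sprintf("FluxVector over %d reactions; objective value %.6g\n",
              length(object@flux), object@objectiveValue))
})

setMethod("show", "ReactionData", function(object) {
  cat(sprintf("ReactionData (%s, sample %s): %d reactions, %d mapped\n",
              object@channel, object@sample, length(object@values),
              sum(!is.na(object@values))))
})

setMethod("show", "GimmeResult", function(object) {
  cat(sprintf(paste0("GimmeResult: inconsistency %.6g, %d active reactions, ",
                     "objective floor %.3g x %.6g\n"),
              object@inconsistencyScore, length(object@activeReactions),
              object@objectiveFraction, object@vOpt))
})

setMethod("show", "DeltaFluxResult", function(object) {
  cat(sprintf(paste0("DeltaFluxResult: %d consistent data reactions, ",
                     "%d altered reactions (|dv| >= %g), %d altered genes\n"),
              object@nConsistent, length(object@alteredReactions),
              object@epsilon, length(object@alteredGenes)))
})

setMethod("show", "FluxComparisonReport", function(object) {
  cat(sprintf("FluxComparisonReport: n = %d, r = %.4f, MSE = %.6g\n",
              object@n, object@pearsonR, object@mse))
  if (length(object@unmatched))
    cat("  unmatched measured ids:", paste(object@unmatched, collapse = ", "), "\n")
})

setMethod("show", "PhaseModels", function(object) {
  cat(sprintf("PhaseModels for phase '%s'\n", object@phase))
  print(object@counts)
})
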