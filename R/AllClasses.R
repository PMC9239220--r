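#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' MetabolicModel: a constraint-based metabolic network
#'
#' Holds the stoichiometric matrix S (metabolites x reactions), flux
#' bounds, GPR rules, the gene list and the objective reaction, plus the
#' growth-associated (GAM, mmol ATP/gDW) and non-growth-associated
#' (NGAM, mmol ATP/gDW/h) maintenance parameters. Reversible reactions
#' are encoded by a negative lower bound; fluxes are in mmol/gDW/h.
#'
#' @slot id Character model identifier.
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`.
#' @slot reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (rule text), `subsystem`.
#' @slot stoichiometry `dgCMatrix`, metabolites x reactions, dimnames set.
#' @slot genes Character vector: exactly the union of GPR leaves.
#' @slot objective Character id of the objective (biomass) reaction.
#' @slot gam,ngam Numeric maintenance parameters (defaults 55.3 and 0.7).
#'
#' @seealso [newMetabolicModel()], [readModelJson()], [solveFBA()]
#' @export
setClass("MetabolicModel",
  representation(
    id            = "character",
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "Matrix",
    genes         = "character",
    objective     = "character",
    gam           = "numeric",
    ngam          = "numeric"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicate reaction ids")
  if (any(!nzchar(met$id))) msgs <- c(msgs, "empty metabolite id")
  if (any(!nzchar(rxn$id))) msgs <- c(msgs, "empty reaction id")
  if (any(rxn$lower_bound > rxn$upper_bound))
    msgs <- c(msgs, "lower_bound > upper_bound for some reaction")
  S <- object@stoichiometry
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msgs <- c(msgs, "stoichiometry dimensions do not match metabolites x reactions")
  else if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    msgs <- c(msgs, "stoichiometry dimnames do not match metabolite/reaction ids")
  if (length(object@objective) != 1L || !(object@objective %in% rxn$id))
    msgs <- c(msgs, "objective reaction not present in the model")
  leaves <- sort(unique(unlist(lapply(rxn$gpr, function(g)
    gprGenes(parseGpr(g))))))
  if (!identical(sort(object@genes), leaves))
    msgs <- c(msgs, "gene list must equal the union of GPR leaves")
  if (length(msgs)) msgs else TRUE
})

#' FluxVector: a steady-state flux distribution
#'
#' A named flux vector over all reactions of a model together with the
#' attained objective value. Every FluxVector returned by a solver in
#' this package satisfies max|S v| <= 1e-6 and the model bounds within
#' 1e-9 (asserted at construction by the solving code).
#'
#' @slot flux Named numeric vector, mmol/gDW/h.
#' @slot objectiveValue Numeric scalar.
#' @slot info List of solver metadata (e.g. `vOpt`, `sumAbsFlux`).
#' @export
setClass("FluxVector",
  representation(flux = "numeric", objectiveValue = "numeric", info = "list"),
  prototype(info = list())
)

setValidity("FluxVector", function(object) {
  if (is.null(names(object@flux)) || anyDuplicated(names(object@flux)))
    return("flux must be a uniquely named numeric vector")
  if (length(object@objectiveValue) != 1L)
    return("objectiveValue must be a scalar")
  TRUE
})

#' ReactionData: reaction-level omics values after GPR mapping
#'
#' A value per model reaction (NA marks unmapped reactions, i.e. no
#' measured gene anywhere in the rule, or no gene association at all)
#' and the provenance of the values.
#'
#' @slot values Named numeric over exactly the model's reaction ids.
#' @slot channel One of `"rna"`, `"atac"`, `"binary"`, `"foldchange"`.
#' @slot sample Sample identifier (may be `NA`).
#' @export
setClass("ReactionData",
  representation(values = "numeric", channel = "character", sample = "character")
)

setValidity("ReactionData", function(object) {
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    return("values must be uniquely named by reaction id")
  if (!object@channel %in% c("rna", "atac", "binary", "foldchange"))
    return("channel must be one of rna/atac/binary/foldchange")
  TRUE
})

#' GimmeResult: outcome of GIMME contextualization
#'
#' @slot flux Canonical inconsistency-optimal [FluxVector-class].
#' @slot inconsistencyScore Optimal penalized flux sum (>= 0).
#' @slot activeReactions Character ids retained in the context model.
#' @slot contextModel The extracted [MetabolicModel-class].
#' @slot vOpt Parent model optimum used for the objective floor.
#' @slot threshold Activity threshold actually applied.
#' @slot objectiveFraction Fraction f of vOpt enforced.
#' @export
setClass("GimmeResult",
  representation(
    flux = "FluxVector", inconsistencyScore = "numeric",
    activeReactions = "character", contextModel = "MetabolicModel",
    vOpt = "numeric", threshold = "numeric", objectiveFraction = "numeric"
  )
)

setValidity("GimmeResult", function(object) {
  if (object@inconsistencyScore < -1e-9)
    return("inconsistencyScore must be nonnegative")
  TRUE
})

#' DeltaFluxResult: differential flux profile between two conditions
#'
#' @slot deltaV Named numeric vector of flux changes (mmol/gDW/h),
#'   satisfying S delta_v = 0 within 1e-6.
#' @slot nConsistent Number of data reactions whose sign constraint is
#'   satisfied at magnitude >= epsilon (the step-1 MILP optimum).
#' @slot consistentReactions Character ids of those reactions.
#' @slot alteredReactions Character ids with |delta_v| >= epsilon.
#' @slot alteredGenes Union of GPR leaf genes over altered reactions.
#' @slot epsilon The threshold used.
#' @export
setClass("DeltaFluxResult",
  representation(
    deltaV = "numeric", nConsistent = "integer",
    consistentReactions = "character", alteredReactions = "character",
    alteredGenes = "character", epsilon = "numeric"
  )
)

#' FluxComparisonReport: predicted vs measured flux agreement
#'
#' @slot matched data.frame with columns `reaction_id`, `predicted`,
#'   `measured` over the common reactions.
#' @slot n Number of matched reactions (>= 4 for any reported r).
#' @slot pearsonR Pearson correlation (NA when a vector has zero
#'   variance; reported as such, not an error).
#' @slot mse Mean squared error (denominator n).
#' @slot unmatched Measured ids absent from the prediction.
#' @export
setClass("FluxComparisonReport",
  representation(
    matched = "data.frame", n = "integer", pearsonR = "numeric",
    mse = "numeric", unmatched = "characterOrNULL"
  )
)

setValidity("FluxComparisonReport", function(object) {
  if (!is.na(object@pearsonR) && object@n < 4L)
    return("a correlation requires at least 4 matched reactions")
  TRUE
})

#' PhaseModels: the per-phase model panel and its flux predictions
#'
#' One metabolic-cycle phase represented by the generic model plus four
#' context models (rna, atac, intersection, union), each with its
#' two-stage FBA flux prediction and Table-1-style content counts.
#'
#' @slot phase Phase label.
#' @slot models Named list of five [MetabolicModel-class] objects
#'   (`generic`, `rna`, `atac`, `intersection`, `union`).
#' @slot fluxes Named list of five [FluxVector-class] objects.
#' @slot counts data.frame with reactions/metabolites/genes per model.
#' @export
setClass("PhaseModels",
  representation(phase = "character", models = "list", fluxes = "list",
                 counts = "data.frame")
)
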