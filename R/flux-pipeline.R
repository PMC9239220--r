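#' Simulation configuration for the two-stage FBA
#'
#' @param glucoseUptake Maximum glucose uptake, mmol/gDW/h (default
#'   1.45); applied to `glucoseExchange` when that reaction exists.
#' @param growthSlack Allowed relative decrease of growth in stage 2
#'   (default 0.1: growth stays within \[0.9 V_opt, V_opt\]).
#' @param medium Optional named vector exchange-id -> maximum uptake.
#'   When given, source exchanges not listed are closed (minimal-medium
#'   semantics); sinks are untouched.
#' @param includeExchanges Should stage 2 also minimize exchange fluxes?
#'   Default `FALSE`: the minimized sum covers intracellular fluxes
#'   only (exchanges still settle by mass balance).
#' @param glucoseExchange Id of the glucose source exchange (default
#'   `"EX_glc"`).
#' @return Named list of configuration values.
#' @export
simulationConfig <- function(glucoseUptake = 1.45, growthSlack = 0.1,
                             medium = NULL, includeExchanges = FALSE,
                             glucoseExchange = "EX_glc") {
  if (glucoseUptake <= 0) stop("glucoseUptake must be positive")
  if (growthSlack < 0 || growthSlack >= 1) stop("growthSlack must be in [0, 1)")
  list(glucoseUptake = glucoseUptake, growthSlack = growthSlack,
       medium = medium, includeExchanges = includeExchanges,
       glucoseExchange = glucoseExchange)
}

.applyMedium <- function(model, config) {
  rxn <- model@reactions
  if (!is.null(config$medium)) {
    S <- model@stoichiometry
    nmet <- Matrix::colSums(S != 0)
    produces <- Matrix::colSums(S > 0)
    sources <- rxn$id[nmet == 1 & produces == 1]
    for (id in sources) {
      j <- match(id, rxn$id)
      rxn$upper_bound[j] <- if (id %in% names(config$medium))
        config$medium[[id]] else 0
    }
  }
  if (!is.null(config$glucoseExchange) &&
      config$glucoseExchange %in% rxn$id) {
    j <- match(config$glucoseExchange, rxn$id)
    rxn$upper_bound[j] <- config$glucoseUptake
  }
  model@reactions <- rxn
  validObject(model)
  model
}

#' Two-stage flux balance analysis
#'
#' Stage 1 maximizes growth (`V_opt`). Stage 2 constrains growth to
#' `[(1 - slack) V_opt, V_opt]` and minimizes the sum of absolute
#' intracellular fluxes (split-variable formulation), narrowing the
#' solution space to a parsimonious flux distribution.
#'
#' @param model A [MetabolicModel-class].
#' @param config See [simulationConfig()]; medium/glucose bounds are
#'   applied before solving.
#' @return A [FluxVector-class]; `info` holds `vOpt`, `sumAbsFlux`
#'   (over all reactions) and `sumAbsInternal` (the minimized
#'   objective's scope). If `V_opt` is zero a warning is issued and the
#'   all-zero flux is returned.
#' @examples
#' m <- exampleChainModel()
#' fv <- twoStepFBA(m, simulationConfig(glucoseExchange = NULL))
#' objectiveValue(fv)  # growth at the stage-2 lower bound, 9
#' @export
twoStepFBA <- function(model, config = simulationConfig()) {
  model <- .applyMedium(model, config)
  rxn <- model@reactions
  n <- nrow(rxn)
  stage1 <- solveFBA(model)
  vOpt <- objectiveValue(stage1)
  if (vOpt <= .tol$zero) {
    warning("V_opt is zero; stage 2 skipped, returning the all-zero flux")
    return(new("FluxVector",
               flux = stats::setNames(rep(0, n), rxn$id),
               objectiveValue = 0,
               info = list(vOpt = vOpt, sumAbsFlux = 0, sumAbsInternal = 0)))
  }
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  iobj <- match(model@objective, rxn$id)
  lb[iobj] <- max(lb[iobj], (1 - config$growthSlack) * vOpt)
  ub[iobj] <- min(ub[iobj], vOpt)
  S <- model@stoichiometry
  m <- nrow(S)
  lo <- c(pmax(lb, 0), pmax(-ub, 0))
  hi <- c(pmax(ub, 0), pmax(-lb, 0))
  A <- cbind(S, -S)
  cost <- rep(1, n)
  if (!config$includeExchanges)
    cost[rxn$id %in% exchangeReactions(model)] <- 0
  obj <- c(cost, cost)
  s2 <- .solveLP(obj, A, rep("=", m), rep(0, m), lo, hi, sense = "min")
  v <- stats::setNames(s2$x[seq_len(n)] - s2$x[n + seq_len(n)], rxn$id)
  .assertFluxVector(model, v)
  new("FluxVector", flux = v, objectiveValue = unname(v[iobj]),
      info = list(vOpt = vOpt,
                  sumAbsFlux = sum(abs(v)),
                  sumAbsInternal = sum(abs(v) * (cost > 0))))
}

#' Build and simulate the four context models of one phase
#'
#' For one phase of the metabolic cycle: averages the phase's replicate
#' samples per channel, maps them to reactions, extracts the RNA- and
#' ATAC-based context models with [gimme()], forms the intersection and
#' union binary vectors from the two active sets and contextualizes
#' them with [contextualizeBinary()], then runs [twoStepFBA()] on all
#' four context models plus the generic model.
#'
#' @param model Generic [MetabolicModel-class].
#' @param rna,atac Omics tables (genes x samples) sharing the phase's
#'   sample ids.
#' @param samples Character vector of replicate sample ids for this
#'   phase (present in both tables).
#' @param phase Phase label (e.g. `"midOX"`).
#' @param gimmeCfg See [gimmeConfig()].
#' @param simCfg See [simulationConfig()].
#' @return A [PhaseModels-class] with models, fluxes and
#'   reaction/metabolite/gene counts per model variant.
#' @export
runPhase <- function(model, rna, atac, samples, phase = samples[1],
                     gimmeCfg = gimmeConfig(), simCfg = simulationConfig()) {
  mrna <- .omicsMatrix(rna); matac <- .omicsMatrix(atac)
  if (!all(samples %in% colnames(mrna)) || !all(samples %in% colnames(matac)))
    stop("all phase samples must be present in both omics tables")
  grouping <- stats::setNames(rep(phase, length(samples)), samples)
  avg_rna <- averageReplicates(mrna[, samples, drop = FALSE], grouping)
  avg_atac <- averageReplicates(matac[, samples, drop = FALSE], grouping)
  d_rna <- mapSampleToReactions(model, avg_rna, phase, channel = "rna")
  d_atac <- mapSampleToReactions(model, avg_atac, phase, channel = "atac")
  g_rna <- gimme(model, d_rna, gimmeCfg)
  g_atac <- gimme(model, d_atac, gimmeCfg)
  b_int <- combineActivity(activeReactions(g_rna), activeReactions(g_atac),
                           "intersection", model)
  b_uni <- combineActivity(activeReactions(g_rna), activeReactions(g_atac),
                           "union", model)
  g_int <- contextualizeBinary(model, b_int, gimmeCfg$objectiveFraction)
  g_uni <- contextualizeBinary(model, b_uni, gimmeCfg$objectiveFraction)
  models <- list(generic = model,
                 rna = contextModel(g_rna), atac = contextModel(g_atac),
                 intersection = contextModel(g_int),
                 union = contextModel(g_uni))
  fluxes <- lapply(models, twoStepFBA, config = simCfg)
  counts <- do.call(rbind, lapply(names(models), function(nm) {
    mm <- models[[nm]]
    data.frame(model = nm, reactions = nrow(mm@reactions),
               metabolites = nrow(mm@metabolites),
               genes = length(mm@genes))
  }))
  new("PhaseModels", phase = phase, models = models, fluxes = fluxes,
      counts = counts)
}

#' Write a flux table
#'
#' @param flux A [FluxVector-class].
#' @param model The model it belongs to (for bounds).
#' @param path Output TSV path (`reaction_id`, `flux`, `lb`, `ub`).
#' @return `path`, invisibly.
#' @export
writeFluxTable <- function(flux, model, path) {
  rxn <- model@reactions
  df <- data.frame(reaction_id = rxn$id,
                   flux = unname(flux@flux[rxn$id]),
                   lb = rxn$lower_bound, ub = rxn$upper_bound)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
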