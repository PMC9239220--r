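#' Construct a MetabolicModel
#'
#' Builds the S4 model from per-reaction stoichiometries. The gene list
#' is derived as the union of GPR leaves; the stoichiometric matrix is
#' assembled sparse (metabolites x reactions, negative = consumed).
#'
#' @param id Model identifier.
#' @param metabolites data.frame with columns `id`, `name`,
#'   `compartment` (missing `name`/`compartment` default to the id and
#'   `"c"`).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem` (missing optional columns get
#'   defaults: name = id, bounds 0/1000, empty gpr, empty subsystem).
#' @param stoichiometry Named list (one entry per reaction id) of named
#'   numeric vectors metabolite-id -> coefficient.
#' @param objective Reaction id of the objective.
#' @param gam,ngam Maintenance parameters (defaults 55.3 mmol ATP/gDW
#'   and 0.7 mmol ATP/gDW/h).
#' @return A validated [MetabolicModel-class].
#' @examples
#' m <- exampleChainModel()
#' m
#' @export
newMetabolicModel <- function(id, metabolites, reactions, stoichiometry,
                              objective, gam = 55.3, ngam = 0.7) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lower_bound)) reactions$lower_bound <- 0
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- 1000
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  metabolites <- metabolites[, c("id", "name", "compartment")]
  reactions <- reactions[, c("id", "name", "lower_bound", "upper_bound",
                             "gpr", "subsystem")]
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))

  missing_sto <- setdiff(reactions$id, names(stoichiometry))
  if (length(missing_sto))
    stop("no stoichiometry given for reaction: ",
         paste(missing_sto, collapse = ", "))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_len(nrow(reactions))) {
    st <- stoichiometry[[reactions$id[j]]]
    if (length(st) == 0L) next
    unknown <- setdiff(names(st), metabolites$id)
    if (length(unknown))
      stop(sprintf("reaction '%s' references unknown metabolite '%s'",
                   reactions$id[j], unknown[1]))
    ii <- c(ii, match(names(st), metabolites$id))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  genes <- sort(unique(unlist(lapply(reactions$gpr,
                                     function(g) gprGenes(parseGpr(g))))))
  if (is.null(genes)) genes <- character()
  new("MetabolicModel", id = id, metabolites = metabolites,
      reactions = reactions, stoichiometry = S, genes = genes,
      objective = objective, gam = gam, ngam = ngam)
}

#' Per-reaction stoichiometry as a named list
#' @param model A [MetabolicModel-class].
#' @return Named list reaction-id -> named numeric coefficient vector.
#' @export
reactionStoichiometry <- function(model) {
  S <- model@stoichiometry
  out <- lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    col[col != 0]
  })
  names(out) <- colnames(S)
  out
}

#' Remove reactions and prune orphans
#'
#' Drops the given reactions, then removes metabolites no longer
#' referenced by any remaining reaction and genes no longer appearing in
#' any remaining GPR rule. The objective reaction cannot be removed.
#'
#' @param model A [MetabolicModel-class].
#' @param reactionIds Ids to drop.
#' @return The reduced, still-valid [MetabolicModel-class].
#' @export
removeReactions <- function(model, reactionIds) {
  unknown <- setdiff(reactionIds, model@reactions$id)
  if (length(unknown))
    stop("unknown reaction id: ", paste(unknown, collapse = ", "))
  if (model@objective %in% reactionIds)
    stop("cannot remove the objective reaction '", model@objective, "'")
  keep <- !(model@reactions$id %in% reactionIds)
  rxn <- model@reactions[keep, , drop = FALSE]
  S <- model@stoichiometry[, keep, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  met <- model@metabolites[used, , drop = FALSE]
  S <- S[used, , drop = FALSE]
  genes <- sort(unique(unlist(lapply(rxn$gpr, function(g) gprGenes(parseGpr(g))))))
  if (is.null(genes)) genes <- character()
  rownames(rxn) <- NULL; rownames(met) <- NULL
  new("MetabolicModel", id = model@id, metabolites = met, reactions = rxn,
      stoichiometry = S, genes = genes, objective = model@objective,
      gam = model@gam, ngam = model@ngam)
}

#' Identify exchange reactions
#'
#' An exchange (boundary) reaction touches exactly one metabolite: a
#' source produces it (+1-signed coefficient), a sink consumes it.
#'
#' @param model A [MetabolicModel-class].
#' @return Character vector of exchange reaction ids.
#' @export
exchangeReactions <- function(model) {
  S <- model@stoichiometry
  n_met <- Matrix::colSums(S != 0)
  colnames(S)[n_met == 1]
}

#' A minimal three-reaction chain model
#'
#' Substrate exchange (bounds 0..10) feeding a conversion feeding the
#' objective sink; used in examples and as the smallest well-understood
#' FBA instance (optimum 10, the exchange bottleneck).
#'
#' @param ub Upper bound of the substrate exchange (default 10).
#' @param gpr GPR rule for the internal conversion (default `"g1"`).
#' @return A [MetabolicModel-class].
#' @export
exampleChainModel <- function(ub = 10, gpr = "g1") {
  newMetabolicModel(
    id = "chain",
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(
      id = c("EX_A", "R1", "GROW"),
      lower_bound = c(0, 0, 0),
      upper_bound = c(ub, 1000, 1000),
      gpr = c("", gpr, "")
    ),
    stoichiometry = list(
      EX_A = c(A = 1),
      R1 = c(A = -1, B = 1),
      GROW = c(B = -1)
    ),
    objective = "GROW"
  )
}
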