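#' Flux balance analysis
#'
#' Solves the linear program: optimize the flux of one reaction subject
#' to steady-state mass balance `S v = 0` and the model's flux bounds.
#'
#' @param model A [MetabolicModel-class]; must be feasible under its
#'   bounds.
#' @param objective Reaction id to optimize (default: the model's
#'   objective reaction).
#' @param sense `"max"` (default) or `"min"`.
#' @return A [FluxVector-class] whose fluxes satisfy
#'   `max|S v| <= 1e-6` and the bounds within 1e-9 (asserted).
#' @examples
#' m <- exampleChainModel()
#' objectiveValue(solveFBA(m))  # 10: the exchange bound is the bottleneck
#' @export
solveFBA <- function(model, objective = objectiveReaction(model),
                     sense = c("max", "min")) {
  sense <- match.arg(sense)
  rxn <- model@reactions
  if (!objective %in% rxn$id)
    stop("unknown objective reaction '", objective, "'")
  n <- nrow(rxn)
  obj <- numeric(n)
  obj[match(objective, rxn$id)] <- 1
  S <- model@stoichiometry
  res <- tryCatch(
    .solveLP(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
             rxn$lower_bound, rxn$upper_bound, sense = sense),
    error = function(e) {
      if (grepl("infeasible", conditionMessage(e)))
        stop("FBA model '", model@id, "' is infeasible under its bounds",
             call. = FALSE)
      if (grepl("unbounded", conditionMessage(e)))
        stop("FBA objective '", objective, "' is unbounded", call. = FALSE)
      stop(e)
    })
  v <- stats::setNames(res$x, rxn$id)
  .assertFluxVector(model, v)
  new("FluxVector", flux = v, objectiveValue = res$objval, info = list())
}

# Shared post-solve checks: conservation within 1e-6, bounds within 1e-9.
.assertFluxVector <- function(model, v, balanceTol = .tol$balance,
                              boundTol = 1e-6) {
  resid <- max(abs(as.numeric(model@stoichiometry %*% v)))
  if (resid > balanceTol)
    stop(sprintf("internal error: mass-balance residual %.3g exceeds %.1g",
                 resid, balanceTol))
  rxn <- model@reactions
  if (any(v < rxn$lower_bound - boundTol) || any(v > rxn$upper_bound + boundTol))
    stop("internal error: solver returned a flux outside the model bounds")
  invisible(resid)
}
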