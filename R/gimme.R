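#' GIMME configuration
#'
#' @param threshold Absolute activity threshold in reaction-value units,
#'   or `NULL` (default) to use the percentile rule.
#' @param thresholdPercentile Percentile (default 25) of the mapped
#'   reaction values of the sample, used when `threshold` is `NULL`.
#' @param objectiveFraction Fraction f in (0, 1] (default 0.5) of the
#'   parent model's optimum that the context must still attain.
#' @param activityTolerance Absolute flux above which a reaction counts
#'   as flux-carrying (default 1e-6).
#' @return Named list of class-free configuration values.
#' @export
gimmeConfig <- function(threshold = NULL, thresholdPercentile = 25,
                        objectiveFraction = 0.5, activityTolerance = 1e-6) {
  if (objectiveFraction <= 0 || objectiveFraction > 1)
    stop("objectiveFraction must be in (0, 1]")
  list(threshold = threshold, thresholdPercentile = thresholdPercentile,
       objectiveFraction = objectiveFraction,
       activityTolerance = activityTolerance)
}

# Split-variable GIMME LP. Returns list(v, score) for penalties cj >= 0.
.gimmeLP <- function(model, penalties, floorValue) {
  rxn <- model@reactions
  n <- nrow(rxn)
  S <- model@stoichiometry
  m <- nrow(S)
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  # v = vplus - vminus; bounds encode [lb, ub] exactly
  lo <- c(pmax(lb, 0), pmax(-ub, 0))
  hi <- c(pmax(ub, 0), pmax(-lb, 0))
  A <- cbind(S, -S)
  dir <- rep("=", m)
  rhs <- rep(0, m)
  iobj <- match(model@objective, rxn$id)
  floor_row <- numeric(2 * n)
  floor_row[iobj] <- 1
  floor_row[n + iobj] <- -1
  A <- rbind(A, floor_row)
  dir <- c(dir, ">=")
  rhs <- c(rhs, floorValue)

  obj1 <- c(penalties, penalties)
  s1 <- tryCatch(
    .solveLP(obj1, A, dir, rhs, lo, hi, sense = "min"),
    error = function(e) {
      if (grepl("infeasible", conditionMessage(e)))
        stop(sprintf("objective-fraction constraint infeasible: cannot attain %.6g",
                     floorValue), call. = FALSE)
      stop(e)
    })
  iStar <- s1$objval
  # canonicalization: with the penalized score fixed at its optimum,
  # minimize total split flux for a deterministic representative
  A2 <- rbind(A, obj1)
  dir2 <- c(dir, "<=")
  rhs2 <- c(rhs, iStar + 1e-9)
  obj2 <- rep(1, 2 * n)
  s2 <- .solveLP(obj2, A2, dir2, rhs2, lo, hi, sense = "min")
  v <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
  names(v) <- rxn$id
  list(v = v, score = iStar)
}

#' GIMME context-specific model extraction
#'
#' Minimizes flux through reactions whose mapped data value lies below
#' the activity threshold, subject to steady state, the model bounds and
#' an objective floor of `f * V_opt`. The three steps are: (1) compute
#' `V_opt` by FBA; (2) solve the penalized LP
#' `min sum_j c_j |v_j|` with `c_j = max(0, T - x_j)` for mapped
#' reactions (unmapped reactions carry no penalty and are always
#' retained), giving the inconsistency score; (3) at that score, minimize
#' total absolute flux so the reported flux vector is a deterministic
#' representative of the optimal face. The active set is
#' `{x_j >= T} U {unmapped} U {|v_j| > activityTolerance}`; the context
#' model is the input model minus inactive reactions, with orphaned
#' metabolites and genes pruned.
#'
#' @param model A feasible [MetabolicModel-class] with positive optimum.
#' @param data A [ReactionData-class] of mapped reaction values.
#' @param config See [gimmeConfig()].
#' @return A [GimmeResult-class].
#' @examples
#' m <- exampleChainModel()
#' d <- mapValuesToReactions(m, c(g1 = 10), channel = "rna")
#' res <- gimme(m, d, gimmeConfig(threshold = 5))
#' inconsistencyScore(res)  # 0: the only route is above threshold
#' @export
gimme <- function(model, data, config = gimmeConfig()) {
  stopifnot(is(data, "ReactionData"))
  x <- data@values[model@reactions$id]
  vOpt <- objectiveValue(solveFBA(model))
  if (vOpt <= .tol$zero)
    stop("GIMME requires a positive model optimum (V_opt = ", vOpt, ")")
  Tval <- if (!is.null(config$threshold)) config$threshold
          else percentileThreshold(x, config$thresholdPercentile)
  penalties <- pmax(0, Tval - x)
  penalties[is.na(penalties)] <- 0
  floorValue <- config$objectiveFraction * vOpt
  sol <- .gimmeLP(model, penalties, floorValue)
  .assertFluxVector(model, sol$v)
  active <- model@reactions$id[
    (!is.na(x) & x >= Tval) | is.na(x) |
      abs(sol$v) > config$activityTolerance]
  ctx <- removeReactions(model, setdiff(model@reactions$id, active))
  iobj <- match(model@objective, model@reactions$id)
  fv <- new("FluxVector", flux = sol$v,
            objectiveValue = unname(sol$v[iobj]),
            info = list(vOpt = vOpt, floor = floorValue))
  new("GimmeResult", flux = fv, inconsistencyScore = max(0, sol$score),
      activeReactions = active, contextModel = ctx, vOpt = vOpt,
      threshold = unname(Tval), objectiveFraction = config$objectiveFraction)
}

#' Combine two active-reaction sets into a binary reaction vector
#'
#' Union: reactions active in either input set get value 1; intersection:
#' only reactions active in both. All other model reactions get 0.
#'
#' @param a,b Character vectors of reaction ids (subsets of the model's
#'   reactions), e.g. `activeReactions()` of two channel results.
#' @param mode `"union"` or `"intersection"`.
#' @param model The base [MetabolicModel-class].
#' @return A binary [ReactionData-class] (channel `"binary"`).
#' @export
combineActivity <- function(a, b, mode = c("union", "intersection"), model) {
  mode <- match.arg(mode)
  ids <- model@reactions$id
  unknown <- setdiff(c(a, b), ids)
  if (length(unknown))
    stop("unknown reaction id: ", paste(unknown, collapse = ", "))
  keep <- if (mode == "union") union(a, b) else intersect(a, b)
  vals <- stats::setNames(as.numeric(ids %in% keep), ids)
  new("ReactionData", values = vals, channel = "binary",
      sample = mode)
}

#' Contextualize a model from a binary activity vector
#'
#' Runs GIMME with threshold 0.5 and objective fraction 0.5: reactions
#' marked 0 carry penalty 0.5, reactions marked 1 carry none, so the
#' algorithm keeps 1-reactions and removes 0-reactions where mass
#' balance and the growth floor allow.
#'
#' @param model Base [MetabolicModel-class].
#' @param binary Binary [ReactionData-class] (values in \{0, 1\}).
#' @param objectiveFraction Growth floor fraction (default 0.5).
#' @return A [GimmeResult-class].
#' @export
contextualizeBinary <- function(model, binary, objectiveFraction = 0.5) {
  v <- binary@values
  if (!all(v %in% c(0, 1)))
    stop("binary vector must contain only 0/1 values")
  gimme(model, binary,
        gimmeConfig(threshold = 0.5, objectiveFraction = objectiveFraction))
}
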