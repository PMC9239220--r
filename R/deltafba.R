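#' Differential-flux configuration
#'
#' @param epsilon Minimum flux-change magnitude enforced on a
#'   sign-consistent data reaction (default 0.1 mmol/gDW/h).
#' @param alpha q-value cutoff for significance filtering (default
#'   0.01; genes with q >= alpha are discarded).
#' @param bigM Big-M constant linking the consistency binaries to the
#'   flux changes; `NULL` (default) uses twice the widest bound range
#'   plus epsilon.
#' @param alteredEpsilon Threshold for calling a reaction altered,
#'   `|delta_v| >= alteredEpsilon` (defaults to `epsilon`; the relaxed
#'   threshold plays both roles but they are independently settable).
#' @param objective `"l2"` (default) minimizes the squared flux change
#'   of non-data reactions in step 2; `"l1"` substitutes an absolute
#'   value minimization solved as an LP.
#' @return Named list of configuration values.
#' @export
deltaFbaConfig <- function(epsilon = 0.1, alpha = 0.01, bigM = NULL,
                           alteredEpsilon = epsilon,
                           objective = c("l2", "l1")) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  list(epsilon = epsilon, alpha = alpha, bigM = bigM,
       alteredEpsilon = alteredEpsilon, objective = match.arg(objective))
}

#' Read a gene-level differential table
#'
#' Tab-delimited with columns `gene_id`, `log2fc`, `qvalue`.
#'
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
readDifferential <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = "NA")
  need <- c("gene_id", "log2fc", "qvalue")
  if (!all(need %in% colnames(df)))
    stop("differential TSV needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in differential table")
  if (any(df$qvalue < 0 | df$qvalue > 1, na.rm = TRUE))
    stop("q-values must lie in [0, 1]")
  df[, need]
}

#' Keep significantly altered genes
#'
#' Retains genes with `qvalue < alpha` only; the boundary `q == alpha`
#' is discarded (genes with q >= alpha count as unaltered).
#'
#' @param diff data.frame with `gene_id`, `log2fc`, `qvalue`.
#' @param alpha Significance cutoff (default 0.01).
#' @return The filtered data.frame.
#' @export
filterSignificant <- function(diff, alpha = 0.01) {
  diff[!is.na(diff$qvalue) & diff$qvalue < alpha, , drop = FALSE]
}

#' Differential flux inference between two conditions
#'
#' Infers a steady-state flux-change vector `delta_v` (with
#' `S delta_v = 0` and `delta_v_j` in `[lb_j - ub_j, ub_j - lb_j]`) from
#' reaction-level signed log2 fold changes of the significant gene set,
#' in two steps. Step 1 (MILP): one binary per data reaction; an active
#' binary enforces `sign(w_j) * delta_v_j >= epsilon` through a big-M
#' link, and the number of active binaries (sign-consistent reactions)
#' is maximized. Step 2 (QP, default): with the step-1 consistency set
#' fixed, minimize the squared flux change of all non-data reactions
#' (plus a 1e-6 ridge on data reactions that makes the program strictly
#' convex, so the reported delta_v is unique). An `"l1"` objective
#' solved by LP is available as an alternative.
#'
#' @param model A [MetabolicModel-class].
#' @param diffReactions A [ReactionData-class] of signed log2 fold
#'   changes mapped from the significant genes (NA = not in the data
#'   set); typically from [mapValuesToReactions()] after
#'   [filterSignificant()].
#' @param config See [deltaFbaConfig()].
#' @return A [DeltaFluxResult-class].
#' @examples
#' m <- exampleChainModel()
#' d <- mapValuesToReactions(m, c(g1 = 1))
#' deltaV(deltaFba(m, d))  # +0.1 along the whole chain
#' @export
deltaFba <- function(model, diffReactions, config = deltaFbaConfig()) {
  stopifnot(is(diffReactions, "ReactionData"))
  rxn <- model@reactions
  n <- nrow(rxn)
  w <- diffReactions@values[rxn$id]
  D <- which(!is.na(w) & w != 0)
  eps <- config$epsilon
  S <- model@stoichiometry
  m <- nrow(S)
  dlo <- rxn$lower_bound - rxn$upper_bound
  dhi <- rxn$upper_bound - rxn$lower_bound
  bigM <- if (is.null(config$bigM)) 2 * max(dhi - dlo) + eps else config$bigM

  if (length(D) == 0L) {
    dv <- stats::setNames(rep(0, n), rxn$id)
    return(new("DeltaFluxResult", deltaV = dv, nConsistent = 0L,
               consistentReactions = character(),
               alteredReactions = character(), alteredGenes = character(),
               epsilon = eps))
  }

  k <- length(D)
  sgn <- sign(w[D])
  # variables: delta_v (n) then y (k binaries)
  # link: sgn_j * dv_j + M * y_j <= M + ... i.e. sgn*dv >= eps - M(1-y)
  nv <- n + k
  A <- matrix(0, m + k, nv)
  A[seq_len(m), seq_len(n)] <- as.matrix(S)
  dir <- rep("=", m)
  rhs <- rep(0, m)
  for (t in seq_len(k)) {
    row <- numeric(nv)
    row[D[t]] <- sgn[t]
    row[n + t] <- -bigM
    A[m + t, ] <- row
  }
  dir <- c(dir, rep(">=", k))
  rhs <- c(rhs, rep(eps - bigM, k))
  obj <- c(rep(0, n), rep(1, k))
  lo <- c(dlo, rep(0, k))
  hi <- c(dhi, rep(1, k))
  s1 <- .solveLP(obj, A, dir, rhs, lo, hi, sense = "max",
                 intIdx = n + seq_len(k))
  y <- round(s1$x[n + seq_len(k)])
  nStar <- as.integer(sum(y))
  consIdx <- D[y == 1]

  # step 2: canonical delta_v at fixed consistency set
  free <- setdiff(seq_len(n), D)
  Sd <- as.matrix(S)
  qrS <- qr(t(Sd))
  Si <- Sd[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]  # independent rows
  mi <- nrow(Si)
  if (config$objective == "l2") {
    wt <- rep(1e-6, n)
    wt[free] <- 1
    Dmat <- diag(2 * wt, n)
    dvec <- rep(0, n)
    Amat <- t(rbind(Si,                        # equalities first
                    diag(1, n),                # dv >= dlo
                    -diag(1, n)))              # -dv >= -dhi
    bvec <- c(rep(0, mi), dlo, -dhi)
    if (length(consIdx)) {
      Acons <- matrix(0, length(consIdx), n)
      for (t in seq_along(consIdx))
        Acons[t, consIdx[t]] <- sign(w[consIdx[t]])
      Amat <- cbind(Amat, t(Acons))
      bvec <- c(bvec, rep(eps, length(consIdx)))
    }
    qp <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = mi)
    dv <- qp$solution
  } else {
    # L1: split dv = p - q, minimize sum over non-data reactions
    A1 <- cbind(as.matrix(S), -as.matrix(S))
    dir1 <- rep("=", m); rhs1 <- rep(0, m)
    if (length(consIdx)) {
      for (j in consIdx) {
        row <- numeric(2 * n)
        row[j] <- sign(w[j]); row[n + j] <- -sign(w[j])
        A1 <- rbind(A1, row)
      }
      dir1 <- c(dir1, rep(">=", length(consIdx)))
      rhs1 <- c(rhs1, rep(eps, length(consIdx)))
    }
    cost <- numeric(2 * n)
    cost[free] <- 1; cost[n + free] <- 1
    cost[D] <- 1e-6; cost[n + D] <- 1e-6
    lo1 <- c(pmax(dlo, 0), pmax(-dhi, 0))
    hi1 <- c(pmax(dhi, 0), pmax(-dlo, 0))
    s2 <- .solveLP(cost, A1, dir1, rhs1, lo1, hi1, sense = "min")
    dv <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
  }
  dv <- stats::setNames(dv, rxn$id)
  resid <- max(abs(as.numeric(S %*% dv)))
  if (resid > .tol$balance)
    stop(sprintf("internal error: delta_v mass-balance residual %.3g", resid))
  altered <- rxn$id[abs(dv) >= config$alteredEpsilon - 1e-9]
  genes <- sort(unique(unlist(lapply(
    rxn$gpr[rxn$id %in% altered], function(g) gprGenes(parseGpr(g))))))
  if (is.null(genes)) genes <- character()
  new("DeltaFluxResult", deltaV = dv, nConsistent = nStar,
      consistentReactions = rxn$id[consIdx],
      alteredReactions = altered, alteredGenes = genes, epsilon = eps)
}

#' Genes behind the altered reactions
#'
#' Union of GPR leaf genes over the altered reaction set, in
#' deterministic (sorted) order.
#'
#' @param result A [DeltaFluxResult-class].
#' @param model The model the result came from.
#' @return Sorted character vector of gene ids.
#' @export
alteredPathwayGenes <- function(result, model) {
  rxn <- model@reactions
  genes <- sort(unique(unlist(lapply(
    rxn$gpr[rxn$id %in% result@alteredReactions],
    function(g) gprGenes(parseGpr(g))))))
  if (is.null(genes)) character() else genes
}
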