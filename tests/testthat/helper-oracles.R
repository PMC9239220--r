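# Independent brute-force oracles: optima located by enumerating basic
# feasible solutions (vertices) of the bounded polytope, with no use of
# the package's LP route.

# min obj'x  s.t.  A x = b, lo <= x <= hi  (all bounds finite).
# Returns the best vertex objective (Inf if infeasible).
enumVertexMin <- function(obj, A, b, lo, hi, tol = 1e-7) {
  A <- as.matrix(A)
  qrA <- qr(t(A))
  r <- qrA$rank
  keep <- qrA$pivot[seq_len(r)]
  A <- A[keep, , drop = FALSE]
  b <- b[keep]
  n <- ncol(A)
  best <- Inf
  if (r == 0L) {
    # box only: optimum at a box corner coordinate-wise
    x <- ifelse(obj >= 0, lo, hi)
    return(sum(obj * x))
  }
  combs <- utils::combn(n, r)
  for (ci in seq_len(ncol(combs))) {
    B <- combs[, ci]
    N <- setdiff(seq_len(n), B)
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-10) next
    nN <- length(N)
    for (mask in seq_len(2^nN) - 1L) {
      atHi <- bitwAnd(mask, 2^(seq_len(nN) - 1L)) > 0
      xN <- ifelse(atHi, hi[N], lo[N])
      rhs <- b - if (nN) A[, N, drop = FALSE] %*% xN else 0
      xB <- drop(solve(AB, rhs))
      if (all(xB >= lo[B] - tol) && all(xB <= hi[B] + tol)) {
        x <- numeric(n)
        x[N] <- xN
        x[B] <- xB
        val <- sum(obj * x)
        if (val < best) best <- val
      }
      if (nN == 0L) break
    }
  }
  best
}

enumVertexMax <- function(obj, A, b, lo, hi, ...) {
  -enumVertexMin(-obj, A, b, lo, hi, ...)
}

# Brute-force GIMME inconsistency optimum: max-growth by vertex
# enumeration, then min sum c_j |v_j| with the objective floor imposed
# as a bound, handling reversible reactions by sign-pattern enumeration.
gimmeOracle <- function(model, penalties, objectiveFraction) {
  S <- as.matrix(stoichiometricMatrix(model))
  rxn <- reactions(model)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  iobj <- match(objectiveReaction(model), rxn$id)
  eobj <- numeric(length(lb)); eobj[iobj] <- 1
  vOpt <- enumVertexMax(eobj, S, rep(0, nrow(S)), lb, ub)
  lo <- lb
  lo[iobj] <- max(lo[iobj], objectiveFraction * vOpt)
  rev_idx <- which(lo < 0)
  best <- Inf
  nrev <- length(rev_idx)
  for (mask in seq_len(2^nrev) - 1L) {
    neg <- if (nrev) bitwAnd(mask, 2^(seq_len(nrev) - 1L)) > 0 else logical(0)
    lo2 <- lo; hi2 <- ub; sgn <- rep(1, length(lb))
    if (nrev) {
      pos_rev <- rev_idx[!neg]; neg_rev <- rev_idx[neg]
      lo2[pos_rev] <- 0
      hi2[neg_rev] <- 0
      sgn[neg_rev] <- -1
    }
    if (any(lo2 > hi2 + 1e-12)) next
    val <- enumVertexMin(penalties * sgn, S, rep(0, nrow(S)), lo2, hi2)
    if (val < best) best <- val
    if (nrev == 0L) break
  }
  list(vOpt = vOpt, iStar = best)
}

# Seeded random feasible network, <= 8 reactions, guaranteed backbone
# EX -> M1 -> ... -> GROW, plus random extra conversions; finite bounds.
randomOracleNetwork <- function(seed) {
  set.seed(seed)
  nm <- sample(2:3, 1)                      # internal metabolites
  mets <- paste0("M", seq_len(nm))
  rxn_ids <- c("EX", paste0("B", seq_len(nm - 1)), "GROW")
  sto <- list(EX = stats::setNames(1, mets[1]))
  if (nm > 1) {
    for (i in seq_len(nm - 1)) {
      s <- stats::setNames(c(-1, 1), c(mets[i], mets[i + 1]))
      sto[[paste0("B", i)]] <- s
    }
  }
  sto$GROW <- stats::setNames(-1, mets[nm])
  n_extra <- sample(0:4, 1)
  for (k in seq_len(n_extra)) {
    if (length(sto) >= 8) break
    from <- sample(mets, 1)
    to <- sample(setdiff(mets, from), 1)
    id <- paste0("X", k)
    coef <- sample(c(1, 2), 1)
    sto[[id]] <- stats::setNames(c(-coef, 1), c(from, to))
    rxn_ids <- c(rxn_ids, id)
  }
  n <- length(sto)
  lb <- rep(0, n)
  ub <- round(stats::runif(n, 2, 10), 1)
  # occasionally one reversible extra reaction
  xs <- grep("^X", names(sto))
  if (length(xs) && stats::runif(1) < 0.4)
    lb[xs[1]] <- -round(stats::runif(1, 1, 5), 1)
  model <- newMetabolicModel(
    id = paste0("rand", seed),
    metabolites = data.frame(id = mets),
    reactions = data.frame(id = names(sto), lower_bound = lb,
                           upper_bound = ub,
                           gpr = ifelse(grepl("^EX|^GROW", names(sto)), "",
                                        paste0("g_", names(sto)))),
    stoichiometry = sto, objective = "GROW")
  # random mapped data and threshold -> penalties on gene-bearing reactions
  rxn <- reactions(model)
  x <- stats::setNames(rep(NA_real_, nrow(rxn)), rxn$id)
  mapped <- rxn$id[rxn$gpr != ""]
  x[mapped] <- round(stats::runif(length(mapped), 0, 10), 2)
  thr <- round(stats::runif(1, 2, 8), 2)
  list(model = model, values = x, threshold = thr)
}
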