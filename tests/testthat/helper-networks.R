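# Small fixture networks built in code.

# EX_A (0..10) -> R1/R2 (parallel A -> B) -> GROW; R1 upper bound settable
toy3Model <- function(r1ub = 1000) {
  newMetabolicModel(
    id = "toy3",
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(
      id = c("EX_A", "R1", "R2", "GROW"),
      lower_bound = 0, upper_bound = c(10, r1ub, 1000, 1000),
      gpr = c("", "g1", "g2", "")),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                         R2 = c(A = -1, B = 1), GROW = c(B = -1)),
    objective = "GROW")
}

# EX_A (0..10); short route P1: A->B; long route P2a: A->C, P2b: C->B;
# GROW: B -> (objective)
parallelPathModel <- function() {
  newMetabolicModel(
    id = "parallel",
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(
      id = c("EX_A", "P1", "P2a", "P2b", "GROW"),
      lower_bound = 0, upper_bound = c(10, 1000, 1000, 1000, 1000),
      gpr = ""),
    stoichiometry = list(EX_A = c(A = 1), P1 = c(A = -1, B = 1),
                         P2a = c(A = -1, C = 1), P2b = c(C = -1, B = 1),
                         GROW = c(B = -1)),
    objective = "GROW")
}

reactionData <- function(model, values, channel = "rna", sample = "s") {
  v <- stats::setNames(rep(NA_real_, nrow(reactions(model))),
                       reactions(model)$id)
  v[names(values)] <- values
  new("ReactionData", values = v, channel = channel, sample = sample)
}
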