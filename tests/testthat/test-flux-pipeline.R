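test_that("two-stage FBA idles the longer branch on the parallel-path toy", {
  m <- parallelPathModel()
  cfg <- simulationConfig(growthSlack = 0.1, glucoseExchange = NULL)
  fv <- twoStepFBA(m, cfg)
  expect_equal(fv@info$vOpt, 10)
  expect_equal(objectiveValue(fv), 9)          # growth at the stage-2 floor
  expect_equal(fv@info$sumAbsFlux, 27)         # EX 9 + P1 9 + GROW 9
  v <- fluxes(fv)
  expect_equal(unname(v["P2a"]), 0)
  expect_equal(unname(v["P2b"]), 0)
})

test_that("zero slack collapses stage 2 onto the optimum", {
  m <- parallelPathModel()
  fv <- twoStepFBA(m, simulationConfig(growthSlack = 0,
                                       glucoseExchange = NULL))
  expect_equal(objectiveValue(fv), fv@info$vOpt)
})

test_that("a single chain rescales to the stage-2 growth floor", {
  m <- exampleChainModel()
  fv <- twoStepFBA(m, simulationConfig(growthSlack = 0.1,
                                       glucoseExchange = NULL))
  expect_equal(unname(fluxes(fv)), rep(9, 3))
})

test_that("stage 2 beats random feasible vectors satisfying the growth floor", {
  m <- parallelPathModel()
  fv <- twoStepFBA(m, simulationConfig(growthSlack = 0.1,
                                       glucoseExchange = NULL))
  best <- fv@info$sumAbsInternal
  set.seed(11)
  for (k in 1:100) {
    g <- stats::runif(1, 9, 10)          # growth within the stage-2 window
    alpha <- stats::runif(1)             # split across the two routes
    v <- c(EX_A = g, P1 = alpha * g, P2a = (1 - alpha) * g,
           P2b = (1 - alpha) * g, GROW = g)
    expect_lte(max(abs(as.numeric(stoichiometricMatrix(m) %*% v))), 1e-9)
    expect_gte(sum(abs(v[c("P1", "P2a", "P2b", "GROW")])) + 1e-9, best)
  }
})

test_that("the returned growth never falls below the slack floor", {
  for (seed in c(1, 6)) {
    spec <- syntheticSpec(seed = seed)
    m <- makeToyNetwork(spec)
    fv <- twoStepFBA(m, simulationConfig(glucoseUptake = spec$glucoseUptake))
    expect_gte(objectiveValue(fv), 0.9 * fv@info$vOpt - 1e-6)
  }
})

test_that("a zero optimum skips stage 2 with a warning", {
  m <- exampleChainModel(ub = 0)
  expect_warning(fv <- twoStepFBA(m, simulationConfig(glucoseExchange = NULL)),
                 "V_opt is zero")
  expect_true(all(fluxes(fv) == 0))
})

test_that("medium bounds close unlisted source exchanges", {
  m <- parallelPathModel()
  cfg <- simulationConfig(medium = c(EX_A = 4), glucoseExchange = NULL)
  fv <- twoStepFBA(m, cfg)
  expect_equal(fv@info$vOpt, 4)
  cfg0 <- simulationConfig(medium = stats::setNames(numeric(0), character(0)),
                           glucoseExchange = NULL)
  expect_warning(twoStepFBA(m, cfg0), "V_opt is zero")
})

test_that("runPhase reproduces the planted module structure", {
  spec <- syntheticSpec(seed = 2, noiseSigmaAtac = 0, noiseSigmaRna = 0)
  m <- makeToyNetwork(spec)
  om <- simulateOmics(m, spec)
  simCfg <- simulationConfig(glucoseUptake = spec$glucoseUptake)

  pm <- runPhase(m, om$rna, om$atac, paste0("midOX_r", 1:2), "midOX",
                 simCfg = simCfg)
  # noise-free channels agree, so all four context models share content
  ids_rna <- reactions(pm@models$rna)$id
  ids_atac <- reactions(pm@models$atac)$id
  expect_setequal(ids_rna, ids_atac)
  expect_setequal(reactions(pm@models$intersection)$id,
                  reactions(pm@models$union)$id)
  # the planted-off fermentation pathway is absent from every context
  for (nm in c("rna", "atac", "intersection", "union"))
    expect_false("FERM" %in% reactions(pm@models[[nm]])$id, info = nm)
  # counts table covers the five variants
  expect_setequal(pm@counts$model,
                  c("generic", "rna", "atac", "intersection", "union"))
  expect_error(runPhase(m, om$rna, om$atac, "missing_sample"),
               "must be present")
})

test_that("channel disagreement lands in the union but not the intersection", {
  spec <- syntheticSpec(seed = 2, noiseSigmaAtac = 0, noiseSigmaRna = 0)
  m <- makeToyNetwork(spec)
  om <- simulateOmics(m, spec)
  d_rna <- mapSampleToReactions(m, om$rna, "midOX_r1", channel = "rna")
  d_atac <- mapSampleToReactions(m, om$atac, "midOX_r1", channel = "atac")
  g_rna <- gimme(m, d_rna)
  g_atac <- gimme(m, d_atac)
  # force disagreement on the storage pathway
  a <- union(activeReactions(g_rna), c("GSY", "GPH"))
  b <- activeReactions(g_atac)
  uni <- contextualizeBinary(m, combineActivity(a, b, "union", m))
  int <- contextualizeBinary(m, combineActivity(a, b, "intersection", m))
  expect_true(all(c("GSY", "GPH") %in% reactions(contextModel(uni))$id))
  expect_false(any(c("GSY", "GPH") %in% reactions(contextModel(int))$id))
})

test_that("writeFluxTable emits reaction_id/flux/lb/ub", {
  m <- exampleChainModel()
  fv <- solveFBA(m)
  p <- tempfile(fileext = ".tsv")
  writeFluxTable(fv, m, p)
  df <- utils::read.delim(p)
  expect_identical(colnames(df), c("reaction_id", "flux", "lb", "ub"))
  expect_equal(df$flux, unname(fluxes(fv)[df$reaction_id]))
})
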