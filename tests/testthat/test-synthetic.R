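test_that("the toy network is feasible with a positive optimum and the stated parts", {
  spec <- syntheticSpec(seed = 1)
  m <- makeToyNetwork(spec)
  expect_gt(objectiveValue(solveFBA(m)), 0)
  rxn <- reactions(m)
  expect_true(nrow(rxn) >= 15 && nrow(rxn) <= 40)
  # at least one AND and one OR rule among the GPRs
  expect_true(any(grepl(" and ", rxn$gpr)))
  expect_true(any(grepl(" or ", rxn$gpr)))
  # one biomass objective and a fixed-bound maintenance reaction
  expect_identical(objectiveReaction(m), "BIOMASS")
  atpm <- rxn[rxn$id == "ATPM", ]
  expect_equal(atpm$lower_bound, atpm$upper_bound)
  expect_equal(atpm$lower_bound, m@ngam)
  # exchanges, maintenance and biomass carry no GPR: never prunable
  expect_true(all(rxn$gpr[rxn$subsystem %in%
                            c("exchange", "maintenance", "biomass")] == ""))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  spec <- syntheticSpec(seed = 7)
  m1 <- makeToyNetwork(spec)
  m2 <- makeToyNetwork(spec)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  writeModelJson(m1, p1); writeModelJson(m2, p2)
  expect_identical(readLines(p1), readLines(p2))

  o1 <- simulateOmics(m1, spec)
  o2 <- simulateOmics(m2, spec)
  expect_identical(SummarizedExperiment::assay(o1$rna),
                   SummarizedExperiment::assay(o2$rna))
  expect_identical(SummarizedExperiment::assay(o1$atac),
                   SummarizedExperiment::assay(o2$atac))
  # a different seed changes the draws
  o3 <- simulateOmics(m1, syntheticSpec(seed = 8))
  expect_false(identical(SummarizedExperiment::assay(o1$rna),
                         SummarizedExperiment::assay(o3$rna)))
})

test_that("noise-free channels coincide and separate active from inactive genes", {
  spec <- syntheticSpec(seed = 5, noiseSigmaAtac = 0, noiseSigmaRna = 0)
  m <- makeToyNetwork(spec)
  om <- simulateOmics(m, spec)
  a <- SummarizedExperiment::assay(om$atac)
  r <- SummarizedExperiment::assay(om$rna)
  expect_identical(a, r)
  gm <- fluxContext:::.geneModules(m)
  for (ph in names(spec$phaseDesign)) {
    act <- gm[rownames(a)] %in% spec$phaseDesign[[ph]]
    col <- paste0(ph, "_r1")
    expect_gt(min(a[act, col]), max(a[!act, col]))
  }
})

test_that("ground-truth fluxes conserve mass and rescue infeasible phase designs", {
  spec <- syntheticSpec(seed = 1)
  m <- makeToyNetwork(spec)
  tr <- groundTruth(m, spec)
  for (ph in names(tr$phases)) {
    p <- tr$phases[[ph]]
    S <- stoichiometricMatrix(p$model)
    expect_lte(max(abs(as.numeric(S %*% fluxes(p$flux)))), 1e-6)
    expect_gt(p$flux@info$vOpt, 0)
  }
  # a phase design with no pyruvate outlet is rescued by the backbone outlet
  spec2 <- syntheticSpec(seed = 1, phaseDesign = list(
    earlyRC = c("glycolysis", "storage"),
    midOX = c("glycolysis", "tca", "ppp"),
    lateRB = c("glycolysis", "fermentation", "ppp")))
  tr2 <- groundTruth(makeToyNetwork(spec2), spec2)
  expect_true(length(tr2$phases$earlyRC$rescued) > 0)
  expect_gt(tr2$phases$earlyRC$flux@info$vOpt, 0)
})

test_that("planted differential tables mark module switches and only those", {
  spec <- syntheticSpec(seed = 3)
  m <- makeToyNetwork(spec)
  d <- simulateDifferential(m, spec, "earlyRC", "lateRB")
  gm <- fluxContext:::.geneModules(m)
  flips <- gm[d$gene_id] %in% spec$phaseDesign$earlyRC !=
    gm[d$gene_id] %in% spec$phaseDesign$lateRB
  expect_equal(d$qvalue[flips], rep(0.001, sum(flips)))
  expect_equal(d$qvalue[!flips], rep(0.5, sum(!flips)))
  # genes switching off go down, genes switching on go up
  onA <- gm[d$gene_id] %in% spec$phaseDesign$earlyRC
  expect_true(all(d$log2fc[flips & onA] < 0))
  expect_true(all(d$log2fc[flips & !onA] > 0))

  same <- simulateDifferential(m, spec, "midOX", "midOX")
  expect_true(all(same$qvalue == 0.5))
  expect_lt(max(abs(same$log2fc)), 1e-12)
})

test_that("measured fluxes are exact at zero noise and noisy otherwise", {
  spec0 <- syntheticSpec(seed = 2, fluxNoiseFrac = 0)
  m <- makeToyNetwork(spec0)
  tr <- groundTruth(m, spec0)
  v0 <- simulateMeasuredFluxes(m, tr, "midOX", spec0)
  tru <- fluxes(tr$phases$midOX$flux)
  expect_equal(v0[names(v0) %in% names(tru)],
               tru[names(v0)[names(v0) %in% names(tru)]])
  expect_true(all(v0[!names(v0) %in% names(tru)] == 0))

  spec1 <- syntheticSpec(seed = 2)
  v1 <- simulateMeasuredFluxes(m, tr, "midOX", spec1)
  expect_false(any(v1 == v0))
  expect_identical(v1, simulateMeasuredFluxes(m, tr, "midOX", spec1))
  expect_error(simulateMeasuredFluxes(m, tr, "noPhase", spec1), "unknown phase")
})

test_that("writeSimulation emits the full artifact set deterministically", {
  spec <- syntheticSpec(seed = 6)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  writeSimulation(spec, d1)
  writeSimulation(spec, d2)
  files <- c("model.json", "rna.tsv", "atac.tsv", "diff_midOX.tsv",
             "diff_lateRB.tsv", "measured_earlyRC.tsv", "measured_midOX.tsv",
             "measured_lateRB.tsv", "truth.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # artifacts reload through the package's own readers
  m <- readModelJson(file.path(d1, "model.json"))
  expect_gt(objectiveValue(solveFBA(m)), 0)
  expect_equal(dim(SummarizedExperiment::assay(
    readOmics(file.path(d1, "rna.tsv")))), c(16L, 6L))
  df <- readDifferential(file.path(d1, "diff_lateRB.tsv"))
  expect_true(all(c("gene_id", "log2fc", "qvalue") %in% colnames(df)))
})
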