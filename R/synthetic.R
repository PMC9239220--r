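# Seeded synthetic stand-in for a real multi-omics metabolic study: a
# mass-balanced central-carbon toy network with GPR rules, three
# metabolic-cycle phases with planted active/inactive pathway modules,
# dual-channel lognormal gene data (a low-noise accessibility-like
# channel and a higher-noise expression-like channel), differential
# tables with planted significance, and noisy measured fluxes derived
# from ground-truth parsimonious FBA solutions.

.syntheticModules <- c("glycolysis", "tca", "fermentation", "storage", "ppp")

#' Synthetic study specification
#'
#' All defaults are the study conditions of the synthetic suite; seeds
#' reproduce every output bit-for-bit.
#'
#' @param seed Integer master seed.
#' @param nPathwayModules Number of pathway modules, 2..5 (default 5:
#'   glycolysis, TCA-like respiration, fermentation, storage, PPP-like
#'   bypass; the first `n` are used and glycolysis is always present).
#' @param phaseDesign Named list phase -> character vector of active
#'   modules. Default: earlyRC = glycolysis+tca+storage, midOX =
#'   glycolysis+tca+ppp, lateRB = glycolysis+fermentation+ppp.
#' @param activityFold Ratio of active to inactive gene means (default 8).
#' @param noiseSigmaAtac,noiseSigmaRna Lognormal noise sd on the log2
#'   scale per channel (defaults 0.15 and 0.45: the accessibility-like
#'   channel is the cleaner one).
#' @param fluxNoiseFrac Relative sd of measured-flux noise (default
#'   0.05; 0 gives exact measurements).
#' @param baseMean Baseline gene signal level (default 100, arbitrary
#'   units).
#' @param baselineSigma Per-gene lognormal baseline spread, log2 scale
#'   (default 0.05): small residual gene-to-gene variability in
#'   baseline signal.
#' @param constitutiveOffset Named numeric vector of fixed basal
#'   abundance offsets (log2) for constitutively high genes (default
#'   `c(PDC1 = 2.5, CIT1 = 2.5)`: fermentative and respiratory marker
#'   genes retain substantial basal signal even when their pathway is
#'   off, as their real counterparts do). These genes sit close below
#'   the activity threshold in their off phases, so whether their
#'   reaction is called active is decided by channel noise — the
#'   feature that separates a clean channel from a noisy one.
#' @param replicates Biological replicates per phase (default 2).
#' @param glucoseUptake Substrate exchange bound, mmol/gDW/h (default
#'   1.45).
#' @return Named list (the spec object consumed by the generators).
#' @export
syntheticSpec <- function(seed = 1, nPathwayModules = 5, phaseDesign = NULL,
                          activityFold = 8, noiseSigmaAtac = 0.15,
                          noiseSigmaRna = 0.45, fluxNoiseFrac = 0.05,
                          baseMean = 100, baselineSigma = 0.05,
                          constitutiveOffset = c(PDC1 = 2.5, CIT1 = 2.5),
                          replicates = 2, glucoseUptake = 1.45) {
  if (activityFold <= 1) stop("activityFold must exceed 1")
  if (noiseSigmaAtac < 0 || noiseSigmaRna < 0) stop("noise sigmas must be >= 0")
  if (nPathwayModules < 2 || nPathwayModules > 5)
    stop("nPathwayModules must be in 2..5")
  modules <- .syntheticModules[seq_len(nPathwayModules)]
  if (is.null(phaseDesign)) {
    phaseDesign <- list(
      earlyRC = intersect(c("glycolysis", "tca", "storage"), modules),
      midOX   = intersect(c("glycolysis", "tca", "ppp"), modules),
      lateRB  = intersect(c("glycolysis", "fermentation", "ppp"), modules))
  }
  phaseDesign <- lapply(phaseDesign, function(m) {
    m <- intersect(m, modules)
    union("glycolysis", m)  # the backbone is always transcribed
  })
  list(seed = as.integer(seed), nPathwayModules = nPathwayModules,
       modules = modules, phaseDesign = phaseDesign,
       activityFold = activityFold, noiseSigmaAtac = noiseSigmaAtac,
       noiseSigmaRna = noiseSigmaRna, fluxNoiseFrac = fluxNoiseFrac,
       baseMean = baseMean, baselineSigma = baselineSigma,
       constitutiveOffset = constitutiveOffset,
       replicates = replicates, glucoseUptake = glucoseUptake)
}

# Run expr under a fixed RNG state without disturbing the caller's.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

.toyReactionTable <- function(spec, gam, ngam) {
  rows <- list(
    # id, lb, ub, gpr, subsystem
    list("EX_glc", 0, spec$glucoseUptake, "", "exchange"),
    # oxygen uptake is capped (respiratory capacity / Crabtree-like
    # limitation): respiration alone cannot reach the nitrogen-limited
    # growth ceiling, so overflow fermentation is part of the generic
    # optimum, as in aerobic glucose-grown yeast
    list("EX_o2",  0, 0.6, "", "exchange"),
    # nitrogen limitation caps growth itself, so context models of a
    # fermentative phase can still satisfy the GIMME objective floor
    list("EX_nh4", 0, 0.015, "", "exchange"),
    list("EX_co2", 0, 1000, "", "exchange"),
    list("EX_eth", 0, 1000, "", "exchange"),
    list("EX_bm",  0, 1000, "", "exchange"),
    list("ATPM", ngam, ngam, "", "maintenance"),
    list("GLCt", 0, 1000, "HXT1 or HXT2", "glycolysis"),
    list("HXK",  0, 1000, "HXK1 or HXK2", "glycolysis"),
    list("PGI", -1000, 1000, "PGI1", "glycolysis"),
    list("PFK_PYK", 0, 1000, "PFK1 and PFK2", "glycolysis"),
    list("RESP", 0, 1000, "CIT1", "tca"),
    list("FERM", 0, 1000, "PDC1 or PDC5", "fermentation"),
    list("GSY", 0, 1000, "GSY1 or GSY2", "storage"),
    list("GPH", 0, 1000, "GPH1", "storage"),
    list("ZWF", 0, 1000, "ZWF1", "ppp"),
    list("TKT", 0, 1000, "TKT1 and TKL1", "ppp"),
    list("BIOMASS", 0, 1000, "", "biomass"))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[[1]], lower_bound = r[[2]], upper_bound = r[[3]],
               gpr = r[[4]], subsystem = r[[5]])))
  keep <- df$subsystem %in% c("exchange", "maintenance", "biomass", spec$modules)
  df[keep, , drop = FALSE]
}

.toyStoichiometry <- function(gam) {
  list(
    EX_glc = c(glc_e = 1),
    EX_o2 = c(o2_c = 1),
    EX_nh4 = c(nh4_c = 1),
    EX_co2 = c(co2_c = -1),
    EX_eth = c(eth_c = -1),
    EX_bm = c(bm = -1),
    ATPM = c(atp = -1),
    GLCt = c(glc_e = -1, glc_c = 1),
    HXK = c(glc_c = -1, atp = -1, g6p = 1),
    PGI = c(g6p = -1, f6p = 1),
    PFK_PYK = c(f6p = -1, pyr = 2, atp = 3),
    RESP = c(pyr = -1, o2_c = -2, co2_c = 3, atp = 13),
    FERM = c(pyr = -1, eth_c = 1, co2_c = 1),
    GSY = c(g6p = -1, atp = -1, glyc_st = 1),
    GPH = c(glyc_st = -1, g6p = 1),
    ZWF = c(g6p = -1, p5p = 1, co2_c = 1),
    TKT = c(p5p = -3, f6p = 2.5),
    BIOMASS = c(pyr = -1, nh4_c = -0.2, atp = -gam, bm = 1)
  )
}

#' Generate the toy metabolic network
#'
#' A ~20-reaction central-carbon network: glucose uptake feeding a
#' glycolysis backbone, TCA-like respiration, fermentation to ethanol,
#' a storage-carbohydrate cycle and a PPP-like bypass, plus a biomass
#' objective carrying the GAM ATP cost in its stoichiometry and a
#' fixed-bound NGAM maintenance reaction. GPR rules include both AND
#' (complexes) and OR (isozymes); exchanges, maintenance and biomass
#' carry no GPR and are therefore never prunable by data.
#'
#' @param spec See [syntheticSpec()].
#' @param gam,ngam Maintenance parameters (defaults 55.3, 0.7).
#' @return A feasible [MetabolicModel-class] with positive optimum.
#' @export
makeToyNetwork <- function(spec = syntheticSpec(), gam = 55.3, ngam = 0.7) {
  rxn <- .toyReactionTable(spec, gam, ngam)
  sto <- .toyStoichiometry(gam)[rxn$id]
  mets <- sort(unique(unlist(lapply(sto, names))))
  newMetabolicModel(
    id = sprintf("toy_ymc_seed%d", spec$seed),
    metabolites = data.frame(id = mets),
    reactions = rxn, stoichiometry = sto,
    objective = "BIOMASS", gam = gam, ngam = ngam)
}

# gene -> module map implied by the GPR rules
.geneModules <- function(model) {
  rxn <- model@reactions
  out <- character()
  for (j in seq_len(nrow(rxn))) {
    gs <- gprGenes(parseGpr(rxn$gpr[j]))
    if (length(gs)) out[gs] <- rxn$subsystem[j]
  }
  out
}

# deterministic per-gene baseline signal (log2 offsets around baseMean);
# designated constitutive genes carry their fixed basal-abundance offset
.geneBaselines <- function(model, spec) {
  genes <- model@genes
  b <- .withSeed(spec$seed + 101L, {
    stats::setNames(stats::rnorm(length(genes), 0, spec$baselineSigma), genes)
  })
  co <- spec$constitutiveOffset
  hit <- intersect(names(co), genes)
  b[hit] <- b[hit] + co[hit]
  b
}

#' Ground truth of the synthetic study
#'
#' For each phase: the designed active reaction set (reactions of
#' active modules plus all data-free reactions) and the true flux
#' distribution, computed by [twoStepFBA()] on the ground-truth
#' submodel. If a designed submodel cannot sustain flux (no outlet for
#' an intermediate), the fermentation module is re-added as the backbone
#' outlet so every phase's truth is feasible; the re-added reactions are
#' recorded.
#'
#' @param model From [makeToyNetwork()].
#' @param spec See [syntheticSpec()].
#' @param simCfg See [simulationConfig()]; defaults match the spec.
#' @return List with `phases` (per phase: `activeReactions`, `flux`
#'   ([FluxVector-class] on the submodel), `model`, `rescued`) and
#'   `geneModule` (gene -> module map).
#' @export
groundTruth <- function(model, spec = syntheticSpec(),
                        simCfg = simulationConfig(glucoseUptake = spec$glucoseUptake)) {
  gm <- .geneModules(model)
  rxn <- model@reactions
  phases <- lapply(names(spec$phaseDesign), function(ph) {
    act_mod <- spec$phaseDesign[[ph]]
    mapped <- rxn$subsystem %in% spec$modules
    inactive <- rxn$id[mapped & !(rxn$subsystem %in% act_mod)]
    sub <- removeReactions(model, inactive)
    res <- tryCatch({
      fv <- suppressWarnings(twoStepFBA(sub, simCfg))
      if (fv@info$vOpt <= .tol$zero) NULL else list(sub = sub, fv = fv,
                                                    rescued = character())
    }, error = function(e) NULL)
    if (is.null(res)) {
      rescue <- rxn$id[rxn$subsystem == "fermentation"]
      sub2 <- removeReactions(model, setdiff(inactive, rescue))
      fv <- twoStepFBA(sub2, simCfg)
      res <- list(sub = sub2, fv = fv, rescued = intersect(inactive, rescue))
    }
    list(activeReactions = res$sub@reactions$id, flux = res$fv,
         model = res$sub, rescued = res$rescued)
  })
  names(phases) <- names(spec$phaseDesign)
  list(phases = phases, geneModule = gm)
}

#' Simulate dual-channel gene-level omics
#'
#' Per phase and replicate, each gene's value is
#' `2^(log2(baseMean) + b_g + s * log2(fold)/2 + e)` where `b_g` is the
#' gene's fixed baseline offset, `s` is +1 when the gene's module is
#' active in the phase and -1 otherwise, and `e ~ N(0, sigma_channel)`.
#' Both channels share the same ground-truth activity and baselines and
#' differ only in their noise sigma.
#'
#' @param model From [makeToyNetwork()].
#' @param spec See [syntheticSpec()].
#' @return List with `rna` and `atac` SummarizedExperiments (columns
#'   `<phase>_r<rep>`).
#' @export
simulateOmics <- function(model, spec = syntheticSpec()) {
  genes <- model@genes
  gm <- .geneModules(model)
  base <- .geneBaselines(model, spec)
  phases <- names(spec$phaseDesign)
  cols <- unlist(lapply(phases, function(ph)
    paste0(ph, "_r", seq_len(spec$replicates))))
  half <- log2(spec$activityFold) / 2
  mu <- matrix(0, length(genes), length(cols),
               dimnames = list(genes, cols))
  for (ph in phases) {
    s <- ifelse(gm[genes] %in% spec$phaseDesign[[ph]], half, -half)
    for (r in seq_len(spec$replicates))
      mu[, paste0(ph, "_r", r)] <- log2(spec$baseMean) + base[genes] + s
  }
  channel <- function(sigma, offset) {
    eps <- .withSeed(spec$seed + offset, {
      matrix(stats::rnorm(length(mu), 0, sigma), nrow(mu), ncol(mu))
    })
    m <- 2^(mu + eps)
    dimnames(m) <- dimnames(mu)
    .omicsLike(m)
  }
  list(rna = channel(spec$noiseSigmaRna, 211L),
       atac = channel(spec$noiseSigmaAtac, 307L))
}

#' Simulate a gene-level differential table between two phases
#'
#' log2 fold change is the mean log2 difference of the channel's
#' replicate values (phase B relative to phase A); the q-value is
#' planted: 0.001 for genes whose module activity differs between the
#' phases, 0.5 otherwise.
#'
#' @param model From [makeToyNetwork()].
#' @param spec See [syntheticSpec()].
#' @param phaseA,phaseB Phase labels (A is the control).
#' @param channel `"atac"` (default) or `"rna"`.
#' @return data.frame with `gene_id`, `log2fc`, `qvalue`.
#' @export
simulateDifferential <- function(model, spec = syntheticSpec(),
                                 phaseA, phaseB, channel = c("atac", "rna")) {
  channel <- match.arg(channel)
  om <- simulateOmics(model, spec)[[channel]]
  mat <- .omicsMatrix(om)
  gm <- .geneModules(model)
  colsA <- paste0(phaseA, "_r", seq_len(spec$replicates))
  colsB <- paste0(phaseB, "_r", seq_len(spec$replicates))
  if (!all(c(colsA, colsB) %in% colnames(mat)))
    stop("unknown phase label: ", phaseA, " / ", phaseB)
  lfc <- rowMeans(log2(mat[, colsB, drop = FALSE])) -
    rowMeans(log2(mat[, colsA, drop = FALSE]))
  actA <- gm[rownames(mat)] %in% spec$phaseDesign[[phaseA]]
  actB <- gm[rownames(mat)] %in% spec$phaseDesign[[phaseB]]
  data.frame(gene_id = rownames(mat), log2fc = unname(lfc),
             qvalue = ifelse(actA != actB, 0.001, 0.5))
}

#' Simulate noisy measured fluxes for one phase
#'
#' Emulates an experimentally measured flux set: the ground-truth flux
#' of each selected reaction plus Gaussian noise with sd
#' `fluxNoiseFrac * (|v| + 0.01)` (exact at `fluxNoiseFrac = 0`).
#' Reactions absent from the phase's ground-truth submodel have true
#' flux zero.
#'
#' @param model From [makeToyNetwork()].
#' @param truth From [groundTruth()].
#' @param phase Phase label.
#' @param spec See [syntheticSpec()].
#' @param reactions Reactions to measure; default: all central-carbon
#'   module reactions (glycolysis, tca, fermentation, ppp) present in
#'   the generic model.
#' @return Named numeric vector reaction-id -> measured flux.
#' @export
simulateMeasuredFluxes <- function(model, truth, phase,
                                   spec = syntheticSpec(),
                                   reactions = NULL) {
  if (!phase %in% names(truth$phases))
    stop("unknown phase '", phase, "'")
  rxn <- model@reactions
  if (is.null(reactions)) {
    central <- intersect(c("glycolysis", "tca", "fermentation", "ppp"),
                         spec$modules)
    reactions <- rxn$id[rxn$subsystem %in% central]
  }
  tru <- fluxes(truth$phases[[phase]]$flux)
  v <- stats::setNames(rep(0, length(reactions)), reactions)
  hit <- intersect(reactions, names(tru))
  v[hit] <- tru[hit]
  iph <- match(phase, names(truth$phases))
  noise <- .withSeed(spec$seed + 401L + iph, {
    stats::rnorm(length(v), 0, spec$fluxNoiseFrac * (abs(v) + 0.01))
  })
  v + noise
}

#' Run the whole synthetic study for one seed
#'
#' Convenience wrapper: network, ground truth, dual-channel omics,
#' per-phase differential tables (relative to the first phase) and
#' per-phase measured fluxes.
#'
#' @param spec See [syntheticSpec()].
#' @param gimmeCfg,simCfg Configurations forwarded to the pipeline
#'   pieces (defaults as in the study design).
#' @return List with `model`, `truth`, `omics`, `differential`,
#'   `measured`.
#' @export
simulateStudy <- function(spec = syntheticSpec(),
                          gimmeCfg = gimmeConfig(),
                          simCfg = simulationConfig(glucoseUptake = spec$glucoseUptake)) {
  model <- makeToyNetwork(spec)
  truth <- groundTruth(model, spec, simCfg)
  omics <- simulateOmics(model, spec)
  phases <- names(spec$phaseDesign)
  ctrl <- phases[1]
  differential <- lapply(setdiff(phases, ctrl), function(ph)
    simulateDifferential(model, spec, ctrl, ph))
  names(differential) <- setdiff(phases, ctrl)
  measured <- lapply(phases, function(ph)
    simulateMeasuredFluxes(model, truth, ph, spec))
  names(measured) <- phases
  list(model = model, truth = truth, omics = omics,
       differential = differential, measured = measured)
}

#' Write every synthetic artifact of one seed to a directory
#'
#' Writes `model.json`, `rna.tsv`, `atac.tsv`, one `diff_<phase>.tsv`
#' per non-control phase, one `measured_<phase>.tsv` per phase and
#' `truth.json` (active sets and true fluxes). Identical seeds produce
#' byte-identical files.
#'
#' @param spec See [syntheticSpec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(spec = syntheticSpec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulateStudy(spec)
  writeModelJson(study$model, file.path(dir, "model.json"))
  writeOmics(study$omics$rna, file.path(dir, "rna.tsv"))
  writeOmics(study$omics$atac, file.path(dir, "atac.tsv"))
  for (ph in names(study$differential)) {
    utils::write.table(study$differential[[ph]],
                       file.path(dir, paste0("diff_", ph, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (ph in names(study$measured)) {
    df <- data.frame(reaction_id = names(study$measured[[ph]]),
                     flux = unname(study$measured[[ph]]))
    utils::write.table(df, file.path(dir, paste0("measured_", ph, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth_doc <- lapply(study$truth$phases, function(p)
    list(activeReactions = p$activeReactions,
         rescued = p$rescued,
         flux = as.list(fluxes(p$flux))))
  jsonlite::write_json(truth_doc, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
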