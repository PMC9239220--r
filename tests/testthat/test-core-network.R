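test_that("FBA solves the chain toy and respects conservation and bounds", {
  m <- exampleChainModel()
  fv <- solveFBA(m)
  expect_equal(objectiveValue(fv), 10)          # exchange bound bottleneck
  v <- fluxes(fv)
  expect_lte(max(abs(as.numeric(stoichiometricMatrix(m) %*% v))), 1e-6)
  b <- bounds(m)
  expect_true(all(v >= b$lower_bound - 1e-9 & v <= b$upper_bound + 1e-9))

  m0 <- exampleChainModel(ub = 0)
  expect_equal(objectiveValue(solveFBA(m0)), 0)  # no input, no growth
})

test_that("FBA reports infeasibility and unboundedness explicitly", {
  # forced production of a metabolite nothing consumes
  m <- newMetabolicModel(
    id = "dead",
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("SRC", "R1"), lower_bound = c(1, 0),
                           upper_bound = c(5, 0), gpr = ""),
    stoichiometry = list(SRC = c(A = 1), R1 = c(A = -1, B = 1)),
    objective = "R1")
  expect_error(solveFBA(m), "infeasible")

  # free-bounded loop: objective can grow without limit
  m2 <- newMetabolicModel(
    id = "loop",
    metabolites = data.frame(id = "A"),
    reactions = data.frame(id = c("F1", "F2"), lower_bound = -Inf,
                           upper_bound = Inf, gpr = ""),
    stoichiometry = list(F1 = c(A = 1), F2 = c(A = -1)),
    objective = "F1")
  expect_error(solveFBA(m2), "unbounded")
})

test_that("FBA agrees with vertex enumeration on small random networks", {
  for (seed in 1:12) {
    net <- randomOracleNetwork(seed)
    m <- net$model
    S <- as.matrix(stoichiometricMatrix(m))
    rxn <- reactions(m)
    eobj <- as.numeric(rxn$id == objectiveReaction(m))
    vref <- enumVertexMax(eobj, S, rep(0, nrow(S)),
                          rxn$lower_bound, rxn$upper_bound)
    fv <- solveFBA(m)
    expect_equal(objectiveValue(fv), vref, tolerance = 1e-7, info = seed)
  }
})

test_that("model JSON round-trips to an equal model", {
  m <- makeToyNetwork(syntheticSpec(seed = 3))
  path <- tempfile(fileext = ".json")
  writeModelJson(m, path)
  m2 <- readModelJson(path)
  expect_identical(reactions(m2), reactions(m))
  expect_identical(metabolites(m2), metabolites(m))
  expect_identical(modelGenes(m2), modelGenes(m))
  expect_identical(objectiveReaction(m2), objectiveReaction(m))
  expect_equal(as.matrix(stoichiometricMatrix(m2)),
               as.matrix(stoichiometricMatrix(m)))
  expect_equal(m2@gam, m@gam)
  expect_equal(m2@ngam, m@ngam)
})

test_that("model JSON schema errors name the offending record", {
  path <- tempfile(fileext = ".json")
  writeLines('{"id":"x","metabolites":[{"id":"A"}],
    "reactions":[{"id":"R1","stoichiometry":{"A":1},
                  "lower_bound":0,"upper_bound":1}]}', path)
  expect_error(readModelJson(path), "objective")

  writeLines('{"id":"x","metabolites":[{"id":"A"}],
    "reactions":[{"id":"R1","stoichiometry":{"ZZ":1},
                  "lower_bound":0,"upper_bound":1}],
    "objective":"R1"}', path)
  expect_error(readModelJson(path), "R1.*ZZ")
})

test_that("model constructor rejects duplicates and inverted bounds", {
  expect_error(newMetabolicModel(
    id = "d", metabolites = data.frame(id = c("A", "A")),
    reactions = data.frame(id = "R", lower_bound = 0, upper_bound = 1),
    stoichiometry = list(R = c(A = 1)), objective = "R"),
    "duplicate metabolite")
  expect_error(validObject(newMetabolicModel(
    id = "d", metabolites = data.frame(id = "A"),
    reactions = data.frame(id = "R", lower_bound = 2, upper_bound = 1),
    stoichiometry = list(R = c(A = 1)), objective = "R")),
    "lower_bound")
})

test_that("the SBML L3+FBC reader recovers bounds, GPRs and the objective", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini" fbc:strict="true">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="B" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_ten" value="10" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_g1"/>
            <fbc:geneProductRef fbc:geneProduct="G_g2"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="GROW" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj1">
      <fbc:objective fbc:id="obj1" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROW" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>'
  path <- tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- readModelSbml(path)
  expect_identical(objectiveReaction(m), "GROW")
  rxn <- reactions(m)
  expect_equal(rxn$upper_bound[rxn$id == "EX_A"], 10)
  expect_identical(gprGenes(parseGpr(rxn$gpr[rxn$id == "R1"])), c("g1", "g2"))
  expect_equal(objectiveValue(solveFBA(m)), 10)
})

test_that("removeReactions prunes orphan metabolites and genes", {
  m <- toy3Model()
  m2 <- removeReactions(m, "R2")
  expect_false("R2" %in% reactions(m2)$id)
  expect_false("g2" %in% modelGenes(m2))
  expect_true(all(c("A", "B") %in% metabolites(m2)$id))
  expect_error(removeReactions(m, "GROW"), "objective")
  expect_error(removeReactions(m, "nope"), "unknown reaction")
})
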