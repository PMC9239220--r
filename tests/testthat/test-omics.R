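writeTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("readOmics parses a small table and flags bad input", {
  p <- writeTsv(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\tNA", "g3\t5\t6"))
  se <- readOmics(p)
  mat <- SummarizedExperiment::assay(se)
  expect_equal(dim(mat), c(3L, 2L))
  expect_equal(mat["g1", "s2"], 2)
  expect_true(is.na(mat["g2", "s2"]))

  empty <- readOmics(writeTsv("gene_id\ts1"))
  expect_equal(nrow(SummarizedExperiment::assay(empty)), 0L)

  expect_error(readOmics(writeTsv(c("gene_id\ts1", "g1\t1", "g1\t2"))),
               "duplicate gene")
  expect_error(readOmics(writeTsv(c("gene_id\ts1", "g1\tabc"))),
               "non-numeric.*g1.*s1")
  expect_error(readOmics(writeTsv(c("foo\ts1", "g1\t1"))), "gene_id")
})

test_that("omics tables round-trip through writeOmics", {
  mat <- matrix(c(1.5, 2, NA, 4), 2, 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
  p <- tempfile(fileext = ".tsv")
  writeOmics(mat, p)
  back <- SummarizedExperiment::assay(readOmics(p))
  expect_equal(back, mat)
})

test_that("restrictToCommonGenes intersects symmetrically and errors on disjoint sets", {
  a <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  b <- matrix(7:12, 3, 2, dimnames = list(c("g2", "g3", "g4"), c("t1", "t2")))
  res <- restrictToCommonGenes(a, b)
  ra <- SummarizedExperiment::assay(res$a)
  rb <- SummarizedExperiment::assay(res$b)
  expect_identical(rownames(ra), c("g2", "g3"))
  expect_identical(rownames(ra), rownames(rb))
  expect_equal(ra, a[c("g2", "g3"), ])   # values preserved
  # identical gene sets pass through
  res2 <- restrictToCommonGenes(a, a)
  expect_equal(SummarizedExperiment::assay(res2$a), a)
  # symmetric in gene-set outcome
  res3 <- restrictToCommonGenes(b, a)
  expect_identical(rownames(SummarizedExperiment::assay(res3$a)),
                   rownames(ra))
  d <- matrix(1, 1, 1, dimnames = list("zz", "s"))
  expect_error(restrictToCommonGenes(a, d), "no genes")
})

test_that("mapSampleToReactions applies GPRs per sample and keeps unmapped NA", {
  m <- newMetabolicModel(
    id = "map3",
    metabolites = data.frame(id = "A"),
    reactions = data.frame(id = c("Rand", "Ror", "Rnone"),
                           lower_bound = -10, upper_bound = 10,
                           gpr = c("g1 and g2", "g1 or g2", "")),
    stoichiometry = list(Rand = c(A = 1), Ror = c(A = -1), Rnone = c(A = 1)),
    objective = "Rnone")
  tab <- matrix(c(1, 4), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  rd <- mapSampleToReactions(m, tab, "s1")
  v <- reactionValues(rd)
  expect_equal(unname(v["Rand"]), 1)
  expect_equal(unname(v["Ror"]), 4)
  expect_true(is.na(v["Rnone"]))
  expect_identical(names(v), reactions(m)$id)
  expect_error(mapSampleToReactions(m, tab, "nope"), "unknown sample")
  # unmapped iff evaluateGpr is NA
  expect_identical(is.na(v),
                   stats::setNames(vapply(reactions(m)$gpr, function(g)
                     is.na(evaluateGpr(parseGpr(g), tab[, 1])), logical(1)),
                     reactions(m)$id))
})

test_that("percentileThreshold uses linear interpolation and is monotone and bounded", {
  expect_equal(percentileThreshold(c(0, 10), 50), 5)
  expect_equal(percentileThreshold(c(5, 5, 5), 30), 5)
  expect_equal(percentileThreshold(c(1, 2, 3, 4), 25), 1.75)
  expect_equal(percentileThreshold(c(1, NA, 2, 3, 4), 25), 1.75)  # NA excluded
  expect_error(percentileThreshold(c(NA_real_, NA_real_), 25), "no mapped")
  expect_error(percentileThreshold(1:3, 101), "pct")
  set.seed(7)
  v <- stats::runif(30, 0, 100)
  ps <- seq(0, 100, by = 10)
  th <- vapply(ps, function(p) percentileThreshold(v, p), numeric(1))
  expect_true(all(diff(th) >= 0))
  expect_gte(min(th), min(v))
  expect_lte(max(th), max(v))
})

test_that("logTransform and averageReplicates behave on the raw scale", {
  mat <- matrix(c(0, 1, 7, 3), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lt <- SummarizedExperiment::assay(logTransform(mat))
  expect_equal(lt["g1", "s1"], 0)
  expect_equal(lt["g2", "s1"], 1)
  expect_equal(lt["g1", "s2"], 3)
  expect_error(logTransform(matrix(-1, 1, 1,
                                   dimnames = list("g", "s"))), "negative")

  mat2 <- matrix(c(1, 10, 3, 20, 100, 2), 2, 3,
                 dimnames = list(c("g1", "g2"), c("a1", "a2", "b1")))
  avg <- SummarizedExperiment::assay(averageReplicates(
    mat2, c(a1 = "A", a2 = "A", b1 = "B")))
  expect_equal(avg["g1", "A"], 2)    # arithmetic mean of 1, 3
  expect_equal(avg["g2", "A"], 15)
  expect_equal(avg["g1", "B"], 100)
  expect_error(averageReplicates(mat2, c(a1 = "A")), "every sample")
})
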