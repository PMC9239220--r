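#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors SimpleList
NULL

# Accept a SummarizedExperiment or a plain gene x sample matrix.
.omicsMatrix <- function(table) {
  if (is(table, "SummarizedExperiment")) return(SummarizedExperiment::assay(table))
  if (is.matrix(table)) {
    if (is.null(rownames(table)) || is.null(colnames(table)))
      stop("omics matrix must have gene rownames and sample colnames")
    return(table)
  }
  stop("omics table must be a SummarizedExperiment or a named matrix")
}

.omicsLike <- function(mat) {
  SummarizedExperiment::SummarizedExperiment(assays = S4Vectors::SimpleList(value = mat))
}

#' Read a gene-level omics table
#'
#' Expects a tab-delimited file whose header starts with `gene_id`
#' followed by sample names; cells are nonnegative values (expression or
#' accessibility, arbitrary units) with `NA` for missing.
#'
#' @param path TSV path.
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay
#'   `value` (genes x samples).
#' @export
readOmics <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = "NA")
  if (ncol(raw) == 0L || colnames(raw)[1] != "gene_id")
    stop("omics TSV must start with a 'gene_id' column")
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene row: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(raw)[-1]
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    bad <- !is.na(col) & is.na(suppressWarnings(as.numeric(col)))
    if (any(bad))
      stop(sprintf("non-numeric cell '%s' at row %d (gene %s), column '%s'",
                   col[which(bad)[1]], which(bad)[1], genes[which(bad)[1]],
                   samples[j]))
    mat[, j] <- as.numeric(col)
  }
  .omicsLike(mat)
}

#' Write a gene-level omics table
#' @param table SummarizedExperiment or matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeOmics <- function(table, path) {
  mat <- .omicsMatrix(table)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two omics tables to their common genes
#'
#' Mirrors the filtered-data variant of the workflow in which genes
#' measured in only one channel are removed so both channels cover the
#' same gene set.
#'
#' @param a,b Omics tables (SummarizedExperiment or matrix).
#' @return A list with elements `a` and `b`, both restricted to the
#'   gene-id intersection (original values preserved, intersection
#'   order).
#' @export
restrictToCommonGenes <- function(a, b) {
  ma <- .omicsMatrix(a); mb <- .omicsMatrix(b)
  common <- intersect(rownames(ma), rownames(mb))
  if (length(common) == 0L)
    stop("the two omics tables share no genes; nothing to analyze")
  list(a = .omicsLike(ma[common, , drop = FALSE]),
       b = .omicsLike(mb[common, , drop = FALSE]))
}

#' Map one sample's gene values to reactions via GPR rules
#'
#' Applies [evaluateGpr()] per reaction: AND takes the minimum over the
#' measured children, OR the maximum; reactions whose rule has no
#' measured gene (or no rule) are unmapped (`NA`).
#'
#' @param model A [MetabolicModel-class].
#' @param table Omics table.
#' @param sample Sample (column) id.
#' @param channel Provenance label (`"rna"`, `"atac"`, `"binary"`,
#'   `"foldchange"`).
#' @return A [ReactionData-class] over all model reactions.
#' @export
mapSampleToReactions <- function(model, table, sample, channel = "rna") {
  mat <- .omicsMatrix(table)
  if (!sample %in% colnames(mat))
    stop("unknown sample id '", sample, "'")
  gv <- mat[, sample]
  vals <- vapply(model@reactions$gpr,
                 function(g) evaluateGpr(parseGpr(g), gv), numeric(1),
                 USE.NAMES = FALSE)
  new("ReactionData", values = stats::setNames(vals, model@reactions$id),
      channel = channel, sample = sample)
}

#' Map a named gene-value vector to reactions
#'
#' Same mapping as [mapSampleToReactions()] but from a bare named
#' vector (used for fold changes of a significant gene set).
#'
#' @param model A [MetabolicModel-class].
#' @param geneValues Named numeric vector.
#' @param channel Provenance label.
#' @param sample Sample label for provenance.
#' @return A [ReactionData-class].
#' @export
mapValuesToReactions <- function(model, geneValues, channel = "foldchange",
                                 sample = NA_character_) {
  vals <- vapply(model@reactions$gpr,
                 function(g) evaluateGpr(parseGpr(g), geneValues), numeric(1),
                 USE.NAMES = FALSE)
  new("ReactionData", values = stats::setNames(vals, model@reactions$id),
      channel = channel, sample = sample)
}

#' Linear-interpolation percentile of mapped values
#'
#' The percentile is computed by linear interpolation between closest
#' ranks (the common default of scientific numeric stacks,
#' `quantile(type = 7)`), over the mapped (non-`NA`) values only.
#'
#' @param values Numeric vector or [ReactionData-class]; `NA`s excluded.
#' @param pct Percent in \[0, 100\] (e.g. 25 for the activity threshold).
#' @return Numeric scalar threshold.
#' @examples
#' percentileThreshold(c(1, 2, 3, 4), 25)  # 1.75
#' @export
percentileThreshold <- function(values, pct) {
  if (is(values, "ReactionData")) values <- values@values
  if (pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("no mapped values to take a percentile of")
  unname(stats::quantile(v, probs = pct / 100, type = 7))
}

#' Log2-transform an omics table
#'
#' @param table Omics table (values >= 0).
#' @param pseudocount Added before the log (default 1).
#' @return A SummarizedExperiment with values `log2(x + pseudocount)`.
#' @export
logTransform <- function(table, pseudocount = 1) {
  mat <- .omicsMatrix(table)
  if (any(mat < 0, na.rm = TRUE))
    stop("negative value encountered; log transform expects nonnegative data")
  .omicsLike(log2(mat + pseudocount))
}

#' Average replicate samples per group
#'
#' Arithmetic mean on the raw scale, the standard replicate handling
#' before mapping a time point's values onto a model.
#'
#' @param table Omics table.
#' @param grouping Named character vector sample-id -> group label; must
#'   cover every column.
#' @return SummarizedExperiment with one column per group (group-label
#'   order of first appearance).
#' @export
averageReplicates <- function(table, grouping) {
  mat <- .omicsMatrix(table)
  if (!all(colnames(mat) %in% names(grouping)))
    stop("grouping must assign every sample to a group")
  g <- grouping[colnames(mat)]
  groups <- unique(unname(g))
  out <- vapply(groups, function(gr)
    rowMeans(mat[, g == gr, drop = FALSE], na.rm = TRUE), numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), groups))
  out[is.nan(out)] <- NA_real_
  .omicsLike(out)
}
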