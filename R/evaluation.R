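#' Read a measured-flux table
#'
#' Tab-delimited with columns `reaction_id`, `flux` (mmol/gDW/h),
#' emulating an experimentally determined (e.g. 13C-MFA) flux set.
#'
#' @param path TSV path.
#' @return Named numeric vector reaction-id -> flux.
#' @export
readMeasuredFluxes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!all(c("reaction_id", "flux") %in% colnames(df)))
    stop("measured flux TSV needs columns reaction_id, flux")
  if (anyDuplicated(df$reaction_id))
    stop("duplicate reaction_id in measured flux table")
  stats::setNames(as.numeric(df$flux), df$reaction_id)
}

#' Compare predicted and measured fluxes
#'
#' Matches the two flux sets on reaction id and reports the Pearson
#' correlation and the mean squared error (denominator n) over the
#' matched set. Measured ids without a prediction are reported, not
#' fatal. Fewer than 4 matches is an error; zero variance in either
#' vector makes r undefined (`NA`), reported as such.
#'
#' @param pred A [FluxVector-class] or named numeric vector.
#' @param measured Named numeric vector (see [readMeasuredFluxes()]).
#' @return A [FluxComparisonReport-class].
#' @examples
#' r <- compareFluxes(c(a = 1, b = 2, c = 3, d = 4, e = 5),
#'                    c(a = 1, b = 2, c = 3, d = 4, e = 5))
#' r@pearsonR  # 1
#' @export
compareFluxes <- function(pred, measured) {
  if (is(pred, "FluxVector")) pred <- fluxes(pred)
  common <- intersect(names(pred), names(measured))
  unmatched <- setdiff(names(measured), names(pred))
  if (length(common) < 4L)
    stop("need at least 4 matched reactions, got ", length(common))
  p <- unname(pred[common]); q <- unname(measured[common])
  r <- if (stats::sd(p) == 0 || stats::sd(q) == 0) NA_real_
       else stats::cor(p, q)
  mse <- mean((p - q)^2)
  new("FluxComparisonReport",
      matched = data.frame(reaction_id = common, predicted = p, measured = q),
      n = length(common), pearsonR = r, mse = mse,
      unmatched = if (length(unmatched)) unmatched else NULL)
}

#' Fisher-z comparison of two correlation coefficients
#'
#' Transforms each correlation with `atanh` and forms the two-sample
#' statistic `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`
#' with a two-sided standard-normal p-value and a significance flag at
#' the 0.05 level.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z`, `p`, `significant`.
#' @examples
#' fisherZTest(0.5, 37, 0.5, 37)$p  # 1: equal correlations
#' @export
fisherZTest <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3)
    stop("Fisher z comparison requires n > 3 in both samples")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 (the z transform diverges at 1)")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, significant = p < 0.05)
}

#' Pairwise Fisher-z comparison across model reports
#'
#' @param reports Named list of [FluxComparisonReport-class] objects.
#' @return data.frame with one row per model pair: `model1`, `model2`,
#'   `r1`, `r2`, `z`, `p`, `significant`.
#' @export
compareReports <- function(reports) {
  nms <- names(reports)
  out <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    a <- reports[[i]]; b <- reports[[j]]
    ft <- fisherZTest(a@pearsonR, a@n, b@pearsonR, b@n)
    out[[length(out) + 1L]] <- data.frame(
      model1 = nms[i], model2 = nms[j], r1 = a@pearsonR, r2 = b@pearsonR,
      z = ft$z, p = ft$p, significant = ft$significant)
  }
  do.call(rbind, out)
}

#' Hierarchical clustering of omics samples
#'
#' Agglomerative clustering of the samples (columns) on Euclidean
#' distance; average linkage by default. Columns are put in
#' lexicographic order before clustering so tied merges resolve by
#' sample id. A constant table yields a flat dendrogram (all merge
#' heights zero), not an error.
#'
#' @param table Omics table (already log-transformed, or set `log2`).
#' @param log2 Apply [logTransform()] first (default `FALSE`).
#' @param method Linkage: `"average"` (default), `"complete"`,
#'   `"ward.D2"`.
#' @param pseudocount Passed to [logTransform()] when `log2 = TRUE`.
#' @return An [stats::hclust] object.
#' @export
hierarchicalCluster <- function(table, log2 = FALSE,
                                method = c("average", "complete", "ward.D2"),
                                pseudocount = 1) {
  method <- match.arg(method)
  if (log2) table <- logTransform(table, pseudocount)
  mat <- .omicsMatrix(table)
  if (ncol(mat) < 2L) stop("clustering requires at least 2 samples")
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- stats::dist(t(mat), method = "euclidean")
  stats::hclust(d, method = method)
}
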