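#' Z-score normalize an expression matrix
#'
#' Standardizes every gene row to mean 0 and unit standard deviation across
#' all samples (tumor and control together), using the sample (n-1) standard
#' deviation. Rows with zero standard deviation are set to all zeros and
#' recorded in the `degenerate` attribute.
#'
#' @param matrix An `ExpressionMatrix`.
#' @return An `ExpressionMatrix` of z-scores with attribute `degenerate`
#'   (character vector of constant-row gene ids).
#' @export
zscore_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  if (ncol(v) < 2) stop("z-score normalization needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  z <- (v - mu) / sdv
  flat <- sdv == 0
  z[flat, ] <- 0
  out <- new_expression_matrix(z, matrix$groups)
  attr(out, "degenerate") <- rownames(v)[flat]
  out
}

#' Per-gene log2 fold change, tumor over control
#'
#' logFC = log2((mean over tumor samples + epsilon) / (mean over control
#' samples + epsilon)). Computed on the positive expression scale, not on
#' z-scores (a z-scored row has mean 0 across samples, so a ratio of means is
#' undefined there).
#'
#' @param matrix An `ExpressionMatrix` on a positive expression scale.
#' @param epsilon Non-negative pseudocount added to both means; default 0.
#'   Useful for count-like data with zero means.
#' @return Named numeric vector of logFC values, one per gene.
#' @export
compute_logfc <- function(matrix, epsilon = 0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), epsilon >= 0)
  v <- matrix$values
  grp <- matrix$groups$group[match(colnames(v), matrix$groups$sample_id)]
  tumor <- rowMeans(v[, grp == "tumor", drop = FALSE]) + epsilon
  control <- rowMeans(v[, grp == "control", drop = FALSE]) + epsilon
  bad <- which(control <= 0 | tumor <= 0)
  if (length(bad) > 0) {
    stop("non-positive group mean after epsilon for gene '", rownames(v)[bad[1]],
         "'; logFC undefined (try a positive epsilon)", call. = FALSE)
  }
  stats::setNames(log2(tumor / control), rownames(v))
}

#' Build the ranked disease signature from logFC values
#'
#' Genes are ranked by decreasing logFC (ties broken lexicographically by gene
#' id, so the ranking is deterministic) and partitioned: logFC > 0 is
#' upregulated, logFC <= 0 downregulated.
#'
#' @param logfc Named numeric vector of log2 fold changes.
#' @return A `DiseaseSignature`: list with `ranked_genes`, `logfc` (in rank
#'   order), `up_set`, `down_set`.
#' @export
build_disease_signature <- function(logfc) {
  stopifnot(is.numeric(logfc), length(logfc) > 0, !is.null(names(logfc)))
  if (anyDuplicated(names(logfc))) stop("duplicate gene ids in logfc", call. = FALSE)
  ord <- order(-logfc, names(logfc), method = "radix")
  logfc <- logfc[ord]
  up <- names(logfc)[logfc > 0]
  down <- names(logfc)[logfc <= 0]
  if (length(down) == 0) warning("no downregulated genes in signature", call. = FALSE)
  if (length(up) == 0) warning("no upregulated genes in signature", call. = FALSE)
  structure(list(
    ranked_genes = names(logfc),
    logfc = logfc,
    up_set = up,
    down_set = down
  ), class = "DiseaseSignature")
}

#' @export
print.DiseaseSignature <- function(x, ...) {
  cat(sprintf("DiseaseSignature: %d genes (%d up, %d down)\n",
              length(x$ranked_genes), length(x$up_set), length(x$down_set)))
  invisible(x)
}
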