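# Transcriptome complexity and composition metrics: expressed-gene counts at
# RPKM thresholds, cumulative abundance curves, tissue-specific mRNA
# fractions and tissue PCA coordinates.

#' Complexity-metric configuration
#'
#' @param thresholds strictly descending positive RPKM thresholds at which
#'   expressed genes are counted (default 5, 1, 0.5, 0.1).
#' @param abundance_threshold RPKM floor defining the "expressed" universe of
#'   a tissue for the tissue-specific mRNA fraction (default 0.5).
#' @param total_gene_count denominator for "fraction of total genes"; when
#'   NULL the number of genes in the matrix is used.
#' @return object of class `complexity_config`.
#' @export
complexity_config <- function(thresholds = c(5, 1, 0.5, 0.1),
                              abundance_threshold = 0.5,
                              total_gene_count = NULL) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (any(diff(thresholds) >= 0)) stop("thresholds must be strictly descending")
  if (abundance_threshold <= 0) stop("abundance_threshold must be positive")
  structure(list(thresholds = thresholds,
                 abundance_threshold = abundance_threshold,
                 total_gene_count = total_gene_count),
            class = "complexity_config")
}

#' Expressed-gene counts per tissue at RPKM thresholds
#'
#' Counts, for every tissue and every threshold, the genes with RPKM at or
#' above the threshold (inclusive), and reports the fraction of the total
#' gene universe (2 decimals, half-up).
#'
#' @param rm an `rpkm_matrix`.
#' @param cfg a [complexity_config()].
#' @param strict use a strictly-greater-than comparison instead of `>=`.
#' @return data.frame with columns `tissue, threshold, n_expressed, fraction`.
#' @export
expressed_counts <- function(rm, cfg = complexity_config(), strict = FALSE) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  total <- if (is.null(cfg$total_gene_count)) nrow(rm$rpkm) else
    cfg$total_gene_count
  if (total < nrow(rm$rpkm)) {
    stop("total_gene_count smaller than the number of genes in the matrix")
  }
  grid <- expand.grid(tissue = colnames(rm$rpkm),
                      threshold = cfg$thresholds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_expressed <- mapply(function(t, th) {
    v <- rm$rpkm[, t]
    if (strict) sum(v > th) else sum(v >= th)
  }, grid$tissue, grid$threshold)
  grid$fraction <- round_half_up(grid$n_expressed / total, 2)
  grid
}

#' Cumulative abundance curve of a tissue
#'
#' Sorts the tissue's genes by RPKM descending (ties by gene id) and returns
#' the cumulative fraction of the tissue's total mRNA (sum of RPKM)
#' contributed by the top-k genes, for every rank k.
#'
#' @param rm an `rpkm_matrix`.
#' @param tissue tissue id.
#' @return object of class `abundance_curve`: list with `tissue`, `ranks`,
#'   `gene_ids` (descending order), `cumulative_fraction`.
#' @export
cumulative_abundance <- function(rm, tissue) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  if (!tissue %in% colnames(rm$rpkm)) stop("unknown tissue: ", tissue)
  v <- stats::setNames(rm$rpkm[, tissue], rownames(rm$rpkm))
  if (sum(v) <= 0) stop("tissue has zero total RPKM: ", tissue)
  ord <- order(-v, names(v))
  cf <- cumsum(v[ord]) / sum(v)
  structure(list(tissue = tissue, ranks = seq_along(v),
                 gene_ids = names(v)[ord],
                 cumulative_fraction = unname(cf)),
            class = "abundance_curve")
}

#' @export
print.abundance_curve <- function(x, ...) {
  k <- min(100L, length(x$ranks))
  cat(sprintf("abundance_curve[%s]: top %d genes contribute %.1f%% of mRNA\n",
              x$tissue, k, 100 * x$cumulative_fraction[k]))
  invisible(x)
}

#' Fraction of a tissue's mRNA contributed by its tissue-specific genes
#'
#' Divides the summed RPKM of the tissue's tissue-specific genes by the
#' summed RPKM of all genes expressed in that tissue (RPKM at or above the
#' abundance threshold, default 0.5). A tissue-specific gene below the
#' threshold in its focal tissue is outside the expressed universe and is
#' excluded from both numerator and denominator.
#'
#' @param rm an `rpkm_matrix`.
#' @param ts_sets named list tissue -> tissue-specific gene ids
#'   (from [classify_tissue_specific()]).
#' @param cfg a [complexity_config()].
#' @return named numeric vector, fraction per tissue.
#' @export
tissue_specific_fraction <- function(rm, ts_sets, cfg = complexity_config()) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  bad <- setdiff(unlist(ts_sets, use.names = FALSE), rownames(rm$rpkm))
  if (length(bad)) stop("tissue-specific id not in matrix: ", bad[1])
  th <- cfg$abundance_threshold
  vapply(colnames(rm$rpkm), function(t) {
    v <- rm$rpkm[, t]
    expressed <- v >= th
    denom <- sum(v[expressed])
    if (denom <= 0) stop("zero expressed mRNA in tissue: ", t)
    ts <- intersect(ts_sets[[t]], names(v)[expressed])
    sum(v[ts]) / denom
  }, numeric(1))
}

#' Tissue PCA coordinates
#'
#' Clusters tissues by expression pattern: RPKM is log2(x+1)-transformed,
#' each gene is centered across tissues, and the tissues are projected onto
#' the principal components of the resulting tissue covariance. The sign of
#' each component is fixed by making its largest-magnitude gene loading
#' positive, so coordinates are deterministic.
#'
#' @param rm an `rpkm_matrix` with at least 2 genes and 2 tissues.
#' @return list with `coordinates` (tissues x 2, PC1/PC2), `scores`
#'   (tissues x all PCs), `loadings` (genes x PCs), `center` (per-gene mean
#'   of the transformed values), `sdev`.
#' @export
tissue_pca <- function(rm) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  x <- log2(rm$rpkm + 1)           # genes x tissues
  if (nrow(x) < 2 || ncol(x) < 2) stop("tissue_pca needs >= 2 genes and tissues")
  if (max(x) == min(x)) stop("constant expression matrix")
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  list(coordinates = p$x[, 1:2, drop = FALSE], scores = p$x,
       loadings = p$rotation, center = p$center, sdev = p$sdev)
}
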