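# RPKM normalization and the housekeeping / tissue-specific classification
# rules of the 13-tissue expression atlas.

#' The 13 atlas tissue names
#'
#' Default tissue panel of the expression atlas: brain, white muscle, red
#' muscle, fat, gill, head kidney, kidney, intestine, skin, spleen, stomach,
#' liver and testis.
#'
#' @return character vector of 13 tissue names.
#' @export
atlas_tissues <- function() {
  c("brain", "white_muscle", "red_muscle", "fat", "gill", "head_kidney",
    "kidney", "intestine", "skin", "spleen", "stomach", "liver", "testis")
}

#' Construct a count matrix container
#'
#' Bundles the genes-by-tissues mapped-read counts with the per-gene
#' transcript lengths and per-tissue library sizes needed for RPKM.
#'
#' @param counts non-negative integer matrix, genes x tissues, with rownames
#'   (gene ids) and colnames (tissue ids).
#' @param lengths per-gene transcript length in nt (named or in row order).
#' @param lib_sizes per-tissue total mapped reads (named or in column order).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, lib_sizes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (is.null(colnames(counts))) stop("counts must have tissue colnames")
  if (!is.null(names(lengths))) {
    if (!all(rownames(counts) %in% names(lengths))) {
      stop("lengths names do not cover the gene ids")
    }
    lengths <- lengths[rownames(counts)]
  }
  if (!is.null(names(lib_sizes))) {
    if (!all(colnames(counts) %in% names(lib_sizes))) {
      stop("lib_sizes names do not cover the tissue ids")
    }
    lib_sizes <- lib_sizes[colnames(counts)]
  }
  lengths <- as.numeric(lengths)
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lengths) != nrow(counts)) stop("lengths/counts dimension mismatch")
  if (length(lib_sizes) != ncol(counts)) stop("lib_sizes/counts dimension mismatch")
  if (any(counts < 0)) stop("negative counts")
  if (any(lengths < 1)) stop("transcript lengths must be >= 1 nt")
  if (any(lib_sizes < 1)) stop("library sizes must be >= 1")
  if (any(sweep(counts, 2, lib_sizes, ">"))) {
    stop("a count exceeds its library size")
  }
  structure(list(counts = counts,
                 lengths = stats::setNames(lengths, rownames(counts)),
                 lib_sizes = stats::setNames(lib_sizes, colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d tissues (total reads %.3g)\n",
              nrow(x$counts), ncol(x$counts), sum(x$lib_sizes)))
  invisible(x)
}

#' Atlas classification thresholds
#'
#' @param hk_min_rpkm housekeeping floor: a gene is housekeeping when its RPKM
#'   is at least this value in every tissue (inclusive; default 1).
#' @param ts_fold tissue-specificity fold: a gene is specific to the tissue
#'   where its RPKM is at least `ts_fold` times its maximum RPKM in all other
#'   tissues (inclusive; default 8).
#' @param ts_focal_min_rpkm optional expression floor on the focal tissue for
#'   tissue-specific calls (default 0: no floor). Fold rules on near-zero
#'   RPKM are noise-sensitive, so a floor can be imposed.
#' @return object of class `atlas_config`.
#' @export
atlas_config <- function(hk_min_rpkm = 1.0, ts_fold = 8.0,
                         ts_focal_min_rpkm = 0.0) {
  if (ts_fold <= 1) stop("ts_fold must be > 1")
  if (hk_min_rpkm < 0) stop("hk_min_rpkm must be >= 0")
  structure(list(hk_min_rpkm = hk_min_rpkm, ts_fold = ts_fold,
                 ts_focal_min_rpkm = ts_focal_min_rpkm),
            class = "atlas_config")
}

#' Compute RPKM from a count matrix
#'
#' RPKM (reads per kilobase of transcript per million mapped reads) of gene g
#' in tissue t is `counts[g,t] * 1e9 / (lengths[g] * lib_sizes[t])`.
#'
#' @param cm a [count_matrix()].
#' @return object of class `rpkm_matrix`: list with `rpkm` (matrix, same axes
#'   as the counts), `lengths`, `lib_sizes`.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  r <- cm$counts * 1e9 / outer(cm$lengths, cm$lib_sizes)
  structure(list(rpkm = r, lengths = cm$lengths, lib_sizes = cm$lib_sizes),
            class = "rpkm_matrix")
}

#' Wrap an existing RPKM matrix
#'
#' For data arriving already normalized (no counts available).
#'
#' @param rpkm non-negative numeric matrix with gene rownames and tissue
#'   colnames.
#' @param lengths,lib_sizes optional axes metadata.
#' @return an `rpkm_matrix` object.
#' @export
rpkm_matrix <- function(rpkm, lengths = NULL, lib_sizes = NULL) {
  rpkm <- as.matrix(rpkm)
  if (is.null(colnames(rpkm)) || (nrow(rpkm) > 0 && is.null(rownames(rpkm)))) {
    stop("rpkm must carry gene rownames and tissue colnames")
  }
  if (is.null(rownames(rpkm))) rownames(rpkm) <- character(0)
  if (any(rpkm < 0)) stop("negative RPKM")
  structure(list(rpkm = rpkm, lengths = lengths, lib_sizes = lib_sizes),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat(sprintf("rpkm_matrix: %d genes x %d tissues\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

#' Pool replicate libraries into per-tissue counts
#'
#' Sums counts and library sizes of libraries belonging to the same tissue
#' (e.g. two sequencing libraries per tissue) before RPKM normalization.
#'
#' @param cm a [count_matrix()] whose columns are libraries, or a list of
#'   `count_matrix` objects sharing the same gene axis (column-bound first).
#' @param grouping named character vector mapping library id to tissue id.
#' @return a [count_matrix()] with one column per tissue.
#' @export
pool_replicates <- function(cm, grouping) {
  if (is.list(cm) && !inherits(cm, "count_matrix")) {
    stopifnot(all(vapply(cm, inherits, logical(1), "count_matrix")))
    g0 <- rownames(cm[[1]]$counts)
    for (m in cm) {
      if (!identical(rownames(m$counts), g0) ||
          !identical(unname(m$lengths), unname(cm[[1]]$lengths))) {
        stop("count matrices to pool must share the same gene axis")
      }
    }
    cm <- count_matrix(do.call(cbind, lapply(cm, `[[`, "counts")),
                       cm[[1]]$lengths,
                       unlist(lapply(cm, `[[`, "lib_sizes")))
  }
  stopifnot(inherits(cm, "count_matrix"))
  libs <- colnames(cm$counts)
  if (!all(libs %in% names(grouping))) {
    stop("grouping missing for library: ",
         paste(setdiff(libs, names(grouping)), collapse = ", "))
  }
  g <- factor(grouping[libs], levels = unique(grouping[libs]))
  pooled <- vapply(levels(g), function(t) {
    rowSums(cm$counts[, g == t, drop = FALSE])
  }, numeric(nrow(cm$counts)))
  pooled <- matrix(pooled, nrow = nrow(cm$counts),
                   dimnames = list(rownames(cm$counts), levels(g)))
  libsz <- tapply(cm$lib_sizes, g, sum)[levels(g)]
  count_matrix(pooled, cm$lengths, libsz)
}

#' Classify housekeeping genes
#'
#' A gene is housekeeping when its RPKM is at least `hk_min_rpkm` (default 1,
#' inclusive) in every tissue.
#'
#' @param rm an `rpkm_matrix`.
#' @param cfg an [atlas_config()].
#' @return character vector of housekeeping gene ids (row order preserved).
#' @export
classify_housekeeping <- function(rm, cfg = atlas_config()) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  if (nrow(rm$rpkm) == 0L) return(character())
  keep <- apply(rm$rpkm, 1, min) >= cfg$hk_min_rpkm
  rownames(rm$rpkm)[keep]
}

#' Classify tissue-specific genes
#'
#' A gene is specific to tissue t when its RPKM there is at least `ts_fold`
#' (default 8, inclusive) times its maximum RPKM in all other tissues, is
#' positive, and meets `ts_focal_min_rpkm`. A positive focal value over an
#' all-zero background qualifies (the fold ratio is +Inf). Since
#' `ts_fold > 1`, the focal tissue is unique, so the per-tissue sets are
#' pairwise disjoint.
#'
#' @param rm an `rpkm_matrix` with at least 2 tissues.
#' @param cfg an [atlas_config()].
#' @return named list, tissue id -> character vector of gene ids.
#' @export
classify_tissue_specific <- function(rm, cfg = atlas_config()) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  x <- rm$rpkm
  if (ncol(x) < 2) stop("tissue-specific classification needs >= 2 tissues")
  out <- stats::setNames(vector("list", ncol(x)), colnames(x))
  for (t in colnames(x)) out[[t]] <- character()
  if (nrow(x) == 0L) return(out)
  top_idx <- max.col(x, ties.method = "first")
  top1 <- x[cbind(seq_len(nrow(x)), top_idx)]
  x2 <- x
  x2[cbind(seq_len(nrow(x)), top_idx)] <- -Inf
  top2 <- apply(x2, 1, max)
  ok <- top1 > 0 & top1 >= cfg$ts_focal_min_rpkm &
    (top2 <= 0 | top1 >= cfg$ts_fold * top2)
  # a tie for the maximum can never satisfy fold >= ts_fold > 1
  ok <- ok & (top1 > top2 | top2 <= 0)
  for (i in which(ok)) {
    t <- colnames(x)[top_idx[i]]
    out[[t]] <- c(out[[t]], rownames(x)[i])
  }
  out
}

#' Full atlas classification report
#'
#' Applies both rules and reports their intersection explicitly: the two
#' definitions do not logically exclude each other (a gene at RPKM >= 1
#' everywhere can still be 8-fold higher in one tissue), so any overlap is
#' surfaced rather than silently removed.
#'
#' @param rm an `rpkm_matrix`.
#' @param cfg an [atlas_config()].
#' @return object of class `atlas_classification`: list with `housekeeping`
#'   (ids), `tissue_specific` (tissue -> ids), `overlap` (ids in both).
#' @export
atlas_report <- function(rm, cfg = atlas_config()) {
  hk <- classify_housekeeping(rm, cfg)
  ts <- classify_tissue_specific(rm, cfg)
  structure(list(housekeeping = hk,
                 tissue_specific = ts,
                 overlap = intersect(hk, unlist(ts, use.names = FALSE))),
            class = "atlas_classification")
}

#' @export
print.atlas_classification <- function(x, ...) {
  nts <- length(unlist(x$tissue_specific, use.names = FALSE))
  cat(sprintf(
    "atlas_classification: %d housekeeping, %d tissue-specific, %d overlap\n",
    length(x$housekeeping), nts, length(x$overlap)))
  invisible(x)
}

#' Per-gene atlas classification table
#'
#' Long-form view used by the CLI: one row per gene with its class, minimum
#' RPKM across tissues, focal tissue and fold over the next tissue.
#'
#' @param rm an `rpkm_matrix`.
#' @param cfg an [atlas_config()].
#' @return data.frame with columns `gene_id, class, min_rpkm, focal_tissue,
#'   fold_over_next`; `class` is one of `housekeeping`, `specific:<tissue>`,
#'   `both:<tissue>`, `neither`.
#' @export
atlas_table <- function(rm, cfg = atlas_config()) {
  cls <- atlas_report(rm, cfg)
  x <- rm$rpkm
  ts_of <- stats::setNames(rep(NA_character_, nrow(x)), rownames(x))
  for (t in names(cls$tissue_specific)) ts_of[cls$tissue_specific[[t]]] <- t
  top_idx <- max.col(x, ties.method = "first")
  top1 <- x[cbind(seq_len(nrow(x)), top_idx)]
  x2 <- x
  x2[cbind(seq_len(nrow(x)), top_idx)] <- -Inf
  top2 <- pmax(apply(x2, 1, max), 0)
  hk <- rownames(x) %in% cls$housekeeping
  ists <- !is.na(ts_of)
  class <- ifelse(hk & ists, paste0("both:", ts_of),
           ifelse(ists, paste0("specific:", ts_of),
           ifelse(hk, "housekeeping", "neither")))
  data.frame(gene_id = rownames(x), class = unname(class),
             min_rpkm = apply(x, 1, min),
             focal_tissue = colnames(x)[top_idx],
             fold_over_next = ifelse(top2 > 0, top1 / top2, Inf),
             stringsAsFactors = FALSE)
}
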