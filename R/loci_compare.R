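# Novel-locus detection against a genome annotation (two-stage: nucleotide
# homology, then coordinate overlap), ORF screening of novel loci, merging of
# novel sets with redundancy removal, and alternative-splicing summaries.

#' Flag predicted loci as known or novel
#'
#' Two-stage filter of predicted gene loci against an annotation. Stage 1: a
#' predicted locus is `known_by_blast` when any of its transcripts (or the
#' locus id itself) has a nucleotide hit against the annotated mRNAs at the
#' E-value cutoff (default 1e-5). Stage 2: a remaining locus is
#' `known_by_overlap` when its span overlaps an annotated locus span on the
#' same seqname by at least `min_overlap_bp` (strand-agnostic by default).
#' Everything else is novel. The three sets partition the predicted ids.
#'
#' @param predicted `locus_set` of predicted loci (see [gtf_loci()]).
#' @param annotated `locus_set` of annotated loci.
#' @param blastn_hits hit data.frame whose `query_id` values are predicted
#'   transcript or locus ids (may be empty).
#' @param e_cutoff stage-1 E-value cutoff (default 1e-5).
#' @param stranded require same-strand overlap in stage 2 (default FALSE).
#' @param min_overlap_bp minimum span overlap in bp (default 1).
#' @return object of class `novel_locus_report`: list with `novel_ids`,
#'   `known_by_blast`, `known_by_overlap` (sorted character vectors) and
#'   `n_predicted`.
#' @export
flag_known_loci <- function(predicted, annotated, blastn_hits = NULL,
                            e_cutoff = 1e-5, stranded = FALSE,
                            min_overlap_bp = 1L) {
  stopifnot(inherits(predicted, "locus_set"), inherits(annotated, "locus_set"))
  pl <- predicted$loci
  ids <- pl$gene_id
  known_blast <- character()
  if (!is.null(blastn_hits) && nrow(blastn_hits)) {
    q <- unique(blastn_hits$query_id[blastn_hits$evalue <= e_cutoff])
    tx2gene <- stats::setNames(predicted$transcripts$gene_id,
                               predicted$transcripts$transcript_id)
    hit_genes <- unique(c(q[q %in% ids], unname(tx2gene[q[q %in% names(tx2gene)]])))
    known_blast <- intersect(ids, hit_genes)
  }
  rest <- setdiff(ids, known_blast)
  known_overlap <- character()
  if (length(rest) && nrow(annotated$loci)) {
    pr <- pl[pl$gene_id %in% rest, , drop = FALSE]
    an <- annotated$loci
    missing_sq <- setdiff(pr$seqname, an$seqname)
    if (length(missing_sq)) {
      message("predicted seqname(s) absent from annotation: ",
              paste(missing_sq, collapse = ", "))
    }
    gp <- GenomicRanges::GRanges(pr$seqname,
                                 IRanges::IRanges(pr$start, pr$end),
                                 strand = pr$strand)
    ga <- GenomicRanges::GRanges(an$seqname,
                                 IRanges::IRanges(an$start, an$end),
                                 strand = an$strand)
    # disjoint seqname sets are expected (already logged above)
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(gp, ga,
                                  minoverlap = as.integer(min_overlap_bp),
                                  ignore.strand = !stranded))
    known_overlap <- unique(pr$gene_id[S4Vectors::queryHits(ov)])
  }
  novel <- setdiff(rest, known_overlap)
  structure(list(novel_ids = sort(novel),
                 known_by_blast = sort(known_blast),
                 known_by_overlap = sort(known_overlap),
                 n_predicted = length(ids)),
            class = "novel_locus_report")
}

#' @export
print.novel_locus_report <- function(x, ...) {
  cat(sprintf(paste0("novel_locus_report: %d predicted = %d novel + ",
                     "%d known by homology + %d known by overlap\n"),
              x$n_predicted, length(x$novel_ids), length(x$known_by_blast),
              length(x$known_by_overlap)))
  invisible(x)
}

#' Screen novel loci for coding ORFs
#'
#' Classifies each novel locus by the interior-ORF rule on its transcript
#' sequence: `full_orf` when the longest ORF is interior (full-length call),
#' `partial_orf` when an ORF of at least `min_aa` residues exists but touches
#' a boundary, `none` otherwise.
#'
#' @param novel_ids character vector of novel locus ids.
#' @param sequences data.frame with `id`, `seq` covering every novel id.
#' @param min_aa minimum protein length (default 100).
#' @return named character vector, id -> one of `full_orf, partial_orf, none`.
#' @export
screen_novel_orfs <- function(novel_ids, sequences, min_aa = 100L) {
  missing <- setdiff(novel_ids, sequences$id)
  if (length(missing)) stop("no sequence for novel id: ", missing[1])
  vapply(novel_ids, function(id) {
    s <- sequences$seq[match(id, sequences$id)]
    orfs <- scan_orfs(s, id = id, min_aa = min_aa)
    if (!nrow(orfs)) return("none")
    v <- classify_full_length(nchar(s), orfs[1, ])
    if (v$is_full_length) "full_orf" else "partial_orf"
  }, character(1))
}

#' Merge novel loci with unmatched contigs, removing redundancy
#'
#' Combines genome-predicted novel loci with de novo contigs that matched no
#' annotated mRNA. Contigs named in any redundancy pair (i.e. judged to
#' duplicate a novel locus by an upstream homology screen) are dropped; the
#' result is the union of the novel loci and the surviving contigs.
#'
#' @param novel_locus_ids character vector of novel locus ids.
#' @param unmatched_contig_ids character vector of unmatched contig ids.
#' @param redundancy_pairs data.frame with columns `locus_id`, `contig_id`
#'   (may be empty/NULL).
#' @return list with `combined_ids`, `n_combined`, `n_novel_loci`,
#'   `n_contigs_kept`, `n_contigs_removed`.
#' @export
merge_novel <- function(novel_locus_ids, unmatched_contig_ids,
                        redundancy_pairs = NULL) {
  novel_locus_ids <- unique(novel_locus_ids)
  unmatched_contig_ids <- unique(unmatched_contig_ids)
  removed <- character()
  if (!is.null(redundancy_pairs) && nrow(redundancy_pairs)) {
    stopifnot(all(c("locus_id", "contig_id") %in% names(redundancy_pairs)))
    badl <- setdiff(redundancy_pairs$locus_id, novel_locus_ids)
    if (length(badl)) stop("redundancy pair references unknown locus: ", badl[1])
    badc <- setdiff(redundancy_pairs$contig_id, unmatched_contig_ids)
    if (length(badc)) stop("redundancy pair references unknown contig: ", badc[1])
    removed <- unique(redundancy_pairs$contig_id)
  }
  kept <- setdiff(unmatched_contig_ids, removed)
  combined <- union(novel_locus_ids, kept)
  list(combined_ids = sort(combined), n_combined = length(combined),
       n_novel_loci = length(novel_locus_ids),
       n_contigs_kept = length(kept),
       n_contigs_removed = length(removed))
}

#' Alternative-splicing summary of a locus set
#'
#' @param loci a `locus_set` from [gtf_loci()] (non-empty).
#' @param k_values transcript-count thresholds for the "loci with at least k
#'   transcripts" counts (default 2, 5, 10).
#' @return object of class `splice_stats`: list with `n_loci, n_transcripts,
#'   mean_transcripts_per_locus, loci_ge_k` (named vector), `n_exons,
#'   mean_exons_per_locus`. Means are rounded half-up to 2 decimals.
#' @export
splice_stats <- function(loci, k_values = c(2L, 5L, 10L)) {
  stopifnot(inherits(loci, "locus_set"))
  df <- loci$loci
  if (nrow(df) == 0L) stop("splice_stats needs at least one locus")
  ge <- stats::setNames(
    vapply(k_values, function(k) sum(df$n_transcripts >= k), integer(1)),
    as.character(k_values))
  structure(list(
    n_loci = nrow(df),
    n_transcripts = sum(df$n_transcripts),
    mean_transcripts_per_locus = round_half_up(
      sum(df$n_transcripts) / nrow(df), 2),
    loci_ge_k = ge,
    n_exons = sum(df$n_exons),
    mean_exons_per_locus = round_half_up(sum(df$n_exons) / nrow(df), 2)),
    class = "splice_stats")
}

#' @export
print.splice_stats <- function(x, ...) {
  cat(sprintf(paste0("splice_stats: %d loci, %d transcripts ",
                     "(%.2f/locus), %d exons (%.2f/locus)\n"),
              x$n_loci, x$n_transcripts, x$mean_transcripts_per_locus,
              x$n_exons, x$mean_exons_per_locus))
  for (k in names(x$loci_ge_k)) {
    cat(sprintf("  loci with >= %s transcripts: %d\n", k, x$loci_ge_k[[k]]))
  }
  invisible(x)
}
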