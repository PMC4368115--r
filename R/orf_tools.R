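# Six-frame ORF scanning and the interior-ORF full-length cDNA rule:
# a contig is a putative full-length cDNA when its ORF begins after the
# first base AND its stop codon ends before the last base.

orf_stop_codons <- c("TAA", "TAG", "TGA")

#' Reverse-complement a nucleotide string
#' @param seq character string over {A,C,G,T,N}.
#' @return reverse complement, same alphabet.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Maximal ATG->stop ORFs within one frame of one strand. Codons containing N
# are ordinary sense codons: they are neither start nor stop and never
# terminate an ORF.
scan_frame <- function(seq, frame) {
  n <- nchar(seq)
  ncod <- (n - frame) %/% 3L
  if (ncod < 2L) {
    return(data.frame(start_idx = integer(), stop_idx = integer()))
  }
  pos <- frame + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(seq, pos, pos + 2L)
  stops <- which(codons %in% orf_stop_codons)
  starts <- which(codons == "ATG")
  if (!length(stops) || !length(starts)) {
    return(data.frame(start_idx = integer(), stop_idx = integer()))
  }
  # for each stop, the leftmost ATG after the previous stop (maximal ORF)
  prev_stop <- c(0L, stops[-length(stops)])
  first_start <- vapply(seq_along(stops), function(i) {
    cand <- starts[starts > prev_stop[i] & starts < stops[i]]
    if (length(cand)) cand[1] else NA_integer_
  }, integer(1))
  keep <- !is.na(first_start)
  data.frame(start_idx = first_start[keep], stop_idx = stops[keep])
}

#' Scan a sequence for open reading frames
#'
#' Finds all maximal ATG-to-stop ORFs (standard code: stops TAA/TAG/TGA) with
#' protein length of at least `min_aa` residues, in the three forward frames
#' and, when `both_strands`, the three reverse frames. Coordinates are always
#' reported on the forward-strand axis with `start <= end` (the interval the
#' ORF occupies); `strand` records which strand encodes it. Results are
#' sorted by ORF length descending, ties by strand then start.
#'
#' @param seq nucleotide string, or single-row data.frame with `id`, `seq`.
#' @param id contig id used in the output (ignored when `seq` carries one).
#' @param min_aa minimum protein length in residues, Met included, stop
#'   excluded (default 100).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame with columns `contig_id, strand, frame, start, end,
#'   length_nt, protein_length_aa`.
#' @export
scan_orfs <- function(seq, id = "seq", min_aa = 100L, both_strands = TRUE) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id
    seq <- seq$seq
  }
  stopifnot(min_aa >= 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(contig_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      length_nt = integer(), protein_length_aa = integer(),
                      stringsAsFactors = FALSE)
  if (n < 3L * (min_aa + 1L)) return(empty)
  res <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    s <- if (st == "+") seq else revcomp(seq)
    for (fr in 0:2) {
      hits <- scan_frame(s, fr)
      if (!nrow(hits)) next
      b0 <- fr + 3L * (hits$start_idx - 1L) + 1L   # start codon, scanned axis
      b1 <- fr + 3L * hits$stop_idx                # stop codon last base
      if (st == "+") {
        fstart <- b0; fend <- b1
      } else {
        fstart <- n - b1 + 1L; fend <- n - b0 + 1L
      }
      res[[length(res) + 1L]] <- data.frame(
        contig_id = id, strand = st, frame = fr,
        start = fstart, end = fend,
        length_nt = b1 - b0 + 1L,
        protein_length_aa = (b1 - b0 + 1L) %/% 3L - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[out$protein_length_aa >= min_aa, , drop = FALSE]
  out <- out[order(-out$length_nt, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the interior-ORF full-length rule
#'
#' A contig is called full-length when its ORF begins after the first base
#' and its stop codon ends before the last base; an ORF touching either
#' boundary (or no ORF at all) fails. Pure boundary logic: only the sequence
#' length and the ORF interval matter.
#'
#' @param seq_length contig length in nt.
#' @param orf single-row data.frame from [scan_orfs()] (forward-axis
#'   `start`/`end`), or NULL when the contig has no ORF.
#' @return list with `is_full_length` (logical) and `reason`, one of
#'   `interior`, `starts_at_first_base`, `ends_at_last_base`, `no_orf`.
#' @export
classify_full_length <- function(seq_length, orf = NULL) {
  if (is.null(orf) || (is.data.frame(orf) && nrow(orf) == 0L)) {
    return(list(is_full_length = FALSE, reason = "no_orf"))
  }
  if (is.data.frame(orf)) orf <- as.list(orf[1, ])
  if (orf$start < 1 || orf$end > seq_length) {
    stop("ORF [", orf$start, ", ", orf$end, "] outside sequence of length ",
         seq_length)
  }
  if (orf$start <= 1) {
    list(is_full_length = FALSE, reason = "starts_at_first_base")
  } else if (orf$end >= seq_length) {
    list(is_full_length = FALSE, reason = "ends_at_last_base")
  } else {
    list(is_full_length = TRUE, reason = "interior")
  }
}

#' Call the full-length cDNA set of a contig collection
#'
#' Scans each contig, classifies its longest ORF with the interior rule, and
#' returns the ids passing plus the per-contig verdicts.
#'
#' @param contigs data.frame with columns `id`, `seq` (see [read_fasta()]).
#' @param min_aa minimum protein length for the ORF scan (default 100).
#' @param both_strands scan both strands (default TRUE).
#' @return list with `full_length_ids` (character) and `verdicts`
#'   (data.frame `contig_id, is_full_length, reason, orf_start, orf_end,
#'   orf_strand`).
#' @export
call_full_length_set <- function(contigs, min_aa = 100L, both_strands = TRUE) {
  verdicts <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
    orfs <- scan_orfs(contigs$seq[i], id = contigs$id[i], min_aa = min_aa,
                      both_strands = both_strands)
    top <- if (nrow(orfs)) orfs[1, ] else NULL
    v <- classify_full_length(nchar(contigs$seq[i]), top)
    data.frame(contig_id = contigs$id[i],
               is_full_length = v$is_full_length, reason = v$reason,
               orf_start = if (is.null(top)) NA_integer_ else top$start,
               orf_end = if (is.null(top)) NA_integer_ else top$end,
               orf_strand = if (is.null(top)) NA_character_ else top$strand,
               stringsAsFactors = FALSE)
  }))
  if (is.null(verdicts)) {
    verdicts <- data.frame(contig_id = character(), is_full_length = logical(),
                           reason = character(), orf_start = integer(),
                           orf_end = integer(), orf_strand = character(),
                           stringsAsFactors = FALSE)
  }
  list(full_length_ids = verdicts$contig_id[verdicts$is_full_length],
       verdicts = verdicts)
}
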