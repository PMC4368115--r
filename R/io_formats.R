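# ---- shared helpers ---------------------------------------------------------

#' Half-up decimal rounding
#'
#' Rounds half-way cases away from zero at a fixed number of decimals, unlike
#' base [round()] which rounds half to even. Used for every reported fraction
#' so that printed summaries are reproducible across platforms.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # tolerance absorbs binary representation error of values like 2.675
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Render an "n (x%)" style fraction
#'
#' @param numerator non-negative count.
#' @param denominator positive count.
#' @param decimals decimal places for the percentage (half-up rounding).
#' @return object of class `fraction_report`: list with `numerator`,
#'   `denominator`, `percent`, `decimals`.
#' @examples
#' format_fraction(43824, 44990, 1)$percent  # 97.4
#' @export
format_fraction <- function(numerator, denominator, decimals = 1) {
  stopifnot(length(numerator) == 1, length(denominator) == 1)
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0) stop("numerator must be non-negative")
  structure(
    list(
      numerator = as.numeric(numerator),
      denominator = as.numeric(denominator),
      percent = round_half_up(100 * numerator / denominator, decimals),
      decimals = as.integer(decimals)
    ),
    class = "fraction_report"
  )
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf("%s (%s%%)\n",
              format(x$numerator, big.mark = ","),
              formatC(x$percent, format = "f", digits = x$decimals)))
  invisible(x)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are upper-cased and restricted to the alphabet {A,C,G,T,N}.
#' Characters outside that alphabet are mapped to N with a warning
#' (`strict = TRUE` turns this into an error). Duplicate ids are disambiguated
#' with an ordinal suffix and a warning; order is preserved.
#'
#' @param path path to a FASTA file.
#' @param strict reject out-of-alphabet characters instead of mapping to N.
#' @return data.frame with columns `id`, `description`, `seq`, `length`.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), description = character(),
                      seq = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  }
  hdr <- which(startsWith(lines, ">"))
  seq_end <- c(hdr[-1] - 1L, length(lines))
  empty <- hdr[vapply(seq_along(hdr), function(i) {
    body <- lines[seq.int(hdr[i] + 1L, length.out = max(0L, seq_end[i] - hdr[i]))]
    !any(nzchar(gsub("\\s", "", body)))
  }, logical(1))]
  if (length(empty)) {
    stop("malformed FASTA: empty sequence for header at line ", empty[1])
  }
  set <- Biostrings::readBStringSet(path)   # BString: defer alphabet handling
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    warning("duplicate FASTA ids suffixed with ordinals: ",
            paste(dup, collapse = ", "))
    id <- make.unique(id, sep = ".")
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (strict) {
      stop("out-of-alphabet characters in record(s): ",
           paste(utils::head(id[bad], 5), collapse = ", "))
    }
    warning(sum(bad), " record(s) contained out-of-alphabet characters; ",
            "mapped to N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  data.frame(id = id, description = desc, seq = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id`, `seq` and optionally
#'   `description`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  desc <- if ("description" %in% names(records)) records$description else
    character(nrow(records))
  desc <- rep_len(desc, nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- BLAST tabular ----------------------------------------------------------

blast_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
                "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "evalue", "bitscore")

empty_hits_df <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character()), 12), blast_cols), stringsAsFactors = FALSE)
  for (j in 3:12) df[[j]] <- numeric()
  df
}

empty_gtf_df <- function() {
  data.frame(seqname = character(), source = character(),
             feature = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             transcript_id = character(), stringsAsFactors = FALSE)
}

#' Read a 12-column tabular BLAST hit file (outfmt 6)
#'
#' @param path path to the tab-separated hit table (no header).
#' @param max_evalue retain rows with `evalue <= max_evalue`. The number of
#'   excluded rows is reported with a message.
#' @return data.frame with the standard 12 columns named
#'   `query_id, subject_id, pct_identity, aln_length, mismatches, gap_opens,
#'   q_start, q_end, s_start, s_end, evalue, bitscore`.
#' @export
read_blast_tab <- function(path, max_evalue = Inf) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) return(empty_hits_df())
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    stop("expected 12 tab-separated columns, got ", nc[nc != 12L][1],
         " at row ", which(nc != 12L)[1])
  }
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   stringsAsFactors = FALSE)
  for (j in 3:12) df[[blast_cols[j]]] <- as.numeric(m[, j])
  if (anyNA(df[3:12])) {
    stop("non-numeric value in a numeric BLAST column at row ",
         which(rowSums(is.na(df[3:12])) > 0)[1])
  }
  if (any(df$evalue < 0)) stop("negative E-value at row ", which(df$evalue < 0)[1])
  keep <- df$evalue <= max_evalue
  if (any(!keep)) {
    message(sum(!keep), " hit(s) excluded at E-value cutoff ", max_evalue)
  }
  df[keep, , drop = FALSE]
}

#' Write hit records as 12-column tabular BLAST format
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(blast_cols %in% names(hits)))
  utils::write.table(hits[, blast_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- GTF --------------------------------------------------------------------

#' Read a GTF file into a feature table
#'
#' Parses the 9-column GTF via \pkg{rtracklayer} and returns a plain feature
#' data.frame restricted to the fields the atlas pipeline needs. Every row
#' must carry a `gene_id` attribute; exon and transcript rows must also carry
#' `transcript_id`.
#'
#' @param path path to a GTF file.
#' @return data.frame with columns `seqname, source, feature, start, end,
#'   strand, gene_id, transcript_id` (1-based inclusive coordinates).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nonblank <- sum(nzchar(trimws(
    grep("^#", readLines(path, warn = FALSE), value = TRUE, invert = TRUE))))
  if (nonblank == 0L) return(empty_gtf_df())
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id) || anyNA(mc$gene_id)) {
    stop("GTF record without gene_id attribute in ", path)
  }
  tx <- if (is.null(mc$transcript_id)) rep(NA_character_, length(gr)) else
    as.character(mc$transcript_id)
  feat <- as.character(mc$type)
  if (any(feat %in% c("exon", "transcript") & (is.na(tx) | !nzchar(tx)))) {
    stop("exon/transcript GTF record without transcript_id in ", path)
  }
  data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    source = if (is.null(mc$source)) "." else as.character(mc$source),
    feature = feat,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(mc$gene_id),
    transcript_id = ifelse(is.na(tx), "", tx),
    stringsAsFactors = FALSE
  )
}

#' Write a feature table as GTF
#'
#' @param features data.frame as returned by [read_gtf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path) {
  need <- c("seqname", "feature", "start", "end", "strand", "gene_id")
  stopifnot(all(need %in% names(features)))
  src <- if ("source" %in% names(features)) features$source else "troutatlas"
  tx <- if ("transcript_id" %in% names(features)) features$transcript_id else ""
  attrs <- ifelse(
    nzchar(tx),
    sprintf('gene_id "%s"; transcript_id "%s";', features$gene_id, tx),
    sprintf('gene_id "%s";', features$gene_id)
  )
  out <- paste(features$seqname, src, features$feature,
               features$start, features$end, ".",
               features$strand, ".", attrs, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Group GTF features into gene loci
#'
#' Builds the locus-level view used by the splice statistics and novel-locus
#' comparison: one row per gene with its span (outermost exon coordinates,
#' falling back to any feature when a gene has no exon rows), and one row per
#' transcript with its exon count.
#'
#' @param features GTF feature data.frame from [read_gtf()].
#' @return object of class `locus_set`: list with elements `loci` (data.frame
#'   `gene_id, seqname, strand, start, end, n_transcripts, n_exons`) and
#'   `transcripts` (data.frame `gene_id, transcript_id, n_exons, start, end`).
#' @export
gtf_loci <- function(features) {
  if (nrow(features) == 0L) {
    return(structure(list(
      loci = data.frame(gene_id = character(), seqname = character(),
                        strand = character(), start = integer(),
                        end = integer(), n_transcripts = integer(),
                        n_exons = integer(), stringsAsFactors = FALSE),
      transcripts = data.frame(gene_id = character(),
                               transcript_id = character(),
                               n_exons = integer(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE)),
      class = "locus_set"))
  }
  if (any(features$start > features$end)) stop("GTF feature with start > end")
  ex <- features[features$feature == "exon", , drop = FALSE]
  span_src <- if (nrow(ex)) ex else features
  loci <- do.call(rbind, lapply(split(span_src, span_src$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], seqname = g$seqname[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  txsrc <- features[nzchar(features$transcript_id), , drop = FALSE]
  transcripts <- do.call(rbind, lapply(
    split(txsrc, txsrc$transcript_id), function(t) {
      e <- t[t$feature == "exon", , drop = FALSE]
      if (!nrow(e)) e <- t
      data.frame(gene_id = t$gene_id[1], transcript_id = t$transcript_id[1],
                 n_exons = sum(t$feature == "exon"),
                 start = min(e$start), end = max(e$end),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(transcripts)) {
    transcripts <- data.frame(gene_id = character(),
                              transcript_id = character(),
                              n_exons = integer(), start = integer(),
                              end = integer(), stringsAsFactors = FALSE)
  }
  ntx <- table(transcripts$gene_id)
  nex <- tapply(transcripts$n_exons, transcripts$gene_id, sum)
  loci$n_transcripts <- as.integer(ntx[loci$gene_id])
  loci$n_transcripts[is.na(loci$n_transcripts)] <- 0L
  loci$n_exons <- as.integer(nex[loci$gene_id])
  loci$n_exons[is.na(loci$n_exons)] <- 0L
  rownames(loci) <- NULL
  rownames(transcripts) <- NULL
  structure(list(loci = loci, transcripts = transcripts), class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("locus_set: %d loci, %d transcripts\n",
              nrow(x$loci), nrow(x$transcripts)))
  invisible(x)
}

# ---- TSV expression matrices ------------------------------------------------

#' Read a genes-by-tissues TSV matrix
#'
#' First column holds transcript/gene ids, header row holds tissue names.
#'
#' @param path path to the TSV.
#' @return numeric matrix with gene rownames and tissue colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a genes-by-tissues matrix as TSV
#' @param m numeric matrix with rownames (gene ids) and colnames (tissues).
#' @param path output path.
#' @param id_col name for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
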