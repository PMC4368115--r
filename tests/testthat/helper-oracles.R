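# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain loops and set algebra only.

bf_n50 <- function(lengths) {
  total <- sum(lengths)
  best <- 0
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) best <- max(best, L)
  }
  best
}

bf_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# all maximal ATG->stop ORFs via exhaustive enumeration: every ATG is walked
# codon-by-codon to its stop; ORFs sharing a stop keep only the leftmost ATG.
bf_scan_orfs <- function(seq, min_aa = 100, both_strands = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (strand in if (both_strands) c("+", "-") else "+") {
    s <- if (strand == "+") seq else bf_revcomp(seq)
    n <- nchar(s)
    for (p in seq_len(max(0, n - 2))) {
      if (substr(s, p, p + 2) != "ATG") next
      q <- p
      stop_at <- NA
      while (q + 2 <= n) {
        if (substr(s, q, q + 2) %in% stops) { stop_at <- q; break }
        q <- q + 3
      }
      if (is.na(stop_at)) next
      found[[length(found) + 1]] <- data.frame(
        strand = strand, sp = p, ep = stop_at + 2, stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) {
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), protein_length_aa = integer()))
  }
  df <- do.call(rbind, found)
  # maximal: leftmost start per (strand, stop)
  df <- df[order(df$strand, df$ep, df$sp), ]
  df <- df[!duplicated(df[, c("strand", "ep")]), ]
  n <- nchar(seq)
  out <- data.frame(
    strand = df$strand,
    start = ifelse(df$strand == "+", df$sp, n - df$ep + 1),
    end = ifelse(df$strand == "+", df$ep, n - df$sp + 1),
    protein_length_aa = (df$ep - df$sp + 1) %/% 3 - 1)
  out <- out[out$protein_length_aa >= min_aa, , drop = FALSE]
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

bf_select_reps <- function(contigs) {
  reps <- character()
  for (comp in unique(contigs$component_id)) {
    members <- contigs[contigs$component_id == comp, ]
    if (nrow(members) > 1) {
      withhit <- members[members$has_hit, ]
      if (nrow(withhit) > 0) {
        best <- withhit$id[1]
        for (i in seq_len(nrow(withhit))) {
          if (withhit$length[i] > withhit$length[withhit$id == best] ||
              (withhit$length[i] == withhit$length[withhit$id == best] &&
               withhit$id[i] < best)) best <- withhit$id[i]
        }
        reps <- c(reps, best)
      }
    }
  }
  tab <- table(contigs$component_id)
  singles <- contigs[tab[contigs$component_id] == 1 & contigs$has_hit, ]
  for (subj in unique(singles$best_hit_subject)) {
    grp <- singles[singles$best_hit_subject == subj, ]
    best <- grp$id[1]
    for (i in seq_len(nrow(grp))) {
      if (grp$length[i] > grp$length[grp$id == best] ||
          (grp$length[i] == grp$length[grp$id == best] &&
           grp$id[i] < best)) best <- grp$id[i]
    }
    reps <- c(reps, best)
  }
  sort(unique(reps))
}

bf_tier_counts <- function(coverages, tiers) {
  sapply(tiers, function(t) {
    n <- 0
    for (cv in coverages) if (cv >= t) n <- n + 1
    n
  })
}

bf_overlapping_pairs <- function(a, b) {
  # all-pairs interval intersection on (seqname, start, end) data.frames
  hits <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$seqname[i] == b$seqname[j] &&
          a$start[i] <= b$end[j] && b$start[j] <= a$end[i]) {
        hits <- hits + 1
      }
    }
  }
  hits
}

bf_ts_classify <- function(rpkm, fold = 8) {
  # brute-force all-(gene, tissue) evaluation of the fold rule
  out <- stats::setNames(vector("list", ncol(rpkm)), colnames(rpkm))
  for (t in colnames(rpkm)) out[[t]] <- character()
  for (g in rownames(rpkm)) {
    for (t in colnames(rpkm)) {
      v <- rpkm[g, t]
      others <- max(rpkm[g, setdiff(colnames(rpkm), t)])
      if (v > 0 && (others == 0 || v >= fold * others)) {
        out[[t]] <- c(out[[t]], g)
      }
    }
  }
  out
}

random_hits_df <- function(n, queries, subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    query_id = sample(queries, n, replace = TRUE),
    subject_id = sample(subjects, n, replace = TRUE),
    pct_identity = round(runif(n, 40, 100), 2),
    aln_length = sample(50:500, n, replace = TRUE),
    mismatches = sample(0:30, n, replace = TRUE),
    gap_opens = sample(0:5, n, replace = TRUE),
    q_start = rep(1L, n), q_end = sample(50:500, n, replace = TRUE),
    s_start = rep(1L, n), s_end = sample(50:500, n, replace = TRUE),
    evalue = 10^runif(n, -50, 0),
    bitscore = round(runif(n, 20, 1000), 1),
    stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
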