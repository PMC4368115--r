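# Synthetic-data generators emulating the statistical structure of the
# 13-tissue non-normalized RNA-seq atlas design, with planted ground truth
# for parameter-recovery tests: an expression matrix with housekeeping and
# tissue-specific genes, multi-contig assembly components, contigs with
# embedded ORFs at interior/boundary positions, and an annotated/predicted
# GTF pair with planted novel loci.

#' Simulation configuration
#'
#' Defaults describe the emulated atlas design: 13 tissues; ~17% of genes
#' housekeeping (the atlas reports 7,678 of 44,990); tissue-specific genes at
#' roughly 9% of genes split evenly across tissues; planted fold factors
#' uniform in \[8, 40\] so the inclusive 8-fold boundary region is exercised;
#' log-normal baseline expression on the RPKM scale; log-normal transcript
#' lengths clamped to the observed \[500, 50000\] nt contig range; library
#' size 1e7 mapped reads per tissue; Poisson count noise (the design has no
#' replication, so no overdispersion is estimable).
#'
#' @param n_genes number of genes (default 2000).
#' @param n_tissues number of tissues (default 13; named via
#'   [atlas_tissues()]).
#' @param frac_housekeeping fraction of genes planted as housekeeping
#'   (default 0.17).
#' @param n_tissue_specific_per_tissue tissue-specific genes planted per
#'   tissue; `NULL` (the default) plants 9% of the genes split evenly across
#'   tissues (the atlas proportion: 4,021 of 44,990), i.e. 14 per tissue at
#'   the default 2000 genes.
#' @param fold_range range of planted tissue-specific fold factors; the lower
#'   bound must be >= 8 so planted genes satisfy the classification rule by
#'   construction (default c(8, 40)).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale mean and sd of the
#'   baseline RPKM distribution (defaults 2 and 1.5: median RPKM 4).
#' @param length_log_mean,length_log_sd natural-log mean and sd of transcript
#'   length (defaults log(1500) and 0.7), clamped to \[500, 50000\] nt.
#' @param library_size mapped reads per tissue (default 1e7).
#' @param noise `"poisson"` (counts drawn Poisson at the expected value) or
#'   `"none"` (counts are the rounded expectation, with a deterministic
#'   repair pass keeping planted truth exactly consistent).
#' @param seed integer seed; generators are pure functions of the config.
#' @param n_multi_components,n_single_components,hit_prob component-simulation
#'   settings (see [simulate_components()]).
#' @param orf_min_aa minimum planted ORF protein length
#'   (see [simulate_orf_contigs()]).
#' @param n_annotated_loci,n_novel_loci annotation-pair settings
#'   (see [simulate_annotation_pair()]).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_tissues = 13L,
                       frac_housekeeping = 0.17,
                       n_tissue_specific_per_tissue = NULL,
                       fold_range = c(8, 40),
                       baseline_log2_mean = 2, baseline_log2_sd = 1.5,
                       length_log_mean = log(1500), length_log_sd = 0.7,
                       library_size = 1e7,
                       noise = c("poisson", "none"),
                       seed = 1L,
                       n_multi_components = 40L, n_single_components = 60L,
                       hit_prob = 0.6,
                       orf_min_aa = 100L,
                       n_annotated_loci = 20L, n_novel_loci = 5L) {
  noise <- match.arg(noise)
  if (is.null(n_tissue_specific_per_tissue)) {
    n_tissue_specific_per_tissue <- max(1L, round(0.09 * n_genes / n_tissues))
  }
  if (fold_range[1] < 8) stop("fold_range lower bound must be >= 8")
  if (fold_range[2] < fold_range[1]) stop("fold_range must be non-decreasing")
  n_hk <- round(frac_housekeeping * n_genes)
  if (n_hk + n_tissues * n_tissue_specific_per_tissue > n_genes) {
    stop("planted housekeeping + tissue-specific genes exceed n_genes")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    frac_housekeeping = frac_housekeeping,
    n_tissue_specific_per_tissue = as.integer(n_tissue_specific_per_tissue),
    fold_range = fold_range,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    length_log_mean = length_log_mean, length_log_sd = length_log_sd,
    library_size = library_size, noise = noise, seed = as.integer(seed),
    n_multi_components = as.integer(n_multi_components),
    n_single_components = as.integer(n_single_components),
    hit_prob = hit_prob, orf_min_aa = as.integer(orf_min_aa),
    n_annotated_loci = as.integer(n_annotated_loci),
    n_novel_loci = as.integer(n_novel_loci)),
    class = "sim_config")
}

sim_tissue_names <- function(n) {
  base <- atlas_tissues()
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("tissue%02d", seq.int(length(base) + 1, n)))
}

# counts needed so that count * 1e9 / (L * N) reaches rpkm
counts_for_rpkm <- function(rpkm, len, lib) ceiling(rpkm * len * lib / 1e9)

#' Simulate an expression count matrix with planted truth
#'
#' Plants three gene classes on a true-RPKM scale, converts to expected
#' counts `rpkm * length * library_size / 1e9`, and emits either Poisson
#' counts or the rounded expectation:
#' \itemize{
#'   \item housekeeping genes: every tissue at RPKM >= 2 (so the RPKM >= 1
#'     rule holds with margin under Poisson noise), max/second-max ratio
#'     capped below 8 so they are never tissue-specific;
#'   \item tissue-specific genes: baseline in 12 tissues with one forced
#'     low-expression tissue (RPKM < 0.3, so they are never housekeeping),
#'     and a focal tissue at `fold` times the maximum of the others,
#'     `fold ~ U(fold_range)`;
#'   \item baseline genes: log-normal expression with 2-4 forced
#'     low-expression tissues and the max/second-max ratio capped below 8,
#'     so they satisfy neither rule.
#' }
#' With `noise = "none"` a deterministic repair pass nudges rounded counts so
#' that re-deriving RPKM from the emitted integers recovers the planted
#' labels exactly.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]), `truth` (list
#'   `housekeeping_ids`, `tissue_specific_ids` = tissue -> ids), and
#'   `true_rpkm` (matrix of planted expression).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  nt <- config$n_tissues
  tissues <- sim_tissue_names(nt)
  gid <- sprintf("gene%05d", seq_len(n))
  lens <- pmin(pmax(round(stats::rlnorm(n, config$length_log_mean,
                                        config$length_log_sd)), 500), 50000)
  n_hk <- round(config$frac_housekeeping * n)
  n_ts <- config$n_tissue_specific_per_tissue
  hk_ids <- gid[seq_len(n_hk)]
  ts_ids <- stats::setNames(vector("list", nt), tissues)
  cursor <- n_hk
  for (t in seq_len(nt)) {
    ts_ids[[t]] <- gid[cursor + seq_len(n_ts)]
    cursor <- cursor + n_ts
  }

  cap_fold <- function(row, cap = 4) {
    # cap max/second-max ratio so the row can never be tissue-specific
    o <- order(row, decreasing = TRUE)
    if (row[o[2]] > 0 && row[o[1]] >= 8 * row[o[2]]) {
      row[o[1]] <- cap * row[o[2]]
    }
    row
  }

  E <- matrix(0, n, nt, dimnames = list(gid, tissues))
  for (i in seq_len(n_hk)) {
    base <- max(2, 2^stats::rnorm(1, config$baseline_log2_mean,
                                  config$baseline_log2_sd))
    row <- pmax(2, base * 2^stats::rnorm(nt, 0, 0.5))
    E[i, ] <- cap_fold(row)
  }
  row_i <- n_hk
  for (t in seq_len(nt)) {
    for (k in seq_len(n_ts)) {
      row_i <- row_i + 1
      base <- max(1, 2^stats::rnorm(1, config$baseline_log2_mean,
                                    config$baseline_log2_sd))
      row <- pmax(0.5, base * 2^stats::rnorm(nt, 0, 0.5))
      dip <- sample(setdiff(seq_len(nt), t), 1)
      row[dip] <- stats::runif(1, 0.02, 0.3)
      fold <- stats::runif(1, config$fold_range[1], config$fold_range[2])
      row[t] <- fold * max(row[-t])
      E[row_i, ] <- row
    }
  }
  for (i in seq.int(row_i + 1, length.out = n - row_i)) {
    base <- max(0.5, 2^stats::rnorm(1, config$baseline_log2_mean,
                                    config$baseline_log2_sd))
    row <- pmax(0.25, base * 2^stats::rnorm(nt, 0, 0.5))
    dips <- sample(seq_len(nt), sample(2:4, 1))
    row[dips] <- stats::runif(length(dips), 0.02, 0.3)
    E[i, ] <- cap_fold(row)
  }

  mu <- E * outer(lens, rep(config$library_size, nt)) / 1e9
  counts <- if (config$noise == "poisson") {
    matrix(stats::rpois(length(mu), mu), n, nt, dimnames = dimnames(mu))
  } else {
    round(mu)
  }

  if (config$noise == "none") {
    counts <- repair_noise_free(counts, lens, config$library_size,
                                hk_ids, ts_ids, tissues)
  }

  cm <- count_matrix(counts, stats::setNames(lens, gid),
                     stats::setNames(rep(config$library_size, nt), tissues))
  list(counts = cm,
       truth = list(housekeeping_ids = hk_ids, tissue_specific_ids = ts_ids),
       true_rpkm = E)
}

# Deterministic post-rounding repair: integer rounding of expected counts can
# perturb a planted gene across the inclusive RPKM>=1 / 8-fold boundaries;
# nudge counts so the emitted integers are exactly consistent with the truth.
repair_noise_free <- function(counts, lens, lib, hk_ids, ts_ids, tissues) {
  gid <- rownames(counts)
  rpkm_of <- function(g) counts[g, ] * 1e9 / (lens[match(g, gid)] * lib)
  hk_min_count <- counts_for_rpkm(1, lens, lib)   # per gene
  names(hk_min_count) <- gid
  for (g in hk_ids) {
    low <- rpkm_of(g) < 1
    counts[g, low] <- hk_min_count[g]
  }
  ts_flat <- unlist(ts_ids, use.names = FALSE)
  focal_of <- stats::setNames(
    rep(names(ts_ids), vapply(ts_ids, length, 1L)), ts_flat)
  for (g in ts_flat) {
    r <- rpkm_of(g)
    t <- focal_of[[g]]
    need <- 8 * max(r[setdiff(tissues, t)])
    if (r[t] < need) {
      counts[g, t] <- counts_for_rpkm(need, lens[match(g, gid)], lib)
    }
  }
  # non-housekeeping genes must dip below RPKM 1 somewhere
  for (g in setdiff(gid, hk_ids)) {
    r <- rpkm_of(g)
    if (all(r >= 1)) {
      low <- which.min(r)
      counts[g, low] <- max(0L, hk_min_count[g] - 1L)
    }
  }
  # unplanted genes must not qualify as tissue-specific
  for (g in setdiff(gid, c(hk_ids, ts_flat))) {
    repeat {
      r <- rpkm_of(g)
      o <- order(r, decreasing = TRUE)
      if (!(r[o[1]] > 0 && (r[o[2]] <= 0 || r[o[1]] >= 8 * r[o[2]]))) break
      counts[g, o[2]] <- counts[g, o[2]] + 1L
    }
  }
  counts
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate assembly components with known representatives
#'
#' Emits multi-contig components (2-6 members) and single-contig components;
#' contigs carry a database hit with probability `hit_prob`. Within each
#' multi-contig component exactly one contig is strictly longest among the
#' hit-bearing members and is recorded as the truth representative.
#' Hit-bearing singletons share subject accessions drawn from a small pool,
#' so subject-group selection is exercised; hit-less contigs occasionally
#' carry a decoy hit above the E-value cutoff.
#'
#' @param config a [sim_config()].
#' @param with_seqs also generate random nucleotide sequences (default FALSE;
#'   lengths alone drive representative selection).
#' @return list with `contigs` (a [contig_table()], hit columns populated),
#'   `hits` (12-column hit data.frame), `truth` (list `representative_ids`),
#'   and optionally `seqs`.
#' @export
simulate_components <- function(config = sim_config(), with_seqs = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  e_good <- 1e-30
  e_decoy <- 1e-3     # above the 1e-10 cutoff: must be filtered out
  rows <- list(); hit_rows <- list()
  subj_pool <- sprintf("NP_%06d", seq_len(max(
    4L, config$n_single_components %/% 2L)))
  cid <- 0L
  add_contig <- function(comp, len, subject, evalue) {
    cid <<- cid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      id = sprintf("comp%04d_seq%04d", comp, cid),
      component_id = sprintf("comp%04d", comp),
      length = as.integer(len),
      best_hit_subject = subject, best_hit_evalue = evalue,
      stringsAsFactors = FALSE)
    if (nzchar(subject)) {
      hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
        query_id = sprintf("comp%04d_seq%04d", comp, cid),
        subject_id = subject, pct_identity = round(stats::runif(1, 70, 99), 2),
        aln_length = as.integer(len %/% 3), mismatches = 5L, gap_opens = 1L,
        q_start = 1L, q_end = as.integer(len %/% 3),
        s_start = 1L, s_end = as.integer(len %/% 3),
        evalue = evalue, bitscore = round(stats::runif(1, 50, 900), 1),
        stringsAsFactors = FALSE)
    }
  }
  reps <- character()
  for (m in seq_len(config$n_multi_components)) {
    k <- sample(2:6, 1)
    lens <- sample(600:3000, k, replace = TRUE)
    has <- stats::runif(k) < config$hit_prob
    top <- NA_integer_
    if (any(has)) {
      hb <- which(has)
      top <- hb[order(-lens[hb])][1]
      if (sum(lens[hb] == lens[top]) > 1L) lens[top] <- max(lens[hb]) + 1L
    }
    first_id <- cid + 1L
    for (j in seq_len(k)) {
      subj <- if (has[j]) sample(subj_pool, 1) else ""
      ev <- if (has[j]) e_good else NA_real_
      if (!has[j] && stats::runif(1) < 0.2) { subj <- ""; ev <- NA_real_ }
      add_contig(m, lens[j], subj, ev)
    }
    if (any(has)) {
      reps <- c(reps, sprintf("comp%04d_seq%04d", m, first_id + top - 1L))
    }
  }
  for (s in seq_len(config$n_single_components)) {
    comp <- config$n_multi_components + s
    len <- sample(600:3000, 1)
    if (stats::runif(1) < config$hit_prob) {
      add_contig(comp, len, sample(subj_pool, 1), e_good)
    } else if (stats::runif(1) < 0.3) {
      # decoy hit above the cutoff: contig stays effectively hit-less
      cid_before <- cid
      add_contig(comp, len, "", NA_real_)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = sprintf("comp%04d_seq%04d", comp, cid_before + 1L),
        subject_id = sample(subj_pool, 1), pct_identity = 45.0,
        aln_length = 40L, mismatches = 20L, gap_opens = 3L,
        q_start = 1L, q_end = 40L, s_start = 1L, s_end = 40L,
        evalue = e_decoy, bitscore = 28.0, stringsAsFactors = FALSE)
    } else {
      add_contig(comp, len, "", NA_real_)
    }
  }
  contigs <- do.call(rbind, rows)
  contigs$has_hit <- nzchar(contigs$best_hit_subject)
  contigs <- contigs[, c("id", "component_id", "length", "has_hit",
                         "best_hit_subject", "best_hit_evalue")]
  # singleton truth: longest hit-bearing contig per subject group
  sizes <- table(contigs$component_id)
  single <- contigs[sizes[contigs$component_id] == 1L & contigs$has_hit, ]
  if (nrow(single)) {
    srep <- vapply(split(single, single$best_hit_subject), function(df) {
      df$id[order(-df$length, df$id)][1]
    }, character(1))
    reps <- c(reps, unname(srep))
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else empty_hits_df()
  out <- list(contigs = contigs, hits = hits,
              truth = list(representative_ids = sort(unique(reps))))
  if (with_seqs) {
    out$seqs <- data.frame(id = contigs$id,
                           seq = vapply(contigs$length, random_dna,
                                        character(1)),
                           stringsAsFactors = FALSE)
  }
  out
}

# Sequence fragments that cannot create start codons: no ATG substring
# (forward starts) and no CAT substring (reverse-strand starts), verified in
# tests. Body codons additionally exclude in-frame stops.
safe_codons <- c("GCC", "GGA", "CTC", "TCC", "ACC", "GAA", "TTC")

safe_seq <- function(n) {
  if (n <= 0) return("")
  s <- paste(sample(safe_codons, ceiling(n / 3), replace = TRUE),
             collapse = "")
  s <- substr(s, 1, n)
  # mid-codon trimming can leave a trailing C (CAT risk before a planted
  # ATG) or trailing ..AT+C; ending in A can create neither ATG nor CAT
  if (substring(s, n, n) == "C") substr(s, n, n) <- "A"
  s
}

#' Simulate contigs with embedded ORFs at known positions
#'
#' Each contig carries at most one ORF (of at least `orf_min_aa` residues)
#' built from codons that cannot spawn secondary start codons on either
#' strand, placed in one of four classes: interior start and stop (truth
#' full-length), starting at base 1, stop ending at the last base, or no ORF
#' at all. Half the contigs are reverse-complemented so minus-strand calls
#' are exercised; truth boundary reasons are recorded on the forward axis.
#'
#' @param config a [sim_config()].
#' @param n_contigs number of contigs (default 200).
#' @return list with `contigs` (data.frame `id, seq, length`) and `truth`
#'   (list `full_length_ids`, `classes` data.frame
#'   `id, reason, is_full_length, strand`).
#' @export
simulate_orf_contigs <- function(config = sim_config(), n_contigs = 200L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  classes <- c("interior", "starts_at_first_base", "ends_at_last_base",
               "no_orf")
  cls <- sample(rep_len(classes, n_contigs))
  rows <- lapply(seq_len(n_contigs), function(i) {
    aa <- sample(config$orf_min_aa:(config$orf_min_aa + 150L), 1)
    body <- paste(sample(safe_codons, aa - 1L, replace = TRUE), collapse = "")
    orf <- paste0("ATG", body, "TAA")
    lf <- safe_seq(sample(2:60, 1))
    rf <- safe_seq(sample(2:60, 1))
    seq <- switch(cls[i],
      interior = paste0(lf, orf, rf),
      starts_at_first_base = paste0(orf, rf),
      ends_at_last_base = paste0(lf, orf),
      no_orf = safe_seq(3L * (aa + 1L) + nchar(lf) + nchar(rf)))
    strand <- "+"
    reason <- cls[i]
    if (stats::runif(1) < 0.5) {
      seq <- revcomp(seq)
      strand <- "-"
      reason <- switch(reason,
                       starts_at_first_base = "ends_at_last_base",
                       ends_at_last_base = "starts_at_first_base",
                       reason)
    }
    data.frame(id = sprintf("orfctg%04d", i), seq = seq,
               length = nchar(seq), reason = reason,
               is_full_length = reason == "interior", strand = strand,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  list(contigs = df[, c("id", "seq", "length")],
       truth = list(full_length_ids = df$id[df$is_full_length],
                    classes = df[, c("id", "reason", "is_full_length",
                                     "strand")]))
}

make_locus_features <- function(gene_id, seqname, strand, start, width,
                                n_tx, source) {
  end <- start + width - 1L
  feats <- list()
  for (j in seq_len(n_tx)) {
    tx <- sprintf("%s.t%d", gene_id, j)
    m <- 1L + stats::rpois(1, 3)
    # m non-overlapping exons tiling part of [start, end], first/last pinned
    cuts <- sort(sample(seq.int(start + 1L, end - 1L), 2L * m - 2L))
    es <- c(start, cuts[seq(2, length.out = m - 1L, by = 2)] + 1L)
    ee <- c(cuts[seq(1, length.out = m - 1L, by = 2)], end)
    if (m == 1L) { es <- start; ee <- end }
    feats[[length(feats) + 1L]] <- data.frame(
      seqname = seqname, source = source, feature = "exon",
      start = as.integer(es), end = as.integer(ee), strand = strand,
      gene_id = gene_id, transcript_id = tx, stringsAsFactors = FALSE)
  }
  do.call(rbind, feats)
}

#' Simulate an annotated/predicted GTF pair with planted novel loci
#'
#' Lays gene loci along toy chromosomes with at least 1.5 kb between
#' neighbours. The predicted set contains every annotated locus (with up to
#' 300 bp of coordinate jitter, so overlap is preserved) plus planted novel
#' loci that are at least 1 kb from any annotated locus. Per-locus transcript
#' counts are drawn from a long-tailed distribution so splice-statistic truth
#' (loci with >= 2, 5, 10 transcripts; exon totals) is known. A nucleotide
#' hit table links ~70% of the reproduced loci to their annotated mRNA at a
#' qualifying E-value; planted novel loci receive at most decoy hits above
#' the cutoff.
#'
#' @param config a [sim_config()].
#' @return list with `annotated` and `predicted` (GTF feature data.frames,
#'   see [read_gtf()]), `hits` (12-column hit data.frame), and `truth` (list
#'   `novel_locus_ids`, `n_transcripts` named per predicted locus).
#' @export
simulate_annotation_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n_ann <- config$n_annotated_loci
  n_nov <- config$n_novel_loci
  tx_pool <- c(1, 1, 1, 2, 2, 3, 5, 6, 10, 12)
  kinds <- sample(c(rep("ann", n_ann), rep("nov", n_nov)))
  cursor <- stats::setNames(c(1000L, 1000L), c("chr1", "chr2"))
  ann <- list(); pred <- list(); hits <- list()
  truth_tx <- integer(); novel_ids <- character()
  ia <- 0L; iv <- 0L
  for (kind in kinds) {
    chr <- sample(names(cursor), 1)
    width <- sample(2000:10000, 1)
    start <- cursor[[chr]]
    cursor[[chr]] <- start + width + sample(1500:4000, 1)
    strand <- sample(c("+", "-"), 1)
    if (kind == "ann") {
      ia <- ia + 1L
      agid <- sprintf("GENE%04d", ia)
      ann[[length(ann) + 1L]] <- make_locus_features(
        agid, chr, strand, start, width, sample(tx_pool, 1), "annotation")
      # reproduced in the predicted set with bounded jitter
      pgid <- sprintf("XLOC_%04d", length(truth_tx) + 1L)
      js <- sample(-300:300, 1); je <- sample(-300:300, 1)
      ntx <- sample(tx_pool, 1)
      pred[[length(pred) + 1L]] <- make_locus_features(
        pgid, chr, strand, start + js, width + je - js, ntx, "prediction")
      truth_tx[pgid] <- ntx
      if (stats::runif(1) < 0.7) {
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = sprintf("%s.t1", pgid), subject_id = agid,
          pct_identity = 98.5, aln_length = as.integer(width %/% 2),
          mismatches = 10L, gap_opens = 1L, q_start = 1L,
          q_end = as.integer(width %/% 2), s_start = 1L,
          s_end = as.integer(width %/% 2), evalue = 1e-30, bitscore = 800,
          stringsAsFactors = FALSE)
      }
    } else {
      iv <- iv + 1L
      pgid <- sprintf("XLOC_%04d", length(truth_tx) + 1L)
      ntx <- sample(tx_pool, 1)
      pred[[length(pred) + 1L]] <- make_locus_features(
        pgid, chr, strand, start, width, ntx, "prediction")
      truth_tx[pgid] <- ntx
      novel_ids <- c(novel_ids, pgid)
      if (stats::runif(1) < 0.3) {
        # decoy hit above the 1e-5 cutoff
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = sprintf("%s.t1", pgid), subject_id = "GENE0001",
          pct_identity = 55, aln_length = 60L, mismatches = 25L,
          gap_opens = 4L, q_start = 1L, q_end = 60L, s_start = 1L,
          s_end = 60L, evalue = 1e-3, bitscore = 30,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(annotated = if (length(ann)) do.call(rbind, ann) else empty_gtf_df(),
       predicted = do.call(rbind, pred),
       hits = if (length(hits)) do.call(rbind, hits) else empty_hits_df(),
       truth = list(novel_locus_ids = sort(novel_ids),
                    n_transcripts = truth_tx))
}

#' Write a full simulated dataset to a directory
#'
#' Materializes counts.tsv, lengths.tsv, libsizes.tsv, contigs.fasta,
#' hits.tsv, annotated.gtf, predicted.gtf and truth.json, as consumed by the
#' CLI subcommands.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(config = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(config)
  comp <- simulate_components(config, with_seqs = TRUE)
  orfs <- simulate_orf_contigs(config)
  ann <- simulate_annotation_pair(config)
  cm <- expr$counts
  write_matrix_tsv(cm$counts, file.path(outdir, "counts.tsv"))
  utils::write.table(
    data.frame(gene_id = names(cm$lengths), length = cm$lengths),
    file.path(outdir, "lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(tissue = names(cm$lib_sizes), library_size = cm$lib_sizes),
    file.path(outdir, "libsizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_fasta(rbind(comp$seqs, orfs$contigs[, c("id", "seq")]),
              file.path(outdir, "contigs.fasta"))
  write_blast_tab(comp$hits, file.path(outdir, "hits.tsv"))
  write_gtf(ann$annotated, file.path(outdir, "annotated.gtf"))
  write_gtf(ann$predicted, file.path(outdir, "predicted.gtf"))
  jsonlite::write_json(
    list(housekeeping_ids = expr$truth$housekeeping_ids,
         tissue_specific_ids = expr$truth$tissue_specific_ids,
         representative_ids = comp$truth$representative_ids,
         full_length_ids = orfs$truth$full_length_ids,
         novel_locus_ids = ann$truth$novel_locus_ids),
    file.path(outdir, "truth.json"), pretty = TRUE)
  invisible(outdir)
}
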