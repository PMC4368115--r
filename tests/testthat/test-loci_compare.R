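# loci_compare: novel-locus flagging, ORF screen, merging, splice stats

toy_locus_set <- function(df) {
  # df: gene_id, seqname, start, end (single-exon, one transcript per locus)
  feats <- data.frame(seqname = df$seqname, source = "toy", feature = "exon",
                      start = df$start, end = df$end, strand = "+",
                      gene_id = df$gene_id,
                      transcript_id = paste0(df$gene_id, ".t1"),
                      stringsAsFactors = FALSE)
  gtf_loci(feats)
}

test_that("flag_known_loci applies blast then overlap then novel", {
  ann <- toy_locus_set(data.frame(gene_id = "A1", seqname = "chr1",
                                  start = 1000L, end = 2000L))
  pred <- toy_locus_set(data.frame(
    gene_id = c("P1", "P2", "P3"), seqname = "chr1",
    start = c(1500L, 12000L, 30000L), end = c(2500L, 13000L, 31000L)))
  hits <- random_hits_df(1, "P2.t1", "A1", seed = 1)
  hits$evalue <- 1e-20
  rep_ <- flag_known_loci(pred, ann, hits)
  expect_equal(rep_$known_by_blast, "P2")
  expect_equal(rep_$known_by_overlap, "P1")
  expect_equal(rep_$novel_ids, "P3")
  # the three sets partition the predicted ids
  expect_equal(sort(c(rep_$novel_ids, rep_$known_by_blast,
                      rep_$known_by_overlap)), c("P1", "P2", "P3"))

  # without the blast stage, ids can only move toward overlap/novel
  rep_nb <- flag_known_loci(pred, ann, NULL)
  expect_true(all(rep_$novel_ids %in% rep_nb$novel_ids))

  # unknown seqname: no overlap possible, logged not fatal
  lonely <- toy_locus_set(data.frame(gene_id = "PX", seqname = "chrZ",
                                     start = 1L, end = 100L))
  expect_message(repx <- flag_known_loci(lonely, ann, NULL), "chrZ")
  expect_equal(repx$novel_ids, "PX")
})

test_that("flag_known_loci recovers planted novel loci from synthgen", {
  for (s in 1:5) {
    sim <- simulate_annotation_pair(sim_config(seed = s))
    rep_ <- flag_known_loci(gtf_loci(sim$predicted),
                            gtf_loci(sim$annotated), sim$hits)
    expect_setequal(rep_$novel_ids, sim$truth$novel_locus_ids)
    expect_equal(length(rep_$novel_ids) + length(rep_$known_by_blast) +
                   length(rep_$known_by_overlap), rep_$n_predicted)
  }
})

test_that("planted novel loci never overlap annotation (brute force)", {
  sim <- simulate_annotation_pair(sim_config(seed = 8, n_annotated_loci = 15,
                                             n_novel_loci = 10))
  pl <- gtf_loci(sim$predicted)$loci
  al <- gtf_loci(sim$annotated)$loci
  novel <- pl[pl$gene_id %in% sim$truth$novel_locus_ids, ]
  expect_equal(bf_overlapping_pairs(novel, al), 0)
  # reproduced loci all still overlap their annotation partner
  known <- pl[!pl$gene_id %in% sim$truth$novel_locus_ids, ]
  expect_gte(bf_overlapping_pairs(known, al), nrow(known))
})

test_that("overlap stage agrees with brute-force interval intersection", {
  set.seed(26)
  for (i in 1:20) {
    na <- sample(3:15, 1); np <- sample(3:15, 1)
    ann_df <- data.frame(gene_id = sprintf("A%02d", 1:na),
                         seqname = sample(c("c1", "c2"), na, replace = TRUE),
                         start = sample(1:50000, na))
    ann_df$end <- ann_df$start + sample(100:5000, na, replace = TRUE)
    pred_df <- data.frame(gene_id = sprintf("P%02d", 1:np),
                          seqname = sample(c("c1", "c2"), np, replace = TRUE),
                          start = sample(1:50000, np))
    pred_df$end <- pred_df$start + sample(100:5000, np, replace = TRUE)
    rep_ <- suppressMessages(
      flag_known_loci(toy_locus_set(pred_df), toy_locus_set(ann_df), NULL))
    for (j in seq_len(np)) {
      ov <- bf_overlapping_pairs(pred_df[j, ], ann_df) > 0
      expect_equal(pred_df$gene_id[j] %in% rep_$known_by_overlap, ov)
    }
  }
})

test_that("screen_novel_orfs delegates to the interior rule", {
  sim <- simulate_orf_contigs(sim_config(seed = 31), n_contigs = 60)
  novel <- sim$contigs$id
  screen <- screen_novel_orfs(novel, sim$contigs)
  cls <- sim$truth$classes
  for (id in novel) {
    expected <- switch(cls$reason[cls$id == id],
                       interior = "full_orf", no_orf = "none", "partial_orf")
    expect_equal(unname(screen[id]), expected, info = id)
  }
  expect_error(screen_novel_orfs("ghost", sim$contigs), "ghost")
})

test_that("merge_novel reproduces the printed new-transcript arithmetic", {
  # 11,843 genome-predicted novel loci + 4,146 unmatched contigs of which
  # 1,162 are redundant: 11,843 + 2,984 = 14,827 new transcripts
  novel <- sprintf("XL%05d", 1:11843)
  contigs <- sprintf("CT%05d", 1:4146)
  red <- data.frame(locus_id = sample(novel, 1162, replace = TRUE),
                    contig_id = contigs[1:1162])
  m <- merge_novel(novel, contigs, red)
  expect_equal(m$n_combined, 14827)
  expect_equal(m$n_contigs_kept, 2984)

  m0 <- merge_novel(c("a", "b"), c("x", "y"))
  expect_equal(m0$n_combined, 4)
  expect_error(
    merge_novel("a", "x", data.frame(locus_id = "a", contig_id = "zz")),
    "unknown contig")

  set.seed(28)
  for (i in 1:20) {
    nv <- sprintf("n%03d", sample(200, sample(5:50, 1)))
    ct <- sprintf("c%03d", sample(200, sample(5:50, 1)))
    np <- sample(0:min(20, length(ct)), 1)
    pr <- if (np > 0) data.frame(locus_id = sample(nv, np, replace = TRUE),
                                 contig_id = sample(ct, np)) else NULL
    got <- merge_novel(nv, ct, pr)
    removed <- if (is.null(pr)) character() else unique(pr$contig_id)
    expect_setequal(got$combined_ids, union(nv, setdiff(ct, removed)))
    expect_equal(got$n_combined,
                 length(nv) + length(ct) - length(removed))
  }
})

test_that("splice_stats counts transcripts and exons per locus", {
  feats <- data.frame(
    seqname = "c1", source = "t", feature = "exon",
    start = c(1, 100, 200, 300, 400, 500, 600),
    end = c(50, 150, 250, 350, 450, 550, 650),
    strand = "+", gene_id = c("g1", "g1", "g1", "g1", "g1", "g2", "g2"),
    transcript_id = c("t1", "t1", "t1", "t2", "t2", "t3", "t3"),
    stringsAsFactors = FALSE)
  s <- splice_stats(gtf_loci(feats))
  expect_equal(s$n_loci, 2L)
  expect_equal(s$n_transcripts, 3L)
  expect_equal(s$mean_transcripts_per_locus, 1.5)
  expect_equal(s$mean_exons_per_locus, 3.5)
  expect_equal(unname(s$loci_ge_k["2"]), 1L)

  mono <- feats[feats$transcript_id %in% c("t1", "t3"), ]
  s2 <- splice_stats(gtf_loci(mono))
  expect_equal(unname(s2$loci_ge_k["2"]), 0L)
  expect_equal(s2$mean_transcripts_per_locus, 1.00)

  expect_error(splice_stats(gtf_loci(troutatlas:::empty_gtf_df())),
               "at least one")
})

test_that("splice_stats matches brute-force counting on random fixtures", {
  for (s in c(3, 9)) {
    sim <- simulate_annotation_pair(sim_config(seed = s,
                                               n_annotated_loci = 30,
                                               n_novel_loci = 10))
    loci <- gtf_loci(sim$predicted)
    st <- splice_stats(loci)
    # brute force from the raw feature table
    feats <- sim$predicted
    ntx <- length(unique(feats$transcript_id))
    nloc <- length(unique(feats$gene_id))
    expect_equal(st$n_loci, nloc)
    expect_equal(st$n_transcripts, ntx)
    expect_equal(st$n_exons, sum(feats$feature == "exon"))
    tx_per <- table(feats$gene_id[!duplicated(feats$transcript_id)])
    for (k in c(2, 5, 10)) {
      expect_equal(unname(st$loci_ge_k[as.character(k)]),
                   sum(tx_per >= k))
    }
    expect_equal(unname(st$n_transcripts),
                 sum(sim$truth$n_transcripts))
    expect_true(all(diff(unname(st$loci_ge_k)) <= 0))
  }
})
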