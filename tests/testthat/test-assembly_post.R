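# assembly_post: length filter, N50, representative selection, hit summaries

test_that("filter_by_length keeps the inclusive 500 nt boundary", {
  ct <- contig_table(c("a", "b", "c"), c("c1", "c2", "c3"),
                     c(499L, 500L, 501L))
  expect_equal(filter_by_length(ct, 500)$id, c("b", "c"))
  expect_equal(filter_by_length(ct, 500, strict = TRUE)$id, "c")
  expect_equal(filter_by_length(ct, 1)$id, ct$id)

  set.seed(3)
  lens <- sample(100:2000, 1000, replace = TRUE)
  big <- contig_table(sprintf("x%04d", 1:1000), sprintf("c%04d", 1:1000), lens)
  for (ml in c(150, 500, 1999)) {
    expect_equal(filter_by_length(big, ml)$id, big$id[lens >= ml])
  }
})

test_that("assembly_stats matches the brute-force N50 definition", {
  s <- assembly_stats(c(5, 4, 3, 2, 1))
  expect_equal(s$n50, 4)
  expect_equal(s$n_bases, 15)
  s1 <- assembly_stats(10)
  expect_equal(s1$n50, 10)
  expect_equal(s1$mean_len, 10)
  expect_error(assembly_stats(numeric()), "at least one")

  set.seed(21)
  for (i in 1:200) {
    lens <- sample(200:5000, sample(1:60, 1), replace = TRUE)
    st <- assembly_stats(lens)
    expect_equal(st$n50, bf_n50(lens))
    expect_true(st$n50 %in% lens)
    expect_true(st$min_len <= st$mean_len && st$mean_len <= st$max_len)
  }
})

test_that("select_representatives follows the longest-hit-bearing rule", {
  ct <- contig_table(c("a", "b", "c"), c("k", "k", "k"),
                     c(700L, 900L, 1200L),
                     best_hit_subject = c("p1", "p1", ""),
                     best_hit_evalue = c(1e-20, 1e-30, NA))
  expect_equal(select_representatives(ct), "b")   # longest *with a hit*
  nohit <- contig_table(c("a", "b"), c("k", "k"), c(700L, 900L))
  expect_equal(select_representatives(nohit), character())

  # singleton components grouped by subject accession
  sg <- contig_table(c("s1", "s2", "s3", "s4"), paste0("c", 1:4),
                     c(800L, 1000L, 900L, 500L),
                     best_hit_subject = c("pA", "pA", "pB", ""),
                     best_hit_evalue = c(1e-20, 1e-20, 1e-20, NA))
  expect_equal(select_representatives(sg), c("s2", "s3"))
  expect_equal(select_representatives(sg, drop_lone_singletons = TRUE), "s2")

  # length ties break lexicographically by id
  tie <- contig_table(c("zz", "aa"), c("k", "k"), c(900L, 900L),
                      best_hit_subject = c("p1", "p1"),
                      best_hit_evalue = c(1e-20, 1e-20))
  expect_equal(select_representatives(tie), "aa")
})

test_that("select_representatives matches oracle and synthgen truth", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    ct <- contig_table(
      sprintf("ctg%03d", 1:n),
      sprintf("comp%02d", sample(1:12, n, replace = TRUE)),
      sample(500:3000, n, replace = TRUE),
      best_hit_subject = ifelse(runif(n) < 0.6,
                                sprintf("p%d", sample(1:5, n, replace = TRUE)),
                                ""),
      best_hit_evalue = 1e-20)
    expect_equal(select_representatives(ct), bf_select_reps(ct))
  }
  for (s in 1:5) {
    sim <- simulate_components(sim_config(seed = s))
    expect_setequal(select_representatives(sim$contigs),
                    sim$truth$representative_ids)
  }
})

test_that("representative invariants hold on random fixtures", {
  set.seed(9)
  sim <- simulate_components(sim_config(seed = 17, n_multi_components = 60))
  reps <- select_representatives(sim$contigs)
  ct <- sim$contigs
  sizes <- table(ct$component_id)
  multi_reps <- reps[sizes[ct$component_id[match(reps, ct$id)]] > 1]
  # at most one representative per multi-contig component
  expect_false(anyDuplicated(ct$component_id[match(multi_reps, ct$id)]) > 0)
  # representative at least as long as every hit-bearing sibling
  for (r in multi_reps) {
    comp <- ct$component_id[ct$id == r]
    sibs <- ct[ct$component_id == comp & ct$has_hit, ]
    expect_true(all(ct$length[ct$id == r] >= sibs$length))
  }
})

test_that("proteome_coverage counts distinct subjects and query overlaps", {
  h1 <- random_hits_df(4, c("q1", "q2"), c("p1", "p2"), seed = 1)
  h1$evalue <- 1e-20
  h1$subject_id <- c("p1", "p2", "p1", "p2")
  h1$query_id <- c("q1", "q1", "q2", "q2")
  cov <- proteome_coverage(list(zebrafish = h1), c(zebrafish = 4))
  expect_equal(cov$per_species$n_subjects_hit, 2L)
  expect_equal(cov$per_species$percent, 50)
  expect_equal(cov$n_queries_all_species, 2L)

  empty <- h1[0, ]
  cov0 <- proteome_coverage(list(sp = empty), c(sp = 10))
  expect_equal(cov0$per_species$n_subjects_hit, 0L)
  expect_equal(cov0$per_species$percent, 0)
  expect_equal(cov0$n_queries_any_species, 0L)

  expect_error(proteome_coverage(list(a = h1), c(b = 3)), "proteome size")

  # randomized equivalence against direct set algebra
  set.seed(31)
  for (i in 1:20) {
    sp <- c("d_rerio", "o_niloticus", "g_morhua")
    hits <- lapply(sp, function(s) {
      random_hits_df(sample(5:80, 1), sprintf("q%d", 1:40),
                     sprintf("%s_p%d", s, 1:25))
    })
    names(hits) <- sp
    sizes <- stats::setNames(sample(25:60, 3), sp)
    got <- proteome_coverage(hits, sizes, e_cutoff = 1e-10)
    qs <- lapply(hits, function(h) unique(h$query_id[h$evalue <= 1e-10]))
    for (s in sp) {
      expect_equal(
        got$per_species$n_subjects_hit[got$per_species$species == s],
        length(unique(hits[[s]]$subject_id[hits[[s]]$evalue <= 1e-10])))
    }
    expect_equal(got$n_queries_all_species,
                 length(intersect(intersect(qs[[1]], qs[[2]]), qs[[3]])))
    expect_equal(got$n_queries_any_species,
                 length(union(union(qs[[1]], qs[[2]]), qs[[3]])))
  }
})

test_that("reciprocal_unmatched computes filtered set differences", {
  hits_ab <- random_hits_df(1, "x", "m1", seed = 2)
  hits_ab$evalue <- 1e-20
  r <- reciprocal_unmatched(hits_ab, c("x", "y", "z"), hits_ab[0, ],
                            c("m1", "m2"))
  expect_setequal(r$unmatched_a, c("y", "z"))
  expect_setequal(r$unmatched_b, c("m1", "m2"))

  set.seed(13)
  for (i in 1:20) {
    ids_a <- sprintf("a%02d", 1:30)
    ids_b <- sprintf("b%02d", 1:25)
    hab <- random_hits_df(sample(0:60, 1), ids_a, ids_b)
    hba <- random_hits_df(sample(0:60, 1), ids_b, ids_a)
    got <- reciprocal_unmatched(hab, ids_a, hba, ids_b, e_cutoff = 1e-5)
    expect_setequal(got$unmatched_a,
                    setdiff(ids_a, hab$query_id[hab$evalue <= 1e-5]))
    expect_setequal(got$unmatched_b,
                    setdiff(ids_b, hba$query_id[hba$evalue <= 1e-5]))
    # no unmatched id carries a qualifying hit
    expect_length(
      intersect(got$unmatched_a, hab$query_id[hab$evalue <= 1e-5]), 0)
  }
})

test_that("coverage_tiers counts nested inclusive thresholds", {
  aln <- data.frame(query_id = c("a", "b", "c", "d"),
                    coverage = c(1.0, 0.95, 0.6, 0.3))
  expect_equal(unname(coverage_tiers(aln)), c(1L, 2L, 3L))
  all1 <- data.frame(query_id = letters[1:5], coverage = 1.0)
  expect_equal(unname(coverage_tiers(all1)), c(5L, 5L, 5L))
  expect_error(
    coverage_tiers(data.frame(query_id = "a", coverage = 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in 1:10) {
    n <- sample(50:1000, 1)
    aln <- data.frame(query_id = sprintf("q%04d", 1:n),
                      coverage = runif(n))
    got <- coverage_tiers(aln)
    expect_equal(unname(got),
                 as.integer(bf_tier_counts(aln$coverage, c(1.0, 0.9, 0.5))))
    expect_true(all(diff(unname(got)) >= 0))  # nested
  }
})
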