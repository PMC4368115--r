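# Post-assembly computations: length filtering, N50-style statistics,
# representative-transcript selection from components, hit-table summaries
# and alignment coverage tiers.

#' Build a contig table
#'
#' @param id contig ids.
#' @param component_id component (contig-group) id per contig.
#' @param length contig length in nt.
#' @param best_hit_subject subject accession of the best database hit, or ""
#'   when the contig has no hit.
#' @param best_hit_evalue E-value of the best hit (NA when no hit).
#' @return data.frame with columns `id, component_id, length, has_hit,
#'   best_hit_subject, best_hit_evalue`.
#' @export
contig_table <- function(id, component_id, length,
                         best_hit_subject = "", best_hit_evalue = NA_real_) {
  stopifnot(all(length >= 1))
  best_hit_subject <- rep_len(as.character(best_hit_subject), length(id))
  best_hit_evalue <- rep_len(as.numeric(best_hit_evalue), length(id))
  data.frame(id = as.character(id), component_id = as.character(component_id),
             length = as.integer(length),
             has_hit = nzchar(best_hit_subject),
             best_hit_subject = best_hit_subject,
             best_hit_evalue = best_hit_evalue,
             stringsAsFactors = FALSE)
}

#' Annotate contigs with their best BLAST hit
#'
#' Picks, per query, the hit with the lowest E-value (ties by highest
#' bitscore, then lexicographic subject id) among hits passing the cutoff.
#'
#' @param contigs contig table ([contig_table()]), hit columns overwritten.
#' @param hits data.frame from [read_blast_tab()].
#' @param e_cutoff retain hits with `evalue <= e_cutoff` (default 1e-10).
#' @return the contig table with `has_hit`, `best_hit_subject`,
#'   `best_hit_evalue` filled in.
#' @export
attach_best_hits <- function(contigs, hits, e_cutoff = 1e-10) {
  hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  contigs$best_hit_subject <- ""
  contigs$best_hit_evalue <- NA_real_
  if (nrow(hits)) {
    ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(hits$query_id), , drop = FALSE]
    m <- match(contigs$id, best$query_id)
    hit <- !is.na(m)
    contigs$best_hit_subject[hit] <- best$subject_id[m[hit]]
    contigs$best_hit_evalue[hit] <- best$evalue[m[hit]]
  }
  contigs$has_hit <- nzchar(contigs$best_hit_subject)
  contigs
}

#' Filter contigs by minimum length
#'
#' The 500 nt cutoff is inclusive by default (the assembly's "long contig"
#' set has a smallest member of exactly 500 nt); `strict = TRUE` switches to
#' a strictly-greater-than comparison.
#'
#' @param contigs contig table with a `length` column.
#' @param min_len minimum length in nt (default 500).
#' @param strict require `length > min_len` instead of `>=`.
#' @return the retained rows, input order preserved.
#' @export
filter_by_length <- function(contigs, min_len = 500L, strict = FALSE) {
  stopifnot(min_len >= 1)
  keep <- if (strict) contigs$length > min_len else contigs$length >= min_len
  contigs[keep, , drop = FALSE]
}

#' Assembly length statistics
#'
#' N50 is the largest length L such that contigs of length >= L together
#' contain at least half of all assembled bases; it is always the length of
#' some contig in the set.
#'
#' @param lengths non-empty vector of contig lengths (nt).
#' @return object of class `assembly_stats`: list with `n_bases, n_contigs,
#'   n50, max_len, min_len, mean_len`.
#' @export
assembly_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("assembly_stats needs at least one contig")
  if (any(lengths < 1)) stop("contig lengths must be >= 1")
  s <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(s)
  n50 <- s[which(csum >= sum(s) / 2)[1]]
  structure(list(n_bases = sum(s), n_contigs = length(s), n50 = n50,
                 max_len = s[1], min_len = s[length(s)],
                 mean_len = sum(s) / length(s)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("assembly_stats: %d contigs, %.0f bases, N50 %d nt, ",
                     "range [%d, %d] nt, mean %.1f nt\n"),
              x$n_contigs, x$n_bases, x$n50, x$min_len, x$max_len, x$mean_len))
  invisible(x)
}

#' Select representative contigs per component
#'
#' Implements the atlas reference-set rule: within each multi-contig
#' component, the longest contig among those with a database hit is the
#' representative (components whose members all lack hits contribute none).
#' Single-contig components with hits are grouped by best-hit subject
#' accession — the computable proxy for "the same gene annotation" — and the
#' longest contig per subject group is retained. Length ties break
#' lexicographically by contig id.
#'
#' @param contigs contig table with populated hit columns (see
#'   [attach_best_hits()]).
#' @param consider_all_members also consider hit-less members of multi-contig
#'   components when picking the longest (off by default: the rule selects
#'   among contigs that matched a protein).
#' @param drop_lone_singletons drop single-contig components whose subject
#'   group contains only themselves (default FALSE: retained).
#' @return character vector of representative contig ids, sorted.
#' @export
select_representatives <- function(contigs, consider_all_members = FALSE,
                                   drop_lone_singletons = FALSE) {
  stopifnot(all(c("id", "component_id", "length", "has_hit",
                  "best_hit_subject") %in% names(contigs)))
  if (nrow(contigs) == 0L) return(character())
  comp_sizes <- table(contigs$component_id)
  multi <- contigs[comp_sizes[contigs$component_id] > 1L, , drop = FALSE]
  single <- contigs[comp_sizes[contigs$component_id] == 1L, , drop = FALSE]

  pick_longest <- function(df) {
    df <- df[order(-df$length, df$id), , drop = FALSE]
    df$id[1]
  }

  reps <- character()
  if (nrow(multi)) {
    pool <- if (consider_all_members) {
      # still requires >= 1 hit in the component for it to contribute
      hit_comp <- unique(multi$component_id[multi$has_hit])
      multi[multi$component_id %in% hit_comp, , drop = FALSE]
    } else {
      multi[multi$has_hit, , drop = FALSE]
    }
    if (nrow(pool)) {
      reps <- vapply(split(pool, pool$component_id), pick_longest,
                     character(1))
    }
  }
  srep <- character()
  shit <- single[single$has_hit, , drop = FALSE]
  if (nrow(shit)) {
    grp <- split(shit, shit$best_hit_subject)
    if (drop_lone_singletons) grp <- grp[vapply(grp, nrow, 1L) > 1L]
    if (length(grp)) srep <- vapply(grp, pick_longest, character(1))
  }
  sort(unique(c(unname(reps), unname(srep))))
}

#' Per-species proteome coverage of a transcript set
#'
#' For each species, counts the distinct proteome subjects hit at the E-value
#' cutoff and reports them as a fraction of the species' proteome size; also
#' counts queries hitting every species and queries hitting at least one.
#'
#' @param hits_by_species named list, species -> hit data.frame
#'   ([read_blast_tab()] columns).
#' @param proteome_sizes named vector, species -> number of proteins.
#' @param e_cutoff E-value cutoff (default 1e-10).
#' @param decimals decimals for the percentage report.
#' @return list with `per_species` (data.frame `species, n_subjects_hit,
#'   proteome_size, percent`), `n_queries_all_species`,
#'   `n_queries_any_species`.
#' @export
proteome_coverage <- function(hits_by_species, proteome_sizes,
                              e_cutoff = 1e-10, decimals = 2) {
  sp <- names(hits_by_species)
  missing_sz <- setdiff(sp, names(proteome_sizes))
  if (length(missing_sz)) {
    stop("no proteome size for species: ", paste(missing_sz, collapse = ", "))
  }
  if (any(proteome_sizes[sp] <= 0)) stop("proteome sizes must be positive")
  filt <- lapply(hits_by_species, function(h) {
    h[h$evalue <= e_cutoff, , drop = FALSE]
  })
  per <- do.call(rbind, lapply(sp, function(s) {
    n <- length(unique(filt[[s]]$subject_id))
    data.frame(species = s, n_subjects_hit = n,
               proteome_size = as.numeric(proteome_sizes[[s]]),
               percent = format_fraction(n, proteome_sizes[[s]],
                                         decimals)$percent,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(species = character(), n_subjects_hit = integer(),
                      proteome_size = numeric(), percent = numeric(),
                      stringsAsFactors = FALSE)
  }
  qsets <- lapply(filt, function(h) unique(h$query_id))
  n_all <- if (length(qsets)) length(Reduce(intersect, qsets)) else 0L
  n_any <- length(unique(unlist(qsets)))
  list(per_species = per, n_queries_all_species = n_all,
       n_queries_any_species = n_any)
}

#' Reciprocal unmatched sets between two sequence collections
#'
#' Given hit tables in both directions (a vs b and b vs a), reports the ids
#' on each side with no qualifying hit — e.g. de novo contigs that match no
#' annotated mRNA and annotated mRNAs that match no contig.
#'
#' @param hits_ab hits of a-queries against b.
#' @param ids_a all ids on side a.
#' @param hits_ba hits of b-queries against a.
#' @param ids_b all ids on side b.
#' @param e_cutoff E-value cutoff (default 1e-10).
#' @param decimals decimals for the fraction reports.
#' @return list with `unmatched_a`, `unmatched_b` (sorted id vectors) and
#'   `fraction_a`, `fraction_b` ([format_fraction()] reports).
#' @export
reciprocal_unmatched <- function(hits_ab, ids_a, hits_ba, ids_b,
                                 e_cutoff = 1e-10, decimals = 1) {
  matched_a <- unique(hits_ab$query_id[hits_ab$evalue <= e_cutoff])
  matched_b <- unique(hits_ba$query_id[hits_ba$evalue <= e_cutoff])
  extra <- setdiff(matched_a, ids_a)
  if (length(extra)) stop("hits_ab queries not in ids_a: ", extra[1])
  extra <- setdiff(matched_b, ids_b)
  if (length(extra)) stop("hits_ba queries not in ids_b: ", extra[1])
  ua <- sort(setdiff(ids_a, matched_a))
  ub <- sort(setdiff(ids_b, matched_b))
  list(unmatched_a = ua, unmatched_b = ub,
       fraction_a = format_fraction(length(ua), max(length(ids_a), 1), decimals),
       fraction_b = format_fraction(length(ub), max(length(ids_b), 1), decimals))
}

#' Coverage-tier configuration
#' @param tiers strictly descending coverage fractions in (0, 1]
#'   (default 1.0, 0.9, 0.5).
#' @param min_contig_len minimum contig length context (default 500 nt).
#' @param hit_evalue_cutoff default hit cutoff carried for provenance.
#' @return object of class `coverage_tier_config`.
#' @export
coverage_tier_config <- function(tiers = c(1.0, 0.9, 0.5),
                                 min_contig_len = 500L,
                                 hit_evalue_cutoff = 1e-10) {
  if (any(tiers <= 0) || any(tiers > 1)) stop("tiers must lie in (0, 1]")
  if (any(diff(tiers) >= 0)) stop("tiers must be strictly descending")
  structure(list(tiers = tiers, min_contig_len = min_contig_len,
                 hit_evalue_cutoff = hit_evalue_cutoff),
            class = "coverage_tier_config")
}

#' Count queries by alignment coverage tier
#'
#' A query counts in tier t when its best-alignment coverage of the reference
#' coding sequence is at least t; the tiers are therefore nested.
#'
#' @param alignments data.frame with columns `query_id` and `coverage`
#'   (fraction of the reference covered, in \[0, 1\]; one best alignment per
#'   query).
#' @param cfg a [coverage_tier_config()].
#' @return named integer vector, one count of unique queries per tier.
#' @export
coverage_tiers <- function(alignments, cfg = coverage_tier_config()) {
  stopifnot(all(c("query_id", "coverage") %in% names(alignments)))
  if (any(alignments$coverage < 0 | alignments$coverage > 1)) {
    stop("coverage must lie in [0, 1]")
  }
  if (anyDuplicated(alignments$query_id)) {
    best <- tapply(alignments$coverage, alignments$query_id, max)
    cov <- as.numeric(best)
  } else {
    cov <- alignments$coverage
  }
  stats::setNames(
    vapply(cfg$tiers, function(t) sum(cov >= t), integer(1)),
    formatC(cfg$tiers, format = "g"))
}
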