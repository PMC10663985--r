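# HSP chaining: the selection procedure applied to each iteration's candidate
# HSP pool before the surviving query consensus is carried forward. Stages,
# applied per query chromosome:
#   1. order by ascending query position, descending score
#   2. sequential insertion, rejecting a lower-scored HSP that overlaps an
#      accepted one by more than `overlap_reject_frac` of the shorter interval
#   3. merging of similar-scored overlapping HSPs on the same subject
#      chromosome and strand
#   4. conflict resolution: chromosome-homology-guided orthologue choice,
#      then greedy removal of synteny-breaking (crossing) pairs
#   5. trimming of residual small overlaps and the minimum-length filter
#
# Chromosome resolution runs before the synteny rule: a homoeologous
# mis-assignment (e.g. wheat 1A vs 1B) would otherwise masquerade as a
# translocation and be resolved by score alone.

#' Chaining parameters
#'
#' @param overlap_reject_frac overlap fraction (of the shorter query interval)
#'   above which the lower-scored HSP is rejected. Default 0.5.
#' @param merge_min_overlap minimum query overlap (bases) for merging. Default 1.
#' @param similar_score_tol maximum relative score difference for two HSPs to
#'   count as similar-scored (merging, homoeologue choice). Default 0.1.
#' @param min_hsp_len minimum query span kept by the length filter; the
#'   threshold is inclusive (an HSP of exactly this span survives). Default 500.
#' @param use_chromosome_info use `homology_map` to resolve homoeologous
#'   alternatives before the synteny rule.
#' @param homology_map named character vector mapping chromosome id to
#'   homology group (required when `use_chromosome_info` is TRUE).
#' @return a list of class `chain_params`.
#' @export
chain_params <- function(overlap_reject_frac = 0.5, merge_min_overlap = 1L,
                         similar_score_tol = 0.1, min_hsp_len = 500L,
                         use_chromosome_info = FALSE, homology_map = NULL) {
  if (!(overlap_reject_frac > 0 && overlap_reject_frac <= 1)) {
    stop_corealign("overlap_reject_frac must be in (0, 1]", "corealign_config_error")
  }
  if (min_hsp_len < 0L) {
    stop_corealign("min_hsp_len must be >= 0", "corealign_config_error")
  }
  if (use_chromosome_info &&
      (is.null(homology_map) || is.null(names(homology_map)))) {
    stop_corealign("use_chromosome_info requires a named homology_map",
                   "corealign_config_error")
  }
  structure(list(overlap_reject_frac = overlap_reject_frac,
                 merge_min_overlap = as.integer(merge_min_overlap),
                 similar_score_tol = similar_score_tol,
                 min_hsp_len = as.integer(min_hsp_len),
                 use_chromosome_info = use_chromosome_info,
                 homology_map = homology_map),
            class = "chain_params")
}

qlen_of <- function(h, i) h$q_end[i] - h$q_start[i]

qoverlap_of <- function(h, i, j) {
  max(0L, min(h$q_end[i], h$q_end[j]) - max(h$q_start[i], h$q_start[j]))
}

similar_score <- function(a, b, tol) {
  abs(a - b) <= tol * max(abs(a), abs(b))
}

#' Order HSPs by ascending query position and descending score
#'
#' Stable sort by (q_start ascending, score descending, q_end ascending,
#' s_chrom, s_start); the last three keys are deterministic tie-breaks.
#' All HSPs must lie on one query chromosome.
#'
#' @param hsps an [hsp_table()].
#' @return the reordered table.
#' @export
order_hsps <- function(hsps) {
  if (nrow(hsps) == 0L) return(hsps)
  if (length(unique(hsps$q_chrom)) > 1L) {
    stop_corealign("order_hsps expects HSPs on a single query chromosome",
                   "corealign_hsp_error")
  }
  o <- order(hsps$q_start, -hsps$score, hsps$q_end, hsps$s_chrom, hsps$s_start)
  out <- hsps[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequential overlap-based HSP selection
#'
#' HSPs are inserted in order into an accepted list. An incoming HSP whose
#' query overlap with any accepted HSP exceeds `overlap_reject_frac` of the
#' shorter of the two intervals is kept only if its score is strictly higher
#' than every such conflicting HSP, in which case the displaced HSPs are
#' removed. Overlaps at or below the threshold leave both HSPs in place
#' (resolved later by merging or trimming).
#'
#' @param ordered an [hsp_table()] already ordered by [order_hsps()].
#' @param params a [chain_params()].
#' @return the accepted subset, in query order.
#' @export
select_hsps <- function(ordered, params = chain_params()) {
  n <- nrow(ordered)
  if (n == 0L) return(ordered)
  accepted <- integer(0)
  for (i in seq_len(n)) {
    conflict <- integer(0)
    for (a in accepted) {
      ov <- qoverlap_of(ordered, i, a)
      shorter <- min(qlen_of(ordered, i), qlen_of(ordered, a))
      if (ov > params$overlap_reject_frac * shorter) {
        conflict <- c(conflict, a)
      }
    }
    if (length(conflict) == 0L) {
      accepted <- c(accepted, i)
    } else if (ordered$score[i] > max(ordered$score[conflict])) {
      accepted <- c(setdiff(accepted, conflict), i)
    }
  }
  out <- ordered[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# subject order consistency of a query-ordered pair (i before j on the query):
# '+' strand pairs must ascend on the subject, '-' pairs descend
subject_order_ok <- function(h, i, j) {
  if (h$strand[i] == "+") h$s_start[i] <= h$s_start[j]
  else h$s_start[j] <= h$s_start[i]
}

# splice two HSPs (i query-before j, same s_chrom/strand, order-consistent)
# into one spanning HSP; j is trimmed at i's query/subject boundary and the
# cigars are joined with explicit indel runs for any jump
splice_hsps <- function(h, i, j) {
  qi_end <- h$q_end[i]
  cg_j <- h$cigar[j]
  q_trim <- max(0L, qi_end - h$q_start[j])
  have_cg <- !is.na(h$cigar[i]) && !is.na(cg_j)
  minus <- h$strand[i] == "-"
  out <- h[i, , drop = FALSE]
  out$q_end <- max(h$q_end[i], h$q_end[j])
  out$s_start <- min(h$s_start[i], h$s_start[j])
  out$s_end <- max(h$s_end[i], h$s_end[j])
  out$score <- h$score[i] + h$score[j]
  if (have_cg) {
    cut1 <- cigar_cut(cg_j, q_take = q_trim)
    # subject position of j's remainder, in the splice frame: forward coords
    # for '+', reverse-complement walk (from s_end downward) for '-'
    if (!minus) {
      s_rest_start <- h$s_start[j] + cut1$s_used
      ds <- s_rest_start - h$s_end[i]
    } else {
      s_rest_end <- h$s_end[j] - cut1$s_used
      ds <- h$s_start[i] - s_rest_end
    }
    extra_q <- 0L
    rest <- cut1$tail
    if (ds < 0L) {
      # subject overlap: consume j further on the subject side; the query
      # bases consumed become an insertion run
      cut2 <- cigar_cut(rest, s_take = -ds)
      extra_q <- cut2$q_used
      rest <- cut2$tail
      ds <- ds + cut2$s_used
    }
    mid <- paste0(if (extra_q > 0L) paste0(extra_q, "I") else "",
                  if (ds > 0L) paste0(ds, "D") else "")
    cg <- paste0(h$cigar[i], mid, rest)
    # normalise adjacent equal ops
    p <- parse_cigar(cg)
    out$cigar <- build_cigar(p$len, p$op)
    wi <- length(cigar_ops(h$cigar[i]))
    wj <- length(cigar_ops(cg_j))
    w <- length(cigar_ops(out$cigar))
    ii <- h$identity[i] * wi
    ij <- h$identity[j] * wj
    out$identity <- if (w > 0) min(1, (ii + ij) / w) else NA_real_
  } else {
    out$cigar <- NA_character_
    out$identity <- NA_real_
  }
  out
}

#' Merge overlapping similar-scored HSPs
#'
#' Two HSPs are merged when their query intervals overlap by more than
#' `merge_min_overlap` bases, their scores are within `similar_score_tol`
#' (relative), they lie on the same subject chromosome and strand, and their
#' subject intervals are order-consistent. The merged HSP spans the union of
#' the intervals; merging repeats to a fixpoint. Pairs are always processed
#' in query order, so the result is deterministic.
#'
#' @param selected output of [select_hsps()].
#' @param params a [chain_params()].
#' @return the merged table, in query order.
#' @export
merge_hsps <- function(selected, params = chain_params()) {
  h <- selected
  repeat {
    if (nrow(h) < 2L) break
    o <- order(h$q_start, h$q_end, h$s_chrom, h$s_start)
    h <- h[o, , drop = FALSE]
    rownames(h) <- NULL
    merged <- FALSE
    for (i in seq_len(nrow(h) - 1L)) {
      for (j in (i + 1L):nrow(h)) {
        if (h$q_start[j] >= h$q_end[i]) break
        ov <- qoverlap_of(h, i, j)
        if (ov <= params$merge_min_overlap) next
        if (h$s_chrom[i] != h$s_chrom[j] || h$strand[i] != h$strand[j]) next
        if (!similar_score(h$score[i], h$score[j], params$similar_score_tol)) next
        if (!subject_order_ok(h, i, j)) next
        new <- splice_hsps(h, i, j)
        h <- rbind(h[-c(i, j), , drop = FALSE], new)
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  o <- order(h$q_start, h$q_end, h$s_chrom, h$s_start)
  h <- h[o, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Resolve homoeologue and translocation conflicts
#'
#' When `use_chromosome_info` is set, similar-scored HSPs covering overlapping
#' query intervals but hitting different subject chromosomes are first
#' resolved by homology group: the HSP whose subject chromosome's group
#' matches the query chromosome's group is retained and its alternatives are
#' dropped. Then, among pairs whose subject order is inconsistent with their
#' query order (crossing pairs, i.e. implied translocations), the lower-scored
#' member is removed iteratively, highest-scoring conflict first, until the
#' set is order-consistent. Inverted ('-' strand) HSPs are order-checked on
#' the reversed subject axis, so inversions are retained.
#'
#' @param merged output of [merge_hsps()].
#' @param params a [chain_params()].
#' @return the conflict-free table, in query order.
#' @export
resolve_conflicts <- function(merged, params = chain_params()) {
  h <- merged
  if (nrow(h) == 0L) return(h)
  if (params$use_chromosome_info) {
    if (is.null(params$homology_map)) {
      stop_corealign("use_chromosome_info requires homology_map",
                     "corealign_config_error")
    }
    hm <- params$homology_map
    repeat {
      drop <- integer(0)
      n <- nrow(h)
      for (i in seq_len(max(0L, n - 1L))) {
        for (j in (i + 1L):n) {
          if (n < 2L) break
          if (h$s_chrom[i] == h$s_chrom[j]) next
          if (qoverlap_of(h, i, j) < 1L) next
          if (!similar_score(h$score[i], h$score[j], params$similar_score_tol)) next
          gq <- unname(hm[h$q_chrom[i]])
          gi <- unname(hm[h$s_chrom[i]])
          gj <- unname(hm[h$s_chrom[j]])
          if (is.na(gq)) next
          mi <- !is.na(gi) && gi == gq
          mj <- !is.na(gj) && gj == gq
          if (mi && !mj) drop <- c(drop, j)
          if (mj && !mi) drop <- c(drop, i)
        }
      }
      if (length(drop) == 0L) break
      h <- h[-unique(drop), , drop = FALSE]
      rownames(h) <- NULL
    }
  }
  # synteny: greedy removal of crossing pairs, highest-scoring conflict first
  repeat {
    n <- nrow(h)
    if (n < 2L) break
    o <- order(h$q_start, h$q_end, h$s_chrom, h$s_start)
    h <- h[o, , drop = FALSE]
    rownames(h) <- NULL
    cross <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (h$s_chrom[i] != h$s_chrom[j] || h$strand[i] != h$strand[j]) next
        if (!subject_order_ok(h, i, j)) {
          cross <- rbind(cross, data.frame(i = i, j = j,
                                           hi = max(h$score[i], h$score[j]),
                                           lo = min(h$score[i], h$score[j])))
        }
      }
    }
    if (is.null(cross)) break
    cross <- cross[order(-cross$hi, -cross$lo, cross$i, cross$j), , drop = FALSE]
    pick <- cross[1, ]
    victim <- if (h$score[pick$i] < h$score[pick$j]) pick$i
              else if (h$score[pick$j] < h$score[pick$i]) pick$j
              else pick$j  # tie: drop the later HSP
    h <- h[-victim, , drop = FALSE]
    rownames(h) <- NULL
  }
  h
}

# trim a cigar-bearing HSP by `n` query bases from the front or back,
# updating intervals; returns NULL if nothing remains
trim_hsp <- function(h, i, n, side = c("front", "back")) {
  side <- match.arg(side)
  row <- h[i, , drop = FALSE]
  span <- row$q_end - row$q_start
  if (n >= span) return(NULL)
  if (is.na(row$cigar)) {
    if (side == "front") row$q_start <- row$q_start + n
    else row$q_end <- row$q_end - n
    return(row)
  }
  if (side == "front") {
    cut <- cigar_cut(row$cigar, q_take = n)
    # drop any leading subject-only run left at the new front
    p <- parse_cigar(cut$tail)
    extra_s <- 0L
    while (nrow(p) > 0L && p$op[1] == "D") {
      extra_s <- extra_s + p$len[1]
      p <- p[-1, , drop = FALSE]
    }
    row$cigar <- build_cigar(p$len, p$op)
    row$q_start <- row$q_start + cut$q_used
    if (row$strand == "+") row$s_start <- row$s_start + cut$s_used + extra_s
    else row$s_end <- row$s_end - cut$s_used - extra_s
  } else {
    keep <- span - n
    cut <- cigar_cut(row$cigar, q_take = keep)
    p <- parse_cigar(cut$head)
    extra_s <- 0L
    while (nrow(p) > 0L && p$op[nrow(p)] == "D") {
      extra_s <- extra_s + p$len[nrow(p)]
      p <- p[-nrow(p), , drop = FALSE]
    }
    row$cigar <- build_cigar(p$len, p$op)
    row$q_end <- row$q_start + cut$q_used
    s_used <- cut$s_used - extra_s
    if (row$strand == "+") row$s_end <- row$s_start + s_used
    else row$s_start <- row$s_end - s_used
  }
  if (row$q_end <= row$q_start || row$s_end <= row$s_start) return(NULL)
  row
}

#' Trim residual query overlaps between accepted HSPs
#'
#' After merging and conflict resolution, dissimilar-scored HSPs may still
#' overlap by up to the rejection threshold. The lower-scored member of each
#' remaining overlapping pair is trimmed at the boundary (ties trim the later
#' HSP), so the output intervals are disjoint and can tile the consensus.
#'
#' @param hsps an [hsp_table()] in query order.
#' @param params a [chain_params()].
#' @return the trimmed table with pairwise-disjoint query intervals.
#' @export
trim_overlaps <- function(hsps, params = chain_params()) {
  h <- hsps
  if (nrow(h) < 2L) return(h)
  repeat {
    o <- order(h$q_start, h$q_end, h$s_chrom, h$s_start)
    h <- h[o, , drop = FALSE]
    rownames(h) <- NULL
    changed <- FALSE
    for (i in seq_len(nrow(h) - 1L)) {
      j <- i + 1L
      ov <- h$q_end[i] - h$q_start[j]
      if (ov <= 0L) next
      if (h$score[j] < h$score[i] ||
          (h$score[j] == h$score[i])) {
        row <- trim_hsp(h, j, ov, "front")
        h <- h[-j, , drop = FALSE]
      } else {
        row <- trim_hsp(h, i, ov, "back")
        h <- h[-i, , drop = FALSE]
      }
      if (!is.null(row)) h <- rbind(h, row)
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  o <- order(h$q_start, h$q_end, h$s_chrom, h$s_start)
  h <- h[o, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Minimum-length filter
#'
#' Keeps HSPs whose query span is at least `min_hsp_len` (inclusive): HSPs
#' shorter than the threshold are excluded to minimise the chance of
#' false-positive orthologues.
#'
#' @param hsps an [hsp_table()].
#' @param params a [chain_params()].
#' @return the filtered table.
#' @export
filter_min_length <- function(hsps, params = chain_params()) {
  out <- hsps[hsps$q_end - hsps$q_start >= params$min_hsp_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain an HSP pool into an accepted, non-overlapping set
#'
#' Partitions by query chromosome, then applies [order_hsps()],
#' [select_hsps()], [merge_hsps()], [resolve_conflicts()], [trim_overlaps()]
#' and [filter_min_length()]. Output is sorted by (q_chrom, q_start) with
#' pairwise-disjoint query intervals, each spanning at least `min_hsp_len`.
#'
#' @param hsps an [hsp_table()].
#' @param params a [chain_params()].
#' @return the accepted [hsp_table()].
#' @export
chain <- function(hsps, params = chain_params()) {
  if (nrow(hsps) == 0L) return(hsps)
  parts <- lapply(split(seq_len(nrow(hsps)), hsps$q_chrom), function(idx) {
    h <- hsps[idx, , drop = FALSE]
    h <- order_hsps(h)
    h <- select_hsps(h, params)
    h <- merge_hsps(h, params)
    h <- resolve_conflicts(h, params)
    h <- trim_overlaps(h, params)
    filter_min_length(h, params)
  })
  parts <- parts[order(names(parts))]
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("hsp_df", "data.frame")
  out
}
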