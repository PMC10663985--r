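# The progressive driver. The longest, least-ambiguous genome starts as the
# query; each iteration aligns the current query consensus to the next
# subject, chains the HSP pool, and carries forward only the consensus
# covered by accepted HSPs. No guide tree is used: the consensus can only
# shrink, so after the last subject it holds the candidate core of the whole
# set. Every iteration keeps its accepted pairwise alignment and a coordinate
# map back to the previous query so the final multi-genome alignment can be
# reconstructed by backtracking.

#' Choose the initial query genome
#'
#' Returns the genome with the greatest total length; ties are broken by the
#' smallest count of ambiguous (non-ATGC) bases, then by lexicographic
#' genome id.
#'
#' @param genomes list of [genome_record()] objects (>= 2).
#' @return the chosen genome id.
#' @export
pick_initial_query <- function(genomes) {
  if (length(genomes) < 2L) {
    stop_corealign("need at least two genomes", "corealign_config_error")
  }
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  len <- vapply(genomes, `[[`, numeric(1), "total_length")
  amb <- vapply(genomes, `[[`, numeric(1), "ambiguous_count")
  o <- order(-len, amb, ids)
  unname(ids[o[1]])
}

#' Extract the surviving consensus and its coordinate map
#'
#' The consensus is the concatenation, in (q_chrom, q_start) order, of the
#' query substrings covered by accepted HSPs. Bases are the query's own bases
#' (no substitution): "consensus" here means the surviving query sequence.
#' Segments from one chromosome are concatenated into a single record that
#' keeps the chromosome's name; segment boundaries live only in the returned
#' map.
#'
#' @param query_seqs named character vector of the current query sequences.
#' @param accepted chained HSPs ([chain()] output) with disjoint query
#'   intervals.
#' @return list with `sequences` (named character vector) and `map`, a
#'   data.frame with columns `chrom`, `cons_start`, `cons_end`, `prev_start`,
#'   `prev_end` (all 0-based half-open); per chromosome the `cons` intervals
#'   tile the consensus from 0.
#' @export
build_consensus <- function(query_seqs, accepted) {
  if (nrow(accepted) > 0L &&
      (any(!accepted$q_chrom %in% names(query_seqs)))) {
    stop_corealign("accepted HSP on unknown query chromosome",
                   "corealign_internal_error")
  }
  chroms <- names(query_seqs)[names(query_seqs) %in% unique(accepted$q_chrom)]
  seqs <- character(0)
  maps <- list()
  for (ch in chroms) {
    h <- accepted[accepted$q_chrom == ch, , drop = FALSE]
    h <- h[order(h$q_start), , drop = FALSE]
    if (any(h$q_end > nchar(query_seqs[[ch]]))) {
      stop_corealign("accepted HSP out of query bounds", "corealign_internal_error")
    }
    if (nrow(h) > 1L && any(h$q_start[-1] < h$q_end[-nrow(h)])) {
      stop_corealign("accepted HSPs overlap on the query", "corealign_internal_error")
    }
    segs <- substring(query_seqs[[ch]], h$q_start + 1L, h$q_end)
    w <- h$q_end - h$q_start
    ends <- cumsum(w)
    maps[[ch]] <- data.frame(
      chrom = ch,
      cons_start = as.integer(ends - w), cons_end = as.integer(ends),
      prev_start = h$q_start, prev_end = h$q_end,
      stringsAsFactors = FALSE)
    seqs[[ch]] <- paste(segs, collapse = "")
  }
  map <- if (length(maps)) do.call(rbind, maps) else
    data.frame(chrom = character(0), cons_start = integer(0),
               cons_end = integer(0), prev_start = integer(0),
               prev_end = integer(0), stringsAsFactors = FALSE)
  rownames(map) <- NULL
  list(sequences = seqs, map = map)
}

#' Run the progressive core alignment over a genome set
#'
#' Iteration i aligns the current consensus against subject i, chains the
#' HSP pool ([chain()]), records the accepted pairwise alignment plus the
#' consensus coordinate map, and shrinks the consensus to the covered
#' segments. Consensus length is non-increasing across iterations. Subjects
#' are visited in input order after removing the initial query (or by
#' decreasing size with `order_by = "size"`).
#'
#' When `second_pass` is TRUE, consensus regions longer than `min_hsp_len`
#' that the primary mode left uncovered are re-aligned with the
#' high-divergence mode and the pooled HSP set is chained once.
#'
#' @param genomes list of [genome_record()] objects (>= 2).
#' @param params a [chain_params()].
#' @param mode a [sensitivity_mode()] for the primary pass.
#' @param backend `"internal"` or `"external"` (see [align_pair()]).
#' @param second_pass rescue uncovered regions with the high-divergence mode.
#' @param order_by `"input"` or `"size"` subject order.
#' @param verbose print per-iteration progress.
#' @return an object of class `progressive_run`: list with `iterations`
#'   (one record per subject: `iteration_index`, `subject_id`, `hsps`,
#'   `query_seqs`, `subject_seqs`, `consensus_map`), `initial_query`,
#'   `genome_order`, and `final_consensus`.
#' @export
run_progressive <- function(genomes, params = chain_params(),
                            mode = sensitivity_mode("low_divergence"),
                            backend = c("internal", "external"),
                            second_pass = TRUE,
                            order_by = c("input", "size"),
                            verbose = FALSE) {
  backend <- match.arg(backend)
  order_by <- match.arg(order_by)
  if (length(genomes) < 2L) {
    stop_corealign("need at least two genomes", "corealign_config_error")
  }
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) {
    stop_corealign("duplicate genome ids", "corealign_config_error")
  }
  names(genomes) <- ids
  q_id <- pick_initial_query(genomes)
  subjects <- setdiff(ids, q_id)
  if (order_by == "size") {
    sz <- vapply(genomes[subjects], `[[`, numeric(1), "total_length")
    subjects <- subjects[order(-sz, subjects)]
  }
  cons <- genomes[[q_id]]$sequences
  iterations <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s_id <- subjects[i]
    subj <- genomes[[s_id]]
    hsps <- align_pair(cons, subj, mode = mode, backend = backend)
    if (second_pass) {
      rescue <- uncovered_regions(cons, chain(hsps, params), params$min_hsp_len)
      if (nrow(rescue) > 0L) {
        hi <- sensitivity_mode("high_divergence")
        extra <- list()
        for (r in seq_len(nrow(rescue))) {
          sub_seq <- substring(cons[[rescue$chrom[r]]],
                               rescue$start[r] + 1L, rescue$end[r])
          eh <- align_pair(stats::setNames(sub_seq, rescue$chrom[r]),
                           subj, mode = hi, backend = backend)
          if (nrow(eh) > 0L) {
            eh$q_start <- eh$q_start + rescue$start[r]
            eh$q_end <- eh$q_end + rescue$start[r]
            extra[[length(extra) + 1L]] <- eh
          }
        }
        if (length(extra)) {
          hsps <- rbind(hsps, do.call(rbind, extra))
          class(hsps) <- c("hsp_df", "data.frame")
          hsps <- sort_hsps_canonical(hsps)
        }
      }
    }
    accepted <- chain(hsps, params)
    if (nrow(accepted) == 0L ||
        sum(accepted$q_end - accepted$q_start) < params$min_hsp_len) {
      stop_corealign(sprintf(
        "no core found: consensus lost at iteration %d (subject %s)", i, s_id),
        "corealign_no_core_error")
    }
    bc <- build_consensus(cons, accepted)
    iterations[[i]] <- structure(list(
      iteration_index = i,
      subject_id = s_id,
      hsps = accepted,
      query_seqs = cons,
      subject_seqs = subj$sequences,
      consensus_map = bc$map
    ), class = "iteration_alignment")
    if (verbose) {
      message(sprintf("iteration %d vs %s: %d HSPs accepted, consensus %s bp",
                      i, s_id, nrow(accepted),
                      format(sum(nchar(bc$sequences)), big.mark = ",")))
    }
    cons <- bc$sequences
  }
  structure(list(
    iterations = iterations,
    initial_query = q_id,
    genome_order = c(q_id, subjects),
    final_consensus = cons
  ), class = "progressive_run")
}

#' @export
print.progressive_run <- function(x, ...) {
  cat(sprintf("<progressive_run> query %s + %d subjects; final consensus %s bp in %d sequence(s)\n",
              x$initial_query, length(x$iterations),
              format(sum(nchar(x$final_consensus)), big.mark = ","),
              length(x$final_consensus)))
  invisible(x)
}

# consensus regions (>= min_len) not covered by accepted HSPs
uncovered_regions <- function(cons, accepted, min_len) {
  out <- list()
  for (ch in names(cons)) {
    L <- nchar(cons[[ch]])
    covered <- rep(FALSE, L)
    h <- accepted[accepted$q_chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      covered[(h$q_start[r] + 1L):h$q_end[r]] <- TRUE
    }
    runs <- logical_runs(!covered)
    runs <- runs[runs$end - runs$start >= max(min_len, 1L), , drop = FALSE]
    if (nrow(runs)) {
      out[[ch]] <- data.frame(chrom = ch, start = runs$start, end = runs$end,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
}
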