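# Candidate-HSP generation between a query sequence set and a subject genome.
# Two backends share one contract: the external adapter shells out to a
# long-read/assembly aligner that emits PAF with cg:Z cigars (minimap2 by
# default), and the internal seed-and-extend aligner (Rcpp) serves test-scale
# inputs. Both are exposed in two sensitivity modes so that more divergent
# homologous sequence can still seed alignments.

#' Sensitivity mode parameter bundle
#'
#' The two modes trade specificity for sensitivity: `low_divergence` uses
#' long seeds and a narrow chaining band (intra-species style), and
#' `high_divergence` short seeds and a wide band (cross-species style). For
#' the external backend the mode maps onto an aligner preset
#' (`asm5`/`asm20` for minimap2).
#'
#' @param label `"low_divergence"` or `"high_divergence"`.
#' @param seed_k exact-match seed length (>= 8).
#' @param band maximum diagonal drift between chained seeds, in bases.
#' @param min_anchor_score minimum alignment score for an HSP to be reported.
#' @param aligner_preset preset name passed to the external aligner.
#' @param max_gap maximum query/subject gap bridged inside one HSP; larger
#'   gaps split the alignment into separate HSPs.
#' @return a list of class `sensitivity_mode`.
#' @export
sensitivity_mode <- function(label = c("low_divergence", "high_divergence"),
                             seed_k = NULL, band = NULL,
                             min_anchor_score = 50, aligner_preset = NULL,
                             max_gap = 2000L) {
  label <- match.arg(label)
  defaults <- switch(label,
    low_divergence = list(seed_k = 15L, band = 100L, aligner_preset = "asm5"),
    high_divergence = list(seed_k = 11L, band = 400L, aligner_preset = "asm20"))
  seed_k <- as.integer(seed_k %||% defaults$seed_k)
  band <- as.integer(band %||% defaults$band)
  aligner_preset <- aligner_preset %||% defaults$aligner_preset
  if (seed_k < 8L) {
    stop_corealign("seed_k must be >= 8", "corealign_config_error")
  }
  if (band < 0L) {
    stop_corealign("band must be >= 0", "corealign_config_error")
  }
  structure(list(label = label, seed_k = seed_k, band = band,
                 min_anchor_score = min_anchor_score,
                 aligner_preset = aligner_preset,
                 max_gap = as.integer(max_gap)),
            class = "sensitivity_mode")
}

# scoring used by the internal backend; only relative ordering matters to the
# chaining stage
INTERNAL_SCORING <- list(match = 1, mismatch = -2, gap_open = -4,
                         gap_ext = -2, xdrop = 20)

#' Align two nucleotide sequences with the internal seed-and-extend backend
#'
#' Seeds exact k-mer matches, chains them, closes inter-seed gaps with
#' affine-gap dynamic programming, and extends the chain ends ungapped.
#' Both orientations of `seq_b` are searched. Scoring: match +1, mismatch -2,
#' gap open -4, gap extend -2 per base.
#'
#' @param seq_a,seq_b nucleotide strings (query and subject).
#' @param mode a [sensitivity_mode()].
#' @param length_cap refuse sequences longer than this (the internal backend
#'   is for test-scale data; use the external backend beyond it).
#' @return an [hsp_table()] with chromosome columns set to `"q"`/`"s"`.
#' @export
internal_align <- function(seq_a, seq_b, mode = sensitivity_mode(),
                           length_cap = 5e6) {
  stopifnot(inherits(mode, "sensitivity_mode"))
  if (nchar(seq_a) > length_cap || nchar(seq_b) > length_cap) {
    stop_corealign(paste0(
      "sequence exceeds the internal aligner cap (", format(length_cap),
      " bp); use the external backend"), "corealign_cap_error")
  }
  sc <- INTERNAL_SCORING
  run1 <- function(sb) {
    .internal_align_cpp(seq_a, sb, mode$seed_k, mode$band, mode$max_gap,
                        mode$min_anchor_score, sc$match, sc$mismatch,
                        sc$gap_open, sc$gap_ext, sc$xdrop)
  }
  fwd <- run1(seq_b)
  rev <- run1(revcomp(seq_b))
  n_b <- nchar(seq_b)
  res <- hsp_table(
    q_chrom = rep("q", nrow(fwd) + nrow(rev)),
    q_start = c(fwd$q_start, rev$q_start),
    q_end = c(fwd$q_end, rev$q_end),
    s_chrom = rep("s", nrow(fwd) + nrow(rev)),
    s_start = c(fwd$s_start, n_b - rev$s_end),
    s_end = c(fwd$s_end, n_b - rev$s_start),
    strand = c(rep("+", nrow(fwd)), rep("-", nrow(rev))),
    score = c(fwd$score, rev$score),
    cigar = c(fwd$cigar, rev$cigar),
    identity = c(fwd$identity, rev$identity)
  )
  res <- drop_contained_hsps(res)
  validate_hsps(res)
  sort_hsps_canonical(res)
}

# drop secondary HSPs almost fully contained (on both query and subject) in a
# higher-scoring HSP of the same strand: tandem-repeat seeds otherwise yield a
# ladder of shifted near-duplicates of the primary alignment
drop_contained_hsps <- function(hsps, frac = 0.9) {
  n <- nrow(hsps)
  if (n < 2L) return(hsps)
  o <- order(-hsps$score, hsps$q_start, hsps$s_start)
  keep <- logical(n)
  for (i in o) {
    contained <- FALSE
    for (j in which(keep)) {
      if (hsps$strand[i] != hsps$strand[j]) next
      qo <- max(0L, min(hsps$q_end[i], hsps$q_end[j]) -
                  max(hsps$q_start[i], hsps$q_start[j]))
      so <- max(0L, min(hsps$s_end[i], hsps$s_end[j]) -
                  max(hsps$s_start[i], hsps$s_start[j]))
      if (qo >= frac * (hsps$q_end[i] - hsps$q_start[i]) &&
          so >= frac * (hsps$s_end[i] - hsps$s_start[i])) {
        contained <- TRUE
        break
      }
    }
    if (!contained) keep[i] <- TRUE
  }
  out <- hsps[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical HSP order: thread-count and backend-order invariant
sort_hsps_canonical <- function(hsps) {
  o <- order(hsps$q_chrom, hsps$q_start, -hsps$score, hsps$s_chrom,
             hsps$s_start, hsps$q_end, hsps$strand)
  out <- hsps[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Produce candidate HSPs between a query sequence set and a subject genome
#'
#' @param query a [genome_record()] (or named character vector) holding the
#'   current query/consensus sequences.
#' @param subject a [genome_record()] for the subject genome.
#' @param mode a [sensitivity_mode()].
#' @param backend `"internal"` (seed-and-extend in this package) or
#'   `"external"` (shell out to `aligner_cmd`).
#' @param aligner_cmd command template for the external backend; `{preset}`,
#'   `{query}`, `{subject}` and `{out}` are substituted. The default runs
#'   minimap2 with the mode's preset and cigar output.
#' @param length_cap passed to [internal_align()] for the internal backend.
#' @return an [hsp_table()] in canonical order; every HSP carries a
#'   base-level cigar.
#' @export
align_pair <- function(query, subject, mode = sensitivity_mode(),
                       backend = c("internal", "external"),
                       aligner_cmd = paste("minimap2 -c -t 1 -x {preset}",
                                           "{subject} {query} -o {out}"),
                       length_cap = 5e6) {
  backend <- match.arg(backend)
  qseqs <- if (inherits(query, "genome_record")) query$sequences else query
  sseqs <- if (inherits(subject, "genome_record")) subject$sequences else subject
  if (length(qseqs) == 0L || length(sseqs) == 0L) {
    stop_corealign("query and subject must be nonempty", "corealign_config_error")
  }
  if (backend == "external") {
    return(align_pair_external(qseqs, sseqs, mode, aligner_cmd))
  }
  parts <- list()
  for (qc in names(qseqs)) {
    for (sc in names(sseqs)) {
      h <- internal_align(qseqs[[qc]], sseqs[[sc]], mode, length_cap)
      if (nrow(h) > 0L) {
        h$q_chrom <- qc
        h$s_chrom <- sc
        parts[[length(parts) + 1L]] <- h
      }
    }
  }
  res <- if (length(parts)) do.call(rbind, parts) else hsp_table()
  class(res) <- c("hsp_df", "data.frame")
  sort_hsps_canonical(res)
}

align_pair_external <- function(qseqs, sseqs, mode, aligner_cmd) {
  exe <- strsplit(aligner_cmd, "\\s+")[[1]][1]
  if (Sys.which(exe) == "") {
    stop_corealign(sprintf("external aligner '%s' not found on PATH", exe),
                   "corealign_external_error")
  }
  td <- tempfile("corealign_ext_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "query.fa")
  sf <- file.path(td, "subject.fa")
  of <- file.path(td, "out.paf")
  write_fasta(qseqs, qf)
  write_fasta(sseqs, sf)
  cmd <- aligner_cmd
  cmd <- gsub("{preset}", mode$aligner_preset, cmd, fixed = TRUE)
  cmd <- gsub("{query}", qf, cmd, fixed = TRUE)
  cmd <- gsub("{subject}", sf, cmd, fixed = TRUE)
  cmd <- gsub("{out}", of, cmd, fixed = TRUE)
  err <- file.path(td, "stderr.txt")
  status <- system(paste(cmd, "2>", shQuote(err)))
  if (status != 0L || !file.exists(of)) {
    msg <- if (file.exists(err)) paste(readLines(err), collapse = "\n") else ""
    stop_corealign(sprintf("external aligner failed (exit %d):\n%s", status, msg),
                   "corealign_external_error")
  }
  res <- read_paf(of)
  res <- res[!is.na(res$cigar), intersect(names(res), names(hsp_table())),
             drop = FALSE]
  # minimap2's cg for '-' hits is oriented for the reverse-complemented query
  # against the forward target; our convention is forward query against the
  # reverse-complemented subject, so the run order flips
  minus <- which(res$strand == "-")
  for (i in minus) {
    p <- parse_cigar(res$cigar[i])
    res$cigar[i] <- build_cigar(rev(p$len), rev(p$op))
  }
  class(res) <- c("hsp_df", "data.frame")
  validate_hsps(res)
  sort_hsps_canonical(res)
}
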