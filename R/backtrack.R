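# Reconstruction of the multi-genome core alignment. Each accepted HSP of the
# last iteration seeds a block whose reference row is the final consensus
# segment. Walking the iteration stack backwards, the block's interval is
# translated through each consensus coordinate map (splitting at map
# discontinuities) and the matching subject row of that level's pairwise
# alignment is threaded into the growing profile by gap projection. Because
# consensus bases are query bases verbatim, the reference text is the same
# string at every level, and the final reference row is the initial query
# genome's row.
#
# Gap projection uses gap-union semantics on the shared reference: for each
# inter-base slot of the ungapped reference, the merged profile holds
# max(profile gaps, pair gaps) gap columns; inserted bases are left-aligned
# within their slot. Ungapping any row is unchanged by projection.

# per-slot gap counts of a gapped reference (raw vector): slot i holds the
# gap columns immediately before reference base i; slot L+1 is trailing
slot_gaps <- function(refraw) {
  isb <- refraw != GAP_RAW
  L <- sum(isb)
  if (all(isb)) return(integer(L + 1L))
  b <- cumsum(isb)
  tabulate(b[!isb] + 1L, nbins = L + 1L)
}

# re-layout a row (aligned against reference layout refraw) into the layout
# whose slot gap counts are g_target (>= the source layout slot-wise)
regap_row <- function(rowraw, refraw, g_target) {
  isb <- refraw != GAP_RAW
  L <- sum(isb)
  cg <- cumsum(g_target)
  W <- L + cg[L + 1L]
  out <- rep(GAP_RAW, W)
  if (L > 0L) {
    out[seq_len(L) + cg[seq_len(L)]] <- rowraw[isb]
  }
  gcols <- which(!isb)
  if (length(gcols)) {
    b <- cumsum(isb)
    gs <- b[gcols] + 1L
    m <- stats::ave(seq_along(gs), gs, FUN = seq_along)
    cg0 <- c(0L, cg)
    out[(gs - 1L) + cg0[gs] + m] <- rowraw[gcols]
  }
  out
}

ungap_raw <- function(x) x[x != GAP_RAW]

#' Thread a new pairwise-aligned row into a gapped profile
#'
#' `profile` is a character vector of gapped rows whose first element is the
#' reference row; `pair` is a length-2 character vector holding the same
#' reference (possibly with different gaps) and a new row aligned to it.
#' Gap columns are merged by slot-wise union (maximum) on the shared
#' reference, existing rows are padded where the pair introduces new gap
#' columns and vice versa, and the new row is appended. Ungapping any row
#' before and after gives identical text.
#'
#' @param profile character vector of equal-length gapped rows, reference
#'   first.
#' @param pair character vector of two equal-length gapped rows: reference,
#'   then the new row.
#' @return character vector: the augmented profile (reference first, new row
#'   last).
#' @export
project_gaps <- function(profile, pair) {
  stopifnot(length(profile) >= 1L, length(pair) == 2L)
  prof_raw <- lapply(profile, charToRaw)
  refA <- prof_raw[[1]]
  refB <- charToRaw(pair[1])
  newB <- charToRaw(pair[2])
  if (length(unique(vapply(prof_raw, length, integer(1)))) != 1L ||
      length(refB) != length(newB)) {
    stop_corealign("profile/pair rows must have equal widths",
                   "corealign_backtrack_error")
  }
  if (!identical(ungap_raw(refA), ungap_raw(refB))) {
    stop_corealign("profile and pair reference rows disagree after ungapping",
                   "corealign_backtrack_error")
  }
  gA <- slot_gaps(refA)
  gB <- slot_gaps(refB)
  g <- pmax(gA, gB)
  out <- c(lapply(prof_raw, regap_row, refraw = refA, g_target = g),
           list(regap_row(newB, refB, g_target = g)))
  vapply(out, rawToChar, character(1))
}

# ---- internal block ("piece") machinery ------------------------------------
# piece: list(chrom, lo, hi   — current-level consensus interval,
#             ref  — raw gapped reference row,
#             rows — list of subject rows: genome_id, chrom, start, end,
#                    strand, text (raw))

row_nongap_counts <- function(text, col_lo, col_hi) {
  if (col_hi <= col_lo) return(0L)
  sum(text[(col_lo + 1L):col_hi] != GAP_RAW)
}

# split a piece at reference offsets (0 < off < ref length, relative to lo);
# gap columns in the slot before base off+1 stay with the left fragment
split_piece <- function(piece, offs) {
  offs <- sort(unique(offs))
  len <- piece$hi - piece$lo
  offs <- offs[offs > 0L & offs < len]
  if (length(offs) == 0L) return(list(piece))
  g <- slot_gaps(piece$ref)
  cg <- cumsum(g)
  cuts <- offs + cg[offs + 1L]   # column index (count of columns on the left)
  bounds <- c(0L, cuts, length(piece$ref))
  ref_bounds <- c(0L, offs, len)
  out <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    c_lo <- bounds[k]; c_hi <- bounds[k + 1L]
    rows <- lapply(piece$rows, function(r) {
      before <- row_nongap_counts(r$text, 0L, c_lo)
      inside <- row_nongap_counts(r$text, c_lo, c_hi)
      nr <- r
      nr$text <- r$text[(c_lo + 1L):c_hi]
      if (r$strand == "+") {
        nr$start <- r$start + before
        nr$end <- nr$start + inside
      } else {
        nr$end <- r$end - before
        nr$start <- nr$end - inside
      }
      nr
    })
    out[[k]] <- list(chrom = piece$chrom,
                     lo = piece$lo + ref_bounds[k],
                     hi = piece$lo + ref_bounds[k + 1L],
                     ref = piece$ref[(c_lo + 1L):c_hi],
                     rows = rows)
  }
  out
}

# extract the sub-alignment of an accepted HSP restricted to query interval
# [a, b); returns list(cigar, s_start, s_end) in forward subject coords
hsp_subalignment <- function(h, a, b) {
  off <- a - h$q_start
  cut1 <- cigar_cut(h$cigar, q_take = off)
  p <- parse_cigar(cut1$tail)
  lead_s <- 0L
  while (nrow(p) > 0L && p$op[1] == "D") {
    lead_s <- lead_s + p$len[1]
    p <- p[-1, , drop = FALSE]
  }
  cut2 <- cigar_cut(build_cigar(p$len, p$op), q_take = b - a)
  s_off <- cut1$s_used + lead_s
  if (h$strand == "+") {
    s_start <- h$s_start + s_off
    s_end <- s_start + cut2$s_used
  } else {
    s_end <- h$s_end - s_off
    s_start <- s_end - cut2$s_used
  }
  list(cigar = cut2$head, s_start = s_start, s_end = s_end)
}

oriented_subject_seq <- function(seqs, chrom, s_start, s_end, strand) {
  s <- substring(seqs[[chrom]], s_start + 1L, s_end)
  if (strand == "-") revcomp(s) else s
}

#' Reconstruct the multi-genome core alignment by backtracking
#'
#' Starting from the accepted pairwise blocks of the last iteration, each
#' block's consensus interval is translated back through every iteration's
#' coordinate map; blocks are split at map discontinuities, and each level's
#' subject row is threaded into the profile with [project_gaps()]. The
#' result has exactly one row per input genome in every block, and removing
#' the gaps from any row reproduces the corresponding genome substring.
#'
#' @param run a `progressive_run` from [run_progressive()] (or its
#'   `iterations` list).
#' @param genomes the input genome list (used for source sizes and the final
#'   per-row verification).
#' @param min_block_len drop final blocks whose reference span is below this
#'   many bases; splitting at map discontinuities can leave fragments shorter
#'   than the chaining length filter, and the emitted core honours the same
#'   contract.
#' @return an object of class `core_alignment`: list with `blocks` (each a
#'   list with `width` and a `rows` data.frame: `genome_id`, `chrom`,
#'   `start`, `end`, `strand`, `src_size`, `text`) and `genome_order`.
#' @export
backtrack_msa <- function(run, genomes, min_block_len = 0L) {
  its <- if (inherits(run, "progressive_run")) run$iterations else run
  if (length(its) == 0L) {
    stop_corealign("no iterations to backtrack", "corealign_backtrack_error")
  }
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  names(genomes) <- ids
  n <- length(its)
  query_id <- if (inherits(run, "progressive_run")) run$initial_query else
    setdiff(ids, vapply(its, `[[`, character(1), "subject_id"))[1]

  # seed pieces from the last iteration's accepted blocks
  last <- its[[n]]
  pieces <- list()
  for (r in seq_len(nrow(last$hsps))) {
    h <- last$hsps[r, ]
    qseq <- substring(last$query_seqs[[h$q_chrom]], h$q_start + 1L, h$q_end)
    sseq <- oriented_subject_seq(last$subject_seqs, h$s_chrom,
                                 h$s_start, h$s_end, h$strand)
    gr <- cigar_gapped_rows(qseq, sseq, h$cigar)
    pieces[[length(pieces) + 1L]] <- list(
      chrom = h$q_chrom, lo = h$q_start, hi = h$q_end, ref = gr$q,
      rows = list(list(genome_id = last$subject_id, chrom = h$s_chrom,
                       start = h$s_start, end = h$s_end, strand = h$strand,
                       text = gr$s)))
  }

  # walk the stack backwards: translate coordinates, split, thread rows
  for (i in rev(seq_len(n - 1L))) {
    it <- its[[i]]
    map <- it$consensus_map
    new_pieces <- list()
    for (piece in pieces) {
      segs <- map[map$chrom == piece$chrom &
                  map$cons_end > piece$lo & map$cons_start < piece$hi, ,
                  drop = FALSE]
      if (nrow(segs) == 0L) {
        stop_corealign("unmappable consensus interval (corrupt map)",
                       "corealign_backtrack_error")
      }
      segs <- segs[order(segs$cons_start), , drop = FALSE]
      cuts <- segs$cons_start[-1] - piece$lo
      frags <- split_piece(piece, cuts)
      for (f in frags) {
        seg <- segs[segs$cons_start <= f$lo & segs$cons_end >= f$hi, , drop = FALSE]
        if (nrow(seg) != 1L) {
          stop_corealign("consensus interval does not map to a unique segment",
                         "corealign_backtrack_error")
        }
        a <- seg$prev_start + (f$lo - seg$cons_start)
        b <- a + (f$hi - f$lo)
        # locate the accepted HSP this segment came from
        hrow <- it$hsps[it$hsps$q_chrom == f$chrom & it$hsps$q_start <= a &
                        it$hsps$q_end >= b, , drop = FALSE]
        if (nrow(hrow) != 1L) {
          stop_corealign("backtracked interval not covered by one accepted HSP",
                         "corealign_backtrack_error")
        }
        h <- hrow[1, ]
        sub <- hsp_subalignment(h, a, b)
        qseq <- substring(it$query_seqs[[f$chrom]], a + 1L, b)
        if (!identical(ungap_raw(f$ref), charToRaw(qseq))) {
          stop_corealign("reference bases disagree across iteration levels",
                         "corealign_backtrack_error")
        }
        sseq <- oriented_subject_seq(it$subject_seqs, h$s_chrom,
                                     sub$s_start, sub$s_end, h$strand)
        gr <- cigar_gapped_rows(qseq, sseq, sub$cigar)
        gA <- slot_gaps(f$ref)
        gB <- slot_gaps(gr$q)
        g <- pmax(gA, gB)
        rows <- lapply(f$rows, function(r) {
          r$text <- regap_row(r$text, f$ref, g)
          r
        })
        new_row <- list(genome_id = it$subject_id, chrom = h$s_chrom,
                        start = sub$s_start, end = sub$s_end,
                        strand = h$strand,
                        text = regap_row(gr$s, gr$q, g))
        f$ref <- regap_row(f$ref, f$ref, g)
        f$rows <- c(rows, list(new_row))
        f$lo <- a
        f$hi <- b
        new_pieces[[length(new_pieces) + 1L]] <- f
      }
    }
    pieces <- new_pieces
  }

  # assemble blocks: reference row (initial query genome) first, subjects in
  # iteration order; strip all-gap columns introduced by splitting
  subj_order <- vapply(its, `[[`, character(1), "subject_id")
  genome_order <- unname(c(query_id, subj_order))
  src_sizes <- lapply(genomes, function(g) nchar(g$sequences))
  blocks <- list()
  pieces <- Filter(function(p) p$hi - p$lo >= min_block_len, pieces)
  ord <- order(vapply(pieces, `[[`, character(1), "chrom"),
               vapply(pieces, `[[`, numeric(1), "lo"))
  for (piece in pieces[ord]) {
    texts <- c(list(piece$ref), lapply(piece$rows, `[[`, "text"))
    mat <- do.call(rbind, texts)
    keep <- apply(mat != GAP_RAW, 2L, any)
    mat <- mat[, keep, drop = FALSE]
    row_meta <- rbind(
      data.frame(genome_id = query_id, chrom = piece$chrom,
                 start = piece$lo, end = piece$hi, strand = "+",
                 stringsAsFactors = FALSE),
      do.call(rbind, lapply(piece$rows, function(r) {
        data.frame(genome_id = r$genome_id, chrom = r$chrom, start = r$start,
                   end = r$end, strand = r$strand, stringsAsFactors = FALSE)
      })))
    o <- match(genome_order, row_meta$genome_id)
    if (anyNA(o)) {
      stop_corealign("block lacks a row for some genome", "corealign_backtrack_error")
    }
    row_meta <- row_meta[o, , drop = FALSE]
    mat <- mat[o, , drop = FALSE]
    row_meta$src_size <- mapply(function(g, ch) src_sizes[[g]][[ch]],
                                row_meta$genome_id, row_meta$chrom)
    row_meta$text <- apply(mat, 1L, function(x) rawToChar(as.raw(x)))
    rownames(row_meta) <- NULL
    blocks[[length(blocks) + 1L]] <- list(width = ncol(mat), rows = row_meta)
  }
  structure(list(blocks = blocks, genome_order = genome_order),
            class = "core_alignment")
}

#' @export
print.core_alignment <- function(x, ...) {
  w <- vapply(x$blocks, `[[`, numeric(1), "width")
  cat(sprintf("<core_alignment> %d genomes, %d blocks, %s aligned columns\n",
              length(x$genome_order), length(x$blocks),
              format(sum(w), big.mark = ",")))
  invisible(x)
}

#' Convert a core alignment to MAF blocks
#'
#' Row names use `"<genome>.<chromosome>"`; '-' strand rows are emitted with
#' the MAF convention (start on the reverse-complemented source).
#'
#' @param core a `core_alignment`.
#' @return list of [maf_block()] objects.
#' @export
core_to_maf <- function(core) {
  stopifnot(inherits(core, "core_alignment"))
  lapply(core$blocks, function(b) {
    r <- b$rows
    maf_start <- ifelse(r$strand == "+", r$start, r$src_size - r$end)
    maf_block(data.frame(
      src = paste(r$genome_id, r$chrom, sep = "."),
      start = as.integer(maf_start), size = as.integer(r$end - r$start),
      strand = r$strand, src_size = as.integer(r$src_size), text = r$text,
      stringsAsFactors = FALSE))
  })
}

#' Convert MAF blocks back to a core alignment
#'
#' Inverse of [core_to_maf()] for blocks with one row per genome and dotted
#' source names.
#'
#' @param blocks list of [maf_block()] objects.
#' @return a `core_alignment`.
#' @export
maf_to_core <- function(blocks) {
  if (length(blocks) == 0L) {
    return(structure(list(blocks = list(), genome_order = character(0)),
                     class = "core_alignment"))
  }
  genome_order <- maf_row_genomes(blocks[[1]])
  core_blocks <- lapply(blocks, function(b) {
    r <- b$rows
    genome_id <- sub("\\..*$", "", r$src)
    chrom <- sub("^[^.]*\\.", "", r$src)
    start <- ifelse(r$strand == "+", r$start, r$src_size - r$start - r$size)
    list(width = maf_block_width(b),
         rows = data.frame(genome_id = genome_id, chrom = chrom,
                           start = as.integer(start),
                           end = as.integer(start + r$size),
                           strand = r$strand, src_size = r$src_size,
                           text = r$text, stringsAsFactors = FALSE))
  })
  structure(list(blocks = core_blocks, genome_order = genome_order),
            class = "core_alignment")
}
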