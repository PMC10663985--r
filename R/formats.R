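# On-disk formats: FASTA genomes, PAF (with cg:Z cigars) for the pairwise
# adapter, MAF v1 for alignment output, and the concatenated multi-FASTA (MFA)
# of the final core alignment. FASTA goes through Biostrings; MAF and PAF are
# parsed here (no installed R package reads them).
#
# MAF row names use the "<genome>.<chromosome>" convention, so genome ids must
# not contain a dot. '-' strand rows follow the strict MAF convention: start is
# the position on the reverse-complemented source.

#' Construct a genome record
#'
#' A genome record holds one assembly: an ordered set of chromosome/contig
#' sequences plus summary counts used by [pick_initial_query()].
#'
#' @param genome_id single string identifying the genome (no `.`).
#' @param sequences named character vector of nucleotide sequences, one per
#'   chromosome/contig; names must be unique. Sequences are uppercased.
#' @return an object of class `genome_record` with fields `genome_id`,
#'   `sequences`, `total_length` and `ambiguous_count` (bases not in A/C/G/T).
#' @export
genome_record <- function(genome_id, sequences) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (grepl(".", genome_id, fixed = TRUE)) {
    stop_corealign("genome_id must not contain '.', it is the MAF name separator",
                   "corealign_format_error")
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_corealign("sequences must be uniquely named by chromosome id",
                   "corealign_format_error")
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTURYSWKMBDHVN]", sequences)
  if (any(bad)) {
    stop_corealign(sprintf("non-nucleotide characters in sequence '%s'",
                           names(sequences)[bad][1]),
                   "corealign_format_error")
  }
  amb <- sum(vapply(sequences, function(s) {
    nchar(s) - sum(charToRaw(s) %in% charToRaw("ACGT"))
  }, numeric(1)))
  structure(list(
    genome_id = genome_id,
    sequences = sequences,
    total_length = sum(nchar(sequences)),
    ambiguous_count = as.numeric(amb)
  ), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d sequence(s), %s bp, %s ambiguous\n",
              x$genome_id, length(x$sequences),
              format(x$total_length, big.mark = ","),
              format(x$ambiguous_count, big.mark = ",")))
  invisible(x)
}

#' Read a genome assembly from FASTA
#'
#' @param path FASTA file, one record per chromosome/contig.
#' @param genome_id genome identifier; defaults to the file name without
#'   extension.
#' @return a [genome_record()].
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    stop_corealign(sprintf("file not found: %s", path), "corealign_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_corealign(sprintf("empty FASTA file: %s", path), "corealign_format_error")
  }
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    stop_corealign(sprintf("duplicate record id in %s: %s", path,
                           nms[duplicated(nms)][1]),
                   "corealign_format_error")
  }
  seqs <- as.character(set)
  names(seqs) <- nms
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
    genome_id <- gsub(".", "_", genome_id, fixed = TRUE)
  }
  genome_record(genome_id, seqs)
}

#' Write a genome record (or named sequence set) to FASTA
#'
#' @param x a [genome_record()] or a named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  seqs <- if (inherits(x, "genome_record")) x$sequences else x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- HSP tables ------------------------------------------------------------

#' Construct an HSP table
#'
#' High-scoring segment pairs are kept as a data.frame, one row per local
#' alignment anchor. Query and subject intervals are 0-based half-open on the
#' forward strand; the cigar of a '-' strand HSP aligns the forward query
#' against the reverse complement of the subject interval.
#'
#' @param q_chrom,q_start,q_end query chromosome and interval.
#' @param s_chrom,s_start,s_end subject chromosome and interval (forward strand).
#' @param strand "+" or "-".
#' @param score alignment score (higher is better).
#' @param cigar CIGAR string (M/I/D) or NA when base-level detail is absent.
#' @param identity fraction of matching columns in \[0,1\] (NA if unknown).
#' @return a data.frame of class `hsp_df`.
#' @export
hsp_table <- function(q_chrom = character(0), q_start = integer(0),
                      q_end = integer(0), s_chrom = character(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), score = numeric(0),
                      cigar = NA_character_, identity = NA_real_) {
  n <- max(length(q_chrom), length(q_start))
  df <- data.frame(
    q_chrom = rep_len(as.character(q_chrom), n),
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_chrom = as.character(s_chrom),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    strand = as.character(strand),
    score = as.numeric(score),
    cigar = rep_len(as.character(cigar), n),
    identity = rep_len(as.numeric(identity), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("hsp_df", "data.frame")
  df
}

#' Validate HSP invariants
#'
#' Checks interval orientation, strand values, finite scores, and (when a
#' cigar is present) that its query- and subject-consuming lengths match the
#' intervals.
#'
#' @param hsps an [hsp_table()].
#' @return `hsps`, invisibly; aborts on violation.
#' @export
validate_hsps <- function(hsps) {
  if (nrow(hsps) == 0L) return(invisible(hsps))
  if (any(hsps$q_start >= hsps$q_end) || any(hsps$s_start >= hsps$s_end)) {
    stop_corealign("HSP with empty or inverted interval", "corealign_hsp_error")
  }
  if (!all(hsps$strand %in% c("+", "-"))) {
    stop_corealign("HSP strand must be '+' or '-'", "corealign_hsp_error")
  }
  if (any(!is.finite(hsps$score))) {
    stop_corealign("HSP score must be finite", "corealign_hsp_error")
  }
  has_cg <- !is.na(hsps$cigar)
  for (i in which(has_cg)) {
    if (cigar_qlen(hsps$cigar[i]) != hsps$q_end[i] - hsps$q_start[i] ||
        cigar_slen(hsps$cigar[i]) != hsps$s_end[i] - hsps$s_start[i]) {
      stop_corealign(sprintf(
        "HSP %d: CIGAR lengths inconsistent with intervals", i),
        "corealign_hsp_error")
    }
  }
  invisible(hsps)
}

# ---- PAF -------------------------------------------------------------------

#' Read HSPs from a PAF file
#'
#' Parses the 12 mandatory PAF columns plus the `cg:Z:` cigar and `AS:i:`
#' score tags when present. Coordinates are kept 0-based half-open as in PAF.
#' The score is `AS` when present, otherwise the number of residue matches
#' (column 10).
#'
#' @param path PAF file.
#' @param strict if TRUE, abort on a malformed line instead of dropping it
#'   with a warning.
#' @return an [hsp_table()] with extra columns `q_len`, `s_len` and
#'   `has_cigar`; rows are in file order.
#' @export
read_paf <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop_corealign(sprintf("file not found: %s", path), "corealign_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    bad <- function(why) {
      msg <- sprintf("PAF line %d %s", i, why)
      if (strict) stop_corealign(msg, "corealign_format_error")
      warn_corealign(paste0(msg, "; line dropped"), "corealign_format_warning")
      NULL
    }
    if (length(f) < 12L) { out[[i]] <- bad("has fewer than 12 columns"); next }
    q_start <- suppressWarnings(as.integer(f[3]))
    q_end <- suppressWarnings(as.integer(f[4]))
    s_start <- suppressWarnings(as.integer(f[8]))
    s_end <- suppressWarnings(as.integer(f[9]))
    nmatch <- suppressWarnings(as.numeric(f[10]))
    if (anyNA(c(q_start, q_end, s_start, s_end, nmatch)) ||
        !f[5] %in% c("+", "-")) {
      out[[i]] <- bad("has unparseable coordinates or strand"); next
    }
    tags <- if (length(f) > 12L) f[13:length(f)] else character(0)
    cg <- tags[startsWith(tags, "cg:Z:")]
    as_tag <- tags[startsWith(tags, "AS:i:")]
    cigar <- if (length(cg)) sub("^cg:Z:", "", cg[1]) else NA_character_
    score <- if (length(as_tag)) as.numeric(sub("^AS:i:", "", as_tag[1])) else nmatch
    if (!is.na(cigar)) {
      ok <- tryCatch({
        cigar_qlen(cigar) == q_end - q_start &&
          cigar_slen(cigar) == s_end - s_start
      }, corealign_error = function(e) FALSE)
      if (!ok) { out[[i]] <- bad("has a cigar inconsistent with its intervals"); next }
    }
    alen <- suppressWarnings(as.numeric(f[11]))
    out[[i]] <- data.frame(
      q_chrom = f[1], q_start = q_start, q_end = q_end,
      s_chrom = f[6], s_start = s_start, s_end = s_end,
      strand = f[5], score = score, cigar = cigar,
      identity = if (is.finite(alen) && alen > 0) nmatch / alen else NA_real_,
      q_len = suppressWarnings(as.integer(f[2])),
      s_len = suppressWarnings(as.integer(f[7])),
      has_cigar = !is.na(cigar),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- cbind(hsp_table(), q_len = integer(0), s_len = integer(0),
                 has_cigar = logical(0))
  }
  class(res) <- c("hsp_df", "data.frame")
  res
}

#' Write an HSP table to PAF
#'
#' @param hsps an [hsp_table()]; optional columns `q_len`/`s_len` supply the
#'   sequence-length columns, otherwise the interval ends are used as a lower
#'   bound.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(hsps, path) {
  validate_hsps(hsps)
  q_len <- if ("q_len" %in% names(hsps)) hsps$q_len else hsps$q_end
  s_len <- if ("s_len" %in% names(hsps)) hsps$s_len else hsps$s_end
  lines <- character(nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    ncol_aln <- if (!is.na(hsps$cigar[i])) length(cigar_ops(hsps$cigar[i])) else
      max(hsps$q_end[i] - hsps$q_start[i], hsps$s_end[i] - hsps$s_start[i])
    nmatch <- if (!is.na(hsps$identity[i])) round(hsps$identity[i] * ncol_aln) else
      min(hsps$q_end[i] - hsps$q_start[i], hsps$s_end[i] - hsps$s_start[i])
    f <- c(hsps$q_chrom[i], q_len[i], hsps$q_start[i], hsps$q_end[i],
           hsps$strand[i], hsps$s_chrom[i], s_len[i], hsps$s_start[i],
           hsps$s_end[i], nmatch, ncol_aln, 255,
           sprintf("AS:i:%d", as.integer(round(hsps$score[i]))))
    if (!is.na(hsps$cigar[i])) f <- c(f, paste0("cg:Z:", hsps$cigar[i]))
    lines[i] <- paste(f, collapse = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- MAF -------------------------------------------------------------------

#' Construct a MAF block
#'
#' @param rows data.frame with columns `src` (source name,
#'   `"<genome>.<chrom>"`), `start` (0-based; for '-' strand rows the MAF
#'   convention: position on the reverse-complemented source), `size`
#'   (ungapped length), `strand`, `src_size` (source sequence length) and
#'   `text` (gapped alignment row).
#' @param score optional numeric block score.
#' @return an object of class `maf_block`.
#' @export
maf_block <- function(rows, score = NA_real_) {
  stopifnot(is.data.frame(rows),
            all(c("src", "start", "size", "strand", "src_size", "text")
                %in% names(rows)))
  widths <- nchar(rows$text)
  if (length(unique(widths)) > 1L) {
    stop_corealign("MAF block rows have unequal widths", "corealign_maf_error")
  }
  ungapped <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  if (any(ungapped != rows$size)) {
    stop_corealign("MAF row size does not match its gap-stripped text",
                   "corealign_maf_error")
  }
  if (!all(rows$strand %in% c("+", "-"))) {
    stop_corealign("MAF strand must be '+' or '-'", "corealign_maf_error")
  }
  structure(list(rows = rows, score = score), class = "maf_block")
}

maf_block_width <- function(block) {
  if (nrow(block$rows) == 0L) 0L else nchar(block$rows$text[1])
}

maf_row_genomes <- function(block) {
  sub("\\..*$", "", block$rows$src)
}

#' Write MAF blocks to a file
#'
#' Emits minimal MAF 1.0: a `##maf version=1` header, then one `a` line
#' (with `score=` when available) and its `s` lines per block.
#'
#' @param blocks list of [maf_block()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 program=corealign", con)
  writeLines("", con)
  for (b in blocks) {
    if (!inherits(b, "maf_block")) {
      stop_corealign("write_maf expects maf_block objects", "corealign_maf_error")
    }
    a <- if (is.na(b$score)) "a" else sprintf("a score=%s", format(b$score))
    writeLines(a, con)
    r <- b$rows
    writeLines(sprintf("s %s %d %d %s %d %s",
                       r$src, r$start, r$size, r$strand, r$src_size, r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read MAF blocks from a file
#'
#' Parses `a`/`s` lines of MAF 1.0; `q`/`i`/`e` lines are ignored.
#'
#' @param path MAF file.
#' @return list of [maf_block()] objects.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) {
    stop_corealign(sprintf("file not found: %s", path), "corealign_io_error")
  }
  lines <- readLines(path)
  blocks <- list()
  cur_rows <- NULL
  cur_score <- NA_real_
  flush <- function() {
    if (!is.null(cur_rows) && nrow(cur_rows) > 0L) {
      blocks[[length(blocks) + 1L]] <<- maf_block(cur_rows, cur_score)
    }
    cur_rows <<- NULL
    cur_score <<- NA_real_
  }
  for (ln in lines) {
    if (startsWith(ln, "#") || !nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "a")) {
      flush()
      cur_rows <- data.frame(src = character(0), start = integer(0),
                             size = integer(0), strand = character(0),
                             src_size = integer(0), text = character(0),
                             stringsAsFactors = FALSE)
      m <- regmatches(ln, regexpr("score=\\S+", ln))
      if (length(m)) cur_score <- as.numeric(sub("score=", "", m))
    } else if (startsWith(ln, "s")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 7L) {
        stop_corealign(sprintf("malformed MAF 's' line: %s", ln),
                       "corealign_maf_error")
      }
      if (is.null(cur_rows)) {
        stop_corealign("MAF 's' line outside a block", "corealign_maf_error")
      }
      cur_rows <- rbind(cur_rows, data.frame(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE))
    }
  }
  flush()
  blocks
}

#' Extract core blocks from a MAF block list
#'
#' Keeps exactly the blocks that contain at least one row from every named
#' genome and whose alignment width is at least `min_len`. Row order within
#' blocks is preserved. Genome names are matched against the part of the MAF
#' source name before the first dot.
#'
#' @param blocks list of [maf_block()] objects.
#' @param genome_names character vector of required genome ids (nonempty).
#' @param min_len minimum alignment width (columns) to keep a block.
#' @return the filtered list (possibly empty).
#' @export
extract_core_from_maf <- function(blocks, genome_names, min_len = 0L) {
  if (length(genome_names) == 0L) {
    stop_corealign("genome_names must be nonempty", "corealign_format_error")
  }
  keep <- vapply(blocks, function(b) {
    all(genome_names %in% maf_row_genomes(b)) && maf_block_width(b) >= min_len
  }, logical(1))
  blocks[keep]
}

#' Write a core alignment as concatenated multi-FASTA (MFA)
#'
#' One FASTA record per genome; each record is the concatenation of that
#' genome's gapped rows across all core blocks in block order, so all records
#' have equal length.
#'
#' @param core a `core_alignment` (see [backtrack_msa()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mfa <- function(core, path) {
  stopifnot(inherits(core, "core_alignment"))
  if (length(core$blocks) == 0L) {
    stop_corealign("cannot write MFA for an empty core alignment",
                   "corealign_format_error")
  }
  seqs <- stats::setNames(
    vapply(core$genome_order, function(g) {
      paste(vapply(core$blocks, function(b) {
        b$rows$text[b$rows$genome_id == g]
      }, character(1)), collapse = "")
    }, character(1)),
    core$genome_order)
  if (length(unique(nchar(seqs))) != 1L) {
    stop_corealign("MFA records have unequal lengths (corrupt core alignment)",
                   "corealign_format_error")
  }
  write_fasta(seqs, path)
}
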