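# Low-level helpers shared across modules: classed conditions, reverse
# complement, and CIGAR arithmetic. All coordinates are 0-based half-open
# internally; conversion to the 1-based or reverse-strand conventions of the
# on-disk formats happens only at I/O boundaries.

stop_corealign <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "corealign_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

warn_corealign <- function(msg, class) {
  warning(structure(
    class = c(class, "corealign_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

GAP_RAW <- charToRaw("-")

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented; case is preserved.
#'
#' @param x a single character string.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  rawToChar(rev(charToRaw(comp)))
}

# ---- CIGAR -----------------------------------------------------------------
# Internal convention: M consumes query and subject (match or mismatch),
# I consumes query only, D consumes subject only. '=' and 'X' are accepted on
# input and normalised to M. The cigar of a '-' strand HSP aligns the forward
# query against the reverse complement of the subject interval.

#' Parse a CIGAR string into run lengths and operations
#'
#' @param cigar a CIGAR string such as `"10M2I3D"`.
#' @return a data.frame with columns `len` (integer) and `op` (character,
#'   one of M/I/D).
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L)
  if (is.na(cigar) || cigar == "") {
    return(data.frame(len = integer(0), op = character(0)))
  }
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)
  if (m[[1]][1] == -1L ||
      sum(attr(m[[1]], "match.length")) != nchar(cigar)) {
    stop_corealign(sprintf("malformed CIGAR string: '%s'", cigar),
                   "corealign_cigar_error")
  }
  runs <- regmatches(cigar, m)[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", runs))
  op <- sub("^\\d+", "", runs)
  op[op %in% c("=", "X")] <- "M"
  if (any(!op %in% c("M", "I", "D"))) {
    stop_corealign(sprintf("unsupported CIGAR operation in '%s'", cigar),
                   "corealign_cigar_error")
  }
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Build a CIGAR string from runs, collapsing adjacent equal operations
#' @param len integer run lengths.
#' @param op character vector of operations (M/I/D).
#' @return a CIGAR string.
#' @export
build_cigar <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (length(op) == 0L) return("")
  r <- rle(paste0(op))
  # collapse runs of the same op by summing lengths
  grp <- rep(seq_along(r$lengths), r$lengths)
  len2 <- as.vector(tapply(len, grp, sum))
  op2 <- r$values
  paste0(len2, op2, collapse = "")
}

# number of query / subject bases a cigar consumes
cigar_qlen <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I")])
}

cigar_slen <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D")])
}

# expand a cigar into a per-column op vector
cigar_ops <- function(cigar) {
  cg <- parse_cigar(cigar)
  rep(cg$op, cg$len)
}

# Split a cigar so that the head consumes exactly q_take query bases and at
# least s_min subject bases (whichever bound is reached later). Returns
# list(head, tail, q_used, s_used). Used when trimming/merging HSPs.
cigar_cut <- function(cigar, q_take = NULL, s_take = NULL) {
  ops <- cigar_ops(cigar)
  qc <- cumsum(ops %in% c("M", "I"))
  sc <- cumsum(ops %in% c("M", "D"))
  n <- length(ops)
  k <- 0L
  if (!is.null(q_take)) {
    k <- if (q_take <= 0L) 0L else which(qc >= q_take)[1]
    if (is.na(k)) k <- n
  } else if (!is.null(s_take)) {
    k <- if (s_take <= 0L) 0L else which(sc >= s_take)[1]
    if (is.na(k)) k <- n
  }
  head_ops <- ops[seq_len(k)]
  tail_ops <- if (k < n) ops[(k + 1L):n] else character(0)
  list(
    head = build_cigar(rep(1L, length(head_ops)), head_ops),
    tail = build_cigar(rep(1L, length(tail_ops)), tail_ops),
    q_used = if (k > 0L) qc[k] else 0L,
    s_used = if (k > 0L) sc[k] else 0L
  )
}

# Materialise the gapped rows of an alignment given ungapped query and subject
# substrings (already oriented) and a cigar. Returns list(q, s) raw vectors.
cigar_gapped_rows <- function(qseq, sseq, cigar) {
  ops <- cigar_ops(cigar)
  qraw <- charToRaw(qseq)
  sraw <- charToRaw(sseq)
  isq <- ops %in% c("M", "I")
  iss <- ops %in% c("M", "D")
  if (sum(isq) != length(qraw) || sum(iss) != length(sraw)) {
    stop_corealign("CIGAR length inconsistent with sequence lengths",
                   "corealign_cigar_error")
  }
  q <- rep(GAP_RAW, length(ops))
  s <- rep(GAP_RAW, length(ops))
  q[isq] <- qraw
  s[iss] <- sraw
  list(q = q, s = s)
}

# run-length intervals of TRUE stretches of a logical vector, 0-based half-open
logical_runs <- function(x) {
  if (length(x) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
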