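# Independent oracles used across the suite. These deliberately re-derive
# expected results with different algorithms/data layouts than the package
# code: a literal replay of the chaining insertion rules, a streaming
# column-merge for gap projection, and recursive split enumeration for RF.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mutate_seq <- function(s, snp_rate) {
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < snp_rate)
  if (length(idx)) {
    v[idx] <- vapply(v[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(v, collapse = "")
}

# random HSP tables (no cigars) for chaining tests
rand_hsp_instance <- function(n, q_len = 2000L, n_s_chrom = 2L,
                              strands = c("+", "-")) {
  starts <- sample(0:(q_len - 60L), n, replace = TRUE)
  lens <- sample(30:400, n, replace = TRUE)
  ends <- pmin(starts + lens, q_len)
  s_starts <- sample(0:5000, n, replace = TRUE)
  s_lens <- pmax(1L, ends - starts + sample(-10:10, n, replace = TRUE))
  hsp_table(
    q_chrom = rep("q1", n), q_start = starts, q_end = ends,
    s_chrom = sample(paste0("s", seq_len(n_s_chrom)), n, replace = TRUE),
    s_start = s_starts, s_end = s_starts + s_lens,
    strand = sample(strands, n, replace = TRUE),
    score = sample(10:100, n, replace = TRUE),
    cigar = NA_character_, identity = NA_real_
  )
}

# ---- literal replay of the chaining rules ----------------------------------

oracle_overlap <- function(h, i, j) {
  max(0, min(h$q_end[i], h$q_end[j]) - max(h$q_start[i], h$q_start[j]))
}

oracle_chain_one_chrom <- function(h, params) {
  # step 1: order by ascending position, descending score (+ tie-breaks)
  h <- h[order(h$q_start, -h$score, h$q_end, h$s_chrom, h$s_start), ,
         drop = FALSE]
  rownames(h) <- NULL
  # step 2: sequential insertion with >frac shorter-interval overlap rejection
  acc <- h[0, , drop = FALSE]
  for (k in seq_len(nrow(h))) {
    x <- h[k, , drop = FALSE]
    confl <- integer(0)
    for (a in seq_len(nrow(acc))) {
      ov <- max(0, min(acc$q_end[a], x$q_end) - max(acc$q_start[a], x$q_start))
      shorter <- min(acc$q_end[a] - acc$q_start[a], x$q_end - x$q_start)
      if (ov > params$overlap_reject_frac * shorter) confl <- c(confl, a)
    }
    if (length(confl) == 0L) {
      acc <- rbind(acc, x)
    } else if (x$score > max(acc$score[confl])) {
      acc <- rbind(acc[-confl, , drop = FALSE], x)
    }
  }
  # step 3: merge similar-scored overlapping, same subject chrom/strand,
  # order-consistent pairs; first pair in query order, to fixpoint
  repeat {
    acc <- acc[order(acc$q_start, acc$q_end, acc$s_chrom, acc$s_start), ,
               drop = FALSE]
    rownames(acc) <- NULL
    hit <- NULL
    for (i in seq_len(max(0L, nrow(acc) - 1L))) {
      for (j in (i + 1L):nrow(acc)) {
        if (acc$q_start[j] >= acc$q_end[i]) break
        if (oracle_overlap(acc, i, j) <= params$merge_min_overlap) next
        if (acc$s_chrom[i] != acc$s_chrom[j]) next
        if (acc$strand[i] != acc$strand[j]) next
        si <- acc$score[i]; sj <- acc$score[j]
        if (abs(si - sj) > params$similar_score_tol * max(abs(si), abs(sj))) next
        ok <- if (acc$strand[i] == "+") acc$s_start[i] <= acc$s_start[j]
              else acc$s_start[j] <= acc$s_start[i]
        if (!ok) next
        hit <- c(i, j); break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    i <- hit[1]; j <- hit[2]
    merged <- acc[i, , drop = FALSE]
    merged$q_end <- max(acc$q_end[i], acc$q_end[j])
    merged$s_start <- min(acc$s_start[i], acc$s_start[j])
    merged$s_end <- max(acc$s_end[i], acc$s_end[j])
    merged$score <- acc$score[i] + acc$score[j]
    merged$cigar <- NA_character_
    merged$identity <- NA_real_
    acc <- rbind(acc[-c(i, j), , drop = FALSE], merged)
  }
  # step 4a: homoeologous chromosome resolution
  if (isTRUE(params$use_chromosome_info)) {
    hm <- params$homology_map
    repeat {
      drop <- integer(0)
      if (nrow(acc) >= 2L) {
        for (i in 1:(nrow(acc) - 1L)) {
          for (j in (i + 1L):nrow(acc)) {
            if (acc$s_chrom[i] == acc$s_chrom[j]) next
            if (oracle_overlap(acc, i, j) < 1) next
            si <- acc$score[i]; sj <- acc$score[j]
            if (abs(si - sj) > params$similar_score_tol * max(abs(si), abs(sj))) next
            gq <- unname(hm[acc$q_chrom[i]])
            gi <- unname(hm[acc$s_chrom[i]]); gj <- unname(hm[acc$s_chrom[j]])
            if (is.na(gq)) next
            mi <- !is.na(gi) && gi == gq; mj <- !is.na(gj) && gj == gq
            if (mi && !mj) drop <- c(drop, j)
            if (mj && !mi) drop <- c(drop, i)
          }
        }
      }
      if (!length(drop)) break
      acc <- acc[-unique(drop), , drop = FALSE]
      rownames(acc) <- NULL
    }
  }
  # step 4b: greedy removal of crossing pairs, highest-scoring conflict first
  repeat {
    acc <- acc[order(acc$q_start, acc$q_end, acc$s_chrom, acc$s_start), ,
               drop = FALSE]
    rownames(acc) <- NULL
    cross <- NULL
    if (nrow(acc) >= 2L) {
      for (i in 1:(nrow(acc) - 1L)) {
        for (j in (i + 1L):nrow(acc)) {
          if (acc$s_chrom[i] != acc$s_chrom[j]) next
          if (acc$strand[i] != acc$strand[j]) next
          ok <- if (acc$strand[i] == "+") acc$s_start[i] <= acc$s_start[j]
                else acc$s_start[j] <= acc$s_start[i]
          if (ok) next
          cross <- rbind(cross, data.frame(
            i = i, j = j, hi = max(acc$score[i], acc$score[j]),
            lo = min(acc$score[i], acc$score[j])))
        }
      }
    }
    if (is.null(cross)) break
    cross <- cross[order(-cross$hi, -cross$lo, cross$i, cross$j), , drop = FALSE]
    i <- cross$i[1]; j <- cross$j[1]
    victim <- if (acc$score[i] < acc$score[j]) i
              else if (acc$score[j] < acc$score[i]) j else j
    acc <- acc[-victim, , drop = FALSE]
  }
  # trim residual overlaps: lower-scored member loses the overlap (tie: later)
  repeat {
    acc <- acc[order(acc$q_start, acc$q_end, acc$s_chrom, acc$s_start), ,
               drop = FALSE]
    rownames(acc) <- NULL
    changed <- FALSE
    for (i in seq_len(max(0L, nrow(acc) - 1L))) {
      j <- i + 1L
      ov <- acc$q_end[i] - acc$q_start[j]
      if (ov <= 0) next
      if (acc$score[j] <= acc$score[i]) {
        if (ov >= acc$q_end[j] - acc$q_start[j]) acc <- acc[-j, , drop = FALSE]
        else acc$q_start[j] <- acc$q_start[j] + ov
      } else {
        if (ov >= acc$q_end[i] - acc$q_start[i]) acc <- acc[-i, , drop = FALSE]
        else acc$q_end[i] <- acc$q_end[i] - ov
      }
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  # length filter (inclusive)
  acc <- acc[acc$q_end - acc$q_start >= params$min_hsp_len, , drop = FALSE]
  acc[order(acc$q_start, acc$q_end, acc$s_chrom, acc$s_start), , drop = FALSE]
}

oracle_chain <- function(hsps, params) {
  parts <- lapply(split(hsps, hsps$q_chrom), oracle_chain_one_chrom,
                  params = params)
  parts <- parts[order(names(parts))]
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

hsp_cols <- c("q_chrom", "q_start", "q_end", "s_chrom", "s_start", "s_end",
              "strand", "score")

expect_same_hsps <- function(a, b) {
  a <- as.data.frame(a)[, hsp_cols]
  b <- as.data.frame(b)[, hsp_cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}

# ---- streaming column merge: gap-projection oracle -------------------------

oracle_project_gaps <- function(profile, pair) {
  a <- strsplit(profile[1], "")[[1]]
  b <- strsplit(pair[1], "")[[1]]
  rows <- lapply(profile[-1], function(x) strsplit(x, "")[[1]])
  nb <- strsplit(pair[2], "")[[1]]
  i <- 1L; j <- 1L
  o_ref <- character(0)
  o_rows <- rep(list(character(0)), length(rows))
  o_new <- character(0)
  while (i <= length(a) || j <= length(b)) {
    agap <- i <= length(a) && a[i] == "-"
    bgap <- j <= length(b) && b[j] == "-"
    if (agap && bgap) {
      o_ref <- c(o_ref, "-")
      for (r in seq_along(rows)) o_rows[[r]] <- c(o_rows[[r]], rows[[r]][i])
      o_new <- c(o_new, nb[j])
      i <- i + 1L; j <- j + 1L
    } else if (agap) {
      o_ref <- c(o_ref, "-")
      for (r in seq_along(rows)) o_rows[[r]] <- c(o_rows[[r]], rows[[r]][i])
      o_new <- c(o_new, "-")
      i <- i + 1L
    } else if (bgap) {
      o_ref <- c(o_ref, "-")
      for (r in seq_along(rows)) o_rows[[r]] <- c(o_rows[[r]], "-")
      o_new <- c(o_new, nb[j])
      j <- j + 1L
    } else {
      o_ref <- c(o_ref, a[i])
      for (r in seq_along(rows)) o_rows[[r]] <- c(o_rows[[r]], rows[[r]][i])
      o_new <- c(o_new, nb[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  c(paste(o_ref, collapse = ""),
    vapply(o_rows, paste, character(1), collapse = ""),
    paste(o_new, collapse = ""))
}

# random gapped layouts of a fixed ungapped reference
rand_gapped <- function(ref_chars, max_gaps = 6L, max_run = 3L) {
  L <- length(ref_chars)
  g <- integer(L + 1L)
  spots <- sample(L + 1L, sample(0:max_gaps, 1L))
  g[spots] <- sample(max_run, length(spots), replace = TRUE)
  out <- character(0)
  for (i in seq_len(L + 1L)) {
    out <- c(out, rep("-", g[i]))
    if (i <= L) out <- c(out, ref_chars[i])
  }
  paste(out, collapse = "")
}

# a row aligned against a gapped reference: random bases under gaps too
rand_row_for <- function(ref_gapped) {
  v <- strsplit(ref_gapped, "")[[1]]
  vapply(v, function(ch) {
    if (ch == "-") sample(c("A", "C", "G", "T", "-"), 1)
    else sample(c("A", "C", "G", "T", "-"), 1, prob = c(rep(0.22, 4), 0.12))
  }, character(1)) |> paste(collapse = "")
}

# ---- split enumeration: Robinson-Foulds oracle -----------------------------

tree_split_keys <- function(tr) {
  tr <- ape::unroot(tr)
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    if (child <= ntip) next
    side <- sort(tips_under(child))
    other <- sort(setdiff(tr$tip.label, side))
    if (length(side) < 2L || length(other) < 2L) next
    pick <- if (side[1] < other[1]) side else other
    keys <- c(keys, paste(pick, collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(a, b) {
  sa <- tree_split_keys(a)
  sb <- tree_split_keys(b)
  (length(setdiff(sa, sb)) + length(setdiff(sb, sa))) / 2
}
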