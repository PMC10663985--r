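# HSP chaining: ordering, overlap selection, merging, conflict resolution,
# length filter, and oracle equivalence of the composed pipeline.

# Worked instance mirroring a canonical selection scenario: seven HSPs on one
# query chromosome; segment 2 displaces 1, segments 4 and 5 displace 3 and 6,
# segment 7 is disjoint; 4 and 5 overlap by 20 bp at similar scores on one
# subject chromosome and merge.
worked_hsps <- function() {
  hsp_table(
    q_chrom = rep("q1", 7),
    q_start = c(0, 100, 1500, 1400, 2380, 2600, 4000),
    q_end   = c(1000, 1100, 2500, 2400, 3380, 3300, 4600),
    s_chrom = c("c1", "c1", "c1", "c2", "c2", "c1", "c3"),
    s_start = c(0, 2000, 9000, 5000, 6100, 7000, 100),
    s_end   = c(1000, 3000, 10000, 6000, 7100, 7700, 700),
    strand  = rep("+", 7),
    score   = c(50, 90, 40, 85, 80, 35, 60))
}

test_that("order_hsps sorts by position then descending score", {
  h <- hsp_table(q_chrom = "q1", q_start = c(10, 10, 3),
                 q_end = c(20, 20, 9), s_chrom = "s1",
                 s_start = c(0, 50, 100), s_end = c(10, 60, 106),
                 strand = "+", score = c(5, 9, 1))
  o <- order_hsps(h)
  expect_equal(o$q_start, c(3L, 10L, 10L))
  expect_equal(o$score, c(1, 9, 5))
  expect_identical(order_hsps(o), o)  # idempotent
  expect_error(order_hsps(hsp_table(q_chrom = c("a", "b"), q_start = 0:1,
                                    q_end = 2:3, s_chrom = "s", s_start = 0:1,
                                    s_end = 2:3, strand = "+", score = 1:2)),
               class = "corealign_hsp_error")
})

test_that("order_hsps output is a sorted permutation of random input", {
  set.seed(301)
  for (rep in 1:5) {
    h <- rand_hsp_instance(50)
    o <- order_hsps(h)
    expect_equal(nrow(o), nrow(h))
    expect_setequal(do.call(paste, as.data.frame(o)[hsp_cols]),
                    do.call(paste, as.data.frame(h)[hsp_cols]))
    key_ok <- order(o$q_start, -o$score, o$q_end, o$s_chrom, o$s_start)
    expect_equal(key_ok, seq_len(nrow(o)))
  }
})

test_that("selection keeps segments 2, 4, 5 and 7 of the worked scenario", {
  sel <- select_hsps(order_hsps(worked_hsps()), chain_params())
  expect_equal(sel$q_start, c(100L, 1400L, 2380L, 4000L))
  expect_equal(sel$score, c(90, 85, 80, 60))
})

test_that("disjoint HSPs are both kept", {
  h <- hsp_table(q_chrom = "q1", q_start = c(0, 500), q_end = c(400, 900),
                 s_chrom = "s1", s_start = c(0, 500), s_end = c(400, 900),
                 strand = "+", score = c(10, 20))
  expect_equal(nrow(select_hsps(order_hsps(h), chain_params())), 2L)
})

oracle_select <- function(ordered, frac) {
  kept <- list()
  for (k in seq_len(nrow(ordered))) {
    x <- ordered[k, , drop = FALSE]
    confl <- which(vapply(kept, function(a) {
      ov <- max(0, min(a$q_end, x$q_end) - max(a$q_start, x$q_start))
      ov > frac * min(a$q_end - a$q_start, x$q_end - x$q_start)
    }, logical(1)))
    if (!length(confl)) {
      kept[[length(kept) + 1L]] <- x
    } else if (x$score > max(vapply(kept[confl], `[[`, numeric(1), "score"))) {
      kept <- c(kept[-confl], list(x))
    }
  }
  out <- do.call(rbind, kept)
  out[order(out$q_start, -out$score, out$q_end, out$s_chrom, out$s_start), ,
      drop = FALSE]
}

test_that("selection equals a literal insertion-rule replay on random instances", {
  set.seed(302)
  params <- chain_params()
  for (rep in 1:100) {
    h <- order_hsps(rand_hsp_instance(sample(2:20, 1)))
    expect_same_hsps(select_hsps(h, params),
                     oracle_select(h, params$overlap_reject_frac))
  }
})

test_that("segments 4 and 5 of the worked scenario merge into one spanning HSP", {
  sel <- select_hsps(order_hsps(worked_hsps()), chain_params())
  m <- merge_hsps(sel, chain_params())
  expect_equal(nrow(m), 3L)
  merged <- m[m$s_chrom == "c2", ]
  expect_equal(merged$q_start, 1400L)
  expect_equal(merged$q_end, 3380L)
  expect_equal(merged$s_start, 5000L)
  expect_equal(merged$s_end, 7100L)
  expect_equal(merged$score, 165)
})

test_that("HSPs on different subject chromosomes never merge", {
  h <- hsp_table(q_chrom = "q1", q_start = c(0, 100), q_end = c(200, 300),
                 s_chrom = c("s1", "s2"), s_start = c(0, 0),
                 s_end = c(200, 200), strand = "+", score = c(50, 52))
  expect_equal(nrow(merge_hsps(h, chain_params())), 2L)
})

test_that("merging a similar-scored chain is input-permutation invariant", {
  set.seed(303)
  base <- hsp_table(q_chrom = "q1",
                    q_start = c(0, 180, 360), q_end = c(200, 380, 560),
                    s_chrom = "s1", s_start = c(0, 180, 360),
                    s_end = c(200, 380, 560), strand = "+",
                    score = c(100, 100, 100))
  ref <- merge_hsps(base, chain_params())
  for (perm in 1:6) {
    shuffled <- base[sample(nrow(base)), ]
    expect_same_hsps(merge_hsps(shuffled, chain_params()), ref)
  }
})

test_that("merged cigars keep interval arithmetic consistent", {
  set.seed(304)
  s <- rand_dna(1200)
  # two overlapping pieces of a real alignment, spliced back together
  h <- hsp_table(q_chrom = "q1", q_start = c(0, 580), q_end = c(600, 1200),
                 s_chrom = "s1", s_start = c(0, 580), s_end = c(600, 1200),
                 strand = "+", score = c(600, 620),
                 cigar = c("600M", "620M"), identity = 1)
  m <- merge_hsps(h, chain_params())
  expect_equal(nrow(m), 1L)
  validate_hsps(m)
  expect_equal(m$q_end - m$q_start, 1200L)
})

test_that("the homoeologous 1A hit is retained over 1B", {
  h <- hsp_table(q_chrom = rep("q1A", 2),
                 q_start = c(5000, 5600), q_end = c(6000, 6600),
                 s_chrom = c("s1A", "s1B"), s_start = c(0, 0),
                 s_end = c(1000, 1000), strand = "+", score = c(70, 68))
  params <- chain_params(use_chromosome_info = TRUE,
                         homology_map = c(q1A = "1A", s1A = "1A", s1B = "1B"))
  r <- resolve_conflicts(h, params)
  expect_equal(nrow(r), 1L)
  expect_equal(r$s_chrom, "s1A")
  # without chromosome info both survive (different chromosomes cannot cross)
  expect_equal(nrow(resolve_conflicts(h, chain_params())), 2L)
  # missing map is a configuration error
  broken <- chain_params()
  broken$use_chromosome_info <- TRUE
  expect_error(resolve_conflicts(h, broken),
               class = "corealign_config_error")
})

test_that("fully collinear input passes conflict resolution unchanged", {
  h <- hsp_table(q_chrom = "q1", q_start = c(0, 300, 600),
                 q_end = c(200, 500, 800), s_chrom = "s1",
                 s_start = c(0, 300, 600), s_end = c(200, 500, 800),
                 strand = "+", score = c(10, 20, 30))
  expect_same_hsps(resolve_conflicts(h, chain_params()), h)
})

test_that("a crossing (translocated) pair loses its lower-scored member", {
  h <- hsp_table(q_chrom = "q1", q_start = c(0, 300), q_end = c(200, 500),
                 s_chrom = "s1", s_start = c(600, 0), s_end = c(800, 200),
                 strand = "+", score = c(90, 40))
  r <- resolve_conflicts(h, chain_params())
  expect_equal(r$score, 90)
  # inverted pairs are consistent when subject order is reversed
  hi <- hsp_table(q_chrom = "q1", q_start = c(0, 300), q_end = c(200, 500),
                  s_chrom = "s1", s_start = c(600, 0), s_end = c(800, 200),
                  strand = "-", score = c(90, 40))
  expect_equal(nrow(resolve_conflicts(hi, chain_params())), 2L)
})

test_that("the length filter is inclusive at the threshold", {
  h <- hsp_table(q_chrom = "q1", q_start = c(0, 1000, 2000),
                 q_end = c(499, 1500, 2501), s_chrom = "s1",
                 s_start = c(0, 1000, 2000), s_end = c(499, 1500, 2501),
                 strand = "+", score = 10)
  f <- filter_min_length(h, chain_params())
  expect_equal(f$q_end - f$q_start, c(500L, 501L))
  expect_equal(nrow(filter_min_length(h, chain_params(min_hsp_len = 0))), 3L)
})

test_that("the composed worked scenario yields segments 2, merged(4,5), 7", {
  res <- chain(worked_hsps(), chain_params())
  expect_equal(nrow(res), 3L)
  expect_equal(res$q_start, c(100L, 1400L, 4000L))
  expect_equal(res$q_end, c(1100L, 3380L, 4600L))
  expect_equal(res$s_chrom, c("c1", "c2", "c3"))
})

test_that("chain is empty on empty input", {
  expect_equal(nrow(chain(hsp_table(), chain_params())), 0L)
})

test_that("chain equals the staged rule-replay oracle on random instances", {
  set.seed(305)
  params <- chain_params(min_hsp_len = 50L)
  for (rep in 1:200) {
    h <- rand_hsp_instance(sample(1:20, 1))
    expect_same_hsps(chain(h, params), oracle_chain(h, params))
  }
})

test_that("chain output is disjoint, sorted and permutation-invariant", {
  set.seed(306)
  params <- chain_params(min_hsp_len = 50L)
  for (rep in 1:20) {
    h <- rand_hsp_instance(sample(5:30, 1))
    out <- chain(h, params)
    if (nrow(out) > 1L) {
      expect_true(all(out$q_start[-1] >= out$q_end[-nrow(out)]))
    }
    expect_true(all(out$q_end - out$q_start >= 50L))
    out2 <- chain(h[sample(nrow(h)), ], params)
    expect_same_hsps(out, out2)
  }
})

test_that("no rejected HSP could profitably replace an accepted one", {
  # local optimality of the insertion rule: swapping any accepted HSP for a
  # rejected one it displaced never increases the accepted score total
  set.seed(307)
  params <- chain_params(min_hsp_len = 0L)
  for (rep in 1:30) {
    h <- order_hsps(rand_hsp_instance(sample(2:10, 1)))
    sel <- select_hsps(h, params)
    acc_key <- do.call(paste, as.data.frame(sel)[hsp_cols])
    all_key <- do.call(paste, as.data.frame(h)[hsp_cols])
    rejected <- h[!(all_key %in% acc_key), , drop = FALSE]
    for (r in seq_len(nrow(rejected))) {
      x <- rejected[r, ]
      confl <- which(pmin(sel$q_end, x$q_end) - pmax(sel$q_start, x$q_start) >
                     params$overlap_reject_frac *
                     pmin(sel$q_end - sel$q_start, x$q_end - x$q_start))
      if (length(confl)) {
        expect_lte(x$score, max(sel$score[confl]))
      }
    }
  }
})
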