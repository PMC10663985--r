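# Gap projection and the backtracking reconstruction of the core alignment.

test_that("project_gaps appends a gap-free pair unchanged", {
  out <- project_gaps(c("ACGT", "ACGA"), c("ACGT", "TCGT"))
  expect_equal(out, c("ACGT", "ACGA", "TCGT"))
})

test_that("project_gaps merges disjoint gap slots", {
  out <- project_gaps(c("AC-GT", "ACTGT"), c("ACG-T", "ACGAT"))
  expect_equal(nchar(out[1]), 6L)
  expect_equal(out[1], "AC-G-T")
  expect_equal(out[2], "ACTG-T")
  expect_equal(out[3], "AC-GAT")
})

test_that("project_gaps matches the streaming column-merge oracle", {
  set.seed(501)
  ref <- strsplit(rand_dna(50), "")[[1]]
  for (rep in 1:50) {
    refA <- rand_gapped(ref)
    refB <- rand_gapped(ref)
    rowA <- rand_row_for(refA)
    rowB <- rand_row_for(refB)
    got <- project_gaps(c(refA, rowA), c(refB, rowB))
    want <- oracle_project_gaps(c(refA, rowA), c(refB, rowB))
    expect_equal(got, want)
    # ungapping is preserved
    expect_equal(gsub("-", "", got[2]), gsub("-", "", rowA))
    expect_equal(gsub("-", "", got[3]), gsub("-", "", rowB))
    # column conservation: width = ref length + slot-wise union of gaps
    gA <- corealign:::slot_gaps(charToRaw(refA))
    gB <- corealign:::slot_gaps(charToRaw(refB))
    expect_equal(nchar(got[1]), length(ref) + sum(pmax(gA, gB)))
  }
})

test_that("threading order does not change the merged column set", {
  set.seed(502)
  ref <- strsplit(rand_dna(40), "")[[1]]
  for (rep in 1:10) {
    layouts <- replicate(3, rand_gapped(ref))
    rows <- vapply(layouts, rand_row_for, character(1))
    thread <- function(ord) {
      prof <- c(layouts[ord[1]], rows[ord[1]])
      for (k in ord[-1]) prof <- project_gaps(prof, c(layouts[k], rows[k]))
      prof[1]  # merged reference layout
    }
    ref123 <- thread(1:3)
    expect_equal(thread(c(2, 3, 1)), ref123)
    expect_equal(thread(c(3, 1, 2)), ref123)
  }
})

test_that("project_gaps rejects disagreeing references", {
  expect_error(project_gaps(c("ACGT", "ACGT"), c("ACCT", "ACGT")),
               class = "corealign_backtrack_error")
})

check_roundtrip <- function(core, genomes) {
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  for (b in core$blocks) {
    for (i in seq_len(nrow(b$rows))) {
      r <- b$rows[i, ]
      expected <- substring(genomes[[r$genome_id]]$sequences[[r$chrom]],
                            r$start + 1L, r$end)
      if (r$strand == "-") expected <- revcomp(expected)
      expect_identical(gsub("-", "", r$text, fixed = TRUE), expected)
    }
  }
  invisible(TRUE)
}

test_that("two genomes backtrack to the chained pairwise alignment", {
  set.seed(503)
  s <- rand_dna(20000)
  s2 <- mutate_seq(s, 0.01)
  g <- list(genome_record("a", c(c1 = s)), genome_record("b", c(c1 = s2)))
  run <- run_progressive(g, chain_params())
  core <- backtrack_msa(run, g)
  expect_equal(length(core$blocks), nrow(run$iterations[[1]]$hsps))
  expect_equal(core$genome_order, c("a", "b"))
  check_roundtrip(core, g)
})

test_that("identical genomes give gap-free identical rows over the genome", {
  set.seed(504)
  s <- rand_dna(10000)
  g <- lapply(c("a", "b", "c"), function(id) genome_record(id, c(c1 = s)))
  core <- backtrack_msa(run_progressive(g, chain_params()), g)
  expect_equal(length(core$blocks), 1L)
  b <- core$blocks[[1]]
  expect_equal(nrow(b$rows), 3L)
  expect_false(any(grepl("-", b$rows$text, fixed = TRUE)))
  expect_equal(unique(b$rows$text), s)
  expect_equal(sum(vapply(core$blocks, `[[`, numeric(1), "width")), 10000)
})

test_that("simulated populations round-trip every row of every block", {
  sim <- simulate_population(sim_config(ancestor_length = 60000,
                                        n_genomes = 5, seed = 505))
  res <- core_align(sim$genomes)
  core <- res$core
  # one row per genome, equal widths, no all-gap columns
  for (b in core$blocks) {
    expect_equal(sort(b$rows$genome_id), sort(core$genome_order))
    expect_true(all(nchar(b$rows$text) == b$width))
    mat <- do.call(rbind, lapply(b$rows$text, function(x)
      strsplit(x, "")[[1]]))
    expect_false(any(apply(mat == "-", 2, all)))
  }
  check_roundtrip(core, sim$genomes)
  # per genome, block source intervals are (essentially) non-overlapping:
  # the reference genome is disjoint by construction; subject rows may share
  # a handful of junction bases where trimmed query overlaps met
  for (g in core$genome_order) {
    total_ovl <- 0
    total_len <- 0
    for (ch in unique(unlist(lapply(core$blocks, function(b)
      b$rows$chrom[b$rows$genome_id == g])))) {
      iv <- do.call(rbind, lapply(core$blocks, function(b) {
        b$rows[b$rows$genome_id == g & b$rows$chrom == ch, c("start", "end")]
      }))
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1L) {
        ovl <- pmax(0, iv$end[-nrow(iv)] - iv$start[-1])
        if (g == core$genome_order[1]) expect_true(all(ovl == 0))
        total_ovl <- total_ovl + sum(ovl)
      }
      total_len <- total_len + sum(iv$end - iv$start)
    }
    expect_lte(total_ovl, 0.001 * total_len)
  }
})

test_that("inversions survive the pipeline and round-trip", {
  sim <- simulate_population(sim_config(ancestor_length = 40000,
                                        n_chromosomes = 1, n_genomes = 3,
                                        n_inversions = 1, n_accessory = 1,
                                        seed = 506))
  res <- core_align(sim$genomes)
  strands <- unlist(lapply(res$core$blocks, function(b) b$rows$strand))
  expect_true(any(strands == "-"))
  check_roundtrip(res$core, sim$genomes)
})

test_that("MAF conversion round-trips a computed core alignment", {
  sim <- simulate_population(sim_config(ancestor_length = 30000,
                                        n_genomes = 3, seed = 507))
  core <- core_align(sim$genomes)$core
  maf <- core_to_maf(core)
  expect_equal(length(maf), length(core$blocks))
  back <- maf_to_core(maf)
  expect_equal(back$genome_order, core$genome_order)
  for (i in seq_along(core$blocks)) {
    expect_equal(back$blocks[[i]]$rows, core$blocks[[i]]$rows)
  }
  expect_identical(maf_to_core(list())$blocks, list())
  expect_identical(core_to_maf(structure(list(blocks = list(),
                                              genome_order = character(0)),
                                         class = "core_alignment")), list())
})
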