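# FASTA/PAF/MAF readers and writers, and the MAF core-extraction utility.

test_that("read_fasta uppercases, counts ambiguity and preserves order", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c2", "NNAC"), tf)
  g <- read_fasta(tf, genome_id = "g1")
  expect_equal(g$total_length, 8)
  expect_equal(g$ambiguous_count, 2)
  expect_equal(names(g$sequences), c("c1", "c2"))

  writeLines(c(">c1", "acgt"), tf)
  expect_equal(unname(read_fasta(tf, "g1")$sequences[["c1"]]), "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), tf)
  expect_error(read_fasta(tf, "g1"), class = "corealign_format_error")
  writeLines(character(0), tf)
  expect_error(read_fasta(tf, "g1"), class = "corealign_format_error")
})

test_that("FASTA write/read round-trips random genomes", {
  set.seed(101)
  tf <- withr::local_tempfile(fileext = ".fa")
  for (rep in 1:3) {
    n <- sample(2:20, 1)
    seqs <- stats::setNames(
      vapply(seq_len(n), function(i) rand_dna(sample(10:300, 1)), character(1)),
      paste0("ctg", seq_len(n)))
    g <- genome_record("g1", seqs)
    write_fasta(g, tf)
    g2 <- read_fasta(tf, "g1")
    expect_identical(g2$sequences, g$sequences)
    expect_identical(g2$total_length, g$total_length)
  }
})

test_that("read_paf maps the 12 mandatory columns and tags", {
  tf <- withr::local_tempfile(fileext = ".paf")
  writeLines("q\t100\t10\t20\t+\ts\t200\t50\t60\t10\t10\t60\tcg:Z:10M", tf)
  h <- read_paf(tf)
  expect_equal(nrow(h), 1L)
  expect_equal(h$q_start, 10L)
  expect_equal(h$q_end, 20L)
  expect_equal(h$s_start, 50L)
  expect_equal(h$s_end, 60L)
  expect_equal(h$strand, "+")
  expect_equal(h$score, 10)
  expect_equal(h$cigar, "10M")
  expect_true(h$has_cigar)
})

test_that("read_paf checks cigar arithmetic against the intervals", {
  tf <- withr::local_tempfile(fileext = ".paf")
  # 5M2I3M consumes 10 query / 8 subject bases: consistent, accepted
  writeLines("q\t100\t10\t20\t+\ts\t200\t50\t58\t8\t10\t60\tcg:Z:5M2I3M", tf)
  expect_silent(h <- read_paf(tf))
  expect_equal(nrow(h), 1L)
  # 5M cannot span 10 query bases: dropped with a warning, strict aborts
  writeLines("q\t100\t10\t20\t+\ts\t200\t50\t55\t5\t5\t60\tcg:Z:5M", tf)
  expect_warning(h <- read_paf(tf), class = "corealign_format_warning")
  expect_equal(nrow(h), 0L)
  expect_error(read_paf(tf, strict = TRUE), class = "corealign_format_error")
  # malformed column count
  writeLines("q\t100\t10", tf)
  expect_warning(h <- read_paf(tf), class = "corealign_format_warning")
  expect_equal(nrow(h), 0L)
})

test_that("PAF write/read round-trips HSP tables", {
  set.seed(102)
  tf <- withr::local_tempfile(fileext = ".paf")
  n <- 30L
  lens <- sample(20:100, n, replace = TRUE)
  h <- hsp_table(
    q_chrom = sample(c("q1", "q2"), n, TRUE),
    q_start = sample(0:1000, n), q_end = NA,
    s_chrom = sample(c("s1", "s2"), n, TRUE),
    s_start = sample(0:1000, n), s_end = NA,
    strand = sample(c("+", "-"), n, TRUE),
    score = sample(10:500, n),
    cigar = paste0(lens, "M"), identity = 1
  )
  h$q_end <- h$q_start + lens
  h$s_end <- h$s_start + lens
  write_paf(h, tf)
  h2 <- read_paf(tf)
  expect_equal(h2$q_start, h$q_start)
  expect_equal(h2$q_end, h$q_end)
  expect_equal(h2$s_start, h$s_start)
  expect_equal(h2$s_end, h$s_end)
  expect_equal(h2$strand, h$strand)
  expect_equal(h2$score, h$score)
  expect_equal(h2$cigar, h$cigar)
})

rand_maf_block <- function(n_genomes = 4L, force_genomes = NULL) {
  width <- sample(5:40, 1)
  gs <- force_genomes %||% paste0("g", sample(4, sample(2:4, 1)))
  rows <- do.call(rbind, lapply(gs, function(g) {
    txt <- paste(sample(c("A", "C", "G", "T", "-"), width, TRUE,
                        prob = c(rep(0.23, 4), 0.08)), collapse = "")
    size <- nchar(gsub("-", "", txt, fixed = TRUE))
    start <- sample(0:500, 1)
    data.frame(src = paste0(g, ".chr1"), start = start, size = size,
               strand = sample(c("+", "-"), 1),
               src_size = start + size + sample(0:100, 1), text = txt,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[rows$size > 0, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  maf_block(rows, score = sample(c(NA_real_, as.numeric(sample(100, 1))), 1))
}

test_that("MAF writer emits the minimal dialect and round-trips", {
  tf <- withr::local_tempfile(fileext = ".maf")
  write_maf(list(), tf)
  lines <- readLines(tf)
  expect_true(startsWith(lines[1], "##maf version=1"))
  expect_false(any(startsWith(lines, "a")))

  b <- maf_block(data.frame(
    src = c("g1.c1", "g2.c1"), start = c(0L, 5L), size = c(4L, 4L),
    strand = c("+", "-"), src_size = c(10L, 20L),
    text = c("AC-GT", "AGGT-"), stringsAsFactors = FALSE))
  write_maf(list(b), tf)
  lines <- readLines(tf)
  expect_equal(sum(startsWith(lines, "a")), 1L)
  expect_equal(sum(startsWith(lines, "s")), 2L)

  set.seed(103)
  blocks <- Filter(Negate(is.null), replicate(20, rand_maf_block(),
                                              simplify = FALSE))
  write_maf(blocks, tf)
  expect_identical(read_maf(tf), blocks)
})

test_that("maf_block rejects invariant violations before writing", {
  expect_error(maf_block(data.frame(
    src = c("g1.c1", "g2.c1"), start = 0L, size = 4L, strand = "+",
    src_size = 10L, text = c("ACGT", "ACG"), stringsAsFactors = FALSE)),
    class = "corealign_maf_error")
  expect_error(maf_block(data.frame(
    src = "g1.c1", start = 0L, size = 3L, strand = "+", src_size = 10L,
    text = "ACGT", stringsAsFactors = FALSE)),
    class = "corealign_maf_error")
})

test_that("extract_core_from_maf keeps exactly the all-genome blocks", {
  b_all <- maf_block(data.frame(
    src = c("A.c", "B.c", "C.c"), start = 0L, size = 4L, strand = "+",
    src_size = 10L, text = "ACGT", stringsAsFactors = FALSE))
  b_two <- maf_block(data.frame(
    src = c("A.c", "B.c"), start = 0L, size = 4L, strand = "+",
    src_size = 10L, text = "ACGT", stringsAsFactors = FALSE))
  expect_identical(extract_core_from_maf(list(b_all, b_two), c("A", "B", "C")),
                   list(b_all))
  expect_identical(extract_core_from_maf(list(b_two), c("A", "B", "C")), list())
  expect_error(extract_core_from_maf(list(b_all), character(0)),
               class = "corealign_format_error")

  # brute force over random blocks: set cover + length threshold
  set.seed(104)
  blocks <- Filter(Negate(is.null), replicate(100, rand_maf_block(),
                                              simplify = FALSE))
  genomes <- c("g1", "g2", "g3", "g4")
  min_len <- 15L
  got <- extract_core_from_maf(blocks, genomes, min_len)
  manual <- blocks[vapply(blocks, function(b) {
    present <- sub("\\..*", "", b$rows$src)
    all(genomes %in% present) && nchar(b$rows$text[1]) >= min_len
  }, logical(1))]
  expect_identical(got, manual)
  # output is a subset of input
  expect_true(all(got %in% blocks))
})

test_that("write_mfa concatenates per-genome rows across blocks", {
  mk_block <- function(w, start) {
    rows <- data.frame(
      genome_id = c("A", "B", "C"), chrom = "c1",
      start = start, end = start + w, strand = "+", src_size = 100L,
      text = vapply(1:3, function(i) rand_dna(w), character(1)),
      stringsAsFactors = FALSE)
    list(width = w, rows = rows)
  }
  set.seed(105)
  core <- structure(list(blocks = list(mk_block(10L, 0L), mk_block(5L, 50L)),
                         genome_order = c("A", "B", "C")),
                    class = "core_alignment")
  tf <- withr::local_tempfile(fileext = ".mfa")
  write_mfa(core, tf)
  recs <- read_fasta(tf, "mfa")
  expect_equal(length(recs$sequences), 3L)
  expect_true(all(nchar(recs$sequences) == 15L))
  expect_equal(unname(recs$sequences[["A"]]),
               paste0(core$blocks[[1]]$rows$text[1], core$blocks[[2]]$rows$text[1]))

  single <- structure(list(blocks = core$blocks[1],
                           genome_order = c("A", "B", "C")),
                      class = "core_alignment")
  write_mfa(single, tf)
  recs <- read_fasta(tf, "mfa")
  expect_equal(unname(recs$sequences[["B"]]), core$blocks[[1]]$rows$text[2])
})
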