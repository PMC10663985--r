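# Synthetic genome populations with known core/accessory structure. All
# genomes descend from one random ancestor; per genome, structural events
# (inversions, translocations, accessory insertions) are applied first, then
# small indels, then SNPs, with ancestor coordinates tracked per base so the
# true core (ancestor sequence not deleted in any genome) is known exactly.

#' Simulation configuration
#'
#' Defaults emulate a small population of closely related haploid genomes:
#' 1% substitution divergence, 0.1% indels, and a couple of multi-kilobase
#' accessory insertions per genome.
#'
#' @param ancestor_length total ancestor length in bases.
#' @param n_chromosomes number of chromosomes (ancestor length split evenly).
#' @param n_genomes number of descendant genomes.
#' @param snp_rate per-base substitution probability.
#' @param indel_rate per-base indel initiation probability (split evenly
#'   between insertions and deletions).
#' @param indel_max maximum indel length (lengths are geometric, capped).
#' @param indel_geom_p success parameter of the geometric length distribution.
#' @param n_inversions,inversion_len inversions per genome and their length
#'   range.
#' @param n_translocations,transloc_len intra-chromosomal translocations per
#'   genome and their length range.
#' @param n_accessory,accessory_len accessory (novel, GC-matched) insertions
#'   per genome and their length range.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(ancestor_length = 1e5, n_chromosomes = 2L,
                       n_genomes = 5L, snp_rate = 0.01, indel_rate = 0.001,
                       indel_max = 50L, indel_geom_p = 0.5,
                       n_inversions = 0L, inversion_len = c(1000L, 5000L),
                       n_translocations = 0L, transloc_len = c(1000L, 5000L),
                       n_accessory = 2L, accessory_len = c(2000L, 5000L),
                       seed = 1L) {
  if (any(c(snp_rate, indel_rate) < 0) || any(c(snp_rate, indel_rate) > 1)) {
    stop_corealign("rates must be in [0, 1]", "corealign_config_error")
  }
  if (ancestor_length < n_chromosomes || ancestor_length <= 0) {
    stop_corealign("ancestor_length must be positive and >= n_chromosomes",
                   "corealign_config_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

rand_seq <- function(n, gc = 0.5) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# sample `n` non-overlapping intervals of lengths in `len_range` on [0, L)
sample_intervals <- function(n, len_range, L, occupied) {
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:200) {
      w <- sample(len_range[1]:len_range[2], 1L)
      if (L - w <= 0) next
      s <- sample(0:(L - w), 1L)
      if (!any(occupied[(s + 1L):(s + w)])) {
        occupied[(s + 1L):(s + w)] <- TRUE
        out <- rbind(out, data.frame(start = s, end = s + w))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop_corealign("requested structural events exceed available sequence",
                     "corealign_config_error")
    }
  }
  list(intervals = out, occupied = occupied)
}

# splice `values` (list of parallel vectors) inserting `ins` (same structure)
# before 0-based position `at`
splice_in <- function(state, at, ins) {
  for (f in names(ins)) {
    v <- state[[f]]
    state[[f]] <- append(v, ins[[f]], after = at)
  }
  state
}

drop_positions <- function(state, mask) {
  for (f in names(state)) state[[f]] <- state[[f]][!mask]
  state
}

#' Simulate a genome population descended from one ancestor
#'
#' Events are applied per genome in the order: inversions, translocations,
#' accessory insertions, deletions, insertions, SNPs, with ancestor
#' coordinates tracked throughout. The true core is the ancestor sequence
#' deleted in no genome; every novel (inserted) base is accessory.
#'
#' @param cfg a [sim_config()].
#' @return list with `genomes` (list of [genome_record()]), `truth` (class
#'   `sim_truth`: per-genome 0-based half-open interval tables `core`,
#'   `accessory`, `inverted`, `translocated`, plus `genome_lengths` and the
#'   ancestor sequences), and `config`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom_len <- rep(floor(cfg$ancestor_length / cfg$n_chromosomes),
                   cfg$n_chromosomes)
  chrom_len[1] <- chrom_len[1] + cfg$ancestor_length -
    sum(chrom_len)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  ancestor <- stats::setNames(lapply(chrom_len, rand_seq), chroms)
  gc <- mean(unlist(ancestor) %in% c("G", "C"))

  genome_ids <- paste0("g", seq_len(cfg$n_genomes))
  states <- list()      # states[[genome]][[chrom]]: chars, apos, inv, trn
  deleted <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) deleted[[ch]] <- integer(0)

  for (g in genome_ids) {
    per_chrom <- list()
    for (ch in chroms) {
      L <- length(ancestor[[ch]])
      st <- list(chars = ancestor[[ch]], apos = 0:(L - 1L),
                 inv = rep(FALSE, L), trn = rep(FALSE, L))
      # inversions and translocations share an occupancy mask so they never
      # overlap each other
      occupied <- rep(FALSE, L)
      if (cfg$n_inversions > 0L) {
        si <- sample_intervals(cfg$n_inversions, cfg$inversion_len, L, occupied)
        occupied <- si$occupied
        for (r in seq_len(nrow(si$intervals))) {
          idx <- (si$intervals$start[r] + 1L):si$intervals$end[r]
          st$chars[idx] <- rev(unname(COMP[st$chars[idx]]))
          st$apos[idx] <- rev(st$apos[idx])
          st$inv[idx] <- TRUE
        }
      }
      if (cfg$n_translocations > 0L) {
        si <- sample_intervals(cfg$n_translocations, cfg$transloc_len, L,
                               occupied)
        for (r in seq_len(nrow(si$intervals))) {
          idx <- (si$intervals$start[r] + 1L):si$intervals$end[r]
          moved <- lapply(st, `[`, idx)
          moved$trn <- rep(TRUE, length(idx))
          st <- drop_positions(st, seq_along(st$chars) %in% idx)
          at <- sample(0:length(st$chars), 1L)
          st <- splice_in(st, at, moved)
        }
      }
      if (cfg$n_accessory > 0L) {
        for (r in seq_len(cfg$n_accessory)) {
          w <- sample(cfg$accessory_len[1]:cfg$accessory_len[2], 1L)
          at <- sample(0:length(st$chars), 1L)
          st <- splice_in(st, at, list(chars = rand_seq(w, gc),
                                       apos = rep(NA_integer_, w),
                                       inv = rep(FALSE, w),
                                       trn = rep(FALSE, w)))
        }
      }
      # deletions
      if (cfg$indel_rate > 0) {
        n <- length(st$chars)
        starts <- which(stats::runif(n) < cfg$indel_rate / 2)
        if (length(starts)) {
          lens <- pmin(stats::rgeom(length(starts), cfg$indel_geom_p) + 1L,
                       cfg$indel_max)
          mask <- rep(FALSE, n)
          for (r in seq_along(starts)) {
            mask[starts[r]:min(n, starts[r] + lens[r] - 1L)] <- TRUE
          }
          deleted[[ch]] <- union(deleted[[ch]], st$apos[mask & !is.na(st$apos)])
          st <- drop_positions(st, mask)
        }
        # insertions
        n <- length(st$chars)
        at <- which(stats::runif(n) < cfg$indel_rate / 2)
        if (length(at)) {
          lens <- pmin(stats::rgeom(length(at), cfg$indel_geom_p) + 1L,
                       cfg$indel_max)
          for (r in rev(seq_along(at))) {
            st <- splice_in(st, at[r], list(
              chars = rand_seq(lens[r], gc),
              apos = rep(NA_integer_, lens[r]),
              inv = rep(FALSE, lens[r]), trn = rep(FALSE, lens[r])))
          }
        }
      }
      # SNPs on ancestor-derived bases
      if (cfg$snp_rate > 0) {
        n <- length(st$chars)
        idx <- which(!is.na(st$apos) & stats::runif(n) < cfg$snp_rate)
        if (length(idx)) {
          st$chars[idx] <- vapply(st$chars[idx], function(b) {
            sample(setdiff(BASES, b), 1L)
          }, character(1))
        }
      }
      per_chrom[[ch]] <- st
    }
    states[[g]] <- per_chrom
  }

  # truth: core = ancestor positions deleted in no genome
  core_anc <- lapply(chroms, function(ch) {
    ok <- rep(TRUE, length(ancestor[[ch]]))
    ok[deleted[[ch]] + 1L] <- FALSE
    ok
  })
  names(core_anc) <- chroms

  genomes <- list()
  truth <- list(core = list(), accessory = list(), inverted = list(),
                translocated = list(), genome_lengths = list())
  for (g in genome_ids) {
    seqs <- character(0)
    truth$core[[g]] <- list()
    truth$accessory[[g]] <- list()
    truth$inverted[[g]] <- list()
    truth$translocated[[g]] <- list()
    for (ch in chroms) {
      st <- states[[g]][[ch]]
      seqs[[ch]] <- paste(st$chars, collapse = "")
      is_core <- !is.na(st$apos) & core_anc[[ch]][st$apos + 1L]
      is_core[is.na(is_core)] <- FALSE
      truth$core[[g]][[ch]] <- logical_runs(is_core)
      truth$accessory[[g]][[ch]] <- logical_runs(is.na(st$apos))
      truth$inverted[[g]][[ch]] <- logical_runs(st$inv)
      truth$translocated[[g]][[ch]] <- logical_runs(st$trn)
    }
    truth$genome_lengths[[g]] <- nchar(seqs)
    genomes[[g]] <- genome_record(g, seqs)
  }
  truth$ancestor <- vapply(ancestor, paste, character(1), collapse = "")
  class(truth) <- "sim_truth"
  list(genomes = unname(genomes), truth = truth, config = cfg)
}

#' Simulate genomes down a known bifurcating topology
#'
#' Sequences evolve from a random ancestor along the branches of `tree` by
#' substitutions only (each edge substitutes each site with probability equal
#' to its branch length, drawing a different base uniformly), so the
#' generating topology is the ground truth for phylogeny recovery.
#'
#' @param tree a `phylo` object or Newick string with branch lengths in
#'   expected substitutions per site.
#' @param ancestor_length,n_chromosomes ancestor dimensions.
#' @param seed integer seed.
#' @return list with `genomes` (one [genome_record()] per tip, ids = tip
#'   labels) and `tree` (the generating `phylo`).
#' @export
simulate_tree_population <- function(tree, ancestor_length = 5e4,
                                     n_chromosomes = 1L, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  chrom_len <- rep(floor(ancestor_length / n_chromosomes), n_chromosomes)
  chrom_len[1] <- chrom_len[1] + ancestor_length - sum(chrom_len)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  root_seq <- lapply(chrom_len, rand_seq)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_seqs <- list()
  node_seqs[[root]] <- root_seq
  # preorder edge walk
  ord <- ape::reorder.phylo(tree, "cladewise")
  mutate <- function(sq, p) {
    lapply(sq, function(v) {
      idx <- which(stats::runif(length(v)) < p)
      if (length(idx)) {
        v[idx] <- vapply(v[idx], function(b) sample(setdiff(BASES, b), 1L),
                         character(1))
      }
      v
    })
  }
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    node_seqs[[child]] <- mutate(node_seqs[[parent]], ord$edge.length[e])
  }
  genomes <- lapply(seq_len(ntip), function(i) {
    seqs <- stats::setNames(
      vapply(node_seqs[[i]], paste, character(1), collapse = ""), chroms)
    genome_record(tree$tip.label[i], seqs)
  })
  list(genomes = genomes, tree = tree)
}

#' Score core recovery against simulation truth
#'
#' Sensitivity is the fraction of true-core bases present in the core
#' alignment; precision is the fraction of core-alignment bases that lie
#' inside the true core. Both are computed by interval intersection per
#' genome and averaged. An empty core alignment scores sensitivity 0 and
#' precision 1 (zero denominator, flagged in the result).
#'
#' @param core a `core_alignment` over simulated genomes.
#' @param truth the `sim_truth` from [simulate_population()].
#' @return list with `sensitivity`, `precision`, and `per_genome`
#'   (data.frame); attribute `zero_denominator` is TRUE for an empty core.
#' @export
score_core_recovery <- function(core, truth) {
  stopifnot(inherits(core, "core_alignment"), inherits(truth, "sim_truth"))
  if (length(core$blocks) == 0L) {
    res <- list(sensitivity = 0, precision = 1,
                per_genome = data.frame(genome_id = character(0),
                                        sensitivity = numeric(0),
                                        precision = numeric(0)))
    attr(res, "zero_denominator") <- TRUE
    return(res)
  }
  unknown <- setdiff(core$genome_order, names(truth$core))
  if (length(unknown)) {
    stop_corealign(sprintf("genome '%s' not present in truth", unknown[1]),
                   "corealign_config_error")
  }
  per <- lapply(core$genome_order, function(g) {
    sens_num <- sens_den <- prec_num <- prec_den <- 0
    for (ch in names(truth$genome_lengths[[g]])) {
      rows <- do.call(rbind, lapply(core$blocks, function(b) {
        r <- b$rows[b$rows$genome_id == g & b$rows$chrom == ch, ,
                    drop = FALSE]
        r[, c("start", "end")]
      }))
      aligned <- if (is.null(rows) || nrow(rows) == 0L) {
        IRanges::IRanges()
      } else {
        IRanges::reduce(IRanges::IRanges(start = rows$start + 1L,
                                         end = rows$end))
      }
      tc <- truth$core[[g]][[ch]]
      true_core <- if (nrow(tc) == 0L) IRanges::IRanges() else
        IRanges::reduce(IRanges::IRanges(start = tc$start + 1L, end = tc$end))
      inter <- IRanges::intersect(aligned, true_core)
      sens_num <- sens_num + sum(IRanges::width(inter))
      sens_den <- sens_den + sum(IRanges::width(true_core))
      prec_num <- prec_num + sum(IRanges::width(inter))
      prec_den <- prec_den + sum(IRanges::width(aligned))
    }
    data.frame(genome_id = g,
               sensitivity = if (sens_den > 0) sens_num / sens_den else NA_real_,
               precision = if (prec_den > 0) prec_num / prec_den else NA_real_)
  })
  per <- do.call(rbind, per)
  list(sensitivity = mean(per$sensitivity, na.rm = TRUE),
       precision = mean(per$precision, na.rm = TRUE),
       per_genome = per)
}
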