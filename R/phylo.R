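# Downstream of the core alignment: summary statistics, Jukes-Cantor
# distances pooled over blocks, a neighbor-joining tree, and Robinson-Foulds
# comparison for validation against a known topology.

#' Core-genome summary statistics
#'
#' Lengths are measured on the ungapped reference (first-genome) row of each
#' block. N50 is the length L such that blocks of length >= L sum to at
#' least half of the total core length.
#'
#' @param core a `core_alignment`.
#' @return list with `fragment_number`, `core_length`, `max_length` and
#'   `n50` (all in bases; an empty core gives all zeros).
#' @export
core_stats <- function(core) {
  stopifnot(inherits(core, "core_alignment"))
  if (length(core$blocks) == 0L) {
    return(list(fragment_number = 0L, core_length = 0, max_length = 0, n50 = 0))
  }
  lens <- vapply(core$blocks, function(b) {
    as.numeric(b$rows$end[1] - b$rows$start[1])
  }, numeric(1))
  total <- sum(lens)
  sl <- sort(lens, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= total / 2)[1]]
  list(fragment_number = length(lens), core_length = total,
       max_length = max(lens), n50 = n50)
}

#' Jukes-Cantor distance matrix from a core alignment
#'
#' For each genome pair, the difference proportion p is computed over all
#' alignment columns where both rows carry an unambiguous base (A/C/G/T),
#' pooled across blocks ("pairwise deletion"; `deletion = "complete"`
#' restricts to columns unambiguous in every row). The JC69 transform
#' d = -(3/4) ln(1 - (4/3) p) is then applied. Pairs with p >= 3/4 are
#' flagged infinite with a warning.
#'
#' @param core a `core_alignment` with >= 2 genomes.
#' @param deletion `"pairwise"` (default) or `"complete"` site filtering.
#' @return object of class `jc_dist`: list with `genome_ids`, `p` (raw
#'   difference proportions) and `d` (JC69 distances), both symmetric
#'   matrices with zero diagonals.
#' @export
jc_distance <- function(core, deletion = c("pairwise", "complete")) {
  stopifnot(inherits(core, "core_alignment"))
  deletion <- match.arg(deletion)
  ids <- core$genome_order
  if (length(ids) < 2L) {
    stop_corealign("need at least two genomes for distances",
                   "corealign_phylo_error")
  }
  ng <- length(ids)
  diff_ct <- matrix(0, ng, ng, dimnames = list(ids, ids))
  site_ct <- matrix(0, ng, ng, dimnames = list(ids, ids))
  acgt <- charToRaw("ACGT")
  for (b in core$blocks) {
    o <- match(ids, b$rows$genome_id)
    mat <- do.call(rbind, lapply(b$rows$text[o], charToRaw))
    ok <- matrix(mat %in% acgt, nrow = ng)
    keep_all <- if (deletion == "complete") {
      apply(ok, 2L, all)
    } else rep(TRUE, ncol(ok))
    for (a in seq_len(ng - 1L)) {
      for (z in (a + 1L):ng) {
        valid <- ok[a, ] & ok[z, ] & keep_all
        n <- sum(valid)
        diff_ct[a, z] <- diff_ct[a, z] + sum(mat[a, valid] != mat[z, valid])
        site_ct[a, z] <- site_ct[a, z] + n
      }
    }
  }
  diff_ct <- diff_ct + t(diff_ct)
  site_ct <- site_ct + t(site_ct)
  p <- diff_ct / pmax(site_ct, 1)
  p[site_ct == 0] <- NA_real_
  d <- matrix(NA_real_, ng, ng, dimnames = list(ids, ids))
  saturated <- !is.na(p) & p >= 0.75
  ok_p <- !is.na(p) & p < 0.75
  d[ok_p] <- -0.75 * log(1 - (4 / 3) * p[ok_p])
  if (any(saturated)) {
    d[saturated] <- Inf
    warn_corealign("some pairs have p >= 3/4: JC distance undefined, flagged Inf",
                   "corealign_saturation_warning")
  }
  diag(p) <- 0
  diag(d) <- 0
  structure(list(genome_ids = ids, p = p, d = d), class = "jc_dist")
}

#' @export
print.jc_dist <- function(x, ...) {
  cat("<jc_dist> JC69 distances for", length(x$genome_ids), "genomes\n")
  print(round(x$d, 5))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch so path lengths are approximately preserved.
#'
#' @param dm a `jc_dist` object, `dist`, or symmetric numeric matrix with
#'   >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "jc_dist")) dm$d else as.matrix(dm)
  if (any(!is.finite(d))) {
    stop_corealign(paste0(
      "distance matrix contains non-finite entries (saturated pairs); ",
      "remove the affected genomes"), "corealign_phylo_error")
  }
  if (nrow(d) < 3L) {
    stop_corealign("need at least three genomes for a tree", "corealign_phylo_error")
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sisters)) {
      tree$edge.length[sisters[1]] <- tree$edge.length[sisters[1]] + deficit
    }
  }
  tree
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The count of non-trivial bipartitions present in exactly one of the two
#' trees, halved (the standard unrooted RF convention: identical trees give
#' 0, maximally different binary trees give n - 3).
#'
#' @param a,b `phylo` trees over the same leaf set.
#' @return a non-negative count (integer-valued numeric).
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) {
    stop_corealign("trees have different leaf sets", "corealign_phylo_error")
  }
  phangorn::RF.dist(a, b, check.labels = TRUE) / 2
}
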