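# One-call pipeline: progressive alignment, backtracking, and output files.

#' Align the core genome of a set of assemblies
#'
#' Runs the full pipeline: initial-query selection, progressive pairwise
#' alignment and chaining across all subjects, and backtracking to the
#' multi-genome core alignment. Optionally writes `core.maf` and `core.mfa`
#' to `outdir`.
#'
#' @param genomes list of [genome_record()] objects, or a character vector of
#'   FASTA paths.
#' @param params a [chain_params()].
#' @param mode a [sensitivity_mode()].
#' @param backend `"internal"` or `"external"` (see [align_pair()]).
#' @param outdir optional output directory for `core.maf`/`core.mfa`.
#' @param ... further arguments passed to [run_progressive()].
#' @return list with `core` (a `core_alignment`), `run` (the
#'   `progressive_run`), and `stats` ([core_stats()] of the core).
#' @export
core_align <- function(genomes, params = chain_params(),
                       mode = sensitivity_mode("low_divergence"),
                       backend = "internal", outdir = NULL, ...) {
  if (is.character(genomes)) {
    genomes <- lapply(genomes, read_fasta)
  }
  run <- run_progressive(genomes, params = params, mode = mode,
                         backend = backend, ...)
  core <- backtrack_msa(run, genomes, min_block_len = params$min_hsp_len)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_maf(core_to_maf(core), file.path(outdir, "core.maf"))
    write_mfa(core, file.path(outdir, "core.mfa"))
  }
  list(core = core, run = run, stats = core_stats(core))
}
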