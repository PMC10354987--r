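#' Pipeline configuration
#'
#' All user-settable thresholds of the pipeline in one object. Defaults
#' mirror the published tool's command-line flags: the read-length NUMT
#' cutoff (`max_read_len`, defaulting to the reference length and applied
#' strictly greater-than), the contig/reference coverage threshold
#' `p_coverage` (flag `-p`, percent, default 50), the minimum terminal
#' overlap for circularity `circular_size` (default 220 bp, strict
#' greater-than), the NCBI genetic-code table (flag `-o`), the taxon mode
#' (flag `-a`; `"plant"` disables the large-contig filter), the mapping
#' quality floor for coverage tables (flag `-covMap`), and the built-in
#' assembler/aligner thresholds.
#'
#' @param max_read_len Reads longer than this are excluded as NUMT-derived;
#'   `NULL` means "use the reference length" (resolved when the pipeline
#'   sees the reference).
#' @param p_coverage Percent of a contig's length that must be covered by
#'   reference alignment blocks for the contig to be retained (strict
#'   greater-than). Must be in (0, 100).
#' @param circular_size Minimum terminal-redundancy length in bp for a
#'   contig to be classified circular (strict greater-than).
#' @param genetic_code_id NCBI translation-table id for CDS checks.
#' @param taxon_mode `"default"`, `"plant"` (skip the upper contig-length
#'   filter) or `"fungi"`.
#' @param threads Number of worker processes for per-contig annotation
#'   (candidates are independent; results are merged deterministically).
#' @param cov_mapq_min Minimum mapping quality for a read to count in the
#'   coverage tables.
#' @param min_overlap Minimum read-to-read overlap length (bp) used by the
#'   assembler.
#' @param min_overlap_identity Minimum identity of a read-to-read overlap.
#' @param min_read_identity Minimum identity of a read against the growing
#'   consensus for the read to support a contig; reads below this (or in
#'   structural disagreement, see `structural_gap`) are deferred to a
#'   second assembly round, which can emit an additional haplotype contig.
#' @param min_read_map_identity Minimum identity for a read to count as
#'   mapped to the (cross-species) reference during recruitment.
#' @param structural_gap A read whose best alignment to a consensus
#'   contains a single gap of at least this many bp is considered to be in
#'   structural disagreement (e.g. a heteroplasmic indel) and deferred.
#' @param seed_k Seed k-mer length of the built-in aligner.
#' @param min_chain_seeds Minimum number of seeds in a chain.
#' @param band Band width (bp) of the banded extension aligner.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(max_read_len = NULL,
                            p_coverage = 50,
                            circular_size = 220L,
                            genetic_code_id = 5L,
                            taxon_mode = c("default", "plant", "fungi"),
                            threads = 1L,
                            cov_mapq_min = 0L,
                            min_overlap = 1000L,
                            min_overlap_identity = 0.99,
                            min_read_identity = 0.97,
                            min_read_map_identity = 0.7,
                            structural_gap = 50L,
                            seed_k = 15L,
                            min_chain_seeds = 3L,
                            band = 150L) {
  taxon_mode <- match.arg(taxon_mode)
  cfg <- list(max_read_len = max_read_len, p_coverage = p_coverage,
              circular_size = as.integer(circular_size),
              genetic_code_id = as.integer(genetic_code_id),
              taxon_mode = taxon_mode, threads = as.integer(threads),
              cov_mapq_min = as.integer(cov_mapq_min),
              min_overlap = as.integer(min_overlap),
              min_overlap_identity = min_overlap_identity,
              min_read_identity = min_read_identity,
              min_read_map_identity = min_read_map_identity,
              structural_gap = as.integer(structural_gap),
              seed_k = as.integer(seed_k),
              min_chain_seeds = as.integer(min_chain_seeds),
              band = as.integer(band))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (!is.null(cfg$max_read_len) && cfg$max_read_len <= 0)
    stop("max_read_len must be positive")
  if (cfg$p_coverage <= 0 || cfg$p_coverage >= 100)
    stop("p_coverage must be in (0, 100)")
  if (cfg$circular_size < 0) stop("circular_size must be >= 0")
  if (cfg$threads < 1) stop("threads must be >= 1")
  if (cfg$min_overlap < 1) stop("min_overlap must be >= 1")
  for (f in c("min_overlap_identity", "min_read_identity",
              "min_read_map_identity"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (is.null(v)) "<reference length>" else
      format(v)))
  }
  invisible(x)
}

# Resolve the max_read_len default ("the exact length of the reference
# genome") once the reference is known.
resolve_config <- function(cfg, reference_length) {
  if (is.null(cfg$max_read_len)) cfg$max_read_len <- as.integer(reference_length)
  cfg
}
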