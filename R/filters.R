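# Candidate-contig filtering against the reference: retain plausible
# whole-mitogenome candidates, excluding NUMT-like and fragmentary
# contigs by the coverage and length rules.

#' Compare a contig to the reference mitogenome
#'
#' Finds local alignment blocks (k-mer seed, chain, banded extend, both
#' strands) at identity >= 0.7, merges them on contig coordinates, and
#' reports the fraction of the contig covered by reference homology.
#'
#' @param contig A [draft_contig()] or [seq_record()].
#' @param reference A [seq_record()] or bases string.
#' @param config A [pipeline_config()].
#' @param min_block_identity Minimum identity of a counted block.
#' @return A list of class `contig_reference_match`: `contig_id`,
#'   `covered_fraction`, `contig_len`, `ref_len`, and `blocks`
#'   (data.frame of aligned intervals).
#' @export
match_contig_to_reference <- function(contig, reference,
                                      config = pipeline_config(),
                                      min_block_identity = 0.7) {
  cb <- contig$bases
  ref <- if (inherits(reference, "seq_record")) reference$bases else
    normalize_bases(reference)
  if (!nchar(cb) || !nchar(ref)) stop("empty contig or reference")
  blocks <- find_blocks(cb, ref, k = config$seed_k, band = config$band,
                        min_chain = config$min_chain_seeds,
                        min_identity = min_block_identity,
                        max_chains = 50L)
  covered <- 0L
  if (nrow(blocks)) {
    iv <- IRanges::reduce(IRanges::IRanges(start = blocks$q_start + 1L,
                                           end = blocks$q_end))
    covered <- sum(IRanges::width(iv))
  }
  structure(list(contig_id = contig$id,
                 covered_fraction = covered / nchar(cb),
                 contig_len = nchar(cb), ref_len = nchar(ref),
                 blocks = blocks),
            class = "contig_reference_match")
}

#' Filter candidate contigs by the reference-comparison rules
#'
#' A contig is retained iff (i) more than `p_coverage` percent of its
#' length is covered by reference alignment blocks (strict), (ii) it is
#' strictly less than five times the reference length (long contigs are
#' likely NUMTs; this rule is skipped entirely in plant mode, where
#' genuine mitogenomes vary greatly in size), and (iii) it is strictly
#' longer than 80 percent of the reference length (shorter contigs are
#' likely incomplete).
#'
#' @param matches List of [match_contig_to_reference()] results.
#' @param config A [pipeline_config()] (`p_coverage`, `taxon_mode`).
#' @return A list with `retained` (character vector of contig ids, input
#'   order) and `verdicts` (data.frame with one row per contig recording
#'   each rule's outcome).
#' @export
filter_contigs <- function(matches, config = pipeline_config()) {
  rows <- lapply(matches, function(m) {
    pass_cov <- m$covered_fraction > config$p_coverage / 100
    pass_max <- if (config$taxon_mode == "plant") TRUE else
      m$contig_len < 5 * m$ref_len
    pass_min <- m$contig_len > 0.8 * m$ref_len
    data.frame(contig_id = m$contig_id, contig_len = m$contig_len,
               ref_len = m$ref_len,
               covered_fraction = round(m$covered_fraction, 4),
               pass_coverage = pass_cov, pass_max_len = pass_max,
               pass_min_len = pass_min,
               retained = pass_cov && pass_max && pass_min,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  rownames(verdicts) <- NULL
  list(retained = verdicts$contig_id[verdicts$retained], verdicts = verdicts)
}

#' Write the contig-filter reports
#'
#' `parsed_blast_all.txt` lists every candidate with its statistics;
#' `parsed_blast.txt` lists only the retained candidates.
#'
#' @param verdicts The `verdicts` data.frame from [filter_contigs()].
#' @param dir Output directory.
#' @return Character vector of the two paths, invisibly.
#' @export
write_parsed_blast <- function(verdicts, dir) {
  p_all <- file.path(dir, "parsed_blast_all.txt")
  p_keep <- file.path(dir, "parsed_blast.txt")
  write_tsv(verdicts, p_all)
  write_tsv(verdicts[verdicts$retained, , drop = FALSE], p_keep)
  invisible(c(p_keep, p_all))
}
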