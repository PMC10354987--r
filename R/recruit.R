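# Read recruitment: map reads to the (doubled) reference mitogenome and
# keep only reads plausibly of organellar origin, excluding NUMT-length
# reads by the strict max-read-len rule.

#' Map reads to a reference mitogenome
#'
#' Approximate mapping by k-mer seeding, diagonal chaining and banded
#' extension against the reference concatenated to itself, so reads that
#' span the origin of the circular reference map contiguously. Mapping is
#' local: a read maps when a substantial block of it (at least 1 kb, or
#' half the read for short reads) aligns, so reads carrying a
#' mitochondrial fragment inside nuclear flanks (NUMT reads) still map
#' and can then be length-filtered. At most one primary mapping is
#' reported per read (best alignment score);
#' placements landing in the second copy are renormalized modulo the
#' reference length. Identity is matches over alignment columns. Mapping
#' quality is 60 for a unique placement and decreases toward 0 as the
#' second-best placement's score approaches the best.
#'
#' @param reads List of [seq_record()] reads.
#' @param reference A [seq_record()] (or bases string) of the reference.
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per mapped read: `read_id`,
#'   `ref_start`, `ref_end`, `read_start`, `read_end` (0-based half-open),
#'   `strand`, `identity`, `mapq`, `read_len`.
#' @export
map_reads <- function(reads, reference, config = pipeline_config()) {
  ref <- if (inherits(reference, "seq_record")) reference$bases else
    normalize_bases(reference)
  L <- nchar(ref)
  if (L < config$seed_k)
    stop("reference shorter than the seed size (", config$seed_k, " bp)")
  if (!length(reads)) stop("no reads to map")
  doubled <- paste0(ref, ref)
  k <- config$seed_k
  rows <- list()
  for (r in reads) {
    cand <- list()
    for (strand in c("+", "-")) {
      q <- if (strand == "+") r$bases else revcomp(r$bases)
      hits <- c_seed_hits(q, doubled, k)
      chains <- seed_chains(hits, k, max_diag_gap = config$band,
                            min_chain = config$min_chain_seeds)
      # the doubled reference duplicates each placement at diag + L;
      # keep distinct placements modulo L
      if (length(chains)) {
        dmod <- vapply(chains, function(ch) ch$diag %% L, numeric(1))
        chains <- chains[!duplicated(round(dmod / max(1, config$band)))]
      }
      for (ch in head(chains, 4L)) {
        al <- chain_align_block(q, doubled, ch, config$band)
        if (is.null(al)) next
        cand[[length(cand) + 1L]] <- list(strand = strand, al = al)
      }
    }
    if (!length(cand)) next
    scores <- vapply(cand, function(x) x$al$score, numeric(1))
    o <- order(-scores)
    best <- cand[[o[1]]]
    # a mapping must be a substantial local block, not a chance seed hit
    min_cols <- min(1000L, as.integer(ceiling(0.5 * nchar(r$bases))))
    if (best$al$identity < config$min_read_map_identity ||
        best$al$columns < min_cols) next
    mapq <- 60L
    if (length(o) > 1L) {
      s1 <- scores[o[1]]; s2 <- scores[o[2]]
      if (s1 > 0 && s2 > 0)
        mapq <- max(0L, min(60L, as.integer(round(60 * (1 - s2 / s1)))))
    }
    rs <- best$al$s_start %% L
    re <- rs + (best$al$s_end - best$al$s_start)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = r$id, ref_start = rs, ref_end = re,
      read_start = best$al$q_start, read_end = best$al$q_end,
      strand = best$strand, identity = best$al$identity, mapq = mapq,
      read_len = nchar(r$bases), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(read_id = character(), ref_start = integer(),
                      ref_end = integer(), read_start = integer(),
                      read_end = integer(), strand = character(),
                      identity = numeric(), mapq = integer(),
                      read_len = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Recruit mapped reads, excluding NUMT-length reads
#'
#' A read is recruited iff it has a primary mapping and its full length
#' is at most `max_read_len` (default: the exact reference length).
#' Exclusion is strictly greater-than: a mapped read exactly as long as
#' the reference is kept, reads longer than it are excluded as likely
#' NUMT-derived. Input order is preserved.
#'
#' @param reads List of [seq_record()] reads (the set given to
#'   [map_reads()]).
#' @param mappings Output of [map_reads()] on `reads`.
#' @param config A [pipeline_config()] whose `max_read_len` has been
#'   resolved (see `reference_length`).
#' @param reference_length Used to resolve a `NULL` `max_read_len`.
#' @return A list with `reads` (recruited [seq_record()]s, input order)
#'   and `report` (`n_in`, `n_mapped`, `n_length_excluded`,
#'   `n_recruited`).
#' @export
recruit_reads <- function(reads, mappings, config = pipeline_config(),
                          reference_length = NULL) {
  if (is.null(config$max_read_len)) {
    if (is.null(reference_length))
      stop("max_read_len is NULL and no reference_length was given")
    config <- resolve_config(config, reference_length)
  }
  mapped_ids <- mappings$read_id
  lens <- vapply(reads, function(r) nchar(r$bases), integer(1))
  ids <- vapply(reads, `[[`, character(1), "id")
  is_mapped <- ids %in% mapped_ids
  too_long <- lens > config$max_read_len
  keep <- is_mapped & !too_long
  list(reads = reads[keep],
       report = list(n_in = length(reads),
                     n_mapped = sum(is_mapped),
                     n_length_excluded = sum(is_mapped & too_long),
                     n_recruited = sum(keep)))
}

#' Write a read-mapping table as TSV
#'
#' @param mappings Output of [map_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mappings <- function(mappings, path) {
  write_tsv(mappings[, c("read_id", "ref_start", "ref_end", "strand",
                         "identity", "mapq")], path)
}
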