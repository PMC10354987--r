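# Homology-based annotation transfer from the reference mitogenome to
# candidate contigs, with frameshift flagging of protein-coding genes.

#' Genetic-code table
#'
#' Wraps the NCBI translation tables (via Biostrings) into a codon map
#' with start and stop codons. Mitochondrial analyses typically use
#' tables 2 (vertebrate), 4 (mold/protozoan), 5 (invertebrate) or 1.
#'
#' @param table_id NCBI translation-table id.
#' @return A list of class `genetic_code`: `table_id`, `codons` (named
#'   character: codon -> amino acid, `*` for stop), `start_codons`,
#'   `stop_codons`.
#' @export
genetic_code <- function(table_id) {
  tid <- as.character(as.integer(table_id))
  if (!tid %in% Biostrings::GENETIC_CODE_TABLE$id)
    stop("unsupported genetic-code table id: ", table_id)
  codons <- Biostrings::getGeneticCode(tid)
  starts <- attr(codons, "alt_init_codons")
  codons <- setNames(as.character(codons), names(codons))
  structure(list(table_id = as.integer(table_id), codons = codons,
                 start_codons = unique(c("ATG", starts)),
                 stop_codons = names(codons)[codons == "*"]),
            class = "genetic_code")
}

translate_cds <- function(bases, code) {
  n3 <- (nchar(bases) %/% 3L) * 3L
  if (n3 < 3L) return("")
  cods <- substring(bases, seq(1L, n3 - 2L, 3L), seq(3L, n3, 3L))
  aa <- code$codons[cods]
  aa[is.na(aa)] <- "X" # codons containing N
  paste(aa, collapse = "")
}

# Extract a feature's sequence from its (possibly circular) source,
# oriented 5'->3' on the gene's sense strand.
extract_feature_seq <- function(bases, f) {
  n <- nchar(bases)
  s <- if (feature_is_origin_spanning(f))
    substr(paste0(bases, bases), f$start + 1L, f$end) else
      substr(bases, f$start + 1L, f$end)
  if (f$strand == "-") revcomp(s) else s
}

#' Transfer reference features to a contig by homology
#'
#' Each reference feature's sequence is aligned to the contig (both
#' strands; the contig is treated as circular via doubling when flagged
#' circular). The best placement with identity >= `min_identity` and
#' reference coverage >= `min_coverage` becomes a gene call; unplaced
#' genes are reported missing. CDS calls are checked for frameshifts.
#'
#' @param reference_record Reference [seq_record()].
#' @param reference_annotation Reference [annotation_set()].
#' @param contig A [draft_contig()] or [seq_record()].
#' @param config A [pipeline_config()].
#' @param circular Treat the contig as circular.
#' @param min_identity Identity floor for a transferred feature
#'   (permissive: the reference is a different species).
#' @param min_coverage Minimum fraction of the reference feature length
#'   that must be aligned.
#' @return A list with `annotation` (an [annotation_set()] whose features
#'   carry `identity` and, for CDS, `frameshift` qualifiers) and
#'   `missing` (character vector of unplaced gene names).
#' @export
transfer_features <- function(reference_record, reference_annotation, contig,
                              config = pipeline_config(), circular = FALSE,
                              min_identity = 0.6, min_coverage = 0.7) {
  if (!length(reference_annotation$features))
    stop("reference annotation is empty")
  cb <- contig$bases
  n <- nchar(cb)
  target <- if (circular) paste0(cb, cb) else cb
  code <- genetic_code(config$genetic_code_id)
  calls <- list()
  missing <- character()
  for (f in reference_annotation$features) {
    fseq <- extract_feature_seq(reference_record$bases, f)
    flen <- nchar(fseq)
    k <- if (flen < 200L) min(11L, config$seed_k) else config$seed_k
    min_chain <- if (flen < 200L) 2L else config$min_chain_seeds
    blocks <- find_blocks(fseq, target, k = k, band = config$band,
                          min_chain = min_chain, min_identity = 0,
                          max_chains = 10L, max_q_gap = max(2000L, flen))
    placed <- NULL
    if (nrow(blocks)) {
      blocks$coverage <- (blocks$q_end - blocks$q_start) / flen
      ok <- blocks[blocks$identity >= min_identity &
                     blocks$coverage >= min_coverage, , drop = FALSE]
      if (nrow(ok)) placed <- ok[which.max(ok$identity), ]
    }
    if (is.null(placed)) { missing <- c(missing, f$name); next }
    # map the placement back to forward contig coordinates
    start <- placed$s_start
    end <- placed$s_end
    strand <- placed$strand
    quals <- list(identity = round(placed$identity, 4))
    if (!is.null(f$qualifiers$product)) quals$product <- f$qualifiers$product
    if (f$kind == "CDS")
      quals$transl_table <- f$qualifiers$transl_table %||% code$table_id
    if (circular && start >= n) { start <- start - n; end <- end - n }
    if (circular && end > n) quals$origin_spanning <- TRUE
    call <- feature_record(contig$id, f$kind, start, end, strand, f$name,
                           quals)
    if (f$kind == "CDS") {
      call$qualifiers$frameshift <- detect_frameshift(
        call, cb, code, ref_cds_len = flen, circular = circular)
    }
    calls[[length(calls) + 1L]] <- call
  }
  list(annotation = annotation_set(contig$id, calls, code$table_id),
       missing = missing)
}

#' Detect a frameshift in a called CDS
#'
#' A gene call is flagged as frameshifted iff the called span length
#' modulo 3 differs from the reference CDS length modulo 3, or its
#' translation contains an internal stop codon before 90 percent of the
#' expected protein length.
#'
#' @param gene_call A CDS [feature_record()] on the contig.
#' @param contig_bases The contig sequence.
#' @param code A [genetic_code()].
#' @param ref_cds_len Reference CDS length in bp.
#' @param circular Whether the contig is circular (origin-spanning calls).
#' @return `TRUE` iff a frameshift is detected.
#' @export
detect_frameshift <- function(gene_call, contig_bases, code, ref_cds_len,
                              circular = FALSE) {
  if (!identical(gene_call$kind, "CDS"))
    stop("frameshift detection is defined for CDS features only")
  if (!inherits(code, "genetic_code")) code <- genetic_code(code)
  span <- gene_call$end - gene_call$start
  if ((span %% 3L) != (ref_cds_len %% 3L)) return(TRUE)
  s <- extract_feature_seq(contig_bases, gene_call)
  aa <- translate_cds(s, code)
  expected <- ref_cds_len %/% 3L - 1L # protein length, stop excluded
  stops <- gregexpr("*", substr(aa, 1L, max(0L, nchar(aa) - 1L)),
                    fixed = TRUE)[[1]]
  if (stops[1] == -1L) return(FALSE)
  any(stops < ceiling(0.9 * expected))
}

#' Count transferred genes and build the shared/missing matrix
#'
#' Counts CDS, rRNA and tRNA features per contig and marks each reference
#' gene present or absent in each contig's annotation.
#'
#' @param annotation_sets Named list of per-contig [annotation_set()]s.
#' @param reference_annotation The reference [annotation_set()].
#' @return A list with `counts` (named integer vector per contig),
#'   `matrix` (logical matrix, reference genes x contigs) and `missing`
#'   (named list of missing gene names per contig).
#' @export
count_genes <- function(annotation_sets, reference_annotation) {
  kinds <- c("CDS", "rRNA", "tRNA")
  ref <- feature_df(reference_annotation)
  ref_genes <- unique(ref$name[ref$kind %in% kinds])
  counts <- vapply(annotation_sets, function(a) {
    df <- feature_df(a)
    sum(df$kind %in% kinds)
  }, integer(1))
  mat <- matrix(FALSE, nrow = length(ref_genes), ncol = length(annotation_sets),
                dimnames = list(ref_genes, names(annotation_sets)))
  for (cid in names(annotation_sets)) {
    have <- feature_df(annotation_sets[[cid]])$name
    mat[, cid] <- ref_genes %in% have
  }
  missing <- lapply(names(annotation_sets), function(cid)
    ref_genes[!mat[, cid]])
  names(missing) <- names(annotation_sets)
  list(counts = counts, matrix = mat, missing = missing)
}
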