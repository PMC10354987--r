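# Finalization: rotate candidates to the conventional tRNA-Phe start,
# rank them, select the representative mitogenome, compute coverage
# tables and emit all report files.

#' Choose the rotation anchor gene
#'
#' Returns `"trnF"` (tRNA-Phe, the conventional start of mitochondrial
#' genomes) if any contig annotates it; otherwise the tRNA occurring on
#' the greatest number of contigs (ties broken lexicographically). With
#' no tRNA anywhere, rotation is skipped and `NA` returned with a
#' warning.
#'
#' @param annotations Named list of per-contig [annotation_set()]s.
#' @return The anchor gene name, or `NA_character_`.
#' @export
choose_rotation_anchor <- function(annotations) {
  if (!length(annotations)) stop("no annotated contigs")
  per_contig <- lapply(annotations, function(a) {
    df <- feature_df(a)
    unique(df$name[df$kind == "tRNA"])
  })
  if (any(vapply(per_contig, function(x) "trnF" %in% x, logical(1))))
    return("trnF")
  all_trna <- unlist(per_contig, use.names = FALSE)
  if (!length(all_trna)) {
    warning("no tRNA annotated on any contig; rotation skipped")
    return(NA_character_)
  }
  tab <- table(all_trna)
  names(tab)[order(-tab, names(tab))][1L]
}

#' Rotate a circular contig to start at the anchor locus
#'
#' If the anchor feature lies on the minus strand the contig is
#' reverse-complemented first; the sequence is then cyclically permuted
#' so position 0 is the anchor's first base. Annotation coordinates are
#' updated; the cyclic sequence content is unchanged.
#'
#' @param contig A trimmed circular [draft_contig()].
#' @param annotation The contig's [annotation_set()].
#' @param anchor Anchor gene name (from [choose_rotation_anchor()]).
#' @return A list with `contig` and `annotation` rotated, or the inputs
#'   unchanged (with a warning) when the anchor is absent.
#' @export
rotate_contig <- function(contig, annotation, anchor) {
  df <- feature_df(annotation)
  hit <- which(df$name == anchor)
  if (!length(hit)) {
    warning("anchor '", anchor, "' not annotated on ", contig$id,
            "; contig left unrotated")
    return(list(contig = contig, annotation = annotation))
  }
  hit <- hit[order(df$start[hit])][1L]
  n <- nchar(contig$bases)
  feats <- annotation$features
  if (feats[[hit]]$strand == "-") {
    contig$bases <- revcomp(contig$bases)
    feats <- lapply(feats, function(f) {
      if (feature_is_origin_spanning(f)) {
        # covered arc [start, n) u [0, end - n) maps to an arc starting
        # at the complement of the wrapped end
        width <- f$end - f$start
        f$start <- 2L * n - f$end
        f$end <- f$start + width
      } else {
        new_start <- n - f$end
        f$end <- n - f$start
        f$start <- new_start
      }
      f$strand <- flip_strand(f$strand)
      f
    })
    ann2 <- annotation_set(contig$id, feats, annotation$genetic_code_id)
    df <- feature_df(ann2)
    hit <- which(df$name == anchor)
    hit <- hit[order(df$start[hit])][1L]
    feats <- ann2$features
  }
  shift <- feats[[hit]]$start %% n
  if (shift > 0L)
    contig$bases <- paste0(substr(contig$bases, shift + 1L, n),
                           substr(contig$bases, 1L, shift))
  feats <- lapply(feats, function(f) {
    width <- f$end - f$start
    f$start <- (f$start - shift) %% n
    f$end <- f$start + width
    f$qualifiers$origin_spanning <- NULL
    if (f$end > n) f$qualifiers$origin_spanning <- TRUE
    f
  })
  list(contig = contig,
       annotation = annotation_set(contig$id, feats,
                                   annotation$genetic_code_id))
}

#' Rank candidates and select the final mitogenome
#'
#' Candidates are sorted by number of genes annotated in relation to the
#' reference (descending; ties by smaller length difference to the
#' reference, then lexicographic id). The first candidate that (A) is
#' circular with redundancy removed, (B) has a size similar to the
#' reference (within 0.8-1.2x) and (C) has no frameshifted gene wins.
#' If none passes all three, the first circular candidate additionally
#' satisfying B is chosen, then the first circular candidate satisfying
#' C, then the first circular candidate. With no circular candidate at
#' all, the top-ranked candidate is selected with a prominent warning.
#'
#' @param reports Data.frame with columns `contig_id`, `length_bp`,
#'   `gene_count`, `frameshift_count`, `is_circular`.
#' @param ref_len Reference length in bp.
#' @return A list with `final_id`, `ranked` (the reports with
#'   `selection_rank`, `size_similar_to_ref` and `is_final` columns) and
#'   `warnings`.
#' @export
rank_and_select <- function(reports, ref_len) {
  if (!nrow(reports)) stop("no final mitogenome: empty candidate list")
  r <- reports
  r$size_similar_to_ref <- r$length_bp >= 0.8 * ref_len &
    r$length_bp <= 1.2 * ref_len
  o <- order(-r$gene_count, abs(r$length_bp - ref_len), r$contig_id)
  r <- r[o, , drop = FALSE]
  r$selection_rank <- seq_len(nrow(r))
  A <- r$is_circular
  B <- r$size_similar_to_ref
  C <- r$frameshift_count == 0L
  warnings <- character()
  pick <- which(A & B & C)
  if (!length(pick)) pick <- which(A & B)
  if (!length(pick)) pick <- which(A & C)
  if (!length(pick)) pick <- which(A)
  if (!length(pick)) {
    pick <- 1L
    msg <- "no circular candidate: selecting the top-ranked linear contig; the assembly may be incomplete"
    warnings <- c(warnings, msg)
    warning(msg)
  }
  final_id <- r$contig_id[pick[1L]]
  r$is_final <- r$contig_id == final_id
  rownames(r) <- NULL
  list(final_id = final_id, ranked = r, warnings = warnings)
}

#' Compute per-base read coverage of contigs
#'
#' Maps the recruited reads to each target contig (circular targets are
#' doubled so origin-spanning placements count), assigns each read to its
#' best-scoring target, discards placements below the mapping-quality
#' floor, and accumulates per-base depth.
#'
#' @param reads Recruited [seq_record()] reads.
#' @param contigs Named list of [draft_contig()]s (targets).
#' @param config A [pipeline_config()] (`cov_mapq_min`, aligner
#'   parameters).
#' @return A data.frame with columns `contig_id`, `pos` (1-based) and
#'   `depth`.
#' @export
compute_coverage <- function(reads, contigs, config = pipeline_config()) {
  depth <- lapply(contigs, function(ct) integer(nchar(ct$bases)))
  names(depth) <- names(contigs)
  for (r in reads) {
    best <- NULL
    for (cid in names(contigs)) {
      ct <- contigs[[cid]]
      m <- tryCatch(
        map_reads(list(r), seq_record(cid, ct$bases), config),
        error = function(e) NULL)
      if (is.null(m) || !nrow(m)) next
      if (is.null(best) || m$identity[1L] > best$identity) {
        best <- as.list(m[1L, ]); best$cid <- cid
      }
    }
    if (is.null(best)) next
    if (best$mapq < config$cov_mapq_min) next
    L <- nchar(contigs[[best$cid]]$bases)
    pos <- seq.int(best$ref_start, best$ref_end - 1L) %% L
    tab <- tabulate(pos + 1L, nbins = L)
    depth[[best$cid]] <- depth[[best$cid]] + tab
  }
  out <- lapply(names(depth), function(cid)
    data.frame(contig_id = cid, pos = seq_along(depth[[cid]]),
               depth = depth[[cid]], stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write per-contig coverage as TSV
#'
#' @param coverage Output of [compute_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  write_tsv(coverage, path)
}
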