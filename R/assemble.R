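# Built-in overlap-layout-consensus assembler for small circular genomes
# at high coverage from long accurate reads. Emits multiple contigs when
# reads support structurally divergent haplotypes (heteroplasmy), and
# accepts pre-assembled contigs as an alternative entry point.

#' Create a draft contig
#'
#' @param id Contig identifier.
#' @param bases Contig sequence.
#' @param supporting_read_ids Ids of reads supporting the consensus.
#' @param layout_is_cyclic Whether the layout closed into a cycle (the
#'   linearized sequence then still carries its terminal redundancy,
#'   which the circularization stage detects and trims).
#' @return An object of class `draft_contig`.
#' @export
draft_contig <- function(id, bases, supporting_read_ids = character(),
                         layout_is_cyclic = FALSE) {
  structure(list(id = id, bases = normalize_bases(bases),
                 supporting_read_ids = supporting_read_ids,
                 layout_is_cyclic = isTRUE(layout_is_cyclic)),
            class = "draft_contig")
}

#' @export
print.draft_contig <- function(x, ...) {
  cat(sprintf("<draft_contig> %s (%d bp, %d supporting reads%s)\n", x$id,
              nchar(x$bases), length(x$supporting_read_ids),
              if (x$layout_is_cyclic) ", cyclic layout" else ""))
  invisible(x)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Compute suffix-prefix overlaps between reads
#'
#' Finds all dovetail overlaps of at least `min_overlap` aligned columns
#' at identity at least `min_identity`, in both orientations, by k-mer
#' seeding and banded extension. Reads fully contained in another read
#' are flagged separately and set aside from layout extension (they still
#' contribute to the consensus).
#'
#' @param reads List of [seq_record()] reads with unique ids.
#' @param min_overlap Minimum overlap length (alignment columns).
#' @param min_identity Minimum overlap identity.
#' @param config A [pipeline_config()] supplying the seeding parameters.
#' @return An object of class `overlap_set`: a list with `overlaps`
#'   (data.frame: `a_id`, `b_id`, `a_hang`, `overlap_len`, `orientation`,
#'   `identity`, plus layout bookkeeping columns) and `containments`
#'   (data.frame: `inner`, `outer`, `identity`).
#' @export
compute_overlaps <- function(reads, min_overlap = NULL, min_identity = NULL,
                             config = pipeline_config()) {
  if (is.null(min_overlap)) min_overlap <- config$min_overlap
  if (is.null(min_identity)) min_identity <- config$min_overlap_identity
  ids <- vapply(reads, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("reads must be deduplicated by id")
  n <- length(reads)
  bases <- lapply(reads, `[[`, "bases")
  rc <- lapply(bases, revcomp)
  lens <- vapply(bases, nchar, integer(1))
  k <- config$seed_k; band <- config$band
  slack <- max(50L, k)
  edges <- list()
  cont <- list()
  add_edge <- function(from, fs, to, ts, a_hang, to_span, olen, ident) {
    edges[[length(edges) + 1L]] <<- data.frame(
      a_id = ids[from], b_id = ids[to], a_strand = fs, b_strand = ts,
      a_hang = a_hang, overlap_len = olen, to_span = to_span,
      orientation = if (fs == ts) "forward" else "reverse",
      identity = ident, stringsAsFactors = FALSE)
  }
  if (n > 1) for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      for (orient in c("+", "-")) {
        b_or <- if (orient == "+") bases[[j]] else rc[[j]]
        hits <- c_seed_hits(bases[[i]], b_or, k)
        chains <- seed_chains(hits, k, max_diag_gap = band,
                              min_chain = config$min_chain_seeds)
        for (ch in head(chains, 4L)) {
          na <- lens[i]; nb <- lens[j]
          b_full <- ch$s0 <= slack && ch$s1 >= nb - slack
          a_full <- ch$q0 <= slack && ch$q1 >= na - slack
          if (b_full || a_full) {
            inner_is_b <- if (b_full && a_full) nb <= na else b_full
            if (inner_is_b) {
              ch2 <- list(q0 = ch$s0, q1 = ch$s1, s0 = ch$q0, s1 = ch$q1,
                          n = ch$n, diag = -ch$diag)
              al <- chain_align_query_global(b_or, bases[[i]], ch2, band)
              if (!is.null(al) && al$identity >= min_identity)
                cont[[length(cont) + 1L]] <- data.frame(
                  inner = ids[j], outer = ids[i], identity = al$identity,
                  stringsAsFactors = FALSE)
            } else {
              al <- chain_align_query_global(bases[[i]], b_or, ch, band)
              if (!is.null(al) && al$identity >= min_identity)
                cont[[length(cont) + 1L]] <- data.frame(
                  inner = ids[i], outer = ids[j], identity = al$identity,
                  stringsAsFactors = FALSE)
            }
            next
          }
          d <- ch$diag
          if (d < 0) { # suffix of a(i,+) overlaps prefix of b(j,orient)
            t <- as.integer(-d)
            span <- na - t
            if (span < min_overlap - band || span > nb + band) next
            qsub <- substr(bases[[i]], t + 1L, na)
            ssub <- substr(b_or, 1L, min(nb, span + band))
            al <- tryCatch(c_banded_align(qsub, ssub, band, FALSE, TRUE),
                           error = function(e) NULL)
            if (is.null(al)) next
            ident <- al$matches / max(1L, al$columns)
            if (al$columns >= min_overlap && ident >= min_identity)
              add_edge(i, "+", j, orient, t, al$b_end, al$columns, ident)
          } else if (d > 0) { # suffix of b(j,orient) overlaps prefix of a(i,+)
            t <- as.integer(d)
            span <- nb - t
            if (span < min_overlap - band || span > na + band) next
            qsub <- substr(b_or, t + 1L, nb)
            ssub <- substr(bases[[i]], 1L, min(na, span + band))
            al <- tryCatch(c_banded_align(qsub, ssub, band, FALSE, TRUE),
                           error = function(e) NULL)
            if (is.null(al)) next
            ident <- al$matches / max(1L, al$columns)
            if (al$columns >= min_overlap && ident >= min_identity)
              add_edge(j, orient, i, "+", t, al$b_end, al$columns, ident)
          }
        }
      }
    }
  }
  ov <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a_id = character(), b_id = character(),
               a_strand = character(), b_strand = character(),
               a_hang = integer(), overlap_len = integer(),
               to_span = integer(), orientation = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(ov)) {
    key <- paste(ov$a_id, ov$a_strand, ov$b_id, ov$b_strand)
    ov <- ov[order(key, -ov$overlap_len, -ov$identity), , drop = FALSE]
    ov <- ov[!duplicated(paste(ov$a_id, ov$a_strand, ov$b_id, ov$b_strand)), ,
             drop = FALSE]
    rownames(ov) <- NULL
  }
  cn <- if (length(cont)) unique(do.call(rbind, cont)) else
    data.frame(inner = character(), outer = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  rownames(cn) <- NULL
  structure(list(overlaps = ov, containments = cn), class = "overlap_set")
}

# Full directed edge table (stored edges plus their reverse-complement
# mirrors), used for layout extension.
overlap_edges <- function(ov, lens) {
  e <- ov$overlaps
  if (!nrow(e)) return(e)
  mirror <- data.frame(
    a_id = e$b_id, b_id = e$a_id,
    a_strand = flip_strand(e$b_strand), b_strand = flip_strand(e$a_strand),
    a_hang = lens[e$b_id] - e$to_span,
    overlap_len = e$overlap_len,
    to_span = lens[e$a_id] - e$a_hang,
    orientation = e$orientation, identity = e$identity,
    stringsAsFactors = FALSE)
  all <- rbind(e, mirror)
  all <- all[order(-all$overlap_len, -all$identity, all$a_id, all$b_id), ,
             drop = FALSE]
  all[!duplicated(paste(all$a_id, all$a_strand, all$b_id, all$b_strand)), ,
      drop = FALSE]
}

#' Greedy best-overlap-first layout
#'
#' Builds layout paths by repeatedly extending from the longest available
#' overlap (ties broken by higher identity, then lexicographic read id).
#' When an extension would return to the first read of the path, the path
#' is closed into a cycle. Contained reads never extend a path. Reads left
#' without any usable overlap become singleton layouts.
#'
#' @param overlaps An `overlap_set` from [compute_overlaps()].
#' @param reads The same read list.
#' @param config A [pipeline_config()].
#' @return A list of layouts. Each layout is a data.frame with columns
#'   `read_id`, `strand`, `splice` (bases of the read consumed by the
#'   overlap with its predecessor; `NA` for the first read), with
#'   attributes `cyclic` (logical) and `closing_span`.
#' @export
greedy_layout <- function(overlaps, reads, config = pipeline_config()) {
  ids <- vapply(reads, `[[`, character(1), "id")
  lens <- setNames(vapply(reads, function(r) nchar(r$bases), integer(1)), ids)
  E <- overlap_edges(overlaps, lens)
  contained <- unique(overlaps$containments$inner)
  if (nrow(E))
    E <- E[!(E$a_id %in% contained) & !(E$b_id %in% contained), , drop = FALSE]
  used <- character()
  layouts <- list()
  repeat {
    open <- E[!(E$a_id %in% used) & !(E$b_id %in% used), , drop = FALSE]
    if (!nrow(open)) break
    seed_edge <- open[1L, ]
    path <- data.frame(read_id = c(seed_edge$a_id, seed_edge$b_id),
                       strand = c(seed_edge$a_strand, seed_edge$b_strand),
                       splice = c(NA_integer_, seed_edge$to_span),
                       stringsAsFactors = FALSE)
    used <- c(used, seed_edge$a_id, seed_edge$b_id)
    cyclic <- FALSE; closing_span <- NA_integer_
    repeat { # extend right
      tip <- path[nrow(path), ]
      outg <- E[E$a_id == tip$read_id & E$a_strand == tip$strand, ,
                drop = FALSE]
      if (!nrow(outg)) break
      back <- outg[outg$b_id == path$read_id[1L] &
                     outg$b_strand == path$strand[1L], , drop = FALSE]
      if (nrow(back)) { # returning to the start closes the cycle
        cyclic <- TRUE; closing_span <- back$to_span[1L]
        break
      }
      ext <- outg[!(outg$b_id %in% used), , drop = FALSE]
      if (!nrow(ext)) break
      e <- ext[1L, ]
      path <- rbind(path, data.frame(read_id = e$b_id, strand = e$b_strand,
                                     splice = e$to_span,
                                     stringsAsFactors = FALSE))
      used <- c(used, e$b_id)
    }
    if (!cyclic) repeat { # extend left
      start <- path[1L, ]
      inc <- E[E$b_id == start$read_id & E$b_strand == start$strand &
                 !(E$a_id %in% used), , drop = FALSE]
      if (!nrow(inc)) break
      e <- inc[1L, ]
      path$splice[1L] <- e$to_span
      path <- rbind(data.frame(read_id = e$a_id, strand = e$a_strand,
                               splice = NA_integer_, stringsAsFactors = FALSE),
                    path)
      used <- c(used, e$a_id)
    }
    attr(path, "cyclic") <- cyclic
    attr(path, "closing_span") <- closing_span
    layouts[[length(layouts) + 1L]] <- path
  }
  # singletons: unused, non-contained reads
  for (id in ids[!(ids %in% used) & !(ids %in% contained)]) {
    p <- data.frame(read_id = id, strand = "+", splice = NA_integer_,
                    stringsAsFactors = FALSE)
    attr(p, "cyclic") <- FALSE
    attr(p, "closing_span") <- NA_integer_
    layouts[[length(layouts) + 1L]] <- p
  }
  if (length(layouts) > 1L) {
    sizes <- vapply(layouts, nrow, integer(1))
    firsts <- vapply(layouts, function(p) p$read_id[1L], character(1))
    layouts <- layouts[order(-sizes, firsts)]
  }
  layouts
}

# Align one read against a consensus backbone: up to two same-strand
# blocks (reads wrapping the cyclic junction align in two pieces).
align_read_to_backbone <- function(q, backbone, config) {
  k <- config$seed_k; band <- max(config$band, 150L)
  nq <- nchar(q)
  blocks <- list()
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") q else revcomp(q)
    hits <- c_seed_hits(qq, backbone, k)
    chains <- seed_chains(hits, k, max_diag_gap = band,
                          min_chain = config$min_chain_seeds)
    for (ch in head(chains, 3L)) {
      al <- chain_align_block(qq, backbone, ch, band)
      if (is.null(al)) next
      al$strand <- strand
      al$qq <- qq
      blocks[[length(blocks) + 1L]] <- al
    }
  }
  if (!length(blocks)) return(list(supported = FALSE, blocks = list()))
  blocks <- blocks[order(-vapply(blocks, `[[`, numeric(1), "score"))]
  keep <- blocks[1L]
  b1 <- blocks[[1L]]
  for (b in blocks[-1L]) {
    if (length(keep) >= 2L) break
    if (!identical(b$strand, b1$strand)) next
    inter <- min(b$q_end, b1$q_end) - max(b$q_start, b1$q_start)
    if (inter < 0.2 * min(b$q_end - b$q_start, b1$q_end - b1$q_start))
      keep <- c(keep, list(b))
  }
  qcov <- sum(vapply(keep, function(b) b$q_end - b$q_start, numeric(1))) / nq
  # A large single gap, or a large net insertion/deletion imbalance,
  # marks structural disagreement with the backbone. The net imbalance is
  # needed because the aligner may fragment a long novel insertion into
  # many small gaps interleaved with chance matches.
  structural <- any(vapply(keep, function(b) {
    net <- abs(sum(b$lens[b$ops == 1L]) - sum(b$lens[b$ops == 2L]))
    max(b$max_ins, b$max_del, net) >= config$structural_gap
  }, logical(1)))
  supported <- b1$identity >= config$min_read_identity && !structural &&
    qcov >= 0.6
  list(supported = supported, identity = b1$identity, coverage = qcov,
       structural = structural, blocks = keep)
}

#' Call a consensus contig from a layout
#'
#' Splices the layout reads into a backbone via their pairwise overlaps,
#' then polishes it by per-column majority vote over all reads whose
#' alignment to the backbone is clean (identity at least
#' `min_read_identity`, no single gap of `structural_gap` or more). Ties
#' are broken toward the earliest read in the layout. Cyclic layouts
#' yield a linear string whose terminal redundancy is left intact for the
#' circularization stage.
#'
#' @param layout One layout from [greedy_layout()].
#' @param reads Reads available to support the consensus (typically the
#'   full read set of the assembly round).
#' @param config A [pipeline_config()].
#' @return A [draft_contig()] (id `"consensus"`; the caller renames it)
#'   whose `supporting_read_ids` are the reads that voted.
#' @export
call_consensus <- function(layout, reads, config = pipeline_config()) {
  if (!nrow(layout)) stop("empty layout")
  ids <- vapply(reads, `[[`, character(1), "id")
  bases <- setNames(lapply(reads, `[[`, "bases"), ids)
  oriented <- function(id, strand)
    if (strand == "+") bases[[id]] else revcomp(bases[[id]])
  backbone <- oriented(layout$read_id[1L], layout$strand[1L])
  if (nrow(layout) > 1L) for (i in seq.int(2L, nrow(layout))) {
    seg <- oriented(layout$read_id[i], layout$strand[i])
    sp <- layout$splice[i]
    if (sp < nchar(seg)) backbone <- paste0(backbone, substr(seg, sp + 1L,
                                                             nchar(seg)))
  }
  # polish: layout reads vote first (tie-break priority), then the rest
  vote_order <- c(layout$read_id, setdiff(ids, layout$read_id))
  starts <- integer(); seqs <- character(); opsl <- list(); lensl <- list()
  supporters <- character()
  for (id in vote_order) {
    ar <- align_read_to_backbone(bases[[id]], backbone, config)
    if (!ar$supported) next
    supporters <- c(supporters, id)
    for (b in ar$blocks) {
      starts <- c(starts, b$s_start)
      seqs <- c(seqs, substr(b$qq, b$q_start + 1L, b$q_end))
      opsl[[length(opsl) + 1L]] <- b$ops
      lensl[[length(lensl) + 1L]] <- b$lens
    }
  }
  consensus <- if (length(starts))
    c_pileup_consensus(backbone, starts, seqs, opsl, lensl) else backbone
  draft_contig("consensus", consensus, supporting_read_ids = supporters,
               layout_is_cyclic = isTRUE(attr(layout, "cyclic")))
}

#' Assemble reads into candidate contigs
#'
#' Runs overlap computation, greedy layout and consensus polishing. Reads
#' whose alignment to every first-round consensus is below the identity
#' floor or shows a structural gap (a divergent haplotype, or sequence
#' from another locus) are deferred to a second assembly round, which can
#' emit additional candidate contigs. Reads still unplaced after the
#' final round become singleton contigs.
#'
#' @param reads List of [seq_record()] reads.
#' @param config A [pipeline_config()].
#' @return A list of [draft_contig()]s named `contig_1`, `contig_2`, ...
#' @export
assemble <- function(reads, config = pipeline_config()) {
  if (!length(reads)) stop("no reads to assemble")
  contigs <- list()
  n_out <- 0L
  remaining <- reads
  for (round in 1:2) {
    if (!length(remaining)) break
    ov <- compute_overlaps(remaining, config = config)
    layouts <- greedy_layout(ov, remaining, config)
    multi <- Filter(function(p) nrow(p) > 1L, layouts)
    if (!length(multi)) break
    assigned <- character()
    for (ly in multi) {
      if (mean(ly$read_id %in% assigned) > 0.5) next
      dc <- call_consensus(ly, remaining, config)
      if (!length(dc$supporting_read_ids)) next
      n_out <- n_out + 1L
      dc$id <- sprintf("contig_%d", n_out)
      contigs[[dc$id]] <- dc
      assigned <- union(assigned, dc$supporting_read_ids)
    }
    if (!length(assigned)) break
    rem_ids <- vapply(remaining, `[[`, character(1), "id")
    remaining <- remaining[!(rem_ids %in% assigned)]
  }
  for (r in remaining) {
    n_out <- n_out + 1L
    id <- sprintf("contig_%d", n_out)
    contigs[[id]] <- draft_contig(id, r$bases, supporting_read_ids = r$id,
                                  layout_is_cyclic = FALSE)
  }
  contigs
}

#' Wrap externally assembled contigs
#'
#' The contig entry point of the pipeline: pre-assembled sequences are
#' passed through unchanged as draft contigs.
#'
#' @param contigs List of [seq_record()]s (e.g. from [read_fasta()]).
#' @return A named list of [draft_contig()]s, byte-identical sequences.
#' @export
accept_contigs <- function(contigs) {
  if (!length(contigs)) stop("no contigs supplied")
  out <- lapply(contigs, function(r)
    draft_contig(r$id, r$bases, supporting_read_ids = r$id,
                 layout_is_cyclic = FALSE))
  names(out) <- vapply(contigs, `[[`, character(1), "id")
  out
}
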