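# Built-in aligner: k-mer seeding, diagonal chaining, banded extension.
# Shared by read mapping, overlap detection, contig/reference comparison,
# circularity checking and annotation transfer.

# Cluster seed hits (qpos, spos matrix, 0-based) into candidate chains.
# Seeds on nearby diagonals are grouped, then split on large query gaps.
seed_chains <- function(hits, k, max_diag_gap = 150L, min_chain = 3L,
                        max_q_gap = 2000L) {
  if (is.null(hits) || nrow(hits) == 0L) return(list())
  d <- hits[, 2L] - hits[, 1L]
  o <- order(d, hits[, 1L])
  q <- hits[o, 1L]; s <- hits[o, 2L]; d <- d[o]
  grp <- cumsum(c(1L, diff(d) > max_diag_gap))
  out <- list()
  for (idx in split(seq_along(grp), grp)) {
    oo <- idx[order(q[idx])]
    sub <- cumsum(c(1L, diff(q[oo]) > max_q_gap))
    for (jj in split(oo, sub)) {
      if (length(jj) < min_chain) next
      out[[length(out) + 1L]] <- list(
        q0 = min(q[jj]), q1 = max(q[jj]) + k,
        s0 = min(s[jj]), s1 = max(s[jj]) + k,
        n = length(jj), diag = stats::median(d[jj]))
    }
  }
  if (length(out) > 1L) {
    # deterministic order: seed-richest first, then coordinates
    ord <- order(-vapply(out, `[[`, integer(1), "n"),
                 vapply(out, `[[`, numeric(1), "q0"),
                 vapply(out, `[[`, numeric(1), "s0"))
    out <- out[ord]
  }
  out
}

# Align the full query against a subject window implied by a chain.
# The query is aligned end-to-end; subject overhangs are free.
# Returns NULL when the window collapses.
chain_align_query_global <- function(query, subject, chain, band) {
  nq <- nchar(query); ns <- nchar(subject)
  s_lo <- max(0L, chain$s0 - chain$q0 - band)
  s_hi <- min(ns, chain$s1 + (nq - chain$q1) + band)
  if (s_hi - s_lo < 1L) return(NULL)
  win <- substr(subject, s_lo + 1L, s_hi)
  al <- c_banded_align(query, win, band, TRUE, TRUE)
  al$s_start <- s_lo + al$b_start
  al$s_end <- s_lo + al$b_end
  al$identity <- al$matches / max(1L, al$columns)
  al
}

# Align only the seed-supported extent of the query (local block).
chain_align_block <- function(query, subject, chain, band) {
  nq <- nchar(query); ns <- nchar(subject)
  q0 <- max(0L, chain$q0); q1 <- min(nq, chain$q1)
  s_lo <- max(0L, chain$s0 - band)
  s_hi <- min(ns, chain$s1 + band)
  if (q1 - q0 < 1L || s_hi - s_lo < 1L) return(NULL)
  qs <- substr(query, q0 + 1L, q1)
  win <- substr(subject, s_lo + 1L, s_hi)
  al <- c_banded_align(qs, win, band, TRUE, TRUE)
  al$q_start <- q0
  al$q_end <- q1
  al$s_start <- s_lo + al$b_start
  al$s_end <- s_lo + al$b_end
  al$identity <- al$matches / max(1L, al$columns)
  al
}

# Find homology blocks of `query` on `subject`, both strands.
# Returns a data.frame of blocks with 0-based half-open coordinates on
# the forward strand of both sequences.
find_blocks <- function(query, subject, k = 15L, band = 150L,
                        min_chain = 3L, min_identity = 0,
                        max_chains = 20L, max_q_gap = 2000L) {
  nq <- nchar(query)
  res <- list()
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") query else revcomp(query)
    hits <- c_seed_hits(qq, subject, k)
    chains <- seed_chains(hits, k, max_diag_gap = band,
                          min_chain = min_chain, max_q_gap = max_q_gap)
    if (length(chains) > max_chains) chains <- chains[seq_len(max_chains)]
    for (ch in chains) {
      al <- chain_align_block(qq, subject, ch, band)
      if (is.null(al) || al$identity < min_identity) next
      qs <- al$q_start; qe <- al$q_end
      if (strand == "-") { tmp <- qs; qs <- nq - qe; qe <- nq - tmp }
      res[[length(res) + 1L]] <- data.frame(
        q_start = qs, q_end = qe, s_start = al$s_start, s_end = al$s_end,
        strand = strand, identity = al$identity, matches = al$matches,
        columns = al$columns, score = al$score,
        max_gap = max(al$max_ins, al$max_del), stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), identity = numeric(),
                      matches = integer(), columns = integer(),
                      score = integer(), max_gap = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(-out$score, out$q_start, out$s_start), , drop = FALSE]
}
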