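# Fully labelled synthetic inputs: circular mitogenomes with planted
# genes, simulated HiFi-class reads, NUMT-bearing nuclear backgrounds and
# heteroplasmic haplotype mixtures. Every read carries provenance so
# end-to-end accuracy can be scored against truth.

# Run expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mito_cds_names <- c("COX1", "COX2", "COX3", "CYTB", "ND1", "ND2", "ND3",
                    "ND4", "ND4L", "ND5", "ND6", "ATP6", "ATP8")
mito_trna_names <- c("trnF", "trnV", "trnL1", "trnI", "trnQ", "trnM",
                     "trnW", "trnA", "trnN", "trnC", "trnY", "trnS1",
                     "trnD", "trnK", "trnG", "trnR", "trnH", "trnS2",
                     "trnL2", "trnE", "trnT", "trnP")

#' Simulate a circular mitogenome with planted genes
#'
#' Builds a random circular sequence carrying non-overlapping planted
#' genes: protein-coding ORFs that are valid under the chosen genetic
#' code (start codon, stop codon, no internal stop), two rRNA-like
#' blocks, and tRNA-like 65-75 bp features including exactly one trnF
#' (tRNA-Phe), on mixed strands. Deterministic under `seed`.
#'
#' @param length Genome length in bp (>= 12000 for the default gene
#'   counts).
#' @param n_cds,n_trna,n_rrna Number of planted genes per class.
#' @param genetic_code_id NCBI translation-table id for the ORFs.
#' @param seed Integer seed.
#' @return A list of class `mito_truth`: `record` ([seq_record()]),
#'   `annotation` ([annotation_set()]), `genetic_code_id`.
#' @export
simulate_mitogenome <- function(length = 16500L, n_cds = 13L, n_trna = 22L,
                                n_rrna = 2L, genetic_code_id = 5L,
                                seed = 1L) {
  if (length < 12000L && (n_cds >= 13L))
    stop("length must be >= 12000 for the default gene counts")
  code <- genetic_code(genetic_code_id)
  if (n_cds > base::length(mito_cds_names) || n_trna > base::length(mito_trna_names))
    stop("too many genes requested")
  with_seed(seed, {
    non_stop <- setdiff(names(code$codons)[code$codons != "*"], character())
    make_cds <- function(n_codons) {
      paste0("ATG",
             paste(sample(non_stop, n_codons - 2L, replace = TRUE),
                   collapse = ""),
             sample(code$stop_codons, 1L))
    }
    genes <- list()
    for (nm in mito_cds_names[seq_len(n_cds)])
      genes[[nm]] <- list(kind = "CDS", seq = make_cds(sample(150:250, 1L)))
    rr <- c("rrnL", "rrnS")[seq_len(min(2L, n_rrna))]
    rr_len <- c(1400L, 950L)
    for (i in seq_along(rr))
      genes[[rr[i]]] <- list(kind = "rRNA", seq = random_dna(rr_len[i]))
    for (nm in mito_trna_names[seq_len(n_trna)])
      genes[[nm]] <- list(kind = "tRNA", seq = random_dna(sample(65:75, 1L)))
    total_gene <- sum(vapply(genes, function(g) nchar(g$seq), integer(1)))
    n_slots <- base::length(genes) + 1L
    spacer_total <- length - total_gene
    if (spacer_total < 10L * n_slots)
      stop("genome length too small for the requested gene content")
    # random spacer partition (each >= 10 bp)
    extra <- spacer_total - 10L * n_slots
    cuts <- sort(sample.int(extra + 1L, n_slots - 1L, replace = TRUE) - 1L)
    parts <- diff(c(0L, cuts, extra))
    spacers <- 10L + parts
    order_idx <- sample(base::length(genes))
    strands <- sample(c("+", "-"), base::length(genes), replace = TRUE)
    bases <- ""
    feats <- list()
    for (i in seq_along(order_idx)) {
      bases <- paste0(bases, random_dna(spacers[i]))
      g <- genes[[order_idx[i]]]
      nm <- names(genes)[order_idx[i]]
      start <- nchar(bases)
      s <- if (strands[i] == "-") revcomp(g$seq) else g$seq
      bases <- paste0(bases, s)
      quals <- list()
      if (g$kind == "CDS") quals$transl_table <- code$table_id
      feats[[base::length(feats) + 1L]] <- feature_record(
        "mito_truth", g$kind, start, start + nchar(g$seq), strands[i], nm,
        quals)
    }
    bases <- paste0(bases, random_dna(spacers[n_slots]))
    stopifnot(nchar(bases) == length)
    structure(list(
      record = seq_record("mito_truth", bases, "simulated circular mitogenome"),
      annotation = annotation_set("mito_truth", feats, code$table_id),
      genetic_code_id = code$table_id),
      class = "mito_truth")
  })
}

apply_read_errors <- function(s, sub_rate, indel_rate) {
  if (sub_rate <= 0 && indel_rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- base::length(v)
  alphabet <- c("A", "C", "G", "T")
  nsub <- rbinom(1L, n, sub_rate)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    for (p in pos) v[p] <- sample(setdiff(alphabet, v[p]), 1L)
  }
  nind <- rbinom(1L, n, indel_rate)
  if (nind > 0) {
    pos <- sort(sample.int(n, nind), decreasing = TRUE)
    for (p in pos) {
      if (runif(1L) < 0.5) v <- append(v, sample(alphabet, 1L), after = p)
      else v <- v[-p]
    }
  }
  paste(v, collapse = "")
}

#' Simulate long accurate reads from a (circular) genome
#'
#' Start positions are uniform on the circle (reads wrap the origin);
#' lengths follow a truncated normal (default mean 10 kb, sd 2 kb,
#' minimum 5 kb, capped at the genome length); substitution and indel
#' errors are i.i.d. at the stated rates (defaults 0.2 percent and 0.05
#' percent, the HiFi >Q20 regime). Provenance records every read's true
#' origin.
#'
#' @param sequence A [seq_record()] or bases string.
#' @param circular Sample across the origin.
#' @param coverage Target mean depth.
#' @param length_mean,length_sd,length_min Read-length distribution (bp).
#' @param sub_rate,indel_rate Per-base error rates.
#' @param seed Integer seed.
#' @param id_prefix Read-id prefix.
#' @param source Provenance source label.
#' @param haplotype Provenance haplotype label.
#' @return A list with `reads` (list of [seq_record()]) and `provenance`
#'   (data.frame: `read_id`, `source`, `start`, `strand`, `length`,
#'   `haplotype`).
#' @export
simulate_reads <- function(sequence, circular = TRUE, coverage = 30,
                           length_mean = 10000, length_sd = 2000,
                           length_min = 5000, sub_rate = 0.002,
                           indel_rate = 0.0005, seed = 1L,
                           id_prefix = "read", source = "mito",
                           haplotype = "h1") {
  b <- if (inherits(sequence, "seq_record")) sequence$bases else
    normalize_bases(sequence)
  L <- nchar(b)
  if (coverage <= 0) stop("coverage must be positive")
  n_reads <- max(1L, as.integer(ceiling(coverage * L / length_mean)))
  with_seed(seed, {
    lens <- integer(0)
    while (base::length(lens) < n_reads) {
      cand <- as.integer(round(rnorm(n_reads, length_mean, length_sd)))
      lens <- c(lens, cand[cand >= length_min])
    }
    lens <- pmin(lens[seq_len(n_reads)], L)
    starts <- if (circular) sample.int(L, n_reads, replace = TRUE) - 1L else
      vapply(lens, function(l) sample.int(max(1L, L - l + 1L), 1L) - 1L,
             integer(1))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    doubled <- if (circular) paste0(b, b) else b
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      s <- substr(doubled, starts[i] + 1L, starts[i] + lens[i])
      s <- apply_read_errors(s, sub_rate, indel_rate)
      if (strands[i] == "-") s <- revcomp(s)
      reads[[i]] <- seq_record(sprintf("%s_%05d", id_prefix, i), s)
    }
    prov <- data.frame(
      read_id = vapply(reads, `[[`, character(1), "id"),
      source = source, start = starts, strand = strands,
      length = vapply(reads, function(r) nchar(r$bases), integer(1)),
      true_span = lens, haplotype = haplotype, stringsAsFactors = FALSE)
    list(reads = reads, provenance = prov)
  })
}

#' Plant a NUMT in a random nuclear background
#'
#' Generates a random nuclear sequence and inserts a (optionally
#' diverged) fragment of the mitogenome at a recorded position,
#' emulating a nuclear-mitochondrial transfer.
#'
#' @param mito A `mito_truth` or [seq_record()].
#' @param nuclear_length Background length in bp.
#' @param fragment 0-based half-open interval of the mitogenome to
#'   transfer; `c(0, 0)` plants nothing (pure nuclear background).
#' @param divergence Per-base substitution rate applied to the fragment.
#' @param seed Integer seed.
#' @return A list of class `nuclear_truth`: `record` ([seq_record()]),
#'   `numt_interval` (0-based half-open interval on the nuclear
#'   sequence), `fragment` (the mitogenome interval), `divergence`.
#' @export
plant_numt <- function(mito, nuclear_length = 100000L, fragment = c(0L, 8000L),
                       divergence = 0.1, seed = 1L) {
  mb <- if (inherits(mito, "mito_truth")) mito$record$bases else mito$bases
  if (fragment[2L] < fragment[1L] || fragment[2L] > nchar(mb))
    stop("fragment interval must lie within the mitogenome")
  with_seed(seed, {
    frag <- if (fragment[2L] > fragment[1L])
      substr(mb, fragment[1L] + 1L, fragment[2L]) else ""
    if (nzchar(frag) && divergence > 0)
      frag <- apply_read_errors(frag, divergence, 0)
    nuc <- random_dna(nuclear_length)
    pos <- sample.int(nuclear_length - 1L, 1L)
    rec <- paste0(substr(nuc, 1L, pos), frag,
                  substr(nuc, pos + 1L, nuclear_length))
    structure(list(
      record = seq_record("nuclear_truth", rec,
                          "synthetic nuclear background with planted NUMT"),
      numt_interval = c(pos, pos + nchar(frag)),
      fragment = fragment, divergence = divergence),
      class = "nuclear_truth")
  })
}

#' Create heteroplasmic haplotypes
#'
#' Derives a second haplotype from the mitogenome truth by the described
#' edit (an insertion of random sequence, or point substitutions) and
#' attaches the stated frequencies.
#'
#' @param mito A `mito_truth`.
#' @param edit List describing the edit: `type` (`"insertion"` or
#'   `"substitutions"`), `pos` (0-based position; `NULL` picks an
#'   intergenic spacer), `length` (insertion length) or `n`
#'   (substitution count).
#' @param frequencies Numeric vector of haplotype frequencies summing to
#'   1 (first entry: the unedited haplotype).
#' @param seed Integer seed.
#' @return A list of class `heteroplasmy_truth`: `haplotypes` (list of
#'   `list(record, frequency)`), `edit` (with the realized position).
#' @export
simulate_heteroplasmy <- function(mito, edit = list(type = "insertion",
                                                    pos = NULL, length = 100L),
                                  frequencies = c(0.5, 0.5), seed = 1L) {
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1")
  b <- mito$record$bases
  n <- nchar(b)
  with_seed(seed, {
    pos <- edit$pos
    if (is.null(pos)) {
      # pick a position between two genes
      df <- feature_df(mito$annotation)
      df <- df[order(df$start), ]
      gaps <- data.frame(from = df$end[-nrow(df)], to = df$start[-1L])
      gaps <- gaps[gaps$to - gaps$from >= 20L, , drop = FALSE]
      g <- gaps[sample.int(nrow(gaps), 1L), ]
      pos <- as.integer((g$from + g$to) %/% 2L)
    }
    type <- edit$type %||% "insertion"
    h2 <- if (identical(type, "insertion")) {
      len <- edit$length %||% 100L
      if (len > 0L)
        paste0(substr(b, 1L, pos), random_dna(len), substr(b, pos + 1L, n))
      else b
    } else if (identical(type, "substitutions")) {
      k <- edit$n %||% 10L
      v <- strsplit(b, "", fixed = TRUE)[[1]]
      if (k > 0L) {
        at <- sample.int(n, k)
        for (p in at) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
      }
      paste(v, collapse = "")
    } else stop("unsupported edit type: ", type)
    recs <- list(
      list(record = seq_record("hap1", b), frequency = frequencies[1L]),
      list(record = seq_record("hap2", h2), frequency = frequencies[2L]))
    structure(list(haplotypes = recs,
                   edit = list(type = type, pos = pos,
                               length = edit$length %||% NA_integer_,
                               n = edit$n %||% NA_integer_)),
              class = "heteroplasmy_truth")
  })
}

#' Simulate reads from a heteroplasmic mixture
#'
#' Draws reads from each haplotype at `coverage * frequency`, merging
#' the provenance with haplotype labels.
#'
#' @param het A `heteroplasmy_truth`.
#' @param coverage Total target depth across haplotypes.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_reads()].
#' @return A list with `reads` and `provenance` as in [simulate_reads()].
#' @export
simulate_heteroplasmy_reads <- function(het, coverage = 30, seed = 1L, ...) {
  out_reads <- list()
  out_prov <- list()
  for (i in seq_along(het$haplotypes)) {
    h <- het$haplotypes[[i]]
    if (h$frequency <= 0) next
    sim <- simulate_reads(h$record, coverage = coverage * h$frequency,
                          seed = seed + i,
                          id_prefix = paste0(h$record$id, "_read"),
                          haplotype = h$record$id, ...)
    out_reads <- c(out_reads, sim$reads)
    out_prov[[base::length(out_prov) + 1L]] <- sim$provenance
  }
  list(reads = out_reads, provenance = do.call(rbind, out_prov))
}
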