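# Brute-force overlap oracle for error-free reads: every dovetail
# suffix-prefix match and every exact containment, found by direct string
# comparison. Mirrors the conventions of compute_overlaps(): for a read
# pair (i < j in list order) read i is always taken forward and read j in
# both orientations; an edge (a -> b) means a's suffix matches b's
# prefix, with a_hang bases of a preceding the overlap and to_span bases
# of b consumed by it.
oracle_overlaps <- function(reads, min_overlap) {
  ids <- vapply(reads, `[[`, character(1), "id")
  bases <- lapply(reads, `[[`, "bases")
  n <- length(reads)
  edges <- list()
  cont <- list()
  add <- function(from, fs, to, ts, a_hang, olen) {
    edges[[length(edges) + 1L]] <<- data.frame(
      a_id = from, a_strand = fs, b_id = to, b_strand = ts,
      a_hang = a_hang, overlap_len = olen, to_span = olen,
      stringsAsFactors = FALSE)
  }
  dovetail <- function(a, b) {
    # all t with suffix(a, from t) == prefix(b) and b extending past a
    na <- nchar(a); nb <- nchar(b)
    hits <- integer()
    for (t in seq_len(na - 1L)) {
      olen <- na - t
      if (olen < min_overlap || olen >= nb) next
      if (substr(a, t + 1L, na) == substr(b, 1L, olen))
        hits <- c(hits, t)
    }
    hits
  }
  if (n > 1) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    for (orient in c("+", "-")) {
      b_or <- if (orient == "+") bases[[j]] else revcomp(bases[[j]])
      a <- bases[[i]]
      if (nchar(b_or) <= nchar(a) && grepl(b_or, a, fixed = TRUE)) {
        cont[[length(cont) + 1L]] <- data.frame(
          inner = ids[j], outer = ids[i], stringsAsFactors = FALSE)
        next
      }
      if (nchar(a) < nchar(b_or) && grepl(a, b_or, fixed = TRUE)) {
        cont[[length(cont) + 1L]] <- data.frame(
          inner = ids[i], outer = ids[j], stringsAsFactors = FALSE)
        next
      }
      for (t in dovetail(a, b_or))
        add(ids[i], "+", ids[j], orient, t, nchar(a) - t)
      for (t in dovetail(b_or, a))
        add(ids[j], orient, ids[i], "+", t, nchar(b_or) - t)
    }
  }
  ov <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a_id = character(), a_strand = character(),
               b_id = character(), b_strand = character(),
               a_hang = integer(), overlap_len = integer(),
               to_span = integer(), stringsAsFactors = FALSE)
  if (nrow(ov)) { # keep the longest overlap per directed oriented pair
    ov <- ov[order(-ov$overlap_len), , drop = FALSE]
    ov <- ov[!duplicated(paste(ov$a_id, ov$a_strand, ov$b_id, ov$b_strand)), ,
             drop = FALSE]
  }
  cn <- if (length(cont)) unique(do.call(rbind, cont)) else
    data.frame(inner = character(), outer = character(),
               stringsAsFactors = FALSE)
  list(overlaps = ov, containments = cn)
}

# Draw one error-free random read instance whose pairwise relations are
# unambiguous (all dovetail hangs and extensions >= 100 bp), suitable for
# exact comparison with the seed-and-extend implementation.
oracle_instance <- function(seed, max_reads = 12L) {
  set.seed(seed)
  repeat {
    G <- sample(2500:4000, 1L)
    genome <- paste(sample(c("A", "C", "G", "T"), G, replace = TRUE),
                    collapse = "")
    start <- 0L
    spans <- list()
    while (length(spans) < max_reads) {
      len <- sample(300:800, 1L)
      if (start + len > G) break
      spans[[length(spans) + 1L]] <- c(start, len)
      step <- sample(seq(120L, len - 120L), 1L)
      start <- start + step
    }
    if (length(spans) < 4L) next
    reads <- lapply(seq_along(spans), function(i) {
      s <- spans[[i]]
      b <- substr(genome, s[1] + 1L, s[1] + s[2])
      if (runif(1) < 0.5) b <- revcomp(b)
      seq_record(sprintf("r%02d", i), b)
    })
    reads <- reads[sample(length(reads))]
    # reject instances with ambiguous near-boundary relations
    ids <- vapply(reads, `[[`, character(1), "id")
    pos <- lapply(spans, function(s) c(s[1], s[1] + s[2]))
    names(pos) <- sprintf("r%02d", seq_along(spans))
    clean <- TRUE
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      if (i == j) next
      a <- pos[[i]]; b <- pos[[j]]
      ol <- min(a[2], b[2]) - max(a[1], b[1])
      if (ol <= 0) next
      margins <- abs(c(a[1] - b[1], a[2] - b[2]))
      contained <- (b[1] >= a[1] && b[2] <= a[2]) ||
        (a[1] >= b[1] && a[2] <= b[2])
      if (!contained && any(margins > 0 & margins < 100)) clean <- FALSE
      if (ol > 0 && ol < 120 && ol >= 90) clean <- FALSE
    }
    if (clean) return(reads)
  }
}
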