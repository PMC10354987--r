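# Shared fixtures, memoized so expensive simulations and pipeline runs
# are computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A small planted genome for fast unit tests.
small_truth <- function() fixture("small_truth",
  simulate_mitogenome(length = 5000L, n_cds = 3L, n_trna = 4L, n_rrna = 1L,
                      seed = 7L))

# The full-size study genome used by the acceptance criteria.
acc_truth <- function() fixture("acc_truth", simulate_mitogenome(seed = 101L))

acc_reads <- function() fixture("acc_reads",
  simulate_reads(acc_truth()$record, coverage = 30, seed = 102L))

# Global alignment identity via an independent oracle (Biostrings).
oracle_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# Are two sequences equal as cyclic strings, up to strand?
cyclic_equal <- function(x, truth) {
  if (nchar(x) != nchar(truth)) return(FALSE)
  dd <- paste0(truth, truth)
  grepl(x, dd, fixed = TRUE) || grepl(revcomp(x), dd, fixed = TRUE)
}

# Best cyclic identity of x against circular truth (tries both strands;
# truth is rotated so the comparison is start-independent).
cyclic_identity <- function(x, truth) {
  L <- nchar(truth)
  dd <- paste0(truth, truth)
  best <- 0
  for (q in c(x, revcomp(x))) {
    # anchor the rotation with an exact 31-mer from the query; several
    # probe offsets are tried in case one lands on a sequencing error
    rot <- truth
    for (off in c(0L, 997L, 2501L, 5003L)) {
      if (off + 31L > nchar(q)) next
      probe <- substr(q, off + 1L, off + 31L)
      at <- regexpr(probe, dd, fixed = TRUE)
      if (at > 0) {
        shift <- (as.integer(at) - 1L - off) %% L
        rot <- substr(dd, shift + 1L, shift + L)
        break
      }
    }
    best <- max(best, oracle_identity(q, rot))
  }
  best
}
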