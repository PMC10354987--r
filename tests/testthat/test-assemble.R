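test_that("compute_overlaps matches the brute-force oracle on small instances", {
  cfg <- pipeline_config(min_overlap = 100L)
  for (seed in c(21L, 22L)) {
    reads <- oracle_instance(seed)
    got <- compute_overlaps(reads, min_overlap = 100L, config = cfg)
    want <- oracle_overlaps(reads, min_overlap = 100L)
    key <- function(df) {
      if (!nrow(df)) return(character())
      sort(sprintf("%s%s->%s%s hang=%d len=%d span=%d", df$a_id, df$a_strand,
                   df$b_id, df$b_strand, df$a_hang, df$overlap_len,
                   df$to_span))
    }
    expect_equal(key(got$overlaps), key(want$overlaps))
    expect_true(all(got$overlaps$identity == 1))
    ckey <- function(df) sort(paste(df$inner, df$outer))
    expect_equal(ckey(got$containments), ckey(want$containments))
  }
})

test_that("contained reads are flagged and never extend a layout", {
  truth <- small_truth()$record$bases
  outer <- seq_record("outer", substr(truth, 1, 2400))
  inner <- seq_record("inner", substr(truth, 501, 2000))
  nxt <- seq_record("next", substr(truth, 1201, 3600))
  cfg <- pipeline_config()
  ov <- compute_overlaps(list(outer, inner, nxt), config = cfg)
  expect_true(any(ov$containments$inner == "inner" &
                    ov$containments$outer == "outer"))
  layouts <- greedy_layout(ov, list(outer, inner, nxt), cfg)
  placed <- unlist(lapply(layouts, `[[`, "read_id"))
  expect_false("inner" %in% placed)
  expect_equal(sort(layouts[[1]]$read_id), c("next", "outer"))
})

test_that("greedy layout closes a cycle on circular read sets", {
  truth <- small_truth()$record
  cfg <- pipeline_config()
  sim <- simulate_reads(truth, coverage = 12, length_mean = 2000,
                        length_sd = 250, length_min = 1500,
                        sub_rate = 0, indel_rate = 0, seed = 11L)
  ov <- compute_overlaps(sim$reads, config = cfg)
  layouts <- greedy_layout(ov, sim$reads, cfg)
  expect_true(isTRUE(attr(layouts[[1]], "cyclic")))
  dc <- call_consensus(layouts[[1]], sim$reads, cfg)
  expect_true(dc$layout_is_cyclic)
  # the linearized cycle carries terminal redundancy over a full turn
  expect_gte(nchar(dc$bases), nchar(truth$bases))
  # and its first genome-length window equals the truth cyclically
  expect_true(grepl(substr(dc$bases, 1, nchar(truth$bases)),
                    paste0(truth$bases, truth$bases), fixed = TRUE) ||
              grepl(revcomp(substr(dc$bases, 1, nchar(truth$bases))),
                    paste0(truth$bases, truth$bases), fixed = TRUE))
})

test_that("a layout without a closing overlap is closed by circularization", {
  # at coverage 8 this read set has one junction where consecutive read
  # starts are more than (read length - min_overlap) apart, so the
  # overlap graph has no cycle; the layout stays linear but still spans a
  # full turn plus redundancy, which circularization then detects
  truth <- small_truth()$record
  cfg <- pipeline_config()
  sim <- simulate_reads(truth, coverage = 8, length_mean = 2000,
                        length_sd = 250, length_min = 1500,
                        sub_rate = 0, indel_rate = 0, seed = 11L)
  ov <- compute_overlaps(sim$reads, config = cfg)
  layouts <- greedy_layout(ov, sim$reads, cfg)
  expect_false(isTRUE(attr(layouts[[1]], "cyclic")))
  dc <- call_consensus(layouts[[1]], sim$reads, cfg)
  expect_gt(nchar(dc$bases), nchar(truth$bases))
  res <- detect_terminal_redundancy(dc, cfg)
  expect_true(res$is_circular)
  tr <- trim_redundancy(dc, res, cfg)
  expect_true(cyclic_equal(tr$contig$bases, truth$bases))
})

test_that("assemble recovers the genome from error-free reads", {
  truth <- small_truth()$record
  sim <- simulate_reads(truth, coverage = 8, length_mean = 2000,
                        length_sd = 250, length_min = 1500,
                        sub_rate = 0, indel_rate = 0, seed = 12L)
  contigs <- assemble(sim$reads, pipeline_config())
  expect_gte(length(contigs), 1L)
  main <- contigs[[1]]
  expect_equal(main$id, "contig_1")
  expect_true(main$layout_is_cyclic)
  expect_gte(length(main$supporting_read_ids), 0.9 * length(sim$reads))
})

test_that("consensus polishing fixes isolated substitution errors", {
  truth <- small_truth()$record
  sim <- simulate_reads(truth, coverage = 10, length_mean = 2000,
                        length_sd = 250, length_min = 1500,
                        sub_rate = 0.002, indel_rate = 0.0005, seed = 13L)
  contigs <- assemble(sim$reads, pipeline_config())
  main <- contigs[[1]]
  # trim the cyclic redundancy, then compare to truth
  tr <- detect_terminal_redundancy(main, pipeline_config())
  expect_true(tr$is_circular)
  trimmed <- trim_redundancy(main, tr, pipeline_config())$contig
  expect_gte(cyclic_identity(trimmed$bases, truth$bases), 0.999)
})

test_that("accept_contigs passes sequences through byte-identically", {
  recs <- list(seq_record("c1", "ACGTACGTACGT"),
               seq_record("c2", "TTTTGGGGCCCC"))
  out <- accept_contigs(recs)
  expect_equal(names(out), c("c1", "c2"))
  expect_equal(out$c1$bases, "ACGTACGTACGT")
  expect_s3_class(out$c2, "draft_contig")
  expect_error(accept_contigs(list()), "no contigs")
})
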