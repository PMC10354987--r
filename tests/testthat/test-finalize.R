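mk_ann <- function(cid, genes, kinds = NULL, strands = NULL) {
  if (is.null(kinds)) kinds <- rep("tRNA", length(genes))
  if (is.null(strands)) strands <- rep("+", length(genes))
  feats <- lapply(seq_along(genes), function(i)
    feature_record(cid, kinds[i], 100L * i, 100L * i + 70L, strands[i],
                   genes[i]))
  annotation_set(cid, feats, 5L)
}

test_that("rotation anchor prefers trnF, then the most frequent tRNA", {
  a1 <- mk_ann("c1", c("trnF", "trnV"))
  a2 <- mk_ann("c2", c("trnV"))
  expect_equal(choose_rotation_anchor(list(c1 = a1, c2 = a2)), "trnF")
  # no trnF anywhere: most frequent wins, ties lexicographic
  b1 <- mk_ann("c1", c("trnV", "trnA"))
  b2 <- mk_ann("c2", c("trnV", "trnW"))
  expect_equal(choose_rotation_anchor(list(c1 = b1, c2 = b2)), "trnV")
  t1 <- mk_ann("c1", c("trnW", "trnA"))
  expect_equal(choose_rotation_anchor(list(c1 = t1)), "trnA")
  # no tRNA at all: NA with a warning
  n1 <- mk_ann("c1", "COX1", kinds = "CDS")
  expect_warning(anchor <- choose_rotation_anchor(list(c1 = n1)),
                 "rotation skipped")
  expect_true(is.na(anchor))
})

test_that("rotation starts the contig at the anchor and preserves the cycle", {
  truth <- small_truth()
  ct <- draft_contig("c1", truth$record$bases, layout_is_cyclic = TRUE)
  feats <- lapply(truth$annotation$features, function(f) {
    f$seq_id <- "c1"; f
  })
  ann <- annotation_set("c1", feats, 5L)
  rot <- rotate_contig(ct, ann, "trnF")
  df <- hifimito:::feature_df(rot$annotation)
  i <- which(df$name == "trnF")
  expect_equal(df$start[i], 0L)
  expect_equal(df$strand[i], "+")
  expect_true(cyclic_equal(rot$contig$bases, truth$record$bases))
  # every gene sequence is preserved by the rotation
  for (f in rot$annotation$features) {
    ref_f <- Filter(function(g) g$name == f$name, truth$annotation$features)[[1]]
    expect_equal(hifimito:::extract_feature_seq(rot$contig$bases, f),
                 hifimito:::extract_feature_seq(truth$record$bases, ref_f))
  }
})

test_that("a minus-strand anchor reverse-complements before rotating", {
  truth <- small_truth()
  b <- truth$record$bases
  rc <- revcomp(b)
  n <- nchar(b)
  ct <- draft_contig("c1", rc, layout_is_cyclic = TRUE)
  feats <- lapply(truth$annotation$features, function(f) {
    g <- f
    g$seq_id <- "c1"
    new_start <- n - f$end
    g$end <- n - f$start
    g$start <- new_start
    g$strand <- if (f$strand == "+") "-" else "+"
    g
  })
  ann <- annotation_set("c1", feats, 5L)
  rot <- rotate_contig(ct, ann, "trnF")
  df <- hifimito:::feature_df(rot$annotation)
  i <- which(df$name == "trnF")
  expect_equal(df$start[i], 0L)
  expect_equal(df$strand[i], "+")
  expect_true(cyclic_equal(rot$contig$bases, b))
})

test_that("rotation is idempotent once the anchor is at base one", {
  truth <- small_truth()
  ct <- draft_contig("c1", truth$record$bases, layout_is_cyclic = TRUE)
  feats <- lapply(truth$annotation$features, function(f) {
    f$seq_id <- "c1"; f
  })
  ann <- annotation_set("c1", feats, 5L)
  once <- rotate_contig(ct, ann, "trnF")
  twice <- rotate_contig(once$contig, once$annotation, "trnF")
  expect_equal(twice$contig$bases, once$contig$bases)
  expect_equal(hifimito:::feature_df(twice$annotation),
               hifimito:::feature_df(once$annotation))
})

test_that("a missing anchor leaves the contig unrotated with a warning", {
  truth <- small_truth()
  ct <- draft_contig("c1", truth$record$bases)
  ann <- mk_ann("c1", "trnV")
  expect_warning(rot <- rotate_contig(ct, ann, "trnQ"), "not annotated")
  expect_equal(rot$contig$bases, truth$record$bases)
})

test_that("selection follows the documented A/B/C preference order", {
  mk <- function(id, len, genes, fs, circ)
    data.frame(contig_id = id, length_bp = len, gene_count = genes,
               frameshift_count = fs, is_circular = circ,
               stringsAsFactors = FALSE)
  ref_len <- 16000L
  # full pass beats higher-ranked candidates failing a criterion
  r <- rank_and_select(rbind(
    mk("big_genes_linear", 16000L, 37L, 0L, FALSE),
    mk("all_good", 16100L, 35L, 0L, TRUE)), ref_len)
  expect_equal(r$final_id, "all_good")
  # circular + size beats circular + frameshift-free when nothing passes all
  r <- rank_and_select(rbind(
    mk("circ_size_fs", 16000L, 37L, 2L, TRUE),
    mk("circ_nofs_oversize", 2L * ref_len, 36L, 0L, TRUE)), ref_len)
  expect_equal(r$final_id, "circ_size_fs")
  # then circular + frameshift-free
  r <- rank_and_select(rbind(
    mk("circ_nofs_oversize", 2L * ref_len, 37L, 0L, TRUE),
    mk("linear_good", 16000L, 36L, 0L, FALSE)), ref_len)
  expect_equal(r$final_id, "circ_nofs_oversize")
  # then any circular
  r <- rank_and_select(rbind(
    mk("circ_bad", 2L * ref_len, 37L, 3L, TRUE),
    mk("linear_good", 16000L, 36L, 0L, FALSE)), ref_len)
  expect_equal(r$final_id, "circ_bad")
  # no circular candidate: top-ranked wins with a warning
  expect_warning(
    r <- rank_and_select(rbind(
      mk("lin1", 16000L, 37L, 0L, FALSE),
      mk("lin2", 16000L, 30L, 0L, FALSE)), ref_len),
    "no circular")
  expect_equal(r$final_id, "lin1")
  expect_equal(sum(r$ranked$is_final), 1L)
})

test_that("ranking orders by gene count, then length closeness, then id", {
  mk <- function(id, len, genes)
    data.frame(contig_id = id, length_bp = len, gene_count = genes,
               frameshift_count = 0L, is_circular = TRUE,
               stringsAsFactors = FALSE)
  r <- rank_and_select(rbind(mk("b", 15000L, 30L), mk("a", 16100L, 30L),
                             mk("c", 16200L, 35L)), 16000L)
  expect_equal(r$ranked$contig_id, c("c", "a", "b"))
  expect_equal(r$ranked$selection_rank, 1:3)
})

test_that("coverage accumulates depth and honours the mapq floor", {
  truth <- small_truth()$record
  ct <- draft_contig("c1", truth$bases)
  reads <- list(seq_record("r1", substr(truth$bases, 1, 2000)),
                seq_record("r2", substr(truth$bases, 1001, 3000)))
  cov <- compute_coverage(reads, list(c1 = ct), pipeline_config())
  expect_equal(nrow(cov), nchar(truth$bases))
  expect_equal(cov$depth[1500], 2L)
  expect_equal(cov$depth[2500], 1L)
  expect_equal(cov$depth[4000], 0L)
  # an impossible mapq floor removes all reads
  cov0 <- compute_coverage(reads, list(c1 = ct),
                           pipeline_config(cov_mapq_min = 61L))
  expect_true(all(cov0$depth == 0L))
})
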