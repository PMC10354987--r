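test_that("genetic_code wraps the NCBI tables correctly", {
  c5 <- genetic_code(5L)
  expect_equal(c5$table_id, 5L)
  expect_equal(unname(c5$codons["ATA"]), "M") # invertebrate mito reassignment
  expect_equal(unname(c5$codons["TGA"]), "W")
  expect_true(all(c("TAA", "TAG") %in% c5$stop_codons))
  expect_true("ATG" %in% c5$start_codons)
  c1 <- genetic_code(1L)
  expect_equal(unname(c1$codons["ATA"]), "I")
  expect_true("TGA" %in% c1$stop_codons)
  expect_error(genetic_code(99L), "unsupported")
})

test_that("translate_cds handles frames, stops and N codons", {
  code <- genetic_code(5L)
  expect_equal(hifimito:::translate_cds("ATGAAATAA", code), "MK*")
  expect_equal(hifimito:::translate_cds("ATGAANTAA", code), "MX*")
  expect_equal(hifimito:::translate_cds("ATGAAATA", code), "MK") # partial codon
})

test_that("feature sequences extract across the origin and minus strand", {
  bases <- paste0(strrep("A", 90), "CCCGGGTTT")  # length 99
  f <- feature_record("s", "rRNA", 93, 102, "+", "x",
                      list(origin_spanning = TRUE))
  expect_equal(hifimito:::extract_feature_seq(bases, f),
               paste0("GGGTTT", "AAA"))
  fm <- feature_record("s", "rRNA", 90, 96, "-", "y")
  expect_equal(hifimito:::extract_feature_seq(bases, fm),
               revcomp("CCCGGG"))
})

test_that("annotation transfer recovers all genes on an exact copy", {
  truth <- small_truth()
  ct <- draft_contig("c1", truth$record$bases)
  res <- transfer_features(truth$record, truth$annotation, ct,
                           pipeline_config(), circular = TRUE)
  expect_equal(length(res$missing), 0L)
  a <- hifimito:::feature_df(truth$annotation)
  b <- hifimito:::feature_df(res$annotation)
  expect_equal(nrow(b), nrow(a))
  expect_equal(b[, c("kind", "start", "end", "strand", "name")],
               a[, c("kind", "start", "end", "strand", "name")],
               ignore_attr = TRUE)
  fs <- vapply(res$annotation$features, function(f)
    isTRUE(f$qualifiers$frameshift), logical(1))
  expect_false(any(fs))
})

test_that("annotation transfer places genes across a rotated origin", {
  truth <- small_truth()
  b <- truth$record$bases
  n <- nchar(b)
  shift <- 2500L
  rotated <- draft_contig("rot", paste0(substr(b, shift + 1L, n),
                                        substr(b, 1L, shift)))
  res <- transfer_features(truth$record, truth$annotation, rotated,
                           pipeline_config(), circular = TRUE)
  expect_equal(length(res$missing), 0L)
  # every transferred gene's sequence equals the reference gene sequence
  for (f in res$annotation$features) {
    ref_f <- Filter(function(g) g$name == f$name, truth$annotation$features)[[1]]
    expect_equal(hifimito:::extract_feature_seq(rotated$bases, f),
                 hifimito:::extract_feature_seq(b, ref_f))
  }
})

test_that("frameshift detection: 1 bp deletion flagged, 3 bp not", {
  truth <- small_truth()
  cds <- Filter(function(f) f$kind == "CDS", truth$annotation$features)[[1]]
  b <- truth$record$bases
  del_at <- cds$start + 30L
  mut1 <- paste0(substr(b, 1, del_at), substr(b, del_at + 2L, nchar(b)))
  mut3 <- paste0(substr(b, 1, del_at), substr(b, del_at + 4L, nchar(b)))
  cfg <- pipeline_config()
  get_call <- function(bases) {
    ct <- draft_contig("m", bases)
    res <- transfer_features(truth$record, truth$annotation, ct, cfg,
                             circular = TRUE)
    Filter(function(f) f$name == cds$name, res$annotation$features)[[1]]
  }
  expect_true(isTRUE(get_call(mut1)$qualifiers$frameshift))
  expect_false(isTRUE(get_call(mut3)$qualifiers$frameshift))
})

test_that("frameshift detection works identically on the minus strand", {
  truth <- small_truth()
  cdss <- Filter(function(f) f$kind == "CDS", truth$annotation$features)
  strands <- vapply(cdss, `[[`, character(1), "strand")
  # the fixture has CDS on both strands; pick a minus-strand one
  expect_true(any(strands == "-"))
  cds <- cdss[strands == "-"][[1]]
  b <- truth$record$bases
  del_at <- cds$start + 31L
  mut1 <- paste0(substr(b, 1, del_at), substr(b, del_at + 2L, nchar(b)))
  res <- transfer_features(truth$record, truth$annotation,
                           draft_contig("m", mut1), pipeline_config(),
                           circular = TRUE)
  call <- Filter(function(f) f$name == cds$name, res$annotation$features)[[1]]
  expect_equal(call$strand, "-")
  expect_true(isTRUE(call$qualifiers$frameshift))
})

test_that("detect_frameshift unit behaviour matches its definition", {
  code <- genetic_code(5L)
  # clean CDS: span mod 3 matches, no internal stop
  bases <- "ATGAAACCCGGGTTTTAA"
  call <- feature_record("c", "CDS", 0, 18, "+", "g")
  expect_false(detect_frameshift(call, bases, code, ref_cds_len = 18L))
  # early internal stop within the same frame length
  bases_stop <- "ATGTAACCCGGGTTTTAA"
  expect_true(detect_frameshift(call, bases_stop, code, ref_cds_len = 18L))
  # span mod 3 mismatch is flagged without translation
  call17 <- feature_record("c", "CDS", 0, 17, "+", "g")
  expect_true(detect_frameshift(call17, substr(bases, 1, 17), code,
                                ref_cds_len = 18L))
  expect_error(detect_frameshift(
    feature_record("c", "tRNA", 0, 18, "+", "g"), bases, code, 18L), "CDS")
})

test_that("count_genes builds the shared/missing matrix", {
  truth <- small_truth()
  ct <- draft_contig("c1", truth$record$bases)
  res <- transfer_features(truth$record, truth$annotation, ct,
                           pipeline_config(), circular = TRUE)
  # rebuild a 3-feature subset under its own contig id
  feats <- lapply(res$annotation$features[1:3], function(f) {
    f$seq_id <- "c2"; f
  })
  partial <- annotation_set("c2", feats, 5L)
  g <- count_genes(list(c1 = res$annotation, c2 = partial), truth$annotation)
  expect_equal(unname(g$counts["c1"]), length(truth$annotation$features))
  expect_equal(unname(g$counts["c2"]), 3L)
  expect_true(all(g$matrix[, "c1"]))
  expect_equal(sum(g$matrix[, "c2"]), 3L)
  expect_equal(length(g$missing$c1), 0L)
})
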