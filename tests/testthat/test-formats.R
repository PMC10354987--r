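test_that("FASTA round trip preserves ids, descriptions and bases", {
  recs <- list(seq_record("a", "ACGTACGTAC", "first record"),
               seq_record("b", paste(rep("ACGT", 40), collapse = "")))
  path <- tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(vapply(back, `[[`, character(1), "id"), c("a", "b"))
  expect_equal(back[[1]]$description, "first record")
  expect_equal(vapply(back, `[[`, character(1), "bases"),
               vapply(recs, `[[`, character(1), "bases"))
})

test_that("FASTQ input is accepted and qualities are discarded", {
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1 desc", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "TTTTCCCC", "+", "########"), path)
  back <- read_fasta(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$bases, "ACGTACGT")
  expect_equal(back[[2]]$id, "r2")
})

test_that("unreadable sequence input gives a clear parse error", {
  empty <- tempfile()
  file.create(empty)
  expect_error(read_fasta(empty), "no sequences")
  junk <- tempfile()
  writeLines(c("not a fasta", "ACGT"), junk)
  expect_error(read_fasta(junk), "parse error at line 1")
  expect_error(read_fasta(tempfile()), "file not found")
})

test_that("GenBank location strings parse and format per convention", {
  loc <- hifimito:::parse_gb_location("1..900", 1000L)
  expect_equal(c(loc$start, loc$end), c(0L, 900L))
  expect_equal(loc$strand, "+")
  loc <- hifimito:::parse_gb_location("complement(11..40)", 1000L)
  expect_equal(c(loc$start, loc$end), c(10L, 40L))
  expect_equal(loc$strand, "-")
  loc <- hifimito:::parse_gb_location("join(951..1000,1..50)", 1000L)
  expect_true(loc$origin_spanning)
  expect_equal(c(loc$start, loc$end), c(950L, 1050L))
  expect_error(hifimito:::parse_gb_location("10..2000", 1000L), "beyond")

  f <- feature_record("s", "CDS", 950, 1050, "-", "x",
                      list(origin_spanning = TRUE))
  expect_equal(hifimito:::format_gb_location(f, 1000L),
               "complement(join(951..1000,1..50))")
})

test_that("GenBank write/read round trip preserves record and features", {
  truth <- small_truth()
  path <- tempfile(fileext = ".gb")
  write_genbank(truth$record, truth$annotation, path)
  back <- read_genbank(path)
  expect_equal(back$record$bases, truth$record$bases)
  a <- hifimito:::feature_df(truth$annotation)
  b <- hifimito:::feature_df(back$annotation)
  b$seq_id <- a$seq_id
  expect_equal(b[, c("kind", "start", "end", "strand", "name")],
               a[, c("kind", "start", "end", "strand", "name")])
  expect_equal(back$annotation$genetic_code_id,
               truth$annotation$genetic_code_id)
})

test_that("GenBank round trip keeps an origin-spanning feature", {
  rec <- seq_record("circ", paste(rep("ACGT", 100), collapse = ""))
  f <- feature_record("circ", "CDS", 350, 430, "+", "COX1",
                      list(origin_spanning = TRUE, transl_table = 5L))
  ann <- annotation_set("circ", list(f), 5L)
  path <- tempfile(fileext = ".gb")
  write_genbank(rec, ann, path)
  back <- read_genbank(path)
  bf <- back$annotation$features[[1]]
  expect_equal(c(bf$start, bf$end), c(350L, 430L))
  expect_true(hifimito:::feature_is_origin_spanning(bf))
})

test_that("GFF3 output is valid per the rtracklayer oracle", {
  skip_if_not_installed("rtracklayer")
  truth <- small_truth()
  path <- tempfile(fileext = ".gff")
  write_gff3(truth$annotation, path, seq_len = nchar(truth$record$bases))
  gr <- rtracklayer::import(path)
  df <- hifimito:::feature_df(truth$annotation)
  expect_equal(length(gr), nrow(df))
  expect_equal(sort(BiocGenerics::start(gr)), sort(df$start + 1L))
  expect_equal(sort(BiocGenerics::end(gr)), sort(df$end))
})

test_that("GFF3 splits origin-spanning features into two part lines", {
  f <- feature_record("c", "rRNA", 900, 1060, "+", "rrnL",
                      list(origin_spanning = TRUE))
  ann <- annotation_set("c", list(f), 5L)
  path <- tempfile(fileext = ".gff")
  write_gff3(ann, path, seq_len = 1000L)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  body <- read.delim(path, header = FALSE, comment.char = "#")
  expect_equal(nrow(body), 2L)
  expect_equal(body$V4, c(901L, 1L))
  expect_equal(body$V5, c(1000L, 60L))
  expect_equal(body$V9[1], body$V9[2]) # shared ID
})

test_that("TSV writer formats mixed column types stably", {
  df <- data.frame(id = c("a", "b"), n = c(1L, 2L),
                   frac = c(0.5, 0.123456789), flag = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  hifimito:::write_tsv(df, path, comment = "# hello")
  lines <- readLines(path)
  expect_equal(lines[1], "# hello")
  expect_equal(lines[2], "id\tn\tfrac\tflag")
  expect_equal(lines[3], "a\t1\t0.5\tTRUE")
  back <- read.delim(path, comment.char = "#")
  expect_equal(back$frac, c(0.5, 0.123457), tolerance = 1e-6)
})
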