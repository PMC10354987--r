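test_that("simulate_mitogenome is deterministic and leaves the RNG alone", {
  set.seed(999)
  before <- .Random.seed
  g1 <- simulate_mitogenome(seed = 3L)
  expect_identical(.Random.seed, before)
  g2 <- simulate_mitogenome(seed = 3L)
  expect_identical(g1$record$bases, g2$record$bases)
  expect_identical(hifimito:::feature_df(g1$annotation),
                   hifimito:::feature_df(g2$annotation))
  g3 <- simulate_mitogenome(seed = 4L)
  expect_false(identical(g1$record$bases, g3$record$bases))
})

test_that("the default genome matches the metazoan blueprint", {
  g <- acc_truth()
  expect_equal(nchar(g$record$bases), 16500L)
  df <- hifimito:::feature_df(g$annotation)
  expect_equal(sum(df$kind == "CDS"), 13L)
  expect_equal(sum(df$kind == "rRNA"), 2L)
  expect_equal(sum(df$kind == "tRNA"), 22L)
  expect_true("trnF" %in% df$name)
  expect_equal(g$genetic_code_id, 5L)
  # genes do not overlap and have at least 10 bp spacers
  o <- order(df$start)
  expect_true(all(df$start[o][-1] - df$end[o][-nrow(df)] >= 10L))
})

test_that("planted CDS are valid ORFs under the declared code", {
  g <- small_truth()
  code <- genetic_code(g$genetic_code_id)
  for (f in Filter(function(f) f$kind == "CDS", g$annotation$features)) {
    s <- hifimito:::extract_feature_seq(g$record$bases, f)
    expect_equal(nchar(s) %% 3L, 0L)
    expect_true(substr(s, 1, 3) %in% code$start_codons)
    aa <- hifimito:::translate_cds(s, code)
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
  }
})

test_that("simulated reads respect the length model and provenance", {
  g <- small_truth()
  sim <- simulate_reads(g$record, coverage = 10, length_mean = 2000,
                        length_sd = 300, length_min = 1200, seed = 8L)
  lens <- vapply(sim$reads, function(r) nchar(r$bases), integer(1))
  expect_true(all(sim$provenance$true_span >= 1200L))
  expect_true(all(sim$provenance$true_span <= nchar(g$record$bases)))
  expect_equal(sim$provenance$read_id,
               vapply(sim$reads, `[[`, character(1), "id"))
  expect_equal(sim$provenance$length, lens)
  # error-free reads are exact substrings of the doubled circle
  sim0 <- simulate_reads(g$record, coverage = 5, length_mean = 2000,
                         length_sd = 300, length_min = 1200,
                         sub_rate = 0, indel_rate = 0, seed = 9L)
  dd <- paste0(g$record$bases, g$record$bases)
  for (i in seq_along(sim0$reads)) {
    p <- sim0$provenance[i, ]
    want <- substr(dd, p$start + 1L, p$start + p$true_span)
    got <- sim0$reads[[i]]$bases
    if (p$strand == "-") got <- revcomp(got)
    expect_equal(got, want)
  }
})

test_that("read simulation is deterministic under the seed", {
  g <- small_truth()
  s1 <- simulate_reads(g$record, coverage = 5, length_mean = 2000,
                       length_sd = 300, length_min = 1200, seed = 10L)
  s2 <- simulate_reads(g$record, coverage = 5, length_mean = 2000,
                       length_sd = 300, length_min = 1200, seed = 10L)
  expect_identical(vapply(s1$reads, `[[`, character(1), "bases"),
                   vapply(s2$reads, `[[`, character(1), "bases"))
  expect_identical(s1$provenance, s2$provenance)
})

test_that("plant_numt plants the fragment where it says it does", {
  g <- small_truth()
  nuc <- plant_numt(g, nuclear_length = 20000L, fragment = c(100L, 2100L),
                    divergence = 0, seed = 12L)
  iv <- nuc$numt_interval
  expect_equal(iv[2] - iv[1], 2000L)
  expect_equal(substr(nuc$record$bases, iv[1] + 1L, iv[2]),
               substr(g$record$bases, 101L, 2100L))
  expect_equal(nchar(nuc$record$bases), 22000L)
  # divergence decorrelates the fragment but keeps its length
  nucd <- plant_numt(g, nuclear_length = 20000L, fragment = c(100L, 2100L),
                     divergence = 0.1, seed = 12L)
  ivd <- nucd$numt_interval
  frag <- substr(nucd$record$bases, ivd[1] + 1L, ivd[2])
  ref <- substr(g$record$bases, 101L, 2100L)
  mism <- sum(strsplit(frag, "")[[1]] != strsplit(ref, "")[[1]])
  expect_gt(mism, 100L)
  expect_lt(mism, 400L)
})

test_that("simulate_heteroplasmy applies the stated edit", {
  g <- small_truth()
  het <- simulate_heteroplasmy(g, edit = list(type = "insertion", pos = 1234L,
                                              length = 100L),
                               frequencies = c(0.5, 0.5), seed = 13L)
  h1 <- het$haplotypes[[1]]$record$bases
  h2 <- het$haplotypes[[2]]$record$bases
  expect_equal(h1, g$record$bases)
  expect_equal(nchar(h2), nchar(h1) + 100L)
  expect_equal(substr(h2, 1, 1234), substr(h1, 1, 1234))
  expect_equal(substr(h2, 1335, nchar(h2)), substr(h1, 1235, nchar(h1)))
  expect_error(simulate_heteroplasmy(g, frequencies = c(0.6, 0.6)),
               "sum to 1")
  # an automatic position lands between genes
  het2 <- simulate_heteroplasmy(g, seed = 14L)
  df <- hifimito:::feature_df(g$annotation)
  pos <- het2$edit$pos
  expect_false(any(df$start < pos & pos < df$end))
})

test_that("heteroplasmy reads carry haplotype provenance at the mix ratio", {
  g <- small_truth()
  het <- simulate_heteroplasmy(g, seed = 15L)
  sim <- simulate_heteroplasmy_reads(het, coverage = 8, length_mean = 2000,
                                     length_sd = 300, length_min = 1200,
                                     seed = 16L)
  tab <- table(sim$provenance$haplotype)
  expect_equal(sort(names(tab)), c("hap1", "hap2"))
  expect_equal(unname(tab[["hap1"]]), unname(tab[["hap2"]]), tolerance = 0.3)
  expect_equal(length(sim$reads), nrow(sim$provenance))
})
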