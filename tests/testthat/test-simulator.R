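test_that("phase binning covers the pool, is seed-deterministic and roughly balanced", {
  snps <- data.frame(pos = seq_len(4996), ref = "A", alt = "G")
  binned <- assign_phase_bins(snps, seed = 7)
  expect_equal(nrow(binned), 4996L)
  expect_setequal(unique(binned$phase), c("maternal", "paternal"))
  # Bernoulli(1/2) split: both bins well populated
  expect_gt(sum(binned$phase == "maternal"), 2200)
  expect_gt(sum(binned$phase == "paternal"), 2200)

  expect_identical(assign_phase_bins(snps, seed = 7), binned)
  expect_false(identical(assign_phase_bins(snps, seed = 8)$phase, binned$phase))

  one <- assign_phase_bins(data.frame(pos = 1, ref = "A", alt = "G"), seed = 1)
  expect_true(one$phase %in% c("maternal", "paternal"))
  expect_error(assign_phase_bins(snps[0, ], seed = 1), "empty")
})

test_that("haplotype construction substitutes alt on the assigned haplotype only", {
  tx <- Biostrings::DNAStringSet(c(t1 = "AAAA"))
  snps <- data.frame(transcript = "t1", offset = 3L, ref = "A", alt = "G",
                     phase = "maternal", stringsAsFactors = FALSE)
  haps <- build_haplotype_transcriptomes(tx, snps, min_transcript_len = 1)
  expect_equal(as.character(haps$maternal[["t1"]]), "AAGA")
  expect_equal(as.character(haps$paternal[["t1"]]), "AAAA")

  # empty pool: both haplotypes identical to the input
  haps0 <- build_haplotype_transcriptomes(tx, snps[0, ], min_transcript_len = 1)
  expect_equal(as.character(haps0$maternal), as.character(tx))
  expect_equal(as.character(haps0$paternal), as.character(tx))

  # ref mismatch is a consistency error
  bad <- transform(snps, ref = "C")
  expect_error(build_haplotype_transcriptomes(tx, bad, min_transcript_len = 1),
               "mismatch")
})

test_that("minus-strand transcripts receive the complemented substitution", {
  # genome fragment 1..12; tx_plus covers 1-6 on '+', tx_minus covers 7-12 on '-'
  # genome:      ACGTAC GTTTGA
  # tx_minus = revcomp(GTTTGA) = TCAAAC
  tx <- Biostrings::DNAStringSet(c(tx_plus = "ACGTAC", tx_minus = "TCAAAC"))
  coord_map <- data.frame(
    transcript = c("tx_plus", "tx_minus"), chrom = "X",
    genome_start = c(1L, 7L), genome_end = c(6L, 12L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "X", pos = c(4L, 9L), ref = c("T", "T"),
                     alt = c("G", "C"), phase = c("maternal", "maternal"),
                     stringsAsFactors = FALSE)
  haps <- build_haplotype_transcriptomes(tx, snps, coord_map, min_transcript_len = 1)
  # pos 4 on '+': offset 4, T->G directly
  expect_equal(as.character(haps$maternal[["tx_plus"]]), "ACGGAC")
  # pos 9 on '-': offset = 12-9+1 = 4; transcript base A (complement of T),
  # substituted with complement of C = G
  expect_equal(as.character(haps$maternal[["tx_minus"]]), "TCAGAC")
  expect_equal(as.character(haps$paternal[["tx_minus"]]), "TCAAAC")
})

test_that("haplotype substitution is an involution on the SNP set", {
  tx <- random_transcriptome(n = 2, len = 600, seed = 3)
  snps <- transcript_snps(tx, offsets = c(100, 300), seed = 3)
  snps$phase <- "maternal"
  fwd <- build_haplotype_transcriptomes(tx, snps, min_transcript_len = 500)
  # swap ref/alt and substitute again: restores the original
  back_snps <- transform(snps, ref = alt, alt = snps$ref)
  back <- build_haplotype_transcriptomes(fwd$maternal, back_snps,
                                         min_transcript_len = 500)
  expect_equal(as.character(back$maternal), as.character(tx))
})

test_that("error-free simulated read pairs are exact substrings of their haplotype", {
  tx <- random_transcriptome(n = 3, len = 700, seed = 5)
  cfg <- simulation_config(base_error_rate = 0, seed = 9)
  reads <- simulate_reads(tx, 300, cfg, "maternal")
  seqs <- as.character(tx)
  for (i in seq_len(nrow(reads))) {
    src <- seqs[[reads$transcript[i]]]
    s <- reads$frag_start[i]
    expect_identical(reads$seq1[i], substr(src, s, s + cfg$read_len - 1L))
    mate2_src <- substr(src, s + cfg$outer_distance - cfg$read_len,
                        s + cfg$outer_distance - 1L)
    expect_identical(reads$seq2[i],
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(mate2_src))))
  }
  # determinism
  expect_identical(simulate_reads(tx, 300, cfg, "maternal"), reads)
})

test_that("base errors appear at the configured per-base rate", {
  tx <- random_transcriptome(n = 1, len = 2000, seed = 11)
  cfg <- simulation_config(base_error_rate = 2e-3, seed = 13)
  reads <- simulate_reads(tx, 3000, cfg, "hap")
  src <- as.character(tx)[[1]]
  mism <- 0L
  for (i in seq_len(nrow(reads))) {
    s <- reads$frag_start[i]
    truth <- substr(src, s, s + cfg$read_len - 1L)
    mism <- mism + sum(strsplit(reads$seq1[i], "")[[1]] != strsplit(truth, "")[[1]])
  }
  n_bases <- nrow(reads) * cfg$read_len
  ci <- stats::binom.test(mism, n_bases)$conf.int
  expect_true(ci[1] <= 2e-3 && 2e-3 <= ci[2])
})

test_that("short transcripts are skipped with a warning", {
  tx <- Biostrings::DNAStringSet(c(short = strrep("A", 100),
                                   long = strrep("ACGT", 200)))
  cfg <- simulation_config(seed = 1)
  expect_warning(reads <- simulate_reads(tx, 50, cfg, "hap"), "skipped")
  expect_true(all(reads$transcript == "long"))
})

test_that("mixing draws exactly the requested counts per haplotype", {
  tx <- random_transcriptome(n = 2, len = 600, seed = 2)
  cfg <- simulation_config(base_error_rate = 0, seed = 4)
  m <- simulate_reads(tx, 200, cfg, "maternal")
  p <- simulate_reads(tx, 200, cfg, "paternal", seed = 5)

  mixed <- mix_at_ratio(m, p, 0.75, 100, seed = 6)
  expect_equal(sum(mixed$haplotype == "maternal"), 75L)
  expect_equal(sum(mixed$haplotype == "paternal"), 25L)

  all_m <- mix_at_ratio(m, p, 1.0, 150, seed = 6)
  expect_true(all(all_m$haplotype == "maternal"))

  half <- mix_at_ratio(m, p, 0.5, 100, seed = 6)
  expect_equal(sum(half$haplotype == "maternal"), 50L)

  expect_error(mix_at_ratio(m, p, 0.9, 400, seed = 6), "short by")
})

test_that("count-level simulation matches its closed-form expected ratio", {
  # complete skew, no bias, no error: maternal-phased ratios are exactly 1
  obs <- simulate_counts(n_snps = 400, xci_ratio = 1, ref_bias = 0,
                         base_error_rate = 0, seed = 21)
  expect_true(all(obs$ratio[obs$phase == "maternal"] == 1))
  expect_true(all(obs$ratio[obs$phase == "paternal"] == 0))

  # moderate skew with mapping bias: empirical mean within 3 SE of
  # m(1-b) / (m(1-b) + (1-m))
  obs2 <- simulate_counts(n_snps = 1600, depth_sampler = function(n) rep(50L, n),
                          xci_ratio = 0.85, ref_bias = 0.02, seed = 22)
  mat <- obs2[obs2$phase == "maternal", ]
  expected <- expected_allelic_ratio(0.85, 0.02)
  se <- sd(mat$ratio) / sqrt(nrow(mat))
  expect_lt(abs(mean(mat$ratio) - expected), 3 * se)

  # symmetry at random XCI
  obs3 <- simulate_counts(n_snps = 2000, depth_sampler = function(n) rep(80L, n),
                          xci_ratio = 0.5, ref_bias = 0, seed = 23)
  expect_lt(abs(mean(obs3$ratio[obs3$phase == "maternal"]) - 0.5), 0.01)
})

test_that("ratio panel produces one dataset per ratio and reproduces under a seed", {
  cfg <- simulation_config(seed = 31, n_snps = 300)
  panel <- run_ratio_panel(cfg)
  expect_length(panel$datasets, 11L)
  expect_named(panel$datasets, names(xci_ratio_panel()))

  single <- run_ratio_panel(cfg, ratios = c("50:50" = 0.5))
  expect_length(single$datasets, 1L)

  again <- run_ratio_panel(cfg)
  expect_identical(panel$datasets, again$datasets)
})
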