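counts_row <- function(pos, A = 0, C = 0, G = 0, T = 0) {
  data.frame(chrom = "X", pos = pos, A = A, C = C, G = G, T = T)
}

test_that("variant-allele ratio uses the full quality-passing depth", {
  sites <- data.frame(chrom = "X", pos = c(1, 2, 3), id = "rs1",
                      ref = "A", alt = "G", filter = "PASS")
  counts <- rbind(counts_row(1, A = 10, G = 10),
                  counts_row(2, A = 0, G = 20),
                  counts_row(3, A = 16, G = 4, T = 1))
  obs <- allelic_ratios(counts, sites)
  expect_equal(obs$ratio, c(0.5, 1.0, 4 / 21))      # third allele stays in denominator
  expect_equal(obs$depth, c(20L, 20L, 21L))
  expect_equal(obs$phase, rep("unphased", 3))

  # optional ref+alt denominator
  obs2 <- allelic_ratios(counts, sites, denominator = "refalt")
  expect_equal(obs2$ratio[3], 4 / 20)

  zero <- counts_row(1)
  expect_error(allelic_ratios(zero, sites), "zero")
})

test_that("ratio times depth is within rounding of an integer count", {
  obs <- simulate_counts(n_snps = 300, xci_ratio = 0.7, seed = 17)
  expect_true(all(abs(obs$ratio * obs$depth - obs$alt_count) < 0.5))
  expect_true(all(obs$ratio >= 0 & obs$ratio <= 1))
})

test_that("filter cascade removes loci stage by stage with full accounting", {
  # 10 engineered loci: 2 fail PAR, 1 fails PASS, 1 fails dbSNP, 2 fail depth
  obs <- data.frame(
    chrom = "X",
    pos = c(100000, 2000000, rep(3e6 + 1:8 * 1000, length.out = 8)),
    id = c(rep("rs", 3), "", rep("rs", 6)),
    filter = c(rep("PASS", 2), "q10", rep("PASS", 7)),
    depth = c(50, 50, 50, 50, 19, 10, 30, 40, 50, 60),
    ratio = 0.5, stringsAsFactors = FALSE)
  res <- apply_filters(obs, min_depth = 20)

  expect_equal(res$report$n,
               c(10L, 10L, 10L, 8L, 7L, 6L, 4L))
  expect_equal(nrow(res$observations), 4L)
  # report is monotone non-increasing
  expect_true(all(diff(res$report$n) <= 0))
  # conservation: kept + rejected reconstruct the input
  expect_equal(nrow(res$observations) + nrow(res$rejected), nrow(obs))
  # boundary: depth 19 removed, depth 20 would be kept
  expect_true(19 %in% obs$depth[!paste(obs$chrom, obs$pos) %in%
                                paste(res$observations$chrom, res$observations$pos)])

  # idempotence
  res2 <- apply_filters(res$observations, min_depth = 20)
  expect_equal(nrow(res2$observations), nrow(res$observations))
  expect_equal(res2$report$n[1], res2$report$n[7])
})

test_that("PAR stage removes default-PAR1 loci specifically", {
  obs <- data.frame(chrom = "X", pos = c(100000, 5e6), id = "rs",
                    filter = "PASS", depth = 50, ratio = 0.5)
  res <- apply_filters(obs)
  expect_equal(res$observations$pos, 5e6)
  expect_equal(res$rejected$stage, "outside_PAR")
})

test_that("attributed-read counting recovers alleles without an aligner", {
  tx <- random_transcriptome(n = 1, len = 700, seed = 8)
  snps <- transcript_snps(tx, offsets = 300, seed = 8)
  snps$phase <- "maternal"
  haps <- build_haplotype_transcriptomes(tx, snps, min_transcript_len = 500)
  cfg <- simulation_config(base_error_rate = 0, seed = 14)

  reads <- simulate_reads(haps$maternal, 400, cfg, "maternal")
  counts <- count_from_attributed_reads(reads, snps, cfg)
  # every counted base at the SNP is the alt allele
  expect_equal(counts$depth, counts[[snps$alt[1]]])
  expect_gt(counts$depth, 0)

  # reads from the reference haplotype contribute only ref
  reads_p <- simulate_reads(haps$paternal, 400, cfg, "paternal")
  counts_p <- count_from_attributed_reads(reads_p, snps, cfg)
  expect_equal(counts_p$depth, counts_p[[snps$ref[1]]])

  expect_error(count_from_attributed_reads(data.frame(seq1 = "A"), snps, cfg),
               "provenance")
})

test_that("a mate-2-only overlap contributes the correct (re-complemented) base", {
  tx <- Biostrings::DNAStringSet(c(t1 = strrep("A", 200)))
  cfg <- simulation_config(read_len = 50L, outer_distance = 150L, seed = 1)
  # fragment at 1..150: mate 1 covers 1-50, mate 2 covers 101-150
  reads <- data.frame(name = "r1", transcript = "t1", frag_start = 1L,
                      seq1 = strrep("A", 50),
                      seq2 = strrep("T", 50),        # revcomp of AAAA...
                      haplotype = "m", stringsAsFactors = FALSE)
  site <- data.frame(transcript = "t1", offset = 120L, ref = "A", alt = "G")
  counts <- count_from_attributed_reads(reads, site, cfg)
  expect_equal(counts$A, 1L)
  expect_equal(counts$depth, 1L)

  # an injected error base lands in the depth
  reads$seq2 <- paste0(strrep("T", 30), "C", strrep("T", 19))  # pos 31 in seq2
  # transcript coord of seq2 position j: t = frag_start + 150 - j = 1 + 150 - 31 = 120
  counts2 <- count_from_attributed_reads(reads, site, cfg)
  expect_equal(counts2$G, 1L)                        # complement of C
  expect_equal(counts2$depth, 1L)
})

test_that("overlapping mates of one pair each contribute a base", {
  tx <- Biostrings::DNAStringSet(c(t1 = strrep("A", 200)))
  cfg <- simulation_config(read_len = 100L, outer_distance = 150L, seed = 1)
  # mate 1 covers 1-100, mate 2 covers 51-150: offsets 51-100 are double-covered
  reads <- data.frame(name = "r1", transcript = "t1", frag_start = 1L,
                      seq1 = strrep("A", 100), seq2 = strrep("T", 100),
                      haplotype = "m", stringsAsFactors = FALSE)
  site <- data.frame(transcript = "t1", offset = 75L, ref = "A", alt = "G")
  counts <- count_from_attributed_reads(reads, site, cfg)
  expect_equal(counts$depth, 2L)
})
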