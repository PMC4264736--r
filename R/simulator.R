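# In-silico XCI experiment: build two variant-bearing haplotype
# transcriptomes, simulate error-bearing paired reads from each and mix them
# at a target XCI ratio; plus a fast count-level shortcut that bypasses reads
# entirely. Reads carry their source haplotype and coordinates ("direct
# attribution"), so allele counting never needs an aligner.

#' Simulation parameters for the in-silico XCI experiment
#'
#' Defaults reproduce the design of the benchmark read simulation: 100 bp
#' paired reads, 150 bp outer distance between mates, uniform Phred quality
#' 40, a 1e-5 per-base substitution error rate, zero indel rate, and
#' transcripts of at least 500 bp. Count-level parameters (`n_snps`,
#' `depth_meanlog`, `depth_sdlog`, `ref_bias`) emulate the read-level study
#' at the allele-count scale: a pool of 4996 heterozygous SNPs whose depths
#' follow a heavy-tailed lognormal — deep sequencing of a transcriptome
#' yields per-SNP coverage spanning orders of magnitude — calibrated so that
#' roughly 1600 of the 4996 SNPs reach the 20X filter; plus a 2%
#' reference-mapping bias (the probability an alt-carrying read is lost to
#' mapping).
#'
#' @param n_pairs Total read pairs to simulate (read-level mode).
#' @param read_len Read length in bp.
#' @param outer_distance Outer fragment distance between mate 5' ends, bp.
#' @param base_error_rate Per-base substitution error probability.
#' @param indel_rate Per-base indel probability (fixed 0; indels are not
#'   simulated).
#' @param base_quality Uniform Phred base quality for simulated reads.
#' @param xci_ratio Maternal fraction in \[0, 1\]; 0.5 is random XCI, 1 is
#'   completely skewed toward the maternal X.
#' @param seed Master RNG seed; per-dataset child seeds are derived from it.
#' @param min_transcript_len Transcripts shorter than this are dropped before
#'   haplotype construction.
#' @param fragment_sd Standard deviation of the fragment length (default 0:
#'   fixed at `outer_distance`).
#' @param n_snps Count-level mode: number of heterozygous SNPs in the pool.
#' @param depth_meanlog,depth_sdlog Count-level mode: lognormal parameters
#'   of per-SNP read depth.
#' @param ref_bias Count-level mode: probability that an alt-carrying read is
#'   lost to reference-biased mapping.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 100000L, read_len = 100L,
                              outer_distance = 150L, base_error_rate = 1e-5,
                              indel_rate = 0, base_quality = 40L,
                              xci_ratio = 0.5, seed = 1L,
                              min_transcript_len = 500L, fragment_sd = 0,
                              n_snps = 4996L, depth_meanlog = log(8),
                              depth_sdlog = 2, ref_bias = 0.02) {
  assert_prob(xci_ratio, "xci_ratio")
  assert_prob(base_error_rate, "base_error_rate")
  assert_prob(indel_rate, "indel_rate")
  if (ref_bias < 0 || ref_bias >= 1) stopf("'ref_bias' must be in [0, 1)")
  if (n_pairs <= 0) stopf("'n_pairs' must be positive")
  if (indel_rate != 0) stopf("indel simulation is not supported (indel_rate must be 0)")
  structure(list(n_pairs = as.integer(n_pairs), read_len = as.integer(read_len),
                 outer_distance = as.integer(outer_distance),
                 base_error_rate = base_error_rate, indel_rate = indel_rate,
                 base_quality = as.integer(base_quality), xci_ratio = xci_ratio,
                 seed = as.integer(seed),
                 min_transcript_len = as.integer(min_transcript_len),
                 fragment_sd = fragment_sd, n_snps = as.integer(n_snps),
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 ref_bias = ref_bias),
            class = "simulation_config")
}

#' The default 11-ratio XCI panel
#'
#' Maternal fractions from completely skewed (100:0) down to random (50:50)
#' in steps of 5.
#'
#' @return Named numeric vector of maternal fractions.
#' @export
xci_ratio_panel <- function() {
  r <- seq(1.0, 0.5, by = -0.05)
  names(r) <- sprintf("%g:%g", round(100 * r), round(100 * (1 - r)))
  r
}

#' Randomly assign heterozygous SNP alt alleles to parental haplotypes
#'
#' Each SNP's alternative allele is independently assigned maternal or
#' paternal with probability 0.5 ("Alt-M" / "Alt-P" bins). Deterministic
#' given `seed`.
#'
#' @param snps A data.frame of variant sites (needs at least `pos`, `ref`,
#'   `alt`; `chrom` recommended).
#' @param seed RNG seed.
#' @return `snps` with an added `phase` column (`"maternal"`/`"paternal"`),
#'   the parental origin of the alt allele.
#' @export
assign_phase_bins <- function(snps, seed) {
  if (is.null(snps) || nrow(snps) == 0L) stopf("empty SNP set")
  snps$phase <- withr::with_seed(seed,
    sample(c("maternal", "paternal"), nrow(snps), replace = TRUE))
  snps
}

# Map genome-space SNPs into transcript space. coord_map has one row per
# transcript: transcript, chrom, genome_start, genome_end, strand; the
# transcript is a single contiguous block (exon-level mapping is out of
# scope). On '-' transcripts both the offset and the alleles are
# reverse-complemented.
map_snps_to_transcripts <- function(snps, coord_map) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (i in seq_len(nrow(snps))) {
    hit <- which(coord_map$chrom == snps$chrom[i] &
                 coord_map$genome_start <= snps$pos[i] &
                 coord_map$genome_end >= snps$pos[i])
    for (j in hit) {
      minus <- identical(coord_map$strand[j], "-")
      off <- if (minus) coord_map$genome_end[j] - snps$pos[i] + 1L
             else snps$pos[i] - coord_map$genome_start[j] + 1L
      row <- snps[i, , drop = FALSE]
      row$transcript <- coord_map$transcript[j]
      row$offset <- off
      row$t_ref <- if (minus) comp[[row$ref]] else row$ref
      row$t_alt <- if (minus) comp[[row$alt]] else row$alt
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Build maternal and paternal haplotype transcriptomes
#'
#' Introduces each SNP's alternative allele into the transcript FASTA of the
#' parental haplotype it was assigned to ([assign_phase_bins()]), leaving the
#' reference base on the other haplotype. Sequence lengths are unchanged.
#'
#' @param transcripts A [Biostrings::DNAStringSet] of transcript sequences.
#' @param snps Phased SNP table. Either transcript-space (columns
#'   `transcript`, `offset`, `ref`, `alt`, `phase`) or genome-space (columns
#'   `chrom`, `pos`, `ref`, `alt`, `phase`) together with `coord_map`.
#' @param coord_map Optional transcript-to-genome map: data.frame with
#'   columns `transcript`, `chrom`, `genome_start`, `genome_end`, `strand`
#'   (single-block transcripts). Minus-strand substitutions are complemented.
#' @param min_transcript_len Transcripts shorter than this are dropped.
#' @return A list with [Biostrings::DNAStringSet] elements `maternal` and
#'   `paternal`, plus `snps`, the transcript-space SNP table actually used.
#' @export
build_haplotype_transcriptomes <- function(transcripts, snps, coord_map = NULL,
                                           min_transcript_len = 500L) {
  keep <- Biostrings::width(transcripts) >= min_transcript_len
  if (!any(keep)) stopf("no transcript reaches min_transcript_len = %d", min_transcript_len)
  transcripts <- transcripts[keep]
  if (is.null(snps) || nrow(snps) == 0L) {         # no variants: identical haplotypes
    return(list(maternal = transcripts, paternal = transcripts,
                snps = snps))
  }
  if (!is.null(coord_map)) {
    tsnps <- map_snps_to_transcripts(snps, coord_map)
    if (is.null(tsnps)) stopf("no SNP maps inside a retained transcript")
  } else {
    tsnps <- snps
    tsnps$t_ref <- tsnps$ref
    tsnps$t_alt <- tsnps$alt
  }
  tsnps <- tsnps[tsnps$transcript %in% names(transcripts), , drop = FALSE]
  if (nrow(tsnps) == 0L) stopf("no SNP maps inside a retained transcript")

  seqs <- as.character(transcripts)
  have <- vapply(seq_len(nrow(tsnps)),
                 function(i) substr(seqs[[tsnps$transcript[i]]], tsnps$offset[i], tsnps$offset[i]),
                 character(1L))
  bad <- have != tsnps$t_ref
  if (any(bad))
    stopf("%d SNP(s) whose ref base mismatches the transcript (first: %s:%d has %s, expected %s)",
          sum(bad), tsnps$transcript[which(bad)[1L]], tsnps$offset[which(bad)[1L]],
          have[which(bad)[1L]], tsnps$t_ref[which(bad)[1L]])

  substitute_set <- function(seqs, rows) {
    for (i in rows) {
      tr <- tsnps$transcript[i]
      substr(seqs[[tr]], tsnps$offset[i], tsnps$offset[i]) <- tsnps$t_alt[i]
    }
    seqs
  }
  mat <- substitute_set(seqs, which(tsnps$phase == "maternal"))
  pat <- substitute_set(seqs, which(tsnps$phase == "paternal"))
  list(maternal = Biostrings::DNAStringSet(mat),
       paternal = Biostrings::DNAStringSet(pat),
       snps = tsnps)
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate error-bearing paired-end reads from a haplotype transcriptome
#'
#' Fragments of length `outer_distance` are drawn uniformly over valid start
#' positions across transcripts, so longer transcripts yield proportionally
#' more pairs (wgsim behaviour; no expression model). Mate 2 is the
#' reverse complement of the fragment's 3' end. Each base is flipped to a
#' random different base with probability `base_error_rate`. Each read
#' remembers its source transcript and fragment start ("direct attribution"),
#' which lets [count_from_attributed_reads()] count alleles without an
#' aligner.
#'
#' @param haplotype A [Biostrings::DNAStringSet] (one haplotype
#'   transcriptome).
#' @param n_pairs Number of read pairs.
#' @param config A [simulation_config()].
#' @param haplotype_label Label recorded in the `haplotype` column
#'   (e.g. `"maternal"`).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A data.frame with columns `name`, `transcript`, `frag_start`
#'   (1-based within the transcript), `seq1`, `seq2`, `haplotype`.
#' @export
simulate_reads <- function(haplotype, n_pairs, config = simulation_config(),
                           haplotype_label = "hap", seed = config$seed) {
  rl <- config$read_len; frag <- config$outer_distance
  ok <- Biostrings::width(haplotype) >= frag
  if (!all(ok)) {
    warnf("%d transcript(s) shorter than outer_distance skipped", sum(!ok))
    haplotype <- haplotype[ok]
  }
  if (length(haplotype) == 0L) stopf("no transcript is long enough for outer_distance = %d", frag)
  seqs <- as.character(haplotype)
  lens <- nchar(seqs)
  nstart <- lens - frag + 1L

  withr::with_seed(seed, {
    idx <- sample.int(length(seqs), n_pairs, replace = TRUE, prob = nstart)
    start <- floor(runif(n_pairs) * nstart[idx]) + 1L
    r1 <- substring(seqs[idx], start, start + rl - 1L)
    r2 <- revcomp(substring(seqs[idx], start + frag - rl, start + frag - 1L))
    # substitution errors: choose flat base positions, replace with one of the
    # other three bases
    inject_errors <- function(reads) {
      nb <- n_pairs * rl
      k <- rbinom(1L, nb, config$base_error_rate)
      if (k > 0L) {
        at <- sample.int(nb, k)
        row <- (at - 1L) %/% rl + 1L
        col <- (at - 1L) %% rl + 1L
        for (e in seq_len(k)) {
          old <- substr(reads[row[e]], col[e], col[e])
          alt <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          substr(reads[row[e]], col[e], col[e]) <- alt
        }
      }
      reads
    }
    r1 <- inject_errors(r1)
    r2 <- inject_errors(r2)
    data.frame(name = sprintf("%s_%07d", haplotype_label, seq_len(n_pairs)),
               transcript = names(seqs)[idx], frag_start = start,
               seq1 = r1, seq2 = r2, haplotype = haplotype_label,
               stringsAsFactors = FALSE)
  })
}

#' Mix maternal and paternal read pools at a target XCI ratio
#'
#' Exactly `round(xci_ratio * total_pairs)` pairs are subsampled without
#' replacement from the maternal pool and the remainder from the paternal
#' pool; the merged order is shuffled. The maternal-pair fraction of the
#' output therefore equals `xci_ratio` exactly by count.
#'
#' @param reads_m,reads_p Read tables from [simulate_reads()].
#' @param xci_ratio Maternal fraction in \[0, 1\].
#' @param total_pairs Total pairs in the merged output.
#' @param seed RNG seed.
#' @return A shuffled data.frame of `total_pairs` rows.
#' @export
mix_at_ratio <- function(reads_m, reads_p, xci_ratio, total_pairs, seed = 1L) {
  assert_prob(xci_ratio, "xci_ratio")
  n_m <- round(xci_ratio * total_pairs)
  n_p <- total_pairs - n_m
  if (nrow(reads_m) < n_m)
    stopf("maternal pool short by %d pairs (%d requested, %d available)",
          n_m - nrow(reads_m), n_m, nrow(reads_m))
  if (nrow(reads_p) < n_p)
    stopf("paternal pool short by %d pairs (%d requested, %d available)",
          n_p - nrow(reads_p), n_p, nrow(reads_p))
  withr::with_seed(seed, {
    take_m <- reads_m[sample.int(nrow(reads_m), n_m), , drop = FALSE]
    take_p <- reads_p[sample.int(nrow(reads_p), n_p), , drop = FALSE]
    merged <- rbind(take_m, take_p)
    merged <- merged[sample.int(nrow(merged)), , drop = FALSE]
    rownames(merged) <- NULL
    merged
  })
}

#' Expected variant-allele ratio under reference-mapping bias
#'
#' For a SNP whose alternative allele sits on a haplotype expressed in a
#' fraction `m` of cells, and with probability `bias` that an alt-carrying
#' read is lost to mapping, the expected variant-allele read fraction is
#' `m (1 - bias) / (m (1 - bias) + (1 - m))`.
#'
#' @param m Expression fraction of the alt-carrying haplotype.
#' @param bias Reference-mapping bias in \[0, 1).
#' @return Expected variant-allele fraction.
#' @export
expected_allelic_ratio <- function(m, bias = 0) {
  m * (1 - bias) / (m * (1 - bias) + (1 - m))
}

# Default heterozygous SNP pool: positions uniform over the non-PAR body of
# chromosome X, distinct ref/alt bases.
make_snp_pool <- function(n_snps, seed) {
  withr::with_seed(seed, {
    pos <- sort(sample(2699521:154931043, n_snps))
    ref <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1L))
    data.frame(chrom = "X", pos = pos,
               id = sprintf("rsSYN%07d", seq_len(n_snps)),
               ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  })
}

#' Simulate phased allele counts directly (alignment-free shortcut)
#'
#' Count-level emulation of the read-level experiment: at each heterozygous
#' SNP of known phase, the alt-allele read count is binomial at the
#' closed-form expected ratio of [expected_allelic_ratio()] — `m(1-b)` vs
#' `(1-m)` for a maternal-phased SNP and symmetrically `(1-m)(1-b)` vs `m`
#' for a paternal-phased one. Sequencing errors then flip each counted read
#' to a random different base with probability `base_error_rate`, so third
#' (non-ref/non-alt) bases can appear and stay in the depth denominator.
#' Zero-depth loci (unexpressed) are dropped.
#'
#' @param n_snps Number of SNPs (ignored when `pool` is given).
#' @param depth_sampler Function `n -> integer depths`; default draws
#'   negative-binomial depths with `config` mean/size.
#' @param xci_ratio Maternal fraction in \[0, 1\].
#' @param ref_bias Probability an alt-carrying read is lost to mapping.
#' @param seed RNG seed.
#' @param base_error_rate Per-base substitution error probability.
#' @param pool Optional phased SNP pool (from [make_snp_pool()] +
#'   [assign_phase_bins()]); lets a ratio panel share one pool.
#' @param config A [simulation_config()] supplying defaults.
#' @return A data.frame of allelic observations: `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `phase`, `ref_count`, `alt_count`, `other_count`,
#'   `depth`, `ratio`, `filter`.
#' @export
simulate_counts <- function(n_snps = NULL, depth_sampler = NULL,
                            xci_ratio = 0.5, ref_bias = NULL, seed = 1L,
                            base_error_rate = NULL, pool = NULL,
                            config = simulation_config()) {
  n_snps <- n_snps %||% config$n_snps
  ref_bias <- ref_bias %||% config$ref_bias
  base_error_rate <- base_error_rate %||% config$base_error_rate
  assert_prob(xci_ratio, "xci_ratio")
  if (ref_bias < 0 || ref_bias >= 1) stopf("'ref_bias' must be in [0, 1)")
  depth_sampler <- depth_sampler %||%
    function(n) round(stats::rlnorm(n, config$depth_meanlog, config$depth_sdlog))
  if (is.null(pool)) {
    pool <- assign_phase_bins(make_snp_pool(n_snps, seed), seed + 1L)
  }
  n <- nrow(pool)
  withr::with_seed(seed + 2L, {
    depth <- as.integer(depth_sampler(n))
    m_alt <- ifelse(pool$phase == "maternal", xci_ratio, 1 - xci_ratio)
    p <- expected_allelic_ratio(m_alt, ref_bias)
    alt <- rbinom(n, depth, p)
    ref <- depth - alt
    # per-read substitution errors: a flipped read lands on the other scored
    # allele 1/3 of the time and on a third base 2/3 of the time
    alt_err <- rbinom(n, alt, base_error_rate)
    ref_err <- rbinom(n, ref, base_error_rate)
    alt_to_ref <- rbinom(n, alt_err, 1 / 3)
    ref_to_alt <- rbinom(n, ref_err, 1 / 3)
    alt_final <- alt - alt_err + ref_to_alt
    ref_final <- ref - ref_err + alt_to_ref
    other <- (alt_err - alt_to_ref) + (ref_err - ref_to_alt)
    obs <- data.frame(chrom = pool$chrom, pos = pool$pos, id = pool$id,
                      ref = pool$ref, alt = pool$alt, phase = pool$phase,
                      ref_count = ref_final, alt_count = alt_final,
                      other_count = other, depth = depth,
                      ratio = ifelse(depth > 0, alt_final / depth, NA_real_),
                      filter = "PASS", stringsAsFactors = FALSE)
    obs[obs$depth > 0L, , drop = FALSE]
  })
}

# Deterministic child seed for dataset i of a panel; kept inside 32-bit range.
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * i) %% .Machine$integer.max)
}

#' Run the multi-ratio in-silico panel
#'
#' Simulates one dataset per XCI ratio over a single shared SNP pool, with
#' per-dataset child seeds derived deterministically from the master seed.
#' In `"counts"` mode the datasets are allelic-observation tables from
#' [simulate_counts()]; in `"reads"` mode each dataset is simulated at read
#' level from haplotype transcriptomes (supply `transcripts` and genome- or
#' transcript-space `snps`), mixed with [mix_at_ratio()] and counted with
#' [count_from_attributed_reads()].
#'
#' @param config A [simulation_config()].
#' @param ratios Maternal fractions, default [xci_ratio_panel()].
#' @param mode `"counts"` (fast, default) or `"reads"`.
#' @param transcripts,coord_map,snps Read-level mode inputs (see
#'   [build_haplotype_transcriptomes()]).
#' @return A list with `datasets` (named list of observation tables),
#'   `expected` (maternal fractions), `config`, `pool`.
#' @export
run_ratio_panel <- function(config = simulation_config(),
                            ratios = xci_ratio_panel(),
                            mode = c("counts", "reads"),
                            transcripts = NULL, coord_map = NULL, snps = NULL) {
  mode <- match.arg(mode)
  if (any(ratios < 0 | ratios > 1)) stopf("ratios must lie in [0, 1]")
  if (is.null(names(ratios)))
    names(ratios) <- sprintf("%g:%g", round(100 * ratios), round(100 * (1 - ratios)))

  if (mode == "counts") {
    pool <- assign_phase_bins(make_snp_pool(config$n_snps, config$seed),
                              child_seed(config$seed, 0L))
    datasets <- lapply(seq_along(ratios), function(i) {
      simulate_counts(xci_ratio = ratios[[i]], seed = child_seed(config$seed, i),
                      pool = pool, config = config)
    })
  } else {
    if (is.null(transcripts) || is.null(snps))
      stopf("read-level mode needs 'transcripts' and 'snps'")
    phased <- if ("phase" %in% names(snps)) snps else
      assign_phase_bins(snps, child_seed(config$seed, 0L))
    haps <- build_haplotype_transcriptomes(transcripts, phased, coord_map,
                                           config$min_transcript_len)
    pool <- haps$snps
    datasets <- lapply(seq_along(ratios), function(i) {
      s <- child_seed(config$seed, i)
      reads_m <- simulate_reads(haps$maternal, config$n_pairs, config,
                                "maternal", seed = s)
      reads_p <- simulate_reads(haps$paternal, config$n_pairs, config,
                                "paternal", seed = s + 1L)
      mixed <- mix_at_ratio(reads_m, reads_p, ratios[[i]], config$n_pairs,
                            seed = s + 2L)
      counts <- count_from_attributed_reads(mixed, pool, config)
      obs <- allelic_ratios(counts, pool)
      obs$phase <- pool$phase[match(paste(obs$transcript, obs$offset),
                                    paste(pool$transcript, pool$offset))]
      obs
    })
  }
  names(datasets) <- names(ratios)
  list(datasets = datasets, expected = ratios, config = config, pool = pool)
}
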