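# Turn pileup / attributed-read evidence into filtered allelic observations:
# per-locus variant-allele ratios and the four-stage quality filter cascade
# (PAR exclusion, PASS recalibration status, dbSNP membership, minimum
# coverage), with per-stage accounting.

#' Compute variant-allele ratios at heterozygous sites
#'
#' Joins allele counts to variant sites by position and computes, per site,
#' `ratio = alt_count / depth` where `depth` is the total quality-passing
#' depth over all four bases (so third-allele reads deflate both allele
#' fractions slightly; set `denominator = "refalt"` to restrict the
#' denominator to ref + alt reads).
#'
#' @param counts Allele-count table ([read_pileup()] or
#'   [count_from_attributed_reads()]): columns `A`, `C`, `G`, `T` plus join
#'   keys.
#' @param sites Variant-site table ([read_vcf()] or a simulator pool):
#'   columns `ref`, `alt` plus join keys; optional `id`, `filter`.
#' @param denominator `"total"` (default) or `"refalt"`.
#' @return A data.frame of allelic observations with columns `ref_count`,
#'   `alt_count`, `depth`, `ratio`, `phase = "unphased"` plus the join keys
#'   and any `id`/`filter` columns present. Zero-depth loci raise an error:
#'   drop them upstream.
#' @export
allelic_ratios <- function(counts, sites, denominator = c("total", "refalt")) {
  denominator <- match.arg(denominator)
  keys <- intersect(c("chrom", "pos", "transcript", "offset"), intersect(names(counts), names(sites)))
  if (!length(keys)) stopf("counts and sites share no join keys (chrom/pos or transcript/offset)")
  kc <- do.call(paste, c(counts[keys], sep = ":"))
  ks <- do.call(paste, c(sites[keys], sep = ":"))
  hit <- match(kc, ks)
  keep <- !is.na(hit)
  counts <- counts[keep, , drop = FALSE]
  s <- sites[hit[keep], , drop = FALSE]
  mat <- as.matrix(counts[, c("A", "C", "G", "T")])
  n <- nrow(counts)
  ref_count <- mat[cbind(seq_len(n), match(s$ref, c("A", "C", "G", "T")))]
  alt_count <- mat[cbind(seq_len(n), match(s$alt, c("A", "C", "G", "T")))]
  depth <- if (denominator == "total") rowSums(mat) else ref_count + alt_count
  if (any(depth == 0))
    stopf("%d locus/loci with zero quality-passing depth; drop them before computing ratios",
          sum(depth == 0))
  out <- counts[, keys, drop = FALSE]
  out$id <- if ("id" %in% names(s)) s$id else ""
  out$ref <- s$ref
  out$alt <- s$alt
  out$filter <- if ("filter" %in% names(s)) s$filter else "PASS"
  out$ref_count <- ref_count
  out$alt_count <- alt_count
  out$depth <- as.integer(depth)
  out$ratio <- alt_count / depth
  out$phase <- "unphased"
  rownames(out) <- NULL
  out
}

#' Apply the quality filter cascade to allelic observations
#'
#' Stages, in order: heterozygous-in-child (only when a `het` column is
#' present), within-transcripts (only when `transcript_regions` is given),
#' outside PAR1/PAR2, recalibration status PASS, dbSNP membership (non-empty
#' `id`), and minimum coverage. Stage counts are monotone non-increasing and,
#' together with the per-stage reject log, reconstruct the input count.
#'
#' @param obs Allelic observations ([allelic_ratios()] /
#'   [simulate_counts()]); optional logical column `het`.
#' @param par PAR table ([par_regions()]); `NULL` skips the stage.
#' @param min_depth Minimum read depth, default 20 ("less than 20X" is
#'   excluded, so depth 19 fails and depth 20 passes).
#' @param require_pass Drop observations whose `filter` is not `"PASS"`.
#' @param require_dbsnp Drop observations with an empty `id`.
#' @param transcript_regions Optional data.frame (`chrom`, `start`, `end`,
#'   1-based inclusive) of transcribed intervals.
#' @return A list with `observations` (kept rows), `report` (data.frame
#'   `stage`, `n` of survivors per stage) and `rejected` (data.frame of
#'   dropped loci with the stage that removed each).
#' @export
apply_filters <- function(obs, par = par_regions(), min_depth = 20,
                          require_pass = TRUE, require_dbsnp = TRUE,
                          transcript_regions = NULL) {
  stages <- c("input", "het_in_child", "in_transcripts", "outside_PAR",
              "pass_quality", "in_dbsnp", "depth_ok")
  n_kept <- integer(length(stages))
  names(n_kept) <- stages
  rejected <- list()
  keep <- rep(TRUE, nrow(obs))
  n_kept["input"] <- nrow(obs)

  drop_stage <- function(stage, fail) {
    fail <- fail & keep
    if (any(fail)) {
      rejected[[stage]] <<- data.frame(chrom = obs$chrom[fail], pos = obs$pos[fail],
                                       stage = stage, stringsAsFactors = FALSE)
    }
    keep <<- keep & !fail
    n_kept[stage] <<- sum(keep)
  }

  drop_stage("het_in_child", if ("het" %in% names(obs)) !obs$het else rep(FALSE, nrow(obs)))
  if (!is.null(transcript_regions)) {
    in_tx <- rep(FALSE, nrow(obs))
    for (i in seq_len(nrow(transcript_regions))) {
      in_tx <- in_tx | (obs$chrom == sub("^chr", "", transcript_regions$chrom[i]) &
                        obs$pos >= transcript_regions$start[i] &
                        obs$pos <= transcript_regions$end[i])
    }
    drop_stage("in_transcripts", !in_tx)
  } else drop_stage("in_transcripts", rep(FALSE, nrow(obs)))
  drop_stage("outside_PAR", if (!is.null(par)) in_par(obs$chrom, obs$pos, par) else rep(FALSE, nrow(obs)))
  drop_stage("pass_quality", if (require_pass) obs$filter != "PASS" else rep(FALSE, nrow(obs)))
  drop_stage("in_dbsnp", if (require_dbsnp) is.na(obs$id) | obs$id == "" else rep(FALSE, nrow(obs)))
  drop_stage("depth_ok", obs$depth < min_depth)

  list(observations = obs[keep, , drop = FALSE],
       report = data.frame(stage = stages, n = unname(n_kept[stages]),
                           stringsAsFactors = FALSE),
       rejected = if (length(rejected)) do.call(rbind, unname(rejected)) else
         data.frame(chrom = character(), pos = integer(), stage = character(),
                    stringsAsFactors = FALSE))
}

#' Count alleles from simulated reads with provenance
#'
#' The alignment-free counting route: every simulated read knows its source
#' transcript and fragment start, so each read contributes its (possibly
#' error-bearing) base at every transcript-space SNP it covers — mate 1
#' directly, mate 2 after undoing the reverse complement. Mates of the same
#' pair that both overlap a SNP each contribute a base (overlapping mates are
#' double-counted, as in a naive pileup).
#'
#' @param reads Attributed read table from [simulate_reads()] /
#'   [mix_at_ratio()].
#' @param sites Transcript-space SNP table (columns `transcript`, `offset`).
#' @param config The [simulation_config()] the reads were generated with
#'   (read length and outer distance locate the mates).
#' @return An allele-count data.frame: `transcript`, `offset`, `A`, `C`,
#'   `G`, `T`, `depth`, plus `chrom`/`pos` when present in `sites`.
#' @export
count_from_attributed_reads <- function(reads, sites, config = simulation_config()) {
  need <- c("transcript", "frag_start", "seq1", "seq2")
  if (!all(need %in% names(reads)))
    stopf("reads lack provenance columns: %s",
          paste(setdiff(need, names(reads)), collapse = ", "))
  rl <- config$read_len; frag <- config$outer_distance
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- sites[, intersect(c("chrom", "pos", "transcript", "offset"), names(sites)), drop = FALSE]
  tallies <- matrix(0L, nrow(sites), 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(sites))) {
    r <- reads[reads$transcript == sites$transcript[i], , drop = FALSE]
    if (nrow(r) == 0L) next
    o <- sites$offset[i]
    # mate 1 covers [s, s + rl - 1]
    c1 <- r$frag_start <= o & o <= r$frag_start + rl - 1L
    b1 <- substr(r$seq1[c1], o - r$frag_start[c1] + 1L, o - r$frag_start[c1] + 1L)
    # mate 2 covers [s + frag - rl, s + frag - 1], stored reverse-complemented
    c2 <- r$frag_start + frag - rl <= o & o <= r$frag_start + frag - 1L
    j <- r$frag_start[c2] + frag - o          # 1-based index into seq2
    b2 <- comp[substr(r$seq2[c2], j, j)]
    tab <- table(factor(c(b1, b2), levels = c("A", "C", "G", "T")))
    tallies[i, ] <- as.integer(tab)
  }
  out <- cbind(out, as.data.frame(tallies))
  out$depth <- rowSums(tallies)
  out
}
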