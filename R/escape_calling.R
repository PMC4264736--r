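# Genes escaping X inactivation are expressed from both the active and the
# inactive X, so their heterozygous SNPs show bi-allelic expression even
# when the chromosome-wide XCI is skewed. A variant is an escape candidate
# when its allelic ratio lies more than two standard deviations outside the
# mean of its phase group's chromosome-wide ratio distribution AND is
# bi-allelic (ratio in [0.1, 0.9]). Candidates on thin coverage (< 7 reads)
# are downgraded to low-confidence rather than dropped.

#' Classify phased allelic observations for escape from XCI
#'
#' The phase-group mean and SD default to the empirical mean/SD of each
#' group's ratios in `obs` (per-group, not pooled); pass `phased_stats` to
#' override, e.g. with chromosome-wide summaries from a larger call set.
#'
#' @param obs Phased allelic observations: columns `ratio`, `depth`,
#'   `phase` in `{"maternal", "paternal"}`, optional `gene`.
#' @param phased_stats Optional data.frame with columns `phase`, `mean`,
#'   `sd`.
#' @param min_depth Depth below which an otherwise-qualifying variant is
#'   called `low_confidence` (default 7).
#' @param z_cut SD multiple defining "outside the distribution" (default 2).
#' @param biallelic_range Ratio bounds defining bi-allelic expression.
#' @return `obs` extended with `phased_mean`, `phased_sd`, `z_distance`,
#'   `biallelic` and `verdict` in `{"escape_candidate", "subject",
#'   "low_confidence"}`.
#' @export
classify_escape <- function(obs, phased_stats = NULL, min_depth = 7,
                            z_cut = 2, biallelic_range = c(0.1, 0.9)) {
  if (any(!obs$phase %in% c("maternal", "paternal")))
    stopf("escape classification needs phased observations (maternal/paternal)")
  if (is.null(phased_stats)) {
    phased_stats <- do.call(rbind, lapply(split(obs, obs$phase), function(g) {
      data.frame(phase = g$phase[1L], mean = mean(g$ratio), sd = sd(g$ratio),
                 stringsAsFactors = FALSE)
    }))
  }
  i <- match(obs$phase, phased_stats$phase)
  if (anyNA(i)) stopf("phased_stats lacks an entry for some phase group")
  mu <- phased_stats$mean[i]
  sg <- phased_stats$sd[i]
  if (any(!is.finite(sg)) || any(sg <= 0))
    stopf("phase-group SD must be positive (singleton group?)")
  z <- abs(obs$ratio - mu) / sg
  biallelic <- obs$ratio >= biallelic_range[1L] & obs$ratio <= biallelic_range[2L]
  qualifies <- z > z_cut & biallelic
  verdict <- ifelse(qualifies,
                    ifelse(obs$depth >= min_depth, "escape_candidate", "low_confidence"),
                    "subject")
  obs$phased_mean <- mu
  obs$phased_sd <- sg
  obs$z_distance <- z
  obs$biallelic <- biallelic
  obs$verdict <- verdict
  obs
}

#' Summarize escape calls per gene
#'
#' A gene is an escape candidate when any of its variants is; a gene whose
#' only qualifying variants are low-coverage is flagged low-confidence.
#'
#' @param calls Output of [classify_escape()] with a `gene` column.
#' @return A data.frame per gene: `gene`, `n_variants`, `n_candidate`,
#'   `n_low_confidence`, `verdict`.
#' @export
escape_summary <- function(calls) {
  if (!"gene" %in% names(calls)) stopf("calls need a 'gene' column")
  rows <- lapply(split(calls, calls$gene), function(g) {
    n_cand <- sum(g$verdict == "escape_candidate")
    n_low <- sum(g$verdict == "low_confidence")
    data.frame(gene = g$gene[1L], n_variants = nrow(g),
               n_candidate = n_cand, n_low_confidence = n_low,
               verdict = if (n_cand > 0L) "escape_candidate"
                         else if (n_low > 0L) "low_confidence" else "subject",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
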