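# Case-vs-control read-depth deletion detection from physical (gapped)
# coverage: each proper mate pair is treated as one fragment spanning its
# outer coordinates (the unsequenced gap between mates included), fragments
# are counted into fixed 100-bp windows, per-sample counts are normalized to
# sum to one, and the per-window log2 difference case - control is smoothed
# with a sliding mean. A heterozygous deletion in the case sample shows as a
# run of windows near log2 difference -1 (half coverage).
#
# Windows are 0-based half-open internally and tile the chromosome from
# coordinate 0; reported calls are 1-based inclusive.

#' Tile a chromosome into fixed-width windows
#'
#' @param chrom Chromosome name.
#' @param chrom_length Length in bp.
#' @param width Window width in bp (default 100).
#' @return A data.frame with `chrom`, `start` (0-based), `end` (half-open).
#' @export
tile_windows <- function(chrom = "X", chrom_length, width = 100L) {
  start <- seq(0L, chrom_length - 1L, by = width)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + width, chrom_length),
             stringsAsFactors = FALSE)
}

#' Count fragments into coverage windows (physical coverage)
#'
#' Every fragment increments every window it overlaps by exactly one.
#' Fragments with `end <= start` are skipped and counted in the `skipped`
#' attribute.
#'
#' @param fragments Data.frame of fragment outer spans: `chrom`, `start`
#'   (0-based), `end` (half-open) — BED convention, as written by
#'   `bedtools bamtobed` on name-sorted proper pairs.
#' @param windows Window grid from [tile_windows()].
#' @return Integer vector of raw counts, one per window, with attribute
#'   `skipped`.
#' @export
physical_coverage <- function(fragments, windows) {
  bad <- fragments$end <= fragments$start
  fragments <- fragments[!bad, , drop = FALSE]
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- windows$chrom == ch
    fr <- fragments[sub("^chr", "", fragments$chrom) == sub("^chr", "", ch), , drop = FALSE]
    if (!nrow(fr)) next
    counts[wi] <- IRanges::countOverlaps(
      IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi]),
      IRanges::IRanges(fr$start + 1L, fr$end))
  }
  attr(counts, "skipped") <- sum(bad)
  counts
}

#' Read a fragment BED file
#'
#' @param path BED path (chrom, start, end, optional name).
#' @return A data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_fragments_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stopf("fragment BED needs at least 3 columns: %s", path)
  data.frame(chrom = as.character(bed[[1L]]), start = as.integer(bed[[2L]]),
             end = as.integer(bed[[3L]]), stringsAsFactors = FALSE)
}

#' Per-window log2 coverage difference between case and control
#'
#' Raw counts are normalized per sample to sum to one, a pseudocount of
#' `0.5 / sum(raw)` per sample keeps zero windows finite, and the log2
#' ratio of (case over control) normalized coverage is returned. Windows
#' where both samples have zero raw coverage are reported `NA` (missing,
#' e.g. off-target in exome capture) rather than zero. Multiplying all raw
#' counts of one sample by a constant leaves the result unchanged.
#'
#' @param windows Window grid from [tile_windows()].
#' @param case_raw,control_raw Raw counts from [physical_coverage()] on the
#'   same grid.
#' @return `windows` extended with `raw_case`, `raw_control`, `norm_case`,
#'   `norm_control`, `log2diff`.
#' @export
log2_difference <- function(windows, case_raw, control_raw) {
  if (length(case_raw) != nrow(windows) || length(control_raw) != nrow(windows))
    stopf("window grid mismatch: %d windows vs %d/%d counts",
          nrow(windows), length(case_raw), length(control_raw))
  eps_c <- 0.5 / sum(case_raw)
  eps_k <- 0.5 / sum(control_raw)
  norm_c <- case_raw / sum(case_raw)
  norm_k <- control_raw / sum(control_raw)
  l2 <- log2((norm_c + eps_c) / (norm_k + eps_k))
  l2[case_raw == 0L & control_raw == 0L] <- NA_real_
  out <- windows
  out$raw_case <- as.integer(case_raw)
  out$raw_control <- as.integer(control_raw)
  out$norm_case <- norm_c
  out$norm_control <- norm_k
  out$log2diff <- l2
  out
}

#' Sliding-mean smoothing of a log2-difference series
#'
#' Centered moving average over `span` windows; missing windows are ignored
#' inside each span and the edges use truncated spans.
#'
#' @param x Numeric series (may contain `NA`).
#' @param span Window count of the sliding mean (default 25).
#' @return Smoothed numeric series of the same length.
#' @export
smooth_log2 <- function(x, span = 25L) {
  zoo::rollapply(x, width = span,
                 FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
                 partial = TRUE, align = "center")
}

# Matched-filter change-point refinement of one call edge: with the outside
# and inside log2 levels fixed (estimated from the flank and the call core),
# choose the split position minimizing the two-segment squared error of the
# raw log2diff. Fixing the levels makes the fit robust when the coarse edge
# from the smoothed series is displaced by several spans.
refine_edge <- function(l2, coarse, search, level_left, level_right, lo, hi) {
  a <- max(lo, coarse - search)
  b <- min(hi, coarse + search)
  if (b - a < 2L) return(coarse)
  seg <- l2[a:b]
  ok <- !is.na(seg)
  # cost(split s) = sum_{i<s} (x - level_left)^2 + sum_{i>=s} (x - level_right)^2
  dl <- ifelse(ok, (seg - level_left)^2, 0)
  dr <- ifelse(ok, (seg - level_right)^2, 0)
  cum_l <- cumsum(dl)
  cum_r <- rev(cumsum(rev(dr)))
  # split before position k (k = 1 .. len): left = 1..k-1, right = k..len
  len <- length(seg)
  cost <- c(cum_r[1L], cum_l[seq_len(len - 1L)] + cum_r[seq_len(len - 1L) + 1L])
  a + which.min(cost) - 1L
}

# Poisson change-point refinement on fragment endpoint counts. k = case
# endpoint counts per window, lam = expected counts under no deletion
# (control counts scaled by the flank depth ratio, pseudocount-stabilized).
# The case rate is lam to the left of the edge and `rate_in * lam` to the
# right (left edge of a deletion; callers flip the series for the right
# edge). Maximizes the profile log-likelihood over the split.
refine_edge_poisson <- function(k, lam, coarse, search, rate_in, lo, hi) {
  a <- max(lo, coarse - search)
  b <- min(hi, coarse + search)
  if (b - a < 2L) return(coarse)
  ks <- k[a:b]; ls <- pmax(lam[a:b], 1e-9)
  # loglik difference of "inside" vs "outside" per window
  d <- ks * log(rate_in) - (rate_in - 1) * ls
  # split s: windows >= s are inside; maximize sum_{i>=s} d_i
  tail_sum <- rev(cumsum(rev(d)))
  a + which.max(tail_sum) - 1L
}

endpoint_counts <- function(pos, windows) {
  width <- windows$end[1L] - windows$start[1L]
  idx <- pos %/% width + 1L
  tabulate(idx[idx >= 1L & idx <= nrow(windows)], nbins = nrow(windows))
}

#' Call deletions from a smoothed log2-difference series
#'
#' Finds maximal runs of at least `min_windows` consecutive windows whose
#' smoothed value is at or below `threshold`; runs separated by fewer than
#' `gap_windows` super-threshold windows are merged. Each breakpoint is then
#' refined by a fixed-level change-point fit on the raw log2diff — the
#' sliding mean alone drags the threshold crossing several windows into the
#' event. When the fragment tables are supplied, breakpoints are further
#' sharpened by a Poisson change-point fit on per-window fragment *end*
#' counts (left edge) and *start* counts (right edge): a deletion removes
#' every fragment of the lost allele that overlaps it, so its edges are
#' exact in those coordinates and, unlike overlap counts, they are not
#' correlated across neighbouring windows. Only deletions (negative
#' log2diff) are called; a heterozygous deletion sits near -1 and the
#' default threshold of -0.7 leaves margin for capture noise around that
#' level.
#'
#' @param cov Coverage table from [log2_difference()].
#' @param smoothed Smoothed series from [smooth_log2()]; computed from
#'   `cov$log2diff` with `span` when omitted.
#' @param threshold Call windows with smoothed value `<= threshold`
#'   (default -0.7).
#' @param min_windows Minimum run length (default 10).
#' @param gap_windows Merge runs separated by fewer than this many
#'   super-threshold windows. Default `6 * span`: at realistic capture noise
#'   the smoothed series makes brief excursions above the threshold inside a
#'   real event, so gaps shorter than a few smoothing spans are below the
#'   detector's resolution and two events that close are reported as one.
#' @param span Sliding-mean span (used when `smoothed` is omitted) and
#'   refinement half-width.
#' @param refine Refine breakpoints by change-point fit (default `TRUE`).
#' @param case_fragments,control_fragments Optional fragment tables (as
#'   given to [physical_coverage()]) enabling the fragment-endpoint
#'   refinement.
#' @return A data.frame of calls: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_windows`, `mean_log2diff`, `origin`
#'   (`"undetermined"`; see [phase_deletion()]).
#' @export
call_deletions <- function(cov, smoothed = NULL, threshold = -0.7,
                           min_windows = 10L, gap_windows = 6L * span,
                           span = 25L, refine = TRUE,
                           case_fragments = NULL, control_fragments = NULL) {
  smoothed <- smoothed %||% smooth_log2(cov$log2diff, span)
  below <- !is.na(smoothed) & smoothed <= threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1L) {                     # merge across short gaps
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L < gap_windows)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  if (nrow(runs)) runs <- runs[runs$end - runs$start + 1L >= min_windows, , drop = FALSE]
  if (!nrow(runs)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), mean_log2diff = numeric(),
                      origin = character(), stringsAsFactors = FALSE))
  }
  n_win <- nrow(cov)
  have_frags <- !is.null(case_fragments) && !is.null(control_fragments)
  if (have_frags) {
    keep_c <- sub("^chr", "", case_fragments$chrom) == sub("^chr", "", cov$chrom[1L])
    keep_k <- sub("^chr", "", control_fragments$chrom) == sub("^chr", "", cov$chrom[1L])
    end_case <- endpoint_counts(case_fragments$end[keep_c] - 1L, cov)
    end_ctl <- endpoint_counts(control_fragments$end[keep_k] - 1L, cov)
    start_case <- endpoint_counts(case_fragments$start[keep_c], cov)
    start_ctl <- endpoint_counts(control_fragments$start[keep_k], cov)
  }
  calls <- lapply(seq_len(nrow(runs)), function(i) {
    w1 <- runs$start[i]; w2 <- runs$end[i]
    if (refine) {
      mid <- (w1 + w2) %/% 2L
      core <- cov$log2diff[max(w1 + span, mid - span):min(w2 - span, mid + span)]
      level_in <- median(core, na.rm = TRUE)
      flank_l <- cov$log2diff[max(1L, w1 - 8L * span):max(1L, w1 - 2L * span)]
      flank_r <- cov$log2diff[min(n_win, w2 + 2L * span):min(n_win, w2 + 8L * span)]
      level_out_l <- median(flank_l, na.rm = TRUE)
      level_out_r <- median(flank_r, na.rm = TRUE)
      search <- 4L * span
      w1 <- refine_edge(cov$log2diff, w1, search, level_out_l, level_in,
                        lo = 1L, hi = mid)
      w2 <- refine_edge(cov$log2diff, w2 + 1L, search, level_in, level_out_r,
                        lo = mid, hi = n_win) - 1L
      if (have_frags) {
        rate_in <- min(max(2^level_in, 0.05), 0.95)
        fl <- max(1L, w1 - 8L * span):max(1L, w1 - 2L * span)
        t_l <- sum(end_case[fl]) / max(sum(end_ctl[fl]), 1L)
        w1 <- refine_edge_poisson(end_case, t_l * (end_ctl + 0.5), w1,
                                  2L * span, rate_in, lo = 1L, hi = mid)
        fr_ <- min(n_win, w2 + 2L * span):min(n_win, w2 + 8L * span)
        t_r <- sum(start_case[fr_]) / max(sum(start_ctl[fr_]), 1L)
        # right edge: reverse the series so it looks like a left edge
        rev_case <- rev(start_case)
        rev_lam <- rev(t_r * (start_ctl + 0.5))
        e_rev <- refine_edge_poisson(rev_case, rev_lam, n_win - w2 + 1L,
                                     2L * span, rate_in,
                                     lo = 1L, hi = n_win - mid + 1L)
        w2 <- n_win - e_rev + 1L
      }
    }
    data.frame(chrom = cov$chrom[w1],
               start = cov$start[w1] + 1L,          # report 1-based inclusive
               end = cov$end[w2],
               n_windows = w2 - w1 + 1L,
               mean_log2diff = mean(cov$log2diff[w1:w2], na.rm = TRUE),
               origin = "undetermined", stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Simulate case/control fragment sets with an engineered deletion
#'
#' Control fragments are placed uniformly over the region. The case sample
#' uses the same process, but each fragment is assigned to one of the two
#' chromosome copies with probability 1/2 and fragments of the deleted copy
#' that overlap the deletion are removed — a heterozygous deletion
#' (`deletion_fraction = 0.5`) therefore halves coverage inside the event
#' with a sharp edge in reference coordinates, exactly as a real deletion
#' does (the deleted allele yields no fragments across the lost interval).
#' Fragment length defaults to 250 bp, a typical exome insert size.
#'
#' @param region_length Region length in bp.
#' @param deletion `c(start, end)` (1-based) of the engineered deletion, or
#'   `NULL` for none.
#' @param mean_fragments_per_window Expected fragments overlapping each
#'   window outside the deletion (default 100, the scale of a deep clinical
#'   exome: ~100X base coverage at 250 bp inserts).
#' @param fragment_length Fragment (outer span) length in bp.
#' @param window Window width the depth target refers to.
#' @param deletion_fraction Retention probability inside the deletion.
#' @param chrom Chromosome name.
#' @param seed RNG seed.
#' @return A list of fragment data.frames `case` and `control` (BED-style,
#'   0-based half-open).
#' @export
simulate_cnv_fragments <- function(region_length, deletion = NULL,
                                   mean_fragments_per_window = 100,
                                   fragment_length = 250L, window = 100L,
                                   deletion_fraction = 0.5, chrom = "X",
                                   seed = 1L) {
  n <- round(region_length * mean_fragments_per_window / (fragment_length + window - 1L))
  draw <- function(s, thin) {
    withr::with_seed(s, {
      start <- floor(runif(n) * (region_length - fragment_length))
      fr <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + fragment_length),
                       stringsAsFactors = FALSE)
      if (thin && !is.null(deletion)) {
        overlaps <- fr$end > deletion[1L] - 1L & fr$start < deletion[2L]
        drop <- overlaps & runif(n) > deletion_fraction
        fr <- fr[!drop, , drop = FALSE]
      }
      fr
    })
  }
  list(case = draw(seed, thin = TRUE), control = draw(seed + 1L, thin = FALSE))
}
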