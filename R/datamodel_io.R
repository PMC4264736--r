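# Domain tables and readers/writers for the standard formats the pipeline
# touches. Coordinates are 1-based inclusive in every user-facing table (the
# VCF/pileup convention); the 0-based half-open convention is used only inside
# the coverage-window machinery (see cnv_coverage.R), with conversion
# centralized in window reporting.

#' Pseudo-autosomal regions of chromosome X
#'
#' Returns the PAR1/PAR2 intervals used to exclude pseudo-autosomal SNPs from
#' XCI analysis (they recombine and follow diploid inheritance on both sexes,
#' so their allelic ratios carry no inactivation signal).
#'
#' @param genome Genome build; only `"grch37"` is bundled. Coordinates are
#'   chrX:60001-2699520 (PAR1) and chrX:154931044-155260560 (PAR2), 1-based
#'   inclusive.
#' @return A data.frame with columns `name`, `chrom`, `start`, `end`.
#' @seealso [read_par_bed()] to override with custom intervals.
#' @export
#' @examples
#' par_regions()
par_regions <- function(genome = "grch37") {
  if (!identical(tolower(genome), "grch37"))
    stopf("unknown genome build '%s'; supply intervals via read_par_bed()", genome)
  data.frame(
    name  = c("PAR1", "PAR2"),
    chrom = c("X", "X"),
    start = c(60001, 154931044),
    end   = c(2699520, 155260560),
    stringsAsFactors = FALSE
  )
}

#' Read PAR intervals from a BED file
#'
#' BED input is 0-based half-open; the returned table is converted to the
#' package's 1-based inclusive convention.
#'
#' @param path Path to a 3+ column BED file (chrom, start, end, \[name\]).
#' @return A data.frame like [par_regions()].
#' @export
read_par_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stopf("PAR BED needs at least 3 columns: %s", path)
  data.frame(
    name  = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else paste0("PAR", seq_len(nrow(bed))),
    chrom = sub("^chr", "", as.character(bed[[1L]])),
    start = as.integer(bed[[2L]]) + 1L,
    end   = as.integer(bed[[3L]]),
    stringsAsFactors = FALSE
  )
}

#' Test positions for PAR membership
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param par PAR table from [par_regions()] or [read_par_bed()].
#' @return Logical vector, `TRUE` where the position falls inside a PAR.
#' @export
in_par <- function(chrom, pos, par = par_regions()) {
  chrom <- sub("^chr", "", as.character(chrom))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(par))) {
    hit <- hit | (chrom == par$chrom[i] & pos >= par$start[i] & pos <= par$end[i])
  }
  hit
}

# VCF -------------------------------------------------------------------------

#' Read biallelic SNVs from a VCF file
#'
#' Parses a VCF 4.x file and returns one row per biallelic SNP record together
#' with the raw per-sample GT strings, which preserve ploidy ("0/1" stays
#' diploid, "1" stays haploid — hemizygous male X calls are not inflated to
#' diploid). Indel and multi-allelic records are skipped and counted.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @return A data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `filter` plus one character column per sample holding the GT string.
#'   Attributes: `skipped` (number of non-biallelic-SNP records dropped) and
#'   `samples` (sample names).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), filter = character(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- 0L
    attr(out, "samples") <- character()
    return(out)
  }
  bases <- c("A", "C", "G", "T")
  keep <- !is.na(fix$ALT) & fix$REF %in% bases & fix$ALT %in% bases
  skipped <- sum(!keep)
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) stopf("malformed GT field in '%s': %s", path, conditionMessage(e)))
  out <- data.frame(
    chrom  = sub("^chr", "", fix$CHROM[keep]),
    pos    = as.integer(fix$POS[keep]),
    id     = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".", "", fix$ID[keep]),
    ref    = fix$REF[keep],
    alt    = fix$ALT[keep],
    filter = ifelse(is.na(fix$FILTER[keep]), ".", fix$FILTER[keep]),
    stringsAsFactors = FALSE
  )
  samples <- colnames(gt) %||% character()
  for (s in samples) out[[s]] <- unname(gt[keep, s])
  bad <- which(!vapply(samples, function(s) all(is.na(out[[s]]) | grepl("^\\.$|^[0-9]+([/|][0-9]+)?$", out[[s]])), TRUE))
  if (length(bad))
    stopf("malformed GT strings for sample(s): %s", paste(samples[bad], collapse = ", "))
  attr(out, "skipped") <- skipped
  attr(out, "samples") <- samples
  out
}

#' Expand a GT string to an allele vector
#'
#' `"0/1"` with ref "A", alt "G" becomes `c("A", "G")`; a haploid `"1"`
#' becomes `"G"`. Missing calls (`"."` or `"./."`) return `NA`.
#'
#' @param gt GT string.
#' @param ref,alt Reference and alternative alleles of the site.
#' @return Character vector of alleles (length = ploidy), or `NA`.
#' @export
gt_alleles <- function(gt, ref, alt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  idx <- strsplit(gt, "[/|]")[[1L]]
  if (any(idx == ".")) return(NA_character_)
  alleles <- c(ref, alt)[as.integer(idx) + 1L]
  if (anyNA(alleles)) stopf("GT '%s' indexes beyond the biallelic site %s/%s", gt, ref, alt)
  alleles
}

# Pileup ----------------------------------------------------------------------

# Decode one mpileup base/quality string pair into per-base counts.
# Consumes read-start (^ + mapq char), read-end ($), indels (+N/-N + seq),
# deletion placeholders (*) and reference skips (<,>) — the latter two use up
# a quality character but are never counted.
parse_pileup_bases <- function(bases, quals, ref, min_base_qual) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  bs <- strsplit(bases, "")[[1L]]
  qs <- utf8ToInt(quals) - 33L
  i <- 1L; qi <- 1L
  ref <- toupper(ref)
  while (i <= length(bs)) {
    ch <- bs[i]
    if (ch == "^") { i <- i + 2L; next }          # start mark + mapping quality
    if (ch == "$") { i <- i + 1L; next }
    if (ch %in% c("+", "-")) {                    # indel token: length then seq
      j <- i + 1L
      while (j <= length(bs) && grepl("[0-9]", bs[j])) j <- j + 1L
      len <- as.integer(paste(bs[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
      next
    }
    if (qi > length(qs)) stopf("base/quality string length mismatch in pileup line")
    q <- qs[qi]; qi <- qi + 1L
    base <- switch(ch,
                   "." = ref, "," = ref,
                   "A" = "A", "a" = "A", "C" = "C", "c" = "C",
                   "G" = "G", "g" = "G", "T" = "T", "t" = "T",
                   NA_character_)                  # *, <, >, N: consume, no count
    if (!is.na(base) && base %in% names(counts) && q > min_base_qual)
      counts[base] <- counts[base] + 1L
    i <- i + 1L
  }
  if (qi != length(qs) + 1L) stopf("base/quality string length mismatch in pileup line")
  counts
}

#' Read a samtools mpileup text file into allele counts
#'
#' Counts, per position, the bases whose Phred quality exceeds
#' `min_base_qual` (strictly greater-than). Read-start/read-end marks and
#' indel tokens in the base string are consumed but never counted, so the
#' returned depth is the quality-passing depth and never exceeds the pileup's
#' declared depth.
#'
#' @param path Path to a samtools mpileup text file (chrom, pos, ref, depth,
#'   bases, qualities).
#' @param min_base_qual Minimum Phred base quality; bases with quality
#'   `> min_base_qual` are counted (default 20).
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`, `depth` (sum of the four counts) and `declared_depth` (the pileup's
#'   own depth column).
#' @export
read_pileup <- function(path, min_base_qual = 20) {
  if (!file.exists(path)) stopf("pileup not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      A = integer(), C = integer(), G = integer(), T = integer(),
                      depth = integer(), declared_depth = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[[k]], "[ \t]+")[[1L]]
    if (length(f) < 6L) stopf("pileup line %d has %d fields (need 6)", k, length(f))
    counts <- tryCatch(parse_pileup_bases(f[5L], f[6L], f[3L], min_base_qual),
                       error = function(e) stopf("pileup line %d: %s", k, conditionMessage(e)))
    data.frame(chrom = sub("^chr", "", f[1L]), pos = as.integer(f[2L]),
               ref = toupper(f[3L]),
               A = counts[["A"]], C = counts[["C"]], G = counts[["G"]], T = counts[["T"]],
               depth = sum(counts), declared_depth = as.integer(f[4L]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# FASTA / FASTQ ---------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (line wrapping is handled).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path, format = "fasta")

#' Write sequences to a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

check_read_alphabet <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stopf("%d read(s) contain characters outside A,C,G,T,N", sum(bad))
  invisible(seq)
}

#' Write sequencing reads to FASTQ (Phred+33)
#'
#' @param reads A data.frame with columns `name`, `seq` and either `qual`
#'   (Phred+33 quality strings) or a uniform `quality` attribute supplied via
#'   the `base_quality` argument.
#' @param path Output path.
#' @param base_quality Uniform Phred quality used when `reads$qual` is absent.
#' @export
write_fastq <- function(reads, path, base_quality = 40) {
  check_read_alphabet(reads$seq)
  qual <- reads$qual %||% strrep(intToUtf8(base_quality + 33L), nchar(reads$seq))
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$name
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(name = names(dna),
             seq = as.character(dna),
             qual = as.character(S4Vectors::mcols(dna)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
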