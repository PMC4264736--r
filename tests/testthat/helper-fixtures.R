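# Fixtures are built in code at test time; nothing binary ships with the
# package.

# A 4-record trio VCF: two biallelic SNPs, one indel, one multi-allelic.
write_toy_trio_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tCHILD\tMOTHER\tFATHER",
    "X\t3000000\trs100\tA\tT\t50\tPASS\t.\tGT\t0/1\t0/1\t0",
    "X\t3000200\t.\tG\tGTT\t50\tPASS\t.\tGT\t0/1\t0/0\t0",
    "X\t3000400\trs101\tC\tG\t50\tq10\t.\tGT\t0/1\t0/1\t1",
    "X\t3000600\trs102\tG\tA,C\t50\tPASS\t.\tGT\t1/2\t0/1\t1"
  )
  writeLines(lines, path)
  path
}

# Trio VCF whose X genotypes exercise phased / uninformative / mendelian /
# out-of-phase cases with known truth.
write_phasing_vcf <- function(path = tempfile(fileext = ".vcf")) {
  rec <- function(pos, id, ref, alt, gc, gm, gf)
    sprintf("X\t%d\t%s\t%s\t%s\t50\tPASS\t.\tGT\t%s\t%s\t%s", pos, id, ref, alt, gc, gm, gf)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tCHILD\tMOTHER\tFATHER",
    rec(5000000, "rs1", "A", "T", "0/1", "0/1", "0/0"),  # maternal T, paternal A
    rec(5000100, "rs2", "A", "T", "0/1", "0/1", "1/1"),  # maternal A, paternal T
    rec(5001000, "rs3", "T", "C", "0/1", "0/0", "0/0"),  # mendelian error (C unattributable)
    rec(5002000, "rs4", "G", "A", "0/0", "0/1", "1/1"),  # out-of-phase: child G, father A
    rec(5003000, "rs5", "G", "A", "0/0", "0/0", "0/0")   # consistent, uninformative
  )
  writeLines(lines, path)
  path
}

write_toy_pileup <- function(lines, path = tempfile(fileext = ".pileup")) {
  writeLines(lines, path)
  path
}

random_transcriptome <- function(n = 3, len = 800, seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("tx%02d", seq_len(n))
    Biostrings::DNAStringSet(seqs)
  })
}

# Transcript-space SNPs at fixed offsets, consistent with the transcriptome.
transcript_snps <- function(transcripts, offsets = c(250, 500), seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    seqs <- as.character(transcripts)
    for (tx in names(seqs)) {
      for (o in offsets) {
        ref <- substr(seqs[[tx]], o, o)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        rows[[length(rows) + 1]] <- data.frame(
          transcript = tx, offset = o, ref = ref, alt = alt,
          chrom = "X", pos = 10000000L + length(rows) * 1000L,
          id = sprintf("rsT%03d", length(rows)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
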