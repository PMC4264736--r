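# The enumeration oracle lives in helper-oracles.R.

test_that("transmission phasing matches the enumeration oracle on every X trio genotype", {
  gts2 <- list(c("A", "A"), c("A", "G"), c("G", "G"))
  gts1 <- list("A", "G")
  for (child in gts2) for (mother in gts2) for (father in gts1) {
    got <- phase_by_transmission(child, mother, father)
    want <- enumerate_transmissions(child, mother, father)
    info <- sprintf("child=%s mother=%s father=%s",
                    paste(child, collapse = "/"), paste(mother, collapse = "/"),
                    paste(father, collapse = "/"))
    expect_equal(got$status, want$status, info = info)
    if (want$status == "phased") {
      expect_equal(got$maternal, want$maternal, info = info)
      expect_equal(got$paternal, want$paternal, info = info)
      # phased alleles reconstruct the child genotype
      expect_setequal(c(got$maternal, got$paternal), child)
    }
  }
})

test_that("transmission phasing matches the oracle for diploid (PAR-like) fathers", {
  gts2 <- list(c("A", "A"), c("A", "G"), c("G", "G"))
  for (child in gts2) for (mother in gts2) for (father in gts2) {
    got <- phase_by_transmission(child, mother, father)
    want <- enumerate_transmissions(child, mother, father)
    expect_equal(got$status, want$status,
                 info = sprintf("child=%s mother=%s father=%s",
                                paste(child, collapse = "/"),
                                paste(mother, collapse = "/"),
                                paste(father, collapse = "/")))
  }
})

test_that("the worked trio examples phase as documented", {
  # child A/T, mother A/T, father hemizygous A: T must be maternal
  r1 <- phase_by_transmission(c("A", "T"), c("A", "T"), "A")
  expect_equal(r1$status, "phased")
  expect_equal(r1$maternal, "T")
  expect_equal(r1$paternal, "A")

  # child T/C with neither parent carrying C: mendelian error
  r2 <- phase_by_transmission(c("T", "C"), c("T", "T"), "T")
  expect_equal(r2$status, "mendelian_error")

  # phase by elimination with the father carrying the other allele
  r3 <- phase_by_transmission(c("A", "T"), c("A", "T"), "T")
  expect_equal(r3$maternal, "A")
  expect_equal(r3$paternal, "T")
})

test_that("ploidy recoding collapses hemizygous calls and flags impossible ones", {
  expect_equal(recode_ploidy(c("A", "A"), "male", "X_nonPAR"), "A")
  expect_equal(recode_ploidy(c("T", "T"), "female", "X_nonPAR", in_deletion = TRUE), "T")
  expect_equal(recode_ploidy(c("G", "A"), "female", "X_nonPAR"), c("G", "A"))
  expect_equal(recode_ploidy(c("A", "A"), "male", "PAR"), c("A", "A"))

  flagged <- recode_ploidy(c("A", "G"), "male", "X_nonPAR")
  expect_equal(attr(flagged, "flag"), "het_at_haploid_locus")
})

test_that("out-of-phase genotypes provide parent-resolved deletion evidence", {
  # the documented pattern: child G, mother G/A, father hemizygous A
  r1 <- detect_out_of_phase("G", c("G", "A"), "A")
  expect_equal(r1$status, "out_of_phase")
  expect_equal(r1$evidence, "paternal_deletion")

  # fully consistent: no evidence
  expect_equal(detect_out_of_phase("G", c("G", "G"), "G")$status, "uninformative")

  # child lacks the mother's obligate allele: maternal deletion evidence
  r3 <- detect_out_of_phase("A", c("G", "G"), "A")
  expect_equal(r3$status, "out_of_phase")
  expect_equal(r3$evidence, "maternal_deletion")
})

test_that("deletion phasing takes a majority vote over informative sites", {
  mk <- function(evidence) data.frame(pos = seq_along(evidence) * 1000,
                                      status = ifelse(is.na(evidence),
                                                      "uninformative", "out_of_phase"),
                                      evidence = evidence, stringsAsFactors = FALSE)
  one <- phase_deletion(mk("paternal_deletion"))
  expect_equal(one$origin, "paternal")
  expect_equal(one$support, 1)

  maj <- phase_deletion(mk(c(rep("paternal_deletion", 3), "maternal_deletion")))
  expect_equal(maj$origin, "paternal")
  expect_equal(maj$support, 0.75)
  expect_equal(maj$n_informative, 4L)

  expect_equal(phase_deletion(mk(NA_character_))$origin, "undetermined")
})

test_that("trio VCF sites phase end to end with correct statuses", {
  sites <- read_vcf(write_phasing_vcf())
  phased <- phase_trio_sites(sites, "CHILD", "MOTHER", "FATHER")

  expect_equal(phased$status,
               c("phased", "phased", "mendelian_error", "out_of_phase", "uninformative"))
  # rs1: alt T maternal; rs2: alt T paternal
  expect_equal(phased$phase[1], "maternal")
  expect_equal(phased$phase[2], "paternal")
  expect_equal(phased$evidence[4], "paternal_deletion")

  del <- phase_deletion(phased)
  expect_equal(del$origin, "paternal")
})

test_that("phase recovery on simulator output is perfect at informative sites", {
  # simulated phased SNPs: mother het, father carries the paternal allele
  pool <- assign_phase_bins(data.frame(
    chrom = "X", pos = 3e6 + (1:200) * 500,
    ref = "A", alt = "G", stringsAsFactors = FALSE), seed = 19)
  # construct trio GTs consistent with the known phase
  gts <- lapply(seq_len(nrow(pool)), function(i) {
    if (pool$phase[i] == "maternal") {       # alt from mother
      list(child = "0/1", mother = "0/1", father = "0")
    } else {                                 # alt from father
      list(child = "0/1", mother = "0/0", father = "1")
    }
  })
  sites <- pool
  sites$CHILD <- vapply(gts, `[[`, "", "child")
  sites$MOTHER <- vapply(gts, `[[`, "", "mother")
  sites$FATHER <- vapply(gts, `[[`, "", "father")
  phased <- phase_trio_sites(sites, "CHILD", "MOTHER", "FATHER")
  expect_true(all(phased$status == "phased"))
  expect_identical(phased$phase, pool$phase)   # zero false phases
})
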