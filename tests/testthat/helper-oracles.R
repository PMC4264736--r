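# Independent oracle: brute-force enumeration of legal transmissions. A
# daughter receives one allele from the mother's genotype and one from the
# father's; a combination is legal when the received pair equals her
# genotype as a multiset. Kept independent of the package's rule-based
# implementation on purpose.
enumerate_transmissions <- function(child, mother, father) {
  legal <- list()
  for (ma in mother) for (pa in father) {
    if (identical(sort(c(ma, pa)), sort(child)))
      legal[[length(legal) + 1L]] <- c(maternal = ma, paternal = pa)
  }
  legal <- unique(legal)
  if (length(legal) == 0L) return(list(status = "mendelian_error"))
  if (length(legal) == 1L)
    return(list(status = "phased", maternal = legal[[1]][["maternal"]],
                paternal = legal[[1]][["paternal"]]))
  list(status = "uninformative")
}
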