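# Phase-by-transmission for family trios on chromosome X: ploidy recoding
# (hemizygous male X, loci inside deletions), parent-of-origin assignment of
# the child's heterozygous alleles, Mendelian-error detection, and
# out-of-phase genotype evidence for hemizygous deletions. A daughter
# receives exactly one X from each parent, and the father's hemizygosity
# outside the PAR makes essentially every high-quality heterozygous X SNP
# phaseable — an asymmetry an autosomal trio does not enjoy.

phase_result <- function(status, maternal = NA_character_,
                         paternal = NA_character_, evidence = NA_character_,
                         note = NA_character_) {
  structure(list(status = status, maternal = maternal, paternal = paternal,
                 evidence = evidence, note = note),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat("phase_result:", x$status)
  if (!is.na(x$maternal)) cat(sprintf("  maternal=%s paternal=%s", x$maternal, x$paternal))
  if (!is.na(x$evidence)) cat("  evidence:", x$evidence)
  if (!is.na(x$note)) cat("  [", x$note, "]")
  cat("\n")
  invisible(x)
}

#' Recode a genotype to match its expected ploidy
#'
#' A male X genotype outside the PAR, or any genotype inside a hemizygous
#' deletion, carries one real allele: a diploid-style call such as `"A/A"` is
#' recoded to `"A"`. A heterozygous call where ploidy 1 is expected is a
#' data-quality signal: it is returned unchanged with attribute
#' `flag = "het_at_haploid_locus"` rather than failing.
#'
#' @param alleles Character vector of alleles (e.g. `c("A", "A")`), or a GT
#'   allele expansion from [gt_alleles()].
#' @param sex `"female"` or `"male"`.
#' @param region_class `"X_nonPAR"`, `"PAR"`, or `"autosome_like"`.
#' @param in_deletion `TRUE` when the locus lies inside a called hemizygous
#'   deletion in this sample.
#' @return Character vector of alleles at the expected ploidy.
#' @export
recode_ploidy <- function(alleles, sex = c("female", "male"),
                          region_class = c("X_nonPAR", "PAR", "autosome_like"),
                          in_deletion = FALSE) {
  sex <- match.arg(sex)
  region_class <- match.arg(region_class)
  if (anyNA(alleles)) return(NA_character_)
  haploid <- in_deletion || (sex == "male" && region_class == "X_nonPAR")
  if (!haploid || length(alleles) == 1L) return(alleles)
  u <- unique(alleles)
  if (length(u) == 1L) return(u)
  attr(alleles, "flag") <- "het_at_haploid_locus"
  alleles
}

#' Assign parent-of-origin to a child's alleles by transmission
#'
#' Given ploidy-recoded trio genotypes at one biallelic site, determines
#' which of the child's alleles came from the mother and which from the
#' father. On X outside the PAR the father is hemizygous, so a heterozygous
#' daughter is phased whenever her genotype is Mendelian-consistent: the
#' paternal allele is the father's single allele and the maternal allele is
#' the other one. A child allele neither parent can have transmitted yields
#' `mendelian_error` (a de novo point variant is indistinguishable from a
#' genotyping error here and maps to the same status, with a note). A
#' diploid father whose transmission cannot be resolved uniquely yields
#' `uninformative`.
#'
#' @param child,mother,father Character vectors of alleles (length 1 or 2),
#'   already ploidy-recoded ([recode_ploidy()]).
#' @return A `phase_result`: `status` in `{phased, uninformative,
#'   mendelian_error}` plus `maternal`/`paternal` alleles when phased. For a
#'   phased result `{maternal, paternal}` reconstructs the child genotype.
#' @export
phase_by_transmission <- function(child, mother, father) {
  if (anyNA(child) || anyNA(mother) || anyNA(father))
    return(phase_result("uninformative", note = "missing genotype"))
  if (length(child) == 1L)
    return(phase_result("uninformative", note = "child not diploid here; see detect_out_of_phase"))

  me <- phase_result("mendelian_error",
                     note = "child allele unattributable; genotype error or de novo variant")
  if (child[1L] == child[2L]) {                       # homozygous child
    a <- child[1L]
    if (a %in% mother && a %in% father)
      return(phase_result("phased", maternal = a, paternal = a))
    return(me)
  }
  # heterozygous child
  if (length(father) == 1L) {                         # hemizygous father (X nonPAR)
    if (!(father %in% child)) return(me)
    pat <- father
    mat <- setdiff(child, pat)
    if (length(mat) == 0L) mat <- pat                 # child het means this cannot happen
    if (!(mat %in% mother)) return(me)
    return(phase_result("phased", maternal = mat, paternal = pat))
  }
  # diploid father (PAR / autosome-like): enumerate legal orderings
  legal <- list()
  for (ord in list(child, rev(child))) {
    if (ord[1L] %in% mother && ord[2L] %in% father)
      legal[[length(legal) + 1L]] <- ord
  }
  if (length(legal) == 0L) return(me)
  uniq <- unique(lapply(legal, paste, collapse = "|"))
  if (length(uniq) == 1L) {
    ord <- legal[[1L]]
    return(phase_result("phased", maternal = ord[1L], paternal = ord[2L]))
  }
  phase_result("uninformative", note = "both transmissions legal")
}

#' Detect an out-of-phase genotype (hemizygous-deletion evidence)
#'
#' A daughter on X outside the PAR must carry one allele from each parent.
#' When she is apparently homozygous/hemizygous for allele `g` while the
#' father is hemizygous for a different allele, the paternal copy of the
#' locus is missing — evidence of a deletion on the paternal X.
#' Symmetrically, a homozygous mother whose obligate allele the child lacks
#' is evidence of a deletion on the maternal X.
#'
#' @inheritParams phase_by_transmission
#' @return A `phase_result` with `status` `"out_of_phase"` (and `evidence`
#'   `"paternal_deletion"` or `"maternal_deletion"`) or `"uninformative"`.
#' @export
detect_out_of_phase <- function(child, mother, father) {
  if (anyNA(child) || anyNA(mother) || anyNA(father))
    return(phase_result("uninformative", note = "missing genotype"))
  if (length(unique(child)) != 1L)
    return(phase_result("uninformative", note = "child heterozygous"))
  g <- unique(child)
  if (length(father) == 1L && father != g && g %in% mother)
    return(phase_result("out_of_phase", maternal = g,
                        evidence = "paternal_deletion"))
  if (length(unique(mother)) == 1L && unique(mother) != g && g %in% father)
    return(phase_result("out_of_phase", paternal = g,
                        evidence = "maternal_deletion"))
  phase_result("uninformative")
}

#' Phase every site of a trio variant table
#'
#' Vectorized driver: recodes the father (and, inside `deletion_region`, the
#' child) to haploid on X outside the PAR, runs [phase_by_transmission()] on
#' heterozygous child sites and [detect_out_of_phase()] on
#' homozygous-looking ones, and labels each site's alt allele with its
#' parental origin for downstream XCI estimation.
#'
#' @param sites Variant table from [read_vcf()] (with per-sample GT
#'   columns).
#' @param child,mother,father Sample column names in `sites`.
#' @param child_sex Sex of the child; phasing assumes `"female"` for XCI.
#' @param par PAR table; sites inside it are treated as diploid for all
#'   members.
#' @param deletion_region Optional `c(start, end)` (1-based) of a called
#'   hemizygous deletion in the child.
#' @return `sites` with added columns `region_class`, `status`,
#'   `maternal_allele`, `paternal_allele`, `evidence`, and `phase` (parental
#'   origin of the alt allele at phased heterozygous sites, else `NA`).
#' @export
phase_trio_sites <- function(sites, child, mother, father,
                             child_sex = "female", par = par_regions(),
                             deletion_region = NULL) {
  for (s in c(child, mother, father))
    if (!s %in% names(sites)) stopf("sample column '%s' not found in sites", s)
  n <- nrow(sites)
  region_class <- ifelse(sites$chrom == "X",
                         ifelse(in_par(sites$chrom, sites$pos, par), "PAR", "X_nonPAR"),
                         "autosome_like")
  status <- character(n); mat <- pat <- evid <- rep(NA_character_, n)
  phase <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    in_del <- !is.null(deletion_region) && sites$chrom[i] == "X" &&
      sites$pos[i] >= deletion_region[1L] && sites$pos[i] <= deletion_region[2L]
    gc <- recode_ploidy(gt_alleles(sites[[child]][i], sites$ref[i], sites$alt[i]),
                        child_sex, region_class[i], in_deletion = in_del)
    gm <- recode_ploidy(gt_alleles(sites[[mother]][i], sites$ref[i], sites$alt[i]),
                        "female", region_class[i])
    gf <- recode_ploidy(gt_alleles(sites[[father]][i], sites$ref[i], sites$alt[i]),
                        "male", region_class[i])
    res <- if (!anyNA(gc) && length(unique(gc)) == 2L)
      phase_by_transmission(gc, gm, gf) else detect_out_of_phase(gc, gm, gf)
    status[i] <- res$status
    mat[i] <- res$maternal; pat[i] <- res$paternal; evid[i] <- res$evidence
    if (res$status == "phased" && !is.na(res$maternal) && res$maternal != res$paternal)
      phase[i] <- if (res$maternal == sites$alt[i]) "maternal" else "paternal"
  }
  sites$region_class <- region_class
  sites$status <- status
  sites$maternal_allele <- mat
  sites$paternal_allele <- pat
  sites$evidence <- evid
  sites$phase <- phase
  sites
}

#' Phase a deletion to a parental chromosome
#'
#' Majority vote over the informative out-of-phase sites inside a region:
#' each site whose missing allele implicates the paternal (maternal) copy
#' votes paternal (maternal). Ties and zero informative sites are
#' `"undetermined"`.
#'
#' @param phased_sites Output of [phase_trio_sites()].
#' @param region Optional `c(start, end)` (1-based) restricting the vote.
#' @return A list: `origin` (`"paternal"`, `"maternal"` or
#'   `"undetermined"`), `n_support`, `n_informative`, `support` (fraction).
#' @export
phase_deletion <- function(phased_sites, region = NULL) {
  x <- phased_sites[phased_sites$status == "out_of_phase", , drop = FALSE]
  if (!is.null(region)) x <- x[x$pos >= region[1L] & x$pos <= region[2L], , drop = FALSE]
  n_pat <- sum(x$evidence == "paternal_deletion", na.rm = TRUE)
  n_mat <- sum(x$evidence == "maternal_deletion", na.rm = TRUE)
  n <- n_pat + n_mat
  if (n == 0L || n_pat == n_mat)
    return(list(origin = "undetermined", n_support = 0L, n_informative = n,
                support = NA_real_))
  if (n_pat > n_mat)
    list(origin = "paternal", n_support = n_pat, n_informative = n, support = n_pat / n)
  else
    list(origin = "maternal", n_support = n_mat, n_informative = n, support = n_mat / n)
}
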