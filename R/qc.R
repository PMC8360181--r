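#' Per-marker genotype call rate
#'
#' Missingness is per-genotype: a genotype with either allele missing is
#' a missing call.
#'
#' @param geno vector of alternate-allele dosages (0/1/2) with `NA` for
#'   missing genotype calls.
#' @return Fraction of animals with a non-missing genotype.
#' @export
call_rate <- function(geno) {
  if (length(geno) == 0)
    hd_domain_error("call_rate: empty genotype column")
  mean(!is.na(geno))
}

#' Minor allele frequency of a genotype column
#'
#' @param geno vector of alternate-allele dosages (0/1/2) with `NA` missing.
#' @return `min(p, 1 - p)` over non-missing alleles.
#' @export
minor_allele_frequency <- function(geno) {
  g <- geno[!is.na(geno)]
  if (length(g) == 0)
    hd_domain_error("minor_allele_frequency: no non-missing genotypes")
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the genotype counts: conditional on the
#' observed allele counts, the probability of each compatible heterozygote
#' count is enumerated (multinomial weight times `2^het`), and the
#' two-sided p-value is the summed mass of all configurations no more
#' probable than the observed one (no mid-p correction). Equivalent to the
#' plink `--hwe` exact test.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return Two-sided exact p-value in \[0, 1\].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    hd_domain_error("hwe_exact_test: counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1)
    hd_domain_error("hwe_exact_test: total count must be at least 1")
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log conditional mass for each compatible het count (unnormalised)
  logp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma(n - (n_minor + hets) / 2 + 1) + hets * log(2)
  logp <- logp - logsumexp(logp)
  obs <- logp[match(n_het, hets)]
  if (is.na(obs))
    hd_domain_error("hwe_exact_test: inconsistent genotype counts")
  min(1, sum(exp(logp[logp <= obs + 1e-10])))
}

#' Apply marker quality control
#'
#' Filters markers on genotype call rate, minor allele frequency and the
#' exact Hardy-Weinberg test, with strict thresholds (a marker passes only
#' if strictly above each threshold). Per-marker statistics are returned
#' for all markers, filtered or not. QC is intended for the pre-phasing
#' genotype matrix (missing codes allowed); the downstream haplotype scan
#' requires the phased, complete matrix.
#'
#' @param g a [hap_genotypes()] object (phased or not).
#' @param min_call_rate,min_maf,min_hwe_p strict lower thresholds
#'   (defaults 0.90, 0.01, 1e-6).
#' @return A list with `genotypes` (the filtered `hap_genotypes`) and
#'   `stats` (a data.frame with `marker_id`, `call_rate`, `maf`, `hwe_p`,
#'   `pass` and `fail_reasons`).
#' @export
apply_qc <- function(g, min_call_rate = 0.90, min_maf = 0.01,
                     min_hwe_p = 1e-6) {
  geno <- g$hap_a + g$hap_b  # NA if either allele missing
  cr <- colMeans(!is.na(geno))
  stats <- data.frame(marker_id = g$map$marker_id, call_rate = cr,
                      maf = NA_real_, hwe_p = NA_real_,
                      stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_len(ncol(geno))) {
    col <- geno[, j][!is.na(geno[, j])]
    if (length(col) == 0) next
    stats$maf[j] <- minor_allele_frequency(col)
    stats$hwe_p[j] <- hwe_exact_test(sum(col == 0), sum(col == 1), sum(col == 2))
  }
  fail_cr <- !(stats$call_rate > min_call_rate)
  fail_maf <- is.na(stats$maf) | !(stats$maf > min_maf)
  fail_hwe <- is.na(stats$hwe_p) | !(stats$hwe_p > min_hwe_p)
  stats$pass <- !(fail_cr | fail_maf | fail_hwe)
  stats$fail_reasons <- vapply(seq_len(nrow(stats)), function(j)
    paste(c("CALL_RATE", "MAF", "HWE")[c(fail_cr[j], fail_maf[j], fail_hwe[j])],
          collapse = ","), character(1))
  keep <- which(stats$pass)
  filtered <- hap_genotypes(g$animal_ids,
                            validate_marker_map(as.data.frame(g$map)[keep, , drop = FALSE]),
                            g$hap_a[, keep, drop = FALSE],
                            g$hap_b[, keep, drop = FALSE],
                            phased = g$phased)
  list(genotypes = filtered, stats = stats)
}
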