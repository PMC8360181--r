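#' Haplotype pseudo-marker dosages for the sequenced panel
#'
#' Treats the candidate haplotype as a pseudo-marker: each sequenced
#' sample's dosage is its haplotype copy number (from scan truth or chip
#' haplotyping).
#'
#' @param sample_ids character vector of sequenced sample ids.
#' @param carriers named vector of haplotype copies (0/1/2) as returned by
#'   [carrier_status()].
#' @return Named integer vector of copies for `sample_ids`.
#' @export
haplotype_dosage <- function(sample_ids, carriers) {
  if (length(sample_ids) == 0)
    hd_domain_error("haplotype_dosage: empty sample panel")
  missing <- setdiff(sample_ids, names(carriers))
  if (length(missing) > 0)
    hd_domain_error(sprintf("haplotype_dosage: no carrier status for: %s",
                            paste(missing, collapse = ", ")))
  setNames(as.integer(carriers[sample_ids]), sample_ids)
}

#' Squared dosage correlation (LD r-squared)
#'
#' Squared Pearson correlation between two dosage vectors over their
#' paired non-missing samples — the standard genotype-LD surrogate when
#' phase between a chip haplotype and a sequence variant is unknown.
#'
#' @param variant_dosage,hap_dosage numeric dosage vectors (NA allowed).
#' @return r-squared in \[0, 1\], or `NA` when either vector has zero
#'   variance (undefined LD; such variants are excluded from shortlists,
#'   not treated as errors).
#' @export
dosage_r2 <- function(variant_dosage, hap_dosage) {
  ok <- !is.na(variant_dosage) & !is.na(hap_dosage)
  if (sum(ok) < 3)
    hd_domain_error("dosage_r2: fewer than 3 paired non-missing samples")
  v <- variant_dosage[ok]; h <- hap_dosage[ok]
  if (stats::var(v) == 0 || stats::var(h) == 0) return(NA_real_)
  unname(cor(v, h)^2)
}

#' Carrier/non-carrier concordance filter
#'
#' A variant is concordant with the haplotype when every carrier sample
#' holds at least one alternate allele and every non-carrier none.
#'
#' @param variant_dosage named dosage vector over the sequenced panel.
#' @param hap_dosage named haplotype copy vector over the same samples.
#' @return `TRUE`/`FALSE` (`NA` dosages fail concordance).
#' @export
concordance_filter <- function(variant_dosage, hap_dosage) {
  carrier <- hap_dosage >= 1
  d <- variant_dosage
  if (anyNA(d)) return(FALSE)
  all(d[carrier] >= 1) && all(d[!carrier] == 0)
}

#' Shortlist candidate causal variants by LD with the haplotype
#'
#' Applies the sequencing quality filter, computes r-squared between each
#' variant's dosages and the haplotype pseudo-marker, and returns variants
#' at or above the LD threshold sorted by decreasing r-squared (ties:
#' concordant first, then position). Variants with undefined r-squared
#' (zero dosage variance) are dropped. Concordance is reported as a
#' column, not used as a filter.
#'
#' @param panel a [seq_panel()].
#' @param hap_dosage named haplotype copy vector (see
#'   [haplotype_dosage()]); names must cover the panel samples.
#' @param r2_threshold minimum r-squared (default 0.8).
#' @param qual_threshold minimum PHRED site quality (default 20; variants
#'   below are discarded).
#' @return data.frame with variant columns plus `r2`, `n_samples_used`
#'   and `concordant`.
#' @export
shortlist_variants <- function(panel, hap_dosage, r2_threshold = 0.8,
                               qual_threshold = 20) {
  hd <- haplotype_dosage(panel$sample_ids, hap_dosage)
  va <- panel$variants
  keep <- !is.na(va$qual) & va$qual >= qual_threshold
  res <- va[keep, , drop = FALSE]
  idx <- which(keep)
  r2 <- numeric(length(idx)); nuse <- integer(length(idx))
  conc <- logical(length(idx))
  for (i in seq_along(idx)) {
    d <- panel$dosages[idx[i], ]
    r2[i] <- dosage_r2(d, hd)
    nuse[i] <- sum(!is.na(d) & !is.na(hd))
    conc[i] <- concordance_filter(d, hd)
  }
  res$r2 <- r2; res$n_samples_used <- nuse; res$concordant <- conc
  res <- res[!is.na(res$r2) & res$r2 >= r2_threshold, , drop = FALSE]
  res <- res[order(-res$r2, !res$concordant, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- coordinate mapping between genome and coding sequence ---------------

#' Map a coding (c.) position to its genomic coordinate
#' @param cds_pos 1-based coding-sequence position.
#' @param model a [gene_model()].
#' @return Genomic bp position.
#' @export
cds_to_genomic <- function(cds_pos, model) {
  len <- model$cds$end - model$cds$start + 1L
  if (cds_pos < 1 || cds_pos > sum(len))
    hd_domain_error("cds_to_genomic: position outside the coding sequence")
  before <- c(0L, cumsum(len))
  seg <- findInterval(cds_pos - 1, before, rightmost.closed = FALSE)
  off <- cds_pos - before[seg]
  if (model$strand == "+") model$cds$start[seg] + off - 1L
  else model$cds$end[seg] - off + 1L
}

#' Map a genomic coordinate to its coding (c.) position
#' @param pos genomic bp position.
#' @param model a [gene_model()].
#' @return 1-based coding position, or `NA` if `pos` is not in the CDS.
#' @export
genomic_to_cds <- function(pos, model) {
  len <- model$cds$end - model$cds$start + 1L
  before <- c(0L, cumsum(len))
  for (seg in seq_len(nrow(model$cds))) {
    s <- model$cds$start[seg]; e <- model$cds$end[seg]
    if (pos >= s && pos <= e) {
      off <- if (model$strand == "+") pos - s + 1L else e - pos + 1L
      return(before[seg] + off)
    }
  }
  NA_integer_
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

#' Annotate the coding consequence of a biallelic SNV
#'
#' Maps the variant's genomic position into the gene model strand-aware
#' (alleles are reverse-complemented on the minus strand), extracts the
#' affected codon from the supplied coding sequence, translates reference
#' and alternate codons with the standard genetic code, and classifies the
#' effect (synonymous, missense, stop_gained, stop_lost, start_lost).
#' HGVS coding and protein strings are emitted; for stop gains the number
#' of truncated residues is `protein_length - (codon_index - 1)`.
#'
#' A mismatch between the VCF reference allele and the coding sequence at
#' the mapped position is a hard reference-mismatch error: silent
#' coordinate bugs are the main failure mode of annotators.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (single bases).
#' @param model a [gene_model()].
#' @param cds_seq coding-strand CDS sequence of the model (character).
#' @return list with `gene_id`, `region` ("CDS", "INTRON", "UTR",
#'   "INTERGENIC"), `effect`, `cds_pos`, `codon_index`, `ref_codon`,
#'   `alt_codon`, `hgvs_c`, `hgvs_p`, `truncated_residues`.
#' @export
annotate_consequence <- function(variant, model, cds_seq) {
  ref <- as.character(variant$ref); alt <- as.character(variant$alt)
  if (nchar(ref) != 1 || nchar(alt) != 1 ||
      !ref %in% DNA_BASES || !alt %in% DNA_BASES)
    hd_domain_error("annotate_consequence: only biallelic SNVs are annotatable")
  pos <- as.integer(variant$pos)
  none <- list(gene_id = model$gene_id, region = "INTERGENIC", effect = "NONE",
               cds_pos = NA_integer_, codon_index = NA_integer_,
               ref_codon = NA_character_, alt_codon = NA_character_,
               hgvs_c = NA_character_, hgvs_p = NA_character_,
               truncated_residues = NA_integer_)
  if (!identical(as.character(variant$chrom), model$chrom) ||
      pos < model$gene_start || pos > model$gene_end)
    return(none)
  cpos <- genomic_to_cds(pos, model)
  if (is.na(cpos)) {
    cds_lo <- min(model$cds$start); cds_hi <- max(model$cds$end)
    none$region <- if (pos >= cds_lo && pos <= cds_hi) "INTRON" else "UTR"
    return(none)
  }
  cds_seq <- unname(as.character(cds_seq))
  if (nchar(cds_seq) != model$cds_length)
    hd_model_error("annotate_consequence: CDS sequence length does not match model")
  ref_c <- if (model$strand == "+") ref else complement_base(ref)
  alt_c <- if (model$strand == "+") alt else complement_base(alt)
  if (substr(cds_seq, cpos, cpos) != ref_c)
    hd_refmismatch_error(sprintf(
      "reference allele %s (coding strand %s) does not match CDS base %s at c.%d",
      ref, ref_c, substr(cds_seq, cpos, cpos), cpos))
  codon_index <- ceiling(cpos / 3)
  cstart <- 3L * (codon_index - 1L) + 1L
  ref_codon <- substr(cds_seq, cstart, cstart + 2L)
  within <- cpos - cstart + 1L
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_c
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
  effect <-
    if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else if (codon_index == 1 && ref_aa == "M") "start_lost"
    else "missense"
  hgvs_c <- sprintf("c.%d%s>%s", cpos, ref_c, alt_c)
  hgvs_p <- switch(effect,
    synonymous = sprintf("p.%s%d=", AA3[ref_aa], codon_index),
    stop_gained = sprintf("p.%s%d*", AA3[ref_aa], codon_index),
    stop_lost = sprintf("p.Ter%d%sext*?", codon_index, AA3[alt_aa]),
    start_lost = "p.Met1?",
    missense = sprintf("p.%s%d%s", AA3[ref_aa], codon_index, AA3[alt_aa]))
  list(gene_id = model$gene_id, region = "CDS", effect = effect,
       cds_pos = cpos, codon_index = codon_index,
       ref_codon = ref_codon, alt_codon = alt_codon,
       hgvs_c = hgvs_c, hgvs_p = unname(hgvs_p),
       truncated_residues = if (effect == "stop_gained")
         model$protein_length - (codon_index - 1L) else NA_integer_)
}
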