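# Fixture builders and independent oracles shared across the suite.

# Minimal phased matrix from explicit allele-pair strings:
# genotypes is a list animal_id -> character vector of "a|b" per marker.
toy_genotypes <- function(genotypes, chrom = "1", pos = NULL) {
  n_mark <- length(genotypes[[1]])
  if (is.null(pos)) pos <- seq_len(n_mark) * 1000L
  map <- marker_map(sprintf("m%d", seq_len(n_mark)), chrom, pos,
                    rep("A", n_mark), rep("C", n_mark))
  hap_a <- t(vapply(genotypes, function(g) as.integer(substr(g, 1, 1)),
                    integer(n_mark)))
  hap_b <- t(vapply(genotypes, function(g) as.integer(substr(g, 3, 3)),
                    integer(n_mark)))
  if (n_mark == 1) { hap_a <- t(hap_a); hap_b <- t(hap_b) }
  hap_genotypes(names(genotypes), map, hap_a, hap_b, phased = TRUE)
}

# Write a small VCF from raw GT strings (markers x samples matrix).
write_toy_vcf <- function(path, samples, records) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts, qual = ".") {
  paste(c(chrom, pos, id, ref, alt, qual, "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Exhaustive-enumeration HWE oracle: enumerates every genotype
# configuration compatible with the observed allele counts, weighting by
# multinomial coefficient x 2^het, using plain choose() arithmetic.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_ref <- 2 * n_hom_ref + n_het
  configs <- list(); mass <- numeric(0)
  for (het in 0:n) {
    hr2 <- n_ref - het
    if (hr2 < 0 || hr2 %% 2 != 0) next
    hr <- hr2 / 2
    ha <- n - hr - het
    if (ha < 0) next
    w <- choose(n, hr) * choose(n - hr, het) * 2^het
    configs[[length(configs) + 1]] <- c(hr, het, ha)
    mass <- c(mass, w)
  }
  prob <- mass / sum(mass)
  obs <- which(vapply(configs, function(cf) cf[2] == n_het, logical(1)))
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

# Two-sided Fisher oracle by direct hypergeometric enumeration
# (summed-mass rule) on a 2x2 table rbind(c(a, b), c(c, d)).
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  mass <- choose(c1, a_vals) * choose(n - c1, r1 - a_vals) / choose(n, r1)
  obs <- mass[a_vals == tab[1, 1]]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

# Full-CDS translation oracle for consequence classification: mutate the
# CDS, translate both with Biostrings, and diff the proteins.
translate_oracle <- function(cds_seq, cds_pos, alt_coding_base) {
  mut <- cds_seq
  substr(mut, cds_pos, cds_pos) <- alt_coding_base
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p_ref <- tr(cds_seq); p_mut <- tr(mut)
  if (p_ref == p_mut) return("synonymous")
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_mut, "")[[1]])[1]
  ref_aa <- substr(p_ref, i, i); mut_aa <- substr(p_mut, i, i)
  if (mut_aa == "*") "stop_gained"
  else if (ref_aa == "*") "stop_lost"
  else if (i == 1 && ref_aa == "M") "start_lost"
  else "missense"
}

# Random single-transcript toy gene on either strand, with its coding
# sequence and a genome lookup table for SNV construction.
random_toy_gene <- function(protein_length = 40, strand = "+",
                            chrom = "7", origin = 10000L) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  codons <- sample(sense, protein_length, replace = TRUE)
  codons[1] <- "ATG"
  cds <- paste(c(codons, "TAA"), collapse = "")
  L <- nchar(cds)
  n_ex <- sample(2:4, 1)
  cuts <- sort(sample(seq_len(L - 1), n_ex - 1))
  lens <- diff(c(0, cuts, L))
  introns <- sample(50:200, n_ex - 1, replace = TRUE)
  starts <- origin + cumsum(c(0, head(lens, -1) + introns))
  cds_genomic <- data.frame(start = as.integer(starts),
                            end = as.integer(starts + lens - 1))
  tr_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  model <- gene_model("toy1", chrom, strand, cds_genomic[tr_order, ],
                      gene_start = min(cds_genomic$start) - 100L,
                      gene_end = max(cds_genomic$end) + 100L)
  list(model = model, cds_seq = cds)
}

# Small default simulation reused by several test files (cached).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 421, n_founders = 200, n_generations = 2,
                        n_genotyped_target = 1200, chrom_length = 10e6,
                        lethal_region = c(4e6, 5e6), cxc_enrichment = 0.3,
                        n_background_variants = 60, n_decoy_variants = 2)
      cache <<- simulate_population(cfg)
    }
    cache
  }
})
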