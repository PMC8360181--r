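#' Simulation configuration for the synthetic breeding population
#'
#' Collects every parameter of the gene-drop simulator. Defaults emulate
#' the mapping population the pipeline targets: a closed pig line with a
#' single recessive lethal haplotype segregating at 4% on one chromosome,
#' litters of about 10.3 total born with 9% stillbirth, 90% baseline
#' pre-weaning survival, fully penetrant pre-weaning lethality of
#' homozygotes concentrated in the first five days and labelled "nervous
#' disease" for 24/38 of recorded deaths, and a sequenced subset of 4
#' carrier plus 21 non-carrier animals.
#'
#' @param seed integer RNG seed (applied once by [simulate_population()]).
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param marker_density markers per Mb (default 40/Mb, so the smallest scan window holds about 20 markers; with
#'   independent founder alleles, sparser
#'   maps create spuriously common short window haplotypes that real chip
#'   LD structure does not produce).
#' @param maf_range founder allele frequencies are drawn uniformly on this
#'   interval.
#' @param lethal_region bp interval (start, end), half-open, carrying the
#'   implanted lethal haplotype.
#' @param lethal_hap_freq target founder frequency of the lethal haplotype.
#' @param n_founders number of founder animals (`NULL` = 60% of
#'   `n_genotyped_target`; a founder majority keeps the realized lethal
#'   frequency close to its target, since founder chromosomes carry it at
#'   the exact configured rate while bred generations drift).
#' @param prop_male_founders fraction of founders that are boars.
#' @param n_generations number of bred generations after the founders.
#' @param n_genotyped_target minimum size of the mature genotyped set
#'   (founders plus surviving offspring); sizes the litter count when
#'   `n_litters_per_gen` is `NULL`.
#' @param n_litters_per_gen litters farrowed per generation (`NULL` =
#'   derived from `n_genotyped_target` with a 8% safety margin).
#' @param litter_size_mean mean total born per litter (Poisson, truncated
#'   to `litter_size_range`).
#' @param litter_size_range inclusive truncation bounds for litter size.
#' @param stillborn_rate per-piglet stillbirth probability.
#' @param baseline_weaning_mortality pre-weaning death probability of
#'   non-homozygous liveborn piglets.
#' @param homozygote_lethality_penetrance probability that a liveborn
#'   lethal homozygote dies before weaning.
#' @param early_death_mass probability mass of homozygote deaths on days
#'   1-5 (remainder uniform on day 6 to `lactation_days`).
#' @param lactation_days length of the lactation period in days; deaths
#'   are recorded over this horizon and `weaned` counts its survivors.
#' @param weaning_day nominal weaning day used for day-of-death binning.
#' @param nervous_cause_prob probability a homozygote death is labelled
#'   "nervous disease" (otherwise cause unknown).
#' @param recomb_rate recombination rate in cM/Mb.
#' @param cxc_enrichment probability a litter is forced to have two
#'   carrier parents (0 = random mating); lets small simulations produce
#'   enough carrier-by-carrier litters for validation tests.
#' @param n_sequenced,n_sequenced_carriers size and carrier composition of
#'   the sequenced subset.
#' @param n_background_variants background sequence variants emitted in
#'   the +/- 2 Mb neighbourhood of the lethal region.
#' @param n_decoy_variants variants in high but imperfect LD with the
#'   haplotype.
#' @param gene_strand strand of the emitted gene model.
#' @param protein_length length (aa) of the encoded protein.
#' @param causal_cds_pos coding position of the causal C>T variant; must
#'   be the first base of a codon that is set to CAG (Gln) so the change
#'   creates a TAG stop.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "9",
                       chrom_length = 20e6,
                       marker_density = 40,
                       maf_range = c(0.05, 0.95),
                       lethal_region = c(11e6, 12e6),
                       lethal_hap_freq = 0.04,
                       n_founders = NULL,
                       prop_male_founders = 0.4,
                       n_generations = 2,
                       n_genotyped_target = 14160,
                       n_litters_per_gen = NULL,
                       litter_size_mean = 10.3,
                       litter_size_range = c(4L, 18L),
                       stillborn_rate = 0.09,
                       baseline_weaning_mortality = 0.10,
                       homozygote_lethality_penetrance = 1.0,
                       early_death_mass = 0.8,
                       lactation_days = 23L,
                       weaning_day = 21L,
                       nervous_cause_prob = 24 / 38,
                       recomb_rate = 1.0,
                       cxc_enrichment = 0,
                       n_sequenced = 25L,
                       n_sequenced_carriers = 4L,
                       n_background_variants = 300L,
                       n_decoy_variants = 3L,
                       gene_strand = "+",
                       protein_length = 2212L,
                       causal_cds_pos = 541L) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_founders))
    cfg$n_founders <- max(200L, round(0.6 * n_genotyped_target))
  n_founders <- cfg$n_founders
  probs <- c(lethal_hap_freq, stillborn_rate, baseline_weaning_mortality,
             homozygote_lethality_penetrance, early_death_mass,
             nervous_cause_prob, cxc_enrichment, prop_male_founders)
  if (any(probs < 0 | probs > 1))
    hd_config_error("all probabilities must lie in [0, 1]")
  if (lethal_region[1] < 1 || lethal_region[2] > chrom_length ||
      lethal_region[1] >= lethal_region[2])
    hd_config_error("lethal_region must be an increasing interval within [1, chrom_length]")
  if (n_sequenced_carriers > n_sequenced)
    hd_config_error("n_sequenced_carriers may not exceed n_sequenced")
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
    hd_config_error("maf_range must be an interval within (0, 1)")
  if (!gene_strand %in% c("+", "-"))
    hd_config_error("gene_strand must be '+' or '-'")
  if (causal_cds_pos %% 3 != 1)
    hd_config_error("causal_cds_pos must be the first base of its codon")
  if (ceiling(causal_cds_pos / 3) > protein_length)
    hd_config_error("causal codon lies beyond the protein")
  if (is.null(cfg$n_litters_per_gen)) {
    per_litter <- litter_size_mean * (1 - stillborn_rate) *
      (1 - baseline_weaning_mortality)
    cfg$n_litters_per_gen <- ceiling(
      1.08 * max(0, n_genotyped_target - n_founders) /
        (n_generations * per_litter))
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d: %d founders, %d generations x %d ",
                     "litters, lethal haplotype %.0f-%.0f kb @ %.1f%%\n"),
              x$seed, x$n_founders, x$n_generations, x$n_litters_per_gen,
              x$lethal_region[1] / 1e3, x$lethal_region[2] / 1e3,
              100 * x$lethal_hap_freq))
  invisible(x)
}

#' Simulate the founder haplotype pool
#'
#' Draws a sorted marker map (positions uniform, allele frequencies
#' uniform on `maf_range`), then `2 * n_founders` founder chromosomes.
#' A fraction `lethal_hap_freq` of the chromosomes (deterministic rounded
#' count) is labelled lethal and shares one fixed allele string across the
#' markers of the lethal region; any non-lethal chromosome colliding with
#' that exact string has one in-region allele flipped. Uses the current
#' RNG stream ([simulate_population()] seeds it from the config).
#'
#' @param config a [sim_config()].
#' @return list with `map` (marker_map), `haps` (chromosomes x markers 0/1
#'   matrix), `lethal` (logical per chromosome), `region_idx` (marker
#'   indices of the lethal region) and `lethal_string`.
#' @export
simulate_founder_haplotypes <- function(config) {
  n_markers <- round(config$marker_density * config$chrom_length / 1e6)
  pos <- sort(unique(round(runif(n_markers, 1, config$chrom_length))))
  region_idx <- which(pos >= config$lethal_region[1] & pos < config$lethal_region[2])
  if (length(region_idx) < 2)
    hd_config_error("lethal_region contains fewer than 2 markers")
  freqs <- runif(length(pos), config$maf_range[1], config$maf_range[2])
  ref <- sample(DNA_BASES, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1))
  map <- marker_map(sprintf("snp_%s_%d", config$chrom, pos), config$chrom,
                    pos, ref, alt)
  H <- 2L * config$n_founders
  haps <- matrix(rbinom(H * length(pos), 1L, rep(freqs, each = H)), nrow = H)
  n_lethal <- round(H * config$lethal_hap_freq)
  lethal <- rep(FALSE, H)
  lethal_alleles <- rbinom(length(region_idx), 1L, freqs[region_idx])
  lethal_string <- paste(lethal_alleles, collapse = "")
  if (n_lethal > 0) {
    lethal[sample.int(H, n_lethal)] <- TRUE
    haps[lethal, region_idx] <- rep(lethal_alleles, each = n_lethal)
  }
  # keep the lethal string unique to labelled chromosomes
  bg <- which(!lethal)
  bg_str <- do.call(paste0, as.data.frame(haps[bg, region_idx, drop = FALSE]))
  collide <- bg[bg_str == lethal_string]
  for (i in collide) {
    j <- region_idx[sample.int(length(region_idx), 1)]
    haps[i, j] <- 1L - haps[i, j]
  }
  list(map = map, haps = haps, freqs = freqs, lethal = lethal,
       region_idx = region_idx, lethal_string = lethal_string)
}

# crossover source mask for one meiosis; returns parental strand (1/2) at
# each marker and at the optional extra position
meiosis_mask <- function(positions, chrom_length, recomb_rate, extra_pos = NULL) {
  morgans <- recomb_rate / 100 * chrom_length / 1e6
  n_cx <- rpois(1L, morgans)
  s0 <- sample.int(2L, 1L)
  if (n_cx == 0L)
    return(list(src = rep.int(s0, length(positions)),
                src_extra = if (is.null(extra_pos)) NULL else s0))
  cx <- sort(runif(n_cx, 0, chrom_length))
  src <- 1L + (s0 - 1L + findInterval(positions, cx)) %% 2L
  src_extra <- if (is.null(extra_pos)) NULL else
    1L + (s0 - 1L + findInterval(extra_pos, cx)) %% 2L
  list(src = src, src_extra = src_extra)
}

#' Simulate one meiosis (gene-drop gamete formation)
#'
#' Crossovers follow a Poisson process (no interference) at `recomb_rate`
#' cM/Mb over the chromosome; a fair coin picks the starting parental
#' strand and the gamete is the resulting mosaic of the two parental
#' haplotypes. Uses the current RNG stream.
#'
#' @param parent_haplotypes list of two equal-length 0/1 allele vectors
#'   (or a 2-row matrix).
#' @param positions marker positions in bp.
#' @param recomb_rate recombination rate in cM/Mb.
#' @param chrom_length chromosome length in bp (default: last marker).
#' @return Gamete allele vector.
#' @export
meiosis <- function(parent_haplotypes, positions, recomb_rate,
                    chrom_length = max(positions)) {
  if (is.matrix(parent_haplotypes))
    parent_haplotypes <- list(parent_haplotypes[1, ], parent_haplotypes[2, ])
  h1 <- parent_haplotypes[[1]]; h2 <- parent_haplotypes[[2]]
  if (length(h1) != length(positions) || length(h2) != length(positions))
    hd_domain_error("meiosis: haplotype length does not match marker positions")
  m <- meiosis_mask(positions, chrom_length, recomb_rate)
  out <- h2
  out[m$src == 1L] <- h1[m$src == 1L]
  out
}

# synthetic gene model inside the lethal region, plus its coding sequence
# and the genomic position of the causal stop-gain site
build_sim_gene <- function(config) {
  L <- 3L * (config$protein_length + 1L)
  n_ex <- max(2L, min(12L, ceiling(L / 700)))
  base <- L %/% n_ex
  lens <- rep(base, n_ex); lens[n_ex] <- lens[n_ex] + L %% n_ex
  introns <- round(runif(n_ex - 1, 1500, 3500))
  span <- sum(lens) + sum(introns)
  g_start <- round(config$lethal_region[1] +
                     0.25 * (config$lethal_region[2] - config$lethal_region[1]))
  if (g_start + span >= config$lethal_region[2])
    hd_config_error("gene does not fit inside the lethal region")
  starts <- g_start + cumsum(c(0, head(lens, -1) + introns))
  cds_genomic <- data.frame(start = as.integer(starts),
                            end = as.integer(starts + lens - 1L))
  tr_order <- if (config$gene_strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  model <- gene_model("SIMGENE1", config$chrom, config$gene_strand,
                      cds_genomic[tr_order, , drop = FALSE],
                      gene_start = min(cds_genomic$start) - 500L,
                      gene_end = max(cds_genomic$end) + 500L)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  codons <- sample(sense, config$protein_length, replace = TRUE)
  codons[1] <- "ATG"
  codons[ceiling(config$causal_cds_pos / 3)] <- "CAG"
  cds_seq <- paste(c(codons, "TAA"), collapse = "")
  causal_pos <- cds_to_genomic(config$causal_cds_pos, model)
  list(model = model, cds_seq = setNames(cds_seq, model$gene_id),
       causal_pos = causal_pos)
}

#' Simulate a complete synthetic breeding population
#'
#' Seeds the RNG from `config$seed`, builds the founder pool (avoiding
#' lethal-homozygous founders, which would not have survived to breed),
#' then drops genes through `n_generations` of litters: litter sizes are
#' truncated Poisson, stillbirths binomial, each conceptus receives one
#' recombinant gamete per parent, liveborn lethal homozygotes die before
#' weaning with the configured penetrance (day and cause from the
#' configured distributions) and all other liveborn die at the baseline
#' rate. Mature animals (survivors) of each generation breed the next.
#' The genotyped set is the founders plus all mature offspring.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_output` with elements `genotypes`
#'   (phased [hap_genotypes()] of the genotyped set), `pedigree`,
#'   `litters` (a [litter_set()]), `seq_panel`, `gene_model`, `cds_seq`
#'   and `truth` (implanted interval and string, causal variant position,
#'   per-animal carrier copies, per-conceptus records, sequenced subset).
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  pool <- simulate_founder_haplotypes(config)
  gene <- build_sim_gene(config)
  M <- nrow(pool$map)
  pos <- pool$map$pos
  causal_pos <- gene$causal_pos

  # founders: pair chromosomes, never two lethal copies in one animal
  H <- nrow(pool$haps)
  idx <- sample.int(H)
  a <- idx[seq(1, H, 2)]; b <- idx[seq(2, H, 2)]
  bad <- which(pool$lethal[a] & pool$lethal[b])
  free <- which(!pool$lethal[a] & !pool$lethal[b])
  if (length(bad) > length(free))
    hd_sim_error("cannot pair founder chromosomes without lethal homozygotes")
  for (k in seq_along(bad)) {
    i <- bad[k]; j <- free[k]
    tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
  }
  nf <- config$n_founders
  founder_ids <- sprintf("F%04d", seq_len(nf))
  n_male <- round(nf * config$prop_male_founders)
  sex <- sample(rep(c("M", "F"), c(n_male, nf - n_male)))

  hap_a <- pool$haps[a, , drop = FALSE]
  hap_b <- pool$haps[b, , drop = FALSE]
  leth_a <- pool$lethal[a]; leth_b <- pool$lethal[b]
  ids <- founder_ids
  sexes <- sex
  sire_of <- rep(NA_character_, nf); dam_of <- rep(NA_character_, nf)
  gen_of <- rep(0L, nf)

  cur <- seq_len(nf)  # indices of the current breeding generation
  litters <- list(); piglet_gen <- list()

  lethal_death_day <- function() {
    if (runif(1) < config$early_death_mass) sample.int(5L, 1L)
    else sample(6:config$lactation_days, 1L)
  }

  for (g in seq_len(config$n_generations)) {
    males <- cur[sexes[cur] == "M"]; females <- cur[sexes[cur] == "F"]
    if (length(males) == 0 || length(females) == 0)
      hd_sim_error("a generation ran out of sires or dams")
    carrier <- leth_a[cur] | leth_b[cur]
    cmales <- cur[sexes[cur] == "M" & carrier]
    cfemales <- cur[sexes[cur] == "F" & carrier]
    nl <- config$n_litters_per_gen
    sizes <- pmin(pmax(rpois(nl, config$litter_size_mean),
                       config$litter_size_range[1]), config$litter_size_range[2])
    n_max <- sum(sizes)
    new_hap_a <- matrix(0L, n_max, M); new_hap_b <- matrix(0L, n_max, M)
    new_leth_a <- logical(n_max); new_leth_b <- logical(n_max)
    keep_new <- logical(n_max); np <- 0L
    pg_id <- character(n_max); pg_lit <- character(n_max)
    pg_sire <- character(n_max); pg_dam <- character(n_max)
    pg_copies <- integer(n_max); pg_live <- logical(n_max)
    pg_day <- rep(NA_integer_, n_max); pg_cause <- rep(NA_character_, n_max)
    pg_mature <- logical(n_max); pc <- 0L
    lit_sire <- character(nl); lit_dam <- character(nl)
    lit_alive <- integer(nl); lit_weaned <- integer(nl)
    for (l in seq_len(nl)) {
      force_cxc <- runif(1) < config$cxc_enrichment &&
        length(cmales) > 0 && length(cfemales) > 0
      si <- if (force_cxc) cmales[sample.int(length(cmales), 1)] else
        males[sample.int(length(males), 1)]
      di <- if (force_cxc) cfemales[sample.int(length(cfemales), 1)] else
        females[sample.int(length(females), 1)]
      litter_id <- sprintf("L%d_%04d", g, l)
      total_born <- sizes[l]
      still <- runif(total_born) < config$stillborn_rate
      n_weaned <- 0L
      for (p in seq_len(total_born)) {
        ms <- meiosis_mask(pos, config$chrom_length, config$recomb_rate,
                           extra_pos = causal_pos)
        gam_s <- hap_b[si, ]; pick <- ms$src == 1L
        gam_s[pick] <- hap_a[si, pick]
        gls <- if (ms$src_extra == 1L) leth_a[si] else leth_b[si]
        md <- meiosis_mask(pos, config$chrom_length, config$recomb_rate,
                           extra_pos = causal_pos)
        gam_d <- hap_b[di, ]; pick <- md$src == 1L
        gam_d[pick] <- hap_a[di, pick]
        gld <- if (md$src_extra == 1L) leth_a[di] else leth_b[di]
        pid <- sprintf("P%d_%04d_%02d", g, l, p)
        hom <- gls && gld
        liveborn <- !still[p]
        death_day <- NA_integer_; cause <- NA_character_
        if (liveborn) {
          if (hom && runif(1) < config$homozygote_lethality_penetrance) {
            death_day <- lethal_death_day()
            if (runif(1) < config$nervous_cause_prob) cause <- "nervous disease"
          } else if (runif(1) < config$baseline_weaning_mortality) {
            death_day <- sample.int(config$weaning_day, 1L)
          }
        }
        mature <- liveborn && is.na(death_day)
        pc <- pc + 1L
        pg_id[pc] <- pid; pg_lit[pc] <- litter_id
        pg_sire[pc] <- ids[si]; pg_dam[pc] <- ids[di]
        pg_copies[pc] <- as.integer(gls) + as.integer(gld)
        pg_live[pc] <- liveborn; pg_day[pc] <- death_day
        pg_cause[pc] <- cause; pg_mature[pc] <- mature
        if (liveborn) {
          np <- np + 1L
          new_hap_a[np, ] <- gam_s; new_hap_b[np, ] <- gam_d
          new_leth_a[np] <- gls; new_leth_b[np] <- gld
          keep_new[np] <- mature
        }
        if (mature) n_weaned <- n_weaned + 1L
      }
      lit_sire[l] <- ids[si]; lit_dam[l] <- ids[di]
      lit_alive[l] <- sum(!still); lit_weaned[l] <- n_weaned
    }
    pg <- data.frame(piglet_id = pg_id[1:pc], litter_id = pg_lit[1:pc],
                     sire_id = pg_sire[1:pc], dam_id = pg_dam[1:pc],
                     lethal_copies = pg_copies[1:pc], liveborn = pg_live[1:pc],
                     death_day = pg_day[1:pc], cause = pg_cause[1:pc],
                     mature = pg_mature[1:pc], stringsAsFactors = FALSE)
    piglet_gen[[g]] <- pg
    litters[[g]] <- data.frame(
      litter_id = sprintf("L%d_%04d", g, seq_len(nl)),
      sire_id = lit_sire, dam_id = lit_dam, total_born = sizes,
      born_alive = lit_alive, weaned = lit_weaned, stringsAsFactors = FALSE)
    live_mature <- pg$mature[pg$liveborn]
    sel <- which(keep_new[seq_len(np)])
    base_n <- length(ids)
    ids <- c(ids, pg$piglet_id[pg$liveborn][live_mature])
    sexes <- c(sexes, sample(c("M", "F"), length(sel), replace = TRUE))
    sire_of <- c(sire_of, pg$sire_id[pg$liveborn][live_mature])
    dam_of <- c(dam_of, pg$dam_id[pg$liveborn][live_mature])
    gen_of <- c(gen_of, rep(g, length(sel)))
    hap_a <- rbind(hap_a, new_hap_a[sel, , drop = FALSE])
    hap_b <- rbind(hap_b, new_hap_b[sel, , drop = FALSE])
    leth_a <- c(leth_a, new_leth_a[sel]); leth_b <- c(leth_b, new_leth_b[sel])
    cur <- base_n + seq_along(sel)
  }

  if (length(ids) < config$n_genotyped_target)
    hd_sim_error(sprintf(
      "produced %d mature genotyped animals, below target %d",
      length(ids), config$n_genotyped_target))

  genotypes <- hap_genotypes(ids, pool$map, hap_a, hap_b, phased = TRUE)
  carrier_copies <- setNames(as.integer(leth_a) + as.integer(leth_b), ids)

  piglets <- do.call(rbind, piglet_gen)
  lit_df <- do.call(rbind, litters)
  dsel <- piglets$liveborn & !is.na(piglets$death_day)
  death_df <- if (any(dsel)) data.frame(
    litter_id = piglets$litter_id[dsel], piglet_id = piglets$piglet_id[dsel],
    death_day = piglets$death_day[dsel], cause = piglets$cause[dsel],
    stringsAsFactors = FALSE) else NULL
  lset <- litter_set(lit_df, death_df)

  ped <- validate_pedigree(data.frame(
    animal_id = c(ids, piglets$piglet_id[!piglets$mature & piglets$liveborn]),
    sire_id = c(sire_of, piglets$sire_id[!piglets$mature & piglets$liveborn]),
    dam_id = c(dam_of, piglets$dam_id[!piglets$mature & piglets$liveborn]),
    sex = c(sexes, rep(NA_character_, sum(!piglets$mature & piglets$liveborn))),
    genotyped = c(rep(TRUE, length(ids)),
                  rep(FALSE, sum(!piglets$mature & piglets$liveborn))),
    stringsAsFactors = FALSE))

  out <- structure(list(
    genotypes = genotypes, pedigree = ped, litters = lset,
    seq_panel = NULL, gene_model = gene$model, cds_seq = gene$cds_seq,
    truth = list(lethal_interval = config$lethal_region,
                 lethal_string = pool$lethal_string,
                 region_marker_idx = pool$region_idx,
                 founder_freqs = pool$freqs,
                 causal_pos = gene$causal_pos,
                 causal_cds_pos = config$causal_cds_pos,
                 carrier_copies = carrier_copies,
                 piglets = piglets,
                 sequenced = NULL),
    config = config), class = "sim_output")
  emit_sequenced_subset(out, config)
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(paste0("<sim_output> %d genotyped animals, %d litters, ",
                     "%d sequenced samples, lethal haplotype %s:%g-%g\n"),
              n_animals(x$genotypes), nrow(x$litters$litters),
              if (is.null(x$seq_panel)) 0 else length(x$seq_panel$sample_ids),
              x$config$chrom, x$truth$lethal_interval[1],
              x$truth$lethal_interval[2]))
  invisible(x)
}

#' Emit the sequenced sample subset and its variant panel
#'
#' Selects `n_sequenced_carriers` truth heterozygous carriers and fills
#' the panel with non-carriers, then generates background variants in the
#' +/- 2 Mb neighbourhood of the lethal region (dosages drawn from random
#' background haplotype frequencies), a configurable number of decoy
#' variants in high but imperfect LD with the haplotype, and one causal
#' stop-gained SNV inside the emitted gene model whose dosage equals each
#' animal's lethal-haplotype copy number (complete LD by construction).
#' About one background variant in ten is emitted with PHRED quality
#' below 20 to exercise the quality filter.
#'
#' @param sim a `sim_output` (its `seq_panel`/`truth$sequenced` are filled).
#' @param config the [sim_config()] used to generate `sim`.
#' @return The updated `sim_output`.
#' @export
emit_sequenced_subset <- function(sim, config) {
  copies <- sim$truth$carrier_copies
  carriers <- names(copies)[copies == 1L]
  noncar <- names(copies)[copies == 0L]
  if (length(carriers) < config$n_sequenced_carriers)
    hd_sim_error(sprintf("only %d carriers available, %d requested",
                         length(carriers), config$n_sequenced_carriers))
  n_non <- config$n_sequenced - config$n_sequenced_carriers
  if (length(noncar) < n_non)
    hd_sim_error("not enough non-carriers for the sequenced subset")
  samples <- c(sample(carriers, config$n_sequenced_carriers),
               sample(noncar, n_non))
  hap_dos <- copies[samples]
  ns <- length(samples)

  lo <- max(1, config$lethal_region[1] - 2e6)
  hi <- min(config$chrom_length, config$lethal_region[2] + 2e6)
  nb <- config$n_background_variants
  bg_pos <- sort(sample(setdiff(seq.int(lo, hi), sim$truth$causal_pos), nb))
  bg_freq <- runif(nb, 0.05, 0.95)
  bg_dos <- matrix(rbinom(nb * ns, 2L, rep(bg_freq, ns)), nrow = nb)
  bg_qual <- ifelse(runif(nb) < 0.1, runif(nb, 2, 19.9), runif(nb, 20, 999))

  nd <- config$n_decoy_variants
  decoy <- NULL
  if (nd > 0) {
    d_pos <- sort(sample(setdiff(seq.int(config$lethal_region[1],
                                         config$lethal_region[2]),
                                 c(bg_pos, sim$truth$causal_pos)), nd))
    d_dos <- matrix(rep(as.integer(hap_dos), each = nd), nrow = nd)
    for (i in seq_len(nd)) {
      j <- sample.int(ns, 1)
      d_dos[i, j] <- if (d_dos[i, j] == 0L) 1L else d_dos[i, j] - 1L
    }
    decoy <- list(pos = d_pos, dos = d_dos)
  }

  ref <- sample(DNA_BASES, nb, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1))
  causal_ref <- if (config$gene_strand == "+") "C" else "G"
  causal_alt <- if (config$gene_strand == "+") "T" else "A"

  va <- data.frame(chrom = config$chrom, pos = bg_pos, ref = ref, alt = alt,
                   qual = bg_qual, stringsAsFactors = FALSE)
  dos <- bg_dos
  if (!is.null(decoy)) {
    va <- rbind(va, data.frame(chrom = config$chrom, pos = decoy$pos,
                               ref = "G", alt = "A",
                               qual = runif(nd, 500, 999),
                               stringsAsFactors = FALSE))
    dos <- rbind(dos, decoy$dos)
  }
  va <- rbind(va, data.frame(chrom = config$chrom, pos = sim$truth$causal_pos,
                             ref = causal_ref, alt = causal_alt, qual = 999,
                             stringsAsFactors = FALSE))
  dos <- rbind(dos, matrix(as.integer(hap_dos), nrow = 1))
  o <- order(va$pos)
  va <- va[o, , drop = FALSE]; rownames(va) <- NULL
  dos <- dos[o, , drop = FALSE]
  colnames(dos) <- samples
  sim$seq_panel <- seq_panel(va, dos)
  sim$truth$sequenced <- data.frame(sample_id = samples,
                                    carrier_copies = as.integer(hap_dos),
                                    stringsAsFactors = FALSE)
  sim
}

#' Write all simulator outputs to a directory
#'
#' Emits `genotypes.vcf`, `pedigree.csv`, `litters.csv`, `deaths.csv`,
#' `seqpanel.vcf`, `genes.gff3`, `cds.fasta` and `truth.json` (requires
#' the jsonlite package for the truth file).
#'
#' @param sim a `sim_output`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phased_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_litters(sim$litters, file.path(dir, "litters.csv"),
                file.path(dir, "deaths.csv"))
  write_variant_vcf(sim$seq_panel, file.path(dir, "seqpanel.vcf"))
  write_gene_model(list(sim$gene_model), file.path(dir, "genes.gff3"))
  write_cds_fasta(sim$cds_seq, file.path(dir, "cds.fasta"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- sim$truth
    jsonlite::write_json(
      list(lethal_interval = tr$lethal_interval,
           lethal_string = tr$lethal_string,
           causal_pos = tr$causal_pos, causal_cds_pos = tr$causal_cds_pos,
           carrier_copies = as.list(tr$carrier_copies),
           sequenced = tr$sequenced),
      file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
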