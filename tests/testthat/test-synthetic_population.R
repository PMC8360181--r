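test_that("founder pool implants the lethal string at the exact rounded count", {
  set.seed(10)
  cfg <- sim_config(seed = 10, n_founders = 500, n_genotyped_target = 500,
                    n_litters_per_gen = 5)
  pool <- simulate_founder_haplotypes(cfg)
  expect_equal(sum(pool$lethal), round(1000 * cfg$lethal_hap_freq))
  strs <- apply(pool$haps[, pool$region_idx], 1, paste, collapse = "")
  expect_true(all(strs[pool$lethal] == pool$lethal_string))
  expect_true(all(strs[!pool$lethal] != pool$lethal_string))

  set.seed(10)
  cfg0 <- sim_config(seed = 10, n_founders = 500, n_genotyped_target = 500,
                     lethal_hap_freq = 0, n_litters_per_gen = 5)
  pool0 <- simulate_founder_haplotypes(cfg0)
  expect_equal(sum(pool0$lethal), 0)
})

test_that("configs with too few in-region markers are rejected", {
  set.seed(1)
  cfg <- sim_config(seed = 1, marker_density = 0.1, n_founders = 50,
                    n_genotyped_target = 50, n_litters_per_gen = 2)
  expect_error(simulate_founder_haplotypes(cfg), class = "hd_config_error")
})

test_that("meiosis honours the zero-crossover and identical-parent limits", {
  pos <- sort(sample(1e7, 200))
  h1 <- rbinom(200, 1, 0.5); h2 <- rbinom(200, 1, 0.5)
  g0 <- meiosis(list(h1, h2), pos, recomb_rate = 0, chrom_length = 1e7)
  expect_true(identical(g0, h1) || identical(g0, h2))
  g1 <- meiosis(list(h1, h1), pos, recomb_rate = 5, chrom_length = 1e7)
  expect_identical(g1, h1)
})

test_that("meiosis crossover counts match the Poisson genetic length", {
  # 10 Mb at 1 cM/Mb = 0.1 Morgan; dense distinguishable parents make
  # every crossover visible as a strand switch (double hits negligible)
  set.seed(55)
  pos <- seq(5e3, 1e7, length.out = 1001)
  h1 <- rep(0L, 1001); h2 <- rep(1L, 1001)
  switches <- replicate(10000, {
    g <- meiosis(list(h1, h2), pos, recomb_rate = 1, chrom_length = 1e7)
    sum(diff(g) != 0)
  })
  se <- sqrt(0.1 / 10000)
  expect_lt(abs(mean(switches) - 0.1), 3 * se)
})

test_that("simulation output is reproducible for a seed and sensitive to it", {
  cfg <- sim_config(seed = 33, n_founders = 150, n_generations = 1,
                    n_genotyped_target = 300, chrom_length = 5e6,
                    lethal_region = c(2e6, 3e6), n_background_variants = 40)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$genotypes$hap_a, s2$genotypes$hap_a)
  expect_identical(s1$litters$litters, s2$litters$litters)
  expect_identical(s1$seq_panel$dosages, s2$seq_panel$dosages)
  expect_identical(s1$truth$lethal_string, s2$truth$lethal_string)
  cfg2 <- sim_config(seed = 34, n_founders = 150, n_generations = 1,
                     n_genotyped_target = 300, chrom_length = 5e6,
                     lethal_region = c(2e6, 3e6), n_background_variants = 40)
  s3 <- simulate_population(cfg2)
  expect_false(identical(s1$genotypes$hap_a, s3$genotypes$hap_a))
})

test_that("full penetrance leaves no lethal homozygote in the mature set", {
  sim <- small_sim()
  expect_true(all(sim$truth$carrier_copies < 2))
  # and every genotyped animal has a truth label
  expect_setequal(names(sim$truth$carrier_copies), sim$genotypes$animal_ids)
})

test_that("carrier-by-carrier conceptuses are homozygous at the Mendelian rate", {
  sim <- small_sim()
  cls <- classify_matings(sim$litters, sim$truth$carrier_copies)
  cxc <- names(cls)[cls == "CxC"]
  expect_gt(length(cxc), 20)  # enrichment knob supplies enough litters
  pg <- sim$truth$piglets[sim$truth$piglets$litter_id %in% cxc, ]
  n <- nrow(pg); k <- sum(pg$lethal_copies == 2)
  ci <- qbinom(c(0.005, 0.995), n, 0.25)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
})

test_that("litter mortality accounting is conserved", {
  sim <- small_sim()
  lit <- sim$litters$litters
  nd <- table(factor(sim$litters$deaths$litter_id, levels = lit$litter_id))
  expect_equal(as.integer(nd), lit$born_alive - lit$weaned)
  expect_true(all(lit$complete))
  # every liveborn piglet appears in exactly one litter
  pg <- sim$truth$piglets[sim$truth$piglets$liveborn, ]
  expect_equal(anyDuplicated(pg$piglet_id), 0)
  expect_equal(as.integer(table(factor(pg$litter_id, levels = lit$litter_id))),
               lit$born_alive)
})

test_that("marker frequencies drift only modestly from founder frequencies", {
  sim <- small_sim()
  g <- sim$genotypes
  freq <- colMeans(g$hap_a + g$hap_b) / 2
  f0 <- sim$truth$founder_freqs
  off_region <- setdiff(seq_along(f0), sim$truth$region_marker_idx)
  # binomial founder sampling + two generations of drift at this scale
  se <- sqrt(f0 * (1 - f0) / (2 * n_animals(g))) +
    sqrt(f0 * (1 - f0) / (2 * sim$config$n_founders))
  expect_true(all(abs(freq[off_region] - f0[off_region]) <
                    4 * (2 * se[off_region] + 0.01)))
})

test_that("the sequenced subset is in complete LD with the causal variant", {
  sim <- small_sim()
  seqd <- sim$truth$sequenced
  expect_equal(sum(seqd$carrier_copies >= 1), sim$config$n_sequenced_carriers)
  expect_equal(nrow(seqd), sim$config$n_sequenced)
  hd <- setNames(seqd$carrier_copies, seqd$sample_id)
  causal_row <- which(sim$seq_panel$variants$pos == sim$truth$causal_pos)
  d <- sim$seq_panel$dosages[causal_row, ]
  expect_identical(as.integer(d[seqd$sample_id]), seqd$carrier_copies)
  expect_equal(dosage_r2(d, hd), 1.0)
  expect_true(concordance_filter(d, hd))
})

test_that("requesting more sequenced carriers than exist is a simulation error", {
  sim <- small_sim()
  cfg_bad <- sim$config
  cfg_bad$n_sequenced_carriers <- 10000L
  cfg_bad$n_sequenced <- 10050L
  expect_error(emit_sequenced_subset(sim, cfg_bad), class = "hd_sim_error")
})

test_that("zero decoys leave only the causal variant in the LD shortlist", {
  cfg <- sim_config(seed = 77, n_founders = 150, n_generations = 1,
                    n_genotyped_target = 300, chrom_length = 5e6,
                    lethal_region = c(2e6, 3e6), n_background_variants = 50,
                    n_decoy_variants = 0)
  sim <- simulate_population(cfg)
  hd <- setNames(sim$truth$sequenced$carrier_copies,
                 sim$truth$sequenced$sample_id)
  sl <- shortlist_variants(sim$seq_panel, hd)
  expect_equal(nrow(sl), 1)
  expect_equal(sl$pos, sim$truth$causal_pos)
  expect_equal(sl$r2, 1.0)
})

test_that("an unreachable genotyped target raises a simulation error", {
  cfg <- sim_config(seed = 5, n_founders = 100, n_generations = 1,
                    n_genotyped_target = 5000, n_litters_per_gen = 3,
                    chrom_length = 5e6, lethal_region = c(2e6, 3e6))
  expect_error(simulate_population(cfg), class = "hd_sim_error")
})

test_that("simulator outputs round-trip through the on-disk formats", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_sim_output(sim, dir)
  g2 <- read_phased_vcf(file.path(dir, "genotypes.vcf"))
  expect_identical(g2$hap_a, sim$genotypes$hap_a)
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(ped2), nrow(sim$pedigree))
  ls2 <- read_litters(file.path(dir, "litters.csv"), file.path(dir, "deaths.csv"))
  expect_equal(ls2$litters$weaned, sim$litters$litters$weaned)
  p2 <- read_variant_vcf(file.path(dir, "seqpanel.vcf"))
  expect_equal(p2$variants$pos, sim$seq_panel$variants$pos)
  expect_identical(p2$dosages[, sim$seq_panel$sample_ids],
                   sim$seq_panel$dosages)
  m2 <- read_gene_model(file.path(dir, "genes.gff3"))[[sim$gene_model$gene_id]]
  expect_equal(m2$cds, sim$gene_model$cds)
  cds2 <- read_cds_fasta(file.path(dir, "cds.fasta"))
  expect_equal(unname(cds2), unname(sim$cds_seq))
})
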