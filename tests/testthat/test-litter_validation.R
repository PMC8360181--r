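make_litters <- function(records, deaths = NULL) {
  lit <- do.call(rbind, lapply(records, function(r)
    data.frame(litter_id = r[[1]], sire_id = r[[2]], dam_id = r[[3]],
               total_born = r[[4]], born_alive = r[[5]], weaned = r[[6]],
               stringsAsFactors = FALSE)))
  litter_set(lit, deaths)
}

test_that("mating classification is symmetric and handles missing parents", {
  ls <- make_litters(list(list("L1", "S", "D", 10, 9, 9),
                          list("L2", "S2", "D2", 10, 9, 9),
                          list("L3", "S3", "D3", 10, 9, 9),
                          list("L4", "S4", "D4", 10, 9, 9)))
  carriers <- c(S = 1, D = 1, S2 = 0, D2 = 1, S3 = 1, D3 = 0, S4 = 0)
  cls <- classify_matings(ls, carriers)
  expect_equal(unname(cls[c("L1", "L2", "L3", "L4")]),
               c("CxC", "CxN", "CxN", "UNKNOWN"))
  # symmetric: swapping sire/dam statuses leaves classes unchanged
  carriers_swapped <- c(S = 1, D = 1, S2 = 1, D2 = 0, S3 = 0, D3 = 1, S4 = 0)
  expect_equal(unname(classify_matings(ls, carriers_swapped)[1:3]),
               unname(cls[1:3]))
  # homozygous parents count as carriers and are flagged
  carriers2 <- c(S = 2, D = 1, S2 = 0, D2 = 1, S3 = 1, D3 = 0, S4 = 0)
  cls2 <- classify_matings(ls, carriers2)
  expect_equal(unname(cls2[["L1"]]), "CxC")
  expect_true(attr(cls2, "homozygous_parent")[["L1"]])
})

test_that("class counts are reproduced on a population-scale fixture", {
  n <- c(NxN = 4556, CxN = 777, CxC = 31)
  status <- rep(names(n), n)
  lit <- data.frame(litter_id = sprintf("L%04d", seq_along(status)),
                    sire_id = sprintf("S%04d", seq_along(status)),
                    dam_id = sprintf("D%04d", seq_along(status)),
                    total_born = 10L, born_alive = 9L, weaned = 8L,
                    stringsAsFactors = FALSE)
  carriers <- setNames(
    c(ifelse(status == "NxN", 0L, 1L), ifelse(status == "CxC", 1L, 0L)),
    c(lit$sire_id, lit$dam_id))
  cls <- classify_matings(litter_set(lit), carriers)
  expect_equal(as.vector(table(cls)[names(n)]), unname(n))
})

test_that("survival summaries distinguish litter-mean and pooled modes", {
  ls <- make_litters(list(list("L1", "S", "D", 10, 9, 9),
                          list("L2", "S", "D", 10, 8, 4),
                          list("L3", "S2", "D2", 10, 10, 10)))
  cls <- setNames(c("CxC", "CxC", "NxN"), c("L1", "L2", "L3"))
  lm <- suppressWarnings(summarize_survival(ls, cls, mode = "litter_mean"))
  cxc <- lm[lm$mating_class == "CxC", ]
  expect_equal(cxc$weaning_survival_pct, 100 * mean(c(1, 0.5)))  # 75
  expect_equal(cxc$farrowing_survival_pct, 100 * mean(c(0.9, 0.8)))
  pooled <- suppressWarnings(summarize_survival(ls, cls, mode = "pooled"))
  cxcp <- pooled[pooled$mating_class == "CxC", ]
  expect_equal(cxcp$weaning_survival_pct, 100 * 13 / 17)
  expect_equal(cxcp$avg_total_born, 10)
  # single-litter sanity: 10/9/9
  one <- suppressWarnings(
    summarize_survival(make_litters(list(list("L1", "S", "D", 10, 9, 9))),
                       c(L1 = "NxN")))
  expect_equal(one$farrowing_survival_pct, 90)
  expect_equal(one$weaning_survival_pct, 100)
})

test_that("pooled pre-weaning mortality reproduces published aggregates", {
  # 281 liveborn, 81 pre-weaning deaths -> 28.8%, i.e. 29% after rounding
  mort <- 100 * 81 / 281
  expect_equal(round(mort), 29)
  expect_equal(round(mort, 1), 28.8)
})

test_that("relative survival decline matches the published contrast", {
  d <- survival_decline(69.99, 90.41)
  expect_equal(round(d, 2), 22.59)
  expect_equal(round(d), 23)
  expect_equal(survival_decline(80, 80), 0)
  expect_equal(survival_decline(75, 100), 25)
  expect_error(survival_decline(10, 0), class = "hd_domain_error")
})

test_that("Fisher survival test matches the hypergeometric oracle", {
  tab <- rbind(c(9, 1), c(5, 5))
  # one-sided tail P(a >= 9) = 13013/184756
  r1 <- 10; c1 <- 14; n <- 20
  one_sided <- sum(choose(c1, 9:10) * choose(n - c1, r1 - (9:10))) /
    choose(n, r1)
  expect_equal(one_sided, 13013 / 184756)
  expect_equal(survival_test(c(9, 1), c(5, 5)), fisher_oracle(tab),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:60) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(survival_test(tab[1, ], tab[2, ]), fisher_oracle(tab),
                 tolerance = 1e-9)
  }
  expect_gt(survival_test(c(500, 50), c(500, 50)), 0.9)
  expect_error(survival_test(c(0, 0), c(1, 2)), class = "hd_domain_error")
})

test_that("carrier-by-carrier litters separate from carrier-by-normal with power", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 6000 + s, n_founders = 500, n_generations = 1,
                      n_genotyped_target = 500, n_litters_per_gen = 450,
                      chrom_length = 5e6, lethal_region = c(2e6, 3e6),
                      cxc_enrichment = 0.25, n_background_variants = 10)
    sim <- simulate_population(cfg)
    cls <- classify_matings(sim$litters, sim$truth$carrier_copies)
    expect_gte(sum(cls == "CxC"), 30)
    expect_gte(sum(cls == "CxN"), 30)
    su <- suppressWarnings(summarize_survival(sim$litters, cls,
                                              mode = "pooled",
                                              reference = "CxN"))
    p <- su$p_vs_reference[su$mating_class == "CxC"]
    if (!is.na(p) && p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("pooled survival over all classes conserves total counts", {
  sim <- small_sim()
  cls <- classify_matings(sim$litters, sim$truth$carrier_copies)
  su <- suppressWarnings(summarize_survival(sim$litters, cls, mode = "pooled"))
  lit <- sim$litters$litters
  # recombining class-wise pooled rates must recover the global counts
  class_alive <- vapply(su$mating_class, function(k)
    sum(lit$born_alive[cls[lit$litter_id] == k]), numeric(1))
  combined_weaned <- sum(su$weaning_survival_pct / 100 * class_alive)
  expect_equal(combined_weaned, sum(lit$weaned), tolerance = 1e-9)
  expect_equal(sum(class_alive), sum(lit$born_alive))
})

test_that("simulated carrier-by-carrier survival approaches the mixture limit", {
  cfg <- sim_config(seed = 314, n_founders = 500, n_generations = 2,
                    n_genotyped_target = 800, n_litters_per_gen = 80,
                    chrom_length = 5e6, lethal_region = c(2e6, 3e6),
                    cxc_enrichment = 0.6, n_background_variants = 10)
  sim <- simulate_population(cfg)
  cls <- classify_matings(sim$litters, sim$truth$carrier_copies)
  cxc <- sim$litters$litters[cls[sim$litters$litters$litter_id] == "CxC", ]
  n_alive <- sum(cxc$born_alive)
  expect_gt(n_alive, 500)
  surv <- sum(cxc$weaned) / n_alive
  s <- 1 - cfg$baseline_weaning_mortality
  p <- cfg$homozygote_lethality_penetrance
  limit <- s * (1 - 0.25 * p)
  se <- sqrt(limit * (1 - limit) / n_alive)
  # 3 SE plus the Mendelian sampling of the homozygote fraction itself
  se_hom <- s * 0.25 * p * sqrt(0.75 * 0.25 / n_alive) / 0.25
  expect_lt(abs(surv - limit), 3 * (se + se_hom))
})

test_that("death tabulations bin days and causes as recorded", {
  d <- data.frame(litter_id = "L1",
                  piglet_id = sprintf("p%02d", 1:38),
                  death_day = c(rep(2, 20), rep(4, 6), rep(9, 8), rep(22, 4)),
                  cause = c(rep("nervous disease", 24), rep(NA, 14)),
                  stringsAsFactors = FALSE)
  ls <- make_litters(list(list("L1", "S", "D", 40, 40, 2)), d)
  tab <- tabulate_deaths(ls, weaning_day = 21)
  expect_equal(unname(tab$day_hist["day1-5"]), 26)
  expect_equal(unname(tab$day_hist["day6-21"]), 8)
  expect_equal(unname(tab$day_hist["post_weaning"]), 4)
  expect_equal(unname(tab$cause_hist[["nervous disease"]]), 24)
  expect_equal(tab$n_known_cause, 24)
  empty <- tabulate_deaths(make_litters(list(list("L9", "S", "D", 10, 10, 10))))
  expect_equal(empty$n_deaths, 0L)
})

test_that("simulated lethal deaths concentrate in the first five days", {
  sim <- small_sim()
  pg <- sim$truth$piglets
  hom_dead <- pg[pg$liveborn & pg$lethal_copies == 2 & !is.na(pg$death_day), ]
  expect_gt(nrow(hom_dead), 30)
  expect_gte(mean(hom_dead$death_day <= 5), 0.70)
  # a majority of lethal deaths carry the nervous-disease label (24/38 rate)
  labelled <- mean(!is.na(hom_dead$cause) & hom_dead$cause == "nervous disease")
  expect_gt(labelled, 0.4)
  expect_lt(labelled, 0.9)
})
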