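#' Classify matings by parental carrier status
#'
#' A litter is `CxC` when both parents carry at least one haplotype copy,
#' `CxN` when exactly one does, `NxN` when neither, and `UNKNOWN` when a
#' parent has no carrier status (ungenotyped). Classification is
#' symmetric in sire and dam. Homozygous parents (two copies) count as
#' carriers; litters with a homozygous parent are flagged in the
#' `homozygous_parent` attribute since such parents should be near-absent
#' when the haplotype is lethal.
#'
#' @param ls a [litter_set()].
#' @param carriers named vector of haplotype copies (0/1/2) for genotyped
#'   animals (see [carrier_status()]).
#' @return Named character vector litter_id -> class, with attribute
#'   `homozygous_parent` (logical).
#' @export
classify_matings <- function(ls, carriers) {
  lit <- ls$litters
  sc <- carriers[lit$sire_id]; dc <- carriers[lit$dam_id]
  cls <- ifelse(is.na(sc) | is.na(dc), "UNKNOWN",
                ifelse(sc >= 1 & dc >= 1, "CxC",
                       ifelse(sc >= 1 | dc >= 1, "CxN", "NxN")))
  out <- setNames(cls, lit$litter_id)
  attr(out, "homozygous_parent") <-
    setNames(!is.na(sc) & sc == 2 | !is.na(dc) & dc == 2, lit$litter_id)
  out
}

#' Summarise farrowing and pre-weaning survival by mating class
#'
#' Farrowing survival is born alive / total born; weaning survival is
#' weaned / born alive. `litter_mean` (default) averages the per-litter
#' ratios, matching how breeding reports average litre-level percentages;
#' `pooled` divides summed counts and is the basis for significance
#' testing. Classes with no litters are omitted with a warning. When a
#' `reference` class is given, each other class gets a two-sided Fisher
#' exact p-value on the pooled weaned/died counts against it (piglet
#' counts are pooled across litters, ignoring litter clustering).
#'
#' @param ls a [litter_set()].
#' @param classes named class vector from [classify_matings()].
#' @param mode "litter_mean" or "pooled".
#' @param reference optional reference class (e.g. "CxN") for p-values.
#' @return data.frame with one row per class: `mating_class`, `n_litters`,
#'   `avg_total_born`, `avg_live_born`, `farrowing_survival_pct`,
#'   `weaning_survival_pct`, `p_vs_reference`.
#' @export
summarize_survival <- function(ls, classes, mode = c("litter_mean", "pooled"),
                               reference = NULL) {
  mode <- match.arg(mode)
  lit <- ls$litters
  cls <- classes[lit$litter_id]
  levels <- c("NxN", "CxN", "CxC", "UNKNOWN")
  present <- levels[levels %in% cls]
  absent <- setdiff(setdiff(levels, "UNKNOWN"), present)
  if (length(absent) > 0)
    warning(sprintf("mating class(es) with zero litters omitted: %s",
                    paste(absent, collapse = ", ")))
  rows <- lapply(present, function(k) {
    m <- lit[cls == k, , drop = FALSE]
    farrow <- if (mode == "litter_mean")
      mean(m$born_alive / m$total_born) else sum(m$born_alive) / sum(m$total_born)
    wean_litters <- m[m$born_alive > 0, , drop = FALSE]
    wean <- if (mode == "litter_mean")
      mean(wean_litters$weaned / wean_litters$born_alive)
    else sum(m$weaned) / sum(m$born_alive)
    data.frame(mating_class = k, n_litters = nrow(m),
               avg_total_born = mean(m$total_born),
               avg_live_born = mean(m$born_alive),
               farrowing_survival_pct = 100 * farrow,
               weaning_survival_pct = 100 * wean,
               p_vs_reference = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    if (!reference %in% out$mating_class)
      hd_domain_error(sprintf("reference class %s has no litters", reference))
    pooled_counts <- function(k) {
      m <- lit[cls == k, , drop = FALSE]
      c(survived = sum(m$weaned), died = sum(m$born_alive) - sum(m$weaned))
    }
    ref_counts <- pooled_counts(reference)
    for (i in seq_len(nrow(out))) {
      if (out$mating_class[i] == reference) next
      out$p_vs_reference[i] <- survival_test(pooled_counts(out$mating_class[i]),
                                             ref_counts)
    }
  }
  out
}

#' Relative decline in pre-weaning survival
#'
#' `(reference - test) / reference * 100`, in percent of the reference
#' class survival.
#'
#' @param test_pct,reference_pct weaning survival percentages (e.g. from
#'   [summarize_survival()]).
#' @return Relative decline in percent.
#' @export
survival_decline <- function(test_pct, reference_pct) {
  if (reference_pct == 0)
    hd_domain_error("survival_decline: reference survival is zero")
  (reference_pct - test_pct) / reference_pct * 100
}

#' Fisher exact test of pooled survival between two mating classes
#'
#' Two-sided Fisher exact test (summed-mass rule) on the 2x2 table of
#' (survived, died) piglet counts for a test class against a reference
#' class. Piglets are pooled across litters; litter clustering is
#' ignored, which makes the test anti-conservative for strongly clustered
#' deaths — interpret borderline p-values with care.
#'
#' @param test_counts,reference_counts length-2 vectors
#'   `c(survived, died)`.
#' @return Two-sided p-value.
#' @export
survival_test <- function(test_counts, reference_counts) {
  tab <- rbind(test = test_counts, reference = reference_counts)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    hd_domain_error("survival_test: empty margin in 2x2 table")
  fisher.test(tab)$p.value
}

#' Tabulate pre-weaning deaths by day and cause
#'
#' Builds a day-of-death histogram (early bin: days 1-5; late bin: day 6
#' to `weaning_day`; later deaths binned as "post_weaning") and a cause
#' histogram over records with a known cause, optionally restricted to a
#' set of litters (e.g. the carrier-by-carrier class).
#'
#' @param ls a [litter_set()].
#' @param litter_ids optional litter ids to restrict to.
#' @param weaning_day end of the late bin (default 21).
#' @return list with `n_deaths`, `day_hist` (named counts), `day_detail`
#'   (per-day table), `cause_hist` (named counts over known causes),
#'   `n_known_cause`.
#' @export
tabulate_deaths <- function(ls, litter_ids = NULL, weaning_day = 21) {
  d <- ls$deaths
  if (!is.null(litter_ids)) d <- d[d$litter_id %in% litter_ids, , drop = FALSE]
  if (nrow(d) == 0)
    return(list(n_deaths = 0L, day_hist = integer(0),
                day_detail = table(integer(0)), cause_hist = integer(0),
                n_known_cause = 0L))
  bin <- cut(d$death_day, breaks = c(0, 5, weaning_day, Inf),
             labels = c("day1-5", sprintf("day6-%d", weaning_day),
                        "post_weaning"))
  known <- d$cause[!is.na(d$cause)]
  list(n_deaths = nrow(d),
       day_hist = table(bin),
       day_detail = table(d$death_day),
       cause_hist = table(known),
       n_known_cause = length(known))
}
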