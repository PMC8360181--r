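#' Build sliding-window tilings over a marker map
#'
#' For each window size, the chromosome is tiled with non-overlapping
#' half-open windows `[k*size, (k+1)*size)` anchored at coordinate 0;
#' windows containing fewer than two markers are dropped and the union
#' over all sizes is returned. A sub-window sliding step can be requested
#' with `step` (default: step equals the window size).
#'
#' @param map a [marker_map()].
#' @param window_sizes window widths in bp (default 500 kb, 1 Mb, 1.5 Mb).
#' @param step optional step in bp between window starts (one value,
#'   applied to every size); default `NULL` means non-overlapping tiling.
#' @return data.frame with columns `chrom`, `start`, `end`, `size`,
#'   `idx_start`, `idx_end` (contiguous marker index range, map-wide).
#' @export
build_windows <- function(map, window_sizes = c(5e5, 1e6, 1.5e6), step = NULL) {
  if (nrow(map) == 0)
    hd_domain_error("build_windows: empty marker map")
  out <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    pos <- map$pos[idx]
    for (size in window_sizes) {
      by <- step %||% size
      starts <- seq(0, max(pos), by = by)
      for (s in starts) {
        lo <- s; hi <- s + size
        in_w <- idx[pos >= lo & pos < hi]
        if (length(in_w) < 2) next
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = lo, end = hi, size = size,
          idx_start = in_w[1], idx_end = in_w[length(in_w)])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), size = numeric(0),
                      idx_start = integer(0), idx_end = integer(0)))
  do.call(rbind, out)
}

window_strings <- function(g, idx_start, idx_end) {
  cols <- idx_start:idx_end
  list(a = do.call(paste0, as.data.frame(g$hap_a[, cols, drop = FALSE])),
       b = do.call(paste0, as.data.frame(g$hap_b[, cols, drop = FALSE])))
}

#' Enumerate haplotypes within one window
#'
#' Counts every distinct allele string occurring in the window across the
#' phased matrix: chromosome copies, carrier animals (at least one copy)
#' and homozygous animals (two copies).
#'
#' @param window one row of [build_windows()] output (or any list with
#'   `idx_start`, `idx_end`).
#' @param g a phased, complete [hap_genotypes()] object.
#' @return data.frame with `allele_string`, `n_copies`, `n_carriers`,
#'   `n_hom_obs`, sorted by decreasing `n_copies`.
#' @export
enumerate_haplotypes <- function(window, g) {
  if (!g$phased || anyNA(g$hap_a) || anyNA(g$hap_b))
    hd_domain_error("enumerate_haplotypes: matrix must be phased and complete")
  if (is.na(window$idx_start) || window$idx_end < window$idx_start)
    hd_domain_error("enumerate_haplotypes: window contains no markers")
  s <- window_strings(g, window$idx_start, window$idx_end)
  levs <- sort(unique(c(s$a, s$b)))
  fa <- factor(s$a, levels = levs); fb <- factor(s$b, levels = levs)
  ca <- tabulate(fa, nbins = length(levs))
  cb <- tabulate(fb, nbins = length(levs))
  hom <- tabulate(fa[s$a == s$b], nbins = length(levs))
  data.frame(allele_string = levs, n_copies = ca + cb,
             n_carriers = ca + cb - hom, n_hom_obs = hom,
             stringsAsFactors = FALSE)[order(-(ca + cb), levs), ]
}

#' Haplotype frequency and expected homozygote count
#'
#' Under Hardy-Weinberg proportions, a haplotype carried on `n_copies`
#' of the `2N` chromosomes has frequency `q = n_copies / (2N)` and an
#' expected `N * q^2` homozygous animals.
#'
#' @param n_copies number of chromosome copies of the haplotype.
#' @param n_genotyped number of genotyped animals `N`.
#' @return list with `q_hat` and `e_hom`.
#' @export
expected_homozygotes <- function(n_copies, n_genotyped) {
  if (any(n_genotyped < 1))
    hd_domain_error("expected_homozygotes: no genotyped animals")
  if (any(n_copies > 2 * n_genotyped))
    hd_domain_error("expected_homozygotes: more copies than chromosomes")
  q <- n_copies / (2 * n_genotyped)
  list(q_hat = q, e_hom = n_genotyped * q^2)
}

#' Exact binomial deficit-of-homozygosity test
#'
#' One-sided lower-tail exact binomial test of the observed homozygote
#' count against the Hardy-Weinberg expectation: with
#' `X ~ Binomial(N, q^2)`, returns `P(X <= n_hom_obs)` by exact term
#' summation in log space.
#'
#' @param n_genotyped number of genotyped animals `N`.
#' @param q_hat estimated haplotype frequency.
#' @param n_hom_obs observed homozygote count.
#' @return Lower-tail p-value.
#' @export
deficit_test <- function(n_genotyped, q_hat, n_hom_obs) {
  if (n_genotyped < 1 || n_hom_obs < 0)
    hd_domain_error("deficit_test: invalid inputs")
  p_hom <- q_hat^2
  if (p_hom >= 1)
    hd_domain_error("deficit_test: homozygote probability q_hat^2 must be < 1")
  if (n_hom_obs >= n_genotyped) return(1)
  if (p_hom == 0) return(1)
  k <- 0:n_hom_obs
  logterms <- lchoose(n_genotyped, k) + k * log(p_hom) +
    (n_genotyped - k) * log1p(-p_hom)
  min(1, exp(logsumexp(logterms)))
}

#' Genome-wide deficit-of-homozygosity scan
#'
#' Enumerates haplotypes in every window, keeps those testable under the
#' expected-homozygote threshold, and attaches frequency, expectation,
#' the exact binomial deficit p-value, carrier frequency and a
#' Bonferroni-adjusted p (per number of tested haplotypes). Results are
#' sorted by `p_deficit` with deterministic tie-breaking.
#'
#' @param g a phased, complete [hap_genotypes()] object.
#' @param windows data.frame from [build_windows()]; default builds the
#'   standard 500 kb / 1 Mb / 1.5 Mb tilings.
#' @param min_expected testability threshold on expected homozygotes
#'   (default 3): below it a zero count cannot reach p < 0.05.
#' @param alpha significance level used for the `significant` flag
#'   (raw p, default 0.05).
#' @return data.frame of class `hap_scan` with one row per tested
#'   haplotype.
#' @export
scan_genome <- function(g, windows = NULL, min_expected = 3, alpha = 0.05) {
  if (is.null(windows)) windows <- build_windows(g$map)
  N <- n_animals(g)
  res <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    hap <- enumerate_haplotypes(win, g)
    eh <- expected_homozygotes(hap$n_copies, N)
    keep <- eh$e_hom >= min_expected
    if (!any(keep)) next
    hap <- hap[keep, , drop = FALSE]
    q <- eh$q_hat[keep]; ehom <- eh$e_hom[keep]
    p <- vapply(seq_len(nrow(hap)), function(i)
      deficit_test(N, q[i], hap$n_hom_obs[i]), numeric(1))
    res[[w]] <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                           size = win$size, allele_string = hap$allele_string,
                           n_copies = hap$n_copies, n_carriers = hap$n_carriers,
                           n_hom_obs = hap$n_hom_obs, q_hat = q, e_hom = ehom,
                           carrier_freq = hap$n_carriers / N, p_deficit = p,
                           stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      size = numeric(0), allele_string = character(0),
                      n_copies = integer(0), n_carriers = integer(0),
                      n_hom_obs = integer(0), q_hat = numeric(0),
                      e_hom = numeric(0), carrier_freq = numeric(0),
                      p_deficit = numeric(0), p_bonferroni = numeric(0),
                      significant = logical(0))
    class(out) <- c("hap_scan", "data.frame")
    return(out)
  }
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_deficit * nrow(out))
  out$significant <- out$p_deficit < alpha
  out <- out[order(out$p_deficit, out$chrom, out$start, out$allele_string), ]
  rownames(out) <- NULL
  attr(out, "n_genotyped") <- N
  attr(out, "n_tested") <- nrow(out)
  class(out) <- c("hap_scan", "data.frame")
  out
}

#' Merge significant windows into candidate deficit regions
#'
#' Haplotypes with `p_deficit < alpha` are grouped per chromosome; windows
#' that overlap or lie within `gap_tolerance` bp of each other are merged
#' into regions. Each region reports its minimal-p haplotype.
#'
#' @param scan a `hap_scan` data.frame from [scan_genome()].
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param gap_tolerance maximum bp gap between merged windows (default 0:
#'   only overlapping or book-ended windows merge).
#' @return data.frame with `chrom`, `start`, `end`,
#'   `n_supporting_windows`, `best_start`, `best_end`,
#'   `best_allele_string`, `best_p`, sorted by `best_p`.
#' @export
merge_regions <- function(scan, alpha = 0.05, gap_tolerance = 0) {
  sig <- scan[scan$p_deficit < alpha, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_supporting_windows = integer(0),
                      best_start = numeric(0), best_end = numeric(0),
                      best_allele_string = character(0), best_p = numeric(0)))
  out <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    cur_start <- s$start[1]; cur_end <- s$end[1]; members <- 1
    flush <- function(members, cur_start, cur_end) {
      m <- s[members, , drop = FALSE]
      best <- m[order(m$p_deficit, m$start, m$allele_string)[1], ]
      data.frame(chrom = chr, start = cur_start, end = cur_end,
                 n_supporting_windows = length(unique(paste(m$start, m$end))),
                 best_start = best$start, best_end = best$end,
                 best_allele_string = best$allele_string, best_p = best$p_deficit,
                 stringsAsFactors = FALSE)
    }
    members <- 1
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        if (s$start[i] <= cur_end + gap_tolerance) {
          cur_end <- max(cur_end, s$end[i]); members <- c(members, i)
        } else {
          out[[length(out) + 1]] <- flush(members, cur_start, cur_end)
          cur_start <- s$start[i]; cur_end <- s$end[i]; members <- i
        }
      }
    }
    out[[length(out) + 1]] <- flush(members, cur_start, cur_end)
  }
  out <- do.call(rbind, out)
  out[order(out$best_p, out$chrom, out$start), , drop = FALSE]
}

#' Per-animal copy number of a specific haplotype
#'
#' Exact allele-string match of each phased chromosome against the query
#' haplotype within a window.
#'
#' @param g a phased [hap_genotypes()] object.
#' @param chrom,start,end half-open window coordinates `[start, end)`.
#' @param allele_string haplotype allele string (0/1 characters, one per
#'   marker in the window).
#' @return Named integer vector (animal id -> copies 0/1/2).
#' @export
carrier_status <- function(g, chrom, start, end, allele_string) {
  idx <- which(g$map$chrom == chrom & g$map$pos >= start & g$map$pos < end)
  if (length(idx) == 0)
    hd_domain_error("carrier_status: window contains no markers")
  if (nchar(allele_string) != length(idx))
    hd_domain_error(sprintf(
      "carrier_status: allele string length %d does not match %d window markers",
      nchar(allele_string), length(idx)))
  s <- window_strings(g, idx[1], idx[length(idx)])
  setNames((s$a == allele_string) + (s$b == allele_string), g$animal_ids)
}

#' Haplotype statistics from published summary counts
#'
#' Reconstructs the full set of scan statistics (copies, frequency,
#' expected homozygotes, carrier frequency, deficit p-value) from the
#' counts a report typically prints: population size, carrier animals and
#' observed homozygotes. Homozygotes contribute two copies.
#'
#' @param n_genotyped number of genotyped animals.
#' @param n_carriers number of animals with at least one copy.
#' @param n_hom_obs number of homozygous animals.
#' @return list with `n_copies`, `q_hat`, `e_hom`, `carrier_freq_pct`,
#'   `hap_freq_pct`, `p_deficit`.
#' @export
haplotype_stat_from_counts <- function(n_genotyped, n_carriers, n_hom_obs) {
  if (n_hom_obs > n_carriers || n_carriers > n_genotyped)
    hd_domain_error("haplotype_stat_from_counts: inconsistent counts")
  n_copies <- n_carriers + n_hom_obs  # het carriers + 2 * homozygotes
  eh <- expected_homozygotes(n_copies, n_genotyped)
  list(n_copies = n_copies, q_hat = eh$q_hat, e_hom = eh$e_hom,
       hap_freq_pct = 100 * eh$q_hat,
       carrier_freq_pct = 100 * n_carriers / n_genotyped,
       p_deficit = deficit_test(n_genotyped, eh$q_hat, n_hom_obs))
}
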