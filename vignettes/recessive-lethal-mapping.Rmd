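---
title: "Mapping recessive lethal haplotypes from a deficit of homozygosity"
author: "hapdeficit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive lethal haplotypes from a deficit of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdeficit)
```

## The problem

A fully penetrant recessive lethal allele is invisible in a breeding
population's phenotypes: carriers are healthy, and homozygotes die so early
(here, before weaning) that they never enter the recorded, genotyped
population. What remains visible is an *absence*: animals homozygous for the
surrounding haplotype are much rarer than Hardy-Weinberg proportions
predict. `hapdeficit` implements the complete discovery chain built on that
signature, for populations of livestock with dense SNP-chip genotypes,
pedigree and litter records, and sequence data for a small subset:

1. **Marker QC** - call rate, minor allele frequency and an exact
   Hardy-Weinberg test, with strict thresholds (defaults: call rate
   \> 0.90, MAF \> 0.01, HWE *P* \> 1e-6).
2. **Deficit-of-homozygosity scan** - enumerate phased haplotypes in
   sliding windows and test each against its expected homozygote count
   with an exact binomial test.
3. **Litter validation** - classify matings by parental carrier status
   and quantify farrowing and pre-weaning survival per class
   (carrier-by-carrier matings lose the homozygous quarter of their
   litters).
4. **Variant prioritisation** - correlate sequence-variant dosages with
   the haplotype (LD r²), check carrier/non-carrier concordance, and
   annotate coding consequences, flagging stop-gained candidates with
   their truncation length.
5. **Synthetic population generator** - a seeded gene-drop simulator that
   implants a lethal haplotype into a breeding population so the whole
   chain is testable end to end without animal data.

## The scan statistic

For a haplotype (an exact allele string over the markers of a window)
carried on $c$ of the $2N$ phased chromosomes, the frequency estimate is
$\hat q = c/2N$ and the Hardy-Weinberg expectation for homozygous animals
is $E = N\hat q^2$; homozygotes contribute two copies to $c$. With $X$ the
number of homozygous animals and $X \sim \mathrm{Binomial}(N, \hat q^2)$
under random mating, the deficit p-value is the exact lower tail

$$p = P(X \le x_\mathrm{obs}) = \sum_{k=0}^{x_\mathrm{obs}} \binom{N}{k}
\hat q^{2k} (1-\hat q^2)^{N-k},$$

summed in log space. One convention question is real: with one observed
homozygote, $P(X \le 1)$ and $P(X = 0)$ differ by an order of magnitude,
and published tables are sometimes consistent with the latter.
`deficit_test()` always uses the inclusive lower tail
$P(X \le x_\mathrm{obs})$; both conventions are reported by the
reproduction script. No published number is used as an oracle for either.

Windows follow three non-overlapping tilings of 500 kb, 1 Mb and 1.5 Mb
(half-open `[k*size, (k+1)*size)` intervals, unioned; a sub-window `step`
is available but not the default), which reproduces round window
boundaries such as an 11.0-12.0 Mb hit. Windows with fewer than two
markers are dropped. Haplotypes are only *tested* when $E \ge 3$
(configurable): below that, even zero observed homozygotes cannot reach
$p < 0.05$ (since $P(X=0) \approx e^{-E} > 0.05$), so rarer haplotypes
are untestable noise that would only inflate the multiple-testing burden.
Raw p-values are flagged at $\alpha = 0.05$ to mirror how such scans are
reported; a Bonferroni column (per tested haplotype) is attached for
reference. Ties in the ranking break deterministically by
(p, chromosome, start, allele string).

## Litter validation

Matings are classified `NxN`, `CxN`, `CxC` (or `UNKNOWN` when a parent is
ungenotyped) from parental haplotype copies; classification is symmetric
and homozygous parents (which should be near-absent for a true lethal)
count as carriers but are flagged. Survival summaries come in two modes,
both emitted because they answer different questions and give visibly
different numbers:

* `litter_mean` (default) averages per-litter ratios - the convention of
  breeding-program reports whose "Avg." columns weight litters equally;
* `pooled` divides summed piglet counts - the correct basis for the
  mortality fraction and for the significance test.

The significance test is a two-sided Fisher exact test on pooled
(survived, died) counts against a reference class (`CxN` by default,
matching how a carrier-mating contrast is normally presented). Pooling
ignores litter clustering and is therefore anti-conservative when deaths
cluster within litters; the output documents this caveat, and a
mixed-model analysis is deliberately out of scope. The expected pooled
pre-weaning survival of `CxC` litters under a lethal with penetrance $p$
and baseline survival $s$ is $s(1 - 0.25p)$ - the quarter of conceptuses
that are homozygous die (with probability $p$), the rest die at baseline
rates; this closed form is verified by simulation in the test suite.

The weaning day defaults to 21 days for day-of-death binning; recorded
death days extend to the end of lactation (23 days), and simulated litter
records count as `weaned` the piglets that survive the full lactation
period, so that `born_alive - weaned` always equals the number of
recorded pre-weaning deaths.

## Variant prioritisation

LD between a sequence variant and the haplotype is the squared Pearson
correlation of dosage vectors, with the haplotype treated as a
pseudo-marker (copies 0/1/2). Dosage correlation is the standard surrogate
when phase between chip haplotypes and sequence variants is unknown;
whether a phased or composite r² was used upstream of any particular
published shortlist is usually unstated, and the difference is immaterial
at r² near 1. The shortlist keeps variants with site quality \>= 20 and
r² \>= 0.8 (both configurable), sorted by descending r² with concordant
variants first. Concordance - every carrier holds the alternate allele,
no non-carrier does - is reported as a separate column rather than used
as a filter, because inspection of genotype patterns is a step a curator
performs *after* the LD shortlist.

The consequence annotator handles biallelic SNVs against a
single-transcript gene model: the genomic position is mapped to a coding
coordinate strand-aware (alleles reverse-complemented on the minus
strand), the affected codon is translated with the standard genetic code,
and effects are classified as synonymous, missense, stop_gained,
stop_lost or start_lost with HGVS c. and p. strings (three-letter amino
acids, `*` for stop). For a stop gain at codon $i$ in a protein of length
$L$, the truncation removes $L - (i - 1)$ residues. A mismatch between
the VCF reference allele and the gene-model CDS sequence is a hard error
rather than a warning: silent coordinate bugs are the dominant failure
mode of annotators, and no downstream number is trustworthy after one.
Indels, splice-site and regulatory annotation, multi-transcript models
and structural variants are out of scope.

## The synthetic population

`simulate_population()` performs a seeded gene drop through a closed
breeding population on one simulated chromosome (default 20 Mb):

* **Markers**: positions uniform, density 40/Mb; founder allele
  frequencies uniform on [0.05, 0.95].
* **Founders**: by default 60% of the genotyped target. Founder
  chromosomes carry the implanted lethal haplotype - one fixed allele
  string across the markers of the lethal region (default 11-12 Mb) - at
  exactly the configured frequency (default 4%, rounded count); colliding
  background chromosomes have one in-region allele flipped so the string
  is unique to the lethal label, and no founder receives two lethal
  copies (such an animal would not have survived to breed).
* **Meiosis**: Poisson crossovers without interference at 1 cM/Mb, fair
  start strand; the causal-locus descent label is propagated through each
  gamete, so truth carrier status is exact even for recombinants.
* **Litters**: truncated-Poisson total born (mean 10.3, range 4-18),
  binomial stillbirths (9%); liveborn lethal homozygotes die before
  weaning with penetrance 1.0 at a day drawn with 80% mass on days 1-5
  (remainder uniform to day 23), labelled "nervous disease" with
  probability 24/38; other liveborn die at the 10% baseline rate with an
  unknown cause. Mature (surviving) piglets breed the next generation
  (default two bred generations). A `cxc_enrichment` knob forces a
  fraction of litters to have two carrier parents so small simulations
  produce enough carrier-by-carrier litters to analyse.
* **Sequenced subset**: 4 truth-carriers and 21 non-carriers; ~300
  background variants with dosages from random background frequencies
  (about one in ten below the quality threshold, to exercise the filter),
  a few decoy variants in high but imperfect LD, and one causal
  stop-gained SNV inside an emitted gene model (2212-residue protein,
  CAG codon at c.541) whose dosage equals each animal's lethal copy
  number - complete LD by construction.

### Why these defaults

The generator's job is to produce data with the statistical structure the
scan assumes, at desk scale. Three choices matter and were made
deliberately:

* **Marker density 40/Mb** puts ~20 markers in the smallest (500 kb)
  window. Founder alleles are drawn independently per marker, so with
  sparser maps (under ~10 markers per window) specific short allele
  strings become *common by coincidence* - 10-20% frequency - and their
  homozygote counts, perturbed by family structure, can out-rank a true
  lethal signal. Real chips avoid this differently (LD-aware SNP
  selection makes window haplotypes tag long ancestral segments), an
  effect the density default emulates. The discovery window of the
  motivating data set itself carries 34 markers/Mb.
* **Founder majority (60%) and two bred generations** keep the realized
  lethal frequency near its 4% target: founder chromosomes carry it at
  exactly the configured rate, while each bred generation adds drift
  through the litter bottleneck (only one sire and dam per litter
  transmit). Deep pedigrees with narrow parent usage - as in real
  nucleus herds - overdisperse homozygote counts and erode the signal,
  which is precisely why the motivating study needed ~14,000 animals;
  at the ~5,000-animal scale used for testing, a shallower design is the
  faithful way to pose the same statistical problem.
* **Survival horizon**: deaths are recorded through the 23-day lactation
  and `weaned` counts its survivors, so mortality accounting is exact;
  the 21-day weaning day only affects death-day binning.

What the simulator does *not* emulate: linkage maps and recombination
hotspots, genotyping and phasing errors, selection on polygenic merit,
parity and seasonal effects on litters, overdispersed litter sizes, and
cross-chip imputation. Passing tests therefore demonstrate the
correctness of the statistical machinery on idealized phased data, not
robustness to those real-data complications - phasing error in
particular would dilute exact string matching and is upstream of this
package's scope.

Reproducibility: `simulate_population()` seeds R's RNG once from
`config$seed` and every stochastic sub-step consumes that single stream,
so outputs are bit-identical for a seed; the building blocks
(`simulate_founder_haplotypes()`, `meiosis()`) use the ambient stream
when called directly.

## Numerical choices

* The exact HWE test enumerates heterozygote counts conditional on allele
  counts in log space (equivalent to the plink exact test), summing all
  configurations with probability \<= the observed one (no mid-p), with a
  1e-10 log-space tolerance on the equality comparison.
* The binomial lower tail is summed in log space via `lchoose` +
  `log1p`; it matches `pbinom` to \<1e-10 relative error up to n = 1e5
  (tested), and is monotone in the observed count.
* QC thresholds are strict inequalities: a marker at MAF exactly 0.01 or
  HWE p exactly 1e-6 is removed. Missingness is per genotype (either
  allele missing makes the call missing). QC is meant for the
  pre-phasing matrix; the scan refuses unphased or incomplete input.
* Windows at chromosome tails with fewer than two markers vanish rather
  than shrink; merged deficit regions use interval union with a
  configurable gap tolerance (default 0, i.e. only overlapping or
  book-ended windows merge).

## Problem sizes used in validation

The packaged checks run the full chain on simulations of ~5,000 genotyped
animals (one 20 Mb chromosome, 800 markers, ~560 litters) for the
rediscovery experiment, repeated over 20 seeds, and on populations of
~1,000-2,500 animals for Mendelian-segregation, survival-mixture and
power checks. At these sizes the implanted window ranks first in at
least 19 of 20 rediscovery replicates (usually all 20), the implanted
haplotype shows zero homozygotes, and the causal variant reaches r² = 1
with full concordance in every replicate; the exact rates are
recomputed, not quoted, by `scripts/acceptance.R`.

## Limitations

Beyond the simulator idealizations above: the scan tests exact string
identity (no IBD clustering), so haplotypes fragmented by historical
recombination dilute across strings; the Fisher pooling caveat applies to
all litter p-values; the annotator supports one transcript per gene; and
X-chromosome dosage, genotype likelihoods and BCF/PLINK binary formats
are unsupported by design.
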