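---
title: "Detecting selective sweeps with sweepkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with sweepkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sweepkit)
```

## The problem

A recent hard selective sweep — the rapid fixation of a beneficial
haplotype — leaves three coupled footprints in resequencing data from the
selected population: locally depressed nucleotide diversity (and hence an
elevated diversity ratio against an unselected reference), elevated allelic
differentiation from that reference, and extended haplotype homozygosity
around the selected site. `sweepkit` implements the composite genome-scan
that intersects empirical outliers of all three statistics in 10-kb
non-overlapping windows, together with the supporting population-genetic
toolbox (windowed π and Tajima's D, Weir–Cockerham F_ST, EHH12/iHH12,
pairwise LD and LD decay, PLINK-style runs of homozygosity) and a forward
Wright–Fisher simulator used for calibration and testing.

## Statistics

**Nucleotide diversity.** Per site, the unbiased heterozygosity for `k`
alt alleles among `n` called alleles is `k (n-k) / C(n,2)`; windowed π sums
this over the SNPs of a window and divides by the full window span, so
monomorphic base pairs count as invariant sequence. This matches the per-bp
magnitudes (order 10⁻³) that diversity scans report. Accessible-site masks
are out of scope; if large fractions of a window are unsequenced, windowed
π is biased downward. The trailing window of each chromosome, when shorter
than the window size, is reported with its true span, flagged `partial`,
and excluded from outlier ranking.

**Tajima's D** is computed per window from the segregating-site count `S`
and the mean pairwise difference, standardised by the Tajima (1989)
constants (`tajima_coefficients()` exposes all eight). Because the sample
size per site must be unambiguous, `windowed_tajima_d()` requires complete
genotypes and directs the user to impute upstream (phased, imputed input is
assumed throughout the haplotype layer, as produced by e.g. Beagle). D is
reported for context in scan output but does not enter the outlier
conjunction, which uses exactly three statistics.

**Weir–Cockerham F_ST.** `wc_site_components()` computes the 1984
variance components a (among populations), b (among individuals within
populations) and c (within individuals) from per-population sample sizes,
allele frequencies and observed heterozygosity; missing genotypes are
excluded from the counts, and a site where a population has no genotyped
individual is skipped. Windows use the weighted (ratio-of-sums) estimator
Σa / Σ(a+b+c), which is also how the genome-wide mean is formed. Negative
estimates (expected under no differentiation) are retained in tables so
ranking is unaffected, and only clamped to zero in summary prose.

**iHH12.** From each core SNP, haplotypes are partitioned by identity over
the extending interval; EHH12 pools the two largest classes —
`[C(n1+n2,2) + Σ_{k>2} C(nk,2)] / C(n,2)` — which keeps power when a sweep
carries two haplotype backgrounds (soft-sweep robustness). The profile is
truncated below a cutoff (default 0.05) or beyond `max_extend` (default
1 Mb), and iHH12 is the trapezoidal integral over physical distance on both
sides, stopping at the linearly interpolated cutoff crossing. Scores are
z-normalised genome-wide — a single normalisation, with the population
(denominator-n) standard deviation — and averaged per window. No genetic
map is used; integration is over bp. The per-core reference implementation
(`ehh12_profile()` + `ihh12()`) and the compiled whole-genome scan
(`ihh12_scan()`) are tested against each other and against brute-force
partition enumeration.

**LD.** `ld_pair()` gives D, D′ and r² from phased haplotype counts;
`decay_curve()` bins all pairs within 300 kb (1-kb bins by default) and
applies the dataset-level MAF ≥ 0.05 filter before pairing. When phase is
absent, r² falls back to squared genotype correlation and the output is
flagged. `adjacent_pair_r2()` summarises consecutive-pair LD.

**ROH.** `detect_roh()` implements the PLINK scanning-window algorithm:
50-SNP windows (≤ 5 Mb span) are homozygous iff they contain ≤ 1
heterozygous and ≤ 5 missing calls; a SNP is in the ROH state iff ≥ 5% of
the valid windows containing it are homozygous; state runs are split at
gaps > 100 kb and filtered by ≥ 10 SNPs, ≥ 100 kb and ≤ 10 kb/SNP density.
The window-het and SNP-count parameters follow the published goat ROH
command; `window_missing = 5` and `hit_threshold = 0.05` adopt the wrapped
tool's defaults because the command line omits them — all are exposed in
`roh_params()`. Segment endpoints are the first/last in-state SNP
positions, not window edges; because the state is a window vote, a segment
may legitimately begin a few SNPs before a planted tract when the adjacent
background is itself homozygous. Segments longer than the scanning-window
span are allowed whenever the SNP states support them. `f_roh()` divides
per-individual merged ROH length by a genome length of 2.92 Gb by default
(the goat reference assembly length used in the ROH literature).

## The outlier scan

`run_scan()` drives the pipeline: optional GATK-style hard filters (strict
inequalities, QUAL < 100, QD < 2, MQ < 40, FS > 60, SOR > 3,
MQRankSum < −12.5, ReadPosRankSum < −8; a missing annotation passes its
rule, matching common GATK practice), the meta-population MAF ≥ 0.05 and
missingness ≤ 10% filters (both strict at the boundary), population
splitting, the three windowed statistics, thresholds and annotation.

Only windows with ≥ 10 SNPs (and not partial) are ranked. Each statistic's
threshold is the nearest-rank (inverse ECDF) 95th percentile of its ranked
values — the "top 5% tail" — and a window is a selection signal iff it
strictly exceeds all three thresholds. Strict inequality means a constant
statistic yields no outliers, and an undefined value (e.g. a diversity
ratio with a zero denominator) never qualifies. A config switch
(`rule = "two_of_three"`) relaxes the conjunction, since printed joint
thresholds in the literature do not always pin down the exact rule; the
conjunction is the default. Signal windows that overlap or share a
boundary are merged into regions, and a gene is assigned to a region iff
their 1-based inclusive spans intersect by at least one bp.

When several reference populations are supplied they are pooled by taking
the union of their samples as a single control population for both π and
F_ST. Pooling mechanics are genuinely open (averaging per-breed statistics
is the alternative); the union was chosen because it keeps both statistics
defined on one consistent sample and mirrors treating the controls as one
panel.

## The simulator and what the calibrations mean

`simulate_genomes()` is a discrete-locus forward Wright–Fisher simulator:
an ancestral diploid population is run from a monomorphic start for a
burn-in of 10N generations (relaxation to mutation–drift equilibrium
leaves < 1% bias in heterozygosity), daughter populations are founded
star-like from the same ancestral snapshot and drift independently.
Mutation is infinite-sites on integer positions (collisions redrawn;
positions of extinct mutations are recycled), recombination draws a
Poisson(rec·L) crossover count with uniform breakpoints, and a sweep is a
single copy introduced at a stated generation with additive fitness
1, 1+s, 1+2s, re-introduced on loss up to `max_attempts` times (optionally
until a minimum final frequency is reached); the truth object records the
realised frequency and attempt count. One seeded R RNG stream drives the
whole run — simpler than per-population substreams and equally
deterministic, which the byte-identical fixture test enforces.

Default parameters are chosen to reproduce the magnitudes this kind of
goat resequencing study reports, not to be a calibrated goat demography:
θ = 4Nμ = 1.5 × 10⁻³/bp (reported genome π 1.5–1.9 × 10⁻³), ρ = 4Nr such
that r² decays to ~0.2 within a few kb, and split times giving weighted
F_ST ≈ 0.15–0.23 (reported 0.14–0.22). Two scaled-down condition sets are
used by the tests and the acceptance script, with sizes picked once:

* **Neutral calibration** — two populations of N = 100, split
  t = 20 = 0.1·2N generations, 200-kb chromosome, 20 sampled diploids
  each: mean windowed π is compared with θ = 4Nμ (15% band), the
  genome-wide weighted F_ST with the pure-drift expectation
  1 − (1 − 1/2N)^t (±0.05), where t is the drift time in each daughter
  since the split, and mean windowed Tajima's D with 0 (±0.3).
* **Sweep recovery** — a domestication-bottleneck design: the focal
  breed has N = 400 (2Ns = 80 for s = 0.1) while the wild reference has
  N = 2000 and barely drifts over the split, as a small domestic breed
  against a large wild progenitor population. The chromosome is 1 Mb
  (100 ranked windows, so each statistic's 5% tail is 5 windows),
  θ = 1.5 × 10⁻³, and the sweep sits at the centre of a window and must
  reach ≥ 95% frequency within the 125 post-split generations — roughly
  the additive fixation time at this 2Ns — so the population is sampled
  close to fixation. The nearly-static reference roughly halves the
  drift variance of the window-level F_ST and diversity-ratio
  backgrounds, which is what makes the empirical 5% tails informative on
  a 100-window genome; the realised genome-wide weighted F_ST
  (~0.10-0.14) lands in the range such breed-versus-wild comparisons
  report. Matched neutral runs measure the conjunction's false-positive
  rate, which should sit far below any single statistic's 5% tail.

What these simulations emulate: divergence-generated F_ST, mutation–drift
diversity, recombination-driven LD decay, hard sweeps, and uniform missing
genotypes. What they do not: variable mutation/recombination maps,
background selection, gene flow after the split, genotyping error
structure, or realistic goat demography — so passing calibrations show the
estimators and the scan logic are correct at these scales, not that the
pipeline would reproduce any particular empirical gene list.

## Numerical and boundary choices

* Coordinates are 1-based inclusive everywhere internally (VCF
  convention); BED output converts to 0-based half-open in one place.
* Multiallelic SNPs are dropped, never decomposed; indels and non-SNPs are
  dropped and counted. Half-calls and non-diploid genotypes are treated as
  missing with a warning. Whether half-calls count toward the 10%
  missingness rule is unstated in the tools this mirrors; here they do.
* Windows tile from position 1 on each chromosome; the shared grid is
  asserted when tables are joined, so statistics computed from the same
  matrix always align.
* The nearest-rank quantile with a strict ">" outlier rule reproduces
  printed thresholds of the form "F_ST > 0.33": the threshold value itself
  is never an outlier, and ties collapse to no outliers.
* iHH12 profiles that reach a chromosome edge or `max_extend` while still
  above the cutoff are integrated to the last observed point; this
  truncation slightly deflates scores of cores near chromosome ends, which
  the genome-wide z-normalisation absorbs.
* `empirical_threshold()` refuses fewer than 20 finite values: a 5% tail
  of a smaller sample is a single order statistic of rank < 1.

## Worked example

```{r example}
p <- sim_params(
  n_anc = 400, pop_sizes = c(400, 400), split_gens = c(125, 125),
  n_sample = c(20, 40), seq_len = 1e6, mu = 9.375e-7, rec = 6.25e-7,
  pop_names = c("focal", "wild"), seed = 418,
  sweep = list(pop = "focal", pos = 495000, s = 0.1, gen = 0,
               min_freq = 0.95)
)
sim <- simulate_genomes(p)
fix <- write_fixture(sim, tempfile("fixture"))

scan <- run_scan(fix[["vcf"]], fix[["popmap"]], focal = "focal",
                 reference = "wild", gff = fix[["gff"]])
scan
tidy(scan)      # one row per merged sweep region, genes attached
glance(scan)    # thresholds and counts in one row
# autoplot(scan) # faceted genome plot with thresholds and signals
```

## Known limitations

* The simulator is discrete-locus and single-chromosome; arbitrary split
  topologies, migration and X-linked inheritance are out of scope.
* iHH12 uses physical distance; with a genetic map the integral would
  change where recombination is uneven.
* The pooled-control comparison treats the union of control samples as one
  population; averaging per-breed statistics would weight breeds equally
  instead and can differ when control breeds have very unequal sizes.
* Window-level statistics inherit the usual 10-kb grid arbitrariness: a
  sweep centred on a window boundary splits its signal between two
  windows.
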