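---
title: "Methods: scanning for sex determiners in wild tilapia data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for sex determiners in wild tilapia data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The problem

Most fish have homomorphic sex chromosomes: males and females cannot be told
apart by karyotype, and the sex-determining locus must be found by
association between genotype and phenotypic sex. In Nile tilapia
(*Oreochromis niloticus*) the strongest candidate is a Y-specific tandem
duplication on LG23 spanning the anti-Müllerian hormone gene *amh*, giving
males two Y copies (*amhY* and the truncated *amhΔY*) next to the single X
copy (*amhX*). `sexscan` implements the two complementary scan designs used
to interrogate such systems in wild populations — family-based RAD genotyping
and sex-pooled whole-genome sequencing — together with the structural
analyses that resolve the Y haplotype, and a synthetic-data module that
generates inputs with the same statistical structure so every stage is
testable without any sequencing data.

## Family scan

For an F1 family with sexed offspring, `site_association()` tests each
biallelic site with

* a **two-sided Fisher's exact test** on the 2×2 ref/alt × male/female
  allele-count table. Two-sided means the *method of small p-values*: the sum
  of hypergeometric probabilities of all tables with the observed margins
  whose probability does not exceed that of the observed table (a relative
  tie guard of $1+10^{-7}$ absorbs floating-point ties; this is also the
  convention of `stats::fisher.test`). Parents are excluded: including them
  would add a fixed heterozygote to every male column and bias the table.
* the **Weir–Cockerham (1984) two-group θ** from diploid genotype counts
  (sample sizes, allele frequencies, and observed heterozygosity per sex).
  The cited lineage of the "AMOVA FST" implemented by RAD pipelines is
  Weir–Cockerham; we implement the canonical estimator and note that other
  implementations may differ numerically in small samples. θ is reported
  unclamped (slightly negative values are valid estimates of zero); sites
  monomorphic among called offspring are undefined and written as 0 in
  output tables.

Before testing, `filter_half_sex_rule()` keeps only sites with calls in at
least ⌈n/2⌉ of each offspring sex, the standard completeness rule for family
RAD tables, and `read_genotype_vcf()` applies the usual site filters
(at most 2 alleles, mean depth ≥ 5).

### Inheritance classification

`classify_inheritance()` evaluates XY against ZW heterogamety on candidate
sites (significant at `alpha`, both parents called). An XY-informative site
has a heterozygous sire and homozygous dam. A subtlety drives the design
here: at a linked site the sire's Y chromosome may carry either of his two
alleles, so the XY-consistent pattern is *either* "sons heterozygous like
the sire, daughters homozygous like the dam" *or* its mirror image. Ignoring
this phase makes pooled concordance hover near 0.5 by construction. Each
site is therefore oriented to the phase that agrees with more offspring, and
its concordance is the agreeing fraction of non-missing calls — at a truly
discriminating site next to the determiner this is 1.0, and one discordant
offspring among 28 gives 1/28 ≈ 3.6%.

Two concordance summaries are reported: the pooled fraction over all
informative sites, and the best single-site concordance. The *decision*
between XY, ZW and inconclusive uses the best site (threshold 0.9 by
default, exposed as `decision`): genotype at the region nearest the sex
determiner is what predicts phenotypic sex, while the pooled value is
diluted by loosely linked significant sites scattered over a 40 Mb
chromosome. Per-offspring recombination breakpoints are reported as switches
of the oriented carrier state between consecutive informative sites.
`sex_ratio_test()` provides the 1-df chi-square (no continuity correction)
used to verify that analysed families have balanced sex ratios.

## Pooled scan

With allele *read counts* per sex pool rather than genotypes, the scan uses:

* `pooled_fst()`: the π-based estimator
  $F_{ST} = (\pi_T - \pi_S)/\pi_T$ with
  $\pi = \frac{n}{n-1}\left(1 - p^2 - q^2\right)$ per pool ($n$ = read
  depth), $\pi_S$ the mean of the two pools and $\pi_T$ from the summed
  counts. Pool-size corrections differ across published pipelines; this
  choice is simple, stated, and reported as 0 when $\pi_T = 0$.
* `pooled_fet()`: the same exact test applied to read counts.
* `sex_snp_finder()`: the XY signature of a divergent site — near-fixed in
  the homogametic pool, intermediate in the heterogametic pool. Defaults are
  the published settings: fixed threshold 0.9, polymorphic band 0.3–0.7,
  depth window 10–100, minimum minor-allele count 2, window size 10,000 bp
  (non-overlapping, anchored at coordinate 0, half-open). Frequencies are
  **major-allele based**, not reference based: a Y-specific allele need not
  be the VCF/sync alternate allele, and the criterion should not depend on
  which haplotype was assembled as the reference. Windows count flagged
  sites per bin.

## B-chromosome blocks

Supernumerary B chromosomes carry amplified fragments of A chromosomes;
their reads pile onto the reference and produce narrow blocks of extreme
coverage that are highly "polymorphic" and, when the B happens to sit in one
sex pool, masquerade as sex-linked differentiation. `flag_bblocks()` flags
bins above `fold_threshold` (default 10) times the genome mean, merges
adjacent bins, and drops merged runs shorter than `min_block` (default
1 kb — no minimum length is published, so this is the package's choice at
the scale of the observed blocks). The genome mean is computed after
discarding the top 1% of bins by rank, so the blocks being detected cannot
inflate their own threshold. `bblock_consistency()` compares block
footprints across pools: only a footprint present in the same-sex pool of
*every* population is a sex-linked candidate; anything else (e.g. female
pool in one population, male pool in the other) is a sex-independent
artefact. `mask_sites()` removes sites inside blocks before the pooled scan.

## Structural inference

`estimate_breakpoints()` works in depth space only: the per-bin male/female
ratio is segmented by greedy least-squares binary segmentation (gain
threshold scaled to a robust noise estimate; adjacent segments closer than
half a copy step re-merged). In an XY male a tandem duplication gives ratio
3/2 = 1.5; segments within `ratio_tol` (default 0.15, half-way to the next
copy state) of 1.5 are duplicated, the duplication spans the first to last
such segment, and interior segments back at ratio 1 are deletions that
removed one of the two Y copies. Breakpoint confidence is one bin. The full
paired-end/split-read machinery of SV callers is intentionally out of scope:
the interpretable evidence is expressible, and testable, in depth space.

`build_y_haplotype()` turns a duplication plus internal deletions into the
ordered segment model of the Y region: reference prefix, two copies of the
duplicated span, reference suffix, with
`total_length = region + duplication − Σ deletions` (placement-invariant).
The default reference span is 42,000 bp (the region is published as "~42 Kb",
not as exact coordinates; the value is a parameter). Deletion placement
follows the *truncated-copy* hypothesis by default — a deletion is drawn on
the copy where the overlapped boundary-gene fragment is already truncated by
the internal chimera, the more parsimonious scenario since the alternative
would leave no intact copy of the flanking gene — with `intact-copy`
selectable to draw the alternative.

`classify_breakpoint_context()` and `annotate_variant()` resolve gene
context against GFF3 models, numbering exons and introns in transcription
order and rebuilding CDS codons with reverse-complementation for antisense
genes (all three genes of the LG23 region — *oaz1*, *amh*, *dot1l* — are
antisense on the reference). Synonymous changes report no amino-acid change.
`predict_genotype_from_markers()` encodes the amh marker rule
(amhX/amhΔY/amhY presence → XX/XY/YY/ND), with the YY (supermale) test
evaluated before XY so that amhX-negative males are not misclassified.

## Synthetic data: what it emulates, and what it does not

`simulate_family()` draws parental haplotypes, then offspring as recombinant
mosaics under a **Haldane** model (Poisson crossover count at
`recomb_rate × chrom_length`, uniform positions, no interference). No
genetic map is published for LG23, so the default 0.025 crossovers/Mb
(≈1 crossover per 40 Mb meiosis) is nominal. Under XY the sire is
heterozygous at `sd_position` and the Y allele is transmitted to exactly the
sons (the gamete's starting phase is conditioned on the sex-determining
site). Genotyping error is a symmetric per-allele flip; missingness is
independent of genotype. Defaults mirror the analysed families: 15 sons,
14 daughters, thousands of RAD-like sites.

`simulate_pools()` draws per-site pool depths as Poisson and read counts as
binomial at the pool allele frequency. Sex-patterned sites use frequency
0.98 in the homogametic pool — a *near-fixed* divergent allele, leaving room
for rare recombinant haplotypes — and exactly 0.5 in the heterogametic pool
(every male XY). B-block sites come as contiguous runs in a single pool per
population, with `bblock_fold` (default 15×) depth and ~50:50 frequencies in
the carrier pool against a conserved near-fixed frequency in the other.
`simulate_depth_profiles()` produces flat female and duplication-structured
male profiles with optional per-bin Poisson reads.

What the generators do **not** emulate: read-level artefacts (mapping bias,
duplicates, indel realignment), linkage disequilibrium among neutral sites,
allele-frequency spectra of real populations, overlapping RAD loci, or
B-chromosome sequence divergence. Passing the recovery suites therefore
shows the estimators are correct under their stated sampling models, not
that real libraries are free of the artefacts the original pipelines guard
against.

## Numerical choices and test scale

* Exact-test ties: relative guard $1+10^{-7}$; agreement with exhaustive
  enumeration is verified to $10^{-12}$ over all 2×2 tables with margins
  ≤ 30.
* Exact-test p-values are discrete and conservative, so null-uniformity is
  checked as stochastic dominance (empirical CDF never exceeding uniform)
  rather than a two-sided KS match, plus a bounded rejection rate.
* Segmentation: greedy binary splits, BIC-like gain floor
  $3.84\,\hat\sigma^2 \log n$ with $\hat\sigma$ from the median absolute
  first difference; merge tolerance half a copy step. Flat profiles produce
  no calls.
* Degenerate inputs: zero-length SVs are flagged; zero female depth aborts
  ratio segmentation; monomorphic sites report θ as missing and p = 1;
  half-missing genotype calls count as missing.
* Test problem sizes (package choices): families of 150–300 sites for
  classification suites (100 seeds), pools of 2,000–20,000 sites for
  finder recovery (10 seeds; the larger size narrows the Monte-Carlo
  interval around the finder's analytic sensitivity of ≈0.905 at the
  planted 0.95/0.5/40× condition), 20 seeds of 900-bin profiles for
  breakpoint recovery.
* Recovery suites that measure the *masking* step run both pools at 40×
  so that the finder's own detectability (which drops at 16–18×) does not
  confound what the mask restores.

## Limitations

Depth-only SV calls cannot place variants on a specific Y copy (*amhY* vs
*amhΔY*) — short reads from the two copies co-map, which is also why the
variant table records changes against the X reference without copy
assignment. The pooled scan cannot estimate B-chromosome population
frequency. The inheritance classifier needs both parents genotyped and
assumes a single-locus system; polygenic or environmentally modulated sex
determination shows up only as reduced concordance.

## A worked run

```{r demo, eval = FALSE}
res <- run_demo(seed = 1, outdir = "demo_out", system = "XY")
readLines(res$summary_path)
```

The demo simulates a family and two pooled populations, scans both, masks
B blocks, reconstructs the duplication from noisy depth, and writes every
artefact with its seed in the header so the run is byte-reproducible.
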