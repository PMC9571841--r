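---
title: "Mapping-by-sequencing of induced mutations: model, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing of induced mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsmap)
```

## The experimental design being modelled

A chemically mutagenized line of a cultivated crop carries a recessive
lesion of interest plus a load of background mutations, all on the
cultivated genome. Crossing the mutant to a wild relative and selfing the
F1 yields an F2 in which every chromosome is a mosaic of cultivated and
wild haplotypes. Mutant-phenotype F2 plants must be homozygous cultivated
at the causal locus; everywhere unlinked they carry wild alleles at the
usual segregating frequencies. Sequencing two pools — mutant plants and
wild-type plants — and tracking the non-reference (wild) allele frequency
along the genome therefore localizes the lesion: the mutant pool's
frequency collapses to zero around it, while the wild-type pool stays
intermediate.

`emsmap` implements this whole loop: a generative simulator of the design,
the allele-frequency mapping analysis, variant triage and annotation, and
the classical statistics around a mutagenesis program.

## The genetic model

**Recombination.** Gametes are drawn from a fully heterozygous F1 under
the Haldane model: the number of crossovers per chromosome is Poisson with
mean `length_cM / 100`, crossover positions are uniform in physical
coordinates, and there is no interference. The implied recombinant
fraction between two positions `d` cM apart is `r = (1 - exp(-2d/100))/2`,
which the test suite checks directly against simulated gametes.

**Phenotype.** Fully penetrant monogenic recessive: an F2 plant is mutant
iff both haplotypes are cultivated at the causal position. Dominant and
complex inheritance are handled at the family-count level (segregation
tests), not at the pool level.

**Pools and read counts.** Pools are random phenotype-stratified subsets
(default 15 mutant + 15 wild-type plants, the bulk size of the design this
package emulates). At a site whose true pool non-reference frequency is
`q` (carrier haplotypes / `2 * pool size`), sequencing depth is
Poisson(`depth_mean`) and non-reference reads are Binomial with success
probability `q(1 - eps) + (1 - q) eps`, a symmetric per-read error model.
Conservation (`ref + nonref = depth`) is exact by construction.

**Mutation spectrum.** Background mutations are spiked at uniform
positions with categories drawn from the EMS spectrum. EMS alkylates
guanine, so G:C -> A:T transitions dominate; the default fractions
0.90 / 0.05 / 0.05 (GC->AT transition / other substitution / single-base
deletion) are a package decision — the chemistry literature gives only the
qualitative bias — and are exposed in the configuration. All induced
mutations ride on the cultivated haplotype, which is what makes them
homozygous in the mutant pool near the causal locus.

## Why the wild-type band is centred on 2/3

Among phenotypically wild-type F2 plants the causal-locus genotypes are
1 homozygous-wild : 2 heterozygous, so the *wild* (non-reference) allele
frequency in the WT pool near the locus is `(2 x 1 + 1 x 2)/6 = 2/3` — and
equivalently the *reference* allele frequency is 1/3, which is the number
visible in a co-segregation table (e.g. 61 heterozygotes among 87 WT
plants gives an induced-allele frequency of 0.35). Because the mapping
profiles are built on non-reference frequencies, the detector's wild-type
band defaults to (0.45, 0.85), centred on 2/3: for a 15-plant pool the
sampling standard deviation of the pool frequency is about 0.061, so the
band is roughly +/- 3 sigma wide. A band centred on 1/3 would be
correct for the *reference* allele, not for the non-reference profile, and
would reject nearly every true signal. The quantitative invariant test
asserts the 2/3 expectation within 4 sigma.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `chrom_lengths`, `chrom_cM` | 2 x 50 Mb, 60 cM | bp, cM | desk-scale genome |
| `marker_spacing_bp` | 100 kb | bp | interspecific SNP density |
| `n_f2` | 200 | plants | F2 population size |
| `pool_size_mut`, `pool_size_wt` | 15, 15 | plants | bulk sizes |
| `depth_mean` | 50 | reads | Poisson depth per site/pool |
| `error_rate` | 0.002 | per read | symmetric miscall rate |
| `n_background_mutations` | 300 | count | EMS load |
| `window_bp`, `step_bp` | 1 Mb, 250 kb | bp | profile smoothing |
| `min_sites`, `min_depth` | 3, 10 | count | window/site usability |
| `tau_mut` | 0.05 | AF | "reaches zero" threshold |
| `wt_band` | (0.45, 0.85) | AF | recessive WT expectation band |
| `min_run` | 3 | windows | minimum hit run |
| `pad_bp` | 1.75 Mb | bp | region padding per side |
| `hom_af` | 0.9 | AF | homozygosity filter |

The marker density, depth and EMS load are design decisions at a scale
where one pipeline run takes well under a second; the detector thresholds
are deliberately conservative (missing windows never count as hits and
break runs). `pad_bp` is chosen so that the shortest reportable run
(3 windows, 1.5 Mb span) is padded to a 5 Mb inspection interval,
mirroring the interval size a practitioner would hand to variant triage;
longer runs give proportionally longer intervals. The F2 population size
is not part of the published design being emulated; 200 keeps the
probability of failing to fill the 15-plant bulks negligible.

## Variant triage and annotation

Inside the top region, candidates must be homozygous in the mutant pool
(`AF >= hom_af` at depth >= 10) and absent from a known-variants panel.
The panel is a user input; in the simulated pipeline the interspecific
marker set plays that role, standing in for "previously sequenced
genomes". Annotation uses single-transcript gene models with 1-based
inclusive coordinates and VCF-anchored indel alleles: SNVs are translated
through the standard genetic code (strand-aware), indels whose length
change is not a multiple of three are frameshifts, and truncated protein
lengths count the amino acids emitted before the first stop of the mutated
spliced CDS. Variants straddling a CDS/intron or gene boundary — and
in-frame indels — are reported as `other` with a diagnostic rather than
guessed. Candidates are ranked frameshift > nonsense > missense >
synonymous > intronic > intergenic, ties broken by mutant-pool AF and
position.

## Segregation statistics and LD50

Goodness-of-fit tests use Pearson's statistic with no continuity
correction and upper-tail chi-square p-values; the uncorrected statistic
is what matches hand-computed family tables (e.g. 87:33 vs 3:1 gives
exactly 0.4). The inheritance classifier calls a line dominant only when
the M1 plant already showed the phenotype and the M2 family fits the 1:3
expectation at level `alpha` (default 0.05, a package decision), recessive
when the 3:1 fit holds, complex otherwise.

LD50 is estimated by pooling replicates per dose and linearly
interpolating the 50% crossing between the two bracketing doses, rather
than by probit/logit fitting — the estimand in this workflow is "which
tested treatment is closest to 50%", and interpolation answers it without
distributional assumptions. The dose-response simulator uses logistic
declines: germination `g(d) = g0 * plogis(g_slope (g_mid - d)) /
plogis(g_slope g_mid)` (normalized so `g(0) = g0` exactly) and seed-level
fertility `f(d) = plogis(f_slope (f_mid - d))`, which crosses 50% exactly
at `f_mid`; fertile counts are drawn conditionally on germinated counts
with probability `min(1, f/g)`.

## What the tests do and do not show

The simulator emulates the *statistical* structure of the design:
Mendelian segregation, Haldane recombination, binomial pooled counts, an
EMS-like spectrum, and a causal CDS deletion. Problem sizes used in the
checks: causal-locus recovery over 50 seeded replicates of the default
design, null calibration over 100 replicates with randomized phenotype
labels, type-I error over 5000 simulated families, Mendelian/Haldane
checks at 10,000 individuals, LD50 recovery over 200 tables. It does not
model read-level artifacts — mapping bias against the wild genome,
duplicated reads, indel-realignment errors, copy-number variation,
segregation distortion, or phenotyping error — so a pass here demonstrates
the analysis logic, not robustness to those failure modes. On real data
the wild-type band and `tau_mut` may need widening precisely because of
such artifacts, which is why every threshold is exposed in the
configuration.

## Numerical and degenerate-input conventions

Allele frequencies at zero depth are missing, never zero; windows with
fewer than `min_sites` usable sites carry missing summaries and break hit
runs. Duplicate positions on a chromosome are an error (upstream callers
deduplicate by letting induced sites take precedence over a colliding
marker). Region ranking is deterministic: run length, then lower
mutant-pool mean, then leftmost start on the natural chromosome order
(`chr2` before `chr11`). Writers emit LF line endings, fixed column
orders and `.` for missing values, so identical inputs and seeds give
byte-identical files; every stochastic function takes a local seed that
leaves the caller's RNG stream untouched.

## Known limitations

Single-transcript gene models only (no isoforms, UTRs or splice-site
effects); biallelic sites only; the CAPS feasibility check counts exact
recognition-site matches and ignores enzyme star activity and methylation
sensitivity; the inheritance classifier sees only two phenotype classes.
These match the scope of the workflow the package implements.
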