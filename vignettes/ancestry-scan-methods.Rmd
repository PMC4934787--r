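---
title: "Methods: windowed divergence ancestry scans and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence ancestry scans and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

## The problem

Wild *Saccharomyces eubayanus* comprises diverged populations (about 1%
apart in DNA sequence) plus a low-diversity Holarctic lineage that
contributed the *S. eubayanus* subgenome of allopolyploid lager-brewing
hybrids. Individual genomes can be mosaics of these sources: wild admixed
strains created by outcrossing and meiosis, and lager subgenomes that drew
different alleles from standing variation in the source lineage.
`hybridscan` locates those mosaic tracts, quantifies each source's
contribution, and computes the population-genetic statistics used to
characterize the source populations themselves.

## The scan statistic

All divergence work happens on a gap-masked alignment: any column with a
gap, missing call or ambiguity code in any strain is removed from the
analysis (`apply_gap_mask()`). Pairwise divergence *d* between two strains
in a window is the number of differing valid sites per valid site, in
non-overlapping windows of 50,000 bp by default — large enough that, at
roughly 1% between-population divergence, a window carries hundreds of
informative differences, and small enough to resolve meiotic-scale tracts.

For a query strain and two candidate source populations the scan computes,
per window, the *minimum* divergence between the query and any member of
each population, and the statistic

$$L(w) \;=\; \log_2 \frac{d_{\min}(\text{pop}_-, \text{query}; w)}
                         {d_{\min}(\text{pop}_+, \text{query}; w)}.$$

`L < 0` means some member of the negative-sign population is the query's
closest relative in that window; `L > 0` points at the positive-sign
population. Using the minimum rather than the mean makes the statistic a
nearest-relative test, robust to uneven within-population diversity. The
statistic is antisymmetric under swapping the populations and invariant to
a common rescaling of the divergences; both properties are asserted in the
test suite.

Numerical choices:

* **Zero-divergence floor.** A window where the query is identical to its
  closest relative would give $d_{\min} = 0$ and an infinite ratio; such a
  window substitutes half a difference, $0.5/n_\text{valid}$, keeping `L`
  finite while preserving ordering, and is flagged.
* **Window validity floor.** Windows with fewer than 20% (configurable)
  of the nominal window size in valid sites are masked rather than
  reported — thin data produce wild ratios.
* **Ties.** `L = 0` leaves a window unassigned; it contributes to neither
  ancestry fraction and never forms a breakpoint.

Breakpoints are called at every boundary between consecutive valid windows
of opposite sign, at the midpoint between the flanking window edges
(masked windows are skipped, so a breakpoint's uncertainty grows across
masked gaps). Ancestry fractions are assigned-window lengths summed per
side over the total assigned length.

## Permutation significance

The scan needs a null for "how large can |L| get when ancestry has no
local structure?". The package builds it by permutation: for the query
against all reference strains, the per-site difference-indicator columns
are shuffled uniformly across the valid positions of the genome, keeping
each window's valid-site count intact, and the windowed statistic is
recomputed; `B = 999` permutations by default. This preserves every
strain's genome-wide difference rate — and therefore the genome-wide mean
of `L` — while destroying the local clustering that real ancestry tracts
create.

Per window, the unbiased estimator $P(w) = (b(w)+1)/(B+1)$ is reported,
with $b(w)$ the number of that window's null values whose $|L|$ reaches
the observed $|L(w)|$; $P$ is therefore never 0 and never exceeds 1.
Side-specific significance thresholds come from the pooled null (all
windows, all permutations): the smallest value whose pooled unbiased
P-value is below `alpha` on each side. The default `alpha = 0.019` matches
the bound printed in the original analysis; because that choice likely
reflects a permutation count, `alpha` is a parameter, not a constant.
When the genome-wide ancestry balance is lopsided the null distribution of
`L` is itself off-center and a side's threshold can land on the "wrong"
side of zero; region calling therefore additionally requires the sign to
agree with the side being tested.

One practical note: with one query mostly descended from one source, the
per-window P-values are calibrated (type-I error at most `alpha` within
binomial error, asserted on non-admixed queries in the acceptance tests),
while the pooled thresholds act like genome-wide bands, which is how the
red significance lines in the original figures behave.

Region calls: `significant_regions()` merges maximal runs of contiguous
significant windows; given two queries it returns regions overlapping in
both (the "shared foreign tract" set). `discordant_regions()` reports runs
where two queries are confidently assigned to *different* sources (strict
tier: opposite signs, both significant). Its weak tier — windows whose `L`
uncertainty bands fail to overlap — needs an interval for `L`; the package
propagates each profile's across-strain divergence SD through the ratio,
$[\log_2\frac{\max(d^-_{\min}-s^-,\,\epsilon)}{d^+_{\min}+s^+},\;
\log_2\frac{d^-_{\min}+s^-}{\max(d^+_{\min}-s^+,\,\epsilon)}]$. That
interval is a deliberate overestimate of the uncertainty (it treats the
minimum as if it varied as much as the population spread), making the weak
tier conservative.

## The 20-SNP window classifier

As an orthogonal method, `fit_panels()`/`assign_query()` implement a
PCA-based local-ancestry classifier in windows of 20 consecutive SNPs
(biallelic, segregating, complete sites from `select_snps()`). Per window,
principal axes are fitted on the reference panels only — the query never
leaks into the fit, and querying a panel member is an error — and each
panel's centroid is stored. A query window is projected and scored by a
softmax of negative centroid distances, with temperature set to the
window's mean within-panel spread so that "confidence" compares
between-panel separation against within-panel noise. Calls below a 0.8
confidence floor are left unassigned, reproducing the published method's
"cannot infer" (white) state with a single interpretable knob. A
majority-vote smoother over 3 windows (ties keep the original call,
unassigned windows do not vote) stands in for HMM posterior smoothing;
it is transparent, idempotent on homogeneous tracks, and in simulation
never reduces window-level accuracy on tracts of 5+ windows.

The number of retained components defaults to 2 (capped by panel rank).
Missing query genotypes are tolerated up to 25% per window and imputed
with the window-local panel mean. Because the two methods partition the
genome differently (physical windows versus SNP-count windows), their
outputs are compared by majority vote within 50-kbp windows; at least 90%
agreement on simulated mosaics is part of the acceptance suite, matching
the "generally concordant, minor discrepancies expected" behavior of the
original pair of methods.

## Population-genetic statistics

`neutrality_tests()` computes Tajima's D, Fu & Li's D (with an outgroup)
or D* (without), Fu's Fs and Fay & Wu's H from their published formulas;
an "outgroup" here is a designated population whose consensus allele
polarizes derived states (sites without a clean consensus are excluded
from polarized statistics). The label "Fu's F" is ambiguous in parts of
the literature; this package defaults to Fu's Fs (via the Ewens sampling
distribution of haplotype counts) and exposes Fu & Li's F/F* behind
`fs_variant = "fu_li_F"`. π is computed as the mean pairwise per-site
difference with gaps deleted per pairwise comparison; the test suite
checks it against the unfolded-SFS formula to 1e-10, and all neutrality
statistics against independent direct-from-definition oracles on dozens of
random fixtures.

Fst uses Hudson's estimator as a ratio of averages (sum of per-site
numerators over sum of denominators), which is robust to unequal sample
sizes; the raw value is recorded alongside a zero-clamped one. TN93
distances use the closed form with empirical base frequencies estimated
from each pair at its shared valid sites (pairwise gap deletion);
saturated pairs return missing with a flag. The ABBA-BABA D statistic uses
population allele frequencies with outgroup-consensus polarity and a
delete-one block jackknife (50-kbp blocks, SE reported only with ≥ 20
non-empty blocks); `f4_ratio()` implements the standard
$f_4(A,O;X,C)/f_4(A,O;B,C)$ admixture-proportion estimator.

Copy-number profiling normalizes per-1-kbp window depths by the strain's
genome-wide median, anchors the chromosome with the lowest mean normalized
coverage at one copy (ties broken by chromosome order; exact .5 rounds
up), and reports windows deviating by more than 0.4 copies from their
chromosome's call as unsmoothed candidate CNV segments. Depth is ingested
from a TSV (`strain, contig, start, end, depth`) rather than BAM, keeping
the package free of alignment-file dependencies; such a table is one
`samtools depth`/`bedtools coverage -mean` invocation away from a BAM.
No subtelomeric mask is applied to heterozygosity windows by default:
shared high-heterozygosity windows near chromosome ends are a known
false-positive mode of reference-based calling and should be judged per
dataset.

## The synthetic-data generator

Every claim above is validated against simulations with complete truth
files, so the generator is first-class, tested code. It emulates the
study system's structure:

* Populations sit on a user-specified lineage tree; each founder accrues
  fixed differences from its parent at a configured per-site rate under
  infinite sites (every mutation hits a fresh position).
* Within-population variation follows a neutral SFS on a star-like
  genealogy approximation: derived-allele counts are drawn with
  probability ∝ 1/i and assigned to uniform carrier subsets, with the
  segregating-site count set to `round(pi * L * a1)` so the SFS-expected
  π equals the target. This gives controlled π, divergence and SFS shape
  without genealogical realism — Tajima-type statistics on its output are
  centered but their sampling variance is not coalescent-calibrated, and
  between-population sharing of polymorphism (incomplete lineage sorting)
  is absent; nulls that need shared standing variation are built by
  splitting one simulated population into groups.
* The default configuration is the desk-scale study system: four 500-kbp
  chromosomes; two populations at 1% fixed divergence with π targets
  0.0035 and 0.0027; and a low-diversity lineage (overall π near 0.002)
  hanging off the second population, split 0.002 into a larger and a
  smaller sublineage (four and two strains). Six strains per population
  is a realistic panel for this kind of survey and keeps a B = 999
  permutation scan around half a minute.
* Admixed mosaics alternate donors at every crossover (as one round of
  meiosis does), with exponential tract lengths whose donor-specific
  scales keep the expected contribution of the second donor at the target
  fraction `f`; a minimum tract length can be enforced by redraw when the
  experiment calls for tracts of a given minimum size. A small
  query-private substitution rate (5e-4 by default) models the fact that
  the sampled donors are relatives, not parents, of the query — without
  it the query is byte-identical to a panel strain and every window hits
  the zero floor.
* Lager-like pairs are mostly background-sublineage genomes with
  implanted foreign tracts: shared regions drawn from the second
  sublineage in both queries, discordant regions alternating between the
  queries. Per-window read depths are Poisson around
  `base_depth × ploidy` per chromosome, and heterozygous flags are
  injected uniformly outside implanted regions, so copy-number and
  heterozygosity profiling can be scored exactly.

Identical configs and seeds reproduce FASTA and truth outputs
byte-for-byte; the truth tables (tracts, crossovers, fractions, implanted
regions, ploidies, realized summary statistics) suffice to score every
scan and classifier output without rerunning the simulator.

What passing these simulations does *not* show: robustness to alignment
error, reference bias, recombination within source populations, selection,
or coalescent variance in tract lengths — real data carry all of these.

## Coordinates and interfaces

Internally, all coordinates are 1-based inclusive (the R/Bioconductor
convention), which keeps window arithmetic aligned with the tabular
reports; BED emission converts to 0-based half-open, and every TSV report
carries a header naming its conventions. The package's interface is its
functions: each analysis step takes and returns tibbles (or small S3
wrappers around them with `tidy()`/`glance()`/`autoplot()` methods), so a
whole analysis chains with the pipe, and `run_pipeline()` orchestrates
simulate → scan → classify → stats → cnv from one config with a JSON run
manifest (seeds, input checksums, per-stage outputs) for reproducibility.

## Worked example

```{r example, fig.width = 7, fig.height = 3, eval = FALSE}
sim <- sim_config(seed = 1) |> simulate_populations() |>
  simulate_admixed("PopA", "PopB", f = 0.42, tract_scale = 100000,
                   seed = 2)
gm <- apply_gap_mask(sim$gm)
scan <- scan_genome(gm, sim$popmap, "admixed_1", "PopA", "PopB",
                    B = 999, alpha = 0.019, seed = 3)
glance(scan)
detect_breakpoints(scan)
autoplot(scan)
```

The chunk above is not evaluated during package build only to keep
installation light; `scripts/acceptance.R` runs the same computations (and
more) end to end, and the README shows its printed output.
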