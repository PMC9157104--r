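---
title: "Differentiation mapping with poolscan: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiation mapping with poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem and the design

Pooled whole-genome sequencing (pool-seq) estimates population allele
frequencies from the read counts of a single library built from many
individuals' DNA in equimolar proportion. When two pools are defined by a
phenotype contrast, loci influencing the phenotype should show elevated
allele-frequency differentiation between them. The design `poolscan`
targets goes one step further: the classic confounder in such scans is a
known major gene, so the two contrasted pools are built from individuals
with the *same* genotype at the major locus but *different* phenotypes
(in the motivating stickleback system: completely versus partially plated
fish that are all heterozygous at the major plate locus). Any residual
differentiation peak then points at a modifier locus rather than at the
major gene. A second scan, between pools homozygous for alternative major
alleles, acts as a positive control: it must light up the major locus
region at complete differentiation.

## The statistic and the per-SNP pipeline

Differentiation is the absolute allele frequency difference,
`AFD = 0.5 * sum(|f1 - f2|)` over the pools' allele-frequency vectors
(`compute_afd()`), equal to `|p1 - p2|` at a biallelic SNP and ranging
from 0 to 1. It is purely descriptive: no evolutionary model, no
significance machinery — candidate loci are taken by rank.

Per site, the pipeline (`run_scan()`):

1. **Biallelic calling** (`call_biallelic()`). Counts of the two pools are
   summed; the two highest-count bases become major/minor. Any third base
   above `error_floor` (default 0.01) of the combined depth rejects the
   site: a true third allele makes the biallelic AFD orientation
   ill-defined, and at pool-seq depths a >1% third base is far above the
   sequencing-error expectation. Reads at non-retained bases are dropped,
   so depths and frequencies are always over the two retained alleles.
   Ranking ties break by fixed base order (A<C<G<T), which is arbitrary
   but deterministic; AFD is unaffected because it is symmetric in the
   allele labelling.
2. **Filters** (`passes_filters()`). Depth within `[depth_min, depth_max]`
   in *both* pools, bounds inclusive (defaults 40–130×; the upper bound
   excises collapsed repeats, the lower bound limits binomial noise), and
   pooled minor-allele frequency at least `maf_min` (default 0.2),
   computed from the *summed read counts* of the two pools rather than
   the mean of the two frequencies — counts are the raw observable, and a
   count-weighted MAF does not over-credit the shallower pool. The MAF
   comparison is done on re-derived integer counts so boundary cases
   (exactly 0.2) are exact, not floating-point accidents.
3. **Median**. The genome-wide median AFD of retained SNPs is reported as
   a background-differentiation summary; for even counts the lower median
   is taken, keeping the value an observed AFD.

## Windows, top SNPs, regions

`smooth_windows()` averages per-SNP AFD in windows of `width` = 40 kb
sliding by `step` = 20 kb, requiring `min_snps` = 6; the mean is
unweighted across SNPs. Windows are anchored at position 1 of every
chromosome, which makes outputs reproducible without a genome index; as
chromosome lengths are unknown from a SNP table, terminal windows keep
nominal width and may overhang the last SNP. Windows are only
materialized where SNPs exist — a windowless stretch contributes nothing
either way because empty windows can never meet `min_snps`.

`top_snps()` returns the `k` = 10 highest-AFD SNPs; ties break by genomic
order with a logged note (rank thresholds have no principled tie rule).
`candidate_regions()` merges top SNPs within `cluster_gap` = 20 kb into
clusters anchored at the midpoint of the outermost members, spans
`anchor ± span/2` (default span 180 kb), clips at position 1, and merges
overlapping regions. `annotate_regions()` then reports every gene
overlapping a region by at least 1 bp — inclusive overlap is the safer
convention for candidate discovery, where missing a boundary-straddling
gene is the costlier mistake — and `flag_keywords()` marks genes whose
name or attribute text contains any of the configured keywords
(case-insensitive substring; defaults `bone`, `ectoderm`,
`tumor necrosis factor`, `wnt`). Keyword flagging deliberately replaces
manual database lookups; it is exactly as good as the supplied annotation
text.

## The Monte-Carlo Hardy–Weinberg deviance test

For a validation panel of `n` diploids genotyped at one SNP, the statistic
is `D = sum((obs_g/n - exp_g)^2)` over the three genotype classes against
Hardy–Weinberg expectations at population frequency `p`. D is computed on
*frequencies*, making it invariant to panel size scaling. The null is
simulated: each random panel gives every individual two independent
Bernoulli(`p`) alleles — implemented as one trinomial draw per panel,
which is the same distribution — and `D` is recomputed (`n_iter` = 9,999
default). The p-value is the add-one estimator
`(1 + #{D_null >= D_obs}) / (1 + n_iter)`, which cannot be zero; the
percentile reported alongside is `100 * #{D_null < D_obs} / n_iter`, so
`p ≈ 1 - percentile/100` up to the probability mass tied exactly at the
observed deviance (genotype counts are discrete, so ties are possible).
Because D is non-negative and grows with departure from HWE in *any*
direction, only the upper tail is informative; the result records
`tail = "upper"`. The add-one estimator makes the test slightly
conservative; the calibration acceptance test (KS distance of null
p-values from uniform) bounds the practical effect.

## What the simulator states, and what it does not

`sim_config()` encodes the emulated study as defaults; these are the
stated world of the acceptance tests and are not tuned:

| parameter | default | why |
|---|---|---|
| `n_individuals` | 186 | the phenotyped-and-assigned sample size |
| `freq_major_low` | 0.39 | low-allele frequency implied by the observed 186-fish genotype counts (2·23 + 99 of 372 chromosomes) |
| `freq_modifier_partial` | 0.583 | the natural-population partial-allele frequency used for the validation panel |
| `penetrance` (PP/PC/CC) | 0.9/0.5/0.1 | "strong modifier" illustration; the real penetrance is unknown, only group sizes are published |
| `n_neutral_snps` | 49,998 | ~50,000 sites total, desk-scale |
| `chrom_length` | 1 Mb ×2 | one chromosome per causal locus; SNP density ~1/40 bp is high, deliberately giving well-populated windows |
| `causal_positions` | 500 kb | mid-chromosome, away from window-anchoring edge effects |
| `ld_length` | 10 kb | copy probability r(d) = exp(−d/L); gives near-complete linkage within a few kb and background by 50 kb, enough to form a window-scale peak |
| `depth_per_pool` | 65/71/118/100× | the four libraries' median depths |
| `error_rate` | 0.003 | the stated instrument error bound |
| `plate_medians` | 47/39/2 | published morph-wise median plate counts (Poisson means; decorative) |
| `background_freq_range` | U(0.05, 0.95) | flat, avoiding exact fixation of background sites; a Beta would be more realistic but adds a shape parameter the analysis never sees |

Genotypes at both loci are drawn from HWE; morphs are deterministic for
major-locus homozygotes (LL → low, CC → complete), matching the observed
pattern and kept absolute for clean truth tables; heterozygotes are
partial with probability `penetrance[modifier genotype]`.

Linkage uses an exponential-decay copying rule: at distance `d` from its
chromosome's causal SNP, each chromosome carries the causal allele state
with probability `r(d)` and otherwise an allele at the site's background
frequency `q`. Implementation note: pooled read counts depend on a site's
*pool allele count* only, so the per-haplotype rule is realized as its
exact group-level binomial equivalent,
`Binom(m1, r + (1−r)q) + Binom(H − m1, (1−r)q)` for a group with `m1` of
`H` chromosomes in causal state 1 — the observable distribution is
identical and no haplotype matrix is needed. The expected frequency
contrast between groups at a linked site is `r ×` (causal contrast),
which is what makes the modifier peak window-detectable; the closed-form
causal contrast implied by the penetrance table is exported as
`expected_modifier_contrast()` and checked against simulation.

What the generator does **not** emulate: recombination maps and
coalescent LD structure (cross-site correlations within a pool are not
realistic, only the site-marginal distributions are), demography and
selection, mapping/alignment artifacts, base-quality structure, indels
beyond count pass-through, and reference bias. A green parameter-recovery
test therefore establishes that the scan machinery finds a
window-scale differentiation peak of the size the stated world implies —
not that the pipeline is robust to alignment pathologies of real data.

## Numerical and degenerate-input choices

- Coordinates are 1-based closed everywhere (mpileup, sync, GFF3 all are);
  no 0-based conversion exists in the package.
- A pool with zero reads at the two retained alleles yields `NaN`
  frequency; such SNPs are dropped by any depth filter with
  `depth_min ≥ 1` rather than erroring.
- "Fixed" in `fixed_snp_panel()` means AFD exactly 1; frequencies are
  integer-count ratios, so 0 and 1 are exact in floating point and the
  comparison is safe.
- `high_afd_panel()` orients each SNP's focal allele as the one more
  frequent in the reduced-plating pool; at an exact 0.5 the minor allele
  is taken deterministically (a 0.5 in the reduced pool *can* co-occur
  with AFD ≥ 0.35 when the other pool is ≤ 0.15).
- Empty inputs return empty, correctly-typed tables; configuration
  mistakes (inverted depth bounds, `width < step`, non-multiple
  width/step) raise classed configuration errors that the CLI maps to
  exit code 2, malformed files to exit 3.
- RNG: every stochastic entry point takes a `seed` and restores the
  caller's RNG state, so library calls never perturb user-level
  reproducibility; identical seeds give bit-identical outputs.

## Known limitations

- The scan is two-pool; the general half-L1 AFD is available for
  multi-pool frequency vectors, but calling/filtering are pairwise.
- No FST or model-based differentiation statistics, no outlier
  significance — ranking is the contract.
- `read_mpileup()` ignores base and mapping qualities (a plain pileup
  tally) and processes sites in R; it is meant for fixtures and modest
  files, with `sync` as the bulk format.
- The annotation keyword screen inherits every bias of the annotation's
  free-text attributes.
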