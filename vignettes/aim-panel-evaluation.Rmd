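---
title: "How many markers does genome ancestry need? Methods and design of aimeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many markers does genome ancestry need? Methods and design of aimeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimeval)
library(dplyr)
```

## The question the package answers

Panels of ancestry-informative markers (AIMs) — from a dozen to a few
hundred SNPs — are widely used to estimate the biogeographical ancestry of
individual genomes in forensic, biomedical and anthropological work. The
question `aimeval` operationalises is: *how accurate is an ancestry
estimate from a reduced SNP panel, compared with the ancestry measured from
a genome-scale marker set, and how does that accuracy depend on panel size
versus per-marker informativeness?*

The package answers it by simulation. It generates structured genotype
data with known truth, estimates individual admixture proportions under
the standard likelihood model, scores markers by their informativeness,
and runs the resampling experiments that quantify how estimates degrade as
panels shrink.

## The admixture model

Individual $i$ carries genotype $g_{il} \in \{0, 1, 2\}$ copies of the
reference allele at locus $l$. With $K$ ancestral populations whose
reference-allele frequencies are $f_{kl}$, and individual ancestry
proportions $q_{ik}$ on the probability simplex, each allele copy is an
independent draw from the mixture $p_{il} = \sum_k q_{ik} f_{kl}$, so

$$\ell_i(q) = \sum_l \left[ g_{il} \log \textstyle\sum_k q_{ik} f_{kl}
 + (2 - g_{il}) \log \sum_k q_{ik} (1 - f_{kl}) \right].$$

The assumptions are the usual ones: Hardy–Weinberg equilibrium within
ancestral populations, linkage equilibrium across loci, and known $K$.
Missing genotypes drop out of the sum, so each individual is scored over
its called loci only.

Two estimation modes are provided:

* **Supervised** (`supervised_ancestry()`): $f_{kl}$ fixed from labelled
  reference samples (`estimate_frequencies()`); each individual's $q$ is
  maximised independently.
* **Unsupervised** (`unsupervised_admixture()`): $Q$ and $F$ estimated
  jointly from unlabelled data, from a seeded random start (Dirichlet(1)
  rows for $Q$, Uniform(0.05, 0.95) for $F$). Cluster labels are arbitrary;
  `align_clusters()` resolves label switching by exhaustive assignment on
  the population-by-cluster mean-membership matrix.

### Numerical approach

Both modes use the multiplicative EM update for this likelihood, which
stays on the simplex exactly and never decreases the log-likelihood.
Around the EM map we apply safeguarded squared extrapolation (the SQUAREM
scheme): two EM steps give an extrapolation direction, the step length is
backtracked toward the plain EM step whenever it would leave the parameter
space, and an extrapolated proposal is accepted only if it does not lose
likelihood against the previous cycle (the fallback being the plain double
EM step). Fixed points — and therefore the estimates — are exactly those
of EM, but genome-scale fits converge in tens rather than hundreds of
iterations, which is what makes the 100-replicate resampling experiments
below practical. The recorded log-likelihood trace is non-decreasing by
construction; the test suite asserts this on every fit it makes.

Further numerical choices, each of which matters somewhere:

* **Frequency clamp.** Estimated and fitted frequencies are clamped to
  $[10^{-6}, 1 - 10^{-6}]$ so the log-likelihood stays finite at loci fixed
  in a sample.
* **Convergence.** Relative log-likelihood change below `tol` (default
  $10^{-6}$) or `max_iter` (default 2000). Cross-validation refits use a
  looser default (`tol` $10^{-5}$, `max_iter` 500): the held-out squared
  error they feed is an average over thousands of masked entries and is
  insensitive to the last increments of log-likelihood.
* **Simplex pinning.** $Q$ rows are renormalised every iteration. Using
  $1 - \sum_k q_{ik} f_{kl}$ for the non-reference mixture is only exact on
  the simplex, and without renormalisation rounding drift compounds
  geometrically over hundreds of iterations.
* **Degenerate inputs.** An individual with no called genotype gets a
  uniform ancestry row and a warning; a locus uncalled in a whole reference
  population gets frequency 0.5 and a warning; `K = 1` returns its closed
  form.

### Choosing K by cross-validation

`cross_validation_error()` partitions the non-missing genotype *entries*
(not individuals) into folds, refits the unsupervised model with each fold
masked, and scores the held-out entries by squared deviation from their
fitted expectation $2\sum_k \hat q_{ik} \hat f_{kl}$. Entry-wise masking
matches the idea of predicting held-out genotypes from the structure
learned off the rest; squared-error is our choice of prediction loss (the
procedure's originators name the method but not the loss). `choose_k()`
shares one fold partition across all candidate $K$ and returns the
minimiser, breaking ties toward smaller $K$. On the three-population
simulation below, $K = 3$ is selected essentially always; the error rises
again for $K > 3$ because extra clusters fit noise frequencies estimated
from fewer effective individuals.

## The synthetic study system

`sim_config()` encodes the study conditions; its defaults are the
conditions everything else is calibrated to:

| parameter | default | meaning |
|---|---|---|
| `K` | 3 | source populations (continental stand-ins) |
| `n_per_pop` | 50 | diploid individuals per population |
| `L` | 5000 | biallelic loci (scaled per experiment) |
| `divergence` | 0.15 | Balding–Nichols drift per population |
| `maf_range` | (0.05, 0.95) | ancestral frequency window |
| `missing_rate` | 0 | per-entry missingness probability |

Population frequencies follow the Balding–Nichols model: ancestral
frequency $p_l \sim U(\text{maf\_range})$, then
$p_{kl} \sim \mathrm{Beta}\!\big(p_l \tfrac{1-F_k}{F_k},
(1-p_l)\tfrac{1-F_k}{F_k}\big)$, which has mean $p_l$ and variance
$F_k\,p_l(1-p_l)$. This is the standard drift model and matches the
admixture likelihood's own assumptions. `divergence = 0.15` per population
produces the strong differentiation characteristic of African / East
Asian / European reference groups (realized pairwise $F_{ST} \approx
0.25$); setting it near 0.01 emulates closely related populations (two
East Asian groups, say) for which small panels lose power — the test
suite exercises both regimes.

**Admixed genomes.** `make_aa_genomes()` builds artificial admixed
("AA") genomes: for each hybrid, loci are partitioned at random into $K$
sets sized by largest-remainder rounding of the target proportions (ties
to the lower population index, for determinism), and each set is copied
from one donor individual drawn from the corresponding population. One
donor per population per hybrid is the simplest scheme satisfying the
expected-ancestry contract (a fresh donor per locus would too; either
way the expected ancestry equals the target proportions). Copying is at
the genotype level — the generator does not phase haplotypes.

**What the generator does *not* emulate** — and hence what passing tests
do and do not show about real data: linkage disequilibrium (loci are
independent, so there are no ancestry tracts and effective marker counts
in real genomes are smaller than nominal), ascertainment bias in SNP
discovery, genotyping error, related individuals, and continuous clines
rather than discrete source populations. Results here quantify sampling
noise of panel-based estimators under the model's own assumptions; real
panels can only do worse.

## Marker informativeness: F_ST and LSBL

`pairwise_fst()` implements the Weir & Cockerham (1984) two-population
$\theta$ per locus, with the overall value as the ratio of summed variance
components. We chose this estimator because it is the field standard and
sample-size aware; the workflow it feeds originally drew $F_{ST}$ values
from public browsers without naming an estimator. Negative per-locus
estimates (pure sampling noise around zero differentiation) are reported
as computed.

The locus-specific branch length (LSBL) decomposes the three pairwise
distances among populations $a, b, c$ onto the unrooted 3-taxon tree:
$\mathrm{LSBL}_a = (d_{ab} + d_{ac} - d_{bc})/2$, cyclically. Branches are
clamped at zero (tree branch lengths are nonnegative) with a flag so
diagnostics can count affected loci; pre-clamp values are kept in the
`raw` attribute and reassemble the $d$'s exactly. `panel_lsbl_summary()`
reports accumulated (summed) and average (accumulated / panel size) LSBL
per branch; `select_aims_lsbl()` builds balanced panels greedily — always
add the best unused locus for the branch currently furthest behind —
which keeps per-branch accumulated values within one locus's contribution
of each other. The greedy rule (with index tie-breaking) is our
deterministic stand-in for multi-step balanced-LSBL selection procedures,
whose published descriptions underdetermine the algorithm.

## The evaluation experiments

All experiments estimate ancestry in supervised mode by default —
reference frequencies are known (estimated from the labelled simulated
populations), which isolates the effect of panel size from the extra
variance of joint estimation. Unsupervised estimates can be substituted,
followed by `align_clusters()`, where label-free behaviour matters.

* `genome_ancestry_reference()` — supervised ancestry from *all* loci; the
  truth proxy every panel is compared against.
* `rsnp_resampling()` — for each panel size, repeatedly (default 500
  replicates) draw that many random SNPs ("rSNPs"), re-estimate, and record
  per replicate the population mean of the focal component (own-population
  membership; for hybrid groups, every component). Summaries across
  replicates: mean, SD, percentile 95% interval (2.5–97.5; the replicate
  distribution is the natural object here, and no parametric form is
  assumed), min–max. Summarising at the replicate level — not pooling
  individuals — is forced by the boundary case: a "panel" equal to all
  loci must show zero sampling variability.
* `evaluate_panel()` — a single fixed panel: summaries across the
  individuals of each population, with the effective (intersected) panel
  size and the count of panel loci absent from the data.
* `panel_error()` — per ancestry component, the RMS deviation of panel
  estimates about the reference values: an "SD about the reference", which
  is the quantity that measures *error* rather than mere spread. The
  centred SD is reported alongside as a diagnostic.
* `sample_size_experiment()` — precision of *population-level* ancestry
  versus sample size: after the 90% call-rate filter, draw (default 1000)
  sub-samples of 5, 10, …, 40 profiles without replacement and report the
  mean of the draw means with the percentile (2.5, 97.5) interval.
* `size_error_correlation()` — Pearson correlation between panel size and
  error, per component and pooled; degenerate (constant) inputs are
  flagged rather than failed.

## IBS and principal coordinates

`ibs_matrix()` scores each pair of individuals by shared alleles over
jointly called loci (both shared = 1, one shared = 0.5, none = 0); pairs
with fewer than 10 joint calls are flagged. `pca_from_ibs()` applies
classical metric MDS (`stats::cmdscale`) to $1 - S$ — double-centring plus
eigendecomposition, which is what "two-dimensional PCA on IBS values"
means operationally in PLINK-style workflows. Axis signs are fixed so the
largest-magnitude loading is positive, making coordinates reproducible.

## Problem sizes and runtimes

The shipped test suite runs the full pipeline at sizes chosen to finish in
minutes on one core while preserving every qualitative regime: 50
individuals per population throughout; 20,000 loci for the genome-scale
reference and the panel-degradation chain (10,000 → 10 SNPs, 100
replicates per size; the locus pool is kept at twice the largest panel so
that even the 10,000-SNP panels are true subsamples); 2,000 loci for the
cross-validation scan over $K = 1..5$; 5,000 loci with 1,000-SNP random
panels for hybrid-genome recovery; 1,000 bootstrap draws per window for
the sample-size experiment. The headline replicate counts (500 resamples,
1,000 sub-samples) remain the defaults of the corresponding functions.

## Interface conventions

Genotypes live in a matrix-backed container (`genotype_matrix`) — an
$N \times L$ integer matrix with `NA` as the missing sentinel (never 0,
which is a valid genotype), sample/locus identifiers and population
labels — because every computation on genotypes is matrix algebra and
$L$ runs to tens of thousands. Everything a user analyses or plots,
however, comes back as a tibble (evaluation summaries, error reports,
F_ST/LSBL tables, PCA coordinates), pipes cleanly, and has a plot
companion (`autoplot()` on fits, `plot_eval_summary()`,
`plot_error_vs_size()`, `plot_size_experiment()`, `plot_pca()`); fitted
objects support `tidy()` and `glance()`.

File formats: PLINK PED/MAP text and a TSV genotype matrix
(`read_genotypes()` / `write_genotypes()`), panel files as one locus ID
per line with `#` comments (`read_panel()`). Genotypes are recoded as
counts of the first allele seen per locus in file order — a deterministic
convention under which any consistent coding yields identical likelihoods
up to relabelling. One consequence, documented rather than hidden: a
matrix whose first called sample at some locus is homozygous-alternate is
not expressible in the PED dialect's stable domain; one write/read cycle
reaches that domain, after which PED round-trips are exact (the TSV
dialect round-trips everything exactly).

## A worked run

```{r worked, eval = FALSE}
cfg <- sim_config(L = 5000, K = 3, n_per_pop = 50, divergence = 0.15,
                  seed = 1)
d <- simulate_dataset(cfg)
freqs <- estimate_frequencies(d$genotypes)
ref <- genome_ancestry_reference(d$genotypes, freqs)

res <- rsnp_resampling(d$genotypes, freqs,
                       panel_sizes = c(2000, 500, 100, 10),
                       n_reps = 100, seed = 2)
res %>% filter(group == ancestry) %>% group_by(panel_size) %>%
  summarise(mean = mean(mean), sd = mean(sd))
plot_eval_summary(res)
```

The SD column grows monotonically as the panel shrinks — the package's
central, repeatedly tested result: the reliability of genome-ancestry
estimates is driven first by the *number* of markers, and only secondarily
by their individual informativeness.

## Known limitations

* No linkage: effective marker numbers for real (correlated) panels are
  smaller than nominal, so real-data errors at a given panel size will be
  at least those simulated here.
* $K$ is assumed known in supervised mode; misspecified reference panels
  ("lack of portability") are not modelled.
* No standard errors on individual $q$; the resampling experiments
  quantify panel-induced variability instead.
* Unsupervised fits use a single random start by default; multi-modal
  likelihoods at large $K$ may want `n_starts > 1`.
* Binary PLINK (.bed), VCF and multi-allelic loci are out of scope for the
  IO layer.
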