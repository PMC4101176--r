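# aimeval

**How many SNPs does it take to measure genome ancestry?**

Panels of ancestry-informative markers (AIMs) — a dozen to a few hundred
SNPs with skewed frequencies between continental groups — are routinely
used to estimate the biogeographical ancestry of individual genomes in
forensic casework, direct-to-consumer testing, admixture mapping and
population studies. `aimeval` is a simulation-and-resampling toolkit for
quantifying how reliable such estimates actually are: it compares
panel-based ancestry estimates against a genome-scale reference and
decomposes the error into the part driven by panel *size* and the part
driven by per-marker *informativeness*.

It is aimed at statistical geneticists who design or audit AIM panels,
and at anyone who needs a defensible answer to "is 46 markers enough?"

## What's inside

**The model.** Individual ancestry proportions $q_{ik}$ are estimated by
maximum likelihood under the standard admixture model: genotype
$g_{il} \sim \mathrm{Binomial}(2,\; \textstyle\sum_k q_{ik} f_{kl})$ with
$f_{kl}$ the ancestral reference-allele frequencies, assuming
Hardy–Weinberg within sources and linkage equilibrium. Both supervised
(fixed $F$ from labelled references; `supervised_ancestry()`) and
unsupervised (joint $Q, F$; `unsupervised_admixture()`) modes are
implemented as simplex-exact multiplicative EM with safeguarded SQUAREM
acceleration, plus entry-wise cross-validation to choose the number of
clusters (`choose_k()`).

**The simulator.** Balding–Nichols source populations
($p_{kl} \sim \mathrm{Beta}$ around an ancestral frequency with drift
$F_k$; `simulate_dataset()`), artificial admixed "AA-genomes" built by
copying random locus sets from per-population donors in exact target
proportions (`make_aa_genomes()`), and controllable missingness.

**Marker informativeness.** Per-locus Weir–Cockerham $F_{ST}$
(`pairwise_fst()`), locus-specific branch lengths
$\mathrm{LSBL}_a = (d_{ab}+d_{ac}-d_{bc})/2$ (`lsbl_table()`), panel
summaries of accumulated/average LSBL (`panel_lsbl_summary()`) and greedy
LSBL-balanced panel selection (`select_aims_lsbl()`).

**The experiments.** Random-SNP panel resampling across sizes
(`rsnp_resampling()`), fixed-panel evaluation (`evaluate_panel()`), RMS
error against the genome-wide reference (`panel_error()`), population
sub-sampling curves (`sample_size_experiment()`), size–error correlation
(`size_error_correlation()`), and IBS-based principal-coordinate maps
(`ibs_matrix()`, `pca_from_ibs()`). Results come back as tibbles with
`plot_*()`/`autoplot()` companions; PLINK PED/MAP and TSV genotype files
are read and written natively.

## A worked example

Three differentiated source populations (drift 0.15, 50 individuals
each, 2,000 SNPs), a genome-wide reference, and random panels of
decreasing size:

```r
library(aimeval)
library(dplyr)

cfg <- sim_config(L = 2000, K = 3, n_per_pop = 50, divergence = 0.15,
                  seed = 1)
d     <- simulate_dataset(cfg)
freqs <- estimate_frequencies(d$genotypes)
ref   <- genome_ancestry_reference(d$genotypes, freqs)
glance(ref)
#> # A tibble: 1 × 6
#>   mode           n     k   loglik n_iter converged
#>   <chr>      <int> <int>    <dbl>  <int> <lgl>
#> 1 supervised   150     3 -274167.     27 TRUE

res <- rsnp_resampling(d$genotypes, freqs,
                       panel_sizes = c(1000, 250, 50, 10),
                       n_reps = 50, seed = 2)
res %>%
  filter(group == ancestry) %>%          # own-population membership
  group_by(panel_size) %>%
  summarise(mean_pct = 100 * mean(mean), sd_pct = 100 * mean(sd),
            ci_width_pct = 100 * mean(ci_high - ci_low))
#> # A tibble: 4 × 4
#>   panel_size mean_pct sd_pct ci_width_pct
#>        <dbl>    <dbl>  <dbl>        <dbl>
#> 1         10     76.3  8.76        33.2
#> 2         50     91.6  1.70         6.25
#> 3        250     97.0  0.492        1.86
#> 4       1000     99.0  0.151        0.525
```

Read: with 1,000 random SNPs each population recovers ~99% of its own
ancestry and 50 resampled panels agree to ±0.15 percentage points; with
10 SNPs the mean collapses to 76% and panels disagree by almost 9
points — panel size, not marker pedigree, dominates reliability.

Admixed genomes built from equal thirds of the three sources are
recovered near the expected 33.3% per component from a 500-SNP random
panel:

```r
aa <- make_aa_genomes(d$genotypes, 30, seed = 3)   # equal thirds
set.seed(4)
fit_aa <- supervised_ancestry(subset_by_panel(aa, sample(aa$loci, 500)),
                              freqs)
round(100 * colMeans(fit_aa$Q), 1)
#> POP1 POP2 POP3
#> 32.5 33.0 34.5
```

`plot_eval_summary(res)`, `plot_error_vs_size()`, `plot_size_experiment()`
and `plot_pca()` turn these tables into the standard figures; see the
vignette (`vignettes/aim-panel-evaluation.Rmd`) for the model,
design decisions and the limits of what the simulations show.

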