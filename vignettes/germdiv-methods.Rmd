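---
title: "Models and methods behind germdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind germdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdiv)
```

`germdiv` characterizes a crop germplasm collection from two data sources:
a replicated incomplete-block field trial scoring quantitative traits, and
a panel of codominant SSR markers on the same genotypes. This vignette
documents the statistical models, the choices that were genuinely open and
how they were settled, and what the synthetic-panel generator does and does
not emulate.

## The field-trial model

Each trait is analyzed with the random-genotype mixed model

$$Y_{ijk} = \mu + \mathrm{Gen}_i + \mathrm{Block}(\mathrm{Rep}_j)_k + \varepsilon_{ijk},$$

fitted by REML with genotype and block-within-replicate as independent
random effects. Treating genotype as random is what makes BLUP shrinkage
and a variance-ratio heritability meaningful for a diversity panel: the
genotypes are viewed as a sample from the germplasm of interest, not as a
fixed set of treatments. Replicates contribute through their nested blocks
(a resolvable incomplete-block, alpha-lattice-type layout); missing plots
are dropped, not imputed, since REML handles unbalance natively.

Heritability is reported on a **plot basis**,
$H^2 = V_g / (V_g + V_{block} + V_e)$. The alternative entry-mean form
$V_g / (V_g + V_e / r)$ is larger for the same components; the plot basis
is the definition consistent with presenting $V_p$ as the simple sum of the
three components in a variance table, which is the convention this package
follows throughout. The genetic coefficient of variation is
$CV_g = 100\sqrt{V_g}/\bar{y}$; the grand mean defaults to the raw plot
mean (a BLUP-based intercept is available via `grand_mean_source`).

The genotype test compares the REML log-likelihoods with and without the
genotype term and refers twice the difference to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, the standard boundary correction for
testing a variance component against zero; an uncorrected $\chi^2_1$ would
be conservative by roughly a factor of two on the p-value scale.

Numerical choices: the REML fits run through `lme4` with optimizer
tolerances tightened to `xtol_abs = ftol_abs = 1e-14`, which makes the
estimates agree with the closed-form expected-mean-squares estimator to
better than $10^{-6}$ on balanced designs (the test suite checks 200 such
fits). One degenerate case is handled analytically: when every plot of a
genotype carries an identical value (the exact zero-residual limit) the
REML surface is flat in $V_g/V_e$ and any numerical optimizer stalls, so
the limit estimator — $V_g$ equal to the between-genotype variance of plot
values, $V_{block} = V_e = 0$ — is returned directly.

## Phenotypic diversity

BLUP means are min–max scaled to $[0, 100]$ and cut into ten equal-width
classes (half-open, final class closed). The Shannon–Weaver index is
$H = -\sum_i P_i \log_2 P_i$ over class proportions, with
$0 \log 0 \equiv 0$. The normalization is the one genuinely open choice
here: $H' = H / \log_2 n$ could use $n = 10$ (all classes) or $n$ = the
number of *occupied* classes. `germdiv` uses occupied classes. This makes
$H'$ a pure evenness measure — it equals 1 exactly when the occupied
classes are equifrequent regardless of how many there are — and it is the
reading consistent with published germplasm tables in which a trait with
three occupied classes at 2/60/38% carries $H \approx 1.10$ and
$H' \approx 0.69 = 1.10/\log_2 3$ (the all-class reading would give 0.33).
Frequencies that do not sum to one (integer-percent rounding) are
renormalized. Categories: high $H' \ge 0.60$, intermediate
$0.40 \le H' < 0.60$, low otherwise.

## Trait associations

Pearson correlations are computed on BLUP means (not plot values), with
two-sided t tests on $n - 2$ df. Partial correlations controlling all
remaining traits come from the standardized inverse correlation matrix,
$r_{ij\cdot rest} = -W_{ij}/\sqrt{W_{ii}W_{jj}}$; the suite verifies this
against regressing both traits on all others and correlating residuals (to
$10^{-10}$). Tests for partials use $n - 2 - g$ df with $g$ the number of
controlled traits. Near-singular correlation matrices are ridge-regularized
with $\varepsilon = 10^{-8}$ and flagged. No multiple-testing correction is
applied by default — the robust-pair analysis (significant under both
marginal and partial tests) is itself the guard against spurious marginal
hits — but a Benjamini–Hochberg option exists.

## PCA, clustering, MGIDI

PCA standardizes traits to unit variance first, so eigenvalues sum to the
trait count and "percent of variance" has its usual meaning. Clustering is
Ward linkage on the retained PC coordinates (eigenvalue $\ge 1$ by
default). When `k = "auto"`, k maximizes the relative drop of
within-cluster inertia over $k = 2..10$ — a deliberately simple elbow rule,
since no principled k is implied by the analysis; k can always be set
directly. Clusters are characterized by v-tests,
$v = (\bar{x}_c - \bar{x}) / \sqrt{(s^2/n_c) \cdot (N - n_c)/(N - 1)}$,
computed on the source traits, and labels are canonicalized by decreasing
cluster size so repeated runs are comparable.

MGIDI follows the factor-analytic construction: (1) each trait is rescaled
to 0–100 with the axis inverted for "decrease" objectives, so 100 always
means desirable and the index is invariant to affine changes of trait
units; (2) factor analysis of the rescaled correlation matrix retains
eigenvalues $\ge 1$, varimax-rotates the loadings, and computes
regression-method scores $Z R^{-1} A$; (3) the ideotype (100 everywhere) is
projected the same way; (4) the index is the Euclidean distance to the
ideotype in factor space. A genotype holding the best observed value of
every trait scores exactly 0. The selected fraction defaults to 20%;
alternatively a reference genotype's own score can serve as the cut line,
selecting everything strictly better than the reference. Selection
differentials are reported in trait units and as percentages of the panel
mean, with an optional multiplication by per-trait $H^2$ for expected
gains.

## Marker statistics

Allele frequencies are counted over scored allele copies; missing calls
leave the denominators. Per locus: $N_e = 1/\sum p^2$, $He = 1 - \sum p^2$
(so $He = 1 - 1/N_e$ holds as an identity), Shannon information
$I = -\sum p \ln p$ in **nats** — the convention under which an
equifrequent biallelic locus shows $I = 0.69$, matching published SSR
tables — and observed heterozygosity as the heterozygous-call fraction.
PIC is reported in the simple frequency form $1 - \sum p_i^2$ and
additionally in a genotypic-class variant ($1 - \sum g_i^2$ over
genotype-pattern frequencies), because published SSR tables sometimes show
biallelic PIC above 0.5, which the frequency form cannot produce; the
variant makes both conventions available for comparison. Discriminating
power uses the confusion-probability complement
$D = 1 - \sum_i g_i (N g_i - 1)/(N - 1)$ over genotype patterns.
Rare alleles are censused at frequency $\le 0.05$; pooling them into one
synthetic class is opt-in, mirroring what some population-genetics formats
require. Band matrices convert to codominant calls as one band =
homozygote, two bands = heterozygote; genotypes with more than two bands
at a locus (possible with pooled DNA in a polyploid) are reduced to the
two panel-wide most frequent bands and flagged rather than dropped.

## Distance and trees

Jaccard dissimilarity on band profiles ignores joint absences — shared
absence of a band is not evidence of similarity for presence-scored data —
and is computed over pairwise-complete bands, flagging pairs with no
informative band. "Neighbor joining" means classical Saitou–Nei NJ with
equal taxon weights (exact on additive distances, which the suite verifies
on a 6-taxon tree metric); taxa are sorted lexicographically before
agglomeration so the tree is invariant to input order. Negative branch
lengths on non-additive data are clamped to zero and counted. Bootstrap
resamples band columns by default (resampling loci as blocks is an
option), rebuilds the tree, and reports bipartition support on the
reference topology. The default 1,000 replicates is a desk-scale choice;
production analyses conventionally use 10,000.

## Admixture model and ΔK

The admixture model is the no-linkage, independent-frequencies form: each
genotype has proportions $Q_i$ over $K$ populations, each population has
per-locus allele frequencies $P_k$, and each allele copy independently
draws an origin from $Q_i$ and an allele from that origin's frequencies.
A Gibbs sampler (implemented in C++ for throughput) alternates the latent
copy origins, $P$ (Dirichlet posterior, prior $\lambda = 1$) and $Q$
(Dirichlet posterior, symmetric prior $\alpha = 1$ by default; a
Metropolis step on $\log\alpha$ is available). Reported $Q$ and $P$ are
posterior means over post-burn-in sweeps; `lnL` is the mean data
log-likelihood over the same sweeps. The model assumes Hardy–Weinberg
proportions within populations, which a selfing species violates — in
practice the two copies of an autozygous locus simply count twice, and
assignment still works, but membership probabilities should not be read as
calibrated under strong inbreeding.

Population labels are arbitrary per run; runs are aligned by greedy
correlation matching of Q columns before averaging or comparison. Evanno's
$\Delta K = |L''(K)| / \mathrm{sd}(L(K))$ uses the mean and standard
deviation of `lnL` across replicate runs; it is undefined at the endpoints
of the K range and wherever fewer than two runs or zero run-to-run spread
exist, and is scale-invariant to shifting all log-likelihoods. Genotypes
with maximum membership below 0.7 are classed admixed, the conventional
threshold for SSR panels.

Desk-scale MCMC defaults are 5,000 burn-in + 10,000 sweeps per run; the
package's own recovery experiments (below) use shorter chains, which is
sufficient because the mean log-likelihood stabilizes within a few hundred
sweeps at these panel sizes.

## AMOVA and population distances

The three-level AMOVA partitions squared differences between allele copies
(mismatch metric summed over loci) into among populations, among
individuals within populations, and within individuals. Variance
components come from equating observed and expected mean squares with the
unequal-size coefficient $n_c = (T - \sum t_g^2 / T)/(G - 1)$ computed on
copy counts; $F_{ST}$, $F_{IS}$, $F_{IT}$ follow, satisfying
$(1 - F_{IT}) = (1 - F_{ST})(1 - F_{IS})$ identically. Negative
method-of-moments components are reported as estimated and flagged, never
truncated, so the percentage decomposition always sums to 100.
Significance: individuals are permuted among populations for $F_{ST}$ and
$F_{IT}$; allele copies are shuffled among individuals within populations
for $F_{IS}$; 999 permutations by default. Genotypes with any missing call
are dropped from AMOVA (flagged) rather than pairwise-deleted, keeping the
sums of squares exact. Nei's standard identity uses the ratio of
across-locus means, $I = \bar{J}_{xy}/\sqrt{\bar{J}_x \bar{J}_y}$, with
$D = -\ln I$; populations fixed for alternative alleles give $I = 0$ and
an infinite, flagged distance.

## The synthetic panel: what it emulates, what it does not

The generator's defaults describe the kind of study the package targets:
132 genotypes in 2 replicates of 12 incomplete blocks × 11 plots (264
plots), 28 correlated traits with plot-basis heritabilities spread over
0.16–0.98, phenotypic CV of 20%, one quarter of the non-genetic variance in
blocks, and 14 SSR loci with 2–10 alleles (64 total) drawn from K = 2
sub-populations at divergence 0.11 with selfing-level autozygosity
(`inbreeding_F = 0.85`, chosen so expected Ho/He ≈ 0.15, the order observed
in selfing cereal panels) and weak admixture (Dirichlet α = 0.1).

Traits are multivariate normal around their means with an AR(1)-like
genetic correlation (parameter 0.3) by default; the generating components
satisfy $V_g/(V_g + V_{block} + V_e) = $ `target_H2` exactly by
construction, so recovery tests have an unambiguous truth. Markers follow
the Balding–Nichols construction: ancestral frequencies per locus from a
flat-ish Dirichlet, sub-population frequencies from
$\mathrm{Dir}(p(1-F_{ST})/F_{ST})$, individual copies drawn through
admixture proportions, and autozygosity duplicating a single drawn copy
with probability `inbreeding_F` — which yields the diagnostic expectation
$E[Ho] = (1 - F)\,He$ checked in the suite.

Deliberately not emulated: hexaploid inheritance (calls are diploid),
linkage between loci, spatial field trends, genotype-by-environment
interaction, trait distributions with skew or hard bounds (disease scores
in real data are often zero-inflated), and the pooled-seedling DNA protocol
some studies use — the simulator emits individual-level calls, so
pooled-sample heterozygote excess is out of scope. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to these real-data features.

## Problem sizes used in validation

The recovery suites run at sizes chosen to give stable Monte-Carlo
averages in minutes on one core: 200 balanced REML fits for the ANOVA
oracle; 40 trials of 120 genotypes for H² recovery; 50 two-population
panels (200 genotypes × 20 loci, divergence 0.2) with five 750-sweep runs
per K over K = 1..5 for the ΔK experiment; 100 panels for the AMOVA
recovery at the 11% among-population level; 200 panels of 132 × 28 for the
MGIDI planted-best experiment. `scripts/acceptance.R` runs the full
pipeline on the default panel with 3 runs per K at 2,000 + 1,000 sweeps,
200 bootstrap replicates and 199 permutations.

## Known limitations

- The admixture sampler implements the independent-frequencies prior only;
  the correlated-frequencies (F-model) prior used for subtle structure is
  out of scope, so very low divergence may need more loci to resolve.
- ΔK cannot, by construction, select K = 1; inspect `mean_lnL` directly
  when a panmictic panel is plausible.
- Partial correlations with 28 traits on 132 genotypes leave ~104 df per
  test; with many more traits than that the precision matrix estimate
  degrades and the ridge fallback activates.
- MGIDI factor retention (eigenvalue ≥ 1) is a convention; the retained
  factor count on a given panel is data-dependent, and the threshold is
  exposed as a parameter rather than fixed.
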