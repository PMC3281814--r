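---
title: "Methods behind haplodem: haplotype-based phylogeography and historical demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind haplodem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodem)
```

`haplodem` analyses aligned mitochondrial sequences sampled from several
demes: it collapses haplotypes, quantifies within-deme diversity, partitions
variation among demes and groups of demes, builds statistical-parsimony
haplotype networks, screens for spatial genetic structure, fits expansion
models to mismatch distributions, tests neutrality with Fu's FS, and fits a
two-deme isolation-with-migration model by genealogy MCMC. This vignette
explains each model, the defaults and their units, the numerical choices,
and what the built-in simulator does and does not emulate.

## Data model and distances

An alignment is a matrix of A/C/G/T/-/N over individuals, each assigned to
a deme; demes can carry group labels and decimal-degree coordinates.
Ingroup alignments are assumed effectively gap-free; any gap or N is
treated as missing for site statistics and ignored site-wise (pairwise
deletion) in distances. The single genetic distance used everywhere is the
raw count of differing sites between two sequences. In the analysis of
molecular variance this count plays the role of the squared inter-individual
distance, the convention used for haplotype data by the standard AMOVA
framework. No model correction (Jukes-Cantor and the like) is applied: at
the within-species divergences the package targets (well under 5%),
multiple hits are rare, and the uncorrected count keeps the diversity,
mismatch and AMOVA modules exactly consistent with one another.

Haplotype collapsing merges identical sequences; sequences differing only
where one carries N are merged into the earlier haplotype (an N is evidence
of nothing, and keeping ambiguous singletons apart would inflate haplotype
counts). Haplotypes are labelled H1, H2, ... by first appearance so output
is reproducible.

## Diversity statistics

Haplotype diversity uses the unbiased estimator
h = n(1 - sum p_i^2)/(n - 1); the mean number of pairwise differences pi is
the average distance over all C(n, 2) pairs of individuals, and nucleotide
diversity is pi/L. The sample-size-corrected forms are the ones that
reproduce, from a haplotype frequency table alone, the per-deme values a
standard population-genetics package prints; the identity between the
pair-average pi and its haplotype-frequency form
(n/(n-1)) sum_{i<j} 2 p_i p_j d_ij is checked in the test suite. Reported
tables round h and pi to 3 decimals and percent nucleotide diversity to 2,
so a printed table can disagree with a recomputation by one unit in the
last digit when a value sits on a rounding boundary (0.7778 printing as
0.777 is truncation, not error); the package always reports the computed
value.

## PhiST and AMOVA

Variation is partitioned by the sums-of-squares decomposition of pairwise
squared distances: within demes, among demes (within groups), and among
groups. Variance components are solved from the expected-mean-squares
equations with the usual unequal-sample-size coefficients, and the fixation
indices follow: F_ST (one level) or F_CT, F_SC, F_ST (two levels), with the
identity (1 - F_CT)(1 - F_SC) = 1 - F_ST holding to machine precision.
Negative components are retained rather than truncated: they are legitimate
method-of-moments estimates and a near-zero true value should be allowed to
fall on either side (pairwise values like -0.02 between two nearly
panmictic ponds are expected output).

Pairwise PhiST is the same one-level decomposition restricted to a deme
pair. Significance is by permutation of individuals between the two demes;
p is the fraction of permuted statistics at least as large as the observed
one (10,000 permutations by default). The family of pairwise tests is
corrected by the sequential Bonferroni (Holm step-down) procedure: sorted
ascending, p_(i) is compared with alpha/(k - i + 1), stopping at the first
failure; with 7 demes the family is C(7,2) = 21 and the initial threshold
is 0.05/21 = 0.0024. Permutation schemes for the two-level design: F_ST
permutes individuals among demes, F_SC permutes individuals among demes
within their group, F_CT permutes whole demes among groups. Permutation
p-values are exactly uniform only when the statistic is effectively
continuous; with very sparse variation ties make them conservative, which
is the standard behaviour of these tests and is how the calibration tests
are framed (they use high-diversity simulated data).

## Statistical-parsimony networks

The network links haplotypes by single-mutation edges, inserting anonymous
intermediate nodes for multi-step connections, and refuses connections
longer than the 95% connection limit. The limit is calibrated by a
homoplasy model over the L sites of the alignment: a path of j successive
mutations is homoplasy-free unless some mutation strikes an already-mutated
site, 2/3 of such repeat hits producing a misleading (parallel or
convergent) state under an equal-rate four-state model, giving

P_j = prod_{i=2..j} (1 - 2(i - 1)/(3L)),

and the limit is the largest j with P_j above the confidence level. The
exact internal computation of the original statistical-parsimony software
is not fully documented; this calibration is the package's own and it
reproduces the canonical published limit of 13 steps for a 1,025-site
mitochondrial alignment at 95%. Construction is agglomerative over
increasing step distance; when several joins compete at the same distance
the pair with the larger joint haplotype frequency connects first (the
frequency criterion), and joins that would create cycles are dropped, so
the default output is a frequency-resolved forest: one subnetwork per
cluster of connectable haplotypes, with far-out haplotypes left unplaced as
singletons.

## Spatial structure

Deme coordinates give great-circle distances (haversine, radius 6371 km);
individuals inherit their deme's location. The correlogram follows the
multivariate autocorrelation approach of treating the genetic
squared-distance matrix by Gower double-centering into a codistance matrix
C; for each half-open distance class (lower, upper] the coefficient is

r(h) = sum of c_ij over pairs in the class / sum of sqrt(c_ii c_jj),

which lies in [-1, 1] and has expectation near zero in the absence of
spatial structure. One-sided p-values come from permuting individual
locations (999 by default, reported as (count + 1)/(n + 1)); 95% confidence
intervals from bootstrap resampling of the pairs within each class (1,000
by default). The x-intercept — the distance at which positive
autocorrelation dies out — is found by linear interpolation of r across
class midpoints at the first positive-to-negative sign change; class width
is a preset (10/50/100 km are typical choices at increasing spatial
scales). Isolation by distance is tested by the Mantel correlation of the
pairwise PhiST matrix with the deme distance matrix, permuting rows and
columns of the second matrix.

## Mismatch distributions and expansion models

The mismatch distribution is the histogram of pairwise differences. Under
a stationary population of mutation-scaled size theta the distribution is
geometric, Fhat_j = theta^j/(1 + theta)^(j+1). For a sudden demographic
expansion (size theta0 switching to theta1 at tau mutational time units
before present; tau = 2ut for t generations and per-sequence rate u) the
package evaluates the exact two-epoch pairwise-coalescent mixture

F_j = Fhat_j(theta1) P(Pois((theta1+1)/theta1 * tau) > j)
    + e^(-tau/theta1) sum_i dpois(i, tau) Fhat_{j-i}(theta0),

a numerically stable equivalent of the classical closed form (the pair
either coalesces in the post-expansion regime or survives past the
expansion, collecting Poisson(tau) mutations plus an ancestral geometric
tail). For a spatial expansion in an infinite-island world (deme size
theta, scaled migration M = 2Nm), two lineages sampled in one deme either
coalesce there (rate 1/theta per mutational unit), or one scatters (rate
M/(2 theta) per lineage) after which they cannot meet until the expansion
time tau, when all lineages drop into the single ancestral deme of size
theta; the three-case integral has a closed form in incomplete gamma
functions. Both expectations sum to one (tested), and M -> infinity
recovers the demographic shape with matched parameters.

Fitting minimises the sum of squared deviations (SSD) between observed and
expected mismatch over 0..max observed difference, by Nelder-Mead on
log-parameters from a small multi-start grid seeded at the observed mean
(18 starts; SSD tolerance 1e-8; theta capped at 9999, the conventional
solver ceiling for an effectively unidentified parameter). A stationary
sample leaves tau unidentified — the fit then reproduces the curve with
theta0 near theta1 and an arbitrary tau, which is reported as-is.
Goodness of fit is a parametric bootstrap: samples of the same size are
simulated from the package's coalescent under the fitted model, refitted,
and P_SSD is the fraction of simulated SSDs at least as large as the
observed one (10,000 replicates in production, scaled down in tests).

Natural-unit conversions use a rate model pinned to a per-sequence
mutation rate u = 2e-5 per year. This is the value implied by a divergence
rate of 2% per million years acting over an effective length of about 1 kb
(divergence accrues at 2u = 4e-5 per year for a pair), and it reproduces
the published conversion arithmetic exactly (tau = 8.996 giving 224,900
years; theta1 = 2.338 giving N1 = 58,450). Then T = tau/(2u) x generation
years, N = theta/(2u), and the per-generation immigration rate is
m = M/(2N). Rows where theta hit the 9999 cap do not yield a meaningful N
and should be read as boundary fits.

## Fu's FS

FS is built from the Ewens sampling distribution: with theta set to the
observed mean pairwise differences, S' = P(K >= k_obs | theta, n) is
computed from unsigned Stirling numbers of the first kind (log-space
recursion, stable to n in the hundreds), and FS = ln(S'/(1 - S')). Large
negative FS — more haplotypes than the pairwise diversity predicts —
signals growth or selection. Significance is the fraction of neutral
constant-size coalescent simulations (theta = observed pi) whose FS is at
most the observed one; by the statistic's construction the conventional
significance cutoff is 0.02 rather than 0.05. Monomorphic samples leave FS
undefined and are flagged rather than scored.

## Isolation with migration

The two-deme model has equal-size demes (theta = 2Nu per sequence) that
split T time units ago (T in units of N generations) and exchange migrants
symmetrically at scaled rate M = 2Nm; the ancestral population has the same
size. Inference is Metropolis-Hastings over the full structured-coalescent
genealogy — topology, node times, and explicit per-branch migration paths —
jointly with (theta, M, T) under uniform priors on [0, bound]. The prior
bounds are required configuration without silent defaults: they materially
shape the posterior (especially for M and T) and should be chosen
deliberately for each data set. Proposal kernels: sliding-window updates
for the three parameters (reflected at the bounds), node-time moves bounded
by adjacent events, migration-path resampling from the rate-M/2 two-state
bridge conditioned on endpoint demes, a Wilson-Balding subtree-regraft
whose attachment path is proposed from the same bridge (with an exponential
time kernel for above-root attachment), and a joint rescale that multiplies
all times (nodes, migrations, T) by a common factor while dividing theta by
it — likelihood-invariant, so it walks along the theta-versus-timescale
ridge that sliding-window moves cross slowly. Sequence likelihoods are
Felsenstein pruning under HKY (compiled code), with empirical base
frequencies and a transition/transversion ratio estimated once from the
data pair; branch lengths are t x theta/(2L) substitutions per site. With
a flat likelihood the sampler reproduces its uniform priors — the standard
end-to-end validity check for every proposal's Hastings ratio — and with
M = 0 the genealogy prior makes inter-deme coalescence below T impossible,
which the tests assert directly.

Desk-scale defaults (200,000 steps, 10% burn-in, 3 chains, thinning 20)
mix well for a dozen sequences per side at mitochondrial diversity levels;
production-scale chains are configuration away. Convergence is summarised
by a split potential-scale-reduction factor over the independent chains;
results exceeding the threshold (1.2) — or with no sequence variation at
all, where T is unidentifiable — are returned flagged rather than silently.
Posterior modes come from histograms with Freedman-Diaconis bin widths;
because the sequences identify the mutation-scaled quantities sharply while
theta and the times trade off along a ridge, the split time is estimated
from the marginal mode of tau = T theta / 2 converted at the theta mode,
rather than from the theta-smeared marginal of T itself.

A caveat worth stating plainly: with a single non-recombining locus the
data localise the first inter-deme coalescence, not the split itself — the
split can sit anywhere below that coalescence, and the coalescent prior
tilts the posterior up against it. When per-deme samples coalesce to one
lineage before the split (which at T around 2 N-generations happens in
roughly half the replicates), the first cross-deme coalescence overshoots T
by an exponential waiting time, so split-time point estimates are
upward-spread by construction: simulation studies here show about
three-quarters of replicates recovering T within a factor of two at that
depth, with the remainder being data sets whose realised genealogies
genuinely diverged much earlier than the split.
Natural units: N_ef = theta/(2 u g) for generation time g; note that
calendar-time conversions of mutation-scaled quantities cancel g
(T_years = T theta/(2u), TMRCA_years = TMRCA/u), so the summary table makes
the g-dependence of N_ef explicit while the year values are
generation-time-free. The TMRCA/T ratio (root age over split time, same
units) is the isolation diagnostic: ratios well above 1 mean coalescence
far predates divergence, as expected under long isolation with sporadic
migration.

## The synthetic-data generator

The simulator draws structured-coalescent genealogies in pairwise
mutational time (a pair accumulates Poisson(t) differences over time t):
panmictic and sudden-expansion single demes, finite island and 1-D
stepping-stone arrays, an isolation-with-migration deme pair, and the
infinite-island spatial-expansion scenario matching the mismatch module's
model. Mutations are infinite-sites (each on a fresh site) or finite-sites
HKY with A+T-rich base frequencies (A 0.33, C 0.17, G 0.19, T 0.31, near
the compositional bias typical of arthropod mitochondrial fragments) and
kappa = 4. Standard expectations — mean pairwise differences equal to
theta, Watterson's expected number of segregating sites — are verified in
the test suite.

`make_study_fixture()` builds the deterministic study-like data set used
throughout the tests: 93 individuals in 7 demes (sizes 16, 10, 14, 20, 13,
10, 10) with real coordinates, two concatenated partitions of 560 and 465
sites, and 27 planted haplotypes in 3 divergent groups. Haplotypes are
planted by explicit mutations at fresh sites, so every pairwise distance is
known: within-group distances are a few steps, the group founders lie 20-45
steps apart (far beyond the 13-step connection limit), two haplotypes sit
16-20 steps outside their own group (and therefore stay unplaced in the
network), and the per-deme haplotype counts match a published-style
frequency table, pinning the diversity column (e.g. the two-haplotype 9/1
deme gives h = 0.200 and pi = 1.000 with its haplotypes planted 5 steps
apart). What the fixture does not emulate: recombination (none in mtDNA),
sequencing error, rate heterogeneity among sites, and realistic gap
patterns — so green tests say the estimators and samplers are correct on
clean data of the study's shape, not that real chromatograms are handled.

## Reproducibility and numerical choices

Every stochastic routine takes an integer seed, restores the caller's RNG
state on exit, and the pipeline derives per-stage seeds from one global
seed by fixed offsets, so disabling one stage never shifts another's
stream. Permutation p-values are reported as plain proportions (PhiST,
AMOVA, Mantel) or (count + 1)/(n + 1) (correlogram), matching the
conventions of the programs each module mirrors. Matrix exponentials for
HKY come from a symmetrised eigendecomposition computed once per run.
Degenerate inputs are signalled, not patched: demes with fewer than two
individuals are excluded from pairwise statistics with a warning,
monomorphic samples make FS undefined, a constant distance matrix is a
Mantel error, and zero-variation IM runs return flagged posteriors.

Problem sizes in the test suite are the package's own scaled-down choices:
calibration checks use 50-200 replicates with 99-200 permutations or
bootstrap draws, and the IM recovery study uses 20 replicates of 8+8
sequences, 600 sites and 30,000-step chains — small enough to run as a
routine suite while leaving the statistical contract (factor-2 recovery in
at least 80% of replicates, uniform null p-values at coarse KS tolerance)
intact.

## Known limitations

Distances are uncorrected site differences; at divergences above a few
percent a model-corrected distance hook would be preferable. The spatial
correlogram treats all individuals of a deme as co-located. The IM model
assumes equal and constant deme sizes, symmetric migration and a single
non-recombining locus. The parsimony-probability calibration is a
documented model choice pinned to the canonical 13-step/1,025-site
behaviour rather than a line-by-line reimplementation of the original
software. Mismatch-model bootstrap p-values inherit the usual caveat that
the fitted model is treated as truth when simulating.
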