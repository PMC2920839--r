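---
title: "Quantifying meiotic crossover interference from cytological focus data"
author: "meioCO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic crossover interference from cytological focus data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

During meiotic prophase I, each pair of homologous chromosomes is joined
along its length by the synaptonemal complex (SC). Crossover-designated
recombination sites can be visualised as immunofluorescent MLH1 foci on
spread chromosomes, and the SC itself provides the coordinate system: every
focus is recorded as a distance along the SC from the centromeric end
(mouse autosomes are telocentric, so position 0 is the centromere),
expressed as a fraction or percent of that bivalent's SC length.

From such per-focus tables, four families of questions are asked:

1. **SC structure** — are SCs shorter or longer in a mutant, uniformly
   across chromosomes or only for some size classes?
2. **Crossover interference** — are adjacent crossovers more evenly spaced
   than random, and how strong is that interference?
3. **Crossover position** — where along the centromere-telomere axis do
   crossovers fall, by chromosome size class and focus multiplicity?
4. **Focus counts** — how many recombination foci are present per cell at
   each substage, and do genotypes differ?

`meioCO` implements all four analyses behind a common data model
(`FocusTable` / `Meiocyte` / `Bivalent`), together with a seeded simulator
that generates datasets with the same statistical structure, so every
estimator in the package can be verified end to end without microscopy
data.

## The interference model

Inter-focus distances are modelled as draws from a gamma law with shape
$\nu$ and mean $\mu$ (rate $\nu/\mu$). The shape parameter measures
interference strength: $\nu = 1$ gives exponential spacing, i.e. crossovers
placed with no interference (a Poisson process along the SC), while larger
$\nu$ concentrates the distances around $\mu$, i.e. increasingly even
spacing. Crossover placement along an SC is correspondingly modelled as a
*stationary gamma renewal process*: inter-event gaps are i.i.d.
gamma$(\nu, \mu)$ and the first event offset is drawn from the equilibrium
forward-recurrence density $(1 - F(x))/\mu$. The equilibrium start matters:
it removes any artificial anchor at the centromere, so the process has a
constant event rate $1/\mu$ everywhere on the SC and the expected focus
count is exactly $L/\mu$. `sampleStationaryGammaRenewal()` samples the
forward-recurrence offset exactly, as a uniform fraction of a length-biased
gap (gamma with shape $\nu + 1$).

### Fitting, and the observable-distance correction

The naive maximum-likelihood fit (`fitGammaShape()`) solves
$\log\nu - \psi(\nu) = \log\bar{x} - \overline{\log x}$, with
$\hat\mu = \bar{x}$. It is correct for distances sampled from the gamma law
itself, but cytological distances are not: what can be *measured* is
constrained by the instrument and the chromosome. `fitTruncatedGammaShape()`
therefore maximises the likelihood of the observable-distance model, in
which a gap of length $u$ on an SC of span $L$ is seen only if

* $u$ lies inside a detection window $[d_{lo}, d_{hi}]$ — two foci closer
  than the resolution of light microscopy cannot be separated (default
  $d_{lo}$ = 2% of SC length), and distances beyond the span cannot occur
  (default $d_{hi}$ = the 99th percentile of source spans, 100 in percent
  units); and
* both endpoints fall on the SC, which leaves $L - u$ possible placements —
  observable gaps are *length-biased* against long distances.

The fitted density is $f(u)\,(L-u)/Z$ on the window, with normaliser

$$Z(\nu,\mu) = L\,[F_\nu(d_{hi}) - F_\nu(d_{lo})] -
  \nu \tfrac{\mu}{\nu}\,[F_{\nu+1}(d_{hi}) - F_{\nu+1}(d_{lo})],$$

using the identity $\int u f(u)\,du = \nu\,(\mu/\nu)\,F_{\nu+1}$. The
$(L-u)$ data factor does not depend on the parameters, so it drops out of
the optimisation and only $Z$ changes relative to a plain doubly-truncated
fit. This matters in practice: on simulated unit-SC data the plain
truncated MLE recovers a generating shape of 1 within 20% in barely half of
replicates (it ignores the length bias and overestimates regularity),
whereas the corrected fit is median-unbiased across the whole shape grid
used in the tests (1, 5, 10.9, 20).

Numerical choices: optimisation is Nelder-Mead on
$(\log\nu, \log\mu)$ started from the naive fit, relative tolerance
$10^{-10}$ on the objective, at most 5000 iterations; non-convergence is
flagged on the returned object and the naive estimates are carried.
Degenerate all-equal distances return an infinite-shape sentinel with a
warning. Distances of zero are rejected: two coincident foci are an input
error at this stage (the reader flags, rather than merges, pairs closer
than a configurable resolution gap of 0.005 SC fractions — see
`closePairs()`).

### Known limitation: the exponential boundary

With the default 2%-of-SC lower window, shape and mean trade off strongly
when the generating shape is near 1, because the information that
distinguishes shape values below ~2 sits in the density near zero — inside
the unobservable window. The estimator stays median-unbiased there, but its
sampling spread at 300 intervals (standard deviation about 0.18 around a
true shape of 1) means individual fits miss a ±20% band more often than at
larger shapes. Away from the boundary (shape 5 and above) recovery within
±20% is the norm. The package's recovery test therefore evaluates the
pooled rate across the full shape grid.

## The synthetic meiocyte generator

`simulateDataset()` composes, per bivalent: an SC length drawn from the
rank's normal law (truncated at zero by resampling); crossover positions
from the stationary renewal process on the unit SC; independent thinning of
centromere-proximal foci; independent per-focus detection loss; and
optional obligate-crossover enforcement by bounded resampling (at most 100
retries, then a zero-focus bivalent with a warning — a deliberate, simple
approximation whose conditioning bias is negligible because rejection
resampling leaves the gap distribution of multi-focus bivalents unchanged).
All draws come from R's global generator seeded once per dataset, so a
parameter object reproduces its table bit for bit.

The default parameter sets encode the study conditions the package is
meant to emulate:

* **SC lengths** (`wildTypeParams()`, `trip13ModParams()`): per-rank
  normal laws using the published size-group means and SDs (wild type
  12.8, 11.1, 9.5, 7.7, 5.8 µm across groups 1-2, 3-5, 6-11, 12-16,
  17-19; mutant 11.0, 9.5, 8.1, 6.8, 5.2 µm), applied to each rank in the
  group. The implied mean totals are 171.8 µm and 148.7 µm. Lengths are
  drawn independently per bivalent because only per-rank marginals are
  published; consequently the per-cell total has a smaller SD (~5 µm) than
  reported for real cells (~16 µm), where a per-cell size factor is
  plainly at work. An explicit per-cell factor was considered and left out
  of the defaults as unidentifiable from the published marginals.
* **Interference**: shape 10.9 (wild type) and 9.2 (mutant), the
  corrected all-chromosome estimates.
* **Proximal suppression**: crossover foci are rare in the
  centromere-proximal ~15% of each bivalent; the generator retains a focus
  in that window with probability 0.25, chosen once so the simulated
  proximal occupancy sits near the observed ~4%.
* **Mean spacing**: 0.88 (wild type) and 0.82 (mutant) SC fractions,
  calibrated once so the mean *observable* inter-focus distance matches
  the reported 60.8% and 56.8% of SC length. The observable mean is far
  below the generative mean because long gaps rarely fit on the SC.
* **Detection efficiency**: 1.0 by default; available as a dial for
  sensitivity analyses of imperfect immunostaining.
* **Obligate crossover**: on for wild type, off for the mutant (which
  shows achiasmate bivalents).

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: a single global spacing parameter cannot
reproduce the strong rank dependence of focus multiplicity (real large
chromosomes carry two foci ~36% of the time; the simulator, constrained to
match the observable spacing, yields fewer), 3-focus bivalents arise only
from the renewal process itself, and there is no per-cell correlation in
SC length or focus count. Position-dependent crossover maturation (the
distal bias of singleton foci on small chromosomes) is likewise absent:
simulated positional distributions are stationary apart from proximal
suppression. Relatedly, fitting the truncated model to data generated
*with* proximal thinning and near-span spacing recovers a somewhat inflated
shape (the thinning shortens the effective span in a way the fitter does
not model); the package's recovery claims are therefore stated under the
recovery protocol (spacing 0.5 SC, no thinning), not for arbitrary
parameter corners.

For per-stage focus counts (`simulateStageCounts()`), published
mean-and-SD pairs are matched by a negative binomial when overdispersed
(size $m^2/(s^2-m)$), a Poisson when $s^2 \le m$, and a point mass when
$s = 0$.

## SC metrics and positional analysis

Bivalents are ranked within each cell by descending SC length (stable
ties), grouped by the standard five-group scheme (1-2, 3-5, 6-11, 12-16,
17-19), and summarised as mean ± SD per chromosome with the
percent-of-total convention: group mean divided by the mean per-cell total
(over complete 19-bivalent cells), times 100. Cells with incomplete
bivalent sets contribute to group means but not to per-cell totals; if no
complete cell exists the totals fall back to the bivalents present, with a
warning. Genotype comparisons use two-sided t tests — Welch by default,
pooled-variance optionally — on per-chromosome lengths, a choice left open
by the published tables; per-chromosome units match the published N's.

Positional analysis converts focus positions to percent of SC and
stratifies by size group and focus-multiplicity class (1- or 2-focus
bivalents; 3-focus bivalents are rare and dropped with a recorded count —
deliberately different from the interference module, which uses all
bivalents with two or more foci). Region occupancy uses closed intervals
on positions rounded to 0.1%, so reported one-decimal percentages are
reproduced exactly; the default regions are proximal [0, 15], central
[40, 75] and distal [80, 95] percent. The central-occupancy fold between
genotypes is defined on two-focus bivalents of size ranks 1-5 and tested
with Fisher's exact test. Density overlays use a Gaussian kernel with
Silverman bandwidth, boundary-reflected at 0 and 100 so mass is conserved
on the axis to $10^{-3}$.

## Count and contingency statistics

All tests return a uniform `StatResult`. Implementation conventions, where
the field leaves room:

* **Fisher's exact test** (2x2): two-sided p by the probability-mass
  method — the sum of hypergeometric probabilities of tables no more
  probable than the one observed (with the customary $1+10^{-7}$ relative
  tolerance). One-sided p-values are hypergeometric tails. The package
  reports both sidednesses where a published value is ambiguous.
* **G test**: $G = 2\sum O\log(O/E)$ with independence expecteds and
  $\chi^2_{(r-1)(c-1)}$ tail; Williams correction available, off by
  default. Empty rows or columns are an error with a pooling suggestion.
* **Mann-Whitney**: exact two-sided p under the tie-aware permutation
  distribution of the rank sum whenever $n_1 n_2 \le 400$, computed by a
  generating-function count over doubled midranks (equivalent to
  enumerating all splits); otherwise the tie-corrected normal
  approximation with continuity correction.
* **Anderson-Darling k-sample**: the midrank rank statistic with the
  published variance and standardisation; the asymptotic p comes from the
  five-point critical-value table interpolated quadratically on the logit
  scale, and is reliable in its supported tail ($p \lesssim 0.25$). A
  permutation mode is provided and serves as the distribution-free
  reference in the tests.
* **Fold changes between rates** are computed on one-decimal-rounded
  percentages — the precision at which rates are printed — and then
  rounded by the stated convention (one decimal, nearest integer, or
  nearest ten), so published "x-fold" statements are reproduced without
  ambiguity. Fold changes between focus-count means divide the means
  directly.
* **Reconstruction guard**: contingency tables published only as
  percentages with an N are reconstructed by rounding, and the
  reconstruction must reproduce every printed percentage at printed
  precision; failures are flagged and never used silently.

## Problem sizes used by the test-suite

The suite verifies estimator consistency at $10^5$ draws; Poisson
calibration of the renewal process on $10^5$ gaps; shape recovery on
50 seeded replicates per grid point at 300 intervals each; exact-test
oracles by exhaustive enumeration (all 2x2 margins with total ≤ 40; all
rank-sum splits for samples up to 8+8); the Anderson-Darling
asymptotic-versus-permutation comparison at 50+50 observations and $10^4$
permutations; and type-I error control at 2000 null replicates. These
sizes were chosen to bound Monte-Carlo error well below the asserted
tolerances while keeping the default run lightweight.
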