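---
title: "Methods: locally weighted contact regression, rhythm statistics, and their calibration"
author: "rhythm4c developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locally weighted contact regression, rhythm statistics, and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical methods: the
models, the tunable parameters and their defaults, what the synthetic-data
generators emulate (and do not), the numerical choices, and the places where
the design was genuinely open and a decision had to be made. It states no
empirical result that the test suite does not itself compute.

# 1. The LWMR model for 4C-seq contact profiles

## 1.1 Preprocessing

4C-seq measures the contact frequency of one *bait* restriction fragment
against the genome. Reads map to the two ends of each restriction fragment,
so the **fragment score** is the mean of the two end counts,
`c = (end1 + end2)/2`. Samples in which at least 75% of fragments within
±1 Mb of the bait carry no counts fail QC (the boundary counts as failing).
The bait fragment and the five fragments on each side (11 total) are masked:
they are dominated by self-ligation and partial-digest products. Each
sample's scores are then rescaled so that all samples share the same total
score on the cis chromosome, excluding the masked fragments; the common
target is the mean of the per-sample cis sums, a choice that cancels in
every downstream contrast (any other constant would too).

Coordinates are 0-based half-open throughout; the in-silico digest places
fragment boundaries at each motif start (`GATC` for DpnII), so fragments
tile each chromosome exactly.

## 1.2 The local model

Scores are variance-stabilized as `Y = log10(c/P + 1)` with pseudocount
`P = 500`: scores far below `P` map near 0, which caps the influence of the
noisiest fragments. Within a Gaussian window centred on each target
fragment, the model is additive,

$$Y_{ijr} = a_i + b_j + \varepsilon_{ijr},$$

with fragment effects $a_i$ and condition effects $b_j$ (time point,
genotype, or tissue; replicates $r$ enter as separate observations).
The weighted least-squares objective uses
$W_{ij} = w_{g}(i) \, w_{s}(i,j)$, where
$w_g(i) = \exp(-(x_i - x_0)^2 / 2\sigma_G^2)$ is the positional kernel and
$w_s = (\text{replicates with nonzero score}) + 0.5$ down-weights cells with
dropout (0.5, 1.5, 2.5, 3.5, 4.5 for 0–4 nonzero replicates; the rule
`n + 0.5` generalizes to any replicate number).

**Kernel width.** One source text prints the window as "2500 kb" and
another as "2500 bp"; 2 500 bp is adopted — a 2.5-Mb kernel could not
resolve a feature tens of kb from a bait — and `sigma_g` is exposed as an
argument everywhere (see §1.6 for why you may want to widen it).

**Identifiability.** $a_i$ and $b_j$ are confounded by a constant. The
constraint $\sum_i w_g(i)\, a_i = 0$ is used, which makes each $b_j$ the
local kernel-weighted mean signal of condition $j$ and makes
$\bar b = \mathrm{mean}_j(b_j)$ the natural "signal level" that enters the
variance floor. The solver pins one fragment effect, solves the two-block
normal equations by a Schur complement (condition block is tiny), and
shifts the solution onto the constraint; this is algebraically identical to
the constrained solution and is verified in the tests against a dense
Lagrange-multiplier solve to 1e-8.

**Window truncation.** The kernel has infinite support; fragments beyond
4 sigma are dropped. The effective sample size `n` reported for the t test
is the number of observations whose cell weight exceeds 1e-3 of the window
maximum, and `p = (#fragments) + (#conditions) - 1`.

## 1.3 Standard errors: why a sandwich

The Gaussian kernel is a *smoothing* weight, not an inverse variance: a
fragment 2 sigma from the window centre is not 50 times noisier than one at
the centre. Treating `W` as inverse variance (the naive
$\sigma^2 (X'WX)^{-1}$) understates the variance of $b_j$ by roughly the
ratio of the kernel's support to its effective size ($\approx 2$ here) and
produced grossly anticonservative Z-scores in null simulations. The package
therefore uses the covariance standard for kernel-weighted local regression
(as in loess),

$$\widehat{\mathrm{Cov}}(\hat\theta) = \hat\sigma^2 \,(X'WX)^{-1} (X'W^2X) (X'WX)^{-1},$$

with $\hat\sigma^2$ = weighted RSS divided by its generalized residual
degrees of freedom $\sum W - \mathrm{tr}\{(X'WX)^{-1}X'W^2X\}$, which is
unbiased for a homoscedastic residual variance. The dropout weights stay
inside `W`: cells with many zeros influence both the fit and the variance
less. Null simulations with the package's own generator (negative-binomial
counts, 20% dropout, no condition effect) show both tests calibrated:
type-I error at the 0.05 level between 0.036 and 0.048 across seeds and
Kolmogorov–Smirnov uniformity of the p-values (the acceptance suite runs
one such world at full scale). The residual mild conservativeness
(~0.04 vs 0.05) traces to the correlation between $w_s$ and the true cell
variance; a fully heteroscedasticity-consistent (HC1) sandwich removes it
for the differential test but destabilizes the rhythm test — its
inverse-variance weights then feed back on per-condition variances
estimated from the same residuals — so the pooled form is retained.

## 1.4 Variance floor

Per window, the regularized variance is

$$\tilde\sigma^2 = \hat\sigma^2 + \sigma_{\min}^2\, e^{-\bar b / b_s}, \qquad b_s = \log_{10} 2 .$$

The floor prevents artificially small variances at high-dropout, low-signal
positions and fades exponentially as the local signal grows. The printed
definition of $\sigma_{\min}$ in the source method is self-referential, so
the package adopts an explicit estimator: the square root of the 10th
percentile of $\hat\sigma^2$ among fragments whose $\bar b$ exceeds the
median — high-signal fragments have little dropout, so their residual
variance approximates the noise floor. Both the quantile and the floor
itself are arguments. Note the floor is *deliberately conservative*: in a
perfectly homogeneous null world the estimated floor approximately equals
the common residual variance and inflates every standard error by
$\approx\sqrt2$, which is why the calibration acceptance test runs with the
floor disabled and separately asserts that the floor only ever pushes
p-values up.

## 1.5 Differential and rhythm tests

Differential contacts between conditions $j_1, j_2$:
$Z = (b_{j_1} - b_{j_2}) / \sqrt{se_{j_1}^2 + se_{j_2}^2}$, two-sided p from
the t distribution with `n - p` df, reported alongside the signed
$-\log_{10} p$ track.

24-h rhythmicity: with $u_j = 1/se_j^2$ and $\omega = 2\pi/24$,

$$F = \frac{2}{\sum_j u_j} \sum_j u_j\, b_j\, e^{-i \omega t_j},$$

so that for a cosine of amplitude $A$ peaking at $t_0$ sampled at equispaced
times, $F = A e^{-i\omega t_0}$ *exactly* — the amplitude is `Mod(F)` (the
cosine amplitude, not peak-to-trough; `log2_fc = 2|F|/log10(2)` converts to
a fold change on the count scale) and the phase is $-\mathrm{Arg}(F)/\omega$
mod 24, with ZT0 = lights-on. The covariance of $(\mathrm{Re}\,F,
\mathrm{Im}\,F)$ is propagated from the full covariance of the $b_j$ and the
null $F = 0$ is tested with the bivariate quadratic form on a chi-square
with 2 df (one per part). The diagonal approximation
$\mathrm{Re}^2/\mathrm{Var(Re)} + \mathrm{Im}^2/\mathrm{Var(Im)}$ coincides
with it for equispaced designs with similar uncertainties and remains as a
numerical fallback.

No multiple-testing correction is applied within profiles (peak p-values
are reported raw, as is conventional for these tracks); a BH-FDR column can
be added trivially by the caller.

## 1.6 Localizing broad features: kernel choice

A practical finding from the recovery simulations, documented here because
it affects how the package should be used: when counts are overdispersed
with roughly constant coefficient of variation (the realistic regime for
biological 4C replicates), the local residual variance rises with the
squared signal, which *cancels* the amplitude peak in the rhythm chi-square
statistic across the top of a feature that is wider than the kernel. With
the default 2.5-kb kernel over a 5-kb-wide rhythmic loop, the most
significant fragment lands within ±2.5 kb of the loop centre in only about
half of simulated experiments (phase recovery is unaffected and essentially
always within ±0.5 h). Matching the kernel to the feature scale
(`sigma_g = 5000` for a 5-kb loop) restores sharp localization — in the
acceptance run, 50/50 seeds within ±2.5 kb. Under near-Poisson noise the
mismatch is harmless. Recommendation: smooth at the scale of the feature
you want to localize, exactly as in ordinary kernel regression bandwidth
choice.

# 2. Binned track rhythms and the HSV/Hill colouring

Reads are binned in 500-bp intervals, library-rescaled, smoothed with a
centred 7-bin running average (edges shrink rather than produce NAs), and
log2 values per bin are fitted by unweighted harmonic regression. Because a
per-bin fit has only `T - 3` residual df (3 with six time points), the
chi-square test with a plug-in variance is not uniform under the null; the
exact F(2, T-3) test is used instead, which simulation in the test suite
confirms is calibrated. (The LWMR rhythm test keeps the chi-square form: its
variance comes from hundreds of window observations, not 3 df.)

Colours: hue = phase/24 with blue at ZT0, saturation 1, and value
$v = \min\{H(X_a;k_a,n),\, H(X_p;k_p,n)\}$ where $H(x;k,n) = x^n/(k^n+x^n)$
is the saturating Hill function with $k_a = 1$ (log2 amplitude units),
$k_p = 4.5$ ($-\log_{10} p$ units), $n = 5$. The printed formula in the
source renders garbled; the standard saturating form is the unique simple
choice that reproduces the stated behaviour: black below threshold, colour
above, smooth transition with $v = 1/2$ exactly at threshold. The hue wheel
direction (increasing phase advances the hue from blue) is fixed by the
colour legend fixture in the tests.

# 3. smRNA-FISH bursting

Spots are detected as local maxima of the negated Laplacian of the
maximum-intensity projection, with non-maximum suppression at 3 px (two
candidate maxima closer than that yield one call) and a default threshold
of mean + 5 sd of the filtered projection (no threshold is stated in the
source; the flag is exposed). Site intensities sum a 3×3 mask on the sum
projection of the nine best-focused slices; the focus metric — unspecified
in the source — is the variance of the per-slice Laplacian, a standard
autofocus measure. Nuclei are segmented by Gaussian smoothing, Otsu
threshold, and a seeded watershed on the (smoothed) chamfer distance
transform; diameters are equivalent-circle diameters in micrometres
(`pixel_size` is required metadata).

Ploidy is inferred from a 4-component univariate Gaussian mixture over
diameters fitted by EM (10 restarts, quantile/k-means-style initialization,
sd floored at 1e-3 of the data sd; log-likelihood is asserted non-decreasing
in the tests). The three smallest-mean components are 2N/4N/8N; a nucleus is
assigned when its posterior for one of them exceeds 0.7, and the
largest-variance component captures outliers, which are discarded. The EM
implementation is the package's own because no mixture package is available
in the target environment; the contract is the fitted parameters, which the
tests verify by parameter recovery.

Burst fraction = active sites / assigned ploidy, pooled over nuclei (the
source pooled animals; per-animal summaries can be derived from the nucleus
table). Nuclei with more sites than ploidy are retained but flagged —
dropping them would bias the estimator down. Genotype effects are tested by
Gaussian likelihood-ratio tests: site counts on ploidy through the origin
with genotype-specific versus shared slopes (a per-allele frequency change
is a slope change), and site intensities with genotype-specific versus
single intercepts; chi-square with 1 df. An animal covariate is optional
and off by default: the desk-scale generator controls animal effects, and a
mixed model adds nothing testable here (documented divergence from the
source, which pooled two animals per condition).

# 4. Circadian period and phase statistics

The chi-square periodogram folds the 5-min binned activity trace at each
candidate period `P` (nearest-integer bins per period; grid step = one bin)
and computes the Sokolove–Bushell statistic
$Q_P = K \sum_h (M_h - \bar M)^2 / \mathrm{Var}(x)$, whose null expectation
is `P - 1`. A paraphrased form with an extra factor of `N` circulating in
some descriptions is dimensionally inconsistent with the chi-square
reference and was not used. The significance line is drawn family-wise
(Bonferroni across the ~97-period grid) because the pointwise 0.001 line is
crossed somewhere by ~10% of pure-noise traces; `adjust = "none"` restores
the pointwise line. Group periods are compared with a Welch t-test on
per-animal estimates, reported in minutes.

Expression phases use the same harmonic machinery per gene and genotype;
circular differences are mapped to (−12, 12] and "advance" means a negative
difference (mutant − reference). The sign test is an exact two-sided
binomial on advanced versus delayed genes among those rhythmic (p < 0.05)
in both genotypes — the source does not state its exact construction, so
this sign-test reading is documented as an assumption. The per-gene
bootstrap resamples replicates within time point × genotype; because naive
resampling of 2–3 replicates deflates the variance of cell means by
$(n-1)/n$ (measured ~9% null rejection at the 5% level), resampled
deviations are rescaled by $\sqrt{n/(n-1)}$ around the original cell mean,
which restores calibration (measured ~4.5%); an add-one correction keeps
p ≥ 2/(B+1).

# 5. The synthetic world: what it emulates, and what it does not

`simulate_4c` draws a fragment map with exponential fragment lengths (mean
250 bp, the expectation for a 4-cutter), and per-end negative-binomial
counts around a mean surface = flat background + power-law decay from the
bait (truncated at one fragment length) + a Gaussian loop bump whose
amplitude is cosine-modulated in time. Defaults: 3-Mb chromosome, background
20 reads/end, decay 1000 reads/end at one fragment length with exponent 1
(the source does not report its decay exponent; it is a free parameter),
loop +26 kb from the bait, sd 5 kb, 300 reads/end, relative amplitude 0.5
peaking at ZT20, NB size 20 (dispersion 0.05, the scale 4C statistical
frameworks report for biological replicates), 20% dropout, 6 time points ×
4 replicates. Two defaults deserve comment. The chromosome must be long
relative to the loop: on a short synthetic chromosome the loop is a large
fraction of the cis library and the cis-sum normalization injects a
spurious anti-phase rhythm into every other fragment — a compositional
artifact that cannot occur at the ~100-Mb scale of a real chromosome. And
the NB size controls the localization behaviour described in §1.6.

`simulate_fish_nuclei` draws ploidy classes from mixture weights
(0.35/0.45/0.15/0.05), diameters from the class Gaussians (means 7, 9.5,
12.5, 17 µm; sds 0.7, 0.8, 1.0, 2.5 — generator defaults placing the
outlier mass beyond 15–18 µm, not measured values), and per-allele Bernoulli
bursting; rendered image stacks place disc nuclei on a grid with 3-D
Gaussian spots. `simulate_actogram` emits Poisson counts on a square-wave
rate of known period.

What a green test does **not** establish: the generators have no mappability
or blind-fragment structure, no PCR duplicates, no spatially varying
background, no segmentation-confounding nucleus shapes, and no animal-level
random effects; real-data performance on those axes is untested by
construction.

# 6. Numerical choices and degenerate inputs

- Weighted RSS is computed from per-cell sufficient statistics and clamped
  at 0 (exact fits can produce tiny negative values by cancellation).
- Singular local designs (empty window sides, zero weights) return a
  flagged empty fit rather than an estimate.
- A digest with no motif occurrence returns a single whole-chromosome
  fragment with a warning; an all-constant bin or gene returns amplitude 0
  and p 1; a constant activity trace returns no periodogram peak.
- Ties in EM restarts resolve by best log-likelihood; components are always
  returned sorted by mean.
- Phases are reported in [0, 24) and compared circularly everywhere.

# 7. Known limitations

- The LWMR tests are mildly conservative under heavy dropout (see §1.3);
  p-values near a threshold should be read accordingly.
- Rhythm-significance *localization* degrades for features much wider than
  the kernel under constant-CV noise (§1.6); use a matched kernel.
- The σ_min estimator is a documented heuristic for a self-referential
  printed definition; its quantile is exposed and its effect on null data
  is conservative by design.
- Image operations target desk-scale synthetic stacks; they are O(pixels ×
  iterations) pure-R implementations, not a microscopy pipeline, and there
  is no TIFF I/O in the target environment (arrays in, arrays out).
- Trans-chromosome contacts, Hi-C/TAD analysis, read mapping, RNA-seq
  quantification, and motif scanning are out of scope.
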