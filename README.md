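# rhythm4c

Tools for analysing how chromatin contacts, enhancer activity, and
transcription change along the 24-hour day. The package re-implements, as a
tested and reusable pipeline, the kind of bespoke analysis used to show that
promoter–enhancer loops in mouse tissues oscillate with circadian time:

- **4C-seq contact profiles** (circular chromosome conformation capture):
  restriction-fragment mapping by in-silico digest, fragment scoring, QC,
  bait masking, cis library normalization, and the core statistic — a
  **locally weighted multilinear regression (LWMR)** of log-transformed
  contact scores with differential-contact Z-scores and a 24-h harmonic
  rhythmicity test with regularized variance.
- **Binned genomic signal tracks** (ChIP-seq / DNase-style): 500-bp binning,
  running-average smoothing, per-bin harmonic regression, and the HSV/Hill
  phase-colour encoding for genome-browser display.
- **smRNA-FISH transcriptional bursting**: spot detection, transcription-site
  intensity, nucleus segmentation, 4-component Gaussian-mixture ploidy
  assignment from nuclear diameters, burst-fraction statistics, and
  genotype likelihood-ratio tests.
- **Circadian behaviour and expression**: chi-square (Sokolove–Bushell)
  periodogram for locomotor period estimation, group period comparisons,
  expression phase tables with circular differences, and binomial/bootstrap
  phase-shift tests.
- **Synthetic data with known ground truth** for every stage, so the entire
  pipeline is testable without any external download.

## The model at the core

Within a Gaussian window (sd `sigma_G`, default 2 500 bp) centred on each
restriction fragment, log-scores `Y = log10(c/P + 1)` (pseudocount
`P = 500`) are modelled additively with fragment effects `a_i` and condition
effects `b_j` (condition = time point, genotype, or tissue):

```
S = argmin_{a,b} sum_{i,j,r} W_ij (Y_ijr - a_i - b_j)^2 ,
W_ij = w_g(i) * w_s(i,j)
```

where `w_g` is the positional Gaussian kernel and `w_s = n_nonzero + 0.5`
down-weights fragment × condition cells with replicate dropout. Under the
constraint `sum_i w_g(i) a_i = 0`, each `b_j` is the local mean contact
signal of condition `j`. Differential contacts are tested with
`Z = (b_1 - b_2)/sqrt(se_1^2 + se_2^2)` (t, `n - p` df); 24-h rhythmicity
with the weighted complex Fourier coefficient of the `b_j` and a chi-square
test on 2 df. Residual variances are floored by
`sigma_tilde^2 = sigma_hat^2 + sigma_min^2 exp(-b_bar / log10(2))` so
high-dropout positions cannot appear spuriously precise. Standard errors use
the sandwich form appropriate for kernel-weighted local regression; see the
methods vignette (`vignettes/rhythm4c-methods.Rmd`) for the full account and
the design decisions behind it.

## Worked example

Simulate a liver-like 4C experiment — a bait with power-law contact decay
and an enhancer loop 26 kb downstream whose strength oscillates with peak at
ZT20 (relative amplitude 0.5), 6 time points × 4 replicates, overdispersed
counts, 20 % dropout — then run the full analysis:

```r
library(rhythm4c)

cfg <- fourc_sim_config(seed = 42)     # defaults are the stated world
sim <- simulate_4c(cfg)

qc <- qc_sample(sim$counts)            # fails samples with >= 75% zeros
cts <- normalize_library(mask_bait_adjacent(sim$counts))
mean(cis_fraction(cts))                # signal share in the first 2 Mb

targ <- which(!cts$masked & abs(cts$fragments$mid - cfg$bait_pos) < 1e5)
prof <- lwmr_profile(cts, targets = targ)
d <- differential_test(prof, c("ZT20", "ZT08"))
r <- rhythm_test(prof)
```

Output from this exact script (seed 42):

```
QC pass: 24 of 24 ; zero fraction range: 0.194-0.205
cis fraction (first 2 Mb): 0.703
sigma_min: 0.00909
max rhythm significance at +4147 bp from the loop centre (truth +26000 bp from bait)
  amplitude 0.052 (Y units), phase ZT19.7 (truth ZT20), p = 1.50e-62
max |Z| (ZT20-ZT08) = 13.2 at +4147 bp from loop centre, p = 9.9e-38
```

All 24 samples pass QC at the simulated 20 % dropout; 70 % of cis signal
lies within ±1 Mb of the bait (signal-rich region); the most rhythmic
fragment sits 4 kb from the true loop centre (within one kernel width of a
5-kb-wide feature) with an estimated peak phase 0.3 h from the truth, and
the ZT20 − ZT08 contrast is maximal in the same region. The loop-recovery
acceptance test repeats this over 50 seeds with a kernel matched to the
feature scale.

Other entry points follow the same pattern: `simulate_fish_nuclei()` →
`fit_ploidy_mixture()` → `assign_ploidy()` → `burst_statistics()` for
bursting; `bin_and_normalize()` → `smooth_track()` → `fit_bin_rhythm()` →
`hsv_encode()` for tracks; `simulate_actogram()` → `chi2_periodogram()` →
`compare_periods()` for behaviour. A thin CLI wraps the main flows:

```sh
exec/rhythm4c simulate 4c --out sim/ --seed 4
exec/rhythm4c lwmr --counts sim/counts.tsv --bait chrS:1500000 \
    --contrast ZT20:ZT08 --rhythm --out out/
exec/rhythm4c period --trace actogram.tsv
```

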