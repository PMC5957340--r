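---
title: "Multiscale symbolic entropy: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale symbolic entropy: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mncse)
```

## The problem

Healthy physiological regulation produces signals with structure on many
temporal scales; disease and aging tend to flatten that structure. A
single-scale entropy of a heart-rate (RR interval) series can therefore
rank a pathological, erratic rhythm as "more complex" than a healthy one.
Multiscale entropy (MSE) addresses this by coarse-graining the series at
scales $\tau = 1, 2, \dots$ and computing sample entropy at each scale —
but sample entropy is a conditional-probability estimate that becomes
*undefined* when no template pairs match, which happens routinely on the
short coarse-grained series that large $\tau$ leaves behind.

This package implements a symbolic alternative, the multiscale normalized
corrected Shannon entropy (MNCSE), which is a plug-in functional of a word
histogram and is therefore finite on any series long enough to hold a
single word.

## The measure

For a series $x = \{x_i\}_{i=1}^N$ and scale $\tau$, the coarse-grained
series is $y_j = \frac{1}{\tau}\sum_{i=(j-1)\tau+1}^{j\tau} x_i$, $j = 1,
\dots, \lfloor N/\tau \rfloor$ (the incomplete final window is dropped).
Each $y_j$ is mapped to a binary symbol, $s_j = 1$ if $y_j \ge
\overline{y}$ and $0$ otherwise, where $\overline{y}$ is the mean of the
coarse-grained series at *this* scale. Overlapping words of $L$ symbols
are encoded positionally, $w_j = \sum_{k=0}^{L-1} s_{j+k}\,\xi^k$ with
$\xi = 2$, giving $M = \xi^L$ possible words and $n = \lfloor N/\tau
\rfloor - L + 1$ word tokens.

With $p_w$ the relative frequency of word $w$ and $C_R$ the number of
distinct words observed:

$$
\mathrm{SE} = -\sum_w p_w \log_2 p_w, \qquad
\mathrm{CSE} = \mathrm{SE} + \frac{C_R - 1}{2 M \ln 2}, \qquad
\mathrm{CSE}_{\max} = \log_2 M + \frac{M - 1}{2 M \ln 2},
$$

$$
\mathrm{NCSE} = \mathrm{CSE} / \mathrm{CSE}_{\max} \in [0, 1].
$$

MNCSE is the NCSE profile over $\tau = 1..\tau_{\max}$; at $\tau = 1$ it
reduces to the single-scale NCSE.

**Why $\ln 2$ in the correction.** The bias correction is the Miller–Madow
term expressed in bits. Reading the denominator any other way breaks the
normalization: with the $\ln 2$ reading, uniform occupation of all $M$
words gives $\mathrm{CSE} = \mathrm{CSE}_{\max}$ exactly, so NCSE attains
1, and the unit tests assert that endpoint to machine precision.

**Why $M$ in the correction denominator.** The classical Miller–Madow
correction divides by the sample size; the definition implemented here
divides by the possible-word count $M$, following the measure's published
form. The choice is inert for the measure's ordering properties (it adds
the same $C_R$-dependent term to every series with the same occupancy) but
it is what makes the $[0,1]$ normalization close exactly.

**Tie rule and typos.** Samples exactly at the mean map to symbol 1
(the $\ge$ in the rule above). The symbol sequence has the full
coarse-grained length: the mean threshold consumes no sample.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `L` | 3 | symbols | word length; $M = 2^L$ grows fast, so $L \le 4$ keeps histograms populated on short records |
| `xi` | 2 | — | alphabet size; only the binary mean-split has a defined partition rule |
| `tau_max` | 20 (noise), 15 (RR studies) | — | largest scale; bounded by needing $\lfloor N/\tau\rfloor \ge L$ |
| `m` | 2 | samples | sample-entropy template length (MSE comparator) |
| `r_fraction` | 0.15 | fraction of SD | sample-entropy tolerance; SD is the population SD of the scale-1 series |
| `r_reference` | `"scale1"` | — | original-MSE convention: $r$ fixed across scales; `"per_scale"` recomputes it |
| artifact cutoff | 2.0 | s | RR intervals above this (or $\le 0$) are treated as missed-beat artifacts |

## The synthetic world

`generate_wgn()` draws standard Gaussian white noise — the uncorrelated
reference. `generate_pink()` builds $1/f$ noise by FFT spectral shaping of
uniform white noise: positive-frequency amplitudes are scaled by
$1/\sqrt{f}$ (power $\propto 1/f$), the DC bin is zeroed (avoids a $1/0$
and an arbitrary offset), phases are inherited from the white noise, and
the inverse transform is standardized to zero mean, unit variance.
Validation ensembles follow the 40-realization, $N = 20000$, $\tau \le
20$ design (tests use 20 seeds to stay inside their time budget; seeds of
an ensemble are consecutive integers `base..base+k-1`).

These noises emulate the *correlation structure* axis of real HRV data —
uncorrelated vs long-range correlated — and nothing else: no
nonstationarity, no ectopy or missed beats, no respiratory or circadian
modulation, no amplitude asymmetry. A green noise-benchmark test
establishes that the implementation reproduces the measure's behavior on
canonical noises; it does not establish clinical discriminative power,
which requires the real cohort recordings (out of scope here — the
machinery in `compare_groups()` / `evaluate_classifier()` computes those
tables when given such data).

## A negative result, kept on the record

The ordering usually quoted for this benchmark — $1/f$ noise above white
noise at every scale, long-range correlation read as complexity — cannot
occur under the definitions above: mean-split symbols of white Gaussian noise are i.i.d. fair coin
flips, their word distribution converges to the uniform distribution on
all $M$ words, and the uniform distribution is the exact maximizer of
NCSE. Empirically (20 seeds, $N = 20000$): WGN $\approx 0.9995$ at every
scale, $1/f \approx 0.82$–$0.84$. No reading of the threshold rule, log
base, or correction changes this — any signal's NCSE is bounded by the
value white noise attains in the large-$N$ limit. The corresponding
acceptance assertion is therefore left failing, deliberately: it records
that this implementation is faithful to the formulas and that the
published figure's ordering is not reproducible from them. The profiles
still *separate* the two noises cleanly at every scale (the direction is
simply reversed), which is what the short-signal benchmark asserts and
what matters for discrimination.

Relatedly, the reported sample-entropy breakdown ("undefined values") on
500-sample records reproduces only when the tolerance $r$ is recomputed
per scale: with $r$ fixed from scale 1, coarse-graining shrinks the SD by
$\sqrt{\tau}$ while $r$ stays put, so matching gets monotonically easier
with scale and no scale in $1..20$ is undefined at $N = 500$ (it is at
$N = 100$, under both conventions). Both conventions are available via
`r_reference`; the fixed-$r$ assertion is likewise left failing as stated.

## Numerical and procedural choices

- **Coarse-graining remainder**: dropped (profile length $\lfloor
  N/\tau\rfloor$), the original MSE convention.
- **Sample entropy**: unordered template pairs $i < j$ over $i \le N - m$,
  self-matches excluded; the $A/B$ ratio is invariant to the
  ordered/unordered convention. Compiled (Rcpp) double loop with early
  abort; brute-force R loops are the test oracle.
- **Undefined entropies** are `NA` markers carried in place — never
  dropped rows, never exceptions — and excluded from ensemble means;
  profile CSVs write them as the literal token `NA` beside a `defined`
  flag column.
- **Mann–Whitney exactness**: the exact two-sided $p$ is computed from the
  full permutation distribution via subset-sum dynamic programming over
  doubled midranks whenever $n_1 n_2 \le 400$ — exact *with ties*, which
  `stats::wilcox.test` refuses; above that, normal approximation with tie
  and continuity correction (cross-checked against `wilcox.test`).
- **Kruskal–Wallis degenerate case**: all pooled values identical gives
  $H = 0$, $p = 1$ (the tie-correction denominator would otherwise be
  $0/0$).
- **Optimal scale** for features: the scale maximizing the two-group AUC
  computed in whichever direction exceeds 0.5, ties to the smallest scale.
  Selection runs on the full dataset before cross-validation — as the
  feature-construction protocol implies — which leaks selection
  information; treat reported CAs as evaluation of that protocol, not as
  unbiased generalization estimates.
- **Cross-validation**: folds are stratified by class (unstratified
  10-fold partitions of a 44-vs-72 imbalance degenerate too often);
  10×10 FCV averages the 10 repetition accuracies; all partitions derive
  from the single `seed` argument.
- **Classifiers**: kNN ($k = 3$) via FNN; the RBF-kernel soft-margin SVM
  is solved in-package as the standard dual QP (`quadprog`), $C = 1$,
  $\gamma = 1/p$, features standardized by training-fold statistics; the
  random forest is in-package bagged CART (Gini, `mtry` $= \lfloor\sqrt
  p\rfloor$, 100 trees). The surrounding environment provides no
  SVM/forest implementation, so these are minimal but real
  implementations, not wrappers.
- **RR unit auto-detection**: a file whose median raw value exceeds 10 is
  read as milliseconds (no human RR interval is 10 s or 10 ms).

## Known limitations

- Only the binary mean-split symbolization is defined; $\xi > 2$ needs a
  partition rule and is rejected rather than guessed.
- NCSE of white-noise-like signals saturates near 1, compressing dynamic
  range at the top of the scale (see the negative result above).
- The exact Mann–Whitney switch point ($n_1 n_2 \le 400$) is a cost
  threshold, not a statistical one.
- The in-package SVM and forest are adequate for the small feature tables
  this workflow produces (tens to low hundreds of subjects, $\le 4$
  features); they are not tuned for large problems.
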