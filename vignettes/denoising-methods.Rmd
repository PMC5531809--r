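---
title: "Universal denoising of amplicon reads: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal denoising of amplicon reads: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dudeseq)
```

## The denoising model

`dudeseq` treats sequencing error as a **discrete memoryless channel**
(DMC): each clean symbol $x_i$ is corrupted independently into a noisy
symbol $z_i$ with probability $\Pi(x, z) = \Pr(Z_i = z \mid x_i = x)$. The
discrete universal denoiser (DUDE) makes no probabilistic assumption about
the underlying *sequence*; it only assumes the channel. It runs in two
passes over the data:

1. **Counting.** For every position with double-sided context
   $(l^k, r^k)$ — the $k$ symbols on each side — increment the statistics
   vector $\mathbf{m}(l^k, r^k)[z_i]$. In amplicon data, reads are short but
   coverage is deep, so counts are pooled across *all* reads of a run into
   a single $\mathbf{m}$ (forward and reverse reads should be pooled
   separately; the package leaves strand handling to the caller).
2. **Denoising.** Each interior position is replaced by
   $$\hat{x}_i = \arg\min_{\hat{x}} \;
     \mathbf{m}^\top \Pi^{-1} \left[ \lambda_{\hat{x}} \odot \pi_{z_i} \right],$$
   where $\pi_z$ is column $z$ of $\Pi$, $\lambda_{\hat{x}}$ column
   $\hat{x}$ of the loss matrix $\Lambda$ (Hamming by default), and
   $\odot$ the elementwise product. Equivalently, the rule minimizes
   expected loss against $\pi_{z_i} \odot \Pi^{-\top}\mathbf{m}$, a
   channel-inverted estimate of the clean-symbol counts for this context.
   This is *not* majority voting: the inversion corrects for what the
   channel itself would have done to a clean majority.

The same rule serves two alphabets:

* **Substitutions** (`denoise_reads`): $\mathcal{X} = \{A, C, G, T\}$,
  $\Pi$ a 4×4 confusion matrix estimated from read/reference alignments
  (`estimate_confusion`) or supplied per platform.
* **Homopolymer indels** (`denoise_flowgram_set`): pyrosequencing flows
  bases in a fixed cycle (default T, A, C, G) and reports an intensity
  $f$ per flow. Intensities are quantized by $Q(f) = \arg\min_{i \in
  \{0..9\}} |i - f|$ (`quantize_flow`); the quantizer plus the
  instrument's conditional intensity densities $P(f \mid N)$ induce a
  **virtual DMC** $\Gamma(i, j) = \int_{j - 1/2}^{j + 1/2} P(f \mid i)\,df$
  over run lengths $\{0..9\}$ (`build_virtual_dmc`). In flow space an
  indel is a substitution of integers, so the same rule applies with
  $\Gamma$ in place of $\Pi$, and the corrected sequence is rebuilt from
  the flow cycle (`reconstruct_sequence`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` (substitution) | 5 | context half-width over bases; window $2k+1 = 11$ |
| `k` (homopolymer) | 2 | context half-width over flows; the 10-letter alphabet makes larger $k$ sparse and costly |
| `quality_threshold` | none | when set, only bases with Phred quality $\le$ threshold are revisited; absent means every eligible interior base is denoised |
| `sigma0`, `sigma1` | 0.05, 0.03 | intensity-model spread, $\mathrm{sd}(N) = \sigma_0 + \sigma_1 N$ (intensity units); widening with $N$ matches the fan-out of published flow densities |
| `zero_rate` | 10 | rate of the exponential intensity density at $N = 0$ (no incorporation) |

There is no analytical rule for $k$ at finite data size; values between 2
and 8 are the practical range, and the defaults are the ones that work
well at typical amplicon depth. Larger $k$ sharpens contexts but thins the
counts each decision rests on.

The intensity model is deliberately **pluggable and explicit**
(`flow_density_model`, serializable via `write_density_config`): the true
$P(f \mid N)$ is an instrument property, and any unimodal family centered
at $N$ can be substituted. The built-in family is a normal truncated to
$[0, \infty)$ for $N \ge 1$ and an exponential for $N = 0$.

## When does the rule correct an error?

With a symmetric channel of total error $p$ and a context whose counts are
dominated by one clean base ($M$ counts), the inversion flips an observed
minority symbol $z$ only when its count satisfies roughly
$m[z] \lesssim 2 (p/3) M$. Two practical consequences:

* **Coverage matters.** At $p = 1\%$, singleton errors flip only once a
  context holds $M \gtrsim 150$ counts. Deeper coverage also suppresses
  the chance that coincident errors at the same locus push $m[z]$ above
  the threshold.
* **Context collisions.** In flow space with $k = 2$, many loci share a
  quantized context, so $\mathbf{m}$ mixes loci with different true
  centers and the rule (correctly) declines to edit where the context
  does not disambiguate. Homopolymer gains are therefore real but more
  modest than substitution gains.

This behavior is the algorithm working as designed — it edits exactly when
the channel model says the observed count is more plausibly noise than
signal.

## The synthetic-data generator

`simulate_amplicon_data` emulates a targeted amplicon experiment:
i.i.d.-uniform reference amplicons, reads drawn from them in even or
log-series uneven proportions (`uneven_proportions` spans two orders of
magnitude, as in skewed mock communities), and corruption through an
explicit channel. Reads are **primer-anchored by default** — every read of
an amplicon starts at the primer position, which is what targeted
amplicon protocols produce and what concentrates per-locus context counts;
`offsets = "uniform"` gives shotgun-style starts instead. An optional
linear position ramp (`error_start` → `error_end`) emulates the
Illumina-style increase of error toward read ends; the interpolation shape
is documented as linear. `generate_flowgrams` computes true run lengths
against the flow cycle and draws intensities from the declared model.
Ground truth travels with every record, so evaluation never depends on an
aligner.

What the generator does **not** emulate: chimeras and PCR artifacts,
quality-score/error correlation, context-dependent (e.g. GGC-motif)
error hotspots, real instrument flow calibration drift, and reverse-strand
reads. Passing tests on this generator therefore demonstrate the
channel-inversion machinery under its own assumptions, not performance on
any particular real dataset.

## Numerical choices

* **Invertibility**: channel matrices with reciprocal condition estimate
  below $10^{-10}$ are rejected; the rule needs $\Pi^{-1}$.
* **Negative inverted counts**: $\Pi^{-\top}\mathbf{m}$ may have negative
  entries; they are used as-is, per the rule's algebra — no clamping.
* **Tie-breaking**: the argmin uses a relative tolerance of $10^{-9}$ and
  takes the first minimizer, so mathematical ties (equal counts under a
  symmetric channel) deterministically break toward A < C < G < T, or
  toward the smaller run length — conservative on insertions — regardless
  of floating-point summation order.
* **Quantizer ties**: $f = i + 0.5$ rounds up, matching round-half-up base
  callers; intensities $\ge 9.5$ saturate at 9.
* **$\Gamma$ tail closure**: the top quantizer cell is $[8.5, \infty)$, so
  rows of $\Gamma$ are exactly stochastic. Cells are integrated by
  adaptive quadrature (absolute tolerance $10^{-8}$) on panels split at
  the half-integer cell edges *and* the integer density means, so very
  narrow densities are never missed; residual quadrature error is
  renormalized out of each row.
* **Precomputation**: the per-(context, $z$) decisions are computed once
  as a table from $\mathbf{m}$, $\Pi^{-1}(\Lambda \odot \pi_z)$ products,
  so per-base work is a lookup and a whole run is linear in the number of
  bases.

## Design choices on open points

* **One $\mathbf{m}$ per input set.** Counts are pooled across all reads
  of a call, matching the deep-amplicon setting. Stratification per
  amplicon group is possible by calling the denoiser per subset.
* **Boundary positions** ($i \le k$, $i > n - k$) are copied verbatim;
  one-sided flanking contexts are deliberately not used (at $k = 5$ the
  flanks are a small fraction of a read).
* **Windows containing `N`** are excluded from counting and passed
  through: the channel model is defined over $\{A,C,G,T\}$ only.
* **Zero-count rows** in `estimate_confusion` become identity rows:
  absent evidence, the channel should not alter that symbol.
* **Composition order** (`denoise_both`): homopolymer correction first —
  flowgrams define the base calls — then substitution correction on the
  resulting sequences. Homopolymer output has no per-base qualities, so
  the second stage runs ungated.
* **Concordance normalizer**: the measure of concordance is
  $(\sum_{ij} f_{ij}^2/(p_i q_j) - 1)/(\sqrt{IJ} - 1)$, the standard form
  with endpoints 1 (identical) and 0 (no concordance); the degenerate
  single-cluster-vs-single-cluster case is defined as 1.
* **DUST scaling**: the windowed score is
  $100 \sum_i n_i(n_i - 1) / (l(l-1))$ over trinucleotide counts $n_i$
  among $l$ words, which pins the endpoints at 0 (all distinct) and 100
  (one repeated word); the unscaled sum is also reported.

## Problem sizes used by the test suite

The stochastic checks run at sizes chosen to hold the relevant effects
comfortably above sampling noise while keeping the suite quick on one
core: the substitution end-to-end check uses 5 amplicons × 250 bp with
2,000 reads × 100 bp at 1% symmetric error ($\approx 320$-fold per-locus
coverage); the homopolymer check uses 2,000 flowgrams at intensity sd
0.15; confusion-matrix recovery uses $10^6$ aligned bases (each cell
within three binomial standard errors); the rule-equivalence property runs
$10^4$ randomized (counts, channel, symbol) triples against a brute-force
minimizer.

## Known limitations

* The channel is assumed position-independent; on ramped (Illumina-like)
  error profiles the single average $\Pi$ is a deliberate approximation.
* Homopolymer correction needs flowgram intensities; it cannot run on
  base-called FASTQ alone, and runs longer than 9 are outside the model.
* The denoiser edits reads in place (read-by-read correction, lengths
  preserved on the substitution path); it does not merge, filter, or
  cluster reads.
* `estimate_confusion` counts only gap-free aligned columns; indel
  columns are skipped, which can differ from alignment pipelines that
  realign around indels.
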