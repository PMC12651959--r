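---
title: "Spike-in normalization of polysome profiling RT-qPCR: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in normalization of polysome profiling RT-qPCR: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyspike)
library(dplyr)
```

## The measurement problem

Polysome profiling separates the mRNAs of a cell lysate on a sucrose
gradient by ribosome load: lightly translated messages sediment in early
(light) fractions, heavily translated ones deep in the polysome region. The
gradient is collected as ~20 discrete fractions, RNA is isolated from each
fraction, and a transcript of interest is measured per fraction by RT-qPCR.
The biological readout is the transcript's *distribution* across fractions,
and how a treatment moves it.

The weak link is per-fraction RNA isolation. Each fraction is an independent
phenol–chloroform extraction from a different sucrose concentration, and
recovery varies tube to tube — by severalfold in practice. Because the
analysis compares *relative* signal across fractions, uneven recovery
distorts the apparent distribution directly.

The remedy modelled here: add a constant amount of total RNA from a distant
species (yeast; measured via its RLP24 transcript, which the target species'
primers do not amplify) to every fraction *before* isolation. Whatever
fraction-specific loss occurs afterwards acts on the spike-in and the
endogenous RNA in that tube alike, so dividing the target's measured
quantity by the spike-in's measured quantity in the same fraction cancels
the loss exactly. That algebraic cancellation is the core claim this package
makes testable.

## From Cq to the shift statistic

For one gene measured across the fractions of one sample, Cq values are
converted to relative quantities with amplification efficiency $E$:

$$\mathrm{RQ}_i = E^{\,\mathrm{Cq}_{\min} - \mathrm{Cq}_i},$$

using the profile's minimum Cq as calibrator (so $\mathrm{RQ} \le 1$). The
calibrator is an arbitrary global scale: the percentage step below divides
it out, so no downstream statistic depends on it. This matters because
vendor software's "relative quantity" baseline conventions differ; any
positive rescaling of a profile gives identical percentages and F_W.

Spike-in normalization divides per fraction:
$\mathrm{NRQ}_i = \mathrm{RQ}^{\text{target}}_i / \mathrm{RQ}^{\text{spike}}_i$.
If the measured quantities are $T_i L_i$ and $S L_i$ (true signal and
constant spike-in, both scaled by the fraction's loss $L_i$), then
$\mathrm{NRQ}_i \propto T_i$ — the loss is gone, with no assumption about
the loss distribution whatsoever.

The distribution over the analysis window $W$ (default fractions 2–16,
covering the 40S, 60S, 80S and polysome regions of a 20-fraction gradient)
is expressed as percentages $p_i = 100\, v_i / \sum_{j \in W} v_j$, and
summarised by the signal-weighted mean fraction number

$$F_W = \sum_{i \in W} f_i \, \frac{p_i}{100},$$

with $f_i$ the integer fraction number. The treatment effect per replicate
is $\Delta F_W = F_W(\text{treated}) - F_W(\text{control})$; positive values
mean redistribution toward heavier polysomes, i.e. increased translational
efficiency. Arms (e.g. two siRNA treatments) are compared by a one-tailed
paired Student's t-test on their per-replicate $\Delta F_W$, with the
Pearson correlation between the paired arms reported as a
pairing-effectiveness diagnostic.

```{r example}
res <- run_pipeline(sim_config(arms = c(siCTRL = 0.3, siARK5 = 1), seed = 42))
res$comparison |>
  select(gene, mode, mean_difference, t_statistic, p_one_tailed, pairing_r)
```

## The generative model behind the simulator

`simulate_experiment()` produces Cq tables whose statistical structure
matches what the analysis assumes, together with the truth they encode.
For arm $a$, condition $c$, replicate $r$, fraction $i$:

* **True distribution.** Each gene has a baseline weight vector over
  fractions (default `bimodal_profile()`: a monosome bump at fraction 5 and
  a polysome bump at fraction 12, width 1.5 fractions, equal mixture — a
  generic shape for a moderately translated mRNA). The treated condition's
  profile is the baseline shifted by `apply_shift()` so that its window F_W
  exceeds the control's by exactly the arm's delta (see below).
* **Isolation loss.** $L_{a,c,r,i} = \exp\!\big(N(0, \sigma_L^2)\big)$,
  drawn independently per tube. The default $\sigma_L = 0.5$ produces
  roughly twofold scatter in per-fraction recovery, the magnitude that makes
  spike-in normalization worth the trouble. The spike-in experiences the
  *same* $L$ (`loss_correlation = 1`); lowering `loss_correlation` lets
  tests probe what happens when the identifiability assumption fails.
* **Readout.** $\mathrm{Cq} = \texttt{cq\_anchor} - \log_E(\text{quantity})
  + N(0, \sigma_{Cq}^2)$, the standard exponential-amplification inversion;
  the default $\sigma_{Cq} = 0.2$ cycles is a typical SYBR replicate SD. A
  structurally zero quantity yields a missing Cq ("no amplification"), which
  the pipeline carries as missing and renormalizes out.
* **Spike-in.** A constant `spikein_amount` (default 320, mirroring 320 ng
  of yeast total RNA per fraction) times the tube's loss factor.

**Replicate effect.** The realised shift of arm $a$ in replicate $r$ is
$\delta_a + b_r$ with $b_r \sim N(0, \texttt{rep\_shift\_sigma}^2)$ shared
by all arms and genes of that replicate (default 0.5 fraction units). This
models day-to-day variation in the magnitude of the global stress response —
biological replicates are separate experiments days apart, and arms
processed in parallel share that day's biology. It is the component of
variance that motivates a *paired* design in the first place: with it,
replicate-matched arms are strongly correlated once measurement noise is
removed, which is exactly the regime in which a pairing correlation near 1
and a more powerful paired test are observed under spike-in normalization.
Without it (set `rep_shift_sigma = 0`) pairing would be pointless and no
normalization scheme could change that. The truth record stores per-replicate
true F_W values, so exactness checks remain exact.

**Shift mechanism.** `apply_shift()` moves mass from the lightest occupied
window fractions to the heaviest window fraction (final donor split
fractionally, negative deltas mirrored) — the simplest deterministic
transport that hits a prescribed F_W change exactly while preserving window
mass. It is a modelling device for "the distribution shifted toward heavier
polysomes", not a mechanistic model of ribosome loading kinetics; recovery
tests only require that the encoded F_W change be exact and controllable.

**Arms are separate samples.** Each arm × condition × replicate is its own
gradient and extraction, so losses are independent between arms. Shared
between arms within a replicate is only the biology ($b_r$).

## What the simulator does and does not emulate

It emulates: per-fraction multiplicative isolation loss revealed by a
constant spike-in; missing/undetermined Cq from empty fractions; Cq-scale
measurement noise; replicate pairing structure; configurable amplification
efficiency. It does **not** emulate: A254 absorbance traces, reverse
transcription competition between species, primer cross-reactivity, RNA
degradation, pipetting error in the spike-in amount itself (a constant
spike-in error would cancel in percentages anyway), or fraction-dependent
RT efficiency distinct from isolation loss. Passing recovery tests
therefore demonstrates the *statistical* correctness of the normalization
arithmetic and its variance benefit under the stated noise model — not that
any particular wet-lab run satisfies the shared-loss assumption. The
`loss_correlation` dial exists precisely to show what partial violation
does (cancellation degrades smoothly).

## Numerical and design choices

* **Calibrator = within-profile minimum Cq** — bounded RQ, and provably
  irrelevant downstream (scale invariance is tested).
* **Missing fractions are renormalized out, not zero-filled.** Percentages
  are "of total observed signal in the window"; zero-filling would drag F_W
  toward the observed fractions' mean and bias comparisons between profiles
  with different missingness.
* **Percentages are computed over the analysis window directly** (not over
  all 20 fractions first): F_W sums over the same set the percentages are
  normalized on, keeping $\sum p_i = 100$ and the window bounds
  $W_{\min} \le F_W \le W_{\max}$ exact. An even-fraction subset
  (`fractions = seq(2, 16, 2)`) is supported for designs that assay
  alternate fractions; F_W then uses the actual fraction numbers of the
  subset.
* **Test direction is an explicit argument.** A one-tailed test's tail is a
  scientific commitment; the package defaults to "test arm greater" only in
  the sense that the caller names which arm is hypothesized larger via the
  arm order, and reports exact p-values rather than significance stars.
* **Degenerate variance** (all paired differences identical) is reported as
  the limiting p (0 or 0.5) with a warning rather than NaN, and a perfect
  pairing correlation reports p = 0 as the limit of the t-based formula.
* **No multiple-testing correction** is applied; the comparison report is a
  small fixed family and prints exact p-values.
* **Determinism.** All randomness flows from one integer seed; the
  generator saves and restores the caller's RNG state, and the pipeline is
  a pure function of (inputs, config, seed) — identical runs produce
  byte-identical output files.

## Validation problem sizes

The shipped validation suite checks: exact loss cancellation (40
three-replicate experiments across loss SD 0–1.2, tolerance 1e-9); shift
recovery and the normalized-vs-raw RMSE ordering (500 three-replicate
experiments at the default configuration); the discernibility pattern —
normalized mode yielding the lower paired-test p-value and the higher mean
pairing correlation (500 two-arm experiments, deltas 0.3 vs 1.0); null
calibration of the one-tailed paired t-test (10,000 three-replicate null
experiments against the binomial interval around 0.05); and brute-force
agreement of every statistic on 100 random instances. Large replicate
batches are drawn in single simulator calls and split into consecutive
triples, which is distributionally identical to independent experiments
because replicate-level draws are iid.

## Limitations

F_W is a one-number summary: distributions differing in shape but not mean
fraction are indistinguishable, and polysome-to-monosome ratio metrics or
curve models of the A254 trace are out of scope. The t-based inference
carries the usual small-sample normality caveat at n = 3 pairs. Efficiency
is assumed constant across fractions within a gene; fraction-dependent RT
or amplification efficiency would not cancel in the spike-in ratio unless
shared by target and spike-in.
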