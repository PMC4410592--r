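---
title: "Single-sample methylation analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample methylation analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soloMeth)
```

## The problem

Imprinting disorders such as transient neonatal diabetes and
Beckwith–Wiedemann syndrome are individually rare, and each patient can carry
a unique pattern of hypomethylation across imprinted loci. Cohort-style
case–control analysis of HumanMethylation450-type array data is therefore
impossible: there is one case, and the only realistic comparison group is a
modest set of batch-matched controls. soloMeth implements a complete pipeline
for this design: array pre-processing, per-CpG single-case statistics,
effect sizes with confidence intervals, and region-level calling of
hypomethylated, imprinted-like differentially methylated regions (DMRs).

Imprinted DMRs are *hemimethylated* in normal tissue — one parental allele
methylated, one not — so their methylation proportion $\beta$ sits near 0.5
and their logit-transformed M value near 0. The pipeline exploits this:
candidate sites must be hemimethylated in controls, significantly
hypomethylated in the case, and clustered.

## Single-case statistics

All tests compare one case score $x^*$ (an M value) with $n$ control scores
summarised by mean $\bar x$ and sample standard deviation $s$ (always the
$n-1$ denominator; every reference value requires it).

* **Crawford–Howell (CH)**, the pipeline default:
  $t_{CH} = (x^* - \bar x)\,/\,(s\sqrt{(n+1)/n})$ on $n-1$ df. It treats
  $\bar x$ and $s$ as sample statistics, which keeps the type I error at the
  nominal level even for very small $n$ — the package's null simulations at
  20 controls give an empirical rate within binomial noise of 5%.
* **One-sample (OS)**: $t_{OS} = (\bar x - x^*)/(s/\sqrt n)$ on $n-1$ df
  (note the reversed sign). Treating the case as a population mean is
  anti-conservative: at 10 controls the simulated type I error exceeds 7%,
  and in full-pipeline comparisons OS never yields fewer candidate sites
  than CH. It is included for comparison, not for production use.
* **Weisberg (WB)** outlier test:
  $t_{WB} = (x^* - \bar x)/(s\sqrt{n/(n-1)})$ on $n-2$ df. Algebraically
  $|t_{WB}| < |t_{CH}|$ for all inputs, so it is slightly more conservative.
  The $n-2$ df follow the published worked example for this design; some
  formulations use other df, which is why the choice is fixed here and
  stated.

All three tests report lower, upper and two-sided tail probabilities. The
pipeline's hypomethylation screen uses the case-below-controls tail (the
lower tail of $t_{CH}$/$t_{WB}$; the upper tail of the sign-reversed
$t_{OS}$). The classic worked example (case 0.4, controls mean 0.5, SD 0.1,
$n=10$) is reproduced by:

```{r}
ctl <- controlSummary(mean = 0.5, sd = 0.1, n = 10)
chTTest(0.4, ctl)
```

A note on conventions: the probabilities usually quoted for this example
(0.365, 0.012, 0.371) match the **two-sided** Student tails of the three
statistics, although they are often labelled one-tailed. soloMeth always
exposes both, and its reproduction tests compare the printed numbers to the
two-sided values; the pipeline's filtering is genuinely one-tailed.

## Effect size and its interval

The effect size is $z_{cc} = (x - \bar x)/s_x$, the single-case analogue of
Cohen's d. Its confidence interval uses the noncentral $t$ construction:
with $w = z_{cc}\sqrt n$, the lower limit is $\delta_L/\sqrt n$ where
$\delta_L$ solves $F_{t;\,n-1,\,\delta_L}(w) = (1+c)/2$, and the upper limit
uses $(1-c)/2$. The CDF is strictly decreasing in $\delta$, so the root is
found by bracketed bisection: the bracket starts at $[w-10,\,w+10]$, doubles
until it straddles the root, and is then halved to a relative width of
$10^{-8}$ (at most 200 iterations; failure to converge is an error, never a
silently clamped interval). Bisection was chosen over derivative-based
root-finding because `pt(ncp=)` has limited relative accuracy at extreme
noncentrality, and a guaranteed bracket is immune to that noise.

```{r}
effectSizeInterval(0.4, ctl)
```

The abnormality point estimate — the percentage of the control population
expected to score below the case — is $100\times$ the lower-tail CH
probability; the interval limits are carried to the percentage scale with the
standard normal CDF applied to the z-scale limits, following the
Crawford–Garthwaite construction. **Limitation:** far in the tails (e.g. a
complete-loss DMR with $z_{cc} < -10$) the heavy-tailed $t$ point estimate
can exceed the normal-mapped upper bound, because $\Phi$ underflows faster
than the $t$ CDF; the containment of the point estimate in the percentage
interval is a moderate-effect property, not an identity, and the class
validity deliberately does not enforce it.

## Pre-processing

The fixed order is: remove probes with any missing beta; drop samples with
>90% of probes at detection $P > 0.05$ (losing the case aborts); drop probes
with >75% of samples at detection $P > 10^{-5}$; remove chrX/chrY probes;
transform $M = \log_2(\beta/(1-\beta))$; quantile-normalise; peak-correct.
Both detection-p inequalities are strict, and every step logs its removal
count. No batch correction exists anywhere in the package: the design
requires the case and its controls to come from one array batch, which is
what makes a single-case contrast defensible.

Numerical choices:

* The logit uses base 2 (the field's M-value convention) with betas clamped
  to $[10^{-6}, 1-10^{-6}]$, so boundary betas stay finite and the
  transform is a bijection on the interior.
* Quantile normalisation maps every column onto the row-wise mean of the
  sorted columns; ties share the mean of the reference values at their rank
  positions. It is idempotent and is skipped (with a warning) for a
  single-sample matrix. Note the hemimethylation band is specified as
  $M \in [-1, +1]$; on a pure base-2 logit that corresponds to
  $\beta \in [1/3, 2/3]$, slightly different from the 0.26–0.70 range
  sometimes quoted for the same band — the band is configurable precisely
  because the two conventions do not coincide.
* Peak correction addresses the compressed dynamic range of Infinium II
  probes: per sample, the unmethylated ($M<0$) and methylated ($M>0$) modes
  of each design-type stratum are located by kernel density estimation
  (Silverman's rule-of-thumb bandwidth), and type II values are rescaled so
  their modes land on the type I modes. Negative and positive values get
  separate factors; signs never flip; type I values are untouched. A sample
  whose strata are not bimodal is left uncorrected with a warning rather
  than corrupted.

## Region calling

Candidate CpGs must satisfy, simultaneously: control mean M inside the
hemimethylation band ($[-1, +1]$ by default); one-tailed $P < 0.05$; and a
negative beta difference (case below controls). The stringent option
replaces the raw threshold with a BH-FDR-adjusted one-tailed
$P < 10^{-7}$ — the cohort-style criterion, available but off by default
because at $n=1$ it is too severe to recover known DMRs. Hypermethylation
screening is symmetric behind the `direction` switch, off by default.

A region is a maximal run of **consecutive** candidates with every adjacent
pair at most 2000 nt apart and at least 3 members. "Consecutive" is genuinely
ambiguous, so it is a configuration switch: by default consecutiveness is
judged among retained *hemimethylated* probes (an intervening hemimethylated
probe that failed significance breaks a run, but a fully methylated probe in
between does not, since it could never have been part of an imprinted DMR);
the alternative judges against all retained probes. Likewise the 2000-nt
bound applies to adjacent member gaps by default, with a whole-span variant
available. The default region rule is verified in the test suite against an
independent brute-force $O(n^2)$ enumeration on random fixtures.

Each region gets Fisher's combined probability over its **member** (candidate)
p-values: $X^2 = -2\sum \ln p_i$ on $2k$ df. The tail is computed in log
space, so a 40-probe region of $p = 10^{-12}$ sites has a finite
$\log_{10} P \approx -380$; on the probability scale the value is displayed
as 0 once it falls below $10^{-350}$. At $k=1$ the combination is exactly the
identity, which the tests assert.

Ties in position are broken by probe id, and calls are invariant to input
row order.

## The synthetic-data generator

Because no patient 450k data are public, the package ships a seeded
generator whose defaults are the study conditions the pipeline targets: one
case against **20 controls** (the size at which detection sensitivity
saturates in the titration experiments), a bimodal background with M peaks
near $\pm 3.17$ ($\beta \approx 0.1/0.9$), DMR probes hemimethylated in
controls ($\beta \approx 0.5$ with probe-level jitter of 0.1 on the M
scale), per-sample noise of 0.4 M units, half the probes type II with M
compressed by a factor of 2/3 (the target peak correction must undo),
and missing-beta / detection-failure rates of 0.1% each. Case
hypomethylation is modelled as cellular mosaicism by linear mixing on the
beta scale, $\beta_{case} = (1-f)\,\beta_{pattern}$: at $f=1$ methylation is
lost completely; intermediate $f$ reproduces the attenuated signals of
mosaic patients. Noise is added on the logit scale and back-transformed, so
betas stay in (0, 1) without truncation artefacts.

What it does *not* emulate: probe-level spatial covariance, SNP-affected or
cross-reactive probes, cell-composition effects, or intensity-level
artefacts upstream of beta extraction. Tests passing on this generator
demonstrate the statistical machinery and the filter logic, not robustness
to those real-data pathologies.

Detection failures are drawn independently of the beta values — a
simplification that is adequate for exercising the QC filters, which is all
they exist for here.

## Problem sizes and runtime policy

The test suite and reproduction script run at desk scale by design: null
type-I experiments use 20 000 replicates (vectorised, seconds), interval
coverage uses 2 000 replicates, end-to-end synthetic runs use 300–800
background probes with 8–10-probe DMRs, and the control titration uses sizes
5/10/20 with two replicates. These sizes give binomial/Monte-Carlo error
well inside the asserted tolerances; all randomness flows through explicit
seeds, so every reported number is reproducible bit-for-bit.

## Known limitations

* `pt(ncp=)` carries limited precision at extreme noncentrality; the
  bisection bracket absorbs this, but interval endpoints for $|z_{cc}| > 30$
  should be read as approximate.
* The percentage-scale interval can fail to contain the point estimate for
  extreme effects (see above).
* Whether quantile normalisation should operate on intensities or M values
  is ambiguous in this design; soloMeth normalises M values, since
  intensities are unavailable downstream of beta extraction.
* The region caller's consecutiveness and gap semantics are interpretations
  of an under-specified rule; both are switches, and the defaults are the
  most biologically conservative reading.
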