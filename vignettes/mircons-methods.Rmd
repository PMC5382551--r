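---
title: "Methods: consensus miRNA target prioritization with ground-truth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus miRNA target prioritization with ground-truth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircons)
```

# Scope and rationale

`mircons` implements the in-silico arm of a murine allergic-airway-inflammation
(AAI) miRNA study design: profile miRNAs on a two-colour array, validate by
qPCR, predict mRNA targets by consensus over several prediction algorithms,
prioritize genes that carry many binding sites, and filter down-regulated
candidate transcription-factor targets by the presence of a cAMP-responsive
element (CRE) in their promoter. Published analyses of this kind depend on
unreleased raw array data and on prediction databases frozen at a point in
time, so the package is built around a synthetic-data generator that emulates
every input with known ground truth. Every analysis stage can therefore be
validated as an inverse of the generative model, which is what the test suite
and the acceptance script do.

# The two-colour array model

## Background correction (normexp)

Observed spot foreground intensity is modelled as
$X = B + S$ with background $B \sim \mathcal N(\mu, \sigma^2)$ and signal
$S \sim \mathrm{Exp}(\text{mean } \alpha)$. `estimate_normexp_params()`
maximizes the convolution likelihood, started from method-of-moments values
(the third central moment $2\alpha^3$ identifies $\alpha$). The corrected
intensity is the posterior mean

$$E[S \mid X = x] = \mu_s + \sigma\,\frac{\phi(\mu_s/\sigma)}{\Phi(\mu_s/\sigma)},
\qquad \mu_s = x - \mu - \sigma^2/\alpha,$$

computed with the inverse-Mills ratio on the log scale, so the result is
strictly positive and strictly increasing in $x$ even far below the
background mean — no spot is ever zeroed or discarded by correction. The
simulator draws spots from exactly this model, which makes parameter
recovery a closed-loop check (recovery within a few percent at
$n = 10^4$).

## Normalization

Within each array, the log-ratio $M = \log_2 R/G$ is detrended against mean
intensity $A$ with a robust cubic B-spline: 5 degrees of freedom, knots at
equally spaced $A$-quantiles, Huber weights (iteratively reweighted via
`MASS::rlm`). Five df is the conventional spline size for intensity trends;
fewer than $5\times$df probes triggers a median-centring fallback with a
warning. Optionally, and before the spline, each array's $M$ is centred on
the mean of designated control probes — the role the small nuclear RNA RNU6B
plays on the real platform; both normalizations are applied because small-RNA
arrays are routinely normalized to a control RNA while model-based
normalization handles the intensity trend. Between arrays, "scaling" is
interpreted as equalizing the median absolute deviation of $M$: each array is
divided by its MAD and rescaled to the geometric mean of the MADs, so the
spread of every array is identical afterwards. A zero-MAD array is an error
naming the array rather than a silent division by zero.

## Inference

Per probe, ordinary least squares against the array-level design matrix gives
$\hat\beta_g$, $s_g^2$ and $d_g$ residual df. Variances are moderated
empirically-Bayes style: under the hierarchical model
$s_g^2 \sim s_0^2 F(d_g, d_0)$, the mean and variance of $\log s_g^2$ are
matched to digamma/trigamma theory, the trigamma equation is inverted by
Newton iteration, and the posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

with the moderated $t$ referred to $d_0 + d_g$ df (two-sided p-values).
When the dispersion of $\log s^2$ does not exceed its pure-sampling
expectation the prior df is reported as infinite (full pooling); literally
constant variances are returned unchanged as the prior. Forcing $d_0 = 0$
reproduces the ordinary $t$ exactly, which the tests assert. Calibration is
checked on fully null hierarchical simulations (5,000 probes, 2×5 arrays,
200 replicates): the type-I error at nominal 0.05 must lie in
$0.05 \pm 0.01$.

Multiple testing uses Bonferroni (the platform's historical convention for
the primary screen) or Benjamini–Hochberg; the significance cut-off
(default $10^{-4}$) is applied to the adjusted p-value by default but can be
applied to the raw p instead, since screening practice varies on this point.
The ranked list breaks ties by $|\hat\beta|$ descending, then probe id, so
output order is fully deterministic.

# qPCR quantification and statistics

The crossing point Cp is normalized per sample to a reference gene
(`HPRT` for murine mRNA, `sno-234` for murine miRNA, `RNU6B` for human
assays — a configuration field, not hard-coded biology):
$\mathrm{dCp} = \mathrm{Cp}_{\text{gene}} - \mathrm{Cp}_{\text{ref}}$.
Note the reversed scale: **higher dCp means lower expression**, and all
correlation outputs carry that note so signs are never misread.
$\Delta\Delta\mathrm{Ct}$ is the difference of group means of dCp
(arithmetic mean by default, the standard definition; median available) and
the fold change is $2^{-\Delta\Delta\mathrm{Ct}}$. Missing Cp values
propagate as missing and are excluded pairwise, never imputed; a "below
detection limit" measurement is an `NA` with a reason code. The generator
inverts this arithmetic exactly (one doubling of expression lowers Cp by
one cycle), so the noise-free round trip must recover planted fold changes
to machine precision.

Group comparison uses the Mann–Whitney U test. For $n + m \le 12$ the
p-value is exact by full enumeration of all $\binom{n+m}{n}$ group
assignments on the pooled mid-ranks, which handles ties without
approximation; the two-sided p uses the symmetry of $U$ about $nm/2$.
Larger samples fall back to the normal approximation with tie and
continuity corrections. Spearman's rho is the Pearson correlation of
mid-ranks; for $n \le 8$ its two-sided p is exact by enumeration of all
$n!$ permutations, otherwise the $t$ approximation on $n-2$ df is used.
Cross-platform concordance inner-joins two platforms on shared identifiers,
reporting each exclusion with a reason (absent from a platform vs below
detection), mirroring how array/LDA comparisons lose candidates in
practice.

# Seed-match target detection and consensus

Canonical seed sites are defined from the miRNA 5′ end: the reverse
complement of positions 2–7 in the 3′UTR is a 6mer; extending the match to
position 8 gives 7mer-m8; an adenosine in the UTR opposite position 1 gives
7mer-A1; both together give the 8mer. Each 6mer core locus is reported once
with its strongest type (8mer > 7mer-m8 > 7mer-A1 > 6mer). `N` never
matches; `U`/`T` are normalized at parse time; every coordinate in the
package, including BED output, is 0-based half-open on the UTR sense
strand. The detector is verified against a naive all-window oracle on
random instances — exact set equality, not statistical agreement.

Real prediction algorithms (miRanda, PicTar, PITA, TargetSpy, TargetScanS
in the original workflow) score sites in tool-specific ways that cannot be
reproduced faithfully; the package instead ingests any predictor's calls in
a generic TSV schema and emulates predictor behaviour with configurable
pseudo-predictors (per-tool sensitivity, false calls per kb, coordinate
jitter up to 3 nt). Sites of the same miRNA on the same gene whose
intervals overlap by at least 1 nt are merged into one site (touching
intervals stay separate), with supporting predictors unioned — the record
of which tool called which site is never lost. Consensus is k-of-n at the
gene–miRNA pair level: a pair survives iff at least $k$ predictors report
at least one site for it ($k = n$ is the strict "full consensus"; an
optional predictor whitelist supports the relaxed two-tool mode). A
gene-level mode is available by flag, since the literature is ambiguous
about the bookkeeping level.

Prioritization retains genes whose merged sites, summed over miRNAs, reach
a threshold (default 4). Counting total sites rather than distinct miRNAs
is a deliberate reading — site-count heatmaps in this field shade by
"more binding sites for the same miRNA" — and the distinct-miRNA
alternative is a flag. Exclusions of genes known to confound the analysis
(e.g. argonaute-associated genes) are a user-supplied list, not hard-coded.
The bundled demo plants a "Creb1-like" gene carrying the composition
3 + 1 + 2 + 2 = 8 sites across four miRNAs, and the whole chain must return
exactly the planted gene set with that breakdown.

# CRE promoter scanning

The CRE element TGACGTCA is matched as an exact string, overlapping
occurrences included, on the given strand only. Because the octamer is its
own reverse complement, a single-strand scan is strand-complete; this is
checked at run time and recorded on the result, with a message when a
user-supplied motif is not palindromic. No position-weight-matrix scoring
is attempted: the matrix-library thresholds behind published MatInspector
scans are not recoverable, so the exact palindromic consensus is the
defensible primitive. Candidate genes are the down-regulated set
(identifiers harmonized case-insensitively) with at least one hit. The
bundled generator defaults to 1,100 nt promoters (nominally −1,000..+100
around a TSS), a conventional window in the absence of a stated one.

# The synthetic-data generator

Design principles:

* **One master seed, hashed sub-streams.** Every generator call takes one
  integer seed and derives independent per-stream seeds by stable string
  hashing, so outputs are bit-identical under one seed and adding a stream
  never perturbs another.
* **Rejection-sampled backgrounds.** UTR and promoter backgrounds are
  uniform i.i.d. A/C/G/T, re-drawn until free of accidental seed or motif
  matches (re-checked after planting, so junction artefacts are also
  excluded). Planted counts are therefore *exact* ground truth, not
  expected values.
* **Spacers.** Planted sites are separated by at least 2 nt so interval
  merging on truth is unambiguous.
* **Symmetric dye effects.** Differential probes split their log2 ratio
  ±effect/2 across the two channels, keeping M centred for normalization
  tests; signs are drawn per probe since real studies see both directions.
* **Study-scale defaults.** 580 probes, 2×5 arrays, 6% differential
  probes, n = 5 per qPCR group, 185 promoters with 35 motif-positive — the
  scale of the study design this package emulates.

What the generator does **not** emulate: spatial array artefacts, dye-swap
designs, probe cross-hybridization, amplification-efficiency deviations
from 2, realistic promoter composition (CpG islands, repeats), or the
thermodynamics that real prediction tools score. Passing tests therefore
demonstrate correctness of the analysis arithmetic and bookkeeping on data
that obey the stated models — not robustness to every artefact of real
arrays.

# Numerical choices and problem sizes

* Normexp likelihood optimization: Nelder–Mead on
  $(\mu, \log\sigma, \log\alpha)$, two restarts, moment-based start.
* Inverse-Mills and log-density computations use `pnorm(log.p = TRUE)`;
  the transform never returns 0, NaN or a negative value.
* Trigamma inversion: Newton iteration on the standard schedule with
  closed-form guards at both ends of the range.
* Exact-test thresholds: enumeration for $n+m \le 12$ (Mann–Whitney,
  924 assignments worst case) and $n \le 8$ (Spearman, 40,320
  permutations) — exactness where small-sample animal work lives, at
  negligible cost.
* Test and acceptance problem sizes (100 random oracle instances at
  500 nt × 10 miRNAs, 200-replicate calibrations at 5,000 probes,
  $10^6$ nt motif scans) were chosen so the whole suite completes in about
  a minute on one CPU while keeping Monte-Carlo error well inside each
  criterion's band.

# Known limitations

* The generative array model draws an independent exponential signal per
  spot; per-probe M noise is therefore large (log-ratio of two
  exponentials), and with 2×5 arrays even strong planted effects do not
  reach a Bonferroni-adjusted $10^{-4}$ — the demo's significant-probe
  count at study scale is realistically zero. Effect-size *estimates*
  remain unbiased (the tests check the regression slope of estimate on
  truth), and null calibration is exact; a per-probe latent intensity
  would be needed for realistic screening power.
* Site detection is sequence-only; no context scores, conservation, or
  thermodynamics, and 3′-compensatory or bulged sites are out of scope.
* The published cut-set sizes of the original workflow (e.g. numbers of
  consensus targets) depend on 2011-era databases and are not
  reproduction targets; the package's claims are about the method's
  behaviour on ground-truth data.
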