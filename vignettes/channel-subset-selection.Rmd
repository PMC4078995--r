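---
title: "Exhaustive channel-subset selection for two-group fNIRS classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive channel-subset selection for two-group fNIRS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirselect)
```

## The problem

Multichannel functional near-infrared spectroscopy (fNIRS) records relative
oxy-hemoglobin concentration changes at a grid of source–detector channels —
here 24 channels, 12 over each temporal area. Given single trials from two
diagnostic groups (labels $t_i \in \{+1, -1\}$), we want (i) to classify an
unseen trial into its group and (ii) to identify *which combination of
channels* carries the discriminative signal. Univariate channel-wise tests
routinely fail at (ii) when effects are weak, heterogeneous in sign, and
distributed across channels; embedded sparse methods (LASSO, sparse logistic
regression) select *a* subset but not necessarily the subset with the best
classification accuracy. The approach implemented here is the exhaustive
wrapper: score **every** nonempty channel subset with a linear
maximum-margin classifier under cross-validation and rank them.

## From raw signal to features

Each trial consists of a baseline period of at least 20 s (fixation) and a
10 s test period (stimulus). Preprocessing, per trial and channel:

1. **Band-pass filter** 0.02–1.0 Hz, removing slow drift and cardiac
   pulsation. The filter family is not dictated by the data model; we use a
   3rd-order Butterworth applied forward–backward (zero phase, squared
   magnitude response), with odd-reflection padding sized to the low cut-off
   period so that edge transients do not reach the analysis window. Order
   and band edges are configurable (`preproc_config()`).
2. **Baseline Z-score**: with $m$ and $s$ the mean and SD of the filtered
   signal over the 3 s immediately before test onset,
   $d = (x_{\mathrm{test}} - m)/s$. This makes the arbitrary-unit NIRS
   signal comparable across channels, trials and participants. We use the
   population SD (divide by $n$) by default; the convention is configurable
   and documented because neither choice is canonical.
   Filtered values are used both for the baseline statistics and the test
   period, so the transform is applied to one internally consistent signal.
3. **Feature**: the mean Z-score over the closed window [3, 10] s after
   onset — the hemodynamic response peaks several seconds after the
   stimulus, so the early samples mostly dilute the effect. Samples at
   exactly 3.0 s and 10.0 s are included.
4. **Quality control**: a trial is kept only if *all* expected channels are
   present, complete and gap-free; one missing sample in one channel
   rejects the whole trial (the strictest reading of an
   all-channels-recorded rule). Trials — not participants — are the
   classification unit.

The result is an $N \times D$ matrix of mean Z-scores (`fnirs_features()`),
$N = 50$ trials and $D = 24$ channels in the reference design.

## The classifier and its cross-validation

The scoring engine is a linear soft-margin support vector machine: the
decision function is $y(x) = w^\top x + b$ and training maximizes the
margin — the distance between the decision boundary and the nearest
training sample. We solve the dual exactly by sequential minimal
optimization (maximal-violating-pair working sets, an authored Rcpp
implementation since no SVM solver ships with the environment), which makes
every fit deterministic. Points with $y(x) = 0$ exactly are assigned class
$-1$; some convention is required because the loss is defined by the sign
of $t\,y(x)$.

* **Cost parameter `C`** (default 1, configurable): the data model reads as
  hard-margin ($t_i y(x_i) > 0$ for all training points), which large `C`
  approximates on separable data. Features are already Z-scores, so no
  re-standardization is applied before fitting.
* **Weight interpretation**: a large $|w_j|$ marks channel $j$ as
  influential; $w_j > 0$ means larger oxy-Hb responses at channel $j$ push
  the decision toward the $+1$ group, $w_j < 0$ toward the $-1$ group.

Generalization is estimated by stratified $K$-fold cross-validation
(default $K = 5$): the cross-validation error (CVE) is the fraction of all
$N$ trials misclassified when held out, and
$\text{accuracy} = (1 - \text{CVE}) \times 100$. The fold assignment is
seeded, stratified by label, and — crucially — **fixed once per search
run**, so the 4095 (or 16.7 M) subset accuracies are computed under the
same partition and are directly comparable. Whether the original analysis
fixed or re-randomized folds across subsets is unknowable from the outside;
fixing them is the only choice that makes the accuracy distribution
well-defined, and it is flagged as our choice, not an established fact.
Because trials of one participant can land in different folds, an optional
participant-grouped mode is available for the univariate screen; the
classifier operates on trials.

## The exhaustive search

`channel_search()` enumerates all $2^D - 1$ nonempty channel subsets as
bitmasks in ascending order, evaluates each by $K$-fold CVE (batched in
C++), and ranks them: CVE ascending, ties broken by smaller subset size,
then by ascending mask. The tie-break is a documented design choice — with
$N = 50$, CVE is a multiple of $1/50$ and tie classes are large, so *some*
reproducible total order is needed; this one prefers parsimony. For each of
the top-$K$ subsets (default 50) the SVM is refit on the full dataset to
report one weight per included channel; summaries count per-channel
occurrence and weight-sign consistency across the top subsets.

The $D = 12$ hemispheric searches run in seconds. The full bilateral
$D = 24$ search (16,777,215 subsets × 5 fits) is hours-scale on one CPU and
is therefore opt-in (`run_bilateral = TRUE`), with chunked TSV
checkpointing (`checkpoint =`) so interrupted runs resume; the final report
is independent of the chunking.

A caveat that matters when interpreting occurrence counts: because of CVE
discreteness, the "top 50" often spans only two or three distinct error
counts, and *which* tied subsets make the cut is decided by the tie-break.
When several informative channels are mutually redundant (similar effects,
correlated noise), tied subsets tend to contain one *or* the other — the
channels alternate rather than co-occur, and per-channel occurrence can sit
well below the occurrence one would naively expect even though every
appearance has the correct weight sign. Sign consistency is the robust
readout; occurrence magnitude is tie-break-sensitive.

## Comparators

Two embedded sparse baselines are evaluated with the *same* outer folds as
the search, so their accuracies can be placed within the exhaustive
distribution (`percentile_rank()`: rank = 1 + number of subsets strictly
better).

* **LASSO** (`lasso_classifier()`): classical L1-penalized least squares on
  ±1 targets — the estimator the name historically refers to — classified
  by the sign of the fit. The penalty is chosen per outer fold by seeded
  inner 5-fold cross-validation over a logarithmic grid (glmnet backend);
  $\lambda = 0$ is routed to exact least squares.
* **Sparse logistic regression** (`sparse_logistic()`): L1-penalized
  logistic likelihood with inner-CV penalty selection and a small penalty
  floor against perfect-separation divergence. This is a clearly-labeled
  functional stand-in for automatic-relevance-determination sparse
  logistic regression: it preserves the embedded-selection role (exact
  zeros chosen during training) without the variational ARD posterior.

Both predict at threshold 0. Note that an accuracy produced by inner-CV
penalty selection is still a multiple of $1/N$ here because the outer folds
are shared; published figures like 57.5% on 50 trials suggest some form of
repeated or averaged CV whose exact scheme is not recoverable — we do not
attempt to imitate it.

## Channel-wise screen

`channel_screen()` runs, per channel, a two-tailed two-sample *t*-test
between groups on the mean-Z features (pooled variance by default, Welch
optional) and, per group, a one-sample *t*-test against the baseline value
0. Each family of $D$ p-values is corrected with Benjamini–Hochberg at
$q = 0.05$. The pooled default reproduces the conventional
$df = n_a + n_b - 2$ reporting of clinical group comparisons. Whether such
screens should use trials or participant means as observations is
genuinely ambiguous; both units are offered (`unit =`), trials being the
default to match the classifier's rows.

## The synthetic world

Real recordings of this kind are not publicly deposited, so the package
ships a generator with known ground truth rather than data files.

`fnirs_sim_spec()` describes the world; `preset_paperlike()` is the default
scenario: 25 + 25 trials, 24 channels, and seven informative channels with
effects of ±1.5 feature-SD — positive at channels 3, 5, 14, 15, 16 and
negative at 6 and 18, echoing a right-hemisphere/left-hemisphere split of
signed effects. Two generators share each spec:

* `simulate_fnirs_features()` draws mean-Z features directly from per-group
  multivariate normals (unit within-group variance, equicorrelation
  $\rho = 0.3$, mean shifts of ±effect/2). Fast path for statistical
  experiments over many seeds.
* `simulate_fnirs_trials()` synthesizes raw 10 Hz time series — slow
  sinusoidal drift (0.008 Hz, amplitude 0.5), cardiac pulsation (1.1 Hz,
  amplitude 0.3), equicorrelated white noise (SD 1.0), and on informative
  channels a signed gamma-shaped hemodynamic response (peak 5.5 s, shape 5,
  zero at onset). The response amplitude is calibrated empirically per seed
  so the realized mean-Z group shift approximates the specified effect;
  across 10 seeds the realized shifts stay within ±15% of target. A
  configurable fraction of trials loses one channel (`NA`) to exercise
  quality control.

Defaults were fixed once on plausibility grounds: channels of an optical
topography array are spatially correlated (hence $\rho = 0.3$); drift and
pulse amplitudes are set so that both are visible in the raw trace but
removable by the band-pass; the response peak at 5.5 s sits centrally in
the [3, 10] s analysis window. What the generator does **not** emulate:
motion artifacts, optode-geometry forward models, physiologic
balloon-model dynamics, participant-level random effects. A green recovery
test therefore establishes that the *pipeline* recovers planted structure
from signals with these noise ingredients — not that it would from any
particular clinical dataset.

On null data (no informative channels), note that the *maximum* of 4095
cross-validated accuracies is strongly upward-biased by selection
(typically ~70% at $N = 50$); chance-level behavior should be — and is —
asserted on an a-priori fixed subset (e.g. all channels) and on the
comparators, not on the search optimum.

## Numerical choices and edge cases

* SMO tolerance $10^{-6}$ on the KKT violation, iteration cap $2 \times
  10^5$; the intercept is averaged over free support vectors, falling back
  to the midpoint of the KKT-feasible interval.
* Zero baseline SD, missing values, single-class training splits,
  dimension mismatches and empty feature windows raise immediate errors
  naming the offending channel or fold.
* Closed-window membership uses a half-sample tolerance ($10^{-6}$ s) so
  floating-point time stamps at exactly 3.0/10.0 s are included.
* Fold assignment deals each label's shuffled rows into folds, continuing
  the cycle across labels, so $K = N$ degenerates to leave-one-out and
  per-label fold sizes differ by at most one.
* All randomness (folds, generators, inner CV) flows from explicit seeds
  via `withr::with_seed`; the global RNG state is never touched.

## Known limitations

* The full $D = 24$ search is practical but slow on one core; sharding
  beyond chunked checkpointing (multi-process) is left to the caller.
* The sparse-logistic comparator is an L1 stand-in, not the ARD method it
  replaces; percentile ranks for it should be read as "an embedded sparse
  baseline", not as a reimplementation of any specific published tool.
* Occurrence counts in the top-$K$ are tie-break-sensitive at small $N$
  (see above); weight-sign consistency is the stable interpretation.

## A worked example

```{r example, eval = FALSE}
library(fnirselect)

sim <- simulate_fnirs_trials(preset_paperlike(), seed = 1)
feats <- fnirs_features(sim$trials)                  # 50 x 24 mean Z-scores
sr <- channel_search(feats, channels = "right")      # 4095 subsets, 5-fold CV
glance(sr)
channel_occurrence(sr)
sign_consistency(sr)
autoplot(sr)                                         # rank-ordered accuracies
plot_weight_matrix(sr)                               # top-50 weight heat map

cmp <- comparator_cv(feats[c("label", sprintf("ch%02d", 13:24))],
                     method = "lasso", folds = sr$folds)
percentile_rank(cmp$accuracy, sr)

channel_screen(feats)                                # FDR-corrected t-tests
```
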