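---
title: "Methods: simulating and evaluating dual-mode oral cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating dual-mode oral cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screening problem

Oral cancer and its precursors (oral potentially malignant disorders,
OPMD) are largely visible on examination, yet most cases in high-burden
regions are found late: frontline health workers (FHWs) without
specialist training have limited sensitivity for suspicious mucosal
change. A dual-mode intraoral imaging device pairs a white-light image
(WLI) with a 405 nm-excited autofluorescence image (AFI) of the same
view. Neoplastic mucosa typically loses green autofluorescence and can
gain red porphyrin fluorescence, so the AFI red/green contrast carries
diagnostic signal that white light alone lacks. Around such a device a
three-level triage can be built: a compact CNN on the phone for offline
settings, a heavier Bayesian CNN in the cloud that also reports
uncertainty, and referral of uncertain cases to a remote specialist.

`oralscreen` implements this whole cascade as testable code: a
synthetic generator for images and screening cohorts, the channel-fusion
preprocessing, the classifier with focal loss and Monte-Carlo dropout,
the uncertainty-threshold triage rule, and a diagnostic-accuracy layer
that reproduces tier-versus-tier contingency analyses exactly from
printed counts.

# Synthetic data: what is emulated, and what is not

## Images

`generate_image_pair()` renders a 64×64 pair per lesion view. The WLI
shows a pinkish mucosa background (low-frequency smoothed-noise texture
plus per-pixel Gaussian noise); a lesion, when present, is an ellipse
whose mean colour follows its class (pale for benign and leukoplakia-like
OPMD, red-white for carcinoma). The AFI background is green-dominant;
inside the lesion the `"loss"` mode removes a `loss_depth` fraction of
green signal and the `"gain"` mode adds red.

Severity is graded, because that is what makes the classification
problem realistic rather than trivially separable:

* OSCC draws `loss_depth` from U(0.35, 0.7),
* OPMD from U(0.2, 0.6),
* 30% of benign lesions are "inflamed" with a mild loss from
  U(0.05, 0.45), the remainder retain normal fluorescence,
* normal mucosa has no lesion.

The overlap between inflamed benign tissue and mild dysplasia mirrors
the classic false-positive source of autofluorescence screening and
gives the task an irreducible error floor of a few percent. A trained
desk-scale model therefore operates in the high-80s/low-90s accuracy
regime, where uncertainty-based referral is meaningful. These
distributions were fixed once, as the package's study conditions, and
all default analyses use them.

What the generator does **not** emulate: oral anatomy, specular
reflections, saliva, motion blur beyond a Gaussian, camera-specific
colour response, or the phone/probe optics difference (views differ only
by a metadata tag). A test suite passing on these images shows the
pipeline's machinery is correct and that its statistical contracts hold
under known ground truth — it says nothing about accuracy on real
patients.

## Cohorts

`generate_cohort()` simulates one subject per row through the screening
flow: true status is Bernoulli(prevalence); each rater tier (FHW,
onsite specialist, remote specialist) calls subjects with its configured
sensitivity/specificity, independently across tiers given the truth
(no inter-tier correlation model is asserted by the data the package
reproduces, so independence is the parsimonious choice). The remote
tier can declare a case not interpretable (drawn before its call,
default 6%); such cases are excluded from every analysis set. Onsite
review is restricted to a configurable fraction (default 0.375) of
remote-suspicious subjects — matching a flow in which 42% of subjects
are remote-suspicious and 16% of the cohort is seen onsite — and biopsy
is performed only on onsite-suspicious subjects with 20% compliance.
This reproduces verification bias: histology is observed almost
exclusively for test-positive subjects, which is why an
onsite-versus-histology comparison shows high sensitivity and a weak,
wide-intervalled specificity. Histology maps deterministically from the
class label (OSCC → carcinoma histology, OPMD → dysplasia, truly
non-suspicious → non-dysplasia).

Default tier parameters (FHW 0.60/0.78, onsite 0.94/0.90, remote
0.95/0.90, prevalence 0.42) were chosen so that the realized
tier-versus-tier tables sit in the regime of the field comparisons the
diagnostics layer reproduces; they are recovered within exact binomial
confidence intervals by the tests at n = 5000–10000.

# Preprocessing

The classifier input is a three-channel fusion of each pair:

1. WLI green, contrast-equalized,
2. WLI red, contrast-equalized,
3. the normalized AFI red/green ratio.

The WLI blue channel is never read: in the physical device a long-pass
filter blocks the 405 nm excitation, leaving blue uninformative; the
tests assert structurally that perturbing blue cannot change the fused
output.

The ratio is `R/(R + G + eps)` with `eps = 1e-6`. This form was chosen
because it is bounded in [0, 1] without any per-image statistics and is
defined (as 0) even for an all-dark AFI. The alternative `R/(G + eps)`
with per-image min-max rescaling is available behind
`ratio_mode = "rg"`; it is scale-free but makes a pixel's value depend
on the rest of its image. Fluorescence loss depresses G, so the ratio
rises inside lesions under either convention.

Equalization is contrast-limited adaptive histogram equalization with
8×8 tiles and a clip limit of 0.01 expressed as a fraction of tile
pixels (converted to the underlying EBImage parameterization as
`limit = clip × bins`). Equalization is applied to the WLI channels
*before* fusion and never to the AFI ratio — the ratio already carries
its contrast and equalizing it would distort the quantity the
fluorescence physics defines. Whether equalization precedes or follows
channel extraction is a convention; the package equalizes the extracted
single channels, and documents this as such. Exactly constant channels
are returned unchanged (there is no contrast to amplify).

Image quality is gated on the mean finite-difference gradient magnitude
of the WLI (central differences inside, one-sided at borders): blur
suppresses edges, so blurred captures score lower and are flagged for
recapture — never silently dropped. A no-reference NIQE-style scorer is
also provided as a pluggable contract (MSCN coefficient statistics and a
Mahalanobis distance to a Gaussian fitted on sharp reference frames);
its absolute scale is not comparable to canonical NIQE scores, which
depend on the original camera corpus, and nothing in the package's
decisions depends on it.

# The classifier

## Architecture and training

The default backbone (`tiny_cnn`) is a two-block CNN for 64×64×3
inputs: 5×5/stride-2 convolution (8 filters), 3×3 convolution (16
filters), each followed by leaky-ReLU and 2×2 average pooling, then a
fully connected head of widths 32 and 8 with the output layer on top.
`mobilenet_like` and `vgg_like` variants exist as lightweight analogues
(pointwise-after-3×3 and stacked-3×3 designs); no default analysis
depends on them. Engineering choices worth recording:

* **Input centring.** Fused channels live in [0, 1]; the forward pass
  maps them to [-1, 1]. All-positive inputs violate the zero-mean
  assumption behind the He initialization and made training outcomes
  strongly seed-dependent; centring removed most of that variance.
* **Leaky ReLU (slope 0.01).** With 0.5 dropout over narrow layers,
  plain ReLU units die in a non-negligible fraction of runs, collapsing
  the model onto the majority class. The leak eliminates the collapse.
* **Seeded restarts.** Heavy dropout over a small network occasionally
  drives a run into the majority-class attractor (flat loss, AUROC near
  0.5–0.8). Like other stochastic small-model fitters, `train()`
  detects a collapsed run on its validation floors (AUROC < 0.85 or
  accuracy < 0.70) and retrains from a derived seed, up to two extra
  attempts — fully deterministic in the configured seed.
* **Narrow Bayesian head.** The two dropout layers (rate 0.5) sit on
  the two hidden fully connected layers, matching the placement used
  with large field models. At desk scale the head is kept narrow
  (32, 8): with few units per layer, dropping half of them genuinely
  perturbs borderline decisions, so Monte-Carlo passes disagree where
  the case is ambiguous. Wide heads average the dropout noise away and
  leave the uncertainty signal uninformative.

Training is minibatch Adam (batch 32) on the focal loss
`FL(p) = -alpha (1-p)^gamma log(p)` with the canonical defaults
`alpha = 0.25`, `gamma = 2`; with `gamma = 0, alpha = 1` the loss and
its gradient reduce exactly to cross-entropy, and the tests assert
this. Probabilities are clamped at `1e-7` before the logarithm. Each
epoch applies one random label-preserving augmentation per sample
(flips, right-angle rotations, ±10% brightness/contrast jitter). The
learning rate decays by ×0.2 every 20 epochs; the decay cadence is one
reading of a tersely stated field schedule ("decay 5 times by every 20
epochs") whose factor-versus-count meaning is ambiguous — the package
implements a factor of 0.2 and flags the choice here. Desk defaults
(learning rate 1e-3, 30 epochs, ~600 training pairs) train in about two
minutes on one CPU; the field-scale values (1e-4, 300 epochs,
ImageNet-pretrained backbones) are documented in `model_config()` but
are not desk defaults, and pretraining is replaced by seeded random
initialization since no weights are downloaded.

## Uncertainty and triage

`predict_mc()` keeps the dropout layers active at inference and runs
`T = 30` stochastic passes. The prediction is the mean positive-class
probability; the uncertainty `u` is the *population* standard deviation
of the per-pass probabilities. The alternative reading of "uncertainty"
as predictive entropy is available via
`model_config(uncertainty = "entropy")`; SD is the default because it
is zero exactly when dropout is disabled (a single deterministic pass)
and lives on a [0, 0.5] scale compatible with a 0.15 referral
threshold. A tie at `p = 0.5` resolves to suspicious — screening
favours sensitivity. A case is referred when `u` strictly exceeds the
threshold `tau`; referral is therefore monotone non-increasing in
`tau`, exactly.

The default `tau = 0.15` is the operating point chosen in the field
study this package models. The uncertainty scale of a desk-scale model
differs from a field-scale one, so the package also implements the
procedure by which such a threshold is chosen: `calibrate_tau()` sweeps
candidate thresholds on held-out predictions and returns the one
maximizing retained accuracy within a referral budget (default 25%).
Analyses that need a working operating point for the small model
calibrate on validation data and apply the frozen threshold to test
data.

## What dropout uncertainty can and cannot flag at desk scale

A finding worth stating plainly, because it shapes how the triage layer
should be used with small models. On the synthetic task, the SD
uncertainty is **high for rare presentations and low for boundary
errors**. The mechanism is structural: inverted dropout injects noise
proportional to the magnitude of the unit contributions, so the spread
of the output probability scales roughly like
`|logit| × p(1 - p)` — which vanishes exactly at the decision boundary
`p ≈ 0.5`, where misclassified borderline lesions sit, and peaks for
moderately confident (mostly correct) cases. Atypical rare phenotypes
(the red-gain presentations), whose evidence is carried by few
non-redundant units, do receive large SD uncertainty, consistent with
the epistemic reading of Monte-Carlo dropout; but a few tens of
training examples suffice to classify them correctly, so they
contribute referrals rather than caught errors. The net effect is that
for this model class, SD-thresholded referral does not enrich errors,
and `calibrate_tau()` honestly selects a minimal-referral operating
point (retained accuracy then equals full-set accuracy). Large
field-scale networks on natural images operate in a different
representation regime, and the operating characteristics measured there
do not transfer to this desk model — in either direction.

The predictive-entropy variant behaves differently: entropy is maximal
at `p = 0.5`, precisely where the borderline errors live, so
entropy-thresholded referral at a validation-calibrated threshold
defers roughly a fifth of cases and raises retained accuracy
substantially (about 0.90 to 0.96 on the default fixture) — the
selective-referral effect the uncertainty threshold exists for. The
package keeps SD as the default (it is zero exactly when dropout is
off, and its [0, 0.5] scale matches a 0.15-type threshold) and offers
entropy via `model_config(uncertainty = "entropy")`; the cascade tests
exercise the entropy pathway as the calibrated run.

# Diagnostic accuracy layer

All accuracy statistics are computed from 2×2 contingency tables
(`build_table()` excludes subjects not interpretable or absent in
either call vector and counts them separately). Sensitivity,
specificity, PPV, NPV, accuracy and prevalence come with exact
Clopper-Pearson intervals, implemented in closed form via beta
quantiles. The choice of the exact interval was itself verified against
the published intervals of the study the package reproduces: every
printed proportion CI (nine of them) matches the Clopper-Pearson
interval of its own counts to the printed precision.

Cohen's kappa uses `(po - pe)/(1 - pe)` with the asymptotic
(Fleiss-Cohen-Everitt) variance; the published kappa intervals likewise
match this variance to the printed precision. "Weighted kappa" on a
binary table equals unweighted kappa for any weighting scheme; the
implementation computes the weighted form and asserts the identity
rather than assuming it. Precision/recall/F1 follow the standard
formulas with F1 defined as 0 when precision + recall is 0; a metric
with a zero denominator is reported as `NA` (undefined), never as 0.

Display rounding is to the nearest integer percent, **half away from
zero** (kappa to 2 dp), recorded in every report. A handful of
published display cells disagree with their own printed counts by one
rounding unit (two accuracy cells, one specificity, one NPV, two
prevalence displays, and three kappa values at 2 dp); the package
asserts the values recomputed from the counts and lists the published
variants alongside in the golden tests. No multiple-testing correction
is applied anywhere, matching the analysis the package reproduces.

The non-inferiority sample size (`sample_size_noninferiority()`) uses
exact binomial enumeration: for each `n`, the critical value of the
one-sided level-`alpha` test of `H0: p <= p0 - delta`, then the exact
power at `p0`; the smallest `n` reaching the target power is returned.
For `p0 = 0.865, delta = 0.10, alpha = 0.05, power = 0.80` this gives
`n = 100` (critical value 84, achieved power 0.812). The power curve is
sawtoothed in `n`, and for these parameters no `n < 12` can reject at
all (`0.765^n > 0.05`), so the small-power limit of the required `n` is
12, not 1.

# The screening cascade

`run_screening()` wires the stages end to end: cohort generation,
per-subject imaging with the sharpness gate (one recapture at best
focus for failed pairs), the deterministic phone tier, the Monte-Carlo
cloud tier, and referral of high-uncertainty cases to the simulated
remote specialist, whose call overrides the model's for those cases
only. The remote specialist is simulated from its rater profile — not
assumed perfect; `oracle_referral = TRUE` provides the perfect-referral
upper bound as an experiment. When both CNN tiers run, the cloud tier's
(post-referral) output is the cascade's final call — the cloud model is
treated as authoritative over the phone model, an assumption recorded
here. The report contains the consort stage table (counts telescope
along the flow), one contingency table and metrics report per tier
pair, the uncertainty sweep, and a config hash; identical configs and
seed give byte-identical reports.

# Numerical and reproducibility choices

* Every stochastic step derives its seed from the user seed and a
  fixed stream offset (kept inside the 32-bit range); identical
  configurations are bit-reproducible, and no function touches the
  global RNG state.
* Probability clamping at `1e-7`; ratio regularizer `eps = 1e-6`;
  kappa degenerate when `pe = 1`; all-referred sweep points have
  undefined retained accuracy.
* Problem sizes used by the default analyses — 800 subjects for
  training/validation (600/200), 200 standalone test pairs, cohorts of
  2000–10000 for recovery checks — were chosen as the sizes at which a
  laptop CPU reproduces every statistical contract in minutes; they are
  the package's desk-scale study conditions.

# Known limitations

* Synthetic images are geometric phantoms; no claim transfers to real
  mucosal photographs, and the published field operating points
  (e.g. phone-tier 82%/77%) are reproducible here only as arithmetic on
  their printed contingency counts, not as model behaviour.
* The rater model is conditionally independent across tiers; real
  raters share context (the same image, similar training) and likely
  correlate.
* MC-dropout uncertainty on a small CNN is a coarse ambiguity signal;
  its scale is model-specific, which is why thresholds must be
  calibrated rather than transplanted.
* The NIQE-style scorer shares NIQE's construction but not its scale.
* Biopsy histology is simulated deterministically from the class
  label; real histopathology grading noise is not modelled.
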