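---
title: "Methods: equid epigenetic clocks and methylation association screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equid epigenetic clocks and methylation association screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiclock)
```

# The problem

DNA methylation at CpG dinucleotides drifts with age in a reproducible,
largely monotone way, and a penalized linear model on a few hundred CpGs —
an *epigenetic clock* — can estimate chronological age with a median error
of about a year in many mammals. This package implements the full analysis
stack around such clocks for horses and related equids: the model itself,
the species-aware transformations of the dependent variable that let one
formula serve several species, the cross-validation designs that give
unbiased accuracy estimates, the per-CpG association screens that
characterize which CpGs age (and whether castration perturbs them), and
the cross-tissue coupling between promoter methylation and gene
expression. Because the cohorts such studies use are large external
datasets, the package also includes synthetic-data generators that emulate
the statistical structure of those cohorts, so every stage is exercisable
and testable against a known ground truth.

# The clock model

`fit_clock()` solves the elastic-net problem

$$
\hat\beta = \arg\min_\beta \frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2
+ \lambda\left[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right]
$$

with $x_i$ the CpG beta values of sample $i$ (predictors standardized
internally, coefficients reported on the beta scale) and $y_i$ a
*transformed* age. The mixing parameter is fixed at $\alpha = 0.5$ by
convention — midway between ridge and lasso — and is deliberately not
tuned. The penalty $\lambda$ is chosen by an internal, seeded 10-fold
cross-validation minimizing mean squared error; among ties the smallest
$\lambda$ (the denser model) is taken, which makes the selection
deterministic. Fitting is delegated to glmnet, the standard machinery for
this model class; the package disables glmnet's early path exit so the
computed path depends only on the data, the seed and the requested path
resolution.

Numerical choices: the default path has 30 points down to 1% of
$\lambda_{\max}$. For the dense, strong aging signal this model targets,
a finer path moves the selected penalty by less than the fold-to-fold
noise of the internal cross-validation; both the path and the
coordinate-descent tolerance are caller-adjustable through `...` when a
near-exact fit is wanted (the test suite uses an explicit path down to
$10^{-8}$ to verify that a noiseless single-CpG signal is recovered to
machine-level precision).

Degenerate inputs: a constant (transformed) age response is an error; a
predictor matrix with no variance anywhere yields an intercept-only clock
whose prediction is the inverse-transformed mean response. Missing betas
are refused by default (`na_action = "error"`); the alternative policy
drops incomplete CpGs. At prediction time, absent model CpGs are an error
under the strict default, or are substituted by the training means stored
in the model file under `missing_cpgs = "impute_mean"`.

# Age transformations

Multi-species clocks need a dependent variable that removes systematic
species differences. Two are provided, each with an exact inverse
(verified to $10^{-9}$ years over a 1000-point grid per species):

* **Relative age** — $a / L$ with $L$ the species' maximum recorded
  lifespan (57 y for the horse, 122.5 y for the human in the bundled
  table). The ratio is unitless and invariant to rescaling ages and
  lifespans jointly, which is what makes a shared human–horse formula
  meaningful.
* **Log-linear maturity transform** — logarithmic before the age of
  sexual maturity $m$ and linear after it,
  $f(a) = \log\frac{a+c}{m+c}$ for $a \le m$ and $f(a) = \frac{a-m}{m+c}$
  for $a > m$, continuous with matching first derivative at $a = m$.
  This is the standard construction when maximum lifespan is considered
  unreliable: it uses the more robustly estimated maturity age instead,
  and compresses the fast methylation drift of juveniles. The offset
  $c$ (default 2 years, configurable) keeps the logarithm finite at
  birth. The continuous, derivative-matched piecewise form was chosen as
  the package's canonical variant; any alternative parameterization can
  be swapped in through the `age_transform` specification without
  touching clock code.

Species constants live in a `species_table`. The bundled defaults use the
anAge-style horse and human values; the zebra and wild-ass entries
(plains zebra 38 / 2.5 y, Grevy's zebra 31 / 3 y, Somali wild ass
40 / 2 y) are typical literature values chosen once — they are inputs,
not estimates, and callers supply their own table for other panels.
Horse maturity defaults to 3 years and human to 15.

# Cross-validation designs

`cross_validate()` supports three schemes, all refitting the clock from
scratch (including the internal $\lambda$ search) in every fold:

* **LOO** — leave one sample out; the unbiased accuracy estimate for the
  population the training panel represents.
* **KFOLD10** — ten folds, assignment seeded and stratified by species so
  small species are spread across folds.
* **LOSO** — leave one species out; the accuracy to expect in a species
  the clock never saw. A species whose methylation baseline is offset
  from the training species retains a high within-species age correlation
  (the ranking survives) while acquiring a systematic error in years —
  the generator can plant exactly this situation
  (`species_offset`), and the package's acceptance tests verify that the
  LOSO median error then exceeds the LOO median error while within-species
  $r$ stays at or above 0.9.

Accuracy is summarized by the Pearson correlation between chronological
age and its estimate and by the median absolute error in years, overall
and per species/tissue.

# EWAS and meta-analysis

`correlation_screen()` computes, per CpG over pairwise-complete samples:
the Pearson correlation $r$ with the trait, the Student statistic
$t = r\sqrt{(n-2)/(1-r^2)}$ with a two-sided $p$ on $n-2$ df, the Fisher
statistic $z = \sqrt{n-3}\,\mathrm{atanh}(r)$ (with $r$ clamped just
inside $\pm1$ so perfect correlations stay finite), and a
Benjamini–Hochberg $q$ over the testable CpGs. CpGs with fewer than four
complete pairs or no variance are flagged missing rather than dropped.
Tissues are combined by the unweighted Stouffer rule
$z_{\text{meta}} = \sum_k z_k/\sqrt{K}$ (`weights = "sqrt_n"` offers
sample-size weighting; the unweighted rule is the default because equal
tissue weighting is the plain reading of the method, and both modes are
exposed). FDR is controlled within tissue and within the meta-analysis
separately.

Supporting operations follow the field's conventions: `select_top()`
takes the top-$k$ CpGs per direction ranked by $z$ (ties broken
lexicographically so results are deterministic); `overlap_test()` gives
the one-sided upper-tail hypergeometric $p$ and an odds ratio with
Haldane correction; `cohens_d_screen()` contrasts two age groups with the
pooled-SD standardized difference (old minus young); and
`category_association()` applies the tie-corrected Kruskal–Wallis test to
ask whether, e.g., CpG-island CpGs carry systematically stronger age
effects. Every one of these is checked against an independent brute-force
oracle in the test suite.

# Castration screening

`covariate_screen()` regresses each CpG on a castration indicator
(1 = gelding, so positive coefficients mean higher methylation in
geldings) with chronological age in years as a covariate, in male samples
only. Age enters untransformed: this is a direct covariate adjustment,
not a clock. Breed is deliberately not a default covariate — breed
structure is a known unresolved confounder in this design — but an
optional covariate hook accepts any extra columns.
`sector_classify()` then compares the aging signal between geldings and
stallions: a CpG is *shared* when strong in both groups
($p < 10^{-4}$, same sign), *group-specific* when strong in one and null
($p > 0.05$) in the other, and *neither* otherwise; the two thresholds
are parameters.

One design choice deserves a note. The specificity property — with
identical planted aging effects in both groups, at most 5% of causal CpGs
may be classified group-specific — is assessed on an equal-group design
(48 geldings vs 48 stallions). With the observational 48/10 imbalance,
the "null in the small group" check fires by sampling noise alone with
probability $\approx 0.17$ for a true effect of $|r| = 0.8$
($P(|z| < 1.96)$ at $n = 10$), so no classifier could meet a 5% bound
there; equal groups isolate the classifier's specificity from the power
asymmetry of the field design. The detection properties of
`covariate_screen()` are, by contrast, assessed at the realistic 48/10
design.

# Atlas coupling analysis

`assign_nearest_gene()` maps each CpG to the gene with the nearest TSS
(minimum absolute distance; ties to the lexicographically first gene),
reporting a signed distance that is negative upstream relative to gene
orientation. `coupling_screen()` then correlates, across tissue samples,
each promoter-window CpG's methylation with the adjacent gene's log2
expression, and reports $r$, Fisher $z$ and a significance flag at
$|z| > 2.8$ (two-sided $p < 0.005$). The promoter window defaults to
$[-10{,}000, +1{,}000]$ bp around the TSS (negative = upstream). Window
conventions vary between studies — upstream-heavy and downstream-heavy
definitions both appear in practice — so the window is fully
configurable and the upstream-heavy orientation was adopted as the
default; the opposite orientation is one argument away. Expression is
transformed as $\log_2(x+1)$ by default since a TPM-like linear scale is
the common input; already-logged matrices set `log2_transform = FALSE`.
Tissue–animal pairs are treated as independent observations (the
replicate-averaging alternative can be emulated by averaging columns
before the call). `state_summary()` aggregates the $z$ statistics per
chromatin state with the median, a notch interval
$\mathrm{med} \pm 1.57\,\mathrm{IQR}/\sqrt{n}$, and a reported flag at
$|\mathrm{median}\ z| > 2.8$.

# The synthetic-data generators

`simulate_methylation()` draws, for CpG $j$ and sample $i$ in tissue $t$:

$$
\beta_{ij} = \mathrm{clip}\!\left(\mu_j + d_{jt} + o_{js}
+ b_{jt}\,g(a_i) + \gamma_j\,\mathrm{gelding}_i + \varepsilon_{ij},\; 0, 1\right)
$$

with $g$ the age scaled to $[0,1]$ over the tissue's design range,
$\mu_j$ a baseline with headroom for the planted effects, $d_{jt}$ a
small tissue offset, $o_{js}$ an optional species offset on causal CpGs,
and Gaussian noise (default SD 0.05 on the beta scale). This
monotone-in-age, linear-in-beta model is deliberately the weakest
structure under which both a Pearson screen and an elastic-net clock are
consistent — nothing in the generator favors the specific estimator under
test. Causal slopes are calibrated so a causal CpG's population age
correlation equals `effect_scale` (default 0.8, matching the effect sizes
real top aging CpGs reach); island CpGs draw slopes 1.5× larger, which
reproduces the island-versus-non-island ordering of age effects by
construction. A `shared_fraction` (default 0.7) of causal CpGs acts in
every tissue, the rest are tissue-specific. Configurations whose planted
effects would clip more than 20% of entries are rejected rather than
silently attenuated.

The default design is the four-equid blood panel (horse 188, plains zebra
76, Grevy's zebra 5, Somali wild ass 7, with the horse males split
49 geldings / 12 stallions and ages uniform over each species' observed
range); `blood_liver_design()` provides the two-tissue horse design
(188 blood + 48 liver). 2000 CpGs with 300 causal keep every planted
effect estimable on one CPU in minutes while preserving the
$p \gg n$ regime the real arrays live in; the methods scale unchanged
to larger panels.

`simulate_atlas()` emulates the two-animal, 29-tissue design: per gene a
latent promoter methylation per tissue, per CpG a noisy copy of it whose
fidelity optionally decays with TSS distance, and log2 expression coupled
to the latent promoter methylation with a sign and strength set by the
gene's chromatin state. The default couplings plant negative associations
in enhancer states (EnhA, EnhWk, TxEnh) and positive ones at bivalent
promoters, polycomb targets, promoter flanks and TSSs — the qualitative
pattern the atlas analysis is meant to detect — with null states (Tx,
TxEx, Acet, Het, Quies) left at zero for type-I-error checks. Distal
CpGs outside the promoter window still track their gene (so the window
filter, not absence of signal, is what excludes them — a sharper test of
window discipline).

What the generators do *not* emulate: probe-level technical noise, batch
effects, cell-composition shifts, breed structure, and realistic
linkage between neighboring CpGs. Passing tests therefore demonstrate
correctness of the machinery and its operating characteristics under the
stated model, not robustness to every artifact of real array data.

# Determinism and the workflow

Both generators restore the session RNG state after use and are
byte-reproducible under a fixed seed. `run_workflow()` executes
simulate → clock → cross-validate → per-tissue EWAS → meta-analysis from
a single config (R list or YAML), writes every table as CSV/TSV with
full-precision numerics, and records a manifest with MD5 hashes, seed
and package version; re-running a config reproduces byte-identical
tables, and failures quarantine partial outputs under `failed/`. All
thresholds (top-$k$ 500, $p < 10^{-4}$ strong, $p > 0.05$ null,
$|z| > 2.8$ atlas, 5% FDR) surface in the config rather than being
hard-coded.

# Known limitations

* The clock's accuracy estimates inherit the generator's idealizations;
  on real cohorts, LOSO error in a novel species is expected to be larger
  than the planted-offset simulations suggest.
* The Kruskal–Wallis and Fisher-z machinery assumes per-CpG statistics
  are exchangeable within category; correlated neighboring CpGs on real
  arrays violate this mildly.
* `assign_nearest_gene()` uses TSS distance only; it does not model gene
  bodies or enhancer–promoter contacts.
* Chromatin-state labels are taken as given (a consensus annotation
  transferred across species); the package neither infers states nor
  corrects for transfer error.
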