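---
title: "Estimating trophic position from amino-acid nitrogen isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trophic position from amino-acid nitrogen isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csiatp)
library(dplyr)
```

## The model

Compound-specific stable isotope analysis of amino acids (CSIA-AA) separates
the two signals that are confounded in bulk-tissue δ15N: the trophic signal
and the baseline signal. "Trophic" amino acids (glutamic acid foremost) pass
their nitrogen through transamination and deamination at each trophic
transfer, enriching 15N by several permil per step. "Source" amino acids
(canonically phenylalanine) keep their amine nitrogen largely intact, so a
consumer's δ15N_Phe is a proxy for the primary-producer baseline it fed
under. Their difference within a single tissue sample,

δ15N_Glx-Phe = δ15N_Glx − δ15N_Phe,

is therefore an internally calibrated measure of trophic position (TP): no
separate baseline sample is needed, which matters for wide-ranging or
migratory consumers whose baseline cannot be sampled at matching scales.

The package implements the four standard estimating equations. With β the
producer-level Glx−Phe offset and TDF the per-step trophic discrimination
factor of that difference:

1. **Single TDF** (`chikaraishi_single`):
   TP = (δ15N_Glx-Phe − β) / TDF + 1, with β = 3.4 ± 0.9 ‰ (marine algae and
   cyanobacteria) and TDF = 7.6 ± 1.2 ‰ (invertebrates and fish).
2. **Multi-AA** (`multi_aa`): the same closed form with the unweighted mean
   of the seven a-priori trophic AAs (Glx, Asx, Ala, Ile, Leu, Pro, Val)
   minus the mean of the source set (Phe alone by default) in place of the
   Glx−Phe difference, to damp single-AA anomalies. Glycine is excluded from
   both sets: it is no longer considered a reliable source AA. The same β
   and TDF are used — no multi-AA-specific β exists in the framework
   registry, deliberately, because the published form uses the identical
   parameters.
3. **Dual TDF, final transfer** (`germain_dual`):
   TP = (δ15N_Glx-Phe − TDF_consumer − β) / TDF + 2, with
   TDF_consumer = 4.3 ± 1.2 ‰ from a controlled harbor-seal feeding study:
   the lower consumer-specific discrimination is applied to the final
   transfer only.
4. **Dual TDF, denominator** (`mcmahon_dual`):
   TP = (δ15N_Glx-Phe − TDF − β) / TDF_consumer + 2, with
   TDF_consumer = 3.5 ± 0.4 ‰ from captive gentoo penguins: the lower
   discrimination applies to every transfer after the first
   (algae → zooplankton) one.

Two structural identities are worth knowing because the tests lean on them:
adding one denominator-TDF to the input difference raises any equation's TP
by exactly 1, and equations 1 and 3 differ by the constant
1 − TDF_consumer/TDF ≈ 0.434 for every input, since both are affine in the
same difference with the same slope.

```{r}
fw <- default_frameworks()
tp_from_delta(12.40, fw$chikaraishi_single)
tp_from_delta(12.40, fw$germain_dual) - tp_from_delta(12.40, fw$chikaraishi_single)
```

## Data model and defaults

Input is a tidy long table: one row per (specimen, amino acid), validated by
`as_aa_profiles()`. Values outside −30 to +60 ‰ are rejected as implausible;
`Glu`/`Gln` and `Asp`/`Asn` are folded into the measurable hydrolysis pools
`Glx`/`Asx` on ingest; duplicate (specimen, AA) rows are an error naming the
specimen. A wide reader exists as a convenience and converts on ingest — the
long form is canonical because replicate SDs attach unambiguously to rows.

Tunable parameters that matter:

* **`default_sd` (0.5 ‰)** — the per-AA measurement SD assumed when a
  specimen carries no replicate SD. Analytical precision in the kind of
  GC-IRMS work this package targets is reported as sub-permil; 0.5 ‰ sits
  mid-range of that bound. Every row where the fallback is used is flagged
  `missing_sd_defaulted`, and the pipeline surfaces the count in its report
  footer, because this default silently changes the error bars (never the
  TPs).
* **`strict` (TRUE)** — the multi-AA equation demands the complete trophic
  and source sets per specimen; permissive mode averages whatever is present
  and flags `permissive_aa_set`.
* Framework parameters are immutable in the registry; overriding means
  constructing a fresh `tdf_framework()`, and output metadata records the
  parameters actually used.

TP values below 1 are physically impossible but numerically reachable (a
consumer difference below β); they are reported as-is with a `below_one`
flag. Clamping would hide exactly the model failure this kind of analysis
needs to expose. Display rounding is half-up (half away from zero) to 1
decimal for TP and 2 for δ15N summaries, matching how such tables are
printed; all internal arithmetic is full precision, and group summaries use
the n−1 sample SD.

## Uncertainty propagation

`propagate_taylor()` carries measurement SDs (on the Glx−Phe difference or
on Glx and Phe separately, combined in quadrature) and parameter SDs (β and
both TDFs) into a TP SD by a first-order Taylor expansion with analytically
coded partials. All inputs are treated as independent; no covariance
structure has been published for them. When only the difference is known,
its SD defaults to sqrt(2) × `default_sd`.

`propagate_mc()` is the package's own check on that expansion: Gaussian
draws of every uncertain input, mandatory seed, denominator draws at or
below zero rejected and redrawn (with a warning above 1% rejections). For
configurations linear in the uncertain inputs — any equation whose
denominator SD is zero — the first-order expansion is exact and the two
agree to Monte-Carlo error. With the default 1.2 ‰ SD on a 7.6 ‰
denominator, the ratio distribution is heavier-tailed than the linearisation
admits and the Taylor SD sits ~8–10% below the MC SD; the tests pin that gap
under the operative measurement-noise settings. Second-order terms are
deliberately out of scope: the published workflow this reproduces used a
first-order expansion, and the comparison above quantifies what that
approximation costs.

```{r}
propagate_taylor(fw$chikaraishi_single, 12.40, delta_sd = 0)
as.numeric(propagate_mc(fw$chikaraishi_single, 12.40,
  delta_sd = 0, n_draws = 1e5, seed = 1
))
```

## The forward simulator

`simulate_consumers()` is the package's ground truth generator: a primary
producer (Phe at `baseline_phe`, Glx at `baseline_phe + beta_true`), a chain
of trophic transfers each adding a per-AA enrichment, Gaussian measurement
noise on every value, and a known consumer TP. Defaults are ~8 ‰/step for
Glx against ~0.4 ‰/step for Phe — the canonical empirical values, making the
per-step Glx−Phe TDF exactly 7.6 ‰ so that equation 1 inverts the simulator
identically at zero noise. Fractional TPs scale the final transfer's
enrichments linearly, because the estimators return continuous TPs and the
forward model must cover their range. Per-step values for the other trophic
AAs (Asx 6.5, Ala 7.5, Ile 6.0, Leu 6.5, Pro 8.0, Val 7.5, Gly 4.0 ‰) are
phenomenological placeholders chosen to respect observed orderings (Pro and
Val high, Asx low); they are config-overridable and nothing downstream
depends on them except the multi-AA equation's simulated inputs.

`simulate_compressed_phe()` models the main confounder for high-TP marine
consumers: trophic 15N enrichment of Phe that is *not* negligible at upper
transfers. From the third transfer on, Phe gains a user-chosen enrichment
per step. No quantitative per-step value for cetaceans has been published
(reported ranges in other taxa span roughly 1–3 ‰), so the elevation is a
free parameter rather than a default. Two qualitative behaviours are locked
in by tests: the realized Glx−Phe difference shrinks, so single-TDF
estimates undershoot the true TP; and when the elevation exceeds the Glx
step gain, a higher-TP consumer can show a *lower* Glx−Phe difference than a
lower-TP one — the anomaly that motivates treating the difference with
caution as a relative-TP index.

What the simulator does **not** emulate: tissue-specific amino-acid routing
(baleen, skin and dentine draw differently on AA pools), diet-quality and
protein-content effects on discrimination, baseline variation across a
consumer's range, and any mechanistic AA metabolism. Passing the recovery
tests therefore shows the estimators invert the stated fractionation model
correctly under Gaussian noise — not that the model is adequate for any real
tissue.

## The built-in study dataset

`study_fixture()` ships 60 per-individual Glx−Phe differences across five
cetacean species and three tissues, with stomach-content TPs, the originally
printed per-equation TP values for cross-checking, species × tissue AA
means, and the killer-whale diet compositions (fish-eating ecotype: 100%
salmon at TP 3.3; marine-mammal-eating: 100% higher vertebrates at TP 4.0;
`tp_stomach_content()` computes 1 + Σ pᵢ·TPᵢ = 4.3 and 5.0). Per-individual
AA profiles were never published, so the multi-AA equation and the exact
printed ± values are not recomputable from the fixture; the uncertainty
tests instead bracket the printed 0.2–0.6 SD band across the full 0–0.9 ‰
plausible range of the unpublished tissue measurement SD.

Two recorded quirks of the printed source: a handful of printed TP cells
disagree at the last digit with recomputation from the printed 2-dp
differences (the authors presumably rounded δ values for display after
computing TPs) — recomputation agrees exactly on well over 90% of cells and
everywhere within one rounding unit, which is what the tests assert; and the printed bowhead-skin mean difference
(13.50 ‰) is not the mean of the printed individual values (13.59 ‰).
Summaries in this package always recompute from per-individual values.

```{r}
fx <- study_fixture()
est <- estimate_tp(fx$deltas)
head(tp_table(est), 3)
```

## Problem sizes and numerical choices

The test suite validates the Monte-Carlo agreement at 10⁶ draws and
parameter recovery with 200 simulated specimens per true TP in {2, 3, 4} at
0.5 ‰ noise — sizes at which Monte-Carlo error is far below the tolerances
being checked while the whole suite stays in seconds. Ties in rounding go
away from zero; rejection sampling (not truncation-aware analytics) keeps MC
denominators positive, which slightly biases the heavy lower tail and is
acceptable because rejections are ~10⁻⁵ at default parameters; file outputs
embed no timestamps so identical configurations reproduce byte-identical
reports.

## Limitations

Equation choice dominates the answer — the four frameworks span more than a
full trophic level for the same input — and this package deliberately ranks
none of them. It also offers no TP-dependent continuous TDF regression, no
Bayesian estimation, and no threonine-based estimator (Thr is not in the
canonical nine-AA panel it targets). The stomach-content comparison
(`run_compare()`) treats the diet-derived TP as fixed and error-free.
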