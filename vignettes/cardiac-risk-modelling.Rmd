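---
title: "Modelling cardiac toxicity risk for photon versus proton radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiac toxicity risk for photon versus proton radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardrisk)
```

## The problem

Children treated with radiotherapy for mediastinal Hodgkin disease (HD) or
with craniospinal irradiation (CSI) for medulloblastoma (MB) carry an
elevated lifetime risk of cardiac late effects, because the heart sits in
or near the treated volume. Proton therapy usually spares normal tissue
better than photon therapy, but passively scattered proton beams produce
stray neutrons whose biological effectiveness is large and poorly known.
Whether protons actually reduce the predicted cardiac risk is therefore a
quantitative question: the answer depends on the therapeutic dose
distribution in the heart, on the neutron equivalent dose, and on the
dose-response model assumed.

`cardrisk` implements that comparison as a reusable pipeline. It ships the
published mean-dose tables of two reference pediatric cases (an 18-fraction
mediastinal HD plan and a 13-fraction craniospinal MB plan, each planned
with 6 MV photons and with passively scattered protons) and a synthetic
DVH generator, so every step can be exercised and tested without
treatment-planning-system exports.

## Dose bookkeeping

All volume information enters as **differential dose-volume histograms**
(DVHs): fractional volume $v_i$ per dose bin $D_i$, with $\sum_i v_i = 1$.
Only volume *fractions* ever appear in the models, so absolute organ
volumes are normalized away on input. Bin values are bin-center doses; the
planning-system convention is not standardized, and the choice moves
results by less than one bin width.

Three corrections precede any risk model:

1. **Radiation weighting.** Mean equivalent dose is
   $H_T = \bar w_R D_T$, with $\bar w_R = 1.1$ for the primary proton
   field (doses in Gy (RBE)), $1.0$ for photons, and a patient-specific
   value of order 10 for stray neutrons. The neutron values used here are
   reconstructed from the ratio of the published stray equivalent to
   stray absorbed doses (whole heart: $0.66/0.078 \approx 8.5$ for the HD
   case, $0.26/0.032 \approx 8.1$ for the MB case); the underlying Monte
   Carlo estimates were never published, so these are configuration
   inputs, not authoritative physics.
2. **Uniform neutron bath.** Stray neutron dose inside the patient is
   spatially nearly uniform, so its mean equivalent dose is added as a
   constant shift to every bin of the proton primary DVH
   (`add_uniform_dose()`): volumes are untouched and the mean rises by
   exactly the shift. Photon plans need no separate stray term — the heart
   lies within the 5% isodose region where the planning system itself is
   accurate, so the exported photon DVH already contains it.
3. **Fractionation correction.** Each bin dose is converted to the
   equivalent dose at 2 Gy per fraction (EQD2) with the linear-quadratic
   model at $\alpha/\beta = 3$ Gy for cardiac late effects:
   $D_i \mapsto D_i\,(d_i + \alpha/\beta)/(2 + \alpha/\beta)$ with per-bin
   fraction dose $d_i = D_i/n$. Spreading each bin's dose evenly over all
   $n$ fractions is the standard DVH-wise LQ practice; the source
   methodology does not pin down the per-bin convention, so this package
   states its own. The map is non-linear, so corrected DVHs no longer sit
   on a uniform grid (`bin_width` becomes `NA`).

The processing order for proton DVHs is: primary DVH in Gy (RBE), then the
neutron shift, then EQD2. Applying an LQ correction to an Sv-valued axis
is a documented approximation — the alternative (correcting only the
primary component) differs negligibly at neutron doses of a few tenths of
a Sv, but the order is explicit in `prepare_equivalent_dvh()` so it can be
audited.

## The three risk models

**Linear relative risk.** Cardiac-mortality risk after childhood
irradiation is modelled as $RR = 1 + \alpha_1 D$ on the *mean* heart dose,
with $\alpha_1 = 0.6\ \mathrm{Gy}^{-1}$ (95% CI 0.2–2.5) from a large
childhood-cancer survivor cohort. For protons $D$ is the total mean
equivalent dose (weighted primary plus stray); confidence bounds
substitute the CI limits of the slope.

**Relative seriality (Källman).** Each subvolume responds with the
Poisson form
$$P(D) = 2^{-\exp\!\left(e\,\gamma\,(1 - D/D_{50})\right)},$$
which passes exactly through $P(D_{50}) = \tfrac12$ with maximum
normalized slope $\gamma$. The organ-level probability combines subvolumes
through the seriality parameter $s \in (0, 1]$:
$$\mathrm{NTCP} = \Big[1 - \prod_i \big(1 - P(D_i)^s\big)^{v_i}\Big]^{1/s}.$$
For uniform irradiation this collapses to $P(D)$ for every $s$ — a useful
identity that the tests assert. The product is evaluated in log space
(`log1p`/`expm1`), so per-bin probabilities down to the underflow limit
are handled exactly; organ-level values below $10^{-300}$ are reported
as 0.

**Lyman.** Complication probability is a normal CDF of the standardized
dose, $\mathrm{NTCP} = \Phi(t)$, $t = (D - TD_{50}(V))/(m\,TD_{50}(V))$,
with the partial-volume tolerance dose $TD_{50}(V) = TD_{50}(1)/V^{n}$.
The model is defined for uniform partial-volume irradiation; full DVHs are
reduced with the Kutcher–Burman effective volume
$V_\mathrm{eff} = \sum_i v_i (D_i/D_\mathrm{max})^{1/n}$ evaluated at the
maximum DVH dose — the standard companion reduction, chosen here because
the source methodology feeds full DVHs to the Lyman model without naming a
reduction. A gEUD-at-full-volume alternative is selectable
(`reduction = "geud"`) so the choice can be tested rather than assumed;
for two-level DVHs both coincide with the exact partial-volume formula.

**Comparison ratios.** Plans are compared through
$RRR = RR_\mathrm{proton}/RR_\mathrm{photon}$ and
$RNTCP = \mathrm{NTCP}_\mathrm{proton}/\mathrm{NTCP}_\mathrm{photon}$.
When both NTCP values fall below $10^{-12}$ the ratio is reported as 0
with a `both_zero` flag (the convention of the source tables); a vanishing
photon NTCP alone yields no finite ratio and is flagged `photon_zero`.
Absolute NTCP values are only *reported* when the parameter set was fitted
on the same disease cohort as the case (the Hodgkin-derived sets for the
HD case); for the MB case no cohort-matched parameters exist, so every set
runs but only ratios are presented. Human-readable reports round RR/RRR to
two decimals and RNTCP to two significant figures; all internal arithmetic
is full precision.

## Worked example

```{r example}
hd <- build_case("HD", generator_settings(seed = 1))
run_case(hd)
```

The whole-heart relative risks (7.27 proton vs 8.37 photon, RRR 0.87)
regenerate the published comparison from the mean-dose table alone. The
absolute NTCP values depend on the full DVH shape, which for the original
patients exists only as published figure curves; the synthetic DVHs
reproduce the means exactly and the published ratios qualitatively, but
not the absolute percentages — see "What the generator does and does not
emulate" below.

## Sensitivity analyses

Three uncertainty analyses mirror the source study:

- `sweep_parameters()` evaluates RNTCP over a Cartesian grid of NTCP
  parameters for one structure, with the DVHs processed once and reused —
  the sweep is a pure function of the parameters, so grid order is
  irrelevant. `rntcp_extreme_presets()` carries the published named
  min/max combinations rather than an automatic optimum.
- `sweep_neutron_wr()` rescales the stray neutron equivalent dose by a
  factor grid. Only the proton arm carries a neutron term, so RRR is
  strictly increasing in the factor; `rrr_unity_crossing()` finds the
  factor where the two modalities' risks coincide, which for affine risks
  has the closed form
  $f^\* = (\bar w_{R,\gamma} D_\gamma - 1.1\,D_p)/H_\mathrm{stray}$
  (about 3.77 for the HD whole heart).
- `compare_contour_variants()` re-runs the pipeline on alternative DVH
  inputs. Because the repository has no imaging, thicker-shell
  re-contouring is emulated at the DVH level
  (`perturb_contour_variant()`): the revised pericardium DVH is a
  volume-weighted mixture (weights summing to one) of the baseline
  pericardium and myocardium DVHs, the revised myocardium an equal
  mixture of myocardium and whole heart.

## The synthetic generator: what it emulates and what it does not

The generator exists so the pipeline is testable end to end without
planning-system data. Its defaults encode the study conditions of the two
reference cases and were fixed once:

- **Mean doses** per structure and modality are pinned exactly to the
  published table by a final affine rescale of the dose axis (not by
  rejection sampling), keeping generation deterministic and fast.
- **Shapes** are logistic-cumulative fall-offs with fixed spreads: 3 Gy
  for both HD modalities (broad in-field heterogeneity of a mediastinal
  field arrangement), 2.5 Gy for the MB photon plans (spinal-field exit
  dose), and 0.06 Gy for the MB proton primary dose, which places more
  than 95% of the heart volume below 1 Gy — the near-zero in-field dose
  of proton CSI — while matching the 0.21 Sv mean. Spreads are free knobs
  of the emulation: the real DVH heterogeneity was never published
  numerically.
- **Volume jitter** (lognormal, sd 0.05, seeded) roughens the smooth
  logistic so tests cannot silently depend on smoothness; identical seeds
  give bit-identical DVH files.
- Generation uses a 0.05 Gy bin grid; the exported bin width of the
  original plans is unknown, and results depend on it only weakly.

Consequently: passing tests demonstrate the *pipeline* — bookkeeping
identities, model mathematics, ratio behaviour, and the qualitative
finding that proton CSI keeps every NTCP ratio far below unity across the
published parameter ranges. They do not certify the absolute NTCP
percentages of the original patients, which require the true DVH shapes.
That limitation is inherent to the available inputs, not to the method.

## Numerical choices and degenerate inputs

- Fractional-volume conservation is enforced to $10^{-9}$ everywhere;
  conversions, rebinning and mixing renormalize conservatively (volume
  split proportional to bin overlap).
- The relative-seriality product and the Lyman CDF are floored at
  $10^{-300}$ and reported as 0 below it; the zero/zero ratio regime is
  flagged rather than silently divided.
- `compute_rntcp()` uses $\epsilon = 10^{-12}$ on the probability scale
  as its zero threshold.
- Grid points violating model validity ($s \le 0$, $m \le 0$,
  $n \notin (0,1]$, $D_{50} \le 0$) are skipped with a warning rather
  than clamped.
- Zero-dose DVHs, single-bin DVHs, and a zero-fraction scheme are either
  handled exactly or rejected with a named error; see the tests for the
  catalogue.

Problem sizes in the shipped tests and the acceptance script are small by
construction — six structures, DVHs of a few hundred bins, sweep grids of
a few dozen points — because every quantity of interest is either closed
form or a sum over bins; nothing requires simulation at scale.

## Known limitations

- No DICOM RT import, contouring, or voxel-level dose grids: the DVH is
  the interface.
- NTCP parameters are taken as configuration, never fitted to outcome
  data here.
- The linear RR model extrapolates a mortality endpoint to "cardiac
  toxicity" broadly, inheriting the source cohort's uncertainties — hence
  the wide CI that dominates all absolute statements.
- Ratios (RRR, RNTCP) are the robust outputs; absolute NTCP values are
  suitable for comparing plans, not for predicting outcomes.
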