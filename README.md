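# cardrisk

Predicted risk of radiogenic cardiac toxicity after photon versus proton
radiotherapy, for radiation-physics and outcomes researchers who want the
full comparison pipeline — dose-volume histogram (DVH) processing,
equivalent-dose bookkeeping with stray neutrons, fractionation correction,
three dose-response models, and the sensitivity analyses that go with
them — as tested, reusable R functions.

The package ships the published mean-dose tables of two pediatric
reference cases (a mediastinal Hodgkin-disease plan, 18 fractions, and a
craniospinal medulloblastoma plan, 13 fractions, each planned with 6 MV
photons and passively scattered protons) plus a deterministic synthetic
DVH generator, so everything runs from code alone.

## Models

**Linear relative risk** on the mean heart dose *D* (total equivalent
dose for protons: primary × w̄R 1.1 + stray neutron Sv):

    RR = 1 + α₁·D,   α₁ = 0.6 Gy⁻¹ (95% CI 0.2–2.5)

**Relative seriality** (Källman) NTCP over a differential DVH
{(Dᵢ, vᵢ)}, with seriality s ∈ (0, 1]:

    P(D)  = 2^(−exp(e·γ·(1 − D/D₅₀)))
    NTCP  = [1 − Πᵢ (1 − P(Dᵢ)ˢ)^{vᵢ}]^{1/s}     (log-space evaluation)

**Lyman** NTCP with Kutcher–Burman effective-volume reduction:

    NTCP = Φ(t),  t = (D − TD₅₀(V)) / (m·TD₅₀(V)),  TD₅₀(V) = TD₅₀(1)/Vⁿ
    V_eff = Σᵢ vᵢ·(Dᵢ/D_max)^{1/n}  evaluated at D_max

Modalities are compared through RRR = RR_proton/RR_photon and
RNTCP = NTCP_proton/NTCP_photon. Before any NTCP evaluation a proton DVH
receives the uniform stray neutron equivalent-dose shift and every DVH a
per-bin EQD2 correction (linear-quadratic, α/β = 3 Gy).

## Worked example

```r
library(cardrisk)
hd <- build_case("HD", generator_settings(seed = 1))
run_case(hd)
```

```
Cardiac toxicity comparison, case 'HD'

Relative risk (linear model, mean equivalent dose):
   structure         RR_proton         RR_photon  RRR
 pericardium 8.77 (3.59-33.39) 9.56 (3.85-36.65) 0.92
  myocardium 7.36 (3.12-27.51) 8.34 (3.45-31.58) 0.88
 whole_heart 7.27 (3.09-27.13) 8.37 (3.46-31.70) 0.87
...
```

The whole-heart line is the headline: proton therapy gives RR 7.27
against 8.37 for photons, RRR 0.87 — comparable cardiac risk for the
mediastinal case, because the neutron bath nearly cancels the protons'
dosimetric advantage. The same pipeline on the craniospinal template
(`build_case("MB")`) gives RRR 0.15 and NTCP ratios far below unity:
protons clearly reduce the predicted cardiac risk there. Sensitivity
sweeps (`sweep_neutron_wr()`, `sweep_parameters()`,
`compare_contour_variants()`) show how those ratios respond to the
neutron weighting factor, the NTCP parameters, and contour variants;
`rrr_unity_crossing()` locates the neutron scaling (≈3.77 for the HD
case) at which the two modalities' risks coincide.

A thin command-line wrapper is installed at
`system.file("cli", "cardrisk.R", package = "cardrisk")` with subcommands
`run`, `sweep`, `synth`, `validate` over YAML case configurations.

See `vignettes/cardiac-risk-modelling.Rmd` for the model assumptions,
parameter choices, and what the synthetic DVHs do and do not emulate.

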