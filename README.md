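# siclimate

A coupled global carbon–silica cycle model for exploring how the collapse of
the marine biological silica factory can sustain multi-million-year warmth.

## The problem

At the end-Permian, rapid volcanic CO2 release drove >10 °C of warming — and
then temperatures stayed high for over five million years, far longer than
the silicate-weathering feedback should allow. This package implements and
tests a mechanism that can hold the Earth system in such a hyperthermal:
with silicifying organisms (radiolarians, siliceous sponges) wiped out,
dissolved silica accumulates in seawater and marine authigenic clay
formation (**reverse weathering**) accelerates. Clay formation consumes
alkalinity while leaving dissolved inorganic carbon untouched, converting
HCO3⁻ back to CO2: a carbon *recycling* flux with no isotopic fingerprint
that raises the steady-state pCO2 the silicate-weathering feedback can reach.

It is intended for paleoclimate and biogeochemistry researchers who want a
transparent, fully scriptable desk-scale implementation of the coupled
model, its Monte Carlo ensemble machinery, and the associated
sedimentological analyses.

## The model in brief

Two ocean boxes (surface, deep) plus an atmosphere carry pCO2, DIC, total
alkalinity TA, dissolved silica DSi, and δ¹³C. Core flux laws:

- Weathering: `F_silw = F_vc (pCO2/pCO2c)^n_si`,
  `F_carbw = F⁰ (pCO2/pCO2c)^n_carb`
- Biogenic silica production: `F_bSip = k_bSi · Vmax [Si] / (Km + [Si])`
  (Michaelis–Menten; Vmax = 1.74, Km = 74.48 µM)
- Opal dissolution: `F_bSid = F_in (1 − [Si]/ς)^ρ`
  (ς = 0.9 mM; ρ = 5.5 water column, 0.4 sediment)
- Reverse weathering: `F_rw = (β + α)(Ω_rw − o)` with
  `Ω_rw = ([Si]^r_si/[H⁺]^r_H) / ([Si]₀^r_si/[H⁺]₀^r_H)`,
  consuming `Alk:Si × F_rw` alkalinity
- Abiotic silica: `F_iSi = (β + α)([Si]_ssw/∂ − 1)^1.1` above the onset
  threshold ∂

Without clay alkalinity consumption the system equilibrates at
`pCO2 = pCO2c` exactly; any reverse weathering pushes the steady state above
it. An extinction scenario (linear initiation ramp, full-extinction
interval, linear recovery, plus a volcanic carbon pulse) can be run with the
clay flux **frozen** at its spin-up value or **dynamic**; Monte Carlo
ensembles over the documented parameter ranges are filtered against a
sea-surface-temperature target curve (±4 °C, ±0.4 Myr). An independent
end-member mixing model (`f_s = M_a f_a + M_d f_d`) connects
sediment-expressed clay:quartz ratios to the authigenic component, and
helpers compute those ratios from mineral-abundance tables (cation-bearing
clays vs quartz, kaolinite excluded) and chert-occurrence fractions by age
bin, lithology and paleolatitude.

## Worked example

```r
library(siclimate)

## modern calibration: reproduces the present-day silica budget
st_modern <- spin_up(default_params("modern"))
print(st_modern)
#> <frw_state> pCO2 295.7 ppm, F_rw 5.38, F_bSi_sed 82.64 Tmol/yr, accepted=TRUE

## Permian background, then the extinction scenario both ways
st <- spin_up(default_params("permian"))
print(st)
#> <frw_state> pCO2 718.9 ppm, F_rw 9.24, F_bSi_sed 45.43 Tmol/yr, accepted=TRUE

scen <- extinction_scenario()          # 42,500 Pg C over 1.5e5 yr at 5 Myr
run_dyn <- run_scenario(st, scen, dynamic_rw = TRUE)
print(run_dyn)
#> <frw_run> 631 samples over 17.1 Myr, dynamic clay formation
#>   peak warming 15.0 C, peak f_rw_ma 1.00, peak residence x4.1

run_frozen <- run_scenario(st, scen, dynamic_rw = FALSE)
cat(sprintf("warm plateau (>8 C) dynamic: %.1f Myr, frozen: %.1f Myr\n",
  warm_duration(run_dyn, 8) / 1e6, warm_duration(run_frozen, 8) / 1e6))
#> warm plateau (>8 C) dynamic: 6.2 Myr, frozen: 0.0 Myr

## sediment mixing model with the observed post-extinction window
mx <- sample_and_filter(n = 500000, post_range = c(0.2, 0.3), seed = 1)
print(summarize_mixing(mx$post))
#> <frw_mixing_summary> 86180 accepted draws
#>   m_d min 0.000  mode 0.738  median 0.577  max 0.937
#>   m_a min 0.063  mode 0.263  median 0.423  max 1.000
#>   f_a min 0.200  mode 0.312  median 0.471  max 1.000
```

Reading the numbers: the modern spin-up lands the reverse-weathering flux
(5.4 Tmol Si/yr) and biogenic silica sediment export (82.6 Tmol Si/yr) on
the present-day budget. Under identical volcanic forcing, the dynamic-clay
run holds a >8 °C warm plateau for 6.2 Myr with the carbon residence time
rising ~4-fold, while the frozen-clay run peaks at +7 °C and relaxes within
a few hundred kyr — the core contrast the model exists to demonstrate. In
the mixing model, no accepted draw has an authigenic-component ratio below
0.200: sediment ratios of 0.2–0.3 with detrital inputs ≤0.15 *require* an
authigenic end member at or above 0.2.

Ensembles, the temperature filter, mineral/chert analyses and the
synthetic-data generators are documented in the methods vignette
(`vignettes/carbon-silica-model.Rmd`) and on the help pages
(`?run_ensemble`, `?filter_by_temperature`, `?section_frw_profile`,
`?make_sst_target`). A thin command-line wrapper ships at
`inst/cli/siclimate.R`.

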