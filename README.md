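# migrisk

Chemical additives compounded into polymer food-contact films —
plasticisers, stabilisers, flame retardants — slowly migrate into the
packaged food, and only the fraction released from the food matrix
during digestion is available for uptake. `migrisk` implements this
packaging–food–digestion chain as a tested R pipeline for risk
assessors and food-contact-material researchers:

1. **Migration kinetics.** One-dimensional Fickian diffusion out of a
   film of thickness *L* (sealed back face) into a finite, well-stirred
   food phase. The transferred fraction is the classical finite-bath
   eigenfunction series

   *M*<sub>F,t</sub>/*M*<sub>F,∞</sub> = 1 − Σ<sub>n</sub>
   [2α(1+α)/(1+α+α²q<sub>n</sub>²)] · exp(−D·t·q<sub>n</sub>²/L²),

   with tan q<sub>n</sub> = −α·q<sub>n</sub> and
   α = V<sub>F</sub>/(K<sub>P/F</sub>·V<sub>P</sub>) the food-phase
   capacity ratio; the observable migration ratio is
   MR(t) = 100·α/(1+α)·*M*<sub>F,t</sub>/*M*<sub>F,∞</sub> percent.
   `fit_migration()` estimates D (cm²/s) and α (hence K<sub>P/F</sub>)
   from migration time series and returns a classed model object with
   the usual `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/
   `simulate` methods. An independent finite-difference solver of the
   same boundary-value problem (`fd_fraction()`) serves as the built-in
   cross-check of the series.

2. **Bioaccessibility.** BA(%) = 100·C<sub>d</sub>V<sub>d</sub> /
   (C<sub>s</sub>V<sub>s</sub>) from simulated-digestion measurements,
   with per-batch procedural-blank correction and replicate summaries
   (`ba_from_digestion()`, `summarize_ba()`).

3. **Exposure and risk.** Bioaccessibility-adjusted estimated daily
   intake EDI = V·C<sub>p</sub>·(MR<sub>f</sub>/100)·m<sub>p</sub>·10³/BW
   · (BA/100) ng/kg bw/day and hazard quotient HQ = EDI/RfD
   (`assess_exposure()`, `risk_summary()`), against a per-compound
   reference-dose registry.

Seeded synthetic-data generators reproduce the study design (5
organophosphate flame retardants × 9 foods, triplicate curves over
0.5–72 h at 40 °C, digestion with blank contamination), and the
published parameter and risk tables ship as plain-text fixtures, so the
whole chain is testable offline. A configuration-driven pipeline
(`run_simulate()` → `run_fit()` → `run_ba()` → `run_risk()`, plus the
CLI in `inst/cli/migrisk.R`) ties the stages together with manifests.

## Worked example

Fit a noisy synthetic migration curve for the reference pair
(TPhP in the "Eastern leaf" beverage; true D = 8.00×10⁻¹¹ cm²/s,
α = 0.328), then summarise digestion data and rank risks:

```r
library(migrisk)
sys   <- contact_system()                      # 80 um film, 15 mL food, 6 dm2/L
truth <- migration_truth()
row   <- truth[truth$food == "Eastern leaf" & truth$compound == "TPhP", ]
d     <- generate_migration_dataset(row, cv = 0.05, n_replicates = 3, seed = 7)
fit   <- fit_migration(mr_percent ~ time_h, d, sys)
summary(fit)
#> Finite-bath Fickian migration fit
#>   mode: co_fit_alpha, n = 24, converged: TRUE
#>   D = 8.736e-11 cm2/s, alpha = 0.3289, K_P/F = 633.4
#>   equilibrium plateau 24.75 %, R2 = 0.9857, RMS residual 0.808 %
```

With 5% replicate noise the fitted D lands within ~9% of the generating
value and the plateau (24.75%) recovers the true equilibrium fraction
100·0.328/1.328 = 24.7%. Risk assessment on the packaged intake table:

```r
edi <- load_fixture("edi_table3")
res <- data.frame(compound = edi$compound, food = edi$food,
                  scenario = edi$scenario, edi = edi$edi_ng_kg_bw_day,
                  hq = hazard_quotient(edi$edi_ng_kg_bw_day,
                                       rfd_registry()[edi$compound]))
risk_summary(res)
#> Worst-case hazard quotient per compound:
#>  compound         food scenario   edi      hq
#>      TPPO       Baijiu      p95  3554   0.178
#>     TBOEP Eastern leaf      p95  2264   0.151
#>      TnBP Cooking wine      p95 572.1  0.0572
#>      TPhP Cooking wine      p95 519.8 0.00743
#>     EHDPP      Vinegar      p95 28.84 0.00481
#>
#> All hazard quotients below 1 (acceptable risk range).
```

All hazard quotients sit below 1 — acceptable risk at the assessed
0.1 g/kg incorporation level — with TPPO and TBOEP closest to the
threshold (HQ 1.78×10⁻¹ and 1.51×10⁻¹ under high consumption), the
compounds worth watching.

`run_reproduce()` prints a pass/fail table re-deriving every
self-consistent published hazard-quotient anchor plus the
parameter-table consistency statistic.

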