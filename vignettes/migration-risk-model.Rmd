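---
title: "From packaging to digestion: the migration, bioaccessibility and risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From packaging to digestion: the migration, bioaccessibility and risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrisk)
```

`migrisk` models the chain by which an additive compounded into a polymer
food-contact film ends up as a dose in a consumer: diffusion out of the
film into the food, release from the food matrix during digestion, and
the resulting intake relative to a toxicological reference dose. This
vignette explains the model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## The migration model

Transport of the additive through the film is one-dimensional Fickian
diffusion,

$$\frac{\partial C}{\partial t} = D \frac{\partial^2 C}{\partial x^2},$$

with a constant diffusion coefficient $D$ (cm²/s). The physical
assumptions are: the additive starts uniformly distributed in the film;
migration occurs only across the film–food interface (the back face is
sealed, appropriate for a thin film in single-sided contact); the film
does not swell; and the food phase is well stirred, of finite volume
$V_F$, so its concentration rises as material arrives (a *finite bath*,
as opposed to the infinite-bath assumption appropriate for a large or
strongly absorbing food simulant).

At equilibrium the additive partitions between polymer and food with
partition coefficient $K_{P/F} = C_{P,\infty}/C_{F,\infty}$. The
dimensionless capacity ratio of the food phase is

$$\alpha = \frac{V_F}{K_{P/F}\,V_P},$$

which is exactly the equilibrium mass ratio $m_{F,\infty}/m_{P,\infty}$:
the fraction of the total additive that ever migrates is
$\alpha/(1+\alpha)$, the plateau of the migration-ratio curve.

A remark on the direction of this relation. Either convention
($\alpha \propto K$ or $\alpha \propto 1/K$) appears in print, and one
occasionally finds the two mixed within one source. The form above is
forced by internal consistency: with $K$ defined polymer-over-food, a
compound that prefers the polymer (large $K$) must have a low migration
plateau (small $\alpha$), and the packaged parameter table obeys exactly
this — the product $\alpha \times K_{P/F}$ is constant across all 45
compound–food pairs (coefficient of variation 0.62%), as $\alpha K = V_F/V_P$
requires, whereas $\alpha/K$ is not. `migrisk` therefore uses
$\alpha = V_F/(K\,V_P)$ throughout, and the data-integrity test asserts
the product constancy. Note the empirical product (~250) differs from the
nominal cell geometry $V_F/V_P = 15\,\mathrm{mL}/0.072\,\mathrm{cm^3} = 208.3$;
the package keeps the two separate — geometry-derived conversions use
208.3, and tests against the printed table use the table's own product —
and does not attempt to explain the gap (an effective contact volume or a
fitting convention in the source data are both possible).

With these boundary conditions the fraction of the equilibrium-migratable
amount transferred by time $t$ has the classical eigenfunction series

$$\frac{M_{F,t}}{M_{F,\infty}} = 1 - \sum_{n=1}^{\infty}
  \frac{2\alpha(1+\alpha)}{1+\alpha+\alpha^2 q_n^2}
  \exp\!\left(-\frac{D\,q_n^2\,t}{L^2}\right),$$

where $L$ is the film thickness and $q_n$ is the $n$-th positive root of
$\tan q_n = -\alpha q_n$. The observable migration ratio is
$\mathrm{MR}(t) = 100\,\frac{\alpha}{1+\alpha}\,M_{F,t}/M_{F,\infty}$ percent.

## Numerical choices

**Roots.** Each $q_n$ lies in $((n-\tfrac12)\pi, n\pi)$ and is unique
there. `solve_roots()` bisects the equivalent smooth function
$\sin q + \alpha q \cos q$ (finite at both bracket ends, unlike $\tan$),
then polishes with Newton steps — no initial guesses, no convergence
luck. The residual in the $\tan$ form is reported per root; because its
conditioning degrades like $1+\alpha^2 q_n^2$, the $10^{-10}$ residual
bound is enforced only where double precision can attain it, while the
roots themselves are always accurate to machine precision in $q$.

**Series truncation.** Terms are accumulated until the next one falls
below $10^{-12}$, with a hard cap of 200 terms. At $t = 0$ the value 0 is
returned exactly by convention (the coefficient identity
$\sum_n 2\alpha(1+\alpha)/(1+\alpha+\alpha^2q_n^2) = 1$ holds only in the
infinite sum; the tests verify it numerically to the expected $1/N$ tail
bound). If the cap is hit while terms are still above the bound — which
happens only at extremely small $D t/L^2$ — the result is flagged
`underresolved` rather than silently returned.

**Independent reference solver.** `fd_fraction()` solves the same
problem by a conservative finite-volume discretisation of the PDE with
the bath attached as a lumped capacity at the surface node, integrated
with a banded implicit ODE solver (no stability restriction; `nx`
controls only spatial resolution). The discrete total mass is conserved
to solver tolerance (~$10^{-14}$ relative in the shipped checks).
Series and solver agree to better than $10^{-4}$ absolute over
$Dt/L^2 \in [10^{-3}, 10]$ and $\alpha \in [0.05, 10]$ at the default
`nx = 400`, and both collapse onto the textbook infinite-bath series at
$\alpha = 10^6$. Because the two routes share nothing but the physics,
this is the primary correctness argument for both.

**Fitting.** `fit_migration()` minimises the sum of squared
migration-ratio residuals over $\log_{10} D \in [-13, -9]$ and (in the
default `co_fit_alpha` mode) $\log_{10}\alpha$, with a coarse grid
search over $\log_{10} D$ in half-decade steps before L-BFGS-B and a
Nelder–Mead polish. The log parameterisation keeps both parameters
positive and makes the grid meaningful across four decades. The
alternative mode `fix_alpha_from_plateau` pins
$\alpha_0 = \mathrm{MR}_{\mathrm{last}}/(100-\mathrm{MR}_{\mathrm{last}})$
and fits only $D$; it is the right choice when the curve has visibly
equilibrated, but at the reference parameters ($D = 8\times10^{-11}$
cm²/s, $L = 80$ µm) the 72 h point still sits ~6% below the plateau,
which is why co-fitting is the default. Whether the source fits fixed or
co-fitted $\alpha$ is not stated; both are provided. Degenerate inputs
(fewer than 4 distinct times, an all-zero curve) error out; an optimiser
failure returns the best candidate flagged `converged = FALSE`.

Time units are hours at every user interface and seconds internally; $D$
is always in cm²/s.

## Geometry and defaults

| Parameter | Default | Meaning |
|---|---|---|
| $L$ | $8\times10^{-3}$ cm | film thickness (80 µm), single-sided contact |
| area | 9 cm² | 3 cm × 3 cm specimen |
| density | 0.90 g/cm³ | polypropylene |
| loading | 100 µg/g | additive incorporation 0.1 g/kg |
| $V_F$ | 15 mL | food volume (S/V = 6 dm²/L, the standard test condition) |
| temperature | 40 °C | metadata only — no Arrhenius extrapolation |
| times | 0.5, 1, 2, 4, 6, 24, 48, 72 h | default sampling grid |

These give an initial additive amount $m_i = 6480$ ng per specimen, the
denominator of the migration ratio.

## Bioaccessibility

Digestion is treated purely as measurement arithmetic — no enzyme
kinetics, pH staging or micelle chemistry. For a food spiked at $C_s$
(ng/mL) in volume $V_s$ and digested into a mixture of volume $V_d$ with
supernatant concentration $C_d$,

$$\mathrm{BA}(\%) = 100\,\frac{C_d V_d}{C_s V_s}.$$

Only the products matter, so the unrecorded dilution factor of a static
oral+gastric+intestinal digestion is inert; the generator defaults to
$V_s = 5$ mL and $V_d = 8 V_s$ (the 1:1 dilution bookkeeping of the
standard static protocol). Measured concentrations are corrected by
subtracting the per-batch procedural-blank value (the batch mean by
default, configurable to the maximum), floored at zero and flagged when
flooring occurred; BA values above 100% are kept and flagged, not
truncated. Replicates are summarised as mean ± sample SD with $n$.

## Exposure and risk

The intake of a compound through one food is
$\mathrm{EDI} = V C / BW$ (ng/kg bw/day) with $V$ the daily consumption
(kg/day) and $BW = 60$ kg. Expressed through the packaging chain, with
$C_p$ the additive content of the packaging (µg/g), $m_p$ the packaging
mass per kg food (g/kg) and $\mathrm{MR}_f$ the final migration ratio:

$$\mathrm{EDI} = \frac{V \cdot C_p \cdot (\mathrm{MR}_f/100) \cdot m_p \cdot 10^3}{BW}
  \cdot \frac{\mathrm{BA}}{100},$$

and $\mathrm{HQ} = \mathrm{EDI}/\mathrm{RfD}$, acceptable below 1.
$\mathrm{MR}_f$ defaults to the model value at the last contact time
(72 h), configurable to the fitted equilibrium plateau. The default
$m_p = 4$ g/kg is adopted from the source assessment even though the
test-cell geometry (6 dm²/L × 80 µm × 0.9 g/cm³) gives 4.32 g/kg; the
discrepancy is documented here and $m_p$ is configurable.

Per-food daily consumptions are not part of the packaged tables. For
demonstration runs `derive_consumption()` inverts the EDI relation
against the packaged intake table (per-food median over compounds, or
exact per-pair inversion for chain-validation runs); a real assessment
must supply its own consumption table. The high-consumption scenario is
a per-food multiplier on the median intake, defaulted from the packaged
table's own 95th/median ratios — these are constant *within* each food
(≈2.5 for the aqueous foods, 3 for vinegar, beer, cooking wine and
coconut milk, 3.33 for baijiu, 4 for soy milk) but not across foods,
which is why the multiplier is per food rather than a single global 2.5.

The packaged intake/HQ table is shipped verbatim, including its internal
inconsistencies: several foods' HQ columns are row-permuted relative to
their EDI columns (vinegar with soy milk, beer with baijiu, cooking wine
with coconut milk) and one HQ entry carries an apparent exponent typo.
These are attached as errata metadata on `load_fixture("edi_table3")`,
never repaired, and only the self-consistent food blocks are used as
numerical anchors.

## The synthetic-data generator

`generate_migration_dataset()` draws replicate migration curves from the
series model at the ground-truth $(D, \alpha)$ of the packaged parameter
table; `generate_digestion_dataset()` draws digest concentrations whose
noise-free bioaccessibility equals a per-compound ground truth, plus
procedural-blank contamination at the documented background levels for
the three affected compounds. Both apply multiplicative lognormal noise
with mean 1 and coefficient of variation 0.05 (triplicates), chosen as a
realistic replicate-level spread for an LC–MS workflow reported as
mean ± SD of $n = 3$; the lognormal keeps concentrations positive
without truncation. All generators are pure functions of (truth, config,
seed).

The bioaccessibility ground truth itself is synthetic: the source
reports only the compound ordering TPPO > TBOEP > TnBP > TPhP > EHDPP,
so the defaults 85/75/65/50/30% encode that ordering with ≥5-point
spacing and are constant across foods. Consequently the generator
emulates the *structure* of the study (design, replication, noise,
blanks, orderings) but not unpublished numeric levels, and it does not
emulate food-matrix effects on BA, non-Fickian migration, matrix
interferences, or instrument drift. Passing the recovery tests therefore
demonstrates that the estimators are unbiased and stable under the
modelled noise — not that real digests behave this simply.

## Validation problem sizes

The shipped checks run at sizes chosen to exercise the numerics
honestly while staying quick: series-vs-solver agreement on a 15-point
log grid of $Dt/L^2 \in [10^{-3},10]$ for five $\alpha$ values at
`nx = 400`; noiseless round-trip refits of the reference pair (8 time
points); 100 seeded noisy refits (cv 0.05, $n = 3$) for the stochastic
recovery statement (median relative error of $D$ well under 15%); and
noiseless simulate–fit–digest–risk chain runs over the two
self-consistent food blocks (10 compound–food pairs) for the end-to-end
reproduction of the published hazard quotients, with the full 45-pair
design exercised by the generator and ordering checks.

## Known limitations

- Constant $D$ and $K$: no swelling, no concentration dependence, no
  temperature extrapolation, no multilayer films.
- The finite-bath model assumes a perfectly stirred food; partially
  stirred or gelled foods violate it in the direction of slower apparent
  migration.
- Digestion is bookkeeping only; the bioaccessibility defaults are
  ordering-faithful placeholders, not measurements.
- Exposure is per food, deterministic, single-population (60 kg adult);
  no Monte Carlo, no aggregation across foods, no age stratification.
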