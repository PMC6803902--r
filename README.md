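# cdretain

Equilibrium modelling and quantification of cyclodextrin (CD) retention of
volatile phenols in model wine, measured by four-phase headspace SPME GC-MS.

## The problem

Volatile phenols (guaiacol, cresols, ethylphenols, eugenol) are the marker
compounds of smoke taint and *Brettanomyces* spoilage in wine. Cyclodextrins
can trap them as 1:1 host–guest inclusion complexes, lowering their headspace
concentration and sensory impact. Measuring *how much* is trapped defeats the
standard stable-isotope-dilution HS-SPME assay: a deuterated internal
standard spiked into the sample is captured by the CDs in the same proportion
as the analyte, so the relative peak area RPA = A_s/A_i never moves — every
treatment reads 100% of control while the absolute signal collapses. The
remedy modelled here isolates the standard in a glass ampoule inside the
vial: a fourth phase that talks to the analysis only through the headspace,
out of the CDs' reach.

`cdretain` is for analytical chemists and modellers who want to simulate,
quantify, and invert such experiments without an instrument.

## The model

Each compound obeys the four-phase mass balance

    C0·Vs = Cs·Vs + Ci·Vi + Ch·Vh + Cf·Vf

with dimensionless partition constants K1 = Cs/Ch (sample/gas, Henry),
K2 = Ch/Cf (gas/fiber) and K3 = Ci/Ch (ampoule liquid/gas, default K3 = K1).
With 1:1 CD binding (constant k_b, L/mol) confined to the sample and free
host concentration h, the closed form per compound is

    Ch = C0·Vs / ( K1·Vs·(1 + k_b·h) + Vh + Vf/K2 + K3·Vi )

and h solves the host mass balance by bisection (unique root, relative
tolerance 1e-12). Special cases: the two-phase identity Ch = C0/(K + β) with
phase ratio β = Vh/V_liquid; the short-extraction mode where nothing crosses
the ampoule wall; and the conventional three-phase mode where the standard is
co-dissolved and treatment effects cancel exactly — the package reproduces
that null result analytically.

On top of the solver sit: RPA/calibration/retention quantification with
one-way ANOVA and compact letter displays, a seeded synthetic peak-area
generator with multiplicative lognormal noise, inversion of apparent binding
constants from observed retention percentages (with Monte Carlo recovery
diagnostics), and exact binomial triangle-test statistics.

## Worked example

```r
library(cdretain)

vial <- vial_config(V_total = 20, V_s = 6, V_i = 0.5)
vial
#> <vial_config> V_total = 20 mL, V_s = 6, V_i = 0.5, V_f = 0.00066, V_h = 13.5
#>   beta_s = 2.25, beta_i = 27
```

The ampoule phase ratio is 27, the sample's 2.25; with Henry constants
around 2.2e4 neither matters much to the headspace — the design argument for
the ampoule.

```r
kb <- default_binding_constants()   # inverted from the reference table
head(kb[kb$cd == "beta", ], 3)
#>            compound   cd        kb percent_source
#> 9          guaiacol beta  13.18952           77.5
#> 10 4-methylguaiacol beta  19.65512           69.8
#> 11    4-ethylphenol beta 151.32135           23.1

cps <- default_compounds()
predict_retention(151.32, 25, cps[["4-ethylphenol"]], "beta")
#> [1] 23.10016
```

The derived constants round-trip: 151.3 L/mol reproduces the observed 23.1%
retention of 4-ethylphenol at 25 g/L beta-CD. Now the full pipeline —
simulate the triplicate dose experiment with 3% peak-area noise, summarize
retention, and refit the constants:

```r
study <- reproduce_retention_study(seed = 1, cv = 0.03)
study$overall
#>   treatment overall_mean_percent
#> 1   alpha-5             95.39003
#> 2  alpha-25             79.22185
#> 3    beta-5             79.21379
#> 4   beta-25             47.46651
#> 5   gamma-5             86.29220
#> 6  gamma-25             54.82876
```

beta-CD at 25 g/L halves the average phenol headspace (the reference value
is 48.4%); 5 g/L arms are genuine model extrapolations. The sensory panel
counts give exact binomial evidence of a perceptible difference:

```r
triangle_test(24, 38)
#>  Exact binomial triangle test (guessing probability 1/3)
#> data:  24 correct of 38 panelists
#> correct = 24, panelists = 38, p-value = 0.0001606
#> decision: difference perceived (reject guessing) at alpha = 0.05
```

See the vignette (`vignettes/cd-retention-model.Rmd`) for the model's
assumptions, parameter defaults, and limitations.

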