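# hpkinetics

Real-time metabolic phenotyping of CAR T cell cultures by NMR, in R.

During a 21-day CAR T expansion, the cells' metabolism swings from
oxidative phosphorylation into aerobic glycolysis (the Warburg shift)
and back. Two NMR readouts capture this: dynamic hyperpolarized
(dissolution-DNP) carbon-13 series, in which an injected labeled
substrate such as [U-13C,2H]glucose is watched converting to
[1-13C]lactate in real time, and proton-NMR quantification of spent
versus fresh culture medium at every feed. `hpkinetics` implements the
computation for both: the kinetic model and its estimation, spectrum
synthesis and reduction, internal-standard quantification, and
synthetic-data generators with embedded ground truth so every stage is
testable without the original raw data. It is aimed at NMR
spectroscopists and immunometabolism groups who want a transparent,
tested reference implementation of this analysis.

## The model

The hyperpolarized substrate pool S converts unidirectionally to the
product pool P while both relax and are depleted by RF sampling:

    dS/dt = -k S - S/T1_s - p S
    dP/dt =  k S - P/T1_p - p P,      p = (1 - cos pw)/TR

Fitting sets `p = 0` (robust at low SNR), so the fitted T1s are
*apparent* values that fold in the pulsing losses; true T1s are
recovered afterwards via `1/T1_true = 1/T1_app - (1 - cos pw)/TR` using
the effective flip angle. The rate constant k is the glycolytic-flux
readout. Medium metabolites are quantified against a DSS internal
standard (0.644 mM buffer, 500 + 100 µL mixing, 9 reference protons)
and reported in the original supernatant frame as consumption
(fresh − spent) profiles over the feed schedule.

See `vignettes/methods.Rmd` for the full account: assumptions,
parameter defaults, the exactness of the flip-angle folding, generator
design, and limitations.

## Worked example

Simulate a pyruvate-run dynamic experiment at its reported operating
point (k = 10.7e-5 /s, apparent T1 30/16 s, effective flip angle 8°,
TR 2 s, 120 scans, 1% per-trace noise), re-fit it, and correct the T1s:

```r
library(hpkinetics)

sc <- hp_preset("fig1a_pyruvate", seed = 42)
series <- generate_dynamic(sc)
fit <- fit_two_pool(series)
fit
#> <fit_result> k = 0.0001052 /s, T1app(S) = 29.7 s, T1app(P) = 16.2 s
#>   R2 = 0.9979 (S) / 0.9993 (P), converged: TRUE, n = 120

correct_T1_apparent(fit$params_hat$T1_substrate_s, sc$acq)
#> [1] 34.68737
fold_change(5.278e-5, 1.146e-5)   # day-7 over day-14 rate constants
#> [1] 4.605585
```

The fitted rate lands within 2% of the generating truth, the R²
values match what dynamic series of this quality support, and the
flip-angle correction recovers the true substrate T1 (a 30 s apparent
value corresponds to 35.1 s true at these settings; the fitted 29.7 s
corrects to 34.7 s). The 4.6-fold ratio is the headline early-vs-late
glycolytic flux decrease.

## Analysis workflow

The `analysis/` scripts run the full story end to end, writing tables
under `results/`:

1. `01_simulate.R` — dynamic runs at the reported operating points
   (three donor replicates for day 7 and day 14) plus the 21-day
   supernatant panel.
2. `02_fit_kinetics.R` — kinetic fits, flip-angle T1 correction, the
   day-7/day-14 fold change and paired two-tailed t-test.
3. `03_summed_spectra.R` — summed-spectra quantification for low-flux
   runs with the SNR ≥ 3 detectability rule and the day-14 → day-21
   flux fold change.
4. `04_exometabolome.R` — spent-vs-fresh consumption profiles: the
   near-complete glucose use through day 10, its collapse after the day
   10–12 metabolic shift, and the lactate/TCA-intermediate pattern.

Run them in order with `Rscript analysis/01_simulate.R` etc. from the
repository root.

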