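# coopdiscern

Tools for deciding whether time-resolved ligand-binding data from a
two-site receptor arise from **negative cooperativity** between identical
sites (NC) or from two **independent sites** of different affinity (IB).

The two mechanisms are equilibrium-indistinguishable: for every NC
parameter set with cooperativity factor ω < 1 there is an IB set with
exactly the same equilibrium dose-response curve, related by

    K10·K01 = K²/ω,    (K10 + K01)/2 = K/ω
    K10,01 = (K/ω)(1 ± √(1−ω)),

so equilibrium titrations cannot separate them. They do differ before
equilibrium. The package's central observable is the **dynamic range** of
the dose-response curve as a function of time after a ligand step,

    DynR(t) = log10( EC90(t) / EC10(t) ),

where ECx is the dose giving x% absolute site occupancy (a single
Langmuir site has equilibrium DynR = log10 81 ≈ 1.91). Three numerically
established facts drive the discrimination: NC target curves DynR(t) are
always increasing; DynR(t→0) depends only on ω for NC and only on
k10/k01 for IB; and the inflection time of an increasing NC target curve
scales inversely with the unbinding rate l.

The pipeline combines

* exact deterministic and stochastic (Gillespie-equivalent) simulators of
  both mass-action models (`simulate_ode()`, `simulate_gillespie()`);
* extraction of the DynR(t) *target curve* and its diagnostic features
  (`target_curve()`);
* a Latin-hypercube scan of the non-identifiability manifold with
  numerical lookup curves and calibrated decision thresholds
  (`lhs_scan()`, `build_database()`, `calibrate_thresholds()`);
* the TC algorithm — equilibrium fit, constrained kinetic fits of both
  models, and an F-statistic C that is ≈1 when IB fits far better, ≈0
  when NC does, ≈½ when comparable (`tc_fit()`);
* a sequential checkpoint cascade on the target curve for the undecided
  band, returning an audited verdict (`discriminate()`);
* a benchmarking harness across receptor copy numbers
  (`benchmark()`, `checkpoint3_error()`, `checkpoint2_standalone()`).

Intended users: quantitative biochemists and systems biologists with
step-stimulation binding time courses (e.g. SPR-style θ(L, t) surfaces)
who suspect two binding events and want to know which microscopic scheme
explains them.

## Worked example

```r
library(coopdiscern)

## reference database on the non-identifiability manifold
pairs <- lhs_scan(500, seed = 42)
db <- build_database(pairs)
db <- calibrate_thresholds(db, r0 = 1000, n_cal = 20, seed = 7)
db
#> Manifold DynR(t) database: 500 pairs (1000 feature rows, 0 failed)
#>   thresholds: dDynR0_NC = 0.176, dDynR0_IB = 0.142, dtip = 2.581 [calibrated at R0 = 1000]

## a stochastic NC dataset (1000 receptors, 20 doses, 41 times)
data <- make_fixture("nc", r0 = 1000, seed = 3)
target_curve(data)
#> DynR(t) target curve: 41/42 valid times; shape = increasing
#>   DynR(t->0) = 1.6177 (unreliable), DynR(t->inf) = 2.2056, t_ip = 3.687

discriminate(data, db)
#> Decision: NC (via tc)
#>   C = 0.0241; omega_hat = 0.6085, k10/k01_hat = 0.3578, l_hat = 0.1858
#>   DynR(t->0) = 1.618 (NC pred 1.478, IB pred 1.474); t_ip = 3.687
```

Reading the output: the target curve rises from 1.62 to 2.21 decades —
wider than a single site's 1.91, so two binding events with an effective
ω < 1 are in play. The constrained NC fit beats the constrained IB fit
decisively (C = 0.024 < 1/3), so the cascade stops at the TC stage with
verdict NC; had C landed in [1/3, 2/3], the shape, early-range and
inflection-time checkpoints would have been compared against the
database predictions shown on the last line.

A thin command-line interface wraps the same functions
(`exec/coopdiscern`): `simulate`, `target-curve`, `build-db`, `tc`,
`discriminate`, `benchmark`, `make-fixture`.

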