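# obscstr

Observability and detectability analysis of a non-linear, uncertain
continuous stirred tank reactor (CSTR) model of aerobic biochemical
processes — the aggregated biomass/substrate/dissolved-oxygen balance model
used as a cognitive stand-in for a wastewater-treatment bioreactor.

The package is aimed at people who design state observers for bioprocesses
and need to know, *before* building an estimator, which measured output makes
which states reconstructible when the reaction kinetics are uncertain.

## The model and the question

States `ν₁ = X` (biomass), `ν₂ = S` (substrate), `ν₃ = O` (dissolved
oxygen), all g/L; known inputs `u₁ = D(t)` (dilution) and `u₂ = kLa(t)`
(oxygen transfer), 1/h. The uncertain Monod kinetics `r = μ_SO(t)·X` (its
parameters are bounded, positive, time-varying, unknown) is replaced by an
exactly known substitute Monod function `μ̂` with midpoint constants, and the
mismatch is eliminated into a bounded scalar unknown input

    Δ(ν, t) = [μ_SO(t) − μ̂(ν)]·ν₁,

acting along the constant direction `ρ = (1, −1/Ys, −1/Yo)ᵀ`, giving the
affine form `ν̇ = φ̂(ν) + ϑ₁(ν)u₁ + ϑ₂(ν)u₂ + ρΔ`. For each of the **nine
cases** (measured output ν₁/ν₂/ν₃ × substitute form μ̂_S/μ̂_O/μ̂_SO) the
package answers whether each state — and the unknown input — is observable,
detectable, or neither, using

1. a **differential-geometry stage**: Lie-derivative observability map
   `[h, L_φ̂h, L²_φ̂h]`, its Jacobian, numeric rank profiling over the
   invariant box, and the matching condition `L_ρh ≠ 0`;
2. an **indistinguishable-dynamics stage**: the 6-dimensional error system
   between the model and a structurally identical copy, reduced to a DAE by
   imposing zero measured error, then classified by structural rules
   (with and without the unknown-input difference `δΔ`);
3. **paired ODE simulation** verifying every observable/detectable label
   (closed-form envelopes, paired-difference oracles, terminal-window
   convergence).

## Worked example

Geometric stage for case 1 (oxygen measured, oxygen-only substitute form):

```r
library(obscstr)
m1 <- case_model(enumerate_cases()[1, ])
observability_matrix(m1, n_points = 200)
#> Observability report: output nu3, kinetics form O
#>   zero columns: 2
#>   sampled ranks: 0:0 1:0 2:200 3:0 over 200 points
#>   verdict (sufficient rank condition): not-observable
```

The substrate column of the observability matrix is identically zero —
substrate never enters the output chain — so the rank is 2 everywhere and the
sufficient condition fails. The trajectory stage then shows what is still
recoverable:

```r
red <- reduce_for_output(build_error_system(m1, with_uncertainty = TRUE), m1)
sc  <- generate_scenario(42)
tf  <- horizon_for_tolerance(sc, tol = 1e-5)   # 267.3 h for this scenario
traj <- simulate_pair(sc, m1, TRUE, TRUE, times = seq(0, tf, length.out = 401))
verify_convergence(traj, classify_states(red, "generic"))
#>        entity      label      status terminal_max
#> 1         nu1 detectable        pass 4.969042e-17
#> 2         nu2 detectable        pass 3.806746e-11
#> 3         nu3   measured not-checked 0.000000e+00
#> 4 delta_delta detectable        pass 1.987617e-19
```

Biomass, substrate and the unknown input are all *detectable*: their errors
decay to zero (terminal maxima far below the 1e-5 g/L tolerance), so an
asymptotic observer is possible even though exact reconstruction is not.

The full pipeline over all nine cases, with verification and CSV/JSON
artifacts:

```r
summary <- run_all(analysis_config(out_dir = "results"))
summary          # geometric verdicts + verification tally
summary$table4   # consolidated per-state coding, e.g. for case 1:
#>  case geom_nu1 geom_nu2 geom_nu3 unc_nu1 unc_nu2 unc_nu3 nounc_nu1 nounc_nu2 nounc_nu3
#>     1       UO       UO        M       D       D       M         O         D         M
```

Coding: `M` measured, `O` observable, `UO` unobservable, `D` detectable
(`O/D` where the generic and wash-out regimes differ). Equivalent shell
interface:

```sh
Rscript inst/scripts/obscstr.R run   --config inst/extdata/default_config.yaml --out results
Rscript inst/scripts/obscstr.R geom  --case 1
Rscript inst/scripts/obscstr.R verify --case 5 --seeds 3
```

Configuration (parameters, kinetics bounds, case subset, tolerances, seeds)
is a YAML file; `inst/extdata/default_config.yaml` documents the schema and
the canonical defaults.

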