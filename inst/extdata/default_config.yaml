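# Canonical analysis configuration: all nine (measured output x substitute
# kinetics) cases, three verification seeds, default CSTR constants and
# true-kinetics bounds. Units: rates 1/h, concentrations g/L.
cases: [1, 2, 3, 4, 5, 6, 7, 8, 9]
seeds: [1, 2, 3]
horizon: [0.0, 50.0]
tol: 1.0e-5          # terminal-window detectability tolerance, g/L
obs_tol: 1.0e-7      # whole-horizon numerical-zero tolerance, g/L
n_rank_points: 200   # sample points for observability-rank profiling
with_uncertainty: true
without_uncertainty: true
verify: true
params:
  Ys: 0.65      # substrate yield (-)
  Yo: 0.2       # oxygen yield (-)
  Sin: 5.0      # inflow substrate, g/L
  Oin: 0.5      # inflow dissolved oxygen, g/L
  Os: 10.0      # oxygen saturation, g/L
  beta_m: 0.05  # biomass mortality, 1/h
  ms: 0.05      # substrate maintenance, 1/h
  mo: 0.02      # oxygen maintenance, 1/h
true_kinetics:
  mu_max: [0.3, 0.5]  # 1/h
  Ks: [0.5, 1.5]      # g/L
  Ko: [0.1, 0.3]      # g/L
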