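# radars

An R package modelling the humoral immune system as a **radial
interaction space**: antibody specificity is a direction in antigen shape
space, binding free energy ΔG is the radial coordinate, and iso-energy
shells are levels of structural resolution. It is aimed at systems
immunologists and network scientists who want a quantitative, simulatable
account of how B-cell development organizes antibody affinities into a
scale-free, fractal interaction network.

## The model in brief

Binding is described thermodynamically, with ΔG stored as the magnitude
of the free-energy decrease on binding:

    K_D = exp(−ΔG/RT),   K_A = exp(+ΔG/RT),
    K_sys = K_A / ⟨K_A⟩ = exp((ΔG − ⟨ΔG⟩)/RT)

and the regulatory principle is that antibody production tunes each free
antigen concentration to the controlling antibody's dissociation
constant, [Ag] ≈ K_D. Random-energy Gaussian interaction energies,
sampled under exponentially distributed antigen availabilities (rate λ,
per-unit variance 2/λ), make log K_sys Laplace(0, 1/λ): K_sys follows a
symmetric **double-Pareto** law

    f(K_sys) = (λ/2) K_sys^(−1−λ)   for K_sys ≥ 1

whose upper tail exponent is 1 + λ. Reading network degree as k = K_sys
gives a scale-free degree distribution p(k) ~ k^(−γ) with γ = λ + 1; for
a scale-free fractal the box dimension obeys d_B = (γ−1)/(γ−2), and the
unique self-consistent ("ideal") exponent γ = d_B is the golden-ratio
fixed point γ = φ + 1 = φ² ≈ 2.618. At 310 K the lognormal mean energy
exp(RT²/2) ≈ 27.7 kJ/mol corresponds to K_D ≈ 2×10⁻⁵.

The package provides: unit-safe thermodynamic conversions; the
double-Pareto law in closed form, by quadrature and by Monte-Carlo
sampling, plus Hill tail-exponent estimation; an agent-based simulation
of B-cell development with germinal-centre affinity maturation and
antigen regulation; and network construction/metrics (plasma-cell-hub
subnetworks, degree-exponent fits, greedy box-covering fractal
dimension). See the methods vignette (`vignettes/radars-model.Rmd`) for
the full account.

## Worked example

```r
library(radars)

# Thermodynamics: the characteristic system scale at 310 K
ctx <- thermo_context(310)
lognormal_mean_energy(0, ctx$rt)            # 27.69746  (kJ/mol)
signif(k_from_dg(27.67, ctx), 1)            # 2e-05     (K_D)
ideal_exponent()                            # 2.618034  (phi^2)

# Double-Pareto affinities -> network degrees -> degree exponent
k <- sample_ksys(double_pareto_model(1.618034), 1e5, seed = 1)
fit_degree_exponent(degrees_from_ksys(k))
#> tail_fit: alpha = 2.6089 (se 0.0238), k_min = 5, n_tail = 4568

# Agent-based repertoire at the default study conditions
cfg <- sim_config(seed = 0)                  # 100 antigens, 500 steps
st  <- simulate_repertoire(cfg)
summarize_repertoire(st, cfg)
#> repertoire_summary
#>   stages:
#> immature  naiveB2       B1       GC      MBC     LLPC
#>       23      542      644        0       47       89
#>   mean dg: 8.499204
#>   emergent K_sys tail exponent: 1.954 (n_tail = 68)
#>   regulated antigens: 90, max |log10(free/K_D)| = 9.64e-17
```

Reading the output: after 500 steps the repertoire has 89 long-lived
plasma cells, each the hub of one antigen-specific subnetwork; all 90
antigens covered by a plasma cell sit exactly at the [Ag] ≈ K_D set
point (the log10 ratio is numerically zero); and the emergent
distribution of above-average affinities is heavy-tailed with a
power-law exponent near 2, inherited from the exponential antigen
availabilities. A command-line wrapper over the same functions is
installed at `inst/cli/radars` (subcommands `thermo`, `sample-ksys`,
`fit-tail`, `simulate`, `build-network`, `box-dim`, `fit-gamma`, `run`).

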