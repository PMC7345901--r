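---
title: "A radial interaction-space model of the antibody repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A radial interaction-space model of the antibody repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radars)
```

## The model

The humoral immune system is treated as a metric *interaction space*. A
direction on a unit sphere stands for an antigen epitope shape; the radial
coordinate of a B-cell clone is the free energy of binding of its receptor,
$\Delta G$, stored as the magnitude of the free-energy decrease on binding
($\Delta G \ge 0$, larger = better binder). Levels of equal energy form
shells: moving outward means resolving target shape at higher structural
resolution, paid for with more noncovalent bonds. The thermodynamic
dictionary is

$$K_D = e^{-\Delta G/RT}, \qquad K_A = e^{+\Delta G/RT},$$

and a clone's standing in the system is its *system equilibrium constant*

$$K_{sys} = K_A/\langle K_A\rangle = e^{(\Delta G - \langle\Delta G\rangle)/RT},$$

its association constant relative to the system reference. The central
regulatory assumption is that antibody production tunes the steady-state
free concentration of each antigen to the dissociation constant of the
controlling antibody, $[Ag] \approx K_D$.

Two distributional ingredients combine into the statistical core. First, a
random-energy picture makes the binding energy of an interface with $r$
bonds Gaussian with variance $r\,\Delta E^2$. Second, antigen
availabilities — and through them the depth to which responses are driven
— are exponentially distributed with rate $\lambda$. Exponentially
sampling the Gaussian variance (per-unit-$r$ variance $2/\lambda$ in
dimensionless log units) makes $\log K_{sys}$ Laplace$(0, 1/\lambda)$, so
$K_{sys}$ follows a symmetric *double-Pareto* (log-Laplace) law:

$$f(K_{sys}) = \tfrac{\lambda}{2}K_{sys}^{-1-\lambda}\ (K_{sys}\ge 1),
\qquad f(K_{sys}) = \tfrac{\lambda}{2}K_{sys}^{\lambda-1}\ (K_{sys}<1).$$

The package implements this law three ways and cross-checks them: the
closed form (`ksys_pdf_closed`), direct quadrature over the bond-count
mixture (`ksys_pdf_quadrature`, agreeing to better than $10^{-6}$
relative), and a Monte-Carlo sampler (`sample_ksys`, whose $n = 10^5$
samples sit within Kolmogorov–Smirnov distance 0.01 of the closed CDF).
The lower branch is not forced by the upper one; we take the symmetric
branch with mass $\tfrac12$ on each side, the form produced by the
exponential-sampling mechanism of Reed and Mitzenmacher.

Identifying network degree with $K_{sys}$ (integerized as
$\max(1, \mathrm{round}(K_{sys}))$ so that every clone keeps at least one
link) gives a scale-free degree distribution $p(k)\sim k^{-\gamma}$ with
$\gamma = \lambda + 1$. For a scale-free fractal network the box-covering
dimension obeys $d_B = (\gamma-1)/(\gamma-2)$. Demanding
$\gamma = d_B$ has a unique solution, the golden-ratio fixed point
$\gamma = \varphi + 1 = \varphi^2 \approx 2.618$, which `ideal_exponent()`
finds by bisection and verifies against the closed form.

With $\mu = 0$ and $\sigma$ equal to the numeric value of $RT$ at 310 K in
kJ/mol ($\approx 2.577$), the lognormal mean energy
$e^{\mu + \sigma^2/2} \approx 27.7$ kJ/mol corresponds to
$K_D \approx 2\times 10^{-5}$ — the scale at which B-cell receptor
sensitivity bottoms out. We treat the $\sigma = RT$ reading as a
documented interpretation: it is the only dimensional reading that
reproduces both printed numbers, and the default temperature is 310 K
because 298 K does not.

```{r}
ctx <- thermo_context(310)
lognormal_mean_energy(0, ctx$rt)
signif(k_from_dg(lognormal_mean_energy(0, ctx$rt), ctx), 1)
ideal_exponent()
```

## The agent-based repertoire simulation

`simulate_repertoire()` grows a repertoire in a `shape_dim`-dimensional
interaction space (default $D = 8$; the model's "infinity of directions"
is discretized only by the sampled antigen set). Per synchronous step:

1. **Influx.** `influx_per_step` clones arrive with uniform random
   directions, `r0` bonds and energy $\Delta G = \varepsilon_0 r_0$
   ($\varepsilon_0 = 2.577$ kJ/mol per well-aligned bond, so the
   27.67 kJ/mol system mean corresponds to 10–11 bonds). A fraction
   `b1_fraction` is committed to the innate-like B1 lineage: stable,
   never affinity-matured. The common-lymphoid-progenitor origin has
   $r = 0$ bonds and zero interaction probability; the
   CLP→proB→preB→immature progression is lineage bookkeeping.
2. **Expansion.** A clone engages an antigen only inside its angular cap
   $\theta(\Delta G) = c/\Delta G$ (resolution narrows as affinity grows;
   $c$ defaults so a naive cap covers 1% of the sphere). Within the cap,
   engagement is receptor occupancy $[Ag]/([Ag] + K_D)$. Cells divide
   with probability `division_rate` × engagement and die at per-stage
   rates, so clones with abundant targets expand and the rest dwindle.
   Sizes are capped at a carrying capacity (`max_clone_size`), since
   unbounded clonal growth is neither biological nor numerically
   representable.
3. **Germinal-centre entry.** Naive clones engaging above `gc_trigger`
   at or beyond the energy gate enter a germinal centre driven by their
   best antigen. The gate defaults to the naive shell energy
   $r_0\varepsilon_0$ — the boundary of the circulating repertoire —
   because a fixed gate at the 27.67 kJ/mol system mean could never be
   reached by influx clones (they are born well below it), and a gate at
   the running population mean closes permanently once the first cohort
   matures. Entry is self-limiting: once an antigen is regulated,
   occupancy at the naive affinity collapses and no further clones are
   recruited (immunodominance by the established response).
4. **Mutation–selection.** Each active GC clone proposes one extra bond
   plus an angular move toward (fraction `gc_pull`) and around (Gaussian,
   sd `gc_mutation_step`) its driving antigen, accepted only if
   $\Delta G = \varepsilon_0\, r\, \mathrm{alignment}$ strictly
   increases. Maturation is *driven while the clone's $K_D$ exceeds
   `clearance_depth` (default 0.01) times the antigen's base
   availability*: affinity is pushed until the clone can hold free
   antigen two orders of magnitude below its unregulated level, then the
   drive ends. The target is the static base level, not the current free
   concentration — the free level itself chases the best $K_D$
   downward, and a stop rule tied to it re-arms every step and ratchets
   maturation to the cycle cap. Because base availabilities are
   exponential, final energies inherit an exponential tail,
   which is exactly what makes the emergent $K_{sys}$ distribution
   heavy-tailed (upper-tail exponent $\approx 2$ at the defaults).
5. **Retraction.** When an antigen's free concentration has fallen to
   the $K_D$ of its best GC clone (within `clear_tol`; free approaches
   $K_D$ from above, so an exact inequality would never fire), the
   response retracts: the best clone becomes the subnetwork's single
   long-lived plasma cell, the rest become resting memory B cells of
   minimal size, and the effector excess is removed by apoptosis. All
   cell creation and removal is recorded in a per-step ledger so that
   conservation can be audited.
6. **Antigen relaxation.** Each antigen's free level relaxes by factor
   `rho` per step toward $\min(\mathrm{base}, K_D^{best})$ over the
   secreting clones (GC effectors and plasma cells) covering it;
   uncovered antigens stay at base. This implements the
   $[Ag]\approx K_D$ steady state: after retraction, regulated antigens
   sit at the plasma-cell $K_D$ to within numerical tolerance.

Defaults — 100 antigens, 25 clones of influx per step, 500 steps,
$\lambda = \varphi$, seed 0 — are the study conditions used throughout
the tests; a full run takes a few seconds and ends with roughly 1300
clones, of which about 90 are plasma-cell hubs.

### What the simulation does and does not emulate

The generator reproduces the *mechanisms* the model proposes: passive
bone-marrow selection by target availability, expansion proportional to
engagement, directed affinity maturation, retraction into
memory/plasma-cell compartments, and antigen regulation toward $K_D$. It
does not emulate sequence-level realism (no V(D)J genetics, no isotypes,
no explicit T-cell help — "help" is folded into the entry threshold),
anatomical compartments, antigen dynamics beyond a static base level, or
re-challenge. Rates and population sizes are free parameters chosen for
realistic qualitative behaviour, not fitted to data; passing tests show
the mechanisms interlock as claimed, not that the parameter values are
physiological.

## Network construction and metrics

`build_hierarchical_network()` realizes the proposed architecture within
each subnetwork (structural direction): the plasma cell is the hub,
linked from every other member — it handles the antigen of everything
below it — and each node additionally links to the angularly nearest
node in the next energy shell up (ties by id). Links are directed from
lower to higher energy (the direction of antigen transfer); no links
cross subnetworks. B1 cells sit at minimal degree, memory cells at
intermediate degrees, plasma cells at hub degree, matching the intended
role ordering.

`box_covering()` measures fractality by greedy box covering: a box of
size $l_B$ holds nodes pairwise within distance $< l_B$; greedy
assignment is repeated over 10 random node orders and the minimum kept;
$d_B$ is the log–log slope over the scaling region $1 < N_B < N$. The
convention is self-consistent ($N_B(1) = N$, $N_B(\mathrm{diam}+1) = 1$)
— note that under it a star has $N_B(2) = n - 1$, not 1, because leaves
are pairwise at distance 2. On reference graphs the estimator recovers
$d_B \approx 1$ for a 64-node path and $d_B \approx 2$ for the
generation-4 (2,2)-flower (analytic dimension
$\log(u+v)/\log u = 2$), and stays within a factor 2 of brute-force
minima on all small fixtures.

Degree exponents are fitted with the continuous-Pareto (Hill) maximum
likelihood estimator; on integer degrees the standard half-integer shift
is applied and the default cutoff is $k_{min} = 5$, which keeps the
small-degree bias of the continuous approximation under ~2% (at
$k_{min} = 2$ it is ~5%). For the *emergent* repertoire tail,
`summarize_repertoire()` places the Hill cutoff at the median of the
$K_{sys} > 1$ exceedances — the usual intermediate-order-statistic
choice — because the near-mode bulk is not yet in the asymptotic regime.

A degree-proportional attachment generator
(`grow_preferential_attachment`, wrapping igraph) is included as a
contrast: its emergent exponent is the classical $\approx 3$, not the
ideal $\varphi^2$, and the package deliberately claims neither generator
produces the ideal network — the fixed point is a property of the
$\gamma = d_B$ condition, not of any particular growth rule.

One algebraic point deserves record: the map
$\gamma \mapsto (\gamma-1)/(\gamma-2)$ is *not* an involution (composed
with itself it is $\gamma \mapsto 1/(3-\gamma)$); only its fixed point
$\varphi + 1$ is distinguished. Tests therefore assert the fixed point
and the golden-ratio identities, not a two-sided inversion.

## Numerical choices

* Quadrature uses `stats::integrate` with relative tolerance $10^{-10}$
  and a pure-relative error target; the integrand's $r^{-1/2}$ endpoint
  singularity at $k = 1$ is integrable and handled by the adaptive rule.
* The bisection for the ideal exponent runs to $10^{-12}$ on $(2, 4)$
  and the result is asserted against $(1+\sqrt5)/2 + 1$ at $10^{-10}$.
* Degenerate inputs: a zero-bond clone has zero interaction probability
  (density 0 away from the mean, flagged as degenerate); tail fits
  require at least 10 exceedances and positive log-spread; a constant
  sample is rejected rather than fitted.
* All randomness flows from explicit seeds. `sample_ksys` and the
  preferential-attachment generator restore the caller's RNG state;
  `simulate_repertoire` seeds the global stream from its config, so a
  given config is bit-reproducible including its CSV exports.
* Clone sizes are integers throughout (binomial births and deaths), and
  the per-step ledger enforces
  total = previous + influx + divisions − deaths − apoptosis.

## Known limitations

* The paper-scale claims about empirical sequencing-derived repertoire
  networks are outside the package's scope; nothing here touches real
  NGS data.
* The simulation's emergent tail exponent (~2.0) is a consequence of the
  exponential availability assumption and the clearance-depth rule; it
  is not tuned to, and does not by itself confirm, the ideal
  $\varphi^2$ exponent.
* Subnetworks are disconnected from one another by construction, so the
  box dimension of a simulated whole-repertoire network is dominated by
  its largest subnetwork and is typically not in the scaling regime;
  fractal-dimension claims are tested on reference graphs instead.
* Memory B cells do not re-enter germinal centres (no antigen
  re-challenge is modelled), and plasma-cell attrition is absent.
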