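# levyswitch

Noise-induced transitions in a bistable genetic switch under Gaussian and
α-stable Lévy fluctuations.

## The problem

A transcription factor activator (TF-A) that stimulates its own
transcription forms one of the simplest bistable gene circuits. With the
monomer concentration `x` (nM) as the single state variable, the kinetics
are

    dx/dt = f(x) = k_f x² / (x² + K_d) − k_d x + R_bas

where `k_f` is the maximal transcription rate, `K_d` the dissociation
constant of the TF-A dimer from its responsive element, `k_d` the
degradation rate and `R_bas` the basal synthesis rate. For suitable rates
the system has two stable states — a low-expression state `x₋` and a
high-expression state `x₊` — separated by an unstable state `x_u`, so the
circuit is a switch.

Transcription and translation are bursty: synthesis-rate fluctuations show
heavy tails that a Brownian term alone cannot capture. The package
therefore studies the jump-diffusion

    dX_t = f(X_t) dt + σ dB_t + ε dL_t^α

with `B` a standard Brownian motion and `L^α` a symmetric α-stable Lévy
motion (pure jumps, index `α ∈ (0, 2)`; small α means rare large jumps).
Switching from the low to the high state is a first-exit problem from
`D = (0, x_u)`, quantified by

* the **mean first exit time** (MFET) `u(x) = E[τ | X₀ = x]`, solving the
  nonlocal equation `A u = −1` in `D` with `u = 0` on all of `D^c`;
* the **first escape probability** (FEP) `p(x) = P[X_τ ∈ E | X₀ = x]`,
  solving `A p = 0` with the Balayage–Dirichlet exterior condition
  `p = 1` on the target `E`, `0` on the rest of `D^c`;
* the **stochastic basin of attraction** (SBA): the closed core
  `K = {u ≥ u*}` together with the return set `M = {x ∈ K^c : p(x) > p*}`
  of outside points likely to re-enter `K`; its size `|K| + |M|` measures
  basin stability under noise.

Here `A` is the generator
`A v = f v′ + (σ²/2) v″ + ε^α C_α PV∫ (v(x+y) − v(x)) |y|^(−1−α) dy`,
discretised by finite differences with exact analytic treatment of the
exterior jump integrals. Everything is cross-checked against closed-form
diffusion formulas and Monte Carlo simulation of the SDE.

The package is aimed at researchers in stochastic gene-circuit dynamics
who want reproducible MFET/FEP/SBA computations for scalar bistable
systems driven by mixed Gaussian/Lévy noise.

## Worked example

```r
library(levyswitch)

p <- tfa_params(6, 10, 1, 0.4)
find_equilibria(p)
#> Bistable TF-A system with equilibria:
#>   x = 0.62685   f'(x) = -0.3036   stable
#>   x = 1.48971   f'(x) = +0.1973   unstable
#>   x = 4.28343   f'(x) = -0.3604   stable

## pure-jump noise, large jumps (alpha = 0.5), intensity 0.5
ns <- noise_spec(0, 0.5, 0.5)
u <- solve_mfet(c(0, 1.48971), p, ns, J = 400)
field_eval(u, 0.62685)
#> [1] 1.414163

## probability of jumping straight into the distant high-expression
## window E = [3, 5] (unreachable for Brownian noise)
fep <- solve_fep(c(0, 1.48971), c(3, 5), p, ns, J = 400)
field_eval(fep, 0.62685)
#> [1] 0.07066809

## stochastic basin of attraction under pure Brownian noise
stochastic_basin(p, noise_spec(0.5, 0, 2), window = c(0, 6),
                 u_star = 2.36, p_star = 0.6, J = 400)
#> Stochastic basin of attraction
#>   K = [0.4355, 0.9833]  (u* = 2.36, |K| = 0.5478)
#>   M = [0.2202, 0.4355] U [0.9833, 2.2925]  (p* = 0.6, |M| = 1.5245)
#>   SBA size |K| + |M| = 2.0723
```

Read the numbers as: started at the low state `x₋ ≈ 0.627`, the process
stays in the low-expression region for about 1.41 min on average under
this jump noise, and about 7% of first exits land directly in the
high-expression window `[3, 5]`. Under Brownian noise the core
`K = [0.44, 0.98]` of long residence times attracts returns (with
probability above 0.6) from `[0.22, 0.44] ∪ [0.98, 2.29]`.

Monte Carlo counterparts (`simulate_path`, `mc_first_exit`, `mc_mfet`,
`mc_fep`) estimate the same quantities from trajectory ensembles and are
used throughout the tests as independent oracles for the solver. RCF
sweeps (`sweep_mfet`, `sweep_fep`, `intensities_from_rcf`) explore the
balance `λ = ε/σ` between the two noise sources under the fixed budget
`σ + ε = 1`.

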