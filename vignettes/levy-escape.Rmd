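---
title: "Exit times, escape probabilities and stochastic basins for a bistable TF-A switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exit times, escape probabilities and stochastic basins for a bistable TF-A switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levyswitch)
```

## The model

The package studies a transcription-factor activator (TF-A) that
activates its own transcription through dimer binding to a responsive
element. Reduced to the monomer concentration $x$ (nM), the kinetics are

$$\frac{dx}{dt} = f(x) = \frac{k_f\,x^2}{x^2 + K_d} - k_d\,x + R_{bas},$$

with maximal transcription rate $k_f$ (1/min), dissociation constant
$K_d$, degradation rate $k_d$ (1/min) and basal synthesis $R_{bas}$
(nM/min). The Hill exponent 2 comes from rapid dimerisation. Units are
carried as documentation only; all computations are unit-agnostic.

`find_equilibria()` locates all roots of $f$ on $[0, x_{\max}]$ by sign
scanning on a 4001-point grid followed by bisection to bracket width
$10^{-12}$. A cubic analysis of $x^2 f(x)$ shows at most three positive
roots, so a count of two signals a saddle-node tangency and is refused.
Bistability is decided by root counting rather than by a closed-form
parameter inequality: the two are equivalent, and counting is robust for
any parameter set. The potential $V$ with $V' = -f$, $V(0) = 0$ is
evaluated by adaptive quadrature (relative tolerance $10^{-10}$) rather
than from the closed antiderivative, keeping the code generic in the
parameters. The default search bound $x_{\max} = 10$ comfortably covers
both parameter sets shipped in the examples (largest root $\approx 5.95$).

## The stochastic model

Synthesis-rate fluctuations enter additively:

$$dX_t = f(X_t)\,dt + \sigma\,dB_t + \varepsilon\,dL_t^\alpha,$$

with $B$ a standard Brownian motion and $L^\alpha$ a symmetric
$\alpha$-stable pure-jump Lévy motion, independent of $B$. The index
$\alpha \in (0,2)$ trades jump size against frequency: small $\alpha$
gives rare large jumps, $\alpha$ near 2 frequent small ones. This is the
standard idealisation of bursty transcription; see the closing section
for what it does and does not capture.

`rstable_standard()` draws $S_\alpha(1,0,0)$ variables by the
Chambers–Mallows–Stuck transform, with the `tan(U)` Cauchy special case
at $\alpha = 1$ and the Gaussian limit (variance 2) at $\alpha = 2$.
Calibration tests pin the $\alpha = 2$ variance to 1%, the $\alpha = 1$
law to the Cauchy CDF by Kolmogorov–Smirnov distance, and the empirical
tail exponent of $P(|L| > u)$ on $u \in [10, 100]$ to $-\alpha \pm 0.1$.

`simulate_path()` and `mc_first_exit()` integrate the SDE by
Euler–Maruyama:

$$X_{n+1} = X_n + f(X_n)\,\Delta t + \sigma\sqrt{\Delta t}\,G_n +
\varepsilon\,\Delta t^{1/\alpha} S_n .$$

The $\Delta t^{1/\alpha}$ scaling is forced by the self-similarity of the
stable motion, so increments are exact in distribution at any step size.
Conventions chosen once and kept fixed:

* both noise streams come from the single R RNG stream in a documented
  order (Gaussian first), so a run is reproducible from
  `(seed, dt, n_paths)`;
* exit is the first step with $X$ outside the open domain, and the exit
  state is the post-jump position — no boundary interpolation. The
  resulting $O(\sqrt{\Delta t})$ diffusive-overshoot bias is accepted at
  the default $\Delta t = 10^{-3}$ min;
* negative concentrations are allowed in the raw process (they lie in
  the exterior, where only the prescribed exterior value matters); the
  drift is evaluated as written;
* without an explicit horizon, the step cap starts at $10^4$ and doubles
  until censoring falls below 5% (hard cap $10^6$ steps). Censoring
  biases the MFET low — censored paths contribute their censoring time —
  so quantitative comparisons in the tests pass an explicit `t_max`
  large enough to make censoring negligible, and `mc_mfet()` warns
  whenever censored paths are present.

## The nonlocal exit equations

Write $\nu_\alpha(dy) = C_\alpha |y|^{-1-\alpha} dy$ for the jump
measure, with

$$C_\alpha = \frac{\alpha\,\Gamma((1+\alpha)/2)}
{2^{1-\alpha}\sqrt{\pi}\,\Gamma(1-\alpha/2)},\qquad C_1 = 1/\pi .$$

The generator of $X$ is

$$A v(x) = f(x) v'(x) + \tfrac{\sigma^2}{2} v''(x) +
\varepsilon^\alpha C_\alpha\,\mathrm{PV}\!\!\int_{\mathbb R}
\frac{v(x+y) - v(x)}{|y|^{1+\alpha}}\,dy .$$

The $\varepsilon^\alpha$ factor again follows from self-similarity
($\varepsilon L_t$ is a time-rescaled standard motion); the symmetric
principal value absorbs the small-jump compensator, whose odd integrand
integrates to zero. The MFET solves $Au = -1$ in $D$ with $u = 0$ on all
of $D^c$; the FEP solves $Ap = 0$ with $p = \mathbf 1_E$ on $D^c$.
Because jumps exit directly into the exterior, the boundary data must be
prescribed on the whole complement (Balayage–Dirichlet condition), not
just at the two boundary points.

### Discretisation

Each domain interval is mapped affinely to $(-1, 1)$ and carries a
uniform grid of `J` cells (default 400, at least 17 so that every
interval has 16+ interior nodes). At an interior node $x_j$:

* **Local part.** $\sigma^2/2\,v''$ by second central differences. The
  singular cell $|y| < h$ of the jump integral is replaced by the
  effective diffusion $C_\alpha h^{2-\alpha}/(2-\alpha)\,v''$, the
  second-order Taylor value of the truncated integral.
* **Advection.** Central differences where the local diffusive coupling
  (Gaussian plus singular-cell correction) keeps the three-point stencil
  sign-stable, i.e. $|f_j|/(2h) \le \sigma^2/(2h^2) + C_\alpha
  \varepsilon^\alpha h^{-\alpha}/(2-\alpha)$; first-order upwinding
  otherwise. Pure-jump runs with small $\alpha$ are advection-dominated
  near the boundaries, and an unconditionally central stencil there
  produces spurious boundary spikes in $u$ (we observed a false maximum
  of the MFET at the first grid node); the hybrid keeps the maximum
  principle at the cost of a localised first-order error.
* **Principal-value sum.** A trapezoid-type sum over all interior nodes,
  $\sum_{k \ne j} w_k\,(v_k - v_j)/|x_k - x_j|^{1+\alpha}$ with
  $w_k = h_k$, except that the two same-interval neighbours at distance
  exactly $h$ carry $h/2$: their quadrature cells then tile $[h, \infty)$
  without overlapping the singular cell. (The naive midpoint weight
  double-counts $[h/2, h]$ against the correction term; on the exact
  drift-free benchmark below the half-weight variant is decisively more
  accurate at $\alpha = 1.5$ and equivalent at small $\alpha$.) Jumps
  between the intervals of a multi-interval domain are ordinary couplings
  in the same sum.
* **Exterior.** The jump integral over the whole complement is evaluated
  analytically, interval by interval: the escaping mass
  $\int |y - x_j|^{-1-\alpha} dy$ enters the diagonal, and exterior
  intervals carrying a nonzero prescribed value contribute
  $\varepsilon^\alpha C_\alpha \int_{c}^{d} |y-x_j|^{-1-\alpha}dy$ to
  the load, with semi-infinite targets integrated to infinity. No
  numerical truncation of the jump integral occurs anywhere, which makes
  non-adjacent (scenario 2) targets exact in the far field and lets the
  assembled operator annihilate constants to rounding error — an
  invariant asserted in the tests over a $(\alpha, \varepsilon, \sigma)$
  lattice.

$\alpha = 2$ (or $\varepsilon = 0$) routes to a pure advection–diffusion
assembly with effective variance $\sigma^2 + 2\varepsilon^2$, since the
$\alpha = 2$ stable law is Gaussian with variance 2. Systems are dense
but small (at most a few thousand nodes) and solved by direct
factorisation; `refine_until()` doubles `J` until successive solutions
change by less than a relative tolerance (default $10^{-3}$), and errors
decay at second order in the Brownian regime and approximately
$O(h^{2-\alpha})$ in the jump-dominated regime.

### Oracles

Three independent routes check the solver:

1. **Brownian closed forms** (`brownian_mfet_closed_form`,
   `brownian_fep_closed_form`): scale-density quadrature
   $\psi(t) = \exp(-(2/\sigma^2)\int_a^t f)$, adaptive tolerance
   $10^{-10}$, giving $p = \int_a^x \psi / \int_a^b \psi$ and the
   two-sided absorption formula for $u$.
2. **Exact stable exit law**: for the drift-free standard motion on
   $(-1,1)$, $u(x) = (1-x^2)^{\alpha/2}/\Gamma(1+\alpha)$.
3. **Monte Carlo**: ensemble estimates at matched $(\alpha, \varepsilon,
   \sigma)$, compared within three standard errors.

## Relative contribution factor

With the total intensity budget $\sigma + \varepsilon = 1$, the ratio
$\lambda = \varepsilon/\sigma$ determines both intensities:
$\sigma = 1/(1+\lambda)$, $\varepsilon = \lambda/(1+\lambda)$
(`intensities_from_rcf`). Sweeps over $\lambda$ (`sweep_mfet`,
`sweep_fep`) reproduce the characteristic response: the MFET rises to an
interior maximum at an optimal noise mix and then flattens, and for a
non-adjacent target the escape probability vanishes at $\lambda = 0$
(continuous paths cannot jump a gap) and saturates for large $\lambda$.

## Stochastic basin of attraction

`stochastic_basin()` composes the two fields:

1. solve the MFET on the deterministic basin of the low state (default
   $(0, x_u)$ from the model's equilibria);
2. threshold it: $K = \{u \ge u^*\}$, taking the connected component of
   the maximiser (leftmost on ties), endpoints interpolated linearly and
   reported to 4 decimals;
3. solve the FEP on the two-interval return domain
   $\text{window} \setminus K$ with target $K$ (indicator exterior
   condition, zero outside the window; default window $(0,6)$, wider
   than the deterministic basin so that returns from the high side are
   visible);
4. threshold that: $M = \{p > p^*\}$, a union of intervals;
5. report $|K| + |M|$.

The thresholds $u^*, p^*$ are explicit user inputs: they are
application-dependent stability demands, not model constants. When
comparing noise settings, we match $|K|$ across settings by solving for
the $u^*$ that yields a common core length, then compare $|M|$ at a
common $p^*$ — this isolates the effect of the noise on the return set.

One subtlety: for jump processes $p$ need not approach 1 at the boundary
of $K$, while the stored boundary nodes carry the prescribed exterior
value 1. Superlevel components of $M$ must therefore contain at least one
interior node; components consisting solely of a boundary node are
prescribed-value artefacts and are dropped. For diffusion, where $p$ is
continuous up to $\partial K$, the component adjacent to $K$ is genuine
and $M$ is nonempty for every $p^* < 1$, shrinking to zero width as
$p^* \to 1$.

## Configuration and reproducibility

`load_config()` reads JSON or YAML run descriptions (model, noise —
either $(\sigma, \varepsilon, \alpha)$ or $(\lambda, \alpha)$ —, interval
lists, solver and Monte Carlo settings), validates every component
invariant, rejects unknown keys, and fills defaults; `write_config()`
round-trips. Result tables are written as CSV under a commented
`# key=value` header (`write_table_csv` / `read_table_csv`) so any file
can be regenerated from its embedded settings. Stochastic defaults use
the fixed seed 20160714 rather than entropy, so default runs are exactly
reproducible. The package deliberately has no shell entry point: it is an
analysis library, and its functions, the test suite and
`scripts/acceptance.R` are the interface.

## Problem sizes and defaults

Defaults were chosen once as the smallest sizes at which the three
oracle routes agree comfortably: solver `J = 400` per interval
(Brownian agreement with closed forms to $10^{-5}$ relative; drift-free
stable benchmark to 0.2–1%), Monte Carlo `n_paths = 10^4` with
$\Delta t = 10^{-3}$ min (standard errors near 1% of the mean), sampler
calibration at $10^5$–$10^6$ draws. The full test suite, including all
cross-method comparisons, runs in about a minute.

## What the simulator does and does not emulate

The trajectory ensembles have exactly the statistical structure the
solver assumes: additive, stationary, mutually independent Gaussian and
symmetric $\alpha$-stable noise on the synthesis rate, a single
well-mixed compartment, and rate constants frozen in time. Passing
cross-method tests therefore validates the numerics, not the biology.
Real single-cell data differ in known ways: burst noise is multiplicative
and state-dependent rather than additive; burst sizes have finite means
for measured tail exponents, whereas $\alpha < 1$ stable laws do not;
concentrations are intrinsically nonnegative while the raw process here
may overshoot below zero; and extrinsic fluctuations drift on the
timescale of the cell cycle. Conclusions about real circuits should rest
on the qualitative orderings (shorter residence for stronger/larger
jumps, jump-only reachability of non-adjacent targets, optimal noise
mixes), which are robust to these idealisations.

## Known limitations

* One-dimensional state only; no multi-gene circuits.
* Symmetric stable noise only (no skewness $\beta$ or shift $\gamma$);
  no tempered or truncated variants.
* Solver convergence degrades to roughly $O(h^{2-\alpha})$ as
  $\alpha \to 2$; near $\alpha = 2$ prefer the diffusion routing.
* Euler–Maruyama detects exits only at grid times; at very coarse
  $\Delta t$ the Monte Carlo MFET is biased high and the comparison
  tolerance must widen accordingly.
* Dense assembly limits resolutions to a few thousand nodes per solve —
  ample in one dimension.
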