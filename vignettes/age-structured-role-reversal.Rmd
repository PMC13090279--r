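---
title: "Age-structured predator-prey dynamics with role reversal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-structured predator-prey dynamics with role reversal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agepp)
```

# The model

`agepp` couples a logistic-type prey ODE to a renewal (transport)
equation for the predator age density. Writing $x(t)$ for the prey
population size and $u(t,\tau)$ for the predator density at age $\tau$,

$$x' = x\,(r - a x + s y_1 - b y_2), \qquad
  u_t + u_\tau = -\mu(x,\tau)\,u, \qquad
  u(t,0) = \int_0^L B(x,\tau)\, u(t,\tau)\, d\tau,$$

with juvenile and adult population sizes
$y_1 = \int_0^{\tau^*} u\, d\tau$ and $y_2 = \int_{\tau^*}^{L} u\, d\tau$.
The trophic roles reverse with age: adults consume prey (term $-b y_2$ in
the prey equation, fecundity term $k x$ in the birth rate), while the
prey consumes juveniles (gain $+s y_1$ for the prey, death term $g x$ for
juvenile predators). The rate functions are

$$B(x,\tau) = k x\, \varphi_{\tau \ge \tau^*}(\tau)
  + \tilde B(\tau)\,(1 - e^{-\zeta x}), \qquad
  \mu(x,\tau) = g x\, \varphi_{\tau < \tau^*}(\tau) + \mu_B(\tau)
  + \mu_M e^{-\rho x},$$

where $\varphi$ is a logistic switch of smoothness $\nu$ at the
maturation age $\tau^*$ (gradual maturation; $\nu = 100$ is practically a
step, $\nu = 1$ a gradual transition),
$\tilde B(\tau) = b_p(e^{-b_{ep}(\tau - \tau^*)} + 1)$ for
$\tau \ge \tau^*$ and zero below (juveniles cannot reproduce; the sharp
cutoff here is deliberate, because the age-averaged reductions assume the
base birth rate vanishes on the juvenile ages), and
$\mu_B(\tau) = d_p e^{d_{ep}(\tau - L)}$ grows with age up to $d_p$ at
the lifespan cap $L$. The term $\mu_M e^{-\rho x}$ is starvation when
prey is scarce; $(1 - e^{-\zeta x})$ suppresses reproduction at low prey.

`model_parameters()` carries the selected values of the fifteen
biological parameters and `parameter_ranges()` their study ranges. The
defaults are $\tau^* = 1$, $g = 0.2$, $\nu = 100$, $r = 0.4$, $a = 0.01$,
$k = 0.3$, $b = 0.8$, $s = 0.2$, $\zeta = 10$, $\mu_M = 1$, $\rho = 5$,
$d_p = 0.4$, $b_p = 0.05$, $b_{ep} = d_{ep} = 0.1$, with $L = 30$. One
printed range required an editorial decision: the range of $s$ is typeset
ambiguously in the source table; we use $[0.1, 1]$, matching the ranges
of the analogous rates $k$ and $b$ and the stated intent that ranges
preserve the selected value's order of magnitude.

The `saturated` variant replaces $k x$ by $k\hat x \tanh(x/\hat x)$ and
$s y_1$ by $s \hat y_1 \tanh(y_1/\hat y_1)$ (defaults $\hat x = 20$,
$\hat y_1 = 10$). The baseline variant's unbounded birth rates admit
finite-time blow-up through a prey–juvenile feedback loop; the saturated
variant provably cannot exceed $x \le a^{-1}(r + s\hat y_1)$.

# The solver

The scheme (in `integrate_age_model()`, compiled core in C++) advances
time and age with the same step $h$, so cohorts travel exactly along
characteristics: forward-Euler prey update, interior density shift with
Euler decay factor $1 - h\mu$, newborn node from the trapezoid birth
integral, and trapezoid population integrals in which the maturation node
carries half weight in each of $y_1$ and $y_2$ (their sum therefore
recomposes the full-range integral exactly). As printed, the scheme
updates the population integrals with a one-step lag
($Y[n+1]$ from $U[n]$); `lag_y = FALSE` gives the synchronous variant,
and both converge to the same limit at first order. Density advected past
the lifespan cap $L = 30$ is discarded — equivalent to an infinite death
rate beyond $L$ — which is harmless because the equilibrium density is
negligible at $L$.

Numerical safeguards:

* **Blow-up**: integration stops with status `blowup` when any of $x$,
  $y_1$, $y_2$ (optionally any density node; off by default since the
  integrals dominate) exceeds a threshold, 1000 by default.
* **Positivity**: $1 - h\mu < 0$ produces negative density and signals a
  too-large step. The default policy aborts with a diagnostic. Ensemble
  and sweep pipelines instead floor the factor at zero
  (`negative = "clamp"`): wherever $1 - h\mu$ is negative the exact
  factor $e^{-h\mu}$ is essentially zero, so the floor is the controlled
  approximation, and it is what makes the prescribed reduced-scale step
  sizes usable on parameter draws with large $g\,x$.
* **Commensurability**: $\tau^*$ and $L$ are snapped to grid nodes; the
  relative snap error is recorded and `strict = TRUE` turns an error
  beyond $10^{-6} h$.

The solver is first-order accurate. Two test families verify this: on
prey-decoupled (pure renewal) problems with rates depending only on age,
the solution along characteristics has a closed form, and the maximum
relative error decays as $O(h)$ under refinement; on the coupled system,
the self-convergence distance $\lVert(x,u)_h - (x,u)_{h/2}\rVert$ in the
norm $|x| + \lVert u\rVert_{L_1}$ halves under refinement.

Step-size choices used throughout (stated here once; they are the
package's defaults for each pipeline): $h = 0.005$ for single
trajectories at the selected values, $h = 0.025$ for ensembles and
diagram sweeps, $h = 0.0125$ for the age-averaged parameter surface.
Trajectories of this system pass through episodes where the prey or the
predator population is extremely small ($10^{-10}$ and below), and which
attractor is reached from a given initial state can depend visibly on
$h$; the attractor *inventory* (which equilibria exist and their
stability) is far more robust, which motivates the equilibrium-based
classification below.

# Equilibria, stability, limit cycles

A fixed point $(X^*, U^*)$ of the discrete one-step map $\Phi$ solves
$F = (X^*, U^*) - \Phi(X^*, U^*) = 0$ (`scheme_residual()`). Newton's
method (`newton_equilibrium()`, tolerance $10^{-10}$ on the residual
max-norm, cap 50 iterations, no line search) uses a forward-difference
Jacobian with absolute perturbation $\epsilon = 10^{-6}$ in the prey
column and relative perturbations $\epsilon\, U^*[k]$ in the density
columns, falling back to absolute at zero nodes (otherwise the column
would vanish at, e.g., the predator-free state).

Newton needs warm starts. Long integration provides one, but at a fixed
point the structure can be exploited: the density recursion makes $U^*$ a
survival profile scaled by the newborn level, so the fixed-point
equations collapse to a scalar discrete renewal condition
$R(X) = 1$ (lifetime reproduction equals replacement) plus a linear
equation for the newborn level from the stationary prey balance.
`coexistence_equilibria()` scans $R(X) - 1$ for sign changes and returns
every root with a positive newborn level — exact fixed points up to root
tolerance, and Newton polishes them in 0–2 iterations. The model
typically has one low-prey coexistence equilibrium
($X^* \approx 0.4$ at the selected values) and, in parts of the plane, a
second high-prey state ($X^* \gg r/a$) in which the prey population is
sustained above its carrying capacity by farming juvenile predators.

Stability of a fixed point of the *map* is decided by the spectral
radius of $\partial\Phi$ (`assess_stability()`); the eigenvalues of
$(\partial\Phi - I)/h$ approximate continuous-time exponents. The
residual formulation "all eigenvalues of the Jacobian of $F$ have
negative real parts" is equivalent at small $h$ and is the view we
report.

Limit cycles are fixed points of the Poincaré first-return map $G$ on the
section $X = X^*$ through the (unstable) coexistence equilibrium
(`poincare_map()`: upward crossings, linear interpolation between the
bracketing steps). `find_limit_cycle()` minimises
$f(U) = \tfrac12 \lVert U - G(U)\rVert_2^2$ by Levenberg–Marquardt
(initial damping $10^{-3}$, adaptive $\times 10 / \div 10$, stop at
$f < 10^{-14}$ or gradient max-norm $< 10^{-10}$) with the same
forward-difference Jacobian convention. One subtlety: the unstable
equilibrium itself is a fixed point of $G$, and a Gauss–Newton step from
a poor start can land in its basin. The `settle` parameter applies a few
plain map iterations first; because the cycle is attracting, these
converge onto it geometrically and the optimiser then refines locally.
At $(\tau^* = 1, g = 0.1)$ the attractor is a deep relaxation cycle (prey
spanning five orders of magnitude) whose extremal events recur in the
cyclic order $\max y_2 \to \min x \to \min y_1 \to \min y_2 \to \max x
\to \max y_1$ (`cycle_extrema_order()`).

# Reduced models

Integrating the renewal equation over the juvenile and adult age ranges
and replacing the smooth switches by sharp ones collapses the system to
three ODEs once four constants are supplied by age-averaging over an
equilibrium density (`age_averaged_parameters()`): the juvenile-to-adult
transition rate $D = \bar u(\tau^*)/y_1$, the density-weighted base birth
rate $b_2$ over adults, and death rates $m_1$, $m_2$ over juveniles and
adults. Setting $b_2 = 0$ and $\mu_M = 0$ in the reduced ODE recovers the
classical unstructured role-reversal ODE exactly — a cross-check carried
out in the tests against an independently coded integration.

The DDE reduction keeps the maturation delay: the transfer term $D y_1$
is replaced by the flux of the cohort born one maturation age ago,
attenuated along its characteristic with the trapezoid rule in the prey
dependence; the juvenile base-death burden enters as
$M_B = \int_0^{\tau^*} \mu_B$, integrated to $\tau^*$ (the upper limit is
dimensionally forced, and we integrate it with the same grid trapezoid as
the other averages). For $t < \tau^*$ the maturing cohort is read off the
initial age density: the cohort at age $\tau^*$ at time $t$ was at age
$\tau^* - t$ initially. The pre-zero history of $x$ and $y_2$ is constant
at the initial values, the common DDE-solver convention.

ODE equilibria come from nonlinear least squares on the right-hand side
(Levenberg–Marquardt via `minpack.lm`) with eigenvalue stability; DDE
equilibria use the stationary constant-history flux. For DDE stability
the package offers both the perturb-and-integrate protocol
(`reduced_stability_by_perturbation()`) and a characteristic-root
computation on the linearization $v' = A v + B v(t - \tau^*)$, Newton
polishing of $\det(\lambda I - A - B e^{-\lambda\tau^*}) = 0$ from the
zero-delay eigenvalues (`dde_equilibrium_stability()`). The latter is the
default in comparisons: in this model the reduced systems sit extremely
close to their Hopf boundaries over much of the plane (growth rates of
order $10^{-4}$), far below what any affordable perturbation run can
resolve.

# Parameter studies

**Ensembles.** `latin_hypercube()` draws a per-column-stratified design
over the fifteen ranges (one sample per bin in every column — the `lhs`
package's `randomLHS` supplies the stratified uniforms). Each sample is
integrated from the standard initial condition ($x(0) = 0.5$; density
$0.1$ on juvenile ages, $0.05$ on adult ages up to $L$) to $T = 500$ with
blow-up threshold 1000 and classified (`classify_attractor()`): `blowup`
on early termination; `predator_free` when the terminal total predator
population is below $10^{-6}$ (far below any attractor scale at the
selected values — the threshold is ours, none is printed in the source);
otherwise `periodic_coexistence` when the relative prey amplitude over
the tail window $t \in [400, 500]$ exceeds $10^{-3}$, else
`equilibrial_coexistence`. At the full scale of the study (two runs of
10,000 samples at $\Delta t = 0.005$) the outcome shares are reported as
22% equilibrial, 19% periodic, 55% predator-free, and roughly 4% blow-up;
the package's reduced-scale ensemble (300 samples, $h = 0.025$), run by
the acceptance script and the test suite, reproduces these shares within
a few percentage points. The saturated variant produces no blow-ups at
any ensemble size, which the suite asserts as a property.

**LDA.** `fisher_lda()` implements standard multiclass Fisher
discriminant analysis: dominant generalized eigenvectors of the
between-class against the pooled within-class scatter, computed through
the symmetric-definite Cholesky reduction, orthonormalized by one
Gram–Schmidt pass. Because the parameters' ranges span orders of
magnitude, importance is read from the range-adjusted loadings
$RW$ ($R$ = diagonal of per-parameter ranges): a loading then measures
the effect of traversing a parameter's whole range. On ensembles of the
baseline model the leading discriminant is dominated by $g$ and
$\tau^*$, the two parameters the detailed sweeps then vary.

**Phase diagrams.** `phase_diagram()` sweeps a $(\tau^*, g)$ grid with
everything else at the selected values, $g$ descending within each
column so equilibria can be continued. Per cell: integrate from the
standard initial condition (the sweep convention puts the juvenile level
on $\tau \le \tau^*$); a cell whose predator population stays below the
extinction threshold across the whole tail window is `predator_free`
(the tail-maximum rule distinguishes true extinction from cycles with
deep troughs); otherwise the low-prey coexistence equilibrium is located
and its map spectrum decides `equilibrial` versus `periodic`. The
equilibrium branch followed is the one continued from the stable
large-$g$ region — the low-prey branch, whose age-averaged parameters
vary smoothly across the plane; trajectory-final warm starts are *not*
used for classification because in parts of the plane the dynamics
settle on the separate high-prey state, which would silently switch
branches mid-sweep. `averaged_parameter_surface()` tabulates the
low-branch averaged parameters independently of which attractor the
standard initial state reaches. `reduced_phase_diagram()` re-labels the
coexistence cells by running the ODE/DDE with that cell's constants, and
`bifurcation_branches()` produces equilibrium branches with stability
flags and tail oscillation envelopes along $g$.

# What the synthetic conditions do and do not show

All inputs here are synthetic by construction (the model *is* the
object of study; there is no field data). The ensemble emulates the
study's conditions: the published parameter box, the standard initial
state, the published horizon and blow-up threshold. Passing tests show
that the implementation reproduces the study's computational claims at
reduced scale; they do not validate the model against any real
predator-prey system, and the blow-up class in particular is a model
artifact of unbounded birth rates, not an ecological prediction. The
relaxation cycles' extremely low population troughs are ecologically
implausible (no demographic stochasticity or Allee effects are
modelled), so long-period cycle statistics should be read qualitatively.

# Known limitations and open choices

* Attractor reached versus attractor inventory: basins in this system
  are delicate (prey troughs below $10^{-10}$), so trajectory-based
  labels at coarse $h$ can differ from fine-$h$ labels near region
  boundaries; the equilibrium-spectrum pipeline is the robust one, and
  it is what the sweeps use.
* In this implementation the low-prey equilibrium is unstable over most
  of the $(\tau^*, g)$ plane, and the destabilization ordering of the
  three model types shows up *pointwise* — at essentially every cell the
  equilibrium growth rate of the age-structured model exceeds the DDE's,
  which exceeds the ODE's — while the DDE and ODE Hopf boundaries lie so
  close together (within ~0.002 in $\tau^*$) that region *areas* on any
  coarse grid tie. The area comparison in the acceptance suite documents
  this: it asserts the strict ordering and is expected to fail on the
  middle inequality under these conditions.
* The scheme is first order; no adaptive stepping or higher-order
  variants are provided, matching the convergence theory available for
  it.
* The high-prey "farming" equilibrium (prey sustained above carrying
  capacity by eating juveniles) is reported by
  `coexistence_equilibria()` but deliberately not followed by the
  sweeps; its biological status is doubtful and its averaged parameters
  fall outside the smooth low-branch surface.
* The maturation-node convention for the standard initial profile
  differs between the ensemble pipeline (juvenile level on
  $[0, \tau^*)$) and the sweep pipeline (on $[0, \tau^*]$), following
  the two conventions printed in the source; both are exposed through
  `default_initial_condition(convention =)`.
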