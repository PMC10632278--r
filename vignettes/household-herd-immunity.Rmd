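---
title: "Herd immunity in household-structured epidemics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herd immunity in household-structured epidemics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhimmunity)
```

## The model

A closed population of $N$ individuals is partitioned into $m$ households;
a fraction $\alpha_n$ of households have size $n$, for
$n = 1, \dots, n_{\max}$ with $n_{\max}$ finite. An infective makes global
contacts with each given individual at rate $\lambda_G / N$ and local
contacts with each given housemate at rate $\lambda_L$. Newly contacted
susceptibles pass through an exposed period $T_E$ and an infectious period
$T_I$, then recover permanently. All contact processes and period
variables are independent. The final-outcome algebra requires only the
mean $E[T_I]$ and Laplace transform $\phi(\theta) = E[e^{-\theta T_I}]$
(exponential, fixed and Erlang laws are provided); the deterministic ODE
limit and the Gillespie simulator additionally assume Markov dynamics,
$T_I \sim \mathrm{Exp}(\gamma)$ and $T_E \sim \mathrm{Exp}(\delta)$.

Final outcomes are invariant to the latent period, so every quantity built
from final sizes ($R_*$, $\tilde h_D$, $h_C$) is the same for SIR and SEIR
variants; only the trajectory-based levels $h_D$ (SIR) and $h_D^L$ (SEIR)
distinguish them.

Two distributions recur throughout. The household size distribution $H$
(of a random *household*) and its size-biased version $\tilde H$ (the
household size of a random *individual*), with
$\tilde\alpha_n = n\alpha_n / \mu_H$. The mean $\mu_{\tilde H}$, variance
$\mathrm{var}(\tilde H)$ and factorial moments
$\mu^{[k]}_{\tilde H}$ of $\tilde H$ are what the ordering results see.

## Quantities computed

* $R_*$: mean global contacts emanating from a newly infected household —
  the epidemic threshold (take-off possible iff $R_* > 1$).
* $R_0$: rank-generation basic reproduction number — the asymptotic
  geometric growth rate of mean shortest-path generations in the infection
  graph; comparable across household structures, unlike $R_*$.
* $h_C$: unique root of $\hat R_U(c) = 1$, where $\hat R_U$ is the
  post-vaccination threshold parameter under uniform vaccination with a
  perfect vaccine.
* $\tilde h_D$: run a first epidemic with global rate $\kappa\lambda_G$
  (local rate untouched) to its final outcome; choose $\hat\kappa$ so the
  residual threshold parameter $\hat R_{DI}(\hat\kappa)$ of a second,
  unrestricted epidemic equals 1; report the first epidemic's final size.
* $h_D$, $h_D^L$: integrate the deterministic household ODE system from a
  small seeded fraction, monitor the residual threshold parameter
  $R_V(t)$, and report $1 - S(T_*)$ at its first crossing of 1.
* $\hat h_D$: as $h_D$ but with the first epidemic under a constant global
  restriction factor $\kappa \in (\hat\kappa, 1]$; it decreases from
  $\tilde h_D$ (at $\kappa \downarrow \hat\kappa$) to $h_D$ (at
  $\kappa = 1$).

## Algorithms and numerical choices

**Single-household algebra.** The coefficients $\beta_k(\lambda_L)$
solving $\sum_{i\le k}\binom{k}{i}\beta_i\phi(i\lambda_L)^{k-i} = k$ are
obtained by forward substitution (the system is unit-triangular), giving
the mean final sizes $\mu_n(\lambda_L)$ and
$\tilde\mu_n(\lambda_L, \pi)$. The per-household outcome proportions
$P_{n,v}$ solve a second triangular system, solved in increasing $v$;
entries are clipped to $[0,1]$ with a negativity tolerance of $10^{-9}$
(beyond which an ill-conditioning error is raised — conditioning for
$n \gtrsim 25$ with extreme parameters is untested territory). The
$\lambda_L = \infty$ flag is a genuine branch, not a large float: it
routes to the exact two-point outcome $(\pi^n, 0, \dots, 1-\pi^n)$ and
$\mu_n = n$.

**Population final size.** $z$ solves
$z = \sum_n \tilde\alpha_n \tilde\mu_n(\lambda_L, e^{-\kappa\lambda_G
E[T_I] z})/n$. Zero is always a root; when the effective $R_*$ exceeds 1
the epidemic root is the unique root in $(0,1)$, bracketed on
$[10^{-12}, 1]$ and solved to $10^{-14}$. Below threshold the solver
returns $z = 0$ without root-hunting. $\pi = 0$ (all introduced) is
handled analytically. Series over $n$ are exact finite sums up to
$n_{\max}$.

**Rank generations.** Conditional on the sum of the current generation's
infectious periods, each not-yet-reached housemate is reached
independently, so the generation process is a Markov chain on (frontier
size, unreached count) with
$P(k \mid f, u) = \binom{u}{k}\sum_j \binom{k}{j}(-1)^j
\phi((j+u-k)\lambda_L)^f$. This gives the mean generation sizes
$\mu_i^{(n)}$ *exactly* for every $n$ at $O(n^3)$ cost; no Monte Carlo
fallback is needed. The construction is validated against brute-force
enumeration of all digraph realisations for $n \le 3$ and against the
partition identity $\sum_i \mu_i^{(n)} = \mu_n(\lambda_L)$. $R_0$ is then
the unique positive root of
$1 = \lambda_G E[T_I]\sum_i \mu_i \lambda^{-(i+1)}$, bracketed on
$(0,\, \lambda_G E[T_I]\sum_i\mu_i + 1]$ — the left side is monotone.

**$\tilde h_D$ solver.** Nested monotone root finds: the outer variable is
$\kappa \in (R_*^{-1}, 1)$ with $\hat R_{DI}(\kappa) - 1$ decreasing; each
evaluation solves the inner final-size fixed point and assembles
$\hat R_{DI}$ from the outcome proportions. Tolerances: $10^{-12}$ on
$\kappa$, $10^{-14}$ on the inner root. In the $\lambda_L = \infty$ branch
the solver works directly in $\pi$ via
$\pi f'_{\tilde H}(\pi) = 1/(\lambda_G E[T_I])$, avoiding the nesting.
Degenerate all-size-one populations collapse analytically to
$1 - 1/(\lambda_G E[T_I])$ before any solver runs.

**ODE limit.** States are household configurations $(s, e, i, r)$ with
$1 \le s+e+i+r \le n_{\max}$ ($e \equiv 0$ for SIR — SIR is integrated on
its own smaller state space rather than as SEIR with huge $\delta$, which
avoids stiffness). The drift is bilinear,
$\dot h = A h + \bar i(t)\, (B h)$ with $\bar i = \sum i\,h$, so the
generator is prebuilt as two dense matrices and each derivative evaluation
is two mat-vecs. One modelling point deserves emphasis: with $h$ a
*per-household* density, the global force of infection per susceptible is
$\kappa\lambda_G \bar i / \mu_H$ — the $1/\mu_H$ normalisation is required
for the ODE final size to converge to the final-size fixed point $z$ as the
seeding fraction vanishes, and the test suite checks exactly that
($|\Delta| < 10^{-4}$ at seeding $10^{-5}$... $10^{-7}$).

Integration uses `deSolve::lsodar` with `rtol = 1e-10`, `atol = 1e-12`,
two root functions ($R_V(t) - 1$, and exposed-plus-infective mass
$10^{-12}$ for extinction) and a horizon of $10^4$ time units. Which root
fired is disambiguated by whether $R_V = 1$ (within $10^{-6}$) at the
stop: the extinction root with $R_V$ still above 1 signals that the
restriction factor is at or below $\hat\kappa$. The initial condition
seeds a fraction $\epsilon$ of households — taken from the largest size
class — in state $(n_{\max}-1, 0, 1, 0)$, all others fully susceptible.
The default $\epsilon = 10^{-5}$ is small enough that levels move by less
than $10^{-3}$ when $\epsilon$ shrinks another decade (tested), yet large
enough that the crossing time stays moderate.

**Residual threshold parameter.** For a frozen household state density,
$R_V = (\lambda_G E[T_I]/\mu_H)\sum h_{s,e,i,r}\, s\, \mu_s(\lambda_L)$:
a global contact lands on a susceptible member of a household with $s$
susceptibles with probability $s h / \mu_H$ and triggers a local epidemic
of mean size $\mu_s$ among them; exposed, infective and recovered members
all count as non-susceptible to the second epidemic. The same formula with
empirical household counts defines the simulator's $R_V^{(m)}(t)$. It
reproduces $R_*$ on a fully susceptible density and the
pgf-route residual parameter on all-or-nothing densities, which is how the
assembled formula is validated.

**Growth rate and calibration.** For Markov laws the early epidemic is a
branching process of household epidemics connected by global contacts; its
Malthusian parameter solves
$\lambda_G \sum_n \tilde\alpha_n \int e^{-rt} E[I_n(t)]\,dt = 1$, with the
Laplace transform computed by one linear solve against the
within-household generator restricted to transient states (valid for
$r$ above minus the slowest decay rate; the solver brackets accordingly).
This reduces to $r = \lambda_G - \gamma$ for homogeneous SIR and satisfies
$(1+r/\delta)(1+r/\gamma) = \lambda_G/\gamma$ for homogeneous SEIR, which
pins it to the standard growth-rate/reproduction-number relationship used
for calibrated comparisons (day units: $\delta = 1/3$,
$\gamma = 1/4$). Because the within-household transform does not involve
$\lambda_G$, calibration to a target growth rate is a single division, not
a root find.

**Orderings.** In the highly locally infectious case the classifiers
compare factorial moments of $\tilde H$ against the geometric reference
$k!\,\mu(\mu-1)^{k-1}$ (just-supercritical regime) or iterate the
convolution criterion on the pmf (high-global regime,
$G^{(n)}(0) = n!\,[(1-n)\tilde\alpha_n +
(\mu-1)\sum_k \tilde\alpha_{n-k}\tilde\alpha_k]$, verdict from the sign of
the first non-zero derivative). A subtlety: any finite-support truncation
of a geometric pmf *genuinely* deviates from the infinite-support
geometric moments, so equality could never be reported from moments alone.
The classifiers therefore first test the pmf for the constant-ratio
(geometric) form — the exact distribution-level characterisation of
equality — and report `equality/geometric` with the truncated mass
recorded; the moment loop (up to $k = n_{\max}$, relative tolerance
$10^{-9}$) only runs otherwise, and an exhausted loop reports
`inconclusive` rather than guessing.

**Simulator.** Two engines. Gillespie (Markov laws) operates on
per-household counts — members are exchangeable, so $(s, e, i)$ per
household is sufficient — with Fenwick trees giving $O(\log m)$ weighted
sampling of the household hit by each event, and maintains
$R_V^{(m)}(t)$ incrementally for empirical disease-induced levels. The
Sellke-threshold engine (any infectious-period law; final outcome only)
assigns each individual an $\mathrm{Exp}(1)$ infection-pressure threshold
and iterates the exposure map to its fixed point, which is exact for
final sizes and fully vectorised. Major outbreaks are classified by final
fraction exceeding $\max(0.1\,z, 20/N)$, separating the bimodal final-size
distribution. Populations are built either with largest-remainder rounding
of $m\alpha_n$ (exact mode) or by sampling sizes (both seeded).

## The synthetic household-size generator

`random_household_distribution(seed, n_max, mean, var)` produces test
distributions with a prescribed size-biased mean and variance — the
coordinates that the ordering corollaries live on. A Dirichlet draw over
$\{1,\dots,n_{\max}\}$ is exponentially tilted in $(n, n^2)$, with a
damped Newton iteration on the two tilting parameters (the Jacobian is the
covariance matrix of $(n, n^2)$, so the iteration is well-conditioned on
the interior of the moment set); boundary targets are returned as their
unique two-point or point-mass solutions. Feasibility
($1 \le \mu \le n_{\max}$,
$\mathrm{frac}(\mu)(1-\mathrm{frac}(\mu)) \le \sigma^2 \le
(\mu-1)(n_{\max}-\mu)$) is checked up front and violations report the
feasible range. The generator emulates the *moment structure* of real
household census data; it does not emulate other features of real
distributions (unimodality, monotone tails), so passing tests demonstrate
correctness of the moment-driven theory, not realism of any particular
country's census.

The related constructor `geometric_size_biased(mu, n_max = 30)` builds the
logarithmic household distribution whose size-biased version is geometric
— the unique structure with $\tilde h_D = h_C$ for every supercritical
global rate in the highly locally infectious case — truncated at
$n_{\max}$ (default 30) with the discarded mass reported as an attribute.

## Problem sizes and runtime

The shipped tests run the ODE solvers on household sizes up to 5 (55 SIR /
125 SEIR states), Monte-Carlo oracles at $10^4$–$10^5$ replicates,
stochastic populations of $10^3$–$10^4$ households, and theorem grids over
roughly a dozen $(\lambda_G, \lambda_L)$ combinations per result; the full
suite completes in well under a minute on one CPU. These sizes were chosen
so each check's discrimination (standard errors, truncation error) is an
order of magnitude below its assertion tolerance.

## Known limitations

* $h_D$/$h_D^L$ require Markov dynamics and a moderate $n_{\max}$: the
  SEIR state space grows like $n_{\max}^4/24$, so trajectory-based levels
  for $n_{\max} \gtrsim 10$ become expensive (the final-size quantities
  $\tilde h_D$, $h_C$, $R_*$, $R_0$ have no such restriction).
* Restrictions are modelled as a *constant* factor $\kappa$ on the global
  rate; time-varying schedules are out of scope.
* The triangular outcome system is solved in plain double precision; for
  $n \gtrsim 25$ with extreme $(\pi, \lambda_L)$ it can lose accuracy, and
  the solver raises an error rather than returning clipped garbage.
* The growth-rate construction is the household Lotka–Euler equation; it
  agrees with the homogeneous closed forms and is internally consistent
  with the threshold quantities (same sign as $R_* - 1$, tested), but
  non-Markov laws are rejected rather than approximated.
* Whether the trajectory-based levels should use SIR or SEIR dynamics in
  time-unit-normalised comparisons is a genuine modelling choice; the
  package uses SIR with $\gamma = 1$ and $\epsilon = 10^{-5}$ for
  `table1_point`, and exposes $h_D^L$ separately so the latency effect can
  be examined directly.
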