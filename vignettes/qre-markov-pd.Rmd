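---
title: "Quantal response and Nash equilibria for the Prisoner's Dilemma in memory-one strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal response and Nash equilibria for the Prisoner's Dilemma in memory-one strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its model, its numerical
conventions, and the design decisions that were genuinely open.  Every
number quoted here is computed by the package's own tests or by
`scripts/acceptance.R`.

## The game and the strategy space

Two players repeatedly play a Prisoner's Dilemma with stage payoffs
R = 5, S = 0, T = 10, P = 1 (row player; `payoff_matrix()` generalizes all
formulas to an arbitrary 2×2 matrix through the bilinear coefficients
`payoff_coefficients()`).  A *memory-one (Markov) strategy* is a pair
(α, γ): the probability of cooperating after the opponent defected
(*tolerance to defection*) and after the opponent cooperated (*mutual
cooperation*).  The coupled response dynamics

$$p_1(t) = \gamma_1 p_2(t-1) + \alpha_1 (1 - p_2(t-1)), \qquad
  p_2(t) = \gamma_2 p_1(t-1) + \alpha_2 (1 - p_1(t-1))$$

have the stationary state

$$p_1 = \frac{\alpha_1 - \alpha_2(\alpha_1-\gamma_1)}
             {1 - (\alpha_1-\gamma_1)(\alpha_2-\gamma_2)},$$

and symmetrically for $p_2$.  When
$(\alpha_1-\gamma_1)(\alpha_2-\gamma_2) = 1$ (to within $10^{-12}$) the
denominator vanishes and no unique stationary state exists;
`stationary_probabilities()` raises an error rather than returning a limit,
because different approach directions give different limits.  The tests
verify the closed form against the stationary distribution of the explicit
4-state pair chain.

Player 1's stationary payoff is
$U(p_1, p_2) = -4 p_1 p_2 - p_1 + 9 p_2 + 1$ with the default matrix.

## The symmetric totally mixed Nash curve

At an interior symmetric equilibrium both first-order conditions
$\partial U/\partial \alpha_1 = \partial U/\partial \gamma_1 = 0$ must hold
at $\alpha_1=\alpha_2=\alpha$, $\gamma_1=\gamma_2=\gamma$.  Carrying out the
differentiation symbolically, both partials factor as

$$\frac{\partial U}{\partial \alpha_1} \propto -(\gamma-1)\,K(\alpha,\gamma),
\qquad
\frac{\partial U}{\partial \gamma_1} \propto \alpha\,K(\alpha,\gamma),$$

with the shared conic factor

$$K(\alpha, \gamma) = 5\alpha^2 + 9\gamma^2 - 14\alpha\gamma
  + 14\alpha - 10\gamma + 1 .$$

$K = 0$ is the operative equilibrium curve (`nash_implicit()`, variant
`"derived"`).  A previously published version of this conic lacks the
$14\alpha$ term.  That version is kept verbatim as variant `"printed"`
because the difference is instructive: the printed conic admits unit-square
solutions at arbitrarily large α (its γ-discriminant never vanishes on
[0, 1], so `max_tolerance("printed")` is 1), which contradicts the known
geometry of the curve, and it fails the numeric first-order-condition
oracle everywhere off the two shared endpoints (0, 1/9) and (0, 1).  The
derived conic passes that oracle along its whole arc; the package treats
the missing linear term as a transcription artifact and never uses the
printed variant in a solver.

The curve is parameterized per α by the quadratic
$9\gamma^2 - (14\alpha+10)\gamma + (5\alpha^2+14\alpha+1) = 0$; the two
branches merge where the discriminant $16(\alpha^2 - 14\alpha + 4)$
vanishes, at $\alpha = 7 - 3\sqrt 5 \approx 0.29180$ — the maximal
tolerance to defection (`max_tolerance()`), confirmed independently by
dense sampling at resolution $10^{-4}$.

## The symmetric logit QRE

Each coordinate responds to the payoff difference between its two pure
restrictions:

$$\alpha = \frac{e^{\lambda U|_{\alpha=1}}}
                {e^{\lambda U|_{\alpha=0}} + e^{\lambda U|_{\alpha=1}}},
\qquad
\gamma = \frac{e^{\lambda U|_{\gamma=1}}}
              {e^{\lambda U|_{\gamma=0}} + e^{\lambda U|_{\gamma=1}}}.$$

The restricted payoffs $U|_{\alpha=0}$ etc. are computed by substituting
the pure strategy for player 1 in the *asymmetric* stationary state and
only then symmetrizing the remaining parameters
(`restricted_stationary()`).  This ordering is essential: symmetrizing
first collapses the four cases to a far poorer set.  The resulting pairs
are deliberately asymmetric in $(p_1, p_2)$ and retain α inside the
"α = 0" expressions — these are formal restriction labels, not ordinary
substitutions.

Two of the four published closed forms for these payoffs
(the γ-pair) carry mistranscribed leading terms: the $-p_1$ term of
$U|_{\gamma=0}$ appears as $-(\alpha^2+\alpha)$ where the substitution
gives $-(\alpha-\alpha^2)$, and that of $U|_{\gamma=1}$ as $-\alpha^2$
where the substitution gives $-(2\alpha-\alpha^2)$.  The package therefore
defines the restricted payoffs *by substitution* (which also matches the
worked value $U|_{\alpha=0}(0.5, 0.5) = 4.75$), keeps the verbatim forms in
`restricted_payoffs_printed()`, and asserts the discrepancy in the test
suite rather than hiding it.

### Numerical conventions

* **Overflow.** Logit responses are computed as
  $1/(1+e^{\lambda(u_0-u_1)})$ with the exponent clamped to ±700; the
  residual is finite up to $\lambda = 10^6$ and beyond.
* **Singular corners.** The restricted states have isolated vanishing
  denominators (e.g. (α, γ) = (0, 1) for the α = 0 case).  The residual is
  defined as 2 there — its supremum on the square — so lattice sweeps and
  bounded optimizers remain well-defined; no minimum is ever located there.
* **Residual minimization.**  `solve_qre()` evaluates the residual on the
  full deterministic 21×21 lattice and refines the best 10 lattice points
  (plus the warm start) with bounded L-BFGS-B using central-difference
  gradients (step $10^{-6}$).  Refining only the screened starts, rather
  than all 441, is about forty times faster and provably immaterial here:
  the tests compare every solve against a pure-enumeration global-minimum
  oracle (401×401 lattice with a $10^{-5}$ zoom inside the winning cell).
  A solution counts as converged when the residual is below $10^{-10}$.
* **Branch continuity.**  In a continuation trace, refined minima tying
  within $10^{-8}$ of the best value are resolved toward the warm start.
  This matters above λ ≈ 6 where several exact equilibria coexist.
* **Local-minima census.**  `count_local_minima()` uses strict 8-neighbour
  comparison on an interior lattice (default 201 per axis), refines each
  candidate, and merges refined minima closer than 0.02.  The merge radius
  and lattice rule were fixed once for stability across resolutions
  101–401.

## What the traced curve actually does

Tracing the global-minimum QRE with warm starts from λ = 0 (grid step
0.01) gives a smooth branch from (0.5, 0.5) that crosses the derived Nash
curve **once, at λ ≈ 5.65, near (α, γ) ≈ (0.203, 0.471)** (bisection
refinement to width $10^{-3}$).  Two findings about this landscape deserve
emphasis because they differ from earlier descriptions:

1. **The residual landscape is not single-basin at small λ.**  Besides the
   principal minimum, a shallow but genuine strict local minimum (depth
   ≈ 0.04, positive-definite Hessian) exists near (0.27, 0.95) already at
   λ = 2.  On 1/5-power contour plots it is nearly invisible, which likely
   explains earlier uniqueness claims for λ below ~4.

2. **The equilibrium branch never collapses to (0, 0).**  At α = 0 the two
   γ-restricted states both sit at mutual defection, so
   $U|_{\gamma=0} = U|_{\gamma=1} = 1$ identically and the γ-logit response
   is exactly 1/2 at any λ; the residual at (0, 0) is 0.25, and (0, 0) is
   never a fixed point.  The global-minimum branch instead continues along
   the Nash curve toward a cooperative boundary equilibrium
   (≈ (0.39, 1) as λ → ∞).  `find_collapse_threshold()` implements the
   delta-ball criterion faithfully and accordingly raises a no-collapse
   error on the default trace.

   The collapse toward defection is real nonetheless — as a *solver*
   phenomenon.  Re-solving at each λ from the fixed start (0.5, 0.5) with
   a single bounded local minimization
   (`trace_qre(method = "single_start")`), the trajectory follows the
   cooperative branch up to λ = 7.00 and then drops permanently into a
   non-equilibrium residual minimum in the defection basin, whose
   minimizer approaches (0, 0) as λ grows.  `find_defection_onset()`
   reports the onset of that permanent departure — **λ = 7.08 at grid step
   0.01** — which is the reproducible, well-defined version of the
   defection-collapse rationality.  The onset is robust here across two
   independent L-BFGS-B implementations; it is by construction a property
   of (landscape × optimizer × start), not of the equilibrium
   correspondence alone, and is documented as such.

The *small-rationality segment* — the traced branch up to the
Nash-intersection rationality, closed with the refined crossing point —
serves as the phase boundary for classification.  `classify_point()`
projects a strategy onto the segment polyline and labels it `above`,
`below`, or `near` (half-width 0.05) by its γ relative to the nearest
segment point.  The rule is deliberately simple; labels are stable under
2× resampling of the polyline (tested), and no statistical claim is
attached to the separation.

## Estimation from play logs

`estimate_strategy()` counts memory-one transitions: the opponent's choice
at round t−1 conditions the focal choice at t, counted only when the same
pairing persisted across both rounds (a re-match breaks the conditioning
object).  First rounds carry no transition but do count toward
`cooperation_rate()`.  Group estimates pool counts across players before
forming ratios — the maximum-likelihood estimate under a shared strategy,
and deliberately *not* the mean of per-player ratios.  Zero denominators
propagate as missing values and are excluded from classification with a
warning count.

## The synthetic experiment generator

Real session logs of the motivating experiments are not publicly
deposited, so `generate_experiment()` emulates the design: 12 strangers
play 11–22 rounds, are split into two groups of 6, and play 15–20 rounds
again.  Per-player strategies are drawn per phase from uniform boxes,
**synthetic stand-ins** chosen once so that pooled cooperation rates
bracket the reported 22% / 58% shift: [0, 0.3] × [0, 0.4] before and
[0.2, 0.7] × [0.5, 1.0] after.  Pairing defaults to a fresh random perfect
matching every round (a fixed-partner mode is provided; the original
protocol is unreported), first-round cooperation defaults to 0.5 (the
response dynamics define behavior only conditional on a previous round),
and round counts are drawn uniformly per experiment.  Everything is
reproducible byte-for-byte from the design seed.

What the generator does *not* emulate: the socialization process itself
(the phase shift is imposed through the strategy boxes), player
heterogeneity beyond the boxes, within-session learning, and the unknown
true pairing protocol.  Passing the recovery tests therefore shows the
estimators are consistent for data of this structure — not that the boxes
describe human play.

## Problem sizes and runtime

Default analyses use: λ grids 0–8 (continuation) and 0–10 (single-start)
at step 0.01; a 21×21 restart lattice with 10 refinements per solve;
201×201 census lattices; 100 pairs × 500 rounds for estimator recovery;
14 synthetic experiments for the calibration bracket.  The full test suite
runs in about a minute on one CPU, the acceptance script in about half a
minute.

## Known limitations

* Only the symmetric QRE is computed; asymmetric equilibria and
  heterogeneous-rationality populations are out of scope.
* The defection-onset rationality is solver-relative (fixed start
  (0.5, 0.5), bounded L-BFGS-B); other optimizers may shift it within a
  few grid steps.
* The classification rule is geometric, not inferential.
* The estimator assumes a stationary memory-one strategy per player per
  phase; time-varying or longer-memory behavior biases it.
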