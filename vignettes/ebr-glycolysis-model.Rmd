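---
title: "Glycolysis in ethanol-consuming erythrocyte-bioreactors: model and methods"
author: "ebrglyc"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Glycolysis in ethanol-consuming erythrocyte-bioreactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebrglyc)
```

## The biological problem

Erythrocyte-bioreactors (EBRs) are red blood cells loaded with foreign
enzymes. For blood alcohol removal the cells are loaded with alcohol
dehydrogenase (ADH), which oxidizes ethanol to acetaldehyde using NAD, and
acetaldehyde dehydrogenase (ALDH), which oxidizes the acetaldehyde further
to acetate, again using NAD. Both reactions draw on the same intracellular
NAD pool that glyceraldehyde-phosphate dehydrogenase (GAPDH) needs to keep
glycolysis — the cell's only ATP source — running. This shared-cofactor loop
is the core of the model: the harder the load enzymes pull on NAD, the more
GAP must accumulate for GAPDH to sustain the glycolytic flux, and beyond a
threshold the coupled system stops settling into a steady state at all.

`ebrglyc` implements the full kinetic model of this system and the analysis
workflow around it: stiff time integration, suspension-level consumption
kinetics, steady-state solving with linear stability analysis, regime scans
with bisection-refined boundaries, and limit-cycle quantification.

## Model structure

The state comprises the glycolytic intermediates (G6P, F6P, FDP, DAP, GAP,
1,3-DPG, 2,3-DPG, 3-PG, 2-PG, PEP), pyruvate and lactate, NAD, the adenylate
energy charge $\Phi$, acetaldehyde, and — in suspension simulations —
ethanol. Two conservation laws and one fast equilibrium close the system
algebraically:

* $[\mathrm{NAD}] + [\mathrm{NADH}] = N = 0.05$ mM,
* $[\mathrm{ATP}] + [\mathrm{ADP}] + [\mathrm{AMP}] = P = 1.744$ mM,
* adenylate kinase at equilibrium,
  $[\mathrm{ATP}][\mathrm{AMP}] = K_{AK}[\mathrm{ADP}]^2$ with $K_{AK}=1$.

Given $\Phi = (2\,\mathrm{ATP} + \mathrm{ADP})/(2P)$, the split into ATP,
ADP and AMP reduces to one quadratic in ADP whose non-negative root is
always the physical one for $\Phi \in [0,1]$ (`adenylate_split()`). Only
$\Phi$ is integrated; the nucleotides are recovered algebraically, so the
pools are conserved to machine precision by construction.

Nineteen rate laws drive the mass balances: hexokinase (HK, strongly
product-inhibited by G6P), glucose-6-phosphate isomerase, phosphofructokinase
(PFK), aldolase, triosephosphate isomerase (TPI), GAPDH, phosphoglycerate
kinase, the 2,3-DPG shunt (diphosphoglycerate mutase and phosphatase, which
bypasses the ATP-producing PGK step and carries ~0.62 of the 2.24 mM/h
triose flux), phosphoglycerate mutase, enolase, pyruvate kinase (PK),
lactate dehydrogenase, the Na/K pump and a lumped ATPase, the two load
enzymes (ordered bi-bi reversible ADH with equilibrium constant
$2\times10^{-4}$; irreversible NADH-inhibited ALDH), and saturable,
cross-inhibited pyruvate and lactate transport. All concentrations are mM
and all rates mM/h, normalized per liter of cells. HK is glucose-independent
(blood glucose is far above its Km), orthophosphate is clamped at 1 mM,
extracellular pyruvate and lactate at 0.07 and 1.2 mM, and extracellular
acetate at zero; acetaldehyde does not leave the cells, while ethanol
equilibrates freely across the membrane.

The PFK law deserves a note, because it carries the oscillation mechanism.
It combines a Michaelis core in ATP and F6P, a saturating (at most two-fold)
AMP activation factor
$g = 1/(1+\mathrm{AMP}/K_3) + 2\,\mathrm{AMP}/(K_3+\mathrm{AMP})$, and a
concerted allosteric factor $1 + L$ with

$$L = 10^8\,\frac{(1+\mathrm{ATP}/K_4)^4}{(1+\mathrm{AMP}/K_3)^4\,(1+\mathrm{F6P}/K_5)^4},$$

so ATP stabilizes and AMP/F6P destabilize the inactive conformation with
fourth-power cooperativity. At the resting state the enzyme is ~98%
suppressed ($L \approx 55$); small swings in AMP or F6P change the rate
steeply. The saturating Michaelis part matters just as much: because the
F6P half-saturation stays fixed at 0.1 mM, PFK cannot drain F6P (and hence
G6P) to zero when ATP falls, so HK remains product-inhibited during the
low-ATP phase of a cycle and trajectories stay bounded through the
oscillatory window instead of running away immediately.

## Regimes and how they are detected

With ethanol clamped and the two load activities varied together
($\alpha_{ADH}=\alpha_{ALDH}=\alpha$), the model passes through four regimes
as $\alpha$ grows:

1. **Stable steady state.** Found by a damped-Newton branch tracker (with a
   scaled Levenberg–Marquardt fallback) on the 15-dimensional
   clamped-ethanol system; stability from the eigenvalues of a
   central-finite-difference Jacobian (relative step $10^{-6}$, floor
   $10^{-9}$ mM; stable means every real part below $-10^{-9}$ h$^{-1}$).
   When both activities are zero, the acetaldehyde equation is structurally
   decoupled (identically zero) and that dimension is excluded from the
   eigenvalue analysis.
2. **Sustained oscillations.** The steady state loses stability through a
   complex pair (a Hopf-type onset, located by bisection on the leading
   eigenvalue). Near onset the cycles are fast and small; toward the upper
   end of the window they become large, slow relaxation oscillations, with
   a coexistence region in between (the fast/slow transition that
   `amplitude_period_curve()` reports as the largest adjacent-point jump in
   period).
3. **Unbounded accumulation.** FDP, DAP and GAP grow without bound while an
   (unstable) steady state still exists; ATP collapses and PFK becomes
   substrate-limited, which is why the accumulation rate *decreases* with
   further activity increases.
4. **No steady state.** The glycolytic branch ends in a fold (saddle-node):
   GAP accumulation can no longer compensate the NAD drop, and GAPDH cannot
   carry the resting flux. The fold is located by adaptive branch tracking
   with a secant predictor (`track_fold`), and non-existence at a point is
   only declared after a multi-start policy (continuation guess, the
   resting reference, and 10 seeded log-uniform random starts) fails.

A caveat on root finding: the model has a second, non-physiological fixed
point at essentially zero glycolytic flux (ATP near zero, consumption run
entirely on pyruvate-import-fueled NAD recycling). Root searches therefore
accept only roots on the glycolytic branch (hexokinase flux above 0.01
mM/h) unless the caller asks for `branch = "any"`.

`classify_regime()` follows the trajectory from the resting start for 600 h
when the root is unstable or absent. Because cycles near the upper boundary
have periods of tens of hours, oscillation is judged by *returns*: the
trajectory counts as accumulating only if the FDP floor rises above 50 mM
and keeps rising to the end of the run; a trajectory that keeps coming back
below the threshold is oscillatory, and one that is above the threshold but
already falling again at the end is reported UNRESOLVED rather than forced
into either class. The 50 mM threshold and the 600 h horizon are the
package's own choices (the regime itself is defined by unboundedness);
tests check that the classification is insensitive to halving the solver
tolerances.

## Numerical choices

* **Integration.** Backward-differentiation formulas (`deSolve::ode`,
  `method = "bdf"`), relative tolerance $10^{-8}$, absolute tolerance
  $10^{-10}$ mM. The system is stiff: TPI turns over at ~2×10⁴ mM/h next
  to net fluxes of 1–2 mM/h, and the Jacobian spectrum spans ~10⁶.
  Trial states proposed by the implicit solver are clamped to the physical
  region (non-negative, $\Phi\in[0,1]$, NAD ≤ N) before rate evaluation;
  genuine negative inputs anywhere else raise errors.
* **Steady states.** Damped Newton on the full right-hand side with
  backtracking line search; Levenberg–Marquardt (trust-region class, via
  `minpack.lm`) in variables scaled by the guess as fallback; residual
  norm below $10^{-8}$ mM/h required.
* **Boundaries.** Stability and existence refined to 0.1 (mM/h on the
  activity axis, mM on the ethanol axis); the oscillation/accumulation
  boundary bisected on the trajectory classification.
* **Oscillation metrics.** Peak-based period (three-point quadratic
  interpolation of maxima) rather than spectral estimation, because the
  cycles are strongly non-sinusoidal in the slow regime; amplitude over the
  last three full cycles; a cycle is only "accepted" with ≥5 post-transient
  peaks and successive-period dispersion below 1%. Phase lags come from
  circular cross-correlation over a whole number of cycles, reported in
  $(-T/2, T/2]$.
* **Transients.** 100 h discarded by default (150 h in the window-mapping
  preset); doubling the transient changes accepted metrics by well under
  1%.
* **Reproducibility.** Everything is deterministic except the multi-start
  policy for declaring non-existence, which takes an explicit seed
  (default 0).

## What the standard runs show

The default parameterization reproduces the resting red-cell steady state
(hexokinase flux 1.118 mM/h, GAPDH/PK flux 2.236 mM/h, PGK flux 1.614 mM/h,
ATP 1.470 mM, ADP 0.236 mM) and the qualitative regime sequence described
above. In this reconstruction the oscillatory window on the activity axis
at 10 mM clamped ethanol runs from ≈105.8 to ≈108.3 mM/h with the fold at
≈164 mM/h; on the ethanol axis at 40 mM/h activity the stable branch ends
at ≈31.7 mM with the fold at ≈57.4 mM. The consumption ceiling is robust:
the steady ethanol consumption rate saturates at ≈1.55 mM/h at the fold
(NAD down to 0.025 mM), and ≈1.50 mM/h marks the hand-off from oscillation
to accumulation — raising the loaded activity beyond the window buys no
extra consumption and only destabilizes the cell. An ADH-only loading
stalls after ≈40 µM of ethanol (per liter of cells) once the ADH reaction
reaches equilibrium against its own acetaldehyde, which is the quantitative
argument for co-encapsulating ALDH.

Several printed rate laws in the source material for this model family are
typographically ambiguous; the forms implemented here were fixed by
requiring the resting steady state, the flux split, and the regime
phenomenology simultaneously, and the test suite pins every law against an
independent naive transcription. Residual reconstruction uncertainty shows
up almost exclusively in the positions of the regime boundaries, which sit
on flat fold/Hopf directions: the onset and fold on the activity axis land
a few percent above the values the model family is known for, while the
boundary *values* of consumption rate and NAD match closely. See the test
suite for the exact tolerances asserted.

## What the model does not cover

Cell volume is constant: the osmotic swelling and lysis that unbounded
FDP/DAP/GAP accumulation would cause in a real cell are outside the state
space, as are the pentose-phosphate pathway, Mg²⁺/pH dependence, glucose
dependence of HK, transmembrane-potential effects on transport, and any
acetate dynamics (extracellular acetate is clamped at zero and ALDH is
irreversible, so acetate never feeds back). The suspension model treats
ethanol as a single well-mixed compartment scaled by hematocrit and ignores
water-content corrections. Conclusions about real EBR preparations should
be read with these simplifications in mind: passing tests demonstrate the
internal consistency of this kinetic model and its agreement with the
printed benchmarks, not the behavior of cells beyond the model's scope.

## A minimal session

```{r example, eval = FALSE}
library(ebrglyc)

# resting steady state and fluxes
ss <- find_steady_state(ebr_parameters(), eth = 0)
ss$rates[c("V_HK", "V_GAPDH", "V_PGK")]

# suspension consumption at 60/60 mM/h load, 50% hematocrit
tc <- simulate_suspension(10, 0.5, alpha_ADH = 60, alpha_ALDH = 60,
                          t_end = 40)
tail(tc$state[, "ETH"], 1)

# regime scan over the load activity at 10 mM clamped ethanol
sc <- scan_activity(alpha = seq(0, 180, by = 4), eth = 10, classify = TRUE)
sc$boundaries
```
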