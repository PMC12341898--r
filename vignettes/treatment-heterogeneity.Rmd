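---
title: "Modelling genetic intra-tumor heterogeneity across treatment"
author: "gith package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genetic intra-tumor heterogeneity across treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gith)
```

## The model and its assumptions

`gith` treats a tumor as a linear birth–death branching process. Each cell
divides at rate $b$ and dies at rate $d$, independently of all others:
there is no spatial structure, no competition, no microenvironment, and
rates are constant within a phase. Two phases are modelled. Phase 1
(growth, $b_1 > d_1$) runs from a single ancestor until *detection*;
phase 2 (treatment) switches the rates abruptly to $b_2, d_2$, covering
shrinking ($b_2 < d_2$), constant ($b_2 = d_2$) and growing ($b_2 > d_2$)
disease. Heterogeneous response adds a second cell type: each daughter of
a sensitive cell acquires a heritable resistance mutation with probability
$\nu$ per division, after which the lineage follows resistant rates
(8 rate parameters in all; by default resistant cells are neutral before
treatment).

Neutral mutations accumulate at division: each daughter gains
$\mathrm{Poisson}(m)$ new mutations, so a division produces $2m$ mutations
on average. The infinite-sites assumption makes every mutation unique and
irreversible, which lets the simulator store only per-branch mutation
*counts* — mutation identities are exchangeable and never materialized.
Resistance mutations in already-resistant cells are ignored (the model has
exactly two types).

Two observation schemes matter biologically. Clinical detection happens at
a *size* $N_d$ (the first-passage time $T_N$ is then random, approximately
Gumbel with mean $E[T_N] = (\ln((b-d)N/b) + \gamma)/(b-d)$); laboratory
experiments stop at a *time*. `fixedSizeExpectation()` converts fixed-time
expectations to fixed-size ones by integrating against the Gumbel
first-passage density; for the spectrum statistics the two agree closely
at large $N_d$, and the analytic SFS/tMB functions use the fixed-time
forms with $N_d$ interpreted as the survival-conditioned mean size, which
is the convention under which the closed forms are exact.

Observing a tumor implies it escaped stochastic extinction, so all
predictions condition on survival through the factor
$1/(1 - \alpha(t)^a)$, where $\alpha(t)$ is the single-lineage extinction
probability. The simulator implements the same conditioning by rejection:
replicates extinct before detection are discarded and rerun with a fresh
seed derived deterministically from the base seed (the attempt count is
recorded). Extinction *during* treatment is a legitimate clinical outcome
and is kept unless `conditionOnFinalSurvival = TRUE`.

## What the simulator generates, and what it does not

`simulateTumor()` is an exact Gillespie simulation: waiting times are
exponential in the total event rate, the event cell is chosen
proportionally to its rates, and the full binary genealogy is recorded
(parent links, per-branch Poisson mutation counts, cell types, founder
flags, birth times, alive flags). Every summary statistic — SFS, branch
widths $W_k$, tMB, scMB, divisional distribution, clone size distribution
— is read off this tree, exactly as it would be read off a perfectly
genotyped population.

The generator therefore emulates *population-genetic* reality: drift,
survivorship bias, Poisson mutation noise, clone founding and extinction.
It deliberately does not emulate *measurement* reality: there is no
sequencing error, no read-depth noise, no purity or copy-number
distortion, and sampling a sequenced subset is modelled only as binomial
(optionally hypergeometric) subsampling of cells (`subsampleSFS`). Tests
passing against this generator therefore validate the mathematics and the
extraction logic, not robustness to sequencing artifacts. The VAF
conversion `vafToSFS()` ($S_k = V_{2k}$) likewise assumes pure, diploid,
copy-number-neutral samples and reports odd-index mass as unconvertible
rather than correcting it.

## Parameters that matter

| parameter | meaning | unit | typical default |
|---|---|---|---|
| $b_1, d_1$ | growth-phase birth/death rates | per cell per day | 1, 0–0.5 |
| $b_2, d_2$ | treatment-phase rates | per cell per day | regime-dependent |
| $m$ | neutral mutations per daughter per division | count | 1–5 |
| $\nu$ | resistance probability per daughter per division | probability | $10^{-7}$–$10^{-2}$ |
| $N_d$ | detection size | cells | $10^3$–$10^4$ (desk), $10^9$–$10^{10}$ (clinical) |
| $t_f$ / $N_f$ | treatment duration / final size | days / cells | scenario |

Two compound parameters control the resistance analytics: $\nu N_d$ (the
expected order of clone foundings; the clone-size laws assume
$\nu N_d \gg 1$) and $A = 2\nu N_d\, b_1/(b_1-d_1)$, which parameterizes
the largest-clone law. The *reference late-stage parameter set* used for
the resistant-load medians is $b_1 = 1$, $d_1 = 0.5$ per day (a typical
cell-loss factor of one half), $\nu = 6.9\times 10^{-7}$ (a point-mutation
resistance target), and $N_d = 10^{10}$ cells (roughly 10 cm$^3$ of
tumor): a plausible clinical detection scenario. Under it the median
resistant fraction is $\approx 3\times 10^{-5}$ and the median
largest-clone fraction $\approx 4\times 10^{-6}$; the latter is nearly
invariant in $N_d$ while the former grows weakly with $N_d$, because
resistant cells keep being seeded as the tumor grows.

Desk-scale study conditions (used throughout the tests and the acceptance
script, chosen to keep a full run in tens of seconds): detection sizes
$10^3$–$10^4$, 60–1000 replicates per ensemble, treatment intervals of a
few rate units. These sizes put ensemble means well inside the asymptotic
regime of the large-$N_d$ formulas while keeping per-bin Monte-Carlo error
measurable.

## Numerical choices

**Transition kernel.** $p(a \to n, t)$ dispatches between closed forms
(pure birth, pure death, single ancestor), an exact sum for
$\min(a,n) \le 50$, and a saddlepoint approximation beyond. The exact sum
is evaluated in log space with log-binomial coefficients and
log-sum-exp accumulation. The saddlepoint works on the cumulant generating
function $K(\theta) = a \ln G(e^\theta)$ of the $a$-fold geometric-with-
atom offspring law, solves $K'(\theta) = n$ by vectorized safeguarded
Newton (bracketed in $(-\infty, -\ln\beta)$), and renormalizes the mass
over $n \in [1, \text{mean} + 12\,\mathrm{SD}]$ against the exact
survival probability $1 - \alpha^a$. At the regime boundary the two
evaluations agree to better than 2%; Chapman–Kolmogorov holds to $10^{-4}$
on small instances.

**Critical case.** $b = d$ is its own closed-form branch
($\alpha = bt/(1+bt)$), guarded by a relative-tolerance switch
$|b-d|/\max(b,d) < 10^{-12}$ so near-critical rates never hit the
catastrophically cancelling generic branch.

**Quadrature and series.** Theorem-style integrals use adaptive quadrature
at relative tolerance $10^{-3}$; the detection-SFS series and the
preexisting-spectrum sums truncate once terms stay below $10^{-12}$ of the
accumulated value for 50 consecutive terms. The pure-death closed form for
the treated spectrum is exact only as $k \to \infty$; its $O(1/k)$ error
is a few percent from $k \approx 20$ at tenfold shrinkage (the exact
mapping `sfsPreGeneral()` covers small $k$).

**Landau distribution.** No installed evaluator exists, so the standard
density is computed from its Bromwich integral along the contour through
the real saddle point $c = e^{-1-x}$, where the integrand is positive,
non-oscillatory and decays like $e^{-\pi y/2}$; the far right tail
($x > 20$) switches to the sine representation under the substitution
$u = xt$, confining the mass to the first sine arch. The computed median
1.35578 and the $x^{-2}$ tail serve as internal checks; the CDF and
quantiles come from integrating this density and root finding.

**Detection time of the clone-size quadrature.** The non-neutral clone
integral needs the time $t_d$ at which the sensitive population reaches
$N_d$; it is defined by $\tilde N(t_d) = N_d$ (the survival-conditioned
mean) and solved by root finding. Using the Gumbel first-passage *mean*
instead would overstate $e^{rt_d}$ by $e^\gamma \approx 1.78$ — the
package's convention reproduces the neutral closed form to 2%.

**Divisional offsets.** The mean-field divisional law
$P_l = \mathrm{Poisson}(2bt)$ overestimates the realized per-cell division
count by an additive constant. At fixed size the constant is exactly 2
(the exact pure-birth mean is $2(H_{N_d}-1)$), and `divisionalFixedSize()`
bakes it in. At fixed time our own simulations put the per-realization
offset near 2 as well, while the population-expectation-weighted mean
shows no offset at all; both correction constants in circulation (2 and
$\ln 4$) are exposed in `divisionalOffsetConstants`, and the package's
tests bracket the fixed-time offset between them rather than asserting
one. Single-realization scMB distributions also show a random *shift*
(early-generation stochasticity); only ensemble expectations are
predicted.

**Preexisting-burden heuristic.** `tmbPreAfter()` maps the detection
burden through $((1-\alpha)/\alpha)\ln(1/(1-\alpha))$. For $d_1 = 0$ this
is an exact identity of the $k^{-2}$ spectrum — the per-class survival sum
telescopes — and the package tests it as such; for $d_1 > 0$ it sits a few
percent *below* the exact Theorem-style sum (`tmbGeneral()`), with the gap
growing in $d_1$. The exact sum is always available when the direction of
the error matters.

**Power-law estimation.** The closed-form discrete MLE
$\hat\gamma = 1 + B_{k_{min}}(\sum_k S_k \ln(k/(k_{min}-\tfrac12)))^{-1}$
is exact for unbounded support but biased upward when a shallow spectrum
is observed over a bounded window: an exponent-1 spectrum on
$k \in [1, 50]$ fits at $\hat\gamma \approx 1.42$ regardless of sample
size. `fitPowerLaw(kmax = ...)` therefore also implements the truncated
discrete power-law MLE (numerical likelihood maximisation), which is
consistent on a finite window, and `homogeneityTest()` uses it with
$k_{max} = N$ — the population size bounds the support, and the unbounded
form would reject perfectly homogeneous spectra. Confidence intervals are
a nonparametric bootstrap over mutations (1000 multinomial resamples,
percentile interval); the verdict is CI containment of the null exponent
2 and is exploratory, not a calibrated hypothesis test.

**Degenerate inputs.** Extinct trees refuse statistics with a clear error;
$\nu = 0$ trees return empty clone records; subsampling the whole
population is the identity; a negative adjusted divisional mean (possible
only for inputs outside the valid $N_d \ge 2$ range) is clamped to zero
with a warning; `tmbPreAfter(alpha = 1)` (no survivors) errors.

## Design choices where the design was open

* $\nu$ is interpreted per daughter per division, with independent
  double-hits allowed; founder flags are set only on sensitive-to-
  resistant transitions, so clones are non-nested by construction, and
  `csdFromTree()` additionally absorbs redundant founders in hand-built
  trees.
* Clone arrival sampling models the foundings of drift-surviving
  resistant lineages as an inhomogeneous Poisson process with intensity
  $2\nu b_1 N(t)(1 - d_1/b_1)$ (eventual-survival thinning) and draws all
  variates by inverse-transform sampling. The cumulative intensity is
  $2\nu(e^{rt}-1)$, so for $\nu \ll 1$ the fraction of sample pairs in
  which the second clone outgrows the first is asymptotically
  parameter-free, $E[L/(2L+G)] \approx 0.307$ with $L, G$ independent
  standard exponentials — "roughly one third". The full tree simulator
  reproduces this fraction and the $\approx 2.4\times$ median size ratio
  of first over second clone independently.
* Peak heights $C_Y$ in the multiclonal SFS are *inputs* (extracted from
  simulated trees by `cloneSharedCounts()`); predicting them analytically
  would require a model of clone relatedness, which is out of scope.
* The homogeneity threshold defaults to mutations above 1% of the
  population — the practical resolution of bulk sequencing — via
  $k_{min} = \lceil 0.01 N \rceil$, overridable.

## Known limitations

Well-mixed populations only; no spatial sampling correlations (a real
multi-region design can miss multiclonality entirely). No sequencing noise
beyond binomial subsampling, no copy-number correction. Rates are
piecewise constant; adaptive or time-varying dosing is out of scope. The
clone-size analytics assume $\nu \ll 1$: at desk-scale parameters with
$\nu N_d = 10$ and $\nu = 0.01$ the resistant fraction reaches ~15% and
visibly suppresses the clone-founding rate, so quantitative agreement with
the $\nu \ll 1$ theory requires the smaller-$\nu$/larger-$N_d$ side of the
same $\nu N_d$ (the tests use $\nu = 0.002$, $N_d = 5000$). The largest-
clone and Landau laws additionally assume $\nu N_d \gg 1$, and the Landau
location is known to carry a small offset relative to simulations — shape,
medians and tail are the tested properties.
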