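---
title: "Methods: cavity occupancy statistics, RDF knitting, and fluctuation theories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cavity occupancy statistics, RDF knitting, and fluctuation theories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavityfluct)
```

# The problem

A spherical observation volume of radius $R$ ("cavity") placed in a liquid
holds a fluctuating number $n$ of solvent centers.  The probability $p_n$
of each occupancy state is the central object of hydrophobic hydration
theory: $-k_BT\,\ln p_0$ is the excess chemical potential of a hard-sphere
solute of radius $R$, and the shape of $p_n$ away from its mean
distinguishes Gaussian density fluctuations (atomic-scale cavities) from
the bubble-dominated "fat tail" regime (meso-scale cavities).  The package
provides three routes to $p_n$ and its differentials
$\ln K_n = \ln(p_{n+1}/p_n)$:

1. **Simulation + WHAM** — NPT Metropolis Monte Carlo of coarse-grained
   (mW) water with a harmonic occupancy umbrella, unbiased by the weighted
   histogram analysis method.
2. **Simulation + RDF knitting** — the occupancy-resolved cavity–solvent
   radial distribution functions $g_n(r)$ are discontinuous at the cavity
   boundary while the cavity correlation function $y_n(r)$ is continuous;
   enforcing continuity fixes the constants $K_n$ and hence the whole
   distribution.
3. **Analytic theory** — an interpolated Gaussian fluctuation theory
   (IGFT) and its augmentation with a bubble-nucleation branch (AFT).

The ideal gas (exactly Poisson occupancies, $y_n \equiv 1$) and the
hard-sphere fluid serve as exact and semi-exact oracles for every
estimator.

# Simulation engine

Water is the mW model: point particles interacting through the
Stillinger–Weber two-body plus three-body potential, whose angular term
penalizes deviations from the tetrahedral angle
($\cos\theta_0 = -1/3$).  Parameters live in a versioned flat file
(`inst/extdata/mw_sw.params`); energies are kJ/mol, lengths Å.  Both terms
vanish, with all derivatives, at $a\sigma = 4.31$ Å, so minimum-image
periodic boxes with edge $\ge 2a\sigma$ are exact.

Sampling is isothermal–isobaric Metropolis Monte Carlo:

* one attempted displacement per particle per pass, with the acceptance
  including the umbrella-energy change whenever the particle crosses the
  cavity boundary;
* one cavity-translation attempt per pass (the cavity is a passive probe,
  so only the umbrella term enters its acceptance).  The attempt frequency
  is a free choice — once per pass keeps the probe diffusing on the same
  time scale as the solvent — and is configurable;
* a volume move every 5 passes by default, proposed symmetrically in
  $\ln V$ and accepted with the $(N+1)\ln(V'/V) - \beta P\Delta V -
  \beta\Delta U$ rule.  The $\ln V$ proposal matters: a proposal whose
  width is proportional to the current volume violates detailed balance,
  which the exact ideal-gas equation of state
  $\langle N/V\rangle = \beta P$ exposes immediately (this oracle is in
  the test suite).

Move sizes are tuned multiplicatively toward 30% acceptance during
equilibration **only** and frozen for production; tuning during production
would make the proposal distribution history-dependent and break detailed
balance.  A particle exactly at distance $R$ counts as *outside* the
cavity (half-open convention, measure-zero but fixed for determinism).
All randomness comes from one `mt19937_64` stream per window, seeded from
the run configuration; identical configurations reproduce trajectories
bit for bit.

Paper-scale production runs of this kind use $\sim 10^6$ equilibration and
$2.5\times 10^7$ production passes per window; the package defaults are
test-scale (hundreds to thousands of passes, 80–150 particles), chosen so
that the statistical oracles in the test suite resolve errors of the size
they assert.  All lengths are configuration-driven.

The umbrella ladder follows the study conditions: centers $n_0 = 0, 2,
4, \dots$ past $\langle n\rangle$ and spring constants interpolated from
9 kJ/mol at $n_0 = 0$ down to 2.5 kJ/mol near the mean (stiffer springs
are needed as the cavity empties because the underlying free-energy
surface steepens).  `window_ladder()` automates this with overrides.

# WHAM

`wham_combine()` iterates the discrete-occupancy WHAM equations in log
space.  Convergence is declared when the largest change in any window
free-energy shift falls below $10^{-8}$ (dimensionless), with a
$10^5$-iteration cap and warm starts; the histogram coverage must be
contiguous, and gaps are hard errors naming the missing occupancy.  Error
bars on $\ln p_n$ come from a block bootstrap over each window's
production series (20 blocks, 20 replicates by default) — the underlying
histogram counts are autocorrelated, so a multinomial bootstrap would be
anti-conservative.

# RDF knitting

`accumulate_gn()` histograms cavity–solvent distances separately for each
observed occupancy and normalizes by ideal shell volumes and the bulk
density.  Two numerical choices matter:

* **Bin alignment.** The radial grid is aligned so the cavity boundary is
  exactly a bin edge.  A bin straddling $R$ mixes the interior and
  exterior density levels and visibly biases $\ln K_n$ (the effect is the
  size of the interior/exterior density step times the straddled volume
  fraction); alignment removes it entirely.  The default bin width is
  0.05 Å.
* **Conditioning and bias.** The umbrella bias depends only on $n$, so it
  is constant within an occupancy class: conditioning on $n$ removes the
  bias exactly, and frames pooled from different windows are weighted
  equally by default.  Per-frame weights are accepted for callers who want
  inverse-bias weighting across windows; both give conditionally unbiased
  $g_n$.

`knit_fit()` fits
$\alpha_2 x^2 + \alpha_1 x + \alpha_0 + \ln K_n\,\Theta(-x)$, $x = r - R$,
simultaneously to $-\ln g_{n+1}$ (interior) and $-\ln g_n$ (exterior) over
$R \pm 1$ Å by weighted least squares (weights proportional to bin counts;
an unweighted mode is provided since the weighting convention is a free
choice).  The quadratic window is configurable because the quadratic
approximation to the potential of mean force degrades beyond about 1 Å.
Bins with non-positive RDF estimates are excluded with a warning; fewer
than six usable bins, or fewer than two on either branch, is an error.
Occupancy states seen in fewer than 100 frames (configurable) are excluded
from knitting rather than interpolated.  `assemble_pn()` accumulates
$\ln K_n$ into $p_n$; `passivity_check()` verifies
$\sum_n p_n g_n(r) = 1$, the statement that the cavity, averaged over its
occupancies, does not perturb the solvent.

The direct test-particle definition of $y_n(r)$ is exercised through the
Widom machinery (`widom_mu_ex()` with a hard-sphere test particle) and
through the ideal-gas oracle where $y_n \equiv 1$; it is deliberately not
offered as a production estimator of $y_n$, since the knitting route uses
strictly more of the same data.

# Gaussian theory and its normalized variance

IGFT models $p_n$ as a continuous normalized Gaussian with mean
$\langle n\rangle = \rho\,\tfrac{4}{3}\pi R^3$ and variance
$\sigma^2 = \chi(R)\,\langle n\rangle$, giving
$\beta\mu_0 = \langle n\rangle/2\chi + \tfrac12\ln(2\pi\chi\langle
n\rangle)$.  The normalized variance interpolates two exact limits —
$\chi \to 1$ (Poisson) as $R \to 0$ and
$\chi \to \chi_\infty = \rho k_BT\kappa_T$ (compressibility) as
$R \to \infty$ — through

$$\frac{1}{\chi(R)} = 1 + \left(\frac{1}{\chi_\infty} - 1\right)
\frac{s}{1+s}, \qquad s = (R/R_0)^{4/3}, \quad R_0 = 3.1764\, d_{ww}.$$

The two shape constants were calibrated once, from the known behavior of
mW water, and then frozen: the crossover radius $R_0$ reproduces the
roughly twofold overshoot of the purely Gaussian $\beta\mu_0^{ex}$ at
$R = 6.3$ Å (a 64 $k_BT$ gap), and the exponent $4/3$ reproduces
short-simulation Widom free energies at $R = 2.5$–$2.9$ Å to better than
0.1 $k_BT$.  Remarkably, the three calibration points are collinear on a
$\log s$ vs $\log R$ plot with slope $1.32$–$1.33$, which is why the
exponent is taken as exactly $4/3$.  With this tail the macroscopic limit
is approached as $(R_0/R)^{4/3}$ — about $10^{-4}$ relative at
$R = 10^4$ Å — slower than quadratic interpolations but irrelevant at any
physical scale.  $\kappa_T$ defaults to $4.5\times10^{-5}$ atm$^{-1}$ and
only enters through $\chi_\infty$; it should be replaced by the simulated
compressibility of the solvent model when available.

# Augmented theory (bubble branch)

When the cavity is emptied below a nucleation occupancy $n^*$, the missing
$\langle n\rangle - n$ solvent molecules are modeled as a single spherical
void of volume $(\langle n\rangle - n)/\rho$ whose interfacial free energy
acts on an effective surface displaced outward by
$\Delta R = (3/4\pi\rho)^{1/3}\delta$ — a Tolman-like offset with $\delta$
the single fitted parameter.  The bubble-branch free energy is

$$\beta\mu_n = Z(\langle n\rangle - n) + \beta\gamma\,4\pi
(R_{b} + \Delta R)^2 + \beta\varepsilon,$$

with $Z = \beta P/\rho$ and $\varepsilon$ fixed by continuity with the
Gaussian branch at $n^*$.  Equating the single-molecule removal work of
the two branches gives, in $x = (\langle n\rangle - n)^{1/3}$, the quintic
$x^5/\sigma^2 = Zx^2 + c(x + \delta)$ with
$c = 2\beta\gamma/(\rho a)$, $a = (3/4\pi\rho)^{1/3}$.
`n_star_numeric()` scans 256 points of this quintic on
$(0, \langle n\rangle^{1/3}]$ for sign changes before bisecting — the
quintic can in principle have several physical roots, in which case the
one closest to $\langle n\rangle$ (the first transition met on emptying)
is returned with a warning.  A negative formal root means no bubble: the
theory is then purely Gaussian.  `n_star_series()` is the second-order
expansion about the $Z = \delta = 0$ closed form
$\langle n\rangle - n^* = (c\sigma^2)^{3/4}$ in the reduced variables
$\zeta = Z\sigma^2/x_0^3$ and $d = \delta/x_0$:

$$\langle n\rangle - n^* = x_0^3\Big[1 + \tfrac34(\zeta + d)
+ \tfrac{3}{32}(\zeta + d)(\zeta - 3d)\Big], \qquad
x_0 = (c\sigma^2)^{1/4}.$$

Its error against the numerical root shrinks by $\ge 8\times$ when $Z$ and
$\delta$ are halved, the signature of a correct second-order expansion
(asserted in the tests as $\ge 4\times$).  Value continuity at $n^*$ is
exact by construction and derivative continuity is the defining equation
of $n^*$; both are asserted numerically.  Because $n^*$ sits several
$\sigma$ below $\langle n\rangle$, the piecewise distribution inherits the
Gaussian normalization (checked to within 5% at the study-scale radii
4.3–6.3 Å).  Surface tension defaults to 66.3 dyn/cm — a 66.0 dyn/cm
reference at 300 K transferred to 298.15 K along the experimental
(IAPWS-correlation) slope of water's surface tension — and is converted
once to kJ/(mol Å$^2$).

`fit_delta()` performs the one-parameter weighted least-squares fit of the
AFT $\beta\mu_0(R)$ to measured empty-cavity free energies
(Levenberg–Marquardt via `minpack.lm`), probing a $\delta$ grid first so a
flat objective (all cavities Gaussian, $\delta$ unidentifiable) is an
error rather than a silent arbitrary answer.

# Structural diagnostics

`rg_from_gn()` evaluates the radius of gyration of the interior solvent
density,
$R_g^2 = \int_0^R g_n r^4 dr / \int_0^R g_n r^2 dr$, whose uniform-density
value is $\sqrt{3/5}\,R$.  Its minimum versus $n$, and the peak of
$\ln K_n$ shifted by $+1/2$ (the differential probes the derivative at
$n + 1/2$), are the two simulation estimators of $n^*$.  Peak/minimum
detection is a 3-point discrete test with ties broken toward larger $n$
(closer to the mean, where the transition is defined) and an optional
running-mean smoother, off by default, for noisy series.

# Synthetic data and what the tests do (and do not) show

The generators produce: i.i.d. uniform ideal-gas frames with
Poisson-distributed particle counts (occupancy exactly Poisson by
construction), Metropolis-equilibrated hard-sphere configurations, and
closed-form occupancy distributions (Gaussian / Poisson / AFT) with
multinomial umbrella-biased sampling.  These fixtures emulate the
*statistics* the estimators consume — conditional RDF levels, biased
histograms, boundary discontinuities — but not the correlated, structured
density profiles of real water (contact peaks, interior adsorption
layers).  Tests passing on them therefore validate estimator correctness
and the continuity/normalization identities, not the physics of mW water;
the mW physics enters through separate checks (ambient density
$0.997$ g/cm$^3$ emerging from NPT runs, and small-cavity
$\beta\mu_0^{ex}$ agreeing with the Gaussian theory within about
1 $k_BT$, mirroring the atomic-scale regime).  The suite runs at desk
scale: $10^4$ fixture frames, $80$–$150$-particle windows of a few
thousand passes, one short 128-water mW run — sizes at which every
asserted tolerance is several times the corresponding standard error.

# Known limitations

* The $\chi(R)$ interpolation is a calibrated closed form, not the exact
  compressibility-route integral; its shape between the anchor radii is an
  assumption of this package.
* No capillary-wave corrections at the bubble interface: below $n^*$ the
  theory captures $\ln K_n$ only semi-quantitatively (simulations show a
  shallow minimum there that the smooth bubble branch cannot produce).
* Spherical cavities only; no Gaussian-curvature terms, no attractive
  solute–solvent interactions, no molecular dynamics, no grand-canonical
  moves.
* Bubble-volume accessibility corrections are deliberately excluded: they
  force $p_0 = 0$ and hence a divergent empty-cavity free energy, and the
  bubble is expected to pin to the cavity center as $n \to 0$.

# A worked call

```{r example, eval = FALSE}
ti <- theory_inputs()                 # mW water, 25 C, 1 atm
mean_occupancy(6.3, ti)               # 34.91 waters
chi_igft(6.3, ti)                     # 0.138
n_star_numeric(6.3, ti)               # 21.3: bubble below ~21 waters
mu0_igft(6.3, ti)                     # 128.0 kT (Gaussian, overshoots)
mu0_aft(6.3, ti)                      # 69.4 kT (bubble-corrected)
```
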