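---
title: "Competitive interactions in generative whole-brain models: methods and design"
author: "gecnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive interactions in generative whole-brain models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecnet)
```

## The model

Every brain region n is a Stuart–Landau oscillator — the normal form of a
supercritical Hopf bifurcation — written in Cartesian coordinates and driven
by additive Gaussian noise:

$$\dot x_n = (a_n - x_n^2 - y_n^2)\,x_n - \omega_n y_n +
  \sum_p G_{np}(x_p - x_n) + \beta\,\eta_n(t),$$

with the mirrored equation ($+\omega_n x_n$) for $y_n$. For $a_n < 0$ the
node relaxes to a noisy fixed point with damped oscillations at
$f_n = \omega_n / 2\pi$; for $a_n > 0$ it settles on a limit cycle of radius
$\sqrt{a_n}$. The whole-brain regime used throughout is subthreshold
($a_n = -0.02$) with weak noise ($\beta = 0.01$), which produces the
fluctuating, narrowband signals characteristic of infra-slow BOLD. Coupling
is diffusive: region p pushes region n toward its own state with weight
$G_{np}$. A *negative* $G_{np}$ — a competitive interaction — pushes region
n *away* from region p's state; no separate inhibitory mechanism is
introduced.

The x component, sampled every TR after a burn-in, is the BOLD proxy. No
haemodynamic convolution is applied, following the Hopf whole-brain
modelling literature this package builds on.

### Numerical integration

`simulateHopf` uses Euler–Maruyama with independent Gaussian increments per
node and component, scaled by $\sqrt{dt}$. Initial conditions are uniform on
$[-0.1, 0.1]^2$, seeded. The default step is the value nearest 0.1 s that
divides the TR exactly (≈0.103 s for TR = 0.72 s), so every output sample
falls on a grid point. Euler integration biases the limit-cycle radius by
$O(\omega^2 dt)$; at the default step and infra-slow frequencies the bias is
a few percent on the supercritical orbit and negligible for the subthreshold
regime used in fitting. The closed-form radius check in the test suite
therefore runs at dt = 0.01 s.

### The linearized fast path

In the subthreshold regime the cubic terms are negligible and the network is
a 2N-dimensional Ornstein–Uhlenbeck process with block Jacobian
$J = \begin{pmatrix} A & -\Omega \\ \Omega & A \end{pmatrix}$,
$A = \mathrm{diag}(a) + G - \mathrm{diag}(G\mathbf 1)$. `linearizedCovariance`
solves the continuous Lyapunov equation $J\Sigma + \Sigma J^\top + \beta^2 I
= 0$ via the eigendecomposition of $J$ and propagates the lag-$\tau$
covariance with $e^{J\tau}\Sigma$. For a stationary Gaussian process the
time-reversed lagged correlation is the transpose of the forward one, which
gives the full set of FC statistics in closed form. This deterministic
engine is validated against the stochastic simulation (maximum FC deviation
< 0.05 at 50,000 samples) and against a brute-force Kronecker-product
Lyapunov solve.

## Fitting generative effective connectivity

`fitGEC` starts from the anatomical support (the nonnegative prior) and
iterates simulate → measure → update with the heuristic gradient rule

$$GEC_{np} \mathrel{+}= \varepsilon\,(FC^{emp}_{np} - FC^{sim}_{np})
 - \varepsilon'\big([FC^{emp}_{f,np} - FC^{emp}_{r,np}]
 - [FC^{sim}_{f,np} - FC^{sim}_{r,np}]\big)$$

on the masked entries only (the known anatomical connections), with
$\varepsilon = 2\times10^{-4}$ and $\varepsilon' = 4\times10^{-5}$. The
forward/reversal term at lag 1 TR injects temporal-asymmetry information, so
a symmetric prior does not force a symmetric GEC. Two variants differ in one
line: the cooperative-only fit clamps entries at zero from below (clamped
edges may later re-grow), the competitive fit lets them go negative. Both
start from identical masks and weights, so differences are attributable to
the sign constraint alone.

Design choices a maintainer should know:

* **Best-iterate return.** The reported GEC is the iterate with the highest
  empirical-vs-simulated FC correlation, not the last one, so stochastic
  fitting noise cannot degrade the result.
* **Convergence.** By default the loop stops when the fit correlation gains
  less than 1e-3 over 10 consecutive iterations, or after `maxIter`, or
  after `patience` consecutive decreases (divergence guard, best-so-far
  returned). With the deterministic linear engine the trajectory improves
  very slowly but steadily near the optimum, so the recovery experiments
  disable the tolerance (`tolerance = 0`) and rely on `maxIter` with a
  decrease guard instead.
* **Per-subject vs group fits.** The pipeline fits each subject's own FC
  statistics (fingerprinting requires it); the ground-truth recovery
  experiment averages FC statistics over subjects (`groupStatistics`) to
  reduce estimator variance.
* **Engines.** The stochastic engine (500 TR per iteration, fresh seeded
  noise stream each iteration) follows the generative protocol literally;
  the linear engine is exact in the subthreshold regime, deterministic and
  two orders of magnitude faster, and is the default for desk-scale studies.

## Dynamical signatures

* **Metastability** (`kuramotoOrder`): the population SD over time of the
  Kuramoto order parameter $KOP_t = |\sum_k e^{i\phi_k(t)}|/N$, with phases
  from the Hilbert analytic signal of band-passed series (`extractPhases`).
  The first and last 5% of samples are trimmed before the summary statistics
  to suppress Hilbert edge effects. Maximum synchrony is reported alongside.
* **Intrinsic-driven ignition** (`ignition`): events are upward crossings of
  z = 1; each driver event opens a 4-TR window, its breadth is the number of
  regions with an event inside the window (the co-occurrence matrix over the
  active set is a clique, so its largest component is the set size). The
  hierarchy is the population SD across regions of the mean event breadth;
  regions with no events are excluded rather than scored zero, and crossings
  inside an ongoing window still open their own window (no refractoriness).
* **Temporal irreversibility** (`irreversibility`): pairwise forward and
  time-reversed lagged correlations at 1 TR, mapped through the Gaussian
  mutual information $FS = -\tfrac12\log(1 - c^2)$; the squared
  forward–reversed difference is the pairwise irreversibility and the
  population SD of its off-diagonal entries the hierarchy. We use the
  squared-correlation (mutual information) form because the raw difference
  of correlations can make the log argument exceed 1. Note that on finite
  samples the reversed lagged correlation matrix is exactly the transpose of
  the forward one, so irreversibility manifests as forward-matrix asymmetry
  and any 2-region "hierarchy" is degenerately zero — pair-level analyses
  should use the pairwise statistic. Both the element-SD headline and the
  SD across regional send–receive means are returned.

## Synergy from integrated information decomposition

`phiidMMI` decomposes the time-delayed mutual information
$I(X_{t-\tau}, Y_{t-\tau};\, X_t, Y_t)$ of a region pair into the 16 atoms
of integrated information decomposition under the
minimum-mutual-information (MMI) redundancy function, appropriate for
Gaussian variables. The cumulative double-redundancy of an antichain pair
$\alpha \to \beta$ is the minimum Gaussian MI between any past subset in
$\alpha$ and any future subset in $\beta$; atoms follow by Möbius inversion
over the product of the two antichain lattices
$\{1\}\{2\} \prec \{1\},\{2\} \prec \{12\}$. Correctness is enforced by two
exact identities tested on random covariances: atoms sum to the TDMI
(1e-10), and marginal sums over future antichains reproduce the
single-target MMI decomposition of each target.

The headline statistic is the temporally persistent synergy atom
$\{12\}\to\{12\}$, averaged over all unordered region pairs
(`synergyProfile`), in nats, at $\tau$ = 1 TR (matching the
irreversibility lag). One property of MMI worth knowing: for two
*independent* processes with self-MIs $m_x, m_y$ the persistent synergy
atom equals $2\min(m_x, m_y)$ rather than zero — the known MMI degeneracy
for equal-information sources (its single-target analogue assigns synergy
$\min(m_x, m_y)$ to independent sources). Cross-unique atoms and the
double redundancy do vanish under independence. Comparative uses of synergy
(between model variants, as here) are unaffected by this common offset.

## Evaluation

* `fcFit`: Pearson correlation over strictly-upper-triangle FC entries.
* `fcSSIM`: single-scale global-statistics SSIM with stabilizers
  $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, L the joint value range; sensitive
  to mean and variance differences that the correlation fit ignores.
* `identifiability`: the S×S similarity matrix between simulated and
  empirical subject FCs; $I_{diff} = I_{self} - I_{others}$ measures
  subject-specificity of the fitted models.
* `cognitiveMatching`: per volume, the largest positive spatial correlation
  against a bank of activation maps, floored at 0 when no map correlates
  positively (volumes with no positive match are counted and flagged);
  scan score = mean over volumes.
* `pairedComparison`: paired t statistic with a two-sided sign-flip
  resampling p-value (10,000 draws by default, add-one corrected) and
  Hedges' g with the small-sample correction. Type-I calibration is tested
  against uniformity under the null.

## Reservoir memory capacity

`memoryCapacity` implements the classical protocol: uniform U(−1,1) input
into a random half of the "visual" input pool, states
$x(t+1) = \tanh(W_{in}u(t+1) + Wx(t))$ with input gain $10^{-4}$, one ridge
readout per lag (penalty 0.5, sklearn-style unpenalized intercept) trained
on the "somatomotor" output-node states, scored as $|\rho(y, \hat y)|$ on an
independent test stream, summed over lags 1–20. The weight matrix — signed
entries used as-is — is rescaled to each spectral radius in the grid
0.1–1.6; MC is averaged over 10 input-node draws per radius and the best
radius retained (ties to the smallest). Defaults follow the protocol
(4050 timepoints, 70:30 split, 50-sample washout); the study pipeline uses a
reduced grid (6 radii × 3 repeats, 1350 timepoints) sized for interactive
runs.

## The synthetic study conditions

`makeGroundTruth` encodes the structural premises the signed effective
connectomes show: balanced spatial modules of strong positive edges (85% of
positive edges within-module, weights U(0.5, 1); between-module positives at
0.3×), plus negative edges placed on the top 40% most distant cross-module
pairs with magnitudes at 0.5× the positive scale — negatives are weaker,
longer-range and less clustered by construction. Defaults: 30 regions, 3
modules, 30% negative edges (inside the empirically reported 25–40%
envelope), 30% density, unit-cube geometry at 100 mm scale.

`makeCohort` draws per-subject couplings by sign-preserving multiplicative
lognormal jitter (SD 0.1), simulates BOLD at species-like TRs (human 0.72 s,
macaque 2.6 s, mouse 1.0 s with a 0.01–0.1 Hz band) and band-pass filters
with a zero-phase second-order Butterworth (0.008–0.09 Hz for the primate
presets). Intrinsic frequencies are drawn once per cohort from U(0.04,
0.07) Hz, the empirical infra-slow range. Because negative diffusive edges
destabilize the origin, the ground truth is rescaled so the linearized
spectral abscissa stays at 25% of the node decay rate |a| (capped at
max-|weight| 0.2): the simulation remains subthreshold and the linear
engine usable. Region roles are module memberships (module 1 = "visual"
input pool, module 2 = "somatomotor" readout); the map bank holds module
indicators plus spatially smoothed random patterns.

What the generator does *not* emulate: haemodynamic convolution and
measurement noise floors, spatial autocorrelation of real parcellations,
global signal structure, motion artefacts, and any species' actual FC
distribution. Passing tests therefore demonstrate internal consistency of
the pipeline and recoverability under the stated premises — not performance
on empirical fMRI.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; the linear engine plus
fixed seeds makes entire study reports byte-identical across runs. The
bundled experiments use: sign-recovery — 30 regions, 3 subjects × 1800
volumes with group-averaged FC statistics (chosen so the FC estimator
standard error ≈ 0.01 is well below the weight contrasts being recovered),
linear engine, up to 2000 iterations; variant comparison — 10 subjects ×
900 volumes, per-subject fits, up to 400 iterations; negative-control — 5
replicate all-positive cohorts at 300 volumes. These sizes are stated here
as the package's reference conditions so results are comparable across
machines.

## Observed behaviour of the synthetic comparison

On signed synthetic cohorts the competitive fit achieves a reliably higher
FC fit correlation than the cooperative-only fit (paired sign-flip test),
recovers the planted negative edges (fraction ≈ the planted 30%), and its
simulated dynamics sit closer to the empirical series on every dynamical
signature, with lower metastability and peak synchrony and higher
irreversibility hierarchy and differential identifiability than the
cooperative-only variant. Two directions are regime-dependent rather than
universal: in this subthreshold synthetic regime the competitive variant
shows slightly *lower* mean persistent synergy and ignition hierarchy than
the cooperative-only one (both tracking the lower empirical values), because
weak negative diffusive couplings damp collective fluctuations. These are
properties the test suite measures, not assumptions.

## Known limitations

* The GEC update is a heuristic gradient; it has no convergence guarantee
  and its fixed point depends on the engine's statistics matching the
  empirical pipeline (band-pass mismatch costs fit correlation).
* The linear engine requires a stable linearization; fits that drift into
  instability stop early with the best iterate (flagged, not silent).
* MMI-ΦID atoms can be negative and carry the equal-information degeneracy
  noted above; interpret absolute synergy levels with care.
* Newman's leading-eigenvector modularity (via igraph) does not refine
  partitions with Kernighan–Lin moves; on well-separated synthetic modules
  this makes no practical difference, and the planted-partition test pins
  the behaviour.
* Ignition on short scans is noisy: with few events per region the
  mean-breadth SD is dominated by event-count variance.
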