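---
title: "Models and methods in mdmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mdmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmri)
```

## The forward model

Multidimensional diffusion-relaxation MRI probes each voxel with a set of
acquisitions $\beta_i = (\tau_I, \tau_E, b)$ that jointly vary inversion
time, echo time and diffusion weighting. The voxel's content is modelled
as a joint distribution $f(T_1, T_2, D)$ of relaxation times and
diffusivities — a mixture of water pools — and the signal is a Fredholm
integral of the first kind over that distribution,

$$ s(\beta) = \int_{\Omega_\alpha} f(\alpha)\, k(\alpha; \beta)\, d\alpha, $$

discretized on a grid as $s = K_0 f$. The kernel is the standard product
of inversion recovery, spin-echo decay and isotropic Gaussian diffusion,

$$ k(\alpha; \beta) = \left(1 - 2 e^{-\tau_I / T_1}\right)
   e^{-\tau_E / T_2}\, e^{-b D}. $$

No single agreed-upon closed form exists in the application literature —
protocols differ in their weighting mechanisms — so this choice is a
package design decision: it is the simplest kernel that exercises all
three contrast mechanisms and has exact, testable landmarks (unit entries
when all decays are disabled, an inversion-recovery null at
$\tau_I = T_1 \ln 2$, a pure $e^{-bD}$ diffusion limb).

**Units.** Internally $T_1$, $T_2$, $\tau_I$, $\tau_E$ are in seconds, $D$
in $\mu m^2/\mathrm{ms}$ and $b$ in $\mathrm{ms}/\mu m^2$, so $bD$ is
dimensionless and order one across tissue-plausible values. A $bD$
product above $10^3$ triggers a unit-sanity warning, since it almost
always means b was given in $\mathrm{s/mm^2}$.

**Sign convention.** Magnitude acquisition is the default
(`sign_mode = "magnitude"`), taking the absolute value of the
inversion-recovery factor; signed mode is available because some
protocols retain phase. All shipped defaults use magnitude mode, which
also keeps every kernel entry (and hence every noiseless signal)
non-negative.

**Noise.** `simulate_signal()` supports Gaussian and Rician noise. SNR is
defined as the maximum noiseless signal divided by the per-channel noise
standard deviation — an explicit convention, since "SNR" is otherwise
ambiguous for multi-contrast data. Rician noise is the magnitude of the
complex signal with two independent Gaussian quadratures, the right model
for magnitude MRI; it is biased upward at low SNR, which is part of what
the inversion has to survive.

**Default grid and scheme.** The default spectral grid is $20^3$
log-spaced nodes over $T_1 \in [0.05, 5]$ s, $T_2 \in [5, 500]$ ms,
$D \in [0.01, 3]\ \mu m^2/\mathrm{ms}$, spanning fixed-tissue values. The
default scheme is a factorial $5 \tau_I \times 5 \tau_E \times 4 b$
design ($d = 100$), log-spaced across the sensitive ranges; it is
overdetermined enough for the package's recovery tests.

## Spectral inversion

The inverse problem is ill-posed: $\tilde f = \arg\min_{f \ge 0}
\|s - K_0 f\|_2^2 + \lambda \|f\|_2^2$, solved by Lawson-Hanson NNLS on
the Tikhonov-augmented system $[K_0; \sqrt\lambda I]$. The Euclidean
residual norm is fixed ($p = 2$): it is the only choice with a standard
non-negative solver. Non-convergence raises an error with diagnostics;
downstream code (the phantom pipeline) records failed voxels and never
imputes them.

Two numerical facts shape the defaults:

* **NNLS is itself a strong regularizer.** The non-negativity constraint
  limits the active support to at most $d$ nodes, so for sparse
  (compartmental) ground truth, $\lambda = 0$ already recovers on-grid
  deltas exactly in the noiseless case, and a small $\lambda$ mainly
  stabilizes against noise. The benchmark pipeline uses a single fixed
  $\lambda = 0.01$ for every voxel so the spectral representation is
  computed identically across the dataset.

* **The L-curve corner tends to over-smooth.** `choose_lambda()`
  implements corner selection by maximum Menger curvature of the
  (log residual, log solution norm) curve, with ties broken toward the
  larger $\lambda$, a consistency shortcut (if the unregularized fit
  already explains the data, the smallest candidate is returned), and a
  degenerate-curve warning when no non-negative combination can reduce
  the residual at all. In our experiments the discrete corner often sits
  one to two decades above the recovery-RMSE optimum — a known behaviour
  of L-curve selection combined with NNLS — so the function is offered as
  a diagnostic (it returns the full candidate table for audit), not wired
  into the benchmark.

`marginalize()` collapses the 3D spectrum onto the three conventional 2D
correlation maps (T1-T2, T1-D, T2-D) by summing over the dropped axis;
mass conservation is exact up to float addition and is tested to 1e-12.
Flattening to classifier features follows one documented index bijection
(T1 slowest, D fastest; 2D maps row-major), with inverse mappings.

## The nearest local convex set classifier

NLCS labels a query $x^*$ by the class whose local geometry comes
closest: for each class, take the $k$ nearest same-class training points,
form their convex hull, and measure

$$ h(x^*) = \arg\min_i\ \min \left\| x^* -
   \mathrm{conv}\!\left(Z_k^i(x^*)\right) \right\|_2 . $$

There is no training phase — the "model" is the partitioned data — and
because the hulls are local, the rule follows curved class manifolds that
defeat linear boundaries (the concentric-rings test in the suite: NLCS
$\ge$ 98% where LDA $\le$ 60%).

The inner minimization is a simplex-constrained least-squares problem (a
convex QP). It is solved in two stages: a weighted-equality NNLS trick
(augmenting the design with a heavily weighted all-ones row) identifies
the active vertex set, then the equality-constrained KKT system on that
support is solved exactly, with active-set corrections (vertex drops for
primal feasibility, additions for dual feasibility) until the KKT
conditions hold to `tol = 1e-8`. The computation is centred at the query
and normalized by the point-cloud radius, so distances are exactly
translation- and scale-equivariant and all tolerances are relative;
witness norms below 1e-9 (relative) are snapped to an exact zero so that
interior points are detected stably at any scale.

Deterministic tie policies, since the method is otherwise silent about
them: neighbour distance ties keep the lower training index (`order()` is
stable), and class-distance ties go to the smaller class index in sorted
label order. With $k = 1$ every hull is a single point and NLCS reduces
exactly to 1-nearest-neighbour — a reduction the suite asserts on random
datasets. Only $p = 2$ is implemented; other norms would make the inner
problem non-quadratic and are rejected with a clear error. The default
neighbourhood $k = 5$ is a declared package default, reported in all
benchmark output.

## Information-theoretic error bounds

For a discrete label $X$ and observation $Y$ the package computes plug-in
entropies and mutual information (base 2 throughout; one `base` argument
keeps the entropy and the $\log|\chi|$ in the bounds consistent), and
three classical results:

* **Fano lower bound** $P_e \ge (H(X|Y) - 1)/\log|\chi|$, implemented in
  exactly this weakened form. It can be negative (vacuous); the raw value
  is reported, with a clamped-at-zero companion field for display.
* **Hellman-Raviv upper bound** $P_e \le \tfrac12 H(X|Y)$ for the
  maximum-likelihood predictor.
* **Data processing inequality** $I(X;Y) \ge I(X;Y')$ for any chain
  $X \to Y \to Y'$, audited exactly from a prior and two stochastic
  channel matrices.

These operate on discrete (or discretized) variables only; continuous MI
estimators are out of scope. On exact joints the suite verifies the
sandwich `fano_lower <= bayes_error <= hr_upper` on random tables and the
BSC(0.1) closed forms ($I \approx 0.5310$ bits, $P_e = 0.1$, upper
$\approx 0.2345$).

The relevance to the pipeline: the estimated spectrum is a deterministic
function of the measured signal, so label, signal and spectrum form a
Markov chain — post-processing cannot add information about the label.
Whether a *practical* classifier does better on one representation or the
other is an empirical question, which is what the benchmark measures.

## The synthetic phantom

The phantom emulates the statistical structure of a two-class
(lesion-like vs control) voxel study. Each class is a mixture of three
water pools shared across classes — myelin-like
($T_1 = 0.25$ s, $T_2 = 15$ ms, $D = 0.25$), intra/extra-cellular
($0.9$ s, $70$ ms, $0.8$) and free-water-like ($3.0$ s, $300$ ms, $2.0$)
— with control fractions $(0.25, 0.55, 0.20)$. The lesion class moves
`effect_size` (default 0.15) of volume fraction from the free-water pool
into the cellular pool, a crude but controllable stand-in for the tissue
densification that reactive gliosis produces. Per voxel, fractions are
jittered logit-normally (sd 0.3) and renormalized; compartment locations
are snapped to the nearest grid node, so ground truth lives exactly on
the grid and discretization error does not confound recovery tests (an
off-grid stress mode would be a separate experiment and is not part of
the shipped checks).

`realize_dataset()` composes the chain per voxel: truth spectrum
$\to$ kernel projection $\to$ noise (the signal representation $Y$)
$\to$ NNLS inversion $\to$ 2D marginals (the spectral representations
$Y'$). The spectral features are computed from the noisy signal only, so
the Markov premise holds *by construction* in the phantom. Seeding is
hierarchical — one master seed, per-voxel streams derived by offset — so
datasets are reproducible voxel-by-voxel. Voxels are optionally tagged
with 14 pseudo-subject ids (7 per class) usable for stratified splitting;
the tags are metadata and introduce no actual between-subject
correlation.

What the phantom does **not** emulate: spatial voxel correlation, partial
volume across a lesion boundary, off-grid and continuously distributed
compartments, field inhomogeneity, and any real histology-to-MRI
registration error. Passing benchmarks on the phantom therefore show that
the pipeline and protocol behave as designed — not that the same margins
would be observed on ex vivo tissue.

The default benchmark phantom uses a $10^3$ grid and 50 voxels per class.
These sizes were chosen once, as desk-scale settings where a full
4 method $\times$ 4 representation $\times$ 30 bootstrap run completes in
minutes on one core; the suite's smaller unit fixtures ($3^3$–$8^3$
grids, 8–20 voxels per class) are stated in the tests themselves.

## The benchmark protocol

`run_benchmark()` mirrors a paired comparison protocol: 30 bootstrap
iterations, each a seeded 50/50 train/test split of the voxel pool, with
the *same* split indices reused for every classifier and every
representation, so all cells of the kappa table are paired. "Bootstrapped
samples" could also be read as resampling with replacement; the package
defaults to repeated re-splits (consistent with splitting into 50/50
instances per sample) and offers `replace = TRUE` behind a flag. A split
that leaves a class absent from training is redrawn (up to 100 times,
with the retry count recorded). Scoring is Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, computed from scratch with its observed
and chance agreement returned alongside; the degenerate $p_e = 1$ case
(both sequences constant and equal) is defined as $\kappa = 1$.

The comparison methods are wrapped behind one fit/predict contract:

* **2-NN** — in-package exhaustive k-nearest-neighbour with fully
  deterministic tie handling (vote ties go to the nearest tied class,
  distance ties to the lower index). The standard library routine breaks
  ties at random, which would break run-to-run reproducibility.
* **LDA** — `MASS::lda`; if it fails on a singular within-class
  covariance (e.g. zero within-class variance in the separable smoke
  phantom), a shrinkage fallback blends the pooled covariance with a
  scaled identity ($\gamma = 0.1$) and classifies by linear discriminant
  score, flagged in the fitted object.
* **MLP** — `nnet` with one hidden layer of 8 units, weight decay 1e-4,
  at most 500 BFGS iterations and relative convergence tolerance 1e-5,
  seeded from the bootstrap index so repeated runs are bit-identical.
  The hidden layer is deliberately small: the phantom's two classes are
  close to linearly separable in both representations, wider layers
  change no qualitative outcome, and a full-batch BFGS fit at input
  dimension 100 scales poorly with width. No early stopping is used.
* **NLCS** — the package classifier with $k = 5$, $p = 2$.

The report records the full bootstrap kappa distribution per cell, cell
means and standard deviations, fit-failure counts (failures are counted,
never silently dropped), the reused split indices for pairing audits, and
row/column maxima annotations in its printout.

## Known limitations

* The kernel assumes isotropic Gaussian diffusion and mono-exponential
  relaxation per pool; anisotropy and exchange are out of scope.
* `choose_lambda()`'s corner detection inherits the L-curve's tendency to
  over-smooth NNLS problems (see above); treat it as a diagnostic.
* NLCS is brute-force ($O(n)$ distances per query per class) — adequate
  for the dataset sizes here, no approximate-neighbour indexing.
* The information bounds apply to discrete labels; applying them to
  continuous features requires explicit discretization, which the package
  leaves to the user (quantile binning is the suggested route).
* Benchmark conclusions are within-dataset: pooled voxels with optional
  pseudo-subject stratification. Cross-subject generalization is
  explicitly not modelled.
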