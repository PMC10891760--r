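---
title: "Methods: partitioned NESTA reconstruction of 5D cardiac CINE data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned NESTA reconstruction of 5D cardiac CINE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cine5d)
```

## The reconstruction problem

A free-breathing cardiac acquisition resolved into $N_c$ cardiac and $N_r$
respiratory phases yields one complex 3D volume $m_{i,j}$ per phase pair,
a 5D image series $m$ of $N_c \times N_r$ frames.  Each frame is sampled
on an undersampled Cartesian k-space grid through $n_\text{coils}$
receiver coils.  The package reconstructs $m$ from the measured data $y$
by solving the smoothed compressed-sensing problem

$$
\hat m \;=\; \arg\min_m \; \tfrac12 \lVert E m - y \rVert_2^2
  \;+\; \lambda\, f_\mu(\Phi m),
$$

where:

* $E$ is the multicoil encoding operator: per frame and coil,
  $E\,m_{i,j} = M_{i,j} F (S_c \odot m_{i,j})$ with the orthonormal 3D DFT
  $F$, coil sensitivities $S_c$ (normalized so
  $\sum_c \lvert S_c\rvert^2 \le 1$, hence $\lVert E\rVert \le 1$) and the
  per-frame binary sampling mask $M_{i,j}$;
* $\Phi$ is the temporal total-variation transform: *non-circular*
  forward differences of the frame sequence along the cardiac and
  respiratory phase axes, with weights $w_c, w_r$ (default $1, 1$).  Its
  operator norm satisfies $\lVert\Phi\rVert^2 \le 4w_c^2 + 4w_r^2$;
* $f_\mu$ is the Huber smoothing of the $\ell_1$ norm,
  $h_\mu(z) = \lvert z\rvert^2/(2\mu)$ for $\lvert z\rvert\le\mu$ and
  $\lvert z\rvert - \mu/2$ otherwise, summed over entries.  Its gradient
  $z/\max(\lvert z\rvert, \mu)$ has magnitude at most 1, making the
  objective gradient Lipschitz with constant
  $L = \lVert E\rVert^2 + \lambda \lVert\Phi\rVert^2/\mu$.

The objective gradient is
$\nabla f(m) = E^H(Em - y) + \lambda\,\Phi^H f_\mu'(\Phi m)$.  The
regularization part $\Lambda = \Phi^H f_\mu'(\Phi m)$ at frame $(i,j)$
depends only on the immediately adjacent phases $(i, j\pm1)$ and
$(i\pm1, j)$.  This locality is what makes the multi-device decomposition
below exact.

## The staged NESTA solver

`run_reconstruction()` minimizes the smoothed objective with a
Nesterov-accelerated first-order method (NESTA) under $\mu$-continuation:

1. Initialize with the zero-filled adjoint $m^0 = E^H y$.
2. Set $\mu_0 = 0.9\,\max\lvert\Phi m^0\rvert_\infty$ (the dynamic range
   of the temporal differences of the data at hand; fallback $10^{-3}$ for
   temporally constant input) and, unless supplied, the data-scaled
   default $\lambda = 0.01\,\max\lvert E^H y\rvert$.
3. Run `n_stages` (default 4) stages with geometrically decreasing
   $\mu_s$, interpolating from $\mu_0$ down to $\mu_\text{final}$
   (default $\mu_0 \cdot 10^{-3}$, i.e. decade steps over four stages).
   Each stage warm-starts from the previous stage's solution.

Within a stage at fixed $\mu$, iteration $k$ (0-based) computes the
fused objective/gradient (one encoding application shared between both),
then the three-sequence Nesterov update with $L_s = 1 + \lambda(4w_c^2 +
4w_r^2)/\mu_s$:

$$
y_k = x_k - \nabla f(x_k)/L, \qquad
z_k = x_0 - \tfrac1L\sum_{i\le k}\tfrac{i+1}{2}\nabla f(x_i), \qquad
x_{k+1} = \tfrac{2}{k+3} z_k + \bigl(1 - \tfrac{2}{k+3}\bigr) y_k .
$$

The stage solution is the final gradient-step iterate $y_k$.

**Stopping.**  Each stage records $f(x_k)$ and halts when the progress
quotient

$$
q_p = \frac{\bar f - f_k}{\bar f},
\qquad \bar f = \text{mean of the last } \tau \text{ values},
$$

drops to `tol` ($10^{-5}$ by default) or below — evaluated only once at
least $\tau = 7$ iterations have run — or at the cap of 100 iterations
per stage.  So every stage performs between 7 and 100 iterations.
Setting `local_stopping = FALSE` disables the quotient test, forcing
exactly `max_iter_per_stage` iterations; this is used for equivalence
audits where all devices must stay synchronized.

## Partitioning across devices

`partition_cardiac(Nc, Nr, capacities, split)` splits the cardiac
dimension into consecutive disjoint ranges, one per device:

* equal capacities: every device receives $\lfloor N_c/d\rfloor$ phases
  and the remainder goes one phase each to the lowest-indexed devices;
* unequal capacities: shares proportional to capacity, rounded by largest
  remainder, with every device keeping at least one phase;
* an explicit `split` (phase counts summing to $N_c$) overrides both.

Because $\Lambda$ couples only adjacent cardiac phases, a device
evaluating its local gradient needs exactly one extra cardiac phase — all
$N_r$ respiratory frames of it — beyond each interior end of its range:
the *ghost* (dependency) frames, held read-only.  A device therefore
keeps `(assigned phases + ghosts) * Nr` resident 3D frames
(`resident_frame_count()`), and each interior boundary induces two
directed dependencies (`dependency_pairs()`), $2(d-1)$ in total.  With
$N_c = 20$, $N_r = 4$: two devices hold 44 frames each; three devices
hold 32/36/28; four hold 24/28/28/24.

## Orchestration and channel semantics

`run_partitioned()` runs one NESTA solver per device.  Devices are
simulated as cooperating workers inside one R process; the
synchronization protocol is reproduced and audited exactly, which is a
deliberate design choice: it makes every scheduling order deterministic
and testable, while real multi-GPU execution would only change *where*
the per-device computations run, not *what* they compute.

Each directed dependency owns a single-slot channel holding the most
recently published payload (one boundary cardiac phase, all $N_r$
respiratory frames) with a `(stage, iteration)` stamp and a `final` flag.
Publishing replaces the slot atomically (last writer wins); retrieval
never blocks — a consumer reuses the latest payload if nothing new has
arrived.  The protocol per reconstruction:

* **Shared constants.**  Every device computes
  $\max\lvert\Phi m^0\rvert_\infty$ and $\max\lvert E^H y\rvert$ on its
  own frames plus ghosts (obtained through an initial exchange), and the
  values are reduced by maximum.  All stage schedules are therefore
  identical to the global solver's.
* **Stage loop.**  At stage entry each device publishes its
  stage-initial boundary frames, and a barrier separates stages so no
  payload ever crosses a stage boundary.
* **Iteration loop** (`lockstep` mode): all devices publish their current
  boundary frames, then all retrieve their ghosts, then all compute one
  NESTA step.  Every retrieved stamp equals the consumer's own
  `(stage, iteration)`, and the whole run is bitwise deterministic.
* **Concurrent mode**: per round, devices act once each in a seeded
  random order, publishing, retrieving and stepping in turn.
  Early-scheduled devices see neighbours' previous-iteration payloads — a
  deterministic simulation of asynchronous workers with stale-reuse
  semantics.
* **Local stopping / final update.**  Each device applies the progress
  quotient to *its own* local objective (computed with the data it works
  with).  A device that halts publishes its final boundary frames once
  more, marked `final`, and goes idle; consumers keep using that payload.

All events (publish, retrieve with payload stamp, converged,
final publish, barrier) are recorded in a trace table
(`write_trace_jsonl()`), which the test suite audits.  After the last
stage the assigned ranges are concatenated into the full 5D image.

With stopping disabled, the per-device gradients (assigned frames, using
ghosts at boundaries) concatenate to exactly the global gradient at every
synchronized iteration, so lockstep runs reproduce the single-device
reconstruction to floating-point round-off; with local stopping enabled,
iteration counts differ per device and the results agree approximately
(in practice SSIM well above 0.95 against the single-device result).

## Synthetic data

`simulate_dataset()` builds a desk-scale analogue of a free-breathing
acquisition:

* **Phantom** (`generate_phantom`): a torso ellipsoid with static liver
  and spine structures and a "heart" whose radii contract sinusoidally
  over the cardiac cycle (peak fractional contraction 0.3 at mid-cycle)
  and whose centre translates along $z$ over the respiratory cycle
  (default 1.5 voxels), under a smooth complex phase ramp.  It is a
  deterministic analytic function of its spec — no RNG involved.  It is
  deliberately simple: smooth piecewise-ellipsoidal anatomy has
  concentrated k-space energy and no fine texture, so absolute SSIM/PSNR
  values are not comparable to patient data; the phantom's job is to
  exercise the pipeline with genuinely beating/breathing content.
* **Coils** (`generate_coils`): Gaussian sensitivity profiles centred
  around the field of view with smooth linear phases, normalized to
  $\sum_c\lvert S_c\rvert^2 = 1$ exactly; a single coil degenerates to a
  uniform map.
* **Masks** (`generate_masks`): the readout axis $k_x$ is fully sampled;
  in the $(k_y, k_z)$ plane a fully sampled elliptical centre
  (4% of the plane by default) is kept and remaining samples are drawn
  without replacement with radially decaying probability, hitting the
  target fraction $1/\text{AF}$ per frame up to rounding.  Presets AF
  $\in \{4, 8, 10\}$; every frame gets its own pattern; the set is a
  deterministic function of the seed.
* **Noise** (`simulate_acquisition`): i.i.d. complex Gaussian noise on
  sampled entries, scaled so the ratio of mean squared signal magnitude
  to noise power equals the requested SNR in dB.

Default sizes used throughout the documentation and tests (e.g.
$32^2\times8$ or $16^2\times6$ grids with $N_c = 20$, $N_r = 4$, 3–4
coils) are the package's own desk-scale choices so that complete
reconstructions run in seconds to minutes on one CPU; all algorithmic
structure (80 frames, staged solver, partitioning) is preserved at this
scale.

## Quality metrics

`ssim_series()`/`psnr_series()` compare magnitude images, the usual MRI
convention.  SSIM uses a 3D Gaussian window ($\sigma = 1.5$, 11-voxel
support truncated to odd widths on small volumes), "valid" filtering
without padding, constants $K_1 = 0.01$, $K_2 = 0.03$, and the data
range of the reference series; the series value is the mean over frames
(`quality_report()` gives the per-frame breakdown).  PSNR is
$10\log_{10}(\text{peak}^2/\text{MSE})$ with the reference peak.

## Numerical choices and limitations

* All arrays are complex double; the DFT is the unitary `stats::fft`
  scaling, so operator-norm bounds hold exactly and adjointness is
  testable to $10^{-10}$.
* The container format stores complex data as `_real`/`_imag` float64
  dataset pairs (HDF5 via rhdf5, which has no portable complex type),
  with dataset contents deterministic for identical inputs.
* Devices are simulated in-process; wall-clock speed-up from real
  parallel hardware is out of scope.  What the package reproduces is the
  *algorithmic* content of multi-device execution: partition arithmetic,
  ghost-frame exchange, synchronization protocol and its convergence
  behaviour.
* `concurrent` mode models asynchrony as a seeded random per-round
  ordering with atomic publish/retrieve/compute per device.  True
  hardware races cannot reorder within a device's step, so this models
  staleness (the consequential phenomenon) rather than data races.
* The progress quotient can stall a stage early on near-flat objectives;
  the $\tau = 7$ minimum and the 100-iteration cap bound each stage on
  both sides.
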