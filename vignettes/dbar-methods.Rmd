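---
title: "The D-bar reconstruction chain in eitdbar: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The D-bar reconstruction chain in eitdbar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eitdbar)
```

# The problem and the model

Electrical impedance tomography (EIT) reconstructs the conductivity
$\gamma(x)$ inside a body from currents injected and voltages measured on
boundary electrodes. The governing equation is the generalized Laplace
equation $\nabla\cdot(\gamma\nabla u) = 0$ on a disk $\Omega$, and all
measurement information is encoded in the Dirichlet-to-Neumann (DN) map
$\Lambda_\gamma$, which takes boundary voltage to boundary current density.

`eitdbar` implements the *D-bar* method: a direct (non-iterative in
conductivity space) nonlinear reconstruction built on inverse scattering
for the two-dimensional Schrödinger equation. Its chain is

1. **Forward simulation** — complete electrode model (CEM) finite elements
   with trigonometric current patterns (`solve_forward_cem`);
2. **Discrete maps** — Neumann-to-Dirichlet matrix $R_{\gamma,r}$, its
   inverse $L_{\gamma,r}$, and the difference $\delta L$ against a
   homogeneous reference, with the best homogeneous fit
   $\gamma_{best}$ (`build_nd_map`, `dn_from_nd`, `delta_dn`,
   `gamma_best`, `fit_reference`);
3. **Scattering transform** — the Born-type boundary approximation
   $t^{exp}_R(k)$ evaluated as a double series over the trigonometric
   matrix elements of $\delta L$, truncated to $|k|\le R$
   (`scattering_transform`, `truncate_scattering`);
4. **D-bar solve** — for each image point $x$, the weakly singular
   integral equation
   $\mu(x,s) = 1 + \frac{1}{4\pi^2}\int \frac{t_R(k)}{(s-k)\bar k}
   e_{-k}(x)\overline{\mu(x,k)}\,dk$
   is collocated at sinc points and solved with real-linear GMRES, the
   convolution with the Cauchy kernel $1/k$ being evaluated by Stenger's
   sinc-convolution separation of variables (`build_sinc_grid`,
   `build_operators`, `separate_convolve`, `solve_dbar_at`);
5. **Image** — $\gamma(x) = \gamma_{best}\,\mathrm{Re}\,\mu(x,0)^2$
   (`reconstruct_image`), evaluated on a pixel grid over the unit disk;
6. **Evaluation** — GREIT figures of merit (amplitude response AR,
   position error PE, ringing RNG, resolution RES, shape deformation SD),
   convergence tables and degree of truth (`greit_measures`,
   `convergence_table`, `degree_of_truth`).

Everything is driven by a single configuration object
(`default_config()`), and by the CLI commands `cmd_simulate`,
`cmd_reconstruct`, `cmd_evaluate`.

# Units and normalization

Conductivities are carried in mS/m, currents in mA, voltages in volts
(mA/mS = V), contact impedance in $\Omega\,\mathrm{m}^2$ at unit electrode
height. Internally the inverse problem is nondimensionalized: measured
voltages are scaled by $\gamma_{best}$ (so the background conductivity is
$\approx 1$), the domain is mapped to the unit disk, and the final image is
scaled back by $\gamma_{best}$. The proof behind the reconstruction formula
assumes $\gamma$ constant near the boundary, so the raw $\mu(x,0)^2$ image
is normalized to 1 at the boundary; multiplication by $\gamma_{best}$ is
what produces physical units.

The electrode area `A` converts electrode currents to boundary current
densities in the discrete-to-continuum identification. The default
$A = (2\pi r/L)\times 1$ (the full per-electrode boundary strip at unit
height) is the value for which the discrete sums converge to the continuum
boundary integrals; it is a config value and never silently inferred.

# Derived constants that the source material leaves ambiguous

Three constants in the chain are not printable from the reference
formulas alone and were fixed by independent oracles (all three checks are
in the test-suite):

* **The series prefactor.** With $\delta L$ built from
  $\gamma_{best}$-normalized voltages, the discrete approximation of the
  unit-disk $(\Lambda_\sigma-\Lambda_1)$ matrix element is
  $(r/A^2)\,\delta L$, and
  $t(k) = \pi\frac{r}{A^2}\sum_{m,n} w_m w_n\,a_m(\bar k)a_n(k)
  [\delta L_{m,n} + \delta L_{m+L/2,n+L/2}
  + i(\delta L_{m,n+L/2}-\delta L_{m+L/2,n})]$
  with weights $w_{L/2}=\sqrt2$ on the half-order boundary terms. This was
  validated against a centered circular inclusion whose DN map has a
  closed-form eigen decomposition ($\Lambda e^{in\theta} =
  n\frac{1+\mu a^{2n}}{1-\mu a^{2n}}e^{in\theta}$), for which the
  boundary-integral definition of $t^{exp}$ reduces to
  $2\pi\sum_n a_n(\bar k)a_n(k) d_n$: the two routes agree to $\sim0.2\%$
  for $|k|\le 2$. A multiplicative `calibration` constant remains exposed
  in the config, default 1.

* **The equation constant.** The Cauchy-transform inversion of the D-bar
  equation carries $1/(4\pi^2)$. An independent uniform-grid collocation
  solve of the same equation (dense real-linear system, no sinc machinery)
  pins this: with $1/(4\pi)$ a centered contrast-2 inclusion reconstructs
  to $\sim33\times$ the background; with $1/(4\pi^2)$ the Born limit at
  contrast 1.1 recovers 1.1 at the center and 1.0 outside.

* **The kernel transform.** For $g(k) = 1/(k_1+ik_2)$ and the Laplace
  convention $e^{-t/s}$, direct integration gives
  $G(u,v) = \frac{uv(\log(u/v) - i\pi/2)}{u - iv}$, valid for
  $\mathrm{Re}\,u>0$, $\mathrm{Re}\,v>0$ (the principal log equals the
  continuous branch there because $|\arg u - \arg v| < \pi$; the point
  $u = iv$ is a removable singularity with limit $v$). The closed form
  matches numeric quadrature of the defining double integral to
  $10^{-6}$ at random complex points, which resolves the sign convention:
  the mirrored quadrants use $G_2(u,v) = \overline{G(\bar u,\bar v)}$ and
  overall signs $(+,+,-,-)$ for the $(++,+-,-+,--)$ kernel reflections.

# Numerical choices

**Sinc grid and the step size $h$.** The integration square is
$[-2R,2R]^2$ with the tanh-type map $\varphi(z)=\log\frac{2R+z}{2R-z}$,
sinc points $z_l=\varphi^{-1}(lh)$ and the *positive* derivative
$\varphi'(z)=\frac{4R}{(2R+z)(2R-z)}$ (the printed negative variant is a
sign typo; a negative $\varphi'$ would flip the quadrature weights). The
classical sinc-quadrature step $h=\pi/\sqrt{m/2}$ is designed for
integrands that live near the interval *endpoints*, where this map
clusters its points. The D-bar integrand is the opposite: it is supported
on the truncation disk $|k|\le R$ in the *middle* of the box and vanishes
identically at the endpoints. With the classical step at k-grid level 16
only five sinc points fall inside the truncation disk and every
reconstruction collapses to a centered blob. The default is therefore
$h = 4/(R\sqrt{m-1})$, which makes the near-origin grid spacing
$\approx Rh = 4/\sqrt{m-1}$: independent of $R$, shrinking with $m$, and
still covering the box. `h` remains configurable.

**Truncation radius under noise.** $R$ is the regularization dial of the
D-bar method. Noiseless data use the configured `R_trunc` (default 4).
For a dataset with declared relative noise $\delta$ the pipeline shrinks
the radius to $\min(R_{trunc},\,2.3(-\ln\delta)^{1/3})$, the functional
form used by the regularized D-bar literature, with the constant set so
that 10% noise gives $R\approx3$ (the low-single-digit radii used in
experimental D-bar work). A sensitivity study on the noisy rotating
target with the DN map deliberately estimated in the raw recorded basis
(so that first-order noise reaches the scattering data) shows why: at the
outermost position the position error is $\sim0.3$–$0.5$ at $R=3$,
$0.5$–$0.7$ at $R=4$ and $\sim0.8$ at $R=5$. Interior noiseless accuracy
is $R$-insensitive across $R\in\{3,4,5\}$ (asserted in the test-suite),
while the outermost position actually prefers $R\approx3$ even without
noise (PE 0.11 vs 0.38 at $R=4$). `R_noise_rule = FALSE` disables the
adaptation.

**$k=0$.** The integrand factor $t_R(k)/\bar k$ is assigned 0 at the
origin ($t$ vanishes there for smooth conductivities); $t(0)=0$ by
convention.

**Real-linear GMRES.** The D-bar operator conjugates $\mu$, so it is
real-linear but not complex-linear; the solver works on the stacked
vector $(\mathrm{Re}\,\mu, \mathrm{Im}\,\mu)$ with a hand-written
restarted GMRES (modified Gram–Schmidt, Givens rotations, true-residual
confirmation). Defaults: tol $10^{-5}$, restart 30, maxit 200. Pixels are
solved independently; results do not depend on evaluation order.

**Eigendecompositions.** $A_1 = hI^{(-1)}D(1/\varphi')$ becomes severely
non-normal as $m$ grows; the eigenvector basis is adequate up to
$m\approx129$ (k-grid level 128) and the build fails loudly with a
conditioning error beyond that. All eigenvalues lie in the open right
half plane (checked for $m\le65$), which is the domain of $G$.

# The synthetic world, and what a green test establishes

`forward_sim` is a first-class synthetic data generator:

* **Meshes** are structured sector triangulations (ring $j$ carries
  $S\,j$ nodes). The pipeline uses $S = L$ so the discretization error
  commutes with the electrode rotation symmetry; the inverse-side
  reference mesh is the same resolution class *rotated by half a
  boundary-node spacing* — a different mesh (the inverse-crime guard is
  asserted structurally) whose $O(h^2)$ bias cancels in $\delta L$ to the
  $\sim10^{-3}$ relative level. This matters: the GREIT target has
  diameter ratio 0.05, whose $\delta L$ signal is only $\sim4\times10^{-4}$
  relative, so a much coarser reference mesh would bury it in
  discretization bias.
* **Homogeneous reference at $\gamma_{best}$.** The CEM is linear in the
  pair $(\gamma, 1/z)$, not in $\gamma$ alone, so a reference solved at
  1 mS/m would mis-scale the contact-impedance term by three orders of
  magnitude relative to tissue-scale data. The reference is solved at
  $\gamma_{best}$ with the same contact impedance and scaled to unit
  conductivity afterwards; it also injects the *recorded* currents so that
  measured and reference DN matrices live in the same pattern basis.
* **Phantoms.** Chest: two elliptical lungs and a circular heart at the
  tabulated conductivities (1000/1500/500 and 424/750/240 mS/m); the
  geometry is never printed for the reference experiments, so a fixed,
  visually plausible configuration is used (centers $(\pm0.45,-0.15)$,
  semi-axes $(0.24, 0.42)$, $\mp20^\circ$; heart at $(0.07,0.42)$,
  radius 0.2). Rotating target: radius 0.05, contrast 2, nine positions
  along $\theta=0$ from the center to 0.9 (the outermost center with
  boundary clearance at least one target radius). Conductivity is
  elementwise constant; an element belongs to an inclusion when its
  centroid does, so the tiny target is represented by only a handful of
  forward elements — a real staircase error that the evaluation inherits.
* **Noise.** The stated 0.1 mA uniform noise is implemented as
  *injected-current* noise: mean-centered per pattern (charge
  conservation), actually injected (the voltages are re-solved) and
  recorded — an imperfect but self-aware current source. Pure
  measurement-error readings (perturbing recorded currents or voltages
  without re-solving) make the data inconsistency two orders of magnitude
  larger than the small target's signal and reduce every noisy image to
  noise — incompatible with the structured accuracy curves the protocol
  is meant to produce. Because the recorded currents are known, the DN
  estimator recovers the responses to the clean trigonometric patterns by
  least squares over the recorded pattern basis (exact for linear data;
  noise effects become second order). Treating the recorded,
  non-orthogonal patterns as if they were the trig basis is a biased
  estimator and made boundary-target localization erratic (position
  errors 0.2–0.7 across noise seeds at the outermost position); with the
  proper estimator the noisy position-error curve rises smoothly to
  ~0.12 at the outermost position and is regularization-bias dominated,
  matching the shape of the reference accuracy curves. Voltage-side
  additive noise remains available through `noise_target = "voltages"`.

What the green tests do **not** establish: performance on non-circular
domains, electrode-position error, 3D effects, adjacent-pair protocols
(the reader ingests such frames but the chain rejects them), or real
hardware noise spectra.

# Known limitations and honest margins

* Position error grows toward the boundary (regularization bias of the
  truncated scattering data), from 0 at the center to $\approx0.12$ at
  the outermost target position under the default configuration — inside
  the printed endpoint 0.5 of the reference curves. If the clean-basis
  least-squares estimator is bypassed (recorded noisy patterns treated as
  the trig basis), that boundary value becomes an unstable 0.2–0.7
  depending on the noise draw.
* Measured against the *true* conductivity, the image error of the full
  chain floors at the regularization error of the truncated Born
  approximation ($t^{exp}$, $|k|\le R$) by k-grid level 32. The
  convergence-rate study therefore measures solver *self-convergence*
  (reference = the level-128 solve of the same data), which is the only
  reading under which sup-norm errors can keep shrinking near-exponentially
  the way the reference tables report.
* $t^{exp}$ overshoots for high contrasts (a centered contrast-2 disk of
  radius 0.5 reconstructs to $\sim3\times$ background at $R=4$); this is a
  property of the Born-type approximation, not of the solver, and is why
  absolute values are quoted through the degree-of-truth and
  relative-extremum metrics rather than asserted pointwise.
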