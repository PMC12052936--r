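---
title: "Acid-mediated tumor invasion fronts: construction, stability, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acid-mediated tumor invasion fronts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidfront)
```

## The model

`acidfront` studies a Gatenby–Gawlinski-type reaction–diffusion model of
acid-mediated tumor invasion,

$$
\begin{aligned}
U_\tau &= U(1-U) - \delta_1 U W,\\
V_\tau &= \rho V(1-V)(V-a) - \delta_2 V W
          + \nabla\cdot\big((1+\kappa-U)\nabla V\big),\\
W_\tau &= \delta_3 (V - W) + \tfrac{1}{\varepsilon^2}\Delta W,
\end{aligned}
$$

for normal cell density $U$, tumor cell density $V$ and lactic acid
concentration $W$.  The acid-mediation hypothesis is that glycolytic tumor
cells acidify their microenvironment and that the acid is more toxic to
normal tissue ($\delta_1$) than to the tumor itself
($\delta_2 < \delta_1$).  Three modeling ingredients matter throughout:

* **Allee effect.** Tumor growth $\rho V(1-V)(V-a)$ is bistable: per-capita
  growth is negative below the threshold density $a\in(0,1)$.  This makes
  invasion fronts *bistable fronts with an isolated wave speed*, which is
  what allows a clean two-dimensional stability analysis (the critical
  spectrum in 1D is the single translational eigenvalue at zero).
* **Regularized cross diffusion.** Tumor motility $(1+\kappa-U)$ is reduced
  by normal tissue but never vanishes ($\kappa>0$); the degenerate
  $\kappa=0$ limit of the original model is out of scope here.
* **Scale separation.** Acid diffuses a factor $\varepsilon^{-2}$ faster
  than cells, $0<\varepsilon\ll 1$, so traveling fronts have a slow–fast
  (singularly perturbed) structure: a sharp $O(1)$-wide interface in $V$
  embedded in $O(1/\varepsilon)$-wide acid tails.

All quantities are dimensionless.  A parameter set is a `model_params()`
object; `load_preset()` carries the tuples used in the reference figures,
e.g. the classic set $(a,\kappa,\delta_1,\delta_2,\delta_3,\rho,\varepsilon)
= (0.35, 0.1, 12.5, 0.1, 70, 1, 0.0063)$ as `"fig1"`.

## Homogeneous states and regimes

Besides the trivial states $P_1=(0,0,0)$ and the healthy state
$P_2=(1,0,0)$, the kinetics admit invaded states built on the tumor
densities $V^\pm$ solving $\rho(1-V)(V-a)=\delta_2 V$
(`equilibrium_V()`): the coexistence states
$P_3^\pm=(1-\delta_1 V^\pm, V^\pm, V^\pm)$ and the tumor-only states
$P_4^\pm=(0, V^\pm, V^\pm)$.  Stability is decided by the $3\times 3$
kinetics Jacobian (`steady_states()`); the pattern is: $P_2$ stable,
$P_1, P_3^-, P_4^-$ unstable, $P_3^+$ stable iff $\delta_1 V^+<1$ and
$P_4^+$ stable iff $\delta_1 V^+>1$.  The quantity $\delta_1 V^+$ is the
*malignancy index*: below one, normal cells survive behind the front
(**benign**); above one they are eliminated (**malignant**).

```{r}
p <- load_preset("fig1")$params
steady_states(p)
classify_regime(p)
```

## The singular front ($\varepsilon \to 0$)

In the comoving coordinate $\xi = x + ct$ the traveling-wave equations
form a five-dimensional slow–fast system in $(u, v, q, w, p)$ with
$q=(1+\kappa-u)v'-cv$ and $p=w'/\varepsilon$.  At $\varepsilon=0$ this
splits into:

* **Layer problem** (fast): with $w$ frozen, the tumor density jumps along
  the classic bistable heteroclinic of
  $D v'' - c v' + \rho v(v^+(w)-v)(v-v^-(w)) = 0$, where
  $v^\pm(w) = \tfrac12\big(1+a \pm \sqrt{(1-a)^2 - 4\delta_2 w/\rho}\big)$
  and $D$ is the frozen diffusion coefficient: $D=\kappa+\delta_1 w$ inside
  the coexistence subspace $u=1-\delta_1 w$ ("branch 1") and $D=1+\kappa$
  in the tumor-only subspace $u=0$ ("branch 0").  The profile is the
  explicit tanh front and the speed is
  $c(w) = \sqrt{2D\rho}\,\big(v^+(w)/2 - v^-(w)\big)$ (`layer_front()`).
  Direct substitution of the tanh ansatz fixes both the steepness
  $b=(v^+/2)\sqrt{\rho/(2D)}$ and this speed; the package's test suite
  verifies the speed against an independent shooting solve of the layer
  ODE over random parameter draws.
* **Reduced problem** (slow): on the critical manifolds the acid follows
  $w_{\zeta\zeta} = -\delta_3(v-w)$ in the slow variable
  $\zeta=\varepsilon\xi$, a Hamiltonian system (`hamiltonian()`).  Ahead
  of the interface ($v=0$) the relevant orbit is the unstable manifold
  $p=\sqrt{\delta_3}\,w$ of the healthy state; behind it ($v=v^+(w)$) the
  stable manifold of the invaded equilibrium $(V^+,0)$.

Matching the two slow orbits through the jump fixes the interface acid
level $w_*$ via an energy balance (`solve_w_star()`); $w_*$ depends only
on $(a,\rho,\delta_2)$.  The front geometry then follows from where $w_*$
sits relative to the *transcritical level* $1/\delta_1$ at which the two
subspaces exchange:

* benign: jump on branch 1, three segments;
* malignant no-gap ($w_*<1/\delta_1$): jump on branch 1, then a slow
  passage through the transcritical level behind the interface;
* malignant gap ($w_*>1/\delta_1$): the slow orbit crosses the
  transcritical level *ahead* of the jump, opening an **acellular gap**
  — a stretch where $u=v=0$ and only acid is present — of slow-scale
  width $\ln(\delta_1 w_*)/\sqrt{\delta_3}$.

```{r}
singular_front(p)
```

With $\delta_2=0$ everything is elementary ($w_*=1/2$, benign/malignant
boundary at $\delta_1=1$, gap onset at $\delta_1=2$); these exact values
anchor the test suite.

## The resolved front (finite $\varepsilon$)

`solve_front()` solves the five-component first-order traveling-wave
system with the speed $c$ as an unknown scalar.  Numerical choices, all
tunable:

* **Collocation.** Hermite–Simpson (Lobatto IIIA) two-point collocation,
  fourth order, with an analytic sparse Jacobian and a damped Newton
  iteration.  Fourth order matters: the translation eigenvalue of the
  downstream linearization inherits the profile error, and the default
  meshes reach $|\lambda_{\rm transl}| \sim 10^{-7}$.
* **Mesh.** Graded: fine ($\approx$ 1/12 of the layer width) around the
  interface at $\xi=0$ and around the normal-tissue collapse where $w$
  crosses $1/\delta_1$ (the sharpest feature, width
  $\sqrt{c/(\delta_1\varepsilon p)}$), coarsening linearly into the slow
  tails.  Typical sizes: 600–1500 points.
* **Domain and boundary conditions.** Half-length
  $L = 16/(\varepsilon\sqrt{\delta_3})$ (sixteen slow e-foldings, placing
  the truncated tails below $10^{-6}$).  The
  truncation uses *projected* conditions — the deviation from the end
  equilibrium must lie in its unstable (left end) or stable (right end)
  eigenspace — rather than hard Dirichlet pinning, which would bias the
  speed by $O(e^{-\text{rate}\cdot L})$.
* **Phase condition.** $v(0)=v^+(w_*)/2$, matching the tanh centering;
  this removes the translation degeneracy and closes the system for the
  extra unknown $c$.
* **Initial guess.** The singular concatenation itself
  (`initial_guess()`); Newton typically converges in 4–6 iterations.

At the classic parameter set the solver yields $c = 0.04006$, a genuine
finite-$\varepsilon$ correction below the singular speed
$c_*=0.0526$ — the slow passage through the transcritical point is felt
strongly even at $\varepsilon = 0.0063$.  Doubling the mesh moves $c$ by
less than $10^{-6}$; pushing $\varepsilon\to 0$ numerically recovers
$c_*$ (tested).  `continue_parameter()` marches a converged front along
any model parameter with adaptive step halving, reproducing the trends:
$c$ and the gap width grow with the acid toxicity $\delta_1$, while a
stronger Allee effect ($a\uparrow$) slows invasion.
`measure_gap_width()` reports the acellular width under the operational
definition "both cell densities below $10\varepsilon$", in both $\xi$ and
$\zeta$ units; only the $\zeta$-width has a finite singular limit, so
comparisons against the closed form are made there.

## Transverse stability

Extending the 1D front trivially in $y$ gives a planar interface whose
perturbations $\propto e^{i\ell y+\lambda\tau}$ satisfy a linear
eigenvalue problem in $\xi$ with an $\ell^2$ penalty
$\mathrm{diag}(0,\,(1+\kappa-u_h),\,1/\varepsilon^2)$.
`assemble_linearization()` discretizes the operator with five-point
(Fornberg) stencils on the front's own mesh; `spectrum()` computes the
point spectrum near a shift by sparse shift-invert ARPACK iterations
(dense fallback on small grids).  In 1D ($\ell=0$) the computed spectra
of the reference gap fronts show the translational eigenvalue at zero
(to $\sim 10^{-6}$) with everything else damped — the longitudinal
stability that the 2D analysis assumes.

The curvature of the critical branch $\lambda_c(\ell)=\lambda_{c,2}\ell^2
+ O(\ell^4)$ decides long-wavelength stability of the interface.
`lambda_c2()` evaluates it from the Fredholm solvability quotient

$$
\lambda_{c,2} = -\,\frac{\int (1+\kappa-u_h)\,v_{h,\xi} v^A
 + \varepsilon^{-2} w_{h,\xi} w^A \,d\xi}
{\int u_{h,\xi}u^A + v_{h,\xi}v^A + w_{h,\xi}w^A \,d\xi},
$$

with $(u^A,v^A,w^A)$ the bounded adjoint null solution.  The adjoint is
obtained by *discretize-then-transpose* (inverse iteration on the
transpose of the discrete operator), so the discrete Fredholm
orthogonality is exact by construction; the printed adjoint operator
serves as an analytic cross-check on residuals and on the fast-field
form $v^A \propto v_{h,\xi} e^{-c\xi/(1+\kappa-u_*)}$.
`lambda_curve()` corroborates the quotient by tracking the eigenvalue
branch in $\ell$ (the quadratic regime lives at $\ell = O(\varepsilon)$;
both routes agree to well under 5%).  Because the quotient scales like
$1/\varepsilon$, reports carry $\varepsilon\lambda_{c,2}$ alongside.

`lambda_c2_asymptotic()` evaluates the leading-order singular-limit
formula built from the closed-form layer and the slow Hamiltonian
orbits.  Its sign factor
$\int (\delta_1 u_* \bar u_* + \delta_2 v_* \bar v_*)\,d\xi$
yields the headline dichotomy: in the gap case $u_*=0$, so the
coefficient is positive whenever $\delta_2>0$ — *an acellular gap
implies long-wavelength transverse instability* for small
$\varepsilon$ — while no-gap and benign fronts can go either way.
`stability_boundary()` maps the sign over $(\delta_1,\delta_2)$
(numerically at the set $\varepsilon$, or via the asymptotics, whose
sign is $\varepsilon$-free) and locates the zero contour by bisection;
the benign/malignant curve $\delta_1 V^+=1$ is returned for overlay.
The map reproduces the published structure: a single sign change along
$\delta_2$, with stable and unstable points in both the benign and the
malignant regions.

The quadratures in the asymptotics pair decaying $\mathrm{sech}$ powers
with the growing weight $e^{-c_*\xi/(1+\kappa-u_*)}$; they are evaluated
in log space with analytic truncation (integrability requires
$4b > c_*/(1+\kappa-u_*)$, which holds across the explored parameter
ranges and is checked at run time).  The degenerate crossover
$w_*=1/\delta_1$ (within $10^{-8}$) is declined rather than
extrapolated.

## 2D simulation and the growth-rate contract

`make_initial_condition()` extends a front across a periodic transverse
direction and seeds uniform noise (default amplitude $10^{-3}$ on $V$,
recorded seed).  `evolve()` advances the comoving-frame PDE with an IMEX
scheme: the stiff $\varepsilon^{-2}$ acid Laplacian is implicit (FFT in
$y$ + precomputed tridiagonal solves in $\xi$; the $1/\varepsilon^2$
stiffness rules out explicit stepping), while reactions, the
conservative flux form of the nonlinear tumor diffusion, and the
advection $c\,\partial_\xi$ are explicit.  No-flux ends in $\xi$ are
backed by a sponge relaxing the outer 5% of the window to the
unperturbed tails, absorbing the slow speed adjustment of the perturbed
interface.

The desk-scale validation contract is *linear-regime growth-rate
matching* rather than reproduction of late-time morphology: the
interface position $h(y)$ (level-crossing of $V$ at $v^+(w_*)/2$) is
Fourier-analyzed, and the fitted exponential rates $\sigma(\ell_k)$ of
the first discrete modes must match the spectral prediction
$\lambda_c(\ell_k)$.  The default benchmark uses the fast-growing
reference preset (`"fig8_row4"`: $\rho=15$, $\delta_3=1$,
$\varepsilon=0.05$), a box carrying four wavelengths of the most
unstable mode ($L_y \approx 250$, $N_y=64$), a comoving window
$|\xi|\le 80$ at $h_x=0.15$, and $dt = 10^{-2}$ to $\tau=40$.  On this
grid the first three mode growth rates agree with $\lambda_c(\ell_k)$
to a few percent (the acceptance contract allows 15%).  These sizes are
the package's chosen benchmark scale; the published late-time
simulations (cusps vs fingers at $t\sim 4\times 10^4$) are far larger
and are deliberately not reproduced pixel-wise — what passing tests
certify is the linear instability mechanism, not nonlinear pattern
selection.

## What the tests do and do not show

The suite verifies: exact singular-limit identities at $\delta_2=0$;
layer speeds against independent shooting; Hamiltonian conservation
along independently integrated slow orbits; the printed front speed at
the classic parameter set (2%); longitudinal spectra and the transverse
criterion for the four reference fronts; the $(\delta_1,\delta_2)$
stability map structure; parameter trends under continuation; and the
2D growth-rate contract.  The 2D runs probe only the linear regime on
periodic desk-scale boxes — statements about long-time finger/cusp
selection, curved interfaces, three-dimensional domains, or
heterogeneous tissue are outside what these tests support.  Longitudinal
stability is verified spectrally in a window near zero, not proved.

## Known limitations

* The fast-front family (frame exponent $\nu=-1$) is not implemented.
* Continuation is natural-parameter with step halving; no pseudo-arclength,
  so folds in a branch would truncate it (none occur in the explored
  sweeps).
* Near the degenerate crossover and near the fold of $v^+(w)$ the
  asymptotic module declines rather than regularizes.  Close to the fold
  (when $V^+$ approaches $\rho(1-a)^2/(4\delta_2)$) the fast subsystem
  loses normal hyperbolicity and the boundary-value Jacobian becomes
  ill-conditioned; the Newton solve can fail within a few percent of the
  fold (e.g. $\delta_2 \gtrsim 0.4$ at $a=0.1$, $\rho=1$, $\delta_1=2$).
* The eigensolver windows the point spectrum near a shift; it does not
  chase spectrum far into the left half plane.
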