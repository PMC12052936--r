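# acidfront

Traveling fronts and interface instabilities in an acid-mediated tumor
invasion model with Allee effect.

## The problem

Invasive tumors acidify their microenvironment: glycolytic tumor cells
export lactic acid, which is more toxic to surrounding normal tissue than
to the tumor itself. The classic Gatenby–Gawlinski description of this
*acid-mediated invasion* is a three-species reaction–diffusion model for
normal cell density *U*, tumor cell density *V*, and acid concentration
*W*. `acidfront` implements a modified form in which tumor growth carries
an Allee effect and the cross-dependent tumor diffusion is regularized:

$$
\begin{aligned}
U_\tau &= U(1-U) - \delta_1 U W,\\
V_\tau &= \rho V(1-V)(V-a) - \delta_2 V W
          + \nabla\cdot\big((1+\kappa-U)\nabla V\big),\\
W_\tau &= \delta_3(V-W) + \tfrac{1}{\varepsilon^2}\Delta W .
\end{aligned}
$$

Because acid diffuses much faster than cells
($0<\varepsilon\ll 1$), invasion fronts are singularly perturbed: a sharp
tumor interface rides on long acid tails. The package is a toolkit for
the full analysis pipeline of these fronts, aimed at researchers in
mathematical oncology and reaction–diffusion pattern formation:

* **Regimes and steady states** — homogeneous equilibria, their kinetic
  stability, and the classification into *benign* ($\delta_1 V^+<1$,
  normal cells coexist behind the front), *malignant no-gap*, and
  *malignant gap* regimes. In the gap regime an **acellular gap** — a
  zone with only acid, no cells — opens between the retreating tissue and
  the advancing tumor.
* **Singular front construction** ($\varepsilon\to 0$) — explicit tanh
  layer fronts at frozen acid level with speed
  $c(w)=\sqrt{2D\rho}\,(v^+(w)/2-v^-(w))$, slow Hamiltonian orbits, the
  energy-matching acid level $w_*$, the regime-specific concatenation,
  and the closed-form gap width $\ln(\delta_1 w_*)/\sqrt{\delta_3}$.
* **Resolved fronts at finite $\varepsilon$** — the five-component
  traveling-wave boundary-value problem with the wave speed as an unknown
  scalar (4th-order collocation, projected boundary conditions, graded
  meshes), plus natural-parameter continuation and gap-width measurement.
* **Stability** — longitudinal point spectra of the front linearization;
  the transverse long-wavelength coefficient $\lambda_{c,2}$ from the
  adjoint (Fredholm) solvability quotient; its singular-limit asymptotics
  and sign criterion (an acellular gap implies transverse instability
  whenever $\delta_2>0$); stability maps over $(\delta_1,\delta_2)$.
* **2D simulation** — IMEX comoving-frame evolution of noise-seeded
  planar fronts with interface Fourier diagnostics, validating the
  spectral growth rates mode by mode.

## Worked example

The classic parameter set
$(a,\kappa,\delta_1,\delta_2,\delta_3,\rho,\varepsilon)
=(0.35, 0.1, 12.5, 0.1, 70, 1, 0.0063)$:

```r
library(acidfront)
p <- load_preset("fig1")$params

classify_regime(p)
#> Regime: malignant_gap
#>   delta1 * V+ = 10.332, w* = 0.43795

sf <- singular_front(p)
sf
#> Singular front (eps -> 0): malignant_gap
#>   w* = 0.43795005, p* = 3.664153, c* = 0.052632123
#>   acellular gap width (slow variable zeta): 0.20319821
#>   segments: slow_M0_1 -> slow_M0_0 -> jump -> slow_Mplus_0

tw <- solve_front(p)
tw
#> Traveling front (nu = 0), regime: malignant_gap
#>   wave speed c = 0.0400572 (singular limit c* = 0.0526321)
#>   mesh: 714 points on [-303.6, 303.6]; residual 5.59e-13; converged
#>   connects p2 (xi -> -Inf) to p4+ (xi -> +Inf)

measure_gap_width(tw)
#>   width_xi width_zeta
#> 28.9415518  0.1823318

lambda_c2(tw)
#> [1] 0.6478326
#> attr(,"eps_scaled")
#> [1] 0.004081345
```

Reading the numbers: the front is a malignant gap front — the fast tumor
interface jumps at acid level $w_*=0.438$, well above the transcritical
level $1/\delta_1=0.08$, so an acellular gap of slow-scale width 0.203
(singular limit) opens; at $\varepsilon=0.0063$ the resolved gap is 0.182.
The boundary-value solve determines the invasion speed $c=0.04006$
(the printed reference value for this parameter set is 0.0401). The
positive transverse coefficient $\lambda_{c,2}=0.648$ means the planar
interface is unstable to long-wavelength transverse perturbations: in 2D
it develops the fingering/cusping dynamics that `make_initial_condition()`
+ `evolve()` + `mode_growth()` quantify in the linear regime.

See the vignette (`vignettes/acid-invasion-fronts.Rmd`) for the numerical
design decisions and the scope of what the tests certify.

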