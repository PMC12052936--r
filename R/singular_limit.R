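#' Fast-branch tumor rest states v+-(w)
#'
#' At a frozen acid level \code{w} the fast (layer) subsystem has the
#' nontrivial rest states
#' \deqn{v^\pm(w) = \frac{1+a \pm \sqrt{(1-a)^2 - 4\delta_2 w/\rho}}{2},}
#' valid up to the fold \eqn{w = \rho(1-a)^2/(4\delta_2)} where the two
#' branches collide (unbounded validity when \eqn{\delta_2 = 0}).
#'
#' @param w acid level(s), nonnegative.
#' @param params a [model_params()] object.
#' @return A list with numeric components \code{v_plus}, \code{v_minus}.
#' @export
v_branch <- function(w, params) {
  wf <- fold_w(params)
  if (any(w < 0) || any(w > wf + 1e-14))
    stop(sprintf("acid level w outside [0, %g]: fold of the fast branches",
                 wf))
  disc <- pmax((1 - params$a)^2 - 4 * params$delta2 * w / params$rho, 0)
  s <- sqrt(disc)
  list(v_plus = (1 + params$a + s) / 2, v_minus = (1 + params$a - s) / 2)
}

fold_w <- function(params) {
  if (params$delta2 == 0) Inf else
    params$rho * (1 - params$a)^2 / (4 * params$delta2)
}

# Layer-front speeds on the two invariant subspaces.  Effective diffusion
# is kappa + delta1*w on branch 1 (u = 1 - delta1 w) and 1 + kappa on
# branch 0 (u = 0).
layer_speed <- function(w, branch, params) {
  vb <- v_branch(w, params)
  D <- layer_diffusion(w, branch, params)
  sqrt(2 * D * params$rho) * (vb$v_plus / 2 - vb$v_minus)
}

layer_diffusion <- function(w, branch, params) {
  if (branch == 1) params$kappa + params$delta1 * w else 1 + params$kappa
}

#' Closed-form layer (interface) front at frozen acid level
#'
#' The fast jump of the singular front: at frozen slow variables
#' \eqn{(w, p)} the tumor density satisfies the planar bistable ODE
#' \deqn{D v'' - c v' + \rho v(1-v)(v-a) - \delta_2 v w = 0,}
#' with \eqn{D = \kappa + \delta_1 w} in the subspace
#' \eqn{u = 1-\delta_1 w} (\code{branch = 1}) or \eqn{D = 1+\kappa} in
#' \eqn{u = 0} (\code{branch = 0}).  Its heteroclinic from 0 to
#' \eqn{v^+(w)} is the explicit tanh profile
#' \deqn{v(\xi) = \frac{v^+}{2}\Big(1 + \tanh\big(\tfrac{v^+}{2}
#'   \sqrt{\rho/(2D)}\,\xi\big)\Big)}
#' traveling at the unique speed
#' \eqn{c = \sqrt{2D\rho}\,(v^+/2 - v^-)} (direct substitution of the
#' tanh ansatz fixes both the rate and this speed).
#'
#' @param w frozen acid level.
#' @param branch 0 or 1, selecting the invariant subspace.
#' @param params a [model_params()] object.
#' @return An object of class \code{"layer_front"}: list with \code{w},
#'   \code{branch}, \code{u_star}, \code{speed}, \code{v_plus},
#'   \code{v_minus}, \code{diffusion}, and functions \code{v_of_xi},
#'   \code{q_of_xi} (companion variable \eqn{q=(1+\kappa-u)v'-cv}).
#' @examples
#' lf <- layer_front(0, 1, model_params(0.1, 0.1, 1, 0, 70, 1, 0.01))
#' lf$speed                      # sqrt(0.2) * 0.4
#' lf$v_of_xi(0)                 # v+/2 at the centering point
#' @export
layer_front <- function(w, branch, params) {
  if (!branch %in% c(0, 1)) stop("branch must be 0 or 1")
  if (branch == 1 && w >= 1 / params$delta1)
    stop("branch 1 requires w < 1/delta1 so that u* = 1 - delta1*w > 0")
  vb <- v_branch(w, params)
  vp <- vb$v_plus; vm <- vb$v_minus
  D <- layer_diffusion(w, branch, params)
  cc <- sqrt(2 * D * params$rho) * (vp / 2 - vm)
  u_star <- if (branch == 1) 1 - params$delta1 * w else 0
  b <- (vp / 2) * sqrt(params$rho / (2 * D))
  v_of_xi <- function(xi) (vp / 2) * (1 + tanh(b * xi))
  dv_of_xi <- function(xi) (vp / 2) * b / cosh(b * xi)^2
  # q is defined with the full diffusion coefficient 1 + kappa - u; on the
  # invariant subspaces this equals D.
  q_of_xi <- function(xi) D * dv_of_xi(xi) - cc * v_of_xi(xi)
  structure(list(w = w, branch = branch, u_star = u_star, speed = cc,
                 v_plus = vp, v_minus = vm, diffusion = D, rate = b,
                 v_of_xi = v_of_xi, dv_of_xi = dv_of_xi, q_of_xi = q_of_xi),
            class = "layer_front")
}

#' @export
print.layer_front <- function(x, ...) {
  cat(sprintf(
    "Layer front on branch %d (u* = %.6g) at w = %.6g: speed c = %.6g\n",
    x$branch, x$u_star, x$w, x$speed))
  cat(sprintf("  rest states v-(w) = %.6g, v+(w) = %.6g, diffusion %.6g\n",
              x$v_minus, x$v_plus, x$diffusion))
  invisible(x)
}

# Exact antiderivative of the load integral
#   int_{V+}^{w} ( 1 + a + sqrt((1-a)^2 - 4 delta2 z / rho) ) dz ,
# used by the matching condition and the slow Hamiltonian.
load_integral <- function(w, params) {
  Vp <- equilibrium_V(params)[["V_plus"]]
  A <- (1 - params$a)^2
  B <- 4 * params$delta2 / params$rho
  lin <- (1 + params$a) * (w - Vp)
  if (B == 0) return(lin + sqrt(A) * (w - Vp))
  lin - (2 / (3 * B)) * ((pmax(A - B * w, 0))^1.5 - (pmax(A - B * Vp, 0))^1.5)
}

#' Slow-field Hamiltonians
#'
#' Conserved energies of the reduced (slow) dynamics
#' \eqn{w_{\zeta\zeta} = -\delta_3(v - w)} on the critical manifolds:
#' on the tumor-free branches (\code{branch = "M0"}, \eqn{v = 0})
#' \deqn{E_0(w, p) = p^2/2 - \delta_3 w^2/2,}
#' and on the invaded branches (\code{branch = "Mplus"},
#' \eqn{v = v^+(w)})
#' \deqn{E_+(w, p) = E_0(w, p) + \delta_3 (V^+)^2/2 +
#'       \int_{V^+}^{w} \delta_3 v^+(s)\, ds,}
#' normalised so that \eqn{E_0(0,0) = 0 = E_+(V^+, 0)}.
#'
#' @param w,p slow variables (acid level and its slow-scale gradient).
#' @param branch \code{"M0"} or \code{"Mplus"}.
#' @param params a [model_params()] object.
#' @return Numeric energy value(s).
#' @export
hamiltonian <- function(w, p, branch, params) {
  branch <- match.arg(branch, c("M0", "Mplus"))
  E0 <- p^2 / 2 - params$delta3 * w^2 / 2
  if (branch == "M0") return(E0)
  if (any(w > fold_w(params)))
    stop("w beyond the fold of v+(w); Mplus Hamiltonian undefined")
  Vp <- equilibrium_V(params)[["V_plus"]]
  E0 + params$delta3 * Vp^2 / 2 + params$delta3 * load_half(w, params)
}

# int_{V+}^{w} v^+(s) ds, exact.
load_half <- function(w, params) {
  Vp <- equilibrium_V(params)[["V_plus"]]
  A <- (1 - params$a)^2
  B <- 4 * params$delta2 / params$rho
  lin <- ((1 + params$a) / 2) * (w - Vp)
  if (B == 0) return(lin + (sqrt(A) / 2) * (w - Vp))
  lin - (1 / (3 * B)) * ((pmax(A - B * w, 0))^1.5 - (pmax(A - B * Vp, 0))^1.5)
}

#' Matching acid level of the fast jump
#'
#' The frozen acid level \eqn{w_*} at which the layer jump connects the
#' slow unstable manifold of the healthy state to the slow stable manifold
#' of the invaded state, fixed by the Hamiltonian matching condition
#' \deqn{0 = (V^+)^2 + \int_{V^+}^{w_*}\Big(1 + a +
#'   \sqrt{(1-a)^2 - 4\delta_2 z/\rho}\Big) dz,}
#' equivalently \eqn{E_+(w_*, \sqrt{\delta_3} w_*) = 0}.  The root is
#' unique in \eqn{(0, V^+)}.  Note \eqn{w_*} does not depend on
#' \eqn{\delta_1}, \eqn{\kappa} or \eqn{\varepsilon}.
#'
#' @param params a [model_params()] object.
#' @return Named numeric vector \code{c(w_star, p_star)} with
#'   \eqn{p_* = \sqrt{\delta_3}\, w_*}.
#' @examples
#' p <- model_params(0.3, 0.1, 1, 0, 70, 1, 0.01)
#' solve_w_star(p)[["w_star"]]   # exactly 1/2 when delta2 = 0
#' @export
solve_w_star <- function(params) {
  Vpm <- equilibrium_V(params)
  if (is.null(Vpm)) stop("V+ does not exist: no nontrivial tumor state")
  Vp <- Vpm[["V_plus"]]
  g <- function(w) Vp^2 + load_integral(w, params)
  lo <- 1e-12 * Vp
  if (g(lo) >= 0 || g(Vp * (1 - 1e-12)) <= 0)
    stop("no sign change of the matching condition in (0, V+)")
  ws <- stats::uniroot(g, c(lo, Vp * (1 - 1e-12)), tol = 1e-14)$root
  c(w_star = ws, p_star = sqrt(params$delta3) * ws)
}

#' Gap-onset boundary in delta1
#'
#' The value of \eqn{\delta_1} at which the acellular gap first appears,
#' i.e. where the jump level \eqn{w_*} meets the transcritical level
#' \eqn{1/\delta_1}.  Since \eqn{w_*} does not involve \eqn{\delta_1},
#' this is simply \eqn{\delta_1 = 1/w_*}.
#'
#' @param params a [model_params()] object; its \code{delta1} is ignored.
#' @return The critical \eqn{\delta_1} (scalar).
#' @export
gap_boundary_delta1 <- function(params) {
  1 / solve_w_star(params)[["w_star"]]
}

#' Slow orbit segments of the singular front
#'
#' The tails of the singular front on the critical manifolds.  On the
#' tumor-free branches (\code{branch = "M0"}) the relevant orbit is the
#' unstable manifold of the healthy rest state, explicitly
#' \eqn{w^-(\zeta) = w_* e^{\sqrt{\delta_3}\,\zeta}} for \eqn{\zeta \le 0},
#' with \eqn{p = \sqrt{\delta_3}\, w} pointwise.  On the invaded branches
#' (\code{branch = "Mplus"}) the orbit through \eqn{(w_*, \sqrt{\delta_3}
#' w_*)} lies on the level set \eqn{E_+ = 0} and converges to the saddle
#' \eqn{(V^+, 0)}; it is sampled by integrating the reduced equations.
#'
#' @param branch \code{"M0"} or \code{"Mplus"}.
#' @param params a [model_params()] object.
#' @param w_star optional precomputed jump level (from
#'   [solve_w_star()]).
#' @param n number of sample points.
#' @param zeta_max half-range of the slow variable; default reaches within
#'   about \code{1e-7} of the end equilibria.
#' @return A list of class \code{"slow_orbit"}: \code{zeta}, \code{w},
#'   \code{p}, \code{branch}, \code{energy} (the conserved Hamiltonian
#'   value, 0 on both relevant orbits).
#' @export
slow_orbit <- function(branch, params, w_star = NULL, n = 400,
                       zeta_max = NULL) {
  branch <- match.arg(branch, c("M0", "Mplus"))
  if (is.null(w_star)) w_star <- solve_w_star(params)[["w_star"]]
  sd3 <- sqrt(params$delta3)
  if (is.null(zeta_max)) zeta_max <- 16 / sd3
  if (branch == "M0") {
    # geometric refinement toward zeta = 0
    zeta <- -zeta_max * (seq(1, 0, length.out = n))^2
    w <- w_star * exp(sd3 * zeta)
    p <- sd3 * w
    orb <- list(zeta = zeta, w = w, p = p, branch = branch, energy = 0)
  } else {
    Vp <- equilibrium_V(params)[["V_plus"]]
    rhs <- function(zeta, y, parms) {
      # clamp trial steps onto the validity range of v+(w)
      wc <- min(max(y[1], 0), fold_w(params))
      vpw <- v_branch(wc, params)$v_plus
      list(c(y[2], -params$delta3 * (vpw - y[1])))
    }
    # stop at the saddle: integrating past it amplifies roundoff at the
    # saddle's exponential rate and the tail wanders off the manifold.
    # Two stopping events: w within 1e-6 of V+ or the slope p collapsing.
    rootf <- function(zeta, y, parms)
      c((Vp - y[1]) - 1e-6 * Vp, y[2] - 1e-9 * sd3 * w_star)
    zeta <- zeta_max * (seq(0, 1, length.out = n))^2
    sol <- deSolve::lsodar(c(w = w_star, p = sd3 * w_star), zeta, rhs,
                           NULL, rootfunc = rootf,
                           rtol = 1e-11, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0)
      stop("slow-orbit integration failed at zeta = ",
           max(sol[, 1]))
    w <- stats::approx(sol[, 1], sol[, 2], xout = zeta, rule = 2)$y
    p <- stats::approx(sol[, 1], sol[, 3], xout = zeta, rule = 2)$y
    done <- zeta >= max(sol[, 1])
    w[done] <- Vp
    p[done] <- 0
    orb <- list(zeta = zeta, w = pmin(pmax(w, 0), Vp), p = pmax(p, 0),
                branch = branch, energy = 0)
  }
  class(orb) <- "slow_orbit"
  orb
}

#' Construct the singular (eps -> 0) heteroclinic front
#'
#' Concatenates slow orbit segments and the fast layer jump into the
#' regime-appropriate singular front: benign fronts jump inside the
#' coexistence subspace \eqn{u = 1-\delta_1 w} and have three segments;
#' malignant no-gap fronts add a slow passage through the transcritical
#' level \eqn{w = 1/\delta_1} behind the interface; malignant gap fronts
#' traverse the transcritical level ahead of the jump, opening an
#' acellular stretch on \eqn{u = v = 0} whose slow-scale width is
#' \eqn{\ln(\delta_1 w_*)/\sqrt{\delta_3}}.  The singular speed is
#' \eqn{c_1(w_*)} (no-gap/benign) or \eqn{c_0(w_*)} (gap).
#'
#' @param params a [model_params()] object.
#' @return Object of class \code{"singular_front"}: list with
#'   \code{regime}, \code{w_star}, \code{p_star}, \code{c_star},
#'   \code{layer} (a [layer_front()]), \code{segments} (data frame of
#'   segment kinds and w-ranges), \code{gap_width_zeta}, \code{params}.
#' @examples
#' sf <- singular_front(load_preset("fig1")$params)
#' sf$c_star
#' @export
singular_front <- function(params) {
  reg <- classify_regime(params)
  if (reg$kind == "no_front")
    stop("no nontrivial tumor state: singular front does not exist")
  ws <- reg$w_star
  ps <- sqrt(params$delta3) * ws
  d1 <- params$delta1
  wtc <- 1 / d1
  degenerate <- reg$kind == "degenerate_crossover"
  gap <- reg$kind == "malignant_gap"
  jump_branch <- if (gap) 0 else 1
  layer <- if (degenerate) layer_front(ws * (1 - 1e-9), 1, params)
           else layer_front(ws, jump_branch, params)
  segs <- if (reg$kind == "benign") {
    data.frame(kind = c("slow_M0_1", "jump", "slow_Mplus_1"),
               w_from = c(0, ws, ws), w_to = c(ws, ws, NA))
  } else if (gap) {
    data.frame(kind = c("slow_M0_1", "slow_M0_0", "jump", "slow_Mplus_0"),
               w_from = c(0, wtc, ws, ws), w_to = c(wtc, ws, ws, NA))
  } else {  # malignant no-gap (and degenerate crossover, flagged)
    data.frame(kind = c("slow_M0_1", "jump", "slow_Mplus_1", "slow_Mplus_0"),
               w_from = c(0, ws, ws, wtc), w_to = c(ws, ws, wtc, NA))
  }
  Vp <- equilibrium_V(params)[["V_plus"]]
  segs$w_to[nrow(segs)] <- Vp
  structure(list(regime = reg, w_star = ws, p_star = ps,
                 c_star = layer$speed, layer = layer, segments = segs,
                 gap_width_zeta = if (gap) log(d1 * ws) / sqrt(params$delta3)
                                  else 0,
                 degenerate = degenerate, V_plus = Vp, params = params),
            class = "singular_front")
}

#' @export
print.singular_front <- function(x, ...) {
  cat("Singular front (eps -> 0):", x$regime$kind, "\n")
  cat(sprintf("  w* = %.8g, p* = %.8g, c* = %.8g\n",
              x$w_star, x$p_star, x$c_star))
  if (x$gap_width_zeta > 0)
    cat(sprintf("  acellular gap width (slow variable zeta): %.8g\n",
                x$gap_width_zeta))
  cat("  segments:", paste(x$segments$kind, collapse = " -> "), "\n")
  if (x$degenerate)
    cat("  NOTE: degenerate crossover (jump at the transcritical level);\n",
        "  persistence for eps > 0 not guaranteed\n")
  invisible(x)
}

#' Sample the concatenated singular profile on a slow grid
#'
#' Evaluates the singular front's (u, v, w, p) as functions of the slow
#' coordinate \eqn{\zeta} (layer jump collapsed to \eqn{\zeta = 0}).
#' Used for initial guesses and plotting.
#'
#' @param sf a [singular_front()] object.
#' @param zeta numeric grid (jump sits at 0).
#' @return Data frame with columns zeta, u, v, w, p, segment.
#' @export
sample_singular_profile <- function(sf, zeta) {
  params <- sf$params
  sd3 <- sqrt(params$delta3)
  gap <- sf$regime$kind == "malignant_gap"
  left <- zeta <= 0
  w <- numeric(length(zeta)); p <- numeric(length(zeta))
  w[left] <- sf$w_star * exp(sd3 * zeta[left])
  p[left] <- sd3 * w[left]
  if (any(!left)) {
    orb <- slow_orbit("Mplus", params, sf$w_star,
                      zeta_max = max(zeta[!left], 1))
    w[!left] <- stats::approx(orb$zeta, orb$w, xout = zeta[!left],
                              rule = 2)$y
    p[!left] <- stats::approx(orb$zeta, orb$p, xout = zeta[!left],
                              rule = 2)$y
  }
  u <- pmax(1 - params$delta1 * w, 0)
  if (gap) u[!left] <- 0          # behind the jump the tissue is gone
  v <- ifelse(left, 0, v_branch(pmin(w, fold_w(params)), params)$v_plus)
  seg <- ifelse(left,
                ifelse(w < 1 / params$delta1, "slow_M0_1", "slow_M0_0"),
                ifelse(u > 0, "slow_Mplus_1", "slow_Mplus_0"))
  data.frame(zeta = zeta, u = u, v = v, w = w, p = p, segment = seg)
}
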