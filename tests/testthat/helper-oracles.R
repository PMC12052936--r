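# Independent numerical oracles used by the tests.  These deliberately
# avoid the package's closed forms: the layer speed is recomputed by
# shooting on the planar layer ODE, equilibrium densities by direct
# root-finding of the growth balance, and the matching level by
# quadrature + bisection.

# Heteroclinic speed of the planar layer ODE D v'' - c v' + g(v) = 0 by
# bisection on the shooting outcome: the unstable-manifold trajectory of
# the origin either falls back (z = 0 before reaching v+; c too small) or
# passes over the saddle at v+ (c too large).
oracle_layer_speed <- function(w, branch, params, iters = 55) {
  D <- if (branch == 1) params$kappa + params$delta1 * w else
    1 + params$kappa
  disc <- (1 - params$a)^2 - 4 * params$delta2 * w / params$rho
  vp <- (1 + params$a + sqrt(disc)) / 2
  g <- function(v) params$rho * v * (1 - v) * (v - params$a) -
    params$delta2 * v * w
  gp0 <- -params$rho * params$a - params$delta2 * w
  b <- (vp / 2) * sqrt(params$rho / (2 * D))
  classify <- function(cc) {
    mu <- (cc + sqrt(cc^2 - 4 * D * gp0)) / (2 * D)
    d0 <- 1e-8 * vp
    rhs <- function(t, y, p) list(c(y[2], (cc * y[2] - g(y[1])) / D))
    root <- function(t, y, p) c(y[2], y[1] - vp)
    sol <- deSolve::lsodar(c(v = d0, z = mu * d0),
                           c(0, 80 * (1 / mu + 1 / b)), rhs, NULL,
                           rootfunc = root, rtol = 1e-11, atol = 1e-13)
    yf <- sol[nrow(sol), ]
    if (yf[["v"]] >= vp - 1e-9) "over" else "under"
  }
  lo <- 0
  hi <- 2 * sqrt(2 * D * params$rho) * vp
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (classify(mid) == "over") hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Nontrivial equilibrium tumor densities by direct root-finding of
# rho (1 - V)(V - a) = delta2 V on bracketing intervals.
oracle_equilibrium_V <- function(a, rho, delta2) {
  f <- function(V) rho * (1 - V) * (V - a) - delta2 * V
  mid <- (1 + a) / 2 - delta2 / (2 * rho)
  if (f(mid) <= 0) return(NULL)
  c(V_plus = uniroot(f, c(mid, 1), tol = 1e-14)$root,
    V_minus = uniroot(f, c(0, mid), tol = 1e-14)$root)
}

# Matching level w* by adaptive quadrature of the load integrand plus
# bisection (independent of the closed-form antiderivative).
oracle_w_star <- function(params) {
  Vp <- oracle_equilibrium_V(params$a, params$rho, params$delta2)[["V_plus"]]
  integrand <- function(z)
    1 + params$a + sqrt(pmax((1 - params$a)^2 -
                               4 * params$delta2 * z / params$rho, 0))
  g <- function(w)
    Vp^2 + integrate(integrand, Vp, w, rel.tol = 1e-12)$value
  uniroot(g, c(1e-10, Vp - 1e-12), tol = 1e-13)$root
}

# Random parameter set with existing nontrivial equilibria.
random_params <- function() {
  repeat {
    a <- runif(1, 0.05, 0.45)
    rho <- runif(1, 0.5, 5)
    delta2 <- runif(1, 0, 0.3 * rho)
    if ((rho * (1 + a) - delta2)^2 - 4 * rho^2 * a > 0.01) break
  }
  suppressWarnings(model_params(a = a, kappa = runif(1, 0.05, 0.3),
                                delta1 = runif(1, 0.3, 12),
                                delta2 = delta2,
                                delta3 = runif(1, 5, 100),
                                rho = rho, eps = 0.01))
}
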