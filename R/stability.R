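# Spectral stability of the planar front: discretized linearization about
# a computed traveling wave, longitudinal spectrum near 0, adjoint null
# solution, transverse long-wavelength coefficient lambda_c2 (solvability
# quotient) and its singular-limit asymptotics.

# Analytic profile derivatives from the traveling-wave ODE right-hand
# sides (avoids differencing noise on the graded mesh).
front_derivatives <- function(front) {
  params <- front$params
  Y <- front$Y
  cc <- front$c
  f <- tw_rhs(Y, cc, params)
  u <- Y[, 1]; v <- Y[, 2]; q <- Y[, 3]; w <- Y[, 4]
  D <- 1 + params$kappa - u
  du <- f[, 1]; dv <- f[, 2]; dq <- f[, 3]; dw <- f[, 4]
  dvv <- (dq + cc * dv) / D + (q + cc * v) * du / D^2
  list(du = du, dv = dv, dw = dw, dvv = dvv)
}

# Finite-difference weights on arbitrary nodes (Fornberg's recursion):
# weights of derivatives 0..m at x0 from the nodes xs.
fornberg_weights <- function(x0, xs, m) {
  n <- length(xs)
  C <- array(0, c(n, m + 1))
  c1 <- 1
  c4 <- xs[1] - x0
  C[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i - 1, m)
    c2 <- 1
    c5 <- c4
    c4 <- xs[i] - x0
    for (j in 1:(i - 1)) {
      c3 <- xs[i] - xs[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        for (k in mn:1)
          C[i, k + 1] <- c1 * (k * C[i - 1, k] - c5 * C[i - 1, k + 1]) / c2
        C[i, 1] <- -c1 * c5 * C[i - 1, 1] / c2
      }
      for (k in mn:1)
        C[j, k + 1] <- (c4 * C[j, k + 1] - k * C[j, k]) / c3
      C[j, 1] <- c4 * C[j, 1] / c3
    }
    c1 <- c2
  }
  C
}

# Sparse first/second-derivative matrices from 5-point Fornberg stencils
# (4th/3rd order accurate even on graded meshes); homogeneous Dirichlet
# behavior outside the domain is obtained by dropping boundary columns
# when the operator is restricted to interior nodes.
fd_matrices <- function(xi, stencil = 5) {
  N <- length(xi)
  half <- (stencil - 1) %/% 2
  ii <- jj <- x1 <- x2 <- vector("list", N - 2)
  for (i in 2:(N - 1)) {
    lo <- max(1, min(i - half, N - stencil + 1))
    js <- lo:(lo + stencil - 1)
    Wm <- fornberg_weights(xi[i], xi[js], 2)
    ii[[i - 1]] <- rep(i, stencil)
    jj[[i - 1]] <- js
    x1[[i - 1]] <- Wm[, 2]
    x2[[i - 1]] <- Wm[, 3]
  }
  iv <- unlist(ii); jv <- unlist(jj)
  D1 <- Matrix::sparseMatrix(i = iv, j = jv, x = unlist(x1),
                             dims = c(N, N))
  D2 <- Matrix::sparseMatrix(i = iv, j = jv, x = unlist(x2),
                             dims = c(N, N))
  list(D1 = D1, D2 = D2)
}

#' Assemble the discretized front linearization
#'
#' Builds the sparse finite-difference representation of the linearized
#' operator about a traveling front at transverse wavenumber \eqn{\ell},
#' acting on perturbations \eqn{(u, v, w)e^{i\ell y + \lambda\tau}}.  The
#' \eqn{v}-row carries the nonlinear-diffusion couplings
#' \eqn{-v_{h,\xi\xi} u - v_{h,\xi} u_\xi} and the drift
#' \eqn{-u_{h,\xi} v_\xi}; the transverse terms are
#' \eqn{-\ell^2(1+\kappa-u_h) v} and \eqn{-\ell^2 w/\varepsilon^2}.
#' Homogeneous Dirichlet conditions are imposed at the (far) domain ends.
#'
#' @param front a converged [solve_front()] object.
#' @param ell transverse wavenumber (only \eqn{|\ell|} matters; the
#'   spectrum is even in \eqn{\ell}).
#' @return A list of class \code{"linearized_operator"}: sparse matrix
#'   \code{A} (size \eqn{3(N-2)}), the interior mesh, quadrature weights,
#'   the front-derivative null direction, and the coefficient fields.
#' @export
assemble_linearization <- function(front, ell = 0) {
  ell <- abs(ell)
  params <- front$params
  xi <- front$xi
  N <- length(xi)
  ii <- 2:(N - 1)
  der <- front_derivatives(front)
  fd <- fd_matrices(xi)
  u <- front$Y[, 1]; v <- front$Y[, 2]; w <- front$Y[, 4]
  a <- params$a
  Fu <- 1 - 2 * u - params$delta1 * w
  Fw <- -params$delta1 * u
  Gv <- params$rho * (-3 * v^2 + 2 * (1 + a) * v - a) - params$delta2 * w
  Gw <- -params$delta2 * v
  Hv <- rep(params$delta3, N)
  Hw <- rep(-params$delta3, N)
  Dv <- 1 + params$kappa - u
  cc <- front$c
  Dg <- function(vals) Matrix::Diagonal(N, vals)
  D1 <- fd$D1; D2 <- fd$D2
  Auu <- -cc * D1 + Dg(Fu)
  Auw <- Dg(Fw)
  Avu <- Dg(-der$dvv) - Dg(der$dv) %*% D1
  Avv <- Dg(Dv) %*% D2 - cc * D1 + Dg(Gv) - Dg(der$du) %*% D1 -
    ell^2 * Dg(Dv)
  Avw <- Dg(Gw)
  Awv <- Dg(Hv)
  Aww <- (1 / params$eps^2) * D2 - cc * D1 + Dg(Hw) -
    Matrix::Diagonal(N, ell^2 / params$eps^2)
  A <- rbind(cbind(Auu[ii, ii], Matrix::Matrix(0, N - 2, N - 2,
                                               sparse = TRUE), Auw[ii, ii]),
             cbind(Avu[ii, ii], Avv[ii, ii], Avw[ii, ii]),
             cbind(Matrix::Matrix(0, N - 2, N - 2, sparse = TRUE),
                   Awv[ii, ii], Aww[ii, ii]))
  wts <- trapezoid_weights(xi)[ii]
  structure(list(A = methods::as(A, "CsparseMatrix"), ell = ell,
                 xi = xi[ii], weights = wts, params = params,
                 front = front,
                 translation = c(der$du[ii], der$dv[ii], der$dw[ii]),
                 fields = list(Fu = Fu[ii], Fw = Fw[ii], Gv = Gv[ii],
                               Gw = Gw[ii], Hv = Hv[ii], Hw = Hw[ii],
                               Dv = Dv[ii]),
                 derivs = lapply(der, function(z) z[ii])),
            class = "linearized_operator")
}

trapezoid_weights <- function(xi) {
  N <- length(xi)
  h <- diff(xi)
  wt <- numeric(N)
  wt[1] <- h[1] / 2
  wt[N] <- h[N - 1] / 2
  wt[2:(N - 1)] <- (h[-1] + h[-(N - 1)]) / 2
  wt
}

# Shift-invert eigensolve of a sparse real matrix: eigenvalues of A
# nearest `shift`.  ARPACK (via igraph) on the inverse map, with retries
# on ARPACK's occasional conjugate-pair truncation / iteration failures;
# dense solve for small problems and a deterministic block inverse
# subspace iteration as the final fallback.
shift_invert_eigs <- function(A, shift, nev = 24, dense_limit = 1500) {
  n <- nrow(A)
  if (n <= dense_limit) {
    ev <- eigen(as.matrix(A))
    ord <- order(Mod(ev$values - shift))
    sel <- ord[seq_len(min(nev, n))]
    return(list(values = ev$values[sel], vectors = ev$vectors[, sel,
                                                              drop = FALSE]))
  }
  M <- A - shift * Matrix::Diagonal(n)
  lu <- Matrix::lu(M)
  fn <- function(x, extra) as.vector(Matrix::solve(lu, x))
  for (bump in 0:3) {
    # a warned (partially converged) ARPACK run counts as a failed attempt
    res <- tryCatch(
      withCallingHandlers(
        igraph::arpack(fn, sym = FALSE,
                       options = list(n = n, nev = nev + bump,
                                      ncv = min(n, max(6 * (nev + bump), 60) +
                                                  20 * bump),
                                      which = "LM", maxiter = 5000)),
        warning = function(w) stop("arpack warning: ",
                                   conditionMessage(w))),
      error = function(e) NULL)
    if (!is.null(res)) {
      mu <- res$values
      vec <- res$vectors
      if (is.null(dim(vec))) vec <- matrix(vec, ncol = 1)
      keep <- seq_len(min(nev, length(mu)))
      return(list(values = (shift + 1 / mu)[keep],
                  vectors = vec[, keep, drop = FALSE]))
    }
  }
  # fallback: block inverse subspace iteration with Rayleigh-Ritz
  k <- min(nev + 4, n)
  X <- qr.Q(qr(matrix(sin(outer(seq_len(n) / n, seq_len(k) * 2.3)), n, k)))
  lam_old <- rep(Inf, k)
  for (it in 1:300) {
    X <- apply(X, 2, function(col) as.vector(Matrix::solve(lu, col)))
    X <- qr.Q(qr(X))
    T <- crossprod(X, as.matrix(A %*% X))
    ev <- eigen(T)
    if (max(Mod(ev$values - lam_old)) < 1e-10 * max(1, Mod(ev$values[1])))
      break
    lam_old <- ev$values
  }
  ord <- order(Mod(ev$values - shift))[seq_len(min(nev, k))]
  list(values = ev$values[ord],
       vectors = X %*% ev$vectors[, ord, drop = FALSE])
}

#' Longitudinal / transverse point spectrum near a shift
#'
#' Eigenvalues of the discretized linearization closest to \code{shift}
#' (default 0), sorted by descending real part.  The translational
#' eigenvalue is flagged by correlating eigenvectors with the front
#' derivative.
#'
#' @param front a converged [solve_front()] object.
#' @param ell transverse wavenumber.
#' @param count number of eigenvalues requested.
#' @param shift center of the spectral window.
#' @param op optional pre-assembled [assemble_linearization()] result.
#' @return Object of class \code{"spectral_report"}: data frame
#'   \code{eigenvalues} (re, im, is_translational), the eigenvectors, and
#'   metadata.
#' @export
spectrum <- function(front, ell = 0, count = 24, shift = 0, op = NULL) {
  if (is.null(op)) op <- assemble_linearization(front, ell)
  eg <- shift_invert_eigs(op$A, shift, nev = count)
  phi0 <- op$translation / sqrt(sum(op$translation^2))
  corr <- apply(eg$vectors, 2, function(z) {
    zr <- Re(z); zi <- Im(z)
    nz <- sqrt(sum(zr^2) + sum(zi^2))
    sqrt(sum((phi0 %*% zr)^2 + (phi0 %*% zi)^2)) / nz
  })
  ord <- order(-Re(eg$values))
  df <- data.frame(re = Re(eg$values)[ord], im = Im(eg$values)[ord],
                   translation_corr = corr[ord],
                   is_translational = (corr > 0.99)[ord])
  structure(list(eigenvalues = df, vectors = eg$vectors[, ord, drop = FALSE],
                 ell = ell, shift = shift, op = op),
            class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat(sprintf("Point spectrum near %g at ell = %g:\n", x$shift, x$ell))
  print(utils::head(x$eigenvalues, 10), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Bounded null solution of the adjoint linearization
#'
#' Computes the (unique up to scale) null vector of the adjoint of the
#' discretized front linearization at \eqn{\ell = 0} by shifted inverse
#' iteration on the transpose (discretize-then-transpose, so discrete
#' Fredholm orthogonality is exact).  The returned fields divide out the
#' trapezoid quadrature weights so that they approximate the continuum
#' adjoint solution in \eqn{L^2}.
#'
#' @param front a converged [solve_front()] object.
#' @param op optional pre-assembled \eqn{\ell = 0} linearization.
#' @param tol residual tolerance (scaled) for the inverse iteration.
#' @return Object of class \code{"adjoint_solution"}: vectors \code{u_A},
#'   \code{v_A}, \code{w_A} on the interior mesh, the raw discrete null
#'   vector \code{y}, the operator used, and the achieved residual.
#' @export
adjoint_null <- function(front, op = NULL, tol = 1e-8) {
  if (is.null(op)) op <- assemble_linearization(front, 0)
  At <- Matrix::t(op$A)
  n <- nrow(At)
  sigma <- 1e-8
  M <- At - sigma * Matrix::Diagonal(n)
  lu <- Matrix::lu(M)
  x <- rep(1, n)
  x <- x / sqrt(sum(x^2))
  lam <- NA_real_
  for (i in 1:50) {
    x2 <- as.vector(Matrix::solve(lu, x))
    x2 <- x2 / sqrt(sum(x2^2))
    lam <- as.numeric(crossprod(x2, as.vector(At %*% x2)))
    res <- sqrt(sum((as.vector(At %*% x2) - lam * x2)^2))
    x <- x2
    if (res < tol * max(1, abs(lam))) break
  }
  scl <- sqrt(sum(as.vector(op$A %*% rnorm(n))^2) / n)  # operator scale
  N <- length(op$xi)
  wts <- op$weights
  y <- x
  ua <- y[1:N] / wts
  va <- y[N + (1:N)] / wts
  wa <- y[2 * N + (1:N)] / wts
  # fix an overall sign: make the v-component positively correlated with
  # the fast reduced adjoint prediction v_h' * exp(-c xi / D)
  s <- sum(va * op$derivs$dv)
  if (s < 0) { ua <- -ua; va <- -va; wa <- -wa; y <- -y }
  structure(list(u_A = ua, v_A = va, w_A = wa, y = y, xi = op$xi,
                 weights = wts, eig_residual = res, eig_value = lam,
                 op = op),
            class = "adjoint_solution")
}

#' Transverse long-wavelength coefficient (solvability quotient)
#'
#' The curvature \eqn{\lambda_{c,2}} of the critical eigenvalue curve
#' \eqn{\lambda_c(\ell) = \lambda_{c,2}\ell^2 + O(\ell^4)} at \eqn{\ell=0},
#' from the Fredholm solvability condition:
#' \deqn{\lambda_{c,2} = - \frac{\int (1+\kappa-u_h) v_{h,\xi} v^A +
#'   \varepsilon^{-2} w_{h,\xi} w^A \, d\xi}
#'   {\int u_{h,\xi} u^A + v_{h,\xi} v^A + w_{h,\xi} w^A \, d\xi}.}
#' Positive \eqn{\lambda_{c,2}} means the planar interface is unstable to
#' long-wavelength transverse perturbations.
#'
#' @param front a converged [solve_front()] object.
#' @param adj optional precomputed [adjoint_null()].
#' @return The coefficient (scalar, units 1/time per squared wavenumber).
#'   Attribute \code{"eps_scaled"} carries \eqn{\varepsilon\lambda_{c,2}},
#'   convenient because the coefficient grows like \eqn{1/\varepsilon}.
#' @export
lambda_c2 <- function(front, adj = NULL) {
  if (is.null(adj)) adj <- adjoint_null(front)
  op <- adj$op
  wts <- op$weights
  e <- op$params$eps
  der <- op$derivs
  num <- sum(wts * (op$fields$Dv * der$dv * adj$v_A +
                      (1 / e^2) * der$dw * adj$w_A))
  den <- sum(wts * (der$du * adj$u_A + der$dv * adj$v_A +
                      der$dw * adj$w_A))
  if (abs(den) < 1e-12)
    stop("solvability denominator vanishes: quotient ill-posed")
  out <- -num / den
  attr(out, "eps_scaled") <- e * out
  out
}

#' Track the critical eigenvalue curve lambda_c(ell)
#'
#' Follows the eigenvalue branch emanating from the translational zero at
#' \eqn{\ell = 0} by shifted inverse iteration at each wavenumber, seeded
#' with the previous eigenpair.  \eqn{\lambda_c(0) = 0} is included as a
#' datum; the curve is even in \eqn{\ell} so only \eqn{\ell \ge 0} is
#' computed.
#'
#' @param front a converged [solve_front()] object.
#' @param ell_max largest wavenumber; default a few multiples of
#'   \eqn{\varepsilon} (the width of the quadratic regime).
#' @param n_points number of samples (excluding \eqn{\ell = 0}).
#' @param ells explicit nonzero wavenumbers to evaluate (overrides
#'   \code{ell_max}/\code{n_points}); useful for matching a simulation's
#'   discrete transverse modes.
#' @param op0 optional pre-assembled \eqn{\ell = 0} operator.
#' @return Object of class \code{"lambda_curve"}: data frame with columns
#'   \code{ell}, \code{lambda}, and the fitted quadratic coefficient (see
#'   [fit_lambda2()]).
#' @export
lambda_curve <- function(front, ell_max = NULL, n_points = 12, ells = NULL,
                         op0 = NULL) {
  if (is.null(op0)) op0 <- assemble_linearization(front, 0)
  lam2 <- lambda_c2(front, adjoint_null(front, op = op0))
  e <- front$params$eps
  if (is.null(ell_max)) {
    # heuristic: the quadratic regime holds for ell = O(eps); step a few
    # multiples beyond to see the turnaround
    ell_max <- 4 * e
  }
  if (is.null(ells)) ells <- seq(0, ell_max, length.out = n_points + 1)[-1]
  ells <- sort(ells[ells > 0])
  n <- nrow(op0$A)
  x <- op0$translation
  x <- x / sqrt(sum(x^2))
  # the discrete translational eigenvalue sits at 0 only up to truncation
  # error; measure it and use it as the lambda_c(0) = 0 datum
  eg0 <- shift_invert_eigs(op0$A, 1e-9, nev = 4)
  i0 <- which.min(Mod(eg0$values))
  lam0 <- Re(eg0$values[i0])
  x <- Re(eg0$vectors[, i0])
  x <- x / sqrt(sum(x^2))
  lam_prev <- lam0
  out <- data.frame(ell = 0, lambda = 0, lambda_raw = lam0)
  Dpen <- transverse_penalty(op0)
  for (ell in ells) {
    A <- op0$A - ell^2 * Dpen
    ell_prev <- out$ell[nrow(out)]
    sigma <- lam_prev + as.numeric(lam2) * (ell^2 - ell_prev^2) + 1e-10
    lam <- NA_real_
    for (k in 1:8) {
      M <- A - sigma * Matrix::Diagonal(n)
      x2 <- tryCatch(as.vector(Matrix::solve(M, x)),
                     error = function(e) NULL)
      if (is.null(x2)) { sigma <- sigma * (1 + 1e-6) + 1e-9; next }
      x2 <- x2 / sqrt(sum(x2^2))
      lam <- as.numeric(crossprod(x2, as.vector(A %*% x2)))
      conv <- sqrt(sum((as.vector(A %*% x2) - lam * x2)^2))
      x <- x2
      if (conv < 1e-9 * max(1, abs(lam))) break
      sigma <- lam
    }
    out <- rbind(out, data.frame(ell = ell, lambda = lam - lam0,
                                 lambda_raw = lam))
    lam_prev <- lam
  }
  structure(list(curve = out, lambda_c2 = as.numeric(lam2),
                 fit = fit_lambda2(out)),
            class = "lambda_curve")
}

# diagonal matrix of the ell^2 penalty (same for every ell)
transverse_penalty <- function(op) {
  N <- length(op$xi)
  Matrix::Diagonal(3 * N, c(rep(0, N), op$fields$Dv,
                            rep(1 / op$params$eps^2, N)))
}

#' Quadratic fit of the critical curve near ell = 0
#'
#' Least-squares fit \eqn{\lambda = \lambda_2 \ell^2 + \lambda_4 \ell^4}
#' through the origin over the smallest sampled wavenumbers.
#'
#' @param curve data frame with columns \code{ell}, \code{lambda}.
#' @param n_use number of smallest nonzero wavenumbers to fit.
#' @return List with \code{lambda2}, \code{lambda4}, \code{r_squared}.
#' @export
fit_lambda2 <- function(curve, n_use = 6) {
  cv <- curve[curve$ell > 0, ]
  cv <- cv[order(cv$ell), ][seq_len(min(n_use, nrow(cv))), ]
  fit <- stats::lm(lambda ~ 0 + I(ell^2) + I(ell^4), data = cv)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum(cv$lambda^2)
  list(lambda2 = unname(stats::coef(fit)[1]),
       lambda4 = unname(stats::coef(fit)[2]),
       r_squared = 1 - ss_res / ss_tot)
}

#' @export
print.lambda_curve <- function(x, ...) {
  cat(sprintf(
    "Critical curve lambda_c(ell): lambda_c2 = %.6g (quotient), %.6g (fit)\n",
    x$lambda_c2, x$fit$lambda2))
  print(x$curve, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Singular-limit asymptotics of the transverse coefficient
#'
#' Leading-order evaluation of \eqn{\lambda_{c,2}} from the closed-form
#' layer profile and the slow Hamiltonian orbits:
#' \deqn{\lambda_{c,2} \sim \frac{1}{\varepsilon \delta_3 v_*^+}
#'  \frac{\int_{-\infty}^0 (w^-_\zeta)^2 d\zeta +
#'        \int_0^\infty (w^+_\zeta)^2 d\zeta}
#'       {\int v_{*,\xi}^2 e^{-c_*\xi/(1+\kappa-u_*)} d\xi}
#'  \int \big(\delta_1 u_* \bar u_* + \delta_2 v_* \bar v_*\big) d\xi,}
#' with \eqn{\bar v_* = v_{*,\xi} e^{-c_*\xi/(1+\kappa-u_*)}} the fast
#' reduced adjoint and \eqn{\bar u_*} its induced normal-cell response.
#' The sign of the last factor alone decides stability at leading order:
#' in the gap case (\eqn{u_* = 0}) it is positive whenever
#' \eqn{\delta_2 > 0}, so gap interfaces are always long-wavelength
#' unstable for small \eqn{\varepsilon}.
#'
#' @param params a [model_params()] object.
#' @return List of class \code{"lambda2_asymptotic"}: \code{value}
#'   (leading-order \eqn{\lambda_{c,2}}), \code{sign} (of the criterion
#'   integral), \code{criterion_integral}, \code{slow_integrals},
#'   \code{fast_denominator}, \code{regime}.
#' @export
lambda_c2_asymptotic <- function(params) {
  sf <- singular_front(params)
  if (sf$degenerate)
    stop("degenerate crossover: leading-order asymptotics not valid")
  lay <- sf$layer
  cs <- sf$c_star
  Du <- 1 + params$kappa - lay$u_star      # 1 + kappa - u_*
  b <- lay$rate
  vp <- lay$v_plus
  # fast quadratures on the closed-form tanh layer.  The integrands pair
  # decaying sech powers with the growing weight e^{-c xi/Du}; evaluate in
  # log space (overflow-safe) and truncate where the combined exponent has
  # dropped by 60.
  logcosh <- function(x) ifelse(abs(x) > 25, abs(x) - log(2), log(cosh(x)))
  vxi <- function(xi) lay$dv_of_xi(xi)
  gam <- cs / Du
  if (4 * b <= gam)
    stop("fast adjoint not integrable: layer decay too slow vs c/(1+kappa-u*)")
  xl <- -60 / (4 * b - gam); xr <- 60 / (4 * b + gam)
  # v_xi^2 e^{-gam xi} = (vp b / 2)^2 exp(-4 logcosh(b xi) - gam xi)
  den <- stats::integrate(function(x)
    (vp * b / 2)^2 * exp(-4 * logcosh(b * x) - gam * x),
    xl, xr, rel.tol = 1e-10)$value
  # v v_xi e^{-gam xi}; v = (vp/2)(1 + tanh(b xi))
  crit_v <- params$delta2 *
    stats::integrate(function(x)
      (vp / 2) * (1 + tanh(b * x)) * (vp * b / 2) *
        exp(-2 * logcosh(b * x) - gam * x),
      xl, xr, rel.tol = 1e-10)$value
  crit_u <- 0
  if (lay$u_star > 0) {
    Fu <- 1 - 2 * lay$u_star - params$delta1 * sf$w_star  # < 0
    # v_xi(s) * d/ds[v_xi e^{-gam s}] in one overflow-safe expression
    pair <- function(s, x0)
      (vp * b / 2)^2 * (-2 * b * tanh(b * s) - gam) *
        exp((Fu / cs) * (s - x0) - 4 * logcosh(b * s) - gam * s)
    ubar <- function(x0)
      (1 / cs) * stats::integrate(pair, x0,
        min(xr + 10 / b, x0 + 200 / max(-Fu / cs, 2 * b)),
        x0 = x0, rel.tol = 1e-9, abs.tol = 1e-13)$value
    crit_u <- params$delta1 * lay$u_star *
      stats::integrate(function(x) vapply(x, ubar, 0), xl, xr,
                       rel.tol = 1e-7)$value
  }
  crit <- crit_u + crit_v
  # slow integrals of (w_zeta)^2 along the concatenated slow path
  sd3 <- sqrt(params$delta3)
  I_left <- sd3 * sf$w_star^2 / 2          # exponential branch(es) on M0
  Vp <- sf$V_plus
  p_of_w <- function(w) {
    val <- 2 * (params$delta3 * w^2 / 2 - params$delta3 * Vp^2 / 2 -
                  params$delta3 * load_half(w, params))
    sqrt(pmax(val, 0))
  }
  I_right <- stats::integrate(p_of_w, sf$w_star, Vp,
                              rel.tol = 1e-10)$value
  value <- (1 / (params$eps * params$delta3 * vp)) *
    ((I_left + I_right) / den) * crit
  structure(list(value = value, sign = sign(crit),
                 criterion_integral = crit,
                 criterion_parts = c(u = crit_u, v = crit_v),
                 slow_integrals = c(left = I_left, right = I_right),
                 fast_denominator = den,
                 regime = sf$regime$kind, w_star = sf$w_star,
                 c_star = cs),
            class = "lambda2_asymptotic")
}

#' @export
print.lambda2_asymptotic <- function(x, ...) {
  cat(sprintf(
    "Leading-order lambda_c2 = %.6g (sign %+d) in regime %s\n",
    x$value, x$sign, x$regime))
  invisible(x)
}

#' Transverse stability boundary in the (delta1, delta2) plane
#'
#' Evaluates the sign of \eqn{\lambda_{c,2}} on a grid over
#' \eqn{(\delta_1, \delta_2)} and locates the zero contour by bisection in
#' \eqn{\delta_2} at each \eqn{\delta_1}.  The benign/malignant boundary
#' \eqn{\delta_1 V^+ = 1} is returned alongside for overlay.
#'
#' @param params base [model_params()] (its delta1/delta2 are ignored).
#' @param delta1 grid of acid-toxicity values.
#' @param delta2 grid of tumor self-toxicity values.
#' @param method \code{"numeric"} (solve the front and evaluate the
#'   solvability quotient at the set \code{eps}) or \code{"asymptotic"}
#'   (leading-order formula; sign is \eqn{\varepsilon}-independent).
#' @param bisection_iter bisection refinements of the contour per column.
#' @return List of class \code{"stability_boundary"}: \code{grid} (data
#'   frame delta1, delta2, lambda_c2, regime), \code{contour} (data frame
#'   delta1, delta2_boundary), \code{benign_boundary} (delta1 where
#'   \eqn{\delta_1 V^+ = 1} along the delta2 grid).
#' @export
stability_boundary <- function(params, delta1, delta2,
                               method = c("numeric", "asymptotic"),
                               bisection_iter = 0) {
  method <- match.arg(method)
  eval_l2 <- function(d1, d2) {
    p <- suppressWarnings(update_params(params, delta1 = d1, delta2 = d2))
    tryCatch(
      withCallingHandlers({
        if (method == "asymptotic") {
          la <- lambda_c2_asymptotic(p)
          c(la$value, NA_real_)
        } else {
          tw <- solve_front(p)
          c(as.numeric(lambda_c2(tw)), tw$c)
        }
      }, warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) c(NA_real_, NA_real_))
  }
  grid <- expand.grid(delta1 = delta1, delta2 = delta2)
  res <- t(apply(grid, 1, function(r) eval_l2(r[1], r[2])))
  grid$lambda_c2 <- res[, 1]
  grid$c <- res[, 2]
  grid$regime <- apply(grid, 1, function(r)
    suppressWarnings(classify_regime(update_params(params,
                                                   delta1 = r[["delta1"]],
                                                   delta2 = r[["delta2"]])))$kind)
  contour <- do.call(rbind, lapply(delta1, function(d1) {
    col <- grid[grid$delta1 == d1, ]
    col <- col[order(col$delta2), ]
    s <- sign(col$lambda_c2)
    flip <- which(diff(s) != 0 & !is.na(diff(s)))
    if (!length(flip)) return(NULL)
    lo <- col$delta2[flip[1]]; hi <- col$delta2[flip[1] + 1]
    flo <- col$lambda_c2[flip[1]]
    for (k in seq_len(bisection_iter)) {
      mid <- (lo + hi) / 2
      fm <- eval_l2(d1, mid)[1]
      if (is.na(fm)) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    data.frame(delta1 = d1, delta2_boundary = (lo + hi) / 2)
  }))
  benign <- vapply(delta2, function(d2) {
    p <- suppressWarnings(update_params(params, delta1 = 1, delta2 = d2))
    Vp <- equilibrium_V(p)
    if (is.null(Vp)) NA_real_ else 1 / Vp[["V_plus"]]
  }, 0)
  structure(list(grid = grid, contour = contour,
                 benign_boundary = data.frame(delta2 = delta2,
                                              delta1 = benign),
                 method = method),
            class = "stability_boundary")
}

#' @export
print.stability_boundary <- function(x, ...) {
  cat("Transverse stability map (", x$method, "):\n", sep = "")
  print(x$grid, row.names = FALSE, digits = 5)
  if (!is.null(x$contour) && nrow(x$contour)) {
    cat("Zero contour (bisection in delta2):\n")
    print(x$contour, row.names = FALSE, digits = 5)
  }
  invisible(x)
}
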