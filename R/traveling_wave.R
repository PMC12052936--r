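# Traveling-wave boundary-value solver: the five-component first-order
# system in (u, v, q, w, p) with the wave speed c as an unknown scalar,
# discretized by trapezoidal collocation on a graded mesh and solved by a
# damped Newton iteration with a sparse Jacobian.

# Right-hand side f(y; c) of the nu = 0 traveling-wave system
#   u' = u (1 - u - delta1 w) / c
#   v' = (q + c v) / (1 + kappa - u)
#   q' = -rho v (1-v)(v-a) + delta2 v w
#   w' = eps p
#   p' = eps (c eps p - delta3 (v - w))
# Vectorized over the mesh: Y is an N x 5 matrix.
tw_rhs <- function(Y, cc, params) {
  u <- Y[, 1]; v <- Y[, 2]; q <- Y[, 3]; w <- Y[, 4]; p <- Y[, 5]
  a <- params$a; e <- params$eps
  cbind(u * (1 - u - params$delta1 * w) / cc,
        (q + cc * v) / (1 + params$kappa - u),
        -params$rho * v * (1 - v) * (v - a) + params$delta2 * v * w,
        e * p,
        e * (cc * e * p - params$delta3 * (v - w)))
}

# 5x5 Jacobian blocks of tw_rhs wrt the state, returned as an N x 25 matrix
# (column-major within each block), plus the derivative wrt c (N x 5).
tw_jacobian <- function(Y, cc, params) {
  u <- Y[, 1]; v <- Y[, 2]; q <- Y[, 3]; w <- Y[, 4]; p <- Y[, 5]
  a <- params$a; e <- params$eps
  D <- 1 + params$kappa - u
  J <- matrix(0, nrow(Y), 25)
  idx <- function(i, j) (j - 1) * 5 + i
  J[, idx(1, 1)] <- (1 - 2 * u - params$delta1 * w) / cc
  J[, idx(1, 4)] <- -params$delta1 * u / cc
  J[, idx(2, 1)] <- (q + cc * v) / D^2
  J[, idx(2, 2)] <- cc / D
  J[, idx(2, 3)] <- 1 / D
  J[, idx(3, 2)] <- params$rho * (3 * v^2 - 2 * (1 + a) * v + a) +
    params$delta2 * w
  J[, idx(3, 4)] <- params$delta2 * v
  J[, idx(4, 5)] <- e
  J[, idx(5, 2)] <- -e * params$delta3
  J[, idx(5, 4)] <- e * params$delta3
  J[, idx(5, 5)] <- cc * e^2
  dc <- cbind(-u * (1 - u - params$delta1 * w) / cc^2,
              v / D,
              0, 0,
              e^2 * p)
  list(J = J, dc = dc)
}

# End equilibria of the 5-dim system.  Left: p2.  Right: p4+ (malignant)
# or p3+ (benign).  q = -c v at equilibria.
tw_end_states <- function(params, cc, regime_kind) {
  Vp <- equilibrium_V(params)[["V_plus"]]
  left <- c(1, 0, 0, 0, 0)
  right <- if (regime_kind == "benign")
    c(1 - params$delta1 * Vp, Vp, -cc * Vp, Vp, 0)
  else c(0, Vp, -cc * Vp, Vp, 0)
  list(left = left, right = right)
}

# Jacobian of tw_rhs at a single state (5x5 dense).
tw_jacobian_point <- function(y, cc, params) {
  res <- tw_jacobian(matrix(y, 1, 5), cc, params)
  matrix(res$J[1, ], 5, 5)
}

# Orthonormal basis of the orthogonal complement of the span of the
# eigenvectors with Re(lambda) > 0 (mode = "unstable") or < 0
# ("stable").  Rows of the returned matrix are the boundary conditions.
projection_conditions <- function(J, mode = c("unstable", "stable")) {
  mode <- match.arg(mode)
  ev <- eigen(J)
  keep <- if (mode == "unstable") Re(ev$values) > 0 else Re(ev$values) < 0
  Vc <- ev$vectors[, keep, drop = FALSE]
  # realify complex-conjugate pairs
  Vr <- cbind(Re(Vc), Im(Vc))
  qrv <- qr(Vr)
  k <- qrv$rank
  Qfull <- qr.Q(qr(cbind(qr.Q(qrv)[, seq_len(k), drop = FALSE], diag(5))))
  t(Qfull[, (k + 1):5, drop = FALSE])   # (5 - k) x 5
}

# Graded mesh: piecewise-uniform segments with fine spacing inside windows
# around sharp features, geometric transitions between spacings.
make_mesh <- function(L, features, h_fine, h_tail, window) {
  h_at <- function(xi) {
    h <- rep(h_tail, length(xi))
    for (i in seq_along(features)) {
      d <- abs(xi - features[i]) - window[i]
      # fine inside the window, growing linearly outside, capped by h_tail
      hf <- ifelse(d <= 0, h_fine[i], pmin(h_fine[i] + 0.3 * d, h_tail))
      h <- pmin(h, hf)
    }
    h
  }
  xi <- -L
  out <- numeric(0)
  repeat {
    out <- c(out, xi)
    if (xi >= L) break
    xi <- xi + h_at(xi)
  }
  out[length(out)] <- L
  # make sure every feature point (esp. xi = 0) is a node: shift nearest
  for (f in features) {
    i <- which.min(abs(out - f))
    out[i] <- f
  }
  sort(unique(out))
}

# Default mesh for a given parameter set, built from the singular front's
# known feature locations: the v-interface at xi = 0 and the u-transition
# where w crosses 1/delta1 (malignant cases only).
default_mesh <- function(params, sf, L = NULL, h_fine = NULL, h_tail = NULL) {
  e <- params$eps
  srate <- e * sqrt(params$delta3)      # slow decay rate in xi
  if (is.null(L)) L <- 16 / srate
  lay <- sf$layer
  wl <- 1 / lay$rate                    # layer width
  if (is.null(h_fine)) h_fine <- min(wl / 12, 0.25)
  if (is.null(h_tail)) h_tail <- min(1 / (12 * srate), L / 60)
  features <- 0; hf <- h_fine; win <- 8 * wl
  kind <- sf$regime$kind
  if (kind %in% c("malignant_gap", "malignant_no_gap")) {
    d1 <- params$delta1
    # slow time from the jump level w* to the transcritical level 1/delta1
    if (kind == "malignant_gap") {
      zeta_u <- log(1 / (d1 * sf$w_star)) / sqrt(params$delta3)  # < 0
    } else {
      orb <- slow_orbit("Mplus", params, sf$w_star)
      mono <- !duplicated(orb$w)      # saddle padding repeats V+
      zeta_u <- stats::approx(orb$w[mono], orb$zeta[mono], xout = 1 / d1,
                              rule = 2)$y
    }
    xi_u <- zeta_u / e
    p_u <- sqrt(params$delta3) / d1     # p = sqrt(d3) w on M0; ~scale on Mplus
    width_u <- sqrt(max(sf$c_star, 1e-3) / (d1 * e * p_u))
    features <- c(features, xi_u)
    hf <- c(hf, min(width_u / 10, h_fine))
    win <- c(win, 8 * width_u)
  }
  make_mesh(L, features, hf, h_tail, win)
}

#' Initial guess for the traveling-wave boundary-value problem
#'
#' Assembles the singular-limit concatenation onto a finite-\eqn{\xi} grid:
#' slow segments mapped by \eqn{\xi = \zeta/\varepsilon}, the closed-form
#' tanh layer centered at \eqn{\xi = 0}, speed initialized at the singular
#' speed \eqn{c_*}.
#'
#' @param params a [model_params()] object.
#' @param xi optional mesh; default built from the singular front's
#'   feature locations.
#' @param L domain half-length (used only when \code{xi} is NULL).
#' @return An (unconverged) object of class \code{"traveling_wave"}.
#' @export
initial_guess <- function(params, xi = NULL, L = NULL) {
  sf <- singular_front(params)
  if (is.null(xi)) xi <- default_mesh(params, sf, L = L)
  e <- params$eps
  prof <- sample_singular_profile(sf, e * xi)
  lay <- sf$layer
  # blend the layer tanh into the slow v profile near xi = 0
  vlay <- lay$v_of_xi(xi)
  wgt <- exp(-(e * xi / 0.2)^2)  # layer dominates on the fast scale
  v <- ifelse(xi <= 0, vlay, prof$v * (1 - wgt) + vlay * wgt)
  u <- prof$u
  if (lay$branch == 1) {
    # in the jump region u tracks 1 - delta1 w; already in prof
  } else {
    u <- ifelse(xi > 0, 0, u)
  }
  w <- prof$w
  p <- prof$p
  D <- 1 + params$kappa - u
  dv <- lay$dv_of_xi(xi)
  q <- D * dv - sf$c_star * v
  Y <- cbind(u = u, v = v, q = q, w = w, p = p)
  structure(list(xi = xi, Y = Y, c = sf$c_star, params = params,
                 singular = sf, converged = FALSE, residual_norm = NA_real_),
            class = "traveling_wave")
}

# Full nonlinear residual of the discretized BVP (Hermite-Simpson /
# Lobatto-IIIA collocation, 4th order):
#   y_{i+1} - y_i = (h/6) (f_i + 4 f(y_m) + f_{i+1}),
#   y_m = (y_i + y_{i+1})/2 + (h/8) (f_i - f_{i+1}).
tw_residual <- function(xi, Y, cc, params, sf, i0) {
  N <- length(xi)
  h <- diff(xi)
  f <- tw_rhs(Y, cc, params)
  Ym <- (Y[-N, ] + Y[-1, ]) / 2 + (h / 8) * (f[-N, ] - f[-1, ])
  fm <- tw_rhs(Ym, cc, params)
  interior <- Y[-1, ] - Y[-N, ] - (h / 6) * (f[-1, ] + 4 * fm + f[-N, ])
  ends <- tw_end_states(params, cc, sf$regime$kind)
  BL <- projection_conditions(tw_jacobian_point(ends$left, cc, params),
                              "unstable")
  BR <- projection_conditions(tw_jacobian_point(ends$right, cc, params),
                              "stable")
  phase <- Y[i0, 2] - sf$layer$v_plus / 2
  c(as.vector(t(interior)),
    as.vector(BL %*% (Y[1, ] - ends$left)),
    as.vector(BR %*% (Y[N, ] - ends$right)),
    phase)
}

# Multiply 5x5 blocks stored row-wise as M x 25 matrices (column-major
# within the block): C = A %*% B per row.
block_mult <- function(A, B) {
  C <- matrix(0, nrow(A), 25)
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (k in 1:5)
      acc <- acc + A[, (k - 1) * 5 + i] * B[, (j - 1) * 5 + k]
    C[, (j - 1) * 5 + i] <- acc
  }
  C
}

# Apply 5x5 blocks (M x 25) to 5-vectors (M x 5): (A v) per row.
block_apply <- function(A, v) {
  out <- matrix(0, nrow(A), 5)
  for (i in 1:5) {
    acc <- 0
    for (k in 1:5) acc <- acc + A[, (k - 1) * 5 + i] * v[, k]
    out[, i] <- acc
  }
  out
}

# Sparse Newton step: analytic Jacobian of the Hermite-Simpson residual
# for the interior rows; finite differences only for the boundary rows'
# c-dependence.
tw_newton_matrix <- function(xi, Y, cc, params, sf, i0) {
  N <- length(xi)
  h <- diff(xi)
  jac <- tw_jacobian(Y, cc, params)
  f <- tw_rhs(Y, cc, params)
  Ym <- (Y[-N, ] + Y[-1, ]) / 2 + (h / 8) * (f[-N, ] - f[-1, ])
  jacm <- tw_jacobian(Ym, cc, params)
  nI <- 5 * (N - 1)
  # interior row r = 5*(i-1)+k (i = 1..N-1 intervals, k = component)
  # depends on blocks i and i+1
  ii <- rep(seq_len(N - 1), each = 25)
  kk <- rep(rep(1:5, times = 5), times = N - 1)   # component k of residual
  jj <- rep(rep(1:5, each = 5), times = N - 1)    # component j of state
  rows <- 5 * (ii - 1) + kk
  colsL <- 5 * (ii - 1) + jj
  colsR <- 5 * ii + jj
  Jl <- jac$J[-N, , drop = FALSE]
  Jr <- jac$J[-1, , drop = FALSE]
  Jm <- jacm$J
  JmJl <- block_mult(Jm, Jl)
  JmJr <- block_mult(Jm, Jr)
  hrep <- rep(h, each = 25)
  eyes <- as.numeric(kk == jj)
  valsL <- -eyes - (hrep / 6) * as.vector(t(Jl)) -
    (hrep / 3) * as.vector(t(Jm)) - (hrep^2 / 12) * as.vector(t(JmJl))
  valsR <- eyes - (hrep / 6) * as.vector(t(Jr)) -
    (hrep / 3) * as.vector(t(Jm)) + (hrep^2 / 12) * as.vector(t(JmJr))
  # c-column for interior rows
  dcL <- jac$dc[-N, , drop = FALSE]
  dcR <- jac$dc[-1, , drop = FALSE]
  dYm_dc <- (h / 8) * (dcL - dcR)
  dfm_dc <- jacm$dc + block_apply(Jm, dYm_dc)
  cvals <- -(h / 6) * (dcL + dcR + 4 * dfm_dc)     # (N-1) x 5
  crow <- 5 * (rep(seq_len(N - 1), times = 5) - 1) + rep(1:5, each = N - 1)
  ncol_tot <- 5 * N + 1
  trip_i <- c(rows, rows, crow)
  trip_j <- c(colsL, colsR, rep(ncol_tot, length(crow)))
  trip_x <- c(valsL, valsR, as.vector(cvals))
  # boundary + phase rows
  ends <- tw_end_states(params, cc, sf$regime$kind)
  BL <- projection_conditions(tw_jacobian_point(ends$left, cc, params),
                              "unstable")
  BR <- projection_conditions(tw_jacobian_point(ends$right, cc, params),
                              "stable")
  nL <- nrow(BL); nR <- nrow(BR)
  rL <- nI + seq_len(nL)
  rR <- nI + nL + seq_len(nR)
  rP <- nI + nL + nR + 1
  trip_i <- c(trip_i, rep(rL, times = 5), rep(rR, times = 5), rP)
  trip_j <- c(trip_j,
              rep(1:5, each = nL),
              rep(5 * (N - 1) + (1:5), each = nR),
              5 * (i0 - 1) + 2)
  trip_x <- c(trip_x, as.vector(BL), as.vector(BR), 1)
  # c-dependence of the boundary rows (right end state moves with c):
  # finite difference, cheap (two 5-vector evaluations)
  dc <- 1e-7 * max(1, abs(cc))
  ends2 <- tw_end_states(params, cc + dc, sf$regime$kind)
  BL2 <- projection_conditions(tw_jacobian_point(ends2$left, cc + dc, params),
                               "unstable")
  BR2 <- projection_conditions(tw_jacobian_point(ends2$right, cc + dc,
                                                 params), "stable")
  bL1 <- as.vector(BL %*% (Y[1, ] - ends$left))
  bL2 <- as.vector(BL2 %*% (Y[1, ] - ends2$left))
  bR1 <- as.vector(BR %*% (Y[N, ] - ends$right))
  bR2 <- as.vector(BR2 %*% (Y[N, ] - ends2$right))
  trip_i <- c(trip_i, rL, rR)
  trip_j <- c(trip_j, rep(ncol_tot, nL + nR))
  trip_x <- c(trip_x, (bL2 - bL1) / dc, (bR2 - bR1) / dc)
  Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                       dims = c(ncol_tot, ncol_tot))
}

#' Solve the traveling-wave boundary-value problem at finite eps
#'
#' Solves the five-component first-order traveling-wave system (frame
#' exponent \eqn{\nu = 0}) with the wave speed \eqn{c} as an unknown
#' scalar, by trapezoidal collocation on a graded mesh and a damped Newton
#' iteration.  The problem is closed by projected boundary conditions
#' (the deviation from the end equilibria must lie in the unstable
#' subspace at \eqn{-\infty} and the stable subspace at \eqn{+\infty})
#' and the phase condition \eqn{v(0) = v^+(w_*)/2} matching the layer
#' centering.
#'
#' @param params a [model_params()] object.
#' @param guess optional starting [initial_guess()] (or a previously
#'   converged front, e.g. during continuation).
#' @param L domain half-length; default \eqn{16/(\varepsilon\sqrt{\delta_3})}
#'   (sixteen slow e-foldings, so truncated tails sit below \code{1e-6}).
#' @param tol Newton tolerance on the max-norm of the residual.
#' @param max_iter maximum Newton iterations.
#' @param quiet suppress the per-iteration residual trace.
#' @return An object of class \code{"traveling_wave"}: mesh \code{xi},
#'   profile matrix \code{Y} (columns u, v, q, w, p), converged speed
#'   \code{c}, \code{residual_norm}, \code{params}, the underlying
#'   \code{singular} front, and endpoint labels.
#' @examples
#' \donttest{
#' tw <- solve_front(load_preset("fig8_row4")$params)
#' tw$c
#' }
#' @export
solve_front <- function(params, guess = NULL, L = NULL, tol = 1e-10,
                        max_iter = 40, quiet = TRUE) {
  if (is.null(guess)) guess <- initial_guess(params, L = L)
  sf <- guess$singular
  xi <- guess$xi
  i0 <- which(xi == 0)
  if (length(i0) != 1) stop("mesh must contain xi = 0 exactly once")
  Y <- guess$Y
  cc <- guess$c
  N <- length(xi)
  hist <- numeric(0)
  reluctant <- 0    # watchdog: tolerated non-decreasing steps in a row
  for (it in seq_len(max_iter)) {
    R <- tw_residual(xi, Y, cc, params, sf, i0)
    rn <- max(abs(R))
    hist <- c(hist, rn)
    if (!quiet) message(sprintf("  newton %2d: |R| = %.3e, c = %.8f",
                                it, rn, cc))
    if (rn < tol) break
    Amat <- tw_newton_matrix(xi, Y, cc, params, sf, i0)
    step <- tryCatch(as.vector(Matrix::solve(Amat, -R)),
                     error = function(e)
                       stop("Newton linear solve failed: ",
                            conditionMessage(e)))
    # damped update
    lam <- 1
    repeat {
      Y2 <- Y + lam * matrix(step[seq_len(5 * N)], N, 5, byrow = TRUE)
      cc2 <- cc + lam * step[5 * N + 1]
      ok <- cc2 > 1e-6 && all(is.finite(Y2))
      if (ok) {
        R2 <- tw_residual(xi, Y2, cc2, params, sf, i0)
        ok <- all(is.finite(R2)) && max(abs(R2)) < rn * (1 - 1e-4 * lam) ||
          max(abs(R2)) < tol
      }
      if (ok || lam < 1 / 64) break
      lam <- lam / 2
    }
    if (!ok) {
      # watchdog: a flat line search near a narrow basin; take a short
      # step anyway a few times before giving up
      reluctant <- reluctant + 1
      if (reluctant > 3 || !all(is.finite(Y2)) || cc2 <= 1e-6)
        stop(sprintf(
          "front solver failed to converge (residual %.3e after %d iterations; history: %s)",
          rn, it, paste(signif(hist, 3), collapse = " ")))
    } else reluctant <- 0
    Y <- Y2; cc <- cc2
  }
  if (max(abs(tw_residual(xi, Y, cc, params, sf, i0))) > tol * 10)
    stop(sprintf("front solver did not reach tolerance (residual %.3e)",
                 max(abs(tw_residual(xi, Y, cc, params, sf, i0)))))
  colnames(Y) <- c("u", "v", "q", "w", "p")
  ends <- tw_end_states(params, cc, sf$regime$kind)
  structure(list(xi = xi, Y = Y, c = cc, params = params, singular = sf,
                 converged = TRUE,
                 residual_norm = max(abs(tw_residual(xi, Y, cc, params, sf,
                                                     i0))),
                 i0 = i0,
                 endpoint_states = list(
                   left = "p2",
                   right = if (sf$regime$kind == "benign") "p3+" else "p4+"),
                 end_values = ends,
                 newton_history = hist),
            class = "traveling_wave")
}

#' @export
print.traveling_wave <- function(x, ...) {
  cat("Traveling front (nu = 0), regime:", x$singular$regime$kind, "\n")
  cat(sprintf("  wave speed c = %.6g (singular limit c* = %.6g)\n",
              x$c, x$singular$c_star))
  cat(sprintf("  mesh: %d points on [%.4g, %.4g]; residual %.2e; %s\n",
              length(x$xi), min(x$xi), max(x$xi), x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  connects %s (xi -> -Inf) to %s (xi -> +Inf)\n",
              x$endpoint_states$left, x$endpoint_states$right))
  invisible(x)
}

#' @export
summary.traveling_wave <- function(object, ...) {
  gw <- measure_gap_width(object)
  cat("Traveling front summary\n")
  print(object)
  print(object$params)
  cat(sprintf("  acellular gap width: xi = %.6g, zeta = %.6g (singular %.6g)\n",
              gw[["width_xi"]], gw[["width_zeta"]],
              object$singular$gap_width_zeta))
  invisible(object)
}

#' @export
coef.traveling_wave <- function(object, ...) c(c = object$c)

#' @export
plot.traveling_wave <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) xlim <- range(x$xi)
  graphics::matplot(x$xi, x$Y[, c("u", "v", "w")], type = "l", lty = 1,
                    col = c("blue", "red", "goldenrod"),
                    xlab = expression(xi), ylab = "density / concentration",
                    xlim = xlim, ...)
  graphics::legend("right", c("u (normal)", "v (tumor)", "w (acid)"),
                   col = c("blue", "red", "goldenrod"), lty = 1, bty = "n")
  invisible(x)
}

#' Measure the acellular gap width of a resolved front
#'
#' Width of the maximal \eqn{\xi}-interval on which both the normal and
#' tumor densities stay below \code{threshold_multiplier}\eqn{\times
#' \varepsilon} (the convention used when comparing finite-\eqn{\varepsilon}
#' widths against the singular-limit curve).
#'
#' @param front a converged [solve_front()] object.
#' @param threshold_multiplier cells count as absent below this multiple of
#'   \eqn{\varepsilon}; default 10.
#' @return Named vector \code{c(width_xi, width_zeta)} with
#'   \code{width_zeta} \eqn{= \varepsilon\,}\code{width_xi}; zero when no
#'   such interval exists.
#' @export
measure_gap_width <- function(front, threshold_multiplier = 10) {
  thr <- threshold_multiplier * front$params$eps
  m <- pmax(front$Y[, "u"], front$Y[, "v"])   # cells of either kind
  low <- m < thr
  if (!any(low)) return(c(width_xi = 0, width_zeta = 0))
  xi <- front$xi
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  wid <- 0
  cross <- function(i, j) {
    # linear interpolation of the m = thr crossing between nodes i, j
    xi[i] + (thr - m[i]) * (xi[j] - xi[i]) / (m[j] - m[i])
  }
  for (k in which(r$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    xl <- if (i1 > 1) cross(i1 - 1, i1) else xi[i1]
    xr <- if (i2 < length(xi)) cross(i2 + 1, i2) else xi[i2]
    wid <- max(wid, xr - xl)
  }
  c(width_xi = wid, width_zeta = front$params$eps * wid)
}

#' Natural-parameter continuation of the traveling front
#'
#' Marches the converged front along one model parameter with adaptive
#' step halving on solver failure, reusing each solution (interpolated
#' onto the next parameter's mesh) as the next initial guess.
#'
#' @param front a converged [solve_front()] object at the branch start.
#' @param name parameter to continue in (\code{"delta1"}, \code{"a"}, ...).
#' @param to stop value.
#' @param n_steps number of (initial) equal steps; halved adaptively on
#'   failure.
#' @param lambda2 also compute the transverse coefficient at every branch
#'   point (slower).
#' @param quiet suppress progress messages.
#' @return Object of class \code{"continuation_branch"}: data frame
#'   \code{branch} with columns value, c, gap_width_zeta, regime (and
#'   lambda_c2 if requested), plus the final front.
#' @export
continue_parameter <- function(front, name, to, n_steps = 10,
                               lambda2 = FALSE, quiet = TRUE) {
  stopifnot(inherits(front, "traveling_wave"))
  from <- front$params[[name]]
  vals <- seq(from, to, length.out = n_steps + 1)[-1]
  rows <- list()
  rec <- function(fr) {
    gw <- measure_gap_width(fr)
    data.frame(value = fr$params[[name]], c = fr$c,
               gap_width_zeta = gw[["width_zeta"]],
               regime = fr$singular$regime$kind,
               lambda_c2 = if (lambda2) lambda_c2(fr) else NA_real_)
  }
  rows[[1]] <- rec(front)
  cur <- front
  i <- 1
  fails <- 0
  while (i <= length(vals)) {
    target <- vals[i]
    p2 <- do.call(update_params,
                  c(list(cur$params), stats::setNames(list(target), name)))
    g <- tryCatch(reguess(cur, p2), error = function(e) NULL)
    sol <- if (is.null(g)) NULL else
      tryCatch(solve_front(p2, guess = g), error = function(e) NULL)
    if (is.null(sol)) {
      fails <- fails + 1
      if (fails > 12)
        return(finish_branch(rows, cur, name,
                             reason = "step underflow"))
      # insert midpoint
      vals <- append(vals, (cur$params[[name]] + target) / 2, after = i - 1)
      next
    }
    fails <- 0
    cur <- sol
    rows[[length(rows) + 1]] <- rec(cur)
    if (!quiet) message(sprintf("  %s = %.6g: c = %.6g", name, target,
                                cur$c))
    i <- i + 1
  }
  finish_branch(rows, cur, name, reason = "completed")
}

finish_branch <- function(rows, cur, name, reason) {
  structure(list(parameter = name,
                 branch = do.call(rbind, rows),
                 front = cur, reason = reason),
            class = "continuation_branch")
}

#' @export
print.continuation_branch <- function(x, ...) {
  cat(sprintf("Continuation in %s (%d points, %s)\n", x$parameter,
              nrow(x$branch), x$reason))
  print(utils::head(x$branch, 12), row.names = FALSE, digits = 6)
  if (nrow(x$branch) > 12) cat("  ...\n")
  invisible(x)
}

# Build a guess for new parameters from an existing converged front by
# interpolating the profile onto the new default mesh.
reguess <- function(front, params2) {
  sf2 <- singular_front(params2)
  xi2 <- default_mesh(params2, sf2)
  Y2 <- sapply(1:5, function(j)
    stats::approx(front$xi, front$Y[, j], xout = xi2, rule = 2)$y)
  # re-center the phase: locate v = v+(w*)/2 crossing and shift
  target <- sf2$layer$v_plus / 2
  v <- Y2[, 2]
  cross <- which(diff(sign(v - target)) != 0)
  if (length(cross)) {
    i <- cross[which.min(abs(xi2[cross]))]
    x0 <- xi2[i] + (target - v[i]) * (xi2[i + 1] - xi2[i]) /
      (v[i + 1] - v[i])
    Y2 <- sapply(1:5, function(j)
      stats::approx(front$xi - x0, front$Y[, j], xout = xi2,
                    rule = 2)$y)
  }
  structure(list(xi = xi2, Y = Y2, c = front$c, params = params2,
                 singular = sf2, converged = FALSE,
                 residual_norm = NA_real_),
            class = "traveling_wave")
}
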