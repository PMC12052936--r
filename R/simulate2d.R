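# Two-dimensional comoving-frame simulation of the full model: IMEX time
# stepping with the stiff acid diffusion (1/eps^2) treated implicitly via
# FFT in the periodic transverse direction and tridiagonal solves in xi,
# explicit reactions and conservative nonlinear tumor diffusion, and
# interface/Fourier-mode diagnostics against the spectral predictions.

#' Noise-seeded planar-front initial condition
#'
#' Extends a converged 1D front trivially in the transverse direction on a
#' uniform comoving grid and adds small independent uniform noise to the
#' tumor density (optionally all fields), with a recorded seed so runs are
#' bit-reproducible.
#'
#' @param front a converged [solve_front()] object.
#' @param Ny number of transverse grid points (periodic).
#' @param Ly transverse domain length.
#' @param noise_amplitude uniform noise half-width added to V.
#' @param seed RNG seed recorded in the object.
#' @param L_xi half-length of the comoving window (default: enough slow
#'   e-foldings that the pinned ends are converged); the front interface
#'   sits at \eqn{\xi = 0}.
#' @param hx grid spacing in \eqn{\xi}; default resolves the layer with
#'   about 8 points.
#' @param noise_on fields to perturb, subset of c("U","V","W").
#' @return Object of class \code{"field2d"}: matrices \code{U}, \code{V},
#'   \code{W} (Nx x Ny), grids \code{xi}, \code{y}, frame speed \code{c},
#'   time \code{tau = 0}, the base (unperturbed) profiles, and metadata.
#' @export
make_initial_condition <- function(front, Ny = 64, Ly = NULL,
                                   noise_amplitude = 1e-3, seed = 1,
                                   L_xi = NULL, hx = NULL,
                                   noise_on = "V") {
  params <- front$params
  lay <- front$singular$layer
  if (is.null(hx)) hx <- min(1 / (8 * lay$rate), 0.5)
  if (is.null(L_xi))
    L_xi <- min(max(front$xi), 7 / (params$eps * sqrt(params$delta3)))
  xi <- seq(-L_xi, L_xi, by = hx)
  Nx <- length(xi)
  if (is.null(Ly)) Ly <- 40
  if (Ny < 8) stop("Ny too coarse to represent transverse modes")
  y <- seq(0, Ly, length.out = Ny + 1)[-(Ny + 1)]
  base <- sapply(c(1, 2, 4), function(j)
    stats::approx(front$xi, front$Y[, j], xout = xi, rule = 2)$y)
  colnames(base) <- c("u", "v", "w")
  U <- matrix(base[, "u"], Nx, Ny)
  V <- matrix(base[, "v"], Nx, Ny)
  W <- matrix(base[, "w"], Nx, Ny)
  set.seed(seed)
  if (noise_amplitude > 0) {
    if ("V" %in% noise_on)
      V <- V + noise_amplitude * (matrix(stats::runif(Nx * Ny), Nx, Ny) - 0.5)
    if ("U" %in% noise_on)
      U <- U + noise_amplitude * (matrix(stats::runif(Nx * Ny), Nx, Ny) - 0.5)
    if ("W" %in% noise_on)
      W <- W + noise_amplitude * (matrix(stats::runif(Nx * Ny), Nx, Ny) - 0.5)
  }
  structure(list(U = U, V = V, W = W, xi = xi, y = y, hx = hx,
                 hy = Ly / Ny, Ly = Ly, tau = 0, c = front$c,
                 params = params, base = base, seed = seed,
                 level = lay$v_plus / 2,
                 noise_amplitude = noise_amplitude),
            class = "field2d")
}

#' @export
print.field2d <- function(x, ...) {
  cat(sprintf(
    "2D comoving field at tau = %g: %d x %d grid, xi in [%g, %g], Ly = %g\n",
    x$tau, length(x$xi), length(x$y), min(x$xi), max(x$xi), x$Ly))
  cat(sprintf("  frame speed c = %.6g, seed %d, noise %g\n",
              x$c, x$seed, x$noise_amplitude))
  invisible(x)
}

#' @export
plot.field2d <- function(x, field = "V", ...) {
  graphics::image(x$xi, x$y, x[[field]], xlab = expression(xi), ylab = "y",
                  main = paste0(field, " at tau = ", signif(x$tau, 5)),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# first derivative in xi (central, one-sided ends), columns = y
ddx <- function(X, hx) {
  Nx <- nrow(X)
  D <- X
  D[2:(Nx - 1), ] <- (X[3:Nx, ] - X[1:(Nx - 2), ]) / (2 * hx)
  D[1, ] <- (X[2, ] - X[1, ]) / hx
  D[Nx, ] <- (X[Nx, ] - X[Nx - 1, ]) / hx
  D
}

# conservative divergence-form nonlinear diffusion div(D grad V) with
# no-flux in xi and periodicity in y
nl_diffusion <- function(V, D, hx, hy) {
  Nx <- nrow(V); Ny <- ncol(V)
  out <- matrix(0, Nx, Ny)
  Dfx <- (D[-1, ] + D[-Nx, ]) / 2            # faces in xi
  flux_x <- Dfx * (V[-1, ] - V[-Nx, ]) / hx
  out[2:(Nx - 1), ] <- (flux_x[-1, ] - flux_x[-(Nx - 1), ]) / hx
  out[1, ] <- flux_x[1, ] / hx
  out[Nx, ] <- -flux_x[Nx - 1, ] / hx
  ip <- c(2:Ny, 1); im <- c(Ny, 1:(Ny - 1))
  Dfy <- (D[, ip] + D) / 2
  flux_y <- Dfy * (V[, ip] - V) / hy
  out + (flux_y - flux_y[, im]) / hy
}

# Precomputed Thomas factorization for (I - mu (Dxx - lam_k)) per
# transverse mode, Neumann ends; mu = dt/eps^2.
make_w_solver <- function(Nx, Ny, hx, hy, mu) {
  k <- 0:(Ny - 1)
  lam <- (2 - 2 * cos(2 * pi * k / Ny)) / hy^2
  off <- -mu / hx^2
  dmain <- matrix(1 + 2 * mu / hx^2 + mu * lam, Nx, Ny, byrow = TRUE)
  dmain[1, ] <- 1 + mu / hx^2 + mu * lam
  dmain[Nx, ] <- 1 + mu / hx^2 + mu * lam
  cp <- matrix(0, Nx, Ny)        # elimination multipliers
  denom <- matrix(0, Nx, Ny)
  denom[1, ] <- 1 / dmain[1, ]
  cp[1, ] <- off * denom[1, ]
  for (i in 2:Nx) {
    denom[i, ] <- 1 / (dmain[i, ] - off * cp[i - 1, ])
    cp[i, ] <- off * denom[i, ]
  }
  list(off = off, cp = cp, denom = denom, Nx = Nx)
}

solve_w_implicit <- function(rhs, solver) {
  # rhs real Nx x Ny; returns solution of the Helmholtz systems per mode
  Nx <- solver$Nx
  Rk <- t(stats::mvfft(t(rhs)))               # Nx x Ny complex, modes in cols
  dp <- Rk
  dp[1, ] <- Rk[1, ] * solver$denom[1, ]
  for (i in 2:Nx)
    dp[i, ] <- (Rk[i, ] - solver$off * dp[i - 1, ]) * solver$denom[i, ]
  X <- dp
  for (i in (Nx - 1):1)
    X[i, ] <- dp[i, ] - solver$cp[i, ] * X[i + 1, ]
  Re(t(stats::mvfft(t(X), inverse = TRUE))) / ncol(rhs)
}

#' Evolve the 2D comoving-frame model
#'
#' IMEX time integration: the stiff acid Laplacian \eqn{\varepsilon^{-2}
#' \Delta W} is treated implicitly (FFT across the periodic transverse
#' direction, tridiagonal solves along \eqn{\xi}); reactions, the
#' conservative nonlinear tumor diffusion
#' \eqn{\nabla\cdot((1+\kappa-U)\nabla V)} and the comoving advection
#' \eqn{c\,\partial_\xi} are explicit.  No-flux conditions in \eqn{\xi}
#' are supplemented by a sponge relaxing the outer 5\% of the domain to
#' the unperturbed front tails.  Interface diagnostics (position per
#' transverse row and its Fourier amplitudes) are recorded at every
#' snapshot.
#'
#' @param state a [make_initial_condition()] field.
#' @param dt time step (checked against explicit stability limits).
#' @param T final time.
#' @param snapshot_stride record diagnostics every this many steps.
#' @param keep_fields also keep full (U,V,W) snapshots (memory-heavy);
#'   default keeps only the final fields.
#' @param quiet suppress progress messages.
#' @return Object of class \code{"simulation2d"}: \code{times}, matrix
#'   \code{interface} (rows = snapshots) of interface positions,
#'   \code{amplitudes} (modulus of the interface Fourier modes), the final
#'   \code{state}, and metadata.
#' @export
evolve <- function(state, dt, T, snapshot_stride = 50L,
                   keep_fields = FALSE, quiet = TRUE) {
  params <- state$params
  hx <- state$hx; hy <- state$hy
  Nx <- length(state$xi); Ny <- length(state$y)
  # explicit stability checks (diffusion on V, reaction scales)
  Dmax <- 1 + params$kappa
  dt_diff <- 1 / (2 * Dmax * (1 / hx^2 + 1 / hy^2))
  if (dt > dt_diff)
    stop(sprintf("dt = %g exceeds the explicit diffusion limit %.3g",
                 dt, dt_diff))
  if (dt * params$delta3 > 1.5)
    stop("dt too large for the acid reaction rate delta3")
  solver <- make_w_solver(Nx, Ny, hx, hy, dt / params$eps^2)
  # sponge: relax the outer 5% toward the unperturbed tails
  spw <- 0.05 * (max(state$xi) - min(state$xi))
  sL <- pmax(0, 1 - (state$xi - min(state$xi)) / spw)
  sR <- pmax(0, 1 - (max(state$xi) - state$xi) / spw)
  sponge <- 5 * (sL^2 + sR^2)
  U <- state$U; V <- state$V; W <- state$W
  Ub <- matrix(state$base[, "u"], Nx, Ny)
  Vb <- matrix(state$base[, "v"], Nx, Ny)
  Wb <- matrix(state$base[, "w"], Nx, Ny)
  cc <- state$c
  a <- params$a
  nsteps <- ceiling(T / dt)
  times <- numeric(0)
  iface <- list()
  fields <- list()
  tau <- state$tau
  for (n in seq_len(nsteps)) {
    Fr <- U * (1 - U) - params$delta1 * U * W
    Gr <- params$rho * V * (1 - V) * (V - a) - params$delta2 * V * W
    Hr <- params$delta3 * (V - W)
    Dv <- 1 + params$kappa - U
    Unew <- U + dt * (Fr - cc * ddx(U, hx) - sponge * (U - Ub))
    Vnew <- V + dt * (Gr + nl_diffusion(V, Dv, hx, hy) -
                        cc * ddx(V, hx) - sponge * (V - Vb))
    rhsW <- W + dt * (Hr - cc * ddx(W, hx) - sponge * (W - Wb))
    Wnew <- solve_w_implicit(rhsW, solver)
    U <- Unew; V <- Vnew; W <- Wnew
    tau <- tau + dt
    if (any(!is.finite(V)))
      stop(sprintf("blow-up detected at tau = %g", tau))
    if (n %% snapshot_stride == 0 || n == nsteps) {
      st <- state; st$U <- U; st$V <- V; st$W <- W; st$tau <- tau
      hpos <- interface_position(st, state$level)
      times <- c(times, tau)
      iface[[length(iface) + 1]] <- hpos
      if (keep_fields) fields[[length(fields) + 1]] <- st
      if (!quiet) message(sprintf("  tau = %8.1f  interface sd = %.4g",
                                  tau, stats::sd(hpos, na.rm = TRUE)))
    }
  }
  iface <- do.call(rbind, iface)
  amps <- t(apply(iface, 1, function(h) {
    h[!is.finite(h)] <- mean(h[is.finite(h)])
    Mod(stats::fft(h)) / length(h)
  }))
  final <- state; final$U <- U; final$V <- V; final$W <- W; final$tau <- tau
  structure(list(times = times, interface = iface, amplitudes = amps,
                 state = final, fields = fields, dt = dt,
                 Ly = state$Ly, Ny = Ny,
                 ells = 2 * pi * (0:(Ny - 1)) / state$Ly),
            class = "simulation2d")
}

#' @export
print.simulation2d <- function(x, ...) {
  cat(sprintf("2D simulation: %d snapshots to tau = %g (dt = %g)\n",
              length(x$times), max(x$times), x$dt))
  cat(sprintf("  final interface sd: %.5g\n",
              stats::sd(x$interface[nrow(x$interface), ])))
  invisible(x)
}

#' Interface position of the tumor front
#'
#' Locates, for each transverse row, the leftmost monotone crossing of the
#' tumor density through \code{level} (default: half the fast-branch rest
#' state, matching the layer centering), by linear interpolation.
#'
#' @param state a \code{field2d} object.
#' @param level crossing level; defaults to the stored layer half-height.
#' @return Numeric vector h(y); rows without a crossing are \code{NA}.
#' @export
interface_position <- function(state, level = NULL) {
  if (is.null(level)) level <- state$level
  V <- state$V
  xi <- state$xi
  apply(V, 2, function(col) {
    s <- col - level
    idx <- which(s[-1] * s[-length(s)] <= 0 & s[-1] != s[-length(s)])
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    xi[i] + (level - col[i]) * (xi[i + 1] - xi[i]) / (col[i + 1] - col[i])
  })
}

#' Fitted transverse mode growth rates
#'
#' Least-squares growth rates \eqn{\sigma(\ell_k)} of the interface
#' Fourier amplitudes \eqn{|\hat h(\ell_k)|(\tau)} over a time window in
#' the linear regime, for comparison against the spectral prediction
#' \eqn{\lambda_c(\ell_k)}.
#'
#' @param sim an [evolve()] result.
#' @param modes integer mode indices \eqn{k \ge 1} to fit.
#' @param window index range into \code{sim$times} (default: from the
#'   second snapshot on, while every fitted amplitude stays below 5\% of
#'   \code{Ly}).
#' @return Data frame with columns \code{k}, \code{ell}, \code{sigma},
#'   \code{r_squared}, \code{amp_start}, \code{amp_end}; a warning is
#'   attached if the window leaves the linear regime.
#' @export
mode_growth <- function(sim, modes = 1:3, window = NULL) {
  amp_cap <- 0.05 * sim$Ly
  if (is.null(window)) {
    ok <- apply(sim$amplitudes[, modes + 1, drop = FALSE] < amp_cap, 1, all)
    last <- if (all(ok)) length(sim$times) else which(!ok)[1] - 1
    window <- seq(2, max(last, 5))
  }
  if (length(window) < 4)
    warning("fewer than 4 snapshots in the linear-regime window")
  if (any(sim$amplitudes[window, modes + 1] > amp_cap))
    warning("fit window extends beyond the linear regime (amplitude > 5% Ly)")
  out <- do.call(rbind, lapply(modes, function(k) {
    av <- sim$amplitudes[window, k + 1]
    tv <- sim$times[window]
    keep <- av > 0
    fit <- stats::lm(log(av[keep]) ~ tv[keep])
    data.frame(k = k, ell = sim$ells[k + 1],
               sigma = unname(stats::coef(fit)[2]),
               r_squared = summary(fit)$r.squared,
               amp_start = av[1], amp_end = av[length(av)])
  }))
  out
}
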