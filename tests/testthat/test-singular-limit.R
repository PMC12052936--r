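test_that("fast-branch rest states: endpoints, fold, and delta2 = 0 degeneracy", {
  p <- model_params(0.2, 0.1, 4, 0.1, 70, 1, 0.01)
  vb <- v_branch(0, p)
  expect_equal(vb$v_plus, 1)
  expect_equal(vb$v_minus, 0.2)
  wf <- p$rho * (1 - p$a)^2 / (4 * p$delta2)
  vf <- v_branch(wf, p)
  expect_equal(vf$v_plus, vf$v_minus)
  expect_equal(vf$v_plus, (1 + p$a) / 2)
  expect_error(v_branch(wf * 1.01, p), "fold")
  p0 <- model_params(0.2, 0.1, 4, 0, 70, 1, 0.01)
  vb0 <- v_branch(7.3, p0)   # w-independent when delta2 = 0
  expect_equal(c(vb0$v_plus, vb0$v_minus), c(1, 0.2))
})

test_that("layer fronts satisfy the planar ODE and the printed centering", {
  set.seed(21)
  for (k in 1:25) {
    p <- random_params()
    branch <- sample(0:1, 1)
    wmax <- min(if (p$delta2 > 0) p$rho * (1 - p$a)^2 / (4 * p$delta2)
                else 2,
                if (branch == 1) 0.999 / p$delta1 else 2)
    w <- runif(1, 0, 0.9 * wmax)
    lf <- layer_front(w, branch, p)
    expect_equal(lf$v_of_xi(0), lf$v_plus / 2, tolerance = 1e-13)
    # closed-form profile solves D v'' - c v' + g(v) = 0
    xi <- seq(-12 / lf$rate, 12 / lf$rate, length.out = 301)
    v <- lf$v_of_xi(xi); v1 <- lf$dv_of_xi(xi)
    v2 <- -2 * lf$rate * tanh(lf$rate * xi) * v1
    g <- p$rho * v * (1 - v) * (v - p$a) - p$delta2 * v * w
    expect_lt(max(abs(lf$diffusion * v2 - lf$speed * v1 + g)), 1e-8)
    # limits at -/+ infinity
    expect_lt(abs(lf$v_of_xi(-60 / lf$rate)), 1e-12)
    expect_equal(lf$v_of_xi(60 / lf$rate), lf$v_plus, tolerance = 1e-12)
  }
  # balanced Allee threshold makes the layer stationary on both branches
  pb <- model_params(0.5, 0.1, 4, 0, 70, 1, 0.01)
  expect_equal(layer_front(0, 1, pb)$speed, 0)
  expect_equal(layer_front(0, 0, pb)$speed, 0)
  # branch/w incompatibility is rejected
  expect_error(layer_front(0.3, 1, model_params(0.2, 0.1, 4, 0, 70, 1, 0.01)),
               "branch 1")
})

test_that("layer speed matches the independent shooting oracle", {
  p <- model_params(0.1, 0.1, 1, 0, 70, 1, 0.01)
  expect_equal(layer_front(0, 1, p)$speed, sqrt(0.2) * 0.4,
               tolerance = 1e-14)
  expect_equal(oracle_layer_speed(0, 1, p), 0.17889, tolerance = 1e-4)
  set.seed(22)
  n_done <- 0
  while (n_done < 8) {
    p <- random_params()
    branch <- sample(0:1, 1)
    wmax <- min(if (p$delta2 > 0) p$rho * (1 - p$a)^2 / (4 * p$delta2)
                else 0.5,
                if (branch == 1) 0.999 / p$delta1 else 0.5)
    w <- runif(1, 0, 0.8 * wmax)
    cf <- layer_front(w, branch, p)$speed
    if (cf < 0.02) next    # shooting bisection assumes a rightward front
    expect_equal(oracle_layer_speed(w, branch, p), cf, tolerance = 1e-6)
    n_done <- n_done + 1
  }
})

test_that("slow Hamiltonians: normalization, closed form at delta2 = 0, conservation", {
  p <- model_params(0.3, 0.1, 4, 0.1, 70, 1, 0.01)
  Vp <- equilibrium_V(p)[["V_plus"]]
  expect_equal(hamiltonian(0, 0, "M0", p), 0)
  expect_equal(hamiltonian(Vp, 0, "Mplus", p), 0, tolerance = 1e-14)
  # delta2 = 0: v+ = 1 makes the load integral linear
  p0 <- model_params(0.3, 0.1, 4, 0, 70, 1, 0.01)
  w <- 0.37; pp <- 1.1
  expect_equal(hamiltonian(w, pp, "Mplus", p0),
               pp^2 / 2 - 70 * w^2 / 2 + 70 / 2 + 70 * (w - 1),
               tolerance = 1e-12)
  # closed-form load integral agrees with adaptive quadrature
  integrand <- function(z)
    70 * (1 + p$a + sqrt((1 - p$a)^2 - 4 * p$delta2 * z / p$rho)) / 2
  quad <- integrate(integrand, Vp, 0.3, rel.tol = 1e-12)$value
  expect_equal(hamiltonian(0.3, 0, "Mplus", p) -
                 hamiltonian(0.3, 0, "M0", p) - 70 * Vp^2 / 2,
               quad, tolerance = 1e-10)
  # conservation along independently integrated reduced orbits
  rhs0 <- function(t, y, q) list(c(y[2], 70 * y[1]))
  sol <- deSolve::ode(c(w = 0.2, p = sqrt(70) * 0.2),
                      seq(0, 0.1, length.out = 51), rhs0, NULL,
                      method = "ode45", rtol = 1e-12, atol = 1e-13)
  E0 <- hamiltonian(sol[, 2], sol[, 3], "M0", p)
  expect_lt(max(abs(E0 - E0[1])), 1e-9)
  vb <- function(w) (1 + p$a + sqrt((1 - p$a)^2 - 4 * p$delta2 * w / p$rho)) / 2
  rhsP <- function(t, y, q) list(c(y[2], -70 * (vb(y[1]) - y[1])))
  ws <- solve_w_star(p)
  solP <- deSolve::ode(c(w = ws[["w_star"]], p = ws[["p_star"]]),
                       seq(0, 0.3, length.out = 101), rhsP, NULL,
                       method = "ode45", rtol = 1e-12, atol = 1e-13)
  EP <- hamiltonian(solP[, 2], solP[, 3], "Mplus", p)
  expect_lt(max(abs(EP)), 1e-9)
})

test_that("matching level w*: exact at delta2 = 0, quadrature oracle, energy zero, monotone in delta2", {
  p0 <- model_params(0.17, 0.1, 4, 0, 70, 1, 0.01)
  expect_equal(solve_w_star(p0)[["w_star"]], 0.5, tolerance = 1e-12)
  p <- model_params(0.35, 0.1, 12.5, 0.1, 70, 1, 0.0063)
  ws <- solve_w_star(p)
  expect_equal(ws[["w_star"]], oracle_w_star(p), tolerance = 1e-10)
  expect_gt(p$delta1 * ws[["w_star"]], 1)          # gap at these parameters
  expect_lt(abs(hamiltonian(ws[["w_star"]], ws[["p_star"]], "Mplus", p)),
            1e-10)
  # w* does not increase with the acid toxicity to tumor cells
  ws_seq <- vapply(seq(0, 0.3, by = 0.05), function(d2)
    solve_w_star(model_params(0.2, 0.1, 4, d2, 70, 1, 0.01))[["w_star"]],
    0)
  expect_true(all(diff(ws_seq) <= 1e-12))
})

test_that("slow orbits live on the invariant manifolds and reach the equilibria", {
  p <- model_params(0.25, 0.1, 4, 0.1, 70, 1, 0.01)
  ws <- solve_w_star(p)[["w_star"]]
  m0 <- slow_orbit("M0", p, ws)
  expect_equal(m0$w[length(m0$w)], ws, tolerance = 1e-12)
  expect_lt(max(abs(m0$p / m0$w - sqrt(70))), 1e-12)
  mp <- slow_orbit("Mplus", p, ws)
  expect_lt(max(abs(hamiltonian(mp$w, mp$p, "Mplus", p))), 1e-9)
  Vp <- equilibrium_V(p)[["V_plus"]]
  expect_equal(mp$w[length(mp$w)], Vp, tolerance = 1e-6)
  expect_lt(abs(mp$p[length(mp$p)]), 1e-5)
})

test_that("singular fronts concatenate the regime-specific segments", {
  benign <- singular_front(model_params(0.2, 0.1, 0.5, 0, 70, 1, 0.01))
  expect_identical(benign$segments$kind,
                   c("slow_M0_1", "jump", "slow_Mplus_1"))
  expect_equal(benign$gap_width_zeta, 0)
  nogap <- singular_front(model_params(0.2, 0.1, 1.5, 0, 70, 1, 0.01))
  expect_identical(nogap$segments$kind,
                   c("slow_M0_1", "jump", "slow_Mplus_1", "slow_Mplus_0"))
  gap <- singular_front(model_params(0.2, 0.1, 4, 0, 70, 1, 0.01))
  expect_identical(gap$segments$kind,
                   c("slow_M0_1", "slow_M0_0", "jump", "slow_Mplus_0"))
  expect_equal(gap$gap_width_zeta, log(2) / sqrt(70), tolerance = 1e-12)
  # gap jump happens on the tumor-only subspace at the corrected speed
  expect_equal(gap$c_star, layer_front(0.5, 0, gap$params)$speed)
  # crossover flagged as degenerate
  dg <- singular_front(model_params(0.2, 0.1, 2, 0, 70, 1, 0.01))
  expect_true(dg$degenerate)
})

test_that("sampled singular profile matches the segment structure", {
  p <- model_params(0.2, 0.1, 4, 0, 70, 1, 0.01)
  sf <- singular_front(p)
  zeta <- seq(-1, 1, length.out = 801)
  prof <- sample_singular_profile(sf, zeta)
  left <- prof$zeta < 0
  expect_true(all(prof$v[left] == 0))
  expect_true(all(prof$u[!left] == 0))            # tumor-only behind the jump
  gapzone <- prof$u < 1e-12 & prof$v < 1e-12
  expect_equal(diff(range(prof$zeta[gapzone])), sf$gap_width_zeta,
               tolerance = 0.02)
})

test_that("gap-onset boundary is the reciprocal matching level and flips the regime", {
  p0 <- model_params(0.23, 0.1, 4, 0, 70, 1, 0.01)
  expect_equal(gap_boundary_delta1(p0), 2, tolerance = 1e-10)
  p <- model_params(0.1, 0.1, 4, 0.1, 70, 1, 0.01)
  d1c <- gap_boundary_delta1(p)
  expect_equal(d1c, 1 / solve_w_star(p)[["w_star"]], tolerance = 1e-10)
  below <- classify_regime(update_params(p, delta1 = d1c - 1e-6))$kind
  above <- classify_regime(update_params(p, delta1 = d1c + 1e-6))$kind
  expect_identical(below, "malignant_no_gap")
  expect_identical(above, "malignant_gap")
})
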