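test_that("linearization annihilates the translation mode and carries the ell^2 penalty", {
  tw <- cached_front("fig1")
  op <- cached_op0("fig1")
  r <- as.vector(op$A %*% op$translation)
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(op$translation^2)), 0.2)
  # the eigenvalue realizing translation invariance is tiny
  sp <- spectrum(tw, 0, count = 12, op = op)
  ev <- sp$eigenvalues
  expect_true(any(ev$is_translational))
  expect_lt(abs(ev$re[which(ev$is_translational)[1]]), 1e-5)
  # transverse terms enter exactly as -ell^2 diag(0, 1+kappa-u, 1/eps^2)
  opl <- assemble_linearization(tw, 0.3)
  x <- sin(seq_len(nrow(op$A)))
  d <- as.vector((op$A - opl$A) %*% x)
  pen <- as.vector((0.3^2 * transverse_penalty(op)) %*% x)
  expect_equal(d, pen, tolerance = 1e-12)
})

test_that("end-state essential spectrum is damped for the gap presets", {
  p <- load_preset("fig1")$params
  Vp <- equilibrium_V(p)[["V_plus"]]
  ks <- seq(0, 20, length.out = 81)
  expect_true(all(dispersion_relation(c(1, 0, 0), ks, p) < 0))
  expect_true(all(dispersion_relation(c(0, Vp, Vp), ks, p) < 0))
})

test_that("adjoint null solution: Fredholm orthogonality, fast-field form, scale invariance", {
  tw <- cached_front("fig1")
  op <- cached_op0("fig1")
  adj <- cached_adjoint("fig1")
  expect_lt(adj$eig_residual, 1e-6)
  # discrete Fredholm orthogonality of the translation image (normalized
  # by the field sizes; the image itself is already near zero)
  t_img <- as.vector(op$A %*% op$translation)
  expect_lt(abs(sum(t_img * adj$y)) /
              (sqrt(sum(op$translation^2)) * sqrt(sum(adj$y^2))), 1e-6)
  # random decaying test fields are orthogonal to the adjoint after L
  set.seed(31)
  for (k in 1:5) {
    phi <- rnorm(nrow(op$A)) * rep(exp(-abs(op$xi) / 40), 3)
    img <- as.vector(op$A %*% phi)
    expect_lt(abs(sum(img * adj$y)) / sqrt(sum(img^2)), 1e-6)
  }
  # in the fast field the v-component is proportional to
  # v_h' exp(-c xi / (1+kappa-u_*))
  lay <- tw$singular$layer
  sel <- abs(op$xi) < 1 / lay$rate
  pred <- op$derivs$dv[sel] *
    exp(-tw$c * op$xi[sel] / (1 + tw$params$kappa - lay$u_star))
  ratio <- adj$v_A[sel] / pred
  expect_lt(stats::sd(ratio) / abs(mean(ratio)), 0.05)
  # quotient invariance under adjoint rescaling
  l2 <- lambda_c2(tw, adj)
  adj2 <- adj
  for (f in c("u_A", "v_A", "w_A")) adj2[[f]] <- 7.3 * adj2[[f]]
  expect_equal(as.numeric(lambda_c2(tw, adj2)), as.numeric(l2),
               tolerance = 1e-12)
})

test_that("transverse coefficient: sign by regime and mesh robustness", {
  tw <- cached_front("fig1")
  l2 <- as.numeric(lambda_c2(tw, cached_adjoint("fig1")))
  expect_gt(l2, 0)                               # gap fronts destabilize
  # mesh doubling moves lambda_c2 by well under 2%
  p <- tw$params
  xi2 <- default_mesh(p, tw$singular, h_fine = 0.12)
  tw2 <- solve_front(p, guess = initial_guess(p, xi = xi2))
  l2b <- as.numeric(lambda_c2(tw2))
  expect_lt(abs(l2b - l2) / abs(l2), 0.02)
  # benign coexistence front with weak acid: transversally stable
  pb <- model_params(0.1, 0.1, 0.6, 0.1, 70, 1, 0.0063)
  twb <- solve_front(pb)
  l2n <- as.numeric(lambda_c2(twb))
  expect_lt(l2n, 0)
  expect_identical(sign(lambda_c2_asymptotic(pb)$value), sign(l2n))
})

test_that("critical curve: zero datum, quadratic regime, turnaround", {
  tw <- cached_front("fig1")
  lc <- lambda_curve(tw, op0 = cached_op0("fig1"))   # quadratic window
  expect_equal(lc$curve$lambda[1], 0)
  expect_equal(lc$fit$lambda2, lc$lambda_c2, tolerance = 0.05)
  expect_gt(lc$fit$r_squared, 0.999)
  lcw <- lambda_curve(tw, ell_max = 10 * tw$params$eps, n_points = 10,
                      op0 = cached_op0("fig1"))      # wide window
  lam <- lcw$curve$lambda
  # unstable band: positive at small ell, eventually decreasing
  expect_true(all(lam[2:4] > 0))
  expect_lt(lam[length(lam)], max(lam))
})

test_that("singular asymptotics: gap instability, neutral delta2 = 0 limit, no-gap both signs", {
  # any gap case with delta2 > 0 is long-wavelength unstable
  for (pars in list(c(0.1, 0.1), c(0.2, 0.2), c(0.35, 0.1))) {
    p <- model_params(pars[1], 0.1, 12.5, pars[2], 70, 1, 0.0063)
    la <- lambda_c2_asymptotic(p)
    expect_identical(la$regime, "malignant_gap")
    expect_gt(la$value, 0)
  }
  # gap with delta2 = 0: both criterion terms vanish identically
  la0 <- lambda_c2_asymptotic(model_params(0.2, 0.1, 4, 0, 70, 1, 0.01))
  expect_equal(la0$criterion_integral, 0, tolerance = 1e-14)
  # no-gap fronts admit either sign
  neg <- lambda_c2_asymptotic(model_params(0.1, 0.1, 1.5, 0.05, 70, 1,
                                           0.0063))
  expect_identical(neg$regime, "malignant_no_gap")
  expect_lt(neg$value, 0)
  pos <- lambda_c2_asymptotic(model_params(0.1, 0.1, 2, 0.3, 70, 1,
                                           0.0063))
  expect_identical(pos$regime, "malignant_no_gap")
  expect_gt(pos$value, 0)
  # degenerate crossover declined
  expect_error(lambda_c2_asymptotic(model_params(0.2, 0.1, 2, 0, 70, 1,
                                                 0.01)),
               "degenerate")
})
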