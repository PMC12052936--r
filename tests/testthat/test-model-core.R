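test_that("reaction terms vanish at kinetic equilibria and reject bad input", {
  p <- load_preset("fig1")$params
  expect_equal(unlist(reaction_terms(1, 0, 0, p)), c(F = 0, G = 0, H = 0))
  expect_equal(unlist(reaction_terms(0, 0, 0, p)), c(F = 0, G = 0, H = 0))
  expect_equal(reaction_terms(0, 1, 0, p)$H, 70)
  expect_error(reaction_terms(NaN, 0, 0, p), "non-finite")
})

test_that("parameter constructor validates ranges and warns on delta2 >= delta1", {
  expect_error(model_params(1.2, 0.1, 1, 0, 70, 1, 0.01), "Allee")
  expect_error(model_params(0.1, 0.1, 1, -0.1, 70, 1, 0.01), "delta2")
  expect_warning(model_params(0.1, 0.1, 1, 2, 70, 1, 0.01),
                 "delta2 < delta1")
  p <- update_params(load_preset("fig1")$params, delta1 = 3)
  expect_equal(p$delta1, 3)
  expect_error(update_params(p, nonsense = 1), "unknown parameter")
})

test_that("equilibrium densities match an independent root-find", {
  # delta2 = 0 collapses to (1, a)
  p0 <- model_params(0.27, 0.1, 1, 0, 70, 1, 0.01)
  expect_equal(unname(equilibrium_V(p0)), c(1, 0.27), tolerance = 1e-14)
  # generic case against direct root-finding of rho(1-V)(V-a) = delta2 V
  p <- model_params(0.1, 0.1, 1, 0.1, 70, 1.0, 0.01)
  V <- equilibrium_V(p)
  Vo <- oracle_equilibrium_V(0.1, 1.0, 0.1)
  expect_equal(V[["V_plus"]], Vo[["V_plus"]], tolerance = 1e-10)
  expect_equal(V[["V_minus"]], Vo[["V_minus"]], tolerance = 1e-10)
  expect_equal(V[["V_plus"]], 0.8873, tolerance = 1e-4)
  # defining relation holds to near machine precision
  for (vv in V)
    expect_lt(abs(p$rho * (1 - vv) * (vv - p$a) - p$delta2 * vv), 1e-12)
  # negative discriminant: no nontrivial equilibria
  pbad <- suppressWarnings(model_params(0.1, 0.1, 1, 0.8, 70, 1, 0.01))
  expect_null(equilibrium_V(pbad))
})

test_that("steady-state stability reproduces the stated pattern over a random sweep", {
  set.seed(11)
  n_ok <- 0
  for (k in 1:1000) {
    p <- random_params()
    ss <- steady_states(p)
    V <- equilibrium_V(p)
    if (is.null(V)) next
    n_ok <- n_ok + 1
    # kinetics residual at every returned state
    for (i in seq_len(nrow(ss))) {
      r <- reaction_terms(ss$U[i], ss$V[i], ss$W[i], p)
      expect_lt(max(abs(unlist(r))), 1e-12)
    }
    get_stab <- function(lab) ss$stability[ss$label == lab]
    expect_identical(get_stab("P2"), "stable")
    expect_identical(get_stab("P1"), "unstable")
    expect_identical(get_stab("P3-"), "unstable")
    expect_identical(get_stab("P4-"), "unstable")
    mi <- p$delta1 * V[["V_plus"]]
    if (abs(mi - 1) > 1e-6) {
      expect_identical(get_stab("P3+"), if (mi < 1) "stable" else "unstable")
      expect_identical(get_stab("P4+"), if (mi > 1) "stable" else "unstable")
    }
  }
  expect_gt(n_ok, 500)
})

test_that("benign P3+ at delta2 = 0 is the coexistence state", {
  p <- model_params(0.2, 0.1, 0.5, 0, 70, 1, 0.01)
  ss <- steady_states(p)
  row <- ss[ss$label == "P3+", ]
  expect_equal(c(row$U, row$V, row$W), c(0.5, 1, 1), tolerance = 1e-14)
  expect_identical(row$stability, "stable")
  expect_true(row$relevant)
})

test_that("regime classification is exhaustive, exclusive, and has exact delta2 = 0 boundaries", {
  base <- function(d1) model_params(0.2, 0.1, d1, 0, 70, 1, 0.01)
  expect_identical(classify_regime(base(0.5))$kind, "benign")
  expect_identical(classify_regime(base(1.5))$kind, "malignant_no_gap")
  expect_identical(classify_regime(base(4))$kind, "malignant_gap")
  # exact switch points: delta1 V+ = 1 at delta1 = 1; delta1 w* = 1 at 2
  expect_identical(classify_regime(base(1 - 1e-6))$kind, "benign")
  expect_identical(classify_regime(base(1 + 1e-6))$kind, "malignant_no_gap")
  expect_identical(classify_regime(base(2 - 1e-6))$kind, "malignant_no_gap")
  expect_identical(classify_regime(base(2 + 1e-6))$kind, "malignant_gap")
  expect_identical(classify_regime(base(2))$kind, "degenerate_crossover")
  # published gap example
  expect_identical(classify_regime(load_preset("fig1")$params)$kind,
                   "malignant_gap")
  # exhaustive and exclusive over random draws
  set.seed(12)
  kinds <- c("benign", "malignant_no_gap", "malignant_gap",
             "degenerate_crossover", "no_front")
  for (k in 1:200) {
    p <- random_params()
    reg <- classify_regime(p)
    expect_true(reg$kind %in% kinds)
    if (reg$kind %in% c("benign")) expect_lt(reg$malignancy_index, 1)
    if (startsWith(reg$kind, "malignant"))
      expect_gt(reg$malignancy_index, 1)
    if (reg$kind == "malignant_gap")
      expect_gt(reg$w_star, 1 / p$delta1)
    if (reg$kind == "malignant_no_gap")
      expect_lt(reg$w_star, 1 / p$delta1)
  }
  # no front when the nontrivial equilibria vanish
  pbad <- suppressWarnings(model_params(0.1, 0.1, 1, 0.8, 70, 1, 0.01))
  expect_identical(classify_regime(pbad)$kind, "no_front")
})

test_that("homogeneous dispersion relation reduces to kinetics at k = 0 and is diffusion-damped", {
  p <- load_preset("fig1")$params
  ss <- steady_states(p)
  p2 <- c(1, 0, 0)
  expect_equal(dispersion_relation(p2, 0, p),
               ss$max_re_eig[ss$label == "P2"], tolerance = 1e-10)
  # large-k modes are strongly damped by the acid diffusion
  expect_lt(dispersion_relation(p2, 10, p), dispersion_relation(p2, 0, p))
})
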