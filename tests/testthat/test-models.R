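# Right-hand sides: hand-evaluated values, structural properties, validation.

test_that("two-species competition RHS matches hand evaluation", {
  # manual substitution: dX = X(alpha - gamma (X+Y)), dY = Y(beta - gamma (X+Y))
  expect_equal(rhs_lv2(c(0.5, 0.2), params_lv2(0.3, 0.1, 0.4)),
               c(X = 0.01, Y = -0.036), tolerance = 1e-12)
  # absorbing origin and symmetry under equal growth rates
  expect_equal(unname(rhs_lv2(c(0, 0), params_lv2(0.7, 0.2, 0.9))), c(0, 0))
  d <- rhs_lv2(c(0.3, 0.3), params_lv2(0.4, 0.4, 0.5))
  expect_equal(d[["X"]], d[["Y"]])
  expect_error(rhs_lv2(c(-0.1, 0.2), params_lv2(0.3, 0.1, 0.4)),
               "nonnegative")
})

test_that("model A RHS matches hand evaluation and degenerate cases", {
  p <- pars_a()
  expect_equal(rhs_model_a(c(0.1, 0.1, 0.1, 0.05, 0.05), p),
               c(S = 0.02, A = -0.008, D = -0.01, L = 0.01, T = -0.015),
               tolerance = 1e-12)
  expect_equal(unname(rhs_model_a(rep(0, 5), p)), rep(0, 5))
  p0 <- pars_a(a1 = 0, b1 = 0, c1 = 0, e1 = 0, f = 0, a2 = 0, b2 = 0, g = 0)
  expect_equal(unname(rhs_model_a(c(0.2, 0.1, 0.3, 0.1, 0.1), p0)), rep(0, 5))
})

test_that("model A growth terms vanish at full niche: dZ/dt <= 0 at Z = K", {
  set.seed(42)
  for (i in 1:25) {
    p <- c(stats::setNames(runif(8), param_names("modelA")), K = 1)
    s <- runif(5)
    s <- s / sum(s)  # Z = K exactly
    d <- suppressWarnings(rhs_model_a(s, p))
    expect_lte(sum(d), 1e-12)
  }
})

test_that("no component flows negative at its own extinction boundary", {
  set.seed(43)
  for (i in 1:20) {
    pa <- c(stats::setNames(runif(8), param_names("modelA")), K = 1)
    pb <- stats::setNames(runif(13), param_names("modelB"))
    for (k in 1:5) {
      s <- runif(5) * 0.15
      s[k] <- 0
      expect_gte(suppressWarnings(rhs_model_a(s, pa))[[k]], 0)
      expect_gte(suppressWarnings(rhs_model_b(s, pb))[[k]], 0)
    }
  }
})

test_that("model A leukaemia equation mirrors the stem equation under renaming", {
  set.seed(44)
  for (i in 1:20) {
    p <- c(stats::setNames(runif(8), param_names("modelA")), K = 1)
    s <- runif(5) * 0.18
    d <- suppressWarnings(rhs_model_a(s, p))
    # swap the species S <-> L and the arm parameters (a1,b1) <-> (a2,b2):
    # the L-derivative must turn into the S-derivative exactly
    s_sw <- s[c(4, 2, 3, 1, 5)]
    d_sw <- suppressWarnings(rhs_model_a(s_sw, arm_swap_a(p)))
    expect_equal(d_sw[["L"]], d[["S"]], tolerance = 1e-14)
    expect_equal(d_sw[["S"]], d[["L"]], tolerance = 1e-14)
  }
})

test_that("feedback multipliers are 1 at zero occupancy and decay correctly", {
  expect_equal(unname(feedback_terms(rep(0, 5))), rep(1, 3))
  expect_equal(unname(feedback_terms(c(0.5, 0.2, 0.1, 0.3, 0.4),
                                     gammas = c(0, 0, 0))), rep(1, 3))
  # phi1 sees only S+L; phi2/phi3 see only A+D+T
  f1 <- feedback_terms(c(0.1, 0.2, 0.1, 0.1, 0.1))
  f2 <- feedback_terms(c(0.4, 0.2, 0.1, 0.1, 0.1))  # S increased
  expect_lt(f2[["phi1"]], f1[["phi1"]])
  expect_equal(f2[["phi2"]], f1[["phi2"]])
  expect_equal(f2[["phi3"]], f1[["phi3"]])
  # strict bounds on reachable states
  set.seed(45)
  for (i in 1:20) {
    f <- feedback_terms(runif(5) * 100)
    expect_true(all(f > 0 & f <= 1))
  }
})

test_that("model B RHS matches hand evaluation", {
  s <- c(S = 0.2, A = 0.3, D = 0.1, L = 0.1, T = 0.05)
  # frozen by substituting into the fate-resolved equations by hand
  expect_equal(rhs_model_b(s, pars_b()),
               c(S = 0.059820135067, A = -0.010089797803,
                 D = 0.104461213180, L = -0.000015078520,
                 T = 0.074640808786),
               tolerance = 1e-10)
  expect_equal(unname(rhs_model_b(rep(0, 5), pars_b())), rep(0, 5))
})

test_that("leukaemia compartments are an invariant subspace of model B", {
  p <- pars_b(kap1 = 0, kap2 = 0, kap3 = 0, nu4 = 0)
  d <- rhs_model_b(c(0.3, 0.2, 0.1, 0, 0), p)
  expect_identical(unname(d[c("L", "T")]), c(0, 0))
  tr <- integrate_model("modelB", p, init = c(S = 0.05, A = 0, D = 0,
                                              L = 0, T = 0))
  expect_equal(max(tr$states[, c("L", "T")]), 0)
})

test_that("parameter validation enforces the documented contracts", {
  expect_error(params_model_a(0.5, 0.1, 0.2, 0.3, 0.4, 0.5, 0.1, 0.4, K = 0),
               "K must be > 0")
  expect_error(rhs_model_a(c(0.1, -0.2, 0.1, 0.1, 0.1), pars_a()),
               "nonnegative")
  expect_error(params_lv2(-0.1, 0.2, 0.3), "nonnegative")
  # rates above 1 warn (outside prior support) but are accepted
  expect_warning(params_model_a(1.5, 0.1, 0.2, 0.3, 0.4, 0.5, 0.1, 0.4),
                 "prior")
  expect_error(model_info("modelC"), "unknown model")
})

test_that("parameter vectors round-trip through flat CSV", {
  p <- pars_b()
  path <- withr::local_tempfile(fileext = ".csv")
  write_params_csv(p, path)
  back <- read_params_csv(path, model = "modelB")
  expect_identical(names(back), names(p))
  expect_equal(unlist(back[1, ]), p)
})
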