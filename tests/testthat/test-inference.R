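# Prior sampling, behavioural distance, rejection ABC and ABC-SMC, validated
# against the closed-form toy posterior and a long-run rejection sampler.

test_that("prior draws respect bounds and uniform moments", {
  pr <- prior_spec("modelA")
  th <- sample_prior(pr, 200, seed = 301)
  expect_true(all(th >= 0 & th <= 1))
  expect_identical(colnames(th), param_names("modelA"))
  # determinism under seed
  expect_identical(th, sample_prior(pr, 200, seed = 301))
  # degenerate bounds give constant draws
  prd <- prior_spec(lower = c(r = 0.3), upper = c(r = 0.3))
  expect_equal(unname(sample_prior(prd, 10, seed = 1)[, 1]), rep(0.3, 10))
  # empirical mean over 1e5 8-dimensional draws within 3 standard errors of 1/2
  big <- sample_prior(prior_spec("modelA"), 1e5, seed = 302)
  se <- sqrt(1 / 12 / length(big))
  expect_lt(abs(mean(big) - 0.5), 3 * se)
})

test_that("behavioural distance is zero exactly on the target and monotone", {
  crit <- criteria_spec()
  hit <- fake_traj(c(S = 0.3, A = 0.2, D = 0.1, L = 0, T = 0))
  expect_identical(qualitative_distance(hit, crit), 0)
  # exactly at the thresholds still satisfies
  at <- fake_traj(c(S = 0.01, A = 0.01, D = 0.01, L = 1e-3, T = 1e-3))
  expect_identical(qualitative_distance(at, crit), 0)
  # frozen hand evaluation: S short by half, L over threshold
  v <- fake_traj(c(S = 0.005, A = 0.05, D = 0.2, L = 0.002, T = 0))
  expect_equal(qualitative_distance(v, crit), 1.19314718056, tolerance = 1e-10)
  # monotone in each leukaemic surplus
  worse <- fake_traj(c(S = 0.005, A = 0.05, D = 0.2, L = 0.004, T = 0))
  expect_gt(qualitative_distance(worse, crit), qualitative_distance(v, crit))
  # and in each healthy shortfall
  worse2 <- fake_traj(c(S = 0.002, A = 0.05, D = 0.2, L = 0.002, T = 0))
  expect_gt(qualitative_distance(worse2, crit), qualitative_distance(v, crit))
  # degenerate runs get the finite ceiling penalty
  expect_equal(qualitative_distance(
    fake_traj(c(S = 1, A = 1, D = 1, L = 1, T = 1), unbounded = TRUE), crit),
    100)
  expect_equal(qualitative_distance(
    fake_traj(c(S = 0.3, A = 0.3, D = 0.3, L = 0, T = 0), steady = FALSE),
    crit), 100)
})

test_that("rejection ABC at infinite tolerance reproduces the prior", {
  toy <- toy_abc_problem()
  pop <- abc_rejection("toy", prior = toy$prior, criteria = toy$criteria,
                       settings = toy$settings, epsilon = 100,
                       n_accept = 400, seed = 303, init = toy$init)
  expect_equal(pop$acceptance_rate, 1)
  expect_lt(ks_uniform_distance(pop, 0, 1), 0.07)
  expect_equal(sum(pop$weight), 1)
})

test_that("rejection ABC recovers the analytic behaviour region of the toy problem", {
  toy <- toy_abc_problem()
  expect_equal(toy$r_star, 0.5)
  pop <- abc_rejection("toy", prior = toy$prior, criteria = toy$criteria,
                       settings = toy$settings, epsilon = 0,
                       n_accept = 400, seed = 304, init = toy$init)
  # accepted rates all at or above the closed-form cutoff
  expect_gte(min(pop$theta), toy$r_star)
  # acceptance rate matches the prior mass of the region within 3 binomial SE
  trials <- 400 / pop$acceptance_rate
  se <- sqrt(toy$prior_mass * (1 - toy$prior_mass) / trials)
  expect_lt(abs(pop$acceptance_rate - toy$prior_mass), 3 * se)
})

test_that("an unattainable tolerance aborts with a diagnostic", {
  toy <- toy_abc_problem(eps = 1e-30)  # cutoff far outside the prior
  expect_error(
    abc_rejection("toy", prior = toy$prior, criteria = toy$criteria,
                  settings = toy$settings, epsilon = 0, n_accept = 5,
                  seed = 305, init = toy$init, min_accept_rate = 1e-3),
    "acceptance rate")
})

test_that("a single SMC generation at open tolerance is prior sampling", {
  toy <- toy_abc_problem()
  fit <- abc_fit("toy", prior = toy$prior, criteria = toy$criteria,
                 settings = toy$settings, n_particles = 400,
                 n_generations = 1, seed = 306, init = toy$init)
  expect_length(fit$generations, 1)
  expect_lt(ks_uniform_distance(fit$final, 0, 1), 0.07)
})

test_that("SMC populations satisfy the construction invariants", {
  fit <- cached_fit("toy")
  sched <- abc_schedule(fit)
  # tolerances never increase
  expect_true(all(diff(sched$epsilon) <= 0))
  for (g in fit$generations) {
    expect_equal(sum(g$weight), 1)
    expect_gt(g$ess, 1)
    expect_true(all(g$distance <= g$epsilon))
    # prior-support invariance
    expect_true(all(g$theta >= 0 & g$theta <= 1))
  }
  # acceptance regions nest: final particles satisfy every earlier tolerance
  expect_true(all(fit$final$distance <= min(sched$epsilon)))
})

test_that("SMC and long-run rejection agree on the toy posterior", {
  toy <- toy_abc_problem()
  fit <- cached_fit("toy")
  expect_identical(fit$final$epsilon, 0)
  rej <- abc_rejection("toy", prior = toy$prior, criteria = toy$criteria,
                       settings = toy$settings, epsilon = 0,
                       n_accept = 1000, seed = 307, init = toy$init)
  ks <- ks_two_sample_weighted(fit$final$theta[, 1], fit$final$weight,
                               rej$theta[, 1], rej$weight)
  expect_lt(ks, 0.07)
})

test_that("posterior-predictive re-simulation reproduces the stored distances", {
  fit <- cached_fit("toy")
  idx <- seq(1, 1000, by = 50)
  toy <- toy_abc_problem()
  for (i in idx) {
    tr <- integrate_model("toy", fit$final$theta[i, ],
                          init = toy$init, settings = toy$settings)
    expect_equal(qualitative_distance(tr, toy$criteria),
                 fit$final$distance[i], tolerance = 1e-12)
  }
})

test_that("the fit object supports the standard modelling verbs", {
  fit <- cached_fit("toy")
  expect_output(print(fit), "Qualitative ABC-SMC")
  s <- summary(fit)
  expect_s3_class(s, "summary.abc_fit")
  expect_true(all(c("mean", "sd") %in% colnames(s$posterior)))
  cf <- coef(fit)
  expect_named(cf, "r")
  # posterior mean of Uniform(0.5, 1) is 0.75
  expect_equal(unname(cf), 0.75, tolerance = 0.03)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "niche_traj")
  labs <- predict(fit)
  expect_s3_class(labs, "factor")
  expect_true(all(labs == "HSC_WIN"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(fit, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 6000)
  expect_true(all(c("generation", "weight", "distance", "r") %in% names(df)))
})

test_that("a seed is mandatory for SMC fits", {
  expect_error(abc_fit("toy", n_particles = 10), "seed is mandatory")
})
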