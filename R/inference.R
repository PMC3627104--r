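# Qualitative ABC: rejection and sequential Monte Carlo samplers that
# approximate the posterior over model parameters conditioned on declared
# behaviour (which species persist, which vanish) instead of observed data.
# The likelihood never appears; a simulated trajectory is compared with the
# behavioural criteria through a distance that is zero exactly on the target
# behaviour.

#' Uniform prior specification
#'
#' Every free rate carries an independent uniform prior, by default on [0,1]
#' (the rates are per-unit-time quantities of order one).  Fixed parameters
#' (the carrying capacity K, the feedback constants gam1-gam3) are excluded
#' from the inference dimensions.
#'
#' @param model Optional registered model name; supplies parameter names and
#'   fixed constants.
#' @param lower,upper Per-parameter bounds (scalars are recycled).
#' @param fixed Named vector of fixed parameters appended to every draw.
#' @return A list of class `"prior_spec"`.
#' @export
prior_spec <- function(model = NULL, lower = 0, upper = 1, fixed = NULL) {
  if (!is.null(model)) {
    m <- model_info(model)
    nm <- m$free
    if (is.null(fixed)) fixed <- m$fixed
  } else {
    nm <- names(lower)
    if (is.null(nm)) nm <- names(upper)
    if (is.null(nm)) stop("without a model, lower or upper must be named")
  }
  lower <- stats::setNames(rep_len(as.numeric(lower), length(nm)), nm)
  upper <- stats::setNames(rep_len(as.numeric(upper), length(nm)), nm)
  if (any(lower > upper)) stop("need lower <= upper for every parameter")
  structure(list(names = nm, lower = lower, upper = upper,
                 fixed = fixed, model = model),
            class = "prior_spec")
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  fn()
}

#' Sample parameter vectors from the prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; draws are deterministic given the seed.
#' @param method `"random"` for i.i.d. uniform draws, `"lhs"` for a Latin
#'   hypercube design (see [lhs_sample()]).
#' @return An `n` x d matrix with parameter names as column names.
#' @export
sample_prior <- function(prior, n, seed = NULL,
                         method = c("random", "lhs")) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  method <- match.arg(method)
  d <- length(prior$names)
  u <- .with_seed(seed, function() {
    if (method == "lhs") lhs::randomLHS(n, d)
    else matrix(stats::runif(n * d), nrow = n)
  })
  theta <- sweep(u, 2, prior$upper - prior$lower, `*`)
  theta <- sweep(theta, 2, prior$lower, `+`)
  colnames(theta) <- prior$names
  theta
}

.in_support <- function(prior, theta) {
  all(theta >= prior$lower & theta <= prior$upper)
}

.full_params <- function(prior, theta) {
  c(stats::setNames(as.numeric(theta), prior$names), prior$fixed)
}

#' Behavioural distance of a trajectory from the criteria
#'
#' The distance is a margin measure, zero exactly when the criteria are
#' satisfied at their thresholds:
#' \deqn{d = \sum_{x \in extinct} \log(1 + \max(0, x_{end}/K - \epsilon)/\epsilon)
#'        + \sum_{x \in viable} \max(0, \delta - x_{end}/K)/\delta}
#' with \eqn{\epsilon} = `extinct_eps` and \eqn{\delta} = `viable_delta`.  It
#' is strictly increasing in every surplus of a required-extinct population
#' and in every shortfall of a required-viable one; the log compression keeps
#' runaway-but-bounded populations from dwarfing the finite penalty `d_max`
#' (default 100) charged for unbounded, non-stationary, or failed runs.
#'
#' @param traj A `"niche_traj"` object.
#' @param criteria A [criteria_spec()].
#' @param d_max Penalty for UNBOUNDED / NO_STEADY_STATE / failed runs.
#' @return A nonnegative scalar; 0 iff the target behaviour is achieved.
#' @export
qualitative_distance <- function(traj, criteria = criteria_spec(),
                                 d_max = 100) {
  if (traj$failed || detect_unbounded(traj)) return(d_max)
  if (criteria$require_steady_state && !traj$reached_steady_state)
    return(d_max)
  fs <- traj$final_state / .capacity_scale(traj)
  eps <- criteria$extinct_eps
  delta <- criteria$viable_delta
  d <- sum(log1p(pmax(0, fs[criteria$extinct] - eps) / eps)) +
    sum(pmax(0, delta - fs[criteria$viable]) / delta)
  unname(d)
}

.simulate_distance <- function(model, prior, theta, criteria, settings,
                               init, use_compiled, d_max) {
  traj <- integrate_model(model, .full_params(prior, theta), init = init,
                          settings = settings, use_compiled = use_compiled)
  list(distance = qualitative_distance(traj, criteria, d_max = d_max),
       label = classify_outcome(traj, criteria))
}

.new_population <- function(theta, weight, distance, label, epsilon,
                            generation, acceptance_rate) {
  weight <- weight / sum(weight)
  structure(list(theta = theta, weight = weight, distance = distance,
                 label = label, epsilon = epsilon, generation = generation,
                 acceptance_rate = acceptance_rate,
                 ess = 1 / sum(weight^2)),
            class = "abc_population")
}

#' @export
print.abc_population <- function(x, ...) {
  cat(sprintf("<abc_population> generation %d: %d particles, eps = %.4g, ",
              x$generation, nrow(x$theta), x$epsilon),
      sprintf("acceptance = %.3f, ESS = %.1f\n", x$acceptance_rate, x$ess))
  invisible(x)
}

#' Rejection ABC
#'
#' Draws from the prior, simulates, and accepts while the behavioural
#' distance is at most `epsilon`, until `n_accept` particles are collected.
#' Accepted particles carry uniform weights.
#'
#' @inheritParams regime_map
#' @param epsilon Acceptance tolerance (>= 0).
#' @param n_accept Number of particles to collect.
#' @param d_max Penalty distance for degenerate runs (see
#'   [qualitative_distance()]).
#' @param min_accept_rate Diagnostic floor: the sampler aborts with an error
#'   once the running acceptance rate can no longer reach this floor.
#' @return An `"abc_population"` object (generation 1).
#' @export
abc_rejection <- function(model, prior = prior_spec(model),
                          criteria = criteria_spec(),
                          settings = solver_settings(),
                          epsilon, n_accept, seed,
                          init = default_init_state(model),
                          use_compiled = TRUE, d_max = 100,
                          min_accept_rate = 1e-5) {
  stopifnot(epsilon >= 0, n_accept >= 1)
  .with_seed(seed, function() {
    max_trials <- ceiling(n_accept / min_accept_rate)
    acc_theta <- matrix(NA_real_, n_accept, length(prior$names),
                        dimnames = list(NULL, prior$names))
    acc_dist <- numeric(n_accept)
    acc_label <- character(n_accept)
    n_acc <- 0L
    trials <- 0L
    while (n_acc < n_accept) {
      batch <- min(1000L, max_trials - trials)
      if (batch <= 0L)
        stop("rejection-ABC acceptance rate fell below ", min_accept_rate,
             " (", n_acc, "/", n_accept, " particles after ", trials,
             " trials); epsilon = ", epsilon, " is likely unattainable")
      theta <- sample_prior(prior, batch)
      for (i in seq_len(batch)) {
        trials <- trials + 1L
        sim <- .simulate_distance(model, prior, theta[i, ], criteria,
                                  settings, init, use_compiled, d_max)
        if (sim$distance <= epsilon) {
          n_acc <- n_acc + 1L
          acc_theta[n_acc, ] <- theta[i, ]
          acc_dist[n_acc] <- sim$distance
          acc_label[n_acc] <- sim$label
          if (n_acc == n_accept) break
        }
      }
    }
    .new_population(acc_theta, rep(1 / n_accept, n_accept), acc_dist,
                    acc_label, epsilon, 1L, n_accept / trials)
  })
}

# Adaptive tolerance: weighted median of the previous generation's distances
# restricted to those strictly below the previous tolerance.  The restriction
# guarantees a strict decrease and steps over distance plateaus (e.g. the
# "every species extinct" region, where all viability shortfalls saturate at
# the same constant); an unrestricted median would stall there.
.next_epsilon <- function(dist, w, prev_eps) {
  if (prev_eps <= 0) return(0)
  below <- dist < prev_eps * (1 - 1e-12)
  if (!any(below)) return(prev_eps)
  .wquantile(dist[below], w[below], 0.5)
}

.wquantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

.wsd <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sqrt(max(0, sum(w * (x - mu)^2)))
}

#' Fit the behaviour-conditioned posterior by ABC-SMC
#'
#' The central fitting function of the package.  A particle population is
#' refined over `n_generations` through a non-increasing tolerance schedule:
#' generation 1 simulates a plain prior sample; each later generation
#' resamples the previous population by weight, perturbs with a component-wise
#' uniform kernel (half-width = `kernel_scale` times the previous
#' population's weighted standard deviation per parameter), discards
#' proposals outside the prior support, accepts at the current tolerance, and
#' weights accepted particles by prior density over the kernel mixture
#' density.  Tolerances adapt as the weighted median of the previous
#' generation's distances; with the margin distance of
#' [qualitative_distance()] the schedule typically reaches 0 within a few
#' generations, after which the remaining generations diffuse the population
#' across the acceptance region, so the final population is an (approximately
#' uniform) sample of the parameter region producing the declared behaviour.
#'
#' @inheritParams abc_rejection
#' @param n_particles Particles per generation (default 1000).
#' @param n_generations Number of generations (default 6); all are run.
#' @param kernel_scale Multiplier on the per-parameter kernel half-width.
#' @param max_trials_factor A generation aborts (with a warning, returning
#'   the completed generations) after `max_trials_factor * n_particles`
#'   proposals.
#' @param verbose Print per-generation progress (epsilon, acceptance, ESS).
#' @return An object of class `"abc_fit"`; see [print.abc_fit()],
#'   [summary.abc_fit()], [coef.abc_fit()], [plot.abc_fit()],
#'   [simulate.abc_fit()], [predict.abc_fit()] and [pca_posterior()].
#' @export
abc_fit <- function(model, prior = prior_spec(model),
                    criteria = criteria_spec(),
                    settings = solver_settings(),
                    n_particles = 1000, n_generations = 6,
                    kernel_scale = 1, seed,
                    init = default_init_state(model),
                    use_compiled = TRUE, d_max = 100,
                    max_trials_factor = 200, verbose = FALSE) {
  stopifnot(n_particles >= 2, n_generations >= 1)
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for ABC runs")
  d <- length(prior$names)
  generations <- .with_seed(seed, function() {
    gens <- vector("list", n_generations)

    # generation 1: plain prior sample (tolerance d_max accepts everything)
    theta <- sample_prior(prior, n_particles)
    dist <- numeric(n_particles)
    label <- character(n_particles)
    for (i in seq_len(n_particles)) {
      sim <- .simulate_distance(model, prior, theta[i, ], criteria,
                                settings, init, use_compiled, d_max)
      dist[i] <- sim$distance
      label[i] <- sim$label
    }
    gens[[1]] <- .new_population(theta, rep(1 / n_particles, n_particles),
                                 dist, label, d_max, 1L, 1)
    if (verbose) print(gens[[1]])

    for (t in seq_len(n_generations - 1L) + 1L) {
      prev <- gens[[t - 1L]]
      eps_t <- .next_epsilon(prev$distance, prev$weight, prev$epsilon)
      sigma <- vapply(seq_len(d),
                      function(k) .wsd(prev$theta[, k], prev$weight),
                      numeric(1))
      sigma <- pmax(sigma * kernel_scale, 1e-9)
      max_trials <- max_trials_factor * n_particles

      acc_theta <- matrix(NA_real_, n_particles, d,
                          dimnames = list(NULL, prior$names))
      acc_dist <- numeric(n_particles)
      acc_label <- character(n_particles)
      n_acc <- 0L
      trials <- 0L
      while (n_acc < n_particles && trials < max_trials) {
        j <- sample.int(nrow(prev$theta), 1L, prob = prev$weight)
        cand <- prev$theta[j, ] + stats::runif(d, -sigma, sigma)
        trials <- trials + 1L
        if (!.in_support(prior, cand)) next
        sim <- .simulate_distance(model, prior, cand, criteria, settings,
                                  init, use_compiled, d_max)
        if (sim$distance <= eps_t) {
          n_acc <- n_acc + 1L
          acc_theta[n_acc, ] <- cand
          acc_dist[n_acc] <- sim$distance
          acc_label[n_acc] <- sim$label
        }
      }
      if (n_acc < n_particles) {
        warning("generation ", t, " filled only ", n_acc, "/", n_particles,
                " particles within ", max_trials, " trials; returning the ",
                t - 1L, " completed generations", call. = FALSE)
        return(gens[seq_len(t - 1L)])
      }
      # importance weights: uniform prior density over kernel mixture density
      w <- numeric(n_particles)
      inv_vol <- prod(1 / (2 * sigma))
      for (i in seq_len(n_particles)) {
        diffs <- abs(sweep(prev$theta, 2, acc_theta[i, ]))
        inside <- rowSums(diffs <= rep(sigma, each = nrow(diffs))) == d
        denom <- sum(prev$weight[inside]) * inv_vol
        w[i] <- if (denom > 0) 1 / denom else 0
      }
      if (all(w == 0)) w <- rep(1, n_particles)
      gens[[t]] <- .new_population(acc_theta, w, acc_dist, acc_label,
                                   eps_t, t, n_particles / trials)
      if (verbose) print(gens[[t]])
    }
    gens
  })

  structure(list(model = model, prior = prior, criteria = criteria,
                 settings = settings, generations = generations,
                 final = generations[[length(generations)]],
                 config = list(n_particles = n_particles,
                               n_generations = n_generations,
                               kernel_scale = kernel_scale, seed = seed,
                               d_max = d_max,
                               max_trials_factor = max_trials_factor),
                 init = init, call = match.call()),
            class = "abc_fit")
}

#' @describeIn abc_fit Tolerance schedule, acceptance rates and effective
#'   sample sizes per generation.
#' @param fit An `"abc_fit"` object.
#' @export
abc_schedule <- function(fit) {
  data.frame(generation = vapply(fit$generations, `[[`, 0L, "generation"),
             epsilon = vapply(fit$generations, `[[`, 0, "epsilon"),
             acceptance_rate = vapply(fit$generations, `[[`, 0,
                                      "acceptance_rate"),
             ess = vapply(fit$generations, `[[`, 0, "ess"))
}

#' @export
print.abc_fit <- function(x, ...) {
  f <- x$final
  cat("Qualitative ABC-SMC fit -- model", x$model, "\n")
  cat(sprintf("  %d free parameters, %d particles, %d generation(s) (seed %s)\n",
              length(x$prior$names), nrow(f$theta), length(x$generations),
              format(x$config$seed)))
  cat(sprintf("  final tolerance %.4g, acceptance %.3f, ESS %.1f\n",
              f$epsilon, f$acceptance_rate, f$ess))
  cat(sprintf("  target behaviour reproduced by %.1f%% of final particles\n",
              100 * mean(f$label == "HSC_WIN")))
  invisible(x)
}

#' Posterior summary of an ABC fit
#'
#' @param object An `"abc_fit"` object.
#' @param ... Unused.
#' @return Object with the tolerance schedule and per-parameter weighted
#'   means, standard deviations and central 95% intervals.
#' @export
summary.abc_fit <- function(object, ...) {
  f <- object$final
  w <- f$weight
  tab <- t(vapply(seq_len(ncol(f$theta)), function(k) {
    x <- f$theta[, k]
    c(mean = sum(w * x), sd = .wsd(x, w),
      q2.5 = .wquantile(x, w, 0.025), q50 = .wquantile(x, w, 0.5),
      q97.5 = .wquantile(x, w, 0.975))
  }, numeric(5)))
  rownames(tab) <- colnames(f$theta)
  structure(list(model = object$model, schedule = abc_schedule(object),
                 posterior = tab,
                 target_rate = mean(f$label == "HSC_WIN")),
            class = "summary.abc_fit")
}

#' @export
print.summary.abc_fit <- function(x, ...) {
  cat("Qualitative ABC-SMC fit -- model", x$model, "\n\nSchedule:\n")
  print(x$schedule, row.names = FALSE, digits = 4)
  cat("\nWeighted posterior marginals:\n")
  print(round(x$posterior, 4))
  cat(sprintf("\nTarget behaviour reproduced by %.1f%% of final particles\n",
              100 * x$target_rate))
  invisible(x)
}

#' @export
coef.abc_fit <- function(object, ...) {
  f <- object$final
  stats::setNames(colSums(f$weight * f$theta), colnames(f$theta))
}

#' Posterior-predictive simulation from an ABC fit
#'
#' Draws parameter vectors from the weighted final population and integrates
#' the model from the fit's initial condition.
#'
#' @param object An `"abc_fit"` object.
#' @param nsim Number of trajectories.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `"niche_traj"` objects (length `nsim`), with the drawn
#'   parameter rows as attribute `"theta"`.
#' @export
simulate.abc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  f <- object$final
  idx <- .with_seed(seed, function()
    sample.int(nrow(f$theta), nsim, replace = TRUE, prob = f$weight))
  out <- lapply(idx, function(j)
    integrate_model(object$model, .full_params(object$prior, f$theta[j, ]),
                    init = object$init, settings = object$settings))
  attr(out, "theta") <- f$theta[idx, , drop = FALSE]
  out
}

#' Outcome labels of the final particle population
#'
#' With `resimulate = TRUE` every final-generation particle is re-integrated
#' and re-classified (the posterior-predictive validity check: the model is
#' deterministic, so accepted particles must reproduce their behaviour).
#'
#' @param object An `"abc_fit"` object.
#' @param resimulate Recompute labels by fresh simulation instead of
#'   returning the stored ones.
#' @param ... Unused.
#' @return Factor of [OUTCOME_LABELS], one per final particle.
#' @export
predict.abc_fit <- function(object, resimulate = FALSE, ...) {
  f <- object$final
  labels <- if (!resimulate) f$label else
    vapply(seq_len(nrow(f$theta)), function(i) {
      traj <- integrate_model(object$model,
                              .full_params(object$prior, f$theta[i, ]),
                              init = object$init, settings = object$settings)
      classify_outcome(traj, object$criteria)
    }, character(1))
  factor(labels, levels = OUTCOME_LABELS)
}

#' Serialize all generations of an ABC fit to CSV
#'
#' One row per particle: generation, weight, distance, then the parameters.
#'
#' @param fit An `"abc_fit"` object.
#' @param path Output file path.
#' @export
write_population_csv <- function(fit, path) {
  rows <- lapply(fit$generations, function(g)
    data.frame(generation = g$generation, weight = g$weight,
               distance = g$distance, g$theta, check.names = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
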