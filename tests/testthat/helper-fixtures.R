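# Shared helpers: synthetic trajectory objects, canonical parameter sets, and
# memoized full-scale ABC runs reused across test files (the suppression
# posteriors are expensive; computing them once keeps the suite fast).

# a hand-built trajectory object for classification/distance tests
fake_traj <- function(final, model = "modelA", params = c(K = 1),
                      unbounded = FALSE, failed = FALSE, steady = TRUE,
                      settings = solver_settings()) {
  states <- rbind(final, final)
  colnames(states) <- names(final)
  structure(list(model = model, params = params, times = c(0, 1),
                 states = states, unbounded = unbounded, failed = failed,
                 settings = settings, reached_steady_state = steady,
                 final_state = final),
            class = "niche_traj")
}

# a bare weighted population for PCA/summary tests
fake_population <- function(theta, weight = NULL, distance = NULL) {
  n <- nrow(theta)
  if (is.null(weight)) weight <- rep(1 / n, n)
  if (is.null(distance)) distance <- rep(0, n)
  structure(list(theta = theta, weight = weight / sum(weight),
                 distance = distance, label = rep("HSC_WIN", n),
                 epsilon = 0, generation = 1L, acceptance_rate = 1,
                 ess = 1 / sum((weight / sum(weight))^2)),
            class = "abc_population")
}

pars_a <- function(...) {
  p <- c(a1 = 0.5, b1 = 0.1, c1 = 0.2, e1 = 0.3, f = 0.4,
         a2 = 0.5, b2 = 0.1, g = 0.4, K = 1)
  over <- c(...)
  p[names(over)] <- over
  p
}

pars_b <- function(...) {
  p <- c(lam1 = 0.6, lam2 = 0.3, lam3 = 0.2, mu4 = 0.1, lam5 = 0.25,
         mu6 = 0.35, chi1 = 0.4, mu8 = 0.15, kap1 = 0.5, kap2 = 0.2,
         kap3 = 0.3, nu4 = 0.2, nu8 = 0.1)
  over <- c(...)
  p[names(over)] <- over
  p
}

arm_swap_a <- function(p) {
  q <- p
  q[c("a1", "b1", "a2", "b2")] <- p[c("a2", "b2", "a1", "b1")]
  q
}

HSC_ARM_A <- c("a1", "b1", "c1", "e1", "f")
LSC_ARM_A <- c("a2", "b2", "g")
HSC_ARM_B <- c("lam1", "lam2", "lam3", "mu4", "lam5", "mu6", "chi1", "mu8")
LSC_ARM_B <- c("kap1", "kap2", "kap3", "nu4", "nu8")

# memoized full-scale runs (1000 particles x 6 generations, seed 1)
.run_cache <- new.env(parent = emptyenv())

cached_fit <- function(model, n_particles = 1000, n_generations = 6,
                       seed = 1) {
  key <- paste(model, n_particles, n_generations, seed, sep = "_")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- if (model == "toy") {
      toy <- toy_abc_problem()
      abc_fit("toy", prior = toy$prior, criteria = toy$criteria,
              settings = toy$settings, n_particles = n_particles,
              n_generations = n_generations, seed = seed, init = toy$init)
    } else {
      abc_fit(model, n_particles = n_particles,
              n_generations = n_generations, seed = seed)
    }
  }
  .run_cache[[key]]
}

# weighted two-sample KS statistic (sup distance of weighted ECDFs)
ks_two_sample_weighted <- function(x1, w1, x2, w2) {
  grid <- sort(unique(c(x1, x2)))
  F1 <- vapply(grid, function(g) sum(w1[x1 <= g]), numeric(1)) / sum(w1)
  F2 <- vapply(grid, function(g) sum(w2[x2 <= g]), numeric(1)) / sum(w2)
  max(abs(F1 - F2))
}
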