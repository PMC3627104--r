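# Synthetic-data generation: global sampling designs, labelled parameter
# regimes found by brute-force screening, and an analytically tractable toy
# inference problem.  Everything the test-suite and the validation recipes
# consume is generated here, in code, deterministically under a seed.

#' Latin-hypercube sample of the prior
#'
#' Each parameter's `n` draws occupy `n` distinct equal-probability strata --
#' a space-filling alternative to i.i.d. sampling when screening large
#' parameter spaces.
#'
#' @inheritParams sample_prior
#' @return An `n` x d matrix with parameter names as column names.
#' @export
lhs_sample <- function(prior, n, seed = NULL) {
  sample_prior(prior, n, seed = seed, method = "lhs")
}

#' Size of a full-factorial design
#'
#' The grid-coverage arithmetic that motivates targeted sampling: covering
#' `dims` dimensions at `levels` levels each costs `levels^dims` model runs
#' (e.g. 4 levels in 10 dimensions already exceeds a million).
#'
#' @param levels Levels per dimension.
#' @param dims Number of dimensions.
#' @return `levels^dims` as a double.
#' @export
full_factorial_count <- function(levels, dims) {
  stopifnot(levels >= 1, dims >= 1)
  as.numeric(levels)^as.numeric(dims)
}

#' Labelled parameter-regime fixtures
#'
#' Brute-force screens prior draws until (up to) `per_label` parameter sets
#' per reachable outcome label are collected; labels that stay empty within
#' `max_draws` draws are recorded as absent (e.g. `UNBOUNDED` can never occur
#' for the hard-capacity model A).  Each fixture row carries the parameter
#' vector, its label and the trajectory's final state.  Regeneration under
#' the same seed is bit-identical; when `dir` is given the fixtures are also
#' persisted as a CSV plus a JSON manifest.
#'
#' @inheritParams regime_map
#' @param per_label Target number of fixtures per label.
#' @param max_draws Screening budget.
#' @param dir Optional output directory for `fixtures_<model>.csv` and
#'   `fixtures_<model>.json`.
#' @return A list of class `"regime_fixtures"`: `sets` (data.frame), `absent`
#'   (labels not found), `seed`, `model`.
#' @export
generate_regime_fixtures <- function(model, seed, per_label = 5,
                                     max_draws = 2000,
                                     criteria = criteria_spec(),
                                     settings = solver_settings(),
                                     prior = prior_spec(model),
                                     init = default_init_state(model),
                                     dir = NULL) {
  theta <- sample_prior(prior, max_draws, seed = seed)
  need <- stats::setNames(rep(per_label, length(OUTCOME_LABELS)),
                          OUTCOME_LABELS)
  rows <- list()
  for (i in seq_len(max_draws)) {
    if (all(need == 0)) break
    traj <- integrate_model(model, .full_params(prior, theta[i, ]),
                            init = init, settings = settings)
    lab <- classify_outcome(traj, criteria)
    if (need[[lab]] > 0) {
      need[[lab]] <- need[[lab]] - 1L
      fs <- as.list(traj$final_state)
      names(fs) <- paste0("final_", names(fs))
      rows[[length(rows) + 1L]] <-
        data.frame(as.list(theta[i, ]), label = lab, fs,
                   check.names = FALSE)
    }
  }
  sets <- do.call(rbind, rows)
  absent <- names(need)[need == per_label]
  out <- structure(list(model = model, sets = sets, absent = absent,
                        seed = seed, per_label = per_label),
                   class = "regime_fixtures")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sets, file.path(dir, paste0("fixtures_", model, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(model = model, seed = seed, per_label = per_label,
           max_draws = max_draws, absent = absent,
           counts = as.list(table(sets$label))),
      file.path(dir, paste0("fixtures_", model, ".json")),
      auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.regime_fixtures <- function(x, ...) {
  cat("<regime_fixtures> model", x$model, "- seed", x$seed, "\n")
  print(table(x$sets$label))
  if (length(x$absent))
    cat("  absent labels:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' One-parameter toy problem with an analytic posterior
#'
#' A pure-decay model dX/dt = -rX, X(0) = `x0`, with the behavioural
#' criterion "X extinct (below `eps`) by `t_end`".  The criterion is
#' satisfied exactly for decay rates above the closed-form cutoff
#' `r_star = log(x0/eps)/t_end`, so under the uniform [0,1] prior the true
#' behaviour-conditioned posterior is uniform on `[r_star, 1]` -- an exact
#' oracle for validating the ABC samplers end to end.
#'
#' @param x0 Initial population (default 1).
#' @param eps Extinction threshold (default `exp(-5)`, giving
#'   `r_star = 0.5` with the default horizon).
#' @param t_end Horizon (default 10).
#' @return List with `model`, `prior`, `criteria`, `settings`, `init`,
#'   `r_star`, and `prior_mass` (the prior probability `1 - r_star` of the
#'   behaviour region).
#' @export
toy_abc_problem <- function(x0 = 1, eps = exp(-5), t_end = 10) {
  stopifnot(x0 > 0, eps > 0, eps < x0, t_end > 0)
  r_star <- log(x0 / eps) / t_end
  list(model = "toy",
       prior = prior_spec("toy"),
       criteria = criteria_spec(viable = character(0), extinct = "X",
                                extinct_eps = eps,
                                viable_delta = min(0.5, 2 * eps + 0.25),
                                require_steady_state = FALSE),
       settings = solver_settings(t_end = t_end, n_points = 100),
       init = c(X = x0),
       r_star = r_star,
       prior_mass = max(0, 1 - r_star))
}
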