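# Mapping trajectories to dynamical outcomes and building regime maps over
# sampled parameter space.

#' Outcome labels
#'
#' Every trajectory is assigned exactly one of: `HSC_WIN` (all required-viable
#' species persist, all required-extinct species vanish), `LSC_WIN` (the
#' mirrored condition), `NEITHER` (coexistence, bistable middle ground, or any
#' final state matching neither pattern), `UNBOUNDED` (divergent), and
#' `NO_STEADY_STATE` (steady state demanded but not reached within the
#' horizon; also used for integrator failures).
#'
#' @export
OUTCOME_LABELS <- c("HSC_WIN", "LSC_WIN", "NEITHER", "UNBOUNDED",
                    "NO_STEADY_STATE")

#' Behavioural criteria
#'
#' Declares the target behaviour: which species must persist at a viable
#' level and which must vanish.  The exact-limit statement "L = T = 0 and
#' S, A, D > 0 at steady state" needs finite thresholds under finite-time
#' simulation; a species is *extinct* below `extinct_eps` and *viable* above
#' `viable_delta` (both as fractions of the carrying capacity).
#'
#' @param viable Character vector of species required to persist.
#' @param extinct Character vector of species required to vanish (disjoint
#'   from `viable`).
#' @param extinct_eps Extinction threshold (fraction of K), default 1e-3.
#' @param viable_delta Viability threshold (fraction of K), default 1e-2;
#'   must exceed `extinct_eps`.
#' @param require_steady_state Demand a pseudo-steady state before scoring
#'   (default `TRUE`, as in the headline analyses).
#' @return A list of class `"criteria_spec"`.
#' @export
criteria_spec <- function(viable = c("S", "A", "D"), extinct = c("L", "T"),
                          extinct_eps = 1e-3, viable_delta = 1e-2,
                          require_steady_state = TRUE) {
  if (length(intersect(viable, extinct)))
    stop("viable and extinct species sets must be disjoint")
  if (!(extinct_eps > 0 && extinct_eps < viable_delta && viable_delta < 1))
    stop("need 0 < extinct_eps < viable_delta < 1")
  structure(list(viable = viable, extinct = extinct,
                 extinct_eps = extinct_eps, viable_delta = viable_delta,
                 require_steady_state = isTRUE(require_steady_state)),
            class = "criteria_spec")
}

.capacity_scale <- function(traj) {
  p <- traj$params
  if (traj$model == "modelA" && !is.null(names(p)) && "K" %in% names(p))
    as.numeric(p[["K"]]) else 1
}

.criteria_satisfied <- function(final_state, criteria, scale = 1) {
  fs <- final_state / scale
  all(fs[criteria$viable] >= criteria$viable_delta) &&
    all(fs[criteria$extinct] <= criteria$extinct_eps)
}

#' Classify a trajectory against behavioural criteria
#'
#' @param traj A `"niche_traj"` object.
#' @param criteria A [criteria_spec()] object.
#' @return One of [OUTCOME_LABELS].
#' @export
classify_outcome <- function(traj, criteria = criteria_spec()) {
  if (traj$failed) return("NO_STEADY_STATE")
  if (detect_unbounded(traj)) return("UNBOUNDED")
  if (criteria$require_steady_state && !traj$reached_steady_state)
    return("NO_STEADY_STATE")
  scale <- .capacity_scale(traj)
  fs <- traj$final_state / scale
  win <- all(fs[criteria$viable] >= criteria$viable_delta) &&
    all(fs[criteria$extinct] <= criteria$extinct_eps)
  if (win) return("HSC_WIN")
  lose <- all(fs[criteria$extinct] >= criteria$viable_delta) &&
    all(fs[criteria$viable] <= criteria$extinct_eps)
  if (lose) return("LSC_WIN")
  "NEITHER"
}

#' Outcome map over sampled parameter space
#'
#' Draws `n_samples` parameter vectors from the prior, integrates each, and
#' labels the outcome.  Failures are counted (as `NO_STEADY_STATE`), never
#' fatal.  Reproducible under a fixed seed.
#'
#' @inheritParams model_info
#' @param n_samples Number of parameter draws (>= 1).
#' @param criteria A [criteria_spec()].
#' @param settings A [solver_settings()].
#' @param seed Integer seed (mandatory).
#' @param sampler `"random"` (i.i.d. uniform) or `"lhs"` (Latin hypercube).
#' @param prior A [prior_spec()]; defaults to the model's uniform [0,1] prior.
#' @param init Initial state, default [default_init_state()].
#' @param use_compiled Use the compiled right-hand sides.
#' @return A list of class `"regime_map"`: `freq` (frequencies over
#'   [OUTCOME_LABELS], summing to 1), `counts`, and `samples` (data.frame of
#'   parameters plus `label`).
#' @export
regime_map <- function(model, n_samples, criteria = criteria_spec(),
                       settings = solver_settings(), seed,
                       sampler = c("random", "lhs"),
                       prior = prior_spec(model),
                       init = default_init_state(model),
                       use_compiled = TRUE) {
  stopifnot(n_samples >= 1)
  sampler <- match.arg(sampler)
  theta <- sample_prior(prior, n_samples, seed = seed, method = sampler)
  labels <- character(n_samples)
  for (i in seq_len(n_samples)) {
    traj <- integrate_model(model, theta[i, ], init = init,
                            settings = settings, use_compiled = use_compiled)
    labels[i] <- classify_outcome(traj, criteria)
  }
  counts <- table(factor(labels, levels = OUTCOME_LABELS))
  structure(list(model = model,
                 freq = as.numeric(counts) / n_samples,
                 counts = stats::setNames(as.integer(counts), OUTCOME_LABELS),
                 samples = data.frame(theta, label = labels,
                                      check.names = FALSE),
                 seed = seed, sampler = sampler),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat("<regime_map> model", x$model, "-", nrow(x$samples), "draws (",
      x$sampler, "sampling, seed", x$seed, ")\n")
  freq <- stats::setNames(x$freq, OUTCOME_LABELS)
  for (lab in OUTCOME_LABELS)
    cat(sprintf("  %-16s %6.3f (%d)\n", lab, freq[[lab]], x$counts[[lab]]))
  invisible(x)
}
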