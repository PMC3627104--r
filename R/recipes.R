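# Run orchestration: configuration handling, named analysis recipes and
# provenance manifests.  A recipe executes a full pipeline (prior -> ABC-SMC
# -> posterior summaries -> PCA -> contribution report, or a regime map) and
# writes every artifact plus a manifest sufficient to re-run bit-compatibly.

RECIPES <- c("modelA_suppression", "modelB_suppression",
             "regime_map_A", "regime_map_B", "toy_abc_validation")

.config_template <- function() {
  list(
    model = NULL, seed = NULL,
    n_particles = 1000, n_generations = 6, kernel_scale = 1,
    n_samples = 1000, sampler = "random",
    make_figures = FALSE,
    criteria = list(viable = c("S", "A", "D"), extinct = c("L", "T"),
                    extinct_eps = 1e-3, viable_delta = 1e-2,
                    require_steady_state = TRUE),
    solver = list(t_end = 1000, n_points = 500, rel_tol = 1e-8,
                  abs_tol = 1e-8, blowup_cap = 1e6, ss_window = 0.2,
                  ss_tol = 1e-4),
    init = list())
}

#' Default configuration of a recipe
#'
#' @param recipe One of `r paste0('\x60', RECIPES, '\x60', collapse = ", ")`.
#' @return A named configuration list (all documented defaults; `seed` unset).
#' @export
config_default <- function(recipe) {
  recipe <- match.arg(recipe, RECIPES)
  cfg <- .config_template()
  cfg$model <- switch(recipe,
                      modelA_suppression = , regime_map_A = "modelA",
                      modelB_suppression = , regime_map_B = "modelB",
                      toy_abc_validation = "toy")
  if (recipe == "toy_abc_validation") {
    toy <- toy_abc_problem()
    cfg$criteria <- list(viable = character(0), extinct = "X",
                         extinct_eps = toy$criteria$extinct_eps,
                         viable_delta = toy$criteria$viable_delta,
                         require_steady_state = FALSE)
    cfg$solver$t_end <- toy$settings$t_end
    cfg$solver$n_points <- toy$settings$n_points
  }
  cfg
}

.merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key '", paste0(path, nm), "'")
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]],
                                  paste0(path, nm, "."))
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a configuration file
#'
#' YAML or JSON; user keys override the recipe defaults, unknown keys are
#' rejected with the offending field path.
#'
#' @param path Configuration file.
#' @param recipe Recipe whose defaults to merge into.
#' @return Validated configuration list.
#' @export
config_load <- function(path, recipe) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(config_default(recipe), user)
  config_validate(cfg)
}

#' Validate a configuration list
#'
#' @param cfg Configuration list (defaults merged).
#' @return The configuration, invisibly unchanged, or an error naming the
#'   offending field.
#' @export
config_validate <- function(cfg) {
  cr <- cfg$criteria
  if (!(cr$extinct_eps > 0 && cr$extinct_eps < cr$viable_delta))
    stop("criteria: need 0 < extinct_eps < viable_delta")
  if (length(intersect(cr$viable, cr$extinct)))
    stop("criteria: viable and extinct sets must be disjoint")
  if (cfg$solver$t_end <= 0) stop("solver: t_end must be > 0")
  if (cfg$n_particles < 2) stop("n_particles must be >= 2")
  if (!cfg$sampler %in% c("random", "lhs"))
    stop("sampler must be 'random' or 'lhs'")
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
config_dump <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.cfg_criteria <- function(cfg) {
  cr <- cfg$criteria
  criteria_spec(viable = as.character(unlist(cr$viable)),
                extinct = as.character(unlist(cr$extinct)),
                extinct_eps = cr$extinct_eps,
                viable_delta = cr$viable_delta,
                require_steady_state = cr$require_steady_state)
}

.cfg_settings <- function(cfg) {
  s <- cfg$solver
  solver_settings(t_end = s$t_end, n_points = s$n_points,
                  rel_tol = s$rel_tol, abs_tol = s$abs_tol,
                  blowup_cap = s$blowup_cap, ss_window = s$ss_window,
                  ss_tol = s$ss_tol)
}

.write_manifest <- function(out_dir, recipe, cfg, extra = list()) {
  manifest <- c(list(recipe = recipe,
                     package = "nichefate",
                     package_version = as.character(
                       utils::packageVersion("nichefate")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"),
                     config = cfg),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.pca_report <- function(pca) {
  shares <- 100 * pca$loadings^2
  list(eigenvalues = pca$eigenvalues,
       param_names = pca$param_names,
       loadings = unname(apply(pca$loadings, 1, identity, simplify = FALSE)),
       squared_loading_shares = unname(apply(shares, 1, identity,
                                             simplify = FALSE)),
       ess = pca$ess)
}

#' Run a named analysis recipe
#'
#' Executes the full pipeline for one of the headline experiments and writes
#' all artifacts (population CSV, PCA JSON, marginal histograms CSV, resolved
#' configuration, manifest with seeds and versions) into `out_dir`.
#'
#' * `modelA_suppression`, `modelB_suppression`: ABC-SMC conditioned on
#'   leukaemia suppression (S, A, D viable; L, T extinct at steady state),
#'   followed by weighted-posterior PCA and stiff-direction contribution
#'   reports.
#' * `regime_map_A`, `regime_map_B`: brute-force outcome maps over prior
#'   draws.
#' * `toy_abc_validation`: ABC-SMC on the analytic toy problem, reporting the
#'   comparison against the closed-form cutoff posterior.
#'
#' @param recipe Recipe name; see [config_default()].
#' @param config Optional configuration: a file path (YAML/JSON) or a list of
#'   overrides; defaults from [config_default()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding `config$seed`; a seed is mandatory
#'   one way or the other.
#' @return Invisibly, a list with the computed objects (`fit`, `pca`,
#'   `map`, ... depending on the recipe) and `out_dir`.
#' @export
run_recipe <- function(recipe, config = NULL, out_dir, seed = NULL) {
  recipe <- match.arg(recipe, RECIPES)
  cfg <- if (is.character(config)) config_load(config, recipe)
         else if (is.list(config)) config_validate(
           .merge_config(config_default(recipe), config))
         else config_default(recipe)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) stop("a seed is mandatory (config$seed or seed=)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  criteria <- .cfg_criteria(cfg)
  settings <- .cfg_settings(cfg)
  model <- cfg$model
  init <- if (length(cfg$init)) unlist(cfg$init) else
    default_init_state(model)
  config_dump(cfg, file.path(out_dir, "config_resolved.yaml"))

  result <- list(out_dir = out_dir, config = cfg)

  if (recipe %in% c("regime_map_A", "regime_map_B")) {
    map <- regime_map(model, n_samples = cfg$n_samples, criteria = criteria,
                      settings = settings, seed = cfg$seed,
                      sampler = cfg$sampler, init = init)
    utils::write.csv(map$samples, file.path(out_dir, "labelled_samples.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = as.list(map$counts),
           freq = as.list(stats::setNames(map$freq, OUTCOME_LABELS))),
      file.path(out_dir, "outcome_frequencies.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .write_manifest(out_dir, recipe, cfg)
    result$map <- map
    return(invisible(result))
  }

  fit <- abc_fit(model, criteria = criteria, settings = settings,
                 n_particles = cfg$n_particles,
                 n_generations = cfg$n_generations,
                 kernel_scale = cfg$kernel_scale, seed = cfg$seed,
                 init = init)
  write_population_csv(fit, file.path(out_dir, "populations.csv"))
  s <- posterior_summaries(fit)
  utils::write.csv(s$marginals, file.path(out_dir, "marginal_histograms.csv"),
                   row.names = FALSE)
  result$fit <- fit

  if (recipe == "toy_abc_validation") {
    toy <- toy_abc_problem()
    acc <- fit$final$theta[, "r"]
    report <- list(
      r_star = toy$r_star,
      prior_mass_above_cutoff = toy$prior_mass,
      min_accepted_rate = min(acc),
      ks_distance_vs_uniform = ks_uniform_distance(fit$final, toy$r_star, 1),
      final_epsilon = fit$final$epsilon)
    jsonlite::write_json(report, file.path(out_dir, "toy_validation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .write_manifest(out_dir, recipe, cfg,
                    list(schedule = abc_schedule(fit), toy = report))
    result$report <- report
    return(invisible(result))
  }

  pca <- pca_posterior(fit)
  jsonlite::write_json(.pca_report(pca), file.path(out_dir, "pca.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(cfg$make_figures)) {
    grDevices::png(file.path(out_dir, "marginals.png"), 1200, 900, res = 120)
    plot(fit)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "pca.png"), 1200, 600, res = 120)
    plot(pca)
    grDevices::dev.off()
  }
  .write_manifest(out_dir, recipe, cfg,
                  list(schedule = abc_schedule(fit),
                       final_target_rate = mean(fit$final$label == "HSC_WIN")))
  result$pca <- pca
  invisible(result)
}

#' Kolmogorov-Smirnov distance of a weighted sample from Uniform(lower, upper)
#'
#' Supremum distance between the weighted empirical CDF of the particles'
#' first parameter (or a supplied vector) and the uniform CDF -- the
#' validation statistic for the toy problem's analytic posterior.
#'
#' @param population An `"abc_population"` (its first parameter column is
#'   used) or a numeric vector; weights taken from the population (uniform
#'   for a bare vector).
#' @param lower,upper Support of the reference uniform distribution.
#' @return The KS statistic in [0, 1].
#' @export
ks_uniform_distance <- function(population, lower, upper) {
  if (inherits(population, "abc_population") ||
      inherits(population, "abc_fit")) {
    pop <- .final_population(population)
    x <- pop$theta[, 1]
    w <- pop$weight
  } else {
    x <- as.numeric(population)
    w <- rep(1 / length(x), length(x))
  }
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  Fx <- pmin(pmax((x - lower) / (upper - lower), 0), 1)
  max(abs(cw - Fx), abs(cw - w - Fx))
}
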