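# Numerical integration of the registered models to a finite-time
# pseudo-steady state.  True t -> Inf equilibria are never computed; instead a
# trajectory is integrated over a long horizon and its tail is tested for
# stationarity.  Runs that cross the blow-up cap are halted early by the
# solver's root function and flagged unbounded.

#' Solver settings
#'
#' @param t_end Integration horizon in model time units.  Rates on [0,1] give
#'   characteristic times of order 1-100, so the default 1000 comfortably
#'   reaches the pseudo-steady state.
#' @param n_points Size of the output time grid.
#' @param rel_tol,abs_tol Integrator tolerances (lsodar).
#' @param blowup_cap Total population treated as divergence; integration stops
#'   when the summed state crosses it.
#' @param ss_window Fraction of the trajectory tail used for the steady-state
#'   test (0 < ss_window < 1).
#' @param ss_tol Maximum relative change over the tail window for a component
#'   to count as stationary; components whose tail maximum is below `ss_tol`
#'   are compared absolutely (extinction floor).
#' @return A list of class `"solver_settings"`.
#' @export
solver_settings <- function(t_end = 1000, n_points = 500,
                            rel_tol = 1e-8, abs_tol = 1e-8,
                            blowup_cap = 1e6, ss_window = 0.2,
                            ss_tol = 1e-4) {
  stopifnot(t_end > 0, n_points >= 10, rel_tol > 0, abs_tol > 0,
            blowup_cap > 0, ss_window > 0, ss_window < 1, ss_tol > 0)
  structure(list(t_end = t_end, n_points = n_points, rel_tol = rel_tol,
                 abs_tol = abs_tol, blowup_cap = blowup_cap,
                 ss_window = ss_window, ss_tol = ss_tol),
            class = "solver_settings")
}

#' Default initial condition of a model
#'
#' An established small leukaemic clone alongside a small HSC pool:
#' S = L = 0.01 (in units of the carrying capacity), all progeny absent.  The
#' published analyses consider the situation where LSC presence is already
#' established; initial conditions are a first-class configuration item
#' because bistable regimes make them consequential.
#'
#' @inheritParams model_info
#' @return Named state vector.
#' @export
default_init_state <- function(model) {
  m <- model_info(model)
  switch(model,
         modelA = ,
         modelB = c(S = 0.01, A = 0, D = 0, L = 0.01, T = 0),
         lv2 = c(X = 0.01, Y = 0.01),
         toy = c(X = 1))
}

.assemble_parms <- function(model, params, cap) {
  m <- .models[[model]]
  p <- .check_params(params, model)
  unname(c(p[c(m$free, names(m$fixed))], cap))
}

.new_traj <- function(model, params, times, states, species,
                      unbounded, failed, settings) {
  # tolerance-scale negative overshoots from stiff decay are clipped to zero
  states[states < 0] <- 0
  traj <- structure(list(model = model, params = params, times = times,
                         states = states, unbounded = unbounded,
                         failed = failed, settings = settings),
                    class = "niche_traj")
  traj$reached_steady_state <- if (unbounded || failed) FALSE else
    steady_state_reached(traj, settings)$reached
  # the state actually reached at the end of the horizon; the tail *average*
  # is available through steady_state_reached()
  traj$final_state <- stats::setNames(states[nrow(states), ], species)
  traj
}

#' Integrate a registered model
#'
#' Solves the model ODEs with the stiff-capable adaptive `lsodar` solver on a
#' dense output grid.  Integration halts early (and the trajectory is flagged
#' `unbounded`) when the summed state crosses `blowup_cap`.  Integrator
#' failures are returned as flagged results (`failed = TRUE`), never as
#' errors, so that batch screening runs survive pathological draws.  The
#' result is deterministic given identical inputs.
#'
#' @inheritParams model_info
#' @param params Model parameters (named vector; free rates, optionally fixed
#'   constants).
#' @param init Initial state; default [default_init_state()].
#' @param settings A [solver_settings()] object.
#' @param use_compiled Use the compiled C right-hand sides (default).  The
#'   plain-R path (`FALSE`) integrates the exported reference implementations
#'   and exists for cross-checking.
#' @return An object of class `"niche_traj"`: list with `times`, `states`
#'   (time x species matrix), flags `unbounded`, `failed`,
#'   `reached_steady_state`, and `final_state` (tail-averaged).
#' @export
integrate_model <- function(model, params, init = default_init_state(model),
                            settings = solver_settings(),
                            use_compiled = TRUE) {
  m <- .models[[model_info(model)$name]]
  species <- m$species
  y0 <- .check_state(init, species)
  times <- seq(0, settings$t_end, length.out = settings$n_points)
  cap <- settings$blowup_cap

  # capture.output: the Fortran core prints step-size diagnostics straight to
  # the console for pathological (near-machine-stiff) draws; such runs are
  # returned as flagged failures, so the chatter is pure noise in batch runs
  out <- NULL
  if (use_compiled) {
    parms <- .assemble_parms(model, params, cap)
    try(utils::capture.output(out <- suppressWarnings(deSolve::lsodar(
      y = y0, times = times, func = m$c_symbols[["derivs"]], parms = parms,
      dllname = "nichefate", initfunc = m$c_symbols[["init"]],
      rootfunc = m$c_symbols[["root"]], nroot = 1,
      rtol = settings$rel_tol, atol = settings$abs_tol))), silent = TRUE)
  } else {
    p <- .check_params(params, model)
    rhs <- .rhs_fun(model)
    fn <- function(t, y, parms) list(unname(suppressWarnings(
      rhs(pmax(y, 0), parms))))
    rootfn <- function(t, y, parms) cap - sum(y)
    try(utils::capture.output(out <- suppressWarnings(deSolve::lsodar(
      y = y0, times = times, func = fn, parms = p,
      rootfunc = rootfn, rtol = settings$rel_tol, atol = settings$abs_tol))),
      silent = TRUE)
  }
  if (is.null(out)) out <- structure("", class = "try-error")

  if (inherits(out, "try-error"))
    return(.new_traj(model, params, times = times[1],
                     states = matrix(y0, nrow = 1,
                                     dimnames = list(NULL, species)),
                     species, unbounded = FALSE, failed = TRUE, settings))

  mat <- unclass(out)
  ok <- stats::complete.cases(mat) & is.finite(rowSums(mat))
  if (!all(ok)) mat <- mat[seq_len(max(1L, which.max(!ok) - 1L)), , drop = FALSE]
  tms <- mat[, 1]
  states <- mat[, -1, drop = FALSE]
  colnames(states) <- species

  hit_root <- length(attr(out, "troot")) > 0
  spilled <- any(rowSums(states) >= cap * (1 - 1e-9))
  unbounded <- hit_root || spilled
  # istate < 0 or a truncated grid without a root means the solver gave up
  istate <- attr(out, "istate")[1]
  failed <- !unbounded &&
    ((!is.null(istate) && istate < 0) || nrow(states) < length(times))
  .new_traj(model, params, tms, states, species, unbounded, failed, settings)
}

#' Test a trajectory tail for (pseudo-)steady state
#'
#' A trajectory has reached its pseudo-steady state when every component's
#' change over the tail window (`ss_window` of the time span) is below
#' `ss_tol`: relatively for components of appreciable size, absolutely for
#' components below the extinction floor (tail maximum < `ss_tol`).
#'
#' @param traj A `"niche_traj"` object.
#' @param settings A [solver_settings()] object; defaults to the settings the
#'   trajectory was integrated with.
#' @return List with `reached` (flag) and `final_state` (tail-averaged state).
#' @export
steady_state_reached <- function(traj, settings = traj$settings) {
  states <- traj$states
  n <- nrow(states)
  if (n < 2L)
    return(list(reached = TRUE,
                final_state = stats::setNames(states[n, ], colnames(states))))
  from <- max(1L, ceiling((1 - settings$ss_window) * n))
  tail_s <- states[from:n, , drop = FALSE]
  hi <- apply(tail_s, 2, max)
  lo <- apply(tail_s, 2, min)
  span <- hi - lo
  reached <- all(ifelse(hi < settings$ss_tol,
                        span < settings$ss_tol,
                        span / hi < settings$ss_tol))
  list(reached = reached,
       final_state = stats::setNames(colMeans(tail_s), colnames(states)))
}

#' Did a trajectory diverge?
#'
#' @inheritParams steady_state_reached
#' @return `TRUE` iff any state crossed `blowup_cap` (the solver's root
#'   function halts integration there) or the integrator itself diverged.
#' @export
detect_unbounded <- function(traj, settings = traj$settings) {
  isTRUE(traj$unbounded) ||
    any(rowSums(traj$states) >= settings$blowup_cap * (1 - 1e-9))
}

#' @export
print.niche_traj <- function(x, ...) {
  cat("<niche_traj> model", x$model, "-", nrow(x$states), "time points on [0,",
      format(max(x$times)), "]\n")
  status <- if (x$failed) "integrator failure"
            else if (x$unbounded) "UNBOUNDED"
            else if (x$reached_steady_state) "pseudo-steady state reached"
            else "no steady state within horizon"
  cat("  status:", status, "\n")
  cat("  final state:",
      paste(sprintf("%s=%.4g", names(x$final_state), x$final_state),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.niche_traj <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Export a trajectory to tidy CSV
#'
#' Columns: `time` plus one column per species.
#'
#' @param traj A `"niche_traj"` object.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
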