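# Model definitions: exact right-hand sides of the niche competition systems.
#
# Three systems are registered.  "modelA" is the five-species hard-capacity
# model: haematopoietic stem cells (S), progenitors (A) and differentiated
# blood cells (D) compete with leukaemia stem cells (L) and differentiated
# leukaemia cells (T) for a niche of carrying capacity K through the shared
# linear feedback factor (1 - Z/K), Z = S+A+D+L+T.  "modelB" resolves the
# individual stem-cell fates (symmetric renewal, asymmetric renewal, symmetric
# differentiation, loss) with exponential feedback split across two sub-niches
# (one occupied by the stem species S and L, one by their progeny A, D and T).
# "lv2" is the two-species Lotka-Volterra competition system used for
# exposition, and "toy" a one-parameter pure-decay model with an analytic
# behaviour region, used to validate the ABC machinery.

.species5 <- c("S", "A", "D", "L", "T")

.par_names_a <- c("a1", "b1", "c1", "e1", "f", "a2", "b2", "g")
.par_names_b <- c("lam1", "lam2", "lam3", "mu4", "lam5", "mu6", "chi1",
                  "mu8", "kap1", "kap2", "kap3", "nu4", "nu8")

.models <- list(
  modelA = list(
    name = "modelA",
    species = .species5,
    free = .par_names_a,
    fixed = c(K = 1),
    c_symbols = c(init = "nf_init_a", derivs = "nf_derivs_a",
                  root = "nf_root_a")
  ),
  modelB = list(
    name = "modelB",
    species = .species5,
    free = .par_names_b,
    fixed = c(gam1 = 0.01, gam2 = 0.01, gam3 = 0.01),
    c_symbols = c(init = "nf_init_b", derivs = "nf_derivs_b",
                  root = "nf_root_b")
  ),
  lv2 = list(
    name = "lv2",
    species = c("X", "Y"),
    free = c("alpha", "beta", "gamma"),
    fixed = c(),
    c_symbols = c(init = "nf_init_lv2", derivs = "nf_derivs_lv2",
                  root = "nf_root_lv2")
  ),
  toy = list(
    name = "toy",
    species = "X",
    free = "r",
    fixed = c(),
    c_symbols = c(init = "nf_init_toy", derivs = "nf_derivs_toy",
                  root = "nf_root_toy")
  )
)

#' Look up a registered model
#'
#' @param model Model name: one of `"modelA"`, `"modelB"`, `"lv2"`, `"toy"`.
#' @return A list with elements `name`, `species` (state variable names),
#'   `free` (names of the free rate parameters, i.e. the inference dimensions)
#'   and `fixed` (named vector of fixed constants and their default values).
#' @export
model_info <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% names(.models))
    stop("unknown model '", paste(model, collapse = ","),
         "'; registered models: ", paste(names(.models), collapse = ", "))
  .models[[model]][c("name", "species", "free", "fixed")]
}

#' Parameter names of a registered model
#'
#' @inheritParams model_info
#' @param free_only If `TRUE` (default) return only the free rates sampled in
#'   inference; otherwise include the fixed constants.
#' @return Character vector of parameter names.
#' @export
param_names <- function(model, free_only = TRUE) {
  m <- model_info(model)
  if (free_only) m$free else c(m$free, names(m$fixed))
}

# shared input checks ---------------------------------------------------------

.check_state <- function(state, species) {
  state <- as.numeric(state)
  if (length(state) != length(species))
    stop("state must have ", length(species), " components (",
         paste(species, collapse = ", "), ")")
  if (anyNA(state) || any(!is.finite(state)))
    stop("state contains non-finite values")
  if (any(state < 0))
    stop("state components must be nonnegative")
  stats::setNames(state, species)
}

.check_params <- function(params, model) {
  m <- .models[[model]]
  want <- c(m$free, names(m$fixed))
  p <- params
  if (!is.null(names(p)) && all(m$free %in% names(p))) {
    fixed <- m$fixed
    if (length(fixed))
      for (nm in names(fixed)) if (nm %in% names(p)) fixed[nm] <- p[[nm]]
    p <- c(stats::setNames(as.numeric(p[m$free]), m$free), fixed)
  } else if (length(p) == length(want) && is.null(names(p))) {
    p <- stats::setNames(as.numeric(p), want)
  } else if (length(p) == length(m$free) && is.null(names(p))) {
    p <- c(stats::setNames(as.numeric(p), m$free), m$fixed)
  } else {
    stop("cannot interpret parameter vector for model '", model,
         "'; expected names ", paste(want, collapse = ", "))
  }
  if (anyNA(p) || any(!is.finite(p))) stop("parameters must be finite")
  if (any(p[m$free] < 0)) stop("rate parameters must be nonnegative")
  if (model == "modelA" && p[["K"]] <= 0) stop("carrying capacity K must be > 0")
  if (model %in% c("modelA", "modelB") && any(p[m$free] > 1))
    warning("rates above 1 lie outside the [0,1] prior support used for ",
            "inference (the model itself permits them)", call. = FALSE)
  p
}

# constructors ----------------------------------------------------------------

#' Parameter vector for the hard-capacity niche model (model A)
#'
#' The eight free rates are, in order: `a1` self-renewal of S, `b1` transition
#' S -> A, `c1` self-renewal of A, `e1` transition A -> D, `f` removal of D,
#' `a2` self-renewal of L, `b2` transition L -> T, `g` removal of T.  All are
#' per-unit-time rates; the uniform priors used for inference live on [0,1],
#' but larger values are accepted with a warning.
#'
#' @param a1,b1,c1,e1,f,a2,b2,g Nonnegative rates.
#' @param K Carrying capacity of the niche (> 0).  The default 1 expresses
#'   populations as concentrations (fractions of the niche).
#' @return Named numeric vector of length 9.
#' @export
params_model_a <- function(a1, b1, c1, e1, f, a2, b2, g, K = 1) {
  .check_params(c(a1 = a1, b1 = b1, c1 = c1, e1 = e1, f = f,
                  a2 = a2, b2 = b2, g = g, K = K), "modelA")
}

#' Parameter vector for the soft-niche fate-resolved model (model B)
#'
#' Thirteen free rates: `lam1` symmetric renewal of S (S -> 2S), `lam2`
#' asymmetric renewal (S -> S + A), `lam3` symmetric differentiation
#' (S -> 2A), `mu4` migration/apoptosis of S, `lam5` amplification of A,
#' `mu6` disappearance of A, `chi1` transition A -> D, `mu8`
#' migration/apoptosis of D, and the leukaemic analogues `kap1`, `kap2`,
#' `kap3` (fates of L), `nu4` (loss of L) and `nu8` (loss of T).  The feedback
#' strengths `gam1`, `gam2`, `gam3` are fixed constants (default 0.01 each, as
#' in the headline configuration).
#'
#' @param lam1,lam2,lam3,mu4,lam5,mu6,chi1,mu8,kap1,kap2,kap3,nu4,nu8
#'   Nonnegative rates.
#' @param gam1,gam2,gam3 Feedback-strength constants (>= 0).
#' @return Named numeric vector of length 16.
#' @export
params_model_b <- function(lam1, lam2, lam3, mu4, lam5, mu6, chi1, mu8,
                           kap1, kap2, kap3, nu4, nu8,
                           gam1 = 0.01, gam2 = 0.01, gam3 = 0.01) {
  if (any(c(gam1, gam2, gam3) < 0)) stop("feedback constants must be >= 0")
  .check_params(c(lam1 = lam1, lam2 = lam2, lam3 = lam3, mu4 = mu4,
                  lam5 = lam5, mu6 = mu6, chi1 = chi1, mu8 = mu8,
                  kap1 = kap1, kap2 = kap2, kap3 = kap3, nu4 = nu4,
                  nu8 = nu8, gam1 = gam1, gam2 = gam2, gam3 = gam3),
                "modelB")
}

#' Parameter vector for the two-species competition model
#'
#' @param alpha,beta Growth rates of species X and Y (>= 0).
#' @param gamma Strength of the shared linear feedback (>= 0).
#' @return Named numeric vector of length 3.
#' @export
params_lv2 <- function(alpha, beta, gamma) {
  .check_params(c(alpha = alpha, beta = beta, gamma = gamma), "lv2")
}

# right-hand sides ------------------------------------------------------------

#' Two-species competition right-hand side
#'
#' dX/dt = X (alpha - gamma (X + Y)),  dY/dt = Y (beta - gamma (X + Y)).
#' Both species experience the same linear feedback, proportional to the
#' combined population.  With alpha != beta (and gamma > 0) the species with
#' the larger growth rate excludes the other.
#'
#' @param state Numeric vector (X, Y), nonnegative.
#' @param params See [params_lv2()].
#' @return Named derivative vector (X, Y).
#' @export
rhs_lv2 <- function(state, params) {
  s <- .check_state(state, c("X", "Y"))
  p <- .check_params(params, "lv2")
  crowd <- p[["gamma"]] * (s[["X"]] + s[["Y"]])
  c(X = s[["X"]] * (p[["alpha"]] - crowd),
    Y = s[["Y"]] * (p[["beta"]] - crowd))
}

#' Hard-capacity niche model right-hand side (model A)
#'
#' All growth/self-renewal terms carry the shared factor (1 - Z/K) with
#' Z = S+A+D+L+T, so they vanish exactly when the niche is full (Z = K): the
#' capacity is "hard".  Transitions move cells S -> A (rate b1), A -> D (e1)
#' and L -> T (b2); differentiated cells leave the niche at rates f and g.
#'
#' @param state Numeric vector (S, A, D, L, T), nonnegative.
#' @param params See [params_model_a()].
#' @return Named derivative vector over (S, A, D, L, T).
#' @export
rhs_model_a <- function(state, params) {
  s <- .check_state(state, .species5)
  p <- .check_params(params, "modelA")
  room <- 1 - sum(s) / p[["K"]]
  c(S = p[["a1"]] * s[["S"]] * room - p[["b1"]] * s[["S"]],
    A = p[["b1"]] * s[["S"]] + p[["c1"]] * s[["A"]] * room - p[["e1"]] * s[["A"]],
    D = p[["e1"]] * s[["A"]] - p[["f"]] * s[["D"]],
    L = p[["a2"]] * s[["L"]] * room - p[["b2"]] * s[["L"]],
    T = p[["b2"]] * s[["L"]] - p[["g"]] * s[["T"]])
}

#' Exponential sub-niche feedback multipliers (model B)
#'
#' Phi1 = exp(-gam1 (S + L)) carries the feedback of the stem sub-niche on the
#' stem species themselves; Phi2 = exp(-gam2 (A + D + T)) and
#' Phi3 = exp(-gam3 (A + D + T)) carry the feedback of the progeny sub-niche
#' on the differentiating species.  Each multiplier is 1 at zero occupancy and
#' decays strictly monotonically as its sub-niche fills.
#'
#' @param state Numeric vector (S, A, D, L, T), nonnegative.
#' @param gammas Numeric vector (gam1, gam2, gam3), nonnegative.
#' @return Named numeric vector (phi1, phi2, phi3), each in (0, 1].
#' @export
feedback_terms <- function(state, gammas = c(0.01, 0.01, 0.01)) {
  s <- .check_state(state, .species5)
  g <- as.numeric(gammas)
  if (length(g) != 3L || anyNA(g) || any(g < 0))
    stop("gammas must be three nonnegative values")
  progeny <- s[["A"]] + s[["D"]] + s[["T"]]
  c(phi1 = exp(-g[1] * (s[["S"]] + s[["L"]])),
    phi2 = exp(-g[2] * progeny),
    phi3 = exp(-g[3] * progeny))
}

#' Soft-niche fate-resolved model right-hand side (model B)
#'
#' Each stem-cell fate appears as its own term: symmetric renewal (lam1, kap1)
#' is damped by the stem sub-niche feedback Phi1; the differentiation fates
#' that deposit progeny into the crowded sub-niche -- asymmetric renewal
#' (lam2, kap2) and symmetric differentiation (lam3, kap3, stoichiometric
#' factor 2) -- are damped by Phi2; the progenitor transit A -> D (chi1) is
#' damped by Phi3.  Removal terms (mu4, mu6, mu8, nu4, nu8) and progenitor
#' amplification (lam5) are bare, which places the system's instability
#' boundary exactly at lam5 = mu6: under crowding the damped transit chi1
#' Phi3 -> 0, so A grows without bound if and only if it amplifies faster than
#' it disappears.  With all gammas 0 the system is a linear compartment model.
#'
#' @param state Numeric vector (S, A, D, L, T), nonnegative.
#' @param params See [params_model_b()].
#' @return Named derivative vector over (S, A, D, L, T).
#' @export
rhs_model_b <- function(state, params) {
  s <- .check_state(state, .species5)
  p <- .check_params(params, "modelB")
  phi <- feedback_terms(s, c(p[["gam1"]], p[["gam2"]], p[["gam3"]]))
  c(S = p[["lam1"]] * phi[["phi1"]] * s[["S"]] -
        p[["lam3"]] * phi[["phi2"]] * s[["S"]] - p[["mu4"]] * s[["S"]],
    A = (p[["lam2"]] + 2 * p[["lam3"]]) * phi[["phi2"]] * s[["S"]] +
        p[["lam5"]] * s[["A"]] - p[["mu6"]] * s[["A"]] -
        p[["chi1"]] * phi[["phi3"]] * s[["A"]],
    D = p[["chi1"]] * phi[["phi3"]] * s[["A"]] - p[["mu8"]] * s[["D"]],
    L = p[["kap1"]] * phi[["phi1"]] * s[["L"]] -
        p[["kap3"]] * phi[["phi2"]] * s[["L"]] - p[["nu4"]] * s[["L"]],
    T = (p[["kap2"]] + 2 * p[["kap3"]]) * phi[["phi2"]] * s[["L"]] -
        p[["nu8"]] * s[["T"]])
}

.rhs_fun <- function(model) {
  switch(model,
         modelA = rhs_model_a,
         modelB = rhs_model_b,
         lv2 = rhs_lv2,
         toy = function(state, params) {
           c(X = -as.numeric(params[["r"]]) * as.numeric(state[[1]]))
         })
}

# parameter CSV round-trip ----------------------------------------------------

#' Write parameter vectors to a flat CSV
#'
#' One column per parameter (header row uses the ascii symbol names of the
#' model's tables, e.g. `a1...g` or `lam1...nu8` plus fixed constants), one
#' row per parameter set.
#'
#' @param params A named numeric vector or a matrix/data.frame with named
#'   columns.
#' @param path Output file path.
#' @export
write_params_csv <- function(params, path) {
  if (is.null(dim(params))) params <- as.data.frame(as.list(params))
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' Read parameter vectors from a flat CSV
#'
#' @param path CSV written by [write_params_csv()] (or compatible).
#' @param model Optional model name; if given, column names are checked to
#'   cover the model's free parameters and each row is validated.
#' @return A data.frame, one row per parameter set.
#' @export
read_params_csv <- function(path, model = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(model)) {
    m <- model_info(model)
    missing <- setdiff(m$free, names(df))
    if (length(missing))
      stop("parameter file lacks columns: ", paste(missing, collapse = ", "))
    for (i in seq_len(nrow(df)))
      .check_params(unlist(df[i, , drop = TRUE]), model)
  }
  df
}
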