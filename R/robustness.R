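# Robustness analysis of the behaviour-conditioned posterior: PCA of the
# weighted particle population.  The *last* principal components (smallest
# eigenvalues) are the directions of least posterior variance -- the "stiff"
# parameter combinations most tightly constrained by the required behaviour.
# Per-parameter contribution percentages to a component are squared-loading
# shares, the only convention under which subset shares over all parameters
# sum to 100 for a unit-norm loading vector.

.final_population <- function(x) {
  if (inherits(x, "abc_fit")) x$final
  else if (inherits(x, "abc_population")) x
  else stop("expected an 'abc_fit' or 'abc_population' object")
}

#' PCA of the weighted posterior sample
#'
#' Eigen-decomposition of the weighted covariance matrix of the particle
#' parameter vectors (covariance, not correlation: all free rates share the
#' same [0,1] prior scale, so no standardization is applied).  Components are
#' ordered by descending eigenvalue, so component 1 is the sloppiest
#' (widest) direction and the last component the stiffest.
#'
#' @param population An `"abc_fit"` or `"abc_population"` object with at
#'   least 2 distinct particles.
#' @param weighted Use the SMC importance weights (default); `FALSE` treats
#'   particles as unweighted.
#' @return A list of class `"niche_pca"`: `eigenvalues` (nonincreasing),
#'   `loadings` (component x parameter orthonormal matrix), `param_names`,
#'   `weighted`, `ess`, and `rank_deficient` (flag; zero eigenvalues are
#'   allowed but flagged).
#' @export
pca_posterior <- function(population, weighted = TRUE) {
  pop <- .final_population(population)
  X <- pop$theta
  if (nrow(unique(X)) < 2L) stop("need at least 2 distinct particles")
  w <- if (weighted) pop$weight else rep(1 / nrow(X), nrow(X))
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  if (ess < 50)
    warning("effective sample size ", round(ess, 1),
            " < 50; PCA of the posterior may be unstable", call. = FALSE)
  mu <- colSums(w * X)
  Xc <- sweep(X, 2, mu)
  # weighted covariance, unbiased normalization 1/(1 - sum w^2)
  C <- crossprod(Xc * w, Xc) / (1 - sum(w^2))
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  loadings <- t(e$vectors)
  colnames(loadings) <- colnames(X)
  rownames(loadings) <- paste0("PC", seq_along(ev))
  structure(list(eigenvalues = ev, loadings = loadings,
                 param_names = colnames(X), weighted = weighted,
                 ess = ess, center = mu,
                 rank_deficient = any(e$values <= 1e-12 * max(e$values))),
            class = "niche_pca")
}

.resolve_component <- function(pca, component) {
  d <- length(pca$eigenvalues)
  if (is.character(component)) {
    component <- match.arg(component, c("last", "second_last", "first"))
    component <- switch(component, last = d, second_last = d - 1L, first = 1L)
  }
  component <- as.integer(component)
  if (component < 0) component <- d + 1L + component
  if (component < 1L || component > d) stop("component index out of range")
  component
}

#' Contribution of a parameter subset to a principal component
#'
#' Returns `100 * sum(loading[component, params]^2)`: the squared-loading
#' share of the subset.  Loadings are unit vectors, so shares over all
#' parameters sum to 100.
#'
#' @param pca A `"niche_pca"` object.
#' @param component Component index from the sloppiest end (1 = largest
#'   eigenvalue); negative indices count from the stiff end (-1 = last,
#'   i.e. smallest eigenvalue), as do `"last"` / `"second_last"`.
#' @param params Character vector of parameter names (may be empty).
#' @param squared Use squared loadings (default).  `FALSE` uses normalized
#'   absolute loadings instead -- provided for sensitivity checks only.
#' @return Percentage in [0, 100].
#' @export
pc_contribution <- function(pca, component, params, squared = TRUE) {
  stopifnot(inherits(pca, "niche_pca"))
  comp <- .resolve_component(pca, component)
  unknown <- setdiff(params, pca$param_names)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  v <- pca$loadings[comp, ]
  if (squared) 100 * sum(v[params]^2)
  else 100 * sum(abs(v[params])) / sum(abs(v))
}

#' @export
print.niche_pca <- function(x, ...) {
  d <- length(x$eigenvalues)
  cat("<niche_pca>", d, "components,",
      if (x$weighted) "weighted" else "unweighted",
      sprintf("(ESS %.1f)%s\n", x$ess,
              if (x$rank_deficient) " -- rank deficient" else ""))
  cat("  eigenvalues:", paste(sprintf("%.3g", x$eigenvalues), collapse = " "),
      "\n")
  for (comp in c(d, d - 1L)) {
    if (comp < 1L) next
    v <- sort(100 * x$loadings[comp, ]^2, decreasing = TRUE)
    top <- utils::head(v, 3)
    cat(sprintf("  PC%d (%s): %s\n", comp,
                if (comp == d) "stiffest" else "second stiffest",
                paste(sprintf("%s %.0f%%", names(top), top), collapse = ", ")))
  }
  invisible(x)
}

#' Weighted marginal and pairwise summaries of a posterior population
#'
#' One-dimensional weighted histograms (fixed `bins` equal-width bins over
#' the prior support; masses sum to 1 per parameter) and, optionally,
#' two-dimensional weighted density grids for all parameter pairs.
#'
#' @param population An `"abc_fit"` (prior bounds taken from the fit) or an
#'   `"abc_population"` (supply `lower`/`upper`).
#' @param bins Number of histogram bins (default 20).
#' @param pairs Also compute `bins` x `bins` grids for all parameter pairs.
#' @param lower,upper Per-parameter support bounds when `population` is a
#'   bare population.
#' @return A list of class `"posterior_summaries"`: `marginals` (data.frame
#'   with columns `param`, `bin`, `mid`, `mass`), `breaks`, and `pairs` (named
#'   list of matrices, or `NULL`).
#' @export
posterior_summaries <- function(population, bins = 20, pairs = FALSE,
                                lower = NULL, upper = NULL) {
  pop <- .final_population(population)
  if (inherits(population, "abc_fit")) {
    lower <- population$prior$lower
    upper <- population$prior$upper
  }
  nm <- colnames(pop$theta)
  if (is.null(lower)) lower <- stats::setNames(rep(0, length(nm)), nm)
  if (is.null(upper)) upper <- stats::setNames(rep(1, length(nm)), nm)
  w <- pop$weight / sum(pop$weight)

  bin_of <- function(x, lo, hi) pmin(pmax(ceiling((x - lo) / (hi - lo) * bins),
                                          1L), bins)
  marg <- do.call(rbind, lapply(nm, function(p) {
    b <- bin_of(pop$theta[, p], lower[[p]], upper[[p]])
    mass <- vapply(seq_len(bins), function(k) sum(w[b == k]), numeric(1))
    mids <- lower[[p]] + (seq_len(bins) - 0.5) / bins * (upper[[p]] - lower[[p]])
    data.frame(param = p, bin = seq_len(bins), mid = mids, mass = mass)
  }))

  pair_grids <- NULL
  if (pairs && length(nm) > 1L) {
    combos <- utils::combn(nm, 2, simplify = FALSE)
    pair_grids <- stats::setNames(lapply(combos, function(pq) {
      bi <- bin_of(pop$theta[, pq[1]], lower[[pq[1]]], upper[[pq[1]]])
      bj <- bin_of(pop$theta[, pq[2]], lower[[pq[2]]], upper[[pq[2]]])
      grid <- matrix(0, bins, bins)
      for (i in seq_along(w))
        grid[bi[i], bj[i]] <- grid[bi[i], bj[i]] + w[i]
      grid
    }), vapply(combos, paste, character(1), collapse = ":"))
  }
  structure(list(marginals = marg, bins = bins, lower = lower, upper = upper,
                 pairs = pair_grids),
            class = "posterior_summaries")
}

#' Shannon entropy of each weighted marginal histogram
#'
#' Computed on the fixed-bin histograms of [posterior_summaries()] in nats;
#' a flat (prior-like) marginal has entropy log(bins), a point mass 0.
#' Parameters that the required behaviour constrains tightly have low
#' entropy; unconstrained ("sloppy") parameters stay close to log(bins).
#'
#' @inheritParams posterior_summaries
#' @return Named numeric vector of entropies.
#' @export
marginal_entropy <- function(population, bins = 20, lower = NULL,
                             upper = NULL) {
  s <- posterior_summaries(population, bins = bins, lower = lower,
                           upper = upper)
  vapply(split(s$marginals, s$marginals$param), function(df) {
    p <- df$mass[df$mass > 0]
    -sum(p * log(p))
  }, numeric(1))[unique(s$marginals$param)]
}

#' Marginal posterior histograms of an ABC fit
#'
#' @param x An `"abc_fit"` object.
#' @param params Parameters to draw (default: all).
#' @param bins Histogram bins.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.abc_fit <- function(x, params = NULL, bins = 20, ...) {
  s <- posterior_summaries(x, bins = bins)
  if (is.null(params)) params <- unique(s$marginals$param)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(params)),
                       mar = c(2.5, 2.5, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in params) {
    df <- s$marginals[s$marginals$param == p, ]
    graphics::barplot(df$mass, names.arg = round(df$mid, 2), main = p,
                      border = NA, space = 0, las = 2, cex.names = 0.5, ...)
  }
  invisible(x)
}

#' Scree and stiff-direction composition plot
#'
#' @param x A `"niche_pca"` object.
#' @param ... Unused.
#' @export
plot.niche_pca <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(old))
  graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
                 log = "y", xlab = "component", ylab = "eigenvalue",
                 main = "posterior variance spectrum")
  d <- length(x$eigenvalues)
  graphics::barplot(100 * x$loadings[d, ]^2, las = 2,
                    ylab = "squared-loading share (%)",
                    main = sprintf("stiffest direction (PC%d)", d))
  invisible(x)
}
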