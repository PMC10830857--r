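#' Game-ending-step distribution implied by the stationary state
#'
#' Each monomorphic strategy's self-play ending-step distribution (two
#' individuals of the same strategy, independent thresholds in their
#' respective roles) is weighted by the chain's stationary distribution
#' `sigma`, giving the model's prediction for the observable distribution
#' of steps at which games end.
#'
#' @param chain an [embedded_chain()].
#' @inheritParams stationary_marginals
#' @return probability vector named `"1".."L"` plus `"pass"`.
#' @export
model_step_distribution <- function(chain, game, rp, eps) {
  labs <- chain$strategies
  ts <- strategy_ts(labs)
  ks <- strategy_ks(labs)
  out <- empty_step_dist(game)
  for (i in seq_along(labs)) {
    if (chain$sigma[i] == 0) next
    s <- tom_strategy(ts[i], ks[i])
    out <- out + chain$sigma[i] * strategy_step_distribution(s, game, rp, eps)
  }
  out / sum(out)
}

#' @rdname model_step_distribution
#' @param strategy a `tom_strategy` (self-play of a monomorphic pair).
#' @export
strategy_step_distribution <- function(strategy, game, rp, eps) {
  a1 <- action_distribution(
    threshold_distribution(strategy, game, rp, eps, 1L), 1L, game)
  a2 <- action_distribution(
    threshold_distribution(strategy, game, rp, eps, 2L), 2L, game)
  s1 <- action_steps(a1)
  s2 <- action_steps(a2)
  end <- outer(s1, s2, pmin)
  w <- outer(as.numeric(a1), as.numeric(a2))
  out <- empty_step_dist(game)
  lab <- ifelse(is.infinite(end), "pass", as.character(end))
  for (nm in names(out)) out[nm] <- sum(w[lab == nm])
  out
}

empty_step_dist <- function(game) {
  structure(numeric(game$L + 1L),
            names = c(as.character(seq_len(game$L)), "pass"))
}

#' Synthetic empirical ending-step fixtures
#'
#' Draws `n` games from a model-implied ending-step distribution
#' (multinomial sampling) and normalizes, emulating an empirical take-step
#' table of `n` observed games. Supply either a precomputed distribution
#' `dist`, or the model parameters from which one is built.
#'
#' @param n number of simulated games.
#' @param dist optional ending-step probability vector (as returned by
#'   [model_step_distribution()]); when missing it is computed from
#'   `game`, `rp`, `beta`, `eps`, `Z`.
#' @inheritParams stationary_marginals
#' @param beta,Z chain parameters used when `dist` is missing.
#' @return normalized probability vector with a `"counts"` attribute.
#' @export
simulate_step_fixture <- function(n, dist = NULL, game = NULL, rp = NULL,
                                  beta = NULL, eps = NULL, Z = 500) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (is.null(dist)) {
    pm <- payoff_matrix(strategy_set(game), game, rp, eps)
    ch <- embedded_chain(pm, Z = Z, beta = beta)
    dist <- model_step_distribution(ch, game, rp, eps)
  }
  counts <- stats::rmultinom(1, size = n, prob = dist)[, 1]
  structure(counts / n, names = names(dist), counts = counts)
}

#' Model ending-step distributions over a parameter grid
#'
#' Precomputes, for every `(beta, eps)` grid point, the stationary
#' ending-step distribution of the full strategy set. The result can be
#' passed to [fit_step_distribution()] to calibrate against many empirical
#' (or fixture) distributions without recomputing the model.
#'
#' @inheritParams sweep_avg_k
#' @return list with `grid` (data frame `beta`, `eps`) and `dists` (matrix,
#'   one row per grid point, columns `"1".."L"`, `"pass"`), plus the
#'   settings used.
#' @export
step_distribution_surface <- function(game, rp, beta_grid, eps_grid,
                                      Z = 500) {
  strategies <- strategy_set(game)
  grid <- expand.grid(beta = beta_grid, eps = eps_grid,
                      KEEP.OUT.ATTRS = FALSE)
  dists <- matrix(NA_real_, nrow(grid), game$L + 1L,
                  dimnames = list(NULL, names(empty_step_dist(game))))
  for (eps in eps_grid) {
    pm <- payoff_matrix(strategies, game, rp, eps)
    rows <- which(grid$eps == eps)
    for (r in rows) {
      ch <- embedded_chain(pm, Z = Z, beta = grid$beta[r])
      dists[r, ] <- model_step_distribution(ch, game, rp, eps)
    }
  }
  list(grid = grid, dists = dists, game = game, rp = rp, Z = Z)
}

#' Calibrate selection strength and error rate to ending-step data
#'
#' Grid search for the `(beta, eps)` pair whose stationary ending-step
#' distribution best matches an empirical one. The default distance is the
#' sum of squared differences over ending-step categories; `"kl"` uses the
#' Kullback-Leibler divergence from the empirical to the model
#' distribution (model probabilities floored at `1e-12`). Both the best
#' grid point and the full distance surface are returned.
#'
#' @param empirical probability vector over ending steps `1..L` plus
#'   `"pass"` (category order as in [model_step_distribution()]); counts
#'   are accepted and normalized.
#' @inheritParams step_distribution_surface
#' @param metric `"ssq"` or `"kl"`.
#' @param surface optional precomputed [step_distribution_surface()];
#'   when supplied, `beta_grid`/`eps_grid`/`Z` are taken from it.
#' @return list with `beta`, `eps` (the best grid point), `distance`,
#'   `surface` (data frame `beta`, `eps`, `distance`), and `model_dist`
#'   (the best-fitting model distribution).
#' @export
fit_step_distribution <- function(empirical, game = NULL, rp = NULL,
                                  beta_grid = NULL, eps_grid = NULL,
                                  Z = 500, metric = c("ssq", "kl"),
                                  surface = NULL) {
  metric <- match.arg(metric)
  emp <- as.numeric(empirical)
  if (any(emp < 0) || sum(emp) <= 0)
    stop("`empirical` must be nonnegative with positive sum", call. = FALSE)
  emp <- emp / sum(emp)
  if (is.null(surface))
    surface <- step_distribution_surface(game, rp, beta_grid, eps_grid, Z)
  if (length(emp) != ncol(surface$dists))
    stop("empirical distribution has the wrong number of categories",
         call. = FALSE)
  d <- apply(surface$dists, 1, function(m) {
    if (metric == "ssq") sum((m - emp)^2)
    else sum(ifelse(emp > 0, emp * log(emp / pmax(m, 1e-12)), 0))
  })
  best <- which.min(d)
  list(beta = surface$grid$beta[best], eps = surface$grid$eps[best],
       distance = d[best], metric = metric,
       surface = cbind(surface$grid, distance = d),
       model_dist = surface$dists[best, ])
}
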