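#' Agent-based mutation-selection simulation
#'
#' Simulates the full finite-population process with explicit mutation:
#' at each update one random individual either mutates (probability `mu`)
#' to a strategy drawn uniformly from the whole set (including its own), or
#' imitates a random role model under the Fermi rule with
#' composition-dependent fitness. Fitness comes from the precomputed
#' pairwise payoff matrix and the current strategy counts, matching the
#' analytic model's fitness definition. Validates the rare-mutation
#' embedded chain: as `mu` shrinks, time-averaged strategy frequencies
#' approach the chain's stationary distribution.
#'
#' The update loop runs in compiled code but draws from R's global RNG, so
#' identical seeds reproduce identical trajectories bit for bit.
#'
#' @param pay a [payoff_matrix()].
#' @param Z population size.
#' @param mu mutation probability per update, in `[0, 1]`.
#' @param beta selection intensity.
#' @param steps number of updates.
#' @param burn_in updates discarded before averaging (`< steps`).
#' @param record_every recording cadence in updates; defaults to `Z`
#'   (one generation).
#' @param keep_trajectory if `TRUE`, also return the recorded frequency
#'   trajectory (can be large).
#' @return list with `frequencies` (named time-averaged strategy
#'   frequencies), `monomorphic_fraction` (share of recorded states with a
#'   single surviving strategy), `n_recorded`, `final_counts`, and
#'   optionally `trajectory` (data frame `generation` + one column per
#'   strategy).
#' @examples
#' g <- icg(4)
#' pm <- payoff_matrix(strategy_set(g), g, "inertia", 0.19)
#' set.seed(1)
#' sim <- simulate_moran(pm, Z = 50, mu = 1e-3, beta = 0.31, steps = 1e5)
#' sum(sim$frequencies)
#' @export
simulate_moran <- function(pay, Z, mu, beta, steps,
                           burn_in = floor(steps / 10),
                           record_every = Z, keep_trajectory = FALSE) {
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]", call. = FALSE)
  if (burn_in < 0 || burn_in >= steps)
    stop("need steps > burn_in >= 0", call. = FALSE)
  res <- .moran_run(unclass(pay), as.integer(Z), mu, beta,
                    as.double(steps), as.double(burn_in),
                    as.integer(record_every), isTRUE(keep_trajectory))
  names(res$frequencies) <- rownames(pay)
  names(res$final_counts) <- rownames(pay)
  if (keep_trajectory) {
    traj <- as.data.frame(res$trajectory)
    names(traj) <- rownames(pay)
    res$trajectory <- cbind(data.frame(generation = res$generation), traj)
    res$generation <- NULL
  }
  res
}
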