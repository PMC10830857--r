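#' Expected pairwise payoffs between ToM strategies
#'
#' The payoff of strategy `X` against strategy `Y` is the expected game
#' payoff to `X`, averaged over `X` playing Player 1 (with `Y` as Player 2)
#' and Player 2 (with `Y` as Player 1). `exact_fitness()` computes the
#' expectation analytically by summing over the product of the two players'
#' exact action distributions in each role assignment; `mc_fitness()`
#' estimates the same quantity by Monte Carlo, sampling fresh thresholds
#' for both roles of both players at every repetition.
#'
#' An optional linear reasoning cost `cost` subtracts `cost * k_X` from
#' `X`'s fitness after payoff averaging; `cost = 0` recovers the baseline.
#'
#' @param X,Y `tom_strategy` objects.
#' @param game a `centipede_game`.
#' @param rp reasoning process, one of [rp_kinds()].
#' @param eps cognitive error probability.
#' @param cost linear cost per reasoning level (default 0).
#' @param R number of Monte Carlo repetitions.
#' @return expected per-interaction payoff to `X` (scalar).
#' @examples
#' g <- icg(4)
#' exact_fitness(tom_strategy(1, 0), tom_strategy(1, 0), g, "inertia", 0.19)
#' @export
exact_fitness <- function(X, Y, game, rp, eps, cost = 0) {
  aX <- role_action_dists(X, game, rp, eps)
  aY <- role_action_dists(Y, game, rp, eps)
  pair_expect(aX, aY, game)[1L] - cost * X$k
}

# both-role action distributions of one strategy
role_action_dists <- function(s, game, rp, eps) {
  lapply(1:2, function(role)
    action_distribution(
      threshold_distribution(s, game, rp, eps, role), role, game))
}

# expected payoffs (to X, to Y) with X role-averaged against Y
pair_expect <- function(aX, aY, game) {
  e1 <- ending_expectation(aX[[1L]], aY[[2L]], game)  # X as P1
  e2 <- ending_expectation(aY[[1L]], aX[[2L]], game)  # Y as P1
  c((e1[["p1"]] + e2[["p2"]]) / 2, (e2[["p1"]] + e1[["p2"]]) / 2)
}

# expected (p1, p2) payoffs given P1 and P2 action distributions
ending_expectation <- function(a1, a2, game) {
  s1 <- action_steps(a1)
  s2 <- action_steps(a2)
  end <- outer(s1, s2, pmin)                 # Inf = pass-through
  w <- outer(as.numeric(a1), as.numeric(a2))
  step <- ifelse(is.infinite(end), NA_integer_, end)
  c(p1 = sum(w * role_payoff(game, step, 1L)),
    p2 = sum(w * role_payoff(game, step, 2L)))
}

action_steps <- function(a) {
  n <- names(a)
  ifelse(n == "never", Inf, suppressWarnings(as.numeric(n)))
}

#' @rdname exact_fitness
#' @export
mc_fitness <- function(X, Y, game, rp, eps, R = 5e4, cost = 0) {
  if (R < 1) stop("`R` must be at least 1", call. = FALSE)
  R <- as.integer(R)
  # fresh thresholds for both roles of both players at each repetition
  x1 <- thresholds_to_steps(sample_thresholds(X, game, rp, eps, 1L, R), 1L, game)
  x2 <- thresholds_to_steps(sample_thresholds(X, game, rp, eps, 2L, R), 2L, game)
  y1 <- thresholds_to_steps(sample_thresholds(Y, game, rp, eps, 1L, R), 1L, game)
  y2 <- thresholds_to_steps(sample_thresholds(Y, game, rp, eps, 2L, R), 2L, game)
  endA <- pmin(x1, y2)  # X as Player 1
  endB <- pmin(y1, x2)  # X as Player 2
  payA <- role_payoff(game, ifelse(is.infinite(endA), NA, endA), 1L)
  payB <- role_payoff(game, ifelse(is.infinite(endB), NA, endB), 2L)
  mean((payA + payB) / 2) - cost * X$k
}

# smallest feasible step >= threshold for the role; Inf = never
thresholds_to_steps <- function(th, role, game) {
  steps <- role_steps(game, role)
  lookup <- vapply(seq_len(game$L + 1L), function(t) {
    s <- steps[steps >= t]
    if (length(s)) as.numeric(s[1L]) else Inf
  }, numeric(1))
  lookup[th]
}

#' Pairwise payoff matrix over a strategy set
#'
#' Fills every ordered pair `(X, Y)` with `X`'s expected per-interaction
#' payoff against `Y`, role-averaged. The exact engine is deterministic;
#' the Monte Carlo engine reproduces the sampling scheme used for the
#' published fitness estimates (`R = 5e4` by default).
#'
#' @param strategies list of `tom_strategy` (e.g. [strategy_set()]).
#' @inheritParams exact_fitness
#' @param mode `"exact"` or `"mc"`.
#' @return square numeric matrix with `"(t,k)"` dimnames, class
#'   `payoff_matrix`.
#' @examples
#' pm <- payoff_matrix(strategy_set(icg(4)), icg(4), "inertia", 0.19)
#' dim(pm)
#' @export
payoff_matrix <- function(strategies, game, rp, eps,
                          mode = c("exact", "mc"), R = 5e4, cost = 0) {
  mode <- match.arg(mode)
  if (!length(strategies)) stop("empty strategy set", call. = FALSE)
  labs <- unname(vapply(strategies, format, character(1)))
  n <- length(strategies)
  pay <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  if (mode == "exact") {
    acts <- lapply(strategies, role_action_dists, game = game, rp = rp,
                   eps = eps)
    for (i in seq_len(n))
      for (j in seq_len(n)) {
        e <- pair_expect(acts[[i]], acts[[j]], game)
        pay[i, j] <- e[1L] - cost * strategies[[i]]$k
      }
  } else {
    for (i in seq_len(n))
      for (j in seq_len(n))
        pay[i, j] <- mc_fitness(strategies[[i]], strategies[[j]],
                                game, rp, eps, R = R, cost = cost)
  }
  structure(pay, class = c("payoff_matrix", "matrix", "array"),
            strategies = strategies)
}
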