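#' Theory-of-Mind strategies
#'
#' A strategy is a duple `(t, k)`: `t` in `1..L+1` is the prior belief about
#' the earliest step at which to Take (`t = L + 1` encodes always-Postpone)
#' and `k >= 0` is the depth of recursive reasoning. An individual with
#' `k > 0` believes every co-player uses `(t, k - 1)` and responds to the
#' behaviour that belief implies, recursively down to the level-0 belief.
#'
#' @param t integer threshold in `1..L+1`.
#' @param k nonnegative integer recursion depth.
#' @return object of class `tom_strategy`.
#' @examples
#' tom_strategy(3, 2)
#' @export
tom_strategy <- function(t, k) {
  if (length(t) != 1L || length(k) != 1L || !is.finite(t) || !is.finite(k) ||
      t != round(t) || k != round(k) || t < 1 || k < 0)
    stop("`t` must be a positive integer and `k` a nonnegative integer",
         call. = FALSE)
  structure(list(t = as.integer(t), k = as.integer(k)),
            class = "tom_strategy")
}

#' @export
print.tom_strategy <- function(x, ...) {
  cat(sprintf("ToM strategy (t = %d, k = %d)\n", x$t, x$k))
  invisible(x)
}

#' @export
format.tom_strategy <- function(x, ...) sprintf("(%d,%d)", x$t, x$k)

#' Full strategy set for a game
#'
#' All `(t, k)` duples with `t` in `1..L+1` and `k` in `0..L`, giving
#' `(L + 1)^2` strategies (25 for `L = 4`, 49 for `L = 6`).
#'
#' @param game a `centipede_game`, or an even integer `L`.
#' @param k_max largest recursion depth; defaults to `L`.
#' @return list of `tom_strategy`, named `"(t,k)"`.
#' @export
strategy_set <- function(game, k_max = NULL) {
  L <- if (inherits(game, "centipede_game")) game$L else check_even_L(game)
  if (is.null(k_max)) k_max <- L
  grid <- expand.grid(k = 0:k_max, t = 1:(L + 1L))
  out <- lapply(seq_len(nrow(grid)),
                function(i) tom_strategy(grid$t[i], grid$k[i]))
  names(out) <- vapply(out, format, character(1))
  out
}

#' @rdname rp_kernel
#' @export
rp_kinds <- function() c("unconditional", "conditional", "inertia")

#' Reasoning-process kernels
#'
#' One step of recursive reasoning: given the threshold `co_threshold` at
#' which the reasoner believes her co-player will take, each kernel returns
#' the threshold she adopts in response.
#'
#' * `"unconditional"`: always preempt, `max(co_threshold - 1, 1)`.
#' * `"conditional"`: compare the payoff from taking one step before the
#'   co-player against the payoff received when the game ends at the
#'   co-player's threshold, and adopt whichever threshold pays more (ties
#'   favour the earlier take).
#' * `"inertia"`: preempt only on a *strict* payoff gain; otherwise keep
#'   `own_prev`, the threshold this reasoner inferred at her previous
#'   (two-lower) recursion level, bottoming out at the prior belief `t`.
#'
#' Payoffs are compared on the game-ending-step scale: preempting at
#' `co_threshold - 1` is valued as the taker's share at that step, while
#' letting the game end at `co_threshold` is valued as the non-taker's
#' share there (or the reasoner's role share of the pass-through when
#' `co_threshold = L + 1`). When `co_threshold = 1` no preemption is
#' possible: the conditional kernel returns 1 and the inertia kernel falls
#' back to `own_prev`.
#'
#' @param rp one of `rp_kinds()`.
#' @param game a `centipede_game`.
#' @param role role (1 or 2) of the reasoner at this recursion level.
#' @param co_threshold believed co-player threshold, `1..L+1`.
#' @param own_prev the reasoner's fallback threshold (inertia only).
#' @return integer threshold in `1..L+1`.
#' @export
rp_kernel <- function(rp, game, role, co_threshold, own_prev = co_threshold) {
  rp <- match.arg(rp, rp_kinds())
  Lp1 <- game$L + 1L
  stopifnot(co_threshold >= 1L, co_threshold <= Lp1,
            own_prev >= 1L, own_prev <= Lp1)
  if (rp == "unconditional") return(max(co_threshold - 1L, 1L))
  if (co_threshold == 1L)
    return(if (rp == "conditional") 1L else as.integer(own_prev))
  pi_take <- taker_units(game, co_threshold - 1L)
  pi_wait <- if (co_threshold == Lp1) pass_units(game, role)
             else other_units(game, co_threshold)
  if (rp == "conditional") {
    if (pi_take >= pi_wait) co_threshold - 1L else as.integer(co_threshold)
  } else {
    if (pi_take > pi_wait) co_threshold - 1L else as.integer(own_prev)
  }
}

# kernel lookup table K[co_threshold, own_prev] for one role
kernel_table <- function(rp, game, role) {
  Lp1 <- game$L + 1L
  K <- matrix(0L, Lp1, Lp1)
  for (co in seq_len(Lp1))
    for (prev in seq_len(Lp1))
      K[co, prev] <- rp_kernel(rp, game, role, co, prev)
  K
}

# role occupied at recursion level j when the final level k is played in
# `role`: seats alternate downwards, so level j matches `role` iff k - j is
# even
role_at_level <- function(role, k, j) {
  if ((k - j) %% 2L == 0L) role else 3L - role
}

#' Deterministic reasoning trace
#'
#' The error-free (`eps = 0`) recursion: the threshold inferred at every
#' level `0..k`, level 0 being the prior belief `t` and level `k` the
#' threshold actually used in `role`.
#'
#' @param strategy a `tom_strategy`.
#' @inheritParams rp_kernel
#' @return integer vector of length `k + 1`, named `level0..levelk`.
#' @examples
#' threshold_trace(tom_strategy(3, 2), icg(4), "inertia", role = 1)
#' @export
threshold_trace <- function(strategy, game, rp, role) {
  check_strategy(strategy, game)
  role <- check_role(role)
  k <- strategy$k
  out <- integer(k + 1L)
  out[1L] <- strategy$t
  for (j in seq_len(k)) {
    # own_prev at level j is the same seat's inference two levels down
    # (level j - 2), bottoming out at the prior belief
    own_prev <- if (j >= 2L) out[j - 1L] else strategy$t
    out[j + 1L] <- rp_kernel(rp, game, role_at_level(role, k, j),
                             out[j], own_prev)
  }
  names(out) <- paste0("level", 0:k)
  out
}

#' Exact threshold distribution of a ToM strategy
#'
#' Enumerates the cognitive-error branching tree exactly. At every
#' recursion level `1..k` the kernel output `x` is perturbed to `x - 1`
#' with probability `eps` and to `x + 1` with probability `eps` (kept at
#' `x` with probability `1 - 2 eps`), clamped to `[1, L + 1]` with boundary
#' mass merged; the level-0 prior belief is error-free. Roles alternate
#' with recursion level so that level `k` is evaluated in the focal
#' individual's `role`.
#'
#' @param strategy a `tom_strategy` with `t` in `1..L+1`.
#' @param eps cognitive error probability per deviation direction,
#'   `0 <= eps <= 0.5`.
#' @inheritParams rp_kernel
#' @return object of class `threshold_distribution`: a probability vector
#'   named `"1".."L+1"` summing to one.
#' @examples
#' threshold_distribution(tom_strategy(3, 2), icg(4), "inertia",
#'                        eps = 0.19, role = 1)
#' @export
threshold_distribution <- function(strategy, game, rp, eps, role) {
  check_strategy(strategy, game)
  role <- check_role(role)
  check_eps(eps)
  Lp1 <- game$L + 1L
  k <- strategy$k
  # state: joint mass over (out_{j-1}, out_j); own_prev at level j+1 is
  # out_{j-1}, the same seat's previous inference (prior t below level 1)
  P <- matrix(0, Lp1, Lp1)
  P[strategy$t, strategy$t] <- 1
  if (k > 0L) {
    branch <- c(eps, 1 - 2 * eps, eps)
    for (j in seq_len(k)) {
      K <- kernel_table(rp, game, role_at_level(role, k, j))
      Pn <- matrix(0, Lp1, Lp1)
      idx <- which(P > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        prev <- idx[r, 1L]; cur <- idx[r, 2L]
        x <- K[cur, prev]
        for (d in -1:1) {
          xi <- min(max(x + d, 1L), Lp1)
          Pn[cur, xi] <- Pn[cur, xi] + P[prev, cur] * branch[d + 2L]
        }
      }
      P <- Pn
    }
  }
  probs <- colSums(P)
  structure(probs / sum(probs),
            names = as.character(seq_len(Lp1)),
            class = "threshold_distribution",
            L = game$L, role = role)
}

#' @export
print.threshold_distribution <- function(x, ...) {
  cat("Take-threshold distribution (threshold L+1 = always-Postpone)\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Sample thresholds from the stochastic reasoning process
#'
#' Draws realizations of the error-branching recursion; empirical
#' frequencies converge to [threshold_distribution()]. Uses R's global RNG,
#' so results are reproducible under `set.seed()`.
#'
#' @inheritParams threshold_distribution
#' @param n number of independent draws.
#' @return integer vector of length `n` with values in `1..L+1`.
#' @export
sample_thresholds <- function(strategy, game, rp, eps, role, n = 1L) {
  check_strategy(strategy, game)
  role <- check_role(role)
  check_eps(eps)
  Lp1 <- game$L + 1L
  k <- strategy$k
  cur <- rep.int(strategy$t, n)
  prev <- cur
  if (k > 0L) {
    for (j in seq_len(k)) {
      K <- kernel_table(rp, game, role_at_level(role, k, j))
      x <- K[cbind(cur, prev)]
      if (eps > 0) {
        d <- sample.int(3L, n, replace = TRUE,
                        prob = c(eps, 1 - 2 * eps, eps)) - 2L
        x <- pmin(pmax(x + d, 1L), Lp1)
      }
      prev <- cur
      cur <- x
    }
  }
  as.integer(cur)
}

#' Map a threshold distribution to role-feasible actions
#'
#' A threshold `t` maps to the smallest step at which the role can act that
#' is `>= t` (odd steps for Player 1, even for Player 2); thresholds beyond
#' the role's last step map to never taking. Probability mass aggregates
#' accordingly.
#'
#' @param tdist a `threshold_distribution` (or bare probability vector over
#'   thresholds `1..L+1`).
#' @inheritParams rp_kernel
#' @return object of class `action_distribution`: probability vector named
#'   by feasible step with a final `"never"` category.
#' @examples
#' td <- threshold_distribution(tom_strategy(3, 0), icg(4), "inertia", 0, 1)
#' action_distribution(td, role = 1, game = icg(4))
#' @export
action_distribution <- function(tdist, role, game) {
  role <- check_role(role)
  Lp1 <- game$L + 1L
  p <- as.numeric(tdist)
  if (length(p) != Lp1 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("`tdist` must be a probability vector over thresholds 1..L+1",
         call. = FALSE)
  steps <- role_steps(game, role)
  # smallest feasible step >= each threshold, NA meaning never
  act <- vapply(seq_len(Lp1), function(t) {
    s <- steps[steps >= t]
    if (length(s)) s[1L] else NA_integer_
  }, integer(1))
  out <- numeric(length(steps) + 1L)
  names(out) <- c(as.character(steps), "never")
  for (t in seq_len(Lp1)) {
    lab <- if (is.na(act[t])) "never" else as.character(act[t])
    out[lab] <- out[lab] + p[t]
  }
  structure(out, class = "action_distribution", role = role, L = game$L)
}

#' @export
print.action_distribution <- function(x, ...) {
  cat(sprintf("Take-step distribution, Player %d\n", attr(x, "role")))
  print(round(unclass(x), 6))
  invisible(x)
}

check_strategy <- function(strategy, game) {
  if (!inherits(strategy, "tom_strategy"))
    stop("`strategy` must be a tom_strategy", call. = FALSE)
  if (strategy$t > game$L + 1L)
    stop("threshold t exceeds L + 1 for this game", call. = FALSE)
  invisible(strategy)
}

check_role <- function(role) {
  if (is.character(role)) role <- match(tolower(role), c("p1", "p2"))
  if (length(role) != 1L || is.na(role) || !(role %in% 1:2))
    stop("`role` must be 1/\"p1\" or 2/\"p2\"", call. = FALSE)
  as.integer(role)
}

check_eps <- function(eps) {
  if (length(eps) != 1L || !is.finite(eps) || eps < 0 || eps > 0.5)
    stop("`eps` must satisfy 0 <= eps <= 0.5 (each deviation direction has probability eps)",
         call. = FALSE)
  invisible(eps)
}
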