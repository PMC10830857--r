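#' Fermi imitation probability
#'
#' Probability that a focal individual with fitness `f_focal` imitates a
#' role model with fitness `f_role_model` under the pairwise-comparison
#' rule `p = (1 + exp(-beta * (f_role_model - f_focal)))^-1`. At `beta = 0`
#' (neutral drift) or equal fitness the probability is exactly 1/2.
#'
#' @param beta selection intensity, `beta >= 0`.
#' @param f_role_model,f_focal fitness values.
#' @return probability in (0, 1); overflow-safe for large `|beta * df|`.
#' @export
fermi_prob <- function(beta, f_role_model, f_focal) {
  if (any(beta < 0)) stop("`beta` must be nonnegative", call. = FALSE)
  stats::plogis(beta * (f_role_model - f_focal))
}

#' Composition-dependent fitness in a two-strategy population
#'
#' With `i` individuals playing `A` and `Z - i` playing `B` in a well-mixed
#' population, each individual's fitness is its average payoff against the
#' other `Z - 1` individuals (self excluded).
#'
#' @param i number of `A` players, `1 <= i <= Z - 1`.
#' @param Z population size.
#' @param pAA,pAB,pBA,pBB pairwise expected payoffs (entry `pXY` is `X`'s
#'   payoff against `Y`).
#' @return list with vectors `fA`, `fB` (vectorised over `i`).
#' @export
composition_fitness <- function(i, Z, pAA, pAB, pBA, pBB) {
  if (any(i < 1L) || any(i > Z - 1L))
    stop("`i` must lie in 1..Z-1", call. = FALSE)
  list(fA = ((i - 1) * pAA + (Z - i) * pAB) / (Z - 1),
       fB = (i * pBA + (Z - i - 1) * pBB) / (Z - 1))
}

pair_payoffs <- function(pay, invader, resident) {
  list(pAA = pay[invader, invader], pAB = pay[invader, resident],
       pBA = pay[resident, invader], pBB = pay[resident, resident])
}

#' Fixation probability of a single mutant under Fermi dynamics
#'
#' Closed form for the birth-death chain induced by pairwise comparison:
#' `rho = 1 / (1 + sum_m prod_{i<=m} lambda_i)` with
#' `lambda_i = exp(-beta * (f_inv(i) - f_res(i)))`. Products are
#' accumulated in log space so large `beta * Z` is safe.
#'
#' @param pay a [payoff_matrix()] (or plain labelled matrix).
#' @param invader,resident strategy labels `"(t,k)"`, `tom_strategy`
#'   objects, or indices into `pay`.
#' @param Z population size, `Z >= 2`.
#' @param beta selection intensity.
#' @return fixation probability of one `invader` mutant in a `resident`
#'   population.
#' @export
fixation_probability <- function(pay, invader, resident, Z, beta) {
  if (Z < 2) stop("`Z` must be at least 2", call. = FALSE)
  invader <- strategy_index(pay, invader)
  resident <- strategy_index(pay, resident)
  if (invader == resident) return(1 / Z)
  p <- pair_payoffs(pay, invader, resident)
  i <- seq_len(Z - 1)
  f <- composition_fitness(i, Z, p$pAA, p$pAB, p$pBA, p$pBB)
  # S_m = log prod_{i<=m} lambda_i
  S <- cumsum(-beta * (f$fA - f$fB))
  exp(-logsumexp(c(0, S)))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

strategy_index <- function(pay, s) {
  labs <- rownames(pay)
  if (inherits(s, "tom_strategy")) s <- format(s)
  if (is.character(s)) {
    i <- match(s, labs)
    if (is.na(i)) stop(sprintf("strategy %s not in payoff matrix", s),
                       call. = FALSE)
    return(i)
  }
  as.integer(s)
}

#' Rare-mutation embedded Markov chain over monomorphic states
#'
#' In the small-mutation limit at most two strategies coexist, so the
#' evolutionary dynamics reduces to a Markov chain whose states are the
#' homogeneous populations. The transition probability from resident `i`
#' to mutant `j` is `rho_ij / (nS - 1)`, with the diagonal absorbing the
#' remainder; the stationary distribution `sigma` is the normalized left
#' fixed vector, obtained by a direct linear solve.
#'
#' `k_transition_weight < 1` optionally down-weights transitions between
#' strategies with different recursion depths `k` (beliefs change more
#' readily than cognitive capacity); the freed mass stays on the diagonal.
#'
#' @inheritParams fixation_probability
#' @param k_transition_weight multiplier in `[0, 1]` on transitions that
#'   change `k` (default 1: unbiased mutation kernel).
#' @return object of class `embedded_chain`: list with `strategies`
#'   (labels), `Gamma`, `sigma`, `rho` (the raw fixation matrix), `Z`,
#'   `beta`.
#' @examples
#' g <- icg(4)
#' pm <- payoff_matrix(strategy_set(g), g, "inertia", 0.19)
#' ch <- embedded_chain(pm, Z = 500, beta = 0.31)
#' head(sort(ch$sigma, decreasing = TRUE))
#' @export
embedded_chain <- function(pay, Z, beta, k_transition_weight = 1) {
  labs <- rownames(pay)
  n <- nrow(pay)
  if (n < 2) stop("need at least two strategies", call. = FALSE)
  rho <- matrix(0, n, n, dimnames = dimnames(pay))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j)
        rho[i, j] <- fixation_probability(pay, invader = j, resident = i,
                                          Z = Z, beta = beta)
  w <- matrix(1, n, n)
  if (k_transition_weight != 1) {
    ks <- strategy_ks(labs)
    w <- 1 - (1 - k_transition_weight) * outer(ks, ks, "!=")
  }
  Gamma <- rho * w / (n - 1)
  diag(Gamma) <- 0
  diag(Gamma) <- 1 - rowSums(Gamma)
  sigma <- stationary_distribution(Gamma)
  structure(list(strategies = labs, Gamma = Gamma, sigma = sigma,
                 rho = rho, Z = Z, beta = beta),
            class = "embedded_chain")
}

strategy_ks <- function(labs) {
  as.integer(sub("^\\((\\d+),(\\d+)\\)$", "\\2", labs))
}

strategy_ts <- function(labs) {
  as.integer(sub("^\\((\\d+),(\\d+)\\)$", "\\1", labs))
}

#' Stationary distribution of a stochastic matrix
#'
#' Solves the left fixed-vector system `(t(Gamma) - I) sigma = 0` with the
#' normalization constraint appended, rather than iterating.
#'
#' @param Gamma row-stochastic matrix.
#' @return probability vector named as `Gamma`'s rows.
#' @export
stationary_distribution <- function(Gamma) {
  n <- nrow(Gamma)
  A <- rbind(t(Gamma) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  sigma <- qr.solve(A, b)
  sigma[sigma < 0 & sigma > -1e-12] <- 0
  sigma <- sigma / sum(sigma)
  names(sigma) <- rownames(Gamma)
  sigma
}

#' @export
print.embedded_chain <- function(x, ...) {
  cat(sprintf("Embedded rare-mutation chain: %d strategies, Z = %d, beta = %g\n",
              length(x$strategies), x$Z, x$beta))
  top <- sort(x$sigma, decreasing = TRUE)[seq_len(min(5, length(x$sigma)))]
  cat("top stationary mass:\n")
  print(round(top, 4))
  invisible(x)
}

#' Stationary marginals and belief-action mismatch
#'
#' Summaries of the stationary distribution `sigma`: marginals over beliefs
#' `t`, recursion depths `k`, and realized take steps `T` (each strategy's
#' own action distributions, both roles pooled equally, with thresholds
#' beyond the role's last step reported as `"never"`); the sigma-weighted
#' average `k`; and, per `k`-level, the mean excess of the prior belief `t`
#' over the realized take-threshold (the optimism bias: positive values
#' mean individuals believe others take later than they themselves end up
#' taking). Strategies without Theory of Mind (`k = 0`) always act exactly
#' at their belief, so their mismatch is zero.
#'
#' @param chain an [embedded_chain()].
#' @param game,rp,eps the game, reasoning process and error rate the chain
#'   was built under.
#' @return list with `t_marginal`, `k_marginal`, `action_marginal`,
#'   `avg_k`, `avg_t`, and `mismatch` (data frame `k`, `weight`,
#'   `mean_belief`, `mean_threshold`, `mismatch`).
#' @export
stationary_marginals <- function(chain, game, rp, eps) {
  labs <- chain$strategies
  sig <- chain$sigma
  ts <- strategy_ts(labs)
  ks <- strategy_ks(labs)
  t_marg <- tapply_sum(sig, ts)
  k_marg <- tapply_sum(sig, ks)

  Lp1 <- game$L + 1L
  steps <- c(as.character(seq_len(game$L)), "never")
  act_marg <- structure(numeric(length(steps)), names = steps)
  mean_thr <- numeric(length(labs))
  for (i in seq_along(labs)) {
    s <- tom_strategy(ts[i], ks[i])
    td1 <- threshold_distribution(s, game, rp, eps, 1L)
    td2 <- threshold_distribution(s, game, rp, eps, 2L)
    a1 <- action_distribution(td1, 1L, game)
    a2 <- action_distribution(td2, 2L, game)
    for (nm in names(a1)) act_marg[nm] <- act_marg[nm] + sig[i] * a1[nm] / 2
    for (nm in names(a2)) act_marg[nm] <- act_marg[nm] + sig[i] * a2[nm] / 2
    mean_thr[i] <- (sum(seq_len(Lp1) * td1) + sum(seq_len(Lp1) * td2)) / 2
  }

  mism <- do.call(rbind, lapply(sort(unique(ks)), function(k) {
    w <- sig * (ks == k)
    tot <- sum(w)
    mb <- if (tot > 0) sum(w * ts) / tot else NA_real_
    mt <- if (tot > 0) sum(w * mean_thr) / tot else NA_real_
    data.frame(k = k, weight = tot, mean_belief = mb,
               mean_threshold = mt, mismatch = mb - mt)
  }))

  list(t_marginal = t_marg, k_marginal = k_marg,
       action_marginal = act_marg,
       avg_k = sum(sig * ks), avg_t = sum(sig * ts),
       mismatch = mism)
}

tapply_sum <- function(x, by) {
  lev <- sort(unique(by))
  structure(vapply(lev, function(l) sum(x[by == l]), numeric(1)),
            names = as.character(lev))
}

#' Gradient of selection for a two-strategy population
#'
#' `G(i) = T+(i) - T-(i)`, the difference between the probabilities that
#' the number of focal-strategy players increases or decreases by one at
#' composition `i`, with
#' `T+-(i) = (i/Z) ((Z-i)/Z) * fermi_prob(beta, +-(f_A - f_B))`. Interior
#' roots are classified from the sign pattern: a `+` to `-` change (as `i`
#' grows) is an attractor of the focal strategy's frequency, a `-` to `+`
#' change is a repeller (coordination threshold).
#'
#' @inheritParams fixation_probability
#' @param focal,other strategy labels/indices; `i` counts `focal` players.
#' @return object of class `selection_gradient`: list with `profile`
#'   (data frame `i`, `G`), `roots` (data frame `i`, `type`), `focal`,
#'   `other`, `Z`, `beta`.
#' @export
gradient_of_selection <- function(pay, focal, other, Z, beta) {
  focal <- strategy_index(pay, focal)
  other <- strategy_index(pay, other)
  p <- pair_payoffs(pay, focal, other)
  i <- seq_len(Z - 1)
  f <- composition_fitness(i, Z, p$pAA, p$pAB, p$pBA, p$pBB)
  df <- f$fA - f$fB
  G <- (i / Z) * ((Z - i) / Z) * tanh(beta * df / 2)
  roots <- classify_roots(i, G)
  structure(list(profile = data.frame(i = i, G = G), roots = roots,
                 focal = rownames(pay)[focal], other = rownames(pay)[other],
                 Z = Z, beta = beta),
            class = "selection_gradient")
}

# interior sign changes of G on the discrete grid, reported midway
classify_roots <- function(i, G, tol = 0) {
  s <- sign(G)
  s[abs(G) <= tol] <- 0
  out <- data.frame(i = numeric(0), type = character(0))
  nz <- which(s != 0)
  if (length(nz) < 2) return(out)
  for (r in seq_len(length(nz) - 1)) {
    a <- nz[r]; b <- nz[r + 1]
    if (s[a] != s[b]) {
      type <- if (s[a] > 0) "attractor" else "repeller"
      out <- rbind(out, data.frame(i = (i[a] + i[b]) / 2, type = type))
    }
  }
  out
}

#' @export
print.selection_gradient <- function(x, ...) {
  cat(sprintf("Gradient of selection: %s (focal) vs %s, Z = %d, beta = %g\n",
              x$focal, x$other, x$Z, x$beta))
  if (nrow(x$roots)) print(x$roots, row.names = FALSE)
  else cat("no interior roots\n")
  invisible(x)
}

#' Evolutionary robustness of a strategy
#'
#' A resident strategy is evolutionarily robust when every mutant's
#' fixation probability into it is below the neutral value `1/Z` (strictly,
#' within a small relative margin; equalities are reported as neutral
#' edges).
#'
#' @inheritParams fixation_probability
#' @param s resident strategy (label, `tom_strategy`, or index).
#' @param margin relative tolerance on the strict inequality.
#' @return list with `robust` (logical), `neutral` (1/Z), and `table`
#'   (data frame `mutant`, `rho`, `below_neutral`, `neutral_edge`).
#' @export
is_evolutionarily_robust <- function(pay, s, Z, beta, margin = 1e-12) {
  s <- strategy_index(pay, s)
  labs <- rownames(pay)
  mutants <- setdiff(seq_along(labs), s)
  rho <- vapply(mutants, function(m)
    fixation_probability(pay, invader = m, resident = s, Z = Z, beta = beta),
    numeric(1))
  neutral <- 1 / Z
  below <- rho < neutral * (1 - margin)
  edge <- !below & rho <= neutral * (1 + margin)
  list(robust = all(below), neutral = neutral,
       table = data.frame(mutant = labs[mutants], rho = rho,
                          below_neutral = below, neutral_edge = edge))
}

#' Average-k surface over a selection/error grid
#'
#' Recomputes the stationary distribution of the full strategy set for
#' every `(beta, eps)` combination and reports the sigma-weighted average
#' recursion depth, as tidy data.
#'
#' @param game a `centipede_game`.
#' @param rp reasoning process.
#' @param beta_grid,eps_grid numeric grids.
#' @param Z population size.
#' @param cost linear reasoning cost per level.
#' @return data frame with columns `beta`, `eps`, `avg_k`, `avg_t`.
#' @export
sweep_avg_k <- function(game, rp, beta_grid, eps_grid, Z = 500, cost = 0) {
  strategies <- strategy_set(game)
  out <- vector("list", length(beta_grid) * length(eps_grid))
  n <- 0L
  for (eps in eps_grid) {
    pm <- payoff_matrix(strategies, game, rp, eps, cost = cost)
    for (beta in beta_grid) {
      ch <- embedded_chain(pm, Z = Z, beta = beta)
      ks <- strategy_ks(ch$strategies)
      ts <- strategy_ts(ch$strategies)
      n <- n + 1L
      out[[n]] <- data.frame(beta = beta, eps = eps,
                             avg_k = sum(ch$sigma * ks),
                             avg_t = sum(ch$sigma * ts))
    }
  }
  do.call(rbind, out)
}
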