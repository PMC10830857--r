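#' Centipede game specifications
#'
#' A centipede game is a two-player alternating sequential game over `L`
#' steps. At each step the mover either Takes (ending the game and claiming
#' the larger share of the resource) or Postpones (letting the resource, or
#' its split, evolve and passing the move). Player 1 moves at odd steps,
#' Player 2 at even steps; `L` must therefore be even so that Player 2 owns
#' the final decision. If Player 2 postpones at step `L` the game "passes
#' through" to a final split favouring Player 1.
#'
#' `icg()` builds the incremental (exponentially growing) variant: the
#' resource starts at `M`, is multiplied by `growth` at every step, and the
#' taker at step `l` receives a `split` fraction of `growth^(l-1) * M`. On
#' pass-through one final growth is applied and Player 1 receives the
#' `split` fraction.
#'
#' `centipede_game()` builds a game from an explicit per-step payoff table,
#' which is how constant-size (CCG-style) and other custom variants are
#' supplied. In such tables the taker at step `l` is the player who owns the
#' seat (Player 1 at odd `l`, Player 2 at even `l`).
#'
#' Payoffs are also stored internally as integers on a fixed decimal scale
#' so that the payoff comparisons inside the reasoning kernels are exact and
#' never tie because of floating-point representation.
#'
#' @param L even number of decision steps (at least 2).
#' @param M initial resource (currency units).
#' @param growth per-step multiplicative growth factor (> 1).
#' @param split fraction of the current resource awarded to the taker,
#'   in `[0.5, 1]`.
#' @param schedule data frame (or matrix) with `L` rows and columns `p1`,
#'   `p2`: the payoffs to Players 1 and 2 when the game ends at each step.
#' @param pass_through length-2 numeric, payoffs `(p1, p2)` when both
#'   players postpone throughout.
#' @param variant label stored on the object; `"constant-size"` additionally
#'   asserts that every row of `schedule` (and `pass_through`) sums to the
#'   same total.
#' @return an object of class `centipede_game` with fields `L`, `variant`,
#'   `schedule` (data frame `step`, `p1`, `p2`), `pass` and, for the
#'   incremental variant, `M`, `growth`, `split`.
#' @examples
#' g <- icg(L = 4)           # McKelvey-Palfrey payoff structure
#' g$schedule                # step payoffs; pass-through in g$pass
#' game_outcome(g, take1 = 3, take2 = 2)
#' @export
icg <- function(L = 4L, M = 0.5, growth = 2, split = 0.8) {
  L <- check_even_L(L)
  if (!is.numeric(M) || length(M) != 1L || M <= 0)
    stop("`M` must be a positive number", call. = FALSE)
  if (!is.numeric(growth) || length(growth) != 1L || growth <= 1)
    stop("`growth` must exceed 1", call. = FALSE)
  if (!is.numeric(split) || length(split) != 1L || split < 0.5 || split > 1)
    stop("`split` must lie in [0.5, 1]", call. = FALSE)

  pot <- growth^(seq_len(L) - 1) * M
  taker <- split * pot
  other <- (1 - split) * pot
  odd <- seq_len(L) %% 2L == 1L
  schedule <- data.frame(
    step = seq_len(L),
    p1 = ifelse(odd, taker, other),
    p2 = ifelse(odd, other, taker)
  )
  pass_pot <- growth^L * M
  pass <- c(p1 = split * pass_pot, p2 = (1 - split) * pass_pot)

  new_centipede_game(L, "incremental", schedule, pass,
                     M = M, growth = growth, split = split)
}

#' @rdname icg
#' @export
centipede_game <- function(schedule, pass_through,
                           variant = c("custom-schedule", "constant-size")) {
  variant <- match.arg(variant)
  schedule <- as.data.frame(schedule)
  if (!all(c("p1", "p2") %in% names(schedule))) {
    if (ncol(schedule) == 2L) names(schedule) <- c("p1", "p2")
    else stop("`schedule` needs columns p1 and p2", call. = FALSE)
  }
  L <- check_even_L(nrow(schedule))
  if (any(!is.finite(schedule$p1)) || any(!is.finite(schedule$p2)) ||
      any(schedule$p1 < 0) || any(schedule$p2 < 0))
    stop("schedule payoffs must be finite and nonnegative", call. = FALSE)
  if (length(pass_through) != 2L || any(!is.finite(pass_through)) ||
      any(pass_through < 0))
    stop("`pass_through` must be two nonnegative payoffs", call. = FALSE)
  pass <- c(p1 = unname(pass_through[[1]]), p2 = unname(pass_through[[2]]))
  schedule <- data.frame(step = seq_len(L),
                         p1 = schedule$p1, p2 = schedule$p2)
  if (variant == "constant-size") {
    sums <- schedule$p1 + schedule$p2
    if (max(abs(sums - sums[1])) > 1e-9 * max(1, sums[1]) ||
        abs(sum(pass) - sums[1]) > 1e-9 * max(1, sums[1]))
      stop("constant-size variant requires equal payoff sums at every outcome",
           call. = FALSE)
  }
  new_centipede_game(L, variant, schedule, pass)
}

check_even_L <- function(L) {
  if (length(L) != 1L || !is.finite(L) || L != round(L) || L < 2 ||
      L %% 2 != 0)
    stop("`L` must be an even integer >= 2 (Player 2 owns the last step)",
         call. = FALSE)
  as.integer(L)
}

# payoff scale for the exact integer copies used by the reasoning kernels
.payoff_scale <- 1e8

new_centipede_game <- function(L, variant, schedule, pass, ...) {
  odd <- schedule$step %% 2L == 1L
  units <- list(
    taker = as.numeric(round(ifelse(odd, schedule$p1, schedule$p2) *
                               .payoff_scale)),
    other = as.numeric(round(ifelse(odd, schedule$p2, schedule$p1) *
                               .payoff_scale)),
    pass = as.numeric(round(pass * .payoff_scale))
  )
  structure(
    c(list(L = L, variant = variant, schedule = schedule, pass = pass,
           units = units), list(...)),
    class = "centipede_game"
  )
}

#' @export
print.centipede_game <- function(x, ...) {
  cat(sprintf("Centipede game (%s), L = %d steps\n", x$variant, x$L))
  print(x$schedule, row.names = FALSE)
  cat(sprintf("pass-through: (%.4g, %.4g)\n", x$pass[["p1"]], x$pass[["p2"]]))
  invisible(x)
}

#' Resolve a centipede game from the two players' take steps
#'
#' The game ends at the earlier of the two committed take steps; if neither
#' player ever takes, the pass-through outcome (favouring Player 1) is
#' realised. `NA` (or any step beyond `L`) encodes never taking; internally
#' this matches the threshold coding in which `t = L + 1` means
#' always-Postpone.
#'
#' @param game a `centipede_game`.
#' @param take1 Player 1's take step: an odd step in `1..L`, or `NA` for
#'   never.
#' @param take2 Player 2's take step: an even step in `1..L`, or `NA` for
#'   never.
#' @return list with `ending_step` (integer, or `NA` for pass-through),
#'   `payoff_p1`, `payoff_p2`.
#' @examples
#' game_outcome(icg(4), take1 = 1, take2 = 2)  # ends at step 1: (0.4, 0.1)
#' game_outcome(icg(4), NA, NA)                # pass-through: (6.4, 1.6)
#' @export
game_outcome <- function(game, take1, take2) {
  stopifnot(inherits(game, "centipede_game"))
  t1 <- normalize_take(take1, game$L, role = 1L)
  t2 <- normalize_take(take2, game$L, role = 2L)
  end <- min(t1, t2)
  if (is.infinite(end)) {
    list(ending_step = NA_integer_,
         payoff_p1 = game$pass[["p1"]], payoff_p2 = game$pass[["p2"]])
  } else {
    list(ending_step = as.integer(end),
         payoff_p1 = game$schedule$p1[end],
         payoff_p2 = game$schedule$p2[end])
  }
}

normalize_take <- function(take, L, role) {
  if (length(take) != 1L) stop("take step must be scalar", call. = FALSE)
  if (is.na(take) || take > L) return(Inf)
  take <- as.integer(take)
  if (take < 1L || take %% 2L != role %% 2L)
    stop(sprintf("Player %d cannot take at step %d", role, take),
         call. = FALSE)
  take
}

# payoff (in exact integer units) to the taker / the other player when the
# game ends at step l; pass-through payoff by role
taker_units <- function(game, l) game$units$taker[l]
other_units <- function(game, l) game$units$other[l]
pass_units <- function(game, role) game$units$pass[role]

#' Role-specific payoff at a game ending
#'
#' Payoff to `role` (1 or 2) when the game ends at `step`, with `NA` for the
#' pass-through ending. Vectorised over `step`.
#'
#' @inheritParams game_outcome
#' @param step ending step in `1..L`, or `NA` for pass-through.
#' @param role 1 or 2.
#' @keywords internal
role_payoff <- function(game, step, role) {
  col <- if (role == 1L) "p1" else "p2"
  out <- numeric(length(step))
  pass <- is.na(step)
  out[pass] <- game$pass[[col]]
  out[!pass] <- game$schedule[[col]][step[!pass]]
  out
}

#' Feasible take steps for a role
#'
#' Player 1 moves at odd steps, Player 2 at even steps.
#' @inheritParams game_outcome
#' @param role 1 or 2.
#' @return integer vector of feasible steps.
#' @export
role_steps <- function(game, role) {
  s <- seq_len(game$L)
  s[s %% 2L == role %% 2L]
}
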