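# shared fixtures and independent oracles

g4 <- icg(4)
g6 <- icg(6)

# brute-force absorption solve of the Fermi birth-death chain on 0..Z:
# probability that a single A-mutant fixates in a B-resident population
bd_fixation_oracle <- function(Z, beta, pAA, pAB, pBA, pBB) {
  i <- seq_len(Z - 1)
  fA <- ((i - 1) * pAA + (Z - i) * pAB) / (Z - 1)
  fB <- (i * pBA + (Z - i - 1) * pBB) / (Z - 1)
  Tplus  <- (i / Z) * ((Z - i) / Z) * stats::plogis(beta * (fA - fB))
  Tminus <- (i / Z) * ((Z - i) / Z) * stats::plogis(-beta * (fA - fB))
  # x_i = P(absorb at Z | start i); x_0 = 0, x_Z = 1
  A <- matrix(0, Z - 1, Z - 1)
  b <- numeric(Z - 1)
  for (r in i) {
    A[r, r] <- Tplus[r] + Tminus[r]
    if (r > 1) A[r, r - 1] <- -Tminus[r]
    if (r < Z - 1) A[r, r + 1] <- -Tplus[r]
    if (r == Z - 1) b[r] <- Tplus[r]
  }
  solve(A, b)[1]
}

# expected total payoff delivered per interaction between X and Y,
# averaged over the two role assignments (independent accounting used to
# check payoff conservation)
expected_total_payoff <- function(X, Y, game, rp, eps) {
  dists <- function(s) lapply(1:2, function(r)
    action_distribution(threshold_distribution(s, game, rp, eps, r), r, game))
  aX <- dists(X); aY <- dists(Y)
  one <- function(a1, a2) {
    st <- function(a) ifelse(names(a) == "never", Inf,
                             suppressWarnings(as.numeric(names(a))))
    e <- outer(st(a1), st(a2), pmin)
    w <- outer(as.numeric(a1), as.numeric(a2))
    tot <- ifelse(is.infinite(e), sum(game$pass),
                  game$schedule$p1[ifelse(is.infinite(e), 1, e)] +
                    game$schedule$p2[ifelse(is.infinite(e), 1, e)])
    sum(w * tot)
  }
  (one(aX[[1]], aY[[2]]) + one(aY[[1]], aX[[2]])) / 2
}
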