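toy_pay <- function(pAA, pAB, pBA, pBB)
  matrix(c(pAA, pBA, pAB, pBB), 2, 2,
         dimnames = list(c("(1,0)", "(2,0)"), c("(1,0)", "(2,0)")))

test_that("Fermi rule is neutral at beta = 0 and saturates at large beta", {
  expect_equal(fermi_prob(0, 3.7, -1), 0.5)
  expect_equal(fermi_prob(2, 1, 1), 0.5)
  expect_equal(fermi_prob(10, 5, 0), 1 / (1 + exp(-50)))
  expect_equal(fermi_prob(1e4, -100, 100), 0)  # overflow-safe
  expect_error(fermi_prob(-1, 0, 0), "nonnegative")
})

test_that("composition fitness excludes self and hits the boundary cases", {
  f <- composition_fitness(1, 50, pAA = 9, pAB = 2, pBA = 3, pBB = 4)
  expect_equal(f$fA, 2)        # lone mutant meets only residents
  f <- composition_fitness(49, 50, 9, 2, 3, 4)
  expect_equal(f$fB, 3)        # lone resident mirrored
  f <- composition_fitness(10, 50, 1, 1, 1, 1)
  expect_equal(f$fA, f$fB)
  expect_error(composition_fitness(0, 50, 1, 1, 1, 1), "1..Z-1")
})

test_that("fixation probability matches neutral drift and a single-step chain", {
  pay <- toy_pay(1, 2, 3, 4)
  for (Z in c(2, 10, 500))
    expect_equal(fixation_probability(pay, 1, 2, Z, beta = 0), 1 / Z)
  # Z = 2: one pairwise comparison decides
  f <- composition_fitness(1, 2, 1, 2, 3, 4)
  expect_equal(fixation_probability(pay, 1, 2, 2, beta = 0.7),
               fermi_prob(0.7, f$fA, f$fB))
})

test_that("closed-form fixation equals the brute-force birth-death solve", {
  set.seed(31)
  for (rep in 1:8) {
    p <- runif(4, 0, 4)
    beta <- runif(1, 0, 2)
    Z <- sample(2:12, 1)
    pay <- toy_pay(p[1], p[2], p[3], p[4])
    expect_equal(fixation_probability(pay, 1, 2, Z, beta),
                 bd_fixation_oracle(Z, beta, p[1], p[2], p[3], p[4]),
                 tolerance = 1e-10)
  }
  # log-space accumulation survives strong selection at large Z
  rho <- fixation_probability(toy_pay(0.25, 0.6, 0.15, 0.5), 2, 1,
                              Z = 500, beta = 10)
  expect_true(is.finite(rho) && rho >= 0 && rho <= 1)
})

test_that("embedded chain rows are stochastic and sigma is its fixed vector", {
  pm <- payoff_matrix(strategy_set(g4), g4, "inertia", 0.19)
  ch <- embedded_chain(pm, Z = 50, beta = 0.31)
  expect_equal(rowSums(ch$Gamma), rep(1, 25), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(ch$sigma >= 0))
  expect_equal(sum(ch$sigma), 1, tolerance = 1e-12)
  expect_lt(max(abs(ch$sigma %*% ch$Gamma - ch$sigma)), 1e-10)
  # neutral drift: uniform stationary distribution
  ch0 <- embedded_chain(pm, Z = 50, beta = 0)
  expect_equal(unname(ch0$sigma), rep(1 / 25, 25), tolerance = 1e-12)
  # two equal strategies split the mass
  ch2 <- embedded_chain(toy_pay(1, 1, 1, 1), Z = 20, beta = 5)
  expect_equal(unname(ch2$sigma), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("k-transition inhibition reweights only depth-changing moves", {
  pm <- payoff_matrix(strategy_set(g4), g4, "inertia", 0.19)
  ch <- embedded_chain(pm, Z = 50, beta = 0.31)
  chw <- embedded_chain(pm, Z = 50, beta = 0.31, k_transition_weight = 0.1)
  ks <- as.integer(sub("^\\((\\d+),(\\d+)\\)$", "\\2", rownames(pm)))
  same_k <- outer(ks, ks, "==")
  off <- !diag(25)
  expect_equal(chw$Gamma[off & same_k], ch$Gamma[off & same_k])
  expect_equal(chw$Gamma[off & !same_k], 0.1 * ch$Gamma[off & !same_k])
  expect_equal(rowSums(chw$Gamma), rep(1, 25), ignore_attr = TRUE)
})

test_that("stationary marginals summarize beliefs, depths and actions", {
  pm <- payoff_matrix(strategy_set(g4), g4, "inertia", 0.19)
  ch <- embedded_chain(pm, Z = 50, beta = 0.31)
  m <- stationary_marginals(ch, g4, "inertia", 0.19)
  expect_equal(sum(m$t_marginal), 1, tolerance = 1e-12)
  expect_equal(sum(m$k_marginal), 1, tolerance = 1e-12)
  expect_equal(sum(m$action_marginal), 1, tolerance = 1e-12)
  # no-ToM strategies act exactly on their beliefs: zero mismatch
  expect_equal(m$mismatch$mismatch[m$mismatch$k == 0], 0, tolerance = 1e-12)
  # reasoning strategies act earlier than they believe (optimism bias)
  expect_true(all(m$mismatch$mismatch[m$mismatch$k > 0] > 0))
  # uniform sigma averages the available depths
  ch0 <- embedded_chain(pm, Z = 50, beta = 0)
  m0 <- stationary_marginals(ch0, g4, "inertia", 0.19)
  expect_equal(m0$avg_k, mean(0:4), tolerance = 1e-12)
})

test_that("gradient of selection is bounded, neutral at beta 0, signed by dominance", {
  Z <- 100
  pay <- toy_pay(2, 2, 1, 1)   # A dominates B
  gr <- gradient_of_selection(pay, 1, 2, Z, beta = 1)
  i <- gr$profile$i
  expect_true(all(gr$profile$G > 0))
  expect_true(all(abs(gr$profile$G) <= i * (Z - i) / Z^2 + 1e-15))
  expect_equal(nrow(gr$roots), 0L)
  g0 <- gradient_of_selection(pay, 1, 2, Z, beta = 0)
  expect_true(all(g0$profile$G == 0))
  # equal fitness at a composition gives a zero gradient there
  pay2 <- toy_pay(2, 1, 1, 2)  # symmetric coordination: repeller at Z/2
  gr2 <- gradient_of_selection(pay2, 1, 2, Z, beta = 2)
  expect_equal(gr2$roots$type, "repeller")
  expect_equal(gr2$roots$i, Z / 2)
})

test_that("evolutionary robustness flags dominant residents and neutral drift", {
  pay <- toy_pay(2, 2, 1, 1)
  rb <- is_evolutionarily_robust(pay, 1, Z = 50, beta = 5)
  expect_true(rb$robust)
  expect_true(all(rb$table$rho < 1 / 50))
  # at beta = 0 every invasion is exactly neutral: nothing is robust
  rb0 <- is_evolutionarily_robust(pay, 1, Z = 50, beta = 0)
  expect_false(rb0$robust)
  expect_true(all(rb0$table$neutral_edge))
  # report invariant to strategy ordering
  pm <- payoff_matrix(strategy_set(g4), g4, "inertia", 0.19)
  rb1 <- is_evolutionarily_robust(pm, "(5,3)", Z = 100, beta = 2)
  perm <- sample(25)
  rb2 <- is_evolutionarily_robust(pm[perm, perm], "(5,3)", Z = 100, beta = 2)
  o1 <- rb1$table[order(rb1$table$mutant), ]
  o2 <- rb2$table[order(rb2$table$mutant), ]
  expect_equal(o1$rho, o2$rho, ignore_attr = TRUE)
})

test_that("average-k sweep returns a tidy grid", {
  sw <- sweep_avg_k(g4, "inertia", beta_grid = c(0, 0.31),
                    eps_grid = c(0.1, 0.19), Z = 50)
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$avg_k[sw$beta == 0], rep(2, 2), tolerance = 1e-12)
  expect_true(all(sw$avg_k >= 0 & sw$avg_k <= 4))
})
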