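test_that("reasoning kernels follow their switching rules", {
  # unconditional: always one step before, floored at 1
  expect_equal(rp_kernel("unconditional", g4, 1, 3), 2L)
  expect_equal(rp_kernel("unconditional", g4, 1, 1), 1L)
  # conditional: preempt when the taker share at c-1 beats waiting at c
  expect_equal(rp_kernel("conditional", g4, 2, 3), 2L)
  # inertia on a Player-1 reasoner facing an always-postponing co-player:
  # the pass-through (6.4) beats taking at step 4 (3.2), so keep the fallback
  expect_equal(rp_kernel("inertia", g4, 1, 5, own_prev = 5), 5L)
  # same situation as Player 2: 3.2 beats the 1.6 pass share, so preempt
  expect_equal(rp_kernel("inertia", g4, 2, 5, own_prev = 5), 4L)
  # no preemption possible below step 1: inertia falls back
  expect_equal(rp_kernel("inertia", g4, 1, 1, own_prev = 4), 4L)
})

test_that("the worked (3,2) recursion yields 3 -> 2 -> 1 and a point mass", {
  tr <- threshold_trace(tom_strategy(3, 2), g4, "inertia", role = 1)
  expect_equal(unname(tr), c(3L, 2L, 1L))
  d <- threshold_distribution(tom_strategy(3, 2), g4, "inertia", 0, 1)
  expect_equal(as.numeric(d), c(1, 0, 0, 0, 0))
})

test_that("error branching reaches exactly thresholds 1..4 for (3,2)", {
  for (eps in c(0.05, 0.19, 0.3)) {
    d <- threshold_distribution(tom_strategy(3, 2), g4, "inertia", eps, 1)
    expect_equal(which(d > 0), 1:4, ignore_attr = TRUE)
  }
})

test_that("threshold distributions are proper over games, RPs and roles", {
  set <- expand.grid(t = c(1, 3, 5), k = c(0, 2, 4), rp = rp_kinds(),
                     eps = c(0, 0.19, 0.4), role = 1:2,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(set))) {
    d <- threshold_distribution(tom_strategy(set$t[i], set$k[i]), g4,
                                set$rp[i], set$eps[i], set$role[i])
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
    expect_length(d, 5L)
  }
})

test_that("k = 0 and eps = 0 collapse to point masses; unconditional has a closed form", {
  for (t in 1:5) {
    d <- threshold_distribution(tom_strategy(t, 0), g4, "inertia", 0.3, 2)
    expect_equal(which(d == 1), t, ignore_attr = TRUE)
  }
  # closed form max(t - k, 1) for the deterministic unconditional recursion
  for (t in 1:5) for (k in 0:4) for (role in 1:2) {
    d <- threshold_distribution(tom_strategy(t, k), g4, "unconditional", 0, role)
    expect_equal(which(d == 1), max(t - k, 1), ignore_attr = TRUE)
  }
})

test_that("error spread grows monotonically with eps (unconditional RP)", {
  base <- threshold_distribution(tom_strategy(4, 2), g4, "unconditional", 0, 1)
  tv <- vapply(seq(0, 0.25, by = 0.025), function(eps) {
    d <- threshold_distribution(tom_strategy(4, 2), g4, "unconditional", eps, 1)
    0.5 * sum(abs(d - base))
  }, numeric(1))
  expect_true(all(diff(tv) >= -1e-12))
})

test_that("sampled thresholds reproduce the exact distribution", {
  s <- tom_strategy(3, 2)
  d <- threshold_distribution(s, g4, "inertia", 0.19, 1)
  set.seed(11)
  draws <- sample_thresholds(s, g4, "inertia", 0.19, 1, n = 1e5)
  obs <- tabulate(draws, nbins = 5)
  keep <- d > 0
  expect_gt(stats::chisq.test(obs[keep], p = d[keep])$p.value, 0.001)
  # eps = 0 draws equal the deterministic recursion result
  expect_true(all(sample_thresholds(s, g4, "inertia", 0, 1, 100) == 1L))
  # k = 0 always returns the prior belief
  expect_true(all(sample_thresholds(tom_strategy(4, 0), g4, "inertia",
                                    0.3, 2, 100) == 4L))
})

test_that("thresholds map to the smallest role-feasible step", {
  point <- function(t) {
    p <- numeric(5); p[t] <- 1
    structure(p, names = as.character(1:5))
  }
  a <- action_distribution(point(3), 1, g4)
  expect_equal(a[["3"]], 1)
  a <- action_distribution(point(3), 2, g4)
  expect_equal(a[["4"]], 1)
  for (role in 1:2)
    expect_equal(action_distribution(point(5), role, g4)[["never"]], 1)
  # Player 1 in the 4-step game has no seat at or after step 4
  expect_equal(action_distribution(point(4), 1, g4)[["never"]], 1)
  # aggregation keeps total mass
  d <- threshold_distribution(tom_strategy(5, 3), g4, "inertia", 0.19, 2)
  a <- action_distribution(d, 2, g4)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_equal(names(a), c("2", "4", "never"))
})

test_that("strategy sets have (L+1)^2 members", {
  expect_length(strategy_set(g4), 25L)
  expect_length(strategy_set(g6), 49L)
  expect_equal(names(strategy_set(g4))[1], "(1,0)")
})

test_that("invalid strategy and eps inputs are rejected", {
  expect_error(tom_strategy(0, 1), "positive")
  expect_error(tom_strategy(2, -1), "nonnegative")
  expect_error(threshold_distribution(tom_strategy(6, 0), g4, "inertia", 0, 1),
               "exceeds")
  expect_error(threshold_distribution(tom_strategy(3, 2), g4, "inertia", 0.6, 1),
               "eps")
})
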