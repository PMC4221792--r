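test_that("division enumeration matches hand-computed hypergeometrics", {
  d <- enumerate_divisions(c(2, 1))
  d <- d[order(d$v_1, d$v_2), ]
  # drawing 2 of 3 cells: v = (1,1) w.p. 2/3, v = (2,0) w.p. 1/3
  expect_equal(d$v_1, c(1, 2))
  expect_equal(d$pi, c(2/3, 1/3))
  # forced split
  d2 <- enumerate_divisions(c(2, 0))
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$v_1, 1)
  expect_equal(d2$pi, 1)
  # normalization
  d3 <- enumerate_divisions(c(3, 3))
  expect_equal(sum(d3$pi), 1)
  expect_true(all(rowSums(d3[, 1:2]) == 3))
  expect_error(enumerate_divisions(c(1, 0)), "cannot divide")
})

test_that("a single cell is always captured", {
  prm <- default_params()
  fit <- ensemble_cost(community_profile(1L, 12e6), prm)
  expect_equal(unname(fit$capture[["1"]]), 1)
  expect_equal(fit$per_genome_capture, 1)
})

test_that("the capture distribution is a probability distribution", {
  prm <- default_params()
  set.seed(21)
  for (rep in 1:15) {
    s <- sample(1:3, 1)
    p <- as.integer(rmultinom(1, sample(2:7, 1), rep(1, s)))
    if (sum(p) == 0) p[1] <- 1L
    g <- sample(c(1e6, 2e6, 4e6, 12e6), s, replace = TRUE)
    pr <- community_profile(p, g)
    I0 <- rbinom(s, 1, 0.3)
    fit <- ensemble_cost(pr, prm, I0 = I0)
    expect_true(all(fit$capture >= -1e-12))
    expect_equal(sum(fit$capture), 1, tolerance = 1e-9)
  }
})

test_that("dynamic program and brute force agree exactly on small communities", {
  # the module's central correctness property: the DP must equal the
  # explicit average over all orderings
  gset <- c(1e6, 2e6, 4e6, 12e6)
  gi <- 0L
  for (tau in c(0, 0.2, 0.4)) {
    prm <- distill_params(tau = tau)
    for (s in 1:3) {
      for (n in s:min(6L, s + 3L)) {
        for (p in all_profiles(s, n)) {
          gi <- gi + 1L
          g <- gset[(seq_len(s) + gi) %% length(gset) + 1L]
          pr <- community_profile(p, g)
          bf <- brute_force_ensemble(pr, prm)
          dp <- ensemble_cost(pr, prm)
          expect_equal(dp$expected_total, bf$expected_total,
                       tolerance = 1e-9)
          expect_lt(max(abs(dp$capture - bf$capture)), 1e-9)
        }
      }
    }
  }
})

test_that("DP equals brute force under the sensed-root policy too", {
  prm <- distill_params(tau = 0.2, root_sensed = TRUE)
  for (p in list(c(3L, 1L), c(2L, 2L), c(1L, 2L, 3L))) {
    pr <- community_profile(p, c(4e6, 12e6, 2e6)[seq_along(p)])
    bf <- brute_force_ensemble(pr, prm)
    dp <- ensemble_cost(pr, prm)
    expect_equal(dp$expected_total, bf$expected_total, tolerance = 1e-9)
    expect_lt(max(abs(dp$capture - bf$capture)), 1e-9)
  }
})

test_that("tau = 0 captures every genome with certainty", {
  prm0 <- distill_params(tau = 0)
  for (p in list(c(5L, 5L, 10L, 20L), c(5L, 5L, 5L, 25L))) {
    fit <- ensemble_cost(community_profile(p, c(4e6, 12e6, 2e6, 1e6)), prm0)
    all_ones <- paste(rep(1, 4), collapse = "")
    expect_equal(unname(fit$capture[[all_ones]]), 1, tolerance = 1e-9)
    expect_equal(fit$per_genome_capture, rep(1, 4), tolerance = 1e-9)
  }
})

test_that("repeated evaluation is deterministic", {
  prm <- default_params()
  pr <- profile_323()
  f1 <- ensemble_cost(pr, prm)
  f2 <- ensemble_cost(pr, prm)
  expect_identical(f1$expected_total, f2$expected_total)
  expect_identical(f1$capture, f2$capture)
})

test_that("marginal capture probabilities are nonincreasing in tau", {
  for (p5 in list(c(1L, 1L, 2L, 4L), c(1L, 1L, 1L, 5L))) {
    pr <- profile4(p5)
    marg <- sapply(c(0, 0.1, 0.2, 0.4), function(tau) {
      ensemble_cost(pr, distill_params(tau = tau))$per_genome_capture
    })
    for (j in 1:4) expect_true(all(diff(marg[j, ]) <= 1e-9))
  }
})

test_that("expected cost covers at least one complete assembly per genome", {
  prm <- default_params()
  set.seed(31)
  for (rep in 1:8) {
    s <- sample(2:3, 1)
    p <- as.integer(sample(1:4, s, replace = TRUE))
    g <- sample(c(1e6, 2e6, 4e6), s, replace = TRUE)
    pr <- community_profile(p, g)
    fit <- ensemble_cost(pr, prm)
    expect_gte(fit$expected_total, prm$M_u * sum(g[p > 0]))
  }
})

test_that("brute force is guarded against intractable communities", {
  expect_error(brute_force_ensemble(profile_323(), default_params()),
               "n <= 8")
})

test_that("the cost curve scales profiles and prefers the log fit", {
  prm <- default_params()
  cv <- expected_cost_curve(c(3, 2, 3), c(4e6, 12e6, 2e6),
                            n_values = c(8, 16, 24, 32), prm)
  expect_equal(cv$n, c(8, 16, 24, 32))
  expect_true(all(diff(cv$expected_total) > 0))
  # the adaptive strategy undercuts naive sequencing once n is large enough
  expect_lt(cv$expected_total[cv$n == 32], cv$naive[cv$n == 32])
  # and its advantage grows with n
  ratio <- cv$expected_total / cv$naive
  expect_true(all(diff(ratio) < 0))
  expect_error(
    expected_cost_curve(c(3, 2, 3), c(4e6, 12e6, 2e6), n_values = 12, prm),
    "multiple")
})
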