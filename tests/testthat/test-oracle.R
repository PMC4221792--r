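test_that("assembly size follows the coverage model and saturates", {
  prm <- default_params()
  expect_equal(assembly_size(2.5, 4e6, prm), 2e6)
  expect_equal(assembly_size(5, 4e6, prm), 4e6)     # continuous at M_u
  expect_equal(assembly_size(50, 4e6, prm), 4e6)    # capped at genome size
  expect_error(assembly_size(-1, 4e6, prm), "non-negative")
  # nondecreasing in c, equal to g beyond M_u
  set.seed(11)
  for (rep in 1:50) {
    g <- runif(1, 1e6, 12e6)
    cs <- sort(runif(6, 0, 15))
    as <- assembly_size(cs, g, prm)
    expect_true(all(diff(as) >= -1e-9))
    expect_equal(as[cs >= prm$M_u], rep(g, sum(cs >= prm$M_u)))
  }
})

test_that("resource allocation scales from the parent pool", {
  prm <- default_params()
  expect_equal(resource_allocate(100e6, 5, 10e6, a_target = 10e6,
                                 params = prm), 100e6)
  expect_equal(resource_allocate(100e6, 10, 10e6, a_target = 5e6,
                                 params = prm), 25e6)
  # error-free reduction: t_parent = c_parent * a_parent gives M_u * a_target
  expect_equal(resource_allocate(60e6, 5, 12e6, a_target = 7e6, params = prm),
               prm$M_u * 7e6)
  expect_error(resource_allocate(100e6, 0, 10e6, a_target = 1e6,
                                 params = prm), "undefined")
})

test_that("the pool oracle allocates, sequences and assembles correctly", {
  prm <- default_params()
  res <- allocate_sequence_assemble(c(2, 2), c(4e6, 2e6), a_parent = 6e6,
                                    params = prm)
  expect_equal(res$t, 60e6)
  expect_equal(res$t_pc, 15e6)
  expect_equal(res$t_pdg, c(30e6, 30e6))
  expect_equal(res$coverage, c(7.5, 15))
  expect_equal(res$a_bar, c(4e6, 2e6))       # both complete
  # absent genomes contribute nothing
  res0 <- allocate_sequence_assemble(c(0, 3), c(4e6, 2e6), 6e6, prm)
  expect_equal(res0$a_bar[1], 0)
  expect_equal(res0$coverage[1], 0)
  expect_error(allocate_sequence_assemble(c(1, 1), c(4e6, 2e6), 0, prm),
               "positive")
})

test_that("the oracle conserves nucleotides across genomes", {
  prm <- default_params()
  set.seed(5)
  for (rep in 1:30) {
    s <- sample(2:5, 1)
    p <- rpois(s, 3); p[sample(s, 1)] <- p[sample(s, 1)] + 1L
    if (sum(p) == 0) p[1] <- 1L
    g <- runif(s, 1e6, 12e6)
    res <- allocate_sequence_assemble(p, g, runif(1, 1e6, 2e7), prm)
    expect_equal(sum(res$t_pdg), res$t)
    expect_equal(res$total, sum(res$a_bar))
    expect_true(all(res$a_bar <= g + 1e-6))
  }
})

test_that("leaf deep-sequencing requires a safety margin above one", {
  # with safety_factor = 1 the re-allocation fixed point keeps coverage
  # constant below M_u, so the constructor rejects it
  expect_error(distill_params(safety_factor = 1), "safety_factor")
  # with the default margin a leaf entered with a small prior converges
  prm <- default_params()
  a <- 1e6; cov <- 0
  for (i in 1:50) {
    res <- allocate_sequence_assemble(1L, 12e6, a, prm)
    cov <- res$coverage[1]; a <- res$total
    if (cov >= 2 * prm$M_u) break
  }
  expect_gte(cov, 2 * prm$M_u)
})

test_that("the containment score behaves at and around the boundary", {
  prm <- default_params()
  expect_equal(d_tau(0, 10e6, prm), 0.2)
  expect_equal(d_tau(3e6, 10e6, prm), -0.1)
  expect_equal(d_tau(2e6, 10e6, prm), 0)     # boundary counts as subsumed
  expect_error(d_tau(1, 0, prm), "positive")
})

test_that("assembly-level subsumption prunes only reliable covered pools", {
  prm <- default_params()
  ref <- c(4e6, 12e6, 2e6)
  # unreliable coverage is never pruned
  expect_false(subsumed(c(4e6, 0, 2e6), ref, c = 0.2, params = prm))
  # full containment
  expect_true(subsumed(c(4e6, 0, 2e6), ref, c = 10, params = prm))
  # 2 Mbp of novel content out of 18 Mbp is within tau = 0.2
  expect_true(subsumed(c(4e6, 12e6, 2e6), c(4e6, 12e6, 0), c = 10,
                       params = prm))
  # 3/10 novel is too much
  expect_false(subsumed(c(1e6, 0, 0) + c(0, 9e6, 0) * 0 + c(3e6, 7e6, 0),
                        c(0, 7e6, 0), c = 10, params = prm))
})

test_that("capture-state subsumption matches the exclusive-content rule", {
  prm <- default_params()
  a <- c(4e6, 12e6, 2e6)
  expect_true(subsumed_ensemble(a, 10, c(1, 1, 1), prm))    # x = 0
  expect_false(subsumed_ensemble(c(4e6, 2e6, 0), 10, c(1, 0, 0), prm))
  # the mechanism that can silently miss the 2 Mbp genome: 2/18 <= 0.2
  expect_true(subsumed_ensemble(a, 10, c(1, 1, 0), prm))
  expect_false(subsumed_ensemble(a, 0.2, c(1, 1, 0), prm))  # low coverage
})

test_that("tau = 0 subsumption means exactly zero exclusive content", {
  prm0 <- distill_params(tau = 0)
  set.seed(9)
  for (rep in 1:40) {
    s <- sample(2:4, 1)
    a <- runif(s, 0, 5e6) * rbinom(s, 1, 0.7)
    if (sum(a) == 0) a[1] <- 1e6
    I <- rbinom(s, 1, 0.5)
    expect_equal(subsumed_ensemble(a, 10, I, prm0),
                 all(a[I == 0] == 0))
  }
})

test_that("increasing tau can only turn not-subsumed into subsumed", {
  set.seed(13)
  for (rep in 1:40) {
    s <- sample(2:4, 1)
    a <- runif(s, 0, 5e6); a[1] <- max(a[1], 1e5)
    I <- rbinom(s, 1, 0.5)
    cov <- runif(1, 0.5, 20)
    verdicts <- vapply(c(0, 0.1, 0.2, 0.4, 0.8),
                       function(tau) {
                         subsumed_ensemble(a, cov, I, distill_params(tau = tau))
                       }, logical(1))
    expect_true(all(diff(verdicts) >= 0))   # FALSE can become TRUE, never back
  }
})
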