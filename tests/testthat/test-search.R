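test_that("a single-genome community is resolved by the first leaf", {
  prm0 <- distill_params(tau = 0)
  cl <- rep(1L, 8)
  res <- run_compressed_search(cl, 4e6, prm0, "DFS")
  expect_equal(res$identified, 1L)
  expect_length(res$missed, 0)
})

test_that("DFS uses at most two pools per round", {
  prm <- default_params()
  pr <- community_profile(c(4, 3, 3), c(4e6, 12e6, 2e6))   # 10 cells
  for (seed in 1:10) {
    cl <- cells_from_profile(pr, seed)
    res <- run_compressed_search(cl, pr$g, prm, "DFS")
    expect_lte(res$max_pools_per_round, 2L)
  }
})

test_that("BFS halves through ceiling(log2(n)) splitting levels", {
  prm0 <- distill_params(tau = 0)
  for (n in c(8L, 13L, 32L)) {
    pr <- community_profile(c(n - 2L, 1L, 1L), c(4e6, 12e6, 2e6))
    cl <- cells_from_profile(pr, seed = n)
    res <- run_compressed_search(cl, pr$g, prm0, "BFS")
    expect_equal(res$splitting_levels, as.integer(ceiling(log2(n))))
  }
})

test_that("tau = 0 searches identify every represented genome", {
  prm0 <- distill_params(tau = 0)
  pr <- community_profile(c(20, 8, 20, 16), c(4e6, 12e6, 2e6, 1e6))  # n = 64
  for (seed in 1:25) {
    cl <- cells_from_profile(pr, seed)
    dfs <- run_compressed_search(cl, pr$g, prm0, "DFS")
    bfs <- run_compressed_search(cl, pr$g, prm0, "BFS")
    expect_setequal(dfs$identified, 1:4)
    expect_setequal(bfs$identified, 1:4)
    expect_setequal(dfs$identified, bfs$identified)
  }
})

test_that("identified genomes are backed by at least a full assembly of data", {
  prm <- default_params()
  pr <- community_profile(c(6, 4, 6), c(4e6, 12e6, 2e6))
  for (seed in 1:10) {
    cl <- cells_from_profile(pr, seed)
    res <- run_compressed_search(cl, pr$g, prm, "DFS")
    expect_gte(res$total_sequenced,
               prm$M_u * sum(pr$g[res$identified]))
    # one representative cell per identified genome, carrying that genome
    expect_length(res$representatives, length(res$identified))
    expect_equal(cl[res$representatives], res$identified)
  }
})

test_that("both strategies terminate on skewed profiles", {
  prm <- default_params()
  pr <- make_profile(4, 33, size_range = 4e6, skew = "worst")
  cl <- cells_from_profile(pr, 3)
  expect_s3_class(run_compressed_search(cl, pr$g, prm, "DFS"),
                  "distill_search")
  expect_s3_class(run_compressed_search(cl, pr$g, prm, "BFS"),
                  "distill_search")
})

test_that("the minimum assembly-set cover picks the cheapest covering pools", {
  prm0 <- distill_params(tau = 0)
  mk <- function(idx, a_bar) {
    list(idx = idx, sense = list(a_bar = a_bar, total = sum(a_bar), c = 10))
  }
  # one pool's assembly equals the union: that pool alone suffices
  pools <- list(mk(1:4, c(4e6, 2e6)), mk(5:6, c(4e6, 0)))
  cov <- min_assembly_set_cover(pools, c(0, 0), prm0)
  expect_length(cov, 1L)
  expect_equal(cov[[1]]$idx, 1:4)
  # disjoint single-genome pools: nothing is redundant
  pools <- list(mk(1:2, c(4e6, 0)), mk(3:4, c(0, 2e6)))
  cov <- min_assembly_set_cover(pools, c(0, 0), prm0)
  expect_length(cov, 2L)
  # pool A covers genomes 1+2 with fewer cells than B+C together
  pools <- list(A = mk(1:2, c(4e6, 2e6)),
                B = mk(3:4, c(4e6, 0)),
                C = mk(5:6, c(0, 2e6)))
  cov <- min_assembly_set_cover(pools, c(0, 0), prm0)
  expect_length(cov, 1L)
  expect_equal(cov[[1]]$idx, 1:2)
  # ...but not when A is more expensive in cells
  pools <- list(A = mk(1:5, c(4e6, 2e6)),
                B = mk(6:7, c(4e6, 0)),
                C = mk(8:9, c(0, 2e6)))
  cov <- min_assembly_set_cover(pools, c(0, 0), prm0)
  expect_length(cov, 2L)
})
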