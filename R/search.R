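#' Simulate one adaptive compressed search over an explicit cell ordering
#'
#' Runs the full adaptive pooling search on a concrete ordering of cells
#' under the error-free sequencing-and-assembly oracle.  Starting from the
#' whole community split in half, each round senses the active pools
#' (allocating `safety_factor * M_u * a_parent` nucleotides each), promotes
#' single-cell pools with reliable coverage to deeply sequenced leaves,
#' routes unreliable pools (coverage `<= M_l`) back for further exploration
#' with doubled allocation, prunes pools whose assembly is subsumed by what
#' has been captured, and halves the survivors.
#'
#' With `strategy = "DFS"` at most two pools are sensed per round: the pool
#' with the largest assembly continues and its sibling waits on a stack,
#' from which subsumed entries are discarded when popped.  With
#' `strategy = "BFS"` all pools of a round are sensed together and the next
#' round keeps a minimum assembly-set cover: the smallest sub-collection
#' (by total cells) whose combined assembly subsumes the round's combined
#' assembly.
#'
#' @param cells Integer vector of genome labels, one per cell, e.g. from
#'   [cells_from_profile()].
#' @param g Genome sizes in base pairs (length `max(cells)` at least).
#' @param params A [distill_params()].
#' @param strategy `"DFS"` (default) or `"BFS"`.
#' @return An object of class `"distill_search"`: a list with
#'   `total_sequenced` (bp), `rounds`, `max_pools_per_round`,
#'   `splitting_levels` (depth of the deepest pool created by halving,
#'   `ceiling(log2(n))` for BFS by construction), `identified` (captured
#'   genome labels),
#'   `representatives` (one cell index per captured genome), `missed`
#'   (represented but uncaptured labels) and `strategy`.
#' @examples
#' pr <- community_profile(c(5, 5), c(4e6, 2e6))
#' cl <- cells_from_profile(pr, seed = 1)
#' run_compressed_search(cl, pr$g, distill_params(tau = 0))
#' @export
run_compressed_search <- function(cells, g, params = distill_params(),
                                  strategy = c("DFS", "BFS")) {
  strategy <- match.arg(strategy)
  stopifnot(length(cells) >= 1, all(cells >= 1), all(cells <= length(g)))
  n <- length(cells)
  s <- length(g)

  total <- 0
  rounds <- 0L
  max_pools <- 0L
  max_depth <- 1L   # depth of the deepest pool created (root halves = 1)
  I <- integer(s)             # capture state
  representatives <- rep(NA_integer_, s)
  a_captured <- numeric(s)    # assembly of deeply sequenced cells (full genomes)

  # A pool: list(idx = cell indices, a_parent = allocation basis (bp),
  #             boost = allocation multiplier for re-explored low-quality pools)
  new_pool <- function(idx, a_parent, boost = 1, depth = 1L) {
    list(idx = idx, a_parent = a_parent, boost = boost, depth = depth)
  }
  pool_profile <- function(pool) tabulate(cells[pool$idx], nbins = s)

  sense_pool <- function(pool) {
    p <- pool_profile(pool)
    res <- allocate_sequence_assemble(p, g, pool$a_parent * pool$boost,
                                      params)
    total <<- total + res$t
    c(pool, list(profile = p, sense = res))
  }

  deep_sequence_leaf <- function(pool) {
    # single-cell pool: repeat allocation until complete coverage
    lab <- cells[pool$idx[1]]
    cov <- pool$sense$coverage[lab]
    a <- pool$sense$a_bar
    guard <- 0L
    while (cov < params$M_u && guard < 500L) {
      res <- allocate_sequence_assemble(pool$profile, g, sum(a), params)
      total <<- total + res$t
      cov <- res$coverage[lab]
      a <- res$a_bar
      guard <- guard + 1L
    }
    if (I[lab] == 0L) representatives[lab] <<- pool$idx[1]
    I[lab] <<- 1L
    a_captured[lab] <<- g[lab]
    invisible(NULL)
  }

  halve <- function(pool) {
    m <- length(pool$idx)
    h <- ceiling(m / 2)
    max_depth <<- max(max_depth, pool$depth + 1L)
    ap <- pool$sense$total
    list(new_pool(pool$idx[seq_len(h)], ap, depth = pool$depth + 1L),
         new_pool(pool$idx[(h + 1):m], ap, depth = pool$depth + 1L))
  }

  # initial split of the (unsensed) root
  a0 <- root_assembly_bp(params, g)
  h <- ceiling(n / 2)
  active <- list(new_pool(seq_len(h), a0))
  if (h < n) active <- c(active, list(new_pool((h + 1):n, a0)))
  waiting <- list()   # DFS stack

  repeat {
    if (length(active) == 0L && length(waiting) == 0L) break
    rounds <- rounds + 1L
    if (rounds > 10L * n + 100L)
      stop("search failed to terminate", call. = FALSE)

    if (length(active) > 0L) {
      max_pools <- max(max_pools, length(active))
      sensed <- lapply(active, sense_pool)
      active <- list()

      low <- list(); keep <- list()
      for (pl in sensed) {
        if (pl$sense$c <= params$M_l && length(pl$idx) > 1L) {
          low <- c(low, list(pl))
        } else if (length(pl$idx) == 1L) {
          deep_sequence_leaf(pl)
        } else {
          keep <- c(keep, list(pl))
        }
      }

      if (strategy == "BFS") {
        cover <- min_assembly_set_cover(keep, a_captured, params)
        nxt <- c(cover, low)
        active <- unlist(lapply(nxt, function(pl) {
          if (length(pl$idx) == 1L) {
            # low-quality singleton: re-sense with doubled allocation
            list(new_pool(pl$idx, pl$a_parent, boost = 2 * pl$boost,
                          depth = pl$depth))
          } else halve(pl)
        }), recursive = FALSE)
      } else {
        # DFS: keep the pool with the largest assembly (ties: first),
        # push the rest; re-queue low-quality pools with doubled allocation
        for (pl in low) {
          waiting <- c(waiting,
                       list(new_pool(pl$idx, pl$a_parent, 2 * pl$boost,
                                     depth = pl$depth)))
        }
        if (length(keep) > 0L) {
          sizes <- vapply(keep, function(pl) pl$sense$total, numeric(1))
          best <- which.max(sizes)
          for (j in seq_along(keep)) {
            if (j != best) waiting <- c(waiting, list(keep[[j]]))
          }
          active <- halve(keep[[best]])
        }
      }
    }

    if (strategy == "DFS" && length(active) == 0L) {
      # unwind the stack: discard subsumed entries, divide the first survivor
      while (length(waiting) > 0L && length(active) == 0L) {
        pl <- waiting[[length(waiting)]]
        waiting <- waiting[-length(waiting)]
        if (is.null(pl$sense)) pl <- sense_pool(pl)
        if (length(pl$idx) == 1L) {
          if (pl$sense$c > params$M_l) deep_sequence_leaf(pl)
          else waiting <- c(waiting,
                            list(new_pool(pl$idx, pl$a_parent, 2 * pl$boost,
                                          depth = pl$depth)))
        } else if (!subsumed(pl$sense$a_bar, a_captured, pl$sense$c, params)) {
          active <- halve(pl)
        }
      }
    }
  }

  represented <- which(tabulate(cells, nbins = s) > 0)
  identified <- which(I == 1L)
  structure(
    list(total_sequenced = total, rounds = rounds,
         max_pools_per_round = max_pools,
         splitting_levels = max_depth,
         identified = identified,
         representatives = representatives[identified],
         missed = setdiff(represented, identified),
         strategy = strategy, n = n),
    class = "distill_search"
  )
}

#' @export
print.distill_search <- function(x, ...) {
  cat(sprintf("Adaptive compressed search (%s) over %d cells\n",
              x$strategy, x$n))
  cat(sprintf("  total sequenced : %.3f Gbp\n", x$total_sequenced / 1e9))
  cat(sprintf("  rounds          : %d\n", x$rounds))
  cat(sprintf("  max pools/round : %d\n", x$max_pools_per_round))
  cat(sprintf("  identified      : %s\n",
              paste(x$identified, collapse = ", ")))
  if (length(x$missed))
    cat(sprintf("  missed          : %s\n", paste(x$missed, collapse = ", ")))
  invisible(x)
}

#' Minimum assembly-set cover of a round's pools
#'
#' Among the sensed pools of a round, finds a sub-collection whose combined
#' assembly (together with the captured set) subsumes the combined assembly
#' of all pools, minimising the total number of cells (ties: fewer pools).
#' Exact subset enumeration is used for up to 12 pools; beyond that a greedy
#' largest-assembly-first heuristic guarantees a valid (not necessarily
#' minimal) cover.
#'
#' @param pools List of sensed pools as built by [run_compressed_search()]
#'   (each with elements `idx` and `sense`).
#' @param a_captured Per-genome assembled bp of the captured set.
#' @param params A [distill_params()].
#' @return The covering sub-list of `pools`.
#' @export
min_assembly_set_cover <- function(pools, a_captured,
                                   params = distill_params()) {
  if (length(pools) == 0L) return(pools)
  s <- length(a_captured)
  assemblies <- lapply(pools, function(pl) pl$sense$a_bar)
  union_all <- Reduce(pmax, assemblies, numeric(s))
  full <- pmax(union_all, a_captured)
  ncells <- vapply(pools, function(pl) length(pl$idx), numeric(1))

  covers <- function(sel) {
    if (length(sel) == 0L) cov <- a_captured
    else cov <- pmax(Reduce(pmax, assemblies[sel], numeric(s)), a_captured)
    tot <- sum(full)
    if (tot <= 0) return(TRUE)
    exclusive <- sum(full) - sum(cov)
    params$tau - exclusive / tot >= -1e-12
  }

  k <- length(pools)
  if (k <= 12L) {
    best <- NULL; best_cost <- Inf; best_size <- Inf
    for (code in 0:(2^k - 1)) {
      sel <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
      if (!covers(sel)) next
      cost <- sum(ncells[sel])
      if (cost < best_cost ||
          (cost == best_cost && length(sel) < best_size)) {
        best <- sel; best_cost <- cost; best_size <- length(sel)
      }
    }
    pools[best]
  } else {
    ord <- order(vapply(pools, function(pl) -pl$sense$total, numeric(1)))
    sel <- integer(0)
    for (j in ord) {
      if (covers(sel)) break
      sel <- c(sel, j)
    }
    pools[sel]
  }
}
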