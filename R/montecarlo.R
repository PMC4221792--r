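# Per-ordering realization of the ensemble model, and Monte-Carlo averaging.

# Run the ensemble-model DFS recursion on one concrete cell ordering:
# sense the node, stop if subsumed by the captured set, deep-sequence
# single-cell leaves, otherwise split in half (first ceiling(m/2) cells vs
# rest) and explore left then right, propagating the capture state.
# Returns list(total = bp, I = capture state).  This is the per-permutation
# quantity whose ensemble average the dynamic program computes.
simulate_ordering <- function(cells, g, params = distill_params()) {
  s <- length(g)
  n <- length(cells)
  total <- 0
  I <- integer(s)

  sense <- function(p, ap) {
    res <- allocate_sequence_assemble(p, g, ap, params)
    total <<- total + res$t
    res
  }

  explore <- function(idx, ap) {
    p <- tabulate(cells[idx], nbins = s)
    res <- sense(p, ap)
    if (subsumed_ensemble(res$a_bar, res$c, I, params)) return(invisible())
    if (length(idx) == 1L) {
      lab <- cells[idx]
      cov <- res$coverage[lab]
      a <- res$a_bar
      guard <- 0L
      while (cov < 2 * params$M_u && guard < 500L) {
        res2 <- sense(p, sum(a))
        cov <- res2$coverage[lab]
        a <- res2$a_bar
        guard <- guard + 1L
      }
      I[lab] <<- 1L
      return(invisible())
    }
    h <- ceiling(length(idx) / 2)
    atot <- res$total
    explore(idx[seq_len(h)], atot)
    explore(idx[(h + 1):length(idx)], atot)
    invisible()
  }

  a0 <- root_assembly_bp(params, g)
  if (params$root_sensed || n == 1L) {
    explore(seq_len(n), a0)
  } else {
    h <- ceiling(n / 2)
    # the two halves of the first split both allocate from the root prior
    explore(seq_len(h), a0)
    explore((h + 1):n, a0)
  }
  list(total = total, I = I)
}

#' Monte-Carlo estimate of the ensemble quantities
#'
#' Estimates the expected total sequenced nucleotides and the capture
#' distribution by averaging over random orderings of the community's
#' cells.  For `strategy = "DFS"` each ordering is run through the same
#' error-free recursion the dynamic program ([ensemble_cost()]) analyses,
#' so the estimates converge to the DP's exact values and serve as its
#' stochastic cross-check.  For `strategy = "BFS"` (for which no exact
#' ensemble analysis exists, because pools of a round are coupled) each
#' ordering is run through the full search simulator
#' [run_compressed_search()].
#'
#' @param profile A [community_profile()].
#' @param params A [distill_params()].
#' @param strategy `"DFS"` (default) or `"BFS"`.
#' @param reps Number of random orderings.
#' @param seed Integer seed.
#' @return An object of class `"distill_mc"`: list with `mean_total` (bp),
#'   `se_total`, `capture` (empirical probability per capture state, named
#'   by bitstring), `capture_se`, `per_genome_capture`, `reps`, `strategy`.
#' @examples
#' pr <- community_profile(c(3, 3), c(4e6, 2e6))
#' ensemble_monte_carlo(pr, distill_params(tau = 0), reps = 50, seed = 1)
#' @export
ensemble_monte_carlo <- function(profile, params = distill_params(),
                                 strategy = c("DFS", "BFS"),
                                 reps = 1000L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(profile, "community_profile"), reps >= 1)
  s <- profile$s
  labels <- rep(seq_len(s), times = profile$p)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)

  totals <- numeric(reps)
  counts <- numeric(2^s)
  for (r in seq_len(reps)) {
    ord <- sample(labels, length(labels), replace = FALSE)
    if (strategy == "DFS") {
      out <- simulate_ordering(ord, profile$g, params)
      totals[r] <- out$total
      idx <- capture_index(out$I)
    } else {
      out <- run_compressed_search(ord, profile$g, params, strategy = "BFS")
      totals[r] <- out$total_sequenced
      I <- integer(s); I[out$identified] <- 1L
      idx <- capture_index(I)
    }
    counts[idx] <- counts[idx] + 1
  }
  phat <- counts / reps
  per_genome <- vapply(seq_len(s), function(j) {
    on_states <- which(vapply(seq_len(2^s),
                              function(i) capture_state(i, s)[j] == 1L,
                              logical(1)))
    sum(phat[on_states])
  }, numeric(1))
  structure(
    list(mean_total = mean(totals),
         se_total = stats::sd(totals) / sqrt(reps),
         capture = stats::setNames(phat, capture_labels(s)),
         capture_se = sqrt(phat * (1 - phat) / reps),
         per_genome_capture = per_genome,
         reps = reps, strategy = strategy, seed = seed),
    class = "distill_mc"
  )
}

#' @export
print.distill_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo ensemble estimate (%s, %d orderings)\n",
              x$strategy, x$reps))
  cat(sprintf("  mean total sequenced : %.4f Gbp (SE %.4f)\n",
              x$mean_total / 1e9, x$se_total / 1e9))
  nz <- x$capture[x$capture > 0]
  cat("  capture states       :",
      paste(sprintf("q%s=%.4f", names(nz), nz), collapse = " "), "\n")
  invisible(x)
}
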