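#' Exact ensemble analysis of the adaptive compressed DFS
#'
#' Computes, by dynamic programming over multivariate-hypergeometric splits,
#' the expected total sequenced nucleotides `E[t]` and the exact joint
#' probability of every capture state after the adaptive depth-first search
#' completes, averaged over all `n!` orderings of the community's cells.
#'
#' The recursion mirrors the search: a node holding cell counts `p` is
#' sensed through the error-free oracle
#' ([allocate_sequence_assemble()]); if its assembly is subsumed by the
#' captured set ([subsumed_ensemble()]) the subtree ends; a single cell is
#' deeply sequenced (allocation repeated until coverage reaches `2 M_u`)
#' and its genome captured; otherwise the node's cells split into two
#' halves in all possible ways, each way weighted by its
#' multivariate-hypergeometric probability, and the two halves are explored
#' left then right with the capture distribution propagated between them.
#'
#' @param profile A [community_profile()].
#' @param params A [distill_params()].  `root_assembly` and `root_sensed`
#'   set the allocation basis of the first sensing round, for which no
#'   parent assembly exists.
#' @param I0 Optional starting capture state (binary vector, default all
#'   zeros).  A non-zero `I0` evaluates the node directly (the community is
#'   then treated as one sensed pool with the given prior).
#' @return An object of class `"distill_ensemble"`: list with
#'   `expected_total` (bp), `capture` (probability per capture state,
#'   named by bitstring, summing to 1), `per_genome_capture`,
#'   `node_evaluations`, `profile`, `params`.
#' @seealso [brute_force_ensemble()] for the independent validation oracle,
#'   [ensemble_monte_carlo()] for the stochastic cross-check.
#' @examples
#' pr <- community_profile(c(15, 10, 15), c(4e6, 12e6, 2e6))
#' fit <- ensemble_cost(pr, distill_params())
#' fit
#' @export
ensemble_cost <- function(profile, params = distill_params(), I0 = NULL) {
  stopifnot(inherits(profile, "community_profile"),
            inherits(params, "distill_params"))
  s <- profile$s
  if (is.null(I0)) I0 <- integer(s)
  stopifnot(length(I0) == s, all(I0 %in% c(0, 1)))
  a0 <- root_assembly_bp(params, profile$g)
  out <- .ensemble_cost_cpp(
    p = as.integer(profile$p), g = as.numeric(profile$g),
    M_u = params$M_u, M_l = params$M_l, tau = params$tau,
    safety_factor = params$safety_factor, root_assembly = a0,
    root_sensed = params$root_sensed,
    coverage_min = params$coverage_summary == "min",
    I0 = as.integer(I0)
  )
  P <- stats::setNames(out$P, capture_labels(s))
  per_genome <- vapply(seq_len(s), function(j) {
    sum(P[vapply(seq_len(2^s),
                 function(i) capture_state(i, s)[j] == 1L, logical(1))])
  }, numeric(1))
  structure(
    list(expected_total = out$expected_total,
         capture = P,
         per_genome_capture = per_genome,
         node_evaluations = out$node_evaluations,
         profile = profile, params = params),
    class = "distill_ensemble"
  )
}

#' @export
print.distill_ensemble <- function(x, digits = 4, ...) {
  cat(sprintf("Ensemble analysis (DFS) of %d cells, %d distinct genomes\n",
              x$profile$n, x$profile$s))
  cat(sprintf("  E[t] = %.4f Gbp  (naive comparator %.4f Gbp)\n",
              x$expected_total / 1e9,
              naive_cost(x$profile, x$params) / 1e9))
  nz <- x$capture[x$capture > 5e-5]
  cat("  capture states:\n")
  for (nm in names(nz))
    cat(sprintf("    q%s = %.*f\n", nm, digits, nz[[nm]]))
  miss <- 1 - x$per_genome_capture
  if (any(miss > 5e-5)) {
    cat("  per-genome missing probability:\n")
    for (j in which(miss > 5e-5))
      cat(sprintf("    genome %d (%.3g Mbp): %.*f\n",
                  j, x$profile$g[j] / 1e6, digits, miss[j]))
  }
  invisible(x)
}

#' @export
summary.distill_ensemble <- function(object, ...) {
  df <- data.frame(
    state = paste0("q", names(object$capture)),
    index = seq_along(object$capture),
    probability = as.numeric(object$capture)
  )
  out <- list(expected_total = object$expected_total,
              naive = naive_cost(object$profile, object$params),
              capture_table = df,
              per_genome_capture = object$per_genome_capture,
              node_evaluations = object$node_evaluations)
  class(out) <- "summary.distill_ensemble"
  out
}

#' @export
print.summary.distill_ensemble <- function(x, ...) {
  cat(sprintf("E[t] = %.4f Gbp; naive = %.4f Gbp; ratio = %.2f\n",
              x$expected_total / 1e9, x$naive / 1e9,
              x$expected_total / x$naive))
  print(x$capture_table[x$capture_table$probability > 0, ], row.names = FALSE)
  invisible(x)
}

#' Brute-force ensemble analysis by permutation enumeration
#'
#' Enumerates every distinct ordering of the community's cells, runs the
#' same per-ordering recursion the dynamic program models, and averages.
#' All distinct orderings of the label multiset are equally likely under a
#' uniformly random permutation, so the average is exact.  Tractable only
#' for tiny communities; guarded at `n <= 8`.  This function is the
#' independent correctness oracle for [ensemble_cost()].
#'
#' @param profile A [community_profile()] with at most 8 cells.
#' @param params A [distill_params()].
#' @return List with `expected_total` (bp), `capture` (named probability
#'   vector), `n_orderings`.
#' @examples
#' pr <- community_profile(c(3, 1), c(4e6, 2e6))
#' brute_force_ensemble(pr, distill_params())
#' @export
brute_force_ensemble <- function(profile, params = distill_params()) {
  stopifnot(inherits(profile, "community_profile"))
  if (profile$n > 8)
    stop("brute force is guarded at n <= 8 (", profile$n, " cells given)",
         call. = FALSE)
  s <- profile$s
  orderings <- multiset_permutations(rep(seq_len(s), times = profile$p))
  tot <- 0
  P <- numeric(2^s)
  for (ord in orderings) {
    out <- simulate_ordering(ord, profile$g, params)
    tot <- tot + out$total
    idx <- capture_index(out$I)
    P[idx] <- P[idx] + 1
  }
  m <- length(orderings)
  list(expected_total = tot / m,
       capture = stats::setNames(P / m, capture_labels(s)),
       n_orderings = m)
}

# All distinct orderings of a label multiset.
multiset_permutations <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(list(labels))
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    for (tail in multiset_permutations(rest))
      out[[length(out) + 1L]] <- c(u, tail)
  }
  out
}

#' Expected cost as a function of community size
#'
#' Scales a base profile to a series of community sizes, runs the ensemble
#' analysis at each, and summarises the growth of `E[t]`.  Fits of
#' `E[t] ~ log(n)` and `E[t] ~ n` are compared by residual sum of squares:
#' in the error-free model the adaptive search grows logarithmically in the
#' number of cells while the naive strategy grows linearly.
#'
#' @param base_profile Integer vector: the profile at the smallest scale
#'   (e.g. `c(3, 2, 3)` for 8 cells).
#' @param g Genome sizes (bp).
#' @param n_values Community sizes; each must be a multiple of
#'   `sum(base_profile)`.
#' @param params A [distill_params()].
#' @return An object of class `"distill_curve"`: a data frame with columns
#'   `n`, `expected_total`, `naive`, and per-genome missing probabilities
#'   `miss_1..miss_s`; attributes `fit_log` and `fit_linear` hold the two
#'   least-squares fits.
#' @examples
#' expected_cost_curve(c(3, 2, 3), c(4e6, 12e6, 2e6), n_values = c(8, 16))
#' @export
expected_cost_curve <- function(base_profile, g, n_values,
                                params = distill_params()) {
  n0 <- sum(base_profile)
  if (any(n_values %% n0 != 0))
    stop("every n must be a multiple of sum(base_profile) = ", n0,
         call. = FALSE)
  rows <- lapply(n_values, function(n) {
    k <- n %/% n0
    pr <- community_profile(base_profile * k, g)
    fit <- ensemble_cost(pr, params)
    c(n = n, expected_total = fit$expected_total,
      naive = naive_cost(pr, params),
      stats::setNames(1 - fit$per_genome_capture,
                      paste0("miss_", seq_along(g))))
  })
  df <- as.data.frame(do.call(rbind, rows))
  fit_log <- stats::lm(expected_total ~ log(n), data = df)
  fit_lin <- stats::lm(expected_total ~ n, data = df)
  attr(df, "fit_log") <- fit_log
  attr(df, "fit_linear") <- fit_lin
  class(df) <- c("distill_curve", "data.frame")
  df
}

#' @export
print.distill_curve <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  df$expected_total <- df$expected_total / 1e9
  df$naive <- df$naive / 1e9
  names(df)[names(df) == "expected_total"] <- "E[t]_Gbp"
  names(df)[names(df) == "naive"] <- "naive_Gbp"
  print(df, row.names = FALSE)
  rss_log <- sum(stats::residuals(attr(x, "fit_log"))^2)
  rss_lin <- sum(stats::residuals(attr(x, "fit_linear"))^2)
  cat(sprintf("RSS: E[t] ~ log(n): %.4g;  E[t] ~ n: %.4g  (%s fit wins)\n",
              rss_log, rss_lin,
              if (rss_log < rss_lin) "logarithmic" else "linear"))
  invisible(x)
}

#' @export
plot.distill_curve <- function(x, ...) {
  graphics::plot(x$n, x$expected_total / 1e9, log = "x", type = "b",
                 pch = 19, xlab = "number of cells n",
                 ylab = "expected total sequenced (Gbp)", ...)
  graphics::lines(x$n, x$naive / 1e9, lty = 2)
  graphics::legend("topleft", legend = c("adaptive E[t]", "naive"),
                   lty = c(1, 2), pch = c(19, NA), bty = "n")
  invisible(x)
}
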