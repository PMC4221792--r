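#' Community profile: cells per distinct genome and genome sizes
#'
#' A community of `n` single cells drawn from `s` distinct genomes is
#' summarised by the population profile `p` (cells per distinct genome) and
#' the genome sizes `g` in base pairs.  Genomes are black boxes: only their
#' sizes enter the model.
#'
#' @param p Integer vector of cell counts per distinct genome (non-negative;
#'   at least one positive entry).
#' @param g_bp Numeric vector of genome sizes in base pairs, same length as
#'   `p`, all positive.
#'
#' @return An object of class `"community_profile"` with elements `p`, `g`,
#'   `s` (number of distinct genomes) and `n` (total cells).
#' @examples
#' community_profile(p = c(15, 10, 15), g_bp = c(4e6, 12e6, 2e6))
#' @export
community_profile <- function(p, g_bp) {
  stopifnot(is.numeric(p), length(p) >= 1L, all(is.finite(p)))
  if (any(p < 0) || any(p != round(p)))
    stop("'p' must contain non-negative integers", call. = FALSE)
  stopifnot(is.numeric(g_bp), length(g_bp) == length(p), all(is.finite(g_bp)))
  if (any(g_bp <= 0))
    stop("all genome sizes must be positive", call. = FALSE)
  if (sum(p) < 1)
    stop("the community must contain at least one cell", call. = FALSE)
  structure(
    list(p = as.integer(p), g = as.numeric(g_bp),
         s = length(p), n = as.integer(sum(p))),
    class = "community_profile"
  )
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("Community profile: %d cells, %d distinct genome%s\n",
              x$n, x$s, if (x$s == 1L) "" else "s"))
  df <- data.frame(genome = seq_len(x$s), cells = x$p,
                   size_Mbp = x$g / 1e6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cost of the naive cell-by-cell deep sequencing strategy
#'
#' Deeply sequencing every cell requires `M_u` complete coverages of the
#' largest genome per cell: `M_u * max(g) * n` base pairs.  This is the
#' comparator against which the adaptive strategies are measured.
#'
#' @param profile A [community_profile()].
#' @param params A [distill_params()] object (only `M_u` is used).
#' @return Total base pairs (numeric scalar).
#' @examples
#' pr <- community_profile(c(15, 10, 15), c(4e6, 12e6, 2e6))
#' naive_cost(pr, distill_params())  # 2.4e9 bp for the 40-cell community
#' @export
naive_cost <- function(profile, params = distill_params()) {
  stopifnot(inherits(profile, "community_profile"),
            inherits(params, "distill_params"))
  params$M_u * max(profile$g) * profile$n
}

#' Deterministic community profile generator
#'
#' Builds profiles for simulation studies.  `skew = "uniform"` spreads the
#' `n` cells as evenly as possible over the `s` genomes (the empirically
#' cheapest arrangement); `skew = "worst"` gives one genome `n - s + 1`
#' cells and every other genome a single cell (the empirically most
#' expensive arrangement).
#'
#' @param s Number of distinct genomes.
#' @param n Total number of cells (`n >= s`).
#' @param size_range Genome size interval in base pairs from which sizes are
#'   drawn uniformly (default 1-12 Mbp, typical for bacteria).  A length-1
#'   value fixes all sizes.
#' @param skew `"uniform"` or `"worst"` (see above).
#' @param seed Integer seed making the size draw reproducible.
#' @return A [community_profile()].
#' @examples
#' make_profile(4, 32, skew = "uniform", seed = 1)$p   # 8 cells each
#' make_profile(4, 32, skew = "worst", seed = 1)$p     # 29, 1, 1, 1
#' @export
make_profile <- function(s, n, size_range = c(1e6, 12e6),
                         skew = c("uniform", "worst"), seed = 1L) {
  stopifnot(s >= 1, n >= 1, s == round(s), n == round(n))
  if (s > n) stop("'s' cannot exceed 'n'", call. = FALSE)
  skew <- match.arg(skew)
  stopifnot(is.numeric(size_range), all(size_range > 0),
            length(size_range) %in% c(1L, 2L))
  p <- if (skew == "uniform") {
    base <- n %/% s
    extra <- n %% s
    base + c(rep(1L, extra), rep(0L, s - extra))
  } else {
    c(n - s + 1L, rep(1L, s - 1L))
  }
  g <- if (length(size_range) == 1L || size_range[1] == size_range[2]) {
    rep(size_range[1], s)
  } else {
    withr_seed <- local_seed(seed)
    on.exit(withr_seed(), add = TRUE)
    stats::runif(s, size_range[1], size_range[2])
  }
  community_profile(p, g)
}

#' Realize one cell ordering from a community profile
#'
#' Draws a uniformly random permutation of the cell labels (one label per
#' cell, labels `1..s`).  The ensemble quantities computed by
#' [ensemble_cost()] are averages over all such orderings.
#'
#' @param profile A [community_profile()].
#' @param seed Integer seed; the same seed always returns the same ordering.
#' @return Integer vector of length `n` with genome label per cell.
#' @examples
#' pr <- community_profile(c(2, 1), c(4e6, 2e6))
#' cells_from_profile(pr, seed = 7)
#' @export
cells_from_profile <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "community_profile"))
  labels <- rep(seq_len(profile$s), times = profile$p)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  sample(labels, length(labels), replace = FALSE)
}

# Set the RNG state from an explicit seed and return a restorer, so that
# package functions never disturb the caller's global random state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
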