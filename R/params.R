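#' Algorithm parameters for adaptive compressed sequencing
#'
#' Bundles the tunable constants of the error-free sequencing-and-assembly
#' model and of the adaptive search, with validation.
#'
#' @param M_u Coverage multiple (x) at or above which the assembly of a
#'   genome is complete.  Any coverage below `M_u` yields a proportionally
#'   partial assembly.
#' @param M_l Coverage multiple (x) at or below which a pooled assembly is
#'   considered low quality/unreliable; such pools are never pruned and are
#'   explored further.  Must satisfy `0 <= M_l < M_u`.
#' @param tau Dissimilarity tolerance in `[0, 1)`: the maximum fraction of
#'   novel assembled content that may be discarded when a pool is declared
#'   subsumed by what has already been captured.  `tau = 0` demands exact
#'   containment.
#' @param safety_factor Dimensionless multiplier applied to the lower-bound
#'   allocation `M_u * a_parent` when sampling a pool (default 2, a 2x
#'   safety margin).  Values at or below 1 stall the deep-sequencing loop at
#'   leaves (coverage then never grows), so `safety_factor > 1` is required.
#' @param root_assembly Prior used for the very first sensing round, before
#'   any assembly exists: `"max"` (largest genome size, the default, mirrors
#'   the naive comparator), `"sum"` (summed genome sizes), or a positive
#'   number of base pairs.
#' @param root_sensed Logical; if `TRUE` the whole input community is sensed
#'   once as a single pool before the first split, and that sensing is
#'   charged.  If `FALSE` (default) analysis starts from the two halves of
#'   the first split, as the search itself does.
#' @param coverage_summary How the scalar coverage of a pool is summarised
#'   from its per-genome coverages: `"min"` (default, most conservative) or
#'   `"mean_weighted"` (total nucleotides over total represented genome
#'   length).
#'
#' @return An object of class `"distill_params"`.
#' @examples
#' distill_params()                      # defaults used throughout
#' distill_params(tau = 0)              # exact containment, no misses
#' @export
distill_params <- function(M_u = 5, M_l = 0.3, tau = 0.2, safety_factor = 2,
                           root_assembly = "max", root_sensed = FALSE,
                           coverage_summary = c("min", "mean_weighted")) {
  stopifnot(is.numeric(M_u), length(M_u) == 1L, is.finite(M_u), M_u > 0)
  stopifnot(is.numeric(M_l), length(M_l) == 1L, is.finite(M_l))
  if (M_l < 0 || M_l >= M_u)
    stop("'M_l' must satisfy 0 <= M_l < M_u", call. = FALSE)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (tau < 0 || tau >= 1)
    stop("'tau' must lie in [0, 1)", call. = FALSE)
  stopifnot(is.numeric(safety_factor), length(safety_factor) == 1L)
  if (safety_factor <= 1)
    stop("'safety_factor' must exceed 1 (leaf deep sequencing cannot ",
         "increase coverage otherwise)", call. = FALSE)
  coverage_summary <- match.arg(coverage_summary)
  if (is.character(root_assembly)) {
    root_assembly <- match.arg(root_assembly, c("max", "sum"))
  } else {
    stopifnot(is.numeric(root_assembly), length(root_assembly) == 1L,
              is.finite(root_assembly), root_assembly > 0)
  }
  stopifnot(is.logical(root_sensed), length(root_sensed) == 1L,
            !is.na(root_sensed))
  structure(
    list(M_u = as.numeric(M_u), M_l = as.numeric(M_l), tau = as.numeric(tau),
         safety_factor = as.numeric(safety_factor),
         root_assembly = root_assembly, root_sensed = root_sensed,
         coverage_summary = coverage_summary),
    class = "distill_params"
  )
}

#' @export
print.distill_params <- function(x, ...) {
  cat("Adaptive compressed sequencing parameters\n")
  cat(sprintf("  complete-assembly coverage  M_u = %g x\n", x$M_u))
  cat(sprintf("  low-quality coverage        M_l = %g x\n", x$M_l))
  cat(sprintf("  dissimilarity tolerance     tau = %g\n", x$tau))
  cat(sprintf("  allocation safety factor        = %g\n", x$safety_factor))
  cat(sprintf("  root assembly prior             = %s%s\n",
              if (is.character(x$root_assembly)) x$root_assembly
              else format(x$root_assembly, big.mark = ","),
              if (x$root_sensed) " (root pool sensed)" else ""))
  cat(sprintf("  pool coverage summary           = %s\n", x$coverage_summary))
  invisible(x)
}

# Resolve the root assembly prior to base pairs for a given size vector.
root_assembly_bp <- function(params, g) {
  if (is.numeric(params$root_assembly)) return(params$root_assembly)
  switch(params$root_assembly, max = max(g), sum = sum(g))
}
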