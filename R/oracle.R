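#' Error-free coverage-to-assembly model
#'
#' Under uniform, error-free sequencing, a genome of size `g` sequenced to
#' coverage `c` assembles to `g * c / M_u` base pairs while `c <= M_u`, and
#' to the complete genome beyond that.  The model is continuous at
#' `c = M_u`.
#'
#' @param c Coverage (x), non-negative.
#' @param g Genome size in base pairs.
#' @param params A [distill_params()].
#' @return Assembled length in base pairs.
#' @examples
#' p <- distill_params(M_u = 5)
#' assembly_size(2.5, 4e6, p)   # 2 Mbp, proportional regime
#' assembly_size(50, 4e6, p)    # 4 Mbp, saturated
#' @export
assembly_size <- function(c, g, params = distill_params()) {
  stopifnot(is.numeric(c), is.numeric(g), all(g > 0))
  if (any(c < 0)) stop("coverage must be non-negative", call. = FALSE)
  ifelse(c <= params$M_u, g * c / params$M_u, g)
}

#' Resource allocation for one pool
#'
#' The sampling size for a child pool is scaled from its parent:
#' `t = t_parent * c_target * a_target / (c_parent * a_parent)`, with the
#' target coverage set to `M_u` so the child's expected assembly completes.
#' In the error-free model, where the parent's nucleotides satisfy
#' `t_parent = c_parent * a_parent`, this reduces to `t = M_u * a_target`;
#' the pool is in practice granted `safety_factor * M_u * a_parent` (the
#' worst case `a_target = a_parent` with a safety margin).
#'
#' @param t_parent,c_parent,a_parent Parent pool totals: sampled
#'   nucleotides (bp), coverage (x) and assembly size (bp), all positive.
#' @param a_target Intended assembly size of the pool (bp).
#' @param c_target Intended coverage; defaults to `M_u`.
#' @param params A [distill_params()].
#' @return Nucleotides to sample for the pool (bp).
#' @examples
#' p <- distill_params()
#' resource_allocate(100e6, 5, 10e6, a_target = 10e6, params = p)  # 100 Mbp
#' @export
resource_allocate <- function(t_parent, c_parent, a_parent, a_target,
                              c_target = NULL, params = distill_params()) {
  if (is.null(c_target)) c_target <- params$M_u
  stopifnot(t_parent > 0, a_target >= 0, c_target > 0)
  if (c_parent <= 0 || a_parent <= 0)
    stop("allocation undefined for zero parent coverage or assembly",
         call. = FALSE)
  t_parent * c_target * a_target / (c_parent * a_parent)
}

#' Sequence-and-assemble oracle for one pool
#'
#' The black box at the heart of the ensemble model.  A pool holding `p_j`
#' cells of genome `j` is granted `t = safety_factor * M_u * a_parent`
#' nucleotides, split evenly over its cells; each genome receives
#' nucleotides in proportion to its cell count, giving per-genome coverage
#' `c_j = (t / n_pool) * p_j / g_j` and assembly [assembly_size()].
#'
#' @param p Integer vector: cells of each genome present in the pool (may
#'   contain zeros; at least one positive entry).
#' @param g Genome sizes (bp), same length as `p`.
#' @param a_parent Parent assembly size in bp (positive).
#' @param params A [distill_params()].
#' @return A list with `t` (total bp drawn), `t_pc` (bp per cell), `t_pdg`
#'   (bp per genome), `coverage` (per-genome coverage, 0 where absent),
#'   `a_bar` (per-genome assembled bp), `total` (sum of `a_bar`) and `c`
#'   (scalar pool coverage under `params$coverage_summary`).
#' @examples
#' allocate_sequence_assemble(c(2, 2), c(4e6, 2e6), a_parent = 6e6)
#' @export
allocate_sequence_assemble <- function(p, g, a_parent,
                                       params = distill_params()) {
  stopifnot(length(p) == length(g), sum(p) >= 1)
  if (a_parent <= 0) stop("'a_parent' must be positive", call. = FALSE)
  t <- params$safety_factor * params$M_u * a_parent
  n_pool <- sum(p)
  t_pc <- t / n_pool
  t_pdg <- t_pc * p
  coverage <- ifelse(p > 0, t_pdg / g, 0)
  a_bar <- ifelse(p > 0, assembly_size(coverage, g, params), 0)
  repr <- p > 0
  c_scalar <- switch(params$coverage_summary,
    min = min(coverage[repr]),
    mean_weighted = t / sum(g[repr])
  )
  list(t = t, t_pc = t_pc, t_pdg = t_pdg, coverage = coverage,
       a_bar = a_bar, total = sum(a_bar), c = c_scalar)
}

#' Relaxed containment score between two assemblies
#'
#' `d_tau = tau - exclusive / total`, where `exclusive` is the assembled
#' content of the first assembly absent from the second and `total` its full
#' assembled length.  Non-negative values mean the first assembly is
#' subsumed: its novel content is within the tolerated fraction `tau`.
#'
#' @param a1_exclusive Assembled bp of the first assembly not present in the
#'   second (`0 <= a1_exclusive <= a1_total`).
#' @param a1_total Total assembled bp of the first assembly (positive).
#' @param params A [distill_params()].
#' @return The score (dimensionless); subsumption holds when `>= 0`.
#' @examples
#' d_tau(0, 10e6)        #  0.2: fully contained
#' d_tau(3e6, 10e6)      # -0.1: too much novel content
#' @export
d_tau <- function(a1_exclusive, a1_total, params = distill_params()) {
  if (a1_total <= 0)
    stop("'a1_total' must be positive", call. = FALSE)
  stopifnot(a1_exclusive >= 0, a1_exclusive <= a1_total)
  params$tau - a1_exclusive / a1_total
}

#' Subsumption test between a pool assembly and a reference assembly
#'
#' A newly sensed pool is subsumed by the reference (and its subtree pruned)
#' when its coverage is reliable (`c > M_l`) and its content novel to the
#' reference is at most a `tau` fraction of its assembled length.  Under the
#' error-free uniform model, assemblies of the same genome are nested, so
#' the per-genome set difference is `max(0, a_new_j - a_ref_j)`.
#'
#' @param a_new,a_reference Per-genome assembled lengths (bp) of the pool
#'   and of the reference (equal lengths).
#' @param c Scalar coverage of the pool (x).
#' @param params A [distill_params()].
#' @return Logical; `FALSE` whenever `c <= M_l` (unreliable pools are
#'   explored further, never pruned).
#' @examples
#' prm <- distill_params()
#' subsumed(c(4e6, 0, 2e6), c(4e6, 12e6, 2e6), c = 10, params = prm)  # TRUE
#' @export
subsumed <- function(a_new, a_reference, c, params = distill_params()) {
  stopifnot(length(a_new) == length(a_reference))
  if (c <= params$M_l) return(FALSE)
  total <- sum(a_new)
  stopifnot(total > 0)
  exclusive <- sum(pmax(0, a_new - a_reference))
  d_tau(min(exclusive, total), total, params) >= -1e-12
}

#' Subsumption test against a capture state
#'
#' Ensemble-analysis variant of [subsumed()]: the reference is the set of
#' already-captured genomes, so the exclusive content of the pool is the
#' assembled length of its uncaptured genomes,
#' `x = sum(a_bar[I == 0])`.  Subsumption holds when `c > M_l` and
#' `tau - x / sum(a_bar) >= 0`.
#'
#' @param a_bar Per-genome assembled lengths (bp) of the pool.
#' @param c Scalar coverage of the pool (x).
#' @param I Binary capture state, same length as `a_bar`.
#' @param params A [distill_params()].
#' @return Logical.
#' @examples
#' prm <- distill_params()
#' subsumed_ensemble(c(4e6, 12e6, 2e6), 10, c(1, 1, 0), prm)
#' # TRUE: the 2 Mbp genome is only 2/18 = 11% novel content, under tau = 0.2
#' @export
subsumed_ensemble <- function(a_bar, c, I, params = distill_params()) {
  stopifnot(length(a_bar) == length(I), all(I %in% c(0, 1)))
  if (c <= params$M_l) return(FALSE)
  total <- sum(a_bar)
  stopifnot(total > 0)
  x <- sum(a_bar[I == 0])
  params$tau - x / total >= -1e-12
}
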