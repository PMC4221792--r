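#' Enumerate the half-splits of a node and their probabilities
#'
#' When a pool holding cell counts `p` (totalling `m` cells) is divided in
#' half, the genome composition `v` of the first half follows the
#' multivariate hypergeometric distribution: drawing `ceiling(m/2)` of the
#' `m` cells without replacement.  This enumerates every attainable `v`
#' with its probability; the weights sum to one.
#'
#' @param p Integer vector of cell counts (sum at least 2).
#' @return A data frame with one row per division: columns `v_1..v_s`,
#'   `w_1..w_s` (the complementary half) and `pi` (probability).
#' @examples
#' enumerate_divisions(c(2, 1))   # v = (2,0) w.p. 1/3, v = (1,1) w.p. 2/3
#' @export
enumerate_divisions <- function(p) {
  stopifnot(all(p >= 0), all(p == round(p)))
  m <- sum(p)
  if (m < 2) stop("a node with fewer than 2 cells cannot divide",
                  call. = FALSE)
  s <- length(p)
  h <- ceiling(m / 2)
  grid <- expand.grid(lapply(p, function(pj) 0:pj))
  keep <- rowSums(grid) == h
  vs <- as.matrix(grid[keep, , drop = FALSE])
  pi <- apply(vs, 1, function(v) prod(choose(p, v))) / choose(m, h)
  out <- data.frame(vs, t(apply(vs, 1, function(v) p - v)), pi = pi)
  names(out) <- c(paste0("v_", seq_len(s)), paste0("w_", seq_len(s)), "pi")
  rownames(out) <- NULL
  out
}
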