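# Shared fixtures: the ensemble-analysis default setting and the two
# community shapes used throughout the tests.

default_params <- function(...) distill_params(...)

# the 40-cell, three-genome community (sizes 4, 12, 2 Mbp)
profile_323 <- function(scale = 5L) {
  community_profile(c(3L, 2L, 3L) * scale, c(4e6, 12e6, 2e6))
}

# four-genome communities over sizes (4, 12, 2, 1) Mbp
profile4 <- function(p5) community_profile(p5 * 5L, c(4e6, 12e6, 2e6, 1e6))

# enumerate all profiles with s genomes and n total cells, each genome
# represented at least once
all_profiles <- function(s, n) {
  if (s == 1L) return(list(n))
  out <- list()
  for (first in seq_len(n - s + 1L)) {
    for (rest in all_profiles(s - 1L, n - first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

# temp file helper that cleans up with the test
withr_tempfile <- function(name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  path
}
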