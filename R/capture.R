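#' Capture states and their indexing
#'
#' A capture state is a binary vector `I` of length `s` marking which
#' distinct genomes have been deeply sequenced and completely assembled.
#' States are indexed `1..2^s` by treating `I` as a binary number read in
#' reverse order and adding one: `index = sum(I * 2^(0:(s-1))) + 1`.  For
#' `s = 3`, `I = c(0, 1, 1)` ("011") has index 7.
#'
#' @param I Binary vector (0/1 entries).
#' @param index Integer state index in `1..2^s`.
#' @param s Number of distinct genomes.
#' @return `capture_index()` returns the integer index;
#'   `capture_state()` returns the binary vector; `capture_labels()` returns
#'   the bitstring labels ("q011"-style, without the "q") for all `2^s`
#'   states in index order.
#' @examples
#' capture_index(c(0, 1, 1))        # 7
#' capture_state(7, 3)              # c(0, 1, 1)
#' capture_labels(2)                # "00" "10" "01" "11"
#' @export
capture_index <- function(I) {
  stopifnot(all(I %in% c(0, 1)))
  as.integer(sum(I * 2^(seq_along(I) - 1)) + 1)
}

#' @rdname capture_index
#' @export
capture_state <- function(index, s) {
  stopifnot(index >= 1, index <= 2^s)
  as.integer(intToBits(index - 1))[seq_len(s)]
}

#' @rdname capture_index
#' @export
capture_labels <- function(s) {
  vapply(seq_len(2^s), function(i) {
    paste(capture_state(i, s), collapse = "")
  }, character(1))
}
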