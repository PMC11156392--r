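#' Construct a fibril type sequence
#'
#' @param x either an integer/numeric vector of 0/1 indicators (0 = wildtype,
#'   1 = variant; element 1 is the first molecule deposited) or a single
#'   string over the alphabet `w`/`v` with the leftmost character at
#'   position 1. Any other character is rejected.
#'
#' @return a [FibrilSequence-class] object.
#' @examples
#' fibrilSequence("vwvwvwvwvwvw")
#' fibrilSequence(c(1, 0, 1, 0))
#' @export
fibrilSequence <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L)
      stop("supply a single sequence string")
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(ch), c("w", "v"))
    if (length(bad))
      stop("sequence string may only contain 'w' and 'v'; found: ",
           paste(bad, collapse = ", "))
    types <- as.integer(ch == "v")
  } else if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1)))
      stop("type indicators must all be 0 or 1")
    types <- as.integer(x)
  } else {
    stop("x must be a 0/1 vector or a 'w'/'v' string")
  }
  new("FibrilSequence", types = types)
}

#' @describeIn fibrilSequence the 0/1 indicator vector.
#' @param seq a [FibrilSequence-class].
#' @export
sequenceTypes <- function(seq) {
  stopifnot(is(seq, "FibrilSequence"))
  seq@types
}

#' @export
setMethod("length", "FibrilSequence", function(x) length(x@types))

#' @export
setMethod("as.character", "FibrilSequence", function(x) {
  paste(c("w", "v")[x@types + 1L], collapse = "")
})

setMethod("show", "FibrilSequence", function(object) {
  cat(sprintf("FibrilSequence of %d molecules: %s\n",
              length(object@types), as.character(object)))
})

#' Map between type sequences and their integer indices
#'
#' A length-`N` sequence of indicators is read as the binary representation
#' of an integer: `index = sum(sigma_i * 2^(i - 1))`, position 1 being the
#' least significant bit. The map is a bijection between length-`N`
#' sequences and `0:(2^N - 1)`; the all-wildtype sequence has index 0 and
#' the all-variant sequence index `2^N - 1`.
#'
#' @param seq a [FibrilSequence-class].
#' @return `sequenceToIndex`: a non-negative number in `[0, 2^N - 1]`
#'   (double, so indices are exact up to `N = 52`).
#' @examples
#' sequenceToIndex(fibrilSequence("vwvwvwvwvwvw")) # 1365
#' indexToSequence(1365, 12)
#' @export
sequenceToIndex <- function(seq) {
  stopifnot(is(seq, "FibrilSequence"))
  sum(seq@types * 2^(seq_along(seq@types) - 1))
}

#' @rdname sequenceToIndex
#' @param m integer index in `[0, 2^N - 1]`.
#' @param N chain length.
#' @return `indexToSequence`: the [FibrilSequence-class] whose index is `m`.
#' @export
indexToSequence <- function(m, N) {
  N <- as.integer(N)
  stopifnot(N >= 2L, m >= 0, m <= 2^N - 1, m == floor(m))
  new("FibrilSequence", types = as.integer(m %/% 2^(0:(N - 1L)) %% 2))
}

#' The two perfectly alternating reference sequences
#'
#' @param N chain length.
#' @return a list with elements `w` (starts with wildtype: w,v,w,v,...) and
#'   `v` (starts with variant: v,w,v,w,...).
#' @export
alternatingReferences <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 2L)
  startw <- as.integer(seq_len(N) %% 2L == 0L)  # 0,1,0,1,...
  list(w = new("FibrilSequence", types = startw),
       v = new("FibrilSequence", types = 1L - startw))
}

# 0/1 matrix of all 2^N sequences, row m+1 = sequence with index m.
# N is capped by enumerationCap() upstream.
allSequenceBits <- function(N) {
  m <- 0:(2^N - 1)
  vapply(0:(N - 1L), function(i) as.integer(m %/% 2^i %% 2), integer(2^N))
}
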