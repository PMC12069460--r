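#' Block-of-markers feature scheme
#'
#' States are featurized by counting, at every block position, the multiset
#' of length-`B` marker blocks over the alphabet `{0, 1, *}` carried by the
#' sequences of the state.  With sequences of `L` markers and blocks of `B`
#' markers shifted by `o` positions there are `P = (L - B + o) / o` block
#' positions and `3^B` possible blocks, giving a feature dimension
#' `c = 3^B * P` that is independent of the number of sequences in the
#' state.  The idea mirrors the three-gamete test: adjacent-marker blocks
#' carry exactly the signal that determines whether recombination is needed.
#'
#' Blocks are ordered lexicographically with symbol order `0 < 1 < *`; for
#' `B = 2` this is `00, 01, 0*, 10, 11, 1*, *0, *1, **`.
#'
#' @param L sequence length in markers.
#' @param B block size, `B <= L`.
#' @param o overlap step shift; `(L - B + o)` must be divisible by `o`.
#' @return An object of class `arg_block_scheme`: list with `L`, `B`, `o`,
#'   `P`, `c`, `blocks` (the `3^B` blocks in canonical order) and
#'   `block_index` (named lookup).
#' @examples
#' make_scheme(4, 2, 1)$c    # 27
#' make_scheme(10, 3, 1)$c   # 216
#' @export
make_scheme <- function(L, B, o = 1L) {
  L <- as.integer(L); B <- as.integer(B); o <- as.integer(o)
  if (B > L) stop("block size B must not exceed the sequence length L")
  if (o < 1L) stop("the step shift o must be at least 1")
  if ((L - B + o) %% o != 0L) {
    stop("(L - B + o) must be divisible by o; got L=", L, ", B=", B, ", o=", o)
  }
  P <- (L - B + o) %/% o
  sym <- c("0", "1", "*")
  g <- do.call(expand.grid,
               c(rep(list(sym), B), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; lexicographic order needs
  # the last block symbol to vary fastest, so read the columns reversed
  blocks <- apply(as.matrix(g[, rev(seq_len(B)), drop = FALSE]), 1L,
                  paste, collapse = "")
  structure(list(L = L, B = B, o = o, P = P,
                 c = as.integer(3L^B * P),
                 blocks = blocks,
                 block_index = stats::setNames(seq_along(blocks), blocks)),
            class = "arg_block_scheme")
}

#' @export
print.arg_block_scheme <- function(x, ...) {
  cat("<arg_block_scheme> L=", x$L, " B=", x$B, " o=", x$o,
      " (P=", x$P, ", c=", x$c, ")\n", sep = "")
  invisible(x)
}

#' Featurize a state under a block scheme
#'
#' Entry `i` of the feature vector is the multiplicity in the state of block
#' `j = ceiling(i / P)` at position `p = i - P (j - 1)` (the position varies
#' fastest within each block).  Every sequence copy contributes exactly one
#' block per position, so the entries sum to `|s| * P`.
#'
#' @param s an [arg_state()] with sequences of length `scheme$L`.
#' @param scheme an [make_scheme()] object.
#' @return Numeric vector of length `scheme$c`.
#' @examples
#' featurize(arg_state(c("0000", "0001")), make_scheme(4, 2, 1))
#' @export
featurize <- function(s, scheme) {
  if (nchar(s[[1L]]) != scheme$L) {
    stop("state has sequences of length ", nchar(s[[1L]]),
         " but the scheme expects L=", scheme$L)
  }
  x <- numeric(scheme$c)
  starts <- (seq_len(scheme$P) - 1L) * scheme$o + 1L
  ends <- starts + scheme$B - 1L
  for (seq in unclass(s)) {
    blks <- substring(seq, starts, ends)
    idx <- (scheme$block_index[blks] - 1L) * scheme$P + seq_len(scheme$P)
    x[idx] <- x[idx] + 1
  }
  x
}
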