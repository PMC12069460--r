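#' Haplotype states
#'
#' A state of the genealogy-construction process is a multiset of equal-length
#' sequences over the alphabet `0` (ancestral allele), `1` (derived allele)
#' and `*` (non-ancestral material).  States are stored in canonical sorted
#' order so that two states built from the same multiset in any insertion
#' order compare equal.
#'
#' @param seqs character vector of sequences over `{0,1,*}`, all of the same
#'   length; each sequence must carry at least one ancestral (non-`*`) symbol.
#' @return An object of class `arg_state`: a sorted character vector with
#'   attribute `L` (number of markers).
#' @examples
#' s <- arg_state(c("0100", "1000", "1010", "0011"))
#' is_terminal_state(s)
#' @export
arg_state <- function(seqs) {
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("a state must contain at least one sequence")
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) {
    stop("all sequences in a state must have the same length")
  }
  if (any(grepl("[^01*]", seqs))) {
    stop("sequences may only contain the symbols '0', '1' and '*'")
  }
  if (any(vapply(seqs, function(x) !grepl("[01]", x), logical(1L)))) {
    stop("a sequence must carry ancestral material at some position")
  }
  new_state(sort(seqs), L)
}

# internal fast-path constructor: assumes validated, sorts
new_state <- function(seqs, L = nchar(seqs[1L])) {
  structure(sort(seqs), class = "arg_state", L = L)
}

#' @export
print.arg_state <- function(x, ...) {
  cat("<arg_state> ", length(x), " sequence(s) of ", attr(x, "L"),
      " markers\n", sep = "")
  cat(paste0("  ", unclass(x)), sep = "\n")
  invisible(x)
}

#' Canonical string key of a state
#'
#' Used as a hash key by the memoized exact solver and the training caches.
#'
#' @param s an [arg_state()].
#' @return A single string; equal states map to equal keys.
#' @export
state_key <- function(s) paste(s, collapse = " ")

#' Test whether a state is terminal (the MRCA)
#'
#' The terminal state consists of exactly one sequence whose symbols are all
#' `0`: the fully ancestral most recent common ancestor.
#'
#' @param s an [arg_state()] (or plain character vector of sequences).
#' @return `TRUE` or `FALSE`.
#' @export
is_terminal_state <- function(s) {
  length(s) == 1L && !grepl("[^0]", s[[1L]])
}

#' Number of segregating sites of a fully ancestral sample
#'
#' @param s an [arg_state()] with no `*` symbols.
#' @return Count of marker columns at which both alleles occur.
#' @export
n_segregating <- function(s) {
  m <- seq_matrix(s)
  sum(apply(m, 2L, function(col) any(col == "1") && any(col == "0")))
}

# character matrix view: one row per sequence copy
seq_matrix <- function(s) {
  matrix(unlist(strsplit(unclass(s), "", fixed = TRUE), use.names = FALSE),
         nrow = length(s), byrow = TRUE)
}

# number of columns still carrying a derived allele: each such column needs
# exactly one further mutation event (events never create new 1s)
n_mutations_left <- function(s) {
  m <- seq_matrix(s)
  sum(apply(m, 2L, function(col) any(col == "1")))
}

# exact lower bound on the remaining number of events from s:
# one mutation per derived column plus n - 1 coalescences; every
# recombination adds two events, so remaining length == bound (mod 2)
length_lower_bound <- function(s) {
  if (is_terminal_state(s)) 0L else n_mutations_left(s) + length(s) - 1L
}
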