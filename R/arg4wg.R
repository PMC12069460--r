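#' Longest shared ends of a state
#'
#' A shared end of a pair of sequences is the maximal run of consecutive
#' positions, starting from the left or the right end, at which both
#' sequences carry ancestral material and agree.  The ARG4WG heuristic
#' recombines at the inner boundary of a longest shared end.
#'
#' @param s a non-terminal [arg_state()].
#' @return A list of records `(pair, side, length)` for every (type pair,
#'   side) achieving the maximal shared-end length over all pairs and both
#'   ends; empty if no pair shares an end.
#' @export
longest_shared_end <- function(s) {
  types <- unique(unclass(s))
  nt <- length(types)
  best <- 0L
  out <- list()
  if (nt < 2L) return(out)
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      for (side in c("prefix", "suffix")) {
        k <- shared_end_length(types[i], types[j], side)
        if (k == 0L || k < best) next
        if (k > best) { best <- k; out <- list() }
        out[[length(out) + 1L]] <-
          list(pair = c(types[i], types[j]), side = side, length = k)
      }
    }
  }
  out
}

shared_end_length <- function(a, b, side = c("prefix", "suffix")) {
  side <- match.arg(side)
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (side == "suffix") { x <- rev(x); y <- rev(y) }
  k <- 0L
  for (i in seq_along(x)) {
    if (x[i] == "*" || y[i] == "*" || x[i] != y[i]) break
    k <- k + 1L
  }
  k
}

# all branches of one heuristic step: each branch is list(events, state).
# priority: any coalescence; else any mutation; else recombination at a
# maximal shared end followed by the forced coalescence of the shared
# fragment with the partner (two events).  Branches duplicated by symmetric
# tie choices (same event pair) are merged.
arg4wg_branches <- function(s) {
  acts <- legal_actions(s)
  kinds <- vapply(acts, `[[`, character(1L), "kind")
  for (phase in c("coalescence", "mutation")) {
    sel <- acts[kinds == phase]
    if (length(sel) > 0L) {
      return(lapply(sel, function(a) {
        r <- apply_action(s, a)
        list(events = list(r$event), state = r$state)
      }))
    }
  }
  ends <- longest_shared_end(s)
  if (length(ends) == 0L) {
    stop("ARG4WG dead end: no coalescence, mutation or shared end in state ",
         state_key(s))
  }
  L <- nchar(s[[1L]])
  branches <- list()
  seen <- character(0L)
  for (e in ends) {
    for (which_rec in 1:2) {
      rec <- e$pair[which_rec]
      other <- e$pair[3L - which_rec]
      g <- if (e$side == "prefix") e$length else L - e$length
      frag <- if (e$side == "prefix") {
        paste0(substr(rec, 1L, g), strrep("*", L - g))
      } else {
        paste0(strrep("*", g), substr(rec, g + 1L, L))
      }
      if (g < 1L || g >= L) next   # whole-sequence shared end: not a split
      r_act <- new_action("recombination", seq = rec, gap = g)
      c_act <- new_action("coalescence", pair = sort(c(frag, other)))
      key <- paste(action_key(r_act), action_key(c_act))
      if (key %in% seen) next
      seen <- c(seen, key)
      r1 <- apply_action(s, r_act)
      r2 <- apply_action(r1$state, c_act)
      branches[[length(branches) + 1L]] <-
        list(events = list(r1$event, r2$event), state = r2$state)
    }
  }
  branches
}

#' One step of the ARG4WG heuristic
#'
#' Applies the heuristic priority: (1) any legal coalescence; (2) else any
#' legal mutation; (3) else a recombination of one sequence of a
#' longest-shared-end pair at the boundary of the shared segment,
#' immediately followed by the coalescence of the shared-segment fragment
#' with the partner (two events).  Choices at the active priority level are
#' resolved uniformly at random (seeded).
#'
#' @param s a non-terminal [arg_state()].
#' @param seed optional seed for the tie-break.
#' @return A list `(events, state)`: one event for phases 1-2, two for
#'   phase 3.
#' @export
arg4wg_step <- function(s, seed = NULL) {
  branches <- arg4wg_branches(s)
  with_seed(seed, branches[[sample.int(length(branches), 1L)]])
}

#' Build an ARG with the ARG4WG heuristic
#'
#' Repeats [arg4wg_step()] until the MRCA is reached.  Every phase strictly
#' reduces a bounded potential on the printed toy scale, but termination is
#' enforced by an explicit step cap.
#'
#' @param sample an [arg_state()] of fully ancestral `0/1` sequences.
#' @param seed optional seed for the tie-breaks.
#' @param step_cap hard cap on the number of events (error when exceeded).
#' @return A complete [new_arg()].
#' @examples
#' arg4wg_build(arg_state(c("0011", "1011", "1000", "1100")), seed = 1)
#' @export
arg4wg_build <- function(sample, seed = NULL, step_cap = 1000L) {
  with_seed(seed, {
    events <- list()
    s <- sample
    while (!is_terminal_state(s)) {
      if (length(events) >= step_cap) {
        stop("ARG4WG step cap (", step_cap, ") exceeded")
      }
      step <- arg4wg_step(s)
      events <- c(events, step$events)
      s <- step$state
    }
    new_arg(sample, events)
  })
}

#' Enumerate every genealogy reachable by ARG4WG tie-breaks
#'
#' Exhaustive depth-first exploration of every tie-break choice (which
#' coalescence or mutation among ties; which pair, which end and which
#' sequence of the pair for the recombination phase), collecting the set of
#' distinct complete event sequences.
#'
#' @param sample an [arg_state()] of fully ancestral `0/1` sequences.
#' @param cap maximum number of distinct genealogies before an explicit
#'   overflow error.
#' @param depth_cap guard against cyclic tie-break branches.
#' @return List of distinct complete [new_arg()]s.
#' @export
arg4wg_enumerate <- function(sample, cap = 10000L, depth_cap = 400L) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  dfs <- function(s, events) {
    if (is_terminal_state(s)) {
      key <- paste(vapply(events, function(e) action_key(e$action),
                          character(1L)), collapse = ";")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <<- new_arg(sample, events)
        if (length(out) > cap) {
          stop("ARG4WG enumeration overflow: more than ", cap,
               " distinct genealogies")
        }
      }
      return(invisible())
    }
    if (length(events) >= depth_cap) {
      stop("ARG4WG enumeration depth cap (", depth_cap, ") exceeded")
    }
    for (branch in arg4wg_branches(s)) {
      dfs(branch$state, c(events, branch$events))
    }
  }
  dfs(sample, list())
  out
}
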