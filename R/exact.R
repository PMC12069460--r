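#' @section Exact layer:
#' The genealogy-construction process is a deterministic unit-cost shortest
#' path problem, so the exact layer can recover the minimal ARG length, count
#' and enumerate every minimal genealogy, and run value iteration on the
#' reachable state space of toy samples (the state space grows as
#' O(n^(3L-1)), so this is feasible only for samples of roughly 4 sequences
#' of 4 SNPs).
#'
#' All searches share one exact pruning rule.  From a state `s`, every
#' remaining completion performs exactly one mutation per marker column still
#' carrying a derived allele (say `m` of them) and `n - 1 + R` coalescences
#' for `R >= 0` recombinations, hence has length `m + n - 1 + 2R`.  A branch
#' with fewer than `m + n - 1` steps left, or a step budget of the wrong
#' parity, therefore contributes exactly zero minimal genealogies and is cut.
#' @name exact-layer
NULL

# memoized count of distinct action sequences of length exactly k from s to
# the terminal state; memo is an environment keyed by "state|k"
count_paths <- function(s, k, memo) {
  if (is_terminal_state(s)) return(if (k == 0L) 1 else 0)
  b <- length_lower_bound(s)
  if (k < b || (k - b) %% 2L != 0L) return(0)
  key <- paste0(state_key(s), "|", k)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  total <- 0
  for (succ in successors(s)) {
    total <- total + count_paths(succ$state, k - 1L, memo)
  }
  memo[[key]] <- total
  total
}

# shared driver: smallest k (of the right parity) with a positive path count
min_search <- function(s0, depth_cap) {
  b <- length_lower_bound(s0)
  if (!is.null(depth_cap) && depth_cap < b) {
    stop("depth_cap (", depth_cap, ") is below the event lower bound ", b)
  }
  memo <- new.env(parent = emptyenv())
  k <- b
  while (is.null(depth_cap) || k <= depth_cap) {
    n <- count_paths(s0, k, memo)
    if (n > 0) return(list(length = k, count = n, memo = memo))
    k <- k + 2L  # remaining length is congruent to the bound mod 2
  }
  stop("cap exceeded: no complete ARG within ", depth_cap,
       " events; raise depth_cap")
}

#' Minimal ARG length of a sample
#'
#' Length of the shortest complete genealogy (event sequence) from the
#' sample to the MRCA, by iterative-deepening exhaustive search with
#' memoization on (state, remaining depth).  Exact because every action
#' costs one event.
#'
#' @param s0 an [arg_state()].
#' @param depth_cap search cap on the ARG length; the default allows up to
#'   ten recombinations beyond the perfect-phylogeny bound.  If no complete
#'   ARG exists within the cap an explicit "cap exceeded" error is raised.
#' @return The minimal length (non-negative integer).
#' @examples
#' min_arg_length(arg_state(c("01", "10")))  # 3
#' @export
min_arg_length <- function(s0, depth_cap = length_lower_bound(s0) + 20L) {
  if (is_terminal_state(s0)) return(0L)
  min_search(s0, depth_cap)$length
}

#' Count the distinct minimal genealogies of a sample
#'
#' Number of distinct action sequences of exactly the minimal length from
#' the sample to the MRCA, via the memoized recursion
#' `count(s, k) = sum over legal actions a of count(apply(s, a), k - 1)`.
#' Distinct genealogies are distinct ordered event lists, which equals the
#' number of genealogies constructible under the optimal policy (every
#' minimal path takes only optimal actions).
#'
#' @inheritParams min_arg_length
#' @return A positive count.
#' @examples
#' count_min_args(arg_state(c("01", "10")))  # 2 (the two mutation orders)
#' @export
count_min_args <- function(s0, depth_cap = length_lower_bound(s0) + 20L) {
  if (is_terminal_state(s0)) return(1)
  min_search(s0, depth_cap)$count
}

#' Value iteration on the reachable toy state space
#'
#' Runs synchronous value iteration with the simplified Bellman update
#' `V(s) <- max over successors s' of (-1 + V(s'))`, values initialized to
#' -1 on non-terminal states and fixed at 0 on terminal states, sweeping
#' until the largest change falls below `theta`.
#'
#' The state space is restricted to states reachable from `s0` at a depth
#' `d` with `d + (m + n - 1) <= depth_cap` — states from which a complete
#' ARG within the cap is still arithmetically possible (the unrestricted
#' reachable space within a depth cap is orders of magnitude larger and adds
#' only states no minimal genealogy visits).  On this deterministic
#' unit-cost process the converged value of every stored state equals minus
#' its breadth-first distance to the terminal state within the restricted
#' subgraph; [terminal_distances()] computes that oracle independently.
#'
#' @inheritParams min_arg_length
#' @param theta convergence tolerance of the sweep (the dynamics are integer
#'   valued, so any `theta < 1` yields exact values; kept as a parameter for
#'   fidelity to the algorithm).
#' @param max_states hard budget on the number of stored states; exceeding
#'   it raises a resource error naming the budget (never silent truncation).
#' @return An object of class `arg_value_table`: list with `values` (named
#'   numeric, `NA` for states with no in-subgraph path to the MRCA),
#'   `states` (named list of [arg_state()]), `s0`, `depth_cap`, `theta`.
#' @export
value_iteration <- function(s0, depth_cap = length_lower_bound(s0) + 2L,
                            theta = 1e-6, max_states = 2e5) {
  b <- length_lower_bound(s0)
  if (depth_cap < b) {
    stop("depth_cap (", depth_cap, ") is below the event lower bound ", b)
  }
  # BFS over the restricted subgraph
  states <- list()
  depth <- list()
  key0 <- state_key(s0)
  states[[key0]] <- s0
  depth[[key0]] <- 0L
  queue <- list(s0)
  edges <- list()    # key -> character vector of successor keys
  while (length(queue) > 0L) {
    s <- queue[[1L]]; queue <- queue[-1L]
    k <- state_key(s)
    d <- depth[[k]]
    if (is_terminal_state(s)) { edges[[k]] <- character(0L); next }
    succ_keys <- character(0L)
    for (succ in successors(s)) {
      s2 <- succ$state
      k2 <- state_key(s2)
      if (d + 1L + length_lower_bound(s2) > depth_cap) next
      succ_keys <- c(succ_keys, k2)
      if (is.null(states[[k2]])) {
        states[[k2]] <- s2
        depth[[k2]] <- d + 1L
        queue[[length(queue) + 1L]] <- s2
        if (length(states) > max_states) {
          stop("state budget exceeded: more than ", max_states,
               " states within depth_cap ", depth_cap)
        }
      } else if (d + 1L < depth[[k2]]) {
        depth[[k2]] <- d + 1L   # keep the shallowest reachable depth
      }
    }
    edges[[k]] <- unique(succ_keys)
  }

  keys <- names(states)
  terminal <- vapply(states, is_terminal_state, logical(1L))
  V <- ifelse(terminal, 0, -1)
  names(V) <- keys
  # any state with a terminal path inside the subgraph is at distance at
  # most |S| - 1; states without one sink to the floor and are marked NA
  floor_val <- -(length(keys) + 2)
  repeat {
    delta <- 0
    for (k in keys[!terminal]) {
      nxt <- edges[[k]]
      v_new <- if (length(nxt) == 0L) floor_val else max(-1 + V[nxt])
      v_new <- max(v_new, floor_val)
      delta <- max(delta, abs(v_new - V[[k]]))
      V[[k]] <- v_new
    }
    if (delta < theta) break
  }
  V[V <= -(length(keys) + 1)] <- NA_real_
  structure(list(values = V, states = states, edges = edges, s0 = s0,
                 depth_cap = depth_cap, theta = theta),
            class = "arg_value_table")
}

#' @export
print.arg_value_table <- function(x, ...) {
  cat("<arg_value_table> ", length(x$values), " states, depth_cap ",
      x$depth_cap, ", value(s0) = ", x$values[[state_key(x$s0)]], "\n",
      sep = "")
  invisible(x)
}

#' Breadth-first distances to the terminal state
#'
#' Independent oracle for [value_iteration()]: computes, by reverse
#' breadth-first search from the terminal states of the stored subgraph, the
#' exact number of events separating each stored state from the MRCA.  On a
#' converged table, `values == -terminal_distances` state for state.
#'
#' @param vt an `arg_value_table` from [value_iteration()].
#' @return Named numeric vector of distances (`NA` where the MRCA is not
#'   reachable within the stored subgraph).
#' @export
terminal_distances <- function(vt) {
  keys <- names(vt$states)
  # reverse adjacency
  preds <- new.env(parent = emptyenv())
  for (k in keys) {
    for (k2 in vt$edges[[k]]) {
      preds[[k2]] <- c(preds[[k2]], k)
    }
  }
  dist <- rep(NA_real_, length(keys))
  names(dist) <- keys
  frontier <- keys[vapply(vt$states, is_terminal_state, logical(1L))]
  dist[frontier] <- 0
  d <- 0
  while (length(frontier) > 0L) {
    nxt <- character(0L)
    for (k in frontier) {
      for (p in preds[[k]]) {
        if (is.na(dist[[p]])) {
          dist[[p]] <- d + 1
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  dist
}

#' Extract the optimal policy from a value table
#'
#' For every stored non-terminal state with a finite value, the optimal
#' actions are those whose successor value is exactly `value(s) + 1`; under
#' the optimal policy all of them are equally likely.
#'
#' @param vt an `arg_value_table` from [value_iteration()].
#' @return An object of class `arg_policy`: list with `actions` (named list,
#'   state key to list of optimal actions) and the originating table.
#' @export
optimal_policy <- function(vt) {
  acts <- list()
  for (k in names(vt$states)) {
    s <- vt$states[[k]]
    if (is_terminal_state(s) || is.na(vt$values[[k]])) next
    target <- vt$values[[k]] + 1
    best <- list()
    for (succ in successors(s)) {
      k2 <- state_key(succ$state)
      v2 <- if (is.null(vt$states[[k2]])) NA_real_ else vt$values[[k2]]
      if (!is.na(v2) && abs(v2 - target) < 0.5) {
        best[[length(best) + 1L]] <- succ$action
      }
    }
    acts[[k]] <- best
  }
  structure(list(actions = acts, table = vt), class = "arg_policy")
}

#' Optimal actions of a policy at a state
#'
#' @param pol an `arg_policy` from [optimal_policy()].
#' @param s a stored [arg_state()]; an unstored state raises an explicit
#'   miss error.
#' @return List of optimal actions.
#' @export
policy_actions <- function(pol, s) {
  k <- state_key(s)
  a <- pol$actions[[k]]
  if (is.null(a)) stop("state not covered by the policy: ", k)
  a
}

#' Enumerate all minimal genealogies of a sample
#'
#' Depth-first enumeration of the distinct action sequences of exactly the
#' minimal length, pruned by the memoized path counts (a branch is entered
#' only if it completes in the remaining budget), so the total number
#' yielded equals [count_min_args()].
#'
#' @inheritParams min_arg_length
#' @param limit optional cap on the number of genealogies returned.
#' @return List of [new_arg()] objects, each complete and of minimal length.
#' @export
enumerate_min_args <- function(s0, depth_cap = length_lower_bound(s0) + 20L,
                               limit = NULL) {
  if (is_terminal_state(s0)) return(list(new_arg(s0)))
  found <- min_search(s0, depth_cap)
  memo <- found$memo
  out <- vector("list", if (is.null(limit)) found$count else
                          min(limit, found$count))
  n_out <- 0L
  emit <- function(events) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- new_arg(s0, events)
    n_out < length(out)     # FALSE stops the walk
  }
  walk <- function(s, k, events) {
    if (k == 0L) return(emit(events))
    for (succ in successors(s)) {
      if (count_paths(succ$state, k - 1L, memo) > 0) {
        keep <- walk(succ$state, k - 1L,
                     c(events, list(succ$event)))
        if (!keep) return(FALSE)
      }
    }
    TRUE
  }
  walk(s0, found$length, list())
  out[seq_len(n_out)]
}

#' Probability of a minimal ARG under the optimal policy
#'
#' Under the optimal policy all optimal actions of a state are equally
#' likely, so a minimal genealogy has probability equal to the product over
#' its steps of one over the number of optimal actions at that state.  The
#' probabilities of all minimal genealogies of a sample sum to one.
#'
#' @param arg a minimal [new_arg()].
#' @param pol an `arg_policy` covering the visited states.
#' @return The probability; exactly 0 (with a diagnostic attribute) if the
#'   genealogy deviates from the policy at some step.
#' @export
arg_probability <- function(arg, pol) {
  s <- arg$initial_state
  p <- 1
  for (i in seq_along(arg$events)) {
    e <- arg$events[[i]]
    opts <- policy_actions(pol, s)
    keys <- vapply(opts, action_key, character(1L))
    if (!(action_key(e$action) %in% keys)) {
      return(structure(0, deviation_step = i))
    }
    p <- p / length(opts)
    s <- apply_action(s, e$action)$state
  }
  p
}
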