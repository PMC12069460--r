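# shared fixtures: all generated in code, none stored on disk

fix <- example_states()

# a value stub that always prefers larger states: greedy rollouts recombine
# forever and never coalesce back to the MRCA
loop_stub <- arg_value_fn(function(s) -1 / length(s))

# random small fully ancestral sample (seeded by caller)
random_sample <- function(n = 3L, L = 3L) {
  repeat {
    m <- matrix(sample(0:1, n * L, replace = TRUE), nrow = n)
    seqs <- apply(m, 1L, paste, collapse = "")
    ok <- tryCatch({ arg_state(seqs); TRUE }, error = function(e) FALSE)
    if (ok && !is_terminal_state(arg_state(unique(seqs)))) {
      return(arg_state(seqs))
    }
  }
}

# walk a few random legal actions from a state (for property tests)
random_walk_states <- function(s0, steps = 4L) {
  out <- list(s0)
  s <- s0
  for (i in seq_len(steps)) {
    if (is_terminal_state(s)) break
    sc <- successors(s)
    s <- sc[[sample.int(length(sc), 1L)]]$state
    out[[length(out) + 1L]] <- s
  }
  out
}

action_keys <- function(actions) vapply(actions, action_key, character(1L))

event_keys <- function(arg) {
  vapply(arg$events, function(e) action_key(e$action), character(1L))
}
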