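#' Training configuration
#'
#' Bundles the hyperparameters of the gradient Monte Carlo training loop.
#' Defaults are the values used throughout: step size `1e-4` and exploration
#' rate `0.1` for same-sample training, an evaluation cap (`stepmax`) of
#' 300 events beyond which a rollout is classified an infinite-length
#' genealogy, checkpoints every 2000 episodes starting at episode 40000 in
#' the generalization regime, and initial states of `n_tr = 5` sequences
#' drawn without replacement from the training pool.
#'
#' @param alpha step size (> 0).
#' @param epsilon exploration rate in `[0, 1]`.
#' @param episodes number of training episodes.
#' @param train_cap maximum steps of a training episode; episodes hitting
#'   the cap are marked truncated and skipped by the update (their returns
#'   are unobserved).
#' @param stepmax evaluation step cap, see [build_arg()].
#' @param checkpoint_every,checkpoint_start checkpoint cadence for
#'   [train_generalize()].
#' @param n_tr initial-state size for [train_generalize()].
#' @param seed master seed; sub-streams (initialization, exploration and
#'   tie-breaks, pool rotation) are derived from it.
#' @param dedupe keep only one sequence of each type as the initial state in
#'   [train_same_sample()] (the learned policy still applies to the full
#'   sample).
#' @return A list of class `arg_train_config`.
#' @export
train_config <- function(alpha = 1e-4, epsilon = 0.1, episodes = 10000L,
                         train_cap = 10000L, stepmax = 300L,
                         checkpoint_every = 2000L, checkpoint_start = 40000L,
                         n_tr = 5L, seed = 1L, dedupe = TRUE) {
  stopifnot(alpha > 0, epsilon >= 0, epsilon <= 1, stepmax > 0,
            train_cap > 0, episodes >= 0)
  structure(list(alpha = alpha, epsilon = epsilon, episodes = episodes,
                 train_cap = train_cap, stepmax = stepmax,
                 checkpoint_every = checkpoint_every,
                 checkpoint_start = checkpoint_start,
                 n_tr = n_tr, seed = seed, dedupe = dedupe),
            class = "arg_train_config")
}

# per-run memo of successors, keyed by canonical state string; states of
# the toy problems recur constantly during training
make_mdp_cache <- function() new.env(parent = emptyenv())

cached_successors <- function(s, cache = NULL) {
  if (is.null(cache)) return(successors(s))
  k <- state_key(s)
  hit <- cache[[k]]
  if (!is.null(hit)) return(hit$succs)
  cache[[k]] <- list(succs = successors(s))
  cache[[k]]$succs
}

# successor expansion with cached feature matrix: the training loop values
# every successor at every step, so featurization is hoisted out of it
expand_state <- function(s, cache, scheme) {
  k <- state_key(s)
  hit <- cache[[k]]
  if (!is.null(hit) && !is.null(hit$X)) return(hit)
  succs <- if (is.null(hit)) successors(s) else hit$succs
  term <- vapply(succs, function(x) is_terminal_state(x$state), logical(1L))
  X <- vapply(succs, function(x) featurize(x$state, scheme),
              numeric(scheme$c))
  entry <- list(succs = succs, term = term,
                X = matrix(X, nrow = scheme$c))
  cache[[k]] <- entry
  entry
}

# state features for the update step, cached alongside the expansions
cached_features <- function(s, cache, scheme) {
  k <- paste0("f|", state_key(s))
  hit <- cache[[k]]
  if (!is.null(hit)) return(hit)
  cache[[k]] <- featurize(s, scheme)
  cache[[k]]
}

# values of all successor states; terminal successors are exactly 0
successor_values <- function(value_obj, succs, ...) {
  states_value(value_obj, lapply(succs, `[[`, "state"), ...)
}

#' Greedy action selection
#'
#' Evaluates the value estimate on every successor state (terminal
#' successors are valued 0) and returns an action with maximal successor
#' value; exact ties are broken uniformly at random.
#'
#' @param value_obj a value provider for [state_value()].
#' @param s a non-terminal [arg_state()].
#' @param seed optional seed for the tie-break draw.
#' @param cache optional successor cache (internal use by the training
#'   loop).
#' @return A list `(action, state, event, value)` for the selected step.
#' @export
select_action_greedy <- function(value_obj, s, seed = NULL, cache = NULL) {
  if (!is.null(cache) && inherits(value_obj, "arg_value_net")) {
    entry <- expand_state(s, cache, value_obj$scheme)
    succs <- entry$succs
    vals <- net_forward(value_obj, entry$X)
    vals[entry$term] <- 0
  } else {
    succs <- cached_successors(s, cache)
    vals <- successor_values(value_obj, succs)
  }
  best <- which(vals >= max(vals) - 1e-12)
  pick <- if (length(best) == 1L) best else
    with_seed(seed, best[sample.int(length(best), 1L)])
  c(succs[[pick]], list(value = vals[[pick]]))
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random legal action, otherwise the
#' greedy choice of [select_action_greedy()].
#'
#' @inheritParams select_action_greedy
#' @param epsilon exploration rate in `[0, 1]`.
#' @export
select_action_epsilon <- function(value_obj, s, epsilon, seed = NULL,
                                  cache = NULL) {
  with_seed(seed, {
    if (epsilon > 0 && stats::runif(1L) < epsilon) {
      succs <- cached_successors(s, cache)
      pick <- sample.int(length(succs), 1L)
      c(succs[[pick]], list(value = NA_real_))
    } else {
      select_action_greedy(value_obj, s, seed = NULL, cache = cache)
    }
  })
}

#' Generate one training episode
#'
#' Rolls the epsilon-greedy behavior policy from `s0` until the MRCA is
#' reached or `cfg$train_cap` steps have been taken.  Returns the visited
#' states, the actions, a terminal flag and (for completed episodes) the
#' returns `G_t = -(T - t)`.
#'
#' @param s0 a non-terminal [arg_state()].
#' @param value_obj a value provider (typically the network being trained).
#' @param cfg an [train_config()].
#' @param cache optional successor cache.
#' @param seed optional seed (the training loop seeds once per run
#'   instead).
#' @return A list of class `arg_trajectory`: `states` (length T + 1),
#'   `actions`, `events`, `terminal`, `returns`.
#' @export
generate_episode <- function(s0, value_obj, cfg, cache = NULL, seed = NULL) {
  with_seed(seed, {
    states <- list(s0)
    actions <- list()
    events <- list()
    s <- s0
    while (!is_terminal_state(s) && length(actions) < cfg$train_cap) {
      step <- select_action_epsilon(value_obj, s, cfg$epsilon, cache = cache)
      actions[[length(actions) + 1L]] <- step$action
      events[[length(events) + 1L]] <- step$event
      s <- step$state
      states[[length(states) + 1L]] <- s
    }
    terminal <- is_terminal_state(s)
    T_len <- length(actions)
    structure(list(states = states, actions = actions, events = events,
                   terminal = terminal,
                   returns = if (terminal) -(T_len - seq_len(T_len) + 1L)
                             else NULL),
              class = "arg_trajectory")
  })
}

#' Train a value network on one fixed sample
#'
#' Runs `cfg$episodes` gradient Monte Carlo episodes, all starting from the
#' (optionally deduplicated) sample, applying [mc_update()] after every
#' completed episode.  The per-episode length history supports
#' moving-average learning curves.
#'
#' @param sample an [arg_state()] of fully ancestral sequences.
#' @param cfg an [train_config()].
#' @param scheme feature scheme; defaults to blocks of
#'   `min(3, L)` markers with one-step overlap on the sample's length.
#' @param net optional pre-initialized network to continue training.
#' @return A list of class `arg_training`: `net`, `history` (per-episode
#'   lengths), `truncated` (logical per episode), `cfg`, `s0`.
#' @export
train_same_sample <- function(sample, cfg = train_config(), scheme = NULL,
                              net = NULL) {
  L <- nchar(sample[[1L]])
  if (is.null(scheme)) scheme <- make_scheme(L, min(3L, L), 1L)
  if (is.null(net)) net <- init_network(scheme, derive_seed(cfg$seed, 1L))
  s0 <- if (cfg$dedupe) arg_state(unique(unclass(sample))) else sample
  cache <- make_mdp_cache()
  history <- integer(cfg$episodes)
  truncated <- logical(cfg$episodes)
  with_seed(derive_seed(cfg$seed, 2L), {
    for (ep in seq_len(cfg$episodes)) {
      traj <- generate_episode(s0, net, cfg, cache = cache)
      history[ep] <- length(traj$actions)
      truncated[ep] <- !traj$terminal
      net <- mc_update(net, traj, cfg$alpha, cache = cache)
    }
  })
  structure(list(net = net, history = history, truncated = truncated,
                 cfg = cfg, s0 = s0),
            class = "arg_training")
}

#' Train with rotating initial samples for generalization
#'
#' At the start of every episode the initial state is the next `cfg$n_tr`
#' sequences of a seeded without-replacement stream over the training pool;
#' when fewer than `n_tr` sequences remain the leftover is discarded and the
#' full pool is reshuffled.  Initial states keep duplicate sequences (with
#' small `n_tr` the duplicates teach the agent when to coalesce).  Model
#' checkpoints are kept at every pool exhaustion and every
#' `cfg$checkpoint_every` episodes from `cfg$checkpoint_start`, and at the
#' final episode.
#'
#' @param pool character vector (or matrix rows via
#'   [haplotypes_to_states()] conventions) of fully ancestral sequences,
#'   `length(pool) >= n_tr`.
#' @param cfg an [train_config()].
#' @param scheme feature scheme (defaults as in [train_same_sample()]).
#' @return A list of class `arg_training`: `net`, `checkpoints` (list of
#'   `(episode, net)`), `history`, `truncated`, `cfg`.
#' @export
train_generalize <- function(pool, cfg = train_config(), scheme = NULL) {
  if (is.matrix(pool)) pool <- apply(pool, 1L, paste, collapse = "")
  if (length(pool) < cfg$n_tr) {
    stop("pool holds ", length(pool), " sequences; n_tr = ", cfg$n_tr,
         " cannot be drawn")
  }
  L <- nchar(pool[1L])
  if (is.null(scheme)) scheme <- make_scheme(L, min(3L, L), 1L)
  net <- init_network(scheme, derive_seed(cfg$seed, 1L))
  cache <- make_mdp_cache()
  history <- integer(cfg$episodes)
  truncated <- logical(cfg$episodes)
  checkpoints <- list()
  keep <- function(ep) {
    checkpoints[[length(checkpoints) + 1L]] <<- list(episode = ep, net = net)
  }
  with_seed(derive_seed(cfg$seed, 3L), {
    stream <- sample(pool)
    pos <- 1L
    for (ep in seq_len(cfg$episodes)) {
      if (pos + cfg$n_tr - 1L > length(stream)) {
        keep(ep - 1L)                       # pool exhausted: checkpoint
        stream <- sample(pool)              # discard remainder, refill
        pos <- 1L
      }
      s0 <- arg_state(stream[pos:(pos + cfg$n_tr - 1L)])
      pos <- pos + cfg$n_tr
      traj <- generate_episode(s0, net, cfg, cache = cache)
      history[ep] <- length(traj$actions)
      truncated[ep] <- !traj$terminal
      net <- mc_update(net, traj, cfg$alpha, cache = cache)
      if (ep >= cfg$checkpoint_start &&
          (ep - cfg$checkpoint_start) %% cfg$checkpoint_every == 0L) {
        keep(ep)
      }
    }
    if (cfg$episodes > 0L) keep(cfg$episodes)
  })
  structure(list(net = net, checkpoints = checkpoints, history = history,
                 truncated = truncated, cfg = cfg),
            class = "arg_training")
}

#' Build an ARG by greedy rollout
#'
#' Rolls the greedy policy of a value provider (network, exact table,
#' ensemble, stub) from the sample, with seeded tie-breaks.  A rollout that
#' has not reached the MRCA within `stepmax` events is classified an
#' infinite-length genealogy and returned as an `arg_infinite` marker
#' carrying the partial ARG.
#'
#' An ensemble with method `"majority"` steps by per-state member vote
#' ([ensemble_action()]); method `"minimum"` delegates to
#' [ensemble_build_min()]; method `"mean"` (and every non-ensemble
#' provider) steps greedily on the estimated value.
#'
#' @param sample an [arg_state()].
#' @param value_obj a value provider.
#' @param stepmax event cap (default 300).
#' @param seed optional seed for tie-breaks.
#' @return An [new_arg()] or an `arg_infinite` marker (test with
#'   [is_infinite_arg()]; the partial ARG sits in its `partial` field).
#' @export
build_arg <- function(sample, value_obj, stepmax = 300L, seed = NULL) {
  if (inherits(value_obj, "arg_ensemble")) {
    if (value_obj$method == "minimum") {
      return(ensemble_build_min(value_obj, sample, stepmax, seed))
    }
    if (value_obj$method == "majority") {
      return(rollout(sample, stepmax, seed, function(s) {
        ensemble_action(value_obj, s)
      }))
    }
  }
  rollout(sample, stepmax, seed, function(s) {
    select_action_greedy(value_obj, s)
  })
}

rollout <- function(sample, stepmax, seed, step_fn) {
  with_seed(seed, {
    events <- list()
    s <- sample
    while (!is_terminal_state(s) && length(events) < stepmax) {
      step <- step_fn(s)
      events[[length(events) + 1L]] <- step$event
      s <- step$state
    }
    if (!is_terminal_state(s)) {
      structure(list(partial = new_arg(sample, events), stepmax = stepmax),
                class = "arg_infinite")
    } else {
      new_arg(sample, events)
    }
  })
}

#' Test for the infinite-length marker
#'
#' @param x result of [build_arg()] or [ensemble_build_min()].
#' @return `TRUE` if the rollout hit the step cap.
#' @export
is_infinite_arg <- function(x) inherits(x, "arg_infinite")

#' @export
print.arg_infinite <- function(x, ...) {
  cat("<arg_infinite> rollout exceeded stepmax =", x$stepmax, "\n")
  invisible(x)
}

#' Softened final policy over the g best actions
#'
#' Instead of the deterministic greedy policy, keeps the `g` actions with
#' the highest successor values and assigns them softmax probabilities at
#' the given temperature.  With `g = 1` (or temperature near 0) this
#' recovers the greedy choice; with `g = |A(s)|` and equal values it is
#' uniform.  The softmax form is this package's choice of distribution; any
#' positive temperature yields a proper distribution over the kept actions.
#'
#' @param value_obj a value provider.
#' @param s a non-terminal [arg_state()].
#' @param g number of best actions kept, `>= 1` (capped at the number of
#'   legal actions).
#' @param temperature softmax temperature, > 0.
#' @return A list with `actions` (the kept step candidates) and `probs`
#'   (summing to 1).
#' @export
soften_policy <- function(value_obj, s, g, temperature = 1) {
  if (g < 1L) stop("g must be at least 1")
  if (temperature <= 0) stop("temperature must be positive")
  succs <- successors(s)
  vals <- successor_values(value_obj, succs)
  ord <- order(vals, decreasing = TRUE)
  keep <- ord[seq_len(min(g, length(ord)))]
  z <- vals[keep] / temperature
  w <- exp(z - max(z))
  list(actions = succs[keep], values = vals[keep], probs = w / sum(w))
}
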