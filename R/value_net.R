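#' Feed-forward value-function approximator
#'
#' The state value is approximated by a small fully connected network on the
#' block feature vector: `c` inputs, one hidden layer of `floor(c / 2)` ReLU
#' units, and a single output unit with activation `-ReLU` so that the
#' estimate is never positive (every step carries reward -1, so true values
#' are non-positive).  The parameter count is
#' `d = (c + 1) * floor(c / 2) + (floor(c / 2) + 1)`; with the default
#' 10-SNP scheme (`c = 216`) this gives `d = 23545`.
#'
#' Terminal states are valued exactly 0 without consulting the network and
#' are excluded from updates: the tabular convention fixes V = 0 on
#' terminals, and without it a greedy agent whose outputs hover near 0 has
#' no reason to prefer finishing.  Pass `terminal_zero = FALSE` to
#' [state_value()] to see the raw network output instead.
#'
#' @param scheme an [make_scheme()] feature scheme.
#' @param seed integer; initialization is scaled-uniform per layer fan-in
#'   (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`) and bit-reproducible: the same
#'   (scheme, seed) always yields identical weights.  The output bias
#'   starts at +1: the initial estimate is then close to -1 for every state
#'   (mirroring the tabular sweep's V = -1 initialization) and the output
#'   unit starts on the active side of its ReLU — started on the flat side
#'   its gradient is zero everywhere and the network can never learn.
#' @return An object of class `arg_value_net` with fields `W1`
#'   (`h x c` hidden weights), `b1`, `w2`, `b2`, `scheme`, `seed`,
#'   `episodes_trained`.
#' @examples
#' net <- init_network(make_scheme(4, 2, 1), seed = 1)
#' net_n_params(net)
#' @export
init_network <- function(scheme, seed = 1L) {
  h <- scheme$c %/% 2L
  lim1 <- 1 / sqrt(scheme$c)
  lim2 <- 1 / sqrt(h)
  with_seed(seed, structure(list(
    W1 = matrix(stats::runif(h * scheme$c, -lim1, lim1), nrow = h),
    b1 = stats::runif(h, -lim1, lim1),
    w2 = stats::runif(h, -lim2, lim2),
    b2 = 1,
    scheme = scheme, seed = as.numeric(seed), episodes_trained = 0L
  ), class = "arg_value_net"))
}

#' @export
print.arg_value_net <- function(x, ...) {
  cat("<arg_value_net> scheme (L=", x$scheme$L, ", B=", x$scheme$B,
      ", o=", x$scheme$o, "), ", net_n_params(x), " parameters, ",
      x$episodes_trained, " episodes trained\n", sep = "")
  invisible(x)
}

#' Parameter count of a value network
#'
#' @param net an [init_network()] object.
#' @return `d = (c + 1) * floor(c / 2) + (floor(c / 2) + 1)`.
#' @export
net_n_params <- function(net) {
  length(net$W1) + length(net$b1) + length(net$w2) + length(net$b2)
}

# forward pass on a feature matrix X (c x m): returns length-m values
net_forward <- function(net, X) {
  Z1 <- net$W1 %*% X + net$b1
  A1 <- Z1 * (Z1 > 0)
  z2 <- drop(crossprod(A1, net$w2)) + net$b2
  -pmax(z2, 0)
}

#' Estimated value of a state
#'
#' Generic over value-providing objects: value networks, exact value tables
#' ([value_iteration()]), ensembles ([arg_ensemble()]) and plain function
#' stubs ([arg_value_fn()]).  Every method returns exactly 0 on terminal
#' states.
#'
#' @param object a value provider.
#' @param s an [arg_state()].
#' @param ... passed to methods.
#' @return A non-positive scalar.
#' @export
state_value <- function(object, s, ...) UseMethod("state_value")

#' @rdname state_value
#' @param terminal_zero bypass the network on terminal states (default).
#' @export
state_value.arg_value_net <- function(object, s, terminal_zero = TRUE, ...) {
  if (terminal_zero && is_terminal_state(s)) return(0)
  x <- featurize(s, object$scheme)
  net_forward(object, matrix(x, ncol = 1L))
}

#' @rdname state_value
#' @export
state_value.arg_value_table <- function(object, s, ...) {
  k <- state_key(s)
  if (is.null(object$states[[k]])) stop("state not in value table: ", k)
  object$values[[k]]
}

#' Wrap a plain function as a value provider
#'
#' Mainly for tests and diagnostics: `fn(state)` must return a scalar value.
#'
#' @param fn function of one [arg_state()] argument.
#' @return An object usable with [state_value()] and the rollout functions.
#' @export
arg_value_fn <- function(fn) structure(list(fn = fn), class = "arg_value_fn")

#' @rdname state_value
#' @export
state_value.arg_value_fn <- function(object, s, ...) {
  if (is_terminal_state(s)) return(0)
  object$fn(s)
}

# batched values over a list of states (used by the greedy step); networks
# get one matrix forward pass, other providers fall back to a loop.  For
# exact value tables, states outside the stored subgraph cannot lie on a
# within-cap path, so action selection ranks them below every stored state
# (-Inf) instead of failing the whole rollout.
states_value <- function(object, states, ...) {
  if (inherits(object, "arg_value_table")) {
    return(vapply(states, function(s) {
      k <- state_key(s)
      if (is.null(object$states[[k]]) || is.na(object$values[[k]])) {
        -Inf
      } else {
        object$values[[k]]
      }
    }, numeric(1L)))
  }
  if (inherits(object, "arg_value_net")) {
    terminal <- vapply(states, is_terminal_state, logical(1L))
    vals <- numeric(length(states))
    if (any(!terminal)) {
      X <- vapply(states[!terminal], featurize, numeric(object$scheme$c),
                  scheme = object$scheme)
      vals[!terminal] <- net_forward(object, matrix(X, nrow = object$scheme$c))
    }
    vals
  } else {
    vapply(states, function(s) state_value(object, s, ...), numeric(1L))
  }
}

#' Analytic gradient of the value estimate
#'
#' Partial derivatives of the network output with respect to the flattened
#' parameter vector `w = c(W1 (column-major), b1, w2, b2)`.  The ReLU
#' derivative at a kink is taken as 0.  Agrees with central finite
#' differences to at least 1e-5 relative error (asserted in the test suite).
#'
#' @param net an [init_network()] object.
#' @param s a non-terminal [arg_state()]; for a terminal state a zero vector
#'   is returned with a warning (no update is defined there).
#' @return Numeric vector of length `net_n_params(net)`.
#' @export
net_gradient <- function(net, s) {
  if (is_terminal_state(s)) {
    warning("gradient requested at a terminal state; returning zeros")
    return(numeric(net_n_params(net)))
  }
  x <- featurize(s, net$scheme)
  g <- net_gradient_parts(net, x)
  c(as.vector(g$W1), g$b1, g$w2, g$b2)
}

# gradient pieces in parameter shapes, for the in-place training update
net_gradient_parts <- function(net, x) {
  z1 <- drop(net$W1 %*% x) + net$b1
  a1 <- z1 * (z1 > 0)
  z2 <- sum(net$w2 * a1) + net$b2
  dz2 <- if (z2 > 0) -1 else 0        # d(-ReLU)/dz2
  dh <- dz2 * net$w2 * (z1 > 0)       # back through the hidden ReLU
  list(W1 = outer(dh, x), b1 = dh, w2 = dz2 * a1, b2 = dz2)
}

#' Gradient Monte Carlo update from one completed episode
#'
#' Applies the every-visit Monte Carlo update
#' `w <- w + alpha * (G_t - v(S_t, w)) * grad v(S_t, w)` sequentially for
#' `t = 0, ..., T - 1`, each step using the weights as already modified by
#' the earlier steps of the same episode.  With unit -1 rewards the return
#' is `G_t = -(T - t)` and `G_T = 0`.  Truncated (incomplete) episodes are
#' skipped: their returns are not observed, so no unbiased target exists.
#'
#' @param net an [init_network()] object.
#' @param trajectory a trajectory from [generate_episode()] (or any list
#'   with elements `states` and `terminal`).
#' @param alpha step size, > 0.
#' @param cache optional feature cache shared with the episode generator.
#' @return The updated network (with `episodes_trained` incremented when an
#'   update was applied).
#' @export
mc_update <- function(net, trajectory, alpha, cache = NULL) {
  stopifnot(alpha >= 0)
  if (!isTRUE(trajectory$terminal)) return(net)
  states <- trajectory$states
  T_len <- length(states) - 1L
  if (T_len < 1L) return(net)
  for (t in seq_len(T_len)) {          # R index t = time t - 1
    s <- states[[t]]
    x <- if (is.null(cache)) featurize(s, net$scheme) else
      cached_features(s, cache, net$scheme)
    G <- -(T_len - (t - 1L))
    v <- net_forward(net, matrix(x, ncol = 1L))
    g <- net_gradient_parts(net, x)
    step <- alpha * (G - v)
    net$W1 <- net$W1 + step * g$W1
    net$b1 <- net$b1 + step * g$b1
    net$w2 <- net$w2 + step * g$w2
    net$b2 <- net$b2 + step * g$b2
  }
  net$episodes_trained <- net$episodes_trained + 1L
  net
}

#' Save / load a value network
#'
#' Portable JSON container with explicit shapes; the round trip is
#' bit-exact on weights, scheme and seed (full IEEE precision is written).
#'
#' @param net an [init_network()] object.
#' @param path file path.
#' @return `load_network()` returns the reconstructed network; a corrupted
#'   file or a shape/scheme mismatch is rejected with an error.
#' @export
save_network <- function(net, path) {
  # weights are written as %.17g strings: 17 significant digits round-trip
  # IEEE doubles bit-exactly, which plain JSON number formatting does not
  payload <- list(
    container = "arg_value_net",
    scheme = list(L = net$scheme$L, B = net$scheme$B, o = net$scheme$o),
    shapes = list(W1 = dim(net$W1), b1 = length(net$b1),
                  w2 = length(net$w2), b2 = length(net$b2)),
    W1 = sprintf("%.17g", as.vector(net$W1)),
    b1 = sprintf("%.17g", net$b1),
    w2 = sprintf("%.17g", net$w2),
    b2 = sprintf("%.17g", net$b2),
    seed = net$seed, episodes_trained = net$episodes_trained
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @param scheme optional [make_scheme()]; when given, the file must match
#'   it or loading is rejected.
#' @export
load_network <- function(path, scheme = NULL) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot parse network file ", path, ": ",
                             conditionMessage(e))
                      })
  if (!identical(payload$container, "arg_value_net")) {
    stop("not a value-network file: ", path)
  }
  sch <- make_scheme(payload$scheme$L, payload$scheme$B, payload$scheme$o)
  if (!is.null(scheme) &&
      !identical(unclass(sch)[c("L", "B", "o")],
                 unclass(scheme)[c("L", "B", "o")])) {
    stop("network scheme (L=", sch$L, ") does not match the requested ",
         "scheme (L=", scheme$L, ")")
  }
  shp <- payload$shapes
  if (length(payload$W1) != prod(shp$W1) ||
      shp$W1[1L] != sch$c %/% 2L || shp$W1[2L] != sch$c) {
    stop("corrupt network file: weight shapes do not match the scheme")
  }
  structure(list(
    W1 = matrix(as.numeric(payload$W1), nrow = shp$W1[1L],
                ncol = shp$W1[2L]),
    b1 = as.numeric(payload$b1), w2 = as.numeric(payload$w2),
    b2 = as.numeric(payload$b2),
    scheme = sch, seed = as.numeric(payload$seed),
    episodes_trained = as.integer(payload$episodes_trained)
  ), class = "arg_value_net")
}
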