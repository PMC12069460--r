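#' Ensemble of value networks
#'
#' Combines `M` independently trained agents into one policy by one of
#' three methods: `"mean"` averages the member value estimates and acts
#' greedily on the average; `"majority"` lets each member vote its greedy
#' action at every state of a single joint rollout and follows the
#' plurality; `"minimum"` builds one ARG per member and keeps the shortest.
#'
#' @param members list of value providers (typically `arg_value_net`), at
#'   least one.
#' @param method `"mean"`, `"majority"` or `"minimum"`.
#' @return An object of class `arg_ensemble` usable with [build_arg()],
#'   [state_value()] (mean method) and [evaluate_policy()].
#' @export
arg_ensemble <- function(members, method = c("mean", "majority", "minimum")) {
  method <- match.arg(method)
  if (length(members) < 1L) stop("an ensemble needs at least one member")
  structure(list(members = members, method = method), class = "arg_ensemble")
}

#' @export
print.arg_ensemble <- function(x, ...) {
  cat("<arg_ensemble>", length(x$members), "members, method", x$method, "\n")
  invisible(x)
}

#' @rdname state_value
#' @export
state_value.arg_ensemble <- function(object, s, ...) {
  if (is_terminal_state(s)) return(0)
  mean(vapply(object$members, function(m) state_value(m, s), numeric(1L)))
}

#' Majority-vote action of an ensemble
#'
#' Each member votes its greedy action (member-level ties broken at
#' random); the plurality action is taken, with plurality ties again broken
#' at random.
#'
#' @param ens an [arg_ensemble()] (any method; the vote itself is what the
#'   `"majority"` rollout uses per state).
#' @param s a non-terminal [arg_state()].
#' @param seed optional seed.
#' @return A step list `(action, state, event)` as in
#'   [select_action_greedy()].
#' @export
ensemble_action <- function(ens, s, seed = NULL) {
  with_seed(seed, {
    steps <- lapply(ens$members, function(m) select_action_greedy(m, s))
    keys <- vapply(steps, function(st) action_key(st$action), character(1L))
    tab <- table(keys)
    winners <- names(tab)[tab == max(tab)]
    win <- if (length(winners) == 1L) winners else
      winners[sample.int(length(winners), 1L)]
    steps[[match(win, keys)]]
  })
}

#' Minimum-method ensemble construction
#'
#' Builds one greedy ARG per member and returns the shortest finite one;
#' the result is infinite only when every member's rollout is.  By
#' construction the returned length never exceeds any member's length.
#'
#' @param ens an [arg_ensemble()].
#' @param sample an [arg_state()].
#' @param stepmax event cap per member rollout.
#' @param seed optional master seed (one sub-seed per member).
#' @return An [new_arg()] or an `arg_infinite` marker.
#' @export
ensemble_build_min <- function(ens, sample, stepmax = 300L, seed = NULL) {
  best <- NULL
  for (i in seq_along(ens$members)) {
    sub <- if (is.null(seed)) NULL else derive_seed(seed, i)
    a <- rollout(sample, stepmax, sub, local({
      m <- ens$members[[i]]
      function(s) select_action_greedy(m, s)
    }))
    if (!is_infinite_arg(a) &&
        (is.null(best) || a$length < best$length)) {
      best <- a
    }
  }
  if (is.null(best)) {
    structure(list(partial = NULL, stepmax = stepmax), class = "arg_infinite")
  } else {
    best
  }
}

#' Evaluate a policy on a set of samples
#'
#' Builds one greedy ARG per sample and aggregates the lengths: the
#' proportion of infinite-length genealogies (rollouts hitting `stepmax`)
#' and the mean length over the finite ones.
#'
#' @param value_obj a value provider or [arg_ensemble()].
#' @param samples list of [arg_state()] samples.
#' @param stepmax event cap.
#' @param seed optional master seed (one sub-seed per sample).
#' @return A list of class `arg_eval_report`: `lengths` (`Inf` where
#'   infinite), `proportion_infinite`, `mean_finite`, `K`, `stepmax`.
#' @export
evaluate_policy <- function(value_obj, samples, stepmax = 300L, seed = NULL) {
  lengths <- vapply(seq_along(samples), function(i) {
    sub <- if (is.null(seed)) NULL else derive_seed(seed, 1000L + i)
    a <- build_arg(samples[[i]], value_obj, stepmax, sub)
    if (is_infinite_arg(a)) Inf else a$length
  }, numeric(1L))
  structure(list(lengths = lengths,
                 proportion_infinite = mean(!is.finite(lengths)),
                 mean_finite = if (any(is.finite(lengths)))
                   mean(lengths[is.finite(lengths)]) else NaN,
                 K = length(samples), stepmax = stepmax),
            class = "arg_eval_report")
}

#' @export
print.arg_eval_report <- function(x, ...) {
  cat("<arg_eval_report> K=", x$K, ", infinite ",
      round(100 * x$proportion_infinite, 1), "%, mean finite length ",
      round(x$mean_finite, 2), "\n", sep = "")
  invisible(x)
}

#' Rank evaluation reports by the selection rule
#'
#' The best model is the one with the smallest proportion of
#' infinite-length genealogies; among equals, the one with the smallest
#' mean finite length; remaining ties go to the earliest candidate.
#'
#' @param reports list of `arg_eval_report`s.
#' @return Index of the best report.
#' @export
best_report_index <- function(reports) {
  props <- vapply(reports, `[[`, numeric(1L), "proportion_infinite")
  means <- vapply(reports, `[[`, numeric(1L), "mean_finite")
  means[is.nan(means)] <- Inf
  ord <- order(props, means)       # stable: earliest wins remaining ties
  ord[1L]
}

#' Select the best checkpoint on a validation set
#'
#' Evaluates every checkpoint on the validation samples and applies the
#' lexicographic (infinite proportion, mean finite length) rule of
#' [best_report_index()].
#'
#' @param checkpoints list of `(episode, net)` checkpoints from
#'   [train_generalize()].
#' @param validation_samples list of [arg_state()] samples.
#' @param stepmax event cap.
#' @param seed optional seed (the same sub-seeds are used for every
#'   checkpoint, so the comparison is paired).
#' @return A list: the winning `checkpoint`, its `report`, and all
#'   `reports`.
#' @export
select_best_checkpoint <- function(checkpoints, validation_samples,
                                   stepmax = 300L, seed = NULL) {
  if (length(checkpoints) < 1L) stop("no checkpoints to select from")
  reports <- lapply(checkpoints, function(cp) {
    evaluate_policy(cp$net, validation_samples, stepmax, seed)
  })
  i <- best_report_index(reports)
  list(checkpoint = checkpoints[[i]], report = reports[[i]],
       index = i, reports = reports)
}
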