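#' Coalesce two sequences
#'
#' Backwards in time, two lineages may merge when their ancestral material is
#' identical wherever both carry it.  The merged sequence carries, at every
#' position, the ancestral symbol if either input has one, and `*` otherwise.
#' Sequences with disjoint ancestral material are compatible (the agreement
#' condition is vacuous); pass `allow_disjoint = FALSE` for the stricter rule
#' requiring at least one overlapping ancestral position.
#'
#' @param a,b sequences (strings over `{0,1,*}`) of equal length.
#' @param allow_disjoint permit coalescence of sequences whose ancestral
#'   material does not overlap (default `TRUE`).
#' @return The merged sequence, or `NULL` if the pair is incompatible.
#' @examples
#' coalesce_result("1000", "1***")  # "1000"
#' coalesce_result("0100", "0011")  # NULL: marker 2 disagrees
#' @export
coalesce_result <- function(a, b, allow_disjoint = TRUE) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  both <- x != "*" & y != "*"
  if (!allow_disjoint && !any(both)) return(NULL)
  if (any(x[both] != y[both])) return(NULL)
  out <- ifelse(x == "*", y, x)
  paste(out, collapse = "")
}

new_action <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "arg_action")
}

#' @export
print.arg_action <- function(x, ...) {
  cat("<arg_action>", action_key(x), "\n")
  invisible(x)
}

#' Canonical string key of an action
#'
#' @param a an action as returned by [legal_actions()].
#' @return A single string identifying the action.
#' @export
action_key <- function(a) {
  switch(a$kind,
    coalescence   = paste("C", a$pair[1L], a$pair[2L]),
    mutation      = paste("M", a$seq, a$marker),
    recombination = paste("R", a$seq, a$gap),
    stop("unknown action kind: ", a$kind)
  )
}

#' Enumerate the legal actions of a state
#'
#' Actions are defined at the level of sequence *types*:
#' \itemize{
#'   \item a coalescence for every unordered pair of compatible types (a type
#'     present in two or more copies may coalesce with itself);
#'   \item a mutation `(type, marker)` whenever exactly one sequence copy in
#'     the state carries the derived allele `1` at that marker (infinite
#'     sites: one mutation event per marker over the whole genealogy);
#'   \item a recombination `(type, gap)` for every type other than the fully
#'     ancestral all-zero sequence (the MRCA itself), at every gap `g`
#'     (between markers `g` and `g + 1`) with ancestral material strictly on
#'     both sides, so no all-`*` fragment can ever be produced.
#' }
#' The result is in a deterministic canonical order: coalescences
#' (lexicographic by type pair), then mutations (by type, then marker), then
#' recombinations (by type, then gap), which makes seeded tie-breaking
#' reproducible.
#'
#' @param s an [arg_state()].
#' @param allow_disjoint see [coalesce_result()].
#' @param recomb_exclude which sequences are never recombined: `"mrca"`
#'   (default) excludes only the fully ancestral all-zero sequence;
#'   `"ancestral-zero"` also excludes partially ancestral sequences whose
#'   ancestral part is all `0`.
#' @return A list of action objects (empty for a terminal state).  A
#'   non-terminal state with no legal action raises a dead-end error
#'   (believed unreachable; diagnostic only).
#' @examples
#' s0 <- arg_state(c("0100", "1000", "1010", "0011"))
#' length(legal_actions(s0))  # 14: 2 mutations + 12 recombinations
#' @export
legal_actions <- function(s, allow_disjoint = TRUE,
                          recomb_exclude = c("mrca", "ancestral-zero")) {
  recomb_exclude <- match.arg(recomb_exclude)
  if (is_terminal_state(s)) return(list())
  L <- nchar(s[[1L]])
  types <- unique(unclass(s))           # already sorted (state is canonical)
  counts <- table(unclass(s))
  acts <- list()

  # coalescences: unordered pairs of types, plus duplicated types
  nt <- length(types)
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      if (i == j && counts[[types[i]]] < 2L) next
      if (!is.null(coalesce_result(types[i], types[j], allow_disjoint))) {
        acts[[length(acts) + 1L]] <-
          new_action("coalescence", pair = c(types[i], types[j]))
      }
    }
  }

  # mutations: derived allele on exactly one sequence copy
  m <- seq_matrix(s)
  for (t in types) {
    chars <- strsplit(t, "", fixed = TRUE)[[1L]]
    for (l in seq_len(L)) {
      if (chars[l] == "1" && sum(m[, l] == "1") == 1L) {
        acts[[length(acts) + 1L]] <- new_action("mutation", seq = t, marker = l)
      }
    }
  }

  # recombinations: ancestral material required strictly on both sides
  for (t in types) {
    if (recomb_exclude == "mrca") {
      if (!grepl("[1*]", t)) next                   # the full all-zero MRCA
    } else {
      if (!grepl("1", t)) next                      # ancestral part all zero
    }
    anc <- which(strsplit(t, "", fixed = TRUE)[[1L]] != "*")
    if (length(anc) < 2L) next
    for (g in seq_len(L - 1L)) {
      if (any(anc <= g) && any(anc > g)) {
        acts[[length(acts) + 1L]] <- new_action("recombination", seq = t, gap = g)
      }
    }
  }

  if (length(acts) == 0L) {
    stop("dead end: non-terminal state ", state_key(s), " has no legal action")
  }
  acts
}

#' Apply an action to a state
#'
#' Coalescence replaces the two participating copies by their merge (one
#' fewer sequence); mutation reverts the derived allele at the stated marker
#' to `0` (same count); recombination splits the sequence at the gap into a
#' left fragment (`*` on the right) and a right fragment (`*` on the left),
#' one more sequence.  Every applied action corresponds to one event of the
#' genealogy and carries a reward of -1 in the decision process.
#'
#' @param s an [arg_state()].
#' @param a an action from [legal_actions()].
#' @inheritParams legal_actions
#' @return A list with elements `state` (the successor [arg_state()]) and
#'   `event` (an `arg_event`: the action plus the consumed and produced
#'   sequence types).  Illegal actions are rejected with a reason.
#' @export
apply_action <- function(s, a, allow_disjoint = TRUE) {
  seqs <- unclass(s)
  L <- nchar(seqs[1L])
  if (a$kind == "coalescence") {
    i <- match(a$pair[1L], seqs)
    if (is.na(i)) stop("illegal coalescence: ", a$pair[1L], " not in state")
    rest <- seqs[-i]
    j <- match(a$pair[2L], rest)
    if (is.na(j)) stop("illegal coalescence: ", a$pair[2L],
                       " not present (twice, if coalescing a type with itself)")
    merged <- coalesce_result(a$pair[1L], a$pair[2L], allow_disjoint)
    if (is.null(merged)) stop("illegal coalescence: incompatible pair ",
                              a$pair[1L], " / ", a$pair[2L])
    out <- c(rest[-j], merged)
    consumed <- a$pair
    produced <- merged
  } else if (a$kind == "mutation") {
    i <- match(a$seq, seqs)
    if (is.na(i)) stop("illegal mutation: ", a$seq, " not in state")
    if (substr(a$seq, a$marker, a$marker) != "1") {
      stop("illegal mutation: no derived allele at marker ", a$marker)
    }
    carriers <- sum(substr(seqs, a$marker, a$marker) == "1")
    if (carriers != 1L) {
      stop("illegal mutation: derived allele at marker ", a$marker,
           " present on ", carriers, " copies (must be exactly one)")
    }
    reverted <- a$seq
    substr(reverted, a$marker, a$marker) <- "0"
    out <- c(seqs[-i], reverted)
    consumed <- a$seq
    produced <- reverted
  } else if (a$kind == "recombination") {
    i <- match(a$seq, seqs)
    if (is.na(i)) stop("illegal recombination: ", a$seq, " not in state")
    if (!grepl("[1*]", a$seq)) {
      stop("illegal recombination: the all-zero MRCA sequence is never split")
    }
    g <- a$gap
    if (g < 1L || g >= L) stop("illegal recombination: invalid breakpoint ", g)
    anc <- which(strsplit(a$seq, "", fixed = TRUE)[[1L]] != "*")
    if (!any(anc <= g) || !any(anc > g)) {
      stop("illegal recombination: breakpoint ", g,
           " leaves no ancestral material on one side")
    }
    left  <- paste0(substr(a$seq, 1L, g), strrep("*", L - g))
    right <- paste0(strrep("*", g), substr(a$seq, g + 1L, L))
    out <- c(seqs[-i], left, right)
    consumed <- a$seq
    produced <- c(left, right)
  } else {
    stop("unknown action kind: ", a$kind)
  }
  list(
    state = new_state(out, L),
    event = structure(list(action = a, consumed = consumed,
                           produced = produced), class = "arg_event")
  )
}

# all (action, successor) pairs of a state, in canonical action order
successors <- function(s, allow_disjoint = TRUE,
                       recomb_exclude = "mrca") {
  acts <- legal_actions(s, allow_disjoint, recomb_exclude)
  lapply(acts, function(a) {
    r <- apply_action(s, a, allow_disjoint)
    list(action = a, state = r$state, event = r$event)
  })
}

#' Does a sample require recombination?
#'
#' The polarized three-gamete test: with known ancestral alleles, a pair of
#' marker columns exhibiting all three gametes `01`, `10` and `11` across the
#' sample forces at least one recombination event in any genealogy.
#'
#' @param s an [arg_state()] of fully ancestral `0/1` sequences.
#' @return `TRUE` if some column pair shows all three gametes.
#' @export
recombination_required <- function(s) {
  if (any(grepl("\\*", s))) {
    stop("recombination_required is defined for fully ancestral samples only")
  }
  m <- seq_matrix(s)
  L <- ncol(m)
  if (L < 2L) return(FALSE)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      g <- paste0(m[, i], m[, j])
      if (all(c("01", "10", "11") %in% g)) return(TRUE)
    }
  }
  FALSE
}

#' Construct an ARG (ordered event list)
#'
#' An ancestral recombination graph is represented as an initial state plus
#' the ordered list of events applied to it; its length is the event count.
#'
#' @param initial_state an [arg_state()].
#' @param events list of `arg_event` objects (as produced by
#'   [apply_action()]).
#' @return An object of class `arg`.
#' @export
new_arg <- function(initial_state, events = list()) {
  structure(list(initial_state = initial_state, events = events,
                 length = length(events)), class = "arg")
}

#' @export
print.arg <- function(x, ...) {
  t <- arg_tallies(x)
  cat("<arg> length ", x$length, " (", t[["mutation"]], " mutations, ",
      t[["coalescence"]], " coalescences, ", t[["recombination"]],
      " recombinations)\n", sep = "")
  invisible(x)
}

#' Event-type tallies of an ARG
#'
#' @param arg an [new_arg()] object.
#' @return Named integer vector with counts of coalescence, mutation and
#'   recombination events.
#' @export
arg_tallies <- function(arg) {
  kinds <- vapply(arg$events, function(e) e$action$kind, character(1L))
  c(coalescence   = sum(kinds == "coalescence"),
    mutation      = sum(kinds == "mutation"),
    recombination = sum(kinds == "recombination"))
}

#' Replay and validate an ARG
#'
#' Replays the event list from the initial state, checking legality of every
#' step, and reports whether the genealogy is complete (reaches the MRCA).
#' For a complete ARG the event tallies obey the conservation laws: exactly
#' one mutation per marker column of the initial sample carrying a derived
#' allele (for a sample whose columns all segregate this is the number of
#' segregating sites `S`), and coalescences equal recombinations plus
#' `n - 1` (with `n` the initial number of sequence copies), so the length
#' is `S + n - 1 + 2 R`.
#'
#' @param arg an [new_arg()] object.
#' @return A list: `legal`, `complete`, `length`, `tallies`,
#'   `tallies_consistent`, `final_state`, and — when a step fails —
#'   `first_illegal` (index) and `message`.
#' @export
validate_arg <- function(arg) {
  s <- arg$initial_state
  for (i in seq_along(arg$events)) {
    e <- arg$events[[i]]
    r <- tryCatch(apply_action(s, e$action), error = function(err) err)
    if (inherits(r, "error")) {
      return(list(legal = FALSE, complete = FALSE, length = arg$length,
                  first_illegal = i, message = conditionMessage(r)))
    }
    s <- r$state
  }
  t <- arg_tallies(arg)
  complete <- is_terminal_state(s)
  consistent <- if (complete) {
    t[["mutation"]] == n_mutations_left(arg$initial_state) &&
      t[["coalescence"]] == t[["recombination"]] + length(arg$initial_state) - 1L
  } else NA
  list(legal = TRUE, complete = complete, length = arg$length,
       tallies = t, tallies_consistent = consistent, final_state = s)
}
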