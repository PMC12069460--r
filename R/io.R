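#' Read a haplotype text file
#'
#' One sequence per line over `{0,1}` (states with `*` are accepted when
#' `allow_star = TRUE`), `#` comment lines and blank lines ignored, no
#' header.  Ragged rows or illegal characters are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @param as return an [arg_state()] (default) or a 0/1 `matrix`.
#' @param allow_star accept `*` symbols (partially ancestral states).
#' @return An [arg_state()] or integer matrix.
#' @export
read_haplotypes <- function(path, as = c("state", "matrix"),
                            allow_star = TRUE) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("haplotype file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  txt <- sub("#.*$", "", raw)
  txt <- gsub("[ \t]", "", txt)
  keep <- nzchar(txt)
  txt <- txt[keep]; lineno <- lineno[keep]
  if (length(txt) == 0L) stop("no sequences in ", path)
  pat <- if (allow_star) "[^01*]" else "[^01]"
  bad <- grepl(pat, txt)
  if (any(bad)) {
    stop("illegal characters in ", path, " at line(s) ",
         paste(lineno[bad], collapse = ", "))
  }
  ragged <- nchar(txt) != nchar(txt[1L])
  if (any(ragged)) {
    stop("ragged rows in ", path, " at line(s) ",
         paste(lineno[ragged], collapse = ", "))
  }
  if (as == "state") {
    arg_state(txt)
  } else {
    if (any(grepl("\\*", txt))) {
      stop("matrix output requires fully ancestral 0/1 sequences")
    }
    m <- do.call(rbind, strsplit(txt, "", fixed = TRUE))
    matrix(as.integer(m), nrow = nrow(m))
  }
}

#' Write sequences to the haplotype text format
#'
#' @param x an [arg_state()], character vector or 0/1 matrix.
#' @param path file path.
#' @export
write_haplotypes <- function(x, path) {
  seqs <- if (is.matrix(x)) apply(x, 1L, paste, collapse = "") else
    as.character(x)
  writeLines(seqs, path)
  invisible(path)
}

event_to_json <- function(e) {
  a <- e$action
  rec <- list(kind = a$kind, inputs = as.list(e$consumed),
              outputs = as.list(e$produced))
  if (a$kind == "mutation") rec$marker <- a$marker
  if (a$kind == "recombination") rec$gap <- a$gap
  rec
}

#' Write / read an ARG as JSON
#'
#' The schema records the initial state, the ordered event list (kind,
#' consumed and produced sequence types, marker or gap), the length and the
#' event tallies.  Reading re-validates the event list by replay and
#' rejects illegal files.
#'
#' @param arg an [new_arg()].
#' @param path file path.
#' @export
write_arg <- function(arg, path) {
  payload <- list(
    initial_state = as.list(unclass(arg$initial_state)),
    events = lapply(arg$events, event_to_json),
    length = arg$length,
    tallies = as.list(arg_tallies(arg))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arg
#' @return `read_arg()` returns the validated [new_arg()].
#' @export
read_arg <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$initial_state) || is.null(payload$events)) {
    stop("not an ARG file: ", path)
  }
  s0 <- arg_state(unlist(payload$initial_state))
  s <- s0
  events <- vector("list", length(payload$events))
  for (i in seq_along(payload$events)) {
    ev <- payload$events[[i]]
    a <- switch(ev$kind,
      coalescence   = new_action("coalescence",
                                 pair = sort(unlist(ev$inputs))),
      mutation      = new_action("mutation", seq = ev$inputs[[1L]],
                                 marker = ev$marker),
      recombination = new_action("recombination", seq = ev$inputs[[1L]],
                                 gap = ev$gap),
      stop("unknown event kind in ", path, ": ", ev$kind)
    )
    r <- tryCatch(apply_action(s, a), error = function(err) {
      stop("invalid ARG file ", path, ": event ", i, " is illegal (",
           conditionMessage(err), ")")
    })
    events[[i]] <- r$event
    s <- r$state
  }
  new_arg(s0, events)
}

#' Export the event graph of an ARG to GraphViz DOT
#'
#' Lineages are nodes (labelled by their sequence), events connect consumed
#' lineages to produced ones.
#'
#' @param arg an [new_arg()].
#' @param path file path.
#' @export
write_dot <- function(arg, path) {
  # live lineage instances: sequence -> stack of node ids
  counter <- 0L
  nodes <- character(0L)
  live <- list()
  push <- function(seq) {
    counter <<- counter + 1L
    id <- paste0("n", counter)
    nodes <<- c(nodes, sprintf("  %s [label=\"%s\"];", id, seq))
    live[[seq]] <<- c(live[[seq]], id)
    id
  }
  pop <- function(seq) {
    ids <- live[[seq]]
    if (is.null(ids) || length(ids) == 0L) {
      stop("DOT export: no live lineage for ", seq)
    }
    id <- ids[[length(ids)]]
    live[[seq]] <<- ids[-length(ids)]
    id
  }
  edges <- character(0L)
  for (seq in unclass(arg$initial_state)) push(seq)
  for (i in seq_along(arg$events)) {
    e <- arg$events[[i]]
    from <- vapply(e$consumed, pop, character(1L))
    to <- vapply(e$produced, push, character(1L))
    lab <- paste0(i, ": ", substr(e$action$kind, 1L, 5L))
    for (f in from) for (t in to) {
      edges <- c(edges, sprintf("  %s -> %s [label=\"%s\"];", f, t, lab))
    }
  }
  writeLines(c("digraph arg {", "  rankdir=BT;", nodes, edges, "}"), path)
  invisible(path)
}
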