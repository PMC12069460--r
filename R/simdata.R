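#' Built-in worked example states
#'
#' The small states used throughout the documentation and tests:
#' \describe{
#'   \item{sample_a}{`{0011, 1011, 1000, 1100}` — a 4-sequence, 4-SNP sample
#'     with 758 distinct minimal genealogies of length 9.}
#'   \item{sample_b}{`{0101, 1000, 1010, 1101}` — its companion with 414
#'     minimal genealogies of length 9.}
#'   \item{worked_state}{`{0100, 1000, 1010, 0011}` — the state whose action
#'     inventory is 2 mutations + 12 recombinations, no coalescence.}
#'   \item{block_state}{`{0000, 0001}` — the two-sequence state used to
#'     illustrate block featurization.}
#' }
#'
#' @return Named list of [arg_state()] objects.
#' @export
example_states <- function() {
  list(
    sample_a     = arg_state(c("0011", "1011", "1000", "1100")),
    sample_b     = arg_state(c("0101", "1000", "1010", "1101")),
    worked_state = arg_state(c("0100", "1000", "1010", "0011")),
    block_state  = arg_state(c("0000", "0001"))
  )
}

#' Simulation configuration
#'
#' Parameters of the built-in single-population coalescent-with-
#' recombination simulator.  Rates are per site per generation; the
#' population follows the standard neutral model with constant (diploid)
#' size `Ne`, so a pair of lineages coalesces at rate `1 / (2 Ne)` per
#' generation.
#'
#' @param n number of sampled sequences.
#' @param Ne diploid population size.
#' @param mu per-site per-generation mutation rate.
#' @param rho per-site per-generation recombination rate.
#' @param region_bp region length in base pairs (candidate mutation sites).
#' @param L_keep number of SNP columns kept: the first `L_keep` segregating
#'   sites in genomic order, the same sites for every individual.
#' @param seed master seed.
#' @param max_retries replicates with fewer than `L_keep` segregating sites
#'   are re-simulated with a fresh sub-seed up to this many times.
#' @return A list of class `arg_sim_config`.
#' @export
sim_config <- function(n = 40L, Ne = 10000, mu = 1.2e-8, rho = 1.2e-8,
                       region_bp = 25000L, L_keep = 10L, seed = 1L,
                       max_retries = 50L) {
  stopifnot(n >= 2L, Ne > 0, mu >= 0, rho >= 0, region_bp >= 1L,
            L_keep >= 1L)
  structure(list(n = as.integer(n), Ne = Ne, mu = mu, rho = rho,
                 region_bp = as.integer(region_bp),
                 L_keep = as.integer(L_keep), seed = seed,
                 max_retries = max_retries),
            class = "arg_sim_config")
}

#' Single replicate of the structured coalescent with recombination
#'
#' Back-in-time simulation in the style of Hudson's algorithm over a
#' discrete sequence of candidate sites.  Lineages carry their ancestral
#' material as intervals of sites annotated with the set of sample
#' descendants; coalescence merges interval maps (dropping intervals whose
#' descendant set reaches the full sample, whose genealogy is then
#' complete), recombination splits a lineage at a uniformly chosen
#' breakpoint inside its ancestral span, and infinite-sites mutations are
#' placed by competing exponential clocks on the total amount of ancestral
#' material (a second hit on an already-mutated site is discarded).  A
#' mutation on a lineage assigns the derived allele to that lineage's
#' descendants at the site.
#'
#' @param cfg an [sim_config()].
#' @param seed overrides `cfg$seed` when non-NULL.
#' @return A list: `genotypes` (n x S matrix over 0/1, one column per
#'   segregating site in genomic order), `sites` (their positions),
#'   `n_segregating`.
#' @export
sim_hudson <- function(cfg, seed = NULL) {
  with_seed(if (is.null(seed)) cfg$seed else seed, {
    n <- cfg$n
    # lineage: list of intervals (lo, hi, members); positions 1..region_bp
    lineages <- lapply(seq_len(n), function(i) {
      list(list(lo = 1L, hi = cfg$region_bp, members = i))
    })
    muts <- list()     # site -> members carrying the derived allele
    used_sites <- integer(0L)

    anc_sites <- function(lin) {
      sum(vapply(lin, function(iv) iv$hi - iv$lo + 1L, integer(1L)))
    }
    span_links <- function(lin) {
      lo <- min(vapply(lin, `[[`, integer(1L), "lo"))
      hi <- max(vapply(lin, `[[`, integer(1L), "hi"))
      hi - lo
    }

    while (length(lineages) > 0L) {
      k <- length(lineages)
      A <- vapply(lineages, anc_sites, integer(1L))
      W <- vapply(lineages, span_links, integer(1L))
      rate_coal <- if (k >= 2L) k * (k - 1) / 2 / (2 * cfg$Ne) else 0
      rate_mut <- cfg$mu * sum(A)
      rate_rec <- cfg$rho * sum(W)
      total <- rate_coal + rate_mut + rate_rec
      if (total <= 0) break      # nothing can happen (e.g. mu = rho = 0)
      u <- stats::runif(1L) * total
      if (u < rate_mut) {
        i <- sample.int(k, 1L, prob = A)
        site <- pick_site(lineages[[i]], A[i])
        if (!(site %in% used_sites)) {       # infinite sites: thin repeats
          used_sites <- c(used_sites, site)
          muts[[length(muts) + 1L]] <-
            list(site = site, members = members_at(lineages[[i]], site))
        }
      } else if (u < rate_mut + rate_coal) {
        pair <- sample.int(k, 2L)
        merged <- merge_lineages(lineages[[pair[1L]]], lineages[[pair[2L]]], n)
        lineages <- lineages[-pair]
        if (length(merged) > 0L) lineages[[length(lineages) + 1L]] <- merged
      } else {
        i <- sample.int(k, 1L, prob = W)
        lin <- lineages[[i]]
        lo <- min(vapply(lin, `[[`, integer(1L), "lo"))
        hi <- max(vapply(lin, `[[`, integer(1L), "hi"))
        bp <- lo + sample.int(hi - lo, 1L) - 1L   # split <= bp / > bp
        left  <- Filter(Negate(is.null), lapply(lin, clip_iv, hi_cap = bp))
        right <- Filter(Negate(is.null), lapply(lin, clip_iv,
                                                lo_cap = bp + 1L))
        lineages <- lineages[-i]
        if (length(left) > 0L) lineages[[length(lineages) + 1L]] <- left
        if (length(right) > 0L) lineages[[length(lineages) + 1L]] <- right
      }
    }

    if (length(muts) == 0L) {
      return(list(genotypes = matrix(0L, nrow = n, ncol = 0L),
                  sites = integer(0L), n_segregating = 0L))
    }
    sites <- vapply(muts, `[[`, integer(1L), "site")
    ord <- order(sites)
    G <- matrix(0L, nrow = n, ncol = length(muts))
    for (j in seq_along(ord)) {
      G[muts[[ord[j]]]$members, j] <- 1L
    }
    # a site where every sample carries the derived allele is not
    # segregating (cannot happen once fixed intervals are dropped, but
    # guard anyway); same for empty carrier sets
    seg <- colSums(G) > 0L & colSums(G) < n
    list(genotypes = G[, seg, drop = FALSE], sites = sites[ord][seg],
         n_segregating = sum(seg))
  })
}

clip_iv <- function(iv, lo_cap = NULL, hi_cap = NULL) {
  if (!is.null(hi_cap)) {
    if (iv$lo > hi_cap) return(NULL)
    iv$hi <- min(iv$hi, hi_cap)
  }
  if (!is.null(lo_cap)) {
    if (iv$hi < lo_cap) return(NULL)
    iv$lo <- max(iv$lo, lo_cap)
  }
  iv
}

pick_site <- function(lin, total) {
  r <- sample.int(total, 1L)
  for (iv in lin) {
    w <- iv$hi - iv$lo + 1L
    if (r <= w) return(iv$lo + r - 1L)
    r <- r - w
  }
  stop("internal error: site draw out of range")
}

members_at <- function(lin, site) {
  for (iv in lin) {
    if (iv$lo <= site && site <= iv$hi) return(iv$members)
  }
  integer(0L)
}

# union of two interval maps; intervals whose descendant set reaches the
# full sample of size n have found their MRCA and are dropped
merge_lineages <- function(a, b, n) {
  cuts <- sort(unique(c(
    vapply(c(a, b), `[[`, integer(1L), "lo"),
    vapply(c(a, b), `[[`, integer(1L), "hi") + 1L
  )))
  out <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L] - 1L
    mem <- sort(unique(c(members_at(a, lo), members_at(b, lo))))
    if (length(mem) == 0L || length(mem) == n) next
    last <- if (length(out) > 0L) out[[length(out)]] else NULL
    if (!is.null(last) && last$hi + 1L == lo &&
        identical(last$members, mem)) {
      out[[length(out)]]$hi <- hi          # merge adjacent equal segments
    } else {
      out[[length(out) + 1L]] <- list(lo = lo, hi = hi, members = mem)
    }
  }
  out
}

#' Simulate a polarized haplotype sample
#'
#' Runs [sim_hudson()] and keeps the first `L_keep` segregating-site
#' columns (the same sites for every individual).  Replicates with too few
#' segregating sites are re-simulated with fresh sub-seeds up to
#' `cfg$max_retries` times before an explicit error.
#'
#' @param cfg an [sim_config()].
#' @return An `n x L_keep` matrix over 0/1 with attributes `sites` (kept
#'   positions), `n_segregating` (before truncation) and `retries`.
#' @examples
#' m <- simulate_sample(sim_config(n = 6, mu = 1e-7, L_keep = 3, seed = 2))
#' dim(m)
#' @export
simulate_sample <- function(cfg) {
  for (try in 0:cfg$max_retries) {
    rep_seed <- if (try == 0L) cfg$seed else derive_seed(cfg$seed, try)
    sim <- sim_hudson(cfg, seed = rep_seed)
    if (sim$n_segregating >= cfg$L_keep) {
      G <- sim$genotypes[, seq_len(cfg$L_keep), drop = FALSE]
      attr(G, "sites") <- sim$sites[seq_len(cfg$L_keep)]
      attr(G, "n_segregating") <- sim$n_segregating
      attr(G, "retries") <- try
      return(G)
    }
  }
  stop("simulation produced fewer than L_keep = ", cfg$L_keep,
       " segregating sites in ", cfg$max_retries + 1L,
       " attempts; raise mu, region_bp or max_retries")
}

#' Convert a haplotype matrix to sequence strings or a state
#'
#' @param m 0/1 matrix, one sequence per row.
#' @return Character vector of sequences (`as = "sequences"`) or an
#'   [arg_state()].
#' @param as output form.
#' @export
haplotypes_to_states <- function(m, as = c("state", "sequences")) {
  as <- match.arg(as)
  seqs <- apply(m, 1L, paste, collapse = "")
  if (as == "state") arg_state(seqs) else seqs
}

#' Split a sequence pool into training, validation and test sets
#'
#' Seeded disjoint row partition in the given sizes.
#'
#' @param m haplotype matrix (or character vector of sequences).
#' @param sizes integer vector (typically length 3) with
#'   `sum(sizes) <= nrow(m)`.
#' @param seed seed of the permutation.
#' @return A list of matrices (or character vectors), one per size, named
#'   `train`, `validation`, `test` when `sizes` has length 3.
#' @export
split_pool <- function(m, sizes, seed = 1L) {
  n <- if (is.matrix(m)) nrow(m) else length(m)
  if (sum(sizes) > n) {
    stop("requested split of ", sum(sizes), " rows from a pool of ", n)
  }
  idx <- with_seed(seed, sample.int(n))
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    take <- idx[seq_len(sizes[i]) + at]
    at <- at + sizes[i]
    out[[i]] <- if (is.matrix(m)) m[take, , drop = FALSE] else m[take]
  }
  if (length(sizes) == 3L) names(out) <- c("train", "validation", "test")
  out
}
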