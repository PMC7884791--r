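#' Transition graphs for binary-network construction
#'
#' A `transition_graph` describes the dynamics a network must follow: `M`
#' network states and, for each state and each of the two stimuli, the
#' destination state. States are 1-based. For the sequence-memory task
#' ("s-task") the graph is a binary de Bruijn shift register: state `m`
#' encodes the last `tau` stimuli as bits of `m - 1`, the most recent
#' stimulus in the least-significant bit. Random graphs follow the same
#' delta-pair algebra but with destinations drawn at random, optionally with
#' a controlled fraction of bicoloured states (states reachable under both
#' stimuli).
#'
#' The field `chains` partitions the states into delta-chains: ordered runs
#' of states whose activation rows differ by the constant vector delta
#' between consecutive members. For the s-task every chain is the pair
#' `(2k - 1, 2k)`. Destination pairs of every edge-slot are consecutive
#' members of a chain, which is what keeps the assembled linear system
#' consistent.
#'
#' @name transition_graph
NULL

new_transition_graph <- function(n_states, tau, kind, edges, chains,
                                 f_bc = 0, bicoloured = integer(0)) {
  stopifnot(is.matrix(edges), nrow(edges) == n_states, ncol(edges) == 2)
  structure(
    list(
      n_states = as.integer(n_states),
      n_stimuli = 2L,
      tau = as.integer(tau),
      kind = kind,
      f_bc = f_bc,
      edges = edges,
      chains = chains,
      bicoloured = as.integer(bicoloured)
    ),
    class = "transition_graph"
  )
}

#' Build the s-task transition graph
#'
#' Constructs the shift-register graph over `M = 2^tau` states. From state
#' `m`, stimulus `c` (1 or 2) leads to state `((m - 1) %% 2^(tau - 1)) * 2 + c`:
#' the stimulus history is shifted one step and the new stimulus bit enters
#' at the least-significant position. States `2k - 1` and `2k` share all
#' history except the most recent stimulus, so they form the delta-pairs on
#' which system consistency rests. All states are monocoloured: every
#' incoming edge of a state carries the same stimulus label.
#'
#' @param tau Sequence length to memorise (positive integer, at most 20).
#' @return A `transition_graph` of kind `"stask"`.
#' @export
#' @examples
#' g <- build_stask_graph(3)
#' g$edges[5, 2]  # state 5 (history 1,0,0) under s2 -> state 2 (history 0,0,1)
build_stask_graph <- function(tau) {
  stopifnot(length(tau) == 1, tau >= 1, tau == as.integer(tau))
  if (tau > 20) {
    stop("tau > 20 would need more than 2^20 states; refusing as a resource guard")
  }
  tau <- as.integer(tau)
  m_states <- 2L^tau
  half <- 2L^(tau - 1L)
  src <- seq_len(m_states)
  edges <- cbind(((src - 1L) %% half) * 2L + 1L,
                 ((src - 1L) %% half) * 2L + 2L)
  chains <- lapply(seq_len(m_states / 2L), function(k) c(2L * k - 1L, 2L * k))
  new_transition_graph(m_states, tau, "stask", edges, chains)
}

#' Build a random transition graph with controlled bicoloured fraction
#'
#' Generates a graph over `M = 2^tau` states whose destination structure is
#' random but still compatible with a consistent linear system. The first
#' `M/2` edge slots use each delta-pair once as a destination pair, so every
#' state receives at least one edge; `round(f_bc * M / 4)` quadruples of
#' consecutive states are then rewired so that exactly one state per
#' quadruple becomes bicoloured: the quadruple's two pairs `(i, i+1)`,
#' `(i+2, i+3)` are replaced by the chain `i -> i+1 -> i+3` (destination
#' pairs `(i, i+1)` and `(i+1, i+3)`, the `(1,2,2,4)` rewiring), and the
#' displaced states `i+2` from consecutive rewired quadruples are re-paired
#' with each other so they stay reachable. The remaining `M/2` slots draw
#' destination pairs uniformly with replacement from the valid pair pool,
#' and source states are attached through a uniform random permutation.
#' Candidate graphs violating the forbidden patterns (a state mapping to the
#' same destination under both stimuli, or two paired states mapping
#' crosswise onto themselves) are rejected and redrawn.
#'
#' The number of bicoloured states must be even: with every state required
#' to keep in-degree >= 1, the bicoloured count equals twice the number of
#' destination-pair slots minus `M` when counted over any edge cover of the
#' delta-chains, which is always even. Odd requested counts are rejected.
#'
#' @param tau Memory length; the graph has `2^tau` states (`tau >= 2`).
#' @param f_bc Bicoloured fraction in `[0, 1]`; `round(f_bc * M / 4)` states
#'   become reachable under both stimuli.
#' @param max_attempts Rejection-sampling cap (default 1000).
#' @return A `transition_graph` of kind `"random"`.
#' @export
build_random_graph <- function(tau, f_bc, max_attempts = 1000) {
  stopifnot(length(tau) == 1, tau >= 2, tau == as.integer(tau))
  if (tau > 20) {
    stop("tau > 20 would need more than 2^20 states; refusing as a resource guard")
  }
  stopifnot(f_bc >= 0, f_bc <= 1)
  tau <- as.integer(tau)
  m_states <- 2L^tau
  k_bc <- as.integer(round(f_bc * m_states / 4))
  if (k_bc %% 2L == 1L) {
    stop("round(f_bc * M / 4) = ", k_bc, " is odd; an odd number of ",
         "bicoloured states cannot coexist with in-degree >= 1 on all states")
  }
  for (attempt in seq_len(max_attempts)) {
    g <- draw_random_graph(tau, m_states, k_bc, f_bc)
    bad <- forbidden_patterns(g)
    if (!bad$any) {
      return(g)
    }
  }
  stop("failed to draw an admissible random graph in ", max_attempts,
       " attempts (tau = ", tau, ", f_bc = ", f_bc, ")")
}

# One candidate draw; see build_random_graph for the recipe.
draw_random_graph <- function(tau, m_states, k_bc, f_bc) {
  # chains start as the M/2 delta-pairs
  chains <- lapply(seq_len(m_states / 2L), function(k) c(2L * k - 1L, 2L * k))
  required <- list()   # destination pairs that must appear at least once
  if (k_bc > 0) {
    # rewire quadruples 1..k_bc: states (4q-3, 4q-2, 4q-1, 4q)
    orphans <- integer(k_bc)
    for (q in seq_len(k_bc)) {
      a <- 4L * q - 3L
      chains[[2L * q - 1L]] <- c(a, a + 1L, a + 3L)  # i -> i+1 -> i+3
      chains[[2L * q]] <- NA                          # pair (i+2, i+3) dissolved
      orphans[q] <- a + 2L
      required <- c(required, list(c(a, a + 1L), c(a + 1L, a + 3L)))
    }
    # orphans re-paired among themselves (k_bc is even)
    for (t in seq_len(k_bc / 2L)) {
      pr <- c(orphans[2L * t - 1L], orphans[2L * t])
      chains <- c(chains, list(pr))
      required <- c(required, list(pr))
    }
    chains <- chains[!vapply(chains, function(x) length(x) == 1 && is.na(x[1]),
                             logical(1))]
  }
  # untouched pairs appear once each
  for (ch in chains) {
    if (length(ch) == 2L && ch[1] > 4L * k_bc) {
      required <- c(required, list(ch))
    }
  }
  # pool of admissible destination pairs = consecutive chain members that are
  # already required (drawing from this pool can never add a bicoloured state)
  pool <- required
  n_extra <- m_states - length(required)
  extra <- pool[sample.int(length(pool), n_extra, replace = TRUE)]
  slots <- c(required, extra)
  # attach source states via a uniform permutation
  perm <- sample.int(m_states)
  edges <- matrix(0L, nrow = m_states, ncol = 2)
  for (i in seq_along(slots)) {
    edges[perm[i], ] <- slots[[i]]
  }
  bic <- bicoloured_states(edges)
  new_transition_graph(m_states, tau, "random", edges, chains,
                       f_bc = f_bc, bicoloured = bic)
}

# states with incoming edges under both stimuli
bicoloured_states <- function(edges) {
  s1_in <- unique(edges[, 1])
  s2_in <- unique(edges[, 2])
  sort(intersect(s1_in, s2_in))
}

# forbidden destination patterns: "(11)" one state leading to a single
# destination under both stimuli; "(1221)" two delta-paired states mapping
# crosswise onto themselves (consistent only for delta = 0)
forbidden_patterns <- function(graph) {
  edges <- graph$edges
  p11 <- which(edges[, 1] == edges[, 2])
  keys <- paste(edges[, 1], edges[, 2])
  rev_keys <- paste(edges[, 2], edges[, 1])
  p1221 <- which(rev_keys %in% keys)
  list(any = length(p11) > 0 || length(p1221) > 0,
       p11 = p11, p1221 = p1221)
}

#' Summary statistics of a transition graph
#'
#' @param graph A `transition_graph`.
#' @return A list with monocoloured/bicoloured counts, the in-degree
#'   distribution, and forbidden-pattern scan results.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "transition_graph"))
  m_states <- graph$n_states
  in_deg <- tabulate(as.vector(graph$edges), nbins = m_states)
  bic <- bicoloured_states(graph$edges)
  bad <- forbidden_patterns(graph)
  list(
    n_states = m_states,
    n_bicoloured = length(bic),
    n_monocoloured = m_states - length(bic),
    bicoloured = bic,
    in_degree = in_deg,
    min_in_degree = min(in_deg),
    forbidden_11 = bad$p11,
    forbidden_1221 = bad$p1221,
    valid = !bad$any && min(in_deg) >= 1
  )
}

#' @export
print.transition_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf(
    "<transition_graph> kind=%s tau=%d states=%d bicoloured=%d min_in_degree=%d\n",
    x$kind, x$tau, x$n_states, st$n_bicoloured, st$min_in_degree
  ))
  invisible(x)
}

#' Walk a transition graph along a stimulus sequence
#'
#' @param graph A `transition_graph`.
#' @param stimuli Integer vector with values in `{1, 2}`.
#' @param start Starting state (default 1).
#' @return Integer vector of visited states, one per stimulus.
#' @export
walk_graph <- function(graph, stimuli, start = 1L) {
  stopifnot(all(stimuli %in% c(1L, 2L)))
  out <- integer(length(stimuli))
  state <- as.integer(start)
  for (t in seq_along(stimuli)) {
    state <- graph$edges[state, stimuli[t]]
    out[t] <- state
  }
  out
}
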