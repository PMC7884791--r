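#' Simulate a binary threshold network
#'
#' Iterates the linear-threshold dynamics
#' `u(t) = y(t) W_in + z(t-1) W_rec`, `z(t) = H(u(t) - theta)` with a strict
#' threshold (`u > theta` fires). Stimulus `s` at time `t` activates input
#' neuron `s` (one-hot codes `y1 = (1,0)`, `y2 = (0,1)`).
#'
#' @param net A `binary_network`.
#' @param stimuli Integer vector of stimuli in `{1, 2}`.
#' @param z0 Initial firing vector of length `n_rec`, or `"auto"` to draw a
#'   uniformly chosen row of the network's stored firing-state matrix
#'   (zeros when no states are stored).
#' @param burn_in Number of leading steps flagged for exclusion from
#'   downstream statistics; defaults to the network's `tau` (0 if unknown).
#' @return A list of class `simulation_trace` with `stimuli`, `raster`
#'   (`T x n_rec` binary), `activations`, `state_ids` (index into the stored
#'   state set, `NA` for novel states), `burn_in`.
#' @export
simulate_network <- function(net, stimuli, z0 = "auto", burn_in = NULL) {
  stopifnot(inherits(net, "binary_network"), all(stimuli %in% c(1L, 2L)))
  n_rec <- ncol(net$w_rec)
  if (identical(z0, "auto")) {
    z <- if (!is.null(net$Z)) net$Z[sample.int(nrow(net$Z), 1), ] else
      rep(0, n_rec)
  } else {
    stopifnot(length(z0) == n_rec)
    z <- as.numeric(z0)
  }
  if (is.null(burn_in)) burn_in <- net$meta$tau %||% 0L
  n_steps <- length(stimuli)
  raster <- matrix(0, n_steps, n_rec)
  acts <- matrix(0, n_steps, n_rec)
  y <- rbind(c(1, 0), c(0, 1))
  for (t in seq_len(n_steps)) {
    u <- y[stimuli[t], ] %*% net$w_in + z %*% net$w_rec
    z <- as.numeric(u > net$theta)
    acts[t, ] <- u
    raster[t, ] <- z
  }
  state_ids <- rep(NA_integer_, n_steps)
  if (!is.null(net$Z)) {
    known <- apply(net$Z, 1, paste, collapse = "")
    seen <- apply(raster, 1, paste, collapse = "")
    state_ids <- match(seen, known)
  }
  structure(
    list(stimuli = as.integer(stimuli), raster = raster, activations = acts,
         state_ids = state_ids, burn_in = as.integer(burn_in)),
    class = "simulation_trace")
}

#' Uniform random stimulus sequence
#'
#' Stimuli 1 and 2, i.i.d. with equal probability (the presentation
#' statistics of the sequence-memory task).
#'
#' @param n_steps Sequence length.
#' @return Integer vector in `{1, 2}`.
#' @export
random_stimuli <- function(n_steps) {
  sample(1:2, n_steps, replace = TRUE)
}

# raster rows after burn-in
post_burn_raster <- function(trace) {
  keep <- seq_len(nrow(trace$raster)) > trace$burn_in
  trace$raster[keep, , drop = FALSE]
}

#' Sequence-memory decoding accuracy
#'
#' The task is solved when the stimulus presented at lag `tau - 1` is
#' univocally encoded by the current firing state. The empirical map from
#' firing state to lag-(tau-1) stimulus is built over the post-burn-in
#' trace; the returned accuracy is the fraction of evaluated steps whose
#' firing state maps to a single stimulus value. 1.0 means perfect sequence
#' memory.
#'
#' @param trace A `simulation_trace`.
#' @param tau Memory length of the task.
#' @return Accuracy in `[0, 1]`.
#' @export
decode_accuracy <- function(trace, tau) {
  n_steps <- nrow(trace$raster)
  lag <- tau - 1L
  t_eval <- seq_len(n_steps)
  t_eval <- t_eval[t_eval > max(trace$burn_in, lag)]
  if (length(t_eval) == 0) return(NA_real_)
  keys <- apply(trace$raster[t_eval, , drop = FALSE], 1, paste, collapse = "")
  stim <- trace$stimuli[t_eval - lag]
  unambiguous <- vapply(split(stim, keys), function(v) length(unique(v)) == 1,
                        logical(1))
  mean(unambiguous[keys])
}

#' Count distinct firing states in a trace
#'
#' @param trace A `simulation_trace`.
#' @return Number of distinct post-burn-in raster rows.
#' @export
count_firing_states <- function(trace) {
  r <- post_burn_raster(trace)
  nrow(unique(r))
}
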