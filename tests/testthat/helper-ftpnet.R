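# Shared helpers for the ftpnet test suite. Fixtures are built in code;
# oracles are independent of the implementation paths they check.

# Independent oracle for the s-task graph: walk an explicit stimulus-history
# buffer and re-encode it as a state index (most recent stimulus in the
# least-significant bit). Does not touch the edge matrix.
oracle_stask_state <- function(history, tau) {
  bits <- utils::tail(history, tau) - 1L
  as.integer(sum(bits * 2^((tau - 1):0)) + 1)
}

oracle_stask_walk <- function(stimuli, tau) {
  vapply(seq_along(stimuli), function(t) {
    if (t < tau) NA_integer_ else
      oracle_stask_state(stimuli[seq_len(t)], tau)
  }, integer(1))
}

# Brute-force Spearman: explicit average ranks + Pearson on the ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Full post-burn-in raster of a freshly constructed s-task network.
quick_trace <- function(fit, n_steps, tau) {
  simulate_network(fit$network, random_stimuli(n_steps + tau),
                   burn_in = tau)
}

post_burn <- function(trace) {
  keep <- seq_len(nrow(trace$raster)) > trace$burn_in
  trace$raster[keep, , drop = FALSE]
}
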