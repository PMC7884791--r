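#' Mean firing rate of a raster
#'
#' @param raster Binary matrix, time steps by neurons (burn-in removed).
#' @return Mean over all entries, in spikes/time step. The per-neuron rates
#'   are attached as attribute `"per_neuron"`.
#' @export
firing_rate <- function(raster) {
  if (length(raster) == 0) stop("empty raster")
  raster <- as.matrix(raster)
  out <- mean(raster)
  attr(out, "per_neuron") <- colMeans(raster)
  out
}

# Spearman correlation matrix with the conventions used throughout:
# average ranks for ties (binary trains are all ties) and 0 for pairs
# involving a constant train.
spearman_matrix <- function(raster, keep_na = FALSE) {
  cm <- suppressWarnings(stats::cor(raster, method = "spearman"))
  if (!keep_na) cm[is.na(cm)] <- 0
  cm
}

mean_upper <- function(cm, absolute = FALSE, drop_constant = FALSE) {
  v <- cm[upper.tri(cm)]
  if (!drop_constant) v[is.na(v)] <- 0
  if (absolute) v <- abs(v)
  mean(v, na.rm = TRUE)
}

#' Mean pairwise spike-train correlation
#'
#' Spearman rank correlation per unordered neuron pair across time steps.
#' With `mode = "all"` (signal correlation) the whole raster is used; with
#' `mode = "noise"` the correlation is computed within each stimulus
#' condition separately and the two per-stimulus means are averaged with
#' equal weight. By default pairs involving a constant train contribute 0;
#' with `drop_constant = TRUE` they are excluded from the average instead.
#' The combination `absolute = TRUE, drop_constant = TRUE` is the
#' convention that reproduces the published correlation values (it is also
#' the only one whose shuffled-raster floor equals the analytic null
#' `sqrt(2 / (pi * (n - 1)))` for the mean absolute coefficient of
#' independent trains of length `n`).
#'
#' @param raster Binary matrix, time steps by neurons (>= 2 neurons).
#' @param stimuli Stimulus sequence aligned with the raster rows (required
#'   for `mode = "noise"`).
#' @param mode `"all"` or `"noise"`.
#' @param absolute Average absolute coefficients instead of signed ones.
#' @param drop_constant Exclude pairs with a constant train instead of
#'   counting them as 0.
#' @return Mean pairwise correlation; the full pair matrix (mode `"all"`)
#'   or per-stimulus matrices (mode `"noise"`) are attached as attribute
#'   `"pairs"`.
#' @export
pairwise_cc <- function(raster, stimuli = NULL, mode = c("all", "noise"),
                        absolute = FALSE, drop_constant = FALSE) {
  mode <- match.arg(mode)
  raster <- as.matrix(raster)
  stopifnot(ncol(raster) >= 2)
  if (mode == "all") {
    cm <- spearman_matrix(raster, keep_na = TRUE)
    out <- mean_upper(cm, absolute, drop_constant)
    attr(out, "pairs") <- cm
    return(out)
  }
  stopifnot(!is.null(stimuli), length(stimuli) == nrow(raster))
  cms <- lapply(1:2, function(s) {
    spearman_matrix(raster[stimuli == s, , drop = FALSE], keep_na = TRUE)
  })
  out <- mean(vapply(cms, mean_upper, numeric(1), absolute = absolute,
                     drop_constant = drop_constant))
  attr(out, "pairs") <- cms
  out
}

#' Shuffle inter-spike intervals of each neuron
#'
#' For each neuron independently, the gaps between consecutive spikes
#' (including the gap before the first spike) are permuted uniformly and
#' the train is rebuilt; trailing silence is preserved as the remainder.
#' Per-neuron spike counts are conserved exactly. This surrogate destroys
#' temporal co-ordination between neurons while keeping each neuron's rate,
#' so correlations of shuffled rasters fall to the finite-sample null.
#'
#' @param raster Binary matrix, time steps by neurons.
#' @return Shuffled raster of the same dimensions.
#' @export
isi_shuffle <- function(raster) {
  raster <- as.matrix(raster)
  out <- matrix(0, nrow(raster), ncol(raster))
  for (j in seq_len(ncol(raster))) {
    pos <- which(raster[, j] > 0)
    if (length(pos) == 0) next
    gaps <- diff(c(0L, pos))  # leading gap included
    new_pos <- cumsum(gaps[sample.int(length(gaps))])
    out[new_pos, j] <- 1
  }
  out
}

#' Reciprocity of a recurrent weight matrix
#'
#' Spearman correlation between the weights of reciprocal connections,
#' computed on `W_norm`: absolute recurrent weights min-max scaled to
#' `[0, 1]` over the off-diagonal entries. Only ordered pairs `(i, j)`,
#' `i != j`, where both `W_norm[i, j]` and `W_norm[j, i]` exceed
#' `zero_tolerance` enter (each unordered pair appears twice, mirrored, so
#' the statistic is symmetric). Structural zeros produced by clipping are
#' thereby excluded.
#'
#' @param w_rec Square recurrent weight matrix.
#' @param zero_tolerance Threshold below which a normalized weight counts
#'   as zero (default 1e-12).
#' @return Reciprocity in `[-1, 1]`, or `NA` (with a warning) when fewer
#'   than 3 unordered pairs survive.
#' @export
reciprocity <- function(w_rec, zero_tolerance = 1e-12) {
  stopifnot(is.matrix(w_rec), nrow(w_rec) == ncol(w_rec))
  n <- nrow(w_rec)
  A <- abs(w_rec)
  off <- A[row(A) != col(A)]
  rng <- range(off)
  if (diff(rng) == 0) {
    warning("degenerate weight matrix: all off-diagonal magnitudes equal")
    return(NA_real_)
  }
  wn <- (A - rng[1]) / (rng[2] - rng[1])
  idx <- which(row(A) != col(A), arr.ind = TRUE)
  fwd <- wn[idx]
  bwd <- wn[idx[, c(2, 1), drop = FALSE]]
  keep <- fwd > zero_tolerance & bwd > zero_tolerance
  if (sum(keep) < 6) {  # fewer than 3 unordered pairs
    warning("fewer than 3 reciprocal weight pairs above tolerance")
    return(NA_real_)
  }
  suppressWarnings(stats::cor(fwd[keep], bwd[keep], method = "spearman"))
}

#' Kolmogorov-Smirnov distance to a matched normal
#'
#' Two-sample KS statistic between the weights and a freshly drawn normal
#' sample of the same mean, variance, and size. Zero-variance input is
#' flagged with a warning and returns 1 by convention (a point mass is
#' treated as maximally non-normal).
#'
#' @param weights Numeric vector or matrix (>= 10 values).
#' @return The KS statistic.
#' @export
ks_normal <- function(weights) {
  w <- as.vector(weights)
  stopifnot(length(w) >= 10)
  s <- stats::sd(w)
  if (s == 0) {
    warning("degenerate weights: zero variance")
    return(1)
  }
  ref <- stats::rnorm(length(w), mean(w), s)
  unname(suppressWarnings(stats::ks.test(w, ref)$statistic))
}

#' Firing and connectivity report for a simulated network
#'
#' Convenience wrapper bundling the statistics used when screening
#' networks: firing rate, signal and noise correlation, correlation split
#' by excitatory/inhibitory pair type when types are available, reciprocity
#' of the recurrent weights, and the KS distance of the recurrent weights
#' to a matched normal.
#'
#' @param net A `binary_network`.
#' @param trace A `simulation_trace` of that network.
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(net, trace) {
  raster <- post_burn_raster(trace)
  stim <- trace$stimuli[seq_len(nrow(trace$raster)) > trace$burn_in]
  types <- net$meta$neuron_types
  cc_by_type <- NULL
  if (!is.null(types)) {
    cm <- spearman_matrix(raster)
    pair_of <- function(a, b) {
      sel <- outer(types == a, types == b) | outer(types == b, types == a)
      mean(cm[sel & upper.tri(cm)])
    }
    cc_by_type <- c(ExEx = pair_of("Ex", "Ex"), InIn = pair_of("In", "In"),
                    ExIn = pair_of("Ex", "In"))
  }
  structure(
    list(fr = as.numeric(firing_rate(raster)),
         cc_all = as.numeric(pairwise_cc(raster)),
         cc_noise = as.numeric(pairwise_cc(raster, stim, mode = "noise")),
         cc_by_type = cc_by_type,
         reciprocity = reciprocity(net$w_rec),
         ks_stat = ks_normal(net$w_rec)),
    class = "metrics_report")
}
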