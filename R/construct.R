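#' Numerical helpers: rank and pseudoinverse
#'
#' Rank uses singular values above `tol * max(singular value)`; the
#' pseudoinverse inverts only those. Both default to a relative tolerance of
#' 1e-10, tight enough for the half-integer activation grids used here.
#' @noRd
mat_rank <- function(A, tol = 1e-10) {
  if (length(A) == 0) return(0L)
  s <- svd(A, nu = 0, nv = 0)$d
  sum(s > tol * s[1])
}

pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

ftp_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ftp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Generate an activation base with target firing statistics
#'
#' Thresholds are sampled uniformly from `{1/2, 3/2, 5/2}`. Each entry of
#' the base matrix is `theta_i + r + 1/2` with `|r|` uniform on `{1..5}` and
#' `sign(r) = +1` with probability `target_fr`, so an entry is
#' supra-threshold exactly when `r > 0` and the expected fraction of firing
#' entries equals the target rate. The delta vector is the difference
#' between the first two rows, scaled by `f_cc`; larger `f_cc` drives the
#' two stimuli to have increasingly different effects per neuron, which is
#' what induces pairwise correlation downstream. The base is resampled until
#' full rank (requires `n_rec >= M/2 + 1`).
#'
#' @param M Number of network states (even).
#' @param n_rec Number of integration neurons.
#' @param target_fr Target firing rate in (0, 1).
#' @param f_cc Delta scaling factor (>= 1).
#' @param max_attempts Full-rank resampling cap.
#' @return A list of class `activation_base` with fields `u_base`
#'   (`(M/2 + 1) x n_rec`), `theta`, `delta` (already scaled), `target_fr`,
#'   `f_cc`.
#' @export
make_activation_base <- function(M, n_rec, target_fr = 0.5, f_cc = 1,
                                 max_attempts = 50) {
  stopifnot(M %% 2 == 0, n_rec >= 1, target_fr > 0, target_fr < 1, f_cc >= 1)
  n_rows <- M / 2 + 1
  if (n_rec < n_rows) {
    ftp_error("ftp_rank_error", sprintf(
      "full-rank base needs n_rec >= M/2 + 1 (%d), got n_rec = %d",
      n_rows, n_rec))
  }
  theta <- sample(c(0.5, 1.5, 2.5), n_rec, replace = TRUE)
  for (attempt in seq_len(max_attempts)) {
    mag <- matrix(sample(1:5, n_rows * n_rec, replace = TRUE), n_rows, n_rec)
    sgn <- matrix(ifelse(stats::runif(n_rows * n_rec) < target_fr, 1, -1),
                  n_rows, n_rec)
    r <- mag * sgn
    u_base <- sweep(r + 0.5, 2, theta, `+`)
    if (mat_rank(u_base) == n_rows) {
      delta <- f_cc * (u_base[2, ] - u_base[1, ])
      return(structure(
        list(u_base = u_base, theta = theta, delta = delta,
             target_fr = target_fr, f_cc = f_cc),
        class = "activation_base"))
    }
  }
  ftp_error("ftp_rank_error",
            sprintf("no full-rank base in %d attempts", max_attempts))
}

#' Expand an activation base into per-state activation rows
#'
#' Produces the `M x n_rec` activation matrix with one row per network
#' state, arranged so that along every delta-chain of the graph consecutive
#' states differ by exactly `delta`. Each chain receives one free base row;
#' with `placement = "random"` the free row lands at a uniformly chosen
#' chain position and the rest are derived by adding/subtracting delta
#' (which balances the activation distributions of the two stimuli), with
#' `"first"` it always lands at the first position (deterministic; used for
#' genetic-algorithm fitness). The chain containing state 1 uses base row 1
#' or 2 (for pairs, according to the placement), the remaining chains use
#' base rows 3 onwards, so the number of derived rows for the s-task is
#' `M/2 - 1`.
#'
#' @param base An `activation_base`.
#' @param graph The `transition_graph` whose chains define the pairing.
#' @param placement `"random"` or `"first"`.
#' @return List with `u_lc` (`M x n_rec`) and `delta`.
#' @export
expand_activations <- function(base, graph, placement = c("random", "first")) {
  placement <- match.arg(placement)
  stopifnot(inherits(base, "activation_base"),
            inherits(graph, "transition_graph"))
  m_states <- graph$n_states
  n_rec <- ncol(base$u_base)
  chains <- graph$chains
  delta <- base$delta
  # anchor chain = the one containing state 1; it consumes base rows 1/2
  anchor <- which(vapply(chains, function(ch) 1L %in% ch, logical(1)))[1]
  order_idx <- c(anchor, setdiff(seq_along(chains), anchor))
  u_lc <- matrix(NA_real_, m_states, n_rec)
  free_row <- 2L  # next free base row for non-anchor chains is 3
  for (j in order_idx) {
    ch <- chains[[j]]
    len <- length(ch)
    pos <- if (placement == "random") sample.int(len, 1) else 1L
    if (j == anchor) {
      # base rows 1 and 2 define delta; honour the random choice of which of
      # the two defines the pair when the anchor is a plain pair
      if (len == 2L && pos == 2L) {
        free <- base$u_base[2, ]
      } else {
        free <- base$u_base[1, ]
        if (len > 2L) pos <- if (placement == "random") pos else 1L
      }
    } else {
      free_row <- free_row + 1L
      free <- base$u_base[free_row, ]
    }
    rows <- matrix(NA_real_, len, n_rec)
    rows[pos, ] <- free
    if (pos < len) {
      for (p in (pos + 1L):len) rows[p, ] <- rows[p - 1L, ] + delta
    }
    if (pos > 1L) {
      for (p in (pos - 1L):1L) rows[p, ] <- rows[p + 1L, ] - delta
    }
    u_lc[ch, ] <- rows
  }
  list(u_lc = u_lc, delta = delta)
}

#' Assemble and validate the linear system C W = U
#'
#' Binarises the activation rows into the firing matrix `Z` (strict
#' threshold `u > theta`), builds the coefficient matrix `C` whose rows
#' `2m - 1` and `2m` are `[y1 z_m]` and `[y2 z_m]` with one-hot input codes
#' `y1 = (1, 0)`, `y2 = (0, 1)`, and the activation matrix `U` whose row for
#' `(m, s)` is the activation row of the destination state
#' `graph$edges[m, s]`. Validity checks: all `Z` rows distinct
#' (`ftp_duplicate_state_error` otherwise) and
#' `rank(C) = rank([C U]) = M + 1` (`ftp_rank_error` otherwise). Both
#' failures mean "restart construction with fresh randomness".
#'
#' @param graph A `transition_graph`.
#' @param u_lc `M x n_rec` activation matrix (one row per state).
#' @param theta Threshold vector.
#' @param delta Per-neuron stimulus-difference vector.
#' @return A list of class `linear_system` with `C`, `U`, `u_lc`, `Z`,
#'   `graph`, `theta`, `delta`, `y_codes`.
#' @export
assemble_system <- function(graph, u_lc, theta, delta) {
  stopifnot(inherits(graph, "transition_graph"),
            nrow(u_lc) == graph$n_states, ncol(u_lc) == length(theta))
  m_states <- graph$n_states
  n_rec <- ncol(u_lc)
  Z <- (u_lc > rep(theta, each = m_states)) * 1
  keys <- apply(Z, 1, paste, collapse = "")
  if (anyDuplicated(keys)) {
    ftp_error("ftp_duplicate_state_error",
              "thresholded activation rows collide: not all network states are distinct")
  }
  y <- rbind(c(1, 0), c(0, 1))
  C <- matrix(0, 2 * m_states, 2 + n_rec)
  U <- matrix(0, 2 * m_states, n_rec)
  for (m in seq_len(m_states)) {
    for (s in 1:2) {
      i <- 2L * (m - 1L) + s
      C[i, ] <- c(y[s, ], Z[m, ])
      U[i, ] <- u_lc[graph$edges[m, s], ]
    }
  }
  rC <- mat_rank(C)
  if (rC != m_states + 1) {
    ftp_error("ftp_rank_error", sprintf(
      "rank(C) = %d, expected M + 1 = %d (firing states not affinely independent)",
      rC, m_states + 1))
  }
  rCU <- mat_rank(cbind(C, U))
  if (rCU != m_states + 1) {
    ftp_error("ftp_rank_error", sprintf(
      "rank([C U]) = %d != %d: system inconsistent", rCU, m_states + 1))
  }
  structure(
    list(C = C, U = U, u_lc = u_lc, Z = Z, graph = graph,
         theta = theta, delta = delta, y_codes = y),
    class = "linear_system")
}

#' Minimum-norm weights of a validated system
#'
#' `W = pinv(C) U` is the unique solution of `C W = U` with minimal
#' Frobenius norm; its rows split into `W_in` (first 2) and `W_rec`.
#'
#' @param system A `linear_system`.
#' @param tol Residual bound (default 1e-8).
#' @return Weight matrix `(2 + n_rec) x n_rec`.
#' @export
solve_weights <- function(system, tol = 1e-8) {
  stopifnot(inherits(system, "linear_system"))
  W <- pinv(system$C) %*% system$U
  resid <- max(abs(system$C %*% W - system$U))
  if (resid > tol) {
    ftp_error("ftp_residual_error", sprintf(
      "residual max|CW - U| = %.3g exceeds %.1g: inconsistent system slipped through",
      resid, tol))
  }
  W
}

new_binary_network <- function(W, theta, Z, meta) {
  n_in <- nrow(W) - ncol(W)
  structure(
    list(w_in = W[seq_len(n_in), , drop = FALSE],
         w_rec = W[-seq_len(n_in), , drop = FALSE],
         theta = theta, Z = Z, meta = meta),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> n_in=%d n_rec=%d states=%d kind=%s\n",
              nrow(x$w_in), ncol(x$w_rec),
              if (is.null(x$Z)) NA_integer_ else nrow(x$Z),
              x$meta$kind %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full weight matrix [W_in; W_rec]
full_weights <- function(net) rbind(net$w_in, net$w_rec)

#' Construct a network from a transition graph
#'
#' Orchestrates the whole pipeline: draw an activation base, expand it along
#' the graph's delta-chains, assemble and validate the linear system, and
#' solve for the minimum-norm weights. On a validity failure (duplicate
#' firing states or rank defect) the construction restarts with fresh
#' randomness, up to `max_restarts` times; the number of restarts is
#' recorded in the network metadata.
#'
#' @param graph A `transition_graph`, or `NULL` to build the s-task graph
#'   from `tau`.
#' @param tau Memory length (used when `graph` is `NULL`).
#' @param n_rec Number of integration neurons; defaults to
#'   `f_r * n_states` (redundancy factor times the state count).
#' @param f_r Redundancy factor (default 1).
#' @param target_fr Target firing rate.
#' @param f_cc Delta scaling factor.
#' @param max_restarts Restart cap (default 50).
#' @return List with `network` (a `binary_network`), `system`
#'   (the `linear_system`), and `restarts`.
#' @export
#' @examples
#' set.seed(1)
#' fit <- construct_network(tau = 3, n_rec = 8)
#' dim(fit$system$C)  # 16 x 10
construct_network <- function(graph = NULL, tau = NULL, n_rec = NULL,
                              f_r = 1, target_fr = 0.5, f_cc = 1,
                              max_restarts = 50) {
  if (is.null(graph)) {
    stopifnot(!is.null(tau))
    graph <- build_stask_graph(tau)
  }
  m_states <- graph$n_states
  if (is.null(n_rec)) n_rec <- as.integer(round(m_states * f_r))
  last <- NULL
  for (restart in 0:max_restarts) {
    result <- tryCatch({
      base <- make_activation_base(m_states, n_rec, target_fr, f_cc)
      exp <- expand_activations(base, graph)
      system <- assemble_system(graph, exp$u_lc, base$theta, exp$delta)
      W <- solve_weights(system)
      meta <- list(tau = graph$tau, kind = graph$kind, n_rec = n_rec,
                   f_r = n_rec / m_states, target_fr = target_fr,
                   f_cc = f_cc, f_bc = graph$f_bc, restarts = restart)
      list(network = new_binary_network(W, base$theta, system$Z, meta),
           system = system, restarts = restart)
    }, ftp_duplicate_state_error = function(e) e, ftp_rank_error = function(e) e)
    if (!inherits(result, "condition")) {
      return(result)
    }
    last <- result
  }
  ftp_error("ftp_construction_error", sprintf(
    "construction failed after %d restarts; last error: %s",
    max_restarts, conditionMessage(last)))
}
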