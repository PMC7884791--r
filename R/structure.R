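#' Orthonormal basis of the null space of C
#'
#' Any weight perturbation `DW = ker(C) %*% Msc` leaves `C W = U` intact, so
#' the affine space `W + ker(C) Msc` collects every network with the same
#' stimulus-response mapping (the isofunction space). The basis columns are
#' the right singular vectors of `C` past its rank; its dimension is
#' `N - rank(C)` with `N = n_in + n_rec`.
#'
#' @param C Coefficient matrix of a validated system.
#' @param tol Relative singular-value tolerance.
#' @return Matrix of orthonormal columns (possibly zero columns).
#' @export
null_space_basis <- function(C, tol = 1e-10) {
  sv <- svd(C, nu = 0, nv = ncol(C))
  r <- sum(sv$d > tol * sv$d[1])
  if (r >= ncol(C)) {
    return(matrix(0, ncol(C), 0))
  }
  sv$v[, (r + 1):ncol(C), drop = FALSE]
}

#' Sample the isofunction space of a network
#'
#' Returns a network with identical stimulus-response behaviour whose
#' weights are `W + ker(C) %*% Msc`, where `Msc` has entries
#' `r_ij * max|W|` with `r_ij` uniform on `[-1, 1]` (so the perturbation
#' stays within the scale of the original weights). These are the "task"
#' (T) networks: they still solve the task but are no longer the
#' minimum-norm solution.
#'
#' @param net A `binary_network`.
#' @param C Coefficient matrix of the system the network solves.
#' @return A `binary_network`.
#' @export
sample_isofunction <- function(net, C) {
  kerC <- null_space_basis(C)
  if (ncol(kerC) == 0) {
    ftp_error("ftp_no_null_space_error",
              "C has full column rank: the solution is unique")
  }
  W <- full_weights(net)
  scale <- max(abs(W))
  Msc <- matrix(stats::runif(ncol(kerC) * ncol(W), -1, 1) * scale,
                ncol(kerC), ncol(W))
  W2 <- W + kerC %*% Msc
  meta <- net$meta
  meta$kind <- paste0(meta$kind %||% "", "_isofunction")
  new_binary_network(W2, net$theta, net$Z, meta)
}

#' Structural-constraint options
#'
#' @param forbid_self Remove self-connections of integration neurons.
#' @param ex_in_ratio Integer pair `c(ex, in)` (e.g. `c(4, 1)`), or `NULL`
#'   to let the excitatory/inhibitory split fall where the weights dictate.
#' @param sparsity Minimum fraction of exactly-zero weights in `[0, 1)`.
#' @param e1 Success threshold on the loss (mean absolute desired change).
#' @param e2 Relative-improvement threshold below which descent stalls.
#' @param e_clip_max Bound on the mean activation error after clipping.
#' @param max_iter Iteration cap of the projected descent.
#' @param dale_inputs Also subject input rows to Dale's principle (off by
#'   default: input neurons carry no type).
#' @return A list of class `constraint_options`.
#' @export
constraint_options <- function(forbid_self = TRUE, ex_in_ratio = NULL,
                               sparsity = 0, e1 = 1e-3, e2 = 1e-4,
                               e_clip_max = 1e-3, max_iter = 2000,
                               dale_inputs = FALSE) {
  stopifnot(sparsity >= 0, sparsity < 1, e1 > 0, e2 > 0, e_clip_max > 0)
  if (!is.null(ex_in_ratio)) {
    stopifnot(length(ex_in_ratio) == 2, all(ex_in_ratio >= 0),
              sum(ex_in_ratio) > 0)
  }
  structure(
    list(forbid_self = forbid_self, ex_in_ratio = ex_in_ratio,
         sparsity = sparsity, e1 = e1, e2 = e2, e_clip_max = e_clip_max,
         max_iter = max_iter, dale_inputs = dale_inputs,
         dale = !is.null(ex_in_ratio)),
    class = "constraint_options")
}

# Excitatory/inhibitory labels from summed outgoing weights (rows of W_rec),
# re-labelled at the |eta| closest to zero to honour a requested Ex:In ratio.
classify_neuron_types <- function(W, n_in, opts) {
  n_rec <- ncol(W)
  eta <- rowSums(W[(n_in + 1):nrow(W), , drop = FALSE])
  types <- ifelse(eta > 0, "Ex", "In")
  if (!is.null(opts$ex_in_ratio)) {
    n_ex <- as.integer(round(n_rec * opts$ex_in_ratio[1] / sum(opts$ex_in_ratio)))
    if (n_ex > n_rec) {
      stop("requested more excitatory neurons than available")
    }
    have_ex <- sum(types == "Ex")
    if (have_ex < n_ex) {
      # flip the inhibitory neurons whose eta is closest to zero
      flip <- order(ifelse(types == "Ex", Inf, abs(eta)))[seq_len(n_ex - have_ex)]
      types[flip] <- "Ex"
    } else if (have_ex > n_ex) {
      flip <- order(ifelse(types == "In", Inf, abs(eta)))[seq_len(have_ex - n_ex)]
      types[flip] <- "In"
    }
  }
  list(types = types, eta = eta)
}

#' Desired structural weight change
#'
#' Builds `DW_d = DW_self + DW_Dale + DW_sp` on the current weights:
#' `DW_self` negates the recurrent self-connections; `DW_Dale` negates
#' entries whose sign conflicts with the presynaptic integration neuron's
#' type (types from the sign of summed outgoing weights on
#' `W_c1 = W + DW_self`, re-labelled to meet a requested Ex:In ratio);
#' `DW_sp` negates the surviving entries of `W_c2 = W_c1 + DW_Dale` whose
#' magnitude falls below the sparsity-percentile of the surviving absolute
#' values. `W_d = W + DW_d` satisfies the constraints exactly but is in
#' general no longer a solution of the system; the projected descent in
#' [constrain_structure()] moves toward it inside the null space.
#'
#' @param W Weight matrix `(n_in + n_rec) x n_rec`.
#' @param opts A `constraint_options`.
#' @param n_in Number of input rows (default 2).
#' @return List with `dw_d`, `mask` (logical matrix of entries the
#'   constraints drive to zero), `neuron_types`.
#' @export
compute_delta_wd <- function(W, opts, n_in = 2L) {
  n_rec <- ncol(W)
  stopifnot(nrow(W) == n_in + n_rec)
  dw <- matrix(0, nrow(W), n_rec)
  mask <- matrix(FALSE, nrow(W), n_rec)
  # self-connections: entry (n_in + j, j)
  if (opts$forbid_self) {
    idx <- cbind(n_in + seq_len(n_rec), seq_len(n_rec))
    dw[idx] <- -W[idx]
    mask[idx] <- TRUE
  }
  w_c1 <- W + dw
  types <- NULL
  if (opts$dale) {
    cls <- classify_neuron_types(w_c1, n_in, opts)
    types <- cls$types
    in_types <- if (opts$dale_inputs) {
      ifelse(rowSums(w_c1[seq_len(n_in), , drop = FALSE]) > 0, "Ex", "In")
    } else {
      rep(NA_character_, n_in)
    }
    row_types <- c(in_types, types)
    bad <- (!is.na(row_types) & row_types == "Ex" & w_c1 < 0) |
      (!is.na(row_types) & row_types == "In" & w_c1 > 0)
    bad <- bad & !mask
    dw[bad] <- dw[bad] - w_c1[bad]
    mask <- mask | bad
  }
  w_c2 <- W + dw
  if (opts$sparsity > 0) {
    surviving <- abs(w_c2[!mask])
    k <- ceiling(opts$sparsity * length(surviving))  # nearest-rank percentile
    if (k >= 1) {
      alpha <- sort(surviving)[k]
      small <- !mask & abs(w_c2) <= alpha
      dw[small] <- dw[small] - w_c2[small]
      mask <- mask | small
    }
  }
  list(dw_d = dw, mask = mask, neuron_types = types)
}

#' Impose structural constraints by projected gradient descent
#'
#' Iterates: classify neuron types, compute the desired change `DW_d`,
#' project it onto the null space of `C`
#' (`DW = ker(C) %*% (t(ker(C)) %*% DW_d)`, the least-squares-closest
#' function-preserving change), update `W`, and evaluate the loss
#' `L(k) = mean(|DW_d|)`. Success requires both criteria at once: the loss
#' below `e1` and, after clipping all constraint-violating entries to
#' exactly zero, a clipping error `e_clip = mean(|C W_sc - U|)` below
#' `e_clip_max`. Because `e_clip` accumulates the per-entry violations
#' column-wise through `C` while the loss dilutes them over all weight
#' entries, the first crossing of `e1` always leaves `e_clip` roughly an
#' order of magnitude larger; the descent therefore continues below `e1`
#' (it converges geometrically once the active constraint sets freeze)
#' until the clipped weights also reproduce `U`, or until the relative
#' improvement `(L(k-1) - L(k)) / L(k)` drops below `e2` (stall). Clipping
#' errors below the bound can never flip a firing state (activation margins
#' are at least 1/2), so a successfully constrained network replays the
#' original dynamics exactly.
#'
#' @param net A `binary_network`.
#' @param system The `linear_system` it solves.
#' @param opts A `constraint_options`.
#' @return A list of class `constraint_report`: `status` (`"success"`,
#'   `"stalled"` or `"clip_rejected"`), `loss_trajectory`, `iterations`,
#'   `e_clip`, `neuron_types`, `w_constrained`, `network` (the constrained
#'   `binary_network`, `NULL` unless successful).
#' @export
constrain_structure <- function(net, system, opts = constraint_options()) {
  stopifnot(inherits(net, "binary_network"), inherits(system, "linear_system"))
  n_in <- nrow(net$w_in)
  W <- full_weights(net)
  kerC <- null_space_basis(system$C)
  loss <- numeric(0)
  cd <- compute_delta_wd(W, opts, n_in)
  loss[1] <- mean(abs(cd$dw_d))  # L(0), before the first update
  clip_error <- function(W, mask) {
    W_sc <- W
    W_sc[mask] <- 0
    mean(abs(system$C %*% W_sc - system$U))
  }
  status <- "running"
  e_clip <- NA_real_
  if (loss[1] <= opts$e1) {
    e_clip <- clip_error(W, cd$mask)
    if (e_clip <= opts$e_clip_max) status <- "success"
  }
  k <- 0L
  while (status == "running" && k < opts$max_iter) {
    k <- k + 1L
    if (ncol(kerC) > 0) {
      W <- W + kerC %*% crossprod(kerC, cd$dw_d)
    }
    cd <- compute_delta_wd(W, opts, n_in)
    loss[k + 1L] <- mean(abs(cd$dw_d))
    # success needs both criteria: the loss below e1 AND a clipping error
    # below its bound; the descent therefore continues below e1 until the
    # clipped weights also reproduce U, or until it stalls
    if (loss[k + 1L] <= opts$e1) {
      e_clip <- clip_error(W, cd$mask)
      if (e_clip <= opts$e_clip_max) {
        status <- "success"
        break
      }
    }
    if (loss[k + 1L] <= 0) {
      status <- "success"
      e_clip <- clip_error(W, cd$mask)
      break
    }
    if ((loss[k] - loss[k + 1L]) / loss[k + 1L] < opts$e2) {
      status <- if (loss[k + 1L] <= opts$e1) "clip_rejected" else "stalled"
      break
    }
  }
  if (status == "running") {
    status <- if (loss[k + 1L] <= opts$e1) "clip_rejected" else "stalled"
  }
  constrained <- NULL
  W_sc <- NULL
  if (status == "success") {
    W_sc <- W
    W_sc[cd$mask] <- 0
    e_clip <- clip_error(W, cd$mask)
    meta <- net$meta
    meta$kind <- paste0(meta$kind %||% "", "_constrained")
    meta$neuron_types <- cd$neuron_types
    constrained <- new_binary_network(W_sc, net$theta, net$Z, meta)
  }
  structure(
    list(status = status, loss_trajectory = loss, iterations = k,
         e_clip = e_clip, neuron_types = cd$neuron_types,
         w_constrained = W_sc, network = constrained),
    class = "constraint_report")
}

#' Construct a structurally constrained network, retrying on failure
#'
#' Not every minimum-norm network admits the requested constraints: the
#' descent may stall or the clipping error may be rejected, in which case a
#' fresh network is drawn. The attempt count (number of networks consumed
#' until the first success, including the successful one) is the efficiency
#' measure of the procedure.
#'
#' @param tau,n_rec,f_r,target_fr,f_cc Construction parameters, as in
#'   [construct_network()].
#' @param graph Optional transition graph (otherwise the s-task graph).
#' @param opts A `constraint_options`.
#' @param max_attempts Cap on fresh networks (default 50).
#' @return The successful `constraint_report`, with `attempts` and the
#'   originating `fit` (network + system) attached.
#' @export
build_constrained_network <- function(tau = NULL, n_rec = NULL, f_r = 1,
                                      target_fr = 0.5, f_cc = 1,
                                      graph = NULL,
                                      opts = constraint_options(),
                                      max_attempts = 50) {
  for (attempt in seq_len(max_attempts)) {
    fit <- construct_network(graph = graph, tau = tau, n_rec = n_rec,
                             f_r = f_r, target_fr = target_fr, f_cc = f_cc)
    report <- constrain_structure(fit$network, fit$system, opts)
    if (report$status == "success") {
      report$attempts <- attempt
      report$fit <- fit
      return(report)
    }
  }
  ftp_error("ftp_construction_error", sprintf(
    "no network accepted the structural constraints in %d attempts",
    max_attempts))
}
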