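#' Save and load networks
#'
#' A network is stored as a JSON manifest holding the metadata and the
#' thresholds, next to tab-separated matrix files (full 17-digit precision,
#' header row of column indices) for `w_in`, `w_rec` and the stored firing
#' states. The round trip is bit-identical on all matrices.
#'
#' @param net A `binary_network`.
#' @param path Manifest path, e.g. `"net.json"`; matrix files are written
#'   alongside with suffixes `_w_in.tsv`, `_w_rec.tsv`, `_Z.tsv`.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "binary_network"))
  stem <- sub("\\.json$", "", path)
  write_tsv_matrix(net$w_in, paste0(stem, "_w_in.tsv"))
  write_tsv_matrix(net$w_rec, paste0(stem, "_w_rec.tsv"))
  if (!is.null(net$Z)) write_tsv_matrix(net$Z, paste0(stem, "_Z.tsv"))
  manifest <- list(
    format = "ftpnet_network",
    theta = net$theta,
    meta = net$meta,
    files = list(w_in = basename(paste0(stem, "_w_in.tsv")),
                 w_rec = basename(paste0(stem, "_w_rec.tsv")),
                 Z = if (!is.null(net$Z)) basename(paste0(stem, "_Z.tsv")))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  manifest <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                       error = function(e) {
                         stop("malformed network file '", path, "': ",
                              conditionMessage(e))
                       })
  for (field in c("format", "theta", "files")) {
    if (is.null(manifest[[field]])) {
      stop("malformed network file: missing field '", field, "'")
    }
  }
  dir <- dirname(path)
  w_in <- read_tsv_matrix(file.path(dir, manifest$files$w_in))
  w_rec <- read_tsv_matrix(file.path(dir, manifest$files$w_rec))
  Z <- if (!is.null(manifest$files$Z)) {
    read_tsv_matrix(file.path(dir, manifest$files$Z))
  }
  theta <- as.numeric(manifest$theta)
  if (length(theta) != ncol(w_rec) || nrow(w_rec) != ncol(w_rec) ||
      ncol(w_in) != ncol(w_rec)) {
    stop("inconsistent network file: theta has length ", length(theta),
         " but w_rec is ", nrow(w_rec), " x ", ncol(w_rec))
  }
  meta <- manifest$meta
  if (!is.null(meta) && is.list(meta)) meta <- lapply(meta, identity)
  new_binary_network(rbind(w_in, w_rec), theta, Z, meta)
}

write_tsv_matrix <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- seq_len(ncol(m))
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file missing: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Save and load transition graphs
#'
#' Graphs are stored as a single JSON file with the edge list as
#' `[source, stimulus, target]` triples (1-based) and the delta-chain
#' pairing.
#'
#' @param graph A `transition_graph`.
#' @param path Output path.
#' @return `path` / the loaded `transition_graph`.
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "transition_graph"))
  m_states <- graph$n_states
  triples <- cbind(rep(seq_len(m_states), each = 2), rep(1:2, m_states),
                   as.integer(t(graph$edges)))
  obj <- list(format = "ftpnet_graph", n_states = m_states, tau = graph$tau,
              kind = graph$kind, f_bc = graph$f_bc,
              edges = unname(apply(triples, 1, as.list)),
              chains = lapply(graph$chains, as.integer))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("format", "n_states", "edges", "chains")) {
    if (is.null(obj[[field]])) {
      stop("malformed graph file: missing field '", field, "'")
    }
  }
  edges <- matrix(0L, obj$n_states, 2)
  tr <- if (is.list(obj$edges)) do.call(rbind, lapply(obj$edges, unlist)) else
    obj$edges
  edges[cbind(tr[, 1], tr[, 2])] <- as.integer(tr[, 3])
  chains <- lapply(obj$chains, as.integer)
  g <- new_transition_graph(obj$n_states, obj$tau, obj$kind, edges, chains,
                            f_bc = obj$f_bc %||% 0)
  g$bicoloured <- bicoloured_states(edges)
  g
}

#' Save a simulation trace as TSV
#'
#' Columns: `t`, `stimulus`, `state_id`, then one binary firing column per
#' neuron.
#'
#' @param trace A `simulation_trace`.
#' @param path Output path.
#' @export
save_trace <- function(trace, path) {
  df <- data.frame(t = seq_along(trace$stimuli), stimulus = trace$stimuli,
                   state_id = trace$state_ids)
  firing <- as.data.frame(trace$raster)
  names(firing) <- paste0("z", seq_len(ncol(firing)))
  utils::write.table(cbind(df, firing), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Deterministic toy instances for tests and documentation
#'
#' `toy_stask` is the worked example of the package: a tau = 3 network of 8
#' integration neurons that solves the sequence-memory task perfectly.
#' `toy_random` follows a random transition graph with bicoloured states
#' (no sequence memory). `constrained` is a tau = 3, 64-neuron network with
#' self-connections removed, Dale's principle at 4:1 and 40% sparsity.
#'
#' @param kind One of `"toy_stask"`, `"toy_random"`, `"constrained"`.
#' @param seed Seed for all randomness.
#' @return A list with `network`, `system`, `trace` (and `report` for the
#'   constrained kind).
#' @export
make_fixture <- function(kind = c("toy_stask", "toy_random", "constrained"),
                         seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "toy_stask") {
    fit <- construct_network(tau = 3, n_rec = 8)
    trace <- simulate_network(fit$network, random_stimuli(83), burn_in = 3)
    list(network = fit$network, system = fit$system, trace = trace)
  } else if (kind == "toy_random") {
    graph <- build_random_graph(4, f_bc = 0.5)
    fit <- construct_network(graph = graph, n_rec = 16)
    trace <- simulate_network(fit$network, random_stimuli(164), burn_in = 4)
    list(network = fit$network, system = fit$system, trace = trace)
  } else {
    report <- build_constrained_network(
      tau = 3, n_rec = 64, target_fr = 0.5,
      opts = constraint_options(forbid_self = TRUE, ex_in_ratio = c(4, 1),
                                sparsity = 0.4))
    trace <- simulate_network(report$network, random_stimuli(83),
                              burn_in = 3)
    list(network = report$network, system = report$fit$system,
         trace = trace, report = report)
  }
}
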