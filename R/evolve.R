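#' Firing statistics of a state set
#'
#' Firing rate and mean pairwise Spearman correlation of the firing matrix
#' `Z`, treating every network state as an equiprobable sample. This is the
#' cheap proxy used by the genetic algorithm: no simulation is needed
#' because under uniform stimuli each state of the sequence-memory task is
#' visited equally often. Constant columns contribute correlation 0.
#'
#' @param Z Binary firing matrix (states by neurons, >= 2 each).
#' @return List with `fr` and `cc`.
#' @export
state_statistics <- function(Z) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) >= 2, ncol(Z) >= 2)
  list(fr = mean(Z), cc = mean_upper(spearman_matrix(Z)))
}

#' Genetic-algorithm options
#'
#' @param pop_size Population size (default 200).
#' @param parent_fraction Fraction kept as parents (default 0.1).
#' @param mutation_sd Standard deviation of the additive Gaussian mutation
#'   applied to activation-base entries (default 0.1).
#' @param elitism Number of unmutated elite copies per generation
#'   (default 1).
#' @param f_target Mean-fitness stopping threshold (default 0.95).
#' @param max_generations Generation cap.
#' @param fr_target,cc_target Firing-rate and absolute-correlation targets.
#' @return A list of class `ga_options`.
#' @export
ga_options <- function(pop_size = 200, parent_fraction = 0.1,
                       mutation_sd = 0.1, elitism = 1, f_target = 0.95,
                       max_generations = 200, fr_target = 0.5,
                       cc_target = 0) {
  stopifnot(pop_size >= 2, parent_fraction > 0, parent_fraction <= 1,
            elitism >= 0, elitism < pop_size)
  structure(
    list(pop_size = as.integer(pop_size), parent_fraction = parent_fraction,
         mutation_sd = mutation_sd, elitism = as.integer(elitism),
         f_target = f_target, max_generations = as.integer(max_generations),
         fr_target = fr_target, cc_target = cc_target),
    class = "ga_options")
}

#' Fitness of an activation-base individual
#'
#' Expands the individual along the graph (deterministic placement so
#' fitness is reproducible), runs the validity checks, and returns
#' `1 - (|FR - FR_target| + ||CC| - |CC_target||) / 2` from the
#' equal-probability state statistics. Any failure (duplicate firing
#' states, rank defect) maps to fitness 0.
#'
#' @param individual A list with `u_base` and `theta` (an
#'   `activation_base` works as is).
#' @param graph The target `transition_graph`.
#' @param opts A `ga_options` (supplies the targets).
#' @return Fitness in `[0, 1]`.
#' @export
individual_fitness <- function(individual, graph, opts) {
  base <- individual
  if (!inherits(base, "activation_base")) {
    base <- structure(individual, class = "activation_base")
  }
  out <- tryCatch({
    exp <- expand_activations(base, graph, placement = "first")
    system <- assemble_system(graph, exp$u_lc, base$theta, exp$delta)
    st <- state_statistics(system$Z)
    1 - (abs(st$fr - opts$fr_target) +
           abs(abs(st$cc) - abs(opts$cc_target))) / 2
  }, ftp_error = function(e) 0)
  max(0, min(1, out))
}

#' Evolve activation bases toward firing-rate and correlation targets
#'
#' Mutation-only genetic algorithm over `(U_base, theta)` pairs. Each
#' generation keeps the `parent_fraction` fittest individuals, refills the
#' population with uniformly chosen parents mutated by additive zero-mean
#' Gaussian noise on the base entries (thresholds are never mutated, and
#' mutated entries are not re-rounded to the initialisation grid), and
#' carries unmutated elite copies. Evolution stops when the population mean
#' fitness exceeds `f_target`, or at `max_generations` with a warning.
#'
#' @param graph Target `transition_graph`.
#' @param n_rec Number of integration neurons.
#' @param opts A `ga_options`.
#' @return List with `elite` (best individual), `fitness` (its fitness),
#'   `history` (data frame of per-generation mean/max fitness),
#'   `converged`.
#' @export
ga_evolve <- function(graph, n_rec, opts = ga_options()) {
  m_states <- graph$n_states
  pop <- replicate(opts$pop_size, simplify = FALSE,
                   make_activation_base(m_states, n_rec,
                                        target_fr = opts$fr_target))
  fit <- vapply(pop, individual_fitness, numeric(1), graph = graph,
                opts = opts)
  n_parents <- max(1L, as.integer(round(opts$parent_fraction * opts$pop_size)))
  history <- data.frame(generation = integer(0), mean_fitness = numeric(0),
                        max_fitness = numeric(0))
  for (gen in seq_len(opts$max_generations)) {
    history[gen, ] <- list(gen, mean(fit), max(fit))
    if (mean(fit) > opts$f_target) {
      best <- which.max(fit)
      return(list(elite = pop[[best]], fitness = fit[best],
                  history = history, converged = TRUE))
    }
    parent_idx <- order(fit, decreasing = TRUE)[seq_len(n_parents)]
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(opts$elitism)]
    offspring <- vector("list", opts$pop_size)
    new_fit <- numeric(opts$pop_size)
    for (e in seq_len(opts$elitism)) {
      offspring[[e]] <- pop[[elite_idx[e]]]
      new_fit[e] <- fit[elite_idx[e]]
    }
    for (i in seq(opts$elitism + 1L, opts$pop_size)) {
      parent <- pop[[parent_idx[sample.int(n_parents, 1)]]]
      child <- parent
      child$u_base <- parent$u_base +
        matrix(stats::rnorm(length(parent$u_base), 0, opts$mutation_sd),
               nrow(parent$u_base), ncol(parent$u_base))
      child$delta <- child$f_cc * (child$u_base[2, ] - child$u_base[1, ])
      offspring[[i]] <- child
      new_fit[i] <- individual_fitness(child, graph, opts)
    }
    pop <- offspring
    fit <- new_fit
  }
  warning("genetic algorithm hit max_generations without reaching f_target")
  best <- which.max(fit)
  list(elite = pop[[best]], fitness = fit[best], history = history,
       converged = FALSE)
}
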