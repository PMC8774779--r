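# Genetic-algorithm learning of WHVDM attribute weights.
#
# A chromosome is a vector of non-negative real genes; the decoded weight
# vector is genes / sum(genes), which satisfies 0 <= w_i <= 1 and
# sum w_i = 1 by construction. Fitness of a chromosome is the number of
# correctly predicted test cases, sum_{t in T} I(y_t = y_s(t)), under 1-NN
# WHVDM with the decoded weights, the conditional-probability table being
# estimated from the reference set only.

#' Genetic-algorithm configuration
#'
#' @param population_size individuals per generation (default 50)
#' @param generations generation budget (default 100; the search stops early
#'   once fitness is perfect)
#' @param crossover_rate probability of arithmetic blend crossover (default 0.9)
#' @param mutation_rate per-gene probability of Gaussian mutation (default 0.1)
#' @param mutation_sd mutation standard deviation on the gene scale (default 0.05)
#' @param tournament_size tournament selection size (default 3)
#' @param elitism number of elite individuals carried over unchanged (default 1)
#' @param seed integer seed; identical seeds give bitwise-identical runs
#' @return list of class `ga_config`
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      mutation_sd = 0.05, tournament_size = 3,
                      elitism = 1, seed = 1) {
  stopifnot(population_size >= 1, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_sd >= 0, tournament_size >= 1,
            elitism >= 0, elitism < population_size)
  structure(list(population_size = population_size, generations = generations,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd, tournament_size = tournament_size,
                 elitism = elitism, seed = seed),
            class = "ga_config")
}

decode_chromosome <- function(genes) {
  s <- sum(genes)
  stopifnot(s > 0)
  weight_vector(genes / s)
}

#' Fitness of a weight chromosome
#'
#' Counts the correctly predicted test cases under 1-NN WHVDM with the
#' decoded weights: sum_{t in T} I(y_t = y_s(t)), an integer in [0, |T|].
#'
#' @param genes non-negative gene vector (length = number of attributes)
#' @param reference,test labeled `case_base` objects sharing a schema
#' @param config a [distance_config()]
#' @return integer count of correct predictions
#' @export
fitness <- function(genes, reference, test, config = distance_config()) {
  if (!n_cases(reference) || !n_cases(test)) stop("reference and test must be non-empty")
  ev <- evaluate(reference, test, decode_chromosome(genes), config)
  ev$n_correct
}

#' Learn WHVDM attribute weights with a genetic algorithm
#'
#' Maximizes the number of correctly predicted test cases. The population
#' is initialized from a flat Dirichlet (plus one uniform-weights
#' individual), evolved by tournament selection, arithmetic blend
#' crossover, additive Gaussian mutation clipped at 0, and single-elite
#' carryover; with elitism >= 1 the best-so-far fitness trace is monotone
#' non-decreasing. The search stops early when fitness reaches |T|.
#'
#' With a single attribute the weight vector is forced to (1) by the
#' simplex constraint and no search is run.
#'
#' @param reference,test labeled `case_base` objects; the test set should be
#'   held out from the reference set (leakage-safe default); resubstitution
#'   (`test = reference`) is permitted but not recommended
#' @param ga a [ga_config()]
#' @param dist a [distance_config()]
#' @return list with `weights` (best-ever [weight_vector()]), `fitness`
#'   (its test-set count), `trace` (data.frame `generation`, `best`, `mean`)
#' @export
learn_weights <- function(reference, test, ga = ga_config(),
                          dist = distance_config()) {
  n_attr <- nrow(reference$schema)
  n_test <- n_cases(test)
  if (length(reference$class_values) < 2)
    stop("weight learning needs at least 2 classes")
  if (n_attr == 1) {
    w <- weight_vector(1)
    return(list(weights = w, fitness = fitness(1, reference, test, dist),
                trace = data.frame(generation = 0L,
                                   best = fitness(1, reference, test, dist),
                                   mean = fitness(1, reference, test, dist))))
  }
  set.seed(ga$seed)
  # precompute per-attribute component matrices once; each fitness
  # evaluation is then a single matrix-vector product plus an argmin
  nr <- normalize_continuous(reference)
  ref_n <- nr$base
  test_n <- apply_normalization(test, nr$map)
  table <- if (dist$metric == "whvdm")
    estimate_cond_probs(ref_n, alpha = dist$alpha) else NULL
  stacked <- stack_components(component_matrices(test_n, ref_n, table, dist))
  truth <- test_n$y
  eval_genes <- function(genes) {
    w <- genes / sum(genes)
    pred <- nn_predict_from_stack(stacked, w, n_test, n_cases(ref_n), ref_n$y)
    sum(pred == truth, na.rm = TRUE)
  }

  pop_size <- ga$population_size
  # flat Dirichlet via normalized Exp(1) draws, plus the uniform individual
  pop <- lapply(seq_len(pop_size), function(i) {
    g <- stats::rexp(n_attr)
    g / sum(g)
  })
  pop[[1]] <- rep(1 / n_attr, n_attr)
  fit <- vapply(pop, eval_genes, numeric(1))
  best_i <- which.max(fit)
  best <- list(genes = pop[[best_i]], fitness = fit[best_i])
  trace <- data.frame(generation = 0L, best = best$fitness, mean = mean(fit))

  tournament <- function() {
    idx <- sample.int(pop_size, ga$tournament_size, replace = TRUE)
    idx[which.max(fit[idx])]
  }
  for (gen in seq_len(ga$generations)) {
    if (best$fitness >= n_test) break
    new_pop <- vector("list", pop_size)
    ord <- order(fit, decreasing = TRUE)
    n_elite <- ga$elitism
    for (e in seq_len(n_elite)) new_pop[[e]] <- pop[[ord[e]]]
    for (k in seq(n_elite + 1, pop_size)) {
      p1 <- pop[[tournament()]]
      p2 <- pop[[tournament()]]
      child <- if (stats::runif(1) < ga$crossover_rate) {
        lam <- stats::runif(1)
        lam * p1 + (1 - lam) * p2
      } else p1
      mut <- stats::runif(n_attr) < ga$mutation_rate
      if (any(mut)) {
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, ga$mutation_sd)
        child <- pmax(child, 0)
      }
      if (sum(child) <= 0) child <- rep(1 / n_attr, n_attr)
      new_pop[[k]] <- child
    }
    pop <- new_pop
    fit <- vapply(pop, eval_genes, numeric(1))
    gi <- which.max(fit)
    if (fit[gi] > best$fitness) best <- list(genes = pop[[gi]], fitness = fit[gi])
    trace <- rbind(trace, data.frame(generation = gen, best = best$fitness,
                                     mean = mean(fit)))
  }
  list(weights = decode_chromosome(best$genes), fitness = best$fitness,
       trace = trace)
}

#' Stratified reference/test split
#'
#' Splits a labeled case base by class at the given reference proportion
#' (default 70/30), deterministically per seed.
#'
#' @param base a labeled `case_base`
#' @param prop_reference proportion assigned to the reference set
#' @param seed integer seed
#' @return list with `reference` and `test` case bases
#' @export
split_case_base <- function(base, prop_reference = 0.7, seed = 1) {
  set.seed(seed)
  n <- n_cases(base)
  ref_idx <- logical(n)
  for (a in unique(base$y)) {
    idx <- which(base$y %in% a)
    n_ref <- max(1, round(length(idx) * prop_reference))
    take <- sample(idx, min(n_ref, length(idx)))
    ref_idx[take] <- TRUE
  }
  list(reference = base[ref_idx], test = base[!ref_idx])
}
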