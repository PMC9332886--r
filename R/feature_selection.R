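# Objective feature selection and genetic-algorithm subset search with
# leave-one-out Q2 fitness.

#' Objective feature selection
#'
#' Activity-blind pruning of a descriptor matrix in three deterministic
#' passes: (1) constant columns; (2) near-constant columns, i.e. columns
#' whose most frequent value covers more than `near_constant_prop` of the
#' rows; (3) greedy correlation pruning — columns are scanned in input
#' order and a column is dropped when its absolute Pearson correlation with
#' any earlier surviving column exceeds `corr_threshold` (the earlier
#' column is kept).
#'
#' @param X numeric matrix or `descriptor_matrix`.
#' @param near_constant_prop dominance share above which a column counts as
#'   near-constant (default 0.95).
#' @param corr_threshold absolute-correlation threshold (default 0.90).
#' @return list with `X` (reduced matrix) and `removal_log` (data frame:
#'   descriptor, reason, partner — the retained correlate, where relevant).
#' @export
objective_feature_selection <- function(X, near_constant_prop = 0.95,
                                        corr_threshold = 0.90) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  X <- as.matrix(X)
  if (anyNA(X)) stop("descriptor matrix contains missing values")
  if (is.null(colnames(X))) colnames(X) <- sprintf("d%d", seq_len(ncol(X)))
  log_rows <- list()
  drop_col <- function(name, reason, partner = NA_character_) {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(descriptor = name, reason = reason, partner = partner,
                 stringsAsFactors = FALSE)
  }
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  for (nm in colnames(X)[const]) drop_col(nm, "constant")
  X <- X[, !const, drop = FALSE]
  near <- apply(X, 2, function(v) max(table(v)) / length(v) > near_constant_prop)
  for (nm in colnames(X)[near]) drop_col(nm, "near_constant")
  X <- X[, !near, drop = FALSE]
  if (ncol(X) > 1) {
    cm <- abs(stats::cor(X))
    keep <- logical(ncol(X))
    for (j in seq_len(ncol(X))) {
      earlier <- which(keep)
      hit <- earlier[cm[earlier, j] > corr_threshold]
      if (length(hit)) {
        drop_col(colnames(X)[j], "correlated", colnames(X)[hit[1]])
      } else keep[j] <- TRUE
    }
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0)
    stop("objective feature selection removed every descriptor")
  removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(descriptor = character(), reason = character(),
               partner = character())
  list(X = X, removal_log = removal_log,
       settings = list(near_constant_prop = near_constant_prop,
                       corr_threshold = corr_threshold))
}

#' GA configuration
#'
#' @param population_size number of chromosomes (descriptor subsets).
#' @param n_generations generations to evolve.
#' @param crossover_rate probability a pair undergoes one-point crossover.
#' @param mutation_rate per-gene probability of replacement by a random
#'   non-member descriptor.
#' @param elitism number of best chromosomes copied unchanged.
#' @param local_search polish the final best subset by best-improvement
#'   swap sweeps until no single-descriptor swap raises fitness.
#' @param seed RNG seed.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 50, n_generations = 100,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      elitism = 2, local_search = TRUE, seed = 1L) {
  stopifnot(population_size >= 1, n_generations >= 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(population_size = population_size,
                 n_generations = n_generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, elitism = elitism,
                 local_search = local_search, seed = seed),
            class = "ga_config")
}

#' Genetic-algorithm descriptor-subset selection
#'
#' Searches fixed-size descriptor subsets maximizing leave-one-out Q2 of
#' the OLS model on the training data. Chromosomes are sorted index sets;
#' selection is binary tournament, crossover is one-point on the sorted
#' lists with duplicate repair by random resampling, and the elite is
#' carried unchanged (so best fitness is monotone over generations).
#' Rank-deficient candidate subsets receive fitness -Inf. Optionally the
#' final subset is polished by best-improvement swap sweeps.
#'
#' @param X training descriptor matrix (columns are candidates).
#' @param y training response.
#' @param k subset size.
#' @param cfg a [ga_config()].
#' @return list with `subset` (column indices), `descriptors` (names),
#'   `fitness` (Q2_LOO of the returned subset), `log` (data frame:
#'   generation, best, mean) and `cfg`.
#' @export
ga_select <- function(X, y, k, cfg = ga_config()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(k >= 1, p >= k)
  if (n <= k + 2) stop("need n_train > k + 2")
  tss <- sum((y - mean(y))^2)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fit_of <- function(idx) {
    key <- paste(idx, collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- .q2_loo_fitness(X, y, idx, tss)
      cache[[key]] <- v
    }
    v
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  pop <- replicate(cfg$population_size, sort(sample.int(p, k)),
                   simplify = FALSE)
  fitness <- vapply(pop, fit_of, 0)
  log <- data.frame(generation = 0L, best = max(fitness),
                    mean = mean(fitness[is.finite(fitness)]))
  mutate <- function(idx) {
    hit <- stats::runif(k) < cfg$mutation_rate
    if (!any(hit)) return(idx)
    avail <- setdiff(seq_len(p), idx)
    idx[hit] <- sample(avail, sum(hit))
    sort(idx)
  }
  crossover <- function(a, b) {
    if (k == 1L || stats::runif(1) >= cfg$crossover_rate) return(list(a, b))
    cut <- sample.int(k - 1L, 1L)
    repair <- function(child) {
      child <- unique(child)
      if (length(child) < k)
        child <- c(child, sample(setdiff(seq_len(p), child),
                                 k - length(child)))
      sort(child)
    }
    list(repair(c(a[seq_len(cut)], b[(cut + 1L):k])),
         repair(c(b[seq_len(cut)], a[(cut + 1L):k])))
  }
  tournament <- function() {
    ij <- sample.int(cfg$population_size, 2L, replace = TRUE)
    pop[[ij[which.max(fitness[ij])]]]
  }
  for (gen in seq_len(cfg$n_generations)) {
    elite_idx <- order(fitness, decreasing = TRUE)[
      seq_len(min(cfg$elitism, cfg$population_size))]
    nextgen <- pop[elite_idx]
    while (length(nextgen) < cfg$population_size) {
      kids <- crossover(tournament(), tournament())
      nextgen <- c(nextgen, lapply(kids, mutate))
    }
    pop <- nextgen[seq_len(cfg$population_size)]
    fitness <- vapply(pop, fit_of, 0)
    log <- rbind(log, data.frame(generation = gen, best = max(fitness),
                                 mean = mean(fitness[is.finite(fitness)])))
  }
  best <- pop[[which.max(fitness)]]
  best_fit <- max(fitness)
  if (isTRUE(cfg$local_search)) {
    repeat {
      improved <- FALSE
      for (pos in seq_len(k)) {
        cand <- setdiff(seq_len(p), best)
        trial_fit <- vapply(cand, function(cc) {
          fit_of(sort(c(best[-pos], cc)))
        }, 0)
        j <- which.max(trial_fit)
        if (trial_fit[j] > best_fit + 1e-12) {
          best <- sort(c(best[-pos], cand[j]))
          best_fit <- trial_fit[j]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  list(subset = best, descriptors = colnames(X)[best], fitness = best_fit,
       log = log, cfg = cfg)
}

#' GA selection across model sizes
#'
#' Runs [ga_select()] for k = 1..`k_max` and returns the per-size best
#' fitness curve alongside the training R2 of each best subset, the inputs
#' the breaking-point rule reads.
#'
#' @param X,y training data.
#' @param k_max largest subset size to consider.
#' @param cfg a [ga_config()]; seed is offset per k for independence.
#' @return list with `results` (per-k [ga_select()] outputs), `curve`
#'   (data frame: k, Q2_LOO, R2).
#' @export
ga_select_sizes <- function(X, y, k_max, cfg = ga_config()) {
  results <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k
    results[[k]] <- ga_select(X, y, k, cfg_k)
  }
  r2_of <- function(res) {
    m <- fit_ols(as.matrix(X)[, res$subset, drop = FALSE], y)
    m$stats$R2
  }
  curve <- data.frame(k = seq_len(k_max),
                      Q2_LOO = vapply(results, `[[`, 0, "fitness"),
                      R2 = vapply(results, r2_of, 0))
  list(results = results, curve = curve)
}

#' Breaking-point choice of model size
#'
#' Reads the fitness-versus-size curve and returns the smallest k at which
#' adding one more descriptor raises Q2_LOO by less than `eps` — the
#' explicit form of choosing the knee of the plot. If every gain exceeds
#' `eps` the largest size is returned with a warning.
#'
#' @param q2 numeric vector of best Q2_LOO per subset size k = 1, 2, ...
#' @param eps minimum worthwhile gain (default 0.02).
#' @return chosen k (integer).
#' @export
breaking_point <- function(q2, eps = 0.02) {
  stopifnot(length(q2) >= 1)
  if (length(q2) == 1L) return(1L)
  gains <- diff(q2)
  hit <- which(gains < eps)
  if (!length(hit)) {
    warning("no plateau: Q2 gains never fall below eps; returning k_max")
    return(length(q2))
  }
  hit[1]
}
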