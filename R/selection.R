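# Rank-based AUC of scores against 0/1 labels (ties counted 1/2).
# Used as the wrapper-selection fitness; the evaluation-report AUC is
# computed from the vote-threshold ROC instead (see roc_votes()).
score_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes required to compute an AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Relief feature relevance scores
#'
#' Classic binary Relief: features are min-max scaled to `[0, 1]`; for
#' each instance the `k` nearest hits (same class) and `k` nearest misses
#' (other class) under Manhattan distance are found, and each feature's
#' weight accumulates the mean near-miss difference minus the mean
#' near-hit difference.  Higher weights mark features that separate the
#' classes locally; a constant feature scores exactly 0 and duplicated
#' features score identically.
#'
#' @param x numeric feature matrix (or `pixel_vectors`).
#' @param y 0/1 labels (taken from `x` when it is a `pixel_vectors`).
#' @param k_neighbors near hits/misses per instance.
#' @return Named numeric vector of per-feature weights.
#' @export
relief_scores <- function(x, y = NULL, k_neighbors = 10) {
  if (inherits(x, "pixel_vectors")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (min(table(y)) < 2)
    stop("Relief needs at least two instances per class")
  mins <- apply(x, 2, min)
  rngs <- apply(x, 2, max) - mins
  rngs[rngs <= 0] <- 1
  xs <- sweep(sweep(x, 2, mins), 2, rngs, "/")
  # constant features contribute 0 by construction (all diffs are 0)
  d <- as.matrix(stats::dist(xs, method = "manhattan"))
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff <- which(y != y[i])
    kh <- same[order(d[i, same])][seq_len(min(k_neighbors, length(same)))]
    km <- diff[order(d[i, diff])][seq_len(min(k_neighbors, length(diff)))]
    hit_diff <- colMeans(abs(sweep(xs[kh, , drop = FALSE], 2, xs[i, ])))
    miss_diff <- colMeans(abs(sweep(xs[km, , drop = FALSE], 2, xs[i, ])))
    w <- w + (miss_diff - hit_diff)
  }
  w <- w / n
  names(w) <- colnames(x)
  w
}

#' Genetic-algorithm wrapper configuration
#'
#' Hyperparameters of the wrapper search.  The published pipeline reports
#' the selected subset size (15) but not the GA settings, so conventional
#' defaults are used: population 40, 50 generations, one-point crossover
#' at rate 0.8, per-bit mutation at rate `1/n_features`, tournament
#' selection of size 3, elitism 1.  Fitness is the mean stratified
#' `cv_folds`-fold cross-validated AUC of the downstream network trained
#' for `fitness_epochs` cycles on the candidate subset.  When
#' `subset_size_target` is set (default 15), the returned subset is
#' reduced/padded to exactly that size by ranked gene frequency in the
#' final population; `NULL` leaves the cardinality free.
#'
#' @param population_size,generations,crossover_rate,mutation_rate,
#'   tournament_size,elitism GA settings (`mutation_rate = NULL` means
#'   `1/n_features`).
#' @param subset_size_target exact subset size to return, or `NULL`.
#' @param cv_folds folds of the fitness cross-validation.
#' @param fitness_epochs training cycles of the reduced-budget network
#'   used inside the fitness.
#' @param hidden hidden width of the fitness network.
#' @return List of class `ga_control`.
#' @export
ga_control <- function(population_size = 40, generations = 50,
                       crossover_rate = 0.8, mutation_rate = NULL,
                       tournament_size = 3, elitism = 1,
                       subset_size_target = 15, cv_folds = 3,
                       fitness_epochs = 30, hidden = 10) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 subset_size_target = subset_size_target,
                 cv_folds = as.integer(cv_folds),
                 fitness_epochs = as.integer(fitness_epochs),
                 hidden = as.integer(hidden)),
            class = "ga_control")
}

#' Select a feature subset with a genetic-algorithm wrapper
#'
#' Searches binary chromosomes (one bit per feature) for the subset that
#' maximises the cross-validated AUC of the downstream pixel classifier.
#' Elitism makes the best fitness non-decreasing across generations; the
#' search is deterministic given the seed; repeated chromosomes are
#' memoised so each distinct subset is evaluated once.
#'
#' @param x feature matrix or `pixel_vectors`.
#' @param y 0/1 labels (from `x` when it is a `pixel_vectors`).
#' @param control a [ga_control()].
#' @param seed integer seed.
#' @return Object of class `feature_subset`: `mask` (logical over
#'   columns), `names`, `fitness` (CV AUC of the returned subset),
#'   `history` (best fitness per generation) and `control`.
#' @export
ga_select <- function(x, y = NULL, control = ga_control(), seed = 1) {
  if (inherits(x, "pixel_vectors")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present for feature selection")
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  mut <- if (is.null(control$mutation_rate)) 1 / p else control$mutation_rate
  fold <- stratified_folds(y, control$cv_folds, seed)

  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (!any(mask)) {
      cache[[key]] <- 0
      return(0)
    }
    xs <- x[, mask, drop = FALSE]
    aucs <- vapply(seq_len(control$cv_folds), function(kf) {
      tr <- fold != kf
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
        return(0.5)
      mins <- apply(xs[tr, , drop = FALSE], 2, min)
      rngs <- apply(xs[tr, , drop = FALSE], 2, max) - mins
      rngs[rngs <= 0] <- 1
      xtr <- sweep(sweep(xs[tr, , drop = FALSE], 2, mins), 2, rngs, "/")
      xte <- sweep(sweep(xs[!tr, , drop = FALSE], 2, mins), 2, rngs, "/")
      fit <- mlp_train_cpp(xtr, as.numeric(y[tr]), control$hidden,
                           control$fitness_epochs, 0.01, 1e-12,
                           as.integer(seed))
      score_auc(mlp_forward(fit, xte), y[!tr])
    }, numeric(1))
    val <- mean(aucs)
    cache[[key]] <- val
    val
  }

  with_seed(seed, {
    pop <- matrix(stats::runif(control$population_size * p) < 0.5,
                  control$population_size, p)
    pop[rowSums(pop) == 0, sample(p, 1)] <- TRUE
    fit_vals <- apply(pop, 1, fitness)
    history <- numeric(control$generations)
    for (gen in seq_len(control$generations)) {
      ord <- order(-fit_vals)
      newpop <- pop[ord[seq_len(control$elitism)], , drop = FALSE]
      while (nrow(newpop) < control$population_size) {
        pick <- function() {
          cand <- sample(control$population_size, control$tournament_size)
          cand[which.max(fit_vals[cand])]
        }
        pa <- pop[pick(), ]
        pb <- pop[pick(), ]
        if (stats::runif(1) < control$crossover_rate && p > 1) {
          cut <- sample(p - 1, 1)
          child1 <- c(pa[seq_len(cut)], pb[(cut + 1):p])
          child2 <- c(pb[seq_len(cut)], pa[(cut + 1):p])
        } else {
          child1 <- pa
          child2 <- pb
        }
        for (child in list(child1, child2)) {
          flip <- stats::runif(p) < mut
          child <- xor(child, flip)
          if (!any(child)) child[sample(p, 1)] <- TRUE
          if (nrow(newpop) < control$population_size)
            newpop <- rbind(newpop, child)
        }
      }
      pop <- newpop
      fit_vals <- apply(pop, 1, fitness)
      history[gen] <- max(fit_vals)
    }

    best <- pop[which.max(fit_vals), ]
    target <- control$subset_size_target
    if (!is.null(target)) {
      # rank genes: members of the best mask first, then by frequency in
      # the final population, index as the last tie-break
      freq <- colMeans(pop)
      rank_ord <- order(-(best * 1), -freq, seq_len(p))
      chosen <- rank_ord[seq_len(min(target, p))]
      best <- rep(FALSE, p)
      best[chosen] <- TRUE
    }
    structure(list(mask = as.logical(best),
                   names = colnames(x)[best],
                   fitness = fitness(as.logical(best)),
                   history = history,
                   control = control),
              class = "feature_subset")
  })
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("Feature subset: %d features (CV AUC fitness %.3f)\n",
              sum(x$mask), x$fitness))
  cat("  ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}
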