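#' Configuration for the intelligent genetic algorithm
#'
#' Defaults follow the published protocol for this method: population 40,
#' full mating pool (ps = 1), mutation probability 0.01, 20 generations,
#' fitness weights (0.9, 0.1) on cross-validated AUC and amino-acid
#' conservation, 10-fold cross-validation. `oa_factors` is the number of
#' contiguous gene blocks used by the orthogonal-array crossover (15 blocks
#' pair with the two-level L16 array).
#'
#' @param npop population size (>= 2).
#' @param ps fraction of the population selected into the mating pool.
#' @param pm per-gene mutation probability in \[0, 1\].
#' @param generations number of generations.
#' @param w1,w2 fitness weights on AUC and R; `w1 + w2` must be positive.
#' @param k_folds cross-validation folds used inside the fitness.
#' @param seed master seed driving population init, folds, selection,
#'   crossover and mutation.
#' @param oa_factors number of crossover blocks.
#' @return object of class `iga_config`.
#' @export
iga_config <- function(npop = 40L, ps = 1.0, pm = 0.01, generations = 20L,
                       w1 = 0.9, w2 = 0.1, k_folds = 10L, seed = 1L,
                       oa_factors = 15L) {
  if (npop < 2L) .stop_input("npop must be >= 2")
  if (pm < 0 || pm > 1) .stop_input("pm must be in [0, 1]")
  if (ps <= 0 || ps > 1) .stop_input("ps must be in (0, 1]")
  if (w1 + w2 <= 0) .stop_input("w1 + w2 must be positive")
  if (k_folds < 2L) .stop_input("k_folds must be >= 2")
  if (oa_factors < 1L || oa_factors > 400L) .stop_input("oa_factors must be in [1, 400]")
  structure(list(npop = as.integer(npop), ps = ps, pm = pm,
                 generations = as.integer(generations), w1 = w1, w2 = w2,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 oa_factors = as.integer(oa_factors)),
            class = "iga_config")
}

# Precomputed context shared by all fitness evaluations of one run: the
# composition matrix, the soluble indicator, fixed stratified fold ids and
# the initial amino-acid scores the R term is anchored to.
.fitness_context <- function(train, cfg, initial_aa) {
  if (!all(c("soluble", "insoluble") %in% train$label)) {
    .stop_input("training set must contain both classes")
  }
  fold <- withr::with_seed(cfg$seed, .kfold_ids(train$label, cfg$k_folds))
  list(M = composition_matrix(train$sequence), sol = train$label == "soluble",
       fold = fold, k = cfg$k_folds, initial_aa = as.numeric(initial_aa),
       w1 = cfg$w1, w2 = cfg$w2)
}

.eval_genes <- function(genes, ctx) {
  s <- as.vector(ctx$M %*% genes)
  aucs <- vapply(seq_len(ctx$k), function(f) {
    v <- ctx$fold == f
    roc_auc(s[v], ctx$sol[v])
  }, numeric(1L))
  r <- pearson_r(.aa_scores_vec(genes), ctx$initial_aa)
  sel <- select_threshold(s, ctx$sol)
  pred <- s > sel$threshold
  fitness_result(auc = mean(aucs), r = r, w1 = ctx$w1, w2 = ctx$w2,
                 train_accuracy = sel$accuracy,
                 sensitivity = sum(pred & ctx$sol) / sum(ctx$sol),
                 specificity = sum(!pred & !ctx$sol) / sum(!ctx$sol),
                 threshold = sel$threshold)
}

#' Fitness of a candidate score card
#'
#' The multi-objective fitness `w1 * AUC + w2 * R`: AUC is the mean of the
#' validation-fold AUCs of the candidate's sequence scores under a stratified
#' k-fold partition of the training set (the candidate card itself needs no
#' per-fold refitting, only its evaluation is cross-validated); R is the
#' Pearson correlation between the candidate's derived amino-acid scores and
#' the initial card's. The threshold and the remaining summary metrics are
#' computed on the pooled training scores.
#'
#' @param genes numeric vector of 400 scores in \[0, 1000\].
#' @param train a [labeled_dataset] with both classes.
#' @param cfg an [iga_config] (supplies weights, folds and the fold seed).
#' @param initial_aa the 20 initial amino-acid scores
#'   ([amino_acid_scores] of the initial card).
#' @return a [fitness_result].
#' @export
scm_fitness <- function(genes, train, cfg, initial_aa) {
  .eval_genes(as.numeric(genes), .fitness_context(train, cfg, initial_aa))
}

# Two-level orthogonal array with 2^ceiling(log2(f+1)) rows: entry (r, c) is
# the parity of popcount(bitwAnd(r-1, c)) -- the Sylvester/Hadamard
# construction, every pair of columns balanced over the four level pairs.
.oa_two_level <- function(n_factors) {
  k <- ceiling(log2(n_factors + 1L))
  rows <- as.integer(2^k)
  parity <- function(x) {
    p <- 0L
    while (x > 0L) { p <- bitwXor(p, bitwAnd(x, 1L)); x <- bitwShiftR(x, 1L) }
    p
  }
  outer(seq_len(rows) - 1L, seq_len(n_factors), Vectorize(function(r, c) parity(bitwAnd(r, c))))
}

# contiguous block id (1..n_blocks) for each of the 400 gene positions
.gene_blocks <- function(n_blocks) {
  bounds <- floor(seq(0L, 400L, length.out = n_blocks + 1L))
  rep(seq_len(n_blocks), diff(bounds))
}

.individual <- function(genes, fit = NULL) list(genes = genes, fit = fit)

#' Orthogonal-array ("intelligent") crossover
#'
#' The 400 genes are partitioned into `oa_factors` contiguous blocks; a
#' two-level orthogonal array over the blocks (level 0: inherit the block
#' from `p1`; level 1: from `p2`) defines a small factorial design of
#' candidate offspring, all of which are evaluated. The first child is the
#' best array row; the second is the main-effect prediction (for each block,
#' the level whose rows average better fitness), evaluated as well. Every
#' child gene equals one parent's gene at that locus.
#'
#' @param p1,p2 evaluated individuals (`list(genes, fit)`).
#' @param evaluate function(genes) returning a [fitness_result].
#' @param oa_factors number of blocks.
#' @return list of two evaluated individuals.
#' @export
intelligent_crossover <- function(p1, p2, evaluate, oa_factors = 15L) {
  if (is.null(p1$fit) || is.null(p2$fit)) .stop_input("both parents must be evaluated")
  if (identical(p1$genes, p2$genes)) return(list(p1, p2))
  oa <- .oa_two_level(oa_factors)
  block <- .gene_blocks(oa_factors)
  rows <- lapply(seq_len(nrow(oa)), function(r) {
    lv <- oa[r, block]
    genes <- ifelse(lv == 0L, p1$genes, p2$genes)
    fit <- if (all(lv == 0L)) p1$fit
           else if (all(lv == 1L)) p2$fit
           else evaluate(genes)
    .individual(genes, fit)
  })
  fits <- vapply(rows, function(x) x$fit$fitness, numeric(1L))
  c1 <- rows[[which.max(fits)]]
  # main effects: per block, the level with the better mean fitness over rows
  best_level <- vapply(seq_len(oa_factors), function(b) {
    as.integer(mean(fits[oa[, b] == 1L]) > mean(fits[oa[, b] == 0L]))
  }, integer(1L))
  lv2 <- best_level[block]
  genes2 <- ifelse(lv2 == 0L, p1$genes, p2$genes)
  match_row <- which(vapply(seq_len(nrow(oa)),
                            function(r) all(oa[r, ] == best_level), logical(1L)))
  c2 <- if (length(match_row) == 1L) rows[[match_row]]
        else .individual(genes2, evaluate(genes2))
  list(c1, c2)
}

#' Real-valued mutation
#'
#' Each gene independently, with probability `pm`, is replaced by a uniform
#' draw from \[0, 1000\]. If any gene changed the stored fitness is
#' invalidated.
#'
#' @param ind an individual (`list(genes, fit)`).
#' @param pm per-gene mutation probability.
#' @return the possibly mutated individual.
#' @export
mutate_individual <- function(ind, pm) {
  if (pm < 0 || pm > 1) .stop_input("pm must be in [0, 1]")
  if (pm == 0) return(ind)
  hit <- runif(length(ind$genes)) < pm
  if (any(hit)) {
    ind$genes[hit] <- runif(sum(hit), 0, 1000)
    ind$fit <- NULL
  }
  ind
}

# linear-rank selection without replacement: probability proportional to rank
.rank_select <- function(fitnesses, m) {
  sample(seq_along(fitnesses), m, prob = rank(fitnesses, ties.method = "average"))
}

#' Optimize a score card with the intelligent genetic algorithm
#'
#' The population is seeded with the initial card plus `npop - 1` uniform
#' random chromosomes. Each generation: a rank-based mating pool of size
#' `ps * npop` is drawn; every pool member is crossed with the incumbent best
#' individual by [intelligent_crossover]; of the two parents and two children
#' the best keeps (or takes) the incumbent slot and the runner-up takes the
#' pool member's slot, so the best fitness never decreases; all individuals
#' except the incumbent are then mutated at rate `pm` and re-evaluated if
#' changed. Identical seeds give identical results.
#'
#' @param initial a [score_card] (typically from [build_initial_ssm]).
#' @param train a [labeled_dataset] with both classes.
#' @param cfg an [iga_config].
#' @return list with `card` (the best card, threshold fitted on the pooled
#'   training scores, provenance `"optimized"`), `fit` (its
#'   [fitness_result]) and `log` (data.frame of best fitness per generation).
#' @export
optimize_ssm <- function(initial, train, cfg) {
  ctx <- .fitness_context(train, cfg, amino_acid_scores(initial))
  ev <- function(genes) .eval_genes(genes, ctx)
  res <- withr::with_seed(cfg$seed, {
    pop <- c(list(.individual(unname(initial$scores))),
             lapply(seq_len(cfg$npop - 1L), function(i) .individual(runif(400L, 0, 1000))))
    pop <- lapply(pop, function(p) { p$fit <- ev(p$genes); p })
    b <- which.max(vapply(pop, function(p) p$fit$fitness, numeric(1L)))
    log <- data.frame(generation = integer(0L), best_fitness = numeric(0L))
    for (gen in seq_len(cfg$generations)) {
      fits <- vapply(pop, function(p) p$fit$fitness, numeric(1L))
      pool <- .rank_select(fits, max(1L, round(cfg$ps * cfg$npop)))
      for (i in pool) {
        if (i == b) next  # crossing the incumbent with itself is a no-op
        ch <- intelligent_crossover(pop[[i]], pop[[b]], ev, cfg$oa_factors)
        cand <- c(list(pop[[i]], pop[[b]]), ch)
        ord <- order(vapply(cand, function(x) x$fit$fitness, numeric(1L)),
                     decreasing = TRUE)
        pop[[b]] <- cand[[ord[1L]]]
        pop[[i]] <- cand[[ord[2L]]]
      }
      for (i in seq_len(cfg$npop)) {
        if (i == b) next  # mutation spares the incumbent best
        pop[[i]] <- mutate_individual(pop[[i]], cfg$pm)
        if (is.null(pop[[i]]$fit)) pop[[i]]$fit <- ev(pop[[i]]$genes)
        if (pop[[i]]$fit$fitness > pop[[b]]$fit$fitness) b <- i
      }
      log <- rbind(log, data.frame(generation = gen,
                                   best_fitness = pop[[b]]$fit$fitness))
    }
    list(best = pop[[b]], log = log)
  })
  card <- score_card(res$best$genes, threshold = res$best$fit$threshold,
                     provenance = list(type = "optimized", seed = cfg$seed,
                                       w1 = cfg$w1, w2 = cfg$w2,
                                       train_accuracy = res$best$fit$train_accuracy))
  list(card = card, fit = res$best$fit, log = res$log)
}

#' Select the best card over independent optimizer runs
#'
#' Genetic algorithms are stochastic; the published protocol therefore runs
#' the optimizer several times with different seeds and keeps the card with
#' the highest training accuracy. The per-run summary table (one row per run
#' plus mean and standard-deviation rows) mirrors the method's run-log
#' format.
#'
#' @param train a [labeled_dataset].
#' @param cfg an [iga_config]; run r uses seed `cfg$seed + r - 1`.
#' @param n_runs number of independent runs (>= 1).
#' @param test optional held-out [labeled_dataset]; when given, each run's
#'   test accuracy is reported.
#' @return list with `card` (best run's card), `fit`, `runs` (the summary
#'   data.frame) and `initial` (the shared initial card).
#' @export
multi_run_select <- function(train, cfg, n_runs = 10L, test = NULL) {
  if (n_runs < 1L) .stop_input("n_runs must be >= 1")
  initial <- build_initial_ssm(train)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    runs[[r]] <- optimize_ssm(initial, train, cfg_r)
  }
  rows <- do.call(rbind, lapply(runs, function(x) as.data.frame(x$fit)))
  if (!is.null(test)) {
    rows$test_pct <- vapply(runs, function(x) {
      100 * unname(confusion_metrics(predict_solubility(test, x$card), test$label)["accuracy"])
    }, numeric(1L))
  }
  best <- which.max(rows$train_pct)
  summary <- rbind(cbind(run = as.character(seq_len(n_runs)), rows),
                   cbind(run = "mean", as.data.frame(lapply(rows, mean))),
                   cbind(run = "sd", as.data.frame(lapply(rows, sd))))
  list(card = runs[[best]]$card, fit = runs[[best]]$fit, runs = summary,
       initial = initial)
}
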