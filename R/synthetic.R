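#' Planted dipeptide-propensity model for synthetic two-class data
#'
#' Defines a pair of first-order Markov chains over residues whose transition
#' weights are tilted in opposite directions by a planted per-dipeptide
#' propensity: the soluble class favors dipeptide d proportionally to
#' `exp(+effect_size * propensity(d))`, the insoluble class proportionally to
#' `exp(-effect_size * propensity(d))`. At `effect_size = 0` the two classes
#' are exchangeable. Base residue usage is uniform.
#'
#' @param propensity numeric vector of 400 planted biases in the
#'   [DIPEPTIDES] order; `NULL` (default) draws standard-normal biases under
#'   `seed`.
#' @param length_range integer pair (min, max) of sequence lengths, min >= 2.
#' @param effect_size nonnegative strength of the planted signal.
#' @param seed integer seed; generation is deterministic given the model.
#' @return object of class `planted_model`.
#' @export
planted_model <- function(propensity = NULL, length_range = c(100L, 300L),
                          effect_size = 1, seed = 1L) {
  if (is.null(propensity)) {
    propensity <- withr::with_seed(seed, stats::rnorm(400L))
  }
  propensity <- as.numeric(propensity)
  if (length(propensity) != 400L || anyNA(propensity)) {
    .stop_input("propensity must be 400 non-missing reals")
  }
  if (length(length_range) != 2L || length_range[1] < 2L ||
      length_range[2] < length_range[1]) {
    .stop_input("length_range must be (min >= 2, max >= min)")
  }
  if (effect_size < 0) .stop_input("effect_size must be >= 0")
  names(propensity) <- DIPEPTIDES
  structure(list(propensity = propensity,
                 length_range = as.integer(length_range),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "planted_model")
}

# 20 x 20 row-stochastic transition matrix tilted by sign * effect * propensity
.transition_matrix <- function(model, sign) {
  W <- exp(sign * model$effect_size *
             matrix(model$propensity, nrow = 20L, byrow = TRUE,
                    dimnames = list(AA_ALPHABET, AA_ALPHABET)))
  W / rowSums(W)
}

# vectorized chain sampling: all sequences advance in lockstep, drawing each
# next residue by inverse-CDF lookup in the class's cumulative transition rows
.sample_chain <- function(n, lengths, P) {
  cumP <- t(apply(P, 1L, cumsum))
  max_len <- max(lengths)
  res <- matrix(0L, nrow = n, ncol = max_len)
  res[, 1L] <- sample.int(20L, n, replace = TRUE)
  for (pos in 2:max_len) {
    active <- lengths >= pos
    if (!any(active)) break
    u <- runif(sum(active))
    res[active, pos] <- rowSums(cumP[res[active, pos - 1L], , drop = FALSE] <
                                  u) + 1L
  }
  vapply(seq_len(n), function(i) {
    paste(AA_ALPHABET[res[i, seq_len(lengths[i])]], collapse = "")
  }, character(1L))
}

#' Generate a labeled dataset with planted dipeptide biases
#'
#' @param n_sol,n_ins class sizes (>= 1 each).
#' @param model a [planted_model].
#' @return a [labeled_dataset] with ids `sol_1..` / `ins_1..`; identical
#'   model (including seed) gives an identical dataset.
#' @export
generate_planted_dataset <- function(n_sol, n_ins, model) {
  if (!inherits(model, "planted_model")) .stop_input("model must be a planted_model")
  if (n_sol < 1L || n_ins < 1L) .stop_input("class sizes must be >= 1")
  withr::with_seed(model$seed, {
    len <- sample(seq(model$length_range[1], model$length_range[2]),
                  n_sol + n_ins, replace = TRUE)
    sol <- .sample_chain(n_sol, len[seq_len(n_sol)], .transition_matrix(model, +1))
    ins <- .sample_chain(n_ins, len[n_sol + seq_len(n_ins)], .transition_matrix(model, -1))
    labeled_dataset(id = c(paste0("sol_", seq_len(n_sol)), paste0("ins_", seq_len(n_ins))),
                    sequence = c(sol, ins),
                    label = rep(c("soluble", "insoluble"), c(n_sol, n_ins)))
  })
}

#' Write a synthetic dataset as a FASTA pair plus a model file
#'
#' @param ds a [labeled_dataset].
#' @param model the generating [planted_model].
#' @param prefix output path prefix; writes `<prefix>_soluble.fasta`,
#'   `<prefix>_insoluble.fasta` and `<prefix>_model.tsv`.
#' @return invisibly, the three paths.
#' @export
write_planted_dataset <- function(ds, model, prefix) {
  sol <- ds$sequence[ds$label == "soluble"]
  names(sol) <- ds$id[ds$label == "soluble"]
  ins <- ds$sequence[ds$label == "insoluble"]
  names(ins) <- ds$id[ds$label == "insoluble"]
  paths <- paste0(prefix, c("_soluble.fasta", "_insoluble.fasta", "_model.tsv"))
  write_fasta(sol, paths[1]); write_fasta(ins, paths[2])
  hdr <- c(sprintf("# effect_size\t%.17g", model$effect_size),
           sprintf("# length_range\t%d\t%d", model$length_range[1], model$length_range[2]),
           sprintf("# seed\t%d", model$seed), "dipeptide\tpropensity")
  writeLines(c(hdr, sprintf("%s\t%.17g", DIPEPTIDES, model$propensity)), paths[3])
  invisible(paths)
}

#' Rank agreement between planted and learned propensities
#'
#' Spearman rank correlation between the model's planted propensity and a
#' learned card's scores, restricted to dipeptides observed at least
#' `min_count` times in the dataset the card was built from (never-seen
#' dipeptides get their score from normalization alone and would only add
#' noise).
#'
#' @param model the generating [planted_model].
#' @param card the [score_card] learned from data under `model`.
#' @param dataset the [labeled_dataset] the card was built from (supplies
#'   the observed-count filter).
#' @param min_count minimum pooled observation count (default 5).
#' @return list with `rho` (Spearman correlation) and `n_used` (dipeptides
#'   retained by the filter).
#' @export
recovery_report <- function(model, card, dataset, min_count = 5L) {
  counts <- class_dipeptide_counts(dataset$sequence)$counts
  keep <- counts >= min_count
  if (sum(keep) < 10L) .stop_degenerate("too few dipeptides observed >= ", min_count, " times")
  rho <- cor(model$propensity[keep], card$scores[keep], method = "spearman")
  list(rho = rho, n_used = sum(keep))
}
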