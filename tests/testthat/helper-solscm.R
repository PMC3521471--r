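# shared fixtures and independent oracles, all built in code

tmp_fasta <- function(seqs, width = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    body <- if (is.null(width)) s else {
      starts <- seq(1L, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

random_card <- function() score_card(runif(400, 0, 1000))

random_toy_dataset <- function(n_sol, n_ins, len_range = c(5L, 30L)) {
  n <- n_sol + n_ins
  labeled_dataset(id = paste0("q", seq_len(n)),
                  sequence = vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                                    random_sequence, character(1L)),
                  label = rep(c("soluble", "insoluble"), c(n_sol, n_ins)))
}

# oracle: AUC by explicit pair counting over all soluble-insoluble pairs
auc_pair_counting <- function(scores, labels) {
  sol <- scores[labels == "soluble" | labels == TRUE]
  ins <- scores[labels == "insoluble" | labels == FALSE]
  total <- 0
  for (a in sol) for (b in ins) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sol) * length(ins))
}

# oracle: best accuracy by exhaustive scan over every observed score +/- eps
threshold_exhaustive <- function(scores, labels) {
  sol <- labels == "soluble" | labels == TRUE
  eps <- 1e-9 * max(1, diff(range(scores)))
  cand <- sort(unique(c(scores - eps, scores + eps,
                        min(scores) - 1, max(scores) + 1)))
  acc <- vapply(cand, function(t) mean((scores > t) == sol), numeric(1))
  max(acc)
}
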