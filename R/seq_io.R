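.NONSTANDARD <- c("B", "J", "O", "U", "X", "Z", "*")

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased on load. Records containing residues outside the
#' standard 20-letter alphabet (B, J, O, U, X, Z, stop codes, gaps) are
#' handled per `policy`: `"drop"` removes them with a warning and records the
#' kept/dropped counts in a `load_report` attribute; `"strict"` raises an
#' error on the first offending record. Records shorter than two residues are
#' treated the same way (a single residue carries no dipeptide).
#'
#' @param path FASTA file (wrapped or unwrapped lines, multi-record).
#' @param policy `"drop"` (default) or `"strict"`.
#' @return named character vector of sequences (ids as names), in file order,
#'   with attribute `load_report = c(kept =, dropped =)`.
#' @export
read_fasta <- function(path, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    .stop_input("cannot read FASTA file: ", paste(path, collapse = " "))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stop_input("malformed FASTA '", path, "': ",
                                                  conditionMessage(e)))
  if (length(set) == 0L) .stop_input("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  ok_alpha <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  ok_len <- nchar(seqs) >= 2L
  ok <- ok_alpha & ok_len
  if (!all(ok)) {
    bad <- ids[!ok]
    if (policy == "strict") {
      .stop_input("record(s) with non-standard residues or length < 2: ",
                  paste(utils::head(bad, 5L), collapse = ", "))
    }
    warning(sprintf("dropped %d of %d records (non-standard residues or length < 2): %s",
                    sum(!ok), length(ok), paste(utils::head(bad, 5L), collapse = ", ")),
            call. = FALSE)
  }
  out <- seqs[ok]
  attr(out, "load_report") <- c(kept = sum(ok), dropped = sum(!ok))
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(unclass(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a labeled two-class sequence dataset
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence character vector over the standard alphabet, lengths >= 2.
#' @param label character vector, each `"soluble"` or `"insoluble"`.
#' @return a `labeled_dataset`: a data.frame with columns id, sequence, label.
#' @export
labeled_dataset <- function(id, sequence, label) {
  id <- as.character(id); sequence <- as.character(sequence); label <- as.character(label)
  if (length(id) != length(sequence) || length(id) != length(label)) {
    .stop_input("id, sequence and label must have equal length")
  }
  if (anyDuplicated(id)) .stop_input("duplicate sequence ids: ",
                                     paste(unique(id[duplicated(id)])[1:min(3, sum(duplicated(id)))],
                                           collapse = ", "))
  if (!all(label %in% c("soluble", "insoluble"))) {
    .stop_input("labels must be 'soluble' or 'insoluble'")
  }
  if (any(nchar(sequence) < 2L)) .stop_input("all sequences must have length >= 2")
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad)) .stop_input("non-standard residues in sequence(s): ",
                            paste(utils::head(id[bad], 5L), collapse = ", "))
  structure(data.frame(id = id, sequence = sequence, label = label,
                       stringsAsFactors = FALSE),
            class = c("labeled_dataset", "data.frame"))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d sequences (%d soluble, %d insoluble)\n",
              nrow(x), sum(x$label == "soluble"), sum(x$label == "insoluble")))
  invisible(x)
}

#' Load a labeled dataset from a soluble and an insoluble FASTA file
#'
#' @param soluble_path FASTA of the soluble class.
#' @param insoluble_path FASTA of the insoluble class.
#' @param policy residue policy passed to [read_fasta].
#' @return a [labeled_dataset].
#' @export
load_labeled_dataset <- function(soluble_path, insoluble_path, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  sol <- read_fasta(soluble_path, policy)
  ins <- read_fasta(insoluble_path, policy)
  if (length(sol) == 0L) .stop_input("soluble class empty after filtering")
  if (length(ins) == 0L) .stop_input("insoluble class empty after filtering")
  dup <- intersect(names(sol), names(ins))
  if (length(dup) > 0L) .stop_input("id(s) present in both classes: ",
                                    paste(utils::head(dup, 5L), collapse = ", "))
  labeled_dataset(id = c(names(sol), names(ins)),
                  sequence = c(unname(sol), unname(ins)),
                  label = rep(c("soluble", "insoluble"), c(length(sol), length(ins))))
}

.subset_ds <- function(ds, idx) {
  structure(as.data.frame(ds)[idx, , drop = FALSE],
            class = c("labeled_dataset", "data.frame"))
}

# round-half-up; base round() rounds half to even
.round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Splits each class independently, taking `round-half-up(fraction * n)` of
#' each class into the training part. The same seed always yields the same
#' partition; the union of the two parts is the input dataset.
#'
#' @param ds a [labeled_dataset] with both classes present.
#' @param train_fraction real in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both labeled datasets.
#' @export
split_dataset <- function(ds, train_fraction, seed) {
  if (train_fraction <= 0 || train_fraction >= 1) .stop_input("train_fraction must be in (0,1)")
  counts <- table(factor(ds$label, levels = c("soluble", "insoluble")))
  if (any(counts < 2L)) .stop_input("each class needs at least 2 sequences to split")
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(c("soluble", "insoluble"), function(lab) {
      idx <- which(ds$label == lab)
      n_train <- .round_half_up(train_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)  # keep both parts nonempty
      sample(idx, n_train)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = .subset_ds(ds, train_idx),
       test = .subset_ds(ds, setdiff(seq_len(nrow(ds)), train_idx)))
}

# stratified fold ids, one per row of ds; folds balanced within each class
.kfold_ids <- function(labels, k) {
  fold <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold partition
#'
#' Every sequence appears in exactly one validation fold; per-fold class
#' proportions differ from the global proportions by at most one sequence per
#' class. Deterministic under `seed`.
#'
#' @param ds a [labeled_dataset].
#' @param k number of folds (>= 2, at most the smaller class size).
#' @param seed integer seed.
#' @return list of k elements, each `list(train =, validation =)`.
#' @export
kfold_partition <- function(ds, k, seed) {
  if (k < 2L) .stop_input("k must be >= 2")
  counts <- table(factor(ds$label, levels = c("soluble", "insoluble")))
  if (any(counts < k)) .stop_input("k exceeds the size of the smaller class")
  fold <- withr::with_seed(seed, .kfold_ids(ds$label, k))
  lapply(seq_len(k), function(f) {
    list(train = .subset_ds(ds, which(fold != f)),
         validation = .subset_ds(ds, which(fold == f)))
  })
}
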