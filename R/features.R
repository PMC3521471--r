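#' @importFrom stats cor runif var sd
#' @importFrom utils read.delim write.table
NULL

#' The 20 standard amino acids, alphabetical by one-letter code
#'
#' Residue order used everywhere in the package: score-card rows, composition
#' vectors, amino-acid score vectors and property scales all follow this order.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The 400 ordered dipeptides, first residue major
#'
#' Index order is first-residue-major, both residues alphabetical
#' (AA, AC, AD, ..., YW, YY). Score-card files and composition vectors share
#' this order, so cards written by one session are readable by another.
#' @export
DIPEPTIDES <- paste0(rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, 20L))

# 40 gene indices contributing to each residue's score: the 20 dipeptides AX
# plus the 20 dipeptides XA. The homodipeptide AA appears in both sets and
# therefore contributes twice to the 40-term mean (documented convention).
.aa_term_idx <- vapply(seq_len(20L), function(a) {
  c((a - 1L) * 20L + seq_len(20L), (seq_len(20L) - 1L) * 20L + a)
}, integer(40L))

.stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("scm_input_error", "error")))
}

.stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("scm_degenerate_error", "error")))
}

#' Count overlapping dipeptides in one sequence
#'
#' A sequence of length L has L-1 overlapping windows; each window is one
#' ordered dipeptide. Returns an integer vector of 400 counts in the
#' [DIPEPTIDES] order.
#'
#' @param sequence character scalar over the 20 standard residue codes.
#' @return named integer vector of length 400.
#' @export
dipeptide_counts <- function(sequence) {
  n <- nchar(sequence)
  if (n < 2L) .stop_input("sequence must have length >= 2")
  pos <- seq_len(n - 1L)
  pairs <- paste0(substring(sequence, pos, pos), substring(sequence, pos + 1L, pos + 1L))
  idx <- match(pairs, DIPEPTIDES)
  if (anyNA(idx)) .stop_input("sequence contains non-standard residues")
  counts <- tabulate(idx, nbins = 400L)
  names(counts) <- DIPEPTIDES
  counts
}

#' Dipeptide composition of a sequence
#'
#' The composition vector w has one weight per ordered dipeptide,
#' w_i = count_i / (L - 1); weights lie in \[0, 1\] and sum to 1.
#'
#' @param sequence character scalar over the standard 20-letter alphabet.
#' @return named numeric vector of length 400 summing to 1.
#' @examples
#' w <- dipeptide_composition("ACA")
#' w[c("AC", "CA")]   # 0.5 each
#' @export
dipeptide_composition <- function(sequence) {
  counts <- dipeptide_counts(sequence)
  counts / sum(counts)
}

#' Composition matrix for a set of sequences
#'
#' One row per sequence, 400 columns in the [DIPEPTIDES] order. This is the
#' workhorse representation: scoring a whole dataset against a card is a
#' single matrix-vector product.
#'
#' @param sequences character vector of sequences (each length >= 2).
#' @return numeric matrix, `length(sequences)` x 400.
#' @export
composition_matrix <- function(sequences) {
  m <- t(vapply(sequences, function(s) dipeptide_composition(s), numeric(400L)))
  dimnames(m) <- list(names(sequences), DIPEPTIDES)
  m
}

#' Pooled dipeptide counts over a class of sequences
#'
#' Counts are pooled over all sequences with overlapping windows; the total
#' equals the sum over sequences of (L - 1).
#'
#' @param sequences character vector (each length >= 2), or a
#'   [labeled_dataset] from which the `sequence` column is taken.
#' @return list with `counts` (named integer, 400) and `total` (integer).
#' @export
class_dipeptide_counts <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (length(sequences) == 0L) .stop_input("empty sequence set")
  counts <- Reduce(`+`, lapply(sequences, dipeptide_counts))
  list(counts = counts, total = sum(counts))
}

#' Derive per-residue scores from a dipeptide score card
#'
#' The score of residue A is the mean of the 40 card entries \{AX\} and \{XA\}
#' over all residues X; the homodipeptide AA contributes twice. This is the
#' amino-acid scoring matrix used for propensity analysis and for the
#' conservation term of the optimizer's fitness.
#'
#' @param card a [score_card], or a bare numeric vector of 400 scores.
#' @return named numeric vector of 20 residue scores.
#' @export
amino_acid_scores <- function(card) {
  scores <- if (inherits(card, "score_card")) card$scores else card
  if (length(scores) != 400L || anyNA(scores)) {
    .stop_input("card must supply 400 non-missing dipeptide scores")
  }
  out <- .aa_scores_vec(as.numeric(scores))
  names(out) <- AA_ALPHABET
  out
}

.aa_scores_vec <- function(genes) {
  colMeans(matrix(genes[.aa_term_idx], nrow = 40L, ncol = 20L))
}

#' Write composition vectors as a tab-delimited table
#'
#' @param compositions numeric matrix from [composition_matrix] (or a single
#'   composition vector).
#' @param path output file path.
#' @export
write_composition_table <- function(compositions, path) {
  if (is.null(dim(compositions))) compositions <- matrix(compositions, nrow = 1L,
                                                         dimnames = list(NULL, DIPEPTIDES))
  df <- data.frame(id = if (is.null(rownames(compositions))) seq_len(nrow(compositions))
                        else rownames(compositions),
                   compositions, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
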