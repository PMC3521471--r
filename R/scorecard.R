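#' Construct a score card
#'
#' A score card is the method's central artifact: 400 dipeptide propensity
#' scores in \[0, 1000\] plus an optional decision threshold. Larger scores
#' mark dipeptides whose presence pushes a sequence toward the soluble class.
#'
#' @param scores numeric vector of 400 scores in \[0, 1000\], in the
#'   [DIPEPTIDES] order (names optional, checked when present).
#' @param threshold decision cut-point, or `NA` if not yet fitted.
#' @param provenance list of free-form metadata (`type` is conventionally
#'   `"initial"` or `"optimized"`).
#' @return object of class `score_card`.
#' @export
score_card <- function(scores, threshold = NA_real_, provenance = list(type = "initial")) {
  scores <- as.numeric(unlist(scores))
  if (length(scores) != 400L || anyNA(scores)) .stop_input("a score card needs 400 non-missing scores")
  if (min(scores) < 0 || max(scores) > 1000) .stop_input("scores must lie in [0, 1000]")
  names(scores) <- DIPEPTIDES
  structure(list(scores = scores, threshold = as.numeric(threshold)[1L],
                 provenance = provenance),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("score_card (%s): 400 dipeptide scores in [%.1f, %.1f], threshold %s\n",
              if (is.null(x$provenance$type)) "?" else x$provenance$type,
              min(x$scores), max(x$scores),
              if (is.na(x$threshold)) "unset" else format(x$threshold)))
  invisible(x)
}

#' Min-max normalize raw propensities to \[0, 1000\]
#'
#' Linear map s_i = 1000 (raw_i - min) / (max - min). Adding a constant to
#' every raw value leaves the result unchanged; applying the map twice is a
#' no-op. A zero-range input (all values equal) is refused: such a card
#' carries no discriminating information.
#'
#' @param raw numeric vector (any length; the card pipeline passes 400).
#' @return numeric vector of the same length spanning \[0, 1000\] exactly.
#' @export
normalize_scores <- function(raw) {
  raw <- as.numeric(raw)
  if (anyNA(raw)) .stop_input("raw scores contain NA")
  rng <- range(raw)
  if (rng[1] == rng[2]) .stop_degenerate("all raw scores equal; card would be uninformative")
  # divide before scaling so the endpoints land on 0 and 1000 exactly
  (raw - rng[1]) / (rng[2] - rng[1]) * 1000
}

# raw per-dipeptide propensity: soluble composition minus insoluble composition
.raw_propensity <- function(counts_sol, total_sol, counts_ins, total_ins) {
  counts_sol / total_sol - counts_ins / total_ins
}

#' Build the initial statistical scoring matrix
#'
#' The coarse estimate of dipeptide propensity: for each dipeptide, the
#' difference between its composition in the soluble class and in the
#' insoluble class (pooled overlapping counts divided by the class's total
#' dipeptide count), min-max normalized to \[0, 1000\].
#'
#' @param train a [labeled_dataset] with both classes nonempty.
#' @return a [score_card] with provenance type `"initial"` and no threshold;
#'   fit one with [fit_threshold].
#' @export
build_initial_ssm <- function(train) {
  sol <- train$sequence[train$label == "soluble"]
  ins <- train$sequence[train$label == "insoluble"]
  if (length(sol) == 0L || length(ins) == 0L) .stop_input("both classes must be nonempty")
  cs <- class_dipeptide_counts(sol)
  ci <- class_dipeptide_counts(ins)
  if (cs$total == 0L || ci$total == 0L) .stop_degenerate("a class has zero dipeptides")
  raw <- .raw_propensity(cs$counts, cs$total, ci$counts, ci$total)
  score_card(normalize_scores(raw), provenance = list(type = "initial"))
}

#' Solubility score of sequences under a card
#'
#' The weighted sum S(P) = sum_i w_i S_i of the card's 400 scores with the
#' sequence's dipeptide composition as weights. Because the weights sum to 1,
#' S(P) always lies between the smallest and largest card score.
#'
#' @param sequences character vector of sequences (each length >= 2), or a
#'   [labeled_dataset].
#' @param card a [score_card].
#' @return numeric vector of scores, one per sequence.
#' @export
solubility_score <- function(sequences, card) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  as.vector(composition_matrix(sequences) %*% card$scores)
}

#' Accuracy-maximizing threshold for the rule "score > t => soluble"
#'
#' Candidate cut-points are the midpoints between consecutive distinct sorted
#' scores, plus one sentinel below the minimum and one above the maximum.
#' Among equally accurate candidates the smallest is returned.
#'
#' @param scores numeric vector of sequence scores.
#' @param labels matching labels (`"soluble"`/`"insoluble"` or logical
#'   soluble indicator).
#' @return list with `threshold` and `accuracy`.
#' @export
select_threshold <- function(scores, labels) {
  sol <- .as_soluble(labels)
  if (length(scores) < 2L) .stop_input("need at least 2 observations")
  if (length(scores) != length(sol)) .stop_input("scores and labels differ in length")
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
  acc <- vapply(cand, function(t) mean((scores > t) == sol), numeric(1L))
  best <- which.max(acc)  # first max; candidates ascending => smallest wins ties
  list(threshold = cand[best], accuracy = acc[best])
}

#' Fit a card's decision threshold on a labeled dataset
#'
#' @param card a [score_card].
#' @param ds a [labeled_dataset].
#' @return the card with `threshold` set to the accuracy-maximizing cut and
#'   `provenance$train_accuracy` recorded.
#' @export
fit_threshold <- function(card, ds) {
  sel <- select_threshold(solubility_score(ds, card), ds$label)
  card$threshold <- sel$threshold
  card$provenance$train_accuracy <- sel$accuracy
  card
}

#' Classify sequences against a card's threshold
#'
#' A sequence is soluble iff its score strictly exceeds the threshold; a
#' score exactly at the threshold is called insoluble.
#'
#' @param sequences character vector or [labeled_dataset].
#' @param card a [score_card] with a fitted threshold.
#' @return character vector of `"soluble"`/`"insoluble"`.
#' @export
predict_solubility <- function(sequences, card) {
  if (is.na(card$threshold)) .stop_input("card has no threshold; fit one first")
  ifelse(solubility_score(sequences, card) > card$threshold, "soluble", "insoluble")
}

#' Classify with an uncertainty region (reject option)
#'
#' Scores within `region_size / 2` of the threshold (the full region width is
#' `region_size`) are answered with `"abstain"`; others as in
#' [predict_solubility]. A width of 0 never abstains and reproduces
#' [predict_solubility] exactly.
#'
#' @inheritParams predict_solubility
#' @param region_size full width of the uncertainty band, >= 0.
#' @return character vector of `"soluble"`/`"insoluble"`/`"abstain"`.
#' @export
predict_with_uncertainty <- function(sequences, card, region_size) {
  if (is.na(card$threshold)) .stop_input("card has no threshold; fit one first")
  if (region_size < 0) .stop_input("region_size must be >= 0")
  s <- solubility_score(sequences, card)
  out <- ifelse(s > card$threshold, "soluble", "insoluble")
  if (region_size > 0) out[abs(s - card$threshold) <= region_size / 2] <- "abstain"
  out
}

#' @export
predict.score_card <- function(object, sequences, region_size = 0, ...) {
  if (region_size > 0) predict_with_uncertainty(sequences, object, region_size)
  else predict_solubility(sequences, object)
}

#' Write a score card to a tab-delimited file
#'
#' Two columns (dipeptide, score) over 400 rows, preceded by `#`-prefixed
#' header lines carrying the threshold and provenance. Scores are written
#' with 17 significant digits so that a read/write cycle is bit-exact.
#'
#' @param card a [score_card].
#' @param path output file path.
#' @export
write_score_card <- function(card, path) {
  hdr <- c(sprintf("# threshold\t%s",
                   if (is.na(card$threshold)) "NA" else sprintf("%.17g", card$threshold)),
           sprintf("# provenance\t%s",
                   if (is.null(card$provenance$type)) "unknown" else card$provenance$type),
           "dipeptide\tscore")
  body <- sprintf("%s\t%.17g", DIPEPTIDES, card$scores)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a score card written by [write_score_card]
#'
#' @param path score-card file.
#' @return a [score_card].
#' @export
read_score_card <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    .stop_input("cannot read score card: ", paste(path, collapse = " "))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get_field <- function(key) {
    m <- hdr[startsWith(hdr, paste0("# ", key))]
    if (length(m) == 0L) return(NA_character_)
    strsplit(m[1L], "\t", fixed = TRUE)[[1L]][2L]
  }
  threshold <- suppressWarnings(as.numeric(get_field("threshold")))
  prov_type <- get_field("provenance")
  body <- lines[!startsWith(lines, "#")]
  body <- body[body != "" & !startsWith(body, "dipeptide")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  dip <- vapply(parts, `[`, character(1L), 1L)
  val <- as.numeric(vapply(parts, `[`, character(1L), 2L))
  if (length(dip) != 400L || !setequal(dip, DIPEPTIDES) || anyNA(val)) {
    .stop_input("malformed score card file: ", path)
  }
  score_card(val[match(DIPEPTIDES, dip)], threshold = threshold,
             provenance = list(type = if (is.na(prov_type)) "unknown" else prov_type))
}

#' Score card as a 20 x 20 matrix (heat-map layout)
#'
#' Rows are the first residue of the dipeptide, columns the second, both in
#' the alphabetical residue order.
#'
#' @param card a [score_card].
#' @return 20 x 20 numeric matrix with residue dimnames.
#' @export
card_matrix <- function(card) {
  matrix(card$scores, nrow = 20L, ncol = 20L, byrow = TRUE,
         dimnames = list(first = AA_ALPHABET, second = AA_ALPHABET))
}
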