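#' Rank dipeptides by card score
#'
#' @param card a [score_card].
#' @param top_n how many dipeptides to return (<= 400).
#' @param decreasing `TRUE` (default) for the highest-scoring dipeptides,
#'   `FALSE` for the lowest. Ties are broken alphabetically either way.
#' @return data.frame with columns dipeptide, score, rank.
#' @export
rank_dipeptides <- function(card, top_n = 10L, decreasing = TRUE) {
  if (top_n < 1L || top_n > 400L) .stop_input("top_n must be in [1, 400]")
  ord <- order(if (decreasing) -card$scores else card$scores, DIPEPTIDES)
  idx <- ord[seq_len(top_n)]
  data.frame(dipeptide = DIPEPTIDES[idx], score = unname(card$scores[idx]),
             rank = seq_len(top_n))
}

#' Construct a physicochemical property vector
#'
#' One AAindex-style property scale: an identifier, a free-text description
#' and 20 per-residue values in the [AA_ALPHABET] order; individual values
#' may be `NA` (such properties are skipped by the correlation analyses).
#'
#' @param id short identifier (e.g. `"KUMS000103"`).
#' @param description free-text description; keyword grouping matches on it.
#' @param values numeric vector of exactly 20 values (NA allowed).
#' @return object of class `property_vector`.
#' @export
property_vector <- function(id, description, values) {
  values <- as.numeric(values)
  if (length(values) != 20L) .stop_input("a property needs exactly 20 values")
  names(values) <- AA_ALPHABET
  structure(list(id = as.character(id), description = as.character(description),
                 values = values),
            class = "property_vector")
}

#' Read a property table from a tab-delimited file
#'
#' Expected columns: `id`, `description`, then 20 value columns in the
#' [AA_ALPHABET] residue order. The string `NA` (or an empty field) marks a
#' missing value.
#'
#' @param path file path.
#' @return list of [property_vector] objects.
#' @export
read_property_table <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    .stop_input("cannot read property table: ", paste(path, collapse = " "))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 22L) .stop_input("property table needs id, description and 20 value columns")
  lapply(seq_len(nrow(tab)), function(i) {
    property_vector(tab$id[i], tab$description[i], as.numeric(tab[i, 3:22]))
  })
}

#' Correlation between amino-acid scores and one property scale
#'
#' Pearson correlation over the 20 residues. A property containing any `NA`
#' is not correlated: the return value is `NA` with attribute
#' `skipped = TRUE`, so downstream summaries can count discarded scales.
#'
#' @param aa named numeric vector of 20 amino-acid scores
#'   (from [amino_acid_scores]).
#' @param prop a [property_vector].
#' @return correlation, or `NA` carrying `attr(, "skipped") = TRUE`.
#' @export
property_correlation <- function(aa, prop) {
  if (anyNA(prop$values)) return(structure(NA_real_, skipped = TRUE))
  pearson_r(as.numeric(aa), as.numeric(prop$values))
}

#' Correlation summary over a keyword-matched property group
#'
#' Properties whose description contains `keyword` (case-insensitive
#' substring) are correlated against the amino-acid scores; properties with
#' missing values are skipped. Returns the group's count and the max, mean,
#' min and variance of the correlations.
#'
#' @param aa 20 amino-acid scores.
#' @param props list of [property_vector] objects.
#' @param keyword substring matched against descriptions.
#' @return list: keyword, n (correlated properties), r_max, r_mean, r_min,
#'   r_var, and `correlations` (named by property id).
#' @export
property_group_summary <- function(aa, props, keyword) {
  hits <- Filter(function(p) grepl(keyword, p$description, ignore.case = TRUE), props)
  rs <- vapply(hits, function(p) as.numeric(property_correlation(aa, p)), numeric(1L))
  names(rs) <- vapply(hits, function(p) p$id, character(1L))
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0L) .stop_input("no non-missing property matches keyword '", keyword, "'")
  list(keyword = keyword, n = length(rs), r_max = max(rs), r_mean = mean(rs),
       r_min = min(rs), r_var = if (length(rs) > 1L) var(rs) else 0,
       correlations = rs)
}

#' Per-class histogram of solubility scores
#'
#' Aligned half-open bins `[lo, hi)` of width `bin_width` covering
#' \[0, 1000\] (the last bin is closed so a score of exactly 1000 is
#' counted). Bin counts sum to the class sizes.
#'
#' @param scores numeric scores in \[0, 1000\].
#' @param labels matching labels.
#' @param bin_width positive bin width.
#' @return data.frame with columns bin_lo, bin_hi, soluble, insoluble.
#' @export
score_histogram <- function(scores, labels, bin_width = 50) {
  if (bin_width <= 0) .stop_input("bin_width must be positive")
  if (length(scores) == 0L) .stop_input("empty input")
  sol <- .as_soluble(labels)
  n_bins <- ceiling(1000 / bin_width)
  bin <- pmin(floor(scores / bin_width) + 1L, n_bins)  # last bin closed
  data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
             bin_hi = pmin(seq_len(n_bins) * bin_width, 1000),
             soluble = tabulate(bin[sol], n_bins),
             insoluble = tabulate(bin[!sol], n_bins))
}

#' Accuracy/coverage trade-off of the abstaining classifier
#'
#' For each uncertainty-region width, sequences scoring within half the width
#' of the threshold are left unclassified; accuracy is computed on the
#' remainder and coverage is the classified fraction. With no sequence left,
#' accuracy is `NA`.
#'
#' @param scores numeric sequence scores.
#' @param labels matching labels.
#' @param threshold decision threshold.
#' @param region_sizes numeric vector of full region widths (>= 0).
#' @return data.frame with columns region_size, coverage, accuracy.
#' @export
uncertainty_accuracy_curve <- function(scores, labels, threshold, region_sizes) {
  if (any(region_sizes < 0)) .stop_input("region sizes must be >= 0")
  sol <- .as_soluble(labels)
  rows <- lapply(region_sizes, function(sz) {
    keep <- abs(scores - threshold) > sz / 2
    data.frame(region_size = sz, coverage = mean(keep),
               accuracy = if (any(keep)) mean((scores[keep] > threshold) == sol[keep])
                          else NA_real_)
  })
  do.call(rbind, rows)
}

#' Positional dipeptide score profile of a sequence
#'
#' One entry per overlapping window: the 1-based position of the window's
#' first residue, the dipeptide, and its card score. The unweighted mean of
#' the profile scores equals the sequence's solubility score exactly.
#'
#' @param sequence character scalar of length >= 2.
#' @param card a [score_card].
#' @return data.frame with columns position, dipeptide, score (L - 1 rows).
#' @export
positional_score_profile <- function(sequence, card) {
  n <- nchar(sequence)
  if (n < 2L) .stop_input("sequence must have length >= 2")
  pos <- seq_len(n - 1L)
  dip <- paste0(substring(sequence, pos, pos), substring(sequence, pos + 1L, pos + 1L))
  idx <- match(dip, DIPEPTIDES)
  if (anyNA(idx)) .stop_input("sequence contains non-standard residues")
  data.frame(position = pos, dipeptide = dip, score = unname(card$scores[idx]))
}
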