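test_that("rank_dipeptides orders by score with alphabetical tie-break", {
  s <- rep(100, 400); names(s) <- DIPEPTIDES
  s[c("LA", "IP", "MC")] <- c(1000, 997, 991)
  card <- score_card(s)
  top <- rank_dipeptides(card, 3)
  expect_identical(top$dipeptide, c("LA", "IP", "MC"))
  expect_equal(top$score, c(1000, 997, 991))

  uniform <- score_card(rep(500, 400))
  expect_identical(rank_dipeptides(uniform, 5)$dipeptide, DIPEPTIDES[1:5])

  all400 <- rank_dipeptides(card, 400)
  expect_setequal(all400$dipeptide, DIPEPTIDES)
  expect_error(rank_dipeptides(card, 401), class = "scm_input_error")

  bottom <- rank_dipeptides(card, 2, decreasing = FALSE)
  expect_identical(bottom$dipeptide, c("AA", "AC"))
})

test_that("property correlation skips NA-containing scales and is affine invariant", {
  aa <- amino_acid_scores(random_card())
  self <- property_vector("SELF", "the scores themselves", unname(aa))
  expect_equal(property_correlation(aa, self), 1)

  holed <- property_vector("HOLED", "has a missing value",
                           replace(unname(aa), 7, NA))
  r <- property_correlation(aa, holed)
  expect_true(is.na(r))
  expect_true(attr(r, "skipped"))

  v <- rnorm(20)
  p1 <- property_vector("P1", "scale", v)
  p2 <- property_vector("P2", "rescaled", 4.2 * v + 11)
  expect_equal(property_correlation(aa, p1), property_correlation(aa, p2))
})

test_that("property group summary matches hand-computed statistics", {
  aa <- amino_acid_scores(random_card())
  v <- rnorm(20)
  props <- list(property_vector("X1", "alpha-helix propensity", unname(aa)),
                property_vector("X2", "Alpha-Helix frequency", v),
                property_vector("X3", "unrelated turn scale", rnorm(20)),
                property_vector("X4", "alpha-helix but missing", replace(v, 3, NA)))
  gs <- property_group_summary(aa, props, "alpha-helix")
  expect_identical(gs$n, 2L)                  # X3 keyword miss, X4 skipped
  rs <- c(1, pearson_r(as.numeric(aa), v))
  expect_equal(gs$r_max, max(rs))
  expect_equal(gs$r_mean, mean(rs))
  expect_equal(gs$r_min, min(rs))
  expect_equal(gs$r_var, var(rs))

  one <- property_group_summary(aa, props[2], "frequency")
  expect_equal(one$r_max, one$r_min)
  expect_equal(one$r_var, 0)
  expect_error(property_group_summary(aa, props, "nothing-matches"),
               class = "scm_input_error")
})

test_that("bundled property table carries the two published 20-value scales", {
  props <- read_property_table(system.file("extdata", "aa_properties.tsv",
                                           package = "solscm"))
  expect_length(props, 2)
  expect_identical(props[[2]]$id, "KUMS000103")
  expect_equal(unname(props[[1]]$values["A"]), 1.39)
  expect_equal(unname(props[[2]]$values[c("L", "A")]), c(9.1, 14.1))
  expect_false(anyNA(props[[1]]$values))
})

test_that("score histogram conserves per-class counts with half-open bins", {
  scores <- c(499.92, 500, 0, 1000, 250)
  labels <- c("soluble", "soluble", "insoluble", "insoluble", "insoluble")
  h <- score_histogram(scores, labels, 50)
  expect_equal(sum(h$soluble), 2)
  expect_equal(sum(h$insoluble), 3)
  expect_equal(h$soluble[h$bin_lo == 450], 1)   # 499.92 in [450, 500)
  expect_equal(h$soluble[h$bin_lo == 500], 1)   # 500 in [500, 550)
  expect_equal(h$insoluble[h$bin_lo == 950], 1) # 1000 closed into the last bin
  expect_error(score_histogram(scores, labels, 0), class = "scm_input_error")
})

test_that("uncertainty-accuracy curve reports coverage and subset accuracy", {
  scores <- c(100, 460, 470, 900)
  labels <- c("insoluble", "insoluble", "soluble", "soluble")
  curve <- uncertainty_accuracy_curve(scores, labels, 465, c(0, 40, 5000))
  expect_equal(curve$coverage, c(1, 0.5, 0))
  expect_equal(curve$accuracy[1], 1)
  expect_equal(curve$accuracy[2], 1)       # the two near-threshold scores abstain
  expect_true(is.na(curve$accuracy[3]))
  expect_error(uncertainty_accuracy_curve(scores, labels, 465, -1),
               class = "scm_input_error")
})

test_that("positional profile lists every window and averages to the sequence score", {
  card <- random_card()
  prof <- positional_score_profile("ACA", card)
  expect_identical(prof$position, 1:2)
  expect_identical(prof$dipeptide, c("AC", "CA"))
  expect_equal(prof$score, unname(card$scores[c("AC", "CA")]))

  set.seed(9)
  for (i in 1:10) {
    s <- random_sequence(sample(2:80, 1))
    prof <- positional_score_profile(s, card)
    expect_identical(nrow(prof), nchar(s) - 1L)
    expect_equal(mean(prof$score), solubility_score(s, card), tolerance = 1e-9)
  }
})
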