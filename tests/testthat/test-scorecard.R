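test_that("build_initial_ssm hand example: one soluble vs one insoluble homopolymer", {
  ds <- labeled_dataset(c("s", "i"), c("AAA", "CCC"), c("soluble", "insoluble"))
  card <- build_initial_ssm(ds)
  expect_equal(unname(card$scores["AA"]), 1000)
  expect_equal(unname(card$scores["CC"]), 0)
  expect_equal(unname(card$scores["AC"]), 500)
  expect_true(all(card$scores[setdiff(DIPEPTIDES, c("AA", "CC"))] == 500))
  expect_identical(card$provenance$type, "initial")

  same <- labeled_dataset(c("s", "i"), c("ACAC", "ACAC"), c("soluble", "insoluble"))
  expect_error(build_initial_ssm(same), class = "scm_degenerate_error")
})

test_that("normalize_scores is a min-max map: endpoints, idempotence, shift invariance", {
  expect_equal(normalize_scores(c(-1, 0, 1)), c(0, 500, 1000))
  v <- runif(400, 0, 1000); v[1] <- 0; v[2] <- 1000
  expect_equal(normalize_scores(v), v)
  raw <- rnorm(400)
  expect_equal(normalize_scores(raw + 17.3), normalize_scores(raw))
  expect_error(normalize_scores(rep(2, 400)), class = "scm_degenerate_error")
})

test_that("label swap maps every normalized score s to 1000 - s", {
  set.seed(13)
  for (i in 1:5) {
    ds <- random_toy_dataset(6, 6)
    swapped <- labeled_dataset(ds$id, ds$sequence,
                               ifelse(ds$label == "soluble", "insoluble", "soluble"))
    expect_equal(unname(build_initial_ssm(swapped)$scores),
                 1000 - unname(build_initial_ssm(ds)$scores), tolerance = 1e-9)
  }
})

test_that("solubility_score is the composition-weighted sum and stays in card range", {
  uniform <- score_card(rep(250, 400))
  expect_equal(solubility_score("MKLAVFE", uniform), 250)

  s <- rep(0, 400); names(s) <- DIPEPTIDES
  s["AC"] <- 300; s["CA"] <- 600
  expect_equal(solubility_score("ACAC", score_card(s)), (2 / 3) * 300 + (1 / 3) * 600)

  set.seed(5)
  card <- random_card()
  for (i in 1:10) {
    sc <- solubility_score(random_sequence(sample(2:50, 1)), card)
    expect_gte(sc, min(card$scores)); expect_lte(sc, max(card$scores))
  }
})

test_that("raising the score of a present dipeptide never lowers a sequence score", {
  set.seed(6)
  card <- random_card()
  seqs <- vapply(rep(20, 10), random_sequence, character(1))
  for (s in seqs) {
    present <- names(which(dipeptide_composition(s) > 0))
    d <- sample(present, 1)
    bumped <- card
    bumped$scores[d] <- min(1000, bumped$scores[d] + 100)
    expect_gte(solubility_score(s, bumped), solubility_score(s, card))
  }
})

test_that("select_threshold maximizes accuracy with midpoint candidates", {
  sel <- select_threshold(c(1, 2, 3, 4), c("insoluble", "insoluble", "soluble", "soluble"))
  expect_equal(sel$threshold, 2.5)
  expect_equal(sel$accuracy, 1)

  sel <- select_threshold(c(1, 2, 3), rep("insoluble", 3))
  expect_equal(sel$accuracy, 1)
  expect_gt(sel$threshold, 3)   # sentinel above the maximum

  sel <- select_threshold(c(1, 2, 3, 4), c("soluble", "insoluble", "soluble", "insoluble"))
  expect_equal(sel$accuracy, 0.5)
})

test_that("prediction uses strict inequality; ties go insoluble; abstention respects the band", {
  s <- rep(0, 400); names(s) <- DIPEPTIDES; s["AA"] <- 1000
  card <- score_card(s, threshold = 1000)
  expect_identical(predict_solubility("AAAA", card), "insoluble")  # score == threshold

  card450 <- score_card(rep(460, 400), threshold = 450)
  expect_identical(predict_solubility("MKLA", card450), "soluble")
  expect_identical(predict_with_uncertainty("MKLA", card450, 40), "abstain")   # |460-450| <= 20
  card475 <- score_card(rep(475, 400), threshold = 450)
  expect_identical(predict_with_uncertainty("MKLA", card475, 40), "soluble")
  expect_identical(predict_with_uncertainty("MKLA", card475, 0),
                   predict_solubility("MKLA", card475))
  expect_error(predict_with_uncertainty("MKLA", card475, -1), class = "scm_input_error")
  expect_error(predict_solubility("MKLA", score_card(rep(1, 400))),
               class = "scm_input_error")
})

test_that("score-card files round-trip bit-exactly, heat-map layout is first-residue-major", {
  card <- random_card()
  card$threshold <- 463.787
  card$provenance$type <- "optimized"
  path <- tempfile(fileext = ".card")
  write_score_card(card, path)
  back <- read_score_card(path)
  expect_identical(unname(back$scores), unname(card$scores))
  expect_identical(back$threshold, card$threshold)
  expect_identical(back$provenance$type, "optimized")

  hm <- card_matrix(card)
  expect_identical(dim(hm), c(20L, 20L))
  expect_equal(hm["A", "C"], unname(card$scores["AC"]))
  expect_equal(hm["Y", "A"], unname(card$scores["YA"]))
})
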