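test_that("exposure classification singles out Complementary Exposure", {
  # published top CML pair: both modules close, mutually separated
  expect_equal(classify_exposure(-7.72, -5.56, 0.03), "II")
  # only one module close: never class II
  expect_equal(classify_exposure(1, -1, 0.5), "IV")
  # both close but overlapping modules
  expect_equal(classify_exposure(-1, -1, -0.5), "I")
  expect_equal(classify_exposure(2, 3, -0.1), "V")
  expect_equal(classify_exposure(2, 3, 0.1), "VI")
  # unordered pair: swapping the drugs never changes the class
  set.seed(1)
  z1 <- stats::rnorm(20); z2 <- stats::rnorm(20); s <- stats::rnorm(20)
  expect_equal(classify_exposure(z1, z2, s), classify_exposure(z2, z1, s))
  # alternative separation-sign convention
  expect_equal(classify_exposure(-1, -1, -0.5, separated_positive = FALSE), "II")
})

test_that("score components follow their defining arithmetic", {
  expect_equal(t_score("II"), 2)
  expect_equal(t_score("I"), 0)
  expect_equal(t_score("V"), 0)
  expect_equal(p_score(1, 0), 0.5)
  expect_equal(p_score(0.9, 0.81), 0.855)
  expect_equal(p_score(0, 0), 0)
  expect_equal(c_score(-0.18, -0.47), 0.325)
  expect_equal(c_score(0.5, -0.5), 0.5)
  expect_equal(prediction_score(2, 0.855, 0.325), 3.18)
  expect_equal(prediction_score(2, 1, 1), 4)
  expect_equal(prediction_score(0, 0, 0), 0)
})

test_that("moving a pair into class II raises the total by exactly 2", {
  p <- 0.4; cc <- 0.25
  expect_equal(prediction_score(t_score("II"), p, cc) -
                 prediction_score(t_score("I"), p, cc), 2)
})

test_that("rank_pairs scores all unordered pairs deterministically", {
  stats_df <- data.frame(drug = c("b", "a", "c"),
                         z = c(-2, -3, 1), P = c(0.5, 1, 0),
                         C = c(0.4, -0.6, NA))
  sep <- matrix(0.2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sep["a", "c"] <- sep["c", "a"] <- -0.3
  ranked <- rank_pairs(stats_df, sep)
  expect_equal(nrow(ranked), 3L)
  # permuting the drug input order leaves the table unchanged
  ranked2 <- rank_pairs(stats_df[c(3, 1, 2), ], sep)
  expect_equal(ranked, ranked2)
  # a-b: both z < 0, separated => class II
  ab <- ranked[ranked$drug_a == "a" & ranked$drug_b == "b", ]
  expect_equal(ab$class, "II")
  expect_equal(ab$total, 2 + (1 + 0.5) / 2 + (0.6 + 0.4) / 2)
  # undefined cosine is imputed to 0 and flagged
  ac <- ranked[ranked$drug_b == "c" & ranked$drug_a == "a", ]
  expect_true(ac$c_imputed)
  expect_equal(ac$C, (0.6 + 0) / 2)
  expect_true(all(diff(ranked$total) <= 0))
})

test_that("ranking AUC matches enumeration oracles", {
  # worked example: scores p1:3, n1:2, p2:1, n2:0 => 3 of 4 comparisons won
  expect_equal(ranking_auc(c(3, 2, 1, 0), c(TRUE, FALSE, TRUE, FALSE)), 3 / 4)
  expect_equal(ranking_auc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(ranking_auc(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_error(ranking_auc(1:3, c(FALSE, FALSE, FALSE)), "positives")

  for (s in 1:50) {
    set.seed(s)
    n <- sample(5:40, 1)
    scores <- sample(0:5, n, replace = TRUE)  # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (any(labels) && any(!labels)) {
      expect_equal(ranking_auc(scores, labels), brute_auc(scores, labels))
    }
  }
})

test_that("ranking AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- stats::rnorm(60)
  labels <- stats::runif(60) < 0.3
  expect_equal(ranking_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("known-pair matching ignores the order within a pair", {
  pairs <- data.frame(drug_a = c("a", "b"), drug_b = c("b", "c"))
  pos <- data.frame(drug_a = "b", drug_b = "a")
  expect_equal(match_known_pairs(pairs, pos), c(TRUE, FALSE))
})

test_that("the published CML table is internally consistent with the score design", {
  tab <- cml_validation_table()
  expect_equal(nrow(tab), 20L)
  # every published top pair is Complementary Exposure
  expect_true(all(classify_exposure(tab$z_qa, tab$z_qb, tab$s_ab) == "II"))
  # back-solved proximity component score - T - C must be a valid mean of
  # two scaled proximities
  P_resid <- tab$score - 2 - c_score(tab$c_qa, tab$c_qb)
  expect_true(all(P_resid > 0 & P_resid < 1 + 1e-9))
  expect_equal(P_resid[1], 0.855)
})
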