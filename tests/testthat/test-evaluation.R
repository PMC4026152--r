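test_that("rank-method AUC reproduces worked examples and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "AUC undefined")
})

test_that("the ROC curve is monotone from (0,0) to (1,1) and its trapezoid area equals the rank AUC", {
  set.seed(7)
  for (i in 1:10) {
    n <- 50
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- roc_auc(scores, labels)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
    trap <- sum(diff(r$points$fpr) *
                  (utils::head(r$points$tpr, -1) + utils::tail(r$points$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-9)
  }
})

test_that("AUC agrees with brute-force pair enumeration and an external implementation", {
  set.seed(11)
  for (i in 1:5) {
    scores <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)
    labels <- rbinom(50, 1, 0.5)
    if (sum(labels) %in% c(0, 50)) next
    a <- roc_auc(scores, labels)$auc
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                   quiet = TRUE,
                                                   direction = "<"))),
                 tolerance = 1e-9)
  }
})

test_that("AUC is invariant to monotone transforms and reverses under score negation", {
  set.seed(3)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, a)
  expect_equal(roc_auc(rank(scores), labels)$auc, a)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a)
})

test_that("Cohen's kappa matches hand-computed cases and is symmetric", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)  # p_o = p_e = 0.5
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 1, 1, 1)), 0)  # constant rater
  set.seed(5)
  a <- rbinom(40, 1, 0.5)
  b <- rbinom(40, 1, 0.5)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)
  # constant but opposite raters: p_o = p_e = 0, so kappa is 0
  expect_equal(cohens_kappa(rep(1, 5), rep(0, 5)), 0)
})

test_that("pairwise kappa summary averages rater pairs and model-rater pairs", {
  grid <- tidyr::expand_grid(session_id = "s1", turn = 0:9,
                             rater = c("R1", "R2", "R3"), code = "QUC")
  grid$present <- rep(c(1, 1, 1, 0, 0, 0), length.out = nrow(grid))
  # all three raters identical by construction
  grid$present <- rep(rep(c(1, 0), 5), each = 3)
  model <- tibble::tibble(session_id = "s1", turn = 0:9, code = "QUC",
                          present = rep(c(1, 0), 5))
  out <- pairwise_kappa_summary(grid, model)
  expect_equal(out$rater_kappa, 1)
  expect_equal(out$model_kappa, 1)
  # the worked zero-kappa pair
  two <- tidyr::expand_grid(session_id = "s1", turn = 0:3,
                            rater = c("R1", "R2"), code = "QUC")
  two$present <- c(1, 1, 1, 0, 0, 1, 0, 0)  # a=(1,1,0,0), b=(1,0,1,0)
  expect_equal(pairwise_kappa_summary(two)$rater_kappa, 0)
  single <- dplyr::filter(two, rater == "R1")
  expect_error(pairwise_kappa_summary(single), ">= 2 raters")
})

test_that("session tallies count rater marks and sum model scores", {
  marks <- tibble::tibble(session_id = "s1", turn = 0:9, rater = "R1",
                          code = "RES", present = c(rep(1, 3), rep(0, 7)))
  expect_equal(session_tallies(marks)$tally, 3)
  scores <- tibble::tibble(session_id = "s1", turn = 0:9, code = "QUO",
                           score = 0.5)
  expect_equal(session_tallies(scores)$tally, 5.0)
  mixed <- tibble::tibble(session_id = rep(c("s1", "s2"), each = 3),
                          turn = rep(0:2, 2), code = "E",
                          score = c(0.2, 0.3, 0.1, 0.9, 0.05, 0.05))
  expect_equal(session_tallies(mixed)$tally, c(0.6, 1.0))
})

test_that("ICC(2,1) matches the ANOVA oracle and penalizes column shifts", {
  m <- matrix(c(1, 2, 3, 3, 5, 4, 7, 8), ncol = 2, byrow = TRUE)
  expect_equal(icc_agreement(m), 0.9440993789, tolerance = 1e-9)
  expect_equal(icc_agreement(m), oracle_icc(m), tolerance = 1e-12)
  # identical columns with variance between sessions agree perfectly
  expect_equal(icc_agreement(cbind(1:5, 1:5)), 1)
  # a constant added to one column lowers absolute agreement
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 3
  expect_lt(icc_agreement(shifted), icc_agreement(m))
  # permuting sessions changes nothing
  expect_equal(icc_agreement(m[c(3, 1, 4, 2), ]), icc_agreement(m))
  # independent equal-variance columns have near-zero ICC at large n
  set.seed(9)
  big <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(icc_agreement(big)), 0.05)
  expect_error(icc_agreement(cbind(c(1, 1, 1), c(2, 2, 2))), "ICC undefined")
  # random fixtures against the aov() oracle
  for (i in 1:10) {
    mm <- matrix(rpois(50, 6), ncol = 5)
    expect_equal(icc_agreement(mm), oracle_icc(mm), tolerance = 1e-10)
  }
})

test_that("proficiency indices follow their definitions with missing-value contracts", {
  tal <- tibble::tibble(session_id = "s1",
                        code = c("QUC", "QUO", "RES", "REC"),
                        tally = c(4, 6, 5, 5))
  p <- proficiency_indices(tal)
  expect_equal(p$reflection_to_question_ratio, 1.0)
  expect_equal(p$percent_open_questions, 60)
  expect_equal(p$percent_complex_reflections, 50)
  # identity: ratio * questions = reflections whenever defined
  expect_equal(p$reflection_to_question_ratio * (4 + 6), 5 + 5)
  noq <- tibble::tibble(session_id = "s1", code = c("RES", "REC"),
                        tally = c(3, 1))
  pn <- proficiency_indices(noq)
  expect_true(is.na(pn$reflection_to_question_ratio))
  expect_true(is.na(pn$percent_open_questions))
  expect_equal(pn$percent_complex_reflections, 25)
  norec <- tibble::tibble(session_id = "s1", code = c("QUC", "RES"),
                          tally = c(2, 3))
  expect_equal(proficiency_indices(norec)$percent_complex_reflections, 0)
})

test_that("prevalence-matched binarization picks the closest achievable rate", {
  expect_equal(binarize_scores(c(0.9, 0.7, 0.2, 0.1), 0.5),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(binarize_scores(c(0.9, 0.7, 0.2, 0.1), 0.001),
               rep(FALSE, 4))
  # all-equal scores break the tie toward fewer positives
  expect_equal(binarize_scores(rep(0.4, 6), 0.5), rep(FALSE, 6))
  # tied scores cross the cut together
  expect_equal(sum(binarize_scores(c(0.8, 0.8, 0.8, 0.1), 0.5)), 3)
})

test_that("confusion pairs report the dominant substitution with ties kept", {
  truth <- tibble::tibble(session_id = "s1", turn = 0:9, code = "QUO")
  pred <- tibble::tibble(session_id = "s1", turn = 0:9,
                         code = c(rep("QUC", 3), rep("QUO", 7)))
  cp <- confusion_pairs(pred, truth)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$code, "QUO")
  expect_equal(cp$predicted_as, "QUC")
  expect_equal(cp$n, 3L)
  # perfect predictions give an empty report
  perfect <- confusion_pairs(dplyr::mutate(pred, code = "QUO"), truth)
  expect_equal(nrow(perfect), 0)
  # a tie reports both substitutes
  pred2 <- tibble::tibble(session_id = "s1", turn = 0:9,
                          code = c("QUC", "QUC", "RES", "RES", rep("QUO", 6)))
  cp2 <- confusion_pairs(pred2, truth)
  expect_setequal(cp2$predicted_as, c("QUC", "RES"))
  expect_equal(cp2$n, c(2L, 2L))
})
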