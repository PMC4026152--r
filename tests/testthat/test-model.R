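# a hand-built model object for tests of pure read-off operations
fake_model <- function(phi, code_ids, studies = character(0), n_bg = 0,
                       vocabulary = paste0("w", seq_len(ncol(phi)))) {
  structure(list(
    phi = phi,
    inventory = topic_inventory(code_ids, studies, n_bg),
    vocabulary = vocabulary,
    vocab_hash = mitopics:::vocab_hash(vocabulary),
    phrases = NULL,
    codes = tibble::tibble(id = code_ids, description = code_ids,
                           speaker_scope = "therapist"),
    studies = studies,
    hyper = mi_hyper(n_iterations = 50, burn_in = 20, sample_lag = 5,
                     n_background = n_bg, seed = 1),
    include_study = length(studies) > 0,
    restrict_codes_by_speaker = FALSE
  ), class = "mi_model")
}

test_that("allowed topics are truth codes + study + background in training, all codes in prediction", {
  codes12 <- misc_codes()$id
  inv <- topic_inventory(codes12, c("ESP21", "HMCBI"), 2)
  tr <- allowed_topics("QUC", "ESP21", "train", inv)
  expect_setequal(tr, inv$topic[inv$label %in% c("QUC", "ESP21", "bg1", "bg2")])
  expect_setequal(allowed_topics(character(0), "HMCBI", "train", inv),
                  inv$topic[inv$label %in% c("HMCBI", "bg1", "bg2")])
  pr <- allowed_topics(character(0), "ESP21", "predict", inv)
  expect_length(pr, 12 + 1 + 2)
  expect_error(allowed_topics("QUC", "NOPE", "train", inv), "NOPE")
})

test_that("the collapsed Gibbs conditional matches hand arithmetic and normalizes", {
  # single allowed topic gets probability 1
  expect_equal(gibbs_conditional(c(0, 0), c(0, 0), c(0, 0), 4, 0.1, 0.01, 1L),
               c(0, 1))
  # symmetric zero counts split evenly
  expect_equal(gibbs_conditional(c(0, 0), c(0, 0), c(0, 0), 4, 0.1, 0.01, c(0L, 1L)),
               c(0.5, 0.5))
  # worked example: (3.1*2.01/10.04, 1.1*0.01/5.04) normalized
  p <- gibbs_conditional(n_dt = c(3, 1), n_tw_w = c(2, 0), n_t = c(10, 5),
                         V = 4, alpha = 0.1, beta = 0.01, allowed = c(0L, 1L))
  expect_equal(p, c(0.9965, 0.0035), tolerance = 1e-3)
  expect_error(gibbs_conditional(c(1), c(1), c(1), 2, 0.1, 0.01, integer(0)),
               "empty")
  # normalization holds for arbitrary counts
  set.seed(42)
  for (i in 1:20) {
    nt <- sample(3:6, 1)
    p <- gibbs_conditional(rpois(nt, 3), rpois(nt, 2), rpois(nt, 10) + 5,
                           V = 50, alpha = 0.1, beta = 0.01,
                           allowed = sort(sample(seq_len(nt) - 1L,
                                                 sample(2:nt, 1))))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("training is deterministic under a seed and keeps counts consistent", {
  sim <- simulate_corpus(small_config(), seed = 5)
  corpus <- retain_codes(fuse_raters(sim$corpus),
                         code_prevalence_filter(fuse_raters(sim$corpus)))
  m1 <- train_model(corpus, fast_hyper(seed = 9))
  m2 <- train_model(corpus, fast_hyper(seed = 9))
  expect_identical(m1$phi, m2$phi)
  m3 <- train_model(corpus, fast_hyper(seed = 10))
  expect_false(identical(m1$phi, m3$phi))
  # marginal count consistency after the final sweep
  expect_equal(as.integer(rowSums(m1$counts$n_tw)), m1$counts$n_t)
  expect_equal(sum(m1$counts$n_dt), sum(lengths(corpus$turns$tokens)))
  # phi rows are probability distributions
  expect_equal(rowSums(m1$phi), rep(1, nrow(m1$phi)), tolerance = 1e-9)
})

test_that("topics unreachable in training stay at the uniform prior", {
  n <- 30
  turns <- tibble::tibble(
    session_id = "s1", study = "A", turn = seq_len(n) - 1L,
    speaker = "therapist",
    text = replicate(n, paste(sample(c("aa", "bb", "cc"), 5, TRUE),
                              collapse = " ")),
    annotations = replicate(n, list(R1 = "QUC"), simplify = FALSE)
  )
  codes <- misc_codes()[misc_codes()$id %in% c("QUC", "QUO"), ]
  corpus <- tokenize_corpus(fuse_raters(mi_corpus(turns, codes)),
                            min_phrase_doc_freq = 1000)
  m <- train_model(corpus, mi_hyper(n_iterations = 60, burn_in = 30,
                                    sample_lag = 5, n_background = 0, seed = 2))
  quo_row <- m$phi[m$inventory$label == "QUO", ]
  V <- length(corpus$vocabulary)
  expect_equal(quo_row, rep(1 / V, V), tolerance = 1e-12)
})

test_that("top terms rank by probability with vocabulary-order tie-break", {
  m <- fake_model(matrix(c(0.5, 0.3, 0.2), nrow = 1), "QUC",
                  vocabulary = c("alpha", "beta", "gamma"))
  expect_equal(top_terms(m, "QUC", 2)$term, c("alpha", "beta"))
  expect_setequal(top_terms(m, "QUC", 3)$term, c("alpha", "beta", "gamma"))
  tied <- fake_model(matrix(c(0.25, 0.25, 0.5), nrow = 1), "QUC",
                     vocabulary = c("zed", "ant", "mid"))
  expect_equal(top_terms(tied, "QUC", 3)$term, c("mid", "zed", "ant"))
  expect_error(top_terms(m, "NOPE"), "NOPE")
})

test_that("scores read off theta and the argmax respects inventory-order ties", {
  phi <- diag(3) * 0.9 + 0.05
  m <- fake_model(phi, c("QUC", "QUO"), studies = "A")
  theta <- tibble::tibble(session_id = "s1", study = "A", turn = 0L,
                          speaker = "therapist")
  theta$theta <- matrix(c(0.0, 0.4, 0.6), nrow = 1,
                        dimnames = list(NULL, m$inventory$label))
  sc <- score_codes(theta, m)
  expect_equal(sc$score[sc$code == "QUO"], 0.4)
  expect_equal(sc$score[sc$code == "QUC"], 0.0)
  expect_equal(predict_most_likely(sc)$code, "QUO")
  # all-zero scores fall back to the first code in inventory order
  sc$score <- 0
  expect_equal(predict_most_likely(sc)$code, "QUC")
})

test_that("fold-in inference: empty turns are uniform, strong evidence concentrates", {
  phi <- rbind(c(rep(0.2, 5), rep(0, 5)),
               c(rep(0, 5), rep(0.2, 5)))
  m <- fake_model(phi, c("QUC", "QUO"),
                  vocabulary = paste0("w", 1:10))
  turns <- tibble::tibble(
    session_id = "s1", study = "A", turn = 0:1, speaker = "therapist",
    text = c("", paste(rep("w3", 10), collapse = " ")),
    annotations = replicate(2, list(), simplify = FALSE)
  )
  corpus <- mi_corpus(turns, codes = m$codes)
  corpus$vocabulary <- m$vocabulary
  corpus$turns$tokens <- list(integer(0), rep(2L, 10))
  th <- infer_heldout(m, corpus, seed = 3)
  expect_equal(unname(th$theta[1, ]), c(0.5, 0.5))
  expect_gt(th$theta[2, "QUC"], 0.9)
  expect_equal(rowSums(th$theta), c(1, 1), tolerance = 1e-9)
})

test_that("long-run fold-in inference matches exact posterior enumeration", {
  set.seed(8)
  V <- 6
  phi <- rbind(rdirich <- {
    g <- matrix(rgamma(3 * V, 0.5), 3)
    g / rowSums(g)
  })
  m <- fake_model(phi, c("A", "B", "C"), vocabulary = paste0("w", 1:V))
  tokens <- list(c(0L, 3L, 5L), c(1L, 1L), integer(0))
  turns <- tibble::tibble(
    session_id = "s1", study = "A", turn = 0:2, speaker = "therapist",
    text = "", annotations = replicate(3, list(), simplify = FALSE)
  )
  corpus <- mi_corpus(turns, codes = m$codes)
  corpus$vocabulary <- m$vocabulary
  corpus$turns$tokens <- tokens
  m$hyper <- mi_hyper(alpha = 0.1, n_iterations = 60000, burn_in = 2000,
                      sample_lag = 1, n_background = 0)
  th <- infer_heldout(m, corpus, seed = 4)
  for (d in 1:3) {
    exact <- oracle_infer_theta(tokens[[d]], 0:2, phi, 0.1)
    expect_lt(max(abs(unname(th$theta[d, ]) - exact)), 0.02)
  }
})

test_that("model artifacts round-trip and refuse mismatched vocabularies", {
  sim <- simulate_corpus(small_config(), seed = 6)
  corpus <- fuse_raters(sim$corpus)
  corpus <- retain_codes(corpus, code_prevalence_filter(corpus))
  m <- train_model(corpus, fast_hyper(seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(back$phi, m$phi, ignore_attr = TRUE)
  expect_equal(back$vocabulary, m$vocabulary)
  expect_equal(back$inventory, m$inventory)
  # scoring a corpus tokenized under another vocabulary is refused
  other <- corpus
  other$vocabulary <- rev(corpus$vocabulary)
  expect_error(infer_heldout(back, other), "vocabulary mismatch")
})

test_that("tidy and glance expose the fitted model in broom style", {
  m <- fake_model(matrix(c(0.5, 0.3, 0.2, 0.1, 0.2, 0.7), nrow = 2,
                         byrow = TRUE), c("QUC", "QUO"))
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 3)
  expect_named(td, c("topic", "kind", "label", "term", "phi"))
  expect_equal(td$phi[td$label == "QUC"], c(0.5, 0.3, 0.2))
  g <- glance(m)
  expect_equal(g$n_codes, 2)
  expect_equal(g$vocab_size, 3)
})
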