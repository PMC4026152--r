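# Independent brute-force oracles used to cross-check the package's
# implementations. Everything here is deliberately naive (pair enumeration,
# exact ANOVA via aov(), exhaustive assignment enumeration) and shares no
# code with the implementation under test.

# AUC by exhaustive positive-negative pair comparison (ties score 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# ICC(2,1) with mean squares taken from a two-way aov() fit
oracle_icc <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    target = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- anova(stats::aov(y ~ target + rater, data = df))
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# expected Cohen's kappa between two independent raters who each miss a
# present code with probability `miss` and add an absent one with `add`,
# at true prevalence `p` (closed-form confusion table)
oracle_expected_kappa <- function(p, miss, add) {
  q <- p * (1 - miss) + (1 - p) * add
  p11 <- p * (1 - miss)^2 + (1 - p) * add^2
  p00 <- p * miss^2 + (1 - p) * (1 - add)^2
  p_o <- p11 + p00
  p_e <- q^2 + (1 - q)^2
  (p_o - p_e) / (1 - p_e)
}

# exact per-token assignment marginals for the collapsed labeled topic model
# by exhaustive enumeration of every admissible assignment vector
oracle_train_marginals <- function(tokens, allowed, n_topics, V, alpha, beta) {
  doc_of <- rep(seq_along(tokens), lengths(tokens))
  words <- unlist(tokens) # 0-based
  sets <- lapply(doc_of, function(d) allowed[[d]]) # 0-based per token
  n_tok <- length(words)
  grid <- expand.grid(lapply(sets, identity), KEEP.OUT.ATTRS = FALSE)
  logw <- apply(as.matrix(grid), 1, function(z) {
    lw <- 0
    for (d in seq_along(tokens)) {
      ndt <- table(factor(z[doc_of == d], levels = allowed[[d]]))
      lw <- lw + sum(lgamma(alpha + ndt) - lgamma(alpha))
    }
    for (t in seq_len(n_topics) - 1L) {
      idx <- z == t
      nt <- sum(idx)
      lw <- lw - lgamma(V * beta + nt) + lgamma(V * beta)
      if (nt > 0) {
        ntw <- table(words[idx])
        lw <- lw + sum(lgamma(beta + ntw) - lgamma(beta))
      }
    }
    lw
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  marg <- matrix(0, n_tok, n_topics)
  zmat <- as.matrix(grid)
  for (i in seq_len(n_tok)) {
    for (t in seq_len(n_topics) - 1L) {
      marg[i, t + 1L] <- sum(w[zmat[, i] == t])
    }
  }
  marg
}

# exact E[theta] for fold-in inference (phi fixed) by enumerating one
# document's assignment vectors
oracle_infer_theta <- function(tokens, allowed, phi, alpha) {
  A <- length(allowed)
  n <- length(tokens)
  if (n == 0) {
    th <- numeric(nrow(phi))
    th[allowed + 1L] <- 1 / A
    return(th)
  }
  grid <- as.matrix(expand.grid(rep(list(allowed), n), KEEP.OUT.ATTRS = FALSE))
  logw <- apply(grid, 1, function(z) {
    ndt <- table(factor(z, levels = allowed))
    sum(log(phi[cbind(z + 1L, tokens + 1L)])) +
      sum(lgamma(alpha + ndt) - lgamma(alpha))
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  th <- numeric(nrow(phi))
  for (j in seq_len(A)) {
    t <- allowed[j]
    share <- apply(grid, 1, function(z) (sum(z == t) + alpha) / (n + A * alpha))
    th[t + 1L] <- sum(w * share)
  }
  th
}

# exact inclusion probability of code `c` in a weighted sample of size m
# drawn without replacement (successive sampling), by enumeration
oracle_inclusion_prob <- function(w, c_idx, m) {
  ids <- seq_along(w)
  w <- w / sum(w)
  if (m == 0) return(0)
  if (m == 1) return(w[c_idx])
  prob_seq <- function(remaining, taken, depth) {
    if (c_idx %in% taken) return(1)
    if (depth == 0) return(0)
    tot <- 0
    for (i in remaining) {
      p_i <- w[i] / sum(w[remaining])
      tot <- tot + p_i * prob_seq(setdiff(remaining, i), c(taken, i), depth - 1)
    }
    tot
  }
  prob_seq(ids, integer(0), m)
}

# ---- small fixture builders -------------------------------------------------

tiny_turns <- function() {
  tibble::tibble(
    session_id = c("s1", "s1", "s1", "s2", "s2"),
    study = c("A", "A", "A", "B", "B"),
    turn = c(0L, 1L, 2L, 0L, 1L),
    speaker = c("therapist", "patient", "therapist", "therapist", "patient"),
    text = c("It sounds like you're doing it.",
             "I don't know.",
             "What do you make of that?",
             "Does that sound about right?",
             "Yeah I guess so."),
    annotations = list(
      list(R1 = c("RES"), R2 = c("RES", "REC")),
      list(R1 = character(0), R2 = c("-")),
      list(R1 = c("QUO"), R2 = c("QUO")),
      list(R1 = c("QUC")),
      list()
    )
  )
}

tiny_corpus <- function() mi_corpus(tiny_turns())

# small well-separated synthetic configuration for fast end-to-end tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(
      vocab_size = 300,
      studies = c(A = 4L, B = 4L),
      n_background = 2,
      turns_per_session = list(mean = 15, dispersion = 10),
      tokens_per_turn = list(mean = 20, dispersion = 10),
      topic_sharpness = 0.05
    ),
    list(...)
  )
  do.call(sim_config, args)
}

fast_hyper <- function(...) {
  mi_hyper(n_iterations = 200, burn_in = 100, sample_lag = 5,
           n_background = 2, ...)
}
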