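#' Sampler hyperparameters
#'
#' @param alpha Symmetric Dirichlet concentration for the per-turn topic
#'   mixture theta. Default 0.1.
#' @param beta Symmetric Dirichlet concentration for the per-topic word
#'   distribution phi. Default 0.01.
#' @param n_background Number of background topics shared by every turn.
#'   Default 10.
#' @param n_iterations Total Gibbs sweeps. Default 1000.
#' @param burn_in Sweeps discarded before sample collection. Default 500.
#' @param sample_lag Collect a phi/theta sample every this many post-burn-in
#'   sweeps. Default 10.
#' @param seed Optional RNG seed; when set, training and inference are
#'   bit-reproducible.
#' @return A list of class `mi_hyper`.
#' @export
mi_hyper <- function(alpha = 0.1, beta = 0.01, n_background = 10,
                     n_iterations = 1000, burn_in = 500, sample_lag = 10,
                     seed = NULL) {
  stopifnot(alpha > 0, beta > 0, n_background >= 0, burn_in < n_iterations,
            sample_lag >= 1)
  structure(
    list(alpha = alpha, beta = beta, n_background = n_background,
         n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in),
         sample_lag = as.integer(sample_lag), seed = seed),
    class = "mi_hyper"
  )
}

#' Topic inventory: one topic per code, one per study, B background topics
#'
#' The three index ranges are disjoint and together cover `[0, T)`: code
#' topics come first (inventory order), then study topics, then background
#' topics labeled `bg1..bgB`.
#'
#' @param code_ids Character vector of retained code ids.
#' @param studies Character vector of study labels (may be empty to ablate
#'   study topics).
#' @param n_background Number of background topics (0 to ablate).
#' @return A tibble with columns `topic` (0-based index), `kind`
#'   (`code`/`study`/`background`) and `label`.
#' @export
topic_inventory <- function(code_ids, studies, n_background) {
  kinds <- c(rep("code", length(code_ids)),
             rep("study", length(studies)),
             rep("background", n_background))
  labels <- c(code_ids, studies,
              if (n_background > 0) paste0("bg", seq_len(n_background)) else character(0))
  tibble::tibble(topic = seq_along(labels) - 1L, kind = kinds, label = labels)
}

#' Allowed topics for one talk turn
#'
#' In training, a turn may only assign its tokens to the topics of its truth
#' codes, its session's study topic, and the background topics; untagged
#' turns get study + background only. In prediction the truth is unknown, so
#' all code topics are admitted.
#'
#' @param truth Character vector of the turn's truth code ids (training mode).
#' @param study The turn's session study label.
#' @param mode `"train"` or `"predict"`.
#' @param inventory A [topic_inventory()].
#' @return Integer vector of 0-based topic indices, ascending.
#' @export
allowed_topics <- function(truth, study, mode = c("train", "predict"),
                           inventory) {
  mode <- match.arg(mode)
  has_study_topics <- any(inventory$kind == "study")
  if (has_study_topics && !study %in% inventory$label[inventory$kind == "study"]) {
    stop("unknown study: ", study)
  }
  keep <- inventory$kind == "background" |
    (inventory$kind == "study" & inventory$label == study)
  if (mode == "predict") {
    keep <- keep | inventory$kind == "code"
  } else {
    keep <- keep | (inventory$kind == "code" & inventory$label %in% truth)
  }
  sort(inventory$topic[keep])
}

#' Collapsed Gibbs full conditional for one token
#'
#' P(z = t) is proportional to `(n_dt[t] + alpha) * (n_tw[t, w] + beta) /
#' (n_t[t] + V beta)` on the allowed set and 0 elsewhere; counts must exclude
#' the token being resampled. Exposed for inspection and testing; the
#' training loop itself runs in compiled code.
#'
#' @param n_dt Per-turn topic counts (length T, minus the current token).
#' @param n_tw_w Topic counts for the current word (length T).
#' @param n_t Topic totals (length T).
#' @param V Vocabulary size.
#' @param alpha,beta Dirichlet concentrations.
#' @param allowed Integer vector of 0-based allowed topic indices.
#' @return Numeric vector of length T summing to 1; zero off the allowed set.
#' @export
gibbs_conditional <- function(n_dt, n_tw_w, n_t, V, alpha, beta, allowed) {
  if (length(allowed) == 0) stop("empty allowed-topic set")
  idx <- allowed + 1L
  p <- numeric(length(n_dt))
  p[idx] <- (n_dt[idx] + alpha) * (n_tw_w[idx] + beta) / (n_t[idx] + V * beta)
  p / sum(p)
}

canonical_phrases <- function(x) {
  if (is.null(x) || length(x) == 0 || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble::tibble(phrase = character(0), n_turns = integer(0)))
  }
  tibble::as_tibble(x)
}

vocab_hash <- function(vocabulary) {
  x <- utf8ToInt(paste(vocabulary, collapse = ""))
  h <- 0
  for (c in x) h <- (h * 31 + c) %% 2147483647
  h
}

turn_allowed_list <- function(corpus, inventory, mode,
                              restrict_codes_by_speaker = FALSE) {
  turns <- corpus$turns
  lapply(seq_len(nrow(turns)), function(i) {
    allowed <- allowed_topics(
      truth = turns$truth[[i]], study = turns$study[i],
      mode = mode, inventory = inventory
    )
    if (restrict_codes_by_speaker) {
      scope <- corpus$codes$speaker_scope[match(inventory$label, corpus$codes$id)]
      off <- inventory$topic[inventory$kind == "code" &
                               !is.na(scope) & scope != turns$speaker[i]]
      allowed <- setdiff(allowed, off)
    }
    allowed
  })
}

#' Train the labeled topic model
#'
#' Runs collapsed Gibbs sampling over every token of the corpus with
#' train-mode allowed-topic sets, then averages `(n_tw + beta)/(n_t + V beta)`
#' over the retained post-burn-in samples into the topic-word estimate
#' phi-hat. Deterministic given `hyper$seed`.
#'
#' @param corpus An [mi_corpus()] that has been tokenized
#'   ([tokenize_corpus()]) and carries fused truth sets ([fuse_raters()]),
#'   with the code inventory already restricted to the retained codes.
#' @param hyper An [mi_hyper()].
#' @param include_study Include one topic per study (set `FALSE` together
#'   with `n_background = 0` for the ablated, codes-only model).
#' @param restrict_codes_by_speaker Only admit code topics whose
#'   `speaker_scope` matches the turn's speaker. Default off: a single model
#'   is fit to therapist and patient codes alike.
#' @param track_assignments Keep per-token topic assignment frequencies
#'   across retained sweeps (memory-heavy; tiny corpora only).
#' @return An object of class `mi_model`: phi-hat, the topic inventory,
#'   vocabulary (with hash), hyperparameters, and final count statistics.
#' @export
train_model <- function(corpus, hyper = mi_hyper(), include_study = TRUE,
                        restrict_codes_by_speaker = FALSE,
                        track_assignments = FALSE) {
  if (nrow(corpus$turns) == 0) stop("empty corpus")
  if (nrow(corpus$codes) == 0) stop("zero retained codes")
  if (is.null(corpus$vocabulary)) stop("corpus must be tokenized first")
  inventory <- topic_inventory(
    code_ids = corpus$codes$id,
    studies = if (include_study) corpus$studies else character(0),
    n_background = hyper$n_background
  )
  allowed <- turn_allowed_list(corpus, inventory, "train",
                               restrict_codes_by_speaker)
  # with study and background topics ablated, untagged turns admit no topic
  # at all and cannot be trained on; they are dropped from the sweep
  trainable <- lengths(allowed) > 0 | lengths(corpus$turns$tokens) == 0
  tokens <- corpus$turns$tokens[trainable]
  allowed <- allowed[trainable]
  if (!is.null(hyper$seed)) set.seed(hyper$seed)
  fit <- gibbs_train_cpp(
    tokens_ = tokens, allowed_ = allowed,
    n_topics = nrow(inventory), vocab_size = length(corpus$vocabulary),
    alpha = hyper$alpha, beta = hyper$beta,
    n_iter = hyper$n_iterations, burn_in = hyper$burn_in,
    lag = hyper$sample_lag, track_assignments = track_assignments
  )
  structure(
    list(
      phi = fit$phi,
      inventory = inventory,
      vocabulary = corpus$vocabulary,
      vocab_hash = vocab_hash(corpus$vocabulary),
      phrases = corpus$phrases,
      codes = corpus$codes,
      studies = corpus$studies,
      hyper = hyper,
      include_study = include_study,
      restrict_codes_by_speaker = restrict_codes_by_speaker,
      counts = fit[c("n_dt", "n_tw", "n_t", "n_samples")],
      assignment_freq = fit$assignment_freq
    ),
    class = "mi_model"
  )
}

#' @export
print.mi_model <- function(x, ...) {
  cat(sprintf(
    "<mi_model> %d topics (%d codes, %d studies, %d background), V = %d\n",
    nrow(x$inventory), sum(x$inventory$kind == "code"),
    sum(x$inventory$kind == "study"), sum(x$inventory$kind == "background"),
    length(x$vocabulary)))
  invisible(x)
}

#' Tidy the topic-word distributions of a fitted model
#'
#' One row per (topic, term) pair, in the style of tidied topic models:
#' columns `topic`, `kind`, `label`, `term`, `phi`.
#'
#' @param x An `mi_model`.
#' @param ... Unused.
#' @export
tidy.mi_model <- function(x, ...) {
  tibble::tibble(
    topic = rep(x$inventory$topic, each = length(x$vocabulary)),
    kind = rep(x$inventory$kind, each = length(x$vocabulary)),
    label = rep(x$inventory$label, each = length(x$vocabulary)),
    term = rep(x$vocabulary, times = nrow(x$inventory)),
    phi = as.vector(t(x$phi))
  )
}

#' @rdname tidy.mi_model
#' @export
glance.mi_model <- function(x, ...) {
  tibble::tibble(
    n_topics = nrow(x$inventory),
    n_codes = sum(x$inventory$kind == "code"),
    n_studies = sum(x$inventory$kind == "study"),
    n_background = sum(x$inventory$kind == "background"),
    vocab_size = length(x$vocabulary),
    alpha = x$hyper$alpha, beta = x$hyper$beta,
    n_iterations = x$hyper$n_iterations,
    retained_samples = if (is.null(x$counts)) NA_integer_ else x$counts$n_samples
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Highest-probability terms of a topic
#'
#' @param model An `mi_model`.
#' @param topic A topic label (code id, study label, or `"bg<i>"`).
#' @param k Number of terms (default 20).
#' @return A tibble with columns `term`, `phi`, descending by `phi`; ties
#'   broken by vocabulary id ascending.
#' @export
top_terms <- function(model, topic, k = 20) {
  i <- match(topic, model$inventory$label)
  if (is.na(i)) stop("unknown topic: ", topic)
  stopifnot(k >= 1, k <= length(model$vocabulary))
  p <- model$phi[i, ]
  ord <- order(-p, seq_along(p))[seq_len(k)]
  tibble::tibble(term = model$vocabulary[ord], phi = p[ord])
}

#' Fold-in inference of per-turn topic mixtures on held-out sessions
#'
#' Topic-word distributions are frozen at the trained phi-hat; only each
#' held-out turn's topic counts are resampled, with predict-mode allowed
#' sets (all code topics + the session's study topic + background). The
#' per-turn mixture theta-hat is the average over retained samples of
#' `(n_dt + alpha) / (n_d + |allowed| alpha)`; rows sum to 1. Refuses a
#' corpus whose vocabulary hash does not match the model's.
#'
#' @param model A trained `mi_model`.
#' @param corpus Held-out sessions, tokenized with the model's vocabulary.
#' @param seed Optional seed for the inference sweep (defaults to
#'   `model$hyper$seed + 1` when the model carries a seed).
#' @return A tibble with columns `session_id`, `study`, `turn`, `speaker`,
#'   and a `theta` matrix column (turns x topics).
#' @export
infer_heldout <- function(model, corpus, seed = NULL) {
  if (is.null(corpus$vocabulary) ||
      vocab_hash(corpus$vocabulary) != model$vocab_hash) {
    stop("vocabulary mismatch: corpus was not tokenized with this model's vocabulary")
  }
  allowed <- turn_allowed_list(corpus, model$inventory, "predict",
                               model$restrict_codes_by_speaker)
  hyper <- model$hyper
  if (is.null(seed) && !is.null(hyper$seed)) seed <- hyper$seed + 1L
  if (!is.null(seed)) set.seed(seed)
  theta <- gibbs_infer_cpp(
    tokens_ = corpus$turns$tokens, allowed_ = allowed, phi = model$phi,
    alpha = hyper$alpha, n_iter = hyper$n_iterations,
    burn_in = hyper$burn_in, lag = hyper$sample_lag
  )
  colnames(theta) <- model$inventory$label
  out <- corpus$turns[, c("session_id", "study", "turn", "speaker")]
  out$theta <- theta
  out
}

#' Per-code prediction scores from inferred topic mixtures
#'
#' The score of code c on a turn is simply theta-hat at c's topic: the
#' posterior mean share of the turn's tokens attributed to that code's
#' language. Scores lie in `[0, 1]`.
#'
#' @param theta Output of [infer_heldout()].
#' @param model The `mi_model` used for inference.
#' @return A long tibble: `session_id`, `study`, `turn`, `speaker`, `code`,
#'   `score`.
#' @export
score_codes <- function(theta, model) {
  code_labels <- model$inventory$label[model$inventory$kind == "code"]
  scores <- theta$theta[, code_labels, drop = FALSE]
  out <- theta[rep(seq_len(nrow(theta)), each = length(code_labels)),
               c("session_id", "study", "turn", "speaker")]
  out$code <- rep(code_labels, times = nrow(theta))
  out$score <- as.vector(t(scores))
  tibble::as_tibble(out)
}

#' Single most likely code per talk turn
#'
#' Argmax of the per-code scores; ties broken by code inventory order (the
#' order of the `code` factor levels, or first appearance).
#'
#' @param scores Long score tibble from [score_codes()].
#' @return A tibble with one row per turn: `session_id`, `turn`, `code`.
#' @export
predict_most_likely <- function(scores) {
  stopifnot(nrow(scores) > 0)
  code_order <- unique(scores$code)
  scores |>
    dplyr::mutate(.code_rank = match(.data$code, code_order)) |>
    dplyr::group_by(.data$session_id, .data$turn) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$.code_rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("session_id", "turn", "code")
}

# ---- model artifact I/O -----------------------------------------------------

#' Save or load a fitted model
#'
#' JSON text artifact holding the topic inventory, vocabulary and its hash,
#' hyperparameters and phi-hat. [infer_heldout()] refuses to score a corpus
#' whose vocabulary hash differs from the stored one.
#'
#' @param model An `mi_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "mitopics-model-1",
    inventory = model$inventory,
    vocabulary = model$vocabulary,
    vocab_hash = model$vocab_hash,
    phrases = model$phrases,
    codes = model$codes,
    studies = model$studies,
    hyper = unclass(model$hyper),
    include_study = model$include_study,
    restrict_codes_by_speaker = model$restrict_codes_by_speaker,
    phi = apply(model$phi, 1, function(r) r, simplify = FALSE)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8", warn = FALSE))
  if (!identical(obj$format, "mitopics-model-1")) {
    stop("not a mitopics model artifact: ", path)
  }
  h <- obj$hyper
  hyper <- mi_hyper(alpha = h$alpha, beta = h$beta,
                    n_background = h$n_background,
                    n_iterations = h$n_iterations, burn_in = h$burn_in,
                    sample_lag = h$sample_lag, seed = h$seed)
  phi <- if (is.list(obj$phi)) do.call(rbind, obj$phi) else as.matrix(obj$phi)
  model <- structure(
    list(
      phi = phi,
      inventory = tibble::as_tibble(obj$inventory),
      vocabulary = obj$vocabulary,
      vocab_hash = obj$vocab_hash,
      phrases = canonical_phrases(obj$phrases),
      codes = tibble::as_tibble(obj$codes),
      studies = obj$studies,
      hyper = hyper,
      include_study = obj$include_study,
      restrict_codes_by_speaker = obj$restrict_codes_by_speaker,
      counts = NULL, assignment_freq = NULL
    ),
    class = "mi_model"
  )
  if (vocab_hash(model$vocabulary) != model$vocab_hash) {
    stop("model artifact corrupt: vocabulary hash mismatch")
  }
  model
}
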