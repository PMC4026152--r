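#' Session-level fold plan
#'
#' Sessions are shuffled uniformly at random under the seed and dealt
#' round-robin into k folds, so fold sizes differ by at most one (e.g. 148
#' sessions in 10 folds: eight folds of 15 and two of 14). Deterministic
#' given the seed.
#'
#' @param session_ids Character vector of session ids.
#' @param k Number of folds (default 10).
#' @param seed RNG seed.
#' @return A tibble `session_id`, `fold` (1-based), with attributes `k` and
#'   `seed`.
#' @export
make_folds <- function(session_ids, k = 10, seed = NULL) {
  session_ids <- unique(session_ids)
  if (k > length(session_ids)) stop("k exceeds the number of sessions")
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(session_ids)
  out <- tibble::tibble(
    session_id = shuffled,
    fold = rep_len(seq_len(k), length(shuffled))
  ) |> dplyr::arrange(.data$session_id)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- seed
  out
}

subset_sessions <- function(corpus, session_ids) {
  corpus$turns <- dplyr::filter(corpus$turns, .data$session_id %in% session_ids)
  corpus
}

#' Pooled held-out predictions by session-level cross-validation
#'
#' For each fold, the model is trained on the other folds' sessions and
#' scores the fold's sessions by fold-in inference, so every session is
#' scored exactly once by a model that never saw it. The vocabulary and
#' phrase table are rebuilt per fold from the training sessions only, and
#' held-out terms outside the training vocabulary are dropped. The code
#' inventory (prevalence filter) is expected to have been fixed once on the
#' full corpus before folding.
#'
#' @param corpus An [mi_corpus()] with fused truth and retained codes (see
#'   [fuse_raters()], [code_prevalence_filter()], [retain_codes()]).
#' @param hyper An [mi_hyper()]; each fold trains with seed
#'   `hyper$seed + fold` when a seed is set.
#' @param plan A [make_folds()] plan covering every session of `corpus`.
#' @param min_phrase_doc_freq Phrase admission threshold per training fold.
#' @param include_study,restrict_codes_by_speaker Passed to [train_model()].
#' @return Long score tibble `session_id`, `study`, `turn`, `speaker`,
#'   `code`, `score`, `fold` covering every talk turn exactly once.
#' @export
run_cv <- function(corpus, hyper = mi_hyper(), plan,
                   min_phrase_doc_freq = 10, include_study = TRUE,
                   restrict_codes_by_speaker = FALSE) {
  sessions <- unique(corpus$turns$session_id)
  if (!setequal(sessions, plan$session_id)) {
    stop("fold plan does not cover exactly the corpus's sessions")
  }
  k <- attr(plan, "k")
  pooled <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- plan$session_id[plan$fold == f]
    train_ids <- setdiff(sessions, test_ids)
    res <- tryCatch({
      train_corpus <- tokenize_corpus(subset_sessions(corpus, train_ids),
                                      min_phrase_doc_freq = min_phrase_doc_freq)
      fold_hyper <- hyper
      if (!is.null(hyper$seed)) fold_hyper$seed <- hyper$seed + f
      model <- train_model(train_corpus, fold_hyper,
                           include_study = include_study,
                           restrict_codes_by_speaker = restrict_codes_by_speaker)
      test_corpus <- tokenize_corpus(subset_sessions(corpus, test_ids),
                                     vocabulary = train_corpus$vocabulary,
                                     phrases = train_corpus$phrases)
      theta <- infer_heldout(model, test_corpus)
      score_codes(theta, model)
    }, error = function(e) {
      stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
    })
    res$fold <- f
    pooled[[f]] <- res
  }
  dplyr::bind_rows(pooled)
}

# long truth tibble (one row per turn x truth code); empty-truth turns absent
truth_long <- function(corpus) {
  turns <- corpus$turns
  n_each <- lengths(turns$truth)
  tibble::tibble(
    session_id = rep(turns$session_id, n_each),
    turn = rep(turns$turn, n_each),
    code = unlist(turns$truth, use.names = FALSE)
  )
}

#' Per-rater binary marks for every coded turn
#'
#' A rater is taken to have coded a session if they annotated any of its
#' turns; within a coded session, a turn the rater left unmarked counts as
#' absence of every code.
#'
#' @param corpus An [mi_corpus()].
#' @param codes Code ids to emit marks for (default: the corpus inventory).
#' @return Long tibble `session_id`, `turn`, `rater`, `code`, `present`.
#' @export
rater_marks <- function(corpus, codes = corpus$codes$id) {
  turns <- corpus$turns
  session_raters <- turns |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      raters = list(sort(unique(unlist(lapply(.data$annotations, names))))),
      .groups = "drop")
  purrr::map_dfr(seq_len(nrow(session_raters)), function(i) {
    sid <- session_raters$session_id[i]
    rts <- session_raters$raters[[i]]
    if (length(rts) == 0) return(NULL)
    st <- turns[turns$session_id == sid, ]
    tidyr::expand_grid(turn = st$turn, rater = rts, code = codes) |>
      dplyr::mutate(
        session_id = sid,
        present = purrr::map2_int(.data$turn, seq_along(.data$turn), function(tn, j) {
          ann <- st$annotations[[match(tn, st$turn)]]
          r <- rater[j]
          as.integer(!is.null(ann[[r]]) && code[j] %in% ann[[r]])
        })
      ) |>
      dplyr::select("session_id", "turn", "rater", "code", "present")
  })
}

#' Evaluate pooled cross-validated predictions against human raters
#'
#' Ties the comparison tasks together: per-code ROC/AUC over all turns
#' (truth = union of raters), mean pairwise Cohen's kappa at the talk-turn
#' level and ICC on session code tallies (both restricted to sessions with
#' two or more raters), proficiency-index ICCs, and confusion pairs of the
#' model's top-1 code. Model kappa uses predictions binarized at each code's
#' corpus-prevalence-matched threshold; model session tallies count the
#' turns whose binarized prediction is positive, putting them on the same
#' count scale as the rater tallies (the expected-count variant, summing raw
#' scores, remains available through [session_tallies()]). When no
#' multiply-coded session exists the kappa/ICC sections are `NA` and AUC is
#' still emitted.
#'
#' @param pooled Output of [run_cv()].
#' @param corpus The same corpus the predictions were pooled over.
#' @return An object of class `mi_evaluation`: tibbles `auc`, `agreement`
#'   (per code: rater/model kappa and ICC), `proficiency`, `confusion`, and
#'   the `roc` curves keyed by code.
#' @export
evaluate_cv <- function(pooled, corpus) {
  codes <- corpus$codes$id
  truth <- truth_long(corpus)
  turn_key <- corpus$turns[, c("session_id", "turn")]
  # --- AUC per code over all turns
  scored <- pooled |>
    dplyr::left_join(dplyr::mutate(truth, present = 1L),
                     by = c("session_id", "turn", "code")) |>
    dplyr::mutate(present = dplyr::coalesce(.data$present, 0L))
  roc <- list()
  auc_rows <- lapply(codes, function(cd) {
    s <- dplyr::filter(scored, .data$code == cd)
    r <- tryCatch(roc_auc(s$score, s$present), error = function(e) NULL)
    roc[[cd]] <<- r
    tibble::tibble(code = cd,
                   auc = if (is.null(r)) NA_real_ else r$auc,
                   n_pos = sum(s$present), n_neg = sum(1 - s$present))
  })
  auc_tbl <- dplyr::bind_rows(auc_rows)
  # reference prevalence per code: the average rate at which a single rater
  # marks it (union prevalence would overshoot any individual rater's margin,
  # biasing the model's counts upward in the kappa/ICC comparisons)
  marks <- rater_marks(corpus, codes)
  rater_prev <- marks |>
    dplyr::group_by(.data$code, .data$rater) |>
    dplyr::summarise(p = mean(.data$present), .groups = "drop") |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(p = mean(.data$p), .groups = "drop")
  prevalence <- stats::setNames(rater_prev$p, rater_prev$code)[auc_tbl$code]
  # --- binarized model marks (prevalence-matched per code)
  model_marks <- pooled |>
    dplyr::group_by(.data$code) |>
    dplyr::mutate(present = as.integer(
      binarize_scores(.data$score,
                      max(min(prevalence[.data$code[1]], 1 - 1e-9), 1e-9)))) |>
    dplyr::ungroup() |>
    dplyr::select("session_id", "turn", "code", "present")
  # --- agreement on multiply-coded sessions
  multi <- marks |>
    dplyr::distinct(.data$session_id, .data$rater) |>
    dplyr::count(.data$session_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$session_id)
  model_counts <- dplyr::rename(model_marks, score = "present")
  if (length(multi) >= 2) {
    kap <- pairwise_kappa_summary(marks, model_marks)
    icc_tbl <- session_icc(marks, model_counts, multi, codes)
    prof <- proficiency_icc(marks, model_counts, multi)
  } else {
    kap <- tibble::tibble(code = codes, rater_kappa = NA_real_,
                          model_kappa = NA_real_, n_turns = NA_integer_)
    icc_tbl <- tibble::tibble(code = codes, rater_icc = NA_real_,
                              model_icc = NA_real_)
    prof <- tibble::tibble(
      index = c("reflection_to_question_ratio", "percent_open_questions",
                "percent_complex_reflections"),
      rater_icc = NA_real_, model_icc = NA_real_)
  }
  agreement <- auc_tbl |>
    dplyr::left_join(kap[, c("code", "rater_kappa", "model_kappa")], by = "code") |>
    dplyr::left_join(icc_tbl, by = "code")
  # --- confusion pairs of the top-1 code
  confusion <- confusion_pairs(predict_most_likely(pooled), truth)
  structure(
    list(agreement = agreement, proficiency = prof, confusion = confusion,
         roc = roc, n_multi_rater_sessions = length(multi)),
    class = "mi_evaluation"
  )
}

# per-code session-tally ICCs on multiply-coded sessions
session_icc <- function(marks, pooled, multi, codes) {
  marks_m <- dplyr::filter(marks, .data$session_id %in% multi)
  rt <- session_tallies(marks_m)
  # raters present in every multiply-coded session (a complete tally matrix)
  complete_raters <- rt |>
    dplyr::distinct(.data$session_id, .data$rater) |>
    dplyr::count(.data$rater) |>
    dplyr::filter(.data$n == length(multi)) |>
    dplyr::pull(.data$rater)
  mt <- session_tallies(
    dplyr::filter(pooled, .data$session_id %in% multi))
  purrr::map_dfr(codes, function(cd) {
    safe_icc <- function(m) tryCatch(icc_agreement(m), error = function(e) NA_real_)
    wide <- rt |>
      dplyr::filter(.data$code == cd, .data$rater %in% complete_raters) |>
      tidyr::pivot_wider(id_cols = "session_id", names_from = "rater",
                         values_from = "tally", values_fill = 0)
    r_icc <- NA_real_
    m_icc <- NA_real_
    if (length(complete_raters) >= 2 && nrow(wide) >= 2) {
      rmat <- as.matrix(wide[, complete_raters])
      r_icc <- safe_icc(rmat)
      mvec <- mt |>
        dplyr::filter(.data$code == cd) |>
        dplyr::arrange(match(.data$session_id, wide$session_id))
      mvec <- mvec$tally[match(wide$session_id, mvec$session_id)]
      mvec[is.na(mvec)] <- 0
      m_icc <- mean(vapply(complete_raters, function(r) {
        safe_icc(cbind(mvec, rmat[, r]))
      }, 0), na.rm = TRUE)
    }
    tibble::tibble(code = cd, rater_icc = r_icc, model_icc = m_icc)
  })
}

# proficiency-index ICCs (rater vs rater, model vs rater) on multi-rater sessions
proficiency_icc <- function(marks, pooled, multi) {
  idx_names <- c("reflection_to_question_ratio", "percent_open_questions",
                 "percent_complex_reflections")
  rt <- session_tallies(dplyr::filter(marks, .data$session_id %in% multi))
  mt <- session_tallies(dplyr::filter(pooled, .data$session_id %in% multi))
  rprof <- proficiency_indices(rt)
  mprof <- proficiency_indices(mt)
  complete_raters <- rprof |>
    dplyr::count(.data$rater) |>
    dplyr::filter(.data$n == length(multi)) |>
    dplyr::pull(.data$rater)
  purrr::map_dfr(idx_names, function(ix) {
    safe_icc <- function(m) tryCatch(icc_agreement(m), error = function(e) NA_real_)
    wide <- rprof |>
      dplyr::filter(.data$rater %in% complete_raters) |>
      tidyr::pivot_wider(id_cols = "session_id", names_from = "rater",
                         values_from = dplyr::all_of(ix))
    r_icc <- NA_real_
    m_icc <- NA_real_
    if (length(complete_raters) >= 2 && nrow(wide) >= 2) {
      rmat <- as.matrix(wide[, complete_raters])
      mvec <- mprof[[ix]][match(wide$session_id, mprof$session_id)]
      ok <- stats::complete.cases(rmat) & !is.na(mvec)
      if (sum(ok) >= 2) {
        r_icc <- safe_icc(rmat[ok, , drop = FALSE])
        m_icc <- mean(vapply(complete_raters, function(r) {
          safe_icc(cbind(mvec[ok], rmat[ok, r]))
        }, 0), na.rm = TRUE)
      }
    }
    tibble::tibble(index = ix, rater_icc = r_icc, model_icc = m_icc)
  })
}

#' @export
print.mi_evaluation <- function(x, ...) {
  cat(sprintf("<mi_evaluation> %d codes, %d multiply-coded sessions\n",
              nrow(x$agreement), x$n_multi_rater_sessions))
  print(x$agreement, n = nrow(x$agreement))
  cat("\nProficiency-index ICCs:\n")
  print(x$proficiency)
  invisible(x)
}

#' Figure-style agreement plot for an evaluation report
#'
#' Bar chart of rater and model reliability per code, talk-turn kappa beside
#' session-tally ICC.
#'
#' @param object An `mi_evaluation`.
#' @param ... Unused.
#' @export
autoplot.mi_evaluation <- function(object, ...) {
  long <- object$agreement |>
    tidyr::pivot_longer(
      cols = c("rater_kappa", "model_kappa", "rater_icc", "model_icc"),
      names_to = c("who", "stat"), names_sep = "_", values_to = "value") |>
    dplyr::mutate(level = ifelse(.data$stat == "kappa",
                                 "Talk turn (kappa)", "Session (ICC)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$code, y = .data$value,
                                     fill = .data$who)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = "MISC code", y = "Agreement", fill = NULL)
}

#' Write an evaluation report as tabular files
#'
#' Emits `agreement.csv` (per-code AUC, kappas, ICCs), `proficiency.csv`,
#' `confusion.csv` and `roc_points.csv` into a directory.
#'
#' @param report An `mi_evaluation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$agreement, file.path(dir, "agreement.csv"),
                   row.names = FALSE)
  utils::write.csv(report$proficiency, file.path(dir, "proficiency.csv"),
                   row.names = FALSE)
  utils::write.csv(report$confusion, file.path(dir, "confusion.csv"),
                   row.names = FALSE)
  pts <- purrr::map_dfr(names(report$roc), function(cd) {
    if (is.null(report$roc[[cd]])) return(NULL)
    dplyr::mutate(report$roc[[cd]]$points, code = cd)
  })
  utils::write.csv(pts, file.path(dir, "roc_points.csv"), row.names = FALSE)
  invisible(dir)
}
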