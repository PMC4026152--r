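#' ROC curve and AUC by the rank (Mann-Whitney) method
#'
#' AUC is the probability that a random positive turn outscores a random
#' negative one, with ties counted 1/2 — computed from rank sums, which
#' equals the trapezoidal area under the threshold-swept ROC curve.
#' 0.5 is chance, 1 perfect discrimination.
#'
#' @param scores Numeric vector of per-turn scores.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return An object of class `mi_roc`: list with `auc` and `points`, a
#'   tibble of operating points (`threshold`, `fpr`, `tpr`) from (0,0) to
#'   (1,1) as the threshold sweeps down.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0) stop("AUC undefined: need both classes")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last_of_tie <- cumsum(rle(s)$lengths)  # all tied scores cross the cut together
  points <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, cumsum(1 - l)[last_of_tie] / n0),
    tpr = c(0, cumsum(l)[last_of_tie] / n1)
  )
  structure(list(auc = auc, points = points, n_pos = n1, n_neg = n0),
            class = "mi_roc")
}

#' @export
print.mi_roc <- function(x, ...) {
  cat(sprintf("<mi_roc> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
autoplot.mi_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    )
}

#' Cohen's kappa for two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and chance
#' agreement `p_e` from the product of the raters' marginal category
#' proportions. When both raters are constant (`p_e = 1`): 1 if they agree
#' everywhere, otherwise an error, since chance-corrected agreement is
#' undefined.
#'
#' @param a,b Equal-length vectors of categorical (here: binary
#'   presence/absence) ratings.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  lev <- union(unique(a), unique(b))
  a <- factor(a, levels = lev)
  b <- factor(b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) return(1)
    stop("kappa undefined: both raters constant but unequal")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Mean pairwise rater-rater and model-rater kappa per code
#'
#' Restricted to sessions carrying two or more human raters, so that
#' human-human (inter-rater) and model-human agreement are estimated on the
#' same turns. Rater kappa averages over all rater pairs that co-coded at
#' least one session; model kappa averages the kappa of the binarized model
#' marks against each rater. Kappas that are undefined for a pair (a
#' constant, disagreeing margin) are dropped from the mean.
#'
#' @param rater_marks Long tibble: `session_id`, `turn`, `rater`, `code`,
#'   `present` (0/1) — one row per turn x rater x code, covering every coded
#'   turn of every rater.
#' @param model_marks Optional tibble `session_id`, `turn`, `code`, `present`
#'   with the model's binarized predictions on the same turns.
#' @return A tibble with one row per code: `code`, `rater_kappa`,
#'   `model_kappa` (NA when `model_marks` is absent), `n_turns`.
#' @export
pairwise_kappa_summary <- function(rater_marks, model_marks = NULL) {
  multi <- rater_marks |>
    dplyr::distinct(.data$session_id, .data$rater) |>
    dplyr::count(.data$session_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$session_id)
  if (length(multi) == 0) stop("no sessions with >= 2 raters")
  marks <- dplyr::filter(rater_marks, .data$session_id %in% multi)
  codes <- unique(marks$code)
  safe_kappa <- function(a, b) {
    tryCatch(cohens_kappa(a, b), error = function(e) NA_real_)
  }
  purrr::map_dfr(codes, function(cd) {
    m <- dplyr::filter(marks, .data$code == cd)
    wide <- tidyr::pivot_wider(m[, c("session_id", "turn", "rater", "present")],
                               names_from = "rater", values_from = "present")
    raters <- setdiff(names(wide), c("session_id", "turn"))
    rk <- c()
    if (length(raters) >= 2) {
      for (i in seq_len(length(raters) - 1)) {
        for (j in seq(i + 1, length(raters))) {
          x <- wide[[raters[i]]]
          y <- wide[[raters[j]]]
          ok <- !is.na(x) & !is.na(y)
          if (sum(ok) >= 2) rk <- c(rk, safe_kappa(x[ok], y[ok]))
        }
      }
    }
    mk <- NA_real_
    if (!is.null(model_marks)) {
      mm <- dplyr::filter(model_marks, .data$code == cd)
      wide2 <- dplyr::left_join(
        wide, mm[, c("session_id", "turn", "present")],
        by = c("session_id", "turn"))
      mks <- vapply(raters, function(r) {
        ok <- !is.na(wide2[[r]]) & !is.na(wide2$present)
        if (sum(ok) < 2) return(NA_real_)
        safe_kappa(wide2$present[ok], wide2[[r]][ok])
      }, 0)
      mk <- mean(mks, na.rm = TRUE)
    }
    tibble::tibble(code = cd,
                   rater_kappa = mean(rk, na.rm = TRUE),
                   model_kappa = mk,
                   n_turns = nrow(wide))
  })
}

#' Per-session code tallies
#'
#' For human raters the tally is the count of turns the rater marked with the
#' code; for the model it is the expected count, the sum of the continuous
#' per-turn scores. The input type is detected from the columns.
#'
#' @param x Either rater marks (`session_id`, `turn`, `rater`, `code`,
#'   `present`) or model scores (`session_id`, `turn`, `code`, `score`).
#' @return A tibble `session_id`, (`rater`,) `code`, `tally`.
#' @export
session_tallies <- function(x) {
  if ("score" %in% names(x)) {
    x |>
      dplyr::group_by(.data$session_id, .data$code) |>
      dplyr::summarise(tally = sum(.data$score), .groups = "drop")
  } else if ("present" %in% names(x)) {
    x |>
      dplyr::group_by(.data$session_id, .data$rater, .data$code) |>
      dplyr::summarise(tally = sum(.data$present), .groups = "drop")
  } else {
    stop("x must carry a 'score' or a 'present' column")
  }
}

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single measure
#'
#' The Shrout-Fleiss ICC(2,1):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from the two-way
#' ANOVA decomposition of an n-target x k-rater matrix. Absolute agreement:
#' a constant shift of one rater's column lowers the coefficient.
#'
#' @param mat Numeric matrix, sessions (targets) in rows, raters in columns.
#' @return The ICC scalar (at most 1).
#' @export
icc_agreement <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  stopifnot(n >= 2, k >= 2, !anyNA(mat))
  gm <- mean(mat)
  rowm <- rowMeans(mat)
  colm <- colMeans(mat)
  if (isTRUE(all.equal(stats::var(rowm), 0))) {
    stop("ICC undefined: zero between-session variance")
  }
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((mat - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' MI proficiency indices from session code tallies
#'
#' Standard MI supervision summaries: reflection-to-question ratio
#' `(RES + REC) / (QUC + QUO)`, percent open questions
#' `100 QUO / (QUC + QUO)`, and percent complex reflections
#' `100 REC / (RES + REC)`. A zero denominator yields `NA`, never an error.
#'
#' @param tallies Long tibble `session_id`, (`rater`,) `code`, `tally`
#'   containing at least the QUC, QUO, RES, REC rows (missing rows count 0).
#' @return One row per session (and rater): the three indices.
#' @export
proficiency_indices <- function(tallies) {
  grp <- intersect(c("session_id", "rater"), names(tallies))
  wide <- tallies |>
    dplyr::filter(.data$code %in% c("QUC", "QUO", "RES", "REC")) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(grp), names_from = "code",
                       values_from = "tally", values_fill = 0)
  for (cd in c("QUC", "QUO", "RES", "REC")) {
    if (!cd %in% names(wide)) wide[[cd]] <- 0
  }
  q <- wide$QUC + wide$QUO
  r <- wide$RES + wide$REC
  wide$reflection_to_question_ratio <- ifelse(q > 0, r / q, NA_real_)
  wide$percent_open_questions <- ifelse(q > 0, 100 * wide$QUO / q, NA_real_)
  wide$percent_complex_reflections <- ifelse(r > 0, 100 * wide$REC / r, NA_real_)
  wide[, c(grp, "reflection_to_question_ratio", "percent_open_questions",
           "percent_complex_reflections")]
}

#' Binarize continuous scores at a prevalence-matched threshold
#'
#' Picks the threshold whose predicted-positive fraction is closest to the
#' reference prevalence (the code's training prevalence); ties are broken
#' toward fewer positives, so all-equal scores yield all negatives.
#'
#' @param scores Numeric vector.
#' @param reference_prevalence Target positive fraction in (0, 1).
#' @return Logical vector of predicted presence.
#' @export
binarize_scores <- function(scores, reference_prevalence) {
  stopifnot(reference_prevalence > 0, reference_prevalence < 1)
  n <- length(scores)
  if (n == 0) return(logical(0))
  thr <- sort(unique(scores), decreasing = TRUE)
  counts <- c(0L, vapply(thr, function(t) sum(scores >= t), 0L))
  dist <- abs(counts / n - reference_prevalence)
  best <- which(dist == min(dist))[1]  # first index = fewest positives
  if (best == 1L) rep(FALSE, n) else scores >= thr[best - 1L]
}

#' Most frequently substituted code on model errors
#'
#' Over turns where the model's top-1 code is not in the turn's (non-empty)
#' truth set, tallies which code the model produced for each true code and
#' reports the most frequent substitute; ties are all reported. The full
#' histogram is attached as attribute `"histogram"`.
#'
#' @param predicted Tibble `session_id`, `turn`, `code`: the model's top-1
#'   code per turn (see [predict_most_likely()]).
#' @param truth Long tibble `session_id`, `turn`, `code`: the turns' truth
#'   codes (one row per code; turns with empty truth are absent).
#' @return A tibble `code`, `predicted_as`, `n` (empty when the model made no
#'   errors).
#' @export
confusion_pairs <- function(predicted, truth) {
  joined <- dplyr::inner_join(
    truth, predicted,
    by = c("session_id", "turn"), suffix = c("_true", "_pred"))
  err_turns <- joined |>
    dplyr::group_by(.data$session_id, .data$turn) |>
    dplyr::filter(!any(.data$code_true == .data$code_pred)) |>
    dplyr::ungroup()
  if (nrow(err_turns) == 0) {
    out <- tibble::tibble(code = character(0), predicted_as = character(0),
                          n = integer(0))
    attr(out, "histogram") <- out
    return(out)
  }
  hist <- err_turns |>
    dplyr::count(code = .data$code_true, predicted_as = .data$code_pred,
                 name = "n") |>
    dplyr::arrange(.data$code, dplyr::desc(.data$n))
  out <- hist |>
    dplyr::group_by(.data$code) |>
    dplyr::filter(.data$n == max(.data$n)) |>
    dplyr::ungroup()
  attr(out, "histogram") <- hist
  out
}
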