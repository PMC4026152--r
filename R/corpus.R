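#' Default MISC code inventory
#'
#' The twelve Motivational Interviewing Skills Code (MISC) behavioral codes
#' retained for modeling: ten therapist codes (closed/open questions, simple/
#' complex reflections, affirm, giving information, structure, support,
#' talk-turn empathy and MI spirit) and two patient codes (change talk `+`
#' and sustain talk `-`).
#'
#' @return A tibble with columns `id`, `description`, `speaker_scope`.
#' @export
#' @examples
#' misc_codes()
misc_codes <- function() {
  tibble::tibble(
    id = c("QUC", "QUO", "RES", "REC", "AF", "GI",
           "ST", "SU", "E", "SP", "+", "-"),
    description = c(
      "Question Closed", "Question Open", "Reflection Simple",
      "Reflection Complex", "Affirm", "Giving Information", "Structure",
      "Support", "High Empathy", "High Spirit", "Change Talk", "Sustain Talk"
    ),
    speaker_scope = c(rep("therapist", 10L), "patient", "patient")
  )
}

#' Summary of the addiction corpus the method was developed on
#'
#' Per-study session, talk-turn and word counts for the five motivational
#' interviewing studies making up the original 148-session addiction corpus,
#' together with its coder-coverage design (117 sessions coded by a single
#' coder, 31 by all three). These magnitudes anchor the defaults of
#' [sim_config()]; the transcripts themselves are confidential and are not
#' distributed.
#'
#' @return A tibble with columns `study`, `sessions`, `talk_turns`, `words`,
#'   carrying attributes `single_coded` and `triple_coded` (session counts).
#' @export
addiction_corpus_summary <- function() {
  out <- tibble::tibble(
    study      = c("ARC", "ESPSB", "ESP21", "HMCBI", "iCHAMP"),
    sessions   = c(10L, 20L, 41L, 70L, 7L),
    talk_turns = c(1768L, 5266L, 9967L, 11039L, 1950L),
    words      = c(72712L, 182738L, 391164L, 284097L, 74213L)
  )
  attr(out, "single_coded") <- 117L
  attr(out, "triple_coded") <- 31L
  out
}

#' Construct a talk-turn corpus
#'
#' Bundles a turn-level tibble with its code inventory and study inventory
#' and validates the structural invariants: turn indices consecutive from 0
#' within each session, speakers in `therapist`/`patient`, non-empty study
#' labels, and every annotated code id present in the inventory.
#'
#' @param turns A data frame with one row per talk turn and columns
#'   `session_id`, `study`, `turn` (0-based index within session), `speaker`,
#'   `text`, and `annotations` (a list column: each element a named list
#'   mapping rater id to a character vector of code ids; empty list for
#'   unannotated turns). Optional list columns `truth` and `tokens` are kept.
#' @param codes Code inventory tibble as produced by [misc_codes()].
#' @return An object of class `mi_corpus`: a list with elements `turns`
#'   (tibble), `codes`, `studies`, and (once [tokenize_corpus()] has run)
#'   `vocabulary` and `phrases`.
#' @export
mi_corpus <- function(turns, codes = misc_codes()) {
  stopifnot(is.data.frame(turns), is.data.frame(codes))
  req <- c("session_id", "study", "speaker", "text", "annotations")
  missing_cols <- setdiff(req, names(turns))
  if (length(missing_cols) > 0) {
    stop("turns is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(codes$id)) stop("code ids must be unique")
  turns <- tibble::as_tibble(turns)
  if (!"turn" %in% names(turns)) {
    turns <- turns |>
      dplyr::group_by(.data$session_id) |>
      dplyr::mutate(turn = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
  }
  turns$turn <- as.integer(turns$turn)
  if (!"truth" %in% names(turns)) {
    turns$truth <- vector("list", nrow(turns))
  }
  if (!"tokens" %in% names(turns)) {
    turns$tokens <- vector("list", nrow(turns))
  }
  corpus <- structure(
    list(
      turns = turns[, c("session_id", "study", "turn", "speaker", "text",
                        "annotations", "truth", "tokens")],
      codes = tibble::as_tibble(codes),
      studies = sort(unique(turns$study)),
      vocabulary = NULL,
      phrases = NULL
    ),
    class = "mi_corpus"
  )
  validate_corpus(corpus)
  corpus
}

validate_corpus <- function(corpus) {
  turns <- corpus$turns
  if (!all(turns$speaker %in% c("therapist", "patient"))) {
    stop("speaker must be 'therapist' or 'patient'")
  }
  if (any(is.na(turns$study) | turns$study == "")) {
    stop("every session must carry a non-empty study label")
  }
  idx_ok <- turns |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(ok = identical(as.integer(.data$turn),
                                    seq_len(dplyr::n()) - 1L)) |>
    dplyr::pull(.data$ok)
  if (!all(idx_ok)) {
    stop("turn indices must be consecutive from 0 within each session")
  }
  ann_codes <- unique(unlist(lapply(turns$annotations, unlist), use.names = FALSE))
  unknown <- setdiff(ann_codes, corpus$codes$id)
  if (length(unknown) > 0) {
    stop("unknown code id(s) in annotations: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(corpus$vocabulary)) {
    V <- length(corpus$vocabulary)
    tok <- unlist(turns$tokens, use.names = FALSE)
    if (length(tok) > 0 && (min(tok) < 0L || max(tok) >= V)) {
      stop("token ids must lie in [0, vocabulary size)")
    }
  }
  invisible(corpus)
}

#' @export
print.mi_corpus <- function(x, ...) {
  n_sess <- length(unique(x$turns$session_id))
  cat(sprintf("<mi_corpus> %d sessions, %d talk turns, %d studies, %d codes\n",
              n_sess, nrow(x$turns), length(x$studies), nrow(x$codes)))
  if (!is.null(x$vocabulary)) {
    cat(sprintf("  vocabulary: %d terms (%d multi-word phrases)\n",
                length(x$vocabulary),
                if (is.null(x$phrases)) 0L else nrow(x$phrases)))
  }
  invisible(x)
}

#' Tokenize raw talk-turn text
#'
#' Lowercases, normalizes curly apostrophes, strips punctuation except
#' intra-word apostrophes and hyphens, and splits on whitespace. Numerals are
#' kept. Total function: empty or all-punctuation input yields a zero-length
#' token vector. Idempotent on its own output joined by spaces.
#'
#' @param text Character vector of raw talk-turn texts.
#' @return A list of character vectors, one per element of `text`.
#' @export
#' @examples
#' tokenize("It sounds like you're doing it.")[[1]]
tokenize <- function(text) {
  text <- tolower(as.character(text))
  text <- gsub("’", "'", text)
  # anything that is not a word character, apostrophe or hyphen separates tokens
  text <- gsub("[^a-z0-9'-]+", " ", text)
  # apostrophes/hyphens survive only between word characters
  text <- gsub("(^|\\s)['-]+", " ", text)
  text <- gsub("['-]+(\\s|$)", " ", text)
  out <- strsplit(trimws(text), "\\s+")
  lapply(out, function(w) w[nzchar(w)])
}

#' Build a table of multi-word phrases
#'
#' Collects all contiguous bigrams and trigrams over the tokenized turns and
#' retains those whose talk-turn document frequency (number of distinct turns
#' containing the phrase) reaches `min_doc_freq`.
#'
#' @param token_lists List of character vectors, one per talk turn.
#' @param min_doc_freq Minimum number of turns a phrase must appear in.
#' @param max_n Maximum phrase length in words (2 or 3).
#' @return A tibble with columns `phrase`, `n_turns`, sorted by descending
#'   `n_turns` then phrase; attribute `min_doc_freq` records the threshold.
#' @export
build_phrase_table <- function(token_lists, min_doc_freq = 10, max_n = 3) {
  stopifnot(min_doc_freq >= 1, max_n %in% c(2, 3))
  grams <- lapply(token_lists, function(w) {
    n <- length(w)
    out <- character(0)
    if (max_n >= 2 && n >= 2) {
      out <- c(out, paste(w[-n], w[-1]))
    }
    if (max_n >= 3 && n >= 3) {
      out <- c(out, paste(w[1:(n - 2)], w[2:(n - 1)], w[3:n]))
    }
    unique(out)
  })
  tab <- table(unlist(grams, use.names = FALSE))
  keep <- tab[tab >= min_doc_freq]
  out <- tibble::tibble(phrase = as.character(names(keep)),
                        n_turns = as.integer(keep)) |>
    dplyr::arrange(dplyr::desc(.data$n_turns), .data$phrase)
  attr(out, "min_doc_freq") <- min_doc_freq
  out
}

#' Segment a word sequence against a phrase table
#'
#' Greedy left-to-right longest match: at each position a trigram is tried,
#' then a bigram, then the single word. Every source word is consumed exactly
#' once, so the concatenation of the output terms' words reproduces the input.
#'
#' @param words Character vector of unigram tokens (from [tokenize()]).
#' @param phrases Phrase table from [build_phrase_table()], or a character
#'   vector of space-joined phrases.
#' @return Character vector of terms (unigrams or space-joined phrases).
#' @export
segment_with_phrases <- function(words, phrases) {
  if (is.data.frame(phrases)) {
    phrases <- if ("phrase" %in% names(phrases)) phrases$phrase else character(0)
  }
  if (length(phrases) == 0 || length(words) == 0) return(words)
  env <- new.env(hash = TRUE, size = max(16L, length(phrases)))
  for (p in phrases) assign(p, TRUE, envir = env)
  n <- length(words)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    took <- 1L
    if (i + 2L <= n) {
      tri <- paste(words[i], words[i + 1L], words[i + 2L])
      if (exists(tri, envir = env, inherits = FALSE)) {
        k <- k + 1L; out[k] <- tri; took <- 3L
      }
    }
    if (took == 1L && i + 1L <= n) {
      bi <- paste(words[i], words[i + 1L])
      if (exists(bi, envir = env, inherits = FALSE)) {
        k <- k + 1L; out[k] <- bi; took <- 2L
      }
    }
    if (took == 1L) {
      k <- k + 1L; out[k] <- words[i]
    }
    i <- i + took
  }
  out[seq_len(k)]
}

#' Fuse multi-rater annotations into a truth set
#'
#' `merge_rater_codes()` takes the union of all raters' code sets for one
#' talk turn, matching the convention that a turn labeled A+B, B+C and D by
#' three raters is treated as carrying codes A, B, C and D. `fuse_raters()`
#' applies it across a corpus, filling the `truth` list column.
#'
#' @param annotations Named list mapping rater id to a character vector of
#'   code ids (empty vectors allowed).
#' @return Sorted character vector: the union of the raters' codes.
#' @export
#' @examples
#' merge_rater_codes(list(r1 = c("A", "B"), r2 = c("B", "C"), r3 = "D"))
merge_rater_codes <- function(annotations) {
  if (length(annotations) == 0) {
    stop("unannotated turn: no rater annotations to merge")
  }
  sort(unique(unlist(annotations, use.names = FALSE)))
}

#' @rdname merge_rater_codes
#' @param corpus An [mi_corpus()].
#' @param unannotated How to treat turns with no annotations: `"empty"`
#'   (default; truth is the empty set, the turn still contributes study and
#'   background language in training) or `"error"`.
#' @export
fuse_raters <- function(corpus, unannotated = c("empty", "error")) {
  unannotated <- match.arg(unannotated)
  corpus$turns$truth <- lapply(corpus$turns$annotations, function(a) {
    if (length(a) == 0) {
      if (unannotated == "error") stop("unannotated turn: no rater annotations to merge")
      character(0)
    } else {
      merge_rater_codes(a)
    }
  })
  corpus
}

#' Retain codes present in a minimum share of talk turns
#'
#' A code is retained iff the fraction of talk turns whose truth set contains
#' it is at least `threshold` (inclusive, so "2% or more" keeps a code sitting
#' exactly at 2%). Requires truth sets (see [fuse_raters()]).
#'
#' @param corpus An [mi_corpus()] with truth populated.
#' @param threshold Prevalence threshold in (0, 1); default 0.02.
#' @return Character vector of retained code ids, in inventory order.
#' @export
code_prevalence_filter <- function(corpus, threshold = 0.02) {
  stopifnot(threshold > 0, threshold < 1)
  n <- nrow(corpus$turns)
  if (n == 0) stop("no talk turns")
  counts <- table(factor(unlist(corpus$turns$truth, use.names = FALSE),
                         levels = corpus$codes$id))
  corpus$codes$id[as.vector(counts) / n >= threshold]
}

#' Restrict a corpus to a subset of codes
#'
#' Drops all other codes from the inventory and intersects every truth set
#' and rater annotation with the retained set.
#'
#' @param corpus An [mi_corpus()].
#' @param code_ids Character vector of code ids to keep.
#' @return The restricted corpus.
#' @export
retain_codes <- function(corpus, code_ids) {
  unknown <- setdiff(code_ids, corpus$codes$id)
  if (length(unknown) > 0) {
    stop("unknown code id(s): ", paste(unknown, collapse = ", "))
  }
  corpus$codes <- corpus$codes[corpus$codes$id %in% code_ids, ]
  corpus$turns$truth <- lapply(corpus$turns$truth, function(s) {
    if (is.null(s)) NULL else intersect(s, code_ids)
  })
  corpus$turns$annotations <- lapply(corpus$turns$annotations, function(a) {
    lapply(a, function(s) intersect(s, code_ids))
  })
  corpus
}

#' Tokenize a corpus into vocabulary ids
#'
#' Runs [tokenize()] over every turn, builds the phrase table on the corpus
#' itself (or applies a supplied vocabulary/phrase table, e.g. the training
#' fold's), segments with greedy longest match, and fills the `tokens` column
#' with dense 0-based vocabulary ids. When an external vocabulary is applied,
#' out-of-vocabulary terms are dropped.
#'
#' @param corpus An [mi_corpus()].
#' @param min_phrase_doc_freq Document-frequency threshold for admitting
#'   bigram/trigram phrases as vocabulary terms.
#' @param vocabulary,phrases Optional: reuse an existing vocabulary (character
#'   vector, ids are position - 1) and phrase table instead of building them.
#' @return The corpus with `vocabulary`, `phrases` and per-turn `tokens` set.
#' @export
tokenize_corpus <- function(corpus, min_phrase_doc_freq = 10,
                            vocabulary = NULL, phrases = NULL) {
  words <- tokenize(corpus$turns$text)
  if (is.null(vocabulary)) {
    phrases <- build_phrase_table(words, min_doc_freq = min_phrase_doc_freq)
    terms <- lapply(words, segment_with_phrases, phrases = phrases)
    vocabulary <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    if (is.null(phrases)) phrases <- tibble::tibble(phrase = character(0),
                                                    n_turns = integer(0))
    terms <- lapply(words, segment_with_phrases, phrases = phrases)
  }
  corpus$vocabulary <- vocabulary
  corpus$phrases <- phrases
  corpus$turns$tokens <- lapply(terms, function(tt) {
    ids <- match(tt, vocabulary) - 1L
    ids[!is.na(ids)]
  })
  validate_corpus(corpus)
  corpus
}

# ---- corpus file I/O (JSON lines; header record carries inventories) --------

#' Read and write talk-turn corpora
#'
#' The on-disk format is UTF-8 JSON lines: a header record carrying the code
#' inventory, study inventory, phrase table and vocabulary, followed by one
#' record per talk turn (session id, study, 0-based turn index, speaker, raw
#' text, per-rater code lists, and the fused truth set if present). Token ids
#' are not stored; they are rebuilt deterministically from the stored
#' vocabulary and phrase table on read. `write_corpus()` then `read_corpus()`
#' reproduces an equal corpus, and re-writing reproduces the file byte for
#' byte.
#'
#' @param path File path.
#' @param corpus An [mi_corpus()].
#' @return `read_corpus()` returns an `mi_corpus`; `write_corpus()` returns
#'   `path` invisibly.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty corpus file: ", path)
  parse_line <- function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec)) stop("malformed record at line ", i, " of ", path)
    rec
  }
  header <- parse_line(1)
  if (!identical(header$type, "header")) {
    stop("malformed record at line 1: expected header record")
  }
  codes <- tibble::tibble(
    id = vapply(header$codes, function(x) x$id, ""),
    description = vapply(header$codes, function(x) x$description, ""),
    speaker_scope = vapply(header$codes, function(x) x$speaker_scope, "")
  )
  recs <- lapply(seq_along(lines)[-1], parse_line)
  chr0 <- function(x) as.character(unlist(x, use.names = FALSE))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (!identical(rec$type, "turn") || is.null(rec$session) ||
        is.null(rec$study) || is.null(rec$speaker) || is.null(rec$text)) {
      stop("malformed record at line ", i + 1, " of ", path)
    }
    bad <- setdiff(unique(chr0(rec$annotations)), codes$id)
    if (length(bad) > 0) {
      stop("unknown code id(s) at line ", i + 1, ": ", paste(bad, collapse = ", "))
    }
  }
  turns <- tibble::tibble(
    session_id = vapply(recs, function(r) r$session, ""),
    study = vapply(recs, function(r) r$study, ""),
    turn = vapply(recs, function(r) as.integer(r$turn), 1L),
    speaker = vapply(recs, function(r) r$speaker, ""),
    text = vapply(recs, function(r) r$text, ""),
    annotations = lapply(recs, function(r) lapply(r$annotations, chr0)),
    truth = lapply(recs, function(r) if (is.null(r$truth)) NULL else chr0(r$truth))
  )
  corpus <- mi_corpus(turns, codes = codes)
  if (!is.null(header$vocabulary)) {
    corpus <- tokenize_corpus(
      corpus,
      vocabulary = chr0(header$vocabulary),
      phrases = tibble::tibble(
        phrase = vapply(header$phrases, function(x) x$phrase, ""),
        n_turns = vapply(header$phrases, function(x) as.integer(x$n_turns), 1L)
      )
    )
  }
  corpus
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  to_json <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                          null = "null")
  header <- list(
    type = "header",
    codes = unname(apply(corpus$codes, 1, as.list)),
    studies = as.list(corpus$studies),
    phrases = if (is.null(corpus$phrases)) NULL else
      unname(lapply(seq_len(nrow(corpus$phrases)), function(i) {
        list(phrase = corpus$phrases$phrase[i],
             n_turns = corpus$phrases$n_turns[i])
      })),
    vocabulary = if (is.null(corpus$vocabulary)) NULL else
      as.list(corpus$vocabulary)
  )
  lines <- character(nrow(corpus$turns) + 1L)
  lines[1] <- to_json(header)
  for (i in seq_len(nrow(corpus$turns))) {
    tr <- corpus$turns[i, ]
    rec <- list(
      type = "turn",
      session = tr$session_id,
      study = tr$study,
      turn = tr$turn,
      speaker = tr$speaker,
      text = tr$text,
      annotations = lapply(tr$annotations[[1]], as.list),
      truth = if (is.null(tr$truth[[1]])) NULL else as.list(tr$truth[[1]])
    )
    lines[i + 1L] <- to_json(rec)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
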