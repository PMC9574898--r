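#' Read a questionnaire answer key from YAML
#'
#' Parses a key like the packaged [sa_answer_key()] into one row per
#' scoreable item. Multi-part questions (the blood-pressure question has a
#' systolic and a diastolic item) expand to one row per item, so the four
#' clinically relevant questions yield five level-1 items.
#'
#' @param path YAML file path.
#' @return A tibble (`question_id`, `item_id`, `category`, `type`,
#'   `correct`, `accepted`, `margin`, `direction`) of class `sa_key`.
#' @export
read_sa_key <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$questions)) abort("Key YAML must have a top-level 'questions' key")
  key <- purrr::map_dfr(doc$questions, function(q) {
    base <- tibble::tibble(
      question_id = as.integer(q$id),
      category = q$category,
      type = q$type,
      margin = q$margin %||% NA_real_,
      direction = q$direction %||% NA_character_,
      accepted = list(q$accepted %||% character())
    )
    if (!is.null(q$items)) {
      purrr::map_dfr(q$items, function(it) {
        dplyr::mutate(base,
          item_id = paste0("q", q$id, "_", it$item),
          correct = as.character(it$correct)
        )
      })
    } else {
      dplyr::mutate(base,
        item_id = paste0("q", q$id),
        correct = as.character(q$correct %||% NA)
      )
    }
  })
  key <- dplyr::select(
    key, "question_id", "item_id", "category", "type",
    "correct", "accepted", "margin", "direction"
  )
  n_sa1 <- sum(key$category == "sa1")
  n_env <- sum(key$category == "environment")
  if (n_sa1 != 5 || n_env != 7) {
    warn(paste0(
      "Key has ", n_env, " environment and ", n_sa1,
      " level-1 items (the standard probe has 7 and 5)"
    ))
  }
  class(key) <- c("sa_key", class(key))
  key
}

#' Packaged answer key for the 13-question awareness probe
#'
#' The default key: seven environment items, five situation-awareness
#' level-1 items across four questions (blood pressure counts systolic and
#' diastolic separately), one open level-2 and one open level-3 question.
#' Numeric items carry an inclusive ±10% margin; the oxygen-saturation key
#' is a lower bound (≥ 97).
#'
#' @return An `sa_key` tibble, see [read_sa_key()].
#' @export
sa_answer_key <- function() {
  read_sa_key(
    system.file("extdata", "sa_answer_key.yaml", package = "seevfit", mustWork = TRUE)
  )
}

# Answer-state helpers. A blank (NA or "") means the item was skipped and is
# excluded from numerator and denominator; an explicit unknown marker
# ("?", "unknown", "dont know", ...) scores 0.
is_blank_answer <- function(x) is.na(x) | trimws(x) == ""

is_unknown_marker <- function(x) {
  norm <- gsub("[^a-z?]", "", tolower(trimws(x)))
  norm %in% c("?", "??", "unknown", "dontknow", "dunno", "idontknow", "noidea")
}

#' Score a closed (yes/no) answer
#'
#' Answers on the 4-point scale (`sure yes`, `yes`, `no`, `sure no`) are
#' collapsed to yes/no before comparison with the key. Blanks are excluded
#' (returned as `NA`); an unknown marker such as `"?"` scores 0; anything
#' outside the scale vocabulary is an error.
#'
#' @param answer Character vector of raw answers.
#' @param correct The keyed answer, `"yes"` or `"no"`.
#' @return Integer vector: 1, 0, or `NA` for excluded.
#' @export
#' @examples
#' score_closed_answer(c("sure yes", "no", "?", ""), "yes")
score_closed_answer <- function(answer, correct) {
  correct <- tolower(trimws(correct))
  stopifnot(correct %in% c("yes", "no"))
  norm <- tolower(gsub("[_-]", " ", trimws(as.character(answer))))
  out <- rep(NA_integer_, length(norm))
  blank <- is_blank_answer(norm)
  unk <- !blank & is_unknown_marker(norm)
  out[unk] <- 0L
  scale_yes <- c("sure yes", "yes")
  scale_no <- c("sure no", "no")
  closed <- !blank & !unk
  bad <- closed & !norm %in% c(scale_yes, scale_no)
  if (any(bad)) {
    abort(paste0(
      "Answer(s) outside the closed-scale vocabulary: ",
      paste(unique(answer[bad]), collapse = ", ")
    ))
  }
  collapsed <- ifelse(norm %in% scale_yes, "yes", "no")
  out[closed] <- as.integer(collapsed[closed] == correct)
  out
}

#' Score a numeric answer against a keyed value with a relative margin
#'
#' An answer is correct iff it lies within the inclusive relative margin
#' around the keyed value: `|value - correct| <= margin * correct`. Strings
#' are parsed to their first numeric token (units like `%` or `bpm` are
#' tolerated); an unparseable non-blank answer is treated as an unknown
#' marker and scores 0 (with a warning unless it is an explicit marker).
#'
#' @param value Numeric or character vector of answers.
#' @param correct Keyed value (> 0).
#' @param margin Relative margin, default 0.10.
#' @return Integer vector: 1, 0, or `NA` for blank answers.
#' @export
#' @examples
#' score_numeric_answer(c(51, 56, 45), correct = 51)
score_numeric_answer <- function(value, correct, margin = 0.10) {
  correct <- as.numeric(correct)
  stopifnot(correct > 0, margin >= 0)
  parsed <- parse_numeric_answer(value)
  out <- rep(NA_integer_, length(parsed))
  keep <- !is.na(parsed)
  # the margin is inclusive on both sides; the small relative slack keeps
  # answers lying exactly on the boundary correct despite floating-point
  # representation (e.g. 51 * 1.1 vs 56.1)
  out[keep] <- as.integer(
    abs(parsed[keep] - correct) <= margin * correct * (1 + 1e-9)
  )
  chr <- as.character(value)
  blank <- is_blank_answer(chr)
  out[!keep & !blank] <- 0L
  out
}

# First numeric token of a free-form numeric answer ("~120", ">=97%", "51 bpm").
parse_numeric_answer <- function(value) {
  if (is.numeric(value)) {
    return(as.numeric(value))
  }
  chr <- as.character(value)
  token <- regmatches(chr, regexpr("-?[0-9]+([.,][0-9]+)?", chr))
  parsed <- rep(NA_real_, length(chr))
  has <- regexpr("-?[0-9]+([.,][0-9]+)?", chr) > 0
  parsed[has] <- as.numeric(gsub(",", ".", unlist(token)))
  unparseable <- !has & !is_blank_answer(chr) & !is_unknown_marker(chr)
  if (any(unparseable)) {
    warn(paste0(
      "Unparseable numeric answer(s) scored as unknown: ",
      paste(unique(chr[unparseable]), collapse = ", ")
    ))
  }
  parsed
}

# Threshold item: correct iff answer clears the keyed bound (inclusive).
score_threshold_answer <- function(value, correct, direction = "ge") {
  parsed <- parse_numeric_answer(value)
  out <- rep(NA_integer_, length(parsed))
  keep <- !is.na(parsed)
  out[keep] <- as.integer(
    if (direction == "ge") parsed[keep] >= correct else parsed[keep] <= correct
  )
  chr <- as.character(value)
  out[!keep & !is_blank_answer(chr)] <- 0L
  out
}

# Free-text item: correct iff any accepted phrase occurs in the normalized
# answer (or vice versa). A crude stand-in for the study's manual scoring.
score_text_answer <- function(answer, accepted) {
  norm <- tolower(trimws(as.character(answer)))
  acc <- tolower(trimws(accepted))
  out <- rep(NA_integer_, length(norm))
  blank <- is_blank_answer(norm)
  unk <- !blank & is_unknown_marker(norm)
  out[unk] <- 0L
  open <- !blank & !unk
  out[open] <- vapply(norm[open], function(a) {
    as.integer(any(vapply(
      acc, function(k) grepl(k, a, fixed = TRUE) || grepl(a, k, fixed = TRUE),
      logical(1)
    )))
  }, integer(1))
  out
}

# Score one key row against a vector of raw answers.
score_item <- function(answer, key_row) {
  switch(key_row$type,
    binary = score_closed_answer(answer, key_row$correct),
    numeric = score_numeric_answer(answer, key_row$correct,
      margin = key_row$margin %||% 0.10
    ),
    numeric_threshold = score_threshold_answer(
      answer, as.numeric(key_row$correct),
      direction = key_row$direction %||% "ge"
    ),
    text = score_text_answer(answer, key_row$accepted[[1]]),
    open = rep(NA_integer_, length(answer)),
    abort(paste0("Unknown item type: ", key_row$type))
  )
}

#' Read questionnaire responses from CSV
#'
#' Expects columns `participant_id`, the item columns named as in the key
#' (`q1`...`q8`, `q9_systolic`, `q9_diastolic`, `q10`...`q13`), and
#' optionally logical flags `q8_excluded` (the item is dropped from that
#' participant's denominators) and `env_events` (`FALSE` marks participants
#' who were run without the environmental events; their environment and
#' global scores are undefined).
#'
#' @param path CSV path.
#' @return A tibble, one row per participant.
#' @export
read_sa_responses <- function(path) {
  df <- tibble::as_tibble(read.csv(path,
    stringsAsFactors = FALSE,
    colClasses = "character"
  ))
  if (!"participant_id" %in% names(df)) abort("Responses CSV needs a participant_id column")
  if ("q8_excluded" %in% names(df)) {
    df$q8_excluded <- tolower(df$q8_excluded) %in% c("true", "1", "yes")
  }
  if ("env_events" %in% names(df)) {
    df$env_events <- !(tolower(df$env_events) %in% c("false", "0", "no"))
  }
  df
}

#' Score awareness questionnaires
#'
#' Scores each participant's closed items against the key and aggregates
#' three proportions of correct among non-excluded items:
#' * `sa1` — the five clinically relevant level-1 items,
#' * `environment` — the seven environment items,
#' * `global` — both sets combined (by default per item, so the two-part
#'   blood-pressure question contributes two countable items; set
#'   `global_denominator = "per_question"` to count it once, with credit
#'   only when all its non-excluded items are correct).
#'
#' Blank answers are excluded from numerator and denominator; unknown
#' markers score 0; a participant's question 8 is excluded when their
#' `q8_excluded` flag is set; participants with `env_events = FALSE` get
#' `NA` environment and global scores. Open level-2/3 answers are passed
#' through unscored; an `overall_sa` column (an expert's binary rating), if
#' present, is carried through untouched.
#'
#' @param responses Wide response tibble, see [read_sa_responses()].
#' @param key An `sa_key`, default [sa_answer_key()].
#' @param global_denominator `"per_item"` (default) or `"per_question"`.
#' @return A tibble with one row per participant: scores (`global`,
#'   `environment`, `sa1`), their numerators and denominators, and any
#'   carried-through columns.
#' @export
compute_sa_scores <- function(responses, key = sa_answer_key(),
                              global_denominator = c("per_item", "per_question")) {
  global_denominator <- match.arg(global_denominator)
  stopifnot(is.data.frame(responses), "participant_id" %in% names(responses))
  closed <- key[key$type != "open", ]
  missing_items <- setdiff(closed$item_id, names(responses))
  if (length(missing_items) > 0) {
    abort(paste0("Responses lack item column(s): ", paste(missing_items, collapse = ", ")))
  }
  q8_excluded <- if ("q8_excluded" %in% names(responses)) responses$q8_excluded else FALSE
  q8_excluded <- rep_len(q8_excluded, nrow(responses))
  env_events <- if ("env_events" %in% names(responses)) responses$env_events else TRUE
  env_events <- rep_len(env_events, nrow(responses))

  # participant x item matrix of 1/0/NA item scores
  scores <- purrr::map(seq_len(nrow(closed)), function(i) {
    k <- closed[i, ]
    s <- score_item(responses[[k$item_id]], k)
    if (k$question_id == 8L) s[q8_excluded] <- NA_integer_
    s
  })
  names(scores) <- closed$item_id
  smat <- do.call(cbind, scores)

  prop_of <- function(cols, rows = TRUE) {
    sub <- smat[, cols, drop = FALSE]
    num <- as.integer(rowSums(sub == 1, na.rm = TRUE))
    den <- as.integer(rowSums(!is.na(sub)))
    list(score = ifelse(den > 0, num / den, NA_real_), num = num, den = den)
  }
  env_cols <- closed$item_id[closed$category == "environment"]
  sa1_cols <- closed$item_id[closed$category == "sa1"]
  env <- prop_of(env_cols)
  sa1 <- prop_of(sa1_cols)

  if (global_denominator == "per_item") {
    glob <- prop_of(c(env_cols, sa1_cols))
  } else {
    # one credit per question; multi-item questions need every
    # non-excluded item correct
    qids <- unique(closed$question_id)
    qnum <- qden <- matrix(0L, nrow(responses), length(qids))
    for (j in seq_along(qids)) {
      cols <- closed$item_id[closed$question_id == qids[j]]
      sub <- smat[, cols, drop = FALSE]
      answered <- rowSums(!is.na(sub)) > 0
      allcorrect <- answered & rowSums(sub == 0, na.rm = TRUE) == 0
      qden[, j] <- as.integer(answered)
      qnum[, j] <- as.integer(allcorrect)
    }
    den <- as.integer(rowSums(qden))
    num <- as.integer(rowSums(qnum))
    glob <- list(
      score = ifelse(den > 0, num / den, NA_real_),
      num = num, den = den
    )
  }

  out <- tibble::tibble(
    participant_id = responses$participant_id,
    global = ifelse(env_events, glob$score, NA_real_),
    global_n = ifelse(env_events, glob$den, NA_integer_),
    environment = ifelse(env_events, env$score, NA_real_),
    environment_n = ifelse(env_events, env$den, NA_integer_),
    sa1 = !!sa1$score,
    sa1_n = !!sa1$den
  )
  if ("overall_sa" %in% names(responses)) {
    out$overall_sa <- as.integer(responses$overall_sa)
  }
  out
}
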