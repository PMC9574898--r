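test_that("the packaged key has the expected category structure", {
  key <- sa_answer_key()
  closed <- key[key$type != "open", ]
  expect_equal(sum(closed$category == "environment"), 7L)
  expect_equal(sum(closed$category == "sa1"), 5L)
  expect_equal(sum(closed$question_id == 9), 2L) # systolic + diastolic
  expect_equal(sum(key$type == "open"), 2L)
})

test_that("closed answers collapse the 4-point scale before comparison", {
  expect_identical(score_closed_answer(c("sure yes", "yes"), "yes"), c(1L, 1L))
  expect_identical(score_closed_answer(c("sure no", "no"), "yes"), c(0L, 0L))
  expect_identical(score_closed_answer("sure no", "no"), 1L)
  # blank is excluded (NA), a question mark scores zero
  expect_identical(score_closed_answer(c("", NA, "?"), "yes"), c(NA_integer_, NA_integer_, 0L))
  expect_error(score_closed_answer("maybe", "yes"), "vocabulary")
})

test_that("numeric answers use an inclusive relative margin", {
  expect_identical(score_numeric_answer(51, 51), 1L)
  expect_identical(score_numeric_answer(56, 51), 1L) # 9.8% off
  expect_identical(score_numeric_answer(45, 51), 0L) # 11.8% off
  # boundary is inclusive on both sides
  expect_identical(score_numeric_answer(51 * 1.1, 51), 1L)
  expect_identical(score_numeric_answer(51 * 0.9, 51), 1L)
  # string answers with units parse; garbage scores zero with a warning
  expect_identical(score_numeric_answer("51 bpm", 51), 1L)
  expect_warning(got <- score_numeric_answer("no idea at all", 51), "Unparseable")
  expect_identical(got, 0L)
  expect_identical(score_numeric_answer("?", 51), 0L)
  expect_identical(score_numeric_answer("", 51), NA_integer_)
})

test_that("the saturation key is a lower bound, not a point", {
  resp <- all_correct_responses()
  key <- sa_answer_key()
  for (ans in c("97", "98%", ">=99", "100")) {
    resp$q11 <- ans
    expect_equal(compute_sa_scores(resp, key)$sa1, 1, info = ans)
  }
  resp$q11 <- "95"
  expect_equal(compute_sa_scores(resp, key)$sa1, 4 / 5)
})

test_that("category scores are proportions of non-excluded items", {
  key <- sa_answer_key()
  resp <- all_correct_responses()
  sc <- compute_sa_scores(resp, key)
  expect_equal(sc$global, 1)
  expect_equal(sc$environment, 1)
  expect_equal(sc$sa1, 1)
  expect_equal(sc$global_n, 12L) # per-item: 7 environment + 5 level-1
  expect_equal(sc$environment_n, 7L)
  expect_equal(sc$sa1_n, 5L)

  # 3 of 5 level-1 items correct
  resp2 <- all_correct_responses()
  resp2$q10 <- "80"
  resp2$q7 <- "no"
  expect_equal(compute_sa_scores(resp2, key)$sa1, 3 / 5)

  # blanks shrink the denominator instead of scoring zero
  resp3 <- all_correct_responses()
  resp3$q9_systolic <- ""
  sc3 <- compute_sa_scores(resp3, key)
  expect_equal(sc3$sa1, 1)
  expect_equal(sc3$sa1_n, 4L)
  # ...while an unknown marker keeps it and scores zero
  resp4 <- all_correct_responses()
  resp4$q9_systolic <- "?"
  expect_equal(compute_sa_scores(resp4, key)$sa1, 4 / 5)
})

test_that("the flagged misleading question leaves the denominators", {
  key <- sa_answer_key()
  resp <- all_correct_responses()
  # 4 of the remaining 6 environment questions correct, q8 flagged
  resp$q2 <- "yes" # wrong
  resp$q4 <- "?" # wrong (counts)
  resp$q8_excluded <- TRUE
  sc <- compute_sa_scores(resp, key)
  expect_equal(sc$environment, 4 / 6)
  expect_equal(sc$environment_n, 6L)
  # unflagged, the same answers score out of 7
  resp$q8_excluded <- FALSE
  expect_equal(compute_sa_scores(resp, key)$environment, 5 / 7)
})

test_that("global score can count questions instead of items", {
  key <- sa_answer_key()
  resp <- all_correct_responses()
  resp$q9_diastolic <- "80" # wrong half of the blood-pressure question
  per_item <- compute_sa_scores(resp, key, global_denominator = "per_item")
  per_q <- compute_sa_scores(resp, key, global_denominator = "per_question")
  expect_equal(per_item$global, 11 / 12)
  # both-correct rule: the two-item question loses its whole credit
  expect_equal(per_q$global, 10 / 11)
})

test_that("scores are invariant to question order and extra blank items", {
  key <- sa_answer_key()
  resp <- all_correct_responses()
  resp$q3 <- "yes" # one wrong answer
  base <- compute_sa_scores(resp, key)
  shuffled <- resp[, sample(ncol(resp))]
  expect_equal(compute_sa_scores(shuffled, key), base)
  # blanking an additional item of another category never changes sa1
  resp$q5 <- ""
  expect_equal(compute_sa_scores(resp, key)$sa1, base$sa1)
})

test_that("participants without environmental events get NA scores", {
  key <- sa_answer_key()
  resp <- all_correct_responses(ids = c("p1", "p2"))
  resp$env_events <- c(TRUE, FALSE)
  sc <- compute_sa_scores(resp, key)
  expect_equal(sc$environment, c(1, NA_real_))
  expect_equal(sc$global, c(1, NA_real_))
  expect_equal(sc$sa1, c(1, 1))
})

test_that("global numerator decomposes into environment plus level-1", {
  key <- sa_answer_key()
  set.seed(9)
  cfg <- sim_config(n_participants = 20, n_no_env_events = 0)
  dwell <- simulate_dwell(cfg, seed = 5)
  resp <- simulate_sa_responses(dwell, cfg, seed = 6)
  sc <- compute_sa_scores(resp, key)
  env_num <- round(sc$environment * sc$environment_n)
  sa1_num <- round(sc$sa1 * sc$sa1_n)
  glob_num <- round(sc$global * sc$global_n)
  expect_equal(glob_num, env_num + sa1_num)
  expect_equal(sc$global_n, sc$environment_n + sc$sa1_n)
})

test_that("responses CSV round-trips with flags intact", {
  resp <- all_correct_responses(ids = c("a", "b"))
  resp$q8_excluded <- c(TRUE, FALSE)
  resp$env_events <- c(TRUE, FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(resp, path, row.names = FALSE)
  back <- read_sa_responses(path)
  expect_identical(back$q8_excluded, c(TRUE, FALSE))
  expect_identical(back$env_events, c(TRUE, FALSE))
  expect_equal(
    compute_sa_scores(back)[c("global", "environment", "sa1")],
    compute_sa_scores(resp)[c("global", "environment", "sa1")]
  )
})
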