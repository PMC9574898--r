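test_that("lowest-ordinal assignment matches a sorting oracle and keeps zeros", {
  expect_identical(assign_lowest_ordinal(c(0.1, 0.5, 0.5, 2.0)), c(1L, 2L, 2L, 3L))
  expect_identical(assign_lowest_ordinal(c(3, 3, 3)), c(1L, 1L, 1L))
  expect_identical(assign_lowest_ordinal(c(0, 3.2)), c(0L, 1L))
  expect_error(assign_lowest_ordinal(c(-1, 2)), "nonnegative")
  expect_error(assign_lowest_ordinal(numeric(0)), "non-empty")

  # property: order-isomorphic to input, dense ranks, idempotent
  set.seed(42)
  for (i in 1:20) {
    x <- round(c(rexp(8), sample(0:1, 3, TRUE) * rexp(3)), 2)
    r <- assign_lowest_ordinal(x)
    expect_identical(order(x), order(r)) # order-isomorphic (stable ties)
    expect_identical(r == 0L, x == 0)
    pos <- sort(unique(r[r > 0]))
    if (length(pos) > 0) expect_identical(pos, seq_along(pos)) # dense from 1
    expect_identical(assign_lowest_ordinal(r), r) # idempotent
  }
})

test_that("value coefficients are task-weighted relevance sums", {
  tm <- function(R, P) {
    list(
      tasks = tibble::tibble(task = c("t1", "t2"), priority = P),
      relevance = tibble::tibble(group = "patient", task = c("t1", "t2"), relevance = R)
    )
  }
  expect_equal(compute_value(tm(c(1, 0), c(2, 1)))$V, 2)
  expect_equal(compute_value(tm(c(0, 0), c(2, 1)))$V, 0)
  expect_equal(compute_value(tm(c(2, 1), c(2, 1)))$V, 5)
  incomplete <- list(
    tasks = tibble::tibble(task = c("t1", "t2"), priority = c(1, 1)),
    relevance = tibble::tibble(group = "patient", task = "t1", relevance = 1)
  )
  expect_error(compute_value(incomplete), "patient, t2")
})

test_that("SEEV scores combine the four factors with their weights", {
  expect_equal(seev_score(EX = 2, V = 3, spec = model_spec()), 5)
  full <- model_spec("SEEV", s = 1, ef = 1, ex = 1, v = 1)
  expect_equal(seev_score(S = 1, EF = 2, EX = 2, V = 3, spec = full), 4)
  # increasing effort strictly decreases the score when ef > 0
  efs <- seev_score(S = 1, EF = c(0, 1, 2, 5), EX = 2, V = 3, spec = full)
  expect_true(all(diff(efs) < 0))
  # EV version equals full SEEV with s = ef = 0 on the same coefficients
  coeffs <- ev_coefficients()
  ev <- predict_pdt(coeffs, model_spec("EV"))
  seev0 <- predict_pdt(coeffs, model_spec("SEEV", s = 0, ef = 0))
  expect_equal(ev, seev0)
})

test_that("predicted PDT normalizes scores to 100 per phase", {
  uniform <- tibble::tibble(
    phase = 1L, group = seevfit::aoi_groups(included = TRUE),
    S = 0, EF = 0, EX = 1, V = 1
  )
  expect_equal(predict_pdt(uniform)$pdt_pred, rep(25, 4))

  two <- tibble::tibble(
    phase = 1L, group = c("patient", "monitoring_equipment"),
    S = 0, EF = 0, EX = c(2, 1), V = c(3, 1)
  )
  expect_equal(predict_pdt(two)$pdt_pred, 100 * c(5, 2) / 7)

  pred <- predict_pdt(ev_coefficients())
  sums <- tapply(pred$pdt_pred, pred$phase, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(pred$pdt_pred >= 0))

  # scale invariance: scaling a phase's raw scores leaves predictions unchanged
  scaled <- ev_coefficients()
  scaled$EX <- scaled$EX * 3
  scaled$V <- scaled$V * 3
  expect_equal(predict_pdt(scaled)$pdt_pred, pred$pdt_pred)
})

test_that("degenerate coefficient tables are refused", {
  zero <- tibble::tibble(
    phase = 1L, group = seevfit::aoi_groups(included = TRUE),
    S = 0, EF = 0, EX = 0, V = 0
  )
  expect_error(predict_pdt(zero), "zero")
  heavy_effort <- tibble::tibble(
    phase = 1L, group = seevfit::aoi_groups(included = TRUE),
    S = 0, EF = 5, EX = 1, V = 1
  )
  expect_error(
    predict_pdt(heavy_effort, model_spec("SEEV", s = 1, ef = 1)),
    "rescale"
  )
})

test_that("model fit is a Pearson correlation over included cells only", {
  pred <- predict_pdt(ev_coefficients())
  # positive affine transform of the predictions fits perfectly
  obs <- pred
  names(obs)[names(obs) == "pdt_pred"] <- "pdt"
  obs$pdt <- 0.9 * obs$pdt + 2
  fit <- model_fit(obs, pred)
  expect_equal(fit$r, 1)
  expect_equal(fit$n_cells, 20L)

  # textbook-formula oracle on a hand-built 4-cell case
  o <- c(50, 30, 15, 5)
  p <- c(40, 40, 15, 5)
  obs4 <- tibble::tibble(phase = 5L, group = seevfit::aoi_groups(TRUE), pdt = o)
  pred4 <- tibble::tibble(phase = 5L, group = seevfit::aoi_groups(TRUE), pdt_pred = p)
  r_oracle <- sum((o - mean(o)) * (p - mean(p))) /
    sqrt(sum((o - mean(o))^2) * sum((p - mean(p))^2))
  expect_equal(model_fit(obs4, pred4)$r, r_oracle, tolerance = 1e-12)

  # excluded-group rows in the observed table are ignored, not renormalized
  obs_with_excluded <- dplyr::bind_rows(
    obs4,
    tibble::tibble(phase = 5L, group = "excluded", pdt = 10)
  )
  expect_equal(model_fit(obs_with_excluded, pred4)$r, r_oracle)
})

test_that("model fit refuses degenerate inputs", {
  pred4 <- tibble::tibble(
    phase = 5L, group = seevfit::aoi_groups(TRUE), pdt_pred = c(40, 40, 15, 5)
  )
  flat <- tibble::tibble(phase = 5L, group = seevfit::aoi_groups(TRUE), pdt = 25)
  expect_error(model_fit(flat, pred4), "zero variance")
  short <- tibble::tibble(phase = 5L, group = c("patient", "documentation"), pdt = c(60, 40))
  expect_error(model_fit(short, pred4), "at least 3")
  unmatched <- tibble::tibble(
    phase = 2L, group = seevfit::aoi_groups(TRUE), pdt = c(50, 30, 15, 5)
  )
  expect_error(model_fit(unmatched, pred4), "without a matching")
})

test_that("coefficient YAML round-trips and converts raw bandwidth", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(
    "phases:
  - phase: 1
    groups:
      patient: {EX_raw: 0.4, V: 2}
      monitoring_equipment: {EX_raw: 0.1, V: 1}
      documentation: {EX_raw: 0.4, V: 3}
      medication_general_equipment: {EX_raw: 0, V: 1}",
    path
  )
  tab <- read_ev_coefficients(path)
  expect_identical(tab$EX, c(2L, 1L, 2L, 0L))
  expect_equal(tab$S, rep(0, 4))
})

test_that("cohort fits agree with the single-scope reference route", {
  cfg <- sim_config(n_participants = 7)
  dwell <- simulate_dwell(cfg, seed = 13)
  fast <- participant_fits(dwell, cfg$predicted)
  for (pid in unique(dwell$participant_id)) {
    for (lab in c("1-5", "5")) {
      ph <- if (lab == "5") 5 else 1:5
      ref <- model_fit(
        dwell[dwell$participant_id == pid & dwell$phase %in% ph, ],
        cfg$predicted,
        scope = pid
      )
      row <- fast[fast$participant_id == pid & fast$phases == lab, ]
      expect_equal(row$r, ref$r, tolerance = 1e-12)
      expect_equal(row$p, ref$p, tolerance = 1e-9)
      expect_equal(row$n_cells, ref$n_cells)
    }
  }
})
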