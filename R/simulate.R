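# Dirichlet draws via independent gammas; rows = draws, cols = components.
# Components with alpha = 0 are structural zeros.
rdirichlet_rows <- function(alpha_matrix) {
  n <- nrow(alpha_matrix)
  k <- ncol(alpha_matrix)
  g <- matrix(0, n, k)
  pos <- alpha_matrix > 0
  g[pos] <- rgamma(sum(pos), shape = alpha_matrix[pos])
  sweep(g, 1, rowSums(g), "/")
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles everything the generator needs: cohort size and split, the model
#' predictions (the fit target), the dwell-center profile, the fidelity
#' distribution, and the attention-awareness link. Defaults emulate the
#' study conditions this package is built around: 61 participants (30
#' junior, 31 senior), five phases, dwell centered on the packaged observed
#' cohort profile with about 9% of dwell outside the included groups,
#' participant fidelity drawn from a log-normal so that individual model
#' fits are heterogeneous, and level-1 answer correctness linked to
#' final-phase attention on the monitoring equipment.
#'
#' @param n_participants Cohort size (default 61).
#' @param n_junior Size of the junior subgroup (default 30).
#' @param predicted Predicted PDT tibble (`phase`, `group`, `pdt_pred`);
#'   default [predict_pdt()] of the packaged [ev_coefficients()].
#' @param center Dwell-center profile (`phase`, `group`, `mean_pdt`,
#'   including the excluded group). Default: the packaged observed cohort
#'   means, pooled n-weighted. Pass `NULL` to center on `predicted` with a
#'   constant excluded share of `excluded_share_mean`.
#' @param kappa_meanlog,kappa_sdlog Log-normal parameters of the
#'   per-participant Dirichlet concentration multiplier kappa (fidelity);
#'   defaults `log(2)` and `0.8`. `kappa_sdlog = 0` fixes kappa.
#' @param excluded_share_mean Mean excluded-dwell share used when `center`
#'   is `NULL` (default 0.09).
#' @param excluded_concentration Beta concentration of the per-phase
#'   excluded share around its center mean (default 100); `Inf` makes the
#'   share deterministic.
#' @param sa1_beta Logistic slope linking level-1 item correctness to the
#'   rank-normal score of final-phase monitoring-equipment PDT (default 3;
#'   0 severs the link).
#' @param sa1_difficulty Named per-item probabilities correct at average
#'   attention.
#' @param env_beta,env_difficulty Same for environment items, linked to the
#'   final-phase excluded-group share.
#' @param numeric_noise_sd Relative SD of reported numeric answers around
#'   the true value (truncated inside the scoring margin; default 0.04).
#' @param blank_prob Probability an item is left blank (default 0.01).
#' @param n_q8_excluded Participants flagged with the misleadingly worded
#'   environment question (default 19).
#' @param n_no_env_events Participants run without environmental events,
#'   whose environment and global scores are undefined (default 11).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 61,
                       n_junior = 30,
                       predicted = predict_pdt(ev_coefficients()),
                       center = pool_group_means(observed_pdt_table()),
                       kappa_meanlog = log(2),
                       kappa_sdlog = 0.8,
                       excluded_share_mean = 0.09,
                       excluded_concentration = 100,
                       sa1_beta = 3,
                       sa1_difficulty = c(
                         q7 = 0.80, q9_systolic = 0.45, q9_diastolic = 0.35,
                         q10 = 0.21, q11 = 0.85
                       ),
                       env_beta = 1.5,
                       env_difficulty = c(
                         q1 = 0.60, q2 = 0.50, q3 = 0.40, q4 = 0.30,
                         q5 = 0.80, q6 = 0.50, q8 = 0.60
                       ),
                       numeric_noise_sd = 0.04,
                       blank_prob = 0.01,
                       n_q8_excluded = 19,
                       n_no_env_events = 11) {
  if (kappa_sdlog < 0) abort("kappa_sdlog must be >= 0")
  if (!is.finite(exp(kappa_meanlog)) || exp(kappa_meanlog) <= 0) {
    abort("kappa must be positive")
  }
  if (excluded_share_mean < 0 || excluded_share_mean >= 1) {
    abort("excluded_share_mean must lie in [0, 1)")
  }
  if (is.null(center)) {
    inc <- predicted |>
      dplyr::mutate(mean_pdt = .data$pdt_pred * (1 - excluded_share_mean)) |>
      dplyr::select("phase", "group", "mean_pdt")
    exc <- tibble::tibble(
      phase = unique(predicted$phase), group = "excluded",
      mean_pdt = 100 * excluded_share_mean
    )
    center <- dplyr::bind_rows(inc, exc)
  }
  structure(
    list(
      n_participants = n_participants, n_junior = n_junior,
      predicted = predicted, center = center,
      kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog,
      excluded_share_mean = excluded_share_mean,
      excluded_concentration = excluded_concentration,
      sa1_beta = sa1_beta, sa1_difficulty = sa1_difficulty,
      env_beta = env_beta, env_difficulty = env_difficulty,
      numeric_noise_sd = numeric_noise_sd, blank_prob = blank_prob,
      n_q8_excluded = n_q8_excluded, n_no_env_events = n_no_env_events
    ),
    class = "sim_config"
  )
}

#' Simulate a cohort's dwell-time tables
#'
#' Per participant and phase, the included-group dwell composition is drawn
#' from a Dirichlet distribution concentrated around the configured center
#' profile with per-participant fidelity kappa (larger kappa, tighter around
#' the center, better individual model fit), then rescaled so the excluded
#' group takes a Beta-distributed share around its center mean. All five
#' group percentages sum to 100 per participant-phase; phases are drawn
#' independently within a participant.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; mandatory (every stochastic call is seeded).
#' @return A dwell table (`participant_id`, `phase`, `group`, `pdt`) with a
#'   `kappa` attribute recording the per-participant fidelity draws and a
#'   `seed` attribute.
#' @export
#' @examples
#' dw <- simulate_dwell(sim_config(n_participants = 4), seed = 1)
#' dplyr::count(dw, participant_id)
simulate_dwell <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) abort("simulate_dwell requires a seed")
  set.seed(seed)
  n <- config$n_participants
  ids <- sprintf("p%02d", seq_len(n))
  kappa <- if (config$kappa_sdlog == 0) {
    rep(exp(config$kappa_meanlog), n)
  } else {
    rlnorm(n, config$kappa_meanlog, config$kappa_sdlog)
  }
  center <- config$center
  phases <- sort(unique(center$phase))
  out <- purrr::map_dfr(phases, function(ph) {
    cen_ph <- center[center$phase == ph, ]
    exc_mean <- cen_ph$mean_pdt[cen_ph$group == "excluded"] / 100
    if (length(exc_mean) == 0) exc_mean <- config$excluded_share_mean
    inc <- cen_ph[match(INCLUDED_GROUPS, cen_ph$group), ]
    p_inc <- inc$mean_pdt / sum(inc$mean_pdt)
    alpha <- outer(kappa, p_inc)
    props <- rdirichlet_rows(alpha)
    e <- if (is.infinite(config$excluded_concentration) || exc_mean == 0) {
      rep(exc_mean, n)
    } else {
      rbeta(
        n, config$excluded_concentration * exc_mean,
        config$excluded_concentration * (1 - exc_mean)
      )
    }
    pdt <- cbind(100 * props * (1 - e), 100 * e)
    tibble::tibble(
      participant_id = rep(ids, times = 5),
      phase = as.integer(ph),
      group = rep(AOI_GROUPS, each = n),
      pdt = as.vector(pdt)
    )
  }) |>
    dplyr::arrange(.data$participant_id, .data$phase, match(.data$group, AOI_GROUPS))
  attr(out, "kappa") <- setNames(kappa, ids)
  attr(out, "seed") <- seed
  out
}

#' Realize a dwell table as fixation records
#'
#' Emits synthetic fixation records whose per-group durations reproduce the
#' dwell table exactly: each participant-phase becomes a sequence of
#' fixations (one per group with nonzero dwell, split in two to exercise
#' contiguous-merge invariance) on a representative AOI label of the group,
#' inside the phase window `[phase_length * (phase - 1), phase_length * phase)`.
#' Onset times are schematic, not behavioral.
#'
#' @param dwell A dwell table (`participant_id`, `phase`, `group`, `pdt`).
#' @param phase_length Seconds of fixation time per phase (default 60).
#' @return A fixation tibble accepted by [compute_pdt()].
#' @export
realize_fixations <- function(dwell, phase_length = 60) {
  rep_aoi <- c(
    patient = "patients_head",
    monitoring_equipment = "patient_monitor",
    documentation = "anesthesia_chart",
    medication_general_equipment = "anesthesia_trolley",
    excluded = "nurses_head"
  )
  dwell |>
    dplyr::filter(.data$pdt > 0) |>
    dplyr::group_by(.data$participant_id, .data$phase) |>
    dplyr::group_modify(function(d, key) {
      dur <- phase_length * d$pdt / sum(d$pdt)
      halves <- rep(dur / 2, each = 2)
      onset <- phase_length * (key$phase[[1]] - 1) + cumsum(c(0, halves[-length(halves)]))
      tibble::tibble(
        onset = onset,
        duration = halves,
        aoi = rep(unname(rep_aoi[d$group]), each = 2)
      )
    }) |>
    dplyr::ungroup()
}

#' Simulate questionnaire responses linked to attention
#'
#' Draws each closed item's correctness from a Bernoulli whose logit is the
#' item's difficulty plus a slope times the participant's standardized
#' (rank-normal) final-phase attention: level-1 items use the
#' monitoring-equipment share (the vital signs live there), environment
#' items use the excluded-group share (room events are seen when looking
#' around). Correct numeric answers are reported with truncated relative
#' noise inside the scoring margin; missed numeric items are answered with
#' a question mark; binary items flip to the wrong pole when missed. A
#' small blank rate and the study-structure flags (`q8_excluded`,
#' `env_events`) are applied, and a synthetic expert `overall_sa` label is
#' attached (an input to downstream comparisons, never computed from the
#' scores).
#'
#' @param dwell A dwell table containing phase 5.
#' @param config A [sim_config()].
#' @param seed Integer seed; mandatory.
#' @return A wide response tibble accepted by [compute_sa_scores()].
#' @export
simulate_sa_responses <- function(dwell, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) abort("simulate_sa_responses requires a seed")
  d5 <- dwell[dwell$phase == 5, ]
  if (nrow(d5) == 0) abort("dwell must contain phase 5")
  set.seed(seed)
  wide <- d5 |>
    dplyr::select("participant_id", "group", "pdt") |>
    tidyr::pivot_wider(names_from = "group", values_from = "pdt")
  for (g in c("monitoring_equipment", "excluded")) {
    if (!g %in% names(wide)) {
      abort(paste0("dwell lacks the relevant group '", g, "' at phase 5"))
    }
  }
  n <- nrow(wide)
  rank_normal <- function(x) qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
  z_sa1 <- rank_normal(wide$monitoring_equipment)
  z_env <- rank_normal(wide$excluded)

  draw_correct <- function(difficulty, beta, z) {
    rbinom(n, 1, plogis(qlogis(difficulty) + beta * z)) == 1
  }
  noisy_value <- function(true, margin = 0.10) {
    eps <- rnorm(n, 0, config$numeric_noise_sd)
    lim <- margin * 0.95
    round(true * (1 + pmin(pmax(eps, -lim), lim)))
  }
  yes_no <- function(correct, key_yes) {
    pole <- ifelse(correct == key_yes, "yes", "no")
    emph <- sample(c("sure ", ""), n, replace = TRUE)
    paste0(emph, pole)
  }

  resp <- tibble::tibble(participant_id = wide$participant_id)
  env_keys <- c(q1 = TRUE, q2 = FALSE, q3 = FALSE, q5 = TRUE, q6 = FALSE, q8 = TRUE)
  for (q in names(config$env_difficulty)) {
    ok <- draw_correct(config$env_difficulty[[q]], config$env_beta, z_env)
    resp[[q]] <- if (q == "q4") {
      ifelse(ok, "shift change", "?")
    } else {
      yes_no(ok, env_keys[[q]])
    }
  }
  sa1_ok <- lapply(config$sa1_difficulty, function(dif) {
    draw_correct(dif, config$sa1_beta, z_sa1)
  })
  resp$q7 <- yes_no(sa1_ok$q7, TRUE)
  resp$q9_systolic <- ifelse(sa1_ok$q9_systolic, as.character(noisy_value(116)), "?")
  resp$q9_diastolic <- ifelse(sa1_ok$q9_diastolic, as.character(noisy_value(46)), "?")
  resp$q10 <- ifelse(sa1_ok$q10, as.character(noisy_value(51)), "?")
  resp$q11 <- ifelse(sa1_ok$q11, as.character(sample(97:100, n, replace = TRUE)), "?")
  resp$q12 <- "patient stable, anesthetized"
  resp$q13 <- "expect continued stability"

  item_cols <- setdiff(names(resp), c("participant_id", "q12", "q13"))
  for (col in item_cols) {
    blank <- stats::runif(n) < config$blank_prob
    resp[[col]][blank] <- ""
  }

  resp$q8_excluded <- seq_len(n) %in% sample.int(n, min(config$n_q8_excluded, n))
  resp$env_events <- !(seq_len(n) %in% sample.int(n, min(config$n_no_env_events, n)))
  resp$overall_sa <- rbinom(n, 1, plogis(qlogis(0.26) + 0.5 * z_sa1))
  attr(resp, "seed") <- seed
  resp
}

#' Full-pipeline recovery experiment
#'
#' Repeats the whole analysis chain — simulate dwell, fit the model per
#' participant, simulate and score the questionnaire, associate final-phase
#' model fit with the level-1 score — and summarizes the distribution of
#' the recovered Spearman association and its rejection rate at `alpha`.
#' With the attention link severed (`sa1_beta = 0`) the rejection rate
#' estimates the type-I error of the association test.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicate cohorts (>= 1).
#' @param seed Integer root seed; replicate r uses `seed + r` offsets drawn
#'   from one root stream.
#' @param alpha Significance level for the rejection-rate summary.
#' @return A tibble with one row per replicate (`replicate`, `rs`, `p`,
#'   `mean_fit_all`, `mean_fit5`), with attributes `median_rs` and
#'   `rejection_rate`.
#' @export
run_recovery_experiment <- function(config, replicates, seed, alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  if (missing(seed) || is.null(seed)) abort("run_recovery_experiment requires a seed")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * replicates)
  predicted <- config$predicted
  res <- purrr::map_dfr(seq_len(replicates), function(r) {
    dwell <- simulate_dwell(config, seed = rep_seeds[2 * r - 1])
    fits <- participant_fits(dwell, predicted)
    resp <- simulate_sa_responses(dwell, config, seed = rep_seeds[2 * r])
    scores <- compute_sa_scores(resp)
    fit5 <- fits[fits$phases == "5", ]
    merged <- dplyr::inner_join(fit5, scores, by = "participant_id")
    assoc <- spearman_assoc(merged$r, merged$sa1, label = "fit_5 ~ sa1")
    tibble::tibble(
      replicate = r, rs = assoc$rs, p = assoc$p,
      mean_fit_all = mean(fits$r[fits$phases == "1-5"]),
      mean_fit5 = mean(fit5$r)
    )
  })
  attr(res, "median_rs") <- stats::median(res$rs)
  attr(res, "rejection_rate") <- mean(res$p < alpha)
  attr(res, "alpha") <- alpha
  res
}
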