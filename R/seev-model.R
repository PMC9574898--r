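#' Lowest-ordinal rank assignment
#'
#' Replaces raw nonnegative factor magnitudes (e.g. expert bandwidth or
#' importance ratings) with the smallest integer ranks that preserve their
#' order: the smallest nonzero value maps to 1, ties share a rank,
#' consecutive distinct values differ by exactly 1, and exact zeros stay 0.
#' The transform is idempotent on its own output.
#'
#' @param raw_scores Numeric vector of nonnegative values.
#' @return Integer vector of the same length.
#' @export
#' @examples
#' assign_lowest_ordinal(c(0.1, 0.5, 0.5, 2.0))
#' assign_lowest_ordinal(c(0, 3.2))
assign_lowest_ordinal <- function(raw_scores) {
  if (length(raw_scores) == 0) abort("raw_scores must be non-empty")
  if (any(is.na(raw_scores))) abort("raw_scores must not contain NA")
  if (any(raw_scores < 0)) abort("raw_scores must be nonnegative")
  out <- integer(length(raw_scores))
  pos <- raw_scores > 0
  if (any(pos)) {
    lev <- sort(unique(raw_scores[pos]))
    out[pos] <- match(raw_scores[pos], lev)
  }
  out
}

#' Define SEEV model weights
#'
#' The SEEV attention score of an area of interest combines salience (S),
#' effort (EF), expectancy (EX) and value (V) as
#' `s*S - ef*EF + ex*EX + v*V`. The EV reduction sets the bottom-up weights
#' `s` and `ef` to zero, leaving only the top-down factors that should drive
#' an expert's scanning; it is treated as the "optimal" allocation standard.
#'
#' @param version `"EV"` (default) or `"SEEV"`.
#' @param s,ef,ex,v Nonnegative weights. For `"EV"`, `s` and `ef` are forced
#'   to zero.
#' @param combine How expectancy and value are combined: `"additive"`
#'   (default, `ex*EX + v*V`) or `"multiplicative"` (`EX^ex * V^v`, only
#'   meaningful for the EV version).
#' @return A list of class `model_spec`.
#' @export
#' @examples
#' model_spec()
#' model_spec("SEEV", s = 1, ef = 1)
model_spec <- function(version = c("EV", "SEEV"), s = 0, ef = 0, ex = 1, v = 1,
                       combine = c("additive", "multiplicative")) {
  version <- match.arg(version)
  combine <- match.arg(combine)
  if (any(c(s, ef, ex, v) < 0)) abort("Model weights must be nonnegative")
  if (version == "EV" && (s != 0 || ef != 0)) {
    abort("The EV version requires s = ef = 0")
  }
  if (combine == "multiplicative" && version != "EV") {
    abort("The multiplicative combination is defined for the EV version only")
  }
  structure(
    list(version = version, s = s, ef = ef, ex = ex, v = v, combine = combine),
    class = "model_spec"
  )
}

#' Value coefficients from a task model
#'
#' Computes the value V of each AOI group as the task-weighted sum of its
#' relevances: `V_g = sum_t R(g, t) * P_t`, where `P_t` is the priority of
#' task `t` (e.g. inducing anesthesia; maintaining hemodynamic stability and
#' ventilation) and `R(g, t)` the relevance of group `g` to that task.
#'
#' @param task_model A list with elements `tasks` (data frame `task`,
#'   `priority`) and `relevance` (data frame `group`, `task`, `relevance`,
#'   optionally `phase`).
#' @return A tibble (`group`, `V`), plus a `phase` column when the relevance
#'   table carries one.
#' @export
#' @examples
#' tm <- list(
#'   tasks = tibble::tibble(task = c("induce", "maintain"), priority = c(2, 1)),
#'   relevance = tibble::tibble(
#'     group = "patient", task = c("induce", "maintain"), relevance = c(2, 1)
#'   )
#' )
#' compute_value(tm) # 2*2 + 1*1 = 5
compute_value <- function(task_model) {
  stopifnot(is.list(task_model), !is.null(task_model$tasks), !is.null(task_model$relevance))
  tasks <- task_model$tasks
  rel <- task_model$relevance
  if (any(tasks$priority < 0) || any(rel$relevance < 0)) {
    abort("Task priorities and relevances must be nonnegative")
  }
  keys <- if ("phase" %in% names(rel)) c("phase", "group") else "group"
  combos <- rel |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys))) |>
    tidyr::crossing(task = tasks$task)
  have <- dplyr::semi_join(combos, rel, by = c(keys, "task"))
  if (nrow(have) < nrow(combos)) {
    miss <- dplyr::anti_join(combos, rel, by = c(keys, "task"))
    abort(paste0(
      "Missing relevance entr", if (nrow(miss) > 1) "ies" else "y", " for: ",
      paste(paste0("(", miss$group, ", ", miss$task, ")"), collapse = ", ")
    ))
  }
  rel |>
    dplyr::inner_join(tasks, by = "task") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(V = sum(.data$relevance * .data$priority), .groups = "drop")
}

#' Raw SEEV attention score of a coefficient cell
#'
#' @param S,EF,EX,V Nonnegative coefficient scores (vectors recycle).
#' @param spec A [model_spec()].
#' @return Numeric attention score(s). May be negative under the full SEEV
#'   combination (effort is subtractive); [predict_pdt()] refuses to
#'   normalize negative scores.
#' @export
#' @examples
#' seev_score(EX = 2, V = 3, spec = model_spec()) # EV: 2 + 3
seev_score <- function(S = 0, EF = 0, EX = 0, V = 0, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(c(S, EF, EX, V) < 0)) abort("Coefficient scores must be nonnegative")
  if (spec$combine == "multiplicative") {
    EX^spec$ex * V^spec$v
  } else {
    spec$s * S - spec$ef * EF + spec$ex * EX + spec$v * V
  }
}

#' Read an expectancy-value coefficient table from YAML
#'
#' The YAML holds one block per phase with per-group coefficient entries
#' (`S`, `EF`, `EX` or `EX_raw`, `V`); missing `S`/`EF` default to 0. When
#' raw bandwidth values `EX_raw` are given instead of `EX`, they are
#' converted per phase with [assign_lowest_ordinal()].
#'
#' @param path YAML file path.
#' @return A tibble (`phase`, `group`, `S`, `EF`, `EX`, `V`).
#' @export
read_ev_coefficients <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$phases)) abort("Coefficient YAML must have a top-level 'phases' key")
  tab <- purrr::map_dfr(doc$phases, function(ph) {
    g <- ph$groups
    rows <- purrr::imap_dfr(g, function(cf, group) {
      tibble::tibble(
        phase = as.integer(ph$phase),
        group = group,
        S = cf[["S"]] %||% 0,
        EF = cf[["EF"]] %||% 0,
        EX = cf[["EX"]] %||% NA_real_,
        EX_raw = cf[["EX_raw"]] %||% NA_real_,
        V = cf[["V"]] %||% NA_real_
      )
    })
    if (all(is.na(rows$EX)) && !all(is.na(rows$EX_raw))) {
      rows$EX <- assign_lowest_ordinal(rows$EX_raw)
    }
    rows
  })
  if (anyNA(tab$EX) || anyNA(tab$V)) {
    abort("Every (phase, group) entry needs EX (or EX_raw) and V")
  }
  bad <- setdiff(unique(tab$group), AOI_GROUPS)
  if (length(bad) > 0) abort(paste0("Unknown group(s) in coefficients: ", paste(bad, collapse = ", ")))
  dplyr::select(tab, "phase", "group", "S", "EF", "EX", "V")
}

#' Packaged reconstructed EV parametrization
#'
#' Loads the packaged expectancy-value coefficient table for the five
#' induction phases. This is a synthetic, documented reconstruction from the
#' phase task structure (lowest-ordinal integer ranks), not the original
#' study's expert parametrization, which is not publicly available; treat
#' absolute predictions from it as non-authoritative.
#'
#' @return A tibble (`phase`, `group`, `S`, `EF`, `EX`, `V`).
#' @export
ev_coefficients <- function() {
  read_ev_coefficients(
    system.file("extdata", "ev_coefficients.yaml", package = "seevfit", mustWork = TRUE)
  )
}

#' Predicted percentage dwell time from model coefficients
#'
#' Scores every included AOI group with [seev_score()] and normalizes within
#' each phase, so the four included-group predictions sum to 100 per phase.
#' The excluded group receives no prediction. Predictions are invariant to
#' scaling all of a phase's raw scores by a positive constant.
#'
#' @param coeffs Coefficient tibble (`phase`, `group`, `S`, `EF`, `EX`,
#'   `V`), e.g. [ev_coefficients()].
#' @param spec A [model_spec()].
#' @return A tibble (`phase`, `group`, `pdt_pred`).
#' @export
#' @examples
#' predict_pdt(ev_coefficients()) |> dplyr::filter(phase == 5)
predict_pdt <- function(coeffs, spec = model_spec()) {
  stopifnot(is.data.frame(coeffs), inherits(spec, "model_spec"))
  inc <- coeffs |> dplyr::filter(.data$group %in% INCLUDED_GROUPS)
  inc$score <- seev_score(inc$S, inc$EF, inc$EX, inc$V, spec = spec)
  if (any(inc$score < 0)) {
    abort(paste0(
      "Negative attention score(s) under the full SEEV combination; ",
      "rescale the effort coefficients or weights before predicting"
    ))
  }
  inc |>
    dplyr::group_by(.data$phase) |>
    dplyr::group_modify(function(d, key) {
      if (sum(d$score) == 0) {
        abort(paste0("All attention scores are zero in phase ", key$phase[[1]]))
      }
      tibble::tibble(group = d$group, pdt_pred = 100 * d$score / sum(d$score))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$phase, match(.data$group, AOI_GROUPS))
}

#' Observed-versus-predicted model fit
#'
#' Pearson correlation between observed percentage dwell times and the
#' model's predicted PDT over matching (phase, included-group) cells.
#' Observed values are taken as-is (never renormalized after dropping the
#' excluded share), so a participant attending heavily outside the included
#' groups fits worse. The two-sided p-value comes from the usual t
#' transform of r.
#'
#' @param observed A dwell table (`participant_id` optional, `phase`,
#'   `group`, and `pdt` or `mean_pdt`) for a single scope (one participant,
#'   or pooled group means).
#' @param predicted Output of [predict_pdt()].
#' @param phases Phases to include (default: all present in `observed`).
#' @param scope Label for the fitted scope, e.g. `"group-level"` or a
#'   participant id.
#' @return A one-row tibble (`scope`, `phases`, `n_cells`, `r`, `p`).
#' @export
#' @examples
#' pooled <- pool_group_means(observed_pdt_table())
#' model_fit(pooled, predict_pdt(ev_coefficients()))
model_fit <- function(observed, predicted, phases = NULL, scope = "group-level") {
  stopifnot(is.data.frame(observed), is.data.frame(predicted))
  val_col <- if ("pdt" %in% names(observed)) "pdt" else "mean_pdt"
  if (!val_col %in% names(observed)) abort("observed needs a 'pdt' or 'mean_pdt' column")
  if ("participant_id" %in% names(observed) &&
    dplyr::n_distinct(observed$participant_id) > 1) {
    abort("model_fit expects a single scope; use participant_fits() for a cohort")
  }
  obs <- observed |>
    dplyr::filter(.data$group %in% INCLUDED_GROUPS) |>
    dplyr::select("phase", "group", obs_pdt = dplyr::all_of(val_col))
  if (!is.null(phases)) obs <- dplyr::filter(obs, .data$phase %in% !!phases)
  paired <- dplyr::left_join(obs, predicted, by = c("phase", "group"))
  if (anyNA(paired$pdt_pred)) {
    abort("Observed cells without a matching model prediction")
  }
  if (nrow(paired) < 3) abort("Model fit needs at least 3 matching cells")
  if (stats::sd(paired$obs_pdt) == 0 || stats::sd(paired$pdt_pred) == 0) {
    abort("Model fit undefined: zero variance in observed or predicted cells")
  }
  ct <- cor.test(paired$obs_pdt, paired$pdt_pred, method = "pearson")
  tibble::tibble(
    scope = scope,
    phases = paste(sort(unique(paired$phase)), collapse = ","),
    n_cells = nrow(paired),
    r = unname(ct$estimate),
    p = ct$p.value
  )
}

#' Per-participant model fits
#'
#' Applies [model_fit()] to every participant of a dwell table, for the full
#' phase range and optionally a phase subset (conventionally the final,
#' event-laden phase on its own).
#'
#' @param dwell A participant-level dwell table from [compute_pdt()] or
#'   [simulate_dwell()].
#' @param predicted Output of [predict_pdt()].
#' @param phase_sets Named list of phase vectors; each entry yields one fit
#'   column set. Default: all phases (`"1-5"`) and phase 5 alone (`"5"`).
#' @return A tibble with one row per participant and phase set
#'   (`participant_id`, `phases`, `n_cells`, `r`, `p`).
#' @export
participant_fits <- function(dwell, predicted,
                             phase_sets = list("1-5" = 1:5, "5" = 5)) {
  stopifnot("participant_id" %in% names(dwell))
  inc <- dwell |>
    dplyr::filter(.data$group %in% INCLUDED_GROUPS) |>
    dplyr::inner_join(predicted, by = c("phase", "group"))
  if (nrow(inc) < nrow(dwell[dwell$group %in% INCLUDED_GROUPS, ])) {
    abort("Observed cells without a matching model prediction")
  }
  purrr::imap_dfr(phase_sets, function(ph, label) {
    sub <- inc[inc$phase %in% ph, ]
    sub <- sub[order(sub$participant_id, sub$phase, match(sub$group, AOI_GROUPS)), ]
    ids <- unique(sub$participant_id)
    k <- nrow(sub) / length(ids)
    if (k < 3) abort("Model fit needs at least 3 matching cells")
    obs <- matrix(sub$pdt, ncol = k, byrow = TRUE)
    pred_v <- sub$pdt_pred[seq_len(k)]
    # rowwise Pearson r against the prediction vector, then the t transform
    xc <- obs - rowMeans(obs)
    pc <- pred_v - mean(pred_v)
    r <- as.vector(xc %*% pc) / (sqrt(rowSums(xc^2)) * sqrt(sum(pc^2)))
    tstat <- r * sqrt((k - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = k - 2)
    tibble::tibble(
      participant_id = ids, phases = label,
      n_cells = as.integer(k), r = r, p = p
    )
  })
}
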