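#' Read fixation records from CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `participant_id`,
#' `phase`, `onset_s`, `duration_s`, `aoi`. Times are seconds from scenario
#' start; durations must be strictly positive.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `participant_id`, `phase`, `onset`,
#'   `duration`, `aoi`.
#' @export
read_fixations <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  req <- c("participant_id", "phase", "onset_s", "duration_s", "aoi")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Fixation CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    participant_id = as.character(df$participant_id),
    phase = as.integer(df$phase),
    onset = as.numeric(df$onset_s),
    duration = as.numeric(df$duration_s),
    aoi = as.character(df$aoi)
  )
  validate_fixations(out)
  out
}

validate_fixations <- function(fix, need_phase = TRUE) {
  stopifnot(is.data.frame(fix))
  req <- c("participant_id", "onset", "duration", "aoi")
  if (need_phase) req <- c(req, "phase")
  missing_cols <- setdiff(req, names(fix))
  if (length(missing_cols) > 0) {
    abort(paste0("Fixation table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(fix$duration <= 0)) abort("All fixation durations must be > 0")
  if (any(fix$onset < 0)) abort("Fixation onsets must be >= 0")
  if (need_phase && !all(fix$phase %in% PHASES)) abort("Fixation phases must be in 1-5")
  invisible(fix)
}

# Split fixations at half-open phase windows [start, end) and (re)assign the
# phase of each piece. `boundaries` is either a numeric vector of length
# n_phases + 1 shared by all participants, or a data frame with columns
# participant_id, phase, start, end.
split_fixations_at_boundaries <- function(fix, boundaries) {
  validate_fixations(fix, need_phase = FALSE)
  if (is.numeric(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE)) {
      abort("Numeric phase boundaries must be strictly increasing")
    }
    nph <- length(boundaries) - 1L
    windows <- tibble::tibble(
      phase = seq_len(nph),
      start = boundaries[-length(boundaries)],
      end = boundaries[-1]
    )
    win_of <- function(pid) windows
  } else {
    stopifnot(all(c("participant_id", "phase", "start", "end") %in% names(boundaries)))
    win_of <- function(pid) boundaries[boundaries$participant_id == pid, ]
  }
  fix |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      w <- win_of(key$participant_id[[1]])
      purrr::map_dfr(seq_len(nrow(w)), function(j) {
        s <- pmax(d$onset, w$start[j])
        e <- pmin(d$onset + d$duration, w$end[j])
        keep <- e > s
        tibble::tibble(
          phase = as.integer(w$phase[j]),
          onset = s[keep],
          duration = (e - s)[keep],
          aoi = d$aoi[keep]
        )
      })
    }) |>
    dplyr::ungroup()
}

#' Compute percentage dwell time per participant, phase and AOI group
#'
#' Sums fixation durations within each (participant, phase, group) cell and
#' expresses them as a percentage of that participant-phase's total fixation
#' time, over the five groups of [aoi_groups()] (zeros are kept, so the five
#' percentages sum to 100). Time is 0-based seconds and phase windows are
#' half-open `[start, end)`; a fixation straddling a boundary is split at it,
#' preserving total dwell.
#'
#' @param fixations A tibble of fixation records (`participant_id`, `phase`,
#'   `onset`, `duration`, `aoi`), e.g. from [read_fixations()].
#' @param map An [aoi_group_map()]; defaults to [default_aoi_group_map()].
#' @param phase_boundaries Optional. Either a strictly increasing numeric
#'   vector of length `n_phases + 1` (shared by all participants) or a data
#'   frame `participant_id`, `phase`, `start`, `end`. When supplied, fixation
#'   phase is (re)derived from onset times and straddling fixations are
#'   split; when `NULL`, the `phase` column is used as-is.
#' @param unknown Unknown-AOI policy passed to [map_fixation_to_group()].
#' @return A tibble (`participant_id`, `phase`, `group`, `pdt`) with `pdt`
#'   in percent. Participant-phases with no fixation time are absent, never
#'   zero-filled.
#' @export
#' @examples
#' fix <- tibble::tibble(
#'   participant_id = "p1", phase = 5L, onset = c(0, 3),
#'   duration = c(3, 1), aoi = c("patients_head", "patient_monitor")
#' )
#' compute_pdt(fix)
compute_pdt <- function(fixations, map = default_aoi_group_map(),
                        phase_boundaries = NULL,
                        unknown = c("error", "excluded")) {
  unknown <- match.arg(unknown)
  if (!is.null(phase_boundaries)) {
    participants <- unique(fixations$participant_id)
    fixations <- split_fixations_at_boundaries(fixations, phase_boundaries)
    if (is.numeric(phase_boundaries)) {
      expected <- tidyr::crossing(
        participant_id = participants,
        phase = seq_len(length(phase_boundaries) - 1L)
      )
      empty <- dplyr::anti_join(expected, fixations, by = c("participant_id", "phase"))
      if (nrow(empty) > 0) {
        warn(paste0(
          "No fixation time in ", nrow(empty),
          " participant-phase window(s); those cells are absent, not zero"
        ))
      }
    }
  }
  validate_fixations(fixations)
  if (nrow(fixations) == 0) {
    warn("No fixation time in any phase; returning an empty dwell table")
    return(tibble::tibble(
      participant_id = character(), phase = integer(),
      group = character(), pdt = numeric()
    ))
  }
  fixations$group <- map_fixation_to_group(
    fixations$aoi, fixations$phase, map, unknown = unknown
  )
  fixations |>
    dplyr::group_by(.data$participant_id, .data$phase, .data$group) |>
    dplyr::summarise(dur = sum(.data$duration), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("participant_id"), !!rlang::sym("phase")),
      group = AOI_GROUPS,
      fill = list(dur = 0)
    ) |>
    dplyr::group_by(.data$participant_id, .data$phase) |>
    dplyr::mutate(pdt = 100 * .data$dur / sum(.data$dur)) |>
    dplyr::ungroup() |>
    dplyr::select(!"dur") |>
    dplyr::arrange(
      .data$participant_id, .data$phase,
      match(.data$group, AOI_GROUPS)
    )
}

#' Pool dwell tables or subgroup means to group-level mean PDT
#'
#' Two pooling modes, chosen from the input's columns:
#' * a participant-level dwell table (`participant_id`, `phase`, `group`,
#'   `pdt`) is averaged over participants per (phase, group);
#' * a subgroup-mean table (`phase`, `group`, `mean_pdt`, `n`, e.g. the
#'   packaged published means from [observed_pdt_table()]) is pooled across
#'   subgroups, by default weighting each subgroup mean by its `n`.
#'
#' @param x A dwell table or subgroup-mean table (see above).
#' @param weights `"n"` (default) for n-weighted pooling of subgroup means,
#'   `"equal"` for the unweighted mean. Ignored for participant-level input
#'   (each participant counts once).
#' @return A tibble (`phase`, `group`, `mean_pdt`, `n`) with attributes
#'   `pooling` (`"participants"`, `"weighted"` or `"unweighted"`) and
#'   `subgroup_n` recording provenance.
#' @export
#' @examples
#' tab <- observed_pdt_table()
#' pool_group_means(tab) |> dplyr::filter(phase == 5)
pool_group_means <- function(x, weights = c("n", "equal")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) abort("Cannot pool an empty table")
  if ("participant_id" %in% names(x)) {
    out <- x |>
      dplyr::group_by(.data$phase, .data$group) |>
      dplyr::summarise(
        mean_pdt = mean(.data$pdt),
        n = dplyr::n_distinct(.data$participant_id),
        .groups = "drop"
      )
    attr(out, "pooling") <- "participants"
    attr(out, "subgroup_n") <- c(all = dplyr::n_distinct(x$participant_id))
  } else {
    stopifnot(all(c("phase", "group", "mean_pdt", "n") %in% names(x)))
    out <- x |>
      dplyr::group_by(.data$phase, .data$group) |>
      dplyr::summarise(
        mean_pdt = if (weights == "n") {
          sum(.data$mean_pdt * .data$n) / sum(.data$n)
        } else {
          mean(.data$mean_pdt)
        },
        n = sum(.data$n),
        .groups = "drop"
      )
    attr(out, "pooling") <- if (weights == "n") "weighted" else "unweighted"
    if ("subgroup" %in% names(x)) {
      sn <- x |> dplyr::distinct(.data$subgroup, .data$n)
      attr(out, "subgroup_n") <- setNames(sn$n, sn$subgroup)
    }
  }
  dplyr::arrange(out, .data$phase, match(.data$group, AOI_GROUPS))
}

#' Published group-level observed PDT means
#'
#' Loads the packaged table of observed percentage-dwell-time means and
#' standard deviations per phase, AOI group and experience subgroup
#' (junior n = 30, senior n = 31) for the five-phase induction scenario.
#'
#' @return A tibble (`phase`, `group`, `subgroup`, `n`, `mean_pdt`,
#'   `sd_pdt`).
#' @export
observed_pdt_table <- function() {
  path <- system.file("extdata", "observed_pdt_means.csv",
    package = "seevfit", mustWork = TRUE
  )
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Share of dwell time inside the model analysis
#'
#' The percentage of total dwell time falling on the four included AOI
#' groups, i.e. 100 minus the mean excluded-group PDT across phases.
#'
#' @param group_means A pooled mean table from [pool_group_means()].
#' @return A single percentage.
#' @export
included_dwell_share <- function(group_means) {
  excl <- group_means |> dplyr::filter(.data$group == "excluded")
  if (nrow(excl) == 0) abort("No excluded-group rows in the pooled table")
  100 - mean(excl$mean_pdt)
}

#' Export a pooled mean table as a wide CSV
#'
#' Writes one row per AOI group and one column per phase, mirroring the
#' usual report layout of observed-PDT tables.
#'
#' @param group_means Output of [pool_group_means()].
#' @param path Output CSV path.
#' @return The reshaped tibble, invisibly.
#' @export
export_group_means <- function(group_means, path) {
  wide <- group_means |>
    dplyr::select("phase", "group", "mean_pdt") |>
    tidyr::pivot_wider(
      names_from = "phase", names_prefix = "phase_",
      values_from = "mean_pdt"
    )
  write.csv(wide, path, row.names = FALSE)
  invisible(wide)
}
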