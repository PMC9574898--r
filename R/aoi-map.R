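#' Build an AOI-to-group mapping
#'
#' An AOI group map assigns every single-AOI label, possibly conditional on
#' the scenario phase, to exactly one of the five fixed groups returned by
#' [aoi_groups()]. Phase-conditional rules cover AOIs whose meaning changes
#' over the procedure (e.g. the face mask belongs with medication and general
#' equipment while it sits on the trolley, but with the patient once it is on
#' the patient's face).
#'
#' @param rules A data frame with columns `aoi` (label), `group` (one of
#'   [aoi_groups()]) and optionally `phases` (a list-column of integer
#'   vectors; `NULL`/missing means all phases).
#' @return A tibble of class `aoi_group_map` with columns `aoi`, `phase`,
#'   `group`, one row per (label, phase) pair.
#' @export
aoi_group_map <- function(rules) {
  stopifnot(is.data.frame(rules), all(c("aoi", "group") %in% names(rules)))
  bad <- setdiff(unique(rules$group), AOI_GROUPS)
  if (length(bad) > 0) {
    abort(paste0("Unknown AOI group(s): ", paste(bad, collapse = ", ")))
  }
  if (!"phases" %in% names(rules)) {
    rules$phases <- vector("list", nrow(rules))
  }
  expanded <- purrr::map_dfr(seq_len(nrow(rules)), function(i) {
    ph <- rules$phases[[i]] %||% PHASES
    ph <- as.integer(ph)
    if (!all(ph %in% PHASES)) {
      abort(paste0("Rule for '", rules$aoi[i], "' names phases outside 1-5"))
    }
    tibble::tibble(aoi = rules$aoi[i], phase = ph, group = rules$group[i])
  })
  dup <- expanded |>
    dplyr::count(.data$aoi, .data$phase) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "AOI label(s) mapped to more than one group for the same phase: ",
      paste(unique(dup$aoi), collapse = ", ")
    ))
  }
  class(expanded) <- c("aoi_group_map", class(expanded))
  expanded
}

#' Read an AOI group map from YAML
#'
#' The YAML lays out one block per group, each a list of entries with an
#' `aoi` label and an optional `phases` list:
#' ```yaml
#' groups:
#'   patient:
#'     - aoi: patients_head
#'     - aoi: face_mask
#'       phases: [3, 4, 5]
#' ```
#'
#' @param path Path to a YAML file.
#' @return An [aoi_group_map()].
#' @export
read_aoi_group_map <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$groups)) abort("AOI map YAML must have a top-level 'groups' key")
  rules <- purrr::imap_dfr(doc$groups, function(entries, group) {
    purrr::map_dfr(entries, function(e) {
      tibble::tibble(
        aoi = e$aoi,
        group = group,
        phases = list(if (is.null(e$phases)) NULL else as.integer(e$phases))
      )
    })
  })
  aoi_group_map(rules)
}

#' Default AOI group map for anesthesia induction
#'
#' The packaged mapping of single AOI labels to the four analysis groups and
#' the excluded set for a five-phase induction of general anesthesia
#' (case history, equipment precheck, preoxygenation and induction, mask
#' ventilation and relaxation, laryngoscopy). Phase-conditional entries: the
#' face mask counts as medication/general equipment in phases 1-2 and as
#' patient from phase 3 on; the laryngoscope's video monitor counts as
#' patient only during laryngoscopy (phase 5).
#'
#' @return An [aoi_group_map()].
#' @export
default_aoi_group_map <- function() {
  read_aoi_group_map(
    system.file("extdata", "aoi_group_map.yaml", package = "seevfit", mustWork = TRUE)
  )
}

#' Map fixation AOI labels to groups
#'
#' @param aoi Character vector of AOI labels.
#' @param phase Integer vector of phases (1-5), recycled against `aoi`.
#' @param map An [aoi_group_map()].
#' @param unknown Policy for labels with no rule at that phase: `"error"`
#'   (default) stops with the offending label; `"excluded"` silently assigns
#'   the excluded group.
#' @return Character vector of group names.
#' @export
#' @examples
#' m <- default_aoi_group_map()
#' map_fixation_to_group("face_mask", 2, m)
#' map_fixation_to_group("face_mask", 4, m)
map_fixation_to_group <- function(aoi, phase, map,
                                  unknown = c("error", "excluded")) {
  unknown <- match.arg(unknown)
  stopifnot(inherits(map, "aoi_group_map"))
  phase <- as.integer(phase)
  if (!all(phase %in% PHASES)) abort("phase must be in 1-5")
  n <- max(length(aoi), length(phase))
  aoi <- rep_len(aoi, n)
  phase <- rep_len(phase, n)
  idx <- match(paste(aoi, phase), paste(map$aoi, map$phase))
  group <- map$group[idx]
  if (anyNA(group)) {
    missing_lab <- unique(aoi[is.na(group)])
    if (unknown == "error") {
      abort(paste0(
        "No AOI group rule for label(s): ",
        paste(missing_lab, collapse = ", "),
        " (at the requested phase). Use unknown = \"excluded\" to drop them."
      ))
    }
    group[is.na(group)] <- "excluded"
  }
  group
}
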