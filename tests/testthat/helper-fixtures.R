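# Shared test fixtures and independent oracles.

# Random fixation sets over the default AOI vocabulary, phases pre-assigned.
random_fixations <- function(n, participants = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- c(
    "patients_head", "patients_thorax", "patient_monitor",
    "anesthesia_machine", "anesthesia_chart", "patient_record",
    "nurses_hands", "anesthesia_trolley", "face_mask",
    "laryngoscope_monitor", "nurses_head", "floor"
  )
  tibble::tibble(
    participant_id = sample(sprintf("p%d", seq_len(participants)), n, replace = TRUE),
    phase = sample(1:5, n, replace = TRUE),
    onset = runif(n, 0, 300),
    duration = runif(n, 0.05, 2),
    aoi = sample(labels, n, replace = TRUE)
  )
}

# Brute-force PDT oracle: raw per-group duration summation, no splitting,
# independent of the dplyr pipeline in compute_pdt.
brute_force_pdt <- function(fixations, map) {
  groups <- vapply(seq_len(nrow(fixations)), function(i) {
    hit <- map$group[map$aoi == fixations$aoi[i] & map$phase == fixations$phase[i]]
    if (length(hit) != 1) stop("oracle: unmapped label ", fixations$aoi[i])
    hit
  }, character(1))
  out <- list()
  for (pid in unique(fixations$participant_id)) {
    for (ph in sort(unique(fixations$phase[fixations$participant_id == pid]))) {
      sel <- fixations$participant_id == pid & fixations$phase == ph
      tot <- sum(fixations$duration[sel])
      for (g in seevfit::aoi_groups()) {
        dur <- sum(fixations$duration[sel & groups == g])
        out[[length(out) + 1]] <- data.frame(
          participant_id = pid, phase = ph, group = g,
          pdt = 100 * dur / tot, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

# A response row where every closed item matches the packaged key.
all_correct_responses <- function(ids = "p1") {
  tibble::tibble(
    participant_id = ids,
    q1 = "yes", q2 = "sure no", q3 = "no", q4 = "shift change",
    q5 = "sure yes", q6 = "no", q7 = "yes", q8 = "yes",
    q9_systolic = "116", q9_diastolic = "46", q10 = "51", q11 = "98",
    q12 = "stable", q13 = "stable"
  )
}
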