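#' Spearman rank association between two paired variables
#'
#' Rank correlation with average ranks for ties. Pairs with a missing member
#' are dropped and the remaining n recorded. The two-sided p-value uses the
#' asymptotic t approximation by default; `exact = TRUE` requests the exact
#' permutation distribution (available without ties for small n).
#'
#' @param x,y Paired numeric vectors.
#' @param label Optional label for the pair.
#' @param exact Passed to [stats::cor.test()]; default `FALSE`.
#' @return A one-row tibble (`pair`, `n`, `rs`, `p`).
#' @export
#' @examples
#' spearman_assoc(1:10, (1:10)^2) # monotone: rs = 1
spearman_assoc <- function(x, y, label = NULL, exact = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Spearman association needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Spearman association undefined for a constant vector")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact, alternative = "two.sided")
  )
  tibble::tibble(
    pair = label %||% NA_character_,
    n = length(x),
    rs = unname(ct$estimate),
    p = ct$p.value
  )
}

# Small-sample (Hedges) correction factor for the standardized mean
# difference, exact gamma form.
hedges_j <- function(df) {
  exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
}

#' Two-group comparison of a continuous variable
#'
#' Student's pooled-variance two-sided t test (df = n1 + n2 - 2), with
#' Cohen's d on the pooled SD and its small-sample corrected version
#' Hedges' g. Welch's unpooled test is available behind `var_equal = FALSE`
#' (effect sizes still use the pooled SD).
#'
#' @param a,b Numeric vectors (missing values dropped).
#' @param labels Length-2 character vector naming the groups.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A one-row tibble with group ns, means, SDs, `t`, `df`, `p`,
#'   `d`, `g`.
#' @export
#' @examples
#' compare_continuous(rnorm(30), rnorm(31, 1))
compare_continuous <- function(a, b, labels = c("a", "b"), var_equal = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("Each group needs at least 2 values")
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) abort("Zero pooled variance; comparison undefined")
  tt <- t.test(a, b, var.equal = var_equal)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  df_pooled <- n1 + n2 - 2
  g <- d * hedges_j(df_pooled)
  tibble::tibble(
    group1 = labels[1], group2 = labels[2],
    n1 = n1, n2 = n2,
    mean1 = mean(a), mean2 = mean(b),
    sd1 = stats::sd(a), sd2 = stats::sd(b),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    d = d, g = g
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p by summation of point probabilities at least as
#' extreme as the observed table (the conventional two-sided rule).
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
#' @examples
#' compare_categorical(matrix(c(19, 11, 12, 19), nrow = 2))
compare_categorical <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("Expected a 2x2 count table")
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Fisher's exact test undefined for an empty margin")
  }
  fisher.test(table, alternative = "two.sided")$p.value
}

#' Association matrix of model fits and dwell shares versus awareness scores
#'
#' Builds the cross table of Spearman associations between attention
#' measures (per-participant model fits for the full phase range and the
#' final phase; final-phase PDT per AOI group including the excluded share)
#' and the three awareness scores (`global`, `sa1`, `environment`). Each
#' cell uses pairwise deletion, so ns differ when some participants lack a
#' score; cells with fewer than 3 complete pairs or a constant member are
#' reported missing rather than erroring the whole table.
#'
#' @param fits Output of [participant_fits()].
#' @param dwell A participant-level dwell table; its final-phase slice
#'   provides the PDT rows.
#' @param scores Output of [compute_sa_scores()].
#' @param phase Phase whose PDT enters the PDT rows (default 5).
#' @param alpha Two-sided significance level for flagging (default 0.05).
#' @return A tibble (`measure`, `score`, `n`, `rs`, `p`, `significant`).
#' @export
build_association_table <- function(fits, dwell, scores, phase = 5, alpha = 0.05) {
  stopifnot(is.data.frame(fits), is.data.frame(dwell), is.data.frame(scores))
  fit_wide <- fits |>
    dplyr::select("participant_id", "phases", "r") |>
    tidyr::pivot_wider(
      names_from = "phases", values_from = "r",
      names_prefix = "fit_"
    )
  pdt_wide <- dwell |>
    dplyr::filter(.data$phase == !!phase) |>
    dplyr::select("participant_id", "group", "pdt") |>
    tidyr::pivot_wider(
      names_from = "group", values_from = "pdt",
      names_prefix = paste0("pdt", phase, "_")
    )
  merged <- fit_wide |>
    dplyr::inner_join(pdt_wide, by = "participant_id") |>
    dplyr::inner_join(
      dplyr::select(scores, "participant_id", "global", "sa1", "environment"),
      by = "participant_id"
    )
  measures <- c(
    grep("^fit_", names(fit_wide), value = TRUE),
    paste0("pdt", phase, "_", c(INCLUDED_GROUPS, "excluded"))
  )
  measures <- intersect(measures, names(merged))
  score_cols <- c("global", "sa1", "environment")
  purrr::map_dfr(measures, function(m) {
    purrr::map_dfr(score_cols, function(s) {
      res <- tryCatch(
        spearman_assoc(merged[[m]], merged[[s]], label = paste(m, s, sep = " ~ ")),
        error = function(e) {
          tibble::tibble(
            pair = paste(m, s, sep = " ~ "),
            n = sum(!is.na(merged[[m]]) & !is.na(merged[[s]])),
            rs = NA_real_, p = NA_real_
          )
        }
      )
      dplyr::mutate(res, measure = m, score = s)
    })
  }) |>
    dplyr::mutate(significant = !is.na(.data$p) & .data$p < alpha) |>
    dplyr::select("measure", "score", "n", "rs", "p", "significant")
}
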