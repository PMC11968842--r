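#' Convert a 20-second pump count to pumps per minute
#'
#' Pharyngeal pumps counted over a 20-s observation window are multiplied by
#' 3 and reported as pumps/min.
#'
#' @param count_20s Non-negative integer pump count(s) over 20 s.
#' @return Pumping rate(s) in pumps per minute.
#' @examples
#' pumps_per_minute(80)  # 240 pumps/min
#' @export
pumps_per_minute <- function(count_20s) {
  if (any(!is.finite(count_20s)) || any(count_20s < 0) ||
      any(count_20s != floor(count_20s))) {
    abort("`count_20s` must be non-negative integer count(s).",
          class = "quiescreen_input_error")
  }
  count_20s * 3
}

assay_categories <- c("dead", "quiescent", "pumping_only", "locomotion_only",
                      "active")

#' Categorize plate-assay animals
#'
#' Each animal observed for 20 s is categorized: `dead` animals (no response
#' to touch) are only dead; otherwise an animal with both pumping and
#' locomotion quiescence is `quiescent`; exactly one of the two gives the
#' partial categories `pumping_only` / `locomotion_only`; neither gives
#' `active`. The last three are collectively "non-quiescent".
#'
#' @param records Data frame with logical columns `pumping_quiescent`,
#'   `locomotion_quiescent`, `dead`.
#' @return `records` with a `category` factor column appended.
#' @export
categorize_assay <- function(records) {
  assert_columns(records, c("pumping_quiescent", "locomotion_quiescent", "dead"),
                 "assay records")
  records |>
    dplyr::mutate(category = factor(dplyr::case_when(
      .data$dead ~ "dead",
      .data$pumping_quiescent & .data$locomotion_quiescent ~ "quiescent",
      .data$pumping_quiescent ~ "pumping_only",
      .data$locomotion_quiescent ~ "locomotion_only",
      TRUE ~ "active"), levels = assay_categories)) |>
    tibble::as_tibble()
}

#' Category fractions of a plate assay
#'
#' Per-category counts divided by the total, with the derived non-quiescent
#' fraction (pumping-only + locomotion-only + active). With grouped input
#' (e.g. by condition) one row per group is returned.
#'
#' @param records Assay records (see [categorize_assay()]); a `category`
#'   column is computed if absent.
#' @return A tibble with `n_animals`, the five primitive fractions
#'   (`dead`, `quiescent`, `pumping_only`, `locomotion_only`, `active`) and
#'   `non_quiescent`.
#' @examples
#' rec <- tibble::tibble(
#'   pumping_quiescent = c(TRUE, TRUE, FALSE, FALSE),
#'   locomotion_quiescent = c(TRUE, FALSE, TRUE, FALSE),
#'   dead = FALSE)
#' summarize_fractions(rec)
#' @export
summarize_fractions <- function(records) {
  if (nrow(records) == 0L) {
    abort("no assay records supplied.", class = "quiescreen_input_error")
  }
  groups <- dplyr::group_vars(records)
  if (!"category" %in% names(records)) {
    records <- categorize_assay(dplyr::ungroup(records)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(groups)))
  }
  records |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      dead = mean(.data$category == "dead"),
      quiescent = mean(.data$category == "quiescent"),
      pumping_only = mean(.data$category == "pumping_only"),
      locomotion_only = mean(.data$category == "locomotion_only"),
      active = mean(.data$category == "active"),
      .groups = "drop") |>
    dplyr::mutate(non_quiescent = .data$pumping_only + .data$locomotion_only +
                    .data$active)
}

#' Bootstrap percentile confidence interval for a fraction
#'
#' Resamples the binary outcome vector with replacement (resample size equal
#' to the sample size) and reports the percentile interval of the resampled
#' mean. Resampling is over animals by default; `by = <plate column>`
#' resamples whole plates instead.
#'
#' @param data Data frame of per-animal records; grouped input gives one
#'   interval per group.
#' @param outcome Logical/0-1 column whose mean fraction is estimated.
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @param by Optional column identifying resampling clusters (e.g.
#'   `plate_id`); default resamples individual animals.
#' @return A tibble per group: `n`, `point`, `low`, `high`.
#' @examples
#' d <- tibble::tibble(q = c(rep(TRUE, 30), rep(FALSE, 70)))
#' bootstrap_fraction_ci(d, q, n_boot = 1000, seed = 1)
#' @export
bootstrap_fraction_ci <- function(data, outcome, n_boot = 10000, level = 0.95,
                                  seed = NULL, by = NULL) {
  out <- enquo(outcome); byq <- enquo(by)
  n_boot <- assert_count(n_boot, "n_boot")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "quiescreen_parameter_error")
  }
  grouped <- if (dplyr::is_grouped_df(data)) data else dplyr::group_by(data)
  alpha <- (1 - level) / 2
  with_seed_or_not(seed, {
    grouped |>
      dplyr::summarise(.res = {
        x <- as.numeric(!!out)
        if (anyNA(x) || !all(x %in% c(0, 1))) {
          abort("`outcome` must be binary with no NA.",
                class = "quiescreen_input_error")
        }
        boots <- if (rlang::quo_is_null(byq)) {
          n <- length(x)
          colMeans(matrix(x[sample.int(n, n * n_boot, replace = TRUE)], n))
        } else {
          cl <- as.character(!!byq)
          idx_by_cl <- split(seq_along(x), cl)
          k <- length(idx_by_cl)
          vapply(seq_len(n_boot), function(b) {
            picked <- unlist(idx_by_cl[sample.int(k, k, replace = TRUE)],
                             use.names = FALSE)
            mean(x[picked])
          }, numeric(1))
        }
        ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
        list(tibble::tibble(n = length(x), point = mean(x),
                            low = ci[1L], high = ci[2L]))
      }, .groups = "drop") |>
      tidyr::unnest(".res")
  })
}

#' Compare quiescence fractions between groups by chi-square test
#'
#' Pearson chi-square on the contingency table of outcome by group, without
#' continuity correction by default, with a Bonferroni-adjusted p-value for
#' a family of `n_comparisons` tests.
#'
#' @param data Data frame of per-animal records.
#' @param group Grouping column (2 or more levels).
#' @param outcome Logical/binary outcome column (e.g. quiescent or not).
#' @param n_comparisons Size of the comparison family for Bonferroni
#'   adjustment (default 1).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
compare_fractions <- function(data, group, outcome, n_comparisons = 1,
                              correct = FALSE) {
  g <- enquo(group); out <- enquo(outcome)
  n_comparisons <- assert_count(n_comparisons, "n_comparisons")
  tab <- table(dplyr::pull(data, !!g), dplyr::pull(data, !!out))
  compare_fraction_counts(tab, n_comparisons = n_comparisons, correct = correct)
}

#' @rdname compare_fractions
#' @param counts A 2-column (or 2-row) contingency matrix of non-negative
#'   integer counts, e.g. `rbind(groupA = c(10, 90), groupB = c(50, 50))`.
#' @export
compare_fraction_counts <- function(counts, n_comparisons = 1, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers.", class = "quiescreen_input_error")
  }
  exp_cells <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(exp_cells == 0) || any(!is.finite(exp_cells))) {
    abort("degenerate table: an expected cell count is 0.",
          class = "quiescreen_input_error")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 p_adjusted = min(1, unname(ct$p.value) * n_comparisons))
}
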