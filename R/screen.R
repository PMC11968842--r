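#' Screen neuron classes for quiescence modulation
#'
#' The full screen: filter identified observations by confidence, merge
#' left/right members into per-animal units, keep classes observed in at
#' least `min_observations` animals, compute each class's real mean QMI, fit
#' the two-state Markov surrogate null on the same animals' quiescence
#' annotations (pooled transitions), simulate `n_sims` surrogate replicates,
#' and assign each class an empirical p-value and a Benjamini-Hochberg
#' q-value with significance flags at the configured FDR.
#'
#' @param data A `quiescence_dataset` from [simulate_quiescence_dataset()],
#'   or a list with elements `traces` (long tibble `animal_id`, `neuron_id`,
#'   `t_index`, `f`), `labels` (`animal_id`, `neuron_id`, `class_name`, `lr`,
#'   `dv`, `confidence`) and `annotation` (per-time-point annotation on the
#'   trace time base).
#' @param config A [screen_config()].
#' @param criteria The [bout_criteria()] under which the annotation was made;
#'   its minimum bout duration is re-applied to every synthetic quiescence
#'   vector so the surrogate null has the bout structure a real annotation
#'   can have.
#' @param quiet Suppress per-stage log messages.
#' @return A `quiescence_screen` object. Its `results` tibble has one row
#'   per tested class: `class_name`, `dv`, `n_obs`, `mean_qmi`,
#'   `p_empirical`, `q_bh`, `significant`. `qmi_matrix` is the
#'   heatmap-shaped class-by-animal tibble of unit QMIs with `NA` for
#'   unobserved cells; `unit_qmis` holds the per-unit values, `null` the
#'   Markov fit, and `config` the configuration echo.
#' @seealso [tidy.quiescence_screen()], [glance.quiescence_screen()],
#'   [autoplot.quiescence_screen()].
#' @export
run_screen <- function(data, config = screen_config(),
                       criteria = bout_criteria(), quiet = FALSE) {
  stopifnot(inherits(config, "screen_config"))
  for (el in c("traces", "labels", "annotation")) {
    if (is.null(data[[el]])) {
      abort(sprintf("`data` must provide `%s`.", el), class = "quiescreen_input_error")
    }
  }
  say <- function(...) if (!quiet) inform(sprintf(...))

  labels <- data$labels |>
    dplyr::filter(!is.na(.data$class_name))
  n_identified <- nrow(labels)
  labels <- labels |> dplyr::filter(.data$confidence >= config$min_confidence)
  say("screen: %d identified observations, %d pass confidence >= %d",
      n_identified, nrow(labels), config$min_confidence)
  if (nrow(labels) == 0L) {
    abort("no observation passes the confidence filter.",
          class = "quiescreen_empty_result")
  }

  obs <- data$traces |>
    dplyr::inner_join(labels, by = c("animal_id", "neuron_id")) |>
    dplyr::group_by(.data$animal_id, .data$neuron_id) |>
    normalize_traces(value = .data$f)
  units <- merge_lr(obs, merge = config$lr_merge)

  # per-animal state vectors and sampling rates on the trace time base
  ann <- data$annotation
  by_animal_ann <- split(ann, ann$animal_id, drop = TRUE)
  states <- lapply(by_animal_ann, function(df) {
    state_to_int(df$quiescent[order(df$time_s)])
  })
  ann_rates <- attr(ann, "sample_rate_hz")
  rates <- vapply(by_animal_ann, function(df) {
    r <- ann_rates[df$animal_id[1L]]
    if (!is.null(r) && length(r) == 1L && !is.na(r)) unname(r)
    else 1 / stats::median(diff(sort(df$time_s)))
  }, numeric(1))

  unit_qmis <- units |>
    dplyr::group_by(.data$animal_id, .data$class_name, .data$dv, .data$unit_id) |>
    dplyr::group_modify(function(df, key) {
      st <- states[[key$animal_id]]
      if (is.null(st) || length(st) != nrow(df)) {
        abort(sprintf("annotation of animal `%s` is not aligned with its traces (use align_annotation()).",
                      key$animal_id),
              class = "quiescreen_input_error")
      }
      res <- qmi_vec(df$f_norm[order(df$t_index)], st)
      tibble::as_tibble(res)
    }) |>
    dplyr::ungroup()
  dropped <- sum(is.na(unit_qmis$qmi))
  if (dropped > 0L) {
    say("screen: dropped %d unit(s) with undefined QMI (a state had no time points)", dropped)
    unit_qmis <- unit_qmis[!is.na(unit_qmis$qmi), , drop = FALSE]
  }

  tested <- unit_qmis |>
    dplyr::count(.data$class_name, .data$dv, name = "n_obs") |>
    dplyr::filter(.data$n_obs >= config$min_observations)
  say("screen: %d class unit(s) observed, %d tested (>= %d observations)",
      dplyr::n_distinct(paste(unit_qmis$class_name, unit_qmis$dv)),
      nrow(tested), config$min_observations)
  if (nrow(tested) == 0L) {
    abort("no neuron class passes the observation-count filter.",
          class = "quiescreen_empty_result")
  }
  unit_qmis_tested <- unit_qmis |>
    dplyr::semi_join(tested, by = c("class_name", "dv"))
  real <- unit_qmis_tested |>
    dplyr::group_by(.data$class_name, .data$dv) |>
    dplyr::summarise(mean_qmi = mean(.data$qmi), n_obs = dplyr::n(),
                     .groups = "drop")

  null <- fit_markov_chain(ann, pseudocount = config$pseudocount,
                           n_sims = config$n_sims, seed = config$seed)
  say("screen: surrogate chain p_enter=%.4g p_exit=%.4g; %d replicates",
      null$p_enter, null$p_exit, config$n_sims)

  units_tested <- units |>
    dplyr::semi_join(unit_qmis_tested,
                     by = c("animal_id", "class_name", "dv", "unit_id"))
  sims <- simulate_null_qmis_matrix(units_tested, null, config$n_sims,
                                    config$seed, config$max_retries,
                                    sample_rate_hz = rates, criteria = criteria)
  sim_key <- paste(sims$classes$class_name, sims$classes$dv, sep = "|")
  real_key <- paste(real$class_name, real$dv, sep = "|")
  p <- vapply(seq_len(nrow(real)), function(k) {
    empirical_pvalue(real$mean_qmi[k],
                     sims$mat[match(real_key[k], sim_key), ],
                     tail = config$tail)
  }, numeric(1))
  adj <- bh_adjust(p, fdr = config$fdr)

  results <- real |>
    dplyr::mutate(p_empirical = p, q_bh = adj$q_value,
                  significant = adj$significant) |>
    dplyr::select("class_name", "dv", "n_obs", "mean_qmi", "p_empirical",
                  "q_bh", "significant") |>
    dplyr::arrange(.data$p_empirical, dplyr::desc(abs(.data$mean_qmi)))
  say("screen: %d of %d classes significant at FDR %.2g",
      sum(results$significant), nrow(results), config$fdr)

  qmi_matrix <- unit_qmis_tested |>
    dplyr::mutate(class = ifelse(.data$dv == "", .data$class_name,
                                 paste0(.data$class_name, .data$dv))) |>
    dplyr::select("class", "animal_id", "qmi") |>
    tidyr::pivot_wider(names_from = "animal_id", values_from = "qmi",
                       names_sort = TRUE)

  structure(list(results = results, qmi_matrix = qmi_matrix,
                 unit_qmis = unit_qmis_tested, null = null, config = config),
            class = "quiescence_screen")
}

#' @export
print.quiescence_screen <- function(x, ...) {
  cat(sprintf("<quiescence_screen> %d classes tested, %d significant at FDR %.2g (n_sims = %d)\n",
              nrow(x$results), sum(x$results$significant), x$config$fdr,
              x$config$n_sims))
  print(head(x$results, 10L))
  if (nrow(x$results) > 10L) cat(sprintf("... and %d more rows\n", nrow(x$results) - 10L))
  invisible(x)
}

#' Tidy a quiescence screen
#'
#' `tidy()` returns the per-class result table; `glance()` a one-row summary.
#'
#' @param x A `quiescence_screen`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy quiescence_screen
#' @export
tidy.quiescence_screen <- function(x, ...) {
  x$results
}

#' @rdname tidy.quiescence_screen
#' @method glance quiescence_screen
#' @export
glance.quiescence_screen <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_positive = sum(x$results$significant & x$results$mean_qmi > 0),
    n_negative = sum(x$results$significant & x$results$mean_qmi < 0),
    fdr = x$config$fdr,
    n_sims = x$config$n_sims,
    p_enter = x$null$p_enter,
    p_exit = x$null$p_exit)
}
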