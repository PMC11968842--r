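# Vector-level primitives --------------------------------------------------

# Mean-normalize one raw trace over included points (NA = excluded).
norm_vec <- function(f) {
  inc <- !is.na(f)
  if (!any(inc)) {
    abort("trace has no included time points.", class = "quiescreen_input_error")
  }
  m <- mean(f[inc])
  if (!is.finite(m) || m <= 0) {
    abort("degenerate trace: mean of included fluorescence is not positive.",
          class = "quiescreen_input_error")
  }
  f / m
}

#' Mean-normalize fluorescence traces
#'
#' Divides each trace by the mean of its included time points, so the
#' normalized trace has mean 1 over the usable part of the recording.
#' Excluded points (`NA` in the value column) stay `NA` and do not enter the
#' mean, so registration failures do not bias the baseline. Normalization is
#' idempotent and invariant to positive rescaling of the raw fluorescence.
#'
#' @param data A long data frame of trace values. Normalization is applied
#'   within each group when `data` is grouped (e.g. by
#'   `animal_id, neuron_id`); ungrouped data is treated as one trace.
#' @param value Column of raw fluorescence values (default `f`).
#' @param out Name of the normalized column added to the result.
#' @return `data` (ungrouped tibble) with the normalized column appended.
#' @examples
#' tr <- tibble::tibble(neuron_id = rep(c("a", "b"), each = 3),
#'                      f = c(2, 2, 2, 1, 2, 3))
#' dplyr::group_by(tr, neuron_id) |> normalize_traces()
#' @export
normalize_traces <- function(data, value = f, out = "f_norm") {
  val <- enquo(value)
  grouped <- dplyr::is_grouped_df(data)
  res <- (if (grouped) data else dplyr::group_by(data)) |>
    dplyr::mutate(!!out := norm_vec(!!val)) |>
    dplyr::ungroup()
  res
}

#' Merge left/right observations of a class into one unit per animal
#'
#' The left/right pair of a neuron class is treated as the same neuron: when
#' both members are observed in an animal the unit's trace is the
#' per-time-point mean of the two mean-normalized traces; a single member
#' passes through unchanged. Dorsal/ventral members are never merged — each
#' `(class_name, dv)` combination is its own unit. More than two
#' observations for one `(animal, class, dv)` is a data error.
#'
#' @param data Long trace tibble with columns `animal_id`, `class_name`,
#'   `dv`, `lr`, `t_index`, and a normalized value column.
#' @param value Normalized trace column (default `f_norm`).
#' @param merge Either `"mean"` (default: pool L and R into one unit) or
#'   `"separate"` (keep L and R as distinct observations).
#' @return A long tibble `animal_id`, `class_name`, `dv`, `unit_id`,
#'   `t_index`, `f_norm` with at most one unit per animal per (class, dv)
#'   under `"mean"`.
#' @export
merge_lr <- function(data, value = f_norm, merge = c("mean", "separate")) {
  merge <- match.arg(merge)
  val <- enquo(value)
  assert_columns(data, c("animal_id", "class_name", "dv", "lr", "t_index"),
                 "observation table")
  data <- dplyr::mutate(data,
                        dv = dplyr::coalesce(as.character(.data$dv), ""),
                        lr = dplyr::coalesce(as.character(.data$lr), ""))
  if (merge == "separate") {
    return(data |>
             dplyr::mutate(unit_id = paste(.data$animal_id, .data$class_name,
                                           .data$dv, .data$lr, sep = "|"),
                           f_norm = !!val) |>
             dplyr::select("animal_id", "class_name", "dv", "unit_id",
                           "t_index", "f_norm"))
  }
  n_obs <- data |>
    dplyr::distinct(.data$animal_id, .data$class_name, .data$dv, .data$lr) |>
    dplyr::count(.data$animal_id, .data$class_name, .data$dv)
  if (any(n_obs$n > 2L)) {
    bad <- n_obs[n_obs$n > 2L, ][1L, ]
    abort(sprintf("more than 2 L/R observations for animal `%s`, class `%s%s`.",
                  bad$animal_id, bad$class_name, bad$dv),
          class = "quiescreen_data_error")
  }
  if (all(n_obs$n == 1L)) {
    # nothing to pool: single observation per unit passes through
    return(data |>
             dplyr::mutate(f_norm = !!val,
                           unit_id = paste(.data$animal_id, .data$class_name,
                                           .data$dv, sep = "|")) |>
             dplyr::select("animal_id", "class_name", "dv", "unit_id",
                           "t_index", "f_norm") |>
             dplyr::arrange(.data$unit_id, .data$t_index))
  }
  data |>
    dplyr::group_by(.data$animal_id, .data$class_name, .data$dv, .data$t_index) |>
    dplyr::summarise(f_norm = mean(!!val), .groups = "drop") |>
    dplyr::mutate(unit_id = paste(.data$animal_id, .data$class_name,
                                  .data$dv, sep = "|")) |>
    dplyr::select("animal_id", "class_name", "dv", "unit_id", "t_index",
                  "f_norm") |>
    dplyr::arrange(.data$unit_id, .data$t_index)
}

#' Mean activity during and outside quiescence
#'
#' Arithmetic means of a normalized trace over quiescent and active time
#' points. Their difference is, by definition, the quiescence-modulation
#' index of [compute_qmi()].
#'
#' @param data Data frame holding (per group, if grouped) one trace and its
#'   aligned binary state.
#' @param value Trace column (default `f_norm`).
#' @param state Binary state column, 1 = quiescent (default `quiescent`).
#' @return One row per group: `mean_quiescent`, `mean_active`,
#'   `n_quiescent`, `n_active`. Groups where either state has no included
#'   point are dropped with a warning.
#' @export
state_means <- function(data, value = f_norm, state = quiescent) {
  val <- enquo(value); st <- enquo(state)
  grouped <- if (dplyr::is_grouped_df(data)) data else dplyr::group_by(data)
  out <- grouped |>
    dplyr::summarise(
      mean_quiescent = mean((!!val)[state_to_int(!!st) == 1L], na.rm = TRUE),
      mean_active = mean((!!val)[state_to_int(!!st) == 0L], na.rm = TRUE),
      n_quiescent = sum(state_to_int(!!st) == 1L & !is.na(!!val)),
      n_active = sum(state_to_int(!!st) == 0L & !is.na(!!val)),
      .groups = "drop")
  bad <- out$n_quiescent == 0L | out$n_active == 0L
  if (any(bad)) {
    warn(sprintf("%d observation(s) dropped: a state had zero included time points.",
                 sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Event-triggered average of traces around bout onsets
#'
#' Aligns trace segments to event onsets (typically quiescence-bout starts)
#' and reports, per offset, the mean and sample (n-1) standard deviation
#' across events. Events whose window does not fit entirely inside the
#' recording are dropped with a message. With a single usable event the SD
#' is reported as 0.
#'
#' @param data Long trace tibble with `animal_id`, `time_s` and a value
#'   column; grouping columns (e.g. `class_name`) are respected, giving one
#'   average per group.
#' @param onsets Either a bout table from [detect_quiescence_bouts()] (its
#'   `start_s` are used) or a data frame with `animal_id`, `onset_s`.
#' @param window_pre_s,window_post_s Window extent before/after onset,
#'   seconds (both >= 0).
#' @param value Trace column (default `f_norm`).
#' @return A tibble with the grouping columns plus `offset_s`, `mean`, `sd`,
#'   `n_events`. Zero usable events yields a zero-row tibble.
#' @export
event_triggered_average <- function(data, onsets, window_pre_s = 10,
                                    window_post_s = 20, value = f_norm) {
  val <- enquo(value)
  assert_columns(data, c("animal_id", "time_s"), "trace table")
  if ("onset_s" %in% names(onsets)) {
    on <- onsets[c("animal_id", "onset_s")]
  } else {
    assert_columns(onsets, c("animal_id", "start_s"), "onsets")
    on <- tibble::tibble(animal_id = onsets$animal_id, onset_s = onsets$start_s)
  }
  stopifnot(window_pre_s >= 0, window_post_s >= 0)
  groups <- dplyr::group_vars(data)
  data <- dplyr::ungroup(data)

  # each observation (neuron/unit) contributes its own event segments
  split_cols <- unique(c(groups, "animal_id",
                         intersect(c("neuron_id", "unit_id"), names(data))))
  pieces <- data |>
    dplyr::mutate(.value = !!val) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(split_cols))) |>
    dplyr::group_map(function(df, key) {
      df <- df[order(df$time_s), , drop = FALSE]
      dt <- check_regular_times(df$time_s, what = "trace time base")
      n_pre <- round(window_pre_s / dt)
      n_post <- round(window_post_s / dt)
      ons <- on$onset_s[on$animal_id == key$animal_id]
      segs <- lapply(ons, function(t0) {
        i0 <- which.min(abs(df$time_s - t0))
        lo <- i0 - n_pre; hi <- i0 + n_post
        if (lo < 1L || hi > nrow(df)) return(NULL)  # partial window dropped
        df$.value[lo:hi]
      })
      dropped <- sum(vapply(segs, is.null, logical(1)))
      segs <- segs[!vapply(segs, is.null, logical(1))]
      if (dropped > 0L) {
        inform(sprintf("event_triggered_average: dropped %d partial-window event(s).",
                       dropped))
      }
      if (length(segs) == 0L) return(NULL)
      mat <- do.call(rbind, segs)
      out <- tibble::tibble(
        offset_s = seq(-n_pre, n_post) * dt,
        mean = colMeans(mat),
        sd = if (nrow(mat) > 1L) apply(mat, 2L, sd) else rep(0, ncol(mat)),
        n_events = nrow(mat))
      dplyr::bind_cols(key[rep(1L, nrow(out)), , drop = FALSE], out)
    }) |>
    purrr::compact()
  if (length(pieces) == 0L) {
    return(tibble::tibble(offset_s = numeric(), mean = numeric(),
                          sd = numeric(), n_events = integer()))
  }
  # pool events across animals within each requested group (weighted mean,
  # pooled sample SD of the combined event set)
  dplyr::bind_rows(pieces) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "offset_s")))) |>
    dplyr::summarise(
      m = sum(.data$mean * .data$n_events) / sum(.data$n_events),
      sd = pooled_sd(.data$mean, .data$sd, .data$n_events),
      n_events = sum(.data$n_events), .groups = "drop") |>
    dplyr::rename(mean = "m") |>
    dplyr::relocate(dplyr::all_of(groups), "offset_s", "mean", "sd", "n_events")
}

# Sample SD of the pooled set of events from per-animal means/SDs/counts.
pooled_sd <- function(means, sds, ns) {
  n <- sum(ns)
  if (n < 2L) return(0)
  gm <- sum(means * ns) / n
  ss <- sum((ns - 1L) * sds^2) + sum(ns * (means - gm)^2)
  sqrt(ss / (n - 1L))
}
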