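#' Thresholds defining a behavioral quiescence bout
#'
#' A quiescent time point is one where locomotion speed, the absolute head
#' curvature derivative and the pharyngeal pumping rate are all sub-threshold;
#' a bout is a maximal run of such points lasting strictly longer than
#' `min_duration_s`. Defaults are the brain-wide imaging criteria: speed below
#' 0.01 mm/s (the measurement noise floor), head curvature derivative below
#' 0.1 rad/s, no visible pumping, and more than 8 consecutive seconds.
#'
#' Speed and curvature are compared with strict `<`; pumping with `<=` so that
#' an exact-zero pumping threshold admits pumping = 0 Hz.
#'
#' @param speed_max Maximum locomotion speed, mm/s. Default 0.01.
#' @param curvature_deriv_max Maximum absolute head-curvature derivative,
#'   rad/s. Default 0.1.
#' @param pumping_max Maximum pumping rate, Hz (inclusive). Default 0.
#' @param min_duration_s Minimum bout duration in seconds; a run qualifies only
#'   if strictly longer. Default 8.
#' @param use_curvature Should the curvature channel be part of the rule? The
#'   speed + pumping variant is available for recordings without a curvature
#'   channel.
#' @return A `bout_criteria` list.
#' @examples
#' bout_criteria()
#' bout_criteria(min_duration_s = 10)
#' @export
bout_criteria <- function(speed_max = 0.01, curvature_deriv_max = 0.1,
                          pumping_max = 0, min_duration_s = 8,
                          use_curvature = TRUE) {
  stopifnot(speed_max >= 0, curvature_deriv_max >= 0, pumping_max >= 0)
  if (!is.numeric(min_duration_s) || min_duration_s <= 0) {
    abort("`min_duration_s` must be > 0.", class = "quiescreen_parameter_error")
  }
  structure(list(speed_max = speed_max,
                 curvature_deriv_max = curvature_deriv_max,
                 pumping_max = pumping_max,
                 min_duration_s = min_duration_s,
                 use_curvature = isTRUE(use_curvature)),
            class = "bout_criteria")
}

# Per-point sub-threshold indicator with gap handling: NA runs of at most
# `max_fill` samples take the nearest neighbour's value (ties -> previous);
# longer gaps are forced non-quiescent so they split the recording into
# independent segments that a bout can never span.
subthreshold_vector <- function(speed, curvature_deriv, pumping, criteria,
                                max_fill = 2L) {
  sub <- speed < criteria$speed_max & pumping <= criteria$pumping_max
  if (criteria$use_curvature) {
    sub <- sub & abs(curvature_deriv) < criteria$curvature_deriv_max
  }
  if (!anyNA(sub)) return(sub)
  r <- rle(is.na(sub))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(sub)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (r$lengths[k] > max_fill || (i0 == 1L && i1 == n)) {
      sub[i0:i1] <- FALSE
      next
    }
    for (i in i0:i1) {
      d_prev <- if (i0 > 1L) i - i0 + 1L else NA_integer_
      d_next <- if (i1 < n) i1 - i + 1L else NA_integer_
      if (!is.na(d_prev) && (is.na(d_next) || d_prev <= d_next)) {
        sub[i] <- sub[i0 - 1L]
      } else {
        sub[i] <- sub[i1 + 1L]
      }
    }
  }
  sub
}

# Maximal sub-threshold runs filtered by strict duration; 0-based half-open
# [start, end) sample intervals. The epsilon guards float noise in the rate
# without ever admitting a run of exactly the minimum duration.
runs_to_bouts <- function(sub, sample_rate_hz, min_duration_s) {
  r <- rle(as.logical(sub))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / sample_rate_hz > min_duration_s * (1 + 1e-9))
  tibble::tibble(start = starts[keep] - 1L, end = ends[keep])
}

#' Annotate each time point as quiescent or active
#'
#' Applies the bout rule to multi-channel behavior data: a time point is
#' sub-threshold iff all enabled channels are below their thresholds, and only
#' maximal sub-threshold runs strictly longer than the minimum duration count
#' as quiescence. Points inside shorter sub-threshold runs stay active (state
#' 0). Runs of at most 2 missing samples are filled from the nearest
#' neighbour; longer gaps split the recording so no bout spans them.
#'
#' @param behavior A data frame with columns `time_s`, `speed_mm_s`,
#'   `curvature_deriv_rad_s` (unless `criteria$use_curvature` is `FALSE`),
#'   `pumping_hz`, and optionally `animal_id` (one series per animal).
#'   Timestamps must be regular within each animal.
#' @param criteria A [bout_criteria()] object.
#' @return A tibble with one row per time point: `animal_id`, `time_s`,
#'   `quiescent` (0/1) and `bout` (bout number within animal, `NA` outside
#'   bouts), carrying a `sample_rate_hz` attribute (named by animal).
#' @seealso [detect_quiescence_bouts()] for the bout table,
#'   [align_annotation()] to resample onto another time base.
#' @examples
#' b <- tibble::tibble(time_s = seq(0, 59.5, by = 0.5),
#'                     speed_mm_s = 0, curvature_deriv_rad_s = 0, pumping_hz = 0)
#' annotate_quiescence(b)
#' @export
annotate_quiescence <- function(behavior, criteria = bout_criteria()) {
  stopifnot(inherits(criteria, "bout_criteria"))
  if (!is.data.frame(behavior) || nrow(behavior) == 0L) {
    abort("`behavior` must be a non-empty data frame.", class = "quiescreen_input_error")
  }
  cols <- c("time_s", "speed_mm_s", "pumping_hz")
  if (criteria$use_curvature) cols <- c(cols, "curvature_deriv_rad_s")
  assert_columns(behavior, cols, "behavior table")
  if (!"animal_id" %in% names(behavior)) behavior$animal_id <- "animal_1"
  if (!"curvature_deriv_rad_s" %in% names(behavior)) {
    behavior$curvature_deriv_rad_s <- 0
  }
  neg <- stats::na.omit(c(behavior$speed_mm_s, behavior$pumping_hz))
  if (any(neg < 0)) {
    abort("speed and pumping must be non-negative.", class = "quiescreen_input_error")
  }

  pieces <- lapply(split(behavior, behavior$animal_id, drop = TRUE), function(df) {
    df <- df[order(df$time_s), , drop = FALSE]
    dt <- check_regular_times(df$time_s,
                              what = sprintf("behavior of animal `%s`", df$animal_id[1L]))
    rate <- 1 / dt
    sub <- subthreshold_vector(df$speed_mm_s, df$curvature_deriv_rad_s,
                               df$pumping_hz, criteria)
    bouts <- runs_to_bouts(sub, rate, criteria$min_duration_s)
    state <- integer(nrow(df))
    bout_id <- rep(NA_integer_, nrow(df))
    if (nrow(bouts) > 0L) {
      for (k in seq_len(nrow(bouts))) {
        idx <- (bouts$start[k] + 1L):bouts$end[k]
        state[idx] <- 1L
        bout_id[idx] <- k
      }
    }
    out <- tibble::tibble(animal_id = df$animal_id, time_s = df$time_s,
                          quiescent = state, bout = bout_id)
    attr(out, "sample_rate_hz") <- rate
    out
  })
  rates <- vapply(pieces, attr, numeric(1), "sample_rate_hz")
  out <- dplyr::bind_rows(pieces)
  attr(out, "sample_rate_hz") <- rates
  out
}

#' Detect quiescence bouts in behavior recordings
#'
#' Returns the bout table implied by [annotate_quiescence()]: maximal runs of
#' sub-threshold behavior strictly longer than `criteria$min_duration_s`.
#' Intervals are half-open, 0-based sample intervals `[start, end)` so that
#' `end - start` is the number of samples in the bout.
#'
#' @inheritParams annotate_quiescence
#' @return A tibble with columns `animal_id`, `bout`, `start`, `end`
#'   (sample indices), `start_s`, `end_s`, `duration_s`, `n_samples`.
#' @examples
#' b <- tibble::tibble(time_s = seq(0, 59.5, by = 0.5),
#'                     speed_mm_s = 0, curvature_deriv_rad_s = 0, pumping_hz = 0)
#' detect_quiescence_bouts(b)
#' @export
detect_quiescence_bouts <- function(behavior, criteria = bout_criteria()) {
  ann <- annotate_quiescence(behavior, criteria)
  bouts_from_annotation(ann)
}

#' Summarise an annotation into its bout table
#'
#' @param annotation A per-time-point annotation from [annotate_quiescence()]
#'   or [align_annotation()].
#' @return The bout tibble described in [detect_quiescence_bouts()].
#' @export
bouts_from_annotation <- function(annotation) {
  assert_columns(annotation, c("animal_id", "time_s", "quiescent", "bout"),
                 "annotation")
  rates <- attr(annotation, "sample_rate_hz")
  if (all(is.na(annotation$bout))) {
    return(tibble::tibble(animal_id = character(), bout = integer(),
                          start = integer(), end = integer(),
                          start_s = numeric(), end_s = numeric(),
                          duration_s = numeric(), n_samples = integer()))
  }
  out <- annotation |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::mutate(
      .idx = dplyr::row_number() - 1L,
      .rate = if (is.null(rates)) 1 / stats::median(diff(.data$time_s))
              else unname(rates[as.character(.data$animal_id[1L])])) |>
    dplyr::filter(!is.na(.data$bout)) |>
    dplyr::group_by(.data$animal_id, .data$bout) |>
    dplyr::summarise(start = min(.data$.idx), end = max(.data$.idx) + 1L,
                     start_s = min(.data$time_s), end_s = max(.data$time_s),
                     n_samples = dplyr::n(),
                     duration_s = dplyr::n() / .data$.rate[1L],
                     .groups = "drop") |>
    dplyr::select("animal_id", "bout", "start", "end", "start_s", "end_s",
                  "duration_s", "n_samples") |>
    dplyr::arrange(.data$animal_id, .data$start)
  out
}

#' Resample a quiescence annotation onto a new time base
#'
#' Each target time point takes the state of the nearest source point; the
#' bout list is then recomputed from the resampled state with the same
#' strict minimum-duration rule at the target rate. Used to carry bout
#' annotations from a fast behavior camera onto slower fluorescence volumes.
#'
#' @param annotation A per-time-point annotation from [annotate_quiescence()].
#' @param target_times Either a numeric vector of target timestamps applied to
#'   every animal, or a data frame with columns `animal_id`, `time_s`. Targets
#'   must lie within the source time span of their animal.
#' @param criteria The [bout_criteria()] whose `min_duration_s` governs the
#'   recomputed bout list.
#' @return A per-time-point annotation tibble on the target time base.
#' @export
align_annotation <- function(annotation, target_times, criteria = bout_criteria()) {
  assert_columns(annotation, c("animal_id", "time_s", "quiescent"), "annotation")
  if (is.numeric(target_times)) {
    target_times <- tidyr::expand_grid(
      animal_id = unique(annotation$animal_id), time_s = target_times)
  }
  assert_columns(target_times, c("animal_id", "time_s"), "target times")

  pieces <- lapply(split(target_times, target_times$animal_id, drop = TRUE), function(tg) {
    src <- annotation[annotation$animal_id == tg$animal_id[1L], , drop = FALSE]
    if (nrow(src) == 0L) {
      abort(sprintf("no source annotation for animal `%s`.", tg$animal_id[1L]),
            class = "quiescreen_input_error")
    }
    tg <- tg[order(tg$time_s), , drop = FALSE]
    span_tol <- 1e-9 * max(1, diff(range(src$time_s)))
    if (min(tg$time_s) < min(src$time_s) - span_tol ||
        max(tg$time_s) > max(src$time_s) + span_tol) {
      abort(sprintf("target times for animal `%s` fall outside the source span [%g, %g] s.",
                    tg$animal_id[1L], min(src$time_s), max(src$time_s)),
            class = "quiescreen_input_error")
    }
    rate <- 1 / check_regular_times(tg$time_s, what = "target time base")
    # nearest-neighbour lookup via midpoints between source samples
    mids <- src$time_s[-nrow(src)] + diff(src$time_s) / 2
    idx <- findInterval(tg$time_s, mids) + 1L
    state <- state_to_int(src$quiescent)[idx]
    bouts <- runs_to_bouts(state == 1L, rate, criteria$min_duration_s)
    new_state <- integer(nrow(tg))
    bout_id <- rep(NA_integer_, nrow(tg))
    if (nrow(bouts) > 0L) {
      for (k in seq_len(nrow(bouts))) {
        sel <- (bouts$start[k] + 1L):bouts$end[k]
        new_state[sel] <- 1L
        bout_id[sel] <- k
      }
    }
    out <- tibble::tibble(animal_id = tg$animal_id, time_s = tg$time_s,
                          quiescent = new_state, bout = bout_id)
    attr(out, "sample_rate_hz") <- rate
    out
  })
  rates <- vapply(pieces, attr, numeric(1), "sample_rate_hz")
  out <- dplyr::bind_rows(pieces)
  attr(out, "sample_rate_hz") <- rates
  out
}

#' Fraction of time spent quiescent
#'
#' The mean of the binary state per animal — used for quality control, e.g.
#' to flag recordings dominated by quiescence.
#'
#' @param annotation A per-time-point annotation.
#' @return A tibble with `animal_id`, `n_points`, `fraction`.
#' @export
quiescent_fraction <- function(annotation) {
  assert_columns(annotation, c("animal_id", "quiescent"), "annotation")
  if (nrow(annotation) == 0L) {
    abort("annotation is empty.", class = "quiescreen_input_error")
  }
  annotation |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(n_points = dplyr::n(),
                     fraction = mean(state_to_int(.data$quiescent)),
                     .groups = "drop")
}
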