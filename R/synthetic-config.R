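#' Default neuron-class catalog for synthetic datasets
#'
#' Builds a catalog of synthetic neuron classes mimicking the anatomy of the
#' C. elegans head ganglia: most classes come as left/right pairs (pooled as
#' one unit per animal), and a fraction come as distinct dorsal/ventral
#' members (kept as separate units). Class names are synthetic (`C001`, ...),
#' not real anatomical identities.
#'
#' @param n_classes Number of base class names.
#' @param frac_lr_paired Fraction of classes with separate L and R members.
#' @param frac_dv Fraction of classes expanded into dorsal and ventral units.
#' @return A tibble with one row per unit: `class_name`, `dv` (`"D"`, `"V"`,
#'   or `""`), `lr_paired` (logical).
#' @examples
#' default_class_catalog(10)
#' @export
default_class_catalog <- function(n_classes = 150, frac_lr_paired = 0.6,
                                  frac_dv = 0.12) {
  n_classes <- assert_count(n_classes, "n_classes")
  name <- sprintf("C%03d", seq_len(n_classes))
  n_dv <- floor(frac_dv * n_classes)
  n_lr <- floor(frac_lr_paired * n_classes)
  dv_classes <- name[seq_len(n_dv)]
  lr_classes <- name[seq_len(n_lr)]  # overlap with dv classes is allowed
  rows <- lapply(name, function(cl) {
    dv <- if (cl %in% dv_classes) c("D", "V") else ""
    tibble::tibble(class_name = cl, dv = dv, lr_paired = cl %in% lr_classes)
  })
  dplyr::bind_rows(rows)
}

#' Configuration of the synthetic multi-animal imaging dataset
#'
#' Defaults emulate the brain-wide imaging study conditions: 8 freely moving
#' animals recorded for 8 minutes, fluorescence volumes at 4 Hz with the
#' behavior camera 4x faster, 117-176 segmented neurons per animal of which
#' 40-121 receive a class identity, and Markovian quiescence bouts. The
#' per-step transition probabilities (at the volume rate) default to
#' `p_enter = 0.01`, `p_exit = 0.02`: mean active runs of 25 s, mean
#' quiescent runs of 12.5 s, and a long-run quiescent fraction of 1/3 —
#' frequent switching with under half the recording quiescent, as the
#' imaging inclusion rules require.
#'
#' @param n_animals Number of animals.
#' @param duration_s Recording length, seconds.
#' @param sample_rate_hz Fluorescence-volume rate, Hz. `duration_s *
#'   sample_rate_hz` must be a whole number of time points.
#' @param behavior_upsample Integer factor by which the behavior channels are
#'   sampled faster than the volumes (nearest-state upsampling of the latent
#'   sequence). 1 disables multirate generation.
#' @param p_enter,p_exit Per-volume-step probabilities of the active->quiescent
#'   and quiescent->active transitions, both strictly inside (0, 1).
#' @param n_neurons_range,n_identified_range Inclusive ranges for segmented
#'   and identified neuron counts per animal (identified <= segmented).
#' @param class_catalog Unit catalog, see [default_class_catalog()].
#' @param effect_map Named numeric vector or two-column data frame
#'   (`class_name`, `effect`) of signed modulation effect sizes; classes not
#'   listed get effect 0. Default: no modulated classes (a pure null).
#' @param noise_sd Gaussian fluorescence noise SD (same unit as baseline).
#' @param baseline_mean Mean baseline fluorescence (> 0).
#' @param confidence_dist Probabilities of identification confidence 1-5.
#' @param criteria [bout_criteria()] used both to write the behavior channels
#'   and to define the ground-truth annotation.
#' @param min_bouts Minimum number of annotated bouts an animal must display
#'   to enter the dataset; animals below it are redrawn. Default 1 —
#'   recordings are of animals that displayed quiescence, mirroring how
#'   imaging subjects are selected. Set to 0 to disable.
#' @param max_quiescent_fraction Animals quiescent for more than this
#'   fraction of the recording are redrawn (default 0.5, the usual
#'   registration-quality discard rule). Set to 1 to disable.
#' @param seed Root seed; expands deterministically into per-animal,
#'   per-purpose streams.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_animals = 8,
                             duration_s = 480,
                             sample_rate_hz = 4,
                             behavior_upsample = 4,
                             p_enter = 0.01,
                             p_exit = 0.02,
                             n_neurons_range = c(117, 176),
                             n_identified_range = c(40, 121),
                             class_catalog = default_class_catalog(),
                             effect_map = NULL,
                             noise_sd = 0.05,
                             baseline_mean = 1,
                             confidence_dist = c(0.05, 0.10, 0.15, 0.30, 0.40),
                             criteria = bout_criteria(),
                             min_bouts = 1L,
                             max_quiescent_fraction = 0.5,
                             seed = 1L) {
  assert_prob(p_enter, "p_enter")
  assert_prob(p_exit, "p_exit")
  n_animals <- assert_count(n_animals, "n_animals")
  behavior_upsample <- assert_count(behavior_upsample, "behavior_upsample")
  n_steps <- duration_s * sample_rate_hz
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    abort("`duration_s * sample_rate_hz` must be an integer number of time points.",
          class = "quiescreen_parameter_error")
  }
  stopifnot(length(n_neurons_range) == 2L, length(n_identified_range) == 2L,
            n_neurons_range[1] <= n_neurons_range[2],
            n_identified_range[1] <= n_identified_range[2])
  if (n_identified_range[2] > n_neurons_range[2]) {
    abort("identified neurons are a subset of segmented neurons: `n_identified_range` must fit inside `n_neurons_range`.",
          class = "quiescreen_parameter_error")
  }
  if (baseline_mean <= 0) {
    abort("`baseline_mean` must be > 0.", class = "quiescreen_parameter_error")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "quiescreen_parameter_error")
  if (!is.numeric(max_quiescent_fraction) || max_quiescent_fraction <= 0 ||
      max_quiescent_fraction > 1) {
    abort("`max_quiescent_fraction` must be in (0, 1].",
          class = "quiescreen_parameter_error")
  }
  if (length(confidence_dist) != 5L || any(confidence_dist < 0) ||
      sum(confidence_dist) <= 0) {
    abort("`confidence_dist` must be 5 non-negative weights for scores 1-5.",
          class = "quiescreen_parameter_error")
  }
  effect_map <- normalize_effect_map(effect_map)
  if (!all(effect_map$class_name %in% class_catalog$class_name)) {
    abort("`effect_map` names classes absent from `class_catalog`.",
          class = "quiescreen_parameter_error")
  }
  structure(list(
    n_animals = n_animals, duration_s = duration_s,
    sample_rate_hz = sample_rate_hz, behavior_upsample = behavior_upsample,
    p_enter = p_enter, p_exit = p_exit,
    n_neurons_range = as.integer(n_neurons_range),
    n_identified_range = as.integer(n_identified_range),
    class_catalog = class_catalog, effect_map = effect_map,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    confidence_dist = confidence_dist / sum(confidence_dist),
    criteria = criteria,
    min_bouts = assert_count(min_bouts, "min_bouts", min = 0L),
    max_quiescent_fraction = max_quiescent_fraction,
    seed = as.integer(seed),
    n_steps = as.integer(round(n_steps))), class = "synthetic_config")
}

normalize_effect_map <- function(effect_map) {
  if (is.null(effect_map)) {
    return(tibble::tibble(class_name = character(), effect = numeric()))
  }
  if (is.data.frame(effect_map)) {
    assert_columns(effect_map, c("class_name", "effect"), "effect_map")
    effect_map <- tibble::as_tibble(effect_map[c("class_name", "effect")])
  } else if (is.numeric(effect_map) && !is.null(names(effect_map))) {
    effect_map <- tibble::tibble(class_name = names(effect_map),
                                 effect = unname(effect_map))
  } else {
    abort("`effect_map` must be a named numeric vector or a data frame with `class_name`, `effect`.",
          class = "quiescreen_parameter_error")
  }
  if (any(!is.finite(effect_map$effect))) {
    abort("effect sizes must be finite.", class = "quiescreen_parameter_error")
  }
  effect_map
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d animals, %g s at %g Hz (%d steps), behavior x%d\n",
              x$n_animals, x$duration_s, x$sample_rate_hz, x$n_steps,
              x$behavior_upsample))
  cat(sprintf("  Markov bouts: p_enter=%g, p_exit=%g (stationary quiescent fraction %.3f)\n",
              x$p_enter, x$p_exit, x$p_enter / (x$p_enter + x$p_exit)))
  cat(sprintf("  neurons %d-%d (identified %d-%d), catalog of %d units, %d modulated class(es)\n",
              x$n_neurons_range[1], x$n_neurons_range[2],
              x$n_identified_range[1], x$n_identified_range[2],
              nrow(x$class_catalog), nrow(x$effect_map)))
  invisible(x)
}
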