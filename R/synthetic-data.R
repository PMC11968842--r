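#' Simulate a binary quiescence state sequence from a two-state Markov chain
#'
#' Generates a first-order Markov sequence of 0 (active) / 1 (quiescent)
#' states. The initial state is drawn from the stationary distribution of the
#' chain unless forced with `init`. Sojourn times are geometric, so the
#' sequence has the bout-and-run temporal structure the surrogate null relies
#' on.
#'
#' @param p_enter Per-step probability of the active -> quiescent transition,
#'   strictly inside (0, 1).
#' @param p_exit Per-step probability of the quiescent -> active transition.
#' @param n_steps Sequence length (>= 1).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param init Optional forced initial state (0 or 1).
#' @return An integer vector of 0/1 states of length `n_steps`.
#' @examples
#' s <- generate_state_sequence(0.02, 0.1, 1e4, seed = 1)
#' mean(s)  # converges to p_enter / (p_enter + p_exit) = 1/6
#' @export
generate_state_sequence <- function(p_enter, p_exit, n_steps, seed = NULL,
                                    init = NULL) {
  assert_prob(p_enter, "p_enter")
  assert_prob(p_exit, "p_exit")
  n_steps <- assert_count(n_steps, "n_steps")
  with_seed_or_not(seed, {
    pi_q <- p_enter / (p_enter + p_exit)
    state0 <- if (is.null(init)) rbinom(1L, 1L, pi_q) else state_to_int(init)[1L]
    # run-length construction: alternate geometric sojourns, batched; runs are
    # capped at n_steps so near-absorbing chains stay in integer range
    cycle_len <- min(1 / p_enter + 1 / p_exit, 2 * n_steps)
    states <- integer(0)
    lens <- numeric(0)
    cur <- state0
    total <- 0
    while (total < n_steps) {
      n_runs <- max(8L, ceiling(2 * (n_steps - total) / cycle_len))
      p_first <- if (cur == 0L) p_enter else p_exit
      p_second <- if (cur == 0L) p_exit else p_enter
      new_lens <- pmin(as.numeric(rbind(rgeom(n_runs, p_first) + 1,
                                        rgeom(n_runs, p_second) + 1)),
                       n_steps)
      new_states <- rep_len(c(cur, 1L - cur), 2L * n_runs)
      states <- c(states, new_states)
      lens <- c(lens, new_lens)
      total <- total + sum(new_lens)
      cur <- state0  # parity of batch is even, next batch starts from state0
    }
    rep.int(states, lens)[seq_len(n_steps)]
  })
}

#' Generate behavior channels consistent with a latent quiescence sequence
#'
#' Writes locomotion speed, head-curvature derivative and pumping channels
#' that are sub-threshold exactly on the latent quiescent steps and
#' supra-threshold (speed always, the others noisily) on active steps, so
#' [detect_quiescence_bouts()] recovers the latent state up to the minimum
#' bout-duration rule. The latent sequence is at the volume rate; `upsample`
#' replicates each latent step onto a faster behavior clock
#' (nearest-state assignment).
#'
#' @param state Binary latent sequence at the volume rate.
#' @param sample_rate_hz Volume rate, Hz.
#' @param criteria [bout_criteria()] whose thresholds the channels respect.
#' @param seed Optional seed.
#' @param upsample Integer behavior-to-volume rate ratio.
#' @param animal_id Identifier written into the output.
#' @return A behavior tibble (`animal_id`, `time_s`, `speed_mm_s`,
#'   `curvature_deriv_rad_s`, `pumping_hz`) at `sample_rate_hz * upsample`.
#' @export
generate_behavior_channels <- function(state, sample_rate_hz,
                                       criteria = bout_criteria(), seed = NULL,
                                       upsample = 1L, animal_id = "animal_1") {
  state <- state_to_int(state)
  if (length(state) == 0L) {
    abort("`state` must be non-empty.", class = "quiescreen_input_error")
  }
  upsample <- assert_count(upsample, "upsample")
  with_seed_or_not(seed, {
    s <- rep(state, each = upsample)
    n <- length(s)
    rate <- sample_rate_hz * upsample
    q <- s == 1L
    speed <- numeric(n)
    curv <- numeric(n)
    pump <- numeric(n)
    # quiescent: strictly sub-threshold on every channel
    speed[q] <- runif(sum(q), 0, 0.8 * criteria$speed_max)
    curv[q] <- runif(sum(q), -0.8, 0.8) * criteria$curvature_deriv_max
    pump[q] <- 0
    # active: speed guaranteed supra-threshold; the others noisy
    speed[!q] <- criteria$speed_max + rexp(sum(!q), rate = 25)
    curv[!q] <- rnorm(sum(!q), 0, 3 * criteria$curvature_deriv_max)
    pump[!q] <- pmax(0, round(rnorm(sum(!q), 4.5, 1.2)))
    tibble::tibble(animal_id = animal_id,
                   time_s = (seq_len(n) - 1L) / rate,
                   speed_mm_s = speed,
                   curvature_deriv_rad_s = curv,
                   pumping_hz = pump)
  })
}

#' Generate neural traces with injected quiescence modulation
#'
#' For a neuron of a class with effect size `d`, the raw trace is
#' `baseline_mean * (1 + d * state_t)` plus Gaussian noise, truncated at 0
#' (fluorescence is non-negative). After mean normalization the expected
#' quiescence-modulation index of such a trace is `d / (1 + d * f)` where `f`
#' is the quiescent fraction of the state sequence — a known monotone
#' function of `d`. Classes with effect 0 are exchangeable with the null.
#'
#' @param state Binary quiescence sequence on the trace time base (after the
#'   bout-duration rule, i.e. the annotation state).
#' @param labels Label tibble with one row per neuron: `neuron_id`,
#'   `class_name` (`NA` for unidentified neurons), `lr`, `dv`, `confidence`.
#' @param effect_map Named vector or `class_name`/`effect` data frame.
#' @param baseline_mean,noise_sd Baseline fluorescence and noise SD.
#' @param seed Optional seed.
#' @param animal_id Identifier written into the output.
#' @return A long tibble `animal_id`, `neuron_id`, `time_s` (index-based,
#'   supplied by the caller via `time_s` attribute not required), `f`.
#' @export
generate_neural_traces <- function(state, labels, effect_map = NULL,
                                   baseline_mean = 1, noise_sd = 0.05,
                                   seed = NULL, animal_id = "animal_1") {
  state <- state_to_int(state)
  effect_map <- normalize_effect_map(effect_map)
  assert_columns(labels, c("neuron_id", "class_name"), "label table")
  with_seed_or_not(seed, {
    n_t <- length(state)
    eff <- effect_map$effect[match(labels$class_name, effect_map$class_name)]
    eff[is.na(eff)] <- 0
    traces <- lapply(seq_len(nrow(labels)), function(i) {
      f <- baseline_mean * (1 + eff[i] * state) + rnorm(n_t, 0, noise_sd)
      pmax(f, 0)
    })
    tibble::tibble(
      animal_id = animal_id,
      neuron_id = rep(labels$neuron_id, each = n_t),
      t_index = rep(seq_len(n_t) - 1L, times = nrow(labels)),
      f = unlist(traces, use.names = FALSE))
  })
}

#' Simulate a complete multi-animal imaging dataset
#'
#' Draws, for each animal, a latent Markov quiescence sequence, behavior
#' channels consistent with the bout criteria, a roster of segmented neurons
#' of which a subset is identified against the class catalog, and neural
#' traces with class-specific modulation injected on the ground-truth
#' (bout-filtered) quiescence state. The ground-truth annotation is exactly
#' what [detect_quiescence_bouts()] + [align_annotation()] recover from the
#' generated behavior channels.
#'
#' @param config A [synthetic_config()].
#' @return A `quiescence_dataset` list with tibbles `behavior` (at the
#'   behavior rate), `annotation` (ground truth at the volume rate), `traces`
#'   (long: `animal_id`, `neuron_id`, `t_index`, `time_s`, `f`), `labels`
#'   (`animal_id`, `neuron_id`, `class_name`, `lr`, `dv`, `confidence`), the
#'   `effect_map` echo and the `config`.
#' @examples
#' ds <- simulate_quiescence_dataset(synthetic_config(
#'   n_animals = 2, duration_s = 60, n_neurons_range = c(12, 15),
#'   n_identified_range = c(8, 12), class_catalog = default_class_catalog(10),
#'   seed = 7))
#' quiescent_fraction(ds$annotation)
#' @export
simulate_quiescence_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cat_tbl <- config$class_catalog
  # roster of individual neurons implied by the unit catalog
  roster <- cat_tbl |>
    dplyr::rowwise() |>
    dplyr::reframe(class_name = .data$class_name, dv = .data$dv,
                   lr = if (.data$lr_paired) c("L", "R") else "") |>
    tibble::as_tibble()

  behavior <- list(); annotation <- list(); traces <- list(); labels <- list()
  volume_times <- (seq_len(config$n_steps) - 1L) / config$sample_rate_hz
  for (a in seq_len(config$n_animals)) {
    id <- sprintf("animal_%d", a)
    # animals that display no quiescence bout, or are quiescent for too much
    # of the recording, are redrawn — mirroring how imaging subjects are
    # selected and quality-filtered
    accepted <- FALSE
    for (attempt in 0:99) {
      latent <- generate_state_sequence(
        config$p_enter, config$p_exit, config$n_steps,
        seed = sub_seed(config$seed, 10L * a + 1L + 1000003 * attempt))
      beh <- generate_behavior_channels(
        latent, config$sample_rate_hz, config$criteria,
        seed = sub_seed(config$seed, 10L * a + 2L + 1000003 * attempt),
        upsample = config$behavior_upsample, animal_id = id)
      ann_beh <- annotate_quiescence(beh, config$criteria)
      ann <- align_annotation(ann_beh, volume_times, config$criteria)
      n_bouts <- length(unique(stats::na.omit(ann$bout)))
      if (n_bouts >= config$min_bouts &&
          mean(ann$quiescent) <= config$max_quiescent_fraction) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      abort(sprintf("could not draw an acceptable animal `%s` in 100 attempts; bout parameters are incompatible with the selection rules.",
                    id),
            class = "quiescreen_simulation_error")
    }

    lab <- with_seed_or_not(sub_seed(config$seed, 10L * a + 3L), {
      pick_in <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
      n_neu <- pick_in(config$n_neurons_range)
      n_id <- min(n_neu, pick_in(config$n_identified_range))
      picked <- roster[sample.int(nrow(roster), min(n_id, nrow(roster))), ]
      n_id <- nrow(picked)
      conf <- sample.int(5L, n_id, replace = TRUE, prob = config$confidence_dist)
      tibble::tibble(
        animal_id = id,
        neuron_id = sprintf("n%03d", seq_len(n_neu)),
        class_name = c(picked$class_name, rep(NA_character_, n_neu - n_id)),
        lr = c(picked$lr, rep(NA_character_, n_neu - n_id)),
        dv = c(picked$dv, rep(NA_character_, n_neu - n_id)),
        confidence = c(conf, rep(NA_integer_, n_neu - n_id)))
    })
    tr <- generate_neural_traces(ann$quiescent, lab, config$effect_map,
                                 config$baseline_mean, config$noise_sd,
                                 seed = sub_seed(config$seed, 10L * a + 4L),
                                 animal_id = id)
    tr$time_s <- volume_times[tr$t_index + 1L]
    behavior[[a]] <- beh; annotation[[a]] <- ann
    traces[[a]] <- tr; labels[[a]] <- lab
  }
  ann_all <- dplyr::bind_rows(annotation)
  attr(ann_all, "sample_rate_hz") <-
    stats::setNames(rep(config$sample_rate_hz, config$n_animals),
                    sprintf("animal_%d", seq_len(config$n_animals)))
  structure(list(behavior = dplyr::bind_rows(behavior),
                 annotation = ann_all,
                 traces = dplyr::bind_rows(traces),
                 labels = dplyr::bind_rows(labels),
                 effect_map = config$effect_map,
                 config = config),
            class = "quiescence_dataset")
}

#' @export
print.quiescence_dataset <- function(x, ...) {
  qf <- quiescent_fraction(x$annotation)
  cat(sprintf("<quiescence_dataset> %d animal(s), %d neurons, %d trace points\n",
              dplyr::n_distinct(x$labels$animal_id), nrow(x$labels), nrow(x$traces)))
  cat(sprintf("  quiescent fraction per animal: %s\n",
              paste(sprintf("%.2f", qf$fraction), collapse = ", ")))
  invisible(x)
}
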