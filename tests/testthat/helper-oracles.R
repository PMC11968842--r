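# Independent oracles and small fixture builders, written as plain loops so
# they share no code path with the package internals.

# Brute-force maximal-run enumerator: explicit index scan over a logical
# sub-threshold vector, returning 0-based half-open [start, end) intervals of
# runs strictly longer than min_duration_s.
oracle_bouts <- function(sub, sample_rate_hz, min_duration_s) {
  sub[is.na(sub)] <- FALSE
  n <- length(sub)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (sub[i]) {
      j <- i
      while (j < n && sub[j + 1L]) j <- j + 1L
      if ((j - i + 1L) / sample_rate_hz > min_duration_s) {
        # 1-based inclusive [i, j] becomes 0-based half-open [i-1, j)
        out[[length(out) + 1L]] <- c(start = i - 1L, end = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Behavior table whose sub-threshold pattern is exactly `sub`.
behavior_from_sub <- function(sub, sample_rate_hz = 2, animal_id = "a1",
                              criteria = quiescreen::bout_criteria()) {
  n <- length(sub)
  tibble::tibble(
    animal_id = animal_id,
    time_s = (seq_len(n) - 1L) / sample_rate_hz,
    speed_mm_s = ifelse(sub, 0, criteria$speed_max * 5),
    curvature_deriv_rad_s = 0,
    pumping_hz = 0)
}

# Hand step-up Benjamini-Hochberg, independent of stats::p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m < 2) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# A tiny multi-animal dataset configuration used across tests.
tiny_config <- function(seed = 1, ...) {
  quiescreen::synthetic_config(
    n_animals = 2, duration_s = 120, sample_rate_hz = 4,
    n_neurons_range = c(12, 15), n_identified_range = c(8, 12),
    class_catalog = quiescreen::default_class_catalog(10, frac_lr_paired = 0.5,
                                                     frac_dv = 0.2),
    seed = seed, ...)
}

# Screen-study configuration: every catalog class identified in every animal
# so that (after the confidence filter) at least 100 classes are testable.
study_config <- function(seed, effect_map = NULL, n_classes = 120) {
  quiescreen::synthetic_config(
    n_animals = 8, duration_s = 120, sample_rate_hz = 4,
    n_neurons_range = c(n_classes, n_classes + 20),
    n_identified_range = c(n_classes, n_classes),
    class_catalog = quiescreen::default_class_catalog(n_classes,
                                                     frac_lr_paired = 0,
                                                     frac_dv = 0),
    noise_sd = 0.05, effect_map = effect_map, seed = seed)
}
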