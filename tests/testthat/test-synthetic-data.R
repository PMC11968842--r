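test_that("state sequences follow the two-state stationary distribution", {
  # symmetric chain: iid fair coin, stationary fraction 1/2
  s <- generate_state_sequence(0.5, 0.5, 1e5, seed = 1)
  expect_lt(abs(mean(s) - 0.5), 3 * 0.5 / sqrt(1e5))
  # asymmetric chain: closed-form stationary fraction p_enter/(p_enter+p_exit),
  # sampling error inflated by the chain autocorrelation rho = 1 - p_enter - p_exit
  p_enter <- 0.02; p_exit <- 0.1; n <- 1e6
  s2 <- generate_state_sequence(p_enter, p_exit, n, seed = 2)
  pi_q <- p_enter / (p_enter + p_exit)
  rho <- 1 - p_enter - p_exit
  se <- sqrt(pi_q * (1 - pi_q) * (1 + rho) / (1 - rho) / n)
  expect_lt(abs(mean(s2) - pi_q), 3 * se)
})

test_that("a vanishing entry probability with forced active start stays active", {
  s <- generate_state_sequence(1e-9, 0.5, 1e4, seed = 3, init = 0)
  expect_true(all(s == 0L))
  expect_error(generate_state_sequence(0, 0.5, 10), class = "quiescreen_parameter_error")
  expect_error(generate_state_sequence(0.5, NaN, 10), class = "quiescreen_parameter_error")
  expect_error(generate_state_sequence(0.5, 0.5, 0), class = "quiescreen_parameter_error")
})

test_that("state generation is deterministic under a seed", {
  expect_identical(generate_state_sequence(0.05, 0.2, 1000, seed = 9),
                   generate_state_sequence(0.05, 0.2, 1000, seed = 9))
})

test_that("generated behavior channels encode the latent state exactly on long runs", {
  # all-quiescent latent sequence -> one bout spanning the recording
  beh_q <- generate_behavior_channels(rep(1L, 240), 4, seed = 4)
  bouts <- detect_quiescence_bouts(beh_q)
  expect_equal(nrow(bouts), 1L)
  expect_equal(c(bouts$start, bouts$end), c(0L, 240L))
  # all-active -> zero bouts
  beh_a <- generate_behavior_channels(rep(0L, 240), 4, seed = 5)
  expect_equal(nrow(detect_quiescence_bouts(beh_a)), 0L)
  # random latent sequence: the detected state matches the latent state on
  # every step inside a latent run longer than the minimum duration
  latent <- generate_state_sequence(0.05, 0.05, 1000, seed = 6)
  beh <- generate_behavior_channels(latent, 4, seed = 7)
  got <- annotate_quiescence(beh)$quiescent
  r <- rle(latent)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  long_q <- r$values == 1L & r$lengths / 4 > 8
  for (k in which(long_q)) {
    expect_true(all(got[starts[k]:ends[k]] == 1L))
  }
  expect_true(all(got[latent == 0L] == 0L))  # active steps never quiescent
})

test_that("injected effects produce the analytically expected QMI", {
  state <- generate_state_sequence(0.05, 0.1, 480, seed = 8)
  labels <- tibble::tibble(neuron_id = "n1", class_name = "X", lr = "", dv = "",
                           confidence = 5L)
  # effect 0, no noise -> constant trace, QMI exactly 0
  tr0 <- generate_neural_traces(state, labels, noise_sd = 0, seed = 1)
  d0 <- dplyr::group_by(tr0, neuron_id) |> normalize_traces(value = f)
  d0$quiescent <- state[d0$t_index + 1L]
  expect_equal(compute_qmi(dplyr::group_by(d0, neuron_id))$qmi, 0)
  # positive effect, no noise -> positive QMI
  trp <- generate_neural_traces(state, labels, effect_map = c(X = 0.4),
                                noise_sd = 0, seed = 1)
  dp <- dplyr::group_by(trp, neuron_id) |> normalize_traces(value = f)
  dp$quiescent <- state[dp$t_index + 1L]
  expect_gt(compute_qmi(dplyr::group_by(dp, neuron_id))$qmi, 0)
})

test_that("mean recovered QMI under noise matches the noise-free oracle", {
  # exact noise-free QMI of a trace B(1 + d*s) after mean normalization is
  # d / (1 + d * mean(s)); average over 50 seeds and compare within 2 SE
  d <- 0.2; noise_sd <- 0.05
  labels <- tibble::tibble(neuron_id = "n1", class_name = "X", lr = "", dv = "",
                           confidence = 5L)
  got <- exact <- numeric(50)
  for (k in 1:50) {
    state <- generate_state_sequence(0.02, 0.04, 480, seed = 1000 + k)
    if (sum(state) == 0 || sum(state) == 480) next
    tr <- generate_neural_traces(state, labels, effect_map = c(X = d),
                                 noise_sd = noise_sd, seed = 2000 + k)
    dd <- dplyr::group_by(tr, neuron_id) |> normalize_traces(value = f)
    dd$quiescent <- state[dd$t_index + 1L]
    got[k] <- compute_qmi(dplyr::group_by(dd, neuron_id))$qmi
    exact[k] <- d / (1 + d * mean(state))
  }
  keep <- exact != 0
  se <- sd(got[keep] - exact[keep]) / sqrt(sum(keep))
  expect_lt(abs(mean(got[keep]) - mean(exact[keep])), 2 * se)
})

test_that("fitting a chain to generated sequences recovers the parameters", {
  p_enter <- 0.05; p_exit <- 0.2
  s <- generate_state_sequence(p_enter, p_exit, 1e5, seed = 10)
  fit <- fit_markov_chain(tibble::tibble(quiescent = s))
  n0 <- sum(s[-length(s)] == 0L); n1 <- sum(s[-length(s)] == 1L)
  expect_lt(abs(fit$p_enter - p_enter), 3 * sqrt(p_enter * (1 - p_enter) / n0))
  expect_lt(abs(fit$p_exit - p_exit), 3 * sqrt(p_exit * (1 - p_exit) / n1))
})

test_that("simulated datasets satisfy their invariants and reproduce under seed", {
  ds <- simulate_quiescence_dataset(tiny_config(seed = 21))
  # ground truth is exactly recoverable from the behavior channels
  redetected <- annotate_quiescence(ds$behavior, ds$config$criteria)
  volume_times <- unique(ds$annotation$time_s)
  realigned <- align_annotation(redetected, volume_times, ds$config$criteria)
  expect_equal(realigned$quiescent, ds$annotation$quiescent)
  # identified labels reference the catalog, confidence 1-5, identified <= segmented
  lab <- ds$labels[!is.na(ds$labels$class_name), ]
  expect_true(all(lab$class_name %in% ds$config$class_catalog$class_name))
  expect_true(all(lab$confidence %in% 1:5))
  counts <- dplyr::count(ds$labels, animal_id)
  expect_true(all(counts$n >= ds$config$n_neurons_range[1] &
                    counts$n <= ds$config$n_neurons_range[2]))
  # traces are non-negative and complete
  expect_true(all(ds$traces$f >= 0))
  expect_equal(nrow(ds$traces), nrow(ds$labels) * ds$config$n_steps)
  # full determinism under the root seed
  ds2 <- simulate_quiescence_dataset(tiny_config(seed = 21))
  expect_identical(ds$traces, ds2$traces)
  expect_identical(ds$behavior, ds2$behavior)
  expect_identical(ds$labels, ds2$labels)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synthetic_config(p_enter = 1.2), class = "quiescreen_parameter_error")
  expect_error(synthetic_config(duration_s = 100.3, sample_rate_hz = 3),
               class = "quiescreen_parameter_error")
  expect_error(synthetic_config(n_identified_range = c(40, 200)),
               class = "quiescreen_parameter_error")
  expect_error(synthetic_config(baseline_mean = 0), class = "quiescreen_parameter_error")
  expect_error(synthetic_config(effect_map = c(NOPE = 0.3)),
               class = "quiescreen_parameter_error")
})
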