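test_that("compute_qmi evaluates the defining difference of means", {
  expect_equal(compute_qmi(tibble::tibble(f_norm = c(2, 0),
                                          quiescent = c(1L, 0L)))$qmi, 2)
  expect_equal(compute_qmi(tibble::tibble(f_norm = rep(1, 8),
                                          quiescent = rep(c(1L, 0L), 4)))$qmi, 0)
  # state-label inversion negates the QMI
  set.seed(2)
  d <- tibble::tibble(f_norm = runif(60), quiescent = rbinom(60, 1, 0.3))
  expect_equal(compute_qmi(dplyr::mutate(d, quiescent = 1L - quiescent))$qmi,
               -compute_qmi(d)$qmi)
  # invariance to positive rescaling of the raw fluorescence via normalization
  raw <- tibble::tibble(f = runif(60, 0.5, 2), quiescent = rbinom(60, 1, 0.4))
  q1 <- compute_qmi(normalize_traces(raw, value = f))
  q2 <- compute_qmi(normalize_traces(dplyr::mutate(raw, f = f * 37), value = f))
  expect_equal(q1$qmi, q2$qmi)
  # excluded (NA) points participate in neither mean
  d_na <- tibble::tibble(f_norm = c(2, NA, 0, 4), quiescent = c(1L, 1L, 0L, 1L))
  expect_equal(compute_qmi(d_na), tibble::tibble(qmi = 3, n_quiescent = 2L,
                                                 n_active = 1L))
  # undefined QMI (single-state recording) drops the observation with a warning
  expect_warning(out <- compute_qmi(tibble::tibble(f_norm = 1:3,
                                                   quiescent = c(1L, 1L, 1L))),
                 "undefined")
  expect_equal(nrow(out), 0L)
})

test_that("the Markov fit matches hand-counted transitions", {
  fit <- fit_markov_chain(tibble::tibble(quiescent = c(0L, 0L, 1L, 1L, 0L)))
  expect_equal(unname(fit$transition_matrix),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(unname(fit$stationary), c(0.5, 0.5))
  # stationary is the left eigenvector; rows are stochastic
  expect_equal(unname(fit$stationary %*% fit$transition_matrix),
               matrix(fit$stationary, 1))
  expect_equal(rowSums(fit$transition_matrix), c(active = 1, quiescent = 1))
  # pooling across animals adds counts
  two <- tibble::tibble(animal_id = rep(c("a", "b"), each = 3),
                        quiescent = c(0L, 1L, 1L, 1L, 0L, 0L))
  t2 <- tidy(fit_markov_chain(two))
  expect_equal(sum(t2$n), 4)
  # an unvisited state with zero pseudocount is a degenerate fit
  expect_error(fit_markov_chain(tibble::tibble(quiescent = rep(0L, 10))),
               class = "quiescreen_degenerate_fit_error")
  expect_silent(fit_markov_chain(tibble::tibble(quiescent = rep(0L, 10)),
                                 pseudocount = 0.5))
})

test_that("empirical p-values follow the smaller-tail rank rule", {
  sims <- 1:10
  expect_equal(empirical_pvalue(8.5, sims), 0.2)    # min(2, 8) / 10
  expect_equal(empirical_pvalue(0, sims), 0.1)      # floored at one count
  expect_equal(empirical_pvalue(11, sims), 0.1)
  expect_equal(empirical_pvalue(5, rep(5, 10)), 1)  # degenerate ties
  expect_equal(empirical_pvalue(3, sims, tail = "doubled"), 0.6)
  expect_error(empirical_pvalue(1, numeric(0)), class = "quiescreen_input_error")
  # invariance under a joint strictly monotone transform
  set.seed(4)
  for (k in 1:20) {
    sims_r <- rnorm(97)
    real <- rnorm(1)
    f <- function(x) exp(2 * x) - 5
    expect_identical(empirical_pvalue(real, sims_r),
                     empirical_pvalue(f(real), f(sims_r)))
  }
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(bh_adjust(0.01)$q_value, 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$q_value, rep(0.04, 4))
  set.seed(6)
  for (k in 1:10) {
    p <- runif(sample(3:40, 1))^2
    got <- bh_adjust(p)
    expect_equal(got$q_value, oracle_bh(p))
    # monotone non-decreasing in sorted-p order
    expect_true(all(diff(got$q_value[order(p)]) >= -1e-12))
    expect_true(all(got$q_value >= got$p_value))
    expect_equal(got$significant, got$q_value <= 0.05)
  }
  expect_error(bh_adjust(c(0.5, 0)), class = "quiescreen_input_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "quiescreen_input_error")
})

make_toy_units <- function(states, classes, seed = 31) {
  # states: named list animal -> 0/1 vector; classes: tibble(class_name, animals)
  set.seed(seed)
  rows <- list()
  for (k in seq_len(nrow(classes))) {
    for (a in classes$animals[[k]]) {
      n_t <- length(states[[a]])
      f <- runif(n_t, 0.5, 1.5)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        animal_id = a, unit_id = paste(a, classes$class_name[k], sep = "|"),
        class_name = classes$class_name[k], dv = "",
        t_index = seq_len(n_t) - 1L, f_norm = f / mean(f))
    }
  }
  dplyr::bind_rows(rows)
}

test_that("null simulation is deterministic, centered, and exact for constant traces", {
  states <- list(a1 = rep(c(0L, 1L), times = c(150, 90)),
                 a2 = rep(c(1L, 0L, 1L), times = c(40, 160, 40)))
  ann <- tibble::tibble(
    animal_id = rep(names(states), each = 240),
    time_s = rep((0:239) / 4, 2),
    quiescent = c(states$a1, states$a2),
    bout = NA_integer_)
  null <- fit_markov_chain(ann, n_sims = 200, seed = 77)
  units <- make_toy_units(states,
                          tibble::tibble(class_name = c("A", "B"),
                                         animals = list(c("a1", "a2"), "a1")))
  s1 <- simulate_null_qmis(units, null)
  s2 <- simulate_null_qmis(units, null)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2 * 200)
  # constant traces: every simulated mean QMI is exactly 0
  const <- dplyr::mutate(units, f_norm = 1)
  expect_true(all(simulate_null_qmis(const, null)$mean_qmi == 0))
  # for a state-independent trace and a symmetric chain the simulated QMI
  # distribution is symmetric about 0
  sym_null <- fit_markov_chain(
    tibble::tibble(quiescent = rep(c(0L, 1L), 50)), n_sims = 2000, seed = 5)
  expect_equal(sym_null$p_enter, 1)  # alternating toy fit is degenerate-free
  sym_null$p_enter <- 0.5; sym_null$p_exit <- 0.5
  one <- make_toy_units(states["a1"],
                        tibble::tibble(class_name = "A", animals = list("a1")))
  sims <- simulate_null_qmis(one, sym_null)$mean_qmi
  expect_lt(abs(mean(sims)) / (sd(sims) / sqrt(length(sims))), 4)
  expect_lt(abs(mean(sims > 0) - 0.5), 4 * 0.5 / sqrt(length(sims)))
})

test_that("the full screen equals a from-scratch scripted recomputation", {
  # toy: 2 animals, 3 classes (A has an L/R pair in a1; C is under-observed),
  # one low-confidence observation that must be excluded
  set.seed(55)
  n_t <- 240
  st1 <- rep(c(0L, 1L, 0L, 1L, 0L), times = c(60, 40, 60, 50, 30))
  st2 <- rep(c(1L, 0L, 1L), times = c(50, 140, 50))
  ann <- tibble::tibble(animal_id = rep(c("a1", "a2"), each = n_t),
                        time_s = rep((0:(n_t - 1)) / 4, 2),
                        quiescent = c(st1, st2), bout = NA_integer_)
  labels <- tibble::tibble(
    animal_id = c("a1", "a1", "a1", "a1", "a2", "a2", "a2"),
    neuron_id = c("n1", "n2", "n3", "n4", "n1", "n2", "n3"),
    class_name = c("A", "A", "B", "C", "A", "B", "B"),
    lr = c("L", "R", "", "", "L", "", ""),
    dv = "",
    confidence = c(5L, 4L, 5L, 5L, 3L, 4L, 2L))  # a2/n3 fails the filter
  traces <- labels |>
    dplyr::group_by(animal_id, neuron_id) |>
    dplyr::reframe(t_index = 0:(n_t - 1),
                   f = runif(n_t, 0.5, 1.5) + 0.1 * c(st1, st2)[
                     (match(animal_id[1], c("a1", "a2")) - 1) * n_t + 1:n_t])
  cfg <- screen_config(min_observations = 2, n_sims = 300, seed = 99)
  scr <- run_screen(list(traces = traces, labels = labels, annotation = ann),
                    cfg, quiet = TRUE)

  ## ---- scripted recomputation, plain base R ----
  states <- list(a1 = st1, a2 = st2)
  keep <- labels$confidence >= 3
  norm_tr <- list()
  for (i in which(keep)) {
    key <- paste(labels$animal_id[i], labels$neuron_id[i], sep = "/")
    f <- traces$f[traces$animal_id == labels$animal_id[i] &
                    traces$neuron_id == labels$neuron_id[i]]
    norm_tr[[key]] <- f / mean(f)
  }
  # merge L/R per (animal, class): per-point mean of normalized traces
  unit_traces <- list(); unit_class <- character()
  for (a in c("a1", "a2")) for (cl in c("A", "B", "C")) {
    idx <- which(keep & labels$animal_id == a & labels$class_name == cl)
    if (length(idx) == 0) next
    mat <- sapply(idx, function(i)
      norm_tr[[paste(labels$animal_id[i], labels$neuron_id[i], sep = "/")]])
    u <- paste(a, cl, sep = "|")
    unit_traces[[u]] <- rowMeans(as.matrix(mat))
    unit_class[u] <- cl
  }
  qmi_of <- function(f, s) mean(f[s == 1]) - mean(f[s == 0])
  unit_qmi <- sapply(names(unit_traces), function(u)
    qmi_of(unit_traces[[u]], states[[substr(u, 1, 2)]]))
  tested_classes <- names(which(table(unit_class) >= 2))  # A and B, not C
  real_mean <- sapply(tested_classes, function(cl)
    mean(unit_qmi[unit_class == cl]))
  # pooled transition counts
  cnt <- matrix(0, 2, 2)
  for (s in states) for (t in seq_len(length(s) - 1))
    cnt[s[t] + 1, s[t + 1] + 1] <- cnt[s[t] + 1, s[t + 1] + 1] + 1
  p_enter <- cnt[1, 2] / sum(cnt[1, ]); p_exit <- cnt[2, 1] / sum(cnt[2, ])
  # surrogate replicates under the documented per-animal seed contract; every
  # raw draw is bout-filtered with the same strict >8 s rule (4 Hz -> a
  # quiescent run must span more than 32 samples)
  keep_long_runs <- function(s) {
    out <- integer(length(s)); i <- 1
    while (i <= length(s)) {
      if (s[i] == 1) {
        j <- i
        while (j < length(s) && s[j + 1] == 1) j <- j + 1
        if ((j - i + 1) / 4 > 8) out[i:j] <- 1
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  tested_units <- names(unit_class)[unit_class %in% tested_classes]
  sim_qmis <- matrix(NA_real_, length(tested_units), cfg$n_sims,
                     dimnames = list(tested_units))
  for (i in 1:2) {
    a <- c("a1", "a2")[i]
    withr::with_seed(quiescreen:::sub_seed(99, i), {
      for (r in seq_len(cfg$n_sims)) {
        repeat {
          s <- keep_long_runs(generate_state_sequence(p_enter, p_exit, n_t))
          if (sum(s) >= 1 && sum(s) <= n_t - 1) break
        }
        for (u in tested_units[substr(tested_units, 1, 2) == a]) {
          sim_qmis[u, r] <- qmi_of(unit_traces[[u]], s)
        }
      }
    })
  }
  sim_mean <- t(sapply(tested_classes, function(cl)
    colMeans(sim_qmis[unit_class[tested_units] == cl, , drop = FALSE])))
  p_scripted <- sapply(tested_classes, function(cl) {
    ge <- sum(sim_mean[cl, ] >= real_mean[cl])
    le <- sum(sim_mean[cl, ] <= real_mean[cl])
    max(1, min(ge, le)) / cfg$n_sims
  })
  q_scripted <- stats::setNames(oracle_bh(p_scripted), names(p_scripted))

  got <- scr$results[order(scr$results$class_name), ]
  expect_equal(got$class_name, sort(tested_classes))  # C filtered out
  expect_equal(got$mean_qmi, unname(real_mean[got$class_name]))
  expect_equal(got$p_empirical, unname(p_scripted[got$class_name]))
  expect_equal(got$q_bh, unname(q_scripted[got$class_name]))
  expect_equal(got$significant, got$q_bh <= 0.05)
  # q >= p and the heatmap matrix has an NA exactly where C/a2, B/a1 etc. are absent
  expect_true(all(got$q_bh >= got$p_empirical))
  expect_true(is.na(scr$qmi_matrix$a2[scr$qmi_matrix$class == "A"]) == FALSE)
})

test_that("classes observed fewer than four times are not tested by default", {
  cfg <- study_config(seed = 3, n_classes = 12)
  ds <- simulate_quiescence_dataset(cfg)
  # restrict one class to 3 animals by dropping its other observations
  lab <- ds$labels
  victim <- "C001"
  keep_animals <- paste0("animal_", 1:3)
  drop <- !is.na(lab$class_name) & lab$class_name == victim &
    !(lab$animal_id %in% keep_animals)
  lab$class_name[drop] <- NA
  scr <- run_screen(list(traces = ds$traces, labels = lab,
                         annotation = ds$annotation),
                    screen_config(n_sims = 50, seed = 8), quiet = TRUE)
  expect_false(victim %in% scr$results$class_name)
  expect_true(all(scr$results$n_obs >= 4))
})

test_that("screens are reproducible under a fixed seed", {
  ds <- simulate_quiescence_dataset(tiny_config(seed = 13))
  cfg <- screen_config(min_observations = 2, n_sims = 100, seed = 21)
  s1 <- run_screen(ds, cfg, quiet = TRUE)
  s2 <- run_screen(ds, cfg, quiet = TRUE)
  expect_identical(s1$results, s2$results)
  expect_identical(s1$qmi_matrix, s2$qmi_matrix)
})
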